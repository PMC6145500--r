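#' Create a pipeline configuration
#'
#' @param minReadLen,maxReadLen retained read length range, nt (18--30).
#' @param minPhred minimum mean Phred quality for a read to be kept.
#' @param precursorMinLen,precursorMaxLen precursor window length range, nt.
#' @param windowLenStep step between enumerated precursor window lengths, nt.
#' @param mfeThreshold hairpin acceptance threshold on folding MFE, kcal/mol
#'   (inclusive: a hairpin at exactly the threshold passes).
#' @param minStemPairs minimum number of base pairs in the hairpin.
#' @param minLoopSize minimum size of the single terminal loop, nt.
#' @param randfoldAlpha randomization-test significance level (strict `<`).
#' @param randfoldShuffles number of dinucleotide shuffles for the null.
#' @param minReads minimum total read support (summed over libraries; may be
#'   fractional after multi-mapper count splitting).
#' @param clusterIdentity greedy clustering identity threshold in (0, 1].
#' @param knownMirnaMaxMismatch maximum mismatches when matching a known
#'   mature miRNA reference.
#' @param seedStart,seedEnd seed region positions on the mature sequence
#'   (1-based, inclusive; the canonical seed is 2--7).
#' @param fcThreshold expression-concordance fold-change threshold
#'   (MYC / PRI).
#' @param duplexEnergyThreshold duplex-mode site threshold, kcal/mol.
#' @param alignmentScoreThreshold alignment-mode score threshold.
#' @param ddgThreshold accessibility-mode threshold on duplex energy plus
#'   site-opening cost, kcal/mol.
#' @param rngSeed integer seed used by stochastic stages (randomization test,
#'   simulation).
#' @param energyParamPath path to the energy parameter TSV; the packaged
#'   table is used when empty.
#' @return a validated [MilrConfig-class] object.
#' @examples
#' cfg <- milrConfig()
#' cfg@mfeThreshold
#' @export
milrConfig <- function(minReadLen = 18L, maxReadLen = 30L, minPhred = 20L,
                       precursorMinLen = 51L, precursorMaxLen = 150L,
                       windowLenStep = 10L,
                       mfeThreshold = -20.0, minStemPairs = 18L,
                       minLoopSize = 4L, randfoldAlpha = 0.01,
                       randfoldShuffles = 999L, minReads = 4,
                       clusterIdentity = 0.95, knownMirnaMaxMismatch = 2L,
                       seedStart = 2L, seedEnd = 7L, fcThreshold = 0.5,
                       duplexEnergyThreshold = -15.0,
                       alignmentScoreThreshold = 80.0, ddgThreshold = -5.0,
                       rngSeed = 1L, energyParamPath = "") {
  new("MilrConfig",
      minReadLen = as.integer(minReadLen), maxReadLen = as.integer(maxReadLen),
      minPhred = as.integer(minPhred),
      precursorMinLen = as.integer(precursorMinLen),
      precursorMaxLen = as.integer(precursorMaxLen),
      windowLenStep = as.integer(windowLenStep),
      mfeThreshold = mfeThreshold, minStemPairs = as.integer(minStemPairs),
      minLoopSize = as.integer(minLoopSize), randfoldAlpha = randfoldAlpha,
      randfoldShuffles = as.integer(randfoldShuffles), minReads = minReads,
      clusterIdentity = clusterIdentity,
      knownMirnaMaxMismatch = as.integer(knownMirnaMaxMismatch),
      seedStart = as.integer(seedStart), seedEnd = as.integer(seedEnd),
      fcThreshold = fcThreshold,
      duplexEnergyThreshold = duplexEnergyThreshold,
      alignmentScoreThreshold = alignmentScoreThreshold,
      ddgThreshold = ddgThreshold, rngSeed = as.integer(rngSeed),
      energyParamPath = energyParamPath)
}

configEnergyModel <- function(cfg) {
  if (nzchar(cfg@energyParamPath)) readEnergyModel(cfg@energyParamPath)
  else defaultEnergyModel()
}
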