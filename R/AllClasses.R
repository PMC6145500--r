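#' Nearest-neighbor energy model for RNA folding
#'
#' Holds the thermodynamic parameters used by [foldMFE()] and
#' [duplexEnergy()]: stacking free energies for the six allowed pair types
#' (AU, UA, CG, GC, GU, UG), size-dependent hairpin/bulge/internal-loop
#' initiation penalties (tabulated to size 30 and extrapolated beyond with
#' the Jacobson--Stockmayer logarithmic term), a linear internal-loop
#' asymmetry penalty, an affine multiloop term, and the intermolecular
#' duplex initiation energy. All energies are in kcal/mol at 37 degrees C.
#'
#' @slot stack 6x6 numeric matrix of stacking energies, rows = outer pair,
#'   columns = inner pair, dimnames over c("AU","UA","CG","GC","GU","UG").
#' @slot hairpin named numeric, loop-initiation penalty by loop size (3..30).
#' @slot bulge named numeric, bulge penalty by size (1..30).
#' @slot internal named numeric, internal-loop penalty by size (2..30).
#' @slot asymPerNt,asymMax numeric, internal-loop asymmetry term.
#' @slot mlOffset,mlBranch,mlUnpaired numeric, affine multiloop parameters.
#' @slot duplexInit numeric, intermolecular initiation penalty.
#' @slot maxLoop integer, largest interior/bulge loop considered by the DP.
#' @export
setClass("EnergyModel", representation(
  stack = "matrix", hairpin = "numeric", bulge = "numeric",
  internal = "numeric", asymPerNt = "numeric", asymMax = "numeric",
  mlOffset = "numeric", mlBranch = "numeric", mlUnpaired = "numeric",
  duplexInit = "numeric", maxLoop = "integer"))

setValidity("EnergyModel", function(object) {
  p <- c("AU", "UA", "CG", "GC", "GU", "UG")
  msg <- character(0)
  if (!identical(dim(object@stack), c(6L, 6L)) ||
      !identical(rownames(object@stack), p) ||
      !identical(colnames(object@stack), p))
    msg <- c(msg, "stack must be a 6x6 matrix with pair-type dimnames")
  wc <- c("AU", "UA", "CG", "GC")
  if (length(msg) == 0 && any(object@stack[wc, wc] > 0))
    msg <- c(msg, "Watson-Crick stack energies must be <= 0")
  if (any(object@hairpin <= 0))
    msg <- c(msg, "hairpin penalties must be positive")
  if (!identical(names(object@hairpin)[1], "3"))
    msg <- c(msg, "hairpin table must start at loop size 3")
  if (length(msg)) msg else TRUE
})

#' Secondary structure of one sequence with its minimum free energy
#'
#' Produced by [foldMFE()]. The structure is in dot-bracket notation
#' ('(' and ')' are paired bases, '.' unpaired); pairs nest (no pseudoknots).
#'
#' @slot sequence the folded sequence as supplied (DNA or RNA alphabet).
#' @slot structure dot-bracket string, same length as the sequence.
#' @slot mfe minimum free energy in kcal/mol (<= 0; 0 for unfoldable input).
#' @slot pairTable integer vector, 1-based pairing partner per position,
#'   0 for unpaired.
#' @export
setClass("FoldResult", representation(
  sequence = "character", structure = "character", mfe = "numeric",
  pairTable = "integer"))

setValidity("FoldResult", function(object) {
  msg <- character(0)
  n <- nchar(object@sequence)
  if (nchar(object@structure) != n)
    msg <- c(msg, "structure length must equal sequence length")
  if (length(object@pairTable) != n)
    msg <- c(msg, "pair table length must equal sequence length")
  if (object@mfe > 0) msg <- c(msg, "mfe must be <= 0")
  pt <- object@pairTable
  paired <- which(pt > 0)
  if (any(pt[pt[paired]] != paired))
    msg <- c(msg, "pair table is not an involution")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FoldResult", function(object) {
  cat(object@sequence, "\n", object@structure,
      sprintf(" (%.2f)\n", object@mfe), sep = "")
})

#' Pipeline configuration
#'
#' All tunable thresholds of the discovery and target-prediction pipeline,
#' with the defaults used throughout: reads of 18--30 nt with mean Phred
#' >= 20, precursor windows of 51--150 nt, hairpins with MFE <= -20 kcal/mol,
#' >= 18 base pairs, a single terminal loop of >= 4 nt, a randomization-test
#' p-value < 0.01 from 999 dinucleotide shuffles, >= 4 supporting reads,
#' 95% clustering identity, seed positions 2--7, and the target-mode
#' thresholds (duplex energy <= -15 kcal/mol, alignment score >= 80,
#' site-opening-corrected energy <= -5 kcal/mol, expression fold-change
#' threshold 0.5).
#'
#' @export
setClass("MilrConfig", representation(
  minReadLen = "integer", maxReadLen = "integer", minPhred = "integer",
  precursorMinLen = "integer", precursorMaxLen = "integer",
  windowLenStep = "integer",
  mfeThreshold = "numeric", minStemPairs = "integer", minLoopSize = "integer",
  randfoldAlpha = "numeric", randfoldShuffles = "integer",
  minReads = "numeric", clusterIdentity = "numeric",
  knownMirnaMaxMismatch = "integer", seedStart = "integer", seedEnd = "integer",
  fcThreshold = "numeric", duplexEnergyThreshold = "numeric",
  alignmentScoreThreshold = "numeric", ddgThreshold = "numeric",
  rngSeed = "integer", energyParamPath = "character"))

setValidity("MilrConfig", function(object) {
  msg <- character(0)
  if (object@minReadLen > object@maxReadLen)
    msg <- c(msg, "minReadLen must be <= maxReadLen")
  if (object@precursorMinLen < object@maxReadLen)
    msg <- c(msg, "precursorMinLen must be >= maxReadLen")
  if (object@clusterIdentity <= 0 || object@clusterIdentity > 1)
    msg <- c(msg, "clusterIdentity must be in (0, 1]")
  if (object@randfoldShuffles < 1)
    msg <- c(msg, "randfoldShuffles must be >= 1")
  if (object@seedStart >= object@seedEnd)
    msg <- c(msg, "seedStart must be < seedEnd")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic milRNA study dataset
#'
#' Describes the toy dataset emulating the statistical structure the pipeline
#' assumes: a multi-contig genome carrying planted pre-milRNA hairpins whose
#' mature arms satisfy all five selection criteria, shuffled decoy hairpin
#' loci, rRNA/tRNA/exon decoy annotation, two read libraries (MYC = mycelium,
#' PRI = primordium) with a 5'-U bias and planted contaminants, 1000-bp
#' downstream target regions carrying perfect-complement sites, and a
#' two-stage expression table with prescribed fold changes.
#'
#' @export
setClass("SimulationSpec", representation(
  nContigs = "integer", contigLen = "integer", nHairpins = "integer",
  nDecoyRrna = "integer", nDecoyTrna = "integer", nDecoyHairpins = "integer",
  nGenes = "integer", readsPerLibrary = "integer",
  fivePrimeUFraction = "numeric", plantedTargetFraction = "numeric",
  contaminantShortFraction = "numeric", contaminantLowqFraction = "numeric",
  adapter = "character", adapterFraction = "numeric",
  noiseSd = "numeric", fcMap = "numeric", nEsts = "integer",
  rngSeed = "integer"))

setValidity("SimulationSpec", function(object) {
  msg <- character(0)
  counts <- c(object@nContigs, object@contigLen, object@nHairpins,
              object@nDecoyRrna, object@nDecoyTrna, object@nDecoyHairpins,
              object@nGenes, object@readsPerLibrary, object@nEsts)
  if (any(counts < 0)) msg <- c(msg, "all counts must be >= 0")
  fr <- c(object@fivePrimeUFraction, object@plantedTargetFraction,
          object@contaminantShortFraction, object@contaminantLowqFraction,
          object@adapterFraction)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must be in [0, 1]")
  if (length(msg)) msg else TRUE
})
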