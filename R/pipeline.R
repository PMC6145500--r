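#' Run the full pipeline on a synthetic dataset
#'
#' End-to-end orchestration: simulate (or accept) a dataset, preprocess
#' both libraries, map unique reads, discover milRNA candidates, and
#' predict/filter targets of the first discovered milRNA. This is the
#' programmatic equivalent of running the simulate / preprocess / map /
#' discover / targets stages in sequence.
#'
#' @param spec a [SimulationSpec-class] (ignored when `dataset` given).
#' @param cfg a [MilrConfig-class].
#' @param dataset optional pre-generated dataset from [simulateDataset()].
#' @param targetMilrna optional mature sequence to use for target
#'   prediction; defaults to the planted mature of the first truth hairpin
#'   (falling back to the top discovered milRNA).
#' @return list with dataset, preprocessing results, library report,
#'   alignments, discovery results, and target-prediction results.
#' @export
runMilrPipeline <- function(spec = simulationSpec(), cfg = milrConfig(),
                            dataset = NULL, targetMilrna = NULL) {
  if (is.null(dataset)) dataset <- simulateDataset(spec, cfg)
  pre <- preprocessLibraries(dataset$reads, cfg, adapter = spec@adapter)
  index <- buildGenomeIndex(dataset$genome, k = cfg@minReadLen %/% 2L + 3L)
  alignments <- mapReads(pre$unique, index)
  classes <- classifyNcRNA(pre$unique, alignments, dataset$annotation)
  mapped <- pre$unique$sequence %in% alignments$sequence
  libReport <- buildLibraryReport(pre$stages, pre$unique, classes, mapped,
                                  cfg@minReadLen, cfg@maxReadLen)
  disc <- discoverMilRNAs(pre$unique, alignments, dataset$genome,
                          dataset$annotation, cfg)
  milrna <- targetMilrna
  if (is.null(milrna)) {
    # prefer the mature that planted target sites refer to
    ts <- dataset$truth[dataset$truth$kind == "target_site", , drop = FALSE]
    hp <- dataset$truth[dataset$truth$kind == "hairpin", , drop = FALSE]
    milrna <- if (nrow(ts)) ts$mature_seq[1L]
      else if (nrow(hp)) hp$mature_seq[1L]
      else if (nrow(disc$milrnas)) disc$milrnas$sequence[1L] else NULL
  }
  targets <- NULL
  if (!is.null(milrna) && nrow(dataset$expression)) {
    utr <- buildUtrDb(dataset$annotation, dataset$genome)
    # direction from the planted/observed counts (elevated stage)
    hp <- dataset$truth[dataset$truth$kind == "hairpin" &
                        dataset$truth$mature_seq == milrna, , drop = FALSE]
    dirn <- if (nrow(hp) && hp$counts_PRI[1L] > hp$counts_MYC[1L])
      "PRI_up" else "MYC_up"
    targets <- predictTargets(milrna, utr, dataset$expression, dirn, cfg)
    targets$milrna <- milrna
    targets$direction <- dirn
  }
  list(dataset = dataset, preprocess = pre, library_report = libReport,
       alignments = alignments, discovery = disc, targets = targets)
}

#' Compare discovered milRNAs against the planted truth
#'
#' @param milrnas discovery table from [discoverMilRNAs()].
#' @param truth truth table from [simulateGenome()].
#' @return list with `recovery` (fraction of planted hairpins whose exact
#'   mature sequence was recovered, among those with total counts >= 4),
#'   `n_planted`, `n_recovered`, `false_positives` (accepted matures that
#'   are neither planted matures nor decoy matures), and
#'   `decoys_recovered`.
#' @export
recoveryStats <- function(milrnas, truth, minReads = 4) {
  hp <- truth[truth$kind == "hairpin", , drop = FALSE]
  hp <- hp[hp$counts_MYC + hp$counts_PRI >= minReads, , drop = FALSE]
  dc <- truth[truth$kind == "decoy_hairpin", , drop = FALSE]
  found <- unique(milrnas$sequence)
  nRec <- sum(hp$mature_seq %in% found)
  fp <- setdiff(found, hp$mature_seq)
  decRec <- sum(dc$mature_seq %in% found)
  list(recovery = if (nrow(hp)) nRec / nrow(hp) else NaN,
       n_planted = nrow(hp), n_recovered = nRec,
       false_positives = length(setdiff(fp, dc$mature_seq)) + decRec,
       decoys_recovered = decRec)
}
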