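#' Load the bundled catalog of reported C. cinerea milRNAs
#'
#' The package ships the published catalog of predicted milRNAs of
#' Coprinopsis cinerea (mature locus, strand, sequence, printed length,
#' and per-library read counts for the mycelium and primordium stages),
#' used for internal-consistency checks and as a worked example.
#'
#' @return data.frame with id, locus, strand, sequence, length, count_MYC,
#'   count_PRI, plus parsed contig/start/end columns.
#' @export
readMilrnaCatalog <- function() {
  path <- system.file("extdata", "cinerea_milrna_catalog.tsv",
                      package = "milrscan", mustWork = TRUE)
  cat <- read.delim(path, stringsAsFactors = FALSE)
  loc <- parseLocus(cat$locus)
  cbind(cat, loc)
}

#' Internal-consistency checks of a milRNA catalog
#'
#' Two checks per row: (1) the printed length equals the length of the
#' printed mature sequence; (2) the locus span (end - start + 1 under
#' 1-based inclusive coordinates) equals the printed length. The second
#' check fails for catalog rows whose published loci are end-exclusive.
#'
#' @param cat catalog data.frame from [readMilrnaCatalog()].
#' @return list with per-row logical vectors `seq_len_ok` and
#'   `span_ok`, and the two agreement fractions.
#' @export
catalogConsistency <- function(cat) {
  seqLen <- nchar(cat$sequence)
  span <- cat$end - cat$start + 1L
  seqOk <- seqLen == cat$length
  spanOk <- span == cat$length
  list(seq_len_ok = seqOk, span_ok = spanOk,
       seq_len_fraction = mean(seqOk), span_fraction = mean(spanOk))
}
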