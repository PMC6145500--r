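# Exact-match alignment of unique reads to both genome strands via a
# k-mer position index (the zero-mismatch mapping stage).

#' Build a k-mer index over the plus strand of a genome
#'
#' @param genome named character vector of contig sequences.
#' @param k k-mer size (must not exceed the minimum read length).
#' @return an opaque index (environment) mapping each k-mer to its
#'   plus-strand positions; contigs shorter than k are skipped with a
#'   warning. Minus-strand lookups are served by querying the reverse
#'   complement of the read.
#' @export
buildGenomeIndex <- function(genome, k = 12L) {
  contigs <- names(genome)
  allKmers <- character(0)
  allCi <- integer(0)
  allSt <- integer(0)
  for (ci in seq_along(genome)) {
    s <- toupper(genome[[ci]])
    n <- nchar(s)
    if (n < k) {
      warning("contig ", contigs[ci], " shorter than k = ", k, "; skipped")
      next
    }
    starts <- seq_len(n - k + 1L)
    allKmers <- c(allKmers, substring(s, starts, starts + k - 1L))
    allCi <- c(allCi, rep.int(ci, length(starts)))
    allSt <- c(allSt, starts)
  }
  idx <- new.env(parent = emptyenv(), hash = TRUE,
                 size = max(29L, length(allKmers)))
  if (length(allKmers)) {
    sp <- split(seq_along(allKmers), allKmers)
    list2env(lapply(sp, function(r) cbind(allCi[r], allSt[r])), envir = idx)
  }
  structure(list(index = idx, k = k, contigs = contigs,
                 genome = vapply(genome, toupper, character(1))),
            class = "GenomeIndex")
}

lookupExact <- function(index, read) {
  k <- index$k
  n <- nchar(read)
  if (n < k) return(NULL)
  cand <- index$index[[substr(read, 1L, k)]]
  if (is.null(cand)) return(NULL)
  hits <- NULL
  for (r in seq_len(nrow(cand))) {
    ci <- cand[r, 1L]
    st <- cand[r, 2L]
    s <- index$genome[[ci]]
    if (st + n - 1L <= nchar(s) &&
        substr(s, st, st + n - 1L) == read)
      hits <- rbind(hits, c(ci, st))
  }
  hits
}

#' Map one read to all perfect-match loci on both strands
#'
#' Every returned locus satisfies the alignment invariant: the genome
#' subsequence at the locus (reverse-complemented for strand "-") equals
#' the read exactly. All loci are returned; no multi-hit cap is applied.
#' Minus-strand loci use plus-strand coordinates.
#'
#' @param read read sequence.
#' @param index from [buildGenomeIndex()].
#' @return data.frame with columns sequence, contig, start, end, strand
#'   (zero rows when the read does not match anywhere).
#' @export
mapRead <- function(read, index) {
  hit <- mapOne(toupper(read), index)
  out <- data.frame(sequence = rep(toupper(read), length(hit$start)),
                    contig = hit$contig, start = hit$start, end = hit$end,
                    strand = hit$strand, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# loci of one read as plain vectors (deduplicated)
mapOne <- function(read, index) {
  n <- nchar(read)
  contig <- character(0)
  start <- integer(0)
  strand <- character(0)
  plus <- lookupExact(index, read)
  if (!is.null(plus)) {
    contig <- index$contigs[plus[, 1L]]
    start <- plus[, 2L]
    strand <- rep("+", nrow(plus))
  }
  minus <- lookupExact(index, revComp(read))
  if (!is.null(minus)) {
    contig <- c(contig, index$contigs[minus[, 1L]])
    start <- c(start, minus[, 2L])
    strand <- c(strand, rep("-", nrow(minus)))
  }
  keep <- !duplicated(paste(contig, start, strand))
  list(contig = contig[keep], start = start[keep],
       end = start[keep] + n - 1L, strand = strand[keep])
}

#' Map a table of unique reads
#'
#' @param unique data.frame with a `sequence` column.
#' @param index from [buildGenomeIndex()].
#' @return data.frame of alignments (one row per read/locus, the union of
#'   [mapRead()] results).
#' @export
mapReads <- function(unique, index) {
  if (nrow(unique) == 0L)
    return(data.frame(sequence = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  hits <- lapply(toupper(unique$sequence), mapOne, index = index)
  nHit <- vapply(hits, function(h) length(h$start), integer(1))
  out <- data.frame(
    sequence = rep(toupper(unique$sequence), nHit),
    contig = unlist(lapply(hits, `[[`, "contig"), use.names = FALSE),
    start = unlist(lapply(hits, `[[`, "start"), use.names = FALSE),
    end = unlist(lapply(hits, `[[`, "end"), use.names = FALSE),
    strand = unlist(lapply(hits, `[[`, "strand"), use.names = FALSE),
    stringsAsFactors = FALSE)
  if (nrow(out) == 0L)
    out <- data.frame(sequence = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  out
}

#' Unique-read mapping rate
#'
#' @param unique unique-read table.
#' @param alignments alignment table from [mapReads()].
#' @return list with `mapped_unique` (count of unique reads with at least
#'   one alignment) and `fraction`.
#' @export
mappingRate <- function(unique, alignments) {
  mapped <- unique$sequence %in% alignments$sequence
  list(mapped_unique = sum(mapped),
       fraction = if (nrow(unique)) sum(mapped) / nrow(unique) else NaN)
}
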