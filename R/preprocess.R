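# Raw-read preprocessing: quality filter, adapter trim, length filter,
# collapapse to unique tags, ncRNA classification, library report.

#' Filter reads on mean Phred quality
#'
#' A read is kept iff its mean Phred score is at least `minPhred` (the
#' per-read reading of the "Phred score lower than 20" rule); order is
#' preserved.
#'
#' @param reads data.frame with id/sequence/quality columns (Phred+33).
#' @param minPhred minimum mean Phred score.
#' @return filtered data.frame.
#' @export
qualityFilter <- function(reads, minPhred = 20L) {
  if (nrow(reads) == 0L) return(reads)
  mq <- vapply(phredScores(reads$quality), mean, numeric(1))
  reads[mq >= minPhred, , drop = FALSE]
}

#' Trim a 3' adapter from one or more reads
#'
#' Exact matching only: if the full adapter occurs anywhere in the read the
#' read is cut at its first occurrence; otherwise, if a read suffix of at
#' least `minOverlap` nt equals a prefix of the adapter, the suffix is
#' removed. At most one trim per read.
#'
#' @param read character vector of read sequences.
#' @param adapter adapter sequence (non-empty).
#' @param minOverlap minimum suffix/prefix overlap for a partial match.
#' @return trimmed sequences.
#' @export
trimAdapter <- function(read, adapter, minOverlap = 8L) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  adapter <- toupper(adapter)
  vapply(toupper(read), function(s) {
    hit <- regexpr(adapter, s, fixed = TRUE)
    if (hit > 0) return(substr(s, 1L, hit - 1L))
    n <- nchar(s)
    maxOv <- min(n, nchar(adapter) - 1L)
    if (maxOv >= minOverlap) {
      for (ov in maxOv:minOverlap) {
        if (substr(s, n - ov + 1L, n) == substr(adapter, 1L, ov))
          return(substr(s, 1L, n - ov))
      }
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Filter reads on length
#'
#' @param reads data.frame with a sequence column (or character vector).
#' @param lo,hi inclusive length bounds (18--30 nt by default).
#' @return filtered object of the same type.
#' @export
lengthFilter <- function(reads, lo = 18L, hi = 30L) {
  if (is.character(reads)) {
    n <- nchar(reads)
    return(reads[n >= lo & n <= hi])
  }
  n <- nchar(reads$sequence)
  reads[n >= lo & n <= hi, , drop = FALSE]
}

#' Collapse per-library read streams to unique reads
#'
#' One row per distinct sequence with exact per-library counts; total
#' counts are conserved.
#'
#' @param readsByLib named list of data.frames (or character vectors of
#'   sequences), one per library.
#' @return data.frame with column `sequence` and one `count_<lib>` column
#'   per library, ordered by decreasing total count then sequence.
#' @export
collapseReads <- function(readsByLib) {
  libs <- names(readsByLib)
  seqsOf <- function(x) if (is.character(x)) x else x$sequence
  all <- unique(unlist(lapply(readsByLib, seqsOf), use.names = FALSE))
  out <- data.frame(sequence = all, stringsAsFactors = FALSE)
  for (lib in libs) {
    t <- table(seqsOf(readsByLib[[lib]]))
    out[[paste0("count_", lib)]] <-
      as.numeric(t[match(all, names(t))])
    out[[paste0("count_", lib)]][is.na(out[[paste0("count_", lib)]])] <- 0
  }
  tot <- rowSums(out[, paste0("count_", libs), drop = FALSE])
  out <- out[order(-tot, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify unique reads by overlapping non-coding RNA annotation
#'
#' A read's class is the highest-priority feature type overlapping any of
#' its alignment loci by at least 1 nt, with priority
#' rRNA > tRNA > snRNA/snoRNA > other. Unmapped reads are "other".
#'
#' @param unique data.frame of unique reads (column `sequence`).
#' @param alignments data.frame with columns sequence, contig, start, end,
#'   strand (from [mapReads()]).
#' @param annotation GRanges with `feature_type` (or NULL: everything is
#'   "other", with a warning).
#' @return named character vector class per sequence.
#' @export
classifyNcRNA <- function(unique, alignments, annotation) {
  cls <- setNames(rep("other", nrow(unique)), unique$sequence)
  if (is.null(annotation) || length(annotation) == 0L) {
    warning("no annotation supplied; all reads classified as 'other'")
    return(cls)
  }
  if (nrow(alignments) == 0L) return(cls)
  alnGr <- GenomicRanges::GRanges(alignments$contig,
                                  IRanges::IRanges(alignments$start,
                                                   alignments$end))
  hits <- GenomicRanges::findOverlaps(alnGr, annotation,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(cls)
  ft <- annotation$feature_type[S4Vectors::subjectHits(hits)]
  ft[ft %in% c("snRNA", "snoRNA")] <- "snRNA/snoRNA"
  prio <- c(rRNA = 1, tRNA = 2, `snRNA/snoRNA` = 3)
  p <- prio[ft]
  keep <- !is.na(p)
  if (!any(keep)) return(cls)
  seqs <- alignments$sequence[S4Vectors::queryHits(hits)][keep]
  p <- p[keep]
  best <- tapply(p, seqs, min)
  lab <- names(prio)[best]
  cls[names(best)] <- lab
  cls
}

#' Build the per-library summary report
#'
#' Reports the per-stage read counts (total, trimmed = after quality and
#' adapter removal, filtered = after the length filter, unique, mapped,
#' rRNA, tRNA, and 18--30 nt unique reads) plus the length histogram and
#' 5'-nucleotide frequency tables.
#'
#' @param stages named list with one entry per library, each a list with
#'   elements `total`, `trimmed`, `filtered` (integer counts).
#' @param unique collapsed unique-read table (with count columns).
#' @param classes class per sequence from [classifyNcRNA()].
#' @param mapped logical vector per unique read (>= 1 alignment).
#' @param lo,hi length-histogram range.
#' @return list with `report` (data.frame, one row per library),
#'   `length_hist` and `five_prime` data.frames.
#' @export
buildLibraryReport <- function(stages, unique, classes, mapped,
                               lo = 18L, hi = 30L) {
  libs <- names(stages)
  lens <- nchar(unique$sequence)
  first <- substr(unique$sequence, 1L, 1L)
  rows <- lapply(libs, function(lib) {
    cnt <- unique[[paste0("count_", lib)]]
    present <- cnt > 0
    data.frame(
      library = lib,
      total_reads = stages[[lib]]$total,
      trimmed_reads = stages[[lib]]$trimmed,
      filtered_reads = stages[[lib]]$filtered,
      unique_reads = sum(present),
      mapped_reads = sum(present & mapped),
      rRNA_reads = sum(present & classes[unique$sequence] == "rRNA"),
      tRNA_reads = sum(present & classes[unique$sequence] == "tRNA"),
      sRNA_reads_18_30 = sum(present & lens >= lo & lens <= hi),
      stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  stopifnot(all(report$total_reads >= report$trimmed_reads),
            all(report$trimmed_reads >= report$filtered_reads))
  hist <- data.frame(length = lo:hi)
  fp <- data.frame(nt = c("A", "C", "G", "T"))
  for (lib in libs) {
    cnt <- unique[[paste0("count_", lib)]]
    hist[[lib]] <- vapply(lo:hi, function(L) sum(cnt[lens == L]),
                          numeric(1))
    tot <- sum(cnt)
    fp[[lib]] <- vapply(c("A", "C", "G", "T"), function(b)
      if (tot > 0) sum(cnt[first == b]) / tot else 0, numeric(1))
  }
  list(report = report, length_hist = hist, five_prime = fp)
}

#' Run the full preprocessing stage on raw libraries
#'
#' Quality filter, adapter trim, length filter and collapse, returning the
#' unique-read table plus per-stage counts for the library report.
#'
#' @param rawReads named list of raw read data.frames (id/sequence/quality).
#' @param cfg a [MilrConfig-class].
#' @param adapter adapter to trim ("" to skip trimming).
#' @return list with `unique` (collapsed table) and `stages` (per-library
#'   total/trimmed/filtered counts).
#' @export
preprocessLibraries <- function(rawReads, cfg = milrConfig(),
                                adapter = "") {
  stages <- list()
  filtered <- list()
  for (lib in names(rawReads)) {
    raw <- rawReads[[lib]]
    qf <- qualityFilter(raw, cfg@minPhred)
    if (nzchar(adapter)) qf$sequence <- trimAdapter(qf$sequence, adapter)
    lf <- lengthFilter(qf, cfg@minReadLen, cfg@maxReadLen)
    stages[[lib]] <- list(total = nrow(raw), trimmed = nrow(qf),
                          filtered = nrow(lf))
    filtered[[lib]] <- lf
  }
  list(unique = collapseReads(filtered), stages = stages)
}
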