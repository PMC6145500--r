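#' Read a FASTA file
#'
#' Sequences are uppercased; both T and U are accepted and preserved as
#' read; record order follows the file. A malformed header or an empty
#' sequence raises a format error naming the offending line.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (names = identifiers, first
#'   whitespace-delimited token of the header), in file order.
#' @export
readFastaFile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (length(lines) && !hdr[1L])
    stop("FASTA format error at line 1: expected '>' header")
  starts <- which(hdr)
  if (!length(starts)) return(setNames(character(0), character(0)))
  ids <- sub("^>\\s*", "", lines[starts])
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids)))
    stop("FASTA format error at line ", starts[!nzchar(ids)][1L],
         ": empty identifier")
  ends <- c(starts[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(starts), function(k) {
    if (ends[k] < starts[k] + 1L) return("")
    paste(lines[(starts[k] + 1L):ends[k]], collapse = "")
  }, character(1))
  seqs <- toupper(gsub("\\s", "", seqs))
  if (any(!nzchar(seqs)))
    stop("FASTA format error at line ", starts[!nzchar(seqs)][1L],
         ": empty sequence for record '", ids[!nzchar(seqs)][1L], "'")
  setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
writeFastaFile <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a four-line-record FASTQ file (Phred+33)
#'
#' @param path path to a FASTQ file.
#' @return data.frame with columns `id`, `sequence`, `quality` (the raw
#'   quality string). Use [phredScores()] for per-base integer scores.
#'   Truncated records or sequence/quality length mismatches raise a format
#'   error with the record index.
#' @export
readFastqFile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("FASTQ format error: truncated record ",
         length(lines) %/% 4L + 1L)
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  idL <- lines[seq(1L, by = 4L, length.out = n)]
  seqL <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  plusL <- lines[seq(3L, by = 4L, length.out = n)]
  qualL <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- !startsWith(idL, "@")
  if (any(bad))
    stop("FASTQ format error: record ", which(bad)[1L],
         " does not start with '@'")
  bad <- !startsWith(plusL, "+")
  if (any(bad))
    stop("FASTQ format error: record ", which(bad)[1L],
         " missing '+' separator")
  bad <- nchar(seqL) != nchar(qualL)
  if (any(bad))
    stop("FASTQ format error: sequence/quality length mismatch in record ",
         which(bad)[1L])
  data.frame(id = sub("^@", "", sub("\\s.*$", "", idL)), sequence = seqL,
             quality = qualL, stringsAsFactors = FALSE)
}

#' Per-base Phred scores from a quality string
#'
#' @param quality character vector of Phred+33 quality strings.
#' @return list of integer vectors.
#' @export
phredScores <- function(quality) {
  lapply(quality, function(q) utf8ToInt(q) - 33L)
}

#' Write a FASTQ file
#'
#' @param reads data.frame with `id`, `sequence`, `quality` columns.
#' @param path output path.
#' @export
writeFastqFile <- function(reads, path) {
  if (nrow(reads) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  out <- rbind(paste0("@", reads$id), reads$sequence, "+", reads$quality)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Read a feature annotation (GFF3 or BED6)
#'
#' Loci are normalized to the package-wide convention: 1-based, inclusive,
#' with strand "+" or "-". BED input (0-based half-open) is converted at the
#' boundary; GFF3 is already 1-based inclusive. Feature types are preserved
#' verbatim (e.g. "rRNA", "tRNA", "exon", "gene", "stop_codon").
#'
#' @param path path to the annotation file.
#' @param dialect "GFF3" or "BED".
#' @return a [GenomicRanges::GRanges] with metadata columns `feature_type`
#'   and `gene_id`.
#' @export
readAnnotation <- function(path, dialect = c("GFF3", "BED")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "GFF3") {
    gr <- rtracklayer::import(path, format = "gff3")
    ft <- as.character(gr$type)
    gid <- if (!is.null(gr$ID)) as.character(gr$ID) else
      rep(NA_character_, length(gr))
    if (!is.null(gr$gene_id)) {
      has <- !is.na(gr$gene_id)
      gid[has] <- as.character(gr$gene_id[has])
    }
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    ft <- if (!is.null(gr$name)) as.character(gr$name) else
      rep("feature", length(gr))
    gid <- ft
  }
  if (any(GenomicRanges::end(gr) < GenomicRanges::start(gr)))
    stop("annotation contains an interval with end < start")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::IRanges(GenomicRanges::start(gr),
                              GenomicRanges::end(gr)),
    strand = strand)
  out$feature_type <- ft
  out$gene_id <- gid
  out
}

#' Write an annotation GRanges as GFF3 or BED6
#'
#' Inverse of [readAnnotation()]; BED output converts back to 0-based
#' half-open coordinates.
#'
#' @param gr GRanges with `feature_type` and `gene_id` metadata columns.
#' @param path output path.
#' @param dialect "GFF3" or "BED".
#' @export
writeAnnotation <- function(gr, path, dialect = c("GFF3", "BED")) {
  dialect <- match.arg(dialect)
  if (dialect == "GFF3") {
    lines <- c("##gff-version 3",
               sprintf("%s\tmilrscan\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                       as.character(GenomicRanges::seqnames(gr)),
                       gr$feature_type,
                       GenomicRanges::start(gr), GenomicRanges::end(gr),
                       as.character(GenomicRanges::strand(gr)), gr$gene_id))
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     as.character(GenomicRanges::seqnames(gr)),
                     GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                     gr$feature_type,
                     as.character(GenomicRanges::strand(gr)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write folded records in Vienna-style dot-bracket format
#'
#' Each record is written as three lines: `>id`, the sequence, and the
#' structure followed by the MFE in parentheses with two decimals.
#'
#' @param records data.frame with columns `id`, `sequence`, `structure`,
#'   `mfe`.
#' @param path output path.
#' @export
writeDotBracket <- function(records, path) {
  if (nrow(records)) {
    for (i in seq_len(nrow(records))) {
      if (nchar(records$structure[i]) != nchar(records$sequence[i]))
        stop("structure/sequence length mismatch for record ",
             records$id[i])
      dotBracketToPairTable(records$structure[i])  # errors if unbalanced
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(c(paste0(">", records$id[i]), records$sequence[i],
                 sprintf("%s (%.2f)", records$structure[i],
                         records$mfe[i])), con)
  }
  invisible(path)
}
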