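# milRNA candidate discovery: precursor-window extension, the five
# selection criteria, known-miRNA matching, identity clustering, locus
# classification, naming, and reporting.

#' Enumerate precursor windows around one read alignment
#'
#' For each window length L in the configured range (stepping by
#' `windowLenStep`, with the minimum and maximum always included), three
#' placements are generated in read orientation: read at the 5' edge,
#' centered, and at the 3' edge. Windows are truncated at contig bounds;
#' truncated windows shorter than the minimum precursor length, or no
#' longer containing the read, are dropped; duplicates are removed.
#'
#' @param alignment one-row alignment data.frame (sequence, contig, start,
#'   end, strand).
#' @param genome named character vector of contigs.
#' @param cfg a [MilrConfig-class].
#' @return data.frame with columns contig, start, end, strand,
#'   mature_offset (1-based position of the read within the window, in
#'   strand orientation), window_len.
#' @export
enumeratePrecursorWindows <- function(alignment, genome, cfg = milrConfig()) {
  contigLen <- nchar(genome[[alignment$contig]])
  r <- alignment$end - alignment$start + 1L
  if (r > cfg@precursorMaxLen)
    stop("read longer than the maximum precursor length")
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mature_offset = integer(0), window_len = integer(0),
                      stringsAsFactors = FALSE)
  if (contigLen < cfg@precursorMinLen) {
    warning("contig ", alignment$contig,
            " shorter than the minimum precursor length")
    return(empty)
  }
  rows <- list()
  for (L in windowLengths(cfg)) {
    if (L < r) next
    for (f in unique(c(0L, (L - r) %/% 2L, L - r))) {
      if (alignment$strand == "+") {
        ws <- alignment$start - f
        we <- ws + L - 1L
      } else {
        we <- alignment$end + f
        ws <- we - L + 1L
      }
      ws <- max(1L, ws)
      we <- min(contigLen, we)
      if (we - ws + 1L < cfg@precursorMinLen) next
      if (ws > alignment$start || we < alignment$end) next
      off <- if (alignment$strand == "+") alignment$start - ws + 1L
             else we - alignment$end + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        contig = alignment$contig, start = ws, end = we,
        strand = alignment$strand, mature_offset = off,
        window_len = we - ws + 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

# Fold one window and assemble a hairpin candidate record.
buildCandidate <- function(window, readLen, genome, model, counts) {
  seq <- substr(genome[[window$contig]], window$start, window$end)
  if (window$strand == "-") seq <- revComp(seq)
  fold <- foldMFE(seq, model)
  loops <- countHairpinLoops(fold)
  st <- stemStatistics(fold, window$mature_offset,
                       window$mature_offset + readLen - 1L)
  list(contig = window$contig, start = window$start, end = window$end,
       strand = window$strand, precursor_seq = seq, fold = fold,
       mature_offset = window$mature_offset, mature_len = readLen,
       total_pairs = st$total_pairs, mature_in_stem = st$mature_in_stem,
       arm = st$arm, n_loops = loops$n_terminal_loops,
       loop_size = if (loops$n_terminal_loops >= 1L)
         loops$loop_sizes[1L] else 0L,
       randfold_pvalue = NA_real_, read_counts = counts)
}

#' Apply the five selection criteria to a hairpin candidate
#'
#' Pass requires: folding MFE at or below the threshold (inclusive), at
#' least the minimum number of base pairs with the mature read inside the
#' stem, exactly one terminal loop of at least the minimum size, a
#' randomization-test p-value strictly below alpha, and total read support
#' of at least the minimum (summed over libraries; fractional counts from
#' multi-mapper splitting allowed). Failures are tagged MFE, STEM, LOOP,
#' RANDFOLD, READS.
#'
#' @param candidate candidate record (see [discoverMilRNAs()]); a missing
#'   (NA) randomization p-value fails the RANDFOLD criterion.
#' @param cfg a [MilrConfig-class].
#' @return list with `pass` (logical) and `failures` (character vector of
#'   violated tags).
#' @export
criteriaCheck <- function(candidate, cfg = milrConfig()) {
  fails <- character(0)
  if (!(candidate$fold@mfe <= cfg@mfeThreshold)) fails <- c(fails, "MFE")
  if (candidate$total_pairs < cfg@minStemPairs ||
      !isTRUE(candidate$mature_in_stem)) fails <- c(fails, "STEM")
  if (candidate$n_loops != 1L || candidate$loop_size < cfg@minLoopSize)
    fails <- c(fails, "LOOP")
  p <- candidate$randfold_pvalue
  if (is.na(p) || !(p < cfg@randfoldAlpha)) fails <- c(fails, "RANDFOLD")
  if (sum(candidate$read_counts) < cfg@minReads) fails <- c(fails, "READS")
  list(pass = length(fails) == 0L, failures = fails)
}

# structural part of the criteria (1-3), used to gate the expensive
# randomization test
structuralPass <- function(candidate, cfg) {
  candidate$fold@mfe <= cfg@mfeThreshold &&
    candidate$total_pairs >= cfg@minStemPairs &&
    isTRUE(candidate$mature_in_stem) &&
    candidate$n_loops == 1L && candidate$loop_size >= cfg@minLoopSize
}

#' Select the best precursor window among passing candidates
#'
#' Lowest MFE wins; ties go to the shortest precursor, then to the
#' leftmost start.
#'
#' @param candidates list of candidate records.
#' @return the selected candidate; error on empty input.
#' @export
selectBestWindow <- function(candidates) {
  if (!length(candidates)) stop("no passing candidate to select")
  key <- vapply(candidates, function(cc)
    c(cc$fold@mfe, cc$end - cc$start + 1L, cc$start), numeric(3))
  ord <- order(key[1L, ], key[2L, ], key[3L, ])
  candidates[[ord[1L]]]
}

#' Match a mature sequence against a known-miRNA reference
#'
#' Ungapped comparison allowing an alignment offset of up to 2 nt in
#' either direction; the best reference with at most `maxMm` mismatches
#' over the overlap (and an overlap within 2 nt of the shorter sequence)
#' is returned, or NA when none qualifies ("novel").
#'
#' @param mature mature sequence.
#' @param reference named character vector of reference mature sequences
#'   (e.g. from [readFastaFile()]); may be empty.
#' @param maxMm maximum mismatches.
#' @return reference identifier or NA_character_.
#' @export
matchKnown <- function(mature, reference, maxMm = 2L) {
  if (!length(reference)) return(NA_character_)
  mature <- chartr("U", "T", toupper(mature))
  best <- NA_character_
  bestMm <- maxMm + 1L
  for (i in seq_along(reference)) {
    ref <- chartr("U", "T", toupper(reference[[i]]))
    for (shift in -2:2) {
      # mature position p aligns with ref position p + shift
      p1 <- max(1L, 1L - shift)
      p2 <- min(nchar(mature), nchar(ref) - shift)
      if (p2 < p1) next
      ov <- p2 - p1 + 1L
      if (ov < min(nchar(mature), nchar(ref)) - 2L) next
      a <- strsplit(substr(mature, p1, p2), "")[[1]]
      b <- strsplit(substr(ref, p1 + shift, p2 + shift), "")[[1]]
      mm <- sum(a != b)
      if (mm <= maxMm && mm < bestMm) {
        bestMm <- mm
        best <- names(reference)[i]
      }
    }
  }
  best
}

#' Greedy identity clustering of mature sequences
#'
#' Sequences are processed by descending total count (ties
#' lexicographically); each joins the first existing cluster whose
#' representative has identity >= the threshold, where identity =
#' 1 - editDistance / max(length), otherwise it founds a new cluster.
#'
#' @param sequences character vector of mature sequences.
#' @param counts numeric total counts (same length).
#' @param identity threshold in (0, 1].
#' @return integer cluster ids in input order (1 = first-founded cluster).
#' @export
clusterCandidates <- function(sequences, counts, identity = 0.95) {
  ord <- order(-counts, sequences)
  reps <- character(0)
  assign <- integer(length(sequences))
  for (i in ord) {
    s <- sequences[i]
    placed <- FALSE
    for (ci in seq_along(reps)) {
      d <- adist(s, reps[ci])[1L, 1L]
      if (1 - d / max(nchar(s), nchar(reps[ci])) >= identity) {
        assign[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, s)
      assign[i] <- length(reps)
    }
  }
  assign
}

#' Classify a mature locus against the annotation
#'
#' Priority rRNA > tRNA > exon > intergenic, by >= 1-nt overlap
#' (strand-blind).
#'
#' @param loci data.frame with contig, start, end columns.
#' @param annotation GRanges with `feature_type`.
#' @return character vector of classifications.
#' @export
classifyLocus <- function(loci, annotation) {
  out <- rep("intergenic", nrow(loci))
  if (is.null(annotation) || length(annotation) == 0L || nrow(loci) == 0L)
    return(out)
  gr <- GenomicRanges::GRanges(loci$contig,
                               IRanges::IRanges(loci$start, loci$end))
  hits <- GenomicRanges::findOverlaps(gr, annotation, ignore.strand = TRUE)
  if (!length(hits)) return(out)
  prio <- c(rRNA = 1, tRNA = 2, exon = 3)
  ft <- annotation$feature_type[S4Vectors::subjectHits(hits)]
  p <- prio[ft]
  keep <- !is.na(p)
  if (!any(keep)) return(out)
  q <- S4Vectors::queryHits(hits)[keep]
  p <- p[keep]
  best <- tapply(p, q, min)
  out[as.integer(names(best))] <- names(prio)[best]
  out
}

#' Assign milRNA identifiers
#'
#' Ids follow the cci-milR naming scheme: clusters are numbered by their
#' first genomic occurrence (contig order, then start); members of one
#' cluster at distinct precursor loci receive letter suffixes a, b, c ...
#' by position; when both arms of one precursor are recovered the ids gain
#' "-5p"/"-3p" suffixes.
#'
#' @param df data.frame with columns contig, start, end, strand (mature
#'   locus), precursor_start, precursor_end, arm, cluster.
#' @param contigOrder contig names in genome order (controls numbering).
#' @param prefix id prefix.
#' @return character vector of ids in input order.
#' @export
assignNames <- function(df, contigOrder = NULL, prefix = "cci-milR") {
  n <- nrow(df)
  if (n == 0L) return(character(0))
  if (is.null(contigOrder)) contigOrder <- sort(unique(df$contig))
  cidx <- match(df$contig, contigOrder)
  pos <- order(cidx, df$start, df$end, df$strand)
  posRank <- integer(n)
  posRank[pos] <- seq_len(n)
  # cluster numbering by first occurrence
  firstOcc <- tapply(posRank, df$cluster, min)
  clusterNum <- setNames(rank(firstOcc, ties.method = "first"),
                         names(firstOcc))
  # precursor locus key: distinct loci within a cluster get letters; both
  # arms recovered from one precursor (in any cluster) get -5p/-3p
  locusKey <- paste(df$contig, df$precursor_start, df$precursor_end,
                    df$strand, sep = ":")
  bothArms <- vapply(seq_len(n), function(i) {
    share <- which(locusKey == locusKey[i])
    length(share) > 1L && length(unique(df$arm[share])) > 1L
  }, logical(1))
  ids <- character(n)
  for (cl in unique(df$cluster)) {
    sel <- which(df$cluster == cl)
    locs <- unique(locusKey[sel][order(posRank[sel])])
    useLetters <- length(locs) > 1L
    for (i in sel) {
      letter <- if (useLetters)
        letters[match(locusKey[i], locs)] else ""
      armSuffix <- if (bothArms[i]) paste0("-", df$arm[i]) else ""
      ids[i] <- paste0(prefix, "-", clusterNum[[as.character(cl)]],
                       letter, armSuffix)
    }
  }
  ids
}

#' Run milRNA discovery over mapped unique reads
#'
#' Implements the prediction procedure: multi-mapper counts are split
#' evenly over loci; loci with total (split) support below the read
#' criterion are dropped; precursor windows are enumerated and folded; the
#' structural criteria (MFE, stem, loop) gate the randomization test,
#' which runs on candidate windows in best-first order until one passes;
#' accepted candidates are deduplicated per (mature, locus), matched
#' against the known reference, clustered at 95% identity, classified,
#' and named.
#'
#' @param unique collapsed unique-read table from [preprocessLibraries()].
#' @param alignments alignment table from [mapReads()].
#' @param genome named character vector of contigs.
#' @param annotation GRanges annotation (may be NULL).
#' @param cfg a [MilrConfig-class].
#' @param knownRef named character vector of known mature miRNAs (may be
#'   empty: everything is novel).
#' @param model an [EnergyModel-class]; configured default when `NULL`.
#' @return list with `milrnas` (report data.frame), `candidates` (accepted
#'   candidate records) and `n_evaluated` (loci that reached folding).
#' @export
discoverMilRNAs <- function(unique, alignments, genome, annotation = NULL,
                            cfg = milrConfig(),
                            knownRef = character(0), model = NULL) {
  if (is.null(model)) model <- configEnergyModel(cfg)
  libs <- sub("^count_", "", grep("^count_", names(unique), value = TRUE))
  counts <- unique[, paste0("count_", libs), drop = FALSE]
  rownames(counts) <- unique$sequence
  nLoci <- table(alignments$sequence)
  accepted <- list()
  nEval <- 0L
  for (ai in seq_len(nrow(alignments))) {
    aln <- alignments[ai, , drop = FALSE]
    r <- nchar(aln$sequence)
    if (r < cfg@minReadLen || r > cfg@maxReadLen) next
    k <- as.integer(nLoci[[aln$sequence]])
    cnt <- as.numeric(counts[aln$sequence, ]) / k
    names(cnt) <- libs
    if (sum(cnt) < cfg@minReads) next       # read-support gate first
    windows <- enumeratePrecursorWindows(aln, genome, cfg)
    if (!nrow(windows)) next
    nEval <- nEval + 1L
    cands <- lapply(seq_len(nrow(windows)), function(w)
      buildCandidate(windows[w, , drop = FALSE], r, genome, model, cnt))
    cands <- Filter(function(cc) structuralPass(cc, cfg), cands)
    if (!length(cands)) next
    key <- vapply(cands, function(cc)
      c(cc$fold@mfe, cc$end - cc$start + 1L, cc$start), numeric(3))
    ord <- order(key[1L, ], key[2L, ], key[3L, ])
    chosen <- NULL
    for (w in ord) {
      cand <- cands[[w]]
      seed <- (cfg@rngSeed + 7919L * ai + w) %% 2147483647L
      cand$randfold_pvalue <- randfoldP(cand$precursor_seq, model,
                                        cfg@randfoldShuffles, seed = seed)
      if (cand$randfold_pvalue < cfg@randfoldAlpha) {
        chosen <- cand
        break
      }
    }
    if (is.null(chosen)) next
    chosen$mature_seq <- aln$sequence
    chosen$mature_start <- aln$start
    chosen$mature_end <- aln$end
    # star arm: span of the mature's pairing partners
    pt <- chosen$fold@pairTable
    mpos <- chosen$mature_offset:(chosen$mature_offset + r - 1L)
    partners <- pt[mpos]
    partners <- partners[partners > 0L]
    chosen$star_seq <- if (length(partners))
      substr(chosen$precursor_seq, min(partners), max(partners)) else
      NA_character_
    accepted[[length(accepted) + 1L]] <- chosen
  }
  if (!length(accepted))
    return(list(milrnas = emptyMilrnaTable(libs), candidates = list(),
                n_evaluated = nEval))
  # deduplicate by (mature sequence, mature locus)
  dedupKey <- vapply(accepted, function(cc)
    paste(cc$mature_seq, cc$contig, cc$mature_start, cc$mature_end,
          cc$strand, sep = ":"), character(1))
  accepted <- accepted[!duplicated(dedupKey)]

  df <- do.call(rbind, lapply(accepted, function(cc) {
    row <- data.frame(
      contig = cc$contig, start = cc$mature_start, end = cc$mature_end,
      strand = cc$strand, sequence = cc$mature_seq,
      length = nchar(cc$mature_seq), precursor_start = cc$start,
      precursor_end = cc$end, precursor_mfe = cc$fold@mfe,
      randfold_pvalue = cc$randfold_pvalue, arm = cc$arm,
      star = cc$star_seq, stringsAsFactors = FALSE)
    for (lib in libs) row[[paste0("count_", lib)]] <- cc$read_counts[[lib]]
    row
  }))
  tot <- rowSums(df[, paste0("count_", libs), drop = FALSE])
  df$cluster <- clusterCandidates(df$sequence, tot, cfg@clusterIdentity)
  df$classification <- classifyLocus(df, annotation)
  df$known_match <- vapply(df$sequence, matchKnown, character(1),
                           reference = knownRef,
                           maxMm = cfg@knownMirnaMaxMismatch)
  df$id <- assignNames(df, contigOrder = names(genome))
  ord <- order(match(df$contig, names(genome)), df$start)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  list(milrnas = df, candidates = accepted[ord], n_evaluated = nEval)
}

emptyMilrnaTable <- function(libs = c("MYC", "PRI")) {
  df <- data.frame(contig = character(0), start = integer(0),
                   end = integer(0), strand = character(0),
                   sequence = character(0), length = integer(0),
                   precursor_start = integer(0), precursor_end = integer(0),
                   precursor_mfe = numeric(0), randfold_pvalue = numeric(0),
                   arm = character(0), star = character(0),
                   stringsAsFactors = FALSE)
  for (lib in libs) df[[paste0("count_", lib)]] <- numeric(0)
  df$cluster <- integer(0)
  df$classification <- character(0)
  df$known_match <- character(0)
  df$id <- character(0)
  df
}

#' Build the discovery report tables
#'
#' The main table follows the published catalog layout: id, mature locus
#' ("contig:start-end"), strand, sequence, length, per-library counts
#' (printed with one decimal when fractional). Summaries: mature length
#' histogram, 5'-nucleotide frequencies, and the classification table
#' with nearest-integer percentages.
#'
#' @param milrnas discovery data.frame from [discoverMilRNAs()].
#' @param dir optional output directory for TSV files.
#' @param candidates optional accepted candidate records (from
#'   [discoverMilRNAs()]); when given together with `dir`, the folded
#'   precursors are written as `precursors.db.txt` in dot-bracket format.
#' @return list with `table`, `length_hist`, `five_prime`,
#'   `classification`.
#' @export
discoveryReport <- function(milrnas, dir = NULL, candidates = NULL) {
  libs <- sub("^count_", "", grep("^count_", names(milrnas), value = TRUE))
  fmtCount <- function(x) ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
                                 sprintf("%.1f", x))
  tab <- data.frame(
    id = milrnas$id,
    locus = if (nrow(milrnas)) formatLocus(milrnas$contig, milrnas$start,
                                           milrnas$end) else character(0),
    strand = milrnas$strand, sequence = milrnas$sequence,
    length = milrnas$length, stringsAsFactors = FALSE)
  for (lib in libs)
    tab[[paste0("count_", lib)]] <- fmtCount(milrnas[[paste0("count_", lib)]])
  lens <- milrnas$length
  hist <- data.frame(length = sort(unique(lens)),
                     n = as.vector(table(lens)))
  first <- substr(milrnas$sequence, 1L, 1L)
  fp <- data.frame(nt = c("A", "C", "G", "T"),
                   fraction = vapply(c("A", "C", "G", "T"), function(b)
                     if (nrow(milrnas)) mean(first == b) else 0,
                     numeric(1)))
  cls <- classificationSummary(milrnas$classification)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.table(tab, file.path(dir, "milrnas.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(hist, file.path(dir, "length_hist.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(fp, file.path(dir, "five_prime.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(cls, file.path(dir, "classification.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(candidates) && length(candidates)) {
      db <- do.call(rbind, lapply(seq_along(candidates), function(i) {
        cc <- candidates[[i]]
        data.frame(id = if (i <= nrow(milrnas)) milrnas$id[i] else
                     sprintf("candidate%03d", i),
                   sequence = cc$precursor_seq,
                   structure = cc$fold@structure, mfe = cc$fold@mfe,
                   stringsAsFactors = FALSE)
      }))
      writeDotBracket(db, file.path(dir, "precursors.db.txt"))
    }
  }
  list(table = tab, length_hist = hist, five_prime = fp,
       classification = cls)
}

#' Summarize locus classifications as counts and percentages
#'
#' Percentages are rounded to the nearest integer (the convention of the
#' published composition: 68% intergenic, 23% rRNA, 9% exon for a 15/5/2
#' split of 22 candidates).
#'
#' @param classification character vector of per-candidate classes.
#' @return data.frame with class, n, percent.
#' @export
classificationSummary <- function(classification) {
  lvls <- c("intergenic", "rRNA", "tRNA", "exon")
  n <- vapply(lvls, function(x) sum(classification == x), numeric(1))
  keep <- n > 0 | lvls %in% c("intergenic", "rRNA", "exon")
  data.frame(class = lvls[keep], n = n[keep],
             percent = if (sum(n) > 0) round(100 * n[keep] / sum(n)) else
               rep(0, sum(keep)),
             row.names = NULL, stringsAsFactors = FALSE)
}
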