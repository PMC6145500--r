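# Target prediction by three-mode consensus over 1000-bp downstream
# regions, expression-concordance filtering, hypergeometric enrichment,
# homolog scanning, and comparative-Ct utilities.

#' Build the 3'-UTR surrogate database
#'
#' For each gene with a stop_codon feature, the surrogate is the 1000 bp
#' immediately downstream of the stop codon on the gene's strand
#' (plus-strand gene: stop_end+1 .. stop_end+1000; minus-strand gene:
#' reverse complement of stop_start-1000 .. stop_start-1), truncated at
#' contig boundaries (flagged). Genes without a stop feature are skipped
#' with a warning.
#'
#' @param annotation GRanges with feature_type/gene_id.
#' @param genome named character vector of contigs.
#' @param utrLen surrogate length (default 1000).
#' @return data.frame with gene, sequence, contig, start, end, strand,
#'   truncated.
#' @export
buildUtrDb <- function(annotation, genome, utrLen = 1000L) {
  stops <- annotation[annotation$feature_type == "stop_codon"]
  genes <- unique(annotation$gene_id[annotation$feature_type == "gene"])
  missing <- setdiff(genes, stops$gene_id)
  if (length(missing))
    warning(length(missing), " gene(s) without a stop_codon feature skipped")
  rows <- lapply(seq_along(stops), function(i) {
    g <- stops[i]
    cn <- as.character(GenomicRanges::seqnames(g))
    clen <- nchar(genome[[cn]])
    strand <- as.character(GenomicRanges::strand(g))
    if (strand == "+") {
      ws <- GenomicRanges::end(g) + 1L
      we <- min(ws + utrLen - 1L, clen)
      if (ws > clen) return(NULL)
      s <- substr(genome[[cn]], ws, we)
    } else {
      we <- GenomicRanges::start(g) - 1L
      ws <- max(we - utrLen + 1L, 1L)
      if (we < 1L) return(NULL)
      s <- revComp(substr(genome[[cn]], ws, we))
    }
    data.frame(gene = g$gene_id, sequence = s, contig = cn, start = ws,
               end = we, strand = strand,
               truncated = nchar(s) < utrLen, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(0), sequence = character(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      truncated = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

emptySites <- function() {
  data.frame(gene = character(0), start = integer(0), end = integer(0),
             mode = character(0), score = numeric(0), energy = numeric(0),
             stringsAsFactors = FALSE)
}

# site frames anchored on a perfect Watson-Crick seed complement:
# milRNA position p binds surrogate position a + m - p, so the reverse
# complement of the seed (positions seedStart..seedEnd) occupies
# surrogate positions [a + m - seedEnd, a + m - seedStart]
seedFrames <- function(milrna, surrogate, cfg) {
  m <- nchar(milrna)
  seed <- substr(milrna, cfg@seedStart, cfg@seedEnd)
  pat <- revComp(seed)
  L <- nchar(surrogate)
  w <- nchar(pat)
  if (L < w) return(integer(0))
  starts <- which(vapply(seq_len(L - w + 1L), function(i)
    substr(surrogate, i, i + w - 1L) == pat, logical(1)))
  a <- starts - m + cfg@seedEnd
  a[a >= 1L & a + m - 1L <= L]
}

#' Duplex-energy mode target scan
#'
#' Slides windows of length len(milrna) + 4 across the surrogate; a window
#' passes iff its minimum intermolecular duplex energy is at or below the
#' threshold; overlapping passing windows are merged keeping the best
#' energy.
#'
#' @param milrna mature milRNA sequence (5' to 3').
#' @param surrogate one row of [buildUtrDb()] (or a list with gene and
#'   sequence).
#' @param cfg a [MilrConfig-class].
#' @param model an [EnergyModel-class]; configured default when `NULL`.
#' @return data.frame of sites (gene, start, end, mode, score, energy).
#' @export
scanDuplexMode <- function(milrna, surrogate, cfg = milrConfig(),
                           model = NULL) {
  if (is.null(model)) model <- configEnergyModel(cfg)
  s <- surrogate$sequence
  if (!nzchar(s)) return(emptySites())
  L <- nchar(milrna) + 4L
  if (nchar(s) < L) return(emptySites())
  x <- encodeSeq(toupper(milrna))
  y <- encodeSeq(toupper(s))
  tabLen <- length(x) + length(y)
  e <- duplex_window_scan_cpp(x, y, L, model@stack,
                              extendLoopTable(model@bulge, tabLen),
                              extendLoopTable(model@internal, tabLen),
                              model@asymPerNt, model@asymMax,
                              model@duplexInit, model@maxLoop)
  pass <- which(e <= cfg@duplexEnergyThreshold)
  if (!length(pass)) return(emptySites())
  # merge overlapping passing windows, keep the best energy per run
  runs <- split(pass, cumsum(c(1L, diff(pass) >= L)))
  do.call(rbind, lapply(runs, function(p) {
    data.frame(gene = surrogate$gene, start = min(p),
               end = max(p) + L - 1L, mode = "DUPLEX",
               score = -min(e[p]), energy = min(e[p]),
               stringsAsFactors = FALSE)
  }))
}

# weighted complementarity local alignment (match +5, GU +1, mismatch -3,
# gap open -8, gap extend -2; substitution columns opposite milRNA
# positions seedStart..8 doubled), milRNA vs the reversed site window
alignScore <- function(milrna, siteWindow, cfg) {
  x <- strsplit(toupper(chartr("U", "T", milrna)), "")[[1]]
  y <- rev(strsplit(toupper(chartr("U", "T", siteWindow)), "")[[1]])
  m <- length(x)
  n <- length(y)
  compl <- c(A = "T", C = "G", G = "C", T = "A")
  subScore <- function(i, b) {
    w <- if (i >= cfg@seedStart && i <= 8L) 2 else 1
    if (compl[[x[i]]] == b) 5 * w
    else if ((x[i] == "G" && b == "T") || (x[i] == "T" && b == "G")) 1 * w
    else -3 * w
  }
  NEG <- -1e9
  M <- matrix(0, m + 1L, n + 1L)
  Ix <- matrix(NEG, m + 1L, n + 1L)  # gap in y (milRNA base unmatched)
  Iy <- matrix(NEG, m + 1L, n + 1L)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      sc <- subScore(i, y[j])
      M[i + 1L, j + 1L] <- max(0, sc + max(M[i, j], Ix[i, j], Iy[i, j]))
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - 8, Ix[i, j + 1L] - 2)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - 8, Iy[i + 1L, j] - 2)
      best <- max(best, M[i + 1L, j + 1L])
    }
  }
  best
}

#' Alignment mode target scan
#'
#' Sites are anchored on perfect seed complementarity (no wobble) and
#' scored by a weighted complementarity alignment against the reversed
#' site window; a site passes iff the score reaches the threshold and its
#' duplex energy is at or below the duplex threshold.
#'
#' @inheritParams scanDuplexMode
#' @return data.frame of sites.
#' @export
scanAlignMode <- function(milrna, surrogate, cfg = milrConfig(),
                          model = NULL) {
  if (is.null(model)) model <- configEnergyModel(cfg)
  s <- surrogate$sequence
  if (!nzchar(s)) return(emptySites())
  m <- nchar(milrna)
  frames <- seedFrames(milrna, s, cfg)
  rows <- lapply(frames, function(a) {
    site <- substr(s, a, a + m - 1L)
    win <- substr(s, max(1L, a - 2L), min(nchar(s), a + m + 1L))
    score <- alignScore(milrna, win, cfg)
    energy <- duplexEnergy(milrna, site, model)$energy
    if (score >= cfg@alignmentScoreThreshold &&
        energy <= cfg@duplexEnergyThreshold)
      data.frame(gene = surrogate$gene, start = a, end = a + m - 1L,
                 mode = "ALIGN", score = score, energy = energy,
                 stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) emptySites() else out
}

#' Accessibility mode target scan
#'
#' For each seed-anchored site, the opening cost is the MFE difference of
#' a 140-nt window centered on the site folded with the site forced
#' unpaired versus unconstrained (always >= 0); the site passes iff the
#' duplex energy plus opening cost is at or below the threshold.
#'
#' @inheritParams scanDuplexMode
#' @return data.frame of sites (score = -ddG).
#' @export
scanAccessMode <- function(milrna, surrogate, cfg = milrConfig(),
                           model = NULL) {
  if (is.null(model)) model <- configEnergyModel(cfg)
  s <- surrogate$sequence
  if (!nzchar(s)) return(emptySites())
  m <- nchar(milrna)
  slen <- nchar(s)
  frames <- seedFrames(milrna, s, cfg)
  rows <- lapply(frames, function(a) {
    b <- a + m - 1L
    mid <- (a + b) %/% 2L
    ws <- max(1L, mid - 69L)
    we <- min(slen, ws + 139L)
    ws <- max(1L, we - 139L)
    win <- substr(s, ws, we)
    sitePos <- (a:b) - ws + 1L
    gOpen <- foldMFE(win, model, constraints = sitePos)@mfe -
      foldMFE(win, model)@mfe
    energy <- duplexEnergy(milrna, substr(s, a, b), model)$energy
    ddg <- energy + gOpen
    if (energy < 0 && ddg <= cfg@ddgThreshold)
      data.frame(gene = surrogate$gene, start = a, end = b,
                 mode = "ACCESS", score = -ddg, energy = energy,
                 stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) emptySites() else out
}

#' Intersect the three prediction modes
#'
#' A gene is a consensus target iff it has at least one passing site in
#' every mode. Venn counts over the three per-mode gene sets are emitted
#' for reporting.
#'
#' @param sites data.frame of sites from the three scans (rbind).
#' @return list with `targets` (data.frame gene + per-mode site counts),
#'   `venn` (named counts of the 7 regions).
#' @export
consensusTargets <- function(sites) {
  modes <- c("DUPLEX", "ALIGN", "ACCESS")
  sets <- lapply(modes, function(md) unique(sites$gene[sites$mode == md]))
  names(sets) <- modes
  inAll <- Reduce(intersect, sets)
  venn <- c(
    DUPLEX = length(sets$DUPLEX), ALIGN = length(sets$ALIGN),
    ACCESS = length(sets$ACCESS),
    `DUPLEX&ALIGN` = length(intersect(sets$DUPLEX, sets$ALIGN)),
    `DUPLEX&ACCESS` = length(intersect(sets$DUPLEX, sets$ACCESS)),
    `ALIGN&ACCESS` = length(intersect(sets$ALIGN, sets$ACCESS)),
    `DUPLEX&ALIGN&ACCESS` = length(inAll))
  targets <- if (length(inAll)) data.frame(
    gene = sort(inAll),
    n_sites_DUPLEX = vapply(sort(inAll), function(g)
      sum(sites$gene == g & sites$mode == "DUPLEX"), numeric(1)),
    n_sites_ALIGN = vapply(sort(inAll), function(g)
      sum(sites$gene == g & sites$mode == "ALIGN"), numeric(1)),
    n_sites_ACCESS = vapply(sort(inAll), function(g)
      sum(sites$gene == g & sites$mode == "ACCESS"), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  else data.frame(gene = character(0), n_sites_DUPLEX = numeric(0),
                  n_sites_ALIGN = numeric(0), n_sites_ACCESS = numeric(0),
                  stringsAsFactors = FALSE)
  list(targets = targets, venn = venn)
}

#' Expression-concordance filter
#'
#' Fold change is Norm_MYC / Norm_PRI. For a milRNA elevated in PRI,
#' targets with FC <= tau are kept (inclusive); for a milRNA elevated in
#' MYC, targets with FC > tau are kept (strict). Genes missing from the
#' table are dropped with a warning.
#'
#' @param targets consensus target data.frame (column `gene`).
#' @param expression data.frame with gene, Norm_MYC, Norm_PRI.
#' @param direction "PRI_up" or "MYC_up".
#' @param tau fold-change threshold.
#' @return filtered data.frame with an added fold_change column.
#' @export
expressionFilter <- function(targets, expression, direction = c("PRI_up",
                             "MYC_up"), tau = 0.5) {
  direction <- match.arg(direction)
  if (any(expression$Norm_MYC <= 0) || any(expression$Norm_PRI <= 0))
    stop("expression values must be strictly positive")
  idx <- match(targets$gene, expression$gene)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " target gene(s) missing from the ",
            "expression table dropped")
    targets <- targets[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  fc <- expression$Norm_MYC[idx] / expression$Norm_PRI[idx]
  targets$fold_change <- fc
  keep <- if (direction == "PRI_up") fc <= tau else fc > tau
  out <- targets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-sided hypergeometric term enrichment
#'
#' For each term, the upper-tail hypergeometric probability of observing
#' at least the seen number of term-annotated genes in the target set,
#' against the background of all genes with at least one term assignment.
#' No multiplicity correction is applied; results are sorted by p-value
#' and flagged significant at 0.05.
#'
#' @param termTable data.frame with columns gene, term.
#' @param targetGenes character vector of target gene ids.
#' @param alpha significance level for the flag.
#' @return data.frame term, k, n, K, N, p_value, significant.
#' @export
enrichTerms <- function(termTable, targetGenes, alpha = 0.05) {
  background <- unique(termTable$gene)
  N <- length(background)
  tset <- intersect(unique(targetGenes), background)
  n <- length(tset)
  terms <- unique(termTable$term)
  rows <- lapply(terms, function(tm) {
    withTerm <- unique(termTable$gene[termTable$term == tm])
    K <- length(withTerm)
    k <- length(intersect(tset, withTerm))
    if (k > K || n > N) stop("inconsistent enrichment contingency")
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  out
}

#' Seed-anchored homolog scan over a transcript set
#'
#' Scans both strands of each transcript for windows of the mature's
#' length with an identical seed region (positions seedStart..seedEnd)
#' and at most two mismatches over the remaining positions ("fewer than
#' three"). Positions are reported on the transcript's plus strand.
#'
#' @param mature mature milRNA sequence (>= 8 nt).
#' @param transcripts named character vector of transcript sequences.
#' @param cfg a [MilrConfig-class] (seed positions).
#' @param maxNonSeedMm maximum non-seed mismatches (default 2).
#' @return data.frame transcript, start, end, strand, mismatches.
#' @export
homologScan <- function(mature, transcripts, cfg = milrConfig(),
                        maxNonSeedMm = 2L) {
  mature <- toupper(chartr("U", "T", mature))
  L <- nchar(mature)
  if (L < 8L) stop("mature sequence must be at least 8 nt")
  seed <- substr(mature, cfg@seedStart, cfg@seedEnd)
  mVec <- strsplit(mature, "")[[1]]
  nonSeed <- setdiff(seq_len(L), cfg@seedStart:cfg@seedEnd)
  rows <- list()
  for (ti in seq_along(transcripts)) {
    tname <- names(transcripts)[ti]
    tplus <- toupper(transcripts[[ti]])
    tlen <- nchar(tplus)
    if (tlen < L) next
    for (strand in c("+", "-")) {
      t <- if (strand == "+") tplus else revComp(tplus)
      for (i in seq_len(tlen - L + 1L)) {
        if (substr(t, i + cfg@seedStart - 1L, i + cfg@seedEnd - 1L) != seed)
          next
        wVec <- strsplit(substr(t, i, i + L - 1L), "")[[1]]
        mm <- sum(mVec[nonSeed] != wVec[nonSeed])
        if (mm <= maxNonSeedMm) {
          st <- if (strand == "+") i else tlen - (i + L - 1L) + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            transcript = tname, start = st, end = st + L - 1L,
            strand = strand, mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(transcript = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Comparative-Ct (delta-delta-Ct) relative quantification
#'
#' Per condition, delta-Ct = mean(target Ct) - mean(reference Ct);
#' delta-delta-Ct subtracts the calibrator's delta-Ct, and relative
#' quantity RQ = 2^(-ddCt), so the calibrator's RQ is exactly 1.
#' A two-sided two-sample Student's t-test compares each condition's
#' per-replicate delta-Ct values (target minus reference, replicate-wise)
#' against the calibrator's.
#'
#' @param ctTarget named list, condition -> numeric replicate Ct values of
#'   the target assay.
#' @param ctRef same structure for the reference (endogenous control).
#' @param calibrator name of the calibrator condition.
#' @return data.frame condition, delta_ct, ddct, RQ, p_value (NA for the
#'   calibrator).
#' @export
relativeExpressionDdct <- function(ctTarget, ctRef, calibrator) {
  conds <- names(ctTarget)
  if (!identical(sort(conds), sort(names(ctRef))))
    stop("ctTarget and ctRef must cover the same conditions")
  if (!calibrator %in% conds) stop("unknown calibrator condition")
  for (cd in conds) {
    if (length(ctTarget[[cd]]) < 2L || length(ctRef[[cd]]) < 2L)
      stop("at least 2 replicates per condition required")
    if (length(ctTarget[[cd]]) != length(ctRef[[cd]]))
      stop("target and reference replicate counts differ in ", cd)
  }
  dct <- vapply(conds, function(cd)
    mean(ctTarget[[cd]]) - mean(ctRef[[cd]]), numeric(1))
  ddct <- dct - dct[[calibrator]]
  perRep <- lapply(conds, function(cd) ctTarget[[cd]] - ctRef[[cd]])
  names(perRep) <- conds
  pv <- vapply(conds, function(cd) {
    if (cd == calibrator) return(NA_real_)
    x <- perRep[[cd]]
    y <- perRep[[calibrator]]
    if (stats::sd(c(x - mean(x), y - mean(y))) == 0 && mean(x) == mean(y))
      return(1)
    tryCatch(t.test(x, y, var.equal = TRUE)$p.value,
             error = function(e) NA_real_)
  }, numeric(1))
  data.frame(condition = conds, delta_ct = unname(dct),
             ddct = unname(ddct), RQ = 2^(-unname(ddct)),
             p_value = unname(pv), stringsAsFactors = FALSE)
}

#' Predict and filter targets of one milRNA
#'
#' Runs the three scanning modes over every 3'-UTR surrogate, intersects
#' them at gene level, and applies the expression-concordance filter.
#'
#' @param milrna mature milRNA sequence.
#' @param utrDb surrogate table from [buildUtrDb()].
#' @param expression expression table (gene, Norm_MYC, Norm_PRI).
#' @param direction "PRI_up" or "MYC_up" (the milRNA's elevated stage).
#' @param cfg a [MilrConfig-class].
#' @param model an [EnergyModel-class]; configured default when `NULL`.
#' @return list with sites, consensus targets, venn counts, and the
#'   expression-filtered target table.
#' @export
predictTargets <- function(milrna, utrDb, expression,
                           direction = c("PRI_up", "MYC_up"),
                           cfg = milrConfig(), model = NULL) {
  direction <- match.arg(direction)
  if (is.null(model)) model <- configEnergyModel(cfg)
  sites <- list()
  for (i in seq_len(nrow(utrDb))) {
    sur <- utrDb[i, , drop = FALSE]
    sites[[length(sites) + 1L]] <- scanDuplexMode(milrna, sur, cfg, model)
    sites[[length(sites) + 1L]] <- scanAlignMode(milrna, sur, cfg, model)
    sites[[length(sites) + 1L]] <- scanAccessMode(milrna, sur, cfg, model)
  }
  sites <- do.call(rbind, c(list(emptySites()), sites))
  cons <- consensusTargets(sites)
  filtered <- expressionFilter(cons$targets, expression, direction,
                               cfg@fcThreshold)
  list(sites = sites, consensus = cons$targets, venn = cons$venn,
       filtered = filtered)
}
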