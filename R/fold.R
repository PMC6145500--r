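#' Predict the minimum-free-energy secondary structure of one sequence
#'
#' Zuker-style dynamic programming over all pseudoknot-free structures under
#' the nearest-neighbor model: stacking energies, hairpin/bulge/internal-loop
#' penalties and an affine multiloop term, with GU wobble pairs allowed and a
#' minimum hairpin loop of 3 nt. T is treated as U throughout, so genomic
#' (DNA) windows fold directly. Energies are evaluated in exact hundredths of
#' kcal/mol and equal-energy structures are resolved by a fixed traceback
#' preference (stack, then interior loop, then multiloop, then hairpin;
#' leftmost first), so results are bit-reproducible.
#'
#' @param seq a single sequence over A/C/G/T/U (case-insensitive).
#' @param model an [EnergyModel-class]; the packaged default when `NULL`.
#' @param constraints optional integer vector of 1-based positions forced to
#'   remain unpaired (used for target-site accessibility).
#' @return a [FoldResult-class]. A sequence with no favourable structure
#'   returns the all-unpaired structure with an MFE of exactly 0.
#' @examples
#' foldMFE("GGGGGAAAACCCCC")
#' @export
foldMFE <- function(seq, model = NULL, constraints = NULL) {
  if (is.null(model)) model <- defaultEnergyModel()
  if (length(seq) != 1L || !nzchar(seq)) stop("seq must be one non-empty string")
  s <- toupper(seq)
  enc <- encodeSeq(s)
  n <- length(enc)
  blocked <- logical(n)
  if (!is.null(constraints)) {
    constraints <- as.integer(constraints)
    if (any(constraints < 1L | constraints > n))
      stop("constraint positions out of range")
    blocked[constraints] <- TRUE
  }
  res <- fold_mfe_cpp(enc, model@stack,
                      extendLoopTable(model@hairpin, n),
                      extendLoopTable(model@bulge, n),
                      extendLoopTable(model@internal, n),
                      model@asymPerNt, model@asymMax,
                      model@mlOffset, model@mlBranch, model@mlUnpaired,
                      blocked, model@maxLoop)
  pt <- as.integer(res$pair_table)
  new("FoldResult", sequence = s, structure = pairTableToDotBracket(pt),
      mfe = res$mfe, pairTable = pt)
}

#' Convert between a pair table and dot-bracket notation
#'
#' @param pt integer vector of 1-based partners (0 = unpaired).
#' @return dot-bracket string.
#' @export
pairTableToDotBracket <- function(pt) {
  ch <- rep(".", length(pt))
  i <- seq_along(pt)
  ch[pt > 0 & pt > i] <- "("
  ch[pt > 0 & pt < i] <- ")"
  paste(ch, collapse = "")
}

#' @rdname pairTableToDotBracket
#' @param db dot-bracket string.
#' @export
dotBracketToPairTable <- function(db) {
  ch <- strsplit(db, "")[[1]]
  if (!all(ch %in% c("(", ")", ".")))
    stop("dot-bracket string may only contain '(', ')' and '.'")
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced structure: unmatched ')'")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced structure: unmatched '('")
  pt
}

#' Count terminal (hairpin) loops of a structure
#'
#' A terminal loop is a maximal run of unpaired positions immediately
#' enclosed by a base pair with no pair inside it.
#'
#' @param fold a [FoldResult-class].
#' @return list with `n_terminal_loops` and `loop_sizes` (5'-to-3' order).
#' @export
countHairpinLoops <- function(fold) {
  pt <- fold@pairTable
  sizes <- integer(0)
  for (i in seq_along(pt)) {
    j <- pt[i]
    if (j > i) {
      # pair (i, j): terminal loop iff everything strictly inside is unpaired
      if (j - i > 1L && all(pt[(i + 1L):(j - 1L)] == 0L))
        sizes <- c(sizes, j - i - 1L)
    }
  }
  list(n_terminal_loops = length(sizes), loop_sizes = sizes)
}

#' Stem statistics for a mature span within a folded precursor
#'
#' Reports the total number of base pairs, whether the mature span lies
#' within one arm of the stem (between the outermost and innermost paired
#' positions of that arm, internal unpaired bases allowed, no overlap with
#' the terminal loop), and which arm it occupies.
#'
#' @param fold a [FoldResult-class].
#' @param matureStart,matureEnd 1-based mature span within the precursor.
#' @return list with `total_pairs`, `mature_in_stem`, `arm`
#'   (one of "5p", "3p", "loop-spanning").
#' @export
stemStatistics <- function(fold, matureStart, matureEnd) {
  n <- nchar(fold@sequence)
  if (matureStart < 1L || matureEnd > n || matureStart > matureEnd)
    stop("mature span out of range")
  pt <- fold@pairTable
  totalPairs <- sum(pt > seq_along(pt))
  loops <- countHairpinLoops(fold)
  if (loops$n_terminal_loops != 1L)
    return(list(total_pairs = totalPairs, mature_in_stem = FALSE,
                arm = "loop-spanning"))
  # locate the single terminal loop
  loopStart <- NA_integer_
  for (i in seq_along(pt)) {
    j <- pt[i]
    if (j > i && j - i > 1L && all(pt[(i + 1L):(j - 1L)] == 0L)) {
      loopStart <- i + 1L
      loopEnd <- j - 1L
      break
    }
  }
  paired <- which(pt > 0L)
  arm5 <- paired[paired < loopStart]
  arm3 <- paired[paired > loopEnd]
  m <- matureStart:matureEnd
  overlapLoop <- any(m >= loopStart & m <= loopEnd)
  inArm5 <- length(arm5) > 0 && matureStart >= min(arm5) &&
    matureEnd <= max(arm5)
  inArm3 <- length(arm3) > 0 && matureStart >= min(arm3) &&
    matureEnd <= max(arm3)
  if (!overlapLoop && inArm5)
    list(total_pairs = totalPairs, mature_in_stem = TRUE, arm = "5p")
  else if (!overlapLoop && inArm3)
    list(total_pairs = totalPairs, mature_in_stem = TRUE, arm = "3p")
  else
    list(total_pairs = totalPairs, mature_in_stem = FALSE,
         arm = if (overlapLoop) "loop-spanning"
               else if (matureEnd < loopStart) "5p" else "3p")
}

#' Minimum intermolecular duplex energy of a small RNA against a site
#'
#' Finds the lowest-energy antiparallel duplex between the two strands,
#' allowing GU wobble, bulges and internal loops but no intramolecular
#' pairs: energy = duplex initiation + stacks + loop penalties. When no
#' base pair can form the energy is 0 by convention (such sites are
#' rejected downstream).
#'
#' @param mirna,site sequences 5'-to-3' (A/C/G/T/U).
#' @param model an [EnergyModel-class]; packaged default when `NULL`.
#' @return list with `energy` (kcal/mol) and `pairing`, a two-line
#'   text rendering of the paired positions.
#' @examples
#' duplexEnergy("GGGGGG", "CCCCCC")$energy
#' @export
duplexEnergy <- function(mirna, site, model = NULL) {
  if (is.null(model)) model <- defaultEnergyModel()
  if (!nzchar(mirna) || !nzchar(site)) stop("both sequences must be non-empty")
  x <- encodeSeq(toupper(mirna))
  y <- encodeSeq(toupper(site))
  res <- duplex_cpp(x, y, model@stack,
                    extendLoopTable(model@bulge, length(x) + length(y)),
                    extendLoopTable(model@internal, length(x) + length(y)),
                    model@asymPerNt, model@asymMax, model@duplexInit,
                    model@maxLoop)
  xs <- rep(".", length(x))
  ys <- rep(".", length(y))
  xs[res$x_pairs] <- "("
  ys[res$y_pairs] <- ")"
  list(energy = res$energy,
       pairing = paste0("5' ", paste(xs, collapse = ""), " 3'\n3' ",
                        paste(rev(ys), collapse = ""), " 5'"))
}

#' Dinucleotide-preserving shuffle
#'
#' Altschul--Erickson Eulerian-walk shuffle: the returned sequence has
#' exactly the same dinucleotide counts as the input (hence also the same
#' mononucleotide counts and the same first and last base), sampled
#' uniformly from the Eulerian sequence space.
#'
#' @param seq a single sequence (length >= 2).
#' @param seed optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @return shuffled sequence (same alphabet case as the uppercased input).
#' @export
dinucleotideShuffle <- function(seq, seed = NULL) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  if (n < 2L) stop("sequence must have length >= 2")
  if (length(unique(s)) == 1L) return(paste(s, collapse = ""))
  with_seed(seed, .eulerShuffle(s, n))
}

.eulerShuffle <- function(s, n) {
    # edge multiset: edges[[a]] = vector of successors of a
    edges <- split(s[-1L], s[-n])
    last <- s[n]
    repeat {
      # pick one random outgoing "last edge" per vertex (except the sink);
      # accept if the chosen last edges connect every vertex to the sink
      lastEdge <- vapply(names(edges), function(a) {
        if (a == last && length(edges[[a]]) == 0L) return(NA_character_)
        sample(edges[[a]], 1L)
      }, character(1))
      ok <- TRUE
      for (a in names(lastEdge)) {
        if (a == last || is.na(lastEdge[[a]])) next
        v <- a
        seen <- character(0)
        while (v != last) {
          if (v %in% seen || is.na(lastEdge[[v]])) { ok <- FALSE; break }
          seen <- c(seen, v)
          v <- lastEdge[[v]]
        }
        if (!ok) break
      }
      if (ok) break
    }
    # shuffle the remaining edges per vertex, appending the chosen last edge
    pool <- lapply(names(edges), function(a) {
      e <- edges[[a]]
      if (!is.na(lastEdge[[a]])) {
        drop <- match(lastEdge[[a]], e)
        e <- e[-drop]
      }
      e <- if (length(e) > 1L) sample(e) else e
      if (!is.na(lastEdge[[a]])) e <- c(e, lastEdge[[a]])
      e
    })
    names(pool) <- names(edges)
    nxt <- lapply(pool, function(e) 1L)
    out <- character(n)
    out[1L] <- s[1L]
    v <- s[1L]
    for (i in 2L:n) {
      k <- nxt[[v]]
      w <- pool[[v]][k]
      nxt[[v]] <- k + 1L
      out[i] <- w
      v <- w
    }
    paste(out, collapse = "")
}

#' Randomization-test p-value for folding stability
#'
#' Folds `n` dinucleotide shuffles of the sequence and reports the add-one
#' estimator p = (1 + #\{shuffles with MFE <= MFE(seq)\}) / (n + 1), so the
#' p-value can never be 0 and lies in (0, 1]. With the default 999 shuffles
#' the smallest attainable p is 0.001, so the acceptance rule p < 0.01 is
#' satisfiable.
#'
#' @param seq sequence to test.
#' @param model an [EnergyModel-class]; packaged default when `NULL`.
#' @param nShuffles number of shuffles (>= 1).
#' @param seed optional integer seed for the shuffle stream.
#' @return p-value in (0, 1].
#' @export
randfoldP <- function(seq, model = NULL, nShuffles = 999L, seed = NULL) {
  if (nShuffles < 1L) stop("nShuffles must be >= 1")
  if (is.null(model)) model <- defaultEnergyModel()
  ref <- foldMFE(seq, model)@mfe
  n <- nchar(seq)
  shuffled <- with_seed(seed,
    lapply(seq_len(nShuffles), function(i)
      encodeSeq(dinucleotideShuffle(seq))))
  mfes <- fold_mfe_batch_cpp(shuffled, model@stack,
                             extendLoopTable(model@hairpin, n),
                             extendLoopTable(model@bulge, n),
                             extendLoopTable(model@internal, n),
                             model@asymPerNt, model@asymMax,
                             model@mlOffset, model@mlBranch,
                             model@mlUnpaired, model@maxLoop)
  (1 + sum(mfes <= ref)) / (nShuffles + 1)
}
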