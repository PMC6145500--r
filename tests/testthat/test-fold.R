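model <- defaultEnergyModel()

test_that("unfoldable sequences return the all-dot structure with MFE 0", {
  f <- foldMFE("AAAAAAA", model)
  expect_identical(f@structure, ".......")
  expect_identical(f@mfe, 0)
  expect_error(foldMFE("ACGX", model), "invalid character")
})

test_that("a simple stem folds to the hand-decomposable minimum", {
  # two GC-context stacks + hairpin(4) penalty, all from the shipped table
  f <- foldMFE("GGGAAAACCC", model)
  expect_identical(f@structure, "(((....)))")
  expected <- 2 * model@stack["GC", "GC"] + model@hairpin[["4"]]
  expect_equal(f@mfe, expected, tolerance = 1e-9)
  # and the enumeration oracle agrees
  expect_equal(f@mfe, oracleMFE("GGGAAAACCC", model), tolerance = 1e-9)
})

test_that("folding equals exhaustive enumeration on short random sequences", {
  set.seed(421)
  for (i in 1:30) {
    s <- randomSeq(sample(5:14, 1))
    expect_equal(foldMFE(s, model)@mfe, oracleMFE(s, model),
                 tolerance = 1e-9, info = s)
  }
})

test_that("constrained folds respect forced-unpaired positions", {
  s <- "GGGGGAAAACCCCC"
  full <- foldMFE(s, model)
  expect_lt(full@mfe, -5)
  allBlocked <- foldMFE(s, model, constraints = seq_len(nchar(s)))
  expect_identical(allBlocked@mfe, 0)
  for (k in c(1L, 3L, 7L)) {
    part <- foldMFE(s, model, constraints = seq_len(k))
    expect_gte(part@mfe, full@mfe)
    expect_true(all(part@pairTable[seq_len(k)] == 0L))
  }
  expect_error(foldMFE(s, model, constraints = 99L), "out of range")
})

test_that("folding is deterministic", {
  s <- randomSeq(80)
  f1 <- foldMFE(s, model)
  f2 <- foldMFE(s, model)
  expect_identical(f1@structure, f2@structure)
  expect_identical(f1@mfe, f2@mfe)
})

test_that("terminal loops are counted as maximal enclosed unpaired runs", {
  f1 <- foldFromDotBracket("GGGAAAACCC", "(((....)))")
  expect_equal(countHairpinLoops(f1),
               list(n_terminal_loops = 1L, loop_sizes = 4L))
  f2 <- foldFromDotBracket("GGAACCGGAAACC", "((..))((...))")
  expect_equal(countHairpinLoops(f2),
               list(n_terminal_loops = 2L, loop_sizes = c(2L, 3L)))
  f3 <- foldFromDotBracket("AAAAAA", "......")
  expect_equal(countHairpinLoops(f3)$n_terminal_loops, 0L)
})

test_that("stem statistics place the mature span on the correct arm", {
  # perfect 20-pair hairpin with a 4-nt loop
  db <- paste0(strrep("(", 20), "....", strrep(")", 20))
  seq <- paste0(strrep("G", 20), "AAAA", strrep("C", 20))
  f <- foldFromDotBracket(seq, db)
  st <- stemStatistics(f, 1L, 20L)
  expect_equal(st$total_pairs, 20L)
  expect_true(st$mature_in_stem)
  expect_identical(st$arm, "5p")
  st3 <- stemStatistics(f, 25L, 44L)
  expect_true(st3$mature_in_stem)
  expect_identical(st3$arm, "3p")
  # overlapping the terminal loop by one base disqualifies
  stLoop <- stemStatistics(f, 2L, 21L)
  expect_false(stLoop$mature_in_stem)
  expect_error(stemStatistics(f, 0L, 10L), "out of range")
})

test_that("duplex energy matches the hand-summed shipped table", {
  d <- duplexEnergy("GGGGGG", "CCCCCC", model)
  expect_equal(d$energy, model@duplexInit + 5 * model@stack["GC", "GC"],
               tolerance = 1e-9)
  expect_identical(duplexEnergy("AAAA", "AAAA", model)$energy, 0)
})

test_that("duplex energy is symmetric under strand swap", {
  set.seed(77)
  for (i in 1:25) {
    a <- randomSeq(sample(5:12, 1))
    b <- randomSeq(sample(5:12, 1))
    expect_equal(duplexEnergy(a, b, model)$energy,
                 duplexEnergy(b, a, model)$energy, tolerance = 1e-9)
  }
})

test_that("the perfect complement is the optimal same-length duplex", {
  set.seed(78)
  combos <- expand.grid(rep(list(c("A", "C", "G", "T")), 6),
                        stringsAsFactors = FALSE)
  all6 <- apply(combos, 1, paste, collapse = "")
  for (i in 1:3) {
    x <- randomSeq(6)
    eref <- duplexEnergy(x, revComp(x), model)$energy
    es <- vapply(all6, function(s) duplexEnergy(x, s, model)$energy,
                 numeric(1))
    expect_true(all(es >= eref - 1e-9), info = x)
  }
})

test_that("dinucleotide shuffling preserves dinucleotide counts exactly", {
  expect_identical(dinucleotideShuffle("AAAA"), "AAAA")
  set.seed(5)
  for (i in 1:200) {
    s <- randomSeq(sample(2:40, 1))
    sh <- dinucleotideShuffle(s)
    expect_identical(dinucCounts(sh), dinucCounts(s), )
    expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
    expect_identical(substr(sh, nchar(s), nchar(s)),
                     substr(s, nchar(s), nchar(s)))
  }
})

test_that("shuffling stays within, and explores, the Eulerian space", {
  # enumerate every sequence with the same dinucleotide multiset by DFS
  enumerateSpace <- function(s) {
    ch <- strsplit(s, "")[[1]]
    edges <- paste0(ch[-length(ch)], ch[-1])
    out <- character(0)
    rec <- function(cur, remaining) {
      if (!length(remaining)) {
        out[[length(out) + 1L]] <<- cur
        return(invisible())
      }
      v <- substr(cur, nchar(cur), nchar(cur))
      nxt <- unique(remaining[substr(remaining, 1, 1) == v])
      for (e in nxt)
        rec(paste0(cur, substr(e, 2, 2)),
            remaining[-match(e, remaining)])
    }
    rec(substr(s, 1, 1), edges)
    unique(out)
  }
  # a one-sequence space maps to itself
  expect_identical(enumerateSpace("ACGCA"), "ACGCA")
  set.seed(61)
  expect_true(all(vapply(1:50, function(i)
    dinucleotideShuffle("ACGCA") == "ACGCA", logical(1))))
  # a multi-sequence space is explored and never left
  space <- enumerateSpace("AACAGA")
  expect_gte(length(space), 2L)
  set.seed(6)
  outs <- vapply(1:200, function(i) dinucleotideShuffle("AACAGA"),
                 character(1))
  expect_true(all(outs %in% space))
  expect_gte(length(unique(outs)), 2L)
})

test_that("randomization p-values follow the add-one estimator", {
  # unfoldable input: every shuffle ties at 0
  expect_identical(randfoldP("AAAAAAAAAA", model, nShuffles = 19,
                             seed = 1), 1)
  # with n = 99 the smallest attainable p is exactly 0.01
  strong <- paste0("GCGCGGCATCGAAGT", "AGCAA", revComp("GCGCGGCATCGAAGT"))
  p99 <- randfoldP(strong, model, nShuffles = 99, seed = 2)
  expect_gte(p99, 1 / 100)
  p <- randfoldP(strong, model, nShuffles = 299, seed = 3)
  expect_lt(p, 0.01)
})

test_that("dot-bracket conversions invert each other and reject junk", {
  db <- "((..((...))..))"
  expect_identical(pairTableToDotBracket(dotBracketToPairTable(db)), db)
  expect_error(dotBracketToPairTable("(()"), "unbalanced")
  expect_error(dotBracketToPairTable("x"), "may only contain")
})
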