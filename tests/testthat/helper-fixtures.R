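# Shared fixtures, built once per test run.

.fixtureEnv <- new.env()

# small simulated study: 2 x 20 kb, 6 hairpins, reduced read depth and a
# lighter randomization test so the whole suite stays fast
smallSpec <- function() simulationSpec(nContigs = 2L, contigLen = 20000L,
                                       nHairpins = 6L, nGenes = 10L,
                                       readsPerLibrary = 500L,
                                       nDecoyHairpins = 3L, rngSeed = 11L)

smallConfig <- function() milrConfig(randfoldShuffles = 299L, rngSeed = 11L)

smallDataset <- function() {
  if (is.null(.fixtureEnv$ds))
    .fixtureEnv$ds <- simulateDataset(smallSpec(), smallConfig())
  .fixtureEnv$ds
}

smallRun <- function() {
  if (is.null(.fixtureEnv$run))
    .fixtureEnv$run <- runMilrPipeline(smallSpec(), smallConfig(),
                                       dataset = smallDataset())
  .fixtureEnv$run
}

# full default-scale study (2 x 50 kb, 20 hairpins, 999 shuffles), shared
# by the stochastic recovery checks; seed-pinned
fullRun <- function() {
  if (is.null(.fixtureEnv$full))
    .fixtureEnv$full <- runMilrPipeline(simulationSpec(rngSeed = 101L),
                                        milrConfig(rngSeed = 101L))
  .fixtureEnv$full
}

# a candidate record with every field the criteria inspect, for boundary
# tests (structure-independent)
fakeCandidate <- function(mfe = -25, totalPairs = 20L, matureInStem = TRUE,
                          nLoops = 1L, loopSize = 6L, p = 0.001,
                          counts = c(MYC = 10, PRI = 10)) {
  fold <- new("FoldResult", sequence = "ACGT", structure = "....",
              mfe = min(mfe, 0), pairTable = integer(4))
  fold@mfe <- mfe
  list(fold = fold, total_pairs = totalPairs,
       mature_in_stem = matureInStem, n_loops = nLoops,
       loop_size = loopSize, randfold_pvalue = p, read_counts = counts)
}

# FoldResult from an explicit dot-bracket structure (mfe placeholder)
foldFromDotBracket <- function(seq, db, mfe = -1) {
  new("FoldResult", sequence = seq, structure = db, mfe = mfe,
      pairTable = dotBracketToPairTable(db))
}
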