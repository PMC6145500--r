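test_that("planted hairpins satisfy the structural criteria by construction", {
  cfg <- milrConfig()
  model <- defaultEnergyModel()
  set.seed(31)
  for (i in 1:8) {
    hp <- plantHairpin(cfg, model)
    f <- foldMFE(hp$precursor, model)
    expect_lte(f@mfe, cfg@mfeThreshold)
    expect_gte(sum(f@pairTable > seq_along(f@pairTable)), cfg@minStemPairs)
    loops <- countHairpinLoops(f)
    expect_identical(loops$n_terminal_loops, 1L)
    expect_gte(loops$loop_sizes[1], cfg@minLoopSize)
    st <- stemStatistics(f, hp$matureStart, hp$matureEnd)
    expect_true(st$mature_in_stem)
    expect_identical(st$arm, hp$arm)
    expect_identical(substr(hp$precursor, hp$matureStart, hp$matureEnd),
                     hp$mature)
  }
})

test_that("planted hairpins pass the full five-criteria check", {
  cfg <- milrConfig(randfoldShuffles = 199L)
  model <- defaultEnergyModel()
  set.seed(32)
  for (i in 1:5) {
    hp <- plantHairpin(cfg, model)
    cand <- list(fold = foldMFE(hp$precursor, model), read_counts = c(X = 10))
    f <- cand$fold
    loops <- countHairpinLoops(f)
    st <- stemStatistics(f, hp$matureStart, hp$matureEnd)
    cand$total_pairs <- st$total_pairs
    cand$mature_in_stem <- st$mature_in_stem
    cand$n_loops <- loops$n_terminal_loops
    cand$loop_size <- loops$loop_sizes[1]
    cand$randfold_pvalue <- randfoldP(hp$precursor, model, 199L,
                                      seed = 1000 + i)
    chk <- criteriaCheck(cand, cfg)
    expect_true(chk$pass, info = paste(chk$failures, collapse = ","))
  }
})

test_that("genome simulation is deterministic and truth loci are extractable", {
  spec <- simulationSpec(nContigs = 2L, contigLen = 8000L, nHairpins = 3L,
                         nGenes = 2L, nDecoyHairpins = 1L,
                         readsPerLibrary = 50L, rngSeed = 99L)
  cfg <- milrConfig()
  g1 <- simulateGenome(spec, cfg)
  g2 <- simulateGenome(spec, cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$truth, g2$truth)
  hp <- g1$truth[g1$truth$kind == "hairpin", ]
  expect_identical(nrow(hp), 3L)
  for (i in seq_len(nrow(hp))) {
    sub <- substr(g1$genome[[hp$contig[i]]], hp$start[i], hp$end[i])
    if (hp$strand[i] == "-") sub <- revComp(sub)
    expect_identical(sub, hp$sequence[i])
    msub <- substr(g1$genome[[hp$contig[i]]], hp$mature_start[i],
                   hp$mature_end[i])
    if (hp$strand[i] == "-") msub <- revComp(msub)
    expect_identical(msub, hp$mature_seq[i])
  }
  # byte-identical files from the same seed
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulateDataset(spec, cfg, dir = d1)
  simulateDataset(spec, cfg, dir = d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
})

test_that("an empty simulation yields background only", {
  spec <- simulationSpec(nContigs = 1L, contigLen = 2000L, nHairpins = 0L,
                         nGenes = 0L, nDecoyRrna = 0L, nDecoyTrna = 0L,
                         nDecoyHairpins = 0L, readsPerLibrary = 0L,
                         rngSeed = 5L)
  g <- simulateGenome(spec, milrConfig())
  expect_identical(nrow(g$truth), 0L)
  expect_identical(length(g$annotation), 0L)
  reads <- simulateReads(g$truth, spec, g$genome)
  expect_identical(nrow(reads$MYC), 0L)
  expect_identical(nrow(reads$PRI), 0L)
})

test_that("a sizing error is raised when contigs cannot host the features", {
  spec <- simulationSpec(nContigs = 1L, contigLen = 900L, nHairpins = 0L,
                         nGenes = 3L, nDecoyRrna = 0L, nDecoyTrna = 0L,
                         nDecoyHairpins = 0L, rngSeed = 1L)
  expect_error(simulateGenome(spec, milrConfig()), "sizing error")
})

test_that("stage-specific matures appear only in their library", {
  ds <- smallDataset()
  hp <- ds$truth[ds$truth$kind == "hairpin", ]
  mycOnly <- hp[hp$counts_PRI == 0 & hp$counts_MYC > 0, ]
  expect_gt(nrow(mycOnly), 0L)
  for (i in seq_len(nrow(mycOnly))) {
    expect_gte(sum(ds$reads$MYC$sequence == mycOnly$mature_seq[i]), 1L)
    expect_identical(sum(ds$reads$PRI$sequence == mycOnly$mature_seq[i]), 0L)
  }
})

test_that("contaminant fractions land within binomial bounds", {
  spec <- simulationSpec(nContigs = 1L, contigLen = 5000L, nHairpins = 0L,
                         nGenes = 0L, nDecoyRrna = 0L, nDecoyTrna = 0L,
                         nDecoyHairpins = 0L, readsPerLibrary = 1000L,
                         contaminantShortFraction = 0.1,
                         contaminantLowqFraction = 0.1, rngSeed = 42L)
  g <- simulateGenome(spec, milrConfig())
  reads <- simulateReads(g$truth, spec, g$genome)$MYC
  trimmed <- trimAdapter(reads$sequence, spec@adapter)
  nShort <- sum(nchar(trimmed) < 18)
  # 99% binomial interval around 100 of 1000
  expect_true(nShort >= 100 - 2.58 * sqrt(1000 * 0.1 * 0.9) &
              nShort <= 100 + 2.58 * sqrt(1000 * 0.1 * 0.9))
  mq <- vapply(phredScores(reads$quality), mean, numeric(1))
  nLow <- sum(mq < 20)
  expect_true(nLow >= 100 - 2.58 * sqrt(1000 * 0.1 * 0.9) &
              nLow <= 100 + 2.58 * sqrt(1000 * 0.1 * 0.9))
})

test_that("expression tables honour fold changes and noise", {
  genes <- sprintf("g%03d", 1:200)
  exact <- simulateExpression(genes, setNames(rep(0.5, 200), genes),
                              noiseSd = 0, seed = 1)
  expect_equal(exact$Norm_MYC / exact$Norm_PRI, rep(0.5, 200),
               tolerance = 1e-12)
  flat <- simulateExpression(genes, noiseSd = 0, seed = 2)
  expect_equal(flat$Norm_MYC, flat$Norm_PRI, tolerance = 1e-12)
  noisy <- simulateExpression(genes, setNames(rep(0.5, 200), genes),
                              noiseSd = 0.1, seed = 3)
  expect_true(all(noisy$Norm_MYC > 0) && all(noisy$Norm_PRI > 0))
  mr <- mean(noisy$Norm_MYC / noisy$Norm_PRI)
  expect_gte(mr, 0.45)
  expect_lte(mr, 0.55)
  expect_error(simulateExpression(genes,
                                  setNames(c(-1, rep(1, 199)), genes)),
               "positive")
  expect_error(simulateExpression(genes, c(nope = 2)), "unknown genes")
})

test_that("planted target sites sit in downstream regions on the coding strand", {
  ds <- smallDataset()
  tg <- ds$truth[ds$truth$kind == "target_site", ]
  expect_gt(nrow(tg), 0L)
  utr <- buildUtrDb(ds$annotation, ds$genome)
  for (i in seq_len(nrow(tg))) {
    sur <- utr$sequence[utr$gene == tg$gene_id[i]]
    expect_true(grepl(revComp(tg$mature_seq[i]), sur, fixed = TRUE))
  }
})

test_that("the EST set carries exact, seed-mismatch and distant copies", {
  ds <- smallDataset()
  mature <- ds$truth$mature_seq[ds$truth$kind == "hairpin"][1]
  hpFirst <- ds$truth[ds$truth$kind == "target_site", ]$mature_seq[1]
  ests <- ds$ests
  exact <- ests[grepl("exact", names(ests))]
  expect_gt(length(exact), 0L)
  expect_true(all(vapply(exact, function(t)
    grepl(hpFirst, t, fixed = TRUE), logical(1))))
  expect_true("est_seed_mm" %in% names(ests))
  expect_true("est_many_mm" %in% names(ests))
})
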