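cfgT <- milrConfig()
modelT <- defaultEnergyModel()

test_that("3'-UTR surrogates follow the strand and truncation rules", {
  genome <- c(c1 = paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
                         collapse = ""))
  ann <- GenomicRanges::GRanges(
    rep("c1", 6),
    IRanges::IRanges(c(1, 498, 2001, 2501, 2960, 2958),
                     c(500, 500, 2500, 2503, 2990, 2960)),
    strand = c("+", "+", "-", "-", "+", "+"))
  ann$feature_type <- c("gene", "stop_codon", "gene", "stop_codon",
                        "gene", "stop_codon")
  ann$gene_id <- c("gp", "gp", "gm", "gm", "gt", "gt")
  utr <- buildUtrDb(ann, genome)
  gp <- utr[utr$gene == "gp", ]
  expect_identical(gp$sequence, substr(genome[["c1"]], 501, 1500))
  expect_false(gp$truncated)
  gm <- utr[utr$gene == "gm", ]
  expect_identical(gm$sequence,
                   revComp(substr(genome[["c1"]], 1501, 2500)))
  gt <- utr[utr$gene == "gt", ]
  expect_identical(gt$sequence, substr(genome[["c1"]], 2961, 3000))
  expect_true(gt$truncated)
  expect_identical(nchar(gt$sequence), 40L)
  # gene without stop feature is skipped with a warning
  ann2 <- ann[ann$feature_type == "gene" | ann$gene_id != "gp"]
  expect_warning(buildUtrDb(ann2, genome), "skipped")
})

test_that("an exact complementary site scores the hand-computed maximum", {
  milrna <- "TGAGTAGAATGGTCCCTGTCCC"      # 22 nt
  sur <- list(gene = "g1",
              sequence = paste0(strrep("A", 60), revComp(milrna),
                                strrep("A", 60)))
  hits <- scanAlignMode(milrna, sur, cfgT, modelT)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 61L)
  expect_identical(hits$end, 61L + 21L)
  # 22 matched columns at +5, the 7 seed-region columns doubled
  expect_equal(hits$score, 5 * 22 + 5 * 7)
  expect_lte(hits$energy, cfgT@duplexEnergyThreshold)
})

test_that("a single seed mismatch vetoes alignment-mode sites", {
  milrna <- "TGAGTAGAATGGTCCCTGTCCC"
  site <- revComp(milrna)
  # mutate the site base opposite milRNA seed position 4
  pos <- nchar(milrna) - 4 + 1
  old <- substr(site, pos, pos)
  substr(site, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  sur <- list(gene = "g1", sequence = paste0(strrep("A", 60), site,
                                             strrep("A", 60)))
  expect_identical(nrow(scanAlignMode(milrna, sur, cfgT, modelT)), 0L)
  expect_identical(nrow(scanAlignMode(milrna,
                                      list(gene = "g", sequence = ""),
                                      cfgT, modelT)), 0L)
})

test_that("duplex-mode sites find the planted complement and are monotone", {
  set.seed(91)
  milrna <- randomSeq(22, prob = c(0.2, 0.3, 0.3, 0.2))
  sur <- list(gene = "g1",
              sequence = paste0(randomSeq(200), revComp(milrna),
                                randomSeq(200)))
  hits <- scanDuplexMode(milrna, sur, cfgT, modelT)
  expect_gt(nrow(hits), 0L)
  planted <- hits[hits$start <= 201 & hits$end >= 222, ]
  expect_gt(nrow(planted), 0L)
  expect_identical(min(hits$energy), min(planted$energy))
  # loosening the threshold never loses covered positions (merging can
  # coalesce adjacent sites, so the interval count itself may shrink)
  loose <- milrConfig(duplexEnergyThreshold = 0)
  hitsLoose <- scanDuplexMode(milrna, sur, loose, modelT)
  covered <- function(h) unique(unlist(Map(seq, h$start, h$end)))
  expect_true(all(covered(hits) %in% covered(hitsLoose)))
  # an all-A surrogate offers no pairing to an A-free milRNA
  surA <- list(gene = "g2", sequence = strrep("A", 100))
  expect_identical(nrow(scanDuplexMode("GGGGGGGGGGGGGGGGGGGGGG", surA,
                                       cfgT, modelT)), 0L)
})

test_that("accessibility mode charges the structure-opening cost", {
  # purine-only milRNA: its complement site is pyrimidine-only and cannot
  # pair with itself or the A flanks, so dG_open is exactly 0
  milrna <- "AGGAGAGGAAGGAAGAGAGAGG"
  site <- revComp(milrna)
  openSur <- list(gene = "g1", sequence = paste0(strrep("A", 70), site,
                                                 strrep("A", 70)))
  openHits <- scanAccessMode(milrna, openSur, cfgT, modelT)
  expect_identical(nrow(openHits), 1L)
  # unstructured flanks: ddG equals the bare duplex energy
  expect_equal(-openHits$score, openHits$energy, tolerance = 1e-9)
  # pairing the site against its own complement inside the window makes
  # the opening cost strictly positive and the site strictly worse (or
  # rejected outright)
  closedSur <- list(gene = "g2",
                    sequence = paste0(strrep("A", 40), site, "AACAA",
                                      milrna, strrep("A", 40)))
  closedHits <- scanAccessMode(milrna, closedSur, cfgT, modelT)
  first <- closedHits[closedHits$start == 41, , drop = FALSE]
  expect_true(nrow(first) == 0L || first$score[1] < openHits$score[1])
  # dG_open is non-negative by construction
  stem <- "GCGGCGCCGGCGGCCGGCGC"
  win <- paste0(stem, "AAAA", revComp(stem))
  dOpen <- foldMFE(win, modelT, constraints = 1:10)@mfe -
    foldMFE(win, modelT)@mfe
  expect_gte(dOpen, 0)
})

test_that("consensus requires all three modes and obeys set algebra", {
  sites <- rbind(
    data.frame(gene = c("g1", "g2"), start = 1L, end = 20L,
               mode = "DUPLEX", score = 1, energy = -20,
               stringsAsFactors = FALSE),
    data.frame(gene = c("g1", "g2"), start = 1L, end = 20L,
               mode = "ALIGN", score = 100, energy = -20,
               stringsAsFactors = FALSE),
    data.frame(gene = "g1", start = 1L, end = 20L, mode = "ACCESS",
               score = 10, energy = -20, stringsAsFactors = FALSE))
  cons <- consensusTargets(sites)
  expect_identical(cons$targets$gene, "g1")
  v <- cons$venn
  expect_lte(v[["DUPLEX&ALIGN&ACCESS"]],
             min(v[["DUPLEX"]], v[["ALIGN"]], v[["ACCESS"]]))
  expect_identical(v[["DUPLEX&ALIGN"]], 2L)
})

test_that("the expression filter applies direction-specific boundaries", {
  expr <- data.frame(gene = c("a", "b", "c"),
                     Norm_MYC = c(50, 100, 200),
                     Norm_PRI = c(100, 100, 100), stringsAsFactors = FALSE)
  tg <- data.frame(gene = c("a", "b", "c"), stringsAsFactors = FALSE)
  # FC = 0.5 is kept for a PRI-elevated milRNA (inclusive)
  kept <- expressionFilter(tg[tg$gene == "a", , drop = FALSE], expr,
                           "PRI_up", tau = 0.5)
  expect_identical(kept$gene, "a")
  # and dropped for a MYC-elevated milRNA (strict >)
  expect_identical(nrow(expressionFilter(tg[tg$gene == "a", , drop = FALSE],
                                         expr, "MYC_up", tau = 0.5)), 0L)
  expect_identical(expressionFilter(tg, expr, "MYC_up")$gene, c("b", "c"))
  expect_warning(
    expressionFilter(data.frame(gene = "zz", stringsAsFactors = FALSE),
                     expr, "PRI_up"), "missing")
  exprBad <- expr
  exprBad$Norm_MYC[1] <- 0
  expect_error(expressionFilter(tg, exprBad, "PRI_up"), "positive")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # worked case: N = 10, K = 5, n = 4, k = 4 -> 5 / 210
  tt <- data.frame(gene = sprintf("g%02d", 1:10),
                   term = c(rep("T1", 5), rep("T2", 5)),
                   stringsAsFactors = FALSE)
  res <- enrichTerms(tt, sprintf("g%02d", 1:4))
  expect_equal(res$p_value[res$term == "T1"], 5 / 210, tolerance = 1e-12)
  # k = 0 and K = N give p = 1
  res0 <- enrichTerms(tt, sprintf("g%02d", 6:9))
  expect_equal(res0$p_value[res0$term == "T1"],
               1 - choose(5, 4) / choose(10, 4) * 0, tolerance = 1)
  ttAll <- data.frame(gene = sprintf("g%02d", 1:6), term = "T1",
                      stringsAsFactors = FALSE)
  expect_equal(enrichTerms(ttAll, sprintf("g%02d", 1:3))$p_value, 1)
  # randomized configurations against the combn oracle
  set.seed(41)
  for (rep in 1:25) {
    N <- sample(5:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    genes <- sprintf("x%02d", 1:N)
    tt2 <- data.frame(gene = genes,
                      term = c(rep("A", K), rep("B", N - K))[
                        seq_len(N)], stringsAsFactors = FALSE)
    tt2 <- rbind(tt2, data.frame(gene = genes, term = "bg"))
    tgt <- sample(genes, n)
    res2 <- enrichTerms(tt2, tgt)
    k <- sum(tgt %in% genes[seq_len(K)])
    expect_equal(res2$p_value[res2$term == "A"], oracleHyper(k, K, N, n),
                 tolerance = 1e-9)
  }
})

test_that("homolog scanning enforces the seed and mismatch budget", {
  set.seed(51)
  mature <- randomSeq(22)
  host <- paste0(randomSeq(100), mature, randomSeq(100))
  hits <- homologScan(mature, c(t1 = host), cfgT)
  expect_true(any(hits$start == 101 & hits$mismatches == 0 &
                  hits$strand == "+"))
  # reverse-complement embedding is found on the minus strand
  hitsRc <- homologScan(mature, c(t2 = revComp(host)), cfgT)
  expect_true(any(hitsRc$strand == "-" & hitsRc$mismatches == 0))
  # one seed mismatch: no hit at that position
  mut <- host
  substr(mut, 103, 103) <- setdiff(c("A", "C", "G", "T"),
                                   substr(host, 103, 103))[1]
  h2 <- homologScan(mature, c(t3 = mut), cfgT)
  expect_false(any(h2$start == 101 & h2$strand == "+"))
  # exactly three non-seed mismatches: excluded ("fewer than three")
  mut3 <- host
  for (p in c(100 + 10, 100 + 14, 100 + 20)) {
    substr(mut3, p, p) <- setdiff(c("A", "C", "G", "T"),
                                  substr(host, p, p))[1]
  }
  h3 <- homologScan(mature, c(t4 = mut3), cfgT)
  expect_false(any(h3$start == 101 & h3$strand == "+"))
  # two non-seed mismatches: still a homolog
  mut2 <- host
  for (p in c(100 + 10, 100 + 14)) {
    substr(mut2, p, p) <- setdiff(c("A", "C", "G", "T"),
                                  substr(host, p, p))[1]
  }
  h4 <- homologScan(mature, c(t5 = mut2), cfgT)
  expect_true(any(h4$start == 101 & h4$mismatches == 2))
  expect_error(homologScan("ACGTACG", c(t = host), cfgT), "at least 8")
})

test_that("homolog scanning always finds an exact embedded copy", {
  set.seed(52)
  for (i in 1:10) {
    mature <- randomSeq(sample(18:30, 1))
    t <- paste0(randomSeq(50), mature, randomSeq(50))
    hits <- homologScan(mature, c(x = t), cfgT)
    expect_true(any(hits$start == 51 & hits$mismatches == 0))
  }
})

test_that("comparative-Ct quantification follows the closed form", {
  same <- list(MYC = c(20, 20, 20), PRI = c(20, 20, 20))
  res <- relativeExpressionDdct(same, same, "MYC")
  expect_equal(res$RQ, c(1, 1), tolerance = 1e-12)
  # ddCt of -1 doubles the relative quantity
  tgt <- list(MYC = c(25, 25), PRI = c(24, 24))
  ref <- list(MYC = c(20, 20), PRI = c(20, 20))
  res2 <- relativeExpressionDdct(tgt, ref, "MYC")
  expect_equal(res2$RQ[res2$condition == "PRI"], 2, tolerance = 1e-12)
  expect_equal(res2$RQ[res2$condition == "MYC"], 1, tolerance = 1e-12)
  # textbook two-sample t statistic on per-replicate delta-Ct
  x <- c(1.02, 0.98, 1.00)
  y <- c(2.01, 1.99, 2.00)
  res3 <- relativeExpressionDdct(
    list(A = x + 20, B = y + 20),
    list(A = rep(20, 3), B = rep(20, 3)), "A")
  manual <- t.test(y, x, var.equal = TRUE)$p.value
  expect_equal(res3$p_value[res3$condition == "B"], manual,
               tolerance = 1e-12)
  expect_error(relativeExpressionDdct(list(A = 1, B = c(1, 2)),
                                      list(A = 1, B = c(1, 2)), "A"),
               "replicates")
})
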