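test_that("precursor windows always contain the read and honour bounds", {
  cfg <- milrConfig()
  genome <- c(c1 = strrep("ACGT", 500))
  aln <- data.frame(sequence = strrep("A", 20), contig = "c1",
                    start = 900L, end = 919L, strand = "+",
                    stringsAsFactors = FALSE)
  w <- enumeratePrecursorWindows(aln, genome, cfg)
  expect_true(all(w$start <= 900 & w$end >= 919))
  expect_true(all(w$window_len >= cfg@precursorMinLen &
                  w$window_len <= cfg@precursorMaxLen))
  nLens <- length(unique(c(seq(51, 150, 10), 150)))
  expect_lte(nrow(w), 3L * nLens)
  # mature offset points at the read within the window, strand-aware
  for (i in seq_len(nrow(w))) {
    sub <- substr(genome[["c1"]], w$start[i], w$end[i])
    expect_identical(substr(sub, w$mature_offset[i],
                            w$mature_offset[i] + 19L),
                     substr(genome[["c1"]], 900, 919))
  }
})

test_that("a read at the contig edge leaves only right-extensions", {
  cfg <- milrConfig()
  genome <- c(c1 = strrep("ACGT", 500))
  aln <- data.frame(sequence = strrep("A", 20), contig = "c1",
                    start = 1L, end = 20L, strand = "+",
                    stringsAsFactors = FALSE)
  w <- enumeratePrecursorWindows(aln, genome, cfg)
  expect_gt(nrow(w), 0L)
  expect_true(all(w$start == 1L))
  # minus-strand alignment mirrors the offsets
  alnM <- data.frame(sequence = strrep("A", 20), contig = "c1",
                     start = 500L, end = 519L, strand = "-",
                     stringsAsFactors = FALSE)
  wm <- enumeratePrecursorWindows(alnM, genome, cfg)
  for (i in seq_len(nrow(wm))) {
    sub <- revComp(substr(genome[["c1"]], wm$start[i], wm$end[i]))
    expect_identical(substr(sub, wm$mature_offset[i],
                            wm$mature_offset[i] + 19L),
                     revComp(substr(genome[["c1"]], 500, 519)))
  }
})

test_that("criteria boundaries are inclusive/strict exactly as specified", {
  cfg <- milrConfig()
  expect_true(criteriaCheck(fakeCandidate(mfe = -20.0), cfg)$pass)
  chk <- criteriaCheck(fakeCandidate(mfe = -19.9), cfg)
  expect_false(chk$pass)
  expect_identical(chk$failures, "MFE")
  expect_identical(criteriaCheck(fakeCandidate(p = 0.01), cfg)$failures,
                   "RANDFOLD")
  expect_true(criteriaCheck(fakeCandidate(p = 0.0099), cfg)$pass)
  expect_identical(
    criteriaCheck(fakeCandidate(totalPairs = 17L), cfg)$failures, "STEM")
  expect_true(criteriaCheck(fakeCandidate(totalPairs = 18L), cfg)$pass)
  expect_identical(
    criteriaCheck(fakeCandidate(loopSize = 3L), cfg)$failures, "LOOP")
  expect_true(criteriaCheck(fakeCandidate(loopSize = 4L), cfg)$pass)
  expect_identical(
    criteriaCheck(fakeCandidate(counts = c(M = 3.5, P = 0)), cfg)$failures,
    "READS")
  expect_true(criteriaCheck(fakeCandidate(counts = c(M = 3.5, P = 0.5)),
                            cfg)$pass)
  # every violated tag is reported
  allBad <- fakeCandidate(mfe = -1, totalPairs = 2L, nLoops = 2L, p = 0.5,
                          counts = c(M = 1))
  expect_setequal(criteriaCheck(allBad, cfg)$failures,
                  c("MFE", "STEM", "LOOP", "RANDFOLD", "READS"))
})

test_that("criteria are monotone in each threshold", {
  cfg <- milrConfig()
  cand <- fakeCandidate(mfe = -21, totalPairs = 19L, loopSize = 5L,
                        p = 0.005, counts = c(M = 5))
  expect_true(criteriaCheck(cand, cfg)$pass)
  relaxed <- list(
    milrConfig(mfeThreshold = -15), milrConfig(minStemPairs = 10L),
    milrConfig(minLoopSize = 3L), milrConfig(randfoldAlpha = 0.05),
    milrConfig(minReads = 2))
  for (cfg2 in relaxed)
    expect_true(criteriaCheck(cand, cfg2)$pass)
})

test_that("best-window selection orders by MFE, length, then start", {
  mk <- function(mfe, start, end)
    list(fold = foldFromDotBracket("A", ".", mfe = mfe),
         start = start, end = end)
  expect_identical(
    selectBestWindow(list(mk(-25, 10, 100), mk(-30, 20, 110)))$start, 20)
  expect_identical(
    selectBestWindow(list(mk(-25, 10, 69), mk(-25, 5, 84)))$start, 10)
  expect_identical(
    selectBestWindow(list(mk(-25, 10, 69), mk(-25, 5, 64)))$start, 5)
  expect_error(selectBestWindow(list()), "no passing candidate")
})

test_that("known-miRNA matching tolerates two mismatches and small shifts", {
  ref <- c(mir1 = "ACGTACGTACGTACGTACGT", mir2 = "TTTTTTTTTTTTTTTTTTTT")
  expect_identical(matchKnown("ACGTACGTACGTACGTACGT", ref), "mir1")
  two <- "ACGTACGTACGTACGTACCC"
  expect_identical(matchKnown(two, ref), "mir1")
  three <- "ACGTACGTACGTACGTGCCC"
  expect_identical(matchKnown(three, ref), NA_character_)
  expect_identical(matchKnown("ACGT", character(0)), NA_character_)
})

test_that("greedy clustering respects the inclusive identity threshold", {
  a <- strrep("ACGTG", 4)                        # 20-mer
  b <- a; substr(b, 3, 3) <- "T"                 # 1 mismatch: 0.95
  c2 <- a; substr(c2, 3, 3) <- "T"; substr(c2, 10, 10) <- "A"  # 0.90
  expect_identical(clusterCandidates(c(a, a), c(5, 1)), c(1L, 1L))
  expect_identical(clusterCandidates(c(a, b), c(5, 1)), c(1L, 1L))
  expect_identical(clusterCandidates(c(a, c2), c(5, 1)), c(1L, 2L))
})

test_that("locus classification applies the rRNA > tRNA > exon priority", {
  ann <- GenomicRanges::GRanges(
    rep("c1", 3), IRanges::IRanges(c(1, 1, 200), c(100, 150, 300)))
  ann$feature_type <- c("rRNA", "exon", "exon")
  ann$gene_id <- c("r", "e", "e2")
  loci <- data.frame(contig = "c1", start = c(10, 210, 400),
                     end = c(40, 240, 430), stringsAsFactors = FALSE)
  expect_identical(classifyLocus(loci, ann),
                   c("rRNA", "exon", "intergenic"))
})

test_that("the published composition reproduces the reported percentages", {
  cls <- c(rep("rRNA", 5), rep("exon", 2), rep("intergenic", 15))
  s <- classificationSummary(cls)
  expect_identical(s$percent[s$class == "intergenic"], 68)
  expect_identical(s$percent[s$class == "rRNA"], 23)
  expect_identical(s$percent[s$class == "exon"], 9)
})

test_that("identifier assignment numbers clusters and letters loci", {
  df <- data.frame(
    contig = c("c1", "c1", "c2", "c1"),
    start = c(100L, 500L, 50L, 900L), end = c(120L, 520L, 70L, 920L),
    strand = c("+", "+", "+", "+"),
    precursor_start = c(80L, 480L, 30L, 880L),
    precursor_end = c(180L, 580L, 130L, 980L),
    arm = c("5p", "5p", "5p", "5p"),
    cluster = c(1L, 1L, 2L, 1L), stringsAsFactors = FALSE)
  ids <- assignNames(df, contigOrder = c("c1", "c2"))
  expect_identical(ids, c("cci-milR-1a", "cci-milR-1b", "cci-milR-2",
                          "cci-milR-1c"))
  # both arms of one precursor
  df2 <- data.frame(
    contig = "c1", start = c(100L, 140L), end = c(120L, 160L),
    strand = "+", precursor_start = 80L, precursor_end = 180L,
    arm = c("5p", "3p"), cluster = c(1L, 2L), stringsAsFactors = FALSE)
  ids2 <- assignNames(df2, contigOrder = "c1")
  expect_identical(ids2, c("cci-milR-1-5p", "cci-milR-2-3p"))
  # order independence of the accepted set
  perm <- c(3L, 1L, 4L, 2L)
  expect_identical(assignNames(df[perm, ], contigOrder = c("c1", "c2")),
                   ids[perm])
})

test_that("the discovery report is internally consistent", {
  run <- smallRun()
  rep <- discoveryReport(run$discovery$milrnas)
  tab <- rep$table
  expect_gt(nrow(tab), 0L)
  expect_identical(tab$length, nchar(tab$sequence))
  loc <- do.call(rbind, lapply(tab$locus, function(x)
    as.integer(strsplit(sub("^.*:", "", x), "-")[[1]])))
  expect_identical(loc[, 2] - loc[, 1] + 1L, tab$length)
  expect_false(any(duplicated(tab$id)))
  expect_identical(sum(rep$length_hist$n), nrow(tab))
})
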