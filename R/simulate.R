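# Synthetic dataset with planted ground truth.
#
# The generator emulates the statistical structure the discovery pipeline
# assumes: a multi-contig genome of i.i.d. uniform background carrying
# planted pre-milRNA hairpins (perfect stems softened by two G:U wobbles on
# the star arm), dinucleotide-shuffled decoy hairpin loci with read support,
# rRNA/tRNA/exon decoy annotation, genes with stop codons and 1000-bp
# downstream target regions (a subset carrying exact reverse-complement
# sites of the first planted mature), two read libraries with a 5'-U bias
# and planted contaminants, a two-stage expression table with prescribed
# fold changes, and a small EST set for homolog scanning.

#' Create a simulation specification
#'
#' Defaults describe the study conditions used throughout the test-suite:
#' a 2 x 50-kb genome, 20 planted hairpins, decoy loci, 30 genes, 4000
#' background reads per library with a 0.6 five-prime-U fraction and 5%
#' each of short and low-quality contaminants.
#'
#' @param nContigs,contigLen genome shape.
#' @param nHairpins number of planted pre-milRNA hairpins.
#' @param nDecoyRrna,nDecoyTrna number of annotated decoy rRNA/tRNA loci.
#' @param nDecoyHairpins number of shuffled decoy hairpin loci that carry
#'   read support but fail the hairpin criteria.
#' @param nGenes number of genes (each with a stop codon and a free 1000-bp
#'   downstream region).
#' @param readsPerLibrary background reads per library (mature reads from
#'   planted counts come on top).
#' @param fivePrimeUFraction fraction of background reads starting with U/T.
#' @param plantedTargetFraction fraction of genes receiving a planted
#'   perfect-complement target site of the first mature milRNA.
#' @param contaminantShortFraction,contaminantLowqFraction fractions of
#'   background reads that are too short (< 18 nt after trimming) or
#'   low-quality (mean Phred < 20).
#' @param adapter 3' adapter appended to contaminant/adapter-bearing reads.
#' @param adapterFraction fraction of normal background reads carrying the
#'   adapter.
#' @param noiseSd log-normal noise sd of the expression table.
#' @param fcMap optional named numeric of per-gene MYC/PRI fold changes;
#'   generated when empty (planted-target genes alternate 0.25 and 2).
#' @param nEsts number of EST/transcript sequences for homolog scanning.
#' @param rngSeed master seed; all outputs are deterministic given it.
#' @return a validated [SimulationSpec-class].
#' @export
simulationSpec <- function(nContigs = 2L, contigLen = 50000L,
                           nHairpins = 20L, nDecoyRrna = 4L,
                           nDecoyTrna = 4L, nDecoyHairpins = 6L,
                           nGenes = 30L, readsPerLibrary = 4000L,
                           fivePrimeUFraction = 0.6,
                           plantedTargetFraction = 0.2,
                           contaminantShortFraction = 0.05,
                           contaminantLowqFraction = 0.05,
                           adapter = "TGGAATTCTCGGGTGCCAAGG",
                           adapterFraction = 0.3, noiseSd = 0.1,
                           fcMap = numeric(0), nEsts = 6L, rngSeed = 1L) {
  new("SimulationSpec", nContigs = as.integer(nContigs),
      contigLen = as.integer(contigLen), nHairpins = as.integer(nHairpins),
      nDecoyRrna = as.integer(nDecoyRrna), nDecoyTrna = as.integer(nDecoyTrna),
      nDecoyHairpins = as.integer(nDecoyHairpins), nGenes = as.integer(nGenes),
      readsPerLibrary = as.integer(readsPerLibrary),
      fivePrimeUFraction = fivePrimeUFraction,
      plantedTargetFraction = plantedTargetFraction,
      contaminantShortFraction = contaminantShortFraction,
      contaminantLowqFraction = contaminantLowqFraction,
      adapter = toupper(adapter), adapterFraction = adapterFraction,
      noiseSd = noiseSd, fcMap = fcMap, nEsts = as.integer(nEsts),
      rngSeed = as.integer(rngSeed))
}

randomDna <- function(n, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# window lengths enumerated by precursor extension; planted precursors use
# the same set so at least one discovery window matches a plant exactly
windowLengths <- function(cfg) {
  sort(unique(c(seq(cfg@precursorMinLen, cfg@precursorMaxLen,
                    by = cfg@windowLenStep),
                cfg@precursorMinLen, cfg@precursorMaxLen)))
}

# star arm: reverse complement of the mature with two G:U wobbles, so the
# mature read does not map exactly onto the opposite strand of the stem
wobbledStar <- function(mature) {
  m <- strsplit(mature, "")[[1]]
  r <- length(m)
  star <- strsplit(revComp(mature), "")[[1]]
  cand <- which(m %in% c("G", "T"))
  if (length(cand) < 2L) return(NULL)
  pick <- sort(sample(cand, 2L))
  for (i in pick) {
    j <- r - i + 1L               # mirrored star position
    star[j] <- if (m[i] == "G") "T" else "G"
  }
  paste(star, collapse = "")
}

#' Draw one planted pre-milRNA hairpin
#'
#' Rejection-samples a precursor whose fold under the shipped energy model
#' satisfies all structural selection criteria: MFE at or below the
#' threshold, at least the required number of base pairs, a single terminal
#' loop of at least the minimum size, and the mature arm fully inside the
#' stem. The precursor length is drawn from the enumerated window-length
#' set with the mature at the precursor end matching its arm.
#'
#' @param cfg a [MilrConfig-class].
#' @param model an [EnergyModel-class]; packaged default when `NULL`.
#' @param matureLen mature length (18--30); random when `NULL`.
#' @param arm "5p" or "3p"; random when `NULL`.
#' @param maxAttempts rejection-sampling bound; exceeding it signals an
#'   incompatibility between the energy model and the thresholds.
#' @return list with `precursor`, `mature`, `star`, `arm`, `matureStart`,
#'   `matureEnd` (1-based within the precursor) and `mfe`.
#' @export
plantHairpin <- function(cfg = milrConfig(), model = NULL, matureLen = NULL,
                         arm = NULL, maxAttempts = 200L) {
  if (is.null(model)) model <- configEnergyModel(cfg)
  lens <- windowLengths(cfg)
  for (attempt in seq_len(maxAttempts)) {
    r <- if (is.null(matureLen))
      sample(cfg@minReadLen:cfg@maxReadLen, 1L) else as.integer(matureLen)
    a <- if (is.null(arm)) sample(c("5p", "3p"), 1L) else arm
    ok <- lens[lens - 2L * r >= cfg@minLoopSize]
    if (!length(ok)) next
    L <- ok[1L]
    loopLen <- L - 2L * r
    mature <- randomDna(r, prob = c(0.22, 0.28, 0.28, 0.22))
    star <- wobbledStar(mature)
    if (is.null(star)) next
    loop <- randomDna(loopLen)
    if (a == "5p") {
      precursor <- paste0(mature, loop, star)
      ms <- 1L; me <- r
    } else {
      precursor <- paste0(star, loop, mature)
      ms <- L - r + 1L; me <- L
    }
    fold <- foldMFE(precursor, model)
    if (fold@mfe > cfg@mfeThreshold) next
    loops <- countHairpinLoops(fold)
    if (loops$n_terminal_loops != 1L ||
        loops$loop_sizes[1L] < cfg@minLoopSize) next
    st <- stemStatistics(fold, ms, me)
    if (st$total_pairs < cfg@minStemPairs || !st$mature_in_stem ||
        st$arm != a) next
    return(list(precursor = precursor, mature = mature, star = star,
                arm = a, matureStart = ms, matureEnd = me, mfe = fold@mfe))
  }
  stop("plantHairpin: no acceptable hairpin after ", maxAttempts,
       " attempts; energy model and thresholds may be incompatible")
}

# a shuffled decoy that fails the structural criteria at its own window
decoyFromHairpin <- function(hp, cfg, model, maxAttempts = 50L) {
  for (i in seq_len(maxAttempts)) {
    sh <- dinucleotideShuffle(hp$precursor)
    fold <- foldMFE(sh, model)
    loops <- countHairpinLoops(fold)
    fails <- fold@mfe > cfg@mfeThreshold ||
      loops$n_terminal_loops != 1L ||
      (loops$n_terminal_loops == 1L &&
         loops$loop_sizes[1L] < cfg@minLoopSize) ||
      sum(fold@pairTable > seq_along(fold@pairTable)) < cfg@minStemPairs
    if (fails) return(sh)
  }
  stop("could not derive a failing decoy from the planted hairpin")
}

#' Simulate the genome, annotation and ground-truth table
#'
#' Lays out planted hairpins, decoy rRNA/tRNA loci, shuffled decoy hairpins
#' and genes (gene body annotated as gene + exon, a 3-nt stop codon at the
#' coding end, and a free 1000-bp downstream region) over i.i.d. uniform
#' background contigs. Planted target sites (exact reverse complements of
#' the first mature) are embedded in the downstream regions of a fraction
#' of genes. Deterministic given `spec@rngSeed`.
#'
#' @param spec a [SimulationSpec-class].
#' @param cfg a [MilrConfig-class].
#' @return list with `genome` (named character vector), `annotation`
#'   (GRanges with feature_type/gene_id), and `truth` (data.frame with
#'   columns kind, contig, start, end, strand, sequence, counts_MYC,
#'   counts_PRI, mature_seq, mature_arm, mature_start, mature_end, gene_id).
#' @export
simulateGenome <- function(spec, cfg = milrConfig()) {
  validObject(spec)
  model <- configEnergyModel(cfg)
  with_seed(spec@rngSeed, {
    nC <- spec@nContigs
    contigNames <- sprintf("ctg%02d", seq_len(max(nC, 1L)))[seq_len(nC)]
    # draw hairpins and their counts first
    hairpins <- if (spec@nHairpins > 0)
      lapply(seq_len(spec@nHairpins), function(i) plantHairpin(cfg, model))
    else list()
    counts <- lapply(seq_along(hairpins), function(i) {
      if (i == 1L) c(MYC = 100, PRI = 1000)        # strongly PRI-elevated
      else if (i <= 3L) c(MYC = sample(10:150, 1L), PRI = 0) # stage-specific
      else c(MYC = sample(5:150, 1L), PRI = sample(5:150, 1L))
    })
    decoys <- if (spec@nDecoyHairpins > 0 && length(hairpins))
      lapply(seq_len(spec@nDecoyHairpins), function(i) {
        src <- hairpins[[((i - 1L) %% length(hairpins)) + 1L]]
        list(seq = decoyFromHairpin(src, cfg, model),
             matureLen = nchar(src$mature))
      })
    else list()

    # feature queue: (type, payload); round-robin over contigs
    queue <- list()
    for (i in seq_along(hairpins))
      queue <- c(queue, list(list(type = "hairpin", i = i)))
    for (i in seq_along(decoys))
      queue <- c(queue, list(list(type = "decoy_hairpin", i = i)))
    for (i in seq_len(spec@nDecoyRrna))
      queue <- c(queue, list(list(type = "rRNA", i = i)))
    for (i in seq_len(spec@nDecoyTrna))
      queue <- c(queue, list(list(type = "tRNA", i = i)))
    geneIds <- if (spec@nGenes > 0)
      sprintf("gene%03d", seq_len(spec@nGenes)) else character(0)
    nTarget <- round(spec@plantedTargetFraction * spec@nGenes)
    targetGenes <- head(geneIds, nTarget)
    for (i in seq_len(spec@nGenes))
      queue <- c(queue, list(list(type = "gene", i = i)))
    if (length(queue)) queue <- sample(queue)   # mix feature kinds

    contigSeq <- setNames(vector("list", nC), contigNames)
    for (cn in contigNames) contigSeq[[cn]] <- character(0)
    cursor <- setNames(rep(1L, nC), contigNames)
    pad0 <- 150L
    for (cn in contigNames) {
      contigSeq[[cn]] <- randomDna(pad0)
      cursor[cn] <- pad0 + 1L
    }

    ann <- list()
    truth <- list()
    addFeature <- function(cn, block, rows, feats) {
      # rows/feats carry start offsets relative to block start
      st <- cursor[cn]
      if (st + nchar(block) - 1L > spec@contigLen)
        stop("sizing error: contig ", cn, " too short for requested features")
      contigSeq[[cn]] <<- c(contigSeq[[cn]], block)
      cursor[cn] <<- st + nchar(block)
      gap <- randomDna(sample(30:120, 1L))
      if (cursor[cn] + nchar(gap) <= spec@contigLen) {
        contigSeq[[cn]] <<- c(contigSeq[[cn]], gap)
        cursor[cn] <<- cursor[cn] + nchar(gap)
      }
      st
    }

    ci <- 0L
    milr1 <- if (length(hairpins)) hairpins[[1L]] else NULL
    for (item in queue) {
      ci <- ci + 1L
      cn <- contigNames[((ci - 1L) %% nC) + 1L]
      if (item$type == "hairpin") {
        hp <- hairpins[[item$i]]
        strand <- sample(c("+", "-"), 1L)
        L <- nchar(hp$precursor)
        block <- if (strand == "+") hp$precursor else revComp(hp$precursor)
        st <- addFeature(cn, block, NULL, NULL)
        # mature plus-strand coordinates
        if (strand == "+") {
          mst <- st + hp$matureStart - 1L; men <- st + hp$matureEnd - 1L
        } else {
          mst <- st + (L - hp$matureEnd); men <- st + (L - hp$matureStart)
        }
        cnt <- counts[[item$i]]
        truth[[length(truth) + 1L]] <- data.frame(
          kind = "hairpin", contig = cn, start = st, end = st + L - 1L,
          strand = strand, sequence = hp$precursor,
          counts_MYC = cnt[["MYC"]], counts_PRI = cnt[["PRI"]],
          mature_seq = hp$mature, mature_arm = hp$arm,
          mature_start = mst, mature_end = men, gene_id = NA_character_,
          stringsAsFactors = FALSE)
      } else if (item$type == "decoy_hairpin") {
        dc <- decoys[[item$i]]
        st <- addFeature(cn, dc$seq, NULL, NULL)
        mlen <- dc$matureLen
        truth[[length(truth) + 1L]] <- data.frame(
          kind = "decoy_hairpin", contig = cn, start = st,
          end = st + nchar(dc$seq) - 1L, strand = "+", sequence = dc$seq,
          counts_MYC = sample(5:40, 1L), counts_PRI = sample(5:40, 1L),
          mature_seq = substr(dc$seq, 1L, mlen), mature_arm = "5p",
          mature_start = st, mature_end = st + mlen - 1L,
          gene_id = NA_character_, stringsAsFactors = FALSE)
      } else if (item$type %in% c("rRNA", "tRNA")) {
        len <- if (item$type == "rRNA") 300L else 75L
        block <- randomDna(len)
        st <- addFeature(cn, block, NULL, NULL)
        ann[[length(ann) + 1L]] <- data.frame(
          contig = cn, start = st, end = st + len - 1L, strand = "+",
          feature_type = item$type,
          gene_id = sprintf("%s%02d", tolower(item$type), item$i),
          stringsAsFactors = FALSE)
      } else { # gene
        gid <- geneIds[item$i]
        strand <- sample(c("+", "-"), 1L)
        bodyLen <- 500L
        downLen <- 1000L
        body <- randomDna(bodyLen)
        down <- randomDna(downLen)
        if (gid %in% targetGenes && !is.null(milr1)) {
          site <- if (strand == "+") revComp(milr1$mature) else milr1$mature
          off <- sample(100:(downLen - nchar(site) - 100L), 1L)
          substr(down, off, off + nchar(site) - 1L) <- site
        }
        if (strand == "+") {
          block <- paste0(body, down)
          st <- addFeature(cn, block, NULL, NULL)
          gStart <- st; gEnd <- st + bodyLen - 1L
          stopStart <- gEnd - 2L; stopEnd <- gEnd
          siteStrandStart <- st + bodyLen
        } else {
          block <- paste0(down, body)
          st <- addFeature(cn, block, NULL, NULL)
          gStart <- st + downLen; gEnd <- st + downLen + bodyLen - 1L
          stopStart <- gStart; stopEnd <- gStart + 2L
          siteStrandStart <- st
        }
        for (ft in c("gene", "exon"))
          ann[[length(ann) + 1L]] <- data.frame(
            contig = cn, start = gStart, end = gEnd, strand = strand,
            feature_type = ft, gene_id = gid, stringsAsFactors = FALSE)
        ann[[length(ann) + 1L]] <- data.frame(
          contig = cn, start = stopStart, end = stopEnd, strand = strand,
          feature_type = "stop_codon", gene_id = gid,
          stringsAsFactors = FALSE)
        if (gid %in% targetGenes && !is.null(milr1)) {
          sLen <- nchar(milr1$mature)
          sStart <- siteStrandStart + off - 1L
          truth[[length(truth) + 1L]] <- data.frame(
            kind = "target_site", contig = cn, start = sStart,
            end = sStart + sLen - 1L, strand = strand,
            sequence = revComp(milr1$mature), counts_MYC = NA_real_,
            counts_PRI = NA_real_, mature_seq = milr1$mature,
            mature_arm = NA_character_, mature_start = NA_integer_,
            mature_end = NA_integer_, gene_id = gid,
            stringsAsFactors = FALSE)
        }
      }
    }
    genome <- vapply(contigNames, function(cn) {
      s <- paste(contigSeq[[cn]], collapse = "")
      if (nchar(s) < spec@contigLen)
        s <- paste0(s, randomDna(spec@contigLen - nchar(s)))
      s
    }, character(1))
    annotation <- if (length(ann)) {
      a <- do.call(rbind, ann)
      gr <- GenomicRanges::GRanges(a$contig,
                                   IRanges::IRanges(a$start, a$end),
                                   strand = a$strand)
      gr$feature_type <- a$feature_type
      gr$gene_id <- a$gene_id
      gr
    } else GenomicRanges::GRanges()
    truthTab <- if (length(truth)) do.call(rbind, truth) else
      data.frame(kind = character(0), contig = character(0),
                 start = integer(0), end = integer(0), strand = character(0),
                 sequence = character(0), counts_MYC = numeric(0),
                 counts_PRI = numeric(0), mature_seq = character(0),
                 mature_arm = character(0), mature_start = integer(0),
                 mature_end = integer(0), gene_id = character(0),
                 stringsAsFactors = FALSE)
    list(genome = genome, annotation = annotation, truth = truthTab)
  })
}

#' Simulate the two small-RNA read libraries
#'
#' Mature-derived reads are emitted with the per-library counts recorded in
#' the truth table (hairpins and decoy hairpins); background reads are drawn
#' uniformly from both genome strands with lengths 18--30 nt, a configurable
#' 5'-U fraction, and planted contaminants: short inserts (< 18 nt) and
#' low-quality reads (mean Phred < 20). Adapter-bearing reads carry the
#' spec's adapter appended at the 3' end.
#'
#' @param truth truth table from [simulateGenome()].
#' @param spec a [SimulationSpec-class].
#' @param genome named character vector of contig sequences.
#' @param seed seed for this stage (defaults to `spec@rngSeed + 1`).
#' @return list of two data.frames (`MYC`, `PRI`) with columns id,
#'   sequence, quality.
#' @export
simulateReads <- function(truth, spec, genome, seed = spec@rngSeed + 1L) {
  contigs <- names(genome)
  clens <- nchar(genome)
  qOK <- function(n) strrep("I", n)     # Phred 40
  qBad <- function(n) strrep("+", n)    # Phred 10
  with_seed(seed, {
    libs <- list()
    for (lib in c("MYC", "PRI")) {
      seqs <- character(0)
      quals <- character(0)
      mat <- truth[truth$kind %in% c("hairpin", "decoy_hairpin"), ,
                   drop = FALSE]
      for (i in seq_len(nrow(mat))) {
        n <- round(mat[[paste0("counts_", lib)]][i])
        if (n > 0) {
          seqs <- c(seqs, rep(mat$mature_seq[i], n))
          quals <- c(quals, rep(qOK(nchar(mat$mature_seq[i])), n))
        }
      }
      nBg <- spec@readsPerLibrary
      if (nBg > 0 && length(genome) > 0) {
        cls <- runif(nBg)
        isShort <- cls < spec@contaminantShortFraction
        isLowq <- !isShort &
          cls < spec@contaminantShortFraction + spec@contaminantLowqFraction
        for (k in seq_len(nBg)) {
          len <- if (isShort[k]) sample(10:17, 1L) else sample(18:30, 1L)
          wantU <- runif(1) < spec@fivePrimeUFraction
          first <- if (wantU) "T" else sample(c("A", "C", "G"), 1L)
          s <- NULL
          for (try in 1:60) {
            cn <- sample(seq_along(contigs), 1L,
                         prob = clens / sum(clens))
            if (clens[cn] < len) next
            st <- sample(clens[cn] - len + 1L, 1L)
            cand <- substr(genome[[cn]], st, st + len - 1L)
            if (runif(1) < 0.5) cand <- revComp(cand)
            if (substr(cand, 1L, 1L) == first) { s <- cand; break }
          }
          if (is.null(s)) s <- cand
          withAdapter <- isShort[k] || runif(1) < spec@adapterFraction
          if (withAdapter) s <- paste0(s, spec@adapter)
          seqs <- c(seqs, s)
          quals <- c(quals, if (isLowq[k]) qBad(nchar(s)) else qOK(nchar(s)))
        }
      }
      if (length(seqs)) {
        ord <- sample(length(seqs))
        seqs <- seqs[ord]
        quals <- quals[ord]
      }
      libs[[lib]] <- data.frame(
        id = if (length(seqs))
          sprintf("%s_r%06d", lib, seq_along(seqs)) else character(0),
        sequence = seqs, quality = quals, stringsAsFactors = FALSE)
    }
    libs
  })
}

#' Simulate a two-stage normalized expression table
#'
#' `Norm_MYC / Norm_PRI` equals the prescribed fold change up to
#' multiplicative log-normal noise of sd `noiseSd`; all values are strictly
#' positive.
#'
#' @param genes character vector of gene ids.
#' @param fcMap named numeric, fold change (MYC over PRI) per gene; genes
#'   absent from the map get fold change 1.
#' @param noiseSd log-normal noise sd (0 = exact ratios).
#' @param seed optional seed.
#' @return data.frame with columns gene, Norm_MYC, Norm_PRI.
#' @export
simulateExpression <- function(genes, fcMap = numeric(0), noiseSd = 0.1,
                               seed = NULL) {
  fc <- rep(1, length(genes))
  names(fc) <- genes
  if (length(fcMap)) {
    unknown <- setdiff(names(fcMap), genes)
    if (length(unknown))
      stop("fcMap contains unknown genes: ",
           paste(head(unknown, 3), collapse = ", "))
    if (any(fcMap <= 0)) stop("fold changes must be positive")
    fc[names(fcMap)] <- fcMap
  }
  with_seed(seed, {
    pri <- exp(rnorm(length(genes), log(500), 0.8))
    myc <- fc * pri *
      if (noiseSd > 0) exp(rnorm(length(genes), 0, noiseSd)) else 1
    data.frame(gene = genes, Norm_MYC = myc, Norm_PRI = pri,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a gene-to-term annotation table
#'
#' @param genes character vector of gene ids.
#' @param nTerms number of distinct terms.
#' @param seed optional seed.
#' @return data.frame with columns gene, term (one row per assignment;
#'   every gene receives 1--3 terms).
#' @export
simulateTerms <- function(genes, nTerms = 6L, seed = NULL) {
  terms <- sprintf("T%02d", seq_len(nTerms))
  with_seed(seed, {
    rows <- lapply(genes, function(g) {
      k <- sample(1:3, 1L)
      data.frame(gene = g, term = sample(terms, k),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate an EST/transcript set for homolog scanning
#'
#' Emits random transcripts, a subset carrying an exact copy of the first
#' planted mature milRNA, one carrying a copy with a single seed mismatch
#' (must not be reported as a homolog) and one with three mismatches
#' downstream of the seed (also a non-homolog).
#'
#' @param truth truth table from [simulateGenome()].
#' @param spec a [SimulationSpec-class].
#' @param seed optional seed.
#' @return named character vector of transcript sequences; names carry the
#'   planted role (exact / seed_mm / many_mm / background).
#' @export
simulateEsts <- function(truth, spec, seed = spec@rngSeed + 2L) {
  # same mature the planted target sites refer to, when present
  ts <- truth[truth$kind == "target_site", , drop = FALSE]
  hp <- truth[truth$kind == "hairpin", , drop = FALSE]
  with_seed(seed, {
    n <- spec@nEsts
    out <- character(0)
    mature <- if (nrow(ts)) ts$mature_seq[1L]
      else if (nrow(hp)) hp$mature_seq[1L] else NULL
    mutateAt <- function(s, pos) {
      for (p in pos) {
        old <- substr(s, p, p)
        substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      }
      s
    }
    embed <- function(insert) {
      t <- randomDna(300L)
      off <- sample(50:200, 1L)
      substr(t, off, off + nchar(insert) - 1L) <- insert
      t
    }
    k <- 0L
    while (length(out) < n) {
      k <- k + 1L
      if (!is.null(mature) && k <= max(1L, n - 3L)) {
        out <- c(out, setNames(embed(mature), sprintf("est_exact_%02d", k)))
      } else if (!is.null(mature) && k == n - 2L) {
        out <- c(out, setNames(embed(mutateAt(mature, 3L)),
                               "est_seed_mm"))
      } else if (!is.null(mature) && k == n - 1L) {
        L <- nchar(mature)
        out <- c(out, setNames(embed(mutateAt(mature, c(10L, 12L, L - 1L))),
                               "est_many_mm"))
      } else {
        out <- c(out, setNames(randomDna(300L),
                               sprintf("est_background_%02d", k)))
      }
    }
    out
  })
}

#' Generate the complete synthetic dataset
#'
#' Runs [simulateGenome()], [simulateReads()], [simulateExpression()],
#' [simulateTerms()] and [simulateEsts()] under seeds derived from
#' `spec@rngSeed`, optionally writing all artifacts (genome.fa,
#' annotation.gff3, truth.tsv, reads_MYC.fastq, reads_PRI.fastq,
#' expression.tsv, terms.tsv, ests.fa) to a directory.
#'
#' @param spec a [SimulationSpec-class].
#' @param cfg a [MilrConfig-class].
#' @param dir optional output directory (created if needed).
#' @return list with genome, annotation, truth, reads, expression, terms,
#'   ests, fcMap.
#' @export
simulateDataset <- function(spec = simulationSpec(), cfg = milrConfig(),
                            dir = NULL) {
  gen <- simulateGenome(spec, cfg)
  reads <- simulateReads(gen$truth, spec, gen$genome)
  genes <- unique(gen$annotation$gene_id[
    gen$annotation$feature_type == "gene"])
  fcMap <- spec@fcMap
  if (!length(fcMap) && length(genes)) {
    tg <- unique(gen$truth$gene_id[gen$truth$kind == "target_site"])
    tg <- tg[!is.na(tg)]
    fcMap <- with_seed(spec@rngSeed + 3L,
                       setNames(exp(rnorm(length(genes), 0, 0.3)), genes))
    if (length(tg)) {
      half <- seq_along(tg) %% 2L == 1L
      fcMap[tg[half]] <- 0.25       # concordant with a PRI-elevated milRNA
      fcMap[tg[!half]] <- 2.0       # discordant: must be filtered out
    }
  }
  expr <- simulateExpression(genes, fcMap, spec@noiseSd,
                             seed = spec@rngSeed + 4L)
  terms <- if (length(genes))
    simulateTerms(genes, seed = spec@rngSeed + 5L) else
    data.frame(gene = character(0), term = character(0))
  ests <- simulateEsts(gen$truth, spec)
  out <- list(genome = gen$genome, annotation = gen$annotation,
              truth = gen$truth, reads = reads, expression = expr,
              terms = terms, ests = ests, fcMap = fcMap)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeFastaFile(out$genome, file.path(dir, "genome.fa"))
    writeAnnotation(out$annotation, file.path(dir, "annotation.gff3"),
                    "GFF3")
    write.table(out$truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeFastqFile(out$reads$MYC, file.path(dir, "reads_MYC.fastq"))
    writeFastqFile(out$reads$PRI, file.path(dir, "reads_PRI.fastq"))
    write.table(out$expression, file.path(dir, "expression.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(out$terms, file.path(dir, "terms.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeFastaFile(out$ests, file.path(dir, "ests.fa"))
  }
  out
}
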