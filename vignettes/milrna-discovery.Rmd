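---
title: "Discovering microRNA-like RNAs in a fungal genome: models and methods"
author: "milrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering microRNA-like RNAs in a fungal genome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milrscan)
```

# The problem

Fungal microRNA-like RNAs (milRNAs) are small RNAs with the biogenesis
hallmarks of canonical miRNAs — a genomic precursor of roughly 51–150 nt that
folds into a stem–loop, from which a defined 18–30 nt mature species is
excised — but without the strong cross-species conservation that anchors
miRNA discovery in animals and plants. `milrscan` implements a complete
discovery and downstream-analysis pipeline for this setting, modelled on the
analysis used for the basidiomycete *Coprinopsis cinerea* across its
mycelium (MYC) to primordium (PRI) developmental transition: two small-RNA
libraries are cleaned, collapsed and mapped exactly to the genome; candidate
precursors are grown around every mapped read and accepted only if they fold
into a bona fide hairpin; accepted matures are clustered, classified and
named; and validated milRNAs are carried into target prediction, expression
concordance filtering, enrichment, homolog scanning and comparative-Ct
quantification.

Everything runs against a bundled synthetic-data generator with planted
ground truth, so each stage is testable end to end without downloads.

# The selection model

A mapped read becomes a milRNA candidate when some genomic window of
51–150 nt containing it satisfies, under the package's folding engine, all
five criteria (defaults in parentheses, all configurable via
`milrConfig()`):

1. hairpin minimum free energy at or below −20 kcal/mol (inclusive);
2. at least 18 base pairs in the structure, with the read lying entirely
   within one arm of the stem (unpaired interior bases are allowed, overlap
   with the terminal loop is not);
3. exactly one terminal loop, of at least 4 nt;
4. a dinucleotide-shuffle randomization p-value strictly below 0.01;
5. total read support of at least 4, summed over libraries.

Two readings in the criteria deserve a note. "At least 18 bp" is read as
base *pairs* in the stem, while the loop clause ("one loop with at least
4 bp") is read as 4 unpaired *nucleotides* — a loop cannot contain pairs,
and this matches standard pre-miRNA geometry. Read support uses the total
across both libraries because published catalogs retain candidates whose
per-library counts are individually below 4 (e.g. 3.5 + 3); fractional
counts arise from multi-mapper splitting, where a read mapping to k loci
contributes count/k to each locus.

Window enumeration steps the window length by 10 nt through [51, 150]
(both endpoints always included) and, for each length, places the read at
the 5' edge, centre, and 3' edge of the window in read orientation,
truncating at contig boundaries. The expensive randomization test runs
lazily: only windows already passing the structural criteria are tested,
best (lowest MFE) first, and testing stops at the first pass. Among
equal-MFE passing windows the shortest, then leftmost, precursor is kept.

# The folding engine

`foldMFE()` is a Zuker-style dynamic program over all pseudoknot-free
structures under a simplified nearest-neighbor model: Turner-style stacking
free energies for Watson–Crick and G·U wobble pairs, size-dependent
hairpin/bulge/internal-loop initiation penalties with Jacobson–Stockmayer
logarithmic extrapolation beyond the tabulated size 30, a linear
internal-loop asymmetry term (0.5 kcal/mol per unpaired-length difference,
capped at 3), and an affine multiloop term (offset 3.4, +0.4 per branch).
There are no dangles, coaxial stacks, or special tetraloops; the minimum
hairpin loop is 3 nt (a physical constraint — the acceptance criterion
later demands 4). The model reproduces MFE magnitudes on the same kcal/mol
scale as the −20 threshold while staying simple enough that an exhaustive
structure-enumeration oracle can verify the DP exactly, which the test
suite does for random sequences up to 18 nt.

Three numerical choices matter for reproducibility:

* all energies are evaluated in integer hundredths of kcal/mol, so ties are
  exact and results platform-independent;
* equal-energy structures are resolved by a fixed traceback preference
  (stack, then interior loop, then multiloop, then hairpin; leftmost
  first);
* a sequence with no negative-energy structure folds to all-dots with an
  MFE of exactly 0.

The shipped parameter table (`inst/extdata/energy_params.tsv`, schema in
`?readEnergyModel`) deviates from the published wobble values in four
entries: the G·U-containing stacks AU/UG, UA/UG, CG/UG and GC/GU are
weakened (to −1.00, −0.80, −1.90 and −2.20 kcal/mol) so that a
Watson–Crick pair always stacks at least as strongly as the wobble
alternative in the same context. This regularization gives the duplex
model a clean optimality property — the exact reverse complement is always
the best same-length binding partner, which the suite verifies
exhaustively at length 6 — at a negligible cost in realism for the
magnitude-scale purposes the model serves here.

`duplexEnergy()` computes the minimum intermolecular energy over
antiparallel duplexes (initiation +4.1, stacks, bulge/internal penalties,
no intramolecular pairs), with 0 as the no-pair convention.
`dinucleotideShuffle()` is the Altschul–Erickson Eulerian-walk shuffle,
preserving all dinucleotide counts exactly; `randfoldP()` uses the add-one
estimator p = (1 + #\{MFE(shuffle) ≤ MFE(seq)\})/(n + 1), so p can never be
0 and, with the default 999 shuffles, p < 0.01 is attainable (with 99 it
would not be, since min p = 0.01 exactly).

# Target prediction

Because fungal 3'-UTRs are rarely annotated, targets are sought in a
surrogate database: the 1000 bp immediately downstream of each gene's stop
codon on the coding strand (`buildUtrDb()`). Three scoring modes emulate
the spirit of the classic thermodynamic target predictors without
reproducing their exact scoring tables (which are not parameterized here);
a gene is a consensus target only if all three modes find a site:

* **DUPLEX** — sliding windows of mature length + 4 pass at duplex energy
  ≤ −15 kcal/mol; overlapping passing windows merge, keeping the best
  energy. This mode is deliberately permissive (it considers energy only),
  so it predicts the largest per-mode gene set.
* **ALIGN** — sites are anchored on perfect Watson–Crick complementarity of
  the seed (mature positions 2–7, no wobble) and scored by a weighted
  complementarity alignment (match +5, G·U +1, mismatch −3, gaps −8/−2;
  substitution columns opposite mature positions 2–8 doubled) against the
  reversed site window; passing requires score ≥ 80 and duplex energy
  ≤ −15.
* **ACCESS** — for each seed-anchored site, the opening cost
  ΔG_open = MFE(140-nt window, site forced unpaired) − MFE(window) ≥ 0 is
  added to the duplex energy; passing requires the sum ≤ −5 kcal/mol.

The expression-concordance filter then applies the stage-direction rule on
the microarray-style table: for a PRI-elevated milRNA, targets with
MYC/PRI fold change ≤ 0.5 are kept (inclusive); for a MYC-elevated one,
fold change > 0.5 (strict). The filter follows the explicit threshold rule
rather than a correlation measure, and expression values are assumed
linear-scale. Term enrichment (`enrichTerms()`) is a one-sided
hypergeometric upper tail against the background of all genes with at
least one term assignment, unadjusted for multiplicity, flagged at 0.05.
Homolog scanning (`homologScan()`) requires an identical seed (positions
2–7) and fewer than three mismatches over the remaining positions,
position 1 included in that budget, on either strand.

# The synthetic-data generator

`simulateDataset()` is first-class, tested code, not a fixture. Its
defaults define the study conditions used by the test-suite and the
acceptance script: a 2 × 50 kb genome of i.i.d. uniform nucleotides
carrying 20 planted hairpins, 6 shuffled decoy hairpin loci with read
support, 4 + 4 decoy rRNA/tRNA features, and 30 genes; 4000 background
reads per library with a 0.6 five-prime-U fraction (the strong 5'-U bias
characteristic of small-RNA populations) and 5% each of short and
low-quality contaminants; and a fifth of the genes carrying planted target
sites.

Design choices worth knowing:

* **Planted hairpins** are built as mature · loop · star (or the reverse),
  where the star arm is the reverse complement of the mature with two G·U
  wobbles introduced. The wobbles serve two purposes: realism (natural
  pre-miRNA stems are imperfect) and cleanliness of the ground truth —
  with a perfect stem the mature read would also map exactly to the
  opposite strand of its own star arm, duplicating every locus. Precursor
  lengths are drawn from the same length set the discovery stage
  enumerates, with the mature at the precursor end matching its arm, so at
  least one enumerated window coincides with the plant exactly. Every
  plant is rejection-sampled until it passes the structural criteria under
  the shipped energy model.
* **Decoy hairpins** are dinucleotide shuffles of planted precursors,
  re-shuffled until they fail the structural criteria at their own window,
  and given read support ≥ 4 — they exercise the fold-based rejection path
  specifically (read support alone would not reject them).
* **Background reads** are genuine genome substrings from both strands
  (so they map perfectly); the 5'-U bias is realized by sampling positions
  whose strand sequence starts with the desired base, keeping reads
  perfect matches. The first planted hairpin is strongly PRI-elevated
  (100 vs 1000 counts) and two hairpins are MYC-only, emulating
  stage-specific expression; remaining counts are uniform in 5–150.
* **Planted target sites** are exact reverse complements of the first
  mature, guaranteeing all three modes fire; planted genes alternate
  prescribed fold changes 0.25 (concordant with a PRI-elevated milRNA)
  and 2.0 (discordant — must be filtered out). Expression noise is
  multiplicative log-normal (sd 0.1 by default).
* **Contaminants** append a fixed known adapter (the standard small-RNA
  3' adapter sequence), giving `trimAdapter()` exact ground truth;
  quality is two-level (Phred 40 pass / Phred 10 fail) by design.

What the generator does *not* emulate — realistic sequencing error models,
graded quality scores, transcriptome-derived read structure, repeat
families, chained/overlapping precursors — bounds what green tests mean:
they demonstrate correctness of the pipeline's logic under its stated
assumptions, not performance on real libraries, where mapping ambiguity
and structured background are harsher.

# Preprocessing conventions

The per-read quality rule ("Phred score lower than 20") is implemented as
*mean* Phred < 20 discards the read — a single testable rule matching
common small-RNA practice. Adapter trimming is exact-match only (full
adapter anywhere, else a ≥ 8 nt suffix/prefix overlap), keeping simulator
ground truth crisp. Reads classified as rRNA/tRNA are *not* discarded
before prediction: rRNA-derived milRNAs are an expected outcome (the
published catalog contains a 28S rDNA-derived precursor), so ncRNA classes
are annotated, not filtered. Genomic coordinates are 1-based inclusive
everywhere; BED I/O converts at the boundary; sequences are stored as DNA
with T, and the folding layer treats T as U transparently.

# Problem sizes and runtime

The suite folds every enumerated window only for loci that pass the cheap
read-support gate first, which reduces the folding load by an order of
magnitude on the default study. The default-scale study
(2 × 50 kb, 20 hairpins, 999 shuffles, 30 genes) completes in a few
minutes on one CPU; the unit suite uses a reduced study (2 × 20 kb, 6
hairpins, 299 shuffles) for everything that does not specifically test the
default conditions. The exhaustive folding oracle is run for sequences up
to 18 nt, where enumeration is still cheap; beyond that the DP is the only
practical evaluator.

# Known limitations

* The energy model is deliberately minimal; absolute MFE values differ
  from full Turner-2004 implementations by a few percent, and the −20
  threshold should be interpreted on this model's scale.
* Identity clustering is greedy with count-ordered seeding, like the
  classic tools, and therefore order-dependent only through counts; exact
  ties are broken lexicographically for determinism.
* Gene-level (not site-level) intersection defines the three-mode
  consensus; site-level overlap is a stricter alternative not implemented.
* The published catalog bundled for consistency checks contains five rows
  whose printed loci are end-exclusive (span = length + 1); the
  consistency checker reports them rather than correcting them.

# A worked micro-example

```{r example}
cfg <- milrConfig()
hp <- with(list(), {set.seed(7); plantHairpin(cfg)})
fold <- foldMFE(hp$precursor)
fold
stemStatistics(fold, hp$matureStart, hp$matureEnd)
randfoldP(hp$precursor, nShuffles = 299, seed = 1)
```
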