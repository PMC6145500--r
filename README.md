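# milrscan

Discovery and downstream analysis of microRNA-like RNAs (milRNAs) from
fungal small-RNA sequencing, modelled on the workflow used for the model
mushroom *Coprinopsis cinerea* across its mycelium (MYC) to primordium
(PRI) developmental transition.

Fungal milRNAs carry the biogenesis hallmarks of canonical miRNAs — a
51–150 nt genomic precursor folding into a stem–loop from which a defined
18–30 nt mature species is excised — but lack cross-kingdom conservation,
so discovery rests entirely on structure and read evidence. `milrscan`
implements that analysis as a tested, reusable R package:

* **Preprocessing** — mean-Phred quality filter, exact adapter trimming,
  18–30 nt length filter, collapsing to unique tags with per-library
  counts, ncRNA classification against an annotation, and the library
  summary report (read-count ladder, length histogram, 5'-nucleotide
  frequencies).
* **Mapping** — exact-match alignment of unique reads to both genome
  strands via a k-mer index; all loci kept, multi-mapper counts split
  evenly (count/k per locus).
* **Discovery** — precursor windows of 51–150 nt grown around every mapped
  read and accepted only if, under the package's own nearest-neighbor MFE
  folding engine, they satisfy the five selection criteria:

  1. hairpin MFE ≤ −20 kcal/mol,
  2. ≥ 18 base pairs with the read inside one stem arm,
  3. exactly one terminal loop of ≥ 4 nt,
  4. dinucleotide-shuffle randomization p < 0.01 (Altschul–Erickson
     shuffle, add-one estimator, 999 shuffles),
  5. ≥ 4 supporting reads (summed over libraries).

  Accepted matures are clustered at 95% identity, classified
  (rRNA > tRNA > exon > intergenic), and named in the `cci-milR-N[letter][-arm]`
  style.
* **Targets** — 3'-UTR surrogates (1000 bp downstream of each stop codon)
  scanned by three thermodynamic modes (duplex energy, seed-anchored
  weighted alignment, seed-anchored accessibility with opening cost);
  genes hit by **all three** modes form the consensus, then an
  expression-concordance filter keeps MYC/PRI fold change ≤ 0.5 for a
  PRI-elevated milRNA (> 0.5 for a MYC-elevated one). Hypergeometric term
  enrichment, seed-exact homolog scanning (< 3 non-seed mismatches), and
  comparative-Ct (2^−ΔΔCt) utilities complete the downstream analysis.
* **Synthetic data** — a first-class generator (`simulateDataset()`)
  plants hairpins, decoys, contaminated read libraries, target sites and
  an expression table with known ground truth, so the whole pipeline is
  testable offline.

The folding engine, duplex model, shuffle and randomization test are
implemented in the package (R + Rcpp) and verified in the test-suite
against exhaustive enumeration oracles. See the methods vignette
(`vignettes/milrna-discovery.Rmd`) for the models, parameter meanings and
design decisions.

## Worked example

A reduced simulated study (2 × 20 kb genome, 6 planted hairpins, 3 shuffled
decoy loci, 500 background reads per library):

```r
library(milrscan)
spec <- simulationSpec(nContigs = 2, contigLen = 20000, nHairpins = 6,
                       nGenes = 10, readsPerLibrary = 500,
                       nDecoyHairpins = 3, rngSeed = 11)
cfg <- milrConfig(randfoldShuffles = 299, rngSeed = 11)
res <- runMilrPipeline(spec, cfg)
discoveryReport(res$discovery$milrnas)$table
```

```
         id           locus strand                     sequence length count_MYC count_PRI
 cci-milR-1   ctg01:307-334      + AGGCCGACGCCATTATCGCGCTTATGGT     28        41       118
 cci-milR-2 ctg01:1321-1347      +  GTGATCGAGTGGCGGACTCTCTTCCGC     27        81         0
 cci-milR-3 ctg01:6222-6246      -    AGCAATTAGCACACTGACCAGTCCT     25       141        36
 cci-milR-4 ctg01:6321-6347      +  GCCACGACCGAATTGGCGCTGGCGGCC     27      33.3     333.3
 cci-milR-5 ctg01:6864-6890      -  CATTCTGTGTTGTCATGGTCCGTGTGT     27        80       111
 cci-milR-6 ctg01:6990-7012      +      GGCAGCTACGTCGACTCTCATGG     23       101         0
```

Each row is one accepted milRNA: its mature locus (1-based inclusive),
strand, mature sequence, and per-library read counts. `cci-milR-2` and
`cci-milR-6` are MYC-only (planted stage-specific species, printed with a
zero count in PRI); `cci-milR-4` shows fractional
counts from multi-mapper splitting — its mature also matches the planted
target sites downstream of two genes, so its counts are divided across
loci. Recovery against the planted truth:

```r
recoveryStats(res$discovery$milrnas, res$dataset$truth)
#> $recovery        [1] 1      # all 6 planted matures recovered exactly
#> $false_positives [1] 0      # no background or decoy locus accepted
```

Target prediction for the PRI-elevated milRNA (`cci-milR-4`'s mature):
10 genes pass the permissive duplex mode, 4 pass all three modes, and the
expression filter keeps only the gene whose simulated fold change is
concordant with the milRNA's direction:

```r
res$targets$venn[c("DUPLEX", "ALIGN", "ACCESS", "DUPLEX&ALIGN&ACCESS")]
#> DUPLEX  ALIGN  ACCESS  DUPLEX&ALIGN&ACCESS
#>     10      4       4                    4
res$targets$filtered[, c("gene", "fold_change")]
#>     gene fold_change
#>  gene002   0.2723157
```

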