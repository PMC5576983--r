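# gbgcCodon

Synonymous codon usage (SCU) varies widely among human genes, and genes in
different functional categories use visibly different codons. `gbgcCodon`
implements the analysis chain that asks *why*: is SCU co-adapted to the tRNA
pool (translational selection), or is it a by-product of GC-biased gene
conversion (gBGC) — the meiotic repair bias that raises GC content wherever
recombination is frequent, with recombination itself suppressed inside genes
that are highly expressed during meiosis?

The package provides, as composable functions over Bioconductor containers:

- **Codon statistics** — codon counting with N- and stop-codon discipline,
  relative synonymous codon usage
  (RSCU: `RSCU_xy = C_xy / (A_x / n_x)` for amino acid *x*, codon *y*,
  degeneracy `n_x`), GC3, intronic GC (GCi) and flanking GC (GC-flank) from
  genome + gene models (`codonCounts()`, `rscu()`, `gc3()`,
  `geneFeatures()`).
- **Genetic-map arithmetic** — piecewise-linear cM interpolation, interval
  crossover rates in cM/Mb with coverage reporting, DSB-hotspot densities,
  expression-decile contrasts and strand-aware metagene profiles around the
  TSS / polyadenylation site (`intervalRate()`, `decileContrast()`,
  `metageneProfile()`).
- **The isoacceptor test** — the translational-selection test: GC3 computed
  separately for mono-isoacceptor amino acids (Phe, Asp, His, Cys — decoded
  by a single tRNA, hence unable to co-adapt to a varying tRNA pool) and
  multi-isoacceptor amino acids, correlated across gene sets
  (`buildPartition()`, `selectionTest()`).
- **Gene sets and expression** — GMT I/O, size/identifier filters, the
  keyword-based proliferation/differentiation classification with a
  negation guard, replicate averaging, sex-averaged meiotic expression,
  equal-count quantile bins (`filterSets()`, `assignCategories()`,
  `meioticSexAverage()`, `quantileBins()`).
- **Statistics** — PCA of gene-set RSCU, pairwise Pearson r², a sequential
  (Type-I) variance partition of GC3 with an independent-oracle-tested F
  machinery, per-sample GC3~expression ranking and group location tests
  (`rscuPCA()`, `sequentialAnova()`, `sampleCorrelationRanking()`,
  `groupTests()`).
- **A synthetic-genome generator** — isochore-like recombination/GC
  landscape, meiotic-expression-dependent intragenic crossover suppression,
  expression matrices with replicate structure, GO-like overlapping gene
  sets, and two switchable generative regimes: `"gbgc"` (codon choice
  driven only by local GC) and `"trna_coadapted"` (multi-isoacceptor codons
  follow per-program preferred-codon tables). Every run writes a truth
  table, so every stage of the analysis is testable against known ground
  truth (`syntheticConfig()`, `simulateGenome()`, `writeSyntheticData()`).

## Worked example

```r
library(gbgcCodon)

cfg <- syntheticConfig(seed = 1)     # 5 x 8 Mb genome, 2000 genes, gBGC regime
sim <- simulateGenome(cfg)
res <- runPipeline(sim)

res$anova
#> VariancePartition of gc3 (n = 1973 genes, 0 dropped)
#>  predictor pairwise_r2 model_r2            F            p
#>        gci       66.5%    66.5% 4291.3056822 0.000000e+00
#>   gc_flank       22.3%    67.3%   49.0799517 3.362309e-12
#>   log_rate       46.6%    69.5%  144.1756327 4.190385e-32
#>   log_expr        8.3%    69.5%    0.6094293 4.350967e-01
#>   category        0.7%    69.5%    0.3147512 7.300072e-01

res$isoacceptor$r_squared            # mono vs multi GC3 across 600 sets
#> [1] 0.9938305
res$contrast$fold_change             # crossover rate, bottom / top decile
#> [1] 3.172851
```

Read: intronic GC is by far the strongest predictor of GC3 (pairwise
r² = 0.67), the measured crossover rate and meiotic expression follow, and
the proliferation/differentiation category adds an order of magnitude less
than the continuous predictors — while mono-isoacceptor GC3 tracks
multi-isoacceptor GC3 almost perfectly across gene sets (R² = 0.99), which
a tRNA-driven model cannot produce. Rerunning with
`syntheticConfig(seed = 1, regime = "trna_coadapted")` drops that R² to
0.02: the test separates the two generative worlds cleanly.

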