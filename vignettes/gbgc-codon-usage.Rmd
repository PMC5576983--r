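---
title: "Synonymous codon usage under GC-biased gene conversion: models and methods"
author: "gbgcCodon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synonymous codon usage under GC-biased gene conversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbgcCodon)
```

## The scientific question

Synonymous codon usage (SCU) varies widely among human genes, and genes in
different functional categories (cellular proliferation versus
differentiation, for example) use visibly different codons. The classical
adaptive reading is translational selection: codon usage co-adapted to the
tRNA pool of the cells where a gene is expressed. The non-adaptive
alternative is GC-biased gene conversion (gBGC): meiotic recombination
repairs heteroduplex DNA with a bias toward G/C alleles, so the long-term
crossover rate of a locus drives its equilibrium GC content — at third codon
positions (GC3) just as in introns (GCi) and flanking DNA (GC-flank).
Because expression during meiosis suppresses crossovers inside the
transcription unit, genes highly expressed in meiotic cells accumulate less
gBGC and drift AT-rich, regardless of any translational constraint.

This package implements the full analysis chain that discriminates the two
models — RSCU/GC3 computation, genetic-map interval arithmetic, the
mono/multi-isoacceptor test, expression-stratified crossover contrasts,
metagene profiles and a sequential variance partition of GC3 — together
with a synthetic-genome generator whose two regimes (`"gbgc"` and
`"trna_coadapted"`) let every stage be validated against a known ground
truth.

## Core quantities

**RSCU.** For amino acid $x$ with $n_x$ synonymous codons and codon counts
$C_{xy}$ (total $A_x = \sum_y C_{xy}$),
$$\mathrm{RSCU}_{xy} = \frac{C_{xy}}{A_x / n_x},$$
the observed count normalised by its expectation under equal synonymous
usage. Met and Trp, encoded by a single codon, are excluded; the working
universe is therefore 59 codons over 18 degenerate amino acids. An amino
acid absent from a sequence yields an explicit `NA`, never 0/0. By default
GC3 is computed over the same 59-codon universe (a `universe = "sense61"`
switch is provided); stop codons are never counted, codons containing N are
skipped and tallied.

**Interval crossover rates.** A genetic map is a piecewise-linear cumulative
genetic position (cM) along each chromosome. The rate of an interval is
$(\mathrm{cM}(e) - \mathrm{cM}(s)) / \text{length in Mb}$, with positions
outside the marker span clamped to the terminal values; a
`covered_fraction` is reported so poorly covered genes can be filtered
rather than silently mis-measured. This makes `intervalRate()` exactly
additive over partitions of an interval, a property the tests exploit.

**The isoacceptor test.** Among the 18 degenerate amino acids, four — Phe,
Asp, His, Cys — are decoded by a single tRNA isoacceptor in the human
repertoire, so their codon usage cannot co-adapt to a tRNA pool that varies
between cell types. If GC3 computed over mono-isoacceptor codons tracks GC3
over multi-isoacceptor codons across gene sets (high $R^2$ in
`selectionTest()`), one process that ignores the tRNA pool drives both —
the gBGC signature. The bundled repertoire table carries the human
anticodon presence/absence structure (48 isoacceptors, 506 genes); its
per-anticodon gene counts are representative values, and the frozen
partition is also available directly as `humanIsoacceptorPartition()`.

**Sequential variance partition.** `sequentialAnova()` fits
ordinary-least-squares models in a fixed predictor order (default: GCi,
GC-flank, log crossover rate, log meiotic expression, functional category)
and reports per step the pairwise $r^2$ with GC3, the cumulative model
$R^2$, and a Type-I $F$ statistic testing the step's increment against the
full model's residual mean square. The sequential choice follows how such
tables are conventionally built (variables added in order); the $F$
denominator uses the full-model residual because that is the standard
sequential-ANOVA convention (`anova.lm`); an independent normal-equations
solver reproduces every step in the tests. An all-pairwise-interactions
variant is available (`interactions = TRUE`).

## The synthetic generator

`simulateGenome(syntheticConfig(...))` produces a genome FASTA-equivalent,
gene models, genetic maps before and after intragenic suppression, DSB
hotspots, an expression matrix with replicate structure, GO-like gene sets
and a per-gene truth table. The causal chain it encodes:

1. **Landscape.** Per chromosome, Gaussian-smoothed white noise
   (correlation length `isochore_scale`, log-sd `landscape_log_sd`) is
   exponentiated into a positive rate field and normalised so the
   genome-wide mean is exactly `base_rate` (default 1.2 cM/Mb, a human-like
   genome average). The smoothing kernel's marginal variance is normalised
   analytically (`sum(w^2)`), not empirically — the empirical per-chromosome
   sd of a strongly autocorrelated field badly underestimates the marginal
   sd and would inflate the spread. If `isochore_scale` reaches the
   chromosome length, the field degenerates cleanly to a constant.
2. **Suppression.** Genes (non-overlapping, with spacing) receive meiotic
   expression from a log-normal (`expression_lognormal_params`, default
   meanlog 1.5, sdlog 1.5 FPKM). Inside each transcription unit the rate is
   multiplied by $f(e) = 1 - s\,\mathrm{rank}(e)/n$ with
   $s$ = `suppression_strength` (default 0.75): rank-based because the
   empirical observation is a monotone decile effect, not a functional
   form. Flanks are untouched; the truth table records $f$ per gene.
3. **Sequences.** A gene's equilibrium GC is
   $\mathrm{logit}^{-1}\!\big(\beta\,(\log_2 r/r_0 + \varepsilon)\big)$
   where $r$ is its long-term suppressed rate, $\beta$ = `gbgc_slope`,
   $r_0$ centres the distribution at 0.5 (the median suppressed gene rate
   implied by the config), and $\varepsilon$ (sd `gc_longterm_sd`) is the
   long-term gBGC intensity drift around what the present-day map implies.
   The "long-term" rate uses an expression state drifted by
   `expression_drift` from the present-day one — present-day FPKM is only a
   proxy of the expression history that gBGC integrated. Third codon
   positions, introns and transcribed UTR are sampled at that GC (each
   compartment with independent noise `noise_sd_gc`); flanking and
   intergenic sequence uses the regional, unsuppressed landscape rate, so
   GC-flank carries the isochore signal but not the meiotic-expression
   signal — suppression acts on the transcription unit only. Under
   `regime = "gbgc"` codon choice within an amino acid depends only on the
   third-base GC class; under `regime = "trna_coadapted"`,
   multi-isoacceptor codons follow per-regulon preferred-codon tables
   (probability `pref_strength`) while mono-isoacceptor codons stay
   GC-driven — the generative embodiment of translational selection that
   `selectionTest()` must detect.
4. **Expression and sets.** Female-meiotic (PGC-like), male-meiotic
   (spermatocyte-like), male-post-meiotic and somatic sample groups with
   log-normal replicates; somatic means are independent of the meiotic
   program, so only meiotic samples predict GC3. Latent gene categories tie
   proliferation-like genes to high meiotic expression; keyword-named sets
   sample from their category, neutral sets by a random expression tilt
   (`expression_bias_of_sets`; 0 disables all tilts).

Every stage seeds its own stream from `seed`, so identical configs are
byte-identical and skipping the genome assembly (`what = "cds"` or
`"maps"`) changes nothing else.

What the generator does **not** emulate: human chromosome counts and sizes,
hotspot fine structure and PRDM9 motifs, realistic FPKM distributions or
cross-protocol expression batch structure, GO graph topology (sets are flat
and overlapping, as the downstream analysis treats them), and mutation-rate
heterogeneity. Passing tests therefore demonstrate that the pipeline's
arithmetic and inference are correct and that the causal chain is
recoverable at realistic signal strengths — not that the pipeline was
validated on real genomes.

## Worked run

```{r, eval = FALSE}
cfg <- syntheticConfig(seed = 1)
sim <- simulateGenome(cfg)
res <- runPipeline(sim)

partitionTable(res$anova)      # the variance-partition table
res$isoacceptor$r_squared      # mono vs multi GC3 across 600 sets
res$contrast$fold_change       # crossover rate, bottom/top expression decile
profileTable(res$metagene)     # stratified TSS metagene profile
```

On the default conditions this prints a partition in which intronic GC is
by far the best predictor of GC3, crossover rate and meiotic expression
follow, and the functional category adds an order of magnitude less than
the continuous predictors — with a bottom/top-decile crossover fold change
close to the imposed suppression ratio and a mono/multi isoacceptor $R^2$
near 1 under `"gbgc"` but near 0 under `"trna_coadapted"`. The
`scripts/acceptance.R` script recomputes exactly these quantities from
scratch.

## Numerical and design choices

- **Coordinates** are 0-based half-open in all tables; IRanges-backed slots
  are 1-based closed internally, converted at the interface.
- **Canonical transcript** = longest total CDS, ties broken by
  lexicographic transcript id; mitochondrial contigs are dropped; a CDS not
  divisible by 3 excludes the gene with a logged message.
- **Flanks** default to 10 kb of contiguous non-genic sequence on each side
  of the transcription unit, truncated at the nearest annotated gene and
  the chromosome end; the width is a parameter because published analyses
  rarely state it.
- **Intragenic** means TSS to polyadenylation site (the transcription
  unit), the span over which expression-linked crossover suppression is
  observed; callers can pass CDS intervals instead.
- **Confidence intervals** are mean ± 1.96·SEM (the normal approximation),
  matching how such figure legends describe them.
- **Quantile bins** are equal-count by rank with a stable tie-break on gene
  id, so "bins of equal sample size" are deterministic under FPKM ties; the
  realised cut points are recorded.
- **Log expression** uses log10(FPKM + 1); the pseudocount is a flag.
- **Male meiotic expression** defaults to the meiotic-stage group alone
  (spermatocyte-like), with pooling of post-meiotic stages available —
  descriptions of such averages are often ambiguous between the two.
- **Undefined values** (intronless GCi, genes missing from the expression
  matrix) are dropped with counts logged, except in PCA, where undefined
  RSCU cells are imputed by the column mean so one missing amino acid does
  not eject a set.
- **PCA** is centred and unscaled by default (RSCU is already
  degeneracy-normalised); PC1's sign is fixed to correlate positively with
  set GC3 so the first axis reads as a GC gradient.
- **Keyword categories** use case-insensitive substring matching with a
  negation guard, so "negative regulation of proliferation" does not count
  as proliferation while the explicit keyword "negative regulation of cell
  cycle" still does; genes matching both categories are discarded from
  category contrasts.
- **Hotspot membership** is by midpoint, avoiding double counting at
  window edges.

## Problem sizes

The shipped tests run the generator at 5 × 8 Mb chromosomes with 2,000
genes for recovery properties (10 seeds), 600 gene sets for the
isoacceptor discrimination (10 seeds per regime), and a 2 × 2 Mb, 200-gene
genome for exact counting oracles; these sizes give comfortable statistical
power for every property while keeping a full run in minutes on one core.

## Known limitations

- The linear-in-rank suppression factor is a stand-in: no quantitative form
  for the expression–recombination relationship is established, only
  monotone decile effects.
- The rate→GC logistic, its log2 scale, and the two long-term noise
  channels are generator design choices that reproduce the observed
  predictor structure (intronic GC strongest, then rate, then expression);
  they are not mechanistic estimates of gBGC fixation dynamics.
- `selectionTest()` trusts the repertoire table's amino-acid column; wobble
  decoding is deliberately not modelled, since only the isoacceptor count
  per amino acid matters for the partition.
- Set-level correlations treat overlapping gene sets as independent points;
  as with the real GO, they are not, which is why the gene-level variance
  partition is the headline analysis.
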