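smallCfg <- function(...) {
  syntheticConfig(n_chromosomes = 2L, chrom_length = 2e6, n_genes = 150L,
                  n_gene_sets = 50L, set_size_range = c(40L, 60L),
                  seed = 9L, ...)
}

test_that("identical config and seed give byte-identical output", {
  cfg <- smallCfg()
  a <- simulateGenome(cfg, what = "cds")
  b <- simulateGenome(cfg, what = "cds")
  expect_identical(truthTable(a), truthTable(b))
  expect_identical(as.character(a@cds), as.character(b@cds))
  expect_identical(mapMarkers(a@map), mapMarkers(b@map))
  expect_identical(a@expression, b@expression)
  expect_identical(unclass(a@sets), unclass(b@sets))
  expect_identical(a@hotspots, b@hotspots)
})

test_that("genome-wide mean crossover rate is recovered from the emitted map", {
  cfg <- syntheticConfig(n_chromosomes = 10L, chrom_length = 1e7,
                         base_rate = 1.2, n_genes = 10L, seed = 5L)
  map <- generateRecombinationLandscape(cfg)
  m <- mapMarkers(map)
  totalCM <- sum(tapply(m$cum_cM, m$chrom, max))
  meanRate <- totalCM / (10 * 10)   # total cM / total Mb
  expect_gt(meanRate, 1.14)
  expect_lt(meanRate, 1.26)
})

test_that("smoothing scale at or above the chromosome length degenerates to a flat field", {
  cfg <- syntheticConfig(n_chromosomes = 3L, chrom_length = 2e6,
                         isochore_scale = 2e6, n_genes = 10L, seed = 2L)
  map <- generateRecombinationLandscape(cfg)
  r <- intervalRate(map, rep(c("chr1", "chr2", "chr3"), each = 2),
                    rep(c(0, 1e6), 3), rep(c(1e6, 2e6), 3))$rate
  expect_equal(r, rep(cfg$base_rate, 6), tolerance = 1e-9)
})

test_that("suppression modifies intragenic rates by exactly the recorded factor", {
  cfg <- smallCfg()
  base <- generateRecombinationLandscape(cfg)
  pl <- placeGenesAndSuppress(cfg, base)
  tr <- pl$truth
  got <- intervalRate(pl$map, tr$chrom, tr$start, tr$end)$rate
  want <- intervalRate(base, tr$chrom, tr$start, tr$end)$rate *
    tr$suppression_factor
  expect_equal(got, want, tolerance = 1e-9)
  # flanks untouched: rates just outside genes identical on both maps
  fs <- tr$start - 1500; fe <- tr$start - 1  # inside the 2 kb spacing buffer
  expect_equal(intervalRate(pl$map, tr$chrom, fs, fe)$rate,
               intervalRate(base, tr$chrom, fs, fe)$rate, tolerance = 1e-9)
})

test_that("suppression endpoints follow the rank formula", {
  cfg <- smallCfg(suppression_strength = 0.8)
  pl <- placeGenesAndSuppress(cfg, generateRecombinationLandscape(cfg))
  tr <- pl$truth
  n <- nrow(tr)
  top <- which.max(tr$meiotic_expression)
  expect_equal(tr$suppression_factor[top], 1 - 0.8)
  expect_true(all(tr$suppression_factor >= 1 - 0.8 - 1e-12 &
                    tr$suppression_factor <= 1))
  expect_equal(sort(tr$suppression_factor), 1 - 0.8 * (n:1) / n)

  cfg0 <- smallCfg(suppression_strength = 0)
  base0 <- generateRecombinationLandscape(cfg0)
  pl0 <- placeGenesAndSuppress(cfg0, base0)
  m0 <- mapMarkers(pl0$map)
  expect_equal(interpolateCM(base0, "chr1", m0$pos[m0$chrom == "chr1"]),
               m0$cum_cM[m0$chrom == "chr1"], tolerance = 1e-9)
})

test_that("an overfull genome fails explicitly", {
  cfg <- syntheticConfig(n_chromosomes = 1L, chrom_length = 1e6,
                         n_genes = 200L, seed = 1L)
  expect_error(placeGenesAndSuppress(cfg, generateRecombinationLandscape(cfg)),
               "genome too small")
})

test_that("decoupled limit: zero slope and zero noise give uniform GC at 0.5", {
  cfg <- smallCfg(gbgc_slope = 0, noise_sd_gc = 0)
  sim <- simulateGenome(cfg, what = "cds")
  tr <- truthTable(sim)
  expect_equal(tr$eq_gc, rep(0.5, nrow(tr)))
  expect_equal(tr$gc_cds_target, rep(0.5, nrow(tr)))
  cnt <- codonCountsMatrix(sim@cds)
  cod <- synonymousCodons()
  gc3v <- rowSums(cnt[, cod[gbgcCodon:::.isGCEnding(cod)]]) / rowSums(cnt[, cod])
  # only binomial sampling spread remains around 0.5
  expect_lt(abs(mean(gc3v) - 0.5), 0.01)
  expect_lt(sd(gc3v), 3 * sqrt(0.25 / median(rowSums(cnt[, cod]))))
})

test_that("gBGC regime couples GC3 to intronic GC at zero compartment noise", {
  cfg <- syntheticConfig(noise_sd_gc = 0, seed = 6L)
  sim <- simulateGenome(cfg)
  f <- geneFeatures(geneModels(sim), sim@genome, cds = sim@cds)
  ok <- complete.cases(f[, c("gc3", "gci")])
  expect_gt(cor(f$gc3[ok], f$gci[ok])^2, 0.9)
})

test_that("tRNA-coadapted regime decouples mono-isoacceptor GC3 from set preference", {
  cfg <- smallCfg(regime = "trna_coadapted")
  sim <- simulateGenome(cfg, what = "cds")
  tabs <- usageTables(sim@cds)
  st <- setUsageTables(sim@sets, tabs)
  iso <- selectionTest(st)
  expect_lt(iso$r_squared, 0.3)
})

test_that("expression stage honours replicate structure and unbiased sets", {
  cfg <- smallCfg(replicate_sigma = 0, expression_bias_of_sets = 0)
  sim <- simulateGenome(cfg, what = "maps")
  expr <- sim@expression
  info <- sim@sampleInfo
  for (g in unique(info$group)) {
    cols <- info$sample[info$group == g]
    expect_equal(expr[, cols[1]], expr[, cols[2]])  # sigma = 0: reps identical
  }
  avg <- averageReplicates(expr, info)
  expect_equal(avg[, "spermatocyte"], expr[, "spermatocyte_rep1"])
  # unbiased sets: set mean meiotic expression tracks the population mean
  tr <- truthTable(sim)
  pop <- mean(log(tr$meiotic_expression))
  setMeans <- vapply(sim@sets, function(ids) {
    mean(log(tr$meiotic_expression[match(ids, tr$gene_id)]))
  }, numeric(1))
  expect_lt(abs(mean(setMeans) - pop), 3 * sd(log(tr$meiotic_expression)) /
              sqrt(mean(lengths(sim@sets))))
})

test_that("emitted GMT respects the configured set sizes", {
  sim <- tinySim()
  dir <- withr::local_tempdir()
  writeSyntheticData(sim, dir)
  sets <- readGMT(file.path(dir, "sets.gmt"))
  expect_equal(length(sets), sim@config$n_gene_sets)
  expect_true(all(lengths(sets) >= sim@config$set_size_range[1]))
  expect_true(all(lengths(sets) <= sim@config$set_size_range[2]))
  expect_true(all(unlist(sets) %in% truthTable(sim)$gene_id))
  # map TSV round-trips
  m2 <- readGeneticMap(file.path(dir, "map.tsv"))
  expect_equal(mapMarkers(m2)$cum_cM, mapMarkers(sim@map)$cum_cM,
               tolerance = 1e-9)
  # expression TSV + sidecar round-trip
  ex <- readExpressionMatrix(file.path(dir, "expression.tsv"),
                             file.path(dir, "samples.tsv"))
  expect_equal(ex$matrix, sim@expression, tolerance = 1e-6)
  expect_equal(ex$sampleInfo$group, sim@sampleInfo$group)
})

test_that("end-to-end recovery: decile contrast matches the imposed suppression", {
  cfg <- syntheticConfig(seed = 31L)
  sim <- simulateGenome(cfg, what = "maps")
  tr <- truthTable(sim)
  gt <- geneTable(geneModels(sim))
  rates <- intervalRate(sim@map, gt$chrom, gt$start, gt$end)$rate
  avg <- averageReplicates(sim@expression, sim@sampleInfo)
  meio <- meioticSexAverage(avg, "pgc_female_17w", "spermatocyte")
  e <- meio$sex_averaged[match(gt$gene_id, meio$gene_id)]
  dc <- decileContrast(rates, e, k = 10, ids = gt$gene_id)
  rk <- rank(e, ties.method = "first")
  n <- length(e)
  imposed <- mean(tr$suppression_factor[rk <= n / 10]) /
    mean(tr$suppression_factor[rk > 9 * n / 10])
  expect_lt(abs(dc$fold_change / imposed - 1), 0.15)
})
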