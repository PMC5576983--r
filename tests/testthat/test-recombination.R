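test_that("cumulative cM interpolation is linear and clamps outside the span", {
  map <- geneticMap(data.frame(chrom = "chr1", pos = c(0, 1e6),
                               cum_cM = c(0, 1)))
  expect_equal(interpolateCM(map, "chr1", 5e5), 0.5)
  expect_equal(interpolateCM(map, "chr1", 1e6), 1)
  expect_equal(interpolateCM(map, "chr1", -1e4), 0)       # clamped
  expect_equal(interpolateCM(map, "chr1", 2e6), 1)        # clamped
  expect_error(interpolateCM(map, "chr9", 1), "chr9")
})

test_that("interval rates are length-weighted and report coverage", {
  expect_equal(intervalRate(uniformMap(1), "chr1", 0, 123456)$rate, 1)
  # two segments at 0.5 and 2.0 cM/Mb, interval half in each -> 1.25
  m <- geneticMap(data.frame(chrom = "chr1", pos = c(0, 1e6, 2e6),
                             cum_cM = c(0, 0.5, 2.5)))
  expect_equal(intervalRate(m, "chr1", 5e5, 15e5)$rate, 1.25)
  expect_error(intervalRate(m, "chr1", 5, 5), "length")
  # interval straddling the span edge: clamped cM, covered_fraction < 1
  ir <- intervalRate(m, "chr1", 15e5, 25e5)
  expect_equal(ir$covered_fraction, 0.5)
  expect_equal(ir$rate, 2.0 * 0.5)
})

test_that("interval rates match numeric integration on random piecewise maps", {
  set.seed(201)
  for (rep in 1:5) {
    map <- randomPiecewiseMap(nSeg = 15)
    start <- runif(100, 0, 1e7 - 1e4)
    end <- start + runif(100, 1e3, 5e5)
    got <- intervalRate(map, "chr1", start, end)$rate
    want <- vapply(seq_along(start), function(i) {
      oracleIntervalRate(map, "chr1", start[i], end[i])
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("interval rate is additive over partitions of an interval", {
  set.seed(202)
  map <- randomPiecewiseMap(nSeg = 10)
  s <- 1.23e6; e <- 4.56e6
  cuts <- sort(c(s, runif(5, s, e), e))
  whole <- intervalRate(map, "chr1", s, e)$rate
  parts <- intervalRate(map, "chr1", cuts[-length(cuts)], cuts[-1])$rate
  w <- diff(cuts)
  expect_equal(whole, sum(parts * w) / sum(w))
})

test_that("hotspot density counts midpoints per kb", {
  hs <- data.frame(chrom = "chr1",
                   start = c(1000, 2000, 5000, 90000),
                   end = c(2000, 3000, 6000, 91000))
  expect_equal(hotspotDensity(hs, "chr1", 0, 6000), 3 / 6)
  expect_equal(hotspotDensity(hs, "chr2", 0, 6000), 0)
  set.seed(203)
  hs2 <- data.frame(chrom = "chr1", start = runif(200, 0, 1e6))
  hs2$end <- hs2$start + 1500
  s <- 2e5; e <- 7.5e5
  mids <- (hs2$start + hs2$end) / 2
  expect_equal(hotspotDensity(hs2, "chr1", s, e),
               sum(mids >= s & mids < e) / ((e - s) / 1000))
})

test_that("decile contrast recovers a null, a closed form, and is monotone-invariant", {
  set.seed(204)
  v <- rlnorm(400); strat <- rnorm(400)
  dc <- decileContrast(v, strat, k = 10)
  expect_true(abs(log(dc$fold_change)) < log(2))  # null: fold near 1
  expect_equal(nrow(dc$bins), 10)
  expect_true(all(dc$bins$n == 40))

  # deterministic closed form on ranks, n = 100, k = 10
  strat2 <- seq_len(100)
  v2 <- 1 / (1 + strat2 / 100)
  dc2 <- decileContrast(v2, strat2, k = 10)
  expect_equal(dc2$fold_change,
               mean(1 / (1 + (1:10) / 100)) / mean(1 / (1 + (91:100) / 100)))

  dc3 <- decileContrast(v2, exp(strat2 / 10), k = 10)  # monotone transform
  expect_equal(dc3$fold_change, dc2$fold_change)
  expect_error(decileContrast(v2, strat2, k = 1), "k must be")
  expect_error(decileContrast(v2[1:15], strat2[1:15], k = 10), "at least 2k")
})

test_that("metagene profiles are flat on a uniform map and match hand windows", {
  sim <- tinySim()
  models <- geneModels(sim)
  L <- sim@config$chrom_length
  flat <- geneticMap(data.frame(chrom = rep(c("chr1", "chr2"), each = 2),
                                pos = c(0, L, 0, L),
                                cum_cM = c(0, 2 * L / 1e6, 0, 2 * L / 1e6)))
  prof <- metageneProfile(flat, models, anchor = "TSS", window = 1000,
                          upstream = 3000, downstream = 5000)
  pt <- profileTable(prof)
  expect_true(all(abs(pt$mean_rate - 2) < 1e-9))
  expect_equal(sort(unique(pt$offset_bp)), seq(-3000, 4000, by = 1000))

  # hand-built three-segment map around a single + strand gene
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 16000),
                              strand = "+")
  names(g) <- "g1"
  cds <- IRanges::IRangesList(g1 = IRanges::IRanges(10001, 10900))
  one <- gbgcCodon:::.newGeneModelSet(
    g, methods::as(cds, "CompressedIRangesList"),
    methods::as(IRanges::IRangesList(g1 = IRanges::IRanges()),
                "CompressedIRangesList"),
    methods::as(IRanges::IRangesList(g1 = IRanges::IRanges()),
                "CompressedIRangesList"), 0)
  hand <- geneticMap(data.frame(chrom = "chr1",
                                pos = c(0, 10000, 12000, 50000),
                                cum_cM = c(0, 0.01, 0.01 + 2e-3 * 2,
                                           0.01 + 4e-3 + 0.5 * 38e-3)))
  pr <- metageneProfile(hand, one, anchor = "TSS", window = 1000,
                        upstream = 1000, downstream = 3000)
  gotRates <- profileTable(pr)$mean_rate
  # windows: [-1000,0) rate 1.0; [0,1000) 2.0; [1000,2000) 2.0; [2000,3000) 0.5
  expect_equal(gotRates, c(1, 2, 2, 0.5), tolerance = 1e-9)
})

test_that("metagene profiles are orientation invariant", {
  # one gene on + strand and its mirror image on - strand over the mirrored
  # map must give identical profiles
  L <- 50000
  mkModels <- function(start, end, strand) {
    g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start, end),
                                strand = strand,
                                seqlengths = c(chr1 = L))
    names(g) <- "g1"
    empt <- methods::as(IRanges::IRangesList(g1 = IRanges::IRanges()),
                        "CompressedIRangesList")
    cds <- methods::as(IRanges::IRangesList(
      g1 = IRanges::IRanges(start, start + 899)), "CompressedIRangesList")
    gbgcCodon:::.newGeneModelSet(g, cds, empt, empt, 0)
  }
  set.seed(205)
  pos <- sort(c(0, sample(1000:49000, 8), L))
  rates <- rlnorm(length(pos) - 1)
  fwd <- geneticMap(data.frame(chrom = "chr1", pos = pos,
                               cum_cM = c(0, cumsum(rates * diff(pos) / 1e6))))
  # mirrored map: position x -> L - x, segment rates reversed
  posR <- L - rev(pos)
  ratesR <- rev(rates)
  mirMap <- geneticMap(data.frame(chrom = "chr1", pos = posR,
                                  cum_cM = c(0, cumsum(ratesR * diff(posR) / 1e6))))
  mPlus <- mkModels(10001, 16000, "+")
  mMinus <- mkModels(L - 16000 + 1, L - 10001 + 1, "-")
  pPlus <- metageneProfile(fwd, mPlus, anchor = "TSS", window = 1000,
                           upstream = 2000, downstream = 4000)
  pMinus <- metageneProfile(mirMap, mMinus, anchor = "TSS", window = 1000,
                            upstream = 2000, downstream = 4000)
  expect_equal(profileTable(pPlus)$mean_rate, profileTable(pMinus)$mean_rate,
               tolerance = 1e-9)
})
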