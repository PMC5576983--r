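test_that("pairwise r-squared matches the textbook formula and handles edge cases", {
  x <- c(1, 2, 4, 5, 7)
  y <- c(2, 1, 5, 4, 9)
  pr <- pairwiseR2(x, y)
  # hand computation of Pearson r
  rHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pr$r_squared, rHand^2)
  expect_equal(pr$sign, sign(rHand))
  expect_equal(pr$n, 5L)

  expect_equal(pairwiseR2(x, 2 * x + 1)$r_squared, 1)
  set.seed(501)
  prNull <- pairwiseR2(rnorm(1e4), rnorm(1e4))
  expect_lt(prNull$r_squared, 0.01)

  pr2 <- pairwiseR2(c(x, NA), c(y, 3))
  expect_equal(pr2$n_dropped, 1L)
  expect_equal(pr2$r_squared, pr$r_squared)
  expect_true(is.na(pairwiseR2(rep(1, 5), y)$r_squared))
  expect_error(pairwiseR2(1:2, 2:3), "at least 3")
})

# RSCU rows along a GC3 gradient: for every degenerate amino acid the
# GC-ending codons share RSCU 2g * n_x/..., i.e. each codon's RSCU is its
# class probability divided by the uniform expectation
gradientRSCU <- function(gs, noise = 0.02) {
  aa <- codonAminoAcids()
  m <- t(vapply(gs, function(g) {
    v <- numeric(length(synonymousCodons()))
    names(v) <- synonymousCodons()
    for (x in degenerateAminoAcids()) {
      cods <- senseCodons()[aa == x]
      gcEnd <- substr(cods, 3, 3) %in% c("G", "C")
      p <- ifelse(gcEnd, g / sum(gcEnd), (1 - g) / sum(!gcEnd))
      v[cods] <- p * length(cods) + rnorm(length(cods), 0, noise)
    }
    v
  }, numeric(length(synonymousCodons()))))
  rownames(m) <- paste0("set", seq_along(gs))
  m
}

test_that("PCA of a pure GC3 gradient loads it on PC1, oriented positively", {
  set.seed(502)
  gs <- seq(0.25, 0.8, length.out = 40)
  m <- gradientRSCU(gs)
  pc <- rscuPCA(m, gc3 = gs)
  expect_gt(cor(pc@coordinates[, 1], gs), 0.95)
  expect_true(all(diff(pc@varianceShare) < 1e-9))
  # duplicated set gets identical coordinates
  m2 <- rbind(m, m[3, , drop = FALSE])
  pc2 <- rscuPCA(m2, gc3 = c(gs, gs[3]))
  expect_equal(pc2@coordinates[41, ], pc2@coordinates[3, ])
})

test_that("isotropic RSCU has no dominant axis and degenerate input errors", {
  set.seed(503)
  for (i in 1:5) {
    m <- matrix(rnorm(40 * 59, 1, 0.1), 40, 59,
                dimnames = list(NULL, synonymousCodons()))
    pc <- rscuPCA(m)
    expect_lt(pc@varianceShare[1], 2 * pc@varianceShare[2])
  }
  flat <- matrix(1, 5, 59, dimnames = list(NULL, synonymousCodons()))
  expect_error(rscuPCA(flat), "distinct")
})

test_that("undefined RSCU cells are imputed by the column mean", {
  set.seed(504)
  m <- gradientRSCU(seq(0.3, 0.7, length.out = 10))
  m[3, "CAA"] <- NA
  pc <- rscuPCA(m)
  expect_equal(pc@nImputed, 1L)
  expect_equal(nrow(pc@coordinates), 10L)
})


test_that("sequential ANOVA matches an independent nested-OLS solver", {
  set.seed(505)
  for (rep in 1:20) {
    n <- 500
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                    cat = sample(c("other", "p", "q"), n, replace = TRUE))
    d$y <- 0.8 * d$x1 - 0.5 * d$x2 + 0.2 * (d$cat == "p") + rnorm(n)
    vp <- sequentialAnova(d, "y", c("x1", "x2", "x3", "cat"))
    o <- oracleSequential(d, "y", c("x1", "x2", "x3", "cat"))
    tab <- partitionTable(vp)
    expect_equal(tab$model_r2, o$model_r2, tolerance = 1e-8)
    expect_equal(tab$F, o$F, tolerance = 1e-8)
    # sequential SS + residual SS = total SS
    expect_equal(sum(o$seqSS) + o$rss, o$tot, tolerance = 1e-8 * o$tot)
    expect_equal(vp@totalSS, o$tot, tolerance = 1e-8 * o$tot)
  }
})

test_that("sequential ANOVA base cases and degeneracies", {
  set.seed(506)
  d <- data.frame(x = rnorm(50))
  d$y <- 2 * d$x + rnorm(50)
  vp <- sequentialAnova(d, "y", "x")
  tab <- partitionTable(vp)
  expect_equal(tab$model_r2, tab$pairwise_r2)        # single predictor

  d2 <- data.frame(a = rnorm(30), b = rnorm(30))
  d2$y <- 1 + 2 * d2$a - 3 * d2$b                    # exact linear, no noise
  vp2 <- suppressWarnings(sequentialAnova(d2, "y", c("a", "b")))  # perfect fit
  expect_equal(partitionTable(vp2)$model_r2[2], 1)
  expect_true(all(is.finite(partitionTable(vp2)$F)))
  expect_true(all(partitionTable(vp2)$F > 0))

  d3 <- data.frame(a = rnorm(30)); d3$b <- d3$a; d3$y <- d3$a + rnorm(30)
  expect_error(sequentialAnova(d3, "y", c("a", "b")), "collinear")

  # complete-case handling is logged
  d4 <- data.frame(a = c(rnorm(29), NA)); d4$y <- rnorm(30)
  vp4 <- sequentialAnova(d4, "y", "a")
  expect_equal(vp4@nDropped, 1L)
  expect_equal(vp4@nUsed, 29L)

  # interaction variant explains at least as much
  set.seed(507)
  d5 <- data.frame(a = rnorm(200), b = rnorm(200))
  d5$y <- d5$a * d5$b + d5$a + rnorm(200)
  r2main <- max(partitionTable(sequentialAnova(d5, "y", c("a", "b")))$model_r2)
  r2int <- max(partitionTable(
    sequentialAnova(d5, "y", c("a", "b"), interactions = TRUE))$model_r2)
  expect_gt(r2int, r2main)
})

test_that("sequential ANOVA is invariant to gene order", {
  set.seed(508)
  d <- data.frame(x1 = rnorm(100), x2 = rnorm(100))
  d$y <- d$x1 + rnorm(100)
  vp <- sequentialAnova(d, "y", c("x1", "x2"))
  perm <- sample(100)
  vpP <- sequentialAnova(d[perm, ], "y", c("x1", "x2"))
  expect_equal(partitionTable(vpP), partitionTable(vp))
})

test_that("sample ranking sorts by r-squared and flags informative samples", {
  set.seed(509)
  n <- 300
  driver <- rnorm(n)
  gc3v <- stats::setNames(0.5 - 0.1 * driver + rnorm(n, 0, 0.03),
                          paste0("g", 1:n))
  expr <- cbind(meiotic = exp(driver + rnorm(n, 0, 0.2)),
                soma1 = rlnorm(n), soma2 = rlnorm(n))
  expr <- cbind(expr, meiotic_dup = expr[, "meiotic"])
  rownames(expr) <- names(gc3v)
  rk <- sampleCorrelationRanking(gc3v, expr)
  expect_equal(rk$r_squared, sort(rk$r_squared))              # ascending
  expect_setequal(tail(rk$sample, 2), c("meiotic", "meiotic_dup"))
  expect_equal(rk$r_squared[rk$sample == "meiotic"],
               rk$r_squared[rk$sample == "meiotic_dup"])      # duplicate column
  expect_true(all(rk$sign[rk$sample %in% c("meiotic", "meiotic_dup")] == -1))
  expect_lt(max(rk$r_squared[grepl("soma", rk$sample)]), 0.05)
  # permuted expression decouples everything
  exprP <- expr[sample(nrow(expr)), , drop = FALSE]
  rownames(exprP) <- rownames(expr)
  rkP <- sampleCorrelationRanking(gc3v, exprP)
  expect_lt(max(rkP$r_squared), 0.05)
})

test_that("group tests match hand calculations and detect shifts", {
  # identical groups: tiny statistic, p near 1
  v <- rep(c(1, 2, 3, 4, 5), 2)
  g <- rep(c("a", "b"), each = 5)
  gt <- groupTests(v, g)
  expect_lt(gt$kruskal$statistic, 0.01)
  expect_gt(gt$kruskal$p_value, 0.9)
  expect_equal(gt$pairwise$delta_mean, 0)

  # power sanity: 3 sd shift, n = 200 per group
  set.seed(510)
  v2 <- c(rnorm(200), rnorm(200, 3))
  g2 <- rep(c("lo", "hi"), each = 200)
  gt2 <- groupTests(v2, g2)
  expect_lt(gt2$pairwise$t_p, 1e-10)
  expect_lt(gt2$pairwise$wilcox_p, 1e-10)
  expect_lt(gt2$kruskal$p_value, 1e-10)

  # fixed 2x5 input: Kruskal-Wallis H computed by hand (no ties)
  v3 <- c(1, 3, 5, 7, 9, 2, 4, 6, 8, 10)
  g3 <- rep(c("a", "b"), each = 5)
  r <- rank(v3)
  H <- 12 / (10 * 11) * (sum(r[1:5])^2 / 5 + sum(r[6:10])^2 / 5) - 3 * 11
  gt3 <- groupTests(v3, g3)
  expect_equal(gt3$kruskal$statistic, H)

  expect_error(groupTests(v3, rep("a", 10)), "at least 2")
  expect_error(groupTests(v3, c(rep("a", 9), "b")), "size < 2")
})
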