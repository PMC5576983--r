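# Shared fixtures, built in code.

# CodonUsageTable from a named count vector (sense codons only), going
# through the public counting path
usageFrom <- function(cnt, source = NA_character_) {
  stopifnot(all(names(cnt) %in% senseCodons()))
  cds <- paste(rep(names(cnt), cnt), collapse = "")
  codonCounts(cds, source = source)
}

# random sense-codon CDS of n codons (no start/stop bookkeeping; all codons
# are sense codons so counting never trips the stop guard)
randomCDS <- function(nCodons) {
  paste(sample(senseCodons(), nCodons, replace = TRUE), collapse = "")
}

# independent brute-force codon recount by string striding
strideCount <- function(cds) {
  n <- nchar(cds)
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  if (codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    codons <- codons[-length(codons)]
  codons <- codons[!grepl("N", codons)]
  table(factor(codons, levels = senseCodons()))
}

# uniform genetic map: one chromosome, constant rate (cM/Mb)
uniformMap <- function(rate = 1, len = 1e7, chrom = "chr1") {
  geneticMap(data.frame(chrom = chrom, pos = c(0, len),
                        cum_cM = c(0, rate * len / 1e6)),
             seqlengths = stats::setNames(len, chrom))
}

# random piecewise-linear map on one chromosome
randomPiecewiseMap <- function(nSeg = 20, len = 1e7, chrom = "chr1") {
  pos <- sort(c(0, sample(seq_len(len - 1), nSeg - 1), len))
  rates <- stats::rlnorm(nSeg, 0, 1)
  geneticMap(data.frame(chrom = chrom, pos = pos,
                        cum_cM = c(0, cumsum(rates * diff(pos) / 1e6))),
             seqlengths = stats::setNames(len, chrom))
}

# independent interval-rate oracle: sum of segment-rate x overlap over the
# map's piecewise-constant rate field (clamped outside the span)
oracleIntervalRate <- function(map, chrom, start, end) {
  m <- mapMarkers(map)
  m <- m[m$chrom == chrom, ]
  segRate <- diff(m$cum_cM) / (diff(m$pos) / 1e6)
  cm <- 0
  for (k in seq_along(segRate)) {
    ov <- max(0, min(end, m$pos[k + 1]) - max(start, m$pos[k]))
    cm <- cm + segRate[k] * ov / 1e6
  }
  cm / ((end - start) / 1e6)
}

# tiny simulation shared across tests needing sequences + genome
tinySim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- syntheticConfig(n_chromosomes = 2L, chrom_length = 2e6,
                             n_genes = 200L, n_gene_sets = 60L,
                             set_size_range = c(40L, 60L), seed = 42L)
      cache <<- simulateGenome(cfg)
    }
    cache
  }
})

# independent sequential-ANOVA oracle via explicit normal equations
oracleSequential <- function(d, response, predictors) {
  y <- d[[response]]
  n <- length(y)
  X <- matrix(1, n, 1)
  rss <- numeric(length(predictors) + 1)
  dfs <- numeric(length(predictors) + 1)
  rss[1] <- sum((y - mean(y))^2)
  dfs[1] <- 1
  for (i in seq_along(predictors)) {
    v <- d[[predictors[i]]]
    Xi <- if (is.factor(v) || is.character(v)) {
      f <- as.factor(v)
      stats::model.matrix(~f)[, -1, drop = FALSE]
    } else {
      matrix(v, ncol = 1)
    }
    X <- cbind(X, Xi)
    beta <- solve(crossprod(X), crossprod(X, y))
    rss[i + 1] <- sum((y - X %*% beta)^2)
    dfs[i + 1] <- ncol(X)
  }
  tot <- rss[1]
  seqSS <- -diff(rss)
  dfFull <- n - dfs[length(dfs)]
  msFull <- rss[length(rss)] / dfFull
  list(model_r2 = (tot - rss[-1]) / tot,
       F = (seqSS / diff(dfs)) / msFull,
       seqSS = seqSS, rss = rss[length(rss)], tot = tot)
}
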