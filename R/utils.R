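# Small internal helpers.

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# mean with normal-approximation 95% CI; figure legends in this field report
# "95% confidence interval of the mean", i.e. mean +/- 1.96 * SEM
.meanCI <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  m <- mean(x)
  se <- if (n > 1L) stats::sd(x) / sqrt(n) else 0
  c(mean = m, lo = m - 1.96 * se, hi = m + 1.96 * se, n = n)
}

# random DNA string of length n with P(G)=P(C)=gc/2, P(A)=P(T)=(1-gc)/2;
# returns a plain character scalar (fast path: raw ASCII assembly)
.randomDNA <- function(n, gc) {
  if (n <= 0L) return("")
  idx <- sample.int(4L, n, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  rawToChar(as.raw(c(65L, 67L, 71L, 84L))[idx])  # A C G T
}

# stable ascending rank used everywhere quantile bins or rank-based
# suppression need a deterministic tie rule: ties broken by `ids` order
.stableRank <- function(values, ids = seq_along(values)) {
  ord <- order(values, ids)
  r <- integer(length(values))
  r[ord] <- seq_along(values)
  r
}

# derive a 32-bit-safe child seed from a base seed and a stage offset
.childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * k) %% 2147483647)
}

.isUndefined <- function(x) is.na(x)

.sortIR <- function(ir) ir[order(IRanges::start(ir))]
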