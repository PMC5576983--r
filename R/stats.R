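# Statistical layer: PCA of gene-set RSCU, pairwise correlations, the
# sequential (Type-I) variance partition of GC3, per-sample GC3~expression
# ranking and group location tests.

#' Squared Pearson correlation with p-value
#'
#' Standard Pearson r-squared; pairs with an undefined value on either side
#' are dropped and their count reported. Zero variance on either side yields
#' the degenerate marker `NA`.
#'
#' @param x,y Paired numeric vectors.
#' @return List: `r_squared`, `sign` (of r), `p_value`, `n`, `n_dropped`.
#' @export
pairwiseR2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  nDropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired defined values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r_squared = NA_real_, sign = NA_real_, p_value = NA_real_,
                n = length(x), n_dropped = nDropped))
  ct <- stats::cor.test(x, y)
  r <- unname(ct$estimate)
  list(r_squared = r^2, sign = sign(r), p_value = ct$p.value,
       n = length(x), n_dropped = nDropped)
}

#' Principal component analysis of a gene-set RSCU matrix
#'
#' Centered (optionally scaled) PCA of sets x codons RSCU. Undefined RSCU
#' entries are imputed by the column mean (count reported in the result);
#' columns that remain constant are dropped when scaling. The sign of PC1 is
#' fixed so that its coordinates correlate positively with set GC3 (supplied,
#' or an RSCU-derived proxy).
#'
#' @param rscuMat Sets x codons matrix (as from [rscuMatrix()]).
#' @param scale. Scale columns to unit variance (default FALSE: RSCU is
#'   already degeneracy-normalised).
#' @param gc3 Optional per-set GC3 used to orient PC1.
#' @return A [PCAResult-class].
#' @export
rscuPCA <- function(rscuMat, scale. = FALSE, gc3 = NULL) {
  stopifnot(is.matrix(rscuMat))
  if (nrow(rscuMat) < 3L) stop("need at least 3 gene sets")
  nImputed <- 0L
  for (j in seq_len(ncol(rscuMat))) {
    na <- is.na(rscuMat[, j])
    if (any(na)) {
      nImputed <- nImputed + sum(na)
      rscuMat[na, j] <- mean(rscuMat[!na, j])
    }
  }
  if (sum(!duplicated(rscuMat)) < 2L)
    stop("rank-deficient input: fewer than 2 distinct RSCU rows")
  keep <- apply(rscuMat, 2L, stats::sd) > 0
  if (scale.) rscuMat <- rscuMat[, keep, drop = FALSE]
  pc <- stats::prcomp(rscuMat, center = TRUE, scale. = scale.)
  if (is.null(gc3)) gc3 <- .rscuGC3Proxy(rscuMat)
  if (stats::sd(gc3) > 0) {
    r <- stats::cor(pc$x[, 1L], gc3)
    if (!is.na(r) && r < 0) {
      pc$x[, 1L] <- -pc$x[, 1L]
      pc$rotation[, 1L] <- -pc$rotation[, 1L]
    }
  }
  shares <- pc$sdev^2 / sum(pc$sdev^2)
  new("PCAResult", coordinates = pc$x, varianceShare = shares,
      loadings = pc$rotation, nImputed = nImputed)
}

# GC3 proxy from an RSCU matrix: mean over degenerate amino acids of the
# RSCU-weighted share of GC-ending codons (exact GC3 would need amino-acid
# composition weights, but for orienting PC1 the proxy suffices)
.rscuGC3Proxy <- function(rscuMat) {
  cods <- intersect(colnames(rscuMat), synonymousCodons())
  aa <- codonAminoAcids()[cods]
  shares <- vapply(split(cods, aa), function(cc) {
    tot <- rowSums(rscuMat[, cc, drop = FALSE])
    gcc <- cc[.isGCEnding(cc)]
    num <- if (length(gcc)) rowSums(rscuMat[, gcc, drop = FALSE]) else
      numeric(nrow(rscuMat))
    ifelse(tot > 0, num / tot, NA_real_)
  }, numeric(nrow(rscuMat)))
  rowMeans(shares, na.rm = TRUE)
}

setMethod("show", "PCAResult", function(object) {
  cat("PCAResult:", nrow(object@coordinates), "sets;",
      "PC1", sprintf("%.1f%%", 100 * object@varianceShare[1L]),
      "PC2", sprintf("%.1f%%", 100 * object@varianceShare[2L]),
      "of variance;", object@nImputed, "cells imputed\n")
})

#' Sequential (Type-I) variance partition
#'
#' Ordinary-least-squares fits of nested models in the stated predictor
#' order. Each step reports its pairwise r-squared with the response, the
#' cumulative model r-squared, and an F statistic for the step's sequential
#' sum of squares tested against the full model's residual mean square (the
#' classical sequential-ANOVA F). Only complete cases are used; the dropped
#' count is recorded.
#'
#' @param data data.frame holding the response and predictors. Character
#'   predictors are treated as unordered factors; a level named "other" is
#'   used as the reference level when present.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor column names, in entry
#'   order.
#' @param interactions Also include all pairwise interactions after the main
#'   effects (the "interaction variant").
#' @return A [VariancePartition-class].
#' @export
sequentialAnova <- function(data, response, predictors,
                            interactions = FALSE) {
  stopifnot(all(c(response, predictors) %in% names(data)))
  d <- data[, c(response, predictors), drop = FALSE]
  for (p in predictors) {
    if (is.character(d[[p]])) d[[p]] <- factor(d[[p]])
    if (is.factor(d[[p]]) && "other" %in% levels(d[[p]]))
      d[[p]] <- stats::relevel(d[[p]], ref = "other")
  }
  cc <- stats::complete.cases(d)
  nDropped <- sum(!cc)
  d <- d[cc, , drop = FALSE]
  rhs <- paste(sprintf("`%s`", predictors), collapse = " + ")
  if (interactions) rhs <- sprintf("(%s)^2", rhs)
  form <- stats::as.formula(sprintf("`%s` ~ %s", response, rhs))
  fit <- stats::lm(form, data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular fit; collinear predictor(s): ",
         paste(unique(bad), collapse = ", "))
  }
  an <- stats::anova(fit)
  terms <- rownames(an)[rownames(an) != "Residuals"]
  ss <- an[terms, "Sum Sq"]
  rss <- an["Residuals", "Sum Sq"]
  totalSS <- sum(ss) + rss
  modelR2 <- cumsum(ss) / totalSS
  y <- d[[response]]
  pairR2 <- vapply(terms, function(tm) {
    nm <- gsub("`", "", tm)
    if (!nm %in% names(d)) return(NA_real_)  # interaction rows
    x <- d[[nm]]
    if (is.factor(x)) summary(stats::lm(y ~ x))$r.squared
    else stats::cor(y, x)^2
  }, numeric(1))
  tab <- data.frame(predictor = gsub("`", "", terms),
                    pairwise_r2 = unname(pairR2),
                    model_r2 = unname(modelR2),
                    F = an[terms, "F value"],
                    p = an[terms, "Pr(>F)"],
                    stringsAsFactors = FALSE)
  fullR2 <- summary(fit)$r.squared
  if (abs(tab$model_r2[nrow(tab)] - fullR2) > 1e-10 * max(1, fullR2))
    stop("internal inconsistency: sequential R2 does not reach the full fit")
  new("VariancePartition", table = tab,
      residualDf = unname(an["Residuals", "Df"]),
      nUsed = nrow(d), nDropped = as.integer(nDropped),
      totalSS = totalSS, response = response)
}

#' @describeIn VariancePartition-class Per-step table.
#' @param x A VariancePartition.
#' @export
setMethod("partitionTable", "VariancePartition", function(x) x@table)

setMethod("show", "VariancePartition", function(object) {
  cat("VariancePartition of", object@response, "(n =", object@nUsed,
      "genes,", object@nDropped, "dropped)\n")
  tab <- object@table
  tab$pairwise_r2 <- sprintf("%.1f%%", 100 * tab$pairwise_r2)
  tab$model_r2 <- sprintf("%.1f%%", 100 * tab$model_r2)
  print(tab, row.names = FALSE)
})

#' Rank samples by how well expression predicts GC3
#'
#' For every sample (column), computes the squared Pearson correlation
#' between per-gene GC3 and log-transformed expression, keeping the sign of
#' the correlation, and returns the table sorted by increasing r-squared —
#' so the most GC3-informative samples (in meiotic tissue, the strongest
#' negative correlations) come last.
#'
#' @param gc3ByGene Named numeric per-gene GC3.
#' @param exprMat Genes x samples FPKM matrix (rownames = gene ids).
#' @param pseudocount Passed to [logTransform()].
#' @return data.frame: `sample`, `r_squared`, `sign`, `p_value`, `n`, sorted
#'   ascending by `r_squared`.
#' @export
sampleCorrelationRanking <- function(gc3ByGene, exprMat, pseudocount = 1) {
  common <- intersect(names(gc3ByGene), rownames(exprMat))
  g <- gc3ByGene[common]
  rows <- lapply(colnames(exprMat), function(s) {
    pr <- pairwiseR2(g, logTransform(exprMat[common, s], pseudocount))
    data.frame(sample = s, r_squared = pr$r_squared, sign = pr$sign,
               p_value = pr$p_value, n = pr$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$r_squared), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Location tests between groups of genes
#'
#' Omnibus rank-based test (Kruskal-Wallis) plus all pairwise Wilcoxon
#' rank-sum tests and pairwise Welch t-tests, with raw (unadjusted)
#' p-values.
#'
#' @param values Numeric vector.
#' @param labels Group labels (>= 2 groups, each of size >= 2).
#' @return List: `kruskal` (statistic, p_value), `pairwise` (data.frame
#'   `group1`, `group2`, `wilcox_p`, `t_p`, `delta_mean`).
#' @export
groupTests <- function(values, labels) {
  labels <- as.factor(droplevels(as.factor(labels)))
  if (nlevels(labels) < 2L) stop("need at least 2 groups")
  sizes <- table(labels)
  if (any(sizes < 2L))
    stop("group(s) of size < 2: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  kw <- stats::kruskal.test(values, labels)
  lev <- levels(labels)
  pairs <- utils::combn(lev, 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- values[labels == pairs[1L, i]]
    b <- values[labels == pairs[2L, i]]
    data.frame(group1 = pairs[1L, i], group2 = pairs[2L, i],
               wilcox_p = suppressWarnings(stats::wilcox.test(a, b)$p.value),
               t_p = stats::t.test(a, b)$p.value,
               delta_mean = mean(a) - mean(b),
               stringsAsFactors = FALSE)
  }))
  list(kruskal = list(statistic = unname(kw$statistic),
                      p_value = kw$p.value),
       pairwise = pw)
}
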