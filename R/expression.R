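# Expression normalisation: replicate averaging, sex-averaged meiotic
# expression, log transformation, quantile binning.

#' Average expression replicates into one column per sample group
#'
#' @param mat Genes x samples numeric matrix (FPKM, non-negative).
#' @param sampleInfo data.frame with columns `sample` (matching colnames of
#'   `mat`) and `group`; every column of `mat` must be mapped.
#' @return Genes x groups matrix of arithmetic per-group means.
#' @export
averageReplicates <- function(mat, sampleInfo) {
  stopifnot(is.matrix(mat))
  unmapped <- setdiff(colnames(mat), sampleInfo$sample)
  if (length(unmapped))
    stop("columns without group mapping: ", paste(unmapped, collapse = ", "))
  grp <- sampleInfo$group[match(colnames(mat), sampleInfo$sample)]
  groups <- unique(grp)
  out <- vapply(groups, function(g) {
    rowMeans(mat[, grp == g, drop = FALSE])
  }, numeric(nrow(mat)))
  dimnames(out) <- list(rownames(mat), groups)
  out
}

#' Sex-averaged meiotic expression
#'
#' The sex-averaged meiotic expression of a gene is the arithmetic mean of
#' its female meiotic value and its male meiotic value, where the male value
#' is itself the mean over the configured male meiotic sample group(s)
#' (default intent: the meiotic stage only, e.g. pachytene spermatocytes;
#' pass several groups to pool meiotic and post-meiotic stages). Genes with
#' an undefined value on either side carry `NA` and an `excluded` flag so
#' downstream analyses can drop them.
#'
#' @param mat Genes x sample-group matrix (as from [averageReplicates()]).
#' @param femaleSample Column name of the female meiotic group.
#' @param maleSamples Column name(s) of the male meiotic group(s).
#' @return data.frame: `gene_id`, `female`, `male`, `sex_averaged`,
#'   `excluded`.
#' @export
meioticSexAverage <- function(mat, femaleSample, maleSamples) {
  stopifnot(femaleSample %in% colnames(mat),
            all(maleSamples %in% colnames(mat)))
  female <- mat[, femaleSample]
  male <- rowMeans(mat[, maleSamples, drop = FALSE])
  avg <- (female + male) / 2
  data.frame(gene_id = rownames(mat), female = unname(female),
             male = unname(male), sex_averaged = unname(avg),
             excluded = is.na(avg), stringsAsFactors = FALSE)
}

#' Equal-count quantile bins
#'
#' Ranks values (stable tie-break by gene id) into `k` bins whose sizes
#' differ by at most one gene. The realised cut points (the value range of
#' each bin) are recorded in the `"cuts"` attribute, the analogue of printed
#' FPKM thresholds for published tercile bins.
#'
#' @param values Numeric vector.
#' @param k Number of bins.
#' @param ids Ids used for the stable tie-break (default input order).
#' @param labels Optional bin labels (default `bin1..bink`, ascending value).
#' @return Factor of bin labels, with attribute `"cuts"` (data.frame `bin`,
#'   `min_value`, `max_value`, `n`).
#' @export
quantileBins <- function(values, k, ids = seq_along(values), labels = NULL) {
  stopifnot(k >= 2L)
  n <- length(values)
  if (k > n) stop("more bins (", k, ") than genes (", n, ")")
  if (is.null(labels)) labels <- paste0("bin", seq_len(k))
  stopifnot(length(labels) == k)
  r <- .stableRank(values, ids)
  bin <- ceiling(r * k / n)
  out <- factor(labels[bin], levels = labels)
  names(out) <- ids
  cuts <- do.call(rbind, lapply(seq_len(k), function(b) {
    v <- values[bin == b]
    data.frame(bin = labels[b], min_value = min(v), max_value = max(v),
               n = length(v))
  }))
  attr(out, "cuts") <- cuts
  out
}

#' Log-transform expression values
#'
#' `log10(value + pseudocount)`; the default pseudocount of 1 maps zero FPKM
#' to zero.
#'
#' @param values Non-negative numeric vector.
#' @param pseudocount Added before taking logs (default 1).
#' @return Transformed vector (monotone in the input).
#' @export
logTransform <- function(values, pseudocount = 1) {
  if (any(values < 0, na.rm = TRUE)) stop("negative expression values")
  log10(values + pseudocount)
}

#' Read an expression matrix TSV with its sample-metadata sidecar
#'
#' @param path TSV with a `gene_id` column followed by one column per
#'   sample (FPKM).
#' @param sampleInfoPath Optional sidecar TSV (`sample`, `group`, ...).
#' @return List: `matrix` (genes x samples), `sampleInfo` (data.frame or
#'   `NULL`).
#' @export
readExpressionMatrix <- function(path, sampleInfoPath = NULL) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot("gene_id" %in% names(d))
  mat <- as.matrix(d[, setdiff(names(d), "gene_id"), drop = FALSE])
  rownames(mat) <- d$gene_id
  info <- if (!is.null(sampleInfoPath))
    utils::read.delim(sampleInfoPath, stringsAsFactors = FALSE) else NULL
  list(matrix = mat, sampleInfo = info)
}
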