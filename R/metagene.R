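# Expression-stratified contrasts and strand-aware metagene profiles.

#' Fold change of a value between bottom and top quantile bins
#'
#' Genes are ranked by the stratifier into `k` equal-size quantile bins
#' (ties broken by stable gene-id order) and the ratio
#' mean(value | bottom bin) / mean(value | top bin) is returned together with
#' per-bin means and 95% confidence intervals of the mean. A value several
#' times lower in the top bin therefore appears as a fold change of several.
#'
#' @param values Numeric per-gene values (e.g. intragenic crossover rate).
#' @param stratifier Numeric per-gene stratifier (e.g. meiotic expression);
#'   the contrast is invariant to monotone transforms of it.
#' @param k Number of bins (default 10, deciles).
#' @param ids Gene ids used for the stable tie-break (defaults to input
#'   order).
#' @return List: `fold_change`, `bins` (data.frame `bin`, `mean_value`,
#'   `ci_low`, `ci_high`, `n`, `mean_stratifier`).
#' @export
decileContrast <- function(values, stratifier, k = 10L,
                           ids = seq_along(values)) {
  stopifnot(length(values) == length(stratifier))
  if (k < 2L) stop("k must be >= 2")
  ok <- is.finite(values) & is.finite(stratifier)
  values <- values[ok]; stratifier <- stratifier[ok]; ids <- ids[ok]
  n <- length(values)
  if (n < 2L * k) stop("need at least 2k genes (", 2L * k, "), got ", n)
  r <- .stableRank(stratifier, ids)
  bin <- ceiling(r * k / n)
  bins <- do.call(rbind, lapply(seq_len(k), function(b) {
    ci <- .meanCI(values[bin == b])
    data.frame(bin = b, mean_value = ci[["mean"]], ci_low = ci[["lo"]],
               ci_high = ci[["hi"]], n = ci[["n"]],
               mean_stratifier = mean(stratifier[bin == b]))
  }))
  list(fold_change = bins$mean_value[1L] / bins$mean_value[k], bins = bins)
}

#' Metagene crossover-rate profile around TSS or polyadenylation site
#'
#' Lays non-overlapping windows of `window` bp in transcriptional orientation
#' around the chosen anchor of every gene (minus-strand genes are flipped, so
#' positive offsets always point into or past the gene body in the direction
#' of transcription), measures each window's crossover rate with
#' [intervalRate()], and averages across genes per window, with a
#' normal-approximation 95% confidence interval of the mean. Windows falling
#' off the chromosome (or outside the map when `requireCovered`) are dropped
#' from the affected genes and `n` adjusted.
#'
#' @param map A [GeneticMap-class].
#' @param models A [GeneModelSet-class].
#' @param anchor `"TSS"` or `"polyA"`.
#' @param window Window width in bp (default 1000).
#' @param upstream,downstream Extent of the profile in bp on each side of the
#'   anchor (must be multiples of `window`).
#' @param strata Optional per-gene factor (e.g. expression terciles); the
#'   profile is then computed per level.
#' @param requireCovered Drop windows whose `covered_fraction` < 1.
#' @return A [MetageneProfile-class].
#' @export
metageneProfile <- function(map, models, anchor = c("TSS", "polyA"),
                            window = 1000, upstream = 5000, downstream = 10000,
                            strata = NULL, requireCovered = FALSE) {
  anchor <- match.arg(anchor)
  if (upstream %% window != 0 || downstream %% window != 0)
    stop("upstream and downstream must be multiples of the window size")
  gt <- geneTable(models)
  a <- if (anchor == "TSS") gt$tss else gt$polya
  minus <- gt$strand == "-"
  offsets <- seq(-upstream, downstream - window, by = window)
  nG <- nrow(gt); nW <- length(offsets)
  geneIdx <- rep(seq_len(nG), each = nW)
  off <- rep(offsets, times = nG)
  ws <- ifelse(minus[geneIdx], a[geneIdx] - off - window, a[geneIdx] + off)
  we <- ws + window
  chrom <- gt$chrom[geneIdx]
  sl <- GenomeInfoDb::seqlengths(models@genes)[chrom]
  keep <- ws >= 0 & (is.na(sl) | we <= sl)
  ir <- intervalRate(map, chrom[keep], ws[keep], we[keep])
  if (requireCovered) {
    cov <- ir$covered_fraction >= 1 - 1e-12
    ir <- ir[cov, , drop = FALSE]
    keep[keep] <- cov
  }
  if (is.null(strata)) strata <- factor(rep("all", nG))
  strata <- as.factor(strata)
  d <- data.frame(stratum = strata[geneIdx[keep]], offset_bp = off[keep],
                  rate = ir$rate)
  prof <- do.call(rbind, lapply(split(d, list(d$stratum, d$offset_bp),
                                      drop = TRUE), function(g) {
    ci <- .meanCI(g$rate)
    data.frame(stratum = g$stratum[1L], offset_bp = g$offset_bp[1L],
               mean_rate = ci[["mean"]], ci_low = ci[["lo"]],
               ci_high = ci[["hi"]], n = as.integer(ci[["n"]]))
  }))
  prof <- prof[order(prof$stratum, prof$offset_bp), , drop = FALSE]
  rownames(prof) <- NULL
  new("MetageneProfile", anchor = anchor, window = window, profile = prof)
}

#' @describeIn MetageneProfile-class Profile table.
#' @param x A MetageneProfile.
#' @export
setMethod("profileTable", "MetageneProfile", function(x) x@profile)

setMethod("show", "MetageneProfile", function(object) {
  cat("MetageneProfile at", object@anchor, "-", object@window, "bp windows,",
      length(unique(object@profile$stratum)), "stratum/strata,",
      nrow(object@profile), "windows\n")
})
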