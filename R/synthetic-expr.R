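# Expression-matrix and gene-set stage of the synthetic generator.

.prolifPhrases <- c("mitotic cell cycle process", "chromatin remodeling at promoter",
                    "translation initiation machinery", "mRNA metabolic process regulation",
                    "nucleosome assembly complex")
.diffPhrases <- c("cell differentiation program", "pattern specification process",
                  "organ development pathway", "cell adhesion signalling",
                  "angiogenesis regulation")
.neutralPhrases <- c("ion transport", "lipid metabolic process",
                     "signal transduction cascade", "protein folding",
                     "oxidative phosphorylation", "DNA repair complex",
                     "vesicle trafficking", "amino acid biosynthesis")

#' Synthesize expression samples and GO-like gene sets
#'
#' Emits a genes x samples FPKM matrix with replicate structure: one female
#' meiotic group (PGC-like), one male meiotic group (spermatocyte-like), one
#' male post-meiotic group (spermatid-like) and `n_somatic_groups` somatic
#' groups with expression independent of the meiotic program. Replicates are
#' log-normal around the per-gene group mean (`replicate_sigma`).
#'
#' Gene sets are overlapping and GO-like: each set draws a tilt toward high
#' or low meiotic expression (strength `expression_bias_of_sets`; 0 gives
#' unbiased membership), and under `regime = "trna_coadapted"` membership
#' concentrates inside one latent regulon so the set shares that regulon's
#' preferred-codon table. Sets tilted strongly toward high meiotic
#' expression receive proliferation-flavoured names, strongly low tilt
#' differentiation-flavoured names, mirroring the association between
#' proliferation annotation and meiotic expression the analysis probes.
#'
#' @param config A `SyntheticConfig`.
#' @param truth Truth table from [placeGenesAndSuppress()].
#' @return List: `expression` (matrix), `sampleInfo` (data.frame `sample`,
#'   `group`, `sex`, `cell_type`, `replicate`), `sets` (named list with
#'   `"description"` and `"tilt"` attributes).
#' @export
synthesizeExpressionAndSets <- function(config, truth) {
  validateSyntheticConfig(config)
  set.seed(.childSeed(config$seed, 4L))
  nG <- nrow(truth)
  mu <- config$expression_lognormal_params[[1L]]
  sig <- config$expression_lognormal_params[[2L]]

  groups <- data.frame(
    group = c("pgc_female_17w", "spermatocyte", "spermatid",
              sprintf("soma%d", seq_len(config$n_somatic_groups))),
    sex = c("female", "male", "male",
            rep("mixed", config$n_somatic_groups)),
    cell_type = c("germ_meiotic", "germ_meiotic", "germ_postmeiotic",
                  rep("somatic", config$n_somatic_groups)),
    stringsAsFactors = FALSE)

  means <- cbind(
    pgc_female_17w = truth$female_mean,
    spermatocyte = truth$male_mean,
    spermatid = truth$male_mean * exp(stats::rnorm(nG, 0, 0.4)))
  for (k in seq_len(config$n_somatic_groups))
    means <- cbind(means, stats::rlnorm(nG, mu, sig))
  colnames(means) <- groups$group

  nRep <- config$n_replicates
  sampleInfo <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    data.frame(sample = sprintf("%s_rep%d", groups$group[i], seq_len(nRep)),
               group = groups$group[i], sex = groups$sex[i],
               cell_type = groups$cell_type[i], replicate = seq_len(nRep),
               stringsAsFactors = FALSE)
  }))
  expr <- matrix(0, nG, nrow(sampleInfo),
                 dimnames = list(truth$gene_id, sampleInfo$sample))
  for (j in seq_len(nrow(sampleInfo))) {
    m <- means[, sampleInfo$group[j]]
    expr[, j] <- m * exp(stats::rnorm(nG, 0, config$replicate_sigma))
  }

  # Latent gene categories tied to meiotic expression: proliferation-like
  # genes concentrate in the top expression ranks, differentiation-like
  # genes in the bottom ranks (the association the analysis probes).
  rk <- .stableRank(truth$meiotic_expression, truth$gene_id) / nG
  pProlif <- 0.30 * rk^3
  pDiff <- 0.45 * (1 - rk)^2
  u <- stats::runif(nG)
  geneCategory <- ifelse(u < pProlif, "proliferation",
                         ifelse(u < pProlif + pDiff, "differentiation",
                                "other"))

  # GO-like overlapping sets. Under the gBGC regime, proliferation- and
  # differentiation-named sets sample (almost) only from their latent
  # category, neutral sets by a random expression tilt; under the
  # tRNA-coadapted regime every set concentrates in one latent regulon so it
  # shares that regulon's preferred-codon table. Setting
  # expression_bias_of_sets to 0 turns all membership sampling unbiased.
  z <- as.numeric(scale(log(truth$meiotic_expression)))
  bias <- config$expression_bias_of_sets
  nSets <- config$n_gene_sets
  sets <- vector("list", nSets)
  descs <- character(nSets)
  tilts <- numeric(nSets)
  setNamesV <- character(nSets)
  for (s in seq_len(nSets)) {
    type <- sample(c("proliferation", "differentiation", "neutral"), 1L,
                   prob = c(0.12, 0.18, 0.70))
    tau <- stats::runif(1, -bias, bias)
    tilts[s] <- tau
    m <- sample(seq(config$set_size_range[1L], config$set_size_range[2L]), 1L)
    if (config$regime == "trna_coadapted") {
      r <- sample.int(config$n_regulons, 1L)
      w <- ifelse(truth$regulon == r, 1, 0.02)
    } else if (bias > 0 && type != "neutral") {
      w <- ifelse(geneCategory == type, 1, 0.001)
    } else {
      w <- exp(tau * z)
    }
    sets[[s]] <- sort(sample(truth$gene_id, m, prob = w))
    phrase <- switch(type,
                     proliferation = sample(.prolifPhrases, 1L),
                     differentiation = sample(.diffPhrases, 1L),
                     neutral = sample(.neutralPhrases, 1L))
    setNamesV[s] <- sprintf("%s (S%05d)", phrase, s)
    descs[s] <- sprintf("synthetic gene set %d, type %s, tilt %.2f",
                        s, type, tau)
  }
  names(sets) <- setNamesV
  attr(sets, "description") <- stats::setNames(descs, setNamesV)
  attr(sets, "tilt") <- stats::setNames(tilts, setNamesV)
  list(expression = expr, sampleInfo = sampleInfo, sets = sets,
       geneCategory = geneCategory)
}
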