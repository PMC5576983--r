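# End-to-end analysis pipeline: from sequences + models + map + expression
# to the variance partition of GC3, the isoacceptor test and the
# recombination/expression contrasts.

#' Run the full codon-usage analysis on a simulation (or equivalent inputs)
#'
#' Reproduces the analysis chain on one set of inputs: per-gene features
#' (GC3, GCi, GC-flank), intragenic crossover rates, meiotic expression,
#' functional categories from set names, set-level RSCU + PCA, the
#' mono/multi-isoacceptor selection test, the expression-decile crossover
#' contrast, metagene profiles stratified by expression terciles, the
#' per-sample GC3~expression ranking and the sequential variance partition
#' of GC3.
#'
#' @param sim A [SyntheticGenome-class] (genome assembled for GCi/GC-flank).
#' @param minGeneLength Gene-length filter in bp (default 5000).
#' @param minSetSize Gene-set size filter (default 40).
#' @param k Bins for the expression-decile contrast (default 10).
#' @param partition Isoacceptor partition for the selection test.
#' @param withMetagene Compute metagene profiles (slower).
#' @return Named list of results; see the vignette for a walk-through.
#' @export
runPipeline <- function(sim, minGeneLength = 5000, minSetSize = 40L,
                        k = 10L, partition = humanIsoacceptorPartition(),
                        withMetagene = TRUE) {
  models <- geneModels(sim)
  gt <- geneTable(models)
  universe <- lengthFilter(gt, minGeneLength)

  features <- if (!is.null(sim@genome)) {
    geneFeatures(models, sim@genome, cds = sim@cds)
  } else {
    cnt <- codonCountsMatrix(sim@cds)
    cod <- synonymousCodons()
    tot <- rowSums(cnt[, cod, drop = FALSE])
    data.frame(gene_id = rownames(cnt),
               gc3 = rowSums(cnt[, cod[.isGCEnding(cod)], drop = FALSE]) / tot,
               gci = NA_real_, gc_flank = NA_real_,
               n_codons = rowSums(cnt), stringsAsFactors = FALSE)
  }

  ratesTU <- intervalRate(sim@map, gt$chrom, gt$start, gt$end)
  features$crossover_rate <- ratesTU$rate
  features$hotspot_density <- hotspotDensity(sim@hotspots, gt$chrom,
                                             gt$start, gt$end)

  avg <- averageReplicates(sim@expression, sim@sampleInfo)
  meiotic <- meioticSexAverage(avg, "pgc_female_17w", "spermatocyte")
  features$meiotic_fpkm <- meiotic$sex_averaged[match(features$gene_id,
                                                      meiotic$gene_id)]

  filteredSets <- filterSets(sim@sets, minSize = minSetSize)
  categories <- assignCategories(filteredSets, universe = universe)
  features$category <- as.character(categories[match(features$gene_id,
                                                     names(categories))])
  features$category[is.na(features$category)] <- "other"

  keep <- features$gene_id %in% universe & features$category != "discarded"
  d <- features[keep, , drop = FALSE]
  d$log_rate <- logTransform(d$crossover_rate, pseudocount = 0.01)
  d$log_expr <- logTransform(d$meiotic_fpkm)

  anova <- tryCatch(
    sequentialAnova(d, "gc3",
                    c("gci", "gc_flank", "log_rate", "log_expr", "category")),
    error = function(e) NULL)

  tables <- usageTables(sim@cds)
  setTabs <- setUsageTables(filteredSets, tables, drop = TRUE)
  rm <- rscuMatrix(setTabs)
  setGC3 <- vapply(setTabs, gc3, numeric(1))
  pca <- rscuPCA(rm, gc3 = setGC3)
  iso <- selectionTest(setTabs, partition)

  contrast <- decileContrast(d$crossover_rate, d$meiotic_fpkm, k = k,
                             ids = d$gene_id)

  metagene <- NULL
  if (withMetagene) {
    terc <- quantileBins(d$meiotic_fpkm, 3L, ids = d$gene_id,
                         labels = c("low", "medium", "high"))
    idx <- match(geneIds(models), d$gene_id)
    strata <- factor(as.character(terc)[idx], levels = c("low", "medium",
                                                         "high"))
    sub <- !is.na(strata)
    metagene <- metageneProfile(sim@map, models[sub],
                                anchor = "TSS", window = 1000,
                                upstream = 5000, downstream = 10000,
                                strata = droplevels(strata[sub]))
  }

  ranking <- sampleCorrelationRanking(
    stats::setNames(d$gc3, d$gene_id), sim@expression)

  groupT <- tryCatch(
    groupTests(d$gc3, d$category), error = function(e) NULL)

  list(features = features, data = d, anova = anova, pca = pca,
       set_gc3 = setGC3, isoacceptor = iso, contrast = contrast,
       metagene = metagene, sample_ranking = ranking,
       group_tests = groupT, categories = categories,
       n_sets = length(filteredSets))
}

#' Subset a GeneModelSet
#'
#' @param x A [GeneModelSet-class].
#' @param i Logical, integer or character index over genes.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "GeneModelSet", function(x, i, j, ..., drop = FALSE) {
  .newGeneModelSet(x@genes[i], x@cds[i], x@introns[i], x@flanks[i],
                   x@flankWidth)
})
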