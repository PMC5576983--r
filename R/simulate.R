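# Orchestration of the synthetic generator and file emission.

#' Run the full synthetic-genome generator
#'
#' Runs, in order: [generateRecombinationLandscape()],
#' [placeGenesAndSuppress()], [synthesizeSequences()],
#' [synthesizeExpressionAndSets()] and hotspot generation. Each stage seeds
#' its own random stream from `config$seed`, so outputs are byte-identical
#' for identical config + seed, and skipping the genome assembly does not
#' change any other output.
#'
#' @param config A `SyntheticConfig` (see [syntheticConfig()]).
#' @param what `"all"` (genome + CDS), `"cds"` (coding sequences only) or
#'   `"maps"` (no sequence synthesis).
#' @return A [SyntheticGenome-class].
#' @export
simulateGenome <- function(config = syntheticConfig(),
                           what = c("all", "cds", "maps")) {
  what <- match.arg(what)
  validateSyntheticConfig(config)
  baseMap <- generateRecombinationLandscape(config)
  pl <- placeGenesAndSuppress(config, baseMap)
  if (what == "maps") {
    seqres <- list(genome = NULL, cds = NULL, truth = pl$truth)
  } else {
    seqres <- synthesizeSequences(config, pl$models, baseMap, pl$truth,
                                  assembleGenome = (what == "all"))
  }
  ex <- synthesizeExpressionAndSets(config, pl$truth)
  hs <- .generateHotspots(config, pl$map)
  seqres$truth$latent_category <- ex$geneCategory
  new("SyntheticGenome", config = unclass(config), map = pl$map,
      baseMap = baseMap, models = pl$models, truth = seqres$truth,
      genome = seqres$genome, cds = seqres$cds, expression = ex$expression,
      sampleInfo = ex$sampleInfo, sets = ex$sets, hotspots = hs)
}

#' @describeIn SyntheticGenome-class Per-gene generative truth.
#' @param x A SyntheticGenome.
#' @export
setMethod("truthTable", "SyntheticGenome", function(x) x@truth)

#' @describeIn SyntheticGenome-class Gene models.
#' @export
setMethod("geneModels", "SyntheticGenome", function(x) x@models)

#' @describeIn SyntheticGenome-class Gene identifiers.
#' @export
setMethod("geneIds", "SyntheticGenome", function(x) x@truth$gene_id)

setMethod("show", "SyntheticGenome", function(object) {
  cfg <- object@config
  cat("SyntheticGenome:", cfg$n_chromosomes, "chromosomes x",
      cfg$chrom_length / 1e6, "Mb,", nrow(object@truth), "genes, regime",
      cfg$regime, "\n  genome:",
      if (is.null(object@genome)) "not assembled" else "assembled",
      "| cds:", if (is.null(object@cds)) "absent" else "present",
      "|", length(object@sets), "gene sets,",
      ncol(object@expression), "expression samples\n")
})

#' Write GFF3 gene models
#'
#' Emits gene, mRNA and CDS records (1-based inclusive coordinates), one
#' canonical transcript per gene, readable back with [loadGeneModels()].
#'
#' @param models A [GeneModelSet-class].
#' @param path Output file.
#' @export
writeGFF3 <- function(models, path) {
  g <- models@genes
  lines <- c("##gff-version 3")
  chrom <- as.character(seqnames(g))
  strand <- as.character(strand(g))
  for (i in seq_along(g)) {
    gid <- names(g)[i]
    tid <- paste0(gid, ".t1")
    lines <- c(lines,
      sprintf("%s\tsynth\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              chrom[i], start(g)[i], end(g)[i], strand[i], gid),
      sprintf("%s\tsynth\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              chrom[i], start(g)[i], end(g)[i], strand[i], tid, gid))
    cds <- models@cds[[i]]
    phase <- .cdsPhases(cds, strand[i])
    lines <- c(lines,
      sprintf("%s\tsynth\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
              chrom[i], start(cds), end(cds), strand[i], phase, tid))
  }
  writeLines(lines, path)
  invisible(path)
}

# GFF3 CDS phase column: offset to the next codon start, walking the CDS in
# transcript order
.cdsPhases <- function(cds, strand) {
  w <- width(cds)
  if (strand == "-") w <- rev(w)
  ph <- (3L - (cumsum(c(0L, w[-length(w)])) %% 3L)) %% 3L
  if (strand == "-") ph <- rev(ph)
  ph
}

#' Write BED12 gene models
#'
#' Blocks are the exonic intervals (transcription unit minus introns); thick
#' range spans the CDS.
#'
#' @param models A [GeneModelSet-class].
#' @param path Output file.
#' @export
writeBED12 <- function(models, path) {
  g <- models@genes
  chrom <- as.character(seqnames(g))
  lines <- vapply(seq_along(g), function(i) {
    tu <- IRanges(start(g)[i], end(g)[i])
    blocks <- IRanges::setdiff(tu, models@introns[[i]])
    cds <- models@cds[[i]]
    s0 <- start(g)[i] - 1L
    paste(chrom[i], s0, end(g)[i], names(g)[i], 0L,
          as.character(strand(g))[i],
          min(start(cds)) - 1L, max(end(cds)), 0L, length(blocks),
          paste0(paste(width(blocks), collapse = ","), ","),
          paste0(paste(start(blocks) - 1L - s0, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write every artefact of a simulation to a directory
#'
#' Emits: `genome.fa`, `cds.fa`, `genes.gff3`, `genes.bed12`, `map.tsv`
#' (suppressed map), `base_map.tsv` (landscape before suppression),
#' `hotspots.bed`, `expression.tsv`, `samples.tsv`, `sets.gmt`, `truth.tsv`.
#' All plain text.
#'
#' @param sim A [SyntheticGenome-class].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeSyntheticData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  if (!is.null(sim@genome))
    Biostrings::writeXStringSet(sim@genome, fp("genome.fa"))
  if (!is.null(sim@cds))
    Biostrings::writeXStringSet(sim@cds, fp("cds.fa"))
  writeGFF3(sim@models, fp("genes.gff3"))
  writeBED12(sim@models, fp("genes.bed12"))
  writeGeneticMap(sim@map, fp("map.tsv"))
  writeGeneticMap(sim@baseMap, fp("base_map.tsv"))
  utils::write.table(sim@hotspots, fp("hotspots.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  expr <- data.frame(gene_id = rownames(sim@expression), sim@expression,
                     check.names = FALSE)
  utils::write.table(expr, fp("expression.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim@sampleInfo, fp("samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeGMT(sim@sets, fp("sets.gmt"))
  tr <- sim@truth
  attr(tr, "structures") <- NULL
  utils::write.table(tr, fp("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}
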