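# Per-gene sequence features: GC3, intronic GC, flanking GC.

# vectorised GC fraction per string; "" -> NA
.gcOfStrings <- function(strings) {
  dss <- Biostrings::DNAStringSet(strings)
  af <- Biostrings::alphabetFrequency(dss)[, c("A", "C", "G", "T"), drop = FALSE]
  tot <- rowSums(af)
  out <- (af[, "G"] + af[, "C"]) / tot
  out[tot == 0] <- NA_real_
  unname(out)
}

#' Per-gene codon-usage and GC features
#'
#' Computes, for every gene in a model set: GC3 (over the 59-synonymous-codon
#' universe by default), intronic GC (GCi; `NA` for intronless genes),
#' flanking GC (GC-flank, over the flank intervals built with the model set),
#' and the number of counted codons.
#'
#' @param models A [GeneModelSet-class].
#' @param genome Genome `DNAStringSet` named by chromosome.
#' @param cds Optional precomputed `DNAStringSet` of coding sequences
#'   (as from [cdsSequences()]); extracted from the genome when `NULL`.
#' @param universe Codon universe passed to the GC3 computation.
#' @return data.frame: `gene_id`, `gc3`, `gci`, `gc_flank`, `n_codons`.
#' @export
geneFeatures <- function(models, genome, cds = NULL,
                         universe = c("syn59", "sense61")) {
  universe <- match.arg(universe)
  if (is.null(cds)) cds <- cdsSequences(models, genome)
  cds <- cds[geneIds(models)]
  cnt <- codonCountsMatrix(cds)
  cod <- if (universe == "syn59") synonymousCodons() else senseCodons()
  gcCod <- cod[.isGCEnding(cod)]
  tot <- rowSums(cnt[, cod, drop = FALSE])
  gc3v <- rowSums(cnt[, gcCod, drop = FALSE]) / tot
  gc3v[tot == 0] <- NA_real_

  chrom <- as.character(seqnames(models@genes))
  gci <- .gcOfStrings(.extractConcat(genome, chrom, models@introns))
  gcFlank <- .gcOfStrings(.extractConcat(genome, chrom, models@flanks))

  data.frame(gene_id = geneIds(models), gc3 = unname(gc3v), gci = gci,
             gc_flank = gcFlank, n_codons = unname(rowSums(cnt)),
             stringsAsFactors = FALSE)
}

#' Per-gene CodonUsageTable list
#'
#' @param cds A `DNAStringSet` of coding sequences named by gene id.
#' @return Named list of [CodonUsageTable-class] objects.
#' @export
usageTables <- function(cds) {
  cnt <- codonCountsMatrix(cds)
  w <- Biostrings::width(cds)
  term <- as.character(Biostrings::subseq(cds, start = w - 2L, end = w))
  nCodon <- w %/% 3L - as.integer(term %in% .stopCodons())
  skippedN <- nCodon - rowSums(cnt)
  out <- lapply(seq_len(nrow(cnt)), function(i) {
    .usageFromCounts(cnt[i, ], source = rownames(cnt)[i],
                     nSkipped = skippedN[i])
  })
  names(out) <- rownames(cnt)
  out
}

#' Codon usage of gene sets (concatenated members)
#'
#' @param sets Named list of gene-id vectors.
#' @param tables Named list of per-gene [CodonUsageTable-class] objects (as
#'   from [usageTables()]).
#' @param drop Drop set members absent from `tables` (with a warning) rather
#'   than erroring.
#' @return Named list of [CodonUsageTable-class] objects, one per set.
#' @export
setUsageTables <- function(sets, tables, drop = FALSE) {
  lapply(stats::setNames(names(sets), names(sets)), function(nm) {
    ids <- sets[[nm]]
    if (drop) {
      absent <- setdiff(ids, names(tables))
      if (length(absent))
        warning(nm, ": dropping ", length(absent), " unknown gene ids")
      ids <- intersect(ids, names(tables))
    }
    concatUsage(tables, geneIds = ids, source = nm)
  })
}

#' RSCU matrix over gene sets
#'
#' @param setTables Named list of set-level [CodonUsageTable-class] objects.
#' @return Numeric matrix, sets x 59 synonymous codons (`NA` marks undefined
#'   entries).
#' @export
rscuMatrix <- function(setTables) {
  m <- t(vapply(setTables, rscu, numeric(length(synonymousCodons()))))
  rownames(m) <- names(setTables)
  m
}
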