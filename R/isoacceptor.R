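# The translational-selection test: partition amino acids by tRNA
# isoacceptor repertoire and compare mono- vs multi-isoacceptor GC3 across
# gene sets. High mono-multi correlation is inconsistent with tRNA-pool
# driven codon usage, because mono-isoacceptor usage cannot co-adapt with a
# varying tRNA pool.

#' Read a tRNA repertoire table
#'
#' gtRNAdb-style TSV with columns `anticodon`, `aa` (one-letter code) and
#' `gene_count`. Wobble rules are deliberately not modelled: an anticodon
#' counts toward the amino acid in its `aa` column only, since the test needs
#' only the number of distinct isoacceptors per amino acid.
#'
#' @param path TSV file; defaults to the bundled human-like repertoire.
#' @return data.frame with the three columns above.
#' @export
readTRNARepertoire <- function(path = system.file("extdata",
                                                  "trna_repertoire_human.tsv",
                                                  package = "gbgcCodon")) {
  rep <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  stopifnot(all(c("anticodon", "aa", "gene_count") %in% names(rep)))
  if (anyDuplicated(rep$anticodon)) stop("duplicate anticodons in repertoire")
  rep
}

#' Partition amino acids by isoacceptor count
#'
#' Amino acids decoded by exactly one tRNA isoacceptor (one distinct
#' anticodon with `gene_count > 0`) go to `mono`, those with two or more to
#' `multi`. The single-codon amino acids Met and Trp are always excluded.
#' A degenerate amino acid with no isoacceptor at all means the repertoire is
#' incomplete and raises an error.
#'
#' @param repertoire data.frame as from [readTRNARepertoire()].
#' @return An [IsoacceptorPartition-class].
#' @export
buildPartition <- function(repertoire) {
  rep <- repertoire[repertoire$gene_count > 0, , drop = FALSE]
  tallies <- tapply(rep$anticodon, rep$aa, function(a) length(unique(a)))
  degen <- degenerateAminoAcids()
  missing <- setdiff(degen, names(tallies))
  if (length(missing) || any(tallies[degen] == 0, na.rm = TRUE))
    stop("repertoire incomplete: no isoacceptor for ",
         paste(missing, collapse = ", "))
  new("IsoacceptorPartition",
      mono = sort(degen[tallies[degen] == 1L]),
      multi = sort(degen[tallies[degen] >= 2L]),
      excluded = c("M", "W"))
}

#' The frozen human isoacceptor partition
#'
#' Mono-isoacceptor amino acids in the human tRNA gene repertoire: Phe, Asp,
#' His and Cys; the 14 other degenerate amino acids are multi-isoacceptor.
#' Shipped as a constant so the test is reproducible without external tRNA
#' census access.
#'
#' @return An [IsoacceptorPartition-class].
#' @export
humanIsoacceptorPartition <- function() {
  degen <- degenerateAminoAcids()
  mono <- c("C", "D", "F", "H")
  new("IsoacceptorPartition", mono = mono,
      multi = sort(setdiff(degen, mono)), excluded = c("M", "W"))
}

#' @describeIn IsoacceptorPartition-class Mono-isoacceptor amino acids.
#' @param x An IsoacceptorPartition.
#' @export
setMethod("monoAminoAcids", "IsoacceptorPartition", function(x) x@mono)

#' @describeIn IsoacceptorPartition-class Multi-isoacceptor amino acids.
#' @export
setMethod("multiAminoAcids", "IsoacceptorPartition", function(x) x@multi)

setMethod("show", "IsoacceptorPartition", function(object) {
  cat("IsoacceptorPartition: mono {", paste(object@mono, collapse = ", "),
      "}, multi {", paste(object@multi, collapse = ", "), "}\n")
})

#' Mono- versus multi-isoacceptor GC3 across gene sets
#'
#' For every gene set, GC3 is computed separately over codons of
#' mono-isoacceptor and multi-isoacceptor amino acids; the two are then
#' related by ordinary least squares (mono on multi) and the squared Pearson
#' correlation reported. Under translational selection the mono side cannot
#' track a varying tRNA pool, so a high R-squared across sets argues that a
#' single non-translational process (GC content) drives both. Sets with an
#' undefined value on either side are dropped with a warning; zero variance
#' on either side yields the degenerate marker `NA` for `r_squared` and
#' `slope`.
#'
#' @param setTables Named list of set-level [CodonUsageTable-class] objects.
#' @param partition An [IsoacceptorPartition-class].
#' @return List: `sets` (data.frame `set`, `gc3_mono`, `gc3_multi`),
#'   `r_squared`, `slope`, `n_sets_used`, `n_sets_dropped`.
#' @export
selectionTest <- function(setTables, partition = humanIsoacceptorPartition()) {
  pg <- t(vapply(setTables, partitionedGC3, numeric(2), partition = partition))
  d <- data.frame(set = names(setTables), gc3_mono = pg[, "gc3_mono"],
                  gc3_multi = pg[, "gc3_multi"], stringsAsFactors = FALSE,
                  row.names = NULL)
  ok <- stats::complete.cases(d[, c("gc3_mono", "gc3_multi")])
  if (any(!ok))
    warning("dropping ", sum(!ok), " set(s) with undefined partitioned GC3")
  du <- d[ok, , drop = FALSE]
  if (nrow(du) < 3L) stop("need at least 3 gene sets with defined values")
  if (stats::sd(du$gc3_mono) == 0 || stats::sd(du$gc3_multi) == 0) {
    r2 <- NA_real_; slope <- NA_real_
  } else {
    fit <- stats::lm(gc3_mono ~ gc3_multi, data = du)
    r2 <- stats::cor(du$gc3_mono, du$gc3_multi)^2
    slope <- unname(stats::coef(fit)[2L])
  }
  list(sets = d, r_squared = r2, slope = slope,
       n_sets_used = nrow(du), n_sets_dropped = sum(!ok))
}
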