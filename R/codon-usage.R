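#' Count sense codons of a coding sequence
#'
#' Walks the CDS in frame (length must be a multiple of 3). A terminal stop
#' codon is allowed and excluded from the counts; an internal stop codon is a
#' malformed CDS and raises an error naming the offending codon position.
#' Codons containing N are skipped and tallied separately, so masked
#' assemblies degrade gracefully.
#'
#' @param cds A single coding sequence: character scalar, `DNAString`, or a
#'   length-one `DNAStringSet`. Alphabet `{A,C,G,T,N}`.
#' @param source Optional identifier stored in the result.
#' @return A [CodonUsageTable-class].
#' @export
#' @examples
#' tab <- codonCounts("ATGTGGTTTTAA")
#' totalCodons(tab)  # 3: ATG, TGG, TTT; the terminal TAA is excluded
codonCounts <- function(cds, source = NA_character_) {
  if (is(cds, "DNAStringSet")) {
    stopifnot(length(cds) == 1L)
    cds <- as.character(cds[[1L]])
  } else if (is(cds, "DNAString")) {
    cds <- as.character(cds)
  }
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("CDS length (", n, ") is not divisible by 3")
  if (grepl("[^ACGTN]", cds))
    stop("CDS contains characters outside {A,C,G,T,N}")
  nc <- n %/% 3L
  if (nc == 0L) {
    return(new("CodonUsageTable",
               counts = stats::setNames(integer(61L), senseCodons()),
               nSkipped = 0L, source = source))
  }
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  if (codons[nc] %in% .stopCodons()) codons <- codons[-nc]
  internal <- which(codons %in% .stopCodons())
  if (length(internal))
    stop("internal stop codon ", codons[internal[1L]],
         " at codon position ", internal[1L])
  hasN <- grepl("N", codons, fixed = TRUE)
  nSkip <- sum(hasN)
  codons <- codons[!hasN]
  cnt <- table(factor(codons, levels = senseCodons()))
  new("CodonUsageTable",
      counts = stats::setNames(as.integer(cnt), senseCodons()),
      nSkipped = as.integer(nSkip), source = as.character(source))
}

#' Codon count matrix for many coding sequences
#'
#' Fast vectorised counterpart of [codonCounts()] built on
#' `Biostrings::oligonucleotideFrequency(..., step = 3)`. Terminal stop
#' codons are excluded; any remaining (internal) stop codon raises an error
#' naming the sequence.
#'
#' @param cdsSet A `DNAStringSet` of in-frame coding sequences.
#' @return Integer matrix, sequences x 61 sense codons.
#' @export
codonCountsMatrix <- function(cdsSet) {
  stopifnot(is(cdsSet, "DNAStringSet"))
  w <- Biostrings::width(cdsSet)
  if (any(w %% 3L != 0L))
    stop("CDS length not divisible by 3 for: ",
         paste(head(names(cdsSet)[w %% 3L != 0L], 5L), collapse = ", "))
  m <- Biostrings::oligonucleotideFrequency(cdsSet, width = 3L, step = 3L)
  term <- as.character(Biostrings::subseq(cdsSet, start = w - 2L, end = w))
  isTermStop <- term %in% .stopCodons()
  for (s in .stopCodons()) {
    m[, s] <- m[, s] - as.integer(isTermStop & term == s)
  }
  bad <- rowSums(m[, .stopCodons(), drop = FALSE]) > 0L
  if (any(bad))
    stop("internal stop codon in: ",
         paste(head(names(cdsSet)[bad], 5L), collapse = ", "))
  out <- m[, senseCodons(), drop = FALSE]
  storage.mode(out) <- "integer"
  rownames(out) <- names(cdsSet)
  out
}

# build a CodonUsageTable from a named count vector (internal)
.usageFromCounts <- function(cnt, source = NA_character_, nSkipped = 0L) {
  full <- stats::setNames(integer(61L), senseCodons())
  full[names(cnt)] <- as.integer(cnt)
  new("CodonUsageTable", counts = full, nSkipped = as.integer(nSkipped),
      source = as.character(source))
}

#' @describeIn CodonUsageTable-class Codon counts (named integer vector).
#' @param object A CodonUsageTable.
#' @export
setMethod("counts", "CodonUsageTable", function(object) object@counts)

#' @describeIn CodonUsageTable-class Total counted codons.
#' @param x A CodonUsageTable.
#' @export
setMethod("totalCodons", "CodonUsageTable", function(x) sum(x@counts))

#' @describeIn CodonUsageTable-class Codons skipped for containing N.
#' @export
setMethod("skipped", "CodonUsageTable", function(x) x@nSkipped)

setMethod("show", "CodonUsageTable", function(object) {
  cat("CodonUsageTable (", object@source, "): ",
      sum(object@counts), " codons, ", object@nSkipped, " skipped\n", sep = "")
})

#' Relative synonymous codon usage
#'
#' For amino acid \eqn{x} with \eqn{n_x} synonymous codons and total count
#' \eqn{A_x = \sum_y C_{xy}}, the RSCU of codon \eqn{y} is
#' \eqn{C_{xy} / (A_x / n_x)}: the observed count normalised by its expected
#' count if all synonymous codons were used equally. Met and Trp (single
#' codon) are excluded; an amino acid with \eqn{A_x = 0} yields `NA` for its
#' codons rather than 0/0.
#'
#' @param table A [CodonUsageTable-class].
#' @return Named numeric vector over the 59 synonymous codons; `NA` marks
#'   undefined entries.
#' @export
#' @examples
#' tab <- codonCounts("CAACAGCAGCAG")  # Gln: CAA x1, CAG x3
#' rscu(tab)[c("CAG", "CAA")]  # 1.5, 0.5
rscu <- function(table) {
  stopifnot(is(table, "CodonUsageTable"))
  cnt <- table@counts
  aa <- codonAminoAcids()
  out <- stats::setNames(rep(NA_real_, length(synonymousCodons())),
                         synonymousCodons())
  for (x in degenerateAminoAcids()) {
    cod <- .codonsOf(x)
    Ax <- sum(cnt[cod])
    if (Ax > 0L) out[cod] <- cnt[cod] / (Ax / length(cod))
  }
  out
}

#' GC content at third codon positions
#'
#' Fraction of counted codons ending in G or C. The default codon universe is
#' the 59 synonymous codons (Met/Trp excluded), the same universe as
#' [rscu()]; set `universe = "sense61"` to count every sense codon.
#'
#' @param table A [CodonUsageTable-class].
#' @param universe `"syn59"` (default) or `"sense61"`.
#' @return Fraction in \[0,1\], or `NA` if no countable codons.
#' @export
gc3 <- function(table, universe = c("syn59", "sense61")) {
  stopifnot(is(table, "CodonUsageTable"))
  universe <- match.arg(universe)
  cod <- if (universe == "syn59") synonymousCodons() else senseCodons()
  .gc3FromCounts(table@counts, cod)
}

.gc3FromCounts <- function(cnt, codons) {
  tot <- sum(cnt[codons])
  if (tot == 0L) return(NA_real_)
  sum(cnt[codons[.isGCEnding(codons)]]) / tot
}

#' GC fraction of a sequence or collection of intervals
#'
#' (#G + #C) / (#A + #C + #G + #T); N (and any other ambiguity code) is
#' excluded from the denominator. For a `DNAStringSet` the fraction is pooled
#' over all elements, so passing the extracted pieces of an interval union
#' gives the GC of the union.
#'
#' @param x Character vector, `DNAString` or `DNAStringSet`.
#' @return Fraction in \[0,1\], or `NA` if no unambiguous base.
#' @export
#' @examples
#' gcFraction("ACGTN")  # 0.5
gcFraction <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (is(x, "DNAString")) x <- Biostrings::DNAStringSet(x)
  stopifnot(is(x, "DNAStringSet"))
  if (length(x) == 0L) return(NA_real_)
  af <- colSums(Biostrings::alphabetFrequency(x)[, c("A", "C", "G", "T"),
                                                 drop = FALSE])
  tot <- sum(af)
  if (tot == 0L) return(NA_real_)
  unname((af["G"] + af["C"]) / tot)
}

#' GC3 split by tRNA isoacceptor class
#'
#' Computes GC3 separately over codons of mono-isoacceptor amino acids and of
#' multi-isoacceptor amino acids, as defined by an
#' [IsoacceptorPartition-class]. An empty partition side (or zero counts on a
#' side) yields `NA` for that side.
#'
#' @param table A [CodonUsageTable-class].
#' @param partition An [IsoacceptorPartition-class].
#' @return Named numeric: `gc3_mono`, `gc3_multi`.
#' @export
partitionedGC3 <- function(table, partition) {
  stopifnot(is(table, "CodonUsageTable"), is(partition, "IsoacceptorPartition"))
  aa <- codonAminoAcids()
  monoCod <- senseCodons()[aa %in% partition@mono]
  multiCod <- senseCodons()[aa %in% partition@multi]
  c(gc3_mono = if (length(monoCod)) .gc3FromCounts(table@counts, monoCod) else NA_real_,
    gc3_multi = if (length(multiCod)) .gc3FromCounts(table@counts, multiCod) else NA_real_)
}

#' Total codon usage of a gene set
#'
#' Elementwise sum of member tables: the codon usage of the concatenated
#' coding sequences of the set.
#'
#' @param tables Either a list of [CodonUsageTable-class] objects (summed as
#'   is) or a named list from which `geneIds` selects members.
#' @param geneIds Optional gene ids to select from `tables`; unknown ids are
#'   an error listing the missing ones.
#' @param source Identifier for the resulting table.
#' @return A [CodonUsageTable-class].
#' @export
concatUsage <- function(tables, geneIds = NULL, source = NA_character_) {
  if (!is.null(geneIds)) {
    missing <- setdiff(geneIds, names(tables))
    if (length(missing))
      stop("unknown gene ids: ", paste(missing, collapse = ", "))
    tables <- tables[geneIds]
  }
  stopifnot(length(tables) >= 1L)
  cnt <- Reduce(`+`, lapply(tables, function(t) t@counts))
  nSkip <- sum(vapply(tables, skipped, integer(1)))
  new("CodonUsageTable", counts = cnt, nSkipped = nSkip,
      source = as.character(source))
}
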