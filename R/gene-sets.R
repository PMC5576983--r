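# GO-like gene-set handling: GMT I/O, size/identifier filters and the
# proliferation / differentiation / other keyword classification.

#' Read gene sets from a GMT file
#'
#' @param path GMT file (`name<TAB>description<TAB>gene1<TAB>...`).
#' @return Named list of gene-id character vectors; descriptions kept in the
#'   `"description"` attribute.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[`, character(1), 2L), names(sets))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of gene-id vectors.
#' @param path Output file.
#' @param descriptions Optional per-set description column (defaults to the
#'   set name).
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "description")
  if (is.null(descriptions)) descriptions <- stats::setNames(names(sets),
                                                             names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Filter a gene-set collection by size and excluded identifiers
#'
#' Sets with fewer than `minSize` members are removed ("at least" is read
#' inclusively: a set of exactly `minSize` genes is kept). Identifiers in
#' `excludedIds` are removed regardless of size — the canonical example being
#' an over-general annotation term such as protein binding (GO:0005515).
#' The operation is idempotent.
#'
#' @param sets Named list of gene-id vectors.
#' @param minSize Minimum set size (default 40).
#' @param excludedIds Set names removed unconditionally.
#' @return Filtered named list.
#' @export
filterSets <- function(sets, minSize = 40L, excludedIds = "GO:0005515") {
  keep <- lengths(sets) >= minSize & !(names(sets) %in% excludedIds)
  out <- sets[keep]
  desc <- attr(sets, "description")
  if (!is.null(desc)) attr(out, "description") <- desc[names(out)]
  out
}

#' Default keyword lists for the proliferation/differentiation classification
#'
#' Case-insensitive substrings matched against set names. The proliferation
#' list carries a negation guard: names matching `negation` are excluded from
#' 'proliferation' even when a keyword matches (so "negative regulation of
#' proliferation" is not 'proliferation', while the explicit keyword
#' "negative regulation of cell cycle" still is).
#'
#' @return List with components `proliferation`, `differentiation`,
#'   `negation` (a regular expression).
#' @export
categoryKeywords <- function() {
  list(
    proliferation = c("chromatin modification", "chromatin remodeling",
                      "mitotic cell cycle", "mRNA metabolic process",
                      "negative regulation of cell cycle",
                      "nucleosome assembly", "translation", "proliferation"),
    differentiation = c("development", "differentiation", "cell adhesion",
                        "pattern specification",
                        "multicellular organism growth", "angiogenesis"),
    negation = "negative regulation of[a-z ]*(proliferation|differentiation)"
  )
}

#' Assign genes to proliferation / differentiation / other
#'
#' A set belongs to a category if its name contains any of the category's
#' keywords (case-insensitive substring), subject to the negation guard (see
#' [categoryKeywords()]). A gene in at least one 'proliferation' set and at
#' least one 'differentiation' set is `discarded`; genes matching exactly one
#' category get that label; the rest are `other`. Assignment is independent
#' of set iteration order.
#'
#' @param sets Named list of gene-id vectors (typically already filtered).
#' @param universe Gene ids to classify (defaults to the union of members).
#' @param keywords As from [categoryKeywords()].
#' @return Factor over `universe` with levels `proliferation`,
#'   `differentiation`, `other`, `discarded`; set-level categories in
#'   attribute `"set_category"`.
#' @export
assignCategories <- function(sets, universe = NULL,
                             keywords = categoryKeywords()) {
  stopifnot(length(keywords$proliferation) > 0,
            length(keywords$differentiation) > 0)
  nm <- tolower(names(sets))
  hit <- function(kw) Reduce(`|`, lapply(tolower(kw), grepl, x = nm,
                                         fixed = TRUE))
  isProlif <- hit(keywords$proliferation)
  isDiff <- hit(keywords$differentiation)
  if (!is.null(keywords$negation)) {
    neg <- grepl(keywords$negation, nm, ignore.case = TRUE)
    isProlif <- isProlif & !neg
    isDiff <- isDiff & !neg
  }
  prolifGenes <- unique(unlist(sets[isProlif], use.names = FALSE))
  diffGenes <- unique(unlist(sets[isDiff], use.names = FALSE))
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  lab <- rep("other", length(universe))
  lab[universe %in% prolifGenes] <- "proliferation"
  lab[universe %in% diffGenes] <- "differentiation"
  lab[universe %in% intersect(prolifGenes, diffGenes)] <- "discarded"
  out <- factor(lab, levels = c("proliferation", "differentiation",
                                "other", "discarded"))
  names(out) <- universe
  setCat <- rep("other", length(sets))
  setCat[isProlif] <- "proliferation"
  setCat[isDiff] <- "differentiation"
  setCat[isProlif & isDiff] <- "both"
  attr(out, "set_category") <- stats::setNames(setCat, names(sets))
  out
}

#' Filter genes by transcription-unit length
#'
#' Retains genes whose TSS-to-polyadenylation span is at least `minLen` bp
#' (inclusive bound), the usual guard for measuring intragenic crossover
#' rates at genetic-map resolution.
#'
#' @param models A [GeneModelSet-class] or a data.frame with a `length`
#'   column and `gene_id` (as from [geneTable()]).
#' @param minLen Minimum length in bp (default 5000).
#' @return Character vector of retained gene ids.
#' @export
lengthFilter <- function(models, minLen = 5000) {
  gt <- if (is(models, "GeneModelSet")) geneTable(models) else models
  gt$gene_id[gt$length >= minLen]
}
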