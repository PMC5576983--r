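# Standard genetic code bookkeeping shared by all codon-level operations.
# Everything is derived once from Biostrings::GENETIC_CODE at load time.

.code_env <- new.env(parent = emptyenv())

.initCode <- function() {
  gc <- Biostrings::GENETIC_CODE
  sense <- sort(names(gc)[gc != "*"])          # 61 sense codons
  aa <- unname(gc[sense])
  names(aa) <- sense
  stops <- sort(names(gc)[gc == "*"])          # TAA TAG TGA
  byAA <- split(sense, aa[sense])
  degeneracy <- vapply(byAA, length, integer(1))
  degenAA <- sort(names(degeneracy)[degeneracy >= 2])   # 18 amino acids
  syn59 <- sense[aa[sense] %in% degenAA]                # Met/Trp excluded
  gcEnding <- substr(sense, 3L, 3L) %in% c("G", "C")
  names(gcEnding) <- sense
  assign("SENSE", sense, envir = .code_env)
  assign("AA", aa, envir = .code_env)
  assign("STOPS", stops, envir = .code_env)
  assign("BY_AA", byAA, envir = .code_env)
  assign("DEGENERACY", degeneracy, envir = .code_env)
  assign("DEGEN_AA", degenAA, envir = .code_env)
  assign("SYN59", syn59, envir = .code_env)
  assign("GC_ENDING", gcEnding, envir = .code_env)
  invisible(NULL)
}

.code <- function(what) {
  if (!exists("SENSE", envir = .code_env)) .initCode()
  get(what, envir = .code_env)
}

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 sense codons, alphabetically sorted.
#' @export
#' @examples
#' length(senseCodons())
senseCodons <- function() .code("SENSE")

#' Amino acid encoded by each sense codon
#'
#' @return Named character vector (one-letter amino-acid codes) over the 61
#'   sense codons.
#' @export
codonAminoAcids <- function() .code("AA")

#' Synonymous codon universe used for RSCU and default GC3
#'
#' The 59 sense codons of the 18 degenerate amino acids; the single-codon
#' amino acids Met (ATG) and Trp (TGG) are excluded, as are stop codons.
#'
#' @return Character vector of 59 codons.
#' @export
synonymousCodons <- function() .code("SYN59")

#' Degenerate amino acids
#'
#' @return The 18 amino acids (one-letter code) encoded by two or more
#'   synonymous codons.
#' @export
degenerateAminoAcids <- function() .code("DEGEN_AA")

.codonsOf <- function(aa) .code("BY_AA")[[aa]]
.degeneracyOf <- function() .code("DEGENERACY")
.isGCEnding <- function(codons) .code("GC_ENDING")[codons]
.stopCodons <- function() .code("STOPS")
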