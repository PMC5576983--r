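# Sequence-synthesis stage: equilibrium GC from the local long-term
# (suppression-affected) crossover rate, codon choice per regime, and genome
# assembly.
#
# Equilibrium GC of a gene: logistic(gbgc_slope * log2(rate / base_rate)),
# i.e. centred at 0.5 for a gene recombining at the genome mean, rising with
# local crossover rate (the gBGC prediction). Independent Gaussian noise
# (sd = noise_sd_gc) is added separately to the CDS-third-position and the
# intron compartment. Flanking/intergenic sequence uses the regional
# (unsuppressed) landscape rate: suppression acts on the transcription unit
# only.

.eqGC <- function(rate, refRate, slope, longtermNoise = 0) {
  stats::plogis(slope * (log2(pmax(rate, 1e-6) / refRate) + longtermNoise))
}

# reference rate of the rate -> equilibrium-GC logistic: the median
# suppressed intragenic rate implied by the config (lognormal landscape
# median times the mean suppression factor), so the per-gene equilibrium GC
# distribution is centred near 0.5
.gcRefRate <- function(config) {
  config$base_rate * exp(-config$landscape_log_sd^2 / 2) *
    (1 - config$suppression_strength / 2)
}

.revcompStr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# vectorised codon sampling for all genes at once. gcds: per-gene CDS GC
# target; regulon/prefTable only used under regime "trna_coadapted".
.sampleCodons <- function(nInternal, gcds, regime, prefStrength,
                          regulon = NULL, prefTable = NULL) {
  nG <- length(nInternal)
  geneIdx <- rep.int(seq_len(nG), nInternal)
  N <- length(geneIdx)
  aaPool <- c(degenerateAminoAcids(), "M", "W")
  aa <- sample(aaPool, N, replace = TRUE)
  gcflag <- stats::runif(N) < gcds[geneIdx]
  prefFlag <- if (regime == "trna_coadapted")
    stats::runif(N) < prefStrength else rep(FALSE, N)
  multiAA <- multiAminoAcids(humanIsoacceptorPartition())
  codon <- character(N)
  for (a in aaPool) {
    idx <- which(aa == a)
    if (!length(idx)) next
    cods <- .codonsOf(a)
    if (length(cods) == 1L) { codon[idx] <- cods; next }
    gcc <- cods[.isGCEnding(cods)]
    atc <- cods[!.isGCEnding(cods)]
    iGC <- idx[gcflag[idx]]
    iAT <- idx[!gcflag[idx]]
    codon[iGC] <- gcc[sample.int(length(gcc), length(iGC), replace = TRUE)]
    codon[iAT] <- atc[sample.int(length(atc), length(iAT), replace = TRUE)]
    if (regime == "trna_coadapted" && a %in% multiAA) {
      iPref <- idx[prefFlag[idx]]
      if (length(iPref))
        codon[iPref] <- prefTable[, a][regulon[geneIdx[iPref]]]
    }
  }
  split(codon, factor(geneIdx, levels = seq_len(nG)))
}

#' Synthesize genome and coding sequences
#'
#' Draws each gene's equilibrium GC from its suppressed local crossover rate
#' (see the regime description in [syntheticConfig()]), samples third codon
#' positions, introns and transcribed UTR with that GC, samples
#' flanking/intergenic sequence with the regional (unsuppressed) equilibrium
#' GC, and assembles the chromosomes. Under `regime = "gbgc"` codon choice is
#' governed only by the GC target; under `regime = "trna_coadapted"`
#' multi-isoacceptor codons follow per-regulon preferred-codon tables while
#' mono-isoacceptor codons stay GC-driven.
#'
#' @param config A `SyntheticConfig`.
#' @param models [GeneModelSet-class] from [placeGenesAndSuppress()].
#' @param map The base landscape [GeneticMap-class] (pre-suppression), used
#'   for regional GC of non-genic sequence.
#' @param truth Truth table from [placeGenesAndSuppress()].
#' @param assembleGenome Build the full genome (set `FALSE` to emit coding
#'   sequences only; the CDS output is byte-identical either way).
#' @return List: `genome` (`DNAStringSet` or `NULL`), `cds` (`DNAStringSet`,
#'   transcript orientation), `truth` (augmented with `eq_gc`,
#'   `gc_cds_target`, `gc_intron_target`).
#' @export
synthesizeSequences <- function(config, models, map, truth,
                                assembleGenome = TRUE) {
  validateSyntheticConfig(config)
  set.seed(.childSeed(config$seed, 3L))
  nG <- nrow(truth)
  structs <- attr(truth, "structures")

  refRate <- .gcRefRate(config)
  g0 <- .eqGC(truth$longterm_rate, refRate, config$gbgc_slope,
              stats::rnorm(nG, 0, config$gc_longterm_sd))
  gcds <- .clamp(g0 + stats::rnorm(nG, 0, config$noise_sd_gc), 0.005, 0.995)
  gintron <- .clamp(g0 + stats::rnorm(nG, 0, config$noise_sd_gc),
                    0.005, 0.995)

  prefTable <- NULL
  if (config$regime == "trna_coadapted") {
    multiAA <- multiAminoAcids(humanIsoacceptorPartition())
    prefTable <- matrix("", config$n_regulons, length(multiAA),
                        dimnames = list(NULL, multiAA))
    for (a in multiAA) {
      cods <- .codonsOf(a)
      prefTable[, a] <- cods[sample.int(length(cods), config$n_regulons,
                                        replace = TRUE)]
    }
  }

  cdsLens <- as.integer(vapply(structs, `[[`, numeric(1), "cds_len"))
  nCod <- cdsLens %/% 3L
  internal <- .sampleCodons(nCod - 2L, gcds, config$regime,
                            config$pref_strength, truth$regulon, prefTable)
  stopCod <- .stopCodons()[sample.int(3L, nG, replace = TRUE)]
  cdsStr <- vapply(seq_len(nG), function(i) {
    paste0("ATG", paste(internal[[i]], collapse = ""), stopCod[i])
  }, character(1))

  intronStr <- vector("list", nG)
  utr3Str <- character(nG)
  for (i in seq_len(nG)) {
    st <- structs[[i]]
    iw <- if (nrow(st$introns)) st$introns[, 2L] - st$introns[, 1L] else
      integer(0)
    intronStr[[i]] <- vapply(iw, .randomDNA, character(1), gc = gintron[i])
    utr3Str[i] <- .randomDNA(st$utr3[2L] - st$utr3[1L], gintron[i])
  }

  # transcript-orientation gene body: E1 I1 E2 I2 ... Ek UTR3
  geneBody <- vapply(seq_len(nG), function(i) {
    st <- structs[[i]]
    ew <- st$cds[, 2L] - st$cds[, 1L]
    eEnd <- cumsum(ew)
    eStart <- eEnd - ew + 1L
    pieces <- character(2L * nrow(st$cds))
    pieces[seq(1L, by = 2L, length.out = nrow(st$cds))] <-
      substring(cdsStr[i], eStart, eEnd)
    if (nrow(st$introns))
      pieces[seq(2L, by = 2L, length.out = nrow(st$introns))] <-
        intronStr[[i]]
    paste0(paste(pieces, collapse = ""), utr3Str[i])
  }, character(1))

  truth$eq_gc <- g0
  truth$gc_cds_target <- gcds
  truth$gc_intron_target <- gintron

  genome <- NULL
  if (assembleGenome) {
    chromStrs <- character(config$n_chromosomes)
    names(chromStrs) <- .chromNames(config)
    L <- config$chrom_length
    for (ch in .chromNames(config)) {
      gi <- which(truth$chrom == ch)
      gi <- gi[order(truth$start[gi])]
      bounds <- cbind(c(0, truth$end[gi]), c(truth$start[gi], L))
      gapLen <- bounds[, 2L] - bounds[, 1L]
      gapGC <- rep(0.5, nrow(bounds))
      nz <- gapLen > 0
      if (any(nz)) {
        gr <- intervalRate(map, ch, bounds[nz, 1L], bounds[nz, 2L])$rate
        gapGC[nz] <- .clamp(
          .eqGC(gr, refRate, config$gbgc_slope,
                stats::rnorm(sum(nz), 0, config$gc_longterm_sd)) +
            stats::rnorm(sum(nz), 0, config$noise_sd_gc),
          0.005, 0.995)
      }
      gapStr <- vapply(seq_along(gapLen), function(k) {
        .randomDNA(gapLen[k], gapGC[k])
      }, character(1))
      gStr <- vapply(seq_along(gi), function(k) {
        i <- gi[k]
        if (truth$strand[i] == "+") geneBody[i] else .revcompStr(geneBody[i])
      }, character(1))
      pieces <- character(length(gapStr) + length(gStr))
      pieces[seq(1L, by = 2L, length.out = length(gapStr))] <- gapStr
      if (length(gStr))
        pieces[seq(2L, by = 2L, length.out = length(gStr))] <- gStr
      chromStrs[ch] <- paste(pieces, collapse = "")
      stopifnot(nchar(chromStrs[ch]) == L)
    }
    genome <- Biostrings::DNAStringSet(chromStrs)
  }

  cds <- Biostrings::DNAStringSet(stats::setNames(cdsStr, truth$gene_id))
  list(genome = genome, cds = cds, truth = truth)
}
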