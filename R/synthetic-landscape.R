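# Landscape and gene-placement stages of the synthetic generator.

# Gaussian-smoothed white noise on a per-chromosome grid, exponentiated to a
# positive rate field and normalised so the genome-wide mean rate equals
# base_rate exactly. If the smoothing scale reaches the chromosome length the
# field degenerates to a constant (the whole chromosome is one isochore).
.landscapeLogField <- function(ngrid, sigmaGrid) {
  if (sigmaGrid >= ngrid) return(numeric(ngrid))
  noise <- stats::rnorm(ngrid)
  half <- min(ceiling(4 * sigmaGrid), (ngrid - 1L) %/% 2L)
  if (half < 1L) return(noise)
  w <- stats::dnorm(seq(-half, half), sd = sigmaGrid)
  w <- w / sum(w)
  sm <- as.numeric(stats::filter(noise, w, method = "convolution",
                                 sides = 2, circular = TRUE))
  # smoothing of unit white noise has marginal variance sum(w^2) exactly
  # (circular convolution), so normalise analytically, not empirically
  sm / sqrt(sum(w^2))
}

#' Generate the recombination landscape
#'
#' Builds one smooth positive crossover-rate field per chromosome (log-scale
#' Gaussian-smoothed white noise with correlation length about
#' `isochore_scale`), normalised so that the genome-wide mean rate equals
#' `base_rate`, and integrates it into a piecewise-linear genetic map with a
#' marker every `map_resolution` bp.
#'
#' @param config A `SyntheticConfig` (see [syntheticConfig()]).
#' @return A [GeneticMap-class] covering all chromosomes.
#' @export
generateRecombinationLandscape <- function(config) {
  validateSyntheticConfig(config)
  set.seed(.childSeed(config$seed, 1L))
  res <- config$map_resolution
  ngrid <- as.integer(ceiling(config$chrom_length / res))
  sigmaGrid <- config$isochore_scale / res
  logf <- lapply(seq_len(config$n_chromosomes), function(i) {
    config$landscape_log_sd * .landscapeLogField(ngrid, sigmaGrid)
  })
  rates <- lapply(logf, exp)
  norm <- config$base_rate / mean(unlist(rates))
  markers <- do.call(rbind, lapply(seq_len(config$n_chromosomes), function(i) {
    r <- rates[[i]] * norm
    pos <- c(seq(0, by = res, length.out = ngrid), config$chrom_length)
    segw <- diff(pos)
    data.frame(chrom = .chromNames(config)[i], pos = pos,
               cum_cM = c(0, cumsum(r * segw / 1e6)))
  }))
  geneticMap(markers,
             seqlengths = stats::setNames(rep(config$chrom_length,
                                              config$n_chromosomes),
                                          .chromNames(config)))
}

# split `total` into n parts, each >= minPart, by a random composition
.randomComposition <- function(total, n, minPart) {
  free <- total - n * minPart
  stopifnot(free >= 0)
  if (n == 1L) return(total)
  cuts <- sort(stats::runif(n - 1L))
  minPart + round(diff(c(0, cuts, 1)) * free)
}

# internal: lay out the exon/intron structure of one gene in transcript
# coordinates (0-based offsets from the TSS). CDS length includes the stop
# codon; the 3'UTR absorbs whatever the CDS and introns leave over, so the
# layout always tiles the full transcription unit.
.geneStructure <- function(geneLen) {
  if (geneLen < 600L)
    stop("gene length ", geneLen, " too short for a model (need >= 600 bp)")
  cdsLen <- max(300L, 3L * ((geneLen * 0.25) %/% 3L))
  if (cdsLen > geneLen - 250L) cdsLen <- 3L * ((geneLen - 250L) %/% 3L)
  intronTotal <- geneLen - cdsLen - 200L
  maxIntrons <- min(6L, intronTotal %/% 300L, (cdsLen %/% 90L) - 1L)
  nIntrons <- if (maxIntrons >= 1L) sample.int(maxIntrons, 1L) else 0L
  if (nIntrons == 0L) intronTotal <- 0L
  utr3 <- geneLen - cdsLen - intronTotal
  nExons <- nIntrons + 1L
  exonLens <- .randomComposition(cdsLen, nExons, 60L)
  exonLens[nExons] <- cdsLen - sum(exonLens[-nExons])
  intronLens <- if (nIntrons > 0L)
    .randomComposition(intronTotal, nIntrons, 200L) else integer(0)
  if (nIntrons > 0L)
    intronLens[nIntrons] <- intronTotal - sum(intronLens[-nIntrons])
  # transcript layout: E1 I1 E2 I2 ... Ek UTR3
  cdsRel <- matrix(0L, nExons, 2L)
  intronRel <- matrix(0L, nIntrons, 2L)
  p <- 0L
  for (i in seq_len(nExons)) {
    cdsRel[i, ] <- c(p, p + exonLens[i])
    p <- p + exonLens[i]
    if (i <= nIntrons) {
      intronRel[i, ] <- c(p, p + intronLens[i])
      p <- p + intronLens[i]
    }
  }
  list(cds = cdsRel, introns = intronRel, cds_len = cdsLen,
       utr3 = c(p, p + utr3))
}

#' Place genes and suppress intragenic recombination
#'
#' Places `n_genes` non-overlapping genes (with inter-gene spacing) across
#' chromosomes, draws each gene's true meiotic expression, and multiplies
#' the crossover rate inside each transcription unit by
#' \eqn{f(e) = 1 - s \cdot \mathrm{rank}(e)/n}, where \eqn{s} is
#' `suppression_strength` and the rank of the meiotic expression is ascending
#' (the most expressed gene gets the full reduction). Flanking and
#' intergenic rates are untouched. A truth table records the factor applied
#' per gene.
#'
#' @param config A `SyntheticConfig`.
#' @param map Base landscape [GeneticMap-class] from
#'   [generateRecombinationLandscape()].
#' @return List: `models` ([GeneModelSet-class]), `map` (modified
#'   [GeneticMap-class]), `truth` (data.frame).
#' @export
placeGenesAndSuppress <- function(config, map) {
  validateSyntheticConfig(config)
  set.seed(.childSeed(config$seed, 2L))
  nChrom <- config$n_chromosomes
  L <- config$chrom_length
  chromNames <- .chromNames(config)
  perChrom <- diff(round(seq(0, config$n_genes, length.out = nChrom + 1L)))
  minGap <- 2000L

  geneRows <- vector("list", nChrom)
  for (ci in seq_len(nChrom)) {
    n <- perChrom[ci]
    if (n == 0L) next
    lens <- round(stats::runif(n, config$gene_length_range[1L],
                               config$gene_length_range[2L]))
    free <- L - sum(lens) - (n + 1L) * minGap
    if (free < 0)
      stop("genome too small: cannot place ", n, " non-overlapping genes ",
           "of total length ", sum(lens), " on a ", L, " bp chromosome")
    gaps <- minGap + diff(c(0, sort(stats::runif(n)), 1)) * free
    starts <- round(cumsum(gaps[seq_len(n)]) + c(0, cumsum(lens))[seq_len(n)])
    geneRows[[ci]] <- data.frame(
      chrom = chromNames[ci], start = starts, end = starts + lens,
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, geneRows)
  genes$gene_id <- sprintf("G%05d", seq_len(nrow(genes)))
  genes <- genes[, c("gene_id", "chrom", "start", "end", "strand")]
  nG <- nrow(genes)

  # true meiotic expression (FPKM): drawn here because suppression needs it
  mu <- config$expression_lognormal_params[[1L]]
  sig <- config$expression_lognormal_params[[2L]]
  meiotic <- stats::rlnorm(nG, mu, sig)
  femaleMean <- meiotic * exp(stats::rnorm(nG, 0, 0.3))
  maleMean <- meiotic * exp(stats::rnorm(nG, 0, 0.3))
  regulon <- sample.int(config$n_regulons, nG, replace = TRUE)

  rk <- .stableRank(meiotic, genes$gene_id)
  factorF <- 1 - config$suppression_strength * rk / nG
  # long-term expression state: what gBGC integrated over evolutionary time;
  # shapes the sequences, while factorF (present-day) shapes the emitted map
  meioticLong <- meiotic * exp(stats::rnorm(nG, 0, config$expression_drift))
  rkLong <- .stableRank(meioticLong, genes$gene_id)
  factorLong <- 1 - config$suppression_strength * rkLong / nG

  # exon/intron structure, transcript coordinates -> genomic coordinates
  # (collected flat and split once: one IRanges allocation for all genes)
  structs <- vector("list", nG)
  cdsRows <- vector("list", nG); intronRows <- vector("list", nG)
  for (i in seq_len(nG)) {
    st <- .geneStructure(genes$end[i] - genes$start[i])
    structs[[i]] <- st
    if (genes$strand[i] == "+") {
      cdsG <- st$cds + genes$start[i]
      intrG <- st$introns + genes$start[i]
    } else {
      cdsG <- cbind(genes$end[i] - st$cds[, 2L], genes$end[i] - st$cds[, 1L])
      intrG <- cbind(genes$end[i] - st$introns[, 2L],
                     genes$end[i] - st$introns[, 1L])
    }
    cdsRows[[i]] <- cbind(i, cdsG)
    if (nrow(intrG)) intronRows[[i]] <- cbind(i, intrG)
  }
  # 0-based half-open -> IRanges (1-based closed)
  asIRList <- function(rows) {
    m <- do.call(rbind, rows)
    if (is.null(m)) m <- matrix(0, 0L, 3L)
    m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
    out <- S4Vectors::split(IRanges(m[, 2L] + 1L, m[, 3L]),
                            factor(m[, 1L], levels = seq_len(nG)))
    names(out) <- genes$gene_id
    out
  }
  cdsList <- asIRList(cdsRows)
  intronList <- asIRList(intronRows)

  gr <- GRanges(genes$chrom, IRanges(genes$start + 1L, genes$end),
                strand = genes$strand)
  names(gr) <- genes$gene_id
  suppressWarnings(seqlengths(gr) <- stats::setNames(
    rep(L, nChrom), chromNames)[seqlevels(gr)])
  models <- .newGeneModelSet(
    gr, cdsList, intronList,
    .buildFlanks(gr, config$flank_width,
                 as.list(stats::setNames(rep(L, nChrom), chromNames))),
    config$flank_width)

  baseRate <- intervalRate(map, genes$chrom, genes$start, genes$end)$rate
  modMap <- .suppressIntragenic(map, genes, factorF)

  truth <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom, start = genes$start,
    end = genes$end, strand = genes$strand,
    local_rate = baseRate,
    meiotic_expression = meiotic,
    female_mean = femaleMean, male_mean = maleMean,
    suppression_factor = factorF,
    suppressed_rate = baseRate * factorF,
    longterm_factor = factorLong,
    longterm_rate = baseRate * factorLong,
    regulon = regulon,
    regime = config$regime,
    stringsAsFactors = FALSE)
  attr(truth, "structures") <- structs
  list(models = models, map = modMap, truth = truth)
}

# multiply the rate field inside each transcription unit by its factor;
# implemented by inserting markers at gene boundaries and rescaling the
# piecewise-linear segments that fall inside genes
.suppressIntragenic <- function(map, genes, factorF) {
  out <- list()
  for (ch in unique(map@markers$chrom)) {
    m <- .mapChrom(map, ch)
    gi <- which(genes$chrom == ch)
    bps <- sort(unique(c(m$pos, genes$start[gi], genes$end[gi])))
    cm <- stats::approx(m$pos, m$cum_cM, xout = bps, rule = 2,
                        ties = "ordered")$y
    segRate <- diff(cm) / (diff(bps) / 1e6)
    mid <- (bps[-1L] + bps[-length(bps)]) / 2
    fac <- rep(1, length(segRate))
    for (j in gi) {
      inside <- mid > genes$start[j] & mid < genes$end[j]
      fac[inside] <- factorF[j]
    }
    out[[ch]] <- data.frame(
      chrom = ch, pos = bps,
      cum_cM = c(0, cumsum(segRate * fac * diff(bps) / 1e6)))
  }
  geneticMap(do.call(rbind, out), seqlengths = map@seqlengths)
}

# DSB hotspots: inhomogeneous Poisson along the suppressed map, intensity
# proportional to the local rate (so highly expressed genes get fewer)
.generateHotspots <- function(config, map) {
  set.seed(.childSeed(config$seed, 5L))
  width <- 1500
  rows <- list()
  for (ch in unique(map@markers$chrom)) {
    m <- .mapChrom(map, ch)
    segCM <- diff(m$cum_cM)
    n <- stats::rpois(length(segCM), segCM * config$hotspots_per_cM)
    if (sum(n) == 0L) next
    starts <- m$pos[-length(m$pos)]
    ends <- m$pos[-1L]
    mids <- unlist(lapply(which(n > 0L), function(i) {
      stats::runif(n[i], starts[i], ends[i])
    }))
    rows[[ch]] <- data.frame(chrom = ch,
                             start = pmax(0, round(mids - width / 2)),
                             end = round(mids + width / 2))
  }
  if (length(rows) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}
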