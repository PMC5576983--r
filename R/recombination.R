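# Genetic-map arithmetic: piecewise-linear cumulative cM, interval crossover
# rates in cM/Mb, DSB hotspot densities.

#' Construct a GeneticMap
#'
#' @param markers data.frame with columns `chrom`, `pos` (bp) and either
#'   `cum_cM` (cumulative genetic position) or `rate_cM_per_Mb` (local rate
#'   of the segment starting at `pos`, integrated to a cumulative position
#'   starting at 0 per chromosome).
#' @param seqlengths Optional named chromosome lengths (bp).
#' @return A [GeneticMap-class].
#' @export
geneticMap <- function(markers, seqlengths = numeric(0)) {
  stopifnot(is.data.frame(markers), all(c("chrom", "pos") %in% names(markers)))
  markers <- markers[order(markers$chrom, markers$pos), , drop = FALSE]
  if (!"cum_cM" %in% names(markers)) {
    if (!"rate_cM_per_Mb" %in% names(markers))
      stop("markers needs a cum_cM or rate_cM_per_Mb column")
    cum <- unlist(lapply(split(markers, markers$chrom), function(m) {
      c(0, cumsum(m$rate_cM_per_Mb[-nrow(m)] * diff(m$pos) / 1e6))
    }), use.names = FALSE)
    markers$cum_cM <- cum
  }
  rownames(markers) <- NULL
  new("GeneticMap",
      markers = markers[, c("chrom", "pos", "cum_cM")],
      seqlengths = seqlengths)
}

#' @describeIn GeneticMap-class Marker table (chrom, pos, cum_cM).
#' @param x A GeneticMap.
#' @export
setMethod("mapMarkers", "GeneticMap", function(x) x@markers)

setMethod("show", "GeneticMap", function(object) {
  m <- object@markers
  cat("GeneticMap:", length(unique(m$chrom)), "chromosomes,",
      nrow(m), "markers,", round(sum(tapply(m$cum_cM, m$chrom, max)), 2),
      "cM total\n")
})

.mapChrom <- function(map, chrom) {
  m <- map@markers[map@markers$chrom == chrom, , drop = FALSE]
  if (nrow(m) == 0L) stop("no markers for chromosome ", chrom)
  m
}

#' Interpolate cumulative genetic position
#'
#' Piecewise-linear interpolation of cumulative cM between flanking markers.
#' Positions outside the marker span are clamped to the terminal values.
#'
#' @param map A [GeneticMap-class].
#' @param chrom Chromosome name (scalar).
#' @param pos Physical positions (bp), vectorised.
#' @return Numeric vector of cumulative cM.
#' @export
interpolateCM <- function(map, chrom, pos) {
  m <- .mapChrom(map, chrom)
  if (nrow(m) == 1L) return(rep(m$cum_cM, length(pos)))
  stats::approx(m$pos, m$cum_cM, xout = pos, rule = 2, ties = "ordered")$y
}

#' Crossover rate of genomic intervals
#'
#' rate = (cM(end) - cM(start)) / (length in Mb), with cumulative positions
#' interpolated (and clamped) as in [interpolateCM()]. `covered_fraction`
#' reports how much of each interval lies inside the map's marker span, so
#' callers can drop poorly covered intervals.
#'
#' @param map A [GeneticMap-class].
#' @param chrom Chromosome names (recycled to the interval count).
#' @param start,end Interval bounds in bp (0-based half-open or any
#'   consistent convention; only differences matter). Zero-length intervals
#'   are an error.
#' @return data.frame: `rate` (cM/Mb), `covered_fraction`.
#' @export
intervalRate <- function(map, chrom, start, end) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n); end <- rep_len(end, n)
  if (any(end <= start)) stop("zero- or negative-length interval")
  rate <- numeric(n)
  covered <- numeric(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    m <- .mapChrom(map, ch)
    cmS <- if (nrow(m) == 1L) rep(m$cum_cM, length(i)) else
      stats::approx(m$pos, m$cum_cM, xout = start[i], rule = 2,
                    ties = "ordered")$y
    cmE <- if (nrow(m) == 1L) rep(m$cum_cM, length(i)) else
      stats::approx(m$pos, m$cum_cM, xout = end[i], rule = 2,
                    ties = "ordered")$y
    rate[i] <- (cmE - cmS) / ((end[i] - start[i]) / 1e6)
    span <- range(m$pos)
    ov <- pmax(0, pmin(end[i], span[2]) - pmax(start[i], span[1]))
    covered[i] <- ov / (end[i] - start[i])
  }
  data.frame(rate = rate, covered_fraction = covered)
}

#' DSB hotspot density of genomic intervals
#'
#' Counts hotspot midpoints inside each interval (membership by midpoint
#' avoids double counting across interval edges) and divides by the interval
#' length in kb.
#'
#' @param hotspots data.frame with columns `chrom`, `start`, `end` (BED-style
#'   0-based half-open).
#' @param chrom,start,end Query intervals (vectorised).
#' @return Numeric vector of hotspots per kb.
#' @export
hotspotDensity <- function(hotspots, chrom, start, end) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n); end <- rep_len(end, n)
  mid <- (hotspots$start + hotspots$end) / 2
  out <- numeric(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    m <- mid[hotspots$chrom == ch]
    out[i] <- vapply(i, function(j) {
      sum(m >= start[j] & m < end[j])
    }, numeric(1)) / ((end[i] - start[i]) / 1000)
  }
  out
}

#' Read a genetic map TSV
#'
#' Accepts either dialect, auto-detected from the header:
#' `chrom pos cum_cM` or `chrom pos rate_cM_per_Mb` (optionally both).
#'
#' @param path TSV file.
#' @return A [GeneticMap-class].
#' @export
readGeneticMap <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  geneticMap(m)
}

#' Write a genetic map TSV
#'
#' Emits `chrom pos rate_cM_per_Mb cum_cM`; the rate column is the local rate
#' of the segment starting at each marker (`NA` on terminal markers).
#'
#' @param map A [GeneticMap-class].
#' @param path Output file.
#' @export
writeGeneticMap <- function(map, path) {
  m <- map@markers
  rate <- unlist(lapply(split(m, m$chrom), function(d) {
    c(diff(d$cum_cM) / (diff(d$pos) / 1e6), NA_real_)
  }), use.names = FALSE)
  out <- data.frame(chrom = m$chrom, pos = m$pos,
                    rate_cM_per_Mb = rate, cum_cM = m$cum_cM)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
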