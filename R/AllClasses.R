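#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom IRanges CompressedIRangesList
NULL

#' CodonUsageTable: codon counts for a gene or a concatenated gene set
#'
#' Holds the counts \eqn{C_{xy}} of each of the 61 sense codons. Stop codons
#' are never counted; codons containing N are skipped and tallied in
#' `skipped()`.
#'
#' @slot counts Named integer vector over the 61 sense codons.
#' @slot nSkipped Number of codons skipped because they contained N.
#' @slot source Identifier of the gene or gene set the counts come from.
#' @export
setClass("CodonUsageTable",
  representation(counts = "integer", nSkipped = "integer", source = "character"),
  prototype(nSkipped = 0L, source = NA_character_)
)

setValidity("CodonUsageTable", function(object) {
  if (!identical(names(object@counts), senseCodons()))
    return("counts must be named by the 61 sense codons (sorted)")
  if (anyNA(object@counts) || any(object@counts < 0L))
    return("counts must be non-negative integers")
  if (length(object@nSkipped) != 1L || object@nSkipped < 0L)
    return("nSkipped must be a single non-negative integer")
  TRUE
})

#' GeneticMap: piecewise-linear cumulative genetic position
#'
#' Markers are (chromosome, physical position in bp, cumulative cM). Between
#' markers the cumulative genetic position is linearly interpolated; outside
#' the marker span it is clamped to the terminal values.
#'
#' @slot markers data.frame with columns `chrom`, `pos` (bp), `cum_cM`.
#' @slot seqlengths Named numeric vector of chromosome lengths (bp), possibly
#'   empty when unknown.
#' @export
setClass("GeneticMap",
  representation(markers = "data.frame", seqlengths = "numeric"),
  prototype(seqlengths = numeric(0))
)

setValidity("GeneticMap", function(object) {
  m <- object@markers
  if (!all(c("chrom", "pos", "cum_cM") %in% names(m)))
    return("markers needs columns chrom, pos, cum_cM")
  for (ch in unique(m$chrom)) {
    i <- m$chrom == ch
    if (is.unsorted(m$pos[i], strictly = TRUE))
      return(sprintf("positions not strictly increasing on %s", ch))
    if (any(diff(m$cum_cM[i]) < -1e-9))
      return(sprintf("cumulative cM decreasing on %s", ch))
  }
  TRUE
})

#' GeneModelSet: one canonical model per gene
#'
#' Coordinates are 0-based half-open throughout. The `genes` ranges span the
#' transcription unit (TSS to polyadenylation site); per-gene CDS, intron and
#' flank intervals are stored as genomic IRanges lists parallel to `genes`.
#'
#' @slot genes GRanges of transcription units, names = gene ids.
#' @slot cds CompressedIRangesList of CDS intervals (genomic, sorted).
#' @slot introns CompressedIRangesList of intron intervals.
#' @slot flanks CompressedIRangesList of flanking intervals (clipped to
#'   exclude annotated genes and chromosome ends).
#' @slot flankWidth Width (bp) used on each side when flanks were built.
#' @export
setClass("GeneModelSet",
  representation(genes = "GRanges", cds = "CompressedIRangesList",
                 introns = "CompressedIRangesList",
                 flanks = "CompressedIRangesList", flankWidth = "numeric")
)

setValidity("GeneModelSet", function(object) {
  n <- length(object@genes)
  if (is.null(names(object@genes))) return("genes must be named by gene id")
  if (length(object@cds) != n || length(object@introns) != n ||
      length(object@flanks) != n)
    return("cds/introns/flanks must be parallel to genes")
  csum <- sum(IRanges::width(object@cds))
  if (any(csum %% 3L != 0L))
    return("total CDS length must be divisible by 3 for every gene")
  TRUE
})

#' MetageneProfile: windowed crossover-rate profile around a common anchor
#'
#' @slot anchor "TSS" or "polyA".
#' @slot window Window width in bp (non-overlapping, contiguous).
#' @slot profile data.frame with columns `stratum`, `offset_bp` (window start
#'   relative to the anchor, transcriptional orientation), `mean_rate`,
#'   `ci_low`, `ci_high`, `n`.
#' @export
setClass("MetageneProfile",
  representation(anchor = "character", window = "numeric", profile = "data.frame")
)

setValidity("MetageneProfile", function(object) {
  if (!object@anchor %in% c("TSS", "polyA")) return("anchor must be TSS or polyA")
  p <- object@profile
  if (nrow(p)) {
    if (any(p$n <= 0L)) return("reported windows must have n > 0")
    if (any(p$ci_low > p$mean_rate + 1e-9 | p$ci_high < p$mean_rate - 1e-9))
      return("CI must contain the mean")
  }
  TRUE
})

#' IsoacceptorPartition: amino acids by tRNA isoacceptor repertoire
#'
#' @slot mono Amino acids decoded by exactly one tRNA isoacceptor.
#' @slot multi Amino acids decoded by two or more isoacceptors.
#' @slot excluded Single-codon amino acids (Met, Trp), never partitioned.
#' @export
setClass("IsoacceptorPartition",
  representation(mono = "character", multi = "character", excluded = "character"),
  prototype(excluded = c("M", "W"))
)

setValidity("IsoacceptorPartition", function(object) {
  both <- sort(c(object@mono, object@multi))
  if (!identical(both, degenerateAminoAcids()))
    return("mono and multi must partition the 18 degenerate amino acids")
  if (length(intersect(object@mono, object@multi)))
    return("mono and multi must be disjoint")
  TRUE
})

#' PCAResult: principal components of a gene-set RSCU matrix
#'
#' @slot coordinates Sets x axes coordinate matrix.
#' @slot varianceShare Per-axis share of total variance (non-increasing).
#' @slot loadings Codons x axes loading matrix (orthonormal columns).
#' @slot nImputed Number of undefined RSCU cells imputed by the column mean.
#' @export
setClass("PCAResult",
  representation(coordinates = "matrix", varianceShare = "numeric",
                 loadings = "matrix", nImputed = "integer")
)

setValidity("PCAResult", function(object) {
  v <- object@varianceShare
  if (any(diff(v) > 1e-9)) return("variance shares must be non-increasing")
  if (sum(v) > 1 + 1e-6) return("variance shares must sum to <= 1")
  TRUE
})

#' VariancePartition: sequential (Type-I) ANOVA of a response
#'
#' Predictors enter an ordinary-least-squares model in a fixed order; each
#' step reports its pairwise r-squared with the response, the cumulative
#' model r-squared, and an F statistic testing the step's increment in
#' explained sum of squares against the full model's residual mean square.
#'
#' @slot table data.frame: `predictor`, `pairwise_r2`, `model_r2`, `F`, `p`.
#' @slot residualDf Residual degrees of freedom of the full model.
#' @slot nUsed Complete cases used.
#' @slot nDropped Genes dropped for undefined values.
#' @slot totalSS Total sum of squares of the response.
#' @slot response Name of the response variable.
#' @export
setClass("VariancePartition",
  representation(table = "data.frame", residualDf = "numeric",
                 nUsed = "integer", nDropped = "integer",
                 totalSS = "numeric", response = "character")
)

setValidity("VariancePartition", function(object) {
  r2 <- object@table$model_r2
  if (any(diff(r2) < -1e-10)) return("cumulative model R2 must be non-decreasing")
  if (any(object@table$F < 0, na.rm = TRUE)) return("F statistics must be >= 0")
  TRUE
})

#' SyntheticGenome: full output of the simulator
#'
#' @slot config The `SyntheticConfig` used.
#' @slot map The (suppression-modified) GeneticMap.
#' @slot baseMap The landscape GeneticMap before intragenic suppression.
#' @slot models GeneModelSet of simulated genes.
#' @slot truth data.frame of per-gene generative truth.
#' @slot genome DNAStringSet or NULL (stage not run).
#' @slot cds DNAStringSet or NULL.
#' @slot expression Genes x samples FPKM matrix or NULL.
#' @slot sampleInfo data.frame of sample metadata (group, sex, cell_type,
#'   replicate).
#' @slot sets Named list of gene-id vectors (GO-like, overlapping).
#' @slot hotspots data.frame of DSB hotspot intervals (chrom, start, end).
#' @export
setClass("SyntheticGenome",
  representation(config = "list", map = "GeneticMap", baseMap = "GeneticMap",
                 models = "GeneModelSet", truth = "data.frame",
                 genome = "ANY", cds = "ANY", expression = "ANY",
                 sampleInfo = "data.frame", sets = "list",
                 hotspots = "data.frame")
)
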