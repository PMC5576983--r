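# Configuration of the synthetic-genome generator. The defaults ARE the
# study conditions: a multi-megabase genome with an isochore-scale
# recombination/GC landscape, human-like mean crossover rate, strong
# meiotic-expression-dependent intragenic crossover suppression, and GO-like
# overlapping gene sets tilted by expression.

#' Configuration for the synthetic-genome generator
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param isochore_scale Correlation length (bp) of the recombination/GC
#'   landscape.
#' @param n_genes Number of non-overlapping genes.
#' @param gene_length_range Min/max transcription-unit length (bp).
#' @param base_rate Genome-wide mean crossover rate (cM/Mb).
#' @param landscape_log_sd Log-scale standard deviation of the rate field.
#' @param gbgc_slope Coupling of equilibrium GC to the local long-term
#'   crossover rate (on the log2 rate ratio scale; 0 decouples them).
#' @param suppression_strength Maximal intragenic crossover reduction at the
#'   highest meiotic expression, in \[0,1\].
#' @param expression_lognormal_params `c(mu, sigma)` of the log-normal
#'   per-gene meiotic expression means (natural-log scale, FPKM).
#' @param replicate_sigma Log-scale replicate noise of emitted samples.
#' @param n_somatic_groups Number of somatic sample groups.
#' @param n_replicates Replicates per sample group.
#' @param n_gene_sets Number of GO-like gene sets.
#' @param set_size_range Min/max set size.
#' @param expression_bias_of_sets Strength of the per-set expression tilt of
#'   membership sampling (0 = unbiased).
#' @param regime `"gbgc"` (codon choice governed only by GC3) or
#'   `"trna_coadapted"` (multi-isoacceptor codons follow per-regulon
#'   preferred-codon tables; mono-isoacceptor GC3 stays GC-driven).
#' @param n_regulons Number of latent co-expression programs used to tie
#'   gene sets to preferred-codon tables under `regime = "trna_coadapted"`.
#' @param pref_strength Probability that a multi-isoacceptor codon follows
#'   the regulon's preferred codon under `regime = "trna_coadapted"`.
#' @param expression_drift Log-scale sd of the drift between a gene's
#'   present-day meiotic expression (which shapes the emitted map) and its
#'   long-term average meiotic expression (which shaped the sequence's GC):
#'   present-day FPKM is an imperfect proxy of the expression history that
#'   gBGC integrated.
#' @param gc_longterm_sd Log2-scale sd of the long-term gBGC intensity of a
#'   locus around what the emitted (present-day) genetic map implies; scaled
#'   by `gbgc_slope`, so 0 slope still decouples GC from recombination.
#'   Makes intronic GC a better predictor of GC3 than the measured crossover
#'   rate, as observed when sequence composition integrates recombination
#'   over long evolutionary times.
#' @param noise_sd_gc Gaussian noise added independently to each sequence
#'   compartment's equilibrium GC.
#' @param map_resolution Marker spacing (bp) of the emitted genetic map.
#' @param flank_width Flank width (bp) used for gene models.
#' @param hotspots_per_cM Expected DSB hotspots per cM of the (suppressed)
#'   map.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @return A validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(n_chromosomes = 5L,
                            chrom_length = 8e6,
                            isochore_scale = 1e6,
                            n_genes = 2000L,
                            gene_length_range = c(5000, 12000),
                            base_rate = 1.2,
                            landscape_log_sd = 0.7,
                            gbgc_slope = 1.0,
                            suppression_strength = 0.75,
                            expression_lognormal_params = c(mu = 1.5,
                                                            sigma = 1.5),
                            replicate_sigma = 0.25,
                            n_somatic_groups = 4L,
                            n_replicates = 2L,
                            n_gene_sets = 600L,
                            set_size_range = c(40L, 120L),
                            expression_bias_of_sets = 1.5,
                            regime = c("gbgc", "trna_coadapted"),
                            n_regulons = 10L,
                            pref_strength = 0.9,
                            expression_drift = 1.0,
                            gc_longterm_sd = 0.8,
                            noise_sd_gc = 0.12,
                            map_resolution = 10000,
                            flank_width = 10000,
                            hotspots_per_cM = 20,
                            seed = 1L) {
  regime <- match.arg(regime)
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length,
              isochore_scale = isochore_scale,
              n_genes = as.integer(n_genes),
              gene_length_range = gene_length_range,
              base_rate = base_rate,
              landscape_log_sd = landscape_log_sd,
              gbgc_slope = gbgc_slope,
              suppression_strength = suppression_strength,
              expression_lognormal_params = expression_lognormal_params,
              replicate_sigma = replicate_sigma,
              n_somatic_groups = as.integer(n_somatic_groups),
              n_replicates = as.integer(n_replicates),
              n_gene_sets = as.integer(n_gene_sets),
              set_size_range = as.integer(set_size_range),
              expression_bias_of_sets = expression_bias_of_sets,
              regime = regime,
              n_regulons = as.integer(n_regulons),
              pref_strength = pref_strength,
              expression_drift = expression_drift,
              gc_longterm_sd = gc_longterm_sd,
              noise_sd_gc = noise_sd_gc,
              map_resolution = map_resolution,
              flank_width = flank_width,
              hotspots_per_cM = hotspots_per_cM,
              seed = as.integer(seed))
  class(cfg) <- "SyntheticConfig"
  validateSyntheticConfig(cfg)
  cfg
}

#' Validate a synthetic-generator configuration
#'
#' @param cfg A `SyntheticConfig`.
#' @return The config, invisibly; errors on an invalid field.
#' @export
validateSyntheticConfig <- function(cfg) {
  stopifnot(cfg$n_chromosomes >= 1L,
            cfg$chrom_length > 0, cfg$isochore_scale > 0,
            cfg$n_genes >= 1L,
            length(cfg$gene_length_range) == 2L,
            all(cfg$gene_length_range > 0),
            cfg$gene_length_range[1L] <= cfg$gene_length_range[2L],
            cfg$base_rate > 0,
            cfg$gbgc_slope >= 0,
            cfg$suppression_strength >= 0, cfg$suppression_strength <= 1,
            length(cfg$expression_lognormal_params) == 2L,
            cfg$expression_lognormal_params[2L] >= 0,
            cfg$replicate_sigma >= 0,
            cfg$n_gene_sets >= 0L,
            length(cfg$set_size_range) == 2L,
            cfg$set_size_range[1L] <= cfg$set_size_range[2L],
            cfg$regime %in% c("gbgc", "trna_coadapted"),
            cfg$expression_drift >= 0,
            cfg$gc_longterm_sd >= 0,
            cfg$noise_sd_gc >= 0,
            cfg$map_resolution > 0,
            cfg$pref_strength >= 0, cfg$pref_strength <= 1)
  invisible(cfg)
}

.chromNames <- function(cfg) sprintf("chr%d", seq_len(cfg$n_chromosomes))
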