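#' Simulation configuration for synthetic fermentation experiments
#'
#' Builds the configuration object consumed by [generate_design()],
#' [simulate_growth_curves()], [simulate_robustness_counts()],
#' [simulate_probe_intensities()] and [simulate_dataset()]. Defaults describe
#' a 13-fermentation combinatorial design over four process parameters
#' (salt, starting pH, temperature, aeration) assayed on a 2369-gene
#' two-color array, with ten "planted" genes per stress whose expression
#' tracks the latent robustness phenotype.
#'
#' @param n_fermentations Number of fermentations (rows of the design).
#' @param factor_levels Named list of allowed levels per fermentation
#'   parameter. Names must be `nacl_mM`, `start_pH`, `temperature_C`,
#'   `aeration`.
#' @param n_genes Number of ORFs on the array.
#' @param probes_per_gene Integer range (length 2) of probes designed per ORF.
#' @param n_planted_per_stress Number of genes per stress whose expression is
#'   linearly coupled to latent robustness.
#' @param planted_slope Expression change (log2 units) per log10 unit of
#'   robustness for planted genes (sign is drawn per gene).
#' @param prop_planted_positive Probability that a planted gene gets a
#'   positive slope.
#' @param n_main_effect_genes Number of genes per fermentation parameter given
#'   a direct expression main effect (independent of robustness).
#' @param main_effect_size Expression shift (log2 units) for main-effect genes.
#' @param dye_bias_amplitude Amplitude (M units) of the smooth
#'   intensity-dependent dye bias applied to both channels.
#' @param cfu_baseline Pre-stress viable count (CFU/ml) around which N0 is
#'   drawn.
#' @param n_replicates Technical replicates per CFU determination.
#' @param noise_sd_expression Per-probe log2 noise standard deviation.
#' @param od_noise_sd Multiplicative (log-scale) noise on OD readings.
#' @param robustness_latent_sd SD (log10 units) of the per-fermentation latent
#'   robustness component shared between the 30 and 60 min time points.
#' @param robustness_noise_sd SD (log10 units) of the time-point-specific
#'   robustness noise.
#' @param seed Integer seed from which all randomness in the generator flows.
#'
#' @return A list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$n_genes
#' @export
sim_config <- function(n_fermentations = 13,
                       factor_levels = list(
                         nacl_mM = c(0, 100),
                         start_pH = c(6.0, 6.5),
                         temperature_C = c(27, 30, 35),
                         aeration = c("+", "-")
                       ),
                       n_genes = 2369,
                       probes_per_gene = c(1L, 5L),
                       n_planted_per_stress = 10,
                       planted_slope = 1.0,
                       prop_planted_positive = 0.7,
                       n_main_effect_genes = 0,
                       main_effect_size = 1.0,
                       dye_bias_amplitude = 0.8,
                       cfu_baseline = 1e8,
                       n_replicates = 2,
                       noise_sd_expression = 0.2,
                       od_noise_sd = 0.02,
                       robustness_latent_sd = 0.8,
                       robustness_noise_sd = 0.35,
                       seed = 1L) {
  stopifnot(
    n_fermentations >= 1,
    is.list(factor_levels), length(factor_levels) > 0,
    all(lengths(factor_levels) > 0),
    n_genes >= 1,
    length(probes_per_gene) == 2, probes_per_gene[1] >= 1,
    probes_per_gene[1] <= probes_per_gene[2],
    n_planted_per_stress <= n_genes,
    n_main_effect_genes <= n_genes,
    cfu_baseline > 0, n_replicates >= 1,
    noise_sd_expression >= 0, dye_bias_amplitude >= 0
  )
  cfg <- list(
    n_fermentations = as.integer(n_fermentations),
    factor_levels = factor_levels,
    n_genes = as.integer(n_genes),
    probes_per_gene = as.integer(probes_per_gene),
    n_planted_per_stress = as.integer(n_planted_per_stress),
    planted_slope = planted_slope,
    prop_planted_positive = prop_planted_positive,
    n_main_effect_genes = as.integer(n_main_effect_genes),
    main_effect_size = main_effect_size,
    dye_bias_amplitude = dye_bias_amplitude,
    cfu_baseline = cfu_baseline,
    n_replicates = as.integer(n_replicates),
    noise_sd_expression = noise_sd_expression,
    od_noise_sd = od_noise_sd,
    robustness_latent_sd = robustness_latent_sd,
    robustness_noise_sd = robustness_noise_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# Stage-specific sub-seed, kept below 2^31. Offsets are fixed per stage so
# each generator is deterministic given (config$seed, stage).
sim_seed <- function(config, offset) {
  (as.integer(config$seed) * 101L + as.integer(offset)) %% 2147483647L
}

stress_levels <- function() c("heat", "oxidative")

stress_times <- function() c(0L, 30L, 60L)
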