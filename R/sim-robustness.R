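#' Simulate planted ground truth: latent robustness and planted genes
#'
#' Latent robustness (log10 survival ratio) per fermentation x stress x time
#' point is built additively: fixed process-parameter effects (aeration
#' raises heat-stress robustness; higher temperature raises oxidative-stress
#' robustness), a per-fermentation latent component shared between the 30 and
#' 60 minute time points (so the two time points correlate, as observed for
#' real stress assays), a fixed extra kill at 60 minutes, and
#' time-point-specific noise. Planted genes per stress are drawn with signed
#' slopes; their expression will track the shared latent component.
#'
#' @param design Output of [generate_design()].
#' @param config A [sim_config()] object.
#' @return A list of class `"planted_truth"` with elements
#'   \describe{
#'     \item{genes}{`data.frame(stress, gene_id, slope)` — the planted set.}
#'     \item{shared}{`data.frame(fermentation_id, stress, latent)` — the
#'       condition-level robustness component driving expression.}
#'     \item{latent}{`data.frame(fermentation_id, stress, time_min,
#'       robustness)` — the realized latent robustness per time point
#'       (0 at t = 0 by definition).}
#'   }
#' @examples
#' cfg <- sim_config(seed = 1)
#' truth <- simulate_robustness_truth(generate_design(cfg), cfg)
#' @export
simulate_robustness_truth <- function(design, config) {
  stopifnot(inherits(config, "sim_config"))
  nf <- nrow(design)
  temp_step <- match(design$temperature_C, sort(unique(config$factor_levels$temperature_C))) - 1
  aer <- as.numeric(design$aeration == "+")

  withr::with_seed(sim_seed(config, 37L), {
    u_heat <- stats::rnorm(nf, 0, config$robustness_latent_sd)
    u_oxid <- stats::rnorm(nf, 0, config$robustness_latent_sd)
    shared <- rbind(
      data.frame(
        fermentation_id = design$fermentation_id, stress = "heat",
        latent = -2.0 + 1.4 * aer + 0.15 * temp_step + u_heat
      ),
      data.frame(
        fermentation_id = design$fermentation_id, stress = "oxidative",
        latent = -2.2 + 0.7 * temp_step + 0.3 * aer + u_oxid
      )
    )

    latent <- do.call(rbind, lapply(stress_levels(), function(st) {
      base <- shared$latent[shared$stress == st]
      do.call(rbind, lapply(stress_times(), function(tm) {
        rob <- if (tm == 0L) {
          rep(0, nf)
        } else {
          offset <- if (tm == 60L) -0.7 else 0
          base + offset + stats::rnorm(nf, 0, config$robustness_noise_sd)
        }
        data.frame(
          fermentation_id = design$fermentation_id,
          stress = st, time_min = tm, robustness = rob
        )
      }))
    }))

    genes <- do.call(rbind, lapply(stress_levels(), function(st) {
      ids <- sample(gene_ids(config$n_genes), config$n_planted_per_stress)
      signs <- ifelse(
        stats::runif(config$n_planted_per_stress) < config$prop_planted_positive,
        1, -1
      )
      data.frame(stress = rep(st, length(ids)), gene_id = ids,
                 slope = signs * config$planted_slope)
    }))
    rownames(genes) <- rownames(latent) <- rownames(shared) <- NULL
    structure(list(genes = genes, shared = shared, latent = latent),
              class = "planted_truth")
  })
}

gene_ids <- function(n) sprintf("gene_%04d", seq_len(n))

#' Simulate CFU survival counts from latent robustness
#'
#' Emulates serial-dilution spot plating: the pre-stress count N0 is drawn
#' around `cfu_baseline` with log-normal variation, the post-stress expectation
#' is `N0 * 10^robustness`, and Poisson noise is applied at the counted-colony
#' scale (at most ~300 colonies per spot; dilution steps of 10) before
#' rescaling by the dilution factor.
#'
#' @param design Output of [generate_design()].
#' @param truth Output of [simulate_robustness_truth()].
#' @param config A [sim_config()] object.
#' @return A `data.frame` with columns `fermentation_id`, `stress`,
#'   `time_min`, `replicate`, `n0_cfu_per_ml`, `nt_cfu_per_ml`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' des <- generate_design(cfg)
#' cfu <- simulate_robustness_counts(des, simulate_robustness_truth(des, cfg), cfg)
#' @export
simulate_robustness_counts <- function(design, truth, config) {
  stopifnot(inherits(truth, "planted_truth"), inherits(config, "sim_config"))
  lat <- truth$latent
  stopifnot(all(design$fermentation_id %in% lat$fermentation_id))
  grid <- lat[rep(seq_len(nrow(lat)), each = config$n_replicates), ]
  grid$replicate <- rep(seq_len(config$n_replicates), times = nrow(lat))

  withr::with_seed(sim_seed(config, 53L), {
    n0_true <- config$cfu_baseline * exp(stats::rnorm(nrow(grid), 0, 0.1))
    n0 <- plated_count(n0_true)
    nt <- plated_count(n0_true * 10^grid$robustness)
    data.frame(
      fermentation_id = grid$fermentation_id,
      stress = grid$stress,
      time_min = grid$time_min,
      replicate = grid$replicate,
      n0_cfu_per_ml = n0,
      nt_cfu_per_ml = nt,
      row.names = NULL
    )
  })
}

# Poisson count at the spotted-dilution scale, rescaled by the dilution.
# Counts per spot are kept at <= ~300 by 10-fold dilution steps.
plated_count <- function(expected, max_colonies = 300) {
  dil <- 10^pmax(0, ceiling(log10(pmax(expected, 1e-12) / max_colonies)))
  stats::rpois(length(expected), expected / dil) * dil
}
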