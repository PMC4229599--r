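#' Simulate two-channel probe intensities with dye bias
#'
#' Generates one two-color array per fermentation on a common-reference
#' layout. Each ORF gets 1-5 probes (per `config$probes_per_gene`) with a
#' shared per-probe affinity; the reference channel comes from a fixed
#' per-gene baseline, while the sample channel adds the planted
#' robustness-coupled signal (slope x shared latent robustness for planted
#' genes), optional process-parameter main effects, and Gaussian log2 noise.
#' Both channels are then distorted by a smooth intensity-dependent dye-bias
#' curve (amplitude `dye_bias_amplitude`, tanh-shaped in A) that shifts M but
#' leaves A unchanged — the artifact lowess normalization is meant to remove.
#'
#' @param design Output of [generate_design()].
#' @param truth Output of [simulate_robustness_truth()].
#' @param config A [sim_config()] object.
#' @return A `data.frame` with columns `array_id` (one array per
#'   fermentation, equal to `fermentation_id`), `probe_id`, `orf_id`,
#'   `channel_sample`, `channel_reference`. The probe->ORF map is the
#'   (`probe_id`, `orf_id`) pairing. If `config$n_main_effect_genes > 0` the
#'   attribute `"main_effects"` records which genes carry which parameter
#'   effect.
#' @examples
#' cfg <- sim_config(n_genes = 50, seed = 1)
#' des <- generate_design(cfg)
#' tr <- simulate_robustness_truth(des, cfg)
#' probes <- simulate_probe_intensities(des, tr, cfg)
#' @export
simulate_probe_intensities <- function(design, truth, config) {
  stopifnot(inherits(truth, "planted_truth"), inherits(config, "sim_config"))
  nf <- nrow(design)
  ng <- config$n_genes
  ids <- gene_ids(ng)

  withr::with_seed(sim_seed(config, 71L), {
    k <- sample(seq(config$probes_per_gene[1], config$probes_per_gene[2]),
                ng, replace = TRUE)
    orf_of_probe <- rep(ids, times = k)
    probe_id <- paste0(orf_of_probe, "_p", unlist(lapply(k, seq_len)))
    np <- length(probe_id)

    baseline <- stats::runif(ng, 6, 14)
    affinity <- stats::rnorm(np, 0, 0.25)

    # True per-gene log2 ratio per fermentation
    m_true <- matrix(0, nrow = ng, ncol = nf, dimnames = list(ids, NULL))
    for (st in stress_levels()) {
      sh <- truth$shared
      lat <- sh$latent[sh$stress == st][match(design$fermentation_id,
                                              sh$fermentation_id[sh$stress == st])]
      pg <- truth$genes[truth$genes$stress == st, ]
      if (nrow(pg) > 0) {
        m_true[pg$gene_id, ] <- m_true[pg$gene_id, , drop = FALSE] +
          outer(pg$slope, lat)
      }
    }
    main_effects <- NULL
    if (config$n_main_effect_genes > 0) {
      main_effects <- do.call(rbind, lapply(names(config$factor_levels), function(f) {
        lvl <- config$factor_levels[[f]]
        hi <- lvl[length(lvl)]
        g <- sample(ids, config$n_main_effect_genes)
        on <- as.numeric(design[[f]] == hi)
        m_true[g, ] <<- m_true[g, , drop = FALSE] +
          config$main_effect_size * matrix(on, nrow = length(g), ncol = nf,
                                           byrow = TRUE)
        data.frame(factor = f, level = as.character(hi), gene_id = g,
                   effect = config$main_effect_size)
      }))
    }

    gidx <- match(orf_of_probe, ids)
    out <- vector("list", nf)
    for (j in seq_len(nf)) {
      log2_ref <- baseline[gidx] + affinity
      log2_smp <- log2_ref + m_true[gidx, j] +
        if (config$noise_sd_expression > 0) {
          stats::rnorm(np, 0, config$noise_sd_expression)
        } else 0
      a <- (log2_smp + log2_ref) / 2
      d <- dye_bias_curve(a, config$dye_bias_amplitude)
      out[[j]] <- data.frame(
        array_id = design$fermentation_id[j],
        probe_id = probe_id,
        orf_id = orf_of_probe,
        channel_sample = 2^(log2_smp + d / 2),
        channel_reference = 2^(log2_ref - d / 2)
      )
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "main_effects") <- main_effects
    res
  })
}

# Smooth monotone dye bias in M as a function of A: stronger distortion at
# low intensities, as commonly seen on two-color arrays.
dye_bias_curve <- function(a, amplitude, center = 10) {
  amplitude * tanh((center - a) / 2)
}

#' Simulate gene coordinates for linkage analysis
#'
#' Places genes sequentially on a single contig with a mixture of short
#' (operon-like, < 100 bp) and long intergenic gaps and persistent strand
#' runs, so that a realistic fraction of adjacent gene pairs is genetically
#' linked in the intergenic-spacing sense.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @examples
#' head(simulate_gene_models(sim_config(n_genes = 20, seed = 1)))
#' @export
simulate_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ng <- config$n_genes
  withr::with_seed(sim_seed(config, 89L), {
    len <- sample(300:1500, ng, replace = TRUE)
    short <- stats::runif(ng) < 0.6
    gap <- ifelse(short, sample(0:80, ng, replace = TRUE),
                  sample(120:400, ng, replace = TRUE))
    start <- cumsum(c(1, (len + gap)[-ng]))
    flip <- stats::runif(ng) < 0.3
    strand <- character(ng)
    strand[1] <- sample(c("+", "-"), 1)
    for (i in seq_len(ng - 1)) {
      strand[i + 1] <- if (flip[i]) setdiff(c("+", "-"), strand[i]) else strand[i]
    }
    data.frame(
      gene_id = gene_ids(ng), contig = "contig_1",
      start = start, end = start + len - 1, strand = strand
    )
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running all generators off a single configuration:
#' design, growth curves, planted truth, CFU counts, probe intensities and
#' gene coordinates. Fixing `config$seed` makes the whole bundle
#' reproducible.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"sim_dataset"` with elements `design`, `curves`,
#'   `truth`, `cfu`, `probes`, `gene_models`, `config`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 40, seed = 1))
#' names(sim)
#' @export
simulate_dataset <- function(config = sim_config()) {
  design <- generate_design(config)
  truth <- simulate_robustness_truth(design, config)
  structure(list(
    design = design,
    curves = simulate_growth_curves(design, config),
    truth = truth,
    cfu = simulate_robustness_counts(design, truth, config),
    probes = simulate_probe_intensities(design, truth, config),
    gene_models = simulate_gene_models(config),
    config = config
  ), class = "sim_dataset")
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes the design, growth-curve, CFU and probe tables as TSV, the planted
#' truth as two TSVs, and the gene models as GFF3.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    design = file.path(dir, "design.tsv"),
    curves = file.path(dir, "growth_curves.tsv"),
    cfu = file.path(dir, "cfu.tsv"),
    probes = file.path(dir, "probes.tsv"),
    truth_genes = file.path(dir, "truth_planted_genes.tsv"),
    truth_latent = file.path(dir, "truth_latent_robustness.tsv"),
    gene_models = file.path(dir, "gene_models.gff3")
  )
  write_tsv(sim$design, paths["design"])
  write_tsv(sim$curves, paths["curves"])
  write_tsv(sim$cfu, paths["cfu"])
  write_tsv(sim$probes, paths["probes"])
  write_tsv(sim$truth$genes, paths["truth_genes"])
  write_tsv(sim$truth$latent, paths["truth_latent"])
  write_gene_models_gff3(sim$gene_models, paths["gene_models"])
  invisible(paths)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
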