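#' Pipeline configuration
#'
#' Bundles either a simulation block or a set of input file paths with all
#' analysis thresholds. Exactly one of `simulation` / `inputs` must be
#' given.
#'
#' @param simulation A [sim_config()] describing synthetic inputs, or `NULL`.
#' @param inputs Named list of paths (`design`, `curves`, `cfu`, `probes`,
#'   optionally `gff`) to TSV/GFF3 inputs in the schemas written by
#'   [write_simulation()], or `NULL`.
#' @param alpha Significance threshold used throughout (t-tests,
#'   correlations, DE calls).
#' @param product_cutoff P-value-product threshold for signature selection.
#' @param lowess_span Span for [lowess_normalize()].
#' @param mu_window Sliding-window width for [estimate_mu_max()].
#' @param max_spacing Strict intergenic-spacing threshold (bp) for linkage.
#' @param seed Integer seed (overrides `simulation$seed` when simulating).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulation = sim_config(), inputs = NULL,
                            alpha = 0.05, product_cutoff = 5e-5,
                            lowess_span = 0.4, mu_window = 4,
                            max_spacing = 100, seed = NULL) {
  if (is.null(simulation) && is.null(inputs)) {
    stop("either a simulation block or input paths must be provided")
  }
  if (!is.null(simulation) && !is.null(inputs)) {
    stop("provide a simulation block or input paths, not both")
  }
  stopifnot(alpha > 0, alpha <= 1, product_cutoff > 0, product_cutoff <= 1,
            lowess_span > 0, lowess_span <= 1, mu_window >= 3,
            max_spacing > 0)
  if (!is.null(simulation) && !is.null(seed)) simulation$seed <- as.integer(seed)
  structure(list(
    simulation = simulation, inputs = inputs,
    alpha = alpha, product_cutoff = product_cutoff,
    lowess_span = lowess_span, mu_window = mu_window,
    max_spacing = max_spacing
  ), class = "pipeline_config")
}

#' Run the full transcriptome-phenotype matching pipeline
#'
#' Executes, in order: input simulation (or loading), growth and robustness
#' phenotyping, parameter-effect t-tests, microarray preprocessing,
#' per-parameter differential expression with the overlap matrix, per-stress
#' signature construction with the cross-stress intersection, and linkage
#' annotation of the signatures. All stage outputs are returned in one
#' report; identical config and seed give identical reports.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, every stage table is also
#'   written as TSV (plus GFF3 gene models and a `report_summary.txt`).
#' @return A list of class `"run_report"`: `design`, `growth_summary`,
#'   `robustness`, `parameter_effects`, `time_point_correlation`,
#'   `de_results`, `overlap`, `signatures` (per stress), `sign_counts`,
#'   `cross_stress`, `linkage`, `linkage_annotation` (per stress),
#'   `provenance`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if (!is.null(config$simulation)) {
    sim <- stage("simulate", simulate_dataset(config$simulation))
    design <- sim$design; curves <- sim$curves; cfu <- sim$cfu
    probes <- sim$probes; gene_models <- sim$gene_models
    truth <- sim$truth
  } else {
    p <- config$inputs
    design <- stage("load", utils::read.delim(p$design,
                                              colClasses = c(aeration = "character")))
    curves <- stage("load", utils::read.delim(p$curves))
    cfu <- stage("load", utils::read.delim(p$cfu))
    probes <- stage("load", utils::read.delim(p$probes))
    gene_models <- if (!is.null(p$gff)) stage("load", read_gene_models(p$gff))
    truth <- NULL
    sim <- NULL
  }

  growth <- stage("phenotype", growth_summaries(curves, config$mu_window))
  robustness <- stage("phenotype", compute_robustness(cfu))

  ids <- design$fermentation_id
  tp_cor <- do.call(rbind, lapply(stress_levels(), function(st) {
    r30 <- robustness_vector(robustness, st, 30L, ids)
    r60 <- robustness_vector(robustness, st, 60L, ids)
    cc <- correlate_profiles(r30, r60)
    data.frame(stress = st, r = cc$r, p_value = cc$p_value, n = cc$n)
  }))

  effects <- stage("phenotype", parameter_effect_table(
    design, growth, robustness, alpha = config$alpha
  ))

  expr <- stage("preprocess", preprocess_probes(probes,
                                                span = config$lowess_span))

  de <- stage("de", de_all_parameters(expr, design, alpha = config$alpha))
  ov <- stage("de", overlap_matrix(de))

  crit <- selection_criterion(config$alpha, config$product_cutoff)
  signatures <- stage("match", lapply(
    stats::setNames(nm = stress_levels()),
    function(st) build_signature(expr, robustness, st, crit)
  ))
  sign_counts <- lapply(signatures, summarize_signs)
  cross <- intersect_signatures(signatures$heat, signatures$oxidative)

  linkage <- NULL
  link_ann <- NULL
  if (!is.null(gene_models)) {
    linkage <- stage("linkage", find_linked_groups(gene_models,
                                                   config$max_spacing))
    link_ann <- lapply(signatures, function(s) {
      if (sum(s$selected) == 0) return(NULL)
      annotate_signature(s, linkage)
    })
  }

  report <- structure(list(
    design = design, growth_summary = growth, robustness = robustness,
    parameter_effects = effects, time_point_correlation = tp_cor,
    de_results = de, overlap = ov,
    signatures = signatures, sign_counts = sign_counts,
    cross_stress = cross, linkage = linkage, linkage_annotation = link_ann,
    truth = truth,
    provenance = list(
      seed = if (!is.null(config$simulation)) config$simulation$seed,
      alpha = config$alpha, product_cutoff = config$product_cutoff,
      lowess_span = config$lowess_span, mu_window = config$mu_window,
      max_spacing = config$max_spacing,
      package_version = as.character(utils::packageVersion("robustmatch"))
    )
  ), class = "run_report")

  if (!is.null(outdir)) write_report(report, sim, outdir)
  report
}

# Phenotype ~ parameter t-tests for every factor level pair, for mu_max,
# od_final, and robustness per stress at 30 min.
parameter_effect_table <- function(design, growth, robustness, alpha = 0.05) {
  ids <- design$fermentation_id
  values <- list(
    mu_max = growth$mu_max[match(ids, growth$fermentation_id)],
    od_final = growth$od_final[match(ids, growth$fermentation_id)],
    robustness_heat_30 = robustness_vector(robustness, "heat", 30L, ids),
    robustness_oxidative_30 = robustness_vector(robustness, "oxidative", 30L, ids)
  )
  rows <- list()
  for (f in c("nacl_mM", "start_pH", "temperature_C", "aeration")) {
    lv <- sort(unique(design[[f]]))
    for (pr in utils::combn(length(lv), 2, simplify = FALSE)) {
      la <- lv[pr[1]]; lb <- lv[pr[2]]
      for (v in names(values)) {
        ok <- is.finite(values[[v]])
        tt <- test_parameter_effect(design[ok, , drop = FALSE],
                                    values[[v]][ok], f, la, lb, alpha)
        rows[[length(rows) + 1]] <- data.frame(
          phenotype = v, factor = f,
          level_a = as.character(la), level_b = as.character(lb),
          t_statistic = tt$t_statistic, p_value = tt$p_value,
          direction = as.character(tt$direction),
          significant = tt$significant
        )
      }
    }
  }
  do.call(rbind, rows)
}

write_report <- function(report, sim, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (!is.null(sim)) write_simulation(sim, file.path(outdir, "inputs"))
  write_tsv(report$growth_summary, file.path(outdir, "growth_summary.tsv"))
  write_tsv(report$robustness, file.path(outdir, "robustness.tsv"))
  write_tsv(report$parameter_effects, file.path(outdir, "parameter_effects.tsv"))
  de_tab <- do.call(rbind, lapply(names(report$de_results), function(nm) {
    r <- report$de_results[[nm]]
    data.frame(contrast = nm, factor = r$factor,
               level_a = as.character(r$level_a),
               level_b = as.character(r$level_b),
               gene_id = names(r$p_value), p_value = unname(r$p_value),
               is_de = names(r$p_value) %in% r$de_genes)
  }))
  write_tsv(de_tab, file.path(outdir, "de_results.tsv"))
  ovl <- as.data.frame.table(report$overlap$count,
                             responseName = "count")
  names(ovl)[1:2] <- c("set_a", "set_b")
  ovl$pct_of_a <- as.data.frame.table(report$overlap$pct)$Freq
  write_tsv(ovl, file.path(outdir, "overlap_matrix.tsv"))
  for (st in names(report$signatures)) {
    write_tsv(as.data.frame(report$signatures[[st]]),
              file.path(outdir, paste0("signature_", st, ".tsv")))
  }
  write_tsv(report$cross_stress, file.path(outdir, "cross_stress_overlap.tsv"))
  if (!is.null(report$linkage)) {
    write_tsv(report$linkage, file.path(outdir, "linkage_groups.tsv"))
  }
  writeLines(format_report_summary(report),
             file.path(outdir, "report_summary.txt"))
  invisible(outdir)
}

format_report_summary <- function(report) {
  sig_sizes <- vapply(report$signatures, function(s) sum(s$selected), 0L)
  c(
    "transcriptome-phenotype matching report",
    sprintf("seed: %s", report$provenance$seed),
    sprintf("fermentations: %d", nrow(report$design)),
    sprintf("genes analyzed: %d", length(report$de_results[[1]]$universe)),
    sprintf("mu_max range: %.3f - %.3f",
            min(report$growth_summary$mu_max),
            max(report$growth_summary$mu_max)),
    sprintf("od_final range: %.3f - %.3f",
            min(report$growth_summary$od_final),
            max(report$growth_summary$od_final)),
    sprintf("signature sizes: heat %d, oxidative %d",
            sig_sizes["heat"], sig_sizes["oxidative"]),
    sprintf("cross-stress overlap: %d genes", nrow(report$cross_stress))
  )
}

#' Extrema of a design/growth table
#'
#' Minimum and maximum `od_final` and `mu_max` with the fermentations
#' attaining them.
#'
#' @param design_plus_growth Table with `fermentation_id`, `od_final`,
#'   `mu_max` columns (e.g. [mg1363_design_growth()]).
#' @return Nested list: for each of `od_final` and `mu_max`, `min`, `max`,
#'   `id_min`, `id_max`.
#' @examples
#' summarize_design_table(mg1363_design_growth())$od_final[c("min", "max")]
#' @export
summarize_design_table <- function(design_plus_growth) {
  for (col in c("od_final", "mu_max")) {
    if (!col %in% names(design_plus_growth) ||
        !is.numeric(design_plus_growth[[col]])) {
      stop("missing or non-numeric column: ", col)
    }
  }
  if (nrow(design_plus_growth) == 0) stop("empty table")
  out <- lapply(c(od_final = "od_final", mu_max = "mu_max"), function(col) {
    v <- design_plus_growth[[col]]
    id <- design_plus_growth$fermentation_id
    list(min = min(v), max = max(v),
         id_min = id[which.min(v)], id_max = id[which.max(v)])
  })
  out
}
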