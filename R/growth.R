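#' Maximum specific growth rate from an OD curve
#'
#' Estimates mu_max (per hour) as the maximum, over all sliding windows of
#' `window` consecutive points, of the ordinary-least-squares slope of
#' ln(OD) versus time. Windows containing non-positive OD are skipped. The
#' estimate is floored at zero.
#'
#' @param times Sampling times in hours, strictly increasing.
#' @param od OD600 readings, same length as `times`.
#' @param window Number of points per regression window (>= 3).
#' @return mu_max in h^-1.
#' @examples
#' t <- 0:4
#' estimate_mu_max(t, 0.05 * exp(1.0 * t)) # exactly 1
#' @export
estimate_mu_max <- function(times, od, window = 4) {
  stopifnot(window >= 3, length(times) == length(od))
  if (length(times) < window) stop("curve shorter than the fitting window")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  n <- length(times)
  best <- -Inf
  for (i in seq_len(n - window + 1)) {
    idx <- i:(i + window - 1)
    if (any(od[idx] <= 0)) next
    x <- times[idx]
    y <- log(od[idx])
    best <- max(best, sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2))
  }
  if (!is.finite(best)) stop("no window with all-positive OD values")
  max(best, 0)
}

#' Growth summaries per fermentation
#'
#' @param curves Long growth-curve table (`fermentation_id`, `time_h`,
#'   `od600`).
#' @param window Sliding-window width passed to [estimate_mu_max()].
#' @return A `data.frame` with `fermentation_id`, `mu_max` (h^-1) and
#'   `od_final` (last OD of each curve).
#' @export
growth_summaries <- function(curves, window = 4) {
  stopifnot(all(c("fermentation_id", "time_h", "od600") %in% names(curves)))
  ids <- unique(curves$fermentation_id)
  out <- lapply(ids, function(id) {
    cc <- curves[curves$fermentation_id == id, ]
    cc <- cc[order(cc$time_h), ]
    data.frame(
      fermentation_id = id,
      mu_max = estimate_mu_max(cc$time_h, cc$od600, window),
      od_final = cc$od600[nrow(cc)]
    )
  })
  do.call(rbind, out)
}

#' Stress robustness from CFU records
#'
#' Robustness is the difference of log10 CFU/ml after stress (Nt) and before
#' stress (N0); per-replicate log10 ratios are averaged arithmetically, and
#' the survival percentage is `100 * 10^robustness`. Entries at t = 0 are 0
#' by definition of N0. Replicates with `nt = 0` are below the detection
#' limit of the plating assay: they are dropped from the average with a
#' warning and the entry is flagged (`below_detection`), with `NA` robustness
#' if no replicate was countable.
#'
#' @param records CFU table with columns `fermentation_id`, `stress`,
#'   `time_min`, `replicate`, `n0_cfu_per_ml`, `nt_cfu_per_ml`.
#' @return A `data.frame` with one row per fermentation x stress x time
#'   point: `robustness_log10`, `survival_pct`, `n_replicates`,
#'   `below_detection`.
#' @examples
#' rec <- data.frame(fermentation_id = 1, stress = "heat", time_min = 30,
#'                   replicate = 1, n0_cfu_per_ml = 1e8, nt_cfu_per_ml = 1e5)
#' compute_robustness(rec) # robustness -3, survival 0.1%
#' @export
compute_robustness <- function(records) {
  need <- c("fermentation_id", "stress", "time_min", "replicate",
            "n0_cfu_per_ml", "nt_cfu_per_ml")
  stopifnot(all(need %in% names(records)))
  if (any(records$n0_cfu_per_ml <= 0)) stop("n0 must be positive")
  if (any(records$nt_cfu_per_ml < 0)) stop("nt must be non-negative")

  key <- interaction(records$fermentation_id, records$stress,
                     records$time_min, drop = TRUE)
  groups <- split(records, key)
  out <- lapply(groups, function(g) {
    countable <- g$nt_cfu_per_ml > 0
    below <- any(!countable)
    rob <- if (g$time_min[1] == 0) {
      0
    } else if (any(countable)) {
      mean(log10(g$nt_cfu_per_ml[countable]) - log10(g$n0_cfu_per_ml[countable]))
    } else {
      NA_real_
    }
    data.frame(
      fermentation_id = g$fermentation_id[1],
      stress = g$stress[1],
      time_min = g$time_min[1],
      robustness_log10 = rob,
      survival_pct = 100 * 10^rob,
      n_replicates = nrow(g),
      below_detection = below
    )
  })
  res <- do.call(rbind, out)
  res <- res[order(res$stress, res$time_min, res$fermentation_id), ]
  rownames(res) <- NULL
  if (any(res$below_detection)) {
    warning(sum(res$below_detection),
            " condition(s) had replicates below the CFU detection limit")
  }
  res
}

#' Pearson correlation between two robustness vectors
#'
#' Used for the 30-vs-60-minute and heat-vs-oxidative comparisons. Returns
#' the Pearson correlation coefficient with its two-sided p-value.
#'
#' @param x,y Numeric vectors of equal length (>= 3), finite values.
#' @return A list with `r`, `p_value`, `n`, and `flagged` (`TRUE` when a
#'   vector has zero variance, in which case `r`/`p_value` are `NA`).
#' @examples
#' correlate_profiles(1:10, 2 * (1:10) + 1)$r # 1
#' @export
correlate_profiles <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("fewer than 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = length(x), flagged = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       flagged = FALSE)
}

#' Effect of one fermentation parameter on a phenotype
#'
#' Welch two-sample t-test comparing a per-fermentation phenotype (e.g.
#' mu_max, OD_final, or robustness at one stress/time point) between two
#' levels of one process parameter, with all other parameters varying in the
#' background as laid out by the combinatorial design.
#'
#' @param design Fermentation design table.
#' @param values Named or design-ordered numeric vector, one value per
#'   fermentation in `design`.
#' @param factor Design column name (`nacl_mM`, `start_pH`, `temperature_C`,
#'   `aeration`).
#' @param level_a,level_b The two levels to compare.
#' @param alpha Significance level (default 0.05).
#' @return A list: `t_statistic`, `p_value`, `direction` (the level with the
#'   larger mean), `mean_a`, `mean_b`, `significant`.
#' @examples
#' tab <- mg1363_design_growth()
#' test_parameter_effect(tab, tab$mu_max, "temperature_C", 27, 35)
#' @export
test_parameter_effect <- function(design, values, factor, level_a, level_b,
                                  alpha = 0.05) {
  stopifnot(factor %in% names(design), length(values) == nrow(design))
  a <- values[design[[factor]] == level_a]
  b <- values[design[[factor]] == level_b]
  if (length(a) < 2 || length(b) < 2) {
    stop("need >= 2 fermentations at each level of ", factor)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(
    t_statistic = unname(tt$statistic),
    p_value = tt$p.value,
    direction = if (mean(a) >= mean(b)) level_a else level_b,
    mean_a = mean(a), mean_b = mean(b),
    significant = tt$p.value < alpha
  )
}

#' Extract one robustness vector aligned to a design
#'
#' @param profile Output of [compute_robustness()].
#' @param stress `"heat"` or `"oxidative"`.
#' @param time_min Time point in minutes.
#' @param fermentation_ids Ids defining the order (default: order found in
#'   the profile).
#' @return Named numeric vector of robustness (log10) values; entries flagged
#'   below detection are `NA`.
#' @export
robustness_vector <- function(profile, stress, time_min,
                              fermentation_ids = NULL) {
  sel <- profile[profile$stress == stress & profile$time_min == time_min, ]
  if (nrow(sel) == 0) stop("no robustness entries for ", stress, " at ",
                           time_min, " min")
  if (is.null(fermentation_ids)) fermentation_ids <- sel$fermentation_id
  v <- sel$robustness_log10[match(fermentation_ids, sel$fermentation_id)]
  names(v) <- fermentation_ids
  v
}
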