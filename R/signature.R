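#' Selection criterion for robustness signatures
#'
#' A gene enters a stress signature when its expression correlates with
#' robustness at both stress time points (each `p < alpha`) and the product
#' of the two p-values falls below `product_cutoff`. Both inequalities are
#' strict.
#'
#' @param alpha Per-time-point significance threshold.
#' @param product_cutoff Threshold on `p30 * p60`.
#' @return A list of class `"selection_criterion"`.
#' @export
selection_criterion <- function(alpha = 0.05, product_cutoff = 5e-5) {
  stopifnot(alpha > 0, alpha <= 1, product_cutoff > 0, product_cutoff <= 1)
  structure(list(alpha = alpha, product_cutoff = product_cutoff),
            class = "selection_criterion")
}

#' Linear-model correlation of one gene with robustness
#'
#' Ordinary least squares of expression (log2) on robustness (log10): slope,
#' Pearson correlation coefficient, and the two-sided p-value of the slope
#' test (identical to the Pearson correlation test). Duplicated fermentation
#' conditions enter as individual samples.
#'
#' @param expr_row Per-fermentation log2 expression values.
#' @param robustness Per-fermentation log10 robustness values.
#' @return A list: `slope` (log2 units per log10 robustness unit), `r`,
#'   `p_value`, `n`, `flagged` (`TRUE` if either vector has zero variance;
#'   statistics are then `NA`).
#' @examples
#' rob <- seq(-3, 0, length.out = 13)
#' correlate_gene(2 * rob + 1, rob) # slope 2, r 1
#' @export
correlate_gene <- function(expr_row, robustness) {
  stopifnot(length(expr_row) == length(robustness))
  ok <- is.finite(expr_row) & is.finite(robustness)
  x <- robustness[ok]; y <- expr_row[ok]
  if (length(x) < 4) stop("fewer than 4 paired finite observations")
  res <- correlate_rows(base::matrix(y, nrow = 1), x)
  list(slope = res$slope[1], r = res$r[1], p_value = res$p_value[1],
       n = length(x), flagged = res$flagged[1])
}

# Vectorized closed-form OLS of each row of `mat` on `x`: slope, Pearson r,
# and the two-sided t-test p-value on n - 2 df. Rows (or x) with zero
# variance are flagged with NA statistics.
correlate_rows <- function(mat, x) {
  n <- length(x)
  stopifnot(ncol(mat) == n, n >= 3)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  ym <- rowMeans(mat)
  sxy <- as.vector((mat - ym) %*% xc)
  syy <- rowSums((mat - ym)^2)
  flagged <- syy == 0 | sxx == 0
  slope <- sxy / sxx
  r <- sxy / sqrt(sxx * syy)
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  slope[flagged] <- r[flagged] <- p[flagged] <- NA_real_
  list(slope = slope, r = r, p_value = p, flagged = flagged)
}

#' Dual-time-point p-value-product selection
#'
#' @param p30,p60 P-values at the 30 and 60 minute time points (vectors of
#'   equal length, values in \[0, 1\]).
#' @param crit A [selection_criterion()].
#' @return A list with `selected` (logical) and `product` (`p30 * p60`).
#'   Selection requires `p30 < alpha`, `p60 < alpha` and
#'   `product < product_cutoff`, all strict.
#' @examples
#' apply_criterion(0.04, 0.001, selection_criterion()) # selected, 4e-5
#' @export
apply_criterion <- function(p30, p60, crit = selection_criterion()) {
  stopifnot(inherits(crit, "selection_criterion"), length(p30) == length(p60))
  stopifnot(all(p30 >= 0 & p30 <= 1, na.rm = TRUE),
            all(p60 >= 0 & p60 <= 1, na.rm = TRUE))
  product <- p30 * p60
  selected <- !is.na(product) & p30 < crit$alpha & p60 < crit$alpha &
    product < crit$product_cutoff
  list(selected = selected, product = product)
}

#' Build a robustness transcriptome signature for one stress
#'
#' Correlates every gene's expression with robustness at the 30 and 60
#' minute time points of one stress, applies the dual-time-point
#' p-value-product criterion, and assigns each selected gene a direction
#' from its slope sign. Genes whose slope signs disagree between the two
#' time points are flagged discordant and never selected. The signature is
#' ordered by ascending p-value product (most significant first).
#'
#' @param expr ORF x fermentation expression matrix (log2), columns named by
#'   fermentation id.
#' @param profile Robustness profile from [compute_robustness()] (or any
#'   table with `fermentation_id`, `stress`, `time_min`, `robustness_log10`).
#' @param stress `"heat"` or `"oxidative"`.
#' @param crit A [selection_criterion()].
#' @return A `data.frame` of class `"signature_set"` with one row per gene:
#'   `gene_id`, `slope_30`, `p_30`, `slope_60`, `p_60`, `product`,
#'   `direction` (`"positive"`/`"negative"`), `discordant`, `selected`;
#'   attribute `"stress"`. Rows with `selected = TRUE`, sorted by `product`,
#'   form the signature; the full table is returned for inspection.
#' @export
build_signature <- function(expr, profile, stress,
                            crit = selection_criterion()) {
  stopifnot(is.matrix(expr))
  ids <- colnames(expr)
  r30 <- robustness_vector(profile, stress, 30L, ids)
  r60 <- robustness_vector(profile, stress, 60L, ids)
  ok <- is.finite(r30) & is.finite(r60)
  if (sum(ok) < 4) stop("fewer than 4 fermentations with finite robustness")
  c30 <- correlate_rows(expr[, ok, drop = FALSE], r30[ok])
  c60 <- correlate_rows(expr[, ok, drop = FALSE], r60[ok])
  sel <- apply_criterion(c30$p_value, c60$p_value, crit)
  discordant <- !is.na(c30$slope) & !is.na(c60$slope) &
    sign(c30$slope) != sign(c60$slope) & sign(c30$slope) != 0 &
    sign(c60$slope) != 0
  out <- data.frame(
    gene_id = rownames(expr),
    slope_30 = c30$slope, p_30 = c30$p_value,
    slope_60 = c60$slope, p_60 = c60$p_value,
    product = sel$product,
    direction = ifelse(c30$slope >= 0, "positive", "negative"),
    discordant = discordant,
    selected = sel$selected & !discordant
  )
  out <- out[order(out$product), ]
  rownames(out) <- NULL
  structure(out, stress = stress, criterion = crit,
            class = c("signature_set", "data.frame"))
}

#' Genes selected by a signature
#'
#' @param sig A `"signature_set"` (from [build_signature()]) or a
#'   `data.frame` with `gene_id` and `direction` columns (e.g. a published
#'   signature table), in which case all rows count as selected.
#' @return `data.frame(gene_id, direction)` in signature order.
#' @export
signature_genes <- function(sig) {
  d <- as.data.frame(sig)
  if ("selected" %in% names(d)) d <- d[d$selected, ]
  stopifnot(all(c("gene_id", "direction") %in% names(d)))
  d[, c("gene_id", "direction")]
}

#' Cross-stress signature intersection
#'
#' Identifier intersection of two signatures, preserving each signature's
#' direction label (genes can correlate positively with one stress and
#' negatively with the other).
#'
#' @param a,b Signatures (see [signature_genes()] for accepted forms).
#' @return `data.frame(gene_id, direction_a, direction_b)`.
#' @export
intersect_signatures <- function(a, b) {
  ga <- signature_genes(a); gb <- signature_genes(b)
  common <- intersect(ga$gene_id, gb$gene_id)
  data.frame(
    gene_id = common,
    direction_a = ga$direction[match(common, ga$gene_id)],
    direction_b = gb$direction[match(common, gb$gene_id)]
  )
}

#' Count positive and negative correlations in a signature
#'
#' @param sig Signature (see [signature_genes()]).
#' @return Named integer vector `c(n_positive, n_negative)`.
#' @export
summarize_signs <- function(sig) {
  g <- signature_genes(sig)
  c(n_positive = sum(g$direction == "positive"),
    n_negative = sum(g$direction == "negative"))
}

#' Closed-form null pass rate of the selection criterion
#'
#' For independent uniform p-values, the probability that a gene passes the
#' dual-time-point criterion is the area of the region `{p < alpha, q <
#' alpha, pq < c}`: `c * (1 + log(alpha^2 / c))` when `c < alpha^2`, and
#' `alpha^2` otherwise (the product constraint is then inactive).
#'
#' @param crit A [selection_criterion()].
#' @return Probability in \[0, 1\].
#' @examples
#' null_selection_rate(selection_criterion(0.05, 5e-5)) # ~2.456e-4
#' @export
null_selection_rate <- function(crit = selection_criterion()) {
  a <- crit$alpha; cc <- crit$product_cutoff
  if (cc >= a^2) a^2 else cc * (1 + log(a^2 / cc))
}

#' Monte-Carlo null pass rate of the selection criterion
#'
#' Fraction of independent uniform p-value pairs passing
#' [apply_criterion()]; a calibration oracle for [null_selection_rate()].
#'
#' @param crit A [selection_criterion()].
#' @param n_pairs Number of simulated pairs (>= 1e4).
#' @param seed Integer seed.
#' @return The pass fraction.
#' @export
null_selection_probability <- function(crit = selection_criterion(),
                                       n_pairs = 1e6, seed = 1L) {
  stopifnot(n_pairs >= 1e4)
  withr::with_seed(as.integer(seed), {
    p30 <- stats::runif(n_pairs)
    p60 <- stats::runif(n_pairs)
    mean(apply_criterion(p30, p60, crit)$selected)
  })
}
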