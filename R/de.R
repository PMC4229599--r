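#' Differential expression by one fermentation parameter
#'
#' Per-gene Welch two-sample t-test comparing expression between the
#' fermentations at two levels of one process parameter, with the remaining
#' parameters varying in the background per the combinatorial design. Genes
#' are called differentially expressed at raw `p < alpha` (no
#' multiple-testing correction by default, matching the reporting convention
#' for this assay; set `adjust = "BH"` for Benjamini-Hochberg).
#'
#' @param expr ORF x fermentation expression matrix (log2), columns named by
#'   fermentation id.
#' @param design Fermentation design table.
#' @param factor Design column name.
#' @param level_a,level_b Levels to compare.
#' @param alpha DE call threshold on (possibly adjusted) p-values.
#' @param adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return A list of class `"de_result"`: `factor`, `level_a`, `level_b`,
#'   `p_value` (named per gene; `NA` where a gene had zero within-group
#'   variance and was excluded), `de_genes` (character vector), `alpha`,
#'   `universe`.
#' @export
de_by_parameter <- function(expr, design, factor, level_a, level_b,
                            alpha = 0.05, adjust = "none") {
  stopifnot(is.matrix(expr), factor %in% names(design))
  cols_a <- as.character(design$fermentation_id[design[[factor]] == level_a])
  cols_b <- as.character(design$fermentation_id[design[[factor]] == level_b])
  stopifnot(all(c(cols_a, cols_b) %in% colnames(expr)))
  if (length(cols_a) < 2 || length(cols_b) < 2) {
    stop("need >= 2 fermentations at each level of ", factor)
  }
  a <- expr[, cols_a, drop = FALSE]
  b <- expr[, cols_b, drop = FALSE]
  p <- vapply(seq_len(nrow(expr)), function(i) {
    tryCatch(stats::t.test(a[i, ], b[i, ], var.equal = FALSE)$p.value,
             error = function(e) NA_real_)
  }, numeric(1))
  names(p) <- rownames(expr)
  p_used <- if (identical(adjust, "none")) p else stats::p.adjust(p, adjust)
  structure(list(
    factor = factor, level_a = level_a, level_b = level_b,
    p_value = p, de_genes = names(p_used)[!is.na(p_used) & p_used < alpha],
    alpha = alpha, universe = rownames(expr)
  ), class = "de_result")
}

#' DE sets for every parameter contrast of a design
#'
#' Runs [de_by_parameter()] for each two-level parameter and for all pairs
#' of temperature levels. Contrast names are `factor:level_a-vs-level_b`.
#'
#' @inheritParams de_by_parameter
#' @param factors Design columns to analyze.
#' @return Named list of `"de_result"` objects.
#' @export
de_all_parameters <- function(expr, design,
                              factors = c("nacl_mM", "start_pH",
                                          "temperature_C", "aeration"),
                              alpha = 0.05, adjust = "none") {
  results <- list()
  for (f in factors) {
    lv <- sort(unique(design[[f]]))
    pairs <- utils::combn(length(lv), 2, simplify = FALSE)
    for (pr in pairs) {
      la <- lv[pr[1]]; lb <- lv[pr[2]]
      nm <- paste0(f, ":", la, "-vs-", lb)
      results[[nm]] <- de_by_parameter(expr, design, f, la, lb,
                                       alpha = alpha, adjust = adjust)
    }
  }
  results
}

#' Pairwise overlap of DE gene sets
#'
#' For every ordered pair of DE sets, the number of genes differentially
#' expressed by both contrasts and the percentage of the row set that is
#' shared (`100 * |A intersect B| / |A|`, 0 when the row set is empty). The
#' count matrix is symmetric with set sizes on the diagonal; the percentage
#' matrix is row-denominated and therefore asymmetric.
#'
#' @param results List of `"de_result"` objects (or plain character vectors
#'   of gene ids) over a common gene universe.
#' @return A list of class `"overlap_matrix"` with `count` and `pct`
#'   matrices and `sizes`.
#' @examples
#' overlap_matrix(list(A = c("g1", "g2"), B = c("g2", "g3")))$count
#' @export
overlap_matrix <- function(results) {
  stopifnot(length(results) >= 2)
  sets <- lapply(results, function(r) {
    if (inherits(r, "de_result")) r$de_genes else as.character(r)
  })
  k <- length(sets)
  nms <- names(sets)
  if (is.null(nms)) nms <- paste0("set", seq_len(k))
  count <- matrix(0L, k, k, dimnames = list(nms, nms))
  pct <- matrix(0, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      count[i, j] <- length(intersect(sets[[i]], sets[[j]]))
      pct[i, j] <- if (length(sets[[i]]) == 0) 0 else
        100 * count[i, j] / length(sets[[i]])
    }
  }
  structure(list(count = count, pct = pct, sizes = lengths(sets)),
            class = "overlap_matrix")
}
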