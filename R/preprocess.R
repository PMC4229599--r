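#' MA transform of a two-channel probe table
#'
#' Computes, per probe and array, the log ratio `M = log2(sample) -
#' log2(reference)` and the mean log intensity `A = (log2(sample) +
#' log2(reference)) / 2`. Probes with a zero channel on an array are flagged
#' and excluded downstream.
#'
#' @param table Probe table with columns `array_id`, `probe_id`, `orf_id`,
#'   `channel_sample`, `channel_reference` (non-negative).
#' @return A `data.frame` of class `"ma_matrix"` with columns `array_id`,
#'   `probe_id`, `orf_id`, `M`, `A`, `flagged`.
#' @examples
#' tab <- data.frame(array_id = 1, probe_id = "p1", orf_id = "g1",
#'                   channel_sample = 400, channel_reference = 100)
#' ma_transform(tab)$M # 2
#' @export
ma_transform <- function(table) {
  need <- c("array_id", "probe_id", "orf_id", "channel_sample",
            "channel_reference")
  stopifnot(all(need %in% names(table)))
  if (any(table$channel_sample < 0) || any(table$channel_reference < 0)) {
    stop("channel intensities must be non-negative")
  }
  flagged <- table$channel_sample == 0 | table$channel_reference == 0
  s <- log2(ifelse(flagged, NA, table$channel_sample))
  r <- log2(ifelse(flagged, NA, table$channel_reference))
  out <- data.frame(
    array_id = table$array_id, probe_id = table$probe_id,
    orf_id = table$orf_id,
    M = s - r, A = (s + r) / 2, flagged = flagged
  )
  bad <- tapply(out$flagged, out$array_id, all)
  if (any(bad)) {
    stop("all probes flagged on array(s): ",
         paste(names(bad)[bad], collapse = ", "))
  }
  class(out) <- c("ma_matrix", "data.frame")
  out
}

#' Lowess normalization of M on A, per array
#'
#' Removes the intensity-dependent dye-bias trend by subtracting, per array,
#' a lowess fit of M versus A (Cleveland's locally weighted regression with
#' robustifying iterations, via [stats::lowess()]) evaluated at each probe's
#' A.
#'
#' @param matrix An `"ma_matrix"` from [ma_transform()].
#' @param span Lowess smoother span in (0, 1].
#' @param iter Robustifying iterations.
#' @return The input with `M` replaced by the corrected values (A and
#'   flags untouched).
#' @export
lowess_normalize <- function(matrix, span = 0.4, iter = 3) {
  stopifnot(inherits(matrix, "ma_matrix"), span > 0, span <= 1)
  out <- matrix
  for (id in unique(out$array_id)) {
    i <- which(out$array_id == id & !out$flagged)
    if (length(i) < 20) stop("fewer than 20 unflagged probes on array ", id)
    a <- out$A[i]; m <- out$M[i]
    if (diff(range(a)) == 0) stop("degenerate A values on array ", id)
    fit <- stats::lowess(a, m, f = span, iter = iter)
    trend <- stats::approx(fit$x, fit$y, xout = a, rule = 2, ties = mean)$y
    out$M[i] <- m - trend
  }
  out
}

#' Residual intensity trend after normalization
#'
#' Refits a lowess curve of M on A and reports its maximum absolute value
#' over the well-sampled part of the intensity range (inner quantiles of A).
#' Used to verify that [lowess_normalize()] removed the dye bias.
#'
#' @param matrix An `"ma_matrix"`.
#' @param span,iter Lowess parameters (as in [lowess_normalize()]).
#' @param trim Tail fraction of A excluded on each side.
#' @return Named numeric vector, one residual amplitude per array.
#' @export
residual_trend <- function(matrix, span = 0.4, iter = 3, trim = 0.05) {
  stopifnot(inherits(matrix, "ma_matrix"))
  vapply(split(matrix[!matrix$flagged, ], matrix$array_id[!matrix$flagged]),
         function(d) {
           fit <- stats::lowess(d$A, d$M, f = span, iter = iter)
           q <- stats::quantile(d$A, c(trim, 1 - trim))
           keep <- fit$x >= q[1] & fit$x <= q[2]
           max(abs(fit$y[keep]))
         }, numeric(1))
}

#' Scale arrays to zero median and unit MAD
#'
#' Makes arrays comparable by rescaling each array's corrected M values to
#' median 0 and median absolute deviation 1 (`mad(..., constant = 1)`).
#'
#' @param matrix An `"ma_matrix"` (normally after [lowess_normalize()]).
#' @return The input with `M` rescaled per array.
#' @export
scale_arrays <- function(matrix) {
  stopifnot(inherits(matrix, "ma_matrix"))
  out <- matrix
  for (id in unique(out$array_id)) {
    i <- which(out$array_id == id & !out$flagged)
    med <- stats::median(out$M[i])
    s <- stats::mad(out$M[i], constant = 1)
    if (s == 0) stop("zero MAD on array ", id)
    out$M[i] <- (out$M[i] - med) / s
  }
  out
}

#' Median-summarize probes to ORF expression
#'
#' The expression level of an ORF on an array is the median of its unflagged
#' probes' corrected M values — the 2-log expression matrix consumed by all
#' downstream analyses. ORFs lacking an unflagged probe on some array are
#' dropped with a warning.
#'
#' @param matrix An `"ma_matrix"`.
#' @param map Optional probe->ORF map (`data.frame(probe_id, orf_id)`);
#'   defaults to the mapping carried in `matrix`.
#' @return A numeric matrix, ORFs x arrays, with `dimnames`.
#' @examples
#' tab <- data.frame(array_id = 1, probe_id = c("p1", "p2", "p3"),
#'                   orf_id = "g1", channel_sample = 2^c(1, 2, 10) * 100,
#'                   channel_reference = 100)
#' summarize_probes_to_orfs(ma_transform(tab)) # median of 1, 2, 10 -> 2
#' @export
summarize_probes_to_orfs <- function(matrix, map = NULL) {
  stopifnot(inherits(matrix, "ma_matrix"))
  if (!is.null(map)) {
    stopifnot(all(c("probe_id", "orf_id") %in% names(map)))
    if (nrow(map) == 0) stop("empty probe->ORF map")
    matrix$orf_id <- map$orf_id[match(matrix$probe_id, map$probe_id)]
    if (anyNA(matrix$orf_id)) stop("probes missing from the probe->ORF map")
  }
  d <- matrix[!matrix$flagged, ]
  arrays <- unique(matrix$array_id)
  orfs <- unique(matrix$orf_id)
  if (length(orfs) == 0) stop("empty probe->ORF map")
  expr <- base::matrix(NA_real_, nrow = length(orfs), ncol = length(arrays),
                       dimnames = list(orfs, as.character(arrays)))
  med <- tapply(d$M, list(factor(d$orf_id, levels = orfs),
                          factor(as.character(d$array_id),
                                 levels = as.character(arrays))),
                stats::median)
  expr[rownames(med), colnames(med)] <- med
  incomplete <- rowSums(is.na(expr)) > 0
  if (any(incomplete)) {
    warning("dropping ", sum(incomplete),
            " ORF(s) without an unflagged probe on every array")
    expr <- expr[!incomplete, , drop = FALSE]
  }
  expr
}

#' Probe intensities to ORF expression matrix
#'
#' End-to-end preprocessing: MA transform, per-array lowess dye-bias
#' normalization, per-array median/MAD scaling, and median probe-to-ORF
#' summarization. The normalization and scaling steps can be disabled (e.g.
#' when analyzing data known to be bias-free).
#'
#' @param table Probe intensity table (see [ma_transform()]).
#' @param span Lowess span.
#' @param normalize,scale Logical switches for the two normalization steps.
#' @return ORF x array expression matrix (log2 scale).
#' @export
preprocess_probes <- function(table, span = 0.4, normalize = TRUE,
                              scale = TRUE) {
  ma <- ma_transform(table)
  if (normalize) ma <- lowess_normalize(ma, span = span)
  if (scale) ma <- scale_arrays(ma)
  summarize_probes_to_orfs(ma)
}
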