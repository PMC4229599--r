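#' Generate a combinatorial fermentation design
#'
#' Returns one row per fermentation, each a combination of the four process
#' parameters. With the default level sets and `n_fermentations = 13` the
#' canonical 12-condition layout plus one duplicated condition is returned
#' (the layout used for *L. lactis* MG1363, in which the duplicate pair is
#' fermentations 6 and 13). When `n_fermentations` equals the number of
#' distinct level combinations, the full factorial is returned, each
#' combination once. Otherwise combinations are sampled without replacement
#' under a coverage constraint: every level of every factor must appear in at
#' least two rows when `n_fermentations >= 12` (at least once otherwise).
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` with columns `fermentation_id`, `nacl_mM`,
#'   `start_pH`, `temperature_C`, `aeration`.
#' @examples
#' head(generate_design(sim_config(seed = 1)))
#' @export
generate_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lv <- config$factor_levels
  n <- config$n_fermentations
  full <- expand.grid(lv, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_full <- nrow(full)

  if (n == 13 && identical(lapply(lv, sort), lapply(sim_config()$factor_levels, sort))) {
    des <- canonical_design()
  } else if (n == n_full) {
    des <- full
  } else {
    min_cover <- if (n >= 12) 2L else 1L
    needed <- max(vapply(lv, length, 1L)) * min_cover
    if (n < needed) {
      stop("cannot cover every factor level ", min_cover,
           " time(s) with ", n, " fermentations (need >= ", needed, ")")
    }
    des <- withr::with_seed(sim_seed(config, 11L), {
      sample_covered_design(full, n, min_cover)
    })
  }
  des <- cbind(fermentation_id = seq_len(nrow(des)), des)
  rownames(des) <- NULL
  des
}

# Rejection-sample rows of the full factorial until every level of every
# factor appears at least min_cover times.
sample_covered_design <- function(full, n, min_cover, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    idx <- if (n <= nrow(full)) {
      sample.int(nrow(full), n)
    } else {
      c(seq_len(nrow(full)), sample.int(nrow(full), n - nrow(full), replace = TRUE))
    }
    cand <- full[idx, , drop = FALSE]
    ok <- all(vapply(names(full), function(f) {
      tab <- table(factor(cand[[f]], levels = unique(full[[f]])))
      all(tab >= min_cover)
    }, logical(1)))
    if (ok) return(cand)
  }
  stop("could not satisfy level coverage after ", max_tries, " draws; ",
       "increase n_fermentations")
}

# The 13-row combinatorial layout: 12 distinct conditions + a duplicate of
# row 6 appended as row 13.
canonical_design <- function() {
  data.frame(
    nacl_mM = c(0, 100, 0, 100, 0, 100, 0, 100, 0, 100, 0, 100, 100),
    start_pH = c(6.0, 6.5, 6.5, 6.0, 6.0, 6.5, 6.5, 6.0, 6.0, 6.5, 6.5, 6.0, 6.5),
    temperature_C = c(27, 27, 27, 27, 30, 30, 30, 30, 35, 35, 35, 35, 30),
    aeration = c("+", "+", "-", "-", "-", "-", "+", "+", "+", "+", "-", "-", "-"),
    stringsAsFactors = FALSE
  )
}
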