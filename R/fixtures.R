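#' Published MG1363 fermentation design and growth characteristics
#'
#' The 13-fermentation combinatorial design for *Lactococcus lactis* MG1363
#' with the measured growth characteristics: salt addition (0/100 mM NaCl),
#' starting pH (6.0/6.5), temperature (27/30/35 degrees C), aeration
#' (shaken `+` / static `-`), final OD600 and maximum specific growth rate
#' (h^-1). Fermentations 6 and 13 are duplicates of the same condition.
#'
#' @return A `data.frame` with columns `fermentation_id`, `nacl_mM`,
#'   `start_pH`, `temperature_C`, `aeration`, `od_final`, `mu_max`.
#' @examples
#' range(mg1363_design_growth()$mu_max)
#' @export
mg1363_design_growth <- function() {
  utils::read.delim(
    system.file("extdata", "mg1363_design_growth.tsv",
                package = "robustmatch"),
    colClasses = c(aeration = "character")
  )
}

#' Published MG1363 robustness signature gene lists
#'
#' The genes whose expression across the 13 MG1363 fermentations correlated
#' with robustness towards heat stress (18 genes) or oxidative stress (54
#' genes) at both the 30 and 60 minute time points under the
#' p-value-product criterion, with the reported correlation direction.
#'
#' @param stress `"heat"` or `"oxidative"`.
#' @return A `data.frame` with columns `gene_id` (llmg locus tag),
#'   `gene_name` (may be empty) and `direction`, usable directly with
#'   [intersect_signatures()] and [summarize_signs()].
#' @examples
#' summarize_signs(mg1363_signature("heat")) # 13 positive, 5 negative
#' @export
mg1363_signature <- function(stress = c("heat", "oxidative")) {
  stress <- match.arg(stress)
  utils::read.delim(
    system.file("extdata", paste0("mg1363_", stress, "_signature.tsv"),
                package = "robustmatch"),
    na.strings = NULL, colClasses = "character"
  )
}
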