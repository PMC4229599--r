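test_that("gene correlation is exact on a perfect line and flags constants", {
  rob <- seq(-3, 0, length.out = 13)
  r <- correlate_gene(2 * rob + 1, rob)
  expect_equal(r$slope, 2)
  expect_equal(r$r, 1)
  expect_lt(r$p_value, 1e-12)

  flat <- correlate_gene(rep(1.5, 13), rob)
  expect_true(flat$flagged)
  expect_true(is.na(flat$p_value))
  expect_error(correlate_gene(1:3, 1:3), "fewer than 4")
})

test_that("slope-test p equals the Pearson correlation p and lm, both orientations", {
  set.seed(61)
  for (i in 1:30) {
    x <- rnorm(13)
    y <- rnorm(13)
    r <- correlate_gene(y, x)
    expect_equal(r$p_value, cor.test(x, y)$p.value, tolerance = 1e-10)
    fit <- summary(lm(y ~ x))$coefficients
    expect_equal(r$slope, fit[2, 1], tolerance = 1e-10)
    expect_equal(r$p_value, fit[2, 4], tolerance = 1e-10)
    # orientation invariance of the p-value (regression of x on y)
    expect_equal(correlate_gene(x, y)$p_value, r$p_value, tolerance = 1e-10)
  }
})

test_that("slope sign and p-value are invariant to positive affine rescaling of robustness", {
  set.seed(62)
  x <- rnorm(13)
  y <- 0.8 * x + rnorm(13, sd = 0.3)
  a <- correlate_gene(y, x)
  b <- correlate_gene(y, 2.5 * x + 7)
  expect_equal(sign(a$slope), sign(b$slope))
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$r, b$r, tolerance = 1e-12)
})

test_that("the dual-time-point criterion applies both thresholds strictly", {
  crit <- selection_criterion(alpha = 0.05, product_cutoff = 5e-5)
  r <- apply_criterion(c(0.04, 0.2, 0.04), c(0.001, 1e-5, 0.04), crit)
  expect_equal(r$selected, c(TRUE, FALSE, FALSE))
  expect_equal(r$product, c(4e-5, 2e-6, 1.6e-3))
  # boundary: products and p-values exactly at the cutoffs are excluded
  at <- apply_criterion(0.05, 1e-9, crit)
  expect_false(at$selected)
  # product exactly at the cutoff (exact in binary floating point)
  expect_false(apply_criterion(0.5, 0.5, selection_criterion(1, 0.25))$selected)
})

test_that("the criterion is monotone: lowering either p never de-selects", {
  crit <- selection_criterion()
  set.seed(63)
  p30 <- runif(500); p60 <- runif(500)
  sel <- apply_criterion(p30, p60, crit)$selected
  shrunk <- apply_criterion(p30 * runif(500), p60, crit)$selected
  expect_true(all(shrunk[sel]))
  shrunk2 <- apply_criterion(p30, p60 * runif(500), crit)$selected
  expect_true(all(shrunk2[sel]))
})

test_that("Monte-Carlo null pass rate matches the closed form", {
  crit <- selection_criterion(0.05, 5e-5)
  closed <- null_selection_rate(crit)
  expect_equal(closed, 5e-5 * (1 + log(0.05^2 / 5e-5)))
  mc <- null_selection_probability(crit, n_pairs = 2e5, seed = 64)
  se <- sqrt(closed * (1 - closed) / 2e5)
  expect_lt(abs(mc - closed), 3 * se)

  # product constraint inactive when c >= alpha^2
  loose <- selection_criterion(0.05, 0.01)
  expect_equal(null_selection_rate(loose), 0.05^2)
  mc2 <- null_selection_probability(loose, n_pairs = 1e5, seed = 65)
  expect_lt(abs(mc2 - 0.0025), 3 * sqrt(0.0025 / 1e5))
  expect_equal(null_selection_rate(selection_criterion(1, 1)), 1)
})

sig_profile <- function(r30, r60, stress = "heat") {
  ids <- seq_along(r30)
  data.frame(
    fermentation_id = rep(ids, 2), stress = stress,
    time_min = rep(c(30L, 60L), each = length(ids)),
    robustness_log10 = c(r30, r60)
  )
}

test_that("build_signature selects planted genes and orders by product", {
  set.seed(66)
  lat <- rnorm(13, -1.5, 1)
  prof <- sig_profile(lat + rnorm(13, 0, 0.1), lat - 0.7 + rnorm(13, 0, 0.1))
  expr <- matrix(rnorm(40 * 13, sd = 0.2), nrow = 40,
                 dimnames = list(sprintf("g%02d", 1:40), 1:13))
  expr["g05", ] <- expr["g05", ] + 1.2 * lat
  expr["g09", ] <- expr["g09", ] - 1.2 * lat
  sig <- build_signature(expr, prof, "heat")
  sel <- signature_genes(sig)
  expect_true(all(c("g05", "g09") %in% sel$gene_id))
  expect_equal(sel$direction[sel$gene_id == "g05"], "positive")
  expect_equal(sel$direction[sel$gene_id == "g09"], "negative")
  expect_false(is.unsorted(sig$product))
})

test_that("alpha = 1, cutoff = 1 selects every non-flagged gene", {
  set.seed(67)
  prof <- sig_profile(rnorm(13), rnorm(13))
  expr <- matrix(rnorm(25 * 13), nrow = 25,
                 dimnames = list(sprintf("g%02d", 1:25), 1:13))
  expr[3, ] <- 4  # constant -> flagged
  sig <- build_signature(expr, prof, "heat", selection_criterion(1, 1))
  # every non-flagged gene passes the thresholds; only the discordant-sign
  # exclusion (and the flagged constant gene) can keep a gene out
  expect_equal(sum(sig$selected) + sum(sig$discordant), 24)
  expect_true(all(sig$selected | sig$discordant | sig$gene_id == "g03"))
  expect_false(sig$selected[sig$gene_id == "g03"] %in% TRUE)
})

test_that("genes with discordant slope signs are never selected", {
  # robustness vectors anti-correlated between time points; a gene tracking
  # the 30-min vector then has opposite slopes at 30 and 60 min
  x <- seq(-2, 0, length.out = 13)
  prof <- sig_profile(x, rev(x))
  expr <- matrix(rnorm(5 * 13, sd = 0.05), nrow = 5,
                 dimnames = list(paste0("g", 1:5), 1:13))
  expr[1, ] <- x + rnorm(13, sd = 0.02)
  sig <- build_signature(expr, prof, "heat", selection_criterion(1, 1))
  row <- sig[sig$gene_id == "g1", ]
  expect_true(row$discordant)
  expect_false(row$selected)
  expect_lt(row$p_30, 0.05)
  expect_lt(row$p_60, 0.05)
})

test_that("planted-gene recovery meets the module thresholds on synthetic data", {
  res <- vapply(1:5, function(s) {
    cfg <- sim_config(n_genes = 400, seed = 200 + s)
    sim <- simulate_dataset(cfg)
    rob <- suppressWarnings(compute_robustness(sim$cfu))
    expr <- preprocess_probes(sim$probes)
    out <- vapply(c("heat", "oxidative"), function(st) {
      sig <- build_signature(expr, rob, st)
      hits <- signature_genes(sig)
      planted <- sim$truth$genes[sim$truth$genes$stress == st, ]
      found <- hits[hits$gene_id %in% planted$gene_id, ]
      dir_ok <- all(found$direction ==
                      ifelse(planted$slope[match(found$gene_id,
                                                 planted$gene_id)] > 0,
                             "positive", "negative"))
      c(sens = mean(planted$gene_id %in% hits$gene_id),
        fp_rate = sum(!hits$gene_id %in% planted$gene_id) /
          (cfg$n_genes - nrow(planted)),
        dir_ok = as.numeric(dir_ok))
    }, numeric(3))
    rowMeans(out)
  }, numeric(3))
  expect_gte(mean(res["sens", ]), 0.8)
  expect_lte(mean(res["fp_rate", ]), 0.01)
  expect_equal(mean(res["dir_ok", ]), 1)
})

test_that("signature intersection and sign counts reproduce the published tables", {
  heat <- mg1363_signature("heat")
  oxid <- mg1363_signature("oxidative")
  expect_equal(nrow(heat), 18)
  expect_equal(nrow(oxid), 54)

  both <- intersect_signatures(heat, oxid)
  expect_equal(nrow(both), 5)
  expect_setequal(both$gene_id,
                  c("llmg_1775", "llmg_1776", "llmg_1494", "llmg_1094",
                    "llmg_1985"))
  expect_equal(summarize_signs(heat), c(n_positive = 13L, n_negative = 5L))
  expect_equal(summarize_signs(oxid), c(n_positive = 37L, n_negative = 17L))

  expect_equal(nrow(intersect_signatures(heat[1:3, ], heat[4:6, ])), 0)
  sub <- intersect_signatures(heat[1:4, ], heat)
  expect_equal(sub$gene_id, heat$gene_id[1:4])
})
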