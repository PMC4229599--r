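test_that("MA transform computes M and A and is invertible", {
  tab <- data.frame(array_id = 1, probe_id = c("p1", "p2"), orf_id = c("g1", "g2"),
                    channel_sample = c(100, 400), channel_reference = c(100, 100))
  ma <- ma_transform(tab)
  expect_equal(ma$M, c(0, 2))
  expect_equal(ma$A[1], log2(100))

  set.seed(7)
  rnd <- data.frame(array_id = 1, probe_id = paste0("p", 1:50),
                    orf_id = paste0("g", 1:50),
                    channel_sample = runif(50, 10, 1e4),
                    channel_reference = runif(50, 10, 1e4))
  ma2 <- ma_transform(rnd)
  expect_equal(2^(ma2$A + ma2$M / 2), rnd$channel_sample)
  expect_equal(2^(ma2$A - ma2$M / 2), rnd$channel_reference)
})

test_that("zero channels are flagged; an all-flagged array errors", {
  tab <- data.frame(array_id = 1, probe_id = c("p1", "p2"), orf_id = c("g1", "g2"),
                    channel_sample = c(0, 50), channel_reference = c(100, 100))
  ma <- ma_transform(tab)
  expect_equal(ma$flagged, c(TRUE, FALSE))
  tab$channel_sample <- 0
  expect_error(ma_transform(tab), "all probes flagged")
  tab$channel_sample <- -1
  expect_error(ma_transform(tab), "non-negative")
})

test_that("lowess normalization leaves trend-free data nearly unchanged", {
  set.seed(21)
  n <- 2000
  tab <- data.frame(array_id = 1, probe_id = paste0("p", 1:n),
                    orf_id = paste0("g", 1:n),
                    channel_sample = NA, channel_reference = NA)
  a <- runif(n, 6, 14)
  m <- rnorm(n, 0, 0.05)
  tab$channel_sample <- 2^(a + m / 2)
  tab$channel_reference <- 2^(a - m / 2)
  ma <- ma_transform(tab)
  out <- lowess_normalize(ma)
  expect_lt(max(abs(out$M - ma$M)), 0.01)
})

test_that("a noise-free smooth M = f(A) trend is removed almost entirely", {
  set.seed(22)
  n <- 2000
  a <- runif(n, 6, 14)
  m <- 0.5 * sin(a / 3) + 0.3
  tab <- data.frame(array_id = 1, probe_id = paste0("p", 1:n),
                    orf_id = paste0("g", 1:n),
                    channel_sample = 2^(a + m / 2),
                    channel_reference = 2^(a - m / 2))
  out <- lowess_normalize(ma_transform(tab))
  # interior of the intensity range is corrected almost exactly; the span-
  # limited edges carry the usual local-regression boundary bias
  expect_lt(max(residual_trend(out)), 0.01)
  expect_lt(max(abs(out$M)), 0.05)
  expect_lt(mean(abs(out$M)), 0.01)
  expect_error(lowess_normalize(ma_transform(transform(
    tab, channel_sample = 1024, channel_reference = 256
  ))), "degenerate")
})

test_that("synthetic dye bias of amplitude 0.8 is reduced below 0.05", {
  cfg <- sim_config(n_genes = 800, n_planted_per_stress = 0,
                    dye_bias_amplitude = 0.8, noise_sd_expression = 0.1,
                    seed = 13)
  des <- generate_design(cfg)
  truth <- simulate_robustness_truth(des, cfg)
  ma <- ma_transform(simulate_probe_intensities(des, truth, cfg))
  before <- residual_trend(ma)
  after <- residual_trend(lowess_normalize(ma))
  expect_gt(min(before), 0.3)   # bias really was planted
  expect_lt(max(after), 0.05)
})

test_that("array scaling fixes median 0 / MAD 1 and is idempotent on scaled input", {
  set.seed(31)
  base <- data.frame(array_id = rep(1:2, each = 201),
                     probe_id = rep(paste0("p", 1:201), 2),
                     orf_id = rep(paste0("g", 1:201), 2))
  m <- c(rnorm(201), 2 * rnorm(201))
  a <- runif(402, 6, 14)
  base$channel_sample <- 2^(a + m / 2)
  base$channel_reference <- 2^(a - m / 2)
  ma <- scale_arrays(ma_transform(base))
  for (id in 1:2) {
    mi <- ma$M[ma$array_id == id]
    expect_equal(median(mi), 0, tolerance = 1e-12)
    expect_equal(mad(mi, constant = 1), 1, tolerance = 1e-12)
  }
  expect_equal(scale_arrays(ma)$M, ma$M, tolerance = 1e-12)
})

test_that("probe-to-ORF summarization takes per-array medians, order-invariantly", {
  tab <- data.frame(array_id = 1, probe_id = c("q1", "q2", "q3", "r1"),
                    orf_id = c("gA", "gA", "gA", "gB"),
                    channel_sample = 2^(10 + c(1, 2, 10, 1.7)),
                    channel_reference = 2^10)
  expr <- summarize_probes_to_orfs(ma_transform(tab))
  expect_equal(expr["gA", 1], 2)        # median of 1, 2, 10
  expect_equal(expr["gB", 1], 1.7)      # single probe passes through

  shuf <- tab[c(3, 1, 4, 2), ]
  expect_equal(summarize_probes_to_orfs(ma_transform(shuf))[rownames(expr), ],
               expr[, 1])
  expect_error(summarize_probes_to_orfs(ma_transform(tab),
                                        map = data.frame(probe_id = character(),
                                                         orf_id = character())),
               "map")
})

test_that("median summarization is bounded by the probe extremes", {
  cfg <- sim_config(n_genes = 120, seed = 3)
  des <- generate_design(cfg)
  truth <- simulate_robustness_truth(des, cfg)
  ma <- ma_transform(simulate_probe_intensities(des, truth, cfg))
  expr <- summarize_probes_to_orfs(ma)
  for (g in sample(rownames(expr), 10)) {
    for (j in sample(ncol(expr), 3)) {
      probes <- ma$M[ma$orf_id == g & ma$array_id == as.integer(colnames(expr)[j])]
      expect_gte(expr[g, j], min(probes))
      expect_lte(expr[g, j], max(probes))
    }
  }
})

test_that("normalization changes neither probe-ORF assignment nor array count", {
  cfg <- sim_config(n_genes = 100, seed = 8)
  des <- generate_design(cfg)
  truth <- simulate_robustness_truth(des, cfg)
  ma <- ma_transform(simulate_probe_intensities(des, truth, cfg))
  out <- scale_arrays(lowess_normalize(ma))
  expect_identical(out[, c("array_id", "probe_id", "orf_id", "flagged")],
                   ma[, c("array_id", "probe_id", "orf_id", "flagged")])
  expect_identical(out$A, ma$A)
})

test_that("bias-free noise-free input round-trips exactly to the planted log2 ratios", {
  cfg <- sim_config(n_genes = 90, n_planted_per_stress = 8,
                    dye_bias_amplitude = 0, noise_sd_expression = 0, seed = 17)
  des <- generate_design(cfg)
  truth <- simulate_robustness_truth(des, cfg)
  probes <- simulate_probe_intensities(des, truth, cfg)
  expr <- preprocess_probes(probes, normalize = FALSE, scale = FALSE)

  planted <- split(truth$genes, truth$genes$stress)
  m_expected <- matrix(0, nrow = cfg$n_genes, ncol = nrow(des),
                       dimnames = list(sort(unique(probes$orf_id)), NULL))
  for (st in names(planted)) {
    sh <- truth$shared[truth$shared$stress == st, ]
    lat <- sh$latent[match(des$fermentation_id, sh$fermentation_id)]
    m_expected[planted[[st]]$gene_id, ] <-
      m_expected[planted[[st]]$gene_id, , drop = FALSE] +
      outer(planted[[st]]$slope, lat)
  }
  expect_equal(unname(expr[rownames(m_expected), ]), unname(m_expected),
               tolerance = 1e-12)
})
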