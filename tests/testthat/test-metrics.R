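test_that("global metrics match their analytic cases", {
  m <- global_metrics(c(1, 0.5), c(1, 0.5) + 0)
  expect_equal(unlist(m), c(rmse = 0, mae = 0, sam_deg = 0, pcc = 1),
               tolerance = 1e-7)
  expect_warning(m45 <- global_metrics(c(1, 0), c(1, 1)), "PCC undefined")
  expect_equal(m45$sam_deg, 45, tolerance = 1e-10)
  expect_true(is.na(m45$pcc))
  # diffs (3, 4) over L = 2
  suppressWarnings(m2 <- global_metrics(c(4, 5), c(1, 1)))
  expect_equal(m2$rmse, sqrt(12.5))
  expect_equal(m2$mae, 3.5)
})

test_that("SAM and PCC have the right invariances; RMSE >= MAE always", {
  set.seed(61)
  for (r in 1:5) {
    a <- rnorm(64); b <- rnorm(64)
    expect_equal(global_metrics(3 * a, b)$sam_deg,
                 global_metrics(a, b)$sam_deg, tolerance = 1e-10)
    expect_equal(global_metrics(a, 2 * b + 1)$pcc,
                 global_metrics(a, b)$pcc, tolerance = 1e-10)
  }
  pr <- matrix(rnorm(1000 * 16), 1000)
  tg <- matrix(rnorm(1000 * 16), 1000)
  mm <- ftircascade:::metrics_rows(pr, tg)
  expect_true(all(mm$rmse >= mm$mae - 1e-12))
  expect_true(all(mm$sam_deg >= 0 & mm$sam_deg <= 180))
  expect_true(all(abs(mm$pcc) <= 1 + 1e-12))
})

test_that("peak detection applies the prominence threshold and cap", {
  # single triangle peak of height 1 on zero
  y <- c(rep(0, 10), seq(0, 1, length.out = 6), seq(0.8, 0, length.out = 5),
         rep(0, 10))
  pk <- detect_peaks(y)
  expect_equal(length(pk$indices), 1L)
  expect_equal(pk$prominences, 1)
  expect_equal(pk$heights, 1)
  # 30 equal peaks of prominence 0.5 -> exactly 20 retained
  y30 <- rep(c(0, 0.5), 31)[1:61]
  pk30 <- detect_peaks(y30)
  expect_equal(length(pk30$indices), 20L)
  expect_true(all(pk30$prominences == 0.5))
  # sub-threshold peaks dropped
  expect_equal(length(detect_peaks(y30 * 0.03)$indices), 0L)
})

test_that("prominence equals the brute-force definition on random signals", {
  set.seed(62)
  for (r in 1:20) {
    y <- rnorm(64)
    core <- y[2:63]
    idx <- which(core > y[1:62] & core > y[3:64]) + 1L
    for (i in idx)
      expect_equal(ftircascade:::peak_prominence(y, i),
                   brute_prominence(y, i), tolerance = 1e-12)
  }
})

test_that("peak matching is exact, tolerant and reported in wavenumbers", {
  ax <- wn_axis(seq(1000, 1000 + 2 * 499, by = 2))
  # identical sets: all matched with zero errors
  a <- as_peakset(c(50L, 120L, 300L), heights = c(1, 2, 3))
  m0 <- match_peaks(a, a, axis = ax)
  expect_equal(nrow(m0$pairs), 3L)
  expect_true(all(m0$pairs$e_pos == 0) && all(m0$pairs$e_amp == 0))
  # tolerance cut: {100, 300} vs {102, 402} -> one pair, errors in cm^-1
  t1 <- as_peakset(c(100L, 300L))
  p1 <- as_peakset(c(102L, 402L))
  m1 <- match_peaks(t1, p1, axis = ax)
  expect_equal(nrow(m1$pairs), 1L)
  expect_equal(m1$pairs$target_index, 100L)
  expect_equal(m1$pairs$e_pos, 2 * 2)  # two samples at 2 cm^-1 interval
  expect_equal(m1$unmatched_target, 1L)
  expect_equal(m1$unmatched_pred, 1L)
  # the case where greedy nearest-neighbour would drop a feasible pair
  t2 <- as_peakset(c(10L, 14L))
  p2 <- as_peakset(c(13L, 17L))
  m2 <- match_peaks(t2, p2, axis = ax)
  expect_equal(nrow(m2$pairs), 2L)
})

test_that("peak matcher equals brute-force assignment on random instances", {
  set.seed(63)
  for (r in 1:200) {
    nt <- sample(0:8, 1); np <- sample(0:8, 1)
    ti <- sort(sample(1:60, nt))
    pi_ <- sort(sample(1:60, np))
    got <- match_peaks(as_peakset(ti), as_peakset(pi_))
    want <- brute_match(ti, pi_, tol = 4L)
    expect_equal(nrow(got$pairs), want$m)
    if (want$m > 0)
      expect_equal(sum(abs(got$pairs$pred_index - got$pairs$target_index)),
                   want$d)
  }
})

test_that("reduction percent follows its closed form", {
  expect_equal(reduction_percent(0.2, 0.1), 50)
  expect_equal(reduction_percent(0.2, 0.2), 0)
  expect_equal(reduction_percent(1.0, 0.487), 51.3)
  expect_error(reduction_percent(0, 1), "> 0")
})

test_that("difficulty scores are z-score sums singling out bad spectra", {
  set.seed(64)
  n <- 12L; L <- 128L
  base <- matrix(rnorm(n * L, 0, 0.01), n) +
    matrix(sin(seq(0, 6, length.out = L)), n, L, byrow = TRUE)
  base[4, ] <- base[4, ] + rnorm(L, 0, 0.1)       # 10x noise
  rmse <- rep(0.1, n); rmse[4] <- 0.3
  sam <- rep(2, n); sam[4] <- 5
  ds <- difficulty_scores(base, rmse, sam)
  expect_equal(which.max(ds$score), 4L)
  expect_equal(mean(ds$score), 0, tolerance = 1e-10)
  expect_equal(mean(ds$z_noise), 0, tolerance = 1e-10)
  # identical spectra: zero spread -> warning and all-zero scores
  same <- matrix(rep(base[1, ], 3), 3, byrow = TRUE)
  ws <- testthat::capture_warnings(
    ds0 <- difficulty_scores(same, rep(1, 3), rep(1, 3)))
  expect_true(all(grepl("zero spread", ws)) && length(ws) == 4L)
  expect_equal(ds0$score, rep(0, 3))
})

test_that("stability metric is exact on lines and unbiased under noise", {
  ax <- make_axis(synthetic_config())
  y <- 2 + 0.001 * ax$values
  expect_equal(stability_metric(y, ax), 0, tolerance = 1e-12)
  set.seed(65)
  r <- replicate(100, stability_metric(y + rnorm(1584, 0, 3e-4), ax) / 3e-4)
  # mean within 3 estimator-sd of 1
  expect_equal(mean(r), 1, tolerance = 3 * stats::sd(r) / sqrt(100) + 0.02)
  expect_error(stability_metric(y, ax, window = c(5000, 5100)),
               "fewer than 3")
})

test_that("loso_evaluate runs one fold per FOV with exact reference rows", {
  pd <- tiny_paired(n_fov = 4L, px = 6L, seed = 66L)
  res <- loso_evaluate(pd, list(oracle = method_oracle(),
                                identity = method_identity()),
                       snip = snip_params(10L), seed = 1L)
  expect_setequal(unique(res$fov_summary$fov),
                  paste0("fov", 1:4))
  expect_equal(sum(res$fov_summary$method == "oracle"), 4L)
  # oracle: zero error, 100% reduction
  s <- res$summary
  expect_equal(s$mean[s$method == "oracle" & s$metric == "rmse"], 0)
  expect_equal(s$reduction_pct[s$method == "oracle" & s$metric == "rmse"],
               100)
  # identity: by definition equal to the LQ baseline -> 0% reduction
  expect_equal(s$reduction_pct[s$method == "identity" & s$metric == "rmse"],
               0, tolerance = 1e-10)
  expect_error(loso_evaluate(ftircascade:::subset_paired(
    pd, which(pd$lq$sample_labels == "fov1")),
    list(oracle = method_oracle())), "at least 2")
})
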