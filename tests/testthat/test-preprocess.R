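test_that("otsu threshold equals the brute-force between-class argmax", {
  # two-level image: perfect split
  x <- c(rep(0, 50), rep(10, 50))
  thr <- otsu_threshold(x)
  expect_true(all(x[x > thr] == 10) && all(x[x <= thr] == 0))
  expect_error(otsu_threshold(rep(3, 10)), "equal")
  # brute-force oracle over histogram bins: for every candidate cut,
  # compute the two class means/weights naively and maximize
  # w0 * w1 * (mu0 - mu1)^2
  set.seed(21)
  for (rep in 1:5) {
    v <- c(rnorm(60, 0, 1), rnorm(40, 4, 1))
    nb <- 64L
    edges <- seq(min(v), max(v), length.out = nb + 1L)
    counts <- tabulate(findInterval(v, edges, rightmost.closed = TRUE),
                       nbins = nb)
    mids <- (edges[-1] + edges[-length(edges)]) / 2
    best <- -Inf; best_thr <- NA
    for (k in 1:(nb - 1L)) {
      n0 <- sum(counts[1:k]); n1 <- sum(counts) - n0
      if (n0 == 0 || n1 == 0) next
      mu0 <- sum(counts[1:k] * mids[1:k]) / n0
      mu1 <- sum(counts[(k + 1):nb] * mids[(k + 1):nb]) / n1
      bcv <- (n0 / sum(counts)) * (n1 / sum(counts)) * (mu0 - mu1)^2
      if (bcv > best) { best <- bcv; best_thr <- edges[k + 1L] }
    }
    expect_equal(otsu_threshold(v, nbins = nb), best_thr, tolerance = 1e-12)
  }
})

test_that("otsu_mask recovers synthetic blobs at high contrast", {
  cfg <- tiny_config(sigma0 = 0.005, wv_amp = 0, baseline_poly_amp = 0.01,
                     osc_amp = 0.005)
  cube <- with_seed(22, make_cube(cfg, height = 24, width = 24,
                                  n_blobs = 3, contrast = 8))
  mk <- otsu_mask(cube, band_ranges = list(c(1000, 1800)))
  recovery <- sum(mk & cube$mask) / sum(cube$mask)
  expect_gte(recovery, 0.95)
  # degenerate contrast-free cube errors cleanly
  flat <- hypercube(array(1, c(4, 4, 64)), make_axis(cfg))
  expect_error(otsu_mask(flat, band_ranges = list(c(1000, 1800))), "equal")
})

test_that("atmospheric correction removes FOV-shared structure", {
  cfg <- tiny_config(sigma0 = 0, baseline_poly_amp = 0, osc_amp = 0,
                     wv_amp = 0.05, wv_lines = 4L)
  ax <- make_axis(cfg)
  wv <- with_seed(23, ftircascade:::water_vapor_profile(ax$values, cfg))
  H <- 8L; W <- 8L
  msk <- matrix(FALSE, H, W); msk[3:6, 3:6] <- TRUE
  arr <- array(0, c(H, W, 64L))
  cleans <- with_seed(24, replicate(H * W, clean_spectrum(cfg, ax)))
  k <- 0L
  for (j in 1:W) for (i in 1:H) {
    k <- k + 1L
    arr[i, j, ] <- (if (msk[i, j]) cleans[, k] else 0) + wv
  }
  cube <- hypercube(arr, ax, msk)
  cc <- atmospheric_correct(cube)
  # foreground restored to clean (background mean = wv exactly)
  flat <- matrix(cc$data, H * W, 64L)
  fg <- which(as.vector(msk))
  expect_equal(flat[fg, ], t(cleans)[fg, ], tolerance = 1e-12)
  # background untouched
  expect_equal(flat[-fg, ], matrix(wv, length(flat[, 1]) - length(fg), 64L,
                                   byrow = TRUE), tolerance = 1e-12)
  # zero background mean -> identity
  cube0 <- hypercube(arr - rep(wv, each = H * W), ax, msk)
  cc0 <- atmospheric_correct(cube0)
  expect_equal(cc0$data, cube0$data, tolerance = 1e-12)
  expect_error(atmospheric_correct(hypercube(arr, ax,
                                             matrix(TRUE, H, W))),
               "background")
})

test_that("trimming drops the configured ranges and re-derives the axis", {
  cfg <- synthetic_config()
  ax <- make_axis(cfg)
  set <- spectrum_set(ax, matrix(seq_len(1584), 1, 1584))
  spec <- trim_spec(exclude = list(c(2250, 2401)), keep = NULL)
  tr <- trim_spectra(set, spec)
  n_excl <- sum(ax$values >= 2250 & ax$values <= 2401)
  expect_equal(length(tr$axis), 1584L - n_excl)
  expect_false(any(tr$axis$values >= 2250 & tr$axis$values <= 2401))
  # values move with their wavenumbers
  expect_equal(tr$intensities[1, ], which(!(ax$values >= 2250 &
                                              ax$values <= 2401)))
  # empty spec is the identity
  id <- trim_spectra(set, trim_spec(exclude = list(), keep = NULL))
  expect_equal(id$intensities, set$intensities)
  # disjoint trims commute
  s1 <- trim_spec(exclude = list(c(2250, 2401)), keep = NULL)
  s2 <- trim_spec(exclude = list(c(3500, 3600)), keep = NULL)
  expect_equal(trim_spectra(trim_spectra(set, s1), s2)$axis$values,
               trim_spectra(trim_spectra(set, s2), s1)$axis$values)
  expect_error(trim_spectra(set, trim_spec(exclude = list(c(900, 4100)),
                                           keep = NULL)),
               "fewer than 8")
  expect_error(trim_spec(exclude = list(c(1000, 1500), c(1400, 1600))),
               "overlap")
})

test_that("SNV matches its closed form and inverts exactly", {
  expect_equal(drop(snv(c(1, 2, 3))$x), c(-1, 0, 1))
  x <- with_seed(25, matrix(rnorm(6 * 40), 6))
  # affine invariance for a > 0
  expect_equal(snv(3.7 * x + 2)$x, snv(x)$x, tolerance = 1e-12)
  sn <- snv(x)
  expect_equal(inverse_snv(sn$x, sn$mean, sn$sd), x, tolerance = 1e-12)
  expect_error(snv(rbind(x[1, ], rep(5, 40))), "row 2")
})

test_that("min-max scaling is train-only, unclipped and invertible", {
  b <- list(min = 0, max = 2)
  expect_equal(minmax_apply(1, b), 0.5)
  expect_equal(minmax_apply(3, b), 1.5)  # held-out value, NOT clipped
  x <- with_seed(26, matrix(rnorm(4 * 30), 4))
  bb <- minmax_fit(x[1:2, ])
  sc <- minmax_apply(x, bb)
  expect_true(all(sc[1:2, ] >= 0 & sc[1:2, ] <= 1))
  expect_equal(minmax_invert(sc, bb), x, tolerance = 1e-12)
  expect_error(minmax_fit(matrix(1, 2, 2)), "degenerate")
})

test_that("the full stage normalization round-trips to <= 1e-12 relative", {
  x <- with_seed(27, matrix(rexp(8 * 50), 8))
  st <- stage_normalize(x, "stage1")
  back <- stage_denormalize(st$x, st$state)
  expect_lt(max(abs(back - x) / pmax(abs(x), 1)), 1e-12)
  # partial-batch inversion via rows
  back2 <- stage_denormalize(st$x[3:5, ], st$state, rows = 3:5)
  expect_equal(back2, x[3:5, ], tolerance = 1e-12)
})

test_that("build_targets keeps target A and flattens target B", {
  cfg <- tiny_config(sigma0 = 0.001, wv_amp = 0)
  ax <- make_axis(cfg)
  nu <- ax$values
  pk <- 0.4 * exp(-0.5 * ((nu - 1400) / 25)^2)
  ramp <- 0.1 + 2e-4 * (nu - 1000)
  hq <- spectrum_set(ax, rbind(pk + ramp, pk * 0.8 + ramp))
  bt <- build_targets(hq, snip = snip_params(15L))
  expect_identical(bt$state_a$stage, "stage1")
  expect_identical(bt$state_b$stage, "stage2")
  # known-baseline oracle: target B peak height within 5% of the true peak
  expect_equal(max(bt$target_b_raw[1, ]), 0.4, tolerance = 0.05)
  # zero-baseline input: target B ~ target A before normalization
  hq0 <- spectrum_set(ax, rbind(pk, 0.8 * pk))
  bt0 <- build_targets(hq0, snip = snip_params(15L))
  expect_equal(bt0$target_b_raw, hq0$intensities,
               tolerance = 0.05 * max(pk))
})

test_that("LOSO hygiene: held-out rows never touch the fitted statistics", {
  pd <- tiny_paired(n_fov = 3L, px = 8L, seed = 31L)
  ctx <- fold_context(pd, "fov2", snip_params(10L))
  # perturb the held-out rows wildly and rebuild: train-derived stats and
  # normalized training rows must be identical
  pd2 <- pd
  pd2$lq$intensities[ctx$test_idx, ] <-
    pd$lq$intensities[ctx$test_idx, ] * 5 + 7
  pd2$hq_with_baseline$intensities[ctx$test_idx, ] <-
    pd$hq_with_baseline$intensities[ctx$test_idx, ] * 3 - 1
  ctx2 <- fold_context(pd2, "fov2", snip_params(10L))
  expect_identical(ctx$bounds1, ctx2$bounds1)
  expect_identical(ctx$bounds2, ctx2$bounds2)
  expect_identical(ctx$x1[ctx$train_idx, ], ctx2$x1[ctx2$train_idx, ])
  expect_identical(ctx$tb2[ctx$train_idx, ], ctx2$tb2[ctx2$train_idx, ])
})
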