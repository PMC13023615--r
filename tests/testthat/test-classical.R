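test_that("SNIP baseline obeys its geometric guarantees", {
  # linear ramp: averages of a line equal the line -> corrected ~ 0
  r <- seq(0, 1, length.out = 100)
  b <- snip_baseline(r, snip_params(10L))
  expect_equal(b, r, tolerance = 1e-12)
  # single spike on flat zero: fully retained for half-window >= 2
  s <- numeric(100); s[50] <- 1
  cs <- s - snip_baseline(s, snip_params(4L))
  expect_gte(cs[50], 0.95)
  # concave-down quadratic: baseline strictly below in the interior
  q <- -(seq(-1, 1, length.out = 64))^2
  bq <- snip_baseline(q, snip_params(8L))
  expect_true(all(bq[5:60] < q[5:60]))
  # pointwise dominance + non-negative correction on random spectra
  x <- with_seed(41, matrix(rnorm(5 * 80), 5))
  bx <- snip_baseline(x, snip_params(12L))
  expect_true(all(bx <= x + 1e-12))
  expect_true(all(x - bx >= -1e-12))
  expect_error(snip_baseline(numeric(10), snip_params(5L)), "L/2")
})

test_that("SNIP sweeps are monotonically non-increasing", {
  y <- with_seed(42, abs(rnorm(120)) + sin(seq(0, 6, length.out = 120)))
  prev <- y
  for (m in c(2L, 5L, 10L, 20L)) {
    b <- snip_baseline(y, snip_params(m))
    expect_true(all(b <= prev + 1e-12))
    prev <- b
  }
})

test_that("SG filter reproduces polynomials and differentiates exactly", {
  x <- seq(0, 1, length.out = 101)
  y <- 1 + 2 * x - 3 * x^2 + 0.5 * x^3
  expect_equal(sg_filter(y, sg_params(17L, 3L)), y, tolerance = 1e-9)
  # second derivative of a*nu^2 is the constant 2a
  nu <- seq(1000, 1200, length.out = 101)
  a <- 0.003
  d2 <- sg_filter(a * nu^2, sg_params(17L, 3L, 2L),
                  interval = nu[2] - nu[1])
  expect_equal(d2, rep(2 * a, 101), tolerance = 1e-9)
  # linearity
  u <- with_seed(43, rnorm(101)); v <- with_seed(44, rnorm(101))
  p <- sg_params(11L, 3L)
  expect_equal(sg_filter(2 * u + 3 * v, p),
               2 * sg_filter(u, p) + 3 * sg_filter(v, p),
               tolerance = 1e-10)
  expect_error(sg_filter(rnorm(10), sg_params(17L, 3L)), "exceeds")
  expect_error(sg_params(16L, 3L), "odd")
  expect_error(sg_params(5L, 5L), "poly_order")
})

test_that("SG white-noise variance matches the kernel-coefficient oracle", {
  # var(filter(noise)) at interior points = sum(kernel^2) * var(noise)
  kern <- sg_kernel(sg_params(17L, 3L))
  expect_equal(sum(kern), 1, tolerance = 1e-12)
  n <- 400L; reps <- 200L
  sm <- with_seed(45, {
    x <- matrix(rnorm(reps * n), reps)
    sg_filter(x, sg_params(17L, 3L))
  })
  v <- stats::var(as.vector(sm[, 9:(n - 8)]))
  expect_equal(v, sum(kern^2), tolerance = 3 * sqrt(2 / (reps * (n - 16))) /
                 sum(kern^2))
})

test_that("second_derivative_view shows band curvature", {
  nu <- seq(1000, 1400, length.out = 201)
  g <- exp(-0.5 * ((nu - 1200) / 20)^2)
  d2 <- second_derivative_view(g, interval = nu[2] - nu[1])
  expect_lt(d2[which.max(g)], 0)       # negative lobe at the band center
  expect_equal(second_derivative_view(rep(2, 50)), rep(0, 50),
               tolerance = 1e-12)
})

test_that("tune_sg is deterministic and matches the exhaustive grid", {
  pd <- tiny_paired(n_fov = 2L, px = 10L, seed = 46L, n_points = 96L)
  ctx <- fold_context(pd, "fov2", snip_params(10L))
  tr <- ctx$train_idx
  lq <- ctx$x1[tr, , drop = FALSE]
  hq <- ctx$ta1[tr, , drop = FALSE]
  r1 <- tune_sg(lq, hq, n_trials = 20L, seed = 7L)
  r2 <- tune_sg(lq, hq, n_trials = 20L, seed = 7L)
  expect_identical(r1$params, r2$params)
  expect_identical(r1$trials, r2$trials)
  # full budget covers the 116-point grid -> equals exhaustive argmin,
  # computed here by an independent double loop
  full <- tune_sg(lq, hq, n_trials = 116L, seed = 1L)
  expect_equal(nrow(full$trials), 116L)
  best <- list(obj = Inf)
  for (w in seq(5L, 61L, 2L)) for (p in 2:5) {
    par <- sg_params(w, min(p, w - 1L))
    sm <- sg_filter(lq, par)
    ang <- acos(pmin(1, pmax(-1, rowSums(sm * hq) /
                               sqrt(rowSums(sm^2) * rowSums(hq^2)))))
    obj <- mean(rowMeans((sm - hq)^2) + 0.1 * ang)
    if (obj < best$obj) best <- list(obj = obj, w = w, p = min(p, w - 1L))
  }
  expect_equal(full$objective, best$obj, tolerance = 1e-12)
  expect_equal(full$params$window_length, best$w)
  expect_equal(full$params$poly_order, best$p)
  # noise-free LQ = HQ: returned objective no worse than the (61, 2) corner
  r0 <- tune_sg(hq, hq, n_trials = 116L, seed = 1L)
  corner <- mean(rowMeans((sg_filter(hq, sg_params(61L, 2L)) - hq)^2))
  expect_lte(r0$objective, corner + 1e-12)
  expect_error(tune_sg(lq, hq, n_trials = 0L), "n_trials")
})

test_that("traditional_restore flattens a known injected baseline", {
  cfg <- tiny_config(sigma0 = 0.002, wv_amp = 0, n_points = 96L)
  pd <- with_seed(47, make_paired_dataset(2L, 12L, cfg,
                                          snip = snip_params(12L)))
  ctx <- fold_context(pd, "fov2", snip_params(12L))
  sg <- sg_params(9L, 3L)
  out <- traditional_restore(ctx$x1, ctx$state1, sg, ctx$snip, ctx$bounds2)
  # restored spectra approximate the stage-2 reference far better than the
  # drifting input does
  m_out <- mean((out - ctx$tb2)^2)
  # row-by-row equals batched (purity)
  rr <- t(vapply(seq_len(nrow(ctx$x1)), function(i)
    drop(traditional_restore(ctx$x1[i, , drop = FALSE], ctx$state1, sg,
                             ctx$snip, ctx$bounds2, rows = i)),
    numeric(ncol(ctx$x1))))
  expect_equal(rr, out, tolerance = 1e-12)
  # residual baseline: compare against stage-2-normalized clean truth
  cl2 <- ftircascade:::to_stage2(pd$clean$intensities, ctx$bounds2)
  expect_lt(sqrt(mean((out - cl2)^2)), 0.5 * sqrt(mean((ctx$x1 - cl2)^2)))
  expect_gt(mean(diag(stats::cor(t(out), t(cl2)))), 0.97)
})
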