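tiny_unet_cfg <- function(L = 24L)
  unet_config(L, depth = 2L, base_channels = 2L, kernel_size = 3L,
              n_res_blocks = 1L, attention = TRUE)

test_that("network construction and forward pass are well-formed", {
  cfg <- tiny_unet_cfg()
  net <- build_unet(cfg, seed = 1L)
  out <- ftircascade:::unet_forward(net$params, cfg, matrix(0, 4, 24))$out
  expect_identical(dim(out), c(4L, 24L))
  expect_true(all(is.finite(out)))
  # attention toggling changes the parameter count
  cfg_noatt <- unet_config(24L, depth = 2L, base_channels = 2L,
                           kernel_size = 3L, n_res_blocks = 1L,
                           attention = FALSE)
  expect_lt(n_params(build_unet(cfg_noatt, 1L)), n_params(net))
  # lengths not divisible by 2^depth are padded transparently
  cfg27 <- unet_config(27L, depth = 2L, base_channels = 2L,
                       kernel_size = 3L, n_res_blocks = 1L)
  expect_equal(cfg27$padded_length, 28L)
  out27 <- ftircascade:::unet_forward(build_unet(cfg27, 1L)$params, cfg27,
                                      matrix(rnorm(2 * 27), 2))$out
  expect_identical(dim(out27), c(2L, 27L))
  expect_error(unet_config(24L, depth = 1L), "depth")
  expect_error(unet_config(8L, depth = 3L, kernel_size = 9L), "too short")
})

test_that("backpropagation matches numerical gradients", {
  cfg <- tiny_unet_cfg(20L)
  P <- build_unet(cfg, seed = 7L)$params
  # randomize biases: exact-zero pre-activations sit on the ReLU kink where
  # finite differences measure the two-sided average, not the subgradient
  P <- with_seed(8L, lapply(P, function(l) {
    l$b <- stats::rnorm(length(l$b), 0, 0.1); l
  }))
  X <- with_seed(9L, matrix(rnorm(3 * 20), 3))
  Y <- with_seed(10L, matrix(rnorm(3 * 20), 3))
  fw <- ftircascade:::unet_forward(P, cfg, X, keep_cache = TRUE)
  G <- ftircascade:::unet_backward(P, cfg, fw$cache,
                                   ftircascade:::mse_grad(fw$out, Y))
  lossfn <- function(P) ftircascade:::mse_loss(
    ftircascade:::unet_forward(P, cfg, X)$out, Y)
  eps <- 1e-5
  set.seed(11)
  for (nm in names(P)) for (fld in c("W", "b")) {
    arr <- P[[nm]][[fld]]
    for (ii in sample(seq_along(arr), min(6L, length(arr)))) {
      Pp <- P; Pp[[nm]][[fld]][ii] <- arr[ii] + eps
      Pm <- P; Pm[[nm]][[fld]][ii] <- arr[ii] - eps
      num <- (lossfn(Pp) - lossfn(Pm)) / (2 * eps)
      expect_equal(G[[nm]][[fld]][ii], num, tolerance = 1e-4,
                   label = paste("grad", nm, fld, ii))
    }
  }
})

test_that("a desk-scale network memorizes a small noise-free set", {
  # residual = FALSE so the network must genuinely learn the mapping
  # (a zero-initialized residual net starts at the identity)
  cfg <- unet_config(64L, depth = 2L, base_channels = 8L, kernel_size = 7L,
                     n_res_blocks = 1L, residual = FALSE)
  scfg <- tiny_config(sigma0 = 0, wv_amp = 0, baseline_poly_amp = 0,
                      osc_amp = 0)
  ax <- make_axis(scfg)
  X <- with_seed(12L, t(replicate(16, clean_spectrum(scfg, ax))))
  Xn <- minmax_apply(snv(X)$x, minmax_fit(snv(X)$x))
  tc <- train_config(batch_size = 16L, patience = 499L, max_epochs = 500L,
                     val_fraction = 0, seed = 2L)
  m <- train_single(Xn, Xn, cfg, tc)
  expect_lt(m$best_loss, 1e-3)
  # the restored weights correspond to the best monitored epoch
  expect_equal(m$best_loss, min(m$history))
  expect_lte(m$best_loss, m$history[length(m$history)])
})

test_that("training is deterministic and batch-size independent", {
  cfg <- tiny_unet_cfg(16L)
  X <- with_seed(13L, matrix(runif(12 * 16), 12))
  Y <- with_seed(14L, matrix(runif(12 * 16), 12))
  tc <- train_config(batch_size = 4L, patience = 4L, max_epochs = 5L,
                     val_fraction = 0.2, seed = 5L)
  m1 <- train_single(X, Y, cfg, tc)
  m2 <- train_single(X, Y, cfg, tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  # inference identical row-by-row vs batched
  p_all <- predict_single(m1, X)
  p_rows <- t(vapply(seq_len(nrow(X)), function(i)
    drop(predict_single(m1, X[i, , drop = FALSE])), numeric(16L)))
  expect_equal(p_rows, p_all, tolerance = 1e-12)
})

test_that("checkpoints round-trip bit-identically", {
  cfg <- tiny_unet_cfg(16L)
  X <- with_seed(15L, matrix(runif(8 * 16), 8))
  tc <- train_config(batch_size = 4L, patience = 2L, max_epochs = 3L,
                     val_fraction = 0, seed = 5L)
  m <- train_single(X, X, cfg, tc)
  d <- withr::local_tempdir()
  save_checkpoint(m, d)
  back <- load_checkpoint(d)
  expect_identical(predict_single(back, X), predict_single(m, X))
  mf <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(mf$n_params, n_params(m$params))
  expect_error(load_checkpoint(withr::local_tempdir()), "checkpoint")
})

cascade_fixture <- function(seed = 16L, px = 10L, epochs = 4L, w1 = 1,
                            w2 = 1) {
  pd <- tiny_paired(n_fov = 2L, px = px, seed = seed)
  ctx <- fold_context(pd, "fov2", snip_params(10L))
  tr <- ctx$train_idx
  cfg <- tiny_unet_cfg(64L)
  tc <- train_config(batch_size = 8L, patience = epochs - 1L,
                     max_epochs = epochs, val_fraction = 0.2, seed = 3L,
                     w1 = w1, w2 = w2, learning_rate = 1)
  list(pd = pd, ctx = ctx, tr = tr, cfg = cfg, tc = tc)
}

test_that("cascade training is decoupled: stage-2 loss never reaches unet1", {
  fx <- cascade_fixture()
  with_fix <- function(tb) train_cascade(
    fx$ctx$x1[fx$tr, ], fx$ctx$ta1[fx$tr, ], tb, fx$ctx$bridge_cfg,
    rows = fx$tr, fx$cfg, fx$tc)
  m_a <- with_fix(fx$ctx$tb2[fx$tr, ])
  m_b <- with_fix(1 - fx$ctx$tb2[fx$tr, ])  # very different stage-2 target
  expect_identical(m_a$unet1, m_b$unet1)    # unet1 sees only Loss_stage1
  expect_false(identical(m_a$unet2, m_b$unet2))
})

test_that("disabling the stage-1 loss degrades stage-1 denoising", {
  fx1 <- cascade_fixture(epochs = 6L, w1 = 1)
  fx0 <- cascade_fixture(epochs = 6L, w1 = 0)
  fit <- function(fx) train_cascade(fx$ctx$x1[fx$tr, ], fx$ctx$ta1[fx$tr, ],
                                    fx$ctx$tb2[fx$tr, ], fx$ctx$bridge_cfg,
                                    rows = fx$tr, fx$cfg, fx$tc)
  m1 <- fit(fx1); m0 <- fit(fx0)
  s1 <- ftircascade:::unet_forward(m1$unet1, fx1$cfg,
                                   fx1$ctx$x1[fx1$tr, ])$out
  s0 <- ftircascade:::unet_forward(m0$unet1, fx0$cfg,
                                   fx0$ctx$x1[fx0$tr, ])$out
  ta <- fx1$ctx$ta1[fx1$tr, ]
  expect_lt(mean((s1 - ta)^2), mean((s0 - ta)^2))
})

test_that("the bridge stays active at inference and can be ablated only explicitly", {
  fx <- cascade_fixture()
  m <- train_cascade(fx$ctx$x1[fx$tr, ], fx$ctx$ta1[fx$tr, ],
                     fx$ctx$tb2[fx$tr, ], fx$ctx$bridge_cfg,
                     rows = fx$tr, fx$cfg, fx$tc)
  te <- fx$ctx$test_idx
  with_b <- predict_cascade(m, fx$ctx$x1[te, ], rows = te)
  no_b <- predict_cascade(m, fx$ctx$x1[te, ], rows = te,
                          bypass_bridge = TRUE)
  expect_false(isTRUE(all.equal(with_b, no_b)))
  # checkpoint round-trip preserves the bridge configuration
  d <- withr::local_tempdir()
  save_checkpoint(m, d)
  expect_identical(predict_cascade(load_checkpoint(d), fx$ctx$x1[te, ],
                                   rows = te), with_b)
})

test_that("restore_spectra runs the full pipeline on raw spectra", {
  fx <- cascade_fixture()
  m <- train_cascade(fx$ctx$x1[fx$tr, ], fx$ctx$ta1[fx$tr, ],
                     fx$ctx$tb2[fx$tr, ], fx$ctx$bridge_cfg,
                     rows = fx$tr, fx$cfg, fx$tc)
  te <- fx$ctx$test_idx
  raw <- ftircascade:::subset_spectra(fx$pd$lq, te)
  out <- restore_spectra(m, raw)
  # equals the context-based prediction path (same stats, same bounds)
  expect_equal(out$intensities,
               predict_cascade(m, fx$ctx$x1[te, ], rows = te),
               tolerance = 1e-12)
  short <- spectrum_set(wn_axis(raw$axis$values[1:32]),
                        raw$intensities[, 1:32])
  expect_error(restore_spectra(m, short), "axis mismatch")
})
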