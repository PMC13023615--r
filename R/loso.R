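# Leave-one-sample-out (LOSO) evaluation: per fold, every statistic
# (min-max bounds, SG tuning, network weights) is derived from the training
# fields of view only; the held-out FOV is evaluated in the common stage-2
# domain against the baseline-free HQ reference. Per-spectrum metrics are
# summarized by the FOV median and reported as mean +/- sd across folds,
# with percentage reductions relative to the processed-input LQ baseline.

#' Build the normalized data context for one LOSO fold
#'
#' Computes, from the training rows only: the shared stage-1 min-max bounds
#' (over SNV-transformed LQ inputs and HQ-with-baseline targets) and the
#' stage-2 bounds (over SNV-transformed baseline-free HQ). All rows are then
#' mapped into those domains (held-out rows may leave [0, 1]; they are not
#' clipped). Also prepares the processed-input LQ baseline: the raw LQ rows
#' passed through SNIP subtraction and stage-2 normalization, with no
#' learning.
#'
#' @param data A [paired_dataset()].
#' @param test_fov Label of the held-out FOV.
#' @param snip A [snip_params()].
#' @return A list (`fold_context`) with the normalized matrices (`x1`,
#'   `ta1`, `tb2`, `lqb2`), index vectors, states and the fold's
#'   [bridge_config()].
#' @export
fold_context <- function(data, test_fov, snip = snip_params()) {
  stopifnot(inherits(data, "paired_dataset"))
  labels <- data$lq$sample_labels
  if (!test_fov %in% labels) stop("unknown FOV label: ", test_fov)
  train_idx <- which(labels != test_fov)
  test_idx <- which(labels == test_fov)
  lq_raw <- data$lq$intensities
  hq_raw <- data$hq_with_baseline$intensities
  sn_lq <- snv(lq_raw)
  sn_a <- snv(hq_raw)
  b_raw <- hq_raw - snip_baseline(hq_raw, snip)
  sn_b <- snv(b_raw)
  bounds1 <- minmax_fit(rbind(sn_lq$x[train_idx, , drop = FALSE],
                              sn_a$x[train_idx, , drop = FALSE]))
  bounds2 <- minmax_fit(sn_b$x[train_idx, , drop = FALSE])
  state1 <- normalization_state(sn_lq$mean, sn_lq$sd, "stage1",
                                bounds1$min, bounds1$max)
  lqb_raw <- lq_raw - snip_baseline(lq_raw, snip)
  list(axis = data$lq$axis, labels = labels,
       train_idx = train_idx, test_idx = test_idx,
       x1 = minmax_apply(sn_lq$x, bounds1),
       ta1 = minmax_apply(sn_a$x, bounds1),
       tb2 = minmax_apply(sn_b$x, bounds2),
       lqb2 = to_stage2(lqb_raw, bounds2),
       state1 = state1, bounds1 = bounds1, bounds2 = bounds2,
       snip = snip,
       bridge_cfg = bridge_config(snip, state1, bounds2))
}

#' Restoration method objects
#'
#' Constructors wrapping each benchmark method behind a common
#' `fit(ctx, seed)` / `predict(model, ctx, rows)` interface consumed by
#' [loso_evaluate()]. `rows` are global row indices of the fold context.
#'
#' * `method_oracle()` returns the stage-2 target itself (upper bound,
#'   100% reduction by construction).
#' * `method_identity()` returns the processed LQ baseline (0% reduction by
#'   definition).
#' * `method_traditional()` tunes a Savitzky-Golay filter on the training
#'   rows ([tune_sg()]; pass `params` to skip tuning) and applies
#'   [traditional_restore()].
#' * `method_single_unet()` trains one end-to-end network LQ -> target B.
#' * `method_cascade()` trains the physics-informed two-stage cascade.
#'
#' @param n_trials,lambda Search budget and spectral-angle penalty for the
#'   SG tuning.
#' @param params Optional fixed [sg_params()] (skips tuning).
#' @param cfg A [unet_config()]; built from the data length at fit time
#'   when NULL (desk-scale defaults).
#' @param tc A [train_config()].
#' @param ... Arguments passed to [unet_config()] when `cfg` is NULL.
#' @return A `restoration_method` object.
#' @name restoration_methods
NULL

new_method <- function(name, fit, predict) {
  structure(list(name = name, fit = fit, predict = predict),
            class = "restoration_method")
}

#' @rdname restoration_methods
#' @export
method_oracle <- function() {
  new_method("oracle",
             fit = function(ctx, seed) NULL,
             predict = function(model, ctx, rows)
               ctx$tb2[rows, , drop = FALSE])
}

#' @rdname restoration_methods
#' @export
method_identity <- function() {
  new_method("identity",
             fit = function(ctx, seed) NULL,
             predict = function(model, ctx, rows)
               ctx$lqb2[rows, , drop = FALSE])
}

#' @rdname restoration_methods
#' @export
method_traditional <- function(n_trials = 60L, lambda = 0.1,
                               params = NULL) {
  new_method(
    "sg_snip",
    fit = function(ctx, seed) {
      if (!is.null(params)) return(list(sg = params))
      tr <- ctx$train_idx
      folds <- split(seq_along(tr), ctx$labels[tr])
      list(sg = tune_sg(ctx$x1[tr, , drop = FALSE],
                        ctx$ta1[tr, , drop = FALSE],
                        n_trials = n_trials, lambda = lambda,
                        folds = folds, seed = seed)$params)
    },
    predict = function(model, ctx, rows)
      traditional_restore(ctx$x1[rows, , drop = FALSE], ctx$state1,
                          model$sg, ctx$snip, ctx$bounds2, rows = rows))
}

#' @rdname restoration_methods
#' @export
method_single_unet <- function(cfg = NULL, tc = train_config(), ...) {
  new_method(
    "single_unet",
    fit = function(ctx, seed) {
      tr <- ctx$train_idx
      cfg <- if (is.null(cfg)) unet_config(ncol(ctx$x1), ...) else cfg
      tc$seed <- derive_seed(seed, 11L)
      train_single(ctx$x1[tr, , drop = FALSE],
                   ctx$tb2[tr, , drop = FALSE], cfg, tc)
    },
    predict = function(model, ctx, rows)
      predict_single(model, ctx$x1[rows, , drop = FALSE]))
}

#' @rdname restoration_methods
#' @export
method_cascade <- function(cfg = NULL, tc = train_config(), ...) {
  new_method(
    "cascade",
    fit = function(ctx, seed) {
      tr <- ctx$train_idx
      cfg <- if (is.null(cfg)) unet_config(ncol(ctx$x1), ...) else cfg
      tc$seed <- derive_seed(seed, 12L)
      train_cascade(ctx$x1[tr, , drop = FALSE],
                    ctx$ta1[tr, , drop = FALSE],
                    ctx$tb2[tr, , drop = FALSE],
                    ctx$bridge_cfg, rows = tr, cfg, tc)
    },
    predict = function(model, ctx, rows)
      predict_cascade(model, ctx$x1[rows, , drop = FALSE], rows = rows))
}

#' Leave-one-sample-out evaluation of restoration methods
#'
#' For every FOV in turn: fit each method on the remaining FOVs' rows and
#' predict the held-out rows; score all predictions (plus the non-learning
#' processed-LQ baseline, reported as method `lq_baseline`) against the
#' stage-2 baseline-free HQ reference.
#'
#' @param data A [paired_dataset()] with at least 2 FOVs.
#' @param methods Named list of `restoration_method` objects.
#' @param snip A [snip_params()] shared by target construction, the bridge
#'   and the LQ baseline.
#' @param seed Master seed (per-fold sub-seeds are derived from it).
#' @param keep_predictions Keep the per-fold prediction matrices.
#' @param model_store Optional directory; fitted models are cached there
#'   and reused on later runs instead of being refit (the basis of the
#'   pipeline's `skip_train` mode).
#' @return Object of class `loso_result` with `per_spectrum` (method, fov,
#'   row, rmse, mae, sam_deg, pcc), `fov_summary` (FOV medians),
#'   `summary` (mean, sd across FOVs and reduction % vs `lq_baseline`),
#'   and optionally `predictions`.
#' @export
loso_evaluate <- function(data, methods, snip = snip_params(), seed = 1L,
                          keep_predictions = FALSE, model_store = NULL) {
  stopifnot(inherits(data, "paired_dataset"))
  fovs <- unique(data$lq$sample_labels)
  if (length(fovs) < 2L) stop("LOSO requires at least 2 FOVs")
  stopifnot(length(methods) > 0,
            all(vapply(methods, inherits, TRUE, "restoration_method")))
  if (is.null(names(methods)))
    names(methods) <- vapply(methods, `[[`, "", "name")
  per <- list()
  preds <- list()
  for (f in seq_along(fovs)) {
    fov <- fovs[f]
    ctx <- fold_context(data, fov, snip)
    te <- ctx$test_idx
    ref <- ctx$tb2[te, , drop = FALSE]
    score <- function(name, pred) {
      m <- metrics_rows(pred, ref)
      cbind(method = name, fov = fov, row = te, m,
            stringsAsFactors = FALSE)
    }
    per[[length(per) + 1L]] <- score("lq_baseline",
                                     ctx$lqb2[te, , drop = FALSE])
    for (nm in names(methods)) {
      meth <- methods[[nm]]
      store <- if (!is.null(model_store))
        file.path(model_store, paste0(nm, "_", fov, ".rds"))
      if (!is.null(store) && file.exists(store)) {
        model <- readRDS(store)
      } else {
        model <- meth$fit(ctx, derive_seed(seed, 100L + f))
        if (!is.null(store) && !is.null(model)) {
          dir.create(model_store, showWarnings = FALSE, recursive = TRUE)
          saveRDS(model, store)
        }
      }
      pred <- meth$predict(model, ctx, te)
      per[[length(per) + 1L]] <- score(nm, pred)
      if (keep_predictions) preds[[paste(nm, fov, sep = ".")]] <- pred
    }
  }
  per <- do.call(rbind, per)
  fov_summary <- stats::aggregate(
    per[, c("rmse", "mae", "sam_deg", "pcc")],
    by = list(method = per$method, fov = per$fov), FUN = stats::median)
  metrics <- c("rmse", "mae", "sam_deg", "pcc")
  rows <- list()
  base <- fov_summary[fov_summary$method == "lq_baseline", ]
  for (nm in unique(fov_summary$method)) {
    sub <- fov_summary[fov_summary$method == nm, ]
    for (m in metrics) {
      red <- if (nm != "lq_baseline" && m != "pcc")
        reduction_percent(mean(base[[m]]), mean(sub[[m]])) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        method = nm, metric = m, mean = mean(sub[[m]]),
        sd = stats::sd(sub[[m]]), reduction_pct = red,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(per_spectrum = per, fov_summary = fov_summary,
                 summary = do.call(rbind, rows),
                 predictions = if (keep_predictions) preds),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat("<loso_result>\n")
  print(x$summary, digits = 4)
  invisible(x)
}
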