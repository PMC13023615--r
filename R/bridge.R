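# The physics bridge: the deterministic, parameter-free layer between the
# cascade's two networks. It maps a stage-1-normalized batch back to
# physical absorbance using the input's stored per-spectrum statistics,
# subtracts the SNIP baseline there (geometric clipping only makes sense on
# absolute intensities), and re-normalizes into the stage-2 domain. It is
# active identically during training and inference; during training no
# gradient is propagated through it (the two networks are supervised
# independently), matching the decoupled deep-supervision scheme.

#' Physics bridge configuration
#'
#' @param snip A [snip_params()] for the absorbance-domain baseline
#'   subtraction.
#' @param state1 Stage-1 [normalization_state()] carrying the per-spectrum
#'   SNV statistics of the raw inputs and the stage-1 min-max bounds.
#' @param stage2_bounds Train-derived stage-2 min-max bounds
#'   (`list(min, max)`).
#' @return An object of class `bridge_config`. The layer has zero trainable
#'   parameters (`n_params` field, asserted by tests).
#' @export
bridge_config <- function(snip, state1, stage2_bounds) {
  stopifnot(inherits(snip, "snip_params"),
            inherits(state1, "normalization_state"))
  if (state1$stage != "stage1")
    stop("bridge stage-1 state has stage label '", state1$stage, "'")
  if (is.null(stage2_bounds$min) || is.null(stage2_bounds$max) ||
      stage2_bounds$max <= stage2_bounds$min)
    stop("invalid stage-2 min-max bounds")
  structure(list(snip = snip, state1 = state1,
                 stage2_bounds = stage2_bounds, n_params = 0L),
            class = "bridge_config")
}

#' Apply the physics bridge
#'
#' `out = stage2_normalize(z - snip_baseline(z))` with
#' `z = inverse_snv(inverse_minmax(x))` computed from the stored stage-1
#' statistics of each input row. A baseline-free absorbance image passes
#' through as a pure renormalization (SNIP finds an ~0 baseline).
#'
#' @param x Stage-1-normalized matrix (or vector), one spectrum per row.
#' @param cfg A [bridge_config()].
#' @param rows Optional indices mapping rows of `x` into the stage-1
#'   state's per-spectrum statistics (for mini-batches).
#' @return Stage-2-normalized, baseline-free matrix of the same shape.
#' @export
bridge <- function(x, cfg, rows = NULL) {
  stopifnot(inherits(cfg, "bridge_config"))
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  n_stats <- length(cfg$state1$snv_mean)
  if (is.null(rows) && nrow(x) != n_stats)
    stop("batch has ", nrow(x), " rows but the stage-1 state stores ",
         n_stats, " spectra; pass `rows`")
  if (!is.null(rows) && any(rows < 1L | rows > n_stats))
    stop("`rows` outside the stored stage-1 statistics")
  z <- stage_denormalize(x, cfg$state1, rows)
  zc <- z - snip_baseline(z, cfg$snip)
  out <- to_stage2(zc, cfg$stage2_bounds, guard = TRUE)
  if (vec) out <- drop(out)
  out
}

#' Serialize / restore a bridge configuration
#'
#' The bridge travels inside model checkpoints as plain JSON so that a
#' restored model applies bit-identical spectroscopic constraints.
#'
#' @param cfg A [bridge_config()].
#' @return `bridge_to_list()`: a plain list; `bridge_from_list()`: the
#'   reconstructed [bridge_config()].
#' @export
bridge_to_list <- function(cfg) {
  list(snip = unclass(cfg$snip),
       state1 = unclass(cfg$state1),
       stage2_bounds = cfg$stage2_bounds)
}

#' @rdname bridge_to_list
#' @param x A list produced by `bridge_to_list()`.
#' @export
bridge_from_list <- function(x) {
  st <- x$state1
  bridge_config(snip_params(x$snip$max_half_window, isTRUE(x$snip$lls)),
                normalization_state(st$snv_mean, st$snv_sd, st$stage,
                                    st$global_min, st$global_max),
                list(min = x$stage2_bounds$min, max = x$stage2_bounds$max))
}
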