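# Preparation and preprocessing: Otsu foreground masking on integrated band
# intensity, mean-background (water vapor) subtraction, spectral trimming,
# SNV, train-only global min-max — all with exact stored-statistics
# inversion, which is the invertibility contract the physics bridge relies
# on.

#' Normalization state
#'
#' Per-spectrum SNV statistics plus stage-wise global min/max bounds. Given
#' this state the normalization pipeline is exactly invertible; held-out
#' values are never clipped to [0, 1] precisely so that inversion stays
#' exact.
#'
#' @param snv_mean,snv_sd Numeric vectors, one entry per spectrum.
#' @param stage `"stage1"` (baseline-retained domain) or `"stage2"`
#'   (baseline-free domain).
#' @param global_min,global_max Train-derived bounds in post-SNV units
#'   (NA until fitted).
#' @return An object of class `normalization_state`.
#' @export
normalization_state <- function(snv_mean, snv_sd, stage = "stage1",
                                global_min = NA_real_,
                                global_max = NA_real_) {
  stage <- match.arg(stage, c("stage1", "stage2"))
  if (length(snv_mean) != length(snv_sd))
    stop("snv_mean and snv_sd lengths differ")
  if (any(snv_sd <= 0)) stop("snv_sd must be > 0 for every spectrum")
  if (!is.na(global_min) && !is.na(global_max) && global_max <= global_min)
    stop("global_max must exceed global_min")
  structure(list(snv_mean = as.numeric(snv_mean),
                 snv_sd = as.numeric(snv_sd), stage = stage,
                 global_min = global_min, global_max = global_max),
            class = "normalization_state")
}

#' Otsu threshold of a numeric vector
#'
#' Histogram-based threshold maximizing the between-class variance; the
#' returned value is the bin edge separating the two classes.
#'
#' @param x Numeric vector with at least two distinct values.
#' @param nbins Number of histogram bins.
#' @return Scalar threshold; `x > threshold` is the foreground class.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2L)
    stop("Otsu threshold undefined: all values are equal")
  edges <- seq(min(x), max(x), length.out = nbins + 1L)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = nbins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w <- counts / sum(counts)
  # between-class variance for every cut after bin k
  w0 <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[nbins]
  valid <- w0 > 0 & w0 < 1
  bcv <- rep(-Inf, nbins)
  bcv[valid] <- (mu_t * w0[valid] - mu[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  k <- which.max(bcv)
  edges[k + 1L]
}

#' Foreground mask from integrated band intensity
#'
#' Sums the absorbance over the union of the given wavenumber ranges per
#' pixel (default: fingerprint 1000-1800 and C-H stretching 2800-3000
#' cm^-1) and thresholds the resulting scalar image with Otsu's method.
#'
#' @param cube A [hypercube()].
#' @param band_ranges List of `c(lo, hi)` wavenumber intervals.
#' @return Logical `height x width` mask; TRUE = foreground.
#' @export
otsu_mask <- function(cube,
                      band_ranges = list(c(1000, 1800), c(2800, 3000))) {
  stopifnot(inherits(cube, "hypercube"))
  nu <- cube$axis$values
  sel <- rep(FALSE, length(nu))
  for (r in band_ranges) {
    if (r[1] > max(nu) || r[2] < min(nu))
      stop("band range [", r[1], ", ", r[2], "] lies outside the axis")
    sel <- sel | (nu >= r[1] & nu <= r[2])
  }
  flat <- matrix(cube$data, cube$height * cube$width, length(nu))
  score <- rowSums(flat[, sel, drop = FALSE])
  thr <- otsu_threshold(score)
  matrix(score > thr, cube$height, cube$width)
}

#' Subtract the mean background spectrum from foreground pixels
#'
#' Removes FOV-shared atmospheric structure (water-vapor lines) by
#' subtracting the average spectrum of the non-sample pixels from every
#' foreground spectrum. Background pixels are left untouched (they are
#' discarded downstream).
#'
#' @param cube A [hypercube()].
#' @param mask Logical foreground mask (defaults to the cube's own).
#' @return A corrected [hypercube()] carrying `mask`.
#' @export
atmospheric_correct <- function(cube, mask = cube$mask) {
  stopifnot(inherits(cube, "hypercube"))
  if (is.null(mask)) stop("a foreground mask is required")
  if (!any(!mask)) stop("no background pixels to average")
  flat <- matrix(cube$data, cube$height * cube$width, length(cube$axis))
  bg <- colMeans(flat[!as.vector(mask), , drop = FALSE])
  fg <- as.vector(mask)
  flat[fg, ] <- sweep(flat[fg, , drop = FALSE], 2, bg, "-")
  hypercube(array(flat, dim(cube$data)), cube$axis, mask)
}

#' Spectral trim specification
#'
#' @param exclude List of `c(lo, hi)` wavenumber ranges to drop (e.g. the
#'   2250-2401 cm^-1 CO2 band). Ranges must not overlap.
#' @param keep Optional `c(lo, hi)` retained range applied first (detector
#'   edge trim); default 964-3800 cm^-1.
#' @return An object of class `trim_spec`.
#' @export
trim_spec <- function(exclude = list(c(2250, 2401)), keep = c(964, 3800)) {
  if (length(exclude)) {
    m <- do.call(rbind, exclude)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[, 2] < m[, 1])) stop("exclude ranges must have lo <= hi")
    if (nrow(m) > 1 && any(m[-1, 1] <= m[-nrow(m), 2]))
      stop("exclude ranges must not overlap")
  }
  structure(list(exclude = exclude, keep = keep), class = "trim_spec")
}

#' Trim a spectrum set
#'
#' Applies the retained edge range, then drops the excluded ranges, from both
#' the axis and every spectrum. The resulting axis is non-uniform across the
#' gaps, so downstream position errors must use actual wavenumbers.
#'
#' @param set A [spectrum_set()].
#' @param spec A [trim_spec()].
#' @return The trimmed [spectrum_set()].
#' @export
trim_spectra <- function(set, spec = trim_spec()) {
  stopifnot(inherits(set, "spectrum_set"), inherits(spec, "trim_spec"))
  nu <- set$axis$values
  keep <- rep(TRUE, length(nu))
  if (!is.null(spec$keep))
    keep <- nu >= spec$keep[1] & nu <= spec$keep[2]
  for (r in spec$exclude)
    keep <- keep & !(nu >= r[1] & nu <= r[2])
  if (sum(keep) < 8L)
    stop("trim would leave fewer than 8 axis points")
  spectrum_set(wn_axis(nu[keep]), set$intensities[, keep, drop = FALSE],
               set$sample_labels)
}

# ---- SNV ---------------------------------------------------------------

#' Standard normal variate transform
#'
#' Centers and scales each spectrum by its own mean and sample standard
#' deviation (denominator L-1), removing additive offsets and multiplicative
#' scatter. The per-spectrum statistics are returned for exact inversion.
#'
#' @param x Numeric matrix (one spectrum per row) or vector.
#' @return List with `x` (transformed matrix), `mean`, `sd`.
#' @export
snv <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (ncol(x) - 1L))
  if (any(s <= 0 | !is.finite(s))) {
    bad <- which(s <= 0 | !is.finite(s))[1]
    stop("SNV undefined for constant spectrum at row ", bad)
  }
  list(x = (x - m) / s, mean = m, sd = s)
}

#' Invert the SNV transform
#'
#' @param x SNV-transformed matrix (one spectrum per row).
#' @param mean,sd Per-row statistics stored by [snv()].
#' @return The original-scale matrix.
#' @export
inverse_snv <- function(x, mean, sd) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (length(mean) != nrow(x) || length(sd) != nrow(x))
    stop("need one stored mean/sd per spectrum row")
  x * sd + mean
}

# ---- global min-max ----------------------------------------------------

#' Fit global min-max bounds on training rows
#'
#' @param x Numeric matrix of training spectra (post-SNV units).
#' @return List with `min`, `max`.
#' @export
minmax_fit <- function(x) {
  mn <- min(x); mx <- max(x)
  if (mx <= mn) stop("min-max bounds degenerate: max <= min")
  list(min = mn, max = mx)
}

#' Apply global min-max scaling
#'
#' Training rows land in [0, 1]; held-out rows may fall outside and are NOT
#' clipped (clipping would break the exact invertibility required by the
#' physics bridge).
#'
#' @param x Numeric matrix or vector.
#' @param bounds Bounds from [minmax_fit()].
#' @return Scaled values, same shape as `x`.
#' @export
minmax_apply <- function(x, bounds) {
  (x - bounds$min) / (bounds$max - bounds$min)
}

#' Invert global min-max scaling
#'
#' @inheritParams minmax_apply
#' @return Original-scale values.
#' @export
minmax_invert <- function(x, bounds) {
  x * (bounds$max - bounds$min) + bounds$min
}

#' Normalize a spectrum matrix into a stage domain
#'
#' SNV per spectrum followed by global min-max under the supplied (or newly
#' fitted) bounds. Returns the data and its full [normalization_state()].
#'
#' @param x Numeric matrix, one spectrum per row.
#' @param stage `"stage1"` or `"stage2"`.
#' @param bounds Min-max bounds from training rows; fitted on `x` when NULL
#'   (only valid if `x` is itself the training set).
#' @return List with `x` (normalized matrix) and `state`.
#' @export
stage_normalize <- function(x, stage = "stage1", bounds = NULL) {
  sn <- snv(x)
  if (is.null(bounds)) bounds <- minmax_fit(sn$x)
  st <- normalization_state(sn$mean, sn$sd, stage,
                            bounds$min, bounds$max)
  list(x = minmax_apply(sn$x, bounds), state = st)
}

#' Invert a stage normalization exactly
#'
#' @param x Normalized matrix (one spectrum per row, aligned with `state`).
#' @param state The matching [normalization_state()].
#' @param rows Optional row indices into the state's per-spectrum stats, for
#'   partial batches.
#' @return Absorbance-scale matrix.
#' @export
stage_denormalize <- function(x, state, rows = NULL) {
  stopifnot(inherits(state, "normalization_state"))
  if (is.na(state$global_min)) stop("state has no fitted min-max bounds")
  mean <- state$snv_mean; sd <- state$snv_sd
  if (!is.null(rows)) { mean <- mean[rows]; sd <- sd[rows] }
  inverse_snv(minmax_invert(x, list(min = state$global_min,
                                    max = state$global_max)), mean, sd)
}

#' Build the cascade's two supervision targets from HQ spectra
#'
#' Target A is the HQ set unchanged (native baseline retained; stage-1
#' domain). Target B is the HQ set after SNIP baseline subtraction (stage-2
#' domain). Each target is normalized under its own stage statistics, with
#' min-max bounds fitted on the rows in `train_idx`.
#'
#' @param hq A [spectrum_set()] of high-quality spectra.
#' @param snip [snip_params()] for the target-B baseline subtraction.
#' @param train_idx Rows used to fit min-max bounds (default: all rows).
#' @return List with `target_a`, `target_b` (normalized matrices),
#'   `state_a`, `state_b`, and `target_b_raw` (absorbance-scale, baseline
#'   free).
#' @export
build_targets <- function(hq, snip = snip_params(), train_idx = NULL) {
  stopifnot(inherits(hq, "spectrum_set"))
  if (is.null(train_idx)) train_idx <- seq_len(n_spectra(hq))
  a_raw <- hq$intensities
  b_raw <- a_raw - snip_baseline(a_raw, snip)
  sn_a <- snv(a_raw); sn_b <- snv(b_raw)
  bounds_a <- minmax_fit(sn_a$x[train_idx, , drop = FALSE])
  bounds_b <- minmax_fit(sn_b$x[train_idx, , drop = FALSE])
  list(target_a = minmax_apply(sn_a$x, bounds_a),
       target_b = minmax_apply(sn_b$x, bounds_b),
       state_a = normalization_state(sn_a$mean, sn_a$sd, "stage1",
                                     bounds_a$min, bounds_a$max),
       state_b = normalization_state(sn_b$mean, sn_b$sd, "stage2",
                                     bounds_b$min, bounds_b$max),
       target_b_raw = b_raw)
}
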