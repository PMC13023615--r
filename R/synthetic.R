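# Synthetic paired LQ/HQ FTIR spectra. The generator states one fixed
# "world": protein/lipid band structure on a smooth additive baseline with a
# broad oscillation, FOV-shared water-vapor lines, a per-spectrum
# multiplicative scatter gain, and white noise whose standard deviation
# scales as sigma0 / sqrt(n_scans). One field of view can be designated as
# drift-affected and receives an out-of-distribution baseline family.

#' Synthetic data configuration
#'
#' Defaults emulate transmission-mode FTIR imaging of cultured carcinoma
#' cells: 1584-point axis over 950-4000 cm^-1, fingerprint / Amide I-II /
#' CHx bands, single-scan white-noise sd `sigma0` = 0.015 a.u. (about 3% of
#' the Amide I amplitude), quadratic baseline drift plus a broad oscillation,
#' sparse water-vapor lines confined to 1300-1900 and 3550-3900 cm^-1, and a
#' log-uniform multiplicative scatter gain in [0.8, 1.25].
#'
#' @param axis_start,axis_end Axis bounds in cm^-1 (`axis_start < axis_end`).
#' @param n_points Number of axis points (>= 64).
#' @param peaks Data frame with columns `center`, `width`, `amplitude`,
#'   `shape` ("gaussian" or "lorentzian"); `width` is the Gaussian sd or the
#'   Lorentzian half-width at half-maximum, in cm^-1.
#' @param amp_jitter Peak amplitudes are scaled per spectrum by
#'   `runif(1 - amp_jitter, 1 + amp_jitter)`.
#' @param baseline_poly_amp Scale (a.u.) of the random polynomial baseline
#'   coefficients (degree 2 by default; the drift FOV adds a cubic term).
#' @param osc_amp,osc_period Amplitude (a.u.) and period (cm^-1) of the broad
#'   baseline oscillation; the phase is random per acquisition.
#' @param sigma0 White-noise sd (a.u.) of a single scan.
#' @param wv_amp Water-vapor line amplitude (a.u.); lines are shared across
#'   the pixels of a FOV so mean-background subtraction can remove them.
#' @param wv_lines Number of water-vapor lines per FOV.
#' @param scatter_range Multiplicative scatter gain range (log-uniform).
#' @param drift_scale Baseline amplification for the drift-affected FOV.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(axis_start = 950, axis_end = 4000,
                             n_points = 1584L,
                             peaks = default_peak_library(),
                             amp_jitter = 0.3,
                             baseline_poly_amp = 0.08,
                             osc_amp = 0.04, osc_period = 1500,
                             sigma0 = 0.015,
                             wv_amp = 0.004, wv_lines = 12L,
                             scatter_range = c(0.8, 1.25),
                             drift_scale = 3) {
  if (axis_end <= axis_start)
    stop("axis_end must exceed axis_start")
  if (n_points < 64L) stop("n_points must be >= 64")
  if (sigma0 < 0) stop("sigma0 must be >= 0")
  stopifnot(is.data.frame(peaks),
            all(c("center", "width", "amplitude", "shape") %in% names(peaks)))
  if (any(peaks$width <= 0)) stop("peak widths must be > 0")
  structure(list(axis_start = axis_start, axis_end = axis_end,
                 n_points = as.integer(n_points), peaks = peaks,
                 amp_jitter = amp_jitter,
                 baseline_poly_amp = baseline_poly_amp,
                 osc_amp = osc_amp, osc_period = osc_period,
                 sigma0 = sigma0, wv_amp = wv_amp,
                 wv_lines = as.integer(wv_lines),
                 scatter_range = scatter_range, drift_scale = drift_scale),
            class = "synthetic_config")
}

#' Default biological band library
#'
#' Bands near 1080 (nucleic acid / carbohydrate), 1240 (Amide III /
#' phosphate), 1400 (COO- symmetric stretch), 1545 (Amide II), 1655
#' (Amide I) and 2850/2925/2960 cm^-1 (lipid CH2/CH3 stretches); amplitudes
#' are in absorbance units typical of single-cell FTIR.
#'
#' @return Data frame usable as the `peaks` field of [synthetic_config()].
#' @export
default_peak_library <- function() {
  data.frame(
    center    = c(1080, 1240, 1400, 1545, 1655, 2850, 2925, 2960),
    width     = c(  25,   22,   18,   18,   20,   10,   12,    9),
    amplitude = c(0.15, 0.12, 0.10, 0.30, 0.50, 0.10, 0.18, 0.08),
    shape     = c("gaussian", "gaussian", "gaussian", "gaussian",
                  "lorentzian", "gaussian", "gaussian", "gaussian"),
    stringsAsFactors = FALSE)
}

#' Build the synthetic wavenumber axis
#'
#' @param config A [synthetic_config()].
#' @return An evenly spaced ascending [wn_axis()].
#' @export
make_axis <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  wn_axis(seq(config$axis_start, config$axis_end,
              length.out = config$n_points))
}

peak_profile <- function(nu, center, width, amplitude, shape) {
  if (shape == "gaussian")
    amplitude * exp(-0.5 * ((nu - center) / width)^2)
  else # lorentzian, width = HWHM
    amplitude / (1 + ((nu - center) / width)^2)
}

#' Generate one noiseless spectrum
#'
#' Sum of the configured band shapes on a zero baseline, with per-spectrum
#' amplitude jitter. Non-negative by construction.
#'
#' @param config A [synthetic_config()].
#' @param axis Optional precomputed [make_axis()] result.
#' @return Numeric vector of length `config$n_points`.
#' @export
clean_spectrum <- function(config, axis = make_axis(config)) {
  if (nrow(config$peaks) == 0L) stop("peak library is empty")
  nu <- axis$values
  y <- numeric(length(nu))
  scale <- stats::runif(nrow(config$peaks), 1 - config$amp_jitter,
                        1 + config$amp_jitter)
  for (i in seq_len(nrow(config$peaks))) {
    p <- config$peaks[i, ]
    y <- y + peak_profile(nu, p$center, p$width, p$amplitude * scale[i],
                          p$shape)
  }
  y
}

# Random smooth baseline on the normalized axis u in [-1, 1]. The drift
# family triples the amplitude and adds a cubic term (non-averageable
# environmental drift).
random_baseline <- function(nu, config, drift = FALSE) {
  u <- 2 * (nu - min(nu)) / (max(nu) - min(nu)) - 1
  amp <- config$baseline_poly_amp * (if (drift) config$drift_scale else 1)
  coef <- stats::rnorm(3, 0, amp)
  b <- coef[1] + coef[2] * u + coef[3] * u^2
  if (drift) b <- b + stats::rnorm(1, 0, amp) * u^3
  osc_amp <- config$osc_amp * (if (drift) config$drift_scale else 1)
  phase <- stats::runif(1, 0, 2 * pi)
  b + osc_amp * sin(2 * pi * nu / config$osc_period + phase)
}

# FOV-shared water-vapor artifact: sparse narrow lines in the rotational
# water bands (1300-1900 and 3550-3900 cm^-1), random sign.
water_vapor_profile <- function(nu, config) {
  wv <- numeric(length(nu))
  if (config$wv_lines == 0L || config$wv_amp == 0) return(wv)
  bands <- rbind(c(1300, 1900), c(3550, 3900))
  ok <- c(nu[nu >= bands[1, 1] & nu <= bands[1, 2]],
          nu[nu >= bands[2, 1] & nu <= bands[2, 2]])
  if (length(ok) == 0L) return(wv)
  centers <- sample(ok, min(config$wv_lines, length(ok)))
  for (cc in centers) {
    a <- config$wv_amp * stats::runif(1, 0.3, 1) * sample(c(-1, 1), 1)
    wv <- wv + a * exp(-0.5 * ((nu - cc) / 2.5)^2)
  }
  wv
}

#' Corrupt a clean spectrum into a measured acquisition
#'
#' `measured = gain * clean + baseline + water_vapor + noise`, with noise
#' i.i.d. normal of sd `sigma0 / sqrt(n_scans)` — the minimal model
#' consistent with 1/sqrt(N) scan averaging. All injected components are
#' returned so tests can verify the exact decomposition.
#'
#' @param clean Numeric spectrum (length = axis length).
#' @param n_scans Positive integer number of co-added scans.
#' @param config A [synthetic_config()].
#' @param axis Optional precomputed axis.
#' @param baseline,water_vapor,gain Optional fixed components; drawn from the
#'   configured families when NULL.
#' @param drift Use the drift (out-of-distribution) baseline family.
#' @return List with `spectrum`, `baseline`, `water_vapor`, `gain`, `noise`.
#' @export
corrupt_spectrum <- function(clean, n_scans, config,
                             axis = make_axis(config),
                             baseline = NULL, water_vapor = NULL,
                             gain = NULL, drift = FALSE) {
  if (length(n_scans) != 1L || n_scans <= 0)
    stop("n_scans must be a positive integer")
  nu <- axis$values
  if (is.null(baseline)) baseline <- random_baseline(nu, config, drift)
  if (is.null(water_vapor)) water_vapor <- water_vapor_profile(nu, config)
  if (is.null(gain))
    gain <- exp(stats::runif(1, log(config$scatter_range[1]),
                             log(config$scatter_range[2])))
  noise <- stats::rnorm(length(nu), 0, config$sigma0 / sqrt(n_scans))
  list(spectrum = gain * clean + baseline + water_vapor + noise,
       baseline = baseline, water_vapor = water_vapor,
       gain = gain, noise = noise)
}

#' Generate a paired LQ/HQ dataset over several fields of view
#'
#' Per pixel, one clean truth; the LQ row is an acquisition at 1 or 8 scans
#' (alternating by default) and the HQ rows at 32 scans. The LQ and HQ
#' acquisitions of a pixel share the scatter gain, baseline and water-vapor
#' component (back-to-back measurements of the same spot) and differ in
#' noise. Target A is the HQ spectrum with its native baseline; target B is
#' the same spectrum after SNIP baseline subtraction. The designated
#' `drift_fov` draws its baselines from the amplified out-of-distribution
#' family.
#'
#' @param n_fov Number of fields of view (>= 2).
#' @param pixels_per_fov Pixels per FOV.
#' @param config A [synthetic_config()].
#' @param drift_fov Index of the drift-affected FOV, or NULL for none.
#' @param scan_counts LQ scan counts cycled over pixels (default `c(1, 8)`).
#' @param snip [snip_params()] used to build target B.
#' @return A [paired_dataset()] with FOV labels `fov1..fovN` and the `clean`
#'   ground truth attached.
#' @export
make_paired_dataset <- function(n_fov, pixels_per_fov, config,
                                drift_fov = NULL,
                                scan_counts = c(1L, 8L),
                                snip = snip_params(
                                  max_half_window = default_snip_hw(config))) {
  stopifnot(inherits(config, "synthetic_config"))
  if (n_fov < 2L) stop("need at least 2 fields of view")
  axis <- make_axis(config)
  n <- n_fov * pixels_per_fov
  L <- length(axis)
  lq <- hq <- cl <- matrix(0, n, L)
  scans <- integer(n)
  labels <- character(n)
  row <- 0L
  for (f in seq_len(n_fov)) {
    drift <- !is.null(drift_fov) && f == drift_fov
    wv <- water_vapor_profile(axis$values, config)  # shared within the FOV
    for (p in seq_len(pixels_per_fov)) {
      row <- row + 1L
      clean <- clean_spectrum(config, axis)
      ns <- scan_counts[((p - 1L) %% length(scan_counts)) + 1L]
      base <- random_baseline(axis$values, config, drift)
      gain <- exp(stats::runif(1, log(config$scatter_range[1]),
                               log(config$scatter_range[2])))
      acq_lq <- corrupt_spectrum(clean, ns, config, axis, baseline = base,
                                 water_vapor = wv, gain = gain)
      acq_hq <- corrupt_spectrum(clean, 32L, config, axis, baseline = base,
                                 water_vapor = wv, gain = gain)
      lq[row, ] <- acq_lq$spectrum
      hq[row, ] <- acq_hq$spectrum
      cl[row, ] <- clean
      scans[row] <- ns
      labels[row] <- paste0("fov", f)
    }
  }
  hq_set <- spectrum_set(axis, hq, labels)
  hq_free <- spectrum_set(axis, hq - snip_baseline(hq, snip), labels)
  paired_dataset(spectrum_set(axis, lq, labels), hq_set, hq_free,
                 scans, clean = spectrum_set(axis, cl, labels))
}

# SNIP half-window sized to ~120 cm^-1 on the configured axis, clamped to
# stay below L/2.
default_snip_hw <- function(config) {
  interval <- (config$axis_end - config$axis_start) / (config$n_points - 1)
  min(max(2L, round(120 / interval)), config$n_points %/% 2L - 1L)
}

#' Generate a synthetic hyperspectral cube with cell-like blobs
#'
#' 2-6 elliptical "cell" blobs of elevated band intensity over a low-signal
#' substrate, plus the configured baseline/noise corruption; the ground-truth
#' blob mask is stored in the cube.
#'
#' @param config A [synthetic_config()].
#' @param height,width Spatial dimensions in pixels.
#' @param n_blobs Number of blobs (drawn uniformly from 2:6 when NULL).
#' @param contrast Foreground-to-substrate amplitude ratio (>= 1). At 1 the
#'   cube is contrast-free, which exercises the degenerate Otsu path.
#' @param n_scans Scan count controlling the noise level.
#' @return A [hypercube()] whose `mask` is the ground-truth blob mask.
#' @export
make_cube <- function(config, height = 32L, width = 32L, n_blobs = NULL,
                      contrast = 8, n_scans = 32L) {
  stopifnot(inherits(config, "synthetic_config"))
  axis <- make_axis(config)
  if (is.null(n_blobs)) n_blobs <- sample(2:6, 1)
  mask <- matrix(FALSE, height, width)
  for (b in seq_len(n_blobs)) {
    cy <- stats::runif(1, 0.15, 0.85) * height
    cx <- stats::runif(1, 0.15, 0.85) * width
    ry <- stats::runif(1, 0.08, 0.2) * height
    rx <- stats::runif(1, 0.08, 0.2) * width
    th <- stats::runif(1, 0, pi)
    yy <- matrix(seq_len(height), height, width) - cy
    xx <- matrix(seq_len(width), height, width, byrow = TRUE) - cx
    u <- cos(th) * xx + sin(th) * yy
    v <- -sin(th) * xx + cos(th) * yy
    mask <- mask | ((u / rx)^2 + (v / ry)^2 <= 1)
  }
  wv <- water_vapor_profile(axis$values, config)
  data <- array(0, c(height, width, length(axis)))
  for (i in seq_len(height)) for (j in seq_len(width)) {
    clean <- clean_spectrum(config, axis)
    amp <- if (mask[i, j]) 1 else 1 / contrast
    data[i, j, ] <- corrupt_spectrum(amp * clean, n_scans, config, axis,
                                     water_vapor = wv)$spectrum
  }
  hypercube(data, axis, mask)
}
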