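# Evaluation suite: global fidelity metrics (RMSE, MAE, spectral angle in
# degrees, Pearson correlation), prominence-based peak detection and
# one-to-one peak matching with position/height errors, the percentage
# reduction versus the processed-input baseline, the per-spectrum difficulty
# score, the band-free background-window stability metric, and the
# second-derivative comparison view.

#' Global reconstruction metrics for one spectrum pair
#'
#' RMSE and MAE of the pointwise difference, the spectral angle mapper (SAM,
#' degrees, cosine clamped to [-1, 1]), and the Pearson correlation
#' coefficient.
#'
#' @param pred,target Equal-length numeric vectors.
#' @return List with `rmse`, `mae`, `sam_deg`, `pcc` (`pcc` is NA with a
#'   warning when either spectrum is constant).
#' @export
global_metrics <- function(pred, target) {
  stopifnot(length(pred) == length(target))
  d <- pred - target
  pcc <- if (stats::sd(pred) == 0 || stats::sd(target) == 0) {
    warning("PCC undefined for a constant spectrum; returning NA")
    NA_real_
  } else stats::cor(pred, target)
  list(rmse = sqrt(mean(d^2)), mae = mean(abs(d)),
       sam_deg = 180 / pi *
         spectral_angle_rows(matrix(pred, 1), matrix(target, 1)),
       pcc = pcc)
}

# Row-wise metric table for aligned prediction/target matrices.
metrics_rows <- function(pred, target) {
  stopifnot(identical(dim(pred), dim(target)))
  d <- pred - target
  data.frame(rmse = sqrt(rowMeans(d^2)), mae = rowMeans(abs(d)),
             sam_deg = 180 / pi * spectral_angle_rows(pred, target),
             pcc = vapply(seq_len(nrow(pred)), function(i)
               stats::cor(pred[i, ], target[i, ]), numeric(1)))
}

#' Detect peaks by topographic prominence
#'
#' Strict local maxima whose prominence (height above the highest saddle
#' connecting the peak to higher terrain, or to the signal edge) reaches
#' `prominence_min`; at most `max_peaks` peaks are retained, ranked by
#' prominence. Defaults follow the normalized-domain convention
#' (prominence >= 0.02, <= 20 peaks).
#'
#' @param y Numeric spectrum.
#' @param axis Optional [wn_axis()] supplying peak wavenumbers.
#' @param prominence_min Minimum prominence.
#' @param max_peaks Retention cap.
#' @return Object of class `peak_set`: `indices`, `wavenumbers`, `heights`,
#'   `prominences`, sorted by prominence descending. May be empty.
#' @export
detect_peaks <- function(y, axis = NULL, prominence_min = 0.02,
                         max_peaks = 20L) {
  L <- length(y)
  if (L < 3L) return(structure(list(indices = integer(0),
                                    wavenumbers = numeric(0),
                                    heights = numeric(0),
                                    prominences = numeric(0)),
                               class = "peak_set"))
  core <- y[2:(L - 1L)]
  idx <- which(core > y[1:(L - 2L)] & core > y[3:L]) + 1L
  prom <- vapply(idx, function(i) peak_prominence(y, i), numeric(1))
  sel <- prom >= prominence_min
  idx <- idx[sel]; prom <- prom[sel]
  ord <- order(prom, decreasing = TRUE)
  if (length(ord) > max_peaks) ord <- ord[seq_len(max_peaks)]
  idx <- idx[ord]; prom <- prom[ord]
  structure(list(indices = idx,
                 wavenumbers = if (is.null(axis)) rep(NA_real_, length(idx))
                               else axis$values[idx],
                 heights = y[idx], prominences = prom),
            class = "peak_set")
}

# Prominence of the local maximum at index i: walk out on each side until a
# strictly higher sample or the edge; the base on that side is the minimum
# encountered; prominence = y[i] - max(left base, right base).
peak_prominence <- function(y, i) {
  left <- y[i]
  j <- i - 1L
  while (j >= 1L && y[j] <= y[i]) { left <- min(left, y[j]); j <- j - 1L }
  right <- y[i]
  j <- i + 1L
  L <- length(y)
  while (j <= L && y[j] <= y[i]) { right <- min(right, y[j]); j <- j + 1L }
  y[i] - max(left, right)
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peak(s)\n", length(x$indices)))
  invisible(x)
}

#' Match target and predicted peaks one-to-one
#'
#' Peaks are associated in spectral index space within a tolerance of
#' `tol` samples. The matching is the exact maximum-cardinality,
#' minimum-total-index-distance assignment, computed by dynamic programming
#' over the index-sorted peak sequences (for peaks on a line an optimal
#' assignment is non-crossing, so the DP is exact). Position errors are
#' reported in wavenumber units using the actual axis values; height bias is
#' the signed difference predicted minus target.
#'
#' @param target,pred [detect_peaks()] results on the same axis.
#' @param axis The shared [wn_axis()] (used for `e_pos`; falls back to the
#'   peak sets' stored wavenumbers, then to index units).
#' @param tol Matching tolerance in spectral samples.
#' @return Object of class `peak_match`: data frame `pairs` (target_index,
#'   pred_index, e_pos, e_amp), plus `unmatched_target`, `unmatched_pred`.
#' @export
match_peaks <- function(target, pred, axis = NULL, tol = 4L) {
  ti <- sort(target$indices); pi_ <- sort(pred$indices)
  nt <- length(ti); np <- length(pi_)
  # dp over prefixes: maximize matches, then minimize total index distance
  M <- matrix(0L, nt + 1L, np + 1L)
  D <- matrix(0, nt + 1L, np + 1L)
  for (i in seq_len(nt)) for (j in seq_len(np)) {
    best_m <- M[i, j + 1L]; best_d <- D[i, j + 1L]
    if (M[i + 1L, j] > best_m ||
        (M[i + 1L, j] == best_m && D[i + 1L, j] < best_d)) {
      best_m <- M[i + 1L, j]; best_d <- D[i + 1L, j]
    }
    dist <- abs(ti[i] - pi_[j])
    if (dist <= tol) {
      cm <- M[i, j] + 1L; cd <- D[i, j] + dist
      if (cm > best_m || (cm == best_m && cd < best_d)) {
        best_m <- cm; best_d <- cd
      }
    }
    M[i + 1L, j + 1L] <- best_m; D[i + 1L, j + 1L] <- best_d
  }
  # backtrack
  pairs_t <- integer(0); pairs_p <- integer(0)
  i <- nt; j <- np
  while (i > 0L && j > 0L) {
    dist <- abs(ti[i] - pi_[j])
    if (dist <= tol && M[i + 1L, j + 1L] == M[i, j] + 1L &&
        D[i + 1L, j + 1L] == D[i, j] + dist) {
      pairs_t <- c(ti[i], pairs_t); pairs_p <- c(pi_[j], pairs_p)
      i <- i - 1L; j <- j - 1L
    } else if (M[i + 1L, j + 1L] == M[i, j + 1L] &&
               D[i + 1L, j + 1L] == D[i, j + 1L]) {
      i <- i - 1L
    } else j <- j - 1L
  }
  nu_of <- function(set, idx) {
    if (!is.null(axis)) return(axis$values[idx])
    pos <- match(idx, set$indices)
    wn <- set$wavenumbers[pos]
    if (anyNA(wn)) as.numeric(idx) else wn
  }
  h_of <- function(set, idx) set$heights[match(idx, set$indices)]
  pairs <- data.frame(target_index = pairs_t, pred_index = pairs_p,
                      e_pos = abs(nu_of(pred, pairs_p) - nu_of(target, pairs_t)),
                      e_amp = h_of(pred, pairs_p) - h_of(target, pairs_t))
  structure(list(pairs = pairs,
                 unmatched_target = length(ti) - nrow(pairs),
                 unmatched_pred = length(pi_) - nrow(pairs)),
            class = "peak_match")
}

#' @export
print.peak_match <- function(x, ...) {
  cat(sprintf("<peak_match> %d pair(s), %d/%d unmatched target/pred\n",
              nrow(x$pairs), x$unmatched_target, x$unmatched_pred))
  invisible(x)
}

#' Percentage reduction versus the processed-input baseline
#'
#' `100 * (m_lq - m_method) / m_lq`.
#'
#' @param m_lq Metric value of the processed LQ baseline (> 0).
#' @param m_method Metric value of the evaluated method.
#' @return Percentage reduction (positive = improvement).
#' @export
reduction_percent <- function(m_lq, m_method) {
  if (any(m_lq <= 0)) stop("baseline metric must be > 0")
  100 * (m_lq - m_method) / m_lq
}

#' Per-spectrum difficulty scores
#'
#' `S_i = z(RMSE_i) + z(SAM_i) + z(noise_i) + z(baseline_i)` where the noise
#' proxy is the residual sd after Savitzky-Golay smoothing of the raw LQ
#' spectrum (window 11, order 3) and the baseline proxy is the fraction of
#' low-frequency power in the Fourier domain (bins 1-8 above DC, over all
#' non-DC power). z-scores use the population sd across the set; a component
#' with zero spread contributes 0 with a warning.
#'
#' @param lq_raw Raw (physical-domain) LQ matrix, one spectrum per row.
#' @param rmse,sam Per-spectrum metric vectors aligned with the rows.
#' @param noise_sg [sg_params()] of the noise proxy.
#' @param lowfreq_bins Fourier bins (above DC) counted as low-frequency.
#' @return Data frame `z_rmse`, `z_sam`, `z_noise`, `z_baseline`, `score`.
#' @export
difficulty_scores <- function(lq_raw, rmse, sam,
                              noise_sg = sg_params(11L, 3L),
                              lowfreq_bins = 8L) {
  if (is.null(dim(lq_raw))) lq_raw <- matrix(lq_raw, nrow = 1L)
  n <- nrow(lq_raw)
  if (n < 2L) stop("difficulty scores need at least 2 spectra")
  stopifnot(length(rmse) == n, length(sam) == n)
  resid <- lq_raw - sg_filter(lq_raw, noise_sg)
  noise <- apply(resid, 1, stats::sd)
  lowfrac <- apply(lq_raw, 1, function(y) {
    p <- Mod(stats::fft(y))^2
    half <- p[2:(floor(length(y) / 2) + 1L)]
    sum(half[seq_len(min(lowfreq_bins, length(half)))]) / sum(half)
  })
  zscore <- function(v, what) {
    s <- sqrt(mean((v - mean(v))^2))
    if (s == 0) {
      warning("zero spread in ", what, " component; z set to 0")
      return(rep(0, length(v)))
    }
    (v - mean(v)) / s
  }
  out <- data.frame(z_rmse = zscore(rmse, "rmse"),
                    z_sam = zscore(sam, "sam"),
                    z_noise = zscore(noise, "noise"),
                    z_baseline = zscore(lowfrac, "baseline"))
  out$score <- rowSums(out)
  out
}

#' Band-free background-window stability metric
#'
#' Standard deviation of the residual after a straight-line least-squares
#' fit of the spectrum over a band-free wavenumber window (default
#' 2500-2600 cm^-1). Under purely random noise, scan averaging reduces this
#' metric as 1/sqrt(N).
#'
#' @param spectrum Numeric spectrum (typically a mean background spectrum).
#' @param axis The [wn_axis()] of the spectrum.
#' @param window `c(lo, hi)` window in cm^-1.
#' @return Scalar noise value.
#' @export
stability_metric <- function(spectrum, axis, window = c(2500, 2600)) {
  sel <- axis$values >= window[1] & axis$values <= window[2]
  if (sum(sel) < 3L)
    stop("fewer than 3 axis points inside the stability window")
  nu <- axis$values[sel]; y <- spectrum[sel]
  fit <- stats::lm.fit(cbind(1, nu), y)
  stats::sd(fit$residuals)
}

#' Second-derivative view of a spectrum
#'
#' Savitzky-Golay second derivative with the fixed comparison settings
#' (window 17, polynomial order 3), taken with respect to wavenumber.
#'
#' @param x Numeric vector or matrix of spectra.
#' @param interval Sampling interval in cm^-1 (e.g. `axis$interval`).
#' @return The derivative spectrum/spectra.
#' @export
second_derivative_view <- function(x, interval = 1) {
  sg_filter(x, sg_params(17L, 3L, 2L), interval = interval)
}
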