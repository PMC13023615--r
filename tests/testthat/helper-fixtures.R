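# Shared fixtures: all synthetic, generated in code at test time.

# tiny fingerprint-region generator config (fast; 64-point axis)
tiny_config <- function(...) {
  args <- list(axis_start = 1000, axis_end = 1800, n_points = 64L,
               wv_lines = 3L)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

# small deterministic spectrum set
tiny_set <- function(n = 5L, L = 32L, seed = 1L, labels = "s1") {
  ax <- wn_axis(seq(1000, 1620, length.out = L))
  with_seed(seed, spectrum_set(ax, matrix(rnorm(n * L), n), labels))
}

# small paired dataset for end-to-end tests
tiny_paired <- function(n_fov = 2L, px = 16L, seed = 3L, n_points = 64L,
                        drift_fov = NULL, ...) {
  cfg <- tiny_config(n_points = n_points, ...)
  with_seed(seed,
            make_paired_dataset(n_fov, px, cfg, drift_fov = drift_fov,
                                snip = snip_params(10L)))
}

# independent brute-force peak prominence: scan to the nearest strictly
# higher sample on each side; base = min in between; edge counts as a base.
brute_prominence <- function(y, i) {
  L <- length(y)
  lo <- 1L; hi <- L
  for (j in seq(i - 1L, 1L)) if (y[j] > y[i]) { lo <- j; break }
  for (j in seq(i + 1L, L)) if (y[j] > y[i]) { hi <- j; break }
  left <- min(y[lo:i]); right <- min(y[i:hi])
  y[i] - max(left, right)
}

# independent brute-force peak matching: enumerate all one-to-one
# assignments within tolerance, maximize matches then minimize total
# index distance
brute_match <- function(ti, pi_, tol = 4L) {
  ti <- sort(ti); pi_ <- sort(pi_)
  best <- list(m = -1L, d = Inf)
  recurse <- function(i, used, m, d) {
    if (i > length(ti)) {
      if (m > best$m || (m == best$m && d < best$d))
        best <<- list(m = m, d = d)
      return(invisible())
    }
    recurse(i + 1L, used, m, d)  # skip target i
    for (j in seq_along(pi_)) {
      if (!used[j] && abs(ti[i] - pi_[j]) <= tol) {
        used[j] <- TRUE
        recurse(i + 1L, used, m + 1L, d + abs(ti[i] - pi_[j]))
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, length(pi_)), 0L, 0)
  best
}

# minimal peak_set for matcher tests
as_peakset <- function(idx, heights = NULL, prom = NULL) {
  structure(list(indices = idx,
                 wavenumbers = rep(NA_real_, length(idx)),
                 heights = if (is.null(heights)) rep(1, length(idx))
                           else heights,
                 prominences = if (is.null(prom)) rep(1, length(idx))
                               else prom),
            class = "peak_set")
}
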