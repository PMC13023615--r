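# Core carrier types (wavenumber axis, spectrum set, hyperspectral cube,
# paired LQ/HQ dataset) and their on-disk formats: delimited text tables for
# spectra and an HDF5 container for cubes.

#' Wavenumber axis
#'
#' An ascending axis of mid-infrared wavenumbers (cm^-1). The axis carries
#' the index -> wavenumber map used for peak position errors; after spectral
#' trimming (e.g. removal of the CO2 band) the axis is no longer uniform, so
#' positions must always be read off `values`, never reconstructed from the
#' nominal interval.
#'
#' @param values Numeric vector of wavenumbers in cm^-1, strictly monotonic,
#'   length >= 8. A descending vector is accepted and reversed.
#' @return An object of class `wn_axis` with fields `values` (ascending) and
#'   `interval` (median sampling interval, cm^-1 per index step).
#' @export
wn_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 8L)
    stop("wavenumber axis needs at least 8 points, got ", length(values))
  if (anyNA(values) || any(!is.finite(values)))
    stop("wavenumber axis must be finite")
  d <- diff(values)
  if (all(d < 0)) values <- rev(values)
  else if (!all(d > 0))
    stop("wavenumber axis must be strictly monotonic")
  interval <- stats::median(diff(values))
  if (interval <= 0) stop("axis sampling interval must be > 0")
  structure(list(values = values, interval = interval), class = "wn_axis")
}

#' @export
length.wn_axis <- function(x) length(x$values)

#' @export
print.wn_axis <- function(x, ...) {
  cat(sprintf("<wn_axis> %d points, %.4g-%.4g cm^-1, interval %.4g cm^-1\n",
              length(x$values), min(x$values), max(x$values), x$interval))
  invisible(x)
}

#' Spectrum set
#'
#' A set of absorbance spectra sharing one wavenumber axis, with a field-of-
#' view (sample) label per spectrum. This is the universal carrier passed
#' between preprocessing, restoration methods and the evaluation suite.
#'
#' @param axis A [wn_axis()].
#' @param intensities Numeric matrix, one spectrum per row, `ncol ==
#'   length(axis)`. A single spectrum may be given as a vector.
#' @param sample_labels Character or factor vector, one label per row
#'   (recycled if length 1). Defaults to `"s1"`.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(axis, intensities, sample_labels = "s1") {
  stopifnot(inherits(axis, "wn_axis"))
  if (is.null(dim(intensities)))
    intensities <- matrix(intensities, nrow = 1L)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (ncol(intensities) != length(axis))
    stop("intensities have ", ncol(intensities), " columns but axis has ",
         length(axis), " points")
  if (any(!is.finite(intensities)))
    stop("intensities must be finite")
  sample_labels <- as.character(sample_labels)
  if (length(sample_labels) == 1L)
    sample_labels <- rep(sample_labels, nrow(intensities))
  if (length(sample_labels) != nrow(intensities))
    stop("need one sample label per spectrum")
  dimnames(intensities) <- NULL
  structure(list(axis = axis, intensities = intensities,
                 sample_labels = sample_labels),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d points, %d sample(s)\n",
              nrow(x$intensities), ncol(x$intensities),
              length(unique(x$sample_labels))))
  invisible(x)
}

n_spectra <- function(set) nrow(set$intensities)

subset_spectra <- function(set, idx) {
  spectrum_set(set$axis, set$intensities[idx, , drop = FALSE],
               set$sample_labels[idx])
}

#' Hyperspectral cube
#'
#' A `height x width x L` absorbance cube on a shared wavenumber axis, with
#' an optional per-pixel boolean foreground mask.
#'
#' @param data 3D numeric array `height x width x L`.
#' @param axis A [wn_axis()] with `length(axis) == dim(data)[3]`.
#' @param mask Optional logical `height x width` matrix.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, axis, mask = NULL) {
  stopifnot(inherits(axis, "wn_axis"))
  d <- dim(data)
  if (length(d) != 3L) stop("cube data must be a 3D array")
  if (d[3] != length(axis))
    stop("cube spectral dimension (", d[3], ") != axis length (",
         length(axis), ")")
  if (any(!is.finite(data))) stop("cube data must be finite")
  storage.mode(data) <- "double"
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), d[1:2]))
      stop("mask shape must match the cube's spatial dimensions")
    mask <- matrix(as.logical(mask), d[1], d[2])
  }
  structure(list(data = data, axis = axis, mask = mask,
                 height = d[1], width = d[2]),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  cat(sprintf("<hypercube> %d x %d pixels x %d points%s\n", x$height,
              x$width, length(x$axis), if (is.null(x$mask)) "" else ", masked"))
  invisible(x)
}

#' Paired low/high-quality dataset
#'
#' Row-aligned low-quality (LQ) inputs with their two high-quality (HQ)
#' supervision targets: target A keeps the native baseline (stage-1 target of
#' the cascade) and target B is baseline-free (final target). Row i of every
#' member refers to the same pixel.
#'
#' @param lq,hq_with_baseline,hq_baseline_free [spectrum_set()]s sharing the
#'   axis, row count and sample labels.
#' @param scan_counts Integer vector, number of co-added scans behind each LQ
#'   row (recycled if length 1).
#' @param clean Optional [spectrum_set()] of noiseless ground-truth spectra
#'   (available for synthetic data only).
#' @return An object of class `paired_dataset`.
#' @export
paired_dataset <- function(lq, hq_with_baseline, hq_baseline_free,
                           scan_counts = 1L, clean = NULL) {
  sets <- list(lq, hq_with_baseline, hq_baseline_free)
  stopifnot(all(vapply(sets, inherits, TRUE, "spectrum_set")))
  n <- n_spectra(lq)
  for (s in sets[-1]) {
    if (n_spectra(s) != n) stop("paired sets must have equal row counts")
    if (!isTRUE(all.equal(s$axis$values, lq$axis$values)))
      stop("paired sets must share one wavenumber axis")
    if (!identical(s$sample_labels, lq$sample_labels))
      stop("paired sets must share sample labels")
  }
  scan_counts <- as.integer(scan_counts)
  if (length(scan_counts) == 1L) scan_counts <- rep(scan_counts, n)
  if (length(scan_counts) != n) stop("need one scan count per LQ row")
  structure(list(lq = lq, hq_with_baseline = hq_with_baseline,
                 hq_baseline_free = hq_baseline_free,
                 scan_counts = scan_counts, clean = clean),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("<paired_dataset> %d pixel rows, scans {%s}, %d FOV(s)\n",
              n_spectra(x$lq), paste(sort(unique(x$scan_counts)),
                                     collapse = ","),
              length(unique(x$lq$sample_labels))))
  invisible(x)
}

subset_paired <- function(pd, idx) {
  paired_dataset(subset_spectra(pd$lq, idx),
                 subset_spectra(pd$hq_with_baseline, idx),
                 subset_spectra(pd$hq_baseline_free, idx),
                 pd$scan_counts[idx],
                 if (!is.null(pd$clean)) subset_spectra(pd$clean, idx))
}

# ---- delimited text tables ---------------------------------------------

#' Read a delimited spectra table
#'
#' Canonical text format: header row of wavenumbers (optionally prefixed by a
#' `sample_label` column), one spectrum per data row. A descending axis in
#' the file is reversed (columns reordered consistently) so the returned axis
#' is always ascending.
#'
#' @param path File path.
#' @param sep Field delimiter; `"auto"` lets [data.table::fread()] sniff it.
#' @return A [spectrum_set()].
#' @export
read_spectra_table <- function(path, sep = "auto") {
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = NULL, data.table = FALSE)
  if (nrow(dt) == 0L) stop("no spectra rows in ", path)
  labels <- NULL
  if (identical(names(dt)[1], "sample_label")) {
    labels <- as.character(dt[[1]])
    dt <- dt[, -1, drop = FALSE]
  }
  wn <- suppressWarnings(as.numeric(names(dt)))
  if (anyNA(wn))
    stop("header of ", path, " must encode the wavenumber axis; ",
         "non-numeric column name at position ",
         which(is.na(wn))[1])
  mat <- as.matrix(dt)
  if (!is.numeric(mat)) {
    bad <- which(!vapply(dt, is.numeric, TRUE))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(dt[[bad]]))))[1]
    stop("non-numeric cell in ", path, " at row ", badrow, ", column ", bad)
  }
  if (all(diff(wn) < 0)) {
    wn <- rev(wn)
    mat <- mat[, ncol(mat):1, drop = FALSE]
  }
  spectrum_set(wn_axis(wn), mat,
               if (is.null(labels)) "s1" else labels)
}

#' Write a delimited spectra table
#'
#' @param set A [spectrum_set()].
#' @param path Output file path.
#' @param sep Field delimiter (default comma).
#' @param labels Write the `sample_label` column (default TRUE).
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(set, path, sep = ",", labels = TRUE) {
  stopifnot(inherits(set, "spectrum_set"))
  df <- as.data.frame(set$intensities)
  names(df) <- format(set$axis$values, digits = 17, trim = TRUE,
                      scientific = FALSE)
  if (labels) df <- cbind(sample_label = set$sample_labels, df)
  data.table::fwrite(df, path, sep = sep, quote = FALSE)
  invisible(path)
}

# ---- HDF5 cubes ---------------------------------------------------------

#' Write a hyperspectral cube to HDF5
#'
#' Fixed dataset names: `axis` (L), `data` (height x width x L), optional
#' `mask` (height x width, 0/1). All values are stored as 64-bit floats so a
#' write/read round-trip is lossless.
#'
#' @param cube A [hypercube()].
#' @param path Output `.h5` path (overwritten if it exists).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(cube$axis$values, path, "axis")
  rhdf5::h5createDataset(path, "data", dim(cube$data),
                         H5type = "H5T_IEEE_F64LE", chunk = NULL, level = 0)
  rhdf5::h5write(cube$data, path, "data")
  if (!is.null(cube$mask))
    rhdf5::h5write(cube$mask + 0L, path, "mask")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a hyperspectral cube from HDF5
#'
#' @param path Path to a container written by [write_cube()] (datasets
#'   `axis`, `data`, optional `mask`).
#' @return A [hypercube()].
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  names <- rhdf5::h5ls(path, recursive = FALSE)$name
  if (!"axis" %in% names)
    stop(path, " is not a cube container: missing dataset 'axis'")
  if (!"data" %in% names)
    stop(path, " is not a cube container: missing dataset 'data'")
  axis <- as.numeric(rhdf5::h5read(path, "axis"))
  data <- rhdf5::h5read(path, "data")
  mask <- if ("mask" %in% names) rhdf5::h5read(path, "mask") else NULL
  rhdf5::h5closeAll()
  if (length(dim(data)) != 3L)
    stop("dataset 'data' must be 3D")
  if (dim(data)[3] != length(axis))
    stop("axis length (", length(axis), ") does not match the cube's ",
         "spectral dimension (", dim(data)[3], ")")
  hypercube(data, wn_axis(axis),
            if (is.null(mask)) NULL else matrix(as.logical(mask),
                                                dim(data)[1], dim(data)[2]))
}

#' Flatten a cube's foreground pixels to a spectrum set
#'
#' @param cube A [hypercube()].
#' @param mask Logical matrix selecting pixels; defaults to the cube's own
#'   mask, or all pixels if it has none.
#' @param label Sample label for the extracted spectra.
#' @return A [spectrum_set()]; rows are in column-major pixel order.
#' @export
cube_to_spectra <- function(cube, mask = cube$mask, label = "s1") {
  if (is.null(mask)) mask <- matrix(TRUE, cube$height, cube$width)
  flat <- matrix(cube$data, cube$height * cube$width, length(cube$axis))
  spectrum_set(cube$axis, flat[as.vector(mask), , drop = FALSE], label)
}
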