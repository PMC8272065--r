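#' Acquisition metadata for a single-voxel MRS experiment
#'
#' Bundles the scalar parameters that fix the geometry and the spectral axis
#' of a multichannel, repeatedly sampled acquisition: the number of receive
#' coils `C`, repeated samplings (averages) `A`, complex time-domain points
#' `N`, the spectral bandwidth, the transmitter frequency, and the chemical
#' shift assigned to the spectral center (the water reference).
#'
#' @param spectral_bandwidth Spectral bandwidth in Hz (sampling rate of the
#'   FID). Typical short-TE PRESS protocols at 3 T use 2000 Hz.
#' @param n_points Number of complex points per FID.
#' @param n_coils Number of receive coils in the phased array.
#' @param n_averages Number of repeated samplings of the voxel.
#' @param transmitter_frequency Transmitter (Larmor) frequency in MHz;
#'   about 128 MHz for protons at 3 T. Converts Hz offsets to ppm.
#' @param reference_ppm Chemical shift (ppm) of the spectral center;
#'   defaults to the in vivo water resonance at 4.7 ppm.
#'
#' @return An object of class `mrs_meta`.
#' @export
#' @examples
#' meta <- mrs_meta(n_coils = 8, n_averages = 16, n_points = 512)
#' range(ppm_axis(meta))
mrs_meta <- function(spectral_bandwidth = 2000,
                     n_points = 2048,
                     n_coils = 32,
                     n_averages = 128,
                     transmitter_frequency = 128,
                     reference_ppm = 4.7) {
  for (nm in c("n_points", "n_coils", "n_averages")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1 ||
        v != round(v)) {
      stop("invalid metadata: `", nm, "` must be a single integer >= 1",
           call. = FALSE)
    }
  }
  if (!is.numeric(spectral_bandwidth) || length(spectral_bandwidth) != 1L ||
      !is.finite(spectral_bandwidth) || spectral_bandwidth <= 0) {
    stop("invalid metadata: `spectral_bandwidth` must be > 0", call. = FALSE)
  }
  if (!is.numeric(transmitter_frequency) || length(transmitter_frequency) != 1L ||
      !is.finite(transmitter_frequency) || transmitter_frequency <= 0) {
    stop("invalid metadata: `transmitter_frequency` must be > 0", call. = FALSE)
  }
  if (!is.numeric(reference_ppm) || length(reference_ppm) != 1L ||
      !is.finite(reference_ppm)) {
    stop("invalid metadata: `reference_ppm` must be a finite number",
         call. = FALSE)
  }
  structure(
    list(spectral_bandwidth = as.numeric(spectral_bandwidth),
         n_points = as.integer(n_points),
         n_coils = as.integer(n_coils),
         n_averages = as.integer(n_averages),
         transmitter_frequency = as.numeric(transmitter_frequency),
         reference_ppm = as.numeric(reference_ppm)),
    class = "mrs_meta")
}

#' @export
print.mrs_meta <- function(x, ...) {
  cat(sprintf(
    "<mrs_meta> C=%d coils, A=%d averages, N=%d points, bw=%g Hz, f0=%g MHz, ref=%g ppm\n",
    x$n_coils, x$n_averages, x$n_points, x$spectral_bandwidth,
    x$transmitter_frequency, x$reference_ppm))
  invisible(x)
}

#' Raw multichannel, multi-average acquisition
#'
#' The central container: a complex array indexed `[coil, average, point]`
#' holding the time-domain FID of every coil and repeated sampling, plus its
#' [mrs_meta()] metadata. Every combination method consumes this object (or
#' the across-average mean produced by [average_block()]).
#'
#' @param data Complex array of dimension `C x A x N` (time domain).
#' @param meta An [mrs_meta()] object whose counts match `dim(data)`.
#' @return An object of class `mrs_block`.
#' @export
mrs_block <- function(data, meta) {
  stopifnot(inherits(meta, "mrs_meta"))
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-d array [coil, average, point]", call. = FALSE)
  }
  d <- dim(data)
  if (!identical(as.integer(d),
                 c(meta$n_coils, meta$n_averages, meta$n_points))) {
    stop(sprintf(
      "shape mismatch: data is %d x %d x %d but metadata says %d x %d x %d",
      d[1], d[2], d[3], meta$n_coils, meta$n_averages, meta$n_points),
      call. = FALSE)
  }
  if (!is.complex(data)) storage.mode(data) <- "complex"
  if (any(!is.finite(data))) {
    stop("acquisition data must be finite", call. = FALSE)
  }
  structure(list(data = data, meta = meta), class = "mrs_block")
}

#' @export
print.mrs_block <- function(x, ...) {
  cat("<mrs_block>\n")
  print(x$meta)
  invisible(x)
}

#' Single-average coil-by-points matrix
#'
#' A `C x N` complex matrix holding one average (or the across-average mean)
#' of the acquisition, tagged with the domain its columns live in. The
#' baseline combiners (Brown, GLS, WSVD) operate on this object.
#'
#' @param data Complex `C x N` matrix.
#' @param meta The acquisition's [mrs_meta()].
#' @param domain Either `"time"` (FID rows) or `"frequency"`.
#' @return An object of class `coil_matrix`.
#' @export
coil_matrix <- function(data, meta, domain = c("time", "frequency")) {
  domain <- match.arg(domain)
  stopifnot(inherits(meta, "mrs_meta"))
  if (!is.matrix(data)) data <- matrix(data, nrow = meta$n_coils)
  if (nrow(data) != meta$n_coils || ncol(data) != meta$n_points) {
    stop(sprintf("coil matrix must be %d x %d", meta$n_coils, meta$n_points),
         call. = FALSE)
  }
  if (!is.complex(data)) storage.mode(data) <- "complex"
  structure(list(data = data, meta = meta, domain = domain),
            class = "coil_matrix")
}

#' Combined single-voxel spectrum
#'
#' The length-`N` complex time-domain result of any coil-combination method,
#' carrying the method label and the parameters used so that every output is
#' traceable to its configuration.
#'
#' @param fid Complex length-`N` time-domain signal.
#' @param meta The source acquisition's [mrs_meta()].
#' @param method One of `"brown"`, `"gls"`, `"svd"`, `"wsvd"`, `"assvd"`.
#' @param params Named list of method parameters (e.g. `kernel_size`).
#' @return An object of class `combined_spectrum`.
#' @export
combined_spectrum <- function(fid, meta, method, params = list()) {
  stopifnot(inherits(meta, "mrs_meta"))
  if (length(fid) != meta$n_points) {
    stop("combined spectrum length must equal n_points", call. = FALSE)
  }
  method <- match.arg(method, c("brown", "gls", "svd", "wsvd", "assvd"))
  structure(list(fid = as.complex(fid), meta = meta, method = method,
                 params = params),
            class = "combined_spectrum")
}

#' @export
print.combined_spectrum <- function(x, ...) {
  p <- if (length(x$params)) {
    paste0(" (", paste(names(x$params),
                       vapply(x$params, function(v) paste(format(v), collapse = ","), ""),
                       sep = "=", collapse = ", "), ")")
  } else ""
  cat(sprintf("<combined_spectrum> method=%s%s, N=%d\n",
              x$method, p, x$meta$n_points))
  invisible(x)
}

#' Chemical-shift axis of an acquisition
#'
#' Returns the length-`N` ppm value of every frequency-domain bin, ordered to
#' match [to_frequency()]: strictly decreasing ppm with increasing index, the
#' conventional MRS display direction (downfield / high ppm on the left).
#' The axis spans `reference_ppm +/- bandwidth / (2 * transmitter_frequency)`
#' and is the single source of truth for every ppm-region selection in the
#' package.
#'
#' @param meta An [mrs_meta()] object.
#' @return Numeric vector of length `n_points`, strictly decreasing.
#' @export
#' @examples
#' ax <- ppm_axis(mrs_meta())
#' ax[1]; ax[length(ax)]   # ~12.5 down to ~-3.1 ppm at 3 T
ppm_axis <- function(meta) {
  stopifnot(inherits(meta, "mrs_meta"))
  n <- meta$n_points
  k <- n %/% 2L
  f_asc <- (seq_len(n) - 1L - k) * meta$spectral_bandwidth / n
  meta$reference_ppm + rev(f_asc) / meta$transmitter_frequency
}

#' Bin indices of a ppm interval
#'
#' Selects the frequency-domain bins whose center falls in the half-open
#' interval `[ppm_lo, ppm_hi)` of the axis returned by [ppm_axis()].
#'
#' @param meta An [mrs_meta()] object.
#' @param ppm_lo,ppm_hi Interval bounds in ppm, `ppm_lo < ppm_hi`.
#' @return Integer vector of bin indices (ascending index order, i.e.
#'   descending ppm).
#' @export
ppm_indices <- function(meta, ppm_lo, ppm_hi) {
  if (!is.finite(ppm_lo) || !is.finite(ppm_hi) || ppm_lo >= ppm_hi) {
    stop("need finite ppm bounds with ppm_lo < ppm_hi", call. = FALSE)
  }
  ax <- ppm_axis(meta)
  idx <- which(ax >= ppm_lo & ax < ppm_hi)
  if (length(idx) == 0L) {
    stop(sprintf("ppm region [%g, %g) lies outside the axis [%g, %g]",
                 ppm_lo, ppm_hi, min(ax), max(ax)), call. = FALSE)
  }
  idx
}

# index permutation from raw DFT bin order to ascending-frequency order
.fftshift_perm <- function(n) {
  k <- n %/% 2L
  ((seq_len(n) - 1L - k) %% n) + 1L
}

#' Time-to-frequency transform with the package's axis convention
#'
#' Discrete Fourier transform of an FID, reordered so that element `i` of the
#' output corresponds to element `i` of [ppm_axis()] (highest ppm first).
#' `from_frequency()` is its exact inverse; a round trip reproduces the input
#' to machine precision.
#'
#' @param fid Complex time-domain vector.
#' @return Complex frequency-domain vector of the same length.
#' @export
to_frequency <- function(fid) {
  if (any(!is.finite(fid))) stop("non-finite FID", call. = FALSE)
  n <- length(fid)
  rev(stats::fft(fid)[.fftshift_perm(n)])
}

#' @rdname to_frequency
#' @param spec Complex frequency-domain vector ordered like [ppm_axis()].
#' @export
from_frequency <- function(spec) {
  n <- length(spec)
  raw <- complex(length.out = n)
  raw[.fftshift_perm(n)] <- rev(spec)
  stats::fft(raw, inverse = TRUE) / n
}

# coil_matrix in the requested domain (per-row transform)
.coil_matrix_in_domain <- function(X, domain) {
  stopifnot(inherits(X, "coil_matrix"))
  if (X$domain == domain) return(X)
  f <- if (domain == "frequency") to_frequency else from_frequency
  coil_matrix(t(apply(X$data, 1L, f)), X$meta, domain)
}

#' Extract one average of a block as a coil matrix
#'
#' @param block An [mrs_block()].
#' @param a Average index, `1 <= a <= n_averages`.
#' @return A time-domain [coil_matrix()].
#' @export
block_average <- function(block, a) {
  stopifnot(inherits(block, "mrs_block"))
  a <- as.integer(a)
  if (a < 1L || a > block$meta$n_averages) stop("average index out of range")
  coil_matrix(block$data[, a, , drop = TRUE], block$meta, "time")
}

#' Read and write acquisition blocks
#'
#' Serializes an [mrs_block()] to a single self-contained file (RDS payload:
#' the complex `C x A x N` array plus every metadata field) and reads it back.
#' A write-then-read round trip is bit-identical for data and metadata. The
#' reader validates the container: a missing field raises a format error
#' naming the field, and a shape/metadata disagreement raises a consistency
#' error.
#'
#' @param block An [mrs_block()].
#' @param path File path.
#' @return `read_block()` returns an [mrs_block()]; `write_block()` returns
#'   `path` invisibly.
#' @export
write_block <- function(block, path) {
  stopifnot(inherits(block, "mrs_block"))
  payload <- list(
    container = "mrscombine_block", version = 1L,
    fid = block$data,
    spectral_bandwidth_hz = block$meta$spectral_bandwidth,
    transmitter_frequency_mhz = block$meta$transmitter_frequency,
    reference_ppm = block$meta$reference_ppm,
    n_coils = block$meta$n_coils,
    n_averages = block$meta$n_averages,
    n_points = block$meta$n_points)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_block
#' @export
read_block <- function(path) {
  payload <- readRDS(path)
  required <- c("fid", "spectral_bandwidth_hz", "transmitter_frequency_mhz",
                "reference_ppm", "n_coils", "n_averages", "n_points")
  missing <- setdiff(required, names(payload))
  if (length(missing)) {
    stop("block container is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  meta <- mrs_meta(
    spectral_bandwidth = payload$spectral_bandwidth_hz,
    n_points = payload$n_points,
    n_coils = payload$n_coils,
    n_averages = payload$n_averages,
    transmitter_frequency = payload$transmitter_frequency_mhz,
    reference_ppm = payload$reference_ppm)
  d <- dim(payload$fid)
  if (is.null(d) || length(d) != 3L ||
      !identical(as.integer(d),
                 c(meta$n_coils, meta$n_averages, meta$n_points))) {
    stop("block container is inconsistent: dataset shape does not match ",
         "n_coils/n_averages/n_points metadata", call. = FALSE)
  }
  mrs_block(payload$fid, meta)
}

#' Export a combined spectrum as CSV
#'
#' Writes the frequency-domain spectrum as a plain-text table with columns
#' `ppm`, `real`, `imag`, `magnitude` (one row per bin, downfield first).
#'
#' @param combined A [combined_spectrum()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(combined, path) {
  stopifnot(inherits(combined, "combined_spectrum"))
  spec <- to_frequency(combined$fid)
  df <- data.frame(ppm = ppm_axis(combined$meta),
                   real = Re(spec), imag = Im(spec),
                   magnitude = Mod(spec))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
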