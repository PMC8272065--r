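#' Across-average mean of an acquisition block
#'
#' The conventional pre-processing for the single-matrix combiners (Brown,
#' GLS, WSVD): the arithmetic mean over the averages dimension, which reduces
#' white noise standard deviation by `1/sqrt(A)`.
#'
#' @param block An [mrs_block()].
#' @return A time-domain [coil_matrix()].
#' @export
average_block <- function(block) {
  stopifnot(inherits(block, "mrs_block"))
  m <- apply(block$data, c(1L, 3L), mean)
  coil_matrix(m, block$meta, "time")
}

#' Brown first-point coil combination
#'
#' Weights each coil's FID by that coil's first time-domain point and sums:
#' `m_hat = sum_c X_c(1) * x_c`. This is the literal first-point weighting;
#' with `conjugate_weights = TRUE` the conjugate `conj(X_c(1))` is used
#' instead, which cancels per-coil phase so coils add constructively.
#'
#' @param X A time-domain [coil_matrix()].
#' @param conjugate_weights Use conjugated first-point weights.
#' @return A [combined_spectrum()] with method `"brown"`.
#' @export
combine_brown <- function(X, conjugate_weights = FALSE) {
  stopifnot(inherits(X, "coil_matrix"))
  if (X$domain != "time") stop("Brown combination needs time-domain input",
                               call. = FALSE)
  w <- X$data[, 1L]
  if (all(Mod(w) == 0)) {
    stop("degenerate weights: every coil's first time-domain point is zero",
         call. = FALSE)
  }
  if (conjugate_weights) w <- Conj(w)
  fid <- as.vector(crossprod(X$data, w))  # sum_c w_c * X[c, ]
  combined_spectrum(fid, X$meta, "brown",
                    params = list(conjugate_weights = conjugate_weights))
}

#' Generalized least squares coil combination
#'
#' Best linear unbiased estimate of the combined spectrum under the rank-1
#' acquisition model with known sensitivities and noise covariance:
#' `m_hat = (s^H Psi^{-1} X) / (s^H Psi^{-1} s)`. On exactly rank-1 input
#' `X = s m^T` it returns `m` exactly, for any valid covariance.
#'
#' @param X A [coil_matrix()] (any domain; the output is reported in the
#'   same domain as a time-domain FID when `X` is time-domain).
#' @param model A [noise_model()]; a rank-deficient covariance is inverted
#'   with its eigenvalue floor.
#' @param s Complex length-`C` sensitivity vector, e.g. from
#'   [pick_naa_sensitivity()].
#' @return A [combined_spectrum()] with method `"gls"`.
#' @export
combine_gls <- function(X, model, s) {
  stopifnot(inherits(X, "coil_matrix"), inherits(model, "noise_model"))
  s <- as.complex(s)
  if (length(s) != nrow(X$data)) {
    stop("sensitivity vector length must equal the coil count", call. = FALSE)
  }
  if (all(Mod(s) == 0)) stop("zero sensitivity vector", call. = FALSE)
  Pinv <- .psi_inverse(model)
  w <- Pinv %*% s                              # Psi^{-1} s
  denom <- as.complex(Conj(t(s)) %*% w)        # s^H Psi^{-1} s (real > 0)
  num <- Conj(t(w)) %*% X$data                 # s^H Psi^{-1} X (1 x N)
  fid <- as.vector(num) / denom
  if (X$domain == "frequency") fid <- from_frequency(fid)
  combined_spectrum(fid, X$meta, "gls", params = list())
}

#' Per-coil NAA peak sensitivity
#'
#' Reads each coil's complex spectrum value at its strongest bin inside a
#' window around the N-acetylaspartate resonance (2.0 ppm), the conventional
#' signal-derived sensitivity estimate used by the GLS combiner.
#'
#' @param X A [coil_matrix()] (time or frequency domain).
#' @param ppm_center Window center in ppm (default 2.0, the NAA CH3 singlet).
#' @param ppm_halfwidth Half-width of the search window in ppm.
#' @return Complex vector of length `C`.
#' @export
pick_naa_sensitivity <- function(X, ppm_center = 2.0, ppm_halfwidth = 0.15) {
  stopifnot(inherits(X, "coil_matrix"))
  Xf <- .coil_matrix_in_domain(X, "frequency")
  idx <- ppm_indices(X$meta, ppm_center - ppm_halfwidth,
                     ppm_center + ppm_halfwidth)
  vapply(seq_len(nrow(Xf$data)), function(cc) {
    row <- Xf$data[cc, idx]
    row[which.max(Mod(row))]
  }, complex(1))
}

#' Rank-1 SVD factorization of a coil matrix
#'
#' Decomposes `X = U S V^H` and returns the principal component: the
#' combined signal `sigma_1 * conj(v_1) * xi` and the coil sensitivity
#' `u_1 * conj(xi)`, so that `sensitivity %*% t(combined)` is exactly the
#' best rank-1 Frobenius approximation of `X`. The free gauge phase `xi`
#' (unit modulus) is fixed so the combined vector's first element (falling
#' back to its largest-magnitude element if the first is zero) is real and
#' non-negative, making the output deterministic.
#'
#' @param X A [coil_matrix()].
#' @return An object of class `svd_solution` with elements `combined`
#'   (length `N`), `sensitivity` (length `C`), `sigma1`, `xi`, and
#'   `tie_flag` (`TRUE` when the top two singular values coincide to within
#'   `1e-12` relative, in which case the factor returned is the
#'   deterministic LAPACK ordering's first component).
#' @export
combine_svd <- function(X) {
  stopifnot(inherits(X, "coil_matrix"))
  sv <- svd(X$data)
  u1 <- sv$u[, 1L]
  v1 <- sv$v[, 1L]
  sigma1 <- sv$d[1L]
  tie_flag <- length(sv$d) > 1L &&
    (sv$d[1L] - sv$d[2L]) <= 1e-12 * max(sv$d[1L], .Machine$double.xmin)
  combined <- sigma1 * Conj(v1)
  ref <- if (Mod(combined[1L]) > 0) combined[1L] else {
    j <- which.max(Mod(combined))
    if (Mod(combined[j]) > 0) combined[j] else 1 + 0i
  }
  xi <- Conj(ref) / Mod(ref)
  structure(
    list(combined = combined * xi,
         sensitivity = u1 * Conj(xi),
         sigma1 = sigma1,
         xi = xi,
         tie_flag = tie_flag,
         meta = X$meta,
         domain = X$domain),
    class = "svd_solution")
}

#' Whitened SVD coil combination
#'
#' Whitens the coil dimension with the noise model (`X_w = W X`), takes the
#' principal SVD component of the whitened matrix, and reports the combined
#' signal `sigma_1 v_1^H xi`. Un-whitening applies to the coil-space factor:
#' the estimated sensitivity is returned as `W^{-1} u_1 conj(xi)` (the
#' length-`N` combined signal lives in signal space, not coil space, so `W`
#' does not act on it). When the noise covariance is proportional to the
#' identity the result coincides with plain SVD combination up to gauge.
#'
#' @param X A time-domain [coil_matrix()] (one average or the
#'   across-average mean).
#' @param model A [noise_model()].
#' @return A [combined_spectrum()] with method `"wsvd"`; the unwhitened
#'   sensitivity estimate and the whitened-domain solution are attached in
#'   `params`.
#' @export
combine_wsvd <- function(X, model) {
  stopifnot(inherits(X, "coil_matrix"), inherits(model, "noise_model"))
  Xw <- whiten(X, model)
  sol <- combine_svd(Xw)
  Winv <- model$eigenvectors %*% diag(sqrt(model$eigenvalues),
                                      nrow(model$psi))
  sens <- as.vector(Winv %*% sol$sensitivity)
  fid <- sol$combined
  if (X$domain == "frequency") fid <- from_frequency(fid)
  combined_spectrum(fid, X$meta, "wsvd",
                    params = list(sensitivity = sens,
                                  sigma1 = sol$sigma1,
                                  tie_flag = sol$tie_flag))
}

#' Pointwise coil sensitivity field over the averages-by-points plane
#'
#' For every repeated sampling `a`, pre-combines the coil matrix by WSVD to
#' get `m_hat_a`, aligns its free gauge to the first average's solution (the
#' complex scalar minimizing `||m_hat_a * z - m_hat_1||`), and then divides
#' pointwise: `s[c, a, n] = x[c, a, n] * conj(m_hat_a(n)) /
#' (|m_hat_a(n)|^2 + eps)` with `eps = eps_rel * max |m_hat_a|^2`. The
#' regularization keeps the division finite where the pre-combined signal
#' crosses zero; because the downstream per-point least squares is invariant
#' to real scalar shrinkage of the sensitivity vector, `eps` only needs to
#' guard against exact zeros, and the default is correspondingly tiny so
#' that noiseless rank-1 data is recovered to machine-level accuracy.
#'
#' @param block An [mrs_block()] (time domain).
#' @param model A [noise_model()].
#' @param domain Plane on which sensitivities are estimated: `"time"`
#'   (default, the domain of the acquisition model) or `"frequency"`.
#' @param eps_rel Relative regularization of the pointwise division.
#' @return An object of class `sensitivity_field`: complex `C x A x N`
#'   arrays `raw` and `smoothed` (initially identical, `kernel_size = 1`),
#'   plus the aligned per-average pre-combined signals `precombined`
#'   (`A x N`) and the `domain` tag.
#' @export
estimate_sensitivity_field <- function(block, model, domain = c("time", "frequency"),
                                       eps_rel = 1e-12) {
  stopifnot(inherits(block, "mrs_block"), inherits(model, "noise_model"))
  domain <- match.arg(domain)
  C <- block$meta$n_coils; A <- block$meta$n_averages; N <- block$meta$n_points
  raw <- array(0 + 0i, c(C, A, N))
  pre <- matrix(0 + 0i, A, N)
  m_ref <- NULL
  for (a in seq_len(A)) {
    Xa <- block_average(block, a)
    if (all(Mod(Xa$data) == 0)) {
      stop("average ", a, " is identically zero; cannot estimate sensitivity",
           call. = FALSE)
    }
    Xa <- .coil_matrix_in_domain(Xa, domain)
    m_a <- combine_wsvd(Xa, model)$fid
    if (domain == "frequency") m_a <- to_frequency(m_a)
    if (is.null(m_ref)) {
      m_ref <- m_a
    } else {
      z <- sum(Conj(m_a) * m_ref) / sum(Mod(m_a)^2)
      m_a <- m_a * z
    }
    pre[a, ] <- m_a
    eps <- eps_rel * max(Mod(m_a)^2)
    denom <- Mod(m_a)^2 + eps
    raw[, a, ] <- Xa$data * matrix(Conj(m_a) / denom, C, N, byrow = TRUE)
  }
  structure(list(raw = raw, smoothed = raw, kernel_size = 1L,
                 precombined = pre, domain = domain, meta = block$meta),
            class = "sensitivity_field")
}

#' Construct a sensitivity field from a raw array
#'
#' Low-level constructor for a `sensitivity_field` around an existing
#' `C x A x N` complex array of pointwise sensitivities (most users get one
#' from [estimate_sensitivity_field()]; this entry point supports smoothing
#' studies on synthetic fields).
#'
#' @param raw Complex `C x A x N` array.
#' @param meta An [mrs_meta()] consistent with `dim(raw)`.
#' @param domain `"time"` or `"frequency"`.
#' @return A `sensitivity_field` with `smoothed = raw` and `kernel_size = 1`.
#' @export
sensitivity_field <- function(raw, meta, domain = c("time", "frequency")) {
  domain <- match.arg(domain)
  stopifnot(inherits(meta, "mrs_meta"))
  if (!is.array(raw) || length(dim(raw)) != 3L ||
      !identical(as.integer(dim(raw)),
                 c(meta$n_coils, meta$n_averages, meta$n_points))) {
    stop("`raw` must be a C x A x N array matching the metadata", call. = FALSE)
  }
  if (!is.complex(raw)) storage.mode(raw) <- "complex"
  structure(list(raw = raw, smoothed = raw, kernel_size = 1L,
                 precombined = NULL, domain = domain, meta = meta),
            class = "sensitivity_field")
}

# running mean of length-k window with replicate padding (complex-safe)
.runmean_replicate <- function(x, k) {
  if (k == 1L) return(x)
  n <- length(x)
  h <- (k - 1L) %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[n], h))
  cs <- cumsum(xp)
  (cs[k:(n + k - 1L)] - c(0, cs[seq_len(n - 1L)])) / k
}

# k x k uniform-kernel smoothing of one A x N plane, replicate padding;
# separable: row running mean then column running mean
.smooth_plane <- function(P, k) {
  if (k == 1L) return(P)
  P1 <- t(apply(P, 1L, .runmean_replicate, k = k))
  apply(P1, 2L, .runmean_replicate, k = k)
}

#' Smooth a sensitivity field with a uniform k-by-k kernel
#'
#' Convolves each coil's `A x N` sensitivity plane with the `k x k` average
#' filtering kernel (all entries `1/k^2`), using replicate padding at the
#' borders so constant fields pass through unchanged. `k = 1` is the
#' identity. This is the smoothing step that exploits the stability of coil
#' sensitivities across repeated samplings.
#'
#' @param field A `sensitivity_field` from [estimate_sensitivity_field()].
#' @param k Odd kernel size, `1 <= k <= min(A, N)`.
#' @return The field with `smoothed` replaced and `kernel_size = k`.
#' @export
smooth_sensitivity <- function(field, k) {
  stopifnot(inherits(field, "sensitivity_field"))
  k <- as.integer(k)
  A <- dim(field$raw)[2L]; N <- dim(field$raw)[3L]
  if (k %% 2L == 0L || k < 1L || k > min(A, N)) {
    stop(sprintf("kernel size must be odd and in [1, %d]", min(A, N)),
         call. = FALSE)
  }
  C <- dim(field$raw)[1L]
  sm <- field$raw
  for (cc in seq_len(C)) {
    plane <- matrix(field$raw[cc, , ], A, N)
    sm[cc, , ] <- .smooth_plane(plane, k)
  }
  field$smoothed <- sm
  field$kernel_size <- k
  field
}

#' Average smoothing SVD (ASSVD) coil combination
#'
#' The repeated-sampling-aware combiner. Pipeline: (1) estimate the
#' pointwise sensitivity field from per-average WSVD pre-combinations
#' ([estimate_sensitivity_field()]); (2) smooth it over the
#' averages-by-points plane with the uniform `k x k` kernel
#' ([smooth_sensitivity()]); (3) for every average and point solve the
#' one-unknown whitened least-squares problem
#' `m(a, n) = sum_c conj(s'_san) x'_san / sum_c |s'_san|^2`, where primes
#' denote whitened coil vectors — the decorrelation advantage of WSVD is
#' carried into the recombination; (4) reduce to one spectrum by the
#' arithmetic mean over averages (the per-average solutions share one gauge
#' because the sensitivity field was gauge-aligned).
#'
#' @param block An [mrs_block()].
#' @param model A [noise_model()].
#' @param k Odd smoothing kernel size; the default 7 is the size at which
#'   the in vivo SNR of this method peaks.
#' @param domain Passed to [estimate_sensitivity_field()].
#' @param field Optionally, a precomputed `sensitivity_field` for `block`
#'   (lets benchmark sweeps reuse one field across kernel sizes).
#' @return A [combined_spectrum()] with method `"assvd"`; `params` records
#'   `kernel_size` and a `uniform_weight_points` count of any points whose
#'   smoothed sensitivity vanished (combined there with equal unit weights).
#' @export
combine_assvd <- function(block, model, k = 7L,
                          domain = c("time", "frequency"), field = NULL) {
  stopifnot(inherits(block, "mrs_block"), inherits(model, "noise_model"))
  domain <- match.arg(domain)
  if (is.null(field)) {
    field <- estimate_sensitivity_field(block, model, domain = domain)
  } else {
    stopifnot(inherits(field, "sensitivity_field"))
    domain <- field$domain
  }
  field <- smooth_sensitivity(field, k)
  C <- block$meta$n_coils; A <- block$meta$n_averages; N <- block$meta$n_points
  W <- model$whitener
  msum <- complex(length.out = N)
  n_uniform <- 0L
  for (a in seq_len(A)) {
    Xa <- .coil_matrix_in_domain(block_average(block, a), domain)
    Xw <- W %*% Xa$data
    Sw <- W %*% matrix(field$smoothed[, a, ], C, N)
    num <- colSums(Conj(Sw) * Xw)
    den <- colSums(Mod(Sw)^2)
    m_a <- num / den
    bad <- !is.finite(m_a) | den <= .Machine$double.xmin
    if (any(bad)) {
      n_uniform <- n_uniform + sum(bad)
      m_a[bad] <- colMeans(Xw[, bad, drop = FALSE])
    }
    msum <- msum + m_a
  }
  fid <- msum / A
  if (domain == "frequency") fid <- from_frequency(fid)
  combined_spectrum(fid, block$meta, "assvd",
                    params = list(kernel_size = k,
                                  domain = domain,
                                  uniform_weight_points = n_uniform))
}
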