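#' Inter-coil noise model
#'
#' Holds the Hermitian `C x C` inter-coil noise covariance `Psi` together
#' with the two factorizations the combiners need: a lower-triangular
#' Cholesky factor `L` with `Psi = L L^H` (used to generate correlated
#' noise) and the whitening matrix `W = D^{-1/2} G^H` from the
#' eigendecomposition `Psi = G D G^H` (used by WSVD/GLS/ASSVD). Eigenvalues
#' below `1e-10 * lambda_max` are clamped to that floor before inversion or
#' factorization; when this happens the model is flagged `rank_deficient`.
#'
#' @param psi Complex (or real) `C x C` covariance matrix; Hermitian up to
#'   round-off (it is symmetrized internally).
#' @param n_samples Number of noise samples per coil the estimate used
#'   (`NA` for a specified rather than estimated covariance).
#' @return An object of class `noise_model` with elements `psi`, `cholesky`,
#'   `whitener`, `n_samples_used`, `rank_deficient`.
#' @export
noise_model <- function(psi, n_samples = NA_integer_) {
  if (!is.matrix(psi) || nrow(psi) != ncol(psi)) {
    stop("`psi` must be a square matrix", call. = FALSE)
  }
  if (!is.complex(psi)) storage.mode(psi) <- "complex"
  herm_err <- max(abs(psi - Conj(t(psi))))
  scale <- max(abs(psi), 1e-300)
  if (herm_err > 1e-6 * scale) {
    stop("`psi` is not Hermitian (relative asymmetry ",
         format(herm_err / scale), ")", call. = FALSE)
  }
  psi <- (psi + Conj(t(psi))) / 2
  C <- nrow(psi)
  ed <- eigen(psi, symmetric = TRUE)
  lam <- ed$values
  lam_max <- max(lam, 0)
  if (lam_max <= 0) stop("`psi` has no positive eigenvalue", call. = FALSE)
  if (min(lam) < -1e-10 * lam_max) {
    stop("`psi` is not positive semidefinite", call. = FALSE)
  }
  floor_val <- 1e-10 * lam_max
  rank_deficient <- any(lam < floor_val)
  lam_cl <- pmax(lam, floor_val)
  G <- ed$vectors
  whitener <- diag(1 / sqrt(lam_cl), C) %*% Conj(t(G))
  psi_floored <- G %*% (lam_cl * Conj(t(G)))  # G diag(lam) G^H
  structure(
    list(psi = psi,
         cholesky = .chol_complex(psi_floored),
         whitener = whitener,
         eigenvectors = G,
         eigenvalues = lam_cl,
         n_samples_used = n_samples,
         rank_deficient = rank_deficient),
    class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> C=%d, n_samples_used=%s%s\n",
              nrow(x$psi), format(x$n_samples_used),
              if (x$rank_deficient) ", rank-deficient (eigenvalue floor applied)" else ""))
  invisible(x)
}

# lower-triangular complex Cholesky, psi = L L^H; base::chol() is real-only
.chol_complex <- function(psi) {
  C <- nrow(psi)
  L <- matrix(0 + 0i, C, C)
  for (j in seq_len(C)) {
    djj <- Re(psi[j, j]) - sum(Mod(L[j, seq_len(j - 1L)])^2)
    if (djj <= 0) {
      stop("matrix not positive definite at pivot ", j, call. = FALSE)
    }
    L[j, j] <- sqrt(djj)
    if (j < C) {
      i <- (j + 1L):C
      acc <- if (j > 1L) {
        L[i, seq_len(j - 1L), drop = FALSE] %*% Conj(L[j, seq_len(j - 1L)])
      } else 0
      L[i, j] <- (psi[i, j] - acc) / L[j, j]
    }
  }
  L
}

# floored inverse of psi from the stored eigendecomposition
.psi_inverse <- function(model) {
  G <- model$eigenvectors
  G %*% ((1 / model$eigenvalues) * Conj(t(G)))
}

#' Extract the noise-only spectral region
#'
#' Restricts each coil's frequency-domain spectrum to a chemical-shift window
#' assumed to contain no metabolite resonances (by convention 0.4-1.0 ppm in
#' brain 1H-MRS), yielding the noise estimate matrix `E_hat` from which the
#' inter-coil covariance is computed.
#'
#' @param x A [coil_matrix()] (any domain; transformed as needed) or an
#'   [mrs_block()], in which case the region is extracted per average.
#' @param ppm_lo,ppm_hi Region bounds in ppm, half-open `[ppm_lo, ppm_hi)`.
#' @return For a coil matrix, a complex `C x M` matrix; for a block, a
#'   complex `C x M x A` array.
#' @export
extract_noise_region <- function(x, ppm_lo = 0.4, ppm_hi = 1.0) {
  if (inherits(x, "mrs_block")) {
    idx <- ppm_indices(x$meta, ppm_lo, ppm_hi)
    out <- array(0 + 0i, c(x$meta$n_coils, length(idx), x$meta$n_averages))
    for (a in seq_len(x$meta$n_averages)) {
      Xf <- .coil_matrix_in_domain(block_average(x, a), "frequency")
      out[, , a] <- Xf$data[, idx, drop = FALSE]
    }
    return(out)
  }
  stopifnot(inherits(x, "coil_matrix"))
  idx <- ppm_indices(x$meta, ppm_lo, ppm_hi)
  if (length(idx) < x$meta$n_coils) {
    warning(sprintf(
      "noise region has %d samples for %d coils; covariance will be rank-deficient",
      length(idx), x$meta$n_coils), call. = FALSE)
  }
  Xf <- .coil_matrix_in_domain(x, "frequency")
  Xf$data[, idx, drop = FALSE]
}

#' Estimate the inter-coil noise covariance
#'
#' Forms `Psi_hat = E_hat E_hat^H / M` from `M` noise-only samples per coil.
#' The `1/M` normalization puts the estimate on a per-sample covariance scale
#' independent of the region width; whitening and Cholesky factors are
#' scale-covariant, so downstream results are unaffected by this convention.
#'
#' @param E_hat Complex `C x M` noise matrix (e.g. from
#'   [extract_noise_region()]).
#' @return A [noise_model()] with `n_samples_used = M`.
#' @export
estimate_covariance <- function(E_hat) {
  if (!is.matrix(E_hat)) E_hat <- matrix(E_hat, nrow = 1L)
  M <- ncol(E_hat)
  if (M < 1L) stop("need at least one noise sample", call. = FALSE)
  psi <- (E_hat %*% Conj(t(E_hat))) / M
  noise_model(psi, n_samples = M)
}

#' Estimate a noise model from an acquisition block
#'
#' Extracts the noise-only region of every repeated sampling and either
#' estimates a covariance per average and averages the estimates (default;
#' each repeated sampling's noise is measured independently) or pools all
#' averages' samples into one estimate.
#'
#' @param block An [mrs_block()].
#' @param ppm_lo,ppm_hi Noise region bounds in ppm.
#' @param pooled If `TRUE`, concatenate the averages' noise samples and
#'   estimate once; if `FALSE` (default) average the per-average estimates.
#' @return A [noise_model()].
#' @export
estimate_noise_model <- function(block, ppm_lo = 0.4, ppm_hi = 1.0,
                                 pooled = FALSE) {
  stopifnot(inherits(block, "mrs_block"))
  E <- extract_noise_region(block, ppm_lo, ppm_hi)
  C <- dim(E)[1]; M <- dim(E)[2]; A <- dim(E)[3]
  if (M < C) {
    warning(sprintf(
      "noise region has %d samples for %d coils; covariance will be rank-deficient",
      M, C), call. = FALSE)
  }
  if (pooled) {
    return(estimate_covariance(matrix(E, nrow = C)))
  }
  psi <- matrix(0 + 0i, C, C)
  for (a in seq_len(A)) {
    Ea <- E[, , a, drop = TRUE]
    psi <- psi + (Ea %*% Conj(t(Ea))) / M
  }
  noise_model(psi / A, n_samples = M)
}

#' Generate correlated complex Gaussian noise
#'
#' Draws a `C x n_points` white complex Gaussian matrix `E_Gaussian` (real
#' and imaginary entries each standard normal, so each complex sample has
#' total variance 2) and colors it as `E_corr = L^H E_Gaussian`, where `L` is
#' the lower Cholesky factor of the model covariance. This literal `L^H`
#' coloring has covariance proportional to `L^H L`; set `exact_cov = TRUE` to
#' color with `L` instead, which reproduces `Psi` itself. For a diagonal
#' `Psi` the two coincide.
#'
#' @param model A [noise_model()].
#' @param n_points Number of complex samples per coil.
#' @param seed Optional integer seed; a fixed seed makes the draw
#'   reproducible.
#' @param exact_cov Color with `L` (covariance `= 2 Psi`) instead of the
#'   default `L^H`.
#' @return Complex `C x n_points` matrix.
#' @export
generate_correlated_noise <- function(model, n_points, seed = NULL,
                                      exact_cov = FALSE) {
  stopifnot(inherits(model, "noise_model"))
  if (!is.null(seed)) set.seed(seed)
  C <- nrow(model$psi)
  Eg <- matrix(complex(real = stats::rnorm(C * n_points),
                       imaginary = stats::rnorm(C * n_points)),
               C, n_points)
  L <- model$cholesky
  if (exact_cov) L %*% Eg else Conj(t(L)) %*% Eg
}

#' Add scaled correlated noise to a block
#'
#' Adds `q` times a unit-level correlated noise draw to every repeated
#' sampling, each average receiving an independent draw (derived seed
#' `seed + a` for average `a`). The noise realization depends only on the
#' seed, not on `q`, so `block(q) - block(0) = q * (block(1) - block(0))`
#' exactly under a fixed seed.
#'
#' @param block An [mrs_block()].
#' @param model A [noise_model()] defining the unit noise level.
#' @param q Non-negative noise level multiplier; `q = 0` returns the input
#'   unchanged.
#' @param seed Integer base seed for the per-average draws.
#' @param exact_cov Passed to [generate_correlated_noise()].
#' @return A new [mrs_block()].
#' @export
add_scaled_noise <- function(block, model, q, seed, exact_cov = FALSE) {
  stopifnot(inherits(block, "mrs_block"), inherits(model, "noise_model"))
  if (!is.numeric(q) || length(q) != 1L || q < 0) {
    stop("noise level `q` must be a single non-negative number", call. = FALSE)
  }
  if (q == 0) return(block)
  out <- block$data
  for (a in seq_len(block$meta$n_averages)) {
    E <- generate_correlated_noise(model, block$meta$n_points,
                                   seed = seed + a, exact_cov = exact_cov)
    out[, a, ] <- out[, a, ] + q * E
  }
  mrs_block(out, block$meta)
}

#' Whiten (or unwhiten) a coil matrix
#'
#' Applies the model's whitening transform `W` to the coil dimension, so the
#' whitened noise covariance is the identity: `W Psi W^H = I` for a full-rank
#' model. `unwhiten()` applies `W^{-1}`; `W = D^{-1/2} G^H` is built from
#' full-rank factors (eigenvalues floored if needed), so the inverse always
#' exists.
#'
#' @param X A [coil_matrix()].
#' @param model A [noise_model()].
#' @return A [coil_matrix()] in the same domain.
#' @export
whiten <- function(X, model) {
  stopifnot(inherits(X, "coil_matrix"), inherits(model, "noise_model"))
  if (nrow(model$psi) != nrow(X$data)) {
    stop("coil count of matrix and noise model disagree", call. = FALSE)
  }
  coil_matrix(model$whitener %*% X$data, X$meta, X$domain)
}

#' @rdname whiten
#' @export
unwhiten <- function(X, model) {
  stopifnot(inherits(X, "coil_matrix"), inherits(model, "noise_model"))
  # W^{-1} = G D^{1/2}
  Winv <- model$eigenvectors %*% diag(sqrt(model$eigenvalues),
                                      nrow(model$psi))
  coil_matrix(Winv %*% X$data, X$meta, X$domain)
}
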