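# shared fixtures and independent oracles for the suite

# reduced-geometry metadata used by most tests
test_meta <- function(C = 8L, A = 16L, N = 512L) {
  mrs_meta(spectral_bandwidth = 2000, n_points = N, n_coils = C,
           n_averages = A, transmitter_frequency = 128, reference_ppm = 4.7)
}

# |normalized inner product| between two complex vectors
abs_corr <- function(a, b) {
  Mod(sum(Conj(a) * b)) / sqrt(sum(Mod(a)^2) * sum(Mod(b)^2))
}

rcplx <- function(n) complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))

# exact rank-1 block: every average is s %*% t(m)
rank1_block <- function(s, m, meta) {
  dat <- array(0 + 0i, c(meta$n_coils, meta$n_averages, meta$n_points))
  for (a in seq_len(meta$n_averages)) dat[, a, ] <- outer(s, m)
  mrs_block(dat, meta)
}

# real 2C x 2C representation of a complex C x C matrix
real_rep <- function(M) {
  rbind(cbind(Re(M), -Im(M)), cbind(Im(M), Re(M)))
}

# brute-force generalized least squares: whiten via base::chol of the real
# representation of psi, then qr.solve the stacked real system; independent
# of the package's eigendecomposition path
oracle_gls <- function(X, psi, s) {
  Rr <- real_rep(psi)
  Wr <- solve(t(chol(Rr)))              # Wr %*% Rr %*% t(Wr) = I
  design <- Wr %*% cbind(c(Re(s), Im(s)), c(-Im(s), Re(s)))
  out <- complex(length.out = ncol(X))
  for (n in seq_len(ncol(X))) {
    rhs <- Wr %*% c(Re(X[, n]), Im(X[, n]))
    beta <- qr.solve(design, rhs)
    out[n] <- complex(real = beta[1], imaginary = beta[2])
  }
  out
}

# power-iteration rank-1 oracle: returns the best rank-1 approximation of X
oracle_rank1 <- function(X, iters = 2000L) {
  set.seed(42)
  v <- rcplx(ncol(X)); v <- v / sqrt(sum(Mod(v)^2))
  G <- Conj(t(X)) %*% X
  for (i in seq_len(iters)) {
    v <- G %*% v
    v <- v / sqrt(sum(Mod(v)^2))
  }
  u <- X %*% v
  sigma <- sqrt(sum(Mod(u)^2))
  u <- u / sigma
  list(sigma1 = sigma, approx = sigma * u %*% Conj(t(v)))
}

# upper-tail Student-t probability by numeric integration of the density
oracle_t_upper <- function(t, df) {
  const <- gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2))
  stats::integrate(function(u) const * (1 + u^2 / df)^(-(df + 1) / 2),
                   lower = t, upper = Inf, rel.tol = 1e-10)$value
}
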