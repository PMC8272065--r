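#' Spectral signal-to-noise ratio
#'
#' The SNR criterion used throughout the package:
#' `SNR = max(x - x_baseline)^2 / ((1/n) ||x - x_fitted||^2)`, evaluated on
#' the real part of the frequency-domain spectrum restricted to a
#' chemical-shift window (default 0.2-4.0 ppm, the conventional analysis
#' range of in vivo 1H-MRS). The numerator is a squared amplitude, i.e. a
#' power, so the decibel conversion is `10 log10(SNR)`.
#'
#' @param x Complex (or real) frequency-domain spectrum ordered like
#'   [ppm_axis()].
#' @param baseline Baseline spectrum (same length); scalar `0` for none.
#' @param fitted Fitted/reference spectrum (same length); the residual is
#'   `x - fitted`.
#' @param meta An [mrs_meta()] supplying the ppm axis.
#' @param region Length-2 ppm window `c(lo, hi)`.
#' @return An object of class `snr_report`: `snr_linear`, `snr_db`,
#'   `peak_value`, `residual_ms`, `region`, and `infinite` (`TRUE` when the
#'   residual is identically zero).
#' @export
snr <- function(x, baseline, fitted, meta, region = c(0.2, 4.0)) {
  stopifnot(inherits(meta, "mrs_meta"))
  n <- meta$n_points
  if (length(baseline) == 1L) baseline <- rep(baseline, n)
  if (length(fitted) == 1L) fitted <- rep(fitted, n)
  if (length(x) != n || length(baseline) != n || length(fitted) != n) {
    stop("x, baseline and fitted must all have length n_points", call. = FALSE)
  }
  idx <- ppm_indices(meta, region[1L], region[2L])
  d <- Re(x - baseline)[idx]
  r <- Re(x - fitted)[idx]
  peak <- max(d)
  ms <- mean(r^2)
  inf_flag <- ms == 0
  ratio <- if (inf_flag) Inf else peak^2 / ms
  structure(list(snr_linear = ratio,
                 snr_db = if (inf_flag) Inf else 10 * log10(ratio),
                 peak_value = peak,
                 residual_ms = ms,
                 region = region,
                 infinite = inf_flag),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("<snr_report> %.2f dB (linear %.4g) over %.2f-%.2f ppm%s\n",
              x$snr_db, x$snr_linear, x$region[1], x$region[2],
              if (x$infinite) " [infinite: zero residual]" else ""))
  invisible(x)
}

#' SNR of a combined spectrum against simulation ground truth
#'
#' Scores a combiner's output on synthetic data where the ideal spectrum is
#' known: the combined spectrum is gauged to the truth by the single complex
#' least-squares scalar over the scoring window (removing the combiner's
#' free amplitude/phase), the baseline is zero, and the fitted spectrum is
#' the true clean spectrum. The result is therefore invariant to any global
#' complex scaling of the combined spectrum.
#'
#' @param combined A [combined_spectrum()].
#' @param truth A `ground_truth` object from [simulate_block()].
#' @param region ppm scoring window.
#' @return An `snr_report` (see [snr()]).
#' @export
snr_synthetic <- function(combined, truth, region = c(0.2, 4.0)) {
  stopifnot(inherits(combined, "combined_spectrum"),
            inherits(truth, "ground_truth"))
  meta <- combined$meta
  if (meta$n_points != truth$meta$n_points) {
    stop("combined spectrum and ground truth have different lengths",
         call. = FALSE)
  }
  spec_t <- to_frequency(truth$clean_m)
  if (all(Mod(spec_t) == 0)) stop("ground truth is identically zero",
                                  call. = FALSE)
  spec_c <- to_frequency(combined$fid)
  idx <- ppm_indices(meta, region[1L], region[2L])
  denom <- sum(Mod(spec_c[idx])^2)
  if (denom == 0) stop("combined spectrum is identically zero in the region",
                       call. = FALSE)
  beta <- sum(Conj(spec_c[idx]) * spec_t[idx]) / denom
  snr(beta * spec_c, 0, spec_t, meta, region = region)
}

#' One-sided paired t-test on per-subject differences
#'
#' Tests whether the mean of paired differences is greater than zero:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom and
#' upper-tail p-value; `sd` uses the `n - 1` denominator. Suitable for small
#' samples (e.g. 20 spectra).
#'
#' @param d Numeric vector of paired differences, length >= 2.
#' @return List with `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
paired_t_one_sided <- function(d) {
  d <- as.numeric(d)
  if (length(d) < 2L) stop("need at least two differences", call. = FALSE)
  if (any(!is.finite(d))) stop("differences must be finite", call. = FALSE)
  s <- stats::sd(d)
  if (s == 0) {
    stop("zero variance in the differences; the t statistic is undefined",
         call. = FALSE)
  }
  n <- length(d)
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1L, p = stats::pt(t, df = n - 1L, lower.tail = FALSE),
       mean_diff = mean(d), n = n)
}

# run the four combiners on one simulated scene; returns named snr_db vector
.score_methods <- function(sim, methods, kernel = 7L,
                           noise_region = c(0.4, 1.0),
                           region = c(0.2, 4.0)) {
  block <- sim$block
  nm <- estimate_noise_model(block, noise_region[1L], noise_region[2L])
  Xbar <- average_block(block)
  out <- numeric(0)
  for (m in methods) {
    cs <- switch(m,
      brown = combine_brown(Xbar),
      gls = combine_gls(Xbar, nm, pick_naa_sensitivity(Xbar)),
      wsvd = combine_wsvd(Xbar, nm),
      assvd = combine_assvd(block, nm, k = kernel),
      stop("unknown method: ", m, call. = FALSE))
    out[m] <- snr_synthetic(cs, sim$truth, region = region)$snr_db
  }
  out
}

#' Benchmark: SNR versus noise level
#'
#' The noise-level sweep design: for each noise level `q` and each replicate
#' seed, simulate an acquisition, combine it with every requested method
#' (Brown, GLS with NAA-peak sensitivities, WSVD on the across-average mean;
#' ASSVD on the full block), and score against ground truth. Also reports,
#' per level, the paired one-sided t-test of ASSVD against each comparator.
#'
#' @param config Named list; recognized entries (with defaults):
#'   `meta` ([mrs_meta()]; default C=8, A=16, N=512), `preset` (`"invivo"`),
#'   `rho` (0.3), `q_levels` (`1:7`), `methods`
#'   (`c("brown","gls","wsvd","assvd")`), `kernel` (7), `seeds` (`1:20`),
#'   `magnitude_spread` (0.5), `region` (`c(0.2, 4.0)`),
#'   `noise_region` (`c(0.4, 1.0)`).
#' @return An object of class `benchmark_result` with `table` (one row per
#'   method x level x seed), `summary` (mean/sd SNR per method x level), and
#'   `t_stats` (ASSVD-minus-comparator contrasts per level).
#' @export
noise_level_sweep <- function(config = list()) {
  cfg <- .benchmark_config(config)
  rows <- list()
  for (q in cfg$q_levels) {
    for (seed in cfg$seeds) {
      sim <- simulate_scene(seed, cfg$meta, preset = cfg$preset,
                            rho = cfg$rho, q = q,
                            magnitude_spread = cfg$magnitude_spread)
      sc <- .score_methods(sim, cfg$methods, kernel = cfg$kernel,
                           noise_region = cfg$noise_region,
                           region = cfg$region)
      rows[[length(rows) + 1L]] <- data.frame(
        method = names(sc), q = q,
        k = ifelse(names(sc) == "assvd", cfg$kernel, 0L),
        seed = seed, snr_db = unname(sc))
    }
  }
  tab <- do.call(rbind, rows)
  .benchmark_result(tab, cfg, contrast_by = "q")
}

#' Benchmark: SNR versus ASSVD kernel size
#'
#' The kernel-size study design: per simulated "subject" (replicate seed) at
#' one noise level, score WSVD and ASSVD at each kernel size on the same
#' data (a fully paired design; the sensitivity field is estimated once per
#' subject and reused across kernels). Reports the paired one-sided t-test
#' of ASSVD at each kernel size against WSVD.
#'
#' @param config As [noise_level_sweep()], plus `q` (default 2) and
#'   `kernels` (default `c(3, 5, 7, 9)`).
#' @return A `benchmark_result`; `t_stats` has one row per kernel size.
#' @export
kernel_size_study <- function(config = list()) {
  cfg <- .benchmark_config(config, defaults = list(q = 2, kernels = c(3, 5, 7, 9)))
  if (any(cfg$kernels %% 2 == 0)) stop("kernel sizes must be odd", call. = FALSE)
  rows <- list()
  for (seed in cfg$seeds) {
    sim <- simulate_scene(seed, cfg$meta, preset = cfg$preset,
                          rho = cfg$rho, q = cfg$q,
                          magnitude_spread = cfg$magnitude_spread)
    nm <- estimate_noise_model(sim$block, cfg$noise_region[1L],
                               cfg$noise_region[2L])
    ws <- combine_wsvd(average_block(sim$block), nm)
    rows[[length(rows) + 1L]] <- data.frame(
      method = "wsvd", q = cfg$q, k = 0L, seed = seed,
      snr_db = snr_synthetic(ws, sim$truth, region = cfg$region)$snr_db)
    field <- estimate_sensitivity_field(sim$block, nm)
    for (k in cfg$kernels) {
      as_k <- combine_assvd(sim$block, nm, k = k, field = field)
      rows[[length(rows) + 1L]] <- data.frame(
        method = "assvd", q = cfg$q, k = k, seed = seed,
        snr_db = snr_synthetic(as_k, sim$truth, region = cfg$region)$snr_db)
    }
  }
  tab <- do.call(rbind, rows)
  .benchmark_result(tab, cfg, contrast_by = "k")
}

.benchmark_config <- function(config, defaults = list()) {
  cfg <- list(meta = mrs_meta(n_coils = 8, n_averages = 16, n_points = 512),
              preset = "invivo", rho = 0.3, q_levels = 1:7,
              methods = c("brown", "gls", "wsvd", "assvd"), kernel = 7L,
              seeds = 1:20, magnitude_spread = 0.5,
              region = c(0.2, 4.0), noise_region = c(0.4, 1.0))
  cfg[names(defaults)] <- defaults
  cfg[names(config)] <- config
  stopifnot(inherits(cfg$meta, "mrs_meta"))
  cfg
}

# assemble table + summary + ASSVD-vs-comparator paired contrasts
.benchmark_result <- function(tab, cfg, contrast_by) {
  summ <- stats::aggregate(snr_db ~ method + q + k, data = tab, FUN = mean,
                           na.action = stats::na.pass)
  names(summ)[names(summ) == "snr_db"] <- "mean_snr_db"
  summ$sd_snr_db <- stats::aggregate(snr_db ~ method + q + k, data = tab,
                                     FUN = stats::sd,
                                     na.action = stats::na.pass)$snr_db
  t_rows <- list()
  if (contrast_by == "q") {
    others <- setdiff(unique(tab$method), "assvd")
    for (q in unique(tab$q)) {
      a <- tab[tab$method == "assvd" & tab$q == q, ]
      a <- a[order(a$seed), ]
      for (m in others) {
        b <- tab[tab$method == m & tab$q == q, ]
        b <- b[order(b$seed), ]
        tt <- tryCatch(paired_t_one_sided(a$snr_db - b$snr_db),
                       error = function(e) list(t = NA, df = NA, p = NA))
        t_rows[[length(t_rows) + 1L]] <- data.frame(
          contrast = paste0("assvd-", m), q = q, k = cfg$kernel,
          t = tt$t, df = tt$df, p = tt$p)
      }
    }
  } else if (contrast_by == "k") {
    b <- tab[tab$method == "wsvd", ]
    b <- b[order(b$seed), ]
    for (k in sort(unique(tab$k[tab$method == "assvd"]))) {
      a <- tab[tab$method == "assvd" & tab$k == k, ]
      a <- a[order(a$seed), ]
      tt <- tryCatch(paired_t_one_sided(a$snr_db - b$snr_db),
                     error = function(e) list(t = NA, df = NA, p = NA))
      t_rows[[length(t_rows) + 1L]] <- data.frame(
        contrast = "assvd-wsvd", q = unique(tab$q), k = k,
        t = tt$t, df = tt$df, p = tt$p)
    }
  }
  structure(list(table = tab,
                 summary = summ[order(summ$method, summ$q, summ$k), ],
                 t_stats = if (length(t_rows)) do.call(rbind, t_rows) else NULL,
                 config = cfg),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$t_stats)) {
    cat("paired one-sided t-tests:\n")
    print(x$t_stats, row.names = FALSE)
  }
  invisible(x)
}
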