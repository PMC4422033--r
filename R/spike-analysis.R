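#' Detect spikes in a voltage trace
#'
#' A spike is an upward crossing of the threshold voltage; crossings within
#' the dead time of the previous spike are ignored. The default threshold
#' of 0 mV sits far above subthreshold fluctuations and below all action
#' potential peaks, and the 2 ms dead time is shorter than the model's
#' refractory period, so detection is unambiguous.
#'
#' @param trace an `hh_trace` (from [simulate.hh_model()]) or any list with
#'   numeric `t` (ms) and `V` (mV).
#' @param threshold crossing threshold, mV.
#' @param dead_time minimum spacing between detected spikes, ms.
#' @return An object of class `spike_train` with `spike_times` (ms, strictly
#'   increasing) and `record_length` (s).
#' @export
detect_spikes <- function(trace, threshold = 0, dead_time = 2) {
  V <- trace$V
  # non-finite samples (flagged runs) can never cross the threshold
  V[!is.finite(V)] <- -Inf
  n <- length(V)
  up <- which(V[-n] < threshold & V[-1] >= threshold)
  times <- trace$t[up + 1]
  if (length(times) > 1) {
    keep <- logical(length(times))
    last <- -Inf
    for (i in seq_along(times)) {
      if (times[i] - last >= dead_time) {
        keep[i] <- TRUE
        last <- times[i]
      }
    }
    times <- times[keep]
  }
  record_s <- if (!is.null(trace$duration)) trace$duration
              else max(trace$t) / 1e3
  spike_train(times, record_s)
}

#' Spike train
#'
#' @param spike_times spike times, ms, strictly increasing.
#' @param record_length record length, s.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(spike_times, record_length = 1) {
  spike_times <- as.numeric(spike_times)
  stopifnot(!is.unsorted(spike_times, strictly = TRUE),
            all(spike_times >= 0),
            all(spike_times <= record_length * 1e3))
  structure(list(spike_times = spike_times, record_length = record_length),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes in %g s (%.1f spikes/s)\n",
              length(x$spike_times), x$record_length,
              length(x$spike_times) / x$record_length))
  invisible(x)
}

#' Convert a spike train to a uniform-height pulse train
#'
#' The spike sequence is reduced to discretised Dirac pulses U(t): the bin
#' containing each spike is set to 100 mV, every other bin to 0, discarding
#' spike shape and retaining timing only. The default 0.5 ms bin gives
#' 2 kHz sampling, so a 1 s record yields 1 Hz spectral spacing with a
#' 1 kHz Nyquist frequency covering the studied 10-500 Hz signal range.
#'
#' @param train a [spike_train()].
#' @param bin_width bin width, ms; must be smaller than the detection dead
#'   time so no two spikes share a bin.
#' @param height pulse height, mV.
#' @return An object of class `pulse_train` with `samples` (mV),
#'   `bin_width` (ms) and `record_length` (s).
#' @export
pulse_train <- function(train, bin_width = 0.5, height = 100) {
  stopifnot(inherits(train, "spike_train"), bin_width > 0)
  n_bins <- as.integer(round(train$record_length * 1e3 / bin_width))
  u <- numeric(n_bins)
  if (length(train$spike_times) > 0) {
    idx <- pmin(floor(train$spike_times / bin_width) + 1, n_bins)
    if (anyDuplicated(idx))
      stop("two spikes fall in one bin; decrease bin_width")
    u[idx] <- height
  }
  structure(list(samples = u, bin_width = bin_width,
                 record_length = train$record_length, height = height),
            class = "pulse_train")
}

#' Total power of a pulse train
#'
#' Time-averaged squared amplitude of the binned U(t), in mV^2. Under the
#' fixed bin discretisation this is proportional to the spike count, so
#' ratios of total power between conditions are independent of the pulse
#' normalisation.
#'
#' @param U a [pulse_train()].
#' @return Total power, mV^2.
#' @export
total_power <- function(U) {
  stopifnot(inherits(U, "pulse_train"))
  mean(U$samples^2)
}

#' Run-averaged periodogram of pulse trains
#'
#' One-sided periodogram (rectangular window, no detrending) of each run's
#' pulse train via the FFT, averaged across runs with a per-frequency
#' standard error. The periodogram is normalised so that
#' `sum(psd) * df` equals the record's time-average power (Parseval), with
#' `df = 1/record_length` (1 Hz for the 1 s records used throughout).
#' Per-run spectra are retained for covariance-based error propagation.
#'
#' @param pulse_trains list of [pulse_train()] objects over replicate runs,
#'   all with the same length and bin width.
#' @return An object of class `psd_estimate` with `freqs` (Hz), `mean_psd`,
#'   `se_psd` (mV^2/Hz), `R`, and the R x nfreq matrix `runs`.
#' @export
averaged_psd <- function(pulse_trains) {
  stopifnot(length(pulse_trains) >= 1,
            all(vapply(pulse_trains, inherits, logical(1), "pulse_train")))
  n <- unique(vapply(pulse_trains, function(u) length(u$samples), integer(1)))
  bw <- unique(vapply(pulse_trains, function(u) u$bin_width, numeric(1)))
  if (length(n) != 1 || length(bw) != 1)
    stop("pulse trains differ in length or bin width")
  rec_s <- pulse_trains[[1]]$record_length
  df <- 1 / rec_s
  half <- floor(n / 2)
  freqs <- (0:half) * df
  runs <- t(vapply(pulse_trains, function(u) {
    X <- stats::fft(u$samples) / n
    p2 <- Mod(X)^2
    one <- p2[1:(half + 1)]
    if (n %% 2 == 0) one[2:half] <- 2 * one[2:half]
    else one[2:(half + 1)] <- 2 * one[2:(half + 1)]
    one / df
  }, numeric(half + 1)))
  R <- length(pulse_trains)
  mean_psd <- colMeans(runs)
  se_psd <- if (R >= 2) apply(runs, 2, stats::sd) / sqrt(R)
            else rep(NA_real_, half + 1)
  structure(list(freqs = freqs, mean_psd = mean_psd, se_psd = se_psd,
                 R = R, runs = runs, df = df),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("PSD estimate: %d frequencies (%g-%g Hz, df = %g Hz), R = %d\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$df, x$R))
  invisible(x)
}

#' @export
plot.psd_estimate <- function(x, xlim = NULL, ...) {
  graphics::plot(x$freqs, x$mean_psd, type = "l", xlab = "frequency (Hz)",
                 ylab = "PSD (mV^2/Hz)", xlim = xlim, ...)
  invisible(x)
}

psd_at <- function(psd, f) {
  i <- which(abs(psd$freqs - f) < psd$df / 2)
  if (length(i) != 1) stop(sprintf("frequency %g Hz not on the grid", f))
  i
}

#' Signal-to-noise ratio at the forcing frequency
#'
#' SNR = mean PSD at the signal frequency divided by the background, where
#' the background is the average of the mean PSD 1 Hz below and 1 Hz above
#' the signal frequency. SNR = 1 means the signal is undetectable. The
#' standard error comes from first-order propagation through the ratio of
#' the three correlated PSD means, using their across-run covariance; the
#' adjacent-bin correlation (about 0.9 under sustained firing) makes this
#' substantially smaller than an uncorrelated propagation would give.
#'
#' @param psd a [psd_estimate()] with per-run spectra.
#' @param f_s signal frequency, Hz; `f_s` and `f_s +/- 1` Hz must be on the
#'   frequency grid.
#' @return An object of class `snr_estimate` with `snr`, `se`, `background`,
#'   and the pairwise across-run correlations `rho`.
#' @export
snr <- function(psd, f_s) {
  stopifnot(inherits(psd, "psd_estimate"))
  ip <- psd_at(psd, f_s)
  im <- psd_at(psd, f_s - 1)
  ii <- psd_at(psd, f_s + 1)
  P <- psd$mean_psd[ip]
  B <- (psd$mean_psd[im] + psd$mean_psd[ii]) / 2
  if (!is.finite(B) || B <= 0) {
    warning("zero background PSD: SNR undefined (no sustained firing)")
    return(structure(list(f_s = f_s, snr = NA_real_, se = NA_real_,
                          background = B, rho = NA_real_, R = psd$R,
                          failed = TRUE),
                     class = "snr_estimate"))
  }
  value <- P / B
  se <- NA_real_
  rho <- NA_real_
  if (psd$R >= 2) {
    tri <- psd$runs[, c(ip, im, ii), drop = FALSE]
    cv <- stats::cov(tri) / psd$R
    grad <- c(1 / B, -value / (2 * B), -value / (2 * B))
    se <- sqrt(drop(t(grad) %*% cv %*% grad))
    rho <- adjacent_psd_correlation(psd, f_s)["below_above"]
  }
  structure(list(f_s = f_s, snr = value, se = se, background = B,
                 rho = unname(rho), R = psd$R, failed = FALSE),
            class = "snr_estimate")
}

#' @export
print.snr_estimate <- function(x, ...) {
  if (isTRUE(x$failed))
    cat(sprintf("SNR at %g Hz: undefined (zero background)\n", x$f_s))
  else
    cat(sprintf("SNR at %g Hz: %.3f +/- %.3f (background %.3g, R = %d)\n",
                x$f_s, x$snr, x$se, x$background, x$R))
  invisible(x)
}

#' Across-run correlation of adjacent PSD samples
#'
#' Pearson correlations, across replicate runs, between the periodogram
#' samples at the signal frequency and its two 1 Hz neighbours. Degenerate
#' (zero-variance) samples give NA.
#'
#' @inheritParams snr
#' @return Named vector: `below_above` (f_s - 1 vs f_s + 1), `peak_below`,
#'   `peak_above`.
#' @export
adjacent_psd_correlation <- function(psd, f_s) {
  stopifnot(inherits(psd, "psd_estimate"), psd$R >= 2)
  ip <- psd_at(psd, f_s)
  im <- psd_at(psd, f_s - 1)
  ii <- psd_at(psd, f_s + 1)
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  c(below_above = safe_cor(psd$runs[, im], psd$runs[, ii]),
    peak_below = safe_cor(psd$runs[, ip], psd$runs[, im]),
    peak_above = safe_cor(psd$runs[, ip], psd$runs[, ii]))
}

#' Firing-rate statistics over replicate runs
#'
#' Mean and standard error of the per-run spike counts per second.
#'
#' @param trains list of [spike_train()] objects.
#' @return Named vector with `mean`, `se` (spikes/s) and `R`.
#' @export
firing_rate_stats <- function(trains) {
  stopifnot(all(vapply(trains, inherits, logical(1), "spike_train")))
  rates <- vapply(trains, function(tr)
    length(tr$spike_times) / tr$record_length, numeric(1))
  R <- length(rates)
  se <- if (R >= 2) stats::sd(rates) / sqrt(R) else NA_real_
  c(mean = mean(rates), se = se, R = R)
}
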