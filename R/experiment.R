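#' Run one experimental condition
#'
#' Simulates `R` replicate 1 s traces of an [hh_model()], detects spikes,
#' builds 100 mV pulse trains, and computes the run-averaged firing rate,
#' total output power, periodogram, and (when a stimulus is present) the
#' SNR at the forcing frequency. This is the unit cell of the frequency and
#' noise sweeps. Traces are processed one at a time, so memory stays flat
#' in `R`.
#'
#' @param model an [hh_model()].
#' @param R number of replicate runs (the reference protocol uses 100 with
#'   channel noise alone and 300 when exogenous noise is present).
#' @param seed master seed.
#' @param bin_width pulse-train bin width, ms.
#' @param threshold,dead_time spike-detection parameters (mV, ms).
#' @param verbose print progress every 50 runs.
#' @return An object of class `condition_result`: firing-rate statistics,
#'   mean total power, a [averaged_psd()] estimate, an [snr()] estimate (or
#'   `NULL` without a stimulus), the adjacent-bin correlations, and the
#'   number of excluded (diverged) runs.
#' @export
run_condition <- function(model, R = 100, seed = 1, bin_width = 0.5,
                          threshold = 0, dead_time = 2, verbose = FALSE) {
  stopifnot(inherits(model, "hh_model"), R >= 1)
  seeds <- child_seeds(seed, R)
  trains <- vector("list", R)
  pulses <- vector("list", R)
  powers <- numeric(R)
  ok <- logical(R)
  for (r in seq_len(R)) {
    tr <- simulate(model, nsim = 1, seed = seeds[r])$traces[[1]]
    ok[r] <- !tr$diverged
    if (!ok[r]) next
    trains[[r]] <- detect_spikes(tr, threshold, dead_time)
    pulses[[r]] <- pulse_train(trains[[r]], bin_width)
    powers[r] <- total_power(pulses[[r]])
    if (verbose && r %% 50 == 0)
      message(sprintf("  run %d/%d (%.1f spikes/s so far)", r, R,
                      unname(firing_rate_stats(trains[seq_len(r)][
                        ok[seq_len(r)]])["mean"])))
  }
  if (any(!ok))
    warning(sprintf("%d of %d runs diverged and were excluded",
                    sum(!ok), R))
  trains <- trains[ok]
  pulses <- pulses[ok]
  rate <- firing_rate_stats(trains)
  psd <- averaged_psd(pulses)
  snr_est <- NULL
  rho <- NULL
  if (!is.null(model$stimulus)) {
    snr_est <- snr(psd, model$stimulus$frequency)
    if (sum(ok) >= 2)
      rho <- adjacent_psd_correlation(psd, model$stimulus$frequency)
  }
  structure(list(model = model, R = sum(ok), n_excluded = sum(!ok),
                 seed = seed, rate = rate,
                 power = c(mean = mean(powers[ok]),
                           se = if (sum(ok) >= 2)
                                  stats::sd(powers[ok]) / sqrt(sum(ok))
                                else NA_real_),
                 psd = psd, snr = snr_est, rho = rho, trains = trains),
            class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("Condition: %g um^2, I0 = %g uA/cm^2, D = %g mV^2, R = %d\n",
              x$model$patch$area, x$model$I0,
              if (is.null(x$model$noise)) 0 else x$model$noise$D, x$R))
  cat(sprintf("  rate  : %.2f +/- %.2f spikes/s\n",
              x$rate["mean"], x$rate["se"]))
  cat(sprintf("  power : %.3g mV^2\n", x$power["mean"]))
  if (!is.null(x$snr)) print(x$snr)
  invisible(x)
}

sweep_row <- function(res) {
  m <- res$model
  data.frame(area = m$patch$area, I0 = m$I0,
             frequency = if (is.null(m$stimulus)) NA_real_
                         else m$stimulus$frequency,
             D = if (is.null(m$noise)) 0 else m$noise$D,
             R = res$R, n_excluded = res$n_excluded, seed = res$seed,
             rate = unname(res$rate["mean"]),
             rate_se = unname(res$rate["se"]),
             power = unname(res$power["mean"]),
             snr = if (is.null(res$snr)) NA_real_ else res$snr$snr,
             snr_se = if (is.null(res$snr)) NA_real_ else res$snr$se)
}

#' Frequency sweep of the SNR
#'
#' Sweeps the sinusoid frequency (no exogenous noise) and records the SNR
#' at each forcing frequency, reproducing the bell-shaped frequency
#' sensitivity of the model. Each grid cell gets an independent child seed
#' derived from `seed`.
#'
#' @param model an [hh_model()]; its stimulus frequency is replaced by each
#'   grid value in turn.
#' @param frequencies signal frequencies, Hz.
#' @param R replicate runs per frequency.
#' @param seed master seed.
#' @param ... passed to [run_condition()].
#' @return A `sweep_result`: a data.frame with one row per frequency plus
#'   attributes `peak_frequency` and `peak_snr`.
#' @export
run_frequency_sweep <- function(model, frequencies = c(10, 50, 100, 150,
                                                       200, 300, 400, 500),
                                R = 100, seed = 1, ...) {
  stopifnot(all(frequencies > 0))
  seeds <- child_seeds(seed, length(frequencies))
  rows <- vector("list", length(frequencies))
  for (i in seq_along(frequencies)) {
    m <- hh_model(area = model$patch, I0 = model$I0,
                  stimulus = stimulus_spec(model$stimulus$amplitude,
                                           frequencies[i],
                                           model$stimulus$phase),
                  noise = model$noise, hh = model$hh, dt = model$dt,
                  duration = model$duration)
    rows[[i]] <- sweep_row(run_condition(m, R = R, seed = seeds[i], ...))
  }
  out <- do.call(rbind, rows)
  ok <- is.finite(out$snr)
  if (any(ok)) {
    attr(out, "peak_frequency") <- out$frequency[ok][which.max(out$snr[ok])]
    attr(out, "peak_snr") <- max(out$snr[ok])
  }
  class(out) <- c("sweep_result", class(out))
  out
}

#' Noise sweep of the SNR (stochastic resonance curve)
#'
#' Sweeps the exogenous noise power D at fixed signal frequency and records
#' SNR(D) and firing rate(D). The SNR maximum over the grid identifies the
#' optimum noise power D_opt; a maximum at an interior D exceeding the
#' D = 0 value is the stochastic-resonance signature.
#'
#' @param model an [hh_model()] with a stimulus; its noise spec is replaced
#'   by each D in turn (D = 0 runs with channel noise alone).
#' @param D_grid noise powers, mV^2. The default grid spans the studied
#'   0.7-25 mV^2 range and includes 0.
#' @param omega_c Lorentzian cutoff, rad/s.
#' @param R replicate runs per noise level.
#' @param seed master seed.
#' @param ... passed to [run_condition()].
#' @return A `sweep_result` data.frame with one row per D plus attributes
#'   `D_opt` and `snr_opt`.
#' @export
run_noise_sweep <- function(model, D_grid = c(0, 0.7, 2, 4, 7, 12, 18, 25),
                            omega_c = 2.5e3, R = 300, seed = 1, ...) {
  stopifnot(!is.null(model$stimulus), all(D_grid >= 0))
  seeds <- child_seeds(seed, length(D_grid))
  rows <- vector("list", length(D_grid))
  for (i in seq_along(D_grid)) {
    m <- hh_model(area = model$patch, I0 = model$I0,
                  stimulus = model$stimulus,
                  noise = if (D_grid[i] > 0) noise_spec(D_grid[i], omega_c),
                  hh = model$hh, dt = model$dt, duration = model$duration)
    rows[[i]] <- sweep_row(run_condition(m, R = R, seed = seeds[i], ...))
  }
  out <- do.call(rbind, rows)
  ok <- is.finite(out$snr)
  if (any(ok)) {
    attr(out, "D_opt") <- out$D[ok][which.max(out$snr[ok])]
    attr(out, "snr_opt") <- max(out$snr[ok])
  }
  class(out) <- c("sweep_result", class(out))
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  if (!is.null(attr(x, "D_opt")))
    cat(sprintf("D_opt = %g mV^2 (SNR %.3f)\n",
                attr(x, "D_opt"), attr(x, "snr_opt")))
  if (!is.null(attr(x, "peak_frequency")))
    cat(sprintf("peak at %g Hz (SNR %.3f)\n",
                attr(x, "peak_frequency"), attr(x, "peak_snr")))
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, ...) {
  if (!is.null(attr(x, "D_opt")))
    graphics::plot(x$D, x$snr, type = "b", xlab = "noise power D (mV^2)",
                   ylab = "SNR", ...)
  else
    graphics::plot(x$frequency, x$snr, type = "b",
                   xlab = "signal frequency (Hz)", ylab = "SNR", ...)
  invisible(x)
}

#' Synthetic fixtures with analytically known statistics
#'
#' Deterministic, seeded inputs for validating the analysis chain: Poisson
#' spike trains of known rate, a strictly periodic train with a known line
#' spectrum, a voltage-clamped channel ensemble with known stationary
#' occupancy, and an analytic voltage trace with known threshold-crossing
#' times.
#'
#' @param kind one of `"poisson_trains"`, `"periodic_train"`,
#'   `"clamped_ensemble"`, `"analytic_crossing_trace"`.
#' @param params list of kind-specific parameters: `rate` (spikes/s) and
#'   `R` for Poisson trains; `frequency` (Hz) for the periodic train; `V`
#'   (mV) and `patch` for the clamped ensemble; `crossing_times` (ms) for
#'   the analytic trace.
#' @param seed RNG seed (used by the stochastic kinds).
#' @return Fixture object of the matching class.
#' @export
make_fixtures <- function(kind, params = list(), seed = 1) {
  switch(kind,
    poisson_trains = withr::with_seed(seed, {
      rate <- params$rate %||% 20
      R <- params$R %||% 100
      dead <- params$dead_time %||% 0
      lapply(seq_len(R), function(i) {
        n <- stats::rpois(1, rate)
        tt <- sort(stats::runif(n, 0, 1000))
        if (dead > 0 && n > 1) tt <- tt[c(TRUE, diff(tt) >= dead)]
        spike_train(tt, 1)
      })
    }),
    periodic_train = {
      f <- params$frequency %||% 100
      spike_train(seq(0, 1000 - 1000 / f, by = 1000 / f), 1)
    },
    clamped_ensemble = withr::with_seed(seed, {
      V <- params$V %||% -65
      patch <- params$patch %||% membrane_patch(300)
      steady_state_counts(V, patch)
    }),
    analytic_crossing_trace = {
      ct <- params$crossing_times %||% c(10, 30, 50)
      dt <- params$dt %||% 0.01
      dur <- params$duration %||% 0.1
      t <- seq(0, dur * 1e3, by = dt)
      V <- rep(-65, length(t))
      for (tc in ct) V[t >= tc & t < tc + 1] <- 20
      list(t = t, V = V, duration = dur)
    },
    stop(sprintf("unknown fixture kind '%s'", kind))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
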