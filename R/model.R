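#' Stochastic Hodgkin-Huxley neuron model
#'
#' Builds the full simulation configuration: a membrane patch whose Na and K
#' channels are simulated as finite Markov ensembles (endogenous channel
#' noise), a constant presynaptic current `I0`, and optional exogenous
#' perturbations applied in series with the membrane — a weak sinusoidal
#' signal and/or Lorentzian-filtered Gaussian voltage noise. The gating
#' rates and ionic driving forces see the total voltage
#' `V_tot = V + V_ES + V_noise`, while the membrane capacitance integrates
#' the physiological voltage `V` (the series sources supply their own
#' displacement current).
#'
#' `I0` below the deterministic firing threshold (about 6.3 uA/cm^2 for the
#' default parameters) models an impaired, understimulated neuron; above it,
#' a healthy one.
#'
#' @param area patch area, um^2 (or a [membrane_patch()]).
#' @param I0 constant presynaptic current, uA/cm^2.
#' @param stimulus a [stimulus_spec()], or `NULL` for no signal.
#' @param noise a [noise_spec()], or `NULL` for channel noise alone.
#' @param hh an [hh_params()] object.
#' @param dt integration step, ms (default 0.01 ms = 10 us).
#' @param duration record length, s.
#' @return An object of class `hh_model`.
#' @examples
#' m <- hh_model(area = 300, I0 = 2)
#' m
#' @seealso [simulate.hh_model()], [run_condition()]
#' @export
hh_model <- function(area = 300, I0 = 2, stimulus = stimulus_spec(),
                     noise = NULL, hh = hh_params(), dt = 0.01,
                     duration = 1) {
  patch <- if (inherits(area, "membrane_patch")) area else membrane_patch(area)
  stopifnot(dt > 0, duration > 0, is.numeric(I0), length(I0) == 1)
  if (!is.null(stimulus)) stopifnot(inherits(stimulus, "stimulus_spec"))
  if (!is.null(noise)) stopifnot(inherits(noise, "noise_spec"))
  structure(list(patch = patch, I0 = I0, stimulus = stimulus, noise = noise,
                 hh = hh, dt = dt, duration = duration,
                 n_steps = as.integer(round(duration * 1e3 / dt))),
            class = "hh_model")
}

#' @export
print.hh_model <- function(x, ...) {
  cat("Stochastic Hodgkin-Huxley neuron model\n")
  cat(sprintf("  patch: %g um^2 (N_Na = %d, N_K = %d)\n",
              x$patch$area, x$patch$N_Na, x$patch$N_K))
  cat(sprintf("  I0 = %g uA/cm^2, dt = %g ms, record %g s\n",
              x$I0, x$dt, x$duration))
  if (is.null(x$stimulus)) cat("  stimulus: none\n")
  else cat(sprintf("  stimulus: %g mV sinusoid at %g Hz\n",
                   x$stimulus$amplitude, x$stimulus$frequency))
  if (is.null(x$noise)) cat("  exogenous noise: none\n")
  else cat(sprintf("  exogenous noise: D = %g mV^2, omega_c = %g rad/s\n",
                   x$noise$D, x$noise$omega_c))
  invisible(x)
}

#' @export
coef.hh_model <- function(object, ...) {
  c(area = object$patch$area, N_Na = object$patch$N_Na,
    N_K = object$patch$N_K, I0 = object$I0,
    amplitude = if (is.null(object$stimulus)) 0 else object$stimulus$amplitude,
    frequency = if (is.null(object$stimulus)) NA_real_
                else object$stimulus$frequency,
    D = if (is.null(object$noise)) 0 else object$noise$D,
    omega_c = if (is.null(object$noise)) NA_real_ else object$noise$omega_c,
    dt = object$dt, duration = object$duration)
}

# per-run child seeds derived from one master seed (kept below 2^31)
child_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Simulate membrane voltage traces
#'
#' Forward-Euler integration (default step 10 us) of the membrane equation
#' with stochastic channel-state tracking: at every step the occupancy
#' counts of the 8 Na and 5 K Markov states are advanced by multinomial
#' draws, the open-channel counts set the Na and K conductances, and the
#' voltage is updated with the constant current `I0` and the exogenous
#' series perturbations. Initial voltage is the deterministic resting
#' potential of the unperturbed (zero-current) model and channel states are
#' drawn from the clamped stationary law at that voltage; no transient is
#' discarded. In `"deterministic"` mode the ensembles are replaced by the
#' classical m, h, n rate equations (conductances `gbar_Na m^3 h`,
#' `gbar_K n^4`), removing the channel noise; exogenous perturbations, if
#' specified, still apply.
#'
#' Runs in which the voltage diverges (|V| > 200 mV) are flagged and
#' excluded by downstream statistics with a warning.
#'
#' @param object an [hh_model()].
#' @param nsim number of replicate runs.
#' @param seed master seed; each run uses an independent child seed derived
#'   from it, so results are reproducible and runs independent.
#' @param mode `"stochastic"` (channel ensembles) or `"deterministic"`
#'   (gating ODEs).
#' @param keep_total also store `V_total = V + V_ES + V_noise`.
#' @param keep_open also store per-step open-channel counts.
#' @param ... unused.
#' @return An object of class `hh_sim`: a list of `hh_trace` objects (each
#'   with time grid `t` in ms and voltage `V` in mV) plus the model.
#' @examples
#' m <- hh_model(area = 200, I0 = 2, duration = 0.05)
#' sim <- simulate(m, nsim = 2, seed = 1)
#' summary(sim)
#' @export
simulate.hh_model <- function(object, nsim = 1, seed = 1,
                              mode = c("stochastic", "deterministic"),
                              keep_total = FALSE, keep_open = FALSE, ...) {
  mode <- match.arg(mode)
  n_steps <- object$n_steps
  dt <- object$dt
  hh <- object$hh
  patch <- object$patch
  v_rest <- resting_potential(hh, patch, I0 = 0)
  ves <- if (is.null(object$stimulus)) numeric(n_steps)
         else sinusoid(object$stimulus, dt, n_steps)
  seeds <- child_seeds(seed, nsim)
  traces <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    traces[[r]] <- withr::with_seed(seeds[r], {
      perturb <- ves
      if (!is.null(object$noise) && object$noise$D > 0)
        perturb <- perturb + lorentzian_noise(object$noise, dt, n_steps)
      if (mode == "deterministic") {
        s <- hh_steady_state(v_rest)
        res <- hh_run_det_cpp(n_steps, dt, s$m_inf, s$h_inf, s$n_inf,
                              v_rest, object$I0, perturb,
                              hh$gamma_Na * patch$density_Na / 10,
                              hh$gamma_K * patch$density_K / 10,
                              hh$Cm, hh$gL, hh$V_Na, hh$V_K, hh$V_L)
      } else {
        st <- steady_state_counts(v_rest, patch)
        res <- hh_run_cpp(n_steps, dt, patch$area, st$na, st$k,
                          v_rest, object$I0, perturb,
                          hh$gamma_Na, hh$gamma_K,
                          hh$Cm, hh$gL, hh$V_Na, hh$V_K, hh$V_L,
                          keep_total, keep_open)
      }
      V <- res$V
      if (res$diverged && res$steps_done + 2 <= length(V))
        V[(res$steps_done + 2):length(V)] <- NA_real_
      tr <- list(t = seq(0, n_steps) * dt, V = V,
                 dt = dt, duration = object$duration,
                 diverged = res$diverged, seed = seeds[r])
      if (isTRUE(keep_total) && mode == "stochastic")
        tr$V_total <- res$V_total
      if (isTRUE(keep_open) && mode == "stochastic") {
        tr$open_na <- res$open_na
        tr$open_k <- res$open_k
      }
      structure(tr, class = "hh_trace")
    })
  }
  n_div <- sum(vapply(traces, function(x) x$diverged, logical(1)))
  if (n_div > 0)
    warning(sprintf("%d of %d runs diverged and are flagged", n_div, nsim))
  structure(list(traces = traces, model = object, mode = mode, seed = seed),
            class = "hh_sim")
}

#' @export
print.hh_sim <- function(x, ...) {
  cat(sprintf("hh_sim: %d %s run(s) of %g s (dt = %g ms), seed %s\n",
              length(x$traces), x$mode, x$model$duration, x$model$dt,
              format(x$seed)))
  invisible(x)
}

#' @export
summary.hh_sim <- function(object, threshold = 0, dead_time = 2, ...) {
  trains <- lapply(object$traces, detect_spikes,
                   threshold = threshold, dead_time = dead_time)
  rate <- firing_rate_stats(trains)
  out <- list(n_runs = length(object$traces),
              n_diverged = sum(vapply(object$traces,
                                      function(x) x$diverged, logical(1))),
              rate = rate, mode = object$mode)
  class(out) <- "summary.hh_sim"
  out
}

#' @export
print.summary.hh_sim <- function(x, ...) {
  cat(sprintf("%d %s run(s), %d diverged\n", x$n_runs, x$mode, x$n_diverged))
  cat(sprintf("mean firing rate: %.2f +/- %.2f spikes/s\n",
              x$rate["mean"], x$rate["se"]))
  invisible(x)
}

#' @export
plot.hh_trace <- function(x, ...) {
  graphics::plot(x$t, x$V, type = "l", xlab = "time (ms)",
                 ylab = "membrane voltage (mV)", ...)
  invisible(x)
}

#' Deterministic repetitive-firing threshold
#'
#' Bisection on the constant current `I0` for the smallest value giving
#' sustained firing (at least two spikes in the final half of the record)
#' of the deterministic model. For the default parameters this recovers the
#' classical threshold near 6.3 uA/cm^2.
#'
#' @param model an [hh_model()] (its `I0` is ignored).
#' @param tolerance bisection tolerance, uA/cm^2.
#' @param bracket initial currents bracketing the threshold.
#' @return The threshold current, uA/cm^2.
#' @examples
#' \donttest{
#' find_firing_threshold(hh_model(area = 300))
#' }
#' @export
find_firing_threshold <- function(model = hh_model(), tolerance = 0.05,
                                  bracket = c(2, 10)) {
  fires <- function(I0) {
    m <- hh_model(area = model$patch, I0 = I0, stimulus = NULL, noise = NULL,
                  hh = model$hh, dt = model$dt, duration = model$duration)
    tr <- simulate(m, nsim = 1, mode = "deterministic")$traces[[1]]
    sp <- detect_spikes(tr)
    half <- model$duration * 500
    sum(sp$spike_times >= half) >= 2
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (fires(lo) || !fires(hi))
    stop("bracket does not straddle the firing threshold")
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
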