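#' Sinusoidal stimulus specification
#'
#' The exogenous electric signal: a weak series voltage perturbation of the
#' membrane, `amplitude * sin(2 pi f t + phase)`. The default 0.5 mV
#' (500 uV) is weak in the sense that it cannot by itself fire a
#' subthreshold neuron without some source of noise.
#'
#' @param amplitude peak amplitude, mV.
#' @param frequency signal frequency, Hz (the studied range is 10-500 Hz).
#' @param phase phase offset, rad.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(amplitude = 0.5, frequency = 150, phase = 0) {
  stopifnot(amplitude >= 0, frequency > 0)
  structure(list(amplitude = amplitude, frequency = frequency, phase = phase),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("Sinusoidal stimulus: %g mV at %g Hz (phase %g rad)\n",
              x$amplitude, x$frequency, x$phase))
  invisible(x)
}

#' Exogenous noise specification
#'
#' Zero-mean Gaussian voltage noise with a Lorentzian power spectrum
#' `PSD(f) = A / (omega_c^2 + (2 pi f)^2)`: flat below the cutoff angular
#' frequency, rolling off as 1/f^2 above it. The amplitude constant A is
#' fixed implicitly by calibrating the delivered variance to the noise
#' power `D`, so the marginal standard deviation is `sqrt(D)`.
#'
#' @param D noise power (variance of the delivered voltage noise), mV^2.
#' @param omega_c cutoff angular frequency, rad/s.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(D, omega_c = 2.5e3) {
  stopifnot(is.numeric(D), length(D) == 1, D >= 0, omega_c > 0)
  structure(list(D = D, omega_c = omega_c), class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("Lorentzian voltage noise: D = %g mV^2, omega_c = %g rad/s\n",
              x$D, x$omega_c))
  invisible(x)
}

#' Sample a sinusoidal stimulus on the simulation grid
#'
#' @param spec a [stimulus_spec()].
#' @param dt time step, ms.
#' @param n_steps number of samples.
#' @return Numeric vector, mV; element k is the stimulus at time
#'   `(k - 1) * dt`.
#' @export
sinusoid <- function(spec, dt, n_steps) {
  stopifnot(inherits(spec, "stimulus_spec"), n_steps > 0)
  t_s <- (seq_len(n_steps) - 1) * dt * 1e-3
  spec$amplitude * sin(2 * pi * spec$frequency * t_s + spec$phase)
}

#' Generate Lorentzian-filtered Gaussian voltage noise
#'
#' White Gaussian innovations are passed through a discrete single-pole
#' low-pass filter with the exact pole `a = exp(-omega_c dt)` (an AR(1)
#' recursion), giving the Lorentzian spectral shape with half-power at
#' `omega_c / 2 pi` Hz. The innovation variance is chosen so the stationary
#' variance of the filtered output is exactly `D`; the filter state starts
#' from the stationary law and a warm-up of five filter time constants is
#' generated and discarded, so the returned series is stationary from the
#' first sample.
#'
#' Uses R's RNG stream: call `set.seed()` for reproducible draws.
#'
#' @param spec a [noise_spec()].
#' @param dt time step, ms.
#' @param n_steps number of samples.
#' @return Numeric vector of voltage noise, mV.
#' @export
lorentzian_noise <- function(spec, dt, n_steps) {
  stopifnot(inherits(spec, "noise_spec"), n_steps > 0, dt > 0,
            spec$omega_c * dt * 1e-3 < 1)
  lorentzian_noise_cpp(as.integer(n_steps), dt, spec$D, spec$omega_c)
}
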