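#' Hodgkin-Huxley membrane parameters
#'
#' Biophysical constants of the squid-axon membrane in the modern resting
#' convention (rest near -65 mV). With the default channel densities of
#' 60 Na/um^2 and 18 K/um^2, single-channel conductances of 20 pS reproduce
#' the macroscopic maxima of 120 and 36 mS/cm^2.
#'
#' @param Cm specific membrane capacitance, uF/cm^2.
#' @param gL leak conductance, mS/cm^2.
#' @param V_Na,V_K,V_L reversal potentials, mV.
#' @param gamma_Na,gamma_K single-channel conductances, pS.
#' @return An object of class `hh_params`.
#' @examples
#' p <- hh_params()
#' p$gamma_Na * 60 / 10   # macroscopic Na maximum, mS/cm^2
#' @export
hh_params <- function(Cm = 1, gL = 0.3, V_Na = 50, V_K = -77, V_L = -54.4,
                      gamma_Na = 20, gamma_K = 20) {
  stopifnot(Cm > 0, gL > 0, gamma_Na > 0, gamma_K > 0)
  structure(list(Cm = Cm, gL = gL, V_Na = V_Na, V_K = V_K, V_L = V_L,
                 gamma_Na = gamma_Na, gamma_K = gamma_K),
            class = "hh_params")
}

#' @export
print.hh_params <- function(x, ...) {
  cat("Hodgkin-Huxley membrane parameters\n")
  cat(sprintf("  Cm = %g uF/cm^2, gL = %g mS/cm^2\n", x$Cm, x$gL))
  cat(sprintf("  V_Na = %g, V_K = %g, V_L = %g mV\n", x$V_Na, x$V_K, x$V_L))
  cat(sprintf("  gamma_Na = %g pS, gamma_K = %g pS\n",
              x$gamma_Na, x$gamma_K))
  invisible(x)
}

#' Membrane patch geometry and channel counts
#'
#' Integer channel counts follow from the patch area and fixed channel
#' densities; patch area is the knob controlling endogenous channel noise
#' (larger patches, more channels, less noise).
#'
#' @param area patch area, um^2.
#' @param density_Na,density_K channel densities, channels/um^2.
#' @return An object of class `membrane_patch` with integer counts
#'   `N_Na = round(area * density_Na)` and `N_K = round(area * density_K)`.
#' @examples
#' membrane_patch(600)  # 36000 Na, 10800 K channels
#' @export
membrane_patch <- function(area, density_Na = 60, density_K = 18) {
  stopifnot(is.numeric(area), length(area) == 1, area > 0,
            density_Na > 0, density_K > 0)
  structure(list(area = area, density_Na = density_Na, density_K = density_K,
                 N_Na = as.integer(round(area * density_Na)),
                 N_K = as.integer(round(area * density_K))),
            class = "membrane_patch")
}

#' @export
print.membrane_patch <- function(x, ...) {
  cat(sprintf("Membrane patch: %g um^2 (N_Na = %d, N_K = %d)\n",
              x$area, x$N_Na, x$N_K))
  invisible(x)
}

#' Voltage-dependent gating rates
#'
#' The six Hodgkin-Huxley transition rates (per ms) at membrane voltage `V`.
#' The removable singularities of the `x/(1 - exp(-x/k))` forms at
#' V = -40 mV (alpha_m) and V = -55 mV (alpha_n) are replaced by their
#' analytic limits.
#'
#' @param V membrane voltage, mV (vectorised).
#' @return A data.frame with columns `alpha_m`, `beta_m`, `alpha_h`,
#'   `beta_h`, `alpha_n`, `beta_n`, one row per voltage.
#' @examples
#' hh_rates(-40)$alpha_m  # exactly 1 by the analytic limit
#' @export
hh_rates <- function(V) {
  if (!all(is.finite(V))) stop("non-finite membrane voltage")
  m <- hh_rates_cpp(as.numeric(V))
  out <- as.data.frame(m)
  names(out) <- c("alpha_m", "beta_m", "alpha_h", "beta_h",
                  "alpha_n", "beta_n")
  out
}

#' Steady-state gating values
#'
#' Equilibrium open probabilities m_inf, h_inf, n_inf and time constants at
#' a clamped voltage.
#'
#' @inheritParams hh_rates
#' @return A data.frame with columns `m_inf`, `h_inf`, `n_inf`, `tau_m`,
#'   `tau_h`, `tau_n` (ms).
#' @export
hh_steady_state <- function(V) {
  r <- hh_rates(V)
  data.frame(
    m_inf = r$alpha_m / (r$alpha_m + r$beta_m),
    h_inf = r$alpha_h / (r$alpha_h + r$beta_h),
    n_inf = r$alpha_n / (r$alpha_n + r$beta_n),
    tau_m = 1 / (r$alpha_m + r$beta_m),
    tau_h = 1 / (r$alpha_h + r$beta_h),
    tau_n = 1 / (r$alpha_n + r$beta_n)
  )
}

#' Deterministic resting potential
#'
#' Voltage at which the steady-state ionic currents balance for a given
#' constant current, found by root bisection of the instantaneous
#' steady-state current.
#'
#' @param hh an [hh_params()] object.
#' @param patch a [membrane_patch()] (sets the macroscopic maximal
#'   conductances via its channel densities).
#' @param I0 constant injected current, uA/cm^2.
#' @param interval search interval, mV.
#' @return The fixed-point voltage, mV.
#' @export
resting_potential <- function(hh = hh_params(), patch = membrane_patch(300),
                              I0 = 0, interval = c(-90, -40)) {
  gbar_na <- hh$gamma_Na * patch$density_Na / 10
  gbar_k <- hh$gamma_K * patch$density_K / 10
  f <- function(V) {
    s <- hh_steady_state(V)
    -gbar_na * s$m_inf^3 * s$h_inf * (V - hh$V_Na) -
      gbar_k * s$n_inf^4 * (V - hh$V_K) - hh$gL * (V - hh$V_L) + I0
  }
  stats::uniroot(f, interval, tol = 1e-10)$root
}
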