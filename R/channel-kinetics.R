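#' Channel ensemble state
#'
#' Integer occupancy counts of the Markov channel states: a 4 x 2 grid for
#' Na (rows = number of activated m-particles 0..3, columns = h-particle
#' inactivated/permissive) and a length-5 vector for K (activated
#' n-particles 0..4). Open channels are `na[4, 2]` and `k[5]`.
#'
#' @param na 4 x 2 integer matrix of Na state counts.
#' @param k length-5 integer vector of K state counts.
#' @return An object of class `channel_state`.
#' @export
channel_state <- function(na, k) {
  na <- matrix(as.integer(na), 4, 2)
  k <- as.integer(k)
  stopifnot(length(k) == 5, all(na >= 0), all(k >= 0))
  structure(list(na = na, k = k), class = "channel_state")
}

#' @export
print.channel_state <- function(x, ...) {
  cat(sprintf("Channel ensemble: %d Na (open %d), %d K (open %d)\n",
              sum(x$na), x$na[4, 2], sum(x$k), x$k[5]))
  invisible(x)
}

#' Number of open channels
#'
#' @param state a [channel_state()].
#' @return Named integer vector with elements `Na` and `K`.
#' @export
open_channels <- function(state) {
  c(Na = state$na[4, 2], K = state$k[5])
}

#' Stationary occupancy probabilities at a clamped voltage
#'
#' Product-binomial law of independent gating particles: Na state (i, j)
#' has probability C(3,i) m^i (1-m)^(3-i) times h^j (1-h)^(1-j); K state i
#' has probability C(4,i) n^i (1-n)^(4-i), with m, h, n at their
#' steady-state values.
#'
#' @param V clamped voltage, mV.
#' @return List with `na` (4 x 2 probability matrix) and `k` (length-5
#'   probability vector).
#' @export
stationary_distribution <- function(V) {
  s <- hh_steady_state(V)
  pm <- stats::dbinom(0:3, 3, s$m_inf)
  ph <- c(1 - s$h_inf, s$h_inf)
  list(na = outer(pm, ph), k = stats::dbinom(0:4, 4, s$n_inf))
}

#' Draw channel states from the clamped stationary law
#'
#' Initialises a channel ensemble at the voltage-clamped equilibrium: counts
#' are multinomial over the product-binomial stationary occupancies. With
#' `deterministic = TRUE` the expected (non-integer) counts are returned
#' instead, which is useful for expected-value (noise-free) channel updates.
#'
#' @param V clamped voltage, mV.
#' @param patch a [membrane_patch()].
#' @param deterministic return expected counts instead of a random draw.
#' @return A [channel_state()] (or a list of numeric expected counts when
#'   `deterministic = TRUE`).
#' @export
steady_state_counts <- function(V, patch, deterministic = FALSE) {
  stopifnot(inherits(patch, "membrane_patch"))
  p <- stationary_distribution(V)
  if (deterministic)
    return(list(na = p$na * patch$N_Na, k = p$k * patch$N_K))
  na <- matrix(stats::rmultinom(1, patch$N_Na, as.vector(p$na)), 4, 2)
  k <- as.vector(stats::rmultinom(1, patch$N_K, p$k))
  channel_state(na, k)
}

#' Advance a channel ensemble by fixed time steps
#'
#' Stochastic channel-state tracking: for each occupied Markov state the
#' channels taking each outgoing transition within `dt` are drawn jointly
#' from a multinomial over `(rate * dt, ..., stay)`, and all states are
#' updated from a snapshot, so channel counts are conserved and can never go
#' negative. Transition probabilities are clamped (with a warning) in the
#' pathological case where their sum reaches 1; at dt = 0.01 ms this does
#' not occur at physiological voltages.
#'
#' @param state a [channel_state()].
#' @param V gating voltage, mV (the total voltage seen by the channels).
#' @param dt time step, ms.
#' @param n_steps number of steps to take.
#' @return The updated [channel_state()].
#' @export
ensemble_step <- function(state, V, dt, n_steps = 1L) {
  stopifnot(inherits(state, "channel_state"), is.finite(V), dt > 0)
  res <- ensemble_step_cpp(state$na, state$k, V, dt, as.integer(n_steps))
  if (res$clamped > 0)
    warning(sprintf("transition probabilities clamped in %d state-updates",
                    res$clamped))
  channel_state(res$na, res$k)
}

#' Voltage-clamped ensemble time course
#'
#' Runs the stochastic ensemble at a fixed voltage and returns the
#' open-channel counts at every step, for occupancy statistics.
#'
#' @inheritParams ensemble_step
#' @return List with integer vectors `open_na`, `open_k` (per step), and the
#'   final [channel_state()] as `state`.
#' @export
ensemble_clamp <- function(state, V, dt, n_steps) {
  stopifnot(inherits(state, "channel_state"))
  res <- ensemble_clamp_cpp(state$na, state$k, V, dt, as.integer(n_steps))
  list(open_na = res$open_na, open_k = res$open_k,
       state = channel_state(res$na, res$k))
}

#' Expected-value master-equation step
#'
#' Forward-Euler step of the 13-state master equation on fractional
#' occupancies: the deterministic limit of [ensemble_step()] in which every
#' multinomial draw is replaced by its mean.
#'
#' @param na 4 x 2 numeric matrix of (fractional) Na occupancies.
#' @param k length-5 numeric vector of K occupancies.
#' @inheritParams ensemble_step
#' @return List with updated numeric `na` and `k`.
#' @export
master_equation_step <- function(na, k, V, dt, n_steps = 1L) {
  master_equation_step_cpp(matrix(as.numeric(na), 4, 2), as.numeric(k),
                           V, dt, as.integer(n_steps))
}
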