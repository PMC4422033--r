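# Independent oracles for the stochastic channel kinetics and spectra.

# Exact event-driven (Gillespie) simulation of the 5-state K chain at a
# clamped voltage: continuous-time Markov chain on the occupancy counts,
# independent of the fixed-step multinomial scheme it cross-checks.
# Returns the time-weighted mean and variance of the open-channel count.
gillespie_k_clamp <- function(counts, V, t_max_ms) {
  r <- neuronsr::hh_rates(V)
  an <- r$alpha_n
  bn <- r$beta_n
  t <- 0
  acc1 <- 0
  acc2 <- 0
  while (t < t_max_ms) {
    rates_up <- (4:1) * an * counts[1:4]
    rates_dn <- (1:4) * bn * counts[2:5]
    rates <- c(rates_up, rates_dn)
    rtot <- sum(rates)
    dt <- stats::rexp(1, rtot)
    dt_eff <- min(dt, t_max_ms - t)
    acc1 <- acc1 + counts[5] * dt_eff
    acc2 <- acc2 + counts[5]^2 * dt_eff
    t <- t + dt
    if (t >= t_max_ms) break
    k <- sample.int(8, 1, prob = rates)
    if (k <= 4) {
      counts[k] <- counts[k] - 1
      counts[k + 1] <- counts[k + 1] + 1
    } else {
      counts[k - 3] <- counts[k - 3] - 1
      counts[k - 4] <- counts[k - 4] + 1
    }
  }
  c(mean = acc1 / t_max_ms, var = acc2 / t_max_ms - (acc1 / t_max_ms)^2)
}

# Same for the 8-state Na chain; returns time-weighted mean open count.
gillespie_na_clamp <- function(na, V, t_max_ms) {
  r <- neuronsr::hh_rates(V)
  t <- 0
  acc <- 0
  # transitions: list of (from_i, from_j, to_i, to_j, rate per channel)
  trans <- list()
  for (j in 1:2) for (i in 1:4) {
    if (i < 4) trans[[length(trans) + 1]] <- c(i, j, i + 1, j, (4 - i) * r$alpha_m)
    if (i > 1) trans[[length(trans) + 1]] <- c(i, j, i - 1, j, (i - 1) * r$beta_m)
    trans[[length(trans) + 1]] <-
      c(i, j, i, 3 - j, if (j == 1) r$alpha_h else r$beta_h)
  }
  tm <- do.call(rbind, trans)
  while (t < t_max_ms) {
    rates <- tm[, 5] * na[cbind(tm[, 1], tm[, 2])]
    rtot <- sum(rates)
    dt <- stats::rexp(1, rtot)
    acc <- acc + na[4, 2] * min(dt, t_max_ms - t)
    t <- t + dt
    if (t >= t_max_ms) break
    k <- sample.int(nrow(tm), 1, prob = rates)
    na[tm[k, 1], tm[k, 2]] <- na[tm[k, 1], tm[k, 2]] - 1
    na[tm[k, 3], tm[k, 4]] <- na[tm[k, 3], tm[k, 4]] + 1
  }
  acc / t_max_ms
}

# Time-domain mean power of a pulse train (Parseval oracle).
time_domain_power <- function(u) mean(u$samples^2)

# Frozen steady-state gating values at -65 mV, evaluated directly from the
# published rate formulas (independent of the package's C++ path).
hh_inf_oracle <- function(V) {
  am <- 0.1 * (V + 40) / (1 - exp(-(V + 40) / 10))
  bm <- 4 * exp(-(V + 65) / 18)
  ah <- 0.07 * exp(-(V + 65) / 20)
  bh <- 1 / (1 + exp(-(V + 35) / 10))
  an <- 0.01 * (V + 55) / (1 - exp(-(V + 55) / 10))
  bn <- 0.125 * exp(-(V + 65) / 80)
  c(m = am / (am + bm), h = ah / (ah + bh), n = an / (an + bn))
}
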