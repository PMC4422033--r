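test_that("gating rates match the squid-axon formulas and their limits", {
  r <- hh_rates(-65)
  expect_true(all(unlist(r) >= 0))
  inf <- hh_steady_state(-65)
  # frozen values computed from the published rate equations
  expect_equal(inf$n_inf, 0.3176769, tolerance = 1e-6)
  expect_equal(inf$m_inf, 0.0529325, tolerance = 1e-6)
  expect_equal(inf$h_inf, 0.5961208, tolerance = 1e-6)
  expect_equal(unname(hh_inf_oracle(-72)["n"]), hh_steady_state(-72)$n_inf)
  # removable singularities handled by the analytic limit
  expect_equal(hh_rates(-40)$alpha_m, 1.0, tolerance = 1e-9)
  expect_equal(hh_rates(-55)$alpha_n, 0.1, tolerance = 1e-9)
  expect_false(any(vapply(hh_rates(seq(-120, 60, by = 0.5)), function(x)
    any(!is.finite(x) | x < 0), logical(1))))
  expect_error(hh_rates(NaN), "non-finite")
})

test_that("patch channel counts follow area times density", {
  p <- membrane_patch(600)
  expect_identical(p$N_Na, 36000L)
  expect_identical(p$N_K, 10800L)
  expect_identical(membrane_patch(200)$N_Na, 12000L)
  expect_identical(membrane_patch(300)$N_Na, 18000L)
  # single-channel conductances recover the macroscopic maxima
  hh <- hh_params()
  expect_equal(hh$gamma_Na * p$density_Na / 10, 120)
  expect_equal(hh$gamma_K * p$density_K / 10, 36)
})

test_that("stationary draws conserve totals and match binomial expectations", {
  patch <- membrane_patch(600)
  set.seed(7)
  st <- steady_state_counts(-65, patch)
  expect_identical(sum(st$na), patch$N_Na)
  expect_identical(sum(st$k), patch$N_K)
  # expected open fraction m_inf^3 h_inf ~ 8.8e-5 -> ~3.2 channels of 36000
  inf <- hh_steady_state(-65)
  det <- steady_state_counts(-65, patch, deterministic = TRUE)
  expect_equal(det$na[4, 2], patch$N_Na * inf$m_inf^3 * inf$h_inf)
  expect_equal(det$na[4, 2], 3.168, tolerance = 0.01)
  expect_equal(det$k[5], patch$N_K * inf$n_inf^4)
  expect_equal(sum(det$na), patch$N_Na)
})

test_that("ensemble updates conserve channel counts over many steps", {
  patch <- membrane_patch(200)
  set.seed(11)
  st <- steady_state_counts(-65, patch)
  # 1e6 state updates at assorted voltages
  for (V in c(-80, -65, -40, 0, 40)) {
    st <- ensemble_step(st, V, dt = 0.01, n_steps = 2e5)
    expect_identical(sum(st$na), patch$N_Na)
    expect_identical(sum(st$k), patch$N_K)
    expect_true(all(st$na >= 0) && all(st$k >= 0))
  }
})

test_that("clamped occupancies relax to the product-binomial law", {
  set.seed(23)
  inf <- hh_steady_state(-65)
  p_open <- inf$n_inf^4
  N <- 50
  # start all channels fully open (far from equilibrium), relax ~11 tau_n,
  # record the final open count over independent replicates
  finals <- replicate(400, {
    st <- channel_state(matrix(c(0, 0, 0, 0, 0, 0, 0, 50), 4, 2),
                        c(0, 0, 0, 0, N))
    ensemble_step(st, -65, dt = 0.01, n_steps = 6000)$k[5]
  })
  # chi-square goodness of fit against Binom(N, n_inf^4), pooled tail
  breaks <- c(-0.5, 0.5, 1.5, 2.5, N)
  obs <- table(cut(finals, breaks))
  pr <- c(dbinom(0:2, N, p_open), 1 - pbinom(2, N, p_open))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = pr))
  expect_gt(gof$p.value, 0.01)
  # long-run time average matches n_inf^4 (N_K = 5400 patch)
  st <- steady_state_counts(-65, membrane_patch(300))
  cl <- ensemble_clamp(st, -65, dt = 0.01, n_steps = 5e4)
  frac <- mean(cl$open_k) / 5400
  expect_equal(frac, p_open, tolerance = 0.15)
})

test_that("fixed-step ensembles agree with an exact Gillespie oracle", {
  set.seed(31)
  N <- 50
  inf <- hh_steady_state(-65)
  # K chain: mean open count, both schemes, vs binomial truth
  st0 <- as.vector(rmultinom(1, N, dbinom(0:4, 4, inf$n_inf)))
  g <- gillespie_k_clamp(st0, -65, t_max_ms = 3e4)
  na_idle <- matrix(0L, 4, 2)
  na_idle[1, 1] <- N
  st <- channel_state(na_idle, st0)
  cl <- ensemble_clamp(st, -65, dt = 0.01, n_steps = 3e6)
  mu_true <- N * inf$n_inf^4
  var_true <- N * inf$n_inf^4 * (1 - inf$n_inf^4)
  # ~3 SE bands using the binomial variance and effective sample sizes
  tau_ms <- 5.5 # slowest n-gate time constant at -65 mV
  se <- sqrt(var_true / (3e4 / (2 * tau_ms)))
  expect_lt(abs(g["mean"] - mu_true), 3 * se)
  expect_lt(abs(mean(cl$open_k) - mu_true), 3 * se)
  expect_lt(abs(g["mean"] - mean(cl$open_k)), 4.5 * se)
  expect_equal(unname(g["var"]), var_true, tolerance = 0.35)
  expect_equal(var(cl$open_k), var_true, tolerance = 0.35)
  # Na chain: open fraction m_inf^3 h_inf is tiny at rest; clamp at -40 mV
  # (smaller ensemble and record keep the event-driven oracle affordable)
  Nna <- 20
  inf40 <- hh_steady_state(-40)
  p_na <- inf40$m_inf^3 * inf40$h_inf
  na0 <- matrix(rmultinom(1, Nna,
                          as.vector(outer(dbinom(0:3, 3, inf40$m_inf),
                                          c(1 - inf40$h_inf,
                                            inf40$h_inf)))), 4, 2)
  gna <- gillespie_na_clamp(na0, -40, t_max_ms = 3e3)
  stna <- channel_state(na0, c(Nna, 0, 0, 0, 0))
  clna <- ensemble_clamp(stna, -40, dt = 0.01, n_steps = 3e5)
  se_na <- sqrt(Nna * p_na * (1 - p_na) / (3e3 / (2 * 8.5)))
  expect_lt(abs(gna - Nna * p_na), 3 * se_na)
  expect_lt(abs(mean(clna$open_na) - Nna * p_na), 3 * se_na)
})

test_that("expected-value update equals the master-equation Euler step", {
  inf <- hh_steady_state(-65)
  p <- stationary_distribution(-50)
  na <- p$na * 100
  k <- p$k * 100
  dt <- 0.01
  one <- master_equation_step(na, k, -50, dt)
  # hand-rolled one-step Euler of the 13-state master equation
  r <- hh_rates(-50)
  dna <- matrix(0, 4, 2)
  for (j in 1:2) for (i in 1:4) {
    out <- 0
    if (i < 4) { f <- na[i, j] * (4 - i) * r$alpha_m * dt
                 dna[i + 1, j] <- dna[i + 1, j] + f; out <- out + f }
    if (i > 1) { f <- na[i, j] * (i - 1) * r$beta_m * dt
                 dna[i - 1, j] <- dna[i - 1, j] + f; out <- out + f }
    fh <- na[i, j] * (if (j == 1) r$alpha_h else r$beta_h) * dt
    dna[i, 3 - j] <- dna[i, 3 - j] + fh
    dna[i, j] <- dna[i, j] - out - fh
  }
  expect_equal(one$na, na + dna, tolerance = 1e-12)
  expect_equal(sum(one$na), 100, tolerance = 1e-9)
  expect_equal(sum(one$k), 100, tolerance = 1e-9)
  # stationarity: the stationary law is a fixed point of the expected update
  pst <- stationary_distribution(-50)
  fix <- master_equation_step(pst$na, pst$k, -50, 0.01, n_steps = 1000)
  expect_equal(fix$na, pst$na, tolerance = 1e-8)
  expect_equal(fix$k, pst$k, tolerance = 1e-8)
})

test_that("master-equation open fractions track the m^3 h / n^4 ODEs", {
  # voltage step from rest to -30 mV: expected-value channel update vs the
  # classical gating ODEs, both forward Euler at the same dt
  V <- -30
  dt <- 0.01
  n_steps <- 2000
  p0 <- stationary_distribution(-65)
  me <- list(na = p0$na, k = p0$k)
  inf0 <- hh_steady_state(-65)
  m <- inf0$m_inf; h <- inf0$h_inf; nn <- inf0$n_inf
  r <- hh_rates(V)
  for (s in seq_len(n_steps)) {
    me <- master_equation_step(me$na, me$k, V, dt)
    m <- m + (r$alpha_m * (1 - m) - r$beta_m * m) * dt
    h <- h + (r$alpha_h * (1 - h) - r$beta_h * h) * dt
    nn <- nn + (r$alpha_n * (1 - nn) - r$beta_n * nn) * dt
  }
  expect_equal(me$na[4, 2], m^3 * h, tolerance = 1e-6)
  expect_equal(me$k[5], nn^4, tolerance = 1e-6)
})
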