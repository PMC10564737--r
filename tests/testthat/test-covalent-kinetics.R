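mn551_params <- function(kon_I = 1e5, E_total = 100e-9, P_total = 10e-9,
                         k_inact = 2.1e-4, K_I = 3.6e-6) {
  # rapid-equilibrium rate constants consistent with the macroscopic
  # steady-state K_I = (koff_I + k_inact) / kon_I
  mechanism_params(kon_P = 1e7, koff_P = 77.56e-9 * 1e7,
                   kon_I = kon_I, koff_I = K_I * kon_I - k_inact,
                   k_inact = k_inact, E_total = E_total, P_total = P_total)
}

test_that("mechanism simulation conserves mass at integrator precision", {
  set.seed(5)
  for (i in 1:4) {
    p <- mechanism_params(kon_P = 10^runif(1, 5, 7),
                          koff_P = 10^runif(1, -3, -1),
                          kon_I = 10^runif(1, 3, 5),
                          koff_I = 10^runif(1, -4, -2),
                          k_inact = 10^runif(1, -5, -3),
                          E_total = 10^runif(1, -8, -6),
                          P_total = 10e-9)
    s <- simulate_mechanism(p, seq(10, 5000, length.out = 25),
                            I_total = 10^runif(1, -6, -4))
    expect_lt(max(attr(s, "conservation")), 1e-8)
  }
})

test_that("simulation limits: no competitor, reversible equilibrium, sink", {
  p0 <- mn551_params(k_inact = 0)

  # no inhibitor: bound probe stays at the two-species equilibrium
  s <- simulate_mechanism(p0, seq(10, 2000, length.out = 10), I_total = 0)
  eq2 <- p0$P_total * probe_bound_fraction(p0$E_total, p0$P_total, p0$K_L)
  expect_true(all(abs(s$EP - eq2) / eq2 < 1e-7))

  # k_inact = 0: long-time observable equals the brute-force competitive
  # equilibrium from the independent oracle
  I <- 5e-6
  s <- simulate_mechanism(p0, c(1e5, 2e5), I_total = I)
  orc <- oracle_equilibrium(p0$E_total, p0$P_total, I, p0$K_L, p0$K_i)
  expect_equal(utils::tail(s$fb, 1), orc$fb, tolerance = 1e-6)
  # and the package's own closed form agrees with the oracle
  expect_equal(competitive_equilibrium(p0$E_total, p0$P_total, I,
                                       p0$K_L, p0$K_i)$fb,
               orc$fb, tolerance = 1e-6)

  # irreversible sink: with excess inhibitor the probe is fully displaced
  p1 <- mn551_params(k_inact = 5e-3)
  s <- simulate_mechanism(p1, c(1e5, 5e5), I_total = 100e-6)
  expect_lt(utils::tail(s$fb, 1), 1e-4)
})

test_that("linearization arithmetic, flat input, and exponential recovery", {
  # pure line: k_obs is -slope / intercept (raw, uncorrected estimate)
  tt <- seq(0, 3000, by = 250)
  lin <- linearize_timecourse(tt, 0.5 - 1.0e-5 * tt, correct = FALSE)
  expect_equal(lin$k_obs, 2.0e-5, tolerance = 1e-9)
  expect_equal(lin$F_b0, 0.5, tolerance = 1e-9)

  # flat time course
  lin <- linearize_timecourse(tt, rep(0.4, length(tt)))
  expect_equal(lin$k_obs, 0)

  # exponential decay sampled within t <= 0.2 / k
  tt <- seq(0, 2000, by = 150)
  lin <- linearize_timecourse(tt, 0.6 * exp(-1e-4 * tt))
  expect_lt(abs(lin$k_obs - 1e-4) / 1e-4, 0.05)
  expect_equal(lin$F_b0, 0.6, tolerance = 1e-6)
  # the uncorrected ratio under-reads the first-order rate
  expect_lt(lin$k_obs_raw, 1e-4)

  expect_error(linearize_timecourse(c(0, 10, 20), c(1, 0.9, 0.8)),
               "at least 4")
})

test_that("saturation fit recovers exact parameters and their ratio", {
  k_inact <- 2.1e-4; K_I <- 3.6e-6
  conc <- c(K_I / 4, K_I / 2, K_I, 2 * K_I, 4 * K_I, 10 * K_I, 20 * K_I)
  fit <- fit_kinact_KI(conc, k_inact * conc / (K_I + conc))
  expect_equal(fit$k_inact, k_inact, tolerance = 1e-6)
  expect_equal(fit$K_I, K_I, tolerance = 1e-6)
  expect_equal(fit$efficiency, fit$k_inact / fit$K_I, tolerance = 1e-9)
  expect_identical(fit$regime, "saturation")

  # concentrations far below K_I: warn and point to the linear regime
  low <- conc / 1e3
  expect_warning(fit_kinact_KI(low, k_inact * low / (K_I + low)),
                 "linear")
})

test_that("linear-regime efficiency: exact line, truncation bias, errors", {
  eff <- 58 + 1 / 3
  conc <- seq(2e-8, 5e-7, length.out = 6)
  fit <- fit_efficiency_linear(conc, eff * conc)
  expect_equal(fit$efficiency, eff, tolerance = 1e-9)
  expect_identical(fit$regime, "linear")

  # Eq.-2 data truncated at 0.1 and 0.2 of K_I: the through-origin slope
  # under-reads k_inact/K_I by roughly max([I])/(2 K_I) (oracle-derived)
  k_inact <- 2.1e-4; K_I <- 3.6e-6
  for (cap in c(0.1, 0.2)) {
    cc <- cap * K_I / 1.4^(0:7)
    sl <- suppressWarnings(
      fit_efficiency_linear(cc, k_inact * cc / (K_I + cc), K_I = K_I)
    )$efficiency
    expect_lt(sl, k_inact / K_I)
    expect_lt(abs(sl - k_inact / K_I) / (k_inact / K_I),
              if (cap == 0.1) 0.10 else 0.15)
  }
  expect_warning(
    fit_efficiency_linear(c(2e-6, 3e-6), c(1e-4, 1.2e-4), K_I = K_I),
    "regime"
  )
  expect_error(fit_efficiency_linear(numeric(0), numeric(0)), "empty")
})

test_that("both regimes agree on the efficiency from shared ground truth", {
  k_inact <- 2.1e-4; K_I <- 3.6e-6
  sat_conc <- K_I * c(0.5, 1, 2, 4, 8, 16)
  sat <- fit_kinact_KI(sat_conc, k_inact * sat_conc / (K_I + sat_conc))
  lin_conc <- 0.1 * K_I / 1.4^(0:6)
  lin <- fit_efficiency_linear(lin_conc,
                               k_inact * lin_conc / (K_I + lin_conc))
  expect_lt(abs(sat$efficiency - lin$efficiency) / sat$efficiency, 0.10)
})

test_that("pipeline over the simulated mechanism recovers the rate law", {
  # low enzyme relative to K_L so the probe reports free enzyme faithfully
  p <- mn551_params(E_total = 5e-9, P_total = 1e-9)
  conc <- c(5e-7, 1e-6, 2e-6, 4e-6, 8e-6, 1.6e-5, 3.2e-5)  # all >= 10 E_t
  tt <- seq(30, 1800, by = 90)
  kobs <- vapply(conc, function(I) {
    s <- simulate_mechanism(p, tt, I_total = I)
    linearize_timecourse(s$time, s$fb)$k_obs
  }, 0)
  fit <- suppressWarnings(fit_kinact_KI(conc, kobs))
  expect_lt(abs(fit$k_inact - p$k_inact) / p$k_inact, 0.15)
  expect_lt(abs(fit$K_I - 3.6e-6) / 3.6e-6, 0.15)
})

test_that("K_i at time zero is recovered from reversible-only intercepts", {
  g <- generate(generator_spec("covalent_fp", noise = 0, seed = 3))
  cal <- default_calib()
  fit <- fit_covalent_fp(g$data, calib = cal, L_total = 10e-9,
                         K_L = 77.56e-9, P_total = 100e-9)
  expect_lt(abs(fit$Ki_t0 - 1.1e-6) / 1.1e-6, 0.15)
  expect_lte(fit$Ki_t0, fit$IC50_t0)

  # no inhibitor effect at any concentration
  conc <- 50e-6 / 2^(0:7)
  expect_error(ki_at_t0(conc, rep(0.55, 8), L_total = 10e-9,
                        K_L = 77.56e-9, P_total = 100e-9),
               "no competition signal")
})

test_that("modification kinetics: identity, noisy recovery, monotonicity", {
  k <- log(20) / 7200
  tt <- seq(0, 7200, by = 600)
  fit <- fit_modification_timecourse(tt, 1 - exp(-k * tt))
  expect_equal(fit$k, k, tolerance = 1e-9)
  expect_equal(fit$t95, 7200, tolerance = 1e-9)
  expect_equal(fit$t95 * fit$k, log(20), tolerance = 1e-12)

  g <- generate(generator_spec("modification_ms", seed = 9))
  fit <- fit_modification_timecourse(g$data$time_s, g$data$response)
  expect_lt(abs(fit$k - k) / k, 0.10)

  expect_warning(
    fit_modification_timecourse(c(0, 600, 1200, 1800, 2400),
                                c(0, 0.5, 0.8, 0.4, 0.9)),
    "decreases"
  )
})
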