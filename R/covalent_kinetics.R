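# Covalent inhibition kinetics: mass-action mechanism simulation,
# time-course linearization to k_obs, saturation fit for k_inact and K_I,
# linear-regime covalent efficiency, reversible K_i at time zero, and
# pseudo-first-order modification kinetics.

#' Mass-action parameters of the two-step covalent mechanism
#'
#' The mechanism is competitive probe displacement with irreversible
#' inactivation from the reversible inhibitor complex:
#' `E + P <-> EP` (probe, `K_L = koff_P / kon_P`),
#' `E + I <-> EI` (inhibitor, `K_i = koff_I / kon_I`),
#' `EI -> E-I` (covalent, rate `k_inact`).
#'
#' @param kon_P,koff_P probe association (M^-1 s^-1) and dissociation (s^-1)
#'   rate constants.
#' @param kon_I,koff_I inhibitor rate constants, same units.
#' @param k_inact maximal inactivation rate from the reversible complex,
#'   s^-1.
#' @param E_total,P_total total protein and probe concentrations, molar.
#' @return object of class `mechanism_params`, carrying the derived `K_L`
#'   and `K_i`.
#' @export
mechanism_params <- function(kon_P, koff_P, kon_I, koff_I, k_inact,
                             E_total, P_total) {
  for (nm in c("kon_P", "koff_P", "kon_I", "koff_I", "k_inact")) {
    .assert_num(get(nm), nm, nonneg = TRUE, len = 1)
  }
  .assert_num(E_total, "E_total", positive = TRUE, len = 1)
  .assert_num(P_total, "P_total", positive = TRUE, len = 1)
  structure(list(
    kon_P = kon_P, koff_P = koff_P, kon_I = kon_I, koff_I = koff_I,
    k_inact = k_inact, E_total = E_total, P_total = P_total,
    K_L = koff_P / kon_P,
    K_i = if (kon_I > 0) koff_I / kon_I else Inf
  ), class = "mechanism_params")
}

#' Closed-form competitive three-species equilibrium
#'
#' Solves the reversible equilibrium of protein `E` with probe `P`
#' (dissociation constant `K_L`) and inhibitor `I` (dissociation constant
#' `K_i`) under exact mass balance, by a bracketed root solve for free
#' protein.
#'
#' @param E_total,P_total,I_total total concentrations, molar.
#' @param K_L,K_i dissociation constants, molar.
#' @return list with free concentrations `E`, `P`, `I`, complexes `EP`,
#'   `EI`, and `fb` (bound probe fraction `EP / P_total`).
#' @export
competitive_equilibrium <- function(E_total, P_total, I_total, K_L, K_i) {
  .assert_num(E_total, "E_total", positive = TRUE, len = 1)
  .assert_num(P_total, "P_total", positive = TRUE, len = 1)
  .assert_num(I_total, "I_total", nonneg = TRUE, len = 1)
  .assert_num(K_L, "K_L", positive = TRUE, len = 1)
  .assert_num(K_i, "K_i", positive = TRUE, len = 1)
  f <- function(E) {
    E * (1 + P_total / (K_L + E) + I_total / (K_i + E)) - E_total
  }
  E <- stats::uniroot(f, c(0, E_total), tol = .Machine$double.eps^0.75)$root
  EP <- E * P_total / (K_L + E)
  EI <- E * I_total / (K_i + E)
  list(E = E, P = P_total - EP, I = I_total - EI, EP = EP, EI = EI,
       fb = EP / P_total)
}

#' Simulate the covalent displacement mechanism
#'
#' Integrates the mass-action system
#' `d[EP]/dt = kon_P*E*P - koff_P*EP`,
#' `d[EI]/dt = kon_I*E*I - (koff_I + k_inact)*EI`,
#' `d[E-I]/dt = k_inact*EI`
#' with a stiff-capable adaptive integrator. By default the probe-protein
#' pair starts at its two-species equilibrium (probe and protein are
#' pre-incubated; the inhibitor is added at `t = 0`).
#'
#' @param params a [mechanism_params()].
#' @param times increasing time grid, seconds.
#' @param I_total total inhibitor concentration, molar.
#' @param preequilibrate start probe binding at equilibrium (default TRUE).
#' @param rtol relative integrator tolerance (default 1e-8).
#' @return data frame with time, species concentrations (`E`, `P`, `EP`,
#'   `I`, `EI`, `EIx` for the covalent adduct), and the observable `fb =
#'   EP / P_total`. Mass-conservation residuals are checked against the
#'   integrator tolerance and attached as attribute `conservation`.
#' @export
simulate_mechanism <- function(params, times, I_total,
                               preequilibrate = TRUE, rtol = 1e-8) {
  stopifnot(inherits(params, "mechanism_params"))
  .assert_num(times, "times", nonneg = TRUE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  .assert_num(I_total, "I_total", nonneg = TRUE, len = 1)

  EP0 <- if (preequilibrate) {
    params$P_total *
      probe_bound_fraction(params$E_total, params$P_total, params$K_L)
  } else 0
  y0 <- c(E = params$E_total - EP0, P = params$P_total - EP0, EP = EP0,
          I = I_total, EI = 0, EIx = 0)
  deriv <- function(t, y, p) {
    vP <- p$kon_P * y["E"] * y["P"] - p$koff_P * y["EP"]
    vI <- p$kon_I * y["E"] * y["I"] - p$koff_I * y["EI"]
    vX <- p$k_inact * y["EI"]
    list(c(E = -vP - vI, P = -vP, EP = vP,
           I = -vI, EI = vI - vX, EIx = vX))
  }
  grid <- times
  if (grid[1] > 0) grid <- c(0, grid)
  sol <- deSolve::lsoda(y0, grid, deriv, params, rtol = rtol,
                        atol = rtol * max(params$E_total, params$P_total))
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE integration failed; istate = ", attr(sol, "istate")[1])
  }
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  out <- out[out$time %in% times, , drop = FALSE]
  rownames(out) <- NULL
  out$fb <- out$EP / params$P_total

  consE <- max(abs(out$E + out$EP + out$EI + out$EIx - params$E_total)) /
    params$E_total
  consP <- max(abs(out$P + out$EP - params$P_total)) / params$P_total
  consI <- if (I_total > 0) {
    max(abs(out$I + out$EI + out$EIx - I_total)) / I_total
  } else 0
  attr(out, "conservation") <- c(E = consE, P = consP, I = consI)
  out
}

#' Linearize an FP displacement time course to F_b0 and k_obs
#'
#' Ordinary least squares on the early, approximately linear window of a
#' bound-fraction decay. The window keeps points with `F_b >= retain *
#' F_b0` (default 30% decay at most, where first-order decay is within a
#' few percent of linear), with at least `min_points` points. The observed
#' rate is `k_obs = -slope / F_b0`; slopes of the wrong (positive) sign
#' beyond noise yield `k_obs = 0` with a flag.
#'
#' Because the underlying decay is first order, the raw slope/intercept
#' ratio of a straight line fitted over a finite window underestimates the
#' rate by about half the fractional decay spanned (about 15% at a 30%
#' window). The returned `k_obs` and `F_b0` therefore include a
#' self-consistency correction: the rate is the value for which an exact
#' first-order decay, sampled on the same window and fitted by the same
#' OLS, reproduces the observed slope/intercept ratio. The uncorrected
#' values are reported alongside (`k_obs_raw`, `F_b0_raw`). Set
#' `correct = FALSE` to use the plain linear estimates throughout.
#'
#' @param times seconds, strictly increasing, length >= 4.
#' @param values bound fractions (or anisotropies if `calib` is given).
#' @param calib optional [anisotropy_calibration()] used to convert
#'   anisotropy input to bound fraction.
#' @param retain fraction of the initial bound fraction defining the linear
#'   window (default 0.7).
#' @param min_points minimum number of points in the fit window.
#' @param correct apply the first-order window correction (default TRUE).
#' @return object of class `linearization` with `F_b0`, `slope`, `k_obs`,
#'   `k_obs_raw`, `F_b0_raw`, `window` (indices used), `standard_errors`,
#'   and `flags`.
#' @export
linearize_timecourse <- function(times, values, calib = NULL, retain = 0.7,
                                 min_points = 4, correct = TRUE) {
  .assert_num(times, "times", nonneg = TRUE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  if (length(times) < 4 || length(values) != length(times)) {
    stop("need at least 4 usable time points with matching values")
  }
  fb <- if (is.null(calib)) values else {
    suppressWarnings(as.numeric(bound_fraction(values, calib)))
  }
  flags <- character(0)

  # provisional intercept from the first few points, then window selection
  head_n <- min(max(min_points, 4), length(fb))
  fit0 <- stats::lm(fb[seq_len(head_n)] ~ times[seq_len(head_n)])
  F0 <- unname(stats::coef(fit0)[1])
  if (!is.finite(F0) || F0 <= 0) F0 <- fb[1]
  keep <- which(fb >= retain * F0)
  keep <- union(keep, seq_len(min(min_points, length(fb))))
  keep <- sort(keep)
  # restrict to the leading contiguous block so late rebounds are ignored
  brk <- which(diff(keep) > 1)
  if (length(brk)) keep <- keep[seq_len(brk[1])]
  if (length(keep) < min_points) keep <- seq_len(min_points)

  fit <- stats::lm(fb[keep] ~ times[keep])
  # summary.lm complains about zero residual variance on noiseless input
  co <- suppressWarnings(summary(fit)$coefficients)
  F_b0 <- co[1, 1]
  slope <- co[2, 1]
  se_slope <- co[2, 2]
  if (F_b0 <= 0) stop("non-positive intercept: no bound probe at t = 0")

  k_raw <- -slope / F_b0
  if (k_raw < 0) {
    if (slope > 2 * se_slope) {
      flags <- c(flags, "positive_slope")
      warning("time course increases beyond noise; k_obs set to 0")
    }
    k_raw <- 0
  }
  k_obs <- k_raw
  F_out <- F_b0
  # the correction is meaningful only when the window sees real decay
  decay_span <- k_raw * diff(range(times[keep]))
  if (correct && k_raw > 0 && decay_span > 1e-8) {
    cw <- .window_correction(times[keep], k_raw)
    k_obs <- cw$k
    F_out <- F_b0 / cw$intercept_shrink
  }
  structure(list(
    F_b0 = unname(F_out), slope = unname(slope), k_obs = unname(k_obs),
    F_b0_raw = unname(F_b0), k_obs_raw = unname(k_raw),
    window = keep,
    standard_errors = c(F_b0 = co[1, 2], slope = se_slope,
                        k_obs = abs(se_slope / F_b0)),
    flags = flags
  ), class = "linearization")
}

# OLS slope/intercept ratio of a unit-amplitude first-order decay sampled
# at `tt`, as a function of the rate; used to invert the finite-window
# bias of the linear estimator.
.ols_ratio <- function(tt, k) {
  y <- exp(-k * tt)
  sl <- stats::cov(tt, y) / stats::var(tt)
  ic <- mean(y) - sl * mean(tt)
  list(ratio = -sl / ic, intercept = ic)
}

.window_correction <- function(tt, k_raw) {
  f <- function(k) .ols_ratio(tt, k)$ratio - k_raw
  # the OLS ratio under-reads the rate, so the root lies at or above k_raw
  upper <- k_raw
  for (i in 1:60) {
    upper <- upper * 1.5
    if (f(upper) >= 0) break
  }
  if (f(upper) < 0) {
    # observed ratio beyond what any first-order decay on this window can
    # produce (heavy noise); keep the raw estimate
    return(list(k = k_raw, intercept_shrink = 1))
  }
  k <- stats::uniroot(f, c(k_raw, upper), tol = k_raw * 1e-10)$root
  list(k = k, intercept_shrink = .ols_ratio(tt, k)$intercept)
}

#' Fit k_inact and K_I from k_obs across inhibitor concentrations
#'
#' Nonlinear least squares of the saturation relation
#' `k_obs = k_inact * [I] / (K_I + [I])`: `k_inact` is the maximal
#' inactivation rate and `K_I` the inhibitor concentration at which
#' `k_obs = k_inact / 2`. The covalent efficiency `k_inact / K_I` is
#' reported with its uncertainty propagated by the delta method.
#'
#' @param conc inhibitor concentrations, molar, length >= 5.
#' @param k_obs observed first-order rates, s^-1, same length.
#' @param se optional standard errors of the `k_obs` estimates; when
#'   supplied the fit is precision-weighted (`1/se^2`). In a competitive
#'   displacement assay the high-concentration rates are estimated from an
#'   almost fully displaced probe and carry little information, so
#'   weighting materially stabilizes `K_I`.
#' @param per_concentration optional list of [linearize_timecourse()]
#'   results carried through to the output.
#' @return object of class `covalent_fit` with `k_inact`, `K_I`,
#'   `efficiency` (M^-1 s^-1), `regime = "saturation"`, `standard_errors`,
#'   and `flags`.
#' @export
fit_kinact_KI <- function(conc, k_obs, se = NULL, per_concentration = NULL) {
  .assert_num(conc, "conc", positive = TRUE)
  .assert_num(k_obs, "k_obs", nonneg = TRUE)
  if (length(conc) < 5 || length(k_obs) != length(conc)) {
    stop("need k_obs at >= 5 inhibitor concentrations")
  }
  d <- .average_ties(conc, k_obs)
  if (!is.null(se)) {
    stopifnot(length(se) == length(conc))
    w <- 1 / .average_ties(conc, se)$y^2
    w[!is.finite(w)] <- max(w[is.finite(w)], 1)
    d$w <- w / mean(w)
  } else {
    d$w <- 1
  }
  flags <- character(0)

  kmax0 <- max(d$y)
  if (kmax0 <= 0) stop("all k_obs are zero; no covalent signal")
  K0 <- d$x[which.min(abs(d$y - kmax0 / 2))]
  fit <- minpack.lm::nlsLM(
    y ~ kinact * x / (KI + x), data = d,
    start = list(kinact = kmax0 * 1.2, KI = K0),
    lower = c(0, 0), weights = d$w,
    control = minpack.lm::nls.lm.control(maxiter = 1000)
  )
  cf <- stats::coef(fit)
  se <- .nls_se(fit)
  k_inact <- cf[["kinact"]]; K_I <- cf[["KI"]]
  if (max(d$x) < K_I) {
    flags <- c(flags, "sub_saturating")
    warning("all concentrations below fitted K_I; the saturation fit is ",
            "ill-conditioned - consider fit_efficiency_linear()")
  }
  eff <- k_inact / K_I
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 2, 2))
  se_eff <- eff * sqrt(vc[1, 1] / k_inact^2 + vc[2, 2] / K_I^2 -
                         2 * vc[1, 2] / (k_inact * K_I))
  structure(list(
    k_inact = unname(k_inact), K_I = unname(K_I),
    efficiency = unname(eff), Ki_t0 = NA_real_,
    per_concentration = per_concentration,
    regime = "saturation",
    standard_errors = c(k_inact = se[["kinact"]], K_I = se[["KI"]],
                        efficiency = unname(se_eff)),
    residuals = unname(stats::residuals(fit)),
    data = d, flags = flags
  ), class = "covalent_fit")
}

#' @export
print.covalent_fit <- function(x, ...) {
  cat("Covalent inhibition fit (", x$regime, " regime)\n", sep = "")
  if (is.finite(x$k_inact)) {
    cat(sprintf("  k_inact = %.4g s^-1, K_I = %.4g M\n", x$k_inact, x$K_I))
  }
  cat(sprintf("  k_inact/K_I = %.4g M^-1 s^-1\n", x$efficiency))
  if (is.finite(x$Ki_t0)) cat(sprintf("  K_i(t=0) = %.4g M\n", x$Ki_t0))
  invisible(x)
}

#' Covalent efficiency from the linear low-concentration regime
#'
#' When `[I] << K_I` the saturation relation reduces to
#' `k_obs = (k_inact / K_I) * [I]`; the efficiency is then the
#' zero-intercept least-squares slope of `k_obs` against concentration. A
#' diagnostic refit with free intercept is reported but not used for the
#' headline value.
#'
#' @param conc inhibitor concentrations, molar.
#' @param k_obs observed rates, s^-1.
#' @param K_I optional known/estimated K_I used to check the regime.
#' @param max_conc_fraction_of_KI concentrations above this fraction of
#'   `K_I` trigger a regime warning (default 0.2).
#' @return object of class `covalent_fit` with `regime = "linear"`;
#'   `k_inact` and `K_I` are `NA`, `efficiency` is the through-origin slope.
#' @export
fit_efficiency_linear <- function(conc, k_obs, K_I = NULL,
                                  max_conc_fraction_of_KI = 0.2) {
  if (length(conc) == 0 || length(k_obs) == 0) {
    stop("empty input: need (concentration, k_obs) pairs")
  }
  .assert_num(conc, "conc", positive = TRUE)
  .assert_num(k_obs, "k_obs", nonneg = TRUE)
  stopifnot(length(conc) == length(k_obs))
  flags <- character(0)
  if (!is.null(K_I) && any(conc > max_conc_fraction_of_KI * K_I)) {
    flags <- c(flags, "regime_violation")
    warning("some concentrations exceed ", max_conc_fraction_of_KI,
            " * K_I; the linear-regime slope may be biased low")
  }
  slope <- sum(conc * k_obs) / sum(conc^2)
  res <- k_obs - slope * conc
  df <- length(conc) - 1
  se <- if (df > 0) sqrt(sum(res^2) / df / sum(conc^2)) else NA_real_
  diag_fit <- stats::lm(k_obs ~ conc)
  structure(list(
    k_inact = NA_real_, K_I = NA_real_,
    efficiency = slope, Ki_t0 = NA_real_,
    per_concentration = NULL,
    regime = "linear",
    standard_errors = c(efficiency = se),
    residuals = res,
    diagnostic_intercept = unname(stats::coef(diag_fit)),
    data = data.frame(x = conc, y = k_obs), flags = flags
  ), class = "covalent_fit")
}

#' Reversible K_i at time zero from per-concentration intercepts
#'
#' The initial bound fractions `F_b0` (time-course intercepts, before any
#' covalent bond has formed) report the purely reversible competition. This
#' fits their dose-response IC50 ([fit_ic50()]) and converts it to `K_i`
#' with the depletion-corrected conversion ([ic50_to_Ki()]).
#'
#' @param conc inhibitor concentrations, molar.
#' @param F_b0 initial bound fractions, same length.
#' @param L_total total probe concentration, molar.
#' @param K_L probe dissociation constant, molar.
#' @param P_total total protein concentration, molar.
#' @return list with `K_i`, `IC50`, the [fit_ic50()] object (`fit`), and
#'   the conversion record (`conversion`).
#' @export
ki_at_t0 <- function(conc, F_b0, L_total, K_L, P_total) {
  fit <- fit_ic50(data.frame(concentration = conc, response = F_b0))
  conv <- ic50_to_Ki(fit$IC50, L_total = L_total, K_L = K_L,
                     P_total = P_total)
  list(K_i = conv$K_i, IC50 = fit$IC50, fit = fit, conversion = conv)
}

#' Pseudo-first-order fit of a covalent modification time course
#'
#' Fits fraction-modified data to `f(t) = 1 - exp(-k t)` (first-order
#' approach to stoichiometric occupancy) and reports the rate and the time
#' to 95% modification, `t95 = ln(20) / k`.
#'
#' @param times seconds.
#' @param fraction fraction of protein modified, in `[0, 1]`.
#' @return list with `k` (s^-1), `t95` (s), `standard_errors`, `residuals`,
#'   and `flags` (`non_monotone` when the data decrease beyond noise).
#' @export
fit_modification_timecourse <- function(times, fraction) {
  .assert_num(times, "times", nonneg = TRUE)
  .assert_num(fraction, "fraction")
  stopifnot(length(times) == length(fraction))
  if (any(fraction < -0.05 | fraction > 1.05)) {
    stop("fractions must lie in [0, 1] (small noise excursions tolerated)")
  }
  flags <- character(0)
  d <- data.frame(t = times, f = fraction)
  # crude initial rate from the first positive fraction
  pos <- which(d$f > 0 & d$f < 1 & d$t > 0)
  k0 <- if (length(pos)) {
    stats::median(-log(1 - pmin(d$f[pos], 0.99)) / d$t[pos])
  } else 1e-4
  fit <- minpack.lm::nlsLM(f ~ 1 - exp(-k * t), data = d,
                           start = list(k = k0), lower = 0,
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  k <- stats::coef(fit)[["k"]]
  res <- stats::residuals(fit)
  # a drop of more than 15% of the observed span is not plausible noise
  # for a first-order approach to saturation
  if (any(diff(fraction) < -0.15 * diff(range(fraction)))) {
    flags <- c(flags, "non_monotone")
    warning("fraction modified decreases beyond noise")
  }
  list(k = k, t95 = log(20) / k,
       standard_errors = c(k = .nls_se(fit)[["k"]]),
       residuals = unname(res), flags = flags)
}

#' Full covalent FP analysis from time courses to kinetic parameters
#'
#' Convenience pipeline: linearize each per-concentration time course
#' ([linearize_timecourse()]), fit the saturation relation
#' ([fit_kinact_KI()]), and, when the assay composition is supplied,
#' compute the reversible `K_i` at time zero ([ki_at_t0()]).
#'
#' @param timecourses data frame with columns `inhibitor_conc` (molar),
#'   `time_s`, and `response` (bound fraction, or anisotropy with `calib`);
#'   replicate rows at the same concentration and time are averaged.
#' @param calib optional [anisotropy_calibration()].
#' @param L_total,K_L,P_total optional assay composition for the K_i(t=0)
#'   conversion.
#' @inheritParams linearize_timecourse
#' @return a `covalent_fit` with `per_concentration` linearizations and,
#'   when composition is given, `Ki_t0` filled in.
#' @export
fit_covalent_fp <- function(timecourses, calib = NULL, L_total = NULL,
                            K_L = NULL, P_total = NULL, retain = 0.7) {
  stopifnot(is.data.frame(timecourses),
            all(c("inhibitor_conc", "time_s", "response") %in%
                  names(timecourses)))
  concs <- sort(unique(timecourses$inhibitor_conc))
  concs <- concs[concs > 0]
  lins <- lapply(concs, function(ci) {
    sub <- timecourses[timecourses$inhibitor_conc == ci, ]
    d <- .average_ties(sub$time_s, sub$response)
    d <- d[order(d$x), ]
    linearize_timecourse(d$x, d$y, calib = calib, retain = retain)
  })
  names(lins) <- format(concs, digits = 6)
  kobs_se <- vapply(lins, function(l) l$standard_errors[["k_obs"]], 0)
  fit <- fit_kinact_KI(concs, vapply(lins, `[[`, 0, "k_obs"),
                       se = kobs_se, per_concentration = lins)
  if (!is.null(L_total) && !is.null(K_L) && !is.null(P_total)) {
    k <- ki_at_t0(concs, vapply(lins, `[[`, 0, "F_b0"),
                  L_total = L_total, K_L = K_L, P_total = P_total)
    fit$Ki_t0 <- k$K_i
    fit$IC50_t0 <- k$IC50
  }
  fit
}
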