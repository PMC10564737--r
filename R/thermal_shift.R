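# Thermal shift analysis: DSF T_m by first-derivative extremum and CETSA
# percent-stabilized normalization, Boltzmann T_agg fitting, and the
# dose-response EC50 of the T_agg shift.

.check_melt <- function(temperatures, signals, min_points = 8) {
  .assert_num(temperatures, "temperatures")
  .assert_num(signals, "signals")
  if (length(temperatures) != length(signals)) {
    stop("temperatures and signals must have the same length")
  }
  if (length(temperatures) < min_points) {
    stop("need at least ", min_points, " temperature points")
  }
  if (is.unsorted(temperatures, strictly = TRUE)) {
    stop("temperatures must be strictly increasing")
  }
  invisible(NULL)
}

#' Percent-stabilized normalization of a CETSA melt curve
#'
#' Expresses each luminescence reading as a percentage of the reading at
#' the reference (lowest) temperature for that sample, making curves
#' comparable across wells regardless of absolute reporter signal. When the
#' requested reference temperature is not on the grid, the lowest measured
#' temperature is used with a warning.
#'
#' @param temperatures degrees C, strictly increasing.
#' @param signals raw luminescence, same length, non-negative.
#' @param reference_T reference temperature (default 40).
#' @return numeric vector of percent-stabilized values (100 at the
#'   reference temperature), with attribute `reference_T`.
#' @export
percent_stabilized <- function(temperatures, signals, reference_T = 40) {
  .check_melt(temperatures, signals)
  i <- which(temperatures == reference_T)
  if (length(i) == 0) {
    i <- 1L
    warning("reference temperature ", reference_T,
            " not on the grid; normalizing to the lowest measured ",
            "temperature (", temperatures[1], " C)")
  }
  ref <- signals[i[1]]
  if (ref == 0) stop("zero signal at the reference temperature")
  out <- 100 * signals / ref
  attr(out, "reference_T") <- temperatures[i[1]]
  out
}

#' Boltzmann sigmoid fit of an aggregation (melt) curve
#'
#' Fits `f(T) = bottom + (top - bottom) / (1 + exp((T_agg - T) / s))` and
#' reports the inflection midpoint `T_agg`. The sign of the slope factor
#' `s` is auto-detected from the curve direction (CETSA luminescence decays
#' with temperature, `s < 0`; a rising curve gives `s > 0`) and recorded.
#' The fit is initialized from the half-maximum crossing.
#'
#' @param temperatures degrees C, strictly increasing (>= 8 points).
#' @param signals melt signal (e.g. percent stabilized).
#' @return object of class `tagg_fit` with `T_agg`, `top`, `bottom`,
#'   `slope_factor`, `standard_errors`, `method = "boltzmann"`, and
#'   `flags` (`extrapolated` if `T_agg` leaves the measured range).
#' @export
fit_tagg_boltzmann <- function(temperatures, signals) {
  .check_melt(temperatures, signals)
  span <- diff(range(signals))
  if (span == 0) stop("no transition: signal is constant")
  # require an actual sigmoidal drop/rise, not just noise
  if (span < 0.05 * max(abs(signals))) {
    stop("no transition: signal span below 5% of the signal scale")
  }
  d <- data.frame(T = temperatures, y = signals)
  decreasing <- stats::cor(d$T, d$y) < 0
  top0 <- if (decreasing) max(d$y) else min(d$y)
  bot0 <- if (decreasing) min(d$y) else max(d$y)
  mid <- (max(d$y) + min(d$y)) / 2
  Tm0 <- stats::approx(d$y, d$T, xout = mid, ties = mean)$y
  if (!is.finite(Tm0)) Tm0 <- stats::median(d$T)
  s0 <- if (decreasing) -2 else 2

  fit <- minpack.lm::nlsLM(
    y ~ bottom + (top - bottom) / (1 + exp((Tagg - T) / s)),
    data = d,
    start = list(top = if (decreasing) max(d$y) else max(d$y),
                 bottom = min(d$y), Tagg = Tm0, s = s0),
    control = minpack.lm::nls.lm.control(maxiter = 1000)
  )
  cf <- stats::coef(fit)
  se <- .nls_se(fit)
  flags <- character(0)
  if (cf[["Tagg"]] < min(d$T) || cf[["Tagg"]] > max(d$T)) {
    flags <- c(flags, "extrapolated")
    warning("fitted T_agg lies outside the measured temperature range")
  }
  structure(list(
    T_agg = unname(cf[["Tagg"]]),
    top = unname(cf[["top"]]), bottom = unname(cf[["bottom"]]),
    slope_factor = unname(cf[["s"]]),
    direction = if (cf[["s"]] < 0) "decreasing" else "increasing",
    standard_errors = c(T_agg = se[["Tagg"]], top = se[["top"]],
                        bottom = se[["bottom"]], slope_factor = se[["s"]]),
    residuals = unname(stats::residuals(fit)),
    method = "boltzmann", flags = flags
  ), class = "tagg_fit")
}

#' @export
print.tagg_fit <- function(x, ...) {
  lab <- if (x$method == "boltzmann") "T_agg" else "T_m"
  cat(sprintf("Melt analysis (%s): %s = %.2f C\n", x$method, lab, x$T_agg))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' DSF melting temperature from the first-derivative extremum
#'
#' Locates the melting midpoint of a dye-based thermal denaturation curve
#' as the temperature of steepest fluorescence increase (the minimum of
#' `d(-F)/dT`). The raw curve is mildly smoothed with a Savitzky-Golay
#' filter (local polynomial, default 5-point window, order 2) before
#' differentiation, and the grid extremum is refined by quadratic
#' interpolation of the derivative over its neighbors.
#'
#' @param temperatures degrees C, strictly increasing (>= 8 points,
#'   typically a 1 C ramp).
#' @param signals fluorescence readings.
#' @param window Savitzky-Golay window length (odd, default 5).
#' @param order polynomial order of the smoother (default 2).
#' @return object of class `tagg_fit` with `T_agg` (the T_m), `method =
#'   "derivative"`, and a `boundary` flag when the extremum sits on the
#'   edge of the ramp (unreliable).
#' @export
dsf_tm <- function(temperatures, signals, window = 5, order = 2) {
  .check_melt(temperatures, signals)
  if (window %% 2 == 0 || window < order + 2) {
    stop("smoothing window must be odd and exceed the polynomial order")
  }
  sm <- signal::sgolayfilt(signals, p = order, n = window)
  dT <- diff(temperatures)
  # centered derivative on the (possibly uneven) grid
  n <- length(sm)
  deriv <- numeric(n)
  deriv[1] <- (sm[2] - sm[1]) / dT[1]
  deriv[n] <- (sm[n] - sm[n - 1]) / dT[n - 1]
  for (i in 2:(n - 1)) {
    deriv[i] <- (sm[i + 1] - sm[i - 1]) / (temperatures[i + 1] -
                                             temperatures[i - 1])
  }
  i <- which.max(deriv)  # steepest increase = min of d(-F)/dT
  flags <- character(0)
  if (i == 1 || i == n) {
    flags <- c(flags, "boundary")
    warning("derivative extremum at the edge of the temperature ramp; ",
            "T_m unreliable")
    Tm <- temperatures[i]
  } else {
    # quadratic interpolation of the derivative around the grid extremum
    x <- temperatures[(i - 1):(i + 1)]
    y <- deriv[(i - 1):(i + 1)]
    denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
    a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) +
            x[1] * (y[3] - y[2])) / denom
    b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) +
            x[1]^2 * (y[2] - y[3])) / denom
    Tm <- if (a < 0) -b / (2 * a) else temperatures[i]
    if (Tm < x[1] || Tm > x[3]) Tm <- temperatures[i]
  }
  structure(list(
    T_agg = unname(Tm), top = NA_real_, bottom = NA_real_,
    slope_factor = NA_real_,
    direction = "increasing",
    standard_errors = c(T_agg = NA_real_),
    derivative = deriv, smoothed = sm,
    method = "derivative", flags = flags
  ), class = "tagg_fit")
}

#' EC50 of the dose-dependent aggregation-temperature shift
#'
#' Fits the T_agg shift against compound concentration with a log-logistic
#' saturation model `dT(c) = max_shift * c^h / (EC50^h + c^h)` (Hill
#' coefficient fixed at 1 by default). The EC50 is the concentration of
#' half-maximal stabilization.
#'
#' @param conc compound concentrations, molar (>= 5 points).
#' @param shift T_agg shifts, degrees C.
#' @param hill_free fit the Hill coefficient (default FALSE).
#' @return list with `EC50` (molar), `max_shift`, `hill`,
#'   `standard_errors`, `residuals`, and `flags` (`no_saturation` when the
#'   tested range does not reach the fitted EC50).
#' @export
fit_tagg_shift_ec50 <- function(conc, shift, hill_free = FALSE) {
  .assert_num(conc, "conc", nonneg = TRUE)
  .assert_num(shift, "shift")
  stopifnot(length(conc) == length(shift))
  d <- .average_ties(conc, shift)
  d <- d[d$x > 0, ]
  if (nrow(d) < 5) stop("need at least 5 nonzero concentrations")
  if (all(abs(d$y) < .Machine$double.eps^0.5)) {
    stop("all shifts are zero: no stabilization to fit")
  }
  max0 <- max(d$y)
  e0 <- d$x[which.min(abs(d$y - max0 / 2))]
  flags <- character(0)
  if (hill_free) {
    fit <- minpack.lm::nlsLM(
      y ~ mx * x^h / (ec^h + x^h), data = d,
      start = list(mx = max0, ec = e0, h = 1), lower = c(0, 0, 0.2),
      control = minpack.lm::nls.lm.control(maxiter = 1000))
  } else {
    fit <- minpack.lm::nlsLM(
      y ~ mx * x / (ec + x), data = d,
      start = list(mx = max0, ec = e0), lower = c(0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 1000))
  }
  cf <- stats::coef(fit)
  se <- .nls_se(fit)
  if (max(d$x) < cf[["ec"]]) {
    flags <- c(flags, "no_saturation")
    warning("tested concentrations do not reach the fitted EC50; wide ",
            "confidence interval expected")
  }
  list(
    EC50 = unname(cf[["ec"]]), max_shift = unname(cf[["mx"]]),
    hill = if (hill_free) unname(cf[["h"]]) else 1,
    standard_errors = c(EC50 = se[["ec"]], max_shift = se[["mx"]]),
    residuals = unname(stats::residuals(fit)),
    flags = flags
  )
}

#' Per-replicate CETSA analysis with T_agg summary
#'
#' Normalizes each replicate curve to its lowest-temperature reading,
#' fits a Boltzmann sigmoid per replicate, and summarizes T_agg as mean
#' and standard deviation across replicates.
#'
#' @param data data frame with columns `temperature_C`, `signal`, and
#'   `replicate`.
#' @param reference_T reference temperature for normalization (default 40).
#' @return list with per-replicate `fits`, `T_agg_mean`, `T_agg_sd`, and
#'   `n_replicates`.
#' @export
cetsa_tagg <- function(data, reference_T = 40) {
  stopifnot(is.data.frame(data),
            all(c("temperature_C", "signal", "replicate") %in% names(data)))
  reps <- unique(data$replicate)
  fits <- lapply(reps, function(r) {
    sub <- data[data$replicate == r, ]
    sub <- sub[order(sub$temperature_C), ]
    y <- percent_stabilized(sub$temperature_C, sub$signal,
                            reference_T = reference_T)
    fit_tagg_boltzmann(sub$temperature_C, as.numeric(y))
  })
  tg <- vapply(fits, `[[`, 0, "T_agg")
  list(fits = fits, T_agg_mean = mean(tg),
       T_agg_sd = if (length(tg) > 1) stats::sd(tg) else NA_real_,
       n_replicates = length(tg))
}
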