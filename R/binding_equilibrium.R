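# Equilibrium probe binding: anisotropy <-> bound fraction, exact one-site
# binding with ligand depletion, probe K_L fitting, competition IC50 and its
# conversion to K_i.

#' Anisotropy calibration of a fluorescent probe
#'
#' Pairs the anisotropy of the fully free probe (`A_f`) with that of the
#' fully protein-bound probe (`A_b`), in milli-anisotropy units. These two
#' endpoints define the linear map between measured anisotropy and the
#' fraction of probe bound.
#'
#' @param A_f anisotropy of the free probe.
#' @param A_b anisotropy of the fully bound probe; must differ from `A_f`.
#' @return an object of class `anisotropy_calibration`.
#' @export
#' @examples
#' anisotropy_calibration(A_f = 20, A_b = 120)
anisotropy_calibration <- function(A_f, A_b) {
  .assert_num(A_f, "A_f", len = 1)
  .assert_num(A_b, "A_b", len = 1)
  if (A_f == A_b) {
    stop("degenerate calibration: A_f equals A_b, bound fraction undefined")
  }
  structure(list(A_f = A_f, A_b = A_b), class = "anisotropy_calibration")
}

#' Bound fraction of the probe from measured anisotropy
#'
#' Converts anisotropy `A` to the bound probe fraction
#' `F_b = (A_f - A) / (A_f - A_b)`. Instrument noise can push raw values
#' slightly outside `[0, 1]`; those are clamped, with the raw values and a
#' per-point out-of-range flag retained as attributes.
#'
#' @param A numeric vector of measured anisotropies.
#' @param calib an [anisotropy_calibration()].
#' @return numeric vector of bound fractions in `[0, 1]`, with attributes
#'   `raw` (unclamped values) and `out_of_range` (logical flags).
#' @seealso [anisotropy_from_fraction()] for the inverse map.
#' @export
#' @examples
#' cal <- anisotropy_calibration(20, 120)
#' bound_fraction(45, cal)  # 0.25
bound_fraction <- function(A, calib) {
  stopifnot(inherits(calib, "anisotropy_calibration"))
  .assert_num(A, "A")
  raw <- (calib$A_f - A) / (calib$A_f - calib$A_b)
  flag <- raw < 0 | raw > 1
  if (any(flag)) {
    warning(sum(flag), " anisotropy value(s) outside the calibration range; ",
            "bound fractions clamped to [0, 1]")
  }
  out <- pmin(1, pmax(0, raw))
  attr(out, "raw") <- raw
  attr(out, "out_of_range") <- flag
  out
}

#' Anisotropy from bound fraction
#'
#' Inverse of [bound_fraction()]: `A = A_f + (A_b - A_f) * F_b`.
#'
#' @param f bound fraction(s).
#' @param calib an [anisotropy_calibration()].
#' @return numeric vector of anisotropies.
#' @export
anisotropy_from_fraction <- function(f, calib) {
  stopifnot(inherits(calib, "anisotropy_calibration"))
  calib$A_f + (calib$A_b - calib$A_f) * f
}

#' Fraction of probe bound under 1:1 binding with depletion
#'
#' Exact solution of the one-site binding quadratic for the fraction of
#' total probe bound, valid when probe and protein concentrations are
#' comparable to the dissociation constant (no "free ligand equals total"
#' approximation):
#' `x = ((P + L + K) - sqrt((P + L + K)^2 - 4 P L)) / (2 L)`.
#' Evaluated in the numerically stable conjugate form `2P / (b + sqrt(...))`.
#'
#' @param P_total total protein concentration(s), molar.
#' @param L_total total probe concentration, molar, > 0.
#' @param K_L probe dissociation constant, molar, > 0.
#' @return fraction of probe bound, in `[0, 1]`.
#' @export
#' @examples
#' probe_bound_fraction(77.56e-9, 10e-9, 77.56e-9)  # ~0.484
probe_bound_fraction <- function(P_total, L_total, K_L) {
  .assert_num(P_total, "P_total", nonneg = TRUE)
  .assert_num(L_total, "L_total", len = 1)
  .assert_num(K_L, "K_L", positive = TRUE, len = 1)
  if (L_total <= 0) {
    stop("L_total must be > 0: probe fraction undefined without probe")
  }
  b <- P_total + L_total + K_L
  disc <- b^2 - 4 * P_total * L_total
  disc[disc < 0] <- 0  # guard tiny negative round-off
  2 * P_total / (b + sqrt(disc))
}

#' Forward saturation binding curve in anisotropy units
#'
#' Predicts the anisotropy of a probe titrated with protein using the exact
#' depletion-corrected one-site model and an anisotropy calibration.
#'
#' @param P_total protein concentration series, molar.
#' @param L_total total probe concentration, molar.
#' @param K_L probe dissociation constant, molar.
#' @param calib an [anisotropy_calibration()].
#' @return data frame with columns `concentration` (protein, molar),
#'   `bound_fraction`, and `response` (anisotropy).
#' @export
saturation_curve <- function(P_total, L_total, K_L, calib) {
  x <- probe_bound_fraction(P_total, L_total, K_L)
  data.frame(
    concentration = P_total,
    bound_fraction = x,
    response = anisotropy_from_fraction(x, calib)
  )
}

#' Fit the probe dissociation constant K_L from a protein titration
#'
#' Least-squares fit of the exact depletion-corrected saturation curve to
#' anisotropy measured across a protein dilution series. `K_L` is fitted on
#' the log10 scale to enforce positivity; `A_f` and `A_b` are estimated
#' jointly unless a calibration is supplied.
#'
#' @param data data frame with columns `concentration` (total protein,
#'   molar) and `response` (anisotropy); replicate rows at the same
#'   concentration are averaged before fitting.
#' @param L_total total probe concentration, molar.
#' @param calib optional [anisotropy_calibration()]; when given, `A_f` and
#'   `A_b` are fixed rather than fitted.
#' @return object of class `binding_fit` with elements `K_L`, `A_f`, `A_b`,
#'   `standard_errors`, `residuals`, `data`, and `warnings`.
#' @export
fit_probe_KL <- function(data, L_total, calib = NULL) {
  stopifnot(is.data.frame(data),
            all(c("concentration", "response") %in% names(data)))
  d <- .average_ties(data$concentration, data$response)
  if (nrow(d) < 6) stop("need at least 6 distinct concentrations")
  if (diff(range(d$y)) == 0) {
    stop("no binding signal: all responses identical")
  }
  span <- diff(range(d$y))
  ord <- order(d$x)
  d <- d[ord, ]
  warnings <- character(0)

  # starting values from the curve endpoints and the half-signal crossing
  Af0 <- d$y[1]
  Ab0 <- d$y[nrow(d)]
  mid <- (Af0 + Ab0) / 2
  pos <- d$x > 0
  K0 <- stats::approx(d$y, d$x, xout = mid, ties = mean)$y
  if (!is.finite(K0) || K0 <= 0) K0 <- stats::median(d$x[pos])

  if (is.null(calib)) {
    fit <- minpack.lm::nlsLM(
      y ~ Af + (Ab - Af) * probe_bound_fraction(x, L_total, 10^lK),
      data = d,
      start = list(Af = Af0, Ab = Ab0, lK = log10(K0)),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    cf <- stats::coef(fit)
    se <- .nls_se(fit)
    A_f <- cf[["Af"]]; A_b <- cf[["Ab"]]
    se_out <- c(K_L = NA, A_f = se[["Af"]], A_b = se[["Ab"]])
    lK <- cf[["lK"]]; se_lK <- se[["lK"]]
  } else {
    A_f <- calib$A_f; A_b <- calib$A_b
    fit <- minpack.lm::nlsLM(
      y ~ A_f + (A_b - A_f) * probe_bound_fraction(x, L_total, 10^lK),
      data = d,
      start = list(lK = log10(K0)),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    se <- .nls_se(fit)
    se_out <- c(K_L = NA, A_f = 0, A_b = 0)
    lK <- stats::coef(fit)[["lK"]]; se_lK <- se[["lK"]]
  }
  K_L <- 10^lK
  # delta method back to the linear scale
  se_out[["K_L"]] <- K_L * log(10) * se_lK

  if (K_L < min(d$x[pos]) || K_L > max(d$x)) {
    warnings <- c(warnings,
                  "fitted K_L lies outside the tested concentration range")
    warning(warnings[length(warnings)])
  }
  res <- stats::residuals(fit)
  if (stats::sd(res) > 0.5 * span) {
    stop("fit did not capture the binding signal (residuals comparable to ",
         "the full response span)")
  }
  structure(list(
    K_L = unname(K_L), A_f = unname(A_f), A_b = unname(A_b),
    standard_errors = se_out,
    residuals = unname(res),
    goodness = c(rss = sum(res^2), sigma = stats::sd(res)),
    data = d, L_total = L_total, warnings = warnings
  ), class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("One-site probe binding fit (depletion-corrected)\n")
  cat(sprintf("  K_L = %.4g M (SE %.2g)\n", x$K_L, x$standard_errors[["K_L"]]))
  cat(sprintf("  A_f = %.4g, A_b = %.4g\n", x$A_f, x$A_b))
  invisible(x)
}

#' Fit a competition dose-response curve (IC50)
#'
#' Four-parameter logistic in log10 concentration fitted to a competition
#' readout (typically the initial bound fraction `F_b0` against inhibitor
#' concentration). Zero-concentration points anchor the starting top
#' asymptote but are excluded from the logistic itself. The IC50 is the
#' concentration midway between the fitted asymptotes.
#'
#' @param data data frame with columns `concentration` (inhibitor, molar)
#'   and `response`; ties averaged before fitting.
#' @param hill_start starting Hill slope magnitude (default 1).
#' @return object of class `competition_fit` with `IC50`, `hill`, `top`,
#'   `bottom`, `standard_errors`, `residuals`, and `flags` (e.g.
#'   `extrapolated` when the IC50 lies outside the tested range).
#' @export
fit_ic50 <- function(data, hill_start = 1) {
  stopifnot(is.data.frame(data),
            all(c("concentration", "response") %in% names(data)))
  d <- .average_ties(data$concentration, data$response)
  zero <- d$x == 0
  top_anchor <- if (any(zero)) mean(d$y[zero]) else NA_real_
  d <- d[!zero, , drop = FALSE]
  if (nrow(d) < 6) stop("need at least 6 nonzero inhibitor concentrations")
  if (diff(range(d$y)) == 0) {
    stop("no competition signal: response constant across concentrations")
  }
  d <- d[order(d$x), ]
  flags <- character(0)

  decreasing <- stats::cor(log10(d$x), d$y) < 0
  top0 <- if (is.finite(top_anchor)) top_anchor else max(d$y)
  bot0 <- min(d$y)
  mid <- (top0 + bot0) / 2
  l0 <- log10(d$x[which.min(abs(d$y - mid))])
  h0 <- if (decreasing) abs(hill_start) else -abs(hill_start)

  fit <- minpack.lm::nlsLM(
    y ~ bottom + (top - bottom) / (1 + 10^(hill * (log10(x) - lIC50))),
    data = d,
    start = list(top = top0, bottom = bot0, lIC50 = l0, hill = h0),
    control = minpack.lm::nls.lm.control(maxiter = 1000)
  )
  cf <- stats::coef(fit)
  se <- .nls_se(fit)
  IC50 <- 10^cf[["lIC50"]]
  if (IC50 < min(d$x) || IC50 > max(d$x)) {
    flags <- c(flags, "extrapolated")
    warning("fitted IC50 lies outside the tested concentration range")
  }
  top <- cf[["top"]]; bottom <- cf[["bottom"]]
  if (bottom > top) {  # normalize so bottom <= top
    tmp <- top; top <- bottom; bottom <- tmp
  }
  structure(list(
    IC50 = unname(IC50),
    hill = unname(cf[["hill"]]),
    top = unname(top), bottom = unname(bottom),
    K_i = NA_real_,
    standard_errors = c(
      IC50 = IC50 * log(10) * se[["lIC50"]],
      hill = se[["hill"]], top = se[["top"]], bottom = se[["bottom"]]
    ),
    residuals = unname(stats::residuals(fit)),
    data = d, flags = flags,
    model = "four-parameter logistic in log10 concentration"
  ), class = "competition_fit")
}

#' @export
print.competition_fit <- function(x, ...) {
  cat("Competition dose-response fit\n")
  cat(sprintf("  IC50 = %.4g M, hill = %.3g, top = %.3g, bottom = %.3g\n",
              x$IC50, x$hill, x$top, x$bottom))
  if (is.finite(x$K_i)) cat(sprintf("  K_i  = %.4g M\n", x$K_i))
  invisible(x)
}

#' Convert a competition IC50 to the inhibitor K_i
#'
#' Exact conversion for a competitive fluorescence-polarization displacement
#' experiment, correcting for probe and protein depletion. The uninhibited
#' probe-protein equilibrium is solved exactly; at 50% inhibition the bound
#' probe is half of that, from which the free probe, free protein, and free
#' inhibitor concentrations follow by mass balance, giving
#' `K_i = P_free * I_free / PI`. In the no-depletion limit
#' (`L_total << K_L`, `P_total << K_L`) this reduces to `K_i = IC50`, and
#' `K_i <= IC50` always.
#'
#' @param IC50 fitted total inhibitor concentration at 50% inhibition, molar.
#' @param L_total total probe concentration, molar.
#' @param K_L probe dissociation constant, molar.
#' @param P_total total protein concentration, molar.
#' @return list with `K_i` (molar), the intermediate free-species
#'   concentrations, and a `method` tag recorded for report metadata.
#' @export
#' @examples
#' ic50_to_Ki(2e-6, L_total = 10e-9, K_L = 77.56e-9, P_total = 100e-9)$K_i
ic50_to_Ki <- function(IC50, L_total, K_L, P_total) {
  .assert_num(IC50, "IC50", positive = TRUE, len = 1)
  .assert_num(L_total, "L_total", positive = TRUE, len = 1)
  .assert_num(K_L, "K_L", positive = TRUE, len = 1)
  .assert_num(P_total, "P_total", positive = TRUE, len = 1)

  PL0 <- L_total * probe_bound_fraction(P_total, L_total, K_L)
  PL50 <- PL0 / 2
  L50 <- L_total - PL50                 # free probe at 50% inhibition
  P50 <- K_L * PL50 / L50               # free protein at 50% inhibition
  PI50 <- P_total - PL50 - P50          # protein-inhibitor complex
  if (PI50 <= 0) {
    stop("mass balance gives no protein-inhibitor complex at 50% ",
         "inhibition; inputs are inconsistent with competitive displacement")
  }
  I50 <- IC50 - PI50                    # free inhibitor at 50% inhibition
  if (I50 <= 0) {
    stop("IC50 does not exceed the depleted inhibitor fraction ",
         "(tight-binding regime); conversion undefined")
  }
  K_i <- P50 * I50 / PI50
  list(
    K_i = K_i, IC50 = IC50,
    free_probe_50 = L50, free_protein_50 = P50,
    complex_PI_50 = PI50, free_inhibitor_50 = I50,
    method = "competitive FP mass-balance conversion (depletion-corrected)"
  )
}
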