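# Closed-form chemistry and thermodynamics: binding free energy, entropy
# term, ligand efficiency, glutathione pseudo-first-order stability, and
# signed elemental-composition mass arithmetic.

# Gas constant in kcal/(mol K); standard state 1 M.
.R_KCAL <- 1.98720425e-3

# Pinned atomic mass table. Monoisotopic masses are the most abundant
# isotope masses (consistent with CODATA/AME); average masses are the
# IUPAC conventional atomic weights. Both in daltons.
.ATOMIC_MASSES <- data.frame(
  element = c("H", "C", "N", "O", "F", "P", "S", "Se", "Cl", "Br", "I",
              "Na", "K", "Si", "B", "Fe", "Zn", "Cu", "Mg", "Ca", "As"),
  monoisotopic = c(
    1.0078250319, 12.0, 14.0030740052, 15.9949146221, 18.99840322,
    30.97376151, 31.97207069, 73.9224766, 34.96885271, 78.9183376,
    126.904468, 22.98976928, 38.9637069, 27.9769265327, 11.0093055,
    55.9349421, 63.9291466, 62.9296011, 23.9850419, 39.9625912, 74.9215964
  ),
  average = c(
    1.008, 12.011, 14.007, 15.999, 18.998403163, 30.973761998, 32.06,
    78.971, 35.45, 79.904, 126.90447, 22.98976928, 39.0983, 28.085,
    10.81, 55.845, 65.38, 63.546, 24.305, 40.078, 74.921595
  ),
  stringsAsFactors = FALSE
)

.MASS_TABLE_PROVENANCE <- paste(
  "monoisotopic: most-abundant-isotope masses (CODATA/AME-consistent);",
  "average: IUPAC conventional atomic weights"
)

#' Parse a signed elemental composition string
#'
#' Accepts the modification-composition dialect used by proteomics search
#' engines: an element symbol optionally followed by a signed integer count
#' in parentheses (`"Se(-1)"`), or by bare digits (`"C2H3NO"`); a bare
#' symbol means count 1. Repeated symbols are summed. Negative counts are
#' legal (they encode replaced atoms in placeholder chemistry).
#'
#' @param text composition string, e.g. `"C(26)H(25)N(3)O(7)FPSe(-1)S"`.
#' @return object of class `composition`: a named integer vector of signed
#'   element counts.
#' @export
#' @examples
#' parse_composition("H(2)O")
#' parse_composition("C2H3NO")
parse_composition <- function(text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(text)) {
    stop("composition must be a single non-empty string")
  }
  known <- .ATOMIC_MASSES$element
  counts <- integer(0)
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    rest <- substr(text, i, n)
    m <- regmatches(rest, regexec("^[A-Z][a-z]?", rest))[[1]]
    if (length(m) == 0) {
      stop("malformed composition at position ", i, ": '",
           substr(text, i, min(n, i + 5)), "'")
    }
    sym <- m[1]
    if (!sym %in% known) {
      # fall back to the one-letter symbol (e.g. the 'S' in "Sx")
      sym <- substr(sym, 1, 1)
      if (!sym %in% known) {
        stop("unknown element symbol '", m[1], "' at position ", i)
      }
    }
    i <- i + nchar(sym)
    rest <- substr(text, i, n)
    cm <- regmatches(rest, regexec("^(\\((-?[0-9]+)\\)|[0-9]+)", rest))[[1]]
    cnt <- 1L
    if (length(cm) && nzchar(cm[1])) {
      cnt <- if (startsWith(cm[1], "(")) as.integer(cm[3]) else {
        as.integer(cm[1])
      }
      i <- i + nchar(cm[1])
    } else if (startsWith(rest, "(")) {
      stop("malformed parenthesized count at position ", i)
    }
    prev <- if (sym %in% names(counts)) counts[[sym]] else 0L
    counts[[sym]] <- prev + cnt
  }
  counts <- counts[counts != 0L]
  if (length(counts) == 0) stop("composition has no nonzero counts")
  structure(counts, class = "composition")
}

#' Canonical serialization of a composition
#'
#' Hill-order serializer (C first, then H, then remaining elements
#' alphabetically) with every count written explicitly in parentheses, so
#' that `parse_composition(format(x))` round-trips exactly.
#'
#' @param x a `composition`.
#' @param ... unused.
#' @return single string.
#' @export
format.composition <- function(x, ...) {
  els <- names(x)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    if (x[[e]] == 1L) e else paste0(e, "(", x[[e]], ")")
  }, ""), collapse = "")
}

#' @export
print.composition <- function(x, ...) {
  cat("<composition> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Combine two compositions element-wise
#'
#' @param a,b `composition` objects.
#' @param sign `+1` to add, `-1` to subtract `b` from `a`.
#' @return a `composition` (zero counts dropped).
#' @export
composition_combine <- function(a, b, sign = 1L) {
  stopifnot(inherits(a, "composition"), inherits(b, "composition"))
  els <- union(names(a), names(b))
  out <- vapply(els, function(e) {
    (if (e %in% names(a)) a[[e]] else 0L) +
      sign * (if (e %in% names(b)) b[[e]] else 0L)
  }, integer(1))
  out <- out[out != 0L]
  if (length(out) == 0) stop("combination cancels to an empty composition")
  structure(out, class = "composition")
}

#' Composition of a covalent adduct after loss of a leaving group
#'
#' Element-wise subtraction of the leaving group from the intact ligand
#' (e.g. a chloroacetamide warhead reacting with a cysteine thiol forms a
#' thioether and releases HCl, so the protein-borne adduct is ligand minus
#' HCl). Every element of the leaving group must be present in the ligand
#' in at least that count.
#'
#' @param ligand `composition` of the intact ligand.
#' @param leaving_group `composition` of the expelled fragment.
#' @return `composition` of the covalent adduct.
#' @export
#' @examples
#' covalent_adduct_composition(parse_composition("C(26)H(26)ClFN(3)O(7)P"),
#'                             parse_composition("HCl"))
covalent_adduct_composition <- function(ligand, leaving_group) {
  stopifnot(inherits(ligand, "composition"),
            inherits(leaving_group, "composition"))
  for (e in names(leaving_group)) {
    have <- if (e %in% names(ligand)) ligand[[e]] else 0L
    if (leaving_group[[e]] > have) {
      stop("leaving group requires ", leaving_group[[e]], " x ", e,
           " but the ligand provides ", have)
    }
  }
  composition_combine(ligand, leaving_group, sign = -1L)
}

#' Mass of an elemental composition
#'
#' Signed sum of per-element masses from the package's pinned atomic-mass
#' table (monoisotopic or conventional average atomic weights).
#'
#' @param composition a `composition` (see [parse_composition()]).
#' @param kind `"monoisotopic"` or `"average"`.
#' @return mass in daltons, with attribute `provenance` describing the mass
#'   table.
#' @export
#' @examples
#' composition_mass(parse_composition("H(2)O"))           # 18.0106
#' composition_mass(parse_composition("C(2)H(3)NO"))      # 57.0215
composition_mass <- function(composition,
                             kind = c("monoisotopic", "average")) {
  stopifnot(inherits(composition, "composition"))
  kind <- match.arg(kind)
  tab <- .ATOMIC_MASSES
  miss <- setdiff(names(composition), tab$element)
  if (length(miss)) {
    stop("element(s) missing from the mass table: ",
         paste(miss, collapse = ", "))
  }
  m <- tab[[kind]][match(names(composition), tab$element)]
  out <- sum(m * as.numeric(composition))
  attr(out, "provenance") <- .MASS_TABLE_PROVENANCE
  out
}

#' Binding free energy from a dissociation constant
#'
#' `dG = R T ln(K_D / 1 M)` in kcal/mol, with
#' `R = 1.98720425e-3 kcal/(mol K)` and natural logarithm. Negative for
#' sub-molar dissociation constants (favorable binding).
#'
#' @param K_D dissociation constant, molar, > 0.
#' @param T temperature, kelvin (default 298, the usual calorimetry
#'   temperature).
#' @return free energy, kcal/mol.
#' @export
#' @examples
#' delta_g(0.38e-6)  # -8.75 kcal/mol
delta_g <- function(K_D, T = 298) {
  .assert_num(K_D, "K_D", positive = TRUE)
  .assert_num(T, "T", positive = TRUE, len = 1)
  .R_KCAL * T * log(K_D)
}

#' Entropic term of binding from dG and dH
#'
#' `-T dS = dG - dH` (kcal/mol), the decomposition used alongside
#' calorimetric enthalpies.
#'
#' @param dG,dH free energy and enthalpy, kcal/mol.
#' @return `-T dS`, kcal/mol.
#' @export
entropy_term <- function(dG, dH) {
  .assert_num(dG, "dG")
  .assert_num(dH, "dH")
  dG - dH
}

#' Ligand efficiency
#'
#' `LE = -R T ln(K_D) / NHA`, the binding free energy per non-hydrogen
#' (heavy) atom; the standard normalization for comparing fragments of
#' different size.
#'
#' @param K_D dissociation constant, molar.
#' @param NHA number of non-hydrogen atoms, >= 1.
#' @param T temperature, kelvin (default 298).
#' @return ligand efficiency, kcal/mol per heavy atom.
#' @export
#' @examples
#' ligand_efficiency(190e-6, 17)  # ~0.30
ligand_efficiency <- function(K_D, NHA, T = 298) {
  .assert_num(NHA, "NHA", positive = TRUE)
  if (any(NHA != round(NHA))) stop("NHA must be a whole number of atoms")
  -delta_g(K_D, T) / NHA
}

#' Thermodynamic record for a binder
#'
#' Bundles the dissociation constant with its derived free energy,
#' entropy decomposition (when an enthalpy is supplied), and ligand
#' efficiency (when a heavy-atom count is supplied). Internal identities
#' (`dG = RT ln K_D`, `-TdS = dG - dH`, `LE = -dG/NHA`) hold by
#' construction.
#'
#' @param K_D molar dissociation constant.
#' @param T kelvin (default 298).
#' @param dH optional calorimetric enthalpy, kcal/mol.
#' @param NHA optional heavy-atom count.
#' @return object of class `thermo_record`.
#' @export
thermo_record <- function(K_D, T = 298, dH = NULL, NHA = NULL) {
  dG <- delta_g(K_D, T)
  structure(list(
    K_D = K_D, T = T, dG = dG,
    dH = dH %||% NA_real_,
    minusTdS = if (is.null(dH)) NA_real_ else entropy_term(dG, dH),
    NHA = NHA %||% NA_integer_,
    LE = if (is.null(NHA)) NA_real_ else ligand_efficiency(K_D, NHA, T)
  ), class = "thermo_record")
}

#' @export
print.thermo_record <- function(x, ...) {
  cat(sprintf("K_D = %.3g M at %g K: dG = %.2f kcal/mol", x$K_D, x$T, x$dG))
  if (is.finite(x$minusTdS)) {
    cat(sprintf(", dH = %.2f, -TdS = %.2f", x$dH, x$minusTdS))
  }
  if (is.finite(x$LE)) cat(sprintf(", LE = %.2f kcal/mol/NHA", x$LE))
  cat("\n")
  invisible(x)
}

#' Pseudo-first-order glutathione-reactivity decay fit
#'
#' Fits analyte peak-area ratios against time to `C(t) = C0 exp(-k_e t)`
#' and reports the electrophile half-life `T_half = ln(2) / k_e`. Percent
#' compound remaining is normalized to the fitted `C0` (the time-zero
#' amount). A series that does not decay is flagged non-reactive with an
#' infinite half-life sentinel.
#'
#' @param time_min minutes (>= 4 points, starting at or extrapolable to
#'   zero).
#' @param response peak-area ratio (analyte over internal standard).
#' @return object of class `decay_fit` with `C0`, `k_e` (min^-1), `T_half`
#'   (min), `percent_remaining`, `standard_errors`, and `flags`.
#' @export
fit_gsh_decay <- function(time_min, response) {
  .assert_num(time_min, "time_min", nonneg = TRUE)
  .assert_num(response, "response")
  if (length(time_min) < 4 || length(response) != length(time_min)) {
    stop("need at least 4 time points with matching responses")
  }
  d <- data.frame(t = time_min, y = response)
  # log-linear screen for the decay direction and a rate seed
  ok <- d$y > 0
  screen <- stats::lm(log(d$y[ok]) ~ d$t[ok])
  slope <- unname(stats::coef(screen)[2])
  if (slope >= 0) {
    warning("series does not decay; compound flagged non-reactive")
    return(structure(list(
      C0 = unname(exp(stats::coef(screen)[1])), k_e = 0, T_half = Inf,
      percent_remaining = 100 * d$y / d$y[1],
      standard_errors = c(C0 = NA_real_, k_e = NA_real_),
      flags = "non_reactive"
    ), class = "decay_fit"))
  }
  fit <- minpack.lm::nlsLM(y ~ C0 * exp(-k * t), data = d,
                           start = list(C0 = max(d$y), k = -slope),
                           lower = c(0, 0),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  se <- .nls_se(fit)
  k_e <- cf[["k"]]
  structure(list(
    C0 = unname(cf[["C0"]]), k_e = unname(k_e), T_half = log(2) / k_e,
    percent_remaining = 100 * d$y / cf[["C0"]],
    standard_errors = c(C0 = se[["C0"]], k_e = se[["k"]]),
    residuals = unname(stats::residuals(fit)),
    flags = character(0)
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (is.infinite(x$T_half)) {
    cat("Non-reactive: no measurable decay (T_half = Inf)\n")
  } else {
    cat(sprintf("Pseudo-first-order decay: k_e = %.4g min^-1, T_half = %.1f min\n",
                x$k_e, x$T_half))
  }
  invisible(x)
}
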