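# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

.unit_factors <- c(
  "M" = 1, "mM" = 1e-3, "uM" = 1e-6, "µM" = 1e-6, "nM" = 1e-9,
  "pM" = 1e-12
)

#' Convert concentrations to molar
#'
#' Concentrations are handled internally in molar throughout the package;
#' tabular inputs declare their unit per row and are converted on read.
#'
#' @param x numeric vector of concentrations.
#' @param unit character vector (length 1 or `length(x)`), one of
#'   `"M"`, `"mM"`, `"uM"` (or the micro sign), `"nM"`, `"pM"`.
#' @return numeric vector in molar.
#' @export
#' @examples
#' to_molar(c(50, 10), c("uM", "nM"))
to_molar <- function(x, unit) {
  unit <- as.character(unit)
  f <- .unit_factors[unit]
  if (anyNA(f)) {
    stop("unknown concentration unit(s): ",
         paste(unique(unit[is.na(f)]), collapse = ", "))
  }
  unname(x * f)
}

.assert_num <- function(x, name, positive = FALSE, nonneg = FALSE,
                        finite = TRUE, len = NULL) {
  if (!is.numeric(x)) stop(name, " must be numeric")
  if (!is.null(len) && length(x) != len) {
    stop(name, " must have length ", len)
  }
  if (finite && any(!is.finite(x))) stop(name, " must be finite")
  if (positive && any(x <= 0)) stop(name, " must be > 0")
  if (nonneg && any(x < 0)) stop(name, " must be >= 0")
  invisible(x)
}

# average replicate responses at identical x values (ties averaged before
# fitting, per the dose-response conventions used throughout)
.average_ties <- function(x, y) {
  key <- factor(x, levels = unique(x))
  data.frame(
    x = as.numeric(tapply(x, key, mean)),
    y = as.numeric(tapply(y, key, mean))
  )
}

# run `expr` under a local RNG seeded with `seed`; global RNG untouched
.with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# standard errors from an nls/nlsLM fit without summary() noise
.nls_se <- function(fit) {
  s <- tryCatch({
    co <- summary(fit)$coefficients
    stats::setNames(co[, "Std. Error"], rownames(co))
  }, error = function(e) NULL)
  if (is.null(s)) {
    s <- rep(NA_real_, length(stats::coef(fit)))
    names(s) <- names(stats::coef(fit))
  }
  s
}
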