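# CSV dialects, JSON fit reports, and the pipeline driver behind the
# command-line entry point.

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("input ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  invisible(df)
}

#' Read a dose-series CSV
#'
#' Long format with columns `series_id, concentration, concentration_unit,
#' response, response_type, replicate`; concentrations are converted to
#' molar on read.
#'
#' @param path CSV path.
#' @return data frame with `concentration` in molar.
#' @export
read_dose_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("series_id", "concentration", "concentration_unit",
                      "response", "response_type", "replicate"), path)
  df$concentration <- to_molar(df$concentration, df$concentration_unit)
  df$concentration_unit <- "M"
  df
}

#' Read a covalent time-course CSV
#'
#' Columns `series_id, inhibitor_conc, conc_unit, time_s, response,
#' replicate`; inhibitor concentrations converted to molar.
#'
#' @param path CSV path.
#' @return data frame with `inhibitor_conc` in molar.
#' @export
read_timecourse_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("series_id", "inhibitor_conc", "conc_unit", "time_s",
                      "response", "replicate"), path)
  df$inhibitor_conc <- to_molar(df$inhibitor_conc, df$conc_unit)
  df$conc_unit <- "M"
  df
}

#' Read a melt-curve CSV
#'
#' Columns `series_id, compound, conc, conc_unit, temperature_C, signal,
#' replicate`; concentrations converted to molar.
#'
#' @param path CSV path.
#' @return data frame with `conc` in molar.
#' @export
read_melt_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("series_id", "compound", "conc", "conc_unit",
                      "temperature_C", "signal", "replicate"), path)
  df$conc <- to_molar(df$conc, df$conc_unit)
  df$conc_unit <- "M"
  df
}

#' Read a decay-series CSV
#'
#' Columns `time_min, response` (a `replicate` column is accepted and
#' averaged by the fitting routines).
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_decay_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("time_min", "response"), path)
  df
}

# strip non-serializable pieces from a fit object for JSON reports
.report_payload <- function(x) {
  if (inherits(x, c("binding_fit", "competition_fit", "covalent_fit",
                    "tagg_fit", "decay_fit"))) {
    x <- unclass(x)
  }
  drop <- c("data", "per_concentration", "fit")
  x[setdiff(names(x), drop)]
}

#' Write a machine-readable JSON fit report
#'
#' Reports carry the result payload, the run configuration, md5 checksums
#' of the inputs, and the package version, so a run can be reproduced from
#' its own report.
#'
#' @param result fit object or list.
#' @param path output JSON path.
#' @param config the run configuration to embed.
#' @param inputs character vector of input file paths to checksum.
#' @return the report list, invisibly.
#' @export
write_report <- function(result, path, config = list(), inputs = character()) {
  report <- list(
    tool = "covchar",
    version = as.character(utils::packageVersion("covchar")),
    config = config,
    input_checksums = if (length(inputs)) {
      as.list(tools::md5sum(inputs))
    } else NULL,
    result = .report_payload(result)
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(report)
}

#' Run one analysis subcommand
#'
#' Dispatch point used by the command-line wrapper; each subcommand reads
#' its CSV dialect, runs the corresponding fit, and (when `config$out` is
#' set) writes a JSON report.
#'
#' Subcommands: `fit-probe` (probe K_L from a saturation titration),
#' `fit-covalent` (full covalent FP pipeline), `fit-ic50`, `fit-gsh`,
#' `fit-melt` (DSF derivative T_m), `fit-cetsa` (Boltzmann T_agg per
#' replicate), `masscalc` (composition masses), `thermo` (K_D to
#' dG/-TdS/LE), `simulate` (synthetic dataset), `demo` (one dataset per
#' assay type).
#'
#' @param name subcommand name.
#' @param config named list; recognized fields depend on the subcommand
#'   (`input`, `out`, `seed`, `L_total`, `P_total`, `K_L`, `composition`,
#'   `K_D`, `dH`, `NHA`, `T`, `assay`, `noise`, `reference_T`).
#' @return the result object, invisibly.
#' @export
run_subcommand <- function(name, config = list()) {
  subcommands <- c("fit-probe", "fit-covalent", "fit-ic50", "fit-gsh",
                   "fit-melt", "fit-cetsa", "masscalc", "thermo",
                   "simulate", "demo")
  if (!name %in% subcommands) {
    stop("unknown subcommand '", name, "'; expected one of: ",
         paste(subcommands, collapse = ", "))
  }
  inputs <- character(0)
  result <- switch(name,
    "fit-probe" = {
      df <- read_dose_csv(config$input); inputs <- config$input
      fit_probe_KL(df, L_total = config$L_total %||% 10e-9)
    },
    "fit-covalent" = {
      df <- read_timecourse_csv(config$input); inputs <- config$input
      calib <- if (!is.null(config$A_f)) {
        anisotropy_calibration(config$A_f, config$A_b)
      } else NULL
      fit_covalent_fp(df, calib = calib,
                      L_total = config$L_total, K_L = config$K_L,
                      P_total = config$P_total)
    },
    "fit-ic50" = {
      df <- read_dose_csv(config$input); inputs <- config$input
      fit <- fit_ic50(df)
      if (!is.null(config$K_L)) {
        conv <- ic50_to_Ki(fit$IC50, L_total = config$L_total,
                           K_L = config$K_L, P_total = config$P_total)
        fit$K_i <- conv$K_i
        fit$conversion <- conv$method
      }
      fit
    },
    "fit-gsh" = {
      df <- read_decay_csv(config$input); inputs <- config$input
      fit_gsh_decay(df$time_min, df$response)
    },
    "fit-melt" = {
      df <- read_melt_csv(config$input); inputs <- config$input
      d <- .average_ties(df$temperature_C, df$signal)
      d <- d[order(d$x), ]
      dsf_tm(d$x, d$y)
    },
    "fit-cetsa" = {
      df <- read_melt_csv(config$input); inputs <- config$input
      cetsa_tagg(df, reference_T = config$reference_T %||% 40)
    },
    "masscalc" = {
      comp <- parse_composition(config$composition)
      list(composition = format(comp),
           monoisotopic_Da = as.numeric(composition_mass(comp,
                                                         "monoisotopic")),
           average_Da = as.numeric(composition_mass(comp, "average")),
           mass_table = .MASS_TABLE_PROVENANCE)
    },
    "thermo" = {
      .report_payload(thermo_record(K_D = config$K_D,
                                    T = config$T %||% 298,
                                    dH = config$dH, NHA = config$NHA))
    },
    "simulate" = {
      spec <- generator_spec(config$assay %||% "covalent_fp",
                             truth = config$truth %||% list(),
                             design = config$design %||% list(),
                             noise = config$noise,
                             seed = config$seed %||% 20231010)
      generate(spec, dir = config$out_dir %||% config$out)
    },
    "demo" = {
      types <- c("saturation_fp", "covalent_fp", "cetsa", "dsf",
                 "gsh_decay", "modification_ms")
      lapply(stats::setNames(types, types), function(a) {
        generate(generator_spec(a, seed = config$seed %||% 20231010),
                 dir = config$out_dir %||% config$out)
      })
    }
  )
  if (!is.null(config$report)) {
    write_report(result, config$report, config = config, inputs = inputs)
  }
  invisible(result)
}
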