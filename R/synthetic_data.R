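# Seeded generators emulating the tabular plate-reader layouts each
# analysis stage consumes, with known ground truth for recovery testing,
# plus benchmark tables of published biophysical values for the SOCS2
# ligand series used by the consistency suite.

#' Specification of a synthetic assay dataset
#'
#' Bundles the assay layout, the mechanistic ground truth, the measurement
#' design, the noise level, and a mandatory seed. Defaults reproduce the
#' SOCS2 covalent-ligand study conditions: 10 nM fluorescent probe with
#' `K_L` = 77.56 nM, threefold protein dilutions from 50 uM for saturation
#' titrations, twofold inhibitor dilutions for covalent displacement with
#' `k_inact` = 2.1e-4 s^-1, `K_I` = 3.6 uM and reversible `K_i` = 1.1 uM,
#' a 16-point 40-72 C CETSA grid, a 1 C 25-95 C DSF ramp, and
#' glutathione decay sampled over two hours.
#'
#' @param assay_type one of `"saturation_fp"`, `"covalent_fp"`, `"cetsa"`,
#'   `"dsf"`, `"gsh_decay"`, `"modification_ms"`.
#' @param truth named list overriding ground-truth parameters.
#' @param design named list overriding the measurement design
#'   (concentration/time/temperature grids, replicate count).
#' @param noise additive Gaussian standard deviation on the instrument
#'   observable (anisotropy, luminescence, fluorescence, or peak-area
#'   ratio), >= 0.
#' @param seed integer seed; the same spec and seed give byte-identical
#'   output.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(assay_type = c("saturation_fp", "covalent_fp",
                                          "cetsa", "dsf", "gsh_decay",
                                          "modification_ms"),
                           truth = list(), design = list(), noise = NULL,
                           seed = 20231010) {
  assay_type <- match.arg(assay_type)
  def <- .generator_defaults(assay_type)
  truth <- utils::modifyList(def$truth, truth)
  design <- utils::modifyList(def$design, design)
  noise <- noise %||% def$noise
  .assert_num(noise, "noise", nonneg = TRUE, len = 1)
  .assert_num(seed, "seed", len = 1)
  .validate_design(assay_type, design)
  structure(list(assay_type = assay_type, truth = truth, design = design,
                 noise = noise, seed = as.integer(seed)),
            class = "generator_spec")
}

.generator_defaults <- function(assay_type) {
  switch(assay_type,
    saturation_fp = list(
      truth = list(K_L = 77.56e-9, A_f = 20, A_b = 120),
      design = list(
        P_total = c(50e-6 / 3^(0:11), 0),  # threefold dilution from 50 uM
        L_total = 10e-9, replicates = 3
      ),
      noise = 1  # milli-anisotropy
    ),
    covalent_fp = list(
      truth = list(k_inact = 2.1e-4, K_I = 3.6e-6, K_i = 1.1e-6,
                   K_L = 77.56e-9, A_f = 20, A_b = 120),
      design = list(
        I_total = 50e-6 / 2^(0:10),        # twofold dilution from 50 uM
        E_total = 100e-9, L_total = 10e-9,
        times = seq(0, 3600, by = 120), replicates = 3
      ),
      noise = 0.5
    ),
    cetsa = list(
      truth = list(T_agg0 = 51, max_shift = 4, EC50 = 2.5e-6,
                   top = 100, bottom = 5, slope_factor = -2.2,
                   L0 = 1000),
      design = list(
        temperatures = seq(40, 72, length.out = 16),
        conc = c(50e-6 / 3^(0:7), 0), replicates = 3
      ),
      noise = 10  # raw luminescence units (L0 = 1000 at 40 C)
    ),
    dsf = list(
      truth = list(T_m = 50, shift = 6, base = 100, amplitude = 900,
                   slope_factor = 2),
      design = list(temperatures = seq(25, 95, by = 1), replicates = 3),
      noise = 5  # fluorescence units
    ),
    gsh_decay = list(
      truth = list(C0 = 1.0, k_e = log(2) / 70),  # half-life 70 min
      design = list(times = c(0, 5, 10, 15, 30, 45, 60, 90, 120),
                    replicates = 1),
      noise = 0.02
    ),
    modification_ms = list(
      truth = list(k = log(20) / 7200),  # 95% occupancy within 2 h
      design = list(times = seq(0, 7200, by = 600), replicates = 1),
      noise = 0.02
    )
  )
}

.validate_design <- function(assay_type, design) {
  bad <- function(msg) stop("design violates the ", assay_type,
                            " stage preconditions: ", msg)
  switch(assay_type,
    saturation_fp = {
      if (sum(design$P_total > 0) < 6) bad("need >= 6 protein concentrations")
      if (design$L_total <= 0) bad("probe concentration must be positive")
    },
    covalent_fp = {
      if (length(design$I_total) < 5) {
        bad("need >= 5 inhibitor concentrations")
      }
      if (length(design$times) < 4) bad("need >= 4 time points")
      if (min(design$I_total) <= 0) bad("inhibitor concentrations must be > 0")
    },
    cetsa = {
      if (length(design$temperatures) < 8) bad("need >= 8 temperatures")
      if (sum(design$conc > 0) < 5) bad("need >= 5 nonzero concentrations")
    },
    dsf = {
      if (length(design$temperatures) < 8) bad("need >= 8 temperatures")
    },
    gsh_decay = ,
    modification_ms = {
      if (length(design$times) < 4) bad("need >= 4 time points")
    }
  )
  invisible(NULL)
}

#' Generate a synthetic dataset with known ground truth
#'
#' Draws one dataset from the forward model of the targeted assay stage
#' with additive Gaussian noise on the instrument observable. Identical
#' spec and seed yield byte-identical output. Optionally writes the CSV
#' (in the consuming module's dialect) and a `truth.json` ground-truth
#' record to a directory.
#'
#' @param spec a [generator_spec()].
#' @param dir optional output directory; created if missing.
#' @return list with `data` (data frame in the stage's CSV dialect),
#'   `truth` (ground-truth record including the seed and design), and, if
#'   `dir` was given, `paths`.
#' @export
generate <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  data <- .with_seed(spec$seed, .generate_data(spec))
  truth <- list(assay_type = spec$assay_type, truth = spec$truth,
                design = spec$design, noise = spec$noise, seed = spec$seed)
  out <- list(data = data, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    csv <- file.path(dir, paste0(spec$assay_type, ".csv"))
    js <- file.path(dir, paste0(spec$assay_type, "_truth.json"))
    utils::write.csv(data, csv, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    out$paths <- c(data = csv, truth = js)
  }
  out
}

.generate_data <- function(spec) {
  tr <- spec$truth
  de <- spec$design
  sd <- spec$noise
  switch(spec$assay_type,
    saturation_fp = {
      calib <- anisotropy_calibration(tr$A_f, tr$A_b)
      grid <- expand.grid(replicate = seq_len(de$replicates),
                          concentration = de$P_total)
      mu <- anisotropy_from_fraction(
        probe_bound_fraction(grid$concentration, de$L_total, tr$K_L), calib)
      data.frame(
        series_id = "saturation_fp",
        concentration = grid$concentration,
        concentration_unit = "M",
        response = mu + stats::rnorm(nrow(grid), 0, sd),
        response_type = "anisotropy",
        replicate = grid$replicate
      )
    },
    covalent_fp = {
      calib <- anisotropy_calibration(tr$A_f, tr$A_b)
      grid <- expand.grid(replicate = seq_len(de$replicates),
                          time_s = de$times, inhibitor_conc = de$I_total)
      fb0 <- vapply(grid$inhibitor_conc, function(I) {
        competitive_equilibrium(de$E_total, de$L_total, I,
                                tr$K_L, tr$K_i)$fb
      }, 0)
      kobs <- tr$k_inact * grid$inhibitor_conc /
        (tr$K_I + grid$inhibitor_conc)
      fb <- fb0 * exp(-kobs * grid$time_s)
      data.frame(
        series_id = "covalent_fp",
        inhibitor_conc = grid$inhibitor_conc,
        conc_unit = "M",
        time_s = grid$time_s,
        response = anisotropy_from_fraction(fb, calib) +
          stats::rnorm(nrow(grid), 0, sd),
        replicate = grid$replicate
      )
    },
    cetsa = {
      grid <- expand.grid(replicate = seq_len(de$replicates),
                          temperature_C = de$temperatures,
                          conc = de$conc)
      Tagg <- tr$T_agg0 + tr$max_shift * grid$conc / (tr$EC50 + grid$conc)
      frac <- tr$bottom + (tr$top - tr$bottom) /
        (1 + exp((Tagg - grid$temperature_C) / tr$slope_factor))
      lum <- tr$L0 * frac / 100
      data.frame(
        series_id = "cetsa",
        compound = "inhibitor",
        conc = grid$conc,
        conc_unit = "M",
        temperature_C = grid$temperature_C,
        signal = lum + stats::rnorm(nrow(grid), 0, sd),
        replicate = grid$replicate
      )
    },
    dsf = {
      grid <- expand.grid(replicate = seq_len(de$replicates),
                          temperature_C = de$temperatures,
                          condition = c("apo", "ligand"))
      Tm <- ifelse(grid$condition == "apo", tr$T_m, tr$T_m + tr$shift)
      mu <- tr$base + tr$amplitude /
        (1 + exp((Tm - grid$temperature_C) / tr$slope_factor))
      data.frame(
        series_id = "dsf",
        compound = as.character(grid$condition),
        conc = ifelse(grid$condition == "apo", 0, 100e-6),
        conc_unit = "M",
        temperature_C = grid$temperature_C,
        signal = mu + stats::rnorm(nrow(grid), 0, sd),
        replicate = grid$replicate
      )
    },
    gsh_decay = {
      grid <- expand.grid(replicate = seq_len(de$replicates),
                          time_min = de$times)
      mu <- tr$C0 * exp(-tr$k_e * grid$time_min)
      data.frame(
        time_min = grid$time_min,
        response = mu + stats::rnorm(nrow(grid), 0, sd),
        replicate = grid$replicate
      )
    },
    modification_ms = {
      grid <- expand.grid(replicate = seq_len(de$replicates),
                          time_s = de$times)
      mu <- 1 - exp(-tr$k * grid$time_s)
      data.frame(
        time_s = grid$time_s,
        response = mu + stats::rnorm(nrow(grid), 0, sd),
        replicate = grid$replicate
      )
    }
  )
}

#' Published benchmark values for the SOCS2 ligand series
#'
#' Fixture tables of reported biophysical measurements used by the
#' package's internal-consistency suite: the first-round dissociation
#' constants with ligand efficiencies (NMR and SPR), the second-round
#' SPR/ITC thermodynamic characterization (K_D, dG, dH, -TdS, LE), and the
#' headline covalent-inhibition parameters of the chloroacetamide ligand
#' (k_inact, K_I, covalent efficiency, probe K_L, reversible K_i at time
#' zero, glutathione half-life lower bound, covalent adduct mass, DSF
#' shift).
#'
#' @param table one of `"round1"`, `"round2"`, `"headline"`, or `"all"`
#'   (default) for the full fixture set.
#' @return a data frame, or for `"all"` a named list of the three tables.
#' @export
socs2_benchmarks <- function(table = c("all", "round1", "round2",
                                       "headline")) {
  table <- match.arg(table)
  path <- function(f) system.file("extdata", f, package = "covchar",
                                  mustWork = TRUE)
  r1 <- utils::read.csv(path("socs2_round1_kd.csv"))
  r2 <- utils::read.csv(path("socs2_round2_thermo.csv"))
  hd <- utils::read.csv(path("socs2_headline.csv"))
  switch(table,
         round1 = r1, round2 = r2, headline = hd,
         all = list(round1 = r1, round2 = r2, headline = hd))
}
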