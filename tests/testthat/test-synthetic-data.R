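test_that("generation is deterministic: same seed, identical bytes", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (assay in c("covalent_fp", "cetsa")) {
    g1 <- generate(generator_spec(assay, seed = 99), dir = d1)
    g2 <- generate(generator_spec(assay, seed = 99), dir = d2)
    expect_identical(g1$data, g2$data)
    expect_identical(unname(tools::md5sum(g1$paths[["data"]])),
                     unname(tools::md5sum(g2$paths[["data"]])))
  }
  # a different seed changes the data
  g3 <- generate(generator_spec("covalent_fp", seed = 100))
  expect_false(identical(g3$data$response,
                         generate(generator_spec("covalent_fp",
                                                 seed = 99))$data$response))
})

test_that("the generator refuses designs that violate stage preconditions", {
  expect_error(generator_spec("saturation_fp",
                              design = list(P_total = c(1e-6, 1e-7))),
               "preconditions")
  expect_error(generator_spec("covalent_fp",
                              design = list(times = c(0, 60))),
               "preconditions")
  expect_error(generator_spec("cetsa",
                              design = list(temperatures = 40:44)),
               "preconditions")
  expect_error(generator_spec("covalent_fp", noise = -1), ">= 0")
})

test_that("generated datasets carry the schema their consumers expect", {
  dir <- withr::local_tempdir()
  g <- generate(generator_spec("saturation_fp", seed = 5), dir = dir)
  expect_s3_class(read_dose_csv(g$paths[["data"]]), "data.frame")
  g <- generate(generator_spec("covalent_fp", seed = 5), dir = dir)
  expect_s3_class(read_timecourse_csv(g$paths[["data"]]), "data.frame")
  g <- generate(generator_spec("cetsa", seed = 5), dir = dir)
  expect_s3_class(read_melt_csv(g$paths[["data"]]), "data.frame")
  g <- generate(generator_spec("gsh_decay", seed = 5), dir = dir)
  expect_s3_class(read_decay_csv(g$paths[["data"]]), "data.frame")
  # the truth record carries every ground-truth parameter
  truth <- jsonlite::read_json(g$paths[["truth"]], simplifyVector = TRUE)
  expect_true(all(c("C0", "k_e") %in% names(truth$truth)))
  expect_identical(truth$seed, 5L)
})

test_that("noise-free generation inverts exactly through each fit", {
  cal <- default_calib()

  g <- generate(generator_spec("saturation_fp", noise = 0, seed = 1))
  expect_equal(fit_probe_KL(g$data, L_total = 10e-9)$K_L, 77.56e-9,
               tolerance = 1e-6)

  g <- generate(generator_spec("covalent_fp", noise = 0, seed = 1))
  cf <- fit_covalent_fp(g$data, calib = cal, L_total = 10e-9,
                        K_L = 77.56e-9, P_total = 100e-9)
  expect_equal(cf$k_inact, 2.1e-4, tolerance = 1e-3)
  expect_equal(cf$K_I, 3.6e-6, tolerance = 1e-3)

  g <- generate(generator_spec("cetsa", noise = 0, seed = 1))
  top <- g$data[g$data$conc == 0, ]
  expect_equal(cetsa_tagg(top)$T_agg_mean, 51, tolerance = 1e-4)

  g <- generate(generator_spec("dsf", noise = 0, seed = 1))
  apo <- g$data[g$data$compound == "apo" & g$data$replicate == 1, ]
  expect_lt(abs(dsf_tm(apo$temperature_C, apo$signal)$T_agg - 50), 0.5)

  g <- generate(generator_spec("gsh_decay", noise = 0, seed = 1))
  expect_equal(fit_gsh_decay(g$data$time_min, g$data$response)$k_e,
               log(2) / 70, tolerance = 1e-6)

  g <- generate(generator_spec("modification_ms", noise = 0, seed = 1))
  expect_equal(fit_modification_timecourse(g$data$time_s,
                                           g$data$response)$k,
               log(20) / 7200, tolerance = 1e-6)
})

test_that("saturation anisotropy equals the forward model exactly at zero noise", {
  g <- generate(generator_spec("saturation_fp", noise = 0, seed = 8))
  d <- g$data[g$data$replicate == 1, ]
  cal <- default_calib()
  expect_equal(d$response,
               saturation_curve(d$concentration, 10e-9, 77.56e-9,
                                cal)$response,
               tolerance = 1e-12)
})

test_that("estimator bias over many seeded replicates is small", {
  cal <- default_calib()
  fits <- lapply(1:100, function(s) {
    g <- generate(generator_spec("covalent_fp", seed = 1000 + s))
    suppressWarnings(
      fit_covalent_fp(g$data, calib = cal, L_total = 10e-9,
                      K_L = 77.56e-9, P_total = 100e-9)
    )
  })
  kin <- vapply(fits, `[[`, 0, "k_inact")
  KI <- vapply(fits, `[[`, 0, "K_I")
  expect_lt(abs(stats::median(kin) - 2.1e-4) / 2.1e-4, 0.15)
  expect_lt(abs(stats::median(KI) - 3.6e-6) / 3.6e-6, 0.15)
})

test_that("benchmark fixtures are complete and stable", {
  all <- socs2_benchmarks()
  expect_named(all, c("round1", "round2", "headline"))
  expect_equal(nrow(all$round1), 8)
  expect_equal(nrow(all$round2), 6)
  expect_gte(nrow(all$headline), 15)
  r1 <- socs2_benchmarks("round1")
  expect_equal(r1$KD_nmr_uM[r1$compound == 5], 32)
  expect_equal(r1$KD_spr_uM[r1$compound == 5], 49)
  hd <- socs2_benchmarks("headline")
  expect_equal(hd$value[hd$parameter == "k_inact"], 2.1e-4)
  expect_equal(hd$value[hd$parameter == "K_I"], 3.6e-6)
})
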