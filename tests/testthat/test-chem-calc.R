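test_that("binding free energy and entropy arithmetic", {
  expect_equal(delta_g(1), 0)
  # frozen values computed independently: RT ln(KD) at 298 K
  expect_equal(delta_g(0.38e-6), -8.7544, tolerance = 1e-4)
  expect_equal(delta_g(1.1e-6), -8.1249, tolerance = 1e-4)
  # strictly increasing in K_D
  kd <- 10^seq(-9, -3, length.out = 20)
  expect_true(all(diff(delta_g(kd)) > 0))

  expect_equal(entropy_term(-5, -5), 0)
  expect_equal(entropy_term(-8.75, -7.13), -1.62)
  expect_equal(entropy_term(-8.12, -5.81), -2.31)
})

test_that("ligand efficiency reproduces published fragment values", {
  # free phosphotyrosine: KD 190 uM over 17 heavy atoms
  expect_equal(ligand_efficiency(190e-6, 17), 0.2985, tolerance = 1e-3)
  expect_lt(abs(ligand_efficiency(190e-6, 17) - 0.29), 0.01)
  # capped analog: KD 186 uM over 21 heavy atoms
  expect_equal(ligand_efficiency(186e-6, 21), 0.2422, tolerance = 1e-3)
  expect_lt(abs(ligand_efficiency(186e-6, 21) - 0.24), 0.01)

  expect_equal(ligand_efficiency(1, 30), 0)
  # strictly decreasing in heavy-atom count
  le <- vapply(10:30, function(n) ligand_efficiency(1e-6, n), 0)
  expect_true(all(diff(le) < 0))
})

test_that("thermo records are internally consistent", {
  r <- thermo_record(0.38e-6, dH = -7.13, NHA = 30)
  expect_equal(r$dG, delta_g(0.38e-6), tolerance = 1e-9)
  expect_equal(r$minusTdS, r$dG - r$dH, tolerance = 1e-9)
  expect_equal(r$LE, -r$dG / r$NHA, tolerance = 1e-9)
})

test_that("published thermodynamic table rows are mutually consistent", {
  tab <- socs2_benchmarks("round2")
  expect_equal(nrow(tab), 6)
  for (i in seq_len(nrow(tab))) {
    dg <- delta_g(tab$KD_itc_uM[i] * 1e-6)
    expect_lt(abs(dg - tab$dG_kcal_mol[i]), 0.05)
    expect_lt(abs((tab$dG_kcal_mol[i] - tab$dH_kcal_mol[i]) -
                    tab$minusTdS_kcal_mol[i]), 0.05)
  }
})

test_that("composition parser handles both dialects and reports errors", {
  expect_identical(unclass(parse_composition("H(2)O")),
                   c(H = 2L, O = 1L))
  expect_identical(unclass(parse_composition("C2H3NO")),
                   c(C = 2L, H = 3L, N = 1L, O = 1L))
  expect_identical(unclass(parse_composition("Se(-1)S")),
                   c(Se = -1L, S = 1L))

  full <- parse_composition("C(26)H(25)N(3)O(7)FPSe(-1)S")
  expect_equal(unclass(full)[c("C", "H", "N", "O", "F", "P", "Se", "S")],
               c(C = 26L, H = 25L, N = 3L, O = 7L, F = 1L, P = 1L,
                 Se = -1L, S = 1L))

  expect_error(parse_composition("C(26)Qq(2)"), "unknown element")
  expect_error(parse_composition("C(x)"), "position")
  expect_error(parse_composition(""), "non-empty")
})

test_that("composition serialization round-trips canonically", {
  set.seed(23)
  els <- c("C", "H", "N", "O", "S", "Se", "Cl", "P", "F")
  for (i in 1:25) {
    n <- sample(2:6, 1)
    cnt <- sample(c(-3:-1, 1:40), n, replace = TRUE)
    comp <- structure(stats::setNames(as.integer(cnt), sample(els, n)),
                      class = "composition")
    rt <- unclass(parse_composition(format(comp)))
    orig <- unclass(comp)
    expect_identical(rt[order(names(rt))], orig[order(names(orig))])
  }
})

test_that("composition masses match independent calculations and add up", {
  # frozen values from an independent proteomics mass calculator
  expect_equal(as.numeric(composition_mass(parse_composition("H(2)O"))),
               18.0105646, tolerance = 1e-6)
  expect_equal(
    as.numeric(composition_mass(parse_composition("C(2)H(3)NO"))),
    57.0214637, tolerance = 1e-6
  )
  adduct <- parse_composition("C(26)H(25)N(3)O(7)FP")
  expect_equal(as.numeric(composition_mass(adduct, "monoisotopic")),
               541.1414, tolerance = 1e-4)
  expect_equal(as.numeric(composition_mass(adduct, "average")),
               541.47, tolerance = 1e-2)

  # additivity to machine precision
  a <- parse_composition("C(6)H(12)O(6)")
  b <- parse_composition("H(2)SO(4)")
  expect_equal(
    as.numeric(composition_mass(composition_combine(a, b))),
    as.numeric(composition_mass(a)) + as.numeric(composition_mass(b)),
    tolerance = 1e-12
  )
})

test_that("covalent adduct bookkeeping matches the search-engine record", {
  ligand <- parse_composition("C(26)H(26)ClFN(3)O(7)P")
  adduct <- covalent_adduct_composition(ligand, parse_composition("HCl"))
  expect_identical(format(adduct), "C(26)H(25)FN(3)O(7)P")

  # the proteomics modification encodes the same adduct on a placeholder
  # residue: composition + S - Se recovers the bare adduct
  mq <- parse_composition("C(26)H(25)N(3)O(7)FPSe(-1)S")
  bare <- composition_combine(composition_combine(mq,
                                                  parse_composition("Se")),
                              parse_composition("S"), sign = -1L)
  expect_identical(format(bare), format(adduct))

  expect_identical(format(covalent_adduct_composition(
    ligand, parse_composition("H"))), "C(26)H(25)ClFN(3)O(7)P")
  expect_error(covalent_adduct_composition(ligand,
                                           parse_composition("Br")),
               "ligand provides")
})

test_that("glutathione decay: identities, recovery, non-reactive flag", {
  # Arrhenius-free arithmetic: T_half * k_e = ln 2 by construction
  tt <- c(0, 10, 20, 40, 60, 90, 120)
  fit <- fit_gsh_decay(tt, 1.0 * exp(-0.00990 * tt))
  expect_equal(fit$k_e, 0.00990, tolerance = 1e-6)
  expect_equal(fit$T_half, 70.0, tolerance = 1e-2)
  expect_equal(fit$T_half * fit$k_e, log(2), tolerance = 1e-12)
  # the fitted curve halves at T_half exactly
  expect_equal(fit$C0 * exp(-fit$k_e * fit$T_half), fit$C0 / 2,
               tolerance = 1e-12)

  g <- generate(generator_spec("gsh_decay",
                               truth = list(C0 = 1, k_e = 0.005),
                               seed = 31))
  fit <- fit_gsh_decay(g$data$time_min, g$data$response)
  expect_lt(abs(fit$k_e - 0.005) / 0.005, 0.10)

  expect_warning(fit <- fit_gsh_decay(tt, 1 + 0.002 * tt), "non-reactive")
  expect_identical(fit$T_half, Inf)
  expect_true("non_reactive" %in% fit$flags)
})
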