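# covchar

Quantitative characterization of covalent small-molecule ligands, built
around the assay suite used for cysteine-directed SH2-domain inhibitors
(the motivating system is a chloroacetamide ligand of the SOCS2 E3-ligase
SH2 domain that covalently engages a cysteine in the EF loop).

Covalent inhibitors bind reversibly before reacting:

    E + I  <=>[K_i]  E·I  --k_inact-->  E–I (irreversible)

Their potency is not a single affinity but the pair (k_inact, K_I) — or
the second-order efficiency k_inact/K_I — measured from the
concentration dependence of the observed inactivation rate:

    k_obs = k_inact [I] / (K_I + [I])

covchar implements the full pipeline from plate-reader tables to these
parameters, plus the surrounding assays used in the same campaign:

- **Equilibrium probe binding** — anisotropy ↔ bound fraction, the exact
  one-site binding quadratic with ligand depletion, probe K_L fitting,
  four-parameter-logistic IC50, and the depletion-corrected IC50 → K_i
  conversion for FP competition.
- **Covalent FP kinetics** — per-concentration early-window linearization
  to (F_b0, k_obs) with a first-order window correction, precision-
  weighted saturation fit for k_inact and K_I, linear-regime efficiency
  (k_obs = (k_inact/K_I)[I]), reversible K_i at t = 0 from the intercepts,
  a mass-action ODE simulator of the full mechanism, and pseudo-first-
  order modification kinetics (f(t) = 1 − e^(−kt), t95 = ln 20 / k).
- **Thermal shift** — DSF T_m by the smoothed first-derivative extremum;
  CETSA percent-stabilized normalization, Boltzmann T_agg fitting, and the
  EC50 of the dose-dependent T_agg shift.
- **Chem/thermo arithmetic** — ΔG = RT ln K_D, −TΔS = ΔG − ΔH, ligand
  efficiency −ΔG/NHA, glutathione-reactivity half-life (C_t = C_0 e^(−k_e t),
  T_1/2 = ln 2 / k_e), and signed elemental-composition parsing with
  monoisotopic/average mass computation for covalent adducts.
- **Synthetic data** — seeded generators for every assay layout with known
  ground truth, so the entire pipeline is testable offline.

## Worked example

Generate a covalent FP dataset at the study's ground truth
(k_inact = 2.1e-4 s⁻¹, K_I = 3.6 µM, reversible K_i = 1.1 µM, probe
K_L = 77.56 nM) and recover the parameters:

```r
library(covchar)

cal <- anisotropy_calibration(A_f = 20, A_b = 120)
sim <- generate(generator_spec("covalent_fp", seed = 101))
head(sim$data, 3)
#>     series_id inhibitor_conc conc_unit time_s response replicate
#> 1 covalent_fp          5e-05         M      0 22.53587         1
#> 2 covalent_fp          5e-05         M      0 22.97511         2
#> 3 covalent_fp          5e-05         M      0 22.36141         3

fit_covalent_fp(sim$data, calib = cal, L_total = 10e-9,
                K_L = 77.56e-9, P_total = 100e-9)
#> Covalent inhibition fit (saturation regime)
#>   k_inact = 0.0002055 s^-1, K_I = 3.466e-06 M
#>   k_inact/K_I = 59.28 M^-1 s^-1
#>   K_i(t=0) = 1.086e-06 M
```

The fitted maximal inactivation rate, half-saturation concentration,
covalent efficiency, and time-zero reversible affinity all land within a
few percent of the generating truth at realistic noise. The probe
constant comes from a saturation titration the same way:

```r
sat <- generate(generator_spec("saturation_fp", seed = 102))
fit_probe_KL(sat$data, L_total = 10e-9)
#> One-site probe binding fit (depletion-corrected)
#>   K_L = 8.16e-08 M (SE 1.9e-09)
#>   A_f = 20.56, A_b = 120.7
```

Adduct mass bookkeeping (chloroacetamide + cysteine thiol → thioether +
HCl) and thermodynamic records:

```r
adduct <- covalent_adduct_composition(
  parse_composition("C(26)H(26)ClFN(3)O(7)P"),  # intact ligand
  parse_composition("HCl"))                      # leaving group
adduct
#> <composition> C(26)H(25)FN(3)O(7)P
composition_mass(adduct, "average")      # 541.47 Da
composition_mass(adduct, "monoisotopic") # 541.14 Da

thermo_record(0.38e-6, dH = -7.13, NHA = 37)
#> K_D = 3.8e-07 M at 298 K: dG = -8.75 kcal/mol, dH = -7.13,
#> -TdS = -1.62, LE = 0.24 kcal/mol/NHA
```

A thin command-line wrapper over the same functions lives at
`inst/cli/covchar.R`:

```sh
Rscript inst/cli/covchar.R masscalc --composition "C(26)H(25)N(3)O(7)FP"
Rscript inst/cli/covchar.R simulate --seed 7 --out datadir
Rscript inst/cli/covchar.R fit-covalent --input datadir/covalent_fp.csv \
        --config config.json --out report.json
```

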