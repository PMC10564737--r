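# Independent oracles used to derive expected values; deliberately
# implemented with different numerics than the package routines.

# Brute-force three-species competitive equilibrium: minimize squared
# mass-balance residuals over log free concentrations (contrast with the
# package's single bracketed root solve).
oracle_equilibrium <- function(E_total, P_total, I_total, K_L, K_i) {
  if (I_total == 0) {
    x <- oracle_bound_fraction(E_total, P_total, K_L)
    EP <- x * P_total
    return(list(E = E_total - EP, P = P_total - EP, I = 0, EP = EP,
                EI = 0, fb = x, value = 0))
  }
  obj <- function(lx) {
    E <- exp(lx[1]); P <- exp(lx[2]); I <- exp(lx[3])
    EP <- E * P / K_L
    EI <- E * I / K_i
    sum(((E + EP + EI - E_total) / E_total)^2,
        ((P + EP - P_total) / P_total)^2,
        if (I_total > 0) ((I + EI - I_total) / I_total)^2 else 0)
  }
  st <- log(pmax(c(E_total, P_total, max(I_total, E_total * 1e-6)), 1e-30) / 2)
  o <- stats::optim(st, obj, method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-16))
  E <- exp(o$par[1]); P <- exp(o$par[2]); I <- exp(o$par[3])
  EP <- E * P / K_L
  list(E = E, P = P, I = I, EP = EP, EI = E * I / K_i,
       fb = EP / P_total, value = o$value)
}

# Single-site bound probe fraction by bracketed root finding on the
# mass-balance equation (oracle for the closed-form quadratic).
oracle_bound_fraction <- function(P_total, L_total, K_L) {
  f <- function(PL) {
    (P_total - PL) * (L_total - PL) / K_L - PL
  }
  PL <- stats::uniroot(f, c(0, min(P_total, L_total)),
                       tol = min(P_total, L_total) * 1e-13)$root
  PL / L_total
}

# Total inhibitor concentration at which the equilibrium bound probe is
# half its uninhibited value (oracle IC50 for the competition fit).
oracle_ic50 <- function(E_total, L_total, K_L, K_i,
                        upper = 1) {
  fb0 <- oracle_equilibrium(E_total, L_total, 0, K_L, K_i)$fb
  f <- function(I) {
    oracle_equilibrium(E_total, L_total, I, K_L, K_i)$fb - fb0 / 2
  }
  stats::uniroot(f, c(K_i * 1e-4, upper), tol = K_i * 1e-9)$root
}

default_calib <- function() anisotropy_calibration(A_f = 20, A_b = 120)
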