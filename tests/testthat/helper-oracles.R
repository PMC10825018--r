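# Shared fixtures and independent oracles used across the test files.

baseline <- function() metabolite_condition(5, 1, "Baseline")

# Independently hand-coded right-hand side of the model ODEs, written
# directly from the printed rate laws (kept deliberately separate from the
# package implementation).
oracle_rhs <- function(y, L, dLdt, params, config, condition) {
  B <- y[1]; C <- y[2]; xB <- y[3]; xC <- y[4]
  atp <- condition$atp; pi_ <- condition$pi
  # metabolite scaling
  if (config$pi_method == "M1") {
    km1 <- params$km1_0 * pi_
    k2 <- params$k2_0
  } else {
    km1 <- params$km1_0 * pi_ / (params$kd_Pi + pi_)
    k2 <- params$k2_0 * params$kd_Pi / (params$kd_Pi + pi_)
  }
  if (config$atp_method == "M1") {
    k3 <- params$k3_0 * atp
    km2 <- params$km2_0
  } else {
    k3 <- params$k3_0 * atp / (params$kd_ATP + atp)
    km2 <- params$km2_0 * params$kd_ATP / (params$kd_ATP + atp)
  }
  k1 <- params$k1
  km3 <- params$km3
  # strain scaling
  ph <- function(nm) {
    if (nm %in% config$strain && nm %in% names(params$phi_s)) {
      params$phi_s[[nm]]
    } else 0
  }
  k1 <- k1 * exp(-ph("k1") * xB)
  km1 <- km1 * exp(ph("km1") * xB)
  k2 <- k2 * exp(-ph("k2") * xB)
  km2 <- km2 * exp(ph("km2") * (xC - params$xC0))
  k3 <- k3 * exp(ph("k3") * (xC - params$xC0))
  Z <- if (L < params$Lmax) 1 + params$phi_l * (L / params$Lmax - 1) else 1
  A <- Z - B - C
  c(k1 * A - (km1 + k2) * B + km2 * C,
    k2 * B - (km2 + k3) * C + km3 * A,
    -(params$phi_x / max(B, 1e-9)) * (k1 * A + km2 * C) * xB +
      params$phi_v * dLdt,
    -(params$phi_x / max(C, 1e-9)) * (k2 * B + km3 * A) *
      (xC - params$xC0) + params$phi_v * dLdt)
}

# Random admissible parameter draw for a permutation (rates of the order of
# the fitted rat values; strain sensitivities within the linear-regime range
# probed by the 0.05 % amplitude protocol).
draw_params <- function(config, seed) {
  set.seed(seed)
  lu <- function(lo, hi) 10^stats::runif(1, log10(lo), log10(hi))
  pi_m1 <- config$pi_method == "M1"
  atp_m1 <- config$atp_method == "M1"
  phi_s <- numeric(0)
  for (r in config$strain) phi_s[r] <- lu(50, 1000)
  kinetic_params(
    k1 = lu(3, 30),
    km1_0 = if (pi_m1) lu(0.5, 10) else lu(2, 40),
    k2_0 = lu(3, 30),
    km2_0 = lu(0.3, 5),
    k3_0 = if (atp_m1) lu(0.3, 5) else lu(2, 30),
    km3 = 0,
    kd_ATP = if (atp_m1) NA_real_ else lu(0.5, 10),
    kd_Pi = if (pi_m1) NA_real_ else lu(1, 20),
    phi_x = lu(3, 20), phi_v = lu(0.03, 0.25), phi_l = lu(1, 5),
    K = lu(1000, 6000), Ks = lu(10, 100), phi_s = phi_s)
}

# complex modulus values as complex vectors for easy comparison
as_complex <- function(spec) {
  complex(real = spec$elastic_kpa, imaginary = spec$viscous_kpa)
}
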