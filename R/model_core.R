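# Nonlinear three-state cross-bridge model: rate laws with metabolite and
# strain scaling, ODE right-hand side, active stress, analytic steady state.
#
# State vector ordering throughout: (B, C, xB, xC) where B and C are the
# occupancies of the pre- and post-power-stroke attached states and xB, xC
# the mean cross-bridge strains in those states (um).

# occupancy floor used when dividing by B or C in the mean-strain ODEs
OCCUPANCY_FLOOR <- 1e-9

#' Cross-bridge availability as a function of sarcomere length
#'
#' Fraction of cross-bridges able to bind at sarcomere length `L`:
#' `Z = 1 + phi_l * (L/Lmax - 1)` on the ascending limb (`L < Lmax`) and 1 on
#' the plateau (`Lmax <= L <= 2.4`).  The model is not defined beyond 2.4 um
#' (descending limb).
#'
#' @param L sarcomere length, um
#' @param phi_l unitless length sensitivity
#' @param Lmax plateau onset length, um
#' @return availability fraction Z
#' @export
availability <- function(L, phi_l, Lmax = 2.3) {
  if (any(L > 2.4)) {
    stop("availability: model undefined for sarcomere lengths > 2.4 um",
         call. = FALSE)
  }
  if (any(L <= 0)) stop("availability: L must be positive", call. = FALSE)
  Z <- ifelse(L < Lmax, 1 + phi_l * (L / Lmax - 1), 1)
  if (any(Z < 0)) {
    stop("availability: negative availability; `phi_l` too steep for this ",
         "length", call. = FALSE)
  }
  Z
}

#' @keywords internal
availability_slope <- function(L, phi_l, Lmax = 2.3) {
  ifelse(L < Lmax, phi_l / Lmax, 0)
}

#' Metabolite-scaled (zero-strain) transition rates
#'
#' Applies the configured metabolite dependence to the primed base rates.
#' Method 1 (direct dependence): `k-1 = k-1' * [Pi]`, `k3 = k3' * [ATP]`,
#' with k2 and k-2 unchanged.  Method 2 (rapid equilibrium): both rates
#' leaving the binding state are scaled by saturation fractions,
#' `k-1 = k-1' * [Pi]/(kd_Pi + [Pi])`, `k2 = k2' * kd_Pi/(kd_Pi + [Pi])`,
#' `k-2 = k-2' * kd_ATP/(kd_ATP + [ATP])`, `k3 = k3' * [ATP]/(kd_ATP + [ATP])`.
#' k1 and k-3 are never metabolite-scaled.
#'
#' @param params a [kinetic_params()] object
#' @param config a [model_config()] object
#' @param condition a [metabolite_condition()] object
#' @return named numeric vector of effective zero-strain rates
#'   (`k1, km1, k2, km2, k3, km3`), 1/s
#' @export
metabolite_scaled_rates <- function(params, config, condition) {
  atp <- condition$atp
  pi_ <- condition$pi
  r <- c(k1 = params$k1, km1 = params$km1_0, k2 = params$k2_0,
         km2 = params$km2_0, k3 = params$k3_0, km3 = params$km3)
  if (config$pi_method == "M1") {
    r[["km1"]] <- params$km1_0 * pi_
  } else {
    kd <- params$kd_Pi
    if (is.na(kd)) stop("Method 2 for Pi requires `kd_Pi`", call. = FALSE)
    if (kd == 0 && pi_ == 0) {
      stop("Method 2 for Pi undefined with kd_Pi = 0 and [Pi] = 0",
           call. = FALSE)
    }
    r[["km1"]] <- params$km1_0 * pi_ / (kd + pi_)
    r[["k2"]] <- params$k2_0 * kd / (kd + pi_)
  }
  if (config$atp_method == "M1") {
    r[["k3"]] <- params$k3_0 * atp
  } else {
    kd <- params$kd_ATP
    if (is.na(kd)) stop("Method 2 for ATP requires `kd_ATP`", call. = FALSE)
    if (kd == 0 && atp == 0) {
      stop("Method 2 for ATP undefined with kd_ATP = 0 and [ATP] = 0",
           call. = FALSE)
    }
    r[["km2"]] <- params$km2_0 * kd / (kd + atp)
    r[["k3"]] <- params$k3_0 * atp / (kd + atp)
  }
  r
}

#' Strain-scaled transition rates
#'
#' Applies exponential strain dependence to the rates selected by
#' `config$strain`.  Each form is chosen so that increasing strain reduces
#' the post-power-stroke occupancy: `k1 * exp(-phi_s1 xB)`,
#' `k-1 * exp(+phi_s-1 xB)`, `k2 * exp(-phi_s2 xB)`,
#' `k-2 * exp(+phi_s-2 (xC - xC0))`, `k3 * exp(+phi_s3 (xC - xC0))`.
#' Rates not in the placement set pass through unchanged.
#'
#' @param rates0 named vector of metabolite-scaled zero-strain rates
#' @param params a [kinetic_params()] object (supplies `phi_s` and `xC0`)
#' @param config a [model_config()] object
#' @param xB,xC mean strains, um
#' @return named numeric vector of effective rates, 1/s
#' @export
strain_scaled_rates <- function(rates0, params, config, xB, xC) {
  r <- rates0
  if (!length(config$strain)) return(r)
  dxC <- xC - params$xC0
  for (nm in config$strain) {
    phi <- if (nm %in% names(params$phi_s)) params$phi_s[[nm]] else 0
    r[[nm]] <- r[[nm]] * switch(nm,
      k1  = exp(-phi * xB),
      km1 = exp(phi * xB),
      k2  = exp(-phi * xB),
      km2 = exp(phi * dxC),
      k3  = exp(phi * dxC),
      stop("strain dependence not supported on ", rate_label(nm),
           call. = FALSE)
    )
  }
  r
}

#' Right-hand side of the cross-bridge ODE system
#'
#' Mass-action kinetics for the attached-state occupancies and first-moment
#' dynamics for the mean strains:
#' `dB/dt = k1 A - (k-1 + k2) B + k-2 C`,
#' `dC/dt = k2 B - (k-2 + k3) C + k-3 A` with `A = Z(L) - B - C`,
#' `dxB/dt = -(phi_x/B)(k1 A + k-2 C) xB + phi_v dL/dt`,
#' `dxC/dt = -(phi_x/C)(k2 B + k-3 A)(xC - xC0) + phi_v dL/dt`.
#' Rates are metabolite- and strain-scaled at the current state.  The
#' divisors B and C are floored at 1e-9 so that the strain ODEs remain
#' finite when occupancies are crushed (as in the force-redevelopment
#' protocol).
#'
#' @param state numeric vector `c(B, C, xB, xC)`
#' @param L sarcomere length, um
#' @param dLdt sarcomere lengthening velocity, um/s
#' @param params,config,condition model definition
#' @param rates0 optional precomputed [metabolite_scaled_rates()] result
#' @return numeric vector `c(dB, dC, dxB, dxC)`
#' @export
ode_rhs <- function(state, L, dLdt, params, config, condition,
                    rates0 = NULL) {
  if (is.null(rates0)) {
    rates0 <- metabolite_scaled_rates(params, config, condition)
  }
  B <- state[[1]]; C <- state[[2]]; xB <- state[[3]]; xC <- state[[4]]
  k <- strain_scaled_rates(rates0, params, config, xB, xC)
  A <- availability(L, params$phi_l, params$Lmax) - B - C
  dB <- k[["k1"]] * A - (k[["km1"]] + k[["k2"]]) * B + k[["km2"]] * C
  dC <- k[["k2"]] * B - (k[["km2"]] + k[["k3"]]) * C + k[["km3"]] * A
  Bdiv <- max(B, OCCUPANCY_FLOOR)
  Cdiv <- max(C, OCCUPANCY_FLOOR)
  dxB <- -(params$phi_x / Bdiv) * (k[["k1"]] * A + k[["km2"]] * C) * xB +
    params$phi_v * dLdt
  dxC <- -(params$phi_x / Cdiv) * (k[["k2"]] * B + k[["km3"]] * A) *
    (xC - params$xC0) + params$phi_v * dLdt
  c(dB, dC, dxB, dxC)
}

#' Active stress of the model
#'
#' `F = K (B xB + C xC) + Ks max(L - L_rest, 0)`: the cross-bridge component
#' plus the cross-bridge-insensitive linear spring engaged beyond the slack
#' length (1.9 um).
#'
#' @param state numeric vector `c(B, C, xB, xC)` (or a matrix with those
#'   columns for a whole trajectory)
#' @param params a [kinetic_params()] object
#' @param L sarcomere length, um (scalar or vector matching the rows)
#' @return active stress, kPa
#' @export
active_stress <- function(state, params, L) {
  if (is.matrix(state)) {
    xb <- state[, 1] * state[, 3] + state[, 2] * state[, 4]
  } else {
    xb <- state[[1]] * state[[3]] + state[[2]] * state[[4]]
  }
  params$K * xb + params$Ks * pmax(L - params$L_rest, 0)
}

#' Analytic steady state of the model
#'
#' Occupancy fractions follow from the King-Altman rule for the three-state
#' cycle evaluated at zero-strain rates (every strain exponential equals 1 at
#' `xB = 0`, `xC = xC0`, so strain sensitivities do not move the steady
#' state).  With `k-3 = 0` the post-power-stroke fraction reduces to
#' `C = k1 k2 / [k3 (k1 + k2 + k-1) + k1 k2 + k-2 (k1 + k-1)]`.
#' Occupancies are scaled by the availability `Z(L)`; the steady-state
#' stress is `F0 = K C0 xC0 + Ks max(L - 1.9, 0)` since `xB = 0` at steady
#' state.
#'
#' @param params,config,condition model definition
#' @param L sarcomere length, um
#' @return list of class `xb_steady_state` with components `A0`, `B0`, `C0`
#'   (occupancies), `xB0` (= 0), `xC0`, `F0` (kPa), and `rates0` (the
#'   zero-strain rates used)
#' @export
steady_state <- function(params, config, condition, L = 2.2) {
  k <- metabolite_scaled_rates(params, config, condition)
  k1 <- k[["k1"]]; km1 <- k[["km1"]]; k2 <- k[["k2"]]
  km2 <- k[["km2"]]; k3 <- k[["k3"]]; km3 <- k[["km3"]]
  # King-Altman: directed spanning-tree sums for the 3-state cycle
  wA <- km1 * km2 + km1 * k3 + k2 * k3
  wB <- k1 * km2 + k1 * k3 + km3 * km2
  wC <- k1 * k2 + km3 * km1 + km3 * k2
  den <- wA + wB + wC
  if (den <= 0) {
    stop("steady_state: degenerate cycle (all spanning-tree weights zero)",
         call. = FALSE)
  }
  Z <- availability(L, params$phi_l, params$Lmax)
  B0 <- Z * wB / den
  C0 <- Z * wC / den
  A0 <- Z - B0 - C0
  F0 <- params$K * C0 * params$xC0 +
    params$Ks * max(L - params$L_rest, 0)
  structure(
    list(A0 = A0, B0 = B0, C0 = C0, xB0 = 0, xC0 = params$xC0,
         F0 = F0, L = L, Z = Z, rates0 = k),
    class = "xb_steady_state"
  )
}

#' @export
print.xb_steady_state <- function(x, ...) {
  cat(sprintf("Steady state at L = %g um (Z = %.4f)\n", x$L, x$Z))
  cat(sprintf("  A0 = %.4f  B0 = %.4f  C0 = %.4f\n", x$A0, x$B0, x$C0))
  cat(sprintf("  xB0 = %g um  xC0 = %g um  F0 = %.3f kPa\n",
              x$xB0, x$xC0, x$F0))
  invisible(x)
}

#' Check that the steady state is independent of strain sensitivities
#'
#' Every strain exponential equals one at the steady-state strains, so the
#' steady state must be identical for any values of the `phi_s` entries.
#' This recomputes the steady state with all strain sensitivities zeroed and
#' compares.
#'
#' @param params,config,condition,L as for [steady_state()]
#' @param tol equality tolerance
#' @return `TRUE` if invariant, `FALSE` otherwise
#' @export
steady_state_invariance_check <- function(params, config, condition,
                                          L = 2.2, tol = 1e-12) {
  ss <- steady_state(params, config, condition, L)
  p0 <- params
  p0$phi_s <- numeric(0)
  ss0 <- steady_state(p0, config, condition, L)
  fields <- c("A0", "B0", "C0", "xB0", "xC0", "F0")
  all(vapply(fields, function(f) {
    abs(ss[[f]] - ss0[[f]]) <= tol * max(1, abs(ss0[[f]]))
  }, logical(1)))
}
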