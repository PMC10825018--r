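# Analytic linearisation of the cross-bridge model about its steady state
# and the resulting complex modulus (frequency response).
#
# The four state ODEs are Taylor-expanded about the steady state; solving
# (jw I - J) X = b(jw) for a unit normalised-length input yields the
# transfer functions of the state variables, which are weighted into the
# complex modulus dF/dL = K (B0 HxB + C0 HxC + xC0 HC) + Ks.

#' Jacobian of the model ODEs at the steady state
#'
#' Analytic partial derivatives of the four state ODEs (ordering B, C, xB,
#' xC) with respect to the state variables and the sarcomere-length input,
#' evaluated at the steady state.  The strain-dependence contributions
#' (entries coupling occupancies to strains) are nonzero only for the
#' configured placements.  The strain rows reduce to pure relaxations:
#' `d(dxB/dt)/dxB = -phi_x (A0 k1 + C0 k-2)/B0` (equal to
#' `-phi_x (k2 + k-1)` at steady state) and
#' `d(dxC/dt)/dxC = -phi_x (B0 k2 + A0 k-3)/C0`.  The velocity coupling
#' `phi_v dL/dt` enters the frequency-domain forcing as `jw phi_v` and is
#' carried separately in `d_velocity`.
#'
#' @param params,config,condition model definition
#' @param L sarcomere length, um
#' @return list of class `xb_jacobian` with `d_state` (4x4 matrix),
#'   `d_input` (length-4 vector of direct length partials), `d_velocity`
#'   (length-4 vector multiplying jw), and the `steady_state` used
#' @export
jacobian_at_steady_state <- function(params, config, condition, L = 2.2) {
  ss <- steady_state(params, config, condition, L)
  if (ss$B0 <= 0 || ss$C0 <= 0) {
    stop("jacobian_at_steady_state: linearisation undefined with B0 or C0 ",
         "equal to zero", call. = FALSE)
  }
  k <- ss$rates0
  k1 <- k[["k1"]]; km1 <- k[["km1"]]; k2 <- k[["k2"]]
  km2 <- k[["km2"]]; k3 <- k[["k3"]]; km3 <- k[["km3"]]
  A0 <- ss$A0; B0 <- ss$B0; C0 <- ss$C0
  phi_x <- params$phi_x

  # strain sensitivity of each rate at the reference (exponentials = 1)
  phi_of <- function(nm) {
    if (nm %in% config$strain && nm %in% names(params$phi_s)) {
      params$phi_s[[nm]]
    } else 0
  }
  dk1_dxB  <- -phi_of("k1") * k1
  dkm1_dxB <-  phi_of("km1") * km1
  dk2_dxB  <- -phi_of("k2") * k2
  dkm2_dxC <-  phi_of("km2") * km2
  dk3_dxC  <-  phi_of("k3") * k3

  J <- matrix(0, 4, 4,
              dimnames = list(c("B", "C", "xB", "xC"),
                              c("B", "C", "xB", "xC")))
  J["B", "B"] <- -k1 - (km1 + k2)
  J["B", "C"] <- -k1 + km2
  J["B", "xB"] <- dk1_dxB * A0 - (dkm1_dxB + dk2_dxB) * B0
  J["B", "xC"] <- dkm2_dxC * C0
  J["C", "B"] <- k2 - km3
  J["C", "C"] <- -(km2 + k3) - km3
  J["C", "xB"] <- dk2_dxB * B0
  J["C", "xC"] <- -(dkm2_dxC + dk3_dxC) * C0
  # strain ODE rows: every non-diagonal partial carries a factor of the
  # steady-state strain deviation (xB = 0, xC - xC0 = 0) and vanishes
  J["xB", "xB"] <- -phi_x * (k1 * A0 + km2 * C0) / B0
  J["xC", "xC"] <- -phi_x * (k2 * B0 + km3 * A0) / C0

  Zp <- availability_slope(L, params$phi_l, params$Lmax)
  d_input <- c(B = k1 * Zp, C = km3 * Zp, xB = 0, xC = 0)
  d_velocity <- c(B = 0, C = 0, xB = params$phi_v, xC = params$phi_v)

  structure(list(d_state = J, d_input = d_input, d_velocity = d_velocity,
                 steady_state = ss, params = params, config = config),
            class = "xb_jacobian")
}

#' Transfer functions of the linearised model at given angular frequencies
#'
#' Solves the 4x4 complex system `(jw I - J) X = d_input + jw d_velocity`
#' for a unit normalised sarcomere-length input at each angular frequency.
#' One generic solve covers every model permutation; the closed-form
#' expressions for the baseline model are recovered as special cases.  The
#' post-power-stroke response `HC` is additionally split into its
#' length-driven part `HCL` (occupancy subsystem forced through the
#' availability slope only) and the strain-driven remainder `HCS`, a
#' negative band-pass component whenever a strain placement is active.
#'
#' @param jac an [jacobian_at_steady_state()] result
#' @param omega angular frequencies, rad/s (vector)
#' @return list of complex vectors `HxB`, `HxC`, `HB`, `HC`, `HCL`, `HCS`,
#'   each of `length(omega)`
#' @export
transfer_functions <- function(jac, omega) {
  J <- jac$d_state
  bu <- jac$d_input
  bv <- jac$d_velocity
  n <- length(omega)
  HxB <- HxC <- HB <- HC <- HCL <- complex(n)
  I4 <- diag(4)
  I2 <- diag(2)
  for (i in seq_len(n)) {
    jw <- 1i * omega[i]
    X <- solve(jw * I4 - J, bu + jw * bv)
    HB[i] <- X[1]; HC[i] <- X[2]; HxB[i] <- X[3]; HxC[i] <- X[4]
    # length-driven occupancy response: 2x2 subsystem with length forcing
    XL <- solve(jw * I2 - J[1:2, 1:2], bu[1:2])
    HCL[i] <- XL[2]
  }
  list(HxB = HxB, HxC = HxC, HB = HB, HC = HC, HCL = HCL, HCS = HC - HCL)
}

# Vectorised evaluation of the same linear system, exploiting its block
# structure: the strain rows are pure relaxations (diagonal), so HxB and HxC
# are scalar high-pass responses and the occupancy pair reduces to a 2x2
# solve in closed form.  Must agree with transfer_functions() to rounding
# error; used on the fitting hot path.
transfer_functions_fast <- function(jac, omega) {
  J <- jac$d_state
  bu <- jac$d_input
  phi_v <- jac$d_velocity[["xB"]]
  jw <- 1i * omega
  HxB <- jw * phi_v / (jw - J["xB", "xB"])
  HxC <- jw * phi_v / (jw - J["xC", "xC"])
  e1 <- bu[["B"]] + J["B", "xB"] * HxB + J["B", "xC"] * HxC
  e2 <- bu[["C"]] + J["C", "xB"] * HxB + J["C", "xC"] * HxC
  a <- jw - J["B", "B"]; b <- -J["B", "C"]
  cc <- -J["C", "B"]; d <- jw - J["C", "C"]
  det <- a * d - b * cc
  HB <- (d * e1 - b * e2) / det
  HC <- (a * e2 - cc * e1) / det
  HCL <- (a * bu[["C"]] - cc * bu[["B"]]) / det
  list(HxB = HxB, HxC = HxC, HB = HB, HC = HC, HCL = HCL, HCS = HC - HCL)
}

#' Complex-modulus spectrum container
#'
#' @param freqs frequencies, Hz (strictly increasing)
#' @param elastic elastic modulus, kPa (per unit normalised length)
#' @param viscous viscous modulus, kPa (per unit normalised length)
#' @param components optional list of complex per-transfer-function
#'   contributions on the same normalisation
#' @return data.frame of class `xb_spectrum` with columns `freq_hz`,
#'   `elastic_kpa`, `viscous_kpa`
#' @export
spectrum <- function(freqs, elastic, viscous, components = NULL) {
  if (length(freqs) < 1L || is.unsorted(freqs, strictly = TRUE)) {
    stop("spectrum: `freqs` must be strictly increasing", call. = FALSE)
  }
  if (length(elastic) != length(freqs) || length(viscous) != length(freqs)) {
    stop("spectrum: component lengths must match `freqs`", call. = FALSE)
  }
  s <- data.frame(freq_hz = freqs, elastic_kpa = elastic,
                  viscous_kpa = viscous)
  class(s) <- c("xb_spectrum", "data.frame")
  attr(s, "components") <- components
  s
}

#' @export
print.xb_spectrum <- function(x, ...) {
  cat(sprintf("Complex modulus spectrum: %d frequencies, %.3g-%.3g Hz\n",
              nrow(x), min(x$freq_hz), max(x$freq_hz)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Analytic complex modulus of a model permutation
#'
#' Complex modulus of the linearised model over a frequency grid:
#' `dF/dL(jw) = K (B0 HxB + C0 HxC + xC0 HC) + Ks`, reported per unit
#' *normalised* muscle length by scaling the sarcomere-length derivative by
#' `L0` (sarcomere strain is taken equal to muscle strain).  The elastic
#' modulus is the real part and the viscous modulus the imaginary part.
#'
#' @param params,config,condition model definition
#' @param freqs frequency grid, Hz (default [frequency_grid()])
#' @param L0 reference sarcomere length, um
#' @param keep_components if `TRUE`, attach the per-transfer-function
#'   decomposition (complex, same normalisation) as an attribute
#' @return an [spectrum()] object
#' @export
complex_modulus_linear <- function(params, config, condition,
                                   freqs = frequency_grid(), L0 = 2.2,
                                   keep_components = FALSE) {
  jac <- jacobian_at_steady_state(params, config, condition, L0)
  ss <- jac$steady_state
  omega <- 2 * pi * freqs
  tf <- transfer_functions_fast(jac, omega)
  K <- params$K
  dFdL <- K * (ss$B0 * tf$HxB + ss$C0 * tf$HxC + ss$xC0 * tf$HC) +
    (if (L0 > params$L_rest) params$Ks else 0)
  H <- L0 * dFdL
  comps <- NULL
  if (keep_components) {
    comps <- list(HxB = L0 * K * ss$B0 * tf$HxB,
                  HxC = L0 * K * ss$C0 * tf$HxC,
                  HCL = L0 * K * ss$xC0 * tf$HCL,
                  HCS = L0 * K * ss$xC0 * tf$HCS,
                  Ks = rep(L0 * params$Ks, length(omega)))
  }
  spectrum(freqs, Re(H), Im(H), components = comps)
}

#' Logarithmic measurement frequency grid
#'
#' `n` log-spaced frequencies spanning `[fmin, fmax)`: generated as `n + 1`
#' log-spaced points from `fmin` to `fmax` inclusive with the top endpoint
#' dropped, matching a grid of 17 points between 0.1 and 100 Hz (100 Hz
#' exclusive).
#'
#' @param n number of frequencies
#' @param fmin lowest frequency, Hz (included)
#' @param fmax upper limit, Hz (excluded)
#' @return numeric vector of `n` frequencies, Hz
#' @export
frequency_grid <- function(n = 17, fmin = 0.1, fmax = 100) {
  if (n < 2) stop("frequency_grid: n must be >= 2", call. = FALSE)
  f <- 10^seq(log10(fmin), log10(fmax), length.out = n + 1)
  f[seq_len(n)]
}
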