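# Full nonlinear simulations of the cross-bridge model: reference ODE
# integration under length protocols, FFT-based complex modulus (the
# independent check on the linearisation), and force-redevelopment runs.

#' Length perturbation protocol
#'
#' @param kind `"constant"`, `"sinusoid"` or `"redevelopment"`
#' @param L0 reference sarcomere length, um
#' @param amplitude sinusoid amplitude as a fraction of `L0`
#' @param freq sinusoid frequency, Hz
#' @param detach_duration duration of the forced-detachment phase, s.  The
#'   default is 2 ms; 10 ms produces the same recovered stress with a longer
#'   transient.
#' @param detach_factor fold-change applied to detachment-direction rates
#'   (k-1, k3 multiplied; k1, k-3 divided) during the detachment phase
#' @param iso_factor fold-change applied to the isomerisation rates (k2,
#'   k-2) during the detachment phase
#' @return an object of class `length_protocol`
#' @export
length_protocol <- function(kind = c("constant", "sinusoid", "redevelopment"),
                            L0 = 2.2, amplitude = 0.0025, freq = 1,
                            detach_duration = 0.002, detach_factor = 500,
                            iso_factor = 10) {
  kind <- match.arg(kind)
  if (amplitude < 0) stop("length_protocol: amplitude must be >= 0",
                          call. = FALSE)
  if (detach_duration <= 0) stop("length_protocol: detach_duration must be ",
                                 "positive", call. = FALSE)
  structure(list(kind = kind, L0 = L0, amplitude = amplitude, freq = freq,
                 detach_duration = detach_duration,
                 detach_factor = detach_factor, iso_factor = iso_factor),
            class = "length_protocol")
}

# length and velocity of a protocol as functions of time
protocol_length <- function(protocol, t) {
  if (protocol$kind == "sinusoid") {
    protocol$L0 * (1 + protocol$amplitude * sin(2 * pi * protocol$freq * t))
  } else {
    rep(protocol$L0, length(t))
  }
}

protocol_velocity <- function(protocol, t) {
  if (protocol$kind == "sinusoid") {
    w <- 2 * pi * protocol$freq
    protocol$L0 * protocol$amplitude * w * cos(w * t)
  } else {
    rep(0, length(t))
  }
}

# Fast right-hand-side closure for deSolve.  Precomputes the metabolite-
# scaled rates (optionally rescaled, as in the detachment protocol) and the
# strain sensitivities so each evaluation is plain arithmetic.  Must agree
# with ode_rhs() exactly.
make_rhs <- function(params, config, condition, protocol,
                     rate_scale = NULL) {
  r0 <- metabolite_scaled_rates(params, config, condition)
  if (!is.null(rate_scale)) r0[names(rate_scale)] <- r0[names(rate_scale)] * rate_scale
  k10 <- r0[["k1"]]; km10 <- r0[["km1"]]; k20 <- r0[["k2"]]
  km20 <- r0[["km2"]]; k30 <- r0[["k3"]]; km3 <- r0[["km3"]]
  phi_of <- function(nm) {
    if (nm %in% config$strain && nm %in% names(params$phi_s)) {
      params$phi_s[[nm]]
    } else 0
  }
  p1 <- phi_of("k1"); pm1 <- phi_of("km1"); p2 <- phi_of("k2")
  pm2 <- phi_of("km2"); p3 <- phi_of("k3")
  phi_x <- params$phi_x; phi_v <- params$phi_v; phi_l <- params$phi_l
  xC0 <- params$xC0; Lmax <- params$Lmax
  sinusoid <- protocol$kind == "sinusoid"
  L0 <- protocol$L0
  a <- protocol$amplitude
  w <- 2 * pi * protocol$freq

  function(t, y, parms) {
    if (sinusoid) {
      s <- sin(w * t)
      L <- L0 * (1 + a * s)
      dLdt <- L0 * a * w * cos(w * t)
    } else {
      L <- L0
      dLdt <- 0
    }
    B <- y[1]; C <- y[2]; xB <- y[3]; xC <- y[4]
    dxC_dev <- xC - xC0
    k1 <- k10 * exp(-p1 * xB)
    km1 <- km10 * exp(pm1 * xB)
    k2 <- k20 * exp(-p2 * xB)
    km2 <- km20 * exp(pm2 * dxC_dev)
    k3 <- k30 * exp(p3 * dxC_dev)
    Z <- if (L < Lmax) 1 + phi_l * (L / Lmax - 1) else 1
    A <- Z - B - C
    dB <- k1 * A - (km1 + k2) * B + km2 * C
    dC <- k2 * B - (km2 + k3) * C + km3 * A
    Bd <- if (B > OCCUPANCY_FLOOR) B else OCCUPANCY_FLOOR
    Cd <- if (C > OCCUPANCY_FLOOR) C else OCCUPANCY_FLOOR
    dxB <- -(phi_x / Bd) * (k1 * A + km2 * C) * xB + phi_v * dLdt
    dxC <- -(phi_x / Cd) * (k2 * B + km3 * A) * dxC_dev + phi_v * dLdt
    list(c(dB, dC, dxB, dxC))
  }
}

#' Integrate the nonlinear cross-bridge model under a length protocol
#'
#' Adaptive stiff-capable integration (deSolve's `lsoda`) of the full
#' nonlinear model.  For sinusoidal protocols the output grid has at least
#' 200 samples per perturbation period.
#'
#' @param params,config,condition model definition
#' @param protocol a [length_protocol()]
#' @param t_end end time, s
#' @param init initial state `c(B, C, xB, xC)`; default is the steady state
#'   of the condition
#' @param times optional explicit output times, s
#' @param rtol,atol integration tolerances
#' @param rate_scale optional named multipliers applied to the zero-strain
#'   rates (used by the detachment protocol)
#' @return data.frame of class `xb_trajectory` with columns `t_s`, `L_um`,
#'   `B`, `C`, `xB_um`, `xC_um`, `F_kpa`
#' @export
integrate_model <- function(params, config, condition, protocol, t_end,
                            init = NULL, times = NULL, rtol = 1e-8,
                            atol = 1e-10, rate_scale = NULL) {
  if (is.null(init)) {
    ss <- steady_state(params, config, condition, protocol$L0)
    init <- c(ss$B0, ss$C0, ss$xB0, ss$xC0)
  }
  if (is.null(times)) {
    if (protocol$kind == "sinusoid") {
      n_per <- 256
      n <- max(2L, ceiling(t_end * protocol$freq * n_per))
      times <- seq(0, t_end, length.out = n + 1L)
    } else {
      times <- seq(0, t_end, length.out = 201L)
    }
  }
  rhs <- make_rhs(params, config, condition, protocol, rate_scale)
  sol <- deSolve::lsoda(y = unname(init), times = times, func = rhs,
                        parms = NULL, rtol = rtol, atol = atol,
                        maxsteps = 100000L)
  if (attr(sol, "istate")[1L] < 0) {
    stop(sprintf("integrate_model: integration failed (%s protocol, [ATP] = %g mM, [Pi] = %g mM)",
                 protocol$kind, condition$atp, condition$pi), call. = FALSE)
  }
  t <- sol[, 1]
  state <- sol[, 2:5, drop = FALSE]
  L <- protocol_length(protocol, t)
  traj <- data.frame(t_s = t, L_um = L,
                     B = state[, 1], C = state[, 2],
                     xB_um = state[, 3], xC_um = state[, 4],
                     F_kpa = active_stress(state, params, L))
  class(traj) <- c("xb_trajectory", "data.frame")
  traj
}

#' FFT-derived complex modulus of the full nonlinear model
#'
#' For each frequency the model is driven with a small sinusoidal length
#' perturbation, the start-up transient is discarded (at least half of the
#' simulated cycles, and always enough time for the slowest linearised
#' eigenmode to decay), and the modulus is the fundamental-frequency
#' component of `FFT(F) / FFT(dL/L0)` over an integer number of periods
#' (no window).  The result is on the same per-unit-normalised-length
#' scale as [complex_modulus_linear()].
#'
#' @param params,config,condition model definition
#' @param freqs frequency grid, Hz
#' @param amplitude perturbation amplitude as a fraction of `L0`
#' @param L0 reference sarcomere length, um
#' @param n_analyse number of cycles analysed (integer periods)
#' @param rtol,atol integration tolerances
#' @return an [spectrum()] object
#' @export
complex_modulus_numeric <- function(params, config, condition,
                                    freqs = frequency_grid(),
                                    amplitude = 0.0025, L0 = 2.2,
                                    n_analyse = 4, rtol = 1e-9,
                                    atol = 1e-12) {
  # settling time from the slowest linearised eigenmode (fall back to a
  # fixed window when the linearisation is undefined, e.g. no cross-bridges)
  ss <- steady_state(params, config, condition, L0)
  t_settle <- tryCatch({
    jac <- jacobian_at_steady_state(params, config, condition, L0)
    lam <- Re(eigen(jac$d_state, only.values = TRUE)$values)
    slowest <- max(lam)  # least negative
    if (slowest < 0) min(8 / abs(slowest), 60) else 60
  }, error = function(e) 5)
  init <- c(ss$B0, ss$C0, ss$xB0, ss$xC0)
  spc <- 256L  # samples per cycle
  elastic <- viscous <- numeric(length(freqs))
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    n_discard <- max(n_analyse, ceiling(t_settle * f))
    n_cycles <- n_discard + n_analyse
    prot <- length_protocol("sinusoid", L0 = L0, amplitude = amplitude,
                            freq = f)
    dt <- 1 / (f * spc)
    times <- (0:(n_cycles * spc)) * dt
    traj <- integrate_model(params, config, condition, prot,
                            t_end = max(times), init = init, times = times,
                            rtol = rtol, atol = atol)
    idx <- (n_discard * spc + 1):(n_cycles * spc)  # n_analyse whole periods
    Fseg <- traj$F_kpa[idx]
    useg <- (traj$L_um[idx] - L0) / L0
    fund <- n_analyse + 1L  # fundamental bin (1-based)
    H <- stats::fft(Fseg)[fund] / stats::fft(useg)[fund]
    # settling check: compare the last two analysed cycles
    last <- traj$F_kpa[((n_cycles - 1) * spc + 1):(n_cycles * spc)]
    prev <- traj$F_kpa[((n_cycles - 2) * spc + 1):((n_cycles - 1) * spc)]
    osc <- max(stats::sd(last), .Machine$double.eps)
    resid <- sqrt(mean((last - prev)^2)) / osc
    if (resid > 1e-4) {
      warning(sprintf("complex_modulus_numeric: response not settled at %.3g Hz (cycle-to-cycle RMS residual %.2g)",
                      f, resid), call. = FALSE)
    }
    elastic[i] <- Re(H)
    viscous[i] <- Im(H)
  }
  spectrum(freqs, elastic, viscous)
}

#' Force-redevelopment (ktr-style) simulation
#'
#' Starting from the steady state, cross-bridges are forcibly detached for
#' `detach_duration` by multiplying the detachment-direction rates (k-1, k3)
#' by `detach_factor`, dividing the attachment-direction rates (k1, k-3) by
#' the same factor, and multiplying the isomerisation rates (k2, k-2) by
#' `iso_factor`.  Rates are then restored and the model integrated at
#' constant length until the stress derivative falls below
#' `1e-4 * F0` per second.  The redevelopment rate is reported as the
#' reciprocal of the time (from the end of the detachment phase) taken to
#' recover half of the developed stress `F_final - F_min`.
#'
#' @param params,config,condition model definition
#' @param protocol a [length_protocol()] with `kind = "redevelopment"`
#' @param t_max hard cap on the redevelopment phase, s
#' @return list of class `xb_redevelopment` with `trajectory` (the full
#'   stitched [integrate_model()] output), `F0` (pre-protocol steady
#'   stress), `F_min`, `F_final`, `t_half` (s) and `rate` (1/s)
#' @export
force_redevelopment <- function(params, config, condition,
                                protocol = length_protocol("redevelopment"),
                                t_max = 60) {
  L0 <- protocol$L0
  ss <- steady_state(params, config, condition, L0)
  init <- c(ss$B0, ss$C0, ss$xB0, ss$xC0)
  dfac <- protocol$detach_factor
  ifac <- protocol$iso_factor
  scale1 <- c(k1 = 1 / dfac, km1 = dfac, k2 = ifac, km2 = ifac,
              k3 = dfac, km3 = 1 / dfac)
  t1 <- seq(0, protocol$detach_duration, length.out = 51L)
  ph1 <- integrate_model(params, config, condition, protocol,
                         t_end = protocol$detach_duration, init = init,
                         times = t1, rate_scale = scale1)
  state <- unlist(ph1[nrow(ph1), c("B", "C", "xB_um", "xC_um")])
  # redevelopment phase in chunks until |dF/dt| < 1e-4 * F0 per second
  rates0 <- metabolite_scaled_rates(params, config, condition)
  chunks <- list(ph1)
  t_off <- protocol$detach_duration
  chunk_len <- 0.5
  repeat {
    tt <- seq(0, chunk_len, length.out = 501L)
    ph <- integrate_model(params, config, condition, protocol,
                          t_end = chunk_len, init = state, times = tt)
    ph$t_s <- ph$t_s + t_off
    t_off <- t_off + chunk_len
    chunks <- c(chunks, list(ph[-1, ]))
    state <- unlist(ph[nrow(ph), c("B", "C", "xB_um", "xC_um")])
    d <- ode_rhs(state, L0, 0, params, config, condition, rates0 = rates0)
    dFdt <- params$K * (d[1] * state[[3]] + state[[1]] * d[3] +
                          d[2] * state[[4]] + state[[2]] * d[4])
    if (abs(dFdt) < 1e-4 * abs(ss$F0) || t_off >= t_max) break
  }
  traj <- do.call(rbind, chunks)
  class(traj) <- c("xb_trajectory", "data.frame")
  F_final <- traj$F_kpa[nrow(traj)]
  F_min <- min(traj$F_kpa)
  redev <- traj[traj$t_s >= protocol$detach_duration, ]
  half <- F_min + 0.5 * (F_final - F_min)
  ih <- which(redev$F_kpa >= half)[1L]
  t_half <- redev$t_s[ih] - protocol$detach_duration
  structure(list(trajectory = traj, F0 = ss$F0, F_min = F_min,
                 F_final = F_final, t_half = t_half, rate = 1 / t_half,
                 condition = condition),
            class = "xb_redevelopment")
}

#' @export
print.xb_redevelopment <- function(x, ...) {
  cat(sprintf("Force redevelopment (\"%s\"): F0 = %.2f kPa, F_min = %.2f kPa, F_final = %.2f kPa\n",
              x$condition$name, x$F0, x$F_min, x$F_final))
  cat(sprintf("  t_half = %.4f s, normalised redevelopment rate = %.3f /s\n",
              x$t_half, x$rate))
  invisible(x)
}
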