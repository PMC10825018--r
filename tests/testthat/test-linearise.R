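# Linearisation: Jacobian, transfer functions, complex modulus, grid.

test_that("analytic Jacobian matches central finite differences for every permutation", {
  perms <- enumerate_permutations()
  h <- 1e-7
  for (i in seq_along(perms)) {
    cfg <- perms[[i]]
    p <- draw_params(cfg, seed = 900 + i)
    cond <- baseline()
    jac <- jacobian_at_steady_state(p, cfg, cond, 2.2)
    ss <- jac$steady_state
    y0 <- c(ss$B0, ss$C0, ss$xB0, ss$xC0)
    Jfd <- matrix(0, 4, 4)
    for (j in 1:4) {
      yp <- y0; ym <- y0
      yp[j] <- yp[j] + h; ym[j] <- ym[j] - h
      Jfd[, j] <- (ode_rhs(yp, 2.2, 0, p, cfg, cond) -
                     ode_rhs(ym, 2.2, 0, p, cfg, cond)) / (2 * h)
    }
    expect_lt(max(abs(Jfd - jac$d_state) /
                    pmax(abs(jac$d_state), 1e-3)), 1e-6)
    bfd <- (ode_rhs(y0, 2.2 + h, 0, p, cfg, cond) -
              ode_rhs(y0, 2.2 - h, 0, p, cfg, cond)) / (2 * h)
    expect_lt(max(abs(bfd - jac$d_input)), 1e-5)
  }
})

test_that("strain couplings vanish without placements and the strain rows are pure relaxations", {
  cfg <- model_config(strain = character(0))
  p <- draw_params(cfg, seed = 77)
  jac <- jacobian_at_steady_state(p, cfg, baseline())
  J <- jac$d_state
  expect_equal(unname(J[1:2, 3:4]), matrix(0, 2, 2))
  k <- jac$steady_state$rates0
  # cutoff of the pre-power-stroke strain response: -phi_x (k2 + k-1)
  expect_equal(J["xB", "xB"], -p$phi_x * (k[["k2"]] + k[["km1"]]))
  # cutoff of the post-power-stroke strain response: -phi_x (k3 + k-2)
  expect_equal(J["xC", "xC"], -p$phi_x * (k[["k3"]] + k[["km2"]]))
})

test_that("the post-power-stroke strain cutoff takes the rapid-equilibrium ATP form", {
  # with ATP in rapid equilibrium the relaxation rate of x_C is
  # -phi_x (k-2' kd + k3' [ATP]) / ([ATP] + kd); the phi_x factor follows
  # from the strain ODE
  p <- final_model_params()
  cfg <- final_model_config()
  for (atp in c(0.1, 1, 5)) {
    jac <- jacobian_at_steady_state(p, cfg, metabolite_condition(atp, 1))
    expect_equal(jac$d_state["xC", "xC"],
                 -p$phi_x * (p$km2_0 * p$kd_ATP + p$k3_0 * atp) /
                   (atp + p$kd_ATP))
  }
})

test_that("the generic solve reproduces the printed closed-form transfer functions", {
  omega <- 2 * pi * frequency_grid()
  for (i in seq_len(10)) {
    cfg <- final_model_config()
    p <- draw_params(cfg, seed = 1100 + i)
    jac <- jacobian_at_steady_state(p, cfg, baseline())
    tf <- transfer_functions(jac, omega)
    J <- jac$d_state
    jw <- 1i * omega
    # high-pass strain responses
    expect_equal(tf$HxB, jw * p$phi_v / (jw - J["xB", "xB"]),
                 tolerance = 1e-10)
    expect_equal(tf$HxC, jw * p$phi_v / (jw - J["xC", "xC"]),
                 tolerance = 1e-10)
    # length-driven occupancy response (k-3 = 0 so only the B row is forced)
    det <- (jw - J["C", "C"]) * (jw - J["B", "B"]) -
      J["C", "B"] * J["B", "C"]
    expect_equal(tf$HCL, jac$d_input[["B"]] * J["C", "B"] / det,
                 tolerance = 1e-10)
    # strain-driven occupancy response
    e1 <- J["B", "xB"] * tf$HxB + J["B", "xC"] * tf$HxC
    e2 <- J["C", "xB"] * tf$HxB + J["C", "xC"] * tf$HxC
    expect_equal(tf$HCS, (J["C", "B"] * e1 + (jw - J["B", "B"]) * e2) / det,
                 tolerance = 1e-10)
    # the vectorised hot path is the same linear system
    tff <- transfer_functions_fast(jac, omega)
    for (nm in names(tf)) expect_equal(tff[[nm]], tf[[nm]], tolerance = 1e-12)
  }
})

test_that("strain responses are high-pass: zero at zero frequency, phi_v plateau", {
  p <- final_model_params()
  jac <- jacobian_at_steady_state(p, final_model_config(), baseline())
  tf <- transfer_functions(jac, c(0, 2 * pi * 1e7))
  expect_equal(tf$HxB[1], 0 + 0i)
  expect_equal(tf$HxC[1], 0 + 0i)
  expect_equal(Mod(tf$HxB[2]), p$phi_v, tolerance = 1e-6)
  expect_equal(Mod(tf$HxC[2]), p$phi_v, tolerance = 1e-6)
})

test_that("low- and high-frequency elastic limits match the closed forms", {
  p <- final_model_params()
  cfg <- final_model_config()
  cond <- baseline()
  ss <- steady_state(p, cfg, cond, 2.2)
  s <- complex_modulus_linear(p, cfg, cond, freqs = c(1e-8, 1e7), L0 = 2.2)
  # static modulus: K xC0 phi_l C0 / (Lmax Z) + Ks, times the L0 scaling
  e0 <- p$K * p$xC0 * p$phi_l * (ss$C0 / ss$Z) / p$Lmax + p$Ks
  expect_equal(s$elastic_kpa[1], 2.2 * e0, tolerance = 1e-6)
  # high-frequency plateau: K phi_v (B0 + C0) + Ks, times the L0 scaling
  emax <- p$K * p$phi_v * (ss$B0 + ss$C0) + p$Ks
  expect_equal(s$elastic_kpa[2], 2.2 * emax, tolerance = 1e-6)
  # viscous modulus vanishes at both limits
  expect_lt(abs(s$viscous_kpa[1]), 1e-4)
})

test_that("the strain-driven component is a negative band-pass in the elastic modulus", {
  p <- final_model_params()
  cfg <- final_model_config()
  freqs <- 10^seq(-3, 3, length.out = 41)
  s <- complex_modulus_linear(p, cfg, baseline(), freqs = freqs,
                              keep_components = TRUE)
  hcs <- Re(attr(s, "components")$HCS)
  expect_lt(min(hcs), 0)                       # negative over an interior band
  expect_lt(abs(hcs[1]), 1e-3 * abs(min(hcs))) # vanishes at both limits
  expect_lt(abs(hcs[length(hcs)]), 1e-2 * abs(min(hcs)))
  expect_equal(which.min(hcs) %in% c(1, length(hcs)), FALSE)
})

test_that("decreasing ATP raises the moduli and shifts the responses leftward", {
  p <- final_model_params()
  cfg <- final_model_config()
  atps <- c(5, 1, 0.1)
  elo <- ehi <- cut_xc <- numeric(3)
  for (i in 1:3) {
    cond <- metabolite_condition(atps[i], 1)
    s <- complex_modulus_linear(p, cfg, cond)
    elo[i] <- s$elastic_kpa[1]
    ehi[i] <- s$elastic_kpa[17]
    cut_xc[i] <- abs(jacobian_at_steady_state(p, cfg, cond)$d_state["xC", "xC"])
  }
  expect_true(all(diff(elo) > 0))   # static modulus grows as ATP falls
  expect_true(all(diff(ehi) > 0))   # plateau modulus grows as ATP falls
  expect_true(all(diff(cut_xc) < 0))  # x_C cutoff shifts left as ATP falls
})

test_that("decreasing Pi raises the moduli and shifts the x_B cutoff leftward", {
  p <- final_model_params()
  cfg <- final_model_config()
  pis <- c(5, 1, 0)
  elo <- ehi <- cut_xb <- numeric(3)
  for (i in 1:3) {
    cond <- metabolite_condition(5, pis[i])
    s <- complex_modulus_linear(p, cfg, cond)
    elo[i] <- s$elastic_kpa[1]
    ehi[i] <- s$elastic_kpa[17]
    cut_xb[i] <- abs(jacobian_at_steady_state(p, cfg, cond)$d_state["xB", "xB"])
  }
  expect_true(all(diff(elo) > 0))
  expect_true(all(diff(ehi) > 0))
  expect_true(all(diff(cut_xb) < 0))
})

test_that("with strain on k-2 the band-pass magnitude grows as ATP falls", {
  # |dC/dxC| = C0 k-2 phi_s-2 at the reference state
  p <- final_model_params()
  p$phi_s <- c(km2 = 995)
  cfg <- model_config(strain = "km2", pi_method = "M2", atp_method = "M2")
  mag <- vapply(c(5, 1, 0.1), function(atp) {
    jac <- jacobian_at_steady_state(p, cfg, metabolite_condition(atp, 1))
    abs(jac$d_state["C", "xC"])
  }, numeric(1))
  expect_true(all(diff(mag) > 0))
})

test_that("the measurement frequency grid is log-spaced on [0.1, 100)", {
  f <- frequency_grid()
  expect_length(f, 17)
  expect_equal(f[1], 0.1)
  expect_true(all(f < 100))
  r <- f[-1] / f[-length(f)]
  expect_lt(max(abs(r - r[1])), 1e-12)
  # n + 1 log-spaced points to 100 Hz inclusive, top point dropped
  expect_equal(f[17], 0.1 * 10^(3 * 16 / 17))
})

test_that("linearisation is rejected when an attached state is empty", {
  p <- final_model_params()
  p$k1 <- 0  # no attachment: B0 = C0 = 0
  expect_error(jacobian_at_steady_state(p, final_model_config(), baseline()),
               "linearisation undefined")
})
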