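# Rate laws, ODE right-hand side, stress and steady state.

test_that("availability follows the two-branch force-length relation", {
  expect_equal(availability(2.3, 3.89), 1)      # plateau onset
  expect_equal(availability(2.35, 3.89), 1)     # plateau
  expect_equal(availability(2.3, 17.2), 1)      # branch boundary, any slope
  expect_equal(availability(2.2, 3.89), 1 + 3.89 * (2.2 / 2.3 - 1))
  expect_equal(availability(2.2, 0), 1)
  expect_error(availability(2.41, 3.89), "undefined")
  expect_error(availability(1.0, 20), "negative availability")
})

test_that("direct (Method 1) metabolite scaling is linear in concentration", {
  p <- final_model_params()
  cfg <- model_config(pi_method = "M1", atp_method = "M1")
  r0 <- metabolite_scaled_rates(p, cfg, metabolite_condition(5, 0))
  expect_equal(r0[["km1"]], 0)                   # zero Pi
  expect_equal(r0[["k2"]], p$k2_0)               # k2 untouched under M1
  expect_equal(r0[["km2"]], p$km2_0)
  r1 <- metabolite_scaled_rates(p, cfg, metabolite_condition(2, 3))
  expect_equal(r1[["km1"]], p$km1_0 * 3)
  expect_equal(r1[["k3"]], p$k3_0 * 2)
})

test_that("rapid-equilibrium (Method 2) scaling saturates with kd", {
  p <- final_model_params()
  cfg <- model_config(pi_method = "M2", atp_method = "M2")
  # half-saturation at [Pi] = kd_Pi
  r <- metabolite_scaled_rates(p, cfg, metabolite_condition(5, p$kd_Pi))
  expect_equal(r[["km1"]], p$km1_0 / 2)
  expect_equal(r[["k2"]], p$k2_0 / 2)
  # fitted values at the baseline solution
  rb <- metabolite_scaled_rates(p, cfg, baseline())
  expect_equal(rb[["k3"]], 13.0 * 5 / (2.36 + 5))
  expect_equal(rb[["km2"]], 1.11 * 2.36 / (2.36 + 5))
  # degenerate 0/0 rejected
  p0 <- p; p0$kd_ATP <- 0
  expect_error(metabolite_scaled_rates(p0, cfg, metabolite_condition(0, 1)),
               "undefined")
})

test_that("Method 2 rates are monotone in the metabolite concentrations", {
  p <- final_model_params()
  cfg <- model_config(pi_method = "M2", atp_method = "M2")
  atps <- c(0.05, 0.1, 0.5, 1, 2, 5, 10)
  k3 <- km2 <- numeric(length(atps))
  for (i in seq_along(atps)) {
    r <- metabolite_scaled_rates(p, cfg, metabolite_condition(atps[i], 1))
    k3[i] <- r[["k3"]]; km2[i] <- r[["km2"]]
  }
  expect_true(all(diff(k3) > 0))    # detachment speeds up with ATP
  expect_true(all(diff(km2) < 0))   # reverse power stroke slows with ATP
  pis <- c(0, 0.5, 1, 2, 5, 10)
  km1 <- k2 <- numeric(length(pis))
  for (i in seq_along(pis)) {
    r <- metabolite_scaled_rates(p, cfg, metabolite_condition(5, pis[i]))
    km1[i] <- r[["km1"]]; k2[i] <- r[["k2"]]
  }
  expect_true(all(diff(km1) > 0))
  expect_true(all(diff(k2) < 0))
})

test_that("strain scaling reduces to identity at the reference strains", {
  p <- final_model_params()
  for (rate in c("k1", "km1", "k2", "km2", "k3")) {
    cfg <- model_config(strain = rate)
    pp <- p; pp$phi_s <- stats::setNames(300, rate)
    r0 <- metabolite_scaled_rates(pp, cfg, baseline())
    expect_equal(strain_scaled_rates(r0, pp, cfg, xB = 0, xC = pp$xC0), r0)
  }
})

test_that("strain scaling applies the exponential forms", {
  p <- final_model_params()   # phi_s[k-2] = 995, phi_s[k3] = 71.1
  cfg <- final_model_config()
  r0 <- metabolite_scaled_rates(p, cfg, baseline())
  r <- strain_scaled_rates(r0, p, cfg, xB = 0, xC = p$xC0 + 1e-3)
  expect_equal(r[["km2"]], r0[["km2"]] * exp(0.995))
  expect_equal(r[["k3"]], r0[["k3"]] * exp(0.0711))
  # k1 placement: strictly decreasing in xB
  cfg1 <- model_config(strain = "k1")
  p1 <- p; p1$phi_s <- c(k1 = 200)
  r01 <- metabolite_scaled_rates(p1, cfg1, baseline())
  k1_at <- vapply(c(0, 1e-4, 1e-3, 5e-3), function(x) {
    strain_scaled_rates(r01, p1, cfg1, xB = x, xC = p1$xC0)[["k1"]]
  }, numeric(1))
  expect_true(all(diff(k1_at) < 0))
  expect_error(model_config(strain = "km3"), "not supported")
})

test_that("the ODE right-hand side vanishes at the steady state and carries the velocity coupling", {
  p <- final_model_params()
  cfg <- final_model_config()
  ss <- steady_state(p, cfg, baseline(), 2.2)
  y0 <- c(ss$B0, ss$C0, ss$xB0, ss$xC0)
  expect_lt(max(abs(ode_rhs(y0, 2.2, 0, p, cfg, baseline()))), 1e-9)
  # velocity enters both strain ODEs additively as phi_v * dLdt
  y <- c(0.2, 0.3, 0.002, 0.011)
  v <- 0.37
  d <- ode_rhs(y, 2.2, v, p, cfg, baseline()) -
    ode_rhs(y, 2.2, 0, p, cfg, baseline())
  expect_equal(d, c(0, 0, p$phi_v * v, p$phi_v * v))
})

test_that("the right-hand side matches an independently hand-coded oracle", {
  set.seed(401)
  perms <- enumerate_permutations()
  for (i in seq_len(20)) {
    cfg <- perms[[sample.int(64, 1)]]
    p <- draw_params(cfg, seed = 500 + i)
    cond <- metabolite_condition(stats::runif(1, 0.1, 5),
                                 stats::runif(1, 0, 5))
    y <- c(stats::runif(1, 0.05, 0.4), stats::runif(1, 0.05, 0.4),
           stats::runif(1, -5e-3, 5e-3), stats::runif(1, 5e-3, 2e-2))
    L <- stats::runif(1, 2.0, 2.35)
    v <- stats::runif(1, -0.1, 0.1)
    expect_equal(ode_rhs(y, L, v, p, cfg, cond),
                 oracle_rhs(y, L, v, p, cfg, cond), tolerance = 1e-12)
  }
})

test_that("active stress reduces to the insensitive spring without cross-bridges", {
  p <- final_model_params()
  expect_equal(active_stress(c(0, 0, 0, 0.01), p, 2.2), p$Ks * 0.3)
  expect_equal(active_stress(c(0, 0, 0, 0.01), p, 1.9), 0)
  expect_equal(active_stress(c(0, 0, 0, 0.01), p, 1.7), 0)  # slack
})

test_that("steady state conserves occupancy and pins the strains", {
  perms <- enumerate_permutations()
  for (i in c(1, 14, 32, 55, 64)) {
    cfg <- perms[[i]]
    p <- draw_params(cfg, seed = 700 + i)
    ss <- steady_state(p, cfg, baseline(), 2.2)
    expect_identical(ss$xB0, 0)
    expect_equal(ss$xC0, p$xC0)
    expect_lt(abs(ss$A0 + ss$B0 + ss$C0 - ss$Z), 1e-12)
    expect_true(all(c(ss$A0, ss$B0, ss$C0) >= 0))
  }
})

test_that("slower detachment accumulates post-power-stroke cross-bridges", {
  p <- final_model_params()
  cfg <- final_model_config()
  base <- steady_state(p, cfg, baseline())
  for (f in c(0.8, 0.5, 0.2)) {
    p2 <- p; p2$k3_0 <- p$k3_0 * f
    expect_gt(steady_state(p2, cfg, baseline())$C0, base$C0)
    p3 <- p; p3$km1_0 <- p$km1_0 * f
    expect_gt(steady_state(p3, cfg, baseline())$C0, base$C0)
  }
  # and therefore C0 (hence F0) rises monotonically as k3 falls
  fs <- c(1, 0.7, 0.4, 0.1)
  c0 <- vapply(fs, function(f) {
    p2 <- p; p2$k3_0 <- p$k3_0 * f
    steady_state(p2, cfg, baseline())$C0
  }, numeric(1))
  expect_true(all(diff(c0) > 0))
})

test_that("steady-state stress is non-increasing in either metabolite for the final model", {
  p <- final_model_params()
  cfg <- final_model_config()
  f0_atp <- vapply(c(0.1, 1, 5), function(a) {
    steady_state(p, cfg, metabolite_condition(a, 1))$F0
  }, numeric(1))
  expect_true(all(diff(f0_atp) < 0))
  f0_pi <- vapply(c(0, 1, 5), function(q) {
    steady_state(p, cfg, metabolite_condition(5, q))$F0
  }, numeric(1))
  expect_true(all(diff(f0_pi) < 0))
})

test_that("the steady state is invariant to the strain sensitivities", {
  p <- final_model_params()
  cfg <- final_model_config()
  # doubling the sensitivities changes nothing
  p2 <- p; p2$phi_s <- p$phi_s * 2
  expect_true(steady_state_invariance_check(p2, cfg, baseline()))
  # no placements vs a k1 placement
  s_none <- steady_state(p, model_config(strain = character(0)), baseline())
  p1 <- p; p1$phi_s <- c(k1 = 123)
  s_k1 <- steady_state(p1, model_config(strain = "k1"), baseline())
  expect_equal(s_none$F0, s_k1$F0)
  # randomised sensitivities over 100 draws leave F0 unchanged
  set.seed(42)
  f0 <- vapply(seq_len(100), function(i) {
    pp <- p
    pp$phi_s <- c(km2 = stats::runif(1, 0, 3000),
                  k3 = stats::runif(1, 0, 3000))
    steady_state(pp, cfg, baseline())$F0
  }, numeric(1))
  expect_equal(max(f0) - min(f0), 0)
})

test_that("occupancy stays admissible along perturbed trajectories", {
  p <- final_model_params()
  cfg <- final_model_config()
  prot <- length_protocol("sinusoid", amplitude = 0.0025, freq = 1)
  traj <- integrate_model(p, cfg, baseline(), prot, t_end = 3,
                          init = c(0.1, 0.1, 0, 0.01))
  expect_true(all(traj$B > -1e-9))
  expect_true(all(traj$C > -1e-9))
  expect_true(all(traj$B + traj$C <=
                    availability(max(traj$L_um), p$phi_l) + 1e-9))
})

test_that("parameter validation rejects inadmissible sets", {
  expect_error(kinetic_params(k1 = -1, km1_0 = 1, k2_0 = 1, km2_0 = 1,
                              k3_0 = 1, phi_x = 1, phi_v = 1, phi_l = 1,
                              K = 1, Ks = 1), "nonnegative")
  expect_error(kinetic_params(k1 = 1, km1_0 = 1, k2_0 = 1, km2_0 = 1,
                              k3_0 = 1, phi_x = 0, phi_v = 1, phi_l = 1,
                              K = 1, Ks = 1), "phi_x")
  expect_error(kinetic_params(k1 = 1, km1_0 = 1, k2_0 = 1, km2_0 = 1,
                              k3_0 = 1, phi_x = 1, phi_v = 1, phi_l = 1,
                              K = 1, Ks = 1,
                              phi_s = c(k1 = 1, k2 = 1, k3 = 1)),
               "at most two")
  expect_error(kinetic_params(k1 = 1, km1_0 = 1, k2_0 = 1, km2_0 = 1,
                              k3_0 = 1, phi_x = 1, phi_v = 1, phi_l = 1,
                              K = 1, Ks = 1, phi_s = c(km3 = 5)),
               "phi_s")
})
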