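# Fitting objective (per-condition modulus RMSE plus dead-zoned
# steady-stress error), particle-swarm fitting of one permutation, and the
# full 64-permutation scan.

# Lean evaluation of the linear modulus and steady stress for one condition,
# used on the optimiser hot path.  Same mathematics as
# jacobian_at_steady_state() + transfer_functions_fast() +
# complex_modulus_linear(), without the container overhead; equality with
# the reference path is asserted in the test suite.
modulus_quick <- function(params, config, condition, freqs, L0) {
  atp <- condition$atp; pi_ <- condition$pi
  k1 <- params$k1; km1 <- params$km1_0; k2 <- params$k2_0
  km2 <- params$km2_0; k3 <- params$k3_0; km3 <- params$km3
  if (config$pi_method == "M1") {
    km1 <- km1 * pi_
  } else {
    kd <- params$kd_Pi
    km1 <- km1 * pi_ / (kd + pi_)
    k2 <- k2 * kd / (kd + pi_)
  }
  if (config$atp_method == "M1") {
    k3 <- k3 * atp
  } else {
    kd <- params$kd_ATP
    km2 <- km2 * kd / (kd + atp)
    k3 <- k3 * atp / (kd + atp)
  }
  wA <- km1 * km2 + km1 * k3 + k2 * k3
  wB <- k1 * km2 + k1 * k3 + km3 * km2
  wC <- k1 * k2 + km3 * km1 + km3 * k2
  den <- wA + wB + wC
  if (den <= 0) return(NULL)
  Z <- if (L0 < params$Lmax) 1 + params$phi_l * (L0 / params$Lmax - 1) else 1
  if (Z < 0) return(NULL)
  B0 <- Z * wB / den; C0 <- Z * wC / den; A0 <- Z - B0 - C0
  if (B0 <= 0 || C0 <= 0) return(NULL)
  ph <- function(nm) {
    if (nm %in% config$strain && nm %in% names(params$phi_s)) {
      params$phi_s[[nm]]
    } else 0
  }
  J13 <- (-ph("k1") * k1) * A0 - (ph("km1") * km1 - ph("k2") * k2) * B0
  J14 <- ph("km2") * km2 * C0
  J23 <- -ph("k2") * k2 * B0
  J24 <- -(ph("km2") * km2 + ph("k3") * k3) * C0
  J11 <- -k1 - (km1 + k2); J12 <- -k1 + km2
  J21 <- k2 - km3; J22 <- -(km2 + k3) - km3
  J33 <- -params$phi_x * (k1 * A0 + km2 * C0) / B0
  J44 <- -params$phi_x * (k2 * B0 + km3 * A0) / C0
  Zp <- if (L0 < params$Lmax) params$phi_l / params$Lmax else 0
  b1 <- k1 * Zp; b2 <- km3 * Zp
  jw <- 2i * pi * freqs
  HxB <- jw * params$phi_v / (jw - J33)
  HxC <- jw * params$phi_v / (jw - J44)
  e1 <- b1 + J13 * HxB + J14 * HxC
  e2 <- b2 + J23 * HxB + J24 * HxC
  a <- jw - J11; b <- -J12; cc <- -J21; d <- jw - J22
  det <- a * d - b * cc
  HC <- (a * e2 - cc * e1) / det
  Ks <- if (L0 > params$L_rest) params$Ks else 0
  H <- L0 * (params$K * (B0 * HxB + C0 * HxC + params$xC0 * HC) + Ks)
  F0 <- params$K * C0 * params$xC0 +
    params$Ks * max(L0 - params$L_rest, 0)
  list(elastic = Re(H), viscous = Im(H), F0 = F0)
}

#' Root-mean-square error between two complex-modulus spectra
#'
#' `sqrt( (1 / (2 Nf)) * sum_j [(Em_j - Ed_j)^2 + (Vm_j - Vd_j)^2] )` over a
#' shared frequency grid: elastic and viscous residuals pooled, unweighted.
#'
#' @param model,data [spectrum()] objects (or data.frames with `freq_hz`,
#'   `elastic_kpa`, `viscous_kpa`) on the same grid
#' @param sem optional list with numeric vectors `elastic` and `viscous`:
#'   when given, residuals are divided by these per-frequency standard
#'   errors before averaging (an SEM-weighted variant; the default objective
#'   is the unweighted form)
#' @return RMSE, kPa (dimensionless if `sem` is used)
#' @export
modulus_rmse <- function(model, data, sem = NULL) {
  if (nrow(model) != nrow(data) ||
      max(abs(model$freq_hz - data$freq_hz)) > 1e-9 * max(data$freq_hz)) {
    stop("modulus_rmse: model and data frequency grids differ",
         call. = FALSE)
  }
  nf <- nrow(data)
  re <- model$elastic_kpa - data$elastic_kpa
  rv <- model$viscous_kpa - data$viscous_kpa
  if (!is.null(sem)) {
    re <- re / sem$elastic
    rv <- rv / sem$viscous
  }
  sqrt(sum(re^2 + rv^2) / (2 * nf))
}

#' Dead-zoned steady-state stress error
#'
#' Zero while the model stress lies within one SEM of the measured mean,
#' and the exceedance beyond the SEM band otherwise:
#' `max(|F0_model - F0_data| - SE, 0)`.
#'
#' @param f0_model model steady-state stress, kPa
#' @param f0_data measured mean, kPa
#' @param se standard error of the mean, kPa (> 0)
#' @return error, kPa
#' @export
f0_error <- function(f0_model, f0_data, se) {
  if (any(se <= 0)) stop("f0_error: `se` must be > 0", call. = FALSE)
  pmax(abs(f0_model - f0_data) - se, 0)
}

#' Fitting objective of a parameter set on a study dataset
#'
#' Mean over conditions of the modulus RMSE plus the dead-zoned steady-state
#' stress error, with model spectra from the analytic linearisation on the
#' dataset's own frequency grid.  A condition whose steady state cannot be
#' evaluated yields an `Inf` sentinel.
#'
#' @param params a [kinetic_params()]
#' @param config a [model_config()]
#' @param dataset an [study_dataset()]
#' @param details if `TRUE`, return the per-condition breakdown
#' @return objective in kPa (scalar), or, with `details = TRUE`, a list with
#'   `objective`, `rmse`, `f0_err`, `f0_model` (per-condition vectors)
#' @export
study_objective <- function(params, config, dataset, details = FALSE) {
  nc <- length(dataset$conditions)
  rmse <- f0e <- f0m <- rep(NA_real_, nc)
  for (i in seq_len(nc)) {
    cd <- dataset$conditions[[i]]
    q <- modulus_quick(params, config, cd$condition, cd$data$freq_hz,
                       dataset$L0)
    ok <- !is.null(q) && all(is.finite(q$elastic)) &&
      all(is.finite(q$viscous)) && is.finite(q$F0)
    if (ok) {
      nf <- length(cd$data$freq_hz)
      rmse[i] <- sqrt(sum((q$elastic - cd$data$elastic_kpa)^2 +
                            (q$viscous - cd$data$viscous_kpa)^2) / (2 * nf))
      f0m[i] <- q$F0
      f0e[i] <- max(abs(q$F0 - cd$f0_kpa) - cd$f0_sem_kpa, 0)
    } else {
      if (details) {
        return(list(objective = Inf, rmse = rmse, f0_err = f0e,
                    f0_model = f0m))
      }
      return(Inf)
    }
  }
  obj <- mean(rmse + f0e)
  if (details) {
    list(objective = obj, rmse = rmse, f0_err = f0e, f0_model = f0m)
  } else {
    obj
  }
}

#' Default box bounds for the free parameters of a permutation
#'
#' Rates in `[1e-3, 1e3]` (1/s, or 1/s/mM under Method 1), dissociation
#' constants in `[0.01, 50]` mM, strain sensitivities in `[0, 5000]` 1/um,
#' `phi_x` in `[0.1, 50]`, `phi_v` in `[1e-3, 10]`, `phi_l` in `[0, 20]`,
#' stiffnesses in `[0, 1e4]` kPa/um.
#'
#' @param config a [model_config()]
#' @return data.frame with columns `slot`, `lower`, `upper`
#' @export
default_bounds <- function(config) {
  slots <- parameter_slots(config)
  lo <- up <- numeric(nrow(slots))
  for (i in seq_len(nrow(slots))) {
    f <- slots$field[i]
    b <- switch(f,
      k1 = , km1_0 = , k2_0 = , km2_0 = , k3_0 = c(1e-3, 1e3),
      kd_ATP = , kd_Pi = c(0.01, 50),
      phi_s = c(0, 5000),
      phi_x = c(0.1, 50),
      phi_v = c(1e-3, 10),
      phi_l = c(0, 20),
      K = , Ks = c(0, 1e4)
    )
    lo[i] <- b[1]; up[i] <- b[2]
  }
  data.frame(slot = slots$slot, lower = lo, upper = up,
             stringsAsFactors = FALSE)
}

# The swarm searches in log10 space (parameter magnitudes span six decades).
# Slots whose lower bound is zero are floored at 1e-6 of the upper bound,
# which is indistinguishable from zero at the fitted scales.
transform_bounds <- function(bounds) {
  lo <- pmax(bounds$lower, 1e-6 * bounds$upper)
  cbind(lower = log10(lo), upper = log10(bounds$upper))
}

#' Fit one model permutation to a study dataset
#'
#' Seeded global particle-swarm search over the free parameters of the
#' permutation (in log10 space, since parameter magnitudes span several
#' decades), each swarm run followed by a local polish: a bounded
#' Levenberg-Marquardt descent on the stacked modulus residuals and then a
#' bounded quasi-Newton step on the exact objective.  `n_restarts`
#' independent swarm runs (seeds derived from `seed`) guard against the
#' swarm stalling outside the global basin; the best polished optimum is
#' returned.
#'
#' @param dataset an [study_dataset()]
#' @param config a [model_config()], or a permutation label such as `"16D"`
#' @param bounds data.frame from [default_bounds()] (or an override with the
#'   same columns)
#' @param settings a [pso_settings()] list
#' @param seed integer seed
#' @param n_restarts number of independent swarm runs
#' @param polish if `TRUE`, apply the local polish after each swarm run
#' @param stop_value optional objective value (kPa) below which remaining
#'   restarts are skipped
#' @return list of class `xb_fit_result`: `config`, `params` (the fitted
#'   [kinetic_params()]), `objective` (kPa), `rmse` and `f0_model` per
#'   condition, `normalised_rmse` (% of the dataset modulus range), `trace`
#'   (swarm best value per iteration, best restart), `seed`, `settings`
#' @export
fit_study <- function(dataset, config, bounds = NULL,
                      settings = pso_settings(), seed = 1L,
                      n_restarts = 3L, polish = TRUE, stop_value = NULL) {
  if (is.character(config)) config <- permutation_config(config)
  if (is.null(bounds)) bounds <- default_bounds(config)
  tb <- transform_bounds(bounds)
  slots <- parameter_slots(config)
  template <- params_from_vector(rep(1, nrow(slots)), config)
  build <- function(z) {
    # box bounds guarantee validity; skip constructor checks on the hot path
    x <- 10^z
    p <- template
    for (i in seq_len(nrow(slots))) {
      f <- slots$field[i]
      if (f == "phi_s") p$phi_s[[slots$rate[i]]] <- x[i] else p[[f]] <- x[i]
    }
    p
  }
  fn <- function(z) study_objective(build(z), config, dataset)
  n_resid <- sum(vapply(dataset$conditions,
                        function(cd) 2L * nrow(cd$data) + 1L, integer(1)))
  resid_fn <- function(z) {
    p <- build(z)
    out <- numeric(0)
    for (cd in dataset$conditions) {
      q <- modulus_quick(p, config, cd$condition, cd$data$freq_hz,
                         dataset$L0)
      if (is.null(q) ||
          !all(is.finite(c(q$elastic, q$viscous, q$F0)))) {
        return(rep(1e3, n_resid))
      }
      nf <- nrow(cd$data)
      out <- c(out, (q$elastic - cd$data$elastic_kpa) / sqrt(2 * nf),
               (q$viscous - cd$data$viscous_kpa) / sqrt(2 * nf),
               max(abs(q$F0 - cd$f0_kpa) - cd$f0_sem_kpa, 0))
    }
    out
  }
  par <- NULL; val <- Inf; trace <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    sw <- pso_optim(fn, tb[, "lower"], tb[, "upper"], settings = settings,
                    seed = seed + 1000L * (r - 1L))
    p_r <- sw$par; v_r <- sw$value
    if (polish && is.finite(v_r)) {
      lm <- tryCatch(
        minpack.lm::nls.lm(p_r, lower = tb[, "lower"],
                           upper = tb[, "upper"], fn = resid_fn,
                           control = minpack.lm::nls.lm.control(maxiter = 400)),
        error = function(e) NULL)
      if (!is.null(lm)) {
        v_lm <- fn(lm$par)
        if (is.finite(v_lm) && v_lm < v_r) {
          p_r <- lm$par; v_r <- v_lm
        }
      }
      pol <- tryCatch(
        stats::optim(p_r, fn, method = "L-BFGS-B", lower = tb[, "lower"],
                     upper = tb[, "upper"],
                     control = list(maxit = 200, factr = 1e3)),
        error = function(e) NULL)
      if (!is.null(pol) && is.finite(pol$value) && pol$value < v_r) {
        p_r <- pol$par; v_r <- pol$value
      }
    }
    if (v_r < val) {
      par <- p_r; val <- v_r; trace <- sw$trace
    }
    if (!is.null(stop_value) && val <= stop_value) break
  }
  sw <- list(trace = trace)
  params <- params_from_vector(10^par, config)
  det <- study_objective(params, config, dataset, details = TRUE)
  structure(list(
    config = config, params = params, objective = det$objective,
    rmse = det$rmse, f0_err = det$f0_err, f0_model = det$f0_model,
    normalised_rmse = 100 * mean(det$rmse) / modulus_range(dataset),
    trace = sw$trace, seed = seed, settings = settings, bounds = bounds,
    converged = is.finite(det$objective)
  ), class = "xb_fit_result")
}

#' @export
print.xb_fit_result <- function(x, ...) {
  cat(sprintf("Fit of permutation %s: objective = %.4g kPa, normalised RMSE = %.3f %%\n",
              if (is.null(x$config$label)) "?" else x$config$label,
              x$objective, x$normalised_rmse))
  cat("  per-condition RMSE (kPa):",
      paste(sprintf("%.3g", x$rmse), collapse = ", "), "\n")
  invisible(x)
}

#' Fit all 64 model permutations to a study dataset
#'
#' Runs [fit_study()] for every permutation from [enumerate_permutations()]
#' (each cell gets its own seed derived from `seed`) and tabulates the
#' normalised RMSE, `100 * mean(RMSE) / modulus_range(dataset)`, on the
#' 16-row by 4-column reference grid.
#'
#' @param dataset an [study_dataset()]
#' @param settings a [pso_settings()] list; the default is a reduced budget
#'   sized for a desk-scale scan
#' @param seed integer seed
#' @param n_restarts,polish passed to [fit_study()] (one swarm run per cell
#'   by default)
#' @param progress if `TRUE`, print one line per cell
#' @return matrix of class `xb_scan_table` (16 x 4, percent normalised
#'   RMSE), with the per-cell [fit_study()] results in attribute `"fits"`
#'   and the seed in attribute `"seed"`
#' @export
scan_permutations <- function(dataset, settings = pso_settings(24, 60),
                              seed = 1L, n_restarts = 1L, polish = TRUE,
                              progress = FALSE) {
  perms <- enumerate_permutations()
  tab <- matrix(NA_real_, 16, 4,
                dimnames = list(paste0("strain_", 1:16), c("A", "B", "C", "D")))
  fits <- list()
  for (i in seq_along(perms)) {
    cfg <- perms[[i]]
    lab <- cfg$label
    fit <- tryCatch(
      fit_study(dataset, cfg, settings = settings,
                seed = seed + i - 1L, n_restarts = n_restarts,
                polish = polish),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning("scan_permutations: fit of ", lab, " failed: ",
              conditionMessage(fit), call. = FALSE)
    } else {
      row <- as.integer(sub("[A-D]$", "", lab))
      col <- sub("^[0-9]+", "", lab)
      tab[row, col] <- fit$normalised_rmse
      fits[[lab]] <- fit
      if (progress) {
        cat(sprintf("%-3s normalised RMSE = %.3f %%\n", lab,
                    fit$normalised_rmse))
      }
    }
  }
  structure(tab, class = c("xb_scan_table", class(tab)), fits = fits,
            seed = seed, settings = settings)
}

#' @export
print.xb_scan_table <- function(x, ...) {
  cat("Normalised RMSE (%) over the 64 model permutations\n")
  y <- x
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  print(round(y, 3))
  best <- arrayInd(which.min(y), dim(y))
  cat(sprintf("Best cell: %d%s (%.3f %%)\n", best[1],
              colnames(y)[best[2]], min(y, na.rm = TRUE)))
  invisible(x)
}
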