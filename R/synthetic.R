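# Synthetic study-data generator: complex-modulus datasets with the
# statistical structure the fitting pipeline assumes (per-frequency means
# with SEMs and a steady-state stress per metabolite condition), generated
# from a known ground-truth model permutation.

#' Specification for a synthetic complex-modulus study
#'
#' The generated data emulate the reference study design: five metabolite
#' conditions, 17 log-spaced frequencies in 0.1-100 Hz, additive Gaussian
#' noise on the elastic and viscous moduli with standard deviation
#' proportional to the local modulus magnitude, and a noisy steady-state
#' stress per condition.  The default noise scales (3 % of the local
#' modulus magnitude; 10 % of the steady stress) are order-of-magnitude
#' emulations of the SEM-to-mean ratios of the reference measurements.
#'
#' @param truth_params ground-truth [kinetic_params()]
#' @param truth_config ground-truth [model_config()]
#' @param conditions list of [metabolite_condition()] objects
#' @param freqs measurement frequency grid, Hz
#' @param L0 reference sarcomere length, um
#' @param noise_scale per-frequency noise standard deviation as a fraction
#'   of the local modulus magnitude
#' @param f0_noise steady-stress noise standard deviation as a fraction of
#'   the true stress
#' @param n_replicates if given, draw this many replicate muscles per
#'   condition and report their mean and sample SEM instead of a single
#'   noisy draw with nominal SEM
#' @param seed integer seed, recorded in every output
#' @return list of class `xb_synth_spec`
#' @export
synth_spec <- function(truth_params = final_model_params(),
                       truth_config = final_model_config(),
                       conditions = study_conditions(),
                       freqs = frequency_grid(), L0 = 2.2,
                       noise_scale = 0.03, f0_noise = 0.10,
                       n_replicates = NULL, seed = 1L) {
  if (noise_scale < 0 || f0_noise < 0) {
    stop("synth_spec: noise scales must be nonnegative", call. = FALSE)
  }
  structure(list(truth_params = truth_params, truth_config = truth_config,
                 conditions = conditions, freqs = freqs, L0 = L0,
                 noise_scale = noise_scale, f0_noise = f0_noise,
                 n_replicates = n_replicates, seed = as.integer(seed)),
            class = "xb_synth_spec")
}

#' Generate a synthetic study dataset from a ground-truth model
#'
#' Per condition, the linear-model spectrum on the frequency grid receives
#' additive Gaussian noise (independently on the elastic and viscous
#' components, uncorrelated across frequencies); the SEM fields carry the
#' generating standard deviation (or, in replicate mode, the sample SEM).
#' The steady-state stress comes from [steady_state()] plus noise.  The
#' ground truth is returned alongside for recovery scoring.
#'
#' @param spec an [synth_spec()]
#' @return list of class `xb_synth_study` with `dataset` (an
#'   [study_dataset()]) and `truth` (params, config, per-condition true
#'   spectra and stresses, seed)
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "xb_synth_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)
  conds <- list()
  truth_spectra <- list()
  truth_f0 <- numeric(length(spec$conditions))
  nf <- length(spec$freqs)
  for (i in seq_along(spec$conditions)) {
    cond <- spec$conditions[[i]]
    true_spec <- tryCatch(
      complex_modulus_linear(spec$truth_params, spec$truth_config, cond,
                             freqs = spec$freqs, L0 = spec$L0),
      error = function(e) {
        stop("generate_study: truth model degenerate under condition \"",
             cond$name, "\": ", conditionMessage(e), call. = FALSE)
      })
    ss <- steady_state(spec$truth_params, spec$truth_config, cond, spec$L0)
    mag <- sqrt(true_spec$elastic_kpa^2 + true_spec$viscous_kpa^2)
    sd_j <- spec$noise_scale * mag
    f0_sd <- spec$f0_noise * ss$F0
    if (is.null(spec$n_replicates)) {
      e <- true_spec$elastic_kpa + stats::rnorm(nf, 0, sd_j)
      v <- true_spec$viscous_kpa + stats::rnorm(nf, 0, sd_j)
      e_sem <- v_sem <- sd_j
      f0 <- ss$F0 + if (f0_sd > 0) stats::rnorm(1, 0, f0_sd) else 0
      f0_sem <- max(f0_sd, 1e-6)
    } else {
      n <- spec$n_replicates
      E <- matrix(stats::rnorm(n * nf, 0, 1), n, nf, byrow = TRUE) *
        rep(sd_j, each = n) + rep(true_spec$elastic_kpa, each = n)
      V <- matrix(stats::rnorm(n * nf, 0, 1), n, nf, byrow = TRUE) *
        rep(sd_j, each = n) + rep(true_spec$viscous_kpa, each = n)
      e <- colMeans(E)
      v <- colMeans(V)
      e_sem <- apply(E, 2, stats::sd) / sqrt(n)
      v_sem <- apply(V, 2, stats::sd) / sqrt(n)
      f0_reps <- ss$F0 + stats::rnorm(n, 0, f0_sd)
      f0 <- mean(f0_reps)
      f0_sem <- max(stats::sd(f0_reps) / sqrt(n), 1e-6)
    }
    conds[[i]] <- condition_dataset(
      cond,
      data.frame(freq_hz = spec$freqs, elastic_kpa = e,
                 elastic_sem_kpa = e_sem, viscous_kpa = v,
                 viscous_sem_kpa = v_sem),
      f0_kpa = f0, f0_sem_kpa = f0_sem)
    truth_spectra[[cond$name]] <- true_spec
    truth_f0[i] <- ss$F0
  }
  structure(list(
    dataset = study_dataset(conds, L0 = spec$L0),
    truth = list(params = spec$truth_params, config = spec$truth_config,
                 spectra = truth_spectra, f0 = truth_f0, seed = spec$seed)
  ), class = "xb_synth_study")
}
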