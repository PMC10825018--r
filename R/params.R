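# Domain types: kinetic parameter sets, model permutations, metabolite
# conditions.  Internal rate names use "km1" for k-1 etc.; display labels and
# file keys use the conventional primed symbols (k-1', ...).

RATE_NAMES <- c("k1", "km1", "k2", "km2", "k3", "km3")
STRAINABLE_RATES <- c("k1", "km1", "k2", "km2", "k3")

#' Display label for an internal rate name
#' @param x internal rate names, e.g. "km2"
#' @return conventional labels, e.g. "k-2"
#' @keywords internal
rate_label <- function(x) {
  sub("^km", "k-", x)
}

#' Kinetic parameter set for the three-state cross-bridge model
#'
#' Bundles every rate constant, dissociation constant, strain/velocity/length
#' sensitivity and stiffness of the model.  Primed rates (`km1_0`, `k2_0`,
#' `km2_0`, `k3_0`) are the values *before* metabolite and strain scaling.
#' Under direct metabolite dependence (Method 1) `km1_0` and `k3_0` carry
#' units of 1/s/mM; under rapid-equilibrium dependence (Method 2) all rates
#' are 1/s.  Stiffnesses are in kPa/um, numerically identical to GPa/m, so
#' published values in either unit can be used verbatim.
#'
#' @param k1 attachment rate, 1/s
#' @param km1_0 pre-scaling reverse attachment-step rate k-1', 1/s (Method 2)
#'   or 1/s/mM (Method 1)
#' @param k2_0 pre-scaling power-stroke rate k2', 1/s
#' @param km2_0 pre-scaling reverse power-stroke rate k-2', 1/s
#' @param k3_0 pre-scaling detachment rate k3', 1/s (Method 2) or 1/s/mM
#'   (Method 1)
#' @param km3 reverse attachment rate k-3, 1/s (default 0; the model assumes
#'   this rate is negligible but it is carried in full)
#' @param kd_ATP ATP dissociation constant, mM (used under Method 2)
#' @param kd_Pi Pi dissociation constant, mM (used under Method 2)
#' @param phi_x strain-decay sensitivity, unitless, > 0
#' @param phi_v sarcomere-velocity coupling, unitless
#' @param phi_l sarcomere-length sensitivity (slope of the force-length
#'   relation), unitless
#' @param K collective myosin stiffness, kPa/um
#' @param Ks cross-bridge-insensitive stiffness, kPa/um
#' @param phi_s named numeric vector of strain sensitivities (1/um) with
#'   names among `k1, km1, k2, km2, k3`; at most two nonzero entries; an
#'   absent name means no strain dependence on that rate
#' @param xC0 power-stroke strain, um
#' @param Lmax sarcomere length of full cross-bridge availability, um
#' @param L_rest slack length of the cross-bridge-insensitive spring, um
#' @return an object of class `kinetic_params`
#' @seealso [final_model_params()] for the packaged rat trabecula values
#' @export
kinetic_params <- function(k1, km1_0, k2_0, km2_0, k3_0, km3 = 0,
                           kd_ATP = NA_real_, kd_Pi = NA_real_,
                           phi_x, phi_v, phi_l, K, Ks,
                           phi_s = numeric(0),
                           xC0 = 0.01, Lmax = 2.3, L_rest = 1.9) {
  p <- list(k1 = k1, km1_0 = km1_0, k2_0 = k2_0, km2_0 = km2_0, k3_0 = k3_0,
            km3 = km3, kd_ATP = kd_ATP, kd_Pi = kd_Pi,
            phi_x = phi_x, phi_v = phi_v, phi_l = phi_l, K = K, Ks = Ks,
            phi_s = phi_s, xC0 = xC0, Lmax = Lmax, L_rest = L_rest)
  class(p) <- "kinetic_params"
  validate_kinetic_params(p)
  p
}

#' @keywords internal
validate_kinetic_params <- function(p) {
  nonneg <- c("k1", "km1_0", "k2_0", "km2_0", "k3_0", "km3", "K", "Ks")
  for (f in nonneg) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || is.na(p[[f]]) ||
        p[[f]] < 0) {
      stop("kinetic_params: `", f, "` must be a single nonnegative number",
           call. = FALSE)
    }
  }
  for (f in c("kd_ATP", "kd_Pi")) {
    v <- p[[f]]
    if (!is.na(v) && v < 0) {
      stop("kinetic_params: `", f, "` must be nonnegative", call. = FALSE)
    }
  }
  if (p$phi_x <= 0) stop("kinetic_params: `phi_x` must be > 0", call. = FALSE)
  if (p$xC0 <= 0) stop("kinetic_params: `xC0` must be > 0", call. = FALSE)
  if (length(p$phi_s)) {
    if (is.null(names(p$phi_s)) ||
        !all(names(p$phi_s) %in% STRAINABLE_RATES)) {
      stop("kinetic_params: `phi_s` names must be among ",
           paste(rate_label(STRAINABLE_RATES), collapse = ", "),
           " (strain dependence on k-3 is not supported)", call. = FALSE)
    }
    if (anyDuplicated(names(p$phi_s))) {
      stop("kinetic_params: duplicated `phi_s` names", call. = FALSE)
    }
    if (sum(p$phi_s != 0) > 2L) {
      stop("kinetic_params: at most two nonzero strain sensitivities are ",
           "supported", call. = FALSE)
    }
    if (any(p$phi_s < 0)) {
      stop("kinetic_params: `phi_s` entries must be nonnegative",
           call. = FALSE)
    }
  }
  invisible(p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Three-state cross-bridge kinetic parameters\n")
  cat(sprintf("  k1 = %.4g /s   k-1' = %.4g   k2' = %.4g /s   k-2' = %.4g /s   k3' = %.4g\n",
              x$k1, x$km1_0, x$k2_0, x$km2_0, x$k3_0))
  cat(sprintf("  k-3 = %.4g /s   kd_ATP = %.4g mM   kd_Pi = %.4g mM\n",
              x$km3, x$kd_ATP, x$kd_Pi))
  cat(sprintf("  phi_x = %.4g  phi_v = %.4g  phi_l = %.4g\n",
              x$phi_x, x$phi_v, x$phi_l))
  cat(sprintf("  K = %.4g kPa/um   Ks = %.4g kPa/um\n", x$K, x$Ks))
  if (length(x$phi_s)) {
    cat("  strain sensitivities (1/um):",
        paste(sprintf("phi_s[%s] = %.4g", rate_label(names(x$phi_s)),
                      x$phi_s), collapse = ", "), "\n")
  } else {
    cat("  no strain sensitivities\n")
  }
  invisible(x)
}

#' Model permutation: strain placements and metabolite binding methods
#'
#' A permutation of the cross-bridge model is defined by (i) the subset of
#' transition rates (at most two, never k-3) that carry exponential strain
#' dependence and (ii) the method used to make each of Pi and ATP modulate
#' the cycle: `"M1"` scales a detachment rate directly by concentration,
#' `"M2"` applies rapid-equilibrium saturation factors to the two rates
#' leaving the binding state.
#'
#' @param strain character vector (length 0-2) of rates with strain
#'   dependence; internal names (`"km2"`) or display names (`"k-2"`) accepted
#' @param pi_method,atp_method `"M1"` (direct) or `"M2"` (rapid equilibrium)
#' @param label optional permutation code such as `"16D"`; filled in by
#'   [enumerate_permutations()]
#' @return an object of class `model_config`
#' @export
model_config <- function(strain = character(0), pi_method = "M2",
                         atp_method = "M2", label = NULL) {
  strain <- sub("^k-", "km", strain)
  if (!all(strain %in% STRAINABLE_RATES)) {
    bad <- setdiff(strain, STRAINABLE_RATES)
    stop("model_config: strain dependence not supported on: ",
         paste(rate_label(bad), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(strain)) {
    stop("model_config: duplicated strain placements", call. = FALSE)
  }
  if (length(strain) > 2L) {
    stop("model_config: at most two strain placements are supported",
         call. = FALSE)
  }
  if (!pi_method %in% c("M1", "M2") || !atp_method %in% c("M1", "M2")) {
    stop("model_config: methods must be \"M1\" or \"M2\"", call. = FALSE)
  }
  cfg <- list(strain = strain, pi_method = pi_method,
              atp_method = atp_method, label = label)
  class(cfg) <- "model_config"
  cfg
}

#' @export
print.model_config <- function(x, ...) {
  s <- if (length(x$strain)) paste(rate_label(x$strain), collapse = ", ")
       else "none"
  cat(sprintf("Cross-bridge model permutation%s\n",
              if (is.null(x$label)) "" else paste0(" \"", x$label, "\"")))
  cat("  strain dependence:", s, "\n")
  cat(sprintf("  Pi: Method %s   ATP: Method %s\n",
              sub("M", "", x$pi_method), sub("M", "", x$atp_method)))
  invisible(x)
}

#' Metabolite condition of an activating solution
#'
#' @param atp MgATP concentration, mM
#' @param pi inorganic phosphate concentration, mM
#' @param name condition label
#' @return an object of class `metabolite_condition`
#' @export
metabolite_condition <- function(atp, pi, name = sprintf("ATP %g mM / Pi %g mM", atp, pi)) {
  if (atp < 0 || pi < 0) {
    stop("metabolite_condition: concentrations must be nonnegative",
         call. = FALSE)
  }
  structure(list(atp = atp, pi = pi, name = name),
            class = "metabolite_condition")
}

#' @export
print.metabolite_condition <- function(x, ...) {
  cat(sprintf("Metabolite condition \"%s\": [ATP] = %g mM, [Pi] = %g mM\n",
              x$name, x$atp, x$pi))
  invisible(x)
}

#' The five activating-solution conditions of the study design
#'
#' ATP and Pi concentrations of the five activating solutions under which the
#' reference complex-modulus data were collected (baseline, low and super-low
#' ATP, no and high Pi).
#'
#' @return list of five [metabolite_condition()] objects
#' @export
study_conditions <- function() {
  list(
    metabolite_condition(5,   1, "Baseline"),
    metabolite_condition(1,   1, "Low ATP"),
    metabolite_condition(0.1, 1, "Super-low ATP"),
    metabolite_condition(5,   0, "No Pi"),
    metabolite_condition(5,   5, "High Pi")
  )
}

#' Measured steady-state active stresses of the reference study
#'
#' Mean +/- SEM of the active steady-state stress of permeabilised rat
#' trabeculae (n = 11) under the five activating solutions of
#' [study_conditions()].  Used as fitting inputs and as the reference that
#' model steady-state stresses are checked against.
#'
#' @return data.frame with columns `condition`, `atp_mM`, `pi_mM`, `f0_kpa`,
#'   `sem_kpa`
#' @export
reference_stress_data <- function() {
  data.frame(
    condition = c("Baseline", "Low ATP", "Super-low ATP", "No Pi", "High Pi"),
    atp_mM = c(5, 1, 0.1, 5, 5),
    pi_mM  = c(1, 1, 1, 0, 5),
    f0_kpa = c(21.8, 27.7, 32.3, 25.5, 18.0),
    sem_kpa = c(2.1, 3.1, 2.4, 2.9, 1.6),
    stringsAsFactors = FALSE
  )
}

#' Final fitted rat-trabecula parameter set
#'
#' The optimal parameter values of the final model permutation (`"16D"`:
#' rapid-equilibrium ATP and Pi binding, strain dependence on k-2 and k3),
#' fitted to rat cardiac trabecula active complex moduli at sarcomere length
#' 2.2 um.
#'
#' @return a [kinetic_params()] object
#' @export
final_model_params <- function() {
  kinetic_params(
    k1 = 9.65, km1_0 = 19.6, k2_0 = 13.5, km2_0 = 1.11, k3_0 = 13.0,
    km3 = 0, kd_ATP = 2.36, kd_Pi = 5.00,
    phi_x = 9.00, phi_v = 0.101, phi_l = 3.89,
    K = 3150, Ks = 45.0,
    phi_s = c(km2 = 995, k3 = 71.1)
  )
}

#' Final model permutation configuration
#'
#' @return the [model_config()] of permutation `"16D"`
#' @export
final_model_config <- function() {
  model_config(strain = c("km2", "k3"), pi_method = "M2", atp_method = "M2",
               label = "16D")
}

# ---- parameter file (de)serialisation --------------------------------------

# file keys use the conventional primed symbols
PARAM_FILE_KEYS <- c(
  k1 = "k1", km1_0 = "k-1'", k2_0 = "k2'", km2_0 = "k-2'", k3_0 = "k3'",
  km3 = "k-3", phi_x = "phi_x", phi_v = "phi_v", phi_l = "phi_l",
  K = "K", Ks = "Ks", kd_ATP = "kd_ATP", kd_Pi = "kd_Pi",
  xC0 = "xC0", Lmax = "Lmax", L_rest = "L_rest"
)
PHI_S_FILE_KEYS <- c(k1 = "phi_s1", km1 = "phi_s-1", k2 = "phi_s2",
                     km2 = "phi_s-2", k3 = "phi_s3")

#' Write a parameter set to a YAML file
#'
#' Keys follow the conventional symbols (`k1`, `k-1'`, `k2'`, `k-2'`, `k3'`,
#' `phi_x`, `phi_v`, `phi_l`, `K`, `Ks`, `phi_s-2`, `phi_s3`, `kd_ATP`,
#' `kd_Pi`, ...), so published parameter tables can be transcribed verbatim.
#'
#' @param params a [kinetic_params()] object
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_params <- function(params, path) {
  out <- list()
  for (f in names(PARAM_FILE_KEYS)) {
    v <- params[[f]]
    if (!is.na(v)) out[[PARAM_FILE_KEYS[[f]]]] <- v
  }
  for (r in names(params$phi_s)) {
    out[[PHI_S_FILE_KEYS[[r]]]] <- unname(params$phi_s[[r]])
  }
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Read a parameter set from a YAML file
#'
#' @param path file written by [write_params()] (or hand-authored with the
#'   same keys)
#' @return a [kinetic_params()] object
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (f in names(PARAM_FILE_KEYS)) {
    key <- PARAM_FILE_KEYS[[f]]
    if (!is.null(raw[[key]])) args[[f]] <- raw[[key]]
  }
  phi_s <- numeric(0)
  for (r in names(PHI_S_FILE_KEYS)) {
    key <- PHI_S_FILE_KEYS[[r]]
    if (!is.null(raw[[key]])) phi_s[r] <- raw[[key]]
  }
  args$phi_s <- phi_s
  do.call(kinetic_params, args)
}
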