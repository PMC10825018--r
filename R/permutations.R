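# Enumeration of the 64 model permutations: 16 strain-placement sets
# (numbered rows) crossed with 4 metabolite-method pairs (lettered columns).

# strain-placement rows in the published reference order
STRAIN_SETS <- list(
  character(0),            # 1  none
  "k1",                    # 2
  "km1",                   # 3
  "k2",                    # 4
  "km2",                   # 5
  "k3",                    # 6
  c("k1", "km1"),          # 7
  c("k1", "k2"),           # 8
  c("k1", "km2"),          # 9
  c("k1", "k3"),           # 10
  c("km1", "k2"),          # 11
  c("km1", "km2"),         # 12
  c("km1", "k3"),          # 13
  c("k2", "km2"),          # 14
  c("k2", "k3"),           # 15
  c("km2", "k3")           # 16
)

# column letters: (Pi method, ATP method)
METHOD_PAIRS <- list(
  A = c(pi = "M1", atp = "M1"),
  B = c(pi = "M2", atp = "M1"),
  C = c(pi = "M1", atp = "M2"),
  D = c(pi = "M2", atp = "M2")
)

#' Enumerate all 64 model permutations
#'
#' The cross product of the 16 strain-placement sets (no strain, each single
#' rate, each pair of rates; never k-3, never more than two) with the four
#' metabolite-method pairs (A: Pi M1/ATP M1, B: Pi M2/ATP M1, C: Pi M1/ATP
#' M2, D: Pi M2/ATP M2), in row-major label order `1A, 1B, ..., 16D`.
#'
#' @return list of 64 [model_config()] objects, named by label
#' @export
enumerate_permutations <- function() {
  out <- list()
  for (row in seq_along(STRAIN_SETS)) {
    for (col in names(METHOD_PAIRS)) {
      lab <- paste0(row, col)
      mp <- METHOD_PAIRS[[col]]
      out[[lab]] <- model_config(strain = STRAIN_SETS[[row]],
                                 pi_method = mp[["pi"]],
                                 atp_method = mp[["atp"]],
                                 label = lab)
    }
  }
  out
}

#' Resolve a permutation label to its model configuration
#'
#' @param label permutation code such as `"14D"` (row 1-16, column A-D)
#' @return a [model_config()] object
#' @export
permutation_config <- function(label) {
  m <- regmatches(label, regexec("^([0-9]{1,2})([A-D])$", label))[[1]]
  if (length(m) != 3L) {
    stop("permutation_config: malformed label \"", label, "\"",
         call. = FALSE)
  }
  row <- as.integer(m[2])
  if (row < 1L || row > 16L) {
    stop("permutation_config: row must be 1-16 in \"", label, "\"",
         call. = FALSE)
  }
  mp <- METHOD_PAIRS[[m[3]]]
  model_config(strain = STRAIN_SETS[[row]], pi_method = mp[["pi"]],
               atp_method = mp[["atp"]], label = label)
}

#' Free-parameter slots of a model permutation
#'
#' Every permutation shares ten base parameters (five rates, phi_x, phi_v,
#' phi_l, K, Ks); each strain placement adds a `phi_s` slot and each
#' rapid-equilibrium (Method 2) metabolite adds a `kd` slot, for 10 to 14
#' free parameters.  Units of `k-1'` and `k3'` depend on the metabolite
#' method (1/s/mM under Method 1, 1/s under Method 2).
#'
#' @param config a [model_config()] object
#' @return data.frame with columns `slot` (display name), `field` (internal
#'   parameter field), `rate` (strain rate for phi_s slots, else `NA`) and
#'   `unit`
#' @export
parameter_slots <- function(config) {
  base <- data.frame(
    slot = c("k1", "k-1'", "k2'", "k-2'", "k3'",
             "phi_x", "phi_v", "phi_l", "K", "Ks"),
    field = c("k1", "km1_0", "k2_0", "km2_0", "k3_0",
              "phi_x", "phi_v", "phi_l", "K", "Ks"),
    rate = NA_character_,
    unit = c("1/s",
             if (config$pi_method == "M1") "1/s/mM" else "1/s",
             "1/s", "1/s",
             if (config$atp_method == "M1") "1/s/mM" else "1/s",
             "unitless", "unitless", "unitless", "kPa/um", "kPa/um"),
    stringsAsFactors = FALSE
  )
  rows <- list(base)
  strain <- intersect(STRAINABLE_RATES, config$strain)  # canonical order
  for (r in strain) {
    rows <- c(rows, list(data.frame(
      slot = PHI_S_FILE_KEYS[[r]], field = "phi_s", rate = r, unit = "1/um",
      stringsAsFactors = FALSE)))
  }
  if (config$pi_method == "M2") {
    rows <- c(rows, list(data.frame(slot = "kd_Pi", field = "kd_Pi",
                                    rate = NA_character_, unit = "mM",
                                    stringsAsFactors = FALSE)))
  }
  if (config$atp_method == "M2") {
    rows <- c(rows, list(data.frame(slot = "kd_ATP", field = "kd_ATP",
                                    rate = NA_character_, unit = "mM",
                                    stringsAsFactors = FALSE)))
  }
  do.call(rbind, rows)
}

#' Build a parameter set from a free-parameter vector
#'
#' Inverse of [parameter_slots()]: maps an ordered numeric vector of free
#' parameters onto a [kinetic_params()] object for the given permutation.
#'
#' @param x numeric vector ordered as `parameter_slots(config)$slot`
#' @param config a [model_config()] object
#' @return a [kinetic_params()] object
#' @export
params_from_vector <- function(x, config) {
  slots <- parameter_slots(config)
  if (length(x) != nrow(slots)) {
    stop("params_from_vector: expected ", nrow(slots), " values for ",
         "permutation ", if (is.null(config$label)) "" else config$label,
         ", got ", length(x), call. = FALSE)
  }
  x <- as.numeric(x)
  args <- list(phi_s = numeric(0))
  for (i in seq_len(nrow(slots))) {
    if (slots$field[i] == "phi_s") {
      args$phi_s[slots$rate[i]] <- x[i]
    } else {
      args[[slots$field[i]]] <- x[i]
    }
  }
  do.call(kinetic_params, args)
}
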