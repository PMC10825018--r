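# Dataset containers: per-condition complex-modulus measurements with SEMs
# and steady-state stress, and the multi-condition study bundle.

#' Per-condition complex-modulus dataset
#'
#' @param condition a [metabolite_condition()]
#' @param data data.frame with columns `freq_hz`, `elastic_kpa`,
#'   `elastic_sem_kpa`, `viscous_kpa`, `viscous_sem_kpa`
#' @param f0_kpa mean steady-state active stress, kPa
#' @param f0_sem_kpa SEM of the steady-state stress, kPa (> 0)
#' @return an object of class `xb_condition_dataset`
#' @export
condition_dataset <- function(condition, data, f0_kpa, f0_sem_kpa) {
  needed <- c("freq_hz", "elastic_kpa", "elastic_sem_kpa", "viscous_kpa",
              "viscous_sem_kpa")
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    stop("condition_dataset: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(data$freq_hz, strictly = TRUE)) {
    stop("condition_dataset: `freq_hz` must be strictly increasing",
         call. = FALSE)
  }
  if (any(data$elastic_sem_kpa < 0) || any(data$viscous_sem_kpa < 0)) {
    stop("condition_dataset: SEM columns must be nonnegative", call. = FALSE)
  }
  if (!is.numeric(f0_sem_kpa) || f0_sem_kpa <= 0) {
    stop("condition_dataset: `f0_sem_kpa` must be > 0", call. = FALSE)
  }
  structure(list(condition = condition, data = data[needed],
                 f0_kpa = f0_kpa, f0_sem_kpa = f0_sem_kpa),
            class = "xb_condition_dataset")
}

#' Multi-condition study dataset
#'
#' @param conditions list of [condition_dataset()] objects sharing one
#'   frequency grid
#' @param L0 reference sarcomere length, um
#' @return an object of class `xb_study_dataset`
#' @export
study_dataset <- function(conditions, L0 = 2.2) {
  if (!length(conditions)) {
    stop("study_dataset: at least one condition is required", call. = FALSE)
  }
  f1 <- conditions[[1]]$data$freq_hz
  for (cd in conditions[-1]) {
    if (length(cd$data$freq_hz) != length(f1) ||
        max(abs(cd$data$freq_hz - f1)) > 1e-9 * max(f1)) {
      stop("study_dataset: all conditions must share the frequency grid",
           call. = FALSE)
    }
  }
  structure(list(conditions = conditions, L0 = L0),
            class = "xb_study_dataset")
}

#' @export
print.xb_study_dataset <- function(x, ...) {
  cat(sprintf("Complex-modulus study dataset: %d condition(s), %d frequencies, L0 = %g um\n",
              length(x$conditions), nrow(x$conditions[[1]]$data), x$L0))
  for (cd in x$conditions) {
    cat(sprintf("  %-14s [ATP] = %4.3g mM  [Pi] = %g mM   F0 = %.2f +/- %.2f kPa\n",
                cd$condition$name, cd$condition$atp, cd$condition$pi,
                cd$f0_kpa, cd$f0_sem_kpa))
  }
  invisible(x)
}

#' Modulus range of a study dataset
#'
#' The normalisation constant for reporting RMSEs as percentages: the mean,
#' over conditions, of the spread (max minus min pooling elastic and viscous
#' moduli over all frequencies).
#'
#' @param dataset an [study_dataset()]
#' @return modulus range, kPa
#' @export
modulus_range <- function(dataset) {
  ranges <- vapply(dataset$conditions, function(cd) {
    v <- c(cd$data$elastic_kpa, cd$data$viscous_kpa)
    max(v) - min(v)
  }, numeric(1))
  mean(ranges)
}

#' Deterministic down-sampling of a study dataset
#'
#' Subsets conditions and/or frequencies, for identifiability experiments
#' (for example, single-condition data cannot separate a dissociation
#' constant from the primed rates).
#'
#' @param dataset an [study_dataset()]
#' @param keep_conditions names (or indices) of conditions to keep
#' @param keep_freqs indices into the frequency grid to keep
#' @return an [study_dataset()]
#' @export
degrade_study <- function(dataset, keep_conditions = NULL,
                          keep_freqs = NULL) {
  conds <- dataset$conditions
  if (!is.null(keep_conditions)) {
    if (is.character(keep_conditions)) {
      nm <- vapply(conds, function(cd) cd$condition$name, character(1))
      idx <- match(keep_conditions, nm)
      if (anyNA(idx)) {
        stop("degrade_study: unknown condition(s): ",
             paste(keep_conditions[is.na(idx)], collapse = ", "),
             call. = FALSE)
      }
    } else {
      idx <- keep_conditions
    }
    conds <- conds[idx]
  }
  if (!length(conds)) {
    stop("degrade_study: at least one condition must remain", call. = FALSE)
  }
  if (!is.null(keep_freqs)) {
    if (length(keep_freqs) < 4L) {
      stop("degrade_study: at least 4 frequencies must remain",
           call. = FALSE)
    }
    conds <- lapply(conds, function(cd) {
      cd$data <- cd$data[keep_freqs, , drop = FALSE]
      rownames(cd$data) <- NULL
      cd
    })
  }
  study_dataset(conds, L0 = dataset$L0)
}
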