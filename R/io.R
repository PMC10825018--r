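# Readers and writers: spectrum CSVs, the per-condition study format
# (one CSV per condition plus a YAML manifest) and result reporting.
#
# Numeric fields are serialised with 17 significant digits ("%.17g"), the
# shortest representation that round-trips IEEE doubles bit-exactly.

fmt_num <- function(x) sprintf("%.17g", x)

write_numeric_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a complex-modulus spectrum to CSV
#'
#' Columns `freq_hz`, `elastic_kpa`, `viscous_kpa` (full precision; the
#' round trip through [read_spectrum_csv()] is bit-exact).
#'
#' @param spec an [spectrum()] object
#' @param path output file
#' @return `path`, invisibly
#' @export
write_spectrum_csv <- function(spec, path) {
  write_numeric_csv(as.data.frame(spec)[c("freq_hz", "elastic_kpa",
                                          "viscous_kpa")], path)
}

#' Read a complex-modulus spectrum from CSV
#'
#' @param path file written by [write_spectrum_csv()]
#' @return an [spectrum()] object
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  needed <- c("freq_hz", "elastic_kpa", "viscous_kpa")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("read_spectrum_csv: ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  spectrum(df$freq_hz, df$elastic_kpa, df$viscous_kpa)
}

#' Write a study dataset to a directory
#'
#' One CSV per condition (`freq_hz`, `elastic_kpa`, `elastic_sem_kpa`,
#' `viscous_kpa`, `viscous_sem_kpa`) plus a `manifest.yaml` naming each
#' condition with its metabolite concentrations, steady-state stress mean
#' and SEM, and the reference sarcomere length.  Numeric manifest fields
#' are stored as 17-digit strings so the round trip is bit-exact.
#'
#' @param dataset an [study_dataset()]
#' @param dir output directory (created if absent)
#' @return the manifest path, invisibly
#' @export
write_study <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- list()
  for (i in seq_along(dataset$conditions)) {
    cd <- dataset$conditions[[i]]
    file <- sprintf("condition_%02d.csv", i)
    write_numeric_csv(cd$data, file.path(dir, file))
    entries[[i]] <- list(name = cd$condition$name,
                         atp_mM = fmt_num(cd$condition$atp),
                         pi_mM = fmt_num(cd$condition$pi),
                         f0_kpa = fmt_num(cd$f0_kpa),
                         f0_sem_kpa = fmt_num(cd$f0_sem_kpa),
                         file = file)
  }
  manifest <- list(format = "xb_study", version = 1L,
                   L0_um = fmt_num(dataset$L0), conditions = entries)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a study dataset written by [write_study()]
#'
#' @param dir directory containing `manifest.yaml`, or the manifest path
#'   itself
#' @return an [study_dataset()]
#' @export
read_study <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "manifest.yaml") else dir
  if (!file.exists(path)) {
    stop("read_study: no manifest at ", path, call. = FALSE)
  }
  manifest <- yaml::read_yaml(path)
  if (is.null(manifest$format) || manifest$format != "xb_study") {
    stop("read_study: ", path, " is not a study manifest", call. = FALSE)
  }
  if (is.null(manifest$version) || manifest$version > 1L) {
    stop("read_study: unsupported manifest version in ", path,
         call. = FALSE)
  }
  base <- dirname(path)
  conds <- lapply(manifest$conditions, function(e) {
    f <- file.path(base, e$file)
    df <- utils::read.csv(f, colClasses = "numeric")
    needed <- c("freq_hz", "elastic_kpa", "elastic_sem_kpa", "viscous_kpa",
                "viscous_sem_kpa")
    missing <- setdiff(needed, names(df))
    if (length(missing)) {
      stop("read_study: ", f, " is missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    condition_dataset(
      metabolite_condition(as.numeric(e$atp_mM), as.numeric(e$pi_mM),
                           e$name),
      df, f0_kpa = as.numeric(e$f0_kpa),
      f0_sem_kpa = as.numeric(e$f0_sem_kpa))
  })
  study_dataset(conds, L0 = as.numeric(manifest$L0_um))
}

#' Write result files for a fit, a scan table, or a study overlay
#'
#' For an `xb_scan_table`: the 16 x 4 normalised-RMSE grid as CSV (layout
#' matching the permutation reference grid).  For an `xb_fit_result`: the
#' fitted parameters (YAML), the per-condition fit summary (CSV), and, when
#' a dataset is supplied, one data-versus-model overlay plot per condition.
#' Every call also writes `provenance.json` recording the seed and settings
#' so a run can be reproduced.
#'
#' @param x an `xb_fit_result` or `xb_scan_table`
#' @param out_dir output directory (created if absent)
#' @param dataset optional [study_dataset()] for overlay plots
#' @return character vector of files written, invisibly
#' @export
write_report <- function(x, out_dir, dataset = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  add <- function(p) written <<- c(written, p)
  if (inherits(x, "xb_scan_table")) {
    tab <- x
    attributes(tab) <- attributes(tab)[c("dim", "dimnames")]
    df <- data.frame(strain_set = rownames(tab), tab, check.names = FALSE)
    p <- file.path(out_dir, "scan_table.csv")
    utils::write.csv(df, p, row.names = FALSE)
    add(p)
    prov <- list(kind = "scan", seed = attr(x, "seed"),
                 settings = attr(x, "settings"),
                 package_version = as.character(utils::packageVersion("xbkinetics")))
  } else if (inherits(x, "xb_fit_result")) {
    p <- file.path(out_dir, "fitted_params.yaml")
    write_params(x$params, p)
    add(p)
    nm <- if (!is.null(dataset)) {
      vapply(dataset$conditions, function(cd) cd$condition$name,
             character(1))
    } else seq_along(x$rmse)
    df <- data.frame(condition = nm, rmse_kpa = x$rmse,
                     f0_model_kpa = x$f0_model, f0_err_kpa = x$f0_err)
    p <- file.path(out_dir, "fit_summary.csv")
    utils::write.csv(df, p, row.names = FALSE)
    add(p)
    if (!is.null(dataset)) {
      for (cd in dataset$conditions) {
        mod <- complex_modulus_linear(x$params, x$config, cd$condition,
                                      freqs = cd$data$freq_hz,
                                      L0 = dataset$L0)
        p <- file.path(out_dir, sprintf("overlay_%s.pdf",
                                        gsub("[^A-Za-z0-9]+", "_",
                                             cd$condition$name)))
        plot_condition_overlay(cd, mod, p)
        add(p)
      }
    }
    prov <- list(kind = "fit",
                 label = if (is.null(x$config$label)) NA else x$config$label,
                 seed = x$seed, settings = x$settings,
                 objective_kpa = x$objective,
                 normalised_rmse_pct = x$normalised_rmse,
                 package_version = as.character(utils::packageVersion("xbkinetics")))
  } else {
    stop("write_report: unsupported object of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
  p <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  add(p)
  invisible(written)
}

# data-vs-model overlay for one condition (elastic and viscous panels)
plot_condition_overlay <- function(cond_data, model_spec, path) {
  d <- cond_data$data
  long <- rbind(
    data.frame(freq_hz = d$freq_hz, modulus = d$elastic_kpa,
               sem = d$elastic_sem_kpa, component = "elastic",
               what = "data"),
    data.frame(freq_hz = d$freq_hz, modulus = d$viscous_kpa,
               sem = d$viscous_sem_kpa, component = "viscous",
               what = "data"),
    data.frame(freq_hz = model_spec$freq_hz,
               modulus = model_spec$elastic_kpa, sem = NA,
               component = "elastic", what = "model"),
    data.frame(freq_hz = model_spec$freq_hz,
               modulus = model_spec$viscous_kpa, sem = NA,
               component = "viscous", what = "model")
  )
  g <- ggplot2::ggplot(long, ggplot2::aes(x = .data$freq_hz,
                                          y = .data$modulus)) +
    ggplot2::geom_line(data = long[long$what == "model", ],
                       ggplot2::aes(colour = .data$component)) +
    ggplot2::geom_pointrange(
      data = long[long$what == "data", ],
      ggplot2::aes(ymin = .data$modulus - .data$sem,
                   ymax = .data$modulus + .data$sem,
                   colour = .data$component), size = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "modulus (kPa)",
                  title = cond_data$condition$name) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, g, width = 6, height = 4)
  invisible(path)
}
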