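#' Path to a bundled example dataset
#'
#' @param file File name within the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @examples
#' girk_example()
#' girk_example("table1_oocytes.csv")
#' @export
girk_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "girkstoich")))
  }
  path <- system.file("extdata", file, package = "girkstoich")
  if (path == "") abort(sprintf("No bundled file named '%s'.", file))
  path
}

measurement_cols <- c("cell_id", "group", "cell_type", "units",
                      "i_basal", "i_evoked", "i_total", "i_bg",
                      "k_out", "holding")

#' Read a table of current measurements
#'
#' Reads a CSV/TSV of per-cell or per-group whole-cell current measurements
#' with (a subset of) the columns `cell_id`, `group`, `cell_type`, `units`,
#' `i_basal`, `i_evoked`, `i_total`, `i_bg`, `k_out`, `holding`. `i_total`
#' is backfilled as `i_basal + i_evoked` where absent; when all three are
#' present, inconsistencies beyond rounding raise a warning and
#' contradictions (`i_basal > i_total`, negative currents) an error listing
#' the offending rows.
#'
#' @param path Path to a delimited text file (delimiter sniffed from the
#'   extension: `.tsv` reads as tab, anything else as comma).
#' @return A tibble of validated measurements. Extra columns are carried
#'   through untouched.
#' @examples
#' read_measurements(girk_example("table1_oocytes.csv"))
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (file.size(path) == 0) {
    return(tibble::tibble(
      group = character(), i_basal = double(), i_evoked = double(),
      i_total = double(), i_bg = double()
    ))
  }
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  data <- reader(path, show_col_types = FALSE, progress = FALSE)
  known <- intersect(names(data), measurement_cols)
  cur_cols <- intersect(c("i_basal", "i_evoked", "i_total", "i_bg"), known)
  if (length(cur_cols) == 0) {
    abort("No current columns (i_basal/i_evoked/i_total/i_bg) found.")
  }
  for (cc in cur_cols) {
    if (!is.numeric(data[[cc]])) {
      abort(sprintf("Column '%s' must be numeric.", cc))
    }
  }
  bad_neg <- which(purrr::reduce(
    purrr::map(cur_cols, ~ !is.na(data[[.x]]) & data[[.x]] < 0), `|`
  ))
  if (length(bad_neg)) {
    abort(paste("Negative currents in row(s):",
                paste(bad_neg, collapse = ", ")))
  }
  if (!"i_total" %in% names(data) &&
      all(c("i_basal", "i_evoked") %in% names(data))) {
    data$i_total <- data$i_basal + data$i_evoked
  }
  if (all(c("i_basal", "i_total") %in% names(data))) {
    bad <- which(!is.na(data$i_basal) & !is.na(data$i_total) &
                   data$i_basal > data$i_total * (1 + 1e-6))
    if (length(bad)) {
      abort(paste("i_basal exceeds i_total in row(s):",
                  paste(bad, collapse = ", ")))
    }
  }
  if (all(c("i_basal", "i_evoked", "i_total") %in% names(data))) {
    disc <- abs(data$i_basal + data$i_evoked - data$i_total)
    bad <- which(!is.na(disc) & disc > 1e-6 * pmax(data$i_total, 1))
    if (length(bad)) {
      warn(sprintf(
        "i_total differs from i_basal + i_evoked in row(s) %s (max discrepancy %.4g).",
        paste(bad, collapse = ", "), max(disc[bad])
      ))
    }
  }
  data
}

#' Write a stoichiometry report
#'
#' Writes a long-format CSV of estimates plus a plain-text summary with the
#' model parameters, solver residuals and package version. Output is
#' deterministic for identical inputs (no timestamps).
#'
#' @param estimates A `girk_stoich` table from [infer_stoichiometry()].
#' @param dir Output directory (created if needed).
#' @param stem File name stem (default `"stoichiometry"`).
#' @return Invisibly, the paths of the files written.
#' @examples
#' est <- infer_stoichiometry(read_measurements(girk_example("table1_oocytes.csv")))
#' write_report(est, tempdir())
#' @export
write_report <- function(estimates, dir, stem = "stoichiometry") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv_path <- file.path(dir, paste0(stem, ".csv"))
  txt_path <- file.path(dir, paste0(stem, "_summary.txt"))
  long <- if (inherits(estimates, "girk_stoich")) {
    tidy(estimates)
  } else {
    tibble::as_tibble(estimates)
  }
  readr::write_csv(long, csv_path)

  lines <- c(
    sprintf("girkstoich %s stoichiometry report",
            as.character(utils::packageVersion("girkstoich"))),
    ""
  )
  if (inherits(estimates, "girk_stoich")) {
    gl <- glance(estimates)
    lines <- c(
      lines,
      sprintf("model variant:   %s", gl$variant),
      sprintf("kd_channel:      %g nM", gl$kd_channel),
      sprintf("kd_trimer:       %g nM", gl$kd_trimer),
      sprintf("po_max:          %g", gl$po_max),
      sprintf("width:           %g nm", gl$width_nm),
      sprintf("density source:  %s", gl$density_source),
      ""
    )
    for (i in seq_len(nrow(estimates))) {
      r <- estimates[i, ]
      lines <- c(lines, if (isTRUE(r$feasible)) {
        sprintf(
          "group %s: density %.3g /um^2; Gbg %.3g /um^2 (%.3g per channel); Ga %.3g /um^2 (%.3g per channel); residuals %.2e / %.2e",
          r$group, r$channel_density, r$gbg_total, r$gbg_per_channel,
          r$ga_total, r$ga_per_channel, r$residual_gbg, r$residual_ga
        )
      } else {
        sprintf("group %s: INFEASIBLE (%s)", r$group, r$note)
      })
    }
  } else {
    lines <- c(lines, sprintf("%d rows written.", nrow(long)))
  }
  writeLines(lines, txt_path)
  invisible(c(csv = csv_path, summary = txt_path))
}
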