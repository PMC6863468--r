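# Canonical measurement CSV schema (schema version 1). Fixed column order.
MEASUREMENT_COLUMNS <- c("individual_id", "species", "tissue", "tissue_class",
                         "quantity", "T_a_C", "T_tissue_C", "flux",
                         "flux_basis", "area_m2", "dry_mass_g")
SCHEMA_VERSION <- "1"

#' Read measurement records from CSV
#'
#' Reads a long-format measurement table in the canonical schema (one row
#' per flux observation; see [write_measurements()] for the column list),
#' validates it, converts any area-basis rows to the canonical dry-mass
#' basis via [convert_area_to_mass_flux()], and attaches the four-level
#' tissue classification. Validation problems are aggregated and reported
#' together, naming the offending columns or rows.
#'
#' @param path CSV file path.
#' @param ta_levels If non-`NULL`, acclimation temperatures are checked
#'   against this set of configured levels.
#' @return A tibble of validated, mass-basis measurement records.
#' @export
read_measurements <- function(path, ta_levels = NULL) {
  # pin the numeric columns (an all-NA optional column must stay numeric);
  # absence of a required column is our own aggregated error below, not a
  # parser complaint
  raw <- withCallingHandlers(
    readr::read_csv(
      path, show_col_types = FALSE,
      col_types = readr::cols(T_a_C = "d", T_tissue_C = "d", flux = "d",
                              area_m2 = "d", dry_mass_g = "d")
    ),
    warning = function(w) {
      if (grepl("parsers don't match", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  problems <- character()

  missing_cols <- setdiff(setdiff(MEASUREMENT_COLUMNS,
                                  c("area_m2", "dry_mass_g")), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"area_m2" %in% names(raw)) raw$area_m2 <- NA_real_
  if (!"dry_mass_g" %in% names(raw)) raw$dry_mass_g <- NA_real_

  bad_tissue <- setdiff(unique(raw$tissue), TISSUES)
  if (length(bad_tissue) > 0) {
    problems <- c(problems, paste0("unknown tissue label(s): ",
                                   paste(bad_tissue, collapse = ", ")))
  }
  bad_class <- setdiff(unique(raw$tissue_class), TISSUE_CLASSES)
  if (length(bad_class) > 0) {
    problems <- c(problems, paste0("unknown tissue class(es): ",
                                   paste(bad_class, collapse = ", ")))
  }
  bad_quantity <- setdiff(unique(raw$quantity), c("rd", "vcmax"))
  if (length(bad_quantity) > 0) {
    problems <- c(problems, paste0("unknown quantity label(s): ",
                                   paste(bad_quantity, collapse = ", ")))
  }
  if (!is.null(ta_levels) && !all(raw$T_a_C %in% ta_levels)) {
    problems <- c(problems,
                  paste0("T_a_C outside configured levels {",
                         paste(ta_levels, collapse = ", "), "}"))
  }
  if (any(!is.finite(raw$flux))) {
    problems <- c(problems, "non-finite flux values")
  }
  dup <- raw |>
    count(.data$individual_id, .data$tissue, .data$quantity,
          .data$T_tissue_C) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    problems <- c(problems,
                  paste0(nrow(dup),
                         " duplicate (individual, tissue, quantity, ",
                         "T_tissue) key(s)"))
  }
  area_rows <- raw$flux_basis == "area"
  if (any(area_rows & (is.na(raw$area_m2) | is.na(raw$dry_mass_g)))) {
    problems <- c(problems,
                  "area-basis rows lacking area_m2 and/or dry_mass_g")
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid measurement file '", path, "':\n- ",
                 paste(problems, collapse = "\n- ")))
  }

  if (any(area_rows)) {
    raw$flux[area_rows] <- convert_area_to_mass_flux(
      raw$flux[area_rows], raw$area_m2[area_rows],
      raw$dry_mass_g[area_rows])
    raw$flux_basis[area_rows] <- "mass"
  }
  raw |>
    mutate(tissue_class4 = tissue_class4(.data$tissue, .data$tissue_class)) |>
    select(all_of(c(MEASUREMENT_COLUMNS[1:4], "tissue_class4",
                    MEASUREMENT_COLUMNS[5:11])))
}

#' Write measurement records to CSV
#'
#' Writes records in the canonical schema: `individual_id`, `species`,
#' `tissue` (leaf/stem/root), `tissue_class`
#' (photosynthetic/non_photosynthetic), `quantity` (rd/vcmax), `T_a_C`,
#' `T_tissue_C` (degC), `flux` (umol g-1 s-1 when `flux_basis = "mass"`,
#' umol m-2 s-1 when `"area"`), `flux_basis`, `area_m2`, `dry_mass_g`.
#'
#' @param records Measurement records (e.g. `simulate_study()$records`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  records |>
    select(all_of(MEASUREMENT_COLUMNS)) |>
    readr::write_csv(path)
  invisible(path)
}

#' Write a pipeline report to disk
#'
#' Writes the tables of a [run_pipeline()] report as CSVs with fixed,
#' versioned headers, a JSON metadata sidecar sufficient to reproduce the
#' run, and a plain-text log:
#'
#' * `fits.csv` — per-series curve fits; `fit_failures.csv` when any.
#' * `table2.csv` — Wald chi-square tests (`parameter`, `term`, `df`,
#'   `chisq`, `p`).
#' * `table3.csv` — least-squares-mean trends (`tissue`, `parameter`,
#'   `slope`, `se`, `df`, `t`, `p`, `intercept`, `intercept_se`).
#' * `table4.csv` — homeostasis grid, one row per acclimation temperature
#'   plus an average row; one tissue per column plus an average column.
#' * `ratio_trends.csv` — ln(R_d,acc/V_cmax,acc) trends (when V_cmax
#'   records were present).
#' * `metadata.json`, `log.txt`.
#'
#' @param report A [run_pipeline()] result.
#' @param outdir Output directory (created if needed).
#' @return The vector of written file paths, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "resp_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) abort(paste0("Cannot create directory ", outdir))
  paths <- character()
  put <- function(df, file) {
    p <- file.path(outdir, file)
    readr::write_csv(df, p)
    paths <<- c(paths, p)
  }
  put(as_tibble(report$fits), "fits.csv")
  if (nrow(fit_failures(report$fits)) > 0) {
    put(fit_failures(report$fits), "fit_failures.csv")
  }
  put(report$table2, "table2.csv")
  put(report$table3, "table3.csv")
  put(homeo_wide(report$table4), "table4.csv")
  if (!is.null(report$ratio_trends)) {
    put(report$ratio_trends, "ratio_trends.csv")
  }
  meta_path <- file.path(outdir, "metadata.json")
  jsonlite::write_json(report$metadata, meta_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_path <- file.path(outdir, "log.txt")
  writeLines(report$log, log_path)
  invisible(c(paths, meta_path, log_path))
}
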