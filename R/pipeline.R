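#' Configure an end-to-end analysis run
#'
#' Bundles every setting of the pipeline: the study design (for
#' simulation) or an input CSV path, the generating-truth configuration,
#' the curve-fitting scale, the degrees-of-freedom method, the reference
#' acclimation temperature and the master seed.
#'
#' @param design Design preset name or [make_design()] object (used when
#'   simulating).
#' @param input Optional path to a measurement CSV ([read_measurements()]
#'   schema); when given, no data are simulated.
#' @param truth A [truth_config()] for simulation.
#' @param scale Curve-fitting scale, see [fit_polynomial()].
#' @param df_method Degrees-of-freedom approximation, see [lsm_trends()].
#' @param t_ref Reference acclimation temperature (degC) for the
#'   homeostasis statistic; must be one of the design's T_a levels.
#' @param ta_grid Acclimation temperatures of the homeostasis grid
#'   (default: the design levels minus `t_ref`).
#' @param seed Integer master seed for all randomness.
#' @param vcmax Include the V_cmax series and the ratio analysis?
#' @return A list of class `resp_config`.
#' @export
run_config <- function(design = "table1", input = NULL,
                       truth = truth_config(),
                       scale = c("log_ols", "original_nls"),
                       df_method = c("satterthwaite", "kenward-roger"),
                       t_ref = 25, ta_grid = NULL, seed = 1, vcmax = TRUE) {
  scale <- match.arg(scale)
  df_method <- match.arg(df_method)
  if (is.character(design)) design <- make_design(design)
  if (!inherits(truth, "truth_config")) truth <- do.call(truth_config, truth)
  if (is.null(input) && !t_ref %in% design$ta_levels) {
    abort("`t_ref` must be one of the design's acclimation temperatures.")
  }
  if (!is.numeric(seed) || seed != round(seed)) {
    abort("`seed` must be an integer.")
  }
  structure(
    list(design = design, input = input, truth = truth, scale = scale,
         df_method = df_method, t_ref = t_ref, ta_grid = ta_grid,
         seed = as.integer(seed), vcmax = vcmax),
    class = "resp_config"
  )
}

#' Run the full acclimation analysis pipeline
#'
#' Orchestrates every stage on one configuration: obtain data (simulate a
#' synthetic study, or read a measurement CSV), fit the per-series
#' temperature-response curves, assemble the parameter table, fit the
#' mixed-model ANCOVA for each curve parameter (and for the
#' ln(R_d,acc/V_cmax,acc) ratio when a V_cmax series is present), compute
#' Wald tables, least-squares-mean trends and the planned photosynthetic
#' vs non-photosynthetic contrast, reconstruct the acclimated surfaces and
#' the homeostasis table. The run is deterministic given the seed; stage
#' errors carry the stage name and partial results are kept on the report.
#'
#' @param config A [run_config()].
#' @return An object of class `resp_report` with elements `fits`,
#'   `models`, `table2` (Wald tests), `table3` (trends), `contrasts`,
#'   `species_means`, `surface`, `table4` (homeostasis), `ratio_records`,
#'   `ratio_trends` (when applicable), `log`, and `metadata`.
#' @examples
#' \donttest{
#' cfg <- run_config("table1", seed = 42)
#' rep <- run_pipeline(cfg)
#' rep$table4
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "resp_config"))
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, paste0("INFO  ", sprintf(...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  report <- list()
  class(report) <- "resp_report"

  # -- data ------------------------------------------------------------
  if (is.null(config$input)) {
    study <- stage("simulate",
                   simulate_study(config$design, config$truth,
                                  seed = config$seed, vcmax = config$vcmax))
    records <- study$records
    vcmax_records <- study$vcmax_records
    report$study <- study
    note("simulated %d respiration records (%d individuals), seed %d",
         nrow(records), length(unique(records$individual_id)), config$seed)
  } else {
    records <- stage("read", read_measurements(config$input))
    vcmax_records <- records |> filter(.data$quantity == "vcmax")
    if (nrow(vcmax_records) == 0) vcmax_records <- NULL
    records <- records |> filter(.data$quantity == "rd")
    note("read %d respiration records from %s", nrow(records), config$input)
  }

  # -- curve fits ------------------------------------------------------
  fits <- stage("fit-curves", suppressWarnings(
    fit_all_individuals(records, scale = config$scale)))
  report$fits <- fits
  note("fitted %d series (%d failures); mean RMSE per tissue: %s",
       nrow(fits), nrow(fit_failures(fits)),
       paste(sprintf("%s %.3g", rmse_by_tissue(fits)$tissue,
                     rmse_by_tissue(fits)$mean_rmse), collapse = ", "))

  # -- mixed models per parameter --------------------------------------
  params <- assemble_parameter_table(fits)
  param_names <- c("a", "b", "c")

  ratio_records <- NULL
  if (!is.null(vcmax_records) && nrow(vcmax_records) > 0) {
    vcmax_fits <- stage("fit-vcmax", suppressWarnings(
      fit_all_individuals(vcmax_records, scale = config$scale)))
    report$vcmax_fits <- vcmax_fits
    ratio_records <- stage("ratio", suppressWarnings(
      compute_ratio_records(fits, vcmax_fits)))
    params <- bind_rows(params, ratio_parameter_table(ratio_records))
    param_names <- c(param_names, "ln_ratio")
    note("computed %d R_d,acc/V_cmax,acc records", nrow(ratio_records))
  }
  report$ratio_records <- ratio_records

  models <- stage("fit-models",
                  setNames(map(param_names,
                               ~ fit_mixed_ancova(params, .x)), param_names))
  report$models <- models
  note("fitted mixed models for: %s", paste(param_names, collapse = ", "))

  report$table2 <- map_dfr(models, wald_type2, .id = "parameter")
  trends <- map(models, lsm_trends, df_method = config$df_method)
  report$table3 <- list_rbind(trends)
  report$contrasts <- map_dfr(models, planned_contrast,
                              df_method = config$df_method,
                              .id = "parameter")
  report$species_means <- map(models, species_marginal_means,
                              df_method = config$df_method)
  if (!is.null(ratio_records)) {
    report$ratio_trends <- trends$ln_ratio
  }

  # -- surfaces and homeostasis ----------------------------------------
  surface_trends <- report$table3 |>
    filter(.data$parameter %in% c("a", "b", "c"))
  report$surface <- stage("acclim", build_surface(surface_trends))
  ta_grid <- config$ta_grid %||%
    setdiff(sort(unique(records$T_a_C)), config$t_ref)
  report$table4 <- stage("acclim",
                         homeostasis_table(report$surface,
                                           ta_levels = ta_grid,
                                           T_ref = config$t_ref))
  note("homeostasis grid: %d tissues x %d T_a levels, grand mean %.3f",
       length(unique(report$table4$tissue)), length(ta_grid),
       attr(report$table4, "grand_mean"))

  report$log <- log_lines
  report$metadata <- list(
    schema_version = SCHEMA_VERSION,
    package_version = as.character(packageVersion("respacclim")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    scale = config$scale,
    df_method = config$df_method,
    t_ref = config$t_ref,
    simulated = is.null(config$input),
    input = config$input,
    n_records = nrow(records),
    n_individuals = length(unique(records$individual_id)),
    ta_levels = if (is.null(config$input)) config$design$ta_levels else
      sort(unique(records$T_a_C))
  )
  report
}

#' @export
print.resp_report <- function(x, ...) {
  cat("<resp_report> seed", x$metadata$seed, "\n")
  cat("  ", x$metadata$n_records, "records,",
      x$metadata$n_individuals, "individuals\n")
  cat("  Wald tests (table2):\n")
  print(x$table2, n = 8)
  cat("  homeostasis (table4):\n")
  print(homeo_wide(x$table4, digits = 2))
  invisible(x)
}
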