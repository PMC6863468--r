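#' Reconstruct acclimated respiration surfaces from parameter trends
#'
#' Given per-tissue linear trends of the curve parameters `a`, `b`, `c`
#' against acclimation temperature (typically the [lsm_trends()] output
#' for the three parameters bound together), builds the two-argument
#' respiration surface
#' `R_d(T_t; T_a) = exp(a(T_a) + b(T_a) T_t + c(T_a) T_t^2)`
#' for each tissue class. At fixed `T_a` the surface is exactly the
#' instantaneous exponential-quadratic curve with the implied parameters.
#'
#' @param trends Data frame with columns `tissue`, `parameter`
#'   (`"a"`, `"b"`, `"c"`), `intercept`, `slope` — e.g.
#'   `dplyr::bind_rows(lsm_trends(fit_a), lsm_trends(fit_b), lsm_trends(fit_c))`.
#' @return An object of class `acclim_surface`; evaluate it with
#'   [predict()][predict.acclim_surface], [rd_at_acclimation()],
#'   [acclim_homeo()] or [homeostasis_table()].
#' @examples
#' tr <- flat_trends(a = -6, b = 0.07)
#' sf <- build_surface(tr)
#' predict(sf, T_t = 25, T_a = 25)
#' @export
build_surface <- function(trends) {
  trends <- as_tibble(trends)
  check_trend_frame(trends, "trends")
  trends <- trends |>
    select("tissue", "parameter", "intercept", "slope") |>
    mutate(tissue = as.character(.data$tissue))
  counts <- trends |>
    filter(.data$parameter %in% c("a", "b", "c")) |>
    distinct(.data$tissue, .data$parameter) |>
    count(.data$tissue)
  incomplete <- counts$tissue[counts$n < 3]
  if (length(incomplete) > 0 || nrow(counts) == 0) {
    abort(paste0("Trends must cover parameters a, b, c for every tissue",
                 if (length(incomplete) > 0)
                   paste0("; incomplete: ",
                          paste(incomplete, collapse = ", "))))
  }
  if (any(!is.finite(c(trends$intercept, trends$slope)))) {
    abort("Trend intercepts and slopes must be finite.")
  }
  structure(list(trends = trends, tissues = sort(counts$tissue)),
            class = "acclim_surface")
}

#' Trend set with constant parameters (no acclimation)
#'
#' Convenience constructor for a [build_surface()] input in which the curve
#' parameters do not change with acclimation temperature — the
#' "non-acclimating" reference surface used in identities and examples.
#'
#' @param a,b,c Constant curve parameters.
#' @param tissues Tissue labels to replicate the trends for.
#' @return A tibble with columns `tissue`, `parameter`, `intercept`, `slope`.
#' @export
flat_trends <- function(a = 0, b = 0, c = 0, tissues = TISSUE_CLASS4) {
  expand_grid(tissue = tissues,
              tibble(parameter = c("a", "b", "c"),
                     intercept = c(a, b, c))) |>
    mutate(slope = 0)
}

#' @export
print.acclim_surface <- function(x, ...) {
  cat("<acclim_surface> tissues:", paste(x$tissues, collapse = ", "), "\n")
  print(pivot_wider(x$trends, names_from = "parameter",
                    values_from = c("intercept", "slope")))
  invisible(x)
}

#' @export
tidy.acclim_surface <- function(x, ...) x$trends

#' Evaluate an acclimation surface
#'
#' @param object An [build_surface()] surface.
#' @param T_t Tissue temperature(s), degC.
#' @param T_a Acclimation temperature(s), degC (recycled against `T_t`).
#' @param tissue Tissue class(es) to evaluate; default all.
#' @param ... Unused.
#' @return A tibble `tissue`, `T_tissue_C`, `T_a_C`, `rd` (umol g-1 s-1,
#'   strictly positive).
#' @export
predict.acclim_surface <- function(object, T_t, T_a, tissue = NULL, ...) {
  tissue <- tissue %||% object$tissues
  pts <- tibble(T_tissue_C = T_t, T_a_C = T_a)
  out <- expand_grid(tissue = tissue, pts)
  pars <- trend_params_at(object$trends, out$tissue, out$T_a_C)
  out |>
    mutate(rd = exp(pars$a + pars$b * .data$T_tissue_C +
                      pars$c * .data$T_tissue_C^2))
}

#' Respiration at the acclimation temperature
#'
#' The acclimated rate `R_d,acc`: the surface evaluated on its diagonal,
#' at tissue temperature equal to the acclimation temperature.
#'
#' @inheritParams predict.acclim_surface
#' @param surface An [build_surface()] surface.
#' @return A tibble `tissue`, `T_a_C`, `rd_acc`.
#' @export
rd_at_acclimation <- function(surface, T_a, tissue = NULL) {
  predict(surface, T_t = T_a, T_a = T_a, tissue = tissue) |>
    select("tissue", "T_a_C", rd_acc = "rd")
}

#' The homeostasis ratio of acclimated respiration
#'
#' The homeostasis statistic compares the acclimated rate at an
#' acclimation temperature `T_a` with the reference acclimated rate at
#' `T_ref` (default 25 degC, the pre-treatment growth temperature):
#' below the reference the ratio is
#' `R_d(T_a; T_a) / R_d(T_ref; T_ref)`, above it the ratio is inverted to
#' `R_d(T_ref; T_ref) / R_d(T_a; T_a)`, and at `T_a = T_ref` it is exactly
#' 1. With this orientation a value of 1 always indicates fully
#' homeostatic respiration and smaller values progressively less
#' homeostasis, on both sides of the reference.
#'
#' @inheritParams rd_at_acclimation
#' @param T_ref Reference acclimation temperature, degC (default 25).
#' @return A tibble `tissue`, `T_a_C`, `acclim_homeo` (dimensionless, > 0).
#' @examples
#' sf <- build_surface(flat_trends(b = 0.07))
#' acclim_homeo(sf, T_a = c(15, 35))  # both exp(-0.7)
#' @export
acclim_homeo <- function(surface, T_a, T_ref = 25, tissue = NULL) {
  acc <- rd_at_acclimation(surface, T_a = T_a, tissue = tissue)
  ref <- rd_at_acclimation(surface, T_a = T_ref, tissue = tissue) |>
    select("tissue", rd_ref = "rd_acc")
  acc |>
    left_join(ref, by = "tissue") |>
    mutate(acclim_homeo = dplyr::case_when(
      .data$T_a_C == T_ref ~ 1,
      .data$T_a_C < T_ref ~ .data$rd_acc / .data$rd_ref,
      TRUE ~ .data$rd_ref / .data$rd_acc
    )) |>
    select("tissue", "T_a_C", "acclim_homeo")
}

#' Homeostasis table across tissues and acclimation temperatures
#'
#' Evaluates [acclim_homeo()] on the tissue x acclimation-temperature grid
#' and attaches the marginal summaries: the per-tissue average, the
#' per-temperature average, and the grand average. Averages are arithmetic
#' means of the full-precision cells; rounding, if any, is a reporting
#' choice (see [homeo_wide()]).
#'
#' @inheritParams acclim_homeo
#' @param ta_levels Acclimation temperatures for the grid rows (degC);
#'   default `c(15, 20, 30, 35)`, the non-reference levels.
#' @return A tibble of class `homeo_table` (`tissue`, `T_a_C`,
#'   `acclim_homeo`) with attributes `tissue_means`, `ta_means`,
#'   `grand_mean`, `T_ref`.
#' @export
homeostasis_table <- function(surface, ta_levels = c(15, 20, 30, 35),
                              T_ref = 25, tissue = NULL) {
  grid <- acclim_homeo(surface, T_a = ta_levels, T_ref = T_ref,
                       tissue = tissue)
  tissue_means <- grid |>
    group_by(.data$tissue) |>
    summarise(mean_acclim_homeo = mean(.data$acclim_homeo),
              .groups = "drop")
  ta_means <- grid |>
    group_by(.data$T_a_C) |>
    summarise(mean_acclim_homeo = mean(.data$acclim_homeo),
              .groups = "drop")
  structure(grid,
            tissue_means = tissue_means, ta_means = ta_means,
            grand_mean = mean(grid$acclim_homeo), T_ref = T_ref,
            class = c("homeo_table", class(grid)))
}

#' @rdname homeostasis_table
#' @param x A `homeo_table`.
#' @param digits Round the wide table for reporting (`NULL` = no rounding).
#' @return `homeo_wide()`: a wide tibble with one row per acclimation
#'   temperature plus an `"average"` row, one column per tissue plus an
#'   `average` column.
#' @export
homeo_wide <- function(x, digits = NULL) {
  stopifnot(inherits(x, "homeo_table"))
  wide <- as_tibble(x) |>
    pivot_wider(names_from = "tissue", values_from = "acclim_homeo") |>
    left_join(attr(x, "ta_means"), by = "T_a_C") |>
    rename(average = "mean_acclim_homeo") |>
    mutate(T_a_C = as.character(.data$T_a_C))
  means <- attr(x, "tissue_means")
  avg_row <- as_tibble(setNames(
    as.list(c(means$mean_acclim_homeo, attr(x, "grand_mean"))),
    c(means$tissue, "average")
  )) |>
    mutate(T_a_C = "average", .before = 1)
  out <- bind_rows(wide, avg_row)
  if (!is.null(digits)) {
    out <- out |> mutate(across(-"T_a_C", ~ round(.x, digits)))
  }
  out
}

#' @export
print.homeo_table <- function(x, ...) {
  cat("<homeo_table> reference T_a =", attr(x, "T_ref"), "degC\n")
  print(homeo_wide(x, digits = 2))
  invisible(x)
}

#' Acclimated respiration-to-photosynthetic-capacity ratios
#'
#' For each individual with both a dark-respiration curve fit and a leaf
#' V_cmax curve fit, evaluates both curves at tissue temperature equal to
#' the individual's acclimation temperature, giving `R_d,acc`,
#' `V_cmax,acc` and `ln_ratio = ln(R_d,acc / V_cmax,acc)`. Records with
#' non-positive or non-finite rates are excluded with a warning. The
#' result feeds [fit_mixed_ancova()] and [lsm_trends()] unchanged via
#' [ratio_parameter_table()].
#'
#' @param rd_fits Respiration fits ([fit_all_individuals()] on `rd`
#'   records), any tissue.
#' @param vcmax_fits V_cmax fits (leaf series), keyed by `individual_id`.
#' @return A tibble: `individual_id`, `species`, `tissue`, `tissue_class4`,
#'   `T_a_C`, `rd_acc`, `vcmax_acc`, `ln_ratio`.
#' @export
compute_ratio_records <- function(rd_fits, vcmax_fits) {
  rd_fits <- as_tibble(rd_fits)
  vc <- as_tibble(vcmax_fits) |>
    select("individual_id", vc_a = "a", vc_b = "b", vc_c = "c")
  joined <- rd_fits |>
    inner_join(vc, by = "individual_id")
  if (nrow(joined) == 0) {
    abort("No individuals with both respiration and V_cmax fits.")
  }
  out <- joined |>
    mutate(
      rd_acc = exp(.data$a + .data$b * .data$T_a_C +
                     .data$c * .data$T_a_C^2),
      vcmax_acc = exp(.data$vc_a + .data$vc_b * .data$T_a_C +
                        .data$vc_c * .data$T_a_C^2)
    )
  valid <- is.finite(out$rd_acc) & is.finite(out$vcmax_acc) &
    out$rd_acc > 0 & out$vcmax_acc > 0
  if (!all(valid)) {
    warn(sprintf(
      "Excluding %d record(s) with non-positive or non-finite rates (%s).",
      sum(!valid),
      paste(utils::head(unique(out$individual_id[!valid]), 5),
            collapse = ", ")))
    out <- out[valid, ]
  }
  out |>
    mutate(ln_ratio = log(.data$rd_acc / .data$vcmax_acc)) |>
    select(any_of(c("individual_id", "species", "tissue", "tissue_class",
                    "tissue_class4", "T_a_C", "rd_acc", "vcmax_acc",
                    "ln_ratio")))
}

#' @rdname compute_ratio_records
#' @param ratio_records A [compute_ratio_records()] result.
#' @return `ratio_parameter_table()`: the long parameter table
#'   (`parameter = "ln_ratio"`) for [fit_mixed_ancova()].
#' @export
ratio_parameter_table <- function(ratio_records) {
  as_tibble(ratio_records) |>
    mutate(parameter = "ln_ratio", value = .data$ln_ratio) |>
    select("individual_id", "species", "tissue", "tissue_class4", "T_a_C",
           "parameter", "value")
}

#' Per-individual homeostasis ratios
#'
#' A descriptive, individual-level variant of the homeostasis statistic:
#' each individual's fitted curve is evaluated at its own acclimation
#' temperature and compared with the mean acclimated rate of the
#' reference-temperature individuals of the same tissue class. Unlike
#' [homeostasis_table()], which uses the population-level reconstructed
#' surfaces (the headline analysis), this variant mixes within- and
#' between-individual variation and is provided for exploration only.
#'
#' @param fits An [fit_all_individuals()] result with `T_a_C` metadata.
#' @param T_ref Reference acclimation temperature, degC.
#' @return A tibble `individual_id`, `tissue_class4`, `T_a_C`,
#'   `acclim_homeo`.
#' @export
acclim_homeo_individual <- function(fits, T_ref = 25) {
  fits <- as_tibble(fits) |>
    mutate(rd_acc = exp(.data$a + .data$b * .data$T_a_C +
                          .data$c * .data$T_a_C^2))
  ref <- fits |>
    filter(.data$T_a_C == T_ref) |>
    group_by(.data$tissue_class4) |>
    summarise(rd_ref = mean(.data$rd_acc), .groups = "drop")
  fits |>
    inner_join(ref, by = "tissue_class4") |>
    mutate(acclim_homeo = ifelse(
      .data$T_a_C == T_ref, 1,
      ifelse(.data$T_a_C < T_ref, .data$rd_acc / .data$rd_ref,
             .data$rd_ref / .data$rd_acc))) |>
    select("individual_id", "tissue_class4", "T_a_C", "acclim_homeo")
}
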