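#' Convert an area-basis flux to a dry-mass basis
#'
#' Gas-exchange instruments report fluxes per unit projected tissue area;
#' the analysis works per gram dry mass. The conversion multiplies by the
#' measured tissue area and divides by its dry mass.
#'
#' @param flux_area Flux in umol m-2 s-1 (vectorised).
#' @param area Projected tissue area in m^2, > 0.
#' @param dry_mass Tissue dry mass in g, > 0.
#' @return Flux in umol g-1 s-1.
#' @examples
#' convert_area_to_mass_flux(2, 0.5, 4) # 0.25
#' @export
convert_area_to_mass_flux <- function(flux_area, area, dry_mass) {
  if (any(!is.finite(area)) || any(area <= 0)) {
    abort("`area` must be finite and > 0.")
  }
  if (any(!is.finite(dry_mass)) || any(dry_mass <= 0)) {
    abort("`dry_mass` must be finite and > 0.")
  }
  flux_area * area / dry_mass
}

#' Fit the exponential-quadratic temperature-response curve
#'
#' Fits `R(T) = exp(a + b T + c T^2)` to one temperature series.
#' `a` is the ln rate at 0 degC (rate units umol g-1 s-1), `b` (degC^-1)
#' the initial exponential sensitivity, and `c` (degC^-2) the change of
#' that sensitivity with temperature. Two fitting scales are offered:
#'
#' * `log_ols` (default): exact least squares of `ln(rate)` on
#'   `(1, T, T^2)` — closed form, matching the ln-quadratic
#'   parameterisation of the model.
#' * `original_nls`: iterative least squares on the original flux scale
#'   (Levenberg-Marquardt), initialised from the log fit.
#'
#' Non-positive rates cannot enter a log fit and are dropped with a
#' warning; at least `min_points` usable points at >= 3 distinct
#' temperatures must remain. RMSE is always reported on the original flux
#' scale.
#'
#' @param data Data frame with columns `T_tissue_C` (degC) and `flux`
#'   (umol g-1 s-1); extra columns are ignored.
#' @param scale `"log_ols"` or `"original_nls"`.
#' @param min_points Minimum usable points (default 4).
#' @return A one-row tibble: `a`, `b`, `c`, `rmse` (umol g-1 s-1, original
#'   scale), `n_points`, `scale`.
#' @examples
#' T <- c(14, 23, 32, 41, 45)
#' d <- data.frame(T_tissue_C = T, flux = exp(-6 + 0.1 * T - 0.001 * T^2))
#' fit_polynomial(d)
#' @export
fit_polynomial <- function(data, scale = c("log_ols", "original_nls"),
                           min_points = 4) {
  scale <- match.arg(scale)
  if (!all(c("T_tissue_C", "flux") %in% names(data))) {
    abort("`data` needs columns T_tissue_C and flux.")
  }
  tt <- data$T_tissue_C
  y <- data$flux
  keep <- is.finite(tt) & is.finite(y)
  if (!all(keep)) {
    warn(sprintf("Dropping %d non-finite point(s).", sum(!keep)))
    tt <- tt[keep]; y <- y[keep]
  }
  pos <- y > 0
  if (!all(pos)) {
    warn(sprintf("Dropping %d non-positive rate(s) before log fitting.",
                 sum(!pos)))
    tt <- tt[pos]; y <- y[pos]
  }
  if (length(y) < min_points) {
    abort(sprintf("Need >= %d usable points, have %d.", min_points,
                  length(y)))
  }
  if (length(unique(tt)) < 3) {
    abort("Degenerate design: need >= 3 distinct temperatures.")
  }

  X <- cbind(1, tt, tt^2)
  beta <- stats::lm.fit(X, log(y))$coefficients
  names(beta) <- c("a", "b", "c")

  if (scale == "original_nls") {
    nls_fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ exp(a + b * tt + c * tt^2),
        start = as.list(beta),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) abort(paste0("original_nls did not converge: ",
                                       conditionMessage(e)))
    )
    beta <- coef(nls_fit)[c("a", "b", "c")]
  }

  fitted_flux <- exp(beta[["a"]] + beta[["b"]] * tt + beta[["c"]] * tt^2)
  tibble(
    a = beta[["a"]], b = beta[["b"]], c = beta[["c"]],
    rmse = sqrt(mean((y - fitted_flux)^2)),
    n_points = length(y), scale = scale
  )
}

#' Evaluate a fitted temperature-response curve
#'
#' @param fit A one-row data frame or named list/vector with elements `a`,
#'   `b`, `c` (e.g. a [fit_polynomial()] result).
#' @param temperature Tissue temperature(s), degC.
#' @return Rate(s) `exp(a + b T + c T^2)`, strictly positive.
#' @examples
#' evaluate_polynomial(list(a = -7.57, b = 0, c = 0), 25) # exp(-7.57)
#' @export
evaluate_polynomial <- function(fit, temperature) {
  if (any(!is.finite(temperature))) abort("`temperature` must be finite.")
  fit <- as.list(fit)
  exp(fit$a + fit$b * temperature + fit$c * temperature^2)
}

#' Fit response curves for every individual x tissue series
#'
#' Groups measurement records by individual, tissue and quantity and fits
#' [fit_polynomial()] to each series. Series that fail the preconditions
#' (too few points, too few distinct temperatures, non-convergence) are not
#' silently dropped: they are collected in a failure report attached to the
#' result and summarised by [fit_failures()].
#'
#' @param records Measurement records in the canonical schema (see
#'   [simulate_measurements()] or [read_measurements()]).
#' @param scale Fitting scale, see [fit_polynomial()].
#' @param min_points Minimum usable points per series.
#' @return A tibble of class `rd_fits`: one row per fitted series with the
#'   series identity, `a`, `b`, `c`, `rmse`, `n_points`, `scale`. Attributes:
#'   `failures` (tibble of failed series with reasons) and `rmse_by_tissue`
#'   (mean original-scale RMSE per tissue).
#' @examples
#' st <- simulate_study("balanced", truth_config(noise_sd_log = 0), seed = 1,
#'                      vcmax = FALSE)
#' fits <- fit_all_individuals(st$records)
#' rmse_by_tissue(fits)
#' @export
fit_all_individuals <- function(records, scale = c("log_ols", "original_nls"),
                                min_points = 4) {
  scale <- match.arg(scale)
  id_cols <- intersect(
    c("individual_id", "species", "tissue", "tissue_class", "tissue_class4",
      "quantity", "T_a_C"),
    names(records)
  )
  if (!all(c("individual_id", "tissue") %in% id_cols)) {
    abort("`records` needs at least individual_id and tissue columns.")
  }
  if (nrow(records) == 0) {
    empty <- as_tibble(records)[0, id_cols]
    out <- bind_cols(empty, tibble(a = double(), b = double(), c = double(),
                                   rmse = double(), n_points = integer(),
                                   scale = character()))
    return(new_rd_fits(out, failures = bind_cols(empty,
                                                 tibble(reason = character()))))
  }

  groups <- records |>
    group_by(across(all_of(id_cols))) |>
    tidyr::nest(.key = "series") |>
    ungroup()

  results <- map(groups$series, function(d) {
    tryCatch(
      list(fit = suppressWarnings(
        fit_polynomial(d, scale = scale, min_points = min_points)
      )),
      error = function(e) list(error = conditionMessage(e))
    )
  })
  ok <- map_lgl(results, ~ is.null(.x$error))

  fits <- bind_cols(groups[ok, id_cols],
                    list_rbind(map(results[ok], "fit")))
  failures <- groups[!ok, id_cols] |>
    mutate(reason = map_chr(results[!ok], "error"))
  if (nrow(failures) > 0) {
    warn(sprintf("%d series could not be fitted; see fit_failures().",
                 nrow(failures)))
  }
  new_rd_fits(fits, failures)
}

new_rd_fits <- function(fits, failures) {
  rmse_summary <- if ("tissue" %in% names(fits) && nrow(fits) > 0) {
    fits |> group_by(.data$tissue) |>
      summarise(mean_rmse = mean(.data$rmse), n_series = dplyr::n(),
                .groups = "drop")
  } else {
    tibble(tissue = character(), mean_rmse = double(), n_series = integer())
  }
  structure(as_tibble(fits), failures = as_tibble(failures),
            rmse_by_tissue = rmse_summary,
            class = c("rd_fits", class(as_tibble(fits))))
}

#' @rdname fit_all_individuals
#' @param fits An `rd_fits` object.
#' @export
fit_failures <- function(fits) attr(fits, "failures")

#' @rdname fit_all_individuals
#' @export
rmse_by_tissue <- function(fits) attr(fits, "rmse_by_tissue")
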