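#' Configuration of the generating ("true") parameter process
#'
#' Describes the population from which a synthetic study's true curve
#' parameters are drawn. Each tissue class carries linear trends of the
#' exponential-quadratic curve parameters `a` (ln rate at 0 degC,
#' ln umol g-1 s-1), `b` (degC^-1) and `c` (degC^-2) against acclimation
#' temperature T_a; species and individuals perturb only the basal-rate
#' parameter `a` (species differed only in basal rate in the motivating
#' study, not in curve shape). Measurement noise is multiplicative
#' lognormal on the flux.
#'
#' Default trend slopes are the published per-tissue least-squares-mean
#' slope magnitudes (e.g. root `b` slope -0.005 degC^-1 per degC); default
#' curve levels at T_a = 25 degC are `b = 0.11` degC^-1 and `c = -6e-4`
#' degC^-2 (instantaneous ln-slope about 0.08 at 25 degC, Q10 about 2.2)
#' with tissue-specific basal rates. Trend intercepts are stored at
#' T_a = 0 degC.
#'
#' @param trend_means Data frame with columns `tissue` (four-level class),
#'   `parameter` (`"a"`, `"b"`, `"c"`), `intercept`, `slope`; the mean
#'   generating trends. Defaults to [default_trend_means()].
#' @param trend_sds Same shape as `trend_means` with columns `intercept_sd`,
#'   `slope_sd`; between-draw variation of the true trends. Default all 0
#'   (the trends *are* the means).
#' @param species_offset_sd SD (ln units) of per-species offsets on `a`.
#' @param individual_offset_sd SD (ln units) of per-individual offsets on `a`.
#' @param noise_sd_log SD of the multiplicative measurement noise on the
#'   ln-flux scale (dimensionless).
#' @param temp_grid Measurement tissue temperatures (degC), >= 4 points.
#' @param top_temp_jitter_sd SD (degC) of the jitter applied to the warmest
#'   grid temperature, emulating the instrument-limited top setpoint.
#' @param vcmax_trend_means Trends for the leaf V_cmax temperature response
#'   (same columns as `trend_means`, leaf only). Defaults to the leaf
#'   respiration trends with the basal rate raised by 3.2 ln units, i.e. a
#'   respiration-to-capacity ratio near 0.04 with no trend in the ratio.
#' @return A list of class `truth_config`.
#' @seealso [draw_true_parameters()], [simulate_study()]
#' @export
truth_config <- function(trend_means = default_trend_means(),
                         trend_sds = NULL,
                         species_offset_sd = 0.35,
                         individual_offset_sd = 0.25,
                         noise_sd_log = 0.15,
                         temp_grid = c(14, 23, 32, 41, 45),
                         top_temp_jitter_sd = 0.5,
                         vcmax_trend_means = NULL) {
  trend_means <- as_tibble(trend_means)
  check_trend_frame(trend_means, "trend_means")
  if (is.null(trend_sds)) {
    trend_sds <- trend_means |>
      select("tissue", "parameter") |>
      mutate(intercept_sd = 0, slope_sd = 0)
  }
  trend_sds <- as_tibble(trend_sds)
  sds <- c(species_offset_sd, individual_offset_sd, noise_sd_log,
           top_temp_jitter_sd, trend_sds$intercept_sd, trend_sds$slope_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    abort("All standard deviations must be finite and >= 0.")
  }
  if (length(temp_grid) < 4) {
    abort("`temp_grid` must have at least 4 points.")
  }
  if (any(!is.finite(c(trend_means$intercept, trend_means$slope)))) {
    abort("Trend means must be finite.")
  }
  if (is.null(vcmax_trend_means)) {
    vcmax_trend_means <- trend_means |>
      filter(.data$tissue == "leaf") |>
      mutate(intercept = .data$intercept +
               ifelse(.data$parameter == "a", 3.2, 0))
  }
  structure(
    list(trend_means = trend_means, trend_sds = trend_sds,
         species_offset_sd = species_offset_sd,
         individual_offset_sd = individual_offset_sd,
         noise_sd_log = noise_sd_log, temp_grid = sort(temp_grid),
         top_temp_jitter_sd = top_temp_jitter_sd,
         vcmax_trend_means = as_tibble(vcmax_trend_means)),
    class = "truth_config"
  )
}

check_trend_frame <- function(x, name) {
  if (!all(c("tissue", "parameter", "intercept", "slope") %in% names(x))) {
    abort(paste0("`", name,
                 "` needs columns tissue, parameter, intercept, slope."))
  }
  invisible(x)
}

#' Default generating trends for the synthetic study
#'
#' Per-tissue linear trends of the curve parameters against acclimation
#' temperature. Slopes are the published per-tissue magnitudes; levels at
#' T_a = 25 degC are `b = 0.11` degC^-1, `c = -6e-4` degC^-2 and
#' tissue-specific basal rates (`a` at 25 degC: leaf -6.0, photosynthetic
#' stem -6.2, non-photosynthetic stem -6.4, root -6.2 ln umol g-1 s-1).
#' Intercepts are returned at T_a = 0 degC.
#'
#' @return A tibble with columns `tissue`, `parameter`, `intercept`, `slope`.
#' @export
default_trend_means <- function() {
  at25 <- tibble(
    tissue = rep(TISSUE_CLASS4, times = 3),
    parameter = rep(c("a", "b", "c"), each = 4),
    value25 = c(-6.0, -6.2, -6.4, -6.2,
                0.11, 0.11, 0.11, 0.11,
                -6e-4, -6e-4, -6e-4, -6e-4),
    slope = c(-0.027, 0.002, 0.060, 0.058,
              0.002, 0.001, -0.005, -0.005,
              -4.1e-5, -3.3e-5, 8.3e-5, 9.4e-5)
  )
  at25 |>
    mutate(intercept = .data$value25 - 25 * .data$slope) |>
    select("tissue", "parameter", "intercept", "slope")
}

#' Draw the true generating parameters for one synthetic study
#'
#' Realises a set of true parameter trends from a [truth_config()]: each
#' trend intercept and slope is drawn from a normal distribution centred on
#' the configured mean with the configured SD (default 0, i.e. the
#' configured means are returned exactly). The draw is deterministic given
#' the seed, and uses a dedicated substream of the master seed so that
#' later noise draws are unaffected.
#'
#' @param config A [truth_config()].
#' @param seed Integer master seed.
#' @return A list of class `resp_truth` mirroring the config with realised
#'   `trends` and `vcmax_trends` tibbles.
#' @examples
#' tr <- draw_true_parameters(truth_config(), seed = 1)
#' tr$trends
#' @export
draw_true_parameters <- function(config, seed) {
  if (!inherits(config, "truth_config")) config <- do.call(truth_config, config)
  draw_one <- function(means, sds) {
    means |>
      left_join(sds, by = c("tissue", "parameter")) |>
      mutate(
        intercept_sd = dplyr::coalesce(.data$intercept_sd, 0),
        slope_sd = dplyr::coalesce(.data$slope_sd, 0),
        intercept = .data$intercept +
          .data$intercept_sd * rnorm(dplyr::n()),
        slope = .data$slope + .data$slope_sd * rnorm(dplyr::n())
      ) |>
      select("tissue", "parameter", "intercept", "slope")
  }
  trends <- withr::with_seed(substream(seed, "parameters"), {
    list(rd = draw_one(config$trend_means, config$trend_sds),
         vcmax = draw_one(config$vcmax_trend_means, config$trend_sds))
  })
  structure(
    list(trends = trends$rd, vcmax_trends = trends$vcmax,
         species_offset_sd = config$species_offset_sd,
         individual_offset_sd = config$individual_offset_sd,
         noise_sd_log = config$noise_sd_log,
         temp_grid = config$temp_grid,
         top_temp_jitter_sd = config$top_temp_jitter_sd,
         seed = seed),
    class = "resp_truth"
  )
}

#' @export
print.resp_truth <- function(x, ...) {
  cat("<resp_truth> seed", x$seed, "\n")
  cat("  noise_sd_log:", x$noise_sd_log,
      "| temp grid:", paste(x$temp_grid, collapse = ", "), "degC\n")
  print(pivot_wider(x$trends, names_from = "parameter",
                    values_from = c("intercept", "slope")))
  invisible(x)
}

# Evaluate trend lines: parameter values (a, b, c) per tissue at given T_a.
trend_params_at <- function(trends, tissue, ta) {
  wide <- trends |>
    filter(.data$tissue %in% !!tissue) |>
    pivot_wider(names_from = "parameter",
                values_from = c("intercept", "slope"))
  out <- tibble(tissue = tissue, T_a_C = ta) |>
    left_join(wide, by = "tissue") |>
    mutate(a = .data$intercept_a + .data$slope_a * .data$T_a_C,
           b = .data$intercept_b + .data$slope_b * .data$T_a_C,
           c = .data$intercept_c + .data$slope_c * .data$T_a_C) |>
    select("tissue", "T_a_C", "a", "b", "c")
  if (any(!is.finite(c(out$a, out$b, out$c)))) {
    abort("Missing or non-finite parameter trend for a requested tissue.")
  }
  out
}
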