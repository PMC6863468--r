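#' Simulate dark-respiration measurements for a study design
#'
#' Generates one flux record per individual x tissue x grid temperature.
#' Each individual x tissue series follows the exponential-quadratic
#' temperature-response curve `R(T) = exp(a + b T + c T^2)` with parameters
#' taken from the tissue-class trend lines at the individual's acclimation
#' temperature; species and individual offsets (ln units) perturb the basal
#' rate `a` only. Measurement noise is multiplicative lognormal:
#' `flux = R(T) * exp(eps)`, `eps ~ N(0, noise_sd_log^2)`. The warmest grid
#' temperature is jittered per series to emulate the instrument-limited top
#' setpoint. All randomness flows through substreams of the single master
#' seed, so the same `(design, truth, seed)` triple is bitwise reproducible
#' and noise draws do not depend on how the truth was drawn.
#'
#' @param design A [make_design()] object.
#' @param truth A [draw_true_parameters()] object.
#' @param seed Integer master seed; defaults to the seed stored in `truth`.
#' @return An object of class `resp_study`: list with `records` (tibble in
#'   the canonical measurement schema), `realized` (true per-individual
#'   `(a, b, c)` per tissue), `truth`, `design`, and `vcmax_records`
#'   (`NULL` until [simulate_vcmax()] is run).
#' @examples
#' d <- make_design("balanced", species = "sp1", n_per_cell = 1)
#' tr <- draw_true_parameters(truth_config(noise_sd_log = 0), seed = 1)
#' st <- simulate_measurements(d, tr)
#' head(st$records)
#' @export
simulate_measurements <- function(design, truth, seed = truth$seed) {
  stopifnot(inherits(design, "resp_design"), inherits(truth, "resp_truth"))
  series <- design_individuals(design)
  missing_cls <- setdiff(levels(droplevels(series$tissue_class4)),
                         unique(truth$trends$tissue))
  if (length(missing_cls) > 0) {
    abort(paste0("Truth has no trends for tissue class(es): ",
                 paste(missing_cls, collapse = ", ")))
  }

  realized <- realize_parameters(series, truth$trends,
                                 truth$species_offset_sd,
                                 truth$individual_offset_sd,
                                 substream(seed, "offsets"))
  records <- noisy_records(realized, truth, substream(seed, "noise"),
                           quantity = "rd")

  structure(
    list(records = records, vcmax_records = NULL,
         realized = realized |> mutate(quantity = "rd"),
         truth = truth, design = design, seed = seed),
    class = "resp_study"
  )
}

#' Simulate a leaf photosynthetic-capacity temperature series
#'
#' As [simulate_measurements()], but for the maximum carboxylation rate
#' V_cmax (per-gram units), which follows the same exponential-quadratic
#' curve form. Measured on leaves only, one series per individual, using
#' the `vcmax_trends` of the truth object and dedicated random substreams.
#'
#' @inheritParams simulate_measurements
#' @return A list with `records` (tibble, `quantity = "vcmax"`) and
#'   `realized` (true per-individual parameters).
#' @export
simulate_vcmax <- function(design, truth, seed = truth$seed) {
  stopifnot(inherits(design, "resp_design"), inherits(truth, "resp_truth"))
  series <- design_individuals(design) |>
    filter(.data$tissue == "leaf")
  realized <- realize_parameters(
    series,
    truth$vcmax_trends,
    truth$species_offset_sd, truth$individual_offset_sd,
    substream(seed, "vcmax_offsets")
  )
  records <- noisy_records(realized, truth, substream(seed, "vcmax_noise"),
                           quantity = "vcmax")
  list(records = records, realized = realized |> mutate(quantity = "vcmax"))
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: draws the truth from a [truth_config()] and
#' simulates dark-respiration records (and optionally the leaf V_cmax
#' series) for a design.
#'
#' @param design A [make_design()] object, or a preset name passed to
#'   [make_design()].
#' @param config A [truth_config()] (or list of its arguments).
#' @param seed Integer master seed.
#' @param vcmax Simulate the leaf V_cmax series too?
#' @return An object of class `resp_study` (see [simulate_measurements()]),
#'   with `vcmax_records` populated when `vcmax = TRUE`.
#' @examples
#' st <- simulate_study("table1", seed = 7)
#' dplyr::count(st$records, tissue)
#' @export
simulate_study <- function(design = "table1", config = truth_config(),
                           seed = 1, vcmax = TRUE) {
  if (is.character(design)) design <- make_design(design)
  if (!inherits(config, "truth_config")) config <- do.call(truth_config, config)
  truth <- draw_true_parameters(config, seed)
  study <- simulate_measurements(design, truth, seed)
  if (vcmax) {
    v <- simulate_vcmax(design, truth, seed)
    study$vcmax_records <- v$records
    study$realized <- bind_rows(study$realized, v$realized)
  }
  study
}

#' @export
print.resp_study <- function(x, ...) {
  cat("<resp_study> seed", x$seed, "\n")
  cat(" ", nrow(x$records), "respiration records,",
      length(unique(x$records$individual_id)), "individuals")
  if (!is.null(x$vcmax_records)) {
    cat(",", nrow(x$vcmax_records), "V_cmax records")
  }
  cat("\n")
  invisible(x)
}

# True per-individual curve parameters: trend value at T_a plus species and
# individual offsets on `a`. Offsets are drawn in sorted label order so the
# draw does not depend on row order or on which tissues are present.
realize_parameters <- function(series, trends, species_offset_sd,
                               individual_offset_sd, stream_seed) {
  species_lvls <- sort(unique(series$species))
  ind_lvls <- sort(unique(series$individual_id))
  offsets <- withr::with_seed(stream_seed, {
    list(
      species = setNames(rnorm(length(species_lvls), 0, species_offset_sd),
                         species_lvls),
      individual = setNames(rnorm(length(ind_lvls), 0, individual_offset_sd),
                            ind_lvls)
    )
  })
  base <- trend_params_at(trends,
                          tissue = as.character(series$tissue_class4),
                          ta = series$T_a_C)
  series |>
    mutate(a = base$a + unname(offsets$species[.data$species]) +
             unname(offsets$individual[.data$individual_id]),
           b = base$b, c = base$c)
}

# Expand realized series parameters into noisy flux records on the
# measurement temperature grid (top point jittered per series).
noisy_records <- function(realized, truth, stream_seed, quantity) {
  grid <- truth$temp_grid
  n_series <- nrow(realized)
  n_grid <- length(grid)
  realized <- realized |> arrange(.data$individual_id, .data$tissue)
  draws <- withr::with_seed(stream_seed, {
    list(jitter = rnorm(n_series, 0, truth$top_temp_jitter_sd),
         eps = rnorm(n_series * n_grid, 0, truth$noise_sd_log))
  })
  out <- realized[rep(seq_len(n_series), each = n_grid), ] |>
    mutate(
      grid_index = rep(seq_len(n_grid), times = n_series),
      T_tissue_C = grid[.data$grid_index] +
        ifelse(.data$grid_index == n_grid,
               rep(draws$jitter, each = n_grid), 0),
      flux = exp(.data$a + .data$b * .data$T_tissue_C +
                   .data$c * .data$T_tissue_C^2) * exp(draws$eps),
      quantity = quantity, flux_basis = "mass",
      area_m2 = NA_real_, dry_mass_g = NA_real_
    ) |>
    select("individual_id", "species", "tissue", "tissue_class",
           "tissue_class4", "quantity", "T_a_C", "T_tissue_C", "flux",
           "flux_basis", "area_m2", "dry_mass_g")
  as_tibble(out)
}
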