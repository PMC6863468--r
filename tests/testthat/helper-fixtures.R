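# Shared fixture builders. Fixtures are generated in code; nothing is
# read from disk.

# Noise-free generating process: configured trends are returned exactly
# and simulated fluxes lie on the curves.
noiseless_config <- function(...) {
  truth_config(species_offset_sd = 0, individual_offset_sd = 0,
               noise_sd_log = 0, top_temp_jitter_sd = 0, ...)
}

# Truth in which non-photosynthetic tissues acclimate strongly (basal-rate
# compensation that holds the acclimated rate nearly constant) while
# photosynthetic tissues do not acclimate at all.
strong_nonps_acclimation_trends <- function(b25 = 0.11, c25 = -6e-4) {
  base <- default_trend_means() |>
    dplyr::mutate(
      value25 = .data$intercept + 25 * .data$slope,
      slope = dplyr::case_when(
        .data$tissue %in% c("leaf", "ps_stem") ~ 0,
        .data$parameter == "a" ~ -(b25 + 50 * c25),
        TRUE ~ 0
      ),
      intercept = .data$value25 - 25 * .data$slope
    ) |>
    dplyr::select("tissue", "parameter", "intercept", "slope")
  base
}

# A balanced single-species design: every tissue at every T_a level.
single_species_design <- function(n_per_cell = 4) {
  make_design("balanced", species = "only_species",
              n_per_cell = n_per_cell)
}

# Long parameter table built directly from a deterministic linear rule --
# bypasses simulation and curve fitting for mixed-model oracle tests.
deterministic_parameter_table <- function(slopes = c(leaf = 0.02,
                                                     ps_stem = 0.02,
                                                     nonps_stem = 0.015,
                                                     root = 0.01),
                                          intercepts = c(leaf = 1,
                                                         ps_stem = 1.2,
                                                         nonps_stem = 1.4,
                                                         root = 1.6),
                                          n_per_cell = 3,
                                          ta = c(15, 20, 25, 30, 35),
                                          parameter = "b",
                                          noise_sd = 0, seed = 1) {
  grid <- tidyr::expand_grid(T_a_C = ta, replicate = seq_len(n_per_cell),
                             tissue_class4 = names(slopes))
  withr::with_seed(seed, {
    grid |>
      dplyr::mutate(
        individual_id = sprintf("ind_%02.0f_%d", .data$T_a_C,
                                .data$replicate),
        species = "only_species",
        tissue = dplyr::case_when(
          .data$tissue_class4 == "leaf" ~ "leaf",
          .data$tissue_class4 == "root" ~ "root",
          TRUE ~ "stem"
        ),
        parameter = parameter,
        value = intercepts[.data$tissue_class4] +
          slopes[.data$tissue_class4] * .data$T_a_C +
          rnorm(dplyr::n(), 0, noise_sd)
      )
  })
}
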