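#' Construct a study design
#'
#' Builds the sampling design for a respiration-acclimation study: which
#' species are grown, at which acclimation temperatures, how many individuals
#' per (species, temperature) cell, and which tissues are measured on each
#' species. Two presets are provided:
#'
#' * `"table1"` — the unbalanced eight-species design of the motivating
#'   study: 84 individuals across acclimation temperatures
#'   \{15, 20, 25, 30, 35\} degC, leaf and root series for every species and
#'   stem series for all species except *Zea mays* (whose stems were too
#'   thick to measure). Herbaceous crops (*Cucumis sativa*, *Glycine max*)
#'   carry photosynthetic stems; the five tree species carry
#'   non-photosynthetic stems.
#' * `"balanced"` — a fully crossed design, useful for oracle tests and
#'   power exploration: `n_per_cell` individuals for every species at every
#'   acclimation temperature.
#'
#' @param preset `"table1"`, `"balanced"`, or `"custom"`.
#' @param species Character vector of species labels (balanced/custom).
#' @param ta_levels Numeric vector of acclimation temperatures (degC),
#'   strictly increasing.
#' @param n_per_cell Individuals per (species, T_a) cell (balanced preset).
#' @param cells For `preset = "custom"`: a data frame with columns
#'   `species`, `T_a_C`, `n` giving the per-cell counts.
#' @param tissue_plan For `"balanced"`/`"custom"`: a data frame with columns
#'   `species`, `tissue`, `tissue_class` saying which tissues are measured
#'   on each species. Defaults to leaf (photosynthetic), stem
#'   (non-photosynthetic) and root (non-photosynthetic) for every species.
#' @return An object of class `resp_design`: a list with tibbles `cells`
#'   (`species`, `T_a_C`, `n`) and `tissue_plan` (`species`, `tissue`,
#'   `tissue_class`, `tissue_class4`), and the vector `ta_levels`.
#' @examples
#' d <- make_design("table1")
#' sum(d$cells$n) # 84 individuals
#' @export
make_design <- function(preset = c("table1", "balanced", "custom"),
                        species = NULL, ta_levels = c(15, 20, 25, 30, 35),
                        n_per_cell = 2, cells = NULL, tissue_plan = NULL) {
  preset <- match.arg(preset)

  if (preset == "table1") {
    return(design_table1())
  }

  if (length(ta_levels) == 0 || any(diff(ta_levels) <= 0)) {
    abort("`ta_levels` must be non-empty and strictly increasing.")
  }

  if (preset == "balanced") {
    species <- species %||% c("species_A", "species_B")
    if (!is.numeric(n_per_cell) || n_per_cell < 0 ||
        n_per_cell != round(n_per_cell)) {
      abort("`n_per_cell` must be a non-negative integer.")
    }
    cells <- expand_grid(species = species, T_a_C = ta_levels) |>
      mutate(n = as.integer(n_per_cell))
  } else {
    if (is.null(cells)) abort("Custom designs require `cells`.")
    cells <- as_tibble(cells)
    required <- c("species", "T_a_C", "n")
    if (!all(required %in% names(cells))) {
      abort("`cells` must have columns species, T_a_C, n.")
    }
    if (any(cells$n < 0)) abort("Cell counts must be >= 0.")
    if (!all(cells$T_a_C %in% ta_levels)) {
      abort("All cell T_a_C values must be in `ta_levels`.")
    }
    species <- unique(cells$species)
  }

  if (is.null(tissue_plan)) {
    tissue_plan <- expand_grid(
      species = species,
      tibble(tissue = TISSUES,
             tissue_class = c("photosynthetic", "non_photosynthetic",
                              "non_photosynthetic"))
    )
  }
  tissue_plan <- as_tibble(tissue_plan)
  if (!all(c("species", "tissue", "tissue_class") %in% names(tissue_plan))) {
    abort("`tissue_plan` must have columns species, tissue, tissue_class.")
  }
  missing_sp <- setdiff(unique(cells$species), unique(tissue_plan$species))
  if (length(missing_sp) > 0) {
    abort(paste0("Species in `cells` absent from `tissue_plan`: ",
                 paste(missing_sp, collapse = ", ")))
  }
  tissue_plan <- tissue_plan |>
    mutate(tissue_class4 = tissue_class4(.data$tissue, .data$tissue_class))

  new_resp_design(cells, tissue_plan, ta_levels)
}

new_resp_design <- function(cells, tissue_plan, ta_levels) {
  structure(
    list(cells = as_tibble(cells), tissue_plan = as_tibble(tissue_plan),
         ta_levels = ta_levels),
    class = "resp_design"
  )
}

# The printed per-cell sample sizes of the motivating study (individuals
# measured for dark respiration), including the missing 25 degC Betula cell
# and 35 degC P. pinea cell, and the Z. mays stem exclusion.
design_table1 <- function() {
  ta <- c(15, 20, 25, 30, 35)
  counts <- rbind(
    "Betula alleghaniensis" = c(1, 3, 0, 3, 1),
    "Cucumis sativa"        = c(3, 2, 1, 1, 2),
    "Glycine max"           = c(5, 2, 1, 6, 1),
    "Pinus nigra"           = c(2, 3, 3, 2, 2),
    "Pinus pinaster"        = c(1, 1, 3, 2, 4),
    "Pinus pinea"           = c(1, 1, 2, 1, 0),
    "Pinus sylvestris"      = c(1, 1, 2, 3, 3),
    "Zea mays"              = c(3, 2, 2, 4, 3)
  )
  cells <- expand_grid(species = rownames(counts), T_a_C = ta) |>
    mutate(n = as.integer(t(counts))[row_number()])

  ps_stem_species <- c("Cucumis sativa", "Glycine max")
  tissue_plan <- map_dfr(rownames(counts), function(sp) {
    tissues <- if (sp == "Zea mays") c("leaf", "root") else TISSUES
    tibble(
      species = sp,
      tissue = tissues,
      tissue_class = dplyr::case_when(
        tissues == "leaf" ~ "photosynthetic",
        tissues == "root" ~ "non_photosynthetic",
        sp %in% ps_stem_species ~ "photosynthetic",
        TRUE ~ "non_photosynthetic"
      )
    )
  }) |>
    mutate(tissue_class4 = tissue_class4(.data$tissue, .data$tissue_class))

  new_resp_design(cells, tissue_plan, ta)
}

#' @export
print.resp_design <- function(x, ...) {
  cat("<resp_design>\n")
  cat("  species:", length(unique(x$cells$species)),
      " | T_a levels:", paste(x$ta_levels, collapse = ", "), "degC\n")
  cat("  individuals:", sum(x$cells$n),
      " | tissue series:", nrow(design_individuals(x)), "\n")
  invisible(x)
}

# Expand a design into one row per individual x tissue series.
design_individuals <- function(design) {
  inds <- design$cells |>
    filter(.data$n > 0) |>
    rowwise() |>
    reframe(species = .data$species, T_a_C = .data$T_a_C,
            replicate = seq_len(.data$n)) |>
    mutate(individual_id = sprintf("%s_T%02d_r%d",
                                   abbreviate(gsub(" ", "", .data$species), 6),
                                   as.integer(.data$T_a_C), .data$replicate))
  inds |>
    inner_join(design$tissue_plan, by = "species",
               relationship = "many-to-many") |>
    select("individual_id", "species", "tissue", "tissue_class",
           "tissue_class4", "T_a_C") |>
    arrange(.data$individual_id, .data$tissue)
}
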