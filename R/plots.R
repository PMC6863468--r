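#' Plot reconstructed acclimated response curves
#'
#' One panel per tissue class: the instantaneous respiration-temperature
#' curve implied by the surface at each acclimation temperature, with the
#' acclimated rates (tissue temperature equal to acclimation temperature)
#' overlaid as points on the diagonal.
#'
#' @param object An [build_surface()] surface.
#' @param ta_levels Acclimation temperatures to draw curves for.
#' @param t_range Tissue-temperature range (degC) of the curves.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.acclim_surface <- function(object, ta_levels = c(15, 20, 25, 30, 35),
                                    t_range = c(14, 45), ...) {
  tt <- seq(t_range[1], t_range[2], length.out = 120)
  curves <- map_dfr(ta_levels, function(ta) {
    predict(object, T_t = tt, T_a = ta)
  })
  acc <- map_dfr(ta_levels, function(ta) rd_at_acclimation(object, ta))
  ggplot(curves, aes(x = .data$T_tissue_C, y = .data$rd,
                     colour = factor(.data$T_a_C))) +
    geom_line() +
    geom_point(data = acc, aes(x = .data$T_a_C, y = .data$rd_acc),
               size = 2) +
    facet_wrap(~tissue, scales = "free_y") +
    labs(x = "Tissue temperature (°C)",
         y = expression(R[d] ~ "(µmol g"^{-1} ~ "s"^{-1} * ")"),
         colour = expression(T[a] ~ "(°C)")) +
    theme_minimal()
}

#' Plot the homeostasis ratios
#'
#' Acclimation-homeostasis ratios against acclimation temperature, one
#' line per tissue class; the dashed reference line at 1 marks fully
#' homeostatic respiration.
#'
#' @param object A [homeostasis_table()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.homeo_table <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$T_a_C, y = .data$acclim_homeo,
             colour = .data$tissue)) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    geom_point(size = 2) +
    geom_line() +
    labs(x = expression(T[a] ~ "(°C)"),
         y = expression(Acclim[Homeo]), colour = "Tissue") +
    theme_minimal()
}

#' Plot fitted parameters against acclimation temperature
#'
#' Per-individual fitted curve parameters by acclimation temperature and
#' tissue class, with the least-squares-mean trend lines overlaid — the
#' visual counterpart of the trend table.
#'
#' @param parameter_records Long table from [assemble_parameter_table()].
#' @param trends Optional [lsm_trends()] rows (possibly several
#'   parameters bound together) to overlay.
#' @return A ggplot object.
#' @export
plot_parameter_trends <- function(parameter_records, trends = NULL) {
  p <- ggplot(parameter_records,
              aes(x = .data$T_a_C, y = .data$value,
                  colour = .data$tissue_class4)) +
    geom_point(alpha = 0.6,
               position = position_dodge(width = 1.6)) +
    facet_wrap(~parameter, scales = "free_y") +
    labs(x = expression(T[a] ~ "(°C)"), y = "Parameter value",
         colour = "Tissue") +
    theme_minimal()
  if (!is.null(trends)) {
    p <- p + geom_abline(
      data = as_tibble(trends) |>
        rename(tissue_class4 = "tissue"),
      aes(intercept = .data$intercept, slope = .data$slope,
          colour = .data$tissue_class4)
    )
  }
  p
}

#' Plot acclimated respiration-to-capacity ratios
#'
#' Per-individual `R_d,acc / V_cmax,acc` ratios on a log scale against
#' acclimation temperature, with the fitted log-linear trend lines.
#'
#' @param ratio_records A [compute_ratio_records()] result.
#' @param ratio_trends Optional `lsm_trends()` rows for the `ln_ratio`
#'   model.
#' @return A ggplot object.
#' @export
plot_ratio_trends <- function(ratio_records, ratio_trends = NULL) {
  p <- ggplot(ratio_records,
              aes(x = .data$T_a_C, y = .data$rd_acc / .data$vcmax_acc,
                  colour = .data$tissue_class4)) +
    geom_point(alpha = 0.6, position = position_dodge(width = 1.6)) +
    scale_y_log10() +
    labs(x = expression(T[a] ~ "(°C)"),
         y = expression(R[d * ",acc"] / V[cmax * ",acc"]),
         colour = "Tissue") +
    theme_minimal()
  if (!is.null(ratio_trends)) {
    lines <- map_dfr(seq_len(nrow(ratio_trends)), function(i) {
      tibble(tissue_class4 = ratio_trends$tissue[i],
             T_a_C = seq(15, 35, length.out = 50)) |>
        mutate(ratio = exp(ratio_trends$intercept[i] +
                             ratio_trends$slope[i] * .data$T_a_C))
    })
    p <- p + geom_line(data = lines, aes(y = .data$ratio))
  }
  p
}
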