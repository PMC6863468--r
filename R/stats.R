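#' Assemble the long parameter table for the inference layer
#'
#' Reshapes per-series curve fits into the long format consumed by
#' [fit_mixed_ancova()]: one row per (individual, tissue, parameter), with
#' the four-level tissue classification and acclimation temperature
#' attached. Metadata already present on the fits is used directly; a
#' separate metadata table (keyed by `individual_id` and `tissue`) can
#' supply or override it. Fits without complete metadata are an error —
#' orphan series must be fixed upstream, not dropped.
#'
#' @param fits An [fit_all_individuals()] result (or any data frame with
#'   `individual_id`, `tissue` and columns `a`, `b`, `c`).
#' @param metadata Optional data frame keyed by `individual_id`, `tissue`
#'   with columns among `species`, `tissue_class`, `T_a_C`.
#' @param parameters Which fitted parameters to carry (default `a`, `b`, `c`).
#' @return A tibble with columns `individual_id`, `species`, `tissue`,
#'   `tissue_class4`, `T_a_C`, `parameter`, `value`.
#' @export
assemble_parameter_table <- function(fits, metadata = NULL,
                                     parameters = c("a", "b", "c")) {
  fits <- as_tibble(fits)
  if (nrow(fits) == 0) {
    return(tibble(individual_id = character(), species = character(),
                  tissue = character(),
                  tissue_class4 = factor(levels = TISSUE_CLASS4),
                  T_a_C = double(), parameter = character(),
                  value = double()))
  }
  if (!is.null(metadata)) {
    keep <- setdiff(names(fits),
                    setdiff(names(metadata), c("individual_id", "tissue")))
    fits <- fits[keep] |>
      left_join(as_tibble(metadata), by = c("individual_id", "tissue"))
  }
  needed <- c("individual_id", "species", "tissue", "tissue_class", "T_a_C")
  if ("tissue_class4" %in% names(fits) &&
      !"tissue_class" %in% names(fits)) {
    fits$tissue_class <- ifelse(
      as.character(fits$tissue_class4) %in% PS_CLASSES,
      "photosynthetic", "non_photosynthetic")
  }
  missing_cols <- setdiff(needed, names(fits))
  if (length(missing_cols) > 0) {
    abort(paste0("Fits lack metadata column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  orphans <- fits |>
    filter(is.na(.data$species) | is.na(.data$tissue_class) |
             is.na(.data$T_a_C))
  if (nrow(orphans) > 0) {
    abort(paste0("No metadata for series: ",
                 paste(utils::head(paste0(orphans$individual_id, "/",
                                          orphans$tissue), 5),
                       collapse = ", ")))
  }
  fits |>
    mutate(tissue_class4 = tissue_class4(.data$tissue, .data$tissue_class)) |>
    select("individual_id", "species", "tissue", "tissue_class4", "T_a_C",
           all_of(intersect(parameters, names(fits)))) |>
    pivot_longer(all_of(intersect(parameters, names(fits))),
                 names_to = "parameter", values_to = "value")
}

#' Mixed-model analysis of covariance for one curve parameter
#'
#' Fits, by restricted maximum likelihood, the hierarchical regression used
#' to test thermal acclimation: the per-individual curve parameter is
#' modelled with fixed effects for species, acclimation temperature
#' (continuous), four-level tissue class and the tissue x acclimation
#' interaction, plus a random intercept per individual (individuals
#' contribute several tissues). Species x temperature interactions are
#' deliberately excluded: the hypotheses are tissue-specific, not
#' species-specific. Factors with a single observed level (e.g. one
#' species) are dropped from the fixed effects so small oracle designs
#' remain estimable.
#'
#' @param records Long parameter table from [assemble_parameter_table()]
#'   (columns `individual_id`, `species`, `tissue_class4`, `T_a_C`,
#'   `parameter`, `value`).
#' @param parameter Which parameter to model (`"a"`, `"b"`, `"c"`,
#'   `"ln_ratio"`, ...).
#' @return An object of class `resp_ancova` wrapping the `lmerMod` fit,
#'   with `tidy()` and `glance()` methods.
#' @seealso [wald_type2()], [lsm_trends()], [planned_contrast()],
#'   [species_marginal_means()]
#' @export
fit_mixed_ancova <- function(records, parameter) {
  d <- as_tibble(records) |>
    filter(.data$parameter == !!parameter) |>
    mutate(species = factor(.data$species),
           tissue_class4 = droplevels(factor(.data$tissue_class4,
                                             levels = TISSUE_CLASS4)))
  if (nrow(d) == 0) abort(paste0("No records for parameter ", parameter))
  if (length(unique(d$T_a_C)) < 2) {
    abort("Acclimation temperature does not vary.")
  }
  n_tissue <- nlevels(d$tissue_class4)
  if (n_tissue < 2) abort("Need >= 2 tissue classes.")
  per_class_ta <- d |>
    group_by(.data$tissue_class4) |>
    summarise(n_ta = length(unique(.data$T_a_C)), .groups = "drop")
  if (any(per_class_ta$n_ta < 2)) {
    abort("Singular design: a tissue class was observed at one T_a level.")
  }

  terms <- c(
    if (nlevels(d$species) > 1) "species",
    "T_a_C * tissue_class4"
  )
  fml <- stats::as.formula(
    paste("value ~", paste(terms, collapse = " + "), "+ (1 | individual_id)")
  )

  msgs <- character()
  # a degenerate (e.g. exactly constant) response breaks the df machinery;
  # fall back to the plain lme4 fit so estimates remain available
  lmer_fun <- function(...) {
    tryCatch(lmerTest::lmer(...), error = function(e) lme4::lmer(...))
  }
  fit <- withCallingHandlers(
    lmer_fun(fml, data = d, REML = TRUE),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  converged <- !any(grepl("failed to converge", msgs))
  if (!converged) {
    warn(paste0("Mixed model for '", parameter,
                "' did not converge cleanly: ",
                paste(unique(msgs), collapse = "; ")))
  }

  structure(
    list(model = fit, parameter = parameter, data = d, formula = fml,
         converged = converged, singular = lme4::isSingular(fit),
         messages = msgs),
    class = "resp_ancova"
  )
}

#' @export
print.resp_ancova <- function(x, ...) {
  cat("<resp_ancova> parameter:", x$parameter, "\n")
  cat("  ", deparse(x$formula), "\n")
  cat("  n =", nrow(x$data),
      "| singular:", x$singular, "| converged:", x$converged, "\n")
  invisible(x)
}

#' @export
tidy.resp_ancova <- function(x, ...) {
  s <- coef(summary(x$model))
  grab <- function(col) if (col %in% colnames(s)) s[, col] else NA_real_
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    df = grab("df"),
    statistic = s[, "t value"],
    p.value = grab("Pr(>|t|)")
  )
}

#' @export
glance.resp_ancova <- function(x, ...) {
  tibble(
    parameter = x$parameter,
    nobs = nrow(x$data),
    n_individuals = length(unique(x$data$individual_id)),
    sigma = stats::sigma(x$model),
    REMLcrit = lme4::REMLcrit(x$model),
    singular = x$singular,
    converged = x$converged
  )
}

# Human-facing term names for report tables.
rename_terms <- function(term) {
  term |>
    gsub("T_a_C", "T_a", x = _) |>
    gsub("tissue_class4", "tissue", x = _)
}

#' Type-II Wald chi-square tests for the model terms
#'
#' The significance summary of the acclimation models: a type-II Wald
#' chi-square for each fixed-effect term (species, T_a, tissue, and the
#' T_a x tissue interaction), computed from the fixed-effect estimates and
#' their covariance.
#'
#' @param fit A [fit_mixed_ancova()] result.
#' @return A tibble with columns `term`, `df`, `chisq`, `p`.
#' @export
wald_type2 <- function(fit) {
  stopifnot(inherits(fit, "resp_ancova"))
  aov_tab <- car::Anova(fit$model, type = 2)
  tibble(
    term = rename_terms(rownames(aov_tab)),
    df = aov_tab$Df,
    chisq = aov_tab$Chisq,
    p = aov_tab$`Pr(>Chisq)`
  )
}

df_method_arg <- function(df_method = c("satterthwaite", "kenward-roger")) {
  match.arg(df_method)
}

#' Least-squares-mean trends of a parameter against acclimation temperature
#'
#' For each tissue class, the marginal (least-squares-mean) slope of the
#' modelled parameter against acclimation temperature — the tissue's own
#' T_a coefficient plus its interaction contrast — and the marginal
#' intercept at T_a = 0, averaging species levels with equal weights.
#' Standard errors come from the fixed-effect covariance; degrees of
#' freedom from the Satterthwaite approximation by default, or
#' Kenward-Roger (the small-sample method of the motivating analysis) on
#' request. A two-sided t-test of slope = 0 is attached.
#'
#' @param fit A [fit_mixed_ancova()] result.
#' @param df_method `"satterthwaite"` (default) or `"kenward-roger"`.
#' @return A tibble of class `resp_trends` with columns `tissue`,
#'   `parameter`, `slope`, `se`, `df`, `t`, `p`, `intercept`,
#'   `intercept_se` (slope units: parameter units per degC).
#' @export
lsm_trends <- function(fit, df_method = "satterthwaite") {
  stopifnot(inherits(fit, "resp_ancova"))
  df_method <- df_method_arg(df_method)
  trends <- emmeans::emtrends(fit$model, ~tissue_class4, var = "T_a_C",
                              lmer.df = df_method)
  slopes <- as.data.frame(summary(trends, infer = c(FALSE, TRUE)))
  # averaging over species at fixed T_a = 0 is the intended marginal
  # intercept; silence the generic interaction advisory
  intercepts <- suppressMessages(as.data.frame(
    emmeans::emmeans(fit$model, ~tissue_class4, at = list(T_a_C = 0),
                     lmer.df = df_method)
  ))
  out <- tibble(
    tissue = as.character(slopes$tissue_class4),
    parameter = fit$parameter,
    slope = slopes$T_a_C.trend,
    se = slopes$SE,
    df = slopes$df,
    t = slopes$t.ratio,
    p = slopes$p.value,
    intercept = intercepts$emmean[match(slopes$tissue_class4,
                                        intercepts$tissue_class4)],
    intercept_se = intercepts$SE[match(slopes$tissue_class4,
                                       intercepts$tissue_class4)]
  )
  structure(out, class = c("resp_trends", class(out)))
}

#' Planned contrast: photosynthetic versus non-photosynthetic trend slopes
#'
#' Tests the study's central hypothesis — that acclimation trends differ
#' between photosynthetic (leaf, photosynthetic stem) and
#' non-photosynthetic (non-photosynthetic stem, root) tissue — as the
#' difference of the unweighted group means of the per-tissue
#' least-squares-mean slopes, with a t-ratio on approximated degrees of
#' freedom.
#'
#' @inheritParams lsm_trends
#' @return A one-row tibble: `estimate` (photosynthetic minus
#'   non-photosynthetic mean slope), `se`, `df`, `t`, `p`.
#' @export
planned_contrast <- function(fit, df_method = "satterthwaite") {
  stopifnot(inherits(fit, "resp_ancova"))
  df_method <- df_method_arg(df_method)
  trends <- emmeans::emtrends(fit$model, ~tissue_class4, var = "T_a_C",
                              lmer.df = df_method)
  lvls <- as.character(summary(trends)$tissue_class4)
  ps <- lvls %in% PS_CLASSES
  nonps <- lvls %in% NONPS_CLASSES
  if (!any(ps) || !any(nonps)) {
    abort("Both photosynthetic and non-photosynthetic classes are required.")
  }
  w <- ifelse(ps, 1 / sum(ps), ifelse(nonps, -1 / sum(nonps), 0))
  ct <- as.data.frame(summary(
    emmeans::contrast(trends, method = list(ps_vs_nonps = w))
  ))
  tibble(estimate = ct$estimate, se = ct$SE, df = ct$df,
         t = ct$t.ratio, p = ct$p.value)
}

#' Species marginal means and Tukey comparisons
#'
#' Model-predicted mean of the parameter per species, averaged over tissue
#' classes with equal weights at the mean acclimation temperature, with
#' all pairwise comparisons Tukey-adjusted. With a single species the
#' grand mean is returned and no comparisons are made.
#'
#' @inheritParams lsm_trends
#' @return A list of class `resp_species_means` with tibbles `means`
#'   (`species`, `emmean`, `se`, `df`) and `comparisons` (`contrast`,
#'   `estimate`, `se`, `df`, `t`, `p`).
#' @export
species_marginal_means <- function(fit, df_method = "satterthwaite") {
  stopifnot(inherits(fit, "resp_ancova"))
  df_method <- df_method_arg(df_method)
  has_species <- "species" %in% all.vars(fit$formula)
  if (!has_species) {
    em <- emmeans::emmeans(fit$model, ~1, lmer.df = df_method)
    s <- as.data.frame(em)
    means <- tibble(species = as.character(unique(fit$data$species)),
                    emmean = s$emmean, se = s$SE, df = s$df)
    comparisons <- tibble(contrast = character(), estimate = double(),
                          se = double(), df = double(), t = double(),
                          p = double())
  } else {
    em <- suppressMessages(
      emmeans::emmeans(fit$model, ~species, lmer.df = df_method))
    s <- as.data.frame(em)
    means <- tibble(species = as.character(s$species), emmean = s$emmean,
                    se = s$SE, df = s$df)
    pr <- as.data.frame(summary(emmeans::contrast(em, "pairwise"),
                                adjust = "tukey"))
    comparisons <- tibble(contrast = pr$contrast, estimate = pr$estimate,
                          se = pr$SE, df = pr$df, t = pr$t.ratio,
                          p = pr$p.value)
  }
  structure(list(means = means, comparisons = comparisons),
            class = "resp_species_means")
}

#' @export
print.resp_species_means <- function(x, ...) {
  cat("<resp_species_means>\n")
  print(x$means)
  if (nrow(x$comparisons) > 0) {
    sig <- filter(x$comparisons, .data$p < 0.05)
    cat(nrow(sig), "of", nrow(x$comparisons),
        "Tukey-adjusted pairwise comparisons significant at 0.05\n")
  }
  invisible(x)
}
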