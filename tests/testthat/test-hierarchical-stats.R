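test_that("the parameter table keeps one row per individual x tissue x parameter", {
  d <- make_design("balanced", species = c("s1", "s2"),
                   ta_levels = c(15, 25, 35), n_per_cell = 1)
  tr <- draw_true_parameters(noiseless_config(), seed = 8)
  st <- simulate_measurements(d, tr)
  fits <- fit_all_individuals(st$records)
  tab <- assemble_parameter_table(fits)

  expect_equal(nrow(tab), 18 * 3) # 18 series x 3 parameters
  expect_setequal(unique(tab$parameter), c("a", "b", "c"))
  per_param <- tab |> dplyr::count(parameter)
  expect_true(all(per_param$n == 18))

  # the eight-species preset has no stem rows for Z. mays
  st2 <- simulate_study("table1", noiseless_config(), seed = 8,
                        vcmax = FALSE)
  tab2 <- assemble_parameter_table(fit_all_individuals(st2$records))
  zm_stem <- tab2 |>
    dplyr::filter(species == "Zea mays", tissue == "stem")
  expect_equal(nrow(zm_stem), 0)

  # empty in, empty out
  expect_equal(nrow(assemble_parameter_table(fits[0, ])), 0)

  # orphan fits without metadata are an error, not silently dropped
  meta <- st$records |>
    dplyr::distinct(individual_id, tissue, species, tissue_class, T_a_C) |>
    dplyr::filter(individual_id != fits$individual_id[1])
  bare <- fits |> dplyr::select(individual_id, tissue, a, b, c)
  expect_error(assemble_parameter_table(bare, metadata = meta),
               "No metadata")
})

test_that("with no random or residual variance the mixed model reproduces OLS", {
  tab <- deterministic_parameter_table(noise_sd = 0)
  fit <- suppressWarnings(fit_mixed_ancova(tab, "b"))
  ols <- lm(value ~ T_a_C * tissue_class4,
            data = tab |> dplyr::mutate(
              tissue_class4 = factor(tissue_class4,
                                     levels = c("leaf", "ps_stem",
                                                "nonps_stem", "root"))))
  expect_lt(max(abs(lme4::fixef(fit$model) - coef(ols))), 1e-3)

  # per-tissue marginal slopes equal the per-tissue OLS slopes
  trends <- lsm_trends(fit)
  by_tissue <- tab |>
    dplyr::group_by(tissue_class4) |>
    dplyr::summarise(slope = coef(lm(value ~ T_a_C))[["T_a_C"]])
  expect_equal(trends$slope[match(by_tissue$tissue_class4, trends$tissue)],
               by_tissue$slope, tolerance = 1e-6)
  # and the recovered slopes are the generating ones
  expect_equal(sort(unique(round(trends$slope, 6))),
               sort(unique(c(0.02, 0.015, 0.01))))
})

test_that("constant and tissue-invariant responses give null slopes", {
  tab <- deterministic_parameter_table(
    slopes = c(leaf = 0, ps_stem = 0, nonps_stem = 0, root = 0),
    intercepts = c(leaf = 2, ps_stem = 2, nonps_stem = 2, root = 2),
    noise_sd = 0
  )
  fit <- suppressWarnings(fit_mixed_ancova(tab, "b"))
  est <- lme4::fixef(fit$model)
  expect_lt(max(abs(est[grepl("T_a_C", names(est))])), 1e-8)

  # T_a-invariant (tissue levels differ, no trend): all marginal slopes 0
  tab_flat <- deterministic_parameter_table(
    slopes = c(leaf = 0, ps_stem = 0, nonps_stem = 0, root = 0),
    intercepts = c(leaf = 2, ps_stem = 2.2, nonps_stem = 2.4, root = 2.6),
    noise_sd = 0
  )
  trends <- lsm_trends(suppressWarnings(fit_mixed_ancova(tab_flat, "b")))
  expect_lt(max(abs(trends$slope)), 1e-8)

  # tissue-invariant but T_a-dependent: identical slopes everywhere,
  # so the planned contrast is exactly zero
  tab2 <- deterministic_parameter_table(
    slopes = c(leaf = 0.01, ps_stem = 0.01, nonps_stem = 0.01, root = 0.01),
    noise_sd = 1e-4
  )
  fit2 <- fit_mixed_ancova(tab2, "b")
  ct <- planned_contrast(fit2)
  expect_lt(abs(ct$estimate), 1e-4)
})

test_that("Wald table reports type-II chi-squares with the design's term df", {
  st <- simulate_study("table1", truth_config(), seed = 31, vcmax = FALSE)
  tab <- assemble_parameter_table(fit_all_individuals(st$records))
  fit <- fit_mixed_ancova(tab, "b")
  w <- wald_type2(fit)

  # 8 species, continuous T_a, 4 tissue classes and the interaction
  expect_equal(w$term, c("species", "T_a", "tissue", "T_a:tissue"))
  expect_equal(w$df, c(7, 1, 3, 3))
  expect_true(all(w$chisq >= 0))
  expect_true(all(w$p >= 0 & w$p <= 1))
})

test_that("the planned contrast is the difference of unweighted group mean slopes", {
  tab <- deterministic_parameter_table(
    slopes = c(leaf = 0, ps_stem = 0, nonps_stem = -0.005, root = -0.005),
    noise_sd = 0
  )
  fit <- suppressWarnings(fit_mixed_ancova(tab, "b"))
  ct <- planned_contrast(fit)
  # mean(Ps slopes) - mean(non-Ps slopes) = 0 - (-0.005)
  expect_equal(ct$estimate, 0.005, tolerance = 1e-8)
  expect_equal(ct$t, ct$estimate / ct$se, tolerance = 1e-8)

  # with visible noise the t statistic and its df are finite and usable
  tab2 <- deterministic_parameter_table(
    slopes = c(leaf = 0, ps_stem = 0, nonps_stem = -0.005, root = -0.005),
    noise_sd = 0.01, seed = 5
  )
  ct2 <- planned_contrast(fit_mixed_ancova(tab2, "b"))
  expect_gt(ct2$df, 0)
  expect_gt(ct2$estimate, 0)
})

test_that("trend estimates are invariant to the species reference level", {
  st <- simulate_study("table1", truth_config(), seed = 13, vcmax = FALSE)
  tab <- assemble_parameter_table(fit_all_individuals(st$records))
  fit1 <- fit_mixed_ancova(tab, "a")

  tab_recode <- tab |>
    dplyr::mutate(species = stats::relevel(factor(species), ref = "Zea mays"))
  fit2 <- fit_mixed_ancova(tab_recode, "a")

  t1 <- lsm_trends(fit1)
  t2 <- lsm_trends(fit2)
  expect_equal(t1$slope, t2$slope, tolerance = 1e-8)
  expect_equal(t1$se, t2$se, tolerance = 1e-6)
  expect_equal(t1$intercept, t2$intercept, tolerance = 1e-8)
})

test_that("generated acclimation signs are recovered with ample data and low noise", {
  # root b declines with T_a, leaf b does not
  means <- default_trend_means() |>
    dplyr::mutate(slope = dplyr::case_when(
      parameter != "b" ~ slope,
      tissue %in% c("leaf", "ps_stem") ~ 0,
      TRUE ~ -0.005
    ))
  cfg <- truth_config(trend_means = means, species_offset_sd = 0.1,
                      individual_offset_sd = 0.1, noise_sd_log = 0.05)
  d <- make_design("balanced", species = c("s1", "s2"), n_per_cell = 6)
  st <- simulate_study(d, cfg, seed = 77, vcmax = FALSE)
  tab <- assemble_parameter_table(fit_all_individuals(st$records))
  trends <- lsm_trends(fit_mixed_ancova(tab, "b"))

  expect_lt(trends$slope[trends$tissue == "root"], 0)
  expect_lt(trends$slope[trends$tissue == "nonps_stem"], 0)
  expect_lt(abs(trends$slope[trends$tissue == "leaf"]), 0.0025)
  # non-photosynthetic slopes more negative than photosynthetic ones
  ct <- planned_contrast(fit_mixed_ancova(tab, "b"))
  expect_gt(ct$t, 0)
})

test_that("species marginal means collapse correctly and support Tukey comparisons", {
  # single species: the marginal mean is the grand mean
  tab <- deterministic_parameter_table(noise_sd = 0.001)
  fit <- fit_mixed_ancova(tab, "b")
  mm <- species_marginal_means(fit)
  expect_equal(nrow(mm$means), 1)
  expect_equal(nrow(mm$comparisons), 0)

  # several species with identical offsets and tiny noise: all means equal
  st <- simulate_study(
    make_design("balanced", species = c("s1", "s2", "s3"), n_per_cell = 2),
    truth_config(species_offset_sd = 0, individual_offset_sd = 0,
                 noise_sd_log = 1e-6, top_temp_jitter_sd = 0),
    seed = 3, vcmax = FALSE
  )
  tab2 <- assemble_parameter_table(fit_all_individuals(st$records))
  mm2 <- species_marginal_means(fit_mixed_ancova(tab2, "a"))
  expect_equal(nrow(mm2$means), 3)
  expect_lt(diff(range(mm2$means$emmean)), 1e-4)
  expect_equal(nrow(mm2$comparisons), 3)
  expect_lt(max(abs(mm2$comparisons$estimate)), 1e-4)

  # a strong species offset is detected as the extreme marginal mean
  st3 <- simulate_study("table1", truth_config(), seed = 19, vcmax = FALSE)
  tab3 <- assemble_parameter_table(fit_all_individuals(st3$records))
  mm3 <- species_marginal_means(fit_mixed_ancova(tab3, "a"))
  expect_equal(nrow(mm3$means), 8)
})

test_that("Kenward-Roger degrees of freedom shift df but not estimates", {
  tab <- deterministic_parameter_table(noise_sd = 0.005, seed = 9)
  fit <- fit_mixed_ancova(tab, "b")
  sat <- lsm_trends(fit, df_method = "satterthwaite")
  kr <- lsm_trends(fit, df_method = "kenward-roger")
  expect_equal(sat$slope, kr$slope, tolerance = 1e-10)
  expect_equal(sat$se, kr$se, tolerance = 1e-6)
  expect_true(all(kr$df > 0))
})

test_that("model preconditions are enforced", {
  tab <- deterministic_parameter_table(noise_sd = 0)
  expect_error(fit_mixed_ancova(tab, "zzz"), "No records")
  one_ta <- tab |> dplyr::filter(T_a_C == 25)
  expect_error(fit_mixed_ancova(one_ta, "b"), "does not vary")
  one_tissue <- tab |> dplyr::filter(tissue_class4 == "leaf")
  expect_error(fit_mixed_ancova(one_tissue, "b"), "tissue classes")
  # a tissue class observed at a single T_a level is a singular design
  degen <- tab |>
    dplyr::filter(!(tissue_class4 == "root" & T_a_C != 25))
  expect_error(fit_mixed_ancova(degen, "b"), "Singular design")
})
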