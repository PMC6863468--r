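test_that("surface evaluation composes the trend lines with the response curve", {
  # explicit trend numbers, checked against direct evaluation
  trends <- tibble::tribble(
    ~tissue, ~parameter, ~intercept, ~slope,
    "leaf", "a", -5.5, -0.02,
    "leaf", "b", 0.12, 0.001,
    "leaf", "c", -8e-4, -2e-5,
    "root", "a", -7.0, 0.05,
    "root", "b", 0.23, -0.005,
    "root", "c", -2.9e-3, 9e-5
  )
  sf <- build_surface(trends)
  direct <- function(tis, tt, ta) {
    p <- trends[trends$tissue == tis, ]
    abc <- setNames(p$intercept + p$slope * ta, p$parameter)
    exp(abc[["a"]] + abc[["b"]] * tt + abc[["c"]] * tt^2)
  }
  for (tis in c("leaf", "root")) {
    for (ta in c(15, 25, 35)) {
      for (tt in c(14, 25, 41)) {
        got <- predict(sf, T_t = tt, T_a = ta, tissue = tis)$rd
        expect_equal(got, direct(tis, tt, ta), tolerance = 1e-12)
      }
    }
  }

  # at fixed T_a the surface is the plain response curve
  ta <- 20
  p <- trends[trends$tissue == "root", ]
  abc <- as.list(setNames(p$intercept + p$slope * ta, p$parameter))
  tt <- seq(14, 45, by = 1)
  expect_equal(predict(sf, T_t = tt, T_a = ta, tissue = "root")$rd,
               evaluate_polynomial(abc, tt), tolerance = 1e-12)

  # diagonal evaluation is the definition of the acclimated rate
  acc <- rd_at_acclimation(sf, T_a = c(15, 30))
  diag <- predict(sf, T_t = c(15, 30), T_a = c(15, 30))
  expect_equal(acc$rd_acc, diag$rd, tolerance = 1e-15)

  # zero trend slopes make the surface independent of T_a
  flat <- build_surface(flat_trends(a = -6, b = 0.1, c = -0.001))
  r1 <- predict(flat, T_t = 25, T_a = 15)$rd
  r2 <- predict(flat, T_t = 25, T_a = 35)$rd
  expect_equal(r1, r2, tolerance = 1e-15)

  # missing parameter trends are an error
  expect_error(build_surface(trends[-2, ]), "incomplete")
})

test_that("the homeostasis ratio obeys its analytic identities", {
  # flat homeostatic surface: ratio 1 everywhere
  flat <- build_surface(flat_trends(a = -6, b = 0, c = 0))
  h <- acclim_homeo(flat, T_a = c(15, 20, 25, 30, 35))
  expect_equal(h$acclim_homeo, rep(1, nrow(h)), tolerance = 1e-15)

  # non-acclimating exponential surface (b = 0.07): e^(-0.7) on both
  # sides of the reference -- the orientation swap makes under- and
  # over-shoot symmetric for a symmetric instantaneous response
  sfe <- build_surface(flat_trends(a = -6, b = 0.07, c = 0))
  h15 <- acclim_homeo(sfe, T_a = 15, tissue = "leaf")
  h35 <- acclim_homeo(sfe, T_a = 35, tissue = "leaf")
  expect_equal(h15$acclim_homeo, exp(-0.7), tolerance = 1e-12)
  expect_equal(h35$acclim_homeo, exp(-0.7), tolerance = 1e-12)

  # identity at the reference temperature is exact
  h25 <- acclim_homeo(sfe, T_a = 25)
  expect_identical(unique(h25$acclim_homeo), 1)

  # all values strictly positive
  expect_true(all(acclim_homeo(sfe, T_a = c(15, 20, 30, 35))$acclim_homeo > 0))
})

test_that("the ratio cancels basal scale: a-intercept shifts change nothing", {
  trends <- dplyr::bind_rows(
    flat_trends(a = -6, b = 0.11, c = -6e-4, tissues = "leaf"),
    flat_trends(a = -7, b = 0.08, c = -4e-4, tissues = "root") |>
      dplyr::mutate(slope = ifelse(parameter == "a", -0.05, slope))
  )
  sf <- build_surface(trends)
  shifted <- trends |>
    dplyr::mutate(intercept = intercept +
                    ifelse(parameter == "a", 1.234, 0))
  sf2 <- build_surface(shifted)
  ta <- c(15, 20, 30, 35)
  expect_equal(acclim_homeo(sf, ta)$acclim_homeo,
               acclim_homeo(sf2, ta)$acclim_homeo, tolerance = 1e-12)
})

test_that("grid values approach 1 monotonically along a homotopy to homeostasis", {
  # start: no acclimation; end: basal-rate trend that exactly cancels the
  # instantaneous sensitivity at the diagonal, i.e. perfect homeostasis
  b0 <- 0.11
  homeo_a_slope <- -b0 # with c = 0: d/dTa ln R(Ta;Ta) = a' + b
  lambdas <- seq(0, 1, length.out = 5)
  vals <- sapply(lambdas, function(lam) {
    tr <- flat_trends(a = -6, b = b0, c = 0, tissues = "leaf") |>
      dplyr::mutate(slope = ifelse(parameter == "a",
                                   lam * homeo_a_slope, slope))
    mean(acclim_homeo(build_surface(tr),
                      T_a = c(15, 20, 30, 35))$acclim_homeo)
  })
  expect_true(all(diff(vals) > 0))
  expect_equal(vals[length(vals)], 1, tolerance = 1e-12)
})

test_that("for a T_a-invariant increasing response the ratio rises toward the reference", {
  sf <- build_surface(flat_trends(a = -6, b = 0.09, c = 5e-5,
                                  tissues = "leaf"))
  below <- acclim_homeo(sf, T_a = c(15, 18, 21, 24))$acclim_homeo
  above <- acclim_homeo(sf, T_a = c(35, 31, 28, 26))$acclim_homeo
  expect_true(all(diff(below) > 0))
  expect_true(all(diff(above) > 0))
  expect_true(all(c(below, above) < 1))
})

test_that("the homeostasis table carries exact marginal averages", {
  trends <- dplyr::bind_rows(
    flat_trends(a = -6, b = 0.11, c = -6e-4, tissues = c("leaf", "ps_stem")),
    strong_nonps_acclimation_trends() |>
      dplyr::filter(tissue %in% c("nonps_stem", "root"))
  )
  sf <- build_surface(trends)
  ht <- homeostasis_table(sf)

  expect_equal(nrow(ht), 4 * 4)
  tm <- attr(ht, "tissue_means")
  for (i in seq_len(nrow(tm))) {
    expect_equal(tm$mean_acclim_homeo[i],
                 mean(ht$acclim_homeo[ht$tissue == tm$tissue[i]]),
                 tolerance = 1e-12)
  }
  am <- attr(ht, "ta_means")
  for (i in seq_len(nrow(am))) {
    expect_equal(am$mean_acclim_homeo[i],
                 mean(ht$acclim_homeo[ht$T_a_C == am$T_a_C[i]]),
                 tolerance = 1e-12)
  }
  expect_equal(attr(ht, "grand_mean"), mean(ht$acclim_homeo),
               tolerance = 1e-12)

  # all-flat surfaces: every cell exactly 1
  all_flat <- homeostasis_table(build_surface(flat_trends(a = -5)))
  expect_true(all(all_flat$acclim_homeo == 1))

  # wide layout: 4 T_a rows + average row; tissue columns + average column
  wide <- homeo_wide(ht)
  expect_equal(nrow(wide), 5)
  expect_equal(wide$T_a_C, c("15", "20", "30", "35", "average"))
  expect_setequal(setdiff(names(wide), "T_a_C"),
                  c("leaf", "ps_stem", "nonps_stem", "root", "average"))
})

test_that("acclimated respiration-to-capacity ratios are evaluated per individual", {
  d <- single_species_design(n_per_cell = 2)
  leaf_trends <- default_trend_means() |> dplyr::filter(tissue == "leaf")
  cfg <- noiseless_config(
    vcmax_trend_means = leaf_trends |>
      dplyr::mutate(intercept = intercept +
                      ifelse(parameter == "a", log(10), 0))
  )
  st <- simulate_study(d, cfg, seed = 6)
  rd_fits <- fit_all_individuals(st$records)
  vc_fits <- fit_all_individuals(st$vcmax_records)
  rr <- compute_ratio_records(rd_fits, vc_fits)

  # every individual contributes one record per fitted tissue
  expect_equal(nrow(rr), nrow(rd_fits))
  # by construction V_cmax = 10 x leaf R_d: leaf ratio exactly 0.1
  leaf_rr <- rr |> dplyr::filter(tissue == "leaf")
  expect_equal(leaf_rr$rd_acc / leaf_rr$vcmax_acc,
               rep(0.1, nrow(leaf_rr)), tolerance = 1e-8)
  # and the ln-ratio trend against T_a is flat for leaves
  leaf_slope <- coef(lm(ln_ratio ~ T_a_C, data = leaf_rr))[["T_a_C"]]
  expect_equal(leaf_slope, 0, tolerance = 1e-8)
})

test_that("a configured ln-ratio trend is recovered exactly at zero noise", {
  # V_cmax curve constructed so that ln(R_d,acc / V_cmax,acc) is linear in
  # T_a with slope -0.063 and intercept -2.20
  slope_ratio <- -0.063
  int_ratio <- -2.20
  leaf_trends <- default_trend_means() |> dplyr::filter(tissue == "leaf")
  vc_trends <- leaf_trends |>
    dplyr::mutate(
      intercept = intercept - ifelse(parameter == "a", int_ratio, 0),
      slope = slope - ifelse(parameter == "a", slope_ratio, 0)
    )
  cfg <- noiseless_config(vcmax_trend_means = vc_trends)
  st <- simulate_study(single_species_design(2), cfg, seed = 10)
  rr <- compute_ratio_records(fit_all_individuals(st$records),
                              fit_all_individuals(st$vcmax_records)) |>
    dplyr::filter(tissue == "leaf")
  fitline <- coef(lm(ln_ratio ~ T_a_C, data = rr))
  expect_equal(fitline[["T_a_C"]], slope_ratio, tolerance = 1e-6)
  expect_equal(fitline[["(Intercept)"]], int_ratio, tolerance = 1e-6)

  # the ratio table feeds the mixed-model layer unchanged
  tab <- ratio_parameter_table(compute_ratio_records(
    fit_all_individuals(st$records), fit_all_individuals(st$vcmax_records)))
  expect_setequal(unique(tab$parameter), "ln_ratio")
  trends <- lsm_trends(suppressWarnings(fit_mixed_ancova(tab, "ln_ratio")))
  expect_equal(trends$slope[trends$tissue == "leaf"], slope_ratio,
               tolerance = 1e-6)
})

test_that("degenerate ratio records are excluded with a warning, never silently", {
  d <- single_species_design(1)
  st <- simulate_study(d, noiseless_config(), seed = 2)
  rd_fits <- fit_all_individuals(st$records)
  vc_fits <- fit_all_individuals(st$vcmax_records)

  # force one individual's V_cmax to evaluate to zero
  vc_broken <- vc_fits
  vc_broken$a[1] <- -Inf
  expect_warning(rr <- compute_ratio_records(rd_fits, vc_broken),
                 "Excluding")
  excluded_id <- vc_broken$individual_id[1]
  expect_false(excluded_id %in% rr$individual_id)

  # disjoint individuals are an error
  vc_other <- vc_fits |>
    dplyr::mutate(individual_id = paste0("other_", individual_id))
  expect_error(compute_ratio_records(rd_fits, vc_other), "No individuals")
})
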