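# respacclim

Thermal acclimation analysis of plant tissue dark respiration.

Plant respiration responds to temperature on two timescales: instantaneously,
rates rise roughly exponentially with tissue temperature; over days, the whole
instantaneous response can shift as the tissue acclimates to its growth
temperature. `respacclim` is for ecophysiologists running (or re-analysing)
multi-species, multi-tissue acclimation experiments: individuals acclimated to
one of several temperatures T<sub>a</sub>, with instantaneous
temperature–response curves of dark respiration R<sub>d</sub> measured on
leaves, stems and roots, and optionally a leaf V<sub>cmax</sub> series as a
photosynthetic-capacity proxy.

## The model

Every curve is the log-quadratic temperature response

> R(T) = exp(a + b·T + c·T²)

with T in °C, `a` the log rate at 0 °C (µmol g⁻¹ s⁻¹, dry-mass basis), `b`
(°C⁻¹) the exponential sensitivity near 0 °C, and `c` (°C⁻²) its change with
temperature. Acclimation enters as linear drifts of (a, b, c) with
T<sub>a</sub> per tissue class, estimated by mixed-model ANCOVA (species +
T<sub>a</sub> × tissue class, random intercept per individual) on the
per-individual fits, with type-II Wald χ² tests, least-squares-mean trends,
and a planned photosynthetic vs non-photosynthetic contrast. The fitted
trends reconstruct the acclimated surface R<sub>d</sub>(T<sub>t</sub>;
T<sub>a</sub>), from which the homeostasis ratio is computed:
Acclim<sub>Homeo</sub> = R<sub>d</sub>(T<sub>a</sub>; T<sub>a</sub>) /
R<sub>d</sub>(25; 25) below the 25 °C reference and its reciprocal above it,
so 1 always means fully homeostatic respiration.

A synthetic-data generator (`simulate_study()`) reproduces the unbalanced
8-species × 5-temperature × 3-tissue design of the motivating study
(84 individuals, no *Zea mays* stems), with configurable parameter trends,
species/individual basal-rate offsets and multiplicative lognormal noise —
so every stage of the pipeline is testable without any download.

## Worked example

Simulate a study at the default conditions (published trend magnitudes,
noise SD 0.15 on the log flux) and run the full chain:

```r
library(respacclim)
library(dplyr)

report <- run_pipeline(run_config("table1", seed = 42))

report$table2 |> filter(parameter == "b")
#>   parameter term          df chisq        p
#> 1 b         species        7  9.61 2.12e- 1
#> 2 b         T_a            1 25.9  3.66e- 7
#> 3 b         tissue         3  5.05 1.68e- 1
#> 4 b         T_a:tissue     3 88.0  5.79e-19
```

The significant T<sub>a</sub> × tissue interaction says the temperature
sensitivity parameter `b` responds to acclimation differently across
tissues. The per-tissue marginal trends show where:

```r
report$table3 |> filter(parameter == "b") |> select(tissue:p)
#>   tissue     parameter     slope       se    df      t        p
#> 1 leaf       b          0.00174  0.000631  220.  2.76  6.30e- 3
#> 2 ps_stem    b          0.000955 0.00111   223.  0.861 3.90e- 1
#> 3 nonps_stem b         -0.00659  0.000906  223. -7.27  5.86e-12
#> 4 root       b         -0.00457  0.000631  220. -7.24  7.56e-12
```

Non-photosynthetic tissues (root, non-photosynthetic stem) lower `b` by
about 0.005 °C⁻¹ per °C of acclimation — the generating value — while
photosynthetic tissues stay near zero; the planned contrast confirms the
group difference (t ≈ 8.3, p < 1e-13 at this seed). The homeostasis table
summarises the reconstructed surfaces:

```r
homeo_wide(report$table4, digits = 2)
#>   T_a_C    leaf nonps_stem ps_stem  root average
#> 1 15       0.43       0.4     0.36  0.41    0.4
#> 2 20       0.66       0.69    0.61  0.67    0.66
#> 3 30       0.7        0.75    0.66  0.7     0.7
#> 4 35       0.52       0.57    0.48  0.48    0.51
#> 5 average  0.58       0.6     0.53  0.57    0.57
```

Each cell compares the acclimated rate at that T<sub>a</sub> with the
25 °C reference; values near 1 mean homeostatic respiration. `autoplot()`
methods on the surface and homeostasis objects, and
`plot_parameter_trends()` / `plot_ratio_trends()`, draw the corresponding
figures. Real data enter through `read_measurements()` (long CSV, one row
per flux observation; area-basis fluxes are converted to dry-mass basis at
ingest) and `run_config(input = "file.csv")`.

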