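---
title: "Methods: thermal acclimation of tissue dark respiration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal acclimation of tissue dark respiration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respacclim)
library(dplyr)
```

## The scientific problem

Plant respiration returns a large fraction of terrestrial carbon to the
atmosphere, and its response to temperature operates on two timescales.
Instantaneously, respiration rises roughly exponentially with tissue
temperature. Over days to weeks, the whole instantaneous response can shift
as the tissue *acclimates* to its growth temperature — typically damping
the realised flux relative to what the instantaneous curve alone would
predict. Whether leaves, stems and roots acclimate alike matters for
land-surface models, which commonly drive stem and root respiration off the
leaf response.

`respacclim` implements a complete analysis chain for studies of this
question: several species, each individual acclimated for a short period to
one temperature $T_a$, with instantaneous temperature–response curves of
dark respiration $R_d$ measured on up to three tissues per individual (and,
optionally, a leaf photosynthetic-capacity series, $V_{cmax}$).

## The response model

Every curve is the log-quadratic ("exponential-polynomial") model

$$R(T) = \exp\!\left(a + bT + cT^2\right),$$

with $T$ the tissue temperature in °C, $a$ the log rate at 0 °C
(rates in µmol g$^{-1}$ s$^{-1}$, dry-mass basis), $b$ (°C$^{-1}$) the
exponential sensitivity near 0 °C and $c$ (°C$^{-2}$) its change with
temperature. Temperatures are used in °C throughout — $a$ is defined at
0 °C, and no Kelvin conversion appears anywhere in the package.

Acclimation is expressed by letting the parameters drift linearly in the
acclimation temperature, per tissue class $k$:

$$a_k(T_a) = \alpha_{0,k} + \alpha_{1,k} T_a, \qquad
  b_k(T_a) = \beta_{0,k} + \beta_{1,k} T_a, \qquad
  c_k(T_a) = \gamma_{0,k} + \gamma_{1,k} T_a.$$

The composed two-argument surface
$R_d(T_t; T_a) = \exp\{a_k(T_a) + b_k(T_a) T_t + c_k(T_a) T_t^2\}$
is the object from which all acclimation statistics are computed.

## The analysis chain

1. **Per-series curve fits** (`fit_polynomial()`, `fit_all_individuals()`).
   The default scale, `log_ols`, is exact least squares of $\ln R$ on
   $(1, T, T^2)$ — closed-form, and the natural scale for a model that is
   linear in its parameters after the log. An `original_nls` scale
   (Levenberg–Marquardt on the flux scale, started from the log fit) is
   offered because reporting conventions for this curve family sometimes
   quote flux-scale errors; RMSE is always reported on the original flux
   scale either way, so the two scales are directly comparable. The choice
   matters little at typical noise levels but log fitting weights
   low-temperature (small-flux) points more heavily. Non-positive fluxes —
   occasional negative instrument readings — cannot enter a log fit; they
   are dropped with a warning rather than aborting a batch, and a series
   must retain at least 4 usable points at 3 distinct temperatures.
2. **Mixed-model ANCOVA** (`fit_mixed_ancova()`). Each fitted parameter
   (and, when $V_{cmax}$ is present, the log acclimated-ratio, below) is
   regressed on species, $T_a$ (continuous), four-level tissue class
   (leaf, photosynthetic stem, non-photosynthetic stem, root) and the
   $T_a\times$ tissue interaction, with a random intercept per individual
   (REML, via `lme4`). Species × $T_a$ interactions are deliberately
   excluded: the hypotheses are tissue-specific, and the replication per
   species–temperature cell is too thin to support them. Unbalanced
   designs are handled by the model itself; no cells are dropped.
3. **Inference** (`wald_type2()`, `lsm_trends()`, `planned_contrast()`,
   `species_marginal_means()`). Term significance uses type-II Wald
   $\chi^2$ (via `car::Anova`). Marginal ("least-squares-mean") trends of
   each parameter against $T_a$ per tissue class, their intercepts at
   $T_a = 0$, and the planned photosynthetic vs non-photosynthetic
   contrast come from `emmeans`.
4. **Surfaces and statistics** (`build_surface()`, `homeostasis_table()`,
   `compute_ratio_records()`). The fitted trends reconstruct
   $R_d(T_t; T_a)$ per tissue; from it come the acclimated rate
   $R_{d,acc} = R_d(T_a; T_a)$ and the homeostasis ratio.

## The homeostasis statistic

With 25 °C as the reference acclimation state (the pre-treatment growth
temperature), the homeostasis ratio is

$$\mathrm{Acclim_{Homeo}}(T_a) =
  \begin{cases}
    R_d(T_a; T_a) \,/\, R_d(25; 25) & T_a < 25\ \text{°C} \\
    1 & T_a = 25\ \text{°C} \\
    R_d(25; 25) \,/\, R_d(T_a; T_a) & T_a > 25\ \text{°C.}
  \end{cases}$$

The orientation swap above the reference makes 1 mean "fully homeostatic"
on both sides, with smaller values meaning progressively less homeostasis.
Two properties follow directly and are enforced by tests: the value at the
reference is exactly 1, and the statistic is invariant to any constant
shift of the $a$ intercepts (basal scale cancels in the ratio).

The headline table is computed from the *population-level* reconstructed
surfaces. A per-individual variant (`acclim_homeo_individual()`) is
provided for exploration, but it mixes within- and between-individual
variation and is not the primary statistic. Grid cells and marginal
averages are kept at full precision; rounding (e.g. to 2 decimals) happens
only at report time via `homeo_wide(digits =)`. Averages of rounded and
unrounded grids can differ in the second decimal, which is worth knowing
when comparing published tables assembled either way.

## The respiration-to-capacity ratio

To probe why photosynthetic tissue might fail to acclimate, each tissue's
$R_{d,acc}$ is compared with the individual's leaf $V_{cmax,acc}$ (the
$V_{cmax}$ curve evaluated at $T_t = T_a$, per-gram units). The ratio
analysis models $\ln(R_{d,acc}/V_{cmax,acc})$ with the same mixed model.
Modelling the log, rather than the raw ratio, is an interpretive choice:
an exponential-in-$T_a$ trend of a strictly positive ratio is only
consistent with a linear model on the log scale, and it protects the model
from the right-skew of ratios. Records where either rate is non-positive
or non-finite are excluded with a warning.

## Degrees of freedom

Satterthwaite approximation is the default for trend and contrast tests;
Kenward-Roger — the classical small-sample choice for REML mixed models —
is available via `df_method = "kenward-roger"` wherever df are computed.
Estimates and standard errors are identical under both; only df and hence
p-values shift, and only materially so in very small designs. The default
favours Satterthwaite because it is far cheaper on models refitted
hundreds of times in simulation studies.

Equal weights are used when marginalising over species (the conventional
estimated-marginal-means definition), and the planned contrast is the
difference of *unweighted* group means of the per-tissue slopes
(photosynthetic = {leaf, photosynthetic stem}; non-photosynthetic =
{non-photosynthetic stem, root}). Both are conventions; weighting by
observed frequencies would pull the marginal means toward the
better-replicated species.

## The synthetic-data generator

`simulate_study()` exists so that every stage can be validated without any
external data. It emulates the structure the inference layer assumes:

* **Design.** The `"table1"` preset reproduces the motivating study's
  unbalanced sampling plan: 8 species × 5 acclimation temperatures
  (15–35 °C), 84 individuals in total, leaf and root series for every
  species, and stem series for all but *Zea mays* (whose stems were too
  thick for the cuvette). Photosynthetic stems are assigned to the
  herbaceous crops (*C. sativa*, *G. max*) and non-photosynthetic stems to
  the five trees — a generator convention: the source study reports the
  two stem classes but not the per-species assignment.
* **Parameters.** Per-tissue trend slopes default to the published
  per-tissue trend magnitudes (e.g. root $b$ slope −0.005 °C$^{-1}$ per
  °C). Published tables give slopes but not intercepts, so the curve
  *levels* at $T_a = 25$ are the package's own choice: $b = 0.11$
  °C$^{-1}$ and $c = -6\times10^{-4}$ °C$^{-2}$ (instantaneous log-slope
  ≈ 0.08 at 25 °C, i.e. $Q_{10} \approx 2.2$, typical for plant tissue),
  with basal rates $a(25)$ of −6.0 (leaf) to −6.4 (non-photosynthetic
  stem) giving mass-based rates of 0.01–0.03 µmol g$^{-1}$ s$^{-1}$ at
  25 °C. Reassuringly, composing these levels with the published leaf
  trend slopes reproduces the published leaf homeostasis value at
  $T_a = 15$ (≈ 0.45) almost exactly.
* **Species and individuals** perturb only $a$ (log-normal offsets,
  defaults 0.35 and 0.25 ln units): species in the source study differed
  in basal rate but not in curve shape. Both SDs are configurable.
* **Noise** is multiplicative lognormal on the flux
  (`noise_sd_log = 0.15` by default): respiration is strictly positive,
  the model is exponential, and multiplicative noise keeps log fitting
  well-posed at every temperature.
* **Measurement grid** {14, 23, 32, 41, 45} °C. The instrument's nominal
  ~50 °C top setpoint is represented by its typically *achieved* ~45 °C
  value, jittered N(0, 0.5 °C) per series to mimic the per-individual
  variation of the attainable maximum. The reported spread of achieved
  top temperatures constrains the mean but not the distribution; the
  Gaussian jitter is our choice.
* **Randomness.** One master seed; design, parameter, offset and noise
  draws use fixed, documented substreams of it, so e.g. adding the
  $V_{cmax}$ series does not perturb the respiration draws, and equal
  `(design, truth, seed)` triples are bitwise reproducible.

What the generator does *not* emulate: instrument error structure
(drift, matching error, leaks), $A/C_i$ curve fitting (the $V_{cmax}$
series is simulated directly from the same curve family), stomatal or
within-day physiology, and any species × temperature interaction.
Passing recovery tests on these simulations therefore demonstrates that
the estimators are correct for the assumed data-generating process — not
that the process captures every feature of field data.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle:
noiseless data must be interpolated exactly; the closed-form log-OLS fit
must beat or match a brute-force grid search refined to $10^{-4}$ on 50
random series; the mixed model must reproduce plain OLS on zero-variance
balanced designs; and the homeostasis statistic must satisfy its analytic
identities (exact 1 at the reference, $e^{-0.7}$ closed form for a
non-acclimating $b = 0.07$ surface, basal-scale invariance, monotone
approach to 1 along a homotopy to a perfectly homeostatic surface).

Sampling properties are checked by Monte Carlo at the `"table1"` design:
95% CIs for tissue trend slopes attain 90–98% empirical coverage over 200
replicates with published-magnitude generating slopes; the type-II Wald
interaction test keeps its size (rejection rate 2–9% at $\alpha = 0.05$)
over 500 null replicates; and a truth with strongly acclimating
non-photosynthetic tissue and non-acclimating photosynthetic tissue ranks
the per-tissue homeostasis averages correctly in at least 18 of 20 seeds.
These replicate counts keep each property estimable with useful binomial
precision (±2–4 percentage points) while the full suite stays quick to
run; they are the package's validation settings, not tuning knobs.

## Known limitations

* Linear parameter-vs-$T_a$ trends are an assumption inherited from the
  analysis design; curvature in acclimation (e.g. saturating responses)
  would be mis-summarised by the reconstructed surfaces.
* The random-effects structure is a single intercept per individual; no
  random slopes are offered, matching the source analysis but limiting
  robustness when individuals differ in sensitivity, not just level.
* The homeostasis statistic depends on the reconstructed population
  surface; with few individuals per cell its uncertainty is substantial
  and is not propagated into the table (no CI on the grid cells).
* Kenward-Roger df are exact only in the balanced Gaussian case; in the
  unbalanced designs used here both df methods are approximations.
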