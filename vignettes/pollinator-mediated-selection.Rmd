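---
title: "Estimating pollinator-mediated selection on floral traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating pollinator-mediated selection on floral traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floralsel)
```

## The question and the design

Floral traits evolve under selection from pollinators and from everything
else — resources, herbivores, abiotic stress.  The supplemental
hand-pollination design separates the two.  Plants are randomized to open
pollination (**C**, natural pollinator service only) or supplemental hand
pollination (**HP**, every flower saturated with outcross pollen).  In HP
plants fitness no longer depends on pollinator visits, so selection
estimated in the HP arm is non-pollinator-mediated; the C-minus-HP
difference in selection gradients isolates the component attributable to
pollinators.  The same contrast of arm means gives the pollen-limitation
index

$$\mathrm{PL} = 1 - \frac{\bar{W}_C}{\bar{W}_{HP}},$$

the fraction of potential seed set lost to inadequate pollination.

`floralsel` implements this analysis for two experimental layouts: a
two-site $\times$ two-year factorial in natural populations of a distylous
alpine primrose (sites differing in soil water content), and a
nutrient-addition common garden (0%, 0.5% and 1% N-P-K levels crossed with
pollination).

## The selection model

Within each analysis cell (pollination $\times$ site $\times$ year, or
pollination $\times$ nutrient level) we follow the classical
multiple-regression approach to phenotypic selection:

* **relative fitness** $w_i = W_i / \bar{W}$, seeds per plant divided by
  the cell mean (mean 1 by construction);
* **standardized traits** $z_{ij}$, each trait centred and divided by its
  within-cell sample SD ($n-1$ denominator);
* **directional gradients** $\beta_j$: OLS coefficients of
  $w \sim z_1 + \dots + z_k$;
* **quadratic gradients** $\gamma_{jj}$: twice the fitted coefficient of
  $z_j^2$ in $w \sim z_1 + \dots + z_k + z_1^2 + \dots + z_k^2$.  The
  doubling makes the coefficient the curvature of the fitness surface, and
  the reported SE is doubled with it (t and p are unaffected).  Negative
  $\gamma$ indicates stabilizing, positive disruptive selection.

Cross-product terms $z_i z_j$ are excluded by default — the quadratic model
uses only linear and pure squared terms — though `fit_quadratic()` operates
on whatever design the caller standardizes, so correlational selection can
be explored by extending the matrix.

Pollinator-mediated selection per trait is
$\Delta\beta_{poll} = \beta_C - \beta_{HP}$ (likewise
$\Delta\gamma_{poll}$) with standard error
$\sqrt{SE_C^2 + SE_{HP}^2}$, since the two arms are disjoint sets of
plants.  A normal $z = \Delta/SE$ is attached as a descriptive guide;
formal inference about variation in selection uses the ANCOVA interaction
models below.

Multicollinearity among traits is screened with variance inflation factors,
$VIF_j = 1/(1 - R^2_j)$, computed for every linear and squared term;
values $\ge 5$ are flagged in the gradient tables and in the pipeline
report but never silently acted on.

## Hypothesis tests

`factorial_anova()` fits the full factorial model of a
(log10-transformed) trait or fitness component on the design factors, with
sequential (Type I) sums of squares by default — matching the convention of
base R's `anova()` — and Type III available because the field cell sizes
are unbalanced.  On balanced designs the two coincide (a property the test
suite checks).

`ancova_selection_variation()` pools all cells after within-cell
standardization and relativization, and fits relative fitness on the trait
covariates fully crossed with the design factors and pollination.
Significant trait $\times$ factor $\times$ pollination interactions
indicate that pollinator-mediated selection differs across that factor.
Standardizing within cells first is the default because it matches the
per-cell gradient analyses; a `global` mode is provided since the pooled
model could also be read as using one common standardization.

`strength_anova()` takes the absolute gradients ($|\beta_C|$,
$|\Delta\beta_{poll}|$, …) assembled by `strength_table()` and tests
whether the *strength* of selection differs among factor levels.

Variance homogeneity, which the factorial ANOVA assumes, can be checked
with `variance_homogeneity()` (Levene's test); it is reported as a
diagnostic only.

## What the generator emulates — and what it does not

`sim_config()`/`simulate_experiment()` reproduce the statistical structure
the estimators assume, cell by cell:

* Traits are multivariate normal with the published per-cell means and SDs
  (`design_moments()`), under an exchangeable correlation of 0.3 among the
  generated traits.  No trait correlation matrix was reported for the
  field data, so 0.3 — a moderate value typical of floral display traits —
  is a free parameter of the generator, and recovery tests treat it as
  such.  Flowering start and duration are drawn jointly and the end date
  derived, so `duration = end - start` holds exactly.  Count-like traits
  (flowers per plant) are rounded Gaussians floored at 1 rather than
  Poisson draws, because the published mean-SD pairs are incompatible with
  equidispersion and matching moments matters more here than distributional
  purity.
* Expected seed set follows
  $\mu(z) = B\,(1 + \sum_j \beta_j z_j + \tfrac{1}{2}\sum_j \gamma_{jj} z_j^2)$,
  floored at a small positive value, multiplied by the pollen-limitation
  retention factor for C plants, and realized as a negative-binomial count
  (size 2.5, chosen so the seeds-per-plant SD is comparable to its mean as
  in the field data; a gamma-mixed Poisson, since the published dispersion
  rules out pure Poisson).  Fruit number is drawn from its cell moments and
  seeds per fruit defined by division, so the accounting identity
  `seeds_per_plant = fruit_production * seeds_per_fruit` is exact.
* When the published moments parameterize a cell, its baseline *is* the
  published seeds-per-plant mean, so pollen limitation is already embodied
  in the C-cell baselines and `pl_intensity` stays 1.  When a scalar
  baseline is supplied (the usual choice for calibration studies),
  `pl_intensity` injects a known PL equal to `1 - pl_intensity`.
* Optional per-cell dropout emulates pre-fruiting mortality, as seen in
  the common-garden experiment; it is off by default.

The generator does **not** model pollinator behaviour, spatial arrangement,
weather, or the genetic architecture of the traits.  Passing recovery tests
therefore shows that the estimators are correct and calibrated *under the
stated sampling model*, not that the field data meet that model.

### The positivity assumption, made explicit

The linear selection surface can go negative for extreme phenotypes; an
expected count cannot.  The generator floors expected fitness at a small
positive value and warns whenever more than 10% of a cell is floored.  In
that truncated regime the estimable quantity is the OLS projection of the
*floored* surface, which is attenuated relative to the injected
$\beta$ — a property of the design, not a bug in the estimator, and the
test suite verifies the fit against a large-n projection oracle there.
Calibration studies (CI coverage, contrast recovery) therefore use mild
gradient configurations (combined $|\beta| \lesssim 0.4$) for which the
surface is positive for $\gtrsim 98\%$ of plants and t-based CIs retain
their nominal coverage; with steep surfaces the induced heteroscedasticity
and truncation push coverage visibly below nominal, which is exactly the
regime practitioners should not interpret OLS standard errors in.

## Numerical and design choices

* Standardization uses the $n-1$ sample SD; zero-seed plants are **kept**
  by default (relative fitness 0), since discarding them would overstate
  fitness and the choice belongs to the analysis, not the file reader.
  The policy is recorded in every gradient table.
* The pollen-limitation CI is a percentile bootstrap with independent
  resampling of the two arms (2,000 iterations by default), seeded and
  reproducible, built on the stratified machinery of the `boot` package.
  Percentile is the default because it is the simplest defensible choice;
  replicates whose resampled HP mean is zero are dropped and counted, with
  a warning past 1%.
* Contrasts are only formed between cells that match on every key except
  pollination; cross-cell contrasts raise an error rather than being
  silently aligned.
* Sequential SS components must add to the total SS (asserted in tests to
  1e-8 relative); VIFs of perfectly collinear columns are reported as
  `Inf` and flagged, not clipped.

## Problem sizes used in validation

The package's statistical validation uses: oracle equivalence on 50 random
instances ($n \le 30$, 2–6 traits, tolerance 1e-10); CI coverage over 200
simulated cells of $n = 500$; contrast recovery at $n = 2000$ per arm;
bootstrap coverage over 200 outer replicates of $n = 500$ per arm with
2,000 iterations each; and null calibration of the ANCOVA interactions and
contrast z-statistics over 500 replicates of the full two-site design.
These sizes give Monte-Carlo error comfortably inside the asserted bands
while keeping the whole suite in the low minutes on a single core.

## A minimal run

```{r example, eval = FALSE}
out <- tempfile("demo")
rep <- run_pipeline(list(input = "exp1_default", out_dir = out,
                         n_boot = 2000, seed = 1))
sapply(rep$pollen_limitation, function(x) x$estimate)
rep$contrasts[["low_water_2019"]]
```

## Known limitations

* Fitness is seeds per plant only; decomposing selection into fruit set
  versus seeds per fruit is out of scope.
* The quadratic model omits cross-product (correlational) gradients by
  default, mirroring the linear-plus-squared specification.
* The ANCOVA's within-cell standardization is one of two defensible
  readings of the pooled model; both are implemented, and the choice is
  recorded in the table attributes.
* Published F statistics from the original field data are not
  reproducible without those data; the machinery is validated against
  known-truth simulations and brute-force oracles instead.
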