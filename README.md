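# floralsel

Phenotypic selection analysis for supplemental hand-pollination
experiments: selection gradients on floral traits, the pollinator-mediated
selection contrast, pollen limitation with bootstrap confidence intervals,
and tests for variation in selection across sites, years and nutrient
treatments.

## The problem

Pollinators exert selection on floral traits, but so does everything else a
plant experiences.  The standard way to separate the two is to randomize
plants to **open pollination** (C, natural pollinator service) or
**supplemental hand pollination** (HP, every flower saturated with outcross
pollen so fitness no longer depends on pollinators).  Within each analysis
cell the package estimates, in the Lande–Arnold multiple-regression
tradition:

- **directional gradients** β<sub>i</sub> — OLS coefficients of relative
  fitness (seeds per plant over the cell mean) on traits standardized to
  mean 0, variance 1 within the cell;
- **quadratic gradients** γ<sub>ii</sub> — twice the fitted coefficient of
  z<sub>i</sub>² in the linear-plus-squared model (negative = stabilizing,
  positive = disruptive), with SE doubled alongside;
- **pollinator-mediated selection** Δβ<sub>poll</sub> = β<sub>C</sub> −
  β<sub>HP</sub> with propagated SE √(SE<sub>C</sub>² + SE<sub>HP</sub>²);
- **pollen limitation** PL = 1 − (mean C seeds / mean HP seeds), with a
  seeded percentile-bootstrap CI (2,000 iterations, arms resampled
  independently);
- **ANOVA / ANCOVA machinery** — full-factorial tests on log10-transformed
  traits and fitness, trait × factor × pollination interaction tests for
  variation in selection, and ANOVAs on |gradient| for variation in the
  *strength* of selection.  VIFs screen every model for multicollinearity.

Two field layouts are built in: a two-site × two-year factorial (sites
differing in soil water content) and a nutrient-addition common garden
(0/0.5/1% N-P-K × pollination).  A synthetic-data generator
(`sim_config()`, `simulate_experiment()`, `make_fixture()`) reproduces both
designs cell by cell from the published trait and seed-set moments
(`design_moments()`), with injectable true selection surfaces and
pollen-limitation intensity, so every estimator is validated against known
truth.

## Worked example

Selection in the 2019 low-water site of the simulated two-site experiment:

```r
library(floralsel)
sim  <- make_fixture("exp1_default")            # published cell sizes & moments
cell <- subset(sim$records, site == "low_water" & year == 2019)

dC <- standardize_cell(subset(cell, pollination == "C"), trait_spec("exp1"),
                       cell = list(site = "low_water", year = 2019, pollination = "C"))
gC <- fit_directional(dC)
print(gC, digits = 3)
#>                 trait estimate std_error t_statistic p_value  vif
#> 1  flowering_duration  -0.2493    0.0947      -2.632  0.0107 1.25
#> 2        plant_height   0.1623    0.0965       1.681  0.0977 1.30
#> 3           n_flowers   0.1079    0.0950       1.136  0.2604 1.26
#> 4        corolla_size   0.0483    0.1012       0.477  0.6347 1.43
#> 5   corolla_tube_size  -0.0343    0.0952      -0.360  0.7198 1.26
#> 6 corolla_tube_length   0.0681    0.1007       0.676  0.5016 1.41
```

Each `estimate` is the change in relative fitness per SD of trait; here a
one-SD longer flowering duration predicts a 25% drop in relative fitness
(p = 0.011), and all VIFs are far below the flag threshold of 5.  The
pollinator-mediated component and the pollen-limitation index for the same
cell pair:

```r
gH <- fit_directional(standardize_cell(subset(cell, pollination == "HP"),
        trait_spec("exp1"),
        cell = list(site = "low_water", year = 2019, pollination = "HP")))
contrast_gradients(gC, gH)   # delta = beta_C - beta_HP, SE propagated

pl_bootstrap(subset(cell, pollination == "C")$seeds_per_plant,
             subset(cell, pollination == "HP")$seeds_per_plant,
             n_boot = 2000, seed = 1)
#> Pollen limitation: 0.477  [0.346, 0.582] (95% percentile CI, 2000 reps; n_C = 70, n_HP = 71)
```

About half the potential seed set in this simulated cell is lost to
inadequate pollination.  `run_pipeline()` chains all of the above —
gradients, contrasts, PL, ANOVA/ANCOVA, strength tests — from one config
and writes every table plus a JSON report and a hash manifest:

```r
rep <- run_pipeline(list(input = "exp1_default", out_dir = "out", seed = 1))
```

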