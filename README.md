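# critweight

Statistical estimation of the **critical weight** checkpoint in insect
larvae from starvation-response experiments.

In *Drosophila* (and holometabolous insects generally), critical weight is
the nutritional checkpoint after which starvation no longer delays the
onset of metamorphosis. Experimentally it is located by starving
carefully staged third-instar larvae at a series of ages (hours after L3
ecdysis, "AL3E", typically on a 2-hr collection grid) and recording each
larva's time from starvation onset to pupariation. The package is for
researchers running such experiments: it turns the per-larva tables into
breakpoint estimates with resampling-based uncertainty, group
comparisons, and the standard companion analyses (relative qPCR
quantification, time-course letter displays).

## The model

Time to pupariation $t$ against age at starvation $a$ follows a continuous
two-segment (hinge) regression

$$ t = \beta_0 + \beta_1 a + \beta_2 \max(0,\, a - \tau) + \varepsilon, $$

whose join $\tau$ is the age at critical weight: before $\tau$ the
starvation delay declines (slope $\beta_1 < 0$), after it the response is
flat or even falls ($\beta_1 + \beta_2 \approx 0$; the second slope is
deliberately unconstrained). For each candidate $\tau$ the coefficients
are the exact OLS solution; $\tau$ minimises the residual sum of squares
over a dense 0.01-hr candidate lattice. A per-group linear growth curve
(mass on age during feeding) converts $\tau$ to a mass at critical weight.
Uncertainty comes from a case bootstrap of larvae (stratified within age
class; percentile intervals, 1000 replicates by convention), and groups
are compared with age-stratified permutation tests on the breakpoint age
or mass, with the add-one p-value rule.

## Worked example

Everything below runs offline on a synthetic cohort whose generative
model — hinge at 9 hr AL3E, 2-hr design, Gaussian noise — is part of the
package (`synthetic_config()`).

```r
library(critweight)

cfg    <- synthetic_config(tau_true = 9, noise_sd = 2, n_per_age = 25, seed = 1)
cohort <- simulate_starvation_cohort(cfg, group = "ctrl", seed = 1)
growth <- simulate_growth(cfg, group = "ctrl", seed = 2)

fit <- fit_bisegmental(cohort)
fit
#> Bi-segmental (hinge) regression [ctrl]
#>   breakpoint (age at critical weight): 9.37 hr AL3E
#>   pre-breakpoint slope: -1.509 hr/hr, post-breakpoint slope: 0.05453 hr/hr
#>   n = 325 (excluded non-pupariating: 0), RSS = 1197

est <- bootstrap_critical_weight(cohort, growth_fit = fit_growth_curve(growth),
                                 n_boot = 1000, seed = 3)
est
#> Critical weight estimate [ctrl]
#>   age : 9.37 hr AL3E  (95% CI 8.82 - 9.94)
#>   mass: 1.552 mg       (95% CI 1.508 - 1.597)
#>   1000 bootstrap datasets (0 failed refits), seed 3
```

The cohort was generated with its breakpoint at 9 hr: the fit recovers
9.37 hr with a 95% CI covering the truth, a pre-breakpoint slope near the
configured −1.5 hr/hr, and a flat plateau. The mass line maps the
breakpoint to 1.55 mg. Comparing against a cohort whose checkpoint sits
4 hr later:

```r
late <- simulate_starvation_cohort(synthetic_config(tau_true = 13, seed = 4),
                                   group = "late", seed = 4)
permute_critical_weight(cohort, late, n_perm = 999, seed = 5)
#> Permutation test on age at critical weight (ctrl vs late)
#>   observed difference: -3.340 hr
#>   p = 0.001  (0 of 999 permutations as extreme, add-one rule; seed 5)
```

Real tables enter through `read_starvation_table()` / `read_growth_table()`
(CSV, user-mappable column schema; larvae that died before pupariating are
retained, flagged, excluded from fits and counted). qPCR Ct tables go
through `relative_expression()` (comparative-Ct against an internal
control and calibrator), and hormone or expression time courses through
`windowed_letter_groups()` (Welch-t comparisons within a sliding ±2-hr
window, compact letter display). A command-line front end wrapping these
functions is installed at `inst/cli/critweight.R` (subcommands `fit`,
`compare`, `simulate`, `qpcr`, `letters`).

See `vignettes/critical-weight-methods.Rmd` for the full account of the
model, the search, the resampling schemes and the synthetic world's
assumptions.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline end-to-end from scratch: it simulates a control
cohort and growth table under the stated synthetic world, fits the hinge
regression, bootstraps the age/mass confidence intervals, runs a
permutation comparison against a shifted cohort, and exercises the qPCR
normalisation and letter display, then writes the JSON report to `--out`.
All randomness derives from `--seed`.
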