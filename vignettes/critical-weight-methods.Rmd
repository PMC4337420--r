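---
title: "Estimating critical weight from starvation-response experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating critical weight from starvation-response experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critweight)
```

## The problem

Holometabolous larvae commit to metamorphosis at a nutritional checkpoint
called *critical weight*. Before the checkpoint, removing food delays the
onset of pupariation — the starved larva waits; after it, starvation no
longer delays development, and larvae may even pupariate slightly early.
The checkpoint is therefore visible in a simple experiment: collect newly
moulted third-instar (L3) larvae on a 2-hr grid, transfer cohorts of known
age (hours after L3 ecdysis, "AL3E") to non-nutritive agar, and record for
each larva the time from starvation onset to pupariation.

Plotting time to pupariation against age at starvation gives a falling line
that abruptly flattens. The age at which it flattens is the *age at critical
weight*; mapped through the larval growth curve it becomes the *mass at
critical weight*. This package estimates both, with resampling-based
uncertainty, and ships the auxiliary analyses such experiments come with:
relative qPCR quantification of ecdysone-biosynthesis genes and
letter-coded comparisons of hormone or expression time courses.

## The model

For larva $i$ starved at age $a_i$ with time to pupariation $t_i$,

$$ t_i = \beta_0 + \beta_1 a_i + \beta_2\,\max(0,\, a_i - \tau) + \varepsilon_i, $$

a continuous two-segment ("hinge") line joined at the breakpoint $\tau$.
$\beta_1$ is the pre-breakpoint slope (typically near $-1$ to $-2$ hr/hr:
the delay shrinks as larvae approach the checkpoint), $\beta_1 + \beta_2$
the post-breakpoint slope (typically $\approx 0$), and $\tau$ the age at
critical weight. We use the continuous hinge rather than two unconnected
lines because only the joined model makes "the inflection point where the
relationship changes" a well-defined quantity; an unconnected-segments mode
(`disjoint = TRUE`) exists for sensitivity analysis, but on data whose
plateau continues the falling segment smoothly its split point is
ill-defined over a whole interval (the fit then reports the smallest
tied split, with a warning).

Neither slope is constrained. Cohorts fed 20-hydroxyecdysone can show a
*negative* post-breakpoint slope — delay rising and then falling — so
forcing a flat plateau would bias exactly the comparisons the method is
used for.

### How $\tau$ is searched

Given $\tau$, the three linear coefficients are an ordinary least-squares
problem; the profile $\mathrm{RSS}(\tau)$ is computed in closed form from
suffix sums, vectorised over all candidates at once. The fitted $\tau$
minimises this profile over a dense lattice at `refine_tol` resolution
(default 0.01 hr) spanning `grid_step` candidates (default every 0.5 hr)
between the 2nd-smallest and 2nd-largest observed ages, with the interior
observed ages themselves included.

Two numerical points deserve a note:

* **Why an exhaustive lattice rather than coarse search plus local
  refinement.** $\mathrm{RSS}(\tau)$ is continuous, smooth between
  consecutive data ages, but multi-modal. With irregular ages the global
  basin can be narrower than any sensible coarse spacing *and* sit inside a
  candidate interval whose endpoints both slope towards other basins, so
  refining around the best coarse candidate — or even around every coarse
  local minimum — can miss it. Because the closed-form profile evaluates
  thousands of candidates in a fraction of a millisecond, the exhaustive
  scan costs nothing and is exact to the stated resolution by construction.
* **Admissibility.** A candidate needs at least two distinct ages on each
  side. With a single age beyond $\tau$ the hinge column can chase
  individual points at the design edge and win on RSS spuriously; the
  restriction is the standard guard, and it is applied identically in the
  brute-force oracles used by the tests.

Ties in RSS (e.g. a constant response) are broken deterministically to the
smallest $\tau$, with a warning; the fit is fully reproducible given the
data and the grid settings.

### From age to mass

During feeding, L3 larvae grow approximately linearly, so a per-group OLS
line of wet mass (mg) on age (hr AL3E) converts breakpoint ages to masses:
`age_to_mass()` evaluates the line, warns when the prediction leaves the
observed feeding window (negative mass), and refuses to convert across
group labels unless explicitly overridden — each genotype gets its own
growth curve.

## Uncertainty: case bootstrap

`bootstrap_critical_weight()` resamples *larvae* (the observational unit)
with replacement, refits the hinge to each of `n_boot` replicate datasets
(the study convention is 1000), and reports percentile intervals of the
replicate breakpoints. Because ages at starvation are fixed by the
experimental design, resampling is stratified within age classes by
default, preserving the design's age coverage; `stratified = FALSE` gives
the plain case bootstrap. The mass interval maps every replicate breakpoint
through the growth line; the growth fit is held fixed by default (only the
starvation data are resampled), with `resample_growth = TRUE` providing
joint resampling for users who want growth-curve uncertainty propagated.

Replicates whose refit fails (degenerate resampled designs) are dropped and
counted; more than 20% failures aborts with an unstable-estimate error
rather than reporting an interval built on a fragile resampling
distribution. The percentile endpoints are expanded, in the rare cases it
is needed, to bracket the point estimate, so the reported triple is always
ordered.

## Comparing groups: permutation test

`permute_critical_weight()` tests the null of equal age (or mass) at
critical weight by pooling the two cohorts and re-assigning group labels at
random — within matched age classes by default, preserving each group's per
class size, since both groups share the 2-hr starvation design. Both
pseudo-groups are refit and the difference in the statistic recorded;
two-sided extremeness uses absolute differences and the add-one rule
$p = (n_{\text{as extreme}} + 1)/(n_{\text{perm}} + 1)$, so $p$ is never
zero. For the mass statistic each pseudo-group is mapped through the growth
curve of the label it carries, the fits held fixed. No multiplicity
correction is applied across group pairs; the letter conventions reported
in this field are raw pairwise decisions, and correcting them is the
caller's choice.

## Relative qPCR quantification

`relative_expression()` implements the comparative-Ct convention with the
amplification efficiency fixed at 2 (no efficiency calibration is
attempted). Per replicate, $\Delta Ct = Ct_{\text{target}} -
Ct_{\text{reference}}$ against the internal control measured on the same
sample (e.g. *RpL3*), and the raw relative quantity is $2^{-\Delta Ct}$.
The calibrator condition (e.g. the control genotype at 0 hr) is fixed at 1.
Two averaging conventions exist for that fixing: dividing by the
calibrator's mean *raw quantity* (the default, `average = "linear"`) makes
the calibrator's arithmetic mean exactly 1 — matching the convention of
reporting the calibrator's value *as* 1 — whereas subtracting the
calibrator's mean $\Delta Ct$ in the exponent (`average = "ct"`, the
classical form) fixes its geometric mean instead. The two agree whenever
calibrator replicates are identical, and differ by Jensen's gap otherwise.
Both are shift-invariant: adding a constant to target and reference Ct
together changes nothing.

## Time-course letter displays

Hormone titres and expression time courses are summarised by the
convention "points sharing a letter are statistically indistinguishable at
the time ±2 hr". `windowed_letter_groups()` reads this as a *sliding
window*: cell means (one cell per group × time, ≥2 replicates) are compared
by Welch's t-test only when they belong to the same group and lie within
`window` hours of each other, or to different groups at the same time;
`all_pairs = TRUE` compares everything. Letters come from the
insert-and-absorb compact-letter-display algorithm, which guarantees the
two defining invariants — significant pairs never share a letter, compared
non-significant pairs always share one — and is deterministic given the
cell ordering (groups, then times). Welch's t is an assumption: the
original reports do not state the underlying test. No correction is applied
to the pairwise p-values by default (`p_adjust = "holm"` is available).

## The synthetic world

`synthetic_config()` states the generative model the estimator assumes:

| parameter | default | meaning |
|---|---|---|
| `tau_true` | 9 hr AL3E | breakpoint (age at critical weight) |
| `intercept_true` | 47.5 hr | expected delay when starved at ecdysis |
| `pre_slope` | −1.5 hr/hr | decline of the delay before the breakpoint |
| `post_slope` | 0 hr/hr | plateau after the breakpoint |
| `noise_sd` | 2 hr | residual SD (Gaussian truncated at 0) |
| `age_grid` | 0, 2, …, 24 hr | the 2-hr collection design |
| `n_per_age` | 25 | larvae starved per age class |
| `growth_intercept`, `growth_slope` | 0.8 mg, 0.08 mg/hr | feeding-period growth line |
| `growth_noise_sd` | 0.05 mg | weighing scatter |

These defaults are *illustrative*, chosen once to look like a plausible
wild-type cohort — the plateau sits near 34 hr (pupariation roughly 32–36
hr after starvation onset past critical weight) and masses run from
0.8 mg at ecdysis to ≈2.7 mg at 24 hr — not calibrated to any deposited
dataset. The qPCR generator holds the reference gene stable and writes the
fold-change trajectory into the target Ct as $-\log_2(\text{fold})$;
an optional lognormal noise mode supports skew sensitivity analyses.

What the generator does *not* emulate: replicate collection plates (no
blocking factor — whether the original analyses pooled plates is unknown),
larvae that die before pupariating (real tables carry them; the fits
exclude and count them), age-dependent variance, and qPCR efficiency
drift. A green test suite therefore establishes that the estimator and its
resampling inference behave correctly *when the hinge-with-Gaussian-noise
world holds*, with coverage, type-I error and power at their nominal rates
in that world; it does not validate the biological model on real cohorts.

## Degenerate inputs and edge cases

* Fewer than 6 larvae, or fewer than 4 distinct ages: typed errors.
* Constant response: flat RSS profile, smallest-τ tie-break, warning.
* Non-pupariating larvae (`ttp = NA` on input): retained in the table,
  flagged, excluded from fits, and counted in every fit report — their time
  to pupariation is undefined, and silent dropping would make exclusions
  unauditable.
* Ages are accepted off the 2-hr grid unless the caller declares a grid
  (`age_grid =` in `read_starvation_table()`), in which case off-grid ages
  are errors.
* CI levels are percentile-based; widening the level never narrows the
  interval on the same replicate set.

## Known limitations

Single breakpoint only (no multi-phase models); no BCa or studentised
intervals; no robust-regression variants; Welch-t letter decisions are an
assumption; the growth conversion is strictly linear. The headline analyses
of the motivating experimental literature (e.g. a wild-type breakpoint
reported at 8.66 hr AL3E) rest on deposited cohort data not shipped here;
this package reproduces the *method*, and its tests certify it on the
synthetic world above.
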