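---
title: "Site form estimation: models, design choices and the synthetic calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site form estimation: models, design choices and the synthetic calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siteform)
```

## The site-form approach

Site quality grading by the classical site index needs stand age, which is
unavailable or meaningless in uneven-aged multispecies forests. The site
form (SF) substitutes the height–diameter relationship: the expected
(mean) dominant height at a **reference diameter**. The package estimates
SF three ways and then asks the two questions any productivity index must
answer — does it track volume production, and is it independent of stand
density?

All curves are built on the Schumacher model

$$h = 1.3 + e^{\beta_0 + \beta_1 / dbh},$$

with $h$ in metres above ground (1.3 m is breast height), $dbh$ in cm, and
$\beta_1 < 0$ for an increasing curve with asymptote $1.3 + e^{\beta_0}$.
Its two *difference forms* project an observed state $(H_1, D_1)$ to a
target diameter:

* **ADA** frees one site-specific parameter (the intercept cancels):
  $H_2 = 1.3 + (H_1 - 1.3)\, e^{-\beta_1/D_2} / e^{-\beta_1/D_1}$, with
  $\beta_1 > 0$ in this parameterisation.
* **GADA** lets both asymptote and shape vary with site through
  $X_0 = \dfrac{\ln(H_1 - 1.3) - \beta_0/D_1}{1 + \beta_1/D_1}$, giving
  $H_2 = 1.3 + e^{X_0 + (\beta_0 + \beta_1 X_0)/D_2}$.

Both forms are self-referencing ($D_2 = D_1$ returns $H_1$ exactly) and
path-invariant (projecting through an intermediate diameter equals the
direct projection); the test suite verifies both identities to $10^{-9}$
absolute over $10^4$ random in-domain states. The GADA form is singular
where $1 + \beta_1/D_1 = 0$; the code refuses such states, and the
identity tests draw states away from the singularity and inside the
forest height range (1.31–100 m), because in floating point the
$\pm 1.3$ breast-height shift loses all precision when an intermediate
projection lands within micrometres of 1.3 m or at astronomical heights.

## Dominant trees and the nine SF variants

Dominants are the `per_ha` (default 100) tallest or thickest trees per
hectare, regardless of species, restricted to trees present, alive and
measured in **every** inventory. The quota is
`round(per_ha × area / 10 000)` — 25 on the 2 500 m² plots the package is
calibrated to, where the rounding rule is immaterial. Two choices the
selection rule leaves open were fixed as follows:

* **Ranking inventory.** Size ranks come from the *first* inventory, so
  the dominant set is one fixed cohort over the whole study period. This
  is the reading most consistent with restricting candidates to trees
  re-measured alive throughout; re-ranking each inventory would let the
  set drift.
* **Ties and shortfalls.** Ties on the criterion variable break by the
  other size variable, then by tree id, making selection stable under
  input order. A plot with fewer eligible trees than the quota keeps all
  of them and carries a shortfall flag rather than being dropped, so
  small or sparse plots stay analysable and downstream consumers can
  filter on the flag.

Per plot-period the pipeline emits nine SF records: SF_H-D (project each
dominant's pair individually, then average) × {ADA, GADA} × {tallest,
thickest}; SF_MH-MD (project the plot-mean pair) on the same 2 × 2 grid;
and SF_h-dbh (the plot's own fitted curve evaluated at the reference
diameter). SF_H-D and SF_MH-MD differ in general because the projection
is nonlinear in diameter — the Jensen gap is itself a fixture in the test
suite. SF values are attached to the *start* inventory of each period so
they pair naturally with the increment (PAI) observed over that period.

## Fitting

**Plot curves.** The base curve is linear in $\ln(h - 1.3)$ versus
$1/dbh$, so plot fits start from that exact linearisation and refine by
`nls` (port algorithm), falling back to Levenberg–Marquardt. At least four
height-measured live trees and a non-degenerate diameter spread are
required; all-equal diameters raise an unidentifiability error. Trees with
missing heights are excluded from fitting (and reported by the validator);
heights at or below 1.3 m are rejected at construction.

**Difference models** are fitted by nonlinear least squares on the
observed second heights of remeasurement pairs (consecutive inventories
only). Conditioning on the observed state $(H_1, D_1)$ absorbs most
plot/tree heterogeneity, which is why the fixed (marginal) curve is an
adequate estimand here; a full nonlinear mixed model with autocorrelated
residuals is out of scope by design. An optional two-stage refinement
re-fits the ADA parameter per unit and shrinks it toward the pooled
estimate with a prior weight of four pseudo-pairs — unit-level curves
without mixed-model machinery.

Numerically, the ADA objective is one-dimensional, so it is minimised by
a deterministic scan over 120 log-spaced values of $\beta_1$ between 0.2
and 800 cm followed by `optimize()` refinement (tolerance $10^{-10}$),
widening once if the optimum sits on the scan boundary. The exponential-
in-$1/D$ family has flat likelihood regions, so GADA uses multi-start
Levenberg–Marquardt over a 5 × 5 grid of starts (plus a positive-$\beta_1$
start), keeps converged fits clear of the $\beta_1 = -D_1$ singularity,
and returns the best residual sum of squares. Degenerate pair sets (all
$D_2 = D_1$) are unidentifiable and rejected; pairs with shrinking
diameters are dropped with a count.

**Fit statistics** follow the adjusted-$R^2$ and RMSE conventions with
$n - p$ degrees of freedom, $p$ being the fixed-curve parameter count
(1 for ADA, 2 for GADA, 2 for plot curves and the evaluation
regressions); the relative error RE is the RMSE as a percentage of the
mean observed response.

## Reference diameter

The reference diameter trades familiarity (a common diameter) against
precision. The package profiles RE across diameter classes (default grid
10–60 cm in 5 cm steps, class width 5 cm) and selects the smallest grid
diameter whose RE is within 5 % of the minimum — an algorithmic encoding
of "choose where the error curve flattens". Classes with too few
observations are excluded with a warning. The default reference diameter
is 40 cm and is overridable everywhere. The binning scheme is a documented
interpretation; the profile is reported so users can inspect the curve
rather than trust the plateau rule blindly.

## Stand metrics and evaluation

Stand attributes per plot-inventory use live trees only: density $N$,
basal area $G$, quadratic mean diameter $D_q$, Reineke's
$SDI = N (D_q/25.4)^{1.605}$, species count, conifer proportion, and
volume from the two-term allometry $v = a_0\,dbh^{a_1} h^{a_2} +
a_3\,dbh^2$ with species-keyed coefficients falling back to group-level
rows (the lookup is total by construction). PAI is the survivor-only
per-hectare volume increment divided by the period length: trees dead at
either end of a period and ingrowth trees contribute nothing, because the
increment of a remeasured cohort is the quantity the difference models
describe; mortality and ingrowth terms would need assumptions the data do
not support. PAI is additive over any partition of a plot's trees, which
the tests exploit.

Evaluation correlates and regresses each SF variant against
$\sqrt{PAI}$ (productivity) and $\sqrt{SDI}$ (density), pooled over
plot-periods and stratified into four conifer-proportion mixture levels.
The strata use exact half-open intervals $[0, 0.25], (0.25, 0.5],
(0.5, 0.75], (0.75, 1]$ rather than the two-decimal labels sometimes
printed for them. Regression diagnostics include a Shapiro–Wilk test on
residuals (subsampled to 5 000 if ever larger, the test's domain).
Empty strata yield unavailable rows, not errors.

## The synthetic stand generator

`generate_forest()` emulates the data structure of permanent-plot
networks in temperate uneven-aged pine–oak forest: 2 500 m² plots, all
trees with dbh ≥ 7.5 cm measured, two to three inventories five years
apart, right-skewed diameter distributions, and species mixtures spanning
pure broadleaf to pure conifer. Its defaults are the package's study
conditions:

| parameter | default | units | rationale |
|---|---|---|---|
| `n_plots` | 100 | – | enough plots for stable correlations at desk scale |
| `area_m2` | 2500 | m² | the plot size the pipeline is calibrated to |
| `trees_per_plot` | 40 | – | 160 stems/ha, inside the observed density band of such networks |
| `dbh_shape`, `dbh_scale` | 1.3, 13 | –, cm | Weibull shape < 2 gives the right skew; mean dbh ≈ 18 cm after truncation at 7.5 |
| `beta0_mean`, `beta1_true` | 3.3, −22 | –, cm | asymptote ≈ 28 m, realistic mid-size heights |
| `site_effect_sd` | 0.15 | – | plot-level offset on $\beta_0$; ≈ ±30 % asymptote spread |
| `height_noise_sd` | 1.5 | m | hypsometer + tree-form scatter |
| `inc_mean`, `inc_cv` | 1.8, 0.5 | cm/period, – | Gamma diameter increments |
| `pai_coupling` | 1 | – | mean increment scales with $e^{s}$: better sites grow faster |
| `mortality_rate` | 0 | /period | survivor-only PAI logic is tested separately |

Every draw flows from one seed, so datasets are bit-reproducible.
Heights follow the plot's true curve plus noise, so the ADA/GADA
assumptions hold by construction and parameter recovery is a meaningful
test. A truth table (site effect, true curve, realized conifer share) is
returned for alignment checks.

What the generator does **not** emulate: spatial structure and
competition, climate covariates, species-specific height curves, crown
variables, and measurement-protocol artefacts (heaping, observer bias).
Tests passing on synthetic stands therefore certify the estimators and
pipeline mechanics, not the field behaviour of SF in any particular
forest.

**Recovery-simulation designs.** The Monte-Carlo recovery checks draw
remeasurement pairs with $D_1 \sim U(12, 70)$ cm, five-year increments
$U(2, 12)$ cm, and (for GADA) observed heights $H_1 \sim U(6, 40)$ m with
the site variable implied by the true curve family — states inside the
diameter and height spans such inventories actually record. These designs
are frozen; the fitted parameters and noise levels in the checks are the
published parameter scale of the models.

**The decoupled (null) configuration.** Checking that the SF–PAI
correlation test holds its nominal size requires SF and PAI to be truly
independent under the null — and that is subtler than switching the
growth coupling off. Both statistics are computed from the same inventory:
shared height measurements enter SF (through the fitted curve) and PAI
(through tree volume), and the shared diameter design enters both, so a
weak spurious dependence survives `pai_coupling = 0` and even
`site_effect_sd = 0`. The null configuration therefore severs every
channel: no site effect, no growth coupling, and a diameter-proportional
volume table ($a_1 = 1$, $a_2 = a_3 = 0$) so PAI is a function of the
independently drawn diameter increments alone. This is a statement about
the estimators worth knowing in its own right: on real inventories, SF
and PAI are never computed from disjoint data, and small correlations
between them should be interpreted with that in mind.

## Problem sizes and runtimes

The test suite and the acceptance script size their simulations for a
single CPU at desk scale: identity checks use $10^4$ state draws;
recovery uses 100 replicates of 400 pairs; site-signal recovery uses the
100-plot default calibration; the null size check uses 1 000 replicates
of a 30-plot, 12-trees-per-plot configuration, which keeps the whole
suite in the minutes range while leaving the binomial error band around
the 5 % rate at about ±2 percentage points.

## Known limitations

* The difference-model fits are marginal least squares; standard errors
  of the fitted parameters are not reported, and no autocorrelation
  correction is applied across a tree's repeated pairs.
* SF_h-dbh inherits the extrapolation risk of per-plot curves on plots
  whose diameter range ends far below the reference diameter.
* The evaluation is correlational; no causal claim about density and
  height growth is made or supported.
* Only the Schumacher base curve is implemented; the difference-form
  machinery is generic, but alternative base models are out of scope.
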