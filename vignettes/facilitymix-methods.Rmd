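---
title: "Estimating the delivery-location mix: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the delivery-location mix: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(facilitymix)
```

`facilitymix` estimates, for every country and year in a location
hierarchy, the share of live births delivered in five mutually exclusive
locations: public or non-profit hospitals, private for-profit hospitals,
public or non-profit lower-level facilities, private for-profit lower-level
facilities, and outside health facilities. This vignette documents the
statistical model, the assumptions behind each stage, the parameters a user
might want to change, and what the accompanying synthetic world does and
does not demonstrate.

## From survey responses to analysable data

Survey instruments word delivery locations inconsistently ("government
hospital", "CHU", "health post", "clinic", "at home", ...). The
categorisation stage maps each response option onto three axes — facility
status, level, ownership sector — through an ordered rulebook applied
first-match-wins after case and whitespace folding. The rulebook is a JSON
data file, not code: country-specific knowledge (e.g. that "polyclinic"
denotes a hospital-level facility in a particular system) belongs in its
override table, which is consulted before the generic rules. The terminal
fallback maps anything unrecognised to `unknown`, so classification never
fails.

Two structural choices matter here:

* **Hospitals are defined by capability, not by name.** A hospital is a
  facility able to provide comprehensive emergency obstetric and neonatal
  care — caesarean delivery and blood transfusion. This motivates the
  caesarean-sorting step: an option whose name cannot be resolved to a
  level is assigned the level whose pooled caesarean rate (computed from
  the resolved options of the same source) is strictly nearest to its own.
  Ties go to `unknown_level`, and options with fewer than
  `csec_min_count = 25` weighted births are never sorted — below that the
  observed caesarean rate is too noisy to be evidence of capability. Note
  that sorting is all-or-nothing: when an ambiguous option genuinely mixes
  levels, sorting misallocates its minority share, an error that does not
  shrink with sample size. The alternative path (leaving the option
  unresolved and redistributing proportionally) is consistent but discards
  the capability signal; both are available via `use_csec_sorting`.
* **The private non-profit sector is merged with the public sector.**
  Non-profit facility births are a small share nearly everywhere and
  resemble the public sector in cost and quality, so modelling carries a
  single `public_nfp` sector.

Completeness of the categorised data decides model inclusion: a
location-year enters the four level-and-sector models only if at least 85%
of its facility births carry both level and sector, and the two level-only
models only if at least 95% carry the level. Both thresholds are inclusive
(`>=`) and configurable via `inclusion_thresholds()`.

## Tabulation, redistribution and the model scale

Proportions are tabulated per (country, source, birth year): a survey with
a five-year recall window contributes up to five separate data points,
which keeps within-survey birth-year structure visible to the model and
matches how multi-survey time series are usually assembled. Facility births
with unknown level are reallocated to hospital/lower in proportion to the
known level masses of the same cell (each retaining its sector); unknown
sector mass within each level is then reallocated proportionally across
sectors. Redistribution conserves facility mass exactly. When a cell has no
known mass in a redistribution group, the country's pooled shares from its
other sources stand in; if none exist the mass stays unknown, is dropped
from the affected indicators, and a warning is logged.

Sampling uncertainty uses the Kish effective sample size
$n_\mathrm{eff} = (\sum w)^2 / \sum w^2$ and the binomial variance
$p(1-p)/n_\mathrm{eff}$. Cluster designs are not observed in the synthetic
inputs, so no design effect beyond Kish weighting is modelled; a
multiplicative `variance_inflation` factor (default 1) is exposed for users
who know their sources are more variable.

Modelling happens on the logit scale, which keeps every back-transformed
estimate inside $(0,1)$ and makes the Gaussian assumptions of the later
stages more tenable for shares near the boundaries. Proportions are clamped
into $[c, 1-c]$ before the transform. The clamp exists only to keep the
transform and the variance finite for empty categories, so its default is
deliberately tiny, $c = 10^{-4}$: category shares of a fraction of a
percent are genuinely common in this problem (private lower-level facility
shares sit below 1% in many country-years), and any clamp large enough to
touch real observations censors them upward and produces overconfident,
systematically high estimates for exactly those small categories. At
$c = 10^{-4}$ only exact zeros hit the clamp, and the delta-method variance
$\mathrm{var}(y) = \mathrm{var}(p)/(p(1-p))^2$ then makes such observations
appropriately uninformative rather than silently biased. `offset` is
configurable everywhere it appears.

## Three-stage spatiotemporal Gaussian process regression

Each of the six indicators is modelled independently over the full
country-year grid.

**Stage 1 — covariate ensemble.** All covariate subsets up to `max_covs`
(default 2) plus an intercept-only model are fitted as linear mixed-effects
models with nested random intercepts for super-region, region and country
(`lme4`). Predictions for any country use the deepest random effects it has
data for, falling back to zero for unseen groups. Each specification's
out-of-sample RMSE comes from cross-validation whose folds partition
*sources*, never rows — the five birth-years of one survey always stay in
one fold, since they share survey-level idiosyncrasies and would otherwise
leak. Ensemble weights are proportional to inverse RMSE, which rewards
predictive covariates without making the result hostage to any single
specification.

**Stage 2 — space-time residual smoothing.** The data residuals from the
stage-1 prediction are smoothed onto every country-year with weights
$\omega = w_t \times w_s$. Time weights follow
$w_t = (1 - (\Delta t/(1+\Delta t_{\max}))^{\lambda})^3$ with
$\lambda = 0.5$, where $\Delta t_{\max}$ is the largest gap between the
prediction year and any visible data year; the cubing concentrates weight
on nearby years while never letting the weight vanish inside the observed
range. Space weights give the country's own data a share $\zeta = 0.9$,
other countries of the same region $\zeta(1-\zeta)$, and the rest of the
super-region $\zeta(1-\zeta)^2$, with each tier's mass split equally among
the countries contributing data in it. A country with no visible data
keeps its stage-1 series unchanged.

**Stage 3 — Gaussian process.** Per country, the final series is the
posterior of a Gaussian process with prior mean equal to the stage-2
series, a Matérn-5/2 kernel over years with length-scale $\ell = 5$ — long
enough to borrow strength across a recall window, short enough to track
decade-scale shifts in the delivery mix — and independent Gaussian noise
equal to each datum's delta-method sampling variance. The kernel amplitude
$\eta$ is estimated per region as $1.4826 \times \mathrm{MAD}$ of the
stage-2 minus stage-1 differences (a robust proxy for how much the prior
had to move to meet the data), multiplied by `gp_amplitude_mult` (default
1) and floored at 0.05 on the logit scale so the prior never collapses to
certainty in data-free regions. Pooling the amplitude by region stabilises
it for countries with little data while letting data-rich regions differ.

Uncertainty propagates by draws: `n_draws` multivariate-normal samples of
the posterior (eigendecomposition, negative eigenvalues clipped at zero,
with an explicit error if the covariance is materially non-PSD), inverse
logit back to proportions. Every random step — fold assignment, each
country's draws, every generator component — derives its own sub-stream
seed from the root seed and a named key, so results are reproducible and
insensitive to the order in which steps run.

## Raking, aggregation, and change decomposition

The modelled indicators are internally consistent only approximately; the
externally supplied in-facility envelope (consumed as draws) defines the
binding total. Raking is multiplicative in proportion space and draw by
draw: hospital and lower-level shares are scaled so their sum equals the
envelope — which defines hospital and lower-level envelopes — then the
sector components are scaled within each level envelope. Multiplicative
scaling preserves zeros and the relative mix, and raking already-consistent
components is the identity. Degenerate cells are pinned: a zero envelope
zeroes the components; zero components under a positive envelope split it
equally with a logged warning. The non-facility share is one minus the
envelope, so the five categories sum to one by construction, per draw. If
an envelope arrives as means only, draws are replicated constant and the
replication is flagged — the resulting intervals then understate envelope
uncertainty.

Regional, super-regional and global series are births-weighted means of the
country draws; aggregation always happens on draws, never on summaries,
because quantiles do not commute with averaging. Summaries report the draw
mean and the empirical 2.5th/97.5th percentiles with linear interpolation
between order statistics (`stats::quantile` type 7) — the interpolation
rule is pinned because reproducibility across implementations depends on
it. The 1995→2023 change decomposition computes, per draw, each facility
category's percentage-point change and its share of the total facility
change; draws where the facility share moved by at most $10^{-6}$ are
excluded from the share summary (the ratio is unstable there) and counted.

## The synthetic world

`simulate_world()` generates the study conditions all pipeline-level tests
run under: 2 super-regions × 2 regions × 5 countries (20 countries) over
1995–2023; 3 surveys per country of 2000 births each, interviewed at evenly
spaced years from 2001 to 2023, each covering the five preceding birth
years; 2% of facility births receive level-ambiguous labels and 7%
sector-ambiguous labels (the average unknown-level and unknown-sector
shares seen in harmonised multi-survey delivery data); caesarean rates of
15% in hospitals versus 3% in lower-level facilities, so level is
identifiable from capability; log-normal survey weights; and an envelope
supplied as the true in-facility share perturbed with logit-normal noise
(sd 0.05), mimicking its status as an externally estimated input.

True compositions are softmaxes of logistic latent trends with region- and
country-level random shifts, so they are valid and smooth by construction,
with facility delivery rising strongly over the period and public hospitals
absorbing most of the rise. Covariates are monotone transforms of the true
facility latent plus country-level noise that is smooth in time (an
intercept and a linear drift): real development indicators evolve slowly,
and covariate noise that jitters independently year-to-year would hand the
stage-1 ensemble a jaggedness no real covariate has, violating the temporal
smoothness the GP prior assumes.

What passing the pipeline tests on this world shows: the stages compose
correctly, the estimator tracks a smooth truth through realistic label
noise, partial information and multi-survey sampling error, and the
draw-based intervals are approximately calibrated under the generator's
assumptions. What it does not show: robustness to cluster sampling designs,
recall or self-report bias, response options that change meaning over time,
conflicting administrative sources, or envelope error that is biased rather
than mean-zero — none of which the generator emulates.

## Numerical and design choices

* Clamp offset $c = 10^{-4}$ (see above); all stages share one value.
* Caesarean sorting: nearest comparator, tie (within $10^{-12}$, guarding
  floating-point noise) → `unknown_level`, minimum 25 weighted births.
* Cross-survey harmonisation is an explicit country-override table, not an
  automatic inference: in practice that reconciliation is expert-driven,
  and an override file keeps it auditable.
* GP linear algebra uses Cholesky solves with one retry after adding
  $10^{-10}$ jitter; failure after the retry is an error, not a silent fix.
* The mixed-model stage drops random-effect terms whose grouping factor has
  fewer than two observed levels (ordinary least squares when none remain),
  which keeps small cross-validation folds fittable.
* Ensemble RMSE of exactly zero (possible on noiseless test data) gives
  those specifications all the weight, split equally.
* Problem sizes in the shipped tests: most checks run on a tiny world
  (8 countries, 2 surveys × 600 births, 20–30 draws); the recovery check
  runs the full default world with 100 draws, enough for stable 2.5th/97.5th
  percentiles while keeping the suite quick on one CPU.
* The command-line interface (`inst/cli/facilitymix`) is a thin wrapper
  over the exported functions; `simulate`, `categorize` and `prep` operate
  incrementally on a shared output directory, while the modelling
  subcommands delegate to `run_all()`, whose determinism makes re-running
  earlier stages free of surprises.

## Limitations

Indicators are modelled independently and reconciled only by raking, so
cross-indicator correlation in the posterior is induced, not estimated.
The GP prior mean is itself built from the data (stages 1–2), a pragmatic
empirical-Bayes shortcut standard in this family of estimators; it can
make intervals somewhat narrow where data are dense. Country-years whose
data fail the inclusion thresholds contribute nothing to the failing
models, even though partial information exists. The smoothing
hyperparameters ($\lambda$, $\zeta$, $\ell$) are fixed defaults, not
cross-validated. And the acceptance of the method rests on synthetic
evidence: real survey microdata carry biases the generator does not
emulate.
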