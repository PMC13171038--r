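---
title: "Modelling neurointerventionalist capacity and EVT access"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling neurointerventionalist capacity and EVT access}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evtgap)
```

## The problem

Endovascular thrombectomy (EVT) is first-line treatment for large-vessel
occlusion ischaemic stroke, yet uptake across Europe spans two orders of
magnitude — from well below 1% to roughly 15% of ischaemic-stroke patients.
A key structural constraint is the supply of neurointerventionalists:
physicians trained in a neuro-specialty who perform the procedure. `evtgap`
implements a country-level (ecological) analysis chain that links the
neurointerventionalist workforce to EVT rates and stroke outcomes:

1. rank correlations between workforce *density* (practitioners per million
   inhabitants) and EVT rates, mortality, DALYs and YLDs, with Fisher-z
   confidence intervals;
2. within-country trend analyses driven by a cumulative *expertise index*;
3. inversion of the fitted density–EVT model into a per-country workforce
   *gap*, optionally adjusted for GDP per capita;
4. a log-linear counterfactual of mortality if all countries reached a 15%
   EVT rate.

Everything operates on a validated country-year panel (`evt_panel`). Because
the underlying survey data are not publicly deposited, the package ships a
synthetic-panel generator that reproduces the *statistical structure* of the
study, so every stage is exercisable and testable end to end.

All associations are descriptive. Country-level mortality reflects many
interacting system factors; nothing here adjusts for confounders or
estimates causal effects.

## The data model

A panel row is one (country, year) observation: ISO-3166 alpha-3 code,
calendar year, the count of practising neurointerventionalists (`n_nir`),
population, the EVT rate as a percent of ischaemic strokes treated,
and optional outcome and context fields (mortality, DALY and YLD rates per
100,000 from burden-of-disease sources; GDP per capita in current US $;
IVT rate; 24-h EVT centre count; weekly work hours). Density is always
derived as `n_nir * 1e6 / population`, never stored, so the two raw fields
stay the single source of truth. Validation is strict: duplicate
(country, year) keys, rates outside [0, 100], non-positive populations or
out-of-window years are hard errors naming the offending row and column;
empty CSV cells and literal `NA` both normalise to one missing marker.
Countries below 100,000 inhabitants are dropped at load (with a warning),
since microstates distort per-million comparisons.

`complete_cases()` encodes the inclusion rule used throughout: a country
enters an analysis only if every required variable is observed in every
required year (the trend and gap analyses use 2020–2022 by default). The
filter is idempotent, and widening the required years can only shrink the
admitted country set.

## Association statistics

The headline association is the Spearman correlation between density and
EVT rate over pooled country-years. Confidence intervals use the Fisher
z-transformation: with $z = \operatorname{atanh}\rho$ and standard error
$1/\sqrt{n-3}$,

$$ \mathrm{CI} = \tanh\!\left(z \pm \frac{z_{1-\alpha/2}}{\sqrt{n-3}}\right). $$

We deliberately use the plain $1/\sqrt{n-3}$ error rather than the
Spearman-specific variance inflation $\sqrt{1+\rho^2/2}$: back-calculation
shows the published intervals of the source analyses are internally
consistent with the plain form at a single sample size per analysis, and
`implied_n()` makes that reconstruction reproducible — it grid-searches
integers $n \in [5, 500]$ for the value whose interval endpoint best matches
a printed bound (ties to the smaller $n$, no-solution error beyond 0.05).
P-values use the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom, which
matches the published values to two significant figures.

```{r}
n <- implied_n(0.507, 0.719)
n
round(fisher_ci(0.507, n), 3)
signif(spearman_p(0.507, n), 2)
```

Complete-case deletion is pairwise (per variable pair), not listwise, and
ties receive midranks. Internal precision is full double; rounding happens
only at presentation.

## The expertise index and trend analyses

Procedural volume per operator is not systematically available across
Europe, so within-country trends use an assumption-based proxy for
accumulated experience. The index for country $c$ starts at

$$ E_{c,t_0} = \frac{d_{c,t_0}}{\max_{c'} d_{c',t_0}} $$

(first-year density relative to the best-supplied country) and evolves as

$$ E_{c,t} = \mathrm{clamp}\left(E_{c,t-1} + \beta_0 + \beta_1 \Delta N_{c,t},\; 0,\; 1\right) $$

with base learning rate $\beta_0 = 0.005$ per year and $\beta_1 = 0.001$
per additional practitioner recruited that year ($\Delta N$ is the change
in the *absolute head count*, not in density — recruiting one person adds
the same experience increment in a small or a large country). The ceiling
of 1 is part of the index's definition; the floor of 0 is our design
choice, letting workforce attrition erode the index without ever producing
a negative value. $\beta_0$ and $\beta_1$ are fixed constants of the proxy,
not estimated from data. Countries entering the panel after the first year
are excluded (the initialisation is defined only at $t_0$), as are years
after a gap in a country's series.

Effective supply is density times the index. Both effective supply and EVT
rate are standardised to within-country z-scores, which makes the trend
estimates invariant to per-country affine rescalings of either series.
Two estimators capture within-country dynamics:

* `first_diff_regression()` pools year-over-year changes (consecutive years
  only) and fits OLS of $\Delta z_{\text{rate}}$ on $\Delta z_{\text{eff}}$,
  with an intercept by default (differencing already removes country
  effects; the intercept absorbs any common drift — drop it with
  `intercept = FALSE` as a sensitivity check);
* `fixed_effects_fit()` is the within estimator: country-demeaned OLS,
  numerically identical to country-dummy regression, with HC1
  heteroskedasticity-robust standard errors in which the absorbed country
  effects are counted in the degrees-of-freedom correction. Classical SEs
  are kept for the pooled first-difference model.

## The workforce gap

The benchmark EVT rate is the maximum observed national rate (about 15% in
the source setting); the 15% policy target can be imposed explicitly via
`benchmark_rate(panel, override = 15)`. `fit_gap_model()` fits

$$ \text{EVT}_i = a + b\, d_i \,[+\, c\, \text{GDPpc}_i] + \varepsilon_i $$

and `needed_density()` solves it for the density that would deliver the
benchmark at each country's own GDP per capita:
$d^\* = (\text{target} - a - c\,\text{GDPpc})/b$. The inversion is refused
when $b \le 0$, where a workforce target is meaningless. The per-million
gap is $\max(0, d^\* - d)$ — countries above the needed density report
zero, though the raw $d^\*$ is preserved for diagnostics — and headcounts
round *up* (`ceiling(gap * population / 1e6)`): a fractional person cannot
staff a call rota. "Current" density defaults to each country's latest
usable year. Both the unadjusted and GDP-adjusted models are always
computed and labelled; which one a reader should prefer depends on whether
economic constraints are treated as binding.

## The mortality counterfactual

`fit_log_linear()` regresses $\log$ (natural) mortality on EVT rate over
pooled complete country-years. With slope $\gamma$, moving a country from
its observed rate $e$ to target $T$ multiplies predicted mortality by
$\exp(\gamma (T - e))$, so

$$ \text{relative reduction} = 1 - \exp(\gamma\,(T - e)) $$

when $e < T$ and $\gamma < 0$, and exactly 0 otherwise — the projection
reports reductions only, and a country already at the target has no
headroom. The baseline is each country's *observed* rate (not its fitted
value), because the projection is displayed per country. A base-10 log
would rescale $\gamma$ but leave the reductions unchanged. Mortality
enters as the GBD-convention rate per 100,000; the fit pools all complete
country-years, while the projection uses each country's latest observed
EVT rate.

## The synthetic generator

`generate_panel()` emulates the study conditions: 25 countries over
2020–2024; populations log-uniform on [0.5M, 80M]; GDP per capita
log-uniform on [4,000, 90,000]; first-year densities uniform on
[0.3, 7.5] per million; head counts growing by Poisson(2) per year; EVT
rates linear in density (intercept 2.5, slope 1.17) with Normal(0, 1.5)
noise, clipped to [0, 100] rather than redrawn (the clipping fraction is
reported so tests can require it to be negligible); mortality log-linear
in EVT rate (intercept 4.0 on the log scale, slope −0.05, noise SD 0.15);
DALY and YLD as noisy 20× and 3× multiples of mortality. The paper-facing
coefficients are the published point estimates; the noise SDs are our
choice, set so the pooled density–EVT regression has an $R^2$ in the
reported neighbourhood at survey-like sample sizes. One RNG stream is
seeded once per panel and sub-draws are consumed in a documented fixed
order, so identical seeds give identical panels even across refactorings.
Missingness is MCAR per outcome cell, which suffices to exercise the
completeness filter; real missingness is country-structured, so passing
recovery tests on MCAR panels says nothing about informative missingness.
The generator does not attempt real country names, GBD uncertainty
intervals, saturation at high density, or serially correlated noise —
recovery results on synthetic panels demonstrate correctness of the
estimators, not validity of the linear model on real data.

## Numerical choices

* Presentation rounds half away from zero to 3 decimals; all internal
  computation is full double precision.
* `gap_table()` zeroes per-million gaps below $10^{-9}$ so floating-point
  dust from an exactly-saturated country can never become a headcount of 1.
* The report bundle (`run_full_analysis()`) serialises floats at 6
  significant digits, which makes byte-identical reproduction across
  platforms achievable; the manifest records the seed, config and MD5
  checksums of every output (its timestamp sits outside the checksummed
  payload).
* Degenerate inputs fail loudly and early: zero rank variance, rank
  deficiency (naming the collinear columns), single-country fixed effects,
  all-zero first-year densities, non-positive mortality under the log
  model.

## Problem sizes used in the test suite

Parameter-recovery checks run 100 seeds of 200-country single-year panels
for the OLS slope and log-linear slope (each required to land within 3
estimated SEs of truth in at least 95 runs), and 100 replicates of the
11-country, 3-year first-difference design with a generating standardised
slope of 0.8. These sizes give the recovery statistics enough precision to
be meaningful while keeping the default suite quick on a single CPU.

## Limitations

Ecological associations carry no individual-level interpretation; the
expertise index is an exploratory proxy with fixed, untested learning-rate
constants; the gap inversion extrapolates a linear fit beyond the observed
density range for low-capacity countries; and the counterfactual assumes
the pooled cross-sectional mortality association would hold under
intervention, which it need not.
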