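---
title: "Models and methods behind nitromit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nitromit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitromit)
```

`nitromit` chains five models: a response-ratio meta-analysis of field
trials, a regional cropland nitrogen mass balance, an emission-factor
abatement model, a monetization layer with Monte-Carlo uncertainty, and a
tiered scenario projection. This vignette explains each model, its
assumptions, the tunable parameters, and the design choices we made where
the methodology left the design open.

## Effect estimation

The estimand for every measure-by-outcome cell is the mean log response
ratio ln r = ln(x̄_t/x̄_c), reported as the percentage change
(r − 1) × 100. We analyse on the log scale because ratios of positive
fluxes are multiplicative: the transform symmetrizes increases and
decreases and the back-transform can never report a change below −100%.
Records with non-positive means are excluded (with a logged warning)
rather than imputed — the ratio is undefined for them.

Effects are **unweighted** means over observations. Field studies
frequently omit variances and replication counts, so inverse-variance
weighting would silently drop a large share of the evidence; the cost is
that precise and imprecise studies count equally, which the confidence
interval partially absorbs.

Confidence intervals come from a nonparametric bootstrap over individual
observations, 4,999 iterations by default. Two variants are implemented:
the default bias-corrected percentile interval and the plain percentile
interval (`ci_type = "percentile"`). The resampling unit is the
observation, not the study, because observations are pooled in the
database; study-level clustering is a known limitation (see below). An
effect is declared *significant* when the interval excludes zero — a
zero-overlap rule whose empirical type-I error `bootstrap_calibration()`
measures at roughly 5–7% for 50 observations per cell.

Numerical details that matter for reproducibility: the log ratios are
sorted before resampling, so the estimate is exactly invariant to row
order; the resample stream is exactly `sample.int(n, n * n_boot,
replace = TRUE)` after `set.seed(seed)`, so an independent implementation
can reproduce the intervals bit-for-bit; the bias-correction factor uses a
continuity split on ties and is clamped to (0, 1) so it stays finite when
nearly all resample means coincide. Cells with one observation or zero
spread collapse to a zero-width interval and are flagged `degenerate`.

Efficacies for the mitigation stage are η = −(percent change)/100 on each
loss pathway, clipped to [0, 1]. Clipping at zero means a
pollution-*increasing* effect never becomes a negative efficacy; such
trade-offs are surfaced separately (the `"tradeoffs"` attribute of
`efficacy_from_effects()`) so they are visible rather than silently
subtracted.

## Nitrogen mass balance

A regional budget has five inputs (fertilizer, manure, biological
fixation, deposition, irrigation water) and four output classes (harvest,
gaseous emission split into NH₃/N₂O/NOₓ/N₂, leaching, runoff), all in
kt N/yr; NUE is harvest over total input. There is no soil-stock term:
input–output closure is a *convention of the synthetic generator*, not a
law we impose on user data — real budgets may legitimately not close
(soil mining or accumulation), so `validate_tables()` flags non-closure as
a warning, never an error. N₂ is stored alongside the reactive gases but
treated separately throughout: its reduction saves fertilizer yet is not
an environmental improvement, so it never enters the monetized benefit.

## Abatement model

The abated flux is ΔE = A · EF · η · X. When no explicit emission-factor
table is given, `activity_from_budget()` derives EF as baseline flux over
activity, which makes A · EF reproduce the baseline exactly — the
decomposition then only matters when users supply their own factors.

Combining measures required three design decisions the methodology leaves
open:

* **Interactions.** Measure pairs with jointly measured efficacy replace
  the sum of their individual terms by the joint efficacy applied at the
  *larger* of the two adoption rates (the joint experiment reflects both
  practices; using the larger rate avoids double-counting the overlap
  while not discarding the wider-adopted measure's coverage). Pairs not in
  the interaction table combine additively, reflecting how sparse the
  evidence on interactions is. The per-pathway abated fraction is capped
  at 1, so no reduction can exceed its baseline flux.
* **Priority order.** Not all measures are needed once a region reaches
  its NUE target, so measures are added in ascending tier (cheap and easy
  first), then descending standalone reduction, until the post-mitigation
  NUE reaches the target. The ordering is our choice; it is deterministic
  and is validated against a brute-force evaluation of the same rules in
  the tests.
* **Fertilizer clamp.** The reduction identity
  ΔN_fer = ΔN_input + ΔN_man − ΔN_dep can exceed the baseline fertilizer
  use. The default caps ΔN_fer at N_fer (post-mitigation fertilizer
  floored at zero), which preserves mass-balance coherence; the literal
  alternative — zeroing the reduction entirely — is available as
  `strict = TRUE`, at the price of discarding that region's saving.

Deposition falls in proportion to the reduction in reactive gaseous
emissions; when no fraction is supplied, each region's baseline
deposition-to-gas ratio (capped at 1) is used, which makes the aggregate
feedback self-consistent with the baseline. Manure recycling increases are
bounded by the production potential and the cropland carrying capacity.
Yield effects multiply harvested N directly (constant N concentration
assumed), applied on the adopted fraction of each measure and capped at
the target harvest. When the fertilizer clamp binds, the post-mitigation
budget no longer closes; the region is flagged (`fer_clamped`) rather
than rebalanced.

## Monetization and uncertainty

All monetization is linear in its physical input: implementation cost
ΔE · UC; ecosystem benefit via benefit transfer of US-reference unit
damage costs scaled by WTP and per-capita-GDP ratios; health and climate
benefits via per-region unit costs; yield benefit via the crop price.
Climate unit costs are signed: N₂O abatement warms the ledger positively
while NH₃/NOₓ reductions remove a cooling aerosol effect and can turn the
climate term negative. The societal benefit is exactly the four-component
sum, in every Monte-Carlo draw. All values are constant 2017 USD; there is
no discounting because the account is single-year.

Two ambiguities are resolved as follows and flagged here prominently:
the *integrated* unit abatement cost of a measure mix is treated as a
per-region scalar applied to the total abated mass (a ΔE-weighted
composition is what a GAINS-style cost curve would produce); and
fertilizer savings are kept separate from UC — both the gross cost and the
net cost (gross minus savings) are reported, with benefit-to-cost ratios
on both denominators.

Uncertainty propagation is Monte Carlo, reported as mean ± 1 SD; ± ranges
in this literature are often printed without a defined propagation method,
so the definition here is explicit. Efficacies are perturbed on
their underlying log response ratio (keeping them in [0, 1)), positive
prices by relative Gaussian noise truncated at zero, signed climate costs
without truncation. Defaults: `eta_sd = 0.05`, `price_rel_sd = 0.1`,
1,000 draws.

## Scenarios

Demand (required harvest N) is exogenous — population and income dynamics
live outside the model — and identical across scenarios. Each scenario's
NUE ramps linearly from the base-year value towards the regional target,
scaled by the share of the full mitigation potential its tier package can
deliver; adoption ramps linearly from zero to the tier-filtered,
attribute-capped maximum. Linear interpolation is a choice, not a finding:
nothing in the underlying method specifies a functional form. Fertilizer
follows the reduction identity against a same-demand baseline in which all
fluxes grow proportionally with harvest. Infeasible demand (requiring
NUE > 1) halts with a diagnostic naming the region and year rather than
silently capping. The potential-share construction makes cumulative tier
packages weakly monotone: each larger package reduces surplus at least as
much as the smaller one, year by year — asserted on synthetic worlds in
the tests. Regional applicability is declarative: a rules table caps
adoption by region attributes (the default caps buffer zones at X = 0.2
where land is scarce, since buffer strips occupy cropland).

## The synthetic world

The generator emulates the statistical *structure* of the real inputs, not
their values: lognormal control means (field fluxes are positive and
right-skewed) with Gaussian noise on the log ratio, so treatment means
stay positive and the per-cell mean converges to the configured truth;
budgets that close exactly with NUE drawn from a configurable range;
economic tables with a US reference region (WTP and PGDP ratios exactly 1)
and signed climate costs. Defaults are chosen to sit where field evidence
typically sits: 17 observations per cell (≈1,500 observations over the
88-cell grid), log-ratio noise SD 0.3, loss reductions of 30–70% with
enhanced-efficiency fertilizers pinned at −47% total loss, +25% yield and
+18% NUE, NUE targets 13 points above baseline, harvest targets 20%
above baseline, and adoption rates of 0.3–0.9.

Passing tests on this world therefore demonstrate *mechanical*
correctness — estimator calibration, mass-balance closure, oracle
equivalence, identity preservation — not empirical validity for any real
region: real meta-databases have unbalanced cells, correlated
observations within studies, publication bias and heavy-tailed noise,
none of which the generator produces.

## Problem sizes and limitations

The test suite and acceptance script use deliberately scaled runs: 500
simulated meta-datasets of 50 observations for calibration (999 bootstrap
iterations each), 4,999 iterations for single-cell estimates, 500–1,000
Monte-Carlo draws on 2–8 region worlds, and 8-point scenario grids. These
sizes give stable checks (coverage bands of 92–98%, recovery within
3 SD) while keeping a full run in minutes on one CPU.

Known limitations: no study-level clustering or moderator regression in
the meta-analysis; no publication-bias diagnostics (both deliberately out
of scope); no process-based nitrogen transformation kinetics; no
crop-species resolution; adoption rates and NUE targets are inputs, not
modelled; and the economic layer transfers, rather than re-estimates, unit
damage costs.
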