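---
title: "Competing heterogeneities and apparent waning of vaccine effectiveness"
author: "mvebias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competing heterogeneities and apparent waning of vaccine effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Observational studies of acute respiratory infections routinely estimate
vaccine effectiveness as one minus a hazard ratio from a Cox model, and
routinely find that this measured effectiveness (mVE) declines over a
season.  Part of that decline can be an artifact of selection: infection
preferentially removes the most susceptible individuals from each arm, so
the survivors' average hazards drift apart even when every individual's
protection is constant.  Two population heterogeneities pull in opposite
directions:

* **baseline susceptibility (frailty)** — shared by both arms; because the
  unvaccinated arm is infected faster, its high-frailty tail is depleted
  sooner, the unvaccinated survivor hazard falls faster than the
  vaccinated one, and mVE *declines* (the classic depletion-of-susceptibles
  or "frailty" effect);
* **vaccine response** — present only in the vaccinated arm; the least
  protected vaccinees are infected first, the vaccinated survivor pool
  becomes better protected, and mVE *rises*.

`mvebias` simulates both effects at scale, estimates mVE the way field
studies do, and predicts the drift analytically.

## Simulation model

A cohort of `n_total` agents (default 100,000, 40% vaccinated, in line
with seasonal influenza coverage) is followed for 365 days.  Agent `i`
carries a relative daily hazard `q_i` drawn — for both arms from the same
law — from Gamma(shape α~γ~, rate β~γ~), with mean α~γ~/β~γ~ and
coefficient of variation α~γ~^−1/2^.  The default mean daily hazard is
0.0025/day, giving a ~60% one-year attack rate among the unvaccinated in
the homogeneous case; homogeneous-risk scenarios pin every `q_i` at that
value.  Protection is leaky: on day `t` a not-yet-infected agent is
infected with probability `1 − exp(−q_i (1 − VE_i(t)))`, with
`VE_i(t) = 0` for the unvaccinated, and infection is sterilizing for the
rest of the season.  The force of infection is an external constant —
no transmission feedback, waves, seasonality, or contact structure.

We use `p = 1 − exp(−h)` rather than `p = h` for the daily Bernoulli
step so that heavy-tailed frailty draws (Gamma(0.2, 80) produces rare
very large hazards) still yield valid probabilities; at typical hazards
the two differ only in the third decimal.  For time-constant hazards the
infection day then has exactly the distribution `ceiling(E/h)` with
`E ~ Exp(1)`, which is how `run_epidemic()` samples those scenarios
(time-varying, antibody-derived protection uses an explicit day loop).
Every random draw comes from a purpose-labelled sub-stream of one master
seed (`substream_seed()`), so changing the protection law does not
perturb the frailty draws and every artifact is byte-reproducible.

## Estimating measured VE

`fit_tvi()` estimates mVE with the estimator used in the waning
literature: a Cox partial likelihood in which each record is split at
time-category boundaries (counting-process form) and the only covariates
are vaccine-by-category interactions, so each category gets its own log
hazard ratio and `mVE = 1 − exp(β)`.  The default scheme is monthly —
eleven 30-day categories plus a final 35-day category covering
(330, 365] — chosen to match the resolution visible in published mVE
step plots; it is configurable.  Ties are handled with the Efron
approximation, the standard recommendation when event times are whole
days and heavily tied.  Internally, censored intervals that are
identical across agents are aggregated with integer case weights (exact,
because risk-set sums are weight-linear), while event rows stay
individual because the Efron correction steps through tied deaths one at
a time; the aggregated fit matches a naive full-split `coxph()` fit to
~1e-13 and is ~30× faster.  "End-of-season mVE" always means the final
category's estimate, averaged over replicates.

## Selection theory

If individual hazards are constant in time, the mean hazard among
survivors is an exponentially tilted expectation, and writing `K` for
the cumulant generating function of `−R` gives `−r̄(t) = K′(t)`: the
n-th derivative of `−r̄` is the (n+1)-th cumulant of the survivor
distribution (for n = 1, the variance — a generalization of Fisher's
fundamental theorem of natural selection).  Applying the quotient rule
to `HR = r̄_v/r̄_u` yields

$$\frac{d}{dt}HR = \frac{-\sigma_v^2\,\bar r_u + \sigma_u^2\,\bar r_v}{\bar r_u^2},$$

implemented in `hr_derivative()`.  A non-constant force of infection is
absorbed by the time rescaling `s(t) = ∫₀ᵗ FOI` (`rescale_time()`).
`predicted_hr_trajectory()` evaluates `r̄` and `σ²` for each arm's
hazard law — gamma conjugacy in closed form (`α/(β+t)` for the
survivor mean), one-dimensional adaptive quadrature (relative tolerance
1e-10, via `stats::integrate`) for the beta-mixture laws — and returns
`HR(t)` and the predicted mVE on a daily grid.

**The sign rule.**  For independent Gamma(α~γ~, β~γ~) frailty and
Beta(α~β~, β~β~) protection, substituting the time-0 moments into the
derivative above (with `w = 1 − VE`) gives

$$\mathrm{sign}\,HR'(0) \;=\; \mathrm{sign}\!\big(V_q\,E[w(1-w)] - \mu_q^2\,V_w\big)
 \;=\; \mathrm{sign}(\alpha_\beta + \beta_\beta - \alpha_\gamma),$$

since `V_q/μ_q² = 1/α_γ` and `E[w(1−w)]/V_w = α_β + β_β`.  The boundary
sits at α~γ~ = α~β~ + β~β~; smaller α~γ~ (stronger frailty
heterogeneity) or larger α~β~ + β~β~ (weaker protection heterogeneity)
makes HR rise, i.e. mVE fall.  This direction convention is forced by
consistency: it reproduces the leaky limit (Beta(c, c) with c → ∞ must
give rising HR, as the scaled-gamma closed form
`HR(t) = (1−v)(β+t)/(β+(1−v)t)` shows), and it agrees with brute-force
Monte Carlo of the tilted means and with finite differences of the
quadrature trajectory in every sampled parameter triple (a
property-style test checks 50 random triples away from the boundary).

## Antibody waning and the two protection maps

To model *real* waning on top of selection, each vaccinee's antibody
titre follows the power law `Ab(t) = C[(t+41)/42]^{−1}` (fast waning;
all vaccinees are fully vaccinated before day 0, so study time is the
same point on every curve) with `ln C` normal with SD 0.75–1.5.
Titre maps to instantaneous protection in two ways:

* **risk-correlate**: `1 − VE = min(Ab^e, 1)` with `e = −0.5` by default
  (the `−0.35` variant estimated from HAI titres alone is available as a
  configuration);
* **within-host stochastic extinction**: the closed-form probability
  that an inoculum (`m = 0.5` expected founders, virion death rate
  `a = 10`, cell-level `R0 = 10`) establishes infection as neutralizing
  antibody `k·Ab` rises.

`calibrate_protection_scale()` fixes each map's free scale — the
lognormal location for the risk-correlate map; `k` for the within-host
map, whose scale is confounded with the location, pinned at 0 — so the
population mean initial VE is 90% at ln-SD 1, using 64-node
Gauss–Hermite quadrature over `ln C` (deterministic, idempotent to
<1e-6, cross-checked against Monte Carlo in the tests).  The calibrated
scale is then held fixed as the SD varies, so mean initial VE drifts
slightly with SD — a property of the design, not a bug.  We calibrate
once per map kind, not per SD level, matching the single stated
calibration convention.  Note that with these default parameters the
within-host map wanes substantially faster over a season (mean VE 0.90 →
~0.44) than the risk-correlate map (0.90 → ~0.69); the two maps agree
qualitatively, not quantitatively.

## Scenario pipeline and the offset statistic

`run_scenario()` wires the pieces together per replicate and
`grid_run()` sweeps antibody-SD by frailty-CoV cells for one or both
maps.  Frailty CoV levels follow contact-survey estimates (0.5–1, grid
default {0, 0.5, 1}); antibody SD levels follow serology (0.75–1.5,
grid default {0, 0.75, 1.5}), the zero levels being the
no-heterogeneity marginals.  For each cell the end-of-season deficit is
`Δ = VE_NE(end) − mVE(end)`, where VE_NE — the no-epidemic mean
efficacy — is averaged over the final category's days to match the mVE
readout window, and the offset percentage of a both-heterogeneity cell
is `100(Δ_frailty-only − Δ_both)/Δ_frailty-only` against the SD = 0
cell at the same CoV and map (0 = no offset, 100 = deficit cancelled,
>100 = overshoot).  The headline summary is the median offset over
both-heterogeneity cells pooled across the two maps; per-map medians
are attached because the two maps differ markedly (the within-host
map's faster waning produces systematically larger offsets, roughly
doubling the pooled median relative to the risk-correlate map alone).

## Sizing, defaults and numerical choices

* Cohort 100,000 / 40% vaccinated / 365 days everywhere; these are the
  study conditions, not tuning knobs.
* Replicates: 20 throughout, for single scenarios and per grid cell
  (end-of-season mVE then has a Monte-Carlo standard error of
  ~0.2–0.5 pp; the offset percentages, being ratios of small deltas,
  need this precision for their median to stabilize).
* Vaccinated-count rounding: `round()` (half-to-even) of
  fraction × n.
* Quadrature: `stats::integrate` at relative tolerance 1e-10 for the
  beta-mixture laws; 64 Gauss–Hermite nodes for lognormal expectations.
* Finite differences (tests only, never in reported outputs): central
  stencils with step scaled to the derivative order, since third-order
  differences of `r̄` at 1e-4 steps would be pure round-off.
* Degenerate inputs: zero FOI gives an all-censored table; categories
  with zero events in either arm are flagged `NA` with a warning rather
  than silently dropped; `sample_protection()` refuses the antibody kind
  (whose per-agent parameter is a titre scale, not a VE).

## What the generator does and does not show

The synthetic cohorts deliberately contain *only* the two
heterogeneities under study: no confounders, no correlation between
frailty and vaccine response, no regression toward the mean, no
transmission dynamics, and vaccination completed before day 0.  Tests
passing on these cohorts therefore demonstrate the estimator's behavior
under pure selection, not its robustness to real-world confounding; in
field data the depletion signatures shown here would be entangled with
exposure differences, prior immunity and pathogen evolution.  The
theory additionally assumes individually constant hazards, so the
analytic overlay applies to the constant-protection scenarios only; the
waning (antibody-derived) scenarios are simulation-only by design.

## Known limitations

* All-or-nothing protection is simulated but has no analytic trajectory
  (its survivor law is a two-atom mixture whose vaccinated-arm variance
  the current law set does not cover).
* The offset median depends visibly on the grid levels and on pooling
  the two maps; it should be read as a coarse summary of a strongly
  heterogeneous table, not a universal constant.
* Hazards are daily; sub-daily dynamics and event-time ties finer than
  a day are outside scope.
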