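---
title: "Decomposing regional convergence in population aging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing regional convergence in population aging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsrdecomp)
```

## The measure and the model

Population aging is tracked through the total support ratio,
$\mathrm{TSR} = W/\mathrm{NW}$: the working-age population (completed ages
in $[15, 65)$) over everyone else. It is the inverse of the total
dependency ratio; the margins are configurable (`working_age_bounds()`)
because raising either retirement or school-leaving ages is a live policy
question, but the defaults reproduce the conventional definition.

The change over an interval decomposes in two exact steps.

**Step 1 — symmetric two-factor split.** With subscripts 1, 2 for the
interval endpoints,
$$
\mathrm{TSR}_2 - \mathrm{TSR}_1
 = \underbrace{\tfrac12 (W_2 + W_1)\left(\tfrac1{\mathrm{NW}_2} -
   \tfrac1{\mathrm{NW}_1}\right)}_{nw}
 + \underbrace{\tfrac12 \left(\tfrac1{\mathrm{NW}_2} +
   \tfrac1{\mathrm{NW}_1}\right)(W_2 - W_1)}_{w}.
$$
This is the standard symmetric decomposition of a change in a ratio into
numerator and denominator contributions; the two terms sum to the total
algebraically, which the code asserts at `1e-12` relative tolerance on all
inputs. A caveat inherent to the method: a change in $W$ also moves the
first term (through the $W_2 + W_1$ factor). On simulated panels this
secondary channel stays below ~5% of the total change on average
(tested in `test-decomposition.R`); it cannot be removed without giving up
exact additivity.

**Step 2 — demographic balance at working ages.** From
$W_2 = W_1 + \mathrm{CT} + M_W - D_W$, with $h = \tfrac12(1/\mathrm{NW}_2 +
1/\mathrm{NW}_1)$,
$$
w = h\,\mathrm{CT} + h\,M_W - h\,D_W = ct + mg + mt .
$$
Cohort turnover $\mathrm{CT}$ is the count aged 14 minus the count aged 64
at each interval start, summed over sub-years — entrants about to join the
working ages minus leavers about to exit. Deaths among those specific
persons are deliberately not netted out of CT, and $D_W$ counts events in
the period rectangle $[15, 65)$: any Lexis slack lands in the residual
term. One balance term is always derived as the residual — net migration
in `"observed"` mode (migration records are unreliable where deaths are
registered) or deaths in `"projected"` mode (projections supply migration
assumptions) — so the balance closes exactly by construction in both modes.

**Convergence.** Unit-weighted cross-sectional OLS of the change on the
initial level: $\Delta\mathrm{TSR}_i = \alpha + \beta\,\mathrm{TSR}_{i,0} +
\varepsilon_i$. $\beta < 0$ is beta convergence. Unit weighting is the
default because the question is about regions as statistical units;
population weights are available (`weights`, `--weights pop`) but change
the question. Convergence is classified by the sign of the point estimate
alone — standard errors are reported, and `classify(..., significance =
TRUE)` adds a 95% CI flag, but significance never gates the bookkeeping.

Because OLS is linear in the response and every partial regression shares
the regressor, the partial slopes satisfy $\beta_{nw} + \beta_w = \beta_g$
and $\beta_{ct} + \beta_{mg} + \beta_{mt} = \beta_w$ exactly, and yearly
slopes within a decade (all on the decade-initial TSR) sum to the pooled
decade slope. These are identities, not approximations; the tests assert
them at `1e-10` absolute.

### A definitional choice in the temporal decomposition

The decade-pooled beta per component is defined as the regression of the
per-region *sum of yearly component changes* on the decade-initial TSR.
For the total change $g$ this coincides with the endpoint definition
(yearly changes telescope); for the Das Gupta terms it does not, because
the two-factor weights differ between a decade-long interval and its
sub-years. Only the summed-yearly definition makes within-decade beta
additivity exact, so it is the one used; the endpoint-only multi-year
decomposition remains available through `decompose_change()` with a
multi-year interval. Cumulative convergence curves are running sums of
yearly betas across the whole study period; the regressor resets at decade
boundaries, which the output records (`regressor_year`), so cumulative
values spanning resets are descriptive, not a single regression.

## What the simulator emulates

`generate_scenario()` runs a one-sex cohort-component projection per
region: deaths first from January-1 stocks ($D = qP$), then net migration
($M = mP$, truncated so removals never exceed occupancy), then aging;
births $\sum_a f(a) P(a)$ form the next age-0 stock and the terminal group
pools its survivors. Stocks are real-valued and stochasticity enters only
through seeded region-level lognormal rate perturbations (mean 1, sd
`noise_sd`), never event-level sampling — this is what makes the balance
identity exact and the residual modes testable against truth.

Flows are recorded by the **age reached during the interval** (the
Eurostat convention for events): the cohort aged $a$ on January 1 appears
at recorded age $a + 1$. Under this labeling the period rectangle
$[15, 65)$ corresponds exactly to the cohorts aged 14–63 at the interval
start, and the residual-mode estimates reproduce simulator truth to
`1e-9` for every region-interval. Under start-age labeling they would not
(the mismatch is the slack the residual absorbs on real data).

The default scenario (`inst/extdata/default_scenario.toml`; four clusters
of 50 regions, 2003–2043, projected from 2013) encodes the stylized world
the analysis assumes:

* **east**: 2.5× working-age mortality, a 1950–1980 boom wave (×1.30) and
  a pronounced 1990s bust cohort (×0.55), net out-migration with a −0.009
  rate shock in 2008. The boom-in-working-ages / bust-in-childhood
  combination gives east the highest initial TSR (~2.7 vs ~2.0), and its
  subsequent fall — bust cohorts entering working ages, boom cohorts
  retiring, excess mortality — drives the convergence of the whole system.
* **west / south / north**: baseline mortality, milder boom waves,
  moderate in- or out-migration, 2008 shocks of −0.006/−0.014/+0.005.
* **projected regime**: each region's *structural* (pre-shock) migration
  schedule converges geometrically (rate 0.5/yr) toward the all-region
  mean. Anchoring on pre-shock rates is deliberate: the crisis shock is a
  transient observed-period phenomenon, and anchoring on post-shock levels
  would leave a common negative rate level whose mechanical correlation
  with TSR would manufacture a spurious migration effect in the projected
  period.

Magnitudes are chosen to be demographically plausible rather than
calibrated to any real series: Gompertz mortality ($q(x) = 1 -
e^{-a e^{bx}}$, $a = 6\times10^{-5}$, $b = 0.095$; life expectancy in the
high 70s), peak both-sex fertility rates ~0.06 per person-year (slightly
below replacement), working-age net migration rates of a few per thousand
with crisis shocks up to ±1.4%, and 8% region-level rate heterogeneity.
Regions are 20,000 persons — far smaller than real second-tier statistical
regions, which is immaterial because the TSR is scale-invariant and keeps
floating-point cancellation in the exact-balance checks far below the
`1e-9` tolerance.

What the generator does **not** emulate: two-sex dynamics, inter-region
migration matrices (net flows only), boundary changes, census revisions and
other harmonization artifacts of real regional data, or any calibration to
real series. A green test therefore establishes the correctness of the
accounting and estimation machinery and the internal consistency of the
stated world — not agreement with any published magnitude.

## Numerical choices

* Algebraic identities are asserted at `1e-12` relative, simulator
  round-trips at `1e-9`, beta additivity at `1e-10` absolute: pure
  floating-point arithmetic, no estimation error.
* The "stationary null" fixture uses mortality confined to ages 64+ with a
  region-varying level: every region is individually stationary (life-table
  initial structure, replacement fertility, no migration), the regressor
  has positive variance, and all six components are identically zero — so
  all betas vanish up to machine noise (~2e-16, asserted < 1e-12). Exact
  binary zeros are unattainable: terminal-group pooling arithmetic and the
  CSV round-trip each leave last-ulp residue.
* `ols_beta()` refuses $n < 3$ and zero-variance regressors rather than
  returning NaN; TSR with zero non-working-age population is an error, not
  infinity.
* Wave windows are inclusive birth-year intervals; a person aged $a$ on
  January 1 of the start year is assigned birth year $\mathrm{start} - a -
  1$. Overlapping windows are rejected rather than composed.
* Death probabilities are capped at 0.999 after multipliers and
  perturbations; migration removals are truncated at occupancy
  ($M \ge -(P - D)$), so counts never go negative.

## A demographic subtlety worth knowing

Raising working-age mortality does *not* unconditionally lower the TSR at
every horizon. With Gompertz-shaped mortality the excess deaths concentrate
at ages 50–64; each death removes a person from $W$ now but also removes a
future member of the 65+ population. Within a decade the working-age loss
dominates and the TSR falls; beyond roughly a decade the forgone old-age
inflow can dominate and the *total* effect reverses sign — even though the
mortality *component* $mt = -h D_W$ is negative throughout (it books the
direct working-age loss; the old-age channel shows up in $nw$). The
simulator's monotonicity test is therefore pinned at a five-year horizon,
and the initial age structure is built from the baseline (unmultiplied)
life table so that the multiplier acts on flows only — the ceteris-paribus
comparison the property requires.

## Limitations

* One-sex, single-region accounting; no migration matrix, no
  sub-population heterogeneity within a region beyond the rate
  perturbation.
* The projected-regime migration convergence is a stylized stand-in for
  trend-based projection practice, not a reconstruction of any agency's
  methodology.
* The decade-level decomposition sums CT, $M_W$, $D_W$ over sub-years
  (year-by-year stocks); computing decade turnover from decade-apart
  stocks at ages 5–14 and 55–64 would be an alternative reading and gives
  slightly different numbers.
* Cross-sectional OLS only: no spatial autocorrelation correction, no
  conditional convergence covariates, no sigma-convergence or inequality
  indices.
* The first observed year's yearly regression uses the decade-initial
  (= study-initial) TSR; where a study period starts mid-decade the choice
  of regressor baseline matters and is recorded in `regressor_year`.
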