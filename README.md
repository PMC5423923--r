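# tsrdecomp

Decomposition and beta-convergence analysis of regional population aging.

## The problem

European regions age at very different speeds, and regional cohesion policy
cares whether those differences are shrinking. `tsrdecomp` measures aging
through the **total support ratio**

```
TSR = W / NW
```

where `W` is the working-age population (ages 15–64 in completed years, the
half-open interval `[15, 65)`) and `NW` everyone younger or older — the
inverse of the total dependency ratio. The package answers two questions for
any multi-region, age-structured panel:

1. **What drives the change in each region's TSR?** The change over an
   interval is decomposed additively in two steps. First a symmetric
   two-factor (Das Gupta) split,

   ```
   TSR2 − TSR1 = [½(W2 + W1)(1/NW2 − 1/NW1)]  +  [½(1/NW2 + 1/NW1)(W2 − W1)]
                  = nw (non-working-age effect)  +  w (working-age effect)
   ```

   then, using the demographic balance at working ages
   `W2 = W1 + CT + M_W − D_W` (cohort turnover, net migration, deaths),

   ```
   w = h·CT + h·M_W − h·D_W = ct + mg + mt,     h = ½(1/NW2 + 1/NW1).
   ```

   Either net migration (`mode = "observed"`, when deaths are recorded) or
   deaths (`mode = "projected"`, when migration is assumed) is derived as
   the balance residual. Both identities hold to machine precision on every
   input — they are the package's central correctness surface.

2. **Are regions converging?** Unit-weighted cross-sectional OLS of the
   change on the initial level (**beta convergence**):

   ```
   TSR2 − TSR1 = α + β·TSR1 + ε,     β < 0  ⇒  convergence.
   ```

   Because the six components add up to the total change and every partial
   regression shares the same regressor, the partial slopes add up exactly:
   `β(nw) + β(w) = β(g)` and `β(ct) + β(mg) + β(mt) = β(w)`. The same
   linearity yields an exact temporal decomposition: yearly betas within a
   decade (all regressed on the decade-initial TSR) sum to the decade's
   pooled beta, and running sums give cumulative convergence curves.

Because the original continental data require external downloads and manual
harmonization, the package ships a **one-sex cohort-component simulator**
that generates multi-region panels with the statistical structure the
analysis assumes: labeled region clusters, cluster-specific working-age
excess mortality, demographic waves (boom and bust cohorts whose echoes
propagate through cohort turnover), observed-period migration shocks and a
projected regime in which migration rates converge across regions. The
balance identity holds exactly in its output, so the residual-estimation
modes can be verified against simulator truth.

## Worked example

```r
library(tsrdecomp)

panels <- generate_scenario(default_scenario(seed = 1))
tsr <- compute_tsr(panels$population)
agg <- aggregate(tsr ~ cluster + year, data = tsr, FUN = mean)
reshape(agg[agg$year %in% c(2003, 2013, 2043), ], idvar = "cluster",
        timevar = "year", direction = "wide")
#>   cluster tsr.2003 tsr.2013 tsr.2043
#>      east     2.73     2.06     1.82
#>     north     1.96     1.83     1.76
#>     south     2.00     2.11     1.93
#>      west     2.03     1.97     1.84
```

The "east" cluster starts with the most favorable age structure (boom
cohorts in working ages, a 1990s bust cohort still in childhood) and loses
it fastest — the engine of convergence. Decomposing one east region's
observed decade:

```r
cc <- decompose_change(panels$population, panels$deaths,
                       interval = c(2003, 2013), mode = "observed")
cc[cc$region == "east_01", c("tsr1", "tsr2", "g", "nw", "w", "ct", "mg", "mt")]
#>    tsr1  tsr2      g     nw      w      ct     mg     mt
#>    2.67  2.03 -0.644 -0.171 -0.474 -0.0223 -0.181 -0.271
```

`g = nw + w` and `w = ct + mg + mt` exactly: of this region's 0.64-point
TSR fall, 0.47 came through the working-age population, mostly excess
working-age mortality (`mt = −0.271`) and crisis out-migration.

Convergence, decomposed by component and decade:

```r
td <- temporal_decomposition(panels$population, panels$deaths, panels$migration,
        decades = list(c(2003, 2013), c(2013, 2023), c(2023, 2033), c(2033, 2043)),
        mode = c("observed", "projected", "projected", "projected"))
td
#> Beta-convergence decomposition: 4 period(s)
#>    period_start period_end          ct          g           mg         mt          nw          w
#> 1:         2003       2013 -0.12608818 -0.8408784 -0.228745679 -0.2570940 -0.22895058 -0.6119279
#> 2:         2013       2023  0.02780223  0.4667958 -0.007443411 -0.2767799  0.72321693 -0.2564211
#> 3:         2023       2033 -0.15425491 -0.2196188  0.002071165 -0.2743986  0.20696353 -0.4265823
#> 4:         2033       2043 -0.32541985 -0.6187916  0.001101700 -0.3392412  0.04476779 -0.6635594
```

Negative betas mean convergence. The mortality effect (`mt`) pushes toward
convergence in every decade and is the most stable component; migration
matters in the observed decade (shock-driven, `mg = −0.23`) but is
negligible once the projected regime converges migration rates across
regions (`mg ≈ 0.00`); cohort turnover swings with the demographic waves.
Over the full horizon the system converges strongly:

```r
t1 <- compute_tsr(panels$population[panels$population$year == 2003, ])
t2 <- compute_tsr(panels$population[panels$population$year == 2043, ])
ols_beta(t1$tsr, t2$tsr - t1$tsr, component = "g")
#> beta = -0.99947 (se 0.02177), alpha = +1.83553, R2 = 0.914, n = 200 [g] -> convergence
```

## Command line

```sh
Rscript inst/scripts/tsrdecomp run --config inst/extdata/default_scenario.toml --seed 42 --out out/
Rscript inst/scripts/tsrdecomp tsr --population out/population.csv --bounds 15:65 --out out/tsr.csv
Rscript inst/scripts/tsrdecomp decompose --population out/population.csv --deaths out/deaths.csv \
    --mode observed --period 2003:2013 --out out/components.csv
Rscript inst/scripts/tsrdecomp fixture tiny --out fixtures/
```

`run` executes the whole pipeline (simulate → tsr → decompose → converge)
and writes `population.csv`, `deaths.csv`, `migration.csv`, `tsr.csv`,
`components.csv`, `betas.csv`, `betas_cumulative.csv`, a run log and a JSON
manifest. Reruns with the same config and seed are byte-identical.

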