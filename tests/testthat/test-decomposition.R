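# Two-step decomposition: symmetric two-factor split, cohort turnover,
# balance residuals, and the component table invariants.

test_that("two-factor split matches hand arithmetic and sums exactly", {
  # TSR stays 2 -> effects cancel at +-21/110
  d <- dasgupta_two_factor(W1 = 100, NW1 = 50, W2 = 110, NW2 = 55)
  expect_equal(d$nw_effect, -21 / 110)
  expect_equal(d$w_effect, 21 / 110)
  expect_equal(d$nw_effect + d$w_effect, 0)
  # no change -> zero effects
  expect_equal(unlist(dasgupta_two_factor(100, 100, 50, 50)),
               c(nw_effect = 0, w_effect = 0))
  # pure denominator change: 2.0 -> 2.5
  d2 <- dasgupta_two_factor(W1 = 100, W2 = 100, NW1 = 50, NW2 = 40)
  expect_equal(d2$nw_effect, 0.5)
  expect_equal(d2$w_effect, 0)
  expect_error(dasgupta_two_factor(100, 100, 0, 50), "positive")
})

test_that("two-factor identity holds to 1e-12 relative on random inputs", {
  set.seed(42)
  for (i in 1:200) {
    W1 <- runif(1, 10, 1e6); W2 <- runif(1, 10, 1e6)
    NW1 <- runif(1, 10, 1e6); NW2 <- runif(1, 10, 1e6)
    d <- dasgupta_two_factor(W1, W2, NW1, NW2)
    g <- W2 / NW2 - W1 / NW1
    expect_lt(abs(d$nw_effect + d$w_effect - g), 1e-12 * max(1, abs(g)))
  }
})

test_that("cohort turnover counts entrants minus leavers from start stocks", {
  pop <- uniform_panel(years = 2000:2002)
  pop$count[pop$age == 14] <- 1200
  pop$count[pop$age == 64] <- 1000
  ct1 <- cohort_turnover(pop, c(2000, 2001))
  expect_equal(ct1$CT, 200)
  # uniform distribution -> zero turnover
  expect_equal(cohort_turnover(uniform_panel(years = 2000:2001),
                               c(2000, 2001))$CT, 0)
  # two-year interval equals the sum of the two one-year intervals
  set.seed(7)
  pop$count <- runif(nrow(pop), 50, 150)
  two <- cohort_turnover(pop, c(2000, 2002))$CT
  expect_equal(two, cohort_turnover(pop, c(2000, 2001))$CT +
                 cohort_turnover(pop, c(2001, 2002))$CT)
  expect_error(cohort_turnover(pop, c(2000, 2005)), "cover")
})

test_that("working-age deaths aggregate over the period rectangle", {
  d0 <- zero_events("r1", 2000)
  expect_equal(deaths_at_working_ages(d0, c(2000, 2001))$D_W, 0)
  d5 <- d0; d5$deaths <- 5
  expect_equal(deaths_at_working_ages(d5, c(2000, 2001))$D_W, 250)
  wide <- deaths_at_working_ages(d5, c(2000, 2001),
                                 bounds = working_age_bounds(15, 70))$D_W
  expect_equal(wide - 250, 5 * 5)    # ages 65..69
  neg <- d5; neg$deaths[1] <- -1
  expect_error(deaths_at_working_ages(neg, c(2000, 2001)), "non-negative")
})

test_that("balance residuals are exact inverses", {
  expect_equal(residual_migration(W1 = 1000, W2 = 1010, CT = 20, D_W = 15), 5)
  expect_equal(residual_migration(1000, 1000, 0, 0), 0)
  expect_equal(residual_deaths(W1 = 1000, W2 = 1010, CT = 20, M_W = 5), 15)
  expect_equal(residual_deaths(1000, 1000 + 20, 20, 0), 0)  # closed population
  # round-trip on random tuples
  set.seed(11)
  for (i in 1:50) {
    v <- runif(4, 0, 1e5)
    mw <- residual_migration(v[1], v[2], v[3], v[4])
    expect_equal(residual_deaths(v[1], v[2], v[3], mw), v[4],
                 tolerance = 1e-12)
  }
})

test_that("working-age effect splits by the shared h weight", {
  p <- decompose_working_age_effect(NW1 = 50, NW2 = 55, CT = 8, M_W = 5,
                                    D_W = 3)
  h <- 0.5 * (1 / 55 + 1 / 50)
  expect_equal(p$ct, h * 8)
  expect_equal(p$mg, h * 5)
  expect_equal(p$mt, -h * 3)
  # CT + M_W - D_W = 10 = W2 - W1 of the two-factor example: sums agree
  expect_equal(p$ct + p$mg + p$mt, 21 / 110)
  expect_equal(unlist(decompose_working_age_effect(50, 55, 0, 0, 0)),
               c(ct = 0, mg = 0, mt = 0))
  expect_equal(unlist(decompose_working_age_effect(50, 55, 16, 10, 6)),
               2 * unlist(p))     # linearity
  expect_error(decompose_working_age_effect(0, 55, 1, 1, 1), "positive")
})

test_that("full decomposition satisfies both additivity identities", {
  out <- generate_scenario(small_two_cluster(seed = 14))
  for (mode in c("observed", "projected")) {
    cc <- decompose_change(out$population, out$deaths, out$migration,
                           interval = c(2001, 2006), mode = mode)
    expect_equal(nrow(cc), 10)
    expect_lt(max(abs(cc$g - cc$nw - cc$w) / pmax(1, abs(cc$g))), 1e-12)
    expect_lt(max(abs(cc$w - cc$ct - cc$mg - cc$mt) / pmax(1, abs(cc$w))),
              1e-12)
    # balance closes exactly in both modes
    W1 <- compute_tsr(out$population[out$population$year == 2001, ])$W
    W2 <- compute_tsr(out$population[out$population$year == 2006, ])$W
    expect_equal(W1 + cc$CT + cc$M_W - cc$D_W, W2)
  }
})

test_that("residual components match simulator truth in both modes", {
  out <- generate_scenario(small_two_cluster(seed = 15))
  m <- data.table::as.data.table(out$migration)
  d <- data.table::as.data.table(out$deaths)
  iv <- c(2002, 2003)
  obs <- decompose_change(out$population, out$deaths, interval = iv,
                          mode = "observed")
  mw_true <- m[m$year == 2002 & m$age >= 15 & m$age < 65,
               list(MW = sum(.SD$net_migration)), by = "region"]
  data.table::setkeyv(mw_true, "region")
  expect_lt(max(abs(obs$M_W - mw_true$MW)), 1e-9)
  prj <- decompose_change(out$population, migration = out$migration,
                          interval = iv, mode = "projected")
  dw_true <- d[d$year == 2002 & d$age >= 15 & d$age < 65,
               list(DW = sum(.SD$deaths)), by = "region"]
  data.table::setkeyv(dw_true, "region")
  expect_lt(max(abs(prj$D_W - dw_true$DW)), 1e-9)
})

test_that("an unchanged region has all six components zero", {
  pop <- uniform_panel(years = 2000:2001)
  cc <- decompose_change(pop, zero_events("r1", 2000),
                         interval = c(2000, 2001), mode = "observed")
  expect_equal(unlist(cc[, c("g", "nw", "w", "ct", "mg", "mt")]),
               c(g = 0, nw = 0, w = 0, ct = 0, mg = 0, mt = 0))
})

test_that("mode and inputs are validated with region context", {
  pop <- uniform_panel(regions = c("a", "b"), years = 2000:2001)
  expect_error(decompose_change(pop, interval = c(2000, 2001),
                                mode = "observed"), "deaths")
  expect_error(decompose_change(pop, deaths = zero_events("a", 2000),
                                interval = c(2000, 2001), mode = "observed"),
               "differ")
  expect_error(decompose_change(pop, interval = c(2000, 2001),
                                mode = "projected"), "migration")
})

test_that("the secondary working-age effect on the nw term stays small", {
  # the two-factor nw term also moves when W changes; on realistic panels
  # that secondary channel is a small fraction of the total change
  out <- generate_scenario(small_two_cluster(seed = 30))
  p <- data.table::as.data.table(out$population)
  iv <- c(2000, 2010)
  t1 <- compute_tsr(p[p$year == iv[1]]); t2 <- compute_tsr(p[p$year == iv[2]])
  full <- dasgupta_two_factor(t1$W, t2$W, t1$NW, t2$NW)
  fixedW <- dasgupta_two_factor(t1$W, t1$W, t1$NW, t2$NW)
  secondary <- full$nw_effect - fixedW$nw_effect
  rel <- secondary / (t2$tsr - t1$tsr)
  expect_lt(mean(abs(rel)), 0.05)
})
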