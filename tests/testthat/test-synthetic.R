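# Cohort-component simulator: schedules, waves, balance, stationarity.

test_that("schedules realize correctly and reject bad lengths", {
  expect_equal(build_schedule(sched_constant(0.01), 5), rep(0.01, 6))
  s <- build_schedule(sched_points(c(0, 10), c(0, 1)), 10)
  expect_equal(s, seq(0, 1, by = 0.1))
  # flat extrapolation beyond the knots
  expect_equal(build_schedule(sched_points(c(5, 6), c(2, 4)), 10)[c(1, 11)],
               c(2, 4))
  g <- build_schedule(sched_gompertz(1e-4, 0.1), 100)
  expect_true(all(g > 0 & g < 1) && !is.unsorted(g))
  expect_equal(g[1], 1 - exp(-1e-4))
  expect_error(build_schedule(rep(0.1, 5), 100), "length")
  expect_error(build_schedule(sched_points(c(3, 2), c(1, 1)), 10))
})

test_that("apply_wave scales exactly the targeted cohorts", {
  pop <- rep(100, 101)
  # multiplier 1.0 everywhere -> identity
  expect_equal(apply_wave(pop, list(list(from = 1900, to = 2000,
                                         multiplier = 1)), 2000), pop)
  # cohort aged 30 at Jan 1 2000 was born in 1969
  one <- apply_wave(pop, list(list(from = 1969, to = 1969, multiplier = 2)),
                    2000)
  expect_equal(one[31], 200)
  expect_equal(one[-31], pop[-31])
  # disjoint windows commute and equal the composition
  w1 <- list(from = 1950, to = 1960, multiplier = 1.5)
  w2 <- list(from = 1980, to = 1990, multiplier = 0.5)
  expect_equal(apply_wave(pop, list(w1, w2), 2000),
               apply_wave(apply_wave(pop, list(w2), 2000), list(w1), 2000))
  expect_error(apply_wave(pop, list(w1, list(from = 1955, to = 1965,
                                             multiplier = 2)), 2000),
               "overlap")
  expect_error(apply_wave(pop, list(list(from = 1950, to = 1960,
                                         multiplier = -1)), 2000))
})

test_that("zero-rate scenario shifts the pyramid up one age", {
  cfg <- scenario_config(
    clusters = list(cluster_spec("z", 2, mortality = sched_constant(0),
                                 initial_growth = 0.01)),
    start_year = 2000, end_year = 2001, open_age = 50, seed = 3)
  out <- generate_scenario(cfg)
  p <- data.table::dcast(out$population[out$population$region == "z_01"],
                         age ~ year, value.var = "count")
  expect_equal(p[["2001"]][1], 0)                        # no births
  expect_equal(p[["2001"]][2:50], p[["2000"]][1:49])      # pure shift
  expect_equal(p[["2001"]][51], sum(p[["2000"]][50:51]))  # terminal pools
  expect_true(all(out$deaths$deaths == 0))
  expect_true(all(out$migration$net_migration == 0))
})

test_that("identical config and seed reproduce the panels exactly", {
  a <- generate_scenario(small_two_cluster(seed = 9))
  b <- generate_scenario(small_two_cluster(seed = 9))
  for (nm in names(a)) expect_cols_equal(a[[nm]], b[[nm]])
  c2 <- generate_scenario(small_two_cluster(seed = 10))
  expect_false(isTRUE(all.equal(a$population$count, c2$population$count)))
})

test_that("stationary scenario keeps TSR constant over a decade", {
  out <- generate_scenario(stationary_scenario(n_regions = 3, seed = 5))
  tsr <- compute_tsr(out$population)
  spread <- tapply(tsr$tsr, tsr$region, function(v) max(abs(v - v[1])))
  expect_lt(max(spread), 1e-9)
})

test_that("demographic balance closes exactly for every region, age, interval", {
  out <- generate_scenario(small_two_cluster(seed = 21))
  p <- data.table::as.data.table(out$population)
  d <- data.table::as.data.table(out$deaths)
  m <- data.table::as.data.table(out$migration)
  A <- max(p$age)
  x <- merge(d[d$age >= 1 & d$age < A], m, by = c("region", "year", "age"))
  x <- merge(x, p[, list(region = p$region, year = p$year, age = p$age + 1L,
                         prev = p$count)], by = c("region", "year", "age"))
  x <- merge(x, p[, list(region = p$region, year = p$year - 1L, age = p$age,
                         nxt = p$count)], by = c("region", "year", "age"))
  expect_lt(max(abs(x$nxt - (x$prev - x$deaths + x$net_migration))), 1e-9)
  expect_true(all(out$population$count >= 0))
})

test_that("higher working-age mortality lowers a cluster's TSR at a
           within-decade horizon", {
  # excess working-age deaths deplete W immediately; only after roughly a
  # decade does the reduced inflow into the 65+ group overtake that loss,
  # so the ceteris-paribus comparison is pinned at a five-year horizon
  diffs <- vapply(1:20, function(s) {
    hi <- generate_scenario(small_two_cluster(seed = s, east_mult = 3,
                                              end_year = 2005L))
    lo <- generate_scenario(small_two_cluster(seed = s, east_mult = 1,
                                              end_year = 2005L))
    sub <- function(p) p[p$year == 2005 & p$cluster == "east", ]
    mean(compute_tsr(sub(hi$population))$tsr) -
      mean(compute_tsr(sub(lo$population))$tsr)
  }, numeric(1))
  expect_true(all(diffs < 0))
  expect_lt(mean(diffs), 0)
})

test_that("a bust cohort entering working ages dips cohort turnover", {
  # bust born 1990-1999 reaches age 14 during 2005-2014
  out <- generate_scenario(small_two_cluster(seed = 2, end_year = 2012))
  comp_pre <- decompose_change(out$population, out$deaths,
                               interval = c(2000, 2003), mode = "observed")
  comp_in <- decompose_change(out$population, out$deaths,
                              interval = c(2007, 2010), mode = "observed")
  east_pre <- mean(comp_pre$ct[comp_pre$cluster == "east"])
  east_in <- mean(comp_in$ct[comp_in$cluster == "east"])
  west_pre <- mean(comp_pre$ct[comp_pre$cluster == "west"])
  west_in <- mean(comp_in$ct[comp_in$cluster == "west"])
  # the dip is specific to the bust cluster
  expect_lt(east_in - east_pre, west_in - west_pre)
  expect_lt(east_in, east_pre)
})

test_that("invalid configs are rejected", {
  ok <- cluster_spec("x", 2, mortality = sched_constant(0.01))
  expect_error(scenario_config(list(ok), 2010, 2005), "end_year")
  expect_error(scenario_config(list(ok), 2000, 2010, observed_until = 2000),
               "observed_until")
  expect_error(scenario_config(list("no"), 2000, 2010), "cluster_spec")
  expect_error(generate_scenario(scenario_config(
    list(cluster_spec("x", 1, mortality = rep(0.5, 10))),
    2000, 2002, open_age = 20)), "length")
  expect_error(generate_scenario(scenario_config(
    list(cluster_spec("x", 1, mortality = rep(1.2, 21))),
    2000, 2002, open_age = 20)), "probabilities")
})
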