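# Shared in-code fixtures: tiny panels built arithmetically, plus a small
# two-cluster scenario cheap enough for Monte-Carlo property tests.

uniform_panel <- function(regions = "r1", years = 2000, open_age = 99,
                          count = 10) {
  g <- expand.grid(region = regions, year = years, age = 0:open_age,
                   stringsAsFactors = FALSE)
  g$count <- count
  g
}

zero_events <- function(regions, years, open_age = 99, value = "deaths") {
  g <- expand.grid(region = regions, year = years, age = 0:open_age,
                   stringsAsFactors = FALSE)
  g[[value]] <- 0
  g
}

small_two_cluster <- function(seed, n_regions = 5L, end_year = 2015L,
                              east_mult = 2.5) {
  scenario_config(
    clusters = list(
      cluster_spec("east", n_regions,
                   mortality = sched_gompertz(8e-5, 0.09),
                   mortality_multiplier_working_age = east_mult,
                   fertility = sched_points(c(14, 25, 35, 50),
                                            c(0, 0.05, 0.03, 0)),
                   migration = sched_constant(-0.002),
                   waves = list(list(from = 1990, to = 1999,
                                     multiplier = 0.6)),
                   noise_sd = 0.05),
      cluster_spec("west", n_regions,
                   mortality = sched_gompertz(8e-5, 0.09),
                   fertility = sched_points(c(14, 25, 35, 50),
                                            c(0, 0.055, 0.033, 0)),
                   migration = sched_constant(0.002),
                   noise_sd = 0.05)),
    start_year = 2000L, end_year = end_year,
    observed_until = min(2008L, end_year),
    seed = seed)
}

expect_cols_equal <- function(a, b, tol = 0) {
  expect_identical(names(a), names(b))
  for (nm in names(a)) {
    if (is.numeric(a[[nm]]) && tol > 0)
      expect_lt(max(abs(a[[nm]] - b[[nm]])), tol)
    else expect_identical(a[[nm]], b[[nm]])
  }
}
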