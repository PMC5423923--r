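#' Cluster specification for the synthetic demographic world
#'
#' A cluster is a group of regions sharing demographic regimes: a mortality
#' schedule (optionally inflated at working ages), a fertility schedule,
#' birth-cohort waves imprinted on the initial population, and a net-migration
#' schedule with an observed-period shock and a projected-period convergence
#' regime. Region-level heterogeneity enters through seeded lognormal
#' perturbations of the cluster rates (mean 1, sd roughly `noise_sd`).
#'
#' @param label free-text cluster label, e.g. `"east"`.
#' @param n_regions number of regions in the cluster.
#' @param mortality age schedule of annual death probabilities q(a) in [0, 1).
#' @param mortality_multiplier_working_age scalar >= 0 applied to q(a) for
#'   ages 15..64 (the conventional working-age range; the analysis bounds
#'   downstream are configurable independently).
#' @param fertility age schedule of annual birth rates per person of age a
#'   (one-sex accounting: births = sum over ages of rate times count).
#' @param migration age schedule of annual net migration rates (may be
#'   negative: net out-migration).
#' @param migration_shock_year calendar year at which `migration_shock_delta`
#'   is added to the migration rates at every age (NA = no shock). The shock
#'   persists to the end of the observed segment.
#' @param migration_shock_delta additive rate shift at the shock.
#' @param migration_convergence_rate per-year geometric shrinkage (in [0, 1])
#'   of each region's deviation from the all-region mean migration schedule
#'   during the projected segment; 1 collapses cross-region variance at once,
#'   0 freezes the observed rates.
#' @param waves list of waves, each `list(from =, to =, multiplier =)`:
#'   birth-cohort calendar-year windows (inclusive) whose initial-population
#'   counts are scaled by `multiplier` (> 0). Windows must not overlap.
#' @param noise_sd standard deviation of the lognormal region-level
#'   perturbation applied to mortality, fertility and migration levels.
#' @param initial_size persons per region at the start year (before waves).
#' @param initial_growth stable-population tilt r: the initial age structure
#'   is proportional to l(a) exp(-r a); r > 0 yields a younger structure.
#' @return object of class `cluster_spec`.
#' @seealso [scenario_config()], [generate_scenario()]
#' @export
cluster_spec <- function(label, n_regions,
                         mortality,
                         mortality_multiplier_working_age = 1,
                         fertility = sched_constant(0),
                         migration = sched_constant(0),
                         migration_shock_year = NA_integer_,
                         migration_shock_delta = 0,
                         migration_convergence_rate = 0,
                         waves = list(),
                         noise_sd = 0,
                         initial_size = 20000,
                         initial_growth = 0) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            n_regions >= 1, mortality_multiplier_working_age >= 0,
            noise_sd >= 0, initial_size > 0,
            migration_convergence_rate >= 0, migration_convergence_rate <= 1)
  waves <- validate_waves(waves)
  structure(list(
    label = label, n_regions = as.integer(n_regions),
    mortality = mortality,
    mortality_multiplier_working_age = mortality_multiplier_working_age,
    fertility = fertility, migration = migration,
    migration_shock_year = migration_shock_year,
    migration_shock_delta = migration_shock_delta,
    migration_convergence_rate = migration_convergence_rate,
    waves = waves, noise_sd = noise_sd,
    initial_size = initial_size, initial_growth = initial_growth
  ), class = "cluster_spec")
}

validate_waves <- function(waves) {
  if (length(waves) == 0L) return(list())
  for (w in waves) {
    if (!all(c("from", "to", "multiplier") %in% names(w)))
      stop("each wave needs fields 'from', 'to', 'multiplier'", call. = FALSE)
    if (w$to < w$from) stop("wave window has to < from", call. = FALSE)
    if (w$multiplier <= 0) stop("wave multipliers must be positive", call. = FALSE)
  }
  froms <- vapply(waves, `[[`, numeric(1), "from")
  tos <- vapply(waves, `[[`, numeric(1), "to")
  o <- order(froms)
  if (length(waves) > 1L && any(froms[o][-1] <= tos[o][-length(o)]))
    stop("wave birth-year windows overlap", call. = FALSE)
  waves
}

#' Scenario configuration
#'
#' Full parameterization of the synthetic multi-region world: a set of
#' clusters, the calendar span, the year splitting the "observed" regime
#' (migration shocks active) from the "projected" regime (migration rates
#' converge across regions), the terminal open-ended age group, and the seed.
#'
#' @param clusters list of [cluster_spec()] objects.
#' @param start_year,end_year calendar span; January-1 population stocks are
#'   produced for every year in `[start_year, end_year]`.
#' @param observed_until first year of the projected regime;
#'   `start_year < observed_until <= end_year`.
#' @param open_age highest age group (open-ended: survivors pool there).
#' @param seed integer RNG seed; identical config + seed reproduces output
#'   bit-for-bit.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(clusters, start_year, end_year,
                            observed_until = end_year, open_age = 100,
                            seed = 1L) {
  if (!length(clusters) || !all(vapply(clusters, inherits, logical(1), "cluster_spec")))
    stop("clusters must be a non-empty list of cluster_spec objects", call. = FALSE)
  if (end_year <= start_year)
    stop("end_year must exceed start_year", call. = FALSE)
  if (observed_until <= start_year || observed_until > end_year)
    stop("observed_until must satisfy start_year < observed_until <= end_year",
         call. = FALSE)
  if (open_age < 1) stop("open_age must be >= 1", call. = FALSE)
  structure(list(
    clusters = clusters,
    n_regions = sum(vapply(clusters, `[[`, integer(1), "n_regions")),
    start_year = as.integer(start_year), end_year = as.integer(end_year),
    observed_until = as.integer(observed_until),
    open_age = as.integer(open_age), seed = as.integer(seed)
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario:", x$n_regions, "regions in", length(x$clusters),
      "clusters,", x$start_year, "-", x$end_year,
      "(projected from", paste0(x$observed_until, "),"),
      "open age", x$open_age, "\n")
  for (cl in x$clusters)
    cat(sprintf("  %-8s %3d regions, working-age mortality x%.2f, %d wave(s)\n",
                cl$label, cl$n_regions, cl$mortality_multiplier_working_age,
                length(cl$waves)))
  invisible(x)
}

#' Imprint birth-cohort waves on an initial age vector
#'
#' Ages whose birth cohorts fall inside a wave window are scaled by the
#' wave's multiplier; all other ages are unchanged. A person of completed
#' age a at January 1 of `start_year` is assigned birth year
#' `start_year - a - 1` (they were born during that calendar year).
#'
#' @param initial_population numeric vector of counts by age `0..length-1`.
#' @param waves list of waves as in [cluster_spec()]; windows must not overlap.
#' @param start_year January-1 reference year of the vector.
#' @return the scaled age vector.
#' @export
apply_wave <- function(initial_population, waves, start_year) {
  waves <- validate_waves(waves)
  ages <- seq_along(initial_population) - 1L
  birth_year <- start_year - ages - 1L
  out <- initial_population
  for (w in waves) {
    hit <- birth_year >= w$from & birth_year <= w$to
    out[hit] <- out[hit] * w$multiplier
  }
  out
}

#' Stationary (life-table) age structure
#'
#' Survivorship structure consistent with the death probabilities `q`:
#' l(0) = 1, l(a+1) = l(a)(1 - q(a)), with the open-ended terminal group
#' holding l(A)/q(A) so that pooling survivors reproduces itself exactly.
#' Combined with [replacement_fertility()] and zero migration this yields a
#' population that the cohort-component projection leaves invariant, which
#' the test suite uses as a stationarity oracle.
#'
#' @param q numeric vector of death probabilities for ages `0..open_age`;
#'   the terminal probability must be positive.
#' @return numeric age vector summing to the stationary person-years.
#' @export
stationary_age_structure <- function(q) {
  A <- length(q) - 1L
  stopifnot(A >= 1, all(q >= 0), all(q[-length(q)] < 1))
  if (q[A + 1L] <= 0)
    stop("terminal death probability must be positive for a stationary structure",
         call. = FALSE)
  l <- cumprod(c(1, 1 - q[seq_len(A)]))   # l(0..A)
  l[A + 1L] <- l[A + 1L] / q[A + 1L]      # open-ended group equilibrium
  l
}

#' Fertility schedule that exactly replaces the birth cohort
#'
#' Scales a fertility shape so that total births on the stationary structure
#' of `q` equal that structure's age-0 count, making the projection exactly
#' stationary.
#'
#' @param q death probabilities for ages `0..open_age`.
#' @param shape an age schedule (or numeric vector) giving relative
#'   age-specific fertility; default flat over ages 20-39.
#' @return explicit numeric fertility schedule.
#' @export
replacement_fertility <- function(q, shape = NULL) {
  A <- length(q) - 1L
  if (is.null(shape)) {
    shape <- numeric(A + 1L)
    shape[pmin(21:40, A + 1L)] <- 1   # ages 20..39
  } else {
    shape <- build_schedule(shape, A)
  }
  s <- stationary_age_structure(q)
  denom <- sum(shape * s)
  if (denom <= 0) stop("fertility shape has zero mass on the structure", call. = FALSE)
  shape * (s[1L] / denom)
}
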