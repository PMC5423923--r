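#' Path to the shipped default scenario file
#'
#' Four clusters of 50 regions each over 2003-2043 (projected from 2013):
#' an "east" cluster with 2.5x working-age mortality, a strong mid-century
#' boom wave, a pronounced 1990s bust cohort and net out-migration, plus
#' "west", "south" and "north" clusters with milder regimes. Designed so
#' the qualitative convergence findings (convergence driven by the east
#' cluster, stable mortality contribution, muted projected-period migration
#' effect) re-emerge from the simulator.
#'
#' @return file path of the TOML scenario.
#' @export
default_scenario_path <- function() {
  system.file("extdata", "default_scenario.toml", package = "tsrdecomp",
              mustWork = TRUE)
}

#' @rdname default_scenario_path
#' @param seed optional seed override.
#' @return `default_scenario()`: the parsed [scenario_config()].
#' @export
default_scenario <- function(seed = NULL) {
  read_scenario_config(default_scenario_path(), seed = seed)
}

decade_tiles <- function(start_year, end_year, width = 10L) {
  cuts <- unique(c(seq(start_year, end_year, by = width), end_year))
  lapply(seq_len(length(cuts) - 1L), function(i) c(cuts[i], cuts[i + 1L]))
}

#' Run the full analysis pipeline
#'
#' simulate (or ingest) -> TSR -> component decomposition -> convergence.
#' Writes `population.csv`, `deaths.csv`, `migration.csv` (when simulated),
#' `tsr.csv`, `components.csv`, `betas.csv`, `betas_cumulative.csv`, a
#' plain-text `run.log` and a `manifest.json` into `out_dir`. Decades
#' before `observed_until` run in observed mode (net migration residual),
#' later decades in projected mode (deaths residual). Any stage error
#' removes the partial outputs of this run before propagating.
#'
#' @param config path to a scenario file or a [scenario_config()]. Ignored
#'   when `population` is supplied.
#' @param out_dir output directory (created if needed).
#' @param seed optional seed override for the simulation.
#' @param bounds a [working_age_bounds()].
#' @param decades optional list of `c(start, end)` tiles; default ten-year
#'   tiles over the panel's span.
#' @param population,deaths,migration optional paths to user CSVs replacing
#'   the simulation stage (population and deaths required together;
#'   migration needed for projected-mode decades).
#' @param observed_until regime switch year when ingesting user CSVs
#'   (default: all decades observed).
#' @param weights `"unit"` (default) or `"pop"` for population-weighted
#'   regressions (initial total population as weight).
#' @return the run manifest, invisibly (list: config hash, seed, paths,
#'   timestamps).
#' @export
run_pipeline <- function(config = default_scenario_path(), out_dir,
                         seed = NULL, bounds = working_age_bounds(),
                         decades = NULL, population = NULL, deaths = NULL,
                         migration = NULL, observed_until = NULL,
                         weights = c("unit", "pop")) {
  weights <- match.arg(weights)
  bounds <- as_bounds(bounds)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  created <- character(0)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                                ..., "\n", sep = "", file = logf, append = TRUE)
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    write_table_csv(x, p)
    created <<- c(created, p)
    log_line("wrote ", name, " (", nrow(x), " rows)")
    p
  }
  cat("", file = logf); created <- c(created, logf)

  tryCatch({
    if (!is.null(population)) {
      if (is.null(deaths))
        stop("user-supplied population requires a deaths CSV", call. = FALSE)
      pop <- read_panel_csv(population, "population")
      dth <- read_panel_csv(deaths, "deaths")
      mig <- if (!is.null(migration)) read_panel_csv(migration, "migration")
      config_hash <- unname(tools::md5sum(population))
      obs_until <- observed_until %||% (max(pop$year) + 1L)
      seed_used <- NA_integer_
      log_line("ingested user panels: ", length(unique(pop$region)),
               " regions, years ", min(pop$year), "-", max(pop$year))
    } else {
      if (is.character(config)) {
        config_hash <- unname(tools::md5sum(config))
        config <- read_scenario_config(config, seed = seed)
      } else {
        config_hash <- NA_character_
        if (!is.null(seed)) config$seed <- as.integer(seed)
      }
      seed_used <- config$seed
      obs_until <- observed_until %||% config$observed_until
      log_line("simulating scenario: ", config$n_regions, " regions, ",
               config$start_year, "-", config$end_year, ", seed ", seed_used)
      panels <- generate_scenario(config)
      pop <- panels$population; dth <- panels$deaths; mig <- panels$migration
      emit(pop, "population.csv"); emit(dth, "deaths.csv")
      emit(mig, "migration.csv")
    }

    tsr <- compute_tsr(pop, bounds)
    emit(tsr, "tsr.csv")

    yrs <- range(pop$year)
    if (is.null(decades)) decades <- decade_tiles(yrs[1], yrs[2])
    modes <- vapply(decades, function(d)
      if (d[1] < obs_until) "observed" else "projected", character(1))
    if (any(modes == "projected") && is.null(mig))
      stop("projected-mode decades need a migration panel", call. = FALSE)
    log_line("decades: ", paste(vapply(decades, paste, character(1),
                                       collapse = ":"), collapse = ", "),
             " modes: ", paste(modes, collapse = ", "))

    comp <- data.table::rbindlist(lapply(seq_along(decades), function(i)
      decompose_change(pop, dth, mig, decades[[i]], bounds, modes[i])))
    emit(comp, "components.csv")
    bad_g <- comp[abs(comp$g - comp$nw - comp$w) >
                    1e-9 * pmax(1, abs(comp$g))]
    log_line("additivity self-check: ", nrow(bad_g), " violations in ",
             nrow(comp), " region-decades")

    w <- if (weights == "pop") {
      tot <- working_age_counts(pop[pop$year == yrs[1]], bounds)
      data.table::setkeyv(tot, "region")
      tot$W + tot$NW
    }
    betas <- temporal_decomposition(pop, dth, mig, decades, bounds,
                                    mode = modes, weights = w)
    emit(data.table::rbindlist(list(betas$pooled, betas$yearly)), "betas.csv")
    emit(betas$cumulative, "betas_cumulative.csv")

    manifest <- list(
      package_version = as.character(utils::packageVersion("tsrdecomp")),
      config_hash = config_hash, seed = seed_used,
      observed_until = obs_until,
      bounds = c(bounds$lower, bounds$upper), weights = weights,
      outputs = basename(created[created != logf]),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    log_line("pipeline complete")
    invisible(manifest)
  }, error = function(e) {
    unlink(setdiff(created, logf))
    log_line("ERROR: ", conditionMessage(e))
    stop(e)
  })
}

#' Deterministic test fixtures
#'
#' Writes small CSV fixture sets used by the test suite and documentation:
#' \describe{
#'   \item{tiny}{3 regions x 3 years x ages 0..4, hand-checkable counts
#'     (use bounds 1:4 downstream).}
#'   \item{two_cluster}{two simulated clusters of 5 regions, 2000-2010.}
#'   \item{stationary}{six identical stationary regions: life-table initial
#'     structure, replacement fertility, no migration, no noise - every
#'     yearly beta downstream is 0.}
#'   \item{divergent}{regions whose working-age population grows faster the
#'     higher their initial TSR - beta(g) > 0 by construction.}
#' }
#'
#' @param name fixture name.
#' @param out_dir destination directory.
#' @return character vector of file paths written.
#' @export
make_fixture <- function(name = c("tiny", "two_cluster", "stationary",
                                  "divergent"), out_dir) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% eval(formals(make_fixture)$name))
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; valid names: tiny, two_cluster, stationary, divergent",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(x, file) {
    p <- file.path(out_dir, file)
    write_table_csv(x, p)
    paths <<- c(paths, p)
  }
  if (name == "tiny") {
    # counts chosen so every aggregate is hand-checkable: region a is
    # constant, b loses working-age mass, c gains it; baseline age-0
    # counts differ so the three regions start at distinct TSRs.
    grid <- data.table::CJ(region = c("a", "b", "c"), year = 2000:2002,
                           age = 0:4)
    base <- c(10, 20, 20, 20, 10)           # ages 0..4; bounds 1:4 -> W = 60
    age0 <- c(a = 10, b = 12, c = 8)
    grid[, "count" := ifelse(grid$age == 0L, age0[grid$region],
                             base[grid$age + 1L]) +
           ifelse(grid$region == "b" & grid$age %in% 1:3, -2, 0) *
             (grid$year - 2000L) +
           ifelse(grid$region == "c" & grid$age %in% 1:3, 3, 0) *
             (grid$year - 2000L)]
    put(grid, "population.csv")
    dth <- data.table::CJ(region = c("a", "b", "c"), year = 2000:2001,
                          age = 0:4)
    dth[, "deaths" := ifelse(dth$region == "b" & dth$age == 2L, 1, 0)]
    put(dth, "deaths.csv")
  } else if (name == "two_cluster") {
    cfg <- scenario_config(
      clusters = list(
        cluster_spec("hi", 5, mortality = sched_gompertz(8e-5, 0.09),
                     mortality_multiplier_working_age = 2,
                     fertility = sched_points(c(14, 25, 35, 50),
                                              c(0, 0.06, 0.03, 0)),
                     migration = sched_constant(-0.002),
                     noise_sd = 0.05),
        cluster_spec("lo", 5, mortality = sched_gompertz(8e-5, 0.09),
                     fertility = sched_points(c(14, 25, 35, 50),
                                              c(0, 0.07, 0.035, 0)),
                     migration = sched_constant(0.002),
                     noise_sd = 0.05)),
      start_year = 2000, end_year = 2010, observed_until = 2006, seed = 11L)
    panels <- generate_scenario(cfg)
    put(panels$population, "population.csv")
    put(panels$deaths, "deaths.csv")
    put(panels$migration, "migration.csv")
  } else if (name == "stationary") {
    cfg <- stationary_scenario(n_regions = 6L, start_year = 2000L,
                               end_year = 2010L, seed = 5L)
    panels <- generate_scenario(cfg)
    put(panels$population, "population.csv")
    put(panels$deaths, "deaths.csv")
    put(panels$migration, "migration.csv")
  } else if (name == "divergent") {
    regions <- sprintf("r%02d", 1:6)
    tsr0 <- seq(1.0, 2.0, length.out = 6L)    # higher start -> faster growth
    years <- 2000:2010
    rows <- lapply(seq_along(regions), function(i) {
      w0 <- 1000 * tsr0[i]
      growth <- 1 + 0.01 * (tsr0[i] - 1)      # growth rises with initial TSR
      lapply(years, function(t) {
        wt <- w0 * growth ^ (t - years[1])
        counts <- numeric(100)
        counts[16:65] <- wt / 50              # ages 15..64
        counts[c(1:15, 66:100)] <- 1000 / 50  # NW fixed at 1000
        data.table::data.table(region = regions[i], year = t, age = 0:99,
                               count = counts)
      })
    })
    pop <- data.table::rbindlist(unlist(rows, recursive = FALSE))
    put(pop, "population.csv")
    dth <- data.table::copy(pop[pop$year < max(years)])
    data.table::setnames(dth, "count", "deaths")
    dth[, "deaths" := 0]
    put(dth, "deaths.csv")
  }
  paths
}

#' Stationary scenario constructor
#'
#' A scenario whose initial structure is the life table of its mortality
#' schedule and whose fertility exactly replaces the birth cohort, with
#' zero migration and zero noise: the projection leaves every region's
#' population (and hence its TSR) invariant, providing the stationarity
#' oracle used in tests.
#'
#' By default mortality is confined to old age (zero below 64, rising
#' Gompertz-style beyond), at a level that varies across regions. That
#' serves two purposes: the support ratios differ across regions (so a
#' convergence regression on the baseline TSR is well defined) while every
#' region has zero cohort turnover, zero working-age deaths and zero
#' migration - all six change components vanish identically, and so do all
#' betas downstream.
#'
#' @param n_regions,start_year,end_year,seed scenario parameters.
#' @param open_age terminal age group.
#' @param q optional explicit death-probability vector (terminal entry
#'   positive) used for every region; overrides the region-varying default.
#' @return a [scenario_config()].
#' @export
stationary_scenario <- function(n_regions = 6L, start_year = 2000L,
                                end_year = 2010L, open_age = 100L,
                                seed = 5L, q = NULL) {
  make_cluster <- function(k, qk) cluster_spec(
    paste0("stat", k), 1L, mortality = qk,
    fertility = replacement_fertility(qk),
    migration = sched_constant(0), noise_sd = 0)
  clusters <- if (!is.null(q)) {
    list(cluster_spec("stat", n_regions, mortality = q,
                      fertility = replacement_fertility(q),
                      migration = sched_constant(0), noise_sd = 0))
  } else {
    lapply(seq_len(n_regions), function(k) {
      ages <- 0:open_age
      level <- 0.04 * 1.15 ^ (k - 1)    # region-varying old-age mortality
      qk <- ifelse(ages < 64, 0, pmin(level * exp(0.1 * (ages - 64)), 0.95))
      make_cluster(k, qk)
    })
  }
  scenario_config(clusters, start_year = start_year, end_year = end_year,
                  observed_until = start_year + 1L, open_age = open_age,
                  seed = seed)
}
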