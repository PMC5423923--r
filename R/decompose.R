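#' Symmetric two-factor decomposition of a change in the support ratio
#'
#' Splits TSR2 - TSR1 = W2/NW2 - W1/NW1 into an additive non-working-age
#' effect and working-age effect using the symmetric (Das Gupta) form:
#' \deqn{nw = \tfrac12 (W_2 + W_1)(1/NW_2 - 1/NW_1), \quad
#'       w  = \tfrac12 (1/NW_2 + 1/NW_1)(W_2 - W_1).}
#' The two effects sum to the TSR change exactly (algebraic identity).
#' All arguments vectorize.
#'
#' @param W1,W2 working-age populations at the start and end of the interval.
#' @param NW1,NW2 non-working-age populations (strictly positive).
#' @return `data.frame` with columns `nw_effect`, `w_effect`.
#' @examples
#' dasgupta_two_factor(W1 = 100, NW1 = 50, W2 = 110, NW2 = 55)  # -0.191, +0.191
#' @export
dasgupta_two_factor <- function(W1, W2, NW1, NW2) {
  if (any(!is.finite(c(W1, W2, NW1, NW2))) || any(c(W1, W2) < 0))
    stop("population counts must be finite and non-negative", call. = FALSE)
  if (any(NW1 <= 0) || any(NW2 <= 0))
    stop("non-working-age populations must be strictly positive", call. = FALSE)
  data.frame(
    nw_effect = 0.5 * (W2 + W1) * (1 / NW2 - 1 / NW1),
    w_effect = 0.5 * (1 / NW2 + 1 / NW1) * (W2 - W1))
}

#' Cohort turnover over an interval
#'
#' The excess of people about to enter working ages over people about to
#' leave them, accumulated over the interval from start-of-year stocks:
#' \deqn{CT = \sum_{t = t_1}^{t_2 - 1} [P(t, lower - 1) - P(t, upper - 1)].}
#' With default bounds and a one-year interval this is the count aged 14
#' minus the count aged 64 at the interval start. Deaths among those
#' specific persons during the year are deliberately not netted out: the
#' residual balance term absorbs that slack.
#'
#' @param panel age-structured population panel.
#' @param interval length-2 vector `c(t1, t2)`, `t1 < t2`, both present in
#'   the panel.
#' @param region optional region id; default all regions.
#' @param bounds a [working_age_bounds()].
#' @return `data.table` with columns region, CT (single row if `region`
#'   given).
#' @export
cohort_turnover <- function(panel, interval, region = NULL,
                            bounds = working_age_bounds()) {
  bounds <- as_bounds(bounds)
  dt <- validate_population_panel(panel)
  if (!is.null(region)) dt <- dt[dt$region %in% region]
  check_interval(dt$year, interval, "population panel")
  yrs <- interval[1]:(interval[2] - 1L)
  sub <- dt[dt$year %in% yrs & dt$age %in% c(bounds$lower - 1L, bounds$upper - 1L)]
  enter_age <- bounds$lower - 1L
  out <- sub[, list(CT = sum(.SD$count[.SD$age == enter_age]) -
                      sum(.SD$count[.SD$age != enter_age])),
             by = "region"]
  data.table::setkeyv(out, "region")
  out[]
}

check_interval <- function(years_present, interval, what) {
  if (length(interval) != 2L || interval[2] <= interval[1])
    stop("interval must be c(t1, t2) with t1 < t2", call. = FALSE)
  missing_years <- setdiff(interval[1]:interval[2], unique(years_present))
  if (length(missing_years))
    stop(what, " does not cover year(s) ",
         paste(missing_years, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Deaths (or net migration) at working ages over an interval
#'
#' Sums events over ages in `[lower, upper)` and flow-years
#' `t1 .. t2 - 1`. Events are counted by age at occurrence within the
#' period rectangle; any Lexis mismatch with the cohort-based turnover term
#' is absorbed by the residual balance component.
#'
#' @param events vital-events panel with columns region, year, age and a
#'   value column (`deaths` or `net_migration`).
#' @inheritParams cohort_turnover
#' @param value which event column to aggregate.
#' @return `data.table` with columns region, value-sum.
#' @export
events_at_working_ages <- function(events, interval, region = NULL,
                                   bounds = working_age_bounds(),
                                   value = c("deaths", "net_migration")) {
  value <- match.arg(value)
  bounds <- as_bounds(bounds)
  dt <- data.table::as.data.table(events)
  if (!all(c("region", "year", "age", value) %in% names(dt)))
    stop("events panel needs columns region, year, age, ", value, call. = FALSE)
  if (value == "deaths" && any(dt$deaths < 0))
    stop("deaths must be non-negative", call. = FALSE)
  if (!is.null(region)) dt <- dt[dt$region %in% region]
  # flows are labeled by interval start: years t1 .. t2-1 cover [t1, t2)
  flow_years <- interval[1]:(interval[2] - 1L)
  check_interval(c(dt$year, interval[2]), interval, "events panel")
  sub <- dt[dt$year %in% flow_years &
              dt$age >= bounds$lower & dt$age < bounds$upper]
  out <- sub[, stats::setNames(list(sum(.SD[[value]])),
                               if (value == "deaths") "D_W" else "M_W"),
             by = "region"]
  data.table::setkeyv(out, "region")
  out[]
}

#' @rdname events_at_working_ages
#' @export
deaths_at_working_ages <- function(events, interval, region = NULL,
                                   bounds = working_age_bounds()) {
  events_at_working_ages(events, interval, region, bounds, value = "deaths")
}

#' Residual components of the working-age demographic balance
#'
#' The balance `W2 = W1 + CT + M_W - D_W` links end-of-period working-age
#' population to its start value plus cohort turnover, net migration and
#' deaths at working ages. When migration records are unreliable (observed
#' period) net migration is derived as the residual
#' `M_W = W2 - W1 - CT + D_W`; when deaths are not yet tabulated (projected
#' period) deaths are the residual `D_W = W1 + CT + M_W - W2`. Either way
#' the balance then closes exactly. All arguments vectorize.
#'
#' @param W1,W2 working-age populations at interval start and end.
#' @param CT cohort turnover over the interval.
#' @param D_W deaths at working ages over the interval.
#' @param M_W net migration at working ages over the interval.
#' @return numeric vector of the residual component (negative net migration
#'   means net out-migration).
#' @export
residual_migration <- function(W1, W2, CT, D_W) {
  stopifnot(is.finite(W1), is.finite(W2), is.finite(CT), is.finite(D_W))
  W2 - W1 - CT + D_W
}

#' @rdname residual_migration
#' @export
residual_deaths <- function(W1, W2, CT, M_W) {
  stopifnot(is.finite(W1), is.finite(W2), is.finite(CT), is.finite(M_W))
  W1 + CT + M_W - W2
}

#' Decompose the working-age effect into its balance components
#'
#' Distributes the Das Gupta working-age effect over cohort turnover,
#' migration and mortality using the shared weight
#' `h = (1/NW2 + 1/NW1) / 2`:
#' ct = h CT, mg = h M_W, mt = -h D_W. Whenever
#' `CT + M_W - D_W = W2 - W1` (the balance holds), ct + mg + mt equals the
#' working-age effect exactly. All arguments vectorize.
#'
#' @param NW1,NW2 non-working-age populations (strictly positive).
#' @inheritParams residual_migration
#' @return `data.frame` with columns ct, mg, mt (mt carries its negative
#'   sign).
#' @export
decompose_working_age_effect <- function(NW1, NW2, CT, M_W, D_W) {
  if (any(NW1 <= 0) || any(NW2 <= 0))
    stop("non-working-age populations must be strictly positive", call. = FALSE)
  h <- 0.5 * (1 / NW2 + 1 / NW1)
  data.frame(ct = h * CT, mg = h * M_W, mt = -h * D_W)
}

#' Full two-step decomposition of TSR change for all regions
#'
#' For every region, decomposes the change in the total support ratio over
#' an interval into the non-working-age and working-age effects (symmetric
#' two-factor step), then splits the working-age effect into cohort
#' turnover, migration and mortality effects via the demographic balance.
#' The mode selects which balance term is derived as the residual:
#' `"observed"` takes deaths from the deaths panel and infers net migration;
#' `"projected"` takes net migration from the migration panel and infers
#' deaths.
#'
#' For a multi-year interval, the first step uses the interval's endpoint
#' stocks only, while CT, M_W and D_W accumulate over the sub-years, so the
#' additivity identities hold on the whole interval.
#'
#' @param panel age-structured population panel.
#' @param deaths vital-events panel with a `deaths` column (required in
#'   observed mode).
#' @param migration vital-events panel with a `net_migration` column
#'   (required in projected mode).
#' @param interval `c(t1, t2)` with both endpoints in the panel.
#' @param bounds a [working_age_bounds()].
#' @param mode `"observed"` (migration residual) or `"projected"` (deaths
#'   residual).
#' @return `data.table` (class `change_components`), one row per region:
#'   region (cluster if present), period_start, period_end, mode, tsr1,
#'   tsr2, g, nw, w, ct, mg, mt, CT, M_W, D_W. Invariants `g = nw + w` and
#'   `w = ct + mg + mt` hold to floating-point accuracy.
#' @export
decompose_change <- function(panel, deaths = NULL, migration = NULL,
                             interval, bounds = working_age_bounds(),
                             mode = c("observed", "projected")) {
  mode <- match.arg(mode)
  bounds <- as_bounds(bounds)
  dt <- validate_population_panel(panel)
  check_interval(dt$year, interval, "population panel")

  ends <- compute_tsr(dt[dt$year %in% interval], bounds)
  tab1 <- ends[ends$year == interval[1]]
  tab2 <- ends[ends$year == interval[2]]
  data.table::setkeyv(tab1, "region"); data.table::setkeyv(tab2, "region")
  if (!identical(tab1$region, tab2$region))
    stop("region sets differ between interval endpoints", call. = FALSE)

  ct_tab <- cohort_turnover(dt, interval, bounds = bounds)
  if (!identical(ct_tab$region, tab1$region))
    stop("region mismatch in cohort turnover", call. = FALSE)

  if (mode == "observed") {
    if (is.null(deaths))
      stop("observed mode requires a deaths panel", call. = FALSE)
    dw <- deaths_at_working_ages(deaths, interval, bounds = bounds)
    if (!identical(dw$region, tab1$region))
      stop("deaths panel regions differ from population panel: ",
           paste(utils::head(setdiff(tab1$region, dw$region), 5L), collapse = ", "),
           call. = FALSE)
    D_W <- dw$D_W
    M_W <- residual_migration(tab1$W, tab2$W, ct_tab$CT, D_W)
  } else {
    if (is.null(migration))
      stop("projected mode requires a migration panel", call. = FALSE)
    mw <- events_at_working_ages(migration, interval, bounds = bounds,
                                 value = "net_migration")
    if (!identical(mw$region, tab1$region))
      stop("migration panel regions differ from population panel: ",
           paste(utils::head(setdiff(tab1$region, mw$region), 5L), collapse = ", "),
           call. = FALSE)
    M_W <- mw$M_W
    D_W <- residual_deaths(tab1$W, tab2$W, ct_tab$CT, M_W)
  }

  dg <- dasgupta_two_factor(tab1$W, tab2$W, tab1$NW, tab2$NW)
  parts <- decompose_working_age_effect(tab1$NW, tab2$NW, ct_tab$CT, M_W, D_W)

  out <- data.table::data.table(
    region = tab1$region,
    period_start = interval[1], period_end = interval[2], mode = mode,
    tsr1 = tab1$tsr, tsr2 = tab2$tsr,
    g = tab2$tsr - tab1$tsr,
    nw = dg$nw_effect, w = dg$w_effect,
    ct = parts$ct, mg = parts$mg, mt = parts$mt,
    CT = ct_tab$CT, M_W = M_W, D_W = D_W)
  if ("cluster" %in% names(tab1)) out[, "cluster" := tab1$cluster]
  data.table::setattr(out, "class", c("change_components", class(out)))
  out[]
}
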