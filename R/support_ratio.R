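#' Working-age bounds
#'
#' The working-age population is the half-open age interval
#' `[lower, upper)` in completed years, i.e. ages 15-64 inclusive under the
#' defaults, matching the Eurostat/UN convention. Both margins are
#' configurable because raising either is a live policy question.
#'
#' @param lower first working age (default 15).
#' @param upper first post-working age (default 65).
#' @return object of class `working_age_bounds`.
#' @export
working_age_bounds <- function(lower = 15L, upper = 65L) {
  lower <- as.integer(lower); upper <- as.integer(upper)
  if (is.na(lower) || is.na(upper) || lower <= 0L || upper <= lower)
    stop("bounds must satisfy 0 < lower < upper", call. = FALSE)
  structure(list(lower = lower, upper = upper), class = "working_age_bounds")
}

as_bounds <- function(bounds) {
  if (inherits(bounds, "working_age_bounds")) return(bounds)
  if (is.numeric(bounds) && length(bounds) == 2L)
    return(working_age_bounds(bounds[1], bounds[2]))
  stop("bounds must be working_age_bounds() or a length-2 numeric", call. = FALSE)
}

#' Validate an age-structured population panel
#'
#' Checks the panel invariants: required columns, one record per
#' (region, year, age), full age coverage `0..open_age` for every
#' region-year, and non-negative counts. Errors name the offending region,
#' year and ages.
#'
#' @param panel data.frame with columns region, year, age, count (cluster
#'   optional).
#' @return the panel as a `data.table` (invisibly validated), with the
#'   inferred `open_age` attached as attribute `"open_age"`.
#' @export
validate_population_panel <- function(panel) {
  if (data.table::is.data.table(panel) &&
      isTRUE(attr(panel, "tsrdecomp_validated", exact = TRUE)))
    return(panel)
  dt <- data.table::as.data.table(panel)
  need <- c("region", "year", "age", "count")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("population panel lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(dt$count) || any(dt$count < 0))
    stop("population counts must be non-negative and non-missing", call. = FALSE)
  open_age <- max(dt$age)
  full <- 0:open_age
  chk <- dt[, list(ok = length(.SD$age) == length(full) &&
                     all(sort(.SD$age) == full)),
            by = c("region", "year")]
  bad <- chk[!chk$ok]
  if (nrow(bad)) {
    first <- bad[1L]
    have <- dt[dt$region == first$region & dt$year == first$year]$age
    missing_ages <- setdiff(full, have)
    dup <- if (length(missing_ages)) paste("missing ages",
      paste(utils::head(missing_ages, 10L), collapse = ",")) else "duplicated ages"
    stop(sprintf("region %s, year %s: %s (and %d more region-years affected)",
                 first$region, first$year, dup, nrow(bad) - 1L), call. = FALSE)
  }
  data.table::setattr(dt, "open_age", open_age)
  data.table::setattr(dt, "tsrdecomp_validated", TRUE)
  dt
}

#' Working-age and non-working-age aggregates
#'
#' Sums person counts inside and outside the working-age interval for every
#' region-year of the panel.
#'
#' @param panel age-structured population panel (region, year, age, count).
#' @param bounds a [working_age_bounds()] (default ages 15-64).
#' @return `data.table` with columns region (cluster if present), year,
#'   W, NW.
#' @export
working_age_counts <- function(panel, bounds = working_age_bounds()) {
  bounds <- as_bounds(bounds)
  dt <- validate_population_panel(panel)
  open_age <- attr(dt, "open_age")
  if (bounds$upper > open_age + 1L)
    stop("upper bound ", bounds$upper, " exceeds panel open age ", open_age,
         call. = FALSE)
  keys <- intersect(c("region", "cluster", "year"), names(dt))
  ag <- dt[, list(
    W = sum(.SD$count[.SD$age >= bounds$lower & .SD$age < bounds$upper]),
    NW = sum(.SD$count[.SD$age < bounds$lower | .SD$age >= bounds$upper])),
    by = keys]
  data.table::setkeyv(ag, c("region", "year"))
  ag[]
}

#' Total support ratio series
#'
#' TSR = W / NW per region-year: the working-age population divided by the
#' non-working-age population, the inverse of the total dependency ratio.
#' A region-year with zero non-working-age population has no defined ratio
#' and raises an error rather than returning infinity.
#'
#' @inheritParams working_age_counts
#' @return `data.table` (class `tsr_series`) with columns region
#'   (cluster if present), year, W, NW, tsr.
#' @examples
#' pop <- expand.grid(region = "r1", year = 2000, age = 0:99)
#' pop$count <- 10
#' compute_tsr(pop)          # uniform ages 0..99 -> TSR = 1
#' @export
compute_tsr <- function(panel, bounds = working_age_bounds()) {
  ag <- working_age_counts(panel, bounds)
  zero <- ag[ag$NW <= 0]
  if (nrow(zero))
    stop(sprintf("TSR undefined (non-working-age population is zero) for region %s, year %s%s",
                 zero$region[1L], zero$year[1L],
                 if (nrow(zero) > 1L) sprintf(" and %d more", nrow(zero) - 1L) else ""),
         call. = FALSE)
  ag[, "tsr" := ag$W / ag$NW]
  data.table::setattr(ag, "class", c("tsr_series", class(ag)))
  ag[]
}
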