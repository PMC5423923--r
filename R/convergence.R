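#' Beta-convergence regression
#'
#' Fits the cross-sectional convergence model
#' \deqn{\Delta y_i = \alpha + \beta\, y_{i,0} + \varepsilon_i}
#' by ordinary least squares: the change in an indicator over a period is
#' regressed on its initial level. A negative slope means beta convergence -
#' units starting high grow less, so cross-unit differences shrink. The
#' default is unit-weighted (every region counts equally, the convergence
#' question about regions as statistical units); population weights may be
#' supplied for the weighted variant.
#'
#' @param x initial levels (one per region).
#' @param y changes over the period.
#' @param weights optional non-negative case weights.
#' @param component optional component label carried into the result.
#' @return object of class `beta_estimate`: list with `component`, `alpha`,
#'   `beta`, `se_beta`, `r_squared`, `n_regions`.
#' @examples
#' ols_beta(c(2, 1.5, 1), c(-0.2, -0.15, -0.1))   # beta = -0.1
#' @export
ols_beta <- function(x, y, weights = NULL, component = NA_character_) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("need at least 3 regions for a convergence regression", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("x and y must not contain NA", call. = FALSE)
  if (stats::var(x) == 0)
    stop("initial levels have zero variance: slope undefined", call. = FALSE)
  if (!is.null(weights) && (length(weights) != length(x) || any(weights < 0)))
    stop("weights must be non-negative, one per region", call. = FALSE)
  fit <- if (is.null(weights)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = weights)
  # exact-fit fixtures trigger the "essentially perfect fit" warning; the
  # coefficient table itself is still what we want
  sm <- suppressWarnings(summary(fit))
  structure(list(
    component = component,
    alpha = unname(stats::coef(fit)[1L]),
    beta = unname(stats::coef(fit)[2L]),
    se_beta = unname(sm$coefficients["x", "Std. Error"]),
    r_squared = sm$r.squared,
    n_regions = length(x)
  ), class = "beta_estimate")
}

#' @export
print.beta_estimate <- function(x, ...) {
  cat(sprintf("beta = %+.5f (se %.5f), alpha = %+.5f, R2 = %.3f, n = %d%s -> %s\n",
              x$beta, x$se_beta, x$alpha, x$r_squared, x$n_regions,
              if (!is.na(x$component)) paste0(" [", x$component, "]") else "",
              classify(x)))
  invisible(x)
}

#' Classify a beta estimate as convergence or divergence
#'
#' Convergence is reported by the sign of beta alone, the headline
#' classification; optionally a 95 percent normal confidence interval flag
#' reports whether zero lies outside `beta +- 1.96 se`.
#'
#' @param estimate a `beta_estimate`.
#' @param significance if `TRUE`, append `" (not significant)"` when the CI
#'   covers zero.
#' @return `"convergence"` or `"divergence"` (a zero slope counts as
#'   neither-shrinking, reported as divergence boundary `"divergence"`).
#' @export
classify <- function(estimate, significance = FALSE) {
  stopifnot(inherits(estimate, "beta_estimate"))
  label <- if (estimate$beta < 0) "convergence" else "divergence"
  if (significance &&
      abs(estimate$beta) <= 1.96 * estimate$se_beta)
    label <- paste0(label, " (not significant)")
  label
}

beta_components <- c("g", "nw", "w", "ct", "mg", "mt")

estimate_to_row <- function(est, period_start, period_end, regressor_year) {
  data.table::data.table(
    component = est$component, period_start = period_start,
    period_end = period_end, regressor_year = regressor_year,
    alpha = est$alpha, beta = est$beta, se_beta = est$se_beta,
    r2 = est$r_squared, n_regions = est$n_regions)
}

#' Partial convergence regressions per demographic component
#'
#' Runs one convergence regression per component of TSR change (g, nw, w,
#' ct, mg, mt), all against the same regressor: the TSR at the baseline
#' year. Because the components add up to the total change and the
#' regressor is shared, the partial slopes add up exactly:
#' beta(nw) + beta(w) = beta(g) and beta(ct) + beta(mg) + beta(mt) =
#' beta(w) - OLS is linear in the response.
#'
#' @param components a `change_components` table (one row per region, see
#'   [decompose_change()]).
#' @param baseline a [compute_tsr()] series (or data.frame with region,
#'   tsr) at the regressor year; must cover exactly the component table's
#'   regions.
#' @param regressor_year baseline year recorded in the output (default
#'   taken from `baseline$year` when unique).
#' @param weights optional per-region weights, aligned after sorting by
#'   region.
#' @return `data.table` of beta estimates, one row per component.
#' @export
partial_betas <- function(components, baseline, regressor_year = NULL,
                          weights = NULL) {
  comp <- data.table::as.data.table(components)
  base <- data.table::as.data.table(baseline)
  if (!all(beta_components %in% names(comp)))
    stop("components table lacks column(s): ",
         paste(setdiff(beta_components, names(comp)), collapse = ", "),
         call. = FALSE)
  if (!all(c("region", "tsr") %in% names(base)))
    stop("baseline needs columns region and tsr", call. = FALSE)
  extra <- setdiff(comp$region, base$region)
  absent <- setdiff(base$region, comp$region)
  if (length(extra) || length(absent))
    stop("region mismatch between components and baseline: ",
         paste(utils::head(c(extra, absent), 10L), collapse = ", "), call. = FALSE)
  data.table::setkeyv(comp, "region"); data.table::setkeyv(base, "region")
  if (is.null(regressor_year))
    regressor_year <- if ("year" %in% names(base) &&
                          length(unique(base$year)) == 1L)
      base$year[1L] else NA_integer_
  ps <- if ("period_start" %in% names(comp)) comp$period_start[1L] else NA
  pe <- if ("period_end" %in% names(comp)) comp$period_end[1L] else NA
  rows <- lapply(beta_components, function(cc)
    estimate_to_row(ols_beta(base$tsr, comp[[cc]], weights, component = cc),
                    ps, pe, regressor_year))
  data.table::rbindlist(rows)
}

#' Temporal decomposition of beta convergence
#'
#' Splits convergence over the study period by decade (or any tiling of
#' year intervals) and by year within each tile. For each tile
#' `[T1, T2]` the TSR distribution at `T1` is the explanatory variable for
#' every regression inside the tile; for each year `t` in `T1..T2-1` the
#' one-year change over `[t, t+1]` is decomposed into the six components
#' and each component is regressed on the tile-initial TSR. The pooled
#' tile-level regressions use the per-region sums of the yearly component
#' changes on the same regressor, so yearly betas within a tile sum to the
#' pooled beta exactly. Cumulative convergence curves are running sums of
#' the yearly betas across the whole period (the regressor resets at tile
#' boundaries, which the output records).
#'
#' @param panel age-structured population panel covering all tiles.
#' @param deaths,migration vital-events panels (see [decompose_change()]).
#' @param decades list of `c(start, end)` intervals tiling the panel's year
#'   range without overlap, e.g. `list(c(2003, 2013), c(2013, 2023))`.
#' @param bounds a [working_age_bounds()].
#' @param mode `"observed"`, `"projected"`, or a vector with one mode per
#'   tile.
#' @param weights optional per-region weights.
#' @return list of class `beta_decomposition`: `yearly` and `pooled` beta
#'   tables (columns as in [partial_betas()]) and `cumulative`
#'   (component, year, cumulative_beta).
#' @export
temporal_decomposition <- function(panel, deaths = NULL, migration = NULL,
                                   decades, bounds = working_age_bounds(),
                                   mode = "observed", weights = NULL) {
  bounds <- as_bounds(bounds)
  if (!length(decades)) stop("decades must be a non-empty list", call. = FALSE)
  starts <- vapply(decades, `[`, numeric(1), 1L)
  endsv <- vapply(decades, `[`, numeric(1), 2L)
  o <- order(starts)
  decades <- decades[o]; starts <- starts[o]; endsv <- endsv[o]
  if (any(endsv <= starts) ||
      (length(decades) > 1L && any(starts[-1] != endsv[-length(endsv)])))
    stop("decades must tile the year range without gaps or overlap", call. = FALSE)
  modes <- rep_len(mode, length(decades))

  dt <- validate_population_panel(panel)
  check_interval(dt$year, c(starts[1L], endsv[length(endsv)]), "population panel")

  yearly <- list(); pooled <- list()
  for (d in seq_along(decades)) {
    T1 <- decades[[d]][1L]; T2 <- decades[[d]][2L]
    base <- compute_tsr(dt[dt$year == T1], bounds)
    comp_sum <- NULL
    for (t in T1:(T2 - 1L)) {
      cc <- decompose_change(dt, deaths, migration, c(t, t + 1L), bounds,
                             modes[d])
      data.table::setkeyv(cc, "region")
      yearly[[length(yearly) + 1L]] <-
        partial_betas(cc, base, regressor_year = T1, weights = weights)
      mat <- as.matrix(cc[, beta_components, with = FALSE])
      comp_sum <- if (is.null(comp_sum)) mat else comp_sum + mat
    }
    pooled_tab <- data.table::as.data.table(comp_sum)
    pooled_tab[, "region" := cc$region]
    pooled_tab[, "period_start" := T1]
    pooled_tab[, "period_end" := T2]
    pooled[[d]] <- partial_betas(pooled_tab, base, regressor_year = T1,
                                 weights = weights)
  }
  yearly <- data.table::rbindlist(yearly)
  pooled <- data.table::rbindlist(pooled)

  cum <- data.table::copy(yearly)
  data.table::setorderv(cum, c("component", "period_start"))
  cum <- cum[, list(year = .SD$period_start,
                    cumulative_beta = cumsum(.SD$beta),
                    regressor_year = .SD$regressor_year),
             by = "component"]
  structure(list(yearly = yearly, pooled = pooled, cumulative = cum),
            class = "beta_decomposition")
}

#' Direct TSR-dynamics generator for estimator calibration
#'
#' Draws a cross-section of regions whose support ratio follows the linear
#' convergence law \eqn{TSR_{t+1} = TSR_t + \alpha + b\,TSR_t + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma^2)}, and returns initial levels and
#' one-period changes. This bypasses the cohort-component machinery so the
#' convergence coefficient is known exactly; the test suite uses it for
#' parameter-recovery checks of [ols_beta()].
#'
#' @param n_regions cross-section size.
#' @param b true convergence coefficient.
#' @param alpha intercept of the dynamics.
#' @param noise_sd standard deviation of the shock.
#' @param tsr0 optional vector of initial levels; default uniform on
#'   `[1.2, 2.2]`, the plausible regional support-ratio range.
#' @param seed optional seed applied locally.
#' @return `data.table` with columns region, tsr0, change.
#' @export
simulate_tsr_dynamics <- function(n_regions, b, alpha = 0, noise_sd = 0.02,
                                  tsr0 = NULL, seed = NULL) {
  stopifnot(n_regions >= 3)
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
  }
  if (is.null(tsr0)) tsr0 <- stats::runif(n_regions, 1.2, 2.2)
  stopifnot(length(tsr0) == n_regions)
  data.table::data.table(
    region = sprintf("r%03d", seq_len(n_regions)),
    tsr0 = tsr0,
    change = alpha + b * tsr0 + stats::rnorm(n_regions, 0, noise_sd))
}

#' @export
print.beta_decomposition <- function(x, ...) {
  cat("Beta-convergence decomposition:", nrow(x$pooled) / 6, "period(s)\n")
  print(data.table::dcast(x$pooled, period_start + period_end ~ component,
                          value.var = "beta"))
  invisible(x)
}
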