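#' Age-schedule constructors
#'
#' Demographic rate schedules (mortality probabilities, fertility rates, net
#' migration rates) are functions of completed age over \code{0..open_age}.
#' Schedules are stored symbolically and realized into a numeric vector of
#' length \code{open_age + 1} by [build_schedule()]. Three parametric forms
#' are supported, matching what a declarative scenario file can express:
#'
#' * `sched_constant(value)` - the same rate at every age.
#' * `sched_points(ages, values)` - piecewise-linear interpolation through
#'   the given (age, value) knots; ages outside the knot range take the
#'   nearest knot's value.
#' * `sched_gompertz(a, b)` - Gompertz-like mortality hazard
#'   \eqn{h(x) = a e^{bx}}, converted to an annual death probability
#'   \eqn{q(x) = 1 - e^{-h(x)}} (so q always stays below 1).
#'
#' @param value non-negative rate applied at all ages.
#' @param ages,values knot coordinates; `ages` strictly increasing.
#' @param a,b Gompertz level (> 0) and slope parameters.
#' @return an object of class `age_schedule`.
#' @examples
#' build_schedule(sched_constant(0.01), open_age = 5)
#' build_schedule(sched_points(c(0, 50, 100), c(0.02, 0.001, 0.4)), 100)[51]
#' @export
sched_constant <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  structure(list(form = "constant", value = value), class = "age_schedule")
}

#' @rdname sched_constant
#' @export
sched_points <- function(ages, values) {
  stopifnot(length(ages) == length(values), length(ages) >= 1L,
            !is.unsorted(ages, strictly = TRUE), all(is.finite(values)))
  structure(list(form = "points", ages = as.numeric(ages),
                 values = as.numeric(values)), class = "age_schedule")
}

#' @rdname sched_constant
#' @export
sched_gompertz <- function(a, b) {
  stopifnot(is.numeric(a), a > 0, is.numeric(b), is.finite(b))
  structure(list(form = "gompertz", a = a, b = b), class = "age_schedule")
}

#' Realize a schedule as a numeric age vector
#'
#' @param sched an `age_schedule`, or an already-numeric vector of length
#'   `open_age + 1` (accepted as-is, allowing fully explicit schedules).
#' @param open_age highest (terminal, open-ended) age group.
#' @return numeric vector of length `open_age + 1`, ages `0..open_age`.
#' @export
build_schedule <- function(sched, open_age) {
  ages <- 0:open_age
  if (is.numeric(sched)) {
    if (length(sched) != open_age + 1L)
      stop("explicit schedule has length ", length(sched),
           " but ages 0..", open_age, " require ", open_age + 1L, call. = FALSE)
    return(as.numeric(sched))
  }
  if (!inherits(sched, "age_schedule"))
    stop("schedule must be an 'age_schedule' or a numeric vector", call. = FALSE)
  switch(sched$form,
    constant = rep(sched$value, open_age + 1L),
    points   = stats::approx(sched$ages, sched$values, xout = ages,
                             rule = 2)$y,
    gompertz = 1 - exp(-sched$a * exp(sched$b * ages)),
    stop("unknown schedule form: ", sched$form, call. = FALSE)
  )
}
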