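`%||%` <- function(a, b) if (is.null(a)) b else a

# --- minimal TOML-subset reader -------------------------------------------
# Supports what scenario files need: comments, [table] headers, [[array of
# tables]] headers, and `key = value` with string / number / boolean /
# single-line array values. Nested inline tables are not supported; schedule
# parameters use flattened key names instead (mortality_form = "gompertz",
# mortality_a = ..., fertility_ages = [...], ...).

parse_toml_value <- function(txt, path, lineno) {
  txt <- trimws(txt)
  if (txt == "") stop(sprintf("%s:%d: empty value", path, lineno), call. = FALSE)
  if (startsWith(txt, "[")) {
    if (!endsWith(txt, "]"))
      stop(sprintf("%s:%d: unterminated array", path, lineno), call. = FALSE)
    inner <- trimws(substr(txt, 2L, nchar(txt) - 1L))
    if (inner == "") return(list())
    parts <- strsplit(inner, ",")[[1]]
    return(unlist(lapply(parts, parse_toml_value, path = path, lineno = lineno)))
  }
  if (startsWith(txt, "\"")) {
    if (nchar(txt) < 2L || !endsWith(txt, "\""))
      stop(sprintf("%s:%d: unterminated string", path, lineno), call. = FALSE)
    return(substr(txt, 2L, nchar(txt) - 1L))
  }
  if (txt %in% c("true", "false")) return(txt == "true")
  num <- suppressWarnings(as.numeric(gsub("_", "", txt)))
  if (is.na(num))
    stop(sprintf("%s:%d: cannot parse value '%s'", path, lineno, txt),
         call. = FALSE)
  num
}

strip_toml_comment <- function(line) {
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  in_str <- FALSE
  for (i in seq_along(chars)) {
    if (chars[i] == "\"") in_str <- !in_str
    if (chars[i] == "#" && !in_str) return(substr(line, 1L, i - 1L))
  }
  line
}

read_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  root <- list()
  sec_name <- NULL          # current [table] or [[array-of-tables]] name
  sec_idx <- NA_integer_    # element index when inside an array of tables
  for (i in seq_along(lines)) {
    line <- trimws(strip_toml_comment(lines[i]))
    if (line == "") next
    if (grepl("^\\[\\[.+\\]\\]$", line)) {
      sec_name <- trimws(gsub("^\\[\\[|\\]\\]$", "", line))
      root[[sec_name]] <- c(root[[sec_name]] %||% list(), list(list()))
      sec_idx <- length(root[[sec_name]])
    } else if (grepl("^\\[.+\\]$", line)) {
      sec_name <- trimws(gsub("^\\[|\\]$", "", line))
      if (is.null(root[[sec_name]])) root[[sec_name]] <- list()
      sec_idx <- NA_integer_
    } else if (grepl("=", line, fixed = TRUE)) {
      eq <- regexpr("=", line, fixed = TRUE)
      key <- trimws(substr(line, 1L, eq - 1L))
      val <- parse_toml_value(substr(line, eq + 1L, nchar(line)), path, i)
      if (is.null(sec_name)) root[[key]] <- val
      else if (is.na(sec_idx)) root[[sec_name]][[key]] <- val
      else root[[sec_name]][[sec_idx]][[key]] <- val
    } else {
      stop(sprintf("%s:%d: cannot parse line '%s'", path, i, line),
           call. = FALSE)
    }
  }
  root
}

schedule_from_keys <- function(tbl, prefix, path) {
  form <- tbl[[paste0(prefix, "_form")]]
  if (is.null(form))
    stop("config ", path, ": missing ", prefix, "_form", call. = FALSE)
  switch(form,
    constant = sched_constant(tbl[[paste0(prefix, "_value")]] %||%
      stop("missing ", prefix, "_value", call. = FALSE)),
    points = sched_points(tbl[[paste0(prefix, "_ages")]],
                          tbl[[paste0(prefix, "_values")]]),
    gompertz = sched_gompertz(tbl[[paste0(prefix, "_a")]],
                              tbl[[paste0(prefix, "_b")]]),
    stop("config ", path, ": unknown ", prefix, "_form '", form, "'",
         call. = FALSE))
}

#' Read a scenario configuration file
#'
#' Parses a declarative scenario file (TOML dialect; see
#' `system.file("extdata", "default_scenario.toml", package = "tsrdecomp")`
#' for the shipped default) into a [scenario_config()]. A `[scenario]`
#' table holds the global keys (start_year, end_year, observed_until,
#' open_age, seed) and each `[[cluster]]` table one cluster. Schedules use
#' flattened keys: `<name>_form` is `"constant"`, `"points"` or
#' `"gompertz"` with parameters `<name>_value`, `<name>_ages` /
#' `<name>_values`, or `<name>_a` / `<name>_b`. Waves are parallel arrays
#' `wave_from`, `wave_to`, `wave_multiplier`.
#'
#' @param path file path.
#' @param seed optional seed overriding the file's value.
#' @return a [scenario_config()].
#' @export
read_scenario_config <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- read_toml(path)
  sc <- raw[["scenario"]]
  if (is.null(sc)) stop("config ", path, ": missing [scenario] table", call. = FALSE)
  cls <- raw[["cluster"]]
  if (is.null(cls) || !length(cls))
    stop("config ", path, ": no [[cluster]] tables", call. = FALSE)
  clusters <- lapply(cls, function(tbl) {
    waves <- list()
    wf <- tbl$wave_from
    if (!is.null(wf)) {
      if (length(tbl$wave_to) != length(wf) ||
          length(tbl$wave_multiplier) != length(wf))
        stop("config ", path, ": wave_from/wave_to/wave_multiplier lengths differ",
             call. = FALSE)
      waves <- lapply(seq_along(wf), function(k)
        list(from = wf[k], to = tbl$wave_to[k],
             multiplier = tbl$wave_multiplier[k]))
    }
    cluster_spec(
      label = tbl$label, n_regions = tbl$n_regions,
      mortality = schedule_from_keys(tbl, "mortality", path),
      mortality_multiplier_working_age =
        tbl$mortality_multiplier_working_age %||% 1,
      fertility = schedule_from_keys(tbl, "fertility", path),
      migration = schedule_from_keys(tbl, "migration", path),
      migration_shock_year = tbl$migration_shock_year %||% NA_integer_,
      migration_shock_delta = tbl$migration_shock_delta %||% 0,
      migration_convergence_rate = tbl$migration_convergence_rate %||% 0,
      waves = waves,
      noise_sd = tbl$noise_sd %||% 0,
      initial_size = tbl$initial_size %||% 20000,
      initial_growth = tbl$initial_growth %||% 0)
  })
  scenario_config(clusters,
                  start_year = sc$start_year, end_year = sc$end_year,
                  observed_until = sc$observed_until %||% sc$end_year,
                  open_age = sc$open_age %||% 100,
                  seed = seed %||% sc$seed %||% 1L)
}

# --- CSV interchange -------------------------------------------------------

csv_schemas <- list(
  population = list(required = c("region", "year", "age", "count"),
                    numeric = c("year", "age", "count")),
  deaths = list(required = c("region", "year", "age", "deaths"),
                numeric = c("year", "age", "deaths")),
  migration = list(required = c("region", "year", "age", "net_migration"),
                   numeric = c("year", "age", "net_migration")))

#' Read an interchange CSV with schema validation
#'
#' Reads one of the pipeline's long-format CSVs (population, deaths or net
#' migration by region, year and single age) and validates its schema.
#' Violations are reported with 1-based data row numbers.
#'
#' @param path file path.
#' @param kind one of `"population"`, `"deaths"`, `"migration"`.
#' @return a `data.table`.
#' @export
read_panel_csv <- function(path, kind = c("population", "deaths", "migration")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  schema <- csv_schemas[[kind]]
  dt <- data.table::fread(path)
  miss <- setdiff(schema$required, names(dt))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "), call. = FALSE)
  for (col in schema$numeric) {
    v <- dt[[col]]
    if (!is.numeric(v))
      stop(path, ": column ", col, " is not numeric", call. = FALSE)
    bad <- which(!is.finite(v))
    if (col != "net_migration" && col != "deaths") bad <- union(bad, which(v < 0))
    if (col == "deaths") bad <- union(bad, which(v < 0))
    if (length(bad))
      stop(path, ": invalid ", col, " at data row(s) ",
           paste(utils::head(sort(bad), 10L), collapse = ", "), call. = FALSE)
  }
  if (kind == "population") dt <- validate_population_panel(dt)
  dt
}

#' Write a pipeline table to CSV
#'
#' Thin wrapper over [data.table::fwrite()] with full numeric precision so
#' that write -> read round-trips preserve values to 1e-15.
#'
#' @param x data.frame to write.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  data.table::fwrite(x, path)
  invisible(path)
}
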