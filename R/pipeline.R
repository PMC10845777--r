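# Orchestration: config, panel validation, and the end-to-end
# three-stage run from county-day panel to burden report.

#' Pipeline configuration
#'
#' Collects inputs and settings for [run_pipeline()]. Tabular inputs may
#' be tibbles or CSV paths (schemas as written by [write_panel()]).
#'
#' @param panel County-day panel (tibble or CSV path).
#' @param counties County metadata with `county_id`, `zone` and the cost
#'   columns `avg_expense`, `avg_stay` (tibble or CSV path).
#' @param annual Annual county exposures `county_id, year, n_admissions,
#'   no2_annual_mean`; computed from the panel when `NULL`.
#' @param costs Cost table `county_id, avg_expense, avg_stay`; taken
#'   from `counties` when `NULL`.
#' @param causes Causes to analyse.
#' @param confounders A [confounder_config()].
#' @param lag A [lag_spec()] for the stage-1 distributed-lag model.
#' @param burden_lag Lag descriptor whose pooled effect feeds the burden
#'   stage (default `"lag0"`).
#' @param strata_by Stratification column (default `"zone"`).
#' @param aqg Counterfactual guideline concentrations, ug/m3.
#' @param co_pollutant Optional co-pollutant column for two-pollutant
#'   models (entered linearly at lag 0).
#' @param fit_curves Also fit and meta-smooth the nonlinear
#'   concentration-response model (knots `curve_knots`).
#' @param curve_knots Internal knots (ug/m3) for the nonlinear model.
#' @param pool_method `"REML"` or `"DL"`.
#' @param seed Integer seed recorded in the manifest.
#' @param out_dir Optional output directory for the report bundle.
#' @return A list of class `no2_pipeline_config`.
#' @export
pipeline_config <- function(panel, counties, annual = NULL, costs = NULL,
                            causes = "cvd",
                            confounders = confounder_config(),
                            lag = lag_spec("single", 4L),
                            burden_lag = "lag0", strata_by = "zone",
                            aqg = c(10, 40), co_pollutant = NULL,
                            fit_curves = FALSE, curve_knots = c(20, 40),
                            pool_method = "REML", seed = 1L,
                            out_dir = NULL) {
  if (any(aqg <= 0)) invalid_argument("all `aqg` values must be positive.")
  structure(list(panel = panel, counties = counties, annual = annual,
                 costs = costs, causes = causes, confounders = confounders,
                 lag = lag, burden_lag = burden_lag, strata_by = strata_by,
                 aqg = aqg, co_pollutant = co_pollutant,
                 fit_curves = isTRUE(fit_curves), curve_knots = curve_knots,
                 pool_method = pool_method,
                 seed = check_count(seed, "seed", min = 0L),
                 out_dir = out_dir),
            class = "no2_pipeline_config")
}

read_table_input <- function(x, name) {
  if (is.character(x)) {
    if (!file.exists(x)) {
      abort(sprintf("input `%s` not found: %s", name, x),
            class = "no2burden_schema")
    }
    readr::read_csv(x, show_col_types = FALSE)
  } else if (is.data.frame(x)) {
    as_tibble(x)
  } else {
    abort(sprintf("input `%s` must be a data frame or CSV path.", name),
          class = "no2burden_schema")
  }
}

#' Validate a county-day panel
#'
#' Checks the panel schema (column presence and types), per-county date
#' continuity, nonnegative admission counts, and concentration
#' plausibility (0-1000 ug/m3).
#'
#' @param panel Tibble or CSV path.
#' @return A tibble of issues (`county_id, row, column, issue`); zero
#'   rows means the panel is well-formed.
#' @export
validate_panel <- function(panel) {
  panel <- read_table_input(panel, "panel")
  issues <- tibble(county_id = character(), row = integer(),
                   column = character(), issue = character())
  add <- function(county, row, column, issue) {
    issues <<- bind_rows(issues, tibble(county_id = county,
                                        row = as.integer(row),
                                        column = column, issue = issue))
  }
  required <- c("county_id", "date", "cause", "admissions", "no2",
                "temp", "rh", "holiday")
  for (col in setdiff(required, names(panel))) {
    add(NA_character_, NA_integer_, col, "missing required column")
  }
  if (nrow(issues)) return(issues)
  if (!inherits(panel$date, "Date")) {
    panel$date <- as.Date(panel$date)
    if (anyNA(panel$date)) add(NA, NA, "date", "unparseable dates")
  }
  for (col in c("admissions", "no2", "temp", "rh")) {
    if (!is.numeric(panel[[col]])) add(NA, NA, col, "non-numeric column")
  }
  if (nrow(issues)) return(issues)
  bad <- which(panel$admissions < 0 | panel$admissions != floor(panel$admissions))
  for (i in bad) add(panel$county_id[i], i, "admissions",
                     "negative or non-integer admission count")
  for (col in c("no2", "copollutant")) {
    if (!col %in% names(panel)) next
    out <- which(panel[[col]] < 0 | panel[[col]] > 1000)
    for (i in out) add(panel$county_id[i], i, col,
                       "concentration outside plausible range (0-1000)")
  }
  panel |>
    group_by(.data$county_id, .data$cause,
             across(dplyr::any_of("age_group"))) |>
    dplyr::group_walk(function(g, key) {
      gaps <- which(diff(as.integer(sort(unique(g$date)))) != 1L)
      if (length(gaps)) {
        add(key$county_id[1], gaps[1], "date", "non-consecutive dates")
      }
    })
  issues
}

pipeline_hash <- function(cfg) {
  semantic <- cfg[setdiff(names(cfg), "out_dir")]
  semantic$confounders <- unclass(semantic$confounders)
  semantic$lag <- unclass(semantic$lag)
  for (nm in c("panel", "counties", "annual", "costs")) {
    if (is.data.frame(semantic[[nm]])) {
      semantic[[nm]] <- rlang::hash(semantic[[nm]])
    }
  }
  rlang::hash(semantic)
}

#' Run the three-stage analysis end to end
#'
#' Validates the panel, fits the county distributed-lag models (stage
#' 1), pools overall and by stratum with urban-rural difference tests
#' (stage 2), and computes the attributable burden table under each
#' guideline (stage 3); optionally meta-smooths the nonlinear
#' concentration-response curve. Deterministic given the inputs: running
#' twice with the same config writes byte-identical CSVs.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `no2_pipeline_result`: `estimates`, `pooled`,
#'   `differences`, `burden`, `curve` (or `NULL`), `exclusions`,
#'   `issues`, `log` (character), `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "no2_pipeline_config"))
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))

  panel <- read_table_input(cfg$panel, "panel")
  counties <- read_table_input(cfg$counties, "counties")
  if (!all(c("county_id", "zone") %in% names(counties))) {
    abort("`counties` must have columns county_id and zone.",
          class = "no2burden_schema")
  }
  issues <- validate_panel(panel)
  if (nrow(issues)) {
    abort(paste0("stage validate: panel has ", nrow(issues),
                 " schema issue(s); first: ",
                 issues$issue[1], " [column ", issues$column[1], "]"),
          class = "no2burden_schema")
  }
  panel$date <- as.Date(panel$date)
  say("validate: panel OK (%d rows, %d counties)", nrow(panel),
      dplyr::n_distinct(panel$county_id))

  annual <- if (is.null(cfg$annual)) {
    panel |>
      mutate(year = as.integer(format(.data$date, "%Y"))) |>
      group_by(.data$county_id, .data$year) |>
      summarise(n_admissions = sum(.data$admissions),
                no2_annual_mean = mean(.data$no2), .groups = "drop")
  } else read_table_input(cfg$annual, "annual")
  costs <- if (is.null(cfg$costs)) {
    select(counties, "county_id", "avg_expense", "avg_stay")
  } else read_table_input(cfg$costs, "costs")

  # stage 1
  estimates <- purrr::map_dfr(cfg$causes, function(cz) {
    fit_all_counties(dplyr::filter(panel, .data$cause == cz), counties,
                     cause = cz, confounders = cfg$confounders,
                     lag = cfg$lag, co_pollutant = cfg$co_pollutant)
  })
  exclusions <- attr(estimates, "exclusions") %||% tibble()
  if (nrow(estimates) == 0) {
    abort("stage fit: no county could be fitted.", class = "no2burden_stage")
  }
  say("fit: %d county-level estimates (%d excluded)",
      dplyr::n_distinct(estimates$county_id), nrow(exclusions))

  # stage 2
  pooled <- pool_by_stratum(estimates, by = cfg$strata_by,
                            method = cfg$pool_method)
  say("pool: %d pooled rows across strata", nrow(pooled))
  strata <- setdiff(unique(pooled$stratum), "overall")
  differences <- if (all(c("urban", "rural") %in% strata)) {
    pooled |>
      dplyr::group_split(.data$cause, .data$lag) |>
      purrr::map_dfr(function(g) {
        u <- g[g$stratum == "urban", ]; r <- g[g$stratum == "rural", ]
        if (nrow(u) == 0 || nrow(r) == 0) return(tibble())
        urban_rural_test(
          list(beta = u$beta, se = u$se, cause = u$cause, lag = u$lag),
          list(beta = r$beta, se = r$se, cause = r$cause, lag = r$lag))
      })
  } else tibble()

  # stage 3
  pooled_b <- dplyr::filter(pooled, .data$lag == cfg$burden_lag,
                            .data$stratum != "overall")
  if (nrow(pooled_b) == 0) {
    pooled_b <- dplyr::filter(pooled, .data$lag == cfg$burden_lag)
  }
  burden <- scenario_report(pooled_b, annual, costs, counties, aqg = cfg$aqg)
  say("burden: %d scenario rows (AQG %s)", nrow(burden),
      paste(cfg$aqg, collapse = ", "))

  curve <- NULL
  if (cfg$fit_curves) {
    rngs <- panel |>
      group_by(.data$county_id) |>
      summarise(lo = min(.data$no2), hi = max(.data$no2), .groups = "drop")
    boundary <- c(min(rngs$lo), max(rngs$hi))
    ok <- rngs$county_id[rngs$lo < min(cfg$curve_knots) &
                           rngs$hi > max(cfg$curve_knots)]
    fits <- panel |>
      dplyr::filter(.data$county_id %in% ok, .data$cause == cfg$causes[1]) |>
      dplyr::group_split(.data$county_id) |>
      purrr::map(~ tryCatch(
        fit_nonlinear_no2(.x, cause = cfg$causes[1], knots = cfg$curve_knots,
                          boundary = boundary, confounders = cfg$confounders),
        error = function(e) NULL)) |>
      purrr::compact()
    if (length(fits)) {
      curve <- pool_curves(fits, reference = mean(panel$no2))
      say("curve: meta-smoothed over %d counties (%s)", length(fits),
          attr(curve, "pooling"))
    } else say("curve: no county spanned both knots; skipped")
  }

  manifest <- list(config_hash = pipeline_hash(cfg),
                   package = "no2burden",
                   package_version = as.character(utils::packageVersion("no2burden")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = cfg$seed,
                   excluded_counties = exclusions$county_id %||% character())

  out <- structure(list(estimates = estimates, pooled = pooled,
                        differences = differences, burden = burden,
                        curve = curve, exclusions = exclusions,
                        log = log, manifest = manifest),
                   class = "no2_pipeline_result")
  if (!is.null(cfg$out_dir)) write_pipeline_result(out, cfg$out_dir)
  out
}

#' Write a pipeline report bundle
#'
#' Emits `estimates.csv`, `pooled.csv`, `differences.csv`, `burden.csv`,
#' optionally `curve.csv`, plus `manifest.json` and `run.log`.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  stopifnot(inherits(result, "no2_pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$estimates, file.path(dir, "estimates.csv"))
  readr::write_csv(result$pooled, file.path(dir, "pooled.csv"))
  readr::write_csv(result$differences, file.path(dir, "differences.csv"))
  readr::write_csv(result$burden, file.path(dir, "burden.csv"))
  if (!is.null(result$curve)) {
    readr::write_csv(as_tibble(result$curve), file.path(dir, "curve.csv"))
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(result$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.no2_pipeline_result <- function(x, ...) {
  cat("Three-stage NO2 admission analysis\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}
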