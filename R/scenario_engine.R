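#' @title Policy scenario analysis
#' @description Policy levers are expressed as multiplicative overrides of
#'   model constants applied as a step change at `t = 0`; each scenario run is
#'   compared against the baseline trajectory (endpoint deltas, dominance
#'   fraction, sign-change times of the difference). The four built-in
#'   scenarios double workforce competence (S1), double the response speed
#'   (S2), halve the number of pharmacists in the prescribing team (S3), and
#'   combine a doubling of all three human-resource levers (S4).
#' @name scenario_engine
NULL

#' Create a scenario specification
#'
#' @param name scenario name.
#' @param overrides named numeric vector/list: parameter field -> positive
#'   multiplier applied at `t = 0`.
#' @param description free-text description.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, overrides = list(), description = "") {
  overrides <- as.list(overrides)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("overrides must be named")
    unknown <- setdiff(names(overrides), parameter_names())
    if (length(unknown))
      stop("override field(s) not in the parameter set: ",
           paste(unknown, collapse = ", "))
    vals <- unlist(overrides)
    if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0))
      stop("override multipliers must be finite and > 0")
  }
  structure(list(name = name, overrides = overrides,
                 description = description),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  ov <- if (length(x$overrides))
    paste(names(x$overrides), unlist(x$overrides), sep = " x ", collapse = ", ")
  else "(none)"
  cat("<scenario_spec> ", x$name, ": ", ov, "\n", sep = "")
  invisible(x)
}

#' The four built-in policy scenarios
#'
#' S1 doubles workforce competence; S2 doubles the base response speed; S3
#' halves the number of pharmacists in the prescribing team; S4 simultaneously
#' doubles competence, response speed and pharmacist involvement (the mirrored
#' increase of the S3 lever).
#'
#' @return list of four [scenario_spec()]s named `S1`..`S4`.
#' @export
builtin_scenarios <- function() {
  list(
    S1 = scenario_spec("S1",
      list(workforce_competence = 2),
      "Increase the competence of human resources (doubled)"),
    S2 = scenario_spec("S2",
      list(response_speed_base = 2),
      "Increase the response speed (doubled)"),
    S3 = scenario_spec("S3",
      list(pharmacists_in_team = 0.5),
      "Pharmacists in the prescribing team reduced by half"),
    S4 = scenario_spec("S4",
      list(workforce_competence = 2, response_speed_base = 2,
           pharmacists_in_team = 2),
      "Simultaneous increase of competence, response speed and pharmacist involvement")
  )
}

#' Apply a scenario to a parameter set
#'
#' Multiplies the overridden fields and leaves every other field untouched;
#' the result is re-validated (an override that pushes a field out of its
#' valid range is an error).
#'
#' @param params parameter set.
#' @param spec a [scenario_spec()].
#' @return the modified, validated parameter set.
#' @export
apply_scenario <- function(params, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  params <- as.list(params)
  for (f in names(spec$overrides))
    params[[f]] <- params[[f]] * spec$overrides[[f]]
  assert_valid_parameters(params)
}

#' Compare one variable between two trajectories
#'
#' @param base,alt trajectories on the same time grid.
#' @param variable variable name present in both.
#' @return list with `variable`, `endpoint_delta` (`alt - base` at the final
#'   time), `dominance_fraction` (share of time points after the start where
#'   `alt > base` strictly; ties count against dominance), and
#'   `crossing_times` (strictly increasing times where the difference changes
#'   sign, located by linear interpolation).
#' @export
compare_trajectories <- function(base, alt, variable) {
  stopifnot(inherits(base, "sd_trajectory"), inherits(alt, "sd_trajectory"))
  if (length(base$times) != length(alt$times) ||
      max(abs(base$times - alt$times)) > 1e-9)
    stop("trajectories are not on the same time grid")
  b <- trajectory_series(base, variable)
  a <- trajectory_series(alt, variable)
  d <- a - b
  after <- seq_along(d)[-1L]  # time points after the start
  dominance <- mean(d[after] > 0)

  crossings <- numeric()
  sgn <- sign(d)
  last <- 0
  for (i in seq_along(d)) {
    if (sgn[i] == 0) next
    if (last != 0 && sgn[i] != last) {
      j <- max(which(sgn[seq_len(i - 1L)] == last))
      t0 <- base$times[j]; t1 <- base$times[i]
      d0 <- d[j]; d1 <- d[i]
      crossings <- c(crossings, t0 + (t1 - t0) * (-d0) / (d1 - d0))
    }
    last <- sgn[i]
  }
  list(variable = variable,
       endpoint_delta = d[length(d)],
       dominance_fraction = dominance,
       crossing_times = crossings)
}

#' Run the baseline and all built-in scenarios
#'
#' Simulates the baseline and one run per scenario (internal adaptation stocks
#' initialized at the baseline operating point, so a step change at `t = 0`
#' produces its adjustment transient), then compares each scenario to the
#' baseline for the reported variables.
#'
#' @param params baseline parameter set.
#' @param config a [sim_config()].
#' @param scenarios list of [scenario_spec()]s; defaults to
#'   [builtin_scenarios()].
#' @param variables variables to compare.
#' @return object of class `scenario_suite`: list with `baseline` (trajectory)
#'   and `scenarios`, a named list with per-scenario `spec`, `trajectory`,
#'   `comparisons` (one [compare_trajectories()] entry per variable) and
#'   `patterns` (trend labels of the scenario profit series).
#' @export
run_scenario_suite <- function(params, config = sim_config(),
                               scenarios = builtin_scenarios(),
                               variables = c("pharmacy_profit",
                                             "total_expiring_medicines",
                                             "total_disposed_medicines")) {
  params <- assert_valid_parameters(params)
  base_model <- build_pharmacy_model(params)
  baseline <- simulate(base_model, params, config)

  runs <- lapply(scenarios, function(spec) {
    p2 <- tryCatch(apply_scenario(params, spec), error = function(e)
      stop("scenario ", spec$name, ": ", conditionMessage(e)))
    model <- build_pharmacy_model(p2, init_params = params)
    traj <- tryCatch(simulate(model, p2, config), error = function(e)
      stop("scenario ", spec$name, ": ", conditionMessage(e)))
    comparisons <- lapply(variables, function(v)
      compare_trajectories(baseline, traj, v))
    names(comparisons) <- variables
    list(spec = spec, trajectory = traj, comparisons = comparisons,
         patterns = classify_trend(trajectory_series(traj, "pharmacy_profit"),
                                   traj$times))
  })
  names(runs) <- vapply(scenarios, `[[`, "", "name")
  structure(list(baseline = baseline, scenarios = runs, config = config),
            class = "scenario_suite")
}

#' Check the documented scenario properties
#'
#' Evaluates, on a [run_scenario_suite()] result, the qualitative scenario
#' responses the reference calibration must reproduce:
#' \itemize{
#'   \item S1: scenario profit strictly above baseline at every time after 0.
#'   \item S2: profit initially below baseline, exactly one crossing within
#'     the first six months, above baseline afterwards; and the expiring stock
#'     at the horizon below baseline.
#'   \item S3: profit at or below baseline at every time.
#'   \item S4: profit at or above baseline at every time, and the final profit
#'     at least that of each single-lever scenario.
#' }
#'
#' @param suite a `scenario_suite`.
#' @return named logical vector of the six property checks.
#' @export
scenario_properties <- function(suite) {
  stopifnot(inherits(suite, "scenario_suite"))
  prof <- function(s) trajectory_series(suite$scenarios[[s]]$trajectory,
                                        "pharmacy_profit")
  base <- trajectory_series(suite$baseline, "pharmacy_profit")
  times <- suite$baseline$times
  after <- times > times[1L]
  final <- length(times)

  cmp2 <- suite$scenarios$S2$comparisons$pharmacy_profit
  d2 <- prof("S2") - base
  s2_cross <- cmp2$crossing_times
  s2_ok <- length(s2_cross) == 1L && s2_cross[1L] > 0 && s2_cross[1L] <= 6 &&
    any(d2[after] < 0) &&
    all(d2[times > s2_cross[1L] + 1e-9] > 0)
  e2 <- trajectory_series(suite$scenarios$S2$trajectory,
                          "total_expiring_medicines")
  e_base <- trajectory_series(suite$baseline, "total_expiring_medicines")

  profits_final <- vapply(c("S1", "S2", "S3"), function(s) prof(s)[final], 0)

  c(
    s1_profit_dominates = all((prof("S1") - base)[after] > 0),
    s2_single_early_crossing = s2_ok,
    s2_expiring_reduced = e2[final] < e_base[final],
    s3_profit_below = all((prof("S3") - base)[after] <= 0),
    s4_profit_dominates = all((prof("S4") - base)[after] >= 0),
    s4_best_endpoint = prof("S4")[final] >= max(profits_final)
  )
}

#' Flat comparison summary of a scenario suite
#'
#' @param suite a `scenario_suite`.
#' @return data.frame with one row per scenario x variable: endpoint delta,
#'   dominance fraction and number of crossings.
#' @export
scenario_summary <- function(suite) {
  stopifnot(inherits(suite, "scenario_suite"))
  rows <- list()
  for (s in names(suite$scenarios)) {
    for (cmp in suite$scenarios[[s]]$comparisons) {
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = s, variable = cmp$variable,
        endpoint_delta = cmp$endpoint_delta,
        dominance_fraction = cmp$dominance_fraction,
        n_crossings = length(cmp$crossing_times))
    }
  }
  do.call(rbind, rows)
}

#' Read scenario specifications from a JSON or YAML file
#'
#' The file holds a list of objects with fields `name`, `overrides` (map
#' field -> multiplier) and optional `description`.
#'
#' @param path file path (`.json`, `.yaml` or `.yml`).
#' @return list of [scenario_spec()]s.
#' @export
read_scenarios <- function(path) {
  raw <- if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    read_config_file(path)
  }
  if (!is.list(raw)) stop("scenario file must hold a list of scenarios")
  lapply(raw, function(x) {
    if (is.null(x$name)) stop("scenario entry without a name")
    scenario_spec(x$name, x$overrides %||% list(), x$description %||% "")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
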