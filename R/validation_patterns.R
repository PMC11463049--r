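#' @title Model validation: trend classification and structural tests
#' @description Operational implementations of the classical system dynamics
#'   model tests — structure verification (equation dependencies match the
#'   documented influence structure), parameter verification (values inside
#'   their plausible ranges) and boundary adequacy (zero-limit behaviour of
#'   the resident pipeline) — plus a deterministic trend-pattern classifier
#'   that turns qualitative trajectory descriptions ("upward", "initial
#'   surge", "fluctuates sinusoidally") into assertable predicates.
#' @name validation_patterns
NULL

PATTERN_LABELS <- c("increasing", "decreasing", "accelerating", "decelerating",
                    "initially_flat", "initial_surge", "oscillatory",
                    "constant")

monthly_resample <- function(series, times) {
  months <- seq(ceiling(min(times) - 1e-9), floor(max(times) + 1e-9))
  idx <- vapply(months, function(m) which.min(abs(times - m)), 0L)
  list(months = months, values = series[idx])
}

#' Classify the qualitative trend of a series
#'
#' The series is resampled to monthly points (nearest grid point, so labels do
#' not depend on the integration step) and tested against fixed operational
#' definitions. With `x` the monthly values over months `m0..T`,
#' `D1 = x(mid) - x(m0)` and `D2 = x(T) - x(mid)` (`mid` the midpoint month):
#' \describe{
#'   \item{increasing}{`x(T) > x(m0)` and every monthly difference `>= -tol`,
#'     `tol = 1e-6 * range(x)`.}
#'   \item{decreasing}{mirror image.}
#'   \item{accelerating}{`D2 > D1 > 0`.}
#'   \item{decelerating}{`D1 > D2 > 0`.}
#'   \item{initially_flat}{`|x(m0+2) - x(m0)| <= 0.05 * |x(T) - x(m0)|`.}
#'   \item{initial_surge}{mean slope over the first two months strictly
#'     exceeds the mean slope over the remainder, both positive.}
#'   \item{oscillatory}{after subtracting the least-squares line, at least two
#'     strict local maxima and two strict local minima.}
#'   \item{constant}{`range(x) <= 1e-6 * max(1, max(|x|))` (an absolute
#'     floor of 1 keeps the test meaningful for all-zero series).}
#' }
#'
#' The classifier is total (every finite series gets a, possibly empty, label
#' set), deterministic, and scale/offset invariant for positive scalings.
#'
#' @param series numeric vector of values.
#' @param times numeric vector of times in months, uniformly spaced,
#'   length >= 3.
#' @return character vector, a subset of the pattern labels.
#' @export
classify_trend <- function(series, times) {
  if (length(series) != length(times) || length(series) < 3L)
    stop("need >= 3 points with matching times")
  if (!all(is.finite(series)) || !all(is.finite(times)))
    stop("series and times must be finite")
  steps <- diff(times)
  if (max(steps) - min(steps) > 1e-9 * max(abs(steps)))
    stop("times must be uniformly spaced")

  rs <- monthly_resample(series, times)
  x <- rs$values
  m <- rs$months
  if (length(x) < 3L) stop("series must span at least 3 monthly points")
  rng <- max(x) - min(x)
  tol <- 1e-6 * rng
  labels <- character()

  if (rng <= 1e-6 * max(1, max(abs(x)))) labels <- c(labels, "constant")
  n <- length(x)
  if (x[n] > x[1L] && all(diff(x) >= -tol)) labels <- c(labels, "increasing")
  if (x[n] < x[1L] && all(diff(x) <= tol)) labels <- c(labels, "decreasing")

  mid <- which.min(abs(m - (m[1L] + m[n]) / 2))
  d1 <- x[mid] - x[1L]
  d2 <- x[n] - x[mid]
  if (d2 > d1 && d1 > 0 && d2 > 0) labels <- c(labels, "accelerating")
  if (d1 > d2 && d2 > 0) labels <- c(labels, "decelerating")

  i2 <- which(m == m[1L] + 2L)
  if (length(i2) == 1L && n > i2) {
    total <- x[n] - x[1L]
    if (abs(x[i2] - x[1L]) <= 0.05 * abs(total))
      labels <- c(labels, "initially_flat")
    slope_early <- (x[i2] - x[1L]) / 2
    slope_late <- (x[n] - x[i2]) / (m[n] - m[i2])
    if (slope_early > slope_late && slope_early > 0 && slope_late > 0)
      labels <- c(labels, "initial_surge")
  }

  detr <- stats::lm.fit(cbind(1, m), x)$residuals
  interior <- seq(2L, n - 1L)
  maxima <- sum(detr[interior] > detr[interior - 1L] &
                  detr[interior] > detr[interior + 1L])
  minima <- sum(detr[interior] < detr[interior - 1L] &
                  detr[interior] < detr[interior + 1L])
  if (maxima >= 2L && minima >= 2L) labels <- c(labels, "oscillatory")

  labels
}

#' Structure verification test
#'
#' Confirms that the dependency structure of a built model matches the
#' documented influence table: for every flow and auxiliary, the set of names
#' its equation reads must equal the table entry. Variables absent from the
#' table, table entries absent from the model, and driver mismatches are all
#' reported.
#'
#' @param model an [sd_model()].
#' @param influence named list mapping variable names to their required driver
#'   sets, e.g. [pharmacy_influence_table()].
#' @return list with `ok` and a data.frame `diffs`
#'   (columns `variable`, `problem`, `detail`).
#' @export
structure_verification <- function(model,
                                   influence = pharmacy_influence_table()) {
  stopifnot(inherits(model, "sd_model"))
  diffs <- list()
  add <- function(variable, problem, detail)
    diffs[[length(diffs) + 1L]] <<- data.frame(variable = variable,
                                               problem = problem,
                                               detail = detail)
  eval_vars <- names(model$kinds)[model$kinds %in% c("auxiliary", "flow")]
  for (nm in eval_vars) {
    if (!nm %in% names(influence)) {
      add(nm, "not_in_table", "model variable missing from influence table")
      next
    }
    got <- sort(model$depends_on[[nm]])
    want <- sort(influence[[nm]])
    extra <- setdiff(got, want)
    missing <- setdiff(want, got)
    if (length(extra))
      add(nm, "extra_driver", paste(extra, collapse = ", "))
    if (length(missing))
      add(nm, "missing_driver", paste(missing, collapse = ", "))
  }
  for (nm in setdiff(names(influence), eval_vars))
    add(nm, "not_in_model", "influence table entry has no model variable")
  diffs <- if (length(diffs)) do.call(rbind, diffs)
           else data.frame(variable = character(), problem = character(),
                           detail = character())
  list(ok = nrow(diffs) == 0L, diffs = diffs)
}

#' Parameter verification test
#'
#' Checks every parameter against its documented valid and plausible range.
#'
#' @param params parameter set.
#' @return list with `ok` and `violations` (character vector).
#' @export
parameter_verification <- function(params) {
  validate_parameter_set(params)
}

# Zero-limit settings: exact 0 for rates; graduation is driven to ~0 by a very
# long residency rather than an infinite one, keeping the division well posed.
BOUNDARY_LONG_RESIDENCY <- 1e6

#' Boundary adequacy test
#'
#' Drives the resident pipeline towards its zero limits and asserts that
#' dependent variables respond rationally:
#' \enumerate{
#'   \item `resident_intake_rate = 0`: the number of residents decays
#'     monotonically (and matches the closed form `R0 * exp(-t / duration)`
#'     up to integrator error).
#'   \item intake 0 and residency duration effectively infinite (graduation
#'     ~ 0): the number of residents stays constant.
#'   \item no residents at all (initial 0, intake 0): the resident-driven
#'     component of the expiring inflow is exactly zero and the expiring stock
#'     stays strictly below the baseline run at the horizon.
#' }
#'
#' @param params parameter set (the baseline the limits are taken from).
#' @param config a [sim_config()].
#' @return list with `ok` and `cases` (list of per-case results, each with
#'   `case`, `ok`, `detail`).
#' @export
boundary_adequacy_test <- function(params, config = sim_config()) {
  params <- assert_valid_parameters(params)
  run <- function(p) simulate(build_pharmacy_model(p, init_params = p),
                              p, config)
  base <- run(params)
  cases <- list()

  p1 <- params; p1$resident_intake_rate <- 0
  tr1 <- run(p1)
  r1 <- trajectory_series(tr1, "number_of_residents")
  mono <- all(diff(r1) <= 1e-9 * max(1, r1[1L]))
  exact <- r1[1L] * exp(-(tr1$times - tr1$times[1L]) / params$residency_duration)
  dt_err <- expm1((tr1$times[length(tr1$times)] - tr1$times[1L]) *
                    config$dt / (2 * params$residency_duration^2))
  close <- max(abs(r1 - exact)) <= max(0.01, 2 * dt_err) * max(r1[1L], 1)
  cases$zero_intake <- list(
    case = "resident_intake_rate -> 0", ok = mono && close,
    detail = sprintf("monotone non-increasing: %s; max deviation from R0*exp(-t/T): %.3g",
                     mono, max(abs(r1 - exact))))

  p2 <- params
  p2$resident_intake_rate <- 0
  p2$residency_duration <- BOUNDARY_LONG_RESIDENCY
  tr2 <- run(p2)
  r2 <- trajectory_series(tr2, "number_of_residents")
  const <- (max(r2) - min(r2)) <= 1e-4 * max(1, abs(r2[1L]))
  cases$zero_graduation <- list(
    case = "intake 0 and graduation ~ 0", ok = const,
    detail = sprintf("relative drift %.3g", (max(r2) - min(r2)) / max(1, abs(r2[1L]))))

  p3 <- params
  p3$resident_intake_rate <- 0
  p3$initial_residents <- 0
  tr3 <- run(p3)
  inflow3 <- trajectory_series(tr3, "expiring_inflow")
  resident_component_zero <- all(abs(inflow3 - params$expiry_inflow_base) <=
                                   1e-12 * max(1, params$expiry_inflow_base))
  e_lim <- trajectory_series(tr3, "total_expiring_medicines")
  e_base <- trajectory_series(base, "total_expiring_medicines")
  n <- length(e_base)
  slower <- e_lim[n] < e_base[n]
  cases$no_residents <- list(
    case = "initial residents 0 and intake 0",
    ok = resident_component_zero && slower,
    detail = sprintf("resident inflow component zero: %s; expiring at horizon %.4g (limit) vs %.4g (baseline)",
                     resident_component_zero, e_lim[n], e_base[n]))

  list(ok = all(vapply(cases, `[[`, TRUE, "ok")), cases = cases)
}

#' Reported trajectory-pattern checks for a pharmacy run
#'
#' Evaluates the seven qualitative pattern assertions the reference
#' calibration is required to reproduce on a 24-month run:
#' cumulative disposed medicines increasing and accelerating; expiring stock
#' initially flat (first two months) and increasing from month 2 onward;
#' cumulative disposal cost increasing and accelerating; cumulative sales of
#' low-consumption medicine showing an initial surge with continued growth;
#' pharmacy profit increasing and decelerating; and both high-consumption
#' buying and selling oscillatory.
#'
#' @param trajectory output of [simulate()] on the pharmacy model.
#' @param params the parameter set of the run.
#' @return named logical vector of the seven checks.
#' @export
pattern_checks <- function(trajectory, params) {
  s <- trajectory$series
  times <- trajectory$times
  rep_tab <- derive_reports(trajectory, params)

  lab <- function(x) classify_trend(x, times)
  disposed <- lab(s$total_disposed_medicines)
  cost <- lab(s$cumulative_disposal_cost)
  profit <- lab(s$pharmacy_profit)
  sales <- lab(rep_tab$table$cumulative_sales_low)
  expiring <- lab(s$total_expiring_medicines)

  # "flat then increasing": flat over the first two months, monotone
  # non-decreasing (with net growth) from month 2 onward.
  em <- monthly_resample(s$total_expiring_medicines, times)
  from2 <- em$values[em$months >= em$months[1L] + 2L]
  tol <- 1e-6 * (max(em$values) - min(em$values))
  expiring_rises_after <- length(from2) >= 2L &&
    all(diff(from2) >= -tol) && from2[length(from2)] > from2[1L]

  c(
    disposed_increasing_accelerating =
      all(c("increasing", "accelerating") %in% disposed),
    expiring_flat_then_increasing =
      ("initially_flat" %in% expiring) && expiring_rises_after,
    disposal_cost_increasing_accelerating =
      all(c("increasing", "accelerating") %in% cost),
    sales_low_initial_surge =
      ("initial_surge" %in% sales) && ("increasing" %in% sales),
    profit_increasing_decelerating =
      all(c("increasing", "decelerating") %in% profit),
    buying_high_oscillatory = "oscillatory" %in% lab(s$buying_high),
    selling_high_oscillatory = "oscillatory" %in% lab(s$selling_high)
  )
}

#' Full validation report
#'
#' Runs the structure verification, parameter verification and boundary
#' adequacy suites, plus the trajectory pattern checks, for one parameter set.
#'
#' @param params parameter set.
#' @param config a [sim_config()].
#' @return list of class `validation_report` with elements `structure`,
#'   `parameters`, `boundary`, `patterns` and `ok` (overall pass of the three
#'   named tests; pattern results are reported alongside).
#' @export
validation_report <- function(params = reference_parameters(),
                              config = sim_config()) {
  params <- assert_valid_parameters(params)
  model <- build_pharmacy_model(params)
  structure_res <- structure_verification(model, pharmacy_influence_table())
  param_res <- parameter_verification(params)
  boundary_res <- boundary_adequacy_test(params, config)
  traj <- simulate(model, params, config)
  patterns <- pattern_checks(traj, params)
  structure(list(
    structure = structure_res,
    parameters = param_res,
    boundary = boundary_res,
    patterns = patterns,
    ok = structure_res$ok && param_res$ok && boundary_res$ok && all(patterns)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n",
      "  structure verification: ", if (x$structure$ok) "pass" else "FAIL", "\n",
      "  parameter verification: ", if (x$parameters$ok) "pass" else "FAIL", "\n",
      "  boundary adequacy:      ", if (x$boundary$ok) "pass" else "FAIL", "\n",
      sep = "")
  cat("  patterns:\n")
  for (nm in names(x$patterns))
    cat("    ", nm, ": ", if (x$patterns[[nm]]) "pass" else "FAIL", "\n", sep = "")
  invisible(x)
}
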