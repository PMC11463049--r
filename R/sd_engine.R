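#' @title Stock-and-flow system dynamics engine
#' @description Declarative model definitions and a fixed-step forward-Euler
#'   integrator. Models are built from four kinds of variables: stocks
#'   (accumulations changed only by their flows), flows (rates, units per
#'   month), auxiliaries (algebraic intermediates) and constants (supplied by
#'   a parameter map at simulation time). Equations are quoted R expressions;
#'   the names an equation reads are extracted automatically and become the
#'   variable's dependency list, so the declared structure of the model always
#'   matches the structure that is actually computed.
#' @name sd_engine
NULL

SD_KINDS <- c("stock", "flow", "auxiliary", "constant")

new_sd_variable <- function(name, kind, units, equation = NULL,
                            initial = NULL, inflows = character(),
                            outflows = character(), non_negative = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!kind %in% SD_KINDS) stop("unknown variable kind: ", kind)
  structure(list(name = name, kind = kind, units = units,
                 equation = equation, initial = initial,
                 inflows = inflows, outflows = outflows,
                 non_negative = isTRUE(non_negative)),
            class = "sd_variable")
}

#' Define an auxiliary variable
#'
#' @param name variable name (must be a valid R symbol).
#' @param eq quoted R expression computing the value from other variables,
#'   constants and the simulation time `t` (in months).
#' @param units unit string (checked for presence only, no dimensional algebra).
#' @return an `sd_variable` of kind `"auxiliary"`.
#' @examples
#' sd_aux("wage_cost", quote(avg_salary * staff_count), "MU/month")
#' @export
sd_aux <- function(name, eq, units = "1") {
  new_sd_variable(name, "auxiliary", units, equation = eq)
}

#' Define a flow variable
#'
#' Flows are rate variables (units per month). A flow may be attached as
#' inflow and/or outflow of any number of stocks; flows are signed unless
#' limited by a non-negative stock (see [simulate()]).
#'
#' @inheritParams sd_aux
#' @return an `sd_variable` of kind `"flow"`.
#' @export
sd_flow <- function(name, eq, units = "1/month") {
  new_sd_variable(name, "flow", units, equation = eq)
}

#' Define a stock variable
#'
#' Stocks carry no equation; their derivative is the sum of their inflows
#' minus the sum of their outflows.
#'
#' @param name stock name.
#' @param initial initial value: a number, or a quoted expression of model
#'   constants (evaluated once against the parameter map before integration).
#' @param inflows,outflows character vectors of flow names.
#' @param units unit string.
#' @param non_negative if `TRUE` the stock is physical material and may never
#'   go below zero: whenever a step would overdraw it, its outflows are scaled
#'   down proportionally so the stock floors at zero.
#' @return an `sd_variable` of kind `"stock"`.
#' @export
sd_stock <- function(name, initial, inflows = character(),
                     outflows = character(), units = "1",
                     non_negative = FALSE) {
  if (!(is.numeric(initial) && length(initial) == 1L) && !is.language(initial))
    stop("initial must be a single number or a quoted expression")
  new_sd_variable(name, "stock", units, initial = initial,
                  inflows = inflows, outflows = outflows,
                  non_negative = non_negative)
}

#' Declare a model constant
#'
#' Constants receive their values from the parameter map passed to
#' [simulate()]; declaring them makes missing parameters a hard error.
#'
#' @param name constant name.
#' @param units unit string.
#' @return an `sd_variable` of kind `"constant"`.
#' @export
sd_constant <- function(name, units = "1") {
  new_sd_variable(name, "constant", units)
}

eq_dependencies <- function(eq, data_names) {
  setdiff(all.vars(eq), c("t", "pi", data_names))
}

#' Assemble a system dynamics model
#'
#' Validates that every referenced name exists, that names are unique, that
#' stocks' inflows/outflows are flows, and that the dependency graph among
#' non-stock variables is acyclic so auxiliaries and flows can be evaluated
#' in a single topological pass per step.
#'
#' @param name model name.
#' @param variables list of [sd_stock()], [sd_flow()], [sd_aux()] and
#'   [sd_constant()] definitions, in any order.
#' @param data optional named list of auxiliary data objects (for example
#'   tabulated schedules) made visible to equations but not treated as model
#'   variables.
#' @return an object of class `sd_model`.
#' @export
sd_model <- function(name, variables, data = list()) {
  stopifnot(is.list(variables), all(vapply(variables, inherits, TRUE, "sd_variable")))
  nms <- vapply(variables, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("duplicate variable names: ", paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(variables) <- nms
  kinds <- vapply(variables, `[[`, "", "kind")
  data_names <- names(data)

  deps <- lapply(variables, function(v) {
    if (v$kind %in% c("auxiliary", "flow")) eq_dependencies(v$equation, data_names)
    else character()
  })
  names(deps) <- nms

  for (v in variables) {
    refs <- c(deps[[v$name]], v$inflows, v$outflows)
    unknown <- setdiff(refs, nms)
    if (length(unknown))
      stop("variable '", v$name, "' references unknown name(s): ",
           paste(unknown, collapse = ", "))
    if (v$kind == "stock") {
      bad <- c(v$inflows, v$outflows)[kinds[c(v$inflows, v$outflows)] != "flow"]
      if (length(bad))
        stop("stock '", v$name, "': inflows/outflows must be flows, got: ",
             paste(bad, collapse = ", "))
    }
  }

  order <- topo_order(nms[kinds %in% c("auxiliary", "flow")], deps, kinds)
  structure(list(name = name, variables = variables, kinds = kinds,
                 depends_on = deps, eval_order = order, data = data),
            class = "sd_model")
}

# Deterministic Kahn topological sort over auxiliaries/flows; dependencies on
# stocks and constants are boundary inputs and ignored. Lexicographic
# tie-break so the evaluation order is independent of declaration order.
topo_order <- function(eval_names, deps, kinds) {
  pending <- sort(eval_names)
  resolved <- character()
  done <- names(kinds)[kinds %in% c("stock", "constant")]
  while (length(pending)) {
    ready <- pending[vapply(pending, function(n)
      all(deps[[n]] %in% c(done, resolved)), TRUE)]
    if (!length(ready)) {
      stop("circular dependency among auxiliaries/flows involving: ",
           paste(pending, collapse = ", "),
           " (instantaneous loops must pass through a stock)")
    }
    resolved <- c(resolved, ready[1L])
    pending <- setdiff(pending, ready[1L])
  }
  resolved
}

#' @export
print.sd_model <- function(x, ...) {
  k <- table(factor(x$kinds, levels = SD_KINDS))
  cat("<sd_model> ", x$name, "\n",
      "  stocks: ", k[["stock"]], "  flows: ", k[["flow"]],
      "  auxiliaries: ", k[["auxiliary"]], "  constants: ", k[["constant"]],
      "\n", sep = "")
  invisible(x)
}

#' Simulation configuration
#'
#' @param start_time,stop_time simulation window in months.
#' @param dt integration step in months; `(stop_time - start_time) / dt` must
#'   be an integer number of steps.
#' @param seed optional integer seed recorded with the run (the integrator
#'   itself is deterministic; the seed is threaded to stochastic inputs such
#'   as cohort sampling).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(start_time = 0, stop_time = 24, dt = 0.25, seed = NULL) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (stop_time <= start_time) stop("stop_time must exceed start_time")
  n <- (stop_time - start_time) / dt
  if (abs(n - round(n)) > 1e-8)
    stop("(stop_time - start_time) / dt must be an integer number of steps")
  structure(list(start_time = start_time, stop_time = stop_time, dt = dt,
                 n_steps = as.integer(round(n)), seed = seed),
            class = "sim_config")
}

sd_eval_env <- function(model) {
  helpers <- new.env(parent = baseenv())
  for (nm in names(model$data)) assign(nm, model$data[[nm]], envir = helpers)
  assign("step_lookup", function(values, t, dt, start = 0) {
    i <- min(length(values), max(1L, floor((t - start) / dt + 1e-9) + 1L))
    values[[i]]
  }, envir = helpers)
  new.env(parent = helpers)
}

#' Run a forward-Euler simulation
#'
#' At each step all auxiliaries and flows are evaluated synchronously from the
#' time-`t` state, then every stock is advanced by `dt * (inflows - outflows)`.
#' Stocks flagged `non_negative` never go below zero: when a step would
#' overdraw such a stock its outflows are scaled down proportionally (the
#' scaled flow values are what downstream stocks receive and what the
#' trajectory records, so material is conserved). Runs are deterministic
#' given `(model, params, config)`.
#'
#' @param model an [sd_model()].
#' @param params named list or vector supplying every declared constant.
#' @param config a [sim_config()].
#' @return an `sd_trajectory`: list with `times` (months) and `series`, a
#'   named list with one numeric vector per stock/flow/auxiliary, all of
#'   length `n_steps + 1`.
#' @export
simulate <- function(model, params, config = sim_config()) {
  stopifnot(inherits(model, "sd_model"), inherits(config, "sim_config"))
  params <- as.list(params)
  const_names <- names(model$kinds)[model$kinds == "constant"]
  missing <- setdiff(const_names, names(params))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))

  stock_names <- names(model$kinds)[model$kinds == "stock"]
  record_names <- names(model$kinds)[model$kinds != "constant"]
  nn_stocks <- stock_names[vapply(model$variables[stock_names],
                                  `[[`, TRUE, "non_negative")]

  penv <- list2env(params[const_names], parent = baseenv())
  state <- vapply(stock_names, function(s) {
    init <- model$variables[[s]]$initial
    val <- if (is.numeric(init)) init else eval(init, penv)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop("initial value of stock '", s, "' is not a finite number")
    val
  }, 0)

  n <- config$n_steps
  times <- config$start_time + (0:n) * config$dt
  out <- matrix(NA_real_, nrow = n + 1L, ncol = length(record_names),
                dimnames = list(NULL, record_names))

  e <- sd_eval_env(model)
  for (nm in const_names) assign(nm, params[[nm]], envir = e)

  for (i in 0:n) {
    t_i <- times[i + 1L]
    assign("t", t_i, envir = e)
    for (s in stock_names) assign(s, state[[s]], envir = e)
    vals <- state
    for (nm in model$eval_order) {
      v <- eval(model$variables[[nm]]$equation, e)
      if (!is.numeric(v) || length(v) != 1L)
        stop("equation of '", nm, "' did not return a single number")
      if (!is.finite(v))
        stop("non-finite value for '", nm, "' at t = ", t_i)
      assign(nm, v, envir = e)
      vals[[nm]] <- v
    }

    if (i < n) {
      flows <- limit_outflows(vals, state, model, nn_stocks, config$dt)
      vals[names(flows)] <- flows
      for (s in stock_names) {
        v <- model$variables[[s]]
        net <- sum(vals[v$inflows]) - sum(vals[v$outflows])
        new <- state[[s]] + config$dt * net
        if (v$non_negative && new < 0) new <- 0  # floor residual rounding
        state[[s]] <- new
      }
    }
    out[i + 1L, ] <- unlist(vals[record_names])
  }

  structure(list(times = times,
                 series = lapply(as.data.frame(out), identity),
                 model_name = model$name, dt = config$dt,
                 config = config),
            class = "sd_trajectory")
}

# Proportional outflow limiting for non-negative stocks. A flow limited for
# one stock keeps the limited value everywhere (conservation), so the pass is
# iterated to a fixed point: downstream stocks whose inflows shrank may need
# their own outflows rescaled.
limit_outflows <- function(vals, state, model, nn_stocks, dt) {
  flow_names <- names(model$kinds)[model$kinds == "flow"]
  flows <- unlist(vals[flow_names])
  if (!length(nn_stocks)) return(flows)
  for (iter in seq_len(10L)) {
    changed <- FALSE
    for (s in nn_stocks) {
      v <- model$variables[[s]]
      inflow <- sum(flows[v$inflows])
      pos_out <- v$outflows[flows[v$outflows] > 0]
      outflow <- sum(flows[pos_out])
      if (outflow <= 0) next
      projected <- state[[s]] + dt * (inflow - sum(flows[v$outflows]))
      if (projected < -1e-12 * max(1, abs(state[[s]]))) {
        avail <- state[[s]] / dt + inflow -
          sum(flows[setdiff(v$outflows, pos_out)])
        phi <- max(0, min(1, avail / outflow))
        flows[pos_out] <- flows[pos_out] * phi
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  flows
}

#' @export
print.sd_trajectory <- function(x, ...) {
  cat("<sd_trajectory> ", x$model_name, ": ", length(x$times), " points, t = ",
      min(x$times), "..", max(x$times), " months, dt = ", x$dt, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.sd_trajectory <- function(x, ...) {
  cbind(data.frame(time_months = x$times), as.data.frame(x$series))
}

#' Extract one series from a trajectory
#'
#' @param trajectory an `sd_trajectory`.
#' @param variable variable name.
#' @return numeric vector aligned with `trajectory$times`.
#' @export
trajectory_series <- function(trajectory, variable) {
  if (!variable %in% names(trajectory$series))
    stop("trajectory has no series '", variable, "'")
  trajectory$series[[variable]]
}

#' Verify stock/flow bookkeeping of a trajectory
#'
#' Recomputes every stock from its initial value and the recorded flow series
#' (`S(t) = S(0) + sum dt * (inflows - outflows)`) and compares against the
#' recorded stock series, allowing a relative tolerance of `1e-9` per
#' accumulated step.
#'
#' @param trajectory output of [simulate()].
#' @param model the same model the trajectory was produced from.
#' @param config the same [sim_config()] used for the run.
#' @return list with `ok` (logical), and on failure `stock`, `time` and
#'   `discrepancy` of the first violation.
#' @export
check_conservation <- function(trajectory, model, config = NULL) {
  stopifnot(inherits(trajectory, "sd_trajectory"), inherits(model, "sd_model"))
  stock_names <- names(model$kinds)[model$kinds == "stock"]
  if (!all(stock_names %in% names(trajectory$series)))
    stop("trajectory does not match model: missing stock series")
  dt <- trajectory$dt
  n <- length(trajectory$times)
  for (s in stock_names) {
    v <- model$variables[[s]]
    rec <- trajectory$series[[s]]
    net <- rep(0, n)
    for (f in v$inflows)  net <- net + trajectory$series[[f]]
    for (f in v$outflows) net <- net - trajectory$series[[f]]
    expected <- rec[1L] + c(0, cumsum(dt * net[-n]))
    if (v$non_negative) expected <- pmax(expected, 0)
    scale <- max(1, max(abs(rec)))
    tol <- 1e-9 * seq_len(n) * scale + 1e-12 * scale
    bad <- which(abs(expected - rec) > tol)
    if (length(bad)) {
      return(list(ok = FALSE, stock = s, time = trajectory$times[bad[1L]],
                  discrepancy = expected[bad[1L]] - rec[bad[1L]]))
    }
  }
  list(ok = TRUE)
}

#' Export a trajectory as CSV
#'
#' Writes a comma-separated file with a `time_months` first column and one
#' column per variable at full precision.
#'
#' @param trajectory an `sd_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
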