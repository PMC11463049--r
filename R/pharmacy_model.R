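#' @title Inpatient pharmacy drug supply chain model
#' @description The concrete stock-and-flow model of a hospital inpatient
#'   pharmacy's drug supply chain. Six reported stocks — pharmacy profit
#'   (money, may go negative), number of residents, total expiring medicines,
#'   cumulative disposed medicines, inventory of high-consumption medicines,
#'   and cumulative disposal cost — plus two internal adaptation stocks (a
#'   staff-accuracy smooth and a launch-phase sales drive) and the in-transit
#'   pipeline of the ordering delay. Slow-moving ("low-consumption") medicines
#'   accumulate as expiring stock fed by a base arrival rate and resident
#'   over-prescription; they leave by being sold before expiry, transferred to
#'   other pharmacies, or disposed at a cost. Fast-moving ("high-consumption")
#'   medicines are ordered against seasonal demand through a first-order
#'   material delay.
#' @name pharmacy_model
NULL

# Calibration constants of the reference functional forms. The source model
# publishes influence structure and qualitative behaviour but no equations;
# these shape parameters are owned by this implementation (see the methods
# vignette for the rationale behind each form).
pharmacy_calibration <- function() {
  list(
    competence_exponent = 0.5,   # diminishing returns of workforce competence
    pharmacist_coeff    = 0.25,  # service gain per pharmacist in the team
    service_half        = 1.5,   # half-saturation of ordering service factor
    sales_capacity      = 190,   # packs/month at unit drivers
    sales_saturation    = 500,   # packs; expiring-stock half-saturation
    incentive_half      = 12.5,  # MU/pack; unit-margin half-saturation
    transfer_horizon    = 1,     # months of stock committed to transfers
    launch_drive_init   = 2.0,   # launch-phase clearance drive multiplier
    launch_drive_time   = 0.8,   # months; decay time of the launch drive
    error_cost_scale    = 9000,  # MU/month at full relative accuracy gap
    price_ratio_high    = 0.4,   # high-consumption pack price / avg_price_low
    inventory_half      = 800    # packs; inventory half-saturation for sales
  )
}

# name, units, lower bound, upper bound, lower-strict flag
parameter_schema <- function() {
  s <- function(name, units, lo, hi = Inf, strict = FALSE)
    list(name = name, units = units, lo = lo, hi = hi, strict = strict)
  list(
    s("initial_profit", "MU", 0),
    s("initial_residents", "persons", 0),
    s("initial_expiring_stock", "packs", 0),
    s("initial_disposed_total", "packs", 0),
    s("initial_inventory_high", "packs", 0),
    s("workforce_competence", "index", 0, strict = TRUE),
    s("pharmacists_in_team", "persons", 0),
    s("response_speed_base", "index", 0, strict = TRUE),
    s("accuracy_adjust_time", "months", 0, strict = TRUE),
    s("avg_price_low", "MU/pack", 0, strict = TRUE),
    s("profit_margin_low", "fraction", 0, 1),
    s("profit_margin_high", "fraction", 0, 1),
    s("disposal_unit_cost", "MU/pack", 0, strict = TRUE),
    s("avg_salary", "MU/person/month", 0, strict = TRUE),
    s("staff_count", "persons", 0, strict = TRUE),
    s("overhead_cost", "MU/month", 0),
    s("expiry_inflow_base", "packs/month", 0),
    s("resident_overprescription_coeff", "packs/month/person", 0),
    s("expiry_fraction", "1/month", 0, 1, strict = TRUE),
    s("transfer_rate_coeff", "1/month", 0, 1),
    s("monthly_purchase", "packs/month", 0, strict = TRUE),
    s("share_high_consumption", "fraction", 0, 1),
    s("order_delay", "months", 0, strict = TRUE),
    s("demand_high_base", "packs/month", 0, strict = TRUE),
    s("demand_seasonal_amplitude", "fraction", 0, 1),
    s("demand_period", "months", 0, strict = TRUE),
    s("resident_intake_rate", "persons/month", 0),
    s("residency_duration", "months", 0, strict = TRUE)
  )
}

#' Names of the pharmacy model parameters
#' @return character vector of the 28 parameter-set field names.
#' @export
parameter_names <- function() {
  vapply(parameter_schema(), `[[`, "", "name")
}

#' Validate a parameter set
#'
#' Checks presence, numeric type and valid range of every field (fractions in
#' \[0, 1\]; rates, prices and durations positive; initial stocks
#' non-negative).
#'
#' @param params named list or vector of parameter values.
#' @param strict_fields if `TRUE` (default), unknown fields are violations
#'   (catches typos in configuration files).
#' @return list with `ok` (logical) and `violations` (character vector).
#' @export
validate_parameter_set <- function(params, strict_fields = TRUE) {
  params <- as.list(params)
  violations <- character()
  for (f in parameter_schema()) {
    v <- params[[f$name]]
    if (is.null(v)) { violations <- c(violations, paste0(f$name, ": missing")); next }
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      violations <- c(violations, paste0(f$name, ": not a finite number")); next
    }
    low_ok <- if (f$strict) v > f$lo else v >= f$lo
    if (!low_ok)
      violations <- c(violations, sprintf("%s = %g: must be %s %g [%s]",
                                          f$name, v, if (f$strict) ">" else ">=",
                                          f$lo, f$units))
    if (v > f$hi)
      violations <- c(violations, sprintf("%s = %g: must be <= %g [%s]",
                                          f$name, v, f$hi, f$units))
  }
  if (strict_fields) {
    extra <- setdiff(names(params), parameter_names())
    if (length(extra))
      violations <- c(violations, paste0("unknown field(s): ",
                                         paste(extra, collapse = ", ")))
  }
  list(ok = length(violations) == 0L, violations = violations)
}

assert_valid_parameters <- function(params, strict_fields = TRUE) {
  chk <- validate_parameter_set(params, strict_fields)
  if (!chk$ok)
    stop("invalid parameter set:\n  ", paste(chk$violations, collapse = "\n  "))
  invisible(as.list(params))
}

#' The packaged reference parameter set
#'
#' The survey values behind the original calibration (16 inpatient pharmacies)
#' are unpublished; the packaged set is a *synthetic* calibration, chosen so
#' that a 24-month run at `dt = 0.25` reproduces all reported qualitative
#' trajectory patterns and scenario responses (see the methods vignette).
#' Units are abstract: MU (money units), packs, persons, months.
#'
#' @return named list of the 28 model parameters.
#' @export
reference_parameters <- function() {
  path <- system.file("extdata", "reference_parameters_synthetic.json",
                      package = "pharmsd")
  params <- jsonlite::read_json(path, simplifyVector = TRUE)
  assert_valid_parameters(as.list(params))
}

#' Build the pharmacy supply chain model
#'
#' Translates a parameter set into a validated [sd_model()]. Initial values of
#' the internal adaptation stocks (accuracy smooth, ordering pipeline) are
#' computed from `init_params`, which defaults to `params`: policy scenarios
#' pass the baseline set there, so that a parameter step-change at `t = 0`
#' meets a system still adapted to the pre-intervention operating point.
#'
#' @param params parameter set (validated with [validate_parameter_set()]).
#' @param init_params parameter set defining the initial operating point.
#' @return an [sd_model()] with stocks `pharmacy_profit`,
#'   `number_of_residents`, `total_expiring_medicines`,
#'   `total_disposed_medicines`, `inventory_high_consumption`,
#'   `cumulative_disposal_cost` plus internal smooth/delay stocks.
#' @export
build_pharmacy_model <- function(params, init_params = params) {
  params <- assert_valid_parameters(params)
  init_params <- assert_valid_parameters(init_params)
  cal <- pharmacy_calibration()

  resp0 <- with(init_params, response_speed_base *
                  workforce_competence^cal$competence_exponent *
                  (1 + cal$pharmacist_coeff * pharmacists_in_team))
  sf0 <- resp0 / (resp0 + cal$service_half)
  transit0 <- with(init_params, order_delay * share_high_consumption *
                     monthly_purchase) * sf0

  vars <- c(
    lapply(parameter_schema(), function(f) sd_constant(f$name, f$units)),
    list(
      # --- service level and staff adaptation -------------------------------
      sd_aux("response_speed",
             bquote(response_speed_base *
                      workforce_competence^.(cal$competence_exponent) *
                      (1 + .(cal$pharmacist_coeff) * pharmacists_in_team)),
             "index"),
      sd_aux("accuracy_target", quote(response_speed_base), "index"),
      sd_aux("accuracy_gap",
             quote(max(0, (accuracy_target - accuracy) / accuracy_target)),
             "fraction"),
      sd_flow("error_cost", bquote(.(cal$error_cost_scale) * accuracy_gap),
              "MU/month"),

      # --- low-consumption (slow mover) chain -------------------------------
      sd_aux("price_incentive_low",
             bquote((profit_margin_low * avg_price_low) /
                      (profit_margin_low * avg_price_low + .(cal$incentive_half))),
             "fraction"),
      sd_aux("expiry_availability",
             bquote(total_expiring_medicines /
                      (total_expiring_medicines + .(cal$sales_saturation))),
             "fraction"),
      sd_flow("sales_low_before_expiration",
              bquote(.(cal$sales_capacity) * response_speed *
                       price_incentive_low * sales_drive * expiry_availability *
                       (1 - transfer_rate_coeff * .(cal$transfer_horizon))),
              "packs/month"),
      sd_flow("transfer_out",
              quote(transfer_rate_coeff * total_expiring_medicines),
              "packs/month"),
      sd_flow("disposal_rate",
              bquote(expiry_fraction *
                       (1 - transfer_rate_coeff * .(cal$transfer_horizon)) *
                       total_expiring_medicines),
              "packs/month"),
      sd_flow("expiring_inflow",
              quote(expiry_inflow_base +
                      resident_overprescription_coeff * number_of_residents),
              "packs/month"),

      # --- residents --------------------------------------------------------
      sd_flow("resident_intake", quote(resident_intake_rate), "persons/month"),
      sd_flow("graduation_rate",
              quote(number_of_residents / residency_duration),
              "persons/month"),

      # --- high-consumption (fast mover) chain ------------------------------
      sd_aux("demand_high",
             quote(demand_high_base *
                     (1 + demand_seasonal_amplitude *
                        sin(2 * pi * t / demand_period))),
             "packs/month"),
      sd_aux("service_factor",
             bquote(response_speed / (response_speed + .(cal$service_half))),
             "fraction"),
      sd_flow("order_rate_high",
              quote(share_high_consumption * monthly_purchase * service_factor *
                      (demand_high / demand_high_base)),
              "packs/month"),
      sd_aux("inventory_availability",
             bquote(inventory_high_consumption /
                      (inventory_high_consumption + .(cal$inventory_half))),
             "fraction"),
      sd_flow("selling_high", quote(demand_high * inventory_availability),
              "packs/month"),

      # --- money ------------------------------------------------------------
      sd_flow("profit_from_sales_low",
              quote(sales_low_before_expiration * avg_price_low *
                      profit_margin_low),
              "MU/month"),
      sd_flow("profit_from_sales_high",
              bquote(selling_high * avg_price_low * .(cal$price_ratio_high) *
                       profit_margin_high),
              "MU/month"),
      sd_flow("disposal_cost_rate", quote(disposal_rate * disposal_unit_cost),
              "MU/month"),
      sd_flow("wage_cost", quote(avg_salary * staff_count), "MU/month"),
      sd_flow("overhead_outflow", quote(overhead_cost), "MU/month"),

      # --- launch-phase clearance drive (initial sales surge) ----------------
      sd_aux("sales_drive_target", quote(1), "index"),

      # --- stocks -------------------------------------------------------------
      sd_stock("pharmacy_profit", initial = init_params$initial_profit,
               inflows = c("profit_from_sales_low", "profit_from_sales_high"),
               outflows = c("disposal_cost_rate", "wage_cost",
                            "overhead_outflow", "error_cost"),
               units = "MU", non_negative = FALSE),
      sd_stock("number_of_residents", initial = init_params$initial_residents,
               inflows = "resident_intake", outflows = "graduation_rate",
               units = "persons", non_negative = TRUE),
      sd_stock("total_expiring_medicines",
               initial = init_params$initial_expiring_stock,
               inflows = "expiring_inflow",
               outflows = c("sales_low_before_expiration", "transfer_out",
                            "disposal_rate"),
               units = "packs", non_negative = TRUE),
      sd_stock("total_disposed_medicines",
               initial = init_params$initial_disposed_total,
               inflows = "disposal_rate", units = "packs", non_negative = TRUE),
      sd_stock("inventory_high_consumption",
               initial = init_params$initial_inventory_high,
               inflows = "buying_high", outflows = "selling_high",
               units = "packs", non_negative = TRUE),
      sd_stock("cumulative_disposal_cost", initial = 0,
               inflows = "disposal_cost_rate", units = "MU",
               non_negative = TRUE)
    ),
    first_order_smooth("accuracy", "accuracy_target",
                       adjust_time = "accuracy_adjust_time",
                       initial = init_params$response_speed_base,
                       units = "index"),
    first_order_smooth("sales_drive", "sales_drive_target",
                       adjust_time = cal$launch_drive_time,
                       initial = cal$launch_drive_init, units = "index"),
    material_delay("buying_high", "order_rate_high",
                   delay_time = "order_delay", initial = transit0,
                   units = "packs")
  )
  sd_model("pharmacy_supply_chain", vars)
}

#' Documented influence structure of the pharmacy model
#'
#' The per-variable driver sets the model is required to have: the map from
#' every flow and auxiliary to the exact set of names its equation reads.
#' [structure_verification()] diffs a built model against this table.
#'
#' @return named list: variable name -> character vector of driver names.
#' @export
pharmacy_influence_table <- function() {
  list(
    response_speed = c("pharmacists_in_team", "response_speed_base",
                       "workforce_competence"),
    accuracy_target = "response_speed_base",
    accuracy_change = c("accuracy", "accuracy_adjust_time", "accuracy_target"),
    accuracy_gap = c("accuracy", "accuracy_target"),
    error_cost = "accuracy_gap",
    price_incentive_low = c("avg_price_low", "profit_margin_low"),
    expiry_availability = "total_expiring_medicines",
    sales_low_before_expiration = c("expiry_availability",
                                    "price_incentive_low", "response_speed",
                                    "sales_drive", "transfer_rate_coeff"),
    transfer_out = c("total_expiring_medicines", "transfer_rate_coeff"),
    disposal_rate = c("expiry_fraction", "total_expiring_medicines",
                      "transfer_rate_coeff"),
    expiring_inflow = c("expiry_inflow_base", "number_of_residents",
                        "resident_overprescription_coeff"),
    resident_intake = "resident_intake_rate",
    graduation_rate = c("number_of_residents", "residency_duration"),
    demand_high = c("demand_high_base", "demand_period",
                    "demand_seasonal_amplitude"),
    service_factor = "response_speed",
    order_rate_high = c("demand_high", "demand_high_base", "monthly_purchase",
                        "service_factor", "share_high_consumption"),
    buying_high = c("buying_high_in_transit", "order_delay"),
    inventory_availability = "inventory_high_consumption",
    selling_high = c("demand_high", "inventory_availability"),
    profit_from_sales_low = c("avg_price_low", "profit_margin_low",
                              "sales_low_before_expiration"),
    profit_from_sales_high = c("avg_price_low", "profit_margin_high",
                               "selling_high"),
    disposal_cost_rate = c("disposal_rate", "disposal_unit_cost"),
    wage_cost = c("avg_salary", "staff_count"),
    overhead_outflow = "overhead_cost",
    sales_drive_target = character(),
    sales_drive_change = c("sales_drive", "sales_drive_target")
  )
}

#' Transitive driver set of a model variable
#'
#' Walks the dependency graph (through auxiliaries, flows and stocks via their
#' flows) and returns every name that can influence `variable`. Useful for
#' checking that a documented causal pathway exists even when it is mediated
#' by intermediate variables.
#'
#' @param model an [sd_model()].
#' @param variable variable name.
#' @return character vector of all upstream variable/constant names.
#' @export
upstream_drivers <- function(model, variable) {
  stopifnot(inherits(model, "sd_model"))
  if (!variable %in% names(model$variables))
    stop("unknown variable: ", variable)
  seen <- character()
  frontier <- variable
  while (length(frontier)) {
    nm <- frontier[[1L]]
    frontier <- frontier[-1L]
    v <- model$variables[[nm]]
    parents <- if (v$kind == "stock") c(v$inflows, v$outflows)
               else model$depends_on[[nm]]
    new <- setdiff(parents, c(seen, variable))
    seen <- c(seen, new)
    frontier <- c(frontier, new)
  }
  sort(seen)
}

#' Derived report table for a pharmacy run
#'
#' Computes, per time point: the disposal cost rate, cumulative sales of
#' low-consumption medicine (dt-weighted running sum of the sales flow,
#' consistent with the integrator), cumulative disposal cost and the net
#' profit change rate (profit inflows minus outflows); plus 0-12 and 12-24
#' month deltas for every reported stock.
#'
#' @param trajectory output of [simulate()] on the pharmacy model.
#' @param params the parameter set of the run.
#' @return list of class `pharmacy_report` with `table` (data.frame) and
#'   `stock_deltas` (data.frame).
#' @export
derive_reports <- function(trajectory, params) {
  stopifnot(inherits(trajectory, "sd_trajectory"))
  params <- as.list(params)
  required <- c("disposal_rate", "sales_low_before_expiration",
                "profit_from_sales_low", "profit_from_sales_high",
                "disposal_cost_rate", "wage_cost", "overhead_outflow",
                "error_cost", "pharmacy_profit")
  missing <- setdiff(required, names(trajectory$series))
  if (length(missing))
    stop("trajectory is missing required series: ",
         paste(missing, collapse = ", "))
  s <- trajectory$series
  dt <- trajectory$dt
  n <- length(trajectory$times)
  cum_sales <- c(0, cumsum(dt * s$sales_low_before_expiration[-n]))
  tab <- data.frame(
    time_months = trajectory$times,
    disposal_cost_rate = s$disposal_rate * params$disposal_unit_cost,
    cumulative_sales_low = cum_sales,
    cumulative_disposal_cost = s$cumulative_disposal_cost,
    net_profit_change = s$profit_from_sales_low + s$profit_from_sales_high -
      s$disposal_cost_rate - s$wage_cost - s$overhead_outflow - s$error_cost
  )
  stocks <- c("pharmacy_profit", "number_of_residents",
              "total_expiring_medicines", "total_disposed_medicines",
              "inventory_high_consumption", "cumulative_disposal_cost")
  stocks <- intersect(stocks, names(s))
  at <- function(m) which.min(abs(trajectory$times - m))
  deltas <- data.frame(
    stock = stocks,
    delta_0_12 = vapply(stocks, function(v) s[[v]][at(12)] - s[[v]][at(0)], 0),
    delta_12_24 = vapply(stocks, function(v) s[[v]][at(24)] - s[[v]][at(12)], 0),
    row.names = NULL
  )
  structure(list(table = tab, stock_deltas = deltas),
            class = "pharmacy_report")
}

#' @export
print.pharmacy_report <- function(x, ...) {
  cat("<pharmacy_report> ", nrow(x$table), " time points\n", sep = "")
  print(x$stock_deltas)
  invisible(x)
}
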