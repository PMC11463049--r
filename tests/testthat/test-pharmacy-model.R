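test_that("the built model carries the six reported stocks and validates", {
  p <- reference_parameters()
  m <- build_pharmacy_model(p)
  stocks <- names(m$kinds)[m$kinds == "stock"]
  expect_true(all(c("pharmacy_profit", "number_of_residents",
                    "total_expiring_medicines", "total_disposed_medicines",
                    "inventory_high_consumption", "cumulative_disposal_cost")
                  %in% stocks))
  expect_false(m$variables$pharmacy_profit$non_negative)
  expect_true(m$variables$total_expiring_medicines$non_negative)
  tr <- simulate(m, p, sim_config())
  expect_true(check_conservation(tr, m)$ok)
})

test_that("switching off a source switches off its whole chain", {
  p <- reference_parameters()

  p1 <- p; p1$share_high_consumption <- 0
  tr1 <- simulate(build_pharmacy_model(p1), p1, sim_config())
  expect_true(all(trajectory_series(tr1, "buying_high") == 0))

  p2 <- p
  p2$expiry_inflow_base <- 0
  p2$resident_overprescription_coeff <- 0
  p2$initial_expiring_stock <- 0
  tr2 <- simulate(build_pharmacy_model(p2), p2, sim_config())
  expect_true(all(trajectory_series(tr2, "disposal_rate") == 0))
  expect_true(all(trajectory_series(tr2, "total_disposed_medicines") ==
                    p2$initial_disposed_total))
})

test_that("parameter validation enforces the declared ranges", {
  p <- reference_parameters()
  expect_true(validate_parameter_set(p)$ok)

  p_bad <- p; p_bad$profit_margin_low <- 1.5
  res <- validate_parameter_set(p_bad)
  expect_false(res$ok)
  expect_match(res$violations, "profit_margin_low", all = FALSE)

  p_bad2 <- p; p_bad2$order_delay <- 0
  expect_false(validate_parameter_set(p_bad2)$ok)

  p_bad3 <- p; p_bad3$not_a_field <- 1
  res3 <- validate_parameter_set(p_bad3)
  expect_false(res3$ok)
  expect_match(res3$violations, "unknown field", all = FALSE)

  expect_error(build_pharmacy_model(p_bad), "profit_margin_low")
})

test_that("documented causal pathways reach their flows", {
  m <- build_pharmacy_model(reference_parameters())
  buying <- upstream_drivers(m, "buying_high")
  expect_true(all(c("response_speed_base", "share_high_consumption",
                    "order_delay", "monthly_purchase") %in% buying))
  sales <- upstream_drivers(m, "sales_low_before_expiration")
  expect_true(all(c("response_speed_base", "pharmacists_in_team",
                    "transfer_rate_coeff", "profit_margin_low",
                    "avg_price_low", "total_expiring_medicines") %in% sales))
  profit_in <- m$variables$pharmacy_profit
  expect_setequal(profit_in$inflows,
                  c("profit_from_sales_low", "profit_from_sales_high"))
  expect_true(all(c("disposal_cost_rate", "wage_cost", "overhead_outflow")
                  %in% profit_in$outflows))
  disp <- m$depends_on$disposal_rate
  expect_true(all(c("total_expiring_medicines", "transfer_rate_coeff") %in% disp))
  sell <- m$depends_on$selling_high
  expect_setequal(sell, c("demand_high", "inventory_availability"))
  expect_equal(m$depends_on$graduation_rate,
               c("number_of_residents", "residency_duration"))
})

test_that("derived reports compute disposal costs and cumulative sales", {
  times <- seq(0, 24, by = 0.25)
  n <- length(times)
  zero <- rep(0, n)
  r <- 4; cost <- 3
  tr <- fake_trajectory(times, list(
    disposal_rate = rep(r, n),
    sales_low_before_expiration = rep(2, n),
    profit_from_sales_low = rep(25, n),
    profit_from_sales_high = zero,
    disposal_cost_rate = rep(r * cost, n),
    wage_cost = zero, overhead_outflow = zero, error_cost = zero,
    pharmacy_profit = cumsum(rep(25 - r * cost, n)) * 0.25,
    cumulative_disposal_cost = c(0, cumsum(rep(r * cost * 0.25, n - 1))),
    number_of_residents = zero, total_expiring_medicines = zero,
    total_disposed_medicines = zero, inventory_high_consumption = zero))
  rep_out <- derive_reports(tr, list(disposal_unit_cost = cost))
  expect_equal(rep_out$table$disposal_cost_rate, rep(r * cost, n))
  # constant disposal at rate r with unit cost c: 24 * r * c at the horizon
  expect_equal(rep_out$table$cumulative_disposal_cost[n], 24 * r * cost,
               tolerance = 1e-12)
  expect_equal(rep_out$table$cumulative_sales_low[n], 48, tolerance = 1e-12)
  expect_equal(rep_out$table$net_profit_change, rep(25 - r * cost, n))

  # zero disposal: all-zero cost column
  tr0 <- tr
  tr0$series$disposal_rate <- zero
  tr0$series$disposal_cost_rate <- zero
  tr0$series$cumulative_disposal_cost <- zero
  rep0 <- derive_reports(tr0, list(disposal_unit_cost = cost))
  expect_true(all(rep0$table$disposal_cost_rate == 0))

  tr_broken <- tr
  tr_broken$series$disposal_rate <- NULL
  expect_error(derive_reports(tr_broken, list(disposal_unit_cost = cost)),
               "disposal_rate")
})

test_that("the reference run reproduces all reported trajectory patterns", {
  p <- reference_parameters()
  tr <- simulate(build_pharmacy_model(p), p, sim_config())
  checks <- pattern_checks(tr, p)
  expect_true(all(checks), info = paste(names(checks)[!checks], collapse = ", "))

  rep_out <- derive_reports(tr, p)
  expect_true(all(c("increasing", "accelerating") %in%
    classify_trend(rep_out$table$cumulative_disposal_cost, tr$times)))
})

test_that("model structure dump is valid JSON covering every variable", {
  m <- build_pharmacy_model(reference_parameters())
  js <- model_structure_json(m)
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_equal(length(parsed), length(m$variables))
  nm <- vapply(parsed, `[[`, "", "name")
  expect_setequal(nm, names(m$variables))
})
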