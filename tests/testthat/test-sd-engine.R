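test_that("constant inflow accumulates exactly, at any step size", {
  m <- constant_inflow_model()
  for (dt in c(1, 0.5, 0.25, 1 / 8)) {
    tr <- simulate(m, list(rate = 1), sim_config(0, 24, dt))
    tank <- trajectory_series(tr, "tank")
    expect_equal(tank[length(tank)], 24, tolerance = 1e-12)
    expect_equal(tr$times, seq(0, 24, by = dt))
  }
})

test_that("exponential decay matches the closed form within the Euler error law", {
  # global relative error of forward Euler on dS/dt = -l*S is
  # exp(T * l^2 * dt / 2) - 1 to leading order; assert the run lands inside
  # a bracket around that prediction rather than an arbitrary tolerance
  m <- decay_model()
  lambda <- 0.5
  run_err <- function(dt) {
    tr <- simulate(m, list(lambda = lambda), sim_config(0, 24, dt))
    tank <- trajectory_series(tr, "tank")
    abs(tank[length(tank)] / (100 * exp(-12)) - 1)
  }
  e64 <- run_err(1 / 64)
  predicted <- expm1(24 * lambda^2 * (1 / 64) / 2)
  expect_lt(e64, 1.2 * predicted)
  expect_gt(e64, 0.8 * predicted)
  # the 1% level is reached once dt satisfies the error law
  expect_lt(run_err(1 / 512), 0.01)
  # first-order convergence: halving dt halves the error (20% slack)
  e128 <- run_err(1 / 128)
  expect_lt(abs(e64 / e128 - 2), 0.4)
})

test_that("stock equals initial plus cumulative dt-weighted net flow", {
  set.seed(11)
  dt <- 0.25
  sched <- stats::rnorm(96, sd = 3)
  m <- schedule_model(sched, dt)
  tr <- simulate(m, list(), sim_config(0, 24, dt))
  tank <- trajectory_series(tr, "tank")
  oracle <- 5 + c(0, cumsum(dt * sched))
  expect_equal(tank, oracle, tolerance = 1e-12)

  chk <- check_conservation(tr, m)
  expect_true(chk$ok)
  tr$series$tank[40] <- tr$series$tank[40] + 1
  chk2 <- check_conservation(tr, m)
  expect_false(chk2$ok)
  expect_equal(chk2$stock, "tank")
  expect_equal(chk2$time, tr$times[40])
})

test_that("closed transfer systems conserve total material", {
  m <- transfer_model()
  tr <- simulate(m, list(k = 0.3), sim_config(0, 24, 0.25))
  total <- trajectory_series(tr, "a") + trajectory_series(tr, "b")
  expect_equal(max(abs(total - 42)), 0, tolerance = 1e-10)
  expect_true(check_conservation(tr, m)$ok)
})

test_that("non-negative stocks floor at zero with proportionally limited outflows", {
  m <- sd_model("drain", list(
    sd_constant("demand", "units/month"),
    sd_flow("draw", quote(demand), "units/month"),
    sd_stock("store", initial = 3, outflows = "draw", units = "units",
             non_negative = TRUE),
    sd_stock("sink", initial = 0, inflows = "draw", units = "units",
             non_negative = TRUE)
  ))
  tr <- simulate(m, list(demand = 2), sim_config(0, 12, 0.5))
  store <- trajectory_series(tr, "store")
  expect_true(all(store >= 0))
  expect_equal(store[length(store)], 0)
  # the limited flow is what the receiving stock sees: conservation holds
  sink <- trajectory_series(tr, "sink")
  expect_equal(max(abs(store + sink - 3)), 0, tolerance = 1e-10)
  expect_true(check_conservation(tr, m)$ok)
})

test_that("simulation is deterministic and declaration-order independent", {
  p <- reference_parameters()
  m1 <- build_pharmacy_model(p)
  t1 <- simulate(m1, p, sim_config())
  t2 <- simulate(m1, p, sim_config())
  expect_identical(t1$series, t2$series)

  m2 <- sd_model(m1$name, rev(unname(m1$variables)))
  t3 <- simulate(m2, p, sim_config())
  expect_identical(t1$series[sort(names(t1$series))],
                   t3$series[sort(names(t3$series))])
})

test_that("model and config validation reject broken inputs", {
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(0, 24, 0.7), "integer number of steps")
  expect_error(sim_config(5, 5), "exceed")

  expect_error(simulate(decay_model(), list(), sim_config()),
               "missing parameter.*lambda")

  blow <- sd_model("blow", list(
    sd_flow("f", quote(1 / (12 - t) - 1 / (12 - t)^2), "1/month"),
    sd_stock("s", initial = 0, inflows = "f")
  ))
  expect_error(simulate(blow, list(), sim_config(0, 24, 0.25)),
               "non-finite value for 'f' at t = 12")

  expect_error(sd_model("dup", list(
    sd_flow("f", quote(1)), sd_flow("f", quote(2)),
    sd_stock("s", initial = 0, inflows = "f"))), "duplicate")
  expect_error(sd_model("bad", list(
    sd_flow("f", quote(ghost)),
    sd_stock("s", initial = 0, inflows = "f"))), "unknown name")
  expect_error(sd_model("circ", list(
    sd_aux("a", quote(b)), sd_aux("b", quote(a)))),
    "circular dependency")
})

test_that("first-order smooth approaches its target along the closed form", {
  base <- list(
    sd_constant("x_const", "1"),
    sd_aux("x", quote(x_const), "1"))
  m <- sd_model("smooth", c(base, first_order_smooth("y", "x", 1, initial = 0)))
  tr <- simulate(m, list(x_const = 1), sim_config(0, 24, 0.25))
  y <- trajectory_series(tr, "y")
  expect_lt(abs(y[length(y)] - 1), 1e-4)

  # fixed point: y starts at the target and stays there
  m2 <- sd_model("smooth2", c(base, first_order_smooth("y", "x", 1, initial = 1)))
  y2 <- trajectory_series(simulate(m2, list(x_const = 1), sim_config()), "y")
  expect_equal(max(abs(y2 - 1)), 0, tolerance = 1e-12)

  # step response: y(T) = 1 - exp(-T/tau), within 2% at T = tau = 2
  m3 <- sd_model("smooth3", c(base, first_order_smooth("y", "x", 2, initial = 0)))
  tr3 <- simulate(m3, list(x_const = 1), sim_config(0, 24, 0.125))
  y3 <- trajectory_series(tr3, "y")
  expect_lt(abs(y3[tr3$times == 2] - (1 - exp(-1))), 0.02 * (1 - exp(-1)))

  expect_error(first_order_smooth("y", "x", 0), "must be > 0")
  expect_error(first_order_smooth("y", "x", -2), "must be > 0")
})

test_that("material delay conserves ordered material", {
  mk <- function(order_eq) sd_model("delay", c(
    list(sd_flow("orders", order_eq, "units/month")),
    material_delay("arrivals", "orders", 2)
  ))
  cfg <- sim_config(0, 40, 0.125)

  zero <- simulate(mk(quote(0)), list(), cfg)
  expect_true(all(trajectory_series(zero, "arrivals") == 0))

  const <- simulate(mk(quote(3)), list(), cfg)
  arr <- trajectory_series(const, "arrivals")
  expect_lt(abs(arr[length(arr)] - 3), 0.03)

  # finite pulse of volume 6 over the first month: all of it arrives
  pulse <- simulate(mk(quote(if (t < 1) 6 else 0)), list(), cfg)
  arr_p <- trajectory_series(pulse, "arrivals")
  cum_arrived <- sum(0.125 * arr_p[-length(arr_p)])
  in_transit <- trajectory_series(pulse, "arrivals_in_transit")
  expect_equal(cum_arrived + in_transit[length(in_transit)], 6,
               tolerance = 1e-9)
  # by t = 10 * delay nearly everything has arrived
  at20 <- sum(0.125 * arr_p[pulse$times < 20])
  expect_lt(abs(at20 - 6), 0.06)

  expect_error(material_delay("a", "o", 0), "must be > 0")
})

test_that("trajectories export to CSV with a time_months column, byte-stable", {
  p <- reference_parameters()
  tr <- simulate(build_pharmacy_model(p), p, sim_config())
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f1)
  write_trajectory_csv(tr, f2)
  expect_identical(readLines(f1), readLines(f2))
  df <- utils::read.csv(f1)
  expect_equal(names(df)[1], "time_months")
  expect_equal(range(df$time_months), c(0, 24))
})
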