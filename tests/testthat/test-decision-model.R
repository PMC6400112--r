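test_that("the annual QALY value follows the WTP conversion chain", {
  expect_equal(qaly_annual_value(economic_params()), 39811.2)
  expect_equal(qaly_annual_value(economic_params(qaly_weight = 0)), 0)
  expect_equal(qaly_annual_value(economic_params(
    wtp_base = 12345, inflation_factor = 1, fx_rate = 1, qaly_weight = 1)),
    12345)
})

test_that("the utility matrix reproduces the published construction", {
  u <- build_utility_matrix(economic_params())
  expect_equal(u$u_tp, 308056)
  expect_equal(u$u_fp, -26000)
  expect_equal(u$u_tn, -2000)
  expect_equal(u$u_fn, -2000)

  zero <- economic_params(wtp_base = 0, annual_care_savings = 0,
                          therapy_cost_annual = 0, scan_cost = 0)
  expect_equal(unlist(unclass(build_utility_matrix(zero))),
               c(u_tp = 0, u_fp = 0, u_tn = 0, u_fn = 0))

  no_therapy <- build_utility_matrix(economic_params(therapy_cost_total = 0))
  expect_equal(no_therapy$u_tp, 27000 * 5 + 39811.2 * 5 - 2000) # 332056
})

test_that("the expected value is the outcome-weighted utility sum", {
  u <- build_utility_matrix(economic_params())
  expect_equal(expected_value(test_characteristics(0.9, 0.9, 0.1), u),
               23745.04)
  expect_equal(expected_value(test_characteristics(1, 1, 0), u), u$u_tn)
  expect_equal(expected_value(test_characteristics(1, 1, 1), u), u$u_tp)
})

test_that("outcome fractions conserve probability exactly", {
  for (args in list(c(0.9, 0.9, 0.1), c(0.83, 0.89, 0.25), c(1, 0.5, 0))) {
    t <- test_characteristics(args[1], args[2], args[3])
    expect_identical(t$tpf * t$p + t$fnf * t$p +
                       t$tnf * (1 - t$p) + t$fpf * (1 - t$p), 1)
  }
})

test_that("the expected value agrees with a Bernoulli simulation oracle", {
  u <- build_utility_matrix(economic_params())
  t <- test_characteristics()
  mc <- mc_expected_value(t, u, n = 1e6, seed = 42)
  expect_lt(abs(mc$mean - expected_value(t, u)), 3 * mc$se)

  # and across random parameter draws
  set.seed(20)
  for (i in 1:20) {
    t_i <- test_characteristics(runif(1, 0.5, 1), runif(1, 0.5, 1),
                                runif(1, 0.01, 0.5))
    u_i <- build_utility_matrix(economic_params(
      annual_care_savings = runif(1, 0, 5e4),
      therapy_cost_annual = runif(1, 0, 1e4),
      scan_cost = runif(1, 0, 5e3),
      delay_years = runif(1, 0, 10)))
    mc_i <- mc_expected_value(t_i, u_i, n = 2e5, seed = 100 + i)
    expect_lt(abs(mc_i$mean - expected_value(t_i, u_i)), 3 * mc_i$se)
  }
})

test_that("sensitivity and specificity move E in the direction of their utilities", {
  cfg <- base_config()
  u <- build_utility_matrix(cfg$params)
  eps <- 1e-6
  dse <- (config_expected_value(demscreen:::set_config_param(cfg, "se", 0.9 + eps)) -
            config_expected_value(demscreen:::set_config_param(cfg, "se", 0.9 - eps))) / (2 * eps)
  expect_identical(dse > 0, u$u_tp > u$u_fn)
  dsp <- (config_expected_value(demscreen:::set_config_param(cfg, "sp", 0.9 + eps)) -
            config_expected_value(demscreen:::set_config_param(cfg, "sp", 0.9 - eps))) / (2 * eps)
  expect_identical(dsp > 0, u$u_tn > u$u_fp)
  # analytic partials from the defining equation
  expect_equal(dse, u$u_tp * 0.1 - u$u_fn * 0.1, tolerance = 1e-4)
  expect_equal(dsp, u$u_tn * 0.9 - u$u_fp * 0.9, tolerance = 1e-4)
})

test_that("E is affine in each monetary input (constant finite differences)", {
  cfg <- base_config()
  for (par in c("wtp_base", "annual_care_savings", "therapy_cost_total",
                "scan_cost")) {
    base <- cfg$params[[par]]
    grid <- base + c(0, 1000, 2000, 3000)
    e <- one_way_sweep(par, grid, cfg)$expected_value
    d2 <- diff(diff(e))
    expect_lt(max(abs(d2)), 1e-6,
              label = sprintf("second difference in %s", par))
  }
})

test_that("net savings per detected case nets out the imaging bill", {
  expect_equal(net_savings_per_detection(27000, 5, 2000, 10), 115000)
  expect_equal(net_savings_per_detection(27000, 5, 0, 10), 135000)
  expect_equal(net_savings_per_detection(27000, 5, 2000, 1), 133000)
  expect_error(net_savings_per_detection(27000, 5, 2000, 0.5), ">=")
})

test_that("E(d) is affine in the delay with only scan costs at d = 0", {
  t <- test_characteristics()
  p <- economic_params()
  expect_equal(expected_value_vs_delay(t, p, 5), 23745.04)
  expect_equal(expected_value_vs_delay(t, p, 0), -2000)
  # slope from the defining equation, root by linear solve
  slope <- (expected_value_vs_delay(t, p, 1) - (-2000))
  root <- 2000 / slope
  expect_equal(expected_value_vs_delay(t, p, root), 0, tolerance = 1e-9)
  expect_equal(root, 0.39, tolerance = 0.01)
  # affine: E(2d) - E(0) is twice E(d) - E(0)
  expect_equal(expected_value_vs_delay(t, p, 8) + 2000,
               2 * (expected_value_vs_delay(t, p, 4) + 2000))
})

test_that("discounting reduces the value of future streams", {
  p_disc <- economic_params(discount_rate = 0.03)
  u_disc <- build_utility_matrix(p_disc)
  u_undisc <- build_utility_matrix(economic_params())
  expect_lt(u_disc$u_tp, u_undisc$u_tp)
  expect_equal(u_disc$u_fp, u_undisc$u_fp) # costs here are not streams
})
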