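test_that("one-way sweeps recompute E on the grid and are order-invariant", {
  cfg <- base_config()
  expect_equal(one_way_sweep("delay_years", 5, cfg)$expected_value, 23745.04)

  zeroed <- base_config(params = economic_params(
    wtp_base = 0, annual_care_savings = 0, therapy_cost_annual = 0,
    scan_cost = 0))
  expect_equal(one_way_sweep("scan_cost", 0, zeroed)$expected_value, 0)

  perfect <- base_config(test = test_characteristics(1, 1, 0.5))
  u <- build_utility_matrix(perfect$params)
  sw <- one_way_sweep("p", c(0, 1), perfect)
  expect_equal(sw$expected_value, c(u$u_tn, u$u_tp))

  grid <- c(0.3, 0.9, 0.6, 0.1)
  a <- one_way_sweep("se", grid, cfg)
  b <- one_way_sweep("se", rev(grid), cfg)
  expect_equal(a, b)

  expect_error(one_way_sweep("se", c(0.5, 1.2), cfg), "domain")
  expect_error(one_way_sweep("not_a_parameter", 1, cfg), "unknown parameter")
})

test_that("break-even thresholds agree with closed-form roots of the affine model", {
  cfg <- base_config()

  d_root <- threshold_analysis("delay_years", cfg)
  slope <- 0.1 * 0.9 * (27000 + 39811.2 - 4800) - 0.9 * 0.1 * 4800
  expect_equal(d_root, 2000 / slope, tolerance = 1e-6)

  # care savings keep E positive even at zero willingness to pay
  expect_identical(threshold_analysis("wtp_base", cfg), "none in domain")

  no_savings <- base_config(params = economic_params(annual_care_savings = 0))
  w_root <- threshold_analysis("wtp_base", no_savings)
  e0 <- 0.09 * (-26000) + 0.9 * 0.1 * (-26000) + 0.81 * (-2000) +
    0.01 * (-2000)
  w_slope <- 0.1 * 0.9 * (1.10 * 1.3 * 0.348 * 5)
  expect_equal(w_root, -e0 / w_slope, tolerance = 1e-6)
  expect_equal(w_root, 28222, tolerance = 1e-4)

  # roots inferred from two sweep points match bisection for affine parameters
  for (par in c("scan_cost", "therapy_cost_total")) {
    dom <- demscreen:::param_domain(par, cfg)
    e <- one_way_sweep(par, dom, cfg)$expected_value
    if (sign(e[1]) != sign(e[2])) {
      lin_root <- dom[1] - e[1] * diff(dom) / (e[2] - e[1])
      expect_equal(threshold_analysis(par, cfg), lin_root, tolerance = 1e-6)
    }
  }
})

test_that("threshold analysis refuses non-monotone problems", {
  cfg <- base_config()
  # make E non-monotone in se by setting u_tp = u_fn is not possible;
  # instead check the diagnostic path via a constant function: p = 0 makes
  # E flat in se, which never changes sign -> "none in domain"
  flat <- base_config(test = test_characteristics(0.9, 0.9, 0))
  expect_identical(threshold_analysis("se", flat), "none in domain")
})

test_that("point-mass PSA reproduces the deterministic model exactly", {
  cfg <- base_config()
  specs <- list(dist_spec("se", "point", value = 0.9),
                dist_spec("scan_cost", "point", value = 2000))
  res <- probabilistic_sa(specs, n_draws = 50, seed = 3, config = cfg)
  expect_equal(res$mean, 23745.04)
  expect_equal(res$sd, 0)
  expect_equal(res$p_positive, 1)
})

test_that("PSA is seed-reproducible and centred on the closed form for affine inputs", {
  cfg <- base_config()
  specs <- list(dist_spec("se", "beta", mean = 0.9, sd = 0.03))
  a <- probabilistic_sa(specs, n_draws = 400, seed = 11, config = cfg)
  b <- probabilistic_sa(specs, n_draws = 400, seed = 11, config = cfg)
  expect_identical(a$mean, b$mean)
  expect_identical(a$quantiles, b$quantiles)
  # E is affine in se, so mean(E) should match E at the mean draw
  mean_se <- mean(a$draws$se)
  expect_equal(a$mean,
               config_expected_value(
                 demscreen:::set_config_param(cfg, "se", mean_se)),
               tolerance = 1e-6)
})

test_that("PSA rejects distributions inconsistent with a parameter's support", {
  expect_error(dist_spec("se", "lognormal", mean = 0.9, sd = 0.1),
               "not valid for probability")
  expect_error(dist_spec("se", "uniform", min = -0.5, max = 0.5), "\\[0, 1\\]")
  expect_error(dist_spec("scan_cost", "point"), "need")
  expect_error(dist_spec("se", "beta", mean = 0.5, sd = 0.9), "method-of-moments")
})

test_that("tornado tables order parameters by influence with named ties stable", {
  cfg <- base_config()
  single <- tornado(cfg, list(delay_years = c(4, 6)))
  slope <- 0.1 * 0.9 * (27000 + 39811.2 - 4800) - 0.9 * 0.1 * 4800
  expect_equal(single$span, 2 * slope)

  zero_width <- tornado(cfg, list(se = c(0.9, 0.9), scan_cost = c(2000, 2000)))
  expect_equal(zero_width$span, c(0, 0))
  expect_equal(zero_width$parameter, c("scan_cost", "se")) # tie -> name order

  ranges <- list(wtp_base = c(40000, 80000), delay_years = c(2, 5),
                 therapy_cost_annual = c(4800, 9600))
  tor <- tornado(cfg, ranges)
  expect_equal(tor$parameter[1], "delay_years") # widest span
  expect_true(all(diff(abs(tor$span)) <= 1e-9))
})
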