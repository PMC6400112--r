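test_that("projection matches a brute-force difference-equation oracle", {
  toy <- toy_projection_inputs()
  for (d in c(0, 2)) {
    traj <- project_cohort(toy$initial, toy$incidence, toy$mortality,
                           delay_scenario(d, 2020, 2025))
    oracle <- brute_force_project(70:72, toy$initial$non_demented,
                                  toy$initial$demented, toy$inc_fun,
                                  toy$mort_fun, toy$hr, d = d, n_years = 5)
    for (k in 0:5) {
      yr <- as.data.frame(traj[traj$year == 2020 + k, ])
      expect_equal(yr$non_demented, unname(oracle[[k + 1]]$nd),
                   tolerance = 1e-9)
      expect_equal(yr$demented, unname(oracle[[k + 1]]$dem), tolerance = 1e-9)
    }
  }
})

test_that("a zero delay reproduces the baseline trajectory exactly", {
  toy <- toy_projection_inputs()
  base <- project_cohort(toy$initial, toy$incidence, toy$mortality,
                         delay_scenario(0, 2020, 2024))
  also <- project_cohort(toy$initial, toy$incidence, toy$mortality,
                         delay_scenario(0, 2020, 2024))
  expect_identical(base, also)
  expect_error(delay_scenario(-1, 2020, 2024), ">=")
})

test_that("persons are conserved: without mortality the total never changes", {
  toy <- toy_projection_inputs()
  no_death <- mortality_schedule(
    rate_schedule("incidence_per_1000py",
                  data.frame(age_lo = 0, age_hi = Inf, rate = 0)), 1)
  traj <- project_cohort(toy$initial, toy$incidence, no_death,
                         delay_scenario(0, 2020, 2030))
  tt <- trajectory_totals(traj)
  expect_equal(tt$total, rep(sum(toy$initial$non_demented) +
                               sum(toy$initial$demented), nrow(tt)),
               tolerance = 1e-12)
  # and the demented pool never shrinks when no one dies
  expect_true(all(diff(tt$demented) >= -1e-9))
})

test_that("delaying onset weakly lowers prevalence, more so for larger delays", {
  sc <- generate_scenario(scenario_spec(total_population = 1e6))
  prev_by_d <- lapply(c(0, 2, 5, 8), function(d) {
    trajectory_totals(project_cohort(
      sc$initial, sc$incidence, sc$mortality,
      delay_scenario(d, 2011, 2026)))$demented
  })
  for (i in 2:length(prev_by_d)) {
    expect_true(all(prev_by_d[[i]] <= prev_by_d[[i - 1]] + 1e-9),
                label = sprintf("delay %d vs %d", c(0, 2, 5, 8)[i],
                                c(0, 2, 5, 8)[i - 1]))
  }
})

test_that("prevalence reduction reproduces the published arithmetic", {
  mk <- function(n_dem) {
    structure(data.frame(year = 2031, age = 80, sex = "all",
                         non_demented = 1e6, demented = n_dem,
                         in_care = 0.768 * n_dem),
              class = c("cohort_trajectory", "data.frame"))
  }
  expect_equal(prevalence_reduction(mk(674000), mk(374000), 2031),
               100 * (674 - 374) / 674)  # 44.5%
  expect_equal(round_half_up(prevalence_reduction(mk(674000), mk(374000), 2031)),
               45)
  expect_equal(prevalence_reduction(mk(674000), mk(674000), 2031), 0)
  expect_equal(prevalence_reduction(mk(674000), mk(0), 2031), 100)
  # the same comparison on cases in care
  expect_equal(prevalence_reduction(mk(674000), mk(374000), 2031,
                                    measure = "in_care"),
               100 * (674 - 374) / 674)
})

test_that("cost deltas turn averted cases into savings", {
  mk <- function(n_dem) {
    structure(data.frame(year = 2031, age = 80, sex = "all",
                         non_demented = 1e6, demented = n_dem, in_care = 0),
              class = c("cohort_trajectory", "data.frame"))
  }
  cd <- cost_delta(mk(674000), mk(374000), 27000)
  expect_equal(cd$delta_prevalence, 300000)
  expect_equal(cd$total_savings, 300000 * 27000)
  expect_equal(cd$per_person, 27000)
  expect_warning(zero <- cost_delta(mk(5e5), mk(5e5), 27000), "zero savings")
  expect_equal(zero$total_savings, 0)

  # dividing published aggregate costs by averted cases
  expect_equal(round(cost_delta_from_totals(8e9, 0, 3e5)), 26667)
  expect_equal(cost_delta_from_totals(18.2e9, 10.25e9, 3e5), 26500)
})

test_that("the stochastic mode is seed-reproducible and tracks the expectation", {
  sc <- generate_scenario(scenario_spec(total_population = 2e6))
  run <- function(seed) {
    trajectory_totals(project_cohort(
      sc$initial, sc$incidence, sc$mortality,
      delay_scenario(0, 2011, 2021), stochastic = TRUE, seed = seed))
  }
  expect_identical(run(7), run(7))
  expect_error(project_cohort(sc$initial, sc$incidence, sc$mortality,
                              delay_scenario(0, 2011, 2021),
                              stochastic = TRUE), "seed")
  det <- trajectory_totals(project_cohort(
    sc$initial, sc$incidence, sc$mortality, delay_scenario(0, 2011, 2021)))
  sto <- run(11)
  expect_lt(abs(sto$demented[11] - det$demented[11]) / det$demented[11], 0.05)
})

test_that("an injected delay is recovered exactly by grid search", {
  sc <- generate_scenario(scenario_spec(total_population = 1e6))
  scen <- delay_scenario(0, 2011, 2026)
  for (d_true in c(2L, 6L)) {
    scen_d <- scen; scen_d$delay_years <- d_true
    obs <- project_cohort(sc$initial, sc$incidence, sc$mortality, scen_d)
    expect_identical(estimate_delay(obs, sc$initial, sc$incidence,
                                    sc$mortality, scen, d_grid = 0:10),
                     d_true)
  }
})
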