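test_that("growth factors and percent increases reproduce printed ratios", {
  expect_equal(percent_increase(769413, 1406105), 82.8)
  expect_equal(round_half_up(growth_factor(769413, 1406105), 3), 1.828)
  expect_equal(round_half_up(growth_factor(106575, 201868), 3), 1.894)
  expect_equal(growth_factor(123456, 123456), 1)
  expect_error(growth_factor(0, 10), ">")
})

test_that("growth factors compose multiplicatively", {
  for (abc in list(c(100, 150, 290), c(769413, 1e6, 1406105), c(3, 7, 2))) {
    expect_equal(growth_factor(abc[1], abc[2]) * growth_factor(abc[2], abc[3]),
                 growth_factor(abc[1], abc[3]))
  }
})

test_that("every printed population ratio is reproduced from the printed counts", {
  t1 <- load_fixture("table1_population")
  for (r in unique(t1$region)) {
    for (g in unique(t1$age_group)) {
      rows <- t1[t1$region == r & t1$age_group == g, ]
      ratio <- growth_factor(rows$count[rows$year == 2010],
                             rows$count[rows$year == 2030])
      printed <- rows$printed_ratio[rows$year == 2030]
      expect_lt(abs(ratio - printed), 1e-3,
                label = sprintf("ratio for %s %s (%.4f vs printed %.3f)",
                                r, g, ratio, printed))
    }
  }
})

test_that("applying incidence rates to a population gives expected annual cases", {
  pop <- age_band_population("toy", 2020,
    data.frame(age_lo = 60, age_hi = 64, count = 1e6))
  sch <- rate_schedule("incidence_per_1000py",
    data.frame(age_lo = 60, age_hi = 64, rate = 3.9))
  expect_equal(count_in_range(apply_rates(pop, sch), 60, 64), 3900)

  zero <- rate_schedule("incidence_per_1000py",
    data.frame(age_lo = 0, age_hi = Inf, rate = 0))
  expect_equal(count_in_range(apply_rates(pop, zero), 0), 0)

  two <- age_band_population("toy", 2020,
    data.frame(age_lo = c(60, 65), age_hi = c(64, 69), count = c(5e5, 5e5)))
  sch2 <- rate_schedule("incidence_per_1000py",
    data.frame(age_lo = c(60, 65), age_hi = c(64, 69), rate = c(2, 4)))
  expect_equal(count_in_range(apply_rates(two, sch2), 60, 69), 3000)
})

test_that("apply_rates is additive over band partitions", {
  sch <- rate_schedule("incidence_per_1000py",
    data.frame(age_lo = 60, age_hi = 69, rate = 7))
  whole <- age_band_population("x", 2020,
    data.frame(age_lo = 60, age_hi = 69, count = 123456))
  split <- age_band_population("x", 2020,
    data.frame(age_lo = c(60, 63), age_hi = c(62, 69),
               count = 123456 * c(3, 7) / 10))
  expect_equal(count_in_range(apply_rates(whole, sch), 60, 69),
               count_in_range(apply_rates(split, sch), 60, 69))
})

test_that("a schedule gap raises a coverage error naming the band", {
  pop <- age_band_population("toy", 2020,
    data.frame(age_lo = 60, age_hi = 69, count = 1000))
  sch <- rate_schedule("incidence_per_1000py",
    data.frame(age_lo = 60, age_hi = 64, rate = 5))
  expect_error(apply_rates(pop, sch), "covers only")
  open_pop <- age_band_population("toy", 2020,
    data.frame(age_lo = 90, age_hi = Inf, count = 1000))
  expect_error(apply_rates(open_pop, sch), "open-ended")
})

test_that("at-risk incidence subtracts prevalent cases before applying rates", {
  pop <- age_band_population("toy", 2020,
    data.frame(age_lo = 60, age_hi = 64, count = 1e5))
  sch <- rate_schedule("incidence_per_1000py",
    data.frame(age_lo = 60, age_hi = 64, rate = 10))
  prev_all <- count_table("toy", "prevalence",
    data.frame(year = 2020, age_lo = 60, age_hi = 64, count = 1e5))
  expect_equal(count_in_range(adi_incidence(pop, prev_all, sch), 60, 64), 0)

  prev_some <- count_table("toy", "prevalence",
    data.frame(year = 2020, age_lo = 60, age_hi = 64, count = 1e4))
  expect_equal(count_in_range(adi_incidence(pop, prev_some, sch), 60, 64), 900)

  prev_over <- count_table("toy", "prevalence",
    data.frame(year = 2020, age_lo = 60, age_hi = 64, count = 2e5))
  expect_error(adi_incidence(pop, prev_over, sch), "exceed")
})

test_that("at-risk incidence never exceeds whole-population incidence", {
  cl <- canada_like_60plus()
  with_prev <- count_in_range(adi_incidence(cl$pop, cl$prev, cl$rates), 60)
  without <- count_in_range(apply_rates(cl$pop, cl$rates), 60)
  expect_lte(with_prev, without)
})

test_that("a Canada-like 60+ snapshot yields incidence near the published level", {
  cl <- canada_like_60plus()
  incident <- count_in_range(adi_incidence(cl$pop, cl$prev, cl$rates), 60)
  expect_lt(abs(incident - 131000) / 131000, 0.10)
})

test_that("incidence/prevalence ratios match the published percentages", {
  t2 <- load_fixture("table2_prevalence")
  t3 <- load_fixture("table3_incidence")
  ip <- function(region) {
    incidence_prevalence_ratio(
      t3$count[t3$region == region & t3$age_group == "60+" & t3$year == 2020],
      t2$count[t2$region == region & t2$year == 2020])
  }
  expect_equal(ip("Canada"), 20.5)
  expect_equal(ip("China"), 21.3)
  expect_equal(ip("USA"), 21.9)
  expect_equal(incidence_prevalence_ratio(0, 100), 0)
  expect_error(incidence_prevalence_ratio(10, 0), ">")
})

test_that("the age-doubling incidence curve doubles on schedule", {
  expect_equal(doubling_rate(68.3), 7.8)
  expect_equal(doubling_rate(74.6), 15.6)
  expect_equal(doubling_rate(62), 3.9)
  sch <- doubling_schedule(3.9, 62, 6.3, age_lo = 60, age_hi = 94)
  expect_equal(rate_at(sch, 62), 3.9)           # 60-64 band carries its midpoint rate
  expect_true(all(diff(sch$entries$rate) > 0))  # monotone in age
})

test_that("count_in_range apportions straddling bands linearly", {
  ct <- count_table("toy", "incidence",
    data.frame(year = 2020, age_lo = c(60, 70), age_hi = c(69, 79),
               count = c(1000, 500)))
  expect_equal(count_in_range(ct, 60, 79), 1500)
  expect_equal(count_in_range(ct, 65, 79), 1000) # half of the first band
})
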