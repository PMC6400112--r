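# Independent oracles and small builders shared across tests. The oracles
# are deliberately written as plain difference equations / brute-force
# simulation, independent of the package's implementation paths.

# Brute-force cohort projection: one named vector per state, explicit loops,
# same model conventions (incidence at delay-shifted age, then mortality,
# then aging with an absorbing top age; zero entries at the youngest age).
brute_force_project <- function(ages, nd0, dem0, inc_fun, mort_fun, hr,
                                d = 0, n_years = 5) {
  nd <- setNames(as.numeric(nd0), ages)
  dem <- setNames(as.numeric(dem0), ages)
  out <- list(list(nd = nd, dem = dem))
  for (t in seq_len(n_years)) {
    nd_next <- setNames(numeric(length(ages)), ages)
    dem_next <- setNames(numeric(length(ages)), ages)
    for (i in seq_along(ages)) {
      a <- ages[i]
      p_inc <- min(inc_fun(a - d) / 1000, 1)
      new_cases <- nd[i] * p_inc
      m <- min(mort_fun(a) / 1000, 1)
      nd_i <- (nd[i] - new_cases) * (1 - m)
      dem_i <- (dem[i] + new_cases) * (1 - min(m * hr, 1))
      j <- if (i == length(ages)) i else i + 1
      nd_next[j] <- nd_next[j] + nd_i
      dem_next[j] <- dem_next[j] + dem_i
    }
    nd <- nd_next; dem <- dem_next
    out[[t + 1]] <- list(nd = nd, dem = dem)
  }
  out
}

# Monte Carlo oracle for the expected test value: Bernoulli disease status,
# Bernoulli test result conditional on status, utilities averaged.
mc_expected_value <- function(test, u, n = 1e6, seed = 42) {
  set.seed(seed)
  diseased <- rbinom(n, 1, test$p)
  positive <- ifelse(diseased == 1,
                     rbinom(n, 1, test$se),
                     rbinom(n, 1, 1 - test$sp))
  util <- ifelse(diseased == 1,
                 ifelse(positive == 1, u$u_tp, u$u_fn),
                 ifelse(positive == 1, u$u_fp, u$u_tn))
  list(mean = mean(util), se = sd(util) / sqrt(n))
}

# Small three-age scenario used by several projection tests.
toy_projection_inputs <- function() {
  list(
    initial = cohort_state(data.frame(age = 70:72, sex = "all",
                                      non_demented = c(1000, 900, 800),
                                      demented = c(50, 60, 70))),
    incidence = rate_schedule("incidence_per_1000py",
                              data.frame(age_lo = c(0, 71, 72),
                                         age_hi = c(70, 71, Inf),
                                         rate = c(12, 18, 27))),
    mortality = mortality_schedule(
      rate_schedule("incidence_per_1000py",
                    data.frame(age_lo = 0, age_hi = Inf, rate = 25)),
      dementia_hazard_ratio = 2),
    inc_fun = function(a) if (a <= 70) 12 else if (a <= 71) 18 else 27,
    mort_fun = function(a) 25,
    hr = 2
  )
}

# Canada-like 60+ snapshot: plausible 2020 population (thousands),
# prevalence proportions and age-doubling incidence rates.
canada_like_60plus <- function() {
  bands <- data.frame(age_lo = c(60, 65, 70, 75, 80, 85, 90),
                      age_hi = c(64, 69, 74, 79, 84, 89, Inf),
                      count = c(2400, 2100, 1700, 1200, 800, 500, 250) * 1000)
  prev_prop <- c(0.01, 0.02, 0.04, 0.08, 0.15, 0.25, 0.40)
  pop <- age_band_population("Canada-like", 2020, bands)
  prev <- count_table("Canada-like", "prevalence",
                      data.frame(year = 2020, age_lo = bands$age_lo,
                                 age_hi = bands$age_hi, sex = "all",
                                 count = bands$count * prev_prop))
  rates <- doubling_schedule(3.9, 62, 6.3, age_lo = 60, age_hi = 94,
                             band_width = 5, open_top = TRUE)
  list(pop = pop, prev = prev, rates = rates)
}

# Anchors of the published Canadian 20-year projection.
canada_anchors <- function() {
  data.frame(year = c(2011, 2031), prevalence = c(340000, 674000))
}

expect_headline <- function(report, check, value) {
  row <- report[report$check == check, ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$computed, value)
  expect_true(row$pass)
}
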