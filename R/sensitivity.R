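# Sensitivity analysis over the decision model: one-way sweeps, break-even
# thresholds, probabilistic sensitivity analysis and tornado tables.
#
# A "configuration" is a list with elements `test` (test_characteristics)
# and `params` (economic_params); parameters are addressed by name across
# both blocks.

#' Base configuration for sensitivity analyses
#'
#' @param test a [test_characteristics()].
#' @param params an [economic_params()].
#' @return List with elements `test` and `params`, class `screen_config`.
#' @examples
#' base_config()
#' @export
base_config <- function(test = test_characteristics(),
                        params = economic_params()) {
  stopifnot(inherits(test, "test_characteristics"),
            inherits(params, "economic_params"))
  structure(list(test = test, params = params), class = "screen_config")
}

#' Expected value of a configuration
#'
#' @param config a [base_config()].
#' @return Currency per screened subject.
#' @export
config_expected_value <- function(config) {
  expected_value(config$test, build_utility_matrix(config$params))
}

sweepable_params <- function() {
  c("se", "sp", "p", "wtp_base", "inflation_factor", "fx_rate",
    "qaly_weight", "delay_years", "annual_care_savings",
    "therapy_cost_annual", "therapy_cost_total", "scan_cost", "fn_penalty")
}

# Domain bounds used for sweep validation and threshold bisection.
# Probabilities use their natural bounds; the onset delay uses [0, 10]
# years; unbounded monetary parameters use [0, 10x the base value] (or a
# floor of 1e6 when the base is 0) as a generous finite search interval.
param_domain <- function(parameter, config) {
  base <- config$params[[parameter]] %||% config$test[[parameter]]
  switch(parameter,
    se = , sp = c(1e-9, 1),
    p = , qaly_weight = c(0, 1),
    delay_years = c(0, 10),
    c(0, max(10 * base, 1e6))
  )
}

set_config_param <- function(config, parameter, value) {
  if (!parameter %in% sweepable_params()) {
    stop(sprintf("unknown parameter `%s`; known: %s", parameter,
                 paste(sweepable_params(), collapse = ", ")), call. = FALSE)
  }
  if (parameter %in% c("se", "sp", "p")) {
    t <- config$test
    args <- list(se = t$se, sp = t$sp, p = t$p)
    args[[parameter]] <- value
    config$test <- do.call(test_characteristics, args)
    return(config)
  }
  p <- config$params
  args <- unclass(p)
  args[[parameter]] <- value
  if (parameter %in% c("delay_years", "therapy_cost_annual")) {
    # therapy accrues per year of delay unless a fixed total was requested
    args$therapy_cost_total <- args$therapy_cost_annual * args$delay_years
  }
  config$params <- do.call(economic_params, args)
  config
}

check_in_domain <- function(parameter, values, config) {
  dom <- param_domain(parameter, config)
  bad <- values < dom[1] | values > dom[2]
  if (any(bad)) {
    stop(sprintf("`%s` value %g outside its domain [%g, %g]", parameter,
                 values[which(bad)[1]], dom[1], dom[2]), call. = FALSE)
  }
}

#' One-way sensitivity sweep
#'
#' Recomputes the expected value at each grid point of one parameter,
#' holding everything else at the base configuration. Sweeping
#' `delay_years` or `therapy_cost_annual` rescales the total therapy cost
#' with the delay, so the sweep traces the model's affine dependence on the
#' delay length.
#'
#' @param parameter one of `se`, `sp`, `p`, `wtp_base`, `inflation_factor`,
#'   `fx_rate`, `qaly_weight`, `delay_years`, `annual_care_savings`,
#'   `therapy_cost_annual`, `therapy_cost_total`, `scan_cost`, `fn_penalty`.
#' @param grid numeric values within the parameter's domain.
#' @param config a [base_config()].
#' @return Data frame with columns `value` and `expected_value`, sorted by
#'   `value`.
#' @examples
#' one_way_sweep("delay_years", c(0, 2.5, 5), base_config())
#' @export
one_way_sweep <- function(parameter, grid, config = base_config()) {
  if (length(grid) == 0L) stop("`grid` must be non-empty", call. = FALSE)
  check_in_domain(parameter, grid, config)
  e <- vapply(grid, function(v) {
    config_expected_value(set_config_param(config, parameter, v))
  }, numeric(1))
  out <- data.frame(value = grid, expected_value = e)
  out <- out[order(out$value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Break-even threshold of one parameter
#'
#' Finds the parameter value at which the expected value crosses `target`
#' (default 0) by bisection over the parameter's domain. The expected value
#' must be monotone in the parameter over the domain (checked on a grid);
#' if it never changes sign the analysis reports `"none in domain"`.
#'
#' @param parameter parameter name (see [one_way_sweep()]).
#' @param config a [base_config()].
#' @param target expected-value level to solve for.
#' @param lower,upper optional domain override.
#' @param tol relative tolerance of the root (default `1e-6`).
#' @return The root, or the character string `"none in domain"` when the
#'   expected value does not cross `target` anywhere in the domain.
#' @examples
#' threshold_analysis("delay_years", base_config()) # ~0.39 years
#' @export
threshold_analysis <- function(parameter, config = base_config(), target = 0,
                               lower = NULL, upper = NULL, tol = 1e-6) {
  dom <- param_domain(parameter, config)
  lower <- lower %||% dom[1]
  upper <- upper %||% dom[2]
  check_in_domain(parameter, c(lower, upper), config)
  f <- function(v) {
    config_expected_value(set_config_param(config, parameter, v)) - target
  }
  grid <- seq(lower, upper, length.out = 21)
  fg <- vapply(grid, f, numeric(1))
  dg <- diff(fg)
  if (any(dg > 1e-9) && any(dg < -1e-9)) {
    stop(sprintf(
      "expected value is not monotone in `%s` over [%g, %g]; no unique threshold",
      parameter, lower, upper), call. = FALSE)
  }
  if (sign(fg[1]) == sign(fg[length(fg)]) && fg[1] != 0 &&
      fg[length(fg)] != 0) {
    return("none in domain")
  }
  a <- lower; b <- upper; fa <- fg[1]
  for (i in seq_len(200)) {
    m <- (a + b) / 2
    fm <- f(m)
    if (fm == 0 || (b - a) <= tol * max(abs(m), 1)) return(m)
    if (sign(fm) == sign(fa)) {
      a <- m; fa <- fm
    } else {
      b <- m
    }
  }
  (a + b) / 2
}

#' Parameter distribution for probabilistic sensitivity analysis
#'
#' @param parameter parameter name (see [one_way_sweep()]).
#' @param family `"point"`, `"beta"`, `"normal"`, `"lognormal"` or
#'   `"uniform"`. Probability-type parameters (`se`, `sp`, `p`,
#'   `qaly_weight`) accept `beta`, `uniform` (within `[0, 1]`) or `point`;
#'   non-negative monetary parameters accept `lognormal`, `normal`
#'   (truncated at 0), `uniform` or `point`.
#' @param mean,sd moments for `beta` (method-of-moments), `normal` and
#'   `lognormal` (natural-scale moments).
#' @param min,max support for `uniform`.
#' @param value location for `point`.
#' @return Object of class `dist_spec`.
#' @examples
#' dist_spec("se", "beta", mean = 0.9, sd = 0.05)
#' @export
dist_spec <- function(parameter,
                      family = c("point", "beta", "normal", "lognormal", "uniform"),
                      mean = NULL, sd = NULL, min = NULL, max = NULL,
                      value = NULL) {
  family <- match.arg(family)
  if (!parameter %in% sweepable_params()) {
    stop(sprintf("unknown parameter `%s`", parameter), call. = FALSE)
  }
  prob_param <- parameter %in% c("se", "sp", "p", "qaly_weight")
  if (prob_param && family %in% c("normal", "lognormal")) {
    stop(sprintf("family `%s` is not valid for probability parameter `%s`",
                 family, parameter), call. = FALSE)
  }
  spec <- list(parameter = parameter, family = family, mean = mean, sd = sd,
               min = min, max = max, value = value)
  if (family == "point" && is.null(value)) {
    stop("point distributions need `value`", call. = FALSE)
  }
  if (family %in% c("beta", "normal", "lognormal") &&
      (is.null(mean) || is.null(sd))) {
    stop(sprintf("%s distributions need `mean` and `sd`", family), call. = FALSE)
  }
  if (family == "uniform") {
    if (is.null(min) || is.null(max) || max < min) {
      stop("uniform distributions need `min` <= `max`", call. = FALSE)
    }
    if (prob_param && (min < 0 || max > 1)) {
      stop("uniform support for a probability parameter must lie in [0, 1]",
           call. = FALSE)
    }
  }
  if (family == "beta") {
    v <- sd^2
    if (mean <= 0 || mean >= 1 || v >= mean * (1 - mean)) {
      stop("beta method-of-moments needs 0 < mean < 1 and sd^2 < mean(1-mean)",
           call. = FALSE)
    }
  }
  structure(spec, class = "dist_spec")
}

draw_dist <- function(spec, n) {
  switch(spec$family,
    point = rep(spec$value, n),
    uniform = runif(n, spec$min, spec$max),
    normal = pmax(0, stats::rnorm(n, spec$mean, spec$sd)),
    beta = {
      m <- spec$mean; v <- spec$sd^2
      k <- m * (1 - m) / v - 1
      stats::rbeta(n, m * k, (1 - m) * k)
    },
    lognormal = {
      m <- spec$mean; s2 <- spec$sd^2
      sdlog <- sqrt(log(1 + s2 / m^2))
      meanlog <- log(m) - sdlog^2 / 2
      stats::rlnorm(n, meanlog, sdlog)
    }
  )
}

#' Probabilistic sensitivity analysis
#'
#' Propagates parameter uncertainty through the decision model by Monte
#' Carlo. One seed governs a single random stream; parameters are drawn in
#' sorted-name order, each consuming a contiguous block of the stream, so
#' results are reproducible and independent of the order in which specs are
#' supplied. Parameters without a spec stay at their configuration value;
#' point-mass specs reproduce the deterministic model exactly.
#'
#' @param specs list of [dist_spec()] objects (at most one per parameter).
#' @param n_draws number of Monte Carlo draws (>= 1).
#' @param seed RNG seed.
#' @param config a [base_config()].
#' @return Object of class `psa_result`: list with `mean`, `sd`,
#'   `p_positive` (probability the expected value exceeds 0), `quantiles`
#'   (2.5/25/50/75/97.5%), `n_draws`, and the per-draw data frame `draws`.
#' @examples
#' probabilistic_sa(list(dist_spec("se", "beta", mean = 0.9, sd = 0.03)),
#'                  n_draws = 200, seed = 1)
#' @export
probabilistic_sa <- function(specs, n_draws = 1000, seed = 1,
                             config = base_config()) {
  stop_if_not_number(n_draws, "n_draws", lower = 1)
  names(specs) <- vapply(specs, function(s) s$parameter, character(1))
  if (anyDuplicated(names(specs))) {
    stop("at most one distribution per parameter", call. = FALSE)
  }
  set.seed(seed)
  order_names <- sort(names(specs))
  draws <- as.data.frame(
    lapply(setNames(order_names, order_names),
           function(nm) draw_dist(specs[[nm]], n_draws)))
  e <- vapply(seq_len(n_draws), function(i) {
    cfg <- config
    for (nm in order_names) {
      cfg <- set_config_param(cfg, nm, draws[[nm]][i])
    }
    config_expected_value(cfg)
  }, numeric(1))
  draws$expected_value <- e
  structure(list(
    mean = mean(e),
    sd = if (n_draws > 1) sd(e) else 0,
    p_positive = mean(e > 0),
    quantiles = quantile(e, c(0.025, 0.25, 0.5, 0.75, 0.975)),
    n_draws = n_draws,
    draws = draws
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws: mean E = %.2f (sd %.2f), P(E > 0) = %.3f\n",
              x$n_draws, x$mean, x$sd, x$p_positive))
  print(round(x$quantiles, 2))
  invisible(x)
}

#' Tornado analysis
#'
#' Evaluates the expected value at a low and a high value of each parameter
#' (all else at base) and orders parameters by the width of the resulting
#' interval — the standard display of which inputs the decision is most
#' sensitive to.
#'
#' @param config a [base_config()].
#' @param ranges named list; each element is `c(low, high)` for one
#'   parameter, within its domain.
#' @return Data frame with columns `parameter`, `e_low`, `e_high`, `span`
#'   (`e_high - e_low`), sorted by `abs(span)` descending, ties broken by
#'   parameter name.
#' @examples
#' tornado(base_config(), list(delay_years = c(4, 6), scan_cost = c(1000, 3000)))
#' @export
tornado <- function(config = base_config(), ranges = list()) {
  if (length(ranges) == 0L) {
    stop("`ranges` must name at least one parameter", call. = FALSE)
  }
  rows <- lapply(names(ranges), function(nm) {
    r <- ranges[[nm]]
    if (length(r) != 2L) stop("each range must be c(low, high)", call. = FALSE)
    check_in_domain(nm, r, config)
    e <- vapply(r, function(v) {
      config_expected_value(set_config_param(config, nm, v))
    }, numeric(1))
    data.frame(parameter = nm, e_low = e[1], e_high = e[2],
               span = e[2] - e[1])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$span), out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot a tornado table
#'
#' Horizontal bars from `e_low` to `e_high` per parameter, widest at the
#' top, with the base-case expected value marked.
#'
#' @param tornado_table output of [tornado()].
#' @param base_e base-case expected value to mark (vertical line).
#' @return Invisibly, `tornado_table`.
#' @export
plot_tornado <- function(tornado_table, base_e = NULL) {
  n <- nrow(tornado_table)
  lo <- pmin(tornado_table$e_low, tornado_table$e_high)
  hi <- pmax(tornado_table$e_low, tornado_table$e_high)
  y <- rev(seq_len(n))
  graphics::plot(range(c(lo, hi, base_e)), c(0.5, n + 0.5), type = "n",
                 xlab = "expected value per screened subject",
                 ylab = "", yaxt = "n", main = "Tornado analysis")
  graphics::axis(2, at = y, labels = tornado_table$parameter, las = 1)
  graphics::rect(lo, y - 0.3, hi, y + 0.3, col = "grey70")
  if (!is.null(base_e)) graphics::abline(v = base_e, lty = 2)
  invisible(tornado_table)
}
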