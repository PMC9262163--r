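# Survival stage: female-year assembly, standardization, the AFT
# likelihood's closed-form limit, and prediction curves.

toy_survival_inputs <- function() {
  individuals <- tibble::tibble(
    id = c("f1", "f2", "f3"), sex = "F",
    birth_date = as.Date(c("2000-07-01", "2002-07-01", "1995-07-01")))
  covariates <- tidyr::expand_grid(id = c("f1", "f2", "f3"),
                                   year = 2010:2014) |>
    dplyr::mutate(group = "A", rank = rep(c(0.9, 0.5, 0.1), each = 5),
                  group_size = 18 + year - 2010)
  demography <- tibble::tibble(
    id = c("f1", "f2", "f3"),
    death_date = as.Date(c("2013-06-01", NA, NA)),
    last_observed = as.Date(c("2013-06-01", "2014-12-31", "2014-12-31")))
  estimates <- tidyr::expand_grid(id = c("f1", "f2", "f3"),
                                  year = 2010:2014) |>
    dplyr::mutate(post_mean = c(seq(-1, 1, length.out = 15)),
                  post_sd = 0.3)
  list(individuals = individuals, covariates = covariates,
       demography = demography, estimates = estimates)
}

test_that("female-year assembly sets status from demography and honors the lag", {
  inp <- toy_survival_inputs()
  rows <- assemble_female_years(inp$individuals, inp$covariates,
                                inp$demography, inp$estimates, lag = 0)
  f1 <- dplyr::filter(rows, female == "f1")
  expect_equal(nrow(f1), 4L)  # 2010-2013, dies 2013
  expect_equal(f1$status, c("survived", "survived", "survived", "died"))
  f2 <- dplyr::filter(rows, female == "f2")
  expect_equal(f2$status[f2$year == 2014], "censored")
  # manual join oracle: integration at t - 1 under lag = 1
  lag1 <- assemble_female_years(inp$individuals, inp$covariates,
                                inp$demography, inp$estimates, lag = 1)
  expect_equal(nrow(lag1), nrow(rows) - 3L)  # each female loses her first year
  byhand <- inp$estimates$post_mean[inp$estimates$id == "f2" &
                                      inp$estimates$year == 2011]
  expect_equal(lag1$integration_mean[lag1$female == "f2" &
                                       lag1$year == 2012], byhand)
  expect_true(all(lag1$year >= 2011))
  # overlapping female-years are an identified-input error
  dup <- dplyr::bind_rows(inp$covariates, inp$covariates[1, ])
  expect_error(assemble_female_years(inp$individuals, dup, inp$demography,
                                     inp$estimates),
               class = "capsoc_error_input")
  # rows lacking an estimate are dropped with a message
  expect_message(
    short <- assemble_female_years(inp$individuals, inp$covariates,
                                   inp$demography,
                                   dplyr::filter(inp$estimates,
                                                 year != 2012), lag = 0),
    "lacking an integration estimate")
  expect_false(any(short$year == 2012))
})

test_that("standardization is exact, links integration sd, and round-trips", {
  inp <- toy_survival_inputs()
  rows <- assemble_female_years(inp$individuals, inp$covariates,
                                inp$demography, inp$estimates, lag = 0)
  std <- standardize_covariates(rows)
  for (v in c("age", "rank", "group_size", "integration_mean")) {
    expect_equal(mean(std[[v]]), 0, tolerance = 1e-9)
    expect_equal(sd(std[[v]]), 1, tolerance = 1e-9)
  }
  sc <- covariate_scaling(std)
  s <- sc$scale[sc$covariate == "integration_mean"]
  ctr <- sc$center[sc$covariate == "integration_mean"]
  # the mean +/- sd interval maps linearly
  expect_equal((std$integration_mean + std$integration_sd) * s + ctr,
               rows$integration_mean + rows$integration_sd)
  back <- unstandardize_covariates(std)
  expect_equal(back$age, rows$age)
  expect_equal(back$integration_sd, rows$integration_sd)
  # zero-variance covariate is an identified error
  flat <- dplyr::mutate(rows, rank = 0.5)
  expect_error(standardize_covariates(flat),
               class = "capsoc_error_input")
})

test_that("intercept-only fit matches the exponential-rate MLE", {
  set.seed(42)
  n <- 800
  mu_true <- 9.2
  p <- 1 - exp(-365.25 * exp(-mu_true))
  rows <- tibble::tibble(
    female = sprintf("f%03d", seq_len(n)), year = 2010L, group = "A",
    age = rnorm(n), rank = rnorm(n), group_size = rnorm(n),
    status = ifelse(rbinom(n, 1, p) == 1, "died", "survived"),
    integration_mean = rnorm(n), integration_sd = 0.3)
  fit <- fit_aft(rows, fast_aft(seed = 4, covariates = character(),
                                social = FALSE, random = character(),
                                samples = 1000))
  deaths <- sum(rows$status == "died")
  # exponential-rate MLE on person-days (deaths are rare, so the Bernoulli
  # and exponential likelihoods almost coincide)
  mle <- log(n * 365.25 / deaths)
  est <- dplyr::filter(tidy(fit), term == "intercept")
  expect_lt(abs(est$estimate - mle), est$std.error)
})

test_that("the annual death probability follows the stated closed form", {
  expect_equal(1 - exp(-365.25 * exp(-9.46)), 0.028, tolerance = 2e-2)
  # fabricated degenerate draws: the curve must reproduce the formula
  fit <- structure(list(
    draws = cbind(intercept = rep(9.46, 100), social = rep(0.5, 100)),
    control = aft_control(seed = 1),
    scaling = tibble::tibble(covariate = "integration_mean", center = 0,
                             scale = 1),
    data = list(integration_range = c(-2, 2))), class = "capsoc_aft")
  curve <- predict_death_probability(fit, grid = c(-1, 0, 1))
  expect_equal(curve$p_mean[2], 1 - exp(-365.25 * exp(-9.46)),
               tolerance = 1e-12)
  # strictly decreasing when every draw of the social effect is positive
  expect_true(all(diff(curve$p_mean) < 0))
  expect_true(all(curve$p_mean > 0 & curve$p_mean < 1))
  # flat when the social effect is exactly zero
  fit$draws[, "social"] <- 0
  flat <- predict_death_probability(fit, grid = c(-1, 0, 1))
  expect_equal(diff(flat$p_mean), c(0, 0))
})

test_that("a strong positive social effect is recovered with the right sign", {
  cfg <- sim_config(n_groups = 5, females_per_group = 6,
                    males_per_group = 2, immatures_per_group = 3,
                    years = 8, beta_social = 0.8, seed = 21)
  sf <- simulate_female_years(cfg)
  fit <- suppressWarnings(
    fit_aft(standardize_covariates(sf$rows),
            fast_aft(seed = 22, samples = 900, warmup = 800)))
  est <- dplyr::filter(tidy(fit), term == "social")
  expect_gt(est$estimate, 0)
  expect_gt(est$conf.low, 0)
  # summary formatting follows the "m (lo; hi)" layout
  lab <- dplyr::filter(summarize_fit(fit), term == "social")$label
  expect_match(lab, "^-?\\d+\\.\\d{2} \\(-?\\d+\\.\\d{2}; -?\\d+\\.\\d{2}\\)$")
  # interval is the central 89%: mean within, bounds ordered
  expect_true(est$conf.low < est$estimate && est$estimate < est$conf.high)
  draws <- fit$draws[, "social"]
  expect_equal(unname(quantile(draws, 0.055)), est$conf.low,
               tolerance = 1e-9)
  expect_equal(unname(quantile(draws, 0.945)), est$conf.high,
               tolerance = 1e-9)
})

test_that("battery fits one model per measure and leaves foraging undirected", {
  cfg <- sim_config(n_groups = 3, females_per_group = 5,
                    males_per_group = 2, immatures_per_group = 2,
                    years = 5, seed = 31)
  pop <- simulate_population(cfg)
  surv <- simulate_survival(pop, pop$truth, cfg)
  est <- dplyr::bind_rows(
    simulate_integration_estimates(pop$truth, "grooming", "giving"),
    simulate_integration_estimates(pop$truth, "grooming", "receiving"),
    simulate_integration_estimates(pop$truth, "support", "giving"),
    simulate_integration_estimates(pop$truth, "support", "receiving"),
    simulate_integration_estimates(pop$truth, "foraging", "undirected")) |>
    dplyr::mutate(dataset = "all")
  bat <- suppressWarnings(suppressMessages(
    run_model_battery(pop$individuals, surv$covariates,
                      surv$demography, est, lag = 0,
                      control = fast_aft(seed = 32, samples = 400,
                                         warmup = 300, adapt = 300))))
  expect_equal(nrow(bat$results), 5L)
  expect_setequal(bat$results$measure,
                  c("grooming_giving", "grooming_receiving",
                    "support_giving", "support_receiving", "foraging"))
  tb <- battery_table(bat)
  expect_true(all(c("measure", "term", "all") %in% names(tb)))
  # every fit reports the full coefficient block
  expect_setequal(unique(tidy(bat)$term),
                  c("intercept", "social", "age", "rank", "group_size",
                    "sigma_female", "sigma_group"))
})
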