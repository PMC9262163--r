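# Bayesian accelerated failure time model for annual adult-female survival.
#
# Each female-year contributes a Bernoulli death indicator with
#   p_it = 1 - exp(-Delta * exp(-eta_it)),   Delta = 365.25 days,
#   eta_it = mu + beta_social * s*_it + beta_age * age_it
#            + beta_rank * rank_it + beta_gs * gs_it + u_female + v_group
# a piecewise-exponential AFT on a log-days timescale: exp(eta) is an
# expected lifetime in days, so positive coefficients lengthen survival and
# the intercept sits near log(lifetime in days) (~9.5). The integration
# covariate enters as a latent variable s*_it ~ Normal(mean_it, sd_it),
# propagating the SRM stage's measurement uncertainty.

#' MCMC, prior and structure settings for the survival model
#'
#' @param chains,adapt,warmup,samples,thin,seed As in [srm_control()].
#' @param delta Exposure per record in days (default 365.25: deaths are
#'   assigned a full year's exposure).
#' @param prior_mu_mean,prior_mu_sd Normal prior on the intercept
#'   (log-days scale).
#' @param prior_beta_sd Normal(0, .) prior SD shared by the slope
#'   coefficients.
#' @param prior_sd_scale Half-Normal scale for random-intercept SDs.
#' @param covariates Character subset of
#'   `c("age", "rank", "group_size")` to include.
#' @param social Include the social-integration term?
#' @param random Character subset of `c("female", "group")`: which crossed
#'   random intercepts to include.
#' @param measurement_error Propagate `integration_sd` through a latent
#'   covariate? If `FALSE` the posterior-mean offsets enter as fixed values.
#' @param ci Credible-interval mass (default 0.89, reported as central
#'   quantiles).
#' @param rhat_threshold Convergence flag threshold.
#' @return A list of class `capsoc_aft_control`.
#' @export
aft_control <- function(chains = 2, adapt = 1000, warmup = 2000,
                        samples = 2000, thin = 2, seed = 1,
                        delta = 365.25, prior_mu_mean = 9.5,
                        prior_mu_sd = 2, prior_beta_sd = 1,
                        prior_sd_scale = 1,
                        covariates = c("age", "rank", "group_size"),
                        social = TRUE, random = c("female", "group"),
                        measurement_error = TRUE, ci = 0.89,
                        rhat_threshold = 1.05) {
  stopifnot(chains >= 2, samples >= 100, delta > 0, ci > 0, ci < 1)
  covariates <- intersect(c("age", "rank", "group_size"), covariates)
  random <- intersect(c("female", "group"), random)
  structure(list(chains = chains, adapt = adapt, warmup = warmup,
                 samples = samples, thin = thin, seed = as.integer(seed),
                 delta = delta, prior_mu_mean = prior_mu_mean,
                 prior_mu_sd = prior_mu_sd, prior_beta_sd = prior_beta_sd,
                 prior_sd_scale = prior_sd_scale, covariates = covariates,
                 social = social, random = random,
                 measurement_error = measurement_error, ci = ci,
                 rhat_threshold = rhat_threshold),
            class = "capsoc_aft_control")
}

#' Assemble the female-year survival table
#'
#' Joins demography, annual covariates and one measure's social integration
#' estimates into the survival model's row unit: one adult female in one
#' calendar year. A female enters in the first year her mid-year (July 1)
#' age reaches 5 and leaves at death or at the end of her observation. With
#' `lag = 1`, survival in year t is paired with integration estimated in
#' year t - 1, which drops each female's first observed year.
#'
#' @param individuals Data frame: `id`, `sex`, `birth_date`.
#' @param covariates Data frame of observed female-years: `id`, `year`,
#'   `group`, `rank` (in `[0, 1]`, 1 = highest), `group_size`.
#' @param demography Data frame: `id`, `death_date` (NA if not observed to
#'   die), `last_observed` (date observation ended).
#' @param estimates Integration estimates for one measure: `id`, `year`,
#'   `post_mean`, `post_sd`.
#' @param lag 0 (same-year integration) or 1 (previous-year).
#' @return Tibble with columns `female`, `year`, `group`, `age`, `rank`,
#'   `group_size`, `status` (died / survived / censored),
#'   `integration_mean`, `integration_sd`, `lag`.
#' @export
assemble_female_years <- function(individuals, covariates, demography,
                                  estimates, lag = 0) {
  stopifnot(lag %in% c(0, 1))
  assert_cols(individuals, c("id", "sex", "birth_date"), "individuals")
  assert_cols(covariates, c("id", "year", "group", "rank", "group_size"),
              "covariates")
  assert_cols(demography, c("id", "death_date", "last_observed"),
              "demography")
  assert_cols(estimates, c("id", "year", "post_mean", "post_sd"),
              "estimates")

  fem <- individuals |> filter(.data$sex == "F")
  rows <- covariates |>
    inner_join(select(fem, "id", "birth_date"), by = "id") |>
    inner_join(select(demography, "id", "death_date", "last_observed"),
               by = "id") |>
    mutate(year = as.integer(.data$year),
           age = age_in_year(.data$birth_date, .data$year)) |>
    filter(.data$age >= 5)
  dup <- rows |> count(.data$id, .data$year) |> filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf("duplicated female-year(s): %s",
                  paste(sprintf("%s/%d", dup$id, dup$year), collapse = ", ")),
          class = "capsoc_error_input")
  }
  rows <- rows |>
    mutate(death_year = lubridate::year(.data$death_date),
           end_year = dplyr::coalesce(.data$death_year,
                                      lubridate::year(.data$last_observed))) |>
    filter(.data$year <= .data$end_year) |>
    group_by(.data$id) |>
    mutate(status = dplyr::case_when(
      !is.na(.data$death_year) & .data$year == .data$death_year ~ "died",
      .data$year == max(.data$year) ~ "censored",
      TRUE ~ "survived")) |>
    ungroup()

  est <- estimates |>
    transmute(id = .data$id, est_year = as.integer(.data$year),
              integration_mean = .data$post_mean,
              integration_sd = .data$post_sd)
  out <- rows |>
    mutate(est_year = .data$year - as.integer(lag)) |>
    left_join(est, by = c("id", "est_year"))
  n_drop <- sum(is.na(out$integration_mean))
  if (n_drop > 0) {
    inform(sprintf("dropped %d female-year(s) lacking an integration estimate (lag = %d)",
                   n_drop, lag))
  }
  out |>
    filter(!is.na(.data$integration_mean)) |>
    transmute(female = .data$id, year = .data$year, group = .data$group,
              age = .data$age, rank = .data$rank,
              group_size = .data$group_size, status = .data$status,
              integration_mean = .data$integration_mean,
              integration_sd = .data$integration_sd,
              lag = as.integer(lag)) |>
    arrange(.data$female, .data$year)
}

aft_covariate_names <- c("age", "rank", "group_size", "integration_mean")

#' Standardize survival-model covariates
#'
#' Centers and scales age, rank, group size and the integration posterior
#' mean over the analysis rows; `integration_sd` is divided by the same SD
#' as `integration_mean` so the mean +/- sd interval is preserved under the
#' transformation. The scaling record is kept as an attribute for
#' back-transformation of predictions.
#'
#' @param rows Output of [assemble_female_years()].
#' @return The rows with standardized covariate columns and a
#'   `capsoc_scaling` attribute (see [covariate_scaling()]).
#' @export
standardize_covariates <- function(rows) {
  assert_cols(rows, aft_covariate_names, "rows")
  sc <- purrr::map(aft_covariate_names, function(v) {
    x <- rows[[v]]
    if (length(unique(x)) < 2 || sd(x) == 0) {
      abort(sprintf("covariate `%s` has zero variance", v),
            class = "capsoc_error_input")
    }
    tibble(covariate = v, center = mean(x), scale = sd(x))
  }) |> bind_rows()
  out <- rows
  for (i in seq_len(nrow(sc))) {
    v <- sc$covariate[i]
    out[[v]] <- (out[[v]] - sc$center[i]) / sc$scale[i]
  }
  int_scale <- sc$scale[sc$covariate == "integration_mean"]
  if ("integration_sd" %in% names(out)) {
    out$integration_sd <- out$integration_sd / int_scale
  }
  attr(out, "capsoc_scaling") <- sc
  out
}

#' Retrieve the scaling record of a standardized table or fit
#' @param x A table from [standardize_covariates()] or a `capsoc_aft` fit.
#' @return Tibble with `covariate`, `center`, `scale`.
#' @export
covariate_scaling <- function(x) {
  if (inherits(x, "capsoc_aft")) return(x$scaling)
  attr(x, "capsoc_scaling")
}

#' Undo covariate standardization
#' @param rows A table produced by [standardize_covariates()].
#' @return The rows on the original covariate scales.
#' @export
unstandardize_covariates <- function(rows) {
  sc <- attr(rows, "capsoc_scaling")
  if (is.null(sc)) abort("`rows` carries no scaling record",
                         class = "capsoc_error_input")
  out <- rows
  for (i in seq_len(nrow(sc))) {
    v <- sc$covariate[i]
    out[[v]] <- out[[v]] * sc$scale[i] + sc$center[i]
  }
  int_scale <- sc$scale[sc$covariate == "integration_mean"]
  out$integration_sd <- out$integration_sd * int_scale
  attr(out, "capsoc_scaling") <- NULL
  out
}

aft_model_string <- function(control, P) {
  me <- control$social && control$measurement_error
  social_lat <- if (me) "
    sl[k] ~ dnorm(sm[k], pow(ssd[k], -2))" else ""
  soc_term <- if (control$social) {
    if (me) " + b_social * sl[k]" else " + b_social * sm[k]"
  } else ""
  x_term <- if (P > 0) " + inprod(X[k, ], b)" else ""
  u_term <- if ("female" %in% control$random) " + u[f[k]]" else ""
  v_term <- if ("group" %in% control$random) " + v[g[k]]" else ""
  blocks <- c(
    if (control$social) "
  b_social ~ dnorm(0, pow(prior_beta_sd, -2))",
    if (P > 0) "
  for (j in 1:P) { b[j] ~ dnorm(0, pow(prior_beta_sd, -2)) }",
    if ("female" %in% control$random) "
  for (i in 1:NF) { u[i] ~ dnorm(0, pow(sigma_female, -2)) }
  sigma_female ~ dnorm(0, pow(prior_sd, -2)) T(0,)",
    if ("group" %in% control$random) "
  for (i in 1:NG) { v[i] ~ dnorm(0, pow(sigma_group, -2)) }
  sigma_group ~ dnorm(0, pow(prior_sd, -2)) T(0,)")
  sprintf("model {
  for (k in 1:N) {%s
    eta[k] <- mu%s%s%s%s
    pdie[k] <- 1 - exp(-delta * exp(-eta[k]))
    died[k] ~ dbern(pdie[k])
  }
  mu ~ dnorm(prior_mu_mean, pow(prior_mu_sd, -2))%s
}", social_lat, soc_term, x_term, u_term, v_term,
      paste(blocks, collapse = ""))
}

#' Fit the Bayesian accelerated failure time survival model
#'
#' Fits annual adult-female survival as a function of one social
#' integration measure (entering as a latent covariate with the SRM
#' posterior SD as measurement error), standardized age, rank and group
#' size, and crossed female and group random intercepts. The annual death
#' probability is `1 - exp(-delta * exp(-eta))`, so positive coefficients
#' increase expected lifetime.
#'
#' @param rows Standardized female-year table from
#'   [standardize_covariates()].
#' @param control An [aft_control()] list.
#' @return An object of class `capsoc_aft` with posterior draws of the
#'   fixed effects and SD hyperparameters, an 89% (by default)
#'   central-interval summary, random-intercept summaries, diagnostics and
#'   the covariate scaling record. Supports [generics::tidy()],
#'   [generics::glance()] and [predict_death_probability()].
#' @export
fit_aft <- function(rows, control = aft_control()) {
  assert_cols(rows, c("female", "year", "group", "status"), "rows")
  if (control$social) assert_cols(rows, c("integration_mean",
                                          "integration_sd"), "rows")
  d <- as_tibble(rows) |> arrange(.data$female, .data$year)
  died <- as.integer(d$status == "died")
  covs <- intersect(control$covariates, names(d))
  P <- length(covs)

  data <- list(N = nrow(d), died = died, delta = control$delta,
               prior_mu_mean = control$prior_mu_mean,
               prior_mu_sd = control$prior_mu_sd)
  if (control$social || P > 0) data$prior_beta_sd <- control$prior_beta_sd
  if (length(control$random)) data$prior_sd <- control$prior_sd_scale
  if (P > 0) {
    data$X <- as.matrix(d[, covs])
    data$P <- P
  }
  if (control$social) {
    data$sm <- d$integration_mean
    if (control$measurement_error) {
      data$ssd <- pmax(d$integration_sd, 1e-6)
    }
  }
  flev <- glev <- NULL
  if ("female" %in% control$random) {
    flev <- sort(unique(d$female))
    data$f <- match(d$female, flev); data$NF <- length(flev)
  }
  if ("group" %in% control$random) {
    glev <- sort(unique(as.character(d$group)))
    data$g <- match(as.character(d$group), glev); data$NG <- length(glev)
  }

  monitor <- c("mu",
               if (control$social) "b_social",
               if (P > 0) "b",
               if (!is.null(flev)) c("sigma_female", "u"),
               if (!is.null(glev)) c("sigma_group", "v"))
  model <- aft_model_string(control, P)
  jm <- rjags::jags.model(textConnection(model), data = data,
                          inits = jags_inits(control$chains, control$seed),
                          n.chains = control$chains,
                          n.adapt = control$adapt, quiet = TRUE)
  if (control$warmup > 0) stats::update(jm, control$warmup,
                                        progress.bar = "none")
  mcl <- rjags::coda.samples(jm, monitor,
                             n.iter = control$samples * control$thin,
                             thin = control$thin, progress.bar = "none")
  arr <- mcmc_array(mcl)
  rh <- split_rhat(arr)
  names(rh) <- dimnames(arr)[[3]]

  # rename columns to stable term names
  nm <- dimnames(arr)[[3]]
  rename_map <- setNames(nm, nm)
  rename_map["mu"] <- "intercept"
  if (control$social) rename_map["b_social"] <- "social"
  if (P == 1) rename_map["b"] <- covs
  if (P > 1) rename_map[sprintf("b[%d]", seq_len(P))] <- covs
  fixed_terms <- c("intercept", if (control$social) "social", covs,
                   if (!is.null(flev)) "sigma_female",
                   if (!is.null(glev)) "sigma_group")
  draws <- apply(arr, 3, c)
  colnames(draws) <- unname(rename_map[colnames(draws)])
  fixed_draws <- draws[, fixed_terms, drop = FALSE]

  alpha <- (1 - control$ci) / 2
  summ <- tibble(term = fixed_terms,
                 estimate = unname(colMeans(fixed_draws)),
                 std.error = unname(apply(fixed_draws, 2, sd)),
                 conf.low = unname(apply(fixed_draws, 2, quantile, alpha)),
                 conf.high = unname(apply(fixed_draws, 2, quantile,
                                          1 - alpha)))

  ranef_tbl <- function(prefix, lev, label) {
    if (is.null(lev)) return(NULL)
    cols <- sprintf("%s[%d]", prefix, seq_along(lev))
    tibble(level = label, id = lev,
           estimate = colMeans(draws[, unname(rename_map[cols]),
                                     drop = FALSE]),
           std.error = apply(draws[, unname(rename_map[cols]),
                                   drop = FALSE], 2, sd))
  }
  ranef <- bind_rows(ranef_tbl("u", flev, "female"),
                     ranef_tbl("v", glev, "group"))

  key_rhat <- rh[names(rename_map)[rename_map %in% fixed_terms]]
  diagnostics <- list(
    rhat = setNames(unname(key_rhat),
                    rename_map[names(key_rhat)]),
    max_rhat = max(key_rhat, na.rm = TRUE),
    ess = ess_safe(mcl, intersect(colnames(as.matrix(mcl[[1]])),
                                  c("mu", "b_social"))),
    converged = all(key_rhat <= control$rhat_threshold, na.rm = TRUE))
  if (!diagnostics$converged) {
    warn(sprintf("AFT fit flagged: max split-Rhat %.3f exceeds %.2f",
                 diagnostics$max_rhat, control$rhat_threshold),
         class = "capsoc_warning_convergence")
  }

  structure(list(
    draws = fixed_draws, summary = summ, ranef = ranef,
    diagnostics = diagnostics, scaling = attr(rows, "capsoc_scaling"),
    data = list(n = nrow(d), n_females = length(unique(d$female)),
                n_groups = length(unique(d$group)), deaths = sum(died),
                person_days = nrow(d) * control$delta,
                integration_range = if (control$social)
                  range(d$integration_mean) else NULL),
    control = control), class = "capsoc_aft")
}

#' @export
print.capsoc_aft <- function(x, ...) {
  cat(sprintf("Bayesian AFT survival model: %d female-years, %d females, %d deaths\n",
              x$data$n, x$data$n_females, x$data$deaths))
  cat(sprintf("  max split-Rhat %.3f (%s)\n", x$diagnostics$max_rhat,
              if (x$diagnostics$converged) "converged" else "FLAGGED"))
  print(summarize_fit(x))
  invisible(x)
}

#' Coefficient table for an AFT fit
#'
#' Posterior means with central credible intervals, formatted
#' "mean (lo; hi)" as in standard reporting of these models.
#'
#' @param result A `capsoc_aft` fit.
#' @param digits Digits for the formatted label.
#' @return Tibble: `term`, `estimate`, `conf.low`, `conf.high`, `label`.
#' @export
summarize_fit <- function(result, digits = 2) {
  stopifnot(inherits(result, "capsoc_aft"))
  result$summary |>
    mutate(label = fmt_est(.data$estimate, .data$conf.low,
                           .data$conf.high, digits)) |>
    select("term", "estimate", "conf.low", "conf.high", "label")
}

#' @export
tidy.capsoc_aft <- function(x, ...) x$summary

#' @export
glance.capsoc_aft <- function(x, ...) {
  tibble(n = x$data$n, n_females = x$data$n_females,
         n_groups = x$data$n_groups, deaths = x$data$deaths,
         max_rhat = x$diagnostics$max_rhat,
         converged = x$diagnostics$converged)
}

#' Predicted annual death probability across the integration range
#'
#' Evaluates, per posterior draw, the annual probability of dying as a
#' function of the social integration measure with all other covariates at
#' their sample means and random intercepts at zero, then summarises the
#' draws into a posterior-mean curve with a central credible band.
#'
#' @param result A `capsoc_aft` fit (with a social term).
#' @param grid Numeric grid on the original (unstandardized) integration
#'   scale; default: 50 points over the fitted data's range.
#' @param n Grid size when `grid` is NULL.
#' @return Tibble of class `capsoc_curve`: `integration`,
#'   `integration_std`, `p_mean`, `p_lo`, `p_hi`.
#' @export
predict_death_probability <- function(result, grid = NULL, n = 50) {
  stopifnot(inherits(result, "capsoc_aft"), result$control$social)
  sc <- result$scaling
  ctr <- sc$center[sc$covariate == "integration_mean"]
  scl <- sc$scale[sc$covariate == "integration_mean"]
  if (is.null(grid)) {
    r_std <- result$data$integration_range
    grid <- seq(r_std[1], r_std[2], length.out = n) * scl + ctr
  }
  s_std <- (grid - ctr) / scl
  mu <- result$draws[, "intercept"]
  bs <- result$draws[, "social"]
  delta <- result$control$delta
  alpha <- (1 - result$control$ci) / 2
  out <- purrr::map(seq_along(grid), function(i) {
    eta <- mu + bs * s_std[i]
    p <- 1 - exp(-delta * exp(-eta))
    tibble(integration = grid[i], integration_std = s_std[i],
           p_mean = mean(p),
           p_lo = unname(quantile(p, alpha)),
           p_hi = unname(quantile(p, 1 - alpha)))
  }) |> bind_rows()
  class(out) <- c("capsoc_curve", class(out))
  out
}

#' Plot a predicted annual death-probability curve
#' @param object A `capsoc_curve` from [predict_death_probability()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.capsoc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$integration,
                                       y = .data$p_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p_lo,
                                      ymax = .data$p_hi),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "social integration offset (logit scale)",
                  y = "annual probability of dying") +
    ggplot2::theme_minimal()
}

#' Fit the full battery of survival models
#'
#' One AFT model per (measure, partner dataset) combination -- five
#' measures (grooming giving/receiving, support giving/receiving,
#' undirected foraging) by three partner datasets gives the full
#' fifteen-model battery -- all under an identical configuration. Flagged
#' (non-converged) fits are recorded and the battery continues.
#'
#' @param individuals,covariates,demography As in
#'   [assemble_female_years()].
#' @param estimates_all Integration estimates across measures and datasets:
#'   columns `dataset`, `id`, `year`, `behavior`, `direction`, `post_mean`,
#'   `post_sd`.
#' @param lag 0 or 1.
#' @param control An [aft_control()] list shared by every model.
#' @return Object of class `capsoc_battery`: tibble `results` with one row
#'   per model (`dataset`, `measure`, fit diagnostics, nested coefficient
#'   summary, the fit object) plus a battery `manifest`.
#' @export
run_model_battery <- function(individuals, covariates, demography,
                              estimates_all, lag = 0,
                              control = aft_control()) {
  assert_cols(estimates_all, c("dataset", "id", "year", "behavior",
                               "direction", "post_mean", "post_sd"),
              "estimates_all")
  cells <- estimates_all |>
    distinct(.data$dataset, .data$behavior, .data$direction) |>
    mutate(measure = if_else(.data$direction == "undirected",
                             .data$behavior,
                             paste(.data$behavior, .data$direction,
                                   sep = "_")))
  results <- purrr::pmap(cells, function(dataset, behavior, direction,
                                         measure) {
    est <- estimates_all |>
      filter(.data$dataset == !!dataset, .data$behavior == !!behavior,
             .data$direction == !!direction)
    rows <- assemble_female_years(individuals, covariates, demography,
                                  est, lag = lag)
    fit <- fit_aft(standardize_covariates(rows), control)
    tibble(dataset = dataset, measure = measure, n = fit$data$n,
           deaths = fit$data$deaths,
           converged = fit$diagnostics$converged,
           max_rhat = fit$diagnostics$max_rhat,
           summary = list(summarize_fit(fit)), fit = list(fit))
  }) |> bind_rows()
  manifest <- list(lag = lag, n_models = nrow(results),
                   flagged = results$measure[!results$converged],
                   control = unclass(control))
  structure(list(results = results, manifest = manifest),
            class = "capsoc_battery")
}

#' @export
print.capsoc_battery <- function(x, ...) {
  cat(sprintf("AFT model battery: %d models, lag %d\n",
              nrow(x$results), x$manifest$lag))
  print(select(x$results, -"summary", -"fit"))
  invisible(x)
}

#' @export
tidy.capsoc_battery <- function(x, ...) {
  x$results |>
    select("dataset", "measure", "summary") |>
    tidyr::unnest("summary")
}

#' Coefficient table across the battery, one column per partner dataset
#'
#' @param battery A `capsoc_battery`.
#' @return Tibble with `measure`, `term` and one formatted
#'   "mean (lo; hi)" column per partner dataset.
#' @export
battery_table <- function(battery) {
  stopifnot(inherits(battery, "capsoc_battery"))
  tidy(battery) |>
    select("dataset", "measure", "term", "label") |>
    tidyr::pivot_wider(names_from = "dataset", values_from = "label")
}
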