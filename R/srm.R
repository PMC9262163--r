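# Multilevel Social Relations Model (SRM) on annual dyadic
# count/opportunity tables.
#
# Directed behaviors:   count_ijt ~ Binomial(opp_ijt, p_ijt)
#                       logit p_ijt = alpha + y_t + g_it + r_jt
# Undirected foraging:  logit p_ijt = alpha + y_t + s_it + s_jt
#
# g (giving), r (receiving) and s are zero-centered Normal(0, sigma) random
# effects per individual-year; y_t are zero-centered year offsets (omitted
# when the table spans a single year). The per-individual-year posterior
# mean and SD of these offsets are the social integration estimates carried
# into the survival stage.

#' MCMC and prior settings for the Social Relations Model
#'
#' @param chains Number of MCMC chains (>= 2 so split-R-hat is defined).
#' @param adapt,warmup,samples,thin JAGS adaptation, burn-in, retained
#'   iterations per chain, and thinning.
#' @param seed Integer seed; chain RNGs are derived from it, so results are
#'   reproducible.
#' @param prior_intercept_sd SD of the Normal(0, .) prior on the intercept
#'   (logit scale).
#' @param prior_sd_scale Scale of the half-Normal prior on random-effect
#'   SDs.
#' @param rhat_threshold Convergence flag threshold on split-R-hat of
#'   reported offsets.
#' @return A list of class `capsoc_srm_control`.
#' @export
srm_control <- function(chains = 2, adapt = 500, warmup = 500,
                        samples = 1500, thin = 1, seed = 1,
                        prior_intercept_sd = 2.5, prior_sd_scale = 1,
                        rhat_threshold = 1.05) {
  stopifnot(chains >= 2, adapt >= 0, warmup >= 0, samples >= 100,
            thin >= 1, is.numeric(seed))
  structure(list(chains = chains, adapt = adapt, warmup = warmup,
                 samples = samples, thin = thin, seed = as.integer(seed),
                 prior_intercept_sd = prior_intercept_sd,
                 prior_sd_scale = prior_sd_scale,
                 rhat_threshold = rhat_threshold),
            class = "capsoc_srm_control")
}

srm_model_string <- function(directed, multi_year) {
  yr <- if (multi_year) " + yr[yi[k]]" else ""
  lin <- if (directed) "g[gi[k]] + r[ri[k]]" else "s[si[k]] + s[sj[k]]"
  re <- if (directed) "
  for (i in 1:NG) { g[i] ~ dnorm(0, pow(sigma_g, -2)) }
  for (i in 1:NR) { r[i] ~ dnorm(0, pow(sigma_r, -2)) }
  sigma_g ~ dnorm(0, pow(prior_sd, -2)) T(0,)
  sigma_r ~ dnorm(0, pow(prior_sd, -2)) T(0,)" else "
  for (i in 1:NS) { s[i] ~ dnorm(0, pow(sigma_s, -2)) }
  sigma_s ~ dnorm(0, pow(prior_sd, -2)) T(0,)"
  yr_block <- if (multi_year) "
  for (t in 1:NY) { yr[t] ~ dnorm(0, pow(sigma_y, -2)) }
  sigma_y ~ dnorm(0, pow(prior_sd, -2)) T(0,)" else ""
  sprintf("model {
  for (k in 1:N) {
    count[k] ~ dbin(p[k], opp[k])
    logit(p[k]) <- alpha%s + %s
  }%s%s
  alpha ~ dnorm(0, pow(prior_alpha_sd, -2))
}", yr, lin, re, yr_block)
}

jags_inits <- function(chains, seed) {
  lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Wichmann-Hill",
         .RNG.seed = as.integer((seed * 131 + ch) %% (2^31 - 1)))
  })
}

# iterations x chains x parameter array from an mcmc.list
mcmc_array <- function(mcl) {
  mats <- lapply(mcl, as.matrix)
  arr <- array(NA_real_, dim = c(nrow(mats[[1]]), length(mats),
                                 ncol(mats[[1]])),
               dimnames = list(NULL, NULL, colnames(mats[[1]])))
  for (ch in seq_along(mats)) arr[, ch, ] <- mats[[ch]]
  arr
}

#' Fit the Social Relations Model to a dyad-year table
#'
#' Fits the annualized multilevel SRM to one behavior's
#' count/opportunity table and returns zero-centered social integration
#' offsets per individual-year with posterior means and SDs. Uncertainty
#' grows for infrequently observed individuals, and that uncertainty is
#' what the survival stage propagates.
#'
#' @param dyads Dyad-year tibble from [build_dyads()]: columns `year`,
#'   `behavior`, `directed`, `actor`, `partner`, `count`, `opportunities`.
#'   Must contain a single behavior.
#' @param control A [srm_control()] list.
#' @return An object of class `capsoc_srm` with elements
#'   \describe{
#'     \item{estimates}{tibble: `id`, `year`, `behavior`, `direction`
#'       (giving / receiving / undirected), `post_mean`, `post_sd`}
#'     \item{params}{posterior summaries of intercept and SD
#'       hyperparameters}
#'     \item{diagnostics}{split-R-hat and effective sample sizes; a
#'       `converged` flag}
#'   }
#'   [generics::tidy()] returns the estimates; [generics::glance()] the
#'   one-row fit summary.
#' @export
fit_srm <- function(dyads, control = srm_control()) {
  assert_cols(dyads, dyad_cols, "dyads")
  behavior <- unique(dyads$behavior)
  if (length(behavior) != 1) {
    abort("`dyads` must contain exactly one behavior",
          class = "capsoc_error_input")
  }
  if (any(dyads$count > dyads$opportunities)) {
    abort("count exceeds opportunities in `dyads`",
          class = "capsoc_error_input")
  }
  directed <- unique(dyads$directed)
  stopifnot(length(directed) == 1)
  d <- dyads |>
    filter(.data$opportunities > 0) |>
    arrange(.data$year, .data$actor, .data$partner)
  years <- sort(unique(d$year))
  multi_year <- length(years) > 1

  iy_key <- function(id, year) paste(id, year, sep = "@")
  data <- list(N = nrow(d), count = as.integer(d$count),
               opp = as.integer(d$opportunities),
               prior_alpha_sd = control$prior_intercept_sd,
               prior_sd = control$prior_sd_scale)
  if (multi_year) data$yi <- match(d$year, years)
  if (multi_year) data$NY <- length(years)
  if (directed) {
    glev <- sort(unique(iy_key(d$actor, d$year)))
    rlev <- sort(unique(iy_key(d$partner, d$year)))
    data$gi <- match(iy_key(d$actor, d$year), glev)
    data$ri <- match(iy_key(d$partner, d$year), rlev)
    data$NG <- length(glev); data$NR <- length(rlev)
    monitor <- c("g", "r", "alpha", "sigma_g", "sigma_r")
  } else {
    slev <- sort(unique(c(iy_key(d$actor, d$year),
                          iy_key(d$partner, d$year))))
    data$si <- match(iy_key(d$actor, d$year), slev)
    data$sj <- match(iy_key(d$partner, d$year), slev)
    data$NS <- length(slev)
    monitor <- c("s", "alpha", "sigma_s")
  }
  if (multi_year) monitor <- c(monitor, "yr", "sigma_y")

  model <- srm_model_string(directed, multi_year)
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
  pm <- apply(arr, 3, mean)
  ps <- apply(arr, 3, sd)
  rh <- split_rhat(arr)
  names(rh) <- dimnames(arr)[[3]]

  unpack <- function(prefix, lev, direction) {
    nm <- sprintf("%s[%d]", prefix, seq_along(lev))
    parts <- strsplit(lev, "@", fixed = TRUE)
    tibble(id = vapply(parts, `[`, "", 1),
           year = as.integer(vapply(parts, `[`, "", 2)),
           behavior = behavior, direction = direction,
           post_mean = unname(pm[nm]), post_sd = unname(ps[nm]),
           rhat = unname(rh[nm]))
  }
  estimates <- if (directed) {
    bind_rows(unpack("g", glev, "giving"), unpack("r", rlev, "receiving"))
  } else {
    unpack("s", slev, "undirected")
  }

  hyper <- setdiff(monitor, c("g", "r", "s", "yr"))
  params <- tibble(term = hyper, estimate = unname(pm[hyper]),
                   std.error = unname(ps[hyper]), rhat = unname(rh[hyper]))
  offset_rhat <- estimates$rhat
  diagnostics <- list(
    max_rhat = max(offset_rhat, na.rm = TRUE),
    rhat = c(setNames(params$rhat, params$term)),
    ess = ess_safe(mcl, hyper),
    converged = all(offset_rhat <= control$rhat_threshold, na.rm = TRUE))
  structure(list(estimates = select(estimates, -"rhat"), params = params,
                 diagnostics = diagnostics, behavior = behavior,
                 directed = directed, years = years, control = control,
                 n_dyad_years = nrow(d)),
            class = "capsoc_srm")
}

#' @export
print.capsoc_srm <- function(x, ...) {
  cat(sprintf("Social Relations Model: %s (%s)\n", x$behavior,
              if (x$directed) "directed" else "undirected"))
  cat(sprintf("  %d dyad-year rows, years %s-%s\n", x$n_dyad_years,
              min(x$years), max(x$years)))
  cat(sprintf("  %d individual-year offsets; max split-Rhat %.3f (%s)\n",
              nrow(x$estimates), x$diagnostics$max_rhat,
              if (x$diagnostics$converged) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.capsoc_srm <- function(x, ...) x$estimates

#' @export
glance.capsoc_srm <- function(x, ...) {
  tibble(behavior = x$behavior, directed = x$directed,
         n_dyad_years = x$n_dyad_years,
         n_offsets = nrow(x$estimates),
         max_rhat = x$diagnostics$max_rhat,
         converged = x$diagnostics$converged)
}

#' Caterpillar plot of social integration offsets
#'
#' @param object A `capsoc_srm` fit.
#' @param ... Unused.
#' @return A ggplot object: individual-year offsets ranked by posterior
#'   mean with +/- 1 posterior SD bars, faceted by direction.
#' @export
autoplot.capsoc_srm <- function(object, ...) {
  est <- object$estimates |>
    group_by(.data$direction) |>
    arrange(.data$post_mean, .by_group = TRUE) |>
    mutate(.rank = row_number()) |>
    ungroup()
  ggplot2::ggplot(est, ggplot2::aes(x = .data$.rank, y = .data$post_mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$post_mean - .data$post_sd,
      ymax = .data$post_mean + .data$post_sd),
      size = 0.2) +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = "individual-year (ranked)",
                  y = "integration offset (logit scale)",
                  title = sprintf("%s offsets", object$behavior)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Ranges of social integration estimates
#'
#' Summarises posterior-mean offsets as (min, max) per measure
#' (behavior x direction) and, when present, per partner dataset -- the
#' shape used to report how much individuals vary on each measure.
#'
#' @param estimates Tibble of estimates from one or more [fit_srm()] runs
#'   (rows bind-able; an optional `dataset` column distinguishes partner
#'   datasets).
#' @return Tibble with `measure`, `dataset`, `min`, `max` and a formatted
#'   `label` ("min; max").
#' @export
summarize_integration_ranges <- function(estimates) {
  assert_cols(estimates, c("behavior", "direction", "post_mean"),
              "estimates")
  if (!nrow(estimates)) {
    abort("`estimates` is empty", class = "capsoc_error_input")
  }
  est <- as_tibble(estimates)
  if (!"dataset" %in% names(est)) est$dataset <- "all"
  est |>
    mutate(measure = if_else(.data$direction == "undirected",
                             .data$behavior,
                             paste(.data$behavior, .data$direction))) |>
    group_by(.data$measure, .data$dataset) |>
    summarise(min = min(.data$post_mean), max = max(.data$post_mean),
              .groups = "drop") |>
    mutate(label = sprintf("%.2f; %.2f", .data$min, .data$max))
}
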