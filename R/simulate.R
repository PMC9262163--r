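# Synthetic study generator: a capuchin-like multi-group population with
# known ground truth, used to validate the whole pipeline by parameter
# recovery.
#
# Latent sociality propensities live on the logit scale, matching what the
# SRM estimates: per behavior, each individual has a persistent giving
# (g), receiving (r) or undirected (s) propensity plus small annual
# jitter. Survival is generated from the same piecewise-exponential AFT
# likelihood the survival stage fits, driven by the TRUE grooming-giving
# propensity (the generator's designated sociality axis).

#' Configuration for the synthetic study generator
#'
#' Defaults describe a mid-sized longitudinal field study: 10 social
#' groups of 8 adult females, 4 adult males and 6 immatures followed for
#' 15 years, with observation densities about one fifth of a
#' high-intensity field site (7 focal follows per individual-year, 64
#' aggressive 5-min intervals and 417 group scans per group-year); the
#' `paper_scale` preset multiplies densities by 5.
#'
#' @param n_groups,females_per_group,males_per_group,immatures_per_group
#'   Population structure.
#' @param years Number of study years.
#' @param start_year First calendar year.
#' @param follows_per_ind_year Mean focal follows per individual-year.
#' @param intervals_per_group_year Mean aggressive conflicts (5-min
#'   intervals) per group-year.
#' @param scans_per_group_year Mean group scans per group-year.
#' @param base_logit Named baseline logit rates per behavior.
#' @param sd_g,sd_r Named SDs of giving and receiving propensities for the
#'   directed behaviors (grooming, support).
#' @param sd_s SD of the undirected foraging propensity.
#' @param sociality_jitter_sd SD of the annual jitter around each
#'   individual's persistent propensity.
#' @param integration_noise_sd Measurement noise SD of the generator's own
#'   synthetic integration "estimates" (used for direct survival-stage
#'   recovery tests that bypass the SRM).
#' @param male_migration_rate Annual probability a male leaves (replaced by
#'   an immigrant, keeping group size stable).
#' @param p_forage Probability a scan is in the foraging context.
#' @param p_background Probability a non-close co-resident appears as a
#'   far (5-10 body length) neighbor in a scan.
#' @param mu,beta_social,beta_age,beta_rank,beta_groupsize True survival
#'   coefficients on the standardized scale; `mu` on log-days.
#' @param sigma_female,sigma_group True random-intercept SDs.
#' @param delta Exposure days per year.
#' @param paper_scale If TRUE, multiply observation densities by 5.
#' @param seed Mandatory integer seed.
#' @return A list of class `capsoc_sim_config`.
#' @export
sim_config <- function(n_groups = 10, females_per_group = 8,
                       males_per_group = 4, immatures_per_group = 6,
                       years = 15, start_year = 2002,
                       follows_per_ind_year = 7,
                       intervals_per_group_year = 64,
                       scans_per_group_year = 417,
                       base_logit = c(grooming = -4, support = -3.5,
                                      foraging = -2),
                       sd_g = c(grooming = 1, support = 0.8),
                       sd_r = c(grooming = 0.5, support = 0.5),
                       sd_s = 0.8, sociality_jitter_sd = 0.2,
                       integration_noise_sd = 0.3,
                       male_migration_rate = 0.2, p_forage = 0.6,
                       p_background = 0.3, mu = 9.46, beta_social = 0.5,
                       beta_age = -0.5, beta_rank = -0.25,
                       beta_groupsize = 0.25, sigma_female = 0.3,
                       sigma_group = 0.3, delta = 365.25,
                       paper_scale = FALSE, seed) {
  if (missing(seed)) abort("`seed` is mandatory in sim_config()",
                           class = "capsoc_error_input")
  stopifnot(n_groups >= 1, years >= 1, females_per_group >= 1)
  k <- if (paper_scale) 5 else 1
  structure(list(
    n_groups = n_groups, females_per_group = females_per_group,
    males_per_group = males_per_group,
    immatures_per_group = immatures_per_group, years = years,
    start_year = start_year,
    follows_per_ind_year = follows_per_ind_year * k,
    intervals_per_group_year = intervals_per_group_year * k,
    scans_per_group_year = scans_per_group_year * k,
    base_logit = base_logit, sd_g = sd_g, sd_r = sd_r, sd_s = sd_s,
    sociality_jitter_sd = sociality_jitter_sd,
    integration_noise_sd = integration_noise_sd,
    male_migration_rate = male_migration_rate, p_forage = p_forage,
    p_background = p_background, mu = mu, beta_social = beta_social,
    beta_age = beta_age, beta_rank = beta_rank,
    beta_groupsize = beta_groupsize, sigma_female = sigma_female,
    sigma_group = sigma_group, delta = delta,
    seed = as.integer(seed)), class = "capsoc_sim_config")
}

rand_date_in_year <- function(year, n = 1) {
  as.Date(sprintf("%d-01-01", year)) + sample.int(365, n, replace = TRUE) - 1
}

rand_time_in_year <- function(year, n = 1) {
  start <- as.POSIXct(sprintf("%d-01-01 06:00:00", year), tz = "UTC")
  start + runif(n, 0, 364 * 86400) + runif(n, 0, 8 * 3600)
}

#' Simulate the study population
#'
#' Generates individuals with birth dates and sex, group membership
#' histories (males migrate; an emigrant is replaced by a new immigrant),
#' latent sociality propensities, and a provisional covariate table
#' computed as if no one dies (the survival stage recomputes rank and group
#' size among survivors year by year).
#'
#' @param config A [sim_config()].
#' @return List with `individuals`, `membership`, `covariates`
#'   (provisional) and `truth` (latent propensities and generator
#'   parameters).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "capsoc_sim_config"))
  set.seed(derive_seed(config$seed, "population"))
  y0 <- config$start_year
  yrs <- seq(y0, y0 + config$years - 1)
  study_start <- as.Date(sprintf("%d-01-01", y0))
  study_end <- as.Date(sprintf("%d-12-31", max(yrs)))

  groups <- sprintf("G%02d", seq_len(config$n_groups))
  mk_ids <- function(prefix, g, n) sprintf("%s%02d_%s", prefix,
                                           match(g, groups), seq_len(n))
  ind <- list(); mem <- list()
  for (g in groups) {
    nf <- config$females_per_group
    fem <- tibble(id = mk_ids("F", g, nf), sex = "F",
                  birth_date = study_start -
                    round(runif(nf, 5, 20) * 365.25))
    # group sizes vary naturally: immature and male counts are Poisson
    # around the configured means (female counts are exact)
    nim <- rpois(1, config$immatures_per_group)
    imm <- tibble(id = mk_ids("I", g, nim),
                  sex = sample(c("F", "M"), nim, replace = TRUE),
                  birth_date = study_start -
                    round(runif(nim, 0.5, 4.5) * 365.25))
    core <- bind_rows(fem, imm)
    ind[[g]] <- core
    mem[[g]] <- tibble(id = core$id, group = g, entry = study_start,
                       exit = study_end)
    # males: migration with replacement
    nm <- rpois(1, config$males_per_group)
    males <- list(); male_mem <- list()
    slots <- seq_len(nm); next_id <- 1L
    entry <- rep(study_start, nm)
    cur <- sprintf("M%02d_%d", match(g, groups), seq_len(nm))
    next_id <- nm + 1L
    bd <- study_start - round(runif(nm, 6, 15) * 365.25)
    for (s in slots) {
      id <- cur[s]; ent <- entry[s]; b <- bd[s]
      repeat {
        stay_years <- rgeom(1, config$male_migration_rate) + 1
        ex <- min(ent + round(stay_years * 365.25), study_end)
        males[[id]] <- tibble(id = id, sex = "M", birth_date = b)
        male_mem[[id]] <- tibble(id = id, group = g, entry = ent, exit = ex)
        if (ex >= study_end) break
        ent <- ex + 1
        id <- sprintf("M%02d_%d", match(g, groups), next_id)
        next_id <- next_id + 1L
        b <- ent - round(runif(1, 6, 15) * 365.25)
      }
    }
    ind[[g]] <- bind_rows(ind[[g]], bind_rows(males))
    mem[[g]] <- bind_rows(mem[[g]], bind_rows(male_mem))
  }
  individuals <- bind_rows(ind)
  membership <- bind_rows(mem)

  # persistent latent propensities per behavior + annual jitter
  n <- nrow(individuals)
  base_lat <- tibble(
    id = individuals$id,
    g_grooming = rnorm(n, 0, config$sd_g[["grooming"]]),
    r_grooming = rnorm(n, 0, config$sd_r[["grooming"]]),
    g_support = rnorm(n, 0, config$sd_g[["support"]]),
    r_support = rnorm(n, 0, config$sd_r[["support"]]),
    s_foraging = rnorm(n, 0, config$sd_s))
  latents <- tidyr::expand_grid(id = individuals$id, year = yrs) |>
    left_join(base_lat, by = "id") |>
    mutate(across(dplyr::starts_with(c("g_", "r_", "s_")),
                  ~ .x + rnorm(dplyr::n(), 0, config$sociality_jitter_sd)))

  rank_base <- tibble(id = individuals$id,
                      rank_base = runif(n),
                      u_female = rnorm(n, 0, config$sigma_female))
  v_group <- tibble(group = groups,
                    v_group = rnorm(length(groups), 0, config$sigma_group))
  rank_noise <- tidyr::expand_grid(id = individuals$id, year = yrs) |>
    mutate(rank_noise = rnorm(dplyr::n(), 0, 0.1))
  # census noise: the annual mean group size is an estimate from repeated
  # counts, so it fluctuates a little around the true monthly mean
  gs_noise <- tidyr::expand_grid(group = groups, year = yrs) |>
    mutate(gs_noise = rnorm(dplyr::n(), 0, 0.4))

  truth <- list(config = config, latents = latents, rank_base = rank_base,
                v_group = v_group, rank_noise = rank_noise,
                gs_noise = gs_noise, years = yrs, groups = groups)
  covariates <- compute_covariates(individuals, membership, truth,
                                   alive_until = NULL)
  list(individuals = individuals, membership = membership,
       covariates = covariates, truth = truth)
}

# rank in [0, 1] (1 = highest) among the group-year's adult females, and
# mean group size over monthly censuses; alive_until (named year vector)
# truncates the population after deaths
compute_covariates <- function(individuals, membership, truth,
                               alive_until = NULL, years = NULL) {
  yrs <- years %||% truth$years
  m <- norm_membership(membership)
  fem <- individuals |> filter(.data$sex == "F")
  out <- list()
  for (y in yrs) {
    mid <- as.Date(sprintf("%d-07-01", y))
    months <- as.Date(sprintf("%d-%02d-15", y, 1:12))
    pres <- m |> filter(.data$entry <= mid, .data$exit >= mid)
    if (!is.null(alive_until)) {
      dead <- names(alive_until)[alive_until < y]
      pres <- pres |> filter(!.data$id %in% dead)
    }
    gs <- purrr::map(months, function(d) {
      mm <- m |> filter(.data$entry <= d, .data$exit >= d)
      if (!is.null(alive_until)) {
        dead <- names(alive_until)[alive_until < y]
        mm <- mm |> filter(!.data$id %in% dead)
      }
      count(mm, .data$group, name = "n_members")
    }) |>
      bind_rows() |>
      group_by(.data$group) |>
      summarise(group_size = mean(.data$n_members), .groups = "drop") |>
      left_join(filter(truth$gs_noise, .data$year == y), by = "group") |>
      mutate(group_size = pmax(.data$group_size + .data$gs_noise, 2)) |>
      select("group", "group_size")
    fy <- pres |>
      inner_join(select(fem, "id", "birth_date"), by = "id") |>
      filter(is_adult_on(.data$birth_date, mid)) |>
      left_join(truth$rank_base, by = "id") |>
      left_join(filter(truth$rank_noise, .data$year == y), by = "id") |>
      group_by(.data$group) |>
      mutate(score = .data$rank_base + .data$rank_noise,
             rank = if (n() == 1) 1 else
               (rank(.data$score) - 1) / (n() - 1)) |>
      ungroup() |>
      left_join(gs, by = "group") |>
      transmute(id = .data$id, year = as.integer(y), group = .data$group,
                rank = .data$rank, group_size = .data$group_size)
    out[[as.character(y)]] <- fy
  }
  bind_rows(out)
}

#' Simulate deaths and censoring from the AFT likelihood
#'
#' Runs the survival process year by year: each adult female-year gets
#' `eta = mu + beta_social * z(sociality) + beta_age * z(age) + beta_rank *
#' z(rank) + beta_gs * z(group size) + u_female + v_group` and dies with
#' probability `1 - exp(-delta * exp(-eta))`, using the TRUE latent
#' grooming-giving propensity (never its estimates). Standardization uses
#' fixed generator scalings so the process is well-defined sequentially.
#' Rank and group size are recomputed each year among survivors.
#'
#' @param population Output of [simulate_population()].
#' @param truth The `truth` element of the population.
#' @param config The [sim_config()] used.
#' @return List with `demography` (`id`, `death_date`, `last_observed`),
#'   final `covariates`, and `truth_survival` (per female-year `eta`, death
#'   draw and the sociality value used).
#' @export
simulate_survival <- function(population, truth, config) {
  set.seed(derive_seed(config$seed, "survival"))
  yrs <- truth$years
  study_end <- as.Date(sprintf("%d-12-31", max(yrs)))
  ind <- population$individuals
  fem_bd <- setNames(as.Date(ind$birth_date), ind$id)

  # fixed generator scalings (documented; not fit to the realized sample)
  exp_gs <- config$females_per_group + config$males_per_group +
    config$immatures_per_group
  sd_soc <- max(sqrt(config$sd_g[["grooming"]]^2 +
                       config$sociality_jitter_sd^2), 1e-8)
  z_age <- function(a) (a - 15) / 7
  z_rank <- function(r) (r - 0.5) / 0.29
  z_gs <- function(g) (g - exp_gs) / 2
  z_soc <- function(s) s / sd_soc

  soc <- truth$latents |> select("id", "year", soc = "g_grooming")
  u <- setNames(truth$rank_base$u_female, truth$rank_base$id)
  v <- setNames(truth$v_group$v_group, truth$v_group$group)

  alive_until <- setNames(rep(Inf, nrow(ind)), ind$id)
  rows <- list()
  for (y in yrs) {
    cov_y <- compute_covariates(ind, population$membership, truth,
                                alive_until = alive_until, years = y) |>
      filter(!(.data$id %in% names(alive_until)[alive_until < y]))
    if (!nrow(cov_y)) next
    cov_y <- cov_y |>
      left_join(filter(soc, .data$year == y), by = c("id", "year")) |>
      mutate(age = age_in_year(fem_bd[.data$id], .data$year),
             eta = config$mu + config$beta_social * z_soc(.data$soc) +
               config$beta_age * z_age(.data$age) +
               config$beta_rank * z_rank(.data$rank) +
               config$beta_groupsize * z_gs(.data$group_size) +
               u[.data$id] + v[.data$group],
             p_die = 1 - exp(-config$delta * exp(-.data$eta)),
             died = rbinom(n(), 1, .data$p_die) == 1)
    died_ids <- cov_y$id[cov_y$died]
    alive_until[died_ids] <- y
    rows[[as.character(y)]] <- cov_y
  }
  tr <- bind_rows(rows)
  death_year <- setNames(rep(NA_integer_, nrow(ind)), ind$id)
  realized <- alive_until[is.finite(alive_until)]
  death_year[names(realized)] <- as.integer(realized)
  demography <- tibble(id = ind$id) |>
    mutate(death_year = unname(death_year[.data$id]),
           death_date = as.Date(ifelse(is.na(.data$death_year), NA,
                                       rand_date_in_year_vec(.data$death_year))),
           last_observed = dplyr::coalesce(.data$death_date, study_end)) |>
    select("id", "death_date", "last_observed")

  covariates <- tr |>
    select("id", "year", "group", "rank", "group_size")
  list(demography = demography, covariates = covariates,
       truth_survival = tr)
}

rand_date_in_year_vec <- function(years) {
  out <- rep(as.Date(NA), length(years))
  ok <- !is.na(years)
  out[ok] <- as.Date(sprintf("%d-01-01", years[ok])) +
    sample.int(365, sum(ok), replace = TRUE) - 1
  out
}

#' Simulate behavioral event streams from the SRM generative model
#'
#' Focal follows, grooming events, aggressive conflicts with joining, and
#' group scans with neighbor distances, all drawn from logistic models in
#' the latent propensities: for a follow of i with co-resident j, i grooms
#' j with probability `plogis(base + g_i + r_j)`; joining and foraging
#' proximity follow the same pattern on their own propensities.
#'
#' @param population Output of [simulate_population()] (with membership
#'   already truncated at deaths if survival was simulated first).
#' @param truth The population's `truth`.
#' @param config The [sim_config()].
#' @return List of event tables: `follows`, `grooming`, `aggression`,
#'   `scans`, `scan_neighbors`.
#' @export
simulate_interactions <- function(population, truth, config) {
  set.seed(derive_seed(config$seed, "interactions"))
  m <- norm_membership(population$membership)
  yrs <- truth$years
  lat <- truth$latents
  lat_of <- function(ids, yr, col) {
    key <- paste(lat$id, lat$year)
    lat[[col]][match(paste(ids, yr), key)]
  }

  follows <- list(); grooming <- list()
  aggression <- list(); scans <- list(); neighbors <- list()
  fid <- 0L; sid <- 0L

  for (y in yrs) {
    mid <- as.Date(sprintf("%d-07-01", y))
    pres <- m |> filter(.data$entry <= mid, .data$exit >= mid)
    if (!nrow(pres)) next

    ## focal follows + grooming
    nfl <- rpois(nrow(pres), config$follows_per_ind_year)
    fl <- pres[rep(seq_len(nrow(pres)), nfl), c("id", "group")]
    if (nrow(fl)) {
      fl$time <- rand_time_in_year(y, nrow(fl))
      fl$follow_id <- sprintf("FL%07d", fid + seq_len(nrow(fl)))
      fid <- fid + nrow(fl)
      fl$duration_min <- 10
      follows[[as.character(y)]] <- fl |>
        select("follow_id", focal = "id", "group", "time", "duration_min")
      # partners co-resident at the follow's date
      fexp <- fl |>
        mutate(date = as.Date(.data$time)) |>
        inner_join(m, by = dplyr::join_by(group, date >= entry,
                                          date <= exit),
                   relationship = "many-to-many",
                   suffix = c("", ".p")) |>
        filter(.data$id.p != .data$id)
      if (nrow(fexp)) {
        gi <- lat_of(fexp$id, y, "g_grooming")
        ri <- lat_of(fexp$id, y, "r_grooming")
        gj <- lat_of(fexp$id.p, y, "g_grooming")
        rj <- lat_of(fexp$id.p, y, "r_grooming")
        b <- config$base_logit[["grooming"]]
        give <- rbinom(nrow(fexp), 1, plogis(b + gi + rj)) == 1
        recv <- rbinom(nrow(fexp), 1, plogis(b + gj + ri)) == 1
        ev <- bind_rows(
          fexp[give, ] |> transmute(follow_id = .data$follow_id,
                                    groomer = .data$id,
                                    groomee = .data$id.p,
                                    time = .data$time + 60),
          fexp[recv, ] |> transmute(follow_id = .data$follow_id,
                                    groomer = .data$id.p,
                                    groomee = .data$id,
                                    time = .data$time + 120))
        if (nrow(ev)) grooming[[as.character(y)]] <- ev
      }
    }

    ## aggressive conflicts with joining
    for (g in unique(pres$group)) {
      members <- pres$id[pres$group == g]
      if (length(members) < 3) next
      niv <- rpois(1, config$intervals_per_group_year)
      if (niv == 0) next
      t0 <- sort(rand_time_in_year(y, niv))
      # keep conflicts >= 10 min apart so bursts stay distinct
      keep <- thin_keep(t0, 10)
      t0 <- t0[keep]
      for (tt in t0) {
        pair <- sample(members, 2)
        a <- pair[1]; bb <- pair[2]
        ev <- tibble(time = as.POSIXct(tt, tz = "UTC",
                                       origin = "1970-01-01"),
                     group = g, aggressor = a, target = bb)
        others <- setdiff(members, pair)
        if (length(others)) {
          bsup <- config$base_logit[["support"]]
          for (j in c(a, bb)) {
            gj_r <- lat_of(j, y, "r_support")
            gi_g <- lat_of(others, y, "g_support")
            join <- rbinom(length(others), 1,
                           plogis(bsup + gi_g + gj_r)) == 1
            if (any(join)) {
              opponent <- if (j == a) bb else a
              ev <- bind_rows(ev, tibble(
                time = as.POSIXct(tt, tz = "UTC",
                                  origin = "1970-01-01") +
                  runif(sum(join), 30, 240),
                group = g, aggressor = others[join],
                target = opponent))
            }
          }
        }
        aggression[[length(aggression) + 1L]] <- ev
      }
    }

    ## group scans with neighbors
    for (g in unique(pres$group)) {
      members <- pres$id[pres$group == g]
      if (length(members) < 2) next
      nsc <- rpois(1, config$scans_per_group_year)
      if (nsc == 0) next
      sc <- tibble(scan_id = sprintf("SC%08d", sid + seq_len(nsc)),
                   time = rand_time_in_year(y, nsc), group = g,
                   subject = sample(members, nsc, replace = TRUE),
                   activity = if_else(runif(nsc) < config$p_forage,
                                      "foraging", "other"))
      sid <- sid + nsc
      scans[[length(scans) + 1L]] <- sc
      fsc <- sc |> filter(.data$activity == "foraging")
      if (nrow(fsc)) {
        nexp <- fsc[rep(seq_len(nrow(fsc)),
                        each = length(members)), ]
        nexp$neighbor <- rep(members, times = nrow(fsc))
        nexp <- nexp |> filter(.data$neighbor != .data$subject)
        si <- lat_of(nexp$subject, y, "s_foraging")
        sj <- lat_of(nexp$neighbor, y, "s_foraging")
        bfor <- config$base_logit[["foraging"]]
        close <- rbinom(nrow(nexp), 1, plogis(bfor + si + sj)) == 1
        far <- !close & runif(nrow(nexp)) < config$p_background
        nb <- bind_rows(
          nexp[close, ] |> transmute(scan_id = .data$scan_id,
                                     neighbor = .data$neighbor,
                                     distance_bl = runif(sum(close),
                                                         0.5, 5)),
          nexp[far, ] |> transmute(scan_id = .data$scan_id,
                                   neighbor = .data$neighbor,
                                   distance_bl = runif(sum(far),
                                                       5.5, 10)))
        if (nrow(nb)) neighbors[[length(neighbors) + 1L]] <- nb
      }
    }
  }
  list(follows = bind_rows(follows),
       grooming = bind_rows(grooming),
       aggression = bind_rows(aggression) |> arrange(.data$group,
                                                     .data$time),
       scans = bind_rows(scans),
       scan_neighbors = bind_rows(neighbors))
}

#' Synthetic integration estimates from the generator's ground truth
#'
#' The generator's stand-in for SRM output: the true latent propensity per
#' female-year plus Normal measurement noise, with the noise SD reported as
#' the estimate's SD. Used to test the survival stage in isolation.
#'
#' @param truth A population's `truth`.
#' @param behavior,direction Which latent to expose (default
#'   grooming giving, the generator's survival-relevant axis).
#' @param noise_sd Measurement noise SD; default from the config.
#' @return Tibble: `id`, `year`, `behavior`, `direction`, `post_mean`,
#'   `post_sd`.
#' @export
simulate_integration_estimates <- function(truth,
                                           behavior = "grooming",
                                           direction = "giving",
                                           noise_sd = NULL) {
  config <- truth$config
  noise_sd <- noise_sd %||% config$integration_noise_sd
  set.seed(derive_seed(config$seed, paste("estimates", behavior,
                                          direction)))
  col <- switch(direction, giving = paste0("g_", behavior),
                receiving = paste0("r_", behavior),
                undirected = paste0("s_", behavior))
  truth$latents |>
    transmute(id = .data$id, year = .data$year, behavior = behavior,
              direction = direction,
              post_mean = .data[[col]] + rnorm(dplyr::n(), 0, noise_sd),
              post_sd = noise_sd)
}

#' Simulate a complete synthetic study
#'
#' Runs population, survival and interaction generation in sequence:
#' membership is truncated at each death before events are generated, so
#' every generated stream respects demography. Returns a study bundle
#' ready for [build_dyads()] plus the full ground truth.
#'
#' @param config A [sim_config()].
#' @return A study bundle: `individuals`, `membership`, `follows`,
#'   `grooming`, `aggression`, `scans`, `scan_neighbors`, `covariates`,
#'   `demography`, and `truth` (latents, survival truth, parameters).
#' @export
simulate_study <- function(config) {
  pop <- simulate_population(config)
  surv <- simulate_survival(pop, pop$truth, config)
  # truncate membership at death
  dd <- setNames(surv$demography$death_date, surv$demography$id)
  mem <- norm_membership(pop$membership) |>
    mutate(death = as.Date(unname(dd[.data$id])),
           exit = pmin(.data$exit, .data$death, na.rm = TRUE)) |>
    filter(.data$exit >= .data$entry) |>
    select(-"death")
  pop2 <- list(individuals = pop$individuals, membership = mem)
  events <- simulate_interactions(pop2, pop$truth, config)
  truth <- pop$truth
  truth$survival <- surv$truth_survival
  c(list(individuals = pop$individuals, membership = mem,
         covariates = surv$covariates, demography = surv$demography),
    events, list(truth = truth))
}

#' Simulate a dyad-year table directly from the SRM generative model
#'
#' Bypasses event streams: draws dyadic binomial counts with
#' `logit p = base + g_i + r_j` (directed) or `base + s_i + s_j`
#' (undirected) for every ordered (or unordered) pair, with a constant
#' opportunity count. Used for SRM parameter-recovery tests where the
#' simulator is the oracle.
#'
#' @param n_individuals Number of individuals.
#' @param opportunities Opportunities per dyad-year.
#' @param sd_g,sd_r SDs of giving/receiving propensities (directed) or
#'   `sd_g` for the undirected propensity.
#' @param base Baseline logit rate.
#' @param directed Directed or undirected table.
#' @param year Calendar year stamped on the rows.
#' @param behavior Behavior label.
#' @param seed Integer seed.
#' @return List: `dyads` (a dyad-year tibble) and `truth` (tibble of the
#'   true propensities per individual).
#' @export
simulate_srm_data <- function(n_individuals = 40, opportunities = 50,
                              sd_g = 1, sd_r = 0.5, base = -3,
                              directed = TRUE, year = 2010,
                              behavior = if (directed) "grooming"
                              else "foraging", seed = 1) {
  set.seed(seed)
  ids <- sprintf("ID%03d", seq_len(n_individuals))
  g <- rnorm(n_individuals, 0, sd_g)
  r <- rnorm(n_individuals, 0, sd_r)
  if (directed) {
    dy <- tidyr::expand_grid(actor = ids, partner = ids) |>
      filter(.data$actor != .data$partner)
    p <- plogis(base + g[match(dy$actor, ids)] +
                  r[match(dy$partner, ids)])
  } else {
    dy <- tidyr::expand_grid(actor = ids, partner = ids) |>
      filter(.data$actor < .data$partner)
    p <- plogis(base + g[match(dy$actor, ids)] +
                  g[match(dy$partner, ids)])
  }
  dy <- dy |>
    mutate(year = as.integer(year), behavior = behavior,
           directed = directed,
           count = rbinom(dplyr::n(), opportunities, p),
           opportunities = as.integer(opportunities)) |>
    select(dplyr::all_of(dyad_cols))
  truth <- tibble(id = ids, g = g, r = r)
  list(dyads = dy, truth = truth)
}

#' Simulate female-year survival rows with known coefficients
#'
#' A direct generative round trip for the survival stage: builds a
#' population, runs the survival process, and attaches the generator's
#' noisy integration estimates, returning rows ready for
#' [standardize_covariates()] + [fit_aft()] along with the truth.
#'
#' @param config A [sim_config()].
#' @return List: `rows` (unstandardized female-year table) and `truth`.
#' @export
simulate_female_years <- function(config) {
  pop <- simulate_population(config)
  surv <- simulate_survival(pop, pop$truth, config)
  est <- simulate_integration_estimates(pop$truth)
  rows <- assemble_female_years(pop$individuals, surv$covariates,
                                surv$demography, est, lag = 0)
  truth <- pop$truth
  truth$survival <- surv$truth_survival
  list(rows = rows, truth = truth)
}
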