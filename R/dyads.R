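# Annual dyadic count/opportunity builders for the three behaviors.
#
# All builders return tibbles with columns
#   year, behavior, directed, actor, partner, count, opportunities
# and emit a row only when opportunities > 0. Grooming and coalitionary
# support are directed (actor = giver); foraging proximity is undirected and
# stored once per unordered pair with actor < partner.

dyad_cols <- c("year", "behavior", "directed", "actor", "partner",
               "count", "opportunities")

empty_dyads <- function() {
  tibble(year = integer(), behavior = character(), directed = logical(),
         actor = character(), partner = character(),
         count = integer(), opportunities = integer())
}

# follow/scan/interval rows expanded to co-resident group mates at the
# event's start time
expand_coresidents <- function(events, membership, id_col) {
  m <- norm_membership(membership)
  events |>
    mutate(date = as.Date(.data$time)) |>
    inner_join(m, by = dplyr::join_by(group, date >= entry, date <= exit),
               relationship = "many-to-many") |>
    filter(.data$id != .data[[id_col]]) |>
    rename(other = "id") |>
    select(-"entry", -"exit")
}

#' Build the annual grooming dyad table
#'
#' Aggregates grooming observed during 10-minute focal follows into directed
#' dyadic counts and opportunities for one calendar year. The opportunity
#' for an ordered dyad (i, j) is the number of focal follows of i plus the
#' number of focal follows of j at times when the two were co-resident; the
#' count is the number of those follows during which i groomed j at least
#' once (grooming is scored dichotomously within a follow).
#'
#' @param follows Data frame of focal follows: `follow_id`, `focal`,
#'   `group`, `time` (start timestamp), `duration_min`.
#' @param grooming Data frame of grooming events: `follow_id`, `groomer`,
#'   `groomee`, `time`.
#' @param individuals Data frame: `id`, `sex`, `birth_date`.
#' @param membership Data frame: `id`, `group`, `entry`, `exit`.
#' @param year Calendar year to aggregate.
#' @param partner_type One of `"all"`, `"adult_females"`, `"adult_males"`.
#'   The subject side is always adult (age >= 5) females; the partner side
#'   is restricted per this argument, both evaluated at the follow date.
#' @return Tibble of directed dyad-year records (see module header).
#' @export
build_grooming_dyads <- function(follows, grooming, individuals, membership,
                                 year, partner_type = "all") {
  assert_cols(follows, c("follow_id", "focal", "group", "time"), "follows")
  assert_cols(grooming, c("follow_id", "groomer", "groomee"), "grooming")
  fl <- as_tibble(follows) |>
    filter(lubridate::year(.data$time) == year)
  if (!nrow(fl)) return(empty_dyads())

  exp <- expand_coresidents(fl, membership, "focal") |>
    filter(pair_eligible(individuals, .data$focal, .data$other,
                         .data$date, partner_type))
  if (!nrow(exp)) return(empty_dyads())

  # opportunities: each follow of either pair member counts once
  opp <- exp |>
    mutate(a = pmin(.data$focal, .data$other),
           b = pmax(.data$focal, .data$other)) |>
    count(.data$a, .data$b, name = "opportunities")

  # counts: at-least-once per follow, per ordered pair
  ev <- as_tibble(grooming)
  known <- ev$follow_id %in% follows$follow_id
  if (any(!known)) {
    warn(sprintf("%d grooming event(s) outside any follow skipped",
                 sum(!known)), class = "capsoc_warning_orphan_event")
    ev <- ev[known, , drop = FALSE]
  }
  # events from other years' follows drop out of the join
  ev <- ev |> inner_join(select(fl, "follow_id", "focal"), by = "follow_id")
  third <- ev$focal != ev$groomer & ev$focal != ev$groomee
  if (any(third)) {
    warn(sprintf("%d grooming event(s) not involving the focal skipped",
                 sum(third)), class = "capsoc_warning_orphan_event")
    ev <- ev[!third, , drop = FALSE]
  }
  cnt <- ev |>
    mutate(other = if_else(.data$focal == .data$groomer,
                           .data$groomee, .data$groomer)) |>
    # keep only events whose follow appears in the co-resident expansion
    semi_join(exp, by = c("follow_id", "other")) |>
    distinct(.data$follow_id, .data$groomer, .data$groomee) |>
    count(actor = .data$groomer, partner = .data$groomee, name = "count")

  directed_pairs <- bind_rows(
    opp |> transmute(actor = .data$a, partner = .data$b,
                     opportunities = .data$opportunities),
    opp |> transmute(actor = .data$b, partner = .data$a,
                     opportunities = .data$opportunities))
  directed_pairs |>
    left_join(cnt, by = c("actor", "partner")) |>
    mutate(count = dplyr::coalesce(.data$count, 0L),
           year = as.integer(year), behavior = "grooming",
           directed = TRUE) |>
    select(dplyr::all_of(dyad_cols)) |>
    arrange(.data$actor, .data$partner)
}

#' Segment an aggression stream into 5-minute conflict intervals
#'
#' The chronological stream of aggressive events is divided, per group, into
#' consecutive windows. Windows are anchored at the first event of each
#' burst: an event at or beyond `interval_len` minutes after the current
#' window's anchor opens a new window anchored at that event. Burst-anchored
#' windows are invariant to clock offset, unlike clock-aligned ones.
#'
#' @param aggression Data frame: `time`, `group`, `aggressor`, `target`.
#' @param interval_len Window length in minutes (default 5).
#' @return Tibble with one row per interval: `interval_id`, `group`,
#'   `start`, `year`, `participants` (list of ids) and `events` (nested
#'   tibble of the interval's events).
#' @export
segment_aggression_intervals <- function(aggression, interval_len = 5) {
  assert_cols(aggression, c("time", "group", "aggressor", "target"),
              "aggression")
  ev <- as_tibble(aggression) |> arrange(.data$group, .data$time)
  if (!nrow(ev)) {
    return(tibble(interval_id = character(), group = character(),
                  start = ev$time[0], year = integer(),
                  participants = list(), events = list()))
  }
  ev <- ev |>
    group_by(.data$group) |>
    mutate(.iv = anchor_windows(.data$time, interval_len)) |>
    ungroup() |>
    mutate(interval_id = paste(.data$group, .data$.iv, sep = ":"))
  ev |>
    group_by(.data$interval_id, .data$group) |>
    summarise(start = min(.data$time),
              participants = list(unique(c(.data$aggressor, .data$target))),
              events = list(dplyr::pick("time", "aggressor", "target")),
              .groups = "drop") |>
    mutate(year = as.integer(lubridate::year(.data$start))) |>
    arrange(.data$group, .data$start)
}

# window index per event under first-event anchoring
anchor_windows <- function(times, len_min) {
  t <- as.numeric(as.POSIXct(times))
  idx <- integer(length(t))
  anchor <- t[1]; k <- 1L
  for (i in seq_along(t)) {
    if (t[i] - anchor >= len_min * 60) {
      anchor <- t[i]
      k <- k + 1L
    }
    idx[i] <- k
  }
  idx
}

#' Score joining within one conflict interval
#'
#' Within a 5-minute conflict interval, individual i joins individual j if i
#' directed aggression at j's opponent (someone who aggressed j) or at j's
#' victim (someone j aggressed). Joining is dichotomous per interval: at
#' most one instance of (i, j) is recorded no matter how many qualifying
#' events occurred. No temporal ordering within the interval is required.
#'
#' @param events Data frame of one interval's events with columns
#'   `aggressor`, `target`.
#' @return Tibble of directed pairs: `joiner`, `joinee`.
#' @export
score_joining <- function(events) {
  assert_cols(events, c("aggressor", "target"), "events")
  ev <- distinct(as_tibble(events), .data$aggressor, .data$target)
  # i aggresses X; j's victim X (j -> X) or j's opponent X (X -> j)
  via_victim <- inner_join(ev, ev, by = "target",
                           relationship = "many-to-many",
                           suffix = c("", ".j")) |>
    transmute(joiner = .data$aggressor, joinee = .data$aggressor.j)
  via_opponent <- inner_join(ev,
                             rename(ev, x = "aggressor", joinee = "target"),
                             by = c(target = "x"),
                             relationship = "many-to-many") |>
    transmute(joiner = .data$aggressor, joinee = .data$joinee)
  bind_rows(via_victim, via_opponent) |>
    filter(.data$joiner != .data$joinee) |>
    distinct()
}

#' Build the annual coalitionary-support dyad table
#'
#' Counts, per ordered dyad (i, j) and calendar year, the conflict intervals
#' in which i joined j (see [score_joining()]). The opportunity for i to
#' support j is the number of intervals in which j was a conflict
#' participant while i was co-resident in that group (and i != j): every
#' co-resident had the opportunity to join on either side of an ongoing
#' conflict.
#'
#' @param intervals Output of [segment_aggression_intervals()].
#' @inheritParams build_grooming_dyads
#' @return Tibble of directed dyad-year records.
#' @export
build_support_dyads <- function(intervals, individuals, membership, year,
                                partner_type = "all") {
  iv <- intervals |> filter(.data$year == !!year)
  if (!nrow(iv)) return(empty_dyads())
  m <- norm_membership(membership)

  # residents of the conflict group at each interval start
  res <- iv |>
    select("interval_id", "group", time = "start") |>
    mutate(date = as.Date(.data$time)) |>
    inner_join(m, by = dplyr::join_by(group, date >= entry, date <= exit),
               relationship = "many-to-many") |>
    select("interval_id", "date", resident = "id")

  parts <- iv |>
    select("interval_id", "participants") |>
    tidyr::unnest_longer("participants", values_to = "joinee")

  universe <- inner_join(res, parts, by = "interval_id",
                         relationship = "many-to-many") |>
    filter(.data$resident != .data$joinee) |>
    filter(pair_eligible(individuals, .data$resident, .data$joinee,
                         .data$date, partner_type))
  if (!nrow(universe)) return(empty_dyads())

  joins <- iv |>
    select("interval_id", "events") |>
    mutate(joined = purrr::map(.data$events, score_joining)) |>
    select("interval_id", "joined") |>
    tidyr::unnest("joined")

  universe |>
    left_join(mutate(joins, hit = 1L),
              by = c("interval_id", resident = "joiner", joinee = "joinee")) |>
    group_by(actor = .data$resident, partner = .data$joinee) |>
    summarise(count = sum(!is.na(.data$hit)), opportunities = n(),
              .groups = "drop") |>
    mutate(year = as.integer(year), behavior = "support", directed = TRUE) |>
    select(dplyr::all_of(dyad_cols)) |>
    arrange(.data$actor, .data$partner)
}

#' Build the annual foraging-proximity dyad table
#'
#' Foraging in close proximity is undirected. For each unordered dyad the
#' qualifying observations are group scans in the foraging context in which
#' one of the two is the scan subject and the other is co-resident; these
#' are thinned per dyad so that retained scans are at least `window` minutes
#' apart (greedy from the earliest). Opportunities = retained scans; count =
#' retained scans in which the partner was recorded within
#' `proximity_threshold` body lengths of the subject.
#'
#' @param scans Data frame: `scan_id`, `time`, `group`, `subject`,
#'   `activity`.
#' @param scan_neighbors Data frame: `scan_id`, `neighbor`, `distance_bl`.
#' @inheritParams build_grooming_dyads
#' @param proximity_threshold Body lengths defining close proximity
#'   (default 5, about 1 m).
#' @param window Minimum minutes between retained scans of a dyad
#'   (default 10).
#' @return Tibble of undirected dyad-year records, one per unordered pair,
#'   with `actor < partner`.
#' @export
build_foraging_dyads <- function(scans, scan_neighbors, individuals,
                                 membership, year, partner_type = "all",
                                 proximity_threshold = 5, window = 10) {
  assert_cols(scans, c("scan_id", "time", "group", "subject", "activity"),
              "scans")
  assert_cols(scan_neighbors, c("scan_id", "neighbor", "distance_bl"),
              "scan_neighbors")
  sc <- as_tibble(scans) |>
    filter(.data$activity == "foraging",
           lubridate::year(.data$time) == year)
  if (!nrow(sc)) return(empty_dyads())

  exp <- expand_coresidents(sc, membership, "subject") |>
    filter(pair_eligible(individuals, .data$subject, .data$other,
                         .data$date, partner_type))
  if (!nrow(exp)) return(empty_dyads())

  nb <- as_tibble(scan_neighbors)
  if (anyNA(nb$distance_bl)) {
    warn(sprintf("%d scan neighbor distance(s) missing; treated as beyond threshold",
                 sum(is.na(nb$distance_bl))),
         class = "capsoc_warning_missing_distance")
  }
  exp <- exp |>
    left_join(nb, by = c(scan_id = "scan_id", other = "neighbor")) |>
    mutate(close = !is.na(.data$distance_bl) &
             .data$distance_bl <= proximity_threshold,
           a = pmin(.data$subject, .data$other),
           b = pmax(.data$subject, .data$other))

  exp |>
    group_by(.data$a, .data$b) |>
    arrange(.data$time, .by_group = TRUE) |>
    mutate(keep = thin_keep(.data$time, window)) |>
    filter(.data$keep) |>
    summarise(count = sum(.data$close), opportunities = n(),
              .groups = "drop") |>
    transmute(year = as.integer(year), behavior = "foraging",
              directed = FALSE, actor = .data$a, partner = .data$b,
              count = as.integer(.data$count),
              opportunities = as.integer(.data$opportunities))
}

# greedy thinning: keep a scan iff >= window minutes after the last kept
thin_keep <- function(times, window_min) {
  t <- as.numeric(as.POSIXct(times))
  keep <- logical(length(t))
  last <- -Inf
  for (i in seq_along(t)) {
    if (t[i] - last >= window_min * 60 || is.infinite(last)) {
      keep[i] <- TRUE
      last <- t[i]
    }
  }
  keep
}

#' Build annual dyad tables for a study bundle
#'
#' High-level dispatcher over the per-behavior builders, looping over
#' calendar years. The subject side is always adult females; `partner_type`
#' restricts the partner side, and the table is rebuilt from the raw event
#' base for each partner dataset (never by subsetting already-aggregated
#' rows).
#'
#' @param study A study bundle: named list with elements `individuals`,
#'   `membership`, `follows`, `grooming`, `aggression`, `scans`,
#'   `scan_neighbors` (see [read_study()] / [simulate_study()]).
#' @param behavior One of `"grooming"`, `"support"`, `"foraging"`.
#' @inheritParams build_grooming_dyads
#' @param years Integer vector of calendar years; default: all years present
#'   in the relevant event stream.
#' @return Tibble of dyad-year records across the requested years.
#' @export
build_dyads <- function(study, behavior = c("grooming", "support", "foraging"),
                        partner_type = "all", years = NULL) {
  behavior <- match.arg(behavior)
  src <- switch(behavior, grooming = study$follows,
                support = study$aggression, foraging = study$scans)
  years <- years %||% sort(unique(lubridate::year(src$time)))
  iv <- if (behavior == "support") {
    segment_aggression_intervals(study$aggression)
  }
  purrr::map(years, function(y) {
    switch(behavior,
      grooming = build_grooming_dyads(study$follows, study$grooming,
                                      study$individuals, study$membership,
                                      y, partner_type),
      support = build_support_dyads(iv, study$individuals, study$membership,
                                    y, partner_type),
      foraging = build_foraging_dyads(study$scans, study$scan_neighbors,
                                      study$individuals, study$membership,
                                      y, partner_type))
  }) |>
    bind_rows()
}

#' Restrict a dyad dataset to one partner type
#'
#' Rebuilds the dyad-year table for the requested partner dataset from the
#' raw event base. Subjects are always adult females; `partner_type`
#' restricts their partners to all group members, adult females, or adult
#' males, evaluated at each event's date (so a female turning 5 mid-study
#' enters as subject only from the moment she is adult).
#'
#' @inheritParams build_dyads
#' @return Tibble of dyad-year records; a structured warning is raised if
#'   the restriction leaves no rows.
#' @export
filter_partner_dataset <- function(study, behavior, partner_type,
                                   years = NULL) {
  out <- build_dyads(study, behavior, partner_type, years)
  if (!nrow(out)) {
    warn(sprintf("no %s dyads remain for partner type '%s'",
                 behavior, partner_type),
         class = "capsoc_warning_empty_dataset")
  }
  out
}
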