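# Small deterministic fixtures and a random toy-stream generator used by
# the builder-equivalence property tests.

toy_time <- function(s) as.POSIXct(s, tz = "UTC")

# A 2-group, 6-individual hand-built study used by the example-based tests.
toy_study <- function() {
  individuals <- tibble::tibble(
    id = c("ada", "bea", "cleo", "dag", "eve", "ivy"),
    sex = c("F", "F", "F", "M", "F", "F"),
    birth_date = as.Date(c("2000-01-01", "2001-06-15", "1998-03-01",
                           "1999-11-20", "2002-02-01", "2006-03-01")))
  # ivy turns 5 on 2011-03-01 (immature for most of 2010)
  membership <- tibble::tibble(
    id = c("ada", "bea", "cleo", "dag", "eve", "ivy"),
    group = c("A", "A", "A", "A", "B", "A"),
    entry = as.Date(c("2009-01-01", "2010-07-01", "2009-01-01",
                      "2009-01-01", "2009-01-01", "2009-01-01")),
    exit = as.Date(rep("2012-12-31", 6)))
  list(individuals = individuals, membership = membership)
}

# Random valid toy stream over <= 10 individuals; the generator is plain
# base R and independent of the package's simulator.
gen_toy_stream <- function(seed) {
  set.seed(seed)
  n <- sample(4:8, 1)
  ids <- paste0("id", seq_len(n))
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.6, 0.4))
  sex[1] <- "F"  # guarantee at least one female subject
  # mix of adults and immatures relative to 2010
  age0 <- runif(n, 1, 15); age0[1] <- runif(1, 6, 15)
  individuals <- data.frame(
    id = ids, sex = sex,
    birth_date = as.Date("2010-01-01") - round(age0 * 365.25))
  groups <- c("A", "B")
  mem <- list()
  for (k in seq_len(n)) {
    if (runif(1) < 0.75) {
      mem[[length(mem) + 1]] <- data.frame(
        id = ids[k], group = sample(groups, 1),
        entry = as.Date("2010-01-01"), exit = as.Date("2010-12-31"))
    } else {
      # mid-year transfer
      cut <- as.Date("2010-01-01") + sample(60:300, 1)
      gs <- sample(groups, 2)
      mem[[length(mem) + 1]] <- data.frame(
        id = rep(ids[k], 2), group = gs,
        entry = c(as.Date("2010-01-01"), cut + 1),
        exit = c(cut, as.Date("2010-12-31")))
    }
  }
  membership <- do.call(rbind, mem)

  res_group <- function(id, d) {
    r <- membership[membership$id == id & membership$entry <= d &
                      membership$exit >= d, "group"]
    if (length(r)) r[1] else NA_character_
  }
  rand_times <- function(m) {
    toy_time("2010-01-01 07:00:00") + runif(m, 0, 360 * 86400)
  }

  nf <- sample(10:25, 1)
  tms <- rand_times(nf)
  focal <- sample(ids, nf, replace = TRUE)
  grp <- mapply(res_group, focal, as.Date(tms))
  keep <- !is.na(grp)
  follows <- data.frame(follow_id = paste0("f", seq_len(sum(keep))),
                        focal = focal[keep], group = grp[keep],
                        time = tms[keep], duration_min = 10)

  grooming <- NULL
  if (nrow(follows)) {
    ne <- sample(5:20, 1)
    rows <- list()
    for (k in seq_len(ne)) {
      f <- follows[sample(nrow(follows), 1), ]
      if (runif(1) < 0.8) {
        other <- sample(setdiff(ids, f$focal), 1)
        pair <- if (runif(1) < 0.5) c(f$focal, other) else c(other, f$focal)
      } else {
        pair <- sample(ids, 2)  # possibly third-party, exercised skip path
      }
      rows[[k]] <- data.frame(follow_id = f$follow_id, groomer = pair[1],
                              groomee = pair[2], time = f$time + 60)
    }
    grooming <- do.call(rbind, rows)
    if (runif(1) < 0.3) {  # orphan event
      grooming <- rbind(grooming, data.frame(
        follow_id = "bogus", groomer = ids[1], groomee = ids[2],
        time = rand_times(1)))
    }
  }

  # clustered aggression bursts
  nb <- sample(3:8, 1)
  agg <- list()
  for (k in seq_len(nb)) {
    t0 <- rand_times(1)
    g <- sample(groups, 1)
    resid <- unique(membership$id[membership$group == g &
                                    membership$entry <= as.Date(t0) &
                                    membership$exit >= as.Date(t0)])
    if (length(resid) < 2) next
    nev <- sample(1:5, 1)
    for (e in seq_len(nev)) {
      pr <- sample(resid, 2)
      agg[[length(agg) + 1]] <- data.frame(
        time = t0 + runif(1, 0, 540), group = g,
        aggressor = pr[1], target = pr[2])
    }
  }
  aggression <- if (length(agg)) do.call(rbind, agg) else
    data.frame(time = rand_times(0), group = character(),
               aggressor = character(), target = character())
  aggression <- aggression[order(aggression$group, aggression$time), ]

  ns <- sample(10:30, 1)
  tms <- rand_times(ns)
  subj <- sample(ids, ns, replace = TRUE)
  grp <- mapply(res_group, subj, as.Date(tms))
  keep <- !is.na(grp)
  scans <- data.frame(scan_id = paste0("s", seq_len(sum(keep))),
                      time = tms[keep], group = grp[keep],
                      subject = subj[keep],
                      activity = sample(c("foraging", "other"), sum(keep),
                                        replace = TRUE, prob = c(0.7, 0.3)))
  nbs <- list()
  for (k in seq_len(nrow(scans))) {
    d <- as.Date(scans$time[k])
    resid <- setdiff(unique(
      membership$id[membership$group == scans$group[k] &
                      membership$entry <= d & membership$exit >= d]),
      scans$subject[k])
    if (!length(resid)) next
    nn <- sample(0:min(3, length(resid)), 1)
    if (nn == 0) next
    who <- sample(resid, nn)
    dist <- runif(nn, 0, 10)
    if (runif(1) < 0.15) dist[1] <- NA  # missing distance path
    nbs[[length(nbs) + 1]] <- data.frame(scan_id = scans$scan_id[k],
                                         neighbor = who,
                                         distance_bl = dist)
  }
  scan_neighbors <- if (length(nbs)) do.call(rbind, nbs) else
    data.frame(scan_id = character(), neighbor = character(),
               distance_bl = numeric())

  list(individuals = individuals, membership = membership,
       follows = follows, grooming = grooming, aggression = aggression,
       scans = scans, scan_neighbors = scan_neighbors)
}

dyad_pairs <- function(df) {
  df <- as.data.frame(df)
  df <- df[order(df$joiner, df$joinee), ]
  unname(lapply(seq_len(nrow(df)),
                function(k) c(df$joiner[k], df$joinee[k])))
}

# canonical comparison form
dyad_df <- function(x) {
  d <- as.data.frame(x)[, c("year", "behavior", "directed", "actor",
                            "partner", "count", "opportunities")]
  d <- d[order(d$actor, d$partner), ]
  rownames(d) <- NULL
  d$year <- as.integer(d$year)
  d$count <- as.integer(d$count)
  d$opportunities <- as.integer(d$opportunities)
  d
}

fast_srm <- function(seed = 1, samples = 600, warmup = 300, adapt = 300) {
  srm_control(samples = samples, warmup = warmup, adapt = adapt, seed = seed)
}

fast_aft <- function(seed = 1, samples = 600, warmup = 500, adapt = 400,
                     thin = 1, ...) {
  aft_control(samples = samples, warmup = warmup, adapt = adapt,
              thin = thin, seed = seed, ...)
}
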