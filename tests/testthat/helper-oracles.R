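# Independent naive re-implementations of the dyad aggregation rules,
# written as direct loops over the event streams. These are the oracles the
# vectorised builders are checked against; they share no code with R/.

oracle_resident_group <- function(membership, id, date) {
  date <- as.Date(date)
  for (k in seq_len(nrow(membership))) {
    if (membership$id[k] == id &&
        as.Date(membership$entry[k]) <= date &&
        (is.na(membership$exit[k]) || as.Date(membership$exit[k]) >= date)) {
      return(membership$group[k])
    }
  }
  NA_character_
}

oracle_coresident <- function(membership, i, j, date) {
  gi <- oracle_resident_group(membership, i, date)
  !is.na(gi) && identical(gi, oracle_resident_group(membership, j, date))
}

oracle_age <- function(individuals, id, date) {
  bd <- individuals$birth_date[individuals$id == id]
  as.numeric(as.Date(date) - as.Date(bd)) / 365.25
}

oracle_pair_ok <- function(individuals, a, b, date, partner_type) {
  subj <- function(x) {
    individuals$sex[individuals$id == x] == "F" &&
      oracle_age(individuals, x, date) >= 5
  }
  part <- function(x) {
    switch(partner_type,
           all = TRUE,
           adult_females = individuals$sex[individuals$id == x] == "F" &&
             oracle_age(individuals, x, date) >= 5,
           adult_males = individuals$sex[individuals$id == x] == "M" &&
             oracle_age(individuals, x, date) >= 5)
  }
  (subj(a) && part(b)) || (subj(b) && part(a))
}

oracle_grooming <- function(follows, grooming, individuals, membership,
                            year, partner_type) {
  ids <- individuals$id
  out <- list()
  fl <- follows[format(follows$time, "%Y") == as.character(year), ]
  for (i in ids) for (j in ids) {
    if (i >= j) next  # handle unordered pair once, emit both directions
    opp <- 0L; cnt_ij <- 0L; cnt_ji <- 0L
    for (k in seq_len(nrow(fl))) {
      foc <- fl$focal[k]
      if (!foc %in% c(i, j)) next
      oth <- if (foc == i) j else i
      d <- as.Date(fl$time[k])
      grp <- oracle_resident_group(membership, foc, d)
      if (is.na(grp) || !identical(grp, fl$group[k])) next
      if (!identical(oracle_resident_group(membership, oth, d), grp)) next
      if (!oracle_pair_ok(individuals, i, j, d, partner_type)) next
      opp <- opp + 1L
      ev <- grooming[grooming$follow_id == fl$follow_id[k], , drop = FALSE]
      if (any(ev$groomer == i & ev$groomee == j)) cnt_ij <- cnt_ij + 1L
      if (any(ev$groomer == j & ev$groomee == i)) cnt_ji <- cnt_ji + 1L
    }
    if (opp > 0) {
      out[[length(out) + 1]] <- data.frame(
        year = year, behavior = "grooming", directed = TRUE,
        actor = c(i, j), partner = c(j, i),
        count = c(cnt_ij, cnt_ji), opportunities = opp)
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df)) df <- data.frame(year = integer(), behavior = character(),
                                    directed = logical(), actor = character(),
                                    partner = character(), count = integer(),
                                    opportunities = integer())
  df[order(df$actor, df$partner), ]
}

oracle_intervals <- function(aggression, len = 5) {
  out <- list()
  for (g in unique(aggression$group)) {
    ev <- aggression[aggression$group == g, , drop = FALSE]
    ev <- ev[order(ev$time), , drop = FALSE]
    anchor <- NULL; cur <- NULL
    for (k in seq_len(nrow(ev))) {
      tk <- ev$time[k]
      if (is.null(anchor) ||
          as.numeric(difftime(tk, anchor, units = "mins")) >= len) {
        if (!is.null(cur)) out[[length(out) + 1]] <- cur
        anchor <- tk
        cur <- ev[k, , drop = FALSE]
      } else {
        cur <- rbind(cur, ev[k, , drop = FALSE])
      }
    }
    if (!is.null(cur)) out[[length(out) + 1]] <- cur
  }
  out
}

oracle_joins <- function(iv_events) {
  inds <- unique(c(iv_events$aggressor, iv_events$target))
  joins <- list()
  for (i in inds) for (j in inds) {
    if (i == j) next
    hit <- FALSE
    for (k in seq_len(nrow(iv_events))) {
      if (iv_events$aggressor[k] != i) next
      x <- iv_events$target[k]
      j_attacked_x <- any(iv_events$aggressor == j & iv_events$target == x)
      x_attacked_j <- any(iv_events$aggressor == x & iv_events$target == j)
      if (j_attacked_x || x_attacked_j) hit <- TRUE
    }
    if (hit) joins[[length(joins) + 1]] <- c(i, j)
  }
  joins
}

oracle_support <- function(aggression, individuals, membership, year,
                           partner_type) {
  ivs <- oracle_intervals(aggression)
  ivs <- Filter(function(iv) format(min(iv$time), "%Y") == as.character(year),
                ivs)
  ids <- individuals$id
  rec <- list()
  for (i in ids) for (j in ids) {
    if (i == j) next
    opp <- 0L; cnt <- 0L
    for (iv in ivs) {
      parts <- unique(c(iv$aggressor, iv$target))
      if (!j %in% parts) next
      d <- as.Date(min(iv$time))
      grp <- iv$group[1]
      if (!identical(oracle_resident_group(membership, i, d), grp)) next
      if (!oracle_pair_ok(individuals, i, j, d, partner_type)) next
      opp <- opp + 1L
      joined <- any(vapply(oracle_joins(iv),
                           function(p) p[1] == i && p[2] == j, TRUE))
      if (joined) cnt <- cnt + 1L
    }
    if (opp > 0) {
      rec[[length(rec) + 1]] <- data.frame(
        year = year, behavior = "support", directed = TRUE,
        actor = i, partner = j, count = cnt, opportunities = opp)
    }
  }
  df <- do.call(rbind, rec)
  if (is.null(df)) df <- data.frame(year = integer(), behavior = character(),
                                    directed = logical(), actor = character(),
                                    partner = character(), count = integer(),
                                    opportunities = integer())
  df[order(df$actor, df$partner), ]
}

oracle_foraging <- function(scans, scan_neighbors, individuals, membership,
                            year, partner_type, threshold = 5,
                            window = 10) {
  ids <- sort(individuals$id)
  sc <- scans[scans$activity == "foraging" &
                format(scans$time, "%Y") == as.character(year), ,
              drop = FALSE]
  sc <- sc[order(sc$time), , drop = FALSE]
  rec <- list()
  for (ai in seq_along(ids)) for (bi in seq_along(ids)) {
    if (ai >= bi) next
    a <- ids[ai]; b <- ids[bi]
    qual <- list()
    for (k in seq_len(nrow(sc))) {
      subj <- sc$subject[k]
      if (!subj %in% c(a, b)) next
      oth <- if (subj == a) b else a
      d <- as.Date(sc$time[k])
      grp <- oracle_resident_group(membership, subj, d)
      if (is.na(grp) || !identical(grp, sc$group[k])) next
      if (!identical(oracle_resident_group(membership, oth, d), grp)) next
      if (!oracle_pair_ok(individuals, a, b, d, partner_type)) next
      qual[[length(qual) + 1]] <- sc[k, , drop = FALSE]
    }
    if (!length(qual)) next
    kept <- list(); last <- NULL
    for (q in qual) {
      if (is.null(last) ||
          as.numeric(difftime(q$time, last, units = "mins")) >= window) {
        kept[[length(kept) + 1]] <- q
        last <- q$time
      }
    }
    cnt <- 0L
    for (q in kept) {
      oth <- if (q$subject == a) b else a
      nb <- scan_neighbors[scan_neighbors$scan_id == q$scan_id &
                             scan_neighbors$neighbor == oth, , drop = FALSE]
      if (nrow(nb) && any(!is.na(nb$distance_bl) &
                            nb$distance_bl <= threshold)) cnt <- cnt + 1L
    }
    rec[[length(rec) + 1]] <- data.frame(
      year = year, behavior = "foraging", directed = FALSE,
      actor = a, partner = b, count = cnt,
      opportunities = length(kept))
  }
  df <- do.call(rbind, rec)
  if (is.null(df)) df <- data.frame(year = integer(), behavior = character(),
                                    directed = logical(), actor = character(),
                                    partner = character(), count = integer(),
                                    opportunities = integer())
  df[order(df$actor, df$partner), ]
}
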