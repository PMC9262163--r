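# Dyad builders: example-based checks against hand-computed values and
# property-based equivalence with the naive-rule oracles.

test_that("co-residence requires overlapping membership in the same group", {
  ts <- toy_study()
  expect_false(coresident(ts$membership, "ada", "bea",
                          as.Date("2010-06-01")))  # before bea's entry
  expect_true(coresident(ts$membership, "ada", "bea",
                         as.Date("2010-08-01")))
  expect_false(coresident(ts$membership, "ada", "eve",
                          as.Date("2010-08-01")))  # different groups
  expect_error(coresident(ts$membership, "ada", "nobody",
                          as.Date("2010-08-01")),
               class = "capsoc_error_unknown_id")
})

test_that("grooming opportunities sum both members' follows; counts are per-follow dichotomous", {
  ts <- toy_study()
  mk_follow <- function(id, focal, t) {
    tibble::tibble(follow_id = id, focal = focal, group = "A",
                   time = toy_time(t), duration_min = 10)
  }
  follows <- dplyr::bind_rows(
    mk_follow("f1", "ada", "2010-08-02 08:00:00"),
    mk_follow("f2", "ada", "2010-08-03 08:00:00"),
    mk_follow("f3", "ada", "2010-08-04 08:00:00"),
    mk_follow("f4", "cleo", "2010-08-05 08:00:00"),
    mk_follow("f5", "cleo", "2010-08-06 08:00:00"))
  none <- tibble::tibble(follow_id = character(), groomer = character(),
                         groomee = character(), time = toy_time(character()))
  dy <- build_grooming_dyads(follows, none, ts$individuals, ts$membership,
                             2010, "adult_females")
  row <- dplyr::filter(dy, actor == "ada", partner == "cleo")
  expect_equal(row$opportunities, 5L)  # 3 follows of ada + 2 of cleo
  expect_equal(row$count, 0L)

  # ada grooms cleo twice inside f1 and once inside cleo's f4:
  # the double event collapses, two distinct follows count
  ev <- tibble::tibble(
    follow_id = c("f1", "f1", "f4"), groomer = "ada", groomee = "cleo",
    time = toy_time(c("2010-08-02 08:01:00", "2010-08-02 08:05:00",
                      "2010-08-05 08:02:00")))
  dy2 <- build_grooming_dyads(follows, ev, ts$individuals, ts$membership,
                              2010, "adult_females")
  expect_equal(dplyr::filter(dy2, actor == "ada",
                             partner == "cleo")$count, 2L)
  expect_equal(dplyr::filter(dy2, actor == "cleo",
                             partner == "ada")$count, 0L)

  # never co-resident dyad absent (eve is in group B)
  expect_false(any(dy$actor == "eve" | dy$partner == "eve"))
})

test_that("partner filtering is age- and sex-aware at the event date", {
  ts <- toy_study()
  follows <- tibble::tibble(
    follow_id = c("f1", "f2"), focal = "ada", group = "A",
    time = toy_time(c("2010-08-02 08:00:00", "2011-08-02 08:00:00")),
    duration_min = 10)
  none <- tibble::tibble(follow_id = character(), groomer = character(),
                         groomee = character(), time = toy_time(character()))
  # ivy (born 2006-03-01) is immature in 2010, adult from 2011-03-01
  dy10 <- build_grooming_dyads(follows, none, ts$individuals,
                               ts$membership, 2010, "adult_females")
  dy11 <- build_grooming_dyads(follows, none, ts$individuals,
                               ts$membership, 2011, "adult_females")
  expect_false(any(dy10$partner == "ivy"))
  expect_true(any(dy11$partner == "ivy"))
  # with partner_type = all, immature partners stay in
  dyall <- build_grooming_dyads(follows, none, ts$individuals,
                                ts$membership, 2010, "all")
  expect_true(any(dyall$partner == "ivy"))
  # males are kept under "all" and "adult_males" but not "adult_females"
  expect_true(any(dyall$partner == "dag"))
  dym <- build_grooming_dyads(follows, none, ts$individuals,
                              ts$membership, 2010, "adult_males")
  expect_setequal(unique(c(dym$actor, dym$partner)[
    !(c(dym$actor, dym$partner) %in% c("ada"))]), "dag")
  expect_false(any(dy10$partner == "dag"))
})

test_that("interval segmentation is burst-anchored", {
  mk <- function(times) {
    tibble::tibble(time = toy_time(times), group = "A",
                   aggressor = "ada", target = "bea")
  }
  one <- segment_aggression_intervals(mk(c("2010-05-01 12:00:00",
                                           "2010-05-01 12:03:00")))
  expect_equal(nrow(one), 1L)
  two <- segment_aggression_intervals(mk(c("2010-05-01 12:00:00",
                                           "2010-05-01 12:06:00")))
  expect_equal(nrow(two), 2L)
  # 12:00, 12:04, 12:08 -> {12:00, 12:04}, {12:08} under first-event anchors
  three <- segment_aggression_intervals(mk(c("2010-05-01 12:00:00",
                                             "2010-05-01 12:04:00",
                                             "2010-05-01 12:08:00")))
  expect_equal(nrow(three), 2L)
  expect_equal(nrow(three$events[[1]]), 2L)
  expect_equal(nrow(three$events[[2]]), 1L)
})

test_that("joining is scored against the joinee's opponent or victim, once per interval", {
  # both attacked x: with no within-interval ordering required, each
  # supported the other's side, so the pair is mutual
  ev <- tibble::tibble(aggressor = c("j", "i"), target = c("x", "x"))
  expect_equal(dyad_pairs(score_joining(ev)),
               list(c("i", "j"), c("j", "i")))
  # dichotomous: three attacks by i still one instance per direction
  ev3 <- tibble::tibble(aggressor = c("j", "i", "i", "i"),
                        target = c("x", "x", "x", "x"))
  expect_equal(dyad_pairs(score_joining(ev3)),
               list(c("i", "j"), c("j", "i")))
  # attacking someone directly is not joining them
  ev0 <- tibble::tibble(aggressor = "i", target = "j")
  expect_equal(nrow(score_joining(ev0)), 0L)
  # joining via the opponent: x attacked j, then i attacks x
  ev_op <- tibble::tibble(aggressor = c("x", "i"), target = c("j", "x"))
  expect_true(any(vapply(dyad_pairs(score_joining(ev_op)),
                         identical, TRUE, c("i", "j"))))
})

test_that("support opportunities require a participating joinee and co-resident joiner", {
  ts <- toy_study()
  # 3 conflicts in group A, all after bea joined
  agg <- tibble::tibble(
    time = toy_time(c("2010-08-01 10:00:00", "2010-08-02 10:00:00",
                      "2010-08-03 10:00:00", "2010-08-03 10:01:00")),
    group = "A",
    aggressor = c("cleo", "cleo", "cleo", "ada"),
    target = c("bea", "bea", "bea", "bea"))
  iv <- segment_aggression_intervals(agg)
  dy <- build_support_dyads(iv, ts$individuals, ts$membership, 2010,
                            "adult_females")
  # ada joined cleo once (attacked cleo's victim bea in interval 3)
  expect_equal(dplyr::filter(dy, actor == "ada",
                             partner == "cleo")$count, 1L)
  expect_equal(dplyr::filter(dy, actor == "ada",
                             partner == "cleo")$opportunities, 3L)
  # eve is in group B: never co-resident, no record
  expect_false(any(dy$actor == "eve" | dy$partner == "eve"))
  # a non-participant cannot be joined: ivy never fought
  expect_false(any(dy$partner == "ivy"))
})

test_that("foraging thinning keeps scans >= 10 min apart and scores proximity", {
  ts <- toy_study()
  mk_scans <- function(times, subj = "ada") {
    tibble::tibble(scan_id = paste0("s", seq_along(times)),
                   time = toy_time(times), group = "A", subject = subj,
                   activity = "foraging")
  }
  nb <- function(ids, dist) {
    tibble::tibble(scan_id = ids, neighbor = "cleo", distance_bl = dist)
  }
  one <- build_foraging_dyads(mk_scans("2010-08-01 09:00:00"),
                              nb("s1", 6), ts$individuals, ts$membership,
                              2010, "adult_females")
  expect_equal(dplyr::filter(one, actor == "ada",
                             partner == "cleo")$count, 0L)  # 6 > 5
  close <- build_foraging_dyads(mk_scans("2010-08-01 09:00:00"),
                                nb("s1", 4), ts$individuals,
                                ts$membership, 2010, "adult_females")
  expect_equal(dplyr::filter(close, actor == "ada",
                             partner == "cleo")$count, 1L)
  # 12:00 + 12:04 thin to one opportunity; 12:00 + 12:11 keep two
  thin <- build_foraging_dyads(
    mk_scans(c("2010-08-01 12:00:00", "2010-08-01 12:04:00")),
    nb(character(0), numeric(0)), ts$individuals, ts$membership, 2010,
    "adult_females")
  expect_equal(dplyr::filter(thin, actor == "ada",
                             partner == "cleo")$opportunities, 1L)
  keep2 <- build_foraging_dyads(
    mk_scans(c("2010-08-01 12:00:00", "2010-08-01 12:11:00")),
    nb(character(0), numeric(0)), ts$individuals, ts$membership, 2010,
    "adult_females")
  expect_equal(dplyr::filter(keep2, actor == "ada",
                             partner == "cleo")$opportunities, 2L)
  # undirected storage: canonical order, no reversed duplicates
  expect_true(all(keep2$actor < keep2$partner))
})

test_that("builders match the naive-rule oracles on random toy streams", {
  partner_types <- c("all", "adult_females", "adult_males")
  for (seed in 1:12) {
    st <- gen_toy_stream(seed)
    pt <- partner_types[(seed %% 3) + 1]
    got_g <- suppressWarnings(
      build_grooming_dyads(st$follows, st$grooming, st$individuals,
                           st$membership, 2010, pt))
    exp_g <- oracle_grooming(st$follows, st$grooming, st$individuals,
                             st$membership, 2010, pt)
    expect_equal(dyad_df(got_g), dyad_df(exp_g),
                 info = sprintf("grooming seed %d (%s)", seed, pt))

    iv <- segment_aggression_intervals(st$aggression)
    got_s <- build_support_dyads(iv, st$individuals, st$membership,
                                 2010, pt)
    exp_s <- oracle_support(st$aggression, st$individuals, st$membership,
                            2010, pt)
    expect_equal(dyad_df(got_s), dyad_df(exp_s),
                 info = sprintf("support seed %d (%s)", seed, pt))

    got_f <- suppressWarnings(
      build_foraging_dyads(st$scans, st$scan_neighbors, st$individuals,
                           st$membership, 2010, pt))
    exp_f <- oracle_foraging(st$scans, st$scan_neighbors, st$individuals,
                             st$membership, 2010, pt)
    expect_equal(dyad_df(got_f), dyad_df(exp_f),
                 info = sprintf("foraging seed %d (%s)", seed, pt))
  }
})

test_that("dyad tables satisfy their structural invariants and are deterministic", {
  st <- gen_toy_stream(99)
  study <- c(st, list())
  for (bh in c("grooming", "support", "foraging")) {
    d1 <- suppressWarnings(build_dyads(study, bh, "all"))
    d2 <- suppressWarnings(build_dyads(study, bh, "all"))
    expect_identical(d1, d2)
    expect_true(all(d1$count <= d1$opportunities))
    expect_true(all(d1$opportunities > 0))
    if (bh == "foraging") {
      expect_false(any(duplicated(d1[, c("year", "actor", "partner")])))
      expect_true(all(d1$actor < d1$partner))
    }
  }
})
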