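# Co-residence and age/adulthood predicates.
#
# Membership is tabular: one row per (id, group, entry, exit) interval, with
# an open interval encoded as exit = NA. Intervals for one individual must
# not overlap, so an individual is in at most one group at any time.

norm_membership <- function(membership) {
  assert_cols(membership, c("id", "group", "entry", "exit"), "membership")
  m <- as_tibble(membership) |>
    mutate(entry = as.Date(.data$entry),
           exit = as.Date(if_else(is.na(.data$exit),
                                  as.Date("9999-12-31"), as.Date(.data$exit))))
  bad <- m |> filter(.data$exit < .data$entry)
  if (nrow(bad)) {
    abort(sprintf("membership has entry > exit for id(s): %s",
                  paste(unique(bad$id), collapse = ", ")),
          class = "capsoc_error_input")
  }
  m
}

# group of each id at each date; returns tibble(id, date, group) for ids
# resident somewhere at that date
groups_at <- function(membership, ids, dates) {
  q <- tibble(id = ids, date = as.Date(dates), .row = seq_along(ids))
  m <- norm_membership(membership)
  q |>
    inner_join(m, by = dplyr::join_by(id, date >= entry, date <= exit)) |>
    select(".row", "id", "date", "group")
}

#' Are two individuals co-resident at a time point?
#'
#' Two individuals are co-resident when some membership interval of each
#' places them in the same group at time `t`. Co-residence is the
#' prerequisite for any interaction opportunity.
#'
#' @param membership Data frame with columns `id`, `group`, `entry`, `exit`
#'   (dates; `exit = NA` means ongoing).
#' @param i,j Character vectors of individual ids (recycled to a common
#'   length).
#' @param t Timestamps or dates (recycled likewise).
#' @return Logical vector.
#' @export
#' @examples
#' mem <- tibble::tibble(
#'   id = c("a", "b"), group = "G",
#'   entry = as.Date(c("2010-01-01", "2010-07-01")),
#'   exit = as.Date(c("2010-12-31", "2010-12-31")))
#' coresident(mem, "a", "b", as.Date("2010-06-01")) # FALSE: b not yet entered
#' coresident(mem, "a", "b", as.Date("2010-08-01")) # TRUE
coresident <- function(membership, i, j, t) {
  n <- max(length(i), length(j), length(t))
  i <- rep_len(i, n); j <- rep_len(j, n); t <- rep_len(as.Date(t), n)
  m <- norm_membership(membership)
  unknown <- setdiff(c(i, j), m$id)
  if (length(unknown)) {
    abort(sprintf("unknown individual id(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "capsoc_error_unknown_id")
  }
  gi <- groups_at(m, i, t)
  gj <- groups_at(m, j, t)
  out <- rep(FALSE, n)
  hit <- inner_join(gi, gj, by = c(".row", "date", "group"))
  out[hit$.row] <- TRUE
  out
}

# Pair-eligibility predicate for one of the three partner datasets.
# The subject side is always adult females; the partner side depends on
# partner_type. A pair qualifies on a date if either ordering satisfies
# (subject-eligible, partner-eligible).
pair_eligible <- function(individuals, a, b, date, partner_type) {
  partner_type <- match.arg(partner_type, c("all", "adult_females", "adult_males"))
  assert_cols(individuals, c("id", "sex", "birth_date"), "individuals")
  bd <- setNames(as.Date(individuals$birth_date), individuals$id)
  sx <- setNames(as.character(individuals$sex), individuals$id)
  date <- as.Date(date)
  adult <- function(x) is_adult_on(bd[x], date)
  subj <- function(x) sx[x] == "F" & adult(x)
  part <- switch(partner_type,
    all = function(x) rep(TRUE, length(x)),
    adult_females = function(x) sx[x] == "F" & adult(x),
    adult_males = function(x) sx[x] == "M" & adult(x))
  (subj(a) & part(b)) | (subj(b) & part(a))
}
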