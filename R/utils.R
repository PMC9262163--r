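# Internal helpers shared across modules.

#' Derive a stage seed from a master seed
#'
#' Deterministic seed-splitting rule used by the pipeline: each named stage
#' gets its own reproducible stream derived from one master seed, so reruns
#' with the same master seed are byte-identical while stages stay
#' independent.
#'
#' @param master Integer master seed.
#' @param stage Character stage label (e.g. `"simulate"`, `"srm_grooming"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(7, "simulate")
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master) * 7919 + h * 104729) %% (2^31 - 1))
}

# Split-Rhat (rank-free classic split version) over an iterations x chains
# matrix; vectorised over parameters when given a 3-d array [iter, chain, par].
split_rhat <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1))
  n <- dim(x)[1]
  half <- floor(n / 2)
  # split each chain in two
  lower <- x[seq_len(half), , , drop = FALSE]
  upper <- x[seq.int(n - half + 1, n), , , drop = FALSE]
  y <- array(NA_real_, dim = c(half, 2 * dim(x)[2], dim(x)[3]))
  y[, seq_len(dim(x)[2]), ] <- lower
  y[, dim(x)[2] + seq_len(dim(x)[2]), ] <- upper
  m <- dim(y)[2]
  cm <- apply(y, c(2, 3), mean)            # chain means  [m, par]
  cv <- apply(y, c(2, 3), stats::var)      # chain vars   [m, par]
  B <- half * apply(cm, 2, stats::var)
  W <- colMeans(cv)
  vhat <- (half - 1) / half * W + B / half
  rh <- sqrt(vhat / W)
  rh[W == 0] <- 1
  rh
}

# Effective sample size via coda on a combined mcmc.list; tolerant of
# constant chains.
ess_safe <- function(mcl, pars) {
  out <- rep(NA_real_, length(pars))
  names(out) <- pars
  es <- try(coda::effectiveSize(mcl[, pars, drop = FALSE]), silent = TRUE)
  if (!inherits(es, "try-error")) out[names(es)] <- es
  out
}

# decimal age in years at a given date
age_at <- function(birth_date, date) {
  as.numeric(as.Date(date) - as.Date(birth_date)) / 365.25
}

# age at mid-year (July 1), the package's convention for annual covariates
age_in_year <- function(birth_date, year) {
  age_at(birth_date, as.Date(sprintf("%d-07-01", year)))
}

# adult = age >= 5 years on the date in question
is_adult_on <- function(birth_date, date) {
  age_at(birth_date, date) >= 5
}

fmt_est <- function(m, lo, hi, digits = 2) {
  sprintf("%.*f (%.*f; %.*f)", digits, m, digits, lo, digits, hi)
}

assert_cols <- function(df, cols, name) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  name, paste(miss, collapse = ", ")),
          class = "capsoc_error_input")
  }
  invisible(df)
}
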