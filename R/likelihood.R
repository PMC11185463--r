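#' Negative-binomial probability mass function (mean / aggregation form)
#'
#' `Pr(X = x) = Gamma(k+x) / (x! Gamma(k)) * (m/(m+k))^x * (k/(m+k))^k`,
#' the ecological parameterisation with mean `m` and aggregation parameter
#' `k`; the Poisson distribution is the limit `k -> Inf`. Computed directly
#' on the log scale (not delegated to `dnbinom()`, which the tests use as an
#' independent oracle).
#'
#' @param x nonnegative integer count(s).
#' @param m mean (> 0).
#' @param k aggregation parameter (> 0); `Inf` gives the Poisson pmf.
#' @param log return the log pmf?
#' @return probability (or log probability), vectorised over `x`.
#' @export
nb_pmf <- function(x, m, k, log = FALSE) {
  if (any(m <= 0)) stop("m must be > 0")
  if (any(k <= 0)) stop("k must be > 0")
  if (any(x < 0) || any(x != floor(x))) stop("x must be a nonnegative integer")
  if (any(!is.finite(k))) {
    lp <- x * base::log(m) - m - lfactorial(x)
  } else {
    lp <- lgamma(k + x) - lfactorial(x) - lgamma(k) +
      x * (base::log(m) - base::log(m + k)) +
      k * (base::log(k) - base::log(m + k))
  }
  if (log) lp else exp(lp)
}

# pmf vector (x = 0..x_hi) of the sum of independent NB(m_t, k) counts,
# by exact discrete convolution. Each night's support is truncated where its
# upper tail mass is < 1e-12; entries above x_hi are dropped as they never
# feed back into lower entries.
nb_sum_pmf <- function(nightly_means, k, x_hi) {
  pmf <- 1
  for (m in nightly_means) {
    hi <- stats::qnbinom(1e-12, size = k, mu = m, lower.tail = FALSE)
    hi <- min(hi, x_hi)
    night <- nb_pmf(0:hi, m, k)
    out <- numeric(min(length(pmf) + hi, x_hi + 1))
    for (i in seq_along(night)) {
      idx <- seq_along(pmf) + i - 1L
      keep <- idx <= length(out)
      out[idx[keep]] <- out[idx[keep]] + pmf[keep] * night[i]
    }
    pmf <- out
  }
  pmf
}

#' One survey observation (count over a multi-night window)
#'
#' @param n observed number of new nests attributed to the window (>= 0).
#' @param window_nights number of nights the window covers (>= 1).
#' @param count_type `"exact_sum"` when the count is the exact sum of
#'   activity over the window, `"minimum"` when track loss makes it a lower
#'   bound (censored).
#' @param n_max upper bound on the true count; required when
#'   `count_type = "minimum"`.
#' @param islet_id,day optional site label and ordinal survey date.
#' @return list of class `count_observation`.
#' @export
count_observation <- function(n, window_nights, count_type = "exact_sum",
                              n_max = NULL, islet_id = NA, day = NA) {
  if (n < 0) stop("n must be >= 0")
  if (window_nights < 1) stop("window_nights must be >= 1")
  count_type <- match.arg(count_type, c("exact_sum", "minimum"))
  if (count_type == "minimum") {
    if (is.null(n_max)) stop("n_max required for a minimum (censored) count")
    if (n_max < n) stop("n_max must be >= n")
  }
  structure(list(n = n, window_nights = window_nights,
                 count_type = count_type, n_max = n_max,
                 islet_id = islet_id, day = day),
            class = "count_observation")
}

#' Log-likelihood of one survey window
#'
#' For an `exact_sum` count the likelihood is the pmf of the sum of the
#' per-night counts evaluated at `n`; with Poisson nights this is the closed
#' form with summed mean, with NB nights an exact discrete convolution. For
#' a `minimum` (censored) count the likelihood integrates the window-total
#' pmf over all admissible true counts `n..n_max`.
#'
#' @param obs a [count_observation()].
#' @param nightly_means numeric vector of per-night means, one per night of
#'   the window.
#' @param k NB aggregation parameter; `Inf` (default) selects the Poisson
#'   model.
#' @return log-likelihood (scalar).
#' @export
window_count_loglik <- function(obs, nightly_means, k = Inf) {
  if (length(nightly_means) != obs$window_nights) {
    stop("length(nightly_means) must equal window_nights")
  }
  nightly_means <- pmax(nightly_means, 1e-9)
  poisson <- !is.finite(k)
  if (obs$count_type == "exact_sum" || obs$n_max == obs$n) {
    if (poisson) {
      return(stats::dpois(obs$n, sum(nightly_means), log = TRUE))
    }
    if (obs$window_nights == 1L) return(nb_pmf(obs$n, nightly_means, k, log = TRUE))
    pmf <- nb_sum_pmf(nightly_means, k, obs$n)
    # support may have been truncated below n where the tail mass is
    # negligible (< 1e-12)
    p <- if (obs$n + 1L <= length(pmf)) pmf[obs$n + 1L] else 0
    return(base::log(max(p, 1e-300)))
  }
  xs <- obs$n:obs$n_max
  if (poisson) {
    lp <- stats::dpois(xs, sum(nightly_means), log = TRUE)
    mx <- max(lp)
    return(mx + base::log(sum(exp(lp - mx))))
  }
  pmf <- nb_sum_pmf(nightly_means, k, obs$n_max)
  idx <- xs[xs + 1L <= length(pmf)] + 1L
  base::log(max(sum(pmf[idx]), 1e-300))
}

#' Total log-likelihood of a survey table under a phenology model
#'
#' Reference (loop) implementation: sums [window_count_loglik()] over all
#' rows of a survey table, with theoretical per-night means from
#' [expected_nightly()]. The optimiser and sampler use an equivalent
#' vectorised Poisson fast path; equality is covered by the tests.
#'
#' @param surveys survey table (see [read_surveys()]): columns `islet_id`,
#'   `season`, `day`, `n`, `window_nights`, `count_type`, `n_max`.
#' @param shapes named list of [phenology_shape()], one per season
#'   (names = season start years).
#' @param max_by_cell named numeric vector of `Max` per `islet_id|season`
#'   cell.
#' @param PMin shared off-season relative level.
#' @param k NB aggregation parameter; `Inf` = Poisson.
#' @return total log-likelihood.
#' @export
season_loglik <- function(surveys, shapes, max_by_cell, PMin = 0, k = Inf) {
  validate_windows(surveys)
  ll <- 0
  for (i in seq_len(nrow(surveys))) {
    row <- surveys[i, ]
    cell <- paste(row$islet_id, row$season, sep = "|")
    shape <- shapes[[as.character(row$season)]]
    nights <- (row$day - row$window_nights + 1L):row$day
    mu <- expected_nightly(nights, shape,
                           phenology_scale(max_by_cell[[cell]], PMin))
    obs <- count_observation(row$n, row$window_nights,
                             count_type = row$count_type,
                             n_max = if (is.na(row$n_max)) NULL else row$n_max,
                             islet_id = row$islet_id, day = row$day)
    ll <- ll + window_count_loglik(obs, mu, k)
  }
  ll
}

# windows of one islet-season must tile without overlap
validate_windows <- function(surveys) {
  key <- paste(surveys$islet_id, surveys$season, sep = "|")
  for (cell in unique(key)) {
    sub <- surveys[key == cell, ]
    sub <- sub[order(sub$day), ]
    if (anyDuplicated(sub$day)) {
      stop(sprintf("duplicate survey dates for %s", cell))
    }
    if (nrow(sub) > 1L) {
      start <- sub$day - sub$window_nights
      if (any(start[-1L] < sub$day[-nrow(sub)])) {
        stop(sprintf("overlapping windows for %s", cell))
      }
    }
  }
  invisible(TRUE)
}
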