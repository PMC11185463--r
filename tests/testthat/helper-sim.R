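# Shared fixture builders. Everything is generated in code at test time.

# Marked-track data from the stated detection model: trajectories are a
# latent standard-normal AR1 thresholded to the marginal logistic curve
# logit(d) = intercept + slope * age. No absorbing-loss modification, so
# the marginal curve is exactly the logistic (the package generator adds
# absorbing loss on top; detection-module tests want the clean model).
gen_tracks <- function(n_tracks = 150, intercept = 1.8, slope = -0.08,
                       phi = 0.5, seasons = 2019:2022, n_obs = 6,
                       seed = 1) {
  set.seed(seed)
  rows <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    ages <- cumsum(c(0, round(stats::runif(n_obs - 1, 10, 20))))
    z <- numeric(n_obs)
    z[1] <- stats::rnorm(1)
    for (j in 2:n_obs) z[j] <- phi * z[j - 1] + sqrt(1 - phi^2) * stats::rnorm(1)
    d <- stats::plogis(intercept + slope * ages)
    det <- as.integer(z < stats::qnorm(d))
    rows[[i]] <- data.frame(track_id = sprintf("T%04d", i),
                            season = sample(seasons, 1),
                            age_days = ages, detected = det)
  }
  do.call(rbind, rows)
}

# Minimal survey table: one islet-season with windows tiling [1, n_surveys*gap]
simple_surveys <- function(counts, gap = 10, islet = "I1", season = 2020,
                           count_type = "exact_sum") {
  k <- length(counts)
  data.frame(islet_id = islet, season = season,
             day = gap * seq_len(k), n = counts,
             window_nights = gap, count_type = count_type,
             n_max = NA_integer_, stringsAsFactors = FALSE)
}

# Small synthetic rookery used by several suites: 3 A-islets + 2 B-islets,
# 2 seasons, perfect detection.
small_config <- function(seed = 1, ...) {
  simulation_config(n_a = 3, n_b = 2, seasons = 2019:2020,
                    P = c(91, 88), Max0 = 0.6, multiplier_sdlog = 0.4,
                    detection = list(S = 3, A = Inf, phi = 0.5,
                                     false_resight = 0.01),
                    seed = seed, ...)
}

# Brute-force oracle: pmf of the sum of independent NB(m_t, k) counts by
# enumeration over all per-night outcome vectors with total <= x_hi.
nb_sum_pmf_oracle <- function(x, nightly_means, k) {
  grids <- lapply(nightly_means, function(m) 0:x)
  combos <- expand.grid(grids)
  tot <- rowSums(combos)
  keep <- combos[tot == x, , drop = FALSE]
  if (nrow(keep) == 0) return(0)
  sum(apply(keep, 1, function(row) {
    prod(vapply(seq_along(row), function(j) {
      if (is.finite(k)) stats::dnbinom(row[j], size = k, mu = nightly_means[j])
      else stats::dpois(row[j], nightly_means[j])
    }, numeric(1)))
  }))
}
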