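#' Probability of detecting a nest track of a given age
#'
#' Logistic decay of track detectability with age,
#' `d_a = 1 / (1 + exp(-(A - a) / (4 S)))`, where `A` is the half-life age
#' (detection probability 0.5) and `S` controls the steepness of the decay.
#'
#' @param a track age(s) in days.
#' @param S scale parameter in days (> 0).
#' @param A half-life age in days.
#' @export
detection_probability <- function(a, S, A) {
  if (S <= 0) stop("S must be > 0")
  stats::plogis((A - a) / (4 * S))
}

#' Convert logit-model coefficients to (S, A) and back
#'
#' The logit model `logit(d_a) = intercept + slope * a` maps to the
#' half-life form via `S = -1 / (4 slope)` and `A = 4 S intercept`.
#'
#' @param intercept,age_slope logit-scale coefficients (`age_slope < 0`).
#' @return `logit_to_sa()`: named vector `c(S, A)`; `sa_to_logit()`: named
#'   vector `c(intercept, age_slope)`.
#' @export
logit_to_sa <- function(intercept, age_slope) {
  if (age_slope >= 0) stop("age_slope must be negative")
  S <- -1 / (4 * age_slope)
  c(S = S, A = 4 * S * intercept)
}

#' @rdname logit_to_sa
#' @param S,A half-life parameterisation (`S > 0`).
#' @export
sa_to_logit <- function(S, A) {
  if (S <= 0) stop("S must be > 0")
  c(intercept = A / (4 * S), age_slope = -1 / (4 * S))
}

#' Fisher's combined probability test
#'
#' Combines independent p-values (here: per-season Wald tests for a season
#' effect on detectability) via `X = -2 sum(log p) ~ chi-squared(2 n)`.
#'
#' @param p_values vector of p-values in (0, 1].
#' @return combined upper-tail p-value.
#' @export
season_effect_test <- function(p_values) {
  if (any(p_values <= 0) || any(p_values > 1)) stop("p-values must be in (0, 1]")
  x <- -2 * sum(base::log(p_values))
  stats::pchisq(x, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Upper bound on the true count behind a censored survey count
#'
#' When a survey window is long, tracks laid early in the window may have
#' faded before the survey; the observed count is then a minimum. The upper
#' bound inflates the count by the mean detection probability over the
#' window's nightly track ages, floored at 0.05:
#' `N_max = ceiling(N_t / max(mean(d), 0.05))`.
#'
#' @param n_t observed count (>= 0).
#' @param window_ages track ages in days, at survey time, of the nights the
#'   window covers.
#' @param S,A detection-curve parameters.
#' @export
estimate_nmax <- function(n_t, window_ages, S, A) {
  if (length(window_ages) == 0L) stop("empty window")
  if (n_t == 0) return(0L)
  dbar <- max(mean(detection_probability(window_ages, S, A)), 0.05)
  as.integer(max(ceiling(n_t / dbar), n_t))
}

# ---------------------------------------------------------------------------
# GEE-style logistic fit with an AR1 working correlation within tracks.
# Returns beta, robust vcov, phi. X rows must be grouped by track in
# observation order.
gee_ar1_logit <- function(y, X, track) {
  fit0 <- stats::glm.fit(X, y, family = stats::binomial())
  beta <- fit0$coefficients
  if (anyNA(beta)) stop("design matrix is rank-deficient")
  groups <- split(seq_along(y), track)
  phi <- 0
  for (iter in 1:50) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    v <- mu * (1 - mu)
    e <- (y - mu) / sqrt(v)
    # lag-1 moment estimator of the working AR1 coefficient
    num <- 0; npairs <- 0
    for (g in groups) {
      if (length(g) > 1L) {
        num <- num + sum(e[g[-length(g)]] * e[g[-1L]])
        npairs <- npairs + length(g) - 1L
      }
    }
    # no df correction: keeps the estimator exactly invariant under
    # duplication of whole clusters
    sig2 <- sum(e^2) / length(y)
    phi <- if (npairs > 0) num / (npairs * sig2) else 0
    phi <- min(max(phi, 0), 0.95)
    B <- matrix(0, ncol(X), ncol(X))
    score <- numeric(ncol(X))
    for (g in groups) {
      ni <- length(g)
      R <- phi^abs(outer(seq_len(ni), seq_len(ni), "-"))
      Ah <- sqrt(v[g])
      Vi <- R * outer(Ah, Ah)
      D <- X[g, , drop = FALSE] * v[g]           # d mu / d beta
      W <- solve(Vi, cbind(D, y[g] - mu[g]))
      B <- B + crossprod(D, W[, seq_len(ncol(X)), drop = FALSE])
      score <- score + crossprod(D, W[, ncol(X) + 1L])
    }
    step <- solve(B, score)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-9) break
  }
  # sandwich variance
  eta <- drop(X %*% beta); mu <- stats::plogis(eta); v <- mu * (1 - mu)
  B <- matrix(0, ncol(X), ncol(X)); Mmat <- B
  for (g in groups) {
    ni <- length(g)
    R <- phi^abs(outer(seq_len(ni), seq_len(ni), "-"))
    Ah <- sqrt(v[g])
    Vi <- R * outer(Ah, Ah)
    D <- X[g, , drop = FALSE] * v[g]
    Wd <- solve(Vi, D)
    B <- B + crossprod(D, Wd)
    u <- crossprod(Wd, y[g] - mu[g])
    Mmat <- Mmat + tcrossprod(u)
  }
  Binv <- solve(B)
  list(beta = beta, vcov = Binv %*% Mmat %*% Binv, phi = phi,
       iterations = iter)
}

#' Fit the nest-track detectability model
#'
#' Marginal logistic regression of detection state on track age (and season,
#' when several are present) with an AR1 working correlation within tracks,
#' fitted by iteratively reweighted estimating equations. Season enters with
#' sum-to-zero contrasts, so the intercept is the across-season mean at age
#' zero. Uncertainty comes from a track-level (cluster) bootstrap.
#'
#' @param observations data.frame with columns `track_id`, `season`,
#'   `age_days`, `detected` (0/1), ordered by age within track.
#' @param n_boot number of track-resampling bootstrap replicates (the field
#'   analysis used 9999; default 999 for desk scale).
#' @param seed integer seed for the bootstrap.
#' @param ages_grid ages at which the bootstrap curve band is evaluated.
#' @return object of class `detection_fit`: `intercept`, `slope`, `S`, `A`,
#'   `phi`, `season_p` (per-season Wald p-values), `season_p_combined`
#'   (Fisher), `boot` (replicate parameter matrix), `curve` (age, d, lo95,
#'   hi95), `vcov`, counts.
#' @export
fit_detection <- function(observations, n_boot = 999, seed = 1L,
                          ages_grid = 0:60) {
  req <- c("track_id", "season", "age_days", "detected")
  if (!all(req %in% names(observations))) {
    stop("observations must have columns ", paste(req, collapse = ", "))
  }
  observations <- observations[order(observations$track_id,
                                     observations$age_days), ]
  y <- as.numeric(observations$detected)
  if (all(y == 1) || all(y == 0)) {
    stop("complete separation: all observations ",
         if (all(y == 1)) "detected" else "missed",
         "; the age slope is not identifiable")
  }
  sizes <- table(observations$track_id)
  if (sum(sizes >= 2) < 2) stop("need at least 2 tracks with >= 2 observations")

  fit_once <- function(df) {
    seasons <- unique(df$season)
    if (length(seasons) > 1L) {
      sf <- factor(df$season)
      X <- stats::model.matrix(~ age_days + sf, df,
                               contrasts.arg = list(sf = "contr.sum"))
    } else {
      X <- stats::model.matrix(~ age_days, df)
    }
    g <- gee_ar1_logit(as.numeric(df$detected), X, df$track_id)
    g$X <- X
    g
  }
  g <- fit_once(observations)
  beta <- g$beta
  intercept <- beta[[1L]]
  slope <- beta[["age_days"]]
  if (slope >= 0) {
    warning("age slope is nonnegative; half-life A is not finite")
    S <- NA_real_; A <- NA_real_
  } else {
    sa <- logit_to_sa(intercept, slope)
    S <- sa[["S"]]; A <- sa[["A"]]
  }
  season_idx <- grep("^sf", colnames(g$X))
  season_p <- NULL; season_p_combined <- NA_real_
  if (length(season_idx) > 0) {
    z <- beta[season_idx] / sqrt(diag(g$vcov)[season_idx])
    season_p <- 2 * stats::pnorm(-abs(z))
    season_p_combined <- season_effect_test(pmin(pmax(season_p, 1e-300), 1))
  }

  # track-level bootstrap
  ids <- unique(observations$track_id)
  boot <- matrix(NA_real_, n_boot, 4,
                 dimnames = list(NULL, c("intercept", "slope", "S", "A")))
  curves <- matrix(NA_real_, n_boot, length(ages_grid))
  if (n_boot > 0) {
    set.seed(seed)
    rows_by_id <- split(seq_len(nrow(observations)), observations$track_id)
    for (b in seq_len(n_boot)) {
      pick <- sample(ids, length(ids), replace = TRUE)
      rows <- unlist(rows_by_id[as.character(pick)], use.names = FALSE)
      df <- observations[rows, ]
      # resampled copies of a track must stay distinct clusters
      df$track_id <- rep(seq_along(pick),
                         lengths(rows_by_id[as.character(pick)]))
      gb <- tryCatch(fit_once(df), error = function(e) NULL)
      if (is.null(gb)) next
      bi <- gb$beta[[1L]]; bs <- gb$beta[["age_days"]]
      boot[b, 1:2] <- c(bi, bs)
      if (bs < 0) boot[b, 3:4] <- logit_to_sa(bi, bs)
      curves[b, ] <- stats::plogis(bi + bs * ages_grid)
    }
  }
  d_hat <- stats::plogis(intercept + slope * ages_grid)
  if (n_boot > 0) {
    band <- apply(curves, 2, stats::quantile, probs = c(0.025, 0.975),
                  na.rm = TRUE)
    curve <- data.frame(age = ages_grid, d = d_hat, lo95 = band[1, ],
                        hi95 = band[2, ])
  } else {
    curve <- data.frame(age = ages_grid, d = d_hat, lo95 = NA_real_,
                        hi95 = NA_real_)
  }
  structure(list(
    intercept = intercept, slope = slope, S = S, A = A, phi = g$phi,
    coefficients = beta, vcov = g$vcov,
    season_p = season_p, season_p_combined = season_p_combined,
    boot = boot, curve = curve,
    n_tracks = length(ids), n_obs = nrow(observations)
  ), class = "detection_fit")
}

#' @export
print.detection_fit <- function(x, ...) {
  cat(sprintf(
    "Track-detectability fit: intercept %.3f, slope %.4f (S = %.2f, A = %.2f days), phi = %.2f\n",
    x$intercept, x$slope, x$S, x$A, x$phi))
  cat(sprintf("  %d tracks, %d observations", x$n_tracks, x$n_obs))
  if (!is.na(x$season_p_combined)) {
    cat(sprintf("; season effect (Fisher combined) p = %.2f",
                x$season_p_combined))
  }
  cat("\n")
  invisible(x)
}

#' Flag censored survey windows and attach count upper bounds
#'
#' Applies the default censoring rule: a window longer than the detection
#' half-life `A` yields a `minimum` count (older tracks may have faded),
#' shorter windows are `exact_sum`. Rows whose `count_type` is not `"auto"`
#' are left as supplied. `n_max` for censored rows comes from
#' [estimate_nmax()] with nightly ages `(window_nights - 1):0`.
#'
#' @param surveys survey table with a `count_type` column that may contain
#'   `"auto"`.
#' @param S,A detection-curve parameters (use `A = Inf` for perfect
#'   detection: every `auto` row becomes `exact_sum`).
#' @return the survey table with resolved `count_type` and `n_max`.
#' @export
assign_count_types <- function(surveys, S, A) {
  auto <- surveys$count_type == "auto"
  if (!any(auto)) return(surveys)
  if (is.null(surveys$n_max)) surveys$n_max <- NA_integer_
  long <- auto & surveys$window_nights > A
  surveys$count_type[auto & !long] <- "exact_sum"
  surveys$count_type[long] <- "minimum"
  for (i in which(long)) {
    ages <- (surveys$window_nights[i] - 1L):0L
    surveys$n_max[i] <- estimate_nmax(surveys$n[i], ages, S, A)
  }
  surveys
}
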