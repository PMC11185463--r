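#' Site proportions from multinomial-logit polynomial predictors
#'
#' The share `p_j(i)` of season `i`'s total nests laid on islet `j` follows
#' a multinomial-logit transform of per-islet polynomial predictors in the
#' (centered) season index. The last islet is the reference (logit fixed at
#' 0), so an order-`d` model has `(K - 1) * (d + 1)` free coefficients and
#' the proportions sum to one by construction.
#'
#' @param params a `spatial_params` object (see [fit_spatial()]), or a list
#'   with `beta` (matrix `(K-1) x (order+1)` of polynomial coefficients),
#'   `order`, and `center` (season-index centering constant).
#' @param season_index season index (1-based) at which to evaluate.
#' @return numeric vector of `K` proportions summing to 1.
#' @export
proportions_at <- function(params, season_index) {
  x <- season_index - params$center
  basis <- x^(0:params$order)
  eta <- c(drop(params$beta %*% basis), 0)
  eta <- eta - max(eta)
  w <- exp(eta)
  w / sum(w)
}

#' Expected islet-season count
#'
#' `E_ij = T_i * p_j`: the expected number of nests on islet `j` in season
#' `i` is the season total times the islet's share.
#'
#' @param T_i season total (> 0).
#' @param p_j islet proportion(s).
#' @export
expected_count <- function(T_i, p_j) T_i * p_j

#' Gamma log-likelihood of an observed islet-season count
#'
#' The observed count `N_ij` (with observation sd `S_ij`) is modelled as
#' gamma with mean `E_ij` and sd `S_ij` (shape `E^2/S^2`, scale `S^2/E`),
#' which stays positive and allows the right skew of poorly covered cells.
#' Zero observations are offset to `zero_offset` before evaluation, the
#' gamma density being undefined at 0.
#'
#' @param N_ij observed count.
#' @param S_ij observation standard deviation (> 0).
#' @param E_ij expected count (> 0).
#' @param zero_offset replacement value for `N_ij = 0` (default 0.5 nests).
#' @export
gamma_loglik <- function(N_ij, S_ij, E_ij, zero_offset = 0.5) {
  if (any(S_ij <= 0) || any(E_ij <= 0)) stop("S_ij and E_ij must be > 0")
  if (any(N_ij < 0)) stop("N_ij must be >= 0")
  N_ij <- ifelse(N_ij == 0, zero_offset, N_ij)
  shape <- E_ij^2 / S_ij^2
  rate <- E_ij / S_ij^2
  sum(stats::dgamma(N_ij, shape = shape, rate = rate, log = TRUE))
}

#' Fit season totals and site proportions to a gapped islet-season table
#'
#' Maximum-likelihood fit of per-season totals `T_i` and sum-to-one site
#' proportions `p_j` (constant, linear or quadratic in season index) under
#' the gamma observation model, one fit per requested polynomial order;
#' the returned selection is by lowest AICc (ties toward fewer parameters).
#'
#' @param estimates data.frame with columns `islet_id`, `season`, `mean`,
#'   `sd`; one row per *observed* islet-season (missing cells are simply
#'   absent).
#' @param orders polynomial orders to try, subset of `0:2`.
#' @param zero_offset passed to [gamma_loglik()].
#' @return list with `fits` (per order: `spatial_params` with `T`, `beta`,
#'   `order`, `center`, `logLik`, `n_params`, `AICc`), `best` (selected
#'   order), `table` (AICc comparison).
#' @export
fit_spatial <- function(estimates, orders = 0:2, zero_offset = 0.5) {
  req <- c("islet_id", "season", "mean", "sd")
  if (!all(req %in% names(estimates))) {
    stop("estimates must have columns ", paste(req, collapse = ", "))
  }
  islets <- sort(unique(estimates$islet_id))
  seasons <- sort(unique(estimates$season))
  K <- length(islets); Y <- length(seasons)
  never <- setdiff(islets, unique(estimates$islet_id[!is.na(estimates$mean)]))
  if (length(never) > 0) {
    stop("islet(s) never observed, proportions unidentifiable: ",
         paste(never, collapse = ", "))
  }
  estimates <- estimates[!is.na(estimates$mean), , drop = FALSE]
  j_idx <- match(estimates$islet_id, islets)
  i_idx <- match(estimates$season, seasons)
  center <- (Y + 1) / 2
  n_obs <- nrow(estimates)
  sd_obs <- pmax(estimates$sd, 1e-6)

  # moment-based starting values
  T0 <- vapply(seq_len(Y), function(i) {
    obs <- estimates$mean[i_idx == i]
    max(sum(obs) * K / max(length(obs), 1L), 1)
  }, numeric(1))
  share0 <- vapply(seq_len(K), function(j) {
    mean(estimates$mean[j_idx == j]) + 0.5
  }, numeric(1))
  share0 <- share0 / sum(share0)
  eta0 <- base::log(share0 / share0[K])

  fits <- list()
  for (d in sort(orders)) {
    npar_beta <- (K - 1) * (d + 1)
    unpack <- function(theta) {
      Tt <- exp(theta[seq_len(Y)])
      beta <- matrix(theta[Y + seq_len(npar_beta)], nrow = K - 1)
      list(T = Tt, beta = beta)
    }
    nll <- function(theta) {
      p <- unpack(theta)
      P <- vapply(seq_len(Y), function(i) {
        proportions_at(list(beta = p$beta, order = d, center = center), i)
      }, numeric(K))
      E <- p$T[i_idx] * P[cbind(j_idx, i_idx)]
      if (any(!is.finite(E))) return(1e10)
      ll <- gamma_loglik(estimates$mean, sd_obs, pmax(E, 1e-12),
                         zero_offset = zero_offset)
      if (!is.finite(ll)) 1e10 else -ll
    }
    start <- c(base::log(T0), eta0[-K], rep(0, npar_beta - (K - 1)))
    opt <- stats::optim(start, nll, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-12))
    opt2 <- stats::optim(opt$par, nll, method = "BFGS",
                         control = list(maxit = 1000, reltol = 1e-12))
    if (opt2$value <= opt$value) opt <- opt2
    p <- unpack(opt$par)
    n_params <- Y + npar_beta
    logLik <- -opt$value
    fits[[as.character(d)]] <- structure(list(
      T = stats::setNames(p$T, seasons), beta = p$beta, order = d,
      center = center, islets = islets, seasons = seasons,
      logLik = logLik, n_params = n_params, n_obs = n_obs,
      AICc = if (n_obs > n_params + 1) aicc(logLik, n_params, n_obs) else Inf
    ), class = "spatial_params")
  }
  av <- vapply(fits, `[[`, numeric(1), "AICc")
  np <- vapply(fits, `[[`, numeric(1), "n_params")
  ord <- order(av, np)
  tab <- data.frame(order = as.integer(names(fits)), AICc = av,
                    n_params = np, row.names = NULL)[ord, ]
  list(fits = fits, best = fits[[ord[1L]]], table = tab)
}

#' Fill unsurveyed islet-seasons with model-expected counts
#'
#' Missing cells of the islet x season grid are filled with
#' `E_ij = T_i * p_j(i)`; observed cells pass through untouched with
#' `source = "fitted_phenology"`. The model-based sd attached to an imputed
#' cell is `cv * E_ij`, where `cv` is the median observed coefficient of
#' variation (configurable).
#'
#' @param estimates observed islet-season table (see [fit_spatial()]).
#' @param params fitted `spatial_params` (e.g. `fit_spatial(...)$best`).
#' @param cv coefficient of variation for imputed-cell sds; default the
#'   median `sd/mean` of the observed cells.
#' @return completed data.frame `islet_id`, `season`, `mean`, `sd`,
#'   `source` covering the full grid.
#' @export
impute_missing <- function(estimates, params, cv = NULL) {
  islets <- params$islets; seasons <- params$seasons
  if (is.null(cv)) {
    pos <- estimates$mean > 0
    cv <- if (any(pos)) stats::median(estimates$sd[pos] / estimates$mean[pos]) else 0.5
    cv <- max(cv, 0.05)
  }
  grid <- expand.grid(islet_id = islets, season = seasons,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key_obs <- paste(estimates$islet_id, estimates$season, sep = "|")
  key_grid <- paste(grid$islet_id, grid$season, sep = "|")
  hit <- match(key_grid, key_obs)
  grid$mean <- estimates$mean[hit]
  grid$sd <- estimates$sd[hit]
  grid$source <- ifelse(is.na(hit), "imputed", "fitted_phenology")
  miss <- which(is.na(hit))
  if (length(miss) > 0) {
    P <- vapply(seq_along(seasons), function(i) proportions_at(params, i),
                numeric(length(islets)))
    for (m in miss) {
      i <- match(grid$season[m], seasons)
      j <- match(grid$islet_id[m], islets)
      E <- expected_count(params$T[[i]], P[j, i])
      grid$mean[m] <- E
      grid$sd[m] <- cv * E
    }
  }
  grid
}
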