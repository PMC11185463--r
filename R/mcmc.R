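#' MCMC configuration
#'
#' @param n_iter total iterations (field analysis: 20,000 for parameter
#'   sampling, 50,000 for the derived-total stage).
#' @param burn_in_fraction fraction of iterations discarded; proposal-scale
#'   adaptation is confined to the burn-in and frozen afterwards, which
#'   preserves detailed balance for the retained draws.
#' @param thinning keep every `thinning`-th post-burn-in draw.
#' @param target_acceptance adaptation target (0.234, the optimal
#'   asymptotic acceptance rate for random-walk proposals).
#' @param seed integer RNG seed.
#' @param lower,upper uniform-prior bounds per parameter (recycled).
#' @export
mcmc_config <- function(n_iter = 20000, burn_in_fraction = 0.1,
                        thinning = 1L, target_acceptance = 0.234,
                        seed = 1L, lower = -Inf, upper = Inf) {
  stopifnot(target_acceptance > 0, target_acceptance < 1,
            burn_in_fraction >= 0, burn_in_fraction <= 0.9)
  structure(list(n_iter = as.integer(n_iter),
                 burn_in_fraction = burn_in_fraction,
                 thinning = as.integer(thinning),
                 target_acceptance = target_acceptance,
                 seed = as.integer(seed), lower = lower, upper = upper),
            class = "mcmc_config")
}

#' Adaptive Metropolis-Hastings sampler
#'
#' Component-wise Gaussian random-walk Metropolis with Robbins-Monro
#' adaptation of the per-component proposal scales toward the target
#' acceptance rate during burn-in; scales are frozen afterwards. Priors are
#' uniform on `[lower, upper]` (proposals outside the bounds are rejected).
#'
#' @param log_posterior function of the parameter vector returning a
#'   (possibly unnormalised) log posterior density.
#' @param config an [mcmc_config()].
#' @param start numeric starting vector with finite log posterior.
#' @param scales initial proposal sds (recycled; default 1).
#' @return object of class `posterior_sample`: `draws` (matrix, one row per
#'   retained draw), `acceptance_rate` (post-adaptation), `scales`.
#' @export
mh_sample <- function(log_posterior, config, start, scales = 1) {
  d <- length(start)
  lower <- rep_len(config$lower, d); upper <- rep_len(config$upper, d)
  if (any(start < lower | start > upper)) stop("start outside prior bounds")
  lp <- log_posterior(start)
  if (!is.finite(lp)) stop("log posterior not finite at start")
  set.seed(config$seed)
  scales <- rep_len(scales, d)
  n_burn <- floor(config$n_iter * config$burn_in_fraction)
  keep_at <- seq(n_burn + 1L, config$n_iter, by = config$thinning)
  draws <- matrix(NA_real_, length(keep_at), d)
  theta <- start
  acc_post <- integer(d); n_post <- integer(d)
  ki <- 1L
  for (it in seq_len(config$n_iter)) {
    for (j in seq_len(d)) {
      prop <- theta
      prop[j] <- theta[j] + stats::rnorm(1, 0, scales[j])
      accept <- FALSE
      if (prop[j] >= lower[j] && prop[j] <= upper[j]) {
        lp_prop <- log_posterior(prop)
        if (is.finite(lp_prop) && base::log(stats::runif(1)) < lp_prop - lp) {
          theta <- prop; lp <- lp_prop; accept <- TRUE
        }
      }
      if (it <= n_burn) {
        eta <- min(1, 5 / it)
        scales[j] <- scales[j] *
          exp(eta * ((if (accept) 1 else 0) - config$target_acceptance))
      } else {
        n_post[j] <- n_post[j] + 1L
        if (accept) acc_post[j] <- acc_post[j] + 1L
      }
    }
    if (ki <= length(keep_at) && it == keep_at[ki]) {
      draws[ki, ] <- theta
      ki <- ki + 1L
    }
  }
  structure(list(draws = draws,
                 acceptance_rate = sum(acc_post) / max(sum(n_post), 1L),
                 acceptance_by_param = acc_post / pmax(n_post, 1L),
                 scales = scales, config = config),
            class = "posterior_sample")
}

#' Summary table of a posterior sample
#'
#' Mean, sd, median and the 2.5%/97.5% quantiles of each column of a draw
#' matrix (or of a `posterior_sample`).
#'
#' @param sample a `posterior_sample`, or a numeric matrix of draws.
#' @return data.frame with one row per parameter/statistic.
#' @export
summarize_posterior <- function(sample) {
  draws <- if (inherits(sample, "posterior_sample")) sample$draws else as.matrix(sample)
  if (nrow(draws) == 0L) stop("no post-burn-in draws to summarise")
  nm <- colnames(draws)
  if (is.null(nm)) nm <- paste0("param", seq_len(ncol(draws)))
  data.frame(
    parameter = nm,
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    median = apply(draws, 2, stats::median),
    q2.5 = apply(draws, 2, stats::quantile, probs = 0.025),
    q97.5 = apply(draws, 2, stats::quantile, probs = 0.975),
    row.names = NULL
  )
}
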