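#' Expected season-integrated nest total for one islet
#'
#' Sum of [expected_nightly()] over all ordinal days of the season
#' (dominated by the interval `[B, E]`).
#'
#' @param shape a [phenology_shape()].
#' @param scale a [phenology_scale()].
#' @param n_days days in the season (365/366; see [season_ndays()]).
#' @export
season_total_expected <- function(shape, scale, n_days = 365) {
  sum(expected_nightly(seq_len(n_days), shape, scale))
}

#' Posterior sampling of phenology parameters and per-islet peak heights
#'
#' Metropolis-within-Gibbs sampler for the phenology model: free shape
#' parameters (peak dates, season lengths, optionally `PMin`, per the
#' fitted family) move by adaptive Gaussian random-walk Metropolis under
#' uniform priors — seasonal peaks are updated as a block of conditionally
#' independent per-season components, the shared season lengths as a joint
#' two-dimensional proposal. Per-cell `Max` values carry the Jeffreys
#' reference prior for a Poisson rate, `p(Max) ~ Max^(-1/2)` (a flat prior
#' on this positive scale parameter systematically inflates low-count
#' islets), and are drawn exactly from their conditional
#' `Gamma(sum N + 1/2, rate sum c)` when all of a cell's windows are
#' exact-sum Poisson counts, by scalar Metropolis steps for cells with
#' censored windows. Proposal-scale adaptation toward acceptance 0.234 is
#' confined to the burn-in.
#'
#' @param fit a [fit_phenology()] result (Poisson dispersion).
#' @param config an [mcmc_config()].
#' @param priors named list of uniform prior bounds: `P` (default
#'   `c(1, 365)`), `LengthB`/`LengthE` (`c(1, 200)`), `PMin` (`c(0, 0.5)`),
#'   `Max` (`c(0, 50)`).
#' @return object of class `phenology_posterior`: `shape_draws` (matrix),
#'   `max_draws`, `cell_totals` (draws x cells matrix of season-integrated
#'   expected totals per islet-season), `cells`, `seasons`,
#'   `acceptance_rate`.
#' @export
sample_phenology_posterior <- function(fit, config = mcmc_config(),
                                       priors = list()) {
  if (fit$dispersion != "poisson") {
    stop("posterior sampler implemented for the Poisson model")
  }
  pr <- utils::modifyList(list(P = c(1, 365), LengthB = c(1, 200),
                               LengthE = c(1, 200), PMin = c(0, 0.5),
                               Max = c(0, 50)), priors)
  prep <- fit$prep
  S <- length(prep$seasons)
  ncell <- nrow(prep$cells)
  fixed <- fit$fixed
  Fv <- if (is.null(fixed$F)) 0 else fixed$F
  peak_seasonal <- fit$family[["peak"]] == "seasonal"
  lble_seasonal <- fit$family[["lble"]] == "seasonal"
  P_free <- is.null(fixed$P)
  L_free <- is.null(fixed$LengthB)
  PMin_free <- is.null(fixed$PMin)

  state <- list(P = vapply(fit$shapes, `[[`, numeric(1), "P"),
                LB = vapply(fit$shapes, `[[`, numeric(1), "LengthB"),
                LE = vapply(fit$shapes, `[[`, numeric(1), "LengthE"),
                PMin = fit$PMin)
  Max <- pmin(pmax(unname(fit$max_by_cell), 1e-6), pr$Max[2])

  cens_cells <- sort(unique(prep$win$cell[prep$win$censored]))
  exact_ok <- setdiff(seq_len(ncell), cens_cells)
  use <- !prep$win$censored
  Sn <- numeric(ncell)
  agg <- rowsum(prep$win$n[use], prep$win$cell[use])
  Sn[as.integer(rownames(agg))] <- agg[, 1L]
  cens_scale <- pmax(Max[cens_cells], 0.5)
  wins_of_cell <- split(seq_len(nrow(prep$win)), prep$win$cell)
  win_seas <- prep$win$season

  # per-window *relative* log-likelihood (the -lfactorial(n) term is
  # constant across iterations and cancels in every MH ratio), then
  # per-season sums
  any_cens <- any(prep$win$censored)
  cens <- prep$win$censored
  n_w <- prep$win$n
  llw_rel <- function(M) {
    out <- n_w * base::log(M) - M
    if (any_cens) {
      p <- stats::ppois(prep$win$n_max[cens], M[cens]) -
        stats::ppois(n_w[cens] - 1L, M[cens])
      out[cens] <- base::log(pmax(p, 1e-300))
    }
    out
  }
  ll_seasons <- function(cw, Max) {
    M <- pmax(Max[prep$win$cell] * cw, 1e-9)
    drop(rowsum(llw_rel(M), win_seas))
  }
  det_w <- fit$det_weights
  curve_sums <- function(st) {
    window_curve_sums(prep, st$P, st$LB, st$LE, Fv, st$PMin, weights = det_w)
  }

  set.seed(config$seed)
  cw <- curve_sums(state)
  ll_s <- ll_seasons(cw, Max)
  win_idx_season <- prep$win_by_season

  # adaptive proposal scales
  sc_P <- rep(2, if (peak_seasonal) S else 1L)
  sc_L <- if (lble_seasonal) matrix(4, S, 2) else matrix(4, 1, 2)
  sc_PMin <- 0.01
  adapt <- function(scale, accepted, it) {
    scale * exp(min(1, 5 / it) * (as.numeric(accepted) - config$target_acceptance))
  }

  n_burn <- floor(config$n_iter * config$burn_in_fraction)
  keep_at <- seq(n_burn + 1L, config$n_iter, by = config$thinning)
  nkeep <- length(keep_at)
  shape_names <- c(if (P_free) paste0("P_", if (peak_seasonal) prep$seasons else "common"),
                   if (L_free) paste0("LengthB_", if (lble_seasonal) prep$seasons else "common"),
                   if (L_free) paste0("LengthE_", if (lble_seasonal) prep$seasons else "common"),
                   if (PMin_free) "PMin")
  shape_draws <- matrix(NA_real_, nkeep, length(shape_names),
                        dimnames = list(NULL, shape_names))
  max_draws <- matrix(NA_real_, nkeep, ncell)
  cell_totals <- matrix(NA_real_, nkeep, ncell)
  acc_n <- 0L; acc_k <- 0L
  ki <- 1L
  ndays_by_season <- season_ndays(prep$seasons)

  for (it in seq_len(config$n_iter)) {
    # ---- peak block ---------------------------------------------------
    if (P_free) {
      if (peak_seasonal) {
        propP <- state$P + stats::rnorm(S, 0, sc_P)
        ok <- propP >= pr$P[1] & propP <= pr$P[2]
        st_prop <- state; st_prop$P <- ifelse(ok, propP, state$P)
        cw_prop <- curve_sums(st_prop)
        ll_prop <- ll_seasons(cw_prop, Max)
        acc <- ok & (base::log(stats::runif(S)) < ll_prop - ll_s)
        if (any(acc)) {
          state$P[acc] <- propP[acc]
          for (s in which(acc)) {
            w <- win_idx_season[[s]]
            cw[w] <- cw_prop[w]
          }
          ll_s[acc] <- ll_prop[acc]
        }
        if (it <= n_burn) {
          sc_P <- mapply(adapt, sc_P, acc, MoreArgs = list(it = it))
        } else { acc_n <- acc_n + S; acc_k <- acc_k + sum(acc) }
      } else {
        prop <- state$P[1] + stats::rnorm(1, 0, sc_P)
        accepted <- FALSE
        if (prop >= pr$P[1] && prop <= pr$P[2]) {
          st_prop <- state; st_prop$P[] <- prop
          cw_prop <- curve_sums(st_prop)
          ll_prop <- ll_seasons(cw_prop, Max)
          if (base::log(stats::runif(1)) < sum(ll_prop) - sum(ll_s)) {
            state <- st_prop; cw <- cw_prop; ll_s <- ll_prop
            accepted <- TRUE
          }
        }
        if (it <= n_burn) sc_P <- adapt(sc_P, accepted, it)
        else { acc_n <- acc_n + 1L; acc_k <- acc_k + accepted }
      }
    }

    # ---- season-length block ------------------------------------------
    if (L_free) {
      if (lble_seasonal) {
        propLB <- state$LB + stats::rnorm(S, 0, sc_L[, 1])
        propLE <- state$LE + stats::rnorm(S, 0, sc_L[, 2])
        ok <- propLB > max(pr$LengthB[1], Fv) & propLB <= pr$LengthB[2] &
          propLE > max(pr$LengthE[1], Fv) & propLE <= pr$LengthE[2]
        st_prop <- state
        st_prop$LB <- ifelse(ok, propLB, state$LB)
        st_prop$LE <- ifelse(ok, propLE, state$LE)
        cw_prop <- curve_sums(st_prop)
        ll_prop <- ll_seasons(cw_prop, Max)
        acc <- ok & (base::log(stats::runif(S)) < ll_prop - ll_s)
        if (any(acc)) {
          state$LB[acc] <- propLB[acc]
          state$LE[acc] <- propLE[acc]
          for (s in which(acc)) {
            w <- win_idx_season[[s]]
            cw[w] <- cw_prop[w]
          }
          ll_s[acc] <- ll_prop[acc]
        }
        if (it <= n_burn) {
          for (s in seq_len(S)) sc_L[s, ] <- adapt(sc_L[s, ], acc[s], it)
        } else { acc_n <- acc_n + S; acc_k <- acc_k + sum(acc) }
      } else {
        prop <- c(state$LB[1], state$LE[1]) + stats::rnorm(2, 0, sc_L[1, ])
        accepted <- FALSE
        if (prop[1] > max(pr$LengthB[1], Fv) && prop[1] <= pr$LengthB[2] &&
            prop[2] > max(pr$LengthE[1], Fv) && prop[2] <= pr$LengthE[2]) {
          st_prop <- state
          st_prop$LB[] <- prop[1]; st_prop$LE[] <- prop[2]
          cw_prop <- curve_sums(st_prop)
          ll_prop <- ll_seasons(cw_prop, Max)
          if (base::log(stats::runif(1)) < sum(ll_prop) - sum(ll_s)) {
            state <- st_prop; cw <- cw_prop; ll_s <- ll_prop
            accepted <- TRUE
          }
        }
        if (it <= n_burn) sc_L[1, ] <- adapt(sc_L[1, ], accepted, it)
        else { acc_n <- acc_n + 1L; acc_k <- acc_k + accepted }
      }
    }

    # ---- PMin ----------------------------------------------------------
    if (PMin_free) {
      prop <- state$PMin + stats::rnorm(1, 0, sc_PMin)
      accepted <- FALSE
      if (prop >= pr$PMin[1] && prop <= pr$PMin[2]) {
        st_prop <- state; st_prop$PMin <- prop
        cw_prop <- curve_sums(st_prop)
        ll_prop <- ll_seasons(cw_prop, Max)
        if (base::log(stats::runif(1)) < sum(ll_prop) - sum(ll_s)) {
          state <- st_prop; cw <- cw_prop; ll_s <- ll_prop
          accepted <- TRUE
        }
      }
      if (it <= n_burn) sc_PMin <- adapt(sc_PMin, accepted, it)
      else { acc_n <- acc_n + 1L; acc_k <- acc_k + accepted }
    }

    # ---- per-cell Max --------------------------------------------------
    Sc <- numeric(ncell)
    agg <- rowsum(cw[use], prep$win$cell[use])
    Sc[as.integer(rownames(agg))] <- agg[, 1L]
    if (length(exact_ok) > 0) {
      # rgamma first; the prior upper bound almost never binds, fall back
      # to inverse-cdf sampling only where it does
      g <- stats::rgamma(length(exact_ok), shape = Sn[exact_ok] + 0.5,
                         rate = Sc[exact_ok])
      over <- g > pr$Max[2]
      if (any(over)) {
        io <- exact_ok[over]
        hi <- stats::pgamma(pr$Max[2], shape = Sn[io] + 0.5, rate = Sc[io])
        u <- stats::runif(length(io)) * hi
        g[over] <- stats::qgamma(pmin(pmax(u, 1e-300), 1 - 1e-12),
                                 shape = Sn[io] + 0.5, rate = Sc[io])
      }
      Max[exact_ok] <- g
    }
    if (length(cens_cells) > 0) {
      for (i in seq_along(cens_cells)) {
        cell <- cens_cells[i]
        w <- wins_of_cell[[as.character(cell)]]
        prop <- Max[cell] + stats::rnorm(1, 0, cens_scale[i])
        accepted <- FALSE
        if (prop > 0 && prop <= pr$Max[2]) {
          ll_cur <- ll_windows_pois(prep$win, pmax(Max[cell] * cw[w], 1e-9), w)
          ll_new <- ll_windows_pois(prep$win, pmax(prop * cw[w], 1e-9), w)
          # Jeffreys prior ratio on Max
          ll_new <- ll_new - 0.5 * base::log(prop)
          ll_cur <- ll_cur - 0.5 * base::log(Max[cell])
          if (base::log(stats::runif(1)) < ll_new - ll_cur) {
            Max[cell] <- prop
            accepted <- TRUE
          }
        }
        if (it <= n_burn) cens_scale[i] <- adapt(cens_scale[i], accepted, it)
      }
    }
    ll_s <- ll_seasons(cw, Max)

    if (ki <= nkeep && it == keep_at[ki]) {
      shape_draws[ki, ] <- c(
        if (P_free) { if (peak_seasonal) state$P else state$P[1] },
        if (L_free) { if (lble_seasonal) state$LB else state$LB[1] },
        if (L_free) { if (lble_seasonal) state$LE else state$LE[1] },
        if (PMin_free) state$PMin)
      max_draws[ki, ] <- Max
      R <- vapply(seq_len(S), function(s) {
        sum(unit_curve_scalar(seq_len(ndays_by_season[s]), state$P[s],
                              state$LB[s], state$LE[s], Fv, state$PMin))
      }, numeric(1))
      cell_totals[ki, ] <- Max * R[match(prep$cells$season, prep$seasons)]
      ki <- ki + 1L
    }
  }
  structure(list(
    shape_draws = shape_draws, max_draws = max_draws,
    cell_totals = cell_totals, cells = prep$cells, seasons = prep$seasons,
    acceptance_rate = if (acc_n > 0) acc_k / acc_n else NA_real_,
    config = config
  ), class = "phenology_posterior")
}

#' Seasonal and multi-season rookery nest totals with credible intervals
#'
#' Per posterior draw, sums the season-integrated expected nest totals over
#' all surveyed islet-season cells and adds gamma-distributed draws for
#' imputed (never-surveyed) cells; reports the median and 2.5%/97.5%
#' quantiles per season and for the across-season mean. With
#' `obs_noise = TRUE` a Poisson observation layer is added on the surveyed
#' cells, giving a posterior-predictive interval for the *realised* total
#' rather than its expectation.
#'
#' @param post a [sample_phenology_posterior()] result.
#' @param imputed completed islet-season table from [impute_missing()]
#'   (only rows with `source == "imputed"` are used), or `NULL` when every
#'   cell was surveyed.
#' @param n_resample number of Monte-Carlo draws for the totals stage
#'   (posterior rows are resampled with replacement; field analysis used
#'   50,000).
#' @param obs_noise add Poisson observation noise on surveyed cells?
#' @param seed RNG seed for this resampling stage.
#' @return list with `seasonal` (data.frame season, lo95, median, hi95),
#'   `overall` (named vector for the across-season mean), `draws` (matrix
#'   of per-season totals).
#' @export
seasonal_totals <- function(post, imputed = NULL, n_resample = 50000,
                            obs_noise = FALSE, seed = 1L) {
  set.seed(seed)
  seasons <- post$seasons
  idx <- sample.int(nrow(post$cell_totals), n_resample, replace = TRUE)
  cell_season <- match(post$cells$season, seasons)
  agg <- t(rowsum(t(post$cell_totals[idx, , drop = FALSE]), cell_season))
  if (obs_noise) {
    agg <- matrix(stats::rpois(length(agg), agg), nrow(agg), ncol(agg))
  }
  if (!is.null(imputed)) {
    imp <- imputed[imputed$source == "imputed", , drop = FALSE]
    if (nrow(imp) > 0) {
      for (r in seq_len(nrow(imp))) {
        s <- match(imp$season[r], seasons)
        if (is.na(s)) next
        shape <- (imp$mean[r] / max(imp$sd[r], 1e-6))^2
        rate <- imp$mean[r] / max(imp$sd[r], 1e-6)^2
        agg[, s] <- agg[, s] + stats::rgamma(n_resample, shape, rate)
      }
    }
  }
  colnames(agg) <- as.character(seasons)
  qs <- apply(agg, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  seasonal <- data.frame(season = seasons,
                         lo95 = qs[1, ], median = qs[2, ], hi95 = qs[3, ],
                         row.names = NULL)
  overall_draws <- rowMeans(agg)
  overall <- stats::quantile(overall_draws, c(0.025, 0.5, 0.975))
  names(overall) <- c("lo95", "median", "hi95")
  list(seasonal = seasonal, overall = overall, draws = agg)
}
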