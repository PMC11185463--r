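make_spatial_params <- function(beta, order, center, islets = NULL,
                                seasons = NULL) {
  structure(list(beta = beta, order = order, center = center,
                 islets = islets, seasons = seasons),
            class = "spatial_params")
}

test_that("proportions are a sum-to-one multinomial logit", {
  p0 <- make_spatial_params(matrix(0, 2, 1), 0, 1)
  expect_equal(proportions_at(p0, 1), rep(1 / 3, 3))
  p1 <- make_spatial_params(matrix(log(3), 1, 1), 0, 1)
  expect_equal(proportions_at(p1, 1), c(0.75, 0.25))
  set.seed(5)
  for (ord in 0:2) {
    K <- sample(3:8, 1)
    beta <- matrix(rnorm((K - 1) * (ord + 1)), K - 1)
    pp <- make_spatial_params(beta, ord, 2.5)
    for (i in 1:4) {
      p <- proportions_at(pp, i)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p > 0))
    }
  }
})

test_that("expected counts multiply and conserve the season total", {
  expect_equal(expected_count(100, 0.25), 25)
  expect_equal(expected_count(437, 0.1), 43.7)
  p <- c(0.5, 0.3, 0.2)
  expect_equal(sum(expected_count(437, p)), 437)
})

test_that("gamma likelihood uses the mean/sd moment mapping", {
  E <- 50; S <- 10
  shape <- E^2 / S^2; rate <- E / S^2
  # moment identity of the implied gamma
  expect_equal(shape / rate, E, tolerance = 1e-10)
  expect_equal(shape / rate^2, S^2, tolerance = 1e-10)
  expect_equal(gamma_loglik(40, S, E),
               dgamma(40, shape, rate, log = TRUE))
  # density integrates to 1 (quadrature oracle)
  q <- integrate(function(x) exp(vapply(x, gamma_loglik, numeric(1),
                                        S_ij = S, E_ij = E)),
                 0, Inf, rel.tol = 1e-9)
  expect_equal(q$value, 1, tolerance = 1e-6)
  # mode near the mean beats the far tail
  for (i in 1:5) {
    E2 <- runif(1, 5, 80); S2 <- runif(1, 1, 15)
    expect_gt(gamma_loglik(E2, S2, E2), gamma_loglik(E2 + 5 * S2, S2, E2))
  }
  # zeros are offset, not rejected
  expect_equal(gamma_loglik(0, 5, 10), gamma_loglik(0.5, 5, 10))
  expect_error(gamma_loglik(5, -1, 10), "must be > 0")
})

test_that("gamma skewness vanishes as E/S grows", {
  skew <- function(E, S) 2 * S / E  # gamma skewness = 2/sqrt(shape)
  expect_equal(skew(50, 10), 2 / sqrt(25))
  expect_lt(skew(500, 10), skew(50, 10))
})

# a small islet-season world with order-0 proportions
make_world <- function(K = 4, Y = 4, Ttot = NULL, noise_cv = 0,
                       seed = 1) {
  set.seed(seed)
  if (is.null(Ttot)) Ttot <- round(runif(Y, 300, 500))
  p <- rev(seq_len(K)) / sum(seq_len(K))
  grid <- expand.grid(islet_id = paste0("I", 1:K), season = 2017:(2016 + Y),
                      stringsAsFactors = FALSE)
  i <- match(grid$season, sort(unique(grid$season)))
  j <- match(grid$islet_id, sort(unique(grid$islet_id)))
  E <- Ttot[i] * p[j]
  obs <- if (noise_cv > 0) rgamma(nrow(grid), shape = 1 / noise_cv^2,
                                  rate = 1 / (noise_cv^2 * E)) else E
  grid$mean <- obs
  grid$sd <- pmax(0.1, noise_cv * E + 0.5)
  list(table = grid, T = Ttot, p = p[order(sort(unique(grid$islet_id)))])
}

test_that("noiseless complete table identifies the proportions to 1e-3", {
  w <- make_world(K = 4, Y = 4, seed = 2)
  w$table$sd <- 0.5
  fit <- fit_spatial(w$table, orders = 0)
  p_hat <- proportions_at(fit$best, 1)
  p_true <- c(0.4, 0.3, 0.2, 0.1)
  expect_lt(max(abs(p_hat - p_true)), 1e-3)
  expect_lt(max(abs(fit$best$T - w$T) / w$T), 0.01)
})

test_that("imputation fills gaps with T_i * p_j and flags sources", {
  w <- make_world(K = 4, Y = 3, seed = 3)
  w$table$sd <- 1
  full <- w$table
  gapped <- full[-c(2, 7), ]
  fit <- fit_spatial(gapped, orders = 0)
  out <- impute_missing(gapped, fit$best)
  expect_equal(nrow(out), 12L)
  expect_setequal(out$source, c("fitted_phenology", "imputed"))
  expect_equal(sum(out$source == "imputed"), 2L)
  imp <- out[out$source == "imputed", ]
  for (r in seq_len(nrow(imp))) {
    i <- match(imp$season[r], fit$best$seasons)
    j <- match(imp$islet_id[r], fit$best$islets)
    E <- expected_count(fit$best$T[[i]], proportions_at(fit$best, i)[j])
    expect_equal(imp$mean[r], E, tolerance = 1e-9)
    truth <- full$mean[full$islet_id == imp$islet_id[r] &
                         full$season == imp$season[r]]
    expect_lt(abs(imp$mean[r] - truth) / truth, 0.2)
  }
  # observed cells pass through untouched
  kept <- out[out$source == "fitted_phenology", ]
  key <- paste(kept$islet_id, kept$season)
  expect_equal(kept$mean, gapped$mean[match(key, paste(gapped$islet_id,
                                                       gapped$season))])
  # no missing cells: identity apart from the source flag
  out_full <- impute_missing(full, fit$best)
  expect_true(all(out_full$source == "fitted_phenology"))
  expect_equal(sum(out_full$mean), sum(full$mean))
})

test_that("noisy gapped tables recover imputed cells within tolerance", {
  ok <- 0L; n_cells <- 0L
  for (seed in 1:5) {
    w <- make_world(K = 5, Y = 4, noise_cv = 0.15, seed = seed)
    drop <- sample(nrow(w$table), 4)
    gapped <- w$table[-drop, ]
    fit <- fit_spatial(gapped, orders = 0)
    out <- impute_missing(gapped, fit$best)
    imp <- out[out$source == "imputed", ]
    for (r in seq_len(nrow(imp))) {
      i <- match(imp$season[r], fit$best$seasons)
      j <- match(imp$islet_id[r], fit$best$islets)
      truth <- w$T[i] * w$p[j]
      n_cells <- n_cells + 1L
      ok <- ok + (abs(imp$mean[r] - truth) <= 2 * pmax(imp$sd[r], 1))
    }
  }
  expect_gte(ok / n_cells, 0.9)
})

test_that("log-likelihood is non-decreasing in polynomial order and AICc
           prefers the true order-0 model", {
  w <- make_world(K = 4, Y = 5, noise_cv = 0.1, seed = 11)
  fit <- fit_spatial(w$table, orders = 0:2)
  ll <- vapply(fit$fits, `[[`, numeric(1), "logLik")
  expect_true(all(diff(ll[order(as.integer(names(ll)))]) >= -1e-3))
  expect_equal(fit$best$order, 0)
})

test_that("an islet never observed is rejected by name", {
  w <- make_world(K = 4, Y = 3, seed = 4)
  gapped <- w$table
  gapped$mean[gapped$islet_id == "I3"] <- NA_real_
  expect_error(fit_spatial(gapped, orders = 0), "I3")
})
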