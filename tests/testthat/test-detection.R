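test_that("detection probability has the half-life form", {
  expect_equal(detection_probability(22.23, S = 3.04, A = 22.23), 0.5)
  expect_equal(detection_probability(10, S = 2, A = 10), 0.5)
  # fresh-track value with the published rounded parameters
  expect_equal(detection_probability(0, S = 3.04, A = 22.23),
               plogis(22.23 / (4 * 3.04)), tolerance = 1e-12)
  expect_equal(detection_probability(0, S = 3.04, A = 22.23), 0.861,
               tolerance = 1e-3)
  # strictly decreasing, bounded in (0, 1), vanishing at great age
  a <- seq(0, 120, by = 1)
  d <- detection_probability(a, 3.04, 22.23)
  expect_true(all(diff(d) < 0))
  expect_true(all(d > 0 & d < 1))
  expect_lt(detection_probability(1e4, 3.04, 22.23), 1e-10)
  expect_error(detection_probability(5, S = -1, A = 10), "S must")
})

test_that("logit <-> (S, A) conversion round-trips and handles edge cases", {
  expect_equal(logit_to_sa(0, -0.25), c(S = 1, A = 0))
  # algebra on the printed rounded coefficients (not the printed S/A pair,
  # which came from unrounded fits)
  sa <- logit_to_sa(1.82, -0.08)
  expect_equal(unname(sa), c(3.125, 22.75), tolerance = 1e-12)
  expect_equal(sa_to_logit(2, 10), c(intercept = 1.25, age_slope = -0.125))
  set.seed(2)
  for (i in 1:20) {
    S <- runif(1, 0.5, 10); A <- runif(1, -5, 60)
    lg <- sa_to_logit(S, A)
    back <- logit_to_sa(lg[["intercept"]], lg[["age_slope"]])
    expect_equal(unname(back), c(S, A), tolerance = 1e-12)
  }
  expect_error(logit_to_sa(1, 0.1), "negative")
  expect_error(sa_to_logit(-1, 5), "S must")
})

test_that("Fisher's combined test matches the chi-squared tail", {
  expect_equal(season_effect_test(c(1, 1, 1)), 1)
  expect_equal(season_effect_test(c(0.5, 0.5)),
               pchisq(-2 * log(0.25), df = 4, lower.tail = FALSE))
  expect_equal(season_effect_test(c(0.5, 0.5)), 0.5966, tolerance = 1e-4)
  expect_equal(season_effect_test(0.073), 0.073)  # n = 1 identity
  expect_error(season_effect_test(c(0.5, 0)), "p-values")
})

test_that("estimate_nmax inflates counts by mean window detectability", {
  S <- 3.04; A <- 22.23
  d0 <- detection_probability(0, S, A)
  expect_equal(estimate_nmax(10, rep(0, 5), S, A), as.integer(ceiling(10 / d0)))
  expect_equal(estimate_nmax(0, 0:10, S, A), 0L)
  # floor at 0.05 for very old windows
  expect_equal(estimate_nmax(3, 200:210, S, A), as.integer(ceiling(3 / 0.05)))
  expect_gte(estimate_nmax(7, 0:30, S, A), 7L)
  expect_error(estimate_nmax(3, numeric(0), S, A), "empty")
})

test_that("GEE fit recovers the marginal slope and agrees with the GLM oracle", {
  tk <- gen_tracks(n_tracks = 250, intercept = 1.8, slope = -0.08,
                   phi = 0.5, seed = 31)
  fit <- fit_detection(tk, n_boot = 0)
  expect_lt(fit$slope, 0)
  expect_lt(abs(fit$slope - (-0.08)), 0.02)
  expect_gt(fit$phi, 0.2)  # strong within-track dependence detected
  # independence GLM estimates the same marginal quantities
  sf <- factor(tk$season)
  X <- model.matrix(~ age_days + sf, tk, contrasts.arg = list(sf = "contr.sum"))
  g <- glm.fit(X, tk$detected, family = binomial())
  expect_equal(fit$slope, g$coefficients[["age_days"]], tolerance = 0.15)
  expect_equal(fit$intercept, g$coefficients[[1]], tolerance = 0.15)
  # no true season effect: combined p should not be extreme
  expect_gt(fit$season_p_combined, 0.001)
  expect_length(fit$season_p, nlevels(sf) - 1L)
})

test_that("true slope falls inside the 95% bootstrap interval (replicated)", {
  hits <- 0L
  n_rep <- 8L
  for (r in seq_len(n_rep)) {
    tk <- gen_tracks(n_tracks = 120, intercept = 1.8, slope = -0.08,
                     phi = 0.5, seed = 100 + r)
    fit <- fit_detection(tk, n_boot = 60, seed = r)
    ci <- quantile(fit$boot[, "slope"], c(0.025, 0.975), na.rm = TRUE)
    hits <- hits + (ci[1] <= -0.08 && -0.08 <= ci[2])
  }
  expect_gte(hits, n_rep - 1L)
})

test_that("bootstrap bands widen with fewer tracks", {
  tk_small <- gen_tracks(n_tracks = 40, seed = 7)
  tk_large <- gen_tracks(n_tracks = 220, seed = 7)
  f_small <- fit_detection(tk_small, n_boot = 40, seed = 1)
  f_large <- fit_detection(tk_large, n_boot = 40, seed = 1)
  w_small <- with(f_small$curve[f_small$curve$age == 20, ], hi95 - lo95)
  w_large <- with(f_large$curve[f_large$curve$age == 20, ], hi95 - lo95)
  expect_gt(w_small, w_large)
})

test_that("duplicating every track leaves the point estimates unchanged", {
  tk <- gen_tracks(n_tracks = 60, seed = 13)
  tk2 <- rbind(tk, transform(tk, track_id = paste0(track_id, "b")))
  f1 <- fit_detection(tk, n_boot = 0)
  f2 <- fit_detection(tk2, n_boot = 0)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-6)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-6)
  expect_equal(f1$phi, f2$phi, tolerance = 1e-3)
})

test_that("degenerate detection data are flagged", {
  tk <- gen_tracks(n_tracks = 20, seed = 3)
  tk$detected <- 1L
  expect_error(fit_detection(tk, n_boot = 0), "separation")
  tk$detected <- 0L
  expect_error(fit_detection(tk, n_boot = 0), "separation")
  # nonnegative slope reported as non-finite half-life with a warning
  tk2 <- gen_tracks(n_tracks = 80, intercept = 0.3, slope = 0.0, seed = 9)
  f <- suppressWarnings(fit_detection(tk2, n_boot = 0))
  if (f$slope >= 0) expect_true(is.na(f$A))
})

test_that("glmmPQL (conditional model) agrees with the GEE in slope sign", {
  skip_if_not_installed("MASS")
  tk <- gen_tracks(n_tracks = 150, seed = 17)
  tk$sf <- factor(tk$season)
  g <- suppressWarnings(MASS::glmmPQL(
    detected ~ age_days + sf, random = ~ 1 | track_id,
    correlation = nlme::corAR1(), family = binomial, data = tk,
    verbose = FALSE))
  fit <- fit_detection(tk, n_boot = 0)
  expect_lt(nlme::fixef(g)[["age_days"]], 0)
  expect_lt(fit$slope, 0)
})

test_that("auto count types resolve by the half-life rule", {
  sv <- data.frame(islet_id = "I1", season = 2020, day = c(30, 45, 80),
                   n = c(4, 2, 5), window_nights = c(30, 15, 35),
                   count_type = c("auto", "auto", "auto"),
                   n_max = NA_integer_)
  out <- assign_count_types(sv, S = 3.04, A = 22.23)
  expect_equal(out$count_type, c("minimum", "exact_sum", "minimum"))
  expect_true(all(out$n_max[out$count_type == "minimum"] >=
                    out$n[out$count_type == "minimum"]))
  # perfect detection: everything exact
  out2 <- assign_count_types(sv, S = 3, A = Inf)
  expect_true(all(out2$count_type == "exact_sum"))
  # explicit types are never overridden
  sv$count_type <- c("exact_sum", "minimum", "exact_sum")
  sv$n_max <- c(NA, 10L, NA)
  expect_identical(assign_count_types(sv, 3.04, 22.23)$count_type,
                   sv$count_type)
})
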