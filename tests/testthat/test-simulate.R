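test_that("depositions honour the curve support and the seed", {
  cfg <- small_config(seed = 4)
  led <- simulate_depositions(cfg, seed = 4)
  # PMin = 0: no nests outside [B, E] in any cell
  for (key in names(led$nightly)) {
    season <- as.integer(sub(".*\\|", "", key))
    si <- match(season, cfg$seasons)
    B <- cfg$P[si] - cfg$LengthB[si]; E <- cfg$P[si] + cfg$LengthE[si]
    x <- led$nightly[[key]]
    out <- setdiff(seq_along(x), floor(B):ceiling(E))
    expect_true(all(x[out] == 0))
    expect_equal(sum(x), led$totals$total[paste(led$totals$islet_id,
                                                led$totals$season,
                                                sep = "|") == key])
  }
  led2 <- simulate_depositions(cfg, seed = 4)
  expect_identical(led$nightly, led2$nightly)
  expect_false(identical(led$nightly,
                         simulate_depositions(cfg, seed = 5)$nightly))
})

test_that("mean simulated totals match the analytic curve sum", {
  cfg <- simulation_config(n_a = 1, n_b = 0, seasons = 2020, P = 91,
                           Max0 = 1, multiplier_sdlog = 0, seed = 1)
  R <- season_total_expected(phenology_shape(91, 58, 87),
                             phenology_scale(cfg$Max0, 0), 365)
  tot <- vapply(1:200, function(s) {
    simulate_depositions(cfg, seed = s)$totals$total
  }, numeric(1))
  se <- sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - R), 3 * se)
})

test_that("NB dispersion inflates the variance of nightly counts", {
  cfg_p <- simulation_config(n_a = 1, n_b = 0, seasons = 2020, Max0 = 3,
                             multiplier_sdlog = 0, seed = 2)
  cfg_nb <- simulation_config(n_a = 1, n_b = 0, seasons = 2020, Max0 = 3,
                              multiplier_sdlog = 0, dispersion = "nb",
                              k = 0.8, seed = 2)
  v <- function(cfg) var(vapply(1:150, function(s) {
    simulate_depositions(cfg, seed = s)$totals$total
  }, numeric(1)))
  expect_gt(v(cfg_nb), 1.5 * v(cfg_p))
})

test_that("surveys respect the A/B design and never exceed the ledger", {
  cfg <- simulation_config(seed = 6)
  sim <- simulate_rookery(cfg, seed = 6, make_tracks = FALSE)
  sv <- sim$surveys
  for (season in cfg$seasons) {
    nb <- table(sv$islet_id[sv$season == season])
    b_islets <- cfg$islets[cfg$set == "B"]
    expect_true(all(nb[b_islets] == 2L))
    expect_true(all(nb[cfg$islets[cfg$set == "A"]] == cfg$n_surveys_a))
  }
  # gaps within the stated bounds
  for (cell in unique(paste(sv$islet_id, sv$season))) {
    d <- sv$day[paste(sv$islet_id, sv$season) == cell]
    if (length(d) > 1) {
      expect_true(all(diff(sort(d)) >= cfg$gap_range[1] &
                        diff(sort(d)) <= cfg$gap_range[2]))
    }
  }
  # thinning consistency: a window's count never exceeds the deposited sum
  for (i in seq_len(nrow(sv))) {
    x <- sim$ledger$nightly[[paste(sv$islet_id[i], sv$season[i], sep = "|")]]
    nights <- (sv$day[i] - sv$window_nights[i] + 1L):sv$day[i]
    expect_lte(sv$n[i], sum(x[nights]))
  }
})

test_that("perfect detection with tiling surveys recovers ledger totals", {
  cfg <- simulation_config(n_a = 2, n_b = 0, seasons = 2020, P = 91,
                           Max0 = 1.5, multiplier_sdlog = 0,
                           detection = list(S = 3, A = Inf, phi = 0.5,
                                            false_resight = 0),
                           gap_range = c(7, 7), n_surveys_a = 50,
                           first_window_a = c(21, 21), seed = 8)
  sim <- simulate_rookery(cfg, seed = 8, make_tracks = FALSE)
  sums <- aggregate(n ~ islet_id, sim$surveys, sum)
  led <- sim$ledger$totals
  expect_equal(sums$n[match(led$islet_id, sums$islet_id)], led$total)
})

test_that("detection thinning at the half-life leaves about half the nests", {
  set.seed(3)
  n <- 3000
  seen <- rbinom(n, 1, detection_probability(22, S = 3, A = 22))
  expect_lt(abs(mean(seen) - 0.5), 0.05)
  # generator-level check: fraction detected in a window whose ages sit at
  # the half-life
  cfg <- simulation_config(n_a = 1, n_b = 0, seasons = 2020, Max0 = 4,
                           multiplier_sdlog = 0,
                           detection = list(S = 3, A = 22, phi = 0.5,
                                            false_resight = 0.01), seed = 9)
  sim <- simulate_rookery(cfg, seed = 9, make_tracks = FALSE)
  sv <- sim$surveys
  led <- sim$ledger$nightly[["A01|2020"]]
  # pooled over windows: observed / deposited should reflect mean d < 1
  dep <- vapply(seq_len(nrow(sv)), function(i) {
    sum(led[(sv$day[i] - sv$window_nights[i] + 1L):sv$day[i]])
  }, numeric(1))
  expect_lt(sum(sv$n), sum(dep))
  expect_gt(sum(sv$n), 0.3 * sum(dep))
})

test_that("track trajectories start detected and rarely resight after loss", {
  cfg <- simulation_config(n_a = 4, n_b = 0, seasons = 2020:2021, Max0 = 1,
                           multiplier_sdlog = 0.3,
                           detection = list(S = 3, A = 22, phi = 0.47,
                                            false_resight = 0.01), seed = 10)
  sim <- simulate_rookery(cfg, seed = 10)
  tk <- sim$tracks
  expect_gt(nrow(tk), 50)
  firsts <- tk[!duplicated(tk$track_id), ]
  expect_true(all(firsts$detected == 1L))
  expect_true(all(firsts$age_days == 0L))
  # 0 -> 1 transitions after a confirmed loss bounded by the false-resight
  # rate (with binomial slack)
  n01 <- 0L; nafter0 <- 0L
  for (id in unique(tk$track_id)) {
    d <- tk$detected[tk$track_id == id]
    if (length(d) < 2) next
    lost <- cummax(1L - d)
    after <- which(lost[-length(d)] == 1L) + 1L
    nafter0 <- nafter0 + length(after)
    n01 <- n01 + sum(d[after] == 1L)
  }
  expect_lte(n01 / max(nafter0, 1), 0.03)
})

test_that("fixtures round-trip through the package readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_rookery(small_config(seed = 15))
  paths <- write_fixtures(sim, dir)
  expect_true(all(file.exists(paths)))
  sv <- read_surveys(file.path(dir, "surveys.csv"))
  expect_equal(nrow(sv), nrow(sim$surveys))
  key <- function(d) paste(d$islet_id, d$season, d$day)
  m <- match(key(sim$surveys), key(sv))
  expect_false(anyNA(m))
  expect_equal(sv$n[m], sim$surveys$n)
  expect_equal(sv$window_nights[m], sim$surveys$window_nights)
  expect_equal(sv$count_type[m], sim$surveys$count_type)
  tk <- read_tracks(file.path(dir, "tracks.csv"))
  expect_equal(nrow(tk), nrow(sim$tracks))
  expect_equal(sort(unique(tk$age_days)), sort(unique(sim$tracks$age_days)))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$season_totals$total, sim$ledger$season_totals$total)
  expect_equal(length(truth$cell_totals$islet_id),
               5L * 2L)  # islets x seasons of the small config
})
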