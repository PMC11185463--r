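#' Configuration of a synthetic rookery
#'
#' The default stated world mirrors the monitored rookery: 28 coral islets
#' split into an A-set of 12 (repeat surveys spanning the season at
#' two-to-three week spacing; default 8 visits per season, a realistic
#' field effort for such programs) and a B-set of 16 (two surveys around
#' the peak), six
#' seasons, nightly nest deposition from the piecewise-cosine curve with
#' Poisson noise, track persistence with half-life `A` days and AR1
#' within-track dependence. Per-season peaks and lengths default to the
#' fitted field values (peaks drifting from late December to mid-December,
#' LengthB 58 and LengthE 87 days, season length 145); the baseline nightly
#' peak mean 0.13 with log-normal per-islet multipliers (sdlog 1) puts the
#' mean rookery total near 437 nests per season.
#'
#' @param n_a,n_b numbers of A-set and B-set islets.
#' @param seasons integer vector of season start years.
#' @param P,LengthB,LengthE,F,PMin per-season shape truth (recycled).
#' @param Max0 per-season baseline peak height (mean nests/night, recycled).
#' @param multiplier_sdlog sdlog of the per-islet log-normal `Max`
#'   multipliers (constant across seasons for a given islet).
#' @param dispersion `"poisson"` or `"nb"`; `k` used only for `"nb"`.
#' @param k NB aggregation parameter of the deposition noise.
#' @param detection list with `S`, `A` (use `A = Inf` for perfect
#'   detection), `phi` (latent AR1 coefficient of track trajectories) and
#'   `false_resight` (probability a confirmedly lost track is seen again).
#' @param gap_range survey-gap bounds in days (uniform jitter).
#' @param n_surveys_a surveys per A-set islet-season.
#' @param first_window_a earliest/latest ordinal day of the first A-set
#'   survey (uniform).
#' @param seed seed used for islet-multiplier draws and as the simulation
#'   default.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_a = 12, n_b = 16, seasons = 2017:2022,
                              P = c(91, 93, 89, 88, 85, 75),
                              LengthB = 58, LengthE = 87, F = 0, PMin = 0,
                              Max0 = 0.13, multiplier_sdlog = 1,
                              dispersion = c("poisson", "nb"), k = 10,
                              detection = list(S = 3.04, A = 22.23,
                                               phi = 0.47,
                                               false_resight = 0.01),
                              gap_range = c(14, 21), n_surveys_a = 8,
                              first_window_a = c(15, 25), seed = 1L) {
  dispersion <- match.arg(dispersion)
  S <- length(seasons)
  islets <- c(sprintf("A%02d", seq_len(n_a)), sprintf("B%02d", seq_len(n_b)))
  set.seed(seed)
  mult <- stats::setNames(exp(stats::rnorm(n_a + n_b, 0, multiplier_sdlog)),
                          islets)
  structure(list(
    islets = islets, set = c(rep("A", n_a), rep("B", n_b)),
    seasons = seasons,
    P = rep_len(P, S), LengthB = rep_len(LengthB, S),
    LengthE = rep_len(LengthE, S), F = rep_len(F, S),
    PMin = rep_len(PMin, S), Max0 = rep_len(Max0, S),
    multipliers = mult, dispersion = dispersion, k = k,
    detection = detection, gap_range = gap_range,
    n_surveys_a = n_surveys_a, first_window_a = first_window_a,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Simulate nightly nest depositions with known ground truth
#'
#' Draws, for every islet-season, one count per night from the seasonal
#' curve (Poisson, or NB with aggregation `k`), and records the truth
#' ledger used to score downstream recovery.
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed (default: the config's).
#' @return list of class `truth_ledger`: `nightly` (named list of integer
#'   vectors per `islet|season`), `totals` (data.frame `islet_id`,
#'   `season`, `set`, `Max`, `total`), `season_totals`, `config`.
#' @export
simulate_depositions <- function(config, seed = config$seed) {
  set.seed(seed)
  nightly <- list()
  rows <- list()
  for (si in seq_along(config$seasons)) {
    season <- config$seasons[si]
    nd <- season_ndays(season)
    u <- unit_nightly(seq_len(nd), config$P[si], config$LengthB[si],
                      config$LengthE[si], config$F[si], config$PMin[si])
    for (isl in config$islets) {
      Max <- config$Max0[si] * config$multipliers[[isl]]
      mu <- pmax(Max * u, 0)
      x <- if (config$dispersion == "poisson") {
        stats::rpois(nd, mu)
      } else {
        stats::rnbinom(nd, size = config$k, mu = pmax(mu, 1e-12))
      }
      key <- paste(isl, season, sep = "|")
      nightly[[key]] <- x
      rows[[key]] <- data.frame(
        islet_id = isl, season = season,
        set = config$set[match(isl, config$islets)],
        Max = Max, total = sum(x), stringsAsFactors = FALSE)
    }
  }
  totals <- do.call(rbind, rows)
  rownames(totals) <- NULL
  season_totals <- stats::aggregate(total ~ season, totals, sum)
  structure(list(nightly = nightly, totals = totals,
                 season_totals = season_totals, config = config),
            class = "truth_ledger")
}

# one AR1 latent-Gaussian detection trajectory thresholded to marginal d_a;
# after a confirmed loss the track stays lost except with probability
# `false_resight` per later look.
ar1_detect <- function(ages, S, A, phi, false_resight) {
  n <- length(ages)
  if (!is.finite(A)) return(rep(1L, n))
  z <- numeric(n)
  z[1] <- stats::rnorm(1)
  if (n > 1) {
    for (j in 2:n) z[j] <- phi * z[j - 1] + sqrt(1 - phi^2) * stats::rnorm(1)
  }
  d <- detection_probability(ages, S, A)
  det <- as.integer(z < stats::qnorm(d))
  lost <- FALSE
  for (j in seq_len(n)) {
    if (lost && det[j] == 1L && stats::runif(1) > false_resight) det[j] <- 0L
    if (det[j] == 0L) lost <- TRUE
  }
  det
}

#' Simulate beach surveys and marked-track follow-ups from a truth ledger
#'
#' Lays out the A-set/B-set survey calendar (A: `n_surveys_a` visits with
#' 14-21-day gaps spanning the season; B: two visits 14-21 days apart
#' centered on the true peak), thins each window's deposited nests by the
#' age-dependent detection probability, and emits both the survey count
#' table (with the default censoring rule applied using the true detection
#' parameters) and a marked-nest detectability table: nests first detected
#' on an A-set survey are re-checked on each later visit with an AR1
#' detection trajectory.
#'
#' @param ledger a [simulate_depositions()] result.
#' @param seed RNG seed.
#' @param make_tracks emit the marked-track follow-up table? (Skipping it
#'   speeds up large simulation studies that only use the counts.)
#' @return list of class `rookery_sim`: `surveys` (survey table),
#'   `tracks` (track-observation table), `ledger`.
#' @export
simulate_surveys <- function(ledger, seed = ledger$config$seed + 1L,
                             make_tracks = TRUE) {
  config <- ledger$config
  set.seed(seed)
  det <- config$detection
  sv <- list(); tr <- list()
  track_no <- 0L
  for (si in seq_along(config$seasons)) {
    season <- config$seasons[si]
    nd <- season_ndays(season)
    for (ii in seq_along(config$islets)) {
      isl <- config$islets[ii]
      is_a <- config$set[ii] == "A"
      if (is_a) {
        d1 <- round(stats::runif(1, config$first_window_a[1],
                                 config$first_window_a[2]))
        gaps <- round(stats::runif(config$n_surveys_a - 1,
                                   config$gap_range[1], config$gap_range[2]))
        days <- cumsum(c(d1, gaps))
      } else {
        gap <- round(stats::runif(1, config$gap_range[1], config$gap_range[2]))
        d1 <- round(config$P[si]) - gap %/% 2L
        days <- c(d1, d1 + gap)
      }
      days <- days[days >= 1 & days <= nd]
      x <- ledger$nightly[[paste(isl, season, sep = "|")]]
      prev <- c(0L, days[-length(days)])
      first <- TRUE
      for (w in seq_along(days)) {
        d <- days[w]
        lo <- if (first) max(d - 30L + 1L, 1L) else prev[w] + 1L
        nights <- lo:d
        dep <- x[nights]
        ages <- d - nights
        pdet <- detection_probability(ages, det$S,
                                      if (is.finite(det$A)) det$A else Inf)
        if (!is.finite(det$A)) pdet <- rep(1, length(ages))
        seen_per_night <- stats::rbinom(length(dep), dep, pdet)
        n_obs <- sum(seen_per_night)
        sv[[length(sv) + 1L]] <- data.frame(
          islet_id = isl, season = season, day = d,
          window_nights = length(nights), n = n_obs,
          count_type = "auto", n_max = NA_integer_,
          stringsAsFactors = FALSE)
        # mark newly seen nests on A-set islets and follow them up
        if (make_tracks && is_a && n_obs > 0 && w < length(days)) {
          dep_nights <- rep(nights, seen_per_night)
          for (t0 in dep_nights) {
            track_no <- track_no + 1L
            later <- days[(w + 1L):length(days)]
            obs_days <- c(d, later)
            ages_tr <- obs_days - d    # age since first detection
            dtr <- ar1_detect(ages_tr, det$S,
                              if (is.finite(det$A)) det$A else Inf,
                              det$phi, det$false_resight)
            dtr[1L] <- 1L
            tr[[length(tr) + 1L]] <- data.frame(
              track_id = sprintf("T%05d", track_no), season = season,
              first_seen_day = d, obs_day = obs_days,
              age_days = ages_tr, detected = dtr,
              stringsAsFactors = FALSE)
          }
        }
        first <- FALSE
      }
    }
  }
  surveys <- do.call(rbind, sv)
  rownames(surveys) <- NULL
  surveys <- assign_count_types(surveys, det$S,
                                if (is.finite(det$A)) det$A else Inf)
  tracks <- if (length(tr) > 0) do.call(rbind, tr) else
    data.frame(track_id = character(), season = integer(),
               first_seen_day = integer(), obs_day = integer(),
               age_days = integer(), detected = integer())
  rownames(tracks) <- NULL
  structure(list(surveys = surveys, tracks = tracks, ledger = ledger),
            class = "rookery_sim")
}

#' One-call synthetic rookery
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed driving both depositions and surveys.
#' @param make_tracks emit the marked-track table? See [simulate_surveys()].
#' @return a `rookery_sim` (see [simulate_surveys()]).
#' @export
simulate_rookery <- function(config = simulation_config(), seed = config$seed,
                             make_tracks = TRUE) {
  ledger <- simulate_depositions(config, seed = seed)
  simulate_surveys(ledger, seed = seed + 1L, make_tracks = make_tracks)
}

#' Write a simulated rookery as plain-text fixtures
#'
#' Emits `surveys.csv` (islet_id, date, n_new_nests, count_type, n_max),
#' `tracks.csv` (track_id, season, first_seen, obs_date, detected) and
#' `truth.json` (per-season and per-cell true totals plus the generating
#' parameters). The files round-trip through [read_surveys()] and
#' [read_tracks()].
#'
#' @param sim a `rookery_sim`.
#' @param directory output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_fixtures <- function(sim, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory ", directory)
  sv <- sim$surveys
  out_sv <- data.frame(
    islet_id = sv$islet_id,
    date = format(from_ordinal(sv$day, sv$season)),
    n_new_nests = sv$n,
    count_type = sv$count_type,
    n_max = sv$n_max)
  p1 <- file.path(directory, "surveys.csv")
  utils::write.csv(out_sv, p1, row.names = FALSE, quote = FALSE)
  tk <- sim$tracks
  out_tk <- data.frame(
    track_id = tk$track_id,
    season = season_label(tk$season),
    first_seen = format(from_ordinal(tk$first_seen_day, tk$season)),
    obs_date = format(from_ordinal(tk$obs_day, tk$season)),
    detected = tk$detected)
  p2 <- file.path(directory, "tracks.csv")
  utils::write.csv(out_tk, p2, row.names = FALSE, quote = FALSE)
  cfg <- sim$ledger$config
  truth <- list(
    season_totals = sim$ledger$season_totals,
    cell_totals = sim$ledger$totals,
    shape = list(P = cfg$P, LengthB = cfg$LengthB, LengthE = cfg$LengthE,
                 F = cfg$F, PMin = cfg$PMin),
    Max0 = cfg$Max0, multipliers = as.list(cfg$multipliers),
    detection = cfg$detection, seed = cfg$seed)
  p3 <- file.path(directory, "truth.json")
  jsonlite::write_json(truth, p3, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(surveys = p1, tracks = p2, truth = p3))
}
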