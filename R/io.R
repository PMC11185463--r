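#' Read a survey-count CSV
#'
#' Expected columns: `islet_id`, `date` (ISO-8601), `n_new_nests`,
#' `count_type` (`exact_sum`, `minimum` or `auto`), optional `n_max`.
#' Seasons are derived from the October-anchored window, dates converted to
#' ordinal day-of-season, and survey windows computed from consecutive
#' surveys of each islet-season: a survey's count covers the half-open
#' night interval since the previous survey; the first survey of a season
#' covers at most `window_cap` nights.
#'
#' @param path CSV file path.
#' @param window_cap nights covered by the first survey of an islet-season
#'   (capped at the ordinal day itself).
#' @return survey table: `islet_id`, `season`, `day`, `n`, `window_nights`,
#'   `count_type`, `n_max`.
#' @export
read_surveys <- function(path, window_cap = 30L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("islet_id", "date", "n_new_nests", "count_type")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$n_max)) df$n_max <- NA_integer_
  lines <- seq_len(nrow(df)) + 1L  # header is line 1
  date <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(date)) {
    stop("malformed date(s) at line(s): ",
         paste(lines[is.na(date)], collapse = ", "))
  }
  if (any(df$n_new_nests < 0 | df$n_new_nests != floor(df$n_new_nests))) {
    bad <- df$n_new_nests < 0 | df$n_new_nests != floor(df$n_new_nests)
    stop("invalid counts at line(s): ", paste(lines[bad], collapse = ", "))
  }
  bad_type <- !df$count_type %in% c("exact_sum", "minimum", "auto")
  if (any(bad_type)) {
    stop("unknown count_type at line(s): ",
         paste(lines[bad_type], collapse = ", "))
  }
  season <- infer_season(date)
  dup <- duplicated(data.frame(df$islet_id, date)) |
    duplicated(data.frame(df$islet_id, date), fromLast = TRUE)
  if (any(dup)) {
    stop("duplicate islet-date rows at lines: ",
         paste(lines[dup], collapse = ", "))
  }
  day <- to_ordinal(date, season)
  out <- data.frame(islet_id = df$islet_id, season = season, day = day,
                    n = as.integer(df$n_new_nests),
                    count_type = df$count_type,
                    n_max = as.integer(df$n_max),
                    stringsAsFactors = FALSE)
  out <- out[order(out$islet_id, out$season, out$day), ]
  key <- paste(out$islet_id, out$season, sep = "|")
  wn <- integer(nrow(out))
  for (cell in unique(key)) {
    i <- which(key == cell)
    d <- out$day[i]
    wn[i] <- c(min(window_cap, d[1L]), diff(d))
  }
  out$window_nights <- wn
  rownames(out) <- NULL
  out[, c("islet_id", "season", "day", "n", "window_nights", "count_type",
          "n_max")]
}

#' Read a track-detectability CSV
#'
#' Expected columns: `track_id`, `season` (label like `2019-20` or a start
#' year), `first_seen` (ISO date), `obs_date` (ISO date), `detected` (0/1).
#' Track age in days is computed as `obs_date - first_seen`.
#'
#' @param path CSV file path.
#' @return track table: `track_id`, `season`, `age_days`, `detected`.
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("track_id", "season", "first_seen", "obs_date", "detected")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  first_seen <- as.Date(df$first_seen)
  obs_date <- as.Date(df$obs_date)
  if (anyNA(first_seen) || anyNA(obs_date)) stop("malformed dates in track file")
  age <- as.integer(obs_date - first_seen)
  if (any(age < 0)) stop("obs_date before first_seen for some rows")
  if (!all(df$detected %in% c(0L, 1L))) stop("detected must be 0/1")
  out <- data.frame(track_id = df$track_id,
                    season = sub("-.*$", "", as.character(df$season)),
                    age_days = age, detected = as.integer(df$detected),
                    stringsAsFactors = FALSE)
  out[order(out$track_id, out$age_days), ]
}
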