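#' Phenology shape parameters
#'
#' The seasonal curve of mean nightly nesting activity is piecewise: a flat
#' off-season floor, a cosine half-ramp from the season beginning `B` up to
#' the peak, an optional flat top of half-width `F` around the peak ordinal
#' date `P`, and a cosine half-ramp down to the season end `E`. Rather than
#' `B` and `E` the model is parameterised by `LengthB = P - B > 0` and
#' `LengthE = E - P > 0`, which enforces `B < P < E`.
#'
#' @param P ordinal date (day-of-season) of the nesting peak.
#' @param LengthB days from season beginning to peak (> 0).
#' @param LengthE days from peak to season end (> 0).
#' @param F half-width in days of the flat top around `P` (>= 0; default 0).
#' @return a list of class `phenology_shape`.
#' @export
phenology_shape <- function(P, LengthB, LengthE, F = 0) {
  if (LengthB <= 0 || LengthE <= 0) {
    stop("LengthB and LengthE must be positive")
  }
  if (F < 0 || F > min(LengthB, LengthE)) {
    stop("F must satisfy 0 <= F <= min(LengthB, LengthE)")
  }
  structure(list(P = P, LengthB = LengthB, LengthE = LengthE, F = F),
            class = "phenology_shape")
}

#' Phenology scale parameters
#'
#' @param Max mean nests per night at the peak (>= 0).
#' @param PMin off-season nightly mean relative to `Max` (>= 0, usually << 1).
#' @return a list of class `phenology_scale`.
#' @export
phenology_scale <- function(Max, PMin = 0) {
  if (Max < 0 || PMin < 0) stop("Max and PMin must be nonnegative")
  structure(list(Max = Max, PMin = PMin), class = "phenology_scale")
}

# Scalar-parameter fast path of the unit curve (hot loop of the fitter and
# sampler); same piecewise definition as unit_nightly below.
unit_curve_scalar <- function(t, P, LB, LE, F, PMin) {
  B <- P - LB
  E <- P + LE
  u <- rep.int(PMin, length(t))
  i <- which(t >= B & t < (P - F))
  if (length(i)) {
    u[i] <- (1 + cos(pi * (P - F - t[i]) / (P - F - B))) / 2 * (1 - PMin) + PMin
  }
  i <- which(t >= (P - F) & t <= (P + F))
  if (length(i)) u[i] <- 1
  i <- which(t > (P + F) & t <= E)
  if (length(i)) {
    u[i] <- (1 + cos(pi * (t[i] - (P + F)) / (E - (P + F)))) / 2 * (1 - PMin) + PMin
  }
  u
}

# Unit-height seasonal curve: value in [PMin, 1], multiplied by Max to get
# the nightly mean. Vectorised over t AND over the parameters (recycled to
# the length of t). Continuous at B, P-F, P+F and E.
unit_nightly <- function(t, P, LengthB, LengthE, F = 0, PMin = 0) {
  nt <- length(t)
  P <- rep_len(P, nt); LengthB <- rep_len(LengthB, nt)
  LengthE <- rep_len(LengthE, nt); F <- rep_len(F, nt)
  PMin <- rep_len(PMin, nt)
  B <- P - LengthB
  E <- P + LengthE
  u <- PMin
  ramp_up <- t >= B & t < (P - F)
  if (any(ramp_up)) {
    i <- which(ramp_up)
    frac <- (1 + cos(pi * (P[i] - F[i] - t[i]) / (P[i] - F[i] - B[i]))) / 2
    u[i] <- frac * (1 - PMin[i]) + PMin[i]
  }
  top <- t >= (P - F) & t <= (P + F)
  u[top] <- 1
  ramp_dn <- t > (P + F) & t <= E
  if (any(ramp_dn)) {
    i <- which(ramp_dn)
    frac <- (1 + cos(pi * (t[i] - (P[i] + F[i])) / (E[i] - (P[i] + F[i])))) / 2
    u[i] <- frac * (1 - PMin[i]) + PMin[i]
  }
  u
}

#' Expected number of nests deposited per night
#'
#' Evaluates the piecewise-cosine seasonal curve at ordinal date(s) `t`.
#' The returned mean is floored at `1e-9` so that count likelihoods remain
#' defined when the curve is exactly zero.
#'
#' @param t ordinal date(s) within the season (numeric vector).
#' @param shape a [phenology_shape()].
#' @param scale a [phenology_scale()].
#' @return numeric vector of mean nests per night.
#' @export
expected_nightly <- function(t, shape, scale) {
  u <- unit_nightly(t, shape$P, shape$LengthB, shape$LengthE, shape$F,
                    scale$PMin)
  pmax(scale$Max * u, 1e-9)
}

#' Season calendar dates implied by a fitted shape
#'
#' Converts the shape parameters to calendar dates for the beginning `B`,
#' peak `P` and end `E` of the nesting season, plus the season length in
#' days (`LengthB + LengthE`).
#'
#' @param shape a [phenology_shape()].
#' @param season_start_year calendar year of the season's opening October.
#' @return data.frame with columns `beginning`, `peak`, `end` (Date) and
#'   `length_days`.
#' @export
season_dates <- function(shape, season_start_year) {
  B <- shape$P - shape$LengthB
  E <- shape$P + shape$LengthE
  data.frame(
    season = season_label(season_start_year),
    beginning = from_ordinal(round(B), season_start_year),
    peak = from_ordinal(round(shape$P), season_start_year),
    end = from_ordinal(round(E), season_start_year),
    length_days = round(shape$LengthB + shape$LengthE)
  )
}
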