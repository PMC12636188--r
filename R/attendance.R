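# Colony attendance and breeding phenology from immersion (wet/dry) and
# light data. Days are half-open UTC calendar days [00:00, 24:00).

#' Reduce raw immersion records to 10-minute wet fractions
#'
#' Accepts either ready-made block records (columns `block_start`,
#' `wet_fraction`) which are validated and passed through, or wet/dry
#' state-change records (columns `timestamp`, `state` in "wet"/"dry")
#' which are integrated exactly over half-open 10-minute block boundaries.
#'
#' @param raw Data frame as above, time-ordered.
#' @param block_min Block length in minutes (default 10).
#' @return Data frame with `block_start` (POSIXct) and `wet_fraction`.
#' @export
reduce_immersion <- function(raw, block_min = 10) {
  block_s <- block_min * 60
  if (all(c("block_start", "wet_fraction") %in% names(raw))) {
    if (any(raw$wet_fraction < 0 | raw$wet_fraction > 1))
      stop("reduce_immersion: wet fractions outside [0, 1]")
    if (anyDuplicated(raw$block_start))
      stop("reduce_immersion: overlapping blocks")
    return(raw[order(raw$block_start), c("block_start", "wet_fraction")])
  }
  stopifnot(all(c("timestamp", "state") %in% names(raw)))
  ts <- as.numeric(as.POSIXct(raw$timestamp, tz = "UTC"))
  if (is.unsorted(ts)) stop("reduce_immersion: records not time-ordered")
  st <- raw$state
  t0 <- floor(ts[1] / block_s) * block_s
  t1 <- ceiling(ts[length(ts)] / block_s) * block_s
  starts <- seq(t0, t1 - block_s, by = block_s)
  wet <- numeric(length(starts))
  # Integrate wet intervals [change to wet, next change) over each block.
  for (i in seq_along(ts)) {
    if (st[i] != "wet") next
    a <- ts[i]
    b <- if (i < length(ts)) ts[i + 1] else t1
    if (b <= a) next
    j0 <- max(1L, floor((a - t0) / block_s) + 1L)
    j1 <- min(length(starts), floor((b - t0 - 1e-9) / block_s) + 1L)
    for (j in j0:j1) {
      lo <- max(a, starts[j]); hi <- min(b, starts[j] + block_s)
      if (hi > lo) wet[j] <- wet[j] + (hi - lo)
    }
  }
  data.frame(block_start = as.POSIXct(starts, tz = "UTC",
                                      origin = "1970-01-01"),
             wet_fraction = wet / block_s)
}

#' Classify colony-attendance days
#'
#' A UTC day is classified as spent at the colony if and only if the
#' logger was dry for strictly more than `dry_threshold` of that 24 h
#' period. Days without complete block coverage are flagged, not
#' classified.
#'
#' @param immersion Data frame from [reduce_immersion()].
#' @param dry_threshold Dry fraction that must be strictly exceeded
#'   (default 0.95).
#' @param block_min Block length in minutes.
#' @return Data frame with `day` (Date), `dry_fraction`, `colony`
#'   (logical, `NA` for incomplete days), `complete`.
#' @export
classify_colony_days <- function(immersion, dry_threshold = 0.95,
                                 block_min = 10) {
  day <- as.Date(immersion$block_start, tz = "UTC")
  agg <- stats::aggregate(immersion$wet_fraction, by = list(day = day),
                          FUN = function(v) c(mean(v), length(v)))
  n_per_day <- 24 * 60 / block_min
  dry <- 1 - agg$x[, 1]
  complete <- agg$x[, 2] == n_per_day
  data.frame(day = agg$day, dry_fraction = dry,
             colony = ifelse(complete, dry > dry_threshold, NA),
             complete = complete)
}

#' Detect nest bouts from shading and attendance
#'
#' A nest bout is a maximal run of consecutive colony-attendance days on
#' which the light sensor was shaded (light below the day threshold) for
#' at least `shading_fraction` of the day's samples, indicating the bird
#' was inside the nest cavity.
#'
#' @param light Light series data frame (`timestamp`, `light`).
#' @param colony_days Data frame from [classify_colony_days()].
#' @param shading_fraction Minimum shaded fraction of the day
#'   (default 0.7).
#' @param day_threshold Light level below which a sample counts as shaded.
#' @return Data frame of bouts: `start_day`, `end_day`, `duration_d`.
#' @export
detect_nest_bouts <- function(light, colony_days, shading_fraction = 0.7,
                              day_threshold = 5) {
  lday <- as.Date(light$timestamp, tz = "UTC")
  sh <- stats::aggregate(light$light < day_threshold, by = list(day = lday),
                         FUN = mean)
  shaded_days <- sh$day[sh$x >= shading_fraction]
  cd <- colony_days$day[!is.na(colony_days$colony) & colony_days$colony]
  nest_days <- sort(as.Date(intersect(as.character(shaded_days),
                                      as.character(cd))))
  if (length(nest_days) == 0L)
    return(data.frame(start_day = as.Date(character()),
                      end_day = as.Date(character()), duration_d = numeric()))
  brk <- c(0, which(diff(as.numeric(nest_days)) > 1), length(nest_days))
  out <- lapply(seq_len(length(brk) - 1L), function(i) {
    run <- nest_days[(brk[i] + 1L):brk[i + 1L]]
    data.frame(start_day = min(run), end_day = max(run),
               duration_d = as.numeric(max(run) - min(run)) + 1)
  })
  do.call(rbind, out)
}

#' Infer breeding phenology from nest bouts
#'
#' The first full nest day is the start of the first bout. Bouts separated
#' from the next by at least `exodus_gap_days` at-sea days split the
#' season into pre-laying bouts and incubation shifts; the pre-laying
#' exodus spans that gap. A bird whose nest shifts continue past 1 January
#' is taken to have hatched a chick; otherwise breeding is considered to
#' have failed at the end of the last recorded shift.
#'
#' @param bouts Data frame from [detect_nest_bouts()], ordered.
#' @param season_start_year Calendar year in which the season begins (the
#'   hatch rule uses 1 January of the following year).
#' @param exodus_gap_days Minimum at-sea gap identifying the pre-laying
#'   exodus (default 5).
#' @return A one-row data frame (class `ir_phenology`): `first_nest_day`,
#'   `n_prelaying_bouts`, `exodus_start`, `first_incubation_shift`,
#'   `outcome` ("hatched"/"failed"/"no_bouts"), `failure_date`.
#' @export
infer_phenology <- function(bouts, season_start_year,
                            exodus_gap_days = 5) {
  empty <- data.frame(first_nest_day = as.Date(NA),
                      n_prelaying_bouts = 0L,
                      exodus_start = as.Date(NA),
                      first_incubation_shift = as.Date(NA),
                      outcome = "no_bouts", failure_date = as.Date(NA),
                      stringsAsFactors = FALSE)
  class(empty) <- c("ir_phenology", "data.frame")
  if (nrow(bouts) == 0L) return(empty)
  bouts <- bouts[order(bouts$start_day), , drop = FALSE]
  gaps <- if (nrow(bouts) > 1L)
    as.numeric(bouts$start_day[-1] - bouts$end_day[-nrow(bouts)]) - 1
  else numeric(0)
  split_at <- which(gaps >= exodus_gap_days)
  first_split <- if (length(split_at) > 0L) split_at[1] else NA_integer_
  jan1 <- as.Date(sprintf("%d-01-01", season_start_year + 1))
  hatched <- any(bouts$start_day > jan1)
  out <- data.frame(
    first_nest_day = bouts$start_day[1],
    n_prelaying_bouts = if (is.na(first_split)) nrow(bouts)
                        else first_split,
    exodus_start = if (is.na(first_split)) as.Date(NA)
                   else bouts$end_day[first_split] + 1,
    first_incubation_shift = if (is.na(first_split)) as.Date(NA)
                             else bouts$start_day[first_split + 1L],
    outcome = if (hatched) "hatched" else "failed",
    failure_date = if (hatched) as.Date(NA)
                   else bouts$end_day[nrow(bouts)],
    stringsAsFactors = FALSE)
  class(out) <- c("ir_phenology", "data.frame")
  out
}
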