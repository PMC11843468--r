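#' Standard error of the mean
#'
#' Sample standard deviation (n - 1 denominator) divided by `sqrt(n)`.
#' Undefined (`NA`) for fewer than two values.
#'
#' @param values Numeric vector; `NA`s are dropped.
#' @return A single number, or `NA` when fewer than two values remain.
#' @examples
#' sem(c(1, 2, 3)) # 1/sqrt(3)
#' @export
sem <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) return(NA_real_)
  stats::sd(values) / sqrt(length(values))
}

#' Daily trip counts per queen
#'
#' Counts retained foraging trips per local calendar day. By default every
#' day in the closed span from a queen's first to last foraging date is a
#' row, days without trips counting as zero — the readers recorded
#' continuously, so an empty day is a real zero. `active_days_only = TRUE`
#' restricts to days with at least one trip (the alternative reading of a
#' "per-day" denominator).
#'
#' @param trips Retained trips (class FORAGING; see [summarize_queens()]).
#' @param config A [pipeline_config()]; supplies the local timezone.
#' @param active_days_only Drop zero-trip days from the span.
#' @return Data.frame `tag_id`, `nest_id`, `date`, `n_trips`.
#' @export
daily_trip_counts <- function(trips, config = pipeline_config(),
                              active_days_only = FALSE) {
  if (nrow(trips) == 0) {
    return(data.frame(tag_id = character(0), nest_id = character(0),
                      date = as.Date(character(0)), n_trips = integer(0)))
  }
  trips$date <- local_date(trips$exit_time, config$local_tz)
  pieces <- lapply(split(trips, trips$tag_id), function(tr) {
    days <- seq(min(tr$date), max(tr$date), by = "day")
    n <- as.integer(table(factor(as.character(tr$date),
                                 levels = as.character(days))))
    out <- data.frame(tag_id = tr$tag_id[1], nest_id = tr$nest_id[1],
                      date = days, n_trips = n, stringsAsFactors = FALSE)
    if (active_days_only) out <- out[out$n_trips > 0, , drop = FALSE]
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Per-queen foraging summaries
#'
#' One row per queen in the style of a study summary table: date range of
#' recorded foraging, number of trips, mean trip duration in minutes with
#' its s.e.m., and trips per day with its s.e.m. Only ordinary foraging
#' trips enter (micro-trips were removed upstream and extended trips —
#' longer than `foraging_max_h` — are excluded here, so outliers do not
#' skew the summaries). The trips/day denominator includes zero-trip
#' calendar days inside the foraging span unless `active_days_only`.
#'
#' @param trips Retained trips from [infer_trips()] (`$trips`).
#' @param config A [pipeline_config()].
#' @param active_days_only Passed to [daily_trip_counts()].
#' @return Data.frame, one row per `tag_id`: `first_date`, `last_date`,
#'   `n_trips`, `mean_duration_min`, `sem_duration_min`,
#'   `trips_per_day_mean`, `trips_per_day_sem`. s.e.m. columns are `NA`
#'   when fewer than two values contribute.
#' @export
summarize_queens <- function(trips, config = pipeline_config(),
                             active_days_only = FALSE) {
  foraging <- trips[trips$trip_class == "FORAGING", , drop = FALSE]
  if (nrow(foraging) == 0) {
    return(data.frame(tag_id = character(0), nest_id = character(0),
                      first_date = as.Date(character(0)),
                      last_date = as.Date(character(0)),
                      n_trips = integer(0), mean_duration_min = numeric(0),
                      sem_duration_min = numeric(0),
                      trips_per_day_mean = numeric(0),
                      trips_per_day_sem = numeric(0)))
  }
  daily <- daily_trip_counts(foraging, config, active_days_only)
  pieces <- lapply(split(foraging, foraging$tag_id), function(tr) {
    dmin <- tr$duration_s / 60
    dd <- daily[daily$tag_id == tr$tag_id[1], , drop = FALSE]
    data.frame(tag_id = tr$tag_id[1], nest_id = tr$nest_id[1],
               first_date = min(dd$date), last_date = max(dd$date),
               n_trips = nrow(tr),
               mean_duration_min = mean(dmin),
               sem_duration_min = sem(dmin),
               trips_per_day_mean = mean(dd$n_trips),
               trips_per_day_sem = sem(dd$n_trips),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Summary of extended overnight absences
#'
#' Queens occasionally remain outside the nest overnight. This summarizes
#' trips longer than the overnight threshold (default 8 h): how many, and
#' their mean duration in hours with its s.e.m.
#'
#' @param trips Retained trips from [infer_trips()].
#' @return List `n_overnight`, `mean_h`, `sem_h` (`NA` when undefined).
#' @export
extended_summary <- function(trips) {
  ov <- trips[trips$overnight_flag, , drop = FALSE]
  h <- ov$duration_s / 3600
  list(n_overnight = nrow(ov),
       mean_h = if (nrow(ov)) mean(h) else NA_real_,
       sem_h = sem(h))
}

#' Trimodal in-nest stay summary
#'
#' Partitions stays into the three duration classes (SHORT below 3 min, MID
#' up to 4 h, LONG above 4 h by default) and reports per-class counts and
#' mean durations. The trimodality reflects three behavioural modes:
#' brief unloading visits, ordinary between-trip nest work, and overnight
#' or multi-hour residence.
#'
#' @param stays Retained stays from [infer_trips()] (`$stays`).
#' @param config A [pipeline_config()]; supplies the class boundaries.
#' @return Data.frame with rows SHORT/MID/LONG: `n`, `mean_duration_s`,
#'   `sem_duration_s` (`NA` for empty classes).
#' @export
stay_mixture_summary <- function(stays, config = pipeline_config()) {
  cls <- factor(classify_stay(stays$duration_s, config),
                levels = c("SHORT", "MID", "LONG"))
  out <- data.frame(stay_class = levels(cls),
                    n = as.integer(table(cls)),
                    mean_duration_s = NA_real_, sem_duration_s = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(3)) {
    d <- stays$duration_s[!is.na(cls) & cls == out$stay_class[i]]
    if (length(d)) out$mean_duration_s[i] <- mean(d)
    out$sem_duration_s[i] <- sem(d)
  }
  out
}

#' Label trips and daily counts with foundress stage
#'
#' The early foundress stage is the first `stage_window_days` calendar days
#' of recorded foraging, defined only for queens who already had larvae in
#' the nest when tagged (brood stage YOUNG_LARVAE or MATURE_LARVAE); the
#' late stage is the last `stage_window_days` days of foraging, defined
#' only for queens who went on to produce adult workers (fate
#' WORKERS_NO_GYNES or GYNES). Only queens with both windows are kept for
#' stage modelling; queens whose foraging span is shorter than two windows
#' (the windows would overlap) are excluded with a flag.
#'
#' @param trips Retained trips from [infer_trips()]; `tag_id` must equal
#'   the `queen_id` of `queens`.
#' @param queens Queen metadata from [read_queens()].
#' @param config A [pipeline_config()].
#' @return List with `trips` (`queen_id`, `stage`, `date`, `duration_s`),
#'   `daily` (`queen_id`, `stage`, `date`, `n_trips`, zero days included),
#'   and `queens` (per-queen eligibility, inclusion and exclusion reason).
#' @export
stage_subsets <- function(trips, queens, config = pipeline_config()) {
  foraging <- trips[trips$trip_class == "FORAGING", , drop = FALSE]
  foraging$date <- local_date(foraging$exit_time, config$local_tz)
  w <- config$stage_window_days
  status <- data.frame(
    queen_id = queens$queen_id,
    early_eligible = queens$brood_stage_at_tagging %in%
      c("YOUNG_LARVAE", "MATURE_LARVAE"),
    late_eligible = queens$fate %in% c("WORKERS_NO_GYNES", "GYNES"),
    included = FALSE, reason = NA_character_, stringsAsFactors = FALSE)
  staged_trips <- NULL
  staged_daily <- NULL
  for (i in seq_len(nrow(status))) {
    q <- status$queen_id[i]
    tr <- foraging[foraging$tag_id == q, , drop = FALSE]
    if (nrow(tr) == 0) {
      status$reason[i] <- "NO_TRIPS"
      next
    }
    if (!status$early_eligible[i] || !status$late_eligible[i]) {
      status$reason[i] <- "MISSING_STAGE"
      next
    }
    first <- min(tr$date); last <- max(tr$date)
    if (as.integer(last - first) + 1L < 2L * w) {
      status$reason[i] <- "WINDOWS_OVERLAP"
      next
    }
    status$included[i] <- TRUE
    early_days <- seq(first, by = "day", length.out = w)
    late_days <- seq(last - w + 1L, by = "day", length.out = w)
    lab <- ifelse(tr$date %in% early_days, "EARLY",
                  ifelse(tr$date %in% late_days, "LATE", NA))
    keep <- !is.na(lab)
    staged_trips <- rbind(staged_trips, data.frame(
      queen_id = q, stage = lab[keep], date = tr$date[keep],
      duration_s = tr$duration_s[keep], stringsAsFactors = FALSE))
    count_window <- function(days, stage) {
      n <- as.integer(table(factor(as.character(tr$date),
                                   levels = as.character(days))))
      data.frame(queen_id = q, stage = stage, date = days, n_trips = n,
                 stringsAsFactors = FALSE)
    }
    staged_daily <- rbind(staged_daily,
                          count_window(early_days, "EARLY"),
                          count_window(late_days, "LATE"))
  }
  empty_tr <- data.frame(queen_id = character(0), stage = character(0),
                         date = as.Date(character(0)),
                         duration_s = numeric(0))
  empty_dd <- data.frame(queen_id = character(0), stage = character(0),
                         date = as.Date(character(0)), n_trips = integer(0))
  list(trips = if (is.null(staged_trips)) empty_tr else staged_trips,
       daily = if (is.null(staged_daily)) empty_dd else staged_daily,
       queens = status)
}

round_half_up <- function(x) floor(x + 0.5)

#' Queen fate flow
#'
#' Collapses per-queen fates into the monotone chain of nesting milestones
#' — observed in a box, laid eggs (colonized), produced adult workers,
#' produced gynes — and reports how many queens reached each node plus the
#' share of gyne-producing queens among observed, egg-laying and
#' worker-producing queens. Percentages are reported to one decimal and in
#' two integer renderings (round-half-up and truncation), since summary
#' figures in the literature use either.
#'
#' @param queens Queen metadata from [read_queens()].
#' @return Object of class `fate_flow`: list with `counts` (named integer
#'   vector OBSERVED/SELECTED_ONLY/EGGS/WORKERS/GYNES) and `percentages`
#'   (data.frame with `pct`, `pct_rounded`, `pct_truncated` for
#'   gynes/observed, gynes/eggs, gynes/workers).
#' @examples
#' q <- data.frame(queen_id = as.character(1:18),
#'                 fate = factor(rep(c("SELECTED_ABSCONDED",
#'                                     "COLONIZED_ABSCONDED", "DIED",
#'                                     "WORKERS_NO_GYNES", "GYNES"),
#'                                   c(5, 4, 2, 4, 3))))
#' fate_flow(q)
#' @export
fate_flow <- function(queens) {
  fate <- as.character(queens$fate)
  counts <- c(
    OBSERVED = length(fate),
    SELECTED_ONLY = sum(fate == "SELECTED_ABSCONDED"),
    EGGS = sum(fate %in% c("COLONIZED_ABSCONDED", "DIED",
                           "WORKERS_NO_GYNES", "GYNES")),
    WORKERS = sum(fate %in% c("WORKERS_NO_GYNES", "GYNES")),
    GYNES = sum(fate == "GYNES"))
  stopifnot(counts["GYNES"] <= counts["WORKERS"],
            counts["WORKERS"] <= counts["EGGS"],
            counts["EGGS"] <= counts["OBSERVED"])
  denom <- counts[c("OBSERVED", "EGGS", "WORKERS")]
  pct <- ifelse(denom > 0, 100 * counts["GYNES"] / denom, 0)
  percentages <- data.frame(
    ratio = c("gynes_of_observed", "gynes_of_eggs", "gynes_of_workers"),
    pct = round(pct, 1),
    pct_rounded = round_half_up(pct),
    pct_truncated = floor(pct),
    stringsAsFactors = FALSE)
  rownames(percentages) <- NULL
  out <- list(counts = counts, percentages = percentages)
  class(out) <- "fate_flow"
  out
}

#' @export
print.fate_flow <- function(x, ...) {
  cat("Queen fate flow\n")
  cat(sprintf("  observed %d | selected-only %d | eggs %d | workers %d | gynes %d\n",
              x$counts["OBSERVED"], x$counts["SELECTED_ONLY"],
              x$counts["EGGS"], x$counts["WORKERS"], x$counts["GYNES"]))
  for (i in seq_len(nrow(x$percentages))) {
    cat(sprintf("  %-17s %5.1f%%\n", x$percentages$ratio[i],
                x$percentages$pct[i]))
  }
  invisible(x)
}
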