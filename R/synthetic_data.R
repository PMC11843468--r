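#' Simulation configuration
#'
#' Parameters of the ground-truth activity generator and the sensor model
#' that corrupts it into raw reads. The defaults describe a "paper-like"
#' foundress queen: alternating in-nest stays drawn from a trimodal
#' lognormal mixture (component means about 52.6 s, 27 min and 13.2 h) and
#' out-of-nest trips drawn from a lognormal with median about 16.1 min and
#' mean about 21.9 min, trips initiated only inside a local-time day
#' window, occasional overnight absences, per-board detection failures,
#' re-reads of a loitering bee, and periodic battery-change outages.
#'
#' The trip lognormal is fully parameterized from its target median and
#' mean: `meanlog = log(median)`, `sdlog = sqrt(2 log(mean/median))`.
#' Stay draws are floored at `stay_min_s`: the reader's pairing window
#' cannot resolve a turnaround faster than a pass-through plus transit, so
#' sub-window stays are below the sensor's resolution by construction.
#'
#' @param n_days Days of recording to simulate.
#' @param start_date Local calendar date of day 1.
#' @param local_tz Olson timezone of the study site.
#' @param day_window Local hours (start, end) within which trips begin.
#' @param stay_weights Mixture weights of the SHORT/MID/LONG stay
#'   components; must sum to 1.
#' @param stay_means_s Target mean of each stay component, seconds.
#' @param stay_sdlogs Lognormal log-sd of each stay component.
#' @param stay_min_s Lower bound on stay draws, seconds (sensor
#'   resolution; see above).
#' @param trip_median_s,trip_mean_s Target median and mean trip duration,
#'   seconds.
#' @param p_overnight_trip Probability that a trip is an overnight absence.
#' @param overnight_mean_s,overnight_sdlog Lognormal parameters of
#'   overnight trips (target mean about 13.1 h).
#' @param p_detect_inner,p_detect_outer Per-read detection probability of
#'   each antenna board, in \[0, 1\].
#' @param transit_min_s,transit_max_s Uniform bounds of the walking time
#'   between the two boards, seconds. Read timestamps are stamped at whole
#'   seconds (the reader clock's resolution), so the default minimum is
#'   1 s; the maximum must stay below the pairing window.
#' @param reread_prob Probability that a detection is followed by one
#'   hardware re-read.
#' @param reread_gap_min_s,reread_gap_max_s Uniform bounds of the re-read
#'   gap, seconds.
#' @param outage_period_h Hours between battery changes (`Inf` for none).
#' @param outage_duration_s Length of each power-off interval, seconds.
#' @param worker_emergence_day Optional day number on which workers emerge;
#'   the queen ceases foraging a uniform 0-7 days later.
#' @param rng_seed Default seed used by the simulation entry points.
#' @return Object of class `sim_config` (validated named list).
#' @export
sim_config <- function(n_days = 14,
                       start_date = "2022-06-15",
                       local_tz = "America/Denver",
                       day_window = c(6, 20),
                       stay_weights = c(0.32, 0.62, 0.06),
                       stay_means_s = c(52.6, 27 * 60, 13.2 * 3600),
                       stay_sdlogs = c(0.6, 0.8, 0.2),
                       stay_min_s = 15,
                       trip_median_s = 16.1 * 60,
                       trip_mean_s = 21.9 * 60,
                       p_overnight_trip = 0.014,
                       overnight_mean_s = 13.1 * 3600,
                       overnight_sdlog = 0.25,
                       p_detect_inner = 0.95,
                       p_detect_outer = 0.95,
                       transit_min_s = 1,
                       transit_max_s = 3,
                       reread_prob = 0.10,
                       reread_gap_min_s = 0.2,
                       reread_gap_max_s = 2,
                       outage_period_h = 84,
                       outage_duration_s = 300,
                       worker_emergence_day = NULL,
                       rng_seed = 1L) {
  cfg <- list(n_days = n_days, start_date = start_date, local_tz = local_tz,
              day_window = day_window, stay_weights = stay_weights,
              stay_means_s = stay_means_s, stay_sdlogs = stay_sdlogs,
              stay_min_s = stay_min_s, trip_median_s = trip_median_s,
              trip_mean_s = trip_mean_s, p_overnight_trip = p_overnight_trip,
              overnight_mean_s = overnight_mean_s,
              overnight_sdlog = overnight_sdlog,
              p_detect_inner = p_detect_inner,
              p_detect_outer = p_detect_outer,
              transit_min_s = transit_min_s, transit_max_s = transit_max_s,
              reread_prob = reread_prob,
              reread_gap_min_s = reread_gap_min_s,
              reread_gap_max_s = reread_gap_max_s,
              outage_period_h = outage_period_h,
              outage_duration_s = outage_duration_s,
              worker_emergence_day = worker_emergence_day,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_days < 0) stop("n_days must be >= 0", call. = FALSE)
  if (abs(sum(cfg$stay_weights) - 1) > 1e-8) {
    stop("stay mixture weights must sum to 1", call. = FALSE)
  }
  if (length(cfg$stay_weights) != 3 || length(cfg$stay_means_s) != 3 ||
      length(cfg$stay_sdlogs) != 3) {
    stop("the stay mixture has three components", call. = FALSE)
  }
  for (p in c(cfg$p_detect_inner, cfg$p_detect_outer)) {
    if (!(p >= 0 && p <= 1)) stop("p_detect must be in [0, 1]", call. = FALSE)
  }
  if (!(cfg$trip_mean_s >= cfg$trip_median_s)) {
    stop("trip mean must be >= trip median (right skew)", call. = FALSE)
  }
  if (!(cfg$day_window[1] < cfg$day_window[2])) {
    stop("day_window start hour must precede end hour", call. = FALSE)
  }
  if (!(cfg$transit_min_s > 0 && cfg$transit_max_s >= cfg$transit_min_s)) {
    stop("need 0 < transit_min_s <= transit_max_s", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic RFID scenario\n")
  cat(sprintf("  %g days from %s (%s), trips start %02d:00-%02d:00 local\n",
              x$n_days, x$start_date, x$local_tz,
              x$day_window[1], x$day_window[2]))
  cat(sprintf("  trips: lognormal median %.1f min, mean %.1f min; P(overnight) = %g\n",
              x$trip_median_s / 60, x$trip_mean_s / 60, x$p_overnight_trip))
  cat(sprintf("  stays: weights %s targeting means %.1f s / %.1f min / %.1f h\n",
              paste(x$stay_weights, collapse = "/"), x$stay_means_s[1],
              x$stay_means_s[2] / 60, x$stay_means_s[3] / 3600))
  cat(sprintf("  sensor: p_detect %g/%g, transit %g-%g s, reread %g, outage every %g h\n",
              x$p_detect_inner, x$p_detect_outer, x$transit_min_s,
              x$transit_max_s, x$reread_prob, x$outage_period_h))
  invisible(x)
}

# lognormal meanlog for a target mean at given sdlog
lnorm_meanlog_for_mean <- function(mean, sdlog) log(mean) - sdlog^2 / 2

trip_sdlog <- function(cfg) sqrt(2 * log(cfg$trip_mean_s / cfg$trip_median_s))

draw_stay_component_s <- function(cfg, k) {
  repeat {
    d <- stats::rlnorm(1, lnorm_meanlog_for_mean(cfg$stay_means_s[k],
                                                 cfg$stay_sdlogs[k]),
                       cfg$stay_sdlogs[k])
    if (d >= cfg$stay_min_s) return(d)
  }
}

# Draw the end of a stay starting at entrance time t, honouring the day
# window: trips begin only inside it. A short/mid draw whose end lands in
# the window is accepted; the first draw that would cross the evening
# window end makes the queen retire for the night (a long-component stay
# landing in a later day window). Long draws and pre-dawn cases are
# rejection-sampled into the window.
draw_stay_end <- function(cfg, t) {
  w1 <- cfg$day_window[1]; w2 <- cfg$day_window[2]
  in_window <- function(tt) {
    h <- local_hour(tt, cfg$local_tz)
    h >= w1 && h < w2
  }
  # evening window end of t's local day
  day_end <- utc_time(as.POSIXct(
    paste(format(t, "%Y-%m-%d", tz = cfg$local_tz),
          sprintf("%02d:00:00", w2)), tz = cfg$local_tz))
  retire <- function() {
    for (i in seq_len(1000L)) {
      cand <- t + draw_stay_component_s(cfg, 3L)
      if (cand > day_end && in_window(cand)) return(cand)
    }
    # guard: next window start after t
    utc_time(as.POSIXct(
      paste(format(t + 86400, "%Y-%m-%d", tz = cfg$local_tz),
            sprintf("%02d:00:00", w1)), tz = cfg$local_tz))
  }
  for (i in seq_len(1000L)) {
    k <- sample.int(3L, 1L, prob = cfg$stay_weights)
    cand <- t + draw_stay_component_s(cfg, k)
    if (in_window(cand)) return(cand)
    if (k < 3L && cand > day_end) return(retire())
  }
  retire()
}

draw_trip_s <- function(cfg) {
  if (stats::runif(1) < cfg$p_overnight_trip) {
    stats::rlnorm(1, lnorm_meanlog_for_mean(cfg$overnight_mean_s,
                                            cfg$overnight_sdlog),
                  cfg$overnight_sdlog)
  } else {
    stats::rlnorm(1, log(cfg$trip_median_s), trip_sdlog(cfg))
  }
}

utc_time <- function(x) {
  as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = "UTC")
}

# simulation origin: local midnight of start_date, carried as UTC POSIXct
sim_origin <- function(cfg) {
  utc_time(as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = cfg$local_tz))
}

local_hour <- function(time, tz) {
  as.numeric(format(time, "%H", tz = tz)) +
    as.numeric(format(time, "%M", tz = tz)) / 60 +
    as.numeric(format(time, "%S", tz = tz)) / 3600
}

#' Simulate ground-truth queen activity
#'
#' An alternating renewal process: the queen is in the nest, draws a stay
#' from the trimodal mixture, exits, draws a trip, re-enters, and so on.
#' A stay whose end would fall outside the day window is redrawn (rejection
#' sampling), so trips begin only in the window and nights are spanned by
#' LONG stays; overnight absences occur with probability
#' `p_overnight_trip` per trip. If `worker_emergence_day` is set, foraging
#' ceases a uniform 0-7 days after it. The sequence strictly alternates
#' EXIT/ENTRANCE and always ends in the nest.
#'
#' @param config A [sim_config()].
#' @param tag_id Tag identifier stamped on the events.
#' @param seed Seed (default `config$rng_seed`); `NA` leaves the RNG state
#'   alone, for use inside a larger seeded simulation.
#' @return Data.frame `tag_id`, `time` (POSIXct UTC), `direction`,
#'   `trip_index` (shared by the exit and entrance of one trip).
#' @export
simulate_truth <- function(config, tag_id = "Q1", seed = config$rng_seed) {
  validate_sim_config(config)
  run <- function() {
    origin <- sim_origin(config)
    end <- origin + config$n_days * 86400
    cease <- if (is.null(config$worker_emergence_day)) end else
      min(end, origin + (config$worker_emergence_day +
                           stats::runif(1, 0, 7)) * 86400)
    times <- numeric(0)
    dirs <- character(0)
    t <- origin
    trip_index <- 0L
    repeat {
      exit_t <- draw_stay_end(config, t)
      if (exit_t >= cease) break
      entr_t <- exit_t + draw_trip_s(config)
      if (entr_t >= end) break
      trip_index <- trip_index + 1L
      times <- c(times, as.numeric(exit_t), as.numeric(entr_t))
      dirs <- c(dirs, "EXIT", "ENTRANCE")
      t <- entr_t
    }
    out <- data.frame(
      tag_id = rep(tag_id, length(times)),
      time = as.POSIXct(times, origin = "1970-01-01", tz = "UTC"),
      direction = dirs,
      trip_index = rep(seq_len(trip_index), each = 2)[seq_along(times)],
      stringsAsFactors = FALSE)
    out
  }
  if (length(seed) == 1 && is.na(seed)) run() else with_seed(seed, run())
}

#' True trips and stays from a truth event sequence
#'
#' @param truth Output of [simulate_truth()].
#' @return `truth_trips()`: one row per trip (`exit_time`,
#'   `entrance_time`, `duration_s`); `truth_stays()`: one row per
#'   between-trip stay (`entrance_time`, `exit_time`, `duration_s`).
#' @export
truth_trips <- function(truth) {
  ex <- truth[truth$direction == "EXIT", , drop = FALSE]
  en <- truth[truth$direction == "ENTRANCE", , drop = FALSE]
  data.frame(tag_id = ex$tag_id, trip_index = ex$trip_index,
             exit_time = ex$time, entrance_time = en$time,
             duration_s = as.numeric(difftime(en$time, ex$time,
                                              units = "secs")),
             stringsAsFactors = FALSE)
}

#' @rdname truth_trips
#' @export
truth_stays <- function(truth) {
  n <- nrow(truth)
  if (n < 4) {
    return(data.frame(tag_id = character(0),
                      entrance_time = parse_utc_time(character(0)),
                      exit_time = parse_utc_time(character(0)),
                      duration_s = numeric(0)))
  }
  en <- truth[truth$direction == "ENTRANCE", , drop = FALSE]
  ex <- truth[truth$direction == "EXIT", , drop = FALSE]
  en <- en[-nrow(en), , drop = FALSE]   # last entrance has no following exit
  ex <- ex[-1, , drop = FALSE]          # first exit ends no stay
  data.frame(tag_id = en$tag_id, entrance_time = en$time,
             exit_time = ex$time,
             duration_s = as.numeric(difftime(ex$time, en$time,
                                              units = "secs")),
             stringsAsFactors = FALSE)
}

outage_schedule <- function(config, nest_id) {
  if (!is.finite(config$outage_period_h)) {
    return(data.frame(nest_id = character(0),
                      off_start = parse_utc_time(character(0)),
                      off_end = parse_utc_time(character(0))))
  }
  origin <- sim_origin(config)
  if (config$outage_period_h > config$n_days * 24) {
    return(data.frame(nest_id = character(0),
                      off_start = parse_utc_time(character(0)),
                      off_end = parse_utc_time(character(0))))
  }
  starts_h <- seq(config$outage_period_h, config$n_days * 24,
                  by = config$outage_period_h)
  off_start <- origin + starts_h * 3600
  data.frame(nest_id = nest_id, off_start = off_start,
             off_end = off_start + config$outage_duration_s,
             stringsAsFactors = FALSE)
}

finalize_reads <- function(reads) {
  reads <- sort_reads(reads)
  reads <- reads[!duplicated(reads), , drop = FALSE]
  rownames(reads) <- NULL
  reads$read_id <- seq_len(nrow(reads))
  reads
}

#' Corrupt a truth sequence into a raw read stream
#'
#' The sensor model: each passage produces a first read on the board the
#' bee meets first and a second read on the other board after a uniform
#' transit time (inner then outer for an exit, outer then inner for an
#' entrance; the truth event time is the second read). Each read is
#' independently lost with probability one minus its board's detection
#' probability — losing one of the two yields a lone read, losing both a
#' fully missed passage. Detections are re-read with probability
#' `reread_prob`, timestamps are stamped at whole seconds, and reads
#' falling inside a scheduled power outage are deleted.
#'
#' @param truth Output of [simulate_truth()].
#' @param config A [sim_config()].
#' @param nest_id Nest identifier for the reads and power log.
#' @param seed Seed (default `config$rng_seed + 1`); `NA` to leave the RNG
#'   state alone.
#' @return List with `reads` (same shape as [read_raw_reads()] output) and
#'   `power` (same shape as [read_power_log()] output).
#' @export
corrupt_to_reads <- function(truth, config, nest_id = "N1",
                             seed = config$rng_seed + 1L) {
  validate_sim_config(config)
  run <- function() {
    n <- nrow(truth)
    power <- outage_schedule(config, nest_id)
    if (n == 0) {
      reads <- data.frame(nest_id = character(0), tag_id = character(0),
                          time = parse_utc_time(character(0)),
                          board = factor(character(0), QT_BOARDS),
                          stringsAsFactors = FALSE)
      return(list(reads = finalize_reads(reads), power = power))
    }
    second_t <- floor(as.numeric(truth$time))
    transit <- stats::runif(n, config$transit_min_s, config$transit_max_s)
    first_t <- floor(as.numeric(truth$time) - transit)
    is_exit <- truth$direction == "EXIT"
    first_board <- ifelse(is_exit, "INNER", "OUTER")
    second_board <- ifelse(is_exit, "OUTER", "INNER")
    tm <- c(first_t, second_t)
    bd <- c(first_board, second_board)
    tg <- rep(truth$tag_id, 2)
    p <- ifelse(bd == "INNER", config$p_detect_inner, config$p_detect_outer)
    keep <- stats::runif(length(tm)) < p
    tm <- tm[keep]; bd <- bd[keep]; tg <- tg[keep]
    reread <- stats::runif(length(tm)) < config$reread_prob
    if (any(reread)) {
      gap <- stats::runif(sum(reread), config$reread_gap_min_s,
                          config$reread_gap_max_s)
      tm <- c(tm, floor(tm[reread] + gap))
      bd <- c(bd, bd[reread])
      tg <- c(tg, tg[reread])
    }
    reads <- data.frame(nest_id = nest_id, tag_id = tg,
                        time = as.POSIXct(tm, origin = "1970-01-01",
                                          tz = "UTC"),
                        board = factor(bd, QT_BOARDS),
                        stringsAsFactors = FALSE)
    in_power <- rep(FALSE, nrow(reads))
    for (j in seq_len(nrow(power))) {
      in_power <- in_power | (reads$time >= power$off_start[j] &
                                reads$time <= power$off_end[j])
    }
    reads <- reads[!in_power, , drop = FALSE]
    list(reads = finalize_reads(reads), power = power)
  }
  if (length(seed) == 1 && is.na(seed)) run() else with_seed(seed, run())
}

#' Simulate one queen end to end
#'
#' Seeds the RNG once, draws the truth sequence and corrupts it into a
#' read stream, so `simulate → corrupt → infer` is reproducible from a
#' single seed.
#'
#' @param config A [sim_config()].
#' @param tag_id,nest_id Identifiers stamped on the outputs.
#' @param seed Single seed for the whole run (default `config$rng_seed`).
#' @return List `truth`, `reads`, `power`.
#' @export
simulate_colony <- function(config, tag_id = "Q1", nest_id = "N1",
                            seed = config$rng_seed) {
  with_seed(seed, {
    truth <- simulate_truth(config, tag_id = tag_id, seed = NA)
    cr <- corrupt_to_reads(truth, config, nest_id = nest_id, seed = NA)
    list(truth = truth, reads = cr$reads, power = cr$power)
  })
}

jaccard_match <- function(true_start, true_end, inf_start, inf_end) {
  nt <- length(true_start); ni <- length(inf_start)
  pairs <- NULL
  for (i in seq_len(nt)) {
    if (!ni) break
    inter <- pmin(true_end[i], inf_end) - pmax(true_start[i], inf_start)
    uni <- pmax(true_end[i], inf_end) - pmin(true_start[i], inf_start)
    frac <- ifelse(inter > 0, inter / uni, 0)
    j <- which.max(frac)
    if (length(j) && frac[j] >= 0.5) {
      pairs <- rbind(pairs, data.frame(i = i, j = j, frac = frac[j]))
    }
  }
  if (is.null(pairs)) {
    return(data.frame(i = integer(0), j = integer(0), frac = numeric(0)))
  }
  # enforce one-to-one: keep the best fraction per inferred interval
  pairs <- pairs[order(-pairs$frac), , drop = FALSE]
  pairs <- pairs[!duplicated(pairs$j), , drop = FALSE]
  pairs[order(pairs$i), , drop = FALSE]
}

#' Recovery metrics of the pipeline against ground truth
#'
#' Matches inferred trips to true trips by interval overlap (intersection
#' over union at least one half, one-to-one) and reports recall,
#' precision, and the mean duration bias; in-nest stays are matched the
#' same way and cross-tabulated by duration class.
#'
#' @param truth Output of [simulate_truth()].
#' @param inference An `rfid_inference` from [infer_trips()] on the
#'   corrupted reads.
#' @param config A [pipeline_config()] for the stay classes.
#' @return List `n_true_trips`, `n_inferred_trips`, `recall`, `precision`,
#'   `duration_bias_s` (mean inferred minus true over matches),
#'   `stay_confusion` (true class in rows, inferred in columns).
#' @export
recovery_report <- function(truth, inference, config = pipeline_config()) {
  tt <- truth_trips(truth)
  it <- inference$trips
  pairs <- jaccard_match(as.numeric(tt$exit_time), as.numeric(tt$entrance_time),
                         as.numeric(it$exit_time), as.numeric(it$entrance_time))
  ts <- truth_stays(truth)
  is_ <- inference$stays
  spairs <- jaccard_match(as.numeric(ts$entrance_time), as.numeric(ts$exit_time),
                          as.numeric(is_$entrance_time), as.numeric(is_$exit_time))
  lv <- c("SHORT", "MID", "LONG")
  confusion <- table(
    true = factor(classify_stay(ts$duration_s[spairs$i], config), lv),
    inferred = factor(classify_stay(is_$duration_s[spairs$j], config), lv))
  list(n_true_trips = nrow(tt), n_inferred_trips = nrow(it),
       recall = if (nrow(tt)) nrow(pairs) / nrow(tt) else NA_real_,
       precision = if (nrow(it)) nrow(pairs) / nrow(it) else NA_real_,
       duration_bias_s = if (nrow(pairs)) {
         mean(it$duration_s[pairs$j] - tt$duration_s[pairs$i])
       } else NA_real_,
       stay_confusion = confusion)
}

#' Synthetic staged trips and daily counts for model calibration
#'
#' Direct generators for the stage-model inputs, bypassing the event
#' pipeline: per-queen lognormal trip durations with a multiplicative
#' late-stage effect and a lognormal queen random intercept
#' (`simulate_stage_trips`), and negative-binomial daily counts with
#' stage-specific means and a queen random intercept on the log scale
#' (`simulate_stage_counts`).
#'
#' @param n_queens Number of queens.
#' @param trips_per_stage Trips per queen per stage.
#' @param effect Multiplicative LATE/EARLY duration ratio (1 = no effect).
#' @param queen_sd SD of the per-queen random intercept (log scale).
#' @param median_s Median early-stage trip duration, seconds.
#' @param sdlog Residual lognormal log-sd.
#' @param seed RNG seed.
#' @return Data.frame in the shape required by [fit_duration_model()] or
#'   [fit_frequency_model()].
#' @export
simulate_stage_trips <- function(n_queens = 6, trips_per_stage = 40,
                                 effect = 1.5, queen_sd = 0.3,
                                 median_s = 16.1 * 60, sdlog = 0.78,
                                 seed = 1L) {
  with_seed(seed, {
    b <- stats::rnorm(n_queens, 0, queen_sd)
    rows <- lapply(seq_len(n_queens), function(q) {
      data.frame(
        queen_id = sprintf("Q%02d", q),
        stage = rep(c("EARLY", "LATE"), each = trips_per_stage),
        duration_s = stats::rlnorm(
          2 * trips_per_stage,
          log(median_s) + b[q] +
            rep(c(0, log(effect)), each = trips_per_stage),
          sdlog),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' @rdname simulate_stage_trips
#' @param days_per_stage Days per queen per stage.
#' @param mean_early,mean_late Mean daily trip counts by stage.
#' @param theta Negative-binomial dispersion (variance `mu + mu^2/theta`).
#' @export
simulate_stage_counts <- function(n_queens = 6, days_per_stage = 5,
                                  mean_early = 12, mean_late = 6,
                                  theta = 2, queen_sd = 0.2, seed = 1L) {
  with_seed(seed, {
    b <- stats::rnorm(n_queens, 0, queen_sd)
    rows <- lapply(seq_len(n_queens), function(q) {
      mu <- exp(log(rep(c(mean_early, mean_late), each = days_per_stage)) +
                  b[q])
      data.frame(
        queen_id = sprintf("Q%02d", q),
        stage = rep(c("EARLY", "LATE"), each = days_per_stage),
        n_trips = stats::rnbinom(2 * days_per_stage, mu = mu, size = theta),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
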