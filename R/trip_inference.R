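#' @name trip_inference
#' @title From raw reads to directed events, trips and stays
#'
#' @description
#' A queen crossing the nest entrance walks under two antenna boards in
#' sequence, so a complete passage is a pair of reads on opposite boards a
#' few seconds apart. The inference pipeline converts the raw read stream of
#' one `(nest, tag)` into directed events and bout intervals in a fixed
#' stage order:
#'
#' 1. collapse same-board re-reads within the pairing window
#'    ([collapse_rereads()]),
#' 2. pair successive opposite-board reads within the strict window and
#'    label each pair's direction ([pair_reads()], [label_direction()]),
#' 3. relabel lone reads flanked by two same-direction events
#'    ([relabel_lone_reads()]),
#' 4. remove spurious inner-board lone reads — a queen standing in the
#'    entrance — and log the rest as unresolvable ([drop_spurious_inner()]),
#' 5. build alternating trips (exit to next entrance) and stays (entrance
#'    to next exit), reporting same-direction runs as anomalies
#'    ([build_trips_and_stays()]),
#' 6. drop micro-trips and trips spanning a reader power outage
#'    ([filter_trips()]).
#'
#' [infer_trips()] composes the stages over every `(nest, tag)` group and
#' returns an `rfid_inference` object. Every raw read is accounted for
#' exactly once: member of a pair, relabeled, collapsed re-read, spurious,
#' or unresolvable.
NULL

empty_events <- function() {
  data.frame(tag_id = character(0), time = parse_utc_time(character(0)),
             direction = character(0), provenance = character(0),
             read1_id = integer(0), read2_id = integer(0),
             stringsAsFactors = FALSE)
}

#' Collapse same-board re-reads
#'
#' A stationary bee sitting under one antenna is read repeatedly. Successive
#' reads on the same board closer together than the pairing window are
#' collapsed onto the first read of the run, so they cannot spawn phantom
#' passages. Collapsing is chained on raw adjacency: each read is compared
#' with the immediately preceding raw read.
#'
#' @param reads Time-sorted reads of one `(nest, tag)` (see
#'   [read_raw_reads()]).
#' @param window Pairing window in seconds (strict `<`).
#' @return List with `reads` (retained) and `collapsed` (dropped re-reads).
#' @export
collapse_rereads <- function(reads, window) {
  n <- nrow(reads)
  if (n <= 1) {
    return(list(reads = reads, collapsed = reads[0, , drop = FALSE]))
  }
  gap <- as.numeric(difftime(reads$time[-1], reads$time[-n], units = "secs"))
  same <- as.character(reads$board[-1]) == as.character(reads$board[-n])
  drop <- c(FALSE, same & gap < window)
  list(reads = reads[!drop, , drop = FALSE],
       collapsed = reads[drop, , drop = FALSE])
}

#' Label the direction of one opposite-board pair
#'
#' Inner board then outer board is an exit; outer then inner is an
#' entrance. The event is stamped with the time of the second read of the
#' pair (the moment the passage completes), so trip durations run from
#' passage completion to passage completion.
#'
#' @param first,second Single-row read data.frames, in time order, on
#'   opposite boards.
#' @return Single-row event data.frame (`tag_id`, `time`, `direction`,
#'   `provenance = "PAIRED"`, `read1_id`, `read2_id`).
#' @export
label_direction <- function(first, second) {
  stopifnot(nrow(first) == 1, nrow(second) == 1)
  b1 <- as.character(first$board)
  b2 <- as.character(second$board)
  if (b1 == b2) stop("a directed pair needs opposite boards", call. = FALSE)
  data.frame(tag_id = first$tag_id, time = second$time,
             direction = if (b1 == "INNER") "EXIT" else "ENTRANCE",
             provenance = "PAIRED",
             read1_id = first$read_id, read2_id = second$read_id,
             stringsAsFactors = FALSE)
}

#' Pair successive opposite-board reads
#'
#' Greedy left-to-right scan: each read pairs with the immediately next read
#' if and only if the boards differ and the gap is strictly less than the
#' window; both reads of a pair are consumed and cannot pair again. All
#' unconsumed reads are returned as lone reads.
#'
#' @inheritParams collapse_rereads
#' @return List with `events` (paired, directed; see [label_direction()])
#'   and `lone` (unpaired reads).
#' @export
pair_reads <- function(reads, window) {
  n <- nrow(reads)
  if (n == 0) return(list(events = empty_events(), lone = reads))
  t <- as.numeric(reads$time)
  board <- as.character(reads$board)
  pair_first <- logical(n)
  lone <- logical(n)
  i <- 1L
  while (i <= n) {
    if (i < n && board[i] != board[i + 1L] && (t[i + 1L] - t[i]) < window) {
      pair_first[i] <- TRUE
      i <- i + 2L
    } else {
      lone[i] <- TRUE
      i <- i + 1L
    }
  }
  idx <- which(pair_first)
  if (length(idx)) {
    events <- data.frame(
      tag_id = reads$tag_id[idx],
      time = reads$time[idx + 1L],
      direction = ifelse(board[idx] == "INNER", "EXIT", "ENTRANCE"),
      provenance = "PAIRED",
      read1_id = reads$read_id[idx],
      read2_id = reads$read_id[idx + 1L],
      stringsAsFactors = FALSE)
  } else {
    events <- empty_events()
  }
  list(events = events, lone = reads[lone, , drop = FALSE])
}

# Merge events and lone reads onto one timeline. Items carry type
# "EVENT"/"LONE"; at equal times events sort first (a completed passage
# precedes a dangling read at the same second).
merge_timeline <- function(events, lone) {
  ev <- if (nrow(events)) {
    data.frame(time = events$time, type = "EVENT",
               direction = events$direction, idx = seq_len(nrow(events)),
               board = NA_character_, stringsAsFactors = FALSE)
  } else {
    data.frame(time = parse_utc_time(character(0)), type = character(0),
               direction = character(0), idx = integer(0),
               board = character(0), stringsAsFactors = FALSE)
  }
  lo <- if (nrow(lone)) {
    data.frame(time = lone$time, type = "LONE",
               direction = NA_character_, idx = seq_len(nrow(lone)),
               board = as.character(lone$board), stringsAsFactors = FALSE)
  } else {
    ev[0, , drop = FALSE]
  }
  tl <- rbind(ev, lo)
  tl[order(tl$time, tl$type), , drop = FALSE]
}

#' Relabel lone reads flanked by same-direction events
#'
#' A lone read immediately preceded and followed by an entrance must have
#' been an exit whose partner read was missed, and vice versa. "Immediately"
#' is positional on the merged timeline of events and lone reads, with no
#' time limit; a lone read at the stream boundary, with mixed-direction
#' flanks, or adjacent to another lone read stays unlabeled. One pass over
#' the original timeline: relabeling one read never enables relabeling a
#' neighbour.
#'
#' @param events Directed events (from [pair_reads()]).
#' @param lone Lone reads (from [pair_reads()]).
#' @return List with `events` (augmented, time-sorted; relabeled events have
#'   `provenance = "RELABELED_LONE"` and `read1_id` the lone read) and
#'   `residual` (still-unlabeled lone reads).
#' @export
relabel_lone_reads <- function(events, lone) {
  if (nrow(lone) == 0) {
    ev <- events[order(events$time), , drop = FALSE]
    rownames(ev) <- NULL
    return(list(events = ev, residual = lone))
  }
  tl <- merge_timeline(events, lone)
  n <- nrow(tl)
  relabeled <- rep(NA_character_, nrow(lone))
  for (k in seq_len(n)) {
    if (tl$type[k] != "LONE" || k == 1L || k == n) next
    prev <- tl[k - 1L, ]
    nxt <- tl[k + 1L, ]
    if (prev$type == "EVENT" && nxt$type == "EVENT" &&
        prev$direction == nxt$direction) {
      relabeled[tl$idx[k]] <-
        if (prev$direction == "ENTRANCE") "EXIT" else "ENTRANCE"
    }
  }
  hit <- !is.na(relabeled)
  new_events <- if (any(hit)) {
    data.frame(tag_id = lone$tag_id[hit], time = lone$time[hit],
               direction = relabeled[hit], provenance = "RELABELED_LONE",
               read1_id = lone$read_id[hit], read2_id = NA_integer_,
               stringsAsFactors = FALSE)
  } else {
    empty_events()
  }
  ev <- rbind(events, new_events)
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  list(events = ev, residual = lone[!hit, , drop = FALSE])
}

#' Remove spurious inner-board lone reads
#'
#' A residual inner-board lone read whose immediately preceding timeline
#' item is an entrance event or another residual inner-board lone read is
#' the signature of a queen standing in the nest entrance without leaving:
#' it is removed and counted. All other residual lone reads (outer-board
#' reads, or inner reads with different predecessors) carry no direction
#' information the filtering rules can recover; they are removed from the
#' event timeline and logged as unresolvable rather than guessed into
#' directions. Predecessors are evaluated on the pre-removal timeline, left
#' to right.
#'
#' @param events Directed events after [relabel_lone_reads()].
#' @param residual Residual lone reads after [relabel_lone_reads()].
#' @return List with `events` (unchanged), `spurious` (removed inner reads)
#'   and `unresolvable` (logged, excluded from the timeline).
#' @export
drop_spurious_inner <- function(events, residual) {
  if (nrow(residual) == 0) {
    return(list(events = events, spurious = residual,
                unresolvable = residual))
  }
  tl <- merge_timeline(events, residual)
  spurious <- logical(nrow(residual))
  for (k in seq_len(nrow(tl))) {
    if (tl$type[k] != "LONE" || tl$board[k] != "INNER") next
    if (k == 1L) next
    prev <- tl[k - 1L, ]
    preceded_by_entrance <- prev$type == "EVENT" &&
      prev$direction == "ENTRANCE"
    preceded_by_inner_lone <- prev$type == "LONE" && prev$board == "INNER"
    if (preceded_by_entrance || preceded_by_inner_lone) {
      spurious[tl$idx[k]] <- TRUE
    }
  }
  list(events = events,
       spurious = residual[spurious, , drop = FALSE],
       unresolvable = residual[!spurious, , drop = FALSE])
}

classify_trip <- function(duration_s, config) {
  ifelse(duration_s < config$min_trip_s, "MICRO",
         ifelse(duration_s > config$foraging_max_h * 3600,
                "EXTENDED", "FORAGING"))
}

classify_stay <- function(duration_s, config) {
  ifelse(duration_s < config$stay_short_max_s, "SHORT",
         ifelse(duration_s <= config$stay_mid_max_h * 3600, "MID", "LONG"))
}

#' Build trips and stays from an alternating event stream
#'
#' Each exit followed next by an entrance is an out-of-nest trip; each
#' entrance followed next by an exit is an in-nest stay. Two consecutive
#' same-direction events mean a missed passage: an anomaly is recorded and
#' no interval spans the gap. Partial intervals before the first and after
#' the last event are never emitted. Trip and stay classes are assigned
#' from `config` thresholds.
#'
#' @param events Cleaned, time-sorted directed events of one tag.
#' @param config A [pipeline_config()].
#' @return List with `trips`, `stays`, `anomalies` data.frames.
#' @export
build_trips_and_stays <- function(events, config = pipeline_config()) {
  n <- nrow(events)
  trips <- data.frame(tag_id = character(0),
                      exit_time = parse_utc_time(character(0)),
                      entrance_time = parse_utc_time(character(0)),
                      duration_s = numeric(0), trip_class = character(0),
                      power_interrupted = logical(0),
                      overnight_flag = logical(0), stringsAsFactors = FALSE)
  stays <- data.frame(tag_id = character(0),
                      entrance_time = parse_utc_time(character(0)),
                      exit_time = parse_utc_time(character(0)),
                      duration_s = numeric(0), stay_class = character(0),
                      power_interrupted = logical(0), stringsAsFactors = FALSE)
  anomalies <- data.frame(tag_id = character(0),
                          time1 = parse_utc_time(character(0)),
                          time2 = parse_utc_time(character(0)),
                          kind = character(0), stringsAsFactors = FALSE)
  if (n < 2) return(list(trips = trips, stays = stays, anomalies = anomalies))
  stopifnot(!is.unsorted(events$time))
  d1 <- events$direction[-n]
  d2 <- events$direction[-1]
  dur <- as.numeric(difftime(events$time[-1], events$time[-n], units = "secs"))
  is_anom <- d1 == d2 | dur <= 0
  is_trip <- !is_anom & d1 == "EXIT"
  is_stay <- !is_anom & d1 == "ENTRANCE"
  if (any(is_trip)) {
    i <- which(is_trip)
    trips <- data.frame(tag_id = events$tag_id[i],
                        exit_time = events$time[i],
                        entrance_time = events$time[i + 1L],
                        duration_s = dur[i],
                        trip_class = classify_trip(dur[i], config),
                        power_interrupted = FALSE,
                        overnight_flag = dur[i] > config$overnight_min_h * 3600,
                        stringsAsFactors = FALSE)
  }
  if (any(is_stay)) {
    i <- which(is_stay)
    stays <- data.frame(tag_id = events$tag_id[i],
                        entrance_time = events$time[i],
                        exit_time = events$time[i + 1L],
                        duration_s = dur[i],
                        stay_class = classify_stay(dur[i], config),
                        power_interrupted = FALSE,
                        stringsAsFactors = FALSE)
  }
  if (any(is_anom)) {
    i <- which(is_anom)
    anomalies <- data.frame(
      tag_id = events$tag_id[i],
      time1 = events$time[i], time2 = events$time[i + 1L],
      kind = ifelse(dur[i] <= 0, "NON_POSITIVE_GAP",
                    ifelse(d1[i] == "EXIT", "CONSECUTIVE_EXITS",
                           "CONSECUTIVE_ENTRANCES")),
      stringsAsFactors = FALSE)
  }
  list(trips = trips, stays = stays, anomalies = anomalies)
}

interval_overlaps_outage <- function(start, end, power) {
  if (is.null(power) || nrow(power) == 0) return(rep(FALSE, length(start)))
  hit <- rep(FALSE, length(start))
  for (j in seq_len(nrow(power))) {
    hit <- hit | (start < power$off_end[j] & end > power$off_start[j])
  }
  hit
}

#' Filter trips (and stays) for micro-trips and power outages
#'
#' Removal follows the published order: first out-of-nest records strictly
#' shorter than `min_trip_s` are removed as micro-trips, then trips whose
#' interval overlaps a reader power-off interval are removed because a loss
#' of power may have swallowed reads and invalidated the duration. Stays
#' overlapping outages are likewise flagged invalid and excluded from stay
#' statistics.
#'
#' @param trips,stays Output of [build_trips_and_stays()] for one nest.
#' @param power Power intervals of the same nest ([read_power_log()]), or
#'   `NULL`.
#' @param config A [pipeline_config()].
#' @return List with `trips` and `stays` (retained), `removed_trips` (with
#'   a `removal_reason` of `MICRO` or `POWER`) and `invalid_stays`.
#' @export
filter_trips <- function(trips, stays, power = NULL,
                         config = pipeline_config()) {
  micro <- trips$trip_class == "MICRO"
  removed_micro <- trips[micro, , drop = FALSE]
  trips <- trips[!micro, , drop = FALSE]
  trips$power_interrupted <- interval_overlaps_outage(
    trips$exit_time, trips$entrance_time, power)
  removed_power <- trips[trips$power_interrupted, , drop = FALSE]
  trips <- trips[!trips$power_interrupted, , drop = FALSE]
  removed <- rbind(
    if (nrow(removed_micro)) cbind(removed_micro, removal_reason = "MICRO"),
    if (nrow(removed_power)) cbind(removed_power, removal_reason = "POWER"))
  if (is.null(removed)) {
    removed <- cbind(trips[0, , drop = FALSE],
                     removal_reason = character(0))
  }
  stays$power_interrupted <- interval_overlaps_outage(
    stays$entrance_time, stays$exit_time, power)
  invalid_stays <- stays[stays$power_interrupted, , drop = FALSE]
  stays <- stays[!stays$power_interrupted, , drop = FALSE]
  rownames(trips) <- rownames(stays) <- rownames(removed) <- NULL
  list(trips = trips, stays = stays, removed_trips = removed,
       invalid_stays = invalid_stays)
}

infer_one_group <- function(reads, power, config) {
  col <- collapse_rereads(reads, config$pairing_window_s)
  pr <- pair_reads(col$reads, config$pairing_window_s)
  rl <- relabel_lone_reads(pr$events, pr$lone)
  sp <- drop_spurious_inner(rl$events, rl$residual)
  bs <- build_trips_and_stays(sp$events, config)
  ft <- filter_trips(bs$trips, bs$stays, power, config)
  list(events = sp$events, collapsed = col$collapsed,
       spurious = sp$spurious, unresolvable = sp$unresolvable,
       anomalies = bs$anomalies, trips = ft$trips, stays = ft$stays,
       removed_trips = ft$removed_trips, invalid_stays = ft$invalid_stays,
       n_relabeled = sum(rl$events$provenance == "RELABELED_LONE"))
}

read_removal_report <- function(reads, reason) {
  data.frame(read_id = reads$read_id, nest_id = reads$nest_id,
             tag_id = reads$tag_id, time = reads$time,
             board = as.character(reads$board), reason = reason,
             stringsAsFactors = FALSE)[seq_len(nrow(reads)), , drop = FALSE]
}

#' Run the full read-filtering pipeline
#'
#' Composes the pipeline stages — collapse re-reads, pair, label, relabel
#' lone reads, drop spurious inner reads, build trips and stays, filter —
#' independently for every `(nest_id, tag_id)` group (multiple tagged
#' queens at one nest, e.g. a resident and an invader, never interact).
#' The whole computation is deterministic.
#'
#' @param reads Raw reads as returned by [read_raw_reads()].
#' @param power Power-off intervals as returned by [read_power_log()], or
#'   `NULL` for none.
#' @param config A [pipeline_config()].
#' @return An object of class `rfid_inference`: a list with `trips`,
#'   `stays`, `events` (all with `nest_id`/`tag_id`), `removed_trips`,
#'   `invalid_stays`, `read_removals` (read-level reasons
#'   `COLLAPSED_REREAD`, `SPURIOUS_INNER`, `UNRESOLVABLE`), `anomalies`,
#'   and a `counts` list of stage-by-stage bookkeeping.
#' @examples
#' reads <- read_raw_reads(system.file("extdata", "worked_trace_reads.csv",
#'                                     package = "queentrack"))
#' power <- read_power_log(system.file("extdata", "worked_trace_power.csv",
#'                                     package = "queentrack"))
#' inf <- infer_trips(reads, power)
#' inf$counts$n_trips
#' @export
infer_trips <- function(reads, power = NULL, config = pipeline_config()) {
  validate_pipeline_config(config)
  key <- interaction(reads$nest_id, reads$tag_id, drop = TRUE, sep = "\r")
  groups <- if (nrow(reads)) split(reads, key) else list()
  acc <- list(events = NULL, trips = NULL, stays = NULL, removed = NULL,
              invalid_stays = NULL, anomalies = NULL, read_removals = NULL)
  n_relabeled <- 0L
  for (g in groups) {
    nest <- g$nest_id[1]
    pw <- if (is.null(power)) NULL else
      power[power$nest_id == nest, , drop = FALSE]
    r <- infer_one_group(g, pw, config)
    n_relabeled <- n_relabeled + r$n_relabeled
    add_ids <- function(df) {
      if (is.null(df) || nrow(df) == 0) return(NULL)
      df$nest_id <- nest
      df
    }
    acc$events <- rbind(acc$events, add_ids(r$events))
    acc$trips <- rbind(acc$trips, add_ids(r$trips))
    acc$stays <- rbind(acc$stays, add_ids(r$stays))
    acc$removed <- rbind(acc$removed, add_ids(r$removed_trips))
    acc$invalid_stays <- rbind(acc$invalid_stays, add_ids(r$invalid_stays))
    acc$anomalies <- rbind(acc$anomalies, add_ids(r$anomalies))
    acc$read_removals <- rbind(
      acc$read_removals,
      if (nrow(r$collapsed)) read_removal_report(r$collapsed, "COLLAPSED_REREAD"),
      if (nrow(r$spurious)) read_removal_report(r$spurious, "SPURIOUS_INNER"),
      if (nrow(r$unresolvable)) read_removal_report(r$unresolvable, "UNRESOLVABLE"))
  }
  tidy <- function(df, template) {
    if (is.null(df)) return(template)
    rownames(df) <- NULL
    df
  }
  ev0 <- empty_events(); ev0$nest_id <- character(0)
  bs0 <- build_trips_and_stays(empty_events(), config)
  tr0 <- bs0$trips; tr0$nest_id <- character(0)
  st0 <- bs0$stays; st0$nest_id <- character(0)
  an0 <- bs0$anomalies; an0$nest_id <- character(0)
  rm0 <- cbind(bs0$trips, removal_reason = character(0))
  rm0$nest_id <- character(0)
  rr0 <- read_removal_report(reads[0, , drop = FALSE], character(0))
  out <- list(
    trips = tidy(acc$trips, tr0),
    stays = tidy(acc$stays, st0),
    events = tidy(acc$events, ev0),
    removed_trips = tidy(acc$removed, rm0),
    invalid_stays = tidy(acc$invalid_stays, st0),
    read_removals = tidy(acc$read_removals, rr0),
    anomalies = tidy(acc$anomalies, an0),
    config = config)
  out$counts <- list(
    n_reads = nrow(reads),
    n_paired_events = sum(out$events$provenance == "PAIRED"),
    n_relabeled = n_relabeled,
    n_collapsed = sum(out$read_removals$reason == "COLLAPSED_REREAD"),
    n_spurious_inner = sum(out$read_removals$reason == "SPURIOUS_INNER"),
    n_unresolvable = sum(out$read_removals$reason == "UNRESOLVABLE"),
    n_trips_built = nrow(out$trips) + nrow(out$removed_trips),
    n_micro_removed = sum(out$removed_trips$removal_reason == "MICRO"),
    n_power_removed = sum(out$removed_trips$removal_reason == "POWER"),
    n_trips = nrow(out$trips),
    n_stays = nrow(out$stays),
    n_anomalies = nrow(out$anomalies))
  class(out) <- "rfid_inference"
  out
}

#' @export
print.rfid_inference <- function(x, ...) {
  c <- x$counts
  cat("RFID trip inference\n")
  cat(sprintf("  reads: %d (%d collapsed re-reads, %d spurious inner, %d unresolvable)\n",
              c$n_reads, c$n_collapsed, c$n_spurious_inner, c$n_unresolvable))
  cat(sprintf("  events: %d paired + %d relabeled lone\n",
              c$n_paired_events, c$n_relabeled))
  cat(sprintf("  trips: %d retained (%d micro and %d power-interrupted removed)\n",
              c$n_trips, c$n_micro_removed, c$n_power_removed))
  cat(sprintf("  stays: %d; anomalies (missed passages): %d\n",
              c$n_stays, c$n_anomalies))
  invisible(x)
}

#' Combined removal report
#'
#' One row per removed record, read-level (`COLLAPSED_REREAD`,
#' `SPURIOUS_INNER`, `UNRESOLVABLE`) and interval-level (`MICRO`, `POWER`)
#' alike, suitable for writing to `removals.csv`.
#'
#' @param x An `rfid_inference` object.
#' @return Data.frame `nest_id`, `tag_id`, `level`, `reason`, `time`,
#'   `duration_s`.
#' @export
removals <- function(x) {
  stopifnot(inherits(x, "rfid_inference"))
  rr <- x$read_removals
  reads_part <- data.frame(nest_id = rr$nest_id, tag_id = rr$tag_id,
                           level = rep("READ", nrow(rr)), reason = rr$reason,
                           time = rr$time, duration_s = NA_real_,
                           stringsAsFactors = FALSE)
  rt <- x$removed_trips
  trips_part <- data.frame(nest_id = rt$nest_id, tag_id = rt$tag_id,
                           level = rep("TRIP", nrow(rt)),
                           reason = rt$removal_reason, time = rt$exit_time,
                           duration_s = rt$duration_s,
                           stringsAsFactors = FALSE)
  st <- x$invalid_stays
  stays_part <- data.frame(nest_id = st$nest_id, tag_id = st$tag_id,
                           level = rep("STAY", nrow(st)),
                           reason = rep("POWER", nrow(st)),
                           time = st$entrance_time, duration_s = st$duration_s,
                           stringsAsFactors = FALSE)
  out <- rbind(reads_part, trips_part, stays_part)
  out <- out[order(out$nest_id, out$tag_id, out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write inferred trips (or stays, events, removals) to CSV
#'
#' @param x An `rfid_inference` object.
#' @param dir Output directory; created if missing.
#' @return Named character vector of the files written, invisibly.
#' @export
write_inference <- function(x, dir) {
  stopifnot(inherits(x, "rfid_inference"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt_df <- function(df) {
    for (col in names(df)) {
      if (inherits(df[[col]], "POSIXct")) df[[col]] <- format_utc_time(df[[col]])
    }
    df
  }
  paths <- c(trips = file.path(dir, "trips.csv"),
             stays = file.path(dir, "stays.csv"),
             events = file.path(dir, "events.csv"),
             removals = file.path(dir, "removals.csv"))
  utils::write.csv(fmt_df(x$trips[c("nest_id", "tag_id", "exit_time",
                                    "entrance_time", "duration_s",
                                    "trip_class", "power_interrupted",
                                    "overnight_flag")]),
                   paths["trips"], row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt_df(x$stays[c("nest_id", "tag_id", "entrance_time",
                                    "exit_time", "duration_s", "stay_class")]),
                   paths["stays"], row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt_df(x$events[c("nest_id", "tag_id", "time", "direction",
                                     "provenance")]),
                   paths["events"], row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt_df(removals(x)), paths["removals"],
                   row.names = FALSE, quote = FALSE)
  invisible(paths)
}
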