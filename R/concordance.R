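#' @name concordance
#' @title RFID versus in-person observation concordance
#'
#' @description
#' Validation of the RFID event stream against concurrent human
#' observation: inside declared observation sessions, inferred events and
#' observer-logged queen events are matched one-to-one by time proximity,
#' and the two error rates are reported — the percentage of observer
#' events the RFID system missed or mislabeled, and the percentage of
#' RFID events the observer missed.
NULL

#' Build the RFID event stream for concordance
#'
#' Returns the inferred directed events, optionally appending unresolvable
#' lone reads as direction-unknown detections — passages the reader
#' registered but whose direction the filtering rules could not recover.
#'
#' @param inference An `rfid_inference` object.
#' @param include_unresolvable Append direction-`NA` events for
#'   unresolvable lone reads.
#' @return Data.frame `nest_id`, `tag_id`, `time`, `direction` (`NA` for
#'   direction-unknown).
#' @export
concordance_events <- function(inference, include_unresolvable = TRUE) {
  stopifnot(inherits(inference, "rfid_inference"))
  ev <- inference$events[c("nest_id", "tag_id", "time", "direction")]
  if (include_unresolvable) {
    un <- inference$read_removals
    un <- un[un$reason == "UNRESOLVABLE", , drop = FALSE]
    if (nrow(un)) {
      ev <- rbind(ev, data.frame(nest_id = un$nest_id, tag_id = un$tag_id,
                                 time = un$time, direction = NA_character_,
                                 stringsAsFactors = FALSE))
    }
  }
  ev <- ev[order(ev$nest_id, ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

check_sessions <- function(sessions) {
  stopifnot(all(c("nest_id", "start", "end") %in% names(sessions)))
  if (any(sessions$start >= sessions$end)) {
    stop("session start must precede end", call. = FALSE)
  }
  for (p in split(sessions, sessions$nest_id)) {
    p <- p[order(p$start), , drop = FALSE]
    if (nrow(p) > 1 && any(p$start[-1] < p$end[-nrow(p)])) {
      stop("overlapping observation sessions for nest ", p$nest_id[1],
           call. = FALSE)
    }
  }
  invisible(sessions)
}

in_sessions <- function(time, nest, sessions) {
  hit <- rep(FALSE, length(time))
  for (j in seq_len(nrow(sessions))) {
    hit <- hit | (nest == sessions$nest_id[j] &
                    time >= sessions$start[j] & time <= sessions$end[j])
  }
  hit
}

# Greedy one-to-one matching by minimal |dt| within tolerance; ties broken
# by earlier observer event, then earlier RFID event. Returns index pairs.
match_greedy <- function(t_obs, t_rfid, tol) {
  cand <- NULL
  for (i in seq_along(t_obs)) {
    dt <- abs(as.numeric(t_rfid) - as.numeric(t_obs[i]))
    j <- which(dt <= tol)
    if (length(j)) {
      cand <- rbind(cand, data.frame(i = i, j = j, dt = dt[j]))
    }
  }
  pairs <- NULL
  if (!is.null(cand)) {
    cand <- cand[order(cand$dt, cand$i, cand$j), , drop = FALSE]
    used_i <- logical(length(t_obs))
    used_j <- logical(length(t_rfid))
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (!used_i[i] && !used_j[j]) {
        used_i[i] <- TRUE; used_j[j] <- TRUE
        pairs <- rbind(pairs, cand[k, c("i", "j", "dt")])
      }
    }
  }
  if (is.null(pairs)) data.frame(i = integer(0), j = integer(0),
                                 dt = numeric(0)) else pairs
}

# Optimal non-crossing matching: maximizes the number of matches, then
# minimizes total |dt|, by dynamic programming over the two time-sorted
# streams (with |dt| costs an optimal matching can be taken non-crossing).
match_optimal <- function(t_obs, t_rfid, tol) {
  n <- length(t_obs); m <- length(t_rfid)
  big <- (tol + 1) * (n + m + 1)
  score <- matrix(0, n + 1, m + 1)   # count * big - total dt
  take <- matrix(0L, n + 1, m + 1)   # 1 = match (i,j), 2 = skip i, 3 = skip j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s_skip_i <- score[i, j + 1]
      s_skip_j <- score[i + 1, j]
      best <- s_skip_i; t <- 2L
      if (s_skip_j > best) { best <- s_skip_j; t <- 3L }
      dt <- abs(as.numeric(t_obs[i]) - as.numeric(t_rfid[j]))
      if (dt <= tol) {
        s_match <- score[i, j] + big - dt
        if (s_match > best) { best <- s_match; t <- 1L }
      }
      score[i + 1, j + 1] <- best
      take[i + 1, j + 1] <- t
    }
  }
  pairs <- NULL
  i <- n; j <- m
  while (i > 0 && j > 0) {
    t <- take[i + 1, j + 1]
    if (t == 1L) {
      pairs <- rbind(data.frame(
        i = i, j = j,
        dt = abs(as.numeric(t_obs[i]) - as.numeric(t_rfid[j]))), pairs)
      i <- i - 1; j <- j - 1
    } else if (t == 2L) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  if (is.null(pairs)) data.frame(i = integer(0), j = integer(0),
                                 dt = numeric(0)) else pairs
}

#' Match RFID events to in-person observations
#'
#' Within the declared observation sessions, observer-logged queen events
#' and RFID events of the same nest are matched one-to-one by minimal time
#' difference within `tolerance_s`. A matched pair with disagreeing
#' directions counts as mislabeled; a match to a direction-unknown RFID
#' event counts separately; unmatched observer events were missed by the
#' RFID system, unmatched RFID events were missed by the observer.
#'
#' @param rfid_events Data.frame `nest_id`, `time`, `direction` (`NA`
#'   allowed for direction-unknown); see [concordance_events()].
#' @param observations Observer log from [read_observations()]; worker
#'   rows are dropped here.
#' @param sessions Data.frame `nest_id`, `start`, `end` (POSIXct UTC) of
#'   the observation sessions. Overlapping sessions for one nest are an
#'   error.
#' @param tolerance_s Matching tolerance in seconds; must be positive.
#' @param method `"greedy"` (minimal-gap first, deterministic tie-break by
#'   earlier event) or `"optimal"` (non-crossing matching maximizing match
#'   count then minimizing total gap).
#' @return Object of class `concordance_result`: counts
#'   (`n_obs_events`, `n_rfid_events`, `n_matched`, `n_mislabeled`,
#'   `n_direction_unknown`, `rfid_missed`, `observer_missed`), the two
#'   rates in percent (`rate_rfid_error`: observer events missed,
#'   mislabeled or direction-unknown; `rate_observer_missed`), session
#'   coverage in hours, and the matched pairs.
#' @export
match_events <- function(rfid_events, observations, sessions,
                         tolerance_s = 120, method = c("greedy", "optimal")) {
  method <- match.arg(method)
  if (!is.numeric(tolerance_s) || tolerance_s <= 0) {
    stop("tolerance must be > 0", call. = FALSE)
  }
  check_sessions(sessions)
  obs <- observations[as.character(observations$caste) == "QUEEN", ,
                      drop = FALSE]
  obs <- obs[in_sessions(obs$time, obs$nest_id, sessions), , drop = FALSE]
  rf <- rfid_events[in_sessions(rfid_events$time, rfid_events$nest_id,
                                sessions), , drop = FALSE]
  obs <- obs[order(obs$nest_id, obs$time), , drop = FALSE]
  rf <- rf[order(rf$nest_id, rf$time), , drop = FALSE]
  n_matched <- n_mislabeled <- n_unknown <- 0L
  all_pairs <- NULL
  for (nest in unique(c(obs$nest_id, rf$nest_id))) {
    o <- obs[obs$nest_id == nest, , drop = FALSE]
    r <- rf[rf$nest_id == nest, , drop = FALSE]
    pairs <- if (method == "greedy") {
      match_greedy(o$time, r$time, tolerance_s)
    } else {
      match_optimal(o$time, r$time, tolerance_s)
    }
    if (nrow(pairs)) {
      dir_o <- as.character(o$direction[pairs$i])
      dir_r <- as.character(r$direction[pairs$j])
      unknown <- is.na(dir_r)
      n_unknown <- n_unknown + sum(unknown)
      n_matched <- n_matched + sum(!unknown)
      n_mislabeled <- n_mislabeled + sum(!unknown & dir_o != dir_r)
      all_pairs <- rbind(all_pairs, data.frame(
        nest_id = nest, obs_time = o$time[pairs$i],
        rfid_time = r$time[pairs$j], dt_s = pairs$dt,
        obs_direction = dir_o, rfid_direction = dir_r,
        stringsAsFactors = FALSE))
    }
  }
  n_obs <- nrow(obs); n_rfid <- nrow(rf)
  rfid_missed <- n_obs - n_matched - n_unknown
  observer_missed <- n_rfid - n_matched - n_unknown
  out <- list(
    n_obs_events = n_obs, n_rfid_events = n_rfid,
    n_matched = n_matched, n_mislabeled = n_mislabeled,
    n_direction_unknown = n_unknown,
    rfid_missed = rfid_missed, observer_missed = observer_missed,
    rate_rfid_error = if (n_obs > 0) {
      100 * (rfid_missed + n_mislabeled + n_unknown) / n_obs
    } else NA_real_,
    rate_observer_missed = if (n_rfid > 0) {
      100 * observer_missed / n_rfid
    } else NA_real_,
    session_hours = sum(as.numeric(difftime(sessions$end, sessions$start,
                                            units = "hours"))),
    tolerance_s = tolerance_s, method = method,
    pairs = if (is.null(all_pairs)) {
      data.frame(nest_id = character(0),
                 obs_time = parse_utc_time(character(0)),
                 rfid_time = parse_utc_time(character(0)),
                 dt_s = numeric(0), obs_direction = character(0),
                 rfid_direction = character(0))
    } else all_pairs)
  class(out) <- "concordance_result"
  out
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("RFID vs in-person concordance (%.2f h of sessions, tolerance %g s, %s matching)\n",
              x$session_hours, x$tolerance_s, x$method))
  cat(sprintf("  events: %d observer, %d RFID; matched %d (%d mislabeled), %d direction-unknown\n",
              x$n_obs_events, x$n_rfid_events, x$n_matched, x$n_mislabeled,
              x$n_direction_unknown))
  cat(sprintf("  RFID missed or mislabeled %.1f%% of observer events\n",
              x$rate_rfid_error))
  cat(sprintf("  observer missed %.1f%% of RFID events\n",
              x$rate_observer_missed))
  invisible(x)
}

#' Tolerance sensitivity of the concordance rates
#'
#' Re-runs [match_events()] over a ladder of matching tolerances, since no
#' single tolerance is canonical for aligning a wristwatch log with reader
#' timestamps.
#'
#' @inheritParams match_events
#' @param tolerances Tolerances in seconds.
#' @return Data.frame, one row per tolerance, with the counts and rates.
#' @export
concordance_sensitivity <- function(rfid_events, observations, sessions,
                                    tolerances = c(30, 60, 120, 300),
                                    method = "greedy") {
  rows <- lapply(tolerances, function(tol) {
    r <- match_events(rfid_events, observations, sessions, tol, method)
    data.frame(tolerance_s = tol, n_matched = r$n_matched,
               n_mislabeled = r$n_mislabeled,
               n_direction_unknown = r$n_direction_unknown,
               rfid_missed = r$rfid_missed,
               observer_missed = r$observer_missed,
               rate_rfid_error = r$rate_rfid_error,
               rate_observer_missed = r$rate_observer_missed)
  })
  do.call(rbind, rows)
}
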