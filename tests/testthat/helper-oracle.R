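# Brute-force reference pipeline, independent of the streaming
# implementation. Pairing enumerates every matching of adjacent
# opposite-board reads within the window and selects the earliest-first
# maximal one lexicographically; the later stages are re-derived with
# plain list processing.

oracle_infer <- function(reads, config = pipeline_config(), power = NULL) {
  W <- config$pairing_window_s
  n0 <- nrow(reads)
  # 1. same-board re-read suppression (gap to previous raw read)
  keep <- rep(TRUE, n0)
  if (n0 > 1) {
    for (i in 2:n0) {
      gap <- as.numeric(reads$time[i]) - as.numeric(reads$time[i - 1])
      if (as.character(reads$board[i]) == as.character(reads$board[i - 1]) &&
          gap < W) {
        keep[i] <- FALSE
      }
    }
  }
  r <- reads[keep, , drop = FALSE]
  n <- nrow(r)
  t <- as.numeric(r$time)
  b <- as.character(r$board)
  # 2. all matchings of adjacent eligible pairs, as lists of start indices
  edge <- if (n > 1) {
    vapply(seq_len(n - 1),
           function(i) b[i] != b[i + 1] && (t[i + 1] - t[i]) < W,
           logical(1))
  } else {
    logical(0)
  }
  enum <- function(i) {
    if (i > n) return(list(integer(0)))
    out <- lapply(enum(i + 1), function(m) m)           # leave i lone
    if (i < n && edge[i]) {
      out <- c(out, lapply(enum(i + 2), function(m) c(i, m)))
    }
    out
  }
  matchings <- enum(1L)
  key <- vapply(matchings, function(m) {
    ind <- rep("0", n)
    ind[m] <- "1"
    paste(ind, collapse = "")
  }, character(1))
  best <- matchings[[which(key == max(key))[1]]]
  paired_first <- sort(best)
  # 3. label pairs; items = events + lone reads on one timeline
  items <- list()
  consumed <- rep(FALSE, n)
  for (i in paired_first) consumed[c(i, i + 1L)] <- TRUE
  for (i in paired_first) {
    items[[length(items) + 1]] <- list(
      time = t[i + 1], kind = "event",
      dir = if (b[i] == "INNER") "EXIT" else "ENTRANCE",
      provenance = "PAIRED")
  }
  for (i in which(!consumed)) {
    items[[length(items) + 1]] <- list(time = t[i], kind = "lone",
                                       board = b[i])
  }
  ord <- order(vapply(items, `[[`, numeric(1), "time"),
               vapply(items, function(x) x$kind == "lone", logical(1)))
  items <- items[ord]
  # 4. relabel lone reads with matching flanks (single pass)
  m <- length(items)
  relab <- rep(FALSE, m)
  newdir <- rep(NA_character_, m)
  for (k in seq_len(m)) {
    if (items[[k]]$kind != "lone" || k == 1 || k == m) next
    p <- items[[k - 1]]; q <- items[[k + 1]]
    if (p$kind == "event" && q$kind == "event" && p$dir == q$dir) {
      relab[k] <- TRUE
      newdir[k] <- if (p$dir == "ENTRANCE") "EXIT" else "ENTRANCE"
    }
  }
  for (k in which(relab)) {
    items[[k]] <- list(time = items[[k]]$time, kind = "event",
                       dir = newdir[k], provenance = "RELABELED_LONE")
  }
  # 5. spurious inner rule on the remaining timeline, else unresolvable
  n_spurious <- 0L
  n_unresolvable <- 0L
  drop_item <- rep(FALSE, length(items))
  for (k in seq_along(items)) {
    if (items[[k]]$kind != "lone") next
    spur <- FALSE
    if (items[[k]]$board == "INNER" && k > 1) {
      p <- items[[k - 1]]
      spur <- (p$kind == "event" && p$dir == "ENTRANCE") ||
        (p$kind == "lone" && p$board == "INNER")
    }
    if (spur) n_spurious <- n_spurious + 1L else
      n_unresolvable <- n_unresolvable + 1L
    drop_item[k] <- TRUE
  }
  events <- items[!drop_item]
  ev_time <- vapply(events, `[[`, numeric(1), "time")
  ev_dir <- vapply(events, `[[`, character(1), "dir")
  ev_prov <- vapply(events, `[[`, character(1), "provenance")
  # 6. alternation scan + filters
  trips <- list(); stays <- list(); n_anom <- 0L
  if (length(events) > 1) {
    for (k in seq_len(length(events) - 1)) {
      d <- ev_time[k + 1] - ev_time[k]
      if (ev_dir[k] == ev_dir[k + 1] || d <= 0) {
        n_anom <- n_anom + 1L
      } else if (ev_dir[k] == "EXIT") {
        trips[[length(trips) + 1]] <- c(ev_time[k], ev_time[k + 1])
      } else {
        stays[[length(stays) + 1]] <- c(ev_time[k], ev_time[k + 1])
      }
    }
  }
  n_micro <- 0L; n_power <- 0L; kept_trips <- list()
  for (tr in trips) {
    if (tr[2] - tr[1] < config$min_trip_s) {
      n_micro <- n_micro + 1L
      next
    }
    hit <- FALSE
    if (!is.null(power) && nrow(power)) {
      for (j in seq_len(nrow(power))) {
        if (tr[1] < as.numeric(power$off_end[j]) &&
            tr[2] > as.numeric(power$off_start[j])) hit <- TRUE
      }
    }
    if (hit) n_power <- n_power + 1L else
      kept_trips[[length(kept_trips) + 1]] <- tr
  }
  kept_stays <- list()
  for (st in stays) {
    hit <- FALSE
    if (!is.null(power) && nrow(power)) {
      for (j in seq_len(nrow(power))) {
        if (st[1] < as.numeric(power$off_end[j]) &&
            st[2] > as.numeric(power$off_start[j])) hit <- TRUE
      }
    }
    if (!hit) kept_stays[[length(kept_stays) + 1]] <- st
  }
  list(
    event_time = ev_time, event_direction = ev_dir,
    event_provenance = ev_prov,
    trip_durations = vapply(kept_trips, function(x) x[2] - x[1], numeric(1)),
    stay_durations = vapply(kept_stays, function(x) x[2] - x[1], numeric(1)),
    n_spurious = n_spurious, n_unresolvable = n_unresolvable,
    n_micro = n_micro, n_power = n_power, n_anomalies = n_anom,
    n_collapsed = sum(!keep))
}

expect_matches_oracle <- function(reads, config = pipeline_config(),
                                  power = NULL) {
  inf <- infer_trips(reads, power, config)
  orc <- oracle_infer(reads, config, power)
  expect_equal(as.numeric(inf$events$time), orc$event_time)
  expect_equal(inf$events$direction, orc$event_direction)
  expect_equal(inf$events$provenance, orc$event_provenance)
  expect_equal(sort(inf$trips$duration_s), sort(orc$trip_durations))
  expect_equal(sort(inf$stays$duration_s), sort(orc$stay_durations))
  expect_identical(inf$counts$n_spurious_inner, orc$n_spurious)
  expect_identical(inf$counts$n_unresolvable, orc$n_unresolvable)
  expect_identical(inf$counts$n_micro_removed, orc$n_micro)
  expect_identical(inf$counts$n_power_removed, orc$n_power)
  expect_identical(inf$counts$n_anomalies, orc$n_anomalies)
  expect_identical(inf$counts$n_collapsed, orc$n_collapsed)
  invisible(inf)
}
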