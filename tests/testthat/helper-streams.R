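# builders for small read streams and event tables used across tests

base_time <- as.POSIXct("2022-06-20 08:00:00", tz = "UTC")

make_reads <- function(offsets_s, boards, tag_id = "Q1", nest_id = "N1",
                       t0 = base_time) {
  stopifnot(length(offsets_s) == length(boards))
  n <- length(offsets_s)
  df <- data.frame(nest_id = rep_len(nest_id, n),
                   tag_id = rep_len(tag_id, n),
                   time = t0 + offsets_s,
                   board = factor(boards, c("INNER", "OUTER")),
                   stringsAsFactors = FALSE)
  df <- df[order(df$time, as.integer(df$board)), , drop = FALSE]
  rownames(df) <- NULL
  df$read_id <- seq_len(nrow(df))
  df
}

make_events <- function(offsets_s, directions, tag_id = "Q1",
                        t0 = base_time) {
  data.frame(tag_id = tag_id, time = t0 + offsets_s,
             direction = directions, provenance = "PAIRED",
             read1_id = NA_integer_, read2_id = NA_integer_,
             stringsAsFactors = FALSE)
}

make_power <- function(off_start_s, off_end_s, nest_id = "N1",
                       t0 = base_time) {
  data.frame(nest_id = nest_id, off_start = t0 + off_start_s,
             off_end = t0 + off_end_s, stringsAsFactors = FALSE)
}

# random read stream exercising pairing, collapse, relabel and removal paths
random_stream <- function(n, t0 = base_time) {
  if (n == 0) return(make_reads(numeric(0), character(0), t0 = t0))
  gaps <- sample(c(1, 2, 4, 8, 9, 10, 11, 15, 40, 200), n - 1,
                 replace = TRUE)
  offs <- cumsum(c(0, gaps))
  boards <- sample(c("INNER", "OUTER"), n, replace = TRUE)
  make_reads(offs, boards, t0 = t0)
}

tmpcsv <- function() tempfile(fileext = ".csv")

make_trips <- function(exit_offsets_s, durations_s, tag_id = "Q1",
                       nest_id = "N1", t0 = base_time,
                       config = pipeline_config()) {
  exit_time <- t0 + exit_offsets_s
  data.frame(tag_id = tag_id, nest_id = nest_id, exit_time = exit_time,
             entrance_time = exit_time + durations_s,
             duration_s = durations_s,
             trip_class = queentrack:::classify_trip(durations_s, config),
             power_interrupted = FALSE,
             overnight_flag = durations_s > config$overnight_min_h * 3600,
             stringsAsFactors = FALSE)
}

make_queens <- function(queen_id, brood, fate) {
  data.frame(queen_id = queen_id, nest_id = paste0("N_", queen_id),
             species = "Bombus sp.", year = 2022L,
             tag_date = as.Date("2022-06-01"),
             brood_stage_at_tagging = factor(brood,
               c("EGGS", "YOUNG_LARVAE", "MATURE_LARVAE", "PUPAE", "WORKERS")),
             fate = factor(fate,
               c("SELECTED_ABSCONDED", "COLONIZED_ABSCONDED", "DIED",
                 "WORKERS_NO_GYNES", "GYNES")),
             worker_first_forage_date = as.Date(NA),
             role = factor("RESIDENT", c("RESIDENT", "INVADER")),
             stringsAsFactors = FALSE)
}
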