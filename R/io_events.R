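#' @name io_events
#' @title On-disk schemas for RFID read streams and study metadata
#'
#' @description
#' All inputs are UTF-8 comma-separated files with a header row. Timestamps
#' are ISO 8601 in UTC (`2022-06-16T08:00:00Z`; a space instead of the `T`
#' is accepted on input), 1 s resolution. The canonical schemas are:
#'
#' * `reads.csv` — `nest_id,tag_id,time,board`, one antenna detection per
#'   row, `board` one of `INNER`, `OUTER`.
#' * `power.csv` — `nest_id,off_start,off_end`, one reader power-off
#'   interval (battery change) per row.
#' * `queens.csv` — `queen_id,nest_id,species,year,tag_date,`
#'   `brood_stage_at_tagging,fate,worker_first_forage_date,role`.
#' * `observations.csv` — `nest_id,time,direction,caste`, one in-person
#'   observation of a bee crossing the nest entrance per row.
#'
#' Readers are strict: a missing or misnamed column is a schema error, and
#' any row that fails validation is reported by its data row number; rows
#' are never silently dropped. Duplicate identical read rows (a stationary
#' bee re-read within the same second) are deduplicated with a message.
#' Reads are returned sorted by `(nest_id, tag_id, time)` with the fixed
#' tie-break that `INNER` sorts before `OUTER` at equal timestamps.
NULL

QT_BOARDS <- c("INNER", "OUTER")
QT_DIRECTIONS <- c("ENTRANCE", "EXIT")
QT_CASTES <- c("QUEEN", "WORKER")
QT_BROOD_STAGES <- c("EGGS", "YOUNG_LARVAE", "MATURE_LARVAE", "PUPAE", "WORKERS")
QT_FATES <- c("SELECTED_ABSCONDED", "COLONIZED_ABSCONDED", "DIED",
              "WORKERS_NO_GYNES", "GYNES")
QT_ROLES <- c("RESIDENT", "INVADER")

read_csv_strict <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (!identical(names(df), columns)) {
    stop("schema error in ", basename(path), ": expected columns [",
         paste(columns, collapse = ","), "], found [",
         paste(names(df), collapse = ","), "]", call. = FALSE)
  }
  df
}

row_errors <- function(bad, what, values = NULL) {
  if (!any(bad)) return(character(0))
  rows <- which(bad)
  shown <- utils::head(rows, 10)
  msg <- sprintf("%s in data row(s) %s", what,
                 paste(shown, collapse = ", "))
  if (!is.null(values)) {
    msg <- paste0(msg, " (e.g. ", values[shown[1]], ")")
  }
  if (length(rows) > length(shown)) {
    msg <- paste0(msg, sprintf(" and %d more", length(rows) - length(shown)))
  }
  msg
}

stop_if_row_errors <- function(errs, path) {
  errs <- unlist(errs)
  if (length(errs)) {
    stop("invalid rows in ", basename(path), ":\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
}

check_enum <- function(x, levels, what) {
  row_errors(!x %in% levels, paste0("invalid ", what), x)
}

#' Read a raw RFID read log
#'
#' @param path Path to a `reads.csv` file (`nest_id,tag_id,time,board`).
#' @return A data.frame with columns `nest_id`, `tag_id`, `time` (POSIXct,
#'   UTC), `board` (factor `INNER`/`OUTER`) and `read_id` (stable integer id
#'   assigned after sorting), sorted by `(nest_id, tag_id, time)` with
#'   `INNER` before `OUTER` at ties. Exact duplicate rows are dropped with a
#'   message; the count is kept in attribute `n_deduplicated`.
#' @seealso [io_events] for the schema contract.
#' @export
read_raw_reads <- function(path) {
  df <- read_csv_strict(path, c("nest_id", "tag_id", "time", "board"))
  time <- parse_utc_time(df$time)
  errs <- list(
    row_errors(is.na(time) | !nzchar(df$time), "unparseable timestamp", df$time),
    check_enum(df$board, QT_BOARDS, "board"),
    row_errors(!nzchar(df$nest_id), "empty nest_id"),
    row_errors(!nzchar(df$tag_id), "empty tag_id")
  )
  stop_if_row_errors(errs, path)
  out <- data.frame(nest_id = df$nest_id, tag_id = df$tag_id, time = time,
                    board = factor(df$board, levels = QT_BOARDS),
                    stringsAsFactors = FALSE)
  dup <- duplicated(out)
  if (any(dup)) {
    message(sum(dup), " duplicate identical read row(s) deduplicated")
    out <- out[!dup, , drop = FALSE]
  }
  out <- sort_reads(out)
  out$read_id <- seq_len(nrow(out))
  attr(out, "n_deduplicated") <- sum(dup)
  out
}

# (nest, tag, time) order with INNER before OUTER at equal times
sort_reads <- function(reads) {
  o <- order(reads$nest_id, reads$tag_id, reads$time, as.integer(reads$board))
  reads <- reads[o, , drop = FALSE]
  rownames(reads) <- NULL
  reads
}

#' Write a raw read table in canonical form
#'
#' Writing and re-reading a canonical table reproduces it exactly.
#'
#' @param reads Data.frame as returned by [read_raw_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raw_reads <- function(reads, path) {
  out <- data.frame(nest_id = reads$nest_id, tag_id = reads$tag_id,
                    time = format_utc_time(reads$time),
                    board = as.character(reads$board))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reader power-outage log
#'
#' Overlapping or touching intervals for the same nest are merged with a
#' warning (a battery change logged twice is one loss of coverage).
#'
#' @param path Path to a `power.csv` file (`nest_id,off_start,off_end`).
#' @return Data.frame `nest_id`, `off_start`, `off_end` (POSIXct UTC),
#'   sorted, with disjoint intervals per nest.
#' @export
read_power_log <- function(path) {
  df <- read_csv_strict(path, c("nest_id", "off_start", "off_end"))
  off_start <- parse_utc_time(df$off_start)
  off_end <- parse_utc_time(df$off_end)
  errs <- list(
    row_errors(is.na(off_start), "unparseable off_start", df$off_start),
    row_errors(is.na(off_end), "unparseable off_end", df$off_end),
    row_errors(!is.na(off_start) & !is.na(off_end) & off_start >= off_end,
               "off_start not before off_end")
  )
  stop_if_row_errors(errs, path)
  out <- data.frame(nest_id = df$nest_id, off_start = off_start,
                    off_end = off_end, stringsAsFactors = FALSE)
  merge_power_intervals(out)
}

merge_power_intervals <- function(power) {
  if (nrow(power) == 0) return(power)
  power <- power[order(power$nest_id, power$off_start), , drop = FALSE]
  pieces <- lapply(split(power, power$nest_id), function(p) {
    keep_start <- p$off_start[1]
    keep_end <- p$off_end[1]
    starts <- ends <- rep(p$off_start[1], 0)
    for (i in seq_len(nrow(p))[-1]) {
      if (p$off_start[i] <= keep_end) {
        keep_end <- max(keep_end, p$off_end[i])
      } else {
        starts <- c(starts, keep_start); ends <- c(ends, keep_end)
        keep_start <- p$off_start[i]; keep_end <- p$off_end[i]
      }
    }
    starts <- c(starts, keep_start); ends <- c(ends, keep_end)
    data.frame(nest_id = p$nest_id[1], off_start = starts, off_end = ends,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  if (nrow(out) < nrow(power)) {
    warning(nrow(power) - nrow(out),
            " overlapping power interval(s) merged", call. = FALSE)
  }
  out
}

#' Write a power-outage table in canonical form
#' @param power Data.frame as returned by [read_power_log()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_power_log <- function(power, path) {
  out <- data.frame(nest_id = power$nest_id,
                    off_start = format_utc_time(power$off_start),
                    off_end = format_utc_time(power$off_end))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read queen metadata
#'
#' @param path Path to a `queens.csv` file; see [io_events] for columns.
#'   `worker_first_forage_date` may be empty (queens that never produced
#'   foraging workers); a fate implying workers without a date draws a
#'   warning but is accepted.
#' @return Data.frame with typed columns (`Date` dates, factor enums).
#' @export
read_queens <- function(path) {
  cols <- c("queen_id", "nest_id", "species", "year", "tag_date",
            "brood_stage_at_tagging", "fate", "worker_first_forage_date",
            "role")
  df <- read_csv_strict(path, cols)
  tag_date <- as.Date(df$tag_date, format = "%Y-%m-%d")
  wdate <- as.Date(df$worker_first_forage_date, format = "%Y-%m-%d")
  has_wdate <- nzchar(df$worker_first_forage_date)
  year <- suppressWarnings(as.integer(df$year))
  errs <- list(
    row_errors(!nzchar(df$queen_id), "empty queen_id"),
    row_errors(duplicated(df$queen_id), "duplicate queen_id", df$queen_id),
    row_errors(is.na(tag_date), "unparseable tag_date", df$tag_date),
    row_errors(has_wdate & is.na(wdate), "unparseable worker_first_forage_date",
               df$worker_first_forage_date),
    row_errors(is.na(year), "unparseable year", df$year),
    check_enum(df$brood_stage_at_tagging, QT_BROOD_STAGES, "brood_stage_at_tagging"),
    check_enum(df$fate, QT_FATES, "fate"),
    check_enum(df$role, QT_ROLES, "role"),
    row_errors(has_wdate & !is.na(wdate) & !is.na(tag_date) & wdate < tag_date,
               "worker_first_forage_date before tag_date")
  )
  stop_if_row_errors(errs, path)
  wdate[!has_wdate] <- NA
  needs_wdate <- df$fate %in% c("WORKERS_NO_GYNES", "GYNES") & !has_wdate
  if (any(needs_wdate)) {
    warning(sum(needs_wdate), " queen(s) with a worker-producing fate but no ",
            "worker_first_forage_date", call. = FALSE)
  }
  data.frame(
    queen_id = df$queen_id, nest_id = df$nest_id, species = df$species,
    year = year, tag_date = tag_date,
    brood_stage_at_tagging = factor(df$brood_stage_at_tagging, QT_BROOD_STAGES),
    fate = factor(df$fate, QT_FATES),
    worker_first_forage_date = wdate,
    role = factor(df$role, QT_ROLES),
    stringsAsFactors = FALSE
  )
}

#' Write queen metadata in canonical form
#' @param queens Data.frame as returned by [read_queens()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_queens <- function(queens, path) {
  out <- data.frame(
    queen_id = queens$queen_id, nest_id = queens$nest_id,
    species = queens$species, year = queens$year,
    tag_date = format(queens$tag_date, "%Y-%m-%d"),
    brood_stage_at_tagging = as.character(queens$brood_stage_at_tagging),
    fate = as.character(queens$fate),
    worker_first_forage_date = ifelse(
      is.na(queens$worker_first_forage_date), "",
      format(queens$worker_first_forage_date, "%Y-%m-%d")),
    role = as.character(queens$role)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an in-person observation log
#'
#' Worker rows are kept as-is: queen-only analyses (concordance) filter on
#' `caste` downstream.
#'
#' @param path Path to an `observations.csv` file
#'   (`nest_id,time,direction,caste`).
#' @return Data.frame `nest_id`, `time` (POSIXct UTC), `direction`, `caste`
#'   (factors), time-sorted within nest.
#' @export
read_observations <- function(path) {
  df <- read_csv_strict(path, c("nest_id", "time", "direction", "caste"))
  time <- parse_utc_time(df$time)
  errs <- list(
    row_errors(is.na(time), "unparseable timestamp", df$time),
    check_enum(df$direction, QT_DIRECTIONS, "direction"),
    check_enum(df$caste, QT_CASTES, "caste")
  )
  stop_if_row_errors(errs, path)
  out <- data.frame(nest_id = df$nest_id, time = time,
                    direction = factor(df$direction, QT_DIRECTIONS),
                    caste = factor(df$caste, QT_CASTES),
                    stringsAsFactors = FALSE)
  out <- out[order(out$nest_id, out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an observation log in canonical form
#' @param observations Data.frame as returned by [read_observations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path) {
  out <- data.frame(nest_id = observations$nest_id,
                    time = format_utc_time(observations$time),
                    direction = as.character(observations$direction),
                    caste = as.character(observations$caste))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
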