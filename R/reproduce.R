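#' Study-scale queen fate table (synthetic records)
#'
#' A per-queen fate table whose marginal counts equal the published study
#' flow — 18 queens observed in nest boxes, of which 5 selected a box but
#' absconded before laying, 13 colonized (laid eggs), 7 produced adult
#' workers and 3 produced gynes. The individual rows are synthetic
#' stand-ins (ids, dates and species are placeholders): only the fate
#' margins are meaningful, which is all [fate_flow()] consumes.
#'
#' @return A queens data.frame in the [read_queens()] shape.
#' @export
study_fate_table <- function() {
  fates <- rep(c("SELECTED_ABSCONDED", "COLONIZED_ABSCONDED", "DIED",
                 "WORKERS_NO_GYNES", "GYNES"), c(5, 4, 2, 4, 3))
  n <- length(fates)
  data.frame(
    queen_id = sprintf("SQ%02d", seq_len(n)),
    nest_id = sprintf("SN%02d", seq_len(n)),
    species = "Bombus sp.",
    year = 2022L,
    tag_date = as.Date("2022-06-01"),
    brood_stage_at_tagging = factor("YOUNG_LARVAE", QT_BROOD_STAGES),
    fate = factor(fates, QT_FATES),
    worker_first_forage_date = as.Date(ifelse(
      fates %in% c("WORKERS_NO_GYNES", "GYNES"), "2022-07-10", NA)),
    role = factor("RESIDENT", QT_ROLES),
    stringsAsFactors = FALSE)
}

#' Reproduce the study-level foraging summaries from raw reads
#'
#' Runs the full pipeline (`infer_trips`) and computes every study-level
#' summary quantity in one pass: total retained trips, the share shorter
#' than 4 h, pooled mean/median foraging-trip duration, pooled trips per
#' day over queen-days, micro-trip and spurious-inner-read removal counts,
#' overnight-absence summary, the per-queen summary table, the trimodal
#' stay summary, and (when queen metadata is supplied) the fate flow.
#'
#' @param reads Raw reads ([read_raw_reads()] shape).
#' @param power Optional power log ([read_power_log()] shape).
#' @param queens Optional queen metadata ([read_queens()] shape).
#' @param config A [pipeline_config()].
#' @return A list of class `published_summaries`; see Details above for
#'   the fields. `$inference` holds the underlying `rfid_inference`.
#' @export
published_summaries <- function(reads, power = NULL, queens = NULL,
                                config = pipeline_config()) {
  inf <- infer_trips(reads, power, config)
  trips <- inf$trips
  foraging <- trips[trips$trip_class == "FORAGING", , drop = FALSE]
  daily <- daily_trip_counts(foraging, config)
  per_queen <- summarize_queens(trips, config)
  ext <- extended_summary(trips)
  out <- list(
    n_trips = nrow(trips),
    n_foraging_trips = nrow(foraging),
    pct_under_4h = if (nrow(trips)) 100 * nrow(foraging) / nrow(trips)
      else NA_real_,
    mean_foraging_min = if (nrow(foraging)) mean(foraging$duration_s / 60)
      else NA_real_,
    sem_foraging_min = sem(foraging$duration_s / 60),
    median_foraging_min = if (nrow(foraging))
      stats::median(foraging$duration_s / 60) else NA_real_,
    trips_per_day_mean = if (nrow(daily)) mean(daily$n_trips) else NA_real_,
    trips_per_day_sem = sem(daily$n_trips),
    n_micro_removed = inf$counts$n_micro_removed,
    n_power_removed = inf$counts$n_power_removed,
    n_spurious_inner = inf$counts$n_spurious_inner,
    n_overnight = ext$n_overnight,
    overnight_mean_h = ext$mean_h,
    overnight_sem_h = ext$sem_h,
    per_queen = per_queen,
    stay_summary = stay_mixture_summary(inf$stays, config),
    fate = if (!is.null(queens)) fate_flow(queens) else NULL,
    inference = inf)
  class(out) <- "published_summaries"
  out
}

#' @export
print.published_summaries <- function(x, ...) {
  cat("Study-level foraging summaries\n")
  cat(sprintf("  %d trips retained; %.1f%% under 4 h\n",
              x$n_trips, x$pct_under_4h))
  cat(sprintf("  foraging trips: mean %.1f +/- %.1f min, median %.1f min\n",
              x$mean_foraging_min, x$sem_foraging_min,
              x$median_foraging_min))
  cat(sprintf("  trips/day over queen-days: %.1f +/- %.1f\n",
              x$trips_per_day_mean, x$trips_per_day_sem))
  cat(sprintf("  removals: %d micro, %d power, %d spurious inner reads\n",
              x$n_micro_removed, x$n_power_removed, x$n_spurious_inner))
  if (x$n_overnight > 0) {
    cat(sprintf("  overnight absences: %d, mean %.1f h\n",
                x$n_overnight, x$overnight_mean_h))
  }
  cat(sprintf("  %d queens summarized\n", nrow(x$per_queen)))
  invisible(x)
}
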