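cfg <- pipeline_config()

test_that("sem matches its closed form and is undefined below n = 2", {
  expect_equal(sem(c(1, 2, 3)), 1 / sqrt(3))
  expect_true(is.na(sem(5)))
  expect_equal(sem(rep(4.2, 4)), 0)
  expect_equal(sem(c(1, NA, 2, 3)), 1 / sqrt(3))
})

test_that("per-queen summaries use minutes and calendar-day denominators", {
  # three trips over two consecutive local days (2 + 1)
  trips <- make_trips(c(0, 3600, 86400), c(600, 1200, 1800))
  s <- summarize_queens(trips, cfg)
  expect_equal(nrow(s), 1)
  expect_equal(s$n_trips, 3)
  expect_equal(s$mean_duration_min, 20)
  expect_equal(s$trips_per_day_mean, 1.5)
  expect_equal(as.integer(s$last_date - s$first_date), 1L)
  # a single trip has no s.e.m.
  s1 <- summarize_queens(make_trips(0, 900), cfg)
  expect_equal(s1$mean_duration_min, 15)
  expect_true(is.na(s1$sem_duration_min))
  # a 5 h trip is excluded from foraging summaries
  s2 <- summarize_queens(make_trips(c(0, 3600), c(600, 5 * 3600)), cfg)
  expect_equal(s2$n_trips, 1)
  expect_equal(s2$mean_duration_min, 10)
})

test_that("zero-trip days count as zeros in the default trips/day span", {
  # 2 trips on day 1, none on day 2, 1 on day 3
  trips <- make_trips(c(0, 3600, 2 * 86400), c(600, 600, 600))
  d <- daily_trip_counts(trips, cfg)
  expect_equal(d$n_trips, c(2L, 0L, 1L))
  expect_equal(mean(d$n_trips), 1)
  da <- daily_trip_counts(trips, cfg, active_days_only = TRUE)
  expect_equal(da$n_trips, c(2L, 1L))
})

test_that("overnight absences are counted and summarized in hours", {
  none <- extended_summary(make_trips(0, 600))
  expect_equal(none$n_overnight, 0)
  expect_true(is.na(none$mean_h))
  one <- extended_summary(make_trips(c(0, 86400), c(13 * 3600, 600)))
  expect_equal(one$n_overnight, 1)
  expect_equal(one$mean_h, 13)
  expect_true(is.na(one$sem_h))
})

test_that("stays partition into the trimodal classes with per-class means", {
  stays <- data.frame(tag_id = "Q1", nest_id = "N1",
                      entrance_time = base_time + 0:3 * 86400,
                      exit_time = base_time + 0:3 * 86400 +
                        c(100, 30 * 60, 5 * 3600, 50),
                      duration_s = c(100, 30 * 60, 5 * 3600, 50),
                      stay_class = NA, stringsAsFactors = FALSE)
  s <- stay_mixture_summary(stays, cfg)
  expect_equal(s$stay_class, c("SHORT", "MID", "LONG"))
  expect_equal(s$n, c(2L, 1L, 1L))
  expect_equal(s$mean_duration_s, c(75, 1800, 18000))
  empty <- stay_mixture_summary(stays[0, ], cfg)
  expect_equal(empty$n, c(0L, 0L, 0L))
  expect_true(all(is.na(empty$mean_duration_s)))
})

test_that("stage windows are the first and last five foraging days", {
  # one trip per day for 12 days
  trips <- make_trips(86400 * (0:11), rep(600, 12))
  queens <- make_queens("Q1", "YOUNG_LARVAE", "GYNES")
  ss <- stage_subsets(trips, queens, cfg)
  expect_true(ss$queens$included)
  expect_equal(sum(ss$trips$stage == "EARLY"), 5)
  expect_equal(sum(ss$trips$stage == "LATE"), 5)
  expect_equal(range(ss$trips$date[ss$trips$stage == "EARLY"]),
               range(ss$daily$date[ss$daily$stage == "EARLY"]))
  expect_equal(nrow(ss$daily), 10)
  # day 6 and 7 trips belong to neither window
  expect_equal(nrow(ss$trips), 10)
})

test_that("stage eligibility follows brood stage and fate", {
  trips <- make_trips(86400 * (0:11), rep(600, 12))
  # eggs at tagging: no early window
  ss1 <- stage_subsets(trips, make_queens("Q1", "EGGS", "GYNES"), cfg)
  expect_false(ss1$queens$included)
  expect_equal(ss1$queens$reason, "MISSING_STAGE")
  # absconded before workers: no late window
  ss2 <- stage_subsets(trips, make_queens("Q1", "MATURE_LARVAE",
                                          "COLONIZED_ABSCONDED"), cfg)
  expect_false(ss2$queens$included)
  # span shorter than two windows is flagged out
  short <- make_trips(86400 * (0:7), rep(600, 8))
  ss3 <- stage_subsets(short, make_queens("Q1", "YOUNG_LARVAE", "GYNES"), cfg)
  expect_equal(ss3$queens$reason, "WINDOWS_OVERLAP")
})

test_that("fate flow reproduces the study percentages in both renderings", {
  ff <- fate_flow(study_fate_table())
  expect_equal(unname(ff$counts),
               c(18L, 5L, 13L, 7L, 3L))
  p <- ff$percentages
  expect_equal(p$pct_rounded[p$ratio == "gynes_of_eggs"], 23)
  expect_equal(p$pct[p$ratio == "gynes_of_workers"], 42.9)
  expect_equal(p$pct_truncated[p$ratio == "gynes_of_workers"], 42)
  expect_equal(p$pct_truncated[p$ratio == "gynes_of_observed"], 16)
  # no gynes: all shares zero
  ff0 <- fate_flow(make_queens(c("A", "B"), "EGGS",
                               c("COLONIZED_ABSCONDED", "DIED")))
  expect_true(all(ff0$percentages$pct == 0))
})

test_that("fate-flow node counts are monotone for any fate mix", {
  set.seed(7)
  fates <- c("SELECTED_ABSCONDED", "COLONIZED_ABSCONDED", "DIED",
             "WORKERS_NO_GYNES", "GYNES")
  for (rep in 1:20) {
    n <- sample(1:25, 1)
    q <- make_queens(sprintf("Q%02d", 1:n), "EGGS",
                     sample(fates, n, replace = TRUE))
    ff <- fate_flow(q)
    cc <- ff$counts
    expect_true(cc["GYNES"] <= cc["WORKERS"] &&
                  cc["WORKERS"] <= cc["EGGS"] &&
                  cc["EGGS"] <= cc["OBSERVED"])
    expect_equal(unname(cc["OBSERVED"]),
                 unname(cc["SELECTED_ONLY"] + cc["EGGS"]))
  }
})

test_that("summaries on simulator output recover the trip-duration mean", {
  hits <- 0
  for (s in 1:10) {
    sim <- simulate_colony(sim_config(n_days = 10, p_detect_inner = 1,
                                      p_detect_outer = 1, reread_prob = 0,
                                      outage_period_h = Inf), seed = s)
    inf <- infer_trips(sim$reads, sim$power, cfg)
    s1 <- summarize_queens(inf$trips, cfg)
    target <- 21.9 # configured foraging-trip mean, minutes
    if (abs(s1$mean_duration_min - target) <= 2 * s1$sem_duration_min +
        .Machine$double.eps) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 9)
})
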