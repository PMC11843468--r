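t0 <- as.POSIXct("2022-06-21 10:00:00", tz = "UTC")

rfid_df <- function(offsets_s, directions, nest_id = "N1") {
  data.frame(nest_id = nest_id, time = t0 + offsets_s,
             direction = directions, stringsAsFactors = FALSE)
}

obs_df <- function(offsets_s, directions, caste = "QUEEN", nest_id = "N1") {
  data.frame(nest_id = nest_id, time = t0 + offsets_s,
             direction = directions, caste = caste, stringsAsFactors = FALSE)
}

sessions_df <- function(start_s = -3600, end_s = 7200, nest_id = "N1") {
  data.frame(nest_id = nest_id, start = t0 + start_s, end = t0 + end_s,
             stringsAsFactors = FALSE)
}

test_that("events within tolerance match one-to-one with agreeing directions", {
  r <- match_events(rfid_df(0, "EXIT"), obs_df(30, "EXIT"), sessions_df(),
                    tolerance_s = 120)
  expect_equal(r$n_matched, 1)
  expect_equal(r$n_mislabeled, 0)
  expect_equal(r$rfid_missed, 0)
  expect_equal(r$observer_missed, 0)
  expect_equal(r$rate_rfid_error, 0)
  expect_equal(r$rate_observer_missed, 0)
})

test_that("a matched pair with disagreeing directions counts as mislabeled", {
  r <- match_events(rfid_df(0, "ENTRANCE"), obs_df(0, "EXIT"), sessions_df())
  expect_equal(r$n_matched, 1)
  expect_equal(r$n_mislabeled, 1)
  expect_equal(r$rate_rfid_error, 100)
  # direction-unknown RFID events count separately, still as RFID error
  r2 <- match_events(rfid_df(0, NA_character_), obs_df(10, "EXIT"),
                     sessions_df())
  expect_equal(r2$n_direction_unknown, 1)
  expect_equal(r2$n_matched, 0)
  expect_equal(r2$rate_rfid_error, 100)
})

test_that("unmatched events become missed counts on the correct side", {
  r <- match_events(rfid_df(0, "EXIT"),
                    obs_df(c(30, 3000), c("EXIT", "ENTRANCE")),
                    sessions_df())
  expect_equal(r$rfid_missed, 1)
  expect_equal(r$observer_missed, 0)
  expect_equal(r$rate_rfid_error, 50)
  # bookkeeping identity over observer events
  expect_equal(r$n_matched + r$n_direction_unknown + r$rfid_missed,
               r$n_obs_events)
})

test_that("worker observations and out-of-session events are excluded", {
  obs <- rbind(obs_df(30, "EXIT"), obs_df(60, "EXIT", caste = "WORKER"),
               obs_df(20000, "EXIT"))
  r <- match_events(rfid_df(0, "EXIT"), obs, sessions_df())
  expect_equal(r$n_obs_events, 1)
  rf <- rbind(rfid_df(0, "EXIT"), rfid_df(30000, "ENTRANCE"))
  r2 <- match_events(rf, obs_df(30, "EXIT"), sessions_df())
  expect_equal(r2$n_rfid_events, 1)
})

test_that("swapping the streams swaps the two miss counts", {
  rf <- rfid_df(c(0, 300, 900), c("EXIT", "ENTRANCE", "EXIT"))
  ob <- obs_df(c(20, 890, 2000, 2400),
               c("EXIT", "EXIT", "ENTRANCE", "EXIT"))
  a <- match_events(rf, ob, sessions_df())
  swapped <- rf
  swapped$caste <- "QUEEN"
  as_rfid <- ob[c("nest_id", "time", "direction")]
  b <- match_events(as_rfid, swapped, sessions_df())
  expect_equal(a$rfid_missed, b$observer_missed)
  expect_equal(a$observer_missed, b$rfid_missed)
  expect_equal(a$n_matched, b$n_matched)
})

test_that("invalid sessions and tolerances are refused", {
  s2 <- rbind(sessions_df(0, 3600), sessions_df(1800, 5400))
  expect_error(match_events(rfid_df(0, "EXIT"), obs_df(0, "EXIT"), s2),
               "overlapping")
  expect_error(match_events(rfid_df(0, "EXIT"), obs_df(0, "EXIT"),
                            sessions_df(), tolerance_s = 0),
               "tolerance")
  expect_error(match_events(rfid_df(0, "EXIT"), obs_df(0, "EXIT"),
                            sessions_df(3600, 0)),
               "precede")
})

test_that("optimal matching can beat greedy on interleaved events", {
  rf <- rfid_df(c(40, 90), c("EXIT", "EXIT"))
  ob <- obs_df(c(0, 50), c("EXIT", "EXIT"))
  g <- match_events(rf, ob, sessions_df(), tolerance_s = 45,
                    method = "greedy")
  o <- match_events(rf, ob, sessions_df(), tolerance_s = 45,
                    method = "optimal")
  expect_equal(g$n_matched, 1)
  expect_equal(o$n_matched, 2)
})

test_that("the tolerance sensitivity ladder is monotone in matches", {
  rf <- rfid_df(c(0, 200, 500, 1000), rep("EXIT", 4))
  ob <- obs_df(c(25, 290, 560, 1290), rep("EXIT", 4))
  sens <- concordance_sensitivity(rf, ob, sessions_df())
  expect_equal(nrow(sens), 4)
  expect_true(all(diff(sens$n_matched) >= 0))
  expect_true(all(diff(sens$rate_rfid_error) <= 0))
})

test_that("a perfect sensor shows zero error against a perfect observer", {
  scfg <- sim_config(n_days = 4, p_detect_inner = 1, p_detect_outer = 1,
                     reread_prob = 0, outage_period_h = Inf)
  sim <- simulate_colony(scfg, seed = 9)
  inf <- infer_trips(sim$reads, sim$power)
  rfid <- concordance_events(inf)
  obs <- data.frame(nest_id = "N1", time = sim$truth$time,
                    direction = sim$truth$direction, caste = "QUEEN",
                    stringsAsFactors = FALSE)
  ses <- data.frame(nest_id = "N1",
                    start = min(sim$truth$time) - 60,
                    end = max(sim$truth$time) + 60)
  r <- match_events(rfid, obs, ses, tolerance_s = 30)
  expect_equal(r$rate_rfid_error, 0)
  expect_equal(r$rate_observer_missed, 0)
  # degraded detection shows up as RFID error against the same observer
  scfg2 <- sim_config(n_days = 4, p_detect_inner = 0.85,
                      p_detect_outer = 0.85, reread_prob = 0,
                      outage_period_h = Inf)
  sim2 <- simulate_colony(scfg2, seed = 9)
  inf2 <- infer_trips(sim2$reads, sim2$power)
  obs2 <- data.frame(nest_id = "N1", time = sim2$truth$time,
                     direction = sim2$truth$direction, caste = "QUEEN",
                     stringsAsFactors = FALSE)
  ses2 <- data.frame(nest_id = "N1",
                     start = min(sim2$truth$time) - 60,
                     end = max(sim2$truth$time) + 60)
  r2 <- match_events(concordance_events(inf2), obs2, ses2, tolerance_s = 30)
  expect_gt(r2$rate_rfid_error, 0)
  expect_lt(r2$rate_rfid_error, 40)
})
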