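cfg <- pipeline_config()

test_that("opposite-board reads pair within a strict 10 s window", {
  # empty stream
  empty <- make_reads(numeric(0), character(0))
  pe <- pair_reads(empty, 10)
  expect_equal(nrow(pe$events), 0)
  expect_equal(nrow(pe$lone), 0)
  # inner then outer 5 s apart is one exit
  r <- make_reads(c(0, 5), c("INNER", "OUTER"))
  p <- pair_reads(r, 10)
  expect_equal(nrow(p$events), 1)
  expect_equal(p$events$direction, "EXIT")
  expect_equal(nrow(p$lone), 0)
  # the window boundary is strict: 10 s and 12 s gaps do not pair
  for (gap in c(10, 12)) {
    p2 <- pair_reads(make_reads(c(0, gap), c("INNER", "OUTER")), 10)
    expect_equal(nrow(p2$events), 0)
    expect_equal(nrow(p2$lone), 2)
  }
  # greedy earliest-first: pair (0,5), leave the third read lone
  p3 <- pair_reads(make_reads(c(0, 5, 8), c("INNER", "OUTER", "INNER")), 10)
  expect_equal(nrow(p3$events), 1)
  expect_equal(p3$events$direction, "EXIT")
  expect_equal(p3$lone$read_id, 3L)
})

test_that("direction labels follow board order; event time is the second read", {
  r <- make_reads(c(0, 3), c("INNER", "OUTER"))
  e <- label_direction(r[1, ], r[2, ])
  expect_equal(e$direction, "EXIT")
  expect_equal(as.numeric(e$time - base_time, units = "secs"), 3)
  r2 <- make_reads(c(0, 3), c("OUTER", "INNER"))
  e2 <- label_direction(r2[1, ], r2[2, ])
  expect_equal(e2$direction, "ENTRANCE")
  expect_error(label_direction(r[1, ], r[1, ]), "opposite boards")
  # simultaneous reads: the INNER-first tie-break fixes the direction
  rt <- make_reads(c(0, 0), c("OUTER", "INNER"))
  pt <- pair_reads(rt, 10)
  expect_equal(pt$events$direction, "EXIT")
})

test_that("same-board re-reads collapse onto the first read before pairing", {
  r <- make_reads(c(0, 5, 8), c("INNER", "INNER", "OUTER"))
  cl <- collapse_rereads(r, 10)
  expect_equal(cl$reads$read_id, c(1L, 3L))
  expect_equal(cl$collapsed$read_id, 2L)
  p <- pair_reads(cl$reads, 10)
  expect_equal(p$events$direction, "EXIT")
})

test_that("lone reads flanked by two same-direction events are relabeled", {
  lone <- make_reads(600, "INNER")
  # between two entrances -> exit
  ev <- make_events(c(0, 1200), c("ENTRANCE", "ENTRANCE"))
  rl <- relabel_lone_reads(ev, lone)
  expect_equal(nrow(rl$residual), 0)
  expect_equal(rl$events$direction, c("ENTRANCE", "EXIT", "ENTRANCE"))
  expect_equal(rl$events$provenance[2], "RELABELED_LONE")
  # between two exits -> entrance
  ev2 <- make_events(c(0, 1200), c("EXIT", "EXIT"))
  expect_equal(relabel_lone_reads(ev2, lone)$events$direction[2], "ENTRANCE")
  # mixed flanks stay unlabeled
  ev3 <- make_events(c(0, 1200), c("EXIT", "ENTRANCE"))
  rl3 <- relabel_lone_reads(ev3, lone)
  expect_equal(nrow(rl3$residual), 1)
  expect_equal(nrow(rl3$events), 2)
  # stream boundary: no predecessor, stays unlabeled
  rl4 <- relabel_lone_reads(make_events(1200, "ENTRANCE"), lone)
  expect_equal(nrow(rl4$residual), 1)
  # adjacent lone reads block each other even with same-direction outer flanks
  lone2 <- make_reads(c(500, 700), c("INNER", "INNER"))
  lone2$read_id <- c(5L, 6L)
  rl5 <- relabel_lone_reads(ev, lone2)
  expect_equal(nrow(rl5$residual), 2)
})

test_that("spurious inner lone reads after an entrance are removed and counted", {
  lone <- make_reads(600, "INNER")
  ev <- make_events(0, "ENTRANCE")
  sp <- drop_spurious_inner(ev, lone)
  expect_equal(nrow(sp$spurious), 1)
  expect_equal(nrow(sp$unresolvable), 0)
  # consecutive inner lone reads: second removed, first unresolvable
  lone2 <- make_reads(c(500, 700), c("INNER", "INNER"))
  sp2 <- drop_spurious_inner(make_events(0, "EXIT"), lone2)
  expect_equal(sp2$spurious$time, base_time + 700)
  expect_equal(sp2$unresolvable$time, base_time + 500)
  # outer lone after an exit is unresolvable, not spurious
  sp3 <- drop_spurious_inner(make_events(0, "EXIT"), make_reads(600, "OUTER"))
  expect_equal(nrow(sp3$spurious), 0)
  expect_equal(nrow(sp3$unresolvable), 1)
})

test_that("alternating events yield trips and stays; runs yield anomalies", {
  b <- build_trips_and_stays(make_events(c(0, 600), c("EXIT", "ENTRANCE")), cfg)
  expect_equal(b$trips$duration_s, 600)
  expect_equal(nrow(b$stays), 0)
  b2 <- build_trips_and_stays(
    make_events(c(0, 100, 700), c("ENTRANCE", "EXIT", "ENTRANCE")), cfg)
  expect_equal(b2$stays$duration_s, 100)
  expect_equal(b2$trips$duration_s, 600)
  b3 <- build_trips_and_stays(make_events(c(0, 500), c("EXIT", "EXIT")), cfg)
  expect_equal(nrow(b3$trips), 0)
  expect_equal(b3$anomalies$kind, "CONSECUTIVE_EXITS")
})

test_that("micro-trips and power-spanning trips are removed in order", {
  ev <- make_events(c(0, 29), c("EXIT", "ENTRANCE"))
  b <- build_trips_and_stays(ev, cfg)
  f <- filter_trips(b$trips, b$stays, NULL, cfg)
  expect_equal(nrow(f$trips), 0)
  expect_equal(f$removed_trips$removal_reason, "MICRO")
  # exactly 30 s is retained: the cutoff is strictly below
  ev2 <- make_events(c(0, 30), c("EXIT", "ENTRANCE"))
  b2 <- build_trips_and_stays(ev2, cfg)
  f2 <- filter_trips(b2$trips, b2$stays, NULL, cfg)
  expect_equal(f2$trips$duration_s, 30)
  # a trip spanning an outage is removed as power-interrupted
  ev3 <- make_events(c(0, 2400), c("EXIT", "ENTRANCE"))
  b3 <- build_trips_and_stays(ev3, cfg)
  f3 <- filter_trips(b3$trips, b3$stays, make_power(1200, 1500), cfg)
  expect_equal(nrow(f3$trips), 0)
  expect_equal(f3$removed_trips$removal_reason, "POWER")
  # and a stay spanning an outage is flagged invalid
  ev4 <- make_events(c(0, 2400), c("ENTRANCE", "EXIT"))
  b4 <- build_trips_and_stays(ev4, cfg)
  f4 <- filter_trips(b4$trips, b4$stays, make_power(1200, 1500), cfg)
  expect_equal(nrow(f4$stays), 0)
  expect_equal(nrow(f4$invalid_stays), 1)
})

test_that("trip and stay classes respect the configured boundaries", {
  expect_equal(classify_trip(c(29, 30, 4 * 3600, 4 * 3600 + 1), cfg),
               c("MICRO", "FORAGING", "FORAGING", "EXTENDED"))
  expect_equal(classify_stay(c(100, 179, 180, 4 * 3600, 4 * 3600 + 1), cfg),
               c("SHORT", "SHORT", "MID", "MID", "LONG"))
})

test_that("a missed passage merges two true trips into one plus an anomaly", {
  # exit, entrance, exit, entrance with the middle entrance+exit reads lost
  r <- make_reads(c(0, 2, 2000, 2002),
                  c("INNER", "OUTER", "INNER", "OUTER"))
  inf <- infer_trips(r, config = cfg)
  expect_equal(inf$counts$n_anomalies, 1)
  expect_equal(nrow(inf$trips), 0)
})

test_that("every raw read is accounted for exactly once", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(0:14, 1)
    reads <- random_stream(n)
    pw <- if (runif(1) < 0.3 && n > 0) {
      make_power(sample(0:200, 1), sample(300:2000, 1))
    } else NULL
    inf <- infer_trips(reads, pw, cfg)
    paired <- inf$events[inf$events$provenance == "PAIRED", ]
    relabeled <- inf$events[inf$events$provenance == "RELABELED_LONE", ]
    ids <- c(paired$read1_id, paired$read2_id, relabeled$read1_id,
             inf$read_removals$read_id)
    expect_equal(sort(ids), reads$read_id)
  }
})

test_that("trips and stays of one tag interleave without overlap", {
  set.seed(202)
  for (rep in 1:25) {
    inf <- infer_trips(random_stream(sample(4:14, 1)), config = cfg)
    iv <- rbind(
      data.frame(s = as.numeric(inf$trips$exit_time),
                 e = as.numeric(inf$trips$entrance_time)),
      data.frame(s = as.numeric(inf$stays$entrance_time),
                 e = as.numeric(inf$stays$exit_time)))
    iv <- iv[order(iv$s), , drop = FALSE]
    if (nrow(iv) > 1) {
      expect_true(all(iv$s[-1] >= iv$e[-nrow(iv)]))
    }
  }
})

test_that("inference is deterministic and matches the brute-force reference", {
  set.seed(303)
  for (rep in 1:100) {
    reads <- random_stream(sample(0:12, 1))
    pw <- if (runif(1) < 0.25 && nrow(reads) > 0) {
      make_power(sample(0:100, 1), sample(200:1500, 1))
    } else NULL
    expect_matches_oracle(reads, cfg, pw)
  }
  reads <- random_stream(12)
  i1 <- infer_trips(reads, config = cfg)
  i2 <- infer_trips(reads, config = cfg)
  expect_identical(i1$trips, i2$trips)
  expect_identical(i1$events, i2$events)
})

test_that("multiple tags at one nest are processed independently", {
  a <- make_reads(c(0, 3, 600, 603), c("INNER", "OUTER", "OUTER", "INNER"),
                  tag_id = "QA")
  b <- make_reads(c(1, 4, 700, 703), c("INNER", "OUTER", "OUTER", "INNER"),
                  tag_id = "QB")
  both <- rbind(a, b)
  both <- both[order(both$tag_id, both$time), ]
  both$read_id <- seq_len(nrow(both))
  inf <- infer_trips(both, config = cfg)
  expect_equal(sort(unique(inf$trips$tag_id)), c("QA", "QB"))
  expect_equal(nrow(inf$trips), 2)
  solo <- infer_trips(a, config = cfg)
  expect_equal(inf$trips$duration_s[inf$trips$tag_id == "QA"],
               solo$trips$duration_s)
})

test_that("mean inferred trip count degrades as detection probability drops", {
  ps <- c(1, 0.95, 0.9, 0.8)
  means <- sapply(ps, function(p) {
    counts <- sapply(1:200, function(s) {
      scfg <- sim_config(n_days = 2, p_detect_inner = p, p_detect_outer = p,
                         reread_prob = 0, outage_period_h = Inf)
      sim <- simulate_colony(scfg, seed = s)
      nrow(infer_trips(sim$reads, config = cfg)$trips)
    })
    mean(counts)
  })
  expect_true(all(diff(means) <= 0))
})

test_that("removal and event tables serialize with reason codes", {
  reads <- read_raw_reads(system.file("extdata", "worked_trace_reads.csv",
                                      package = "queentrack"))
  power <- read_power_log(system.file("extdata", "worked_trace_power.csv",
                                      package = "queentrack"))
  inf <- infer_trips(reads, power, cfg)
  rm <- removals(inf)
  expect_setequal(unique(rm$reason), c("SPURIOUS_INNER", "MICRO", "POWER"))
  dir <- file.path(tempdir(), "qt_out")
  paths <- write_inference(inf, dir)
  expect_true(all(file.exists(paths)))
  trips_back <- utils::read.csv(paths[["trips"]])
  expect_equal(nrow(trips_back), nrow(inf$trips))
})
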