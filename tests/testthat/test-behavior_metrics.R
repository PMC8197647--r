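test_that("lick summary reports latencies from extension and flags missing solutions", {
  trials <- data.frame(t_extend = c(100, 150), latency = c(1.5, NA),
                       n_licks = c(34, 0), sipper = c("left", "right"))
  ev <- make_events(trials)
  dff <- make_dff(rnorm(200 * 20), fs = 20)
  tm <- trialMetrics(segmentTrials(dff, ev))
  ls <- lickSummary(tm)
  cas <- ls[ls$solution == "casein", ]
  mal <- ls[ls$solution == "maltodextrin", ]
  expect_equal(cas$mean_latency, 1.5)
  expect_identical(cas$n_analyzable, 1L)
  # lickless maltodextrin trial: latency missing, not zero
  expect_true(is.na(mal$mean_latency))
  expect_identical(mal$n_lickless, 1L)
})

test_that("sample median latency tracks the generating distribution", {
  # log-normal latency with median 2 s, 45 forced trials
  hits <- 0
  for (seed in 1:20) {
    g <- generateSession(schedule = scheduleParams(
      n_free = 0, p_lick = 1, presession_s = 15,
      latency = list(casein = c(meanlog = log(2), sdlog = 0.5),
                     maltodextrin = c(meanlog = log(2), sdlog = 0.5))),
      seed = seed, sample_rate = 20)
    tr <- g$truth@trials
    med <- median(tr$t_first_lick - tr$t_extend, na.rm = TRUE)
    if (abs(med - 2) / 2 < 0.2) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("casein preference counts first-licked sippers on free trials", {
  mk <- function(n_cas, n_mal, n_none) {
    data.frame(trial_type = "free",
               solution = c(rep("casein", n_cas),
                            rep("maltodextrin", n_mal),
                            rep(NA, n_none)),
               t_first_lick = c(seq_len(n_cas + n_mal),
                                rep(NA, n_none)))
  }
  expect_equal(caseinPreference(mk(20, 0, 0))$preference, 1.0)
  expect_equal(caseinPreference(mk(10, 10, 0))$preference, 0.5)
  p <- caseinPreference(mk(13, 5, 2))
  expect_equal(p$preference, 13 / 18)
  expect_identical(p$n_no_choice, 2L)
  expect_identical(p$n_casein_choices + p$n_malt_choices + p$n_no_choice, 20L)
  expect_error(caseinPreference(mk(0, 0, 3)), "no choices")
})

test_that("preference is invariant under consistent sipper-side relabeling", {
  g <- quick_session(seed = 17,
                     schedule = tiny_schedule(n_forced = 0, n_free = 12))
  s <- preprocessSession(g$session)
  tm <- trialMetrics(segmentTrials(sessionSignal(s, "dff"), sessionEvents(s)))
  p1 <- caseinPreference(tm)
  # swap sides and solution_map together
  ev <- sessionEvents(g$session)@events
  ev$sipper_id <- c(left = "right", right = "left", none = "none")[ev$sipper_id]
  ev_swapped <- EventLog(ev, c(left = "maltodextrin", right = "casein"))
  tm2 <- trialMetrics(segmentTrials(sessionSignal(s, "dff"), ev_swapped))
  expect_identical(caseinPreference(tm2)$preference, p1$preference)
})

test_that("position summary is symmetric, detects parking, and is rigid-motion invariant", {
  sippers <- list(left = c(300, 80), right = c(300, 160))
  sol_map <- c(left = "casein", right = "maltodextrin")
  mk_track <- function(xy, n = 200) {
    d <- do.call(rbind, lapply(c("nose", "ear_left", "ear_right"),
      function(p) data.frame(frame = seq_len(n) - 1L, body_part = p,
                             x = xy[1], y = xy[2], likelihood = 0.99)))
    TrackingTable(d, 10)
  }
  # static animal equidistant from both sippers
  eq <- positionSummary(mk_track(c(150, 120)), sippers, sol_map)
  expect_equal(eq$mean_dist_casein, eq$mean_dist_malt)
  expect_equal(eq$total_distance_moved, 0)
  expect_equal(sum(eq$occupancy), 1)
  # parked at the casein sipper
  at_cas <- positionSummary(mk_track(sippers$left), sippers, sol_map)
  expect_lt(at_cas$mean_dist_casein, 1e-9)
  expect_lt(at_cas$mean_dist_casein, at_cas$mean_dist_malt)
  # rigid translation + rotation of all coordinates
  set.seed(3)
  n <- 150
  base <- data.frame(x = runif(n, 0, 300), y = runif(n, 0, 240))
  mk_from <- function(xy) {
    d <- do.call(rbind, lapply(c("nose", "ear_left", "ear_right"),
      function(p) data.frame(frame = seq_len(nrow(xy)) - 1L, body_part = p,
                             x = xy$x, y = xy$y, likelihood = 0.99)))
    TrackingTable(d, 10)
  }
  theta <- 0.7; shift <- c(55, -20)
  rot <- function(x, y) list(x = cos(theta) * x - sin(theta) * y + shift[1],
                             y = sin(theta) * x + cos(theta) * y + shift[2])
  moved <- as.data.frame(rot(base$x, base$y))
  sip_moved <- lapply(sippers, function(p) unlist(rot(p[1], p[2])))
  a <- positionSummary(mk_from(base), sippers, sol_map)
  b <- positionSummary(mk_from(moved), sip_moved, sol_map)
  expect_equal(b$mean_dist_casein, a$mean_dist_casein, tolerance = 1e-9)
  expect_equal(b$total_distance_moved, a$total_distance_moved,
               tolerance = 1e-9)
})

test_that("low-likelihood frames are dropped with a retention warning", {
  n <- 100
  d <- do.call(rbind, lapply(c("nose", "ear_left", "ear_right"),
    function(p) data.frame(frame = seq_len(n) - 1L, body_part = p,
                           x = 10, y = 10,
                           likelihood = rep(c(0.99, 0.1), c(0.4 * n, 0.6 * n)))))
  out <- positionSummary(TrackingTable(d, 10),
                         list(left = c(0, 0), right = c(20, 20)),
                         c(left = "casein", right = "maltodextrin"))
  expect_true(length(out$warnings) >= 1)
  expect_lt(out$frames_retained, n)
})

test_that("conditioning intake builds a tidy per-session table", {
  mk_sess <- function(rat, sn, n_licks) {
    ev <- if (n_licks > 0)
      data.frame(time = c(10, 10 + seq_len(n_licks) * 0.002,
                          10 + n_licks * 0.002 + 5),
                 kind = c("sipper_extend", rep("lick", n_licks),
                          "sipper_retract"),
                 sipper_id = "left")
    else data.frame(time = c(10, 40), kind = c("sipper_extend",
                                               "sipper_retract"),
                    sipper_id = "left")
    PhotometrySession(
      SessionMeta(rat, session_kind = "conditioning",
                  extra = list(session_number = sn)),
      list(PhotometrySignal(rep(1, 100), 2, "470_demod"),
           PhotometrySignal(rep(1, 100), 2, "405_demod")),
      EventLog(ev, c(left = "casein", right = "maltodextrin")))
  }
  tab <- conditioningIntake(list(mk_sess("r1", 1, 500), mk_sess("r1", 2, 800),
                                 mk_sess("r2", 1, 0)))
  r1 <- tab[tab$rat_id == "r1" & tab$solution == "casein", ]
  expect_equal(r1$n_licks[r1$session_number == 1], 500)
  expect_equal(r1$n_licks[r1$session_number == 2], 800)
  # empty session keeps a zero row
  expect_equal(tab$n_licks[tab$rat_id == "r2" & tab$solution == "casein"], 0)
})
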