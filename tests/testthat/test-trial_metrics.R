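test_that("segmentation yields one trial per presentation with correct flags", {
  trials <- data.frame(t_extend = c(100, 150, 200),
                       latency = c(1.5, NA, 3), n_licks = c(10, 0, 8),
                       sipper = c("left", "right", "left"))
  ev <- make_events(trials)
  dff <- make_dff(rnorm(300 * 50), fs = 50)   # 300 s
  ts <- segmentTrials(dff, ev)
  inf <- trialInfo(ts)
  expect_identical(nrow(inf), 3L)
  expect_identical(sum(inf$analyzable), 2L)
  expect_identical(inf$solution, c("casein", "maltodextrin", "casein"))
  # alignment window in session time: [first_lick - 10, first_lick + 20)
  centers <- binCenters(ts) + inf$t_first_lick[1]
  expect_equal(centers[1], 101.5 - 10 + 0.05)
  expect_equal(centers[length(centers)], 101.5 + 20 - 0.05)
})

test_that("the generated schedule segments into exactly 45 forced trials", {
  g <- generateSession(seed = 7, sample_rate = 20)
  s <- preprocessSession(g$session)
  ts <- segmentTrials(sessionSignal(s, "dff"), sessionEvents(s))
  expect_identical(sum(trialInfo(ts)$trial_type == "forced"), 45L)
  expect_identical(sum(trialInfo(ts)$trial_type == "free"), 20L)
})

test_that("z-scoring normalises against the 10-s pre-lick baseline", {
  fs <- 50
  # 100 baseline bins with mean 2, sd 0.5 (two-point bins keep exact values)
  baseline_bins <- rep(c(1.5, 2.5), 50)
  vals <- c(rep(baseline_bins, each = round(0.1 * fs)),
            rep(3.0, 20 * fs))
  dff <- make_dff(vals, fs = fs, t0 = -10)
  z <- zscoreTrial(dff, t_first_lick = 0)
  centers <- attr(z, "bin_centers")
  bl <- z[centers < 0]
  expect_lt(abs(mean(bl)), 1e-9)
  expect_lt(abs(sd(bl) - 1), 1e-9)
  expect_equal(attr(z, "baseline_mean"), 2.0)
  # post-lick value 3.0: z = (3 - 2) / 0.5 = 2
  expect_equal(unname(z[centers > 0][1]), (3 - 2) / attr(z, "baseline_sd"))
  expect_lt(abs(attr(z, "baseline_sd") - 0.5), 0.01)

  expect_error(zscoreTrial(make_dff(rep(1, 31 * fs), fs = fs, t0 = -10), 0),
               "degenerate baseline")
})

test_that("z traces are invariant to shifting and positive scaling of dff", {
  set.seed(1)
  fs <- 50
  vals <- rnorm(31 * fs)
  z0 <- zscoreTrial(make_dff(vals, fs, t0 = -10), 0)
  z_shift <- zscoreTrial(make_dff(vals + 7, fs, t0 = -10), 0)
  z_scale <- zscoreTrial(make_dff(vals * 3.2, fs, t0 = -10), 0)
  expect_equal(as.numeric(z_shift), as.numeric(z0), tolerance = 1e-9)
  expect_equal(as.numeric(z_scale), as.numeric(z0), tolerance = 1e-9)
})

test_that("AUC of the binned trace matches closed forms and is additive", {
  centers <- -10 + (seq_len(300) - 0.5) * 0.1
  z_zero <- numeric(300)
  expect_equal(aucWindow(z_zero, c(0, 5), centers), 0)
  z_one <- as.numeric(centers >= 0 & centers < 5)
  expect_equal(aucWindow(z_one, c(0, 5), centers), 5.0, tolerance = 0.05)
  # linear ramp 0 -> 2 over [0, 5): integral 5
  ramp <- ifelse(centers >= 0 & centers < 5, centers * 2 / 5, 0)
  expect_equal(aucWindow(ramp, c(0, 5), centers), 5.0, tolerance = 0.05)
  # additivity to 1e-9
  set.seed(2)
  z <- rnorm(300)
  expect_lt(abs(aucWindow(z, c(0, 5), centers) +
                  aucWindow(z, c(5, 10), centers) -
                  aucWindow(z, c(0, 10), centers)), 1e-9)
  expect_error(aucWindow(z, c(15, 25), centers), "not covered")
  # z_bins scale is 10x the z_seconds scale
  expect_equal(aucWindow(z, c(0, 5), centers, scale = "z_bins"),
               10 * aucWindow(z, c(0, 5), centers))
})

test_that("latency to peak honours the search window and tie rule", {
  centers <- -10 + (seq_len(300) - 0.5) * 0.1
  # monotone decreasing trace: peak at the start of the search window
  z_dec <- -seq_along(centers)
  lat <- latencyToPeak(z_dec, t_extend = -2, t_first_lick = 0, t_retract = 5,
                       bin_centers = centers)
  expect_lt(lat, 0.1)
  # Gaussian bump 3.2 s after extension
  z_bump <- exp(-(centers - 1.2)^2 / (2 * 0.5^2))  # peak 1.2 s after lick
  lat2 <- latencyToPeak(z_bump, t_extend = -2, t_first_lick = 0,
                        t_retract = 5, bin_centers = centers)
  expect_equal(lat2, 3.2, tolerance = 0.1)
  # two equal maxima: the earlier wins
  z_tie <- numeric(300)
  z_tie[centers > 0.95 & centers < 1.05] <- 5
  z_tie[centers > 1.95 & centers < 2.05] <- 5
  lat3 <- latencyToPeak(z_tie, t_extend = 0, t_first_lick = 0, t_retract = 5,
                        bin_centers = centers)
  expect_equal(lat3, 1.0, tolerance = 0.06)
  expect_error(latencyToPeak(z_tie, 50, 0, 60, centers), "empty")
})

test_that("peak z matches the injected amplitude over repeated synthetic trials", {
  # analytic oracle: peak z = amplitude (kernel is peak-normalised and
  # amplitude is expressed in binned-baseline SD units)
  fs <- 50
  amp <- 3
  kp <- kernelParams(amplitude = amp, jitter_sd = 0)
  n_rep <- 200
  tau_grid <- (0:(20 * fs - 1)) / fs
  kern <- (exp(-tau_grid / kp$decay_tau) - exp(-tau_grid / kp$rise_tau))
  kern <- kern / max(kern)
  kb <- colMeans(matrix(kern, nrow = 0.1 * fs))  # binned kernel
  pk_bin <- which.max(kb)                        # bin holding the peak
  set.seed(99)
  bin_sd <- 1 / sqrt(0.1 * fs)
  z_at_peak <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    vals <- rnorm(30 * fs)                    # unit per-sample noise
    vals[(10 * fs + 1):(30 * fs)] <-
      vals[(10 * fs + 1):(30 * fs)] + amp * bin_sd * kern
    z <- zscoreTrial(make_dff(vals, fs, t0 = -10), 0)
    z_at_peak[i] <- z[attr(z, "bin_centers") > 0][pk_bin]
  }
  se <- sd(z_at_peak) / sqrt(n_rep)
  expect_lt(abs(mean(z_at_peak) - amp * max(kb)), 3 * se)
})

test_that("session baseline is centred at zero for white noise", {
  fs <- 50
  set.seed(5)
  aucs <- replicate(200, {
    dff <- make_dff(rnorm(40 * fs), fs)
    ev <- make_events(data.frame(t_extend = 30, latency = 1, n_licks = 3,
                                 sipper = "left"))
    sessionBaseline(dff, ev)$auc_presession
  })
  expect_lt(abs(mean(aucs)), 3 * sd(aucs) / sqrt(200))
  # deterministic given the data
  dff <- make_dff(rnorm(40 * fs), fs)
  ev <- make_events(data.frame(t_extend = 30, latency = 1, n_licks = 3,
                               sipper = "left"))
  expect_identical(sessionBaseline(dff, ev), sessionBaseline(dff, ev))
  # degenerate epoch propagates the baseline error
  expect_error(sessionBaseline(make_dff(rep(1, 40 * fs), fs), ev),
               "degenerate baseline")
  ev0 <- EventLog(data.frame(time = c(0, 30), kind = c("sipper_extend",
                                                       "sipper_retract"),
                             sipper_id = "left"),
                  c(left = "casein", right = "maltodextrin"))
  expect_error(sessionBaseline(dff, ev0), "pre-session")
})

test_that("trial metrics table carries AUCs, latencies and exclusion flags", {
  g <- quick_session(seed = 13, amp_cas = 3, amp_mal = 1)
  s <- preprocessSession(g$session)
  ts <- segmentTrials(sessionSignal(s, "dff"), sessionEvents(s))
  tm <- trialMetrics(ts)
  expect_identical(nrow(tm), nrow(trialInfo(ts)))
  ok <- tm$analyzable
  expect_true(all(is.finite(tm$auc_0_5[ok])))
  expect_true(all(is.na(tm$auc_0_5[!ok])))
  expect_true(all(tm$latency_peak[ok] >= 0 &
                    tm$latency_peak[ok] <=
                      tm$t_retract[ok] - tm$t_extend[ok] + 0.1))
  expect_equal(tm$latency_lick[ok],
               tm$t_first_lick[ok] - tm$t_extend[ok])
})
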