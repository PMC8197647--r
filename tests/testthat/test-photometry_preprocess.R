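test_that("demodulation recovers single- and two-tone amplitudes", {
  fs <- 6100
  t <- seq(0, 10, by = 1 / fs)
  cfg <- demodConfig()
  zero <- demodulate(PhotometrySignal(numeric(length(t)) + 0 * t, fs,
                                      "470_raw", timestamps = t), cfg)
  expect_lt(max(abs(signalValues(zero$sig470))), 1e-9)
  expect_lt(max(abs(signalValues(zero$sig405))), 1e-9)

  one <- demodulate(PhotometrySignal(2.0 * sin(2 * pi * 211 * t), fs,
                                     "470_raw", timestamps = t), cfg)
  tt <- signalTimes(one$sig470)
  interior <- tt > 0.5 & tt < max(tt) - 0.5     # outside filter settling
  expect_lt(max(abs(signalValues(one$sig470)[interior] - 2.0)), 0.02)
  expect_lt(max(abs(signalValues(one$sig405)[interior])), 0.02)

  two <- demodulate(PhotometrySignal(1.5 * sin(2 * pi * 211 * t) +
                                       0.7 * sin(2 * pi * 539 * t), fs,
                                     "470_raw", timestamps = t), cfg)
  expect_lt(max(abs(signalValues(two$sig470)[interior] - 1.5)), 0.015)
  expect_lt(max(abs(signalValues(two$sig405)[interior] - 0.7)), 0.007)
})

test_that("demodulation rejects carriers at or above Nyquist", {
  sig <- PhotometrySignal(rnorm(1000), 1000, "470_raw")
  expect_error(demodulate(sig, demodConfig(carrier_405 = 600)), "Nyquist")
  expect_error(demodConfig(carrier_470 = 30, lowpass_cutoff = 20), "twice")
})

test_that("FFT-domain subtraction: identity, cancellation, time-domain equivalence", {
  set.seed(42)
  n <- 4096
  v470 <- 2 + 0.1 * rnorm(n)
  v405 <- 1 + 0.05 * rnorm(n)
  s470 <- PhotometrySignal(v470, 100, "470_demod")
  s405 <- PhotometrySignal(v405, 100, "405_demod")
  zero <- PhotometrySignal(numeric(n), 100, "405_demod")

  rms <- function(x) sqrt(mean(x^2))
  out_id <- fftSubtractCorrect(s470, zero)
  expect_lt(rms(signalValues(out_id) - v470), 1e-9 * rms(v470))
  out_cancel <- fftSubtractCorrect(s470, s470)
  expect_lt(rms(signalValues(out_cancel)), 1e-9 * rms(v470))
  out <- fftSubtractCorrect(s470, s405)
  expect_lt(rms(signalValues(out) - (v470 - v405)), 1e-9 * rms(v470 - v405))
  # linearity
  s470b <- PhotometrySignal(rnorm(n), 100, "470_demod")
  s405b <- PhotometrySignal(rnorm(n), 100, "405_demod")
  sum_sig <- PhotometrySignal(v470 + signalValues(s470b), 100, "470_demod")
  sum_ref <- PhotometrySignal(v405 + signalValues(s405b), 100, "405_demod")
  lhs <- signalValues(fftSubtractCorrect(sum_sig, sum_ref))
  rhs <- signalValues(fftSubtractCorrect(s470, s405)) +
    signalValues(fftSubtractCorrect(s470b, s405b))
  expect_lt(rms(lhs - rhs), 1e-9 * rms(rhs))
  expect_error(fftSubtractCorrect(s470, PhotometrySignal(rnorm(10), 100,
                                                         "405_demod")),
               "length mismatch")
})

test_that("correction isolates the neural component from shared artifacts", {
  fs <- 100
  t <- (0:(60 * fs - 1)) / fs
  bumps <- rep(0, length(t))
  for (c0 in seq(5, 55, by = 5))
    bumps <- bumps + 0.5 * exp(-(t - c0)^2 / (2 * 0.3^2))
  artifact <- 0.4 * sin(2 * pi * 0.1 * t)
  artifact[seq(1000, 5800, by = 400)] <- artifact[seq(1000, 5800, by = 400)] + 2
  s470 <- PhotometrySignal(bumps + artifact, fs, "470_demod", timestamps = t)
  s405 <- PhotometrySignal(artifact, fs, "405_demod", timestamps = t)
  out <- signalValues(fftSubtractCorrect(s470, s405))
  expect_gt(cor(out, bumps), 0.99)
  # shared-artifact attenuation
  resid <- out - bumps
  expect_lt(sqrt(mean(resid^2)) / sqrt(mean(artifact^2)), 0.05)
})

test_that("dF/F is the corrected trace over the 470 trend and is scale invariant", {
  fs <- 50
  n <- 20 * fs
  f0_level <- 2.0
  corrected <- PhotometrySignal(rep(0, n), fs, "corrected")
  s470 <- PhotometrySignal(rep(f0_level, n), fs, "470_demod")
  expect_equal(max(abs(signalValues(deltaFOverF(corrected, s470)))), 0)

  corr2 <- PhotometrySignal(rep(0.05 * f0_level, n), fs, "corrected")
  dff <- deltaFOverF(corr2, s470)
  expect_lt(max(abs(signalValues(dff) - 0.05)), 1e-9)

  scale <- 3.7
  dff_scaled <- deltaFOverF(
    PhotometrySignal(scale * signalValues(corr2), fs, "corrected"),
    PhotometrySignal(scale * signalValues(s470), fs, "470_demod"))
  expect_lt(max(abs(signalValues(dff_scaled) - signalValues(dff))), 1e-12)

  neg <- PhotometrySignal(rep(-1, n), fs, "470_demod")
  expect_error(deltaFOverF(corrected, neg), "non-physical")
})

test_that("injected transients are recovered in dff at zero lag", {
  g <- generateSession(
    kernels = list(casein = kernelParams(amplitude = 4, jitter_sd = 0),
                   maltodextrin = kernelParams(amplitude = 4, jitter_sd = 0)),
    schedule = tiny_schedule(n_forced = 6, n_free = 0),
    seed = 9, sample_rate = 50)
  s <- preprocessSession(g$session)
  dff <- sessionSignal(s, "dff")
  t <- signalTimes(dff)
  # reconstruct the injected train (unit kernel at each ground-truth onset)
  kp <- kernelParams(amplitude = 4, jitter_sd = 0)
  tr <- g$truth@trials
  injected <- rep(0, length(t))
  for (on in tr$onset[!is.na(tr$onset)]) {
    ix <- which(t >= on & t <= on + 15)
    tau <- t[ix] - on
    injected[ix] <- injected[ix] +
      exp(-tau / kp$decay_tau) - exp(-tau / kp$rise_tau)
  }
  cc <- ccf(signalValues(dff), injected, lag.max = 5, plot = FALSE)
  expect_lte(abs(cc$lag[which.max(cc$acf)]), 1)
})
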