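# shared fixtures, built in code

# small, fast schedule for structural tests
tiny_schedule <- function(n_forced = 4, n_free = 2, ...) {
  scheduleParams(n_forced = n_forced, n_free = n_free, iti_min = 4,
                 iti_max = 8, iti_mean = 6, presession_s = 15, ...)
}

quick_session <- function(seed = 1, amp_cas = 2, amp_mal = 2,
                          schedule = tiny_schedule(), sample_rate = 50, ...) {
  generateSession(kernels = list(casein = kernelParams(amplitude = amp_cas),
                                 maltodextrin = kernelParams(amplitude = amp_mal)),
                  schedule = schedule, seed = seed,
                  sample_rate = sample_rate, ...)
}

# events helper: one forced trial per row of (t_extend, latency, n_licks)
make_events <- function(trials, solution_map = c(left = "casein",
                                                 right = "maltodextrin"),
                        access_s = 5, timeout_s = 30) {
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    sip <- tr$sipper
    if (!is.na(tr$latency)) {
      t1 <- tr$t_extend + tr$latency
      t_ret <- t1 + access_s
      lt <- t1 + seq(0, by = 0.15, length.out = tr$n_licks)
      data.frame(time = c(tr$t_extend, lt, t_ret),
                 kind = c("sipper_extend", rep("lick", length(lt)),
                          "sipper_retract"),
                 sipper_id = sip, stringsAsFactors = FALSE)
    } else {
      data.frame(time = c(tr$t_extend, tr$t_extend + timeout_s),
                 kind = c("sipper_extend", "sipper_retract"),
                 sipper_id = sip, stringsAsFactors = FALSE)
    }
  })
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$time), ]
  EventLog(ev, solution_map)
}

# dff signal from a plain numeric vector
make_dff <- function(values, fs = 50, t0 = 0)
  PhotometrySignal(values, sample_rate = fs, channel_label = "dff", t0 = t0)

expect_empty_report <- function(report) expect_identical(nrow(report), 0L)
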