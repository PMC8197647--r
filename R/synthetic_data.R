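## Synthetic session generator.
##
## Emulates the statistical structure the analysis chain assumes: GCaMP6s-like
## transients time-locked to the first lick of each trial with
## solution-dependent amplitude, artifacts (drift, motion impulses,
## photobleaching) shared by the 470 and isosbestic channels, the task's
## trial schedule (forced then free-choice trials, uniform 10-30 s ITI, 5-s
## access after the first lick, 30-s no-lick timeout), Poisson lick bouts and
## log-normal first-lick latencies. Ground truth (injected amplitudes and
## onsets) is returned alongside, so downstream metrics can be checked
## against what was injected.

.F_LEVEL <- 2.0   # baseline fluorescence of both channels (V); equal levels
                  # give the unit artifact gain ratio the correction assumes

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Transient kernel parameters
#'
#' The injected calcium transient is a peak-normalised difference of
#' exponentials, \eqn{k(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}}, a standard
#' GCaMP6s-like shape. Amplitude is expressed in z-equivalent units of the
#' corrected trace (units of the binned-baseline noise SD), so ground truth
#' maps directly onto the z/AUC scale of the trial metrics.
#'
#' @param amplitude peak response in z-equivalent units.
#' @param rise_tau rise time constant (s).
#' @param decay_tau decay time constant (s); must exceed \code{rise_tau}.
#' @param jitter_sd scale (median, s) of the log-normal onset delay of the
#'   response after the first lick; 0 locks onset exactly to the lick.
#' @return list with class \code{"KernelParams"}.
#' @export
kernelParams <- function(amplitude = 2, rise_tau = 0.2, decay_tau = 1.5,
                         jitter_sd = 0.15) {
  if (rise_tau <= 0 || decay_tau <= 0) stop("taus must be positive")
  if (decay_tau <= rise_tau) stop("decay_tau must exceed rise_tau")
  if (!is.finite(amplitude)) stop("amplitude must be finite")
  structure(list(amplitude = amplitude, rise_tau = rise_tau,
                 decay_tau = decay_tau, jitter_sd = jitter_sd),
            class = "KernelParams")
}

#' Artifact parameters
#'
#' Calcium-independent components added with unit gain to both channels:
#' a slow sinusoidal drift, Poisson motion impulses smoothed by a 0.3-s
#' boxcar, multiplicative exponential photobleaching of the baseline
#' fluorescence, and white measurement noise (independent per channel).
#'
#' @param drift_amplitude sinusoidal drift amplitude (V).
#' @param drift_period drift period (s).
#' @param motion_rate motion-impulse rate (events/s).
#' @param motion_amplitude SD of motion impulse amplitudes (V).
#' @param bleach_tau photobleaching time constant (s).
#' @param noise_sd per-sample measurement noise SD (V), per channel.
#' @return list with class \code{"ArtifactParams"}.
#' @export
artifactParams <- function(drift_amplitude = 0.05, drift_period = 60,
                           motion_rate = 0.1, motion_amplitude = 0.1,
                           bleach_tau = 2400, noise_sd = 0.02) {
  vals <- c(drift_amplitude, drift_period, motion_rate, motion_amplitude,
            noise_sd)
  if (any(vals < 0)) stop("artifact parameters must be non-negative")
  if (bleach_tau <= 0) stop("bleach_tau must be positive")
  structure(list(drift_amplitude = drift_amplitude,
                 drift_period = drift_period, motion_rate = motion_rate,
                 motion_amplitude = motion_amplitude, bleach_tau = bleach_tau,
                 noise_sd = noise_sd), class = "ArtifactParams")
}

#' Trial schedule parameters
#'
#' Defaults encode the task: 45 forced-choice trials followed by 20
#' free-choice trials; intertrial interval uniform on [10, 30] s (mean 20 s);
#' sippers retract 5 s after the first lick or after a 30-s no-lick timeout;
#' licking is a 6 Hz Poisson bout within the access window; first-lick
#' latency from sipper extension is log-normal per solution.
#'
#' @param n_forced,n_free trial counts.
#' @param iti_min,iti_max,iti_mean ITI bounds and mean (s); the ITI is drawn
#'   uniform on [iti_min, iti_max] and \code{iti_mean} must match the
#'   midpoint.
#' @param access_s access duration after the first lick (s).
#' @param timeout_s no-lick timeout (s).
#' @param p_lick probability that a trial has licks (before latency
#'   truncation at the timeout).
#' @param latency named list per solution of \code{c(meanlog, sdlog)} for the
#'   log-normal first-lick latency.
#' @param lick_rate within-bout lick rate (Hz).
#' @param presession_s quiet epoch before the first trial (s), used for the
#'   session baseline.
#' @param choice_values named numeric per solution; free-choice probability
#'   of choosing casein is \code{softmax(choice_values)}. Equal values give
#'   preference 0.5.
#' @return list with class \code{"ScheduleParams"}.
#' @export
scheduleParams <- function(n_forced = 45, n_free = 20,
                           iti_min = 10, iti_max = 30, iti_mean = 20,
                           access_s = 5, timeout_s = 30, p_lick = 0.9,
                           latency = list(casein = c(meanlog = log(2), sdlog = 0.5),
                                          maltodextrin = c(meanlog = log(2), sdlog = 0.5)),
                           lick_rate = 6, presession_s = 60,
                           choice_values = c(casein = 0, maltodextrin = 0)) {
  if (n_forced < 0 || n_free < 0) stop("trial counts must be non-negative")
  if (iti_min > iti_max) stop("nonsensical schedule: iti_min > iti_max")
  if (iti_mean < iti_min || iti_mean > iti_max)
    stop("iti_mean must lie within [iti_min, iti_max]")
  if (p_lick < 0 || p_lick > 1) stop("p_lick must lie in [0, 1]")
  structure(list(n_forced = n_forced, n_free = n_free, iti_min = iti_min,
                 iti_max = iti_max, iti_mean = iti_mean, access_s = access_s,
                 timeout_s = timeout_s, p_lick = p_lick, latency = latency,
                 lick_rate = lick_rate, presession_s = presession_s,
                 choice_values = choice_values), class = "ScheduleParams")
}

## peak-normalised difference-of-exponentials kernel
.kernel_norm <- function(kp) {
  tpk <- log(kp$decay_tau / kp$rise_tau) *
    kp$rise_tau * kp$decay_tau / (kp$decay_tau - kp$rise_tau)
  peak <- exp(-tpk / kp$decay_tau) - exp(-tpk / kp$rise_tau)
  list(fun = function(t) {
    v <- numeric(length(t))
    pos <- t >= 0
    v[pos] <- (exp(-t[pos] / kp$decay_tau) - exp(-t[pos] / kp$rise_tau)) / peak
    v
  }, t_peak = tpk, peak = peak)
}

## integral of the normalised kernel over [0, x]
.kernel_cum <- function(kp, x) {
  k <- .kernel_norm(kp)
  x <- pmax(x, 0)
  (kp$decay_tau * (1 - exp(-x / kp$decay_tau)) -
   kp$rise_tau * (1 - exp(-x / kp$rise_tau))) / k$peak
}

#' Expected AUC of an injected response over a peri-lick window
#'
#' The analytic ground-truth value the trial AUC estimates: the injected
#' amplitude times the integral of the peak-normalised kernel over the
#' window, averaged over the log-normal onset-delay distribution.
#'
#' @param kp a \code{\link{kernelParams}}.
#' @param window numeric c(a, b), seconds relative to first lick.
#' @return expected AUC in z·s.
#' @export
expectedResponseAuc <- function(kp, window = c(0, 5)) {
  one <- function(d)
    .kernel_cum(kp, window[2] - d) - .kernel_cum(kp, window[1] - d)
  if (kp$jitter_sd <= 0) return(kp$amplitude * one(0))
  q <- stats::qlnorm(seq(0.0005, 0.9995, by = 0.001),
                     meanlog = log(kp$jitter_sd), sdlog = 0.5)
  kp$amplitude * mean(vapply(q, one, numeric(1)))
}

## draws the event schedule; all trial-level randomness happens here so that
## raw- and demodulated-stage sessions share one realisation
.draw_schedule <- function(schedule, solution_map, kernels) {
  sol_of <- solution_map                       # sipper -> solution
  sip_of <- stats::setNames(names(sol_of), sol_of)  # solution -> sipper
  n_tot <- schedule$n_forced + schedule$n_free
  forced_sol <- sample(rep(.SOLUTIONS,
                           length.out = schedule$n_forced)[sample.int(schedule$n_forced)])
  p_cas <- exp(schedule$choice_values[["casein"]]) /
    sum(exp(schedule$choice_values))
  t_cur <- schedule$presession_s
  ev_t <- list(); ev_k <- list(); ev_s <- list()
  gt_type <- gt_sol <- character(n_tot)
  gt_ext <- gt_lick <- gt_ret <- gt_amp <- gt_on <- numeric(n_tot)
  gt_nl <- integer(n_tot)
  for (i in seq_len(n_tot)) {
    free <- i > schedule$n_forced
    t_ext <- t_cur
    if (free) {
      chosen_sol <- if (stats::runif(1) < p_cas) "casein" else "maltodextrin"
      sippers <- c("left", "right")
    } else {
      chosen_sol <- forced_sol[i]
      sippers <- sip_of[[chosen_sol]]
    }
    licked <- stats::runif(1) < schedule$p_lick
    lat <- stats::rlnorm(1, schedule$latency[[chosen_sol]][["meanlog"]],
                         schedule$latency[[chosen_sol]][["sdlog"]])
    if (licked && lat < schedule$timeout_s) {
      t_lick1 <- t_ext + lat
      t_ret <- t_lick1 + schedule$access_s
      n_extra <- stats::rpois(1, schedule$lick_rate * schedule$access_s)
      lick_times <- sort(c(t_lick1,
                           stats::runif(n_extra, t_lick1, t_ret)))
      kp <- kernels[[chosen_sol]]
      delay <- if (kp$jitter_sd > 0)
        stats::rlnorm(1, log(kp$jitter_sd), 0.5) else 0
      amp <- kp$amplitude
      onset <- t_lick1 + delay
    } else {
      t_lick1 <- NA_real_; t_ret <- t_ext + schedule$timeout_s
      lick_times <- numeric(0); amp <- 0; onset <- NA_real_
    }
    sip_chosen <- sip_of[[chosen_sol]]
    ns <- length(sippers); nl <- length(lick_times)
    ev_t[[i]] <- c(rep(t_ext, 2 * ns), lick_times, rep(t_ret, 2 * ns))
    ev_k[[i]] <- c(rep("cue_on", ns), rep("sipper_extend", ns),
                   rep("lick", nl), rep("sipper_retract", ns),
                   rep("cue_off", ns))
    ev_s[[i]] <- c(sippers, sippers, rep(sip_chosen, nl), sippers, sippers)
    gt_type[i] <- if (free) "free" else "forced"
    gt_sol[i] <- if (nl || !free) chosen_sol else NA_character_
    gt_ext[i] <- t_ext; gt_lick[i] <- t_lick1; gt_ret[i] <- t_ret
    gt_amp[i] <- amp; gt_on[i] <- onset; gt_nl[i] <- nl
    t_cur <- t_ret + stats::runif(1, schedule$iti_min, schedule$iti_max)
  }
  events <- data.frame(time = unlist(ev_t), kind = unlist(ev_k),
                       sipper_id = unlist(ev_s), stringsAsFactors = FALSE)
  events <- events[order(events$time, match(events$kind, .EVENT_KINDS)), ]
  rownames(events) <- NULL
  truth <- data.frame(index = seq_len(n_tot), trial_type = gt_type,
                      solution = gt_sol, t_extend = gt_ext,
                      t_first_lick = gt_lick, t_retract = gt_ret,
                      amplitude = gt_amp, onset = gt_on, n_licks = gt_nl,
                      stringsAsFactors = FALSE)
  list(events = events, truth = truth)
}

## baseband channel pair on a time grid, given the realised schedule
.synth_baseband <- function(t, truth, kernels, artifacts, fs) {
  n <- length(t)
  bleach <- exp(-t / artifacts$bleach_tau)
  drift_phase <- stats::runif(1, 0, 2 * pi)
  drift <- if (artifacts$drift_amplitude > 0)
    artifacts$drift_amplitude *
      sin(2 * pi * t / artifacts$drift_period + drift_phase) else numeric(n)
  dur <- t[n] - t[1]
  n_mot <- stats::rpois(1, artifacts$motion_rate * dur)
  motion <- numeric(n)
  mot_t <- sort(stats::runif(n_mot, t[1], t[n]))
  mot_a <- stats::rnorm(n_mot, 0, artifacts$motion_amplitude)
  half <- 0.15                               # 0.3-s boxcar
  idx_range <- function(a, b)                # uniform grid: direct indexing
    seq.int(max(1L, ceiling(a * fs) + 1L), min(n, floor(b * fs) + 1L))
  for (j in seq_len(n_mot)) {
    ix <- idx_range(mot_t[j] - half, mot_t[j] + half)
    motion[ix] <- motion[ix] + mot_a[j]
  }
  ## z-equivalent amplitude scale: one binned-baseline SD of the corrected
  ## trace in raw volts (two independent noise channels, 0.1-s bins). When
  ## 0.1*fs is not an integer the bins alternate sample counts; the binned
  ## variance is then sigma^2 * E[1/k] over the two counts.
  bin_f <- 0.1 * fs
  fl <- max(floor(bin_f), 1); ce <- ceiling(bin_f); fr <- bin_f - floor(bin_f)
  e_inv <- if (fr == 0) 1 / fl else (1 - fr) / fl + fr / ce
  z_unit <- if (artifacts$noise_sd > 0)
    artifacts$noise_sd * sqrt(2) * sqrt(e_inv) else 1
  transients <- numeric(n)
  act <- truth[truth$amplitude != 0 & !is.na(truth$onset), , drop = FALSE]
  for (j in seq_len(nrow(act))) {
    kp <- kernels[[act$solution[j]]]
    kf <- .kernel_norm(kp)$fun
    ix <- idx_range(act$onset[j], act$onset[j] + 12 * kp$decay_tau)
    transients[ix] <- transients[ix] +
      act$amplitude[j] * z_unit * kf(t[ix] - act$onset[j])
  }
  shared <- .F_LEVEL * bleach + drift + motion
  list(b470 = shared + transients,
       b405 = shared,
       drift_phase = drift_phase, motion_t = mot_t, motion_a = mot_a,
       z_unit = z_unit)
}

#' Generate one synthetic session with ground truth
#'
#' Draws a full task session (event log + two-channel photometry) under the
#' given kernel, artifact and schedule parameters. Identical
#' \code{(params, seed)} give identical output. The returned session passes
#' \code{\link{validateEvents}} with an empty report.
#'
#' @param meta a \linkS4class{SessionMeta}.
#' @param kernels named list (\code{casein}, \code{maltodextrin}) of
#'   \code{\link{kernelParams}}.
#' @param artifacts an \code{\link{artifactParams}}.
#' @param schedule a \code{\link{scheduleParams}}.
#' @param seed integer seed.
#' @param stage \code{"demodulated"} (baseband 470/405 channels, default) or
#'   \code{"raw"} (carrier-modulated at 211 and 539 Hz).
#' @param sample_rate sampling rate (Hz); defaults to 1017 for the
#'   demodulated stage and 6100 for the raw stage. Lower rates give faster
#'   large-scale simulations.
#' @param solution_map named character sipper -> solution.
#' @return list with elements \code{session}
#'   (\linkS4class{PhotometrySession}) and \code{truth}
#'   (\linkS4class{SyntheticGroundTruth}).
#' @export
generateSession <- function(meta = SessionMeta("synthetic_rat"),
                            kernels = list(casein = kernelParams(),
                                           maltodextrin = kernelParams()),
                            artifacts = artifactParams(),
                            schedule = scheduleParams(),
                            seed = 1L,
                            stage = c("demodulated", "raw"),
                            sample_rate = NULL,
                            solution_map = c(left = "casein",
                                             right = "maltodextrin")) {
  stage <- match.arg(stage)
  if (is.null(sample_rate)) sample_rate <- if (stage == "raw") 6100 else 1017
  .with_seed(seed, {
    sched <- .draw_schedule(schedule, solution_map, kernels)
    truth <- sched$truth
    dur <- max(sched$events$time) + 22       # covers the +20 s z window
    n <- ceiling(dur * sample_rate) + 1L
    t <- (seq_len(n) - 1L) / sample_rate
    bb <- .synth_baseband(t, truth, kernels, artifacts, sample_rate)
    noise470 <- stats::rnorm(n, 0, artifacts$noise_sd)
    noise405 <- stats::rnorm(n, 0, artifacts$noise_sd)
    if (stage == "demodulated") {
      signals <- list(
        PhotometrySignal(bb$b470 + noise470, sample_rate, "470_demod",
                         timestamps = t),
        PhotometrySignal(bb$b405 + noise405, sample_rate, "405_demod",
                         timestamps = t))
    } else {
      signals <- list(
        PhotometrySignal((bb$b470 + noise470) * sin(2 * pi * 211 * t),
                         sample_rate, "470_raw", timestamps = t),
        PhotometrySignal((bb$b405 + noise405) * sin(2 * pi * 539 * t),
                         sample_rate, "405_raw", timestamps = t))
    }
    events <- EventLog(sched$events, solution_map)
    session <- PhotometrySession(meta, signals, events)
    truth_obj <- new("SyntheticGroundTruth", trials = truth,
                     artifacts = list(drift_phase = bb$drift_phase,
                                      motion_t = bb$motion_t,
                                      motion_a = bb$motion_a,
                                      z_unit = bb$z_unit),
                     params = list(kernels = kernels, artifacts = artifacts,
                                   schedule = schedule, stage = stage,
                                   sample_rate = sample_rate),
                     seed = as.integer(seed))
    list(session = session, truth = truth_obj)
  })
}

#' Generate a multi-rat cohort
#'
#' Builds one session per rat per group with deterministically derived
#' per-rat seeds, counterbalanced flavor-nutrient mappings and sipper sides,
#' and per-rat response amplitudes drawn around the group mean.
#'
#' @param group_spec named list, one entry per diet group, each
#'   \code{list(n_rats =, kernels = list(casein =, maltodextrin =))}.
#' @param artifacts,schedule shared \code{\link{artifactParams}} /
#'   \code{\link{scheduleParams}}. \code{schedule} may also be a named list
#'   (per group) to give groups different latency/choice structure.
#' @param seed master seed; rat seeds are derived from it.
#' @param rat_sd between-rat variability of the photometry response: the
#'   log-SD of a shared per-rat gain (mean 1) multiplying both solutions'
#'   amplitudes, emulating expression-level and fiber-placement differences.
#'   A shared gain preserves each rat's casein/maltodextrin amplitude ratio,
#'   so a null group (equal amplitudes) stays null within every rat.
#' @param sample_rate passed to \code{\link{generateSession}}.
#' @param test_index preference-test number stored in each session's
#'   metadata.
#' @return list of \code{list(session =, truth =)}, one per rat, named
#'   \code{<group>_<i>}.
#' @export
generateCohort <- function(group_spec, artifacts = artifactParams(),
                           schedule = scheduleParams(), seed = 1L,
                           rat_sd = 0.3, sample_rate = NULL,
                           test_index = 1L) {
  stopifnot(all(vapply(group_spec, function(g) g$n_rats >= 1, logical(1))))
  out <- list(); k <- 0L
  for (grp in names(group_spec)) {
    spec <- group_spec[[grp]]
    grp_schedule <- if (is(schedule, "ScheduleParams")) schedule
                    else schedule[[grp]]
    for (i in seq_len(spec$n_rats)) {
      k <- k + 1L
      ## rat_seed fixes the animal's identity (gain) across tests; the
      ## session seed adds the test day, so retesting the same cohort gives
      ## the same rats in a fresh recording
      rat_seed <- as.integer((as.numeric(seed) * 1009 + k * 7919) %%
                               .Machine$integer.max)
      session_seed <- as.integer((as.numeric(rat_seed) +
                                    100003 * as.numeric(test_index)) %%
                                   .Machine$integer.max)
      flip <- k %% 2L == 0L                  # counterbalancing
      sol_map <- if (flip) c(left = "maltodextrin", right = "casein")
                 else c(left = "casein", right = "maltodextrin")
      flav <- if (flip) c(grape = "casein", cherry = "maltodextrin")
              else c(cherry = "casein", grape = "maltodextrin")
      kern <- spec$kernels
      if (rat_sd > 0) {
        ## per-rat photometry gain (expression level, fiber placement):
        ## multiplies both solutions' responses together, mean 1
        .with_seed(rat_seed + 1L, {
          g <- stats::rlnorm(1, -rat_sd^2 / 2, rat_sd)
          for (s in names(kern))
            kern[[s]]$amplitude <- kern[[s]]$amplitude * g
        })
      }
      meta <- SessionMeta(rat_id = sprintf("%s_%02d", grp, i),
                          diet_state = grp, session_kind = "preference_test",
                          test_index = as.integer(test_index),
                          flavor_map = flav)
      out[[sprintf("%s_%02d", grp, i)]] <-
        generateSession(meta, kern, artifacts, grp_schedule,
                        seed = session_seed, sample_rate = sample_rate,
                        solution_map = sol_map)
    }
  }
  out
}

#' Generate synthetic pose tracking for a session
#'
#' Simulates head-position tracking as a mean-reverting random walk that is
#' attracted toward the extended sipper(s) during access windows, with
#' attraction split between sippers in proportion to
#' per-solution weights, and wanders around the chamber otherwise. Geometry:
#' 305 x 241 chamber (1 px = 1 mm), sippers on the right wall.
#'
#' @param session a \linkS4class{PhotometrySession}.
#' @param sipper_bias named numeric attraction weights per solution.
#' @param seed integer seed.
#' @param frame_rate video rate (Hz), 5 or 10 typically.
#' @return a \linkS4class{TrackingTable}; sipper pixel coordinates are
#'   attached as attribute \code{"sippers"} (named list).
#' @export
generateTracking <- function(session, sipper_bias = c(casein = 1,
                                                      maltodextrin = 1),
                             seed = 1L, frame_rate = 10) {
  ev <- session@events@events
  stopifnot(nrow(ev) > 0)
  sol_map <- session@events@solution_map
  sippers <- list(left = c(300, 80), right = c(300, 160))
  dur <- max(ev$time)
  trials <- .parse_trial_windows(session@events)
  .with_seed(seed, {
    n <- ceiling(dur * frame_rate)
    tt <- (seq_len(n) - 1L) / frame_rate
    center <- c(150, 120)
    pos <- matrix(NA_real_, n, 2)
    p <- center
    ## per-frame target: extended sipper during access (weight-proportional
    ## choice), chamber wander otherwise
    target <- matrix(rep(center, each = n), n, 2)
    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      ix <- which(tt >= tr$t_extend & tt <= tr$t_retract)
      if (!length(ix)) next
      if (tr$trial_type == "forced") sip <- tr$sipper_id
      else {
        w <- sipper_bias[sol_map[c("left", "right")]]
        sip <- sample(c("left", "right"), 1, prob = w / sum(w))
      }
      target[ix, 1] <- sippers[[sip]][1]
      target[ix, 2] <- sippers[[sip]][2]
    }
    k_attract <- 0.35
    step_sd <- 6
    for (f in seq_len(n)) {
      p <- p + k_attract * (target[f, ] - p) + stats::rnorm(2, 0, step_sd)
      p[1] <- min(max(p[1], 0), 305)
      p[2] <- min(max(p[2], 0), 241)
      pos[f, ] <- p
    }
    parts <- list(nose = c(8, 0), ear_left = c(-4, -7), ear_right = c(-4, 7),
                  tail_base = c(-30, 0))
    rows <- lapply(names(parts), function(pp) {
      off <- parts[[pp]]
      lk <- ifelse(stats::runif(n) < 0.05, stats::runif(n, 0, 0.5),
                   stats::runif(n, 0.92, 1))
      data.frame(frame = seq_len(n) - 1L, body_part = pp,
                 x = pos[, 1] + off[1] + stats::rnorm(n, 0, 1.5),
                 y = pos[, 2] + off[2] + stats::rnorm(n, 0, 1.5),
                 likelihood = lk, stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, rows)
    d <- d[order(d$frame, match(d$body_part, .BODY_PARTS)), ]
    rownames(d) <- NULL
    out <- TrackingTable(d, frame_rate)
    attr(out, "sippers") <- sippers
    out
  })
}
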