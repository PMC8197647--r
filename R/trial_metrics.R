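## Trial-level neural metrics: first-lick-aligned segmentation, 100-ms
## binned z-scores against a 10-s pre-lick baseline, epoch AUCs, latency to
## peak, and the pre-session baseline AUC.

.BIN_W <- 0.1

## mean of `sig` values in consecutive .BIN_W bins starting at t_start;
## returns n_bins values (NaN for empty bins)
.bin_trace <- function(sig, t_start, n_bins) {
  t <- sig@timestamps
  lo <- t_start
  hi <- t_start + n_bins * .BIN_W
  ## the grid is uniform (class invariant): restrict to a candidate slice
  ## before the exact comparison
  fs <- sig@sample_rate
  i1 <- max(1L, floor((lo - t[1]) * fs) - 1L)
  i2 <- min(length(t), ceiling((hi - t[1]) * fs) + 2L)
  cand <- i1:i2
  ix <- cand[t[cand] >= lo - 1e-9 & t[cand] < hi - 1e-9]
  ## 1-ns guard keeps grid points that land on bin edges (binary float
  ## representation of 0.1-s multiples) in the intended bin
  bin <- floor((t[ix] - lo + 1e-9) / .BIN_W) + 1L
  bin[bin < 1L] <- 1L
  bin[bin > n_bins] <- n_bins
  sums <- rowsum(sig@values[ix], bin)
  cnts <- rowsum(rep(1, length(ix)), bin)
  out <- rep(NaN, n_bins)
  out[as.integer(rownames(sums))] <- sums / cnts
  out
}

#' z-score one trial's trace against its pre-lick baseline
#'
#' Bins the dF/F trace into 100-ms means on \code{window} around the first
#' lick and z-scores each bin against the mean and SD of the 10-s pre-lick
#' baseline bins: \eqn{z_b = (x_b - \mu_{bl}) / \sigma_{bl}}. The baseline
#' bins of the result have mean 0 and SD 1 by construction.
#'
#' @param dff the \code{"dff"} \linkS4class{PhotometrySignal}.
#' @param t_first_lick first-lick time (s, session time).
#' @param window c(start, end) of the peri-lick trace (s relative to first
#'   lick); default c(-10, 20).
#' @param baseline_s baseline duration immediately preceding the first lick
#'   (s); default 10.
#' @return numeric z trace (one value per 0.1-s bin), with attributes
#'   \code{bin_centers}, \code{baseline_mean}, \code{baseline_sd}.
#' @export
zscoreTrial <- function(dff, t_first_lick, window = c(-10, 20),
                        baseline_s = 10) {
  n_bins <- round((window[2] - window[1]) / .BIN_W)
  x <- .bin_trace(dff, t_first_lick + window[1], n_bins)
  centers <- window[1] + (seq_len(n_bins) - 0.5) * .BIN_W
  bl <- x[centers > -baseline_s & centers < 0]
  bl <- bl[is.finite(bl)]
  if (length(bl) < 2L) stop("baseline window not covered by recording")
  mu <- mean(bl)
  sd_bl <- stats::sd(bl)
  if (sd_bl == 0) stop("degenerate baseline: zero variance")
  z <- (x - mu) / sd_bl
  attr(z, "bin_centers") <- centers
  attr(z, "baseline_mean") <- mu
  attr(z, "baseline_sd") <- sd_bl
  z
}

#' Segment a session into first-lick-aligned trials
#'
#' One trial per sipper presentation; simultaneous extensions on both
#' sippers form one free-choice trial whose solution is that of the
#' first-licked sipper. Lickless trials are kept but flagged non-analyzable
#' (no z trace); trials whose peri-lick window is not covered by the
#' recording are flagged truncated and excluded from analysis.
#'
#' @param dff the \code{"dff"} \linkS4class{PhotometrySignal}.
#' @param events the session \linkS4class{EventLog}.
#' @param window peri-lick window (s relative to first lick).
#' @param baseline_s pre-lick baseline duration (s).
#' @return a \linkS4class{TrialSet}.
#' @export
segmentTrials <- function(dff, events, window = c(-10, 20),
                          baseline_s = 10) {
  stopifnot(is(dff, "PhotometrySignal"), is(events, "EventLog"))
  wins <- .parse_trial_windows(events)
  sol_map <- events@solution_map
  n_bins <- round((window[2] - window[1]) / .BIN_W)
  span <- range(dff@timestamps)
  n <- nrow(wins)
  z <- matrix(NA_real_, n, n_bins)
  info <- data.frame(index = seq_len(n), trial_type = wins$trial_type,
                     solution = NA_character_, sipper_id = wins$sipper_id,
                     t_extend = wins$t_extend,
                     t_first_lick = wins$t_first_lick,
                     t_retract = wins$t_retract, n_licks = wins$n_licks,
                     analyzable = FALSE, truncated = FALSE,
                     baseline_mean = NA_real_, baseline_sd = NA_real_,
                     stringsAsFactors = FALSE)
  info$solution[!is.na(wins$sipper_id)] <-
    unname(sol_map[wins$sipper_id[!is.na(wins$sipper_id)]])
  licks <- events@events[events@events$kind == "lick", , drop = FALSE]
  lick_times <- vector("list", n)
  for (i in seq_len(n)) {
    lick_times[[i]] <- licks$time[licks$time >= wins$t_extend[i] &
                                  licks$time <= wins$t_retract[i] + 1e-9]
    t1 <- wins$t_first_lick[i]
    if (is.na(t1)) next
    if (t1 + window[1] < span[1] - 1e-9 || t1 + window[2] > span[2] + .BIN_W) {
      info$truncated[i] <- TRUE
      next
    }
    zt <- zscoreTrial(dff, t1, window, baseline_s)
    z[i, ] <- as.numeric(zt)
    info$baseline_mean[i] <- attr(zt, "baseline_mean")
    info$baseline_sd[i] <- attr(zt, "baseline_sd")
    info$analyzable[i] <- TRUE
  }
  new("TrialSet", info = info, z = z,
      bin_centers = window[1] + (seq_len(n_bins) - 0.5) * .BIN_W,
      lick_times = lick_times)
}

#' AUC of a binned z trace over a peri-lick window
#'
#' Integral of the 100-ms-binned trace over \code{[a, b)} seconds relative
#' to the first lick: \code{dt * sum(bin means)} over the bins inside the
#' window (exact for the integral of the underlying trace in expectation,
#' and exactly additive over adjacent windows). Units are z·s.
#'
#' @param z numeric z trace (from \code{\link{zscoreTrial}}) or the z matrix
#'   of a \linkS4class{TrialSet} (trials in rows).
#' @param window c(a, b), s relative to first lick.
#' @param bin_centers bin-center times; taken from the \code{z} attribute or
#'   \linkS4class{TrialSet} when omitted.
#' @param scale \code{"z_seconds"} (default, dt = 0.1 s) or \code{"z_bins"}
#'   (sum of bin z values, 10x larger).
#' @return numeric AUC (vector, one per row, for matrix input).
#' @export
aucWindow <- function(z, window, bin_centers = NULL,
                      scale = c("z_seconds", "z_bins")) {
  scale <- match.arg(scale)
  if (is(z, "TrialSet")) {
    bin_centers <- z@bin_centers
    z <- z@z
  }
  if (is.null(bin_centers)) bin_centers <- attr(z, "bin_centers")
  if (is.null(bin_centers)) stop("bin_centers required")
  sel <- bin_centers > window[1] & bin_centers < window[2]
  n_expect <- round((window[2] - window[1]) / .BIN_W)
  if (sum(sel) < n_expect)
    stop("window not covered by the z trace")
  dt <- if (scale == "z_seconds") .BIN_W else 1
  if (is.matrix(z)) rowSums(z[, sel, drop = FALSE]) * dt
  else sum(z[sel]) * dt
}

#' Latency from sipper extension to the peak of the z trace
#'
#' Time from sipper extension to the maximum of the trial's z-scored trace,
#' searched between extension and retraction (ties resolved to the earliest
#' bin).
#'
#' @param z numeric z trace of one trial.
#' @param t_extend,t_first_lick,t_retract trial event times (s, session
#'   time).
#' @param bin_centers bin centers relative to first lick; default from
#'   attribute.
#' @return latency in seconds from \code{t_extend}.
#' @export
latencyToPeak <- function(z, t_extend, t_first_lick, t_retract,
                          bin_centers = attr(z, "bin_centers")) {
  t_sess <- t_first_lick + bin_centers
  sel <- which(t_sess >= t_extend & t_sess <= t_retract & is.finite(z))
  if (!length(sel)) stop("empty peak-search window")
  peak <- sel[which.max(z[sel])]
  t_sess[peak] - t_extend
}

#' Pre-session baseline AUC
#'
#' Quantifies spontaneous activity in the epoch from session start to the
#' first sipper extension: the dF/F trace is binned at 100 ms, z-scored
#' against the statistics of the first \code{baseline_s} seconds of the
#' epoch (the same 10-s baseline rule the trial metrics use), and integrated
#' over the whole epoch.
#'
#' @param dff the \code{"dff"} \linkS4class{PhotometrySignal}.
#' @param events the session \linkS4class{EventLog}.
#' @param baseline_s duration used for the z statistics (s).
#' @return list with \code{auc_presession} (z·s) and \code{epoch}
#'   (c(0, t_first_trial)).
#' @export
sessionBaseline <- function(dff, events, baseline_s = 10) {
  ext <- events@events$time[events@events$kind == "sipper_extend"]
  if (!length(ext)) stop("no sipper_extend events")
  t1 <- min(ext)
  if (t1 <= 0) stop("first trial at t = 0: no pre-session epoch")
  n_bins <- floor(t1 / .BIN_W)
  x <- .bin_trace(dff, 0, n_bins)
  x <- x[is.finite(x)]
  nb <- min(round(baseline_s / .BIN_W), length(x))
  mu <- mean(x[seq_len(nb)])
  sd_bl <- stats::sd(x[seq_len(nb)])
  if (is.na(sd_bl) || sd_bl == 0) stop("degenerate baseline: zero variance")
  z <- (x - mu) / sd_bl
  list(auc_presession = sum(z) * .BIN_W, epoch = c(0, t1))
}

#' Tidy per-trial metrics table
#'
#' One row per trial with the identifiers and the neural/behavioral trial
#' metrics: lick count, latency to lick, AUC over [0, 5) s after the first
#' lick (consumption epoch, equal to the lick-to-retract window), AUC over
#' [5, 10) s (post-retraction epoch), pre-lick baseline statistics, and
#' latency from extension to the z-trace peak.
#'
#' @param trials a \linkS4class{TrialSet}.
#' @param auc_windows list of two windows (s relative to first lick).
#' @param scale AUC scale, see \code{\link{aucWindow}}.
#' @return data.frame, one row per trial; non-analyzable trials carry NA
#'   metrics.
#' @export
trialMetrics <- function(trials, auc_windows = list(c(0, 5), c(5, 10)),
                         scale = "z_seconds") {
  stopifnot(is(trials, "TrialSet"))
  inf <- trials@info
  out <- data.frame(index = inf$index, trial_type = inf$trial_type,
                    solution = inf$solution, sipper_id = inf$sipper_id,
                    t_extend = inf$t_extend, t_first_lick = inf$t_first_lick,
                    t_retract = inf$t_retract, n_licks = inf$n_licks,
                    latency_lick = inf$t_first_lick - inf$t_extend,
                    auc_0_5 = NA_real_, auc_5_10 = NA_real_,
                    baseline_mean = inf$baseline_mean,
                    baseline_sd = inf$baseline_sd,
                    latency_peak = NA_real_, analyzable = inf$analyzable,
                    truncated = inf$truncated, stringsAsFactors = FALSE)
  ok <- which(inf$analyzable)
  if (length(ok)) {
    out$auc_0_5[ok] <- aucWindow(trials@z[ok, , drop = FALSE],
                                 auc_windows[[1]], trials@bin_centers,
                                 scale = scale)
    out$auc_5_10[ok] <- aucWindow(trials@z[ok, , drop = FALSE],
                                  auc_windows[[2]], trials@bin_centers,
                                  scale = scale)
    out$latency_peak[ok] <- vapply(ok, function(i)
      latencyToPeak(trials@z[i, ], inf$t_extend[i], inf$t_first_lick[i],
                    inf$t_retract[i], trials@bin_centers), numeric(1))
  }
  out
}
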