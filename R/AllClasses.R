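#' @import methods
NULL

.CHANNEL_LABELS <- c("470_raw", "405_raw", "470_demod", "405_demod",
                     "corrected", "dff")
.EVENT_KINDS <- c("sipper_extend", "sipper_retract", "cue_on", "cue_off", "lick")
.SIPPER_IDS <- c("left", "right", "none")
.SOLUTIONS <- c("casein", "maltodextrin")
.BODY_PARTS <- c("nose", "ear_left", "ear_right", "tail_base")
.DIET_STATES <- c("NR", "PR")
.SESSION_KINDS <- c("pretraining", "conditioning", "preference_test")

#' PhotometrySignal: one continuous photometry channel
#'
#' A uniformly sampled fluorescence trace with an explicit time axis in
#' seconds from session start. Channels are labelled by their place in the
#' processing chain: raw carrier-modulated (\code{470_raw}, \code{405_raw}),
#' demodulated baseband (\code{470_demod}, \code{405_demod}), the
#' isosbestic-corrected trace (\code{corrected}) and the normalised trace
#' (\code{dff}).
#'
#' @slot timestamps numeric, seconds from session start; strictly increasing
#'   and uniform to within 1e-9 s.
#' @slot values numeric, fluorescence in volts (or dimensionless for
#'   \code{corrected}/\code{dff}).
#' @slot sample_rate numeric scalar, Hz.
#' @slot channel_label one of the six channel labels above.
#' @exportClass PhotometrySignal
setClass("PhotometrySignal",
  representation(timestamps = "numeric", values = "numeric",
                 sample_rate = "numeric", channel_label = "character"))

setValidity("PhotometrySignal", function(object) {
  ts <- object@timestamps
  if (length(ts) < 2L) return("signal must have length >= 2")
  if (length(object@values) != length(ts))
    return("timestamps and values differ in length")
  if (length(object@sample_rate) != 1L || !is.finite(object@sample_rate) ||
      object@sample_rate <= 0)
    return("sample_rate must be a positive scalar")
  if (!(object@channel_label %in% .CHANNEL_LABELS))
    return(sprintf("channel_label must be one of %s",
                   paste(.CHANNEL_LABELS, collapse = ", ")))
  dt <- diff(ts)
  if (any(dt <= 0)) return("timestamps must be strictly increasing")
  if (max(abs(dt - 1 / object@sample_rate)) > 1e-9)
    return("timestamps must be uniform at 1/sample_rate to within 1e-9 s")
  TRUE
})

#' Construct a PhotometrySignal
#'
#' @param values numeric trace.
#' @param sample_rate sampling rate in Hz.
#' @param channel_label channel label; see \linkS4class{PhotometrySignal}.
#' @param t0 time of the first sample (s); default 0.
#' @param timestamps explicit time axis; overrides \code{t0} if given.
#' @return a \linkS4class{PhotometrySignal}.
#' @examples
#' sig <- PhotometrySignal(sin(seq(0, 2 * pi, length.out = 100)),
#'                         sample_rate = 10, channel_label = "470_demod")
#' sampleRate(sig)
#' @export
PhotometrySignal <- function(values, sample_rate, channel_label,
                             t0 = 0, timestamps = NULL) {
  if (is.null(timestamps))
    timestamps <- t0 + (seq_along(values) - 1) / sample_rate
  new("PhotometrySignal", timestamps = as.numeric(timestamps),
      values = as.numeric(values), sample_rate = as.numeric(sample_rate),
      channel_label = as.character(channel_label))
}

#' EventLog: time-stamped behavioral events
#'
#' Holds the lickometer / sipper TTL record of one session and the mapping
#' from sipper side to the solution it delivers.
#'
#' @slot events data.frame with columns \code{time} (s), \code{kind}
#'   (sipper_extend, sipper_retract, cue_on, cue_off, lick) and
#'   \code{sipper_id} (left, right, none).
#' @slot solution_map named character: sipper side -> solution
#'   (casein or maltodextrin).
#' @exportClass EventLog
setClass("EventLog",
  representation(events = "data.frame", solution_map = "character"))

setValidity("EventLog", function(object) {
  ev <- object@events
  need <- c("time", "kind", "sipper_id")
  if (!all(need %in% names(ev)))
    return("events must have columns time, kind, sipper_id")
  if (nrow(ev)) {
    if (any(!is.finite(ev$time)) || any(ev$time < 0))
      return("event times must be finite and non-negative")
    if (is.unsorted(ev$time)) return("event times must be sorted")
    if (!all(ev$kind %in% .EVENT_KINDS))
      return("unknown event kind")
    if (!all(ev$sipper_id %in% .SIPPER_IDS))
      return("unknown sipper_id")
    if (any(ev$kind == "lick" & ev$sipper_id == "none"))
      return("every lick must carry a sipper_id other than 'none'")
  }
  sm <- object@solution_map
  if (length(sm) && (!all(names(sm) %in% c("left", "right")) ||
                     !all(sm %in% .SOLUTIONS)))
    return("solution_map must map left/right to casein/maltodextrin")
  TRUE
})

#' Construct an EventLog
#'
#' @param events data.frame with columns \code{time}, \code{kind},
#'   \code{sipper_id}.
#' @param solution_map named character vector, e.g.
#'   \code{c(left = "casein", right = "maltodextrin")}.
#' @return an \linkS4class{EventLog}.
#' @export
EventLog <- function(events, solution_map) {
  events <- data.frame(time = as.numeric(events$time),
                       kind = as.character(events$kind),
                       sipper_id = as.character(events$sipper_id),
                       stringsAsFactors = FALSE)
  new("EventLog", events = events, solution_map = solution_map)
}

#' TrackingTable: pose-estimation coordinates
#'
#' Long-format body-part coordinates exported by markerless pose tracking
#' (one row per frame x body part), plus the video frame rate.
#'
#' @slot data data.frame with columns \code{frame} (integer, 0-based),
#'   \code{body_part}, \code{x}, \code{y} (pixels), \code{likelihood} in
#'   [0, 1].
#' @slot frame_rate numeric scalar, Hz (typically 5 or 10).
#' @exportClass TrackingTable
setClass("TrackingTable",
  representation(data = "data.frame", frame_rate = "numeric"))

setValidity("TrackingTable", function(object) {
  d <- object@data
  need <- c("frame", "body_part", "x", "y", "likelihood")
  if (!all(need %in% names(d)))
    return("tracking data must have columns frame, body_part, x, y, likelihood")
  if (length(object@frame_rate) != 1L || object@frame_rate <= 0)
    return("frame_rate must be a positive scalar")
  if (nrow(d)) {
    if (any(d$frame < 0)) return("frame indices must be non-negative")
    lk <- d$likelihood
    if (any(!is.na(lk) & (lk < 0 | lk > 1)))
      return("likelihood must lie in [0, 1]")
    if (!all(d$body_part %in% .BODY_PARTS))
      return("unknown body_part")
  }
  TRUE
})

#' Construct a TrackingTable
#' @param data long-format data.frame (frame, body_part, x, y, likelihood).
#' @param frame_rate video frame rate in Hz.
#' @return a \linkS4class{TrackingTable}.
#' @export
TrackingTable <- function(data, frame_rate) {
  new("TrackingTable",
      data = data.frame(frame = as.integer(data$frame),
                        body_part = as.character(data$body_part),
                        x = as.numeric(data$x), y = as.numeric(data$y),
                        likelihood = as.numeric(data$likelihood),
                        stringsAsFactors = FALSE),
      frame_rate = as.numeric(frame_rate))
}

#' SessionMeta: identity and design of one recording session
#'
#' @slot rat_id character.
#' @slot diet_state current diet: \code{"NR"} (14\% protein chow) or
#'   \code{"PR"} (5\% protein).
#' @slot diet_history ordered character vector of diet states (captures
#'   diet-switch designs such as NR then PR).
#' @slot session_kind pretraining, conditioning or preference_test.
#' @slot test_index integer 1..3 for preference tests, NA otherwise.
#' @slot flavor_map named character: flavor label -> nutrient.
#' @slot sipper_coordinates named list: sipper side -> c(x, y) pixels, or
#'   empty.
#' @slot extra list of unknown metadata keys, preserved on round-trip.
#' @exportClass SessionMeta
setClass("SessionMeta",
  representation(rat_id = "character", diet_state = "character",
                 diet_history = "character", session_kind = "character",
                 test_index = "integer", flavor_map = "character",
                 sipper_coordinates = "list", extra = "list"))

setValidity("SessionMeta", function(object) {
  if (!(object@diet_state %in% .DIET_STATES))
    return("diet_state must be NR or PR")
  if (!(object@session_kind %in% .SESSION_KINDS))
    return("unknown session_kind")
  if (object@session_kind == "preference_test" &&
      (length(object@test_index) != 1L || is.na(object@test_index)))
    return("preference_test sessions require test_index")
  if (!is.na(object@test_index) && !(object@test_index %in% 1:3))
    return("test_index must be 1, 2 or 3")
  if (length(object@flavor_map) &&
      !all(.SOLUTIONS %in% object@flavor_map))
    return("flavor_map must cover both nutrients")
  TRUE
})

#' Construct a SessionMeta
#'
#' @param rat_id subject identifier.
#' @param diet_state "NR" or "PR".
#' @param diet_history ordered diet states; defaults to \code{diet_state}.
#' @param session_kind "pretraining", "conditioning" or "preference_test".
#' @param test_index preference-test number (1..3) or NA.
#' @param flavor_map named character, flavor -> nutrient; default maps
#'   cherry/grape to casein/maltodextrin.
#' @param sipper_coordinates named list sipper -> c(x, y) pixels.
#' @param extra list of additional metadata, preserved verbatim.
#' @return a \linkS4class{SessionMeta}.
#' @export
SessionMeta <- function(rat_id, diet_state = "NR",
                        diet_history = diet_state,
                        session_kind = "preference_test",
                        test_index = if (session_kind == "preference_test") 1L else NA_integer_,
                        flavor_map = c(cherry = "casein", grape = "maltodextrin"),
                        sipper_coordinates = list(), extra = list()) {
  new("SessionMeta", rat_id = as.character(rat_id),
      diet_state = diet_state, diet_history = as.character(diet_history),
      session_kind = session_kind, test_index = as.integer(test_index),
      flavor_map = flavor_map, sipper_coordinates = sipper_coordinates,
      extra = extra)
}

setClassUnion("TrackingTableOrNULL", c("TrackingTable", "NULL"))

#' PhotometrySession: one rat-day recording bundle
#'
#' The central container: photometry channels, event log, metadata and
#' (optionally) pose tracking for one session.
#'
#' @slot meta a \linkS4class{SessionMeta}.
#' @slot signals named list of \linkS4class{PhotometrySignal}, keyed by
#'   channel label. At least one complete pair (470_raw + 405_raw or
#'   470_demod + 405_demod) must be present.
#' @slot events an \linkS4class{EventLog}.
#' @slot tracking a \linkS4class{TrackingTable} or NULL.
#' @exportClass PhotometrySession
setClass("PhotometrySession",
  representation(meta = "SessionMeta", signals = "list",
                 events = "EventLog", tracking = "TrackingTableOrNULL"))

setValidity("PhotometrySession", function(object) {
  sg <- object@signals
  if (!all(vapply(sg, is, logical(1), "PhotometrySignal")))
    return("signals must be PhotometrySignal objects")
  labs <- vapply(sg, function(s) s@channel_label, character(1))
  if (!identical(unname(labs), names(sg)) && !is.null(names(sg)))
    if (!all(names(sg) == labs)) return("signal list names must equal channel labels")
  has_raw <- all(c("470_raw", "405_raw") %in% labs)
  has_dem <- all(c("470_demod", "405_demod") %in% labs)
  if (!has_raw && !has_dem)
    return("need 470_raw+405_raw or 470_demod+405_demod channels")
  ev <- object@events@events
  if (nrow(ev)) {
    span <- range(unlist(lapply(sg, function(s) range(s@timestamps))))
    if (min(ev$time) < span[1] - 1e-6 || max(ev$time) > span[2] + 1e-6)
      return("event times must fall within the signal time span")
  }
  TRUE
})

#' Construct a PhotometrySession
#'
#' @param meta \linkS4class{SessionMeta}.
#' @param signals list of \linkS4class{PhotometrySignal}; named by channel
#'   label (names are filled in from the labels when missing).
#' @param events \linkS4class{EventLog}.
#' @param tracking \linkS4class{TrackingTable} or NULL.
#' @return a \linkS4class{PhotometrySession}.
#' @export
PhotometrySession <- function(meta, signals, events, tracking = NULL) {
  names(signals) <- vapply(signals, function(s) s@channel_label, character(1))
  new("PhotometrySession", meta = meta, signals = signals, events = events,
      tracking = tracking)
}

#' TrialSet: first-lick-aligned trials of one session
#'
#' Produced by \code{\link{segmentTrials}}. Carries one row of trial info per
#' sipper presentation and, for analyzable (licked) trials, the 100-ms-binned
#' z-scored trace on [-10, +20) s around the first lick.
#'
#' @slot info data.frame with one row per trial: \code{index},
#'   \code{trial_type} (forced/free), \code{solution}, \code{sipper_id},
#'   \code{t_extend}, \code{t_first_lick}, \code{t_retract}, \code{n_licks},
#'   \code{analyzable}, \code{truncated}.
#' @slot z matrix (trials x bins) of z values; NA rows for non-analyzable
#'   trials.
#' @slot bin_centers numeric, bin-center times (s) relative to first lick.
#' @slot lick_times list of per-trial lick time vectors (session time, s).
#' @exportClass TrialSet
setClass("TrialSet",
  representation(info = "data.frame", z = "matrix", bin_centers = "numeric",
                 lick_times = "list"))

setValidity("TrialSet", function(object) {
  if (nrow(object@z) != nrow(object@info))
    return("z must have one row per trial")
  if (ncol(object@z) != length(object@bin_centers))
    return("z columns must match bin_centers")
  if (length(object@bin_centers) > 1 &&
      max(abs(diff(object@bin_centers) - 0.1)) > 1e-9)
    return("bin width must be exactly 0.1 s")
  ok <- object@info$analyzable
  bad <- which(ok & object@info$t_first_lick <= object@info$t_extend)
  if (length(bad)) return("t_extend must precede t_first_lick")
  TRUE
})

#' EstimationResult: effect size with BCa CI and permutation p
#'
#' The result of \code{\link{meanDifference}}: a mean-difference effect size
#' with a bias-corrected and accelerated (BCa) bootstrap confidence interval
#' and a permutation p-value from t-statistic reshuffles.
#'
#' @slot design "paired", "unpaired" or "one_sample".
#' @slot effect mean difference (or mean minus null value).
#' @slot ci_low,ci_high BCa 95\% bounds.
#' @slot n_boot,n_perm numbers of resamples.
#' @slot p_perm permutation p-value, (count+1)/(n_perm+1).
#' @slot seed integer seed used for resampling.
#' @slot n integer group sizes.
#' @slot flags character vector of quality flags (e.g. "degenerate",
#'   "ci_reordered").
#' @exportClass EstimationResult
setClass("EstimationResult",
  representation(design = "character", effect = "numeric",
                 ci_low = "numeric", ci_high = "numeric",
                 n_boot = "integer", p_perm = "numeric", n_perm = "integer",
                 seed = "integer", n = "integer", flags = "character"))

setValidity("EstimationResult", function(object) {
  if (!(object@design %in% c("paired", "unpaired", "one_sample")))
    return("unknown design")
  if (!is.na(object@p_perm) && (object@p_perm <= 0 || object@p_perm > 1))
    return("p_perm must lie in (0, 1]")
  TRUE
})

#' SyntheticGroundTruth: what the generator injected
#'
#' @slot trials data.frame: per-trial injected response amplitude (z units),
#'   onset (s), solution, trial type and event times.
#' @slot artifacts list of realised artifact parameters/components.
#' @slot params list: the generator parameter sets used.
#' @slot seed integer seed.
#' @exportClass SyntheticGroundTruth
setClass("SyntheticGroundTruth",
  representation(trials = "data.frame", artifacts = "list", params = "list",
                 seed = "integer"))

setMethod("show", "PhotometrySignal", function(object) {
  cat(sprintf("PhotometrySignal [%s] %d samples @ %.6g Hz, t = [%.3f, %.3f] s\n",
              object@channel_label, length(object@values),
              object@sample_rate, object@timestamps[1],
              object@timestamps[length(object@timestamps)]))
})

setMethod("show", "EventLog", function(object) {
  ev <- object@events
  cat(sprintf("EventLog: %d events (%d licks), solutions: %s\n", nrow(ev),
              sum(ev$kind == "lick"),
              paste(sprintf("%s=%s", names(object@solution_map),
                            object@solution_map), collapse = ", ")))
})

setMethod("show", "PhotometrySession", function(object) {
  cat(sprintf("PhotometrySession: rat %s [%s, %s%s]\n", object@meta@rat_id,
              object@meta@diet_state, object@meta@session_kind,
              if (!is.na(object@meta@test_index))
                paste0(" ", object@meta@test_index) else ""))
  cat("  channels:", paste(names(object@signals), collapse = ", "), "\n")
  show(object@events)
  cat("  tracking:", if (is.null(object@tracking)) "none"
      else sprintf("%d rows @ %g Hz", nrow(object@tracking@data),
                   object@tracking@frame_rate), "\n")
})

setMethod("show", "TrialSet", function(object) {
  inf <- object@info
  cat(sprintf("TrialSet: %d trials (%d forced, %d free), %d analyzable\n",
              nrow(inf), sum(inf$trial_type == "forced"),
              sum(inf$trial_type == "free"), sum(inf$analyzable)))
})

setMethod("show", "EstimationResult", function(object) {
  cat(sprintf("EstimationResult (%s): effect = %.4g, 95%% BCa CI [%.4g, %.4g]\n",
              object@design, object@effect, object@ci_low, object@ci_high))
  cat(sprintf("  p_perm = %.4g (%d reshuffles, %d bootstrap samples, seed %d)\n",
              object@p_perm, object@n_perm, object@n_boot, object@seed))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})
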