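## Behavioral metrics: lick microstructure, two-bottle choice preference,
## conditioning intake tables, and pose-track position/distance summaries.

#' Lick counts and latencies per solution
#'
#' Per trial: lick count and latency from sipper extension to first lick;
#' per solution: totals and means over analyzable (licked) trials. Lickless
#' trials are excluded from latency summaries (their count is reported);
#' solutions without analyzable trials report NA, never 0.
#'
#' @param trials a \linkS4class{TrialSet} or the data.frame from
#'   \code{\link{trialMetrics}}.
#' @param trial_type restrict to "forced", "free" or "all" (default
#'   "forced", the convention for latency/lick analyses).
#' @return data.frame, one row per solution: \code{n_trials},
#'   \code{n_analyzable}, \code{n_lickless}, \code{total_licks},
#'   \code{mean_licks}, \code{mean_latency}, \code{median_latency}.
#' @export
lickSummary <- function(trials, trial_type = c("forced", "free", "all")) {
  trial_type <- match.arg(trial_type)
  tm <- if (is(trials, "TrialSet")) trialMetrics(trials) else trials
  if (trial_type != "all") tm <- tm[tm$trial_type == trial_type, , drop = FALSE]
  out <- lapply(.SOLUTIONS, function(s) {
    d <- tm[!is.na(tm$solution) & tm$solution == s, , drop = FALSE]
    a <- d[d$analyzable, , drop = FALSE]
    data.frame(solution = s, n_trials = nrow(d), n_analyzable = nrow(a),
               n_lickless = sum(is.na(d$t_first_lick)),
               total_licks = sum(d$n_licks),
               mean_licks = if (nrow(a)) mean(a$n_licks) else NA_real_,
               mean_latency = if (nrow(a)) mean(a$latency_lick) else NA_real_,
               median_latency = if (nrow(a)) stats::median(a$latency_lick)
                                else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Casein preference from free-choice trials
#'
#' The choice on a free-choice trial is the sipper of the first lick;
#' preference is the fraction of choices that were casein. Lickless free
#' trials count as no-choice and are excluded from the denominator.
#'
#' @param trials a \linkS4class{TrialSet} or \code{\link{trialMetrics}}
#'   data.frame.
#' @return list: \code{n_casein_choices}, \code{n_malt_choices},
#'   \code{n_no_choice}, \code{preference}.
#' @export
caseinPreference <- function(trials) {
  tm <- if (is(trials, "TrialSet")) trialMetrics(trials) else trials
  fc <- tm[tm$trial_type == "free", , drop = FALSE]
  if (!nrow(fc)) stop("no free-choice trials")
  chosen <- fc$solution[!is.na(fc$t_first_lick)]
  n_cas <- sum(chosen == "casein")
  n_mal <- sum(chosen == "maltodextrin")
  if (n_cas + n_mal == 0) stop("no choices made on free-choice trials")
  list(n_casein_choices = n_cas, n_malt_choices = n_mal,
       n_no_choice = nrow(fc) - n_cas - n_mal,
       preference = n_cas / (n_cas + n_mal))
}

## linear interpolation of short gaps in a coordinate series
.interp_gaps <- function(v, max_gap = 5L) {
  bad <- which(is.na(v))
  if (!length(bad) || all(is.na(v))) return(v)
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values & r$lengths <= max_gap)) {
    a <- starts[j] - 1L; b <- ends[j] + 1L
    if (a >= 1L && b <= length(v))
      v[starts[j]:ends[j]] <- v[a] + (v[b] - v[a]) *
        (seq_len(r$lengths[j])) / (r$lengths[j] + 1L)
  }
  v
}

#' Position and distance summary from pose tracking
#'
#' Head position is the centroid of nose and both ears on frames where all
#' three exceed the likelihood threshold; gaps of up to \code{max_gap}
#' frames are linearly interpolated, longer gaps dropped. Distances are
#' Euclidean in mm; total distance moved is the summed frame-to-frame
#' centroid displacement. The occupancy histogram sums to 1 and per-sipper
#' distance densities use Scott's-rule kernel bandwidths.
#'
#' @param tracking a \linkS4class{TrackingTable}.
#' @param sippers named list: sipper side -> c(x, y) in pixels.
#' @param solution_map named character sipper -> solution.
#' @param mm_per_px calibration; default scales the 305-px chamber image to
#'   the 30.5-cm chamber width (1 mm/px).
#' @param likelihood_threshold minimum per-part likelihood (default 0.9).
#' @param max_gap longest interpolated gap, frames.
#' @param grid occupancy grid size c(nx, ny).
#' @return list: \code{mean_dist_casein}, \code{mean_dist_malt},
#'   \code{total_distance_moved} (mm), \code{occupancy} (matrix summing to
#'   1 plus \code{xbreaks}/\code{ybreaks} attributes),
#'   \code{distance_density} (per-solution \code{stats::density} objects),
#'   \code{frames_retained}, \code{frames_total}, \code{warnings}.
#' @export
positionSummary <- function(tracking, sippers, solution_map,
                            mm_per_px = 1, likelihood_threshold = 0.9,
                            max_gap = 5L, grid = c(30, 24)) {
  stopifnot(is(tracking, "TrackingTable"))
  d <- tracking@data
  head_parts <- c("nose", "ear_left", "ear_right")
  frames <- sort(unique(d$frame))
  coord <- function(part, ax) {
    sub <- d[d$body_part == part, , drop = FALSE]
    v <- rep(NA_real_, length(frames))
    ok <- sub$likelihood >= likelihood_threshold
    v[match(sub$frame[ok], frames)] <- sub[[ax]][ok]
    v
  }
  xs <- sapply(head_parts, coord, ax = "x")
  ys <- sapply(head_parts, coord, ax = "y")
  cx <- .interp_gaps(rowMeans(xs), max_gap)
  cy <- .interp_gaps(rowMeans(ys), max_gap)
  keep <- is.finite(cx) & is.finite(cy)
  warnings <- character(0)
  if (mean(keep) < 0.5)
    warnings <- sprintf("only %.0f%% of frames retained after filtering",
                        100 * mean(keep))
  cx <- cx[keep]; cy <- cy[keep]
  dist_to <- function(p) sqrt((cx - p[1])^2 + (cy - p[2])^2) * mm_per_px
  sip_of <- stats::setNames(names(solution_map), solution_map)
  d_cas <- dist_to(sippers[[sip_of[["casein"]]]])
  d_mal <- dist_to(sippers[[sip_of[["maltodextrin"]]]])
  total <- sum(sqrt(diff(cx)^2 + diff(cy)^2)) * mm_per_px
  occ <- NULL
  if (length(cx) > 1) {
    pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r
    rx <- pad(range(cx)); ry <- pad(range(cy))
    xb <- seq(rx[1], rx[2], length.out = grid[1] + 1)
    yb <- seq(ry[1], ry[2], length.out = grid[2] + 1)
    occ <- table(cut(cx, xb, include.lowest = TRUE),
                 cut(cy, yb, include.lowest = TRUE))
    occ <- matrix(occ / sum(occ), nrow = grid[1])
    attr(occ, "xbreaks") <- xb
    attr(occ, "ybreaks") <- yb
  }
  dens <- list(
    casein = if (length(d_cas) > 1 && stats::sd(d_cas) > 0)
      stats::density(d_cas, bw = stats::bw.nrd(d_cas)) else NULL,
    maltodextrin = if (length(d_mal) > 1 && stats::sd(d_mal) > 0)
      stats::density(d_mal, bw = stats::bw.nrd(d_mal)) else NULL)
  list(mean_dist_casein = mean(d_cas), mean_dist_malt = mean(d_mal),
       total_distance_moved = total, occupancy = occ,
       distance_density = dens, frames_retained = sum(keep),
       frames_total = length(keep), warnings = warnings)
}

#' Intake table across conditioning sessions
#'
#' Tidy per-rat x session x nutrient lick totals from conditioning sessions,
#' suitable for external repeated-measures ANOVA.
#'
#' @param sessions list of \linkS4class{PhotometrySession}s
#'   (session_kind "conditioning"); each needs an \code{extra$session_number}
#'   metadata key, or sessions are numbered in list order per rat.
#' @return data.frame: \code{rat_id}, \code{diet_state},
#'   \code{session_number}, \code{solution}, \code{n_licks}. Sessions with
#'   no licks keep a 0-lick row.
#' @export
conditioningIntake <- function(sessions) {
  counters <- new.env()
  rows <- lapply(sessions, function(s) {
    stopifnot(is(s, "PhotometrySession"))
    meta <- s@meta
    sn <- meta@extra$session_number
    if (is.null(sn)) {
      prev <- mget(meta@rat_id, envir = counters, ifnotfound = 0L)[[1]]
      sn <- prev + 1L
      assign(meta@rat_id, sn, envir = counters)
    }
    ev <- s@events@events
    licks <- ev[ev$kind == "lick", , drop = FALSE]
    sols <- unname(s@events@solution_map[licks$sipper_id])
    present <- unique(unname(s@events@solution_map))
    do.call(rbind, lapply(present, function(sol)
      data.frame(rat_id = meta@rat_id, diet_state = meta@diet_state,
                 session_number = as.integer(sn), solution = sol,
                 n_licks = sum(sols == sol), stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
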