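## Session bundle I/O.
##
## A session bundle is a directory holding:
##   metadata.json              identity, design, solution map, unknown keys
##   signal_<label>.csv         time_s,value per photometry channel
##   events.csv                 time_s,kind,sipper_id
##   tracking.csv (optional)    pose export in the 3-row scorer/bodyparts/coords
##                              header dialect
## All times are seconds from session start (float64); numeric columns are
## written with %.17g so that read(write(s)) is lossless and two writes of the
## same session are byte-identical.

.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.write_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

.signal_filename <- function(label) paste0("signal_", label, ".csv")

#' Write a session bundle
#'
#' Serialises a \linkS4class{PhotometrySession} to a directory of
#' plain-text files (metadata JSON, one CSV per photometry channel, an
#' events CSV, and a pose-tracking CSV when tracking is present). Output is
#' deterministic: identical sessions produce byte-identical bundles.
#'
#' @param session a valid \linkS4class{PhotometrySession}.
#' @param path directory to create/overwrite.
#' @return \code{invisible(path)}.
#' @seealso \code{\link{readSession}}
#' @export
writeSession <- function(session, path) {
  stopifnot(is(session, "PhotometrySession"))
  validObject(session)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create bundle directory: ", path)

  meta <- session@meta
  meta_list <- list(
    rat_id = meta@rat_id,
    diet_state = meta@diet_state,
    diet_history = as.list(meta@diet_history),
    session_kind = meta@session_kind,
    test_index = if (is.na(meta@test_index)) NULL else meta@test_index,
    flavor_map = as.list(meta@flavor_map),
    solution_map = as.list(session@events@solution_map),
    sipper_coordinates = meta@sipper_coordinates,
    channels = as.list(names(session@signals)),
    tracking_frame_rate = if (is.null(session@tracking)) NULL
                          else session@tracking@frame_rate)
  meta_list <- c(meta_list, meta@extra)
  jsonlite::write_json(meta_list, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  for (label in names(session@signals)) {
    sig <- session@signals[[label]]
    .write_lines(c("time_s,value",
                   paste(.fmt_num(sig@timestamps), .fmt_num(sig@values),
                         sep = ",")),
                 file.path(path, .signal_filename(label)))
  }

  ev <- session@events@events
  .write_lines(c("time_s,kind,sipper_id",
                 if (nrow(ev)) paste(.fmt_num(ev$time), ev$kind, ev$sipper_id,
                                     sep = ",") else character(0)),
               file.path(path, "events.csv"))

  if (!is.null(session@tracking))
    .write_tracking_csv(session@tracking, file.path(path, "tracking.csv"))
  invisible(path)
}

## pose-export dialect: row1 scorer, row2 bodyparts, row3 coords, then one
## row per frame with x,y,likelihood triplets per body part
.write_tracking_csv <- function(tracking, path) {
  d <- tracking@data
  parts <- intersect(.BODY_PARTS, unique(d$body_part))
  frames <- sort(unique(d$frame))
  header1 <- paste(c("scorer", rep("protophot", 3 * length(parts))),
                   collapse = ",")
  header2 <- paste(c("bodyparts", rep(parts, each = 3)), collapse = ",")
  header3 <- paste(c("coords", rep(c("x", "y", "likelihood"), length(parts))),
                   collapse = ",")
  wide <- matrix(NA_real_, nrow = length(frames), ncol = 3 * length(parts))
  fidx <- match(d$frame, frames)
  pidx <- match(d$body_part, parts)
  wide[cbind(fidx, 3 * (pidx - 1) + 1)] <- d$x
  wide[cbind(fidx, 3 * (pidx - 1) + 2)] <- d$y
  wide[cbind(fidx, 3 * (pidx - 1) + 3)] <- d$likelihood
  rows <- vapply(seq_along(frames), function(i)
    paste(c(frames[i], .fmt_num(wide[i, ])), collapse = ","), character(1))
  .write_lines(c(header1, header2, header3, rows), path)
}

.read_tracking_csv <- function(path, frame_rate) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("tracking.csv: missing pose-export header")
  parts_row <- strsplit(lines[2], ",", fixed = TRUE)[[1]][-1]
  coords_row <- strsplit(lines[3], ",", fixed = TRUE)[[1]][-1]
  body <- if (length(lines) > 3L)
    utils::read.csv(text = lines[-(1:3)], header = FALSE) else
    data.frame(V1 = integer(0))
  parts <- unique(parts_row)
  out <- do.call(rbind, lapply(parts, function(p) {
    cols <- 1L + which(parts_row == p)       # +1 for frame column
    names(cols) <- coords_row[cols - 1L]
    data.frame(frame = as.integer(body[[1]]),
               body_part = p,
               x = as.numeric(body[[cols[["x"]]]]),
               y = as.numeric(body[[cols[["y"]]]]),
               likelihood = as.numeric(body[[cols[["likelihood"]]]]),
               stringsAsFactors = FALSE)
  }))
  out <- out[stats::complete.cases(out[, c("x", "y")]), , drop = FALSE]
  out <- out[order(out$frame, match(out$body_part, .BODY_PARTS)), ,
             drop = FALSE]
  rownames(out) <- NULL
  TrackingTable(out, frame_rate)
}

#' Read a session bundle
#'
#' Reads a bundle written by \code{\link{writeSession}} and returns a
#' validated \linkS4class{PhotometrySession}. Numeric round-trip is lossless
#' to better than 1e-12 relative tolerance.
#'
#' @param path bundle directory.
#' @return a \linkS4class{PhotometrySession}.
#' @export
readSession <- function(path) {
  meta_file <- file.path(path, "metadata.json")
  if (!file.exists(meta_file))
    stop("missing component: metadata.json in ", path)
  m <- jsonlite::read_json(meta_file)

  known <- c("rat_id", "diet_state", "diet_history", "session_kind",
             "test_index", "flavor_map", "solution_map",
             "sipper_coordinates", "channels", "tracking_frame_rate")
  meta <- SessionMeta(
    rat_id = m$rat_id,
    diet_state = m$diet_state,
    diet_history = unlist(m$diet_history),
    session_kind = m$session_kind,
    test_index = if (is.null(m$test_index)) NA_integer_
                 else as.integer(m$test_index),
    flavor_map = unlist(m$flavor_map),
    sipper_coordinates = lapply(m$sipper_coordinates, function(p)
      as.numeric(unlist(p))),
    extra = m[setdiff(names(m), known)])

  channels <- unlist(m$channels)
  signals <- lapply(channels, function(label) {
    f <- file.path(path, .signal_filename(label))
    if (!file.exists(f)) stop("missing component: ", .signal_filename(label))
    d <- utils::read.csv(f)
    dt <- diff(d$time_s)
    PhotometrySignal(d$value, sample_rate = 1 / stats::median(dt),
                     channel_label = label, timestamps = d$time_s)
  })

  ev_file <- file.path(path, "events.csv")
  if (!file.exists(ev_file)) stop("missing component: events.csv")
  ed <- utils::read.csv(ev_file, colClasses = c("numeric", "character",
                                                "character"))
  events <- EventLog(data.frame(time = ed$time_s, kind = ed$kind,
                                sipper_id = ed$sipper_id),
                     solution_map = unlist(m$solution_map))

  tracking <- NULL
  tr_file <- file.path(path, "tracking.csv")
  if (file.exists(tr_file)) {
    fr <- if (is.null(m$tracking_frame_rate)) 10 else
      as.numeric(m$tracking_frame_rate)
    tracking <- .read_tracking_csv(tr_file, fr)
  }

  session <- PhotometrySession(meta, signals, events, tracking)
  validObject(session)
  session
}

## ---- trial-window parsing shared by validateEvents and segmentTrials ----

## Groups sipper_extend events into trials. Extensions on different sippers
## within `simultaneous_tol` seconds form one free-choice trial; a lone
## extension is a forced trial. Returns one row per trial with the matched
## retraction and first lick (NA when lickless).
.parse_trial_windows <- function(events, simultaneous_tol = 0.5) {
  ev <- events@events
  ext <- ev[ev$kind == "sipper_extend", , drop = FALSE]
  ret <- ev[ev$kind == "sipper_retract", , drop = FALSE]
  licks <- ev[ev$kind == "lick", , drop = FALSE]
  if (!nrow(ext))
    return(data.frame(t_extend = numeric(0), t_retract = numeric(0),
                      t_first_lick = numeric(0), trial_type = character(0),
                      sipper_id = character(0), n_licks = integer(0),
                      unmatched_retract = logical(0)))
  ## group simultaneous extensions
  grp <- cumsum(c(TRUE, diff(ext$time) > simultaneous_tol))
  used_ret <- logical(nrow(ret))
  rows <- lapply(split(seq_len(nrow(ext)), grp), function(ix) {
    t_ext <- min(ext$time[ix])
    sippers <- unique(ext$sipper_id[ix])
    type <- if (length(sippers) > 1L) "free" else "forced"
    ## matching retraction: first unused retract after extension, per sipper;
    ## a trial's window ends at the earliest of its sippers' retractions
    t_ret <- NA_real_
    for (s in sippers) {
      cand <- which(!used_ret & ret$sipper_id == s & ret$time > t_ext)
      if (length(cand)) {
        used_ret[cand[1]] <<- TRUE
        t_ret <- if (is.na(t_ret)) ret$time[cand[1]] else
          max(t_ret, ret$time[cand[1]])
      }
    }
    in_win <- licks$time >= t_ext &
      (is.na(t_ret) | licks$time <= t_ret + 1e-9) &
      licks$sipper_id %in% sippers
    lk <- licks[in_win, , drop = FALSE]
    first <- if (nrow(lk)) lk$time[1] else NA_real_
    sip <- if (type == "forced") sippers else
      if (nrow(lk)) lk$sipper_id[1] else NA_character_
    data.frame(t_extend = t_ext, t_retract = t_ret, t_first_lick = first,
               trial_type = type, sipper_id = sip[1], n_licks = nrow(lk),
               unmatched_retract = is.na(t_ret), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate an event log against the task's trial-structure rules
#'
#' Checks the structural invariants (sorted non-negative times, licks carry a
#' sipper, every extension has a matching retraction) plus the task's access
#' rules: on trials with at least one lick the sippers retract 5 s after the
#' first lick; on lickless trials they retract after the 30-s timeout.
#' Violations are returned as data, never raised.
#'
#' @param events an \linkS4class{EventLog}.
#' @param access_s programmed access duration after the first lick (s).
#' @param timeout_s programmed no-lick timeout (s).
#' @param tolerance allowed deviation of retraction timing (s); default 0.25
#'   to absorb hardware retraction latency.
#' @return data.frame with columns \code{rule}, \code{time}, \code{detail};
#'   zero rows iff the log is consistent.
#' @export
validateEvents <- function(events, access_s = 5, timeout_s = 30,
                           tolerance = 0.25) {
  stopifnot(is(events, "EventLog"))
  ev <- events@events
  viol <- list()
  add <- function(rule, time, detail)
    viol[[length(viol) + 1L]] <<- data.frame(rule = rule, time = time,
                                             detail = detail,
                                             stringsAsFactors = FALSE)
  if (nrow(ev)) {
    if (any(ev$time < 0))
      add("nonnegative_times", min(ev$time), "event before session start")
    if (is.unsorted(ev$time))
      add("sorted_times", NA_real_, "event times not sorted")
    bad_lick <- ev$kind == "lick" & ev$sipper_id == "none"
    if (any(bad_lick))
      add("lick_sipper", ev$time[which(bad_lick)[1]],
          "lick without sipper_id")
  }
  trials <- .parse_trial_windows(events)
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    if (tr$unmatched_retract) {
      add("matched_retract", tr$t_extend,
          "sipper_extend without matching sipper_retract")
      next
    }
    if (!is.na(tr$t_first_lick)) {
      if (abs((tr$t_retract - tr$t_first_lick) - access_s) > tolerance)
        add("access_duration", tr$t_extend,
            sprintf("retract - first_lick = %.3f s, expected %g +/- %g",
                    tr$t_retract - tr$t_first_lick, access_s, tolerance))
    } else {
      if (abs((tr$t_retract - tr$t_extend) - timeout_s) > tolerance)
        add("timeout_duration", tr$t_extend,
            sprintf("retract - extend = %.3f s, expected %g +/- %g",
                    tr$t_retract - tr$t_extend, timeout_s, tolerance))
    }
  }
  if (!length(viol))
    return(data.frame(rule = character(0), time = numeric(0),
                      detail = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, viol)
  rownames(out) <- NULL
  out
}
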