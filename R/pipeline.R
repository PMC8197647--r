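## Cohort-level orchestration: preprocess -> trials -> behavior -> stats,
## from sessions in memory or a YAML/JSON config naming session bundles,
## with seed-deterministic estimation statistics and tidy outputs.

#' Read a cohort configuration file
#'
#' YAML or JSON (by extension) with keys: \code{bundles} (session bundle
#' directories), and optionally \code{n_boot}, \code{n_perm},
#' \code{master_seed}, \code{out_dir}.
#'
#' @param path config file.
#' @return validated config list.
#' @export
readCohortConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$bundles) || !length(cfg$bundles))
    stop("config validation error: no session bundles listed")
  cfg$bundles <- as.character(unlist(cfg$bundles))
  missing <- cfg$bundles[!dir.exists(cfg$bundles)]
  if (length(missing))
    stop("config validation error: unresolvable bundle(s): ",
         paste(missing, collapse = ", "))
  cfg$n_boot <- if (is.null(cfg$n_boot)) 5000L else as.integer(cfg$n_boot)
  cfg$n_perm <- if (is.null(cfg$n_perm)) 5000L else as.integer(cfg$n_perm)
  cfg$master_seed <- if (is.null(cfg$master_seed)) 1L
                     else as.integer(cfg$master_seed)
  cfg
}

.as_session_list <- function(cohort) {
  if (is(cohort, "PhotometrySession")) return(list(cohort))
  lapply(cohort, function(el)
    if (is(el, "PhotometrySession")) el
    else if (is.list(el) && is(el$session, "PhotometrySession")) el$session
    else stop("cohort elements must be PhotometrySession objects"))
}

#' Run the full analysis pipeline over a cohort
#'
#' For every session: preprocess (demodulation if raw, FFT-domain
#' isosbestic correction, dF/F), segment into first-lick-aligned trials,
#' compute trial metrics, lick summaries and free-choice preference. Then,
#' per diet group: paired casein-vs-maltodextrin contrasts of the
#' consumption-epoch AUC, lick latency and free-choice licks (BCa CIs and
#' permutation p), one-sample preference test against 0.5, pooled
#' latency-to-lick vs latency-to-peak correlations, and per-rat
#' classification proportions. Fully deterministic given (cohort,
#' master_seed).
#'
#' @param cohort list of \linkS4class{PhotometrySession}s (or of
#'   \code{list(session =, truth =)} pairs as returned by
#'   \code{\link{generateCohort}}), or a config file path / list from
#'   \code{\link{readCohortConfig}} naming session bundles.
#' @param out_dir if non-NULL, writes \code{trials.csv},
#'   \code{behavior.csv}, \code{stats.json} and \code{report.md} there.
#' @param n_boot,n_perm resample counts for the estimation layer.
#' @param master_seed master seed; per-analysis seeds are derived from it
#'   by stable hashing of the analysis label.
#' @param auc_windows the two AUC windows (s relative to first lick).
#' @param verbose log each stage.
#' @return a list with class \code{"StudyReport"}: \code{trials},
#'   \code{behavior}, \code{rat_summary}, \code{contrasts},
#'   \code{preference_tests}, \code{classifications},
#'   \code{classification_proportions}, \code{latency_correlations},
#'   \code{params}.
#' @export
runPipeline <- function(cohort, out_dir = NULL, n_boot = 5000, n_perm = 5000,
                        master_seed = 1L,
                        auc_windows = list(c(0, 5), c(5, 10)),
                        verbose = FALSE) {
  if (is.character(cohort) && length(cohort) == 1 && file.exists(cohort))
    cohort <- readCohortConfig(cohort)
  if (is.list(cohort) && !is.null(cohort$bundles)) {
    n_boot <- cohort$n_boot %||% n_boot
    n_perm <- cohort$n_perm %||% n_perm
    master_seed <- cohort$master_seed %||% master_seed
    out_dir <- out_dir %||% cohort$out_dir
    cohort <- lapply(cohort$bundles, readSession)
  }
  sessions <- .as_session_list(cohort)
  if (!length(sessions)) stop("config validation error: empty cohort")
  say <- function(...) if (verbose) message(sprintf(...))

  trial_tabs <- list(); behav_tabs <- list(); rat_rows <- list()
  for (s in sessions) {
    id <- s@meta@rat_id
    stage_name <- "preprocess"
    res <- tryCatch({
      if (!"dff" %in% names(s@signals)) s <- preprocessSession(s)
      say("preprocessed %s", id)
      stage_name <- "trials"
      ts <- segmentTrials(sessionSignal(s, "dff"), s@events)
      tm <- trialMetrics(ts, auc_windows = auc_windows)
      tm$rat_id <- id
      tm$diet_state <- s@meta@diet_state
      tm$test_index <- s@meta@test_index
      stage_name <- "behavior"
      ls_ <- lickSummary(tm)
      ls_$rat_id <- id; ls_$diet_state <- s@meta@diet_state
      pref <- tryCatch(caseinPreference(tm), error = function(e) NULL)
      bl <- sessionBaseline(sessionSignal(s, "dff"), s@events)
      fa <- tm[tm$analyzable & tm$trial_type == "forced", , drop = FALSE]
      mean_auc <- function(sol)
        if (any(fa$solution == sol)) mean(fa$auc_0_5[fa$solution == sol])
        else NA_real_
      list(tm = tm, ls = ls_,
           rat = data.frame(
             rat_id = id, diet_state = s@meta@diet_state,
             test_index = s@meta@test_index,
             mean_auc_casein = mean_auc("casein"),
             mean_auc_malt = mean_auc("maltodextrin"),
             z_diff = mean_auc("casein") - mean_auc("maltodextrin"),
             mean_latency_casein =
               ls_$mean_latency[ls_$solution == "casein"],
             mean_latency_malt =
               ls_$mean_latency[ls_$solution == "maltodextrin"],
             preference = if (is.null(pref)) NA_real_ else pref$preference,
             n_no_choice = if (is.null(pref)) NA_integer_
                           else pref$n_no_choice,
             auc_presession = bl$auc_presession,
             stringsAsFactors = FALSE))
    }, error = function(e)
      stop(sprintf("pipeline stage '%s' failed for session '%s': %s",
                   stage_name, id, conditionMessage(e)), call. = FALSE))
    trial_tabs[[id]] <- res$tm
    behav_tabs[[id]] <- res$ls
    rat_rows[[id]] <- res$rat
  }
  trials <- do.call(rbind, trial_tabs); rownames(trials) <- NULL
  behavior <- do.call(rbind, behav_tabs); rownames(behavior) <- NULL
  rat_summary <- do.call(rbind, rat_rows); rownames(rat_summary) <- NULL

  groups <- unique(rat_summary$diet_state)
  contrasts <- list(); preference_tests <- list()
  classifications <- list(); latcors <- list()
  for (g in groups) {
    rs <- rat_summary[rat_summary$diet_state == g, , drop = FALSE]
    ok <- is.finite(rs$mean_auc_casein) & is.finite(rs$mean_auc_malt)
    if (sum(ok) >= 2) {
      contrasts[[paste0(g, "_auc_0_5")]] <- meanDifference(
        rs$mean_auc_casein[ok], rs$mean_auc_malt[ok], design = "paired",
        n_boot = n_boot, n_perm = n_perm,
        seed = deriveSeed(master_seed, paste0("auc_", g)))
    }
    okl <- is.finite(rs$mean_latency_casein) & is.finite(rs$mean_latency_malt)
    if (sum(okl) >= 2) {
      contrasts[[paste0(g, "_latency")]] <- meanDifference(
        rs$mean_latency_casein[okl], rs$mean_latency_malt[okl],
        design = "paired", n_boot = n_boot, n_perm = n_perm,
        seed = deriveSeed(master_seed, paste0("latency_", g)))
    }
    okp <- is.finite(rs$preference)
    if (sum(okp) >= 2) {
      preference_tests[[g]] <- meanDifference(
        rs$preference[okp], null_value = 0.5, design = "one_sample",
        n_boot = n_boot, n_perm = n_perm,
        seed = deriveSeed(master_seed, paste0("pref_", g)))
    }
    gt <- trials[trials$diet_state == g & trials$analyzable &
                 trials$trial_type == "forced", , drop = FALSE]
    cls <- lapply(unique(gt$rat_id), function(id) {
      d <- gt[gt$rat_id == id, ]
      classifyRat(d$auc_0_5[d$solution == "casein"],
                  d$auc_0_5[d$solution == "maltodextrin"], rat_id = id)
    })
    classifications[[g]] <- do.call(rbind, cls)
    for (sol in .SOLUTIONS) {
      d <- gt[gt$solution == sol, ]
      latcors[[paste(g, sol, sep = "_")]] <- tryCatch(
        c(latencyCorrelation(d$latency_lick, d$latency_peak),
          group = g, solution = sol),
        error = function(e) NULL)
    }
    say("group %s statistics done", g)
  }
  cls_prop <- lapply(classifications, function(cl)
    if (is.null(cl) || !nrow(cl)) NULL else
      as.list(table(factor(cl$label,
                           levels = c("casein", "maltodextrin", "ns"))) /
                nrow(cl)))

  report <- structure(list(
    trials = trials, behavior = behavior, rat_summary = rat_summary,
    contrasts = contrasts, preference_tests = preference_tests,
    classifications = classifications,
    classification_proportions = cls_prop,
    latency_correlations = latcors,
    params = list(n_boot = n_boot, n_perm = n_perm,
                  master_seed = master_seed,
                  auc_windows = auc_windows)), class = "StudyReport")
  if (!is.null(out_dir)) .write_report(report, out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.est_as_list <- function(e)
  list(design = e@design, effect = e@effect, ci_low = e@ci_low,
       ci_high = e@ci_high, n_boot = e@n_boot, p_perm = e@p_perm,
       n_perm = e@n_perm, seed = e@seed, n = e@n,
       flags = as.list(e@flags))

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$trials, file.path(out_dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(report$behavior, file.path(out_dir, "behavior.csv"),
                   row.names = FALSE)
  stats_json <- list(
    contrasts = lapply(report$contrasts, .est_as_list),
    preference_tests = lapply(report$preference_tests, .est_as_list),
    classification_proportions = report$classification_proportions,
    latency_correlations = lapply(report$latency_correlations, function(l)
      l[c("r", "p", "n", "group", "solution")]),
    rat_summary = report$rat_summary,
    params = report$params)
  jsonlite::write_json(stats_json, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  md <- c("# Study report", "",
          "## Forced-choice behavior (licks, latencies)",
          utils::capture.output(print(report$behavior)), "",
          "## Free-choice preference",
          utils::capture.output(print(
            report$rat_summary[, c("rat_id", "diet_state", "preference")])),
          "", "## AUC contrasts (casein - maltodextrin)",
          unlist(lapply(names(report$contrasts), function(nm)
            c(paste0("### ", nm),
              utils::capture.output(show(report$contrasts[[nm]]))))),
          "", "## Per-rat classification proportions",
          utils::capture.output(utils::str(report$classification_proportions)))
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' Longitudinal diet-switch summary across preference tests
#'
#' Combines per-test study reports of one diet-switch group into per-rat
#' preference and neural-contrast (z_diff) trajectories, between-test paired
#' contrasts (each later test against test 1), per-test classification
#' proportions, and preference-vs-photometry regressions (simple, and with
#' test day as covariate).
#'
#' @param reports named/ordered list of \code{StudyReport}s, one per
#'   preference test (test 1 first).
#' @param group label, e.g. "NR_to_PR" or "PR_to_NR".
#' @param n_boot,n_perm,master_seed estimation-layer controls.
#' @return list: \code{trajectories} (per rat x test), \code{contrasts}
#'   (paired \linkS4class{EstimationResult}s for preference and z_diff),
#'   \code{classification_proportions} (per test), \code{regressions},
#'   \code{excluded_rats}.
#' @export
dietSwitchReport <- function(reports, group = "group", n_boot = 5000,
                             n_perm = 5000, master_seed = 1L) {
  stopifnot(length(reports) >= 2)
  traj <- do.call(rbind, lapply(seq_along(reports), function(i) {
    rs <- reports[[i]]$rat_summary
    data.frame(rat_id = rs$rat_id, test = i, preference = rs$preference,
               z_diff = rs$z_diff, stringsAsFactors = FALSE)
  }))
  counts <- table(traj$rat_id)
  complete <- names(counts)[counts == length(reports)]
  excluded <- setdiff(names(counts), complete)
  wide <- function(var) {
    m <- matrix(NA_real_, length(complete), length(reports),
                dimnames = list(complete, NULL))
    for (i in seq_along(reports)) {
      rs <- traj[traj$test == i, ]
      m[, i] <- rs[[var]][match(complete, rs$rat_id)]
    }
    m
  }
  pref <- wide("preference"); zd <- wide("z_diff")
  contrasts <- list()
  for (i in 2:length(reports)) {
    lab <- sprintf("test%d_vs_test1", i)
    contrasts[[paste0("preference_", lab)]] <- meanDifference(
      pref[, i], pref[, 1], design = "paired", n_boot = n_boot,
      n_perm = n_perm,
      seed = deriveSeed(master_seed, paste0(group, "_pref_", lab)))
    contrasts[[paste0("z_diff_", lab)]] <- meanDifference(
      zd[, i], zd[, 1], design = "paired", n_boot = n_boot, n_perm = n_perm,
      seed = deriveSeed(master_seed, paste0(group, "_zd_", lab)))
  }
  props <- lapply(reports, function(r) r$classification_proportions)
  test_day <- rep(seq_along(reports), each = length(complete))
  regressions <- list(
    simple = tryCatch(preferenceRegression(as.vector(pref), as.vector(zd)),
                      error = function(e) NULL),
    with_test_day = tryCatch(
      preferenceRegression(as.vector(pref), as.vector(zd),
                           test_day = test_day),
      error = function(e) NULL))
  list(group = group, trajectories = traj, contrasts = contrasts,
       classification_proportions = props, regressions = regressions,
       excluded_rats = excluded)
}
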