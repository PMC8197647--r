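## Estimation statistics: mean-difference effect sizes with BCa bootstrap
## confidence intervals and permutation p-values from t-statistic
## reshuffles, per-rat trial-level classification, latency correlations,
## rank tests and preference-vs-neural regressions.

## stable per-analysis seed derived from a master seed and a label
deriveSeed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  as.integer((as.numeric(master) * 48271 + h) %% 2147483647)
}

.t_one <- function(d) {
  s <- stats::sd(d)
  if (s == 0) return(NA_real_)
  mean(d) / (s / sqrt(length(d)))
}

.t_pooled <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 == 0) return(NA_real_)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

## BCa interval from a bootstrap distribution, observed estimate and
## jackknife estimates
.bca_ci <- function(boot, obs, jack, conf = 0.95) {
  flags <- character(0)
  if (stats::sd(boot) == 0 || all(boot == boot[1]))
    return(list(ci = c(obs, obs), flags = "degenerate"))
  p0 <- (sum(boot < obs) + 0.5 * sum(boot == obs)) / length(boot)
  if (p0 <= 0 || p0 >= 1) {
    flags <- c(flags, "z0_extreme")
    p0 <- min(max(p0, 1 / length(boot)), 1 - 1 / length(boot))
  }
  z0 <- stats::qnorm(p0)
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * sum((jm - jack)^2)^1.5
  a <- if (den == 0) 0 else num / den
  alpha <- (1 - conf) / 2
  zlo <- stats::qnorm(alpha); zhi <- stats::qnorm(1 - alpha)
  adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  ci <- unname(stats::quantile(boot, probs = c(adj(zlo), adj(zhi)),
                               names = FALSE))
  list(ci = ci, flags = flags)
}

#' Mean-difference effect size with BCa CI and permutation p
#'
#' The estimation-statistics workhorse: computes the mean difference for a
#' paired, unpaired or one-sample design, a 95\% bias-corrected and
#' accelerated (BCa) bootstrap confidence interval (bias correction from the
#' bootstrap distribution, acceleration from the leave-one-out jackknife),
#' and a two-sided permutation p-value defined as the proportion of
#' reshuffled t-statistics at least as extreme as the observed one, with the
#' finite-sample estimator (count + 1) / (n_perm + 1). Reshuffling: random
#' within-pair sign flips of differences (paired), random group-label
#' reassignment (unpaired), sign flips about the null value (one-sample).
#' All resampling is seed-deterministic.
#'
#' @param x numeric vector (first group, or differences' minuend).
#' @param y numeric vector (second group) for paired/unpaired designs.
#' @param null_value null for the one-sample design (default 0).
#' @param design "paired", "unpaired" or "one_sample".
#' @param n_boot,n_perm resample counts (default 5000 each).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return an \linkS4class{EstimationResult}.
#' @examples
#' r <- meanDifference(c(0.9, 0.8, 0.85, 0.95), null_value = 0.5,
#'                     design = "one_sample", seed = 1)
#' effectSize(r); confInt(r); permP(r)
#' @export
meanDifference <- function(x, y = NULL, null_value = 0,
                           design = c("paired", "unpaired", "one_sample"),
                           n_boot = 5000, n_perm = 5000, seed = 1L,
                           conf = 0.95) {
  design <- match.arg(design)
  x <- as.numeric(x)
  flags <- character(0)
  if (design == "one_sample") {
    if (length(x) < 2) stop("one_sample design needs length >= 2")
    d <- x - null_value
  } else if (design == "paired") {
    if (is.null(y) || length(x) != length(y) || length(x) < 2)
      stop("paired design needs two equal-length vectors, length >= 2")
    d <- x - as.numeric(y)
  } else {
    if (is.null(y) || length(x) < 2 || length(y) < 2)
      stop("unpaired design needs two vectors of length >= 2")
    y <- as.numeric(y)
  }

  .with_seed(seed, {
    if (design %in% c("paired", "one_sample")) {
      n <- length(d)
      effect <- mean(d)
      t_obs <- .t_one(d)
      if (stats::sd(d) == 0) {
        return(new("EstimationResult", design = design, effect = effect,
                   ci_low = effect, ci_high = effect,
                   n_boot = as.integer(n_boot), p_perm = NA_real_,
                   n_perm = as.integer(n_perm), seed = as.integer(seed),
                   n = as.integer(n), flags = "degenerate"))
      }
      boot <- rowMeans(matrix(d[sample.int(n, n * n_boot, replace = TRUE)],
                              n_boot, n))
      jack <- (sum(d) - d) / (n - 1)
      ss <- sum(d^2)
      signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE),
                      n_perm, n)
      m_perm <- as.vector(signs %*% d) / n
      sd_perm <- sqrt(pmax(ss - n * m_perm^2, 0) / (n - 1))
      t_perm <- ifelse(sd_perm == 0, Inf * sign(m_perm),
                       m_perm / (sd_perm / sqrt(n)))
      sizes <- n
    } else {
      nx <- length(x); ny <- length(y)
      effect <- mean(x) - mean(y)
      t_obs <- .t_pooled(x, y)
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        return(new("EstimationResult", design = design, effect = effect,
                   ci_low = effect, ci_high = effect,
                   n_boot = as.integer(n_boot), p_perm = NA_real_,
                   n_perm = as.integer(n_perm), seed = as.integer(seed),
                   n = as.integer(c(nx, ny)), flags = "degenerate"))
      }
      bx <- rowMeans(matrix(x[sample.int(nx, nx * n_boot, replace = TRUE)],
                            n_boot, nx))
      by <- rowMeans(matrix(y[sample.int(ny, ny * n_boot, replace = TRUE)],
                            n_boot, ny))
      boot <- bx - by
      all_v <- c(x, y)
      jack <- vapply(seq_len(nx + ny), function(i)
        if (i <= nx) mean(all_v[seq_len(nx)][-i]) - mean(y)
        else mean(x) - mean(all_v[nx + seq_len(ny)][-(i - nx)]),
        numeric(1))
      t_perm <- vapply(seq_len(n_perm), function(b) {
        idx <- sample.int(nx + ny)
        .t_pooled(all_v[idx[seq_len(nx)]], all_v[idx[nx + seq_len(ny)]])
      }, numeric(1))
      sizes <- c(nx, ny)
    }
    p_perm <- (sum(abs(t_perm) >= abs(t_obs) - 1e-12, na.rm = TRUE) + 1) /
      (n_perm + 1)
    bca <- .bca_ci(boot, effect, jack, conf)
    flags <- c(flags, bca$flags)
    if (effect < bca$ci[1] - 1e-12 || effect > bca$ci[2] + 1e-12)
      flags <- c(flags, "effect_outside_ci")
    new("EstimationResult", design = design, effect = effect,
        ci_low = bca$ci[1], ci_high = bca$ci[2],
        n_boot = as.integer(n_boot), p_perm = p_perm,
        n_perm = as.integer(n_perm), seed = as.integer(seed),
        n = as.integer(sizes), flags = flags)
  })
}

#' Per-rat trial-level classification of nutrient responses
#'
#' Compares a rat's per-trial AUCs on casein versus maltodextrin trials with
#' a classical (pooled-variance) unpaired two-tailed t test and labels the
#' rat "casein" or "maltodextrin" when p < alpha with the corresponding
#' direction, "ns" otherwise. These labels are what population pie-chart
#' proportions are built from.
#'
#' @param casein_aucs,malt_aucs per-trial AUC vectors.
#' @param alpha significance level (default 0.05).
#' @param welch use the Welch t test instead of the pooled-variance test.
#' @param rat_id optional identifier carried through.
#' @return data.frame row: \code{rat_id}, \code{label}, \code{t_statistic},
#'   \code{p_value}, \code{n_casein_trials}, \code{n_malt_trials},
#'   \code{alpha}, \code{flag}.
#' @export
classifyRat <- function(casein_aucs, malt_aucs, alpha = 0.05, welch = FALSE,
                        rat_id = NA_character_) {
  n_c <- length(casein_aucs); n_m <- length(malt_aucs)
  if (n_c < 2 || n_m < 2)
    return(data.frame(rat_id = rat_id, label = "ns", t_statistic = NA_real_,
                      p_value = NA_real_, n_casein_trials = n_c,
                      n_malt_trials = n_m, alpha = alpha,
                      flag = "insufficient_trials", stringsAsFactors = FALSE))
  tt <- stats::t.test(casein_aucs, malt_aucs, var.equal = !welch)
  label <- if (tt$p.value < alpha) {
    if (mean(casein_aucs) > mean(malt_aucs)) "casein" else "maltodextrin"
  } else "ns"
  data.frame(rat_id = rat_id, label = label,
             t_statistic = unname(tt$statistic), p_value = tt$p.value,
             n_casein_trials = n_c, n_malt_trials = n_m, alpha = alpha,
             flag = "", stringsAsFactors = FALSE)
}

#' Correlation between latency to lick and latency to neural peak
#'
#' Pearson correlation (two-sided p from the t transform of r) between the
#' behavioral latency to start licking and the latency of the photometry
#' signal to peak, both measured from sipper extension and pooled across
#' trials.
#'
#' @param latency_lick,latency_peak numeric vectors, one value per trial.
#' @return list: \code{r}, \code{p}, \code{n}, \code{coefficients}
#'   (intercept and slope of peak ~ lick).
#' @export
latencyCorrelation <- function(latency_lick, latency_peak) {
  ok <- is.finite(latency_lick) & is.finite(latency_peak)
  x <- latency_lick[ok]; y <- latency_peak[ok]
  if (length(x) < 3) stop("need at least 3 trials")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in latencies")
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       coefficients = c(intercept = unname(stats::coef(fit)[1]),
                        slope = unname(stats::coef(fit)[2])))
}

#' Mann-Whitney U comparison of two samples
#'
#' Two-sided rank test: exact null distribution when the combined sample
#' size is at most 20 and there are no ties, normal approximation with tie
#' correction otherwise. U is reported for the first sample.
#'
#' @param a,b numeric vectors.
#' @return list: \code{U}, \code{p}, \code{method}.
#' @export
rankCompare <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  ties <- any(duplicated(c(a, b)))
  exact <- (length(a) + length(b) <= 20) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal_tie_corrected")
}

#' Regression of behavioral preference on the neural contrast
#'
#' Relates per-rat(-per-test) casein preference to the neural contrast
#' (AUC(casein) - AUC(maltodextrin)). Without a covariate this is a simple
#' linear regression reported as Pearson r and p; with \code{test_day} it is
#' an ordinary least-squares fit on both predictors with named beta
#' coefficients.
#'
#' @param preference numeric, casein preference per rat x test.
#' @param z_diff numeric, matching neural AUC contrast.
#' @param test_day optional numeric covariate.
#' @return list: \code{coefficients} (named betas), \code{r} (NA for the
#'   multivariate fit), \code{p}, \code{n}.
#' @export
preferenceRegression <- function(preference, z_diff, test_day = NULL) {
  ok <- is.finite(preference) & is.finite(z_diff) &
    (if (is.null(test_day)) TRUE else is.finite(test_day))
  preference <- preference[ok]; z_diff <- z_diff[ok]
  if (!is.null(test_day)) test_day <- test_day[ok]
  if (length(preference) < 3) stop("need n >= 3")
  if (stats::sd(z_diff) == 0)
    stop("rank-deficient design: constant predictor")
  if (is.null(test_day)) {
    fit <- stats::lm(preference ~ z_diff)
    ct <- stats::cor.test(preference, z_diff)
    list(coefficients = c(intercept = unname(stats::coef(fit)[1]),
                          photometry = unname(stats::coef(fit)[2])),
         r = unname(ct$estimate), p = ct$p.value, n = length(preference))
  } else {
    if (stats::sd(test_day) == 0)
      stop("rank-deficient design: constant covariate")
    fit <- stats::lm(preference ~ z_diff + test_day)
    cf <- stats::coef(fit)
    if (any(is.na(cf))) stop("rank-deficient design")
    sm <- summary(fit)
    list(coefficients = c(intercept = unname(cf[1]),
                          photometry = unname(cf["z_diff"]),
                          test_day = unname(cf["test_day"])),
         r = NA_real_,
         p = stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                       lower.tail = FALSE),
         n = length(preference))
  }
}
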