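#' Harrell's concordance index
#'
#' Over all ordered pairs (i, j) with `T_i < T_j` and `event_i = 1`, risk
#' scores concordant with the outcome (`risk_i > risk_j`) count 1, tied
#' risks count 0.5, and `c = (concordant + 0.5 * ties) / comparable`.
#' Equal-time pairs are never comparable (tied event times carry no
#' ordering information).
#'
#' @param risks numeric risk score per patient (higher = worse).
#' @param outcomes data frame with `time`, `event`.
#' @return concordance in \[0, 1\].
#' @export
concordance_index <- function(risks, outcomes) {
  outcomes <- check_outcomes(outcomes)
  if (length(risks) != nrow(outcomes))
    stop_cms("risks and outcomes are not aligned")
  cnt <- .concordance_counts(as.numeric(outcomes$time),
                             as.integer(outcomes$event), as.numeric(risks))
  if (cnt[3] == 0)
    stop_cms("concordance undefined: no comparable pairs")
  (cnt[1] + 0.5 * cnt[2]) / cnt[3]
}

#' Percentile bootstrap confidence interval for the c-index
#'
#' Patients are resampled with replacement; replicates without comparable
#' pairs are redrawn (their count is reported).
#'
#' @inheritParams concordance_index
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param level interval level, default 0.95.
#' @return list with `point`, `low`, `high`, `n_boot`, `n_redrawn`.
#' @export
bootstrap_ci <- function(risks, outcomes, n_boot = 1000, seed = 1L,
                         level = 0.95) {
  n_boot <- check_count(n_boot, "n_boot", min = 100L)
  check_prob(level, "level")
  point <- concordance_index(risks, outcomes)
  n <- length(risks)
  time <- as.numeric(outcomes$time); event <- as.integer(outcomes$event)
  rk <- as.numeric(risks)
  redrawn <- 0L
  stats <- with_seed(derive_seed(seed, "boot"), {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
    s <- .concordance_boot(time, event, rk, idx)
    while (anyNA(s)) {  # replicates without comparable pairs are redrawn
      bad <- which(is.na(s))
      redrawn <- redrawn + length(bad)
      if (redrawn > 100L * n_boot)
        stop_cms("could not draw bootstrap replicates with comparable pairs")
      idx2 <- matrix(sample.int(n, n * length(bad), replace = TRUE), n)
      s[bad] <- .concordance_boot(time, event, rk, idx2)
    }
    s
  })
  qs <- quantile(stats, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  list(point = point, low = qs[1], high = qs[2], n_boot = n_boot,
       n_redrawn = redrawn)
}

#' Paired bootstrap comparison of two risk models
#'
#' The same patient resample is applied to both models; the two-sided
#' p-value of the c-index difference uses the add-one correction
#' `(count + 1) / (n_boot + 1)`.
#'
#' @param risks_a,risks_b aligned risk vectors from the two models.
#' @inheritParams bootstrap_ci
#' @return list with `p_value`, `delta` (observed `c_a - c_b`) and the
#'   bootstrap mean difference.
#' @export
paired_model_compare <- function(risks_a, risks_b, outcomes, n_boot = 1000,
                                 seed = 1L) {
  if (length(risks_a) != length(risks_b))
    stop_cms("risk vectors are not aligned")
  outcomes <- check_outcomes(outcomes)
  if (length(risks_a) != nrow(outcomes))
    stop_cms("risks and outcomes are not aligned")
  n_boot <- check_count(n_boot, "n_boot", min = 100L)
  n <- length(risks_a)
  time <- as.numeric(outcomes$time); event <- as.integer(outcomes$event)
  a <- as.numeric(risks_a); b <- as.numeric(risks_b)
  delta <- with_seed(derive_seed(seed, "pairboot"), {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
    ca <- .concordance_boot(time, event, a, idx)
    cb <- .concordance_boot(time, event, b, idx)
    while (anyNA(ca)) {  # same resample applied to both models
      bad <- which(is.na(ca))
      idx2 <- matrix(sample.int(n, n * length(bad), replace = TRUE), n)
      ca[bad] <- .concordance_boot(time, event, a, idx2)
      cb[bad] <- .concordance_boot(time, event, b, idx2)
    }
    ca - cb
  })
  p_le <- (sum(delta <= 0) + 1) / (n_boot + 1)
  p_ge <- (sum(delta >= 0) + 1) / (n_boot + 1)
  obs <- concordance_index(risks_a, outcomes) -
    concordance_index(risks_b, outcomes)
  list(p_value = min(1, 2 * min(p_le, p_ge)), delta = obs,
       boot_mean_delta = mean(delta))
}

# Kaplan-Meier product-limit estimate for one group
km_curve <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ev_times <- unique(time[event == 1])
  surv <- 1
  out <- data.frame(time = 0, survival = 1,
                    at_risk = length(time))
  for (t in ev_times) {
    at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    surv <- surv * (1 - d / at_risk)
    out <- rbind(out, data.frame(time = t, survival = surv, at_risk = at_risk))
  }
  out
}

#' Median-split risk stratification with Kaplan-Meier and log-rank
#'
#' Patients with risk strictly above the median form the high-risk group;
#' those at or below it the low-risk group. Kaplan-Meier curves are
#' estimated per group and the standard two-group log-rank statistic
#' (observed minus expected events over event times, hypergeometric
#' variance) is referred to the chi-square distribution with 1 df.
#'
#' @inheritParams concordance_index
#' @return list with `groups` (factor), `km_curves` (named list of step
#'   function data frames), `statistic` and `p_value`.
#' @export
median_split_logrank <- function(risks, outcomes) {
  outcomes <- check_outcomes(outcomes)
  if (length(risks) < 4) stop_cms("need at least 4 patients")
  med <- median(risks)
  groups <- factor(ifelse(risks > med, "high", "low"), c("low", "high"))
  if (any(table(groups) == 0))
    stop_cms("degenerate split: all risks on one side of the median")
  time <- outcomes$time; event <- outcomes$event
  km <- lapply(split(seq_along(risks), groups), function(i)
    km_curve(time[i], event[i]))
  # two-group log-rank
  g1 <- groups == "high"
  ev_times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ev_times) {
    at <- time >= t
    n_t <- sum(at); n1 <- sum(at & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n_t
    if (n_t > 1)
      V <- V + d * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d) / (n_t - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  p <- if (V > 0) pchisq(stat, df = 1, lower.tail = FALSE) else 1
  list(groups = groups, km_curves = km, statistic = stat, p_value = p)
}

#' Silhouette of embeddings with respect to 5-year survival status
#'
#' Patients are labelled died-within-horizon versus survived-past-horizon;
#' patients censored before the horizon have unknown status and are
#' excluded (their count is reported). The mean silhouette
#' `s_i = (b_i - a_i) / max(a_i, b_i)` over labelled patients uses
#' Euclidean distances; coincident geometry (`a = b = 0`) scores 0.
#'
#' @param embeddings patients x dim numeric matrix.
#' @param outcomes data frame with `time`, `event`.
#' @param horizon label horizon in the cohort's time units (default 5,
#'   i.e. years when times are years).
#' @return list with `score`, `n_excluded_censored`, `labels`.
#' @export
silhouette_by_survival <- function(embeddings, outcomes, horizon = 5) {
  embeddings <- as.matrix(embeddings)
  outcomes <- check_outcomes(outcomes)
  if (nrow(embeddings) != nrow(outcomes))
    stop_cms("embeddings and outcomes are not aligned")
  died <- outcomes$event == 1 & outcomes$time <= horizon
  known <- died | outcomes$time > horizon
  if (sum(known) < 2 || length(unique(died[known])) < 2)
    stop_cms("silhouette undefined: need both labels after exclusion")
  lab <- died[known]
  X <- embeddings[known, , drop = FALSE]
  D <- as.matrix(stats::dist(X))
  s <- vapply(seq_len(nrow(X)), function(i) {
    same <- lab == lab[i]; same[i] <- FALSE
    a <- if (any(same)) mean(D[i, same]) else 0
    b <- mean(D[i, !same & seq_len(nrow(X)) != i])
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  list(score = mean(s), n_excluded_censored = sum(!known),
       labels = ifelse(lab, "died_within_horizon", "survived"))
}

#' Paired t-test on per-fold scores
#'
#' One-sided paired t-test of the hypothesis that `scores_b` exceed
#' `scores_a` (e.g. silhouette after versus before contrastive
#' alignment), paired by cross-validation fold.
#'
#' @param scores_a,scores_b equal-length numeric vectors, paired by fold.
#' @return list with `t`, `p_value`, `mean_diff` and a `degenerate` flag
#'   for zero-variance differences.
#' @export
paired_fold_ttest <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b) || length(scores_a) < 2)
    stop_cms("need equal-length score vectors with at least 2 folds")
  d <- scores_b - scores_a
  if (sd(d) < 1e-15) {
    if (abs(mean(d)) < 1e-15)
      return(list(t = 0, p_value = 1, mean_diff = 0, degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf,
                p_value = if (mean(d) > 0) 0 else 1,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(scores_b, scores_a, paired = TRUE,
                      alternative = "greater")
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_diff = mean(d), degenerate = FALSE)
}
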