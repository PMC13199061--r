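test_that("concordance matches hand-worked and degenerate cases", {
  oc5 <- data.frame(time = 1:5, event = rep(1, 5))
  expect_equal(concordance_index(5:1, oc5), 1)
  expect_equal(concordance_index(rep(2, 5), oc5), 0.5)
  # four-patient fixture: comparable pairs enumerated by hand
  oc <- data.frame(time = 1:4, event = c(1, 1, 0, 1))
  expect_equal(concordance_index(c(4, 2, 3, 1), oc), 0.8)
  expect_error(concordance_index(c(1, 2), data.frame(time = c(1, 2),
                                                     event = c(0, 0))),
               "comparable")
})

test_that("concordance agrees with brute-force enumeration on random instances", {
  set.seed(12)
  for (k in 1:100) {
    n <- sample(3:15, 1)
    oc <- data.frame(time = runif(n, 1, 10), event = rbinom(n, 1, 0.6))
    oc$event[which.min(oc$time)] <- 1   # guarantee a comparable pair
    r <- sample(1:5, n, replace = TRUE) + 0   # deliberate risk ties
    expect_equal(concordance_index(r, oc), brute_cindex(r, oc))
  }
})

test_that("concordance is invariant under monotone transforms and complements", {
  set.seed(13)
  n <- 40
  oc <- data.frame(time = runif(n, 1, 10), event = rbinom(n, 1, 0.5))
  oc$event[1] <- 1
  r <- rnorm(n)
  c0 <- concordance_index(r, oc)
  expect_equal(concordance_index(exp(2 * r) + 3, oc), c0)
  expect_equal(concordance_index(rank(r), oc), c0)
  expect_equal(concordance_index(-r, oc), 1 - c0)  # no risk ties
})

test_that("concordance agrees with survival::concordance on tie-free data", {
  set.seed(14)
  n <- 60
  oc <- data.frame(time = runif(n, 1, 10), event = rbinom(n, 1, 0.5))
  oc$event[1] <- 1
  r <- rnorm(n)
  ref <- survival::concordance(survival::Surv(oc$time, oc$event) ~ r,
                               reverse = TRUE)$concordance
  expect_equal(concordance_index(r, oc), unname(ref), tolerance = 1e-12)
})

test_that("bootstrap intervals are seeded, ordered and degenerate-safe", {
  set.seed(15)
  n <- 50
  oc <- data.frame(time = runif(n, 1, 10), event = rbinom(n, 1, 0.5))
  oc$event[1] <- 1
  r <- rnorm(n)
  ci <- bootstrap_ci(r, oc, n_boot = 200, seed = 4)
  expect_identical(ci, bootstrap_ci(r, oc, n_boot = 200, seed = 4))
  expect_lte(ci$low, ci$high)
  tied <- bootstrap_ci(rep(1, n), oc, n_boot = 100, seed = 1)
  expect_equal(c(tied$low, tied$high), c(0.5, 0.5))
})

test_that("paired model comparison is symmetric and null under identity", {
  set.seed(16)
  n <- 60
  oc <- data.frame(time = runif(n, 1, 10), event = rbinom(n, 1, 0.5))
  oc$event[1] <- 1
  a <- rnorm(n)
  same <- paired_model_compare(a, a, oc, n_boot = 200, seed = 2)
  expect_equal(same$p_value, 1, tolerance = 0.02)
  b <- rnorm(n)
  p_ab <- paired_model_compare(a, b, oc, n_boot = 200, seed = 5)$p_value
  p_ba <- paired_model_compare(b, a, oc, n_boot = 200, seed = 5)$p_value
  expect_equal(p_ab, p_ba)
})

test_that("a real signal is detected against noise risks", {
  hits <- 0
  for (s in 1:10) {
    ch <- small_cohort(n = 300, seed = 400 + s)
    noise <- with(list(), {set.seed(s); rnorm(300)})
    p <- paired_model_compare(ch$true_linear_predictor, noise, ch$outcomes,
                              n_boot = 300, seed = s)$p_value
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / 10, 0.9)
})

test_that("median-split log-rank matches the hypergeometric hand computation", {
  # two groups of five with distinct event times
  time <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  event <- rep(1, 10)
  risks <- c(rep(1, 5), rep(0, 5))   # group high = first five
  res <- median_split_logrank(risks, data.frame(time = time, event = event))
  O <- 0; E <- 0; V <- 0
  g1 <- risks > stats::median(risks)
  for (t in time) {
    at <- time >= t; n_t <- sum(at); n1 <- sum(at & g1)
    d <- 1; d1 <- as.numeric(g1[which(time == t)])
    O <- O + d1; E <- E + d * n1 / n_t
    if (n_t > 1) V <- V + d * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d) / (n_t - 1)
  }
  expect_lt(abs(res$statistic - (O - E)^2 / V), 1e-10)
  expect_equal(res$p_value, stats::pchisq(res$statistic, 1, lower.tail = FALSE))
})

test_that("log-rank agrees with survival::survdiff", {
  set.seed(17)
  n <- 80
  oc <- data.frame(time = runif(n, 1, 10), event = rbinom(n, 1, 0.6))
  oc$event[1] <- 1
  r <- rnorm(n)
  res <- median_split_logrank(r, oc)
  grp <- as.integer(r > stats::median(r))
  ref <- survival::survdiff(survival::Surv(oc$time, oc$event) ~ grp)
  expect_equal(res$statistic, unname(ref$chisq), tolerance = 1e-8)
})

test_that("exchangeable groups give statistic zero and KM curves behave", {
  oc <- data.frame(time = rep(c(1, 2, 3, 4), 2), event = rep(c(1, 0, 1, 1), 2))
  risks <- rep(c(0, 1), each = 4)
  res <- median_split_logrank(risks, oc)
  expect_lt(res$statistic, 1e-12)
  expect_equal(res$p_value, 1)
  for (km in res$km_curves) {
    expect_equal(km$survival[1], 1)
    expect_true(all(diff(km$survival) <= 1e-12))
  }
  # group without events stays at survival 1
  oc2 <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = c(1, 1, 1, 0, 0, 0))
  res2 <- median_split_logrank(c(3, 2, 4, 0, 1, -1), oc2)
  expect_true(all(res2$km_curves$low$survival == 1))
  expect_error(median_split_logrank(rep(1, 6), oc2), "degenerate")
})

test_that("silhouette matches hand computation and cluster::silhouette", {
  # four planar points, two per label
  X <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  oc <- data.frame(time = c(1, 1, 10, 10), event = c(1, 1, 0, 0))
  res <- silhouette_by_survival(X, oc, horizon = 5)
  a <- 1; b <- sqrt(100)  # within-pair distance 1, to the far pair ~10
  expect_equal(res$score,
               mean(c((mean(c(10, sqrt(101))) - 1) / mean(c(10, sqrt(101))),
                      (mean(c(sqrt(101), 10)) - 1) / mean(c(sqrt(101), 10)),
                      (mean(c(10, sqrt(101))) - 1) / mean(c(10, sqrt(101))),
                      (mean(c(sqrt(101), 10)) - 1) / mean(c(sqrt(101), 10)))),
               tolerance = 1e-12)
  ref <- mean(cluster::silhouette(c(1, 1, 2, 2), stats::dist(X))[, "sil_width"])
  expect_equal(res$score, ref, tolerance = 1e-12)
})

test_that("silhouette degenerate and exclusion rules apply", {
  X <- matrix(1, 4, 3)   # identical embeddings: a = b convention gives 0
  oc <- data.frame(time = c(1, 2, 10, 10), event = c(1, 1, 0, 0))
  expect_equal(silhouette_by_survival(X, oc, horizon = 5)$score, 0)
  # two coincident points per label, labels far apart -> score 1
  Y <- rbind(c(0, 0), c(0, 0), c(9, 9), c(9, 9))
  expect_equal(silhouette_by_survival(Y, oc, horizon = 5)$score, 1)
  # patients censored before the horizon are excluded
  oc2 <- data.frame(time = c(1, 2, 3, 10, 10), event = c(1, 1, 0, 0, 0))
  res <- silhouette_by_survival(rbind(Y, c(9, 9)), oc2, horizon = 5)
  expect_equal(res$n_excluded_censored, 1)
  expect_error(silhouette_by_survival(Y, data.frame(time = c(1, 2, 3, 4),
                                                    event = c(1, 1, 1, 1)),
                                      horizon = 5), "both labels")
})

test_that("paired fold t-test conventions and reference values hold", {
  same <- paired_fold_ttest(c(0.2, 0.21, 0.19), c(0.2, 0.21, 0.19))
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
  jit <- paired_fold_ttest(rep(0.2, 5), rep(0.24, 5) + c(1, -1, 2, -2, 0) * 1e-4)
  expect_lt(jit$p_value, 1e-5)
  a <- c(0.18, 0.22, 0.19, 0.21, 0.2)
  b <- c(0.23, 0.25, 0.22, 0.26, 0.24)
  res <- paired_fold_ttest(a, b)
  d <- b - a
  tref <- mean(d) / (stats::sd(d) / sqrt(5))
  pref <- stats::pt(tref, df = 4, lower.tail = FALSE)
  expect_equal(res$t, tref, tolerance = 1e-12)
  expect_lt(abs(res$p_value - pref), 1e-9)
})

test_that("metrics are invariant to patient order", {
  set.seed(18)
  n <- 30
  oc <- data.frame(time = runif(n, 1, 10), event = rbinom(n, 1, 0.6))
  oc$event[1] <- 1
  r <- rnorm(n)
  X <- matrix(rnorm(n * 4), n, 4)
  perm <- sample(n)
  ocp <- data.frame(time = oc$time[perm], event = oc$event[perm])
  expect_equal(concordance_index(r, oc), concordance_index(r[perm], ocp))
  expect_equal(median_split_logrank(r, oc)$statistic,
               median_split_logrank(r[perm], ocp)$statistic, tolerance = 1e-12)
  expect_equal(silhouette_by_survival(X, oc, 5)$score,
               silhouette_by_survival(X[perm, ], ocp, 5)$score,
               tolerance = 1e-12)
})
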