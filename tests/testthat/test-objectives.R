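test_that("Cox partial likelihood matches its analytic special cases", {
  # single patient with an event: h - log(e^h) = 0 for any h
  for (h in c(-3, 0, 2.7))
    expect_equal(cox_partial_nll(h, data.frame(time = 1, event = 1)), 0)
  # equal risks, all events, distinct times: each term log |risk set|
  oc <- data.frame(time = c(1, 2, 3), event = c(1, 1, 1))
  expect_equal(cox_partial_nll(rep(0.4, 3), oc), (log(3) + log(2) + log(1)) / 3)
  # shift invariance
  set.seed(7)
  r <- rnorm(10); oc <- tiny_outcomes(10)
  expect_lt(abs(cox_partial_nll(r, oc) - cox_partial_nll(r + 13.7, oc)), 1e-9)
})

test_that("Cox loss equals the brute-force risk-set enumeration", {
  set.seed(42)
  for (k in 1:60) {
    n <- sample(2:12, 1)
    oc <- data.frame(time = sample(1:6, n, replace = TRUE) + 0,  # many ties
                     event = rbinom(n, 1, 0.7))
    if (sum(oc$event) == 0) oc$event[1] <- 1
    r <- rnorm(n, sd = 1.5)
    expect_lt(abs(cox_partial_nll(r, oc) - brute_cox_nll(r, oc)), 1e-10)
  }
})

test_that("Cox loss gradient matches finite differences", {
  set.seed(3)
  n <- 9
  oc <- data.frame(time = c(1, 1, 2, 3, 3, 3, 4, 5, 6),
                   event = c(1, 0, 1, 1, 1, 0, 0, 1, 1))
  r <- rnorm(n)
  g <- cox_partial_nll_grad(r, oc)$grad
  fd <- vapply(seq_len(n), function(i) {
    e <- rep(0, n); e[i] <- 1e-6
    (cox_partial_nll(r + e, oc) - cox_partial_nll(r - e, oc)) / 2e-6
  }, numeric(1))
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-4)
})

test_that("Cox loss refuses degenerate inputs", {
  expect_error(cox_partial_nll(c(1, 2), data.frame(time = c(1, 2), event = c(0, 0))),
               "zero events")
  expect_error(cox_partial_nll(c(NaN, 1), data.frame(time = c(1, 2), event = c(1, 1))),
               "finite")
})

test_that("InfoNCE analytic cases hold", {
  # batch of one: softmax over a single logit
  expect_equal(info_nce_loss(matrix(1, 1, 1), matrix(1, 1, 1)), 0)
  # four identical rows in both modalities: complete ambiguity, log 4
  v <- c(3, 4) / 5
  P <- matrix(v, 4, 2, byrow = TRUE)
  expect_lt(abs(info_nce_loss(P, P) - log(4)), 1e-10)
  # B = 2 hand-enumerated logits at temperature 0.5
  A <- rbind(c(1, 0), c(0, 1))
  B <- rbind(c(3, 4) / 5, c(-4, 3) / 5)
  tau <- 0.5
  S <- A %*% t(B) / tau
  hand <- -mean(log(exp(diag(S)) / rowSums(exp(S))))
  handT <- -mean(log(exp(diag(S)) / colSums(exp(S))))
  cfg <- contrastive_config(temperature = tau, symmetric = FALSE)
  expect_lt(abs(info_nce_loss(A, B, cfg) - hand), 1e-10)
  cfgS <- contrastive_config(temperature = tau, symmetric = TRUE)
  expect_lt(abs(info_nce_loss(A, B, cfgS) - (hand + handT) / 2), 1e-10)
})

test_that("InfoNCE approaches zero under perfect separation at low temperature", {
  d <- 6; Bn <- 5
  P <- diag(1, Bn, d)   # orthogonal unit rows: matched cosine 1, mismatched 0
  cfg <- contrastive_config(temperature = 0.02)
  expect_lt(info_nce_loss(P, P, cfg), 1e-10)
  expect_gte(info_nce_loss(P, P, contrastive_config(temperature = 1)), 0)
})

test_that("InfoNCE gradient matches finite differences", {
  set.seed(11)
  B <- 4; d <- 3
  mk <- function(M) M / sqrt(rowSums(M^2))
  P <- mk(matrix(rnorm(B * d), B, d)); Q <- mk(matrix(rnorm(B * d), B, d))
  cfg <- contrastive_config(temperature = 0.3)
  g <- info_nce_grad(P, Q, cfg)
  # the loss renormalises its inputs, so raw-coordinate finite differences
  # would differ; check directional derivatives along tangent vectors
  # (orthogonal to each row), where renormalisation is first-order inert
  for (i in seq_len(B)) {
    v <- rnorm(d); v <- v - sum(v * P[i, ]) * P[i, ]; v <- v / sqrt(sum(v^2))
    e <- 1e-6
    up <- P; up[i, ] <- (P[i, ] + e * v) / sqrt(sum((P[i, ] + e * v)^2))
    dn <- P; dn[i, ] <- (P[i, ] - e * v) / sqrt(sum((P[i, ] - e * v)^2))
    fd <- (suppressWarnings(info_nce_loss(up, Q, cfg)) -
             suppressWarnings(info_nce_loss(dn, Q, cfg))) / (2 * e)
    an <- sum(g$grad_image[i, ] * v)
    expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-8), 1e-4)
  }
})

test_that("combined stage-2 loss is linear in lambda", {
  set.seed(5)
  B <- 6; d <- 4
  mk <- function(M) M / sqrt(rowSums(M^2))
  P <- mk(matrix(rnorm(B * d), B, d)); Q <- mk(matrix(rnorm(B * d), B, d))
  risks <- rnorm(B)
  oc <- tiny_outcomes(B)
  nce <- info_nce_loss(P, Q, contrastive_config(lambda_weight = 0))
  cox <- cox_partial_nll(risks, oc)
  expect_equal(stage2_combined_loss(P, Q, risks, oc,
                                    contrastive_config(lambda_weight = 0)), nce)
  expect_lt(abs(stage2_combined_loss(P, Q, risks, oc,
                                     contrastive_config(lambda_weight = 1)) -
                  (nce + cox)), 1e-12)
  l1 <- stage2_combined_loss(P, Q, risks, oc, contrastive_config(lambda_weight = 1))
  l2 <- stage2_combined_loss(P, Q, risks, oc, contrastive_config(lambda_weight = 2))
  expect_lt(abs((l2 - l1) - cox), 1e-12)
})
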