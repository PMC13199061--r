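mk_model <- function(seed = 3, dropout = 0) {
  init_model(5, 3, 6, small_encoder_config(dropout_rate = dropout,
                                           weight_decay = 0), seed = seed)
}

test_that("inference passes are deterministic and batch-invariant", {
  set.seed(1)
  m <- mk_model(dropout = 0.4)   # dropout must be inert at inference
  Xm <- matrix(rbinom(10, 1, 0.5), 2, 5)
  Xc <- matrix(rnorm(6), 2, 3)
  e1 <- encode_nonimage(m, Xm, Xc)
  expect_identical(e1, encode_nonimage(m, Xm, Xc))
  # batch of two equals row-wise concatenation of singleton batches
  r1 <- encode_nonimage(m, Xm[1, , drop = FALSE], Xc[1, , drop = FALSE])
  r2 <- encode_nonimage(m, Xm[2, , drop = FALSE], Xc[2, , drop = FALSE])
  expect_equal(e1, rbind(r1, r2), tolerance = 1e-12)
  # all-zero input maps to a finite embedding
  z <- encode_nonimage(m, matrix(0, 1, 5), matrix(0, 1, 3))
  expect_true(all(is.finite(z)))
})

test_that("shape mismatches name the offending branch", {
  m <- mk_model()
  expect_error(encode_nonimage(m, matrix(0, 1, 4), matrix(0, 1, 3)), "mutation")
  expect_error(encode_nonimage(m, matrix(0, 1, 5), matrix(0, 1, 2)), "clinical")
})

test_that("gated attention weights form a probability vector", {
  set.seed(2)
  m <- mk_model()
  tile <- matrix(rnorm(6), 1, 6)
  fw <- cmsurv:::attention_forward(m$image, tile, 1L, 1L, cache = TRUE)
  expect_equal(fw$a, 1)   # single tile gets weight exactly one
  H <- matrix(rnorm(30), 5, 6)
  fw5 <- cmsurv:::attention_forward(m$image, H, rep(1L, 5), 1L, cache = TRUE)
  expect_equal(sum(fw5$a), 1)
  expect_true(all(fw5$a > 0))
})

test_that("tile aggregation is permutation-invariant and convex over duplicates", {
  set.seed(4)
  m <- mk_model()
  H <- matrix(rnorm(30), 5, 6)
  z <- aggregate_tiles(m, H)
  z_perm <- aggregate_tiles(m, H[sample(5), ])
  expect_equal(z, z_perm, tolerance = 1e-6)
  single <- aggregate_tiles(m, H[3, , drop = FALSE])
  doubled <- aggregate_tiles(m, H[c(3, 3), , drop = FALSE])
  expect_equal(single, doubled, tolerance = 1e-12)
  expect_error(aggregate_tiles(m, list()), "empty")
})

test_that("contrastive projections have unit rows and flag zero vectors", {
  set.seed(5)
  m <- mk_model()
  E <- matrix(rnorm(4 * 6), 4, 6)
  P <- project_contrastive(m, E, "image")
  expect_equal(unname(sqrt(rowSums(P^2))), rep(1, 4), tolerance = 1e-6)
  expect_equal(P[1, ], project_contrastive(m, E[c(1, 1), , drop = FALSE],
                                           "image")[2, ])
  # trained heads have non-zero biases, making them non-homogeneous:
  # scaling an input then changes the projected direction (zero-initialised
  # biases would make the ReLU stack exactly positively homogeneous)
  m2 <- m
  for (l in seq_along(m2$proj$image$layers))
    m2$proj$image$layers[[l]]$b[] <- 0.1 * l
  Pb <- project_contrastive(m2, E, "image")
  P2 <- project_contrastive(m2, 2 * E, "image")
  expect_gt(max(abs(Pb - P2)), 1e-4)
})

test_that("fused risk is deterministic and Cox-shift-irrelevant", {
  set.seed(6)
  m <- mk_model()
  Ei <- matrix(rnorm(5 * 6), 5, 6); En <- matrix(rnorm(5 * 6), 5, 6)
  r <- predict_risk_fused(m, Ei, En)
  expect_identical(r, predict_risk_fused(m, Ei, En))
  oc <- tiny_outcomes(5)
  expect_lt(abs(cox_partial_nll(r, oc) - cox_partial_nll(r + 5, oc)), 1e-9)
  expect_equal(concordance_index(r, oc), concordance_index(r + 5, oc))
  expect_error(predict_risk_fused(m, Ei[1:3, ], En), "misaligned")
})

test_that("every stage loss gradient matches finite differences", {
  data <- small_training_data(n = 12, seed = 2)
  ec <- small_encoder_config(dropout_rate = 0, weight_decay = 0)
  tc <- training_config(encoder = ec,
                        contrastive = contrastive_config(temperature = 0.5,
                                                         lambda_weight = 0.7),
                        seed = 2)
  m <- init_model(5, 3, 6, ec, seed = 3)
  # nudge all parameters off the ReLU kinks created by zero-initialised
  # biases (subgradients differ from two-sided finite differences there)
  jiggle <- function(x) x + matrix(rnorm(length(x), sd = 0.01), nrow(x))
  set.seed(99)
  for (st in c("stage1_nonimage", "stage1_image", "stage2_contrastive",
               "stage3_fused", "adapt_fused")) {
    p <- cmsurv:::get_stage_params(m, st)
    m <- cmsurv:::set_stage_params(m, st, cmsurv:::tree_map(jiggle, p))
  }
  m$trained_stages <- c("stage1_image", "stage1_nonimage", "stage2_contrastive")
  for (st in c("stage1_nonimage", "stage1_image", "stage2_contrastive",
               "stage3_fused", "adapt_fused")) {
    g <- cmsurv:::stage_grad(m, st, data, 1:12, tc, training = FALSE)
    params <- cmsurv:::get_stage_params(m, st)
    fp <- flatten_tree(params)
    fg <- flatten_tree(g$grads)
    expect_identical(names(fp), names(fg))
    worst <- 0
    for (nm in names(fp)) {
      ks <- sample(length(fp[[nm]]), min(2, length(fp[[nm]])))
      for (k in ks) {
        eps <- 1e-5
        bump <- function(d) {
          f2 <- fp; f2[[nm]][k] <- f2[[nm]][k] + d
          cmsurv:::set_stage_params(m, st, unflatten_tree(params, f2))
        }
        l1 <- cmsurv:::stage_grad(bump(eps), st, data, 1:12, tc, training = FALSE)$loss
        l2 <- cmsurv:::stage_grad(bump(-eps), st, data, 1:12, tc, training = FALSE)$loss
        fd <- (l1 - l2) / (2 * eps)
        rel <- abs(fd - fg[[nm]][k]) / max(abs(fd), abs(fg[[nm]][k]), 1e-6)
        worst <- max(worst, rel)
      }
    }
    expect_lt(worst, 1e-4)
  }
})
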