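test_that("cohort generation is deterministic given the seed", {
  cfg <- simulation_config(n_patients = 10, n_mutation_genes = 5,
                           n_causal_mutations = 2, tile_dim = 4,
                           n_tiles_per_patient_range = c(3, 5), seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(simulation_config(n_patients = 10, n_mutation_genes = 5,
                                          n_causal_mutations = 2, tile_dim = 4,
                                          n_tiles_per_patient_range = c(3, 5),
                                          seed = 8))
  expect_false(identical(a$mutation_matrix, c2$mutation_matrix))
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_causal_mutations = 10, n_mutation_genes = 5),
               "exceeds")
  expect_error(simulation_config(n_patients = 0), "integer")
  expect_error(simulation_config(mutation_prevalence_range = c(0, 0.5)),
               "prevalence")
  expect_error(simulation_config(censoring_rate_target = 1.2), "probability|\\(0, 1\\)")
})

test_that("stored generating coefficients exactly reproduce the linear predictor", {
  ch <- small_cohort(n = 60, seed = 3)
  expect_equal(reconstruct_linear_predictor(ch), ch$true_linear_predictor,
               tolerance = 1e-12)
})

test_that("zero image-signal weight makes the predictor independent of tiles", {
  ch <- small_cohort(n = 40, seed = 5, image_signal_weight = 0)
  lp <- ch$true_linear_predictor
  perm <- sample(seq_along(ch$tile_embeddings))
  ch$tile_embeddings <- ch$tile_embeddings[perm]
  expect_equal(reconstruct_linear_predictor(ch), lp, tolerance = 1e-12)
  expect_equal(ch$true_coefficients$class_effects, c(0, 0, 0))
})

test_that("the censoring calibration hits the target event rate", {
  cfg <- simulation_config(n_patients = 500, censoring_rate_target = 0.76, seed = 1)
  ch <- generate_cohort(cfg)
  expect_lt(abs(mean(ch$outcomes$event) - 0.24), 0.05)
})

test_that("survival simulation approaches the no-censoring limit", {
  oc <- simulate_survival_times(rep(0, 400), 0.1, 1e-6, seed = 2)
  expect_gt(mean(oc$event), 0.99)
  expect_identical(oc, simulate_survival_times(rep(0, 400), 0.1, 1e-6, seed = 2))
})

test_that("exponential race probability matches the closed form", {
  # two patients with linear predictors 0 and +2: the high-risk patient
  # fails first with probability e^2 / (1 + e^2)
  set.seed(9)
  n_rep <- 10000
  t_lo <- rexp(n_rep, 0.1 * exp(0))
  t_hi <- rexp(n_rep, 0.1 * exp(2))
  p_hat <- mean(t_hi < t_lo)
  p_true <- exp(2) / (1 + exp(2))   # 0.8808
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / n_rep) + 0.005)
})

test_that("a large uncensored cohort recovers the generating coefficients", {
  cfg <- simulation_config(n_patients = 2000, n_mutation_genes = 12,
                           n_causal_mutations = 4, mutation_log_hazards = 0.8,
                           image_signal_weight = 0, censoring_rate_target = 0.01,
                           n_tiles_per_patient_range = c(2, 3), tile_dim = 4,
                           seed = 21)
  ch <- generate_cohort(cfg)
  X <- ch$mutation_matrix[, 1:4]
  age_z <- (ch$clinical_table$age - 43) / 13.4
  fit <- survival::coxph(survival::Surv(ch$outcomes$time, ch$outcomes$event) ~
                           X + age_z, ties = "breslow")
  truth <- c(ch$true_coefficients$mutation[1:4],
             ch$true_coefficients$clinical$age$coef * 13.4)
  expect_lt(max(abs(unname(coef(fit)) - unname(truth))), 0.15)
})

test_that("tile embeddings carry the class structure at high separation", {
  set.seed(31)
  classes <- sample(1:3, 120, replace = TRUE)
  tiles <- generate_tile_embeddings(classes, n_tiles = 8, tile_dim = 8,
                                    cluster_separation = 10, seed = 4)
  means <- t(vapply(tiles, colMeans, numeric(8)))
  centroids <- diag(3) * 10 / sqrt(2)
  pred <- apply(means[, 1:3], 1, function(m)
    which.min(colSums((t(centroids) - m)^2)))
  expect_gte(mean(pred == classes), 0.99)
})

test_that("zero separation yields indistinguishable class means", {
  hits <- 0
  for (s in 1:20) {
    classes <- rep(1:2, each = 15)
    tiles <- generate_tile_embeddings(classes, n_tiles = 6, tile_dim = 4,
                                      cluster_separation = 0, seed = s)
    means <- t(vapply(tiles, colMeans, numeric(4)))
    p <- stats::t.test(means[classes == 1, 1], means[classes == 2, 1])$p.value
    hits <- hits + (p > 0.05)
  }
  expect_gte(hits / 20, 0.9)
})

test_that("degenerate tile ranges and invalid dimensions are handled", {
  cfg <- simulation_config(n_patients = 6, n_tiles_per_patient_range = c(5, 5),
                           tile_dim = 4, seed = 2)
  ch <- generate_cohort(cfg)
  expect_true(all(vapply(ch$tile_embeddings, nrow, 1L) == 5L))
  expect_error(generate_tile_embeddings(1:2, 3, tile_dim = 0, seed = 1), "tile_dim")
  expect_error(generate_tile_embeddings(1:2, 0, tile_dim = 4, seed = 1), "n_tiles")
})
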