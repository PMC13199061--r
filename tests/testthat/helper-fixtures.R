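# shared fixtures: all built in code, sized for speed

tiny_outcomes <- function(n, seed = 1, event_p = 0.6) {
  with_seed <- cmsurv:::with_seed
  with_seed(seed, {
    data.frame(time = runif(n, 0.5, 10), event = rbinom(n, 1, event_p))
  })
}

# brute-force Cox negative log partial likelihood (Breslow risk sets)
brute_cox_nll <- function(risks, outcomes) {
  ev <- which(outcomes$event == 1)
  s <- 0
  for (i in ev) {
    R <- which(outcomes$time >= outcomes$time[i])
    s <- s + (risks[i] - log(sum(exp(risks[R]))))
  }
  -s / length(ev)
}

# brute-force Harrell concordance with the package's tie conventions
brute_cindex <- function(risks, outcomes) {
  conc <- tied <- comp <- 0
  n <- length(risks)
  for (i in seq_len(n)) {
    if (outcomes$event[i] != 1) next
    for (j in seq_len(n)) {
      if (i == j || outcomes$time[i] >= outcomes$time[j]) next
      comp <- comp + 1
      if (risks[i] > risks[j]) conc <- conc + 1
      else if (risks[i] == risks[j]) tied <- tied + 0.5
    }
  }
  (conc + tied) / comp
}

small_encoder_config <- function(...) {
  encoder_config(mutation_hidden_sizes = c(8, 6), clinical_hidden_sizes = c(4, 4),
                 shared_hidden_sizes = 6, aggregator_attention_dim = 4,
                 image_embed_dim = 6, nonimage_embed_dim = 6, projection_dim = 4,
                 fusion_hidden_sizes = 5, ...)
}

small_cohort <- function(n = 80, seed = 1, ...) {
  generate_cohort(simulation_config(
    n_patients = n, n_mutation_genes = 30, n_causal_mutations = 6,
    mutation_log_hazards = 1.5, n_tiles_per_patient_range = c(4, 8),
    tile_dim = 8, class_log_hazards = c(-2, 0, 2), cluster_separation = 4,
    censoring_rate_target = 0.6, seed = seed, ...))
}

small_training_data <- function(n = 30, seed = 2, n_mut = 5, n_clin = 3,
                                tile_dim = 6) {
  with_seed <- cmsurv:::with_seed
  with_seed(seed, {
    list(X_mut = matrix(rbinom(n * n_mut, 1, 0.3), n, n_mut),
         X_clin = matrix(rnorm(n * n_clin), n, n_clin),
         tiles = lapply(seq_len(n),
                        function(i) matrix(rnorm(5 * tile_dim), 5, tile_dim)),
         outcomes = data.frame(time = runif(n, 1, 10) + seq_len(n) * 1e-6,
                               event = pmax(rbinom(n, 1, 0.6),
                                            c(1, rep(0, n - 1)))))
  })
}

# flatten a nested parameter tree into named matrices (for gradient checks)
flatten_tree <- function(x, prefix = "") {
  if (is.matrix(x)) return(setNames(list(x), prefix))
  nms <- names(x)
  if (is.null(nms)) nms <- as.character(seq_along(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, flatten_tree(x[[i]], paste(prefix, nms[i])))
  out
}

# rebuild the nested tree from a flat named list
unflatten_tree <- function(template, flat, prefix = "") {
  if (is.matrix(template)) return(flat[[prefix]])
  nms <- names(template)
  if (is.null(nms)) nms <- as.character(seq_along(template))
  for (i in seq_along(template))
    template[[i]] <- unflatten_tree(template[[i]], flat, paste(prefix, nms[i]))
  template
}
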