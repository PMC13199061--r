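#' Architecture configuration for the multimodal model
#'
#' Widths of the mutation and clinical branches, the shared non-image
#' stack, the gated attention tile aggregator, the contrastive projection
#' heads and the fusion head. Defaults are sized for desk-scale cohorts
#' (hundreds of patients); every value can be overridden.
#'
#' @param mutation_hidden_sizes,clinical_hidden_sizes,shared_hidden_sizes
#'   integer vectors of hidden-layer widths for the three non-image stacks.
#' @param aggregator_attention_dim width of the gated attention scoring
#'   branches.
#' @param image_embed_dim,nonimage_embed_dim pre-projection embedding
#'   dimensions of the two modalities.
#' @param projection_dim dimension of the shared contrastive space.
#' @param fusion_hidden_sizes hidden widths of the fused risk head.
#' @param dropout_rate hidden-unit dropout probability, training mode only.
#' @param weight_decay decoupled L2 penalty applied to weight matrices.
#' @return list of class `cms_encoder_config`.
#' @export
encoder_config <- function(mutation_hidden_sizes = c(128, 64),
                           clinical_hidden_sizes = c(32, 32),
                           shared_hidden_sizes = 64,
                           aggregator_attention_dim = 32,
                           image_embed_dim = 64,
                           nonimage_embed_dim = 64,
                           projection_dim = 32,
                           fusion_hidden_sizes = c(64, 32),
                           dropout_rate = 0.25,
                           weight_decay = 0.01) {
  for (s in list(mutation_hidden_sizes, clinical_hidden_sizes,
                 shared_hidden_sizes, fusion_hidden_sizes))
    if (any(s < 1)) stop_cms("all layer sizes must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_cms("dropout_rate must lie in [0, 1)")
  if (weight_decay < 0) stop_cms("weight_decay must be >= 0")
  structure(list(
    mutation_hidden_sizes = as.integer(mutation_hidden_sizes),
    clinical_hidden_sizes = as.integer(clinical_hidden_sizes),
    shared_hidden_sizes = as.integer(shared_hidden_sizes),
    aggregator_attention_dim = check_count(aggregator_attention_dim,
                                           "aggregator_attention_dim"),
    image_embed_dim = check_count(image_embed_dim, "image_embed_dim"),
    nonimage_embed_dim = check_count(nonimage_embed_dim, "nonimage_embed_dim"),
    projection_dim = check_count(projection_dim, "projection_dim"),
    fusion_hidden_sizes = as.integer(fusion_hidden_sizes),
    dropout_rate = dropout_rate,
    weight_decay = weight_decay), class = "cms_encoder_config")
}

#' Initialise an untrained multimodal model
#'
#' Builds all sub-networks with seeded uniform fan-in initialisation:
#' mutation and clinical branch MLPs feeding a shared non-image stack, the
#' gated attention tile aggregator, per-modality contrastive projection
#' heads, linear Cox risk readouts used in stages 1 and 2, and the fused
#' risk head trained in stage 3.
#'
#' @param n_mutation_features,n_clinical_features input widths of the two
#'   non-image branches.
#' @param tile_dim dimension of the tile embeddings fed to the aggregator.
#' @param config an [encoder_config()].
#' @param seed integer seed controlling initialisation.
#' @return object of class `cms_model` with `stage_provenance = "init"`.
#' @export
init_model <- function(n_mutation_features, n_clinical_features, tile_dim,
                       config = encoder_config(), seed = 1L) {
  n_mutation_features <- check_count(n_mutation_features, "n_mutation_features")
  n_clinical_features <- check_count(n_clinical_features, "n_clinical_features")
  tile_dim <- check_count(tile_dim, "tile_dim")
  with_seed(derive_seed(seed, "init"), {
    mut <- mlp_new(n_mutation_features, config$mutation_hidden_sizes,
                   tail(config$mutation_hidden_sizes, 1))
    # branches end at their last hidden width; the shared stack maps the
    # concatenation to the non-image embedding
    clin <- mlp_new(n_clinical_features, config$clinical_hidden_sizes,
                    tail(config$clinical_hidden_sizes, 1))
    concat_dim <- tail(config$mutation_hidden_sizes, 1) +
      tail(config$clinical_hidden_sizes, 1)
    shared <- mlp_new(concat_dim, config$shared_hidden_sizes,
                      config$nonimage_embed_dim)
    a <- config$aggregator_attention_dim
    image <- list(V = init_mat(tile_dim, a), U = init_mat(tile_dim, a),
                  w = init_mat(a, 1),
                  W_out = init_mat(tile_dim, config$image_embed_dim),
                  b_out = matrix(0, 1, config$image_embed_dim))
    proj_image <- mlp_new(config$image_embed_dim, config$projection_dim,
                          config$projection_dim)
    proj_nonimage <- mlp_new(config$nonimage_embed_dim, config$projection_dim,
                             config$projection_dim)
    fused_dim <- config$image_embed_dim + config$nonimage_embed_dim
    fusion <- mlp_new(fused_dim, config$fusion_hidden_sizes, 1)
    readout <- list(
      image = list(W = init_mat(config$image_embed_dim, 1), b = matrix(0, 1, 1)),
      nonimage = list(W = init_mat(config$nonimage_embed_dim, 1), b = matrix(0, 1, 1)),
      stage2 = list(W = init_mat(fused_dim, 1), b = matrix(0, 1, 1)))
    structure(list(
      nonimage = list(mut = mut, clin = clin, shared = shared),
      image = image,
      proj = list(image = proj_image, nonimage = proj_nonimage),
      fusion = fusion,
      readout = readout,
      dims = list(mutation = n_mutation_features,
                  clinical = n_clinical_features, tile = tile_dim),
      config = config,
      seed = as.integer(seed),
      stage_provenance = "init"), class = "cms_model")
  })
}

#' @export
print.cms_model <- function(x, ...) {
  cat("<cms_model> stage:", x$stage_provenance,
      "| inputs: mut", x$dims$mutation, "clin", x$dims$clinical,
      "tile", x$dims$tile,
      "| embed:", x$config$image_embed_dim, "+", x$config$nonimage_embed_dim,
      "-> proj", x$config$projection_dim, "\n")
  invisible(x)
}

# forward through the non-image hierarchy with optional caches
nonimage_forward <- function(model, X_mut, X_clin, training = FALSE,
                             cache = FALSE) {
  X_mut <- as.matrix(X_mut); X_clin <- as.matrix(X_clin)
  if (ncol(X_mut) != model$dims$mutation)
    stop_cms("mutation branch expects ", model$dims$mutation,
             " features, got ", ncol(X_mut))
  if (ncol(X_clin) != model$dims$clinical)
    stop_cms("clinical branch expects ", model$dims$clinical,
             " features, got ", ncol(X_clin))
  dr <- if (training) model$config$dropout_rate else 0
  fm <- mlp_forward(model$nonimage$mut, X_mut, training, dr, cache = cache)
  fc <- mlp_forward(model$nonimage$clin, X_clin, training, dr, cache = cache)
  Am <- if (cache) fm$out else fm
  Ac <- if (cache) fc$out else fc
  H <- cbind(Am, Ac)
  fs <- mlp_forward(model$nonimage$shared, H, training, dr, cache = cache)
  if (!cache) return(fs)
  list(out = fs$out, mut = fm, clin = fc, shared = fs, split = ncol(Am))
}

nonimage_backward <- function(model, fw, dE) {
  bs <- mlp_backward(model$nonimage$shared, fw$shared, dE)
  dH <- bs$dX
  k <- fw$split
  bm <- mlp_backward(model$nonimage$mut, fw$mut, dH[, seq_len(k), drop = FALSE])
  bc <- mlp_backward(model$nonimage$clin, fw$clin,
                     dH[, -seq_len(k), drop = FALSE])
  list(mut = bm$layers, clin = bc$layers, shared = bs$layers)
}

#' Encode non-image features into patient embeddings
#'
#' The mutation and clinical branches run independently; their outputs are
#' concatenated and passed through the shared stack. Inference mode is
#' deterministic (no dropout).
#'
#' @param model a `cms_model`.
#' @param mutation_features,clinical_features numeric matrices, patients in
#'   rows, aligned.
#' @return patients x `nonimage_embed_dim` embedding matrix.
#' @export
encode_nonimage <- function(model, mutation_features, clinical_features) {
  nonimage_forward(model, mutation_features, clinical_features)
}

# gated attention forward over stacked tiles.
# H: total_tiles x tile_dim, idx: patient index (1..n) per tile row.
attention_forward <- function(p, H, idx, n, cache = FALSE) {
  A <- tanh(H %*% p$V)
  B <- 1 / (1 + exp(-(H %*% p$U)))
  G <- A * B
  s <- as.vector(G %*% p$w)
  # softmax within each patient's tile group
  mx <- ave(s, idx, FUN = max)
  e <- exp(s - mx)
  denom <- ave(e, idx, FUN = sum)
  a <- e / denom
  Tt <- H %*% p$W_out + matrix(p$b_out, nrow(H), ncol(p$b_out), byrow = TRUE)
  Z <- rowsum(a * Tt, idx, reorder = TRUE)
  if (nrow(Z) != n) stop_cms("every patient needs at least one tile")
  if (!cache) return(Z)
  list(Z = Z, A = A, B = B, G = G, a = a, Tt = Tt, H = H, idx = idx)
}

attention_backward <- function(p, fw, dZ) {
  idx <- fw$idx
  dZt <- dZ[idx, , drop = FALSE]
  dT <- fw$a * dZt
  dW_out <- crossprod(fw$H, dT)
  db_out <- matrix(colSums(dT), 1)
  da <- rowSums(fw$Tt * dZt)
  # softmax backward within groups
  ada <- fw$a * da
  ds <- ada - fw$a * ave(ada, idx, FUN = sum)
  dG <- ds %*% t(p$w)          # outer product: tiles x attn_dim
  dw <- matrix(crossprod(fw$G, ds), ncol = 1)
  dA <- dG * fw$B
  dB <- dG * fw$A
  dZa <- dA * (1 - fw$A^2)
  dZb <- dB * fw$B * (1 - fw$B)
  list(V = crossprod(fw$H, dZa), U = crossprod(fw$H, dZb),
       w = dw, W_out = dW_out, b_out = db_out)
}

#' Aggregate tile embeddings into a slide-level embedding
#'
#' Two-branch gated attention pooling: each tile is scored by
#' `w' (tanh(V'h) * sigmoid(U'h))`, scores are softmax-normalised across
#' the patient's tiles (weights sum to one), and the slide embedding is the
#' weighted sum of linearly transformed tile embeddings. Permutation
#' invariant in tile order.
#'
#' @param model a `cms_model`.
#' @param tiles a single tiles x dim matrix, or a list of such matrices
#'   (one per patient).
#' @return a 1 x `image_embed_dim` matrix for a single tile set, or a
#'   patients x dim matrix for a list.
#' @export
aggregate_tiles <- function(model, tiles) {
  if (is.matrix(tiles)) tiles <- list(tiles)
  if (!length(tiles)) stop_cms("empty tile set")
  for (m in tiles) {
    if (!is.matrix(m) || nrow(m) < 1L)
      stop_cms("each patient needs a non-empty tile matrix")
    if (ncol(m) != model$dims$tile)
      stop_cms("tile embeddings have dim ", ncol(m), ", model expects ",
               model$dims$tile)
  }
  H <- do.call(rbind, tiles)
  idx <- rep(seq_along(tiles), vapply(tiles, nrow, 1L))
  attention_forward(model$image, H, idx, length(tiles))
}

# row-wise unit normalisation with deterministic fallback for zero rows
unit_rows <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  zero <- nrm < 1e-12
  if (any(zero)) {
    warning(sum(zero), " zero-norm projection row(s) replaced by e1",
            call. = FALSE)
    M[zero, 1] <- 1
    nrm[zero] <- 1
  }
  M / nrm
}

#' Project embeddings into the shared contrastive space
#'
#' Applies the named modality's projection head and scales each row to unit
#' Euclidean norm. Rows that are exactly zero before normalisation are
#' replaced by the first unit basis vector (with a warning).
#'
#' @param model a `cms_model`.
#' @param embedding patients x dim pre-projection embedding matrix.
#' @param which `"image"` or `"nonimage"`.
#' @return patients x `projection_dim` matrix with unit rows.
#' @export
project_contrastive <- function(model, embedding, which = c("image", "nonimage")) {
  which <- match.arg(which)
  unit_rows(mlp_forward(model$proj[[which]], embedding))
}

#' Fused scalar risk prediction
#'
#' Concatenates the PRE-projection embeddings of the two modalities and
#' applies the fused feed-forward risk head. Scores are relative (Cox):
#' only differences between patients matter.
#'
#' @param model a `cms_model`.
#' @param image_embeddings,nonimage_embeddings aligned patients x dim
#'   matrices.
#' @return numeric risk score per patient, higher = worse prognosis.
#' @export
predict_risk_fused <- function(model, image_embeddings, nonimage_embeddings) {
  image_embeddings <- as.matrix(image_embeddings)
  nonimage_embeddings <- as.matrix(nonimage_embeddings)
  if (nrow(image_embeddings) != nrow(nonimage_embeddings))
    stop_cms("image and non-image embeddings are misaligned")
  as.vector(mlp_forward(model$fusion, cbind(image_embeddings,
                                            nonimage_embeddings)))
}

linear_readout <- function(ro, E) as.vector(E %*% ro$W + ro$b[1, 1])
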