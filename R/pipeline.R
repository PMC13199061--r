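#' Training hyperparameters for the three-stage pipeline
#'
#' @param epochs named integer vector with entries `stage1`, `stage2`,
#'   `stage3` (epoch counts per stage).
#' @param batch_size mini-batch size; batches are event-stratified so each
#'   carries at least one event wherever arithmetically possible.
#' @param learning_rate Adam step size.
#' @param contrastive a [contrastive_config()].
#' @param encoder an [encoder_config()].
#' @param seed integer root seed for initialisation, batching and dropout.
#' @param early_stopping_patience epochs without improvement of the stage
#'   loss on an inner 15% holdout of the training fold before stopping;
#'   `NULL` disables early stopping (all data used for training).
#' @return list of class `cms_training_config`.
#' @export
training_config <- function(epochs = c(stage1 = 30, stage2 = 30, stage3 = 30),
                            batch_size = 64,
                            learning_rate = 1e-3,
                            contrastive = contrastive_config(),
                            encoder = encoder_config(),
                            seed = 1L,
                            early_stopping_patience = NULL) {
  if (!all(c("stage1", "stage2", "stage3") %in% names(epochs)))
    stop_cms("epochs must name stage1, stage2 and stage3")
  if (any(epochs < 0)) stop_cms("epoch counts must be >= 0")
  structure(list(epochs = epochs,
                 batch_size = check_count(batch_size, "batch_size"),
                 learning_rate = learning_rate,
                 contrastive = contrastive, encoder = encoder,
                 seed = as.integer(seed),
                 early_stopping_patience = early_stopping_patience),
            class = "cms_training_config")
}

#' Event-stratified k-fold assignment
#'
#' Patients are shuffled within event strata (deaths, censored) and dealt
#' round-robin across folds so fold sizes differ by at most one and
#' per-fold event counts differ by at most one.
#'
#' @param outcomes data frame with `time`, `event`.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return list of class `cms_folds`: `assignments` (fold index per
#'   patient), `k`, `seed`.
#' @export
make_folds <- function(outcomes, k = 5, seed = 1L) {
  outcomes <- check_outcomes(outcomes)
  k <- check_count(k, "k", min = 2L)
  n <- nrow(outcomes)
  if (k > n) stop_cms("k exceeds the number of patients")
  assignments <- integer(n)
  with_seed(derive_seed(seed, "folds"), {
    ev <- sample(which(outcomes$event == 1))
    ce <- sample(which(outcomes$event == 0))
    dealt <- c(ev, ce)
    assignments[dealt] <- rep_len(seq_len(k), n)
  })
  structure(list(assignments = assignments, k = k, seed = as.integer(seed)),
            class = "cms_folds")
}

# event-stratified mini-batches: events dealt round-robin first so every
# batch gets one wherever possible
make_batches <- function(event, batch_size) {
  n <- length(event)
  n_batches <- max(1L, ceiling(n / batch_size))
  slot <- integer(n)
  dealt <- c(sample(which(event == 1)), sample(which(event == 0)))
  slot[dealt] <- rep_len(seq_len(n_batches), n)
  unname(split(seq_len(n), slot))
}

# ---- stage parameter plumbing ----------------------------------------------

get_stage_params <- function(model, stage) {
  switch(stage,
    stage1_nonimage = list(mut = model$nonimage$mut$layers,
                           clin = model$nonimage$clin$layers,
                           shared = model$nonimage$shared$layers,
                           ro = model$readout$nonimage),
    stage1_image = list(att = model$image, ro = model$readout$image),
    stage2_contrastive = list(mut = model$nonimage$mut$layers,
                              clin = model$nonimage$clin$layers,
                              shared = model$nonimage$shared$layers,
                              att = model$image,
                              pi = model$proj$image$layers,
                              pn = model$proj$nonimage$layers,
                              ro = model$readout$stage2),
    stage3_fused = list(fusion = model$fusion$layers),
    adapt_fused = list(mut = model$nonimage$mut$layers,
                       clin = model$nonimage$clin$layers,
                       shared = model$nonimage$shared$layers,
                       att = model$image,
                       fusion = model$fusion$layers),
    stop_cms("unknown stage: ", stage))
}

set_stage_params <- function(model, stage, params) {
  if (!is.null(params$mut)) model$nonimage$mut$layers <- params$mut
  if (!is.null(params$clin)) model$nonimage$clin$layers <- params$clin
  if (!is.null(params$shared)) model$nonimage$shared$layers <- params$shared
  if (!is.null(params$att)) model$image <- params$att
  if (!is.null(params$pi)) model$proj$image$layers <- params$pi
  if (!is.null(params$pn)) model$proj$nonimage$layers <- params$pn
  if (!is.null(params$fusion)) model$fusion$layers <- params$fusion
  if (!is.null(params$ro)) {
    slot <- switch(stage, stage1_nonimage = "nonimage",
                   stage1_image = "image", stage2_contrastive = "stage2")
    model$readout[[slot]] <- params$ro
  }
  model
}

# stack a list of tile matrices for a patient subset
stack_tiles <- function(tiles, idx) {
  sel <- tiles[idx]
  list(H = do.call(rbind, sel),
       map = rep(seq_along(sel), vapply(sel, nrow, 1L)),
       n = length(sel))
}

# normalisation backward: y = x / ||x||
norm_backward <- function(P, nrm, dP) {
  (dP - P * rowSums(dP * P)) / nrm
}

project_cached <- function(model, net_name, E, training, dr) {
  fw <- mlp_forward(model$proj[[net_name]], E, training, dr, cache = TRUE)
  raw <- fw$out
  nrm <- pmax(sqrt(rowSums(raw^2)), 1e-12)
  list(fw = fw, P = raw / nrm, nrm = nrm)
}

# ---- per-stage loss/gradient on one batch -----------------------------------

stage_grad <- function(model, stage, data, bidx, config, training = TRUE) {
  dr <- if (training) model$config$dropout_rate else 0
  out <- outcomes_subset(data$outcomes, bidx)
  if (stage == "stage1_nonimage") {
    fw <- nonimage_forward(model, data$X_mut[bidx, , drop = FALSE],
                           data$X_clin[bidx, , drop = FALSE],
                           training = training, cache = TRUE)
    ro <- model$readout$nonimage
    risk <- as.vector(fw$out %*% ro$W + ro$b[1, 1])
    cg <- cox_partial_nll_grad(risk, out)
    drisk <- matrix(cg$grad, ncol = 1)
    dE <- drisk %*% t(ro$W)
    genc <- nonimage_backward(model, fw, dE)
    return(list(loss = cg$loss,
                grads = c(genc, list(ro = list(W = crossprod(fw$out, drisk),
                                               b = matrix(sum(drisk), 1, 1))))))
  }
  if (stage == "stage1_image") {
    st <- stack_tiles(data$tiles, bidx)
    fw <- attention_forward(model$image, st$H, st$map, st$n, cache = TRUE)
    ro <- model$readout$image
    risk <- as.vector(fw$Z %*% ro$W + ro$b[1, 1])
    cg <- cox_partial_nll_grad(risk, out)
    drisk <- matrix(cg$grad, ncol = 1)
    gatt <- attention_backward(model$image, fw, drisk %*% t(ro$W))
    return(list(loss = cg$loss,
                grads = list(att = gatt,
                             ro = list(W = crossprod(fw$Z, drisk),
                                       b = matrix(sum(drisk), 1, 1)))))
  }
  if (stage == "stage2_contrastive") {
    cc <- config$contrastive
    fwn <- nonimage_forward(model, data$X_mut[bidx, , drop = FALSE],
                            data$X_clin[bidx, , drop = FALSE],
                            training = training, cache = TRUE)
    st <- stack_tiles(data$tiles, bidx)
    fwa <- attention_forward(model$image, st$H, st$map, st$n, cache = TRUE)
    E_n <- fwn$out; E_i <- fwa$Z
    pj_i <- project_cached(model, "image", E_i, training, dr)
    pj_n <- project_cached(model, "nonimage", E_n, training, dr)
    # zero-norm rows (dead ReLU at init) stay zero vectors here; their
    # gradient is Adam-bounded, so the renormalization warning is noise
    nce <- suppressWarnings(info_nce_internal(pj_i$P, pj_n$P, cc, grad = TRUE))
    dRaw_i <- norm_backward(pj_i$P, pj_i$nrm, nce$grad_image)
    dRaw_n <- norm_backward(pj_n$P, pj_n$nrm, nce$grad_nonimage)
    bpi <- mlp_backward(model$proj$image, pj_i$fw, dRaw_i)
    bpn <- mlp_backward(model$proj$nonimage, pj_n$fw, dRaw_n)
    dE_i <- bpi$dX; dE_n <- bpn$dX
    loss <- nce$loss
    ro <- model$readout$stage2
    gro <- list(W = ro$W * 0, b = ro$b * 0)
    if (cc$lambda_weight > 0) {
      Ecat <- cbind(E_i, E_n)
      risk <- as.vector(Ecat %*% ro$W + ro$b[1, 1])
      cg <- cox_partial_nll_grad(risk, out)
      loss <- loss + cc$lambda_weight * cg$loss
      drisk <- matrix(cc$lambda_weight * cg$grad, ncol = 1)
      dEcat <- drisk %*% t(ro$W)
      di <- ncol(E_i)
      dE_i <- dE_i + dEcat[, seq_len(di), drop = FALSE]
      dE_n <- dE_n + dEcat[, -seq_len(di), drop = FALSE]
      gro <- list(W = crossprod(Ecat, drisk), b = matrix(sum(drisk), 1, 1))
    }
    gatt <- attention_backward(model$image, fwa, dE_i)
    gnm <- nonimage_backward(model, fwn, dE_n)
    return(list(loss = loss,
                grads = list(mut = gnm$mut, clin = gnm$clin,
                             shared = gnm$shared, att = gatt,
                             pi = bpi$layers, pn = bpn$layers, ro = gro)))
  }
  if (stage %in% c("stage3_fused", "adapt_fused")) {
    frozen <- stage == "stage3_fused"
    if (frozen && !is.null(data$E_i)) {
      E_i <- data$E_i[bidx, , drop = FALSE]
      E_n <- data$E_n[bidx, , drop = FALSE]
    } else {
      fwn <- nonimage_forward(model, data$X_mut[bidx, , drop = FALSE],
                              data$X_clin[bidx, , drop = FALSE],
                              training = !frozen && training, cache = !frozen)
      st <- stack_tiles(data$tiles, bidx)
      fwa <- attention_forward(model$image, st$H, st$map, st$n, cache = !frozen)
      E_n <- if (!frozen) fwn$out else fwn
      E_i <- if (!frozen) fwa$Z else fwa
    }
    Ecat <- cbind(E_i, E_n)
    ff <- mlp_forward(model$fusion, Ecat, training, dr, cache = TRUE)
    risk <- as.vector(ff$out)
    cg <- cox_partial_nll_grad(risk, out)
    bf <- mlp_backward(model$fusion, ff, matrix(cg$grad, ncol = 1))
    grads <- list(fusion = bf$layers)
    if (!frozen) {
      di <- ncol(E_i)
      dE_i <- bf$dX[, seq_len(di), drop = FALSE]
      dE_n <- bf$dX[, -seq_len(di), drop = FALSE]
      gatt <- attention_backward(model$image, fwa, dE_i)
      gnm <- nonimage_backward(model, fwn, dE_n)
      grads <- c(list(mut = gnm$mut, clin = gnm$clin, shared = gnm$shared,
                      att = gatt), grads)
    }
    return(list(loss = cg$loss, grads = grads))
  }
  stop_cms("unknown stage: ", stage)
}

outcomes_subset <- function(outcomes, idx) {
  data.frame(time = outcomes$time[idx], event = outcomes$event[idx])
}

stage_epochs <- function(config, stage) {
  key <- switch(stage, stage1_nonimage = "stage1", stage1_image = "stage1",
                stage2_contrastive = "stage2", stage3_fused = "stage3",
                adapt_fused = "stage3")
  as.integer(config$epochs[[key]])
}

#' Train one stage of the pipeline
#'
#' Mini-batch Adam on the stage's objective: stage 1 fits each modality's
#' encoder with a linear Cox risk readout; stage 2 optimises
#' `InfoNCE + lambda * Cox` through both encoders and the projection heads
#' (the Cox term reads a throwaway linear head on the concatenated
#' pre-projection embeddings); stage 3 trains the fused risk head on
#' frozen encoder outputs. With `epochs = 0` the model is returned
#' unchanged. When `early_stopping_patience` is set, an inner
#' event-stratified 15% holdout of the training data monitors the stage
#' loss and the best parameters are restored.
#'
#' @param model a `cms_model`.
#' @param stage one of `"stage1_nonimage"`, `"stage1_image"`,
#'   `"stage2_contrastive"`, `"stage3_fused"`, `"adapt_fused"`.
#' @param data list with `X_mut`, `X_clin` (numeric feature matrices),
#'   `tiles` (list of tile-embedding matrices) and `outcomes`.
#' @param config a [training_config()].
#' @param epochs optional override of the stage's epoch count.
#' @param check_prior enforce the pipeline order (stage 2 requires both
#'   stage-1 passes; stage 3 requires stage 2)?
#' @param anchor_decay optional L2-SP penalty pulling parameters toward
#'   their values at entry (used for small-sample fine-tuning).
#' @return the trained model with updated `stage_provenance` and a
#'   `loss_history` attribute for the stage.
#' @export
train_stage <- function(model, stage, data, config, epochs = NULL,
                        check_prior = TRUE, anchor_decay = 0) {
  if (!inherits(model, "cms_model")) stop_cms("model must be a cms_model")
  done <- model$trained_stages %||% character()
  if (check_prior) {
    need <- switch(stage,
                   stage2_contrastive = c("stage1_image", "stage1_nonimage"),
                   stage3_fused = "stage2_contrastive",
                   character())
    if (!all(need %in% done))
      stop_cms("stage '", stage, "' requires prior stage(s): ",
               paste(setdiff(need, done), collapse = ", "))
  }
  epochs <- epochs %||% stage_epochs(config, stage)
  n <- nrow(data$outcomes)
  if (epochs == 0L) {
    model$trained_stages <- union(done, stage)
    model$stage_provenance <- stage
    return(model)
  }
  if (sum(data$outcomes$event) == 0)
    stop_cms("cannot train a Cox objective with zero events")

  patience <- config$early_stopping_patience
  hold_idx <- integer()
  if (!is.null(patience)) {
    with_seed(derive_seed(config$seed, paste0(stage, "_holdout")), {
      ev <- which(data$outcomes$event == 1)
      ce <- which(data$outcomes$event == 0)
      hold_idx <- c(sample(ev, max(1L, round(0.15 * length(ev)))),
                    sample(ce, round(0.15 * length(ce))))
    })
  }
  fit_idx <- setdiff(seq_len(n), hold_idx)

  st <- adam_init(get_stage_params(model, stage))
  anchor <- if (anchor_decay > 0) get_stage_params(model, stage)
  history <- numeric()
  best <- list(loss = Inf, params = NULL, since = 0L)
  with_seed(derive_seed(config$seed, paste0(stage, "_train")), {
    for (ep in seq_len(epochs)) {
      batches <- make_batches(data$outcomes$event[fit_idx], config$batch_size)
      ep_loss <- 0; ep_n <- 0L
      for (b in batches) {
        bidx <- fit_idx[b]
        if (sum(data$outcomes$event[bidx]) == 0) {
          warning("skipping batch with zero events", call. = FALSE)
          next
        }
        g <- stage_grad(model, stage, data, bidx, config, training = TRUE)
        params <- get_stage_params(model, stage)
        if (anchor_decay > 0)
          g$grads <- tree_grad_anchor(g$grads, params, anchor, anchor_decay)
        r <- adam_step(params, g$grads, st, lr = config$learning_rate,
                       weight_decay = config$encoder$weight_decay)
        st <- r$state
        model <- set_stage_params(model, stage, r$params)
        ep_loss <- ep_loss + g$loss * length(bidx); ep_n <- ep_n + length(bidx)
      }
      history <- c(history, ep_loss / max(ep_n, 1L))
      if (length(hold_idx)) {
        hl <- stage_grad(model, stage, data, hold_idx, config,
                         training = FALSE)$loss
        if (hl < best$loss - 1e-8) {
          best <- list(loss = hl, params = get_stage_params(model, stage),
                       since = 0L)
        } else {
          best$since <- best$since + 1L
          if (best$since >= patience) break
        }
      }
    }
  })
  if (length(hold_idx) && !is.null(best$params))
    model <- set_stage_params(model, stage, best$params)
  model$trained_stages <- union(done, stage)
  model$stage_provenance <- stage
  attr(model, "loss_history") <- history
  model
}

# inference-mode embeddings for a data list
model_embeddings <- function(model, data, idx = NULL) {
  idx <- idx %||% seq_len(nrow(data$outcomes))
  E_n <- nonimage_forward(model, data$X_mut[idx, , drop = FALSE],
                          data$X_clin[idx, , drop = FALSE])
  st <- stack_tiles(data$tiles, idx)
  E_i <- attention_forward(model$image, st$H, st$map, st$n)
  list(E_i = E_i, E_n = E_n)
}

unimodal_risks <- function(model, data, idx = NULL) {
  em <- model_embeddings(model, data, idx)
  list(image = linear_readout(model$readout$image, em$E_i),
       nonimage = linear_readout(model$readout$nonimage, em$E_n))
}

# fold-local preprocessing: screening + clinical encoding fitted on train
fit_fold_features <- function(cohort, train_idx, alpha = 0.05) {
  scr <- screen_mutations(cohort$mutation_matrix[train_idx, , drop = FALSE],
                          outcomes_subset(cohort$outcomes, train_idx),
                          alpha = alpha)
  selected <- scr$selected
  if (!length(selected)) selected <- colnames(cohort$mutation_matrix)[1]
  bf <- build_feature_matrix(cohort$clinical_table[train_idx, , drop = FALSE])
  list(selected = selected, clin_state = bf$state, screening = scr)
}

apply_fold_features <- function(cohort, prep, idx = NULL) {
  idx <- idx %||% seq_along(cohort$patient_ids)
  X_mut <- align_mutation_features(
    cohort$mutation_matrix[idx, , drop = FALSE], prep$selected)
  X_clin <- build_feature_matrix(cohort$clinical_table[idx, , drop = FALSE],
                                 state = prep$clin_state)$features
  list(X_mut = X_mut, X_clin = X_clin,
       tiles = cohort$tile_embeddings[idx],
       outcomes = outcomes_subset(cohort$outcomes, idx),
       ids = cohort$patient_ids[idx])
}

#' Cross-validated three-stage training
#'
#' For every fold: mutation screening and clinical preprocessing are
#' fitted on the training patients only, stages 1 (both modalities), 2 and
#' 3 are trained on the training patients, and the validation patients —
#' never seen by any stage — are scored with the stage-3 fused head.
#' Unimodal stage-1 validation risks, matched-pair cross-modal cosine
#' similarities before and after contrastive alignment, and silhouette
#' scores of the fused pre-projection embeddings before/after stage 2 are
#' recorded per fold.
#'
#' @param cohort a `cms_cohort` (or compatible list).
#' @param config a [training_config()].
#' @param folds a [make_folds()] split; the same split is reused across
#'   all stages.
#' @param use_stage2 run the contrastive stage? `FALSE` gives the
#'   non-contrastive multimodal baseline (stage 3 directly on stage-1
#'   encoders).
#' @param alpha screening level for the univariate Cox gene filter.
#' @param silhouette_horizon horizon for the survival-status silhouette.
#' @return list of class `cms_cv_result`.
#' @export
cross_validate <- function(cohort, config, folds = NULL, use_stage2 = TRUE,
                           alpha = 0.05, silhouette_horizon = 5) {
  folds <- folds %||% make_folds(cohort$outcomes, 5, seed = config$seed)
  n <- length(cohort$patient_ids)
  if (length(folds$assignments) != n)
    stop_cms("fold assignment does not cover the cohort")
  fused_risk <- setNames(rep(NA_real_, n), cohort$patient_ids)
  fold_results <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    val_idx <- which(folds$assignments == f)
    train_idx <- which(folds$assignments != f)
    res <- tryCatch({
      prep <- fit_fold_features(cohort, train_idx, alpha)
      dtr <- apply_fold_features(cohort, prep, train_idx)
      dva <- apply_fold_features(cohort, prep, val_idx)
      fcfg <- config
      fcfg$seed <- derive_seed(config$seed, paste0("fold", f))
      model <- init_model(ncol(dtr$X_mut), ncol(dtr$X_clin),
                          ncol(dtr$tiles[[1]]), config$encoder,
                          seed = fcfg$seed)
      model <- train_stage(model, "stage1_nonimage", dtr, fcfg)
      model <- train_stage(model, "stage1_image", dtr, fcfg)
      em_pre <- model_embeddings(model, dva)
      cos_pre <- suppressWarnings(mean(rowSums(
        project_contrastive(model, em_pre$E_i, "image") *
          project_contrastive(model, em_pre$E_n, "nonimage"))))
      sil_pre <- tryCatch(
        silhouette_by_survival(cbind(em_pre$E_i, em_pre$E_n), dva$outcomes,
                               silhouette_horizon)$score,
        error = function(e) NA_real_)
      if (use_stage2)
        model <- train_stage(model, "stage2_contrastive", dtr, fcfg)
      # stage 3 on frozen encoders: precompute training embeddings once
      em_tr <- model_embeddings(model, dtr)
      dtr3 <- c(dtr, list(E_i = em_tr$E_i, E_n = em_tr$E_n))
      model <- train_stage(model, "stage3_fused", dtr3, fcfg,
                           check_prior = use_stage2)
      em_post <- model_embeddings(model, dva)
      cos_post <- suppressWarnings(mean(rowSums(
        project_contrastive(model, em_post$E_i, "image") *
          project_contrastive(model, em_post$E_n, "nonimage"))))
      sil_post <- tryCatch(
        silhouette_by_survival(cbind(em_post$E_i, em_post$E_n), dva$outcomes,
                               silhouette_horizon)$score,
        error = function(e) NA_real_)
      vr <- predict_risk_fused(model, em_post$E_i, em_post$E_n)
      ur <- unimodal_risks(model, dva)
      ci <- function(r) tryCatch(concordance_index(r, dva$outcomes),
                                 error = function(e) NA_real_)
      list(model = model, prep = prep, val_ids = dva$ids, val_risk = vr,
           c_fused = ci(vr), c_image = ci(ur$image),
           c_nonimage = ci(ur$nonimage),
           cosine_pre = cos_pre, cosine_post = cos_post,
           silhouette_pre = sil_pre, silhouette_post = sil_post)
    }, error = function(e) {
      warning("fold ", f, " failed: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(res)) fused_risk[res$val_ids] <- res$val_risk
    fold_results[[f]] <- res
  }
  ok <- !vapply(fold_results, is.null, logical(1))
  if (!any(ok)) stop_cms("every fold failed")
  pull <- function(field) vapply(fold_results[ok], `[[`, numeric(1), field)
  structure(list(
    folds = folds, fold_results = fold_results,
    val_risk = fused_risk,
    c_index = data.frame(fold = which(ok), fused = pull("c_fused"),
                         image = pull("c_image"),
                         nonimage = pull("c_nonimage")),
    cosine = data.frame(fold = which(ok), pre = pull("cosine_pre"),
                        post = pull("cosine_post")),
    silhouette = data.frame(fold = which(ok), pre = pull("silhouette_pre"),
                            post = pull("silhouette_post")),
    use_stage2 = use_stage2), class = "cms_cv_result")
}

#' @export
print.cms_cv_result <- function(x, ...) {
  cat("<cms_cv_result>", x$folds$k, "folds",
      if (x$use_stage2) "(contrastive)" else "(no stage 2)", "\n")
  cat("  mean val c-index: fused", round(mean(x$c_index$fused, na.rm = TRUE), 3),
      "| image", round(mean(x$c_index$image, na.rm = TRUE), 3),
      "| non-image", round(mean(x$c_index$nonimage, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Ensemble risk over cross-validation fold models
#'
#' Each fold's trained model (with its own fold-fitted preprocessing)
#' scores all requested patients; Cox risks are shift/scale-free, so
#' per-model scores are rank-standardised to (0, 1) before averaging.
#'
#' @param cv a [cross_validate()] result.
#' @param cohort the cohort to score (defaults patients in cohort order).
#' @return named numeric risk per patient.
#' @export
ensemble_risk <- function(cv, cohort) {
  models <- Filter(Negate(is.null), cv$fold_results)
  if (!length(models)) stop_cms("empty CV result")
  scores <- vapply(models, function(fr) {
    d <- apply_fold_features(cohort, fr$prep)
    em <- model_embeddings(fr$model, d)
    r <- predict_risk_fused(fr$model, em$E_i, em$E_n)
    (rank(r) - 0.5) / length(r)
  }, numeric(length(cohort$patient_ids)))
  setNames(rowMeans(scores), cohort$patient_ids)
}

#' Zero-shot and domain-adapted evaluation on an external cohort
#'
#' The external cohort is preprocessed with the TRAINING cohort's fitted
#' state (selected genes absent from the external panel are zero-filled).
#' The zero-shot report evaluates the frozen model on the full external
#' cohort. For adaptation, an event-stratified fraction (default 20%) is
#' used to fine-tune all prediction-path parameters (encoders, aggregator
#' and fused head — tile embeddings are fixed inputs) for `epochs` epochs,
#' and the complement (80%) is evaluated. With `epochs = 0` the adapted
#' report coincides with zero-shot scoring of the evaluation subset.
#'
#' @param model a stage-3 `cms_model`.
#' @param external a `cms_cohort`-compatible external cohort.
#' @param prep the training cohort's preprocessing (element `prep` of a CV
#'   fold result, or from [fit_fold_features()]).
#' @param config a [training_config()] (learning rate/batch size reused).
#' @param fraction adaptation fraction of the external cohort.
#' @param epochs fine-tuning epochs (default 10).
#' @param seed integer seed for the split and fine-tuning.
#' @param n_boot bootstrap replicates for the confidence intervals.
#' @param anchor_decay L2-SP anchoring strength: during fine-tuning the
#'   parameters are penalised toward their source values, keeping the
#'   small-sample update conservative; 0 disables.
#' @return list with `zero_shot` and `adapted` reports (`c_index`, `ci`,
#'   patient ids used).
#' @export
domain_adapt_evaluate <- function(model, external, prep, config,
                                  fraction = 0.2, epochs = 10, seed = 1L,
                                  n_boot = 1000, anchor_decay = 0.1) {
  check_prob(fraction, "fraction")
  d_all <- apply_fold_features(external, prep)
  em <- model_embeddings(model, d_all)
  risk_all <- predict_risk_fused(model, em$E_i, em$E_n)
  zs_ci <- bootstrap_ci(risk_all, d_all$outcomes, n_boot = n_boot, seed = seed)
  n <- length(external$patient_ids)
  n_adapt <- round(fraction * n)
  with_seed(derive_seed(seed, "adapt_split"), {
    ev <- sample(which(d_all$outcomes$event == 1))
    ce <- sample(which(d_all$outcomes$event == 0))
    n_ev <- round(n_adapt * length(ev) / n)
    adapt_idx <- sort(c(ev[seq_len(min(n_ev, length(ev)))],
                        ce[seq_len(min(n_adapt - min(n_ev, length(ev)),
                                       length(ce)))]))
  })
  eval_idx <- setdiff(seq_len(n), adapt_idx)
  if (epochs > 0 && sum(d_all$outcomes$event[adapt_idx]) == 0)
    stop_cms("adaptation split has zero events; choose another seed or fraction")
  adapted <- model
  if (epochs > 0) {
    d_adapt <- apply_fold_features(external, prep, adapt_idx)
    acfg <- config
    acfg$seed <- derive_seed(seed, "adapt")
    acfg$early_stopping_patience <- NULL
    adapted <- train_stage(model, "adapt_fused", d_adapt, acfg,
                           epochs = epochs, check_prior = FALSE,
                           anchor_decay = anchor_decay)
  }
  d_eval <- apply_fold_features(external, prep, eval_idx)
  em_ev <- model_embeddings(adapted, d_eval)
  risk_ev <- predict_risk_fused(adapted, em_ev$E_i, em_ev$E_n)
  ad_ci <- bootstrap_ci(risk_ev, d_eval$outcomes, n_boot = n_boot,
                        seed = derive_seed(seed, "adapt_boot"))
  list(
    zero_shot = list(c_index = zs_ci$point, ci = c(zs_ci$low, zs_ci$high),
                     ids = d_all$ids, risk = risk_all),
    adapted = list(c_index = ad_ci$point, ci = c(ad_ci$low, ad_ci$high),
                   ids = d_eval$ids, risk = risk_ev,
                   n_adapt = length(adapt_idx), n_eval = length(eval_idx)))
}
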