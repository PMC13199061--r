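#' Configuration of the contrastive training objective
#'
#' Bundles the InfoNCE temperature, the weight `lambda` multiplying the Cox
#' partial-likelihood term in the stage-2 combined loss, and whether the
#' InfoNCE term is symmetrised over the image->non-image and
#' non-image->image directions.
#'
#' @param temperature positive scaling of cosine similarities before the
#'   softmax. Lower values sharpen the contrast between the matched pair
#'   and in-batch negatives.
#' @param lambda_weight non-negative weight of the Cox term in the stage-2
#'   loss `InfoNCE + lambda * CoxNLL`.
#' @param symmetric average the two softmax directions (rows and columns of
#'   the similarity matrix)?
#' @return a list of class `cms_contrastive_config`.
#' @export
contrastive_config <- function(temperature = 0.1, lambda_weight = 1,
                               symmetric = TRUE) {
  if (!is.numeric(temperature) || temperature <= 0)
    stop_cms("temperature must be > 0")
  if (!is.numeric(lambda_weight) || lambda_weight < 0)
    stop_cms("lambda_weight must be >= 0")
  structure(list(temperature = temperature,
                 lambda_weight = lambda_weight,
                 symmetric = check_flag(symmetric, "symmetric")),
            class = "cms_contrastive_config")
}

#' Cox negative log partial likelihood
#'
#' Breslow form: for each observed event i the risk set is every patient
#' whose follow-up time is at least `T_i` (tied event times share one risk
#' set), and the loss averages `-(h_i - log sum_{j in R(T_i)} exp(h_j))`
#' over the observed events. Computed with log-sum-exp stabilisation.
#'
#' @param risks numeric risk score per patient (higher = worse prognosis).
#' @param outcomes data frame with columns `time`, `event`, aligned to
#'   `risks`.
#' @return the scalar loss (non-negative up to floating point).
#' @seealso [cox_partial_nll_grad()] for the gradient used in training.
#' @export
cox_partial_nll <- function(risks, outcomes) {
  cox_nll_internal(risks, outcomes, grad = FALSE)$loss
}

#' Gradient of the Cox partial likelihood loss with respect to the risks
#'
#' @inheritParams cox_partial_nll
#' @return list with elements `loss` and `grad` (numeric, same length as
#'   `risks`).
#' @export
cox_partial_nll_grad <- function(risks, outcomes) {
  cox_nll_internal(risks, outcomes, grad = TRUE)
}

cox_nll_internal <- function(risks, outcomes, grad = FALSE) {
  outcomes <- check_outcomes(outcomes)
  n <- length(risks)
  if (n != nrow(outcomes))
    stop_cms("risks and outcomes are not aligned")
  if (any(!is.finite(risks))) stop_cms("risk scores must be finite")
  n_event <- sum(outcomes$event)
  if (n_event == 0)
    stop_cms("Cox partial likelihood is undefined with zero events")

  time <- outcomes$time
  event <- outcomes$event
  ord <- order(time, decreasing = TRUE)   # largest time first
  h <- risks[ord]
  m <- max(h)
  e <- exp(h - m)
  cum <- cumsum(e)                         # sum over {T_j >= T_i} up to ties
  t_ord <- time[ord]
  # tied times must share the full risk-set sum: take the cumulative sum at
  # the LAST position of each tie block
  riskset_sum <- cum[ave(seq_len(n), t_ord, FUN = max)]
  log_den <- m + log(riskset_sum)
  is_event <- event[ord] == 1
  loss <- -sum(h[is_event] - log_den[is_event]) / n_event
  out <- list(loss = loss)
  if (grad) {
    # d/dh_k = -(1/Ne) [ delta_k - exp(h_k) * sum_{events i: T_i <= T_k} 1/S_i ]
    # stabilised: exp(h_k)/S_i = exp(h_k - m)/riskset_sum_i
    inv <- ifelse(is_event, 1 / riskset_sum, 0)
    # patients ordered by decreasing time: events with T_i <= T_k are those at
    # positions >= first position of k's tie block... work on tie blocks:
    first_of_tie <- ave(seq_len(n), t_ord, FUN = min)
    cum_inv <- cumsum(inv)
    # sum of inv over events with time <= T_k = total - sum over events with
    # time > T_k = cum_inv[n] - cum_inv[first_of_tie - 1]
    before <- ifelse(first_of_tie > 1, cum_inv[pmax(first_of_tie - 1, 1)], 0)
    before[first_of_tie == 1] <- 0
    tail_sum <- cum_inv[n] - before
    g_ord <- -(ifelse(is_event, 1, 0) - e * tail_sum) / n_event
    g <- numeric(n)
    g[ord] <- g_ord
    out$grad <- g
  }
  out
}

#' Cross-modal InfoNCE loss
#'
#' Rows of `proj_image` and `proj_nonimage` are unit-norm projections of the
#' same patients in the two modalities. The similarity matrix
#' `S = proj_image %*% t(proj_nonimage) / temperature` is scored row-wise by
#' softmax cross-entropy against the diagonal (each patient's matched
#' cross-modal embedding is the positive; every other patient in the batch
#' is a negative). With `symmetric = TRUE` the column-wise direction is
#' averaged in.
#'
#' @param proj_image,proj_nonimage numeric matrices, batch x d, unit rows.
#' @param config a [contrastive_config()].
#' @return scalar loss, non-negative.
#' @export
info_nce_loss <- function(proj_image, proj_nonimage, config = contrastive_config()) {
  info_nce_internal(proj_image, proj_nonimage, config, grad = FALSE)$loss
}

#' @rdname info_nce_loss
#' @return for `info_nce_grad`: list with `loss`, `grad_image`,
#'   `grad_nonimage` (gradients with respect to the projected rows).
#' @export
info_nce_grad <- function(proj_image, proj_nonimage, config = contrastive_config()) {
  info_nce_internal(proj_image, proj_nonimage, config, grad = TRUE)
}

info_nce_internal <- function(proj_image, proj_nonimage, config, grad) {
  P <- as.matrix(proj_image); Q <- as.matrix(proj_nonimage)
  B <- nrow(P)
  if (B == 0) stop_cms("InfoNCE requires a non-empty batch")
  if (!all(dim(P) == dim(Q)))
    stop_cms("projected matrices must have identical dimensions")
  renorm <- function(M) {
    nrm <- sqrt(rowSums(M^2))
    bad <- abs(nrm - 1) > 1e-6
    if (any(bad)) {
      warning("non-unit projection rows renormalized", call. = FALSE)
      M[bad, ] <- M[bad, , drop = FALSE] / pmax(nrm[bad], 1e-12)
    }
    M
  }
  P <- renorm(P); Q <- renorm(Q)
  S <- tcrossprod(P, Q) / config$temperature
  row_dir <- function(S) {
    m <- apply(S, 1, max)
    lse <- m + log(rowSums(exp(S - m)))
    list(loss = mean(lse - diag(S)),
         dS = (exp(S - lse) - diag(nrow(S))) / nrow(S))
  }
  r <- row_dir(S)
  loss <- r$loss; dS <- r$dS
  if (isTRUE(config$symmetric)) {
    c2 <- row_dir(t(S))
    loss <- (loss + c2$loss) / 2
    dS <- (dS + t(c2$dS)) / 2
  }
  out <- list(loss = loss)
  if (grad) {
    out$grad_image <- (dS %*% Q) / config$temperature
    out$grad_nonimage <- (t(dS) %*% P) / config$temperature
  }
  out
}

#' Stage-2 combined contrastive + survival loss
#'
#' `InfoNCE(proj_image, proj_nonimage) + lambda * CoxNLL(risks, outcomes)`.
#' During stage-2 training the risks come from a lightweight linear readout
#' on the concatenated pre-projection embeddings (see the pipeline
#' documentation); here the components are combined from whatever the
#' caller supplies.
#'
#' @inheritParams info_nce_loss
#' @inheritParams cox_partial_nll
#' @return scalar loss.
#' @export
stage2_combined_loss <- function(proj_image, proj_nonimage, risks, outcomes,
                                 config = contrastive_config()) {
  if (config$lambda_weight < 0) stop_cms("lambda_weight must be >= 0")
  nce <- info_nce_loss(proj_image, proj_nonimage, config)
  if (config$lambda_weight == 0) return(nce)
  nce + config$lambda_weight * cox_partial_nll(risks, outcomes)
}
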