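#' Two-step LASSO-then-OLS feature importance
#'
#' Step 1: L1-penalised linear regression of the response (by default the
#' fused model's predicted risk score) on the standardized non-image
#' features, with the penalty chosen by k-fold cross-validated prediction
#' error over a log-spaced grid descending four decades from the
#' all-zero penalty. Step 2: unpenalised least squares on the selected
#' columns with per-coefficient Wald t statistics, two-sided p-values and
#' 95% confidence intervals. P-values are post-selection and nominal: the
#' selection step is not accounted for, so they should be read as
#' descriptive, as flagged in the output.
#'
#' @param features patients x features numeric matrix (standardized;
#'   column names required).
#' @param response numeric response per patient (e.g. predicted risk).
#' @param penalty_grid optional decreasing positive penalty values; the
#'   default is 50 log-spaced values from the data-derived maximum down 4
#'   decades.
#' @param cv_folds folds for the penalty choice.
#' @param seed integer seed (fold assignment in the penalty search).
#' @return data frame of class `cms_importance` sorted by `|coefficient|`
#'   descending, with columns `feature`, `coefficient`, `ci_low`,
#'   `ci_high`, `p_value`, `selected_by_lasso`; attribute
#'   `inference = "post-selection, nominal"`.
#' @export
lasso_ols_importance <- function(features, response, penalty_grid = NULL,
                                 cv_folds = 5, seed = 1L) {
  X <- as.matrix(features)
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("feature_%03d", seq_len(ncol(X)))
  y <- as.numeric(response)
  if (length(y) != nrow(X)) stop_cms("features and response are not aligned")
  if (any(!is.finite(y)) || any(!is.finite(X)))
    stop_cms("features and response must be finite")
  cv_folds <- check_count(cv_folds, "cv_folds", min = 2L)
  if (is.null(penalty_grid)) {
    lam_max <- max(abs(crossprod(X, y - mean(y)))) / nrow(X)
    if (lam_max <= 0) lam_max <- 1
    penalty_grid <- exp(seq(log(lam_max), log(lam_max * 1e-4), length.out = 50))
  }
  if (any(penalty_grid <= 0)) stop_cms("penalties must be > 0")
  penalty_grid <- sort(penalty_grid, decreasing = TRUE)

  empty <- function() {
    out <- data.frame(feature = character(), coefficient = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p_value = numeric(), selected_by_lasso = logical())
    attr(out, "inference") <- "post-selection, nominal"
    class(out) <- c("cms_importance", class(out))
    out
  }

  foldid <- with_seed(derive_seed(seed, "lasso_cv"),
                      sample(rep_len(seq_len(cv_folds), nrow(X))))
  cvfit <- glmnet::cv.glmnet(X, y, alpha = 1, lambda = penalty_grid,
                             foldid = foldid, standardize = FALSE)
  beta <- as.vector(coef(cvfit, s = "lambda.min"))[-1]
  selected <- colnames(X)[beta != 0]
  if (!length(selected)) {
    warning("LASSO selected no features", call. = FALSE)
    return(empty())
  }
  Xs <- X[, selected, drop = FALSE]
  # drop machine-precision collinear duplicates, keeping earlier columns
  qrd <- qr(cbind(1, Xs))
  keep_cols <- qrd$pivot[seq_len(qrd$rank)]
  keep_cols <- sort(setdiff(keep_cols, 1)) - 1L
  if (length(keep_cols) < length(selected))
    message(length(selected) - length(keep_cols),
            " collinear selected feature(s) dropped")
  selected <- selected[keep_cols]
  Xs <- X[, selected, drop = FALSE]
  if (nrow(Xs) <= ncol(Xs) + 1)
    stop_cms("too few patients for the OLS step on ", ncol(Xs), " features")

  df <- data.frame(y = y, Xs, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = 0.95)
  rows <- match(make.names(selected), rownames(sm))
  # lm backtick-mangles names; fall back to positional (intercept first)
  if (anyNA(rows)) rows <- seq_along(selected) + 1L
  out <- data.frame(feature = selected,
                    coefficient = sm[rows, "Estimate"],
                    ci_low = ci[rows, 1], ci_high = ci[rows, 2],
                    p_value = sm[rows, "Pr(>|t|)"],
                    selected_by_lasso = TRUE,
                    row.names = NULL)
  out <- out[order(-abs(out$coefficient)), ]
  rownames(out) <- NULL
  attr(out, "inference") <- "post-selection, nominal"
  attr(out, "lambda") <- cvfit$lambda.min
  class(out) <- c("cms_importance", class(out))
  out
}
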