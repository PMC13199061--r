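#' @useDynLib cmsurv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rexp rbinom uniroot median pchisq pt qt
#'   quantile sd coef setNames ave
#' @importFrom utils read.csv write.csv modifyList head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cms <- function(...) stop(..., call. = FALSE)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_cms(name, " must be TRUE or FALSE")
  x
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop_cms(name, " must be an integer >= ", min)
  as.integer(x)
}

check_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_cms(name, " must be a probability")
  if (open && (x <= 0 || x >= 1)) stop_cms(name, " must lie in (0, 1)")
  if (!open && (x < 0 || x > 1)) stop_cms(name, " must lie in [0, 1]")
  x
}

check_outcomes <- function(outcomes) {
  if (!is.data.frame(outcomes) || !all(c("time", "event") %in% names(outcomes)))
    stop_cms("outcomes must be a data frame with columns 'time' and 'event'")
  if (any(!is.finite(outcomes$time)) || any(outcomes$time <= 0))
    stop_cms("all follow-up times must be finite and > 0")
  if (!all(outcomes$event %in% c(0, 1)))
    stop_cms("event indicator must be 0 (censored) or 1 (death)")
  outcomes
}

#' Derive a named child seed from a root seed
#'
#' All randomness in the package flows from one root seed expanded into
#' named sub-streams (simulation, folds, init, bootstrap, ...) so a single
#' integer reproduces an entire experiment.
#'
#' @param seed integer root seed.
#' @param what character tag naming the sub-stream.
#' @return an integer seed deterministically derived from `seed` and `what`.
#' @export
derive_seed <- function(seed, what) {
  codes <- utf8ToInt(what)
  h <- sum(codes * seq_along(codes))
  as.integer((as.double(seed) * 48271 + h * 1009) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
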