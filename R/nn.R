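# Minimal dense-network machinery: fully connected stacks with ReLU hidden
# units, inverted dropout, explicit backward passes, and Adam. Parameters
# live in nested lists of plain matrices; tree_* helpers walk them.

relu <- function(x) pmax(x, 0)

# seeded uniform fan-in initialisation: U(-1/sqrt(fan_in), 1/sqrt(fan_in)),
# drawn from the CURRENT RNG stream (callers seed it)
init_mat <- function(n_in, n_out) {
  s <- 1 / sqrt(n_in)
  matrix(runif(n_in * n_out, -s, s), n_in, n_out)
}

#' @noRd
mlp_new <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden, n_out)
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    layers[[l]] <- list(W = init_mat(sizes[l], sizes[l + 1L]),
                        b = matrix(0, 1, sizes[l + 1L]))
  }
  structure(list(layers = layers, sizes = sizes), class = "cms_mlp")
}

# forward pass; hidden layers ReLU (+ dropout in training mode), linear
# output. Returns list(out, cache) when cache = TRUE.
mlp_forward <- function(net, X, training = FALSE, dropout = 0, cache = FALSE) {
  X <- as.matrix(X)
  if (ncol(X) != net$sizes[1L])
    stop_cms("input has ", ncol(X), " features but network expects ",
             net$sizes[1L])
  L <- length(net$layers)
  acts <- if (cache) vector("list", L) else NULL
  masks <- if (cache) vector("list", L) else NULL
  A <- X
  for (l in seq_len(L)) {
    if (cache) acts[[l]] <- A
    Z <- A %*% net$layers[[l]]$W +
      matrix(net$layers[[l]]$b, nrow(A), ncol(net$layers[[l]]$b), byrow = TRUE)
    if (l < L) {
      A <- relu(Z)
      if (training && dropout > 0) {
        keep <- matrix(runif(length(A)) >= dropout, nrow(A), ncol(A))
        A <- A * keep / (1 - dropout)
        if (cache) masks[[l]] <- keep
      }
    } else A <- Z
  }
  if (cache) list(out = A, acts = acts, masks = masks, dropout = dropout)
  else A
}

# backward pass given upstream gradient dOut; returns gradients in the same
# nested shape as net$layers plus dX
mlp_backward <- function(net, fw, dOut) {
  L <- length(net$layers)
  grads <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    A_in <- fw$acts[[l]]
    grads[[l]] <- list(W = crossprod(A_in, delta),
                       b = matrix(colSums(delta), 1))
    dA <- delta %*% t(net$layers[[l]]$W)
    if (l > 1L) {
      # undo dropout then ReLU of the previous layer's output
      if (!is.null(fw$masks[[l - 1L]]))
        dA <- dA * fw$masks[[l - 1L]] / (1 - fw$dropout)
      dA <- dA * (fw$acts[[l]] > 0)
      # note: acts[[l]] is the post-activation input to layer l; its
      # positivity pattern equals that of the pre-activation for ReLU
    }
    delta <- dA
  }
  list(layers = grads, dX = delta)
}

# ---- parameter-tree helpers -------------------------------------------------

tree_map <- function(f, x) {
  if (is.matrix(x)) return(f(x))
  lapply(x, function(el) tree_map(f, el))
}

tree_map2 <- function(f, a, b) {
  if (is.matrix(a)) return(f(a, b))
  mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
}

tree_axpy <- function(a, x, y) tree_map2(function(p, g) p + a * g, y, x)

# L2-SP anchoring for transfer: gradient += decay * (param - anchor)
tree_grad_anchor <- function(grads, params, anchor, decay) {
  if (is.matrix(grads)) return(grads + decay * (params - anchor))
  mapply(function(g, p, a) tree_grad_anchor(g, p, a, decay),
         grads, params, anchor, SIMPLIFY = FALSE)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params),
       t = 0L)
}

# one Adam step; weight_decay applies to matrices named W only (decoupled,
# skipped for biases). Returns list(params, state).
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v, decay) {
    if (decay > 0) g <- g + decay * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v, name = "") {
    if (is.matrix(p)) {
      decay <- if (identical(name, "b")) 0 else weight_decay
      return(upd(p, g, m, v, decay))
    }
    out_p <- p; out_m <- m; out_v <- v
    for (nm in names(p) %||% as.character(seq_along(p))) {
      i <- if (is.null(names(p))) as.integer(nm) else nm
      r <- walk(p[[i]], g[[i]], m[[i]], v[[i]],
                if (is.null(names(p))) name else nm)
      out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
    }
    list(p = out_p, m = out_m, v = out_v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
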