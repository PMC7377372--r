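# Whole-network assembly on top of the nn-core primitives. A model is a
# plain list: $spec (layer chain + sizes) and $params (named arrays). All
# gradients are hand-derived and checked against central finite differences
# in the test suite, including the tied-rotation accumulation of the FRSS
# block.

MODEL_NAMES <- c("conv4-FRSS", "conv3-FRSS", "conv4", "conv4-nonFRSS",
                 "deepsea-type")

# Truncated normal init (resample outside 2 sd), the conventional scheme for
# small sequence CNNs.
trunc_normal <- function(n, sd = 0.05) {
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

init_kernels <- function(M, N, H, K, sd = 0.05) {
  array(trunc_normal(M * N * H * K, sd), dim = c(M, N, H, K))
}

# Built-in layer chains. The original hyperparameter table is not public, so
# map counts / pooling below are this package's defaults (documented in the
# vignette); every entry can be overridden at build time.
arch_layers <- function(name) {
  switch(name,
    "conv4-FRSS" = list(
      list(type = "frss", maps = c(320L, 320L), kh = c(9L, 8L), pool = 2L,
           tied = TRUE),
      list(type = "conv", maps = 480L, kh = 8L, pool = 2L),
      list(type = "conv", maps = 480L, kh = 8L, pool = 4L)),
    "conv4-nonFRSS" = list(
      list(type = "frss", maps = c(320L, 320L), kh = c(9L, 8L), pool = 2L,
           tied = FALSE),
      list(type = "conv", maps = 480L, kh = 8L, pool = 2L),
      list(type = "conv", maps = 480L, kh = 8L, pool = 4L)),
    "conv3-FRSS" = list(
      list(type = "frss", maps = c(320L, 480L), kh = c(9L, 8L), pool = 2L,
           tied = TRUE),
      list(type = "conv", maps = 960L, kh = 8L, pool = 4L)),
    "conv4" = list(
      list(type = "conv", maps = 320L, kh = 9L, pool = 2L),
      list(type = "conv", maps = 320L, kh = 8L, pool = 2L),
      list(type = "conv", maps = 480L, kh = 8L, pool = 2L),
      list(type = "conv", maps = 480L, kh = 8L, pool = 4L)),
    "deepsea-type" = list(
      list(type = "conv", maps = 320L, kh = 8L, pool = 4L),
      list(type = "conv", maps = 480L, kh = 8L, pool = 4L),
      list(type = "conv", maps = 960L, kh = 8L, pool = 1L)),
    stop(sprintf("unknown model '%s'; choose one of %s", name,
                 paste(MODEL_NAMES, collapse = ", ")))
  )
}

#' Build a strand-scan network
#'
#' Assembles one of the named architectures and initializes its weights
#' (truncated normal, sd 0.05; biases zero) under the given seed. The FRSS
#' variants start with a tied-rotation block (the reverse-strand stream is a
#' derived 180-degree rotation of the forward kernels); `conv4-nonFRSS` is
#' the ablation with the same shapes but independently trainable
#' second-stream kernels, so it has strictly more parameters.
#'
#' @param name One of `"conv4-FRSS"`, `"conv3-FRSS"`, `"conv4"`,
#'   `"conv4-nonFRSS"`, `"deepsea-type"`.
#' @param class_count Number of output classes (epigenomic datasets).
#' @param window Input window size in bp (default 1000).
#' @param seed Integer seed for weight initialization (mandatory for
#'   reproducibility).
#' @param overrides Named list overriding defaults: `layers` (a full layer
#'   chain as produced internally), `fc_units`, `frss_mode`
#'   (`"figure"`/`"literal"`), `dropout`, `init_sd`, `regularize`,
#'   `global_pool` (take the maximum of each feature map over all positions
#'   before the fully-connected layer; off for the full-scale
#'   architectures, used by the small benchmark models where per-position
#'   fully-connected weights would simply memorize a desk-scale training
#'   set).
#' @return An object of class `strand_model` with elements `spec` and
#'   `params`.
#' @export
build_model <- function(name, class_count, window = 1000L, seed = 1L,
                        overrides = list()) {
  name <- match.arg(name, MODEL_NAMES)
  stopifnot(class_count >= 1L)
  layers <- overrides$layers %||% arch_layers(name)
  fc_units <- overrides$fc_units %||% 925L
  frss_mode <- overrides$frss_mode %||% "figure"
  dropout <- overrides$dropout %||% 0
  init_sd <- overrides$init_sd %||% 0.05
  regularize <- overrides$regularize %||% TRUE
  global_pool <- overrides$global_pool %||% FALSE
  spec <- list(name = name, window = as.integer(window),
               class_count = as.integer(class_count), layers = layers,
               fc_units = as.integer(fc_units), frss_mode = frss_mode,
               dropout = dropout, seed = as.integer(seed),
               regularize = regularize, global_pool = global_pool)
  # shape chain: channels C and length S through the layer list
  S <- as.integer(window); C <- 4L
  shapes <- list()
  for (li in seq_along(layers)) {
    ly <- layers[[li]]
    if (ly$type == "frss") {
      S1 <- S - ly$kh[1L] + 1L
      if (S1 < 1L) stop("window too short for first FRSS kernel")
      S1 <- S1 %/% ly$pool
      S2 <- S1 - ly$kh[2L] + 1L
      if (S2 < 1L) stop("pooled length too short for second FRSS kernel")
      S <- S2 %/% ly$pool
      C <- ly$maps[2L]
    } else {
      S1 <- S - ly$kh + 1L
      if (S1 < 1L)
        stop(sprintf("layer %d: input length %d shorter than kernel %d",
                     li, S, ly$kh))
      S <- S1 %/% ly$pool
      C <- ly$maps
    }
    if (S < 1L) stop(sprintf("layer %d: pooling exhausted the sequence", li))
    shapes[[li]] <- c(S = S, C = C)
  }
  spec$flat_dim <- if (global_pool) C else S * C
  spec$shapes <- shapes
  params <- withr::with_seed(seed, {
    p <- list()
    C_in <- 4L
    for (li in seq_along(layers)) {
      ly <- layers[[li]]
      nm <- paste0("L", li)
      if (ly$type == "frss") {
        p[[paste0(nm, ".W0")]] <- init_kernels(ly$kh[1L], 4L, 1L,
                                               ly$maps[1L], init_sd)
        p[[paste0(nm, ".W1")]] <- init_kernels(ly$kh[2L], 1L, ly$maps[1L],
                                               ly$maps[2L], init_sd)
        if (!isTRUE(ly$tied)) {
          p[[paste0(nm, ".W0b")]] <- init_kernels(ly$kh[1L], 4L, 1L,
                                                  ly$maps[1L], init_sd)
          p[[paste0(nm, ".W1b")]] <- init_kernels(ly$kh[2L], 1L,
                                                  ly$maps[1L], ly$maps[2L],
                                                  init_sd)
        }
        C_in <- ly$maps[2L]
      } else {
        p[[paste0(nm, ".W")]] <- init_kernels(ly$kh, 1L, C_in, ly$maps,
                                              init_sd)
        C_in <- ly$maps
      }
    }
    p[["fc.W"]] <- matrix(trunc_normal(spec$flat_dim * fc_units, init_sd),
                          nrow = spec$flat_dim)
    p[["fc.b"]] <- numeric(fc_units)
    p[["out.W"]] <- matrix(trunc_normal(fc_units * class_count, init_sd),
                           nrow = fc_units)
    p[["out.b"]] <- numeric(class_count)
    p
  })
  structure(list(spec = spec, params = params), class = "strand_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.strand_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<strand_model> %s: window %d bp -> %d class(es)\n",
              s$name, s$window, s$class_count))
  for (li in seq_along(s$layers)) {
    ly <- s$layers[[li]]
    if (ly$type == "frss") {
      cat(sprintf("  L%d frss%s [%s]: maps %s, kernels %s, pool %d -> %d x %d\n",
                  li, if (isTRUE(ly$tied)) "" else " (untied)", s$frss_mode,
                  paste(ly$maps, collapse = "/"),
                  paste(ly$kh, collapse = "/"), ly$pool,
                  s$shapes[[li]]["S"], s$shapes[[li]]["C"]))
    } else {
      cat(sprintf("  L%d conv: maps %d, kernel %d, pool %d -> %d x %d\n",
                  li, ly$maps, ly$kh, ly$pool,
                  s$shapes[[li]]["S"], s$shapes[[li]]["C"]))
    }
  }
  cat(sprintf("  fc %d -> sigmoid head %d; %s trainable parameters\n",
              s$fc_units, s$class_count,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#' @param model A `strand_model`.
#' @return Integer count over all weight arrays (tied rotated copies are
#'   views, not parameters, so they do not count).
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Forward pass of a model
#'
#' @param model A `strand_model`.
#' @param X One-hot inputs: a single S x 4 window or a B x S x 4 array.
#' @param need_cache Keep intermediate activations for a backward pass.
#' @param train Apply dropout (if configured) using the current RNG stream.
#' @return List with `logits` and `probs` (B x class matrices) and, when
#'   requested, `cache`.
#' @export
model_forward <- function(model, X, need_cache = FALSE, train = FALSE) {
  bx <- as_batch_array(X)
  if (dim(bx$x)[2L] != model$spec$window)
    stop(sprintf("input length %d does not match model window %d",
                 dim(bx$x)[2L], model$spec$window))
  X <- bx$x
  p <- model$params
  caches <- list()
  H <- X
  for (li in seq_along(model$spec$layers)) {
    ly <- model$spec$layers[[li]]
    nm <- paste0("L", li)
    if (ly$type == "frss") {
      fw <- frss_forward_cached(p[[paste0(nm, ".W0")]],
                                p[[paste0(nm, ".W1")]],
                                ly$pool, model$spec$frss_mode, H,
                                W0b = p[[paste0(nm, ".W0b")]],
                                W1b = p[[paste0(nm, ".W1b")]])
      H <- fw$out
      caches[[li]] <- fw$cache
    } else {
      W <- p[[paste0(nm, ".W")]]
      A <- .conv_fwd_cpp(H, matrix(W, ncol = dim(W)[4L]), dim(H),
                         dim(W)[1L])
      R <- relu(A)
      P <- pool_max(R, ly$pool)
      caches[[li]] <- list(type = "conv", X = H, A = A, P = P, W = W)
      H <- P$out
    }
  }
  B <- dim(H)[1L]
  gp_cache <- NULL
  if (isTRUE(model$spec$global_pool)) {
    gp_cache <- pool_max(H, dim(H)[2L])
    H <- gp_cache$out
  }
  flat <- matrix(H, nrow = B)
  fcA <- sweep(flat %*% p[["fc.W"]], 2L, p[["fc.b"]], "+")
  fcR <- relu(fcA)
  drop_mask <- NULL
  if (train && model$spec$dropout > 0) {
    drop_mask <- matrix(stats::runif(length(fcR)) >= model$spec$dropout,
                        nrow = B) / (1 - model$spec$dropout)
    fcR <- fcR * drop_mask
  }
  logits <- sweep(fcR %*% p[["out.W"]], 2L, p[["out.b"]], "+")
  colnames(logits) <- NULL
  out <- list(logits = logits, probs = sigmoid(logits))
  if (need_cache)
    out$cache <- list(layers = caches, flat = flat, fcA = fcA, fcR = fcR,
                      drop_mask = drop_mask, feat_dim = dim(H),
                      gp_cache = gp_cache, B = B)
  out
}

#' Multi-label cross-entropy loss with weight and logit penalties
#'
#' Mean over batch and classes of the Bernoulli cross-entropy
#' `-[y log p + (1-y) log(1-p)]` with probabilities clipped to
#' `[eps, 1-eps]`, plus `lambda1 * sum(w^2)` over all trainable weights and
#' `lambda2 * sum(|logit|)` (an L1 penalty on pre-sigmoid predictions).
#' The penalty terms are applied for the convolutional architecture families
#' and switched off by `regularize = FALSE`.
#'
#' @param labels 0/1 matrix, batch x classes.
#' @param logits Pre-sigmoid scores, same shape.
#' @param params Named list of weight arrays (for the L2 term); `NULL`
#'   drops it.
#' @param lambda1 L2 coefficient, default `5e-7`.
#' @param lambda2 Logit-L1 coefficient, default `1e-8`.
#' @param regularize Include the penalty terms (default TRUE).
#' @param eps Probability clip, default `1e-8`.
#' @return The scalar loss, with a `"components"` attribute (bce, l2, l1).
#' @export
bce_loss <- function(labels, logits, params = NULL, lambda1 = 5e-7,
                     lambda2 = 1e-8, regularize = TRUE, eps = 1e-8) {
  labels <- as.matrix(labels); logits <- as.matrix(logits)
  stopifnot(all(dim(labels) == dim(logits)))
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  p <- pmin(pmax(sigmoid(logits), eps), 1 - eps)
  bce <- -mean(labels * log(p) + (1 - labels) * log(1 - p))
  l2 <- 0; l1 <- 0
  if (regularize) {
    if (!is.null(params))
      l2 <- lambda1 * sum(vapply(params, function(w) sum(w^2), numeric(1)))
    l1 <- lambda2 * sum(abs(logits))
  }
  structure(bce + l2 + l1, components = c(bce = bce, l2 = l2, l1 = l1))
}

# Gradient of bce_loss w.r.t. logits (clip region treated as flat is
# irrelevant at trainable scales; the analytic form below matches finite
# differences in the tests).
dloss_dlogits <- function(labels, logits, lambda2 = 1e-8, regularize = TRUE) {
  p <- sigmoid(logits)
  g <- (p - labels) / length(labels)
  if (regularize) g <- g + lambda2 * sign(logits)
  g
}

#' Backward pass: gradients of a scalar objective through the network
#'
#' @param model A `strand_model`.
#' @param fw Result of [model_forward()] with `need_cache = TRUE`.
#' @param dlogits Gradient of the objective w.r.t. the logits (B x classes).
#' @param need_dx Also return the gradient w.r.t. the one-hot input (used by
#'   saliency and activation maximization).
#' @return List with `grads` (named like `model$params`) and optionally `dX`.
#' @export
model_backward <- function(model, fw, dlogits, need_dx = FALSE) {
  p <- model$params
  cache <- fw$cache
  grads <- list()
  grads[["out.W"]] <- crossprod(cache$fcR, dlogits)
  grads[["out.b"]] <- colSums(dlogits)
  dfcR <- dlogits %*% t(p[["out.W"]])
  if (!is.null(cache$drop_mask)) dfcR <- dfcR * cache$drop_mask
  dfcA <- dfcR * (cache$fcA > 0)
  grads[["fc.W"]] <- crossprod(cache$flat, dfcA)
  grads[["fc.b"]] <- colSums(dfcA)
  dH <- array(dfcA %*% t(p[["fc.W"]]), dim = cache$feat_dim)
  if (!is.null(cache$gp_cache))
    dH <- pool_max_backward(dH, cache$gp_cache, cache$B,
                            cache$feat_dim[3L])
  for (li in rev(seq_along(model$spec$layers))) {
    ly <- model$spec$layers[[li]]
    nm <- paste0("L", li)
    lc <- cache$layers[[li]]
    last <- li == 1L && !need_dx
    if (ly$type == "frss") {
      bk <- frss_backward(lc, dH, need_dx = !last)
      grads[[paste0(nm, ".W0")]] <- bk$W0
      grads[[paste0(nm, ".W1")]] <- bk$W1
      if (!is.null(bk$W0b)) grads[[paste0(nm, ".W0b")]] <- bk$W0b
      if (!is.null(bk$W1b)) grads[[paste0(nm, ".W1b")]] <- bk$W1b
      if (!last) dH <- bk$dX
    } else {
      W <- lc$W; K <- dim(W)[4L]
      dR <- pool_max_backward(dH, lc$P, dim(lc$X)[1L], K)
      dA <- relu_backward(dR, lc$A)
      bw <- .conv_bwd_cpp(lc$X, matrix(W, ncol = K), dA, dim(lc$X),
                          dim(W)[1L], !last)
      grads[[paste0(nm, ".W")]] <- array(bw$dW, dim = dim(W))
      if (!last) dH <- bw$dX
    }
  }
  out <- list(grads = grads)
  if (need_dx) out$dX <- dH
  out
}

# Loss + full parameter gradients on one batch (adds the L2/L1 penalty
# gradients when the model family uses them).
model_loss_grads <- function(model, X, y, lambda1 = 5e-7, lambda2 = 1e-8,
                             train = TRUE) {
  reg <- isTRUE(model$spec$regularize)
  fw <- model_forward(model, X, need_cache = TRUE, train = train)
  lo <- bce_loss(y, fw$logits, model$params, lambda1, lambda2,
                 regularize = reg)
  dlog <- dloss_dlogits(y, fw$logits, lambda2, regularize = reg)
  bk <- model_backward(model, fw, dlog)
  if (reg && lambda1 != 0) {
    for (nm in names(bk$grads))
      bk$grads[[nm]] <- bk$grads[[nm]] + 2 * lambda1 * model$params[[nm]]
  }
  list(loss = as.numeric(lo), grads = bk$grads, probs = fw$probs,
       logits = fw$logits)
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(w) w * 0),
       v = lapply(params, function(w) w * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
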