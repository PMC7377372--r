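# Numeric core: VALID cross-correlation, 180-degree kernel rotation and
# max pooling, implemented with im2col matrix multiplication so the whole
# batch runs through one BLAS call per layer.
#
# Tensor conventions (column-major R arrays):
#   inputs/features  X : B x S x C   (batch, position, channels; C = N * H
#                        with nucleotide width n fastest, then feature map h)
#   kernel stacks    W : M x N x H x K (height, width, in-channels, maps)
# Flattening W with matrix(W, M*N*H, K) matches the im2col column order
# (m fastest, then n, then h), which is what makes the single matrix
# multiply equal the quadruple-sum cross-correlation.

#' Create a kernel stack
#'
#' @param weights Numeric array of dimension M x N x H x K: kernel height
#'   (positions), kernel width (nucleotide axis; 4 in the first layer, 1
#'   afterwards), input channels, and output maps.
#' @return The array with class `kernel_stack`.
#' @export
kernel_stack <- function(weights) {
  stopifnot(is.array(weights), length(dim(weights)) == 4L,
            all(is.finite(weights)))
  structure(weights, class = "kernel_stack")
}

#' Rotate a kernel stack by 180 degrees
#'
#' Index-reverses the position (M) and width (N) axes while leaving input
#' channels and output maps untouched: `out[m,n,h,k] = w[M-1-m, N-1-n, h, k]`
#' (0-based). Scanning a sequence with the rotated kernels is equivalent to
#' scanning the reverse-complement strand with the originals, which is how
#' one set of weights serves both DNA strands. The operation is an
#' involution; for second-layer kernels (N = 1) only the position axis
#' reverses.
#'
#' @param W A kernel array (M x N x H x K) or [kernel_stack()].
#' @return The rotated array, same class and dimensions.
#' @export
rotate_kernels <- function(W) {
  d <- dim(W)
  stopifnot(length(d) == 4L)
  out <- W[rev(seq_len(d[1L])), rev(seq_len(d[2L])), , , drop = FALSE]
  attributes(out)$class <- class(W)
  out
}

# Coerce user input (single window matrix S x 4, or B x S x C array) to the
# internal batch array, remembering whether to drop the batch axis on return.
as_batch_array <- function(X) {
  if (is.matrix(X)) {
    a <- array(0, dim = c(1L, nrow(X), ncol(X)))
    a[1L, , ] <- X
    list(x = a, single = TRUE)
  } else {
    stopifnot(is.array(X), length(dim(X)) == 3L)
    list(x = X, single = FALSE)
  }
}

# im2col: B x S x C -> (B*L) x (M*C) with L = S - M + 1; row index runs b
# fastest then output position i; column index m fastest then channel c.
# One slab assignment per kernel offset m keeps the loop count at M, not M*C.
im2col <- function(X, M) {
  .im2col_cpp(X, dim(X), as.integer(M))
}

# Adjoint of im2col: scatter-add (B*L) x (M*C) gradients back onto B x S x C.
col2im <- function(dZ, dims, M) {
  .col2im_cpp(dZ, as.integer(dims), as.integer(M))
}

#' VALID cross-correlation of a kernel stack with an input
#'
#' Computes the deep-learning "convolution" (a sliding dot product, no
#' kernel flip, no padding): for output position i and map k,
#' `out[i,k] = sum_{m,n,h} W[m,n,h,k] * X[i+m, n, h]`, producing
#' `S - M + 1` positions from a length-S input.
#'
#' @param W Kernel array M x N x H x K; `N * H` must equal the input channel
#'   count (4 for one-hot windows).
#' @param X A single window (S x 4 matrix) or a batch array B x S x C.
#' @param stride Output subsampling along position (default 1).
#' @return For matrix input, an (S-M+1) x K matrix; for batch input, a
#'   B x (S-M+1) x K array.
#' @export
corr_valid <- function(W, X, stride = 1L) {
  bx <- as_batch_array(X)
  d <- dim(bx$x); dW <- dim(W)
  if (length(dW) != 4L)
    stop("kernel stack must be a 4-d array (M x N x H x K)")
  M <- dW[1L]; C_w <- dW[2L] * dW[3L]; K <- dW[4L]
  if (d[2L] < M)
    stop(sprintf("input length %d is shorter than kernel height %d", d[2L], M))
  if (d[3L] != C_w)
    stop(sprintf("channel mismatch: input is %d x %d x %d but kernels are %s",
                 d[1L], d[2L], d[3L], paste(dW, collapse = " x ")))
  L <- d[2L] - M + 1L
  out <- .conv_fwd_cpp(bx$x, matrix(W, nrow = M * C_w, ncol = K), d,
                       as.integer(M))
  if (stride > 1L)
    out <- out[, seq.int(1L, L, by = stride), , drop = FALSE]
  if (bx$single) matrix(out[1L, , ], nrow = dim(out)[2L], ncol = K) else out
}

relu <- function(x) .relu_cpp(x)

# dR * (relu'(A)): zero where the pre-activation was non-positive.
relu_backward <- function(dR, A) .relu_backward_cpp(dR, A)

# Non-overlapping max pooling along the position axis of a B x L x K array.
# Odd trailing positions are floor-dropped. Returns the pooled array plus the
# argmax offsets needed by the backward pass.
pool_max <- function(X, p) {
  d <- dim(X); L <- d[2L]
  if (L %/% p == 0L)
    stop(sprintf("cannot pool length %d with window %d", L, p))
  if (L %% p != 0L) note_pool_drop(L, p)
  pm <- .pool_max_cpp(X, d, as.integer(p))
  list(out = pm$out, amax = pm$amax, in_len = L, p = p)
}

pool_max_backward <- function(dOut, cache, B, K) {
  .pool_max_bwd_cpp(dOut, cache$amax, dim(dOut), cache$p, cache$in_len)
}

# Each distinct (length, pool) floor-drop is reported once per session.
.pool_notes <- new.env(parent = emptyenv())
note_pool_drop <- function(L, p) {
  key <- paste(L, p, sep = "/")
  if (is.null(.pool_notes[[key]])) {
    .pool_notes[[key]] <- TRUE
    message(sprintf("pooling: dropping %d trailing position(s) (length %d, window %d)",
                    L %% p, L, p))
  }
}

#' Construct an FRSS block
#'
#' The forward- and reverse-sequence scan block: two convolution layers in
#' which a parallel stream scans the input with 180-degree-rotated copies of
#' the same kernels, so the reverse strand is read without any extra
#' trainable weights. The rotated stacks are derived views recomputed from
#' `W0`/`W1` at every forward pass, never independently updated.
#'
#' @param W0 First-layer kernels, M x 4 x 1 x K.
#' @param W1 Second-layer kernels, M2 x 1 x K x K2.
#' @param pool Pooling window (and stride) applied after each layer;
#'   default 2.
#' @param mode `"figure"` (default): the rotated second-layer stream consumes
#'   the rotated first-layer stream, which makes the block exactly
#'   reverse-complement equivariant. `"literal"`: both second-layer streams
#'   consume the forward stream; provided for fidelity to the summation
#'   formula written with X1 in both branches, but it does not satisfy the
#'   equivariance (see the package vignette).
#' @return An object of class `frss_block`.
#' @export
frss_block <- function(W0, W1, pool = 2L, mode = c("figure", "literal")) {
  mode <- match.arg(mode)
  stopifnot(length(dim(W0)) == 4L, length(dim(W1)) == 4L)
  if (dim(W0)[2L] != 4L) stop("first-layer kernels must have width 4")
  if (dim(W1)[2L] != 1L) stop("second-layer kernels must have width 1")
  if (dim(W1)[3L] != dim(W0)[4L])
    stop("second-layer input channels must equal first-layer map count")
  structure(list(W0 = W0, W1 = W1, pool = as.integer(pool), mode = mode),
            class = "frss_block")
}

#' Forward pass of the FRSS block
#'
#' Computes `X1 = pool(relu(corr(W0, X0)))` and its rotated-stream twin
#' `X1rc = pool(relu(corr(rot(W0), X0)))`, then merges the second-layer
#' streams by element-wise summation before the second pooling:
#' `X2 = pool(relu(corr(W1, X1)) + relu(corr(rot(W1), X1rc)))` in figure
#' mode (the default; in literal mode the rotated branch consumes `X1`).
#' In figure mode the block is reverse-complement equivariant: feeding
#' `rc180(X0)` yields the position-reversed `X2` whenever every pooling
#' input length is even.
#'
#' @param block An [frss_block()].
#' @param X0 A single one-hot window (S x 4) or a batch array B x S x 4.
#' @return The merged feature grid X2 (matrix L2 x K2 for a single window,
#'   else B x L2 x K2).
#' @export
frss_forward <- function(block, X0) {
  bx <- as_batch_array(X0)
  out <- frss_forward_cached(block$W0, block$W1, block$pool, block$mode,
                             bx$x)$out
  if (bx$single) matrix(out[1L, , ], nrow = dim(out)[2L], ncol = dim(out)[3L])
  else out
}

# Internal forward with caches for backprop. W1b: independent second-stream
# kernels for the untied (nonFRSS) variant; NULL means tied rotation.
# W0b likewise for the untied first layer. The two first-layer streams share
# one gather: their kernel stacks are stacked column-wise into a single
# gemm.
frss_forward_cached <- function(W0, W1, pool, mode, X, W0b = NULL, W1b = NULL) {
  W0r <- if (is.null(W0b)) rotate_kernels(W0) else W0b
  W1r <- if (is.null(W1b)) rotate_kernels(W1) else W1b
  K1 <- dim(W0)[4L]; K2 <- dim(W1)[4L]
  W0mat <- cbind(matrix(W0, ncol = K1), matrix(W0r, ncol = K1))
  Aboth <- .conv_fwd_cpp(X, W0mat, dim(X), dim(W0)[1L])
  Rboth <- relu(Aboth)
  Pboth <- pool_max(Rboth, pool)
  X1 <- Pboth$out[, , seq_len(K1), drop = FALSE]
  X1rc <- Pboth$out[, , K1 + seq_len(K1), drop = FALSE]
  Xsec <- if (mode == "figure") X1rc else X1
  B2f <- .conv_fwd_cpp(X1, matrix(W1, ncol = K2), dim(X1), dim(W1)[1L])
  B2r <- .conv_fwd_cpp(Xsec, matrix(W1r, ncol = K2), dim(Xsec), dim(W1)[1L])
  R2f <- relu(B2f); R2r <- relu(B2r)
  P2 <- pool_max(R2f + R2r, pool)
  list(out = P2$out,
       cache = list(X = X, Aboth = Aboth, Pboth = Pboth,
                    X1 = X1, X1rc = X1rc, Xsec = Xsec,
                    B2f = B2f, B2r = B2r, P2 = P2,
                    W0 = W0, W1 = W1, W0r = W0r, W1r = W1r, W0mat = W0mat,
                    pool = pool, mode = mode, tied0 = is.null(W0b),
                    tied1 = is.null(W1b)))
}

# Backward pass of the FRSS block. Returns gradients for W0, W1 (tied
# rotation folded in), for the untied copies when present, and for the input.
frss_backward <- function(cache, dOut, need_dx = TRUE) {
  B <- dim(cache$X)[1L]
  K2 <- dim(cache$W1)[4L]; K1 <- dim(cache$W0)[4L]
  M1 <- dim(cache$W0)[1L]; M2 <- dim(cache$W1)[1L]
  dSum <- pool_max_backward(dOut, cache$P2, B, K2)
  dB2f <- relu_backward(dSum, cache$B2f)
  dB2r <- relu_backward(dSum, cache$B2r)
  b2f <- .conv_bwd_cpp(cache$X1, matrix(cache$W1, ncol = K2), dB2f,
                       dim(cache$X1), M2, TRUE)
  b2r <- .conv_bwd_cpp(cache$Xsec, matrix(cache$W1r, ncol = K2), dB2r,
                       dim(cache$Xsec), M2, TRUE)
  dW1f <- array(b2f$dW, dim = dim(cache$W1))
  dW1r <- array(b2r$dW, dim = dim(cache$W1))
  dX1 <- b2f$dX
  if (cache$mode == "figure") {
    dX1rc <- b2r$dX
  } else {
    dX1 <- dX1 + b2r$dX
    dX1rc <- array(0, dim = dim(cache$X1rc))
  }
  # pooled gradients of the two first-layer streams, re-stacked to match
  # the combined forward gemm
  dPboth <- array(0, dim = dim(cache$Pboth$out))
  dPboth[, , seq_len(K1)] <- dX1
  dPboth[, , K1 + seq_len(K1)] <- dX1rc
  dRboth <- pool_max_backward(dPboth, cache$Pboth, B, 2L * K1)
  dAboth <- relu_backward(dRboth, cache$Aboth)
  b1 <- .conv_bwd_cpp(cache$X, cache$W0mat, dAboth, dim(cache$X), M1,
                      need_dx)
  dW0f <- array(b1$dW[, seq_len(K1)], dim = dim(cache$W0))
  dW0r <- array(b1$dW[, K1 + seq_len(K1)], dim = dim(cache$W0))
  grads <- list()
  if (cache$tied0) {
    grads$W0 <- dW0f + rotate_kernels(dW0r)
  } else {
    grads$W0 <- dW0f
    grads$W0b <- dW0r
  }
  if (cache$tied1) {
    grads$W1 <- dW1f + rotate_kernels(dW1r)
  } else {
    grads$W1 <- dW1f
    grads$W1b <- dW1r
  }
  if (need_dx) grads$dX <- b1$dX
  grads
}
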