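# Independent oracles and shared fixtures for the test suite. Oracles are
# deliberately naive (triple loops, per-base arrays, exhaustive threshold
# sweeps) and never call the code paths they check.

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

random_onehot_batch <- function(B, S, seed = 1) {
  withr::with_seed(seed, {
    X <- array(0, dim = c(B, S, 4L))
    for (b in seq_len(B))
      X[b, , ] <- encode_sequence(random_dna(S))
    X
  })
}

# Triple-loop VALID cross-correlation.
corr_oracle <- function(W, X) {
  M <- dim(W)[1L]; K <- dim(W)[4L]
  C <- dim(W)[2L] * dim(W)[3L]
  L <- nrow(X) - M + 1L
  out <- matrix(0, L, K)
  Wm <- matrix(W, nrow = M * C)
  for (i in seq_len(L)) {
    patch <- as.vector(X[i:(i + M - 1L), , drop = FALSE])
    # patch is (position, channel) column-major = m fastest, matching Wm rows
    for (k in seq_len(K)) out[i, k] <- sum(patch * Wm[, k])
  }
  out
}

# Exhaustive threshold-sweep AUROC (trapezoid) and average precision.
auroc_oracle <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1); N <- sum(labels == 0)
  tpr <- c(0, vapply(ths, function(t) sum(scores >= t & labels == 1) / P,
                     numeric(1)))
  fpr <- c(0, vapply(ths, function(t) sum(scores >= t & labels == 0) / N,
                     numeric(1)))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

auprc_oracle <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  tp_prev <- 0; ap <- 0
  for (t in ths) {
    sel <- scores >= t
    tp <- sum(sel & labels == 1)
    ap <- ap + (tp - tp_prev) / P * (tp / sum(sel))
    tp_prev <- tp
  }
  ap
}

# Per-base boolean-array coverage oracle.
coverage_oracle <- function(reads, genome_sizes) {
  covered <- 0
  for (chr in names(genome_sizes)) {
    v <- logical(genome_sizes[[chr]])
    iv <- reads$intervals[reads$intervals$chrom == chr, , drop = FALSE]
    for (i in seq_len(nrow(iv)))
      v[(iv$start[i] + 1L):iv$end[i]] <- TRUE
    covered <- covered + sum(v)
  }
  covered / sum(genome_sizes)
}

# A tiny model for gradient and interpretability tests; biases are nudged
# off zero so no rectifier sits exactly on its kink (where one-sided
# derivatives differ and finite differences are undefined).
tiny_model <- function(seed = 7, window = 40L, class_count = 2L,
                       tied = TRUE, extra_conv = TRUE) {
  layers <- list(list(type = "frss", maps = c(3L, 4L), kh = c(5L, 4L),
                      pool = 2L, tied = tied))
  if (extra_conv)
    layers <- c(layers, list(list(type = "conv", maps = 5L, kh = 3L,
                                  pool = 2L)))
  m <- build_model(if (tied) "conv4-FRSS" else "conv4-nonFRSS", class_count,
                   window = window, seed = seed,
                   overrides = list(layers = layers, fc_units = 6L))
  withr::with_seed(seed + 1L, {
    m$params[["fc.b"]] <- stats::rnorm(length(m$params[["fc.b"]]), 0, 0.1)
    m$params[["out.b"]] <- stats::rnorm(length(m$params[["out.b"]]), 0, 0.1)
  })
  m
}

# Shared benchmark cache: building a 400-kb genome dataset costs a few
# seconds, and several acceptance properties reuse the same seeds.
.bm_cache <- new.env(parent = emptyenv())
cached_benchmark <- function(seed) {
  key <- as.character(seed)
  if (is.null(.bm_cache[[key]]))
    .bm_cache[[key]] <- suppressMessages(
      synthetic_benchmark(synthetic_spec(seed = seed)))
  .bm_cache[[key]]
}

# Frozen benchmark training protocol (see the methods vignette): lr 1e-2,
# 20 epochs, 1 validation mini-batch, 2 restarts chosen by validation F1.
benchmark_train <- function(seed, tied = TRUE, restarts = 2L, epochs = 20L) {
  bm <- cached_benchmark(seed)
  cfg <- train_config(seed = seed, epochs = epochs, val_batches = 1L,
                      lr = 1e-2)
  suppressMessages(
    train_restarts(function(s) small_frss_model(seed = s, tied = tied),
                   bm$train, cfg, holdout = bm$holdout,
                   restarts = restarts))
}

# Trained 40-bp fixture models for the saliency/mutagenesis agreement
# checks: an untrained rectifier network sits exactly at its kinks, where a
# first-order comparison is uninformative; the method is used on trained
# models. Cached per seed.
trained_fixture <- function(seed) {
  key <- paste0("tf_", seed)
  if (is.null(.bm_cache[[key]])) {
    ds <- withr::with_seed(600 + seed, {
      n <- 240L
      X <- random_onehot_batch(n, 40L, seed = 700 + seed)
      y <- matrix(0L, n, 1L)
      pos <- sample(n, 120)
      y[pos, 1] <- 1L
      for (i in pos) {
        at <- sample(1:33, 1)
        X[i, at:(at + 7), ] <- encode_sequence(
          if (stats::runif(1) < 0.5) "AGGTCATC" else "GATGACCT")
      }
      ds <- list(inputs = X, labels = y,
                 windows = data.frame(chrom = "c", start = 1:n,
                                      end = 2:(n + 1), index = 1:n),
                 class_names = "a", window = 40L, stride = 20L)
      class(ds) <- "window_dataset"
      ds
    })
    m <- small_frss_model(1L, 40L, seed = 800 + seed)
    tr <- train(m, ds, train_config(seed = seed, epochs = 10L,
                                    val_batches = 1L, lr = 1e-2,
                                    batch_size = 40L))
    .bm_cache[[key]] <- list(model = tr$model, data = ds)
  }
  .bm_cache[[key]]
}

# Pooled sign agreement between ISM score changes and their first-order
# gradient predictions, restricted to the larger half of the effects.
ism_sign_agreement <- function(model, X0) {
  sal <- saliency(model, X0, 1L)
  delta <- ism_oracle(model, X0, 1L)
  if (all(delta == 0)) return(c(0, 0))
  pred <- sal$omega - sal$omega[cbind(seq_len(nrow(X0)), max.col(X0))]
  big <- abs(delta) > stats::quantile(abs(delta[delta != 0]), 0.5)
  c(sum(sign(pred[big]) == sign(delta[big])), sum(big))
}
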