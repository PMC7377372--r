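#' Training configuration
#'
#' Bundles the training-schedule knobs: Adam with learning rate 1e-4
#' (optimizer named in the protocol; the rate is this package's default),
#' mini-batches of 100 split into two sub-mini-batches with two alternating
#' update passes (four optimizer updates per mini-batch), on-line F1
#' monitoring with a 0.75 trigger, and three withheld validation
#' mini-batches for checkpointing.
#'
#' @param batch_size Mini-batch size (default 100).
#' @param sub_batches Number of sub-mini-batches per mini-batch (default 2);
#'   must divide `batch_size`.
#' @param update_passes Alternating passes over the sub-mini-batches
#'   (default 2, i.e. four updates per mini-batch of two halves).
#' @param lr Adam learning rate (default 1e-4).
#' @param f1_trigger Mean of the last three training F1 scores that triggers
#'   a validation test (default 0.75).
#' @param f1_history Number of recent F1 scores averaged for the trigger
#'   (default 3).
#' @param val_batches Mini-batches withheld (at random, seeded) as the
#'   validation set (default 3).
#' @param epochs Passes over the training data (default 1).
#' @param lambda1,lambda2 Penalty coefficients passed to [bce_loss()].
#' @param f1_threshold Probability cut for the monitoring F1 (default 0.5).
#' @param seed Integer seed controlling shuffling and validation withholding.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 100L, sub_batches = 2L,
                         update_passes = 2L, lr = 1e-4, f1_trigger = 0.75,
                         f1_history = 3L, val_batches = 3L, epochs = 1L,
                         lambda1 = 5e-7, lambda2 = 1e-8, f1_threshold = 0.5,
                         seed = 1L) {
  if (batch_size %% sub_batches != 0L)
    stop("batch_size must be divisible by sub_batches")
  structure(list(batch_size = as.integer(batch_size),
                 sub_batches = as.integer(sub_batches),
                 update_passes = as.integer(update_passes),
                 lr = lr, f1_trigger = f1_trigger,
                 f1_history = as.integer(f1_history),
                 val_batches = as.integer(val_batches),
                 epochs = as.integer(epochs),
                 lambda1 = lambda1, lambda2 = lambda2,
                 f1_threshold = f1_threshold, seed = as.integer(seed)),
            class = "train_config")
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 p r / (p + r)`; defined as 0 when both are 0.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return The F1 score.
#' @export
f1_score <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

# Micro-averaged F1 over all (window, class) entries at a probability cut.
micro_f1 <- function(labels, probs, threshold = 0.5) {
  pred <- probs >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1_score(prec, rec)
}

#' Train a model with the alternating sub-mini-batch schedule
#'
#' For every mini-batch the model is first evaluated (F1 at the monitoring
#' threshold) *before* any update, then updated `update_passes` times on each
#' of the `sub_batches` halves alternately (2 x 2 = four updates per
#' mini-batch by default). When the mean of the last three monitoring F1
#' scores exceeds the trigger, the model is tested on the withheld
#' validation mini-batches and checkpointed iff the validation F1 improved.
#' If a holdout dataset is supplied, the delivered model is whichever of the
#' end-of-training model and the best checkpoint has the higher holdout
#' AUPRC (macro mean).
#'
#' @param model A `strand_model` from [build_model()].
#' @param dataset A `window_dataset` (holdout chromosome already excluded).
#' @param cfg A [train_config()].
#' @param holdout Optional `window_dataset` used only to pick the delivered
#'   model.
#' @return List of class `train_result`: `model` (the delivered model),
#'   `end_model`, `checkpoint` (or NULL), `log` (one row per mini-batch:
#'   step, loss, f1), `n_updates`, `best_val_f1`, `delivered`
#'   (`"end"` or `"checkpoint"`), `holdout_auprc`.
#' @export
train <- function(model, dataset, cfg = train_config(), holdout = NULL) {
  n <- nrow(dataset$labels)
  if (n == 0L) stop("empty training dataset")
  state <- adam_init(model$params)
  n_updates <- 0L
  f1_hist <- numeric(0)
  best_val_f1 <- -Inf
  checkpoint <- NULL
  log_rows <- list()
  withr::with_seed(cfg$seed, {
    ord <- sample.int(n)
    nb <- n %/% cfg$batch_size
    if (nb < 1L) stop(sprintf("need at least %d windows for one mini-batch",
                              cfg$batch_size))
    batches <- lapply(seq_len(nb), function(b)
      ord[((b - 1L) * cfg$batch_size + 1L):(b * cfg$batch_size)])
    n_val <- min(cfg$val_batches, max(nb - 1L, 0L))
    val_idx <- if (n_val > 0L) sample.int(nb, n_val) else integer(0)
    val_rows <- unlist(batches[val_idx])
    train_batches <- batches[setdiff(seq_len(nb), val_idx)]
    if (length(train_batches) == 0L) stop("no training mini-batches left")
    step <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ep_order <- if (ep == 1L) seq_along(train_batches)
                  else sample.int(length(train_batches))
      for (bi in ep_order) {
        rows <- train_batches[[bi]]
        Xb <- dataset$inputs[rows, , , drop = FALSE]
        yb <- dataset$labels[rows, , drop = FALSE]
        step <- step + 1L
        # test-before-update monitoring
        fw <- model_forward(model, Xb)
        f1 <- micro_f1(yb, fw$probs, cfg$f1_threshold)
        lo <- bce_loss(yb, fw$logits, model$params, cfg$lambda1,
                       cfg$lambda2, regularize = model$spec$regularize)
        if (!is.finite(lo)) stop(sprintf("non-finite loss at step %d", step))
        f1_hist <- c(f1_hist, f1)
        log_rows[[step]] <- data.frame(step = step, loss = as.numeric(lo),
                                       f1 = f1)
        # alternating sub-mini-batch updates
        half <- cfg$batch_size %/% cfg$sub_batches
        subs <- lapply(seq_len(cfg$sub_batches), function(s)
          rows[((s - 1L) * half + 1L):(s * half)])
        for (pass in seq_len(cfg$update_passes)) {
          for (s in seq_len(cfg$sub_batches)) {
            lg <- model_loss_grads(model,
                                   dataset$inputs[subs[[s]], , , drop = FALSE],
                                   dataset$labels[subs[[s]], , drop = FALSE],
                                   cfg$lambda1, cfg$lambda2)
            upd <- adam_step(model$params, lg$grads, state, lr = cfg$lr)
            model$params <- upd$params
            state <- upd$state
            n_updates <- n_updates + 1L
          }
        }
        # F1-triggered validation checkpointing
        k <- cfg$f1_history
        if (length(f1_hist) >= k &&
            mean(utils::tail(f1_hist, k)) > cfg$f1_trigger &&
            length(val_rows) > 0L) {
          vfw <- model_forward(model,
                               dataset$inputs[val_rows, , , drop = FALSE])
          vf1 <- micro_f1(dataset$labels[val_rows, , drop = FALSE],
                          vfw$probs, cfg$f1_threshold)
          if (vf1 > best_val_f1) {
            best_val_f1 <- vf1
            checkpoint <- model
          }
        }
      }
    }
  })
  res <- list(end_model = model, checkpoint = checkpoint,
              log = do.call(rbind, log_rows), n_updates = n_updates,
              best_val_f1 = if (is.finite(best_val_f1)) best_val_f1 else NA,
              delivered = "end", holdout_auprc = NA_real_)
  res$model <- model
  if (!is.null(holdout)) {
    auprc_of <- function(m) {
      pr <- model_predict(m, holdout$inputs)
      ev <- evaluate(pr$probs, holdout$labels)
      ev$macro_auprc
    }
    a_end <- auprc_of(model)
    res$holdout_auprc <- a_end
    if (!is.null(checkpoint)) {
      a_ck <- auprc_of(checkpoint)
      if (a_ck > a_end) {
        res$model <- checkpoint
        res$delivered <- "checkpoint"
        res$holdout_auprc <- a_ck
      }
    }
  }
  class(res) <- "train_result"
  res
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result> %d mini-batches, %d updates; delivered: %s model\n",
              nrow(x$log), x$n_updates, x$delivered))
  if (!is.na(x$holdout_auprc))
    cat(sprintf("  holdout macro AUPRC %.4f\n", x$holdout_auprc))
  invisible(x)
}

#' Predict class probabilities in mini-batches
#' @param model A `strand_model`.
#' @param X Batch array B x S x 4 (or a single S x 4 window).
#' @param batch_size Forward-pass chunk size (default 100).
#' @return List with `probs` and `logits` (B x classes matrices).
#' @export
model_predict <- function(model, X, batch_size = 100L) {
  bx <- as_batch_array(X)
  B <- dim(bx$x)[1L]
  probs <- matrix(NA_real_, B, model$spec$class_count)
  logits <- matrix(NA_real_, B, model$spec$class_count)
  for (start in seq.int(1L, B, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, B)
    fw <- model_forward(model, bx$x[idx, , , drop = FALSE])
    probs[idx, ] <- fw$probs
    logits[idx, ] <- fw$logits
  }
  list(probs = probs, logits = logits)
}

# Area under the ROC curve by trapezoidal integration over the threshold
# sweep (ties grouped, so tied score runs contribute diagonal segments; an
# all-constant score therefore gives 0.5).
auroc <- function(scores, labels) {
  P <- sum(labels == 1); N <- sum(labels == 0)
  stopifnot(P > 0, N > 0)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / P); fpr <- c(0, fp[last] / N)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Area under the precision-recall curve as average precision (step-wise
# sum of delta-recall times precision, ties grouped by threshold).
auprc <- function(scores, labels) {
  P <- sum(labels == 1)
  stopifnot(P > 0)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y == 1); n_pred <- seq_along(y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp_l <- tp[last]; n_l <- n_pred[last]
  prec <- tp_l / n_l
  dtp <- diff(c(0, tp_l))
  sum(dtp / P * prec)
}

#' Evaluate predictions against labels
#'
#' Per-class AUROC (trapezoidal rule over the ROC threshold sweep) and
#' AUPRC (average precision), macro means over scorable classes, confusion
#' counts at probability 0.5, and the false-positive count at a display
#' threshold. Classes without both a positive and a negative are skipped
#' with a warning.
#'
#' @param probs Predicted probabilities, windows x classes.
#' @param labels 0/1 label matrix of the same shape.
#' @param fp_threshold Threshold for the reported false-positive count
#'   (default 0.2, the display cut used for prediction tracks).
#' @return List of class `eval_report`: `per_class` data.frame (class,
#'   n_pos, auroc, auprc), `macro_auroc`, `macro_auprc`, `confusion`
#'   (tp/fp/fn/tn at 0.5), `fp_count` at `fp_threshold`.
#' @export
evaluate <- function(probs, labels, fp_threshold = 0.2) {
  probs <- as.matrix(probs); labels <- as.matrix(labels)
  stopifnot(all(dim(probs) == dim(labels)))
  C <- ncol(probs)
  cls <- colnames(labels) %||% paste0("class", seq_len(C))
  rows <- lapply(seq_len(C), function(ci) {
    y <- labels[, ci]; s <- probs[, ci]
    if (sum(y == 1) == 0 || sum(y == 0) == 0) {
      warning(sprintf("class %s has no positives or no negatives; skipped",
                      cls[ci]))
      return(data.frame(class = cls[ci], n_pos = sum(y == 1),
                        auroc = NA_real_, auprc = NA_real_))
    }
    data.frame(class = cls[ci], n_pos = sum(y == 1),
               auroc = auroc(s, y), auprc = auprc(s, y))
  })
  per_class <- do.call(rbind, rows)
  pred5 <- probs >= 0.5
  conf <- c(tp = sum(pred5 & labels == 1), fp = sum(pred5 & labels == 0),
            fn = sum(!pred5 & labels == 1), tn = sum(!pred5 & labels == 0))
  structure(list(per_class = per_class,
                 macro_auroc = mean(per_class$auroc, na.rm = TRUE),
                 macro_auprc = mean(per_class$auprc, na.rm = TRUE),
                 confusion = conf,
                 fp_count = sum(probs >= fp_threshold & labels == 0),
                 fp_threshold = fp_threshold),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> macro AUROC %.4f, macro AUPRC %.4f\n",
              x$macro_auroc, x$macro_auprc))
  print(x$per_class, row.names = FALSE)
  cat(sprintf("  false positives at %.2g: %d\n", x$fp_threshold, x$fp_count))
  invisible(x)
}

#' Genome-wide prediction with track output
#'
#' Tiles any FASTA (or pre-loaded genome) into model-sized windows, streams
#' them through the model, and optionally writes one bedGraph track per
#' class plus a BED file of windows whose probability reaches the display
#' threshold. Works on genomes the model never saw (cross-species
#' prediction).
#'
#' @param model A trained `strand_model`.
#' @param genome FASTA path or named character vector of sequences.
#' @param stride Window stride (default half the model window).
#' @param out_prefix If non-NULL, write `<prefix>.<class>.bedGraph` and
#'   `<prefix>.calls.bed`.
#' @param threshold Display threshold for the BED output (default 0.2).
#' @param exclude_chroms Passed to [make_windows()].
#' @return Data frame: chrom, start, end, then one probability column per
#'   class.
#' @export
predict_genome <- function(model, genome, stride = NULL, out_prefix = NULL,
                           threshold = 0.2, exclude_chroms = c("chrM", "MT")) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- load_genome(genome)
  window <- model$spec$window
  stride <- as.integer(stride %||% (window %/% 2L))
  lens <- vapply(genome, nchar, integer(1))
  win <- make_windows(lens, window = window, stride = stride,
                      exclude_chroms = exclude_chroms)
  if (nrow(win) == 0L) stop("no windows fit in the supplied genome")
  n <- nrow(win)
  probs <- matrix(NA_real_, n, model$spec$class_count)
  for (chr in unique(win$chrom)) {
    enc <- encode_sequence(genome[[chr]])
    rows <- which(win$chrom == chr)
    for (start in seq.int(1L, length(rows), by = 100L)) {
      idx <- rows[start:min(start + 99L, length(rows))]
      Xb <- array(0, dim = c(length(idx), window, 4L))
      for (j in seq_along(idx))
        Xb[j, , ] <- enc[(win$start[idx[j]] + 1L):win$end[idx[j]], ,
                         drop = FALSE]
      probs[idx, ] <- model_forward(model, Xb)$probs
    }
  }
  cls <- paste0("class", seq_len(ncol(probs)))
  colnames(probs) <- cls
  out <- cbind(win[, c("chrom", "start", "end")], as.data.frame(probs))
  if (!is.null(out_prefix)) {
    for (ci in seq_along(cls)) {
      path <- sprintf("%s.%s.bedGraph", out_prefix, cls[ci])
      con <- file(path, "w")
      writeLines(sprintf("track type=bedGraph name=%s", cls[ci]), con)
      utils::write.table(data.frame(out$chrom, out$start, out$end,
                                    signif(probs[, ci], 6)),
                         con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      close(con)
    }
    hits <- which(apply(probs, 1L, max) >= threshold)
    bed <- data.frame(out$chrom, out$start, out$end,
                      apply(probs, 1L, function(p)
                        cls[which.max(p)]))[hits, ]
    utils::write.table(bed, sprintf("%s.calls.bed", out_prefix), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  out
}

#' Train with random-initialization restarts
#'
#' Desk-scale motif discovery is sensitive to the random initialization: a
#' sizeable fraction of starts never break out of the constant-prediction
#' plateau (the per-class base rate). Mirroring the common practice of
#' training several replicates and keeping the best, this wrapper trains
#' `restarts` models from independent initializations and returns the one
#' with the highest validation F1 (the withheld validation mini-batches of
#' its own run -- never the holdout, which is reserved for reporting).
#'
#' @param model_builder Function `seed -> strand_model`, e.g.
#'   `function(s) small_frss_model(seed = s)`.
#' @param dataset,cfg,holdout As in [train()]; `cfg$seed` fixes the data
#'   shuffling for every restart, only the initialization seed varies.
#' @param restarts Number of initializations (default 2).
#' @return The selected [train()] result, with `restart_scores` (validation
#'   F1 per restart) and `restart_chosen` added.
#' @export
train_restarts <- function(model_builder, dataset, cfg = train_config(),
                           holdout = NULL, restarts = 2L) {
  stopifnot(restarts >= 1L)
  results <- vector("list", restarts)
  scores <- numeric(restarts)
  for (r in seq_len(restarts)) {
    init_seed <- cfg$seed + 7919L * (r - 1L)
    model <- model_builder(init_seed)
    results[[r]] <- train(model, dataset, cfg, holdout = holdout)
    vf1 <- results[[r]]$best_val_f1
    scores[r] <- if (is.na(vf1)) utils::tail(results[[r]]$log$f1, 1L)
                 else vf1
  }
  best <- which.max(scores)
  out <- results[[best]]
  out$restart_scores <- scores
  out$restart_chosen <- best
  out
}
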