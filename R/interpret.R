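#' Class saliency ("influential values") for a window
#'
#' Computes the gradient of the pre-sigmoid class score `S_i` with respect
#' to the one-hot input, `w = dS_i/dX0`, and reports the per-position
#' influential value `sum_n |w[s, n]|` — a first-order estimate of how much
#' any nucleotide substitution at position s would move the class score,
#' equivalent to (but far cheaper than) in silico saturation mutagenesis.
#' Saliency is always taken on the pre-sigmoid score, never the probability.
#' Windows whose class score falls below `score_cutoff` are flagged as
#' suppressed (the track is returned but marked, mirroring the display rule
#' that removes irrelevant low-scoring sequences).
#'
#' @param model A `strand_model`.
#' @param X0 A single one-hot window (S x 4 matrix).
#' @param class_i Class index (1-based).
#' @param score_cutoff Suppress tracks with `S_i < score_cutoff`
#'   (default -2).
#' @return List of class `saliency_track`: `influence` (length-S vector),
#'   `omega` (the S x 4 gradient), `score` (S_i), `class_i`, `suppressed`.
#' @export
saliency <- function(model, X0, class_i, score_cutoff = -2) {
  stopifnot(is.matrix(X0))
  if (class_i < 1L || class_i > model$spec$class_count)
    stop(sprintf("class index %d outside 1..%d", class_i,
                 model$spec$class_count))
  fw <- model_forward(model, X0, need_cache = TRUE)
  dlog <- matrix(0, 1L, model$spec$class_count)
  dlog[1L, class_i] <- 1
  bk <- model_backward(model, fw, dlog, need_dx = TRUE)
  omega <- matrix(bk$dX[1L, , ], ncol = 4L,
                  dimnames = list(NULL, DNA_CHANNELS))
  score <- fw$logits[1L, class_i]
  structure(list(influence = rowSums(abs(omega)), omega = omega,
                 score = score, class_i = class_i,
                 suppressed = score < score_cutoff),
            class = "saliency_track")
}

#' In silico saturation mutagenesis oracle
#'
#' Brute-force reference for [saliency()]: for every position s and base b,
#' replaces row s of the window with the one-hot of b and reports the change
#' in the pre-sigmoid class score, `Delta S = S_i(mutated) - S_i(X0)`.
#' Substituting the base already present gives exactly 0.
#'
#' @inheritParams saliency
#' @return An S x 4 matrix of score changes (columns A,G,C,T).
#' @export
ism_oracle <- function(model, X0, class_i) {
  stopifnot(is.matrix(X0))
  S <- nrow(X0)
  base_score <- model_forward(model, X0)$logits[1L, class_i]
  delta <- matrix(0, S, 4L, dimnames = list(NULL, DNA_CHANNELS))
  for (s in seq_len(S)) {
    orig <- X0[s, ]
    for (b in seq_len(4L)) {
      row <- numeric(4L); row[b] <- 1
      if (all(row == orig)) next
      X0[s, ] <- row
      delta[s, b] <- model_forward(model, X0)$logits[1L, class_i] - base_score
    }
    X0[s, ] <- orig
  }
  delta
}

#' Activation maximization ("dreaming" an input sequence)
#'
#' Optimizes a free real-valued window X0 (no simplex constraint) to
#' maximize a class objective with an L2 pull toward zero, by Adam ascent
#' on the analytic gradient. X0 is initialized from Normal(0.02, 0.02) —
#' small and slightly positive, which matters for escaping the flat region
#' of the rectifiers. Objectives:
#' \describe{
#'   \item{class-specific}{`yhat_i / sum_{k != i} yhat_k - lambda * ||X0||^2`
#'     (ratio form: maximize class i while holding the other classes down;
#'     with a single class the empty-sum denominator is taken as 1). The
#'     literal product form `yhat_i * sum_{k != i} yhat_k` is available via
#'     `objective = "product"`.}
#'   \item{common}{`prod_i yhat_i - lambda * ||X0||^2` (a sequence all
#'     classes respond to).}
#' }
#' The best-objective iterate is returned, not the last one; the optimizer
#' can wander on this rugged landscape and convergence is not guaranteed.
#'
#' @param model A `strand_model`.
#' @param mode `"class"` (with `class_i`) or `"common"`.
#' @param class_i Target class for class-specific mode.
#' @param lambda L2 penalty coefficient (default 5e-3).
#' @param steps Optimization steps (default 200).
#' @param lr Adam learning rate for the input (default 0.05).
#' @param seed Seed for the initialization.
#' @param objective `"ratio"` (default) or `"product"` for the
#'   class-specific mode.
#' @return List of class `dream_result`: `X0` (optimized window), `trace`
#'   (objective per step), `best_objective`, `sequence` (argmax string
#'   view), `mode`, `lambda`, `seed`.
#' @export
activation_maximization <- function(model, mode = c("class", "common"),
                                    class_i = 1L, lambda = 5e-3,
                                    steps = 200L, lr = 0.05, seed = 1L,
                                    objective = c("ratio", "product")) {
  mode <- match.arg(mode)
  objective <- match.arg(objective)
  S <- model$spec$window
  C <- model$spec$class_count
  X <- withr::with_seed(seed,
         matrix(stats::rnorm(S * 4L, mean = 0.02, sd = 0.02), S, 4L))
  state <- NULL
  best <- list(obj = -Inf, X = X)
  trace <- numeric(steps)
  for (it in seq_len(steps)) {
    fw <- model_forward(model, X, need_cache = TRUE)
    p <- as.numeric(fw$probs[1L, ])
    # objective value and its gradient w.r.t. the probabilities
    if (mode == "class") {
      others <- if (C > 1L) sum(p[-class_i]) else 1
      dp <- numeric(C)
      if (objective == "ratio") {
        val <- p[class_i] / others
        dp[class_i] <- 1 / others
        if (C > 1L) dp[-class_i] <- -p[class_i] / others^2
      } else {
        val <- p[class_i] * others
        dp[class_i] <- others
        if (C > 1L) dp[-class_i] <- p[class_i]
      }
    } else {
      val <- prod(p)
      dp <- vapply(seq_len(C), function(k) prod(p[-k]), numeric(1))
    }
    obj <- val - lambda * sum(X^2)
    if (!is.finite(obj)) stop(sprintf("objective diverged at step %d", it))
    trace[it] <- obj
    if (obj > best$obj) best <- list(obj = obj, X = X)
    dlogits <- matrix(dp * p * (1 - p), nrow = 1L)  # chain through sigmoid
    bk <- model_backward(model, fw, dlogits, need_dx = TRUE)
    grad <- matrix(bk$dX[1L, , ], ncol = 4L) - 2 * lambda * X
    if (is.null(state)) state <- adam_init(list(X = X))
    upd <- adam_step(list(X = X), list(X = -grad), state, lr = lr)
    X <- upd$params$X
    state <- upd$state
  }
  structure(list(X0 = best$X, trace = trace, best_objective = best$obj,
                 sequence = decode_onehot(best$X), mode = mode,
                 class_i = if (mode == "class") class_i else NA_integer_,
                 lambda = lambda, seed = seed),
            class = "dream_result")
}

#' @export
print.dream_result <- function(x, ...) {
  cat(sprintf("<dream_result> mode %s, objective %.4g after %d steps\n",
              x$mode, x$best_objective, length(x$trace)))
  cat(" ", substr(x$sequence, 1L, 60L),
      if (nchar(x$sequence) > 60L) "..." else "", "\n")
  invisible(x)
}

#' Convert first-layer kernels to position probability matrices
#'
#' Each kernel column (position) is mapped to a nucleotide probability
#' vector by a softmax over the four channels, `p[m, n] =
#' exp(w[m, n] / t) / sum_n' exp(w[m, n'] / t)`, and annotated with the
#' per-position information content `IC[m] = 2 + sum_n p log2 p` (bits,
#' in [0, 2]). Motif-logo letter heights are `p * IC`.
#'
#' @param W0 First-layer kernel stack (M x 4 x 1 x K).
#' @param temperature Softmax temperature (default 1).
#' @return List of `pwm` objects, one per kernel: `prob` (M x 4, rows sum
#'   to 1), `ic` (length M), `source`.
#' @export
kernels_to_pwms <- function(W0, temperature = 1) {
  d <- dim(W0)
  stopifnot(length(d) == 4L, d[2L] == 4L)
  lapply(seq_len(d[4L]), function(k) {
    w <- matrix(W0[, , 1L, k], ncol = 4L)
    pwm_from_matrix(exp(w / temperature) / rowSums(exp(w / temperature)),
                    source = sprintf("kernel_%d", k))
  })
}

#' Construct a PWM object from a probability matrix
#' @param prob M x 4 matrix of per-position nucleotide probabilities
#'   (columns A,G,C,T); rows are re-normalized if they drift from 1.
#' @param source Provenance label.
#' @return A `pwm` object with `prob`, `ic` (bits per position), `source`.
#' @export
pwm_from_matrix <- function(prob, source = "pwm") {
  stopifnot(is.matrix(prob), ncol(prob) == 4L, all(prob >= 0))
  prob <- prob / rowSums(prob)
  colnames(prob) <- DNA_CHANNELS
  plogp <- ifelse(prob > 0, prob * log2(prob), 0)
  structure(list(prob = prob, ic = pmin(pmax(2 + rowSums(plogp), 0), 2),
                 source = source), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s: %d positions, total IC %.2f bits, consensus %s\n",
              x$source, nrow(x$prob), sum(x$ic), pwm_consensus(x)))
  invisible(x)
}

#' Consensus string of a PWM (argmax base per position)
#' @param pwm A `pwm` object.
#' @return A DNA string.
#' @export
pwm_consensus <- function(pwm) {
  paste0(DNA_CHANNELS[max.col(pwm$prob, ties.method = "first")],
         collapse = "")
}

#' Reverse complement of a PWM
#' @param pwm A `pwm` object.
#' @return The PWM read off the opposite strand (180-degree rotation of the
#'   probability matrix).
#' @export
pwm_reverse_complement <- function(pwm) {
  pwm_from_matrix(rc180(pwm$prob), source = paste0(pwm$source, "_rc"))
}

#' Write PWMs in MEME minimal motif format
#'
#' Emits a file consumable by the MEME suite (Tomtom, FIMO): version
#' header, ACGT alphabet, and one letter-probability matrix per motif.
#' Note the MEME column order is A,C,G,T, so columns are re-ordered from
#' the package's symmetric A,G,C,T layout on the way out (and back on the
#' way in by [read_meme()]).
#'
#' @param pwms A list of `pwm` objects (or a single one).
#' @param path Output path.
#' @param nsites Pseudo site count written per motif (default 20).
#' @return The path, invisibly.
#' @export
write_meme <- function(pwms, path, nsites = 20L) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (length(pwms) == 0L) stop("empty PWM list")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (pw in pwms) {
    prob <- pw$prob[, c("A", "C", "G", "T"), drop = FALSE]
    drift <- abs(rowSums(prob) - 1)
    if (any(drift > 1e-6)) prob <- prob / rowSums(prob)
    writeLines(sprintf("MOTIF %s", pw$source), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      nrow(prob), nsites), con)
    writeLines(apply(prob, 1L, function(r)
      paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a MEME minimal motif file
#' @param path Path written by [write_meme()] (or any minimal MEME file).
#' @return A list of `pwm` objects (columns back in A,G,C,T order).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  lapply(starts, function(i) {
    name <- sub("^MOTIF +", "", lines[i])
    name <- strsplit(name, " +")[[1L]][1L]
    hdr <- grep("^letter-probability matrix", lines[i:length(lines)])[1L] +
      i - 1L
    w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[hdr]))
    block <- lines[(hdr + 1L):(hdr + w)]
    acgt <- do.call(rbind, lapply(strsplit(trimws(block), " +"), as.numeric))
    prob <- acgt[, c(1L, 3L, 2L, 4L), drop = FALSE]  # ACGT -> AGCT
    pwm_from_matrix(prob, source = name)
  })
}

#' Best match score of a PWM along a sequence
#'
#' Log-probability scan of both strands (the reverse strand via the rotated
#' PWM); used to score recovered and dreamed sequences against a reference
#' motif.
#'
#' @param pwm A `pwm` object.
#' @param seq DNA string, at least as long as the motif.
#' @return List: `score` (best log2 probability), `pos` (1-based offset),
#'   `strand` (`"+"`/`"-"`).
#' @export
pwm_best_match <- function(pwm, seq) {
  onehot <- encode_sequence(seq)
  scan1 <- function(prob) {
    lp <- log2(pmax(prob, 1e-9))
    M <- nrow(lp); L <- nrow(onehot) - M + 1L
    stopifnot(L >= 1L)
    vapply(seq_len(L), function(i)
      sum(onehot[i:(i + M - 1L), ] * lp), numeric(1))
  }
  fwd <- scan1(pwm$prob)
  rev <- scan1(rc180(pwm$prob))
  if (max(fwd) >= max(rev))
    list(score = max(fwd), pos = which.max(fwd), strand = "+")
  else
    list(score = max(rev), pos = which.max(rev), strand = "-")
}

#' Best alignment correlation between two PWMs
#'
#' Pearson correlation over the overlapping columns at the best offset,
#' trying both orientations of `query` (forward and reverse-complement).
#' Used to ask whether a trained first-layer kernel recovered a planted
#' motif.
#'
#' @param query,target `pwm` objects.
#' @param min_overlap Minimum overlapping positions (default 4).
#' @return List: `cor` (best correlation), `offset`, `orientation`
#'   (`"+"`/`"-"`).
#' @export
pwm_align_cor <- function(query, target, min_overlap = 4L) {
  score_orient <- function(q) {
    best <- list(cor = -Inf, offset = NA_integer_)
    nq <- nrow(q$prob); nt <- nrow(target$prob)
    for (off in seq(-(nq - min_overlap), nt - min_overlap)) {
      qi <- max(1L, 1L - off):min(nq, nt - off)
      ti <- qi + off
      if (length(qi) < min_overlap) next
      cc <- suppressWarnings(
        stats::cor(as.vector(q$prob[qi, ]), as.vector(target$prob[ti, ])))
      if (is.finite(cc) && cc > best$cor)
        best <- list(cor = cc, offset = off)
    }
    best
  }
  fwd <- score_orient(query)
  rev <- score_orient(pwm_reverse_complement(query))
  if (fwd$cor >= rev$cor)
    list(cor = fwd$cor, offset = fwd$offset, orientation = "+")
  else
    list(cor = rev$cor, offset = rev$offset, orientation = "-")
}
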