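# A model that is exactly linear in its input on the whole one-hot domain:
# non-negative conv weights keep every rectifier in its active (or
# identically-zero) linear piece, pooling is disabled, and the fc/head
# weights are positive.
linear_model <- function(seed = 97, window = 12L) {
  m <- build_model("conv4", class_count = 1L, window = window, seed = seed,
                   overrides = list(
                     layers = list(list(type = "conv", maps = 2L, kh = 1L,
                                        pool = 1L)),
                     fc_units = 3L))
  withr::with_seed(seed, {
    m$params[["L1.W"]][] <- abs(rnorm(length(m$params[["L1.W"]]), 1, 0.2))
    m$params[["fc.W"]][] <- abs(rnorm(length(m$params[["fc.W"]]), 1, 0.2))
    m$params[["fc.b"]][] <- 0.5
    m$params[["out.W"]][] <- abs(rnorm(length(m$params[["out.W"]]), 1, 0.2))
    m$params[["out.b"]][] <- 0
  })
  m
}

test_that("saliency of a constant-logit model is identically zero", {
  m <- linear_model()
  m$params[["out.W"]][] <- 0
  sal <- saliency(m, encode_sequence(random_dna(12, seed = 101)), 1L)
  expect_true(all(sal$influence == 0))
  expect_true(all(sal$omega == 0))
})

test_that("on a linear model saliency equals the coefficients and ISM the
           coefficient differences", {
  m <- linear_model()
  X0 <- encode_sequence(random_dna(12, seed = 103))
  sal <- saliency(m, X0, 1L)
  delta <- ism_oracle(m, X0, 1L)
  # ISM: Delta[s, b] = c[s, b] - c[s, current base]; substituting the
  # existing base gives exactly zero
  cur <- max.col(X0)
  for (s in seq_len(nrow(X0))) {
    expect_equal(unname(delta[s, cur[s]]), 0)
    for (b in 1:4)
      expect_equal(unname(delta[s, b]),
                   unname(sal$omega[s, b] - sal$omega[s, cur[s]]),
                   tolerance = 1e-8)
  }
  # influential value definition
  expect_equal(sal$influence, rowSums(abs(sal$omega)))
})

test_that("low-scoring windows are suppressed at the -2 display cutoff", {
  m <- linear_model()
  m$params[["out.b"]][] <- -1e3
  sal <- saliency(m, encode_sequence(random_dna(12, seed = 107)), 1L)
  expect_true(sal$suppressed)
  expect_lt(sal$score, -2)
  expect_error(saliency(m, encode_sequence("ACGT"), 5L), "class index")
})

test_that("saliency agrees with the mutagenesis oracle on trained fixtures", {
  tot <- c(0, 0); rank_cors <- numeric(0)
  for (seed in 1:5) {
    tf <- trained_fixture(seed)
    pos <- which(tf$data$labels[, 1] == 1)[1]
    X0 <- matrix(tf$data$inputs[pos, , ], ncol = 4)
    tot <- tot + ism_sign_agreement(tf$model, X0)
    sal <- saliency(tf$model, X0, 1L)
    delta <- ism_oracle(tf$model, X0, 1L)
    if (all(delta == 0)) next
    rank_cors <- c(rank_cors,
                   suppressWarnings(
                     stats::cor(sal$influence, apply(abs(delta), 1, max),
                                method = "spearman")))
  }
  expect_gt(tot[1] / tot[2], 0.8)
  rank_cors <- rank_cors[is.finite(rank_cors)]
  expect_gte(length(rank_cors), 3L)
  expect_gt(stats::median(rank_cors), 0.6)
})

test_that("influential positions of a trained model localize the motif", {
  # the top influential positions of a positive window should fall inside
  # or next to the planted instance in most seeds
  hits <- 0; tried <- 0
  for (seed in 1:5) {
    tf <- trained_fixture(seed)
    if (all(abs(tf$model$params[["out.W"]]) < 1e-6)) next
    pos_rows <- which(tf$data$labels[, 1] == 1)
    pos <- pos_rows[2]
    X0 <- matrix(tf$data$inputs[pos, , ], ncol = 4)
    sal <- saliency(tf$model, X0, 1L)
    if (all(sal$influence == 0)) next
    # locate the planted instance by motif scan
    match <- pwm_best_match(fixture_pwm("nonpal"), decode_onehot(X0))
    span <- (match$pos - 2):(match$pos + 9)
    top5 <- order(sal$influence, decreasing = TRUE)[1:5]
    tried <- tried + 1
    hits <- hits + (sum(top5 %in% span) >= 3)
  }
  expect_gte(tried, 3)
  expect_gte(hits / tried, 0.6)
})

test_that("activation maximization recovers a hand-built detector's motif", {
  # class-0 logit = scaled match score of TAAT via a one-kernel conv and
  # global max pooling
  m <- build_model("conv4", class_count = 1L, window = 30L, seed = 1,
                   overrides = list(
                     layers = list(list(type = "conv", maps = 1L, kh = 4L,
                                        pool = 1L)),
                     fc_units = 1L, global_pool = TRUE))
  m$params[["L1.W"]][, 1L, , 1L] <- 5 * (2 * encode_sequence("TAAT") - 1)
  m$params[["fc.W"]][] <- 1; m$params[["fc.b"]][] <- 0
  m$params[["out.W"]][] <- 1; m$params[["out.b"]][] <- -10
  dr <- activation_maximization(m, mode = "class", class_i = 1L,
                                steps = 150L, lr = 0.1, seed = 5)
  expect_true(grepl("TAAT", dr$sequence))
  expect_equal(dr$mode, "class")
  # accepted-step objective is non-decreasing by construction
  expect_equal(dr$best_objective, max(dr$trace))
  # a dominant penalty shrinks the input below its initialization norm
  init_norm <- sum(withr::with_seed(5,
    matrix(rnorm(30 * 4, 0.02, 0.02), 30, 4))^2)
  dr2 <- activation_maximization(m, mode = "class", class_i = 1L,
                                 lambda = 1e3, steps = 50L, lr = 0.01,
                                 seed = 5)
  expect_lt(sum(dr2$X0^2), init_norm)
})

test_that("the common-mode objective multiplies the class probabilities", {
  m <- tiny_model(seed = 113, window = 30L, class_count = 2L,
                  extra_conv = FALSE)
  dr <- activation_maximization(m, mode = "common", steps = 20L, seed = 7)
  fw <- model_forward(m, dr$X0)
  expect_equal(dr$best_objective,
               prod(fw$probs[1, ]) - 5e-3 * sum(dr$X0^2),
               tolerance = 1e-8)
})

test_that("kernel-to-PWM conversion is a softmax with information content", {
  W <- array(0, dim = c(3L, 4L, 1L, 2L))
  W[1, , 1, 1] <- c(10, 0, 0, 0)      # near-certain A
  W[2, , 1, 1] <- c(1, 1, 1, 1)       # uniform
  pwms <- kernels_to_pwms(W)
  expect_length(pwms, 2L)
  p <- pwms[[1]]
  expect_gt(p$prob[1, "A"], 0.999)
  expect_gt(p$ic[1], 1.98)
  expect_equal(unname(p$prob[2, ]), rep(0.25, 4))
  expect_equal(p$ic[2], 0, tolerance = 1e-12)
  expect_equal(rowSums(p$prob), rep(1, 3), tolerance = 1e-9)
  expect_true(all(p$ic >= 0 & p$ic <= 2))
})

test_that("MEME files round-trip through write and read", {
  pw <- fixture_pwm("nonpal")
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(pw, pwm_reverse_complement(pw)), path)
  lines <- readLines(path)
  expect_match(lines[1], "^MEME version")
  expect_true(any(grepl("^ALPHABET= ACGT", lines)))
  expect_equal(sum(grepl("^MOTIF ", lines)), 2L)
  expect_true(any(grepl("w= 8", lines)))
  back <- read_meme(path)
  expect_lt(max(abs(back[[1]]$prob - pw$prob)), 1e-6)
  expect_lt(max(abs(back[[2]]$prob - pwm_reverse_complement(pw)$prob)), 1e-6)
  expect_error(write_meme(list(), path), "empty")
})

test_that("PWM alignment finds identity and reverse-complement matches", {
  pw <- fixture_pwm("nonpal")
  expect_equal(pwm_align_cor(pw, pw)$cor, 1, tolerance = 1e-12)
  rc <- pwm_reverse_complement(pw)
  hit <- pwm_align_cor(rc, pw)
  expect_equal(hit$cor, 1, tolerance = 1e-12)
  expect_equal(hit$orientation, "-")
  # best-match scanning reports position and strand
  seqc <- paste0("ACGTACGTAC", pwm_consensus(pw), "GTACGT")
  m1 <- pwm_best_match(pw, seqc)
  expect_equal(m1$pos, 11L)
  expect_equal(m1$strand, "+")
  m2 <- pwm_best_match(pw, reverse_complement(seqc))
  expect_equal(m2$strand, "-")
  expect_equal(m2$score, m1$score, tolerance = 1e-9)
})
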