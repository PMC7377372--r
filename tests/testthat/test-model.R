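test_that("VALID cross-correlation matches the triple-loop oracle", {
  withr::with_seed(1, {
    for (rep in 1:5) {
      M <- sample(3:9, 1); K <- sample(1:4, 1); S <- sample(20:50, 1)
      W <- array(rnorm(M * 4 * K), dim = c(M, 4L, 1L, K))
      X <- encode_sequence(random_dna(S))
      expect_lt(max(abs(corr_valid(W, X) - corr_oracle(W, X))), 1e-6)
    }
  })
  # shape arithmetic: 1000-bp window, kernel height 9 -> 992 positions
  W <- array(0, dim = c(9L, 4L, 1L, 2L))
  X <- encode_sequence(random_dna(1000, seed = 2))
  expect_equal(nrow(corr_valid(W, X)), 992L)
  # a kernel written as the one-hot of a sequence scores its own sequence
  # with a maximum response of 8 at offset 0
  W <- array(0, dim = c(8L, 4L, 1L, 1L))
  W[, , 1L, 1L] <- encode_sequence("AGCTAAAG")
  out <- corr_valid(W, encode_sequence("AGCTAAAG"))
  expect_equal(out[1, 1], 8)
  expect_equal(dim(out), c(1L, 1L))
  # shape errors name both operands
  expect_error(corr_valid(W, encode_sequence("ACGT")), "shorter")
  expect_error(corr_valid(array(0, c(3, 2, 1, 1)), encode_sequence("ACGTACGT")),
               "mismatch")
})

test_that("kernel rotation is the reverse-complement view and an involution", {
  withr::with_seed(3, {
    W <- array(rnorm(9 * 4 * 2 * 5), dim = c(9L, 4L, 2L, 5L))
    expect_equal(rotate_kernels(rotate_kernels(W)), W)
    # explicit index check of [W'rc]_{m,n,h,k} = w_{(M-1-m),(N-1-n),h,k}
    Wr <- rotate_kernels(W)
    expect_equal(Wr[1, 1, 2, 3], W[9, 4, 2, 3])
    expect_equal(Wr[3, 2, 1, 4], W[7, 3, 1, 4])
  })
  # one-hot kernel of AGCTAAAG rotates to the one-hot of its reverse
  # complement CTTTAGCT
  W <- array(0, dim = c(8L, 4L, 1L, 1L))
  W[, , 1L, 1L] <- encode_sequence("AGCTAAAG")
  expect_equal(rotate_kernels(W)[, , 1L, 1L],
               unname(encode_sequence("CTTTAGCT")))
  # width-1 kernels rotate along position only
  W2 <- array(seq_len(6), dim = c(6L, 1L, 1L, 1L))
  expect_equal(as.vector(rotate_kernels(W2)), 6:1)
  # rotation identity: corr(rot(W), X)[i] == corr(W, rc180(X))[S-M-i]
  withr::with_seed(5, {
    for (rep in 1:5) {
      M <- sample(3:9, 1); S <- sample(20:40, 1)
      W <- array(rnorm(M * 4 * 3), dim = c(M, 4L, 1L, 3L))
      X <- encode_sequence(random_dna(S))
      a <- corr_valid(rotate_kernels(W), X)
      b <- corr_valid(W, rc180(X))
      expect_lt(max(abs(a - b[nrow(b):1, , drop = FALSE])), 1e-9)
    }
  })
})

test_that("the FRSS block computes the documented shape chain", {
  withr::with_seed(7, {
    W0 <- array(rnorm(9 * 4 * 16), dim = c(9L, 4L, 1L, 16L))
    W1 <- array(rnorm(8 * 16 * 16), dim = c(8L, 1L, 16L, 16L))
    blk <- frss_block(W0, W1, pool = 2L)
    X <- encode_sequence(random_dna(1000))
    out <- suppressMessages(frss_forward(blk, X))
    # 1000 -> 992 -> 496 -> 489 -> 244 (odd length floor-dropped)
    expect_equal(dim(out), c(244L, 16L))
    # all-zero weights give an all-zero output
    z <- frss_block(W0 * 0, W1 * 0, pool = 2L)
    expect_true(all(suppressMessages(frss_forward(z, X)) == 0))
  })
})

test_that("figure mode is reverse-complement equivariant, literal mode is not", {
  withr::with_seed(9, {
    # lengths chosen so every pooling input is even: 100 -> 92 -> 46 -> 40 -> 20
    W0 <- array(rnorm(9 * 4 * 5), dim = c(9L, 4L, 1L, 5L))
    W1 <- array(rnorm(7 * 5 * 6), dim = c(7L, 1L, 5L, 6L))
    fig <- frss_block(W0, W1, pool = 2L, mode = "figure")
    lit <- frss_block(W0, W1, pool = 2L, mode = "literal")
    worst <- 0
    for (rep in 1:10) {
      X <- encode_sequence(random_dna(100))
      f <- frss_forward(fig, X)
      fr <- frss_forward(fig, rc180(X))
      worst <- max(worst, max(abs(fr - f[nrow(f):1, , drop = FALSE])))
    }
    expect_lt(worst, 1e-6)
    # crafted input demonstrating the literal-mode violation
    X <- encode_sequence(paste0(strrep("A", 40), "AGGTCATC",
                                strrep("C", 52)))
    l <- frss_forward(lit, X)
    lr <- frss_forward(lit, rc180(X))
    expect_gt(max(abs(lr - l[nrow(l):1, , drop = FALSE])), 1e-3)
  })
})

test_that("architectures build with valid shapes and seeded weights", {
  for (name in c("conv4-FRSS", "conv3-FRSS", "conv4", "conv4-nonFRSS",
                 "deepsea-type")) {
    m <- build_model(name, class_count = 3L, window = 1000L, seed = 42)
    X <- random_onehot_batch(2L, 1000L, seed = 17)
    fw <- suppressMessages(model_forward(m, X))
    expect_equal(dim(fw$probs), c(2L, 3L))
    expect_true(all(fw$probs > 0 & fw$probs < 1))
  }
  # same seed, same name -> bitwise-identical weights
  a <- build_model("conv4-FRSS", 2L, seed = 9)
  b <- build_model("conv4-FRSS", 2L, seed = 9)
  expect_identical(a$params, b$params)
  # first layer emits 320 feature maps by default
  expect_equal(dim(a$params[["L1.W0"]])[4L], 320L)
  # tying removes the rotated copies from the trainable set
  nf <- build_model("conv4-nonFRSS", 2L, seed = 9)
  expect_gt(n_parameters(nf), n_parameters(a))
  expect_equal(n_parameters(nf) - n_parameters(a),
               length(nf$params[["L1.W0b"]]) + length(nf$params[["L1.W1b"]]))
  expect_error(build_model("convnet-9000", 2L), "one of")
})

test_that("the loss is clipped cross-entropy plus the stated penalties", {
  y <- matrix(c(1, 0, 0, 1), 2, 2)
  # logits 0 -> probabilities 0.5 -> cross-entropy ln 2
  l <- bce_loss(y, matrix(0, 2, 2), params = NULL)
  expect_equal(as.numeric(l), log(2), tolerance = 1e-12)
  # near-correct hard predictions leave only the penalties
  big <- matrix(c(30, -30, -30, 30), 2, 2)
  l2 <- bce_loss(y, big, params = list(w = c(1, 2)), lambda1 = 5e-7,
                 lambda2 = 1e-8)
  comps <- attr(l2, "components")
  expect_lt(comps["bce"], 1e-7)  # 2*eps-order after clipping
  expect_equal(unname(comps["l2"]), 5e-7 * 5)
  expect_equal(unname(comps["l1"]), 1e-8 * 120)
  # independent scalar computation on a hand-set 2-class case
  yy <- matrix(c(1, 0), 1, 2)
  lg <- matrix(c(0.3, -1.2), 1, 2)
  p <- 1 / (1 + exp(-lg))
  manual <- -mean(yy * log(p) + (1 - yy) * log(1 - p)) +
    5e-7 * sum(lg^2 * 0) + 1e-8 * sum(abs(lg))
  expect_equal(as.numeric(bce_loss(yy, lg)), manual, tolerance = 1e-10)
  expect_error(bce_loss(matrix(2, 1, 1), matrix(0, 1, 1)), "labels")
})

test_that("analytic gradients match central finite differences", {
  for (tied in c(TRUE, FALSE)) {
    m <- tiny_model(seed = if (tied) 7 else 13, tied = tied)
    X <- random_onehot_batch(2L, 40L, seed = 23)
    y <- matrix(c(1, 0, 0, 1), 2, 2)
    lg <- strandscan:::model_loss_grads(m, X, y)
    eps <- 1e-5
    withr::with_seed(29, {
      for (nm in names(m$params)) {
        idx <- sample(length(m$params[[nm]]), min(4, length(m$params[[nm]])))
        for (j in idx) {
          mp <- m; mp$params[[nm]][j] <- m$params[[nm]][j] + eps
          mm <- m; mm$params[[nm]][j] <- m$params[[nm]][j] - eps
          num <- (strandscan:::model_loss_grads(mp, X, y)$loss -
                  strandscan:::model_loss_grads(mm, X, y)$loss) / (2 * eps)
          an <- lg$grads[[nm]][j]
          expect_lt(abs(num - an) / max(1e-4, abs(num) + abs(an)), 1e-4)
        }
      }
    })
  }
})

test_that("tied rotated streams never drift from the forward kernels", {
  # after several optimizer updates the reverse-stream response must still
  # equal the cross-correlation with rotate_kernels() of the current W0
  m <- tiny_model(seed = 31, extra_conv = FALSE)
  X <- random_onehot_batch(4L, 40L, seed = 37)
  y <- matrix(rbinom(8, 1, 0.5), 4, 2)
  st <- strandscan:::adam_init(m$params)
  for (i in 1:5) {
    lg <- strandscan:::model_loss_grads(m, X, y)
    up <- strandscan:::adam_step(m$params, lg$grads, st, lr = 1e-2)
    m$params <- up$params; st <- up$state
  }
  expect_null(m$params[["L1.W0b"]])  # no independent rotated copy exists
  W0 <- m$params[["L1.W0"]]
  x1 <- encode_sequence(random_dna(40, seed = 41))
  rot_response <- corr_valid(rotate_kernels(W0), x1)
  # recompute what the model's reverse stream sees
  direct <- corr_valid(W0, rc180(x1))
  expect_lt(max(abs(rot_response - direct[nrow(direct):1, , drop = FALSE])),
            1e-9)
})
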