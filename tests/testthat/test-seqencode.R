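test_that("one-hot encoding follows the symmetric A,G,C,T layout", {
  expect_equal(unname(encode_sequence("AGCT")), diag(4))
  expect_equal(unname(encode_sequence("N")), matrix(0, 1, 4))
  expect_equal(unname(encode_sequence("agct")), diag(4))  # case-insensitive
  # unrecognized symbols behave like N
  expect_equal(unname(encode_sequence("X")[1, ]), rep(0, 4))
  expect_error(encode_sequence(""), "empty")
  # every row sums to 0 (N) or 1
  m <- encode_sequence("ACGTNNACGT")
  expect_true(all(rowSums(m) %in% c(0, 1)))
})

test_that("rc180 is the reverse complement in matrix form", {
  expect_equal(rc180(encode_sequence("AGCTAAAG")),
               encode_sequence("CTTTAGCT"), ignore_attr = TRUE)
  expect_equal(rc180(encode_sequence("A")), encode_sequence("T"),
               ignore_attr = TRUE)
  expect_equal(rc180(matrix(0, 5, 4)), matrix(0, 5, 4), ignore_attr = TRUE)
  # involution and string-level agreement, fuzzed
  withr::with_seed(11, {
    for (i in 1:20) {
      s <- random_dna(sample(5:60, 1))
      x <- encode_sequence(s)
      expect_equal(rc180(rc180(x)), x)
      expect_equal(rc180(x), encode_sequence(reverse_complement(s)),
                   ignore_attr = TRUE)
    }
  })
})

test_that("decode_onehot inverts encoding and flags N rows", {
  expect_equal(decode_onehot(encode_sequence("AGGTCNTC")), "AGGTCNTC")
})

test_that("window tiling drops partial windows and respects the stride", {
  w <- make_windows(c(chr1 = 3000L), window = 1000L, stride = 500L)
  expect_equal(w$start, seq(0L, 2000L, by = 500L))
  expect_equal(nrow(w), 5L)
  expect_equal(nrow(make_windows(c(chr1 = 999L), window = 1000L)), 0L)
  expect_equal(nrow(make_windows(c(chr1 = 1000L), window = 1000L,
                                 stride = 1L)), 1L)
  expect_error(make_windows(c(chr1 = 5000L), stride = 0L), "stride")
  # count formula and exact tiling at stride == window
  withr::with_seed(4, {
    for (i in 1:10) {
      L <- sample(500:5000, 1); win <- sample(100:600, 1)
      w <- make_windows(c(c1 = L), window = win, stride = win)
      expect_equal(nrow(w), L %/% win)
      if (nrow(w) > 0) {
        expect_equal(w$start, seq(0L, by = win, length.out = nrow(w)))
        expect_equal(max(w$end), (L %/% win) * win)
      }
    }
  })
  # mitochondrial names excluded by default
  w <- make_windows(c(chr1 = 2000L, chrM = 2000L))
  expect_false("chrM" %in% w$chrom)
})

test_that("window labels are summit containment, half-open", {
  w <- data.frame(chrom = "chr1", start = 1000L, end = 2000L, index = 1L)
  in_peak <- peak_set("chr1", 1100L, 1400L, 100L, "a")     # summit 1200
  at_999 <- peak_set("chr1", 900L, 1100L, 99L, "b")        # summit 999
  at_end <- peak_set("chr1", 1900L, 2100L, 100L, "c")      # summit 2000
  lab <- label_windows(w, list(in_peak, at_999, at_end))
  expect_equal(unname(lab[1, ]), c(1L, 0L, 0L))
  # two summits in one window still give 1
  two <- peak_set("chr1", c(1100L, 1500L), c(1300L, 1700L), c(100L, 100L),
                  "d")
  expect_equal(unname(label_windows(w, list(two))[1, 1]), 1L)
  # unknown chromosome warns and is skipped
  expect_warning(
    lab2 <- label_windows(w, list(peak_set("chrX", 10L, 50L, 20L, "e"))),
    "unknown")
  expect_equal(sum(lab2), 0L)
})

test_that("label matrix equals the brute-force double loop", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      w <- make_windows(c(c1 = 6000L, c2 = 4000L), window = 1000L,
                        stride = 500L)
      ps <- lapply(1:3, function(ci) {
        n <- sample(3:12, 1)
        chrom <- sample(c("c1", "c2"), n, replace = TRUE)
        start <- sapply(chrom, function(ch)
          sample(0:(if (ch == "c1") 5800 else 3800), 1))
        peak_set(chrom, start, start + 100L, sample(0:99, n, replace = TRUE),
                 paste0("cl", ci))
      })
      lab <- label_windows(w, ps)
      brute <- matrix(0L, nrow(w), 3L)
      for (wi in seq_len(nrow(w))) for (ci in 1:3) {
        s <- peak_summits(ps[[ci]])
        for (si in seq_len(nrow(s)))
          if (s$chrom[si] == w$chrom[wi] && s$pos[si] >= w$start[wi] &&
              s$pos[si] < w$end[wi])
            brute[wi, ci] <- 1L
      }
      expect_equal(unname(lab), brute)
      expect_equal(sum(lab), sum(brute))
    }
  })
})

test_that("negative downsampling is seeded, binomial, and spares positives", {
  n <- 10000L
  ds <- list(inputs = array(0, dim = c(n, 4L, 4L)),
             labels = matrix(0L, n, 1L),
             windows = data.frame(chrom = "c1", start = seq_len(n),
                                  end = seq_len(n) + 4L, index = seq_len(n)))
  class(ds) <- "window_dataset"
  ds$labels[1:100, 1] <- 1L  # positives
  kept <- downsample_negatives(ds, 0.25, seed = 5)
  n_neg_kept <- sum(kept$labels == 0)
  ci <- qnorm(0.995) * sqrt(9900 * 0.25 * 0.75)
  expect_gt(n_neg_kept, 9900 * 0.25 - ci)
  expect_lt(n_neg_kept, 9900 * 0.25 + ci)
  expect_equal(sum(kept$labels), 100L)            # positives untouched
  expect_false(is.unsorted(kept$windows$index))   # order preserved
  # identity at fraction 1, determinism at fixed seed
  expect_equal(nrow(downsample_negatives(ds, 1, seed = 5)$labels), n)
  again <- downsample_negatives(ds, 0.25, seed = 5)
  expect_equal(kept$windows$index, again$windows$index)
})

test_that("low-peak classes are excluded at the >= threshold", {
  ps <- list(peak_set("c", 0L, 100L, 50L, "big"),
             peak_set("c", rep(0L, 2), rep(100L, 2), rep(50L, 2), "small"))
  ps[[1]]$peak_count <- 12000L
  ps[[2]]$peak_count <- 9999L
  ps3 <- peak_set("c", 0L, 100L, 50L, "edge"); ps3$peak_count <- 10000L
  expect_message(out <- filter_low_peak_classes(c(ps, list(ps3))),
                 "excluding")
  expect_equal(vapply(out, function(p) p$source_id, ""), c("big", "edge"))
  expect_length(filter_low_peak_classes(ps, min_peaks = 0L), 2L)
  expect_error(filter_low_peak_classes(ps, min_peaks = 1e6), "fewer")
})

test_that("narrowPeak files round-trip and summits drive labels", {
  pk <- peak_set("chrS1", c(100L, 900L), c(400L, 1200L), c(150L, 100L),
                 "demo")
  path <- withr::local_tempfile(fileext = ".narrowPeak")
  write_narrowpeak(pk, path)
  back <- read_narrowpeak(path)
  expect_equal(back$records, pk$records)
  expect_equal(back$peak_count, 2L)
})

test_that("build_dataset wires windows, encoding and labels together", {
  withr::with_seed(31, {
    genome <- c(cA = random_dna(5000), cB = random_dna(3000))
    pk <- peak_set("cA", 1200L, 1500L, 150L, "m")  # summit 1350
    ds <- build_dataset(genome, pk, window = 1000L, stride = 500L)
    expect_s3_class(ds, "window_dataset")
    expect_equal(dim(ds$inputs), c(nrow(ds$windows), 1000L, 4L))
    # the labelled windows are exactly those containing position 1350
    pos <- which(ds$labels[, 1] == 1)
    expect_true(all(ds$windows$chrom[pos] == "cA"))
    expect_true(all(ds$windows$start[pos] <= 1350 &
                    ds$windows$end[pos] > 1350))
    expect_equal(length(pos), 2L)  # stride 500: two windows cover any locus
    # window content matches the sequence
    i <- pos[1]
    expect_equal(ds$inputs[i, , ],
                 unname(encode_sequence(substr(genome[["cA"]],
                                               ds$windows$start[i] + 1,
                                               ds$windows$end[i]))))
    # holdout split separates chromosomes
    sp <- split_holdout(ds, "cB")
    expect_true(all(sp$train$windows$chrom == "cA"))
    expect_true(all(sp$holdout$windows$chrom == "cB"))
    expect_error(split_holdout(ds, "nope"), "holdout")
  })
})
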