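# Ground-truthed synthetic data: a small multi-chromosome genome with motif
# instances planted on random strands from a stated PWM, peak files whose
# summits mark the planted instances, and read sets with a controllable
# in-peak fraction. Every module in the package is testable against these
# with no external download.

#' Named fixture PWMs
#'
#' `fixture_pwm("nonpal")` is an 8-bp non-palindromic motif (consensus
#' AGGTCATC), the default planted signal for strand-randomized benchmarks:
#' because its reverse complement is a different string, only a
#' strand-aware model sees both orientations with one set of kernels.
#' `fixture_pwm("pal")` is an 8-bp palindromic motif (consensus TGACGTCA,
#' equal to its own reverse complement), the motivating case of dimeric
#' transcription-factor binding.
#'
#' @param which `"nonpal"` (default) or `"pal"`.
#' @param strength Probability mass on the consensus base per position
#'   (default 0.99, about 1.9 bits per position -- the information
#'   content of a strong, CTCF-like binding motif; at substantially lower
#'   strength mismatched instances fall below the best chance 8-mer match
#'   of a 1-kb window, so even an ideal matched filter cannot separate the classes).
#' @return A `pwm` object.
#' @export
fixture_pwm <- function(which = c("nonpal", "pal"), strength = 0.99) {
  which <- match.arg(which)
  consensus <- switch(which, nonpal = "AGGTCATC", pal = "TGACGTCA")
  bases <- strsplit(consensus, "")[[1L]]
  prob <- matrix((1 - strength) / 3, nrow = length(bases), ncol = 4L,
                 dimnames = list(NULL, DNA_CHANNELS))
  prob[cbind(seq_along(bases), match(bases, DNA_CHANNELS))] <- strength
  pwm_from_matrix(prob, source = paste0("fixture_", which))
}

#' Specification of a synthetic benchmark genome
#'
#' The defaults are the package's reference study conditions, reused by the
#' test-suite and the acceptance script: a two-chromosome ~400-kb genome
#' (300 kb for training, 100 kb held out), uniform base composition, one
#' 8-bp non-palindromic PWM planted on random strands at 0.5 instances per
#' kb, 150-bp peak half-width, and 20,000 100-bp reads of which half are
#' sampled inside peaks.
#'
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param composition Background base probabilities, named A,G,C,T.
#' @param motifs List of planting instructions: each a list with `pwm` (a
#'   `pwm` object), `rate` (expected instances per bp), `strand`
#'   (`"random"` or `"forward"`), `class` (label/class name).
#' @param peak_half_width Half-width of the peak drawn around each planted
#'   instance center (bp).
#' @param read_length,n_reads,p_in_peak Read model for [generate_reads()].
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(chrom_lengths = c(chrS1 = 300000L,
                                             chrS2 = 100000L),
                           composition = c(A = 0.25, G = 0.25, C = 0.25,
                                           T = 0.25),
                           motifs = list(list(pwm = fixture_pwm("nonpal"),
                                              rate = 5e-4,
                                              strand = "random",
                                              class = "planted")),
                           peak_half_width = 150L, read_length = 100L,
                           n_reads = 20000L, p_in_peak = 0.5, seed = 1L) {
  stopifnot(abs(sum(composition) - 1) < 1e-9, all(composition >= 0),
            p_in_peak >= 0, p_in_peak <= 1)
  for (m in motifs) {
    exp_per_window <- m$rate * 1000
    if (exp_per_window > 1)
      warning(sprintf("planting rate %.3g gives > 1 expected instance per kb window",
                      m$rate))
    stopifnot(m$strand %in% c("random", "forward"))
  }
  structure(list(chrom_lengths = chrom_lengths,
                 composition = composition[DNA_CHANNELS],
                 motifs = motifs,
                 peak_half_width = as.integer(peak_half_width),
                 read_length = as.integer(read_length),
                 n_reads = as.integer(n_reads), p_in_peak = p_in_peak,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Sample one motif instance string from a PWM.
sample_motif_instance <- function(pwm) {
  paste0(apply(pwm$prob, 1L, function(p) sample(DNA_CHANNELS, 1L, prob = p)),
         collapse = "")
}

#' Generate a synthetic genome with planted motif instances
#'
#' Background bases are drawn i.i.d. from the spec composition; for each
#' motif the number of instances per chromosome is Poisson with mean
#' `rate * length`, each instance is sampled from its PWM, reverse
#' complemented with probability 0.5 under strand policy `"random"`, and
#' written into the sequence at a non-overlapping position (collisions are
#' resampled with bounded retries). Everything is deterministic given the
#' spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_genome`: `genome` (named character
#'   vector), `truth` (data.frame: chrom, start, end, center, strand,
#'   class), `spec`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    genome <- vapply(names(spec$chrom_lengths), function(chr) {
      paste0(sample(DNA_CHANNELS, spec$chrom_lengths[[chr]], replace = TRUE,
                    prob = spec$composition), collapse = "")
    }, character(1))
    truth <- list()
    for (mi in seq_along(spec$motifs)) {
      m <- spec$motifs[[mi]]
      len <- nrow(m$pwm$prob)
      for (chr in names(genome)) {
        L <- spec$chrom_lengths[[chr]]
        n_inst <- stats::rpois(1L, m$rate * L)
        if (n_inst == 0L) next
        placed <- integer(0)
        for (i in seq_len(n_inst)) {
          ok <- FALSE
          for (try in 1:100) {
            pos <- sample.int(L - len + 1L, 1L) - 1L  # 0-based start
            if (all(abs(pos - placed) >= len)) { ok <- TRUE; break }
          }
          if (!ok) stop("could not place motif instance without collision")
          placed <- c(placed, pos)
          inst <- sample_motif_instance(m$pwm)
          strand <- "+"
          if (m$strand == "random" && stats::runif(1) < 0.5) {
            inst <- reverse_complement(inst)
            strand <- "-"
          }
          substr(genome[[chr]], pos + 1L, pos + len) <- inst
          truth[[length(truth) + 1L]] <-
            data.frame(chrom = chr, start = pos, end = pos + len,
                       center = pos + len %/% 2L, strand = strand,
                       class = m$class, stringsAsFactors = FALSE)
        }
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth)
             else data.frame(chrom = character(), start = integer(),
                             end = integer(), center = integer(),
                             strand = character(), class = character(),
                             stringsAsFactors = FALSE)
    structure(list(genome = genome, truth = truth, spec = spec),
              class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %d chromosome(s), %s bp, %d planted instance(s)\n",
              length(x$genome),
              format(sum(nchar(x$genome)), big.mark = ","), nrow(x$truth)))
  invisible(x)
}

#' Write a synthetic genome as FASTA
#' @param sg A `synthetic_genome` (or named character vector).
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_genome_fasta <- function(sg, path) {
  seqs <- if (inherits(sg, "synthetic_genome")) sg$genome else sg
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Turn a truth table into per-class peak sets
#'
#' One peak per planted instance, centred on the instance: interval
#' `[center - half_width, center + half_width)` with the summit offset at
#' `half_width` (i.e. the summit is the instance center). Overlapping peaks
#' of the same class are merged, keeping the summit of the first.
#'
#' @param truth Truth data.frame from [generate_genome()].
#' @param half_width Peak half-width (bp).
#' @return Named list of [peak_set()] objects, one per class.
#' @export
truth_to_peaks <- function(truth, half_width = 150L) {
  if (nrow(truth) == 0L) stop("truth table is empty")
  half_width <- as.integer(half_width)
  out <- lapply(split(truth, truth$class), function(tt) {
    tt <- tt[order(tt$chrom, tt$center), , drop = FALSE]
    start <- pmax(tt$center - half_width, 0L)
    end <- tt$center + half_width
    summit <- tt$center
    # merge overlapping peaks, keeping the first summit of each run
    keep_s <- integer(0); keep_e <- integer(0); keep_sum <- integer(0)
    keep_chr <- character(0)
    for (i in seq_len(nrow(tt))) {
      k <- length(keep_s)
      if (k > 0L && tt$chrom[i] == keep_chr[k] && start[i] < keep_e[k]) {
        keep_e[k] <- max(keep_e[k], end[i])
      } else {
        keep_s <- c(keep_s, start[i]); keep_e <- c(keep_e, end[i])
        keep_sum <- c(keep_sum, summit[i])
        keep_chr <- c(keep_chr, tt$chrom[i])
      }
    }
    peak_set(keep_chr, keep_s, keep_e, keep_sum - keep_s,
             source_id = tt$class[1L])
  })
  out[unique(truth$class)]
}

#' Generate a synthetic read set with a controlled in-peak fraction
#'
#' Each read is placed inside a uniformly chosen peak with probability
#' `p_in_peak`, otherwise uniformly on the genome, so the expected FRiP is
#' analytically `p + (1 - p) * peak_bases / genome_bases` up to edge
#' effects. Exercises the QC module end to end.
#'
#' @param genome_sizes Named chromosome lengths (bp).
#' @param peaks A [peak_set()].
#' @param read_length Read length (bp).
#' @param n_reads Number of reads.
#' @param p_in_peak Probability a read is sampled inside a peak.
#' @param seed Integer seed.
#' @return A [read_set()] with attribute `expected_frip`.
#' @export
generate_reads <- function(genome_sizes, peaks, read_length = 100L,
                           n_reads = 20000L, p_in_peak = 0.5, seed = 1L) {
  stopifnot(p_in_peak >= 0, p_in_peak <= 1, n_reads > 0L)
  rec <- peaks$records
  withr::with_seed(seed, {
    in_peak <- stats::runif(n_reads) < p_in_peak
    chrom <- character(n_reads); start <- integer(n_reads)
    n_in <- sum(in_peak)
    if (n_in > 0L && nrow(rec) > 0L) {
      pk <- sample.int(nrow(rec), n_in, replace = TRUE)
      lo <- rec$start[pk]
      hi <- pmax(rec$end[pk] - read_length, lo)
      start[in_peak] <- lo + floor(stats::runif(n_in) * (hi - lo + 1L))
      chrom[in_peak] <- rec$chrom[pk]
    } else {
      in_peak[] <- FALSE
    }
    n_out <- sum(!in_peak)
    if (n_out > 0L) {
      pr <- genome_sizes / sum(genome_sizes)
      chr <- sample(names(genome_sizes), n_out, replace = TRUE, prob = pr)
      hi <- pmax(genome_sizes[chr] - read_length, 0L)
      start[!in_peak] <- floor(stats::runif(n_out) * (hi + 1L))
      chrom[!in_peak] <- chr
    }
    rs <- read_set(chrom, start, start + read_length, source_id = "synthetic")
  })
  peak_bases <- sum(rec$end - rec$start)
  attr(rs, "expected_frip") <- p_in_peak +
    (1 - p_in_peak) * peak_bases / sum(as.numeric(genome_sizes))
  rs
}

#' Build the reference planted-motif benchmark
#'
#' Runs the full synthetic pipeline under one seed: generate the genome,
#' derive peaks from the truth table, window/encode/label, downsample
#' negatives, and split off the holdout chromosome. This is the fixture the
#' motif-recovery and FRSS-benefit benchmarks run on.
#'
#' @param spec A [synthetic_spec()]; its seed drives everything.
#' @param window,stride Window scheme (defaults 1000/500).
#' @param neg_fraction Negative downsampling fraction (default 0.25).
#' @param holdout_chrom Held-out chromosome name (default the spec's last
#'   chromosome).
#' @return List: `train`, `holdout` (window datasets), `genome` (the
#'   `synthetic_genome`), `peaks`.
#' @export
synthetic_benchmark <- function(spec = synthetic_spec(), window = 1000L,
                                stride = 500L, neg_fraction = 0.25,
                                holdout_chrom = NULL) {
  sg <- generate_genome(spec)
  peaks <- truth_to_peaks(sg$truth, spec$peak_half_width)
  ds <- build_dataset(sg$genome, peaks, window = window, stride = stride)
  holdout_chrom <- holdout_chrom %||%
    utils::tail(names(spec$chrom_lengths), 1L)
  sp <- split_holdout(ds, holdout_chrom)
  sp$train <- downsample_negatives(sp$train, neg_fraction,
                                   seed = spec$seed + 1L)
  list(train = sp$train, holdout = sp$holdout, genome = sg, peaks = peaks)
}

#' Small FRSS model for benchmarks
#'
#' A two-layer FRSS block (16/16 maps, kernel heights 9/8, pool 2), global
#' max pooling over positions, a 16-unit fully-connected layer and a
#' sigmoid head — small enough to train on a laptop CPU in seconds, and the
#' reference model for the planted-motif benchmarks. The global pooling
#' reduces each feature map to "was this pattern seen anywhere in the
#' window", the right inductive bias for motif detection at desk scale
#' (per-position fully-connected weights would memorize a benchmark-sized
#' training set long before the kernels learn anything). `tied = FALSE`
#' gives the untied ablation (independent second-stream kernels, same
#' shapes).
#'
#' @param class_count Number of classes (default 1).
#' @param window Window size (default 1000).
#' @param seed Initialization seed.
#' @param tied Tie the rotated stream to the forward kernels (default TRUE).
#' @param maps Map counts of the two FRSS layers (default c(16, 16)).
#' @return A `strand_model`.
#' @export
small_frss_model <- function(class_count = 1L, window = 1000L, seed = 1L,
                             tied = TRUE, maps = c(16L, 16L)) {
  build_model(if (tied) "conv4-FRSS" else "conv4-nonFRSS", class_count,
              window = window, seed = seed,
              overrides = list(
                layers = list(list(type = "frss", maps = as.integer(maps),
                                   kh = c(9L, 8L), pool = 2L,
                                   tied = tied)),
                fc_units = 16L, global_pool = TRUE))
}
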