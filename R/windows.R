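#' Construct a peak set
#'
#' A peak set is the in-memory form of a narrowPeak file: intervals in
#' 0-based half-open coordinates plus the summit offset from each interval
#' start. Window labels and the FRiP QC both consume this type.
#'
#' @param chrom,start,end Vectors of chromosome name and 0-based half-open
#'   interval coordinates.
#' @param summit_offset Offset of the summit from `start`; must satisfy
#'   `0 <= summit_offset < end - start`.
#' @param source_id Dataset identifier (one per peak set / epigenomic class).
#' @return An object of class `peak_set` with elements `records` (data.frame
#'   with columns chrom, start, end, summit_offset), `source_id`, `peak_count`.
#' @export
peak_set <- function(chrom, start, end, summit_offset, source_id = "peaks") {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(start))
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            length(end) == length(summit_offset))
  if (any(start < 0) || any(end <= start))
    stop("peak intervals must satisfy 0 <= start < end")
  if (any(summit_offset < 0) || any(summit_offset >= end - start))
    stop("summit offsets must satisfy 0 <= offset < end - start")
  structure(list(
    records = data.frame(chrom = as.character(chrom),
                         start = as.integer(start), end = as.integer(end),
                         summit_offset = as.integer(summit_offset),
                         stringsAsFactors = FALSE),
    source_id = source_id,
    peak_count = length(start)
  ), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %s: %d peaks on %d chromosome(s)\n",
              x$source_id, x$peak_count, length(unique(x$records$chrom))))
  invisible(x)
}

#' Summit positions of a peak set
#' @param peaks A [peak_set()].
#' @return Data frame with columns chrom and pos (0-based summit position).
#' @export
peak_summits <- function(peaks) {
  data.frame(chrom = peaks$records$chrom,
             pos = peaks$records$start + peaks$records$summit_offset,
             stringsAsFactors = FALSE)
}

#' Read a narrowPeak (10-column BED dialect) file
#'
#' Column 10 is the summit offset from the interval start; a value of -1
#' (summit not called) is replaced by the interval midpoint.
#'
#' @param path Path to a narrowPeak file.
#' @param source_id Dataset identifier; defaults to the file name.
#' @return A [peak_set()].
#' @export
read_narrowpeak <- function(path, source_id = NULL) {
  if (is.null(source_id))
    source_id <- sub("\\.narrowPeak$", "", basename(path))
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "character", "numeric", "character",
                                          "numeric", "numeric", "numeric",
                                          "integer"))
  off <- tab[[10L]]
  mid <- (tab[[3L]] - tab[[2L]]) %/% 2L
  off[off < 0L] <- mid[off < 0L]
  peak_set(tab[[1L]], tab[[2L]], tab[[3L]], off, source_id = source_id)
}

#' Write a peak set as a narrowPeak file
#' @param peaks A [peak_set()].
#' @param path Output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  r <- peaks$records
  tab <- data.frame(r$chrom, r$start, r$end,
                    paste0(peaks$source_id, "_peak_", seq_len(nrow(r))),
                    0L, ".", 0, -1, -1, r$summit_offset)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Tile chromosomes into fixed-length windows
#'
#' Scans each chromosome from position 0 with the given stride, emitting only
#' windows that fit entirely inside the chromosome (trailing partial windows
#' are dropped, never padded). With `stride == window` the windows tile the
#' prefix `[0, floor(L/window) * window)` exactly.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param window Window size in bp (default 1000).
#' @param stride Shift between successive window starts, `1 <= stride <=
#'   window`. The half-overlapping scheme is the special case
#'   `stride = window / 2`.
#' @param exclude_chroms Chromosome names dropped before tiling; defaults to
#'   the mitochondrial names `chrM` and `MT`.
#' @return Data frame with columns chrom, start, end (0-based half-open) and
#'   index (ordinal over the whole window set).
#' @export
make_windows <- function(chrom_lengths, window = 1000L, stride = 500L,
                         exclude_chroms = c("chrM", "MT")) {
  stopifnot(length(chrom_lengths) > 0, !is.null(names(chrom_lengths)))
  window <- as.integer(window); stride <- as.integer(stride)
  if (is.na(stride) || stride <= 0L) stop("stride must be a positive integer")
  if (window < 1L) stop("window must be >= 1")
  if (stride > window) stop("stride must not exceed the window size")
  chrom_lengths <- chrom_lengths[!names(chrom_lengths) %in% exclude_chroms]
  pieces <- lapply(names(chrom_lengths), function(chr) {
    L <- as.integer(chrom_lengths[[chr]])
    if (L < window) return(NULL)
    starts <- seq.int(0L, L - window, by = stride)
    data.frame(chrom = chr, start = starts, end = starts + window,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  out$index <- seq_len(nrow(out))
  out
}

#' Label windows by peak-summit overlap
#'
#' Entry (w, c) of the result is 1 iff at least one summit of peak set c
#' falls inside window w, i.e. `start_w <= summit < end_w` (half-open, so a
#' summit exactly at `end_w` does not count). Peaks on chromosomes absent
#' from the window set are skipped with a warning.
#'
#' @param windows Data frame from [make_windows()].
#' @param peaksets A list of [peak_set()] objects (one per class).
#' @return Integer 0/1 matrix, windows x classes, columns named by
#'   `source_id`.
#' @export
label_windows <- function(windows, peaksets) {
  if (inherits(peaksets, "peak_set")) peaksets <- list(peaksets)
  ids <- vapply(peaksets, function(p) p$source_id, character(1))
  labels <- matrix(0L, nrow = nrow(windows), ncol = length(peaksets),
                   dimnames = list(NULL, ids))
  if (nrow(windows) == 0L) return(labels)
  wr <- GenomicRanges::GRanges(
    windows$chrom, IRanges::IRanges(start = windows$start + 1L,
                                    end = windows$end))
  known <- unique(windows$chrom)
  for (ci in seq_along(peaksets)) {
    s <- peak_summits(peaksets[[ci]])
    bad <- !(s$chrom %in% known)
    if (any(bad)) {
      warning(sprintf("peak set '%s': skipping %d summit(s) on unknown chromosome(s) %s",
                      ids[ci], sum(bad),
                      paste(unique(s$chrom[bad]), collapse = ",")))
      s <- s[!bad, , drop = FALSE]
    }
    if (nrow(s) == 0L) next
    sr <- GenomicRanges::GRanges(
      s$chrom, IRanges::IRanges(start = s$pos + 1L, width = 1L))
    hit <- IRanges::overlapsAny(wr, sr)
    labels[hit, ci] <- 1L
  }
  labels
}

#' Drop classes with too few peaks
#'
#' Low peak counts are a strong sign of poor assay quality; classes whose
#' `peak_count` falls below the threshold are removed (the threshold itself
#' is kept: `>= min_peaks` survives).
#'
#' @param peaksets List of [peak_set()] objects.
#' @param min_peaks Minimum peak count to keep a class (default 10000).
#' @return The filtered list; removals are reported via `message()`.
#' @export
filter_low_peak_classes <- function(peaksets, min_peaks = 10000L) {
  counts <- vapply(peaksets, function(p) p$peak_count, numeric(1))
  keep <- counts >= min_peaks
  if (!any(keep))
    stop(sprintf("all %d classes have fewer than %d peaks", length(peaksets),
                 min_peaks))
  if (any(!keep)) {
    dropped <- vapply(peaksets[!keep], function(p) p$source_id, character(1))
    message(sprintf("excluding %d class(es) with < %d peaks: %s",
                    sum(!keep), min_peaks,
                    paste(sprintf("%s (%d)", dropped, counts[!keep]),
                          collapse = ", ")))
  }
  peaksets[keep]
}

#' Load a FASTA genome as named sequences
#' @param fasta Path to a (multi-)FASTA file.
#' @return A named character vector of upper-case sequences.
#' @export
load_genome <- function(fasta) {
  ss <- Biostrings::readDNAStringSet(fasta)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Build a labelled one-hot window dataset from a genome and peak files
#'
#' Runs the whole data-structuring pipeline: tile each chromosome into
#' windows, one-hot encode every window in the symmetric A,G,C,T layout, and
#' label each window per class by peak-summit containment. Chromosomes are
#' encoded once and windows are views into the per-chromosome matrix, so the
#' cost is linear in genome size.
#'
#' @param genome Named character vector of chromosome sequences (see
#'   [load_genome()]), or a path to a FASTA file.
#' @param peaksets List of [peak_set()] objects (one class each).
#' @param window,stride,exclude_chroms Passed to [make_windows()].
#' @param max_n_fraction Optional filter: drop windows whose fraction of
#'   ambiguous (N) bases exceeds this value. Default `1` keeps every window
#'   (N rows encode as zeros and carry no signal either way).
#' @return An object of class `window_dataset`: list with `inputs` (array
#'   n x window x 4), `labels` (n x classes 0/1 matrix), `windows` (the
#'   coordinate data frame), `class_names`, `window`, `stride`.
#' @export
build_dataset <- function(genome, peaksets, window = 1000L, stride = 500L,
                          exclude_chroms = c("chrM", "MT"),
                          max_n_fraction = 1) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- load_genome(genome)
  if (inherits(peaksets, "peak_set")) peaksets <- list(peaksets)
  lens <- vapply(genome, nchar, integer(1))
  win <- make_windows(lens, window = window, stride = stride,
                      exclude_chroms = exclude_chroms)
  labels <- label_windows(win, peaksets)
  n <- nrow(win)
  inputs <- array(0, dim = c(n, window, 4L))
  for (chr in unique(win$chrom)) {
    enc <- encode_sequence(genome[[chr]])
    rows <- which(win$chrom == chr)
    for (i in rows) {
      inputs[i, , ] <- enc[(win$start[i] + 1L):win$end[i], , drop = FALSE]
    }
  }
  keep <- seq_len(n)
  if (max_n_fraction < 1 && n > 0L) {
    nfrac <- 1 - apply(inputs, 1L, sum) / window
    keep <- which(nfrac <= max_n_fraction)
  }
  ds <- list(inputs = inputs[keep, , , drop = FALSE],
             labels = labels[keep, , drop = FALSE],
             windows = win[keep, , drop = FALSE],
             class_names = colnames(labels),
             window = as.integer(window), stride = as.integer(stride))
  class(ds) <- "window_dataset"
  ds
}

#' @export
print.window_dataset <- function(x, ...) {
  cat(sprintf("<window_dataset> %d windows of %d bp (stride %d), %d class(es)\n",
              nrow(x$windows), x$window, x$stride, ncol(x$labels)))
  cat(sprintf("  positives per class: %s\n",
              paste(sprintf("%s=%d", x$class_names, colSums(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Subset a window dataset by row indices
#' @param ds A `window_dataset`.
#' @param idx Integer row indices (order preserved as given).
#' @return The subset dataset.
#' @export
subset_dataset <- function(ds, idx) {
  ds$inputs <- ds$inputs[idx, , , drop = FALSE]
  ds$labels <- ds$labels[idx, , drop = FALSE]
  ds$windows <- ds$windows[idx, , drop = FALSE]
  ds
}

#' Split a dataset into held-out chromosome(s) and the rest
#'
#' Chromosome holdout is the evaluation discipline for genome models:
#' overlapping strides make nearby windows near-duplicates, so a random
#' window split leaks training sequence into the test set. Holding out whole
#' chromosomes avoids that.
#'
#' @param ds A `window_dataset`.
#' @param holdout_chroms Chromosome name(s) to hold out.
#' @return List with elements `train` and `holdout`, both `window_dataset`s.
#' @export
split_holdout <- function(ds, holdout_chroms) {
  is_h <- ds$windows$chrom %in% holdout_chroms
  if (!any(is_h))
    stop(sprintf("no windows on holdout chromosome(s) %s",
                 paste(holdout_chroms, collapse = ",")))
  list(train = subset_dataset(ds, which(!is_h)),
       holdout = subset_dataset(ds, which(is_h)))
}

#' Randomly downsample negative windows
#'
#' A genome is overwhelmingly unlabelled, so all-negative windows (label row
#' entirely zero) are each retained independently with the given probability;
#' windows positive for any class are always kept, and the original order of
#' retained windows is preserved.
#'
#' @param ds A `window_dataset`.
#' @param fraction Retention probability for negative windows, in (0, 1].
#'   Default 0.25.
#' @param seed Integer seed making the selection reproducible.
#' @return The downsampled `window_dataset`.
#' @export
downsample_negatives <- function(ds, fraction = 0.25, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(ds)
  neg <- rowSums(ds$labels) == 0
  keep <- rep(TRUE, nrow(ds$labels))
  withr::with_seed(seed, {
    keep[neg] <- stats::runif(sum(neg)) < fraction
  })
  subset_dataset(ds, which(keep))
}
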