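#' Construct a read set from aligned-read intervals
#'
#' @param chrom,start,end Interval coordinates of aligned reads (0-based
#'   half-open, BED convention); `start < end` required.
#' @param source_id Dataset identifier.
#' @return An object of class `read_set` with `intervals` (data.frame),
#'   `total_reads`, `source_id`.
#' @export
read_set <- function(chrom, start, end, source_id = "reads") {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(end <= start)) stop("read intervals must satisfy start < end")
  structure(list(intervals = data.frame(chrom = as.character(chrom),
                                        start = as.integer(start),
                                        end = as.integer(end),
                                        stringsAsFactors = FALSE),
                 total_reads = length(start), source_id = source_id),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %s: %d reads\n", x$source_id, x$total_reads))
  invisible(x)
}

#' Read a 3+ column BED file of read intervals
#' @param path BED path (plain or gzipped).
#' @param source_id Dataset identifier; defaults to the file name.
#' @return A [read_set()].
#' @export
read_bed_reads <- function(path, source_id = NULL) {
  if (is.null(source_id)) source_id <- sub("\\.bed(\\.gz)?$", "",
                                           basename(path))
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  read_set(tab[[1L]], tab[[2L]], tab[[3L]], source_id = source_id)
}

reads_granges <- function(reads) {
  GenomicRanges::GRanges(reads$intervals$chrom,
                         IRanges::IRanges(start = reads$intervals$start + 1L,
                                          end = reads$intervals$end))
}

#' Fraction of the genome covered by at least one read
#'
#' Length of the union of read intervals (overlaps counted once) divided by
#' the total genome length.
#'
#' @param reads A [read_set()].
#' @param genome_sizes Named vector of chromosome lengths (bp).
#' @return A fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(reads, genome_sizes) {
  gr <- GenomicRanges::reduce(reads_granges(reads))
  sum(as.numeric(IRanges::width(gr))) / sum(as.numeric(genome_sizes))
}

#' FRiP and coverage-corrected FRiP (cFRiP)
#'
#' The fraction of reads in peaks (FRiP) is a standard enrichment QC for
#' chromatin assays, but it inflates when total read depth is low. The
#' corrected score multiplies FRiP by the fraction of the genome covered by
#' at least one read, deflating shallow libraries. Before counting,
#' mitochondrial peaks and peaks overlapping a blacklist are removed
#' (reads are not filtered, only peaks). A read counts as "in peaks" when
#' it overlaps any retained peak by at least one bp (set
#' `rule = "midpoint"` to require the read midpoint inside a peak).
#'
#' @param reads A [read_set()].
#' @param peaks A [peak_set()].
#' @param genome_sizes Named vector of chromosome lengths (bp); must cover
#'   every chromosome carrying reads.
#' @param blacklist Optional data.frame with columns chrom, start, end
#'   (0-based half-open) of regions whose peaks are discarded; default none.
#' @param chrM_names Chromosome names treated as mitochondrial
#'   (default chrM, MT).
#' @param rule Overlap rule for read-in-peak counting: `"any"` (>= 1 bp,
#'   default) or `"midpoint"`.
#' @return List of class `qc_record`: `frip`, `coverage_fraction`, `cfrip`
#'   (`= frip * coverage_fraction`), `peak_count` (retained),
#'   `excluded_peaks`, `total_reads`, `reads_in_peaks`, `source`.
#' @export
compute_frip <- function(reads, peaks, genome_sizes, blacklist = NULL,
                         chrM_names = c("chrM", "MT"),
                         rule = c("any", "midpoint")) {
  rule <- match.arg(rule)
  if (reads$total_reads == 0L) stop("read set is empty")
  chroms <- unique(reads$intervals$chrom)
  if (!all(chroms %in% names(genome_sizes)))
    stop("genome_sizes must cover all chromosomes carrying reads")
  rec <- peaks$records
  keep <- !(rec$chrom %in% chrM_names)
  if (!is.null(blacklist) && nrow(blacklist) > 0L && any(keep)) {
    pg <- GenomicRanges::GRanges(rec$chrom,
                                 IRanges::IRanges(start = rec$start + 1L,
                                                  end = rec$end))
    bg <- GenomicRanges::GRanges(blacklist$chrom,
                                 IRanges::IRanges(start = blacklist$start + 1L,
                                                  end = blacklist$end))
    keep <- keep & !IRanges::overlapsAny(pg, bg)
  }
  excluded <- sum(!keep)
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) == 0L) {
    warning("no peaks retained after chrM/blacklist exclusion; FRiP = 0")
    in_peaks <- 0L
  } else {
    pg <- GenomicRanges::GRanges(rec$chrom,
                                 IRanges::IRanges(start = rec$start + 1L,
                                                  end = rec$end))
    rg <- if (rule == "any") reads_granges(reads)
          else {
            mid <- (reads$intervals$start + reads$intervals$end) %/% 2L
            GenomicRanges::GRanges(reads$intervals$chrom,
                                   IRanges::IRanges(start = mid + 1L,
                                                    width = 1L))
          }
    in_peaks <- sum(IRanges::overlapsAny(rg, pg))
  }
  frip <- in_peaks / reads$total_reads
  cov <- coverage_fraction(reads, genome_sizes)
  structure(list(frip = frip, coverage_fraction = cov, cfrip = frip * cov,
                 peak_count = nrow(rec), excluded_peaks = excluded,
                 total_reads = reads$total_reads,
                 reads_in_peaks = as.integer(in_peaks),
                 source = reads$source_id),
            class = "qc_record")
}

#' @export
print.qc_record <- function(x, ...) {
  cat(sprintf(
    "<qc_record> %s: FRiP %.4f x coverage %.4f = cFRiP %.4f (%d/%d reads in %d peaks; %d peak(s) excluded)\n",
    x$source, x$frip, x$coverage_fraction, x$cfrip, x$reads_in_peaks,
    x$total_reads, x$peak_count, x$excluded_peaks))
  invisible(x)
}

#' Write QC records as a TSV report
#' @param records A list of `qc_record` objects (or one).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_qc_tsv <- function(records, path) {
  if (inherits(records, "qc_record")) records <- list(records)
  tab <- do.call(rbind, lapply(records, function(r)
    data.frame(source = r$source, total_reads = r$total_reads,
               reads_in_peaks = r$reads_in_peaks, frip = r$frip,
               coverage_fraction = r$coverage_fraction, cfrip = r$cfrip,
               peak_count = r$peak_count)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
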