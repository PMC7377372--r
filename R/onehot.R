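#' One-hot DNA encoding in the strand-symmetric A,G,C,T layout
#'
#' Encodes a DNA string as a length x 4 zero-one matrix. The channel order is
#' deliberately A, G, C, T (not alphabetical): with this symmetric layout a
#' 180-degree rotation of the matrix (reverse both axes) is exactly the
#' encoding of the reverse-complement sequence, which is the algebraic fact
#' the whole FRSS architecture rests on. Changing the column order silently
#' breaks every strand-symmetry property in the package, so it is fixed and
#' not a parameter.
#'
#' `N` and any unrecognized symbol encode as an all-zero row.
#'
#' @param seq A single DNA string over A,C,G,T,N (case-insensitive).
#' @return A `nchar(seq)` x 4 numeric matrix with columns named A,G,C,T; each
#'   row is the one-hot vector of the corresponding base, or all zeros for N.
#' @examples
#' encode_sequence("AGCT")
#' all(rc180(encode_sequence("AGCTAAAG")) == encode_sequence("CTTTAGCT"))
#' @export
encode_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (is.na(seq) || nchar(seq) == 0L)
    stop("cannot encode an empty sequence")
  bases <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  idx <- match(bases, DNA_CHANNELS)  # NA for N or anything unrecognized
  m <- matrix(0, nrow = length(bases), ncol = 4L,
              dimnames = list(NULL, DNA_CHANNELS))
  hit <- !is.na(idx)
  m[cbind(which(hit), idx[hit])] <- 1
  m
}

#' @rdname encode_sequence
#' @format NULL
#' @export
DNA_CHANNELS <- c("A", "G", "C", "T")

#' Rotate a one-hot window by 180 degrees
#'
#' Reverses both the position and the channel axis: `out[s, n] =
#' x[S - 1 - s, 3 - n]` in 0-based terms. Under the symmetric A,G,C,T channel
#' layout this maps the encoding of a sequence to the encoding of its
#' reverse complement. The operation is an involution.
#'
#' @param x A positions x 4 numeric matrix (any values, not only 0/1).
#' @return The rotated matrix, same dimensions.
#' @export
rc180 <- function(x) {
  stopifnot(is.matrix(x), ncol(x) == 4L)
  out <- x[rev(seq_len(nrow(x))), rev(seq_len(ncol(x))), drop = FALSE]
  dimnames(out) <- dimnames(x)
  out
}

#' Decode a one-hot (or real-valued) window back to a DNA string
#'
#' Takes the per-position argmax over the four channels; positions whose row
#' is entirely zero (the encoding of N) decode to "N". For real-valued inputs
#' (e.g. activation-maximization results) this is the argmax view.
#'
#' @param x A positions x 4 numeric matrix.
#' @return A single DNA string.
#' @export
decode_onehot <- function(x) {
  stopifnot(is.matrix(x), ncol(x) == 4L)
  if (nrow(x) == 0L) return("")
  best <- max.col(x, ties.method = "first")
  chars <- DNA_CHANNELS[best]
  chars[rowSums(x != 0) == 0] <- "N"
  paste0(chars, collapse = "")
}

#' String-level reverse complement
#'
#' Thin wrapper over [Biostrings::reverseComplement()]; `N` maps to `N`.
#'
#' @param seq A single DNA string.
#' @return The reverse-complement string.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
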