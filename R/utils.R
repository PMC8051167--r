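#' Round half away from zero
#'
#' Plain "schoolbook" rounding: 37.5 rounds to 38, 35.58 to 36. Used for all
#' printed percentages so that integer percent columns are reproducible,
#' unlike [base::round()] which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Reverse-complement a DNA string
#'
#' @param x character vector of sequences over A,C,G,T,N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split sequences (equal length) into a character matrix, one row per sequence.
seq_char_matrix <- function(seqs) {
  stopifnot(length(unique(nchar(seqs))) == 1L)
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

# DNA string -> integer indices 1..4 for A,C,G,T; NA for anything else.
dna_to_int <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  match(chars, c("A", "C", "G", "T"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
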