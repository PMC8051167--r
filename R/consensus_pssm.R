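#' Build the position score matrix of an alignment
#'
#' Tallies, for every alignment column, how many rows carry each of A, C, G,
#' T, gap (`-`) and N, and the corresponding fractions of the row count.
#' Gaps and N are counted as their own categories: an N is never evidence of
#' conservation, and a column containing a gap can never be 100% conserved.
#'
#' @param msa an `msa_block`.
#' @return a `pssm` object: `counts` and `fractions` are 6 x L matrices with
#'   rows A,C,G,T,-,N; `n_rows` the number of alignment rows.
#' @export
build_pssm <- function(msa) {
  stopifnot(inherits(msa, "msa_block"))
  chars <- seq_char_matrix(msa$rows)
  cats <- c("A", "C", "G", "T", "-", "N")
  idx <- matrix(match(chars, cats), nrow = nrow(chars))
  counts <- vapply(seq_len(ncol(idx)),
                   function(j) tabulate(idx[, j], nbins = 6L),
                   integer(6L))
  rownames(counts) <- cats
  structure(list(counts = counts, fractions = counts / nrow(chars),
                 n_rows = nrow(chars), length = ncol(counts),
                 gene_id = msa$gene_id, region_kind = msa$region_kind,
                 ordinal = msa$ordinal),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> %d columns x %d rows (%s %s %s)\n", x$length, x$n_rows,
              x$gene_id, x$region_kind, x$ordinal))
  invisible(x)
}

#' Majority-rule ("dumb") consensus profile
#'
#' Emits, per column, the most common nucleotide when its fraction of rows
#' strictly exceeds `threshold`, and the ambiguity character `X` otherwise.
#' Only A,C,G,T can be emitted: columns whose majority is a gap or N, and
#' ties for the most common nucleotide, give `X`. The strict inequality
#' means a 0.7 majority at the default threshold of 0.7 is still `X`.
#'
#' @param pssm a `pssm`.
#' @param threshold fraction in (0, 1], default 0.7.
#' @return a `consensus_profile` object with fields `profile` (string over
#'   A,C,G,T,X) and `threshold`.
#' @export
dumb_consensus <- function(pssm, threshold = 0.7) {
  stopifnot(inherits(pssm, "pssm"))
  if (!(threshold > 0 && threshold <= 1)) stop("`threshold` must be in (0, 1]")
  nt <- pssm$fractions[c("A", "C", "G", "T"), , drop = FALSE]
  top <- apply(nt, 2L, max)
  arg <- apply(nt, 2L, which.max)
  tied <- apply(nt, 2L, function(col) sum(col == max(col)) > 1L)
  chars <- rep("X", pssm$length)
  keep <- top > threshold & !tied
  chars[keep] <- rownames(nt)[arg[keep]]
  structure(list(profile = paste(chars, collapse = ""), threshold = threshold),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("<consensus_profile> %d columns, threshold %.2f\n",
              nchar(x$profile), x$threshold))
  invisible(x)
}
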