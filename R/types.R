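#' Orthologous sequence set for one gene region
#'
#' Bundles the sequences of a single intron or exon across several species.
#' This is the unit the conserved-sequence detector consumes: the region must
#' have the same position and phase relative to the coding sequence in every
#' species, so that column-wise identity in the alignment is evidence of
#' purifying selection rather than paralogy.
#'
#' @param gene_id gene symbol or identifier.
#' @param region_kind `"intron"` or `"exon"`.
#' @param ordinal 1-based intron/exon number within the transcript.
#' @param sequences named character vector, one DNA string per species; names
#'   are species identifiers and must be unique. Alphabet A,C,G,T,N.
#' @return an `ortholog_set` object.
#' @export
ortholog_set <- function(gene_id, region_kind, ordinal, sequences) {
  region_kind <- match.arg(region_kind, c("intron", "exon"))
  ordinal <- as.integer(ordinal)
  if (is.na(ordinal) || ordinal < 1L) stop("`ordinal` must be a positive integer")
  if (length(sequences) < 2L) stop("an ortholog set needs at least 2 species")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)) ||
      any(names(sequences) == "")) {
    stop("`sequences` must be named by unique species ids")
  }
  if (any(nchar(sequences) == 0L)) stop("empty sequence for species: ",
                                        paste(names(sequences)[nchar(sequences) == 0L], collapse = ", "))
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) stop("non-nucleotide characters (outside A,C,G,T,N) in species: ",
                     paste(names(sequences)[bad], collapse = ", "))
  structure(list(gene_id = gene_id, region_kind = region_kind,
                 ordinal = ordinal, sequences = sequences),
            class = "ortholog_set")
}

#' @export
print.ortholog_set <- function(x, ...) {
  cat(sprintf("<ortholog_set> %s %s %d: %d species, lengths %s\n",
              x$gene_id, x$region_kind, x$ordinal, length(x$sequences),
              paste(range(nchar(x$sequences)), collapse = "-")))
  invisible(x)
}

#' Multiple sequence alignment block
#'
#' A gapped alignment of one ortholog set. Rows carry gaps as `-`; degapping
#' any row must reproduce the corresponding input sequence exactly.
#'
#' @param rows named character vector of gapped rows (equal lengths) over
#'   A,C,G,T,N,-.
#' @param gene_id,region_kind,ordinal region metadata (optional, carried
#'   through to downstream tables).
#' @return an `msa_block` object with fields `rows`, `length` (columns) and
#'   the metadata.
#' @export
msa_block <- function(rows, gene_id = NA_character_, region_kind = NA_character_,
                      ordinal = NA_integer_) {
  if (length(rows) < 2L) stop("an alignment needs at least 2 rows")
  if (is.null(names(rows)) || anyDuplicated(names(rows))) {
    stop("`rows` must be named by unique species ids")
  }
  widths <- unique(nchar(rows))
  if (length(widths) != 1L) stop("ragged alignment: row lengths ",
                                 paste(sort(widths), collapse = ", "))
  bad <- grepl("[^ACGTN-]", rows)
  if (any(bad)) stop("invalid alignment characters in row: ",
                     paste(names(rows)[bad], collapse = ", "))
  structure(list(rows = rows, length = widths,
                 gene_id = gene_id, region_kind = region_kind,
                 ordinal = if (is.na(ordinal)) NA_integer_ else as.integer(ordinal)),
            class = "msa_block")
}

#' @export
print.msa_block <- function(x, ...) {
  cat(sprintf("<msa_block> %d rows x %d columns (%s %s %s)\n",
              length(x$rows), x$length, x$gene_id, x$region_kind, x$ordinal))
  invisible(x)
}

#' Remove gaps from alignment rows
#'
#' @param msa an `msa_block`.
#' @return named character vector of ungapped sequences.
#' @export
degap_msa <- function(msa) {
  gsub("-", "", msa$rows, fixed = TRUE)
}

#' Treat an ortholog set of equal-length sequences as an alignment
#'
#' When the per-species sequences already have equal length (e.g. simulator
#' output without indels, or externally pre-aligned input) the set maps onto
#' a gap-free alignment directly.
#'
#' @param os an `ortholog_set`.
#' @return an `msa_block`.
#' @export
msa_from_ortholog_set <- function(os) {
  if (length(unique(nchar(os$sequences))) != 1L) {
    stop("sequences have unequal lengths; align them first (see align_ortholog_set)")
  }
  msa_block(os$sequences, gene_id = os$gene_id, region_kind = os$region_kind,
            ordinal = os$ordinal)
}

#' Position-probability motif model
#'
#' One motif from a CIS-BP-style library: a per-position probability matrix
#' over A,C,G,T plus the transcription factors mapped to the motif and their
#' DNA-binding-domain family.
#'
#' @param motif_id motif identifier.
#' @param tf_names character vector of TF gene symbols mapped to this motif
#'   (direct or inferred).
#' @param family binding-domain family label (e.g. "Homeodomain").
#' @param matrix numeric matrix, width x 4, columns A,C,G,T; each row sums to
#'   1 within 1e-3 (renormalised on construction).
#' @return a `motif_model` object.
#' @export
motif_model <- function(motif_id, tf_names, family, matrix) {
  m <- as.matrix(matrix)
  if (ncol(m) != 4L) stop("motif matrix must have 4 columns (A,C,G,T)")
  colnames(m) <- c("A", "C", "G", "T")
  if (nrow(m) < 1L) stop("motif width must be >= 1")
  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-3)) {
    stop(sprintf("motif %s: matrix row sums deviate from 1 by more than 1e-3", motif_id))
  }
  m <- m / rs
  structure(list(motif_id = motif_id, tf_names = tf_names, family = family,
                 matrix = m, width = nrow(m)),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s width %d, family '%s', TFs: %s\n",
              x$motif_id, x$width, x$family, paste(x$tf_names, collapse = ",")))
  invisible(x)
}
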