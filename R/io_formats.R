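#' Read one gene region's orthologous sequences from FASTA
#'
#' One record per species; record ids are taken as species ids. Sequences are
#' upper-cased and RNA `U` is mapped to `T`; any character outside A,C,G,T,N
#' is an error.
#'
#' @param path FASTA file.
#' @param gene_id,region_kind,ordinal region metadata (see [ortholog_set()]).
#' @return an `ortholog_set`.
#' @export
read_ortholog_fasta <- function(path, gene_id, region_kind, ordinal) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids)) stop("duplicate species id in ", path, ": ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- chartr("u", "t", toupper(as.character(recs)))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- ids
  ortholog_set(gene_id, region_kind, ordinal, seqs)
}

#' Write an ortholog set as FASTA
#'
#' @param os an `ortholog_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ortholog_fasta <- function(os, path) {
  x <- Biostrings::DNAStringSet(os$sequences)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a pre-aligned FASTA into an alignment block
#'
#' @param path aligned FASTA (rows of equal length; gaps as `-`).
#' @param gene_id,region_kind,ordinal optional region metadata.
#' @return an `msa_block`.
#' @export
read_msa_fasta <- function(path, gene_id = NA_character_,
                           region_kind = NA_character_, ordinal = NA_integer_) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) < 2L) stop("alignment needs at least 2 rows: ", path)
  ids <- sub("\\s.*$", "", names(recs))
  rows <- chartr("Uu", "Tt", as.character(recs))
  rows <- toupper(rows)
  names(rows) <- ids
  msa_block(rows, gene_id = gene_id, region_kind = region_kind, ordinal = ordinal)
}

#' Align an ortholog set with an external aligner
#'
#' The alignment step is delegated to a user-configured command (MAFFT by
#' default); this package only consumes its FASTA output. Requires the
#' aligner to be on `PATH`.
#'
#' @param os an `ortholog_set`.
#' @param command command template; `{in}` is replaced by the input FASTA
#'   path. Output is read from stdout.
#' @return an `msa_block`.
#' @export
align_ortholog_set <- function(os, command = "mafft --auto --quiet {in}") {
  fin <- tempfile(fileext = ".fasta")
  on.exit(unlink(fin), add = TRUE)
  write_ortholog_fasta(os, fin)
  cmd <- sub("{in}", shQuote(fin), command, fixed = TRUE)
  out <- system(cmd, intern = TRUE)
  fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(fout), add = TRUE)
  writeLines(out, fout)
  msa <- read_msa_fasta(fout, gene_id = os$gene_id, region_kind = os$region_kind,
                        ordinal = os$ordinal)
  if (!setequal(names(msa$rows), names(os$sequences))) {
    stop("aligner dropped or renamed records")
  }
  if (!identical(degap_msa(msa)[names(os$sequences)], os$sequences)) {
    stop("aligner output does not degap to the input sequences")
  }
  msa
}

#' Read a CIS-BP-style motif library
#'
#' Expects the CIS-BP dump layout: a TF-information TSV mapping motifs to TF
#' names and binding-domain families, plus one position-probability matrix
#' file per motif under `pwm_dir`, named `<motif_id>.txt` with a
#' `Pos A C G T` header. Both "direct" and "inferred" TF rows are kept; a
#' hit on a motif is attributed to every TF mapped to it. Motifs whose
#' matrix file is missing or empty are skipped with a warning; matrix rows
#' whose probabilities deviate from sum 1 by more than 1e-3 abort the read.
#'
#' @param info_path TSV with (at least) the three columns below.
#' @param pwm_dir directory of per-motif matrix files.
#' @param motif_col,tf_col,family_col column names in `info_path`.
#' @return list of [motif_model()] objects, named by motif id.
#' @export
read_cisbp_library <- function(info_path, pwm_dir,
                               motif_col = "Motif_ID", tf_col = "TF_Name",
                               family_col = "Family_Name") {
  info <- utils::read.delim(info_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  need <- c(motif_col, tf_col, family_col)
  missing_cols <- setdiff(need, names(info))
  if (length(missing_cols)) {
    stop("motif info table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  info <- info[info[[motif_col]] != "" & !is.na(info[[motif_col]]), , drop = FALSE]
  motifs <- list()
  for (mid in unique(info[[motif_col]])) {
    rows <- info[info[[motif_col]] == mid, , drop = FALSE]
    mat_path <- file.path(pwm_dir, paste0(mid, ".txt"))
    mat <- read_pwm_file(mat_path, mid)
    if (is.null(mat)) {
      warning("skipping motif ", mid, ": missing or empty matrix file", call. = FALSE)
      next
    }
    fam <- unique(rows[[family_col]])
    if (length(fam) > 1L) {
      warning("motif ", mid, " maps to several families; keeping '", fam[1L], "'",
              call. = FALSE)
      fam <- fam[1L]
    }
    motifs[[mid]] <- motif_model(mid, tf_names = sort(unique(rows[[tf_col]])),
                                 family = fam, matrix = mat)
  }
  motifs
}

# Parse one CIS-BP PWM file. NULL for missing/empty; error on malformed rows.
read_pwm_file <- function(path, motif_id) {
  if (!file.exists(path) || file.size(path) == 0L) return(NULL)
  tab <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                  error = function(e) stop("motif ", motif_id,
                                           ": malformed matrix file: ",
                                           conditionMessage(e)))
  if (nrow(tab) == 0L) return(NULL)
  need <- c("A", "C", "G", "T")
  if (!all(need %in% names(tab))) {
    stop("motif ", motif_id, ": matrix file must have columns Pos A C G T")
  }
  m <- as.matrix(tab[, need])
  if (!is.numeric(m) || anyNA(m)) stop("motif ", motif_id, ": non-numeric matrix row")
  m
}

#' Write the annotated pattern table
#'
#' One row per conserved pattern with its classification and element counts.
#' Coordinates in the file are 1-based inclusive alignment columns (internal
#' coordinates are 0-based half-open); a header comment states the
#' convention.
#'
#' @param patterns pattern data frame from [extract_conserved_patterns()].
#' @param classes named character vector from [classify_patterns()] (optional;
#'   `NOT_IDENTIFIED` assumed when absent).
#' @param tfbs_hits,splice_hits hit data frames (optional, used for counts).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_pattern_table <- function(patterns, path, classes = NULL,
                                tfbs_hits = NULL, splice_hits = NULL) {
  tab <- data.frame(
    gene = patterns$gene_id,
    region_kind = patterns$region_kind,
    ordinal = patterns$ordinal,
    aln_start = patterns$aln_start + 1L,
    aln_end = patterns$aln_end,
    length = patterns$length,
    sequence = patterns$sequence,
    class = if (is.null(classes)) rep("NOT_IDENTIFIED", nrow(patterns))
            else unname(classes[patterns$pattern_id]),
    n_tfbs = count_hits(patterns$pattern_id, tfbs_hits),
    n_ss = count_hits(patterns$pattern_id, splice_hits),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based inclusive alignment columns", con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

count_hits <- function(ids, hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(integer(length(ids)))
  tab <- table(hits$pattern_id)
  n <- as.integer(tab[ids])
  n[is.na(n)] <- 0L
  n
}

#' Read a pattern table written by [write_pattern_table()]
#'
#' @param path TSV file.
#' @return data frame with internal 0-based half-open coordinates restored.
#' @export
read_pattern_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  data.frame(
    pattern_id = sprintf("%s_%s%d_%d", tab$gene, tab$region_kind, tab$ordinal,
                         tab$aln_start - 1L),
    gene_id = tab$gene, region_kind = tab$region_kind, ordinal = tab$ordinal,
    aln_start = tab$aln_start - 1L, aln_end = tab$aln_end,
    length = tab$length, sequence = tab$sequence, class = tab$class,
    n_tfbs = tab$n_tfbs, n_ss = tab$n_ss, stringsAsFactors = FALSE
  )
}
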