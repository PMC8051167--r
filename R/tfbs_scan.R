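#' Convert a position-probability matrix to log-odds scores
#'
#' Per-position, per-base score in bits:
#' `log2((p + pseudocount * b) / ((1 + pseudocount) * b))`, i.e. the
#' probability is mixed proportionally with the background `b` before taking
#' the log ratio. With the default uniform background a uniform motif scores
#' exactly 0 everywhere, for any pseudocount.
#'
#' @param motif a `motif_model`.
#' @param background length-4 base frequencies (A,C,G,T), default uniform.
#' @param pseudocount positive mixing fraction, default 0.01.
#' @return a `logodds_matrix` object with fields `motif_id`, `tf_names`,
#'   `family`, `scores` (width x 4, bits), `width`, `max_score`.
#' @export
pwm_to_logodds <- function(motif, background = rep(0.25, 4), pseudocount = 0.01) {
  stopifnot(inherits(motif, "motif_model"))
  if (pseudocount <= 0) stop("`pseudocount` must be positive")
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6) {
    stop("`background` must be 4 positive frequencies summing to 1")
  }
  b <- matrix(background, nrow = motif$width, ncol = 4L, byrow = TRUE)
  scores <- log2((motif$matrix + pseudocount * b) / ((1 + pseudocount) * b))
  colnames(scores) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif$motif_id, tf_names = motif$tf_names,
                 family = motif$family, scores = scores, width = motif$width,
                 max_score = sum(apply(scores, 1L, max))),
            class = "logodds_matrix")
}

#' @export
print.logodds_matrix <- function(x, ...) {
  cat(sprintf("<logodds_matrix> %s width %d, max score %.2f bits\n",
              x$motif_id, x$width, x$max_score))
  invisible(x)
}

#' Scan one sequence with one log-odds matrix
#'
#' Every window of the motif's width is scored on the requested strands; a
#' window is a hit when its summed score reaches `threshold` bits. Motifs
#' narrower than `min_width` never produce hits (sparse short matches are
#' excluded wholesale). Reverse-strand windows are scored on the reverse
#' complement but reported in forward coordinates. Hits may overlap.
#'
#' @param seq DNA string (windows containing N or other non-ACGT characters
#'   are skipped).
#' @param lom a `logodds_matrix`.
#' @param threshold minimum score in bits (default 10).
#' @param min_width minimum motif width considered (default 10 nt).
#' @param strands `"both"` (default), `"+"` or `"-"`.
#' @return data frame with motif_id, tf_names (comma-joined), family, offset
#'   (0-based start within `seq`, forward coordinates), strand, score.
#' @export
scan_pattern <- function(seq, lom, threshold = 10, min_width = 10L,
                         strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  stopifnot(inherits(lom, "logodds_matrix"))
  w <- lom$width
  L <- nchar(seq)
  if (w < min_width || L < w) return(empty_hit_frame())
  do_strand <- function(s, strand) {
    idx <- dna_to_int(s)
    n_win <- length(idx) - w + 1L
    sc <- vapply(seq_len(n_win), function(j) {
      win <- idx[j:(j + w - 1L)]
      if (anyNA(win)) return(NA_real_)
      sum(lom$scores[cbind(seq_len(w), win)])
    }, numeric(1L))
    hit <- which(!is.na(sc) & sc >= threshold)
    if (!length(hit)) return(NULL)
    off <- if (strand == "+") hit - 1L else L - w - (hit - 1L)
    data.frame(motif_id = lom$motif_id,
               tf_names = paste(lom$tf_names, collapse = ","),
               family = lom$family, offset = off, strand = strand,
               score = sc[hit], stringsAsFactors = FALSE)
  }
  out <- list()
  if (strands %in% c("both", "+")) out$fwd <- do_strand(seq, "+")
  if (strands %in% c("both", "-")) out$rev <- do_strand(revcomp(seq), "-")
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty_hit_frame())
  rownames(res) <- NULL
  res
}

empty_hit_frame <- function() {
  data.frame(motif_id = character(), tf_names = character(),
             family = character(), offset = integer(), strand = character(),
             score = numeric(), stringsAsFactors = FALSE)
}

#' Scan a set of patterns against a motif library
#'
#' Runs [scan_pattern()] for every (pattern, motif) pair and concatenates
#' the hits with a deterministic ordering (pattern, offset, motif, strand).
#' The counting unit for downstream summaries is one (motif, offset, strand)
#' triple; the TFs mapped to a motif multiply TF-level tallies only.
#'
#' @param patterns pattern data frame (needs `pattern_id`, `sequence`).
#' @param library list of `motif_model`s from [read_cisbp_library()].
#' @param threshold,min_width,strands,background,pseudocount scan parameters,
#'   see [scan_pattern()] and [pwm_to_logodds()].
#' @return data frame of hits with a leading `pattern_id` column.
#' @export
scan_all <- function(patterns, library, threshold = 10, min_width = 10L,
                     strands = "both", background = rep(0.25, 4),
                     pseudocount = 0.01) {
  loms <- lapply(library, pwm_to_logodds, background = background,
                 pseudocount = pseudocount)
  out <- list()
  for (i in seq_len(nrow(patterns))) {
    for (lom in loms) {
      h <- scan_pattern(patterns$sequence[i], lom, threshold = threshold,
                        min_width = min_width, strands = strands)
      if (nrow(h)) {
        h$pattern_id <- patterns$pattern_id[i]
        out[[length(out) + 1L]] <- h
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(cbind(data.frame(pattern_id = character(), stringsAsFactors = FALSE),
                 empty_hit_frame()))
  }
  res <- res[c("pattern_id", "motif_id", "tf_names", "family", "offset",
               "strand", "score")]
  res <- res[order(res$pattern_id, res$offset, res$motif_id, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Write a TFBS hit table
#'
#' Offsets are 1-based in the written file.
#'
#' @param hits hit data frame from [scan_all()].
#' @param patterns pattern data frame (for the gene column).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_tfbs_table <- function(hits, patterns, path) {
  gene <- patterns$gene_id[match(hits$pattern_id, patterns$pattern_id)]
  tab <- cbind(data.frame(pattern_id = hits$pattern_id, gene = gene,
                          stringsAsFactors = FALSE),
               hits[c("motif_id", "tf_names", "family", "strand", "score")])
  tab$offset <- hits$offset + 1L
  tab <- tab[c("pattern_id", "gene", "motif_id", "tf_names", "family",
               "offset", "strand", "score")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# offset: 1-based within pattern sequence", con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
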