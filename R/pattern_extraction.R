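#' Which alignment columns are 100% conserved?
#'
#' A column counts as fully conserved only when a single nucleotide (never a
#' gap or N) is present in every row.
#'
#' @param pssm a `pssm`.
#' @return logical vector over columns.
#' @export
conserved_columns <- function(pssm) {
  nt <- pssm$counts[c("A", "C", "G", "T"), , drop = FALSE]
  apply(nt == pssm$n_rows, 2L, any)
}

#' Extract maximal fully conserved patterns from an alignment
#'
#' Scans the position score matrix for maximal runs of 100%-conserved
#' columns (one nucleotide in every row; gaps and N disqualify a column) and
#' keeps runs of at least `min_len` columns. Each run is emitted whole, with
#' its alignment interval (0-based half-open), its sequence, and for every
#' species the 0-based ungapped start of the identical subsequence.
#'
#' @param pssm `pssm` built from `msa`.
#' @param msa the `msa_block`.
#' @param min_len minimum pattern length in nucleotides (default 15, chosen
#'   to exclude chance identity and retain binding-site-sized elements).
#' @return data frame of patterns sorted by `aln_start`, with a
#'   `species_starts` list column; zero rows when nothing qualifies.
#' @export
extract_conserved_patterns <- function(pssm, msa, min_len = 15L) {
  stopifnot(inherits(pssm, "pssm"), inherits(msa, "msa_block"),
            pssm$length == msa$length)
  cons <- conserved_columns(pssm)
  runs <- runs_of(cons, min_len)
  chars <- seq_char_matrix(msa$rows)
  # ungapped offset of each column within each row
  before <- apply(chars != "-", 1L, cumsum)          # length x n_rows
  if (is.null(dim(before))) before <- matrix(before, ncol = nrow(chars))
  out <- lapply(seq_len(nrow(runs)), function(i) {
    s <- runs$start[i]; e <- runs$end[i]            # 0-based half-open
    seqch <- chars[1L, (s + 1L):e]
    starts <- before[s + 1L, ] - 1L                 # 0-based ungapped starts
    names(starts) <- rownames(chars)
    data.frame(
      pattern_id = sprintf("%s_%s%d_%d", pssm$gene_id, pssm$region_kind,
                           pssm$ordinal, s),
      gene_id = pssm$gene_id, region_kind = pssm$region_kind,
      ordinal = pssm$ordinal, aln_start = s, aln_end = e, length = e - s,
      sequence = paste(seqch, collapse = ""),
      species_starts = I(list(starts)),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_pattern_frame()
  res
}

empty_pattern_frame <- function() {
  data.frame(pattern_id = character(), gene_id = character(),
             region_kind = character(), ordinal = integer(),
             aln_start = integer(), aln_end = integer(), length = integer(),
             sequence = character(), species_starts = I(list()),
             stringsAsFactors = FALSE)
}

# Maximal runs of TRUE of length >= min_len; 0-based half-open intervals.
runs_of <- function(flag, min_len) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

#' Sample matched non-conserved control sequences
#'
#' Controls are drawn from the maximal runs of columns that are *not* 100%
#' conserved, mirroring the conserved-pattern extraction with the condition
#' inverted. Runs of at least `min_len` usable columns are enumerated (a
#' usable column has a nucleotide plurality; gap-majority columns split
#' runs), `min(n, available)` runs are sampled without replacement with
#' probability proportional to run length, and each sampled run contributes
#' one uniformly placed sub-window whose length is drawn uniformly from
#' `[min_len, run length]`. The control sequence reads the per-column
#' majority nucleotide (ties broken alphabetically). Sampling is
#' reproducible under `seed`.
#'
#' @param pssm,msa as in [extract_conserved_patterns()].
#' @param n number of controls requested.
#' @param min_len minimum control length (default 15).
#' @param seed integer seed (required: controls are part of the analysis and
#'   must be reproducible).
#' @return data frame like the pattern frame plus an `rng_seed` column;
#'   warns when fewer than `n` controls exist.
#' @export
extract_nonconserved_controls <- function(pssm, msa, n, min_len = 15L, seed) {
  stopifnot(inherits(pssm, "pssm"), inherits(msa, "msa_block"))
  if (missing(seed)) stop("`seed` is required for control sampling")
  if (n < 0L) stop("`n` must be >= 0")
  nt <- pssm$counts[c("A", "C", "G", "T"), , drop = FALSE]
  gap <- pssm$counts["-", ]
  usable <- !conserved_columns(pssm) &
    apply(nt, 2L, max) > 0L & gap < pssm$n_rows / 2
  runs <- runs_of(usable, min_len)
  if (n == 0L) return(cbind(empty_pattern_frame(), rng_seed = integer()))
  if (nrow(runs) < n) {
    warning(sprintf("only %d non-conserved runs of >= %d columns available (%d requested)",
                    nrow(runs), min_len, n), call. = FALSE)
  }
  if (nrow(runs) == 0L) return(cbind(empty_pattern_frame(), rng_seed = integer()))
  majority <- rownames(nt)[apply(nt, 2L, which.max)]   # ties: alphabetical
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  k <- min(n, nrow(runs))
  pick <- sample.int(nrow(runs), k, replace = FALSE,
                     prob = runs$end - runs$start)
  out <- lapply(sort(pick), function(i) {
    s0 <- runs$start[i]; e0 <- runs$end[i]
    len <- e0 - s0
    w <- if (len == min_len) min_len else sample(seq.int(min_len, len), 1L)
    s <- if (len == w) s0 else s0 + sample.int(len - w + 1L, 1L) - 1L
    data.frame(
      pattern_id = sprintf("ctrl_%s_%s%d_%d", pssm$gene_id, pssm$region_kind,
                           pssm$ordinal, s),
      gene_id = pssm$gene_id, region_kind = pssm$region_kind,
      ordinal = pssm$ordinal, aln_start = s, aln_end = s + w, length = w,
      sequence = paste(majority[(s + 1L):(s + w)], collapse = ""),
      species_starts = I(list(NULL)),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  res$rng_seed <- as.integer(seed)
  res
}

#' Group patterns by their ordinal position
#'
#' @param patterns pattern data frame.
#' @return named list, one data frame per ordinal ("1", "2", ...), in
#'   increasing ordinal order; empty list for empty input.
#' @export
group_by_ordinal <- function(patterns) {
  if (nrow(patterns) == 0L) return(list())
  split(patterns, factor(patterns$ordinal, levels = sort(unique(patterns$ordinal))))
}

#' Normalise per-ordinal pattern counts
#'
#' Corrects raw counts for the unequal number of genes containing each
#' intron and for total sequence length: `per_gene = count / genes` and
#' `per_kb = count / (total length in kb)`.
#'
#' @param groups output of [group_by_ordinal()] (or a named vector of counts).
#' @param genes_per_ordinal named numeric: number of genes containing each
#'   ordinal.
#' @param length_per_ordinal named numeric: total sequence length (nt) per
#'   ordinal.
#' @return data frame with columns ordinal, n_patterns, per_gene, per_kb;
#'   ordinals lacking a denominator are omitted with a warning.
#' @export
normalize_counts <- function(groups, genes_per_ordinal, length_per_ordinal) {
  counts <- if (is.list(groups)) vapply(groups, nrow, integer(1L)) else groups
  ords <- names(counts)
  have <- ords %in% names(genes_per_ordinal) & ords %in% names(length_per_ordinal)
  if (any(!have)) {
    warning("no denominator for ordinal(s): ", paste(ords[!have], collapse = ", "),
            "; omitted", call. = FALSE)
  }
  ords <- ords[have]
  g <- genes_per_ordinal[ords]; l <- length_per_ordinal[ords]
  if (any(g <= 0) || any(l <= 0)) stop("denominators must be > 0")
  data.frame(ordinal = as.integer(ords), n_patterns = as.integer(counts[ords]),
             per_gene = as.numeric(counts[ords] / g),
             per_kb = as.numeric(counts[ords] / (l / 1000)),
             stringsAsFactors = FALSE)
}

#' Per-region conservation percentages
#'
#' Fraction of each region's alignment covered by conserved patterns, the
#' unit of observation for the between-intron rank tests.
#'
#' @param patterns pattern data frame (possibly several regions).
#' @param region_lengths data frame with gene_id, ordinal, length (alignment
#'   columns).
#' @return data frame gene_id, ordinal, pct_conserved in [0, 100]. Regions
#'   with no patterns get 0.
#' @export
conservation_fractions <- function(patterns, region_lengths) {
  key <- paste(region_lengths$gene_id, region_lengths$ordinal)
  covered <- numeric(length(key))
  if (nrow(patterns) > 0L) {
    agg <- stats::aggregate(patterns$length,
                            by = list(key = paste(patterns$gene_id, patterns$ordinal)),
                            FUN = sum)
    covered[match(agg$key, key)] <- agg$x
  }
  data.frame(gene_id = region_lengths$gene_id, ordinal = region_lengths$ordinal,
             pct_conserved = 100 * covered / region_lengths$length,
             stringsAsFactors = FALSE)
}
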