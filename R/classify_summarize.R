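#' Classify patterns by their regulatory-element content
#'
#' Four mutually exclusive groups: `TFBS` (binding-site hits only),
#' `TFBS_SS` (both binding-site and splice hits), `SS` (splice hits only),
#' `NOT_IDENTIFIED` (neither).
#'
#' @param patterns pattern data frame.
#' @param tfbs_hits hit data frame from [scan_all()].
#' @param splice_hits hit data frame from [scan_splice_all()].
#' @return named character vector, one class per `pattern_id`.
#' @export
classify_patterns <- function(patterns, tfbs_hits, splice_hits) {
  dangling <- setdiff(c(tfbs_hits$pattern_id, splice_hits$pattern_id),
                      patterns$pattern_id)
  if (length(dangling)) {
    stop("hits reference unknown pattern(s): ",
         paste(utils::head(dangling, 3L), collapse = ", "))
  }
  has_tfbs <- patterns$pattern_id %in% tfbs_hits$pattern_id
  has_ss <- patterns$pattern_id %in% splice_hits$pattern_id
  cls <- ifelse(has_tfbs & has_ss, "TFBS_SS",
                ifelse(has_tfbs, "TFBS",
                       ifelse(has_ss, "SS", "NOT_IDENTIFIED")))
  stats::setNames(cls, patterns$pattern_id)
}

#' Per-intron frequency summary from integer counts
#'
#' The arithmetic core of the per-ordinal summary: given per-ordinal counts
#' of patterns, patterns-with-TFBS and patterns-with-SS, appends a totals
#' row and integer percentage columns (`pct_tfbs`, `pct_ss`), rounded half
#' up.
#'
#' @param counts data frame with columns `ordinal`, `n_patterns`, `n_tfbs`,
#'   `n_ss` (one row per ordinal).
#' @return data frame with the same columns plus `pct_tfbs`, `pct_ss` and a
#'   final `"total"` row.
#' @export
summarize_counts <- function(counts) {
  need <- c("ordinal", "n_patterns", "n_tfbs", "n_ss")
  stopifnot(all(need %in% names(counts)))
  counts <- counts[order(counts$ordinal), need]
  if (any(counts$n_tfbs > counts$n_patterns) ||
      any(counts$n_ss > counts$n_patterns)) {
    stop("element-positive counts exceed pattern counts")
  }
  tot <- data.frame(ordinal = "total",
                    n_patterns = sum(counts$n_patterns),
                    n_tfbs = sum(counts$n_tfbs), n_ss = sum(counts$n_ss))
  counts$ordinal <- as.character(counts$ordinal)
  out <- rbind(counts, tot)
  pct <- function(num, den) ifelse(den > 0, round_half_up(100 * num / den), NA)
  out$pct_tfbs <- pct(out$n_tfbs, out$n_patterns)
  out$pct_ss <- pct(out$n_ss, out$n_patterns)
  out
}

#' Build the per-intron summary table
#'
#' A pattern counts toward the TFBS column when its class is `TFBS` or
#' `TFBS_SS`, and toward the SS column when its class is `SS` or `TFBS_SS`;
#' class counts per ordinal are carried alongside.
#'
#' @param groups output of [group_by_ordinal()].
#' @param classes named class vector from [classify_patterns()].
#' @return data frame: ordinal, n_patterns, n_tfbs, n_ss, pct_tfbs, pct_ss,
#'   n_class_tfbs, n_class_tfbs_ss, n_class_ss, n_class_not_identified,
#'   with a totals row.
#' @export
build_summary <- function(groups, classes) {
  rows <- lapply(names(groups), function(ord) {
    cls <- unname(classes[groups[[ord]]$pattern_id])
    if (anyNA(cls)) stop("unclassified pattern(s) in ordinal ", ord)
    data.frame(ordinal = ord,
               n_patterns = length(cls),
               n_tfbs = sum(cls %in% c("TFBS", "TFBS_SS")),
               n_ss = sum(cls %in% c("SS", "TFBS_SS")),
               n_class_tfbs = sum(cls == "TFBS"),
               n_class_tfbs_ss = sum(cls == "TFBS_SS"),
               n_class_ss = sum(cls == "SS"),
               n_class_not_identified = sum(cls == "NOT_IDENTIFIED"),
               stringsAsFactors = FALSE)
  })
  counts <- do.call(rbind, rows)
  if (is.null(counts)) {
    counts <- data.frame(ordinal = character(), n_patterns = integer(),
                         n_tfbs = integer(), n_ss = integer(),
                         n_class_tfbs = integer(), n_class_tfbs_ss = integer(),
                         n_class_ss = integer(),
                         n_class_not_identified = integer())
  }
  base <- summarize_counts(counts[c("ordinal", "n_patterns", "n_tfbs", "n_ss")])
  cls_cols <- c("n_class_tfbs", "n_class_tfbs_ss", "n_class_ss",
                "n_class_not_identified")
  cls <- rbind(counts[cls_cols],
               as.data.frame(as.list(colSums(counts[cls_cols]))))
  cbind(base, cls)
}

#' Tally binding-site hits by binding-domain family
#'
#' Counts hits at the site level (one per (motif, offset, strand) triple,
#' which is how the hit table is laid out) per binding-domain family and
#' reports the ten most populous families, ties broken alphabetically.
#'
#' @param tfbs_hits hit data frame.
#' @param top_k how many leading families to flag (default 10).
#' @param nr_label family label treated as the nuclear-receptor class
#'   (default "Nuclear receptor").
#' @return data frame family, n_tfbs, rank, top (logical), nr (logical),
#'   sorted by decreasing count then family name.
#' @export
tally_families <- function(tfbs_hits, top_k = 10L, nr_label = "Nuclear receptor") {
  if (nrow(tfbs_hits) == 0L) {
    return(data.frame(family = character(), n_tfbs = integer(),
                      rank = integer(), top = logical(), nr = logical(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(tfbs_hits$family)
  out <- data.frame(family = names(tab), n_tfbs = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_tfbs, out$family), ]
  out$rank <- seq_len(nrow(out))
  out$top <- out$rank <= top_k
  out$nr <- out$family %in% nr_label
  rownames(out) <- NULL
  out
}

#' Nuclear-receptor cluster report
#'
#' For every gene region whose patterns carry hits from motifs of a
#' nuclear-receptor binding-domain family, lists the deduplicated, sorted
#' nuclear-receptor gene symbols inferred to bind there — the evidence used
#' to read crosstalk between endocrine systems off the hit table.
#'
#' @param tfbs_hits hit data frame (needs family and comma-joined tf_names).
#' @param patterns pattern data frame (maps pattern ids to gene regions).
#' @param nr_family_labels family labels that count as nuclear receptor
#'   (default `"Nuclear receptor"`).
#' @return data frame gene, location (e.g. "Intron 1"), receptors
#'   (comma-joined sorted symbols); zero rows when no NR-family hits exist.
#' @export
nr_cluster_report <- function(tfbs_hits, patterns,
                              nr_family_labels = "Nuclear receptor") {
  hits <- tfbs_hits[tfbs_hits$family %in% nr_family_labels, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(data.frame(gene = character(), location = character(),
                      receptors = character(), stringsAsFactors = FALSE))
  }
  m <- match(hits$pattern_id, patterns$pattern_id)
  hits$gene <- patterns$gene_id[m]
  hits$location <- paste0(ifelse(patterns$region_kind[m] == "intron",
                                 "Intron ", "Exon "), patterns$ordinal[m])
  keys <- unique(hits[c("gene", "location")])
  keys <- keys[order(keys$gene, keys$location), , drop = FALSE]
  keys$receptors <- vapply(seq_len(nrow(keys)), function(i) {
    sel <- hits$gene == keys$gene[i] & hits$location == keys$location[i]
    tfs <- unlist(strsplit(hits$tf_names[sel], ",", fixed = TRUE))
    paste(sort(unique(tfs)), collapse = ",")
  }, character(1L))
  rownames(keys) <- NULL
  keys
}
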