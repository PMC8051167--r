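#' Significance stars for a p-value
#'
#' `ns` for p >= 0.05, then `*` < 0.05, `**` < 0.01, `***` < 0.001,
#' `****` < 0.0001.
#'
#' @param p p-value(s) in [0, 1].
#' @return character vector of star annotations.
#' @export
signif_stars <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  cut_pts <- c(0, 1e-4, 1e-3, 1e-2, 5e-2, 1)
  labs <- c("****", "***", "**", "*", "ns")
  labs[findInterval(p, cut_pts, rightmost.closed = TRUE)]
}

#' Pairwise Mann-Whitney tests of conservation between introns
#'
#' Compares the per-gene conservation values of every pair of intron groups
#' with the two-sided Mann-Whitney U (rank-sum) test; exact p-values for
#' small tie-free samples, normal approximation otherwise (the standard
#' [stats::wilcox.test()] behaviour).
#'
#' @param groups named list of numeric vectors, one per intron group (e.g.
#'   per-gene conservation percentages from [conservation_fractions()]).
#' @return list with `results` (long data frame: group1, group2, n1, n2,
#'   statistic U, p_value, stars) and `p_matrix` (symmetric matrix of
#'   p-values, 1 on the diagonal).
#' @export
mannwhitney_conservation <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(!vapply(groups, length, 1L))) stop("empty group")
  ids <- names(groups) %||% as.character(seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    wt <- suppressWarnings(stats::wilcox.test(groups[[i]], groups[[j]],
                                              alternative = "two.sided"))
    data.frame(group1 = ids[i], group2 = ids[j],
               n1 = length(groups[[i]]), n2 = length(groups[[j]]),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               stars = signif_stars(wt$p.value), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  pm <- matrix(1, length(groups), length(groups), dimnames = list(ids, ids))
  for (k in seq_len(nrow(res))) {
    pm[res$group1[k], res$group2[k]] <- res$p_value[k]
    pm[res$group2[k], res$group1[k]] <- res$p_value[k]
  }
  list(results = res, p_matrix = pm)
}

#' Chi-square tests of the four-class distribution per intron
#'
#' Tests, for each intron, whether its observed TFBS / TFBS-SS / SS /
#' not-identified class counts follow the expected class distribution. The
#' expected proportions default to the pooled distribution across all
#' introns (override with `expected` for, e.g., a uniform null). When any
#' expected cell in an intron falls below 1, the SS class is collapsed into
#' TFBS-SS for that intron with a warning; a zero expected cell after
#' collapsing is an error.
#'
#' @param observed matrix or data frame of counts, rows = introns, columns
#'   = the four classes (`TFBS`, `TFBS_SS`, `SS`, `NOT_IDENTIFIED`).
#' @param expected optional expected proportions (length = n classes,
#'   summing to 1); default pooled column sums.
#' @return data frame: ordinal, statistic, df, p_value, stars, collapsed.
#' @export
chisq_class_distribution <- function(observed, expected = NULL) {
  obs <- as.matrix(observed)
  if (is.null(expected)) {
    expected <- colSums(obs) / sum(obs)
  }
  if (abs(sum(expected) - 1) > 1e-8) stop("`expected` must sum to 1")
  cls <- colnames(obs)
  rows <- lapply(seq_len(nrow(obs)), function(i) {
    o <- obs[i, ]; p <- expected
    collapsed <- FALSE
    if (any(p * sum(o) < 1) && all(c("SS", "TFBS_SS") %in% cls)) {
      warning("intron ", rownames(obs)[i] %||% i,
              ": expected cell < 1; collapsing SS into TFBS_SS", call. = FALSE)
      keep <- setdiff(cls, "SS")
      o2 <- o[keep]; o2["TFBS_SS"] <- o2["TFBS_SS"] + o["SS"]
      p2 <- p[keep]; p2["TFBS_SS"] <- p2["TFBS_SS"] + p["SS"]
      o <- o2; p <- p2
      collapsed <- TRUE
    }
    if (any(p * sum(o) == 0)) stop("zero expected cell after collapsing")
    ct <- suppressWarnings(stats::chisq.test(o, p = p))
    data.frame(ordinal = rownames(obs)[i] %||% as.character(i),
               statistic = unname(ct$statistic),
               df = unname(ct$parameter), p_value = ct$p.value,
               stars = signif_stars(ct$p.value), collapsed = collapsed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired Wilcoxon test of element counts, conserved vs control
#'
#' Two-sided Wilcoxon signed-rank test on paired per-region element counts
#' (e.g. number of binding-site hits in the conserved patterns of a region
#' vs in its matched non-conserved controls). Zero differences are dropped,
#' as in the standard signed-rank procedure.
#'
#' @param conserved_counts,control_counts equal-length paired numeric
#'   vectors.
#' @return one-row data frame: test, n_pairs (nonzero differences),
#'   statistic V, p_value, stars.
#' @export
wilcoxon_paired_counts <- function(conserved_counts, control_counts) {
  if (length(conserved_counts) != length(control_counts)) {
    stop("paired vectors must have equal length")
  }
  d <- conserved_counts - control_counts
  if (all(d == 0)) stop("all paired differences are zero; test undefined")
  wt <- suppressWarnings(stats::wilcox.test(conserved_counts, control_counts,
                                            paired = TRUE,
                                            alternative = "two.sided"))
  data.frame(test = "wilcoxon_paired", n_pairs = sum(d != 0),
             statistic = unname(wt$statistic), p_value = wt$p.value,
             stars = signif_stars(wt$p.value), stringsAsFactors = FALSE)
}
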