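#' Load a splice-site frequency matrix
#'
#' A splice matrix is a TSV with one row per position and columns A, C, G, T
#' holding nucleotide frequencies (each row sums to 1 within 1e-3 after an
#' optional common rescaling — the consensus value is invariant to a
#' positive constant factor). The packaged defaults
#' (`donor_synthetic.tsv`, width 9 = 3 exonic + 6 intronic positions, and
#' `acceptor_synthetic.tsv`, width 14) are synthetic matrices constructed
#' around the canonical mammalian consensus (MAG|GTRAGT donor;
#' polypyrimidine tract + NCAG|G acceptor) and are user-replaceable.
#'
#' @param path matrix TSV; or `"donor"` / `"acceptor"` for the packaged
#'   defaults.
#' @param site_type `"donor"` or `"acceptor"`.
#' @return a `splice_matrix` object with fields `site_type`, `freq`
#'   (width x 4), `width`, `source`.
#' @export
read_splice_matrix <- function(path, site_type = c("donor", "acceptor")) {
  site_type <- match.arg(site_type)
  if (path %in% c("donor", "acceptor")) {
    path <- system.file("extdata", "splice", paste0(path, "_synthetic.tsv"),
                        package = "crescan", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("A", "C", "G", "T")
  if (!all(need %in% names(tab))) stop("splice matrix needs columns A C G T")
  m <- as.matrix(tab[, need])
  rs <- rowSums(m)
  if (any(rs <= 0)) stop("splice matrix row with non-positive sum")
  splice_matrix(m / rs, site_type, source = basename(path))
}

#' Construct a splice matrix from a frequency matrix
#'
#' @param freq width x 4 matrix of per-position frequencies (columns
#'   A,C,G,T), rows summing to 1 within 1e-3.
#' @param site_type `"donor"` or `"acceptor"`.
#' @param source free-text provenance label.
#' @return a `splice_matrix`.
#' @export
splice_matrix <- function(freq, site_type = c("donor", "acceptor"),
                          source = "user") {
  site_type <- match.arg(site_type)
  freq <- as.matrix(freq)
  if (ncol(freq) != 4L) stop("`freq` must have 4 columns")
  colnames(freq) <- c("A", "C", "G", "T")
  if (any(abs(rowSums(freq) - 1) > 1e-3)) {
    stop("splice matrix rows must sum to 1 within 1e-3")
  }
  structure(list(site_type = site_type, freq = freq, width = nrow(freq),
                 source = source),
            class = "splice_matrix")
}

#' The packaged default donor + acceptor matrices
#'
#' @return named list with elements `donor` and `acceptor`.
#' @export
default_splice_matrices <- function() {
  list(donor = read_splice_matrix("donor", "donor"),
       acceptor = read_splice_matrix("acceptor", "acceptor"))
}

#' Consensus value of a window against a splice matrix
#'
#' The min-max-normalised sum of per-position frequencies, scaled to 0-100:
#' with `t = sum_i freq_i(window_i)` and `t_min`/`t_max` the sums of the
#' per-position minima/maxima, `CV = 100 * (t - t_min) / (t_max - t_min)`.
#' The window spelling the per-position most-frequent base everywhere scores
#' exactly 100; the least-frequent everywhere scores 0.
#'
#' @param window DNA string of the matrix width, no N.
#' @param mat a `splice_matrix`.
#' @return score in [0, 100].
#' @export
consensus_value <- function(window, mat) {
  stopifnot(inherits(mat, "splice_matrix"))
  if (nchar(window) != mat$width) {
    stop(sprintf("window width %d does not match matrix width %d",
                 nchar(window), mat$width))
  }
  idx <- dna_to_int(window)
  if (anyNA(idx)) stop("window contains non-ACGT characters")
  t_val <- sum(mat$freq[cbind(seq_len(mat$width), idx)])
  t_min <- sum(apply(mat$freq, 1L, min))
  t_max <- sum(apply(mat$freq, 1L, max))
  100 * (t_val - t_min) / (t_max - t_min)
}

#' Load a maximum-entropy splice model from a directory
#'
#' The model directory contract: each table is a TSV named
#' `<site_type>_<start>_<end>.tsv` with columns `kmer` and `score` (log2
#' units), where `start`..`end` are 1-based positions within the scoring
#' window. A site type's window width is the largest `end` among its
#' tables; the score of a window is the sum of the table lookups of its
#' sub-k-mers (a single full-width table is the unfactored special case).
#' A k-mer absent from a table scores `-Inf`, i.e. can never be called.
#'
#' @param dir model directory.
#' @return a `maxent_model`: per site type, a list of tables
#'   `(start, end, scores)` plus the window width; site types with no
#'   tables are absent.
#' @export
read_maxent_model <- function(dir) {
  files <- list.files(dir, pattern = "^(donor|acceptor)_\\d+_\\d+\\.tsv$",
                      full.names = TRUE)
  if (!length(files)) stop("no maxent tables found in ", dir)
  model <- list()
  for (f in files) {
    parts <- strsplit(sub("\\.tsv$", "", basename(f)), "_")[[1L]]
    st <- parts[1L]; from <- as.integer(parts[2L]); to <- as.integer(parts[3L])
    tab <- utils::read.delim(f, stringsAsFactors = FALSE)
    if (!all(c("kmer", "score") %in% names(tab))) {
      stop("maxent table needs columns kmer, score: ", f)
    }
    scores <- stats::setNames(as.numeric(tab$score), toupper(tab$kmer))
    model[[st]]$tables <- c(model[[st]]$tables,
                            list(list(start = from, end = to, scores = scores)))
    model[[st]]$width <- max(model[[st]]$width %||% 0L, to)
  }
  structure(model, class = "maxent_model")
}

#' Maximum-entropy score of a window
#'
#' @param window DNA string matching the model width for `site_type`.
#' @param model a `maxent_model`.
#' @param site_type `"donor"` or `"acceptor"`.
#' @return score in log2 units; `-Inf` when any sub-k-mer is absent from its
#'   table.
#' @export
maxent_score <- function(window, model, site_type = c("donor", "acceptor")) {
  site_type <- match.arg(site_type)
  sub <- model[[site_type]]
  if (is.null(sub)) stop("model has no tables for site type ", site_type)
  if (nchar(window) != sub$width) {
    stop(sprintf("window width %d does not match model width %d",
                 nchar(window), sub$width))
  }
  total <- 0
  for (tb in sub$tables) {
    k <- substr(window, tb$start, tb$end)
    s <- tb$scores[k]
    if (is.na(s)) return(-Inf)
    total <- total + s
  }
  unname(total)
}

#' Scan a pattern sequence for donor/acceptor splice signals
#'
#' Every window position is tested for both site types. A window is called
#' by the consensus-value scorer when `CV >= cv_threshold` and by the
#' maximum-entropy scorer (when a model is supplied) when
#' `score >= maxent_threshold`. Under `ss_rule = "any"` (default) a hit is
#' emitted when either scorer calls it; under `"all"` both must call the
#' same site type at the same offset (requires a model whose window width
#' equals the matrix width; without a model, `"all"` degrades to
#' consensus-only with a warning). Windows containing N are skipped.
#'
#' @param seq DNA string to scan.
#' @param matrices list with `donor` and/or `acceptor` [splice_matrix()]s.
#' @param model optional `maxent_model`.
#' @param cv_threshold consensus-value call threshold (default 75; raised
#'   from the scorer's historical 65 for higher confidence calls).
#' @param maxent_threshold maximum-entropy call threshold in log2 units
#'   (default 3).
#' @param ss_rule `"any"` or `"all"`.
#' @return data frame with site_type, offset (0-based window start), cv,
#'   maxent (NA when not scored), called_by.
#' @export
scan_splice <- function(seq, matrices = default_splice_matrices(),
                        model = NULL, cv_threshold = 75, maxent_threshold = 3,
                        ss_rule = c("any", "all")) {
  ss_rule <- match.arg(ss_rule)
  if (ss_rule == "all" && is.null(model)) {
    warning("ss_rule = 'all' without a maxent model: using consensus calls only",
            call. = FALSE)
    ss_rule <- "any"
  }
  idx <- dna_to_int(seq)
  L <- length(idx)
  out <- list()
  for (st in names(matrices)) {
    mat <- matrices[[st]]
    cv_hits <- data.frame(offset = integer(), cv = numeric())
    if (L >= mat$width) {
      t_min <- sum(apply(mat$freq, 1L, min))
      t_max <- sum(apply(mat$freq, 1L, max))
      for (j in 0:(L - mat$width)) {
        win <- idx[(j + 1L):(j + mat$width)]
        if (anyNA(win)) next
        t_val <- sum(mat$freq[cbind(seq_len(mat$width), win)])
        cv <- 100 * (t_val - t_min) / (t_max - t_min)
        if (cv >= cv_threshold) {
          cv_hits <- rbind(cv_hits, data.frame(offset = j, cv = cv))
        }
      }
    }
    me_hits <- data.frame(offset = integer(), maxent = numeric())
    if (!is.null(model) && !is.null(model[[st]]) && L >= model[[st]]$width) {
      wme <- model[[st]]$width
      for (j in 0:(L - wme)) {
        win <- substr(seq, j + 1L, j + wme)
        if (grepl("[^ACGT]", win)) next
        s <- maxent_score(win, model, st)
        if (is.finite(s) && s >= maxent_threshold) {
          me_hits <- rbind(me_hits, data.frame(offset = j, maxent = s))
        }
      }
    }
    offs <- sort(union(cv_hits$offset, me_hits$offset))
    for (o in offs) {
      in_cv <- o %in% cv_hits$offset
      in_me <- o %in% me_hits$offset
      keep <- if (ss_rule == "any") in_cv || in_me else in_cv && in_me
      if (!keep) next
      out[[length(out) + 1L]] <- data.frame(
        site_type = st, offset = o,
        cv = if (in_cv) cv_hits$cv[cv_hits$offset == o] else NA_real_,
        maxent = if (in_me) me_hits$maxent[me_hits$offset == o] else NA_real_,
        called_by = paste(c(if (in_cv) "HSF", if (in_me) "MaxEnt"),
                          collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(site_type = character(), offset = integer(),
                      cv = numeric(), maxent = numeric(),
                      called_by = character(), stringsAsFactors = FALSE))
  }
  res <- res[order(res$site_type, res$offset), ]
  rownames(res) <- NULL
  res
}

#' Scan all patterns for splice signals
#'
#' @param patterns pattern data frame.
#' @param ... passed to [scan_splice()].
#' @return hit data frame with a leading `pattern_id` column.
#' @export
scan_splice_all <- function(patterns, ...) {
  out <- list()
  for (i in seq_len(nrow(patterns))) {
    h <- scan_splice(patterns$sequence[i], ...)
    if (nrow(h)) {
      h <- cbind(data.frame(pattern_id = patterns$pattern_id[i],
                            stringsAsFactors = FALSE), h)
      out[[length(out) + 1L]] <- h
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(pattern_id = character(), site_type = character(),
                      offset = integer(), cv = numeric(), maxent = numeric(),
                      called_by = character(), stringsAsFactors = FALSE))
  }
  rownames(res) <- NULL
  res
}
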