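# Independent brute-force oracles. These deliberately use the most naive
# possible formulation (explicit loops, no shared helpers with the package)
# so that agreement with the implementation is meaningful.

# Per-column conservation scan: a column is conserved iff every row carries
# the same character and that character is one of A,C,G,T. Returns maximal
# runs of >= min_len conserved columns as 0-based half-open intervals.
oracle_conserved_runs <- function(rows, min_len) {
  L <- nchar(rows[[1L]])
  cons <- logical(L)
  for (j in seq_len(L)) {
    ch <- substr(rows[1L], j, j)
    same <- ch %in% c("A", "C", "G", "T")
    if (same) {
      for (r in rows[-1L]) {
        if (substr(r, j, j) != ch) { same <- FALSE; break }
      }
    }
    cons[j] <- same
  }
  starts <- integer(); ends <- integer()
  j <- 1L
  while (j <= L) {
    if (cons[j]) {
      k <- j
      while (k < L && cons[k + 1L]) k <- k + 1L
      if (k - j + 1L >= min_len) {
        starts <- c(starts, j - 1L); ends <- c(ends, k)
      }
      j <- k + 1L
    } else j <- j + 1L
  }
  data.frame(start = starts, end = ends)
}

# Naive double-loop PWM scan over both strands.
oracle_pwm_scan <- function(seq, scores, threshold, min_width) {
  w <- nrow(scores)
  if (w < min_width) return(data.frame(offset = integer(), strand = character(),
                                       score = numeric()))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  L <- nchar(seq)
  out <- data.frame(offset = integer(), strand = character(), score = numeric(),
                    stringsAsFactors = FALSE)
  if (L < w) return(out)
  for (j in 0:(L - w)) {
    for (strand in c("+", "-")) {
      total <- 0; ok <- TRUE
      for (i in seq_len(w)) {
        base <- if (strand == "+") substr(seq, j + i, j + i) else
          comp[[substr(seq, j + w - i + 1L, j + w - i + 1L)]]
        if (!base %in% colnames(scores)) { ok <- FALSE; break }
        total <- total + scores[i, base]
      }
      if (ok && total >= threshold) {
        out <- rbind(out, data.frame(offset = j, strand = strand,
                                     score = total, stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments,
# mirroring the convention of the standard exact test: double the smaller
# tail of the U distribution, capped at 1.
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2L, function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  })
  if (u_obs > n1 * n2 / 2) p <- 2 * mean(us >= u_obs) else p <- 2 * mean(us <= u_obs)
  min(p, 1)
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments of
# the nonzero differences.
oracle_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[seq_len(n)]
    vs[m + 1L] <- sum(r[signs == 1L])
  }
  if (v_obs > n * (n + 1) / 4) p <- 2 * mean(vs >= v_obs) else p <- 2 * mean(vs <= v_obs)
  min(p, 1)
}

# Random test alignment with a tunable per-column chance of full identity.
random_alignment <- function(n_rows, len, p_identical = 0.3,
                             species = paste0("sp", seq_len(n_rows))) {
  bases <- c("A", "C", "G", "T")
  cols <- vapply(seq_len(len), function(j) {
    if (stats::runif(1) < p_identical) rep(sample(bases, 1L), n_rows)
    else sample(bases, n_rows, replace = TRUE)
  }, character(n_rows))
  rows <- apply(cols, 1L, paste, collapse = "")
  names(rows) <- species
  msa_block(rows)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Random position-probability motif, moderately peaked.
random_motif <- function(id, width, family = "TestFam") {
  m <- matrix(stats::rgamma(width * 4L, shape = 0.6), ncol = 4L)
  m <- m / rowSums(m)
  motif_model(id, tf_names = paste0("TF_", id), family = family, matrix = m)
}

# A small 3-position splice matrix with hand-enterable frequencies.
toy_splice_matrix <- function(site_type = "donor") {
  freq <- rbind(c(0.5, 0.2, 0.2, 0.1),
                c(0.1, 0.6, 0.1, 0.2),
                c(0.25, 0.25, 0.25, 0.25))
  splice_matrix(freq, site_type, source = "toy")
}

# Write a toy maxent model directory; tables is a list of
# list(site, start, end, kmers = named scores).
write_toy_maxent <- function(dir, tables) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tb in tables) {
    path <- file.path(dir, sprintf("%s_%d_%d.tsv", tb$site, tb$start, tb$end))
    utils::write.table(data.frame(kmer = names(tb$kmers),
                                  score = unname(tb$kmers)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  dir
}
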