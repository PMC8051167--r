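make_msa5 <- function(...) {
  rows <- c(...)
  msa_block(setNames(rows, paste0("sp", seq_along(rows))),
            gene_id = "G1", region_kind = "intron", ordinal = 1L)
}

test_that("fully identical alignments give one whole-region pattern", {
  row <- random_dna(20L)
  msa <- make_msa5(rep(row, 5L))
  pats <- extract_conserved_patterns(build_pssm(msa), msa)
  expect_equal(nrow(pats), 1L)
  expect_equal(pats$aln_start, 0L)
  expect_equal(pats$aln_end, 20L)
  expect_equal(pats$length, 20L)
  expect_identical(pats$sequence, row)
})

test_that("a single central mismatch splits a region below the length floor", {
  row <- strrep("A", 20L)
  broken <- paste0(substr(row, 1, 10), "C", substr(row, 12, 20))
  msa <- make_msa5(c(rep(row, 4L), broken))
  pats <- extract_conserved_patterns(build_pssm(msa), msa)
  expect_equal(nrow(pats), 0L)
  # with a lower floor both flanking runs appear
  pats2 <- extract_conserved_patterns(build_pssm(msa), msa, min_len = 9L)
  expect_equal(pats2$aln_start, c(0L, 11L))
  expect_equal(pats2$length, c(10L, 9L))
})

test_that("gap and N columns break conserved runs and coordinates degap correctly", {
  # a gapped/mismatching column at position 3 splits the region; only the
  # 17-column run after it clears the length floor
  tail15 <- random_dna(15L)
  msa <- make_msa5(c(paste0("AC-GT", tail15),
                     paste0("ACCGT", tail15),
                     paste0("AC-GT", tail15)))
  pats <- extract_conserved_patterns(build_pssm(msa), msa)
  expect_equal(nrow(pats), 1L)
  expect_equal(pats$aln_start, 3L)
  expect_identical(pats$sequence, paste0("GT", tail15))
  starts <- pats$species_starts[[1L]]
  expect_equal(unname(starts), c(2L, 3L, 2L))  # gap rows have one fewer nt before
  # the invariant: each species' ungapped subsequence equals the pattern
  ungapped <- degap_msa(msa)
  for (s in names(starts)) {
    expect_identical(substr(ungapped[[s]], starts[[s]] + 1L,
                            starts[[s]] + pats$length), pats$sequence)
  }
})

test_that("extraction equals the naive per-column oracle on random alignments", {
  set.seed(2024)
  for (rep in 1:30) {
    msa <- random_alignment(5L, sample(30:400, 1L),
                            p_identical = runif(1, 0.5, 0.95))
    min_len <- sample(c(5L, 10L, 15L), 1L)
    pats <- extract_conserved_patterns(build_pssm(msa), msa, min_len = min_len)
    oracle <- oracle_conserved_runs(unname(msa$rows), min_len)
    expect_equal(pats$aln_start, oracle$start)
    expect_equal(pats$aln_end, oracle$end)
  }
})

test_that("planted blocks are recovered exactly from simulated alignments", {
  spec <- simulation_spec(n_genes = 6L, introns_per_gene = 2L,
                          intron_length = 400L, n_blocks = 8L,
                          n_motif_blocks = 0L, n_donor_blocks = 4L, seed = 99)
  sim <- simulate_ortholog_sets(spec)
  found <- do.call(rbind, lapply(sim$sets, function(os) {
    msa <- msa_from_ortholog_set(os)
    extract_conserved_patterns(build_pssm(msa), msa)
  }))
  key <- function(g, o, s, l) paste(g, o, s, l)
  expect_setequal(key(found$gene_id, found$ordinal, found$aln_start, found$length),
                  key(sim$truth$gene_id, sim$truth$ordinal,
                      sim$truth$block_start, sim$truth$block_length))
})

test_that("lowering min_len only adds patterns, raising it only removes them", {
  set.seed(31)
  msa <- random_alignment(5L, 500L, p_identical = 0.9)
  pssm <- build_pssm(msa)
  prev <- extract_conserved_patterns(pssm, msa, min_len = 5L)
  for (ml in c(10L, 15L, 25L)) {
    cur <- extract_conserved_patterns(pssm, msa, min_len = ml)
    expect_true(all(cur$pattern_id %in% prev$pattern_id))
    prev <- cur
  }
})

test_that("control sampling is seeded, in-bounds and disjoint from patterns", {
  set.seed(40)
  # block-structured alignment: identical segments separated by noise,
  # so both long conserved and long non-conserved runs exist
  noise <- function(len) unname(random_alignment(5L, len, p_identical = 0)$rows)
  ident <- function(len) rep(random_dna(len), 5L)
  parts <- list(ident(20L), noise(60L), ident(25L), noise(50L), ident(18L))
  rows <- setNames(do.call(paste0, parts), paste0("sp", 1:5))
  msa <- msa_block(rows, gene_id = "G1", region_kind = "intron", ordinal = 1L)
  pssm <- build_pssm(msa)
  pats <- extract_conserved_patterns(pssm, msa)
  expect_gte(nrow(pats), 3L)
  ctl <- suppressWarnings(extract_nonconserved_controls(pssm, msa, n = 2L, seed = 123))
  ctl2 <- suppressWarnings(extract_nonconserved_controls(pssm, msa, n = 2L, seed = 123))
  expect_gte(nrow(ctl), 2L)
  expect_identical(ctl$sequence, ctl2$sequence)
  expect_identical(ctl$aln_start, ctl2$aln_start)
  expect_true(all(ctl$length >= 15L))
  cons <- conserved_columns(pssm)
  for (i in seq_len(nrow(ctl))) {
    cols <- (ctl$aln_start[i] + 1L):ctl$aln_end[i]
    expect_true(all(!cons[cols]))     # every column < 100% conserved
  }
  # no overlap with any conserved pattern interval
  if (nrow(pats) && nrow(ctl)) {
    for (i in seq_len(nrow(ctl))) {
      expect_true(all(ctl$aln_end[i] <= pats$aln_start |
                        ctl$aln_start[i] >= pats$aln_end))
    }
  }
  # control letters are the column majority of the alignment
  chars <- do.call(rbind, strsplit(unname(msa$rows), ""))
  for (i in seq_len(min(3L, nrow(ctl)))) {
    expected <- vapply((ctl$aln_start[i] + 1L):ctl$aln_end[i], function(j) {
      tab <- table(factor(chars[, j], levels = c("A", "C", "G", "T")))
      names(tab)[which.max(tab)]
    }, character(1L))
    expect_identical(ctl$sequence[i], paste(expected, collapse = ""))
  }
})

test_that("a fully conserved alignment yields zero controls with a warning", {
  msa <- make_msa5(rep(random_dna(50L), 5L))
  pssm <- build_pssm(msa)
  expect_warning(ctl <- extract_nonconserved_controls(pssm, msa, n = 3L, seed = 1),
                 "available")
  expect_equal(nrow(ctl), 0L)
})

test_that("grouping by ordinal partitions the patterns", {
  pats <- rbind(
    data.frame(pattern_id = c("a", "b", "c"), gene_id = "G",
               region_kind = "intron", ordinal = c(1L, 1L, 3L),
               aln_start = 0L, aln_end = 15L, length = 15L, sequence = "x",
               stringsAsFactors = FALSE))
  g <- group_by_ordinal(pats)
  expect_identical(names(g), c("1", "3"))
  expect_equal(vapply(g, nrow, 1L), c("1" = 2L, "3" = 1L))
  expect_identical(group_by_ordinal(pats[0, ]), list())
})

test_that("count normalisation divides by genes and kilobases", {
  groups <- list("1" = data.frame(x = 1:10))
  out <- normalize_counts(groups, genes_per_ordinal = c("1" = 5),
                          length_per_ordinal = c("1" = 2000))
  expect_equal(out$per_gene, 2.0)
  expect_equal(out$per_kb, 5.0)
  expect_warning(out2 <- normalize_counts(groups, c("2" = 5), c("2" = 1000)),
                 "omitted")
  expect_equal(nrow(out2), 0L)
})

test_that("conservation fractions cover patterns and default to zero", {
  lens <- data.frame(gene_id = c("G1", "G2"), ordinal = 1L, length = 200L)
  pats <- data.frame(pattern_id = "p", gene_id = "G1", region_kind = "intron",
                     ordinal = 1L, aln_start = 0L, aln_end = 50L, length = 50L,
                     sequence = "x", stringsAsFactors = FALSE)
  cf <- conservation_fractions(pats, lens)
  expect_equal(cf$pct_conserved, c(25, 0))
})
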