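test_that("zero substitution yields identical species and whole-region patterns", {
  spec <- simulation_spec(n_genes = 2L, introns_per_gene = 1L,
                          intron_length = 100L, substitution_prob = 0,
                          n_blocks = 0L, n_motif_blocks = 0L,
                          n_donor_blocks = 0L, seed = 3)
  sim <- simulate_ortholog_sets(spec)
  expect_equal(nrow(sim$truth), 0L)
  for (os in sim$sets) {
    expect_length(unique(os$sequences), 1L)
    msa <- msa_from_ortholog_set(os)
    pats <- extract_conserved_patterns(build_pssm(msa), msa)
    expect_equal(nrow(pats), 1L)
    expect_equal(pats$length, 100L)
  }
})

test_that("a single planted block is recovered exactly at background 0.3", {
  blocks <- data.frame(gene = 1L, intron = 1L, offset = 120L, length = 20L,
                       element = "none", stringsAsFactors = FALSE)
  spec <- simulation_spec(n_genes = 1L, introns_per_gene = 1L,
                          intron_length = 500L, substitution_prob = 0.3,
                          planted_blocks = blocks, seed = 17)
  sim <- simulate_ortholog_sets(spec)
  expect_equal(nrow(sim$truth), 1L)
  msa <- msa_from_ortholog_set(sim$sets[[1L]])
  pats <- extract_conserved_patterns(build_pssm(msa), msa)
  expect_equal(pats$aln_start, 120L)
  expect_equal(pats$length, 20L)
})

test_that("simulation is byte-identical under a fixed seed", {
  spec <- simulation_spec(n_genes = 2L, introns_per_gene = 1L,
                          intron_length = 200L, n_blocks = 2L,
                          n_motif_blocks = 0L, n_donor_blocks = 1L, seed = 9)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_ortholog_fasta(simulate_ortholog_sets(spec)$sets[[1L]], f1)
  write_ortholog_fasta(simulate_ortholog_sets(spec)$sets[[1L]], f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("infeasible planting is rejected", {
  blocks <- data.frame(gene = 1L, intron = 1L, offset = 95L, length = 20L,
                       element = "none")
  spec <- simulation_spec(n_genes = 1L, introns_per_gene = 1L,
                          intron_length = 100L, planted_blocks = blocks,
                          seed = 1)
  expect_error(simulate_ortholog_sets(spec), "exceeds region")
  expect_error(simulation_spec(block_length = 10L, seed = 1), ">= 15")
})

test_that("the toy library writes a readable dump with sharp consensus motifs", {
  dir <- withr::local_tempdir()
  lib_spec <- simulate_toy_library(dir, seed = 21)
  info <- read.delim(lib_spec$info_path)
  expect_equal(length(unique(info$Motif_ID)), 10L)
  expect_true("Nuclear receptor" %in% info$Family_Name)
  lib <- read_cisbp_library(lib_spec$info_path, lib_spec$pwm_dir)
  expect_length(lib, 10L)
  # scanning a motif's consensus achieves its maximum score
  tr <- lib_spec$truth[1L, ]
  lom <- pwm_to_logodds(lib[[tr$motif_id]])
  hits <- scan_pattern(tr$consensus, lom, threshold = 0)
  expect_equal(max(hits$score), lom$max_score, tolerance = 1e-9)

  # a fully deterministic motif still round-trips
  dir2 <- withr::local_tempdir()
  lib2 <- simulate_toy_library(dir2, families = "Ets", sharpness = 1,
                               widths = 10L, seed = 2)
  m <- read_cisbp_library(lib2$info_path, file.path(dir2, "pwms"))[[1L]]
  expect_equal(sort(unique(as.vector(m$matrix))), c(0, 1))
})

test_that("planted elements drive the downstream classes exactly", {
  dir <- withr::local_tempdir()
  lib_spec <- simulate_toy_library(dir, seed = 31)
  lib <- read_cisbp_library(lib_spec$info_path, lib_spec$pwm_dir)
  spec <- simulation_spec(n_genes = 8L, introns_per_gene = 2L,
                          intron_length = 400L, n_blocks = 12L,
                          n_motif_blocks = 6L, n_donor_blocks = 3L, seed = 13)
  sim <- simulate_ortholog_sets(spec, library = lib)
  res <- run_pipeline(sim$sets, lib, config = run_config(seed = 13))
  expect_equal(nrow(res$patterns), 12L)
  truth_key <- paste(sim$truth$gene_id, sim$truth$ordinal, sim$truth$block_start)
  found_key <- paste(res$patterns$gene_id, res$patterns$ordinal,
                     res$patterns$aln_start)
  expect_setequal(found_key, truth_key)
  expected_class <- c(motif = "TFBS", donor = "SS", none = "NOT_IDENTIFIED")
  truth_cls <- expected_class[sim$truth$element[match(found_key, truth_key)]]
  expect_identical(unname(res$classes[res$patterns$pattern_id]),
                   unname(truth_cls))
  # the planted motif offset is covered by a reported hit
  motif_truth <- sim$truth[sim$truth$element == "motif", ]
  for (i in seq_len(nrow(motif_truth))) {
    pid <- res$patterns$pattern_id[res$patterns$gene_id == motif_truth$gene_id[i] &
                                     res$patterns$ordinal == motif_truth$ordinal[i]]
    h <- res$tfbs_hits[res$tfbs_hits$pattern_id == pid, ]
    local_off <- motif_truth$element_offset[i] - motif_truth$block_start[i]
    expect_true(any(h$motif_id == motif_truth$element_id[i] &
                      h$offset == local_off & h$strand == "+"))
  }
})
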