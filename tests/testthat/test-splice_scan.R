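test_that("consensus value is min-max normalised to [0, 100]", {
  mat <- toy_splice_matrix()
  # per-position maxima: A (0.5), C (0.6), any (0.25) -> best window "AC?"
  expect_equal(consensus_value("ACA", mat), 100)
  # per-position minima: T (0.1), G (0.1), any (0.25) -> worst window "TG?"
  expect_equal(consensus_value("TGC", mat), 0)
  # arbitrary window against a hand-computed sum
  t_val <- 0.2 + 0.1 + 0.25          # "C" 0.2, "G" 0.1, "T" 0.25
  t_min <- 0.1 + 0.1 + 0.25
  t_max <- 0.5 + 0.6 + 0.25
  expect_equal(consensus_value("CGT", mat),
               100 * (t_val - t_min) / (t_max - t_min), tolerance = 1e-9)
  expect_error(consensus_value("ACGT", mat), "width")
  expect_error(consensus_value("ACN", mat), "non-ACGT")
})

test_that("consensus value is invariant to a common scaling of the frequencies", {
  dir <- withr::local_tempdir()
  freq <- matrix(c(0.5, 0.2, 0.2, 0.1,
                   0.1, 0.6, 0.1, 0.2,
                   0.25, 0.25, 0.25, 0.25), nrow = 3L, byrow = TRUE,
                 dimnames = list(NULL, c("A", "C", "G", "T")))
  f1 <- file.path(dir, "m1.tsv"); f2 <- file.path(dir, "m2.tsv")
  write.table(cbind(Pos = 1:3, as.data.frame(freq)), f1, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cbind(Pos = 1:3, as.data.frame(freq * 80)), f2, sep = "\t",
              quote = FALSE, row.names = FALSE)
  m1 <- read_splice_matrix(f1, "donor")
  m2 <- read_splice_matrix(f2, "donor")
  for (w in c("ACG", "TTT", "CGT")) {
    expect_equal(consensus_value(w, m1), consensus_value(w, m2), tolerance = 1e-9)
  }
})

test_that("the packaged donor matrix gives CV 100 to the canonical consensus", {
  mats <- default_splice_matrices()
  expect_equal(mats$donor$width, 9L)
  expect_equal(mats$acceptor$width, 14L)
  # best instantiation of MAG|GTRAGT under the packaged frequencies
  best <- paste(c("A", "C", "G", "T")[apply(mats$donor$freq, 1L, which.max)],
                collapse = "")
  expect_identical(substr(best, 4L, 5L), "GT")   # invariant donor dinucleotide
  expect_equal(consensus_value(best, mats$donor), 100)
  expect_match(best, "^[AC]AGGT[AG]AGT$")        # an instance of MAGGTRAGT
})

test_that("maxent tables are looked up and combined additively", {
  dir <- write_toy_maxent(withr::local_tempdir(), list(
    list(site = "donor", start = 1L, end = 9L,
         kmers = c(CAGGTAAGT = 8.0, CAGGTAAGA = 2.5))))
  model <- read_maxent_model(dir)
  expect_equal(maxent_score("CAGGTAAGT", model, "donor"), 8.0)
  expect_equal(maxent_score("CAGGTAAGA", model, "donor"), 2.5)
  expect_equal(maxent_score("TTTTTTTTT", model, "donor"), -Inf)

  # factored model: score is the sum of the sub-table lookups
  dir2 <- write_toy_maxent(withr::local_tempdir(), list(
    list(site = "acceptor", start = 1L, end = 3L, kmers = c(TTT = 1.5, CCC = -1)),
    list(site = "acceptor", start = 4L, end = 6L, kmers = c(CAG = 2.25, AAA = 0))))
  model2 <- read_maxent_model(dir2)
  expect_equal(maxent_score("TTTCAG", model2, "acceptor"), 1.5 + 2.25)
  expect_equal(maxent_score("CCCAAA", model2, "acceptor"), -1)
  expect_equal(maxent_score("ACGCAG", model2, "acceptor"), -Inf)
  expect_error(maxent_score("TTT", model2, "acceptor"), "width")
  expect_error(maxent_score("TTTCAG", model2, "donor"), "no tables")
})

test_that("splice scanning calls planted consensus sites and respects thresholds", {
  mats <- default_splice_matrices()
  donor_best <- paste(c("A", "C", "G", "T")[apply(mats$donor$freq, 1L, which.max)],
                      collapse = "")
  # poly-A never reaches the default threshold
  expect_equal(nrow(scan_splice(strrep("A", 40L), mats)), 0L)
  # a planted consensus donor is found with CV 100
  seq <- paste0("AAAAAA", donor_best, "AAAAAA")
  hits <- scan_splice(seq, mats)
  donor_hits <- hits[hits$site_type == "donor", ]
  expect_equal(donor_hits$offset, 6L)
  expect_equal(donor_hits$cv, 100)
  expect_identical(donor_hits$called_by, "HSF")
  # an impossible threshold empties the scan
  expect_equal(nrow(scan_splice(seq, mats, cv_threshold = 101)), 0L)
  # raising the threshold never adds hits
  set.seed(12)
  rseq <- random_dna(400L)
  h_lo <- scan_splice(rseq, mats, cv_threshold = 60)
  h_hi <- scan_splice(rseq, mats, cv_threshold = 80)
  expect_true(all(paste(h_hi$site_type, h_hi$offset) %in%
                    paste(h_lo$site_type, h_lo$offset)))
  # windows containing N are skipped: an N inside the consensus core kills
  # every overlapping window
  seq_n <- paste0("AAAAAA", donor_best)
  substr(seq_n, 8L, 8L) <- "N"
  expect_equal(nrow(scan_splice(seq_n, mats["donor"])), 0L)
})

test_that("the union and conjunction call rules combine the two scorers", {
  mats <- list(donor = toy_splice_matrix("donor"))
  # window "ACA" has CV 100; give maxent a table calling a different window
  dir <- write_toy_maxent(withr::local_tempdir(), list(
    list(site = "donor", start = 1L, end = 3L, kmers = c(ACA = 9, TTT = 5))))
  model <- read_maxent_model(dir)
  seq <- "ACATTT"
  any_hits <- scan_splice(seq, mats, model = model, cv_threshold = 75,
                          maxent_threshold = 3)
  expect_equal(any_hits$offset, c(0L, 3L))
  expect_identical(any_hits$called_by, c("HSF,MaxEnt", "MaxEnt"))
  expect_true(all(any_hits$cv[any_hits$called_by == "HSF,MaxEnt"] >= 75))
  all_hits <- scan_splice(seq, mats, model = model, ss_rule = "all")
  expect_equal(all_hits$offset, 0L)
  expect_identical(all_hits$called_by, "HSF,MaxEnt")
  expect_warning(deg <- scan_splice(seq, mats, model = NULL, ss_rule = "all"),
                 "consensus calls only")
  expect_equal(deg$offset, 0L)
})
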