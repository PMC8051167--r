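#' Default run configuration
#'
#' All tunables of the pipeline with their default values: consensus
#' threshold 0.7 (strict majority fraction), minimum conserved-pattern
#' length 15 nt, PWM log-odds threshold 10 bits with minimum motif width
#' 10 nt, splice consensus-value threshold 75 and maximum-entropy threshold
#' 3, union rule for the two splice scorers, both strands scanned.
#'
#' @param ... overrides for any default field.
#' @return named list of configuration values.
#' @export
run_config <- function(...) {
  cfg <- list(
    consensus_threshold = 0.7,
    min_pattern_len = 15L,
    logodds_threshold = 10,
    min_motif_width = 10L,
    cv_threshold = 75,
    maxent_threshold = 3,
    ss_rule = "any",
    strands = "both",
    pseudocount = 0.01,
    seed = 1L,
    input_dir = NULL,
    motif_info = NULL,
    pwm_dir = NULL,
    donor_matrix = "donor",
    acceptor_matrix = "acceptor",
    maxent_dir = NULL,
    out_dir = "crescan_out",
    aligner = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$consensus_threshold > 0, cfg$consensus_threshold <= 1,
            cfg$min_pattern_len > 0, cfg$logodds_threshold > 0,
            cfg$min_motif_width > 0, cfg$cv_threshold > 0,
            cfg$maxent_threshold > 0)
  cfg
}

#' Load a YAML or JSON run configuration
#'
#' Values in the file override the defaults of [run_config()].
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return configuration list.
#' @export
load_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, vals)
}

#' Run the full detection-and-annotation pipeline in memory
#'
#' For each orthologous region: align (only if needed and an aligner is
#' configured), build the position score matrix, extract maximal fully
#' conserved patterns and count-matched non-conserved controls, scan both
#' sets for motif hits and splice signals, classify patterns into the four
#' element groups, and run the between-intron and conserved-vs-control
#' statistics.
#'
#' @param sets list of [ortholog_set()]s (intron regions, typically).
#' @param library motif library from [read_cisbp_library()].
#' @param config configuration list from [run_config()].
#' @param splice_matrices donor/acceptor matrices (default packaged).
#' @param maxent_model optional `maxent_model`.
#' @return list with elements patterns, controls, tfbs_hits, splice_hits,
#'   ctrl_tfbs_hits, ctrl_splice_hits, classes, ctrl_classes, summary,
#'   families, ctrl_families, nr_clusters, region_lengths, conservation,
#'   stats (list: mannwhitney, chisq, wilcoxon).
#' @export
run_pipeline <- function(sets, library, config = run_config(),
                         splice_matrices = default_splice_matrices(),
                         maxent_model = NULL) {
  patterns <- list(); controls <- list(); region_lengths <- list()
  for (os in sets) {
    msa <- if (length(unique(nchar(os$sequences))) == 1L) msa_from_ortholog_set(os)
           else if (!is.null(config$aligner)) align_ortholog_set(os, config$aligner)
           else stop("unaligned region ", os$gene_id, " and no aligner configured")
    pssm <- build_pssm(msa)
    pats <- extract_conserved_patterns(pssm, msa, min_len = config$min_pattern_len)
    region_lengths[[length(region_lengths) + 1L]] <-
      data.frame(gene_id = os$gene_id, ordinal = os$ordinal,
                 length = msa$length, stringsAsFactors = FALSE)
    if (nrow(pats)) patterns[[length(patterns) + 1L]] <- pats
    if (nrow(pats)) {
      ctl <- suppressWarnings(
        extract_nonconserved_controls(pssm, msa, n = nrow(pats),
                                      min_len = config$min_pattern_len,
                                      seed = config$seed + 7L * length(controls)))
      if (nrow(ctl)) controls[[length(controls) + 1L]] <- ctl
    }
  }
  patterns <- if (length(patterns)) do.call(rbind, patterns) else empty_pattern_frame()
  controls <- if (length(controls)) do.call(rbind, controls) else
    cbind(empty_pattern_frame(), rng_seed = integer())
  region_lengths <- do.call(rbind, region_lengths)

  scan1 <- function(pats) {
    list(
      tfbs = scan_all(pats, library, threshold = config$logodds_threshold,
                      min_width = config$min_motif_width,
                      strands = config$strands, pseudocount = config$pseudocount),
      ss = scan_splice_all(pats, matrices = splice_matrices,
                           model = maxent_model,
                           cv_threshold = config$cv_threshold,
                           maxent_threshold = config$maxent_threshold,
                           ss_rule = config$ss_rule)
    )
  }
  hits <- scan1(patterns)
  ctrl_hits <- scan1(controls)
  classes <- classify_patterns(patterns, hits$tfbs, hits$ss)
  ctrl_classes <- classify_patterns(controls, ctrl_hits$tfbs, ctrl_hits$ss)
  summary_tab <- build_summary(group_by_ordinal(patterns), classes)
  conservation <- conservation_fractions(patterns, region_lengths)

  stats <- run_pipeline_stats(patterns, controls, hits, ctrl_hits,
                              summary_tab, conservation)
  list(patterns = patterns, controls = controls,
       tfbs_hits = hits$tfbs, splice_hits = hits$ss,
       ctrl_tfbs_hits = ctrl_hits$tfbs, ctrl_splice_hits = ctrl_hits$ss,
       classes = classes, ctrl_classes = ctrl_classes,
       summary = summary_tab,
       families = tally_families(hits$tfbs),
       ctrl_families = tally_families(ctrl_hits$tfbs),
       nr_clusters = nr_cluster_report(hits$tfbs, patterns),
       region_lengths = region_lengths, conservation = conservation,
       stats = stats)
}

run_pipeline_stats <- function(patterns, controls, hits, ctrl_hits,
                               summary_tab, conservation) {
  out <- list(mannwhitney = NULL, chisq = NULL, wilcoxon = NULL)
  groups <- split(conservation$pct_conserved, conservation$ordinal)
  groups <- groups[vapply(groups, length, 1L) > 0L]
  if (length(groups) >= 2L) {
    out$mannwhitney <- tryCatch(mannwhitney_conservation(groups),
                                error = function(e) NULL)
  }
  body <- summary_tab[summary_tab$ordinal != "total" & summary_tab$n_patterns > 0, ]
  if (nrow(body) >= 2L) {
    obs <- as.matrix(body[c("n_class_tfbs", "n_class_tfbs_ss", "n_class_ss",
                            "n_class_not_identified")])
    colnames(obs) <- c("TFBS", "TFBS_SS", "SS", "NOT_IDENTIFIED")
    rownames(obs) <- body$ordinal
    out$chisq <- tryCatch(suppressWarnings(chisq_class_distribution(obs)),
                          error = function(e) NULL)
  }
  regions <- unique(rbind(patterns[c("gene_id", "ordinal")],
                          controls[c("gene_id", "ordinal")]))
  if (nrow(regions) >= 2L) {
    per_region <- function(pats, h) {
      ids <- pats$pattern_id[paste(pats$gene_id, pats$ordinal) %in%
                               paste(regions$gene_id, regions$ordinal)]
      vapply(paste(regions$gene_id, regions$ordinal), function(k) {
        pid <- pats$pattern_id[paste(pats$gene_id, pats$ordinal) == k]
        sum(h$pattern_id %in% pid)
      }, numeric(1L))
    }
    wil <- list()
    for (what in c("tfbs", "ss")) {
      a <- per_region(patterns, hits[[what]])
      b <- per_region(controls, ctrl_hits[[what]])
      wil[[what]] <- tryCatch({
        r <- wilcoxon_paired_counts(a, b)
        r$test <- paste0("wilcoxon_paired_", what)
        r
      }, error = function(e) NULL)
    }
    out$wilcoxon <- do.call(rbind, wil)
  }
  out
}

#' Write all pipeline outputs to a directory
#'
#' Emits the pattern/control tables, hit tables, per-intron summary, family
#' tallies, nuclear-receptor cluster report, statistics TSVs and a JSON run
#' manifest recording the package version, the effective configuration and
#' its hash.
#'
#' @param res result list from [run_pipeline()].
#' @param config the configuration used.
#' @param out_dir output directory (created).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, config, out_dir = config$out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_pattern_table(res$patterns, file.path(out_dir, "patterns.tsv"),
                      classes = res$classes, tfbs_hits = res$tfbs_hits,
                      splice_hits = res$splice_hits)
  write_pattern_table(res$controls, file.path(out_dir, "controls.tsv"),
                      classes = res$ctrl_classes, tfbs_hits = res$ctrl_tfbs_hits,
                      splice_hits = res$ctrl_splice_hits)
  write_tfbs_table(res$tfbs_hits, res$patterns,
                   file.path(out_dir, "tfbs_hits.tsv"))
  write_tfbs_table(res$ctrl_tfbs_hits, res$controls,
                   file.path(out_dir, "control_tfbs_hits.tsv"))
  tsv(res$splice_hits, "splice_hits.tsv")
  tsv(res$ctrl_splice_hits, "control_splice_hits.tsv")
  tsv(res$summary, "summary.tsv")
  tsv(res$families, "families.tsv")
  tsv(res$ctrl_families, "control_families.tsv")
  tsv(res$nr_clusters, "nr_clusters.tsv")
  tsv(res$conservation, "conservation.tsv")
  if (!is.null(res$stats$mannwhitney)) tsv(res$stats$mannwhitney$results,
                                           "stats_mannwhitney.tsv")
  if (!is.null(res$stats$chisq)) tsv(res$stats$chisq, "stats_chisq.tsv")
  if (!is.null(res$stats$wilcoxon)) tsv(res$stats$wilcoxon, "stats_wilcoxon.tsv")
  manifest <- list(
    package = "crescan",
    version = as.character(utils::packageVersion("crescan")),
    r_version = as.character(getRversion()),
    config = config[!vapply(config, is.null, logical(1L))],
    config_hash = config_hash(config),
    n_patterns = nrow(res$patterns), n_controls = nrow(res$controls)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(config[!vapply(config, is.null, logical(1L))]), tf)
  unname(tools::md5sum(tf))
}

#' Read a directory of per-region ortholog FASTA files
#'
#' File naming convention: `<gene>_<intron|exon><ordinal>.fasta` (or
#' `.fa`), e.g. `AR_intron1.fasta`.
#'
#' @param dir directory of FASTA files.
#' @return list of [ortholog_set()]s.
#' @export
read_region_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  if (!length(files)) stop("no FASTA files in ", dir)
  rx <- "^(.+)_(intron|exon)(\\d+)\\.(fa|fasta)$"
  bad <- !grepl(rx, basename(files))
  if (any(bad)) stop("file name(s) not matching <gene>_<intron|exon><N>.fasta: ",
                     paste(basename(files)[bad], collapse = ", "))
  lapply(files, function(f) {
    b <- basename(f)
    read_ortholog_fasta(f, gene_id = sub(rx, "\\1", b),
                        region_kind = sub(rx, "\\2", b),
                        ordinal = as.integer(sub(rx, "\\3", b)))
  })
}

#' Write ortholog sets as a directory of FASTA files
#'
#' Inverse of [read_region_dir()].
#'
#' @param sets list of `ortholog_set`s.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_region_dir <- function(sets, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (os in sets) {
    write_ortholog_fasta(os, file.path(dir, sprintf("%s_%s%d.fasta",
                                                    os$gene_id, os$region_kind,
                                                    os$ordinal)))
  }
  invisible(dir)
}
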