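#' Specification for the orthologous-region simulator
#'
#' Defaults emulate the study conditions the pipeline targets: five closely
#' related mammalian species, tens of genes with a few introns each, a
#' per-site background substitution probability of 0.3 per species, no
#' indels (conserved patterns are gap-free by definition; turn indels on to
#' exercise gap handling), and planted fully conserved blocks of >= 15 nt of
#' which half carry a motif instance and a quarter a canonical splice donor.
#'
#' @param n_genes number of genes (default 25).
#' @param introns_per_gene introns per gene (default 3).
#' @param intron_length region length in nt (default 600).
#' @param n_species number of species (default 5).
#' @param species species ids.
#' @param substitution_prob per-site, per-species substitution probability
#'   outside planted blocks (default 0.3).
#' @param indel_prob per-site, per-species deletion probability outside
#'   planted blocks (default 0).
#' @param n_blocks,n_motif_blocks,n_donor_blocks planted-block mix used when
#'   `planted_blocks` is not given: total blocks, how many embed a motif,
#'   how many a splice donor (default 40 / 20 / 10; the remainder carry no
#'   element).
#' @param block_length planted block length (default 20).
#' @param planted_blocks optional explicit data frame with columns gene
#'   (index), intron, offset (0-based), length, element (`"none"`,
#'   `"motif:<id>"`, `"donor"`, `"acceptor"`); blocks must not overlap
#'   within a region.
#' @param seed integer seed (required).
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(n_genes = 25L, introns_per_gene = 3L,
                            intron_length = 600L, n_species = 5L,
                            species = c("hsap", "ggor", "ptro", "mmus", "rnor"),
                            substitution_prob = 0.3, indel_prob = 0,
                            n_blocks = 40L, n_motif_blocks = 20L,
                            n_donor_blocks = 10L, block_length = 20L,
                            planted_blocks = NULL, seed) {
  if (missing(seed)) stop("`seed` is required")
  species <- species[seq_len(n_species)]
  if (anyNA(species)) species <- paste0("sp", seq_len(n_species))
  if (block_length < 15L) stop("planted blocks must be >= 15 nt")
  structure(list(n_genes = as.integer(n_genes),
                 introns_per_gene = as.integer(introns_per_gene),
                 intron_length = as.integer(intron_length),
                 n_species = as.integer(n_species), species = species,
                 substitution_prob = substitution_prob,
                 indel_prob = indel_prob, n_blocks = as.integer(n_blocks),
                 n_motif_blocks = as.integer(n_motif_blocks),
                 n_donor_blocks = as.integer(n_donor_blocks),
                 block_length = as.integer(block_length),
                 planted_blocks = planted_blocks, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate orthologous gene regions with planted conserved blocks
#'
#' Draws a uniform-random ancestor per region, embeds the planted blocks,
#' and derives each species' copy by independent per-site substitution (and
#' optional deletion) *outside* the blocks; block content is copied
#' verbatim into every species, so each block is a fully conserved run. The
#' single column on either side of a block is forced to mismatch in one
#' species so that every planted block is maximal and the truth table is
#' exact. Block content is screened at generation time so that, under the
#' supplied scan settings, a block triggers exactly the element planted in
#' it and nothing else — the truth table therefore determines the
#' downstream class of every pattern.
#'
#' @param spec a [simulation_spec()].
#' @param library motif library (list of `motif_model`s); required when
#'   motif blocks are planted. Planted motif instances spell the motif's
#'   per-position consensus.
#' @param splice_matrices donor/acceptor matrices used for screening and
#'   for spelling planted donor/acceptor consensus windows (default
#'   packaged).
#' @param scan_params list of thresholds used for screening:
#'   `logodds_threshold`, `min_motif_width`, `cv_threshold` (defaults 10,
#'   10, 75).
#' @return list with `sets` (list of [ortholog_set()]) and `truth` (data
#'   frame: gene_id, region_kind, ordinal, block_start, block_length,
#'   element, element_id, element_offset). Deterministic under `spec$seed`.
#' @export
simulate_ortholog_sets <- function(spec, library = NULL,
                                   splice_matrices = default_splice_matrices(),
                                   scan_params = list()) {
  stopifnot(inherits(spec, "simulation_spec"))
  sp <- c(list(logodds_threshold = 10, min_motif_width = 10L, cv_threshold = 75),
          scan_params)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)
  genes <- sprintf("GENE%02d", seq_len(spec$n_genes))
  blocks <- spec$planted_blocks %||% auto_plant_blocks(spec, library)
  validate_blocks(blocks, spec)
  loms <- if (!is.null(library)) lapply(library, pwm_to_logodds) else list()
  bases <- c("A", "C", "G", "T")
  sets <- list()
  truth <- list()
  for (g in seq_len(spec$n_genes)) {
    for (intr in seq_len(spec$introns_per_gene)) {
      L <- spec$intron_length
      anc <- sample(bases, L, replace = TRUE)
      myb <- blocks[blocks$gene == g & blocks$intron == intr, , drop = FALSE]
      blocked <- rep(FALSE, L)
      for (b in seq_len(nrow(myb))) {
        off <- myb$offset[b]; len <- myb$length[b]
        made <- make_screened_block(len, myb$element[b], library, loms,
                                    splice_matrices, sp)
        anc[(off + 1L):(off + len)] <- made$content
        blocked[(off + 1L):(off + len)] <- TRUE
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = genes[g], region_kind = "intron", ordinal = intr,
          block_start = off, block_length = len, element = made$kind,
          element_id = made$element_id, element_offset = off + made$local_offset,
          stringsAsFactors = FALSE)
      }
      copies <- matrix(rep(anc, spec$n_species), nrow = spec$n_species,
                       byrow = TRUE)
      for (s in seq_len(spec$n_species)) {
        mut <- !blocked & stats::runif(L) < spec$substitution_prob
        if (any(mut)) {
          idx0 <- match(anc[mut], bases)
          shift <- sample.int(3L, sum(mut), replace = TRUE)
          copies[s, mut] <- bases[((idx0 - 1L + shift) %% 4L) + 1L]
        }
      }
      # Disrupt the columns flanking each block in two species, with two
      # distinct non-ancestral bases, so a flank column can never be
      # conserved and every planted block is a maximal run.
      if (nrow(myb) && spec$n_species >= 3L) {
        for (b in seq_len(nrow(myb))) {
          for (fl in c(myb$offset[b], myb$offset[b] + myb$length[b] + 1L)) {
            if (fl >= 1L && fl <= L && !blocked[fl]) {
              alt <- setdiff(bases, anc[fl])
              copies[2L, fl] <- alt[1L]
              copies[3L, fl] <- alt[2L]
            }
          }
        }
      }
      if (spec$indel_prob > 0) {
        for (s in seq_len(spec$n_species)) {
          del <- !blocked & stats::runif(L) < spec$indel_prob
          copies[s, del] <- ""
        }
      }
      seqs <- apply(copies, 1L, paste, collapse = "")
      names(seqs) <- spec$species
      sets[[length(sets) + 1L]] <- ortholog_set(genes[g], "intron", intr, seqs)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(), region_kind = character(),
               ordinal = integer(), block_start = integer(),
               block_length = integer(), element = character(),
               element_id = character(), element_offset = integer(),
               stringsAsFactors = FALSE)
  list(sets = sets, truth = truth)
}

# Random non-overlapping block placement: at most one block per region,
# regions drawn without replacement, offsets clear of the region edges.
auto_plant_blocks <- function(spec, library) {
  n_regions <- spec$n_genes * spec$introns_per_gene
  if (spec$n_blocks == 0L) {
    return(data.frame(gene = integer(), intron = integer(), offset = integer(),
                      length = integer(), element = character(),
                      stringsAsFactors = FALSE))
  }
  if (spec$n_blocks > n_regions) {
    stop("default planting places one block per region; need n_blocks <= regions")
  }
  if (spec$n_motif_blocks > 0L && (is.null(library) || !length(library))) {
    stop("motif blocks requested but no motif library supplied")
  }
  regions <- sample.int(n_regions, spec$n_blocks)
  elements <- c(rep("motif", spec$n_motif_blocks),
                rep("donor", spec$n_donor_blocks),
                rep("none", spec$n_blocks - spec$n_motif_blocks - spec$n_donor_blocks))
  motif_ids <- if (length(library)) names(library) else character()
  elem <- vapply(elements, function(e) {
    if (e == "motif") paste0("motif:", sample(motif_ids, 1L)) else e
  }, character(1L))
  len <- spec$block_length
  data.frame(gene = ((regions - 1L) %/% spec$introns_per_gene) + 1L,
             intron = ((regions - 1L) %% spec$introns_per_gene) + 1L,
             offset = sample.int(spec$intron_length - len - 3L, spec$n_blocks,
                                 replace = TRUE) + 1L,
             length = len, element = elem, stringsAsFactors = FALSE)
}

validate_blocks <- function(blocks, spec) {
  need <- c("gene", "intron", "offset", "length", "element")
  stopifnot(all(need %in% names(blocks)))
  if (any(blocks$length < 15L)) stop("planted blocks must be >= 15 nt")
  if (any(blocks$offset < 0L |
          blocks$offset + blocks$length > spec$intron_length)) {
    stop("planted block exceeds region bounds")
  }
  for (key in unique(paste(blocks$gene, blocks$intron))) {
    b <- blocks[paste(blocks$gene, blocks$intron) == key, , drop = FALSE]
    b <- b[order(b$offset), , drop = FALSE]
    if (nrow(b) > 1L &&
        any(b$offset[-1L] <= b$offset[-nrow(b)] + b$length[-nrow(b)] + 1L)) {
      stop("planted blocks overlap or touch within a region")
    }
  }
  invisible(blocks)
}

# Build block content that triggers exactly its planted element under the
# screening scanners: filler is redrawn until no unplanned motif or splice
# call appears inside the block.
make_screened_block <- function(len, element, library, loms, splice_matrices,
                                sp, max_tries = 500L) {
  bases <- c("A", "C", "G", "T")
  kind <- sub(":.*$", "", element)
  element_seq <- NULL; element_id <- NA_character_
  if (kind == "motif") {
    element_id <- sub("^motif:", "", element)
    motif <- library[[element_id]]
    if (is.null(motif)) stop("planted motif not in library: ", element_id)
    if (motif$width > len) stop("motif wider than its block")
    element_seq <- paste(bases[apply(motif$matrix, 1L, which.max)], collapse = "")
  } else if (kind %in% c("donor", "acceptor")) {
    element_id <- kind
    mat <- splice_matrices[[kind]]
    if (is.null(mat)) stop("no splice matrix for ", kind)
    if (mat$width > len) stop("splice window wider than its block")
    element_seq <- paste(bases[apply(mat$freq, 1L, which.max)], collapse = "")
  } else if (kind != "none") {
    stop("unknown element kind: ", element)
  }
  ew <- if (is.null(element_seq)) 0L else nchar(element_seq)
  local_offset <- if (ew) sample.int(len - ew + 1L, 1L) - 1L else NA_integer_
  for (try in seq_len(max_tries)) {
    content <- sample(bases, len, replace = TRUE)
    if (ew) {
      content[(local_offset + 1L):(local_offset + ew)] <-
        strsplit(element_seq, "")[[1L]]
    }
    seqstr <- paste(content, collapse = "")
    tf_n <- 0L
    for (lom in loms) {
      tf_n <- tf_n + nrow(scan_pattern(seqstr, lom, threshold = sp$logodds_threshold,
                                       min_width = sp$min_motif_width))
    }
    ss <- scan_splice(seqstr, matrices = splice_matrices,
                      cv_threshold = sp$cv_threshold)
    ok <- switch(kind,
                 none = tf_n == 0L && nrow(ss) == 0L,
                 motif = tf_n >= 1L && nrow(ss) == 0L &&
                   all_hits_overlap(seqstr, loms, sp, local_offset, ew),
                 donor = ,
                 acceptor = tf_n == 0L && nrow(ss) >= 1L)
    if (ok) {
      return(list(content = content, kind = kind, element_id = element_id,
                  local_offset = local_offset))
    }
  }
  stop("could not generate a clean planted block after ", max_tries, " tries")
}

# All motif hits in a motif block must overlap the planted instance, so the
# block's TFBS class is attributable to the plant alone.
all_hits_overlap <- function(seqstr, loms, sp, local_offset, ew) {
  for (lom in loms) {
    h <- scan_pattern(seqstr, lom, threshold = sp$logodds_threshold,
                      min_width = sp$min_motif_width)
    if (nrow(h) &&
        any(h$offset + lom$width <= local_offset | h$offset >= local_offset + ew)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Write a synthetic CIS-BP-style motif library to disk
#'
#' Generates sharp position-probability matrices (consensus base probability
#' `sharpness`, remainder spread evenly) for one motif per binding-domain
#' family and writes them in the dump layout [read_cisbp_library()] reads: a
#' TF-information TSV plus one matrix file per motif. The default family
#' list covers the ten families most often seen in binding-domain tallies
#' of intronic scans, including a "Nuclear receptor" family whose motif
#' carries several receptor gene symbols so cluster reports are exercised.
#'
#' @param dir output directory (created).
#' @param families family labels, one motif each.
#' @param widths motif widths (recycled; default 12).
#' @param sharpness consensus probability per position (default 0.97).
#' @param tf_names optional list (per family) of TF symbols; defaults to
#'   `TF_<k>` with three receptor symbols for the nuclear-receptor family.
#' @param screen_matrices splice matrices used to keep motif consensus
#'   sequences distinguishable from splice signals: a consensus is redrawn
#'   while any of its windows reaches `screen_cv` so that a planted motif
#'   can never be mistaken for a planted splice site (set `NULL` to
#'   disable).
#' @param screen_cv consensus-value ceiling used for the screening
#'   (default 75, the scan call threshold).
#' @param seed integer seed.
#' @return list with `dir`, `info_path`, `pwm_dir` and `truth` (data frame:
#'   motif_id, family, width, consensus, tf_names).
#' @export
simulate_toy_library <- function(dir,
                                 families = c("Homeodomain", "Forkhead",
                                              "Homeodomain POU", "C2H2 ZF",
                                              "bZIP", "Nuclear receptor",
                                              "bHLH", "Ets", "Sox", "GATA"),
                                 widths = 12L, sharpness = 0.97,
                                 tf_names = NULL,
                                 screen_matrices = default_splice_matrices(),
                                 screen_cv = 75, seed) {
  if (missing(seed)) stop("`seed` is required")
  if (sharpness <= 0.25 || sharpness > 1) stop("`sharpness` must be in (0.25, 1]")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  widths <- rep_len(as.integer(widths), length(families))
  dir.create(file.path(dir, "pwms"), recursive = TRUE, showWarnings = FALSE)
  bases <- c("A", "C", "G", "T")
  info <- list(); truth <- list()
  for (k in seq_along(families)) {
    mid <- sprintf("M%03d_synth", k)
    w <- widths[k]
    for (try in seq_len(500L)) {
      cons <- sample(bases, w, replace = TRUE)
      if (is.null(screen_matrices) ||
          consensus_splice_safe(cons, screen_matrices, screen_cv)) break
      if (try == 500L) stop("could not draw a splice-free motif consensus")
    }
    m <- matrix((1 - sharpness) / 3, nrow = w, ncol = 4L,
                dimnames = list(NULL, bases))
    m[cbind(seq_len(w), match(cons, bases))] <- sharpness
    tfs <- if (!is.null(tf_names)) tf_names[[k]]
           else if (families[k] == "Nuclear receptor") c("RARA", "RARB", "RARG")
           else sprintf("TF_%02d", k)
    write_pwm_file(file.path(dir, "pwms", paste0(mid, ".txt")), m)
    info[[k]] <- data.frame(TF_ID = sprintf("T%03d", k), TF_Name = tfs,
                            Motif_ID = mid,
                            TF_Status = rep_len(c("D", "I"), length(tfs)),
                            Family_Name = families[k], stringsAsFactors = FALSE)
    truth[[k]] <- data.frame(motif_id = mid, family = families[k], width = w,
                             consensus = paste(cons, collapse = ""),
                             tf_names = paste(tfs, collapse = ","),
                             stringsAsFactors = FALSE)
  }
  info_path <- file.path(dir, "TF_Information.txt")
  utils::write.table(do.call(rbind, info), info_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(dir = dir, info_path = info_path, pwm_dir = file.path(dir, "pwms"),
       truth = do.call(rbind, truth))
}

# TRUE when no splice window overlapping the consensus can be forced to a
# call: for every window placement, the surrounding positions are scored at
# their per-position minimum frequency (the worst filler), and the window
# must stay below the consensus-value threshold. A consensus failing this
# has a splice-like core that any embedding would call, which would make a
# planted motif indistinguishable from a planted splice site.
consensus_splice_safe <- function(cons_chars, matrices, cv_threshold) {
  w <- length(cons_chars)
  for (mat in matrices) {
    v <- mat$width
    minf <- apply(mat$freq, 1L, min)
    t_min <- sum(minf)
    t_max <- sum(apply(mat$freq, 1L, max))
    for (j in (-(v - 1L)):(w - 1L)) {
      t_val <- 0
      for (p in seq_len(v)) {
        ci <- j + p
        t_val <- t_val + if (ci >= 1L && ci <= w) mat$freq[p, cons_chars[ci]]
                         else minf[p]
      }
      if (100 * (t_val - t_min) / (t_max - t_min) >= cv_threshold) return(FALSE)
    }
  }
  TRUE
}

write_pwm_file <- function(path, m) {
  tab <- data.frame(Pos = seq_len(nrow(m)), A = m[, "A"], C = m[, "C"],
                    G = m[, "G"], T = m[, "T"])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
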