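---
title: "Detecting conserved patterns and their cis-regulatory elements"
author: "crescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved patterns and their cis-regulatory elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crescan)
```

## The model and its assumptions

`crescan` operationalises a simple but strict notion of functional
conservation: an alignment column of orthologous sequences counts as
conserved only when **every** species carries the **same nucleotide** —
a gap, an `N`, or a single substitution disqualifies the column — and only
**maximal runs of at least 15 such columns** are reported as conserved
patterns. The strictness is deliberate. With five closely related mammals,
perfect identity over 15+ nt is vanishingly unlikely by chance (at a
per-site, per-species substitution probability of 0.3 the chance that a
column is identical in five independent copies is about 0.17, and a
15-column run about $10^{-12}$ per start position), so every reported
pattern is a strong candidate for purifying selection. The cost is
sensitivity: a functional element with a single compensatory substitution
in one rodent is invisible. The method assumes the input regions are truly
orthologous and positionally equivalent (same intron/exon number and phase);
it does not attempt to detect or correct mis-annotated orthology.

Detection proceeds through three stages so that each intermediate is
inspectable: (1) a position score matrix (`build_pssm()`) tallying per-column
occupancy of A, C, G, T, gap and N; (2) a majority-rule consensus profile
(`dumb_consensus()`) that emits the most common nucleotide when its fraction
*strictly* exceeds a threshold, default 0.7, else `X`; (3) run extraction
(`extract_conserved_patterns()`) over the 100 %-conserved columns. Stage 2
is informative output rather than a gate for stage 3: any column that is
100 % conserved has fraction 1 > 0.7, so the final pattern set is invariant
to the 0.7 threshold — a property pinned by the consensus test suite rather
than assumed.

Patterns are then scanned for two kinds of cis-regulatory element:

* **TFBS** by position-weight-matrix log-odds. A motif's per-position
  probabilities $p_{ib}$ are converted to bits against a uniform background
  with a proportional pseudocount ($0.01$):
  $s_{ib} = \log_2\frac{p_{ib} + 0.01/4}{1.01/4}$. Every window of the
  motif's width, on both strands, is summed; windows reaching **10 bits**
  count, and motifs narrower than **10 nt** are excluded wholesale so that
  short, information-poor matrices cannot flood the results.
* **Splice signals** by a consensus-value scorer over donor (width 9:
  3 exonic + 6 intronic positions) and acceptor (width 14) frequency
  matrices: $CV = 100\,(t - t_{\min})/(t_{\max} - t_{\min})$ where $t$ sums
  the per-position frequencies of the window's bases. CV is scale-free (a
  common factor on the frequencies cancels) and bounded in $[0, 100]$ by
  construction. Calls require **CV ≥ 75**. A maximum-entropy scorer can be
  plugged in as score tables on disk (threshold **3**, log2 units); by
  default the two scorers combine by union — a window called by either is a
  splice hit — with a `ss_rule = "all"` conjunction mode available, since
  reasonable readings of "HSF and MaxEnt thresholds" differ and we prefer
  to expose the ambiguity as a switch rather than guess silently.

Each pattern lands in exactly one of four classes — `TFBS`, `TFBS_SS`,
`SS`, `NOT_IDENTIFIED` — and per-intron summaries report pattern counts,
counts of TFBS- and SS-positive patterns, and integer percentages.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `consensus_threshold` | 0.7 | fraction of rows | strict-majority profile; exceed (not reach) to emit a base |
| `min_pattern_len` | 15 | nt | excludes chance identity, retains binding-site-sized elements |
| `logodds_threshold` | 10 | bits | restrictive motif-match cutoff (≈ 1 : 1000 odds vs background) |
| `min_motif_width` | 10 | nt | "at least 10 consecutive nucleotides" of match; a width filter because log-odds matches are whole-motif |
| `cv_threshold` | 75 | CV units (0–100) | raised from the scorer's historical 65 for higher-confidence splice calls |
| `maxent_threshold` | 3 | log2 units | conventional lower bound for a plausible site |
| `pseudocount` | 0.01 | fraction | keeps log-odds finite for 0-probability cells without distorting sharp motifs |
| `strands` | both | — | binding sites are double-stranded elements |
| `seed` | required | — | controls control-sampling and all simulation |

All defaults are carried by `run_config()` and surfaced unchanged in the
command line (`exec/crescan`); the acceptance suite asserts they stay in
lockstep.

## Design choices where the design was open

* **Log-odds base and background.** The scoring convention (base 2, uniform
  background, proportional pseudocount 0.01) is the common one for
  CIS-BP-style matrices; all three are config-exposed because scan scores —
  unlike the detection stage — do depend on them.
* **"≥ 10 consecutive nucleotides".** Interpreted as a minimum motif width:
  a log-odds scan produces whole-motif matches, so the motif width is the
  only "consecutive matched nucleotides" a hit has. Partial-window matches
  are never emitted.
* **Counting units.** One (motif, offset, strand) triple is one TFBS; the
  several TFs mapped to a motif (direct + inferred) multiply TF-level and
  cluster reports but not site counts. Summary percentages count
  *patterns containing* an element, not element instances — the only
  reading under which per-intron percentages and their denominators are
  mutually consistent.
* **Controls.** Non-conserved control sequences mirror the pattern
  extraction with the condition inverted: maximal runs of < 100 %-conserved
  columns (split at gap-majority columns), ≥ 15 nt, sampled without
  replacement with probability proportional to run length — length-
  proportional sampling avoids biasing controls toward the many short runs
  — then a uniformly placed sub-window of uniformly drawn length. The
  control sequence reads the per-column majority base (ties alphabetical)
  so that a concrete, scannable sequence exists even where species
  disagree. Controls are count-matched per region to the conserved
  patterns; their length distribution is reported rather than matched
  pairwise, since only the count matching is unambiguous.
* **Chi-square expectations.** "Expected frequency distribution" of the four
  classes is taken as the pooled class distribution across all introns
  (overridable, e.g. to uniform). Cells with expected count < 1 collapse
  `SS` into `TFBS_SS` with a warning rather than silently producing an
  invalid test.
* **Mann–Whitney unit of observation.** Per-gene conservation percentage
  (pattern-covered fraction of the region) per intron group — the unit that
  makes "conservation differs between intron 1 and downstream introns" a
  statement about genes rather than about pattern counts.
* **Rounding.** All printed percentages round half *up* (`round_half_up()`),
  reproducing 37.5 → 38 and 35.58 → 36; R's default half-to-even would not.
* **Splice matrices.** The canonical scorer's exact frequency tables are not
  redistributable, so the packaged donor/acceptor matrices are synthetic
  (`inst/extdata/splice/*_synthetic.tsv`): constructed around the canonical
  mammalian consensus (MAG|GTRAGT; polypyrimidine tract + NCAG|G) with
  realistic frequency mass, and user-replaceable by any TSV of the same
  shape. The CV formula, not the table values, is the tested contract.
* **Alignment is external.** Conservation detection, not alignment, is the
  contribution; `align_ortholog_set()` shells out to a configurable command
  (MAFFT by default) and verifies that the output degaps back to its input.

## The synthetic-data generator

`simulate_ortholog_sets()` emulates the study conditions the pipeline
targets: 25 genes × 3 introns × 600 nt across 5 species, per-site
substitution probability 0.3 per species (star phylogeny — conservation
detection, not phylogenetics, is the target), indels off by default, and 40
planted conserved blocks of 20 nt — 20 embedding a sharp width-12 motif
instance, 10 a consensus splice donor, 10 nothing.

Three generator invariants make the truth table exact rather than merely
likely, for any seed:

1. planted blocks are copied verbatim into every species, so each is a
   conserved run;
2. the two columns flanking each block are forced to two *distinct*
   non-ancestral bases in two species, so no flank column can ever be
   conserved and each block is recovered as exactly one maximal pattern;
3. block content is screened at generation time: filler is redrawn until
   the block triggers exactly its planted element and nothing else under
   the configured scanners, and toy-library motif consensus sequences are
   redrawn while any splice window overlapping them would reach CV ≥ 75
   even under the least favourable flanking bases (without this, a motif
   whose consensus ends in a donor-like core is *unplantable* — every
   filler completes a splice call — and the class truth table would be
   wrong by construction).

What the generator deliberately does **not** emulate: realistic
substitution models (no transition/transversion bias, no rate variation,
no phylogenetic correlation), indel dynamics (an indel-on mode exists only
to exercise gap handling), overlapping or clustered regulatory elements,
and base composition biases. Passing the planted-recovery tests therefore
demonstrates the *correctness of the machinery* — extraction finds exactly
the fully conserved runs, scanners find exactly the planted elements — not
that real intronic elements are recovered at any particular sensitivity;
on real data sensitivity is governed by the biology (how conserved real
elements are) rather than by anything these tests can show.

## Numerical choices and degenerate inputs

* Motif-matrix rows must sum to 1 within $10^{-3}$ (then renormalised);
  larger deviations abort the library read with the offending motif named.
* Consensus ties (two bases at the same top fraction) emit `X`; control
  majority ties break alphabetically — both deterministic.
* Windows containing `N` are skipped by both scanners; `N` never supports
  conservation.
* Sequences shorter than a scanner's width return empty hit sets, not
  errors; empty pattern sets propagate as empty (but well-formed) tables.
* An absent maximum-entropy table or k-mer scores $-\infty$: such a window
  can be called by the consensus scorer but never by the model.
* Control sampling with fewer available runs than requested warns and
  returns what exists; a fully conserved region yields zero controls.
* All p-values use the standard exact/approximate switching of the stats
  routines; the test suite pins them to exhaustive enumeration for
  $n \le 8$.

## Problem sizes used by the tests

The packaged verification runs at sizes chosen to give airtight oracles
while staying desk-sized: 200 random 5-row alignments of 50–2,000 columns
against a naive per-column scan; 200 random sequence/motif pairs against a
double-loop scorer; rank statistics against full enumeration at $n \le 8$;
and one end-to-end synthetic run at the default study conditions above
(40 planted blocks, classes checked exactly). `scripts/acceptance.R`
re-runs all of these from a single seed.

## Known limitations

* 100 % identity is an all-or-nothing criterion; there is no graded
  conservation score and no tolerance for aligned indels inside a pattern.
* Motif hits are threshold calls without p-value calibration; thresholds
  are global, not per-motif.
* The packaged splice matrices are synthetic stand-ins; analyses that
  depend on exact splice-site strengths should supply measured frequency
  tables and/or a full maximum-entropy model.
* Database-scale results (which TFs, which families, how many thousands of
  hits) depend entirely on the motif library version supplied by the user;
  the package reproduces arithmetic and mechanics, not any particular
  library snapshot.
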