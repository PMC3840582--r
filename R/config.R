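#' Pipeline parameter set
#'
#' All numeric thresholds used across the pipeline, with the defaults of the
#' cabbage leaf small RNA protocol the package implements.  Units and
#' meaning:
#'
#' * `max_bases_below_q10` / `max_bases_below_q13`: a read is discarded when
#'   more than 4 bases have Phred quality < 10 or more than 6 bases have
#'   quality < 13.
#' * `min_read_len`: minimum trimmed insert length (18 nt).
#' * `max_edits_ncrna_native` / `max_edits_ncrna_relative`: edit budgets
#'   (mismatches + 1-nt gaps) of the annotation cascade against same-species
#'   references (1) and close-relative references (2, i.e. "fewer than
#'   three").
#' * `seed_start` / `seed_end`: seed region, positions 2..8 from the tag
#'   5' end (1-based, inclusive); edits there disqualify miRNA homology.
#' * `max_edits_conserved_native` / `max_edits_conserved_other`: edit
#'   budgets of the conserved-miRNA passes (1 native, 3 other plants),
#'   edits outside the seed only.
#' * `max_coverage_diff`: maximum tag/reference length difference (2 nt).
#' * `min_family_mean_norm`: families not described in Brassicaceae
#'   relatives are dropped below this mean normalized abundance (15).
#' * `mapping_seed_len` / `mapping_max_mismatch`: genomic mapping seeds
#'   (8 nt exact) and mismatch allowance (1 genome mode, 0 contig mode).
#' * `precursor_mfe_max`: hairpin acceptance threshold, -18 kcal/mol.
#' * `min_duplex_pairs`, `max_bulge`, `max_asymmetry`: miRNA:miRNA* duplex
#'   criteria (>= 16 pairs, bulge <= 4, asymmetry <= 4).
#' * `min_dominance`, `max_5p_heterogeneity`: single-dominant-product
#'   curation (mature reads >= 50% of the precursor pileup; supporting 5'
#'   ends within 2 nt).
#' * `phase_len`, `phase_cycles`, `min_phase_abundance`, `tas_p_threshold`:
#'   tasiRNA scan (21-nt register, 11-cycle window, abundance >= 4, locus
#'   p <= 0.001).
#' * `match_score`, `wobble_score`, `mismatch_score`, `gap_open`,
#'   `gap_extend`, `seed_scale`: target-alignment column scores (+5
#'   canonical, +2 G:U; penalties and the 4x seed scaling follow the
#'   reference complementarity scorer's documented defaults).
#' * `target_score_min`, `target_mfe_max`: target acceptance (score >= 130,
#'   duplex energy <= -17 kcal/mol).
#' * `enrich_p_threshold`: adjusted-p cutoff of the GO enrichment (0.05).
#' * `top_n_targets`: per-miRNA ranked hits kept, 10 or 20 depending on the
#'   raw hit count (NULL = automatic).
#'
#' @param ... named overrides of any default listed above.
#' @return a classed list (`pipeline_config`) of validated parameters.
#' @examples
#' cfg <- pipeline_config(min_read_len = 19)
#' cfg$precursor_mfe_max
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    max_bases_below_q10 = 4L,
    max_bases_below_q13 = 6L,
    min_read_len = 18L,
    max_edits_ncrna_native = 1L,
    max_edits_ncrna_relative = 2L,
    seed_start = 2L,
    seed_end = 8L,
    max_edits_conserved_native = 1L,
    max_edits_conserved_other = 3L,
    max_coverage_diff = 2L,
    min_family_mean_norm = 15,
    mapping_seed_len = 8L,
    mapping_max_mismatch = 1L,
    precursor_mfe_max = -18,
    min_duplex_pairs = 16L,
    max_bulge = 4L,
    max_asymmetry = 4L,
    min_dominance = 0.5,
    max_5p_heterogeneity = 2L,
    excision_flank_long = 250L,
    excision_flank_short = 50L,
    phase_len = 21L,
    phase_cycles = 11L,
    min_phase_abundance = 4L,
    tas_p_threshold = 0.001,
    match_score = 5,
    wobble_score = 2,
    mismatch_score = -3,
    gap_open = 9,
    gap_extend = 4,
    seed_scale = 4.0,
    target_score_min = 130,
    target_mfe_max = -17,
    seed_allow_wobble = FALSE,
    enrich_p_threshold = 0.05,
    top_n_targets = NULL,
    norm_scale = 1e6,
    adapter_min_overlap = 6L,
    adapter_max_mismatch = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stopf("unknown pipeline_config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (cfg$seed_start >= cfg$seed_end) stopf("seed_start must be < seed_end")
  counts <- c("max_bases_below_q10", "max_bases_below_q13", "min_read_len",
              "max_edits_ncrna_native", "max_edits_ncrna_relative",
              "max_edits_conserved_native", "max_edits_conserved_other",
              "max_coverage_diff", "mapping_max_mismatch", "min_duplex_pairs",
              "max_bulge", "max_asymmetry", "min_phase_abundance")
  for (f in counts) if (cfg[[f]] < 0) stopf("%s must be >= 0", f)
  if (cfg$precursor_mfe_max >= 0) stopf("precursor_mfe_max must be negative")
  if (cfg$target_mfe_max >= 0) stopf("target_mfe_max must be negative")
  if (!is.null(cfg$top_n_targets) &&
      (cfg$top_n_targets < 10 || cfg$top_n_targets > 20))
    stopf("top_n_targets must lie in [10, 20]")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-26s %s\n", nm, if (is.null(v)) "auto" else format(v)))
  }
  invisible(x)
}
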