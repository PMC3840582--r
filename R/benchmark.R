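#' Ground-truth recovery metrics of a synthetic pipeline run
#'
#' Compares a [run_pipeline()] result obtained on synthetic libraries with
#' the planted ground truth and returns the benchmark quantities of the
#' study design: conserved-family recovery (over the families planted at
#' recoverable abundance, i.e. excluding the low-abundance decoys),
#' contaminant-to-family misassignments, novel-hairpin recovery, and TAS
#' locus recovery with the worst called p-value.
#'
#' @param run a `pipeline_run` whose config contained a `sim` section.
#' @return list of metrics: `conserved_recovery`, `contaminant_assignments`,
#'   `decoy_families_kept`, `novel_recovery`, `tas_recovery`,
#'   `tas_max_pvalue`, plus the underlying counts.
#' @export
recovery_metrics <- function(run) {
  stopifnot(inherits(run, "pipeline_run"))
  truth <- run$refs$truth

  ## conserved families
  pm <- truth$planted_mirnas
  recoverable <- pm$family[!pm$decoy]
  kept <- run$families$kept$family
  conserved_recovery <- if (length(recoverable))
    mean(recoverable %in% kept) else NA_real_
  decoy_kept <- sum(pm$family[pm$decoy] %in% kept)

  ## contaminant-to-family assignments: assigned tags whose true category
  ## is an ncRNA/repeat/exon contaminant
  cont_tags <- truth$expected_category$seq[
    truth$expected_category$category %in%
      c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA", "repeat", "exon")]
  contaminant_assignments <-
    sum(run$assignments$tag_seq %in% as_tag_seq(cont_tags))

  ## novel hairpins: planted loci overlapped by an accepted novel locus
  pn <- truth$planted_novel
  nv <- if (is.null(run$novel)) NULL else run$novel$novel
  novel_hit <- if (nrow(pn) && !is.null(nv) && nrow(nv)) {
    vapply(seq_len(nrow(pn)), function(i) {
      any(nv$ref_id == pn$contig[i] & nv$locus_start < pn$pre_end[i] &
            nv$locus_end > pn$pre_start[i])
    }, TRUE)
  } else rep(FALSE, nrow(pn))
  novel_recovery <- if (nrow(pn)) mean(novel_hit) else NA_real_

  ## TAS loci
  pt <- truth$planted_tas
  loci <- if (is.null(run$tasi)) NULL else run$tasi$loci
  tas_p <- rep(NA_real_, nrow(pt))
  if (nrow(pt) && !is.null(loci) && nrow(loci)) {
    for (i in seq_len(nrow(pt))) {
      ov <- loci$ref_id == pt$contig[i] & loci$start < pt$end[i] &
        loci$end > pt$start[i]
      if (any(ov)) tas_p[i] <- min(loci$p_value[ov])
    }
  }
  tas_called <- !is.na(tas_p)

  list(conserved_recovery = conserved_recovery,
       n_recoverable_families = length(recoverable),
       decoy_families_kept = decoy_kept,
       contaminant_assignments = contaminant_assignments,
       novel_recovery = novel_recovery,
       n_planted_hairpins = nrow(pn),
       tas_recovery = if (nrow(pt)) mean(tas_called) else NA_real_,
       tas_max_pvalue = if (any(tas_called)) max(tas_p, na.rm = TRUE) else
         NA_real_,
       n_planted_tas = nrow(pt))
}

#' Hairpin acceptances on a dinucleotide-shuffled genome
#'
#' Negative control of the novel-miRNA stage: every genomic contig is
#' dinucleotide-shuffled ([shuffle_dinucleotide()]) and the run's
#' unannotated tags are re-mapped, excised, folded and evaluated on the
#' shuffled genome.  On a shuffled genome no planted structure survives,
#' so accepted candidates are false positives.
#'
#' @param run a `pipeline_run` with a synthetic reference set.
#' @param seed integer seed of the shuffle.
#' @return number of accepted hairpin candidates on the shuffled genome.
#' @export
shuffled_genome_acceptances <- function(run, seed = 1) {
  stopifnot(inherits(run, "pipeline_run"))
  genome <- run$refs$genome
  shuffled <- with_seed(seed, vapply(genome, shuffle_dinucleotide, ""))
  names(shuffled) <- names(genome)
  ann <- run$cascade$annotations
  unann <- setdiff(ann$tag_seq[ann$category == "unannotated"],
                   run$assignments$tag_seq)
  cfg <- do.call(pipeline_config, run$manifest$config$pipeline)
  res <- predict_novel_mirnas(subset_tags(run$table, unann), shuffled, cfg,
                              mode = "contig")
  nrow(res$novel)
}
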