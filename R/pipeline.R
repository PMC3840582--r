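#' Run the full small RNA analysis pipeline
#'
#' Orchestrates every stage on one configuration: (optional) synthetic
#' library generation, read QC, tag collapsing and normalization, the
#' annotation cascade, conserved-family classification and filtering,
#' novel hairpin prediction, the tasiRNA phasing scan (fed with the
#' unannotated tags plus the exon-matching tags), target prediction for
#' all identified miRNAs, and GO enrichment of the predicted target genes.
#' Writes all TSV/GFF3 outputs and a run manifest into `out_dir` and
#' returns the stage results.
#'
#' @param config list with elements `sim` (a [sim_config()]; or `fastq` =
#'   named FASTQ paths plus `refs` = a reference bundle of the
#'   [simulate_references()] layout), `cfg` (a [pipeline_config()]),
#'   and optional logical switches `run_novel`, `run_tasi`, `run_targets`,
#'   `run_enrichment` (all `TRUE` by default).  A path to a YAML file with
#'   the same structure is also accepted.
#' @param out_dir output directory.
#' @param verbose print per-stage progress.
#' @return object of class `pipeline_run`: list of stage results plus a
#'   `manifest` (config snapshot, per-stage counts, seeds, tool version).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("srna_run"),
                         verbose = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- config_from_yaml(config)
  }
  cfg <- config$cfg %||% pipeline_config()
  opts <- list(run_novel = config$run_novel %||% TRUE,
               run_tasi = config$run_tasi %||% TRUE,
               run_targets = config$run_targets %||% TRUE,
               run_enrichment = config$run_enrichment %||% TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(tool = paste0("sRNAcascade ",
                                 as.character(utils::packageVersion("sRNAcascade"))),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  ledger <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  ## inputs -----------------------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- config$sim
    manifest$rng_seed <- sim$rng_seed
    say("simulate: %d libraries x %d reads", sim$n_libraries,
        sim$reads_per_library)
    refs <- simulate_references(sim)
    libs <- simulate_libraries(sim, refs, file.path(out_dir, "fastq"))
    fastq <- libs$files
    adapter3 <- sim$adapter3
    adapter5 <- sim$adapter5
    ledger("simulate", libraries = length(fastq),
           reads_per_library = sim$reads_per_library)
  } else {
    if (is.null(config$fastq) || is.null(config$refs))
      stopf("config needs either a 'sim' section or 'fastq' + 'refs'")
    refs <- config$refs
    fastq <- config$fastq
    libs <- NULL
    adapter3 <- config$adapter3 %||% stopf("config$adapter3 missing")
    adapter5 <- config$adapter5 %||% stopf("config$adapter5 missing")
  }
  manifest$config <- list(pipeline = unclass(cfg))

  ## QC ---------------------------------------------------------------------
  clean <- list()
  reports <- list()
  for (lib in names(fastq)) {
    reads <- read_fastq(fastq[[lib]])
    res <- qc_filter(reads, adapter3, adapter5, cfg)
    clean[[lib]] <- res$clean
    reports[[lib]] <- res$report
    write_qc_report(res$report, file.path(out_dir, paste0("qc_", lib, ".tsv")))
    say("qc %s: %d -> %d reads", lib, res$report$input_reads,
        res$report$clean_reads)
  }
  ledger("qc", input = sum(vapply(reports, `[[`, 0L, "input_reads")),
         clean = sum(vapply(reports, `[[`, 0L, "clean_reads")))

  ## collapse + normalize ----------------------------------------------------
  table <- collapse_tags(clean)
  table <- normalize_counts(table, scale = cfg$norm_scale)
  write_tag_table(table, file.path(out_dir, "tag_table.tsv"))
  say("collapse: %d unique tags", length(table$seq))
  ledger("collapse", unique_tags = length(table$seq))

  ## annotation cascade -------------------------------------------------------
  casc <- annotate_cascade(table, refs$refsets, cfg)
  ann <- casc$annotations
  write.table(ann, file.path(out_dir, "annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(casc$stats, file.path(out_dir, "cascade_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  unann <- ann$tag_seq[ann$category == "unannotated"]
  say("cascade: %d tags unannotated", length(unann))
  ledger("cascade", unannotated = length(unann))

  ## conserved miRNA classification -------------------------------------------
  assignments <- classify_conserved(unann, refs$native_mirnas,
                                    refs$other_mirnas, cfg)
  families <- filter_families(assignments, table,
                              refs$brassicaceae_families, cfg)
  write.table(assignments, file.path(out_dir, "conserved_assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(families$kept, file.path(out_dir, "families.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  say("conserved: %d tags in %d families (%d dropped)",
      nrow(assignments), nrow(families$kept), nrow(families$dropped))
  ledger("conserved", assigned_tags = nrow(assignments),
         families_kept = nrow(families$kept),
         families_dropped = nrow(families$dropped))
  kept_assign <- assignments[assignments$family %in% families$kept$family, ,
                             drop = FALSE]
  unann2 <- setdiff(unann, assignments$tag_seq)

  ## novel miRNA prediction -----------------------------------------------------
  novel <- NULL
  if (opts$run_novel) {
    nv_table <- subset_tags(table, unann2)
    novel <- predict_novel_mirnas(nv_table, refs$genome, cfg, mode = "contig")
    write_novel_mirnas(novel$novel, file.path(out_dir, "novel_mirnas.tsv"),
                       file.path(out_dir, "novel_mirnas.gff3"))
    say("novel: %d candidates, %d accepted", nrow(novel$candidates),
        nrow(novel$novel))
    ledger("novel", candidates = nrow(novel$candidates),
           accepted = nrow(novel$novel))
  }

  ## tasiRNA scan ---------------------------------------------------------------
  tasi <- NULL
  if (opts$run_tasi) {
    # unannotated tags plus the full set of exon-matching tags
    tasi_tags <- union(unann2, ann$tag_seq[ann$category == "exon"])
    tasi_hits <- map_tags(tasi_tags, refs$genome, cfg, mode = "contig")
    tasi_hits <- tasi_hits[tasi_hits$strand == "+", , drop = FALSE]
    counts <- setNames(rowSums(table$counts), table$seq)
    pileup <- data.frame(ref_id = tasi_hits$ref_id, pos = tasi_hits$start,
                         len = nchar(tasi_hits$tag_seq),
                         count = as.numeric(counts[tasi_hits$tag_seq]),
                         tag_seq = tasi_hits$tag_seq)
    windows <- scan_phasing(pileup, vapply(refs$genome, nchar, 0L), cfg)
    tasi <- call_tas_loci(windows, pileup, cfg)
    if (length(refs$known_tas) && length(tasi_tags)) {
      tasi$known <- match_known_tas(tasi_tags, refs$known_tas, cfg)
    }
    write.table(tasi$loci, file.path(out_dir, "tas_loci.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (nrow(tasi$loci)) {
      write_gff3(data.frame(ref_id = tasi$loci$ref_id,
                            start = tasi$loci$start, end = tasi$loci$end,
                            strand = tasi$loci$strand, type = "TAS_locus",
                            id = tasi$loci$locus_id),
                 file.path(out_dir, "tas_loci.gff3"))
    }
    say("tasi: %d windows, %d loci", nrow(windows), nrow(tasi$loci))
    ledger("tasi", windows = nrow(windows), loci = nrow(tasi$loci))
  }

  ## target prediction ------------------------------------------------------------
  targets <- NULL
  if (opts$run_targets) {
    mirnas <- character(0)
    if (nrow(kept_assign)) {
      # one representative tag per reference miRNA (fewest edits), so
      # sequencing-error isoforms do not multiply the scan
      m <- kept_assign[!kept_assign$is_star, , drop = FALSE]
      m <- m[order(m$source_mirna, m$mismatches + m$gaps, m$tag_seq), ,
             drop = FALSE]
      m <- m[!duplicated(m$source_mirna), , drop = FALSE]
      mirnas <- setNames(m$tag_seq, m$source_mirna)
    }
    if (!is.null(novel) && nrow(novel$novel))
      mirnas <- c(mirnas, setNames(novel$novel$mature_seq, novel$novel$name))
    targets <- find_targets(mirnas, refs$transcripts, cfg)
    write.table(targets, file.path(out_dir, "targets.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    say("targets: %d hits for %d miRNAs", nrow(targets),
        length(unique(targets$mirna_id)))
    ledger("targets", mirnas = length(mirnas), hits = nrow(targets))
  }

  ## GO enrichment ------------------------------------------------------------------
  enrichment <- NULL
  if (opts$run_enrichment && !is.null(targets) && nrow(targets) &&
      !is.null(refs$go)) {
    map <- propagate_annotations(
      annotation_map(refs$go$annotations, refs$go$parents))
    study <- unique(targets$target_id)
    population <- names(refs$transcripts)
    enrichment <- term_for_term(study, population, map, cfg)
    write.table(enrichment, file.path(out_dir, "go_enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    say("enrichment: %d terms tested, %d significant", nrow(enrichment),
        sum(enrichment$significant))
    ledger("enrichment", tested = nrow(enrichment),
           significant = sum(enrichment$significant))
  }

  out <- list(table = table, qc_reports = reports, cascade = casc,
              assignments = assignments, families = families,
              novel = novel, tasi = tasi, targets = targets,
              enrichment = enrichment, refs = refs, libraries = libs,
              manifest = manifest, out_dir = out_dir)
  class(out) <- "pipeline_run"
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(y$sim)) out$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$cfg)) out$cfg <- do.call(pipeline_config, y$cfg)
  for (k in c("run_novel", "run_tasi", "run_targets", "run_enrichment",
              "fastq", "refs", "adapter3", "adapter5"))
    if (!is.null(y[[k]])) out[[k]] <- y[[k]]
  out
}

#' Summary report of a pipeline run
#'
#' Markdown summary in the layout of a clean-reads annotation ledger:
#' per-category unique/total counts and percentages per library, the kept
#' family table, and novel/TAS/target/enrichment counts.
#'
#' @param run a `pipeline_run` from [run_pipeline()].
#' @return character vector of markdown lines (also printable).
#' @export
pipeline_report <- function(run) {
  stopifnot(inherits(run, "pipeline_run"))
  st <- run$cascade$stats
  libs <- run$table$library_ids
  lines <- c("# Small RNA pipeline summary", "",
             "## Clean read annotation", "",
             paste0("| category | unique | ",
                    paste(vapply(libs, function(l)
                      sprintf("total %s | pct %s", l, l), ""),
                      collapse = " | "), " |"),
             paste0("|", paste(rep("---", 2 + 2 * length(libs)),
                               collapse = "|"), "|"))
  # tags assigned to conserved families are carved out of 'unannotated'
  for (i in seq_len(nrow(st))) {
    row <- st[i, ]
    cells <- vapply(libs, function(l)
      sprintf("%d | %.2f%%", row[[paste0("total_", l)]],
              row[[paste0("pct_", l)]]), "")
    lines <- c(lines, sprintf("| %s | %d | %s |", row$category, row$unique,
                              paste(cells, collapse = " | ")))
  }
  fam <- run$families$kept
  lines <- c(lines, "", sprintf("## Conserved families kept: %d", nrow(fam)))
  if (nrow(fam)) {
    ord <- order(-fam$mean_norm_total)
    top <- utils::head(fam[ord, ], 10)
    lines <- c(lines, "", "| family | members | mean norm |", "|---|---|---|",
               sprintf("| %s | %d | %.1f |", top$family, top$n_members,
                       top$mean_norm_total))
  }
  lines <- c(lines,
             "",
             sprintf("- novel miRNAs accepted: %d",
                     if (is.null(run$novel)) 0L else nrow(run$novel$novel)),
             sprintf("- TAS loci called: %d",
                     if (is.null(run$tasi)) 0L else nrow(run$tasi$loci)),
             sprintf("- target hits: %d",
                     if (is.null(run$targets)) 0L else nrow(run$targets)),
             sprintf("- enriched GO terms: %d",
                     if (is.null(run$enrichment)) 0L else
                       sum(run$enrichment$significant)))
  lines
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(pipeline_report(x), sep = "\n")
  invisible(x)
}
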