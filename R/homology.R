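#' Edit-bounded alignment of a tag against a reference
#'
#' Minimum-edit end-to-end alignment of the tag against the best location in
#' the reference: the tag is fully consumed, reference end points are free,
#' and every mismatch or 1-nt gap costs one edit.  This deterministic
#' bounded matcher stands in for the BlastN searches of the original
#' protocol (at up to 3 edits over 18-30 nt queries it is strictly more
#' sensitive, so E-values are not modelled).
#'
#' With `protect_seed = TRUE` an alignment is rejected when any edit falls
#' in the tag's seed region (positions `seed_start`..`seed_end`, 1-based
#' from the 5' end; a gap between tag positions counts against the position
#' it precedes), or when the tag and reference lengths differ by more than
#' `max_coverage_diff`.
#'
#' @param tag single tag sequence (non-empty).
#' @param ref single reference sequence.
#' @param max_edits maximum edits (mismatches + gaps).
#' @param protect_seed reject alignments with seed-region edits and apply
#'   the length-coverage rule.
#' @param cfg a [pipeline_config()] (seed coordinates, coverage bound).
#' @return `NULL` when there is no qualifying match, otherwise a list with
#'   `ref_start`/`ref_end` (0-based half-open), `mismatches`, `gaps`,
#'   `seed_violations`, `len_diff`, `aligned_tag`, `aligned_ref`.
#' @examples
#' align_tag("ACGUACGU", "GGACGUACGUGG", max_edits = 0)$ref_start  # 2
#' @export
align_tag <- function(tag, ref, max_edits, protect_seed = FALSE,
                      cfg = pipeline_config()) {
  if (!nzchar(tag)) stopf("empty tag")
  tag <- as_tag_seq(tag)
  ref <- as_tag_seq(ref)
  check_alphabet(c(tag, ref))
  a <- align_tag_cpp(tag, ref, as.integer(max_edits),
                     if (protect_seed) cfg$seed_start else 0L,
                     if (protect_seed) cfg$seed_end else 0L)
  if (!a$found) return(NULL)
  len_diff <- abs(nchar(tag) - nchar(ref))
  if (protect_seed &&
      (a$seed_violations > 0 || len_diff > cfg$max_coverage_diff))
    return(NULL)
  a$found <- NULL
  a$len_diff <- len_diff
  a
}

# Best bounded match of many tags against one reference set (compiled
# pigeonhole-seeded matcher).  refs: data frame with id, seq.
match_refset <- function(tags, refs, max_edits, protect_seed = FALSE,
                         cfg = pipeline_config(), max_len_diff = -1L) {
  if (length(tags) == 0 || nrow(refs) == 0) {
    return(data.frame(tag_seq = character(), reference_id = character(),
                      mismatches = integer(), gaps = integer(),
                      seed_violations = integer(), ref_start = integer(),
                      ref_end = integer(), aligned_tag = character(),
                      aligned_ref = character()))
  }
  refs <- refs[order(refs$id), , drop = FALSE]  # deterministic tie-break
  m <- match_refset_cpp(as_tag_seq(tags), as_tag_seq(refs$seq),
                        as.integer(max_edits), protect_seed,
                        cfg$seed_start, cfg$seed_end,
                        as.integer(max_len_diff))
  hit <- !is.na(m$ref)
  data.frame(tag_seq = tags[hit], reference_id = refs$id[m$ref[hit]],
             mismatches = m$mismatches[hit], gaps = m$gaps[hit],
             seed_violations = m$seed_violations[hit],
             ref_start = m$ref_start[hit], ref_end = m$ref_end[hit],
             aligned_tag = m$aligned_tag[hit],
             aligned_ref = m$aligned_ref[hit],
             ref_row = m$ref[hit], row.names = NULL)
}

cascade_categories <- c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA",
                        "repeat", "exon")

#' Cascading annotation of unique tags
#'
#' Two-pass annotation cascade: every tag is matched first against the
#' same-species ("native") reference sets in the fixed category order rRNA,
#' tRNA, snRNA, snoRNA, scRNA, repeat, exon (edit budget
#' `max_edits_ncrna_native` = 1), then against close-relative sets in the
#' same order (`max_edits_ncrna_relative` = 2).  A tag receives the
#' category of the first set it matches; later sets never re-annotate.
#'
#' @param table a `tag_table` of clean unique tags.
#' @param refsets data frame of references: columns `id`, `seq`, `category`
#'   (one of the cascade categories above) and `native` (logical or 0/1).
#' @param cfg a [pipeline_config()].
#' @return list with `annotations` (data frame `tag_seq`, `category`,
#'   `reference_id`, `mismatches`, `gaps`; unannotated tags carry category
#'   `"unannotated"` and empty `reference_id`) and `stats` (per-category,
#'   per-library unique/total tallies and percentages of clean reads, in
#'   clean-reads-ledger layout).
#' @export
annotate_cascade <- function(table, refsets, cfg = pipeline_config()) {
  stopifnot(inherits(table, "tag_table"))
  refsets$native <- as.logical(as.integer(refsets$native))
  bad <- setdiff(unique(refsets$category), cascade_categories)
  if (length(bad))
    stopf("unknown refset label(s): %s", paste(bad, collapse = ", "))
  ann <- data.frame(tag_seq = table$seq, category = "unannotated",
                    reference_id = "", mismatches = NA_integer_,
                    gaps = NA_integer_, row.names = NULL)
  for (native in c(TRUE, FALSE)) {
    budget <- if (native) cfg$max_edits_ncrna_native else
      cfg$max_edits_ncrna_relative
    for (cat in cascade_categories) {
      refs <- refsets[refsets$category == cat & refsets$native == native, ,
                      drop = FALSE]
      if (nrow(refs) == 0) next
      open <- which(ann$category == "unannotated")
      if (!length(open)) break
      hits <- match_refset(ann$tag_seq[open], refs, budget, FALSE, cfg)
      if (nrow(hits) == 0) next
      idx <- open[match(hits$tag_seq, ann$tag_seq[open])]
      ann$category[idx] <- cat
      ann$reference_id[idx] <- hits$reference_id
      ann$mismatches[idx] <- hits$mismatches
      ann$gaps[idx] <- hits$gaps
    }
  }
  list(annotations = ann, stats = cascade_stats(table, ann))
}

# Clean-reads-ledger layout: per category and library, unique tag count,
# total (count-weighted) reads, and percent of clean reads.
cascade_stats <- function(table, ann) {
  libs <- table$library_ids
  cats <- c("clean", cascade_categories, "unannotated")
  rows <- lapply(cats, function(cat) {
    sel <- if (cat == "clean") rep(TRUE, length(table$seq)) else
      ann$category == cat
    cnt <- table$counts[sel, , drop = FALSE]
    row <- data.frame(category = cat, unique = sum(sel))
    for (l in libs) {
      row[[paste0("unique_", l)]] <- sum(cnt[, l] > 0)
      row[[paste0("total_", l)]] <- sum(cnt[, l])
      row[[paste0("pct_", l)]] <-
        100 * sum(cnt[, l]) / max(1, table$library_totals[[l]])
    }
    row
  })
  do.call(rbind, rows)
}

#' Conserved miRNA family classification
#'
#' Two homology passes over (still unannotated) tags: first against the
#' same-species mature miRNA set (at most `max_edits_conserved_native` = 1
#' mismatch/gap outside the seed region), then, for tags not assigned
#' there, against mature miRNAs of other plant species (at most
#' `max_edits_conserved_other` = 3 non-seed edits).  Both passes require
#' the tag and reference lengths to differ by no more than
#' `max_coverage_diff` = 2 nt.  Ties between equal-edit references break to
#' the lexicographically smallest reference id.  Tags matching a
#' star-labelled reference are reported as miRNA* (`is_star`).
#'
#' @param tags character vector of unannotated tag sequences.
#' @param native_mirnas data frame `id`, `seq`, `family`, `star` (0/1) of
#'   same-species mature miRNAs (18-26 nt).
#' @param other_mirnas same layout, other plant species.
#' @param cfg a [pipeline_config()].
#' @return data frame of family assignments: `tag_seq`, `family`,
#'   `source_mirna`, `is_star`, `pass` ("native"/"other"), `mismatches`,
#'   `gaps`, `seed_violations` (always 0: seed protection is absolute).
#' @export
classify_conserved <- function(tags, native_mirnas, other_mirnas,
                               cfg = pipeline_config()) {
  one_pass <- function(tags, refs, budget, pass) {
    if (length(tags) == 0 || is.null(refs) || nrow(refs) == 0) return(NULL)
    hits <- match_refset(tags, refs, budget, protect_seed = TRUE, cfg = cfg,
                         max_len_diff = cfg$max_coverage_diff)
    if (nrow(hits) == 0) return(NULL)
    data.frame(tag_seq = hits$tag_seq,
               family = refs$family[order(refs$id)][hits$ref_row],
               source_mirna = hits$reference_id,
               is_star = as.integer(refs$star[order(refs$id)][hits$ref_row]) == 1L,
               pass = pass, mismatches = hits$mismatches, gaps = hits$gaps,
               seed_violations = hits$seed_violations, row.names = NULL)
  }
  tags <- as_tag_seq(tags)
  nat <- one_pass(tags, native_mirnas, cfg$max_edits_conserved_native,
                  "native")
  rest <- setdiff(tags, nat$tag_seq)
  oth <- one_pass(rest, other_mirnas, cfg$max_edits_conserved_other, "other")
  out <- rbind(nat, oth)
  if (is.null(out))
    out <- data.frame(tag_seq = character(), family = character(),
                      source_mirna = character(), is_star = logical(),
                      pass = character(), mismatches = integer(),
                      gaps = integer(), seed_violations = integer())
  out
}

#' Abundance filter of conserved miRNA families
#'
#' A family is dropped when it is not described in plants closely related
#' to the Brassicaceae and the mean (over libraries) of its members' summed
#' normalized counts falls below `min_family_mean_norm` (15).  Star members
#' do not count toward the abundance sum.
#'
#' @param assignments output of [classify_conserved()].
#' @param table normalized `tag_table` holding the assigned tags.
#' @param brassicaceae_families character vector of family names described
#'   in Brassicaceae relatives.
#' @param cfg a [pipeline_config()].
#' @return list with `kept` and `dropped` family summaries (`family`,
#'   `n_members`, `mean_norm_total`, `brassicaceae_described`).
#' @export
filter_families <- function(assignments, table, brassicaceae_families,
                            cfg = pipeline_config()) {
  empty <- data.frame(family = character(), n_members = integer(),
                      mean_norm_total = numeric(),
                      brassicaceae_described = logical())
  if (nrow(assignments) == 0) return(list(kept = empty, dropped = empty))
  if (is.null(table$norm)) stopf("normalize_counts() must be run first")
  fams <- sort(unique(assignments$family))
  summaries <- do.call(rbind, lapply(fams, function(f) {
    a <- assignments[assignments$family == f, , drop = FALSE]
    nonstar <- a$tag_seq[!a$is_star]
    idx <- match(nonstar, table$seq)
    idx <- idx[!is.na(idx)]
    per_lib <- if (length(idx)) colSums(table$norm[idx, , drop = FALSE]) else
      setNames(rep(0, length(table$library_ids)), table$library_ids)
    data.frame(family = f, n_members = length(unique(a$tag_seq)),
               mean_norm_total = mean(per_lib),
               brassicaceae_described = f %in% brassicaceae_families)
  }))
  drop <- !summaries$brassicaceae_described &
    summaries$mean_norm_total < cfg$min_family_mean_norm
  list(kept = summaries[!drop, , drop = FALSE],
       dropped = summaries[drop, , drop = FALSE])
}
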