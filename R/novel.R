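#' Map tags to genomic or transcript references
#'
#' Exact-seed-and-extend mapping (8-nt seeds) of tags against a reference
#' set, substitutions only, both strands.  In `"contig"` mode no mismatches
#' are allowed; in `"genome"` mode up to `mapping_max_mismatch` (1).
#' Reverse-strand hits are found by searching the tag's reverse complement
#' and reported with forward-strand coordinates and strand `"-"`.
#'
#' @param tags character vector of tag sequences.
#' @param references named character vector of reference sequences.
#' @param cfg a [pipeline_config()].
#' @param mode `"contig"` (0 mismatches) or `"genome"`.
#' @return data frame of hits: `tag_seq`, `ref_id`, `start`, `end` (0-based
#'   half-open), `strand`, `edits`.
#' @export
map_tags <- function(tags, references, cfg = pipeline_config(),
                     mode = c("contig", "genome")) {
  mode <- match.arg(mode)
  max_mm <- if (mode == "contig") 0L else as.integer(cfg$mapping_max_mismatch)
  if (length(tags) == 0 || length(references) == 0) {
    return(data.frame(tag_seq = character(), ref_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), edits = integer()))
  }
  hits <- map_tags_cpp(as_tag_seq(tags), as_tag_seq(references), max_mm)
  data.frame(tag_seq = tags[hits$tag], ref_id = names(references)[hits$ref],
             start = hits$start, end = hits$end, strand = hits$strand,
             edits = hits$edits, row.names = NULL)
}

#' Excise and fold hairpin precursor candidates around a genomic hit
#'
#' For each mapped tag two precursor windows are excised around the hit,
#' `[start - 250, end + 50)` and `[start - 50, end + 250)` (clipped to the
#' reference; windows shorter than 40 nt are skipped), folded, and turned
#' into hairpin candidates.  A candidate is kept only when the mature span
#' lies on an arm of the fold, i.e. does not overlap a hairpin loop, and
#' pairs with an opposite arm.  The miRNA* span is the pairing partner of
#' the mature span extended by a 2-nt 3' overhang.
#'
#' Duplex statistics stored per candidate: `duplex_pairs` (mature bases
#' paired to the star arm), `max_bulge` (longest unpaired run interior to
#' the duplex on either strand), `asymmetry` (absolute difference of
#' interior unpaired counts between the two strands).
#'
#' @param hits data frame from [map_tags()] (one or more rows).
#' @param references named character vector of reference sequences.
#' @param cfg a [pipeline_config()].
#' @return data frame of candidates: reference coordinates of the window
#'   (`ref_id`, `locus_start`, `locus_end`, `strand`), `precursor_seq`,
#'   `structure`, `mfe`, `mature_seq`, 1-based `mature_start`/`mature_end`
#'   and `star_start`/`star_end` within the precursor, duplex statistics
#'   and `arm` (`"5p"`/`"3p"`).
#' @export
excise_candidates <- function(hits, references, cfg = pipeline_config()) {
  empty <- data.frame(ref_id = character(), locus_start = integer(),
                      locus_end = integer(), strand = character(),
                      precursor_seq = character(), structure = character(),
                      mfe = numeric(), mature_seq = character(),
                      mature_start = integer(), mature_end = integer(),
                      star_start = integer(), star_end = integer(),
                      duplex_pairs = integer(), max_bulge = integer(),
                      asymmetry = integer(), arm = character())
  if (nrow(hits) == 0) return(empty)
  fl <- cfg$excision_flank_long
  fs <- cfg$excision_flank_short
  # collect windows
  win <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    refseq <- as_tag_seq(references[[h$ref_id]])
    L <- nchar(refseq)
    if (h$strand == "-") {
      refseq <- revcomp(refseq)
      s <- L - h$end
      e <- L - h$start
    } else {
      s <- h$start
      e <- h$end
    }
    for (geom in list(c(fl, fs), c(fs, fl))) {
      ws <- max(0L, s - geom[1])
      we <- min(L, e + geom[2])
      if (we - ws < 40) next
      win[[length(win) + 1]] <- list(
        ref_id = h$ref_id, strand = h$strand,
        # forward-reference coordinates of the window for locus book-keeping
        locus_start = if (h$strand == "-") L - we else ws,
        locus_end = if (h$strand == "-") L - ws else we,
        seq = substr(refseq, ws + 1, we),
        mat_start = s - ws + 1L, mat_end = e - ws,
        tag = h$tag_seq)
    }
  }
  if (!length(win)) return(empty)
  folded <- fold_rna(vapply(win, `[[`, "", "seq"))
  out <- list()
  for (i in seq_along(win)) {
    w <- win[[i]]
    st <- hairpin_stats(folded$structure[i], w$mat_start, w$mat_end)
    if (is.null(st)) next
    out[[length(out) + 1]] <- data.frame(
      ref_id = w$ref_id, locus_start = w$locus_start,
      locus_end = w$locus_end, strand = w$strand,
      precursor_seq = folded$seq[i], structure = folded$structure[i],
      mfe = folded$mfe[i], mature_seq = w$tag,
      mature_start = w$mat_start, mature_end = w$mat_end,
      star_start = st$star_start, star_end = st$star_end,
      duplex_pairs = st$duplex_pairs, max_bulge = st$max_bulge,
      asymmetry = st$asymmetry, arm = st$arm)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# Duplex statistics of a mature span within a folded precursor; NULL when
# the mature overlaps a hairpin loop or pairs with nothing outside itself.
hairpin_stats <- function(structure, mat_start, mat_end) {
  pt <- db_pairs(structure)
  loops <- db_hairpin_loops(pt)
  for (lp in loops) {
    if (mat_start <= lp[2] && mat_end >= lp[1]) return(NULL)
  }
  span <- mat_start:mat_end
  partners <- pt[span]
  outside <- partners != 0 & (partners < mat_start | partners > mat_end)
  if (!any(outside)) return(NULL)
  duplex_pairs <- sum(outside)
  star_lo <- min(partners[outside])
  star_hi <- max(partners[outside])
  star_end <- min(length(pt), star_hi + 2L)  # 2-nt 3' overhang
  run_max <- function(unpaired) {
    r <- rle(unpaired)
    m <- r$lengths[r$values]
    if (length(m)) max(m) else 0L
  }
  interior <- function(lo, hi) {
    pos <- lo:hi
    up <- pt[pos] == 0 | (pt[pos] >= mat_start & pt[pos] <= mat_end &
                            pos >= mat_start & pos <= mat_end)
    paired_idx <- which(!up)
    if (length(paired_idx) < 2) return(list(run = 0L, n = 0L))
    core <- up[min(paired_idx):max(paired_idx)]
    list(run = run_max(core), n = sum(core))
  }
  m_int <- interior(mat_start, mat_end)
  s_int <- interior(star_lo, star_hi)
  list(duplex_pairs = duplex_pairs,
       max_bulge = max(m_int$run, s_int$run),
       asymmetry = abs(m_int$n - s_int$n),
       star_start = star_lo, star_end = star_end,
       arm = if (mean(span) < mean(c(star_lo, star_hi))) "5p" else "3p")
}

#' Structural acceptance of a hairpin candidate
#'
#' A candidate is accepted iff all criteria hold simultaneously: folding
#' free energy at most -18 kcal/mol, at least 16 base pairs in the
#' miRNA:miRNA* duplex, bulge size at most 4 nt, strand asymmetry at most
#' 4 nt, and the mature on a single arm (guaranteed by excision).  Failed
#' criteria are reported as reason codes.
#'
#' @param candidates data frame from [excise_candidates()].
#' @param cfg a [pipeline_config()].
#' @return the candidates with logical `accept` and a `reasons` column
#'   (comma-separated codes among `mfe`, `duplex_pairs`, `max_bulge`,
#'   `asymmetry`; empty when accepted).
#' @export
evaluate_hairpin <- function(candidates, cfg = pipeline_config()) {
  n <- nrow(candidates)
  reasons <- character(n)
  add <- function(reasons, bad, code)
    ifelse(bad, ifelse(nzchar(reasons), paste0(reasons, ",", code), code),
           reasons)
  reasons <- add(reasons, candidates$mfe > cfg$precursor_mfe_max, "mfe")
  reasons <- add(reasons, candidates$duplex_pairs < cfg$min_duplex_pairs,
                 "duplex_pairs")
  reasons <- add(reasons, candidates$max_bulge > cfg$max_bulge, "max_bulge")
  reasons <- add(reasons, candidates$asymmetry > cfg$max_asymmetry,
                 "asymmetry")
  candidates$accept <- !nzchar(reasons)
  candidates$reasons <- reasons
  candidates
}

#' Single-dominant-product curation of accepted hairpins
#'
#' Implements the expression-based curation of the community annotation
#' criteria: a candidate is kept when the mature tag contributes at least
#' `min_dominance` (50 percent) of all reads mapped within its precursor
#' locus and the 5' ends of its supporting reads vary by at most
#' `max_5p_heterogeneity` (2 nt).  Overlapping same-strand precursors are
#' collapsed to the candidate with the highest dominance.
#'
#' @param candidates evaluated candidates ([evaluate_hairpin()]) —
#'   only accepted rows are considered.
#' @param hits full mapping table ([map_tags()]) of all tags on the same
#'   references (the precursor pileup).
#' @param counts named numeric vector: total read count per tag sequence.
#' @param cfg a [pipeline_config()].
#' @return the surviving candidates with `dominance` added.
#' @export
dominance_filter <- function(candidates, hits, counts,
                             cfg = pipeline_config()) {
  cand <- candidates[candidates$accept, , drop = FALSE]
  if (nrow(cand) == 0) {
    cand$dominance <- numeric(0)
    return(cand)
  }
  dom <- numeric(nrow(cand))
  homog <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    c1 <- cand[i, ]
    inlocus <- hits[hits$ref_id == c1$ref_id &
                      hits$start < c1$locus_end &
                      hits$end > c1$locus_start, , drop = FALSE]
    cnt <- counts[inlocus$tag_seq]
    cnt[is.na(cnt)] <- 0
    total <- sum(cnt)
    # mature span in forward-reference coordinates
    if (c1$strand == "-") {
      mat_fwd_end <- c1$locus_end - (c1$mature_start - 1L)
      mat_fwd_start <- c1$locus_end - c1$mature_end
    } else {
      mat_fwd_start <- c1$locus_start + c1$mature_start - 1L
      mat_fwd_end <- c1$locus_start + c1$mature_end
    }
    sup <- inlocus[pmin(inlocus$end, mat_fwd_end) -
                     pmax(inlocus$start, mat_fwd_start) >= 16, , drop = FALSE]
    mature_cnt <- sum(counts[unique(sup$tag_seq)], na.rm = TRUE)
    dom[i] <- if (total > 0) mature_cnt / total else 0
    five_prime <- if (c1$strand == "-") sup$end else sup$start
    homog[i] <- length(five_prime) > 0 &&
      diff(range(five_prime)) <= cfg$max_5p_heterogeneity
  }
  cand$dominance <- dom
  cand <- cand[dom >= cfg$min_dominance & homog, , drop = FALSE]
  if (nrow(cand) <= 1) return(cand)
  # collapse overlapping same-strand loci, highest dominance first
  cand <- cand[order(-cand$dominance, cand$ref_id, cand$locus_start), ,
               drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))[-1]) {
    prev <- which(keep[seq_len(i - 1)])
    clash <- any(cand$ref_id[prev] == cand$ref_id[i] &
                   cand$strand[prev] == cand$strand[i] &
                   cand$locus_start[prev] < cand$locus_end[i] &
                   cand$locus_end[prev] > cand$locus_start[i])
    keep[i] <- !clash
  }
  cand[keep, , drop = FALSE]
}

#' Predict novel miRNAs from unannotated tags
#'
#' Full novel-miRNA stage: map the tags to the reference contigs (no
#' mismatches), excise and fold precursor windows around every hit, apply
#' the structural acceptance rules and the dominance curation.
#'
#' @param table `tag_table` restricted to unannotated tags (or a character
#'   vector of tags plus `counts`).
#' @param references named character vector of genomic contigs.
#' @param cfg a [pipeline_config()].
#' @param mode mapping mode, see [map_tags()].
#' @return list with `hits`, `candidates` (evaluated) and `novel` (the
#'   final curated data frame, one row per novel miRNA).
#' @export
predict_novel_mirnas <- function(table, references, cfg = pipeline_config(),
                                 mode = "contig") {
  if (inherits(table, "tag_table")) {
    tags <- table$seq
    counts <- setNames(rowSums(table$counts), table$seq)
  } else {
    tags <- table
    counts <- setNames(rep(1, length(tags)), tags)
  }
  keep <- nchar(tags) >= 18 & nchar(tags) <= 24
  hits <- map_tags(tags[keep], references, cfg, mode = mode)
  all_hits <- map_tags(tags, references, cfg, mode = mode)
  cands <- excise_candidates(hits, references, cfg)
  cands <- evaluate_hairpin(cands, cfg)
  novel <- dominance_filter(cands, all_hits, counts, cfg)
  if (nrow(novel)) {
    novel$name <- sprintf("novel-m%04d", seq_len(nrow(novel)))
    novel$count <- as.numeric(counts[novel$mature_seq])
  }
  list(hits = all_hits, candidates = cands, novel = novel)
}

#' Write novel miRNA predictions
#'
#' TSV of the curated novel set (name, mature and precursor sequences,
#' dot-bracket structure, MFE, arm, dominance, counts) plus a GFF3 of the
#' precursor loci.
#'
#' @param novel data frame from [predict_novel_mirnas()]`$novel`.
#' @param tsv,gff3 output paths (either may be `NULL` to skip).
#' @export
write_novel_mirnas <- function(novel, tsv = NULL, gff3 = NULL) {
  if (!is.null(tsv)) {
    cols <- c("name", "mature_seq", "precursor_seq", "structure", "mfe",
              "arm", "dominance", "count")
    write.table(novel[, intersect(cols, names(novel)), drop = FALSE], tsv,
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(gff3)) {
    df <- data.frame(ref_id = novel$ref_id, start = novel$locus_start,
                     end = novel$locus_end, strand = novel$strand,
                     type = "miRNA_primary_transcript", id = novel$name)
    write_gff3(df, gff3)
  }
  invisible(novel)
}
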