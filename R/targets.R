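#' Complementarity score of a miRNA against a target site
#'
#' Local antiparallel complementarity alignment of the miRNA (5'→3')
#' against the site (read 3'→5'), by dynamic programming with affine gaps.
#' Column scores: canonical pair (A:U, G:C) `+match_score` (5), G:U wobble
#' `+wobble_score` (2), mismatch `mismatch_score` (-3), gap open -9 and gap
#' extend -4; every column consuming a miRNA seed position (2..8 from the
#' 5' end) is scaled by `seed_scale` (4).
#'
#' @param mirna miRNA sequence, 18-26 nt.
#' @param site target site sequence (5'→3').
#' @param cfg a [pipeline_config()].
#' @return list with `score`, `pair_string` (per column: `|` canonical,
#'   `:` wobble, `.` mismatch, `-` gap), `aligned_mirna` (5'→3'),
#'   `aligned_target` (3'→5', columns aligned with the miRNA),
#'   `mirna_span` and `target_span` (the latter 0-based half-open on the
#'   forward site), and `seed_ok` (no gap and no non-canonical pair within
#'   miRNA positions 2..8; G:U counts as non-canonical unless
#'   `seed_allow_wobble`).
#' @examples
#' m <- "UGAAGCUGCCAGCAUGAUCUA"
#' score_duplex_alignment(m, revcomp(m))$score   # 210
#' @export
score_duplex_alignment <- function(mirna, site, cfg = pipeline_config()) {
  mirna <- as_tag_seq(mirna)
  site <- as_tag_seq(site)
  check_alphabet(mirna, what = "miRNA")
  check_alphabet(site, extra = "N", what = "site")
  if (nchar(mirna) < 18 || nchar(mirna) > 26)
    stopf("miRNA length must be 18-26 nt")
  rsite <- paste(rev(strsplit(site, "")[[1]]), collapse = "")
  a <- target_align_cpp(mirna, rsite, cfg$match_score, cfg$wobble_score,
                        cfg$mismatch_score, cfg$gap_open, cfg$gap_extend,
                        cfg$seed_start, cfg$seed_end, cfg$seed_scale)
  Ls <- nchar(site)
  list(score = a$score, pair_string = a$pairs,
       aligned_mirna = a$aligned_mirna, aligned_target = a$aligned_target,
       mirna_span = c(a$mir_start, a$mir_end),
       target_span = c(Ls - a$tar_end, Ls - a$tar_start),
       seed_ok = seed_ok_from_alignment(a, cfg))
}

# Rule: the seed region of the alignment must contain no gaps and no
# non-canonical pairs.  Walk the aligned miRNA string, tracking the miRNA
# position each column consumes.
seed_ok_from_alignment <- function(a, cfg) {
  if (a$mir_start > cfg$seed_start || a$mir_end < cfg$seed_end) return(FALSE)
  cols <- strsplit(a$aligned_mirna, "")[[1]]
  syms <- strsplit(a$pairs, "")[[1]]
  pos <- a$mir_start - 1L
  ok_sym <- if (isTRUE(cfg$seed_allow_wobble)) c("|", ":") else "|"
  for (i in seq_along(cols)) {
    if (cols[i] != "-") pos <- pos + 1L
    inseed <- if (cols[i] != "-") {
      pos >= cfg$seed_start && pos <= cfg$seed_end
    } else {
      # a target bulge between seed positions also breaks the seed
      pos >= cfg$seed_start && pos < cfg$seed_end
    }
    if (inseed && !(syms[i] %in% ok_sym)) return(FALSE)
  }
  TRUE
}

#' Predict miRNA targets on a transcript set
#'
#' Scans every miRNA against every transcript: non-overlapping candidate
#' sites are extracted greedily (best site first, then masked), and a site
#' becomes a hit when its alignment score is at least `target_score_min`
#' (130), its RNA:RNA duplex free energy ([duplex_energy()]) is at most
#' `target_mfe_max` (-17 kcal/mol) and the seed rule holds.  Hits are
#' ranked per miRNA by descending score, then ascending duplex energy, and
#' truncated to the top N (20 when a miRNA produced more than 50
#' score-passing sites, else 10; fixed via `top_n_targets`).
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param transcripts named character vector of transcript sequences.
#' @param cfg a [pipeline_config()].
#' @return data frame of target hits: `mirna_id`, `target_id`,
#'   `target_start`/`target_end` (0-based half-open), `score`,
#'   `duplex_mfe`, `seed_ok` (always `TRUE` for emitted hits),
#'   `aligned_mirna`, `aligned_target`, `pair_string`, `rank`.
#' @export
find_targets <- function(mirnas, transcripts, cfg = pipeline_config()) {
  empty <- data.frame(mirna_id = character(), target_id = character(),
                      target_start = integer(), target_end = integer(),
                      score = numeric(), duplex_mfe = numeric(),
                      seed_ok = logical(), aligned_mirna = character(),
                      aligned_target = character(), pair_string = character(),
                      rank = integer())
  if (length(mirnas) == 0 || length(transcripts) == 0) return(empty)
  if (is.null(names(mirnas)) || is.null(names(transcripts)))
    stopf("mirnas and transcripts must be named")
  mirnas <- setNames(as_tag_seq(mirnas), names(mirnas))
  tx <- setNames(as_tag_seq(transcripts), names(transcripts))
  # reversed transcripts (3'->5'), precomputed once; masking edits them
  rtx <- vapply(strsplit(tx, ""), function(ch)
    paste(rev(ch), collapse = ""), "")
  sites <- list()
  for (mid in names(mirnas)) {
    mir <- mirnas[[mid]]
    for (tid in names(tx)) {
      rtar <- rtx[[tid]]
      Ls <- nchar(rtar)
      for (iter in 1:25) {
        a <- target_align_cpp(mir, rtar, cfg$match_score, cfg$wobble_score,
                              cfg$mismatch_score, cfg$gap_open,
                              cfg$gap_extend, cfg$seed_start, cfg$seed_end,
                              cfg$seed_scale)
        if (a$score < cfg$target_score_min) break
        sites[[length(sites) + 1]] <- data.frame(
          mirna_id = mid, target_id = tid,
          target_start = Ls - a$tar_end, target_end = Ls - a$tar_start,
          score = a$score, seed_ok = seed_ok_from_alignment(a, cfg),
          aligned_mirna = a$aligned_mirna,
          aligned_target = a$aligned_target, pair_string = a$pairs)
        # mask the site so remaining sites do not overlap it
        substr(rtar, a$tar_start + 1, a$tar_end) <-
          strrep("N", a$tar_end - a$tar_start)
      }
    }
  }
  if (!length(sites)) return(empty)
  sites <- do.call(rbind, sites)
  site_seq <- substr(tx[sites$target_id], sites$target_start + 1,
                     sites$target_end)
  sites$duplex_mfe <- duplex_energy(mirnas[sites$mirna_id], site_seq)
  raw_per_mirna <- table(sites$mirna_id)
  hits <- sites[sites$seed_ok & sites$duplex_mfe <= cfg$target_mfe_max, ,
                drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  out <- list()
  for (mid in unique(hits$mirna_id)) {
    h <- hits[hits$mirna_id == mid, , drop = FALSE]
    h <- h[order(-h$score, h$duplex_mfe, h$target_id, h$target_start), ,
           drop = FALSE]
    top_n <- if (!is.null(cfg$top_n_targets)) cfg$top_n_targets else
      if (raw_per_mirna[[mid]] > 50) 20L else 10L
    h <- utils::head(h, top_n)
    h$rank <- seq_len(nrow(h))
    out[[length(out) + 1]] <- h
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, names(empty)]
}

#' Render a target alignment block
#'
#' Human-readable three-line alignment (target 5'→3' on top, pairing
#' symbols, miRNA 3'→5' below), in the display style of classic
#' complementarity target predictors.
#'
#' @param hit one row of [find_targets()] output.
#' @return character vector of display lines.
#' @export
format_target_alignment <- function(hit) {
  rev1 <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
  c(sprintf("%s:%d-%d score=%.1f mfe=%.2f", hit$target_id,
            hit$target_start + 1, hit$target_end, hit$score, hit$duplex_mfe),
    paste0("5' ", rev1(hit$aligned_target), " 3'  (target)"),
    paste0("   ", rev1(hit$pair_string)),
    paste0("3' ", rev1(hit$aligned_mirna), " 5'  (miRNA)"))
}
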