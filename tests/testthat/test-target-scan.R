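# recompute a score from the stored alignment strings, independently of
# the DP: canonical +5, wobble +2, mismatch -3, affine gaps 9/4, seed
# columns (miRNA positions 2-8) scaled by 4
rescore <- function(hit, cfg = pipeline_config()) {
  mir <- strsplit(hit$aligned_mirna, "")[[1]]
  sym <- strsplit(hit$pair_string, "")[[1]]
  # recover the first aligned miRNA position from the unaligned prefix
  gapless <- paste(mir[mir != "-"], collapse = "")
  pos <- 0L
  total <- 0
  in_gap <- FALSE
  mir_start <- hit$mirna_start %||% 1L
  pos <- mir_start - 1L
  for (i in seq_along(sym)) {
    consumed <- mir[i] != "-"
    if (consumed) pos <- pos + 1L
    w <- if (pos >= cfg$seed_start && pos <= cfg$seed_end) cfg$seed_scale else 1
    if (sym[i] == "|") { total <- total + cfg$match_score * w; in_gap <- FALSE }
    else if (sym[i] == ":") { total <- total + cfg$wobble_score * w; in_gap <- FALSE }
    else if (sym[i] == ".") { total <- total + cfg$mismatch_score * w; in_gap <- FALSE }
    else {
      pen <- if (in_gap) cfg$gap_extend else cfg$gap_open
      total <- total - pen * (if (consumed) w else 1)
      in_gap <- TRUE
    }
  }
  total
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the +5/+2 scoring with seed scaling reproduces the worked scores", {
  m <- "UGAAGCUGCCAGCAUGAUCUA"
  perfect <- score_duplex_alignment(m, revcomp(m))
  expect_equal(perfect$score, 210)           # 7 x 5 x 4 + 14 x 5
  expect_true(perfect$seed_ok)
  expect_equal(perfect$pair_string, strrep("|", 21))

  # one canonical pair outside the seed replaced by a G:U wobble
  site <- strsplit(revcomp(m), "")[[1]]
  pos <- 15                                   # miRNA position 15 (non-seed)
  stopifnot(substr(m, pos, pos) %in% c("U", "G"))
  site[21 - pos + 1] <- if (substr(m, pos, pos) == "U") "G" else "U"
  wob <- score_duplex_alignment(m, paste(site, collapse = ""))
  expect_equal(wob$score, 207)                # 140 + 13 x 5 + 2
  expect_equal(sum(strsplit(wob$pair_string, "")[[1]] == ":"), 1)

  # no complementarity at all: empty alignment, score 0
  none <- score_duplex_alignment(strrep("A", 21), strrep("A", 30))
  expect_equal(none$score, 0)
  expect_equal(none$pair_string, "")
})

test_that("wobble or gap inside the seed clears seed_ok", {
  m <- "UGAAGCUGCCAGCAUGAUCUA"
  site <- strsplit(revcomp(m), "")[[1]]
  pos <- 5                                    # inside the 2-8 seed (a G)
  site[21 - pos + 1] <- if (substr(m, pos, pos) == "U") "G" else "U"
  s <- score_duplex_alignment(m, paste(site, collapse = ""))
  expect_false(s$seed_ok)
  # the permissive variant accepts seed wobbles
  s2 <- score_duplex_alignment(m, paste(site, collapse = ""),
                               pipeline_config(seed_allow_wobble = TRUE))
  expect_true(s2$seed_ok)
})

test_that("duplex energies behave like duplex energies", {
  m <- "UGAAGCUGCCAGCAUGAUCUA"
  e <- duplex_energy(m, revcomp(m))
  expect_lt(e, -17)
  expect_equal(e, duplex_energy(revcomp(m), m))  # symmetric
  expect_gt(duplex_energy("AUAUAU", "AUAUAU"), -17)  # weak 6-nt AU duplex
  expect_error(duplex_energy("ACGU", "ACGX"), "alphabet")
})

test_that("find_targets emits ranked, threshold-clean, non-overlapping hits", {
  set.seed(21)
  mirnas <- c(mirA = "UGAAGCUGCCAGCAUGAUCUA",
              mirB = random_tag(21))
  tx <- setNames(random_tag(400), "tx1")
  # plant two perfect sites for mirA
  site <- as_dna_seq(revcomp(mirnas[["mirA"]]))
  substr(tx, 50, 50 + nchar(site) - 1) <- site
  substr(tx, 200, 200 + nchar(site) - 1) <- site
  hits <- find_targets(mirnas, c(tx1 = tx))
  a <- hits[hits$mirna_id == "mirA", ]
  expect_gte(nrow(a), 2)
  expect_equal(a$rank, seq_len(nrow(a)))
  expect_true(all(a$seed_ok))
  expect_true(all(a$score >= 130 & a$duplex_mfe <= -17))
  # the planted spans are recovered and do not overlap
  expect_true(any(a$target_start == 49) && any(a$target_start == 199))
  o <- order(a$target_start)
  expect_true(all(a$target_start[o][-1] >= a$target_end[o][-nrow(a)]))
  # scores re-derive exactly from the stored pair strings
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    h$mirna_start <- 1L
    expect_equal(rescore(h), h$score)
  }
})

test_that("sub-threshold or seed-broken sites are rejected", {
  m <- "UGAAGCUGCCAGCAUGAUCUA"
  # seed wobble site: strong score but seed_ok FALSE -> no hit
  site <- strsplit(revcomp(m), "")[[1]]
  site[21 - 5 + 1] <- "U"                     # G:U against miRNA position 5
  tx <- paste0(strrep("A", 50), as_dna_seq(paste(site, collapse = "")),
               strrep("A", 50))
  expect_equal(nrow(find_targets(c(x = m), c(t = tx))), 0)

  # a truncated site scoring below 130 is not emitted
  half <- substr(revcomp(m), 1, 13)   # complements positions 9-21: no seed
  tx2 <- paste0(strrep("C", 40), as_dna_seq(half), strrep("A", 40))
  s <- score_duplex_alignment(m, as_tag_seq(tx2))
  expect_lt(s$score, 130)
  expect_equal(nrow(find_targets(c(x = m), c(t = tx2))), 0)
})

test_that("planted sites outscore shuffled transcripts", {
  set.seed(8)
  m <- setNames(random_tag(21), "m")
  tx <- random_tag(300)
  site <- as_dna_seq(revcomp(m[[1]]))
  planted <- tx
  substr(planted, 100, 100 + nchar(site) - 1) <- site
  shuffled <- shuffle_dinucleotide(planted, seed = 4)
  n_planted <- nrow(find_targets(m, c(t = planted)))
  n_shuffled <- nrow(find_targets(m, c(t = shuffled)))
  expect_lte(n_shuffled, n_planted)
  expect_gte(n_planted, 1)
})
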