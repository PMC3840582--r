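test_that("map_tags agrees with a naive all-offsets scan", {
  naive_scan <- function(tag, refs, max_mm) {
    hits <- list()
    rc <- revcomp(tag)
    for (r in names(refs)) {
      ref <- as_tag_seq(refs[[r]])
      L <- nchar(tag)
      for (q in c("+", "-")) {
        query <- strsplit(if (q == "+") tag else rc, "")[[1]]
        for (s in 0:(nchar(ref) - L)) {
          mm <- sum(strsplit(substr(ref, s + 1, s + L), "")[[1]] != query)
          if (mm <= max_mm)
            hits[[length(hits) + 1]] <- sprintf("%s:%d:%s:%d", r, s, q, mm)
        }
      }
    }
    sort(as.character(unlist(hits)))
  }
  set.seed(42)
  refs <- setNames(as.list(vapply(1:4, function(i) random_tag(150), "")),
                   paste0("c", 1:4))
  refs <- lapply(refs, identity)
  for (i in 1:100) {
    tag <- if (i %% 2) random_tag(sample(18:24, 1)) else {
      # plant the tag (or a 1-mismatch copy) inside a reference
      r <- sample(4, 1)
      s <- sample(120, 1)
      t0 <- substr(refs[[r]], s, s + 20)
      if (i %% 4 == 0) {
        p <- sample(21, 1)
        substr(t0, p, p) <- setdiff(c("A", "C", "G", "U"),
                                    substr(t0, p, p))[1]
      }
      t0
    }
    for (mm in 0:1) {
      got <- map_tags(tag, unlist(refs),
                      pipeline_config(mapping_max_mismatch = mm),
                      mode = if (mm == 0) "contig" else "genome")
      got_keys <- sort(sprintf("%s:%d:%s:%d", got$ref_id, got$start,
                               got$strand, got$edits))
      expect_equal(got_keys, naive_scan(tag, unlist(refs), mm))
    }
  }
})

test_that("contig mode forbids the mismatch genome mode allows", {
  set.seed(9)
  ref <- c(chr = random_tag(300))
  tag <- substr(ref[[1]], 100, 120)
  substr(tag, 11, 11) <- setdiff(c("A", "C", "G", "U"),
                                 substr(tag, 11, 11))[1]
  expect_equal(nrow(map_tags(tag, ref, mode = "contig")), 0)
  gen <- map_tags(tag, ref, mode = "genome")
  expect_equal(gen$edits, 1L)
  expect_equal(gen$start, 99L)
})

test_that("folding is deterministic and a GC stem folds below -18 kcal/mol", {
  hairpin <- paste0(strrep("GC", 15), "GAAA", strrep("GC", 15))
  f1 <- fold_rna(hairpin)
  f2 <- fold_rna(hairpin)
  expect_identical(f1, f2)
  expect_lt(f1$mfe, -18)
  expect_equal(nchar(f1$structure), nchar(hairpin))
  expect_equal(fold_rna(strrep("A", 60))$mfe, 0)
  expect_error(fold_rna("ACGTX" |> strrep(10)), "alphabet")
  expect_error(fold_rna("ACGU"), "length")
})

test_that("hairpin acceptance enforces every structural criterion", {
  cand <- data.frame(mfe = c(-30, -30, -17.5, -30, -30),
                     duplex_pairs = c(18L, 15L, 18L, 18L, 18L),
                     max_bulge = c(2L, 2L, 2L, 5L, 2L),
                     asymmetry = c(1L, 1L, 1L, 1L, 6L))
  res <- evaluate_hairpin(cand)
  expect_equal(res$accept, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(res$reasons,
               c("", "duplex_pairs", "mfe", "max_bulge", "asymmetry"))
})

test_that("excision windows are clipped at reference boundaries", {
  refs <- small_refs()
  pn <- refs$truth$planted_novel[1, ]
  # a hit 10 nt from the contig start: the long upstream flank is clipped
  hit <- data.frame(tag_seq = substr(refs$genome[[pn$contig]], 11, 31),
                    ref_id = pn$contig, start = 10L, end = 31L,
                    strand = "+", edits = 0L)
  expect_no_error(cand <- excise_candidates(hit, refs$genome))
  if (nrow(cand)) expect_true(all(cand$locus_start >= 0))
})

test_that("planted precursors are recovered at the planted arm", {
  refs <- small_refs()
  pn <- refs$truth$planted_novel
  hits <- map_tags(pn$mature, refs$genome, mode = "contig")
  hits <- hits[hits$strand == "+", ]
  cand <- evaluate_hairpin(excise_candidates(hits, refs$genome))
  acc <- cand[cand$accept, ]
  for (i in seq_len(nrow(pn))) {
    mine <- acc[acc$ref_id == pn$contig[i] &
                  acc$mature_seq == pn$mature[i], ]
    expect_gt(nrow(mine), 0)
    # mature span inside the planted precursor, on the 5' arm
    expect_true(any(mine$locus_start + mine$mature_start - 1 >=
                      pn$pre_start[i] &
                      mine$locus_start + mine$mature_end <= pn$pre_end[i]))
    expect_true(all(mine$arm == "5p"))
  }
})

test_that("dominance curation keeps dominant, homogeneous matures and dedups loci", {
  cand <- data.frame(ref_id = "chr",
                     locus_start = c(0L, 10L, 500L),
                     locus_end = c(300L, 310L, 800L), strand = "+",
                     mature_seq = c("AAA", "AAA", "CCC"),
                     mature_start = c(51L, 41L, 51L),
                     mature_end = c(71L, 61L, 71L),
                     accept = TRUE)
  hits <- data.frame(tag_seq = c("AAA", "ZZZ", "CCC", "YYY"),
                     ref_id = "chr", start = c(50L, 120L, 550L, 600L),
                     end = c(71L, 141L, 571L, 621L), strand = "+",
                     edits = 0L)
  counts <- c(AAA = 80, ZZZ = 20, CCC = 30, YYY = 70)
  res <- dominance_filter(cand, hits, counts)
  # AAA: 80 of 100 reads in its locus -> dominance 0.8, kept; the two
  # overlapping windows of the same mature collapse to one survivor
  expect_equal(sum(res$mature_seq == "AAA"), 1)
  expect_equal(res$dominance[res$mature_seq == "AAA"], 0.8)
  # CCC: 30 of 100 -> below the 50% dominance cutoff
  expect_false("CCC" %in% res$mature_seq)
})
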