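test_that("align_tag matches the exhaustive dynamic-programming oracle", {
  set.seed(101)
  for (i in 1:200) {
    tag <- random_tag(sample(18:30, 1))
    ref <- if (runif(1) < 0.5) {
      random_tag(sample(18:30, 1))
    } else {
      # embed a mutated copy so small distances are well represented
      mut <- strsplit(tag, "")[[1]]
      for (p in sample(seq_along(mut), sample(0:3, 1)))
        mut[p] <- sample(c("A", "C", "G", "U"), 1)
      paste0(random_tag(sample(0:6, 1)), paste(mut, collapse = ""),
             random_tag(sample(0:6, 1)))
    }
    want <- dp_edit_oracle(tag, ref)
    got <- align_tag(tag, ref, max_edits = 30)
    expect_equal(got$mismatches + got$gaps, want,
                 info = paste(tag, ref, sep = " / "))
  }
})

test_that("seed protection and coverage bounds are absolute", {
  ref <- "UGAAGCUGCCAGCAUGAUCUA"
  # mismatch at position 5 only: inside the 2-8 seed, rejected
  tag5 <- ref
  substr(tag5, 5, 5) <- if (substr(ref, 5, 5) == "A") "C" else "A"
  expect_null(align_tag(tag5, ref, max_edits = 1, protect_seed = TRUE))
  expect_false(is.null(align_tag(tag5, ref, max_edits = 1)))

  # two mismatches at 10 and 15: outside the seed, allowed at budget 3
  tag2 <- ref
  for (p in c(10, 15))
    substr(tag2, p, p) <- if (substr(ref, p, p) == "G") "U" else "G"
  got <- align_tag(tag2, ref, max_edits = 3, protect_seed = TRUE)
  expect_equal(got$mismatches, 2)
  expect_equal(got$seed_violations, 0)

  # identical but 3 nt shorter than the reference: coverage rule fires
  ref24 <- paste0(ref, "GCA")
  expect_null(align_tag(ref, ref24, max_edits = 0, protect_seed = TRUE))
  expect_error(align_tag("", ref, 1), "empty")

  # adversarial: an equal-cost alignment could hide the seed edit in a
  # gap placement; any qualifying alignment must still be seed-clean
  set.seed(7)
  for (i in 1:50) {
    base <- random_tag(21)
    tag <- base
    p <- sample(2:8, 1)
    substr(tag, p, p) <- setdiff(c("A", "C", "G", "U"),
                                 substr(base, p, p))[1]
    res <- align_tag(tag, base, max_edits = 1, protect_seed = TRUE)
    if (!is.null(res)) expect_equal(res$seed_violations, 0)
  }
})

test_that("the cascade annotates in fixed category order and partitions tags", {
  trna <- "GGGCGAAUUCGGAUCCGGCUAGCUAGGAUCG"
  tag <- substr(trna, 3, 24)
  refsets <- data.frame(
    id = c("t1", "rep1"),
    seq = c(trna, paste0("AAAA", tag, "GGGG")),  # tag matches both
    category = c("tRNA", "repeat"), native = c(1L, 1L))
  tt <- normalize_counts(collapse_tags(list(
    L = c(tag, tag, "ACGUACGUACGUACGUACGUA"))))
  res <- annotate_cascade(tt, refsets)
  ann <- res$annotations
  expect_equal(ann$category[ann$tag_seq == as_tag_seq(tag)], "tRNA")
  expect_equal(ann$category[ann$tag_seq == "ACGUACGUACGUACGUACGUA"],
               "unannotated")
  expect_equal(ann$reference_id[ann$category == "unannotated"], "")
  # partition: unique category tallies sum to the tag count
  expect_equal(sum(table(ann$category)), length(tt$seq))
  expect_error(annotate_cascade(tt, transform(refsets, category = "mRNA")),
               "unknown refset")
})

test_that("native and relative passes use their own edit budgets", {
  ref <- random_tag(60)
  tag <- substr(ref, 10, 31)
  tag2 <- tag
  substr(tag2, 5, 5) <- setdiff(c("A", "C", "G", "U"), substr(tag, 5, 5))[1]
  substr(tag2, 12, 12) <- setdiff(c("A", "C", "G", "U"),
                                  substr(tag, 12, 12))[1]
  # 2 edits: too many for the native budget (1), fine for relative (2)
  refsets_nat <- data.frame(id = "r", seq = ref, category = "rRNA",
                            native = 1L)
  refsets_rel <- data.frame(id = "r", seq = ref, category = "rRNA",
                            native = 0L)
  tt <- normalize_counts(collapse_tags(list(L = tag2)))
  expect_equal(annotate_cascade(tt, refsets_nat)$annotations$category,
               "unannotated")
  expect_equal(annotate_cascade(tt, refsets_rel)$annotations$category,
               "rRNA")
})

test_that("conserved classification respects pass order, budgets and stars", {
  set.seed(5)
  nat <- data.frame(id = c("bol-miR1", "bol-miR9*"),
                    seq = c(random_tag(21), random_tag(21)),
                    family = c("MIR001", "MIR009"), star = c(0L, 1L))
  oth <- data.frame(id = "ath-miR2", seq = random_tag(21),
                    family = "MIR002", star = 0L)
  # three non-seed edits: other-plant pass only
  tag3 <- oth$seq
  for (p in c(10, 14, 18))
    substr(tag3, p, p) <- setdiff(c("A", "C", "G", "U"),
                                  substr(oth$seq, p, p))[1]
  res <- classify_conserved(c(nat$seq[1], nat$seq[2], tag3), nat, oth)
  expect_equal(res$pass[res$tag_seq == nat$seq[1]], "native")
  expect_equal(res$mismatches[res$tag_seq == nat$seq[1]], 0)
  expect_true(res$is_star[res$tag_seq == nat$seq[2]])
  expect_equal(res$pass[res$tag_seq == tag3], "other")
  expect_equal(res$family[res$tag_seq == tag3], "MIR002")
  expect_true(all(res$seed_violations == 0))

  # a 21-nt tag against a 24-nt reference: no match despite 0 edits
  ref24 <- data.frame(id = "x", seq = random_tag(24), family = "MIRX",
                      star = 0L)
  expect_equal(nrow(classify_conserved(substr(ref24$seq, 1, 21), ref24,
                                       NULL)), 0)
})

test_that("the family abundance filter spares Brassicaceae-described families", {
  tags <- vapply(1:3, function(i) random_tag(21), "")
  asg <- data.frame(tag_seq = tags, family = c("MIRA", "MIRB", "MIRC"),
                    source_mirna = c("a", "b", "c"), is_star = FALSE,
                    pass = "native", mismatches = 0L, gaps = 0L,
                    seed_violations = 0L)
  tt <- collapse_tags(list(L1 = rep(tags, c(12, 20, 3))), c(L1 = 1e6))
  tt <- normalize_counts(tt)
  res <- filter_families(asg, tt, brassicaceae_families = "MIRC")
  expect_setequal(res$dropped$family, "MIRA")      # mean 12 < 15, not described
  expect_true("MIRB" %in% res$kept$family)          # mean 20 >= 15
  expect_true("MIRC" %in% res$kept$family)          # described, mean 3 kept
  # star members do not count toward the abundance sum
  asg2 <- asg[2, ]
  asg2$is_star <- TRUE
  res2 <- filter_families(rbind(asg[2, ], asg2), tt, character(0))
  expect_equal(res2$kept$mean_norm_total, 20)
})
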