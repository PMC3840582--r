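test_that("read_fastq decodes Phred+33 records and rejects malformed input", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
  reads <- read_fastq(fq)
  expect_equal(reads$seq, "ACGT")
  expect_equal(reads$qual[[1]], rep(40L, 4))

  writeLines(c("@r1", "ACGT", "+", "III"), fq)
  expect_error(read_fastq(fq), "record 1")

  file.create(fq2 <- tempfile(fileext = ".fastq"))
  expect_equal(nrow(read_fastq(fq2)), 0)
})

test_that("collapse_tags counts distinct sequences per library with T/U identified", {
  tt <- collapse_tags(list(lib1 = c("ACGU", "ACGU", "GGGC")))
  expect_setequal(tt$seq, c("ACGU", "GGGC"))
  expect_equal(tt$counts[match("ACGU", tt$seq), "lib1"], c(lib1 = 2L))
  expect_equal(tt$counts[match("GGGC", tt$seq), "lib1"], c(lib1 = 1L))

  tt2 <- collapse_tags(list(L = c("ACGT", "ACGU")))
  expect_equal(length(tt2$seq), 1L)
  expect_equal(unname(rowSums(tt2$counts)), 2)

  tt3 <- collapse_tags(list(A = "ACGU", B = c("ACGU", "ACGU")))
  expect_equal(unname(tt3$counts[1, ]), c(1L, 2L))

  # conservation: per-library sums equal input read counts
  set.seed(1)
  reads <- list(x = random_tag(20), y = random_tag(21))
  libs <- lapply(1:3, function(i) sample(unlist(reads), 30, replace = TRUE))
  names(libs) <- paste0("L", 1:3)
  tt4 <- collapse_tags(libs)
  expect_equal(unname(colSums(tt4$counts)), rep(30L, 3))
})

test_that("normalize_counts applies library scaling and is scale-equivariant", {
  tt <- collapse_tags(list(L1 = rep("ACGU", 50)), c(L1 = 500000))
  expect_equal(unname(normalize_counts(tt)$norm[1, "L1"]), 100)

  tt2 <- collapse_tags(list(L1 = rep("ACGU", 10), L2 = "GGCC"),
                       c(L1 = 1e6, L2 = 1e6))
  tt2$counts["GGCC" == tt2$seq, "L2"] <- 0L   # force a zero-count tag
  n2 <- normalize_counts(tt2)
  i <- match("ACGU", n2$seq)
  expect_equal(unname(n2$norm[i, ]), c(10, 0))
  expect_equal(n2$mean_norm[i], 5)
  # mean_norm invariant
  expect_equal(n2$mean_norm, rowMeans(n2$norm), tolerance = 1e-9)

  # scale equivariance: c x counts with c x totals leaves norm unchanged
  tt3 <- collapse_tags(list(L = rep(c("ACGU", "GGCC"), c(3, 7))), c(L = 100))
  tt3b <- tt3
  tt3b$counts <- tt3$counts * 5L
  tt3b$library_totals <- tt3$library_totals * 5
  expect_equal(normalize_counts(tt3)$norm, normalize_counts(tt3b)$norm)

  tt$library_totals[1] <- 0
  expect_error(normalize_counts(tt), "zero library total")
})

test_that("normalized totals agree across libraries when all tags are retained", {
  set.seed(2)
  libs <- lapply(1:3, function(i)
    sample(vapply(1:5, function(j) random_tag(21), ""),
           1000 * i, replace = TRUE))
  names(libs) <- paste0("L", 1:3)
  n <- normalize_counts(collapse_tags(libs))
  sums <- colSums(n$norm)
  expect_equal(max(sums) / min(sums), 1, tolerance = 1e-6)
})

test_that("length_distribution returns fractions over tags or reads", {
  tt <- collapse_tags(list(L = c(random_tag(21), random_tag(21),
                                 random_tag(24))))
  d <- length_distribution(tt)
  expect_equal(unname(d[c("21", "24")]), c(2 / 3, 1 / 3))
  expect_equal(sum(d), 1, tolerance = 1e-9)

  one <- collapse_tags(list(L = "ACGUACGUACGUACGUACGUA"))
  expect_equal(unname(length_distribution(one)), 1)

  tt2 <- collapse_tags(list(L = rep(c(random_tag(21), random_tag(24)),
                                    c(90, 10))))
  dw <- length_distribution(tt2, weighted = TRUE)
  expect_equal(unname(dw[c("21", "24")]), c(0.9, 0.1))

  expect_error(length_distribution(collapse_tags(list())), "empty")
})

test_that("tag tables round-trip through their TSV serialization", {
  tt <- normalize_counts(collapse_tags(
    list(L1 = c("ACGU", "ACGU", "GGCC"), L2 = "ACGU")))
  path <- tempfile(fileext = ".tsv")
  write_tag_table(tt, path)
  df <- read.delim(path)
  expect_equal(nrow(df), 2)
  expect_equal(df$count_L1[df$seq == "ACGU"], 2L)
  expect_equal(df$mean_norm, tt$mean_norm[match(df$seq, tt$seq)])
})
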