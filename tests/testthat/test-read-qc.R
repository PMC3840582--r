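test_that("the worked six-read library keeps exactly the rule-permitted survivors", {
  fq <- worked_qc_fastq(tempfile(fileext = ".fastq"))
  res <- qc_filter(read_fastq(fq), adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                   adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC")
  rep <- res$report
  expect_equal(rep$input_reads, 6L)
  expect_equal(rep$clean_reads, 2L)
  expect_equal(rep$removed_n, 1L)
  expect_equal(rep$removed_q10, 1L)
  expect_equal(rep$removed_short, 1L)
  expect_equal(rep$removed_no_3prime_adapter, 1L)
  expect_equal(rep$removed_q13, 0L)
  expect_setequal(res$clean$insert,
                  c("GTACGTACGTACGTACGTACG", "ATGCATGCATGCATGCATGCAT"))
  # first-match accounting: counters plus survivors partition the input
  expect_equal(sum(unlist(rep[grep("removed", names(rep))])) +
                 rep$clean_reads, rep$input_reads)
})

test_that("single-rule reads are charged to the right counter", {
  ad3 <- "TCGTATGCCGTCTTCTGCTTG"
  ad5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
  mk <- function(seq, qual = strrep("I", nchar(seq))) {
    data.frame(read_id = "r", seq = seq, qual_string = qual)
  }
  # poly-A insert
  res <- qc_filter(mk(paste0(strrep("A", 22), ad3)), ad3, ad5)
  expect_equal(res$report$removed_polyA, 1L)
  # 5' adapter contamination (first 8 nt of the insert)
  res <- qc_filter(mk(paste0(substr(ad5, 1, 8), "ACGTACGTACGTA", ad3)),
                   ad3, ad5)
  expect_equal(res$report$removed_5prime_adapter, 1L)
  # exactly 4 bases below Q10 is still allowed, 5 is not
  r <- mk(paste0("GTACGTACGTACGTACGTACG", ad3))
  q <- utf8ToInt(r$qual_string)
  q[1:4] <- 33 + 9
  r4 <- r; r4$qual_string <- intToUtf8(q)
  expect_equal(qc_filter(r4, ad3, ad5)$report$clean_reads, 1L)
  q[5] <- 33 + 9
  r5 <- r; r5$qual_string <- intToUtf8(q)
  expect_equal(qc_filter(r5, ad3, ad5)$report$removed_q10, 1L)
  # 7 bases in Q10..Q12 trip the Q13 rule without touching the Q10 one
  q <- utf8ToInt(r$qual_string)
  q[1:7] <- 33 + 12
  r7 <- r; r7$qual_string <- intToUtf8(q)
  expect_equal(qc_filter(r7, ad3, ad5)$report$removed_q13, 1L)
})

test_that("the filter is idempotent on its own clean output", {
  fq <- worked_qc_fastq(tempfile(fileext = ".fastq"))
  res <- qc_filter(read_fastq(fq), "TCGTATGCCGTCTTCTGCTTG",
                   adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC")
  again <- qc_filter(
    data.frame(read_id = res$clean$read_id, seq = res$clean$insert,
               qual_string = strrep("I", nchar(res$clean$insert))),
    "TCGTATGCCGTCTTCTGCTTG", "GTTCAGAGTTCTACAGTCCGACGATC",
    require_adapter3 = FALSE)
  expect_equal(again$report$clean_reads, nrow(res$clean))
  expect_equal(again$clean$insert, res$clean$insert)
})

test_that("raising the length threshold never increases the survivor count", {
  refs <- small_refs()
  sc <- small_sim()
  libs <- simulate_libraries(sc, refs, tempfile())
  reads <- read_fastq(libs$files[[1]])
  clean <- vapply(c(18L, 20L, 22L, 24L), function(L) {
    qc_filter(reads, sc$adapter3, sc$adapter5,
              pipeline_config(min_read_len = L))$report$clean_reads
  }, 0L)
  expect_true(all(diff(clean) <= 0))
})

test_that("planted QC negatives are all removed and no clean read is lost", {
  sc <- sim_config(rng_seed = 3, reads_per_library = 2000, n_libraries = 1,
                   error_rate = 0, n_conserved_families = 8,
                   n_novel_hairpins = 3, n_tas_loci = 1,
                   n_transcripts = 10, qc_negative_fraction = 0.1)
  refs <- simulate_references(sc)
  libs <- simulate_libraries(sc, refs, tempfile())
  reads <- read_fastq(libs$files[[1]])
  res <- qc_filter(reads, sc$adapter3, sc$adapter5)
  info <- libs$read_info
  neg_ids <- info$read_id[info$class == "qc_negative"]
  expect_gt(length(neg_ids), 100)
  # recall of removal is 100%
  expect_length(intersect(res$clean$read_id, neg_ids), 0)
  # and with error_rate = 0 every planted read survives
  expect_setequal(res$clean$read_id, setdiff(info$read_id, neg_ids))
  # surviving inserts are exactly the planted species sequences
  expect_true(all(as_tag_seq(res$clean$insert) %in%
                    refs$truth$species$seq))
})
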