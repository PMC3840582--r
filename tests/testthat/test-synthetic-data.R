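test_that("reference and library generation is deterministic under a fixed seed", {
  sc <- sim_config(rng_seed = 4, reads_per_library = 500,
                   n_conserved_families = 5, n_novel_hairpins = 2,
                   n_tas_loci = 1, n_transcripts = 8)
  r1 <- simulate_references(sc)
  r2 <- simulate_references(sc)
  expect_identical(r1$genome, r2$genome)
  expect_identical(r1$truth$species, r2$truth$species)
  d1 <- tempfile(); d2 <- tempfile()
  l1 <- simulate_libraries(sc, r1, d1)
  l2 <- simulate_libraries(sc, r2, d2)
  for (lib in names(l1$files)) {
    expect_identical(readLines(l1$files[[lib]]), readLines(l2$files[[lib]]))
  }
})

test_that("planted structure follows the requested design", {
  refs <- small_refs()
  sc <- small_sim()
  truth <- refs$truth
  expect_equal(nrow(truth$planted_novel), sc$n_novel_hairpins)
  expect_equal(nrow(truth$planted_tas), sc$n_tas_loci)
  expect_equal(nrow(truth$planted_mirnas), sc$n_conserved_families)
  # every planted mature appears in the expected-category map
  expect_true(all(truth$planted_mirnas$mature %in%
                    truth$expected_category$seq))
  # planted tags are pairwise distinct
  expect_false(any(duplicated(truth$species$seq)))
  # TAS loci: consecutive 21-nt phased tags embedded verbatim in the contig
  for (i in seq_len(nrow(truth$planted_tas))) {
    row <- truth$planted_tas[i, ]
    contig <- as_tag_seq(refs$genome[[row$contig]])
    tags <- row$tags[[1]]
    expect_equal(nchar(tags), rep(21L, length(tags)))
    expect_equal(substr(contig, row$start + 1, row$end),
                 paste(tags, collapse = ""))
  }
  # no TAS requested, none planted
  r0 <- simulate_references(sim_config(rng_seed = 2, n_tas_loci = 0,
                                       reads_per_library = 100,
                                       n_conserved_families = 4,
                                       n_novel_hairpins = 2,
                                       n_transcripts = 6))
  expect_equal(nrow(r0$truth$planted_tas), 0)
  expect_length(r0$known_tas, 0)
})

test_that("every planted precursor passes the hairpin acceptance rules", {
  refs <- small_refs()
  pn <- refs$truth$planted_novel
  hits <- map_tags(pn$mature, refs$genome, mode = "contig")
  cand <- evaluate_hairpin(excise_candidates(
    hits[hits$strand == "+", ], refs$genome))
  for (i in seq_len(nrow(pn))) {
    expect_true(any(cand$accept[cand$ref_id == pn$contig[i] &
                                  cand$mature_seq == pn$mature[i]]),
                info = pn$id[i])
  }
})

test_that("error-free libraries contain only planted inserts at the stated depth", {
  sc <- sim_config(rng_seed = 6, reads_per_library = 1000, n_libraries = 2,
                   error_rate = 0, qc_negative_fraction = 0,
                   n_conserved_families = 6, n_novel_hairpins = 2,
                   n_tas_loci = 1, n_transcripts = 8)
  refs <- simulate_references(sc)
  libs <- simulate_libraries(sc, refs, tempfile())
  for (lib in names(libs$files)) {
    reads <- read_fastq(libs$files[[lib]])
    expect_equal(nrow(reads), 1000)
    res <- qc_filter(reads, sc$adapter3, sc$adapter5)
    expect_true(all(as_tag_seq(res$clean$insert) %in% refs$truth$species$seq))
  }
})

test_that("sampled abundances track the drawn abundance parameters", {
  sc <- sim_config(rng_seed = 12, reads_per_library = 50000, n_libraries = 1,
                   qc_negative_fraction = 0)
  refs <- simulate_references(sc)
  libs <- simulate_libraries(sc, refs, tempfile())
  sp <- refs$truth$species
  fam <- sp$class == "conserved_mature" & !sp$label %in%
    refs$truth$planted_mirnas$family[refs$truth$planted_mirnas$decoy]
  rho <- cor(sp$weight[fam], libs$species_counts[fam, 1],
             method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("the reference bundle round-trips through its on-disk formats", {
  refs <- small_refs()
  dir <- tempfile()
  paths <- write_reference_bundle(refs, dir)
  expect_true(all(file.exists(paths)))
  nat <- read_reference_fasta(paths[["native_mirnas"]])
  expect_setequal(nat$seq, refs$native_mirnas$seq)
  expect_true(all(c("family", "star", "native") %in% names(nat)))
  manifest <- read.delim(paths[["manifest"]])
  expect_true(all(refs$truth$planted_mirnas$mature %in% manifest$seq))
  genome <- Biostrings::readDNAStringSet(paths[["genome"]])
  expect_identical(as.character(genome), refs$genome)
})

test_that("the dinucleotide shuffle preserves composition exactly", {
  set.seed(31)
  for (i in 1:5) {
    s <- random_tag(500)
    sh <- shuffle_dinucleotide(s, seed = i)
    dinuc <- function(x) {
      ch <- strsplit(x, "")[[1]]
      sort(table(paste0(ch[-length(ch)], ch[-1])))
    }
    expect_equal(nchar(sh), nchar(s))
    expect_equal(dinuc(sh), dinuc(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
  }
})
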