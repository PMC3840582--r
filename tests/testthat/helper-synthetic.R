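# Shared small synthetic study and an independent plain-R alignment oracle.

.cache <- new.env(parent = emptyenv())

small_sim <- function() {
  sim_config(rng_seed = 11, reads_per_library = 3000,
             n_conserved_families = 10, n_novel_hairpins = 5,
             n_tas_loci = 2, n_contaminant_refs = 12, n_transcripts = 16)
}

small_refs <- function() {
  if (is.null(.cache$refs)) .cache$refs <- simulate_references(small_sim())
  .cache$refs
}

small_run <- function() {
  if (is.null(.cache$run)) {
    .cache$run <- run_pipeline(list(sim = small_sim()),
                               out_dir = file.path(tempdir(), "small_run"))
  }
  .cache$run
}

# Full (unbanded, unseeded) dynamic-programming oracle for the semiglobal
# edit distance of tag vs reference: tag consumed end-to-end, free reference
# ends.  Kept deliberately independent of the package's seeded matcher.
dp_edit_oracle <- function(tag, ref) {
  t <- strsplit(tag, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  m <- length(t)
  n <- length(r)
  prev <- rep(0L, n + 1)
  for (i in seq_len(m)) {
    cur <- c(i, rep(0L, n))
    for (j in seq_len(n)) {
      cur[j + 1] <- min(prev[j] + (t[i] != r[j]), prev[j + 1] + 1L,
                        cur[j] + 1L)
    }
    prev <- cur
  }
  min(prev)
}

# Exact hypergeometric upper tail by explicit combinatorial summation —
# the shared enumeration oracle of the phasing and enrichment statistics.
hyper_tail_oracle <- function(N, K, n, k) {
  if (k <= 0) return(1)
  xs <- k:min(n, K)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

random_tag <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Worked six-read QC example: two rule-abiding reads and one violation of
# each of four cleaning rules.
worked_qc_fastq <- function(path, adapter3 = "TCGTATGCCGTCTTCTGCTTG") {
  good1 <- "GTACGTACGTACGTACGTACG"            # 21-nt insert
  good2 <- "ATGCATGCATGCATGCATGCAT"           # 22-nt insert
  short1 <- "ACGTACGTACGTACGTA"               # 17-nt insert
  nbase <- "GTACGTACGTNCGTACGTACG"
  lowq <- "CCGTACGTACGTACGTACGTC"
  noad <- paste0("TTGCAGTCAGGCATTGCAGTC", strrep("G", 16))
  reads <- c(paste0(good1, adapter3), paste0(nbase, adapter3),
             paste0(lowq, adapter3), paste0(short1, adapter3),
             noad, paste0(good2, adapter3))
  quals <- vapply(nchar(reads), function(n) strrep("I", n), "")  # Q40
  q <- utf8ToInt(quals[3])
  q[2:6] <- 33 + 9                            # five bases at Q9
  quals[3] <- intToUtf8(q)
  writeLines(as.vector(rbind(paste0("@r", 1:6), reads, "+", quals)), path)
  path
}
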