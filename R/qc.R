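#' Quality-filter and adapter-trim small RNA reads
#'
#' Applies the read-cleaning rules of the protocol in a fixed first-match
#' order, so each removed read increments exactly one counter:
#'
#' 1. `removed_n`: any `N` base;
#' 2. `removed_q10`: more than `max_bases_below_q10` (4) bases with
#'    Phred quality < 10;
#' 3. `removed_q13`: more than `max_bases_below_q13` (6) bases with
#'    quality < 13;
#' 4. `removed_short`: 3' adapter found but trimmed insert shorter than
#'    `min_read_len` (18 nt; adapter dimers, insert length 0, fall here);
#' 5. `removed_5prime_adapter`: insert whose first 8 nt match the 5'
#'    adapter with at most one mismatch;
#' 6. `removed_polyA`: insert at least 80 percent `A`, or ending in a run
#'    of 8 or more `A`;
#' 7. `removed_no_3prime_adapter`: no detectable 3' adapter.
#'
#' Quality rules are evaluated on the untrimmed read.  The 3' adapter is
#' detected as the earliest position where a prefix of `adapter3` (at least
#' `adapter_min_overlap` = 6 nt, at most one mismatch) matches through the
#' read end.  For reads without a detectable adapter the 5' adapter and
#' poly-A rules are evaluated on the whole read.
#'
#' @param reads data frame from [read_fastq()] (columns `read_id`, `seq`,
#'   `qual_string` or `qual`).
#' @param adapter3,adapter5 adapter sequences (non-empty).
#' @param cfg a [pipeline_config()].
#' @param require_adapter3 set `FALSE` when the input is already trimmed
#'   (e.g. re-filtering clean inserts); disables rules 4 and 7's adapter
#'   dependency and treats each read as its own insert.
#' @return list with `clean` (data frame `read_id`, `insert`, the trimmed
#'   insert in the read's original alphabet) and `report` (a `qc_report`
#'   with the counters above; counters plus `clean_reads` sum to
#'   `input_reads`).
#' @export
qc_filter <- function(reads, adapter3, adapter5, cfg = pipeline_config(),
                      require_adapter3 = TRUE) {
  if (!nzchar(adapter3) || !nzchar(adapter5))
    stopf("adapters must be non-empty")
  n <- nrow(reads)
  report <- c(input_reads = n, removed_n = 0L, removed_q10 = 0L,
              removed_q13 = 0L, removed_short = 0L,
              removed_5prime_adapter = 0L, removed_polyA = 0L,
              removed_no_3prime_adapter = 0L, clean_reads = 0L)
  if (n == 0) {
    return(list(clean = data.frame(read_id = character(), insert = character()),
                report = structure(as.list(report), class = "qc_report")))
  }
  seqs <- toupper(reads$seq)
  quals <- if (!is.null(reads$qual_string)) reads$qual_string else
    vapply(reads$qual, function(q) intToUtf8(q + 33L), "")

  qc <- qual_counts_cpp(quals, 10L, 13L)
  has_n <- grepl("N", seqs, fixed = TRUE)

  if (require_adapter3) {
    apos <- adapter_pos_cpp(as_dna_seq(seqs), as_dna_seq(adapter3),
                            cfg$adapter_min_overlap, cfg$adapter_max_mismatch)
  } else {
    apos <- nchar(seqs)
  }
  insert <- substr(seqs, 1, ifelse(apos >= 0, apos, nchar(seqs)))

  a5 <- as_dna_seq(substr(adapter5, 1, 8))
  first8 <- as_dna_seq(substr(insert, 1, 8))
  is_a5 <- nchar(insert) >= 8 &
    adapter_pos_cpp(first8, a5, 8L, 1L) == 0L

  n_a <- nchar(insert) - nchar(gsub("A", "", insert, fixed = TRUE))
  frac_a <- ifelse(nchar(insert) > 0, n_a / nchar(insert), 1)
  is_polya <- frac_a >= 0.8 | grepl("A{8,}$", insert)

  # assigned from lowest to highest precedence so that later (higher
  # priority) rules overwrite, giving first-match accounting
  status <- rep("clean", n)
  status[is_polya] <- "removed_polyA"
  status[is_a5] <- "removed_5prime_adapter"
  if (require_adapter3) {
    status[apos < 0 & !is_a5 & !is_polya] <- "removed_no_3prime_adapter"
    status[apos >= 0 & apos < cfg$min_read_len] <- "removed_short"
  } else {
    status[nchar(insert) < cfg$min_read_len] <- "removed_short"
  }
  status[qc[, 2] > cfg$max_bases_below_q13] <- "removed_q13"
  status[qc[, 1] > cfg$max_bases_below_q10] <- "removed_q10"
  status[has_n] <- "removed_n"

  for (s in setdiff(unique(status), "clean")) report[s] <- sum(status == s)
  keep <- status == "clean"
  report["clean_reads"] <- sum(keep)
  list(clean = data.frame(read_id = reads$read_id[keep],
                          insert = insert[keep], row.names = NULL),
       report = structure(as.list(report), class = "qc_report"))
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param report a `qc_report` from [qc_filter()].
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  write.table(data.frame(metric = names(report),
                         reads = unlist(report, use.names = FALSE)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
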