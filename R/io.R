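#' Read a small RNA FASTQ file
#'
#' Reads single-end FASTQ (4-line records, Phred+33 qualities only; other
#' encodings are rejected, not auto-detected) into a data frame of reads.
#' Qualities are decoded to integer Phred scores.
#'
#' @param path path to a FASTQ file.
#' @return data frame with columns `read_id`, `seq` (uppercase, as read),
#'   `qual` (list column of integer Phred scores) and `qual_string`
#'   (raw Phred+33 string, kept for fast downstream filtering).
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' read_fastq(fq)$qual[[1]]   # 40 40 40 40
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stopf("FASTQ file not found: %s", path)
  # structural validation first: the heavy parser pads or garbles records
  # whose sequence and quality lengths disagree instead of failing
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4 != 0)
    stopf("FASTQ parse error in %s: truncated record at end of file", path)
  if (length(lines)) {
    sl <- nchar(lines[seq(2, length(lines), by = 4)])
    ql <- nchar(lines[seq(4, length(lines), by = 4)])
    bad <- which(sl != ql)
    if (length(bad))
      stopf("FASTQ parse error in %s: record %d has %d bases but %d quality values",
            path, bad[1], sl[bad[1]], ql[bad[1]])
  }
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stopf("FASTQ parse error in %s: %s", path,
                              conditionMessage(e)))
  if (length(x) == 0) {
    return(data.frame(read_id = character(), seq = character(),
                      qual_string = character()))
  }
  quals <- as.character(S4Vectors::mcols(x)$qualities)
  seqs <- as.character(x)
  bad <- which(nchar(quals) != nchar(seqs))
  if (length(bad))
    stopf("FASTQ parse error in %s: record %d has %d bases but %d quality values",
          path, bad[1], nchar(seqs[bad[1]]), nchar(quals[bad[1]]))
  if (any(nchar(seqs) < 1))
    stopf("FASTQ parse error in %s: empty read at record %d", path,
          which(nchar(seqs) < 1)[1])
  qrange <- range(utf8ToInt(paste(quals, collapse = "")))
  if (qrange[1] < 33 || qrange[2] > 104)
    stopf("FASTQ parse error in %s: quality characters outside Phred+33", path)
  out <- data.frame(read_id = names(x), seq = toupper(seqs),
                    qual_string = quals, row.names = NULL)
  out$qual <- lapply(quals, function(q) utf8ToInt(q) - 33L)
  out[, c("read_id", "seq", "qual", "qual_string")]
}

#' Read a reference FASTA with structured header labels
#'
#' Reference sets carry key=value labels in their FASTA headers, e.g.
#' `>osa-miR169a|family=MIR169|star=0|native=0`.  Unlabelled headers yield
#' `NA` for the missing fields.
#'
#' @param path FASTA file.
#' @return data frame with columns `id`, `seq` (tag space, `U` alphabet)
#'   plus one column per label key found.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  headers <- names(x)
  parts <- strsplit(headers, "|", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1)
  keys <- unique(unlist(lapply(parts, function(p) sub("=.*", "", p[-1]))))
  out <- data.frame(id = ids, seq = as_tag_seq(as.character(x)),
                    row.names = NULL)
  for (k in keys) {
    if (!nzchar(k)) next
    out[[k]] <- vapply(parts, function(p) {
      hit <- grep(paste0("^", k, "="), p[-1], value = TRUE)
      if (length(hit)) sub(".*=", "", hit[1]) else NA_character_
    }, "")
  }
  out
}

#' Write labelled reference FASTA
#'
#' @param df data frame with `id`, `seq` and optional label columns.
#' @param path output path.
#' @param label_cols columns to embed as `key=value` header labels.
#' @export
write_reference_fasta <- function(df, path, label_cols = NULL) {
  hdr <- df$id
  for (k in label_cols) hdr <- paste0(hdr, "|", k, "=", df[[k]])
  x <- Biostrings::BStringSet(setNames(df$seq, hdr))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

write_fastq <- function(seqs, quals, ids, path) {
  x <- Biostrings::DNAStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

#' Write planted or predicted loci as GFF3
#'
#' Internal 0-based half-open coordinates are converted to the 1-based
#' inclusive convention of GFF3.
#'
#' @param df data frame with `ref_id`, `start`, `end` (0-based half-open),
#'   `strand`, `type`, `id` and optional extra attribute columns.
#' @param path output file.
#' @export
write_gff3 <- function(df, path) {
  if (nrow(df) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = df$ref_id,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
  gr$type <- df$type
  gr$ID <- df$id
  extra <- setdiff(names(df), c("ref_id", "start", "end", "strand", "type", "id"))
  for (k in extra) S4Vectors::mcols(gr)[[k]] <- df[[k]]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
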