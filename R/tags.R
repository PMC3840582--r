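#' Collapse reads into a unique-tag table
#'
#' Identical insert sequences are combined into unique tags with one raw
#' count per library.  `T` and `U` are identified (tags are stored in the
#' RNA alphabet), so DNA- and RNA-alphabet inputs collapse together.
#'
#' @param reads_per_library named list, one element per library, each either
#'   a character vector of insert sequences or a data frame with a
#'   `seq`/`insert` column (the output of [qc_filter()] works directly).
#' @param library_totals optional named vector of clean-read totals per
#'   library (the denominators of normalization); defaults to the number of
#'   input reads per library.
#' @return a `tag_table`: list with `seq` (unique tags), `counts` (tag x
#'   library integer matrix), `norm`/`mean_norm` (filled by
#'   [normalize_counts()]), `library_ids` and `library_totals`.
#' @examples
#' tt <- collapse_tags(list(L1 = c("ACGU", "ACGT", "GGGC")))
#' tt$counts   # ACGU counted twice: T/U identified
#' @export
collapse_tags <- function(reads_per_library, library_totals = NULL) {
  if (is.null(names(reads_per_library)) && length(reads_per_library))
    names(reads_per_library) <- paste0("L", seq_along(reads_per_library))
  libs <- names(reads_per_library)
  seq_of <- function(x) {
    if (is.data.frame(x)) {
      col <- intersect(c("insert", "seq"), names(x))[1]
      if (is.na(col)) stopf("library element has no 'seq' or 'insert' column")
      x[[col]]
    } else x
  }
  per_lib <- lapply(reads_per_library, function(x) as_tag_seq(seq_of(x)))
  all_tags <- sort(unique(unlist(per_lib, use.names = FALSE)))
  counts <- matrix(0L, nrow = length(all_tags), ncol = length(libs),
                   dimnames = list(NULL, libs))
  for (l in libs) {
    tb <- table(per_lib[[l]])
    counts[match(names(tb), all_tags), l] <- as.integer(tb)
  }
  if (is.null(library_totals)) {
    library_totals <- vapply(per_lib, length, 0L)
  } else {
    if (!all(libs %in% names(library_totals)))
      stopf("library_totals must name every library")
    library_totals <- library_totals[libs]
    short <- colSums(counts) > library_totals
    if (any(short))
      stopf("library %s has more reads than its stated total",
            libs[which(short)[1]])
  }
  structure(list(seq = all_tags, counts = counts, norm = NULL,
                 mean_norm = NULL, library_ids = libs,
                 library_totals = library_totals),
            class = "tag_table")
}

#' Normalize tag counts by library scaling
#'
#' Library-scaling normalization: each tag count is divided by its library's
#' clean-read total and multiplied by `scale` (default reads per million).
#' `mean_norm` is the arithmetic mean of the normalized counts over all
#' configured libraries, zeros included.
#'
#' @param table a `tag_table`.
#' @param scale scaling base (default 1e6, reads per million).
#' @return the table with `norm` and `mean_norm` filled.
#' @examples
#' tt <- collapse_tags(list(L1 = rep("ACGU", 50)), c(L1 = 500000))
#' normalize_counts(tt)$norm[1, "L1"]   # 100
#' @export
normalize_counts <- function(table, scale = 1e6) {
  stopifnot(inherits(table, "tag_table"))
  tot <- table$library_totals
  if (any(tot <= 0)) stopf("zero library total for %s",
                           paste(names(tot)[tot <= 0], collapse = ", "))
  table$norm <- sweep(table$counts, 2, tot, "/") * scale
  table$mean_norm <- rowMeans(table$norm)
  table
}

#' Tag length distribution
#'
#' @param table a `tag_table`.
#' @param weighted if `FALSE` (default) fractions are over unique tags; if
#'   `TRUE` they are weighted by total raw counts.
#' @return named numeric vector mapping length to fraction (sums to 1).
#' @export
length_distribution <- function(table, weighted = FALSE) {
  stopifnot(inherits(table, "tag_table"))
  if (length(table$seq) == 0) stopf("empty tag table")
  len <- nchar(table$seq)
  w <- if (weighted) rowSums(table$counts) else rep(1, length(len))
  tb <- tapply(w, len, sum)
  out <- as.numeric(tb) / sum(w)
  names(out) <- names(tb)
  out
}

#' Subset a tag table by tag sequence
#'
#' @param table a `tag_table`.
#' @param tags character vector of tag sequences to keep.
#' @return the subsetted `tag_table` (library totals unchanged).
#' @export
subset_tags <- function(table, tags) {
  stopifnot(inherits(table, "tag_table"))
  keep <- table$seq %in% as_tag_seq(tags)
  table$seq <- table$seq[keep]
  table$counts <- table$counts[keep, , drop = FALSE]
  if (!is.null(table$norm)) {
    table$norm <- table$norm[keep, , drop = FALSE]
    table$mean_norm <- table$mean_norm[keep]
  }
  table
}

#' Serialize a tag table as TSV
#'
#' Columns: `seq`, one raw-count and one normalized-count column per
#' library, then `mean_norm`.
#'
#' @param table a `tag_table` (normalized or not).
#' @param path output file.
#' @export
write_tag_table <- function(table, path) {
  stopifnot(inherits(table, "tag_table"))
  df <- data.frame(seq = table$seq)
  for (l in table$library_ids) df[[paste0("count_", l)]] <- table$counts[, l]
  if (!is.null(table$norm)) {
    for (l in table$library_ids) df[[paste0("norm_", l)]] <- table$norm[, l]
    df$mean_norm <- table$mean_norm
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.tag_table <- function(x, ...) {
  cat(sprintf("<tag_table> %d unique tags x %d libraries (%s)\n",
              length(x$seq), length(x$library_ids),
              paste(x$library_ids, collapse = ", ")))
  cat(sprintf("  library totals: %s\n",
              paste(format(x$library_totals), collapse = ", ")))
  cat(sprintf("  normalized: %s\n", !is.null(x$norm)))
  invisible(x)
}
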