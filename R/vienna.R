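# ViennaRNA command-line wrappers.  Both binaries ship with the ViennaRNA
# distribution; the thermodynamic parameter set is the tool's default
# (Turner 2004), recorded in run manifests for reproducibility.

vienna_binary <- function(name) {
  path <- Sys.which(name)
  if (!nzchar(path))
    stopf("%s not found on PATH; install ViennaRNA to fold structures", name)
  path
}

#' Minimum-free-energy secondary structure of RNA sequences
#'
#' Folds each sequence with `RNAfold` (no pseudoknots, deterministic for a
#' fixed sequence and parameter set) and returns the dot-bracket structure
#' and MFE in kcal/mol.
#'
#' @param seqs character vector of sequences (RNA or DNA alphabet; `T` is
#'   read as `U`); lengths must lie in `[min_len, max_len]`.
#' @param min_len,max_len allowed sequence length range (hairpin-precursor
#'   windows by default).
#' @return data frame with columns `seq`, `structure`, `mfe`.
#' @examples
#' \dontrun{
#' fold_rna(strrep("A", 60))$mfe   # 0: no pairing possible
#' }
#' @export
fold_rna <- function(seqs, min_len = 40, max_len = 400) {
  if (length(seqs) == 0)
    return(data.frame(seq = character(), structure = character(),
                      mfe = numeric()))
  seqs <- as_tag_seq(seqs)
  check_alphabet(seqs, what = "RNA")
  n <- nchar(seqs)
  if (any(n < min_len | n > max_len))
    stopf("fold_rna: sequence length outside [%d, %d]", min_len, max_len)
  ids <- paste0("s", seq_along(seqs))
  input <- paste0(">", ids, "\n", seqs, collapse = "\n")
  out <- system2(vienna_binary("RNAfold"), args = c("--noPS"),
                 input = input, stdout = TRUE, stderr = FALSE)
  recs <- grep("^>", out)
  if (length(recs) != length(seqs))
    stopf("RNAfold returned %d records for %d sequences", length(recs),
          length(seqs))
  struct_lines <- out[recs + 2]
  m <- regmatches(struct_lines,
                  regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", struct_lines))
  bad <- vapply(m, length, 0L) != 3
  if (any(bad)) stopf("unparseable RNAfold output: %s", struct_lines[bad][1])
  data.frame(seq = seqs,
             structure = vapply(m, `[`, "", 2),
             mfe = as.numeric(vapply(m, `[`, "", 3)))
}

#' Hybridization free energy of RNA:RNA duplexes
#'
#' Computes the nearest-neighbor duplex free energy of each miRNA:site pair
#' with `RNAduplex` (intermolecular pairing only).
#'
#' @param mirna,site character vectors (recycled to common length).
#' @return numeric vector of duplex free energies in kcal/mol.
#' @export
duplex_energy <- function(mirna, site) {
  n <- max(length(mirna), length(site))
  if (n == 0) return(numeric())
  mirna <- rep_len(as_tag_seq(mirna), n)
  site <- rep_len(as_tag_seq(site), n)
  if (any(!nzchar(mirna)) || any(!nzchar(site)))
    stopf("duplex_energy: empty sequence")
  check_alphabet(c(mirna, site), what = "RNA")
  input <- paste0(mirna, "\n", site, collapse = "\n")
  out <- system2(vienna_binary("RNAduplex"), input = input,
                 stdout = TRUE, stderr = FALSE)
  out <- out[nzchar(out) & !grepl("^>", out)]
  if (length(out) != n)
    stopf("RNAduplex returned %d records for %d pairs", length(out), n)
  m <- regmatches(out, regexec("\\(\\s*(-?[0-9.]+)\\)\\s*$", out))
  bad <- vapply(m, length, 0L) != 2
  if (any(bad)) stopf("unparseable RNAduplex output: %s", out[bad][1])
  as.numeric(vapply(m, `[`, "", 2))
}

# Pairing partners from a dot-bracket string: integer vector, 0 = unpaired,
# otherwise 1-based partner position.
db_pairs <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stopf("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) stopf("unbalanced dot-bracket string")
  pt
}

# Hairpin-loop intervals of a structure: list of c(start, end) (1-based,
# inclusive) runs of unpaired bases directly enclosed by a pair.
db_hairpin_loops <- function(pt) {
  loops <- list()
  n <- length(pt)
  i <- 1
  while (i <= n) {
    j <- pt[i]
    if (j > i + 1) {
      inner <- (i + 1):(j - 1)
      if (all(pt[inner] == 0)) loops[[length(loops) + 1]] <- c(i + 1, j - 1)
    }
    i <- i + 1
  }
  loops
}
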