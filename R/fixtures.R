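#' Northern-blot validation panel
#'
#' The packaged panel of 13 leaf miRNAs (4 novel, 8 conserved, 1 star)
#' whose expression was evaluated by northern blot hybridization, with
#' their sequences (novel entries in the DNA alphabet, conserved in RNA —
#' the two alphabets collapse in tag space), printed sequence lengths and
#' sequencing read counts.  Useful as a realistic mixed-alphabet input for
#' the tag utilities and as a fixed reference panel in examples.
#'
#' @return data frame with columns `lp`, `mirna_name`, `sequence`,
#'   `sequence_length`, `n_reads`.
#' @examples
#' panel <- northern_blot_panel()
#' all(nchar(panel$sequence) == panel$sequence_length)
#' @export
northern_blot_panel <- function() {
  path <- system.file("extdata", "northern_blot_panel.tsv",
                      package = "sRNAcascade", mustWork = TRUE)
  read.delim(path, colClasses = c("integer", "character", "character",
                                  "integer", "integer"))
}
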