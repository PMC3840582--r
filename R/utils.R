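#' Sequence alphabet helpers
#'
#' Tags are held internally in the RNA alphabet (uppercase, `T` mapped to
#' `U`) so that DNA-alphabet references and RNA-alphabet small RNA sequences
#' collapse onto one tag space.
#'
#' @param x character vector of nucleotide sequences.
#' @return `as_tag_seq()` returns the sequences uppercased with `T`
#'   replaced by `U`; `as_dna_seq()` the reverse mapping; `revcomp()` the
#'   reverse complement (in tag space).
#' @examples
#' as_tag_seq("acgt")   # "ACGU"
#' revcomp("ACGU")      # "ACGU"
#' @export
as_tag_seq <- function(x) chartr("Tt", "Uu", toupper(x))

#' @rdname as_tag_seq
#' @export
as_dna_seq <- function(x) chartr("Uu", "Tt", toupper(x))

#' @rdname as_tag_seq
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGU", "UGCA", as_tag_seq(x))
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

check_alphabet <- function(x, extra = "", what = "sequence") {
  bad <- grepl(sprintf("[^ACGUN%s]", extra), as_tag_seq(x))
  if (any(bad)) {
    stop(sprintf("invalid %s alphabet in: %s", what,
                 paste(utils::head(x[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_seq <- function(n, len, gc = 0.5, alphabet = c("A", "C", "G", "U")) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, if (length(len) > 1) len[i] else len,
                 replace = TRUE, prob = p), collapse = "")
  }, "")
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Random permutation of a sequence that preserves its exact dinucleotide
#' composition (Altschul-Erikson style: a uniform random Eulerian walk on the
#' dinucleotide transition multigraph).  Used to build null genomes on which
#' no hairpin candidate should survive.
#'
#' @param seq single nucleotide string.
#' @param seed optional integer seed for reproducibility.
#' @return shuffled sequence of identical length and dinucleotide counts.
#' @export
shuffle_dinucleotide <- function(seq, seed = NULL) {
  run <- function() {
    ch <- strsplit(as_tag_seq(seq), "")[[1]]
    n <- length(ch)
    if (n < 3) return(paste(ch, collapse = ""))
    # adjacency lists of the transition multigraph
    adj <- split(ch[-1], ch[-n])
    vs <- names(adj)
    terminal <- ch[n]
    # draw, for every non-terminal vertex, a random reserved last edge such
    # that the last-edge graph forms paths into the terminal vertex
    repeat {
      last <- vapply(vs, function(v) sample(adj[[v]], 1), "")
      ok <- TRUE
      for (v in vs) {
        if (v == terminal) next
        seen <- character(0)
        w <- v
        while (w != terminal && !w %in% seen) {
          seen <- c(seen, w)
          if (!w %in% vs) break
          w <- last[[w]]
        }
        if (w != terminal) { ok <- FALSE; break }
      }
      if (ok) break
    }
    # shuffle the remaining out-edges, reserved edge kept for last
    bag <- lapply(vs, function(v) {
      e <- adj[[v]]
      if (v != terminal) {
        drop <- match(last[[v]], e)
        e <- c(sample(e[-drop]), e[drop])
      } else sample(e)
    })
    names(bag) <- vs
    ptr <- setNames(rep(1L, length(bag)), vs)
    out <- character(n)
    out[1] <- ch[1]
    v <- ch[1]
    for (i in 2:n) {
      w <- bag[[v]][ptr[[v]]]
      ptr[[v]] <- ptr[[v]] + 1L
      out[i] <- w
      v <- w
    }
    paste(out, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
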