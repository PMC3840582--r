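#' Hypergeometric phasing tail probability
#'
#' Probability of observing at least `k` occupied in-phase positions when
#' `n` occupied positions are drawn without replacement from a window of
#' `N` positions of which `K` are in phase: `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`.  Computed with the numerically stable
#' log-space tail of [stats::phyper()].
#'
#' @param N window size in positions (21 x cycles).
#' @param K in-phase positions (cycles).
#' @param n occupied positions.
#' @param k occupied in-phase positions.
#' @return tail probability in `[0, 1]`; 1 when `k = 0`.
#' @examples
#' phasing_pvalue(42, 2, 1, 1)   # 2/42
#' phasing_pvalue(42, 2, 2, 2)   # 1/choose(42, 2)
#' @export
phasing_pvalue <- function(N, K, n, k) {
  if (K > N || n > N || k < 0 || k > min(n, K))
    stopf("phasing_pvalue: need 0 <= k <= min(n, K), K <= N, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Scan a tag pileup for 21-nt phased windows
#'
#' Tags of exactly `phase_len` (21) nt with mapping abundance of at least
#' `min_phase_abundance` (4) define occupied 5'-start positions.  A window
#' of `phase_cycles` (11) cycles, i.e. 231 nt, slides over each reference
#' in 21-nt steps; in every window each of the 21 phase registers is scored
#' with [phasing_pvalue()] (`N` = window positions, `K` = cycles, `n` =
#' occupied positions, `k` = occupied positions in the register) and the
#' best register is emitted.
#'
#' @param pileup data frame with `ref_id`, `pos` (0-based 5' start on the
#'   forward strand), `len` (tag length), `count` (mapping abundance) and
#'   optionally `tag_seq`.
#' @param ref_lengths named integer vector of reference lengths.
#' @param cfg a [pipeline_config()].
#' @return data frame of phase windows: `ref_id`, `start` (0-based window
#'   start), `cycles`, `register` (0..20), `occupied`, `in_phase`,
#'   `p_value`.
#' @export
scan_phasing <- function(pileup, ref_lengths, cfg = pipeline_config()) {
  pl <- cfg$phase_len
  win <- pl * cfg$phase_cycles
  pileup <- pileup[pileup$len == pl &
                     pileup$count >= cfg$min_phase_abundance, , drop = FALSE]
  out <- list()
  for (ref in unique(pileup$ref_id)) {
    pos <- sort(unique(pileup$pos[pileup$ref_id == ref]))
    L <- ref_lengths[[ref]]
    if (is.null(L) || is.na(L)) stopf("unknown reference length: %s", ref)
    starts <- seq(0L, max(0L, L - win), by = pl)
    for (w in starts) {
      inwin <- pos[pos >= w & pos < w + win]
      n <- length(inwin)
      if (n == 0) next
      k_by_reg <- tabulate(((inwin - w) %% pl) + 1L, nbins = pl)
      p <- vapply(k_by_reg, function(k)
        phasing_pvalue(win, cfg$phase_cycles, n, k), 0)
      best <- which.min(p)
      out[[length(out) + 1]] <- data.frame(
        ref_id = ref, start = w, cycles = cfg$phase_cycles,
        register = best - 1L, occupied = n, in_phase = k_by_reg[best],
        p_value = p[best])
    }
  }
  if (!length(out)) {
    return(data.frame(ref_id = character(), start = integer(),
                      cycles = integer(), register = integer(),
                      occupied = integer(), in_phase = integer(),
                      p_value = numeric()))
  }
  do.call(rbind, out)
}

#' Call TAS loci from scanned phase windows
#'
#' Windows whose best-register p-value is at or below `tas_p_threshold`
#' (0.001) are retained and overlapping significant windows on one
#' reference are merged into loci.  (The protocol prose reads as if
#' significant loci were discarded; the only consistent reading — loci
#' passing the threshold are retained — is implemented.)  Member tasiRNAs
#' are the in-phase 21-nt tags of the merged windows.
#'
#' @param windows output of [scan_phasing()].
#' @param pileup the pileup passed to [scan_phasing()] (with `tag_seq`).
#' @param cfg a [pipeline_config()].
#' @return list with `loci` (data frame `locus_id`, `ref_id`, `start`,
#'   `end`, `strand`, `p_value`, `n_members`) and `members` (data frame
#'   `locus_id`, `tag_seq`, `pos`).
#' @export
call_tas_loci <- function(windows, pileup, cfg = pipeline_config()) {
  pl <- cfg$phase_len
  win_len <- pl * cfg$phase_cycles
  sig <- windows[windows$p_value <= cfg$tas_p_threshold, , drop = FALSE]
  loci <- list()
  members <- list()
  if (nrow(sig)) {
    sig <- sig[order(sig$ref_id, sig$start), , drop = FALSE]
    for (ref in unique(sig$ref_id)) {
      s <- sig[sig$ref_id == ref, , drop = FALSE]
      cur_start <- s$start[1]
      cur_end <- s$start[1] + win_len
      cur_p <- s$p_value[1]
      cur_regs <- s$register[1]
      flush <- function(cur_start, cur_end, cur_p, cur_regs) {
        id <- sprintf("TAS-%s-%d", ref, cur_start)
        mem <- pileup[pileup$ref_id == ref & pileup$len == pl &
                        pileup$count >= cfg$min_phase_abundance &
                        pileup$pos >= cur_start & pileup$pos < cur_end &
                        ((pileup$pos - cur_start) %% pl) %in%
                          unique((cur_regs + 0L) %% pl), , drop = FALSE]
        loci[[length(loci) + 1]] <<- data.frame(
          locus_id = id, ref_id = ref, start = cur_start, end = cur_end,
          strand = "+", p_value = cur_p, n_members = nrow(mem))
        if (nrow(mem)) {
          members[[length(members) + 1]] <<- data.frame(
            locus_id = id,
            tag_seq = if ("tag_seq" %in% names(mem)) mem$tag_seq else
              NA_character_,
            pos = mem$pos)
        }
      }
      if (nrow(s) > 1) {
        for (i in 2:nrow(s)) {
          if (s$start[i] <= cur_end) {
            cur_end <- max(cur_end, s$start[i] + win_len)
            cur_p <- min(cur_p, s$p_value[i])
            cur_regs <- c(cur_regs, (s$register[i] + s$start[i] - cur_start) %% pl)
          } else {
            flush(cur_start, cur_end, cur_p, cur_regs)
            cur_start <- s$start[i]
            cur_end <- s$start[i] + win_len
            cur_p <- s$p_value[i]
            cur_regs <- s$register[i]
          }
        }
      }
      flush(cur_start, cur_end, cur_p, cur_regs)
    }
  }
  loci <- if (length(loci)) do.call(rbind, loci) else
    data.frame(locus_id = character(), ref_id = character(),
               start = integer(), end = integer(), strand = character(),
               p_value = numeric(), n_members = integer())
  members <- if (length(members)) do.call(rbind, members) else
    data.frame(locus_id = character(), tag_seq = character(),
               pos = integer())
  list(loci = loci, members = members)
}

#' Match tags against known TAS tasiRNAs
#'
#' Edit-bounded surrogate for the homology search against known TAS family
#' tasiRNAs: a tag is assigned when it matches a reference tasiRNA with at
#' most one mismatch or gap; the reference name is carried verbatim.
#'
#' @param tags character vector of (unannotated) tag sequences.
#' @param known_tas named character vector of known tasiRNA sequences.
#' @param cfg a [pipeline_config()].
#' @return data frame `tag_seq`, `tas_id`, `mismatches`, `gaps`.
#' @export
match_known_tas <- function(tags, known_tas, cfg = pipeline_config()) {
  refs <- data.frame(id = names(known_tas), seq = as_tag_seq(known_tas))
  hits <- match_refset(tags, refs, max_edits = 1L, protect_seed = FALSE,
                       cfg = cfg)
  data.frame(tag_seq = hits$tag_seq, tas_id = hits$reference_id,
             mismatches = hits$mismatches, gaps = hits$gaps)
}

#' Null calibration of the phasing scan
#'
#' Simulates windows with `n_occupied` occupied positions placed uniformly
#' at random among the window's positions and returns the fraction whose
#' best-register p-value reaches `tas_p_threshold` — the expected
#' false-positive window rate of [scan_phasing()] under a random pileup of
#' matched density.
#'
#' @param n_occupied occupied positions per window.
#' @param n_windows number of simulated windows.
#' @param cfg a [pipeline_config()].
#' @param seed integer seed.
#' @return list with `fp_rate` and the vector of simulated `p_values`.
#' @export
simulate_phasing_null <- function(n_occupied, n_windows = 1000,
                                  cfg = pipeline_config(), seed = 1) {
  pl <- cfg$phase_len
  win <- pl * cfg$phase_cycles
  p <- with_seed(seed, vapply(seq_len(n_windows), function(i) {
    pos <- sample.int(win, n_occupied) - 1L
    k_by_reg <- tabulate((pos %% pl) + 1L, nbins = pl)
    min(vapply(k_by_reg, function(k)
      phasing_pvalue(win, cfg$phase_cycles, n_occupied, k), 0))
  }, 0))
  list(fp_rate = mean(p <= cfg$tas_p_threshold), p_values = p)
}
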