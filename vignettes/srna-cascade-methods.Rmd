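---
title: "Methods: the small RNA annotation cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the small RNA annotation cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and design choices behind
`sRNAcascade`, stage by stage, and states what the synthetic benchmark
does and does not demonstrate about real data.

## The analysis model

The pipeline treats a small RNA experiment as a fixed sequence of
filters over *unique tags* — distinct insert sequences with per-library
raw and normalized counts.  Tags are held in one alphabet (uppercase,
`T` ≡ `U`) because reference sets and sequencing reads mix DNA- and
RNA-alphabet conventions.  Every stage consumes the tags the previous
stage left unexplained, mirroring how such catalogues are curated by
hand: contaminants first, then known miRNA homology, then de novo
structure, then phased siRNAs.

## Read cleaning

A read survives quality control iff, in this order: it contains no `N`;
at most `max_bases_below_q10` = 4 bases have Phred quality < 10; at most
`max_bases_below_q13` = 6 bases have quality < 13; the 3′ adapter is
found and the trimmed insert is at least `min_read_len` = 18 nt; the
insert does not begin with the 5′ adapter; and it is not poly-A.  Each
removed read increments exactly one counter (first-match accounting), so
the report partitions the input.

Choices the rule set leaves open, fixed here:

* 3′ adapter detection is the earliest position where a prefix of the
  adapter (≥ 6 nt overlap, ≤ 1 mismatch) matches through the read end;
  reads without a detectable adapter count as "missing 3′ primer".
* 5′-adapter contamination means the first 8 nt of the insert match the
  5′ adapter with ≤ 1 mismatch; poly-A means ≥ 80 % `A` or a terminal
  run of ≥ 8 `A`.  Both are evaluated on the whole read when no 3′
  adapter was found.
* Quality rules are evaluated on the untrimmed read, and the thresholds
  are strict inequalities (Q < 10, Q < 13) read literally.
* Adapter dimers (insert length 0) fall under the "too short" counter.

Only Phred+33 input is accepted; other encodings are rejected rather
than auto-detected, because silent mis-detection is worse than a hard
error.

## Normalization

Counts are normalized by library scaling to reads per million of clean
reads (`norm_scale` = 1e6).  The scaling base is configurable because
the underlying protocol names the method but not the constant; RPM is
the standard instance.  `mean_norm` averages over **all** configured
libraries, zeros included, so low-abundance filters see a replicate-wide
mean rather than a presence-weighted one.

## Edit-bounded homology instead of BlastN

All similarity searches are banded semiglobal alignments with an
explicit edit budget: the tag is consumed end-to-end, reference ends are
free, and every mismatch or 1-nt gap costs one edit.  For 18–30 nt
queries and budgets ≤ 3 this is exhaustive — strictly more sensitive
than a heuristic word-seeded search — and deterministic, so E-values are
not modelled at all.  The compiled matcher seeds candidate windows by
the pigeonhole principle (one of *e* + 1 tag pieces must match exactly)
and verifies each window by full dynamic programming; a plain-R DP
oracle in the test suite checks the minimum edit distance on random
pairs.

Conventions fixed by design: the seed region is measured on the **tag**,
positions 2–8 from the 5′ end (1-based, inclusive); a gap between tag
positions counts against the position it precedes; "sequence coverage
differing by ≤ 2 nt" is read as the tag/reference length difference;
ties among equal-edit references break to fewest seed-adjacent edits and
then the lexicographically smallest reference id.  The relative-species
ncRNA budget ("fewer than three mismatches or gaps") is implemented as
≤ 2 edits.

The cascade runs native references first (budget 1), then
close-relative references (budget 2), in the fixed category order rRNA,
tRNA, snRNA, snoRNA, scRNA, repeat, exon.  A tag keeps the first
category it matches.  The conserved-miRNA classification then makes two
passes over the remaining tags (native budget 1, other-plant budget 3,
both seed-protected and length-bounded); tags matching only
star-labelled references are reported as miRNA\*.  Star members are
excluded from the family-abundance sum, since the filter is meant to
measure mature expression; families not described in Brassicaceae
relatives are dropped below `min_family_mean_norm` = 15 RPM.

## Novel hairpin evaluation

Unannotated tags are mapped by exact 8-nt seed-and-extend
(substitutions only; 0 allowed on same-species contigs, ≤ 1 on relative
genomes; both strands).  Around each hit two windows are excised,
`[start − 250, end + 50)` and `[start − 50, end + 250)` — a common plant
precursor-excision geometry, configurable because the original
window is not printed — and folded with RNAfold (ViennaRNA, default
Turner parameters, no pseudoknots).  Because a single folding engine is
used, the two −18 kcal/mol checks of the original two-program protocol
collapse into one.

From the fold, the mature span must avoid every hairpin loop (i.e. lie
on an arm) and pair with an opposite arm.  Duplex statistics are
computed from the pairing table: `duplex_pairs` (mature bases paired
outside the mature span), `max_bulge` (longest interior unpaired run on
either strand of the duplex), `asymmetry` (difference of interior
unpaired counts).  Acceptance requires MFE ≤ −18 kcal/mol, ≥ 16 duplex
pairs, bulge ≤ 4 and asymmetry ≤ 4.  In place of external
machine-learned precursor classifiers, expression curation implements
the community annotation criteria directly: the mature tag must carry at
least 50 % of the reads mapped inside its precursor (`min_dominance`)
with supporting 5′ ends varying by ≤ 2 nt, and overlapping same-strand
precursors collapse to the highest-dominance candidate.  The 50 % and
2-nt values are design choices (the criteria are qualitative) and are
exposed in the configuration.  Short stems are not given any relaxation
of the 16-pair rule at precursor ends.

## Phased siRNA detection

Only 21-nt tags with mapping abundance ≥ `min_phase_abundance` = 4
define occupied positions.  A window of `phase_cycles` = 11 cycles
(231 nt, following the published phasing scheme) slides in 21-nt steps;
within a window each of the 21 registers is scored by the hypergeometric
tail P(X ≥ k) with N = 231 positions, K = 11 in-phase positions, n
occupied, k occupied-in-phase, computed in log space via `phyper`.  The
best register per window is emitted, and overlapping windows at
p ≤ 0.001 merge into loci.  Scanning is single-strand by default (an
optional dual-strand mode with the +2 duplex offset exists) because the
original strand handling is unstated.  The published wording would
discard loci *below* the 0.001 threshold — i.e. the significant ones;
the only self-consistent reading, retaining them, is implemented and
documented on `call_tas_loci()`.  A null calibration
(`simulate_phasing_null()`) places the same number of occupied positions
uniformly and reports the best-register false-positive rate, which stays
at or below 0.005 at the benchmark's density.

## Target prediction

The complementarity scorer aligns the miRNA antiparallel to the site by
local dynamic programming with affine gaps.  Column scores follow the
published scheme where stated — canonical +5, G:U +2 — and the reference
implementation's documented defaults where not: mismatch −3, gap open
−9, gap extend −4, with columns at miRNA positions 2–8 scaled ×4.  The
scaling is not optional: without it a perfect 21-mer scores 105 and the
published acceptance threshold of 130 would be unreachable.  A site is
accepted iff score ≥ 130, RNAduplex hybridization energy ≤ −17 kcal/mol,
and the seed alignment contains no gap and no non-canonical pair; G:U
counts as non-canonical in the seed (while still scoring +2 outside it),
with a `seed_allow_wobble` switch for the permissive reading.  Sites are
extracted greedily per (miRNA, transcript) — best first, then masked —
so reported sites never overlap; hits are ranked by score, then lower
duplex energy, and truncated to the top 20 when a miRNA produced more
than 50 raw sites, else 10.

## GO enrichment

Term-for-term overrepresentation: for every term annotating at least one
study gene, the hypergeometric upper tail against the population, with
Bonferroni correction over the number of *tested* terms (terms with zero
study genes neither get tested nor inflate the correction, matching the
cited tool's behaviour).  The population defaults to the full annotation
universe supplied by the caller, since the original population set is
implicit.  True-path propagation over an optional `is_a` ontology is
provided; the bundled OBO reader is deliberately minimal (`[Term]`,
`id`, `is_a`, obsolete skipping) as no ontology parser is assumed to be
installed.

## The synthetic benchmark

`sim_config()` defaults define the study conditions: three libraries of
50,000 reads, ~30 conserved families (two of them low-abundance
non-Brassicaceae decoys pinned at ~6 RPM to exercise the family filter),
20 novel hairpin loci, 5 TAS loci of 8 consecutive phased 21-mers,
ncRNA/repeat/transcript contaminant references, log-normal species
abundance (σ = 1.5) over a heavily skewed range, a 0.5 % per-base
substitution error rate, and a 4 % labelled fraction of QC-violating
reads cycling through the violation classes.  Planted hairpins are
near-perfect inverted repeats (one mismatch opposite a mid-mature
position, GC-biased stems, a stable tetraloop) so that each folds into
an arm-borne mature with ≥ 20 duplex pairs — the generator's
self-oracle.  TAS member tags are floored at 4 reads per library so the
phasing scan's abundance filter cannot erase a planted locus.

What passing the benchmark shows: every stage implements its stated rule
(the planted signal is recovered, the planted negatives are rejected,
the negative controls — a dinucleotide-shuffled genome and a uniform
phasing null — stay clean).  What it does not show: robustness to
sequencing chemistry artefacts, true genomic repeat structure,
paralogous precursor families, or reference incompleteness; the
generator makes no attempt at instrument error profiles or genome-scale
realism, so recovery rates on real libraries will be lower and
reference-dependent.

## Numerical and reproducibility notes

* All randomness flows through explicit integer seeds; reference and
  library generation restore the caller's RNG state.
* Folding is delegated to ViennaRNA (`RNAfold`, `RNAduplex`), which is
  deterministic for a fixed sequence and parameter set; the tool version
  is recorded in the run manifest.
* Hypergeometric tails use `phyper(..., lower.tail = FALSE)`; the test
  suite checks them against explicit combinatorial summation over the
  full small-parameter sweep (N ≤ 30, K ≤ 6, n ≤ 6).
* Degenerate inputs are contracts, not surprises: empty FASTQ files
  yield empty streams; empty tag tables are an error for distribution
  summaries; windows clipped below 40 nt are skipped; zero library
  totals are an error for normalization.
* Test and benchmark problem sizes — three libraries × 50,000 reads for
  the full study, 200 random pairs for the alignment oracle, 1,000
  windows for the phasing null — were chosen as the smallest sizes at
  which the planted effects are comfortably resolvable.

## Known limitations

* The annotation cascade is sequence-level only; no genomic context
  (synteny, repeat masking quality) informs category calls.
* miRNA-trigger assignment to TAS loci is reported only as a known-TAS
  homology flag, not modelled.
* The target scorer predicts complementarity sites, not regulatory
  outcome; translation inhibition and degradome validation are out of
  scope.
* BlastX-based GO assignment and pathway mapping are out of scope:
  annotation maps are inputs.
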