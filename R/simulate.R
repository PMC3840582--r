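#' Configuration of the synthetic small RNA study
#'
#' The defaults emulate the three-replicate leaf small RNA design the
#' pipeline was built for: three libraries of 50,000 reads, a skewed
#' (log-normal) species abundance with a few dominant miRNAs and a long
#' tail, conserved miRNA families with occasional star reads, novel
#' hairpin loci, 21-nt phased TAS loci, ncRNA/repeat contaminants and mRNA
#' degradation fragments, plus a labelled fraction of reads violating each
#' QC rule.
#'
#' @param rng_seed integer seed driving every random draw.
#' @param n_libraries number of libraries (biological replicates).
#' @param reads_per_library reads per library.
#' @param n_conserved_families planted conserved miRNA families (includes
#'   `n_decoy_families` low-abundance families not described in
#'   Brassicaceae relatives, planted to exercise the family filter).
#' @param n_novel_hairpins planted novel hairpin loci.
#' @param n_tas_loci planted 21-nt phased TAS loci.
#' @param n_contaminant_refs ncRNA/repeat reference sequences.
#' @param n_transcripts transcript (assembled contig) references.
#' @param abundance_shape log-normal sigma of species abundance.
#' @param error_rate per-base substitution rate in read inserts.
#' @param adapter3,adapter5 adapter sequences (DNA alphabet).
#' @param genome_contig_len length of each genomic contig.
#' @param fraction_star fraction of conserved families with sequenced star
#'   reads.
#' @param qc_negative_fraction fraction of reads per library planted as
#'   labelled QC violations.
#' @param n_phase_positions consecutive phased positions per TAS locus.
#' @param n_decoy_families low-abundance non-Brassicaceae decoy families.
#' @return classed list `sim_config`.
#' @export
sim_config <- function(rng_seed = 1L, n_libraries = 3L,
                       reads_per_library = 50000L,
                       n_conserved_families = 30L, n_novel_hairpins = 20L,
                       n_tas_loci = 5L, n_contaminant_refs = 18L,
                       n_transcripts = 40L, abundance_shape = 1.5,
                       error_rate = 0.005,
                       adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                       adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                       genome_contig_len = 4000L, fraction_star = 0.4,
                       qc_negative_fraction = 0.04,
                       n_phase_positions = 8L, n_decoy_families = 2L) {
  cfg <- as.list(environment())
  if (cfg$n_libraries >= 1 && cfg$reads_per_library < 1)
    stopf("reads_per_library must be >= 1")
  for (f in c("n_libraries", "n_conserved_families", "n_novel_hairpins",
              "n_tas_loci", "n_contaminant_refs", "n_transcripts"))
    if (cfg[[f]] < 0) stopf("%s must be >= 0", f)
  if (cfg$error_rate < 0 || cfg$error_rate >= 1)
    stopf("error_rate must lie in [0, 1)")
  if (cfg$fraction_star < 0 || cfg$fraction_star > 1)
    stopf("fraction_star must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

# One planted hairpin precursor: a near-perfect inverted repeat whose 5'
# arm carries the mature.  Layout: ext5(10) mature(21) ext3(10) loop(15)
# revcomp(ext3 mature ext5) with one planted mismatch opposite a mid-mature
# position, giving >= 20 duplex pairs, bulge <= 1 and a deep MFE.
make_hairpin <- function() {
  ext5 <- random_seq(1, 10, gc = 0.6)
  mature <- random_seq(1, 21, gc = 0.55)
  ext3 <- random_seq(1, 10, gc = 0.6)
  loop <- paste0(random_seq(1, 5, gc = 0.2), "UUCG", random_seq(1, 6, gc = 0.2))
  stem <- paste0(ext5, mature, ext3)
  rc <- strsplit(revcomp(stem), "")[[1]]
  # mismatch opposite mature position 12 (non-seed): stem position 10+12,
  # partner index in rc = len - (10+12) + 1
  mpos <- length(rc) - 21L
  alt <- setdiff(c("A", "C", "G", "U"), c(rc[mpos], chartr("ACGU", "UGCA", rc[mpos])))
  rc[mpos] <- alt[1]
  pre <- paste0(stem, loop, paste(rc, collapse = ""))
  # star: partner of the mature with a 2-nt 3' overhang
  Lp <- nchar(pre)
  star_start <- Lp - (10 + 21) + 1 + 2
  star <- substr(pre, star_start, star_start + 20)
  list(precursor = pre, mature = mature, star = star,
       mat_offset = 10L)  # 0-based offset of the mature in the precursor
}

#' Generate synthetic reference sets with known ground truth
#'
#' Builds every reference the pipeline consumes — genomic contigs with
#' planted novel hairpins and phased TAS loci, conserved mature miRNA sets
#' (same-species and other-plant), ncRNA/repeat/transcript cascade
#' references, known TAS tasiRNAs, and a small gene-to-GO annotation map —
#' together with a ground-truth object listing every planted species and
#' its expected annotation category.  Deterministic for a fixed
#' `rng_seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `genome` (named character), `refsets` (cascade
#'   reference data frame), `native_mirnas`, `other_mirnas`,
#'   `brassicaceae_families`, `transcripts`, `known_tas`, `go` (list
#'   `annotations`, `parents`, `target_genes`) and `truth` (planted
#'   miRNAs/hairpins/TAS/contaminants/fragments, expected categories and
#'   species abundance weights).
#' @export
simulate_references <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$rng_seed, simulate_references_impl(cfg))
}

simulate_references_impl <- function(cfg) {
  used <- character(0)  # all planted tag sequences, kept pairwise distinct
  fresh <- function(gen) {
    for (i in 1:50) {
      s <- gen()
      if (!s %in% used) { used <<- c(used, s); return(s) }
    }
    stopf("could not generate a distinct planted sequence")
  }

  ## conserved miRNA families ---------------------------------------------
  nfam <- cfg$n_conserved_families
  fam_names <- sprintf("MIR%03d", 100 + seq_len(nfam))
  decoy <- rep(FALSE, nfam)
  if (cfg$n_decoy_families > 0 && nfam > cfg$n_decoy_families)
    decoy[sample.int(nfam, cfg$n_decoy_families)] <- TRUE
  has_star <- runif(nfam) < cfg$fraction_star
  native <- runif(nfam) < 0.5
  matures <- character(nfam)
  stars <- rep(NA_character_, nfam)
  for (i in seq_len(nfam)) {
    len <- sample(20:22, 1)
    matures[i] <- fresh(function() random_seq(1, len, gc = 0.5))
    if (has_star[i]) {
      m <- matures[i]
      stars[i] <- fresh(function() {
        # star = revcomp with a 2-nt shift emulating the duplex overhang
        paste0(revcomp(substr(m, 3, nchar(m))), random_seq(1, 2))
      })
    }
  }
  native_mirnas <- data.frame(
    id = paste0("bol-", tolower(sub("MIR", "miR", fam_names[native]))),
    seq = matures[native], family = fam_names[native], star = 0L)
  other_mirnas <- data.frame(
    id = paste0("ath-", tolower(sub("MIR", "miR", fam_names))),
    seq = matures, family = fam_names, star = 0L)
  if (any(has_star)) {
    star_native <- data.frame(
      id = paste0("bol-", tolower(sub("MIR", "miR", fam_names[has_star])), "*"),
      seq = stars[has_star], family = fam_names[has_star], star = 1L)
    native_mirnas <- rbind(native_mirnas, star_native)
  }
  brassicaceae_families <- fam_names[!decoy]

  ## novel hairpin loci ----------------------------------------------------
  nh <- cfg$n_novel_hairpins
  hairpins <- lapply(seq_len(nh), function(i) {
    h <- make_hairpin()
    while (h$mature %in% used || h$star %in% used) h <- make_hairpin()
    used <<- c(used, h$mature, h$star)
    h
  })

  ## TAS loci ---------------------------------------------------------------
  nt <- cfg$n_tas_loci
  tas <- lapply(seq_len(nt), function(i) {
    tags <- vapply(seq_len(cfg$n_phase_positions), function(j)
      fresh(function() random_seq(1, 21, gc = 0.5)), "")
    list(tags = tags, locus_seq = paste(tags, collapse = ""))
  })

  ## genomic contigs --------------------------------------------------------
  L <- cfg$genome_contig_len
  plant_in_contig <- function(insert, name) {
    li <- nchar(insert)
    if (L < li + 100)
      stopf("genome_contig_len %d too short for a %d nt locus", L, li)
    off <- sample(50:(L - li - 50), 1)
    seq <- paste0(random_seq(1, off, gc = 0.4), insert,
                  random_seq(1, L - off - li, gc = 0.4))
    list(name = name, seq = seq, start = off)  # 0-based insert start
  }
  genome <- character(0)
  planted_novel <- list()
  for (i in seq_along(hairpins)) {
    h <- hairpins[[i]]
    ct <- plant_in_contig(h$precursor, sprintf("contig_hp%02d", i))
    genome[ct$name] <- ct$seq
    planted_novel[[i]] <- data.frame(
      id = sprintf("hairpin%02d", i), contig = ct$name,
      pre_start = ct$start, pre_end = ct$start + nchar(h$precursor),
      mature = h$mature, star = h$star,
      mat_start = ct$start + h$mat_offset,
      mat_end = ct$start + h$mat_offset + nchar(h$mature))
  }
  planted_tas <- list()
  for (i in seq_along(tas)) {
    ct <- plant_in_contig(tas[[i]]$locus_seq, sprintf("contig_tas%02d", i))
    # phase-align the locus start so scan windows (21-nt steps from 0)
    # can hit the register exactly
    genome[ct$name] <- ct$seq
    planted_tas[[i]] <- data.frame(
      locus = sprintf("TASL%02d", i), contig = ct$name, start = ct$start,
      end = ct$start + nchar(tas[[i]]$locus_seq),
      n_positions = cfg$n_phase_positions,
      tags = I(list(tas[[i]]$tags)))
  }
  for (i in 1:2) {
    nm <- sprintf("contig_bg%02d", i)
    genome[nm] <- random_seq(1, L, gc = 0.4)
  }
  genome <- as_dna_seq(genome)

  ## known TAS reference (one planted locus is the TAS3 homologue) ----------
  known_tas <- character(0)
  if (nt > 0) {
    d7 <- planted_tas[[1]]$tags[[1]][min(7L, cfg$n_phase_positions)]
    known_tas <- setNames(d7, "TAS3a-D7(+)")
  }

  ## cascade contaminant references -----------------------------------------
  cats <- c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA", "repeat")
  ncont <- cfg$n_contaminant_refs
  cont <- data.frame(
    id = sprintf("%s_ref%02d", cats[(seq_len(ncont) - 1) %% length(cats) + 1],
                 seq_len(ncont)),
    category = cats[(seq_len(ncont) - 1) %% length(cats) + 1],
    native = as.integer(seq_len(ncont) %% 2 == 1))
  cont$seq <- random_seq(ncont, sample(90:250, ncont, replace = TRUE), gc = 0.5)
  cont_frags <- list()
  for (i in seq_len(ncont)) {
    for (j in 1:2) {
      len <- sample(19:24, 1)
      st <- sample(nchar(cont$seq[i]) - len, 1)
      frag <- substr(cont$seq[i], st, st + len - 1)
      if (frag %in% used) next
      used <- c(used, frag)
      cont_frags[[length(cont_frags) + 1]] <- data.frame(
        seq = frag, category = cont$category[i], ref_id = cont$id[i])
    }
  }
  cont_frags <- do.call(rbind, cont_frags)

  ## transcripts (exon references, target space, GO genes) ------------------
  ntx <- cfg$n_transcripts
  tx <- setNames(random_seq(ntx, sample(350:600, ntx, replace = TRUE),
                            gc = 0.45),
                 sprintf("transcript%03d", seq_len(ntx)))
  # plant perfect complementarity sites of the first conserved matures in
  # the first transcripts (reverse complement: the cascade matches the
  # forward strand only, so miRNA tags are not annotated as exon)
  n_sites <- min(10L, ntx, nfam)
  target_genes <- character(0)
  for (i in seq_len(n_sites)) {
    site <- as_dna_seq(revcomp(matures[i]))
    s <- nchar(tx[i]) %/% 2
    substr(tx[i], s, s + nchar(site) - 1) <- site
    target_genes <- c(target_genes, names(tx)[i])
  }
  tx_frag <- list()
  frag_src <- setdiff(seq_len(ntx), seq_len(n_sites))
  for (i in utils::head(frag_src, 15)) {
    for (j in 1:2) {
      len <- sample(19:24, 1)
      st <- sample(nchar(tx[i]) - len, 1)
      frag <- as_tag_seq(substr(tx[i], st, st + len - 1))
      if (frag %in% used) next
      used <- c(used, frag)
      tx_frag[[length(tx_frag) + 1]] <- data.frame(
        seq = frag, category = "exon", ref_id = names(tx)[i])
    }
  }
  tx_frag <- do.call(rbind, tx_frag)

  refsets <- rbind(
    cont[, c("id", "seq", "category", "native")],
    data.frame(id = names(tx), seq = as.character(tx), category = "exon",
               native = 1L))

  ## GO annotations ----------------------------------------------------------
  terms <- sprintf("GO:%07d", 1:12)
  parents <- setNames(vector("list", 12), terms)
  parents[[terms[2]]] <- terms[1]
  parents[[terms[3]]] <- terms[1]
  for (i in 4:12) parents[[terms[i]]] <- terms[sample(2:3, 1)]
  genes <- names(tx)
  go_rows <- list()
  for (g in genes) {
    k <- sample(1:3, 1)
    t_g <- if (g %in% target_genes) {
      unique(c(terms[4], sample(terms[5:12], k)))   # term 4 enriched in targets
    } else sample(terms[5:12], k)
    go_rows[[length(go_rows) + 1]] <- data.frame(gene = g, term = t_g)
  }
  go_annotations <- do.call(rbind, go_rows)

  ## ground truth -------------------------------------------------------------
  planted_mirnas <- data.frame(
    family = fam_names, mature = matures, star = stars,
    native = native, has_star = has_star, decoy = decoy,
    brassicaceae = !decoy)
  planted_novel <- do.call(rbind, planted_novel)
  planted_tas_df <- if (length(planted_tas)) do.call(rbind, planted_tas) else
    data.frame(locus = character(), contig = character(), start = integer(),
               end = integer(), n_positions = integer(), tags = I(list()))

  expected <- rbind(
    data.frame(seq = matures, category = "conserved_miRNA"),
    if (any(has_star))
      data.frame(seq = stars[has_star], category = "miRNA_star"),
    if (nh > 0) data.frame(seq = planted_novel$mature, category = "novel_miRNA"),
    if (nh > 0) data.frame(seq = planted_novel$star, category = "novel_miRNA"),
    if (nt > 0) data.frame(seq = unlist(lapply(planted_tas, function(x) x$tags[[1]])),
                           category = "tasiRNA"),
    cont_frags[, c("seq", "category")],
    tx_frag[, c("seq", "category")])

  ## species abundance -------------------------------------------------------
  species <- rbind(
    data.frame(seq = matures, class = "conserved_mature",
               label = fam_names,
               meanlog = log(ifelse(decoy, 2, 200))),
    if (any(has_star))
      data.frame(seq = stars[has_star], class = "conserved_star",
                 label = paste0(fam_names[has_star], "*"),
                 meanlog = log(20)),
    if (nh > 0)
      data.frame(seq = planted_novel$mature, class = "novel_mature",
                 label = planted_novel$id, meanlog = log(60)),
    if (nh > 0)
      data.frame(seq = planted_novel$star, class = "novel_star",
                 label = paste0(planted_novel$id, "*"), meanlog = log(6)),
    if (nt > 0)
      data.frame(seq = unlist(lapply(planted_tas, function(x) x$tags[[1]])),
                 class = "tasiRNA",
                 label = rep(vapply(planted_tas, function(x) x$locus[1], ""),
                             each = cfg$n_phase_positions),
                 meanlog = log(40)),
    data.frame(seq = cont_frags$seq, class = "contaminant",
               label = cont_frags$ref_id, meanlog = log(30)),
    data.frame(seq = tx_frag$seq, class = "exon_fragment",
               label = tx_frag$ref_id, meanlog = log(30)))
  species$weight <- rlnorm(nrow(species), species$meanlog, cfg$abundance_shape)
  # decoy families sit under the abundance filter: their expected share is
  # pinned to ~6 reads per million, well below the 15-RPM family cutoff
  decoy_rows <- species$class == "conserved_mature" &
    species$label %in% fam_names[decoy]
  if (any(decoy_rows)) {
    species$weight[decoy_rows] <-
      6e-6 * sum(species$weight[!decoy_rows]) / max(1, sum(decoy_rows))
  }

  list(genome = genome, refsets = refsets, native_mirnas = native_mirnas,
       other_mirnas = other_mirnas,
       brassicaceae_families = brassicaceae_families,
       transcripts = tx, known_tas = known_tas,
       go = list(annotations = go_annotations, parents = parents,
                 target_genes = target_genes),
       truth = list(planted_mirnas = planted_mirnas,
                    planted_novel = planted_novel,
                    planted_tas = planted_tas_df,
                    planted_contaminants = cont_frags,
                    planted_fragments = tx_frag,
                    expected_category = expected,
                    species = species))
}

#' Simulate FASTQ libraries from planted references
#'
#' Draws `reads_per_library` reads per library: insert species are sampled
#' multinomially with log-normal weights (jittered per library as
#' biological replicates), the 3' adapter is appended and the read
#' truncated to at most 44 nt, substitution errors are planted at
#' `error_rate` per insert base, and Phred qualities are drawn high
#' (35-40).  TAS member tags are guaranteed at least `min_phase_abundance`
#' reads per library (counts are transferred from the most abundant
#' species).  A labelled `qc_negative_fraction` of reads violates the QC
#' rules, cycling through the violation classes.
#'
#' @param cfg a [sim_config()].
#' @param refs output of [simulate_references()].
#' @param dir output directory (created if needed).
#' @param min_phase_abundance floor for TAS member reads per library.
#' @return list with `files` (named FASTQ paths), `read_info` (data frame
#'   `library`, `read_id`, `class`, `species_seq`, `qc_class`) and
#'   `species_counts` (species x library matrix of sampled insert counts).
#' @export
simulate_libraries <- function(cfg, refs, dir = tempfile("simlib"),
                               min_phase_abundance = 4L) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(cfg$rng_seed + 1L, simulate_libraries_impl(cfg, refs, dir,
                                                       min_phase_abundance))
}

qc_negative_classes <- c("n_base", "low_q10", "low_q13", "short_insert",
                         "adapter5", "polyA", "no_adapter3")

simulate_libraries_impl <- function(cfg, refs, dir, min_phase_abundance) {
  species <- refs$truth$species
  ns <- nrow(species)
  libs <- sprintf("lib%d", seq_len(cfg$n_libraries))
  files <- setNames(file.path(dir, paste0(libs, ".fastq")), libs)
  info <- list()
  counts_mat <- matrix(0L, nrow = ns, ncol = length(libs),
                       dimnames = list(species$seq, libs))
  n_neg <- round(cfg$qc_negative_fraction * cfg$reads_per_library)
  n_pos <- cfg$reads_per_library - n_neg
  for (li in seq_along(libs)) {
    lib <- libs[li]
    w <- species$weight * exp(rnorm(ns, 0, 0.15))
    cnt <- as.vector(rmultinom(1, n_pos, w / sum(w)))
    # floor TAS members so planted loci stay detectable
    tas_rows <- which(species$class == "tasiRNA")
    for (r in tas_rows) {
      need <- min_phase_abundance - cnt[r]
      if (need > 0) {
        donor <- which.max(cnt)
        cnt[donor] <- cnt[donor] - need
        cnt[r] <- cnt[r] + need
      }
    }
    counts_mat[, li] <- cnt
    idx <- rep.int(seq_len(ns), cnt)
    inserts <- species$seq[idx]
    # substitution errors
    if (cfg$error_rate > 0) {
      nerr <- stats::rbinom(length(inserts), nchar(inserts), cfg$error_rate)
      for (i in which(nerr > 0)) {
        s <- strsplit(inserts[i], "")[[1]]
        pos <- sample.int(length(s), nerr[i])
        for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "U"), s[p]), 1)
        inserts[i] <- paste(s, collapse = "")
      }
    }
    reads <- make_reads(as_dna_seq(inserts), cfg$adapter3)
    neg <- make_qc_negatives(n_neg, cfg)
    all_seq <- c(reads$seq, neg$seq)
    all_qual <- c(reads$qual, neg$qual)
    ids <- sprintf("%s_r%06d", lib, seq_along(all_seq))
    ord <- sample.int(length(all_seq))  # interleave negatives
    write_fastq(all_seq[ord], all_qual[ord], ids, files[[lib]])
    info[[li]] <- data.frame(
      library = lib, read_id = ids,
      class = c(species$class[idx], rep("qc_negative", n_neg))[ord],
      species_seq = c(species$seq[idx], rep(NA_character_, n_neg))[ord],
      qc_class = c(rep(NA_character_, length(reads$seq)), neg$class)[ord])
  }
  list(files = files, read_info = do.call(rbind, info),
       species_counts = counts_mat)
}

# insert + 3' adapter, capped at 44 nt, high-quality Phred strings
make_reads <- function(inserts_dna, adapter3) {
  seqs <- substr(paste0(inserts_dna, adapter3), 1, 44)
  qual <- vapply(nchar(seqs), function(n)
    intToUtf8(sample(68:73, n, replace = TRUE)), "")  # Phred 35-40
  list(seq = seqs, qual = qual)
}

# labelled reads violating exactly one QC rule each
make_qc_negatives <- function(n, cfg) {
  if (n == 0) return(list(seq = character(), qual = character(),
                          class = character()))
  classes <- qc_negative_classes[(seq_len(n) - 1) %% length(qc_negative_classes) + 1]
  base_insert <- function(len) random_seq(1, len, alphabet = c("A", "C", "G", "T"))
  seqs <- character(n)
  quals <- character(n)
  hi <- function(n) intToUtf8(sample(68:73, n, replace = TRUE))
  for (i in seq_len(n)) {
    ins <- base_insert(21)
    cl <- classes[i]
    if (cl == "n_base") substr(ins, 10, 10) <- "N"
    if (cl == "short_insert") ins <- substr(ins, 1, 15)
    if (cl == "adapter5") ins <- paste0(substr(cfg$adapter5, 1, 8),
                                        substr(ins, 9, 21))
    if (cl == "polyA") ins <- strrep("A", 22)
    s <- if (cl == "no_adapter3") {
      # tail that cannot be mistaken for the adapter
      paste0(ins, strrep("C", 18))
    } else paste0(ins, cfg$adapter3)
    s <- substr(s, 1, 44)
    q <- hi(nchar(s))
    if (cl == "low_q10") {
      qq <- utf8ToInt(q); qq[1:5] <- 33 + 9; q <- intToUtf8(qq)  # 5 bases Q9
    }
    if (cl == "low_q13") {
      qq <- utf8ToInt(q); qq[1:7] <- 33 + 12; q <- intToUtf8(qq) # 7 bases Q12
    }
    seqs[i] <- s
    quals[i] <- q
  }
  list(seq = seqs, qual = quals, class = classes)
}

#' Write the synthetic reference bundle to disk
#'
#' FASTA files for the genome, cascade references, miRNA sets, transcripts
#' and known TAS tasiRNAs; a GFF3 of planted loci; a TSV manifest mapping
#' every planted tag to its expected category; and the GO annotation TSV.
#'
#' @param refs output of [simulate_references()].
#' @param dir output directory.
#' @return named vector of written paths.
#' @export
write_reference_bundle <- function(refs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fasta"),
             refsets = file.path(dir, "cascade_refs.fasta"),
             native_mirnas = file.path(dir, "mirna_native.fasta"),
             other_mirnas = file.path(dir, "mirna_other.fasta"),
             transcripts = file.path(dir, "transcripts.fasta"),
             known_tas = file.path(dir, "known_tas.fasta"),
             loci = file.path(dir, "planted_loci.gff3"),
             manifest = file.path(dir, "expected_category.tsv"),
             go = file.path(dir, "go_annotations.tsv"))
  write_fasta(refs$genome, paths["genome"])
  write_reference_fasta(refs$refsets, paths["refsets"],
                        label_cols = c("category", "native"))
  nat <- refs$native_mirnas
  nat$native <- 1L
  write_reference_fasta(nat, paths["native_mirnas"],
                        label_cols = c("family", "star", "native"))
  oth <- refs$other_mirnas
  oth$native <- 0L
  write_reference_fasta(oth, paths["other_mirnas"],
                        label_cols = c("family", "star", "native"))
  write_fasta(refs$transcripts, paths["transcripts"])
  if (length(refs$known_tas)) write_fasta(refs$known_tas, paths["known_tas"])
  pn <- refs$truth$planted_novel
  pt <- refs$truth$planted_tas
  loci <- rbind(
    if (nrow(pn)) data.frame(ref_id = pn$contig, start = pn$pre_start,
                             end = pn$pre_end, strand = "+",
                             type = "miRNA_primary_transcript", id = pn$id),
    if (nrow(pt)) data.frame(ref_id = pt$contig, start = pt$start,
                             end = pt$end, strand = "+",
                             type = "TAS_locus", id = pt$locus))
  if (is.null(loci)) loci <- data.frame(ref_id = character(),
                                        start = integer(), end = integer(),
                                        strand = character(),
                                        type = character(), id = character())
  write_gff3(loci, paths["loci"])
  write.table(refs$truth$expected_category, paths["manifest"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(refs$go$annotations, paths["go"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  paths
}
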