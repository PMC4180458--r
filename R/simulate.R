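#' Specify a synthetic NSR-seq fixture
#'
#' Collects every knob of the synthetic-data generator into a validated
#' spec. The defaults emulate the study design this toolkit targets: a
#' small AT-rich genome (GC 0.36), 200 annotated ncRNA loci of which 20
#' carry a planted 2.5-fold difference between the two conditions
#' (6 of them organized into two same-direction genomic clusters), a
#' 92-species spike-in ladder spanning a 10^6-fold concentration range with
#' lengths 250-2000 nt, 80-nt single-end reads, and a genomic read mix of
#' 10% rRNA / 60% mRNA / 5% ncRNA / 5% antisense / 10% intronic /
#' 10% intergenic.
#'
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   fixtures.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param gc Genome GC fraction (default 0.36).
#' @param n_mrna,n_ncrna,n_rrna Locus counts per biotype. mRNA loci have
#'   two 300-nt exons separated by a 200-nt intron; ncRNA loci are 200-nt
#'   single exons; rRNA loci 1500-nt single exons.
#' @param n_spikein Spike-in species count (default 92, grouped into 23
#'   concentration levels of 4 species as in commercial mixes).
#' @param spike_length_range Spike-in length range in nt.
#' @param spike_dynamic_range Max/min spike-in concentration ratio.
#' @param spike_read_fraction Fraction of reads drawn from spike-ins.
#' @param n_reads Target primary reads per sample.
#' @param read_length Read length in nt (default 80).
#' @param sigma Lognormal noise sd on log10 expected counts. The
#'   multiplier is drawn once per locus/species and shared across samples
#'   (species-specific priming/amplification bias that is technically
#'   reproducible), with independent per-sample Poisson sampling on top.
#' @param category_mix Named fractions over
#'   rRNA/mRNA/known_ncRNA/antisense/intronic/intergenic; must sum to 1.
#' @param samples Length-2 character vector: reference and comparison
#'   sample names.
#' @param planted_de `"default"` (20 ncRNA loci at 2.5-fold: the cluster
#'   members plus 14 isolated singletons, half repressed half activated),
#'   `NULL` (none), or a tibble with `transcript_id`, `fold`, `direction`
#'   (`"repressed"` = higher in the comparison sample).
#' @param planted_de_uv Optional second planted-difference table; when
#'   given, two additional samples `<samples>_uv` are generated from it and
#'   the ledger records the expected status shifts.
#' @param planted_clusters Tibble with `chrom`, `n_members`, `gap`
#'   (between successive member starts), `direction`; default two
#'   3-member repressed clusters with 4-kb gaps on the last two
#'   chromosomes. `NULL` for none.
#' @param planted_motifs `NULL`, or a tibble with `transcript_id` and
#'   `offset` (TSS-relative, negative upstream) naming promoters to seed
#'   with one concrete instance of `motif_pattern`.
#' @param motif_pattern IUPAC pattern whose random concrete expansions are
#'   planted (default `"RRRCWWGYYY"`).
#' @param planted_counts Optional tibble (`transcript_id`, `sample`,
#'   `count`) of exact counts that bypass the count model entirely.
#' @param de_weight Expression weight of planted-DE loci relative to null
#'   ncRNA loci (default 6; keeps planted loci comfortably above the RPKM
#'   gate).
#' @param poisson Draw per-sample counts as Poisson around the expectation
#'   (default). With `poisson = FALSE` and `sigma = 0` counts equal the
#'   continuous expectation exactly, for noise-free contract checks.
#' @param exact_category_counts If `TRUE`, per-category read totals are
#'   fixed at `round(category_mix * n_reads)` (and split across loci
#'   multinomially) instead of Poisson; use for exact breakdown checks.
#' @return A list of class `nsr_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1,
                         chrom_lengths = c(chrI = 250000, chrII = 250000,
                                           chrIII = 250000, chrIV = 250000,
                                           chrV = 250000, chrX = 250000),
                         gc = 0.36,
                         n_mrna = 42, n_ncrna = 200, n_rrna = 2,
                         n_spikein = 92,
                         spike_length_range = c(250, 2000),
                         spike_dynamic_range = 1e6,
                         spike_read_fraction = 0.005,
                         n_reads = 200000,
                         read_length = 80,
                         sigma = 0.1,
                         category_mix = c(rRNA = 0.10, mRNA = 0.60,
                                          known_ncRNA = 0.05,
                                          antisense = 0.05,
                                          intronic = 0.10,
                                          intergenic = 0.10),
                         samples = c("wildtype", "mutant"),
                         planted_de = "default",
                         planted_de_uv = NULL,
                         planted_clusters = "default",
                         planted_motifs = NULL,
                         motif_pattern = "RRRCWWGYYY",
                         planted_counts = NULL,
                         de_weight = 6,
                         poisson = TRUE,
                         exact_category_counts = FALSE) {
  stopifnot(length(samples) == 2, is.numeric(seed), length(seed) == 1)
  if (is.null(names(chrom_lengths))) {
    stop("chrom_lengths must be named", call. = FALSE)
  }
  if (abs(sum(category_mix) - 1) > 1e-9) {
    stop("category_mix must sum to 1", call. = FALSE)
  }
  need_cat <- c("rRNA", "mRNA", "known_ncRNA", "antisense", "intronic",
                "intergenic")
  if (!setequal(names(category_mix), need_cat)) {
    stop("category_mix must be named over: ",
         paste(need_cat, collapse = ", "), call. = FALSE)
  }
  if (n_mrna < 1 || n_ncrna < 1 || n_rrna < 1 || n_reads < 1 ||
      spike_dynamic_range < 1 || gc <= 0 || gc >= 1 || sigma < 0) {
    stop("invalid fixture spec: counts must be positive, dynamic range ",
         ">= 1, 0 < gc < 1, sigma >= 0", call. = FALSE)
  }
  if (identical(planted_clusters, "default")) {
    nch <- names(chrom_lengths)
    planted_clusters <- tibble::tibble(
      chrom = nch[c(length(nch), length(nch) - 1)],
      n_members = 3L, gap = 4000, direction = "repressed")
  }
  spec <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
               gc = gc, n_mrna = n_mrna, n_ncrna = n_ncrna, n_rrna = n_rrna,
               n_spikein = n_spikein,
               spike_length_range = spike_length_range,
               spike_dynamic_range = spike_dynamic_range,
               spike_read_fraction = spike_read_fraction,
               n_reads = n_reads, read_length = read_length, sigma = sigma,
               category_mix = category_mix[need_cat], samples = samples,
               planted_de = planted_de, planted_de_uv = planted_de_uv,
               planted_clusters = planted_clusters,
               planted_motifs = planted_motifs,
               motif_pattern = motif_pattern,
               planted_counts = planted_counts, de_weight = de_weight,
               poisson = poisson,
               exact_category_counts = exact_category_counts)
  class(spec) <- "nsr_fixture_spec"
  spec
}

# deterministic genome layout: planted clusters at the head of their
# chromosome with a wide isolation margin, then the regular loci dealt
# round-robin with a fixed inter-locus gap
fixture_layout <- function(spec) {
  chroms <- names(spec$chrom_lengths)
  cursor <- stats::setNames(rep(2000, length(chroms)), chroms)
  spacing <- 5000
  isolation <- 25000
  nc_len <- 200; rr_len <- 1500
  mr_exon <- 300; mr_intron <- 200

  loci <- list()
  nc_counter <- 0
  add_locus <- function(chrom, biotype, strand) {
    start <- cursor[[chrom]]
    if (biotype == "mRNA") {
      span <- 2 * mr_exon + mr_intron
      ex_s <- c(start, start + mr_exon + mr_intron)
      ex_e <- ex_s + mr_exon
    } else {
      span <- if (biotype == "rRNA") rr_len else nc_len
      ex_s <- start; ex_e <- start + span
    }
    if (start + span > spec$chrom_lengths[[chrom]] - 1000) {
      stop("infeasible fixture spec: loci exceed length of ", chrom,
           call. = FALSE)
    }
    cursor[[chrom]] <<- start + span + spacing
    id <- switch(biotype,
      mRNA = sprintf("mrna_%03d", length(loci) + 1),
      rRNA = sprintf("rrna_%03d", length(loci) + 1),
      known_ncRNA = {
        nc_counter <<- nc_counter + 1
        sprintf("nc_%04d", nc_counter)
      })
    loci[[length(loci) + 1]] <<- tibble::tibble(
      transcript_id = id, chrom = chrom, start = start, end = start + span,
      strand = strand, biotype = biotype,
      exon_starts = list(ex_s), exon_ends = list(ex_e))
    id
  }

  cluster_members <- list()
  pc <- spec$planted_clusters
  if (!is.null(pc)) {
    for (i in seq_len(nrow(pc))) {
      ch <- pc$chrom[i]
      if (!ch %in% chroms) {
        stop("infeasible fixture spec: cluster chromosome ", ch,
             " not in genome", call. = FALSE)
      }
      ids <- character(pc$n_members[i])
      for (m in seq_len(pc$n_members[i])) {
        start <- cursor[[ch]]
        ids[m] <- add_locus(ch, "known_ncRNA", if (m %% 2) "+" else "-")
        # enforce the requested start-to-start gap
        cursor[[ch]] <- start + pc$gap[i]
      }
      cursor[[ch]] <- cursor[[ch]] - pc$gap[i] + nc_len + isolation
      cluster_members[[i]] <- ids
    }
  }
  n_cluster_nc <- length(unlist(cluster_members))
  if (n_cluster_nc > spec$n_ncrna) {
    stop("infeasible fixture spec: cluster members exceed n_ncrna",
         call. = FALSE)
  }

  regular <- c(rep("rRNA", spec$n_rrna), rep("mRNA", spec$n_mrna),
               rep("known_ncRNA", spec$n_ncrna - n_cluster_nc))
  # deterministic interleave so every chromosome gets each biotype
  regular <- regular[order(seq_along(regular) %% length(chroms),
                           regular)]
  for (j in seq_along(regular)) {
    ch <- chroms[(j - 1) %% length(chroms) + 1]
    add_locus(ch, regular[j], if (j %% 2) "+" else "-")
  }
  ann <- transcript_models(dplyr::bind_rows(loci))
  list(annotation = ann, cluster_members = cluster_members)
}

resolve_planted_de <- function(spec, annotation, cluster_members) {
  if (is.null(spec$planted_de)) {
    return(tibble::tibble(transcript_id = character(), fold = numeric(),
                          direction = character()))
  }
  if (is.data.frame(spec$planted_de)) return(spec$planted_de)
  # default: cluster members plus isolated singletons, 2.5-fold
  nc <- annotation$transcript_id[annotation$biotype == "known_ncRNA"]
  clust <- unlist(cluster_members)
  singles_pool <- setdiff(nc, clust)
  n_singles <- max(0, 20 - length(clust))
  take <- singles_pool[seq(7, by = 10, length.out = n_singles)]
  take <- take[!is.na(take)]
  dir_c <- if (!is.null(spec$planted_clusters)) {
    rep(spec$planted_clusters$direction,
        times = spec$planted_clusters$n_members)
  } else character(0)
  tibble::tibble(
    transcript_id = c(clust, take),
    fold = 2.5,
    direction = c(dir_c,
                  rep(c("repressed", "activated"), length.out = length(take)))
  )
}

random_genome <- function(chrom_lengths, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(chrom_lengths, function(L) {
    paste(sample(names(probs), L, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
  tibble::tibble(id = names(chrom_lengths), sequence = unname(seqs))
}

sample_iupac_instance <- function(pattern) {
  letters <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(letters, function(l) sample(iupac_expand[[l]], 1),
               character(1)), collapse = "")
}

plant_motifs <- function(genome, annotation, planted, pattern) {
  seqs <- stats::setNames(genome$sequence, genome$id)
  plen <- nchar(pattern)
  planted$instance <- vapply(seq_len(nrow(planted)),
                             function(i) sample_iupac_instance(pattern),
                             character(1))
  for (i in seq_len(nrow(planted))) {
    tx <- annotation[annotation$transcript_id == planted$transcript_id[i], ]
    if (nrow(tx) == 0) {
      stop("planted motif names unknown transcript: ",
           planted$transcript_id[i], call. = FALSE)
    }
    off <- planted$offset[i]
    if (tx$strand == "+") {
      g0 <- tx$tss + off
      ins <- planted$instance[i]
    } else {
      g0 <- tx$tss - off - plen + 1
      ins <- revcomp(planted$instance[i])
    }
    if (g0 < 0 || g0 + plen > nchar(seqs[[tx$chrom]])) {
      stop("planted motif outside chromosome for ",
           planted$transcript_id[i], call. = FALSE)
    }
    substring(seqs[[tx$chrom]], g0 + 1, g0 + plen) <- ins
  }
  genome$sequence <- unname(seqs[genome$id])
  list(genome = genome, motifs = planted)
}

# ladder organized like the commercial mixes: concentration levels with a
# few species each. Lengths are drawn over the range, then dealt to levels
# snake-wise by size so every level's aggregate length is balanced and the
# aggregate expected read mass per level tracks the concentration ladder.
spikein_ladder_ref <- function(n_species, length_range, dynamic_range,
                               levels_per_group = 4) {
  n_levels <- ceiling(n_species / levels_per_group)
  conc_levels <- 10^seq(log10(0.01), log10(0.01 * dynamic_range),
                        length.out = n_levels)
  conc <- rep(conc_levels, each = levels_per_group)[seq_len(n_species)]
  lens_sorted <- sort(round(stats::runif(n_species, length_range[1],
                                         length_range[2])))
  snake <- rep(c(seq_len(n_levels), rev(seq_len(n_levels))),
               length.out = n_species)
  dealt <- split(lens_sorted, snake)
  level_of_species <- rep(seq_len(n_levels),
                          each = levels_per_group)[seq_len(n_species)]
  out_len <- integer(n_species)
  taken <- integer(n_levels)
  pool <- integer(0)  # overflow when n_species is not a multiple
  for (i in seq_len(n_species)) {
    l <- as.character(level_of_species[i])
    taken[level_of_species[i]] <- taken[level_of_species[i]] + 1
    v <- dealt[[l]]
    if (taken[level_of_species[i]] <= length(v)) {
      out_len[i] <- v[taken[level_of_species[i]]]
    } else {
      if (length(pool) == 0) pool <- lens_sorted
      out_len[i] <- pool[1]; pool <- pool[-1]
    }
  }
  tibble::tibble(id = sprintf("spike_%03d", seq_len(n_species)),
                 concentration = conc, length = out_len)
}

empty_reads <- function() {
  tibble::tibble(read_id = character(), sample = character(),
                 chrom = character(), start = numeric(), end = numeric(),
                 strand = character(), is_primary = logical(),
                 category = character(), transcript_id = character())
}

# vectorized uniform placement over the valid read-start positions of each
# transcript's exons (a read must fit inside one exon; if no exon can hold
# a full-length read the read is truncated to the exon)
place_sense_reads <- function(annotation, counts_by_tx, read_length,
                              sample, category_label, id_prefix) {
  counts_by_tx <- round(counts_by_tx)
  if (sum(counts_by_tx) == 0) return(empty_reads())
  ex_s <- annotation$exon_starts
  ex_e <- annotation$exon_ends
  nex <- max(lengths(ex_s))
  S <- E <- matrix(NA_real_, nrow(annotation), nex)
  for (r in seq_len(nex)) {
    has <- lengths(ex_s) >= r
    S[has, r] <- vapply(ex_s[has], function(v) v[r], numeric(1))
    E[has, r] <- vapply(ex_e[has], function(v) v[r], numeric(1))
  }
  W <- pmax(E - S - read_length + 1, 0)
  fb <- rowSums(W, na.rm = TRUE) == 0
  W[fb, ] <- pmax(E - S, 0)[fb, ]

  idx <- rep(seq_len(nrow(annotation)), counts_by_tx)
  n <- length(idx)
  wtot <- rowSums(W, na.rm = TRUE)[idx]
  o <- floor(stats::runif(n) * wtot)
  pos <- numeric(n)
  chosen_end <- numeric(n)
  done <- logical(n)
  csum <- numeric(n)
  for (r in seq_len(nex)) {
    wr <- W[idx, r]
    wr[is.na(wr)] <- 0
    pick <- !done & o < csum + wr
    pos[pick] <- S[idx[pick], r] + (o[pick] - csum[pick])
    chosen_end[pick] <- E[idx[pick], r]
    done <- done | pick
    csum <- csum + wr
  }
  tibble::tibble(
    read_id = sprintf("%s_%s_%06d", sample, id_prefix, seq_len(n)),
    sample = sample, chrom = annotation$chrom[idx], start = pos,
    end = pmin(pos + read_length, chosen_end),
    strand = annotation$strand[idx], is_primary = TRUE,
    category = category_label,
    transcript_id = annotation$transcript_id[idx])
}

draw_total <- function(expected, exact, poisson) {
  if (exact) return(round(expected))
  if (poisson) stats::rpois(length(expected), expected) else round(expected)
}

#' Generate a complete synthetic NSR-seq fixture
#'
#' Builds, deterministically under the spec's seed, a toy genome with
#' annotated mRNA/ncRNA/rRNA loci and spike-in species, a two-condition
#' read set with the requested genomic category mix and planted
#' differential loci / clusters / promoter motifs, and a ground-truth
#' ledger sufficient to score every downstream analysis exactly.
#'
#' Per-locus expected counts follow the generator's count model: a base
#' expression weight, times the planted fold in the comparison sample,
#' times a per-locus lognormal bias multiplier `10^N(0, sigma)` shared
#' across samples, with independent per-sample Poisson sampling. Spike-in
#' expectations are proportional to concentration times length, so RPKM is
#' proportional to concentration. Sense reads are placed uniformly within
#' exons on the transcript strand; antisense, intronic, and intergenic
#' reads are placed on coding exons (opposite strand), introns, and
#' annotation-free gaps respectively.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional output directory; when given, writes `genome.fa`,
#'   `annotation.gff3`, `rrna.fa`, `spikein.tsv`, one `<sample>.sam` per
#'   sample, and the ledger (`ledger_*.tsv`, `ledger.json`).
#' @return A list: `genome`, `annotation`, `rrna`, `spikein_ref`,
#'   `alignments` (tibble across all samples), and `ledger` (list with
#'   `reads`, `counts`, `de`, `de_uv`, `shifts`, `clusters`, `motifs`).
#' @export
simulate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "nsr_fixture_spec"))
  withr::with_seed(spec$seed, simulate_fixture_impl(spec, dir))
}

simulate_fixture_impl <- function(spec, dir) {
  lay <- fixture_layout(spec)
  ann <- lay$annotation
  genome <- random_genome(spec$chrom_lengths, spec$gc)

  motifs <- NULL
  if (!is.null(spec$planted_motifs)) {
    pm <- plant_motifs(genome, ann, spec$planted_motifs,
                       spec$motif_pattern)
    genome <- pm$genome
    motifs <- pm$motifs
  }

  spike_ref <- spikein_ladder_ref(spec$n_spikein, spec$spike_length_range,
                                  spec$spike_dynamic_range)
  spike_gc <- 0.5  # "moderate GC content" of the commercial ladder
  spike_seqs <- random_genome(stats::setNames(spike_ref$length,
                                              spike_ref$id), spike_gc)
  spike_ann <- transcript_models(tibble::tibble(
    transcript_id = spike_ref$id, chrom = spike_ref$id, start = 0,
    end = spike_ref$length, strand = "+", biotype = "spike_in"))
  full_ann <- dplyr::bind_rows(ann, spike_ann)

  de <- resolve_planted_de(spec, ann, lay$cluster_members)
  de_uv <- if (is.null(spec$planted_de_uv)) NULL else spec$planted_de_uv

  # per-locus base weights and shared lognormal bias multipliers
  w <- rep(1, nrow(ann))
  names(w) <- ann$transcript_id
  w[ann$biotype == "mRNA"] <- 10^stats::rnorm(sum(ann$biotype == "mRNA"),
                                              0, 0.5)
  w[de$transcript_id] <- w[de$transcript_id] * spec$de_weight
  bias <- 10^stats::rnorm(nrow(ann), 0, spec$sigma)
  names(bias) <- ann$transcript_id
  spike_bias <- 10^stats::rnorm(nrow(spike_ref), 0, spec$sigma)

  fold_for <- function(de_tab, sample_role) {
    f <- rep(1, nrow(ann))
    names(f) <- ann$transcript_id
    if (sample_role == "b" && !is.null(de_tab) && nrow(de_tab) > 0) {
      mult <- ifelse(de_tab$direction == "repressed", de_tab$fold,
                     1 / de_tab$fold)
      f[de_tab$transcript_id] <- mult
    }
    f
  }

  sense_cats <- c("rRNA", "mRNA", "known_ncRNA")
  gen_sample <- function(sample, role, de_tab) {
    reads <- list()
    counts <- stats::setNames(rep(0, nrow(full_ann)),
                              full_ann$transcript_id)
    fold <- fold_for(de_tab, role)
    for (cat in sense_cats) {
      sel <- ann$biotype == cat
      wn <- w[sel] / sum(w[sel])
      expected <- spec$category_mix[[cat]] * spec$n_reads * wn *
        fold[sel] * bias[sel]
      if (spec$exact_category_counts) {
        n_cat <- round(spec$category_mix[[cat]] * spec$n_reads)
        cts <- as.numeric(stats::rmultinom(1, n_cat,
                                           expected / sum(expected)))
      } else {
        cts <- draw_total(expected, FALSE, spec$poisson)
      }
      names(cts) <- ann$transcript_id[sel]
      if (!is.null(spec$planted_counts)) {
        pc <- spec$planted_counts[spec$planted_counts$sample == sample, ]
        hit <- intersect(pc$transcript_id, names(cts))
        cts[hit] <- pc$count[match(hit, pc$transcript_id)]
      }
      counts[names(cts)] <- cts
      reads[[cat]] <- place_sense_reads(ann[sel, ], cts, spec$read_length,
                                        sample, cat, cat)
    }
    # spike-in reads: expectation proportional to concentration x length
    sp_exp <- spike_ref$concentration * spike_ref$length * spike_bias
    sp_exp <- spec$spike_read_fraction * spec$n_reads * sp_exp / sum(sp_exp)
    sp_cts <- draw_total(sp_exp, spec$exact_category_counts, spec$poisson)
    counts[spike_ref$id] <- sp_cts
    reads$spike <- place_sense_reads(spike_ann, sp_cts, spec$read_length,
                                     sample, "spike_in", "spk")

    reads$antisense <- place_background_reads(
      spec, ann, genome, sample, "antisense")
    reads$intronic <- place_background_reads(
      spec, ann, genome, sample, "intronic")
    reads$intergenic <- place_background_reads(
      spec, ann, genome, sample, "intergenic")

    list(reads = dplyr::bind_rows(reads),
         counts = tibble::tibble(transcript_id = names(counts),
                                 sample = sample,
                                 true_count = as.numeric(counts)))
  }

  pairs <- list(list(samples = spec$samples, de = de))
  if (!is.null(de_uv)) {
    pairs[[2]] <- list(samples = paste0(spec$samples, "_uv"), de = de_uv)
  }
  out_reads <- list(); out_counts <- list()
  for (p in pairs) {
    for (i in 1:2) {
      g <- gen_sample(p$samples[i], c("a", "b")[i], p$de)
      out_reads[[p$samples[i]]] <- g$reads
      out_counts[[p$samples[i]]] <- g$counts
    }
  }
  reads <- dplyr::bind_rows(out_reads)
  counts <- dplyr::bind_rows(out_counts)

  shifts <- NULL
  if (!is.null(de_uv)) {
    dir_of <- function(tab, ids) {
      d <- rep("unchanged", length(ids))
      d[match(tab$transcript_id, ids)] <- tab$direction
      d
    }
    ids <- ann$transcript_id
    d1 <- dir_of(de, ids); d2 <- dir_of(de_uv, ids)
    shifts <- tibble::tibble(transcript_id = ids, status_normal = d1,
                             status_uv = d2)[d1 != d2, ]
  }

  clusters <- NULL
  if (!is.null(spec$planted_clusters)) {
    clusters <- spec$planted_clusters
    clusters$members <- lay$cluster_members
  }

  ledger <- list(
    reads = reads[, c("read_id", "sample", "category", "transcript_id")],
    counts = counts, de = de, de_uv = de_uv, shifts = shifts,
    clusters = clusters, motifs = motifs)
  alignments <- reads[, c("read_id", "sample", "chrom", "start", "end",
                          "strand", "is_primary")]
  rrna <- ann[ann$biotype == "rRNA", ]
  rrna_seq <- tibble::tibble(
    id = rrna$transcript_id,
    sequence = extract_locus_sequence(rrna, genome))

  fx <- list(genome = dplyr::bind_rows(genome, spike_seqs),
             annotation = full_ann, rrna = rrna_seq,
             spikein_ref = spike_ref, alignments = alignments,
             ledger = ledger, spec = spec)
  if (!is.null(dir)) write_fixture(fx, dir)
  fx
}

extract_locus_sequence <- function(loci, genome) {
  seqs <- stats::setNames(genome$sequence, genome$id)
  s <- substring(seqs[loci$chrom], loci$start + 1, loci$end)
  ifelse(loci$strand == "-", revcomp(s), s)
}

# antisense reads sit on coding exons opposite the transcript strand;
# intronic reads inside mRNA introns; intergenic reads in annotation-free
# gaps padded by one read length
place_background_reads <- function(spec, ann, genome, sample, kind) {
  n <- draw_total(spec$category_mix[[kind]] * spec$n_reads,
                  spec$exact_category_counts, spec$poisson)
  if (n == 0) return(empty_reads())
  rl <- spec$read_length
  if (kind == "antisense") {
    m <- ann[ann$biotype == "mRNA", ]
    cts <- tabulate(sample.int(nrow(m), n, replace = TRUE), nrow(m))
    out <- place_sense_reads(m, cts, rl, sample, "antisense", "as")
    out$strand <- ifelse(out$strand == "+", "-", "+")
    out$transcript_id <- NA_character_
    return(out)
  }
  intervals <- if (kind == "intronic") {
    m <- ann[ann$biotype == "mRNA", ]
    purrr::map_dfr(seq_len(nrow(m)), function(i) {
      s <- m$exon_starts[[i]]; e <- m$exon_ends[[i]]
      if (length(s) < 2) return(NULL)
      tibble::tibble(chrom = m$chrom[i], start = e[-length(e)], end = s[-1])
    })
  } else {
    # intergenic: complement of annotated spans, padded by one read length
    purrr::map_dfr(names(spec$chrom_lengths), function(ch) {
      spans <- ann[ann$chrom == ch, c("start", "end")]
      spans <- spans[order(spans$start), ]
      tibble::tibble(chrom = ch,
                     start = c(0, spans$end + rl),
                     end = c(spans$start - rl, spec$chrom_lengths[[ch]]))
    })
  }
  intervals <- intervals[intervals$end - intervals$start >= rl, ]
  if (nrow(intervals) == 0) {
    stop("infeasible fixture spec: no ", kind, " interval can hold a read",
         call. = FALSE)
  }
  widths <- intervals$end - intervals$start - rl + 1
  idx <- sample.int(nrow(intervals), n, replace = TRUE, prob = widths)
  pos <- intervals$start[idx] + floor(stats::runif(n) * widths[idx])
  tag <- if (kind == "intronic") "in" else "ig"
  tibble::tibble(
    read_id = sprintf("%s_%s_%06d", sample, tag, seq_len(n)),
    sample = sample, chrom = intervals$chrom[idx], start = pos,
    end = pos + rl,
    strand = sample(c("+", "-"), n, replace = TRUE), is_primary = TRUE,
    category = kind, transcript_id = NA_character_)
}

write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fx$genome, file.path(dir, "genome.fa"))
  write_annotation_gff3(fx$annotation, file.path(dir, "annotation.gff3"))
  write_fasta(fx$rrna, file.path(dir, "rrna.fa"))
  write_spikein_ref(fx$spikein_ref, file.path(dir, "spikein.tsv"))
  for (s in unique(fx$alignments$sample)) {
    write_alignments_sam(fx$alignments[fx$alignments$sample == s, ],
                         file.path(dir, paste0(s, ".sam")),
                         genome = fx$genome)
  }
  write_tsv_report(fx$ledger$reads, file.path(dir, "ledger_reads.tsv"))
  write_tsv_report(fx$ledger$counts, file.path(dir, "ledger_counts.tsv"))
  write_tsv_report(fx$ledger$de, file.path(dir, "ledger_de.tsv"))
  meta <- fx$ledger[c("de", "shifts", "clusters", "motifs")]
  meta <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(meta, file.path(dir, "ledger.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate a spike-in ladder experiment
#'
#' A focused generator for ladder QC: expected read mass per species is
#' proportional to concentration times length (so RPKM is proportional to
#' concentration), modulated by a per-species lognormal bias multiplier
#' `10^N(0, sigma)` shared across samples, with per-sample Poisson
#' sampling. With `sigma = 0` and `poisson = FALSE` the counts equal the
#' continuous expectation and the reference correlation is exactly 1.
#'
#' @param n_species Species count (default 92).
#' @param length_range,dynamic_range Ladder geometry (defaults 250-2000 nt
#'   and 10^6).
#' @param depth Expected total spike-in reads per sample, also used as the
#'   library size (default 5e5).
#' @param sigma Per-species lognormal sd on log10 expected counts.
#' @param samples Sample names.
#' @param seed Seed.
#' @param poisson Poisson-sample per-species counts (default `TRUE`).
#' @return A list: `ref` (id, concentration, length), `counts` tibble
#'   (`transcript_id`, `sample`, `count`, with library sizes in the
#'   attribute), and `rpkm` (counts with an `rpkm` column).
#' @export
simulate_spikein_ladder <- function(n_species = 92,
                                    length_range = c(250, 2000),
                                    dynamic_range = 1e6, depth = 5e5,
                                    sigma = 0.2,
                                    samples = c("s1", "s2"), seed = 1,
                                    poisson = TRUE) {
  withr::with_seed(seed, {
    ref <- spikein_ladder_ref(n_species, length_range, dynamic_range)
    bias <- 10^stats::rnorm(n_species, 0, sigma)
    expected <- ref$concentration * ref$length * bias
    expected <- depth * expected / sum(expected)
    counts <- purrr::map_dfr(samples, function(s) {
      cts <- if (poisson) stats::rpois(n_species, expected) else expected
      tibble::tibble(transcript_id = ref$id, sample = s, count = cts)
    })
    attr(counts, "library_sizes") <- stats::setNames(
      rep(depth, length(samples)), samples)
    rpkm <- compute_rpkm(counts,
                         stats::setNames(ref$length, ref$id))
    list(ref = ref, counts = counts, rpkm = rpkm)
  })
}

#' Construct an rRNA reference with a known k-mer inventory
#'
#' Builds a reference whose distinct k-mer inventory is exactly the first
#' `target_removed` k-mers in lexicographic order, by joining them with
#' `N` separators (windows containing an ambiguity code never match, so
#' junctions contribute nothing). The inventory is verified against a
#' substring scan before the reference is returned. Useful for testing the
#' filter at a controlled scale.
#'
#' @param target_removed Number of k-mers the reference should contain
#'   (0 to `4^k`).
#' @param k K-mer length.
#' @return A tibble with `id` and `sequence` (zero rows when
#'   `target_removed` is 0).
#' @export
make_rrna_filter_case <- function(target_removed, k = 6) {
  if (target_removed < 0 || target_removed > 4^k) {
    stop("target_removed must be between 0 and 4^k = ", 4^k, call. = FALSE)
  }
  if (target_removed == 0) {
    return(tibble::tibble(id = character(), sequence = character()))
  }
  chosen <- enumerate_kmers(k)$hexamer[seq_len(target_removed)]
  seq <- paste(chosen, collapse = "N")
  got <- suppressWarnings(kmer_inventory(seq, k))
  if (!setequal(got, chosen)) {
    stop("internal error: constructed reference inventory mismatch",
         call. = FALSE)
  }
  tibble::tibble(id = "synthetic_rrna", sequence = seq)
}
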