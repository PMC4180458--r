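tiny_annotation <- function() {
  transcript_models(tibble::tibble(
    transcript_id = c("rr1", "m1", "n1"),
    chrom = "chr1",
    start = c(100, 100, 2000),
    end = c(300, 1000, 2200),
    strand = c("+", "+", "-"),
    biotype = c("rRNA", "mRNA", "known_ncRNA"),
    exon_starts = list(100, c(100, 700), 2000),
    exon_ends = list(300, c(400, 1000), 2200)))
}

aln_row <- function(id, start, end, strand, chrom = "chr1",
                    sample = "s1", primary = TRUE) {
  tibble::tibble(read_id = id, sample = sample, chrom = chrom,
                 start = start, end = end, strand = strand,
                 is_primary = primary)
}

test_that("classification priority and strand rules are respected", {
  ann <- tiny_annotation()
  aln <- dplyr::bind_rows(
    aln_row("rna_and_mrna", 150, 230, "+"),  # overlaps rRNA and mRNA exons
    aln_row("antisense", 150, 230, "-"),     # minus read in + coding exon*
    aln_row("mrna_sense", 750, 830, "+"),
    aln_row("intronic", 450, 530, "+"),      # inside the mRNA intron
    aln_row("intergenic", 1300, 1380, "+"),
    aln_row("nc_sense", 2050, 2130, "-"))
  # * also overlaps the rRNA exon, so priority puts it in rRNA first;
  #   check the pure antisense case on a window past the rRNA
  aln <- dplyr::bind_rows(aln, aln_row("antisense2", 750, 830, "-"))
  cls <- classify_alignments(aln, ann)
  got <- stats::setNames(as.character(cls$reads$category),
                         cls$reads$read_id)
  expect_equal(got[["rna_and_mrna"]], "rRNA")
  expect_equal(got[["antisense"]], "rRNA")      # priority over antisense
  expect_equal(got[["antisense2"]], "antisense")
  expect_equal(got[["mrna_sense"]], "mRNA")
  expect_equal(got[["intronic"]], "intronic")
  expect_equal(got[["intergenic"]], "intergenic")
  expect_equal(got[["nc_sense"]], "known_ncRNA")

  expect_warning(classify_alignments(aln_row("x", 0, 80, "+", chrom = "nope"),
                                     ann),
                 "absent")
  expect_error(classify_alignments(aln[0, ], ann), "no primary")
})

test_that("classification fractions sum to one and counts to read totals", {
  fx <- default_fixture()
  cls <- classify_alignments(fx$alignments, fx$annotation)
  sums <- tapply(cls$breakdown$fraction, cls$breakdown$sample, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(sum(cls$breakdown$n_reads),
               sum(fx$alignments$is_primary))
})

test_that("a category-exact fixture is classified to its planted fractions", {
  spec <- fixture_spec(seed = 23, n_reads = 1000,
                       exact_category_counts = TRUE,
                       spike_read_fraction = 0, planted_de = NULL,
                       planted_clusters = NULL)
  fx <- simulate_fixture(spec)
  one <- fx$alignments[fx$alignments$sample == "wildtype", ]
  cls <- classify_alignments(one, fx$annotation)
  b <- cls$breakdown
  fr <- stats::setNames(b$fraction, as.character(b$category))
  expect_equal(fr[["mRNA"]], 0.6)
  expect_equal(fr[["rRNA"]], 0.1)
  expect_equal(fr[["known_ncRNA"]], 0.05)
  expect_equal(fr[["antisense"]], 0.05)
  expect_equal(fr[["intronic"]], 0.1)
  expect_equal(fr[["intergenic"]], 0.1)
  # every single read is classified as the generator intended
  agree <- dplyr::inner_join(cls$reads, fx$ledger$reads,
                             by = c("read_id", "sample"))
  expect_equal(as.character(agree$category.x), agree$category.y)
})

test_that("read counting respects strandedness and multi-overlap", {
  ann <- tiny_annotation()
  hit <- aln_row("r1", 750, 830, "+")
  cts <- count_reads(hit, ann, "stranded")
  expect_equal(cts$count[cts$transcript_id == "m1"], 1L)
  expect_equal(sum(cts$count), 1L)

  miss <- aln_row("r1", 750, 830, "-")
  cts2 <- count_reads(miss, ann, "stranded")
  expect_equal(sum(cts2$count), 0L)
  cts3 <- count_reads(miss, ann, "unstranded")
  expect_equal(cts3$count[cts3$transcript_id == "m1"], 1L)

  # overlapping rRNA and mRNA exons increments both transcripts
  both <- aln_row("r1", 150, 230, "+")
  cts4 <- count_reads(both, ann, "stranded")
  expect_equal(sum(cts4$count), 2L)
  expect_equal(attr(cts4, "library_sizes"), c(s1 = 1))
})

test_that("RPKM follows the exact formula and inverts to counts", {
  one <- compute_rpkm(
    tibble::tibble(transcript_id = "t1", sample = "s1", count = 10),
    c(t1 = 500), c(s1 = 1e6))
  expect_identical(one$rpkm, 20)

  zero <- compute_rpkm(
    tibble::tibble(transcript_id = "t1", sample = "s1", count = 0),
    c(t1 = 500), c(s1 = 1e6))
  expect_identical(zero$rpkm, 0)

  # spreadsheet-style recomputation
  odd <- compute_rpkm(
    tibble::tibble(transcript_id = "t1", sample = "s1", count = 7),
    c(t1 = 1234), c(s1 = 3.3e6))
  expect_equal(odd$rpkm, 7 / (1234 / 1000) / (3.3e6 / 1e6))

  expect_error(compute_rpkm(one[, 1:3], c(t1 = 0), c(s1 = 1)), "t1")
  expect_error(compute_rpkm(one[, 1:3], c(t1 = 10), c(s1 = 0)), "s1")

  # inversion on the default fixture recovers integer counts exactly
  rpkm <- default_rpkm()
  fx <- default_fixture()
  len <- stats::setNames(fx$annotation$exonic_length,
                         fx$annotation$transcript_id)
  lib <- attr(rpkm, "library_sizes")
  inverted <- rpkm$rpkm * (len[rpkm$transcript_id] / 1000) *
    (lib[rpkm$sample] / 1e6)
  expect_equal(unname(inverted), as.numeric(rpkm$count))
})

test_that("RPKM is invariant to duplicating reads and doubling depth", {
  cts <- tibble::tibble(transcript_id = c("a", "b"), sample = "s1",
                        count = c(10L, 3L))
  r1 <- compute_rpkm(cts, c(a = 500, b = 800), c(s1 = 1e5))
  r2 <- compute_rpkm(dplyr::mutate(cts, count = count * 2L),
                     c(a = 500, b = 800), c(s1 = 2e5))
  expect_equal(r1$rpkm, r2$rpkm)
})

test_that("spike-in correlation satisfies its exactness contracts", {
  ref <- tibble::tibble(id = sprintf("s%02d", 1:10),
                        concentration = 10^seq(-1, 4, length.out = 10),
                        length = rep(c(400L, 1200L), 5))
  # observed = reference up to a positive scale factor -> r exactly 1
  rpkm <- tibble::tibble(transcript_id = ref$id, sample = "x",
                         count = NA, rpkm = 3.7 * ref$concentration)
  sc <- spikein_correlation(rpkm, ref, pseudocount = 0)
  expect_equal(tidy(sc)$r_reference, 1)

  # two identical samples -> pairwise r = 1
  rpkm2 <- dplyr::bind_rows(rpkm,
                            dplyr::mutate(rpkm, sample = "y"))
  sc2 <- spikein_correlation(rpkm2, ref, pseudocount = 0)
  expect_equal(unname(sc2$pairwise_spikein["x", "y"]), 1)

  # global scaling leaves the log-scale correlation untouched
  sc3 <- spikein_correlation(dplyr::mutate(rpkm, rpkm = rpkm * 1e3), ref,
                             pseudocount = 0)
  expect_equal(tidy(sc3)$r_reference, tidy(sc)$r_reference)

  expect_error(
    spikein_correlation(rpkm[1:2, ], ref[1:2, ], pseudocount = 0),
    "fewer than 3")
  flat <- dplyr::mutate(rpkm, rpkm = 5)
  expect_true(is.na(tidy(spikein_correlation(flat, ref))$r_reference))
})

test_that("a noisy ladder lands in the precomputed correlation band", {
  # band [0.93, 0.97] frozen from a 100-replicate simulation at sigma 0.2
  lad <- simulate_spikein_ladder(seed = 17)
  sc <- spikein_correlation(lad$rpkm, lad$ref)
  expect_true(all(tidy(sc)$r_reference > 0.93 &
                    tidy(sc)$r_reference < 0.97))
  expect_gte(tidy(sc)$n_detected[1], 60)
  expect_gt(min(sc$pairwise_spikein), 0.9)
})
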