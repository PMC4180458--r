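test_that("the p53-family element expands to exactly 256 concrete 10-mers", {
  expansion <- oracle_expand_iupac("RRRCWWGYYY")
  expect_equal(length(expansion), 2^3 * 2^2 * 2^3)
  expect_equal(anyDuplicated(expansion), 0)
  # membership test agrees with the package's IUPAC matcher on all of them
  expect_true(all(matches_iupac(expansion, "RRRCWWGYYY")))
})

test_that("worked single-base variants are accepted/rejected correctly", {
  expansion <- oracle_expand_iupac("RRRCWWGYYY")
  expect_true("AAACATGCTC" %in% expansion)
  expect_true(matches_iupac("AAACATGCTC", "RRRCWWGYYY"))
  expect_true("AAACATGCTT" %in% expansion)   # final C -> T still fits Y
  expect_true(matches_iupac("AAACATGCTT", "RRRCWWGYYY"))
  expect_false("CAACATGCTC" %in% expansion)  # first A -> C violates R
  expect_false(matches_iupac("CAACATGCTC", "RRRCWWGYYY"))
})

test_that("promoter windows are cut strand-aware around the TSS", {
  ann <- transcript_models(tibble::tibble(
    transcript_id = c("plus", "minus", "edge"),
    chrom = "chr1",
    start = c(10000, 8000, 100), end = c(10300, 10000, 400),
    strand = c("+", "-", "+"), biotype = "known_ncRNA"))
  withr::with_seed(2, genome <- c(chr1 = random_dna(15000)))
  w <- suppressWarnings(extract_promoters(ann, genome))
  w <- w[match(ann$transcript_id, w$transcript_id), ]
  expect_equal(w$start, c(8000, 9500, 0))
  expect_equal(w$end, c(10500, 12000, 600))
  expect_equal(w$tss_offset, c(2000, 2000, 100))
  expect_equal(w$clipped, c(FALSE, FALSE, TRUE))
  # the minus-strand window is the reverse complement of the genomic slice
  expect_equal(w$sequence[2],
               oracle_revcomp(substr(genome[["chr1"]], 9501, 12000)))
  # position 0 of every sequence is the most-upstream base; the plus
  # window is the genomic slice verbatim
  expect_equal(w$sequence[1], substr(genome[["chr1"]], 8001, 10500))

  expect_error(extract_promoters(
    transcript_models(tibble::tibble(
      transcript_id = "x", chrom = "chrZ", start = 5000, end = 5100,
      strand = "+", biotype = "mRNA")), genome), "chrZ")
})

test_that("motif scanning equals the exhaustive-expansion oracle", {
  expansion <- oracle_expand_iupac("RRRCWWGYYY")
  rc_expansion <- oracle_revcomp(expansion)
  withr::with_seed(29, {
    for (rep in 1:5) {
      win <- tibble::tibble(transcript_id = "w", sequence = random_dna(500),
                            tss_offset = 250)
      hits <- scan_motif(win, "RRRCWWGYYY", both_strands = TRUE)
      sense_pos <- oracle_scan_positions(win$sequence, expansion)
      anti_pos <- oracle_scan_positions(win$sequence, rc_expansion)
      expect_setequal(
        hits$tss_offset[hits$strand_relative == "sense"],
        sense_pos - 250)
      expect_setequal(
        hits$tss_offset[hits$strand_relative == "antisense"],
        anti_pos - 250)
      # every reported match satisfies the pattern on its strand
      expect_true(all(matches_iupac(hits$matched_sequence, "RRRCWWGYYY")))
    }
  })
})

test_that("degenerate positions reject homopolymer and ambiguous bases", {
  all_c <- tibble::tibble(transcript_id = "c", sequence = strrep("C", 60),
                          tss_offset = 0)
  expect_equal(nrow(scan_motif(all_c)), 0)
  # an N in the genome matches nothing even where the pattern is degenerate
  clean <- tibble::tibble(transcript_id = "n",
                          sequence = "GGAAACATGCTCGG", tss_offset = 0)
  expect_gt(nrow(scan_motif(clean)), 0)
  with_n <- dplyr::mutate(clean, sequence = "GGNAACATGCTCGG")
  expect_equal(nrow(scan_motif(with_n)), 0)
  expect_error(scan_motif(all_c, pattern = "RRRCXWGYYY"), "X")
})

test_that("strand symmetry mirrors hit positions", {
  withr::with_seed(37, {
    s <- random_dna(400)
  })
  L <- nchar(s); plen <- 10
  fwd <- scan_motif(tibble::tibble(transcript_id = "w", sequence = s,
                                   tss_offset = 0))
  rev <- scan_motif(tibble::tibble(transcript_id = "w",
                                   sequence = oracle_revcomp(s),
                                   tss_offset = 0))
  mirror <- function(p) sort(L - plen - p)
  expect_equal(sort(rev$tss_offset[rev$strand_relative == "sense"]),
               mirror(fwd$tss_offset[fwd$strand_relative == "antisense"]))
  expect_equal(sort(rev$tss_offset[rev$strand_relative == "antisense"]),
               mirror(fwd$tss_offset[fwd$strand_relative == "sense"]))
})

test_that("offsets of unclipped windows stay in the TSS-relative range", {
  ann <- transcript_models(tibble::tibble(
    transcript_id = sprintf("t%d", 1:4), chrom = "chr1",
    start = c(4000, 5000, 8000, 9000) + 1000,
    end = c(4200, 5200, 8200, 9200) + 1000,
    strand = c("+", "-", "+", "-"), biotype = "known_ncRNA"))
  withr::with_seed(41, genome <- c(chr1 = random_dna(14000)))
  w <- extract_promoters(ann, genome, upstream_len = 1000,
                         downstream_len = 300)
  expect_false(any(w$clipped))
  hits <- scan_motif(w)
  expect_true(all(hits$tss_offset >= -1000))
  expect_true(all(hits$tss_offset <= 300 - 10))
})

test_that("gene-set motif fractions count genes, not hits", {
  hits <- tibble::tibble(transcript_id = c("g1", "g1", "g3"))
  fr <- motif_fraction(c("g1", "g2", "g3", "g4"), hits)
  expect_equal(fr$n_with_hit, 2L)
  expect_equal(fr$fraction, 0.5)
  expect_equal(motif_fraction(c("a", "b"),
                              hits[0, , drop = FALSE])$fraction, 0)
  # the printed-ratio arithmetic
  expect_equal(round(81 / 195, 3), 0.415)
  expect_error(motif_fraction(character(0), hits), "empty")
})

test_that("planted promoter motifs are found plus only chance background", {
  planted <- tibble::tibble(transcript_id = sprintf("nc_%04d", 1:40),
                            offset = -1000)
  spec <- fixture_spec(seed = 53, n_ncrna = 100, n_reads = 1000,
                       planted_clusters = NULL, planted_de = NULL,
                       planted_motifs = planted)
  fx <- simulate_fixture(spec)
  nc <- fx$annotation[fx$annotation$biotype == "known_ncRNA", ]
  win <- extract_promoters(nc, fx$genome)
  hits <- scan_motif(win)
  fr <- motif_fraction(nc$transcript_id, hits)
  expect_gte(fr$n_with_hit, 40)
  # the excess over 40 is exactly the genes the brute-force oracle finds
  # hit by chance in the unplanted background
  expansion <- oracle_expand_iupac("RRRCWWGYYY")
  both <- c(expansion, oracle_revcomp(expansion))
  oracle_hit <- vapply(win$transcript_id, function(id) {
    s <- win$sequence[win$transcript_id == id]
    length(oracle_scan_positions(s, both)) > 0
  }, logical(1))
  expect_equal(fr$n_with_hit, sum(oracle_hit))
  expect_true(all(planted$transcript_id %in%
                    win$transcript_id[oracle_hit]))
  # planted instances sit at the planted offset
  planted_hits <- hits[hits$transcript_id %in% planted$transcript_id, ]
  expect_true(all(planted$transcript_id %in%
                    planted_hits$transcript_id[planted_hits$tss_offset ==
                                                 -1000]))
})
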