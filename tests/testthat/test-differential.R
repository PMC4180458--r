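rpkm_pair <- function(ids, a, b, sample_a = "wt", sample_b = "mut") {
  dplyr::bind_rows(
    tibble::tibble(transcript_id = ids, sample = sample_a, rpkm = a),
    tibble::tibble(transcript_id = ids, sample = sample_b, rpkm = b))
}

test_that("threshold calling applies the fold and expression gates", {
  calls <- call_differential(rpkm_pair("t1", 1.5, 4.0), "wt", "mut")
  expect_equal(calls$fold_change, (4.0 + 0.01) / (1.5 + 0.01))
  expect_true(calls$passes)
  expect_equal(calls$direction, "repressed")

  flat <- call_differential(rpkm_pair("t1", 5, 5), "wt", "mut")
  expect_false(flat$passes)
  expect_equal(flat$direction, "unchanged")

  # fold is ample but both samples sit under the RPKM gate
  low <- call_differential(rpkm_pair("t1", 0.5, 0.9), "wt", "mut",
                           fc_min = 1.5)
  expect_false(low$passes)

  expect_error(call_differential(rpkm_pair("t1", 1, 2), "wt", "nope"),
               "nope")
})

test_that("swapping the samples inverts folds and flips directions", {
  withr::with_seed(31, {
    tab <- rpkm_pair(sprintf("t%02d", 1:30), runif(30, 0, 20),
                     runif(30, 0, 20))
  })
  ab <- call_differential(tab, "wt", "mut")
  ba <- call_differential(tab, "mut", "wt")
  ba <- ba[match(ab$transcript_id, ba$transcript_id), ]
  expect_equal(ba$fold_change, 1 / ab$fold_change)
  expect_equal(ab$passes, ba$passes)
  flip <- c(repressed = "activated", activated = "repressed",
            unchanged = "unchanged")
  expect_equal(ba$direction, unname(flip[ab$direction]))
  # partition: every locus is in exactly one direction class
  expect_equal(sum(table(ab$direction)), nrow(ab))
})

test_that("planted two-condition signal is recovered with high fidelity", {
  fx <- default_fixture()
  rpkm <- default_rpkm()
  calls <- call_differential(rpkm, "wildtype", "mutant",
                             annotation = fx$annotation)
  nc <- calls[calls$biotype == "known_ncRNA", ]
  planted <- nc$transcript_id %in% fx$ledger$de$transcript_id
  expect_gte(mean(nc$passes[planted]), 0.95)   # sensitivity
  expect_lte(mean(nc$passes[!planted]), 0.05)  # false-positive rate
  hit <- dplyr::inner_join(tibble::as_tibble(nc[nc$passes, ]),
                           fx$ledger$de, by = "transcript_id")
  expect_true(all(hit$direction.x == hit$direction.y))
  # planted loci clear the expression gate by construction
  expect_true(all(pmax(nc$rpkm_a, nc$rpkm_b)[planted] > 2))
})

test_that("chromosomal enrichment uses the exact one-sided binomial tail", {
  calls <- tibble::tibble(
    transcript_id = sprintf("t%03d", 1:100),
    passes = TRUE, direction = "repressed",
    chrom = c(rep("chrX", 35), rep("chrI", 65)))
  universe <- tibble::tibble(
    transcript_id = sprintf("u%03d", 1:100),
    chrom = c(rep("chrX", 15), rep("chrI", 85)))
  enr <- chromosome_enrichment(calls, universe)
  x <- enr[enr$chrom == "chrX", ]
  expect_equal(x$fraction_observed, 0.35)
  expect_equal(x$p_value,
               stats::pbinom(34, 100, 0.15, lower.tail = FALSE))

  # observed equal to expectation: one-sided p is not small
  null <- dplyr::mutate(calls,
                        chrom = c(rep("chrX", 15), rep("chrI", 85)))
  expect_gte(chromosome_enrichment(null, universe)$p_value[2], 0.4)

  # degenerate universe all on one chromosome
  uni1 <- dplyr::mutate(universe, chrom = "chrX")
  one <- dplyr::mutate(calls, chrom = "chrX")
  enr1 <- chromosome_enrichment(one, uni1)
  expect_equal(enr1$fraction_observed, 1)
  expect_equal(enr1$p_value, 1)

  expect_error(chromosome_enrichment(dplyr::mutate(calls, passes = FALSE),
                                     universe), "no passing")
})

test_that("cluster chaining follows the gap rule and ignores row order", {
  mk <- function(starts, dirs = "repressed", chrom = "chr1") {
    tibble::tibble(transcript_id = sprintf("t%d", seq_along(starts)),
                   chrom = chrom, start = starts, end = starts + 200,
                   passes = TRUE, direction = dirs)
  }
  one <- find_clusters(mk(c(1000, 4000, 9000)), max_gap = 5000)
  expect_equal(nrow(one), 1)
  expect_equal(one$n_members, 3L)
  expect_equal(one$members[[1]], c("t1", "t2", "t3"))

  none <- find_clusters(mk(c(1000, 4000, 9000)), max_gap = 2000)
  expect_equal(nrow(none), 0)

  # interleaved directions never mix when homogeneity is required
  mixed <- mk(c(1000, 2000, 3000, 4000, 5000, 6000),
              dirs = rep(c("repressed", "activated"), 3))
  cl <- find_clusters(mixed, max_gap = 2500, min_size = 3)
  expect_true(all(!is.na(cl$direction)))
  cl2 <- find_clusters(mixed, max_gap = 2500, min_size = 3,
                       same_direction = FALSE)
  expect_equal(cl2$n_members, 6L)

  # order invariance
  withr::with_seed(19, {
    big <- mk(sort(sample.int(1e6, 40)),
              dirs = sample(c("repressed", "activated"), 40, TRUE))
  })
  a <- find_clusters(big)
  b <- find_clusters(big[sample.int(nrow(big)), ])
  expect_equal(a, b)
  # boundary members of adjacent clusters are > max_gap apart (starts of
  # the last member of one cluster and the first member of the next)
  if (nrow(a) > 1) {
    last_member_start <- a$end[-nrow(a)] - 200
    expect_true(all(a$start[-1] - last_member_start > 10000))
  }
})

test_that("planted genomic clusters are recovered exactly", {
  fx <- default_fixture()
  calls <- call_differential(default_rpkm(), "wildtype", "mutant",
                             annotation = fx$annotation)
  nc <- calls[calls$biotype == "known_ncRNA", ]
  found <- find_clusters(nc)  # defaults: 10 kb, >= 3, same direction
  truth <- fx$ledger$clusters
  expect_equal(nrow(found), nrow(truth))
  for (i in seq_len(nrow(truth))) {
    match_row <- found[found$chrom == truth$chrom[i], ]
    expect_equal(nrow(match_row), 1)
    expect_setequal(match_row$members[[1]], truth$members[[i]])
    expect_equal(match_row$direction, truth$direction[i])
  }
  # shuffled input gives the identical cluster table
  expect_equal(find_clusters(nc[sample.int(nrow(nc)), ]), found)
})

test_that("status shifts are detected over the shared universe", {
  calls_a <- tibble::tibble(transcript_id = c("a", "b", "c"),
                            direction = c("repressed", "unchanged",
                                          "activated"))
  calls_b <- tibble::tibble(transcript_id = c("a", "b", "c"),
                            direction = c("activated", "unchanged",
                                          "activated"))
  sh <- status_shift(calls_a, calls_b)
  expect_equal(sh$transcript_id, "a")
  expect_true(sh$repressed_to_activated)

  expect_error(status_shift(calls_a,
                            dplyr::mutate(calls_b,
                                          transcript_id = c("x", "y", "z"))),
               "share no transcripts")
})

test_that("planted condition-dependent shifts are recovered end to end", {
  base <- default_fixture()
  de <- base$ledger$de
  de_uv <- de
  flip_idx <- which(de_uv$direction == "repressed")[1:10]
  de_uv$direction[flip_idx] <- "activated"
  # noise-free counts so condition status is exactly the planted one
  spec <- fixture_spec(seed = 77, planted_de = de, planted_de_uv = de_uv,
                       sigma = 0, poisson = FALSE)
  fx <- simulate_fixture(spec)
  counts <- count_reads(fx$alignments, fx$annotation)
  rpkm <- compute_rpkm(counts, fx$annotation)
  normal <- call_differential(rpkm, "wildtype", "mutant")
  uv <- call_differential(rpkm, "wildtype_uv", "mutant_uv")
  shifts <- status_shift(normal, uv)
  truth <- fx$ledger$shifts
  expect_setequal(shifts$transcript_id, truth$transcript_id)
  expect_equal(sum(shifts$repressed_to_activated), 10)
})

test_that("the 2^-ddCt calculator matches hand-worked examples", {
  same <- ddct_fold_change(tibble::tibble(
    ct_target_sample = 21, ct_ref_sample = 19,
    ct_target_control = 23, ct_ref_control = 21))
  expect_equal(same$fold_change, 1)  # ddCt 0

  dbl <- ddct_fold_change(tibble::tibble(
    ct_target_sample = 20, ct_ref_sample = 20,
    ct_target_control = 21, ct_ref_control = 20))
  expect_equal(dbl$fold_change, 2)   # ddCt -1

  worked <- ddct_fold_change(tibble::tibble(
    ct_target_sample = 22, ct_ref_sample = 20,
    ct_target_control = 24, ct_ref_control = 20))
  expect_equal(worked$ddct, -2)
  expect_equal(worked$fold_change, 4)

  # replicate SEM reported on the ddCt scale
  reps <- ddct_fold_change(tibble::tibble(
    ct_target_sample = c(22, 22.3, 21.7), ct_ref_sample = 20,
    ct_target_control = 24, ct_ref_control = 20))
  dd <- c(-2, -1.7, -2.3)
  expect_equal(reps$ddct, mean(dd))
  expect_equal(reps$sem_ddct, stats::sd(dd) / sqrt(3))
  expect_equal(reps$fold_change, 2^(-mean(dd)))

  expect_error(ddct_fold_change(tibble::tibble(ct_target_sample = 20)),
               "ct_ref_sample")
})
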