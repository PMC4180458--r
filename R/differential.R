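#' Call differentially expressed loci between two samples
#'
#' Pure threshold calling as used for ncRNA profiling between wild type and
#' a *cep-1* deletion mutant: a locus passes when the larger of the two RPKM
#' values exceeds `rpkm_min` and the (pseudocounted) fold change is at least
#' `fc_min` in either direction. Direction is reported relative to the
#' regulator: higher expression in the mutant (`sample_b`) means the locus
#' is *repressed* by the factor, lower means *activated*.
#'
#' @param rpkm Tibble with `transcript_id`, `sample`, `rpkm`.
#' @param sample_a Reference (wild-type) sample id.
#' @param sample_b Comparison (mutant) sample id.
#' @param fc_min Minimum fold change (default 2).
#' @param rpkm_min Expression gate applied to the larger of the two values
#'   (default 1, i.e. RPKM > 1).
#' @param pseudocount Added to both RPKM values in the ratio so on/off loci
#'   stay finite (default 0.01).
#' @param annotation Optional [transcript_models()] tibble; when given,
#'   `chrom`, `start`, `end`, `strand`, `biotype` are joined onto the calls
#'   (needed for [find_clusters()] and [chromosome_enrichment()]).
#' @return A tibble of class `nsr_diff_calls`, one row per transcript:
#'   `transcript_id`, `rpkm_a`, `rpkm_b`, `fold_change`
#'   (`(rpkm_b + pseudocount) / (rpkm_a + pseudocount)`), `passes`,
#'   `direction` (`"repressed"`, `"activated"`, `"unchanged"`). Calling
#'   parameters are kept in attributes.
#' @examples
#' rp <- tibble::tibble(transcript_id = c("t1", "t1"),
#'                      sample = c("wt", "mut"), rpkm = c(1.5, 4))
#' call_differential(rp, "wt", "mut")
#' @export
call_differential <- function(rpkm, sample_a, sample_b, fc_min = 2,
                              rpkm_min = 1, pseudocount = 0.01,
                              annotation = NULL) {
  stopifnot(all(c("transcript_id", "sample", "rpkm") %in% names(rpkm)))
  for (s in c(sample_a, sample_b)) {
    if (!s %in% rpkm$sample) stop("sample not in table: ", s, call. = FALSE)
  }
  wide <- rpkm[rpkm$sample %in% c(sample_a, sample_b),
               c("transcript_id", "sample", "rpkm")] |>
    tidyr::pivot_wider(names_from = "sample", values_from = "rpkm")
  calls <- tibble::tibble(
    transcript_id = wide$transcript_id,
    rpkm_a = wide[[sample_a]],
    rpkm_b = wide[[sample_b]]
  ) |>
    dplyr::mutate(
      fold_change = (.data$rpkm_b + pseudocount) /
        (.data$rpkm_a + pseudocount),
      passes = pmax(.data$rpkm_a, .data$rpkm_b) > rpkm_min &
        (.data$fold_change >= fc_min | .data$fold_change <= 1 / fc_min),
      direction = dplyr::case_when(
        .data$passes & .data$fold_change > 1 ~ "repressed",
        .data$passes & .data$fold_change < 1 ~ "activated",
        TRUE ~ "unchanged"
      )
    )
  if (!is.null(annotation)) {
    calls <- dplyr::left_join(
      calls,
      annotation[, c("transcript_id", "chrom", "start", "end", "strand",
                     "biotype")],
      by = "transcript_id")
  }
  attr(calls, "params") <- list(sample_a = sample_a, sample_b = sample_b,
                                fc_min = fc_min, rpkm_min = rpkm_min,
                                pseudocount = pseudocount)
  class(calls) <- c("nsr_diff_calls", class(calls))
  calls
}

#' @export
print.nsr_diff_calls <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "# differential calls %s vs %s (fold >= %g, RPKM > %g): %d of %d pass (%d repressed, %d activated)\n",
    p$sample_a, p$sample_b, p$fc_min, p$rpkm_min, sum(x$passes), nrow(x),
    sum(x$direction == "repressed"), sum(x$direction == "activated")))
  NextMethod()
  invisible(x)
}

#' @rdname call_differential
#' @param x An `nsr_diff_calls` tibble.
#' @param ... Unused.
#' @exportS3Method
glance.nsr_diff_calls <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    n_loci = nrow(x), n_pass = sum(x$passes),
    n_repressed = sum(x$direction == "repressed"),
    n_activated = sum(x$direction == "activated"),
    fc_min = p$fc_min, rpkm_min = p$rpkm_min
  )
}

#' Chromosomal enrichment of differential loci
#'
#' For each chromosome, compares the fraction of passing loci located there
#' against the fraction expected from the annotation universe (all loci the
#' calling was run over, e.g. all annotated ncRNAs), with a one-sided exact
#' binomial test for enrichment.
#'
#' @param calls An [call_differential()] result carrying `chrom` (pass
#'   `annotation =` when calling), or any tibble with `passes`/`chrom`.
#' @param universe Tibble with `transcript_id` and `chrom` covering the
#'   comparison population, or a named vector of per-chromosome locus
#'   counts.
#' @param correct `"none"` (default) or `"bonferroni"`.
#' @return A tibble: `chrom`, `n_observed`, `fraction_observed`,
#'   `fraction_universe`, `p_value` (one-sided, greater).
#' @export
chromosome_enrichment <- function(calls, universe,
                                  correct = c("none", "bonferroni")) {
  correct <- match.arg(correct)
  if (!"chrom" %in% names(calls)) {
    stop("calls carry no `chrom`; call_differential() with `annotation =`",
         call. = FALSE)
  }
  passing <- calls[calls$passes, , drop = FALSE]
  if (nrow(passing) == 0) stop("no passing calls", call. = FALSE)
  if (is.data.frame(universe)) {
    uni <- table(universe$chrom)
  } else {
    uni <- universe
  }
  uni_frac <- uni / sum(uni)
  obs <- table(factor(passing$chrom, levels = names(uni_frac)))
  n <- nrow(passing)
  out <- tibble::tibble(
    chrom = names(uni_frac),
    n_observed = as.integer(obs),
    fraction_observed = as.numeric(obs) / n,
    fraction_universe = as.numeric(uni_frac),
    p_value = purrr::map2_dbl(as.integer(obs), as.numeric(uni_frac),
      ~ stats::binom.test(.x, n, .y, alternative = "greater")$p.value)
  )
  if (correct == "bonferroni") {
    out$p_value <- pmin(1, out$p_value * nrow(out))
  }
  out
}

#' Find genomic clusters of differential loci
#'
#' Single-linkage chaining along each chromosome: passing loci whose
#' successive start coordinates are within `max_gap` bases are merged into a
#' chain, and chains with at least `min_size` members become clusters. With
#' `same_direction = TRUE` (default) only loci sharing the call direction
#' chain together. The result does not depend on the input row order.
#'
#' @param calls An [call_differential()] result with `chrom` and `start`
#'   columns (pass `annotation =` when calling).
#' @param max_gap Maximum distance in bases between successive member
#'   starts (default 10000).
#' @param min_size Minimum number of members (default 3).
#' @param same_direction Require direction homogeneity (default `TRUE`).
#' @return A tibble: `cluster_id`, `chrom`, `start`, `end`, `n_members`,
#'   `direction` (`NA` when mixed), `members` (list-column of transcript
#'   ids sorted by start).
#' @export
find_clusters <- function(calls, max_gap = 10000, min_size = 3,
                          same_direction = TRUE) {
  if (!all(c("chrom", "start") %in% names(calls))) {
    stop("calls carry no coordinates; call_differential() with `annotation =`",
         call. = FALSE)
  }
  passing <- calls[calls$passes, , drop = FALSE]
  passing <- passing[order(passing$chrom, passing$start,
                           passing$transcript_id), , drop = FALSE]
  if (nrow(passing) == 0) {
    return(tibble::tibble(cluster_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_members = integer(), direction = character(),
                          members = list()))
  }
  key <- if (same_direction) paste(passing$chrom, passing$direction)
         else passing$chrom
  groups <- split(seq_len(nrow(passing)), key)
  chains <- purrr::map(groups, function(idx) {
    st <- passing$start[idx]
    new_chain <- c(TRUE, diff(st) > max_gap)
    split(idx, cumsum(new_chain))
  })
  chains <- purrr::flatten(chains)
  chains <- chains[purrr::map_int(chains, length) >= min_size]
  if (length(chains) == 0) {
    return(tibble::tibble(cluster_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_members = integer(), direction = character(),
                          members = list()))
  }
  out <- purrr::map_dfr(chains, function(idx) {
    tibble::tibble(
      chrom = passing$chrom[idx[1]],
      start = min(passing$start[idx]),
      end = max(if ("end" %in% names(passing)) passing$end[idx]
                else passing$start[idx]),
      n_members = length(idx),
      direction = if (length(unique(passing$direction[idx])) == 1)
        passing$direction[idx[1]] else NA_character_,
      members = list(passing$transcript_id[idx])
    )
  })
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$cluster_id <- sprintf("cluster_%03d", seq_len(nrow(out)))
  out[, c("cluster_id", "chrom", "start", "end", "n_members", "direction",
          "members")]
}

#' Track condition-dependent status shifts
#'
#' Joins two call sets over their shared transcript universe and records
#' every locus whose direction differs between conditions (e.g. repressed
#' under normal growth but activated after UV irradiation).
#'
#' @param calls_normal,calls_uv Two [call_differential()] results over the
#'   same transcript universe.
#' @return A tibble: `transcript_id`, `status_normal`, `status_uv`, and
#'   the convenience flag `repressed_to_activated`.
#' @export
status_shift <- function(calls_normal, calls_uv) {
  shared <- intersect(calls_normal$transcript_id, calls_uv$transcript_id)
  if (length(shared) == 0) {
    stop("the two call sets share no transcripts", call. = FALSE)
  }
  a <- calls_normal[match(shared, calls_normal$transcript_id), ]
  b <- calls_uv[match(shared, calls_uv$transcript_id), ]
  diffed <- a$direction != b$direction
  tibble::tibble(
    transcript_id = shared[diffed],
    status_normal = a$direction[diffed],
    status_uv = b$direction[diffed],
    repressed_to_activated = a$direction[diffed] == "repressed" &
      b$direction[diffed] == "activated"
  )
}

#' Relative expression by the 2^-ddCt method
#'
#' qPCR validation calculator. For each replicate,
#' `dCt_sample = Ct_target_sample - Ct_ref_sample` and likewise for the
#' control condition; `ddCt = dCt_sample - dCt_control` and the fold change
#' is `2^-mean(ddCt)`. Uncertainty is reported as the SEM of ddCt across
#' replicates (on the Ct scale, where it is symmetric).
#'
#' @param ct A data frame with one row per replicate and columns
#'   `ct_target_sample`, `ct_ref_sample`, `ct_target_control`,
#'   `ct_ref_control` (positive Ct values).
#' @return A one-row tibble: `n_replicates`, `ddct` (mean), `sem_ddct`,
#'   `fold_change`.
#' @examples
#' ddct_fold_change(tibble::tibble(
#'   ct_target_sample = 22, ct_ref_sample = 20,
#'   ct_target_control = 24, ct_ref_control = 20)) # fold 4
#' @export
ddct_fold_change <- function(ct) {
  need <- c("ct_target_sample", "ct_ref_sample", "ct_target_control",
            "ct_ref_control")
  miss <- setdiff(need, names(ct))
  if (length(miss)) {
    stop("missing Ct column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  vals <- unlist(ct[need])
  if (anyNA(vals) || any(vals <= 0)) {
    stop("Ct values must be positive and complete", call. = FALSE)
  }
  ddct_reps <- (ct$ct_target_sample - ct$ct_ref_sample) -
    (ct$ct_target_control - ct$ct_ref_control)
  n <- length(ddct_reps)
  tibble::tibble(
    n_replicates = n,
    ddct = mean(ddct_reps),
    sem_ddct = if (n > 1) stats::sd(ddct_reps) / sqrt(n) else NA_real_,
    fold_change = 2^(-mean(ddct_reps))
  )
}
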