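#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

aln_granges <- function(aln) {
  GenomicRanges::GRanges(aln$chrom,
                         IRanges::IRanges(aln$start + 1, aln$end),
                         strand = aln$strand)
}

exon_granges <- function(annotation) {
  ex <- tidyr::unnest(
    annotation[, c("transcript_id", "chrom", "strand", "biotype",
                   "exon_starts", "exon_ends")],
    cols = c("exon_starts", "exon_ends"))
  GenomicRanges::GRanges(ex$chrom,
                         IRanges::IRanges(ex$exon_starts + 1, ex$exon_ends),
                         strand = ex$strand,
                         transcript_id = ex$transcript_id,
                         biotype = ex$biotype)
}

overlaps_any <- function(reads_gr, subject_gr, same_strand = NA,
                         min_overlap = 1) {
  if (length(subject_gr) == 0) return(rep(FALSE, length(reads_gr)))
  # seqlevel mismatches are expected (reads on unannotated chromosomes get
  # their own package-level warning); silence the seqinfo merge chatter
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(reads_gr, subject_gr,
                                minoverlap = min_overlap,
                                ignore.strand = TRUE))
  if (!is.na(same_strand)) {
    rs <- as.character(GenomicRanges::strand(reads_gr))[S4Vectors::queryHits(hits)]
    ss <- as.character(GenomicRanges::strand(subject_gr))[S4Vectors::subjectHits(hits)]
    keep <- if (same_strand) rs == ss else rs != ss
    hits <- hits[keep]
  }
  out <- rep(FALSE, length(reads_gr))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Classify read alignments into genomic categories
#'
#' Assigns each primary alignment exactly one category by fixed priority:
#' `rRNA` > `spike_in` > sense-exonic `mRNA` > sense-exonic `known_ncRNA` >
#' `antisense` (of coding exons) > `intronic` > `intergenic`. "Sense" means
#' the read strand equals the transcript strand; rRNA and spike-in loci
#' capture reads on either strand. A read counts for a category when its
#' span overlaps the relevant feature by at least `min_overlap` bases.
#' Reads on chromosomes absent from the annotation are classified
#' `intergenic` with a warning.
#'
#' @param alignments Alignment tibble (see [read_alignments_sam()]); only
#'   rows with `is_primary` are classified.
#' @param annotation A [transcript_models()] tibble.
#' @param min_overlap Minimum overlap in bases (default 1).
#' @return An object of class `nsr_classification`. `tidy()` gives the
#'   per-category counts and fractions (fractions sum to 1 over classified
#'   reads); `$reads` holds the per-read assignment.
#' @export
classify_alignments <- function(alignments, annotation, min_overlap = 1) {
  aln <- alignments[alignments$is_primary, , drop = FALSE]
  if (nrow(aln) == 0) stop("no primary alignments to classify", call. = FALSE)
  known_chroms <- unique(annotation$chrom)
  off <- !(aln$chrom %in% known_chroms)
  if (any(off)) {
    warning(sum(off), " read(s) on chromosomes absent from the annotation; ",
            "classified intergenic", call. = FALSE)
  }
  reads_gr <- aln_granges(aln)
  ex <- exon_granges(annotation)
  span_gr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start + 1, annotation$end),
    strand = annotation$strand)

  pick <- function(bt) ex[ex$biotype == bt]
  cat <- rep(NA_character_, nrow(aln))
  assign_cat <- function(cat, label, hit) {
    cat[is.na(cat) & hit] <- label
    cat
  }
  cat <- assign_cat(cat, "rRNA",
                    overlaps_any(reads_gr, pick("rRNA"), NA, min_overlap))
  cat <- assign_cat(cat, "spike_in",
                    overlaps_any(reads_gr, pick("spike_in"), NA, min_overlap))
  cat <- assign_cat(cat, "mRNA",
                    overlaps_any(reads_gr, pick("mRNA"), TRUE, min_overlap))
  cat <- assign_cat(cat, "known_ncRNA",
                    overlaps_any(reads_gr, pick("known_ncRNA"), TRUE,
                                 min_overlap))
  cat <- assign_cat(cat, "antisense",
                    overlaps_any(reads_gr, pick("mRNA"), FALSE, min_overlap))
  cat <- assign_cat(cat, "intronic",
                    overlaps_any(reads_gr, span_gr, NA, min_overlap))
  cat[is.na(cat)] <- "intergenic"

  levels <- c("rRNA", "spike_in", "mRNA", "known_ncRNA", "antisense",
              "intronic", "intergenic")
  reads <- tibble::tibble(read_id = aln$read_id, sample = aln$sample,
                          category = factor(cat, levels = levels))
  breakdown <- reads |>
    dplyr::count(.data$sample, .data$category, .drop = FALSE,
                 name = "n_reads") |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(fraction = .data$n_reads / sum(.data$n_reads)) |>
    dplyr::ungroup()
  structure(list(reads = reads, breakdown = breakdown,
                 n_classified = nrow(reads)),
            class = "nsr_classification")
}

#' @export
print.nsr_classification <- function(x, ...) {
  cat(sprintf("# genomic read classification: %d primary reads\n",
              x$n_classified))
  print(x$breakdown, ...)
  invisible(x)
}

#' @rdname classify_alignments
#' @param x An `nsr_classification` object.
#' @param ... Unused.
#' @exportS3Method
tidy.nsr_classification <- function(x, ...) x$breakdown

#' @rdname classify_alignments
#' @exportS3Method
glance.nsr_classification <- function(x, ...) {
  tibble::tibble(n_reads = x$n_classified,
                 n_samples = length(unique(x$reads$sample)))
}

#' Count reads per transcript
#'
#' A read increments a transcript when its span overlaps the transcript's
#' exons (on the same strand when `strandedness = "stranded"`). A read
#' overlapping several transcripts increments each of them (no fractional
#' assignment). Only primary alignments are counted; the per-sample library
#' size is the number of primary alignments, rRNA and spike-in included.
#'
#' @param alignments Alignment tibble.
#' @param annotation A [transcript_models()] tibble.
#' @param strandedness `"stranded"` (default, sense-only) or `"unstranded"`.
#' @param min_overlap Minimum overlap in bases (default 1).
#' @return A tibble `transcript_id` x `sample` with a `count` column
#'   (complete grid, zeros included), carrying the per-sample library sizes
#'   in the `library_sizes` attribute.
#' @export
count_reads <- function(alignments, annotation,
                        strandedness = c("stranded", "unstranded"),
                        min_overlap = 1) {
  strandedness <- match.arg(strandedness)
  aln <- alignments[alignments$is_primary, , drop = FALSE]
  samples <- unique(alignments$sample)
  lib <- table(factor(aln$sample, levels = samples))
  reads_gr <- aln_granges(aln)
  ex <- exon_granges(annotation)
  hits <- GenomicRanges::findOverlaps(reads_gr, ex,
                                      minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (strandedness == "stranded") {
    keep <- aln$strand[qh] ==
      as.character(GenomicRanges::strand(ex))[sh]
    qh <- qh[keep]; sh <- sh[keep]
  }
  # a read hitting several exons of one transcript still counts once
  pairs <- unique(data.frame(read = qh, sample = aln$sample[qh],
                             transcript_id = ex$transcript_id[sh]))
  counts <- tidyr::expand_grid(transcript_id = annotation$transcript_id,
                               sample = samples) |>
    dplyr::left_join(
      dplyr::count(pairs, .data$transcript_id, .data$sample, name = "count"),
      by = c("transcript_id", "sample")) |>
    dplyr::mutate(count = dplyr::coalesce(as.integer(.data$count), 0L))
  attr(counts, "library_sizes") <- stats::setNames(as.numeric(lib), samples)
  counts
}

#' Compute RPKM from counts
#'
#' Reads per kilobase of exon model per million mapped reads:
#' `count / (exonic_length / 1000) / (library_size / 1e6)`.
#'
#' @param counts Tibble with `transcript_id`, `sample`, `count` (e.g. from
#'   [count_reads()]).
#' @param lengths Exonic lengths: a [transcript_models()] tibble, a data
#'   frame with `transcript_id` and `exonic_length`, or a named numeric
#'   vector.
#' @param library_sizes Named numeric vector or data frame
#'   (`sample`, `library_size`); defaults to the `library_sizes` attribute
#'   of `counts`.
#' @return `counts` with an added `rpkm` column.
#' @examples
#' compute_rpkm(
#'   tibble::tibble(transcript_id = "t1", sample = "s1", count = 10),
#'   c(t1 = 500), c(s1 = 1e6))$rpkm # 20
#' @export
compute_rpkm <- function(counts, lengths, library_sizes = NULL) {
  stopifnot(all(c("transcript_id", "sample", "count") %in% names(counts)))
  if (is.data.frame(lengths)) {
    lcol <- if ("exonic_length" %in% names(lengths)) "exonic_length"
            else "length"
    lengths <- stats::setNames(lengths[[lcol]], lengths$transcript_id)
  }
  if (is.null(library_sizes)) library_sizes <- attr(counts, "library_sizes")
  if (is.data.frame(library_sizes)) {
    library_sizes <- stats::setNames(library_sizes$library_size,
                                     library_sizes$sample)
  }
  if (is.null(library_sizes)) {
    stop("`library_sizes` not supplied and not carried by `counts`",
         call. = FALSE)
  }
  len <- lengths[counts$transcript_id]
  if (any(is.na(len)) || any(len <= 0)) {
    bad <- unique(counts$transcript_id[is.na(len) | len <= 0])
    stop("missing or non-positive exonic length for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  lib <- library_sizes[counts$sample]
  if (any(is.na(lib)) || any(lib <= 0)) {
    bad <- unique(counts$sample[is.na(lib) | lib <= 0])
    stop("missing or non-positive library size for sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::mutate(counts,
                       rpkm = .data$count / (unname(len) / 1000) /
                         (unname(lib) / 1e6))
  attr(out, "library_sizes") <- library_sizes
  out
}

#' Spike-in correlation report
#'
#' Quantifies priming/amplification bias using an external ladder of known
#' concentrations: per sample, the Pearson correlation between observed
#' spike-in RPKM and the reference concentration (log10 by default, since a
#' million-fold ladder makes linear Pearson degenerate); plus pairwise
#' sample-vs-sample correlations over spike-in RPKM and over all
#' transcripts (technical-replicate agreement).
#'
#' @param rpkm Tibble with `transcript_id`, `sample`, `rpkm` (e.g. from
#'   [compute_rpkm()]).
#' @param spikein_ref Tibble with `id`, `concentration`, `length` (see
#'   [read_spikein_ref()]).
#' @param scale `"log10"` (default) or `"linear"`.
#' @param pseudocount Added to RPKM before the log transform (default 0.01;
#'   use 0 when all values are known positive and exact affine invariance is
#'   wanted).
#' @return An object of class `nsr_spikein_cor`: `tidy()` gives the
#'   per-sample reference correlations with detected-species counts;
#'   `$pairwise_spikein` and `$pairwise_all` are sample correlation
#'   matrices.
#' @export
spikein_correlation <- function(rpkm, spikein_ref,
                                scale = c("log10", "linear"),
                                pseudocount = 0.01) {
  scale <- match.arg(scale)
  stopifnot(all(c("transcript_id", "sample", "rpkm") %in% names(rpkm)))
  trans <- function(x) if (scale == "log10") log10(x + pseudocount) else x
  transc <- function(x) if (scale == "log10") log10(x) else x

  sp <- dplyr::inner_join(rpkm, spikein_ref,
                          by = c(transcript_id = "id"))
  samples <- unique(rpkm$sample)
  per <- purrr::map_dfr(samples, function(s) {
    d <- sp[sp$sample == s, , drop = FALSE]
    if (nrow(d) < 3) {
      stop("fewer than 3 spike-in species quantified in sample ", s,
           call. = FALSE)
    }
    x <- trans(d$rpkm); y <- transc(d$concentration)
    keep <- is.finite(x) & is.finite(y)  # pseudocount 0 logs zeros to -Inf
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3) {
      stop("fewer than 3 finite spike-in values in sample ", s,
           call. = FALSE)
    }
    r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
         else stats::cor(x, y)
    tibble::tibble(sample = s, n_species = nrow(d),
                   n_detected = sum(d$rpkm > 0), r_reference = r)
  })

  pair_mat <- function(df) {
    wide <- tidyr::pivot_wider(df[, c("transcript_id", "sample", "rpkm")],
                               names_from = "sample", values_from = "rpkm")
    m <- trans(as.matrix(wide[, -1, drop = FALSE]))
    if (ncol(m) < 2) return(NULL)
    m[!is.finite(m)] <- NA
    stats::cor(m, use = "pairwise.complete.obs")
  }
  structure(list(per_sample = per,
                 pairwise_spikein = pair_mat(sp),
                 pairwise_all = pair_mat(rpkm),
                 spike_data = sp,
                 scale = scale, pseudocount = pseudocount),
            class = "nsr_spikein_cor")
}

#' @export
print.nsr_spikein_cor <- function(x, ...) {
  cat(sprintf("# spike-in correlation report (%s scale)\n", x$scale))
  print(x$per_sample, ...)
  if (!is.null(x$pairwise_spikein)) {
    cat("# pairwise sample correlation over spike-ins:\n")
    print(round(x$pairwise_spikein, 3))
  }
  invisible(x)
}

#' @rdname spikein_correlation
#' @param x An `nsr_spikein_cor` object.
#' @param ... Unused.
#' @exportS3Method
tidy.nsr_spikein_cor <- function(x, ...) x$per_sample

#' @rdname spikein_correlation
#' @exportS3Method
glance.nsr_spikein_cor <- function(x, ...) {
  off_diag <- function(m) if (is.null(m)) NA_real_
                          else m[upper.tri(m)]
  tibble::tibble(
    n_samples = nrow(x$per_sample),
    min_r_reference = min(x$per_sample$r_reference, na.rm = TRUE),
    max_r_reference = max(x$per_sample$r_reference, na.rm = TRUE),
    min_r_pairwise = suppressWarnings(min(off_diag(x$pairwise_spikein))),
    scale = x$scale
  )
}
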