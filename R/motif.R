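iupac_expand <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

check_iupac_pattern <- function(pattern) {
  letters <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(letters, names(iupac_expand))
  if (length(bad)) {
    stop("invalid IUPAC letter(s) in pattern: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  paste(letters, collapse = "")
}

#' Extract strand-aware promoter windows
#'
#' Cuts the genomic window spanning `upstream_len` bases upstream of the
#' TSS through `downstream_len` bases downstream (TSS included in the
#' downstream part), in transcription orientation: minus-strand windows are
#' reverse-complemented so position 0 of the returned sequence is always
#' the window's most-upstream base. Windows are clipped at chromosome ends
#' (with a warning) and the TSS position within the oriented sequence is
#' recorded so hit offsets stay TSS-anchored.
#'
#' @param annotation A [transcript_models()] tibble (uses `tss`, the span
#'   start on `+` and `end - 1` on `-`; for multi-isoform genes supply the
#'   most-upstream isoform).
#' @param genome Named character vector, `id`/`sequence` tibble, or FASTA
#'   path.
#' @param upstream_len,downstream_len Window extents in bases (defaults
#'   2000 and 500).
#' @return A tibble: `transcript_id`, `chrom`, `strand`, `start`, `end`
#'   (genomic, 0-based half-open), `sequence` (oriented), `tss_offset`
#'   (0-based position of the TSS within `sequence`), `clipped`.
#' @export
extract_promoters <- function(annotation, genome, upstream_len = 2000,
                              downstream_len = 500) {
  if (is.character(genome) && length(genome) == 1 &&
      is.null(names(genome)) && file.exists(genome)) {
    genome <- read_rna_fasta(genome)
  }
  if (is.character(genome)) {
    genome <- tibble::tibble(id = names(genome), sequence = unname(genome))
  }
  seqs <- stats::setNames(genome$sequence, genome$id)
  missing_chr <- setdiff(unique(annotation$chrom), names(seqs))
  if (length(missing_chr)) {
    stop("chromosome(s) missing from genome: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  }
  out <- purrr::map_dfr(seq_len(nrow(annotation)), function(i) {
    tss <- annotation$tss[i]
    chrom <- annotation$chrom[i]
    strand <- annotation$strand[i]
    chrom_len <- nchar(seqs[[chrom]])
    if (strand == "+") {
      gstart <- tss - upstream_len
      gend <- tss + downstream_len
    } else {
      gstart <- tss - downstream_len + 1
      gend <- tss + upstream_len + 1
    }
    cstart <- max(0, gstart)
    cend <- min(chrom_len, gend)
    clipped <- cstart != gstart || cend != gend
    s <- substring(seqs[[chrom]], cstart + 1, cend)
    if (strand == "-") s <- revcomp(s)
    # upstream bases surviving the clip = distance from the window's
    # upstream edge to the TSS in oriented coordinates
    tss_offset <- if (strand == "+") tss - cstart else cend - 1 - tss
    tibble::tibble(transcript_id = annotation$transcript_id[i],
                   chrom = chrom, strand = strand,
                   start = cstart, end = cend, sequence = s,
                   tss_offset = tss_offset, clipped = clipped)
  })
  if (any(out$clipped)) {
    warning(sum(out$clipped), " promoter window(s) clipped at chromosome ",
            "boundaries", call. = FALSE)
  }
  attr(out, "upstream_len") <- upstream_len
  attr(out, "downstream_len") <- downstream_len
  out
}

#' Scan promoter windows for a degenerate IUPAC motif
#'
#' Reports every position whose substring satisfies the pattern under IUPAC
#' expansion; with `both_strands = TRUE` (default) the reverse complement
#' of the pattern is scanned too, since p53-family response elements are
#' functional on either strand. Overlapping hits are all reported.
#' Ambiguity codes in the *genome* (e.g. N) never match: a degenerate
#' pattern position only accepts concrete bases.
#'
#' @param windows Output of [extract_promoters()], or any tibble with
#'   `transcript_id`, `sequence`, and `tss_offset` columns.
#' @param pattern IUPAC motif (default the p53/CEP-1 response element
#'   `"RRRCWWGYYY"`).
#' @param both_strands Scan the antisense orientation as well (default
#'   `TRUE`).
#' @return A tibble of hits: `transcript_id`, `pattern`,
#'   `matched_sequence` (the concrete sequence satisfying the pattern on
#'   the reported strand), `strand_relative` (`"sense"`/`"antisense"` of
#'   promoter orientation), `tss_offset` (signed; negative upstream of the
#'   TSS; anchored at the match's most-upstream base).
#' @examples
#' w <- tibble::tibble(transcript_id = "t1",
#'                     sequence = "GGAAACATGCTCGG", tss_offset = 5)
#' scan_motif(w)
#' @export
scan_motif <- function(windows, pattern = "RRRCWWGYYY",
                       both_strands = TRUE) {
  pattern <- check_iupac_pattern(pattern)
  plen <- nchar(pattern)
  stopifnot(all(c("transcript_id", "sequence", "tss_offset")
                %in% names(windows)))

  scan_one <- function(seq, pat) {
    # fixed = "subject": degeneracy honored in the pattern only, so an N
    # in the genomic sequence matches nothing
    m <- Biostrings::matchPattern(pat, Biostrings::DNAString(seq),
                                  fixed = "subject")
    Biostrings::start(m) - 1L
  }
  hits <- purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    s <- toupper(windows$sequence[i])
    if (nchar(s) < plen) return(NULL)
    res <- list()
    pos <- scan_one(s, pattern)
    if (length(pos)) {
      res$sense <- tibble::tibble(
        transcript_id = windows$transcript_id[i], pattern = pattern,
        matched_sequence = substring(s, pos + 1, pos + plen),
        strand_relative = "sense",
        tss_offset = pos - windows$tss_offset[i])
    }
    if (both_strands) {
      pos <- scan_one(s, revcomp(pattern))
      if (length(pos)) {
        res$antisense <- tibble::tibble(
          transcript_id = windows$transcript_id[i], pattern = pattern,
          matched_sequence = revcomp(substring(s, pos + 1, pos + plen)),
          strand_relative = "antisense",
          tss_offset = pos - windows$tss_offset[i])
      }
    }
    dplyr::bind_rows(res)
  })
  if (nrow(hits) == 0) {
    hits <- tibble::tibble(transcript_id = character(),
                           pattern = character(),
                           matched_sequence = character(),
                           strand_relative = character(),
                           tss_offset = integer())
  }
  hits
}

#' Does a concrete sequence satisfy an IUPAC pattern?
#'
#' @param sequence Character vector of concrete DNA strings.
#' @param pattern A single IUPAC pattern of the same length.
#' @return Logical vector.
#' @examples
#' matches_iupac(c("AAACATGCTC", "CAACATGCTC"), "RRRCWWGYYY")
#' @export
matches_iupac <- function(sequence, pattern) {
  pattern <- check_iupac_pattern(pattern)
  pletters <- strsplit(pattern, "")[[1]]
  vapply(toupper(sequence), function(s) {
    if (nchar(s) != length(pletters)) return(FALSE)
    sl <- strsplit(s, "")[[1]]
    all(purrr::map2_lgl(sl, pletters, ~ .x %in% iupac_expand[[.y]]))
  }, logical(1), USE.NAMES = FALSE)
}

#' Fraction of a gene set with at least one motif hit
#'
#' @param gene_set Character vector of transcript ids (non-empty).
#' @param hits A [scan_motif()] hit tibble.
#' @return A one-row tibble: `n_genes`, `n_with_hit`, `fraction`.
#' @examples
#' motif_fraction(c("a", "b"), tibble::tibble(transcript_id = "a"))
#' @export
motif_fraction <- function(gene_set, hits) {
  if (length(gene_set) == 0) stop("empty gene set", call. = FALSE)
  n_hit <- sum(unique(gene_set) %in% hits$transcript_id)
  tibble::tibble(n_genes = length(unique(gene_set)),
                 n_with_hit = n_hit,
                 fraction = n_hit / length(unique(gene_set)))
}
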