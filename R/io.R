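#' Read an RNA or DNA FASTA file
#'
#' Reads a (possibly line-wrapped) FASTA file, uppercases, and normalizes
#' U to T so rRNA references distributed in the RNA alphabet can be used
#' directly.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header) and `sequence`.
#' @export
read_rna_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  normalize_reference(tibble::tibble(id = ids,
                                     sequence = unname(as.character(ss))))
}

#' Write sequences to FASTA
#'
#' @param seqs Data frame with `id` and `sequence` columns, or a named
#'   character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (is.character(seqs)) {
    seqs <- tibble::tibble(id = names(seqs), sequence = unname(seqs))
  }
  ss <- Biostrings::BStringSet(seqs$sequence)
  names(ss) <- seqs$id
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Write a primer oligo sheet
#'
#' Tab-separated, columns `hexamer`, `first_strand`, `second_strand`, for
#' handoff to oligo synthesis.
#'
#' @param oligos Output of [design_oligos()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_oligo_sheet <- function(oligos, path) {
  stopifnot(all(c("hexamer", "first_strand", "second_strand")
                %in% names(oligos)))
  utils::write.table(oligos[, c("hexamer", "first_strand", "second_strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a primer oligo sheet
#'
#' @param path A TSV written by [write_oligo_sheet()].
#' @return A tibble with `hexamer`, `first_strand`, `second_strand`.
#' @export
read_oligo_sheet <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      colClasses = "character"))
}

#' Read a spike-in concentration table
#'
#' Tab-separated, ERCC-style: one row per control species with its expected
#' concentration (arbitrary units, e.g. attomoles/uL) and length in nt.
#' Column names are matched case-insensitively; `id`, `concentration`, and
#' `length` are required.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `id`, `concentration`, `length`.
#' @export
read_spikein_ref <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  need <- c("id", "concentration", "length")
  if (!all(need %in% names(df))) {
    stop("spike-in table must have columns id, concentration, length",
         call. = FALSE)
  }
  out <- tibble::as_tibble(df[, need])
  if (any(out$concentration <= 0)) {
    stop("spike-in concentrations must be strictly positive", call. = FALSE)
  }
  out
}

#' Write a spike-in concentration table
#'
#' @param ref Tibble with `id`, `concentration`, `length`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spikein_ref <- function(ref, path) {
  utils::write.table(ref[, c("id", "concentration", "length")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- annotation ------------------------------------------------------------

tx_required_cols <- c("transcript_id", "chrom", "start", "end", "strand",
                      "biotype")

#' Build a transcript model table
#'
#' Validates and completes a transcript annotation tibble: 0-based half-open
#' `start`/`end`, strand-aware `tss` (the span start on `+`, `end - 1` on
#' `-`), exon list-columns, and exonic length. Single-exon models are filled
#' in from the span when exons are absent.
#'
#' @param df Data frame with at least `transcript_id`, `chrom`, `start`,
#'   `end`, `strand`, `biotype`; optionally list-columns `exon_starts`,
#'   `exon_ends`.
#' @return A tibble with the columns above plus `tss`, `exon_starts`,
#'   `exon_ends`, `exonic_length`.
#' @export
transcript_models <- function(df) {
  stopifnot(is.data.frame(df))
  miss <- setdiff(tx_required_cols, names(df))
  if (length(miss)) {
    stop("annotation missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  if (!all(df$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  if (any(df$end <= df$start)) stop("empty transcript span", call. = FALSE)
  if (!("exon_starts" %in% names(df))) {
    df$exon_starts <- as.list(df$start)
    df$exon_ends <- as.list(df$end)
  }
  df$exon_starts <- purrr::map(df$exon_starts, as.numeric)
  df$exon_ends <- purrr::map(df$exon_ends, as.numeric)
  bad <- purrr::map2_lgl(df$exon_starts, df$exon_ends, function(s, e) {
    length(s) != length(e) || any(e <= s) || is.unsorted(s, strictly = TRUE) ||
      (length(s) > 1 && any(s[-1] < e[-length(e)]))
  })
  if (any(bad)) {
    stop("exons must be sorted, non-empty, disjoint for: ",
         paste(df$transcript_id[bad], collapse = ", "), call. = FALSE)
  }
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  df$exonic_length <- purrr::map2_dbl(df$exon_starts, df$exon_ends,
                                      ~ sum(.y - .x))
  df
}

#' Read a transcript annotation (GFF3 or BED12)
#'
#' GFF3 files are expected to carry `transcript` (or `mRNA`/gene-like)
#' features with an `ID` and a `biotype` attribute, and `exon` features with
#' a `Parent`. BED12 gives one transcript per line with block structure; the
#' `biotype` is taken from an optional 13th column, else `"mRNA"`.
#' Coordinates are converted to the package's internal 0-based half-open
#' convention.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @return A [transcript_models()] tibble.
#' @export
read_annotation <- function(path) {
  if (grepl("\\.bed[0-9]*$", path, ignore.case = TRUE)) {
    return(read_annotation_bed12(path))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble::as_tibble(as.data.frame(gr))
  is_tx <- df$type %in% c("transcript", "mRNA", "ncRNA", "rRNA", "gene")
  tx <- df[is_tx, , drop = FALSE]
  # a gene row that parents a transcript row is container only; drop it
  if ("Parent" %in% names(tx) && any(tx$type == "gene") &&
      any(tx$type != "gene")) {
    tx <- tx[tx$type != "gene", , drop = FALSE]
  }
  if (nrow(tx) == 0) stop("no transcript features in ", path, call. = FALSE)
  biotype <- if ("biotype" %in% names(tx)) as.character(tx$biotype)
             else as.character(tx$type)
  biotype[is.na(biotype)] <- as.character(tx$type)[is.na(biotype)]
  ann <- tibble::tibble(
    transcript_id = as.character(tx$ID),
    chrom = as.character(tx$seqnames),
    start = tx$start - 1,   # GFF is 1-based closed
    end = tx$end,
    strand = as.character(tx$strand),
    biotype = biotype
  )
  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) > 0 && "Parent" %in% names(ex)) {
    parent <- vapply(ex$Parent, function(p) as.character(p)[1], character(1))
    exl <- split(data.frame(s = ex$start - 1, e = ex$end), parent)
    ann$exon_starts <- purrr::map(ann$transcript_id, function(id) {
      if (id %in% names(exl)) sort(exl[[id]]$s) else NULL
    })
    ann$exon_ends <- purrr::map(ann$transcript_id, function(id) {
      if (id %in% names(exl)) exl[[id]]$e[order(exl[[id]]$s)] else NULL
    })
    none <- purrr::map_lgl(ann$exon_starts, is.null)
    ann$exon_starts[none] <- as.list(ann$start[none])
    ann$exon_ends[none] <- as.list(ann$end[none])
  }
  transcript_models(ann)
}

read_annotation_bed12 <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 12) stop("expected BED12", call. = FALSE)
  ann <- tibble::tibble(
    transcript_id = df[[4]], chrom = df[[1]], start = df[[2]], end = df[[3]],
    strand = df[[6]],
    biotype = if (ncol(df) >= 13) df[[13]] else "mRNA"
  )
  sizes <- strsplit(as.character(df[[11]]), ",")
  offs <- strsplit(as.character(df[[12]]), ",")
  ann$exon_starts <- purrr::map2(offs, df[[2]],
                                 ~ as.numeric(.x[nzchar(.x)]) + .y)
  ann$exon_ends <- purrr::pmap(list(ann$exon_starts, sizes),
                               function(s, sz) s + as.numeric(sz[nzchar(sz)]))
  transcript_models(ann)
}

#' Write a transcript annotation as GFF3
#'
#' Emits one `transcript` feature (with `ID` and `biotype` attributes) plus
#' `exon` children per model, 1-based closed as GFF3 requires.
#'
#' @param annotation A [transcript_models()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  ann <- transcript_models(annotation)
  tx_gr <- GenomicRanges::GRanges(
    ann$chrom,
    IRanges::IRanges(ann$start + 1, ann$end),
    strand = ann$strand,
    type = "transcript", ID = ann$transcript_id, biotype = ann$biotype
  )
  ex <- tidyr::unnest(
    ann[, c("transcript_id", "chrom", "strand", "exon_starts", "exon_ends")],
    cols = c("exon_starts", "exon_ends"))
  ex_gr <- GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$exon_starts + 1, ex$exon_ends),
    strand = ex$strand, type = "exon",
    ID = paste0(ex$transcript_id, ".e", seq_len(nrow(ex))),
    Parent = ex$transcript_id
  )
  rtracklayer::export(c(tx_gr, ex_gr), path, format = "gff3")
  invisible(path)
}

# ---- alignments ------------------------------------------------------------

#' Read a minimal SAM alignment file
#'
#' Parses the subset of SAM this toolkit consumes: QNAME, FLAG (strand bit
#' 0x10; secondary 0x100 and supplementary 0x800 mark non-primary records),
#' RNAME, POS, and CIGAR (reference span). Unmapped records (flag 0x4 or
#' RNAME `*`) are dropped.
#'
#' @param path Path to a SAM text file.
#' @param sample Sample id to attach; defaults to the file name.
#' @return An alignment tibble: `read_id`, `sample`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `is_primary`.
#' @export
read_alignments_sam <- function(path, sample = NULL) {
  if (is.null(sample)) sample <- sub("\\.sam$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) stop("no alignment records in ", path, call. = FALSE)
  f <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(f, `[[`, "", 1)
  flag <- as.integer(vapply(f, `[[`, "", 2))
  rname <- vapply(f, `[[`, "", 3)
  pos <- as.integer(vapply(f, `[[`, "", 4))
  cigar <- vapply(f, `[[`, "", 6)
  mapped <- bitwAnd(flag, 4L) == 0L & rname != "*"
  width <- rep(NA_integer_, length(cigar))
  width[mapped] <- GenomicAlignments::cigarWidthAlongReferenceSpace(
    cigar[mapped])
  tibble::tibble(
    read_id = qname[mapped],
    sample = sample,
    chrom = rname[mapped],
    start = pos[mapped] - 1,
    end = pos[mapped] - 1 + width[mapped],
    strand = ifelse(bitwAnd(flag[mapped], 16L) > 0L, "-", "+"),
    is_primary = bitwAnd(flag[mapped], 0x900L) == 0L
  )
}

#' Read alignments from 6-column BED
#'
#' @param path Path to a BED6 file (0-based half-open already).
#' @param sample Sample id to attach; defaults to the file name.
#' @return An alignment tibble as in [read_alignments_sam()]; all records
#'   are treated as primary.
#' @export
read_alignments_bed <- function(path, sample = NULL) {
  if (is.null(sample)) sample <- sub("\\.bed$", "", basename(path))
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  tibble::tibble(read_id = df[[4]], sample = sample, chrom = df[[1]],
                 start = df[[2]], end = df[[3]], strand = df[[6]],
                 is_primary = TRUE)
}

#' Write alignments as SAM
#'
#' @param alignments An alignment tibble (see [read_alignments_sam()]).
#' @param path Output path.
#' @param genome Optional genome (`id`/`sequence` tibble or named character
#'   vector) used both for `@SQ` header lines and to fill in read sequences;
#'   without it SEQ is `*` and `@SQ` lengths are inferred from the data.
#' @return `path`, invisibly.
#' @export
write_alignments_sam <- function(alignments, path, genome = NULL) {
  aln <- alignments
  if (!is.null(genome)) {
    if (is.character(genome)) {
      genome <- tibble::tibble(id = names(genome), sequence = unname(genome))
    }
    sq <- sprintf("@SQ\tSN:%s\tLN:%d", genome$id, nchar(genome$sequence))
    seqs <- stats::setNames(genome$sequence, genome$id)
    readseq <- substring(seqs[aln$chrom], aln$start + 1, aln$end)
    readseq <- ifelse(aln$strand == "-", revcomp(readseq), readseq)
  } else {
    lens <- tapply(aln$end, aln$chrom, max)
    sq <- sprintf("@SQ\tSN:%s\tLN:%d", names(lens), as.integer(lens))
    readseq <- rep("*", nrow(aln))
  }
  flag <- ifelse(aln$strand == "-", 16L, 0L) +
    ifelse(aln$is_primary, 0L, 256L)
  qual <- ifelse(readseq == "*", "*",
                 strrep("I", nchar(readseq)))
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
                 aln$read_id, flag, aln$chrom, aln$start + 1,
                 aln$end - aln$start, readseq, qual)
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", sq, rec), path)
  invisible(path)
}

#' Write a tibble as TSV
#'
#' Convenience writer used for all tabular reports (no quoting, no row
#' names). List-columns are collapsed with commas.
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], paste, "", collapse = ",")
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
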