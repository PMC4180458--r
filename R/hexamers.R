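#' Enumerate all DNA k-mers
#'
#' Builds the full candidate primer universe: every k-mer over the DNA
#' alphabet \{A, C, G, T\}, in lexicographic order. For the classic
#' not-so-random (NSR) design `k = 6`, giving the 4096 input hexamers from
#' which rRNA-matching primers are then removed with [filter_hexamers()].
#'
#' @param k K-mer length, an integer between 1 and 12 (default 6).
#' @return A tibble of class `nsr_hexamers` with one column, `hexamer`,
#'   holding all `4^k` k-mers in lexicographic order. The k-mer length is
#'   stored in the `k` attribute; `filter_mode` is unset until the set has
#'   been filtered.
#' @examples
#' enumerate_kmers(3)
#' nrow(enumerate_kmers(6)) # 4096
#' @export
enumerate_kmers <- function(k = 6) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k != as.integer(k)) {
    stop("`k` must be a single integer", call. = FALSE)
  }
  if (k < 1 || k > 12) {
    stop("`k` must be between 1 and 12 (got ", k, ")", call. = FALSE)
  }
  k <- as.integer(k)
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid, c(rep(list(bases), k),
                                 stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse columns so the
  # leftmost position is the slowest, i.e. lexicographic order
  kmers <- do.call(paste0, rev(grid))
  new_hexamer_set(kmers, k = k)
}

new_hexamer_set <- function(kmers, k, filter_mode = NA_character_,
                            source_digest = NA_character_,
                            n_removed = NA_integer_) {
  out <- tibble::tibble(hexamer = kmers)
  attr(out, "k") <- as.integer(k)
  attr(out, "filter_mode") <- filter_mode
  attr(out, "source_digest") <- source_digest
  attr(out, "n_removed") <- n_removed
  class(out) <- c("nsr_hexamers", class(out))
  out
}

#' @export
print.nsr_hexamers <- function(x, ...) {
  k <- attr(x, "k")
  mode <- attr(x, "filter_mode")
  cat(sprintf("# NSR %d-mer set: %d members", k, nrow(x)))
  if (!is.na(mode)) {
    cat(sprintf(" (filter mode '%s', %d removed)", mode,
                attr(x, "n_removed")))
  }
  cat("\n")
  NextMethod()
  invisible(x)
}

iupac_dna_letters <- function() {
  c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
}

#' Normalize an RNA/DNA reference table
#'
#' Uppercases sequences and converts U to T. Records with characters outside
#' the IUPAC DNA alphabet (after normalization) raise an error naming the
#' offending ids; ambiguity codes such as N are retained but never match any
#' concrete k-mer.
#'
#' @param ref A data frame with columns `id` and `sequence`, or a named
#'   character vector of sequences.
#' @return A tibble with columns `id` and `sequence`, normalized.
#' @export
normalize_reference <- function(ref) {
  if (is.character(ref)) {
    ids <- names(ref)
    if (is.null(ids)) ids <- paste0("seq", seq_along(ref))
    ref <- tibble::tibble(id = ids, sequence = unname(ref))
  }
  stopifnot(is.data.frame(ref), all(c("id", "sequence") %in% names(ref)))
  ref <- tibble::as_tibble(ref[, c("id", "sequence")])
  if (anyDuplicated(ref$id)) {
    stop("duplicate sequence ids: ",
         paste(unique(ref$id[duplicated(ref$id)]), collapse = ", "),
         call. = FALSE)
  }
  ref$sequence <- chartr("u", "T", toupper(ref$sequence))
  ref$sequence <- gsub("U", "T", ref$sequence, fixed = TRUE)
  if (nrow(ref) > 0 && any(!nzchar(ref$sequence))) {
    stop("empty sequence for id(s): ",
         paste(ref$id[!nzchar(ref$sequence)], collapse = ", "), call. = FALSE)
  }
  ok <- !grepl(sprintf("[^%s]", paste(iupac_dna_letters(), collapse = "")),
               ref$sequence)
  if (!all(ok)) {
    stop("non-IUPAC characters after U->T normalization in record(s): ",
         paste(ref$id[!ok], collapse = ", "), call. = FALSE)
  }
  ref
}

# Distinct k-length windows over ACGT in a set of sequences. Windows that
# contain an ambiguity code are skipped: a primer cannot perfectly match an
# ambiguous base. Sequences shorter than k contribute nothing (with a
# warning, since that usually signals a malformed reference).
kmer_inventory <- function(sequences, k, warn_short = TRUE) {
  lens <- nchar(sequences)
  if (warn_short && any(lens < k)) {
    warning(sum(lens < k), " reference sequence(s) shorter than k = ", k,
            " contribute no occurrences", call. = FALSE)
  }
  seqs <- sequences[lens >= k]
  if (length(seqs) == 0) return(character(0))
  windows <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1), k:n)
  }), use.names = FALSE)
  windows <- windows[grepl("^[ACGT]+$", windows)]
  unique(windows)
}

#' Filter k-mers against an rRNA reference
#'
#' The heart of the NSR design: removes every k-mer with a perfect substring
#' occurrence in the reference under the chosen orientation, leaving the
#' "not-so-random" set that cannot prime rRNA. With the full hexamer
#' universe and an organism's rRNA transcripts this yields the depleting
#' primer set (939 hexamers for the *C. elegans* rRNA collection).
#'
#' @param hexamers An `nsr_hexamers` set from [enumerate_kmers()], or any
#'   data frame with a `hexamer` column.
#' @param reference rRNA reference: data frame with `id`/`sequence` columns,
#'   a named character vector, or a path readable by [read_rna_fasta()].
#'   Normalized with [normalize_reference()].
#' @param mode Orientation of matching that removes a k-mer: `"sense"` (the
#'   k-mer itself occurs in the reference, default), `"antisense"` (its
#'   reverse complement occurs), or `"both"` (either).
#' @return The retained subset, in the original order, with attributes
#'   `filter_mode`, `n_removed`, and `source_digest` (a checksum of the
#'   normalized reference sequences).
#' @examples
#' hx <- enumerate_kmers(3)
#' filter_hexamers(hx, c(r1 = "AAACCC"), mode = "sense")
#' @export
filter_hexamers <- function(hexamers, reference,
                            mode = c("sense", "antisense", "both")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(hexamers), "hexamer" %in% names(hexamers))
  if (nrow(hexamers) == 0) stop("`hexamers` is empty", call. = FALSE)
  k <- attr(hexamers, "k")
  if (is.null(k) || is.na(k)) k <- unique(nchar(hexamers$hexamer))
  if (length(k) != 1) stop("k-mers of mixed length", call. = FALSE)

  if (is.character(reference) && length(reference) == 1 &&
      is.null(names(reference)) && file.exists(reference)) {
    reference <- read_rna_fasta(reference)
  }
  ref <- normalize_reference(reference)
  digestv <- digest::digest(ref$sequence)

  present <- kmer_inventory(ref$sequence, k)
  hit <- switch(mode,
    sense = hexamers$hexamer %in% present,
    antisense = revcomp(hexamers$hexamer) %in% present,
    both = hexamers$hexamer %in% present |
      revcomp(hexamers$hexamer) %in% present
  )
  new_hexamer_set(hexamers$hexamer[!hit], k = k, filter_mode = mode,
                  source_digest = digestv, n_removed = sum(hit))
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA (IUPAC letters allowed).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Emit adapter-bearing primer oligos
#'
#' Expands each k-mer of the set into the two synthesis templates used for
#' directional cDNA library construction: the first-strand primer
#' `adapter1 + "N" + reverse-complement(k-mer)` (anneals to the RNA) and the
#' second-strand primer `adapter2 + "N" + k-mer`.
#'
#' @param hexamers An `nsr_hexamers` set or data frame with a `hexamer`
#'   column.
#' @param adapter1,adapter2 5' amplification annealing sites, non-empty
#'   IUPAC DNA strings. Defaults are the Illumina-compatible sites
#'   `"TCCGATCTCT"` and `"TCCGATCTGA"`.
#' @return A tibble with columns `hexamer`, `first_strand`, `second_strand`,
#'   one row per set member in set order.
#' @examples
#' design_oligos(tibble::tibble(hexamer = "AAAAAA"))
#' @export
design_oligos <- function(hexamers, adapter1 = "TCCGATCTCT",
                          adapter2 = "TCCGATCTGA") {
  stopifnot(is.data.frame(hexamers), "hexamer" %in% names(hexamers))
  for (ad in list(adapter1, adapter2)) {
    if (!is.character(ad) || length(ad) != 1 || !nzchar(ad) ||
        grepl(sprintf("[^%s]", paste(iupac_dna_letters(), collapse = "")),
              toupper(ad))) {
      stop("adapters must be non-empty IUPAC DNA strings", call. = FALSE)
    }
  }
  tibble::tibble(
    hexamer = hexamers$hexamer,
    first_strand = paste0(toupper(adapter1), "N", revcomp(hexamers$hexamer)),
    second_strand = paste0(toupper(adapter2), "N", hexamers$hexamer)
  )
}

#' Coverage of target transcripts by a k-mer set
#'
#' Counts, per transcript, how many distinct set members occur as perfect
#' substrings and how many match occurrences there are in total (overlapping
#' occurrences counted, since each is a distinct priming start site). The
#' density is the mean spacing between priming sites: transcript length
#' divided by total occurrences, `NA` when there are none.
#'
#' @param hexamers An `nsr_hexamers` set or data frame with a `hexamer`
#'   column.
#' @param transcripts Data frame with `id`/`sequence` columns, a named
#'   character vector, or a FASTA path.
#' @param both_strands If `TRUE`, also count occurrences of each member's
#'   reverse complement (default `FALSE`: sense strand of the supplied
#'   sequence only).
#' @return An object of class `nsr_coverage`: use [tidy()] for the
#'   per-transcript table (`id`, `length`, `n_hexamers`, `n_occurrences`,
#'   `density`) and [glance()] for the summary (`n_transcripts`,
#'   `mean_matches`, `mean_density`).
#' @examples
#' cov <- hexamer_coverage(tibble::tibble(hexamer = "AAAAAA"),
#'                         c(tx = "AAAAAAAA"))
#' generics::tidy(cov)
#' @export
hexamer_coverage <- function(hexamers, transcripts, both_strands = FALSE) {
  stopifnot(is.data.frame(hexamers), "hexamer" %in% names(hexamers))
  if (is.character(transcripts) && length(transcripts) == 1 &&
      is.null(names(transcripts)) && file.exists(transcripts)) {
    transcripts <- read_rna_fasta(transcripts)
  }
  tx <- normalize_reference(transcripts)
  if (nrow(tx) == 0) stop("empty transcript collection", call. = FALSE)
  k <- attr(hexamers, "k")
  if (is.null(k) || is.na(k)) k <- unique(nchar(hexamers$hexamer))
  members <- hexamers$hexamer
  if (both_strands) members <- unique(c(members, revcomp(members)))

  per <- purrr::map_dfr(seq_len(nrow(tx)), function(i) {
    s <- tx$sequence[i]
    n <- nchar(s)
    if (n < k) {
      return(tibble::tibble(id = tx$id[i], length = n, n_hexamers = 0L,
                            n_occurrences = 0L, density = NA_real_))
    }
    windows <- substring(s, 1:(n - k + 1), k:n)
    is_hit <- windows %in% members
    occ <- sum(is_hit)
    tibble::tibble(
      id = tx$id[i], length = n,
      n_hexamers = length(intersect(unique(windows[is_hit]),
                                    hexamers$hexamer)),
      n_occurrences = occ,
      density = if (occ > 0) n / occ else NA_real_
    )
  })
  structure(list(per_transcript = per, k = k, n_members = nrow(hexamers)),
            class = "nsr_coverage")
}

#' @export
print.nsr_coverage <- function(x, ...) {
  cat(sprintf(
    "# k-mer coverage: %d members vs %d transcripts; mean matches %.1f\n",
    x$n_members, nrow(x$per_transcript), mean(x$per_transcript$n_hexamers)))
  print(x$per_transcript, ...)
  invisible(x)
}

#' @rdname hexamer_coverage
#' @param x An `nsr_coverage` object.
#' @param ... Unused.
#' @exportS3Method
tidy.nsr_coverage <- function(x, ...) x$per_transcript

#' @rdname hexamer_coverage
#' @exportS3Method
glance.nsr_coverage <- function(x, ...) {
  per <- x$per_transcript
  tibble::tibble(
    n_transcripts = nrow(per),
    n_members = x$n_members,
    mean_matches = mean(per$n_hexamers),
    mean_density = if (all(is.na(per$density))) NA_real_
                   else mean(per$density, na.rm = TRUE)
  )
}
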