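# Brute-force oracles kept independent of the package's implementation.

# substring inventory by explicit position loop
oracle_kmer_inventory <- function(seqs, k) {
  out <- character(0)
  for (s in seqs) {
    s <- gsub("U", "T", toupper(s))
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (!grepl("[^ACGT]", w)) out <- c(out, w)
    }
  }
  unique(out)
}

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# exhaustive expansion of a degenerate IUPAC pattern into concrete strings
oracle_expand_iupac <- function(pattern) {
  map <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"),
              S = c("C", "G"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  sets <- map[strsplit(toupper(pattern), "")[[1]]]
  grid <- do.call(expand.grid, c(sets, stringsAsFactors = FALSE))
  apply(grid, 1, paste, collapse = "")
}

# 0-based positions where a window substring is in the expansion set
oracle_scan_positions <- function(window, expansion) {
  plen <- nchar(expansion[1])
  if (nchar(window) < plen) return(integer(0))
  pos <- integer(0)
  for (i in seq_len(nchar(window) - plen + 1)) {
    if (substr(window, i, i + plen - 1) %in% expansion) {
      pos <- c(pos, i - 1L)
    }
  }
  pos
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

empty_reference <- function() {
  tibble::tibble(id = character(), sequence = character())
}
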