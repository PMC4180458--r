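#' Round half away from zero
#'
#' Plain half-up rounding (as used in the printed report tables), rather
#' than base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

category_order <- c("rRNA", "mRNA", "known_ncRNA", "antisense",
                    "intergenic", "intronic")

#' Render a category breakdown as a report row
#'
#' Formats the six canonical genomic read categories as percentages with
#' two decimals (half-up), in the fixed column order rRNA, mRNA, known
#' ncRNA, antisense, intergenic, intronic.
#'
#' @param fractions Named numeric vector of category fractions; names may
#'   use `known_ncRNA` or `ncRNA`.
#' @return A single string, e.g. `"1.97% 83.82% 2.30% 4.13% 6.78% 0.99%"`.
#' @export
render_category_row <- function(fractions) {
  names(fractions)[names(fractions) == "ncRNA"] <- "known_ncRNA"
  miss <- setdiff(category_order, names(fractions))
  if (length(miss)) {
    stop("missing category fraction(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pct <- round_half_up(100 * as.numeric(fractions[category_order]), 2)
  paste(sprintf("%.2f%%", pct), collapse = " ")
}

render_correlation_matrix <- function(m, digits = 3) {
  if (is.null(m)) return(character(0))
  fmt <- formatC(m, format = "f", digits = digits)
  c(paste(c("Sample", colnames(m)), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], fmt[i, ]), collapse = "\t")
    }, character(1)))
}

#' Assemble a human-readable summary report
#'
#' Joins the per-module outputs into one plain-text report: per-sample
#' genomic category percentages, spike-in correlation results, differential
#' direction counts per chromosome, cluster list, and motif fractions.
#' Sections whose input is `NULL` are omitted. The report is a pure
#' function of its inputs.
#'
#' @param classification An [classify_alignments()] result.
#' @param spikein An [spikein_correlation()] result.
#' @param calls A [call_differential()] result.
#' @param clusters A [find_clusters()] table.
#' @param motif A [motif_fraction()] row.
#' @return Character vector of report lines.
#' @export
report_summary <- function(classification = NULL, spikein = NULL,
                           calls = NULL, clusters = NULL, motif = NULL) {
  sample_sets <- list()
  if (!is.null(classification)) {
    sample_sets$classification <- unique(classification$reads$sample)
  }
  if (!is.null(spikein)) sample_sets$spikein <- spikein$per_sample$sample
  if (length(sample_sets) > 1) {
    common <- Reduce(intersect, sample_sets)
    if (length(common) == 0) {
      stop("conflicting sample ids across report inputs", call. = FALSE)
    }
  }
  lines <- character(0)
  sect <- function(title) c("", paste0("== ", title, " =="))
  if (!is.null(classification)) {
    lines <- c(lines, sect("Genomic distribution of mapped reads"),
               paste("Sample", paste(category_order, collapse = " "),
                     sep = " "))
    for (s in unique(classification$breakdown$sample)) {
      b <- classification$breakdown
      fr <- stats::setNames(b$fraction[b$sample == s],
                            as.character(b$category[b$sample == s]))
      fr6 <- fr[names(fr) %in% category_order]
      lines <- c(lines, paste(s, render_category_row(fr6)))
      if ("spike_in" %in% names(fr) && fr[["spike_in"]] > 0) {
        lines <- c(lines, sprintf("  (%s: %.2f%% of reads on spike-ins)",
                                  s, 100 * fr[["spike_in"]]))
      }
    }
  }
  if (!is.null(spikein)) {
    lines <- c(lines, sect("Spike-in correlation with reference values"))
    ps <- spikein$per_sample
    lines <- c(lines, sprintf("%s\t%.3f\t(%d species)", ps$sample,
                              ps$r_reference, ps$n_species))
    if (!is.null(spikein$pairwise_spikein)) {
      lines <- c(lines, "", "Pairwise sample correlation over spike-ins:",
                 render_correlation_matrix(spikein$pairwise_spikein))
    }
  }
  if (!is.null(calls)) {
    lines <- c(lines, sect("Differential calls"))
    g <- glance(calls)
    lines <- c(lines, sprintf(
      "%d of %d loci pass (%d repressed, %d activated) at fold >= %g, RPKM > %g",
      g$n_pass, g$n_loci, g$n_repressed, g$n_activated, g$fc_min,
      g$rpkm_min))
    if ("chrom" %in% names(calls)) {
      per_chr <- dplyr::count(calls[calls$passes, ], .data$chrom,
                              .data$direction)
      lines <- c(lines, sprintf("  %s\t%s\t%d", per_chr$chrom,
                                per_chr$direction, per_chr$n))
    }
  }
  if (!is.null(clusters) && nrow(clusters) > 0) {
    lines <- c(lines, sect("Genomic clusters of differential loci"))
    lines <- c(lines, sprintf("%s\t%s\t%d-%d\t%d members\t%s",
                              clusters$cluster_id, clusters$chrom,
                              clusters$start, clusters$end,
                              clusters$n_members, clusters$direction))
  }
  if (!is.null(motif)) {
    lines <- c(lines, sect("Promoter motif scan"),
               sprintf("%d of %d genes with >= 1 motif hit (%.1f%%)",
                       motif$n_with_hit, motif$n_genes,
                       100 * motif$fraction))
  }
  lines
}
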