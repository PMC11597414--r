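# Base composition, AT/GC skew and start/stop-codon tabulation.
# AT skew = (A - T) / (A + T); GC skew = (G - C) / (G + C). Ambiguity codes
# are excluded from all counts and denominators; a skew whose denominator is
# zero is NA (undefined), never silently zero.

#' Base composition and strand skews of a DNA sequence
#'
#' @param seq DNA string.
#' @param scope Label for the record (e.g. `"whole_genome"`, `"PCGs"`).
#' @return A one-row data frame with counts `A`, `T`, `G`, `C`, `at_content`
#'   (over unambiguous bases), `at_skew` and `gc_skew` (NA when undefined).
#' @export
composition <- function(seq, scope = "whole_genome") {
  stopifnot(nchar(seq) > 0)
  ch <- split_chars(toupper(seq))
  A <- sum(ch == "A"); T <- sum(ch == "T")
  G <- sum(ch == "G"); C <- sum(ch == "C")
  tot <- A + T + G + C
  data.frame(scope = scope, A = A, T = T, G = G, C = C,
             at_content = if (tot > 0) (A + T) / tot else NA_real_,
             at_skew = if (A + T > 0) (A - T) / (A + T) else NA_real_,
             gc_skew = if (G + C > 0) (G - C) / (G + C) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Composition per functional class of a mitogenome
#'
#' One record for the whole genome and one for the concatenate of each
#' feature class (PCG, rRNA, tRNA). Classes without any feature are omitted
#' with a warning.
#'
#' @param g A [mito_genome()].
#' @return Data frame of composition records (one row per scope).
#' @export
composition_by_class <- function(g) {
  recs <- list(composition(g$sequence, "whole_genome"))
  for (cl in c("PCG", "rRNA", "tRNA")) {
    idx <- which(g$features$cls == cl)
    if (!length(idx)) {
      warning(sprintf("%s: no %s features; scope omitted", g$id, cl),
              call. = FALSE)
      next
    }
    cat_seq <- paste(vapply(idx, function(i) {
      f <- g$features[i, ]
      s <- seq_span(g$sequence, f$start, f$end, g$topology == "circular")
      if (f$strand == "-") revcomp(s) else s
    }, character(1)), collapse = "")
    scope <- c(PCG = "PCGs", rRNA = "rRNAs", tRNA = "tRNAs")[[cl]]
    recs[[length(recs) + 1L]] <- composition(cat_seq, scope)
  }
  out <- do.call(rbind, recs)
  out <- cbind(genome = g$id, out, stringsAsFactors = FALSE)
  out
}

#' Start/stop codon usage of the protein-coding genes
#'
#' Tabulates the initiation codon (honoring `codon_start`) and the
#' termination codon of every annotated PCG; a CDS whose length is not a
#' multiple of 3 and ends in T or TA is flagged as an incomplete stop codon
#' (completed to TAA by transcript polyadenylation). Two aggregate start
#' fractions are reported: `atd_fraction` counts starts in {ATA, ATT, ATG}
#' (IUPAC D = not C) and `atn_fraction` counts any AT[ACGT] start; both are
#' given because annotation practice varies on whether ATC is included.
#'
#' @param g A [mito_genome()].
#' @param code Translation table id (default "5", invertebrate mitochondrial).
#' @return A list of class `codon_usage_report` with a per-gene data frame
#'   (`table`) and the aggregate fractions with their denominator `n_pcg`.
#' @export
codon_usage <- function(g, code = "5") {
  idx <- which(g$features$cls == "PCG")
  rows <- list()
  for (i in idx) {
    f <- g$features[i, ]
    s <- extract_gene_seq(g, f$gene,
                          occurrence = sum(g$features$gene[seq_len(i)] == f$gene))
    if (f$codon_start > 1L) s <- substr(s, f$codon_start, nchar(s))
    if (nchar(s) < 6L) {
      warning(sprintf("%s: CDS %s shorter than 6 nt, skipped", g$id, f$gene),
              call. = FALSE)
      next
    }
    rem <- nchar(s) %% 3L
    start_codon <- substr(s, 1L, 3L)
    if (rem == 0L) {
      stop_codon <- substr(s, nchar(s) - 2L, nchar(s))
      incomplete <- FALSE
    } else {
      tail_nt <- substr(s, nchar(s) - rem + 1L, nchar(s))
      incomplete <- tail_nt %in% c("T", "TA")
      stop_codon <- paste0(tail_nt, strrep("-", 3L - rem))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene = f$gene, start_codon = start_codon, stop_codon = stop_codon,
      incomplete_stop = incomplete, stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), start_codon = character(),
               stop_codon = character(), incomplete_stop = logical())
  n <- nrow(tab)
  atd <- sum(tab$start_codon %in% c("ATA", "ATT", "ATG"))
  atn <- sum(substr(tab$start_codon, 1, 2) == "AT")
  out <- list(table = tab, n_pcg = n,
              atd_fraction = if (n) atd / n else NA_real_,
              atn_fraction = if (n) atn / n else NA_real_)
  class(out) <- "codon_usage_report"
  out
}

#' @export
print.codon_usage_report <- function(x, ...) {
  print(x$table)
  cat(sprintf("ATD starts (A/T/G third base): %.1f%% of %d PCGs; ATN: %.1f%%\n",
              100 * x$atd_fraction, x$n_pcg, 100 * x$atn_fraction))
  invisible(x)
}

#' Write per-genome composition records as TSV
#'
#' @param genomes List of [mito_genome()] objects.
#' @param path Output TSV path.
#' @return The combined data frame, invisibly.
#' @export
write_composition_tsv <- function(genomes, path) {
  out <- do.call(rbind, lapply(genomes, composition_by_class))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
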