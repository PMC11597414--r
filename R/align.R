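# Global pairwise alignment plumbing. Needleman-Wunsch optimal global
# alignment via Biostrings; a gap of length k costs 2 + 0.5*(k-1) under the
# default nucleotide scoring (match +1, mismatch -1). Codon mode aligns the
# translations and threads the nucleotides back through the protein
# alignment, so gap runs stay in frame.

default_align_params <- function(mode) {
  switch(mode,
    nt = list(match = 1, mismatch = -1, gap_open = 2, gap_extend = 0.5),
    aa = list(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1),
    codon = list(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1))
}

#' Optimal global pairwise alignment
#'
#' @param a,b Sequences (DNA for `nt`/`codon` mode, protein for `aa`).
#' @param mode `"nt"` (nucleotide), `"aa"` (protein, BLOSUM62) or `"codon"`
#'   (translate with the invertebrate mitochondrial code, align proteins,
#'   thread nucleotides back).
#' @param params Optional scoring overrides: `match`, `mismatch`,
#'   `gap_open`, `gap_extend` for `nt`; a substitution `matrix` (name or
#'   matrix) plus gap costs for `aa`/`codon`. `gap_open` is the cost of a
#'   gap of length 1; each additional gapped position costs `gap_extend`.
#' @param code Translation table id for codon mode.
#' @return Object of class `pairwise_alignment`: aligned strings `seq_a`,
#'   `seq_b` (gap `"-"`), `mode`, `score`, `aligned_columns`.
#' @export
global_align <- function(a, b, mode = c("nt", "aa", "codon"), params = list(),
                         code = "5") {
  mode <- match.arg(mode)
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  p <- utils::modifyList(default_align_params(mode), params)

  if (mode == "codon") {
    ta <- trim_to_frame(a)
    tb <- trim_to_frame(b)
    pa <- translate_cds(ta, code = code)
    pb <- translate_cds(tb, code = code)
    chk <- function(prot, which) {
      ist <- which(split_chars(prot) == "*")
      ist <- ist[ist < nchar(prot)]
      if (length(ist)) stop(sprintf(
        "internal stop codon at codon %d in %s sequence", ist[1], which))
    }
    chk(pa, "first"); chk(pb, "second")
    pa <- sub("\\*$", "", pa); pb <- sub("\\*$", "", pb)
    aln <- global_align(pa, pb, mode = "aa", params = p)
    thr <- thread_codons(aln, substr(ta, 1, 3 * nchar(pa)),
                         substr(tb, 1, 3 * nchar(pb)))
    return(structure(list(seq_a = thr$a, seq_b = thr$b, mode = "codon",
                          score = aln$score,
                          aligned_columns = nchar(thr$a) / 3L),
                     class = "pairwise_alignment"))
  }

  if (mode == "nt") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = p$match, mismatch = p$mismatch, baseOnly = FALSE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      substitutionMatrix = mat, type = "global",
      gapOpening = p$gap_open - p$gap_extend, gapExtension = p$gap_extend)
  } else {
    mat <- p$matrix
    if (is.character(mat)) {
      e <- new.env()
      utils::data(list = mat, package = "Biostrings", envir = e)
      mat <- get(p$matrix, envir = e)
    }
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = mat, type = "global",
      gapOpening = p$gap_open - p$gap_extend, gapExtension = p$gap_extend)
  }
  sa <- as.character(Biostrings::alignedPattern(pa))
  sb <- as.character(Biostrings::alignedSubject(pa))
  structure(list(seq_a = unname(sa), seq_b = unname(sb), mode = mode,
                 score = Biostrings::score(pa),
                 aligned_columns = nchar(sa)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> mode=%s columns=%d score=%.1f\n",
              x$mode, x$aligned_columns, x$score))
  invisible(x)
}

# Drop trailing incomplete codon (1 or 2 nt, the incomplete-stop remainder).
trim_to_frame <- function(s) substr(s, 1L, nchar(s) - nchar(s) %% 3L)

#' Translate a coding sequence with the invertebrate mitochondrial code
#'
#' @param s In-frame DNA string (length a multiple of 3).
#' @param code Translation table id.
#' @return Protein string (`*` = stop).
#' @export
translate_cds <- function(s, code = "5") {
  stopifnot(nchar(s) %% 3 == 0)
  gc <- genetic_code_5()
  if (code != "5") gc <- setNames(as.character(Biostrings::getGeneticCode(code)),
                                  names(Biostrings::getGeneticCode(code)))
  cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  aa <- gc[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Thread nucleotide triplets through a protein alignment.
thread_codons <- function(aa_aln, nt_a, nt_b) {
  ca <- split_chars(aa_aln$seq_a)
  cb <- split_chars(aa_aln$seq_b)
  coda <- substring(nt_a, seq(1, nchar(nt_a), 3), seq(3, nchar(nt_a), 3))
  codb <- substring(nt_b, seq(1, nchar(nt_b), 3), seq(3, nchar(nt_b), 3))
  ia <- 0L; ib <- 0L
  outa <- character(length(ca)); outb <- character(length(cb))
  for (k in seq_along(ca)) {
    if (ca[k] == "-") outa[k] <- "---" else { ia <- ia + 1L; outa[k] <- coda[ia] }
    if (cb[k] == "-") outb[k] <- "---" else { ib <- ib + 1L; outb[k] <- codb[ib] }
  }
  list(a = paste(outa, collapse = ""), b = paste(outb, collapse = ""))
}

#' Write a pairwise alignment as aligned FASTA
#'
#' @param al A `pairwise_alignment`.
#' @param path Output path.
#' @param names Two sequence names.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(al, path, names = c("seq_a", "seq_b")) {
  writeLines(c(paste0(">", names[1]), al$seq_a,
               paste0(">", names[2]), al$seq_b), path)
  invisible(path)
}
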