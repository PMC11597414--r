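#' @useDynLib duimito, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median setNames rbinom runif
#' @importFrom utils read.delim write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a DNA string
#'
#' @param s DNA string (character scalar, IUPAC codes allowed).
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Wrap-aware substring on a circular sequence; start0 0-based inclusive,
# end0 0-based exclusive, end0 <= start0 encodes an origin-spanning span.
seq_span <- function(seq, start0, end0, circular = TRUE) {
  n <- nchar(seq)
  stopifnot(start0 >= 0, start0 < n, end0 >= 0, end0 <= n)
  if (end0 > start0) {
    substr(seq, start0 + 1L, end0)
  } else {
    if (!circular) stop("origin-spanning span on a linear sequence")
    paste0(substr(seq, start0 + 1L, n), substr(seq, 1L, end0))
  }
}

# Span length under circular arithmetic (end==start means full circle is NOT
# allowed for features; callers guarantee non-degenerate spans).
span_len <- function(start0, end0, L) {
  ifelse(end0 > start0, end0 - start0, L - start0 + end0)
}

split_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Invertebrate mitochondrial genetic code (NCBI table 5), as a named vector
# codon -> single-letter amino acid ("*" = stop).
genetic_code_5 <- local({
  code <- NULL
  function() {
    if (is.null(code)) {
      gc <- Biostrings::getGeneticCode("5")
      code <<- setNames(as.character(gc), names(gc))
    }
    code
  }
})

all_codons <- function() {
  b <- c("T", "C", "A", "G")
  as.vector(t(outer(outer(b, b, paste0), b, paste0)))
}

sense_codons <- function(code = genetic_code_5()) {
  names(code)[code != "*"]
}

fmt1 <- function(x) round(x, 1)
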