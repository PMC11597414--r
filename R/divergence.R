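# F-vs-M divergence statistics: uncorrected p-distances, Nei-Gojobori (1986)
# dN/dS with Jukes-Cantor correction, cox2 modification scanning and a
# Kyte-Doolittle hydropathy heuristic for transmembrane helices.

#' Uncorrected p-distance from a pairwise alignment
#'
#' p = mismatching columns / compared columns. Columns containing a gap or
#' an ambiguous symbol (non-ACGT for nucleotides, X/*/- for proteins) are
#' excluded from the comparison. For a single pair, `pairwise` and
#' `complete` deletion coincide; the option is kept for interface parity
#' with multi-sequence use.
#'
#' @param al A `pairwise_alignment` from [global_align()].
#' @param gene Label carried into the record.
#' @param deletion Gap-handling mode (`"pairwise"` or `"complete"`).
#' @return A one-row data frame: `gene`, `p` (NA when no comparable
#'   columns), `sites_compared`, `gap_excluded` (columns dropped).
#' @export
p_distance <- function(al, gene = "seq", deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  a <- split_chars(al$seq_a)
  b <- split_chars(al$seq_b)
  stopifnot(length(a) == length(b))
  ok_set <- if (al$mode %in% c("nt", "codon")) c("A", "C", "G", "T")
            else setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z"))
  keep <- a %in% ok_set & b %in% ok_set
  n <- sum(keep)
  p <- if (n > 0) sum(a[keep] != b[keep]) / n else NA_real_
  if (n == 0) warning("no comparable columns; p-distance undefined",
                      call. = FALSE)
  data.frame(gene = gene, p = p, sites_compared = n,
             gap_excluded = length(a) - n, stringsAsFactors = FALSE)
}

#' Whole-genome p-distance between two genomes
#'
#' `method = "align"` performs a global nucleotide alignment first (the UR
#' content of both genomes is included; insertions fall out as gap-excluded
#' columns under pairwise deletion). `method = "positional"` compares
#' position by position and requires equal lengths (exact for
#' substitution-only pairs).
#'
#' @param f,m Two [mito_genome()] objects (or DNA strings).
#' @param method `"align"` or `"positional"`.
#' @return A p-distance record as from [p_distance()].
#' @export
whole_genome_p_distance <- function(f, m, method = c("align", "positional")) {
  method <- match.arg(method)
  sa <- if (inherits(f, "mito_genome")) f$sequence else f
  sb <- if (inherits(m, "mito_genome")) m$sequence else m
  if (method == "positional") {
    if (nchar(sa) != nchar(sb))
      stop("positional whole-genome distance requires equal lengths")
    ra <- charToRaw(toupper(sa)); rb <- charToRaw(toupper(sb))
    acgt <- as.raw(c(65L, 67L, 71L, 84L))
    ok <- (ra %in% acgt) & (rb %in% acgt)
    n <- sum(ok)
    return(data.frame(gene = "whole_genome",
                      p = if (n > 0) sum(ra[ok] != rb[ok]) / n else NA_real_,
                      sites_compared = n, gap_excluded = length(ra) - n,
                      stringsAsFactors = FALSE))
  }
  al <- global_align(sa, sb, mode = "nt")
  p_distance(al, gene = "whole_genome")
}

# ---- Nei-Gojobori 1986 ---------------------------------------------------

# Per-codon synonymous site count: at each position, (number of the 3
# possible single-nucleotide changes that are synonymous) / 3; changes to a
# stop codon count as nonsynonymous. Total sites per codon = 3.
ng86_codon_sites <- function(code = genetic_code_5()) {
  bases <- c("A", "C", "G", "T")
  cods <- sense_codons(code)
  s <- setNames(numeric(length(cods)), cods)
  for (cd in cods) {
    ch <- split_chars(cd)
    syn <- 0
    for (pos in 1:3) for (nb in setdiff(bases, ch[pos])) {
      mut <- ch; mut[pos] <- nb
      mc <- paste(mut, collapse = "")
      if (code[[mc]] != "*" && code[[mc]] == code[[cd]]) syn <- syn + 1
    }
    s[cd] <- syn / 3
  }
  s
}

# Average synonymous/nonsynonymous difference counts between two sense
# codons over all minimal mutational pathways; pathways passing through a
# stop codon are excluded (if every pathway is blocked, all are used).
ng86_codon_diffs <- function(c1, c2, code = genetic_code_5()) {
  if (c1 == c2) return(c(syn = 0, nonsyn = 0))
  pos <- which(split_chars(c1) != split_chars(c2))
  perms <- switch(as.character(length(pos)),
    "1" = list(pos),
    "2" = list(pos, rev(pos)),
    "3" = {
      p <- pos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    })
  walk <- function(order) {
    cur <- split_chars(c1)
    tgt <- split_chars(c2)
    syn <- 0; nonsyn <- 0
    for (p in order) {
      prev <- paste(cur, collapse = "")
      cur[p] <- tgt[p]
      nxt <- paste(cur, collapse = "")
      if (code[[nxt]] == "*") return(NULL)
      if (code[[nxt]] == code[[prev]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk))
  if (!length(res)) {
    # all pathways pass through stops: count them anyway (stop steps are
    # nonsynonymous)
    walk2 <- function(order) {
      cur <- split_chars(c1); tgt <- split_chars(c2)
      syn <- 0; nonsyn <- 0
      for (p in order) {
        prev <- paste(cur, collapse = "")
        cur[p] <- tgt[p]
        nxt <- paste(cur, collapse = "")
        if (code[[nxt]] != "*" && code[[prev]] != "*" &&
            code[[nxt]] == code[[prev]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
      }
      c(syn = syn, nonsyn = nonsyn)
    }
    res <- lapply(perms, walk2)
  }
  Reduce(`+`, res) / length(res)
}

#' Nei-Gojobori (1986) dN/dS from a codon alignment
#'
#' Counting method: synonymous site fractions per codon position averaged
#' over the two sequences; codon differences resolved by averaging
#' synonymous/nonsynonymous steps over all minimal mutational pathways,
#' excluding pathways through stop codons; proportions converted to rates
#' with the Jukes-Cantor correction d = -(3/4) ln(1 - (4/3) p).
#'
#' @param al A codon-mode `pairwise_alignment` (see [global_align()]).
#' @param gene Label carried into the record.
#' @param code Translation table id (only "5" is precomputed; others are
#'   derived on the fly).
#' @return A one-row data frame of class `dnds_record`: `N_sites`,
#'   `S_sites`, `Nd`, `Sd`, `pN`, `pS`, `dN`, `dS`, `omega`,
#'   `codons_compared`. `dS`/`omega` are NA when undefined (pS >= 0.75 or
#'   dS = 0).
#' @export
ng86_dnds <- function(al, gene = "gene", code = "5") {
  stopifnot(al$mode == "codon")
  gc <- genetic_code_5()
  if (code != "5") {
    g <- Biostrings::getGeneticCode(code)
    gc <- setNames(as.character(g), names(g))
  }
  sites <- ng86_codon_sites(gc)
  n3 <- al$aligned_columns
  ca <- substring(al$seq_a, seq(1, 3 * n3, 3), seq(3, 3 * n3, 3))
  cb <- substring(al$seq_b, seq(1, 3 * n3, 3), seq(3, 3 * n3, 3))
  ok <- ca %in% names(sites) & cb %in% names(sites)
  ca <- ca[ok]; cb <- cb[ok]
  ncod <- length(ca)
  if (ncod == 0) stop("no comparable codons in alignment")
  S <- (sum(sites[ca]) + sum(sites[cb])) / 2
  N <- 3 * ncod - S
  diffs <- which(ca != cb)
  Sd <- 0; Nd <- 0
  if (length(diffs)) {
    key <- paste(ca[diffs], cb[diffs])
    per <- tapply(seq_along(key), key, length)
    for (k in names(per)) {
      pair <- strsplit(k, " ")[[1]]
      d <- ng86_codon_diffs(pair[1], pair[2], gc)
      Sd <- Sd + per[[k]] * d[["syn"]]
      Nd <- Nd + per[[k]] * d[["nonsyn"]]
    }
  }
  pN <- Nd / N; pS <- Sd / S
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dN <- jc(pN); dS <- jc(pS)
  omega <- if (is.na(dS) || dS == 0 || is.na(dN)) NA_real_ else dN / dS
  if (!is.na(pS) && pS >= 0.75)
    warning("pS >= 0.75: Jukes-Cantor correction undefined", call. = FALSE)
  out <- data.frame(gene = gene, N_sites = N, S_sites = S, Nd = Nd, Sd = Sd,
                    pN = pN, pS = pS, dN = dN, dS = dS, omega = omega,
                    codons_compared = ncod, stringsAsFactors = FALSE)
  class(out) <- c("dnds_record", class(out))
  out
}

#' dN/dS for one gene of an F/M genome pair
#'
#' Convenience wrapper: extracts the gene from both genomes, codon-aligns
#' and runs [ng86_dnds()].
#'
#' @param f,m Two [mito_genome()] objects.
#' @param gene Gene symbol.
#' @return A `dnds_record`.
#' @export
gene_dnds <- function(f, m, gene) {
  al <- global_align(extract_gene_seq(f, gene), extract_gene_seq(m, gene),
                     mode = "codon")
  ng86_dnds(al, gene = gene)
}

# ---- cox2 modification scanning -----------------------------------------

#' Scan a cox2 sequence for lineage-specific modifications
#'
#' Aligns the translated query against a translated reference cox2. A run of
#' at least `min_codons` consecutive query codons absent from the reference
#' is reported: internal runs as `insertion` (or `duplication` when the
#' inserted peptide matches the reference protein at >= 50% identity), runs
#' past the reference 3' terminus as `extension_3prime`. The modified region
#' is also scanned for transmembrane helices ([tmh_scan()]).
#'
#' @param query_cox2,reference_cox2 DNA strings (translatable after
#'   incomplete-stop trimming).
#' @param min_codons Minimum run length to call a modification (default 30).
#' @return A list of class `cox2_mod_report`: `kind` (`none`, `insertion`,
#'   `extension_3prime`, `duplication`), `length_nt`, `length_codons`,
#'   `position` (alignment columns, 1-based), `tmh_in_modified_region`.
#' @export
cox2_mod_scan_one <- function(query_cox2, reference_cox2, min_codons = 30) {
  pq <- sub("\\*$", "", translate_cds(trim_to_frame(query_cox2)))
  pr <- sub("\\*$", "", translate_cds(trim_to_frame(reference_cox2)))
  al <- global_align(pq, pr, mode = "aa")
  qa <- split_chars(al$seq_a)
  ra <- split_chars(al$seq_b)
  ins <- ra == "-"   # query has residue, reference gapped
  r <- rle(ins)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  kind <- "none"; len_cod <- 0L; posn <- c(NA_integer_, NA_integer_)
  region_aa <- ""
  last_ref <- max(which(ra != "-"))
  for (j in which(r$values & r$lengths >= min_codons)) {
    s <- starts[j]; e <- ends[j]
    if (s > last_ref) {
      kind <- "extension_3prime"
    } else {
      kind <- "insertion"
      seg <- paste(qa[s:e], collapse = "")
      segal <- global_align(seg, pr, mode = "aa")
      idr <- p_distance(segal, gene = "seg")
      if (!is.na(idr$p) && idr$sites_compared >= min_codons &&
          (1 - idr$p) >= 0.5) kind <- "duplication"
    }
    len_cod <- e - s + 1L
    posn <- c(s, e)
    region_aa <- paste(qa[s:e], collapse = "")
    break
  }
  tmh_n <- 0L
  if (kind != "none" && nchar(region_aa) >= 19) {
    tmh_n <- nrow(tmh_scan(region_aa))
  }
  structure(list(kind = kind, length_nt = 3L * len_cod,
                 length_codons = len_cod, position = posn,
                 tmh_in_modified_region = tmh_n),
            class = "cox2_mod_report")
}

#' @export
print.cox2_mod_report <- function(x, ...) {
  cat(sprintf("cox2 modification: %s (%d codons / %d nt), TMH in region: %d\n",
              x$kind, x$length_codons, x$length_nt, x$tmh_in_modified_region))
  invisible(x)
}

#' Scan F and M cox2 genes against a reference
#'
#' @param f_cox2,m_cox2,reference_cox2 DNA strings.
#' @param min_codons Modification threshold in codons.
#' @return List with elements `F` and `M`, each a `cox2_mod_report`.
#' @export
cox2_mod_scan <- function(f_cox2, m_cox2, reference_cox2, min_codons = 30) {
  list(F = cox2_mod_scan_one(f_cox2, reference_cox2, min_codons),
       M = cox2_mod_scan_one(m_cox2, reference_cox2, min_codons))
}

# ---- transmembrane-helix heuristic --------------------------------------

# Kyte-Doolittle hydropathy index.
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                   Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                   L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                   S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Transmembrane-helix scan by sliding-window hydropathy
#'
#' Kyte-Doolittle heuristic: every window of `window` residues with mean
#' hydropathy above `cutoff` is a candidate; overlapping candidates are
#' merged into segments.
#'
#' @param protein Protein string (length >= window).
#' @param window Window length (default 19).
#' @param cutoff Mean-hydropathy threshold (default 1.6).
#' @return Data frame of segments: `start`, `end` (0-based half-open
#'   protein coordinates), `mean_hydropathy` over the merged segment.
#' @export
tmh_scan <- function(protein, window = 19, cutoff = 1.6) {
  ch <- split_chars(toupper(protein))
  n <- length(ch)
  empty <- data.frame(start = integer(), end = integer(),
                      mean_hydropathy = numeric())
  if (n < window) return(empty)
  h <- unname(KD_HYDROPATHY[ch])
  h[is.na(h)] <- 0
  cs <- c(0, cumsum(h))
  wm <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  hit <- which(wm > cutoff)
  if (!length(hit)) return(empty)
  # merge overlapping windows
  iv <- cbind(hit - 1L, hit - 1L + window)   # 0-based half-open
  merged <- list(iv[1, ])
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    last <- merged[[length(merged)]]
    if (iv[i, 1] < last[2]) merged[[length(merged)]][2] <- iv[i, 2]
    else merged[[length(merged) + 1L]] <- iv[i, ]
  }
  out <- do.call(rbind, lapply(merged, function(seg) {
    data.frame(start = seg[1], end = seg[2],
               mean_hydropathy = mean(h[(seg[1] + 1):seg[2]]))
  }))
  out
}
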