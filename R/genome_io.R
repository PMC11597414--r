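# Shared data model: annotated circular mitogenomes with normalized gene
# symbols. Coordinates are 0-based half-open internally; GenBank's 1-based
# inclusive convention is converted at the boundary. On circular genomes a
# feature with end <= start spans the origin.

PCG_SYMBOLS  <- c("cox1", "cox2", "cox3", "cob", "atp6", "atp8",
                  "nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6")
RRNA_SYMBOLS <- c("rrnS", "rrnL")
TRNA_SYMBOLS <- c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH",
                  "trnI", "trnK", "trnL1", "trnL2", "trnM", "trnN", "trnP",
                  "trnQ", "trnR", "trnS1", "trnS2", "trnT", "trnV", "trnW",
                  "trnY")
CANONICAL_SYMBOLS <- c(PCG_SYMBOLS, RRNA_SYMBOLS, TRNA_SYMBOLS)

#' Construct a gene feature
#'
#' @param gene Normalized gene symbol (see [normalize_gene_symbol()]), or
#'   `"unknown:<raw>"` for unmappable names.
#' @param cls Feature class: `"PCG"`, `"tRNA"` or `"rRNA"`.
#' @param start,end 0-based half-open coordinates; `end <= start` encodes an
#'   origin-spanning feature on a circular genome.
#' @param strand `"+"` or `"-"`.
#' @param incomplete_stop Logical; `TRUE` when a coding sequence ends with an
#'   incomplete stop codon (terminal T or TA completed by polyadenylation).
#' @param codon_start Reading-frame offset (1, 2 or 3), as in GenBank.
#' @return A one-row data frame usable as a feature-table row.
#' @export
gene_feature <- function(gene, cls, start, end, strand = "+",
                         incomplete_stop = FALSE, codon_start = 1L) {
  stopifnot(cls %in% c("PCG", "tRNA", "rRNA"), strand %in% c("+", "-"))
  data.frame(gene = gene, cls = cls, start = as.integer(start),
             end = as.integer(end), strand = strand,
             incomplete_stop = incomplete_stop,
             codon_start = as.integer(codon_start),
             stringsAsFactors = FALSE)
}

#' Construct an annotated mitogenome
#'
#' The shared container for all downstream analyses: a (usually circular)
#' mitochondrial genome sequence plus an ordered feature table and a
#' sex-type label (F = female-transmitted, M = male-transmitted).
#'
#' @param id Genome identifier (accession or synthetic id).
#' @param species Species name.
#' @param sex_type `"F"`, `"M"` or `"unknown"`.
#' @param sequence Upper-case IUPAC DNA string.
#' @param features Data frame of features as built by [gene_feature()]
#'   (rbind of rows); sorted by start coordinate on construction.
#' @param topology `"circular"` or `"linear"`.
#' @param source Provenance string (accession or `"synthetic"`).
#' @return An object of class `mito_genome`.
#' @export
mito_genome <- function(id, species, sex_type = "unknown", sequence,
                        features = NULL, topology = "circular",
                        source = "unknown") {
  stopifnot(nchar(sequence) > 0,
            sex_type %in% c("F", "M", "unknown"),
            topology %in% c("circular", "linear"))
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (is.null(features) || nrow(features) == 0) {
    features <- gene_feature("none", "PCG", 0, 1)[0, ]
  } else {
    bad <- features$start < 0 | features$start >= L |
      features$end < 0 | features$end > L
    if (any(bad)) stop("feature coordinates outside [0, genome length)")
    if (topology == "linear" && any(features$end <= features$start))
      stop("origin-spanning feature on a linear genome")
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(id = id, species = species, sex_type = sex_type,
                 topology = topology, sequence = sequence,
                 features = features, source = source),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s  %s [%s]  %s, %d bp, %d features (%s)\n",
              x$id, x$species, x$sex_type, x$topology, nchar(x$sequence),
              nrow(x$features), x$source))
  invisible(x)
}

#' Genome length in nucleotides
#' @param g A `mito_genome`.
#' @return Integer length.
#' @export
genome_length <- function(g) nchar(g$sequence)

feature_lengths <- function(g) {
  span_len(g$features$start, g$features$end, genome_length(g))
}

# ---- gene-symbol normalization ------------------------------------------

aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

default_synonyms <- function() {
  syn <- c(
    "COI" = "cox1", "CO1" = "cox1", "COX1" = "cox1", "COXI" = "cox1",
    "COII" = "cox2", "CO2" = "cox2", "COX2" = "cox2", "COXII" = "cox2",
    "COIII" = "cox3", "CO3" = "cox3", "COX3" = "cox3", "COXIII" = "cox3",
    "CYTB" = "cob", "CYB" = "cob", "COB" = "cob", "CYTOCHROMEB" = "cob",
    "ATP6" = "atp6", "ATPASE6" = "atp6", "ATP8" = "atp8", "ATPASE8" = "atp8",
    "ND1" = "nad1", "ND2" = "nad2", "ND3" = "nad3", "ND4" = "nad4",
    "ND4L" = "nad4l", "ND5" = "nad5", "ND6" = "nad6",
    "NAD1" = "nad1", "NAD2" = "nad2", "NAD3" = "nad3", "NAD4" = "nad4",
    "NAD4L" = "nad4l", "NAD5" = "nad5", "NAD6" = "nad6", "NADH1" = "nad1",
    "NADH2" = "nad2", "NADH3" = "nad3", "NADH4" = "nad4", "NADH4L" = "nad4l",
    "NADH5" = "nad5", "NADH6" = "nad6",
    "12S" = "rrnS", "12SRRNA" = "rrnS", "SRRNA" = "rrnS", "S-RRNA" = "rrnS",
    "RRNS" = "rrnS", "12SRIBOSOMALRNA" = "rrnS", "SSU" = "rrnS",
    "16S" = "rrnL", "16SRRNA" = "rrnL", "LRRNA" = "rrnL", "L-RRNA" = "rrnL",
    "RRNL" = "rrnL", "16SRIBOSOMALRNA" = "rrnL", "LSU" = "rrnL")
  syn
}

load_synonyms <- function(path = NULL) {
  syn <- default_synonyms()
  if (is.null(path)) {
    path <- system.file("extdata", "gene_synonyms.tsv", package = "duimito")
    if (!nzchar(path)) path <- NULL
  }
  if (!is.null(path) && file.exists(path)) {
    tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    syn[toupper(tab$raw)] <- tab$symbol
  }
  syn
}

#' Normalize a raw gene name to the canonical symbol vocabulary
#'
#' Maps annotation spellings ("COI", "ND4L", "12S rRNA", "tRNA-Ser(AGN)", ...)
#' onto the closed vocabulary cox1..cox3, cob, nad1..nad6, nad4l, atp6, atp8,
#' rrnS, rrnL, trnA..trnY with trnL1/trnL2 and trnS1/trnS2 distinguished by
#' their codon families (L1 = CUN, L2 = UUR; S1 = AGN, S2 = UCN).
#'
#' @param raw Raw gene/product name.
#' @param synonyms Named character vector of extra synonym mappings
#'   (names = cleaned raw form, values = canonical symbol).
#' @return The canonical symbol, or `"unknown:<raw>"` (with a warning) when
#'   the name cannot be mapped.
#' @export
normalize_gene_symbol <- function(raw, synonyms = load_synonyms()) {
  if (is.na(raw) || !nzchar(raw)) return("unknown:")
  key <- toupper(gsub("[ _]", "", raw))
  if (raw %in% CANONICAL_SYMBOLS) return(raw)
  low <- CANONICAL_SYMBOLS[match(tolower(raw), tolower(CANONICAL_SYMBOLS))]
  if (!is.na(low)) return(low)
  if (key %in% names(synonyms)) return(unname(synonyms[key]))
  # tRNA forms: TRNA-SER(AGN), TRN S, TRNS1, TRNA-LEU(UUR) ...
  m <- regmatches(key, regexec("^TRNA?-?([A-Z]{3})(\\(([ACGTU]{3}|AGN|UCN|CUN|UUR)\\))?$", key))[[1]]
  if (length(m)) {
    aa <- aa3to1[m[2]]
    tag <- m[4]
    if (!is.na(aa)) {
      if (aa == "L") {
        if (tag %in% c("CUN", "UAG", "TAG")) return("trnL1")
        if (tag %in% c("UUR", "UAA", "TAA")) return("trnL2")
      } else if (aa == "S") {
        if (tag %in% c("AGN", "UCU", "GCU", "TCT")) return("trnS1")
        if (tag %in% c("UCN", "UGA", "TGA")) return("trnS2")
      } else {
        return(paste0("trn", aa))
      }
    }
  }
  m <- regmatches(key, regexec("^TRNA?-?([A-Z])([12])?$", key))[[1]]
  if (length(m) && m[2] %in% c(LETTERS)) {
    sym <- paste0("trn", m[2], m[3])
    if (sym %in% TRNA_SYMBOLS) return(sym)
  }
  warning(sprintf("unmappable gene name '%s'", raw), call. = FALSE)
  paste0("unknown:", raw)
}

infer_cls <- function(key) {
  switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA", "PCG")
}

# ---- GenBank flat-file reader/writer ------------------------------------

parse_gb_location <- function(loc) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(loc, ",")[[1]]
    first <- as.integer(strsplit(parts[1], "\\.\\.")[[1]])
    last  <- as.integer(strsplit(parts[length(parts)], "\\.\\.")[[1]])
    return(list(start = first[1] - 1L, end = last[2], strand = strand))
  }
  ab <- as.integer(strsplit(loc, "\\.\\.")[[1]])
  if (length(ab) == 1) ab <- c(ab, ab)
  list(start = ab[1] - 1L, end = ab[2], strand = strand)
}

#' Read a single-record GenBank flat file as a mitogenome
#'
#' Parses LOCUS/ORGANISM/FEATURES/ORIGIN of a single GenBank record, keeps
#' CDS/tRNA/rRNA features, converts coordinates to 0-based half-open and
#' normalizes gene names to the canonical vocabulary. The sex-type label is
#' taken from a `/sex="F"` (or `/note="sex_type:F"`) qualifier on the
#' `source` feature when present, else from a `_F` / `_M` filename suffix,
#' else `"unknown"`.
#'
#' @param path Path to a GenBank flat file.
#' @param synonyms Optional synonym table (see [normalize_gene_symbol()]).
#' @return A [mito_genome()].
#' @export
read_genbank <- function(path, synonyms = load_synonyms()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file (no LOCUS line): ", path)
  topology <- if (grepl("circular", locus[1], ignore.case = TRUE))
    "circular" else "linear"
  id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]
  org <- grep("^  ORGANISM", lines, value = TRUE)
  species <- if (length(org)) trimws(sub("^  ORGANISM", "", org[1])) else ""

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(fstart) || !length(ostart)) stop("malformed GenBank file: ", path)
  fl <- lines[(fstart + 1L):(ostart - 1L)]

  # group feature lines: a new feature starts with key at column 6
  idx <- grep("^ {5}\\S", fl)
  if (!length(idx)) stop("no features in GenBank file: ", path)
  ends <- c(idx[-1] - 1L, length(fl))
  sex <- "unknown"
  rows <- list()
  for (k in seq_along(idx)) {
    block <- fl[idx[k]:ends[k]]
    key <- strsplit(trimws(block[1]), "\\s+")[[1]][1]
    body <- paste(trimws(c(sub("^ {5}\\S+\\s*", "", block[1]), block[-1])),
                  collapse = "\n")
    # location = text up to first qualifier
    loctxt <- strsplit(body, "\n/", fixed = TRUE)[[1]][1]
    loctxt <- gsub("\\s", "", loctxt)
    quals <- regmatches(body, gregexpr('/([A-Za-z_]+)=(\"[^\"]*\"|[^\\s\n]+)', body))[[1]]
    qv <- list()
    for (q in quals) {
      nm <- sub("^/([A-Za-z_]+)=.*$", "\\1", q)
      vl <- sub("^/[A-Za-z_]+=", "", q)
      qv[[nm]] <- gsub('"', "", gsub("\n\\s*", " ", vl))
    }
    if (key == "source") {
      if (!is.null(qv$organism) && !nzchar(species)) species <- qv$organism
      if (!is.null(qv$sex) && toupper(qv$sex) %in% c("F", "M"))
        sex <- toupper(qv$sex)
      if (!is.null(qv$note)) {
        m <- regmatches(qv$note, regexec("sex_?type[:=]\\s*([FM])", qv$note,
                                         ignore.case = TRUE))[[1]]
        if (length(m)) sex <- toupper(m[2])
      }
      next
    }
    if (!key %in% c("CDS", "tRNA", "rRNA")) next
    loc <- tryCatch(parse_gb_location(loctxt),
                    error = function(e) stop("unparseable location '",
                                             loctxt, "' in ", path))
    raw <- qv$gene %||% qv$product %||% ""
    sym <- normalize_gene_symbol(raw, synonyms)
    cs <- as.integer(qv$codon_start %||% "1")
    rows[[length(rows) + 1L]] <-
      gene_feature(sym, infer_cls(key), loc$start, loc$end, loc$strand,
                   codon_start = cs)
  }
  features <- do.call(rbind, rows)
  seq <- paste(gsub("[^A-Za-z]", "", lines[(ostart + 1L):length(lines)]),
               collapse = "")
  seq <- toupper(seq)
  seq <- sub("//$", "", seq)
  if (!nzchar(seq)) stop("no sequence in GenBank file: ", path)
  L <- nchar(seq)
  # flag incomplete stops on CDS features
  if (!is.null(features)) {
    len <- span_len(features$start, features$end, L)
    features$incomplete_stop <- features$cls == "PCG" & (len %% 3L) != 0L
  }
  if (sex == "unknown") {
    base <- sub("\\.[A-Za-z]+$", "", basename(path))
    if (grepl("_F$", base)) sex <- "F"
    if (grepl("_M$", base)) sex <- "M"
  }
  mito_genome(id = id, species = species, sex_type = sex, sequence = seq,
              features = features, topology = topology, source = id)
}

#' Write a mitogenome as a GenBank-style flat file
#'
#' Inverse of [read_genbank()]: coordinates are converted back to 1-based
#' inclusive, origin-spanning features to `join()` locations, and the
#' sex-type to a `/sex` qualifier on the source feature.
#'
#' @param g A [mito_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(g, path) {
  L <- genome_length(g)
  top <- if (g$topology == "circular") "circular" else "linear"
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s   INV", g$id, L, top),
           sprintf("DEFINITION  %s mitochondrion %s-type.", g$species, g$sex_type),
           sprintf("  ORGANISM  %s", g$species),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", L),
           sprintf('                     /organism="%s"', g$species))
  if (g$sex_type %in% c("F", "M"))
    out <- c(out, sprintf('                     /sex="%s"', g$sex_type))
  key_of <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA")
  for (i in seq_len(nrow(g$features))) {
    f <- g$features[i, ]
    loc <- if (f$end > f$start) sprintf("%d..%d", f$start + 1L, f$end)
           else sprintf("join(%d..%d,1..%d)", f$start + 1L, L, f$end)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    out <- c(out,
             sprintf("     %-16s%s", key_of[[f$cls]], loc),
             sprintf('                     /gene="%s"', f$gene))
    if (f$codon_start != 1L)
      out <- c(out, sprintf("                     /codon_start=%d", f$codon_start))
  }
  out <- c(out, "ORIGIN")
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    chunk <- substr(g$sequence, p, min(p + 59L, L))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, paste(tolower(groups), collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Read a mitogenome from FASTA plus a tab-delimited feature table
#'
#' @param fasta_path FASTA file with a single sequence.
#' @param table_path Tab-delimited table with columns `gene`, `class`
#'   (PCG/tRNA/rRNA), `start`, `end` (1-based inclusive) and `strand`.
#' @param species,sex_type,topology Metadata (see [mito_genome()]).
#' @return A [mito_genome()].
#' @export
read_fasta_features <- function(fasta_path, table_path, species = "",
                                sex_type = "unknown", topology = "circular") {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(ss) != 1) stop("expected a single FASTA record")
  tab <- read.delim(table_path, stringsAsFactors = FALSE)
  need <- c("gene", "class", "start", "end", "strand")
  if (!all(need %in% names(tab))) stop("feature table must have columns: ",
                                       paste(need, collapse = ", "))
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    gene_feature(normalize_gene_symbol(tab$gene[i]), tab$class[i],
                 tab$start[i] - 1L, tab$end[i], tab$strand[i])
  })
  mito_genome(id = names(ss)[1], species = species, sex_type = sex_type,
              sequence = as.character(ss[[1]]), features = do.call(rbind, rows),
              topology = topology, source = basename(fasta_path))
}

#' Serialize a mitogenome to JSON (and back)
#'
#' @param g A [mito_genome()].
#' @param path Output (input) path.
#' @return `path` invisibly; `read_genome_json()` returns a [mito_genome()].
#' @export
write_genome_json <- function(g, path) {
  jsonlite::write_json(unclass(g), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_genome_json
#' @export
read_genome_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- as.data.frame(x$features, stringsAsFactors = FALSE)
  mito_genome(id = x$id, species = x$species, sex_type = x$sex_type,
              sequence = x$sequence, features = feats, topology = x$topology,
              source = x$source)
}

# ---- completeness, extraction, rotation ---------------------------------

#' Check gene-content completeness of a mitogenome
#'
#' A venerid-type mitogenome is complete when all 13 protein-coding gene
#' identities, both rRNAs and all 22 canonical tRNA identities are present
#' (serine and leucine isoacceptors counted as distinct identities;
#' duplications are allowed and reported).
#'
#' @param g A [mito_genome()].
#' @return A list of class `completeness_report` with counts `n_pcg`,
#'   `n_trna`, `n_rrna`, character vectors `missing` and `duplicated`, and
#'   logical `is_complete`.
#' @export
check_completeness <- function(g) {
  f <- g$features
  syms <- f$gene
  tab <- table(syms[syms %in% CANONICAL_SYMBOLS])
  present <- names(tab)
  rep <- list(
    n_pcg = sum(f$cls == "PCG"),
    n_trna = sum(f$cls == "tRNA"),
    n_rrna = sum(f$cls == "rRNA"),
    missing = setdiff(CANONICAL_SYMBOLS, present),
    duplicated = names(tab)[tab > 1])
  rep$is_complete <- length(rep$missing) == 0L
  class(rep) <- "completeness_report"
  rep
}

#' @export
print.completeness_report <- function(x, ...) {
  cat(sprintf("PCG %d  tRNA %d  rRNA %d  complete: %s\n",
              x$n_pcg, x$n_trna, x$n_rrna, x$is_complete))
  if (length(x$missing)) cat("missing:", paste(x$missing, collapse = " "), "\n")
  if (length(x$duplicated)) cat("duplicated:",
                                paste(x$duplicated, collapse = " "), "\n")
  invisible(x)
}

#' Extract the sequence of an annotated gene
#'
#' Returns the forward-strand (coding) sequence of the requested gene:
#' reverse-complemented for minus-strand features and wrap-aware for
#' origin-spanning features on circular genomes.
#'
#' @param g A [mito_genome()].
#' @param gene Canonical gene symbol.
#' @param occurrence Which copy to take when the gene is duplicated
#'   (1 = first in genome order).
#' @return DNA string.
#' @export
extract_gene_seq <- function(g, gene, occurrence = 1L) {
  hits <- which(g$features$gene == gene)
  if (length(hits) < occurrence)
    stop(sprintf("gene '%s' (occurrence %d) not found in %s",
                 gene, occurrence, g$id))
  f <- g$features[hits[occurrence], ]
  s <- seq_span(g$sequence, f$start, f$end, g$topology == "circular")
  if (f$strand == "-") s <- revcomp(s)
  s
}

#' Rotate the origin of a circular genome
#'
#' Moves the sequence origin forward by `k` nucleotides and shifts all
#' feature coordinates accordingly. Gene extraction is invariant under
#' rotation.
#'
#' @param g A circular [mito_genome()].
#' @param k Rotation offset in nucleotides.
#' @return The rotated `mito_genome`.
#' @export
rotate_genome <- function(g, k) {
  stopifnot(g$topology == "circular")
  L <- genome_length(g)
  k <- ((k %% L) + L) %% L
  if (k == 0) return(g)
  seq2 <- paste0(substr(g$sequence, k + 1L, L), substr(g$sequence, 1L, k))
  f <- g$features
  if (nrow(f)) {
    f$start <- (f$start - k) %% L
    f$end <- (f$end - k) %% L
    f$end[f$end == 0L] <- L
  }
  mito_genome(g$id, g$species, g$sex_type, seq2, f, g$topology, g$source)
}

#' Write gene sequences to FASTA
#'
#' @param g A [mito_genome()].
#' @param genes Character vector of gene symbols (default: all features).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genes_fasta <- function(g, path, genes = NULL) {
  if (is.null(genes)) genes <- g$features$gene
  seqs <- vapply(genes, function(gn) extract_gene_seq(g, gn), character(1))
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- paste(g$id, genes, sep = "|")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
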