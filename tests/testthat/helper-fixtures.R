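# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# one default simulated F/M pair, reused across test files
shared_pair <- function() {
  if (is.null(.fixture_env$pair))
    .fixture_env$pair <- simulate_pair(sim_config(seed = 101))
  .fixture_env$pair
}

# a full canonical feature set laid end-to-end on a synthetic sequence
canonical_feature_genome <- function(drop = character(0),
                                     duplicate = character(0)) {
  syms <- c(duimito:::PCG_SYMBOLS, duimito:::RRNA_SYMBOLS,
            duimito:::TRNA_SYMBOLS)
  syms <- setdiff(syms, drop)
  syms <- c(syms, duplicate)
  cls <- ifelse(syms %in% duimito:::PCG_SYMBOLS, "PCG",
         ifelse(syms %in% duimito:::RRNA_SYMBOLS, "rRNA", "tRNA"))
  len <- ifelse(cls == "PCG", 30L, ifelse(cls == "rRNA", 60L, 21L))
  start <- cumsum(c(0L, len[-length(len)]))
  feats <- do.call(rbind, lapply(seq_along(syms), function(i)
    gene_feature(syms[i], cls[i], start[i], start[i] + len[i])))
  set.seed(7)
  mito_genome("FIXT", "Fixturia canonica", "F",
              sequence = rand_dna(sum(len) + 50),
              features = feats, topology = "circular", source = "synthetic")
}

# random in-frame CDS with no internal stop (table 5), as a string
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  code <- Biostrings::getGeneticCode("5")
  sense <- names(code)[code != "*"]
  body <- sample(setdiff(sense, c("ATG")), n_codons - 2, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

write_test_genbank <- function(path) {
  seqs <- paste(rep("ACGT", 30), collapse = "")  # 120 nt
  lines <- c(
    "LOCUS       TEST001 120 bp    DNA     circular   INV",
    "DEFINITION  Testia minima mitochondrion.",
    "  ORGANISM  Testia minima",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    '                     /organism="Testia minima"',
    '                     /sex="F"',
    "     CDS             1..12",
    '                     /gene="COI"',
    "     tRNA            complement(20..30)",
    '                     /product="tRNA-Met"',
    "     rRNA            40..60",
    '                     /product="12S ribosomal RNA"',
    "     CDS             join(113..120,1..4)",
    '                     /gene="ND1"',
    "ORIGIN",
    paste0("        1 ", paste(substring(tolower(seqs),
                                         seq(1, 60, 10), seq(10, 60, 10)),
                               collapse = " ")),
    paste0("       61 ", paste(substring(tolower(seqs),
                                         seq(61, 120, 10), seq(70, 120, 10)),
                               collapse = " ")),
    "//")
  writeLines(lines, path)
  path
}
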