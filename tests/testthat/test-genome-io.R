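# Genome I/O: GenBank parsing, coordinate conventions, symbol
# normalization, completeness, gene extraction, rotation, round-trips.

test_that("GenBank records parse with 0-based half-open coordinates and normalized symbols", {
  path <- write_test_genbank(tempfile(fileext = ".gb"))
  g <- read_genbank(path)
  expect_s3_class(g, "mito_genome")
  expect_equal(g$species, "Testia minima")
  expect_equal(g$sex_type, "F")
  expect_equal(g$topology, "circular")
  expect_equal(nchar(g$sequence), 120)

  f <- g$features
  cox1 <- f[f$gene == "cox1", ]
  expect_equal(c(cox1$start, cox1$end), c(0, 12))   # 1..12 one-based
  trnm <- f[f$gene == "trnM", ]
  expect_equal(trnm$strand, "-")
  expect_equal(trnm$cls, "tRNA")
  expect_equal(f[f$gene == "rrnS", "cls"], "rRNA")
  nad1 <- f[f$gene == "nad1", ]
  expect_equal(c(nad1$start, nad1$end), c(112, 4))  # origin-spanning join
  # 1-based inclusive lengths equal end - start (mod L)
  L <- genome_length(g)
  lens <- ifelse(f$end > f$start, f$end - f$start, L - f$start + f$end)
  expect_equal(lens[f$gene == "nad1"], 12)
})

test_that("sex type falls back to filename suffix, else unknown", {
  path <- file.path(tempdir(), "whatever_M.gb")
  write_test_genbank(path)
  txt <- readLines(path)
  writeLines(txt[!grepl("/sex=", txt)], path)
  expect_equal(read_genbank(path)$sex_type, "M")
  path2 <- file.path(tempdir(), "whatever.gb")
  writeLines(txt[!grepl("/sex=", txt)], path2)
  expect_equal(read_genbank(path2)$sex_type, "unknown")
})

test_that("gene symbols normalize through synonyms, tRNA isoacceptor tags and unknowns warn", {
  expect_equal(normalize_gene_symbol("COI"), "cox1")
  expect_equal(normalize_gene_symbol("ND4L"), "nad4l")
  expect_equal(normalize_gene_symbol("CYTB"), "cob")
  expect_equal(normalize_gene_symbol("s-rRNA"), "rrnS")
  expect_equal(normalize_gene_symbol("16S ribosomal RNA"), "rrnL")
  expect_equal(normalize_gene_symbol("tRNA-Ser(AGN)"), "trnS1")
  expect_equal(normalize_gene_symbol("tRNA-Ser(UCN)"), "trnS2")
  expect_equal(normalize_gene_symbol("tRNA-Leu(UUR)"), "trnL2")
  expect_equal(normalize_gene_symbol("tRNA-Ala"), "trnA")
  expect_equal(normalize_gene_symbol("trnK"), "trnK")
  expect_warning(out <- normalize_gene_symbol("mystery ORF"),
                 "unmappable")
  expect_equal(out, "unknown:mystery ORF")
})

test_that("completeness counts the 13+2+22 vocabulary with duplications allowed", {
  g0 <- mito_genome("E", "sp", "F", sequence = strrep("A", 100))
  r0 <- check_completeness(g0)
  expect_false(r0$is_complete)
  expect_length(r0$missing, 37)
  expect_equal(r0$n_pcg, 0)

  g1 <- canonical_feature_genome()
  r1 <- check_completeness(g1)
  expect_true(r1$is_complete)
  expect_equal(r1$n_pcg, 13)
  expect_equal(r1$n_rrna, 2)
  expect_equal(r1$n_trna, 22)

  g2 <- canonical_feature_genome(drop = "trnM")
  r2 <- check_completeness(g2)
  expect_false(r2$is_complete)
  expect_equal(r2$missing, "trnM")

  g3 <- canonical_feature_genome(duplicate = "trnK")
  r3 <- check_completeness(g3)
  expect_true(r3$is_complete)
  expect_equal(r3$duplicated, "trnK")

  # rrnS duplication as in an M genome with a duplicated small rRNA
  g4 <- canonical_feature_genome(duplicate = "rrnS")
  expect_equal(check_completeness(g4)$duplicated, "rrnS")
})

test_that("gene extraction honors strand, wrap-around and rotation invariance", {
  set.seed(11)
  s <- rand_dna(100)
  feats <- rbind(gene_feature("cox1", "PCG", 0, 6, "+"),
                 gene_feature("nad2", "PCG", 10, 16, "-"),
                 gene_feature("nad1", "PCG", 97, 3, "+"))
  g <- mito_genome("R1", "sp", "F", s, feats)
  expect_equal(extract_gene_seq(g, "cox1"), substr(s, 1, 6))
  expect_equal(extract_gene_seq(g, "nad2"), revcomp(substr(s, 11, 16)))
  expect_equal(extract_gene_seq(g, "nad1"),
               paste0(substr(s, 98, 100), substr(s, 1, 3)))
  expect_error(extract_gene_seq(g, "atp6"), "not found")

  # rotating so the origin-spanning feature becomes contiguous gives the
  # same string, for several rotations
  for (k in c(3, 17, 50, 97)) {
    gr <- rotate_genome(g, k)
    for (gn in c("cox1", "nad2", "nad1"))
      expect_equal(extract_gene_seq(gr, gn), extract_gene_seq(g, gn),
                   info = sprintf("gene %s rotation %d", gn, k))
  }
})

test_that("GenBank and JSON writers round-trip a simulated genome", {
  pair <- shared_pair()
  for (g in list(pair$F, pair$M)) {
    gb <- tempfile(fileext = ".gb")
    write_genbank(g, gb)
    g2 <- read_genbank(gb)
    expect_equal(g2$sequence, g$sequence)
    expect_equal(g2$sex_type, g$sex_type)
    expect_equal(g2$species, g$species)
    expect_equal(g2$topology, "circular")
    expect_equal(g2$features[, c("gene", "cls", "start", "end", "strand")],
                 g$features[, c("gene", "cls", "start", "end", "strand")])
    js <- tempfile(fileext = ".json")
    write_genome_json(g, js)
    g3 <- read_genome_json(js)
    expect_equal(g3$sequence, g$sequence)
    expect_equal(g3$features$start, g$features$start)
  }
})

test_that("FASTA plus feature table loads with 1-based inclusive conversion", {
  fa <- tempfile(fileext = ".fasta")
  tb <- tempfile(fileext = ".tsv")
  set.seed(5)
  s <- rand_dna(60)
  writeLines(c(">toy", s), fa)
  writeLines(c("gene\tclass\tstart\tend\tstrand",
               "COI\tPCG\t1\t30\t+",
               "tRNA-Met\ttRNA\t35\t55\t-"), tb)
  g <- read_fasta_features(fa, tb, species = "Toyia", sex_type = "M")
  expect_equal(g$features$gene, c("cox1", "trnM"))
  expect_equal(g$features$start, c(0, 34))
  expect_equal(g$features$end, c(30, 55))
  expect_equal(extract_gene_seq(g, "cox1"), substr(s, 1, 30))
})
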