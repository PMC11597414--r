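# Synthetic-data generator: determinism, divergence control, planted
# structure, rearrangements, clade scenarios.

test_that("the generator is deterministic under a fixed seed", {
  p1 <- simulate_pair(sim_config(seed = 11, nt_divergence = 0.05))
  p2 <- simulate_pair(sim_config(seed = 11, nt_divergence = 0.05))
  expect_identical(p1$F$sequence, p2$F$sequence)
  expect_identical(p1$M$sequence, p2$M$sequence)
  expect_identical(p1$truth$nt_divergence_realized,
                   p2$truth$nt_divergence_realized)
  p3 <- simulate_pair(sim_config(seed = 12, nt_divergence = 0.05))
  expect_false(identical(p1$F$sequence, p3$F$sequence))
})

test_that("zero divergence leaves F and M identical apart from planned edits", {
  cfg0 <- sim_config(seed = 21, nt_divergence = 0, m_lur_extra = 0)
  p <- simulate_pair(cfg0)
  expect_identical(p$F$sequence, p$M$sequence)
  expect_equal(p$truth$nt_divergence_realized, 0)

  cfg1 <- sim_config(seed = 21, nt_divergence = 0, m_lur_extra = 0,
                     rearrangement_plan = list(
                       list(gene = "trnM", action = "move", after = "trnF")))
  p1 <- simulate_pair(cfg1)
  expect_equal(p1$truth$moved, "trnM")
  oF <- gene_order_of(p1$F); oM <- gene_order_of(p1$M)
  r <- compare_orders(oF, oM)
  expect_equal(r$transposed, "trnM")
  expect_equal(r$breakpoint_distance, 3)
  # all genes otherwise intact
  expect_true(check_completeness(p1$M)$is_complete)
})

test_that("emitted genomes are complete, forward-strand and within venerid size range", {
  p <- shared_pair()
  for (g in list(p$F, p$M)) {
    expect_true(check_completeness(g)$is_complete)
    expect_true(all(g$features$strand == "+"))
    expect_gte(genome_length(g), 15000)
    expect_lte(genome_length(g), 26000)
    # every PCG translates without internal stops
    for (gn in duimito:::PCG_SYMBOLS) {
      aa <- translate_cds(extract_gene_seq(g, gn))
      expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)),
                   info = paste(g$id, gn))
    }
  }
  expect_gt(genome_length(p$M), genome_length(p$F))  # longer M LUR
})

test_that("realized divergence hits the configured target", {
  for (tgt in c(0.05, 0.20)) {
    p <- simulate_pair(sim_config(seed = round(100 * tgt), nt_divergence = tgt,
                                  m_lur_extra = 0))
    meas <- whole_genome_p_distance(p$F, p$M, method = "positional")$p
    expect_equal(meas, p$truth$nt_divergence_realized, tolerance = 1e-12)
    expect_lte(abs(meas - tgt), 0.005 + 1e-9)
  }
})

test_that("gene duplication plans produce duplicated features", {
  cfg <- sim_config(seed = 31, nt_divergence = 0.02,
                    rearrangement_plan = list(
                      list(gene = "trnK", action = "duplicate",
                           after = "rrnS")))
  p <- simulate_pair(cfg)
  rep <- check_completeness(p$M)
  expect_true(rep$is_complete)
  expect_true("trnK" %in% rep$duplicated)
  expect_equal(sum(p$M$features$gene == "trnK"), 2)
  # both copies extract to the same sequence at zero-ish divergence
  expect_equal(extract_gene_seq(p$M, "trnK", 1),
               extract_gene_seq(p$M, "trnK", 2))
})

test_that("purifying selection in the generator keeps dN/dS below one", {
  p <- shared_pair()   # omega = 0.1 on every PCG
  om <- vapply(c("cox1", "cob", "nad5"), function(gn)
    suppressWarnings(gene_dnds(p$F, p$M, gn))$omega, numeric(1))
  expect_true(all(om < 1))
})

test_that("clade scenarios emit the declared true trees and labels", {
  cl <- simulate_clade("taxon_joining", n_species = 2, seed = 41)
  expect_length(cl$genomes, 5)  # 2 species x 2 sexes + outgroup
  expect_equal(unname(cl$truth$expected),
               rep("taxon_joining", 2))
  tru <- ape::read.tree(text = cl$truth$tree)
  expect_setequal(tru$tip.label,
                  c("spA__F", "spA__M", "spB__F", "spB__M", "Outgroup"))

  cg <- simulate_clade("gender_joining", n_species = 2, seed = 42)
  expect_equal(unname(cg$truth$expected), rep("gender_joining", 2))

  cm <- simulate_clade("masculinization", n_species = 2, seed = 43)
  expect_equal(unname(cm$truth$expected["spA"]), "taxon_joining")
  expect_equal(unname(cm$truth$expected["spB"]), "masculinization_signature")
  expect_error(simulate_clade("masculinization", n_species = 3, seed = 1),
               "exactly 2")
  expect_error(simulate_clade("taxon_joining", n_species = 1, seed = 1),
               "at least 2")
})

test_that("one clade run flows through distances, NJ and classification", {
  cl <- simulate_clade("gender_joining", n_species = 2, seed = 51)
  d <- p_distance_matrix(cl$genomes, method = "positional")
  expect_true(isSymmetric(d))
  t <- nj_tree(d, outgroup = "Outgroup")
  calls <- classify_patterns(t)
  expect_equal(setNames(calls$label, calls$species)[names(cl$truth$expected)],
               cl$truth$expected)
})

test_that("codon-pair simulation controls divergence and respects omega extremes", {
  cp0 <- simulate_codon_pair(400, omega = 0, target_p = 0.08, seed = 61)
  al <- global_align(cp0$a, cp0$b, mode = "codon")
  r <- suppressWarnings(ng86_dnds(al))
  # omega 0: every accepted change is synonymous (pathway averaging over
  # multiply-hit codons can still attribute a small nonsynonymous residue)
  expect_gt(r$Sd, 0)
  expect_lt(r$Nd, 0.05 * r$Sd)
  expect_lt(r$omega, 0.1)
  expect_lte(abs(cp0$realized_p - 0.08), 0.005 + 1e-9)
})
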