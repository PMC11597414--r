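# Unassigned-region extraction and control-region characterization.

test_that("UR extraction finds inter-feature gaps, flanks, principal and LUR flags", {
  set.seed(101)
  s <- rand_dna(4000)
  feats <- rbind(gene_feature("nad1", "PCG", 0, 900),
                 gene_feature("nad2", "PCG", 1442, 2342),
                 gene_feature("nad5", "PCG", 2342, 2542),
                 gene_feature("trnF", "tRNA", 3543, 3608),
                 gene_feature("rrnL", "rRNA", 3608, 4000))
  g <- mito_genome("GD_F", "Gd", "F", s, feats)
  urs <- extract_urs(g)
  expect_equal(nrow(urs), 2)
  expect_equal(urs$length, c(542, 1001))
  expect_equal(urs$flank5, c("nad1", "nad5"))
  expect_equal(urs$flank3, c("nad2", "trnF"))
  expect_true(all(urs$is_principal))
  expect_equal(urs$is_lur, c(FALSE, TRUE))
  # fully covered genome -> no URs
  g2 <- mito_genome("FULL", "sp", "F", rand_dna(100),
                    gene_feature("cox1", "PCG", 0, 100))
  expect_equal(nrow(extract_urs(g2)), 0)
  # featureless genome is one UR, with a warning
  g3 <- mito_genome("NONE", "sp", "F", rand_dna(100))
  expect_warning(u3 <- extract_urs(g3), "no features")
  expect_equal(u3$length, 100)
})

test_that("the gap spanning the origin is one UR on circular genomes", {
  set.seed(102)
  g <- mito_genome("W", "sp", "F", rand_dna(1000),
                   rbind(gene_feature("cox1", "PCG", 200, 500),
                         gene_feature("nad1", "PCG", 700, 900)))
  urs <- extract_urs(g)
  expect_equal(nrow(urs), 2)
  wrap <- urs[urs$flank5 == "nad1", ]
  expect_equal(wrap$length, 300)   # 900..1000 plus 0..200
  expect_equal(wrap$flank3, "cox1")
  expect_equal(nchar(ur_seq(g, wrap)), 300)
})

test_that("UR lengths plus feature coverage account for every position", {
  set.seed(103)
  for (rep in 1:20) {
    L <- sample(300:800, 1)
    n <- sample(2:6, 1)
    starts <- sort(sample(0:(L - 30), n))
    feats <- do.call(rbind, lapply(seq_len(n), function(i)
      gene_feature(paste0("g", i), "PCG", starts[i],
                   min(L, starts[i] + sample(10:60, 1)))))
    feats$gene <- duimito:::PCG_SYMBOLS[seq_len(n)]
    g <- mito_genome(paste0("P", rep), "sp", "F", rand_dna(L), feats)
    urs <- suppressWarnings(extract_urs(g))
    covered <- logical(L)
    for (i in seq_len(nrow(feats)))
      covered[(feats$start[i] + 1):feats$end[i]] <- TRUE
    expect_equal(sum(urs$length), sum(!covered), info = paste("rep", rep))
  }
})

test_that("UR fraction reproduces the printed percent from printed totals", {
  set.seed(104)
  g <- mito_genome("GDIV_M", "Gafrarium divaricatum", "M",
                   rand_dna(25197),
                   gene_feature("cox1", "PCG", 8055, 25197))
  uf <- ur_fraction(g)
  expect_equal(uf$ur_nt, 8055)
  expect_equal(uf$ur_percent, 32.0)
  # degenerate bounds
  g_none <- mito_genome("N", "sp", "F", rand_dna(50),
                        gene_feature("cox1", "PCG", 0, 50))
  expect_equal(ur_fraction(g_none)$ur_percent, 0)
  g_all <- mito_genome("A", "sp", "F", rand_dna(50))
  expect_equal(suppressWarnings(ur_fraction(g_all))$ur_percent, 100)
})

test_that("tandem repeat finder recovers planted arrays and rejects i.i.d. nulls", {
  set.seed(105)
  flank1 <- rand_dna(120); flank2 <- rand_dna(120)
  arr <- strrep("ACGTT", 6)
  hits <- find_tandem_repeats(paste0(flank1, arr, flank2))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$period, 5)
  expect_equal(hits$copy_number, 6.0)
  expect_gte(hits$score, 50)

  # two arrays with copy numbers 2.0 and 2.4 in one sequence
  u1 <- rand_dna(30); u2 <- rand_dna(30)
  seq2 <- paste0(rand_dna(80), strrep(u1, 2), rand_dna(90),
                 u2, u2, substr(u2, 1, 12), rand_dna(80))
  h2 <- find_tandem_repeats(seq2)
  expect_equal(nrow(h2), 2)
  expect_true(any(abs(h2$copy_number - 2.0) <= 0.1))
  expect_true(any(abs(h2$copy_number - 2.4) <= 0.1))

  # null calibration: >= 99/100 i.i.d. uniform 500-mers give no hit
  fp <- 0
  for (i in 1:100) {
    set.seed(20000 + i)
    if (nrow(find_tandem_repeats(rand_dna(500))) > 0) fp <- fp + 1
  }
  expect_lte(fp, 1)
})

test_that("planted repeats across unit lengths and identities are recovered", {
  # plants span unit lengths 4-200 and identities down to 85%, with copy
  # numbers scaled so each array carries enough signal for the minimum
  # score (short, low-identity, two-copy arrays are statistically
  # invisible to any detector at these weights)
  set.seed(106)
  ok <- 0; ok_det <- 0; total <- 0
  for (period in c(4, 10, 25, 60, 120, 200)) {
    for (rep in 1:8) {
      total <- total + 1
      identity <- if (period < 25) runif(1, 0.95, 1) else runif(1, 0.85, 1)
      lo <- max(3.2, 1 + 60 / period) + (identity < 0.9) * 1.5
      copies <- round(runif(1, lo, lo + 1.5), 1)
      # reject degenerate units whose true period is a sub-period
      repeat {
        unit <- rand_dna(period)
        u <- strsplit(unit, "")[[1]]
        subper <- vapply(seq_len(period %/% 2), function(q)
          period %% q == 0 &&
            mean(u == rep(u[seq_len(q)], length.out = period)) >= 0.9,
          logical(1))
        if (!any(subper)) break
      }
      arr_len <- round(copies * period)
      arr <- strsplit(strrep(unit, ceiling(copies + 1)), "")[[1]][1:arr_len]
      nmut <- rbinom(1, arr_len, 1 - identity)
      if (nmut > 0) {
        pos <- sample(arr_len, nmut)
        arr[pos] <- vapply(arr[pos], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      }
      s <- paste0(rand_dna(100), paste(arr, collapse = ""), rand_dna(100))
      h <- find_tandem_repeats(s)
      det <- h[abs(h$period - period) <= 1 &
               h$start < 100 + arr_len & h$end > 101, ]
      if (nrow(det) > 0) ok_det <- ok_det + 1
      if (nrow(det[abs(det$copy_number - copies) <= 0.2, ]) > 0)
        ok <- ok + 1
    }
  }
  # detection (right period, overlapping the plant) is near-certain; exact
  # copy numbers are boundary-limited for very short units, where +-0.2
  # copies is sub-nucleotide precision
  expect_gte(ok_det / total, 0.9)
  expect_gte(ok / total, 0.75)
})

test_that("G-string scan matches the brute-force window oracle", {
  set.seed(107)
  # a planted pure-G string of 20 among random flanks
  s <- paste0(rand_dna(60, prob = c(0.35, 0.2, 0.1, 0.35)), strrep("G", 20),
              rand_dna(60, prob = c(0.35, 0.2, 0.1, 0.35)))
  h <- g_string_scan(s)
  expect_equal(nrow(h), 1)
  expect_equal(h$g_fraction, 1.0)
  expect_gte(h$length, 20)
  expect_equal(nrow(g_string_scan("ATATATATATATATATATATATAT")), 0)

  # 22-mer with four A at interior positions 5, 9, 13, 18: the full window
  # beats every shorter sub-window
  # G-free flanks so no window can borrow flanking G
  plant <- rep("G", 22)
  plant[c(5, 9, 13, 18)] <- "A"
  s2 <- paste0(rand_dna(40, prob = c(0.45, 0.25, 0, 0.3)),
               paste(plant, collapse = ""),
               rand_dna(40, prob = c(0.45, 0.25, 0, 0.3)))
  h2 <- g_string_scan(s2)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$g_fraction, 18 / 22)
  expect_equal(h2$length, 22)

  # random-sequence equality with the oracle
  for (i in 1:25) {
    s3 <- rand_dna(sample(60:200, 1), prob = c(0.2, 0.15, 0.45, 0.2))
    got <- g_string_scan(s3)
    want <- oracle_g_windows(s3)
    if (is.null(want)) {
      expect_equal(nrow(got), 0, info = paste("rep", i))
    } else {
      expect_equal(nrow(got), nrow(want), info = paste("rep", i))
      expect_equal(got$start, unname(want[, 1]), info = paste("rep", i))
      expect_equal(got$g_fraction, unname(want[, 3]), info = paste("rep", i))
    }
  }
})

test_that("motif similarity equals the exhaustive scan oracle and reports orientation", {
  set.seed(108)
  el <- "ACGTACGTAC"
  s <- paste0(rand_dna(50), el, rand_dna(50))
  h <- motif_similarity(s, el, "custom")
  expect_equal(h$identity, 1.0)
  expect_equal(h$ur_start, 51)
  expect_equal(h$orientation, "+")

  elb <- "ACGGTATCCA"                    # aperiodic element
  el2 <- strsplit(elb, "")[[1]]
  el2[c(2, 5, 9)] <- c("G", "C", "T")   # 3 genuine mismatches in 10
  s2 <- paste0(strrep("T", 40), paste(el2, collapse = ""), strrep("T", 40))
  h2 <- motif_similarity(s2, elb, "custom")
  expect_equal(h2$identity, 0.7)
  expect_equal(h2$ur_start, 41)

  s3 <- paste0(strrep("C", 30), revcomp(el), strrep("C", 30))
  h3 <- motif_similarity(s3, el, "custom")
  expect_equal(h3$orientation, "-")
  expect_equal(h3$identity, 1.0)

  expect_error(motif_similarity(s, "ACGT"), "shorter than 8")

  for (i in 1:20) {
    sr <- rand_dna(120)
    er <- rand_dna(12)
    h4 <- motif_similarity(sr, er, min_identity = 0)
    expect_equal(h4$identity, oracle_motif_best(sr, er),
                 info = paste("rep", i))
  }
})

test_that("fold inventory maximizes pairs (oracle <= 14 nt) and labels stems", {
  f0 <- fold_inventory("AAAA")
  expect_equal(f0$max_pairs, 0)
  expect_length(f0$labels, 0)

  f1 <- fold_inventory("GGGGGAAACCCCC")
  expect_gte(f1$max_pairs, 5)
  expect_equal(nrow(f1$stems), 1)
  expect_equal(f1$stems$n_pairs, 5)
  expect_equal(f1$stems$loop_len, 3)
  expect_equal(f1$labels, "stem_loop")

  set.seed(109)
  for (i in 1:100) {
    s <- rand_dna(sample(6:14, 1))
    expect_equal(fold_inventory(s)$max_pairs, oracle_max_pairs(s),
                 info = paste("rep", i, s))
  }

  # a long perfect hairpin earns the hairpin label
  arm <- "GCCGGCGCCGGCGCG"
  fh <- fold_inventory(paste0(arm, "TTTTT", revcomp(arm)))
  expect_true("hairpin" %in% fh$labels)
  expect_equal(max(fh$stems$n_pairs), 15)
})

test_that("windowed folding of long sequences still reports planted stems", {
  set.seed(111)
  arm <- rand_dna(15)
  long <- paste0(rand_dna(500), arm, "AAAAA", revcomp(arm), rand_dna(600))
  f <- fold_inventory(long, max_len = 400, window = 300)
  expect_gt(nrow(f$stems), 0)
  expect_true("stem_loop" %in% f$labels)
})

test_that("homopolymer runs at or above threshold are reported", {
  h <- homopolymer_runs(paste0("ACG", strrep("A", 9), "T", strrep("G", 8)))
  expect_equal(h$base, c("A", "G"))
  expect_equal(h$length, c(9, 8))
  expect_equal(nrow(homopolymer_runs("ACGTACGT")), 0)
})

test_that("the composite UR protocol annotates planted truth on synthetic genomes", {
  pair <- shared_pair()
  for (side in c("F", "M")) {
    g <- pair[[side]]
    rep <- characterize_urs(g)
    expect_s3_class(rep, "ur_report")
    # every principal UR of the generator carries a planted stem-loop
    for (rec in rep$records)
      expect_true("stem_loop" %in% rec$fold$labels,
                  info = paste(side, rec$ur$flank5))
    tab <- ur_table(rep)
    expect_true(all(c("species", "ur", "length_bp", "copy_numbers")
                    %in% names(tab)))
    expect_equal(nrow(tab), sum(rep$urs$is_principal))
    # the LUR carries the planted repeat array
    lur_row <- tab[tab$is_lur, ]
    expect_gte(lur_row$n_repeat_units, 1)
  }
  # paired table sorts F before M
  tab2 <- ur_table(list(characterize_urs(pair$M), characterize_urs(pair$F)))
  expect_equal(tab2$sex_type[1], "F")
})
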