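# Circular gene-order comparison: canonical rotation, duplications,
# transpositions, breakpoint distance, conserved clusters.

order_genome <- function(syms, id = "O") {
  len <- 10L
  feats <- do.call(rbind, lapply(seq_along(syms), function(i)
    gene_feature(syms[i],
                 if (syms[i] %in% duimito:::PCG_SYMBOLS) "PCG"
                 else if (syms[i] %in% duimito:::RRNA_SYMBOLS) "rRNA"
                 else "tRNA",
                 (i - 1L) * len, i * len)))
  set.seed(1)
  mito_genome(id, "sp", "F", rand_dna(length(syms) * len + 5), feats)
}

base8 <- c("cox1", "trnG", "cox2", "trnM", "nad2", "trnW", "rrnL", "nad5")

test_that("gene order canonicalizes by rotation and marks duplicates", {
  g <- order_genome(base8)
  go <- gene_order_of(g)
  expect_equal(go$order[1], "cox1")
  for (k in c(13, 27, 44)) {
    gr <- rotate_genome(g, k)
    expect_equal(gene_order_of(gr)$order, go$order, info = paste("k", k))
  }
  gd <- order_genome(c(base8, "trnK", "trnK"))
  god <- gene_order_of(gd)
  expect_true(all(c("trnK", "trnK.2") %in% god$order))
  g0 <- mito_genome("E", "sp", "F", "ACGT")
  expect_length(gene_order_of(g0)$order, 0)
})

test_that("identical orders compare clean; a single moved tRNA is a 3-breakpoint transposition", {
  a <- gene_order_of(order_genome(base8, "A"))
  b <- gene_order_of(order_genome(base8, "B"))
  r <- compare_orders(a, b)
  expect_equal(r$breakpoint_distance, 0)
  expect_length(r$transposed, 0)
  expect_length(r$absent_in_a, 0)

  moved <- c("cox1", "trnG", "cox2", "nad2", "trnW", "trnM", "rrnL", "nad5")
  r2 <- compare_orders(a, gene_order_of(order_genome(moved, "B")))
  expect_equal(sort(r2$transposed), "trnM")
  expect_equal(r2$breakpoint_distance, 3)
})

test_that("duplications and absences come from the multiset difference", {
  a <- gene_order_of(order_genome(base8, "A"))
  b <- gene_order_of(order_genome(c(base8, "trnK", "rrnS", "rrnS"), "B"))
  r <- compare_orders(a, b)
  expect_setequal(r$absent_in_a, c("trnK", "rrnS"))
  expect_equal(r$duplicated_in_b, "rrnS")
  expect_equal(r$breakpoint_distance, 0)  # shared single-copy set unchanged
})

test_that("breakpoint distance equals the adjacency oracle on random permutations", {
  syms <- base8
  set.seed(203)
  for (i in 1:100) {
    pa <- sample(syms); pb <- sample(syms)
    a <- gene_order_of(order_genome(pa, "A"))
    b <- gene_order_of(order_genome(pb, "B"))
    r <- compare_orders(a, b)
    # oracle works on the canonicalized circular sequences
    expect_equal(r$breakpoint_distance, oracle_breakpoints(a$base, b$base),
                 info = paste("rep", i))
    # symmetry of the distance
    expect_equal(compare_orders(b, a)$breakpoint_distance,
                 r$breakpoint_distance)
  }
})

test_that("breakpoint distance is invariant under rotation of either input", {
  set.seed(204)
  pa <- sample(base8); pb <- sample(base8)
  ga <- order_genome(pa, "A"); gb <- order_genome(pb, "B")
  d0 <- compare_orders(gene_order_of(ga), gene_order_of(gb))$breakpoint_distance
  for (k in c(7, 23, 41))
    expect_equal(
      compare_orders(gene_order_of(rotate_genome(ga, k)),
                     gene_order_of(rotate_genome(gb, 80 - k)))$breakpoint_distance,
      d0)
})

test_that("conserved clusters recover the constructed block structure", {
  a <- gene_order_of(order_genome(base8, "A"))
  cl <- conserved_clusters(a, gene_order_of(order_genome(base8, "B")))
  expect_length(cl, 1)
  expect_length(cl[[1]]$gene, 8)

  # cut into blocks and shuffle the blocks: the cut count is recovered
  blocks <- list(base8[1:3], base8[4:5], base8[6:8])
  shuffled <- unlist(blocks[c(2, 1, 3)])
  b <- gene_order_of(order_genome(shuffled, "B"))
  cl2 <- conserved_clusters(a, b)
  sizes <- sort(vapply(cl2, nrow, integer(1)))
  expect_equal(sum(sizes), 8)
  expect_true(length(cl2) <= 3)
  # every reported run is genuinely contiguous in both orders
  for (run in cl2) {
    ia <- match(run$gene, a$base)
    expect_equal(ia, seq(min(ia), length.out = nrow(run)))
  }

  # number of clusters equals breakpoint distance on co-oriented inputs
  set.seed(205)
  for (i in 1:20) {
    pb <- sample(base8)
    b2 <- gene_order_of(order_genome(pb, "B"))
    expect_equal(length(conserved_clusters(a, b2)),
                 max(1, compare_orders(a, b2)$breakpoint_distance),
                 info = paste("rep", i))
  }
})

test_that("order strings round-trip through the text format", {
  a <- gene_order_of(order_genome(c(base8, "trnK", "trnK"), "A"))
  txt <- format_gene_order(a)
  b <- parse_gene_order(txt, "A")
  expect_equal(b$order, a$order)
  expect_equal(b$strand, a$strand)
})

test_that("a reverse-complemented block is reported as a minus-orientation cluster", {
  a <- parse_gene_order("cox1,trnG,cox2,trnM,nad2", "A")
  b <- parse_gene_order("cox1,trnG,-nad2,-trnM,cox2", "B")
  cl <- conserved_clusters(a, b)
  rev_runs <- Filter(function(r) all(r$orientation == "-"), cl)
  expect_gte(length(rev_runs), 1)
  expect_true(any(vapply(rev_runs, function(r)
    all(c("trnM", "nad2") %in% r$gene), logical(1))))
})

test_that("disjoint gene sets yield an undefined, flagged distance", {
  a <- parse_gene_order("cox1,trnG,cox2", "A")
  b <- parse_gene_order("nad1,trnK,nad2", "B")
  r <- compare_orders(a, b)
  expect_true(is.na(r$breakpoint_distance))
  expect_length(r$shared, 0)
})
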