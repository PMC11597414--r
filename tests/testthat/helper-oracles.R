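# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive each quantity with a different algorithm
# (naive enumeration / brute force) and share no code with the package.

rand_dna <- function(n, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# affine-gap global alignment score by explicit Gotoh recursion;
# gap of length k costs open + (k-1) * ext
oracle_nw_score <- function(a, b, match = 1, mismatch = -1,
                            open = 2, ext = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - (i - 2) * ext
  for (j in 2:(m + 1)) Y[1, j] <- -open - (j - 2) * ext
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (A[i - 1] == B[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - open, X[i - 1, j] - ext,
                   Y[i - 1, j] - open)
    Y[i, j] <- max(M[i, j - 1] - open, Y[i, j - 1] - ext,
                   X[i, j - 1] - open)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Nei-Gojobori per-codon-pair difference counts by full recursive pathway
# enumeration (paths through stop codons dropped; if all are dropped, all
# paths are used with stop transitions counted as nonsynonymous).
oracle_ng86_diffs <- function(c1, c2, code) {
  if (c1 == c2) return(c(syn = 0, nonsyn = 0))
  enum <- function(cur, tgt, allow_stop) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(tgt, "")[[1]])
    if (!length(pos)) return(list(c(syn = 0, nonsyn = 0)))
    out <- list()
    for (p in pos) {
      ch <- strsplit(cur, "")[[1]]
      ch[p] <- strsplit(tgt, "")[[1]][p]
      nxt <- paste(ch, collapse = "")
      if (!allow_stop && code[[nxt]] == "*") next
      step <- if (code[[nxt]] != "*" && code[[cur]] != "*" &&
                  code[[nxt]] == code[[cur]]) c(1, 0) else c(0, 1)
      for (tailc in enum(nxt, tgt, allow_stop))
        out[[length(out) + 1L]] <- step + tailc
    }
    out
  }
  paths <- enum(c1, c2, allow_stop = FALSE)
  if (!length(paths)) paths <- enum(c1, c2, allow_stop = TRUE)
  avg <- unname(Reduce(`+`, paths) / length(paths))
  c(syn = avg[1], nonsyn = avg[2])
}

# synonymous site count of one codon (independent recount)
oracle_ng86_sites <- function(cod, code) {
  ch <- strsplit(cod, "")[[1]]
  syn <- 0
  for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"), ch[p])) {
    mu <- ch; mu[p] <- b
    mc <- paste(mu, collapse = "")
    if (code[[mc]] != "*" && code[[mc]] == code[[cod]]) syn <- syn + 1
  }
  syn / 3
}

# maximum base pairs by exhaustive (non-memoized) enumeration of nested
# structures; feasible for n <= 14
oracle_max_pairs <- function(s, min_loop = 3) {
  ch <- strsplit(toupper(s), "")[[1]]
  pairable <- function(x, y) {
    paste0(x, y) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (!pairable(ch[i], ch[k])) next
      v <- 1 + (if (k - 1 >= i + 1) rec(i + 1, k - 1) else 0) +
        (if (k + 1 <= j) rec(k + 1, j) else 0)
      if (v > best) best <- v
    }
    best
  }
  if (length(ch) < 2) 0 else rec(1, length(ch))
}

# circular breakpoint distance between two permutations (single copy,
# forward strand): adjacencies of a missing from b
oracle_breakpoints <- function(a, b) {
  adj <- function(x) {
    n <- length(x)
    paste(x, x[c(2:n, 1)], sep = ">")
  }
  sum(!(adj(a) %in% adj(b)))
}

# brute-force best G window: all (start, len) windows meeting the
# threshold, grouped by overlap, best fraction / longest / leftmost kept
oracle_g_windows <- function(seq, lens = 18:23, minf = 0.8) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  wins <- NULL
  for (len in lens) {
    if (n < len) next
    for (s in 1:(n - len + 1)) {
      f <- mean(ch[s:(s + len - 1)] == "G")
      if (f >= minf) wins <- rbind(wins, c(s, len, f))
    }
  }
  if (is.null(wins)) return(NULL)
  wins <- wins[order(wins[, 1], wins[, 1] + wins[, 2]), , drop = FALSE]
  groups <- list(); cur <- wins[1, , drop = FALSE]
  cur_end <- wins[1, 1] + wins[1, 2] - 1
  if (nrow(wins) > 1) for (i in 2:nrow(wins)) {
    if (wins[i, 1] <= cur_end) {
      cur <- rbind(cur, wins[i, ])
      cur_end <- max(cur_end, wins[i, 1] + wins[i, 2] - 1)
    } else {
      groups[[length(groups) + 1L]] <- cur
      cur <- wins[i, , drop = FALSE]
      cur_end <- wins[i, 1] + wins[i, 2] - 1
    }
  }
  groups[[length(groups) + 1L]] <- cur
  do.call(rbind, lapply(groups, function(gw) {
    gw <- gw[order(-gw[, 3], -gw[, 2], gw[, 1]), , drop = FALSE]
    gw[1, ]
  }))
}

# brute-force best motif window over both orientations
oracle_motif_best <- function(seq, element) {
  ch <- strsplit(toupper(seq), "")[[1]]
  m <- nchar(element)
  best <- 0
  for (el in c(element, duimito::revcomp(element))) {
    ech <- strsplit(toupper(el), "")[[1]]
    for (s in 1:(length(ch) - m + 1))
      best <- max(best, mean(ch[s:(s + m - 1)] == ech))
  }
  best
}
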