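# Unassigned-region (UR) extraction and control-region characterization:
# composition, tandem repeats (simplified Tandem Repeats Finder scoring),
# G-strings, conserved-element motif similarity, homopolymer runs and a
# base-pair-maximization secondary-structure inventory. The largest UR
# (LUR) of each genome is the prime control-region candidate; "principal"
# URs are those longer than 150 nt.

#' Extract unassigned (intergenic) regions
#'
#' URs are the maximal genome spans not covered by any annotated feature;
#' on circular genomes the gap spanning the origin is a single UR. Each UR
#' is flanked by the nearest features in genome order. The single longest
#' UR is flagged `is_lur` (ties broken by genome order and flagged in the
#' `lur_tie` attribute); URs longer than `min_principal` nt are
#' `is_principal`.
#'
#' @param g A [mito_genome()].
#' @param min_principal Principal-UR length threshold in nt (default 150,
#'   i.e. principal URs are > 150 nt).
#' @return Data frame with columns `genome`, `flank5`, `flank3`, `start`,
#'   `end` (0-based half-open, wrap-aware), `length`, `at_content`,
#'   `is_principal`, `is_lur`. Attribute `overlap_nt` reports nucleotides
#'   covered by more than one feature.
#' @export
extract_urs <- function(g, min_principal = 150) {
  L <- genome_length(g)
  circ <- g$topology == "circular"
  cov <- integer(L)
  owner_end <- rep(NA_integer_, L)  # feature index whose span ends after pos
  f <- g$features
  for (i in seq_len(nrow(f))) {
    s <- f$start[i]; e <- f$end[i]
    idx <- if (e > s) (s + 1L):e else c((s + 1L):L, seq_len(e))
    cov[idx] <- cov[idx] + 1L
  }
  if (nrow(f) == 0) {
    warning(sprintf("%s: no features; whole genome is one UR", g$id),
            call. = FALSE)
  }
  un <- cov == 0L
  if (!any(un)) {
    out <- data.frame(genome = character(), flank5 = character(),
                      flank3 = character(), start = integer(),
                      end = integer(), length = integer(),
                      at_content = numeric(), is_principal = logical(),
                      is_lur = logical(), stringsAsFactors = FALSE)
    attr(out, "overlap_nt") <- sum(cov > 1L)
    return(out)
  }
  # maximal uncovered runs (positions are 1-based here; convert at the end)
  r <- rle(un)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # circular merge across the origin
  wrap <- FALSE
  if (circ && nrow(runs) > 1 && runs[1, 1] == 1L && runs[nrow(runs), 2] == L) {
    runs[1, 1] <- runs[nrow(runs), 1]
    runs <- runs[-nrow(runs), , drop = FALSE]
    wrap <- TRUE
  }
  flank_of <- function(pos1) {
    # gene covering 1-based position pos1 (wrapped); prefer a feature whose
    # span ends exactly there / starts exactly there handled by caller
    if (nrow(f) == 0) return(NA_character_)
    pos1 <- ((pos1 - 1L) %% L) + 1L
    hits <- which(vapply(seq_len(nrow(f)), function(i) {
      s <- f$start[i]; e <- f$end[i]
      if (e > s) pos1 > s && pos1 <= e else pos1 > s || pos1 <= e
    }, logical(1)))
    if (!length(hits)) NA_character_ else f$gene[hits[1]]
  }
  rows <- lapply(seq_len(nrow(runs)), function(k) {
    s1 <- runs[k, 1]; e1 <- runs[k, 2]
    len <- if (k == 1 && wrap) (L - s1 + 1L) + e1 else e1 - s1 + 1L
    start0 <- s1 - 1L
    end0 <- e1 %% L
    ur_seq <- seq_span(g$sequence, start0, if (end0 == 0) L else end0, circ)
    comp <- composition(ur_seq, "UR")
    data.frame(genome = g$id,
               flank5 = flank_of(s1 - 1L), flank3 = flank_of(e1 + 1L),
               start = start0, end = if (end0 == 0) L else end0,
               length = len, at_content = comp$at_content,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  out$is_principal <- out$length > min_principal
  out$is_lur <- FALSE
  mx <- which(out$length == max(out$length))
  out$is_lur[mx[1]] <- TRUE
  attr(out, "lur_tie") <- length(mx) > 1
  attr(out, "overlap_nt") <- sum(cov > 1L)
  rownames(out) <- NULL
  out
}

#' Fraction of a genome that is unassigned
#'
#' @param genomes A [mito_genome()] or list of them.
#' @return Data frame `genome`, `ur_nt`, `genome_nt`, `ur_percent`
#'   (one decimal, as conventionally printed).
#' @export
ur_fraction <- function(genomes) {
  if (inherits(genomes, "mito_genome")) genomes <- list(genomes)
  do.call(rbind, lapply(genomes, function(g) {
    urs <- suppressWarnings(extract_urs(g))
    tot <- sum(urs$length)
    data.frame(genome = g$id, ur_nt = tot, genome_nt = genome_length(g),
               ur_percent = round(100 * tot / genome_length(g), 1),
               stringsAsFactors = FALSE)
  }))
}

#' Ungapped UR sequence for one extracted UR row
#' @param g A [mito_genome()].
#' @param ur One row of the data frame from [extract_urs()].
#' @return DNA string.
#' @export
ur_seq <- function(g, ur) {
  seq_span(g$sequence, ur$start, ur$end, g$topology == "circular")
}

# ---- tandem repeats ------------------------------------------------------

#' Find tandem repeats (simplified Tandem Repeats Finder scoring)
#'
#' Period-by-period self-comparison: positions matching one period ahead
#' (`s[i] == s[i+p]`, or two periods ahead where the array is long enough)
#' score `+match`, others `-mismatch`; maximal positive-scoring segments
#' with score >= `min_score` seed repeat arrays of period `p` (indel-free
#' approximation of the published default weights 2/7/7, minimum score 50,
#' maximum period 500). Array boundaries are then extended against the
#' majority consensus of the seed region, which recovers edges clipped by
#' mutation clusters. Overlapping calls at multiple periods are reduced to
#' the best-scoring (smallest-period on ties) call; arrays whose consensus
#' is a homopolymer and arrays below `min_copies` copies are dropped.
#'
#' @param seq DNA string.
#' @param match,mismatch Alignment weights (defaults 2 and 7).
#' @param min_score Minimum array score (default 50).
#' @param min_period,max_period Period range searched (defaults 3 and 500).
#' @param min_copies Reporting threshold on copy number (default 1.8).
#' @return Data frame: `start`, `end` (1-based inclusive, local to `seq`),
#'   `period`, `copy_number` (one decimal), `consensus`, `score`,
#'   `percent_matches`.
#' @export
find_tandem_repeats <- function(seq, match = 2, mismatch = 7, min_score = 50,
                                min_period = 3, max_period = 500,
                                min_copies = 1.8) {
  empty <- data.frame(start = integer(), end = integer(), period = integer(),
                      copy_number = numeric(), consensus = character(),
                      score = numeric(), percent_matches = numeric(),
                      stringsAsFactors = FALSE)
  ch <- split_chars(toupper(seq))
  n <- length(ch)
  if (n < 2 * min_period) return(empty)
  cands <- list()
  for (p in min_period:min(max_period, floor(n / 2))) {
    eq <- ch[seq_len(n - p)] == ch[(p + 1):n]
    if (n > 2 * p) {
      idx2 <- seq_len(n - 2 * p)
      eq[idx2] <- eq[idx2] | (ch[idx2] == ch[idx2 + 2L * p])
    }
    sc <- ifelse(eq, match, -mismatch)
    # array boundaries: walk outward from the seed-core centre comparing
    # the sequence to the seed consensus at phase (+1 match / -2 mismatch),
    # place each boundary at the walk's maximum, then trim boundaries until
    # at least 3 of the outermost 4 positions match the consensus
    extend <- function(from, dir, cons, anchor) {
      run <- 0L; best <- 0L; best_at <- from
      k <- from
      for (step in seq_len(6L * p + 30L)) {
        k <- k + dir
        if (k < 1L || k > n) break
        ph <- ((k - anchor) %% p) + 1L
        run <- run + (if (ch[k] == cons[ph]) 1L else -2L)
        if (run > best) { best <- run; best_at <- k }
        if (run < best - 18L) break
      }
      best_at
    }
    trim <- function(s, e, cons, anchor) {
      msk <- ch[s:e] == cons[(((s:e) - anchor) %% p) + 1L]
      a <- 1L; b <- length(msk)
      while (b - a + 1L >= 4L && sum(msk[(b - 3L):b]) < 3L) b <- b - 1L
      while (b - a + 1L >= 4L && sum(msk[a:(a + 3L)]) < 3L) a <- a + 1L
      c(s + a - 1L, s + b - 1L)
    }
    flush <- function(cur_start, best, best_end) {
      if (best >= min_score) {
        s0 <- cur_start; e0 <- best_end + p   # seed region (sequence coords)
        reg <- ch[s0:e0]
        phases <- ((seq_along(reg) - 1L) %% p) + 1L
        cons <- vapply(seq_len(p), function(ph) {
          t <- table(reg[phases == ph])
          names(t)[which.max(t)]
        }, character(1))
        centre <- (s0 + e0) %/% 2L
        s <- extend(centre, -1L, cons, s0)
        e <- extend(centre, 1L, cons, s0)
        se <- trim(s, e, cons, s0)
        s <- se[1]; e <- se[2]
        # collapse to the smallest sub-period the consensus itself repeats
        # (an array of period q also matches itself at lag 2q, 3q, ...);
        # the first q positions match trivially and are excluded
        per <- p
        for (q in seq_len(p %/% 2)) {
          if (p %% q != 0L) next
          tailpos <- (q + 1L):p
          if (mean(cons[tailpos] ==
                   cons[((tailpos - 1L) %% q) + 1L]) >= 0.75) {
            per <- q
            cons <- cons[seq_len(q)]
            break
          }
        }
        reg <- ch[s:e]
        phases <- (((s:e) - s0) %% per) + 1L
        matches <- sum(reg == cons[phases])
        cands[[length(cands) + 1L]] <<- data.frame(
          start = s, end = e, period = per,
          copy_number = round((e - s + 1L) / per, 1),
          consensus = paste(cons, collapse = ""),
          score = best, percent_matches = round(100 * matches / length(reg), 1),
          stringsAsFactors = FALSE)
      }
    }
    cur <- 0; cur_start <- 1L; best <- 0; best_end <- 0L
    for (i in seq_along(sc)) {
      if (cur + sc[i] <= 0) {
        flush(cur_start, best, best_end)
        cur <- 0; best <- 0; cur_start <- i + 1L
      } else {
        cur <- cur + sc[i]
        if (cur > best) { best <- cur; best_end <- i }
      }
    }
    flush(cur_start, best, best_end)
  }
  if (!length(cands)) return(empty)
  cand <- do.call(rbind, cands)
  # overlap resolution: highest consensus fidelity first (a half-period
  # artifact fits its consensus poorly), then smallest period, then score
  cand <- cand[order(-round(cand$percent_matches), cand$period,
                     -cand$score), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    ol <- FALSE
    for (j in which(keep)) {
      inter <- min(e, cand$end[j]) - max(s, cand$start[j]) + 1L
      if (inter > 0.5 * (e - s + 1L)) { ol <- TRUE; break }
    }
    homop <- length(unique(split_chars(cand$consensus[i]))) == 1L
    keep[i] <- !ol && !homop && cand$copy_number[i] >= min_copies
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- G-strings -----------------------------------------------------------

#' Scan for G-rich strings
#'
#' All windows with length in `len_range` whose G fraction is at least
#' `min_fraction` are found; overlapping windows are merged and the best
#' window per merged region reported (highest fraction, then longest, then
#' leftmost). Mirrors the string of ~20 Gs that marks the sea-urchin
#' control region.
#'
#' @param seq DNA string.
#' @param len_range Window length range (default 18-23 nt).
#' @param min_fraction Minimum G fraction (default 0.8).
#' @return Data frame: `start` (1-based), `length`, `g_fraction`.
#' @export
g_string_scan <- function(seq, len_range = c(18, 23), min_fraction = 0.8) {
  ch <- split_chars(toupper(seq))
  n <- length(ch)
  gind <- as.integer(ch == "G")
  cs <- c(0L, cumsum(gind))
  wins <- list()
  for (len in len_range[1]:len_range[2]) {
    if (n < len) next
    frac <- (cs[(len + 1):(n + 1)] - cs[1:(n - len + 1)]) / len
    hit <- which(frac >= min_fraction)
    if (length(hit))
      wins[[length(wins) + 1L]] <- data.frame(start = hit, length = len,
                                              g_fraction = frac[hit])
  }
  empty <- data.frame(start = integer(), length = integer(),
                      g_fraction = numeric())
  if (!length(wins)) return(empty)
  w <- do.call(rbind, wins)
  w$end <- w$start + w$length - 1L
  w <- w[order(w$start, w$end), , drop = FALSE]
  # merge into overlap groups
  grp <- integer(nrow(w)); gid <- 1L; grp[1] <- 1L; cur_end <- w$end[1]
  if (nrow(w) > 1) for (i in 2:nrow(w)) {
    if (w$start[i] <= cur_end) { grp[i] <- gid; cur_end <- max(cur_end, w$end[i]) }
    else { gid <- gid + 1L; grp[i] <- gid; cur_end <- w$end[i] }
  }
  out <- do.call(rbind, lapply(split(w, grp), function(d) {
    d <- d[order(-d$g_fraction, -d$length, d$start), , drop = FALSE]
    d[1, c("start", "length", "g_fraction")]
  }))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- conserved-element motif similarity ---------------------------------

#' Best ungapped similarity of a control-region element in a sequence
#'
#' Slides the element over both orientations of `seq` and reports the
#' best-scoring window (percent identity; ties resolved leftmost, plus
#' orientation first) when identity exceeds `min_identity`.
#'
#' @param seq DNA string (the UR).
#' @param element Element DNA string (length >= 8).
#' @param element_name Element label (TAS, CSB1, mTF1, mt3, mt4 or custom).
#' @param min_identity Reporting threshold (default 0.5, strict).
#' @return One-row data frame `element`, `ur_start` (1-based), `orientation`
#'   (`+`/`-`), `identity`, `matched` (the matched window on the + strand),
#'   or `NULL` when nothing exceeds the threshold.
#' @export
motif_similarity <- function(seq, element, element_name = "custom",
                             min_identity = 0.5) {
  if (nchar(element) < 8) stop("element shorter than 8 nt")
  ch <- split_chars(toupper(seq))
  n <- length(ch)
  m <- nchar(element)
  if (n < m) return(NULL)
  scan_one <- function(el) {
    ech <- split_chars(toupper(el))
    ids <- vapply(seq_len(n - m + 1L), function(o)
      sum(ch[o:(o + m - 1L)] == ech) / m, numeric(1))
    ids
  }
  best <- NULL
  for (ori in c("+", "-")) {
    el <- if (ori == "+") element else revcomp(element)
    ids <- scan_one(el)
    i <- which.max(ids)
    cand <- list(id = ids[i], start = i, ori = ori)
    if (is.null(best) || cand$id > best$id) best <- cand
  }
  if (best$id <= min_identity) return(NULL)
  data.frame(element = element_name, ur_start = best$start,
             orientation = best$ori, identity = best$id,
             matched = paste(ch[best$start:(best$start + m - 1L)],
                             collapse = ""),
             stringsAsFactors = FALSE)
}

#' Load a control-region element library from FASTA
#'
#' The package ships a stand-in library
#' (`extdata/control_region_elements_synthetic.fasta`) with synthetic
#' TAS/CSB1/mTF1/mt3/mt4 sequences; supply your own FASTA of reference
#' elements for real analyses.
#'
#' @param path FASTA path (default: the shipped synthetic library).
#' @return Named character vector of element sequences.
#' @export
load_elements <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "control_region_elements_synthetic.fasta",
                        package = "duimito")
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

# ---- secondary structure -------------------------------------------------

#' Secondary-structure inventory by base-pair maximization
#'
#' Nussinov dynamic programming (Watson-Crick + GU pairs, minimum hairpin
#' loop 3) yields the maximum non-crossing pairing; stems of at least
#' `min_stem` contiguous pairs are reported. Labels: `stem_loop` when at
#' least one stem exists, additionally `hairpin` when a hairpin-closing
#' stem has >= `hairpin_pairs` pairs and a loop of <= `hairpin_loop` nt.
#' Sequences longer than `max_len` are folded in overlapping windows of
#' `window` nt (step `window/2`) and the per-window results pooled.
#'
#' @param seq DNA string.
#' @param max_len Maximum length folded in one piece (default 3500).
#' @param window Window size for long sequences (default 1000).
#' @param min_stem Minimum contiguous pairs per reported stem (default 5).
#' @param hairpin_pairs,hairpin_loop Hairpin label thresholds.
#' @return List of class `fold_result`: `max_pairs`, `stems` (data frame
#'   `stem5_start`, `stem5_end`, `stem3_start`, `stem3_end`, `n_pairs`,
#'   `loop_len`, `hairpin_closing`; 1-based coordinates), `labels`.
#' @export
fold_inventory <- function(seq, max_len = 3500, window = 1000, min_stem = 5,
                           hairpin_pairs = 10, hairpin_loop = 10) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n <= max_len) {
    res <- .nussinov_cpp(seq, 3L)
    stems <- stems_from_pairs(res$pairs, offset = 0L)
    max_pairs <- res$max_pairs
  } else {
    step <- max(1L, window %/% 2L)
    starts <- seq(1L, max(1L, n - window + 1L), by = step)
    if (starts[length(starts)] + window - 1L < n)
      starts <- c(starts, n - window + 1L)
    stems <- NULL
    max_pairs <- 0L
    for (s in starts) {
      sub <- substr(seq, s, min(n, s + window - 1L))
      res <- .nussinov_cpp(sub, 3L)
      max_pairs <- max(max_pairs, res$max_pairs)
      st <- stems_from_pairs(res$pairs, offset = s - 1L)
      stems <- rbind(stems, st)
    }
    if (!is.null(stems) && nrow(stems)) {
      stems <- stems[!duplicated(stems[, c("stem5_start", "stem3_end")]), ,
                     drop = FALSE]
      stems <- stems[order(stems$stem5_start), , drop = FALSE]
    }
  }
  stems <- stems[stems$n_pairs >= min_stem, , drop = FALSE]
  rownames(stems) <- NULL
  labels <- character(0)
  if (nrow(stems)) {
    labels <- "stem_loop"
    if (any(stems$hairpin_closing & stems$n_pairs >= hairpin_pairs &
            stems$loop_len <= hairpin_loop))
      labels <- c(labels, "hairpin")
  }
  structure(list(max_pairs = max_pairs, stems = stems, labels = labels),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("fold: %d pairs, %d stems [%s]\n", x$max_pairs, nrow(x$stems),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

# Group a pair list into helical stems: runs of pairs (i,j), (i+1,j-1), ...
stems_from_pairs <- function(pairs, offset = 0L) {
  empty <- data.frame(stem5_start = integer(), stem5_end = integer(),
                      stem3_start = integer(), stem3_end = integer(),
                      n_pairs = integer(), loop_len = integer(),
                      hairpin_closing = logical())
  if (is.null(pairs) || nrow(pairs) == 0) return(empty)
  p <- pairs[order(pairs[, 1]), , drop = FALSE]
  i <- p[, 1]; j <- p[, 2]
  brk <- c(TRUE, !(i[-1] == i[-length(i)] + 1L & j[-1] == j[-length(j)] - 1L))
  grp <- cumsum(brk)
  out <- do.call(rbind, lapply(split(seq_along(grp), grp), function(idx) {
    i1 <- i[idx[1]]; i2 <- i[idx[length(idx)]]
    j2 <- j[idx[length(idx)]]; j1 <- j[idx[1]]
    inner <- any(pairs[, 1] > i2 & pairs[, 2] < j2)
    data.frame(stem5_start = i1 + 1L + offset, stem5_end = i2 + 1L + offset,
               stem3_start = j2 + 1L + offset, stem3_end = j1 + 1L + offset,
               n_pairs = length(idx), loop_len = j2 - i2 - 1L,
               hairpin_closing = !inner)
  }))
  rownames(out) <- NULL
  out
}

# ---- homopolymers --------------------------------------------------------

#' Homopolymer runs of at least `min_len` nt
#'
#' @param seq DNA string.
#' @param min_len Minimum run length (default 8).
#' @return Data frame `base`, `start` (1-based), `length`.
#' @export
homopolymer_runs <- function(seq, min_len = 8) {
  ch <- split_chars(toupper(seq))
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_len & r$values %in% c("A", "C", "G", "T")
  data.frame(base = r$values[keep], start = starts[keep],
             length = r$lengths[keep], stringsAsFactors = FALSE)
}

# ---- composite protocol --------------------------------------------------

#' Characterize the unassigned regions of a genome
#'
#' The composite control-region assessment protocol: extract URs, then for
#' every principal UR run composition, tandem-repeat search, G-string scan,
#' element-similarity scan, homopolymer runs and the secondary-structure
#' inventory.
#'
#' @param g A [mito_genome()].
#' @param elements Named element library (see [load_elements()]).
#' @param min_principal Principal threshold in nt.
#' @param config Optional list of threshold overrides passed to the
#'   scanners: `trf` (list), `gstring` (list), `motif_min_identity`,
#'   `homopolymer_min`, `fold` (list).
#' @return List of class `ur_report`: `genome`, `urs` (the [extract_urs()]
#'   table), `records` (per-principal-UR list with elements `ur`, `repeats`,
#'   `g_strings`, `motifs`, `homopolymers`, `fold`).
#' @export
characterize_urs <- function(g, elements = load_elements(),
                             min_principal = 150, config = list()) {
  urs <- extract_urs(g, min_principal = min_principal)
  recs <- list()
  for (k in seq_len(nrow(urs))) {
    if (!urs$is_principal[k]) next
    s <- ur_seq(g, urs[k, ])
    reps <- do.call(find_tandem_repeats, c(list(seq = s), config$trf))
    gs <- do.call(g_string_scan, c(list(seq = s), config$gstring))
    mots <- do.call(rbind, Filter(Negate(is.null), lapply(names(elements),
      function(nm) motif_similarity(
        s, elements[[nm]], nm,
        min_identity = config$motif_min_identity %||% 0.5))))
    hp <- homopolymer_runs(s, min_len = config$homopolymer_min %||% 8)
    fold <- do.call(fold_inventory, c(list(seq = s), config$fold))
    recs[[length(recs) + 1L]] <- list(ur = urs[k, ], repeats = reps,
                                      g_strings = gs, motifs = mots,
                                      homopolymers = hp, fold = fold)
  }
  if (!any(urs$is_principal))
    message(sprintf("%s: no principal UR (> %d nt)", g$id, min_principal))
  structure(list(genome = g$id, species = g$species, sex_type = g$sex_type,
                 urs = urs, records = recs),
            class = "ur_report")
}

#' Tabulate UR reports in the style of a control-region summary table
#'
#' One row per principal UR: flanks, length, A-T content, number of repeat
#' arrays, copy numbers joined with `+` (`/` when none), and other
#' characteristics (structure labels, homopolymer tags like `(A)n`,
#' G-string presence).
#'
#' @param reports A single `ur_report` or list of them (F reported before M
#'   per species).
#' @param path Optional TSV output path.
#' @return The data frame, invisibly when `path` given.
#' @export
ur_table <- function(reports, path = NULL) {
  if (inherits(reports, "ur_report")) reports <- list(reports)
  ord <- order(vapply(reports, function(r) r$species, character(1)),
               match(vapply(reports, function(r) r$sex_type, character(1)),
                     c("F", "M", "unknown")))
  reports <- reports[ord]
  rows <- list()
  for (r in reports) {
    for (rec in r$records) {
      other <- rec$fold$labels
      if (any(rec$g_strings$g_fraction >= 0.8)) other <- c(other, "G-string")
      if (nrow(rec$homopolymers))
        other <- c(other, paste0("(", unique(rec$homopolymers$base), ")n"))
      rows[[length(rows) + 1L]] <- data.frame(
        species = r$species, sex_type = r$sex_type, genome = r$genome,
        ur = paste0(rec$ur$flank5, "-", rec$ur$flank3),
        length_bp = rec$ur$length,
        at_content_pct = round(100 * rec$ur$at_content, 1),
        n_repeat_units = nrow(rec$repeats),
        copy_numbers = if (nrow(rec$repeats))
          paste(format(rec$repeats$copy_number, nsmall = 1, trim = TRUE),
                collapse = "+") else "/",
        other_characteristics = if (length(other))
          paste(other, collapse = ", ") else "/",
        is_lur = rec$ur$is_lur, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), sex_type = character(),
               genome = character(), ur = character(), length_bp = integer(),
               at_content_pct = numeric(), n_repeat_units = integer(),
               copy_numbers = character(), other_characteristics = character(),
               is_lur = logical(), stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
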