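# Circular gene-order comparison: duplications, losses, transpositions and
# breakpoint distance. Orders are canonicalized by rotation to cox1 (all
# venerid mitochondrial genes sit on the forward strand, so reflection is
# NOT identified: orientation is meaningful).

#' Gene order of a mitogenome
#'
#' @param g A [mito_genome()].
#' @return Object of class `gene_order`: `genome`, `order` (gene symbols in
#'   genome-start order, duplicate copies suffixed `.2`, `.3`, ...),
#'   `strand`, canonically rotated to start at cox1 (or at the
#'   lexicographically smallest symbol when cox1 is absent).
#' @export
gene_order_of <- function(g) {
  f <- g$features
  syms <- f$gene
  strands <- f$strand
  new_gene_order(g$id, syms, strands)
}

new_gene_order <- function(id, syms, strands = rep("+", length(syms))) {
  # multiplicity markers
  if (length(syms)) {
    cnt <- stats::ave(seq_along(syms), syms, FUN = seq_along)
    marked <- ifelse(cnt > 1, paste0(syms, ".", cnt), syms)
  } else marked <- character(0)
  obj <- structure(list(genome = id, order = marked, strand = strands,
                        base = syms),
                   class = "gene_order")
  canonical_rotation(obj)
}

canonical_rotation <- function(go) {
  n <- length(go$order)
  if (n == 0) return(go)
  anchor <- if ("cox1" %in% go$base) which(go$base == "cox1")[1]
            else which(go$base == sort(go$base)[1])[1]
  idx <- ((seq_len(n) + anchor - 2L) %% n) + 1L
  go$order <- go$order[idx]
  go$strand <- go$strand[idx]
  go$base <- go$base[idx]
  go
}

#' @export
print.gene_order <- function(x, ...) {
  tags <- ifelse(x$strand == "-", paste0("-", x$order), x$order)
  cat(sprintf("<gene_order> %s: %s\n", x$genome, paste(tags, collapse = ",")))
  invisible(x)
}

#' Read/write gene orders as comma-separated strings
#'
#' Minus-strand genes carry a `-` prefix.
#'
#' @param x A `gene_order` (for write) or a string/path (for read).
#' @param id Genome id for the parsed order.
#' @return `format_gene_order()` a string; `parse_gene_order()` a
#'   `gene_order`.
#' @export
format_gene_order <- function(x) {
  tags <- ifelse(x$strand == "-", paste0("-", x$order), x$order)
  paste(tags, collapse = ",")
}

#' @rdname format_gene_order
#' @export
parse_gene_order <- function(x, id = "order") {
  toks <- strsplit(trimws(x), ",")[[1]]
  strands <- ifelse(grepl("^-", toks), "-", "+")
  syms <- sub("^-", "", toks)
  syms <- sub("\\.\\d+$", "", syms)
  new_gene_order(id, syms, strands)
}

# circular, orientation-respecting adjacency set on a projected order
adjacencies <- function(syms, strands) {
  n <- length(syms)
  if (n < 2) return(character(0))
  nxt <- c(2:n, 1L)
  paste0(strands, syms, ">", strands[nxt], syms[nxt])
}

# project an order onto a symbol set, keeping circular order
project_order <- function(go, set) {
  keep <- go$base %in% set
  list(syms = go$base[keep], strands = go$strand[keep])
}

rotations_equal <- function(a_syms, a_str, b_syms, b_str) {
  n <- length(a_syms)
  if (n != length(b_syms)) return(FALSE)
  if (n == 0) return(TRUE)
  start <- which(b_syms == a_syms[1] & b_str == a_str[1])
  for (s in start) {
    idx <- ((seq_len(n) + s - 2L) %% n) + 1L
    if (all(b_syms[idx] == a_syms) && all(b_str[idx] == a_str)) return(TRUE)
  }
  FALSE
}

#' Compare two circular gene orders
#'
#' Reports duplications and absences from the multiset difference, then on
#' the shared single-copy gene set computes the breakpoint distance (number
#' of circular, orientation-respecting adjacencies of `a` absent from `b`)
#' and searches for a minimal set of at most two genes whose removal makes
#' the orders rotation-identical (`transposed`; exact for single- and
#' two-gene moves, `NA` beyond that).
#'
#' @param a,b `gene_order` objects.
#' @return List of class `rearrangement_report`: `shared`,
#'   `duplicated_in_a`, `duplicated_in_b`, `absent_in_a`, `absent_in_b`,
#'   `transposed`, `breakpoint_distance` (NA when the shared set is empty).
#' @export
compare_orders <- function(a, b) {
  ta <- table(a$base); tb <- table(b$base)
  shared <- intersect(names(ta), names(tb))
  rep <- list(
    shared = shared,
    duplicated_in_a = names(ta)[ta > 1],
    duplicated_in_b = names(tb)[tb > 1],
    absent_in_a = setdiff(names(tb), names(ta)),
    absent_in_b = setdiff(names(ta), names(tb)))
  single <- shared[ta[shared] == 1 & tb[shared] == 1]
  if (!length(single)) {
    rep$breakpoint_distance <- NA_integer_
    rep$transposed <- NA_character_
    rep$note <- "shared single-copy gene set empty; distance undefined"
    class(rep) <- "rearrangement_report"
    return(rep)
  }
  pa <- project_order(a, single)
  pb <- project_order(b, single)
  adj_a <- adjacencies(pa$syms, pa$strands)
  adj_b <- adjacencies(pb$syms, pb$strands)
  rep$breakpoint_distance <- sum(!(adj_a %in% adj_b))
  # minimal removal set (<= 2) making the projected orders rotation-equal
  rep$transposed <- character(0)
  if (!rotations_equal(pa$syms, pa$strands, pb$syms, pb$strands)) {
    found <- NULL
    for (g1 in single) {
      s <- setdiff(single, g1)
      qa <- project_order(a, s); qb <- project_order(b, s)
      if (rotations_equal(qa$syms, qa$strands, qb$syms, qb$strands)) {
        found <- g1; break
      }
    }
    if (is.null(found) && length(single) >= 2) {
      cmb <- utils::combn(single, 2)
      for (k in seq_len(ncol(cmb))) {
        s <- setdiff(single, cmb[, k])
        qa <- project_order(a, s); qb <- project_order(b, s)
        if (rotations_equal(qa$syms, qa$strands, qb$syms, qb$strands)) {
          found <- cmb[, k]; break
        }
      }
    }
    rep$transposed <- if (is.null(found)) NA_character_ else found
  }
  class(rep) <- "rearrangement_report"
  rep
}

#' @export
print.rearrangement_report <- function(x, ...) {
  cat(sprintf("breakpoint distance: %s\n",
              format(x$breakpoint_distance)))
  cat("transposed:", if (all(is.na(x$transposed))) "(no <=2-gene solution)"
      else if (!length(x$transposed)) "none"
      else paste(x$transposed, collapse = " "), "\n")
  if (length(x$absent_in_b)) cat("absent in b:",
                                 paste(x$absent_in_b, collapse = " "), "\n")
  if (length(x$absent_in_a)) cat("absent in a:",
                                 paste(x$absent_in_a, collapse = " "), "\n")
  if (length(x$duplicated_in_a)) cat("duplicated in a:",
                                     paste(x$duplicated_in_a, collapse = " "), "\n")
  if (length(x$duplicated_in_b)) cat("duplicated in b:",
                                     paste(x$duplicated_in_b, collapse = " "), "\n")
  invisible(x)
}

#' Maximal conserved gene clusters of two circular orders
#'
#' Maximal runs of shared single-copy genes contiguous and co-oriented in
#' both circular orders; a block conserved in reverse-complement
#' orientation is reported with `orientation = "-"`.
#'
#' @param a,b `gene_order` objects.
#' @return List of data frames, each a cluster with columns `gene`,
#'   `orientation`.
#' @export
conserved_clusters <- function(a, b) {
  ta <- table(a$base); tb <- table(b$base)
  single <- intersect(names(ta)[ta == 1], names(tb)[tb == 1])
  if (!length(single)) return(list())
  pa <- project_order(a, single)
  pb <- project_order(b, single)
  n <- length(pa$syms)
  posb <- match(pa$syms, pb$syms)
  # relative orientation of each gene: + if strands agree
  rel <- ifelse(pa$strands == pb$strands[posb], "+", "-")
  nb <- length(pb$syms)
  nxt_ok <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    if (rel[i] == "+" && rel[j] == "+") {
      ((posb[i] %% nb) + 1L) == posb[j]
    } else if (rel[i] == "-" && rel[j] == "-") {
      ((posb[j] %% nb) + 1L) == posb[i]
    } else FALSE
  }, logical(1))
  if (all(nxt_ok)) {
    return(list(data.frame(gene = pa$syms, orientation = rel,
                           stringsAsFactors = FALSE)))
  }
  # cut at breaks: cluster = run between breaks (circular)
  breaks_after <- which(!nxt_ok)
  first <- (breaks_after[1] %% n) + 1L
  ordidx <- ((seq_len(n) + first - 2L) %% n) + 1L
  cl <- list(); cur <- integer(0)
  for (i in ordidx) {
    cur <- c(cur, i)
    if (!nxt_ok[i]) { cl[[length(cl) + 1L]] <- cur; cur <- integer(0) }
  }
  lapply(cl, function(idx) data.frame(gene = pa$syms[idx],
                                      orientation = rel[idx],
                                      stringsAsFactors = FALSE))
}
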