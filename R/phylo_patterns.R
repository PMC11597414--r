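# Labelled F/M phylogenies and DUI pattern classification. Trees are rooted
# (sister-group relations are root-dependent); neighbor-joining from
# p-distance matrices is provided as plumbing from distances to a tree.

#' Build a labelled sex tree
#'
#' @param phy A rooted `ape::phylo` tree.
#' @param sep Separator in tip labels of the form `<species><sep><F|M>`;
#'   tips without the separator (e.g. outgroups) get sex `"unknown"`.
#' @param outgroup Character vector of outgroup tip labels.
#' @return Object of class `sex_tree`: `phy`, `species`, `sex` (per tip),
#'   `outgroup`.
#' @export
sex_tree <- function(phy, sep = "__", outgroup = character(0)) {
  stopifnot(inherits(phy, "phylo"))
  if (anyDuplicated(phy$tip.label)) stop("tip labels must be unique")
  parts <- strsplit(phy$tip.label, sep, fixed = TRUE)
  species <- vapply(parts, `[`, character(1), 1)
  sex <- vapply(parts, function(p) if (length(p) >= 2 && p[2] %in% c("F", "M"))
    p[2] else "unknown", character(1))
  dup <- paste(species, sex)[sex != "unknown"]
  if (anyDuplicated(dup)) stop("every species may have at most one F and one M tip")
  structure(list(phy = phy, species = species, sex = sex,
                 outgroup = outgroup),
            class = "sex_tree")
}

#' @export
print.sex_tree <- function(x, ...) {
  cat(sprintf("<sex_tree> %d tips (%d F, %d M), rooted: %s\n",
              length(x$phy$tip.label), sum(x$sex == "F"), sum(x$sex == "M"),
              ape::is.rooted(x$phy)))
  invisible(x)
}

#' Read a sex-labelled tree from newick
#'
#' @param path Newick file path.
#' @param sep Tip-label separator (default `"__"`).
#' @param outgroup Outgroup tip labels; when given, the tree is rooted on
#'   them.
#' @return A `sex_tree`.
#' @export
read_sex_tree <- function(path, sep = "__", outgroup = character(0)) {
  phy <- ape::read.tree(path)
  if (length(outgroup)) phy <- ape::root(phy, outgroup, resolve.root = TRUE)
  sex_tree(phy, sep = sep, outgroup = outgroup)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via ape); negative branch lengths are clamped
#' to zero with a warning; the result is rooted at the outgroup when one is
#' supplied (classification requires a rooted tree).
#'
#' @param d Symmetric distance matrix with zero diagonal (labels as
#'   dimnames), n >= 3.
#' @param outgroup Tip label(s) to root on.
#' @param sep Tip-label separator for species/sex parsing.
#' @return A `sex_tree`.
#' @export
nj_tree <- function(d, outgroup = character(0), sep = "__") {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  phy <- ape::nj(d)
  if (any(phy$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0", call. = FALSE)
    phy$edge.length[phy$edge.length < 0] <- 0
  }
  if (length(outgroup)) phy <- ape::root(phy, outgroup, resolve.root = TRUE)
  sex_tree(phy, sep = sep, outgroup = outgroup)
}

tips_under <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_under, phy = phy))
}

#' Classify the F/M phylogenetic pattern of each DUI species
#'
#' For every species with both an F and an M tip, in order:
#' (a) `taxon_joining` when the smallest clade containing the species' F
#' and M tips contains no other species' F/M tips; (b) `gender_joining`
#' when the sister group of the F tip consists only of other species' F
#' tips and the sister group of the M tip only of other species' M tips;
#' (c) `masculinization_signature` when some other species' M tip lies
#' inside the smallest clade containing the two species' F tips while this
#' species' M tip attaches outside it (the F-like M genome of a recently
#' masculinized lineage); (d) `indeterminate` otherwise. Species missing
#' one sex tip are skipped with a note. Calls are topology-based; branch
#' supports do not change calls.
#'
#' @param t A rooted `sex_tree`.
#' @return Data frame of class `pattern_calls`: `species`, `label`,
#'   `evidence`.
#' @export
classify_patterns <- function(t) {
  phy <- t$phy
  if (!ape::is.rooted(phy)) stop("classification requires a rooted tree")
  ntip <- length(phy$tip.label)
  sp <- t$species; sex <- t$sex
  dui_species <- intersect(sp[sex == "F"], sp[sex == "M"])
  skipped <- setdiff(unique(sp[sex %in% c("F", "M")]), dui_species)
  if (length(skipped))
    message("species missing one sex tip, skipped: ",
            paste(skipped, collapse = ", "))
  tip_of <- function(s, x) which(sp == s & sex == x)
  fm_tips <- which(sex %in% c("F", "M"))
  rows <- list()
  for (s in dui_species) {
    fs <- tip_of(s, "F"); ms <- tip_of(s, "M")
    mrca <- ape::getMRCA(phy, c(fs, ms))
    clade <- tips_under(phy, mrca)
    others <- setdiff(intersect(clade, fm_tips), c(fs, ms))
    label <- NULL; evidence <- ""
    if (!length(others)) {
      label <- "taxon_joining"
      evidence <- sprintf("smallest clade containing %s F and M holds no other F/M tips", s)
    } else {
      sister_set <- function(tip) {
        parent <- phy$edge[phy$edge[, 2] == tip, 1]
        setdiff(tips_under(phy, parent), tip)
      }
      sis_f <- intersect(sister_set(fs), fm_tips)
      sis_m <- intersect(sister_set(ms), fm_tips)
      pure_f <- length(sis_f) > 0 && all(sex[sis_f] == "F") &&
        !fs %in% sis_f && !ms %in% sis_f
      pure_m <- length(sis_m) > 0 && all(sex[sis_m] == "M") &&
        !ms %in% sis_m && !fs %in% sis_m
      if (pure_f && pure_m) {
        label <- "gender_joining"
        evidence <- sprintf("F sister group {%s}; M sister group {%s}",
                            paste(phy$tip.label[sis_f], collapse = ","),
                            paste(phy$tip.label[sis_m], collapse = ","))
      } else {
        for (tsp in setdiff(dui_species, s)) {
          ft <- tip_of(tsp, "F"); mt <- tip_of(tsp, "M")
          cl <- tips_under(phy, ape::getMRCA(phy, c(fs, ft)))
          if (mt %in% cl && !(ms %in% cl)) {
            label <- "masculinization_signature"
            evidence <- sprintf(
              "clade {%s} joins %s F with both genomes of %s; %s M attaches outside",
              paste(phy$tip.label[intersect(cl, fm_tips)], collapse = ","),
              s, tsp, s)
            break
          }
        }
        if (is.null(label)) {
          label <- "indeterminate"
          evidence <- sprintf("clade of %s F+M also holds {%s}", s,
                              paste(phy$tip.label[others], collapse = ","))
        }
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(species = s, label = label,
                                            evidence = evidence,
                                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), label = character(),
               evidence = character(), stringsAsFactors = FALSE)
  class(out) <- c("pattern_calls", class(out))
  out
}

#' Tally pattern calls
#'
#' @param calls A `pattern_calls` data frame.
#' @return Named list: `counts` (table of labels), `species` (list of
#'   species per label).
#' @export
pattern_summary <- function(calls) {
  if (!nrow(calls)) return(list(counts = table(character(0)),
                                species = list()))
  list(counts = table(calls$label),
       species = split(calls$species, calls$label))
}

#' Pairwise p-distance matrix for a set of genomes
#'
#' @param genomes List of [mito_genome()] objects.
#' @param method Passed to [whole_genome_p_distance()]; `"positional"`
#'   requires equal genome lengths.
#' @param labels Tip labels (default `<species>__<sex>`).
#' @param sep Label separator.
#' @return Symmetric matrix of uncorrected p-distances.
#' @export
p_distance_matrix <- function(genomes, method = c("positional", "align"),
                              labels = NULL, sep = "__") {
  method <- match.arg(method)
  n <- length(genomes)
  if (is.null(labels))
    labels <- vapply(genomes, function(g)
      if (g$sex_type == "unknown") g$species
      else paste(g$species, g$sex_type, sep = sep), character(1))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- whole_genome_p_distance(genomes[[i]], genomes[[j]],
                                 method = method)$p
    d[i, j] <- d[j, i] <- p
  }
  d
}
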