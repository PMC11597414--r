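# Orchestration: run the full per-species F/M comparative analysis from a
# YAML config and emit the publication-style report tables (composition,
# divergence, dN/dS, cox2 modifications, UR characterization, gene orders,
# pattern calls) as TSV/JSON plus a provenance block.

#' Run the full comparative pipeline
#'
#' Config keys: `genomes` — list of entries `file` (GenBank flat file),
#' optional `species`/`sex` overrides; `out` — output directory (overridden
#' by the `out` argument); optional `tree` (newick with `<species>__<F|M>`
#' tips) and `outgroup`; optional `seed`; optional threshold overrides
#' `min_principal`, `trf`, `gstring`, `motif_min_identity`, `fold`,
#' `dnds_genes`, `distance_method` (`positional`/`align`). Species present
#' with only one sex-type are kept in single-genome tables and excluded
#' from F/M comparisons (logged).
#'
#' @param config Path to a YAML config file, or an equivalent list.
#' @param out Output directory (created if needed).
#' @return An `analysis_report` list with all tables (also written to
#'   `out`).
#' @export
run_pipeline <- function(config, out = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$genomes) || !length(cfg$genomes))
    stop("config lists no genomes (usage error)")
  out <- out %||% cfg$out %||% stop("no output directory configured")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "log.txt")
  logi <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                            append = TRUE)
  cat("", file = logf)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  genomes <- lapply(cfg$genomes, function(e) {
    g <- read_genbank(e$file)
    if (!is.null(e$species)) g$species <- e$species
    if (!is.null(e$sex)) g$sex_type <- e$sex
    g
  })
  logi("loaded %d genomes", length(genomes))

  # composition + codon usage
  comp <- do.call(rbind, lapply(genomes, composition_by_class))
  write.table(comp, file.path(out, "composition.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cu <- do.call(rbind, lapply(genomes, function(g) {
    r <- codon_usage(g)
    if (nrow(r$table)) cbind(genome = g$id, r$table) else NULL
  }))
  write.table(cu, file.path(out, "codon_usage.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # species F/M pairing
  sp <- vapply(genomes, function(g) g$species, character(1))
  sx <- vapply(genomes, function(g) g$sex_type, character(1))
  pair_species <- intersect(sp[sx == "F"], sp[sx == "M"])
  unpaired <- setdiff(unique(sp), pair_species)
  if (length(unpaired))
    logi("species without both sex-types (excluded from F/M comparisons): %s",
         paste(unpaired, collapse = ", "))

  dnds_genes <- cfg$dnds_genes %||% PCG_SYMBOLS
  div_rows <- list(); dnds_rows <- list(); cox2_rows <- list()
  for (s in pair_species) {
    f <- genomes[[which(sp == s & sx == "F")[1]]]
    m <- genomes[[which(sp == s & sx == "M")[1]]]
    meth <- cfg$distance_method %||%
      (if (genome_length(f) == genome_length(m)) "positional" else "align")
    wg <- whole_genome_p_distance(f, m, method = meth)
    div_rows[[length(div_rows) + 1L]] <- cbind(species = s, wg)
    logi("%s whole-genome p-distance (%s): %.4f", s, meth, wg$p)
    shared <- intersect(f$features$gene, m$features$gene)
    for (gn in intersect(dnds_genes, shared)) {
      al <- tryCatch(global_align(extract_gene_seq(f, gn),
                                  extract_gene_seq(m, gn), mode = "codon"),
                     error = function(e) NULL)
      if (is.null(al)) { logi("%s %s: codon alignment failed", s, gn); next }
      div_rows[[length(div_rows) + 1L]] <-
        cbind(species = s, p_distance(al, gene = gn))
      dnds_rows[[length(dnds_rows) + 1L]] <-
        cbind(species = s, ng86_dnds(al, gene = gn))
    }
    for (gn in intersect(RRNA_SYMBOLS, shared)) {
      al <- global_align(extract_gene_seq(f, gn), extract_gene_seq(m, gn),
                         mode = "nt")
      div_rows[[length(div_rows) + 1L]] <-
        cbind(species = s, p_distance(al, gene = gn))
    }
    if ("cox2" %in% shared) {
      sc <- cox2_mod_scan(extract_gene_seq(f, "cox2"),
                          extract_gene_seq(m, "cox2"),
                          extract_gene_seq(f, "cox2"))
      for (side in c("F", "M"))
        cox2_rows[[length(cox2_rows) + 1L]] <- data.frame(
          species = s, sex_type = side, kind = sc[[side]]$kind,
          length_nt = sc[[side]]$length_nt,
          length_codons = sc[[side]]$length_codons,
          tmh_in_modified_region = sc[[side]]$tmh_in_modified_region,
          stringsAsFactors = FALSE)
    }
  }
  divergence <- do.call(rbind, div_rows)
  dnds <- do.call(rbind, dnds_rows)
  cox2 <- do.call(rbind, cox2_rows)
  for (nm in c("divergence", "dnds", "cox2")) {
    obj <- get(nm)
    if (!is.null(obj))
      write.table(obj, file.path(out, paste0(nm, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }

  # UR characterization
  urcfg <- list(trf = cfg$trf, gstring = cfg$gstring,
                motif_min_identity = cfg$motif_min_identity,
                fold = cfg$fold)
  elements <- if (!is.null(cfg$elements)) load_elements(cfg$elements)
              else load_elements()
  ur_reports <- lapply(genomes, characterize_urs, elements = elements,
                       min_principal = cfg$min_principal %||% 150,
                       config = urcfg)
  urtab <- ur_table(ur_reports, file.path(out, "ur_table.tsv"))
  jsonlite::write_json(
    lapply(ur_reports, function(r) {
      r$records <- lapply(r$records, function(rec) {
        rec$fold <- list(max_pairs = rec$fold$max_pairs,
                         stems = rec$fold$stems, labels = rec$fold$labels)
        rec
      })
      unclass(r)
    }),
    file.path(out, "ur_details.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)

  # gene orders + rearrangements within species
  orders <- lapply(genomes, gene_order_of)
  writeLines(vapply(orders, format_gene_order, character(1)),
             file.path(out, "gene_orders.tsv"))
  rear_rows <- list()
  for (s in pair_species) {
    a <- orders[[which(sp == s & sx == "F")[1]]]
    b <- orders[[which(sp == s & sx == "M")[1]]]
    r <- compare_orders(a, b)
    rear_rows[[length(rear_rows) + 1L]] <- data.frame(
      species = s, breakpoint_distance = r$breakpoint_distance,
      transposed = paste(r$transposed, collapse = ","),
      duplicated_in_M = paste(r$duplicated_in_b, collapse = ","),
      absent_in_M = paste(r$absent_in_b, collapse = ","),
      stringsAsFactors = FALSE)
  }
  rear <- do.call(rbind, rear_rows)
  if (!is.null(rear))
    write.table(rear, file.path(out, "rearrangements.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  # phylogenetic patterns
  calls <- NULL; tally <- NULL
  tr <- NULL
  if (!is.null(cfg$tree)) {
    tr <- read_sex_tree(cfg$tree, outgroup = cfg$outgroup %||% character(0))
  } else if (length(genomes) >= 4) {
    lens <- vapply(genomes, genome_length, numeric(1))
    meth <- if (length(unique(lens)) == 1) "positional" else "align"
    d <- p_distance_matrix(genomes, method = meth)
    og <- cfg$outgroup %||% rownames(d)[sx == "unknown"][1]
    if (!is.null(og) && !is.na(og)) {
      tr <- nj_tree(d, outgroup = og)
      logi("NJ tree built from %s whole-genome p-distances, rooted on %s",
           meth, og)
    } else logi("no outgroup available; pattern classification skipped")
  }
  if (!is.null(tr)) {
    calls <- classify_patterns(tr)
    tally <- pattern_summary(calls)
    write.table(calls, file.path(out, "pattern_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(tally$counts),
                file.path(out, "pattern_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  prov <- list(package = "duimito",
               version = as.character(packageVersion("duimito")),
               seed = cfg$seed %||% NA,
               config_hash = if (is.character(config))
                 unname(tools::md5sum(config)) else NA,
               thresholds = list(
                 min_principal = cfg$min_principal %||% 150,
                 motif_min_identity = cfg$motif_min_identity %||% 0.5))
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE)
  structure(list(composition = comp, codon_usage = cu,
                 divergence = divergence, dnds = dnds, cox2 = cox2,
                 ur_table = urtab, ur_reports = ur_reports,
                 rearrangements = rear, pattern_calls = calls,
                 pattern_summary = tally, provenance = prov, out = out),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(sprintf("  genomes: %d composition scopes, %d UR rows\n",
              nrow(x$composition), nrow(x$ur_table)))
  if (!is.null(x$divergence))
    cat(sprintf("  divergence rows: %d; dN/dS rows: %d\n",
                nrow(x$divergence), if (is.null(x$dnds)) 0L else nrow(x$dnds)))
  if (!is.null(x$pattern_calls)) {
    cat("  pattern calls:\n")
    print(x$pattern_summary$counts)
  }
  cat(sprintf("  outputs in: %s\n", x$out))
  invisible(x)
}
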