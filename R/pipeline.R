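#' Bundled annotation fixtures: two strombid gastropod mitogenomes
#'
#' Loads the full published organization tables of the Harpago chiragra
#' (15,460 bp) and Lambis lambis (15,481 bp) mitochondrial genomes shipped
#' with the package (annotations only; the deposited sequences are not
#' redistributed).
#'
#' @return a `mito_annotation` without sequence.
#' @export
#' @examples
#' scan_spacers(chiragra_annotation())$overlap_count # 4
chiragra_annotation <- function() {
  read_annotation_tsv(system.file("extdata", "harpago_chiragra_anno.tsv",
                                  package = "mitocomp", mustWork = TRUE))
}

#' @rdname chiragra_annotation
#' @export
lambis_annotation <- function() {
  read_annotation_tsv(system.file("extdata", "lambis_lambis_anno.tsv",
                                  package = "mitocomp", mustWork = TRUE))
}

#' Run the full comparative characterization pipeline
#'
#' Produces the package's report bundle for one or more annotated genomes:
#' per-genome organization tables, validation findings, gene-order
#' comparison (equivalence and breakpoint distances), start/stop codon
#' comparison, and -- for genomes that carry sequence -- per-region
#' composition tables, pooled RSCU tables with the A+T-rich codon usage
#' ratio, and pairwise distance matrices on the concatenated PCGs (computed
#' only when gene spans match across genomes, i.e. for alignment-free
#' identical-length gene sets such as simulated pairs; externally aligned
#' gene blocks can be fed to [distance_matrix()] directly). Sections whose
#' inputs are unavailable are skipped with a notice, not an error.
#'
#' @param genomes named list of `mito_annotation` objects.
#' @param out_dir optional directory; when given, every table is written as
#'   TSV with fixed ordering and rounding (2 decimals for percents and
#'   skews) plus a machine-readable `summary.json`.
#' @param reference_gene anchor for gene-order canonicalization.
#' @param genetic_code genetic code id for codon work (default `"5"`).
#' @return list of class `report_bundle` with elements
#'   `organization_tables`, `validation`, `gene_order_report`,
#'   `codon_comparison`, `composition_tables`, `rscu_tables`,
#'   `at_rich_ratios`, `distance_matrix`, `notices`.
#' @export
run_pipeline <- function(genomes, out_dir = NULL, reference_gene = "cox1",
                         genetic_code = "5") {
  if (inherits(genomes, "mito_annotation")) genomes <- list(genomes)
  stopifnot(length(genomes) >= 1L)
  labels <- names(genomes)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- vapply(genomes, function(g) {
      if (nzchar(g$organism)) g$organism else "genome"
    }, character(1L))
    labels <- make.unique(gsub("[^A-Za-z0-9._ -]", "", labels), sep = "_")
    names(genomes) <- labels
  }
  notices <- character()
  bundle <- list()
  bundle$organization_tables <- lapply(genomes, organization_table)
  bundle$validation <- lapply(genomes, validate_annotation)
  bundle$spacer_reports <- lapply(genomes, scan_spacers)
  bundle$protein_lengths <- lapply(genomes, protein_lengths)

  if (length(genomes) >= 2L) {
    orders <- lapply(genomes, gene_order)
    pairs <- utils::combn(labels, 2L, simplify = FALSE)
    bundle$gene_order_report <- do.call(rbind, lapply(pairs, function(pr) {
      a <- orders[[pr[1L]]]; b <- orders[[pr[2L]]]
      data.frame(genome_a = pr[1L], genome_b = pr[2L],
                 equivalent = orders_equivalent(a, b, reference_gene),
                 breakpoints = breakpoint_distance(a, b),
                 stringsAsFactors = FALSE)
    }))
    bundle$codon_comparison <- start_stop_table(genomes)
  } else {
    notices <- c(notices, "single genome: pairwise sections empty")
    bundle$gene_order_report <- NULL
    bundle$codon_comparison <- NULL
  }

  with_seq <- vapply(genomes, function(g) !is.null(g$sequence), logical(1L))
  if (any(with_seq)) {
    seqd <- genomes[with_seq]
    bundle$composition_tables <- lapply(seqd, region_class_stats)
    usage <- lapply(seqd, function(g) codon_usage(g, genetic_code))
    bundle$rscu_tables <- lapply(usage, rscu, genetic_code = genetic_code)
    bundle$at_rich_ratios <- vapply(usage, at_rich_ratio, numeric(1L))
    if (sum(with_seq) >= 2L) {
      blocks <- try(pcg_blocks(seqd), silent = TRUE)
      if (inherits(blocks, "try-error")) {
        notices <- c(notices,
                     "PCG spans differ across genomes: distance matrix skipped (align externally and use distance_matrix())")
        bundle$distance_matrix <- NULL
      } else {
        bundle$distance_matrix <- distance_matrix(blocks, mode = "k2p",
                                                  level = "concatenated")
      }
    }
  } else {
    notices <- c(notices,
                 "no genome carries sequence: composition/RSCU/distance skipped")
  }
  bundle$notices <- notices
  class(bundle) <- "report_bundle"
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

# internal: per-gene sequence blocks across genomes; errors if a shared PCG
# has unequal spans (those inputs need external alignment)
pcg_blocks <- function(genomes) {
  gene_sets <- lapply(genomes, function(g) {
    g$features$gene[g$features$class == "PCG"]
  })
  shared <- Reduce(intersect, gene_sets)
  if (length(shared) == 0L) stop("no shared PCGs")
  blocks <- lapply(shared, function(gn) {
    seqs <- vapply(genomes, function(g) {
      row <- g$features[g$features$gene == gn, ][1L, ]
      feature_sequence(g, row, strand = "gene")
    }, character(1L))
    if (length(unique(nchar(seqs))) != 1L) {
      stop("unequal spans for gene ", gn)
    }
    seqs
  })
  stats::setNames(blocks, shared)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Comparative mitogenome report bundle\n")
  cat("  genomes: ", paste(names(x$organization_tables), collapse = ", "),
      "\n", sep = "")
  sections <- c("organization_tables", "gene_order_report",
                "codon_comparison", "composition_tables", "rscu_tables",
                "distance_matrix")
  present <- sections[vapply(sections, function(s) !is.null(x[[s]]),
                             logical(1L))]
  cat("  sections: ", paste(present, collapse = ", "), "\n", sep = "")
  for (n in x$notices) cat("  notice: ", n, "\n", sep = "")
  invisible(x)
}

# internal: round percent/skew columns for report output (2 decimals,
# full precision retained in the in-memory bundle)
round_stats <- function(df) {
  for (col in intersect(c("at_content", "at_skew", "gc_skew", "rscu"),
                        names(df))) {
    df[[col]] <- round(df[[col]], 2)
  }
  df
}

write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  slug <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)
  wt <- function(df, file) {
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  }
  for (nm in names(bundle$organization_tables)) {
    wt(bundle$organization_tables[[nm]],
       paste0("organization_", slug(nm), ".tsv"))
  }
  if (!is.null(bundle$codon_comparison)) {
    wt(bundle$codon_comparison$table, "start_stop_codons.tsv")
  }
  if (!is.null(bundle$gene_order_report)) {
    wt(bundle$gene_order_report, "gene_order.tsv")
  }
  for (nm in names(bundle$composition_tables)) {
    wt(round_stats(bundle$composition_tables[[nm]]),
       paste0("composition_", slug(nm), ".tsv"))
  }
  for (nm in names(bundle$rscu_tables)) {
    wt(round_stats(bundle$rscu_tables[[nm]]), paste0("rscu_", slug(nm), ".tsv"))
  }
  if (!is.null(bundle$distance_matrix)) {
    dm <- as.data.frame(round(bundle$distance_matrix, 4))
    dm <- cbind(taxon = rownames(dm), dm)
    wt(dm, "k2p_distance.tsv")
  }
  summary <- list(
    genomes = lapply(names(bundle$organization_tables), function(nm) {
      sp <- bundle$spacer_reports[[nm]]
      list(label = nm,
           genome_length = sp$genome_length,
           n_features = nrow(bundle$organization_tables[[nm]]),
           overlap_count = sp$overlap_count,
           noncoding_count = sp$noncoding_count,
           largest_gap_bp = if (is.null(sp$largest_gap)) NULL else sp$largest_gap$bp,
           total_aa = bundle$protein_lengths[[nm]]$total,
           n_validation_findings = nrow(bundle$validation[[nm]]))
    }),
    n_start_stop_differences =
      if (is.null(bundle$codon_comparison)) NULL else bundle$codon_comparison$n_differ,
    at_rich_ratios = as.list(bundle$at_rich_ratios),
    notices = bundle$notices
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}
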