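# Genetic-code helpers. The default throughout is NCBI translation table 5
# (invertebrate mitochondrial: TGA=Trp, AGA/AGG=Ser, ATA=Met; stops TAA/TAG),
# obtained from Biostrings; any table id accepted by getGeneticCode() works.

get_code <- function(genetic_code = "5") {
  Biostrings::getGeneticCode(genetic_code)
}

#' Synonymous codon families of a genetic code
#'
#' @param genetic_code id or name understood by
#'   [Biostrings::getGeneticCode()]; default `"5"` (invertebrate
#'   mitochondrial).
#' @return named list, one character vector of DNA codons per amino acid
#'   (stop codons excluded).
#' @export
codon_families <- function(genetic_code = "5") {
  code <- get_code(genetic_code)
  sense <- code[code != "*"]
  split(names(sense), unname(sense))
}

#' Extract the codon sequence of every protein-coding gene
#'
#' Slices each PCG from the genome sequence, reverse-complements minus-strand
#' genes so codons are read in the gene's own frame, and splits the span into
#' consecutive 3-mers. The first codon is the start codon and the last the
#' terminator. Genes whose span is not divisible by 3, or which contain an
#' internal stop codon, are reported in the `findings` attribute (the gene is
#' still returned, truncated to whole codons when necessary).
#'
#' @param g a `mito_annotation` carrying its sequence.
#' @param genetic_code genetic code used to recognize stop codons.
#' @return named list of character vectors of codons, one per PCG, with a
#'   `findings` attribute (data.frame `gene`, `code`, `message`).
#' @export
extract_codons <- function(g, genetic_code = "5") {
  stopifnot(inherits(g, "mito_annotation"))
  if (is.null(g$sequence)) stop("annotation carries no sequence")
  code <- get_code(genetic_code)
  stops <- names(code)[code == "*"]
  p <- g$features[g$features$class == "PCG", , drop = FALSE]
  findings <- list()
  out <- lapply(seq_len(nrow(p)), function(i) {
    s <- feature_sequence(g, p[i, ], strand = "gene")
    n <- nchar(s)
    if (n %% 3L != 0L) {
      findings[[length(findings) + 1L]] <<- data.frame(
        gene = p$gene[i], code = "span_not_divisible_by_3",
        message = sprintf("span %d truncated to %d codons", n, n %/% 3L),
        stringsAsFactors = FALSE)
      s <- substr(s, 1L, 3L * (n %/% 3L))
    }
    codons <- substring(s, seq(1L, nchar(s), by = 3L),
                        seq(3L, nchar(s), by = 3L))
    internal <- which(codons[-length(codons)][-1L] %in% stops) + 1L
    if (length(internal) > 0L) {
      findings[[length(findings) + 1L]] <<- data.frame(
        gene = p$gene[i], code = "internal_stop",
        message = paste("internal stop codon at codon position",
                        paste(internal, collapse = ", ")),
        stringsAsFactors = FALSE)
    }
    codons
  })
  names(out) <- p$gene
  attr(out, "findings") <- if (length(findings) > 0L) {
    do.call(rbind, findings)
  } else {
    data.frame(gene = character(), code = character(), message = character(),
               stringsAsFactors = FALSE)
  }
  out
}

#' Pooled codon usage counts of the protein-coding genes
#'
#' Counts every codon across PCGs excluding each gene's terminator (the
#' start codon encodes an amino acid under the mitochondrial code and is
#' included), so the count total equals the total encoded amino acids.
#'
#' @param codons output of [extract_codons()], or a `mito_annotation` with
#'   sequence (codons are then extracted first).
#' @param genetic_code genetic code id; stop codons are excluded from counts.
#' @return named integer vector over the sense codons of the code (zeros
#'   kept), in alphabetical codon order.
#' @export
codon_usage <- function(codons, genetic_code = "5") {
  if (inherits(codons, "mito_annotation")) {
    codons <- extract_codons(codons, genetic_code)
  }
  code <- get_code(genetic_code)
  sense <- sort(names(code)[code != "*"])
  used <- unlist(lapply(codons, function(cs) {
    if (length(cs) > 0L) cs[-length(cs)] else character()
  }), use.names = FALSE)
  used <- used[used %in% sense]  # drop internal stops / ambiguous codons
  cnt <- table(factor(used, levels = sense))
  stats::setNames(as.integer(cnt), sense)
}

#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of codon c = count(c) divided by the mean count over c's synonymous
#' family; 1 means no bias within the family. Families come from the genetic
#' code (62 sense codons under the invertebrate mitochondrial code). A family
#' with zero total usage has undefined (`NA`) RSCU, reported rather than
#' zeroed. Within every used family the RSCU values sum to the family size.
#'
#' @param counts named codon count vector as from [codon_usage()] (DNA
#'   alphabet), or anything [codon_usage()] accepts.
#' @param genetic_code genetic code id.
#' @return data.frame of class `rscu_table`: `codon` (DNA), `codon_rna`,
#'   `aa` (single-letter), `count`, `family_size`, `rscu`.
#' @export
#' @examples
#' counts <- codon_usage(list(g = c("TTT", "TTT", "TTT", "TTC", "TAA")))
#' rscu(counts)[c("TTT", "TTC") , ]
rscu <- function(counts, genetic_code = "5") {
  if (!is.numeric(counts)) counts <- codon_usage(counts, genetic_code)
  code <- get_code(genetic_code)
  sense <- sort(names(code)[code != "*"])
  if (is.null(names(counts)) || !all(names(counts) %in% names(code))) {
    stop("counts must be named by DNA codons of the chosen code")
  }
  full <- stats::setNames(rep(0L, length(sense)), sense)
  keep <- intersect(names(counts), sense)
  full[keep] <- counts[keep]
  aa <- unname(code[sense])
  fam_total <- tapply(full, aa, sum)
  fam_size <- table(aa)
  mean_cnt <- fam_total[aa] / as.integer(fam_size[aa])
  val <- ifelse(fam_total[aa] > 0, full / mean_cnt, NA_real_)
  out <- data.frame(
    codon = sense,
    codon_rna = chartr("T", "U", sense),
    aa = aa,
    count = as.integer(full),
    family_size = as.integer(fam_size[aa]),
    rscu = as.numeric(val),
    stringsAsFactors = FALSE
  )
  rownames(out) <- out$codon
  class(out) <- c("rscu_table", class(out))
  out
}

# internal: is a codon A+T-rich (2 or 3 of its positions A/T)? With three
# positions there are no ties, so every codon classifies.
is_at_rich <- function(codon) {
  vapply(strsplit(toupper(codon), "", fixed = TRUE),
         function(ch) sum(ch %in% c("A", "T", "U")) >= 2L, logical(1L))
}

#' Ratio of A+T-rich to G+C-rich codon usage
#'
#' A codon is A+T-rich when at least 2 of its 3 positions are A or T, and
#' G+C-rich otherwise (a majority always exists). The ratio is the total
#' usage of A+T-rich codons divided by the total usage of G+C-rich codons --
#' occurrences, not codon types. This majority-position definition is this
#' package's resolution of a term the literature leaves informal.
#'
#' @param counts named codon count vector (DNA alphabet), or anything
#'   [codon_usage()] accepts.
#' @return single numeric ratio; `NA` when no G+C-rich codon is used.
#' @export
#' @examples
#' at_rich_ratio(c(AAA = 27, GGG = 10)) # 2.7
at_rich_ratio <- function(counts) {
  if (!is.numeric(counts)) counts <- codon_usage(counts)
  if (length(counts) == 0L || sum(counts) == 0) stop("empty codon counts")
  rich <- is_at_rich(names(counts))
  denom <- sum(counts[!rich])
  if (denom == 0) {
    warning("no G+C-rich codon usage: ratio undefined")
    return(NA_real_)
  }
  sum(counts[rich]) / denom
}

#' Compare annotated start/stop codons across genomes
#'
#' Tabulates the annotated start and termination codon of every shared PCG in
#' each genome and counts the genes that initiate or terminate differently.
#' Works from the annotation's codon columns, so no sequence is needed.
#'
#' @param gs list of `mito_annotation` objects (named, or organism labels are
#'   used).
#' @return list with `table` (data.frame: `gene`, then `start_<label>` and
#'   `stop_<label>` per genome, plus logical `differs`) and `n_differ`.
#' @export
start_stop_table <- function(gs) {
  stopifnot(is.list(gs), length(gs) >= 1L)
  labels <- names(gs)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- vapply(gs, function(g) {
      if (nzchar(g$organism)) g$organism else "genome"
    }, character(1L))
    labels <- make.unique(labels, sep = "_")
  }
  pcg_sets <- lapply(gs, function(g) g$features$gene[g$features$class == "PCG"])
  shared <- Reduce(intersect, pcg_sets)
  missing <- unique(unlist(lapply(pcg_sets, function(s) setdiff(s, shared))))
  if (length(missing) > 0L) {
    stop("PCG sets differ across genomes: ", paste(missing, collapse = ", "))
  }
  tab <- data.frame(gene = shared, stringsAsFactors = FALSE)
  for (i in seq_along(gs)) {
    f <- gs[[i]]$features
    idx <- match(shared, f$gene)
    tab[[paste0("start_", labels[i])]] <- f$start_codon[idx]
    tab[[paste0("stop_", labels[i])]] <- f$stop_codon[idx]
  }
  starts <- tab[, grep("^start_", names(tab)), drop = FALSE]
  stops <- tab[, grep("^stop_", names(tab)), drop = FALSE]
  n_distinct <- function(x) length(unique(x[!is.na(x)]))
  tab$differs <- apply(starts, 1L, n_distinct) > 1L |
    apply(stops, 1L, n_distinct) > 1L
  list(table = tab, n_differ = sum(tab$differs))
}

#' Bar chart of RSCU values in the style of codon-usage figures
#'
#' @param rscu_tables named list of `rscu_table` objects (one per genome).
#' @return a ggplot object (requires ggplot2).
#' @export
plot_rscu <- function(rscu_tables) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plot_rscu()")
  }
  if (inherits(rscu_tables, "rscu_table")) {
    rscu_tables <- list(genome = rscu_tables)
  }
  df <- do.call(rbind, lapply(names(rscu_tables), function(nm) {
    cbind(genome = nm, rscu_tables[[nm]][, c("codon_rna", "aa", "rscu")])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = codon_rna, y = rscu, fill = genome)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(. ~ aa, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "RSCU") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}
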