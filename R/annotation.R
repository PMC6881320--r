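#' Construct an annotated circular mitochondrial genome
#'
#' The central container of the package: an ordered feature table plus the
#' genome length, topology and (optionally) the (+)-strand sequence. Feature
#' coordinates are 1-based inclusive, mirroring the convention of published
#' mitogenome organization tables; conversion to 0-based half-open happens
#' only inside sequence slicing. Origin-spanning features (end < start) are
#' not modeled and are rejected.
#'
#' @param features data.frame with columns `gene` (unique symbol, e.g.
#'   `cox1`, `trnD`, `rrnL`), `class` (one of `PCG`, `tRNA`, `rRNA`),
#'   `start`, `end` (1-based inclusive, `end >= start`), `strand` (`+` or
#'   `-`), and optionally `start_codon`/`stop_codon` (3-mers for PCGs, `NA`
#'   otherwise). Extra columns are dropped.
#' @param genome_length total genome size in bp.
#' @param organism free-text label used in reports.
#' @param circular logical; all supported genomes are circular.
#' @param sequence optional single character string of length
#'   `genome_length`: the (+)-strand nucleotide sequence.
#'
#' @return An object of class `mito_annotation`: a list with elements
#'   `organism`, `genome_length`, `circular`, `features` (sorted by start)
#'   and `sequence` (`NULL` if absent).
#'
#' @details Structural problems beyond basic type errors (coordinates out of
#'   range, spans not divisible by 3, census deviations, ...) are *not*
#'   raised here; they are reported as findings by [validate_annotation()] so
#'   that imperfect annotations can still be inspected.
#'
#' @seealso [validate_annotation()], [scan_spacers()], [read_annotation_tsv()]
#' @export
#' @examples
#' feats <- data.frame(
#'   gene = c("g1", "g2"), class = c("PCG", "tRNA"),
#'   start = c(1L, 34L), end = c(30L, 99L), strand = c("+", "-"),
#'   start_codon = c("ATG", NA), stop_codon = c("TAA", NA)
#' )
#' g <- genome_annotation(feats, genome_length = 100, organism = "toy")
#' g
genome_annotation <- function(features, genome_length, organism = "",
                              circular = TRUE, sequence = NULL) {
  stopifnot(is.data.frame(features), length(genome_length) == 1L,
            is.numeric(genome_length), genome_length >= 1)
  required <- c("gene", "class", "start", "end", "strand")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols) > 0L) {
    stop("features is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"start_codon" %in% names(features)) features$start_codon <- NA_character_
  if (!"stop_codon" %in% names(features)) features$stop_codon <- NA_character_
  features <- features[, c(required, "start_codon", "stop_codon")]
  features$gene <- as.character(features$gene)
  features$class <- as.character(features$class)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$strand <- as.character(features$strand)
  features$start_codon <- toupper(as.character(features$start_codon))
  features$stop_codon <- toupper(as.character(features$stop_codon))
  if (anyNA(features$start) || anyNA(features$end)) {
    stop("feature coordinates must be non-missing integers")
  }
  if (any(features$end < features$start)) {
    bad <- features$gene[features$end < features$start]
    stop("origin-spanning or inverted features are not supported: ",
         paste(bad, collapse = ", "))
  }
  if (!all(features$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  if (!all(features$class %in% c("PCG", "tRNA", "rRNA"))) {
    stop("class must be one of PCG, tRNA, rRNA")
  }
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  if (!is.null(sequence)) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    sequence <- toupper(sequence)
    if (nchar(sequence) != genome_length) {
      stop("sequence length (", nchar(sequence),
           ") does not match genome_length (", genome_length, ")")
    }
  }
  structure(
    list(organism = organism, genome_length = as.integer(genome_length),
         circular = isTRUE(circular), features = features, sequence = sequence),
    class = "mito_annotation"
  )
}

#' @export
print.mito_annotation <- function(x, ...) {
  cat("Annotated mitochondrial genome: ",
      if (nzchar(x$organism)) x$organism else "<unlabeled>", "\n", sep = "")
  cat("  length: ", x$genome_length, " bp (",
      if (x$circular) "circular" else "linear", "), sequence ",
      if (is.null(x$sequence)) "absent" else "present", "\n", sep = "")
  census <- table(factor(x$features$class, levels = c("PCG", "tRNA", "rRNA")))
  cat("  features: ", nrow(x$features), " (",
      paste(census, names(census), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Feature length in nucleotides
#'
#' Length of one or more features under 1-based inclusive coordinates:
#' `end - start + 1`. Vectorized over the rows of a feature table.
#'
#' @param f a `mito_annotation`, its `features` data.frame, or any
#'   data.frame-like with `start` and `end` columns.
#' @return integer vector of lengths, named by gene when available.
#' @export
#' @examples
#' feature_length(data.frame(start = 1, end = 1536)) # 1536
feature_length <- function(f) {
  if (inherits(f, "mito_annotation")) f <- f$features
  len <- as.integer(f$end - f$start + 1L)
  if (!is.null(f$gene)) names(len) <- f$gene
  len
}

#' Signed intergenic spacing between two adjacent features
#'
#' Number of nucleotides strictly between an upstream and a downstream
#' feature. Negative values signal an overlap. For the circular junction
#' (upstream = last feature, downstream = first), the spacer wraps across
#' the origin: `(genome_length - upstream$end) + (downstream$start - 1)`.
#'
#' @param upstream,downstream one-row data.frames (or lists) with `start`,
#'   `end` (and ideally `gene`) fields; `upstream` must precede `downstream`
#'   in annotation order.
#' @param genome_length genome size in bp; required when
#'   `circular_junction = TRUE`.
#' @param circular_junction is this the wrap-around pair closing the circle?
#' @return signed integer spacing in bp.
#' @export
#' @examples
#' gene_spacing(list(start = 1, end = 1536), list(start = 1556, end = 2242)) # 19
#' gene_spacing(list(start = 1556, end = 2242), list(start = 2241, end = 2308)) # -2
gene_spacing <- function(upstream, downstream, genome_length = NULL,
                         circular_junction = FALSE) {
  up_end <- as.integer(upstream$end)
  down_start <- as.integer(downstream$start)
  if (circular_junction) {
    if (is.null(genome_length)) {
      stop("genome_length is required for the circular junction")
    }
    sp <- (as.integer(genome_length) - up_end) + (down_start - 1L)
  } else {
    sp <- down_start - up_end - 1L
  }
  if (sp < 0) {
    up_len <- as.integer(upstream$end) - as.integer(upstream$start) + 1L
    down_len <- as.integer(downstream$end) - as.integer(downstream$start) + 1L
    if (-sp > up_len || -sp > down_len) {
      stop("malformed annotation: overlap of ", -sp,
           " bp exceeds a feature length")
    }
  }
  sp
}

#' Scan all intergenic spacers of a circular annotation
#'
#' Computes the signed spacing for every adjacent feature pair, including the
#' junction pair that closes the circle, and summarizes overlaps and
#' non-coding gaps. For a circular genome the number of pairs equals the
#' number of features, and the tiling identity holds:
#' sum of feature lengths + sum of signed spacings = genome length.
#'
#' @param g a `mito_annotation`.
#' @return An object of class `spacer_report`: list with `pairs` (data.frame
#'   `upstream`, `downstream`, `spacing`), `overlap_count`, `noncoding_count`,
#'   `largest_gap` (list `upstream`, `downstream`, `bp`; `NULL` if no positive
#'   gap), and `size_range` (min/max positive gap, `c(NA, NA)` if none).
#' @export
#' @examples
#' g <- read_annotation_tsv(system.file("extdata", "harpago_chiragra_anno.tsv",
#'                                      package = "mitocomp"))
#' rep <- scan_spacers(g)
#' rep$overlap_count   # 4
#' rep$largest_gap$bp  # 53
scan_spacers <- function(g) {
  stopifnot(inherits(g, "mito_annotation"))
  f <- g$features
  n <- nrow(f)
  if (n == 0L) stop("annotation has no features")
  if (is.unsorted(f$start)) stop("features must be sorted by start")
  if (n == 1L) {
    sp <- gene_spacing(f[1L, ], f[1L, ], g$genome_length, circular_junction = TRUE)
    pairs <- data.frame(upstream = f$gene, downstream = f$gene, spacing = sp,
                        stringsAsFactors = FALSE)
  } else {
    up <- seq_len(n - 1L)
    sp <- vapply(up, function(i) {
      gene_spacing(f[i, ], f[i + 1L, ])
    }, integer(1L))
    junction <- gene_spacing(f[n, ], f[1L, ], g$genome_length,
                             circular_junction = TRUE)
    pairs <- data.frame(
      upstream = f$gene[c(up, n)],
      downstream = f$gene[c(up + 1L, 1L)],
      spacing = c(sp, junction),
      stringsAsFactors = FALSE
    )
  }
  pos <- pairs$spacing > 0L
  largest <- NULL
  if (any(pos)) {
    i <- which.max(ifelse(pos, pairs$spacing, -Inf))
    largest <- list(upstream = pairs$upstream[i],
                    downstream = pairs$downstream[i],
                    bp = pairs$spacing[i])
  }
  structure(
    list(pairs = pairs,
         overlap_count = sum(pairs$spacing < 0L),
         noncoding_count = sum(pos),
         largest_gap = largest,
         size_range = if (any(pos)) range(pairs$spacing[pos]) else c(NA_integer_, NA_integer_),
         genome_length = g$genome_length,
         organism = g$organism),
    class = "spacer_report"
  )
}

#' @export
print.spacer_report <- function(x, ...) {
  cat("Spacer scan", if (nzchar(x$organism)) paste0(" (", x$organism, ")"),
      ": ", nrow(x$pairs), " adjacent pairs on a ", x$genome_length,
      " bp circle\n", sep = "")
  cat("  overlaps: ", x$overlap_count,
      "; non-coding gaps: ", x$noncoding_count, "\n", sep = "")
  if (!is.null(x$largest_gap)) {
    cat("  largest gap: ", x$largest_gap$bp, " bp between ",
        x$largest_gap$upstream, " and ", x$largest_gap$downstream, "\n",
        sep = "")
    cat("  positive gap range: ", x$size_range[1L], "-", x$size_range[2L],
        " bp\n", sep = "")
  }
  invisible(x)
}

#' Amino acids encoded per protein-coding gene
#'
#' For each PCG, the encoded protein length excluding the terminator:
#' `span/3 - 1`. Genes whose span is not divisible by 3 are flagged and
#' excluded from the total with a warning.
#'
#' @param g a `mito_annotation`.
#' @return list with `per_gene` (data.frame `gene`, `span_nt`, `aa`,
#'   `divisible`) and `total` (sum of `aa` over divisible PCGs).
#' @export
#' @examples
#' g <- read_annotation_tsv(system.file("extdata", "harpago_chiragra_anno.tsv",
#'                                      package = "mitocomp"))
#' protein_lengths(g)$total  # 3744
protein_lengths <- function(g) {
  stopifnot(inherits(g, "mito_annotation"))
  p <- g$features[g$features$class == "PCG", , drop = FALSE]
  span <- feature_length(p)
  divisible <- span %% 3L == 0L
  aa <- ifelse(divisible, span %/% 3L - 1L, NA_integer_)
  if (any(!divisible)) {
    warning("PCG span not divisible by 3, excluded from total: ",
            paste(p$gene[!divisible], collapse = ", "))
  }
  list(
    per_gene = data.frame(gene = p$gene, span_nt = as.integer(span),
                          aa = as.integer(aa), divisible = divisible,
                          stringsAsFactors = FALSE),
    total = sum(aa, na.rm = TRUE)
  )
}

#' Validate an annotation and report findings
#'
#' Structural checks returning machine-readable findings rather than errors:
#' coordinates out of range, unsorted features, duplicate gene names, PCG
#' spans not divisible by 3, missing or misplaced start/stop codons,
#' overlaps exceeding a feature length, and deviations from the canonical
#' animal mitogenome census of 13 PCGs, 22 tRNAs and 2 rRNAs.
#'
#' @param g a `mito_annotation`.
#' @param expected_census named integer vector of expected feature counts per
#'   class; set to `NULL` to skip the census check.
#' @return data.frame with columns `severity` (`error` or `warning`), `code`,
#'   `gene` (`NA` for genome-level findings) and `message`; zero rows for a
#'   clean annotation.
#' @export
validate_annotation <- function(g, expected_census = c(PCG = 13L, tRNA = 22L,
                                                       rRNA = 2L)) {
  stopifnot(inherits(g, "mito_annotation"))
  f <- g$features
  findings <- list()
  add <- function(severity, code, gene, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      severity = severity, code = code, gene = gene, message = message,
      stringsAsFactors = FALSE)
  }
  out <- f$start < 1L | f$end > g$genome_length
  for (gname in f$gene[out]) {
    add("error", "coordinate_out_of_range", gname,
        "feature coordinates fall outside [1, genome_length]")
  }
  if (is.unsorted(f$start)) {
    add("error", "unsorted", NA_character_, "features not sorted by start")
  }
  dup <- unique(f$gene[duplicated(f$gene)])
  for (gname in dup) {
    add("error", "duplicate_name", gname,
        "gene name occurs more than once (disambiguate isotypes, e.g. trnL1/trnL2)")
  }
  is_pcg <- f$class == "PCG"
  span <- feature_length(f)
  for (gname in f$gene[is_pcg & span %% 3L != 0L]) {
    add("warning", "span_not_divisible_by_3", gname,
        "PCG nucleotide span is not divisible by 3")
  }
  miss <- is_pcg & (is.na(f$start_codon) | is.na(f$stop_codon))
  for (gname in f$gene[miss]) {
    add("warning", "missing_codon", gname,
        "PCG lacks an annotated start or stop codon")
  }
  stray <- !is_pcg & (!is.na(f$start_codon) | !is.na(f$stop_codon))
  for (gname in f$gene[stray]) {
    add("warning", "codon_on_non_pcg", gname,
        "non-PCG feature carries start/stop codon annotation")
  }
  # overlaps deeper than a whole feature indicate mis-assembled coordinates
  if (nrow(f) >= 2L && !is.unsorted(f$start)) {
    for (i in seq_len(nrow(f) - 1L)) {
      ov <- f$end[i] - f$start[i + 1L] + 1L
      if (ov > 0 && (ov > span[i] || ov > span[i + 1L])) {
        add("error", "overlap_exceeds_feature", f$gene[i + 1L],
            "overlap deeper than an adjacent feature (non-adjacent overlap?)")
      }
    }
  }
  if (!is.null(expected_census)) {
    census <- table(factor(f$class, levels = names(expected_census)))
    for (cl in names(expected_census)) {
      if (census[[cl]] != expected_census[[cl]]) {
        add("warning", paste0("census_", cl), NA_character_,
            sprintf("expected %d %s features, found %d",
                    expected_census[[cl]], cl, census[[cl]]))
      }
    }
  }
  if (length(findings) == 0L) {
    data.frame(severity = character(), code = character(),
               gene = character(), message = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, findings)
  }
}

# internal: tiling check used by tests and the pipeline summary
tiling_identity <- function(g) {
  rep <- scan_spacers(g)
  sum(feature_length(g)) + sum(rep$pairs$spacing)
}
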