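IUPAC_AMBIGUOUS <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

#' Base counts, A+T content and AT/GC skews of a nucleotide sequence
#'
#' The two strand-asymmetry statistics standard in mitogenomics:
#' AT skew = (A - T)/(A + T) and GC skew = (G - C)/(G + C), with
#' A+T content = 100 (A + T)/(A + T + G + C). IUPAC ambiguity codes are
#' tallied separately and excluded from every denominator. A skew whose
#' denominator is zero is `NA` (undefined), never forced to 0.
#'
#' @param seq single character string over the IUPAC nucleotide alphabet
#'   (case-insensitive; `U` treated as `T`).
#' @return one-row data.frame of class `composition_stats` with columns
#'   `length`, `n_A`, `n_T`, `n_G`, `n_C`, `n_ambiguous`, `at_content`
#'   (percent), `at_skew`, `gc_skew`.
#' @export
#' @examples
#' composition_stats("AATTTG") # at_skew -0.2, gc_skew 1
composition_stats <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (is.na(seq) || nchar(seq) == 0L) {
    stop("empty sequence: composition statistics are undefined")
  }
  s <- chartr("u", "T", toupper(seq))
  s <- chartr("U", "T", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  ok <- chars %in% c("A", "C", "G", "T", IUPAC_AMBIGUOUS)
  if (!all(ok)) {
    stop("non-nucleotide character(s) in sequence: ",
         paste(unique(chars[!ok]), collapse = ", "))
  }
  cnt <- table(factor(chars, levels = c("A", "C", "G", "T", IUPAC_AMBIGUOUS)))
  a <- cnt[["A"]]; t <- cnt[["T"]]; g <- cnt[["G"]]; c <- cnt[["C"]]
  amb <- length(chars) - (a + t + g + c)
  unamb <- a + t + g + c
  res <- data.frame(
    length = length(chars), n_A = a, n_T = t, n_G = g, n_C = c,
    n_ambiguous = amb,
    at_content = if (unamb > 0) 100 * (a + t) / unamb else NA_real_,
    at_skew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
    gc_skew = if (g + c > 0) (g - c) / (g + c) else NA_real_
  )
  class(res) <- c("composition_stats", class(res))
  res
}

# internal: (+)-strand subsequence of a feature row
feature_sequence <- function(g, row, strand = c("plus", "gene")) {
  strand <- match.arg(strand)
  s <- substr(g$sequence, row$start, row$end)
  if (strand == "gene" && row$strand == "-") s <- revcomp(s) else s
}

#' Reverse complement of a nucleotide string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] operating on plain
#' character strings.
#'
#' @param seq single nucleotide character string.
#' @return reverse-complemented character string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Composition statistics per region class of an annotated genome
#'
#' Reproduces the layout of per-gene mitogenome composition tables: one row
#' for the whole genome, one for the 13 protein-coding genes concatenated,
#' one per individual PCG, one for all tRNAs concatenated, and one each for
#' the small and large rRNAs. All statistics are computed on the (+)-strand
#' text regardless of gene strand (the convention of published skew tables);
#' `strand = "gene"` switches to native-strand sequences for exploration.
#' Overlapping bases count once per region they fall in.
#'
#' @param g a `mito_annotation` carrying its sequence.
#' @param class_spec character vector of region classes, any of `"whole"`,
#'   `"PCG"` (concatenated), `"genes"` (one row per PCG), `"tRNA"`
#'   (concatenated), `"rrnS"`, `"rrnL"`, or any annotated gene name.
#' @param strand `"plus"` (default) or `"gene"`.
#' @return data.frame with a `feature` column followed by the
#'   [composition_stats()] columns, one row per requested region.
#' @export
region_class_stats <- function(g,
                               class_spec = c("whole", "PCG", "genes",
                                              "tRNA", "rrnS", "rrnL"),
                               strand = c("plus", "gene")) {
  stopifnot(inherits(g, "mito_annotation"))
  if (is.null(g$sequence)) stop("annotation carries no sequence")
  strand <- match.arg(strand)
  f <- g$features
  get_seq <- function(rows) {
    paste(vapply(seq_len(nrow(rows)), function(i) {
      feature_sequence(g, rows[i, ], strand)
    }, character(1L)), collapse = "")
  }
  rows <- list()
  for (spec in class_spec) {
    if (spec == "whole") {
      rows[["whole genome"]] <- g$sequence
    } else if (spec == "PCG") {
      rows[["protein coding genes"]] <- get_seq(f[f$class == "PCG", ])
    } else if (spec == "genes") {
      p <- f[f$class == "PCG", , drop = FALSE]
      for (i in seq_len(nrow(p))) {
        rows[[p$gene[i]]] <- feature_sequence(g, p[i, ], strand)
      }
    } else if (spec == "tRNA") {
      rows[["tRNAs"]] <- get_seq(f[f$class == "tRNA", ])
    } else if (spec %in% f$gene) {
      rows[[spec]] <- feature_sequence(g, f[f$gene == spec, ][1L, ], strand)
    } else {
      stop("unknown region or gene: ", spec)
    }
  }
  out <- do.call(rbind, lapply(rows, composition_stats))
  out <- cbind(feature = names(rows), out)
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}
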