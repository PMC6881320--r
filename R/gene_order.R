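#' Signed circular gene order
#'
#' Represents a mitochondrial gene arrangement as a signed circular
#' permutation: an ordered list of (gene, strand) pairs around the circle.
#' Because a circular molecule has no intrinsic first gene and either strand
#' may serve as reference, comparisons are made on a canonical form (see
#' [canonicalize()]).
#'
#' @param x a `mito_annotation` (order taken from the sorted feature table),
#'   a data.frame with `gene` and `strand` columns, or a character vector of
#'   gene tokens where a leading `-` marks the minor strand
#'   (e.g. `c("cox1", "cox2", "-trnM")`).
#' @param circular logical, default `TRUE`.
#' @return object of class `gene_order`: data.frame with columns `gene`,
#'   `strand` and attribute `circular`.
#' @export
#' @examples
#' gene_order(c("cox1", "cox2", "-trnM", "rrnS"))
gene_order <- function(x, circular = TRUE) {
  if (inherits(x, "mito_annotation")) {
    df <- x$features[, c("gene", "strand")]
  } else if (is.data.frame(x)) {
    df <- data.frame(gene = as.character(x$gene),
                     strand = as.character(x$strand),
                     stringsAsFactors = FALSE)
  } else if (is.character(x)) {
    x <- trimws(x)
    minus <- startsWith(x, "-")
    df <- data.frame(gene = sub("^-", "", x),
                     strand = ifelse(minus, "-", "+"),
                     stringsAsFactors = FALSE)
  } else {
    stop("cannot build a gene order from class ", paste(class(x), collapse = "/"))
  }
  if (anyDuplicated(df$gene)) {
    stop("gene names must be unique in a gene order: ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  rownames(df) <- NULL
  structure(df, class = c("gene_order", "data.frame"), circular = circular)
}

#' @export
print.gene_order <- function(x, ...) {
  tokens <- ifelse(x$strand == "-", paste0("-", x$gene), x$gene)
  cat("Signed ", if (isTRUE(attr(x, "circular"))) "circular" else "linear",
      " gene order (", nrow(x), " genes):\n  ",
      paste(tokens, collapse = ","), "\n", sep = "")
  invisible(x)
}

# internal: rotate so element i is first
rotate_order <- function(o, i) {
  n <- nrow(o)
  idx <- ((seq_len(n) + i - 2L) %% n) + 1L
  o2 <- o[idx, , drop = FALSE]
  rownames(o2) <- NULL
  class(o2) <- class(o)
  attr(o2, "circular") <- attr(o, "circular")
  o2
}

# internal: view the circle from the opposite strand: reverse order, flip
# every strand
flip_order <- function(o) {
  o2 <- o[rev(seq_len(nrow(o))), , drop = FALSE]
  o2$strand <- ifelse(o2$strand == "+", "-", "+")
  rownames(o2) <- NULL
  class(o2) <- class(o)
  attr(o2, "circular") <- attr(o, "circular")
  o2
}

#' Canonical form of a circular gene order
#'
#' Rotates the circle so a fixed reference gene comes first and, if the
#' reference lies on the minor strand, flips the whole circle (reverse order
#' and all strands) first. Two arrangements of the same circular molecule
#' therefore share a single canonical form regardless of where the linear
#' representation was cut or which strand was reported.
#'
#' @param o a `gene_order` (or anything [gene_order()] accepts).
#' @param reference reference gene symbol, default `"cox1"` (the
#'   conventional anchor of mitogenome maps).
#' @return canonicalized `gene_order`.
#' @export
canonicalize <- function(o, reference = "cox1") {
  if (!inherits(o, "gene_order")) o <- gene_order(o)
  i <- match(reference, o$gene)
  if (is.na(i)) stop("reference gene '", reference, "' absent from order")
  if (o$strand[i] == "-") {
    o <- flip_order(o)
    i <- match(reference, o$gene)
  }
  rotate_order(o, i)
}

#' Are two circular gene orders equivalent?
#'
#' True iff the canonical forms (same reference gene, same rotation and
#' strand convention) agree in both gene sequence and strands.
#'
#' @param a,b gene orders over the same gene set.
#' @param reference reference gene for canonicalization.
#' @return logical.
#' @export
orders_equivalent <- function(a, b, reference = "cox1") {
  if (!inherits(a, "gene_order")) a <- gene_order(a)
  if (!inherits(b, "gene_order")) b <- gene_order(b)
  check_same_genes(a, b)
  ca <- canonicalize(a, reference)
  cb <- canonicalize(b, reference)
  identical(ca$gene, cb$gene) && identical(ca$strand, cb$strand)
}

check_same_genes <- function(a, b) {
  only_a <- setdiff(a$gene, b$gene)
  only_b <- setdiff(b$gene, a$gene)
  if (length(only_a) > 0L || length(only_b) > 0L) {
    stop("gene orders are incomparable; symmetric difference: ",
         paste(c(only_a, only_b), collapse = ", "))
  }
  invisible(TRUE)
}

#' Signed adjacency set of a circular gene order
#'
#' Every pair of neighbouring genes on the circle yields one adjacency.
#' In signed mode an adjacency records the relative orientation of the two
#' genes and is normalized over the two reading directions of the circle, so
#' the set is invariant to rotation and to a global strand flip. In unsigned
#' mode an adjacency is just the unordered gene pair.
#'
#' @param o a `gene_order`.
#' @param signed take strands into account (default `TRUE`).
#' @return character vector of normalized adjacency tokens.
#' @export
adjacencies <- function(o, signed = TRUE) {
  if (!inherits(o, "gene_order")) o <- gene_order(o)
  n <- nrow(o)
  nxt <- c(seq_len(n)[-1L], 1L)
  flip <- function(s) ifelse(s == "+", "-", "+")
  vapply(seq_len(n), function(i) {
    j <- nxt[i]
    if (!signed) {
      return(paste(sort(c(o$gene[i], o$gene[j])), collapse = "|"))
    }
    fwd <- paste0(o$strand[i], o$gene[i], ">", o$strand[j], o$gene[j])
    rev <- paste0(flip(o$strand[j]), o$gene[j], ">",
                  flip(o$strand[i]), o$gene[i])
    min(fwd, rev)
  }, character(1L))
}

#' Breakpoint distance between two circular gene orders
#'
#' Number of adjacencies present in `a` but absent from `b`. With equal gene
#' sets the count is symmetric in its arguments, zero iff the orders are
#' equivalent (in signed mode), and invariant to rotations and global strand
#' flips.
#'
#' @param a,b gene orders over the same gene set.
#' @param signed strand-aware adjacencies (default `TRUE`).
#' @return non-negative integer.
#' @export
#' @examples
#' breakpoint_distance(c("A", "B", "C", "D"), c("A", "B", "C", "D")) # 0
breakpoint_distance <- function(a, b, signed = TRUE) {
  if (!inherits(a, "gene_order")) a <- gene_order(a)
  if (!inherits(b, "gene_order")) b <- gene_order(b)
  check_same_genes(a, b)
  length(setdiff(adjacencies(a, signed), adjacencies(b, signed)))
}
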