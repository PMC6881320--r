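#' Kimura 2-parameter distance between two aligned sequences
#'
#' Tallies transitions (A<->G, C<->T) and transversions over the sites where
#' both sequences carry an unambiguous base (pairwise deletion of gaps and
#' ambiguity codes), then corrects for multiple hits:
#' \deqn{d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q)}
#' with P and Q the transition and transversion proportions. When the
#' alignment is saturated (either log argument non-positive) the distance is
#' `NA` while P, Q and the usable-site count are retained, so saturated pairs
#' never silently corrupt a matrix.
#'
#' @param a,b aligned nucleotide strings of equal length (alphabet
#'   A/C/G/T plus `-` and IUPAC ambiguity codes; case-insensitive).
#' @return list of class `distance_pair`: `usable_sites`, `transitions`,
#'   `transversions`, `P`, `Q`, `p_distance` (= P + Q) and `k2p`.
#' @export
#' @examples
#' k2p_distance("ACGTACGT", "ACGTACGT")$k2p # 0
k2p_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b)) {
    stop("aligned sequences must have equal length (", nchar(a), " vs ",
         nchar(b), ")")
  }
  x <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  y <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  use <- x %in% bases & y %in% bases
  n <- sum(use)
  if (n == 0L) {
    warning("no usable sites after pairwise deletion")
    return(structure(list(usable_sites = 0L, transitions = 0L,
                          transversions = 0L, P = NA_real_, Q = NA_real_,
                          p_distance = NA_real_, k2p = NA_real_),
                     class = "distance_pair"))
  }
  xs <- x[use]; ys <- y[use]
  diff <- xs != ys
  purine <- c("A", "G")
  ts <- diff & ((xs %in% purine) == (ys %in% purine))
  n_ts <- sum(ts)
  n_tv <- sum(diff) - n_ts
  P <- n_ts / n
  Q <- n_tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  k2p <- if (w1 > 0 && w2 > 0) -0.5 * log(w1) - 0.25 * log(w2) else NA_real_
  structure(list(usable_sites = n, transitions = n_ts, transversions = n_tv,
                 P = P, Q = Q, p_distance = P + Q, k2p = k2p),
            class = "distance_pair")
}

#' @export
print.distance_pair <- function(x, ...) {
  cat("Aligned pair: ", x$usable_sites, " usable sites; P = ",
      signif(x$P, 4), ", Q = ", signif(x$Q, 4), "\n", sep = "")
  cat("  p-distance = ", signif(x$p_distance, 4), "; K2P = ",
      if (is.na(x$k2p)) "undefined (saturated)" else signif(x$k2p, 4),
      "\n", sep = "")
  invisible(x)
}

#' Pairwise distance matrix over named aligned sequences
#'
#' Builds the symmetric p-distance or K2P matrix over a set of aligned
#' sequences, either from a single alignment or from per-gene alignment
#' blocks. In `"concatenated"` mode the blocks are joined per taxon before
#' tallying (the standard treatment for concatenated protein-coding genes);
#' `"per-gene"` mode returns one matrix per block.
#'
#' @param seqs named character vector (one alignment) or named list of such
#'   vectors (gene blocks; all blocks must share taxon names).
#' @param mode `"k2p"` (default) or `"p"`.
#' @param level `"concatenated"` (default) or `"per-gene"`; ignored when a
#'   single alignment is supplied.
#' @return numeric matrix with zero diagonal (or a named list of matrices in
#'   per-gene mode). Saturated K2P entries are `NA`.
#' @export
distance_matrix <- function(seqs, mode = c("k2p", "p"),
                            level = c("concatenated", "per-gene")) {
  mode <- match.arg(mode)
  level <- match.arg(level)
  if (is.list(seqs)) {
    blocks <- seqs
    if (is.null(names(blocks))) names(blocks) <- paste0("block", seq_along(blocks))
    taxa <- names(blocks[[1L]])
    for (nm in names(blocks)) {
      blk <- blocks[[nm]]
      if (is.null(names(blk)) || !setequal(names(blk), taxa)) {
        stop("gene block '", nm, "' does not cover the same taxa")
      }
      if (length(unique(nchar(blk))) != 1L) {
        stop("sequences in gene block '", nm, "' differ in length")
      }
    }
    if (level == "per-gene") {
      return(lapply(blocks, distance_matrix, mode = mode))
    }
    seqs <- vapply(taxa, function(tx) {
      paste(vapply(blocks, function(blk) blk[[tx]], character(1L)),
            collapse = "")
    }, character(1L))
  }
  if (is.null(names(seqs))) stop("sequences must be named")
  if (length(unique(nchar(seqs))) != 1L) {
    stop("aligned sequences differ in length")
  }
  n <- length(seqs)
  m <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        dp <- k2p_distance(seqs[[i]], seqs[[j]])
        m[i, j] <- m[j, i] <- if (mode == "k2p") dp$k2p else dp$p_distance
      }
    }
  }
  m
}

#' Expected transition/transversion proportions under the K2P model
#'
#' Closed-form P(d) and Q(d) for two sequences separated by total distance
#' `d` (substitutions/site) under Kimura's two-parameter model with
#' transition/transversion rate ratio `kappa`:
#' \deqn{Q(d) = \tfrac12 (1 - e^{-4d/(\kappa+2)}),\quad
#'       P(d) = \tfrac14 + \tfrac14 e^{-4d/(\kappa+2)}
#'              - \tfrac12 e^{-2d(\kappa+1)/(\kappa+2)}}
#'
#' @param d total distance (branch-length sum) in substitutions/site.
#' @param kappa transition/transversion rate ratio (> 0).
#' @return list with `P` and `Q`.
#' @export
k2p_expected_pq <- function(d, kappa) {
  stopifnot(d >= 0, kappa > 0)
  e2 <- exp(-4 * d / (kappa + 2))
  e1 <- exp(-2 * d * (kappa + 1) / (kappa + 2))
  list(P = 0.25 + 0.25 * e2 - 0.5 * e1, Q = 0.5 - 0.5 * e2)
}

#' Large-sample standard error of the K2P distance
#'
#' Kimura's delta-method variance of the corrected distance given observed
#' P, Q and the number of usable sites.
#'
#' @param P,Q observed transition and transversion proportions.
#' @param n usable sites.
#' @return standard error (`NA` if the distance is saturated).
#' @export
k2p_stderr <- function(P, Q, n) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0 || n <= 0) return(NA_real_)
  c1 <- 1 / w1
  c2 <- 1 / w2
  c3 <- (c1 + c2) / 2
  v <- (c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / n
  sqrt(v)
}
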