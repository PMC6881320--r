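# Independent oracles and small generators used across the suite. These are
# deliberately written without reference to the package internals they check.

random_seq <- function(n, alphabet = c("A", "C", "G", "T"),
                       prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

# site-by-site substitution classification (transition pairs listed
# explicitly), independent of k2p_distance()
oracle_site_classes <- function(a, b) {
  ts_pairs <- c("AG", "GA", "CT", "TC")
  ax <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  bx <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  good <- ax %in% c("A", "C", "G", "T") & bx %in% c("A", "C", "G", "T")
  pairs <- paste0(ax, bx)[good]
  changed <- substr(pairs, 1L, 1L) != substr(pairs, 2L, 2L)
  list(n = sum(good),
       ts = sum(pairs %in% ts_pairs),
       tv = sum(changed & !(pairs %in% ts_pairs)))
}

# exhaustive adjacency check on two signed circular orders given as
# data.frames with gene/strand columns; counts adjacencies of a without a
# strand-compatible counterpart in b (reading b in either direction)
oracle_breakpoints <- function(a, b) {
  flip <- function(s) ifelse(s == "+", "-", "+")
  n <- nrow(a)
  nxt <- c(seq_len(n)[-1L], 1L)
  bn <- nrow(b)
  bnxt <- c(seq_len(bn)[-1L], 1L)
  bp <- data.frame(g1 = b$gene, s1 = b$strand,
                   g2 = b$gene[bnxt], s2 = b$strand[bnxt])
  missing <- 0L
  for (i in seq_len(n)) {
    g1 <- a$gene[i]; s1 <- a$strand[i]
    g2 <- a$gene[nxt[i]]; s2 <- a$strand[nxt[i]]
    hit <- any((bp$g1 == g1 & bp$s1 == s1 & bp$g2 == g2 & bp$s2 == s2) |
               (bp$g1 == g2 & bp$s1 == flip(s2) &
                bp$g2 == g1 & bp$s2 == flip(s1)))
    if (!hit) missing <- missing + 1L
  }
  missing
}

# all permutations of a vector (plain recursion; small n only)
all_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# every signed circular order over `genes`, one representative per rotation
# class: first gene fixed in first position, all sign patterns enumerated
all_signed_circular_orders <- function(genes) {
  n <- length(genes)
  sign_patterns <- expand.grid(rep(list(c("+", "-")), n),
                               stringsAsFactors = FALSE)
  out <- list()
  for (perm in all_perms(genes[-1L])) {
    ord <- c(genes[1L], perm)
    for (r in seq_len(nrow(sign_patterns))) {
      out[[length(out) + 1L]] <- data.frame(
        gene = ord, strand = unlist(sign_patterns[r, ], use.names = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  out
}

# rotate the coordinates of an annotation by k (mod genome length), keeping
# features that would span the origin out of the picture by construction in
# the tests that use it
rotate_annotation <- function(g, k) {
  f <- g$features
  f$start <- ((f$start - 1L + k) %% g$genome_length) + 1L
  f$end <- ((f$end - 1L + k) %% g$genome_length) + 1L
  ok <- all(f$end >= f$start)
  if (!ok) return(NULL)
  genome_annotation(f, g$genome_length, organism = g$organism,
                    circular = g$circular)
}
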