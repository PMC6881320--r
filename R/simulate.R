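# Synthetic mitogenome generation. The generator emulates the structure of a
# littorinimorph gastropod mitochondrial genome: ~15.5 kb circle, 13 PCGs,
# 22 tRNAs, 2 rRNAs in the consensus order, short intergenic spacers with a
# few small overlaps and one larger putative-control-region gap, A+T-biased
# composition with a negative AT skew on the (+) strand.

#' Consensus gene-order template for the synthetic generator
#'
#' One row per feature in circular order starting at `cox1`: gene symbol,
#' class, strand, span length (bp) and the signed spacer preceding the gene
#' (from the previous gene around the circle), plus start/stop codons for the
#' PCGs. Lengths and spacers mirror a real strombid gastropod mitogenome,
#' with one adjustment: the single PCG-over-PCG overlap of the real map is
#' relocated to a tRNA boundary (trnT/nad4l) so that generated
#' protein-coding content is never overwritten by another reading frame and
#' generated PCGs are guaranteed internally stop-free.
#'
#' @return data.frame with columns `gene`, `class`, `strand`, `length`,
#'   `spacer_before`, `start_codon`, `stop_codon`.
#' @export
mitogenome_template <- function() {
  tpl <- utils::read.table(header = TRUE, stringsAsFactors = FALSE, text = "
gene  class strand length spacer_before start_codon stop_codon
cox1  PCG   +      1536    5  ATG TAG
cox2  PCG   +       687   19  ATG TAA
trnD  tRNA  +        68   -2  NA  NA
atp8  PCG   +       159    0  ATG TAA
atp6  PCG   +       696    2  ATG TAA
trnM  tRNA  -        68   36  NA  NA
trnY  tRNA  -        66   18  NA  NA
trnC  tRNA  -        65    2  NA  NA
trnW  tRNA  -        67    1  NA  NA
trnQ  tRNA  -        62    1  NA  NA
trnG  tRNA  -        67   12  NA  NA
trnE  tRNA  -        70    1  NA  NA
rrnS  rRNA  +       978    5  NA  NA
trnV  tRNA  +        67    0  NA  NA
rrnL  rRNA  +      1391  -15  NA  NA
trnL1 tRNA  +        69    6  NA  NA
trnL2 tRNA  +        69    9  NA  NA
nad1  PCG   +       942    1  ATG TAG
trnP  tRNA  +        68   10  NA  NA
nad6  PCG   +       507    1  ATG TAA
cytb  PCG   +      1140   11  ATG TAA
trnS2 tRNA  +        66   14  NA  NA
trnT  tRNA  -        67   18  NA  NA
nad4l PCG   +       297   -7  ATG TAG
nad4  PCG   +      1374    1  GTG TAA
trnH  tRNA  +        67    9  NA  NA
nad5  PCG   +      1728    0  ATG TAA
trnF  tRNA  +        69   31  NA  NA
cox3  PCG   +       780   53  ATG TAA
trnK  tRNA  +        70   38  NA  NA
trnA  tRNA  +        72   27  NA  NA
trnR  tRNA  +        69   11  NA  NA
trnN  tRNA  +        67   12  NA  NA
trnI  tRNA  +        68    2  NA  NA
nad3  PCG   +       354    1  ATG TAA
trnS1 tRNA  +        68    2  NA  NA
nad2  PCG   +      1071  -12  ATC TAG
")
  tpl
}

#' Configuration for the synthetic mitogenome generator
#'
#' Defaults reproduce the study conditions the package emulates: a ~15.5 kb
#' circular genome in the littorinimorph consensus order with an A+T content
#' of 66.22% and AT/GC skews of -0.128/+0.019 on the (+) strand.
#'
#' @param seed integer seed; all randomness flows from it (no global RNG
#'   state is touched).
#' @param at_content_target target A+T percent, in (0, 100).
#' @param at_skew_target,gc_skew_target target skews, in (-1, 1).
#' @param codon_bias_strength in `[0, 1]`: how strongly third codon
#'   positions are pulled toward A/T, concentrating synonymous codon usage
#'   on A+T-ending codons (0 = no extra bias).
#' @param randomize_spacers resample positive spacer lengths (small gaps
#'   0-12 bp, the control-region gap 40-60 bp) instead of using the template
#'   values verbatim; overlaps are kept fixed.
#' @param template gene-order template as from [mitogenome_template()].
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             at_content_target = 66.22,
                             at_skew_target = -0.128,
                             gc_skew_target = 0.019,
                             codon_bias_strength = 0.3,
                             randomize_spacers = FALSE,
                             template = mitogenome_template()) {
  stopifnot(at_content_target > 0, at_content_target < 100,
            abs(at_skew_target) < 1, abs(gc_skew_target) < 1,
            codon_bias_strength >= 0, codon_bias_strength <= 1)
  pcg <- template$class == "PCG"
  if (any(template$length[pcg] %% 3L != 0L)) {
    stop("infeasible template: PCG length not divisible by 3")
  }
  neg <- template$spacer_before < 0
  prev_len <- template$length[c(nrow(template), seq_len(nrow(template) - 1L))]
  if (any(neg & (-template$spacer_before > prev_len |
                 -template$spacer_before > template$length))) {
    stop("infeasible template: overlap longer than a flanking gene")
  }
  structure(
    list(seed = as.integer(seed),
         at_content_target = at_content_target,
         at_skew_target = at_skew_target,
         gc_skew_target = gc_skew_target,
         codon_bias_strength = codon_bias_strength,
         randomize_spacers = isTRUE(randomize_spacers),
         template = template,
         gene_census = table(factor(template$class,
                                    levels = c("PCG", "tRNA", "rRNA")))),
    class = "generator_config"
  )
}

# internal: base frequencies from an A+T fraction and the two skews
skewed_base_freqs <- function(at, at_skew, gc_skew) {
  gc <- 1 - at
  c(A = at * (1 + at_skew) / 2,
    T = at * (1 - at_skew) / 2,
    G = gc * (1 + gc_skew) / 2,
    C = gc * (1 - gc_skew) / 2)
}

#' Generate a synthetic annotated mitogenome
#'
#' Lays the template features around a circle (optionally resampling the
#' positive spacers), samples a background sequence from the base
#' frequencies implied by the composition targets, then writes each
#' protein-coding gene's codon content in its own frame: the annotated start
#' codon, sense codons drawn base-wise (with the third position biased
#' toward A/T by `codon_bias_strength`; stop codons rejected and redrawn),
#' and the annotated terminator. tRNA/rRNA spans keep the background
#' composition. The result passes [validate_annotation()] with zero errors
#' and its PCGs contain no internal stop codons.
#'
#' @param cfg a [generator_config()].
#' @return a `mito_annotation` with sequence.
#' @export
#' @examples
#' g <- generate_genome(generator_config(seed = 7))
#' table(g$features$class)
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  withr::with_seed(cfg$seed, generate_genome_impl(cfg))
}

generate_genome_impl <- function(cfg) {
  tpl <- cfg$template
  n <- nrow(tpl)
  spacer <- tpl$spacer_before
  if (cfg$randomize_spacers) {
    pos <- spacer > 0
    big <- pos & spacer >= 30
    spacer[pos & !big] <- sample(0:12, sum(pos & !big), replace = TRUE)
    spacer[big] <- sample(40:60, sum(big), replace = TRUE)
  }
  start <- integer(n)
  end <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    start[i] <- pos
    end[i] <- pos + tpl$length[i] - 1L
    if (i < n) pos <- end[i] + 1L + spacer[i + 1L]
  }
  genome_length <- end[n] + spacer[1L]
  # The third-position codon bias adds A/T over the PCG third positions, so
  # the frequencies used everywhere else are solved for the value that makes
  # the genome-wide A+T expectation equal the configured target:
  # at_base (1 - b f3) + b f3 = at_target, f3 = fraction of sites that are
  # PCG third positions and b the bias strength.
  f3 <- (sum(tpl$length[tpl$class == "PCG"]) / 3) / genome_length
  at_target <- cfg$at_content_target / 100
  b <- cfg$codon_bias_strength
  at_base <- (at_target - b * f3) / (1 - b * f3)
  if (at_base <= 0 || at_base >= 1) {
    stop("infeasible config: codon bias incompatible with A+T target")
  }
  freqs <- skewed_base_freqs(at_base, cfg$at_skew_target, cfg$gc_skew_target)
  bases <- names(freqs)
  genome <- sample(bases, genome_length, replace = TRUE, prob = freqs)
  # third-position frequencies pulled toward A/T by the bias strength
  at_only <- c(freqs[c("A", "T")] / sum(freqs[c("A", "T")]), G = 0, C = 0)[bases]
  third <- (1 - b) * freqs + b * at_only
  stops <- c("TAA", "TAG")
  draw_sense_codons <- function(k) {
    out <- character(k)
    need <- seq_len(k)
    while (length(need) > 0L) {
      c1 <- sample(bases, length(need), replace = TRUE, prob = freqs)
      c2 <- sample(bases, length(need), replace = TRUE, prob = freqs)
      c3 <- sample(bases, length(need), replace = TRUE, prob = third)
      cand <- paste0(c1, c2, c3)
      ok <- !(cand %in% stops)
      out[need[ok]] <- cand[ok]
      need <- need[!ok]
    }
    out
  }
  for (i in which(tpl$class == "PCG")) {
    k <- tpl$length[i] %/% 3L
    codons <- c(tpl$start_codon[i], draw_sense_codons(k - 2L), tpl$stop_codon[i])
    gene_seq <- paste(codons, collapse = "")
    if (tpl$strand[i] == "-") gene_seq <- revcomp(gene_seq)
    genome[start[i]:end[i]] <- strsplit(gene_seq, "", fixed = TRUE)[[1L]]
  }
  feats <- data.frame(
    gene = tpl$gene, class = tpl$class, start = start, end = end,
    strand = tpl$strand, start_codon = tpl$start_codon,
    stop_codon = tpl$stop_codon, stringsAsFactors = FALSE
  )
  genome_annotation(feats, genome_length,
                    organism = paste0("synthetic mitogenome (seed ",
                                      cfg$seed, ")"),
                    circular = TRUE,
                    sequence = paste(genome, collapse = ""))
}

#' Configuration for the K2P sequence-evolution simulator
#'
#' @param true_distance total distance separating the simulated pair, in
#'   substitutions/site (each descendant evolves half of it).
#' @param kappa transition/transversion rate ratio (> 0); 2 is a typical
#'   value for mitochondrial DNA.
#' @param seed integer seed.
#' @param preserve_codons protect annotated start/stop codon positions from
#'   substitution so downstream codon tabulation stays meaningful; set
#'   `FALSE` for a free-running process.
#' @return list of class `evolution_config`.
#' @export
evolution_config <- function(true_distance, kappa = 2, seed = 1L,
                             preserve_codons = TRUE) {
  stopifnot(true_distance >= 0, kappa > 0)
  structure(list(true_distance = true_distance, kappa = kappa,
                 seed = as.integer(seed),
                 preserve_codons = isTRUE(preserve_codons)),
            class = "evolution_config")
}

# internal: one K2P branch applied site-wise to a character vector
k2p_mutate <- function(chars, branch_length, kappa, protected) {
  pq <- k2p_expected_pq(branch_length, kappa)
  u <- stats::runif(length(chars))
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv1 <- c(A = "C", G = "C", C = "A", T = "A")
  tv2 <- c(A = "T", G = "T", C = "G", T = "G")
  known <- chars %in% names(ts_map) & !protected
  do_ts <- known & u < pq$P
  do_tv <- known & u >= pq$P & u < pq$P + pq$Q
  pick <- stats::runif(length(chars)) < 0.5
  chars[do_ts] <- ts_map[chars[do_ts]]
  chars[do_tv & pick] <- tv1[chars[do_tv & pick]]
  chars[do_tv & !pick] <- tv2[chars[do_tv & !pick]]
  chars
}

#' Evolve a genome into a diverged pair under the K2P model
#'
#' Both descendants evolve independently from `g` for half the configured
#' distance under Kimura's two-parameter substitution process (no indels, so
#' the pair stays aligned by construction). By default the six start/stop
#' codon positions of every PCG are protected from substitution. The truth
#' record carries the model's expected transition/transversion proportions
#' at the full pair distance, for comparison against estimates from
#' [k2p_distance()].
#'
#' @param g a `mito_annotation` with sequence.
#' @param ecfg an [evolution_config()].
#' @return list with `a`, `b` (diverged `mito_annotation`s) and `truth`
#'   (list: `true_distance`, `kappa`, `expected_P`, `expected_Q`,
#'   `protected_sites`, `saturated`).
#' @export
#' @examples
#' g <- generate_genome(generator_config(seed = 3))
#' pair <- evolve_pair(g, evolution_config(true_distance = 0.1, seed = 4))
#' k2p_distance(pair$a$sequence, pair$b$sequence)$k2p
evolve_pair <- function(g, ecfg) {
  stopifnot(inherits(g, "mito_annotation"), inherits(ecfg, "evolution_config"))
  if (is.null(g$sequence)) stop("genome carries no sequence")
  protected <- logical(g$genome_length)
  if (ecfg$preserve_codons) {
    p <- g$features[g$features$class == "PCG", , drop = FALSE]
    for (i in seq_len(nrow(p))) {
      protected[p$start[i]:(p$start[i] + 2L)] <- TRUE
      protected[(p$end[i] - 2L):p$end[i]] <- TRUE
    }
  }
  chars <- strsplit(g$sequence, "", fixed = TRUE)[[1L]]
  b <- ecfg$true_distance / 2
  res <- withr::with_seed(ecfg$seed, list(
    a = k2p_mutate(chars, b, ecfg$kappa, protected),
    b = k2p_mutate(chars, b, ecfg$kappa, protected)
  ))
  pq <- k2p_expected_pq(ecfg$true_distance, ecfg$kappa)
  saturated <- (1 - 2 * pq$P - pq$Q) < 1e-3 || (1 - 2 * pq$Q) < 1e-3
  if (saturated) {
    warning("true_distance ", ecfg$true_distance,
            " is near saturation; estimated distances will be unstable")
  }
  make_desc <- function(seq_chars, tag) {
    genome_annotation(g$features, g$genome_length,
                      organism = paste0(g$organism, " / descendant ", tag),
                      circular = g$circular,
                      sequence = paste(seq_chars, collapse = ""))
  }
  list(a = make_desc(res$a, "a"), b = make_desc(res$b, "b"),
       truth = list(true_distance = ecfg$true_distance, kappa = ecfg$kappa,
                    expected_P = pq$P, expected_Q = pq$Q,
                    protected_sites = sum(protected), saturated = saturated))
}
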