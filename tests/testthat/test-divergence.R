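test_that("identical sequences have zero distance", {
  dp <- k2p_distance("ACGTACGTAC", "ACGTACGTAC")
  expect_equal(dp$P, 0)
  expect_equal(dp$Q, 0)
  expect_equal(dp$k2p, 0)
  expect_equal(dp$p_distance, 0)
})

test_that("the K2P correction matches its closed form", {
  # 20 sites: 2 transitions, 1 transversion -> P = 0.1, Q = 0.05
  a <- paste(rep("ACGTA", 4), collapse = "")
  b <- a
  substr(b, 1, 1) <- "G"   # A->G transition
  substr(b, 6, 6) <- "G"   # A->G transition
  substr(b, 11, 11) <- "C" # A->C transversion
  dp <- k2p_distance(a, b)
  expect_equal(dp$P, 0.1)
  expect_equal(dp$Q, 0.05)
  expect_equal(round(dp$k2p, 4), 0.1702)
  expect_gte(dp$k2p, dp$p_distance)
})

test_that("transition/transversion tallies match a site-by-site oracle", {
  withr::with_seed(81, {
    for (i in 1:30) {
      n <- sample(5:30, 1)
      a <- random_seq(n, alphabet = c("A", "C", "G", "T", "-", "N"))
      b <- random_seq(n, alphabet = c("A", "C", "G", "T", "-", "N"))
      ora <- oracle_site_classes(a, b)
      if (ora$n == 0) {
        expect_warning(dp <- k2p_distance(a, b), "no usable sites")
        expect_true(is.na(dp$k2p))
        next
      }
      dp <- k2p_distance(a, b)
      expect_equal(dp$usable_sites, ora$n)
      expect_equal(dp$transitions, ora$ts)
      expect_equal(dp$transversions, ora$tv)
    }
  })
})

test_that("pairwise deletion removes gap/ambiguity sites from the tallies", {
  dp <- k2p_distance("ACG-ANTT", "ACGTNNTA")
  # usable sites: positions 1,2,3,7,8 minus ambiguity -> 1,2,3,7,8 have
  # bases in both except 5,6; site 4 gapped; A->A,C->C,G->G,T->T,T->A
  expect_equal(dp$usable_sites, 5L)
  expect_equal(dp$transitions, 0L)
  expect_equal(dp$transversions, 1L)
})

test_that("K2P approaches the p-distance for nearly identical sequences", {
  n <- 10000L
  a <- strrep("ACGT", n / 4)
  b <- a
  substr(b, 8, 8) <- "A"  # one transversion: P+Q = 1e-4
  dp <- k2p_distance(a, b)
  expect_lt(abs(dp$k2p - dp$p_distance), 1e-6)
})

test_that("saturated pairs return undefined distances with tallies retained", {
  a <- strrep("A", 50)
  b <- strrep("G", 50)  # P = 1: log-domain violation
  dp <- k2p_distance(a, b)
  expect_true(is.na(dp$k2p))
  expect_equal(dp$P, 1)
  expect_equal(dp$usable_sites, 50L)
})

test_that("K2P agrees with an independent implementation on random alignments", {
  skip_if_not_installed("ape")
  withr::with_seed(91, {
    for (i in 1:5) {
      n <- 600L
      a <- random_seq(n)
      b <- strsplit(a, "")[[1]]
      mut <- sample(n, 60)
      b[mut] <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
      b <- paste(b, collapse = "")
      m <- rbind(strsplit(tolower(a), "")[[1]], strsplit(tolower(b), "")[[1]])
      rownames(m) <- c("a", "b")
      ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(m), model = "K80",
                                     pairwise.deletion = TRUE))["a", "b"]
      expect_equal(k2p_distance(a, b)$k2p, unname(ref), tolerance = 1e-10)
    }
  })
})

test_that("distance matrices are symmetric with zero diagonal", {
  seqs <- c(x = "ACGTACGTAC", y = "ACGTACGTAC", z = "ACGAACGTTC")
  m <- distance_matrix(seqs, mode = "p")
  expect_equal(m, t(m))
  expect_equal(diag(m), c(x = 0, y = 0, z = 0))
  expect_equal(m["x", "y"], 0)
  # concatenated gene blocks equal the pasted alignment
  blocks <- list(g1 = c(x = "ACGT", y = "ACGA"), g2 = c(x = "TTTT", y = "TATT"))
  mc <- distance_matrix(blocks, mode = "p")
  mp <- distance_matrix(c(x = "ACGTTTTT", y = "ACGATATT"), mode = "p")
  expect_equal(mc, mp)
  pg <- distance_matrix(blocks, mode = "p", level = "per-gene")
  expect_named(pg, c("g1", "g2"))
  expect_error(distance_matrix(list(g1 = c(x = "ACGT", y = "ACG"))), "g1")
})

test_that("simulated K2P distances are recovered without bias", {
  # indel-free pairs at 10 kb; the replicate-averaged estimate must sit
  # within 2 analytic standard errors (of a single 10 kb estimate) of the
  # truth -- a systematic bias of that order would be caught, while
  # single-draw noise (SE/sqrt(replicates)) is averaged away
  for (case in list(list(d = 0.05, seed = 101), list(d = 0.15, seed = 102),
                    list(d = 0.3, seed = 103))) {
    ests <- numeric(12L)
    ses <- numeric(12L)
    for (r in seq_along(ests)) {
      base <- withr::with_seed(case$seed + 10L * r, random_seq(10000L))
      g <- genome_annotation(
        data.frame(gene = "rrnL", class = "rRNA", start = 1, end = 10000L,
                   strand = "+"),
        genome_length = 10000L, sequence = base)
      pair <- evolve_pair(g, evolution_config(case$d, kappa = 2,
                                              seed = case$seed + 10L * r + 1L,
                                              preserve_codons = FALSE))
      dp <- k2p_distance(pair$a$sequence, pair$b$sequence)
      ests[r] <- dp$k2p
      ses[r] <- k2p_stderr(dp$P, dp$Q, dp$usable_sites)
    }
    expect_lt(abs(mean(ests) - case$d), 2 * mean(ses))
  }
})

test_that("amino-acid divergence is below nucleotide divergence under synonymous-biased change", {
  # synonymous-biased change emulated by a transition-heavy process confined
  # to third codon positions (every third-position transition is silent
  # under the invertebrate mitochondrial code)
  g <- generate_genome(generator_config(seed = 111))
  cds <- mitocomp:::pcg_blocks(list(g = g))
  a <- paste(vapply(cds, `[[`, character(1), "g"), collapse = "")
  chars <- strsplit(a, "")[[1]]
  protected <- rep(c(TRUE, TRUE, FALSE), length.out = length(chars))
  b <- withr::with_seed(112, paste(
    mitocomp:::k2p_mutate(chars, 0.3, kappa = 20, protected = protected),
    collapse = ""))
  nt <- k2p_distance(a, b)$p_distance
  expect_gt(nt, 0.01)
  code <- Biostrings::getGeneticCode("5")
  translate <- function(s) {
    cd <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    paste(ifelse(cd %in% names(code), code[cd], "X"), collapse = "")
  }
  ax <- strsplit(translate(a), "")[[1]]
  bx <- strsplit(translate(b), "")[[1]]
  aa_dist <- mean(ax != bx)
  expect_lt(aa_dist, nt)
})
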