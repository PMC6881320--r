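test_that("generated genomes carry the canonical census and validate cleanly", {
  g <- generate_genome(generator_config(seed = 1))
  census <- table(g$features$class)
  expect_equal(census[["PCG"]], 13L)
  expect_equal(census[["tRNA"]], 22L)
  expect_equal(census[["rRNA"]], 2L)
  v <- validate_annotation(g)
  expect_equal(nrow(v[v$severity == "error", ]), 0L)
  expect_equal(nrow(v), 0L)
  expect_equal(nchar(g$sequence), g$genome_length)
})

test_that("generation is deterministic in the seed and leaves the global RNG alone", {
  g1 <- generate_genome(generator_config(seed = 5))
  g2 <- generate_genome(generator_config(seed = 5))
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$features, g2$features)
  g3 <- generate_genome(generator_config(seed = 6))
  expect_false(identical(g1$sequence, g3$sequence))
  set.seed(99); before <- .Random.seed
  invisible(generate_genome(generator_config(seed = 7)))
  expect_identical(before, .Random.seed)
})

test_that("generated PCGs honor their annotated codons with no internal stops", {
  g <- generate_genome(generator_config(seed = 8))
  cod <- extract_codons(g)
  expect_equal(nrow(attr(cod, "findings")), 0L)
  for (gene in names(cod)) {
    row <- g$features[g$features$gene == gene, ]
    expect_equal(cod[[gene]][1L], row$start_codon)
    expect_equal(cod[[gene]][length(cod[[gene]])], row$stop_codon)
  }
})

test_that("spacer randomization keeps overlaps and the tiling identity", {
  g <- generate_genome(generator_config(seed = 9, randomize_spacers = TRUE))
  rep <- scan_spacers(g)
  expect_equal(rep$overlap_count, 4L)
  expect_equal(mitocomp:::tiling_identity(g), g$genome_length)
  pos <- rep$pairs$spacing[rep$pairs$spacing > 0]
  expect_true(all(pos <= 60))
  expect_true(max(pos) >= 40)  # one control-region-like gap retained
})

test_that("infeasible configurations are rejected", {
  tpl <- mitogenome_template()
  tpl$length[tpl$gene == "cox1"] <- 1537L
  expect_error(generator_config(template = tpl), "divisible")
  tpl2 <- mitogenome_template()
  tpl2$spacer_before[tpl2$gene == "trnD"] <- -5000L
  expect_error(generator_config(template = tpl2), "overlap")
  expect_error(generator_config(at_content_target = 120), "at_content")
})

test_that("an evolved pair at distance zero is unchanged", {
  g <- generate_genome(generator_config(seed = 10))
  pair <- evolve_pair(g, evolution_config(0, seed = 11))
  expect_identical(pair$a$sequence, g$sequence)
  expect_identical(pair$b$sequence, g$sequence)
})

test_that("the evolved pair recovers the true distance and ts/tv balance", {
  g <- generate_genome(generator_config(seed = 12))
  ecfg <- evolution_config(0.2, kappa = 2, seed = 13)
  pair <- evolve_pair(g, ecfg)
  dp <- k2p_distance(pair$a$sequence, pair$b$sequence)
  se <- k2p_stderr(dp$P, dp$Q, dp$usable_sites)
  expect_lt(abs(dp$k2p - 0.2), 3 * se)
  # observed transition count within binomial error of the model expectation
  truth <- pair$truth
  n_free <- g$genome_length - truth$protected_sites
  expect_equal(truth$expected_P,
               mitocomp::k2p_expected_pq(0.2, 2)$P)
  obs_ts <- dp$transitions
  exp_ts <- truth$expected_P * g$genome_length
  expect_lt(abs(obs_ts - exp_ts),
            4 * sqrt(g$genome_length * truth$expected_P *
                       (1 - truth$expected_P)) +
              truth$protected_sites * truth$expected_P)
})

test_that("swapping the descendants leaves the estimated distance unchanged", {
  g <- generate_genome(generator_config(seed = 14))
  pair <- evolve_pair(g, evolution_config(0.1, seed = 15))
  d1 <- k2p_distance(pair$a$sequence, pair$b$sequence)$k2p
  d2 <- k2p_distance(pair$b$sequence, pair$a$sequence)$k2p
  expect_equal(d1, d2)
})

test_that("protected codon positions never mutate by default", {
  g <- generate_genome(generator_config(seed = 16))
  pair <- evolve_pair(g, evolution_config(0.5, kappa = 2, seed = 17))
  p <- g$features[g$features$class == "PCG", ]
  for (i in seq_len(nrow(p))) {
    idx <- c(p$start[i]:(p$start[i] + 2L), (p$end[i] - 2L):p$end[i])
    expect_identical(substring(pair$a$sequence, idx, idx),
                     substring(g$sequence, idx, idx))
  }
})

test_that("near-saturating distances raise a warning and flag the truth record", {
  g <- generate_genome(generator_config(seed = 18))
  expect_warning(pair <- evolve_pair(g, evolution_config(8, seed = 19)),
                 "saturation")
  expect_true(pair$truth$saturated)
})

test_that("generated genomes round-trip through the TSV and GenBank writers", {
  g <- generate_genome(generator_config(seed = 20))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_tsv(g, tsv)
  back <- read_annotation_tsv(tsv)
  expect_identical(back$features, g$features)
  expect_equal(back$genome_length, g$genome_length)
  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank_record(g, gb, accession = "SYNTEST1")
  back2 <- read_genbank_record(gb)
  expect_identical(back2$features, g$features)
  expect_identical(back2$sequence, g$sequence)
  expect_equal(back2$genome_length, g$genome_length)
})
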