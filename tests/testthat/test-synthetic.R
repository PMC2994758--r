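test_that("generation is bit-reproducible under a fixed seed", {
  g1 <- generate(emulate_paper_shape("tiny", seed = 13))
  g2 <- generate(emulate_paper_shape("tiny", seed = 13))
  expect_identical(as.data.frame(g1$dataset), as.data.frame(g2$dataset))
  expect_identical(g1$truth$sequences, g2$truth$sequences)
  g3 <- generate(emulate_paper_shape("tiny", seed = 14))
  expect_false(identical(g1$dataset$residues, g3$dataset$residues))
})

test_that("presets honour their documented contracts", {
  tiny <- generate(emulate_paper_shape("tiny", seed = 2))
  expect_lte(nrow(tiny$dataset), 12)

  tl <- emulate_paper_shape("tim_like", seed = 2)
  gtl <- generate(tl)
  expect_equal(dplyr::n_distinct(gtl$dataset$structure_id), 1L)
  expect_gte(dplyr::n_distinct(gtl$truth$sequences$family_id), 10)
  expect_true(any(gtl$truth$families$monofunctional))
  expect_true(any(!gtl$truth$families$monofunctional))

  ms <- generate(emulate_paper_shape("multi_structure", seed = 2))
  expect_gte(dplyr::n_distinct(ms$dataset$structure_id), 5)
  planted <- ms$truth$functions[ms$truth$functions$planted, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$n_structures, 4L)
})

test_that("switching off multifunctionality and promiscuity forces R_F = 0", {
  cfg <- generator_config(n_structures = 4, families_per_structure = 3,
                          seqs_per_family = 5, p_multifunctional = 0,
                          p_promiscuous = 0, plant_promiscuous_k = 0,
                          rng_seed = 8)
  g <- generate(cfg)
  p <- structural_promiscuity(g$dataset)
  expect_true(all(p$n_structures == 1))
  expect_true(all(p$R_F == 0))
})

test_that("zero-divergence families produce identical sequences", {
  cfg <- generator_config(n_structures = 1, families_per_structure = 1,
                          seqs_per_family = 5,
                          subfamilies_per_family = c(1, 1),
                          intra_family_divergence = 0,
                          intra_subfamily_divergence = 0,
                          p_multifunctional = 0, p_promiscuous = 0,
                          gap_rate = 0, rng_seed = 3)
  g <- generate(cfg)
  d <- all_pairwise_distances(g$dataset)
  expect_equal(nrow(d), choose(5, 2))
  expect_true(all(d$d == 0))
})

test_that("empirical divergences match the closed-form expectations", {
  # two large single-subfamily families: within-family pairs hit the
  # intra_subfamily target, cross-family pairs hit 95
  cfg <- generator_config(n_structures = 1, families_per_structure = 2,
                          seqs_per_family = 40,
                          subfamilies_per_family = c(1, 1),
                          intra_family_divergence = 10,
                          intra_subfamily_divergence = 10,
                          p_multifunctional = 0, p_promiscuous = 0,
                          gap_rate = 0, rng_seed = 31)
  g <- generate(cfg)
  d <- all_pairwise_distances(g$dataset)
  fam <- g$truth$sequences
  same_fam <- fam$family_id[match(d$seq_id_a, fam$seq_id)] ==
    fam$family_id[match(d$seq_id_b, fam$seq_id)]
  p2 <- g$truth$params$p_site_subfamily
  expect_equal(mean(d$d[same_fam]), expected_pairwise_divergence(p2),
               tolerance = 0.05)
  expect_equal(mean(d$d[!same_fam]), 95, tolerance = 0.02)

  # three-level case: cross-subfamily divergence composes both branches
  cfg2 <- generator_config(n_structures = 1, families_per_structure = 1,
                           seqs_per_family = 60,
                           subfamilies_per_family = c(2, 2),
                           intra_family_divergence = 50,
                           intra_subfamily_divergence = 15,
                           p_multifunctional = 0, p_promiscuous = 0,
                           gap_rate = 0, rng_seed = 32)
  g2 <- generate(cfg2)
  d2 <- all_pairwise_distances(g2$dataset)
  sub <- g2$truth$sequences
  same_sub <- sub$subfamily_id[match(d2$seq_id_a, sub$seq_id)] ==
    sub$subfamily_id[match(d2$seq_id_b, sub$seq_id)]
  expect_equal(mean(d2$d[same_sub]), 15, tolerance = 0.06)
  expect_equal(mean(d2$d[!same_sub]), 50, tolerance = 0.06)
})

test_that("infeasible configurations are rejected before generation", {
  expect_error(generator_config(intra_family_divergence = 92,
                                inter_family_divergence = 90),
               "Infeasible")
  expect_error(generator_config(intra_subfamily_divergence = 60,
                                intra_family_divergence = 50))
  expect_error(generator_config(inter_family_divergence = 99), "95")
  expect_error(generator_config(p_multifunctional = 0.5,
                                subfamilies_per_family = c(1, 1)),
               "subfamilies")
  expect_error(generator_config(gap_rate = 1.2), "0, 1")
})

test_that("planted family partitions are recovered by clustering", {
  for (seed in c(101, 102, 103)) {
    g <- generate(generator_config(
      n_structures = 2, families_per_structure = 4, seqs_per_family = 8,
      intra_family_divergence = 50, intra_subfamily_divergence = 15,
      inter_family_divergence = 90, p_multifunctional = 0.3,
      rng_seed = seed))
    d <- all_pairwise_distances(g$dataset)
    fam <- cluster_families(g$dataset, dists = d, threshold = 70)
    m <- dplyr::left_join(fam,
                          g$truth$sequences[, c("seq_id", "family_id")],
                          by = "seq_id")
    expect_equal(rand_index(m$family_id.x, m$family_id.y), 1.0)
  }
})
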