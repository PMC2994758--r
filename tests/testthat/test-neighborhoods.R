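toy_dists <- function() {
  tibble::tibble(seq_id_a = c("G", "G", "A"),
                 seq_id_b = c("A", "B", "B"),
                 d = c(3, 7, 5))
}

toy_anno <- function() {
  tibble::tibble(seq_id = c("G", "A", "B"),
                 structure_id = "s1",
                 function_id = c("1.1.1.1", "2.2.2.2", "3.3.3.3"))
}

test_that("ball membership uses an inclusive radius", {
  nb <- neighborhood(toy_dists(), "G", 5, toy_anno())
  expect_setequal(nb$members, c("G", "A"))
  expect_setequal(nb$functions, c("1.1.1.1", "2.2.2.2"))
  expect_setequal(neighborhood(toy_dists(), "G", 0)$members, "G")
  expect_setequal(neighborhood(toy_dists(), "G", 100)$members,
                  c("G", "A", "B"))
  expect_error(neighborhood(toy_dists(), "Z", 5), "Unknown center")
})

test_that("F_u matches the set formula and equals the Jaccard distance", {
  expect_equal(fraction_unique_functions("a", "a"), 0)
  expect_equal(fraction_unique_functions("a", "b"), 1)
  expect_equal(fraction_unique_functions(c("a", "b"), c("b", "c")), 2 / 3)
  expect_error(fraction_unique_functions(character(0), character(0)),
               "undefined")
  # algebraic identity with 1 - |intersection| / |union| on random sets
  withr::with_seed(4, {
    for (i in 1:50) {
      s1 <- sample(letters[1:8], sample(0:6, 1))
      s2 <- sample(letters[1:8], sample(1:6, 1))
      jac <- 1 - length(intersect(s1, s2)) / length(union(s1, s2))
      expect_equal(fraction_unique_functions(s1, s2), jac)
    }
  })
})

test_that("pair sampling is uniform over distinct pairs and deterministic", {
  ids <- sprintf("q%02d", 1:10)
  all45 <- sample_pairs(ids, 100)
  expect_equal(nrow(all45), 45L)
  expect_equal(nrow(dplyr::distinct(all45)), 45L)
  expect_true(all(all45$seq_id_a != all45$seq_id_b))
  s1 <- sample_pairs(ids, 20, seed = 11)
  expect_equal(nrow(dplyr::distinct(s1)), 20L)
  expect_identical(s1, sample_pairs(ids, 20, seed = 11))
  # every sampled pair is a genuine unordered pair of the universe
  key <- paste(pmin(s1$seq_id_a, s1$seq_id_b),
               pmax(s1$seq_id_a, s1$seq_id_b))
  expect_equal(length(unique(key)), 20L)
})

test_that("fu_for_pairs emits one record per pair and radius", {
  rec <- fu_for_pairs(tibble::tibble(seq_id_a = "G", seq_id_b = "A"),
                      toy_dists(), toy_anno(), radii = c(1, 5, 10))
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$r, c(1, 5, 10))
  expect_equal(rec$d, rep(3, 3))
  # r = 10 balls around G and A both contain everything: identical sets
  expect_equal(rec$F_u[rec$r == 10], 0)
  expect_error(fu_for_pairs(tibble::tibble(seq_id_a = "G", seq_id_b = "Z"),
                            toy_dists(), toy_anno(), radii = 5),
               "not in the distance table")
})

test_that("fu_for_pairs equals brute-force enumeration on small instances", {
  for (seed in 1:12) {
    ds <- random_tiny_dataset(seed, n_seq = sample(5:10, 1),
                              n_struct = 1, len = 25)
    d <- all_pairwise_distances(ds)
    pairs <- sample_pairs(ds$seq_id, Inf)
    radii <- c(0, 10, 50, 100)
    got <- fu_for_pairs(pairs, d, ds, radii)
    want <- bf_fu_records(as.data.frame(pairs), as.data.frame(d),
                          as.data.frame(ds), radii)
    key <- function(x) paste(x$seq_id_a, x$seq_id_b, x$r)
    got <- got[order(key(got)), ]
    want <- want[order(key(want)), ]
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$F_u, want$F_u)
    expect_equal(got$n_functions_union, want$n_functions_union)
    expect_true(all(got$F_u >= 0 & got$F_u <= 1))
  }
})

test_that("ball function sets grow monotonically with the radius", {
  ds <- random_tiny_dataset(77, n_seq = 12, n_struct = 1, len = 30)
  d <- all_pairwise_distances(ds)
  radii <- c(0, 5, 20, 60, 100)
  for (center in ds$seq_id[1:4]) {
    sets <- lapply(radii, function(r)
      neighborhood(d, center, r, ds)$functions)
    for (k in seq_len(length(radii) - 1)) {
      expect_true(all(sets[[k]] %in% sets[[k + 1]]))
    }
  }
})

test_that("grid aggregation bins, averages and flags as specified", {
  rec <- tibble::tibble(seq_id_a = "a", seq_id_b = "b",
                        d = c(2, 2, 12, 12, 99.5),
                        r = 5,
                        F_u = c(0, 1, 0.5, 0.5, 1),
                        n_functions_union = 2L)
  g <- aggregate_grid(rec)
  expect_equal(length(unique(g$d_bin_lo)), 20L)  # width 5 over [0, 100]
  cell1 <- g[g$d_bin_lo == 0, ]
  expect_equal(cell1$mean_fu, 0.5)
  expect_equal(cell1$se, 0.5)  # sd(c(0,1))/sqrt(2)
  cell3 <- g[g$d_bin_lo == 10, ]
  expect_equal(cell3$se, 0)    # equal values
  # last bin is closed at 100
  expect_equal(g$n_pairs[g$d_bin_lo == 95], 1L)
  # empty cells stay flagged as empty, not zero
  empty <- g[g$d_bin_lo == 50, ]
  expect_equal(empty$n_pairs, 0L)
  expect_true(is.na(empty$mean_fu))
  # non-overlap region flag: r < d/2
  expect_true(g$non_overlapping[g$d_bin_lo == 95])
  expect_false(g$non_overlapping[g$d_bin_lo == 0])
  expect_error(aggregate_grid(rec, bin_width = 0), "positive")
})

test_that("across-sample summaries average cell-wise", {
  rec <- function(fu) tibble::tibble(seq_id_a = "a", seq_id_b = "b",
                                     d = 7, r = 5, F_u = fu,
                                     n_functions_union = 2L)
  g1 <- aggregate_grid(rec(0.4))
  g2 <- aggregate_grid(rec(0.6))
  s <- multi_sample_summary(list(g1, g2))
  cell <- s[s$d_bin_lo == 5 & s$r == 5, ]
  expect_equal(cell$mean_fu, 0.5)
  expect_equal(cell$sd_fu, sd(c(0.4, 0.6)))
  expect_equal(cell$n_samples, 2L)
  # identical grids: zero dispersion
  s2 <- multi_sample_summary(list(g1, g1))
  expect_equal(unique(s2$sd_fu[!is.na(s2$sd_fu)]), 0)
  # single grid: mean equals input, sd 0
  s3 <- multi_sample_summary(list(g1))
  expect_equal(s3$mean_fu[s3$d_bin_lo == 5], 0.4)
  expect_equal(s3$sd_fu[s3$d_bin_lo == 5], 0)
})
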