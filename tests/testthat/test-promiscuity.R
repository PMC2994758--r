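anno_from_counts <- function(counts_by_fun) {
  # counts_by_fun: named list fun -> named vector structure -> count
  rows <- list()
  i <- 0
  for (fun in names(counts_by_fun)) {
    for (s in names(counts_by_fun[[fun]])) {
      for (k in seq_len(counts_by_fun[[fun]][[s]])) {
        i <- i + 1
        rows[[i]] <- tibble::tibble(seq_id = sprintf("q%04d", i),
                                    structure_id = s, function_id = fun)
      }
    }
  }
  dplyr::bind_rows(rows)
}

test_that("R_F hits its analytic anchors", {
  # one function on a single structure, another spread uniformly
  anno <- anno_from_counts(list(
    "1.1.1.1" = c(sA = 5),
    "2.2.2.2" = c(sA = 3, sB = 3, sC = 3, sD = 3)))
  p <- structural_promiscuity(anno)
  expect_equal(p$R_F[p$function_label == "1.1.1.1"], 0)
  expect_equal(p$R_F[p$function_label == "2.2.2.2"], 1)  # uniform over all N=4
  # counts {2, 2} with N_total = 4: H = ln 2, R_F = 1/2
  anno2 <- anno_from_counts(list(
    "1.1.1.1" = c(s1 = 2, s2 = 2),
    "3.3.3.3" = c(s3 = 1, s4 = 1)))
  p2 <- structural_promiscuity(anno2)
  row <- p2[p2$function_label == "1.1.1.1", ]
  expect_equal(row$H, log(2))
  expect_equal(row$R_F, 0.5)
  expect_error(structural_promiscuity(anno_from_counts(
    list("1.1.1.1" = c(sA = 3)))), "2 distinct structures")
})

test_that("V_S mirrors R_F with structure and function roles swapped", {
  # structure with function counts {1, 3} among M_total = 4 functions
  anno <- dplyr::bind_rows(
    anno_from_counts(list("1.1.1.1" = c(sA = 1), "2.2.2.2" = c(sA = 3))),
    anno_from_counts(list("3.3.3.3" = c(sB = 1), "4.4.4.4" = c(sB = 1))))
  v <- functional_versatility(anno)
  row <- v[v$structure_id == "sA", ]
  H_expect <- -(0.25 * log(0.25) + 0.75 * log(0.75))
  expect_equal(row$H, H_expect, tolerance = 1e-12)
  expect_equal(row$V_S, H_expect / log(4), tolerance = 1e-12)
  mono <- v[v$structure_id == "sB", ]
  expect_true(all(mono$n_functions == 2))
})

test_that("promiscuity and versatility match a brute-force oracle", {
  for (seed in 1:30) {
    anno <- random_annotations(n_seq = sample(10:50, 1),
                               n_struct = sample(2:8, 1),
                               n_fun = sample(2:8, 1), seed = seed)
    got <- structural_promiscuity(anno)
    want <- bf_promiscuity(as.data.frame(anno))
    got <- got[order(got$function_label), ]
    want <- want[order(want$function_label), ]
    expect_equal(got$function_label, want$function_label)
    expect_equal(got$H, want$H, tolerance = 1e-12)
    expect_equal(got$R_F, want$R_F, tolerance = 1e-12)
    # versatility via the same oracle on the transposed annotation
    swapped <- data.frame(seq_id = anno$seq_id,
                          structure_id = anno$function_id,
                          function_id = anno$structure_id)
    vfun <- bf_promiscuity(swapped)
    v <- functional_versatility(anno)
    v <- v[order(v$structure_id), ]
    vfun <- vfun[order(vfun$function_label), ]
    expect_equal(v$V_S, vfun$R_F, tolerance = 1e-12)
  }
})

test_that("entropy bounds and duplication invariance hold", {
  anno <- random_annotations(60, 6, 5, seed = 42)
  p <- structural_promiscuity(anno)
  N <- attr(p, "N_total")
  expect_true(all(p$R_F >= 0))
  expect_true(all(p$R_F <= log(p$n_structures) / log(N) + 1e-12))
  expect_true(all(vapply(p$f, function(x) abs(sum(x) - 1) < 1e-9,
                         logical(1))))
  expect_true(all((p$R_F == 0) == (p$n_structures == 1)))
  # doubling every record leaves all fractions, H and R_F unchanged
  doubled <- dplyr::bind_rows(anno,
                              dplyr::mutate(anno, seq_id = paste0(seq_id, "b")))
  p2 <- structural_promiscuity(doubled)
  expect_equal(p2$R_F, p$R_F)
  expect_equal(p2$H, p$H)
})

test_that("histograms and count controls match hand-computed values", {
  anno <- anno_from_counts(list(
    "1.1.1.1" = c(sA = 1),
    "2.2.2.2" = c(sB = 1),
    "3.3.3.3" = c(sA = 1, sB = 1)))
  h <- structures_per_function_histogram(structural_promiscuity(anno))
  expect_equal(h$n_structures, c(1L, 2L))
  expect_equal(h$n_functions, c(2L, 1L))
  expect_equal(attr(h, "mean"), 4 / 3)

  # global structure fractions 0.9 / 0.1
  anno2 <- anno_from_counts(list(
    "1.1.1.1" = c(big = 85, small = 5),
    "2.2.2.2" = c(big = 5),
    "3.3.3.3" = c(small = 5)))
  m <- mean_structure_frequency_per_function(anno2)
  expect_equal(m$mean_f_i[m$function_label == "1.1.1.1"], 0.5)
  expect_equal(m$mean_f_i[m$function_label == "3.3.3.3"], 0.1)
  # single-structure dataset: every function maps to 1
  single <- anno_from_counts(list("1.1.1.1" = c(sA = 2),
                                  "2.2.2.2" = c(sA = 3)))
  expect_equal(unique(mean_structure_frequency_per_function(single)$mean_f_i), 1)
})

test_that("top_promiscuous ranks by R_F with deterministic tie-breaks", {
  anno <- anno_from_counts(list(
    "2.2.2.2" = c(s1 = 1, s2 = 1),            # R_F = ln2/ln4 = 0.5
    "1.1.1.1" = c(s1 = 2, s2 = 1, s3 = 1),     # H = 1.0397, R_F = 0.75
    "3.3.3.3" = c(s4 = 5),
    "0.0.0.0" = c(s3 = 7)))
  top <- top_promiscuous(structural_promiscuity(anno), k = 10)
  expect_equal(top$function_label[1], "1.1.1.1")
  expect_equal(top$function_label[2], "2.2.2.2")
  # all-zero ties fall back to lexicographic order
  expect_equal(top$function_label[3:4], c("0.0.0.0", "3.3.3.3"))
  expect_equal(nrow(top_promiscuous(structural_promiscuity(anno), k = 2)), 2L)
})

test_that("tidy and glance summarise result tables", {
  anno <- random_annotations(40, 4, 4, seed = 9)
  p <- structural_promiscuity(anno)
  td <- tidy(p)
  expect_false("f" %in% names(td))
  gl <- glance(p)
  expect_equal(gl$n_functions, nrow(p))
  expect_equal(gl$frac_single_structure, mean(p$n_structures == 1))
})
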