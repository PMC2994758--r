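# Build a symmetric distance lookup matrix from a pair table.  Missing
# pairs stay NA; the diagonal is 0 (every sequence is in its own ball).
dist_lookup_matrix <- function(dists, ids = NULL) {
  if (is.null(ids)) ids <- sort(unique(c(dists$seq_id_a, dists$seq_id_b)))
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  ia <- match(dists$seq_id_a, ids)
  ib <- match(dists$seq_id_b, ids)
  m[cbind(ia, ib)] <- dists$d
  m[cbind(ib, ia)] <- dists$d
  diag(m) <- 0
  m
}

# Integer function codes per sequence of the universe; NA for sequences
# without an annotation (they contribute no function to any ball).
function_codes <- function(ids, annotations, level) {
  anno <- validate_annotations(annotations)
  fun <- function_at_level(anno$function_id, level)
  codes <- match(fun, sort(unique(fun)))
  codes[match(ids, anno$seq_id)]
}

# For each center (column of dmat) and each radius, the sorted unique
# function codes carried by the ball's members.
ball_function_sets <- function(dmat, codes, radii) {
  lapply(radii, function(r) {
    lapply(seq_len(ncol(dmat)), function(ci) {
      d <- dmat[, ci]
      members <- which(!is.na(d) & d <= r)
      sort(unique(codes[members][!is.na(codes[members])]))
    })
  })
}

#' A genotype neighborhood (ball) around one sequence
#'
#' The neighborhood N_G(r) of a sequence G is the set of sequences whose
#' distance to G is at most r percent (inclusive; G itself is always a
#' member).  Its function set is the set of function labels carried by
#' its members at the chosen EC level.
#'
#' @param dists Pair table of distances (`seq_id_a`, `seq_id_b`, `d`),
#'   e.g. from [all_pairwise_distances()].
#' @param center A `seq_id` present in the distance table's universe.
#' @param r Radius in percent.
#' @param annotations Optional annotation data frame; when supplied the
#'   neighborhood's function set is collected.
#' @param level EC level for the function set (default 4).
#' @return A list with `center`, `radius`, `members` (character vector)
#'   and `functions` (character vector, `NULL` without annotations).
#' @export
neighborhood <- function(dists, center, r, annotations = NULL, level = 4L) {
  ids <- sort(unique(c(dists$seq_id_a, dists$seq_id_b)))
  if (!center %in% ids) {
    abort(paste0("Unknown center '", center, "': not in the distance table."))
  }
  m <- dist_lookup_matrix(dists, ids)
  d <- m[, center]
  members <- ids[!is.na(d) & d <= r]
  functions <- NULL
  if (!is.null(annotations)) {
    anno <- validate_annotations(annotations)
    fun <- function_at_level(anno$function_id, level)
    functions <- sort(unique(fun[anno$seq_id %in% members]))
  }
  list(center = center, radius = r, members = members,
       functions = functions)
}

#' Fraction of functions unique to one of two neighborhoods
#'
#' For the function sets S1 and S2 of two neighborhoods,
#' `F_u = (|S1| + |S2| - 2 |S1 n S2|) / |S1 u S2|`:
#' the fraction of functions found in one neighborhood but not the
#' other.  It equals the Jaccard distance `1 - |S1 n S2| / |S1 u S2|`
#' and lies in \[0, 1\]; it is undefined (error) when both sets are
#' empty.
#'
#' @param s1,s2 Vectors of function labels (duplicates ignored).
#' @return A number in \[0, 1\].
#' @examples
#' fraction_unique_functions(c("a", "b"), c("b", "c"))
#' @export
fraction_unique_functions <- function(s1, s2) {
  s1 <- unique(s1)
  s2 <- unique(s2)
  u <- length(union(s1, s2))
  if (u == 0) {
    abort("F_u undefined: both function sets are empty.")
  }
  (length(s1) + length(s2) - 2 * length(intersect(s1, s2))) / u
}

#' Sample unordered sequence pairs uniformly
#'
#' Draws `n_pairs` distinct unordered pairs uniformly at random from all
#' C(n, 2) pairs of the given sequences (all pairs when `n_pairs` is at
#' least C(n, 2)); deterministic under `seed`.
#'
#' @param ids Character vector of sequence ids, or a dataset (its
#'   `seq_id` column is used).
#' @param n_pairs Number of pairs to draw.
#' @param seed Integer seed.
#' @return A tibble with columns `seq_id_a`, `seq_id_b`.
#' @export
sample_pairs <- function(ids, n_pairs, seed = 1L) {
  if (is.data.frame(ids)) ids <- ids$seq_id
  n <- length(ids)
  if (n < 2) abort("Need at least 2 sequences to form pairs.")
  total <- n * (n - 1) / 2
  if (n_pairs >= total) {
    idx <- seq_len(total)
  } else {
    idx <- withr::with_seed(as.integer(seed),
                            sample.int(total, n_pairs, replace = FALSE))
  }
  # invert the row-major upper-triangle linear index:
  # pairs (i, j), i < j, ordered by i then j; cum(i) = i*n - i(i+1)/2
  k <- as.numeric(idx)
  i <- ceiling(((2 * n - 1) - sqrt((2 * n - 1)^2 - 8 * k)) / 2)
  # guard floating-point edges
  cum <- function(i) i * n - i * (i + 1) / 2
  too_big <- cum(i - 1) >= k
  i[too_big] <- i[too_big] - 1
  too_small <- cum(i) < k
  i[too_small] <- i[too_small] + 1
  j <- i + (k - cum(i - 1))
  tibble(seq_id_a = ids[i], seq_id_b = ids[as.integer(j)])
}

#' F_u records for sequence pairs over a list of radii
#'
#' For every requested pair of neighborhood centers and every radius r,
#' computes the centers' distance d, the fraction F_u of functions
#' unique to one of the two balls, and the size of the union of their
#' function sets.  Pairs whose two balls both carry no annotated
#' function have undefined F_u; such (pair, radius) records are skipped
#' and counted in the `"n_undefined"` attribute.
#'
#' @param pairs Tibble with columns `seq_id_a`, `seq_id_b` (e.g. from
#'   [sample_pairs()]), or `"all"` for every pair in the distance
#'   table's universe.
#' @param dists Distance pair table (`seq_id_a`, `seq_id_b`, `d`).
#' @param annotations Annotation data frame (`seq_id`, `structure_id`,
#'   `function_id`).
#' @param radii Numeric vector of neighborhood radii in percent.
#' @param level EC level at which functions are equated (default 4).
#' @return A tibble with columns `seq_id_a`, `seq_id_b`, `d`, `r`,
#'   `F_u`, `n_functions_union`.
#' @export
fu_for_pairs <- function(pairs, dists, annotations, radii, level = 4L) {
  ids <- sort(unique(c(dists$seq_id_a, dists$seq_id_b)))
  dmat <- dist_lookup_matrix(dists, ids)
  codes <- function_codes(ids, annotations, level)
  if (identical(pairs, "all")) {
    pairs <- sample_pairs(ids, n_pairs = Inf)
  }
  ia <- match(pairs$seq_id_a, ids)
  ib <- match(pairs$seq_id_b, ids)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- c(pairs$seq_id_a[is.na(ia)], pairs$seq_id_b[is.na(ib)])
    abort(paste0("Pair id(s) not in the distance table: ",
                 paste(unique(bad), collapse = ", ")))
  }
  sets_by_r <- ball_function_sets(dmat, codes, radii)
  d_pair <- dmat[cbind(ia, ib)]
  out <- vector("list", length(radii))
  n_undefined <- 0L
  for (k in seq_along(radii)) {
    sets <- sets_by_r[[k]]
    # F_u depends on a pair only through its two function sets, so
    # compute it once per distinct (set, set) combination
    keys <- vapply(sets, paste, character(1), collapse = ",")
    set_id <- match(keys, unique(keys))
    uniq_sets <- sets[match(unique(keys), keys)]
    ka <- set_id[ia]
    kb <- set_id[ib]
    combo <- paste(pmin(ka, kb), pmax(ka, kb))
    ucombo <- unique(combo)
    combo_fu <- numeric(length(ucombo))
    combo_union <- integer(length(ucombo))
    for (m in seq_along(ucombo)) {
      ids2 <- as.integer(strsplit(ucombo[m], " ", fixed = TRUE)[[1]])
      s1 <- uniq_sets[[ids2[1]]]
      s2 <- uniq_sets[[ids2[2]]]
      u <- length(union(s1, s2))
      if (u == 0) {
        combo_fu[m] <- NA_real_
        combo_union[m] <- 0L
      } else {
        combo_fu[m] <- (length(s1) + length(s2) -
                          2 * length(intersect(s1, s2))) / u
        combo_union[m] <- u
      }
    }
    mi <- match(combo, ucombo)
    rec <- tibble(seq_id_a = pairs$seq_id_a,
                  seq_id_b = pairs$seq_id_b,
                  d = d_pair,
                  r = radii[k],
                  F_u = combo_fu[mi],
                  n_functions_union = combo_union[mi])
    n_undefined <- n_undefined + sum(is.na(rec$F_u))
    out[[k]] <- rec[!is.na(rec$F_u), ]
  }
  res <- bind_rows(out)
  attr(res, "n_undefined") <- n_undefined
  res
}

#' Aggregate F_u records into a (distance bin x radius) grid
#'
#' Distances are grouped into half-open bins `[lo, lo + width)` of the
#' given width spanning `span` (the last bin is closed at the upper
#' end); the default width 5 over \[0, 100\] yields exactly 20 bins.
#' Each (bin, radius) cell reports the mean F_u, the number of pairs,
#' and the standard error (sample standard deviation / sqrt(n); missing
#' for n = 1).  Cells with no pairs are kept with `n_pairs = 0` and
#' missing mean, never silently treated as zero.  Cells where the two
#' balls cannot overlap (`r < lo / 2` for the whole bin) are flagged.
#'
#' @param records F_u record tibble from [fu_for_pairs()].
#' @param bin_width Bin width in percent (default 5).
#' @param span Two-element numeric range of distances (default
#'   `c(0, 100)`).
#' @return An `fu_grid` tibble with columns `d_bin_lo`, `d_bin_hi`, `r`,
#'   `mean_fu`, `n_pairs`, `se`, `non_overlapping`.
#' @export
aggregate_grid <- function(records, bin_width = 5, span = c(0, 100)) {
  if (bin_width <= 0) abort("`bin_width` must be positive.")
  if (nrow(records) == 0) abort("No F_u records to aggregate.")
  lo <- seq(span[1], span[2] - bin_width, by = bin_width)
  nbin <- length(lo)
  radii <- sort(unique(records$r))
  rec <- records[!is.na(records$d) &
                   records$d >= span[1] & records$d <= span[2], ]
  bin <- pmin(floor((rec$d - span[1]) / bin_width) + 1L, nbin)
  cells <- tibble(bin = bin, r = rec$r, F_u = rec$F_u) |>
    group_by(bin, r) |>
    summarise(mean_fu = mean(F_u), n_pairs = n(),
              se = if (n() > 1) sd(F_u) / sqrt(n()) else NA_real_,
              .groups = "drop")
  grid <- tidyr::expand_grid(bin = seq_len(nbin), r = radii) |>
    left_join(cells, by = c("bin", "r")) |>
    mutate(n_pairs = tidyr::replace_na(n_pairs, 0L),
           d_bin_lo = lo[bin],
           d_bin_hi = lo[bin] + bin_width,
           non_overlapping = r < d_bin_lo / 2) |>
    select(d_bin_lo, d_bin_hi, r, mean_fu, n_pairs, se, non_overlapping) |>
    arrange(r, d_bin_lo)
  class(grid) <- c("fu_grid", class(tibble()))
  attr(grid, "bin_width") <- bin_width
  attr(grid, "span") <- span
  attr(grid, "radii") <- radii
  grid
}

#' Combine F_u grids across resampled datasets
#'
#' Cell-wise mean and standard deviation of `mean_fu` across a list of
#' grids computed on independent resamples.  Cells empty in some
#' samples are averaged over the non-empty ones, with the number of
#' contributing samples reported; the standard deviation over a single
#' contributing sample is 0.
#'
#' @param grids A list of `fu_grid` objects sharing bin edges and radii.
#' @return An `fu_grid_summary` tibble with columns `d_bin_lo`,
#'   `d_bin_hi`, `r`, `mean_fu`, `sd_fu`, `n_samples`, `n_pairs_total`.
#' @export
multi_sample_summary <- function(grids) {
  if (length(grids) == 0) abort("No grids supplied.")
  key <- function(g) paste(g$d_bin_lo, g$d_bin_hi, g$r, collapse = ";")
  if (length(unique(vapply(grids, key, character(1)))) != 1L) {
    abort("All grids must share bin edges and radii.")
  }
  all <- bind_rows(lapply(seq_along(grids), function(i) {
    g <- as_tibble(grids[[i]])
    g$sample <- i
    g
  }))
  out <- all |>
    group_by(d_bin_lo, d_bin_hi, r) |>
    summarise(n_samples = sum(!is.na(mean_fu)),
              n_pairs_total = sum(n_pairs),
              sd_fu = if (sum(!is.na(mean_fu)) >= 2)
                sd(mean_fu[!is.na(mean_fu)]) else
                  ifelse(sum(!is.na(mean_fu)) == 1, 0, NA_real_),
              mean_fu = if (sum(!is.na(mean_fu)) >= 1)
                mean(mean_fu[!is.na(mean_fu)]) else NA_real_,
              .groups = "drop") |>
    select(d_bin_lo, d_bin_hi, r, mean_fu, sd_fu, n_samples,
           n_pairs_total) |>
    arrange(r, d_bin_lo)
  class(out) <- c("fu_grid_summary", class(tibble()))
  out
}
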