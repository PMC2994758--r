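#' Decompose structures into distance-threshold protein families
#'
#' A protein family is operationalised as a single-linkage connected
#' component of the graph on one structure's sequences with an edge
#' wherever the pairwise distance is strictly below `threshold` percent
#' (70 by default, the divergence up to which common ancestry is
#' usually recognisable).  Components are order-free, so the clustering
#' does not depend on input order; family identifiers are derived from
#' the lexicographically smallest member id, making them deterministic.
#'
#' @param data A dataset (used for the sequence universe and function
#'   labels; `residues` only needed when `dists` is not supplied).
#' @param dists Optional pre-computed within-structure distance pair
#'   table; computed with [all_pairwise_distances()] when `NULL`.
#' @param threshold Distance threshold in percent; edges require
#'   `d < threshold` (strict).
#' @return A `genospace_families` tibble with one row per sequence:
#'   `family_id`, `structure_id`, `seq_id`, `function_id`.  Attribute
#'   `"threshold"` records the cutoff.
#' @export
cluster_families <- function(data, dists = NULL, threshold = 70) {
  data <- validate_annotations(data, require_residues = is.null(dists))
  if (is.null(dists)) {
    dists <- all_pairwise_distances(data, within_structure_only = TRUE)
  }
  parts <- split(data, data$structure_id)
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    edges <- dists |>
      filter(seq_id_a %in% p$seq_id, seq_id_b %in% p$seq_id,
             !is.na(d), d < threshold)
    g <- igraph::graph_from_data_frame(
      edges[, c("seq_id_a", "seq_id_b")],
      directed = FALSE,
      vertices = data.frame(name = p$seq_id))
    comp <- igraph::components(g)$membership
    # order components by their smallest member id for stable naming
    members_by_comp <- split(names(comp), comp)
    ord <- order(vapply(members_by_comp, function(m) min(m), character(1)))
    fam_of_comp <- integer(length(members_by_comp))
    fam_of_comp[ord] <- seq_along(ord)
    fam_idx <- fam_of_comp[comp]
    p$family_id <- sprintf("%s/F%03d", p$structure_id[1],
                           fam_idx[match(p$seq_id, names(comp))])
    out[[i]] <- p[, c("family_id", "structure_id", "seq_id", "function_id")]
  }
  res <- bind_rows(out) |> arrange(family_id, seq_id)
  class(res) <- c("genospace_families", class(tibble()))
  attr(res, "threshold") <- threshold
  res
}

#' Per-family summary: members, function sets, monofunctionality
#'
#' @param families A `genospace_families` tibble from
#'   [cluster_families()] (or any data frame with `family_id`,
#'   `structure_id`, `seq_id`, `function_id`).
#' @param level EC level at which the family's function set is formed.
#' @return A tibble with `family_id`, `structure_id`, `n_members`,
#'   `functions` (list-column), `n_functions`, `monofunctional`.
#' @export
family_summary <- function(families, level = 4L) {
  families |>
    mutate(fun = function_at_level(function_id, level)) |>
    group_by(family_id, structure_id) |>
    summarise(n_members = n(),
              functions = list(sort(unique(fun))),
              n_functions = n_distinct(fun),
              .groups = "drop") |>
    mutate(monofunctional = n_functions == 1L)
}

#' Restrict a dataset to members of monofunctional families
#'
#' The control analysis: keeping only families that carry a single
#' function removes within-family functional diversity, so neighborhood
#' function sets become homogeneous below the family divergence scale.
#'
#' @param families A `genospace_families` tibble.
#' @param data The dataset to filter (matched on `seq_id`).
#' @param level EC level for deciding monofunctionality (default 4).
#' @return The filtered dataset.  Attributes `"n_families_kept"`,
#'   `"n_sequences_kept"`, `"n_functions_kept"` report retained counts.
#' @export
monofunctional_subset <- function(families, data, level = 4L) {
  fs <- family_summary(families, level)
  mono <- fs$family_id[fs$monofunctional]
  keep_ids <- families$seq_id[families$family_id %in% mono]
  out <- data[data$seq_id %in% keep_ids, ]
  attr(out, "n_families_kept") <- length(mono)
  attr(out, "n_sequences_kept") <- nrow(out)
  attr(out, "n_functions_kept") <-
    n_distinct(function_at_level(out$function_id, level))
  out
}

#' Fraction of family pairs sharing at least one function
#'
#' Over all unordered pairs of families (optionally only monofunctional
#' ones), the fraction whose function sets intersect.  In real data
#' this fraction is small: most families do their own thing.
#'
#' @param families A `genospace_families` tibble.
#' @param restrict_monofunctional Only consider monofunctional families.
#' @param level EC level for function sets (default 4).
#' @return A single fraction in \[0, 1\].
#' @export
fraction_family_pairs_same_function <- function(families,
                                                restrict_monofunctional = FALSE,
                                                level = 4L) {
  fs <- family_summary(families, level)
  if (restrict_monofunctional) fs <- fs[fs$monofunctional, ]
  nf <- nrow(fs)
  if (nf < 2) abort("Need at least 2 families after restriction.")
  sets <- fs$functions
  pairs <- utils::combn(nf, 2)
  share <- vapply(seq_len(ncol(pairs)), function(k) {
    length(intersect(sets[[pairs[1, k]]], sets[[pairs[2, k]]])) > 0
  }, logical(1))
  mean(share)
}

#' Histogram of families per structure
#'
#' @param families A `genospace_families` tibble.
#' @return A tibble `n_families`, `n_structures` with attributes `min`,
#'   `max`, `mean` of the per-structure family counts.
#' @export
families_per_structure_histogram <- function(families) {
  per_struct <- families |>
    group_by(structure_id) |>
    summarise(n_families = n_distinct(family_id), .groups = "drop")
  counts <- per_struct$n_families
  out <- per_struct |>
    count(n_families, name = "n_structures") |>
    arrange(n_families)
  attr(out, "min") <- if (length(counts)) min(counts) else NA_integer_
  attr(out, "max") <- if (length(counts)) max(counts) else NA_integer_
  attr(out, "mean") <- if (length(counts)) mean(counts) else NA_real_
  out
}
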