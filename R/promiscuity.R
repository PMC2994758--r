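#' Shannon entropy of a discrete distribution (natural log)
#'
#' @param p Numeric vector of probabilities or nonnegative weights;
#'   zero entries are ignored, weights are normalised to sum to one.
#' @return The entropy in nats.
#' @keywords internal
entropy_nat <- function(p) {
  p <- p[p > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Structural promiscuity of enzyme functions
#'
#' For each function F (equated at the chosen EC hierarchy level), let
#' f(i) be the fraction of F's sequences that fold into structure i.
#' The Shannon entropy H of the nonzero f(i), normalised by the maximal
#' entropy ln(N) attainable over the N structures present in the whole
#' dataset, defines the structural promiscuity
#' R_F = H / ln(N) in \[0, 1\]: zero when the function is carried out by
#' a single structure, one when it is spread uniformly over every
#' structure in the dataset.
#'
#' @param data A dataset or any data frame with `seq_id`,
#'   `structure_id`, `function_id` columns (residues not needed).
#' @param level EC hierarchy level (1..4) at which functions are
#'   equated; default 4, the finest-grained level.
#' @return A `promiscuity_tbl` tibble with one row per function:
#'   `function_label`, `n_sequences`, `n_structures`, `f` (list-column
#'   of named structure fractions), `H`, `R_F`.  Attributes: `N_total`
#'   (distinct structures in the dataset) and `ec_level`.
#' @examples
#' anno <- tibble::tibble(
#'   seq_id = paste0("s", 1:4),
#'   structure_id = c("a", "a", "b", "b"),
#'   function_id = "1.1.1.1")
#' structural_promiscuity(anno)
#' @export
structural_promiscuity <- function(data, level = 4L) {
  anno <- validate_annotations(data)
  if (nrow(anno) == 0) abort("Empty dataset.")
  N_total <- n_distinct(anno$structure_id)
  if (N_total < 2) {
    abort("Promiscuity normalization needs at least 2 distinct structures.")
  }
  anno$fun <- function_at_level(anno$function_id, level)
  out <- anno |>
    count(fun, structure_id, name = "n_seq") |>
    group_by(fun) |>
    summarise(n_sequences = sum(n_seq),
              n_structures = n(),
              f = list(setNames(n_seq / sum(n_seq), structure_id)),
              H = entropy_nat(n_seq / sum(n_seq)),
              .groups = "drop") |>
    mutate(R_F = H / log(N_total)) |>
    dplyr::rename(function_label = fun) |>
    arrange(function_label)
  class(out) <- c("promiscuity_tbl", class(tibble()))
  attr(out, "N_total") <- N_total
  attr(out, "ec_level") <- as.integer(level)
  out
}

#' Functional versatility of protein structures
#'
#' The mirror statistic of [structural_promiscuity()]: for each
#' structure S, g(F) is the fraction of S's sequences performing
#' function F, and V_S = H(g) / ln(M) where M is the number of distinct
#' functions (at the chosen EC level) in the whole dataset.  V_S is zero
#' for a monofunctional structure and one for a structure spread
#' uniformly over every function.
#'
#' @inheritParams structural_promiscuity
#' @return A `versatility_tbl` tibble with one row per structure:
#'   `structure_id`, `n_sequences`, `n_functions`, `g` (list-column of
#'   named function fractions), `H`, `V_S`.  Attributes: `M_total`,
#'   `ec_level`.
#' @export
functional_versatility <- function(data, level = 4L) {
  anno <- validate_annotations(data)
  if (nrow(anno) == 0) abort("Empty dataset.")
  anno$fun <- function_at_level(anno$function_id, level)
  M_total <- n_distinct(anno$fun)
  if (M_total < 2) {
    abort("Versatility normalization needs at least 2 distinct functions.")
  }
  out <- anno |>
    count(structure_id, fun, name = "n_seq") |>
    group_by(structure_id) |>
    summarise(n_sequences = sum(n_seq),
              n_functions = n(),
              g = list(setNames(n_seq / sum(n_seq), fun)),
              H = entropy_nat(n_seq / sum(n_seq)),
              .groups = "drop") |>
    mutate(V_S = H / log(M_total)) |>
    arrange(structure_id)
  class(out) <- c("versatility_tbl", class(tibble()))
  attr(out, "M_total") <- M_total
  attr(out, "ec_level") <- as.integer(level)
  out
}

#' Histogram of structures per function
#'
#' Counts how many functions are associated with 1, 2, ... structures
#' (the skew of this distribution is the headline pattern: most
#' functions are monostructural).
#'
#' @param table A `promiscuity_tbl` from [structural_promiscuity()].
#' @return A tibble `n_structures`, `n_functions` with attributes
#'   `min`, `max`, `mean` of the per-function structure counts.
#' @export
structures_per_function_histogram <- function(table) {
  counts <- table$n_structures
  out <- table |>
    count(n_structures, name = "n_functions") |>
    arrange(n_structures)
  attr(out, "min") <- if (length(counts)) min(counts) else NA_integer_
  attr(out, "max") <- if (length(counts)) max(counts) else NA_integer_
  attr(out, "mean") <- if (length(counts)) mean(counts) else NA_real_
  out
}

#' Histogram of functions per structure
#'
#' @param table A `versatility_tbl` from [functional_versatility()].
#' @return A tibble `n_functions`, `n_structures` with attributes
#'   `min`, `max`, `mean` of the per-structure function counts.
#' @export
functions_per_structure_histogram <- function(table) {
  counts <- table$n_functions
  out <- table |>
    count(n_functions, name = "n_structures") |>
    arrange(n_functions)
  attr(out, "min") <- if (length(counts)) min(counts) else NA_integer_
  attr(out, "max") <- if (length(counts)) max(counts) else NA_integer_
  attr(out, "mean") <- if (length(counts)) mean(counts) else NA_real_
  out
}

#' Mean global structure frequency per function
#'
#' A control for uneven sequence counts: for each structure i, let f_i
#' be the fraction of all dataset sequences adopting i; for each
#' function, the unweighted mean of f_i over its associated structures
#' is reported.  Functions associated only with rarely-sequenced
#' structures score low even if they use several of them.
#'
#' @inheritParams structural_promiscuity
#' @return A tibble `function_label`, `mean_f_i`.
#' @export
mean_structure_frequency_per_function <- function(data, level = 4L) {
  anno <- validate_annotations(data)
  if (nrow(anno) == 0) abort("Empty dataset.")
  global_f <- anno |>
    count(structure_id, name = "n_seq") |>
    mutate(f_i = n_seq / sum(n_seq))
  anno$fun <- function_at_level(anno$function_id, level)
  anno |>
    distinct(fun, structure_id) |>
    left_join(global_f[, c("structure_id", "f_i")], by = "structure_id") |>
    group_by(fun) |>
    summarise(mean_f_i = mean(f_i), .groups = "drop") |>
    dplyr::rename(function_label = fun) |>
    arrange(function_label)
}

#' The k most structurally promiscuous functions
#'
#' Ranks functions by R_F descending; ties are broken by `n_structures`
#' descending, then by function label lexicographically.
#'
#' @param table A `promiscuity_tbl`.
#' @param k Number of rows to return (the whole table if larger).
#' @return The top rows with a `rank` column prepended.
#' @export
top_promiscuous <- function(table, k = 10L) {
  ranked <- table |>
    arrange(desc(R_F), desc(n_structures), function_label) |>
    mutate(rank = row_number()) |>
    select(rank, dplyr::everything())
  head(ranked, k)
}
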