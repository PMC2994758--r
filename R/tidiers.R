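#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a promiscuity table
#'
#' @param x A `promiscuity_tbl`.
#' @param ... Unused.
#' @return A plain tibble without list-columns: `function_label`,
#'   `n_sequences`, `n_structures`, `H`, `R_F`.
#' @export
tidy.promiscuity_tbl <- function(x, ...) {
  flatten_promiscuity(x)
}

#' One-row summary of a promiscuity table
#'
#' @param x A `promiscuity_tbl`.
#' @param ... Unused.
#' @return A tibble with `n_functions`, `n_structures_total`,
#'   `ec_level`, `frac_single_structure` (the fraction of functions
#'   carried out by exactly one structure), `mean_R_F`, `max_R_F`.
#' @export
glance.promiscuity_tbl <- function(x, ...) {
  tibble(n_functions = nrow(x),
         n_structures_total = attr(x, "N_total"),
         ec_level = attr(x, "ec_level"),
         frac_single_structure = mean(x$n_structures == 1),
         mean_R_F = mean(x$R_F),
         max_R_F = max(x$R_F))
}

#' Tidy a versatility table
#'
#' @param x A `versatility_tbl`.
#' @param ... Unused.
#' @return A plain tibble: `structure_id`, `n_sequences`,
#'   `n_functions`, `H`, `V_S`.
#' @export
tidy.versatility_tbl <- function(x, ...) {
  flatten_versatility(x)
}

#' One-row summary of a versatility table
#'
#' @param x A `versatility_tbl`.
#' @param ... Unused.
#' @return A tibble with `n_structures`, `n_functions_total`,
#'   `ec_level`, `frac_single_function`, `mean_V_S`, `max_V_S`.
#' @export
glance.versatility_tbl <- function(x, ...) {
  tibble(n_structures = nrow(x),
         n_functions_total = attr(x, "M_total"),
         ec_level = attr(x, "ec_level"),
         frac_single_function = mean(x$n_functions == 1),
         mean_V_S = mean(x$V_S),
         max_V_S = max(x$V_S))
}

#' Tidy an F_u grid
#'
#' @param x An `fu_grid`.
#' @param ... Unused.
#' @return The grid as a plain tibble.
#' @export
tidy.fu_grid <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of an F_u grid
#'
#' @param x An `fu_grid`.
#' @param ... Unused.
#' @return A tibble with `n_cells`, `n_nonempty_cells`,
#'   `n_pairs_total`, `bin_width`, `n_radii`.
#' @export
glance.fu_grid <- function(x, ...) {
  tibble(n_cells = nrow(x),
         n_nonempty_cells = sum(x$n_pairs > 0),
         n_pairs_total = sum(x$n_pairs),
         bin_width = attr(x, "bin_width"),
         n_radii = length(attr(x, "radii")))
}
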