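#' Encode aligned residue strings as an integer code matrix
#'
#' Internal representation consumed by the compiled distance kernel:
#' gaps become 0, `X` becomes -1 (mismatching everything, including
#' another `X`), amino acids become their 1-based alphabet index.
#'
#' @param residues Character vector of equal-length aligned rows.
#' @return An integer matrix, sequences in rows.
#' @keywords internal
residue_codes <- function(residues) {
  n <- length(residues)
  L <- unique(nchar(residues))
  if (length(L) != 1L) abort("Residue strings must have equal length.")
  chars <- matrix(unlist(strsplit(residues, "", fixed = TRUE)),
                  nrow = n, ncol = L, byrow = TRUE)
  codes <- match(chars, aa_alphabet())
  codes[chars == "-"] <- 0L
  codes[chars == "X"] <- -1L
  if (anyNA(codes)) abort("Illegal residue characters in input.")
  matrix(as.integer(codes), nrow = n, ncol = L)
}

#' Percent divergence between two aligned sequences
#'
#' Columns where either sequence carries a gap are excluded (pairwise
#' deletion); over the remaining columns the distance is
#' `100 * mismatches / n_compared`.  The unknown residue `X` mismatches
#' every character, including another `X`.
#'
#' @param a,b Aligned residue strings of equal length (or single-row data
#'   frames with `seq_id` and `residues` columns).
#' @param seq_id_a,seq_id_b Optional identifiers for the output row.
#' @return A one-row tibble with `seq_id_a`, `seq_id_b`, `d` (percent, in
#'   \[0, 100\]) and `n_compared`.
#' @examples
#' pairwise_distance("AAAA", "AAAT")
#' pairwise_distance("AA-A", "AATA")
#' @export
pairwise_distance <- function(a, b, seq_id_a = "a", seq_id_b = "b") {
  if (is.data.frame(a)) { seq_id_a <- a$seq_id[1]; a <- a$residues[1] }
  if (is.data.frame(b)) { seq_id_b <- b$seq_id[1]; b <- b$residues[1] }
  if (nchar(a) != nchar(b)) {
    abort("Sequences must come from the same alignment (equal length).")
  }
  res <- dist_matrix_codes(residue_codes(c(a, b)))
  d <- res$d[1, 2]
  if (is.na(d)) {
    abort(paste0("Distance undefined for pair ('", seq_id_a, "', '",
                 seq_id_b, "'): no gap-free column to compare."))
  }
  tibble(seq_id_a = seq_id_a, seq_id_b = seq_id_b,
         d = d, n_compared = res$n_compared[1, 2])
}

# Distance + n_compared matrices for a block of aligned rows.
distance_matrices <- function(seq_ids, residues) {
  res <- dist_matrix_codes(residue_codes(residues))
  dimnames(res$d) <- list(seq_ids, seq_ids)
  dimnames(res$n_compared) <- list(seq_ids, seq_ids)
  res
}

matrix_to_pair_tbl <- function(res) {
  ids <- rownames(res$d)
  n <- length(ids)
  if (n < 2) {
    return(tibble(seq_id_a = character(), seq_id_b = character(),
                  d = numeric(), n_compared = integer()))
  }
  idx <- which(upper.tri(res$d), arr.ind = TRUE)
  tibble(seq_id_a = ids[idx[, 1]], seq_id_b = ids[idx[, 2]],
         d = res$d[idx], n_compared = res$n_compared[idx])
}

#' All pairwise sequence distances in a dataset
#'
#' Enumerates every unordered sequence pair once, either within each
#' structure alignment separately (the default; the per-structure
#' exhaustive analysis) or across the whole dataset (possible only when
#' all alignments share the same column count, e.g. after window
#' resampling, so that all sequences live in one genotype space).
#' Pairs with no gap-free column to compare have no defined distance;
#' they are dropped and counted in the `"n_undefined_dropped"` attribute.
#'
#' @param data A `genospace_dataset` (or data frame with `seq_id`,
#'   `structure_id`, `residues`).
#' @param within_structure_only If `TRUE` (default), only pairs sharing a
#'   structure are compared.
#' @return A tibble with columns `seq_id_a`, `seq_id_b`, `d`,
#'   `n_compared`.
#' @export
all_pairwise_distances <- function(data, within_structure_only = TRUE) {
  data <- validate_annotations(data, require_residues = TRUE)
  if (within_structure_only) {
    parts <- split(data, data$structure_id)
    tbl <- bind_rows(lapply(parts, function(p) {
      matrix_to_pair_tbl(distance_matrices(p$seq_id, p$residues))
    }))
  } else {
    widths <- unique(nchar(data$residues))
    if (length(widths) != 1L) {
      abort(paste0("Cross-structure distances need equal column counts; ",
                   "found widths ", paste(sort(widths), collapse = ", "),
                   ". Resample equal-length sections first."))
    }
    tbl <- matrix_to_pair_tbl(distance_matrices(data$seq_id, data$residues))
  }
  undef <- is.na(tbl$d)
  out <- tbl[!undef, ]
  attr(out, "n_undefined_dropped") <- sum(undef)
  out
}
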