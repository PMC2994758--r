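#' Filtering and resampling configuration
#'
#' Bundles the alignment-hygiene thresholds used across the pipeline:
#' a minimum ungapped sequence length, a cap on pairwise identity (to
#' curb redundancy without collapsing the data to representatives), gap
#' thresholds applied per sequence and per alignment column, and the
#' parameters of the equal-length window resampling that embeds
#' different structures in one genotype space.
#'
#' @param min_length Sequences are kept only if their ungapped residue
#'   count exceeds this value (default 50).
#' @param max_identity_pct Maximum allowed pairwise percent identity
#'   between kept sequences (default 99).
#' @param max_gap_col_fraction An alignment is discarded when more than
#'   this fraction of its columns contains any gap (default 0.10).
#' @param max_gap_seq_fraction A sequence is discarded when more than
#'   this fraction of its positions are gaps (default 0.10).
#' @param section_length Width, in columns, of resampled windows
#'   (default 100).
#' @param n_resamples Number of independent window resamples (default 10).
#' @param rng_seed Master seed for the resampling streams.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_length = 50L,
                          max_identity_pct = 99,
                          max_gap_col_fraction = 0.10,
                          max_gap_seq_fraction = 0.10,
                          section_length = 100L,
                          n_resamples = 10L,
                          rng_seed = 1L) {
  stopifnot(min_length >= 0,
            max_identity_pct >= 0, max_identity_pct <= 100,
            max_gap_col_fraction >= 0, max_gap_col_fraction <= 1,
            max_gap_seq_fraction >= 0, max_gap_seq_fraction <= 1,
            section_length >= 1, n_resamples >= 1)
  structure(list(min_length = as.integer(min_length),
                 max_identity_pct = max_identity_pct,
                 max_gap_col_fraction = max_gap_col_fraction,
                 max_gap_seq_fraction = max_gap_seq_fraction,
                 section_length = as.integer(section_length),
                 n_resamples = as.integer(n_resamples),
                 rng_seed = as.integer(rng_seed)),
            class = "filter_config")
}

gap_fraction <- function(residues) {
  stringr::str_count(residues, stringr::fixed("-")) / nchar(residues)
}

ungapped_length <- function(residues) {
  nchar(residues) - stringr::str_count(residues, stringr::fixed("-"))
}

#' Drop sequences shorter than the single-domain length floor
#'
#' Keeps sequences whose ungapped residue count strictly exceeds
#' `min_length` ("longer than" the floor, so a sequence of exactly
#' `min_length` residues is dropped).
#'
#' @param data A dataset tibble.
#' @param min_length Length floor in residues (default 50).
#' @return The filtered dataset; dropped-row count in attribute
#'   `"n_dropped"`.
#' @export
filter_min_length <- function(data, min_length = 50L) {
  data <- validate_annotations(data, require_residues = TRUE)
  keep <- ungapped_length(data$residues) > min_length
  out <- data[keep, ]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Gap filtering of structure alignments
#'
#' Applied per structure, in two passes: first, sequences whose own gap
#' fraction exceeds `max_gap_seq_fraction` are removed; second, if the
#' fraction of remaining columns that contain any gap exceeds
#' `max_gap_col_fraction`, the whole alignment is discarded.  Surviving
#' alignments keep their original column count.
#'
#' @param data A dataset tibble (one or more structures).
#' @param max_gap_seq_fraction,max_gap_col_fraction Thresholds in
#'   \[0, 1\]; defaults 0.10.
#' @return The filtered dataset.  Attribute `"gap_filter_log"` holds a
#'   per-structure tibble of dropped-sequence counts and whether the
#'   alignment itself was dropped; `"n_dropped"` the total count of
#'   removed sequences.
#' @export
filter_gappy <- function(data,
                         max_gap_seq_fraction = 0.10,
                         max_gap_col_fraction = 0.10) {
  data <- validate_annotations(data, require_residues = TRUE)
  parts <- split(data, data$structure_id)
  kept <- vector("list", length(parts))
  log <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    seq_ok <- gap_fraction(p$residues) <= max_gap_seq_fraction
    surv <- p[seq_ok, ]
    aln_dropped <- FALSE
    if (nrow(surv) > 0) {
      cols <- matrix(unlist(strsplit(surv$residues, "", fixed = TRUE)),
                     nrow = nrow(surv), byrow = TRUE)
      frac_gapped_cols <- mean(apply(cols == "-", 2, any))
      if (frac_gapped_cols > max_gap_col_fraction) {
        aln_dropped <- TRUE
        surv <- surv[0, ]
      }
    }
    kept[[i]] <- surv
    log[[i]] <- tibble(structure_id = p$structure_id[1],
                       n_in = nrow(p),
                       n_dropped_gappy_seqs = sum(!seq_ok),
                       alignment_dropped = aln_dropped,
                       n_out = nrow(surv))
  }
  out <- bind_rows(kept)
  log <- bind_rows(log)
  attr(out, "gap_filter_log") <- log
  attr(out, "n_dropped") <- sum(log$n_in - log$n_out)
  out
}

#' Cap pairwise identity by a greedy dedupe pass
#'
#' Within each structure alignment, members are scanned in input order
#' and a member is kept only if its percent identity (100 - d) to every
#' already-kept member does not exceed `max_identity_pct`.  Input order
#' therefore defines priority; the pass is deterministic.  Pairs with no
#' comparable column have undefined identity and do not block keeping.
#'
#' @param data A dataset tibble.
#' @param max_identity_pct Identity cap in percent (default 99).
#' @return The filtered dataset; dropped count in attribute
#'   `"n_dropped"`.
#' @export
dedupe_by_identity <- function(data, max_identity_pct = 99) {
  data <- validate_annotations(data, require_residues = TRUE)
  parts <- split(data, data$structure_id)
  kept <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (nrow(p) <= 1) { kept[[i]] <- p; next }
    d <- distance_matrices(p$seq_id, p$residues)$d
    keep_idx <- integer(0)
    for (j in seq_len(nrow(p))) {
      ident <- 100 - d[j, keep_idx]
      if (all(is.na(ident)) || all(ident <= max_identity_pct, na.rm = TRUE)) {
        keep_idx <- c(keep_idx, j)
      }
    }
    kept[[i]] <- p[keep_idx, ]
  }
  out <- bind_rows(kept)
  attr(out, "n_dropped") <- nrow(data) - nrow(out)
  out
}

#' Apply the full filter funnel
#'
#' Runs, in order: the ungapped length floor, the per-sequence and
#' per-column gap filters, and the identity-cap dedupe.  Gap filters
#' run before the identity cap so that identity is computed on the
#' cleaned alignments.
#'
#' @param data A dataset tibble.
#' @param cfg A [filter_config()].
#' @return The filtered dataset.  Attribute `"funnel"` is a tibble with
#'   one row per stage (`stage`, `n_in`, `n_out`, `n_dropped`) whose
#'   counts are conserved: `n_in` of each stage equals `n_out` of the
#'   previous one, and `n_out + n_dropped = n_in` everywhere.
#' @export
filter_dataset <- function(data, cfg = filter_config()) {
  data <- validate_annotations(data, require_residues = TRUE)
  stages <- list(
    min_length = function(d) filter_min_length(d, cfg$min_length),
    gap_filter = function(d) filter_gappy(d, cfg$max_gap_seq_fraction,
                                          cfg$max_gap_col_fraction),
    identity_cap = function(d) dedupe_by_identity(d, cfg$max_identity_pct))
  funnel <- vector("list", length(stages))
  cur <- data
  for (i in seq_along(stages)) {
    n_in <- nrow(cur)
    cur <- stages[[i]](cur)
    funnel[[i]] <- tibble(stage = names(stages)[i], n_in = n_in,
                          n_out = nrow(cur), n_dropped = n_in - nrow(cur))
  }
  attr(cur, "funnel") <- bind_rows(funnel)
  cur
}

# Deterministic per-(structure, resample) RNG substream seed, so adding
# or removing one alignment never changes the windows cut from others.
substream_seed <- function(master_seed, structure_id, resample_index) {
  h <- 0
  for (ch in utf8ToInt(structure_id)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + master_seed * 7919 + resample_index * 104729) %% 2147483647)
}

#' Cut random equal-length sections from every alignment
#'
#' To compare sequences with different structures (hence alignments of
#' different widths) in one genotype space, every alignment at least
#' `section_length` columns wide contributes one uniformly random
#' contiguous window of exactly `section_length` columns per resample;
#' narrower alignments are excluded.  Each window is then re-filtered
#' with [filter_gappy()] (windows can be gappier than the full
#' alignment).  With a fixed `rng_seed` the output is bit-reproducible,
#' and each (structure, resample) pair draws from its own substream.
#'
#' @param data A dataset tibble.
#' @param cfg A [filter_config()]; uses `section_length`, `n_resamples`,
#'   `rng_seed` and the gap thresholds.
#' @return A list of `n_resamples` datasets, each of width
#'   `section_length`.
#' @export
resample_sections <- function(data, cfg = filter_config()) {
  data <- validate_annotations(data, require_residues = TRUE)
  L <- cfg$section_length
  parts <- split(data, data$structure_id)
  widths <- vapply(parts, function(p) nchar(p$residues[1]), integer(1))
  parts <- parts[widths >= L]
  widths <- widths[widths >= L]
  lapply(seq_len(cfg$n_resamples), function(i) {
    cut <- lapply(seq_along(parts), function(k) {
      p <- parts[[k]]
      s <- withr::with_seed(
        substream_seed(cfg$rng_seed, p$structure_id[1], i),
        sample.int(widths[k] - L + 1L, 1L))
      p$residues <- substr(p$residues, s, s + L - 1L)
      attr(p, "window_start") <- s
      p
    })
    filter_gappy(bind_rows(cut), cfg$max_gap_seq_fraction,
                 cfg$max_gap_col_fraction)
  })
}
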