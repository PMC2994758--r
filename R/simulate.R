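#' Expected pairwise divergence under per-site resampling
#'
#' The generator mutates sequences by resampling each site, with some
#' probability per branch, to a uniformly random amino acid (possibly
#' the same one).  For two sequences whose chains of descent from their
#' common ancestor carry total per-site resampling probabilities `c1`
#' and `c2`, a site ends up differing exactly when at least one chain
#' resampled it and the final draws disagree, which happens with
#' probability 19/20.  The expected percent divergence is therefore
#' `95 * (1 - (1 - c1) * (1 - c2))`; two sequences with independent
#' uniform ancestors (`c = 1`) diverge by 95 percent in expectation.
#'
#' @param c1,c2 Per-site resampling probabilities of the two chains.
#' @return Expected percent divergence.
#' @export
expected_pairwise_divergence <- function(c1, c2 = c1) {
  95 * (1 - (1 - c1) * (1 - c2))
}

# chain composition: probability that a site was resampled at least
# once along consecutive branches with per-site probabilities p, q
combine_chain <- function(p, q) 1 - (1 - p) * (1 - q)

# invert expected_pairwise_divergence for two equal chains
site_prob_for_divergence <- function(target_pct) {
  if (target_pct < 0 || target_pct >= 95) {
    abort("Target divergence must be in [0, 95) percent.")
  }
  1 - sqrt(1 - target_pct / 95)
}

#' Configuration of the synthetic sequence generator
#'
#' The generator emulates the shape of curated enzyme data: several
#' structures, each an alignment of 100-400 columns; sequences within a
#' structure fall into families (clusters diverged below the family
#' threshold) that are star-shaped around remote ancestors; families
#' are subdivided into subfamilies, and a family is multifunctional
#' when its subfamilies carry distinct functions (function turnover
#' happens between, not within, close relatives); some functions recur
#' in several structures (structural promiscuity).
#'
#' @param n_structures Number of structures.
#' @param families_per_structure Either a fixed count or
#'   `list(poisson = mean)`.
#' @param seqs_per_family Either a fixed count or `list(poisson =
#'   mean)`; draws are clamped to at least 2.
#' @param subfamilies_per_family Two-element integer range; each family
#'   draws its subfamily count uniformly from it (multifunctional
#'   families from its part that is at least 2).
#' @param seq_length Alignment columns (default 100).
#' @param intra_family_divergence Target expected percent divergence
#'   between members of the same family but different subfamilies
#'   (default 55, the scale of typical same-structure-and-function
#'   divergence); must stay below `inter_family_divergence`.
#' @param intra_subfamily_divergence Target expected percent divergence
#'   within a subfamily (default 15).
#' @param inter_family_divergence Required minimum expected divergence
#'   between families (default 90).  Families descend from independent
#'   uniform ancestors, so their expected divergence is 95 percent;
#'   this parameter is a validated floor recorded in the ground truth.
#' @param p_multifunctional Probability that a family carries more than
#'   one function.
#' @param n_functions_pool Number of distinct EC-like labels available.
#' @param p_promiscuous Probability that a newly assigned function
#'   reuses a label already used in another structure.
#' @param plant_promiscuous_k If positive, one designated function is
#'   deliberately planted into exactly one family in each of the first
#'   `k` structures (ground truth for promiscuity recovery).
#' @param gap_col_fraction Fraction of alignment columns per structure
#'   designated as indel hotspots, the only columns that may carry
#'   gaps (default 0.05).  Real alignments concentrate gaps in a few
#'   indel-prone columns; spreading them independently over all
#'   columns would make almost every column gapped in large
#'   alignments.
#' @param gap_rate Per-site probability of replacing a residue by a
#'   gap character within a hotspot column (column-preserving, so rows
#'   stay aligned); the expected overall gap fraction per sequence is
#'   `gap_col_fraction * gap_rate`.
#' @param rng_seed Integer seed; generation is bit-reproducible.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_structures = 3L,
                             families_per_structure = 4L,
                             seqs_per_family = 10L,
                             subfamilies_per_family = c(1L, 3L),
                             seq_length = 100L,
                             intra_family_divergence = 55,
                             intra_subfamily_divergence = 15,
                             inter_family_divergence = 90,
                             p_multifunctional = 0.25,
                             n_functions_pool = 50L,
                             p_promiscuous = 0.05,
                             plant_promiscuous_k = 0L,
                             gap_col_fraction = 0.05,
                             gap_rate = 0.3,
                             rng_seed = 1L) {
  cfg <- structure(list(n_structures = as.integer(n_structures),
                        families_per_structure = families_per_structure,
                        seqs_per_family = seqs_per_family,
                        subfamilies_per_family = as.integer(subfamilies_per_family),
                        seq_length = as.integer(seq_length),
                        intra_family_divergence = intra_family_divergence,
                        intra_subfamily_divergence = intra_subfamily_divergence,
                        inter_family_divergence = inter_family_divergence,
                        p_multifunctional = p_multifunctional,
                        n_functions_pool = as.integer(n_functions_pool),
                        p_promiscuous = p_promiscuous,
                        plant_promiscuous_k = as.integer(plant_promiscuous_k),
                        gap_col_fraction = gap_col_fraction,
                        gap_rate = gap_rate,
                        rng_seed = as.integer(rng_seed)),
                   class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  probs <- c(cfg$p_multifunctional, cfg$p_promiscuous, cfg$gap_rate,
             cfg$gap_col_fraction)
  if (any(probs < 0 | probs > 1)) {
    abort("Probabilities must lie in [0, 1].")
  }
  if (cfg$seq_length < 1) abort("seq_length must be at least 1.")
  if (cfg$intra_subfamily_divergence > cfg$intra_family_divergence) {
    abort("intra_subfamily_divergence must not exceed intra_family_divergence.")
  }
  if (cfg$intra_family_divergence >= cfg$inter_family_divergence) {
    abort("Infeasible config: intra-family divergence must be below inter-family divergence.")
  }
  if (cfg$inter_family_divergence > 95) {
    abort("inter_family_divergence cannot exceed 95 (independent uniform ancestors).")
  }
  if (cfg$p_multifunctional > 0 && max(cfg$subfamilies_per_family) < 2) {
    abort("Multifunctional families need at least 2 subfamilies allowed.")
  }
  if (cfg$plant_promiscuous_k > cfg$n_structures) {
    abort("plant_promiscuous_k cannot exceed n_structures.")
  }
  invisible(cfg)
}

draw_count <- function(spec, n, minimum = 1L) {
  if (is.numeric(spec) && length(spec) == 1L) {
    rep(max(as.integer(spec), minimum), n)
  } else if (is.list(spec) && !is.null(spec$poisson)) {
    pmax(rpois(n, spec$poisson), minimum)
  } else {
    abort("Count spec must be a number or list(poisson = mean).")
  }
}

mutate_sites <- function(chars, p) {
  if (p <= 0) return(chars)
  hit <- runif(length(chars)) < p
  chars[hit] <- sample(aa_alphabet(), sum(hit), replace = TRUE)
  chars
}

make_function_pool <- function(n) {
  sprintf("%d.%d.%d.%d",
          sample(1:6, n, replace = TRUE),
          sample(1:30, n, replace = TRUE),
          sample(1:30, n, replace = TRUE),
          seq_len(n))
}

#' Generate a synthetic annotated, aligned dataset with ground truth
#'
#' See [generator_config()] for the generative model.  Families are
#' stars: a family ancestor is uniform over the 20 amino acids, each
#' subfamily ancestor is a per-site mutant of it, and each member a
#' per-site mutant of its subfamily ancestor, with site probabilities
#' solved from the closed form in [expected_pairwise_divergence()] so
#' that expected within-subfamily and within-family divergences hit
#' their configured targets; different families diverge by 95 percent
#' in expectation.  Gaps are confined to per-structure hotspot columns
#' and inserted there per site at `gap_rate`, keeping all rows aligned.
#'
#' @param cfg A [generator_config()].
#' @return A list with elements `dataset` (a `genospace_dataset`
#'   tibble), `truth` (list of tibbles `sequences`, `families`,
#'   `functions`, plus the solved site probabilities in `params`) and
#'   `config`.
#' @export
generate <- function(cfg = generator_config()) {
  validate_generator_config(cfg)
  p2 <- site_prob_for_divergence(cfg$intra_subfamily_divergence)
  # expected cross-subfamily divergence within a family:
  # both chains pass the subfamily branch (p1) and the member branch (p2)
  p1 <- 1 - sqrt(1 - cfg$intra_family_divergence / 95) / (1 - p2)

  withr::with_seed(cfg$rng_seed, {
    pool <- make_function_pool(cfg$n_functions_pool)
    planted_label <- if (cfg$plant_promiscuous_k > 0) pool[1] else NA_character_
    unused <- if (cfg$plant_promiscuous_k > 0) pool[-1] else pool
    used_by_structure <- list()
    pool_exhausted_warned <- FALSE

    take_function <- function(structure_id) {
      other <- setdiff(unique(unlist(used_by_structure[
        setdiff(names(used_by_structure), structure_id)])), planted_label)
      if (length(other) > 0 && runif(1) < cfg$p_promiscuous) {
        return(sample(other, 1))
      }
      if (length(unused) > 0) {
        f <- unused[1]
        unused <<- unused[-1]
        return(f)
      }
      if (!pool_exhausted_warned) {
        warn("Function pool exhausted; reusing labels.")
        pool_exhausted_warned <<- TRUE
      }
      sample(setdiff(unique(unlist(used_by_structure)), planted_label), 1)
    }

    n_fam <- draw_count(cfg$families_per_structure, cfg$n_structures,
                        minimum = 1L)
    seq_rows <- list()
    fam_rows <- list()
    for (si in seq_len(cfg$n_structures)) {
      structure_id <- sprintf("3.90.%d.10", si)
      n_hot <- round(cfg$gap_col_fraction * cfg$seq_length)
      hotspots <- if (n_hot > 0) sample.int(cfg$seq_length, n_hot) else integer(0)
      used_here <- character(0)
      for (fi in seq_len(n_fam[si])) {
        family_id <- sprintf("%s/fam%02d", structure_id, fi)
        planted <- cfg$plant_promiscuous_k > 0 && si <= cfg$plant_promiscuous_k &&
          fi == 1L
        multi <- !planted && runif(1) < cfg$p_multifunctional
        sub_range <- cfg$subfamilies_per_family
        if (multi) sub_range[1] <- max(sub_range[1], 2L)
        n_sub <- if (sub_range[1] >= sub_range[2]) sub_range[1] else
          sample(seq(sub_range[1], sub_range[2]), 1)
        if (planted) {
          sub_funs <- rep(planted_label, n_sub)
        } else if (multi) {
          sub_funs <- character(n_sub)
          for (u in seq_len(n_sub)) {
            repeat {
              f <- take_function(structure_id)
              if (!f %in% sub_funs) { sub_funs[u] <- f; break }
            }
          }
        } else {
          sub_funs <- rep(take_function(structure_id), n_sub)
        }
        used_here <- c(used_here, sub_funs)
        used_by_structure[[structure_id]] <- unique(used_here)

        n_members <- draw_count(cfg$seqs_per_family, 1L, minimum = 2L)
        # near-even allocation of members to subfamilies
        alloc <- rep(n_members %/% n_sub, n_sub)
        extra <- n_members %% n_sub
        if (extra > 0) alloc[seq_len(extra)] <- alloc[seq_len(extra)] + 1L
        ancestor <- sample(aa_alphabet(), cfg$seq_length, replace = TRUE)
        mi <- 0L
        for (u in seq_len(n_sub)) {
          sub_anc <- mutate_sites(ancestor, p1)
          for (m in seq_len(alloc[u])) {
            mi <- mi + 1L
            member <- mutate_sites(sub_anc, p2)
            if (cfg$gap_rate > 0 && length(hotspots) > 0) {
              gap <- hotspots[runif(length(hotspots)) < cfg$gap_rate]
              member[gap] <- "-"
            }
            seq_rows[[length(seq_rows) + 1L]] <- tibble(
              seq_id = sprintf("s%02d_f%02d_m%03d", si, fi, mi),
              structure_id = structure_id,
              family_id = family_id,
              subfamily_id = sprintf("%s/sub%d", family_id, u),
              function_id = sub_funs[u],
              residues = paste(member, collapse = ""))
          }
        }
        fam_rows[[length(fam_rows) + 1L]] <- tibble(
          family_id = family_id,
          structure_id = structure_id,
          n_members = n_members,
          n_subfamilies = n_sub,
          functions = list(sort(unique(sub_funs))),
          monofunctional = length(unique(sub_funs)) == 1L,
          planted = planted)
      }
    }

    seqs <- bind_rows(seq_rows)
    fams <- bind_rows(fam_rows)
    funs <- seqs |>
      distinct(function_id, structure_id) |>
      group_by(function_id) |>
      summarise(structures = list(sort(structure_id)),
                n_structures = n(), .groups = "drop") |>
      mutate(planted = function_id %in% planted_label)

    dataset <- as_dataset(seqs[, c("seq_id", "structure_id",
                                   "function_id", "residues")])
    truth <- list(
      sequences = seqs[, c("seq_id", "structure_id", "family_id",
                           "subfamily_id", "function_id")],
      families = fams,
      functions = funs,
      params = list(p_site_subfamily = p2,
                    p_site_family_branch = p1,
                    expected_intra_subfamily =
                      expected_pairwise_divergence(p2),
                    expected_intra_family =
                      expected_pairwise_divergence(combine_chain(p1, p2)),
                    expected_inter_family = 95,
                    planted_function = planted_label))
    list(dataset = dataset, truth = truth, config = cfg)
  })
}

#' Preset generator configurations emulating the study's data shapes
#'
#' * `"tiny"`: at most 12 sequences over 2 structures; the testbed for
#'   exhaustive brute-force cross-checks.
#' * `"tim_like"`: one structure with many families of mixed mono- and
#'   multifunctionality, emulating a TIM-barrel-like superfamily; the
#'   testbed for neighborhood-diversity patterns and the
#'   monofunctional-family control.
#' * `"multi_structure"`: six structures of about a thousand sequences
#'   in total with one function planted across four structures; the
#'   testbed for promiscuity recovery and family clustering.
#'
#' @param preset One of `"tiny"`, `"tim_like"`, `"multi_structure"`.
#' @param seed RNG seed stored in the config.
#' @return A [generator_config()].
#' @export
emulate_paper_shape <- function(preset = c("tiny", "tim_like",
                                           "multi_structure"),
                                seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    tiny = generator_config(
      n_structures = 2L, families_per_structure = 2L,
      seqs_per_family = 3L, subfamilies_per_family = c(1L, 2L),
      seq_length = 50L, intra_family_divergence = 30,
      intra_subfamily_divergence = 10, inter_family_divergence = 90,
      p_multifunctional = 0.5, n_functions_pool = 10L,
      p_promiscuous = 0.2, rng_seed = seed),
    tim_like = generator_config(
      n_structures = 1L, families_per_structure = 16L,
      seqs_per_family = list(poisson = 40), subfamilies_per_family = c(2L, 3L),
      seq_length = 100L, intra_family_divergence = 55,
      intra_subfamily_divergence = 15, inter_family_divergence = 90,
      p_multifunctional = 0.4, n_functions_pool = 60L,
      p_promiscuous = 0, rng_seed = seed),
    multi_structure = generator_config(
      n_structures = 6L, families_per_structure = 6L,
      seqs_per_family = list(poisson = 30), subfamilies_per_family = c(1L, 3L),
      seq_length = 100L, intra_family_divergence = 55,
      intra_subfamily_divergence = 15, inter_family_divergence = 90,
      p_multifunctional = 0.25, n_functions_pool = 150L,
      p_promiscuous = 0.05, plant_promiscuous_k = 4L,
      rng_seed = seed))
}
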