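#' Configuration for a full analysis run
#'
#' @param out_dir Output directory for the report bundle.
#' @param alignments_dir Directory of per-structure aligned FASTA files
#'   (named `<structure_id>.fasta`); may be `NULL` when a dataset is
#'   passed directly to [run_full_analysis()].
#' @param annotations_path Path to the annotation TSV; may be `NULL`
#'   with an in-memory dataset.
#' @param ec_level EC level for all function statistics (default 4).
#' @param radii Neighborhood radii in percent (default `c(1, 2, 5, 10,
#'   20)`).
#' @param bin_width Distance bin width in percent (default 5).
#' @param pairs `"all"` for exhaustive pair enumeration or an integer
#'   number of random pairs per analysis.
#' @param family_threshold Family clustering distance threshold
#'   (default 70).
#' @param filter A [filter_config()]; also supplies `section_length`
#'   and `n_resamples` for the cross-structure analysis.
#' @param seed Master seed for pair sampling.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       alignments_dir = NULL,
                       annotations_path = NULL,
                       ec_level = 4L,
                       radii = c(1, 2, 5, 10, 20),
                       bin_width = 5,
                       pairs = "all",
                       family_threshold = 70,
                       filter = filter_config(),
                       seed = 1L) {
  structure(list(out_dir = out_dir,
                 alignments_dir = alignments_dir,
                 annotations_path = annotations_path,
                 ec_level = as.integer(ec_level),
                 radii = radii,
                 bin_width = bin_width,
                 pairs = pairs,
                 family_threshold = family_threshold,
                 filter = filter,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised top-level keys mirror the arguments of [run_config()];
#' keys under `filter:` mirror [filter_config()].
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  fc <- do.call(filter_config, y$filter %||% list())
  y$filter <- NULL
  y <- y[intersect(names(y), setdiff(names(formals(run_config)), "filter"))]
  do.call(run_config, c(y, list(filter = fc)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Stage '", stage, "' failed: ", conditionMessage(e)),
          class = "genospace_stage_error")
  })
}

empty_grid_tbl <- function() {
  tibble(d_bin_lo = numeric(), d_bin_hi = numeric(), r = numeric(),
         mean_fu = numeric(), n_pairs = integer(), se = numeric(),
         non_overlapping = logical())
}

flatten_promiscuity <- function(tbl) {
  as_tibble(tbl)[, c("function_label", "n_sequences", "n_structures",
                     "H", "R_F")]
}

flatten_versatility <- function(tbl) {
  as_tibble(tbl)[, c("structure_id", "n_sequences", "n_functions",
                     "H", "V_S")]
}

#' Run the full genotype-space analysis and write a report bundle
#'
#' Executes, in order: input loading, the filter funnel, within-
#' structure pairwise distances, promiscuity and versatility tables,
#' family clustering, the per-structure exhaustive neighborhood
#' analysis, and the cross-structure neighborhood analysis on
#' equal-length resampled windows summarised across resamples.  Every
#' table is written as a TSV with a header line into `cfg$out_dir`,
#' along with `funnel.tsv` (stage-wise sequence counts, conserved:
#' input = output + drops) and a machine-readable `manifest.yaml`
#' recording inputs, parameters, seeds, drop counters and output
#' files.  Any stage error aborts with the stage name.
#'
#' @param cfg A [run_config()].
#' @param dataset Optional in-memory `genospace_dataset`; when `NULL`,
#'   inputs are read from `cfg$alignments_dir` and
#'   `cfg$annotations_path`.
#' @return Invisibly, a list with the computed objects (`dataset`,
#'   `funnel`, `distances`, `promiscuity`, `versatility`, `families`,
#'   `grid_within`, `grid_resampled`) and the manifest.
#' @export
run_full_analysis <- function(cfg, dataset = NULL) {
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)

  ds <- run_stage("load", {
    if (is.null(dataset)) {
      if (is.null(cfg$alignments_dir) || is.null(cfg$annotations_path)) {
        abort("Either a dataset or alignments_dir + annotations_path is required.")
      }
      fastas <- sort(list.files(cfg$alignments_dir, pattern = "\\.fasta$",
                                full.names = TRUE))
      if (length(fastas) == 0) abort(paste0("No .fasta files in ",
                                            cfg$alignments_dir))
      aln <- bind_rows(lapply(fastas, function(f) {
        read_alignment_fasta(f, sub("\\.fasta$", "", basename(f)))
      }))
      build_dataset(aln, read_annotation_table(cfg$annotations_path))
    } else {
      as_dataset(dataset)
    }
  })

  filtered <- run_stage("filter", filter_dataset(ds, cfg$filter))
  funnel <- attr(filtered, "funnel")

  dists <- run_stage("distances",
                     all_pairwise_distances(filtered,
                                            within_structure_only = TRUE))
  n_undef_dist <- attr(dists, "n_undefined_dropped") %||% 0L

  prom <- run_stage("promiscuity",
                    structural_promiscuity(filtered, cfg$ec_level))
  vers <- run_stage("versatility",
                    functional_versatility(filtered, cfg$ec_level))

  fams <- run_stage("families",
                    cluster_families(filtered, dists = dists,
                                     threshold = cfg$family_threshold))

  pick_pairs <- function(ids, seed) {
    if (identical(cfg$pairs, "all")) sample_pairs(ids, Inf)
    else sample_pairs(ids, cfg$pairs, seed = seed)
  }

  n_undef_fu <- 0L
  grid_within <- run_stage("neighborhoods_within", {
    if (nrow(dists) == 0) empty_grid_tbl() else {
      ids <- sort(unique(c(dists$seq_id_a, dists$seq_id_b)))
      rec <- fu_for_pairs(pick_pairs(ids, cfg$seed), dists, filtered,
                          cfg$radii, cfg$ec_level)
      n_undef_fu <- n_undef_fu + (attr(rec, "n_undefined") %||% 0L)
      if (nrow(rec) == 0) empty_grid_tbl() else
        aggregate_grid(rec, cfg$bin_width)
    }
  })

  grid_resampled <- run_stage("neighborhoods_resampled", {
    samples <- resample_sections(filtered, cfg$filter)
    grids <- list()
    for (i in seq_along(samples)) {
      s <- samples[[i]]
      if (nrow(s) < 2) next
      sd_i <- all_pairwise_distances(s, within_structure_only = FALSE)
      if (nrow(sd_i) == 0) next
      ids <- sort(unique(c(sd_i$seq_id_a, sd_i$seq_id_b)))
      rec <- fu_for_pairs(pick_pairs(ids, cfg$seed + i), sd_i, s,
                          cfg$radii, cfg$ec_level)
      n_undef_fu <- n_undef_fu + (attr(rec, "n_undefined") %||% 0L)
      if (nrow(rec) > 0) {
        grids[[length(grids) + 1L]] <- aggregate_grid(rec, cfg$bin_width)
      }
    }
    if (length(grids) == 0) {
      tibble(d_bin_lo = numeric(), d_bin_hi = numeric(), r = numeric(),
             mean_fu = numeric(), sd_fu = numeric(),
             n_samples = integer(), n_pairs_total = integer())
    } else {
      multi_sample_summary(grids)
    }
  })

  paths <- list(
    distances = "distances.tsv",
    promiscuity = "promiscuity.tsv",
    versatility = "versatility.tsv",
    families = "families.tsv",
    fu_grid_within = "fu_grid_within.tsv",
    fu_grid_resampled = "fu_grid_resampled.tsv",
    funnel = "funnel.tsv")
  paths <- lapply(paths, function(p) file.path(cfg$out_dir, p))

  run_stage("write", {
    readr::write_tsv(dists, paths$distances, progress = FALSE)
    readr::write_tsv(flatten_promiscuity(prom), paths$promiscuity,
                     progress = FALSE)
    readr::write_tsv(flatten_versatility(vers), paths$versatility,
                     progress = FALSE)
    readr::write_tsv(as_tibble(fams), paths$families, progress = FALSE)
    readr::write_tsv(as_tibble(grid_within), paths$fu_grid_within,
                     progress = FALSE)
    readr::write_tsv(as_tibble(grid_resampled), paths$fu_grid_resampled,
                     progress = FALSE)
    readr::write_tsv(funnel, paths$funnel, progress = FALSE)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("genospace")),
    inputs = list(alignments_dir = cfg$alignments_dir,
                  annotations_path = cfg$annotations_path,
                  in_memory_dataset = is.null(cfg$alignments_dir)),
    parameters = list(ec_level = cfg$ec_level, radii = cfg$radii,
                      bin_width = cfg$bin_width,
                      pairs = cfg$pairs,
                      family_threshold = cfg$family_threshold,
                      filter = unclass(cfg$filter)),
    seeds = list(pair_seed = cfg$seed,
                 resample_seed = cfg$filter$rng_seed),
    counters = list(n_input_sequences = nrow(ds),
                    n_filtered_sequences = nrow(filtered),
                    funnel = lapply(seq_len(nrow(funnel)), function(i)
                      as.list(funnel[i, ])),
                    n_undefined_distances_dropped = n_undef_dist,
                    n_undefined_fu_skipped = n_undef_fu),
    outputs = lapply(paths, basename))
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))

  invisible(list(dataset = filtered, funnel = funnel, distances = dists,
                 promiscuity = prom, versatility = vers, families = fams,
                 grid_within = grid_within,
                 grid_resampled = grid_resampled, manifest = manifest))
}
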