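#' The amino-acid alphabet used throughout the package
#'
#' The twenty standard amino acids in one-letter code.  Aligned sequences
#' may additionally contain the gap character `"-"` and the unknown-residue
#' character `"X"`.
#'
#' @return A character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

legal_residue_chars <- function() c(aa_alphabet(), "-", "X")

#' Validate EC labels
#'
#' An EC (Enzyme Commission) label is accepted only when all four levels of
#' the hierarchy carry numeric descriptors (e.g. `"4.2.1.20"`); partially
#' specified labels such as `"4.2.1.-"` are rejected.
#'
#' @param x Character vector of putative EC labels.
#' @return Logical vector, `TRUE` where the label is a complete 4-level
#'   numeric EC number.
#' @export
is_valid_ec <- function(x) {
  !is.na(x) & grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$", x)
}

#' Truncate an EC label to a hierarchy level
#'
#' The EC classification has four hierarchical levels (class, subclass,
#' sub-subclass, serial number).  Coarser analyses equate functions by a
#' prefix of the label: at level 1 `"4.2.1.20"` becomes `"4"` (a lyase),
#' at level 2 `"4.2"`, and so on.  Level 4 is the identity.
#'
#' @param function_id Character vector of 4-level EC labels.
#' @param level Integer in 1..4: how many leading fields to keep.
#' @return Character vector of truncated labels.
#' @examples
#' function_at_level("4.2.1.20", 1)
#' function_at_level(c("2.7.7.7", "1.1.1.1"), 2)
#' @export
function_at_level <- function(function_id, level) {
  if (length(level) != 1L || !level %in% 1:4) {
    abort("`level` must be a single integer in 1, 2, 3, 4.")
  }
  bad <- !is_valid_ec(function_id)
  if (any(bad)) {
    abort(paste0("Invalid EC label(s): ",
                 paste(unique(function_id[bad]), collapse = ", "),
                 ". All four levels must be numeric."))
  }
  if (level == 4L) return(function_id)
  vapply(strsplit(function_id, ".", fixed = TRUE),
         function(p) paste(p[seq_len(level)], collapse = "."),
         character(1))
}

check_residues <- function(seq_id, residues) {
  chars <- unique(unlist(strsplit(residues, "", fixed = TRUE)))
  bad <- setdiff(chars, legal_residue_chars())
  if (length(bad) > 0) {
    offender <- seq_id[vapply(strsplit(residues, "", fixed = TRUE),
                              function(x) any(x %in% bad), logical(1))][1]
    abort(paste0("Illegal residue character(s) ",
                 paste0("'", bad, "'", collapse = ", "),
                 " (first offending record: '", offender, "'). ",
                 "Allowed: 20 amino acids, '-', 'X'."))
  }
  invisible(TRUE)
}

#' Read one aligned FASTA file as a structure alignment
#'
#' Reads an aligned (equal-width) amino-acid FASTA file and returns its
#' records as a tibble, one row per sequence.  The first whitespace-
#' delimited token of each header becomes the sequence identifier.
#'
#' @param path Path to an aligned FASTA file.
#' @param structure_id Structure label (e.g. a CATH-style dotted
#'   homologous-superfamily identifier) attached to every record.
#' @return A tibble with columns `seq_id`, `structure_id`, `residues`,
#'   in file order.
#' @export
read_alignment_fasta <- function(path, structure_id) {
  aln <- Biostrings::readAAStringSet(path)
  if (length(aln) == 0) {
    abort(paste0("Empty alignment file: ", path))
  }
  w <- Biostrings::width(aln)
  if (length(unique(w)) != 1L) {
    off <- names(aln)[which(w != w[1])[1]]
    abort(paste0("Not an alignment: record '", off, "' in ", path,
                 " has length ", w[which(w != w[1])[1]],
                 " but the first record has length ", w[1], "."))
  }
  ids <- sub("\\s.*$", "", names(aln))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate FASTA header(s) in ", path, ": ",
                 paste(unique(dup), collapse = ", ")))
  }
  residues <- as.character(aln)
  check_residues(ids, residues)
  tibble(seq_id = ids,
         structure_id = structure_id,
         residues = unname(residues))
}

#' Write one structure alignment as aligned FASTA
#'
#' @param alignment A data frame with columns `seq_id` and `residues`
#'   (one structure's aligned rows).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(alignment, path) {
  x <- Biostrings::AAStringSet(setNames(alignment$residues,
                                        alignment$seq_id))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a sequence annotation table
#'
#' The annotation table is tab-separated with three columns `seq_id`,
#' `structure_id`, `function_id`; lines starting with `#` are comments and
#' an optional header row naming the three columns is recognised.  Rows
#' whose function label is not a complete 4-level numeric EC number are
#' dropped; the number of dropped rows is reported in the
#' `"n_dropped_incomplete_ec"` attribute and via a message.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `seq_id`, `structure_id`, `function_id`.
#' @export
read_annotation_table <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) abort(paste0("Empty annotation table: ", path))
  if (ncol(raw) < 3) {
    abort(paste0("Annotation table ", path,
                 " needs 3 tab-separated columns: seq_id, structure_id, function_id."))
  }
  raw <- raw[, 1:3]
  names(raw) <- c("seq_id", "structure_id", "function_id")
  if (identical(unname(unlist(raw[1, ])),
                c("seq_id", "structure_id", "function_id"))) {
    raw <- raw[-1, ]
  }
  raw <- distinct(raw)
  conflict <- raw$seq_id[duplicated(raw$seq_id)]
  if (length(conflict) > 0) {
    abort(paste0("Conflicting annotation rows for seq_id(s): ",
                 paste(unique(conflict), collapse = ", ")))
  }
  keep <- is_valid_ec(raw$function_id)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(paste0("Dropped ", n_dropped,
                  " annotation row(s) without a complete 4-level EC label."))
  }
  out <- raw[keep, ]
  attr(out, "n_dropped_incomplete_ec") <- n_dropped
  out
}

#' Write an annotation table
#'
#' @param annotations Data frame with columns `seq_id`, `structure_id`,
#'   `function_id`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  readr::write_tsv(annotations[, c("seq_id", "structure_id", "function_id")],
                   path, progress = FALSE)
  invisible(path)
}

# Check the minimal annotation contract shared by the statistics functions:
# any data frame carrying seq_id / structure_id / function_id qualifies.
validate_annotations <- function(data, require_residues = FALSE) {
  need <- c("seq_id", "structure_id", "function_id")
  if (require_residues) need <- c(need, "residues")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  as_tibble(data)
}

#' Assemble an annotated, aligned sequence dataset
#'
#' Joins one or more structure alignments (rows of `seq_id`,
#' `structure_id`, `residues`, e.g. from [read_alignment_fasta()]) with an
#' annotation table and validates the result: sequence identifiers must be
#' unique across the whole dataset, all rows of one structure must have
#' equal alignment width, residues must come from the declared alphabet,
#' and every function label must be a complete 4-level EC number.
#' Sequences without an annotation row are dropped and counted in the
#' `"n_unannotated"` attribute.
#'
#' @param alignments A data frame of aligned rows (`seq_id`,
#'   `structure_id`, `residues`) or a list of such data frames.
#' @param annotations A data frame with `seq_id`, `structure_id`,
#'   `function_id` (structure labels must agree with the alignments).
#' @return A `genospace_dataset` tibble with columns `seq_id`,
#'   `structure_id`, `function_id`, `residues`.
#' @export
build_dataset <- function(alignments, annotations) {
  if (is.data.frame(alignments)) alignments <- list(alignments)
  aln <- bind_rows(alignments)
  annotations <- validate_annotations(annotations)
  merged <- dplyr::inner_join(aln[, c("seq_id", "structure_id", "residues")],
                              annotations[, c("seq_id", "structure_id", "function_id")],
                              by = c("seq_id", "structure_id"))
  # a seq present in the alignment but absent (or mislabelled) in the table
  n_unannotated <- nrow(aln) - nrow(merged)
  out <- as_dataset(merged[, c("seq_id", "structure_id", "function_id", "residues")])
  attr(out, "n_unannotated") <- n_unannotated
  out
}

#' Validate a data frame as a genospace dataset
#'
#' @param data Data frame with columns `seq_id`, `structure_id`,
#'   `function_id`, `residues`.
#' @return The validated `genospace_dataset` tibble.
#' @export
as_dataset <- function(data) {
  data <- validate_annotations(data, require_residues = TRUE)
  dup <- data$seq_id[duplicated(data$seq_id)]
  if (length(dup) > 0) {
    abort(paste0("seq_id not unique across the dataset: ",
                 paste(unique(dup), collapse = ", ")))
  }
  widths <- nchar(data$residues)
  by_struct <- tapply(widths, data$structure_id, function(w) length(unique(w)))
  if (any(by_struct > 1)) {
    bad <- names(by_struct)[by_struct > 1][1]
    abort(paste0("Unequal alignment widths within structure '", bad, "'."))
  }
  if (any(widths == 0)) abort("Empty residue string(s) in dataset.")
  check_residues(data$seq_id, data$residues)
  bad_ec <- !is_valid_ec(data$function_id)
  if (any(bad_ec)) {
    abort(paste0("Invalid EC label(s) in dataset: ",
                 paste(unique(data$function_id[bad_ec]), collapse = ", ")))
  }
  class(data) <- c("genospace_dataset", class(tibble()))
  data
}

#' Alignment widths per structure
#'
#' @param data A dataset (or any data frame with `structure_id` and
#'   `residues`).
#' @return A tibble with `structure_id`, `n_columns`, `n_sequences`.
#' @export
alignment_widths <- function(data) {
  data |>
    group_by(structure_id) |>
    summarise(n_columns = nchar(residues[1]), n_sequences = n(),
              .groups = "drop")
}

#' Write a dataset as per-structure FASTA files plus an annotation table
#'
#' Inverse of [read_dataset()]: each structure's alignment is written to
#' `<structure_id>.fasta` inside `dir`, and all annotations to
#' `annotations.tsv`.
#'
#' @param data A `genospace_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  data <- as_dataset(data)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (sid in sort(unique(data$structure_id))) {
    write_alignment_fasta(data[data$structure_id == sid, ],
                          file.path(dir, paste0(sid, ".fasta")))
  }
  write_annotation_table(data, file.path(dir, "annotations.tsv"))
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `<structure_id>.fasta` files and
#'   `annotations.tsv`.
#' @return A `genospace_dataset` tibble.
#' @export
read_dataset <- function(dir) {
  anno_path <- file.path(dir, "annotations.tsv")
  if (!file.exists(anno_path)) {
    abort(paste0("No annotations.tsv in ", dir))
  }
  fastas <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  if (length(fastas) == 0) abort(paste0("No .fasta files in ", dir))
  aln <- bind_rows(lapply(fastas, function(f) {
    read_alignment_fasta(f, sub("\\.fasta$", "", basename(f)))
  }))
  build_dataset(aln, read_annotation_table(anno_path))
}
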