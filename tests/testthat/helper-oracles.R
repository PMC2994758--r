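# Independent brute-force reference implementations used to cross-check
# the package's vectorised/compiled paths.  These deliberately share no
# code with the package internals: plain loops and base R only.

# per-column distance with pairwise gap deletion; X mismatches all
bf_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  mism <- 0L
  comp <- 0L
  for (k in seq_along(ca)) {
    if (ca[k] == "-" || cb[k] == "-") next
    comp <- comp + 1L
    if (ca[k] == "X" || cb[k] == "X" || ca[k] != cb[k]) mism <- mism + 1L
  }
  if (comp == 0L) return(list(d = NA_real_, n = 0L))
  list(d = 100 * mism / comp, n = comp)
}

# all unordered within-structure pairs via loops
bf_pair_table <- function(data) {
  out <- list()
  for (sid in unique(data$structure_id)) {
    p <- data[data$structure_id == sid, ]
    if (nrow(p) < 2) next
    for (i in seq_len(nrow(p) - 1)) {
      for (j in (i + 1):nrow(p)) {
        r <- bf_distance(p$residues[i], p$residues[j])
        if (is.na(r$d)) next
        out[[length(out) + 1L]] <- data.frame(
          seq_id_a = p$seq_id[i], seq_id_b = p$seq_id[j],
          d = r$d, n_compared = r$n)
      }
    }
  }
  do.call(rbind, out)
}

# promiscuity by direct enumeration; entropy written out independently
bf_promiscuity <- function(anno, level = 4) {
  trunc_ec <- function(x) {
    parts <- strsplit(x, ".", fixed = TRUE)[[1]]
    paste(parts[1:level], collapse = ".")
  }
  anno$fun <- vapply(anno$function_id, trunc_ec, character(1))
  N <- length(unique(anno$structure_id))
  funs <- sort(unique(anno$fun))
  res <- data.frame(function_label = funs, H = NA_real_, R_F = NA_real_)
  for (i in seq_along(funs)) {
    sub <- anno[anno$fun == funs[i], ]
    cnt <- table(sub$structure_id)
    f <- as.numeric(cnt) / sum(cnt)
    H <- 0
    for (p in f) if (p > 0) H <- H - p * log(p)
    res$H[i] <- H
    res$R_F[i] <- H / log(N)
  }
  res
}

# F_u records by direct neighborhood enumeration from a pair table
bf_fu_records <- function(pairs, dist_tbl, anno, radii, level = 4) {
  trunc_ec <- function(x) {
    parts <- strsplit(x, ".", fixed = TRUE)[[1]]
    paste(parts[1:level], collapse = ".")
  }
  ids <- sort(unique(c(dist_tbl$seq_id_a, dist_tbl$seq_id_b)))
  lookup <- matrix(NA_real_, length(ids), length(ids),
                   dimnames = list(ids, ids))
  for (k in seq_len(nrow(dist_tbl))) {
    lookup[dist_tbl$seq_id_a[k], dist_tbl$seq_id_b[k]] <- dist_tbl$d[k]
    lookup[dist_tbl$seq_id_b[k], dist_tbl$seq_id_a[k]] <- dist_tbl$d[k]
  }
  for (x in ids) lookup[x, x] <- 0
  dist_of <- function(x, y) lookup[x, y]
  ball_funs <- function(center, r) {
    members <- character(0)
    for (x in ids) {
      dx <- dist_of(center, x)
      if (!is.na(dx) && dx <= r) members <- c(members, x)
    }
    sort(unique(vapply(anno$function_id[anno$seq_id %in% members],
                       trunc_ec, character(1))))
  }
  out <- list()
  for (r in radii) {
    for (k in seq_len(nrow(pairs))) {
      s1 <- ball_funs(pairs$seq_id_a[k], r)
      s2 <- ball_funs(pairs$seq_id_b[k], r)
      u <- length(union(s1, s2))
      if (u == 0) next
      fu <- (length(s1) + length(s2) - 2 * length(intersect(s1, s2))) / u
      out[[length(out) + 1L]] <- data.frame(
        seq_id_a = pairs$seq_id_a[k], seq_id_b = pairs$seq_id_b[k],
        d = dist_of(pairs$seq_id_a[k], pairs$seq_id_b[k]),
        r = r, F_u = fu, n_functions_union = u)
    }
  }
  do.call(rbind, out)
}

rand_index <- function(a, b) {
  n <- length(a)
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(table(a), 2))
  sb <- sum(choose(table(b), 2))
  tot <- choose(n, 2)
  (tot + 2 * sij - sa - sb) / tot
}

# small random annotation set (no residues needed)
random_annotations <- function(n_seq, n_struct, n_fun, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      seq_id = sprintf("q%03d", seq_len(n_seq)),
      structure_id = sample(sprintf("3.20.%d.10", seq_len(n_struct)),
                            n_seq, replace = TRUE),
      function_id = sample(sprintf("1.1.1.%d", seq_len(n_fun)),
                           n_seq, replace = TRUE))
  })
}

# small random aligned dataset with residues
random_tiny_dataset <- function(seed, n_seq = 10, n_struct = 2, len = 30) {
  withr::with_seed(seed, {
    aa <- aa_alphabet()
    # first rows cover every structure so the requested count is realised
    sids <- sprintf("3.20.%d.10", seq_len(n_struct))
    tibble::tibble(
      seq_id = sprintf("q%03d", seq_len(n_seq)),
      structure_id = c(sids, sample(sids, n_seq - n_struct,
                                    replace = TRUE)),
      function_id = sample(sprintf("2.7.7.%d", 1:4), n_seq, replace = TRUE),
      residues = vapply(seq_len(n_seq), function(i) {
        x <- sample(aa, len, replace = TRUE)
        x[runif(len) < 0.05] <- "-"
        paste(x, collapse = "")
      }, character(1)))
  })
}
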