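# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (brute-force scans, hand arithmetic) and never call the code paths
# they check.

tiny_signal <- function(values, ids = sprintf("f%d", seq_len(nrow(values))),
                        timepoints = seq(24, 44, by = 4), replicates = 1,
                        value_kind = "rpkm") {
  signal_matrix(values, ids,
    timepoints = timepoints, replicates = replicates,
    value_kind = value_kind
  )
}

# one feature per row of `means`, replicated `reps` times with no noise
signal_from_means <- function(means, reps = 1, ids = sprintf("f%d", seq_len(nrow(means))),
                              value_kind = "rpkm") {
  vals <- means[, rep(seq_len(ncol(means)), each = reps), drop = FALSE]
  signal_matrix(vals, ids, replicates = reps, value_kind = value_kind)
}

write_tmp_lines <- function(lines, ext = ".txt", env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ext, .local_envir = env)
  writeLines(lines, path)
  path
}

# brute-force O(n*m) ACR classifier: plain arithmetic, no interval trees
brute_classify <- function(acrs, genes, window = 1000) {
  # gap convention: bases strictly between the TSS/TES base and the interval
  point_dist <- function(a, b, p) {
    if (p < a) a - p - 1 else if (p >= b) p - b else 0
  }
  out <- character(nrow(acrs))
  dist <- numeric(nrow(acrs))
  gene_ids <- vector("list", nrow(acrs))
  for (i in seq_len(nrow(acrs))) {
    a <- acrs$start[i]
    b <- acrs$end[i]
    dmin <- Inf
    genic <- character(0)
    near <- character(0)
    for (j in seq_len(nrow(genes))) {
      if (acrs$chrom[i] != genes$chrom[j]) next
      if (a < genes$end[j] && genes$start[j] < b) genic <- c(genic, genes$gene_id[j])
      dj <- min(
        point_dist(a, b, genes$tss[j]),
        point_dist(a, b, genes$tes[j])
      )
      if (dj <= window) near <- c(near, genes$gene_id[j])
      dmin <- min(dmin, dj)
    }
    out[i] <- if (length(genic) > 0) "gACR" else if (dmin <= window) "pACR" else "dACR"
    dist[i] <- dmin
    gene_ids[[i]] <- if (out[i] == "dACR") character(0) else sort(unique(c(genic, near)))
  }
  tibble::tibble(
    acr_id = acrs$acr_id, class = out, distance = dist,
    gene_ids = gene_ids
  )
}

brute_associate <- function(acrs, genes, window = 1000) {
  cls <- brute_classify(acrs, genes, window)
  rows <- list()
  for (i in seq_len(nrow(cls))) {
    for (g in cls$gene_ids[[i]]) {
      rows[[length(rows) + 1]] <- tibble::tibble(gene_id = g, acr_id = cls$acr_id[i])
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(gene_id = character(), acr_id = character()))
  }
  dplyr::arrange(dplyr::distinct(dplyr::bind_rows(rows)), gene_id, acr_id)
}

# random annotation not built by the package generator (independent layout)
random_annotation <- function(n_genes, n_acrs, seed, chrom_span = 500000) {
  set.seed(seed)
  gs <- sort(sample.int(chrom_span - 5000, n_genes))
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = "chrT",
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    start = gs,
    end = gs + sample(500:3000, n_genes, replace = TRUE)
  )
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$tes <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
  as_ <- sample.int(chrom_span, n_acrs)
  acrs <- tibble::tibble(
    acr_id = sprintf("a%03d", seq_len(n_acrs)),
    chrom = "chrT",
    start = as_,
    end = as_ + sample(100:400, n_acrs, replace = TRUE),
    summit = NA_integer_
  )
  list(genes = genes, acrs = acrs)
}

# squared-distance FCM objective recomputed from scratch (used with e1071)
fcm_objective_of <- function(x, centers, membership, m) {
  d2 <- outer(seq_len(nrow(x)), seq_len(nrow(centers)), function(i, c) {
    rowSums((x[i, , drop = FALSE] - centers[c, , drop = FALSE])^2)
  })
  sum(membership^m * d2)
}

two_blob_matrix <- function(seed = 1, n_per = 10, sep = 6, dims = 6, sd = 0.2) {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(n_per * dims, 0, sd), n_per),
    matrix(rnorm(n_per * dims, sep, sd), n_per)
  )
  rownames(x) <- sprintf("f%02d", seq_len(2 * n_per))
  x
}

# per-timepoint mean helper independent of compute_profiles
naive_timepoint_means <- function(vals, n_tp, reps) {
  sapply(seq_len(n_tp), function(j) {
    rowMeans(vals[, (j - 1) * reps + seq_len(reps), drop = FALSE])
  })
}
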