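# Fuzzy c-means co-clustering and the co-oscillation screening funnel.
# Genes and ACRs are clustered jointly in one z-profile space so cluster
# labels are shared; a gene-ACR pair is in the co-oscillation group (COG)
# when both are core members of the same cluster, and in the core
# co-oscillation group (CCOG) when their timepoint-mean profiles are
# additionally Spearman-synchronized.

fcm_memberships <- function(d2, m) {
  # u_ic = 1 / sum_k (d_ic / d_ik)^(1/(m-1)) on squared distances,
  # computed as normalized negative powers for stability
  eps <- 1e-12
  zero <- d2 < eps
  w <- d2^(-1 / (m - 1))
  u <- w / rowSums(w)
  any_zero <- rowSums(zero) > 0L
  if (any(any_zero)) {
    u[any_zero, ] <- zero[any_zero, , drop = FALSE] /
      rowSums(zero[any_zero, , drop = FALSE])
  }
  u
}

fcm_dist2 <- function(x, centers) {
  # squared Euclidean feature x center distances
  outer(rowSums(x^2), rep(1, nrow(centers))) - 2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
}

fcm_single <- function(x, n_clusters, m, tol, max_iter) {
  # one run from the current RNG state; centers initialized from random rows
  init <- sample(nrow(x), n_clusters)
  centers <- x[init, , drop = FALSE] +
    matrix(rnorm(n_clusters * ncol(x), 0, 1e-6), n_clusters)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d2 <- pmax(fcm_dist2(x, centers), 0)
    u <- fcm_memberships(d2, m)
    trace[it] <- sum(u^m * d2)
    um <- u^m
    new_centers <- (t(um) %*% x) / colSums(um)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) {
      converged <- TRUE
      break
    }
  }
  d2 <- pmax(fcm_dist2(x, centers), 0)
  u <- fcm_memberships(d2, m)
  list(
    centers = centers, membership = u, objective = sum(u^m * d2),
    iterations = it, converged = converged, trace = trace
  )
}

#' Fit a fuzzy c-means model to z-profiles
#'
#' Minimizes the fuzzified within-cluster sum of squares
#' `sum_i sum_c u(i,c)^m * ||x_i - v_c||^2` by alternating membership and
#' center updates, with seeded random-row initialization and multiple
#' restarts keeping the best objective. The objective is non-increasing
#' across iterations and every membership row sums to 1.
#'
#' @param profiles Tibble from [compute_profiles()] (its `z_ZT*` columns are
#'   used) or a numeric feature x dimension matrix with rownames.
#' @param n_clusters Number of clusters (>= 2, fewer than the features).
#' @param m Fuzzifier (> 1; default 1.25, a common choice for tight
#'   expression profiles).
#' @param seed Integer seed; restart r uses `seed + r - 1`.
#' @param tol Convergence tolerance on the maximum center shift.
#' @param max_iter Maximum iterations per restart.
#' @param n_restarts Number of seeded restarts.
#' @return An object of class `chrono_fcm`: list with `centers`
#'   (cluster x dimension), `membership` (feature x cluster, rows sum to
#'   1), `n_clusters`, `m`, `objective`, `iterations`, `converged`,
#'   `trace` (objective per iteration of the winning restart).
#' @export
fcm_fit <- function(profiles, n_clusters, m = 1.25, seed = 1, tol = 1e-6,
                    max_iter = 1000, n_restarts = 10) {
  x <- if (is.matrix(profiles)) profiles else profile_zmatrix(profiles)
  if (n_clusters < 2L) {
    abort("n_clusters must be >= 2", class = "chronoaccess_config_error")
  }
  if (nrow(x) <= n_clusters) {
    abort("need more features than clusters", class = "chronoaccess_config_error")
  }
  if (m <= 1) abort("fuzzifier m must be > 1", class = "chronoaccess_config_error")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    fit <- fcm_single(x, n_clusters, m, tol, max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (!best$converged) {
    warn(sprintf("fuzzy c-means did not converge within %d iterations", max_iter))
  }
  rownames(best$membership) <- rownames(x)
  colnames(best$membership) <- seq_len(n_clusters)
  rownames(best$centers) <- seq_len(n_clusters)
  colnames(best$centers) <- colnames(x)
  structure(
    list(
      centers = best$centers, membership = best$membership,
      n_clusters = n_clusters, m = m, objective = best$objective,
      iterations = best$iterations, converged = best$converged,
      trace = best$trace, seed = seed
    ),
    class = "chrono_fcm"
  )
}

#' @export
print.chrono_fcm <- function(x, ...) {
  cat(sprintf(
    "<fuzzy c-means: %d features, %d clusters, m = %g, objective = %.6g%s>\n",
    nrow(x$membership), x$n_clusters, x$m, x$objective,
    if (x$converged) "" else " (not converged)"
  ))
  invisible(x)
}

#' @export
tidy.chrono_fcm <- function(x, ...) {
  as_tibble(x$membership, rownames = "feature_id") |>
    pivot_longer(-"feature_id", names_to = "cluster", values_to = "membership") |>
    mutate(cluster = as.integer(.data$cluster))
}

#' @export
glance.chrono_fcm <- function(x, ...) {
  tibble(
    n_features = nrow(x$membership), n_clusters = x$n_clusters, m = x$m,
    objective = x$objective, iterations = x$iterations, converged = x$converged
  )
}

#' Assign features to their core cluster
#'
#' A feature is assigned to its maximum-membership cluster iff that
#' membership is at least `core_threshold` (the `min.acore` idea);
#' otherwise it stays unassigned. Ties go to the lowest cluster index.
#'
#' @param model A `chrono_fcm` fit.
#' @param core_threshold Minimum top membership for assignment (default
#'   0.3).
#' @return A tibble `feature_id`, `cluster`, `membership` for assigned
#'   features only.
#' @export
core_members <- function(model, core_threshold = 0.3) {
  u <- model$membership
  top <- max.col(u, ties.method = "first")
  top_u <- u[cbind(seq_len(nrow(u)), top)]
  keep <- top_u >= core_threshold
  tibble(
    feature_id = rownames(u)[keep],
    cluster = top[keep],
    membership = top_u[keep]
  )
}

#' Select the co-oscillation group (COG)
#'
#' A gene-ACR pair enters the COG when the ACR is associated with the gene
#' and both are core members of the same cluster. By default both feature
#' kinds come from one joint fit (shared labels); alternatively a separate
#' ACR fit can be supplied, whose cluster labels are matched to the gene
#' fit's by nearest centers.
#'
#' @param model Joint `chrono_fcm` fit over gene and ACR z-profiles (or the
#'   gene-only fit when `acr_model` is given).
#' @param associations Tibble `gene_id`, `acr_id` from [associate_acrs()].
#' @param core_threshold Minimum top membership.
#' @param acr_model Optional separate `chrono_fcm` fit of the ACR profiles.
#' @return A tibble `gene_id`, `acr_id`, `cluster` of COG pairs.
#' @export
select_cog <- function(model, associations, core_threshold = 0.3, acr_model = NULL) {
  if (nrow(associations) == 0L) {
    return(tibble(gene_id = character(), acr_id = character(), cluster = integer()))
  }
  gene_core <- core_members(model, core_threshold)
  if (is.null(acr_model)) {
    acr_core <- gene_core
  } else {
    acr_core <- core_members(acr_model, core_threshold)
    # map ACR-fit labels onto gene-fit labels via nearest centers
    d2 <- fcm_dist2(acr_model$centers, model$centers)
    label_map <- max.col(-d2, ties.method = "first")
    acr_core$cluster <- label_map[acr_core$cluster]
  }
  associations |>
    inner_join(
      rename(gene_core, gene_id = "feature_id", gene_cluster = "cluster"),
      by = "gene_id"
    ) |>
    inner_join(
      rename(acr_core, acr_id = "feature_id", acr_cluster = "cluster"),
      by = "acr_id"
    ) |>
    filter(.data$gene_cluster == .data$acr_cluster) |>
    transmute(.data$gene_id, .data$acr_id, cluster = .data$gene_cluster)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive average
#' ranks). When either vector has zero rank variance the coefficient is
#' undefined and 0 is returned, carrying attribute `undefined = TRUE`.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return The correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(structure(0, undefined = TRUE))
  }
  cor(rx, ry)
}

#' Select the core co-oscillation group (CCOG)
#'
#' Keeps COG pairs whose gene and ACR timepoint-mean profiles are
#' Spearman-correlated at or above `rho_threshold`. A gene enters the CCOG
#' when at least one of its pairs passes.
#'
#' @param cog_pairs Tibble from [select_cog()].
#' @param gene_profiles,acr_profiles Profile tibbles from
#'   [compute_profiles()] covering all pair members.
#' @param rho_threshold Minimum correlation (default 0.6).
#' @param square Threshold `rho^2` instead of `rho` (an alternative reading
#'   of an "R^2 >= 0.6" rule; off by default).
#' @return A tibble of co-oscillation records: `gene_id`, `acr_id`,
#'   `spearman_rho`, `cluster`.
#' @export
select_ccog <- function(cog_pairs, gene_profiles, acr_profiles,
                        rho_threshold = 0.6, square = FALSE) {
  if (nrow(cog_pairs) == 0L) {
    return(tibble(
      gene_id = character(), acr_id = character(),
      spearman_rho = numeric(), cluster = integer()
    ))
  }
  gm <- profile_mean_matrix(gene_profiles)
  am <- profile_mean_matrix(acr_profiles)
  missing <- setdiff(
    c(unique(cog_pairs$gene_id), unique(cog_pairs$acr_id)),
    c(rownames(gm), rownames(am))
  )
  if (length(missing) > 0L) {
    abort(sprintf("no profile for pair member '%s'", missing[1]),
      class = "chronoaccess_validation_error"
    )
  }
  rho <- map_dbl(seq_len(nrow(cog_pairs)), function(i) {
    as.numeric(spearman_rho(gm[cog_pairs$gene_id[i], ], am[cog_pairs$acr_id[i], ]))
  })
  stat <- if (square) rho^2 * sign(rho) else rho
  cog_pairs |>
    mutate(spearman_rho = rho) |>
    filter(stat >= rho_threshold) |>
    select("gene_id", "acr_id", "spearman_rho", "cluster")
}

#' Partition CCOG genes into phase-ordered clusters
#'
#' Refits fuzzy c-means on the CCOG genes' z-profiles, assigns every gene
#' to its maximum-membership cluster, computes each cluster's peak time as
#' the grid argmax of the mean member z-profile, classifies clusters as
#' subjective-light (peak in the first half of the grid) or subjective-dark
#' (second half), and renumbers clusters by ascending peak time so light
#' clusters come first.
#'
#' @param ccog Records from [select_ccog()].
#' @param gene_profiles Profile tibble covering the CCOG genes.
#' @param n_clusters Number of clusters (default 11).
#' @param seed,m,n_restarts Passed to [fcm_fit()].
#' @param light_zt ZT hours classified as subjective light (default
#'   24, 28, 32).
#' @return An object of class `chrono_partition`: list with `model`
#'   (`chrono_fcm`), `genes` (tibble `gene_id`, `cluster`, `membership`,
#'   `peak_zt`, `phase_class`), `clusters` (tibble `cluster`, `peak_zt`,
#'   `phase_class`, `n_genes`), and `records` (the CCOG records annotated
#'   with their gene's cluster).
#' @export
partition_ccog <- function(ccog, gene_profiles, n_clusters = 11, seed = 1,
                           m = 1.25, n_restarts = 10, light_zt = c(24, 28, 32)) {
  gene_ids <- unique(ccog$gene_id)
  if (length(gene_ids) <= n_clusters) {
    abort("need more CCOG genes than clusters", class = "chronoaccess_config_error")
  }
  prof <- filter(gene_profiles, .data$feature_id %in% gene_ids)
  z <- profile_zmatrix(prof)
  fit <- fcm_fit(z,
    n_clusters = n_clusters, m = m, seed = seed,
    n_restarts = n_restarts
  )
  assign <- core_members(fit, core_threshold = 0)
  tps <- as.numeric(sub("^z_ZT", "", grep("^z_ZT", names(prof), value = TRUE)))
  cluster_means <- sapply(seq_len(n_clusters), function(c) {
    members <- assign$feature_id[assign$cluster == c]
    if (length(members) == 0L) {
      fit$centers[c, ]
    } else {
      colMeans(z[members, , drop = FALSE])
    }
  })
  peak_zt <- tps[apply(cluster_means, 2L, which.max)]
  phase_class <- ifelse(peak_zt %in% light_zt, "light", "dark")
  # renumber ascending peak time (light first); stable tie-break by old label
  new_order <- order(peak_zt, seq_len(n_clusters))
  relabel <- match(seq_len(n_clusters), new_order)
  clusters <- tibble(
    cluster = relabel, peak_zt = peak_zt, phase_class = phase_class
  ) |> arrange(.data$cluster)
  genes <- assign |>
    transmute(
      gene_id = .data$feature_id,
      cluster = relabel[.data$cluster],
      membership = .data$membership
    ) |>
    left_join(clusters, by = "cluster")
  clusters <- clusters |>
    left_join(count(genes, .data$cluster, name = "n_genes"), by = "cluster") |>
    mutate(n_genes = ifelse(is.na(.data$n_genes), 0L, .data$n_genes))
  records <- ccog |>
    select(-dplyr::any_of("cluster")) |>
    left_join(genes, by = "gene_id") |>
    rename(cluster_label = "cluster")
  structure(
    list(model = fit, genes = genes, clusters = clusters, records = records),
    class = "chrono_partition"
  )
}

#' @export
print.chrono_partition <- function(x, ...) {
  cat(sprintf(
    "<phase partition: %d genes in %d clusters (%d light, %d dark)>\n",
    nrow(x$genes), nrow(x$clusters),
    sum(x$clusters$phase_class == "light"), sum(x$clusters$phase_class == "dark")
  ))
  print(x$clusters)
  invisible(x)
}

#' @export
tidy.chrono_partition <- function(x, ...) x$genes

#' @export
glance.chrono_partition <- function(x, ...) {
  tibble(
    n_genes = nrow(x$genes), n_clusters = nrow(x$clusters),
    n_light = sum(x$clusters$phase_class == "light"),
    n_dark = sum(x$clusters$phase_class == "dark"),
    objective = x$model$objective
  )
}

#' Summarize the screening funnel
#'
#' Computes each stage's share of its base, rounded half-up to one decimal
#' percent, the convention used when reporting funnel percentages.
#'
#' @param stage_counts Tibble with columns `stage`, `count`, `base`
#'   (non-negative integers, `count <= base`, `base > 0`).
#' @return The input with a `percent` column added.
#' @export
funnel_summary <- function(stage_counts) {
  stopifnot(all(c("stage", "count", "base") %in% names(stage_counts)))
  if (any(stage_counts$base <= 0)) {
    abort("funnel base counts must be positive", class = "chronoaccess_validation_error")
  }
  if (any(stage_counts$count < 0 | stage_counts$count > stage_counts$base)) {
    abort("stage counts must lie in [0, base]", class = "chronoaccess_validation_error")
  }
  mutate(stage_counts, percent = round_half_up(100 * .data$count / .data$base, 1))
}
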