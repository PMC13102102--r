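test_that("well-separated blobs get near-crisp memberships", {
  x <- two_blob_matrix()
  fit <- fcm_fit(x, n_clusters = 2, m = 2, seed = 1)
  top <- apply(fit$membership, 1, max)
  expect_true(all(top > 0.99))
  expect_true(all(abs(rowSums(fit$membership) - 1) < 1e-9))
  blob <- rep(1:2, each = 10)
  assign <- max.col(fit$membership)
  expect_true(length(unique(assign[blob == 1])) == 1)
  expect_true(length(unique(assign[blob == 2])) == 1)
  expect_false(assign[1] == assign[11])
})

test_that("a feature equidistant from both centers splits membership 0.5/0.5", {
  x <- two_blob_matrix(seed = 2, sd = 0) # two point-masses at 0 and 6
  mid <- matrix(3, 1, 6, dimnames = list("mid", NULL))
  fit <- fcm_fit(rbind(x, mid), n_clusters = 2, m = 2, seed = 1)
  u_mid <- fit$membership["mid", ]
  expect_equal(unname(u_mid[1]), 0.5, tolerance = 1e-6)
})

test_that("FCM objective is non-increasing and membership rows stay normalized", {
  x <- two_blob_matrix(seed = 3, sd = 1.5)
  fit <- fcm_fit(x, n_clusters = 3, m = 1.5, seed = 5, n_restarts = 3)
  expect_true(all(diff(fit$trace) <= 1e-10)) # monotone descent, every iteration
  # normalization holds for arbitrary distance matrices, not just at the end
  set.seed(8)
  for (i in 1:20) {
    d2 <- matrix(runif(12 * 3, 0, 5), 12)
    d2[sample(36, 2)] <- 0 # coincident feature/center case
    u <- chronoaccess:::fcm_memberships(d2, m = 1.7)
    expect_true(all(abs(rowSums(u) - 1) < 1e-9))
    expect_true(all(u >= 0 & u <= 1))
  }
})

test_that("FCM reaches the multi-restart brute-force optimum on a 12-point instance", {
  skip_if_not_installed("e1071")
  set.seed(42)
  x <- rbind(
    matrix(rnorm(24, 0, 1), 4),
    matrix(rnorm(24, 4, 1), 4),
    matrix(rnorm(24, 8, 1), 4)
  )[, 1:3]
  rownames(x) <- sprintf("p%02d", 1:12)
  fit <- fcm_fit(x, n_clusters = 2, m = 2, seed = 1)
  best <- Inf
  for (i in 1:500) {
    set.seed(10000 + i)
    cm <- e1071::cmeans(x, 2, m = 2, iter.max = 1000)
    best <- min(best, fcm_objective_of(x, cm$centers, cm$membership, m = 2))
  }
  expect_lt(fit$objective, best + 1e-6)
})

test_that("core membership assignment honors the threshold and ties", {
  model <- structure(
    list(
      membership = matrix(
        c(
          0.8, 0.2,
          0.5, 0.5, # tie -> lowest index
          0.25, 0.75
        ),
        ncol = 2, byrow = TRUE,
        dimnames = list(c("a", "b", "c"), NULL)
      ),
      n_clusters = 2
    ),
    class = "chrono_fcm"
  )
  cm <- core_members(model, 0.3)
  expect_equal(cm$cluster[cm$feature_id == "a"], 1L)
  expect_equal(cm$cluster[cm$feature_id == "b"], 1L)

  flat <- structure(
    list(membership = matrix(0.25, 1, 4, dimnames = list("x", NULL))),
    class = "chrono_fcm"
  )
  expect_equal(nrow(core_members(flat, 0.3)), 0L) # below core -> unassigned
  expect_equal(nrow(core_members(flat, 0)), 1L) # degenerate threshold assigns all
})

test_that("spearman_rho matches the rank-Pearson definition and stats::cor", {
  expect_equal(spearman_rho(1:6, c(2, 4, 6, 8, 10, 12)), 1)
  expect_equal(spearman_rho(1:6, 6:1), -1)

  x <- c(1, 2, 2, 3, 4, 5)
  y <- c(1, 3, 2, 4, 6, 5)
  # average-rank Pearson oracle, by hand
  rx <- rank(x)
  ry <- rank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_rho(x, y), oracle, tolerance = 1e-12)
  expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"), tolerance = 1e-12)

  z <- spearman_rho(rep(1, 6), 1:6)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "undefined"))
})

test_that("COG pairs require shared core clusters; CCOG adds the rho gate", {
  # two phase groups, coupled pairs within each
  prof <- function(v, ids) {
    m <- matrix(rep(v, length(ids)), ncol = 6, byrow = TRUE)
    compute_profiles(signal_from_means(m, ids = ids))
  }
  up <- c(1, 2, 3, 4, 5, 6)
  down <- rev(up)
  gp <- dplyr::bind_rows(prof(up, c("gU")), prof(down, c("gD")))
  ap <- dplyr::bind_rows(prof(up + 0.1, c("aU")), prof(down + 0.1, c("aD")))
  joint <- dplyr::bind_rows(gp, ap)
  fit <- fcm_fit(joint, n_clusters = 2, m = 2, seed = 1)
  assoc <- tibble::tibble(
    gene_id = c("gU", "gD", "gU"),
    acr_id = c("aU", "aD", "aD")
  )
  cog <- select_cog(fit, assoc)
  expect_true(all(c("gU.aU", "gD.aD") %in% paste(cog$gene_id, cog$acr_id, sep = ".")))
  # cross-phase pair lands in different clusters -> excluded
  expect_false("gU.aD" %in% paste(cog$gene_id, cog$acr_id, sep = "."))
  expect_equal(nrow(select_cog(fit, assoc[0, ])), 0L)

  ccog <- select_ccog(cog, gp, ap)
  expect_equal(sort(ccog$gene_id), c("gD", "gU")) # identical shapes: rho = 1
  expect_true(all(ccog$spearman_rho == 1))

  # antiphase profiles would be excluded by the rho gate
  anti <- select_ccog(
    tibble::tibble(gene_id = "gU", acr_id = "aD", cluster = 1L), gp, ap
  )
  expect_equal(nrow(anti), 0L)
})

test_that("kept CCOG count is non-increasing in the rho threshold", {
  sim <- simulate_study(n_genes = 80, n_acrs = 120, noise_sd = 2, seed = 61)
  gp <- compute_profiles(sim$gene_signal)
  ap <- compute_profiles(sim$acr_signal)
  assoc <- associate_acrs(sim$acrs, sim$genes)
  joint <- dplyr::bind_rows(gp, ap)
  fit <- fcm_fit(joint, n_clusters = 6, seed = 2, n_restarts = 3)
  cog <- select_cog(fit, assoc)
  kept <- vapply(
    c(0, 0.3, 0.6, 0.9),
    function(t) nrow(select_ccog(cog, gp, ap, rho_threshold = t)),
    numeric(1)
  )
  expect_true(all(diff(kept) <= 0))
})

test_that("phase partition orders clusters by peak time and classifies light/dark", {
  sim <- simulate_study(n_genes = 150, n_acrs = 220, seed = 71)
  gp <- compute_profiles(sim$gene_signal)
  ap <- compute_profiles(sim$acr_signal)
  assoc <- associate_acrs(sim$acrs, sim$genes)
  joint <- dplyr::bind_rows(
    dplyr::filter(gp, feature_id %in% sim$truth$feature_id[sim$truth$oscillating & sim$truth$type == "gene"]),
    dplyr::filter(ap, feature_id %in% sim$truth$feature_id[sim$truth$oscillating & sim$truth$type == "acr"])
  )
  fit <- fcm_fit(joint, n_clusters = 6, seed = 3, n_restarts = 3)
  cog <- select_cog(fit, assoc)
  ccog <- select_ccog(cog, gp, ap)
  part <- partition_ccog(ccog, gp, n_clusters = 6, seed = 4, n_restarts = 3)
  expect_true(all(diff(part$clusters$peak_zt) >= 0)) # renumbered by ascending peak
  expect_equal(
    part$clusters$phase_class,
    ifelse(part$clusters$peak_zt %in% c(24, 28, 32), "light", "dark")
  )
  # containment: CCOG genes are COG genes are fluctuating genes
  expect_true(all(ccog$gene_id %in% cog$gene_id))
  expect_true(all(cog$gene_id %in% joint$feature_id))
})

test_that("funnel percentages use one-decimal round-half-up", {
  f <- funnel_summary(tibble::tibble(
    stage = c("genebody", "synchronous", "zero"),
    count = c(5581, 4056, 0),
    base = c(35737, 24620, 100)
  ))
  expect_equal(f$percent, c(15.6, 16.5, 0.0))
  # round-half-up at an exact .x5 boundary
  g <- funnel_summary(tibble::tibble(stage = "h", count = 125, base = 1000))
  expect_equal(g$percent, 12.5)
  h <- funnel_summary(tibble::tibble(stage = "h", count = 145, base = 100000))
  expect_equal(h$percent, 0.1) # 0.145% -> 0.1
  expect_error(funnel_summary(tibble::tibble(stage = "x", count = 1, base = 0)),
    class = "chronoaccess_validation_error"
  )
  expect_error(funnel_summary(tibble::tibble(stage = "x", count = 5, base = 4)),
    class = "chronoaccess_validation_error"
  )
})
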