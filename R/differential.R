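# Genotype-dependent differential accessibility. A deliberately minimal
# negative-binomial Wald test with a method-of-moments common dispersion:
# the decision rule (p < alpha AND >1.5-fold in every replicate pairing,
# consistent sign) is the screening rule of interest, not any particular
# count-model machinery.

as_count_matrix <- function(x, zt = NULL) {
  if (is.matrix(x)) {
    return(x)
  }
  layout <- signal_layout(x)
  if (!is.null(zt)) {
    cols <- sprintf("ZT%d_rep%d", zt, seq_len(layout$replicates))
  } else {
    cols <- layout$columns
  }
  m <- as.matrix(as.data.frame(x)[, cols, drop = FALSE])
  rownames(m) <- x$feature_id
  m
}

#' Median-of-ratios library-size normalization
#'
#' Estimates one size factor per column as the median across features of
#' the ratio to the per-feature geometric mean (features containing a zero
#' are ignored for factor estimation), then divides each column by its
#' factor.
#'
#' @param counts Count matrix (features x columns) or a signal tibble of
#'   counts.
#' @return The normalized matrix (or signal tibble), with attribute
#'   `size_factors`.
#' @export
normalize_libraries <- function(counts) {
  m <- as_count_matrix(counts)
  if (ncol(m) < 2L) {
    abort("need >= 2 columns to normalize", class = "chronoaccess_config_error")
  }
  usable <- rowSums(m == 0) == 0L
  if (!any(usable)) {
    abort("no feature is nonzero in every column; size factors undefined",
      class = "chronoaccess_validation_error"
    )
  }
  log_geo <- rowMeans(log(m[usable, , drop = FALSE]))
  sf <- apply(m[usable, , drop = FALSE], 2L, function(col) {
    exp(median(log(col) - log_geo))
  })
  norm <- sweep(m, 2L, sf, "/")
  if (is.matrix(counts)) {
    attr(norm, "size_factors") <- sf
    return(norm)
  }
  out <- counts
  layout <- signal_layout(counts)
  out[, layout$columns] <- as.data.frame(norm)
  attr(out, "size_factors") <- sf
  out
}

#' Negative-binomial Wald test for differential accessibility
#'
#' Tests mutant vs wild type per feature with a Wald statistic on the log
#' mean ratio. The NB variance `mu + a * mu^2` uses a common dispersion
#' `a`, estimated by method of moments (mean of per-feature
#' `(pooled within-group variance - mean) / mean^2`). A feature is called
#' `induced` or `repressed` only when `p < alpha` and every per-replicate
#' fold change (replicate k of mutant over replicate k of wild type)
#' exceeds `fc_threshold` in the same direction; otherwise it is
#' `retained`. Zero denominators use pseudo-count 1 and are flagged.
#'
#' @param wt,mut Count matrices (features x replicates, same rownames) or
#'   signal tibbles; with signal tibbles, `zt` selects one time point.
#' @param zt Optional ZT hour selecting replicate columns from signal
#'   tibbles.
#' @param alpha Significance level (default 0.05).
#' @param fc_threshold Per-replicate fold-change gate (default 1.5).
#' @param dispersion Optional fixed common dispersion (skips estimation).
#' @param normalize Apply joint median-of-ratios normalization first.
#' @return A tibble with `acr_id`, `timepoint`, `base_mean_wt`,
#'   `base_mean_mut`, `log2fc`, `p_value`, `direction`
#'   (induced/repressed/retained), `per_replicate_fc` (list column),
#'   `pseudo_flag`.
#' @export
test_differential <- function(wt, mut, zt = NULL, alpha = 0.05, fc_threshold = 1.5,
                              dispersion = NULL, normalize = TRUE) {
  w <- as_count_matrix(wt, zt)
  m <- as_count_matrix(mut, zt)
  stopifnot(nrow(w) == nrow(m))
  n1 <- ncol(w)
  n2 <- ncol(m)
  if (n1 < 2L || n2 < 2L) {
    abort("need >= 2 replicates per condition", class = "chronoaccess_config_error")
  }
  if (normalize) {
    joint <- normalize_libraries(cbind(w, m))
    w <- joint[, seq_len(n1), drop = FALSE]
    m <- joint[, n1 + seq_len(n2), drop = FALSE]
  }
  mu1 <- rowMeans(w)
  mu2 <- rowMeans(m)

  if (is.null(dispersion)) {
    v1 <- apply(w, 1L, stats::var)
    v2 <- apply(m, 1L, stats::var)
    pooled <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    mu_bar <- (mu1 + mu2) / 2
    ok <- mu_bar > 0
    a_i <- (pooled[ok] - mu_bar[ok]) / mu_bar[ok]^2
    dispersion <- max(mean(a_i, na.rm = TRUE), 1e-8)
  }

  pseudo <- mu1 == 0 | mu2 == 0
  mu1p <- ifelse(pseudo, mu1 + 1, mu1)
  mu2p <- ifelse(pseudo, mu2 + 1, mu2)
  log2fc <- log2(mu2p / mu1p)
  se <- sqrt((1 / mu1p + dispersion) / n1 + (1 / mu2p + dispersion) / n2)
  z <- log(mu2p / mu1p) / se
  p <- pmin(pmax(2 * pnorm(-abs(z)), 1e-300), 1)

  k <- min(n1, n2)
  fc <- (m[, seq_len(k), drop = FALSE] + pseudo) / (w[, seq_len(k), drop = FALSE] + pseudo)
  all_up <- rowSums(fc > fc_threshold) == k
  all_dn <- rowSums(fc < 1 / fc_threshold) == k
  direction <- ifelse(p < alpha & all_up, "induced",
    ifelse(p < alpha & all_dn, "repressed", "retained")
  )

  tibble(
    acr_id = rownames(w) %||% sprintf("feature%d", seq_len(nrow(w))),
    timepoint = if (is.null(zt)) NA_real_ else zt,
    base_mean_wt = unname(mu1), base_mean_mut = unname(mu2),
    log2fc = unname(log2fc), p_value = unname(p), direction = unname(direction),
    per_replicate_fc = lapply(seq_len(nrow(fc)), function(i) unname(fc[i, ])),
    pseudo_flag = unname(pseudo),
    dispersion = dispersion
  )
}

#' Genome-average accessibility shift between genotypes
#'
#' Percent difference of the mean signal in the mutant relative to wild
#' type, over a region set (genome-wide or a subset such as the CCOG ACRs)
#' and optionally a single time point.
#'
#' @param wt,mut Signal tibbles or matrices with matching features.
#' @param regions Optional character vector of feature ids to restrict to.
#' @param zt Optional ZT hour restricting to that time point's replicate
#'   columns.
#' @return Percent shift: `100 * (mean(mut) - mean(wt)) / mean(wt)`.
#' @export
genome_average_shift <- function(wt, mut, regions = NULL, zt = NULL) {
  w <- as_count_matrix(wt, zt)
  m <- as_count_matrix(mut, zt)
  if (!is.null(regions)) {
    w <- w[rownames(w) %in% regions, , drop = FALSE]
    m <- m[rownames(m) %in% regions, , drop = FALSE]
  }
  mw <- mean(w)
  if (mw == 0) {
    abort("wild-type mean signal is zero; shift undefined",
      class = "chronoaccess_validation_error"
    )
  }
  100 * (mean(m) - mw) / mw
}
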