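# Accessibility/expression floors and the coefficient-of-variation
# fluctuation screen. All filters operate on per-timepoint means (replicates
# averaged first); CV is reported in percent using the sample sd (n - 1),
# and z-profiles use the population sd across the timepoint means, matching
# heatmap-style standardization.

round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Summarize replicated signals into per-feature profiles
#'
#' Averages replicate columns within each time point, then derives the
#' percent coefficient of variation (100 * sd / mean, sample sd) and the
#' z-scored profile (population sd across the timepoint means; all-equal
#' means give an all-zero profile and CV 0).
#'
#' @param x A signal tibble (see [signal_matrix()]).
#' @return A tibble with `feature_id`, `cv`, per-timepoint means
#'   (`mean_ZT*`) and z-scores (`z_ZT*`).
#' @export
compute_profiles <- function(x) {
  layout <- signal_layout(x)
  tps <- layout$timepoints
  if (length(unique(tps)) < 2L) {
    abort("at least 2 distinct timepoints are required",
      class = "chronoaccess_config_error"
    )
  }
  vals <- signal_values(x)
  means <- vapply(seq_along(tps), function(j) {
    cols <- (j - 1L) * layout$replicates + seq_len(layout$replicates)
    rowMeans(vals[, cols, drop = FALSE])
  }, numeric(nrow(vals)))
  if (nrow(vals) == 1L) means <- matrix(means, nrow = 1L)
  mu <- rowMeans(means)
  s <- apply(means, 1L, sd)
  cv <- ifelse(mu == 0, 0, 100 * s / mu)
  s_pop <- sqrt(rowMeans((means - mu)^2))
  z <- (means - mu) / ifelse(s_pop == 0, 1, s_pop)
  z[s_pop == 0, ] <- 0
  colnames(means) <- sprintf("mean_ZT%d", tps)
  colnames(z) <- sprintf("z_ZT%d", tps)
  bind_cols(
    tibble(feature_id = x$feature_id, cv = cv),
    as_tibble(means), as_tibble(z)
  )
}

#' Extract the z-profile matrix from a profile tibble
#'
#' @param profiles Tibble from [compute_profiles()].
#' @return Numeric matrix (features x timepoints) of z-scores, rownames =
#'   feature ids.
#' @export
profile_zmatrix <- function(profiles) {
  cols <- grep("^z_ZT", names(profiles), value = TRUE)
  m <- as.matrix(profiles[, cols, drop = FALSE])
  rownames(m) <- profiles$feature_id
  m
}

profile_mean_matrix <- function(profiles) {
  cols <- grep("^mean_ZT", names(profiles), value = TRUE)
  m <- as.matrix(profiles[, cols, drop = FALSE])
  rownames(m) <- profiles$feature_id
  m
}

new_screen_result <- function(kept_ids, removed = list(), fluctuating_ids = character(),
                              stable_ids = character(), thresholds = list()) {
  structure(
    list(
      kept_ids = kept_ids,
      removed_top_signal_ids = removed$top %||% character(),
      removed_low_ids = removed$low %||% character(),
      fluctuating_ids = fluctuating_ids,
      stable_ids = stable_ids,
      thresholds = thresholds
    ),
    class = "chrono_screen"
  )
}

#' @export
print.chrono_screen <- function(x, ...) {
  cat(sprintf(
    "<screen: %d kept (%d removed top, %d removed low; %d fluctuating / %d stable)>\n",
    length(x$kept_ids), length(x$removed_top_signal_ids),
    length(x$removed_low_ids), length(x$fluctuating_ids), length(x$stable_ids)
  ))
  thr <- x$thresholds
  if (length(thr)) {
    cat("thresholds:", paste(names(thr), unlist(thr), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.chrono_screen <- function(x, ...) {
  bind_rows(
    tibble(feature_id = x$removed_top_signal_ids, status = "removed_top_signal"),
    tibble(feature_id = x$removed_low_ids, status = "removed_low"),
    tibble(
      feature_id = setdiff(
        x$kept_ids,
        c(x$fluctuating_ids, x$stable_ids)
      ),
      status = "kept"
    ),
    tibble(feature_id = x$fluctuating_ids, status = "fluctuating"),
    tibble(feature_id = x$stable_ids, status = "stable")
  )
}

#' Apply the accessibility floors to an ACR signal matrix
#'
#' Three sequential removals on per-timepoint means: (a) features whose
#' maximum exceeds the `1 - top_fraction` quantile of maxima (the brightest
#' regions, typically saturated peaks), (b) features below `floor` at every
#' time point, (c) features whose maximum falls strictly below the
#' `percentile_floor` quantile of the surviving maxima (the realized value
#' is recorded in `thresholds` and can be re-imposed via
#' `percentile_value`).
#'
#' @param x A signal tibble of RPKM values.
#' @param top_fraction Fraction of brightest features to drop (quantile
#'   threshold).
#' @param floor Absolute per-timepoint floor (all means below it drop the
#'   feature).
#' @param percentile_floor Quantile of the surviving maxima used as a low
#'   floor; `NULL` disables step (c).
#' @param percentile_value Absolute override for step (c); when given, the
#'   quantile is not recomputed (this makes the filter idempotent on its own
#'   output).
#' @return A `chrono_screen` with kept/removed ids and realized thresholds.
#' @export
filter_accessibility <- function(x, top_fraction = 0.005, floor = 10,
                                 percentile_floor = 0.05, percentile_value = NULL) {
  profiles <- compute_profiles(x)
  means <- profile_mean_matrix(profiles)
  maxima <- apply(means, 1L, max)
  n <- length(maxima)
  if (n * top_fraction < 1) {
    warn("fewer than 1/top_fraction features; top-signal step removes the single maximum")
  }
  thr_top <- unname(quantile(maxima, 1 - top_fraction, type = 7))
  rm_top <- maxima > thr_top
  rm_floor <- apply(means < floor, 1L, all) & !rm_top
  surviving <- maxima[!rm_top & !rm_floor]
  thr_low <- if (!is.null(percentile_value)) {
    percentile_value
  } else if (!is.null(percentile_floor)) {
    unname(quantile(surviving, percentile_floor, type = 7))
  } else {
    -Inf
  }
  rm_low <- !rm_top & !rm_floor & maxima < thr_low
  ids <- profiles$feature_id
  new_screen_result(
    kept_ids = ids[!rm_top & !rm_floor & !rm_low],
    removed = list(top = ids[rm_top], low = ids[rm_floor | rm_low]),
    thresholds = list(
      top_fraction = top_fraction, top_signal_value = thr_top,
      floor = floor, percentile_floor = percentile_floor,
      percentile_value = thr_low
    )
  )
}

#' Apply the expression floor to a gene signal matrix
#'
#' Removes genes whose per-timepoint mean expression is strictly below
#' `floor` at every time point.
#'
#' @param x A signal tibble of TPM values.
#' @param floor TPM floor (default 1).
#' @return A `chrono_screen`.
#' @export
filter_expression <- function(x, floor = 1) {
  profiles <- compute_profiles(x)
  means <- profile_mean_matrix(profiles)
  rm_floor <- apply(means < floor, 1L, all)
  new_screen_result(
    kept_ids = profiles$feature_id[!rm_floor],
    removed = list(low = profiles$feature_id[rm_floor]),
    thresholds = list(floor = floor)
  )
}

#' Split features into fluctuating and stable by coefficient of variation
#'
#' In fixed mode, features with `cv >= cv_threshold` are fluctuating
#' (inclusive, so a CV exactly at the threshold fluctuates). In percentile
#' mode (`"percentile:10"`) the threshold is the given percentile of the CV
#' distribution (linear-interpolation quantile); the realized value is
#' recorded.
#'
#' @param profiles Tibble from [compute_profiles()].
#' @param cv_threshold Numeric threshold in percent, or a string
#'   `"percentile:P"`.
#' @return A `chrono_screen` with `fluctuating_ids`, `stable_ids` and the
#'   realized threshold.
#' @export
split_fluctuating <- function(profiles, cv_threshold = 13) {
  stopifnot(nrow(profiles) > 0L)
  cv <- profiles$cv
  if (is.character(cv_threshold)) {
    m <- str_match(cv_threshold, "^percentile:([0-9.]+)$")
    if (is.na(m[1, 2])) {
      abort("cv_threshold must be numeric or 'percentile:P'",
        class = "chronoaccess_config_error"
      )
    }
    thr <- unname(quantile(cv, as.numeric(m[1, 2]) / 100, type = 7))
    mode <- "percentile"
  } else {
    thr <- cv_threshold
    mode <- "fixed"
  }
  if (length(unique(cv)) == 1L) {
    warn("all CV values identical; every feature classified fluctuating")
  }
  fluct <- cv >= thr
  new_screen_result(
    kept_ids = profiles$feature_id,
    fluctuating_ids = profiles$feature_id[fluct],
    stable_ids = profiles$feature_id[!fluct],
    thresholds = list(cv_mode = mode, cv_threshold = thr)
  )
}
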