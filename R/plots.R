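# ggplot2 views of the main result types.

#' @describeIn fcm_fit Plot the cluster center profiles of a fuzzy c-means
#'   fit.
#' @param object A `chrono_fcm` fit.
#' @param ... Unused.
#' @export
autoplot.chrono_fcm <- function(object, ...) {
  centers <- as_tibble(object$centers, rownames = "cluster") |>
    pivot_longer(-"cluster", names_to = "dim", values_to = "value") |>
    mutate(
      zt = as.numeric(sub("^z_ZT", "", .data$dim)),
      cluster = factor(as.integer(.data$cluster))
    )
  ggplot(centers, aes(.data$zt, .data$value, colour = .data$cluster)) +
    geom_line() +
    geom_point(size = 1) +
    labs(x = "ZT (h)", y = "z-score", colour = "cluster") +
    theme_minimal()
}

#' @describeIn partition_ccog Plot per-cluster mean z-profiles with member
#'   spread, phase-ordered.
#' @param object A `chrono_partition`.
#' @param ... Unused.
#' @export
autoplot.chrono_partition <- function(object, ...) {
  ggplot(object$clusters, aes(.data$peak_zt, factor(.data$cluster))) +
    geom_point(aes(size = .data$n_genes, colour = .data$phase_class)) +
    scale_colour_manual(values = c(light = "#E8B93B", dark = "#3B5BA5")) +
    labs(
      x = "cluster peak ZT (h)", y = "cluster",
      size = "genes", colour = "phase"
    ) +
    theme_minimal()
}

#' Plot a screening funnel
#'
#' Horizontal bars of each stage's percent of its base.
#'
#' @param funnel Tibble from [funnel_summary()].
#' @return A ggplot.
#' @export
plot_funnel <- function(funnel) {
  funnel <- mutate(funnel, stage = factor(.data$stage, levels = rev(.data$stage)))
  ggplot(funnel, aes(.data$percent, .data$stage)) +
    geom_col(fill = "#3B5BA5") +
    geom_text(aes(label = sprintf("%s (%.1f%%)", .data$count, .data$percent)),
      hjust = -0.05, size = 3
    ) +
    xlim(0, 110) +
    labs(x = "% of stage base", y = NULL) +
    theme_minimal()
}

#' @describeIn extract_haplotypes Plot haplotype proportions stacked by
#'   group.
#' @param object A `chrono_haplotypes` object (metadata must be joined).
#' @param group_field Grouping column.
#' @param ... Unused.
#' @export
autoplot.chrono_haplotypes <- function(object, group_field = "region_group", ...) {
  freqs <- group_frequencies(object, group_field = group_field)
  ggplot(freqs, aes(.data$group, .data$proportion, fill = .data$label)) +
    geom_col() +
    labs(x = NULL, y = "proportion of homozygous accessions", fill = "haplotype") +
    theme_minimal()
}

#' Plot per-timepoint mean profiles for selected features
#'
#' @param x A signal tibble.
#' @param features Feature ids to plot (default the first 6).
#' @return A ggplot of timepoint means, one line per feature.
#' @export
plot_profiles <- function(x, features = head(x$feature_id, 6)) {
  prof <- compute_profiles(filter(x, .data$feature_id %in% features))
  prof |>
    select("feature_id", dplyr::starts_with("mean_ZT")) |>
    pivot_longer(-"feature_id", names_to = "zt", values_to = "mean") |>
    mutate(zt = as.numeric(sub("^mean_ZT", "", .data$zt))) |>
    ggplot(aes(.data$zt, .data$mean, colour = .data$feature_id)) +
    geom_line() +
    geom_point(size = 1) +
    labs(x = "ZT (h)", y = "mean signal", colour = NULL) +
    theme_minimal()
}
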