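# Classification of ACRs relative to gene models. Classes follow the usual
# genic / proximal / distal trichotomy: gACR overlaps a gene body (UTRs
# included), pACR lies within `window` bp of a TSS or TES without body
# overlap, dACR is farther than `window` from every TSS/TES. Precedence is
# gACR > pACR > dACR so the classes partition the input.

acr_granges <- function(acrs, use_summit = FALSE) {
  if (use_summit) {
    if (!"summit" %in% names(acrs) || any(is.na(acrs$summit))) {
      abort("use_summit = TRUE requires a summit for every ACR",
        class = "chronoaccess_config_error"
      )
    }
    GenomicRanges::GRanges(acrs$chrom, IRanges::IRanges(acrs$summit + 1L, width = 1L))
  } else {
    GenomicRanges::GRanges(acrs$chrom, IRanges::IRanges(acrs$start + 1L, acrs$end))
  }
}

gene_body_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
}

# TSS and TES as width-1 points, two per gene, with the gene row index carried
tss_tes_granges <- function(genes) {
  pos <- c(genes$tss, genes$tes)
  gr <- GenomicRanges::GRanges(
    rep(genes$chrom, 2L),
    IRanges::IRanges(pos + 1L, width = 1L)
  )
  S4Vectors::mcols(gr)$gene_idx <- rep(seq_len(nrow(genes)), 2L)
  gr
}

#' Classify ACRs as genic, proximal or distal
#'
#' Assigns each ACR exactly one class with precedence `gACR > pACR > dACR`:
#' `gACR` when the ACR overlaps a gene body (5'/3' UTRs included), `pACR`
#' when the nearest TSS or TES lies within `window` bp of the nearest ACR
#' edge without body overlap, and `dACR` otherwise. Distance is the gap
#' between the ACR interval and the nearest TSS/TES point (0 when the point
#' falls inside the ACR); with an empty gene set every ACR is `dACR` with
#' distance `Inf`.
#'
#' @param acrs Tibble of ACR intervals as from [read_bed()].
#' @param genes Tibble of gene models as from [read_gene_models()].
#' @param window Proximal window in bp (default 1000).
#' @param use_summit Measure from the ACR summit instead of the interval
#'   edges.
#' @return A tibble with columns `acr_id`, `class` (factor
#'   gACR/pACR/dACR), `gene_ids` (list column of associated genes, empty for
#'   dACR) and `distance` (bp to the nearest TSS/TES).
#' @export
classify_acrs <- function(acrs, genes, window = 1000, use_summit = FALSE) {
  empty_classes <- function(dist) {
    tibble(
      acr_id = acrs$acr_id,
      class = factor(rep("dACR", nrow(acrs)), levels = c("gACR", "pACR", "dACR")),
      gene_ids = rep(list(character()), nrow(acrs)),
      distance = dist
    )
  }
  if (nrow(genes) == 0L) {
    return(empty_classes(rep(Inf, nrow(acrs))))
  }
  acr_gr <- acr_granges(acrs, use_summit = use_summit)
  body_gr <- gene_body_granges(genes)
  pt_gr <- tss_tes_granges(genes)

  body_hits <- GenomicRanges::findOverlaps(acr_gr, body_gr)
  near <- suppressWarnings(GenomicRanges::distanceToNearest(acr_gr, pt_gr))
  dist <- rep(Inf, nrow(acrs))
  dist[S4Vectors::queryHits(near)] <- S4Vectors::mcols(near)$distance
  if (all(is.infinite(dist)) && nrow(acrs) > 0L) {
    warn("no ACR shares a chromosome with any gene; all classified dACR")
  }

  is_genic <- seq_len(nrow(acrs)) %in% S4Vectors::queryHits(body_hits)
  cls <- ifelse(is_genic, "gACR", ifelse(dist <= window, "pACR", "dACR"))

  # associated genes: body overlap, or TSS/TES within `window` of the ACR
  pt_win <- GenomicRanges::resize(pt_gr, width = 2L * window + 3L, fix = "center")
  win_hits <- GenomicRanges::findOverlaps(acr_gr, pt_win)
  assoc <- tibble(
    acr_idx = c(S4Vectors::queryHits(body_hits), S4Vectors::queryHits(win_hits)),
    gene_idx = c(
      S4Vectors::subjectHits(body_hits),
      S4Vectors::mcols(pt_gr)$gene_idx[S4Vectors::subjectHits(win_hits)]
    )
  ) |> distinct()
  gene_lists <- rep(list(character()), nrow(acrs))
  if (nrow(assoc) > 0L) {
    by_acr <- split(genes$gene_id[assoc$gene_idx], assoc$acr_idx)
    gene_lists[as.integer(names(by_acr))] <- lapply(by_acr, unique)
  }
  gene_lists[cls == "dACR"] <- list(character())

  tibble(
    acr_id = acrs$acr_id,
    class = factor(cls, levels = c("gACR", "pACR", "dACR")),
    gene_ids = gene_lists,
    distance = dist
  )
}

#' Associate ACRs with nearby genes
#'
#' Lists, for every gene, the ACRs that overlap its body or lie within
#' `window` bp of its TSS or TES. An ACR may be associated with several
#' genes; genes without any ACR in range are absent from the result.
#'
#' @inheritParams classify_acrs
#' @return A tibble with columns `gene_id`, `acr_id`, one row per
#'   association.
#' @export
associate_acrs <- function(acrs, genes, window = 1000) {
  if (nrow(genes) == 0L || nrow(acrs) == 0L) {
    return(tibble(gene_id = character(), acr_id = character()))
  }
  acr_gr <- acr_granges(acrs)
  body_hits <- GenomicRanges::findOverlaps(acr_gr, gene_body_granges(genes))
  pt_gr <- tss_tes_granges(genes)
  pt_win <- GenomicRanges::resize(pt_gr, width = 2L * window + 3L, fix = "center")
  win_hits <- GenomicRanges::findOverlaps(acr_gr, pt_win)
  tibble(
    gene_id = genes$gene_id[c(
      S4Vectors::subjectHits(body_hits),
      S4Vectors::mcols(pt_gr)$gene_idx[S4Vectors::subjectHits(win_hits)]
    )],
    acr_id = acrs$acr_id[c(S4Vectors::queryHits(body_hits), S4Vectors::queryHits(win_hits))]
  ) |>
    distinct() |>
    arrange(.data$gene_id, .data$acr_id)
}

#' Convert promoter-relative coordinates to genomic coordinates
#'
#' Maps a relative interval (negative = upstream of the anchor, as in
#' "-1654 to -924 bp upstream of ATG") to a 0-based half-open genomic
#' interval, strand-aware: on `-` strand genes upstream means larger
#' genomic coordinates.
#'
#' @param gene One-row tibble of a gene model.
#' @param rel_start,rel_end Relative coordinates (inclusive, `rel_start <=
#'   rel_end`); negative values lie upstream of the anchor.
#' @param anchor `"tss"` (default) or `"atg"`.
#' @param atg 0-based genomic coordinate of the translation start, required
#'   for `anchor = "atg"` unless `fallback_tss = TRUE` (then the TSS is used
#'   with a warning).
#' @param fallback_tss Fall back to the TSS when `anchor = "atg"` but no ATG
#'   coordinate is available.
#' @return One-row tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `strand`.
#' @export
relative_to_genomic <- function(gene, rel_start, rel_end, anchor = c("tss", "atg"),
                                atg = NULL, fallback_tss = TRUE) {
  anchor <- match.arg(anchor)
  stopifnot(nrow(gene) == 1L)
  if (rel_start > rel_end) {
    abort("rel_start must be <= rel_end", class = "chronoaccess_validation_error")
  }
  a <- if (anchor == "atg") {
    if (is.null(atg)) {
      if (!fallback_tss) {
        abort("anchor = 'atg' requires an atg coordinate",
          class = "chronoaccess_config_error"
        )
      }
      warn("no ATG coordinate available; anchoring relative interval at the TSS")
      gene$tss
    } else {
      atg
    }
  } else {
    gene$tss
  }
  if (gene$strand == "+") {
    start <- a + rel_start
    end <- a + rel_end + 1L
  } else {
    start <- a - rel_end
    end <- a - rel_start + 1L
  }
  tibble(chrom = gene$chrom, start = as.integer(start), end = as.integer(end), strand = gene$strand)
}
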