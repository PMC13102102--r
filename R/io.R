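# Readers and writers for the plain-text formats the pipeline touches.
# Internal coordinates are 0-based half-open everywhere; GFF's 1-based closed
# convention is converted at the boundary and never leaks inward.

#' Read ACR intervals from a BED file
#'
#' Parses a BED3+ file of accessible chromatin regions (ACRs) into a tibble.
#' Coordinates are kept 0-based half-open as in BED. When a fourth column is
#' present it is used as the ACR identifier; otherwise identifiers are
#' auto-generated as `chrom:start-end`. An optional fifth numeric column is
#' interpreted as the summit offset within the interval (bp from `start`).
#'
#' @param path Path to a BED file (tab-separated, no header).
#' @return A tibble with columns `acr_id`, `chrom`, `start`, `end`, `summit`
#'   (absolute genomic coordinate of the summit, `NA` when absent), in input
#'   order.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200", bed)
#' read_bed(bed)
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(
      acr_id = character(), chrom = character(),
      start = integer(), end = integer(), summit = integer()
    ))
  }
  fields <- str_split(lines, "\t")
  n_fields <- lengths(fields)
  bad <- which(n_fields < 3L)
  if (length(bad) > 0L) {
    abort(
      sprintf("malformed BED line %d: fewer than 3 fields", bad[1]),
      class = "chronoaccess_parse_error"
    )
  }
  chrom <- map_chr(fields, 1L)
  start <- suppressWarnings(as.integer(map_chr(fields, 2L)))
  end <- suppressWarnings(as.integer(map_chr(fields, 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    abort(
      sprintf("malformed BED line %d: non-numeric coordinates", bad[1]),
      class = "chronoaccess_parse_error"
    )
  }
  bad <- which(start >= end)
  if (length(bad) > 0L) {
    abort(
      sprintf(
        "invalid interval on BED line %d: start (%d) >= end (%d)",
        bad[1], start[bad[1]], end[bad[1]]
      ),
      class = "chronoaccess_validation_error"
    )
  }
  acr_id <- if (all(n_fields >= 4L)) {
    map_chr(fields, 4L)
  } else {
    sprintf("%s:%d-%d", chrom, start, end)
  }
  summit <- rep(NA_integer_, length(lines))
  if (all(n_fields >= 5L)) {
    off <- suppressWarnings(as.integer(map_chr(fields, 5L)))
    in_range <- !is.na(off) & off >= 0L & (start + off) < end
    summit[in_range] <- start[in_range] + off[in_range]
  }
  tibble(acr_id = acr_id, chrom = chrom, start = start, end = end, summit = summit)
}

#' Write ACR intervals to a BED file
#'
#' Inverse of [read_bed()]: writes `acr_id` as the name column and, when any
#' summit is present, the summit offset (summit − start) as a fifth column.
#'
#' @param acrs Tibble with columns `acr_id`, `chrom`, `start`, `end` and
#'   optionally `summit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(acrs, path) {
  stopifnot(all(c("acr_id", "chrom", "start", "end") %in% names(acrs)))
  lines <- sprintf("%s\t%d\t%d\t%s", acrs$chrom, acrs$start, acrs$end, acrs$acr_id)
  if ("summit" %in% names(acrs) && any(!is.na(acrs$summit))) {
    off <- ifelse(is.na(acrs$summit), ".", as.character(acrs$summit - acrs$start))
    lines <- paste(lines, off, sep = "\t")
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3/GTF
#'
#' Imports gene features and converts them to the package's 0-based half-open
#' convention with strand-aware TSS/TES assignment: on `+` the TSS is the
#' converted start, on `-` it is `end - 1`. When the annotation has no
#' features of type `gene` (some GTFs), transcript-level features are
#' collapsed to the extremal per-gene span.
#'
#' @param path Path to a GFF3 or GTF file.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open gene body) and `tss`, `tes` (0-based coordinates).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type %||% rep("gene", length(gr)))
  ids <- md$gene_id %||% md$ID %||% md$Name
  if (is.null(ids)) {
    abort("no gene_id/ID/Name attribute found in annotation",
      class = "chronoaccess_validation_error"
    )
  }
  keep <- type == "gene"
  if (!any(keep)) keep <- type %in% c("transcript", "mRNA")
  if (!any(keep)) {
    abort("annotation contains no gene or transcript features",
      class = "chronoaccess_validation_error"
    )
  }
  gr <- gr[keep]
  ids <- as.character(ids[keep])
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) {
    abort("gene feature without strand", class = "chronoaccess_validation_error")
  }
  genes <- tibble(
    gene_id = ids,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    strand = strand,
    start = BiocGenerics::start(gr) - 1L, # GFF 1-based closed -> 0-based half-open
    end = BiocGenerics::end(gr)
  ) |>
    summarise(
      chrom = .data$chrom[1], strand = .data$strand[1],
      start = min(.data$start), end = max(.data$end),
      n_strand = dplyr::n_distinct(.data$strand),
      .by = "gene_id"
    )
  if (any(genes$n_strand > 1L)) {
    abort("gene with features on both strands", class = "chronoaccess_validation_error")
  }
  type_was_gene <- any(type == "gene")
  if (type_was_gene && anyDuplicated(ids) > 0L) {
    abort(
      sprintf("duplicate gene_id: %s", ids[anyDuplicated(ids)]),
      class = "chronoaccess_validation_error"
    )
  }
  genes |>
    mutate(
      tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
      tes = ifelse(.data$strand == "+", .data$end - 1L, .data$start)
    ) |>
    select("gene_id", "chrom", "strand", "start", "end", "tss", "tes")
}

#' Write gene models to GFF3
#'
#' @param genes Tibble as returned by [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c(
    "##gff-version 3",
    sprintf(
      "%s\tchronoaccess\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      genes$chrom, genes$start + 1L, genes$end, genes$strand, genes$gene_id
    )
  )
  readr::write_lines(lines, path)
  invisible(path)
}

# --- signal matrices ---------------------------------------------------------

signal_col_names <- function(timepoints, replicates) {
  as.vector(t(outer(timepoints, seq_len(replicates),
    function(t, k) sprintf("ZT%d_rep%d", t, k)
  )))
}

new_signal_tbl <- function(df, timepoints, replicates, value_kind) {
  structure(df,
    class = c("chrono_signal", class(tibble())),
    timepoints = as.numeric(timepoints),
    replicates = as.integer(replicates),
    value_kind = value_kind
  )
}

#' Construct a signal matrix from a feature-by-column tibble or matrix
#'
#' A signal matrix holds one row per feature (ACR or gene) and one column per
#' time point x replicate, named `ZT{hour}_rep{k}`. Values are non-negative
#' RPKM, TPM or raw counts.
#'
#' @param values Numeric matrix (features x columns) or data frame of values.
#' @param feature_ids Character vector of feature identifiers.
#' @param timepoints Ordered ZT hours (default `seq(24, 44, by = 4)`).
#' @param replicates Replicates per time point.
#' @param value_kind One of `"rpkm"`, `"tpm"`, `"count"`.
#' @return A signal tibble (class `chrono_signal`) with a `feature_id` column
#'   followed by the value columns.
#' @export
signal_matrix <- function(values, feature_ids, timepoints = seq(24, 44, by = 4),
                          replicates = 3, value_kind = c("rpkm", "tpm", "count")) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  cols <- signal_col_names(timepoints, replicates)
  if (ncol(values) != length(cols)) {
    abort(
      sprintf(
        "value matrix has %d columns but the declared grid implies %d",
        ncol(values), length(cols)
      ),
      class = "chronoaccess_config_error"
    )
  }
  if (any(values < 0)) {
    abort("signal values must be non-negative", class = "chronoaccess_validation_error")
  }
  if (length(feature_ids) != nrow(values)) {
    abort("feature_ids length must match row count", class = "chronoaccess_validation_error")
  }
  colnames(values) <- cols
  df <- bind_cols(tibble(feature_id = as.character(feature_ids)), as_tibble(values))
  new_signal_tbl(df, timepoints, replicates, value_kind)
}

#' @export
print.chrono_signal <- function(x, ...) {
  cat(sprintf(
    "<signal matrix: %d features x %d timepoints x %d replicates [%s]>\n",
    nrow(x), length(attr(x, "timepoints")), attr(x, "replicates"),
    attr(x, "value_kind")
  ))
  NextMethod()
}

#' Grid metadata of a signal matrix
#'
#' @param x A signal tibble.
#' @return A list with `timepoints`, `replicates`, `value_kind` and the value
#'   `columns`.
#' @export
signal_layout <- function(x) {
  list(
    timepoints = attr(x, "timepoints"),
    replicates = attr(x, "replicates"),
    value_kind = attr(x, "value_kind"),
    columns = signal_col_names(attr(x, "timepoints"), attr(x, "replicates"))
  )
}

signal_values <- function(x) {
  layout <- signal_layout(x)
  m <- as.matrix(as.data.frame(x)[, layout$columns, drop = FALSE])
  rownames(m) <- x$feature_id
  m
}

#' Read a signal matrix from TSV
#'
#' The file must have a `feature_id` first column followed by value columns
#' named `ZT{hour}_rep{k}`; the declared grid must match the header exactly.
#'
#' @inheritParams signal_matrix
#' @param path Path to a tab-separated file.
#' @return A signal tibble.
#' @export
read_signal_matrix <- function(path, timepoints = seq(24, 44, by = 4),
                               replicates = 3, value_kind = c("rpkm", "tpm", "count")) {
  value_kind <- match.arg(value_kind)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  expected <- signal_col_names(timepoints, replicates)
  have <- setdiff(names(df), names(df)[1])
  if (!identical(sort(have), sort(expected))) {
    abort(
      sprintf(
        "header does not match declared grid: expected %d columns (%s...), found %d (%s...)",
        length(expected), expected[1], length(have), have[1] %||% "none"
      ),
      class = "chronoaccess_config_error"
    )
  }
  vals <- as.matrix(df[, expected, drop = FALSE])
  if (any(is.na(vals))) {
    abort("missing values in signal matrix", class = "chronoaccess_validation_error")
  }
  if (any(vals < 0)) {
    abort(
      sprintf("negative value for feature '%s'", df[[1]][which(rowSums(vals < 0) > 0)[1]]),
      class = "chronoaccess_validation_error"
    )
  }
  signal_matrix(vals, df[[1]],
    timepoints = timepoints, replicates = replicates,
    value_kind = value_kind
  )
}

#' Write a signal matrix to TSV
#'
#' @param x A signal tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(x, path) {
  readr::write_tsv(as_tibble(as.data.frame(x)), path, progress = FALSE)
  invisible(path)
}
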