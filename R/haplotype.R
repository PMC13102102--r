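# Cis-regulatory haplotype geography: enumerate haplotypes over the SNPs in
# an interval and stratify their frequencies by geographic group. Only
# phased or homozygous genotypes define haplotypes; unphased heterozygotes
# are excluded from labeling (the analysis concerns homozygous haplotypes)
# and tallied.

parse_region <- function(region) {
  if (is.character(region)) {
    m <- str_match(region, "^([^:]+):([0-9]+)-([0-9]+)$")
    if (is.na(m[1, 1])) {
      abort("region must be 'chrom:start-end' (0-based half-open)",
        class = "chronoaccess_config_error"
      )
    }
    list(chrom = m[1, 2], start = as.integer(m[1, 3]), end = as.integer(m[1, 4]))
  } else {
    stopifnot(all(c("chrom", "start", "end") %in% names(region)))
    as.list(region[c("chrom", "start", "end")])
  }
}

#' Extract haplotypes over the SNPs inside a cis-regulatory interval
#'
#' Reads biallelic SNPs from a VCF within a genomic region, builds a
#' two-haplotype allele string per accession from phased or homozygous
#' genotypes, labels haplotypes `H01`, `H02`, ... by descending count
#' (ties broken lexicographically by allele string), and pools haplotypes
#' below `min_frequency` of chromosomes as `"rare"`.
#'
#' @param vcf Path to a VCF file.
#' @param region Genomic interval, either `"chrom:start-end"` (0-based
#'   half-open) or a list/one-row tibble with `chrom`, `start`, `end`.
#' @param meta Optional tibble of accession metadata (must have an
#'   `accession` column) joined onto the per-accession table.
#' @param min_frequency Haplotypes rarer than this share of chromosomes are
#'   pooled as `"rare"`.
#' @return An object of class `chrono_haplotypes`: list with `snps`
#'   (tibble `pos`, `ref`, `alt`), `haplotypes` (tibble `label`,
#'   `allele_string`, `count`, `frequency`), `accessions` (tibble
#'   `accession`, `hap1`, `hap2`, `label1`, `label2`, `homozygous`, plus
#'   metadata), `site_homozygous` (accession x SNP logical matrix over all
#'   genotyped accessions) and `n_excluded` (unphased heterozygotes).
#' @export
extract_haplotypes <- function(vcf, region, meta = NULL, min_frequency = 0.01) {
  reg <- parse_region(region)
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  pos1 <- as.integer(fix$POS)
  keep <- fix$CHROM == reg$chrom & (pos1 - 1L) >= reg$start & (pos1 - 1L) < reg$end
  biallelic <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  if (any(keep & !biallelic)) {
    warn(sprintf("skipping %d non-biallelic site(s) in region", sum(keep & !biallelic)))
  }
  keep <- keep & biallelic
  snps <- tibble(
    pos = pos1[keep] - 1L,
    ref = fix$REF[keep], alt = fix$ALT[keep]
  )
  empty <- structure(
    list(
      snps = snps,
      haplotypes = tibble(
        label = character(), allele_string = character(),
        count = integer(), frequency = numeric()
      ),
      accessions = tibble(),
      site_homozygous = matrix(logical(0), 0, nrow(snps)),
      n_excluded = 0L
    ),
    class = "chrono_haplotypes"
  )
  if (!any(keep)) {
    return(empty)
  }
  gt <- vcfR::extract.gt(v)[keep, , drop = FALSE]
  acc <- colnames(gt)
  n_snps <- nrow(gt)
  ref <- snps$ref
  alt <- snps$alt

  a1 <- matrix(NA_character_, length(acc), n_snps)
  a2 <- matrix(NA_character_, length(acc), n_snps)
  phased_ok <- matrix(FALSE, length(acc), n_snps)
  for (j in seq_len(n_snps)) {
    g <- gt[j, ]
    parts <- str_match(g, "^([01.])([/|])([01.])$")
    l <- parts[, 2]
    sep <- parts[, 3]
    r <- parts[, 4]
    ok <- !is.na(l) & l != "." & r != "."
    usable <- ok & (sep == "|" | l == r) # phased, or homozygous (order immaterial)
    a1[usable, j] <- ifelse(l[usable] == "0", ref[j], alt[j])
    a2[usable, j] <- ifelse(r[usable] == "0", ref[j], alt[j])
    phased_ok[, j] <- usable
  }
  site_hom <- a1 == a2
  rownames(site_hom) <- acc
  complete <- rowSums(!phased_ok) == 0L
  n_excluded <- sum(!complete)
  hap1 <- apply(a1[complete, , drop = FALSE], 1L, paste, collapse = "")
  hap2 <- apply(a2[complete, , drop = FALSE], 1L, paste, collapse = "")

  counts <- sort(table(c(hap1, hap2)), decreasing = TRUE)
  ord <- order(-as.integer(counts), names(counts)) # ties: lexicographic
  counts <- counts[ord]
  total <- sum(counts)
  freq <- as.numeric(counts) / total
  is_rare <- freq < min_frequency
  labels <- character(length(counts))
  labels[!is_rare] <- sprintf("H%02d", seq_len(sum(!is_rare)))
  labels[is_rare] <- "rare"
  hap_tbl <- tibble(
    label = labels, allele_string = names(counts),
    count = as.integer(counts), frequency = freq
  )
  label_of <- setNames(labels, names(counts))
  accessions <- tibble(
    accession = acc[complete],
    hap1 = hap1, hap2 = hap2,
    label1 = unname(label_of[hap1]), label2 = unname(label_of[hap2]),
    homozygous = hap1 == hap2
  )
  if (!is.null(meta)) {
    accessions <- left_join(accessions, meta, by = "accession")
  }
  structure(
    list(
      snps = snps, haplotypes = hap_tbl, accessions = accessions,
      site_homozygous = site_hom, n_excluded = n_excluded
    ),
    class = "chrono_haplotypes"
  )
}

#' @export
print.chrono_haplotypes <- function(x, ...) {
  cat(sprintf(
    "<haplotypes: %d SNPs, %d accessions labeled (%d excluded), %d haplotypes>\n",
    nrow(x$snps), nrow(x$accessions), x$n_excluded,
    sum(x$haplotypes$label != "rare")
  ))
  print(x$haplotypes)
  invisible(x)
}

#' @export
tidy.chrono_haplotypes <- function(x, ...) x$haplotypes

#' @export
glance.chrono_haplotypes <- function(x, ...) {
  tibble(
    n_snps = nrow(x$snps),
    n_accessions = nrow(x$accessions),
    n_excluded = x$n_excluded,
    n_haplotypes = sum(x$haplotypes$label != "rare"),
    pct_homozygous = if (nrow(x$accessions)) {
      100 * mean(x$accessions$homozygous)
    } else {
      NA_real_
    }
  )
}

#' Group-stratified haplotype frequencies
#'
#' Within each group, the proportion of homozygous accessions carrying each
#' haplotype label; proportions sum to 1 per group. Empty groups (no
#' homozygous accession) are omitted with a warning.
#'
#' @param haps A `chrono_haplotypes` object.
#' @param group_field Name of the grouping column in the accession table
#'   (e.g. `"region_group"` or `"germplasm"`).
#' @return A tibble `group`, `label`, `n`, `proportion`.
#' @export
group_frequencies <- function(haps, group_field = "region_group") {
  acc <- haps$accessions
  if (!group_field %in% names(acc)) {
    abort(sprintf("accession table has no '%s' column", group_field),
      class = "chronoaccess_config_error"
    )
  }
  hom <- filter(acc, .data$homozygous, !is.na(.data[[group_field]]))
  all_groups <- unique(acc[[group_field]][!is.na(acc[[group_field]])])
  missing <- setdiff(all_groups, unique(hom[[group_field]]))
  if (length(missing) > 0L) {
    warn(sprintf(
      "group(s) with no homozygous accession omitted: %s",
      paste(missing, collapse = ", ")
    ))
  }
  hom |>
    count(group = .data[[group_field]], label = .data$label1, name = "n") |>
    mutate(proportion = .data$n / sum(.data$n), .by = "group") |>
    arrange(.data$group, desc(.data$proportion))
}

#' Per-SNP homozygosity rates by group
#'
#' Fraction of genotyped accessions homozygous at each SNP, within each
#' group.
#'
#' @param haps A `chrono_haplotypes` object.
#' @param meta Tibble with `accession` and the grouping column (defaults to
#'   the metadata already joined on the accession table).
#' @param group_field Grouping column name.
#' @return A tibble `snp` (1-based index along the region), `pos`, `group`,
#'   `rate`.
#' @export
snp_homozygosity <- function(haps, meta = NULL, group_field = "region_group") {
  sh <- haps$site_homozygous
  if (is.null(meta)) meta <- haps$accessions
  idx <- match(rownames(sh), meta$accession)
  grp <- meta[[group_field]][idx]
  keep <- !is.na(grp)
  map(unique(grp[keep]), function(g) {
    rows <- keep & grp == g
    tibble(
      snp = seq_len(ncol(sh)),
      pos = haps$snps$pos,
      group = g,
      rate = colMeans(sh[rows, , drop = FALSE], na.rm = TRUE)
    )
  }) |> list_rbind()
}

#' Latitude trend of homozygosity (or any rate) across ordered groups
#'
#' Spearman correlation between group rank (south to north) and the rate;
#' constant rates give an undefined coefficient, reported as 0 with
#' attribute `undefined = TRUE`.
#'
#' @param rates Named numeric vector of per-group rates, or a tibble with
#'   `group` and `rate` columns.
#' @param group_order Character vector ordering the groups from south to
#'   north, e.g. `c("Southern", "Middle", "Northern")`.
#' @return Spearman rho (attribute `undefined` when rank variance is zero).
#' @export
latitude_trend <- function(rates, group_order) {
  if (is.data.frame(rates)) {
    rates <- setNames(rates$rate, rates$group)
  }
  stopifnot(length(group_order) >= 3L)
  r <- rates[group_order]
  if (any(is.na(r))) {
    abort("every ordered group needs a rate", class = "chronoaccess_validation_error")
  }
  spearman_rho(seq_along(group_order), r)
}
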