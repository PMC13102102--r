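# Synthetic study generator. Plants cosine rhythms, gene-ACR phase coupling,
# genotype effects, ChIP summit offsets and geographic haplotype structure
# with full ground truth, so every pipeline stage can be validated without
# sequencing data. All generators are deterministic under a fixed seed.

.sim_phases <- c(0, 4, 8, 12, 16, 20)

#' Simulate gene models and ACR intervals with planted classes
#'
#' Lays `n_genes` genes on a single chromosome with wide intergenic gaps and
#' places `n_acrs` ACRs so that each one's planted class (gACR inside a gene
#' body, pACR within `window` bp of a TSS, dACR farther than `window` from
#' every TSS/TES) is exactly what [classify_acrs()] computes.
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_acrs Number of ACRs (default `ceiling(1.5 * n_genes)`).
#' @param acr_class_mix Named proportions for classes gACR, pACR, dACR;
#'   must sum to 1. Defaults mirror a typical genome-wide ACR distribution
#'   (15.6 / 48.5 / 35.9 percent).
#' @param window Proximal window in bp.
#' @param seed Integer seed.
#' @return A list with `genes`, `acrs` (tibbles in the [read_gene_models()] /
#'   [read_bed()] layout) and `truth`, a tibble with `acr_id`, `class`,
#'   `host_gene`.
#' @export
simulate_annotation <- function(n_genes, n_acrs = ceiling(1.5 * n_genes),
                                acr_class_mix = c(gACR = 0.156, pACR = 0.485, dACR = 0.359),
                                window = 1000, seed = 1) {
  stopifnot(n_genes >= 1, n_acrs >= 1)
  if (abs(sum(acr_class_mix) - 1) > 1e-9) {
    abort("acr_class_mix proportions must sum to 1",
      class = "chronoaccess_config_error"
    )
  }
  set.seed(seed)
  gap <- 8000L
  acr_w <- 200L
  gene_len <- sample(2200:3000, n_genes, replace = TRUE)
  start <- cumsum(c(10000L, head(gene_len, -1) + gap))
  genes <- tibble(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    chrom = "chr1",
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    start = start,
    end = start + gene_len
  ) |>
    mutate(
      tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
      tes = ifelse(.data$strand == "+", .data$end - 1L, .data$start)
    )

  host <- sort(sample(rep_len(seq_len(n_genes), n_acrs)))
  cls <- sample(names(acr_class_mix), n_acrs, replace = TRUE, prob = acr_class_mix)
  slot <- stats::ave(seq_len(n_acrs), host, cls, FUN = seq_along) - 1L

  g <- genes[host, ]
  a_start <- integer(n_acrs)
  for (i in seq_len(n_acrs)) {
    if (cls[i] == "gACR") {
      span <- g$end[i] - g$start[i] - acr_w - 200L
      a_start[i] <- g$start[i] + 100L + (220L * slot[i]) %% span
    } else if (cls[i] == "pACR") {
      d <- 100L + (150L * slot[i]) %% 700L # realized edge distance <= window
      if (g$strand[i] == "+") {
        a_start[i] <- g$tss[i] - d - acr_w
      } else {
        a_start[i] <- g$end[i] + d - 1L # gap to the TSS point = d
      }
    } else {
      a_start[i] <- g$end[i] + 1500L + (250L * slot[i]) %% 5000L
    }
  }
  acrs <- tibble(
    acr_id = sprintf("acr%05d", seq_len(n_acrs)),
    chrom = "chr1",
    start = a_start,
    end = a_start + acr_w,
    summit = a_start + acr_w %/% 2L
  )
  truth <- tibble(
    acr_id = acrs$acr_id,
    class = cls,
    host_gene = genes$gene_id[host]
  )
  list(genes = genes, acrs = acrs, truth = truth)
}

#' Plant rhythm parameters on a simulated annotation
#'
#' Assigns each gene an oscillating flag (cosine rhythm with a grid-aligned
#' phase) or a stable profile, and couples each genic/proximal ACR to its
#' host gene's rhythm with exactly the same phase. Distal ACRs, and ACRs
#' hosted by stable genes, oscillate independently with probability
#' `oscillating_fraction`.
#'
#' @param annotation Result of [simulate_annotation()].
#' @param oscillating_fraction Fraction of genes (and of uncoupled ACRs)
#'   that oscillate.
#' @param baseline_range Per-feature baselines are drawn uniformly from this
#'   range (signal units).
#' @param amplitude Cosine amplitude for oscillating features (signal units).
#' @param noise_sd Gaussian noise sd per matrix cell (signal units).
#' @param period Rhythm period in hours.
#' @param phases Candidate peak phases (hours, taken modulo `period`).
#' @param seed Integer seed.
#' @return A tibble of per-feature ground truth: `feature_id`, `type`
#'   (gene/acr), `oscillating`, `baseline`, `amplitude`, `phase`, `period`,
#'   `noise_sd`, `partner` (coupled gene for an ACR, `NA` otherwise),
#'   `cluster` (planted phase index, `NA` for stable features).
#' @export
simulate_rhythms <- function(annotation, oscillating_fraction = 0.4,
                             baseline_range = c(20, 40), amplitude = 10,
                             noise_sd = 0.5, period = 24,
                             phases = .sim_phases, seed = 1) {
  set.seed(seed)
  genes <- annotation$genes
  truth <- annotation$truth
  ng <- nrow(genes)
  g_osc <- runif(ng) < oscillating_fraction
  g_phase <- sample(phases, ng, replace = TRUE)
  g_tbl <- tibble(
    feature_id = genes$gene_id,
    type = "gene",
    oscillating = g_osc,
    baseline = runif(ng, baseline_range[1], baseline_range[2]),
    amplitude = ifelse(g_osc, amplitude, 0),
    phase = ifelse(g_osc, g_phase, 0),
    period = period,
    noise_sd = noise_sd,
    partner = NA_character_,
    cluster = ifelse(g_osc, match(g_phase, phases), NA_integer_)
  )
  host_row <- match(truth$host_gene, genes$gene_id)
  coupled <- truth$class != "dACR" & g_osc[host_row]
  na <- nrow(truth)
  a_own_osc <- runif(na) < oscillating_fraction
  a_own_phase <- sample(phases, na, replace = TRUE)
  a_osc <- coupled | a_own_osc
  a_phase <- ifelse(coupled, g_phase[host_row], a_own_phase)
  a_tbl <- tibble(
    feature_id = truth$acr_id,
    type = "acr",
    oscillating = a_osc,
    baseline = runif(na, baseline_range[1], baseline_range[2]),
    amplitude = ifelse(a_osc, amplitude, 0),
    phase = ifelse(a_osc, a_phase, 0),
    period = period,
    noise_sd = noise_sd,
    partner = ifelse(coupled, truth$host_gene, NA_character_),
    cluster = ifelse(a_osc, match(a_phase, phases), NA_integer_)
  )
  bind_rows(g_tbl, a_tbl)
}

cosine_expectation <- function(features, timepoints) {
  outer(seq_len(nrow(features)), timepoints, function(i, t) {
    features$baseline[i] +
      features$amplitude[i] * cos(2 * pi * (t - features$phase[i]) / features$period[i])
  })
}

#' Simulate a replicated time-series signal matrix from planted rhythms
#'
#' Each cell is `max(0, baseline + amplitude * cos(2 * pi * (t - phase) /
#' period) + e)` with `e ~ Normal(0, noise_sd^2)` drawn independently per
#' cell; coupled gene-ACR pairs share their phase exactly by construction of
#' the ground-truth table.
#'
#' @param features Ground-truth tibble from [simulate_rhythms()] (or any
#'   tibble with `feature_id`, `baseline`, `amplitude`, `phase`, `period`,
#'   `noise_sd`).
#' @param timepoints Ordered ZT hours.
#' @param replicates Replicates per time point.
#' @param value_kind Unit label for the matrix.
#' @param seed Integer seed.
#' @return A signal tibble (see [signal_matrix()]).
#' @export
simulate_signal <- function(features, timepoints = seq(24, 44, by = 4),
                            replicates = 3, value_kind = c("rpkm", "tpm", "count"),
                            seed = 1) {
  value_kind <- match.arg(value_kind)
  stopifnot(length(timepoints) >= 1)
  set.seed(seed)
  mu <- cosine_expectation(features, timepoints)
  vals <- matrix(0, nrow(features), length(timepoints) * replicates)
  for (j in seq_along(timepoints)) {
    for (k in seq_len(replicates)) {
      col <- (j - 1L) * replicates + k
      vals[, col] <- pmax(0, mu[, j] + rnorm(nrow(features), 0, features$noise_sd))
    }
  }
  signal_matrix(vals, features$feature_id,
    timepoints = timepoints,
    replicates = replicates, value_kind = value_kind
  )
}

#' Simulate a mutant signal matrix with planted genotype effects
#'
#' Regenerates the rhythm with fresh noise and scales the expected signal by
#' a per-timepoint multiplier before noise is added, emulating a clock
#' mutant whose chromatin accessibility is shifted at selected time points.
#'
#' @inheritParams simulate_signal
#' @param effects Named numeric vector of multipliers keyed by ZT hour,
#'   e.g. `c("24" = 1.33)`; unlisted time points keep multiplier 1.
#' @return A signal tibble of the mutant condition.
#' @export
simulate_mutant <- function(features, effects, timepoints = seq(24, 44, by = 4),
                            replicates = 3, value_kind = c("rpkm", "tpm", "count"),
                            seed = 2) {
  value_kind <- match.arg(value_kind)
  if (any(effects <= 0)) {
    abort("effect multipliers must be > 0", class = "chronoaccess_config_error")
  }
  keys <- suppressWarnings(as.numeric(names(effects)))
  if (any(is.na(keys)) || !all(keys %in% timepoints)) {
    abort(
      sprintf(
        "unknown timepoint key in effects: %s",
        paste(names(effects)[is.na(keys) | !(keys %in% timepoints)], collapse = ", ")
      ),
      class = "chronoaccess_config_error"
    )
  }
  set.seed(seed)
  mult <- setNames(rep(1, length(timepoints)), timepoints)
  mult[as.character(keys)] <- effects
  mu <- cosine_expectation(features, timepoints)
  vals <- matrix(0, nrow(features), length(timepoints) * replicates)
  for (j in seq_along(timepoints)) {
    for (k in seq_len(replicates)) {
      col <- (j - 1L) * replicates + k
      vals[, col] <- pmax(0, mult[j] * mu[, j] + rnorm(nrow(features), 0, features$noise_sd))
    }
  }
  signal_matrix(vals, features$feature_id,
    timepoints = timepoints,
    replicates = replicates, value_kind = value_kind
  )
}

#' Simulate ChIP peak summits offset downstream of ACR summits
#'
#' Places one histone-mark peak summit per ACR at the planted downstream
#' offset (strand of the host gene decides which direction is downstream)
#' plus Gaussian jitter.
#'
#' @param annotation Result of [simulate_annotation()].
#' @param offset Planted downstream offset in bp.
#' @param jitter_sd Gaussian sd of the placement noise in bp.
#' @param seed Integer seed.
#' @return A tibble of ChIP peaks: `peak_id`, `chrom`, `summit`, plus the
#'   `acr_id` and host-gene `strand` used for planting.
#' @export
simulate_chip_summits <- function(annotation, offset = 250, jitter_sd = 30, seed = 1) {
  set.seed(seed)
  acrs <- annotation$acrs
  strand <- annotation$genes$strand[match(annotation$truth$host_gene, annotation$genes$gene_id)]
  sign <- ifelse(strand == "+", 1, -1)
  summit <- round(acrs$summit + sign * (offset + rnorm(nrow(acrs), 0, jitter_sd)))
  tibble(
    peak_id = sprintf("chip%05d", seq_len(nrow(acrs))),
    chrom = acrs$chrom,
    summit = as.integer(summit),
    acr_id = acrs$acr_id,
    strand = strand
  )
}

#' Simulate negative-binomial count replicates for two genotypes
#'
#' Draws per-feature NB counts for wild type and mutant with a common
#' dispersion; the first `n_affected` features carry a planted
#' `effect_multiplier` on the mutant mean.
#'
#' @param n_features Number of features.
#' @param n_reps Replicates per genotype.
#' @param mu_range Per-feature means drawn uniformly from this range.
#' @param dispersion NB dispersion (`var = mu + dispersion * mu^2`).
#' @param effect_multiplier Mutant mean multiplier for affected features.
#' @param n_affected Number of affected features (taken from the top of the
#'   table).
#' @param seed Integer seed.
#' @return A list with `wt` and `mut` count matrices (features x replicates,
#'   rownames = feature ids) and `truth` (tibble `feature_id`, `affected`).
#' @export
simulate_differential_counts <- function(n_features, n_reps = 2,
                                         mu_range = c(50, 500), dispersion = 0.05,
                                         effect_multiplier = 1, n_affected = 0,
                                         seed = 1) {
  set.seed(seed)
  ids <- sprintf("feat%05d", seq_len(n_features))
  mu <- runif(n_features, mu_range[1], mu_range[2])
  affected <- seq_len(n_features) <= n_affected
  mu_mut <- mu * ifelse(affected, effect_multiplier, 1)
  size <- 1 / dispersion
  draw <- function(m) {
    matrix(rnbinom(n_features * n_reps, mu = rep(m, n_reps), size = size),
      nrow = n_features, dimnames = list(ids, NULL)
    )
  }
  list(
    wt = draw(mu), mut = draw(mu_mut),
    truth = tibble(feature_id = ids, affected = affected, mu_wt = mu, mu_mut = mu_mut)
  )
}

#' Simulate a VCF of cis-regulatory haplotypes stratified by geography
#'
#' Draws diploid genotypes for `n_accessions` accessions, each belonging to
#' a geographic group with its own haplotype frequency spectrum, and writes
#' a plain-text VCF plus an accession metadata table.
#'
#' @param n_accessions Total accessions.
#' @param haplotype_freqs Named list: group -> named numeric vector of
#'   haplotype frequencies. Haplotype names are allele strings over
#'   `0` (REF) / `1` (ALT), one character per SNP, e.g. `"0101"`. Each
#'   group's frequencies must sum to 1.
#' @param snp_positions 0-based genomic positions of the SNPs.
#' @param chrom Chromosome name.
#' @param hom_rate Probability that an accession is homozygous (its second
#'   haplotype copies the first); otherwise the second copy is drawn
#'   independently.
#' @param germplasm_probs Named proportions for germplasm labels.
#' @param vcf_path Output VCF path (default a tempfile).
#' @param seed Integer seed.
#' @return A list with `vcf` (path), `meta` (tibble `accession`,
#'   `region_group`, `germplasm`) and `truth` (tibble `accession`, `hap1`,
#'   `hap2`).
#' @export
simulate_vcf <- function(n_accessions, haplotype_freqs, snp_positions,
                         chrom = "chr16", hom_rate = 0.9,
                         germplasm_probs = c(wild = 0.025, landrace = 0.31, cultivar = 0.665),
                         vcf_path = tempfile(fileext = ".vcf"), seed = 1) {
  n_snps <- length(snp_positions)
  haps_all <- unique(unlist(lapply(haplotype_freqs, names)))
  if (any(nchar(haps_all) != n_snps)) {
    abort("haplotype allele strings must have one character per SNP",
      class = "chronoaccess_config_error"
    )
  }
  sums <- map_dbl(haplotype_freqs, sum)
  if (any(abs(sums - 1) > 1e-9)) {
    abort("per-group haplotype frequencies must sum to 1",
      class = "chronoaccess_config_error"
    )
  }
  set.seed(seed)
  groups <- names(haplotype_freqs)
  grp <- sort(rep_len(groups, n_accessions))
  acc <- sprintf("acc%04d", seq_len(n_accessions))
  draw_hap <- function(g) {
    f <- haplotype_freqs[[g]]
    sample(names(f), 1L, prob = f)
  }
  hap1 <- map_chr(grp, draw_hap)
  hap2 <- ifelse(runif(n_accessions) < hom_rate, hap1, map_chr(grp, draw_hap))

  ref <- rep(c("A", "G", "C", "T"), length.out = n_snps)
  alt <- rep(c("T", "C", "G", "A"), length.out = n_snps)
  a1 <- do.call(rbind, strsplit(hap1, ""))
  a2 <- do.call(rbind, strsplit(hap2, ""))
  gts <- matrix(paste0(a1, "|", a2), nrow = n_accessions)

  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", chrom),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", acc
    ), collapse = "\t")
  )
  body <- vapply(seq_len(n_snps), function(i) {
    paste(c(
      chrom, snp_positions[i] + 1L, sprintf("snp%d", i), ref[i], alt[i],
      ".", "PASS", ".", "GT", gts[, i]
    ), collapse = "\t")
  }, character(1))
  readr::write_lines(c(header, body), vcf_path)

  meta <- tibble(
    accession = acc,
    region_group = grp,
    germplasm = sample(names(germplasm_probs), n_accessions,
      replace = TRUE, prob = germplasm_probs
    )
  )
  list(vcf = vcf_path, meta = meta, truth = tibble(accession = acc, hap1 = hap1, hap2 = hap2))
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper that generates annotation, planted rhythms, and the
#' gene (TPM) and ACR (RPKM) signal matrices from one seed.
#'
#' @inheritParams simulate_annotation
#' @inheritParams simulate_rhythms
#' @param timepoints Ordered ZT hours.
#' @param replicates Replicates per time point.
#' @return A list with `genes`, `acrs`, `classes` (planted class truth),
#'   `truth` (per-feature rhythm ground truth), `gene_signal`, `acr_signal`.
#' @export
simulate_study <- function(n_genes = 1000, n_acrs = 1500,
                           acr_class_mix = c(gACR = 0.156, pACR = 0.485, dACR = 0.359),
                           oscillating_fraction = 0.4, amplitude = 10,
                           noise_sd = 0.5, timepoints = seq(24, 44, by = 4),
                           replicates = 3, seed = 1) {
  ann <- simulate_annotation(n_genes,
    n_acrs = n_acrs, acr_class_mix = acr_class_mix,
    seed = seed
  )
  truth <- simulate_rhythms(ann,
    oscillating_fraction = oscillating_fraction,
    amplitude = amplitude, noise_sd = noise_sd, seed = seed + 1L
  )
  g_truth <- filter(truth, .data$type == "gene")
  a_truth <- filter(truth, .data$type == "acr")
  list(
    genes = ann$genes,
    acrs = ann$acrs,
    classes = ann$truth,
    truth = truth,
    gene_signal = simulate_signal(g_truth,
      timepoints = timepoints,
      replicates = replicates, value_kind = "tpm", seed = seed + 2L
    ),
    acr_signal = simulate_signal(a_truth,
      timepoints = timepoints,
      replicates = replicates, value_kind = "rpkm", seed = seed + 3L
    )
  )
}
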