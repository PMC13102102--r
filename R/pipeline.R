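# End-to-end orchestration: annotate -> screen -> cooscillate with optional
# differential, network and haplotype stages, from a single configuration
# with one seed, writing stage outputs, a funnel, a manifest of realized
# thresholds and a log. Reruns with the same config and seed are
# bit-identical.

#' Default pipeline configuration
#'
#' All thresholds of the analysis in one list: proximal window 1000 bp,
#' top-signal fraction 0.005, RPKM floor 10 with a 5th-percentile low
#' floor, TPM floor 1, CV thresholds 13 (ACRs) / 16 (genes), core
#' membership 0.3, Spearman threshold 0.6, 11 phase clusters, differential
#' alpha 0.05 with 1.5-fold gate, network edge alpha 0.005.
#'
#' @param ... Overrides merged over the defaults.
#' @return A named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    # input paths (filled by the caller)
    acr_bed = NULL, gene_models = NULL,
    acr_matrix = NULL, gene_matrix = NULL,
    mutant_matrix = NULL, acr_fasta = NULL, pwm_file = NULL,
    clock_genes = NULL, vcf = NULL, vcf_meta = NULL, vcf_region = NULL,
    # grid
    timepoints = seq(24, 44, by = 4), replicates = 3,
    # thresholds
    window = 1000, top_fraction = 0.005, rpkm_floor = 10,
    percentile_floor = 0.05, tpm_floor = 1,
    cv_acr = 13, cv_gene = 16,
    min_acore = 0.3, rho_threshold = 0.6,
    n_clusters = 11, cog_clusters = 11, fuzzifier = 1.25, n_restarts = 10,
    diff_zt = 24, alpha = 0.05, fc_threshold = 1.5,
    edge_alpha = 0.005, min_frequency = 0.01,
    seed = 1
  )
  modifyList(cfg, list(...))
}

require_path <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    abort(sprintf("%s path missing or unreadable: %s", what, path %||% "<NULL>"),
      class = "chronoaccess_config_error"
    )
  }
  path
}

#' Run the full co-oscillation pipeline
#'
#' Executes annotate, screen and cooscillate (and, when the corresponding
#' inputs are configured, differential, network and haplotype stages),
#' writing stage outputs with stable filenames into `outdir` together with
#' `funnel.json`, `manifest.json` and `pipeline.log`. The manifest records
#' the package version, a configuration hash, the seed and every realized
#' data-driven threshold.
#'
#' @param config Configuration list from [default_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the stage results (`classes`,
#'   `associations`, `screens`, `cog`, `ccog`, `partition`, `funnel`, and
#'   any optional stage outputs).
#' @export
run_pipeline <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "pipeline.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    readr::write_lines(log_lines, log_path)
  }
  on_failure <- function(e) {
    readr::write_lines(conditionMessage(e), file.path(outdir, "FAILED"))
    abort(conditionMessage(e), class = "chronoaccess_pipeline_error", parent = e)
  }
  withCallingHandlers(
    run_pipeline_impl(config, outdir, say),
    error = function(e) {
      if (!inherits(e, "chronoaccess_pipeline_error")) on_failure(e)
    }
  )
}

run_pipeline_impl <- function(config, outdir, say) {
  stages <- character(0)
  realized <- list()

  # --- inputs ---------------------------------------------------------------
  acrs <- read_bed(require_path(config$acr_bed, "ACR BED"))
  genes <- read_gene_models(require_path(config$gene_models, "gene models"))
  acr_sig <- read_signal_matrix(require_path(config$acr_matrix, "ACR matrix"),
    timepoints = config$timepoints, replicates = config$replicates,
    value_kind = "rpkm"
  )
  gene_sig <- read_signal_matrix(require_path(config$gene_matrix, "gene matrix"),
    timepoints = config$timepoints, replicates = config$replicates,
    value_kind = "tpm"
  )
  say("inputs: %d ACRs, %d genes", nrow(acrs), nrow(genes))

  # --- annotate -------------------------------------------------------------
  classes <- classify_acrs(acrs, genes, window = config$window)
  assoc <- associate_acrs(acrs, genes, window = config$window)
  classes |>
    mutate(gene_ids = map_chr(.data$gene_ids, paste, collapse = ",")) |>
    readr::write_tsv(file.path(outdir, "acr_classes.tsv"), progress = FALSE)
  readr::write_tsv(assoc, file.path(outdir, "associations.tsv"), progress = FALSE)
  stages <- c(stages, "annotate")
  say(
    "annotate: %d gACR / %d pACR / %d dACR",
    sum(classes$class == "gACR"), sum(classes$class == "pACR"),
    sum(classes$class == "dACR")
  )

  # --- screen ---------------------------------------------------------------
  acc <- filter_accessibility(acr_sig,
    top_fraction = config$top_fraction,
    floor = config$rpkm_floor, percentile_floor = config$percentile_floor
  )
  expr <- filter_expression(gene_sig, floor = config$tpm_floor)
  acr_prof <- compute_profiles(acr_sig) |> filter(.data$feature_id %in% acc$kept_ids)
  gene_prof <- compute_profiles(gene_sig) |> filter(.data$feature_id %in% expr$kept_ids)
  acr_split <- split_fluctuating(acr_prof, cv_threshold = config$cv_acr)
  gene_split <- split_fluctuating(gene_prof, cv_threshold = config$cv_gene)
  realized$accessibility <- acc$thresholds
  realized$cv_acr <- acr_split$thresholds
  realized$cv_gene <- gene_split$thresholds
  stages <- c(stages, "screen")
  say(
    "screen: %d/%d ACRs kept (%d fluctuating); %d/%d genes kept (%d fluctuating)",
    length(acc$kept_ids), nrow(acrs), length(acr_split$fluctuating_ids),
    length(expr$kept_ids), nrow(genes), length(gene_split$fluctuating_ids)
  )

  # --- cooscillate ----------------------------------------------------------
  fl_gene_prof <- filter(gene_prof, .data$feature_id %in% gene_split$fluctuating_ids)
  fl_acr_prof <- filter(acr_prof, .data$feature_id %in% acr_split$fluctuating_ids)
  fl_assoc <- filter(
    assoc, .data$gene_id %in% fl_gene_prof$feature_id,
    .data$acr_id %in% fl_acr_prof$feature_id
  )
  joint <- bind_rows(fl_gene_prof, fl_acr_prof)
  model <- fcm_fit(joint,
    n_clusters = config$cog_clusters, m = config$fuzzifier,
    seed = config$seed, n_restarts = config$n_restarts
  )
  cog <- select_cog(model, fl_assoc, core_threshold = config$min_acore)
  ccog <- select_ccog(cog, fl_gene_prof, fl_acr_prof,
    rho_threshold = config$rho_threshold
  )
  part <- partition_ccog(ccog, fl_gene_prof,
    n_clusters = config$n_clusters,
    seed = config$seed, m = config$fuzzifier, n_restarts = config$n_restarts
  )
  readr::write_tsv(part$records, file.path(outdir, "ccog.tsv"), progress = FALSE)
  readr::write_tsv(part$clusters, file.path(outdir, "clusters.tsv"), progress = FALSE)
  stages <- c(stages, "cooscillate")
  say(
    "cooscillate: %d COG pairs -> %d CCOG pairs (%d genes, %d ACRs)",
    nrow(cog), nrow(ccog), length(unique(ccog$gene_id)), length(unique(ccog$acr_id))
  )

  funnel <- funnel_summary(tibble(
    stage = c(
      "expressed_genes", "total_acrs", "fluctuating_genes", "fluctuating_acrs",
      "associated_genes", "associated_acrs", "cog_genes", "ccog_genes", "ccog_acrs"
    ),
    count = c(
      length(expr$kept_ids), nrow(acrs),
      length(gene_split$fluctuating_ids), length(acr_split$fluctuating_ids),
      length(unique(fl_assoc$gene_id)), length(unique(fl_assoc$acr_id)),
      length(unique(cog$gene_id)),
      length(unique(ccog$gene_id)), length(unique(ccog$acr_id))
    ),
    base = c(
      length(expr$kept_ids), nrow(acrs),
      length(expr$kept_ids), length(acc$kept_ids),
      length(gene_split$fluctuating_ids), length(acr_split$fluctuating_ids),
      length(expr$kept_ids),
      length(expr$kept_ids), length(acc$kept_ids)
    )
  ))
  jsonlite::write_json(funnel, file.path(outdir, "funnel.json"),
    auto_unbox = TRUE, digits = NA
  )

  out <- list(
    classes = classes, associations = assoc,
    screens = list(
      accessibility = acc, expression = expr,
      acr_fluctuation = acr_split, gene_fluctuation = gene_split
    ),
    cog = cog, ccog = ccog, partition = part, funnel = funnel
  )

  # --- optional: differential -----------------------------------------------
  if (!is.null(config$mutant_matrix)) {
    mut_sig <- read_signal_matrix(require_path(config$mutant_matrix, "mutant matrix"),
      timepoints = config$timepoints, replicates = config$replicates,
      value_kind = "rpkm"
    )
    diff <- test_differential(acr_sig, mut_sig,
      zt = config$diff_zt,
      alpha = config$alpha, fc_threshold = config$fc_threshold
    )
    diff |>
      mutate(per_replicate_fc = map_chr(
        .data$per_replicate_fc,
        \(v) paste(signif(v, 5), collapse = ",")
      )) |>
      readr::write_tsv(file.path(outdir, "differential.tsv"), progress = FALSE)
    out$differential <- diff
    stages <- c(stages, "differential")
    say(
      "differential (ZT%s): %d induced, %d repressed",
      config$diff_zt, sum(diff$direction == "induced"),
      sum(diff$direction == "repressed")
    )
  }

  # --- optional: network ----------------------------------------------------
  if (!is.null(config$acr_fasta) && !is.null(config$pwm_file)) {
    seqs <- Biostrings::readDNAStringSet(require_path(config$acr_fasta, "ACR FASTA"))
    acr_seqs <- setNames(as.character(seqs), names(seqs))
    pwms <- read_jaspar(require_path(config$pwm_file, "PWM file"))
    clock <- config$clock_genes %||% unique(assoc$gene_id)
    net <- build_network(clock, assoc, acr_seqs, pwms,
      edge_alpha = config$edge_alpha, shuffle_seed = config$seed
    )
    readr::write_tsv(net$edges, file.path(outdir, "network_edges.tsv"), progress = FALSE)
    out$network <- net
    stages <- c(stages, "network")
    say("network: %d genes, %d edges", net$summary$n_genes, net$summary$n_edges)
  }

  # --- optional: haplotype --------------------------------------------------
  if (!is.null(config$vcf)) {
    meta <- if (!is.null(config$vcf_meta)) {
      readr::read_tsv(require_path(config$vcf_meta, "VCF metadata"),
        show_col_types = FALSE, progress = FALSE
      )
    } else {
      NULL
    }
    haps <- extract_haplotypes(require_path(config$vcf, "VCF"),
      region = config$vcf_region,
      meta = meta, min_frequency = config$min_frequency
    )
    readr::write_tsv(haps$haplotypes, file.path(outdir, "haplotypes.tsv"),
      progress = FALSE
    )
    if (!is.null(meta)) {
      readr::write_tsv(group_frequencies(haps),
        file.path(outdir, "haplotype_group_frequencies.tsv"),
        progress = FALSE
      )
    }
    out$haplotypes <- haps
    stages <- c(stages, "haplotype")
    say(
      "haplotype: %d haplotypes over %d SNPs",
      sum(haps$haplotypes$label != "rare"), nrow(haps$snps)
    )
  }

  manifest <- list(
    package = "chronoaccess",
    version = as.character(packageVersion("chronoaccess")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    stages = stages,
    config = config[setdiff(names(config), "timepoints")],
    timepoints = config$timepoints,
    realized_thresholds = realized
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  say("done: %d stages", length(stages))
  invisible(out)
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()]. Configurations
#' round-trip through [save_config()] unchanged.
#'
#' @param path Path to a YAML file.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(require_path(path, "config"))
  cfg <- modifyList(default_config(), user, keep.null = TRUE)
  if (!is.null(cfg$timepoints)) cfg$timepoints <- as.numeric(unlist(cfg$timepoints))
  cfg
}

#' Write a pipeline configuration to YAML
#'
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
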