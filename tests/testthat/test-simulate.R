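test_that("annotation generator is deterministic and respects the class mix", {
  a <- simulate_annotation(30, seed = 5)
  b <- simulate_annotation(30, seed = 5)
  expect_identical(a, b)

  # degenerate mix: everything proximal
  p <- simulate_annotation(10, n_acrs = 10, acr_class_mix = c(gACR = 0, pACR = 1, dACR = 0), seed = 2)
  cls <- classify_acrs(p$acrs, p$genes)
  expect_true(all(cls$class == "pACR"))
  expect_true(all(cls$distance <= 1000))

  expect_error(
    simulate_annotation(10, acr_class_mix = c(gACR = 0.5, pACR = 0.2, dACR = 0.2)),
    class = "chronoaccess_config_error"
  )
})

test_that("equal-mix class counts fall within binomial 99% bounds", {
  mix <- c(gACR = 1 / 3, pACR = 1 / 3, dACR = 1 / 3)
  ann <- simulate_annotation(200, n_acrs = 300, acr_class_mix = mix, seed = 8)
  counts <- table(factor(ann$truth$class, levels = names(mix)))
  lo <- qbinom(0.005, 300, 1 / 3)
  hi <- qbinom(0.995, 300, 1 / 3)
  expect_true(all(counts >= lo & counts <= hi))
})

test_that("planted classes agree exactly with the classifier", {
  ann <- simulate_annotation(150, n_acrs = 260, seed = 13)
  cls <- classify_acrs(ann$acrs, ann$genes)
  expect_equal(as.character(cls$class), ann$truth$class)
})

test_that("signal generator reproduces the cosine model in closed form", {
  flat <- tibble::tibble(
    feature_id = "s", baseline = 7, amplitude = 0, phase = 0,
    period = 24, noise_sd = 0
  )
  x <- simulate_signal(flat, replicates = 2, seed = 1)
  expect_true(all(signal_values(x) == 7))

  f <- tibble::tibble(
    feature_id = "o", baseline = 10, amplitude = 5, phase = 24,
    period = 24, noise_sd = 0
  )
  y <- signal_values(simulate_signal(f, replicates = 1, seed = 1))
  # closed form: ZT36 is half a period from the ZT24 peak
  expect_equal(unname(y[1, "ZT36_rep1"]), 10 + 5 * cos(pi), tolerance = 1e-12)
  expect_equal(unname(y[1, "ZT24_rep1"]), 15, tolerance = 1e-12)
  # peak attained at the grid point matching the phase
  expect_equal(names(which.max(y[1, ])), "ZT24_rep1")
})

test_that("mutant generator scales the expectation before noise", {
  f <- tibble::tibble(
    feature_id = c("a", "b"), baseline = c(10, 20), amplitude = c(5, 0),
    phase = 24, period = 24, noise_sd = 0
  )
  wt <- signal_values(simulate_signal(f, replicates = 2, seed = 3))
  same <- signal_values(simulate_mutant(f, c("24" = 1), replicates = 2, seed = 99))
  expect_equal(same, wt, tolerance = 1e-12)

  mut <- signal_values(simulate_mutant(f, c("24" = 1.33), replicates = 2, seed = 4))
  zt24 <- grepl("^ZT24_", colnames(wt))
  expect_equal(mut[, zt24], 1.33 * wt[, zt24], tolerance = 1e-12)
  expect_equal(mut[, !zt24], wt[, !zt24], tolerance = 1e-12)

  expect_error(simulate_mutant(f, c("23" = 2)), class = "chronoaccess_config_error")
  expect_error(simulate_mutant(f, c("24" = 0)), class = "chronoaccess_config_error")
})

test_that("rhythm truth couples genic/proximal ACRs to oscillating hosts", {
  ann <- simulate_annotation(80, seed = 31)
  tr <- simulate_rhythms(ann, seed = 32)
  acr <- dplyr::filter(tr, type == "acr", !is.na(partner))
  gene <- dplyr::filter(tr, type == "gene")
  ph <- setNames(gene$phase, gene$feature_id)
  osc <- setNames(gene$oscillating, gene$feature_id)
  expect_true(all(osc[acr$partner])) # partners oscillate
  expect_equal(acr$phase, unname(ph[acr$partner])) # phases shared exactly
  cls <- setNames(ann$truth$class, ann$truth$acr_id)
  expect_false(any(cls[acr$feature_id] == "dACR"))
})

test_that("VCF generator plants recoverable haplotype structure", {
  # one haplotype at frequency 1 -> everyone homozygous for it
  sim1 <- simulate_vcf(12, list(Northern = c("010" = 1)),
    snp_positions = c(10, 20, 30), seed = 4
  )
  h1 <- extract_haplotypes(sim1$vcf, "chr16:0-100", meta = sim1$meta)
  expect_equal(nrow(h1$haplotypes), 1L)
  expect_equal(h1$haplotypes$frequency, 1)
  expect_true(all(h1$accessions$homozygous))

  # two groups with disjoint fixed haplotypes -> group-exclusive frequencies
  sim2 <- simulate_vcf(
    20,
    list(Northern = c("000" = 1), Southern = c("111" = 1)),
    snp_positions = c(10, 20, 30), seed = 5
  )
  h2 <- extract_haplotypes(sim2$vcf, "chr16:0-100", meta = sim2$meta)
  gf <- group_frequencies(h2)
  expect_true(all(gf$proportion == 1))
  expect_equal(nrow(gf), 2L)
  expect_false(gf$label[gf$group == "Northern"] == gf$label[gf$group == "Southern"])

  expect_error(
    simulate_vcf(10, list(N = c("00" = 0.5, "01" = 0.4)), snp_positions = c(1, 2)),
    class = "chronoaccess_config_error"
  )
})

test_that("generators are byte-deterministic under a fixed seed", {
  s1 <- simulate_study(n_genes = 40, n_acrs = 60, seed = 77)
  s2 <- simulate_study(n_genes = 40, n_acrs = 60, seed = 77)
  expect_identical(s1, s2)
  v1 <- simulate_vcf(8, list(G = c("01" = 0.5, "10" = 0.5)),
    snp_positions = c(5, 9),
    vcf_path = withr::local_tempfile(fileext = ".vcf"), seed = 3
  )
  v2 <- simulate_vcf(8, list(G = c("01" = 0.5, "10" = 0.5)),
    snp_positions = c(5, 9),
    vcf_path = withr::local_tempfile(fileext = ".vcf"), seed = 3
  )
  expect_identical(readLines(v1$vcf), readLines(v2$vcf))
  expect_identical(v1$meta, v2$meta)
})
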