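vcf_fixture <- function(gts, positions = c(100L, 200L, 300L), chrom = "chr16",
                        ref = c("A", "G", "C"), alt = c("T", "C", "G")) {
  # gts: accession x SNP matrix of GT strings
  acc <- rownames(gts)
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", chrom),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", acc),
      collapse = "\t"
    ),
    vapply(seq_len(ncol(gts)), function(j) {
      paste(c(chrom, positions[j], sprintf("s%d", j), ref[j], alt[j], ".", "PASS", ".", "GT", gts[, j]),
        collapse = "\t"
      )
    }, character(1))
  )
  write_tmp_lines(lines, ext = ".vcf", env = parent.frame())
}

test_that("all-reference homozygotes collapse to a single H01 haplotype", {
  gts <- matrix("0|0", 10, 3, dimnames = list(sprintf("a%02d", 1:10), NULL))
  h <- extract_haplotypes(vcf_fixture(gts), "chr16:0-1000")
  expect_equal(nrow(h$haplotypes), 1L)
  expect_equal(h$haplotypes$label, "H01")
  expect_equal(h$haplotypes$allele_string, "AGC") # the REF bases
  expect_equal(h$haplotypes$frequency, 1)
  expect_equal(h$haplotypes$count, 20L) # 2 chromosomes per accession
})

test_that("haplotype labels are ordered by descending count with stable ties", {
  gts <- rbind(
    matrix("0|0", 6, 3), # AGC x 6 accessions
    matrix("1|1", 4, 3) # TCG x 4
  )
  rownames(gts) <- sprintf("a%02d", 1:10)
  h <- extract_haplotypes(vcf_fixture(gts), "chr16:0-1000")
  expect_equal(h$haplotypes$label, c("H01", "H02"))
  expect_equal(h$haplotypes$frequency, c(0.6, 0.4))
  expect_equal(h$haplotypes$allele_string, c("AGC", "TCG"))

  # label assignment is invariant to accession order
  perm <- gts[sample(nrow(gts)), , drop = FALSE]
  h2 <- extract_haplotypes(vcf_fixture(perm), "chr16:0-1000")
  expect_equal(h2$haplotypes, h$haplotypes)
})

test_that("unphased heterozygotes are excluded and tallied; counts sum to 2n", {
  gts <- rbind(
    matrix("0|0", 4, 3),
    matrix("0/1", 2, 3), # unphased het -> excluded
    matrix("0|1", 1, 3) # phased het -> labeled, not homozygous
  )
  rownames(gts) <- sprintf("a%02d", 1:7)
  h <- extract_haplotypes(vcf_fixture(gts), "chr16:0-1000")
  expect_equal(h$n_excluded, 2L)
  expect_equal(nrow(h$accessions), 5L)
  expect_equal(sum(h$haplotypes$count), 2L * nrow(h$accessions))
  expect_false(h$accessions$homozygous[h$accessions$accession == "a07"])
})

test_that("region filtering is half-open and multi-allelic sites are skipped", {
  gts <- matrix("0|0", 3, 3, dimnames = list(sprintf("a%d", 1:3), NULL))
  path <- vcf_fixture(gts, positions = c(100L, 200L, 300L))
  # 0-based half-open [99, 200) keeps POS 100 and 200 (1-based)
  h <- extract_haplotypes(path, "chr16:99-200")
  expect_equal(h$snps$pos, c(99L, 199L))

  lines <- readLines(path)
  lines[6] <- sub("\tC\t", "\tC,G\t", sub("\tG\t", "\tG,T\t", lines[6]))
  multi <- write_tmp_lines(lines, ext = ".vcf")
  expect_warning(h2 <- extract_haplotypes(multi, "chr16:0-1000"), "non-biallelic")
  expect_equal(nrow(h2$snps), 2L)
})

test_that("planted haplotypes and their counts are recovered exactly", {
  freqs <- list(G = c("000" = 0.5, "011" = 0.3, "110" = 0.2))
  sim <- simulate_vcf(120, freqs, snp_positions = c(10, 20, 30), hom_rate = 1, seed = 44)
  h <- extract_haplotypes(sim$vcf, "chr16:0-100", meta = sim$meta)
  got <- table(c(h$accessions$hap1, h$accessions$hap2))
  planted <- table(vapply(c(sim$truth$hap1, sim$truth$hap2), function(hp) {
    # translate 0/1 strings into the written REF/ALT bases
    paste(ifelse(strsplit(hp, "")[[1]] == "0", c("A", "G", "C"), c("T", "C", "G")),
      collapse = ""
    )
  }, character(1)))
  expect_equal(sort(as.vector(got)), sort(as.vector(planted)))
  expect_equal(sum(h$haplotypes$count), 240L)
})

test_that("group frequencies sum to one and reduce to global for one group", {
  freqs <- list(Only = c("00" = 0.7, "11" = 0.3))
  sim <- simulate_vcf(80, freqs, snp_positions = c(5, 9), hom_rate = 1, seed = 45)
  h <- extract_haplotypes(sim$vcf, "chr16:0-100", meta = sim$meta)
  gf <- group_frequencies(h)
  expect_equal(sum(gf$proportion), 1)
  glob <- table(h$accessions$label1) / nrow(h$accessions)
  expect_equal(
    gf$proportion[order(gf$label)],
    as.vector(glob[order(names(glob))])
  )
})

test_that("latitude trend is the Spearman rank correlation over ordered groups", {
  ord <- c("Southern", "Middle", "Northern")
  expect_equal(as.numeric(latitude_trend(c(Southern = 0.2, Middle = 0.5, Northern = 0.9), ord)), 1)
  expect_equal(as.numeric(latitude_trend(c(Southern = 0.9, Middle = 0.5, Northern = 0.2), ord)), -1)
  flat <- latitude_trend(c(Southern = 0.5, Middle = 0.5, Northern = 0.5), ord)
  expect_equal(as.numeric(flat), 0)
  expect_true(attr(flat, "undefined"))
})

test_that("a planted homozygosity gradient yields a positive mean trend", {
  # northern groups are progressively more fixed for one haplotype, so
  # per-SNP homozygosity climbs south -> north
  freqs <- list(
    Southern = c("111" = 0.5, "000" = 0.5),
    Middle = c("111" = 0.75, "000" = 0.25),
    Northern = c("111" = 0.95, "000" = 0.05)
  )
  ord <- c("Southern", "Middle", "Northern")
  trends <- vapply(1:10, function(s) {
    sim <- simulate_vcf(150, freqs,
      snp_positions = c(10, 20, 30), hom_rate = 0.5,
      seed = 100 + s
    )
    h <- extract_haplotypes(sim$vcf, "chr16:0-100", meta = sim$meta)
    rates <- snp_homozygosity(h)
    snp1 <- dplyr::filter(rates, snp == 1)
    as.numeric(latitude_trend(dplyr::select(snp1, group, rate), ord))
  }, numeric(1))
  expect_gt(mean(trends), 0)
})
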