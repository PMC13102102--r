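pwm_A6 <- pwm(matrix(rep(c(0.97, 0.01, 0.01, 0.01), 6), nrow = 4), "A6")

random_seq <- function(n, chars = c("A", "C", "G", "T")) {
  paste(sample(chars, n, replace = TRUE), collapse = "")
}

test_that("PWM scores follow the closed-form log-odds arithmetic", {
  hits <- pwm_scan("AAAAAA", pwm_A6)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$score, 6 * log2(0.97 / 0.25), tolerance = 1e-12)
  expect_equal(hits$position, 1L)

  # an N contributes exactly zero
  h2 <- pwm_scan("AANAAA", pwm_A6, score_threshold = 0)
  expect_equal(h2$score[h2$strand == "+"], 5 * log2(0.97 / 0.25), tolerance = 1e-12)

  # all-N: zero score everywhere, no hits at positive threshold
  expect_equal(nrow(pwm_scan(strrep("N", 30), pwm_A6, score_threshold = 1e-9)), 0L)
  # sequence shorter than the motif
  expect_equal(nrow(pwm_scan("AAA", pwm_A6)), 0L)
})

test_that("scanning is strand-symmetric for arbitrary PWMs and sequences", {
  set.seed(17)
  for (i in 1:10) {
    mat <- matrix(runif(4 * 7, 0.05, 1), 4)
    mat <- sweep(mat, 2, colSums(mat), "/")
    p <- pwm(mat, "rand")
    s <- random_seq(60)
    fwd <- pwm_scan(s, p, score_threshold = -Inf)
    rev <- pwm_scan(chronoaccess:::revcomp(s), p, score_threshold = -Inf)
    expect_equal(sort(fwd$score), sort(rev$score), tolerance = 1e-9)
  }
})

test_that("JASPAR matrix text parses to per-column probability matrices", {
  path <- write_tmp_lines(c(
    ">MA0001.1 TESTA",
    "A [ 10  0  5  2 ]",
    "C [  0 10  5  2 ]",
    "G [  0  0  5  2 ]",
    "T [  0  0  5  4 ]",
    ">MA0002.1 TESTB",
    "A 1 1 1 1",
    "C 1 1 1 1",
    "G 1 1 1 1",
    "T 7 7 7 7"
  ), ext = ".jaspar")
  pwms <- read_jaspar(path)
  expect_named(pwms, c("MA0001.1", "MA0002.1"))
  expect_equal(pwms[["MA0001.1"]]$name, "TESTA")
  expect_true(all(abs(colSums(pwms[["MA0001.1"]]$matrix) - 1) < 1e-9))
  expect_equal(ncol(pwms[["MA0002.1"]]$matrix), 4L)
  # dominant base keeps the bulk of the probability mass
  expect_gt(pwms[["MA0001.1"]]$matrix["A", 1], 0.9)
})

test_that("enrichment p equals the exact hypergeometric tail and BH is monotone", {
  # fixture where hit status is fully controlled: motif AAAAAA present or not
  fg <- c(rep("CCAAAAAACC", 9), "CCCCCCCCCC")
  bg <- c("GGAAAAAAGG", rep("GGGGGGGGGG", 9))
  res <- motif_enrich(fg, pwm_A6, background = bg)
  expect_equal(res$foreground_hits, 9L)
  expect_equal(res$background_hits, 1L)
  # one-sided Fisher == hypergeometric tail sum, by hand
  oracle <- sum(dhyper(9:10, 10, 10, 10))
  expect_equal(res$p_value, oracle, tolerance = 1e-12)
  expect_equal(res$pct_tp, 90)

  # identical fg/bg: no enrichment signal
  same <- motif_enrich(fg, pwm_A6, background = fg)
  expect_gt(same$p_value, 0.5)

  # extreme table
  ext <- motif_enrich(rep("TTAAAAAATT", 20), pwm_A6, background = rep(strrep("G", 10), 20))
  expect_equal(ext$pct_tp, 100)
  expect_equal(ext$p_value, 1 / choose(40, 20), tolerance = 1e-12)

  # BH across motifs: adjusted >= raw, order preserved
  pwm_C6 <- pwm(matrix(rep(c(0.01, 0.97, 0.01, 0.01), 6), nrow = 4), "C6")
  multi <- motif_enrich(fg, list(pwm_A6, pwm_C6), background = bg)
  expect_true(all(multi$adjusted_p >= multi$p_value - 1e-15))
  expect_equal(order(multi$adjusted_p), order(multi$p_value))
})

test_that("dinucleotide shuffling preserves composition exactly", {
  dinuc_counts <- function(s) {
    ch <- strsplit(s, "")[[1]]
    table(paste0(head(ch, -1), ch[-1]))
  }
  set.seed(23)
  for (i in 1:8) {
    s <- random_seq(sample(40:120, 1))
    sh <- shuffle_dinucleotide(s)
    expect_equal(nchar(sh), nchar(s))
    expect_identical(dinuc_counts(sh), dinuc_counts(s))
  }
})

test_that("a planted motif yields exactly one network edge at its target", {
  set.seed(29)
  assoc <- tibble::tibble(
    gene_id = rep(c("gA", "gB", "gC"), each = 8),
    acr_id = sprintf("acr%02d", 1:24)
  )
  seqs <- setNames(replicate(24, random_seq(80, c("C", "G", "T"))), assoc$acr_id)
  withB <- assoc$acr_id[assoc$gene_id == "gB"]
  seqs[withB] <- vapply(seqs[withB], function(s) {
    paste0(substr(s, 1, 40), "AAAAAA", substr(s, 47, 80))
  }, character(1))
  net <- build_network(
    c("gA", "gB", "gC"), assoc, seqs, list(A6 = pwm_A6),
    background = replicate(50, random_seq(80, c("C", "G", "T"))),
    edge_alpha = 0.005
  )
  expect_equal(net$edges$target_gene_id, "gB")
  expect_equal(net$edges$tf_gene_id, "A6")
  expect_equal(net$summary$n_edges, 1L)
  expect_equal(net$summary$mean_edges_per_acr, 1 / 24)

  empty <- build_network(c("gA", "gB", "gC"), assoc, seqs, list(A6 = pwm_A6),
    background = replicate(50, random_seq(80, c("C", "G", "T"))),
    edge_alpha = 0
  )
  expect_equal(nrow(empty$edges), 0L)
})

test_that("summit offsets are strand-normalized and window-limited", {
  acrs <- tibble::tibble(
    acr_id = c("p", "m", "far"), chrom = "chr1",
    start = c(1000L, 5000L, 9000L), end = c(1200L, 5200L, 9200L),
    summit = c(1100L, 5100L, 9100L)
  )
  chip <- tibble::tibble(
    chrom = "chr1",
    summit = c(1350L, 4850L, 20000L) # +250 / -250 / out of window
  )
  strands <- tibble::tibble(acr_id = c("p", "m", "far"), strand = c("+", "-", "+"))
  off <- summit_offset(acrs, chip, strand_by = strands, window = 2000)
  expect_equal(off$offset[off$acr_id == "p"], 250L)
  expect_equal(off$offset[off$acr_id == "m"], 250L) # flipped on minus strand
  expect_true(is.na(off$offset[off$acr_id == "far"]))
})

test_that("planted 250 bp ChIP offsets are recovered within the CLT bound", {
  # one ACR per gene so each ACR's nearest ChIP summit is its own planted one
  ann <- simulate_annotation(400, n_acrs = 400, seed = 33)
  chip <- simulate_chip_summits(ann, offset = 250, jitter_sd = 30, seed = 34)
  strands <- tibble::tibble(
    acr_id = ann$truth$acr_id,
    strand = ann$genes$strand[match(ann$truth$host_gene, ann$genes$gene_id)]
  )
  off <- summit_offset(ann$acrs, chip, strand_by = strands, window = 2000)
  # nearest-peak matching can pick a neighbor, but the planted geometry is
  # sparse enough that the mean stays well within +/- 15 bp of 250 at n = 400
  expect_equal(mean(off$offset, na.rm = TRUE), 250, tolerance = 15 / 250)
})
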