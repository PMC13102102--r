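# Motif scanning, enrichment against a background set, clock regulatory
# network assembly, and histone-mark summit-offset geometry. Scanning is a
# plain log2-odds PWM scan on both strands; enrichment is a one-sided
# Fisher exact test on sequences-with-hit counts, BH-adjusted across
# motifs.

#' Construct a position weight matrix object
#'
#' @param matrix Numeric 4 x L matrix of per-position base probabilities,
#'   rows A, C, G, T; each column must sum to 1 (within 1e-9). Count
#'   matrices are normalized with a small pseudocount.
#' @param motif_id Identifier.
#' @param name Optional display name.
#' @param background Named base frequencies (default uniform).
#' @return An object of class `chrono_pwm`.
#' @export
pwm <- function(matrix, motif_id, name = motif_id,
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  matrix <- as.matrix(matrix)
  stopifnot(nrow(matrix) == 4L, ncol(matrix) >= 4L)
  rownames(matrix) <- c("A", "C", "G", "T")
  csums <- colSums(matrix)
  if (any(abs(csums - 1) > 1e-9)) {
    matrix <- sweep(matrix + 0.01, 2L, colSums(matrix + 0.01), "/")
  }
  structure(
    list(
      motif_id = motif_id, name = name, matrix = matrix,
      background = background[c("A", "C", "G", "T")]
    ),
    class = "chrono_pwm"
  )
}

#' @export
print.chrono_pwm <- function(x, ...) {
  cat(sprintf("<PWM %s (%s), length %d>\n", x$motif_id, x$name, ncol(x$matrix)))
  invisible(x)
}

#' Read position weight matrices from JASPAR-format text
#'
#' Parses the JASPAR matrix dialect: a `>ID name` header followed by four
#' rows `A [ counts... ]` (brackets optional). Counts are normalized to
#' per-column probabilities with a small pseudocount.
#'
#' @param path Path to a JASPAR-style matrix file.
#' @param background Named base frequencies for all motifs.
#' @return A named list of `chrono_pwm` objects.
#' @export
read_jaspar <- function(path, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) {
    abort("no '>' motif headers found", class = "chronoaccess_parse_error")
  }
  out <- list()
  for (i in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    parts <- strsplit(hdr, "\\s+")[[1]]
    id <- parts[1]
    name <- if (length(parts) > 1L) parts[2] else id
    stop_at <- if (i < length(starts)) starts[i + 1] - 1L else length(lines)
    block <- lines[(starts[i] + 1L):stop_at]
    if (length(block) < 4L) {
      abort(sprintf("motif %s: expected 4 matrix rows", id),
        class = "chronoaccess_parse_error"
      )
    }
    rows <- lapply(block[1:4], function(l) {
      stripped <- sub("^\\s*[ACGTacgt]", "", l)
      as.numeric(regmatches(stripped, gregexpr("[0-9.]+", stripped))[[1]])
    })
    if (length(unique(lengths(rows))) != 1L) {
      abort(sprintf("motif %s: ragged matrix rows", id),
        class = "chronoaccess_parse_error"
      )
    }
    mat <- do.call(rbind, rows)
    out[[id]] <- pwm(mat, motif_id = id, name = name, background = background)
  }
  out
}

revcomp <- function(seq) {
  chartr("ACGTacgtN", "TGCAtgcaN", vapply(seq, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

pwm_max_score <- function(p) {
  lo <- log2(p$matrix / p$background)
  sum(apply(lo, 2L, max))
}

scan_one_strand <- function(chars, lo) {
  L <- ncol(lo)
  n <- length(chars)
  if (n < L) {
    return(numeric(0))
  }
  idx <- match(chars, c("A", "C", "G", "T"))
  idx[is.na(idx)] <- 5L # N and anything else contributes log-odds 0
  lo5 <- rbind(lo, 0)
  s <- numeric(n - L + 1L)
  for (j in seq_len(L)) {
    s <- s + lo5[cbind(idx[j:(j + n - L)], j)]
  }
  s
}

#' Scan a DNA sequence with a PWM on both strands
#'
#' Log2-odds scoring against the PWM background; `N` (or any non-ACGT
#' character) contributes 0 at its position. Positions are 1-based starts
#' of the match on the forward sequence; minus-strand hits are reported at
#' the forward-strand start of the reverse-complement match.
#'
#' @param seq A DNA string over A/C/G/T/N.
#' @param pwm A `chrono_pwm`.
#' @param score_threshold Minimum log2-odds score for a hit; default 80% of
#'   the motif's maximum attainable score.
#' @return A tibble `position`, `strand`, `score`, ordered by position.
#' @export
pwm_scan <- function(seq, pwm, score_threshold = NULL) {
  stopifnot(inherits(pwm, "chrono_pwm"), length(seq) == 1L)
  if (is.null(score_threshold)) score_threshold <- 0.8 * pwm_max_score(pwm)
  lo <- log2(pwm$matrix / pwm$background)
  L <- ncol(lo)
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  fwd <- scan_one_strand(chars, lo)
  rev_chars <- strsplit(revcomp(toupper(seq)), "")[[1]]
  rev <- scan_one_strand(rev_chars, lo)
  hits_f <- which(fwd >= score_threshold)
  hits_r <- which(rev >= score_threshold)
  out <- bind_rows(
    tibble(position = hits_f, strand = "+", score = fwd[hits_f]),
    tibble(
      position = n - (hits_r + L - 1L) + 1L, strand = "-",
      score = rev[hits_r]
    )
  )
  arrange(out, .data$position, .data$strand)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: permutes a sequence while preserving its
#' exact dinucleotide (and hence mononucleotide) composition, by drawing a
#' random Eulerian walk on the dinucleotide transition multigraph.
#'
#' @param seq A DNA string.
#' @return A shuffled string of the same length and dinucleotide counts.
#' @export
shuffle_dinucleotide <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n <= 2L) {
    return(seq)
  }
  verts <- unique(chars)
  edges <- split(chars[-1], factor(chars[-n], levels = verts))
  last <- chars[n]
  # pick a random last-exit edge per vertex (except the terminal vertex)
  # that forms a tree toward the terminal vertex, then shuffle the rest
  repeat {
    last_exit <- lapply(verts, function(v) {
      if (v == last || length(edges[[v]]) == 0L) {
        return(NULL)
      }
      sample(edges[[v]], 1L)
    })
    names(last_exit) <- verts
    # check connectivity: following last-exit edges from every vertex
    # must reach `last`
    ok <- all(vapply(verts, function(v) {
      seen <- character(0)
      while (!is.null(last_exit[[v]]) && !(v %in% seen) && v != last) {
        seen <- c(seen, v)
        v <- last_exit[[v]]
      }
      v == last || length(edges[[v]]) == 0L
    }, logical(1)))
    if (ok) break
  }
  pools <- lapply(verts, function(v) {
    pool <- edges[[v]]
    le <- last_exit[[v]]
    if (!is.null(le)) {
      pool <- pool[-match(le, pool)]
    }
    if (length(pool) > 1L) pool <- sample(pool)
    c(pool, le)
  })
  names(pools) <- verts
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- chars[1]
  v <- chars[1]
  for (i in 2:n) {
    nxt <- pools[[v]][ptr[[v]]]
    ptr[[v]] <- ptr[[v]] + 1L
    out[i] <- nxt
    v <- nxt
  }
  paste(out, collapse = "")
}

count_hit_seqs <- function(seqs, pwm, score_threshold) {
  sum(vapply(seqs, function(s) {
    nrow(pwm_scan(s, pwm, score_threshold)) > 0L
  }, logical(1)))
}

#' Motif enrichment of a foreground sequence set against a background
#'
#' Counts sequences containing at least one PWM hit in foreground and
#' background, tests the 2x2 table with a one-sided (greater) Fisher exact
#' test per motif, and BH-adjusts across motifs. `%TP` is the percent of
#' foreground sequences with a hit.
#'
#' @param foreground Character vector of DNA sequences.
#' @param pwms A `chrono_pwm` or list of them.
#' @param background Character vector of background sequences; by default a
#'   dinucleotide shuffle of the foreground (seeded).
#' @param score_threshold Minimum hit score; default per motif, 80% of its
#'   maximum.
#' @param shuffle_seed Seed for the default background shuffle.
#' @return A tibble per motif: `motif_id`, `foreground_hits`,
#'   `foreground_total`, `background_hits`, `background_total`, `p_value`,
#'   `adjusted_p`, `pct_tp`.
#' @export
motif_enrich <- function(foreground, pwms, background = NULL,
                         score_threshold = NULL, shuffle_seed = 1) {
  if (inherits(pwms, "chrono_pwm")) pwms <- list(pwms)
  stopifnot(length(foreground) > 0L)
  if (is.null(background)) {
    set.seed(shuffle_seed)
    background <- vapply(foreground, shuffle_dinucleotide, character(1),
      USE.NAMES = FALSE
    )
  }
  res <- map(pwms, function(p) {
    fg <- count_hit_seqs(foreground, p, score_threshold)
    bg <- count_hit_seqs(background, p, score_threshold)
    tab <- matrix(
      c(
        fg, length(foreground) - fg,
        bg, length(background) - bg
      ),
      nrow = 2L, byrow = TRUE
    )
    tibble(
      motif_id = p$motif_id,
      foreground_hits = fg, foreground_total = length(foreground),
      background_hits = bg, background_total = length(background),
      p_value = fisher.test(tab, alternative = "greater")$p.value,
      pct_tp = 100 * fg / length(foreground)
    )
  }) |> list_rbind()
  mutate(res, adjusted_p = p.adjust(.data$p_value, method = "BH")) |>
    select(
      "motif_id", "foreground_hits", "foreground_total",
      "background_hits", "background_total", "p_value", "adjusted_p", "pct_tp"
    )
}

#' Assemble the clock regulatory network from per-gene motif enrichments
#'
#' For every clock gene, tests each motif for enrichment in the sequences
#' of the gene's associated ACRs against a shared background, and draws an
#' edge TF -> gene for every motif passing `edge_alpha` (raw p by default,
#' matching a per-gene enrichment screen; set `adjusted = TRUE` to gate on
#' the BH-adjusted value instead).
#'
#' @param clock_genes Character vector of target clock gene ids.
#' @param associations Tibble `gene_id`, `acr_id` (see [associate_acrs()]).
#' @param acr_seqs Named character vector: ACR id -> DNA sequence.
#' @param pwms Named list of `chrono_pwm`.
#' @param motif_tf Tibble `motif_id`, `tf_gene_id` mapping motifs to the
#'   transcription factor genes they represent; defaults to using the motif
#'   id as the TF id.
#' @param background Background sequences shared by all genes; default a
#'   dinucleotide shuffle of all ACR sequences.
#' @param edge_alpha Edge significance threshold (default 0.005).
#' @param adjusted Gate edges on the BH-adjusted p instead of the raw p.
#' @param score_threshold Passed to the scanner.
#' @param shuffle_seed Seed for the default background.
#' @return An object of class `chrono_network`: list with `edges` (tibble
#'   `tf_gene_id`, `target_gene_id`, `motif_id`, `p_value`, `adjusted_p`,
#'   `n_acrs`), `enrichments` (per gene x motif), and `summary` (tibble
#'   with node/edge counts and mean edges per ACR).
#' @export
build_network <- function(clock_genes, associations, acr_seqs, pwms,
                          motif_tf = NULL, background = NULL,
                          edge_alpha = 0.005, adjusted = FALSE,
                          score_threshold = NULL, shuffle_seed = 1) {
  if (inherits(pwms, "chrono_pwm")) pwms <- list(pwms)
  if (is.null(motif_tf)) {
    motif_tf <- tibble(
      motif_id = unname(map_chr(pwms, "motif_id")),
      tf_gene_id = unname(map_chr(pwms, "motif_id"))
    )
  }
  if (is.null(background)) {
    set.seed(shuffle_seed)
    background <- vapply(unname(acr_seqs), shuffle_dinucleotide, character(1))
  }
  enr <- map(clock_genes, function(g) {
    acrs <- associations$acr_id[associations$gene_id == g]
    acrs <- intersect(acrs, names(acr_seqs))
    if (length(acrs) == 0L) {
      return(NULL)
    }
    motif_enrich(unname(acr_seqs[acrs]), pwms,
      background = background,
      score_threshold = score_threshold
    ) |>
      mutate(target_gene_id = g, n_acrs = length(acrs), .before = 1L)
  }) |> list_rbind()
  gate <- if (adjusted) enr$adjusted_p else enr$p_value
  edges <- enr[!is.na(gate) & gate < edge_alpha, ] |>
    inner_join(motif_tf, by = "motif_id") |>
    select(
      "tf_gene_id", "target_gene_id", "motif_id",
      "p_value", "adjusted_p", "n_acrs"
    )
  n_acr_total <- length(unique(associations$acr_id[associations$gene_id %in% clock_genes]))
  summary <- tibble(
    n_genes = length(unique(c(edges$tf_gene_id, edges$target_gene_id))),
    n_edges = nrow(edges),
    n_acrs = n_acr_total,
    mean_edges_per_acr = if (n_acr_total > 0L) nrow(edges) / n_acr_total else NA_real_
  )
  structure(list(edges = edges, enrichments = enr, summary = summary),
    class = "chrono_network"
  )
}

#' @export
print.chrono_network <- function(x, ...) {
  cat(sprintf(
    "<clock network: %d genes, %d edges (%.2f edges/ACR)>\n",
    x$summary$n_genes, x$summary$n_edges, x$summary$mean_edges_per_acr
  ))
  invisible(x)
}

#' @export
tidy.chrono_network <- function(x, ...) x$edges

#' @export
glance.chrono_network <- function(x, ...) x$summary

#' Signed strand-normalized offsets from ACR summits to ChIP peak summits
#'
#' For each ACR with a summit, finds the nearest ChIP peak summit within
#' `window` bp on the same chromosome and reports the signed offset
#' (ChIP summit minus ACR summit), with the sign flipped on minus-strand
#' genes so that positive always means downstream of the ACR.
#'
#' @param acrs Tibble of ACRs with a `summit` column.
#' @param chip_peaks Tibble with `chrom`, `summit` (and optionally
#'   `peak_id`).
#' @param strand_by Tibble `acr_id`, `strand` giving each ACR's host-gene
#'   strand; ACRs without a strand are assumed `+`.
#' @param window Maximum search distance in bp (default 2000).
#' @return A tibble `acr_id`, `offset` (bp, `NA` when no peak lies within
#'   the window).
#' @export
summit_offset <- function(acrs, chip_peaks, strand_by = NULL, window = 2000) {
  stopifnot("summit" %in% names(acrs))
  strand <- rep("+", nrow(acrs))
  if (!is.null(strand_by)) {
    idx <- match(acrs$acr_id, strand_by$acr_id)
    strand[!is.na(idx)] <- strand_by$strand[idx[!is.na(idx)]]
  }
  offset <- rep(NA_integer_, nrow(acrs))
  for (ch in unique(acrs$chrom)) {
    ai <- which(acrs$chrom == ch & !is.na(acrs$summit))
    cp <- chip_peaks$summit[chip_peaks$chrom == ch]
    if (length(ai) == 0L || length(cp) == 0L) next
    for (i in ai) {
      d <- cp - acrs$summit[i]
      j <- which.min(abs(d))
      if (abs(d[j]) <= window) offset[i] <- d[j]
    }
  }
  sign <- ifelse(strand == "-", -1L, 1L)
  tibble(acr_id = acrs$acr_id, strand = strand, offset = sign * offset)
}
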