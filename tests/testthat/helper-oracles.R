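# Independent brute-force oracles and small fixture builders used across
# the test files. These deliberately share no code with the package
# internals they check.

# Naive per-read tag counting: one environment-based tally loop.
naive_count_tags <- function(reads, min_mapq = 0L, primary_only = TRUE) {
  env <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(reads))) {
    if (reads$mapq[i] < min_mapq) next
    if (primary_only && !reads$is_primary[i]) next
    pos <- if (reads$strand[i] == "+") reads$start[i] else reads$end[i] - 1L
    key <- paste(reads$chrom[i], pos, reads$strand[i])
    env[[key]] <- (if (is.null(env[[key]])) 0L else env[[key]]) + 1L
  }
  keys <- ls(env)
  if (!length(keys)) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), count = integer()))
  }
  parts <- strsplit(keys, " ")
  df <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    pos = as.integer(vapply(parts, `[`, "", 2)),
    strand = vapply(parts, `[`, "", 3),
    count = vapply(keys, function(k) env[[k]], integer(1)),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$chrom, df$pos, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Direct evaluation of the two classification inequalities for a single
# (tpm_all, tpm_ct, tpm_cip) triple.
naive_classify <- function(tpm_all, tpm_ct, tpm_cip,
                           min_tpm = 1, hc_ratio = 1, cip_threshold = 4) {
  if (tpm_all < min_tpm) {
    return(list(status = "not_candidate", pol_class = "unassigned",
                quadrant = "none"))
  }
  er <- if (tpm_ct == 0) Inf else tpm_all / tpm_ct
  cr <- if (tpm_cip == 0) Inf else tpm_all / tpm_cip
  hc <- er >= hc_ratio
  sens <- cr >= cip_threshold
  list(
    status = if (hc) "high_confidence" else "false_positive",
    pol_class = if (!hc) "unassigned" else if (sens) "non_pol2" else "pol2",
    quadrant = if (hc) {
      if (sens) "II" else "IV"
    } else {
      if (sens) "I" else "III"
    }
  )
}

# All-pairs scan for closest-downstream-exon assignment.
naive_assign <- function(tss, genes, max_upstream = 200L) {
  out <- data.frame(gene_id = rep(NA_character_, nrow(tss)),
                    distance = rep(NA_integer_, nrow(tss)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tss))) {
    best_d <- Inf
    best_j <- NA_integer_
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != tss$chrom[i] ||
          genes$strand[j] != tss$strand[i]) next
      p <- tss$pos[i]
      if (p >= genes$start[j] && p < genes$end[j]) {
        d <- 0L
      } else if (tss$strand[i] == "+" && genes$start[j] > p) {
        d <- genes$start[j] - p
      } else if (tss$strand[i] == "-" && genes$end[j] - 1L < p) {
        d <- p - (genes$end[j] - 1L)
      } else {
        next  # exon upstream of the TSS in gene orientation
      }
      if (d < best_d) {
        best_d <- d
        best_j <- j
      }
    }
    if (!is.na(best_j) && best_d <= max_upstream) {
      out$gene_id[i] <- genes$gene_id[best_j]
      out$distance[i] <- as.integer(best_d)
    }
  }
  out
}

# Random read fixture covering both strands, MAPQ spread, secondary
# alignments and 5' soft clips.
random_reads <- function(n, seed, n_chrom = 3L, softclip = TRUE) {
  withr::with_seed(seed, {
    chrom <- sample(sprintf("chr%d", seq_len(n_chrom)), n, replace = TRUE)
    start <- sample.int(10000L, n, replace = TRUE)
    len <- sample(30:60, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    clip <- if (softclip) sample(0:3, n, replace = TRUE) else rep(0L, n)
    clip_seq <- vapply(clip, function(k) {
      paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
    }, character(1))
    aligned_reads(chrom = chrom, start = start, end = start + len,
                  strand = strand,
                  mapq = sample(0:60, n, replace = TRUE),
                  is_primary = runif(n) > 0.1,
                  five_prime_softclip = clip, softclip_seq = clip_seq)
  })
}

expect_tables_equal <- function(tab, oracle) {
  testthat::expect_equal(tab$chrom, oracle$chrom)
  testthat::expect_equal(tab$pos, oracle$pos)
  testthat::expect_equal(tab$strand, oracle$strand)
  testthat::expect_equal(tab$count, oracle$count)
}
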