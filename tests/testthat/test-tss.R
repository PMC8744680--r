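# Candidate calling, high-confidence filtering, polymerase
# classification and serialization of the calls object.

make_tables <- function(df, ls = 1e6) {
  # df: chrom/pos/strand + count_all/count_ct/count_cip
  list(
    all = tag_count_table(df$chrom, df$pos, df$strand, df$count_all, ls),
    ct = tag_count_table(df$chrom[df$count_ct > 0], df$pos[df$count_ct > 0],
                         df$strand[df$count_ct > 0],
                         df$count_ct[df$count_ct > 0], ls),
    cip = tag_count_table(df$chrom[df$count_cip > 0],
                          df$pos[df$count_cip > 0],
                          df$strand[df$count_cip > 0],
                          df$count_cip[df$count_cip > 0], ls)
  )
}

test_that("candidate threshold is inclusive at min_tpm", {
  ls <- 1e6  # 1 count == 1 TPM
  tab <- tag_count_table("chr1", c(1L, 2L, 3L), rep("+", 3),
                         c(1L, 2L, 10L), ls)
  # fractional TPM below threshold via a larger library
  tab_small <- tag_count_table("chr1", 1L, "+", 99L, 1e8)  # 0.99 TPM
  expect_equal(nrow(call_candidates(tab_small)$tss), 0L)
  x <- call_candidates(tab)
  expect_equal(nrow(x$tss), 3L)               # TPM exactly 1 included
  expect_true(all(x$tss$status == "candidate"))
  expect_equal(nrow(call_candidates(tag_count_table(library_size = 1))$tss),
               0L)
})

test_that("high-confidence filtering follows the enrichment ratio", {
  df <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                   strand = "+",
                   count_all = c(10L, 10L, 5L),
                   count_ct = c(5L, 20L, 0L),
                   count_cip = c(1L, 1L, 1L))
  tt <- make_tables(df)
  x <- filter_high_confidence(call_candidates(tt$all), tt$ct)
  expect_equal(x$tss$enrich_ratio, c(2, 0.5, Inf))
  expect_equal(x$tss$status,
               c("high_confidence", "false_positive", "high_confidence"))
})

test_that("polymerase classification follows the CIP ratio", {
  df <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L), strand = "+",
                   count_all = c(10L, 8L, 4L),
                   count_ct = c(0L, 0L, 0L),
                   count_cip = c(1L, 8L, 0L))
  tt <- make_tables(df)
  x <- call_tss(tt$all, tt$ct, tt$cip)
  expect_equal(x$tss$cip_ratio, c(10, 1, Inf))
  expect_equal(x$tss$pol_class, c("non_pol2", "pol2", "non_pol2"))
  expect_equal(x$tss$quadrant, c("II", "IV", "II"))
})

test_that("classification requires high-confidence filtering first", {
  tab <- tag_count_table("chr1", 1L, "+", 10L, 1e6)
  x <- call_candidates(tab)
  expect_error(classify_polymerase(x, tab), regexp = "filter_high_confidence")
})

test_that("candidates partition into HC/FP and HC into pol2/non_pol2", {
  reads <- random_reads(2000L, seed = 31L, softclip = FALSE)
  tabs <- lapply(c(41L, 42L, 43L), function(s) {
    count_tags(random_reads(2000L, seed = s, softclip = FALSE))
  })
  x <- call_tss(tabs[[1]], tabs[[2]], tabs[[3]])
  rec <- x$tss
  expect_true(all(rec$status %in% c("high_confidence", "false_positive")))
  hc <- rec[rec$status == "high_confidence", ]
  expect_true(all(hc$pol_class %in% c("pol2", "non_pol2")))
  expect_true(all(rec$pol_class[rec$status == "false_positive"] ==
                  "unassigned"))
  q <- table(factor(rec$quadrant, c("I", "II", "III", "IV")))
  expect_equal(q[["II"]] + q[["IV"]], nrow(hc))
  expect_equal(sum(q), nrow(rec))
})

test_that("raising the CIP library signal never flips pol2 to non_pol2", {
  ls <- 1e6
  all_tab <- tag_count_table("chr1", 1L, "+", 10L, ls)
  ct_tab <- tag_count_table("chr1", 1L, "+", 1L, ls)
  classes <- vapply(c(1L, 2L, 5L, 10L, 40L), function(cip_count) {
    cip_tab <- tag_count_table("chr1", 1L, "+", cip_count, ls)
    call_tss(all_tab, ct_tab, cip_tab)$tss$pol_class
  }, character(1))
  # cip_ratio decreases along the sequence: once pol2, always pol2
  first_pol2 <- match("pol2", classes)
  expect_true(all(classes[first_pol2:length(classes)] == "pol2"))
})

test_that("classification is invariant under joint library-size rescaling", {
  df <- data.frame(chrom = "chr1", pos = seq(10L, 60L, 10L), strand = "+",
                   count_all = c(10L, 3L, 8L, 2L, 50L, 7L),
                   count_ct = c(5L, 9L, 0L, 2L, 10L, 7L),
                   count_cip = c(1L, 0L, 8L, 2L, 5L, 30L))
  base <- make_tables(df, ls = 1e6)
  x1 <- call_tss(base$all, base$ct, base$cip, min_tpm = 1)
  scaled <- make_tables(df, ls = 4e6)
  x2 <- call_tss(scaled$all, scaled$ct, scaled$cip, min_tpm = 0.25)
  expect_equal(x1$tss$status, x2$tss$status)
  expect_equal(x1$tss$pol_class, x2$tss$pol_class)
  expect_equal(x1$tss$quadrant, x2$tss$quadrant)
})

test_that("pseudocount regularizes the zero-denominator ratios", {
  df <- data.frame(chrom = "chr1", pos = 10L, strand = "+",
                   count_all = 5L, count_ct = 0L, count_cip = 0L)
  tt <- make_tables(df)
  x <- call_tss(tt$all, tt$ct, tt$cip, pseudocount = 1)
  expect_true(is.finite(x$tss$enrich_ratio))
  expect_equal(x$tss$enrich_ratio, 6 / 1)
})

test_that("mitochondrial unique-mapping filter keeps ratio >= 0.8", {
  tal <- data.frame(chrom = "MT", pos = c(1L, 2L, 3L), strand = "+",
                    n_unique = c(8L, 7L, 0L), n_total = c(10L, 10L, 0L))
  expect_warning(kept <- mito_unique_filter(tal), regexp = "no tags")
  expect_equal(kept$pos, 1L)
  expect_equal(kept$ratio, 0.8)
})

test_that("mapq_unique_tallies counts unique tags per position", {
  reads <- aligned_reads(chrom = rep("MT", 4), start = c(5L, 5L, 5L, 9L),
                         end = c(55L, 55L, 60L, 59L), strand = "+",
                         mapq = c(60L, 3L, 60L, 2L))
  tal <- mapq_unique_tallies(reads, mapq_threshold = 3L)
  expect_equal(tal$n_total, c(3L, 1L))
  expect_equal(tal$n_unique, c(2L, 0L))
})

test_that("bedGraph writer encodes the class in the value's sign", {
  df <- data.frame(chrom = c("chr1", "chr5"), pos = c(100L, 500L),
                   strand = c("+", "-"),
                   count_all = c(3L, 5L), count_ct = c(0L, 0L),
                   count_cip = c(3L, 1L))
  tt <- make_tables(df, ls = 1e6)
  x <- call_tss(tt$all, tt$ct, tt$cip)
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(x, path)
  lines <- readLines(path)
  expect_equal(lines[1], "chr1\t100\t101\t3")   # pol2 -> positive
  expect_equal(lines[2], "chr5\t500\t501\t-5")  # non_pol2 -> negative
  back <- read_bedgraph(path)
  expect_equal(back$pol_class, c("pol2", "non_pol2"))
  expect_equal(back$tpm_all, c(3, 5))
  # unclassified records are refused
  y <- filter_high_confidence(call_candidates(tt$all), tt$ct)
  expect_error(write_bedgraph(y, path), regexp = "unclassified")
})

test_that("BED6 and TSS-table round trips are lossless", {
  reads <- random_reads(500L, seed = 61L, softclip = FALSE)
  tabs <- lapply(c(61L, 62L, 63L), function(s) {
    count_tags(random_reads(500L, seed = s, softclip = FALSE))
  })
  x <- call_tss(tabs[[1]], tabs[[2]], tabs[[3]])
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed6(x, bed)
  back <- read_bed6(bed)
  hc <- x$tss[x$tss$status == "high_confidence", ]
  expect_equal(back$pos, hc$pos)
  expect_equal(back$strand, hc$strand)
  expect_equal(back$tpm_all, hc$tpm_all)
  expect_equal(back$pol_class, hc$pol_class)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_tss_table(x, tsv)
  y <- read_tss_table(tsv)
  expect_equal(y$tss, x$tss)
  expect_equal(y$params, x$params)
  expect_equal(y$library_sizes, x$library_sizes)
})

test_that("print, summary and plot methods run and report the headline numbers", {
  df <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L), strand = "+",
                   count_all = c(10L, 10L, 10L, 10L),
                   count_ct = c(1L, 1L, 1L, 20L),
                   count_cip = c(10L, 1L, 10L, 1L))
  tt <- make_tables(df)
  x <- call_tss(tt$all, tt$ct, tt$cip)
  s <- summary(x)
  expect_equal(s$n_candidates, 4L)
  expect_equal(s$n_high_confidence, 3L)
  expect_equal(s$hc_fraction_pct, 75)
  expect_equal(s$n_non_pol2, 1L)
  expect_equal(s$non_pol2_share_pct, 100 / 3)
  expect_output(print(x), "high confidence: 3")
  expect_output(print(s), "non-Pol II 1")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(x))
})
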