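# Gene assignment, locus clustering, positional and compositional
# profiles, interval overlap.

toy_genes <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC"),
    gene_type = c("protein_coding", "tRNA", "protein_coding"),
    transcript_id = c("gA.t1", "gB.t1", "gC.t1"),
    chrom = "chr1",
    strand = c("+", "+", "-"),
    start = c(1100L, 5000L, 8000L),
    end = c(1200L, 5100L, 8100L),
    stringsAsFactors = FALSE
  )
}

test_that("TSSs are assigned to the closest downstream exon within range", {
  tss <- data.frame(chrom = "chr1",
                    pos = c(1000L, 850L, 1150L, 8150L, 8350L),
                    strand = c("+", "+", "+", "-", "-"))
  asg <- assign_tss_to_genes(tss, toy_genes(), max_upstream = 200L)
  expect_equal(asg$gene_id, c("gA", NA, "gA", "gC", NA))
  expect_equal(asg$distance, c(100L, NA, 0L, 51L, NA))
})

test_that("exons upstream of the TSS are never assignment candidates", {
  # + strand TSS downstream of gA's exon: past the gene, not assignable
  tss <- data.frame(chrom = "chr1", pos = 1250L, strand = "+")
  genes <- toy_genes()[1, ]
  asg <- assign_tss_to_genes(tss, genes, max_upstream = 200L)
  expect_true(is.na(asg$gene_id))
})

test_that("assignment at exactly max_upstream is inclusive and ties break by input order", {
  tss <- data.frame(chrom = "chr1", pos = 900L, strand = "+")
  genes <- toy_genes()[1, ]
  expect_equal(assign_tss_to_genes(tss, genes, 200L)$gene_id, "gA")
  expect_true(is.na(assign_tss_to_genes(tss, genes, 199L)$gene_id))
  # two exons starting at the same coordinate: first annotation row wins
  dup <- rbind(toy_genes()[1, ], toy_genes()[1, ])
  dup$gene_id <- c("first", "second")
  expect_equal(assign_tss_to_genes(tss, dup, 200L)$gene_id, "first")
})

test_that("assignment agrees with a brute-force all-pairs scan", {
  fixture <- withr::with_seed(77L, {
    list(
      tss = data.frame(chrom = sample(c("chr1", "chr2"), 200, TRUE),
                       pos = sample.int(20000L, 200),
                       strand = sample(c("+", "-"), 200, TRUE)),
      genes = {
        s <- sample.int(20000L, 80)
        data.frame(gene_id = sprintf("g%02d", 1:80),
                   gene_type = "misc", transcript_id = sprintf("t%02d", 1:80),
                   chrom = sample(c("chr1", "chr2"), 80, TRUE),
                   strand = sample(c("+", "-"), 80, TRUE),
                   start = s, end = s + sample(50:500, 80, TRUE),
                   stringsAsFactors = FALSE)
      }
    )
  })
  asg <- assign_tss_to_genes(fixture$tss, fixture$genes, 200L)
  oracle <- naive_assign(fixture$tss, fixture$genes, 200L)
  expect_equal(asg$gene_id, oracle$gene_id)
  expect_equal(asg$distance, oracle$distance)
})

test_that("locus clustering chains positions within the gap", {
  one <- data.frame(chrom = "chr1", pos = 100L, strand = "+")
  expect_equal(nrow(cluster_unannotated(one)), 1L)
  two <- data.frame(chrom = "chr1", pos = c(100L, 115L, 140L), strand = "+")
  loci <- cluster_unannotated(two, max_gap = 20L)
  expect_equal(nrow(loci), 2L)
  expect_equal(loci$n_tss, c(2L, 1L))
  chain <- data.frame(chrom = "chr1", pos = c(100L, 118L, 136L), strand = "+")
  expect_equal(nrow(cluster_unannotated(chain, 20L)), 1L)  # single linkage
})

test_that("clustering is order-independent, strand-separated and monotone in the gap", {
  tss <- withr::with_seed(5L, data.frame(
    chrom = sample(c("chr1", "chr2"), 300, TRUE),
    pos = sample.int(5000L, 300, replace = TRUE),
    strand = sample(c("+", "-"), 300, TRUE)
  ))
  a <- cluster_unannotated(tss, 20L)
  b <- cluster_unannotated(tss[withr::with_seed(6L, sample(nrow(tss))), ], 20L)
  expect_identical(a, b)
  # same position on both strands stays in strand-specific loci
  expect_true(all(table(paste(a$chrom, a$strand)) >= 1))
  n_loci <- vapply(c(5L, 20L, 100L), function(g) {
    nrow(cluster_unannotated(tss, g))
  }, integer(1))
  expect_true(all(diff(n_loci) <= 0))
})

test_that("anchor-relative offsets are strand-oriented", {
  anchors <- data.frame(chrom = "chr1", pos = c(1000L, 2000L),
                        strand = c("+", "-"))
  tss <- data.frame(chrom = "chr1", pos = c(995L, 1000L, 2007L),
                    strand = c("+", "+", "-"))
  h <- relative_position_histogram(tss, anchors, window = 50L)
  expect_equal(h[["-5"]], 1L)   # 5 bp upstream of the + anchor
  expect_equal(h[["0"]], 1L)
  expect_equal(h[["-7"]], 1L)   # upstream of the - anchor at pos + 7
})

test_that("base composition is strand-oriented and excludes edge TSSs", {
  genome <- Biostrings::DNAStringSet(c(chrA = "AACATGGG"))
  # + TSS at pos 3 (0-based): -1 base "C" (pos 2), +1 base "A" (pos 3)
  tss_p <- data.frame(chrom = "chrA", pos = 3L, strand = "+")
  bc <- base_composition_profile(tss_p, genome, flank = 1L)
  expect_equal(bc$frac_plus1_AG, 1)
  expect_equal(bc$frac_minus1_CT, 1)
  expect_equal(bc$freq["0", "A"], 1)
  # same position read on the minus strand: +1 base is complement "T"
  tss_m <- data.frame(chrom = "chrA", pos = 3L, strand = "-")
  bm <- base_composition_profile(tss_m, genome, flank = 1L)
  expect_equal(bm$freq["0", "T"], 1)
  expect_equal(bm$frac_plus1_AG, 0)
  # TSS at the contig edge is excluded and counted
  edge <- data.frame(chrom = "chrA", pos = c(0L, 3L), strand = "+")
  be <- base_composition_profile(edge, genome, flank = 1L)
  expect_equal(be$n_used, 1L)
  expect_equal(be$n_excluded, 1L)
})

test_that("composition over a uniform random genome approaches 0.25 per base", {
  cfg <- sim_config(genome_length = 50000L, seed = 13L)
  genome <- make_genome(cfg)
  tss <- withr::with_seed(14L, data.frame(
    chrom = "simchr1", pos = sample(100:49900, 2000),
    strand = sample(c("+", "-"), 2000, TRUE)
  ))
  bc <- base_composition_profile(tss, genome, flank = 5L)
  # binomial sampling bound: 0.25 +/- 4 s.e. at n = 2000
  se <- sqrt(0.25 * 0.75 / 2000)
  expect_true(all(abs(bc$freq - 0.25) < 4 * se))
})

test_that("interval overlap is inclusive at start, exclusive at end", {
  iv <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  tss <- data.frame(chrom = "chr1", pos = c(100L, 199L, 200L, 50L),
                    strand = "+")
  ov <- interval_overlap(tss, iv)
  expect_equal(ov$hit, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(ov$interval_counts, 2L)
  bad <- data.frame(chrom = "chr1", start = 200L, end = 100L)
  expect_error(interval_overlap(tss, bad), regexp = "line 1")
})

test_that("every TSS lands in exactly one gene or one locus", {
  genes <- toy_genes()
  tss <- withr::with_seed(9L, data.frame(
    chrom = "chr1", pos = sample.int(10000L, 150),
    strand = sample(c("+", "-"), 150, TRUE)
  ))
  asg <- assign_tss_to_genes(tss, genes, 200L)
  unassigned <- tss[is.na(asg$gene_id), , drop = FALSE]
  loci <- cluster_unannotated(unassigned, 20L)
  expect_equal(sum(loci$n_tss), nrow(unique(unassigned)))
  expect_equal(sum(!is.na(asg$gene_id)) + nrow(unique(unassigned)),
               nrow(unique(tss)))
})

test_that("GTF gene models round-trip through rtracklayer import", {
  cfg <- sim_config(seed = 2L, genes_per_class = c(capped = 3L, ppp = 2L,
                                                   methyl_ppp = 1L,
                                                   processed = 1L))
  genome <- make_genome(cfg)
  pg <- place_genes(cfg, genome)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_sim_gtf(pg$genes, path)
  gm <- read_gene_models(path)
  expect_equal(nrow(gm), nrow(pg$genes))
  expect_setequal(gm$gene_id, pg$genes$gene_id)
  # exon span covers the unit and the 5' end matches the true TSS
  plus <- gm$strand == "+"
  tss_from_gtf <- ifelse(plus, gm$start, gm$end - 1L)
  expect_setequal(
    paste(gm$chrom, tss_from_gtf, gm$strand),
    paste(pg$genes$chrom, pg$genes$tss_pos, pg$genes$strand)
  )
})
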