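# Synthetic ReCappable-seq libraries with ground truth.
#
# The generator emulates the enrichment chemistry as sampling: every
# transcription unit carries one of four 5'-end classes (m7G cap, 5'
# triphosphate, gamma-methyl triphosphate, processed), and each library
# (ALL = enriched, CIP = CIP-pretreated enriched, CT = unenriched
# control) captures a class with a library-specific probability. A
# configurable fraction of reads starts at random internal positions
# with processed ends, emulating degraded/processed background, which is
# what the unenriched control is there to flag.

SIM_CLASSES <- c("capped", "ppp", "methyl_ppp", "processed")
SIM_LIBRARIES <- c("ALL", "CIP", "CT")

#' Simulator configuration
#'
#' Parameters of the synthetic-library generator. The defaults define the
#' package's standard validation conditions: a 100 kb uniform-random
#' contig carrying 50 transcription units (20 capped, 15 triphosphate,
#' 5 gamma-methyl triphosphate, 10 processed) of 350-600 bp with relative
#' abundances uniform in [0.5, 2], 50 nt reads, 1e5 reads per library, a
#' background capture probability `epsilon = 0.01` for chemistries a
#' library should reject, 30% degraded reads, and 5% probability mass of
#' +/-1 start jitter.
#'
#' @param genome_length total contig length in bp.
#' @param n_contigs number of contigs (the length is split evenly).
#' @param genes_per_class named integer vector over
#'   `capped/ppp/methyl_ppp/processed`.
#' @param gene_length_range min/max transcription-unit length (bp).
#' @param abundance_range min/max relative expression weight.
#' @param epsilon background capture probability for rejected
#'   chemistries, in [0, 1].
#' @param capture optional full capture matrix (classes x libraries);
#'   default [default_capture_matrix()] with `epsilon`.
#' @param degraded_fraction probability that a read is a degraded
#'   fragment starting at a random internal position with a processed
#'   end.
#' @param positional_jitter probability mass for +/-1 bp start offsets.
#' @param read_length read length in nt (the study analysed 50 nt reads).
#' @param n_reads reads emitted per library.
#' @param mapq mapping quality written for simulated alignments.
#' @param seed RNG seed; every simulator artifact is a pure function of
#'   the configuration including this seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 100000L,
                       n_contigs = 1L,
                       genes_per_class = c(capped = 20L, ppp = 15L,
                                           methyl_ppp = 5L, processed = 10L),
                       gene_length_range = c(350L, 600L),
                       abundance_range = c(0.5, 2),
                       epsilon = 0.01,
                       capture = NULL,
                       degraded_fraction = 0.3,
                       positional_jitter = 0.05,
                       read_length = 50L,
                       n_reads = 100000L,
                       mapq = 60L,
                       seed = 1L) {
  if (genome_length <= 0) stop("sim_config: genome_length must be > 0")
  if (is.null(capture)) capture <- default_capture_matrix(epsilon)
  stopifnot(identical(rownames(capture), SIM_CLASSES),
            identical(colnames(capture), SIM_LIBRARIES),
            all(capture >= 0 & capture <= 1),
            degraded_fraction >= 0, degraded_fraction <= 1,
            positional_jitter >= 0, positional_jitter <= 1,
            n_reads > 0)
  miss <- setdiff(SIM_CLASSES, names(genes_per_class))
  if (length(miss)) genes_per_class[miss] <- 0L
  structure(list(genome_length = as.integer(genome_length),
                 n_contigs = as.integer(n_contigs),
                 genes_per_class = genes_per_class[SIM_CLASSES],
                 gene_length_range = as.integer(gene_length_range),
                 abundance_range = abundance_range,
                 epsilon = epsilon, capture = capture,
                 degraded_fraction = degraded_fraction,
                 positional_jitter = positional_jitter,
                 read_length = as.integer(read_length),
                 n_reads = as.integer(n_reads),
                 mapq = as.integer(mapq),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default capture-probability matrix
#'
#' Encodes the enrichment chemistry per library. ALL (decapping +
#' recapping + streptavidin) captures capped and triphosphorylated ends
#' and rejects processed ends; CIP pretreatment removes the triphosphate
#' so the CIP library additionally rejects `ppp` ends, while the
#' gamma-methyl triphosphate (the RN7SK-type end) resists CIP and is
#' still captured; the unenriched control CT captures everything.
#' Rejected chemistries leak through at rate `epsilon` so that
#' ratio-based filtering (not mere presence/absence) is exercised.
#'
#' @param epsilon background capture probability (default 0.01).
#' @return numeric matrix, rows `capped/ppp/methyl_ppp/processed`,
#'   columns `ALL/CIP/CT`.
#' @export
default_capture_matrix <- function(epsilon = 0.01) {
  m <- matrix(c(1,       1,       1,    # capped
                1,       epsilon, 1,    # ppp
                1,       1,       1,    # methyl_ppp
                epsilon, epsilon, 1),   # processed
              nrow = 4, byrow = TRUE,
              dimnames = list(SIM_CLASSES, SIM_LIBRARIES))
  m
}

#' Generate a random genome
#'
#' Seeded i.i.d. uniform A/C/G/T contigs; deterministic per seed.
#'
#' @param config a [sim_config].
#' @return a [Biostrings::DNAStringSet] named `simchr1`, `simchr2`, ...
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  per <- rep(config$genome_length %/% config$n_contigs, config$n_contigs)
  per[1] <- per[1] + config$genome_length %% config$n_contigs
  seqs <- with_seed(config$seed, {
    vapply(per, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("simchr%d", seq_along(out))
  out
}

# Truth rules: which polymerase class the pipeline is expected to report
# for each end chemistry. The gamma-methyl triphosphate end is expected
# to be (mis)assigned to Pol II because it resists CIP — the method's
# documented behaviour for RN7SK. Processed ends should never reach
# high confidence.
truth_rules <- function(end_class) {
  data.frame(
    expected_pol_class = c(capped = "pol2", ppp = "non_pol2",
                           methyl_ppp = "pol2", processed = "none")[end_class],
    expected_hc = end_class != "processed",
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Place transcription units on a genome
#'
#' Draws non-overlapping transcription units on both strands, assigns
#' each an end chemistry and an abundance, and derives the ground-truth
#' table mechanically from the chemistry (capped -> Pol II, ppp ->
#' non-Pol II, gamma-methyl triphosphate -> Pol II, processed -> no
#' high-confidence TSS expected).
#'
#' @param config a [sim_config].
#' @param genome genome from [make_genome()].
#' @return list with `genes` (`gene_id`, `chrom`, `strand`, `tss_pos`
#'   0-based, `length`, `end_class`, `abundance`) and `truth` (the genes
#'   table plus `expected_pol_class`, `expected_hc`).
#' @export
place_genes <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  n_genes <- sum(config$genes_per_class)
  if (n_genes == 0L) {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        strand = character(), tss_pos = integer(),
                        length = integer(), end_class = character(),
                        abundance = numeric(), stringsAsFactors = FALSE)
    return(list(genes = genes, truth = cbind(genes, truth_rules(character(0)))))
  }
  classes <- rep(SIM_CLASSES, config$genes_per_class)
  clens <- Biostrings::width(genome)
  genes <- with_seed(config$seed + 1L, {
    lens <- sample(seq(config$gene_length_range[1],
                       config$gene_length_range[2]), n_genes, replace = TRUE)
    placed <- vector("list", n_genes)
    occupied <- lapply(seq_along(genome), function(i) integer(0))
    for (g in seq_len(n_genes)) {
      ok <- FALSE
      for (try in 1:1000) {
        ci <- sample(seq_along(genome), 1L,
                     prob = as.numeric(clens) / sum(clens))
        if (clens[ci] < lens[g] + 2L) next
        s <- sample.int(clens[ci] - lens[g] - 1L, 1L)  # 0-based unit start
        span <- s:(s + lens[g] - 1L)
        if (any(span %in% occupied[[ci]])) next
        occupied[[ci]] <- c(occupied[[ci]], span)
        strand <- sample(c("+", "-"), 1L)
        tss <- if (strand == "+") s else s + lens[g] - 1L
        placed[[g]] <- data.frame(
          gene_id = sprintf("simgene%03d", g),
          chrom = names(genome)[ci], strand = strand,
          tss_pos = as.integer(tss), length = as.integer(lens[g]),
          end_class = classes[g],
          abundance = runif(1, config$abundance_range[1],
                            config$abundance_range[2]),
          stringsAsFactors = FALSE)
        ok <- TRUE
        break
      }
      if (!ok) {
        stop("place_genes: could not place gene ", g,
             " without overlap after 1000 tries; reduce gene number/length")
      }
    }
    do.call(rbind, placed)
  })
  rownames(genes) <- NULL
  truth <- cbind(genes, truth_rules(genes$end_class))
  list(genes = genes, truth = truth)
}

# 0-based half-open genomic span of a unit.
gene_span <- function(genes) {
  start <- ifelse(genes$strand == "+", genes$tss_pos,
                  genes$tss_pos - genes$length + 1L)
  cbind(start = start, end = start + genes$length)
}

#' Write simulated genes as GTF
#'
#' One gene/transcript/exon triple per unit, exon = the full unit span,
#' `gene_type` set from the end chemistry (`capped`/`methyl_ppp` ->
#' `protein_coding`-like Pol II unit, `ppp` -> `tRNA`, `processed` ->
#' `rRNA`), which gives the annotation-side modules realistic gene types
#' to work with.
#'
#' @param genes genes table from [place_genes()].
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
write_sim_gtf <- function(genes, path) {
  span <- gene_span(genes)
  gtype <- c(capped = "protein_coding", ppp = "tRNA",
             methyl_ppp = "snRNA", processed = "rRNA")[genes$end_class]
  lines <- unlist(lapply(seq_len(nrow(genes)), function(i) {
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s.t1"; gene_type "%s";',
      genes$gene_id[i], genes$gene_id[i], gtype[i])
    sprintf("%s\trecaptss_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
            genes$chrom[i], c("gene", "transcript", "exon"),
            span[i, "start"] + 1L, span[i, "end"], genes$strand[i], attrs)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate one aligned library
#'
#' Draws `n_reads` reads. Each read is either a degraded fragment (with
#' probability proportional to `degraded_fraction` times the library's
#' capture probability for processed ends) starting at a uniform internal
#' position of an abundance-weighted unit, or a primary 5' end read of a
#' unit drawn proportional to `abundance * capture[end_class, library]`,
#' starting at the unit's TSS with optional +/-1 jitter. Reads extend
#' `read_length` bp in the unit's direction (clipped at unit and contig
#' boundaries) and are emitted as already-aligned records, so no external
#' aligner is involved.
#'
#' @param genes genes table from [place_genes()].
#' @param config a [sim_config].
#' @param library one of `"ALL"`, `"CIP"`, `"CT"`.
#' @param genome optional genome (bounds checking); lengths inferred from
#'   the config when omitted.
#' @return an [aligned_reads] table of exactly `n_reads` primary reads,
#'   with attribute `"source"` (`"primary"`/`"degraded"` per read).
#' @export
simulate_library <- function(genes, config, library = c("ALL", "CIP", "CT"),
                             genome = NULL) {
  library <- match.arg(library)
  stopifnot(inherits(config, "sim_config"), nrow(genes) > 0)
  cap <- config$capture[genes$end_class, library]
  w_primary <- (1 - config$degraded_fraction) * genes$abundance *
    cap / sum(genes$abundance)
  w_degraded <- config$degraded_fraction *
    config$capture["processed", library]
  if (sum(w_primary) + w_degraded == 0) {
    stop("simulate_library: all capture probabilities are zero for ", library)
  }
  span <- gene_span(genes)
  lib_seed <- config$seed + 1000L * match(library, SIM_LIBRARIES)
  with_seed(lib_seed, {
    n <- config$n_reads
    # degraded vs primary, then the source unit
    p_deg <- w_degraded / (sum(w_primary) + w_degraded)
    degraded <- runif(n) < p_deg
    gene_idx <- integer(n)
    n_deg <- sum(degraded)
    if (n_deg) {
      w_frag <- genes$abundance * genes$length   # fragments scale with length
      gene_idx[degraded] <- sample.int(nrow(genes), n_deg, replace = TRUE,
                                       prob = w_frag)
    }
    if (n - n_deg) {
      gene_idx[!degraded] <- sample.int(nrow(genes), n - n_deg,
                                        replace = TRUE, prob = w_primary)
    }
    strand <- genes$strand[gene_idx]
    tss <- genes$tss_pos[gene_idx]
    # 5' start: TSS (with jitter) for primary, uniform internal otherwise
    start5 <- integer(n)
    if (n - n_deg) {
      jit <- runif(n - n_deg)
      off <- ifelse(jit < config$positional_jitter / 2, -1L,
                    ifelse(jit < config$positional_jitter, 1L, 0L))
      dir <- ifelse(strand[!degraded] == "+", 1L, -1L)
      start5[!degraded] <- tss[!degraded] + off * dir
    }
    if (n_deg) {
      gl <- genes$length[gene_idx[degraded]]
      rel <- floor(runif(n_deg, min = 1, max = gl))  # internal, not the TSS
      dir <- ifelse(strand[degraded] == "+", 1L, -1L)
      start5[degraded] <- tss[degraded] + as.integer(rel) * dir
    }
    # read extends read_length bp downstream of its 5' end
    dir <- ifelse(strand == "+", 1L, -1L)
    end3 <- start5 + dir * (config$read_length - 1L)
    left <- pmin(start5, end3)
    right <- pmax(start5, end3)
    # clip at contig bounds
    if (is.null(genome)) {
      clens <- setNames(rep(config$genome_length %/% config$n_contigs,
                            config$n_contigs),
                        sprintf("simchr%d", seq_len(config$n_contigs)))
      clens[1] <- clens[1] + config$genome_length %% config$n_contigs
    } else {
      clens <- setNames(Biostrings::width(genome), names(genome))
    }
    chrom <- genes$chrom[gene_idx]
    left <- pmax(left, 0L)
    right <- pmin(right, clens[chrom] - 1L)
    reads <- aligned_reads(
      chrom = chrom, start = left, end = right + 1L, strand = strand,
      mapq = config$mapq, is_primary = TRUE,
      qname = sprintf("%s_read%06d", tolower(library), seq_len(n))
    )
    attr(reads, "source") <- ifelse(degraded, "degraded", "primary")
    reads
  })
}

#' Simulate a full ReCappable-seq experiment to disk
#'
#' Writes `genome.fa`, `annotation.gtf`, `all.sam`, `cip.sam`, `ct.sam`
#' and `truth.tsv` into `out_dir`. Every file is a pure function of the
#' configuration (including its seed).
#'
#' @param config a [sim_config].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the genome, genes, truth table and the
#'   three read sets.
#' @export
simulate_recappable <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- make_genome(config)
  pg <- place_genes(config, genome)
  Biostrings::writeXStringSet(genome, file.path(out_dir, "genome.fa"))
  write_sim_gtf(pg$genes, file.path(out_dir, "annotation.gtf"))
  reads <- lapply(setNames(SIM_LIBRARIES, SIM_LIBRARIES), function(lib) {
    r <- simulate_library(pg$genes, config, lib, genome = genome)
    write_sam(r, file.path(out_dir, paste0(tolower(lib), ".sam")),
              genome = genome)
    r
  })
  write.table(pg$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(genome = genome, genes = pg$genes, truth = pg$truth,
                 reads = reads))
}

#' End-to-end pipeline check against simulator ground truth
#'
#' Simulates the three libraries, counts tags, runs the full calling and
#' classification pipeline, and compares the outcome at each true TSS
#' position with the expectation derived from its end chemistry. Also
#' reports how candidate positions that are not true TSSs (degraded
#' background, jitter neighbours) were handled by the high-confidence
#' filter.
#'
#' @param config a [sim_config].
#' @param min_tpm,hc_ratio,cip_threshold thresholds passed to
#'   [call_tss()].
#' @return list with `confusion` (expected x observed class matrix over
#'   true TSSs), `recovery_pct` (percent of true TSSs whose observed
#'   class matches expectation), `background` (status table of non-truth
#'   candidates), `calls`, and `truth`.
#' @export
end_to_end_check <- function(config, min_tpm = 1, hc_ratio = 1,
                             cip_threshold = 4) {
  genome <- make_genome(config)
  pg <- place_genes(config, genome)
  tabs <- lapply(setNames(SIM_LIBRARIES, SIM_LIBRARIES), function(lib) {
    count_tags(simulate_library(pg$genes, config, lib, genome = genome))
  })
  calls <- call_tss(tabs$ALL, tabs$CT, tabs$CIP, min_tpm = min_tpm,
                    hc_ratio = hc_ratio, cip_threshold = cip_threshold)
  rec <- calls$tss
  truth <- pg$truth
  idx <- match(tag_key(truth$chrom, truth$tss_pos, truth$strand),
               tag_key(rec$chrom, rec$pos, rec$strand))
  observed <- ifelse(is.na(idx), "not_called",
                     ifelse(rec$status[idx] != "high_confidence",
                            "not_called", rec$pol_class[idx]))
  expected <- ifelse(truth$expected_hc, truth$expected_pol_class,
                     "not_called")
  confusion <- table(
    expected = factor(paste(truth$end_class, expected, sep = ":")),
    observed = factor(observed, c("pol2", "non_pol2", "not_called"))
  )
  in_truth <- !is.na(match(tag_key(rec$chrom, rec$pos, rec$strand),
                           tag_key(truth$chrom, truth$tss_pos,
                                   truth$strand)))
  list(confusion = confusion,
       recovery_pct = 100 * mean(observed == expected),
       background = table(status = rec$status[!in_truth]),
       calls = calls, truth = truth)
}
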