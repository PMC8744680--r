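# Relating classified TSSs to gene annotation: closest-downstream-exon
# assignment, locus clustering of unannotated TSSs, anchor-relative
# positioning, base composition, and generic interval overlap.

#' Read gene models from a GTF file
#'
#' Imports exon features (GENCODE dialect: `gene_id`, `gene_type`
#' attributes; predicted tRNA genes merged into the annotation appear as
#' `gene_type == "tRNA"`). Annotation input order is preserved — it is
#' the tie-breaker in [assign_tss_to_genes()].
#'
#' @param path GTF file.
#' @return a `data.frame` of exons with columns `gene_id`, `gene_type`,
#'   `transcript_id`, `chrom`, `strand`, `start` (0-based), `end`
#'   (half-open).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  md <- S4Vectors::mcols(gr)
  data.frame(
    gene_id = as.character(md$gene_id),
    gene_type = if ("gene_type" %in% names(md)) as.character(md$gene_type)
                else NA_character_,
    transcript_id = if ("transcript_id" %in% names(md))
                      as.character(md$transcript_id) else NA_character_,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Assign TSSs to genes via the closest downstream exon
#'
#' For each TSS the candidate exons are the same-strand exons that either
#' overlap the TSS or begin downstream of it in gene orientation (exons
#' strictly upstream of the TSS are never candidates — a TSS may sit
#' upstream of or within its gene, not past it). The nearest candidate is
#' chosen, ties broken by annotation input order, and the assignment is
#' made iff the TSS overlaps the exon (distance 0) or lies within
#' `max_upstream` bp of it (inclusive).
#'
#' @param tss `data.frame` with `chrom`, `pos` (0-based), `strand`.
#' @param genes exon table from [read_gene_models()].
#' @param max_upstream maximum upstream distance in bp (default 200).
#' @return `data.frame` with the TSS key columns plus `gene_id`
#'   (`NA` when unassigned), `gene_type` and `distance` (0 = overlap,
#'   positive = TSS upstream of the exon in gene orientation).
#' @export
assign_tss_to_genes <- function(tss, genes, max_upstream = 200L) {
  n <- nrow(tss)
  gene_id <- rep(NA_character_, n)
  gene_type <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)
  if (n && nrow(genes)) {
    ex_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1L,
                                                     genes$end),
                                    strand = genes$strand)
    ts_gr <- GenomicRanges::GRanges(tss$chrom,
                                    IRanges::IRanges(tss$pos + 1L, width = 1L),
                                    strand = tss$strand)
    # overlap case: distance 0, tie -> lowest exon index (input order)
    ov <- GenomicRanges::findOverlaps(ts_gr, ex_gr)
    if (length(ov)) {
      first_hit <- tapply(S4Vectors::subjectHits(ov),
                          S4Vectors::queryHits(ov), min)
      qi <- as.integer(names(first_hit))
      gene_id[qi] <- genes$gene_id[first_hit]
      gene_type[qi] <- genes$gene_type[first_hit]
      distance[qi] <- 0L
    }
    # downstream case (strand-aware): nearest exon start ahead of the TSS
    todo <- which(is.na(distance))
    if (length(todo)) {
      pr <- GenomicRanges::precede(ts_gr[todo], ex_gr, select = "all")
      if (length(pr)) {
        q <- S4Vectors::queryHits(pr)
        s <- S4Vectors::subjectHits(pr)
        p <- tss$pos[todo[q]]
        d <- ifelse(tss$strand[todo[q]] == "+",
                    genes$start[s] - p,
                    p - (genes$end[s] - 1L))
        ok <- d <= max_upstream
        q <- q[ok]; s <- s[ok]; d <- d[ok]
        if (length(q)) {
          # nearest distance first, then annotation order
          o <- order(q, d, s)
          q <- q[o]; s <- s[o]; d <- d[o]
          f <- !duplicated(q)
          qi <- todo[q[f]]
          gene_id[qi] <- genes$gene_id[s[f]]
          gene_type[qi] <- genes$gene_type[s[f]]
          distance[qi] <- as.integer(d[f])
        }
      }
    }
  }
  out <- tss[, c("chrom", "pos", "strand"), drop = FALSE]
  out$gene_id <- gene_id
  out$gene_type <- gene_type
  out$distance <- distance
  rownames(out) <- NULL
  out
}

#' Cluster unannotated TSSs into loci
#'
#' Single-linkage chaining per (chromosome, strand): consecutive sorted
#' positions at most `max_gap` bp apart join one locus. Used for the
#' non-Pol II TSSs that match neither annotated genes nor predicted
#' tRNAs.
#'
#' @param tss `data.frame` with `chrom`, `pos`, `strand`.
#' @param max_gap maximum gap between consecutive members (default 20).
#' @return `data.frame` of loci: `chrom`, `strand`, `start`, `end`
#'   (0-based half-open span covering the member positions), `n_tss`,
#'   and a list-column `members` of member positions.
#' @export
cluster_unannotated <- function(tss, max_gap = 20L) {
  if (!nrow(tss)) {
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      n_tss = integer()))
  }
  tss <- unique(tss[, c("chrom", "pos", "strand")])
  tss <- tss[order(tss$chrom, tss$strand, tss$pos), , drop = FALSE]
  grp <- paste(tss$chrom, tss$strand)
  loci <- do.call(rbind, lapply(split(tss, grp), function(d) {
    gap <- c(Inf, diff(d$pos))
    id <- cumsum(gap > max_gap)
    do.call(rbind, lapply(split(d$pos, id), function(p) {
      data.frame(chrom = d$chrom[1], strand = d$strand[1],
                 start = min(p), end = max(p) + 1L,
                 n_tss = length(p), stringsAsFactors = FALSE)
    }))
  }))
  loci <- loci[order(loci$chrom, loci$start), , drop = FALSE]
  rownames(loci) <- NULL
  loci
}

#' Histogram of TSS positions relative to anchors
#'
#' Strand-oriented signed offsets of TSSs around anchor positions (for
#' example annotated mature tRNA 5' ends): negative = upstream of the
#' anchor in its gene orientation. Each TSS is counted at its offset to
#' every same-strand anchor within `window` bp.
#'
#' @param tss `data.frame` with `chrom`, `pos`, `strand`.
#' @param anchors `data.frame` with `chrom`, `pos`, `strand`.
#' @param window maximum absolute offset retained.
#' @return named integer vector: counts per offset (names are offsets).
#' @export
relative_position_histogram <- function(tss, anchors, window = 50L) {
  offs <- integer(0)
  for (i in seq_len(nrow(anchors))) {
    same <- tss$chrom == anchors$chrom[i] & tss$strand == anchors$strand[i]
    d <- tss$pos[same] - anchors$pos[i]
    if (anchors$strand[i] == "-") d <- -d
    offs <- c(offs, d[abs(d) <= window])
  }
  tab <- table(factor(offs, levels = sort(unique(offs))))
  setNames(as.integer(tab), names(tab))
}

#' Base composition around TSSs
#'
#' Per-offset nucleotide frequencies in a strand-oriented window around
#' each TSS (sequences on `-` are reverse-complemented so that offset 0,
#' the "+1" position, is the first transcribed base). Also reports the
#' fraction of TSSs whose +1 base is A or G and whose -1 base is C or T —
#' the canonical -1[C/T]+1[A/G] initiator motif.
#'
#' @param tss `data.frame` with `chrom`, `pos`, `strand`.
#' @param genome a [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param flank half-window in bp.
#' @return list with `freq` (matrix offsets x A/C/G/T, rows named by
#'   offset), `n_used`, `n_excluded` (TSSs too close to a contig edge),
#'   `frac_plus1_AG`, `frac_minus1_CT`.
#' @export
base_composition_profile <- function(tss, genome, flank = 10L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  clen <- setNames(Biostrings::width(genome), names(genome))
  start1 <- tss$pos - flank + 1L        # 1-based window start
  end1 <- tss$pos + flank + 1L
  ok <- start1 >= 1L & end1 <= clen[tss$chrom] & tss$chrom %in% names(genome)
  ok[is.na(ok)] <- FALSE
  used <- tss[ok, , drop = FALSE]
  if (!nrow(used)) {
    stop("base_composition_profile: no TSS with a full flanking window")
  }
  seqs <- extract_seqs(genome, used$chrom, start1[ok], end1[ok])
  minus <- used$strand == "-"
  if (any(minus)) seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  cm <- Biostrings::consensusMatrix(seqs, baseOnly = TRUE)
  freq <- t(cm[c("A", "C", "G", "T"), , drop = FALSE]) / nrow(used)
  rownames(freq) <- as.character(seq(-flank, flank))
  plus1 <- substr(as.character(seqs), flank + 1L, flank + 1L)
  minus1 <- substr(as.character(seqs), flank, flank)
  list(freq = freq, n_used = nrow(used), n_excluded = sum(!ok),
       frac_plus1_AG = mean(plus1 %in% c("A", "G")),
       frac_minus1_CT = mean(minus1 %in% c("C", "T")))
}

#' Overlap TSSs with genomic intervals
#'
#' Exact point-in-interval tests of TSS positions against 0-based
#' half-open intervals (for example enhancer or DNase peak BED records).
#'
#' @param tss `data.frame` with `chrom`, `pos`, optionally `pol_class`.
#' @param intervals `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return list with `hit` (logical per TSS), `interval_counts` (TSSs per
#'   interval) and, when `tss$pol_class` exists, `hits_by_class`.
#' @export
interval_overlap <- function(tss, intervals) {
  bad <- which(intervals$start >= intervals$end)
  if (length(bad)) {
    stop(sprintf("interval_overlap: malformed interval (start >= end) at line %d",
                 bad[1]))
  }
  ts_gr <- GenomicRanges::GRanges(tss$chrom,
                                  IRanges::IRanges(tss$pos + 1L, width = 1L))
  iv_gr <- GenomicRanges::GRanges(intervals$chrom,
                                  IRanges::IRanges(intervals$start + 1L,
                                                   intervals$end))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(ts_gr, iv_gr))
  hit <- seq_len(nrow(tss)) %in% S4Vectors::queryHits(ov)
  cnt <- tabulate(S4Vectors::subjectHits(ov), nbins = nrow(intervals))
  out <- list(hit = hit, interval_counts = cnt)
  if ("pol_class" %in% names(tss)) {
    out$hits_by_class <- tapply(hit, tss$pol_class, sum)
  }
  out
}

#' Read a BED file of intervals or anchor positions
#'
#' @param path BED3+/BED6 file.
#' @return `data.frame` with `chrom`, `start`, `end` (0-based half-open)
#'   and, when present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 6) names(df)[4:6] <- c("name", "score", "strand")
  df
}
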