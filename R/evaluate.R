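# Benchmarking called TSSs against reference sets, transcript body
# coverage, and the qPCR percent-recovery formula.

#' Match query TSSs against reference positions
#'
#' A query hits iff any reference position lies within `window` bp of it
#' (`window = 0` is an exact match), on the same strand when
#' `strand_aware`. This is the positional comparison used against CAGE
#' (window 1) and annotation first-exon starts (window 0).
#'
#' @param query,reference `data.frame`s with `chrom`, `pos`, `strand`.
#' @param window half-window in bp (>= 0).
#' @param strand_aware require matching strands (default `TRUE`).
#' @return logical vector, one flag per query row.
#' @export
match_positions <- function(query, reference, window = 0L,
                            strand_aware = TRUE) {
  if (window < 0) stop("match_positions: window must be >= 0")
  if (!nrow(query)) return(logical(0))
  if (!nrow(reference)) return(rep(FALSE, nrow(query)))
  st <- function(d) if (strand_aware) d$strand else "*"
  q_gr <- GenomicRanges::GRanges(query$chrom,
                                 IRanges::IRanges(query$pos + 1L, width = 1L),
                                 strand = st(query))
  r_gr <- GenomicRanges::GRanges(reference$chrom,
                                 IRanges::IRanges(reference$pos + 1L - window,
                                                  reference$pos + 1L + window),
                                 strand = st(reference))
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(q_gr, r_gr, ignore.strand = !strand_aware)
  )
  seq_len(nrow(query)) %in% S4Vectors::queryHits(ov)
}

eval_result <- function(tp, fp = NA_integer_, fn = NA_integer_) {
  precision <- if (!is.na(fp) && tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  sensitivity <- if (!is.na(fn) && tp + fn > 0) tp / (tp + fn) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 sensitivity = sensitivity),
            class = "recaptss_eval")
}

#' @export
print.recaptss_eval <- function(x, ...) {
  cat(sprintf("TP %s  FP %s  FN %s  precision %s  sensitivity %s\n",
              x$tp, x$fp, x$fn,
              ifelse(is.na(x$precision), "NA",
                     sprintf("%.1f%%", x$precision)),
              ifelse(is.na(x$sensitivity), "NA",
                     sprintf("%.3f", x$sensitivity))))
  invisible(x)
}

#' Precision of called TSSs against a reference
#'
#' True positives are the query TSSs (the high-confidence Pol II set in
#' the study) overlapping the reference; false positives are the
#' remainder; `precision = 100 * TP / (TP + FP)`. The reference is either
#' a position set (`chrom`/`pos`/`strand`, matched within `window`) or a
#' peak interval set (`chrom`/`start`/`end`, point-in-interval).
#'
#' @param query `data.frame` with `chrom`, `pos`, `strand`.
#' @param reference position or interval `data.frame` (see above).
#' @param window half-window for position references (default 0).
#' @param strand_aware strand requirement for position references.
#' @return a `recaptss_eval` result (`tp`, `fp`, `precision` in percent;
#'   an empty query yields precision `NA`, never 0).
#' @export
tss_precision <- function(query, reference, window = 0L,
                          strand_aware = TRUE) {
  hit <- if ("pos" %in% names(reference)) {
    match_positions(query, reference, window, strand_aware)
  } else {
    interval_overlap(query, reference)$hit
  }
  eval_result(tp = sum(hit), fp = sum(!hit))
}

#' Sensitivity of called TSSs against an expressed, peak-supported
#' reference
#'
#' False negatives are the reference TSSs that (1) belong to transcripts
#' expressed at `fpkm >= fpkm_cutoff`, (2) overlap at least one peak, and
#' (3) are not matched by any query TSS. `sensitivity = TP / (TP + FN)`
#' with TP the query TSSs matching the reference. Reference entries whose
#' transcript has no FPKM value are excluded (their count is reported).
#'
#' @param query `data.frame` with `chrom`, `pos`, `strand`.
#' @param ref_tss reference positions with `chrom`, `pos`, `strand`,
#'   `transcript_id`.
#' @param fpkm named numeric vector, `transcript_id -> FPKM`.
#' @param fpkm_cutoff expression threshold (the study sweeps this on the
#'   sensitivity plot's x-axis).
#' @param peaks interval `data.frame` (`chrom`, `start`, `end`).
#' @param window half-window for query/reference matching (default 0).
#' @return a `recaptss_eval` result with attribute `n_missing_fpkm`.
#' @export
tss_sensitivity <- function(query, ref_tss, fpkm, fpkm_cutoff, peaks,
                            window = 0L) {
  have <- ref_tss$transcript_id %in% names(fpkm)
  n_missing <- sum(!have)
  if (n_missing) {
    warning(sprintf("tss_sensitivity: %d reference TSS(s) without FPKM excluded",
                    n_missing))
    ref_tss <- ref_tss[have, , drop = FALSE]
  }
  expressed <- fpkm[ref_tss$transcript_id] >= fpkm_cutoff
  peaked <- interval_overlap(ref_tss, peaks)$hit
  detected <- match_positions(ref_tss, query, window = window)
  fn <- sum(expressed & peaked & !detected)
  tp <- sum(match_positions(query, ref_tss, window = window))
  out <- eval_result(tp = tp, fn = fn)
  attr(out, "n_missing_fpkm") <- n_missing
  out
}

#' Transcript body coverage of 5' tags or reads
#'
#' Maps per-position tag counts along each transcript (exons
#' concatenated 5' to 3') into 100 percentile bins. Transcripts of
#' length <= `min_len` are excluded. In `"tags"` mode, transcripts whose
#' overlapping 5' tags total fewer than `library_size / 1e6` reads are
#' discarded; in `"reads"` mode transcripts with `fpkm < fpkm_cutoff` are
#' discarded. Binning sends 0-based position rank `r` of a transcript of
#' length `L` to bin `floor(r * 100 / L) + 1` (ties to the lower bin), so
#' each row sums to the transcript's kept tag count.
#'
#' @param tags a [tag_count_table].
#' @param transcripts exon table ([read_gene_models()]) with
#'   `transcript_id`.
#' @param min_len minimum transcript length, exclusive (default 300).
#' @param mode `"tags"` (5'-end libraries) or `"reads"` (RNA-seq style).
#' @param fpkm named vector for `"reads"` mode filtering.
#' @param fpkm_cutoff expression filter for `"reads"` mode (default 10).
#' @return numeric matrix (kept transcripts x 100 bins) with attribute
#'   `"mean_profile"` (column means).
#' @export
transcript_body_coverage <- function(tags, transcripts, min_len = 300L,
                                     mode = c("tags", "reads"),
                                     fpkm = NULL, fpkm_cutoff = 10) {
  mode <- match.arg(mode)
  key <- tag_key(tags$chrom, tags$pos, tags$strand)
  count_at <- function(chrom, pos, strand) {
    idx <- match(tag_key(chrom, pos, strand), key)
    ifelse(is.na(idx), 0L, tags$count[idx])
  }
  min_tags <- library_size(tags) / 1e6
  rows <- list()
  for (tid in unique(transcripts$transcript_id)) {
    ex <- transcripts[transcripts$transcript_id == tid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    pos <- unlist(mapply(seq, ex$start, ex$end - 1L, SIMPLIFY = FALSE))
    L <- length(pos)
    if (L == 0L) stop("transcript_body_coverage: zero-length transcript ", tid)
    if (L <= min_len) next
    strand <- ex$strand[1]
    if (strand == "-") pos <- rev(pos)      # 5' -> 3'
    cov <- count_at(ex$chrom[1], pos, strand)
    if (mode == "tags") {
      if (sum(cov) < min_tags) next
    } else {
      if (is.null(fpkm) || is.na(fpkm[tid]) || fpkm[tid] < fpkm_cutoff) next
    }
    bin <- floor((seq_len(L) - 1L) * 100 / L) + 1L
    rows[[tid]] <- vapply(split(cov, bin), sum, numeric(1))[as.character(1:100)]
  }
  if (!length(rows)) {
    m <- matrix(numeric(0), nrow = 0, ncol = 100)
  } else {
    m <- do.call(rbind, rows)
    m[is.na(m)] <- 0
  }
  colnames(m) <- as.character(1:100)
  attr(m, "mean_profile") <- if (nrow(m)) colMeans(m) else rep(NA_real_, 100)
  m
}

#' Percent recovery from qPCR quantification cycles
#'
#' `100 * 2^-(mean(cq_input) - mean(cq_enriched))`: the fraction of a
#' target transcript recovered after streptavidin enrichment, relative to
#' the unenriched input set to 100%.
#'
#' @param cq_input Cq values of the unenriched input (non-empty, > 0).
#' @param cq_enriched Cq values of the enriched sample.
#' @return percentage.
#' @examples
#' qpcr_recovery(c(25.9, 25.7), c(24.2, 24.1))  # ~32% recovery
#' @export
qpcr_recovery <- function(cq_input, cq_enriched) {
  if (!length(cq_input) || !length(cq_enriched)) {
    stop("qpcr_recovery: Cq vectors must be non-empty")
  }
  if (any(cq_input <= 0) || any(cq_enriched <= 0)) {
    stop("qpcr_recovery: Cq values must be positive")
  }
  100 * 2^(-(mean(cq_input) - mean(cq_enriched)))
}
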