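# TSS calling, high-confidence filtering and Pol II / non-Pol II
# classification. This is the core of the pipeline: a candidate TSS is a
# genomic position whose enriched-library signal reaches min_tpm; the
# unenriched control separates genuine primary 5' ends from processed or
# degraded background; the CIP-pretreated library separates capped
# (CIP-resistant, Pol II) from triphosphorylated (CIP-sensitive,
# non-Pol II) starts.

#' Call candidate TSSs from an enriched tag table
#'
#' A candidate TSS is a position with `tpm_all >= min_tpm` (inclusive; the
#' default 1 TPM is the study's genome-wide threshold at 63 million
#' primary mappable reads). Returns a `recaptss_calls` object holding one
#' record per candidate, to be refined by [filter_high_confidence()] and
#' [classify_polymerase()], or use [call_tss()] to run all three steps.
#'
#' @param all_table [tag_count_table] of the enriched (ALL) library.
#' @param min_tpm candidate threshold in TPM (default 1).
#' @return an object of class `recaptss_calls`.
#' @export
call_candidates <- function(all_table, min_tpm = 1) {
  stopifnot(inherits(all_table, "tag_count_table"))
  tpm_all <- tpm(all_table)
  keep <- tpm_all >= min_tpm
  rec <- data.frame(
    chrom = all_table$chrom[keep],
    pos = all_table$pos[keep],
    strand = all_table$strand[keep],
    count_all = all_table$count[keep],
    tpm_all = tpm_all[keep],
    tpm_ct = rep(NA_real_, sum(keep)),
    tpm_cip = rep(NA_real_, sum(keep)),
    enrich_ratio = rep(NA_real_, sum(keep)),
    cip_ratio = rep(NA_real_, sum(keep)),
    status = rep("candidate", sum(keep)),
    pol_class = rep("unassigned", sum(keep)),
    quadrant = rep("none", sum(keep)),
    stringsAsFactors = FALSE
  )
  structure(
    list(tss = rec,
         params = list(min_tpm = min_tpm, hc_ratio = NA_real_,
                       cip_threshold = NA_real_, pseudocount = 0),
         library_sizes = c(all = library_size(all_table), ct = NA_real_,
                           cip = NA_real_)),
    class = "recaptss_calls"
  )
}

ratio_with_pseudocount <- function(num, den, pseudocount) {
  if (pseudocount > 0) {
    (num + pseudocount) / (den + pseudocount)
  } else {
    ifelse(den == 0, Inf, num / den)
  }
}

#' Filter candidates against the unenriched control
#'
#' Computes the enrichment ratio `tpm_all / tpm_ct` per candidate and sets
#' `status` to `"high_confidence"` (ratio >= `hc_ratio`, inclusive) or
#' `"false_positive"`. A position absent from the control is maximally
#' enriched (ratio `+Inf`, high confidence); set `pseudocount > 0` for the
#' regularized alternative.
#'
#' @param x a `recaptss_calls` object from [call_candidates()].
#' @param ct_table [tag_count_table] of the unenriched control library.
#' @param hc_ratio high-confidence threshold (default 1).
#' @param pseudocount added to numerator and denominator TPM when > 0.
#' @return the updated `recaptss_calls` object.
#' @export
filter_high_confidence <- function(x, ct_table, hc_ratio = 1,
                                   pseudocount = 0) {
  stopifnot(inherits(x, "recaptss_calls"), inherits(ct_table, "tag_count_table"))
  rec <- x$tss
  rec$tpm_ct <- tpm(ct_table, rec$chrom, rec$pos, rec$strand)
  rec$enrich_ratio <- ratio_with_pseudocount(rec$tpm_all, rec$tpm_ct,
                                             pseudocount)
  rec$status <- ifelse(rec$enrich_ratio >= hc_ratio,
                       "high_confidence", "false_positive")
  x$tss <- rec
  x$params$hc_ratio <- hc_ratio
  x$params$pseudocount <- pseudocount
  x$library_sizes["ct"] <- library_size(ct_table)
  x
}

#' Classify high-confidence TSSs into Pol II and non-Pol II
#'
#' Computes the CIP ratio `tpm_all / tpm_cip` and classifies each
#' high-confidence record as `"non_pol2"` (ratio >= `cip_threshold`,
#' CIP-sensitive: the 5' triphosphate was removed by CIP, so the position
#' is depleted in the CIP library) or `"pol2"` (CIP-resistant cap).
#' Quadrants follow the enrichment/CIP ratio plane: II = high-confidence
#' non-Pol II, IV = high-confidence Pol II; false positives split into
#' I (CIP ratio >= threshold) and III. `pol_class` is set only for
#' high-confidence records.
#'
#' @param x a `recaptss_calls` object that has been through
#'   [filter_high_confidence()].
#' @param cip_table [tag_count_table] of the CIP-pretreated enriched
#'   library.
#' @param cip_threshold classification threshold on the CIP ratio
#'   (default 4, inclusive on the non-Pol II side).
#' @return the updated `recaptss_calls` object.
#' @export
classify_polymerase <- function(x, cip_table, cip_threshold = 4) {
  stopifnot(inherits(x, "recaptss_calls"), inherits(cip_table, "tag_count_table"))
  rec <- x$tss
  if (nrow(rec) && any(rec$status == "candidate")) {
    stop("classify_polymerase: run filter_high_confidence() first ",
         "(records still have status 'candidate')")
  }
  rec$tpm_cip <- tpm(cip_table, rec$chrom, rec$pos, rec$strand)
  rec$cip_ratio <- ratio_with_pseudocount(rec$tpm_all, rec$tpm_cip,
                                          x$params$pseudocount)
  hc <- rec$status == "high_confidence"
  sensitive <- rec$cip_ratio >= cip_threshold
  rec$pol_class <- ifelse(hc, ifelse(sensitive, "non_pol2", "pol2"),
                          "unassigned")
  rec$quadrant <- ifelse(hc, ifelse(sensitive, "II", "IV"),
                         ifelse(sensitive, "I", "III"))
  x$tss <- rec
  x$params$cip_threshold <- cip_threshold
  x$library_sizes["cip"] <- library_size(cip_table)
  x
}

#' Call, filter and classify TSSs from three matched libraries
#'
#' One-step wrapper chaining [call_candidates()],
#' [filter_high_confidence()] and [classify_polymerase()]: candidates are
#' positions with enriched-library TPM >= `min_tpm`; candidates enriched
#' over the unenriched control (`tpm_all/tpm_ct >= hc_ratio`) are high
#' confidence; high-confidence TSSs depleted by CIP pretreatment
#' (`tpm_all/tpm_cip >= cip_threshold`) are non-Pol II, the rest Pol II.
#'
#' @inheritParams call_candidates
#' @inheritParams filter_high_confidence
#' @inheritParams classify_polymerase
#' @param ct_table,cip_table control and CIP [tag_count_table]s.
#' @return a `recaptss_calls` object; see [as.data.frame.recaptss_calls()]
#'   for the per-record fields.
#' @examples
#' all <- tag_count_table("chr1", c(100, 200), c("+", "+"),
#'                        c(10, 10), 1e6)
#' ct  <- tag_count_table("chr1", 100, "+", 5, 1e6)
#' cip <- tag_count_table("chr1", 100, "+", 10, 1e6)
#' calls <- call_tss(all, ct, cip)
#' as.data.frame(calls)
#' @export
call_tss <- function(all_table, ct_table, cip_table, min_tpm = 1,
                     hc_ratio = 1, cip_threshold = 4, pseudocount = 0) {
  x <- call_candidates(all_table, min_tpm = min_tpm)
  x <- filter_high_confidence(x, ct_table, hc_ratio = hc_ratio,
                              pseudocount = pseudocount)
  classify_polymerase(x, cip_table, cip_threshold = cip_threshold)
}

#' @method as.data.frame recaptss_calls
#' @export
as.data.frame.recaptss_calls <- function(x, ...) x$tss

#' @export
print.recaptss_calls <- function(x, ...) {
  rec <- x$tss
  cat("ReCappable-seq TSS calls\n")
  cat(sprintf("  candidates:      %d (TPM >= %g)\n", nrow(rec),
              x$params$min_tpm))
  if (!is.na(x$params$hc_ratio)) {
    hc <- sum(rec$status == "high_confidence")
    cat(sprintf("  high confidence: %d (%.1f%%, enrichment ratio >= %g)\n",
                hc, if (nrow(rec)) 100 * hc / nrow(rec) else NA_real_,
                x$params$hc_ratio))
  }
  if (!is.na(x$params$cip_threshold)) {
    cat(sprintf("  Pol II:          %d\n  non-Pol II:      %d (CIP ratio >= %g)\n",
                sum(rec$pol_class == "pol2"),
                sum(rec$pol_class == "non_pol2"), x$params$cip_threshold))
  }
  invisible(x)
}

#' Summarize TSS calls
#'
#' @param object a `recaptss_calls` object.
#' @param ... unused.
#' @return a list with candidate/high-confidence/class counts, the
#'   high-confidence fraction (percent), the non-Pol II share of
#'   high-confidence positions (percent) and quadrant counts.
#' @method summary recaptss_calls
#' @export
summary.recaptss_calls <- function(object, ...) {
  rec <- object$tss
  n <- nrow(rec)
  hc <- sum(rec$status == "high_confidence")
  pol2 <- sum(rec$pol_class == "pol2")
  non <- sum(rec$pol_class == "non_pol2")
  out <- list(
    n_candidates = n,
    n_high_confidence = hc,
    n_false_positive = sum(rec$status == "false_positive"),
    n_pol2 = pol2,
    n_non_pol2 = non,
    hc_fraction_pct = if (n) 100 * hc / n else NA_real_,
    non_pol2_share_pct = if (hc) 100 * non / (pol2 + non) else NA_real_,
    quadrants = table(factor(rec$quadrant, c("I", "II", "III", "IV", "none"))),
    params = object$params
  )
  class(out) <- "summary.recaptss_calls"
  out
}

#' @export
print.summary.recaptss_calls <- function(x, ...) {
  cat(sprintf("candidates %d | high-confidence %d (%.1f%%) | Pol II %d | non-Pol II %d (%.0f%% of HC)\n",
              x$n_candidates, x$n_high_confidence, x$hc_fraction_pct,
              x$n_pol2, x$n_non_pol2, x$non_pol2_share_pct))
  cat("quadrants: ",
      paste(names(x$quadrants), as.integer(x$quadrants), sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

#' Quadrant scatter of TSS calls
#'
#' Plots each candidate in the (enrichment ratio, CIP ratio) plane on log
#' scales, with dotted lines at the high-confidence and CIP thresholds
#' dividing the four quadrants. Infinite ratios are drawn at the plot
#' margin.
#'
#' @param x a classified `recaptss_calls` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @method plot recaptss_calls
#' @export
plot.recaptss_calls <- function(x, ...) {
  rec <- x$tss
  if (!nrow(rec)) {
    warning("no TSS records to plot")
    return(invisible(x))
  }
  cap <- function(v) {
    fin <- v[is.finite(v) & v > 0]
    hi <- if (length(fin)) max(fin) * 2 else 10
    lo <- if (length(fin)) min(fin) / 2 else 0.1
    pmin(pmax(v, lo), hi)
  }
  er <- cap(rec$enrich_ratio)
  cr <- cap(rec$cip_ratio)
  cols <- c(pol2 = "#1f78b4", non_pol2 = "#e31a1c", unassigned = "grey60")
  graphics::plot(er, cr, log = "xy", pch = 20,
                 col = cols[rec$pol_class],
                 xlab = "enrichment ratio (ALL / Ct TPM)",
                 ylab = "CIP ratio (ALL / CIP TPM)", ...)
  graphics::abline(v = x$params$hc_ratio, lty = 3)
  graphics::abline(h = x$params$cip_threshold, lty = 3)
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 20,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Filter mitochondrial positions by unique-mapping ratio
#'
#' The mitochondrial genome shares sequence with nuclear pseudogenes
#' (NUMTs), so mitochondrial TSS positions are kept only when at least
#' `min_ratio` of their tags map uniquely (MAPQ above the aligner's
#' uniqueness threshold: > 3 for STAR, > 39 for Bowtie 2).
#'
#' @param tallies `data.frame` with columns `chrom`, `pos`, `strand`,
#'   `n_unique` and `n_total` per mitochondrial position.
#' @param min_ratio minimum unique fraction (default 0.8, inclusive).
#' @return the rows of `tallies` that pass, with a `ratio` column added.
#'   Positions with `n_total == 0` are dropped with a warning.
#' @export
mito_unique_filter <- function(tallies, min_ratio = 0.8) {
  stopifnot(all(c("n_unique", "n_total") %in% names(tallies)))
  if (any(tallies$n_unique > tallies$n_total)) {
    stop("mito_unique_filter: n_unique exceeds n_total")
  }
  empty <- tallies$n_total == 0
  if (any(empty)) {
    warning(sprintf("mito_unique_filter: dropping %d position(s) with no tags",
                    sum(empty)))
    tallies <- tallies[!empty, , drop = FALSE]
  }
  tallies$ratio <- tallies$n_unique / tallies$n_total
  out <- tallies[tallies$ratio >= min_ratio, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-position unique-mapping tallies from reads
#'
#' Convenience builder for [mito_unique_filter()]: tags reads, then counts
#' per position the total tags and the tags with MAPQ above
#' `mapq_threshold`.
#'
#' @param reads an [aligned_reads] table (restrict to the mitochondrial
#'   contig for the mitochondrial filter).
#' @param mapq_threshold uniqueness cutoff, exclusive (default 3, the
#'   STAR convention).
#' @return a `data.frame` with `chrom`, `pos`, `strand`, `n_unique`,
#'   `n_total`.
#' @export
mapq_unique_tallies <- function(reads, mapq_threshold = 3L) {
  tags <- extract_five_prime_tag(reads)
  key <- tag_key(tags$chrom, tags$pos, tags$strand)
  tot <- table(key)
  uni <- table(key[reads$mapq > mapq_threshold])
  first <- tags[!duplicated(key), , drop = FALSE]
  fk <- key[!duplicated(key)]
  data.frame(chrom = first$chrom, pos = first$pos, strand = first$strand,
             n_unique = as.integer(ifelse(is.na(match(fk, names(uni))), 0L,
                                          uni[fk])),
             n_total = as.integer(tot[fk]),
             stringsAsFactors = FALSE)
}
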