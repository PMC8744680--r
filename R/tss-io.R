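# Serialization of classified TSS calls: TSV, bedGraph, BED6.

#' Write and read the classified TSS table
#'
#' Plain TSV with one row per record and all fields of the calls table,
#' plus header comments recording thresholds and library sizes so the
#' round trip restores the object.
#'
#' @param x a `recaptss_calls` object.
#' @param path file path.
#' @return `write_tss_table` returns `path` invisibly; `read_tss_table`
#'   a `recaptss_calls` object.
#' @export
write_tss_table <- function(x, path) {
  stopifnot(inherits(x, "recaptss_calls"))
  con <- file(path, "w")
  on.exit(close(con))
  p <- x$params
  writeLines(sprintf("# min_tpm=%g hc_ratio=%g cip_threshold=%g pseudocount=%g",
                     p$min_tpm, p$hc_ratio, p$cip_threshold, p$pseudocount), con)
  writeLines(sprintf("# library_sizes=%.0f,%.0f,%.0f",
                     x$library_sizes[["all"]], x$library_sizes[["ct"]],
                     x$library_sizes[["cip"]]), con)
  suppressWarnings(write.table(x$tss, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' @rdname write_tss_table
#' @export
read_tss_table <- function(path) {
  hdr <- readLines(path, n = 2L)
  pairs <- strsplit(sub("^# ", "", hdr[1]), " ")[[1]]
  pv <- as.numeric(sub("^.*=", "", pairs))
  ls <- as.numeric(strsplit(sub("^# library_sizes=", "", hdr[2]), ",")[[1]])
  rec <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  structure(
    list(tss = rec,
         params = list(min_tpm = pv[1], hc_ratio = pv[2],
                       cip_threshold = pv[3], pseudocount = pv[4]),
         library_sizes = c(all = ls[1], ct = ls[2], cip = ls[3])),
    class = "recaptss_calls"
  )
}

#' Write high-confidence TSSs as bedGraph
#'
#' Browser-track convention: one row `chrom start0 end value` per
#' high-confidence TSS with `value = +tpm_all` for Pol II (CIP-resistant)
#' and `-tpm_all` for non-Pol II (CIP-sensitive) positions. Strand is not
#' encoded (use [write_bed6()] for the lossless companion).
#'
#' @param x a classified `recaptss_calls` object; records with
#'   `pol_class == "unassigned"` among the high-confidence set are an
#'   error.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  stopifnot(inherits(x, "recaptss_calls"))
  rec <- x$tss[x$tss$status == "high_confidence", , drop = FALSE]
  if (any(rec$pol_class == "unassigned")) {
    stop("write_bedgraph: unclassified high-confidence records; ",
         "run classify_polymerase() first")
  }
  value <- ifelse(rec$pol_class == "pol2", rec$tpm_all, -rec$tpm_all)
  lines <- sprintf("%s\t%d\t%d\t%s", rec$chrom, rec$pos, rec$pos + 1L,
                   sprintf("%.15g", value))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bedgraph
#' @return `read_bedgraph` returns a `data.frame` with `chrom`, `pos`,
#'   `tpm_all`, `pol_class` (sign-decoded).
#' @export
read_bedgraph <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "value"),
                   colClasses = c("character", "integer", "integer", "numeric"))
  data.frame(chrom = df$chrom, pos = df$start,
             tpm_all = abs(df$value),
             pol_class = ifelse(df$value >= 0, "pol2", "non_pol2"),
             stringsAsFactors = FALSE)
}

#' Write and read classified TSSs as BED6
#'
#' Lossless single-nucleotide BED6: `name` carries the polymerase class,
#' `score` the enriched-library TPM at full precision, `strand` the TSS
#' strand. Only high-confidence records are written.
#'
#' @param x a classified `recaptss_calls` object.
#' @param path file path.
#' @return `write_bed6` returns `path` invisibly; `read_bed6` a
#'   `data.frame` with `chrom`, `pos`, `strand`, `tpm_all`, `pol_class`.
#' @export
write_bed6 <- function(x, path) {
  stopifnot(inherits(x, "recaptss_calls"))
  rec <- x$tss[x$tss$status == "high_confidence", , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", rec$chrom, rec$pos,
                   rec$pos + 1L, rec$pol_class,
                   sprintf("%.15g", rec$tpm_all),
                   rec$strand)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bed6
#' @export
read_bed6 <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "name", "score",
                                 "strand"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "numeric", "character"))
  data.frame(chrom = df$chrom, pos = df$start, strand = df$strand,
             tpm_all = df$score, pol_class = df$name,
             stringsAsFactors = FALSE)
}
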