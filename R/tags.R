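# 5' end tag counting and TPM normalization.

#' Per-position 5' end tag-count table
#'
#' A `tag_count_table` stores, for every (chromosome, 0-based position,
#' strand) at which at least one read 5' end was observed, the number of
#' tags, together with the library size (total primary mappable reads)
#' used as the tags-per-million denominator. The study also calls this
#' normalization "TRM" (TSS tags per million mapped reads); the two names
#' denote the same quantity and this package uses TPM throughout.
#'
#' @param chrom,pos,strand position keys (`pos` 0-based).
#' @param count tag counts (>= 1).
#' @param library_size total primary mappable reads in the library.
#' @return a `data.frame` of class `tag_count_table` with columns
#'   `chrom`, `pos`, `strand`, `count` and attribute `library_size`.
#' @seealso [count_tags()], [tpm()]
#' @export
tag_count_table <- function(chrom = character(), pos = integer(),
                            strand = character(), count = integer(),
                            library_size = 0) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   strand = as.character(strand), count = as.integer(count),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(tag_key(df$chrom, df$pos, df$strand))) {
    stop("tag_count_table: duplicate (chrom, pos, strand) keys")
  }
  df <- df[order(df$chrom, df$pos, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "library_size") <- as.numeric(library_size)
  class(df) <- c("tag_count_table", "data.frame")
  df
}

#' @rdname tag_count_table
#' @param x a `tag_count_table`.
#' @export
library_size <- function(x) attr(x, "library_size")

#' Extract the 5' end tag of aligned reads
#'
#' The 5' end tag is the 5'-most *aligned* nucleotide of a read: the
#' leftmost aligned base (`start`) for `+` reads and the rightmost
#' (`end - 1`) for `-` reads. Soft-clipped (nontemplated) prefixes occupy
#' no reference position and never shift the tag.
#'
#' @param reads an [aligned_reads] table of primary, mapped reads.
#' @return a `data.frame` with columns `chrom`, `pos` (0-based), `strand`.
#' @export
extract_five_prime_tag <- function(reads) {
  if (any(is.na(reads$chrom) | is.na(reads$start))) {
    stop_recaptss("extract_five_prime_tag: unmapped read in input",
                  "recaptss_unmapped_read")
  }
  data.frame(
    chrom = reads$chrom,
    pos = ifelse(reads$strand == "+", reads$start, reads$end - 1L),
    strand = reads$strand,
    stringsAsFactors = FALSE
  )
}

#' Count 5' end tags per genomic position
#'
#' Reduces a library to strand-aware single-nucleotide 5' tag counts.
#' Counting is order-independent: any permutation of the input rows yields
#' the same table.
#'
#' @param reads an [aligned_reads] table for one library.
#' @param min_mapq minimum mapping quality; reads below are discarded.
#' @param primary_only drop secondary/supplementary alignments (default
#'   `TRUE`, matching the study's `samtools -F 256` selection).
#' @param library_size TPM denominator; defaults to the number of primary
#'   mapped reads in `reads` (override to reproduce a down-sampled
#'   normalization).
#' @return a [tag_count_table].
#' @export
count_tags <- function(reads, min_mapq = 0L, primary_only = TRUE,
                       library_size = NULL) {
  if (is.null(library_size)) library_size <- sum(reads$is_primary)
  if (nrow(reads) == 0L) {
    return(tag_count_table(library_size = library_size))
  }
  keep <- reads$mapq >= min_mapq
  if (primary_only) keep <- keep & reads$is_primary
  reads <- reads[keep, , drop = FALSE]
  if (nrow(reads) == 0L) {
    return(tag_count_table(library_size = library_size))
  }
  tags <- extract_five_prime_tag(reads)
  key <- tag_key(tags$chrom, tags$pos, tags$strand)
  cnt <- table(key)
  first <- tags[!duplicated(key), , drop = FALSE]
  first_key <- key[!duplicated(key)]
  tag_count_table(first$chrom, first$pos, first$strand,
                  as.integer(cnt[first_key]), library_size)
}

#' Tags per million for one or all positions
#'
#' `TPM = count / library_size * 1e6`. Positions absent from the table
#' have TPM 0. A library size of 0 is an error rather than a silent 0/0.
#'
#' @param table a [tag_count_table].
#' @param chrom,pos,strand optional position query; omitted, returns the
#'   TPM vector for all rows of the table.
#' @return numeric TPM value(s).
#' @export
tpm <- function(table, chrom = NULL, pos = NULL, strand = NULL) {
  ls <- library_size(table)
  if (is.null(ls) || ls <= 0) {
    stop_recaptss("tpm: library_size must be > 0", "recaptss_zero_library")
  }
  if (is.null(chrom)) {
    return(table$count / ls * 1e6)
  }
  idx <- match(tag_key(chrom, pos, strand),
               tag_key(table$chrom, table$pos, table$strand))
  cnt <- ifelse(is.na(idx), 0L, table$count[idx])
  cnt / ls * 1e6
}

#' Down-sample a library to a fixed number of primary reads
#'
#' Samples exactly `n` primary mappable reads uniformly without
#' replacement (the study merged replicates and sampled 63 million
#' primary mappable reads before TSS analysis). Reproducible for a fixed
#' seed; the result is a subset of the input rows.
#'
#' @param reads an [aligned_reads] table.
#' @param n number of primary reads to keep.
#' @param seed RNG seed.
#' @return an [aligned_reads] table with `n` rows.
#' @export
downsample <- function(reads, n, seed = NULL) {
  prim <- which(reads$is_primary)
  if (n > length(prim)) {
    stop(sprintf("downsample: requested %d reads but only %d primary reads available",
                 n, length(prim)))
  }
  idx <- with_seed(seed, sample(prim, n))
  out <- reads[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of reads mapping to rRNA
#'
#' `100 * n_rrna_mapped / n_genome_mapped`, the study's specificity
#' surrogate for processed/degraded 5' ends (counted against a processed
#' rRNA reference that excludes the Pol III-transcribed 5S genes).
#'
#' @param n_rrna_mapped reads mapped to the rRNA reference.
#' @param n_genome_mapped reads mapped to the genome (> 0).
#' @return percentage.
#' @export
rrna_fraction <- function(n_rrna_mapped, n_genome_mapped) {
  if (n_genome_mapped <= 0) {
    stop("rrna_fraction: n_genome_mapped must be > 0")
  }
  100 * n_rrna_mapped / n_genome_mapped
}

#' Profile nontemplated 5' prefixes at one position
#'
#' Tallies the soft-clipped 5' prefixes of reads tagged at a single
#' (chrom, position, strand) — the signature of transcription-initiation
#' stuttering with nontemplated adenosines seen at mitochondrial
#' promoters. Prefixes are compared in read orientation (a clip stored as
#' "T" in SAM query space for a `-` read is an "A" prefix after
#' orientation normalization, which [read_alignments()] applies).
#'
#' @param reads_at_position an [aligned_reads] table whose rows all share
#'   one tag position.
#' @return a list with `counts` (named prefix tally; `""` = templated
#'   start) and `a_prefix_fraction` (fraction of reads whose prefix is
#'   non-empty and all-A).
#' @export
nontemplated_prefix_profile <- function(reads_at_position) {
  if (nrow(reads_at_position) == 0L) {
    return(list(counts = integer(0), a_prefix_fraction = NA_real_))
  }
  tg <- extract_five_prime_tag(reads_at_position)
  if (length(unique(tag_key(tg$chrom, tg$pos, tg$strand))) != 1L) {
    stop("nontemplated_prefix_profile: reads must share one tag position")
  }
  pref <- reads_at_position$softclip_seq
  counts <- table(pref)
  all_a <- nchar(pref) > 0L & grepl("^A+$", pref)
  list(counts = setNames(as.integer(counts), names(counts)),
       a_prefix_fraction = mean(all_a))
}

#' Read and write CTSS tag tables
#'
#' The on-disk form of a [tag_count_table] is a CTSS-style TSV with
#' columns `chrom pos0 strand count tpm` and a `# library_size=` header
#' line so that the round trip is lossless.
#'
#' @param table a [tag_count_table].
#' @param path file path.
#' @return `write_ctss` returns `path` invisibly; `read_ctss` a
#'   [tag_count_table].
#' @export
write_ctss <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# library_size=%.0f", library_size(table)), con)
  writeLines("chrom\tpos0\tstrand\tcount\ttpm", con)
  if (nrow(table)) {
    tpms <- if (library_size(table) > 0) tpm(table) else rep(NA_real_, nrow(table))
    writeLines(sprintf("%s\t%d\t%s\t%d\t%s", table$chrom, table$pos,
                       table$strand, table$count,
                       sprintf("%.15g", tpms)), con)
  }
  invisible(path)
}

#' @rdname write_ctss
#' @export
read_ctss <- function(path) {
  first <- readLines(path, n = 1L)
  ls <- as.numeric(sub("^# library_size=", "", first))
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = c("character", "integer", "character",
                                  "integer", "numeric"))
  tag_count_table(df$chrom, df$pos0, df$strand, df$count, ls)
}
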