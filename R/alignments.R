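# Alignment ingestion: SAM/BAM -> aligned_reads data.frame.

#' Construct a table of aligned reads
#'
#' The in-memory representation of a library is a plain `data.frame` with
#' one row per alignment, class `aligned_reads`. Coordinates are 0-based
#' half-open: `start` is the leftmost aligned reference position, `end` one
#' past the rightmost. `five_prime_softclip` is the number of soft-clipped
#' bases at the *read's* 5' end (leading clip for `+` reads, trailing clip
#' in reference orientation for `-` reads) and `softclip_seq` holds those
#' bases in read orientation (5' to 3' of the read, reverse-complemented
#' from the stored SAM sequence for `-` reads).
#'
#' @param chrom character, reference sequence names.
#' @param start,end integer, 0-based half-open aligned span (`start < end`).
#' @param strand character, `"+"` or `"-"`.
#' @param mapq integer mapping quality (>= 0).
#' @param is_primary logical, primary-alignment flag.
#' @param five_prime_softclip integer, clipped bases at the read's 5' end.
#' @param softclip_seq character, the clipped bases in read orientation.
#' @param qname optional read names.
#' @return a `data.frame` of class `aligned_reads`.
#' @export
aligned_reads <- function(chrom, start, end, strand,
                          mapq = 60L, is_primary = TRUE,
                          five_prime_softclip = 0L, softclip_seq = "",
                          qname = NULL) {
  n <- length(chrom)
  df <- data.frame(
    qname = if (is.null(qname)) sprintf("read%d", seq_len(n)) else qname,
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    mapq = rep_len(as.integer(mapq), n),
    is_primary = rep_len(as.logical(is_primary), n),
    five_prime_softclip = rep_len(as.integer(five_prime_softclip), n),
    softclip_seq = rep_len(as.character(softclip_seq), n),
    stringsAsFactors = FALSE
  )
  validate_aligned_reads(df)
}

validate_aligned_reads <- function(df) {
  if (nrow(df)) {
    if (any(df$start >= df$end)) {
      stop("aligned_reads: 'start' must be < 'end' (0-based half-open)")
    }
    if (!all(df$strand %in% c("+", "-"))) {
      stop("aligned_reads: strand must be '+' or '-'")
    }
    if (any(df$five_prime_softclip != nchar(df$softclip_seq))) {
      stop("aligned_reads: five_prime_softclip must equal nchar(softclip_seq)")
    }
  }
  class(df) <- c("aligned_reads", "data.frame")
  df
}

#' Read alignments from a SAM or BAM file
#'
#' Loads mapped alignments into an [aligned_reads] table. SAM input is
#' converted on the fly with [Rsamtools::asBam()]. Unmapped records are
#' dropped; secondary/supplementary alignments are dropped unless
#' `keep_secondary` (the study selected primary alignments with
#' `samtools -F 256`). For paired-end input only read 1 contributes
#' (5'-end libraries are analysed single-end).
#'
#' The 5' soft clip is taken from the CIGAR: the leading `S` operation for
#' `+` alignments, the trailing one for `-` alignments. Clipped bases are
#' reported in read orientation.
#'
#' @param path path to a SAM or BAM file.
#' @param keep_secondary keep secondary/supplementary alignments
#'   (diagnostics only; default `FALSE`).
#' @return an [aligned_reads] `data.frame`.
#' @export
read_alignments <- function(path, keep_secondary = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE)
    )
    on.exit(unlink(bam), add = TRUE)
  }
  what <- c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar", "seq")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1]]
  flag <- res$flag
  mapped <- !bitwAnd(flag, 4L)
  primary <- !bitwAnd(flag, 256L) & !bitwAnd(flag, 2048L)
  paired <- bitwAnd(flag, 1L) > 0L
  read1 <- !paired | bitwAnd(flag, 64L) > 0L
  keep <- mapped & read1 & (keep_secondary | primary)
  if (!any(keep)) {
    return(validate_aligned_reads(aligned_reads(character(), integer(),
                                                integer(), character())))
  }
  cigar <- res$cigar[keep]
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  strand <- as.character(res$strand[keep])
  start0 <- res$pos[keep] - 1L
  seq <- as.character(res$seq[keep])

  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  lead <- vapply(seq_along(ops), function(i) {
    if (length(ops[[i]]) && ops[[i]][1] == "S") lens[[i]][1] else 0L
  }, integer(1))
  trail <- vapply(seq_along(ops), function(i) {
    k <- length(ops[[i]])
    if (k && ops[[i]][k] == "S") lens[[i]][k] else 0L
  }, integer(1))
  clip_n <- ifelse(strand == "+", lead, trail)
  clip_seq <- character(length(clip_n))
  plus <- strand == "+"
  clip_seq[plus] <- substr(seq[plus], 1L, clip_n[plus])
  minus <- !plus
  if (any(minus)) {
    tail_seq <- substr(seq[minus], nchar(seq[minus]) - clip_n[minus] + 1L,
                       nchar(seq[minus]))
    tail_seq[clip_n[minus] == 0L] <- ""
    clip_seq[minus] <- revcomp_chr(tail_seq)
  }

  validate_aligned_reads(data.frame(
    qname = res$qname[keep],
    chrom = as.character(res$rname[keep]),
    start = start0,
    end = start0 + refw,
    strand = strand,
    mapq = as.integer(res$mapq[keep]),
    is_primary = primary[keep],
    five_prime_softclip = as.integer(clip_n),
    softclip_seq = clip_seq,
    stringsAsFactors = FALSE
  ))
}

#' Write aligned reads as SAM
#'
#' Emits a minimal valid SAM file (used by the simulator so that the
#' counting path can be exercised through standard alignment files without
#' an external aligner). Sequences are taken from `genome` when supplied,
#' otherwise written as `*`. Soft-clipped 5' prefixes are encoded in the
#' CIGAR and prepended to the sequence.
#'
#' @param reads an [aligned_reads] table.
#' @param path output path (`.sam`).
#' @param genome optional [Biostrings::DNAStringSet] for sequence fields
#'   and `@SQ` lengths; without it, `@SQ` lengths are inferred as
#'   `max(end)` per contig.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, genome = NULL) {
  contigs <- unique(reads$chrom)
  if (!is.null(genome)) {
    contigs <- names(genome)
    lens <- Biostrings::width(genome)
  } else {
    lens <- vapply(contigs, function(cc) {
      max(reads$end[reads$chrom == cc])
    }, integer(1))
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", contigs, lens))
  n <- nrow(reads)
  if (n == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  flag <- ifelse(reads$strand == "-", 16L, 0L) +
    ifelse(reads$is_primary, 0L, 256L)
  alen <- reads$end - reads$start
  clip <- reads$five_prime_softclip
  # CIGAR in reference orientation: 5' clip leads for +, trails for -
  cigar <- ifelse(clip > 0L,
                  ifelse(reads$strand == "+",
                         sprintf("%dS%dM", clip, alen),
                         sprintf("%dM%dS", alen, clip)),
                  sprintf("%dM", alen))
  if (is.null(genome)) {
    seq <- rep("*", n)
  } else {
    aligned <- as.character(
      extract_seqs(genome, reads$chrom, reads$start + 1L, reads$end)
    )
    clip_ref <- ifelse(reads$strand == "+", reads$softclip_seq,
                       revcomp_chr(reads$softclip_seq))
    seq <- ifelse(reads$strand == "+", paste0(clip_ref, aligned),
                  paste0(aligned, clip_ref))
  }
  rows <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  reads$qname, flag, reads$chrom, reads$start + 1L,
                  reads$mapq, cigar, seq)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# Extract per-read subsequences of a DNAStringSet by contig name.
extract_seqs <- function(genome, chrom, start1, end1) {
  out <- Biostrings::DNAStringSet(rep("", length(chrom)))
  for (cc in unique(chrom)) {
    i <- chrom == cc
    out[i] <- Biostrings::extractAt(
      genome[[cc]], IRanges::IRanges(start1[i], end1[i])
    )
  }
  out
}
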