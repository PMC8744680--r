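# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never clobbers user-level seeds.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Composite character key for a (chrom, pos, strand) triple. Positions are
# 0-based throughout the package.
tag_key <- function(chrom, pos, strand) {
  paste(chrom, pos, strand, sep = "\r")
}

#' Convert between 0-based and 1-based coordinates
#'
#' All positions inside recaptss are 0-based half-open (BED/bedGraph
#' convention). These helpers centralize conversion to and from the 1-based
#' convention used by SAM, GTF and genome-browser displays.
#'
#' @param pos integer vector of positions.
#' @return integer vector of converted positions.
#' @examples
#' pos0_to_pos1(0L)  # 1
#' pos1_to_pos0(1L)  # 0
#' @export
pos0_to_pos1 <- function(pos) as.integer(pos) + 1L

#' @rdname pos0_to_pos1
#' @export
pos1_to_pos0 <- function(pos) as.integer(pos) - 1L

revcomp_chr <- function(x) {
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

stop_recaptss <- function(msg, class) {
  stop(structure(
    class = c(class, "recaptss_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
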