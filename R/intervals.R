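## Genomic intervals are plain data.frames with columns chrom, start, end
## (0-based half-open throughout the package) and optionally strand/id.
## GenomicRanges is used internally for all overlap arithmetic; conversion
## adds 1 to start because GRanges is 1-based closed.

#' Validate a 0-based half-open interval table
#'
#' @param df data.frame with at least chrom, start, end.
#' @param what label used in error messages.
#' @return `df`, invisibly, after validation.
#' @export
validate_intervals <- function(df, what = "interval table") {
  check_cols(df, c("chrom", "start", "end"), what)
  if (any(is.na(df$chrom) | !nzchar(df$chrom))) {
    stopf("%s: empty chromosome name", what)
  }
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) {
    stopf("%s: invalid coordinates (need 0 <= start < end) at row %d (%s:%s-%s)",
          what, bad[1], df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]])
  }
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", "."))) {
    stopf("%s: strand must be one of +, -, .", what)
  }
  invisible(df)
}

#' Convert a 0-based half-open interval table to a GRanges
#' @param df interval data.frame (chrom, start, end, optional strand).
#' @return a [GenomicRanges::GRanges] object.
#' @keywords internal
as_granges0 <- function(df) {
  strand <- if ("strand" %in% names(df)) {
    ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  } else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

# Inverse of as_granges0 (strand "*" maps back to ".").
granges0_as_df <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ifelse(s == "*", ".", s),
    stringsAsFactors = FALSE
  )
}

# indices of rows in `query` overlapping any row of `subject` by >= 1 bp
overlaps_any0 <- function(query, subject) {
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  IRanges::overlapsAny(as_granges0(query), as_granges0(subject),
                       ignore.strand = TRUE)
}
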