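#' @importFrom IRanges IRanges reduce start end
NULL

#' Construct a genomic interval table
#'
#' Intervals are held as a data frame with integer `start`/`end` columns in
#' 0-based, half-open coordinates (the BED convention). VCF positions are
#' converted on ingest.
#'
#' @param chrom character vector of contig names
#' @param start,end integer vectors, 0-based half-open; `start < end`
#' @return data.frame with columns chrom, start, end
#' @export
genomic_intervals <- function(chrom, start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(chrom) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  if (any(is.na(chrom)) || any(!nzchar(chrom))) {
    stop("interval chrom must be non-empty")
  }
  if (any(is.na(start)) || any(is.na(end)) || any(start >= end)) {
    stop("intervals require start < end")
  }
  data.frame(chrom = as.character(chrom), start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Merge overlapping or touching intervals
#'
#' Coalesces intervals per contig; touching intervals (end == start) merge.
#' Idempotent and order-independent.
#'
#' @param ivs interval data.frame from [genomic_intervals()]
#' @return merged interval data.frame, sorted by chrom then start
#' @export
merge_intervals <- function(ivs) {
  if (nrow(ivs) == 0L) return(ivs)
  out <- lapply(split(ivs, ivs$chrom), function(d) {
    # IRanges is 1-based closed; half-open [s, e) maps to [s + 1, e]
    r <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    data.frame(chrom = d$chrom[1L], start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Expand intervals by a symmetric flank
#'
#' @param ivs interval data.frame
#' @param flank non-negative integer number of bases added on each side
#' @return flanked (unmerged) interval data.frame; starts floored at 0
#' @export
flank_intervals <- function(ivs, flank) {
  flank <- as.integer(flank)
  stopifnot(length(flank) == 1L, !is.na(flank), flank >= 0L)
  if (nrow(ivs) == 0L) return(ivs)
  ivs$start <- pmax(0L, ivs$start - flank)
  ivs$end <- ivs$end + flank
  ivs
}

#' Total number of bases covered by an interval set
#'
#' @param ivs interval data.frame (overlaps are collapsed first)
#' @return integer base count
#' @export
interval_bases <- function(ivs) {
  m <- merge_intervals(ivs)
  sum(m$end - m$start)
}

#' Test positions for membership in an interval set
#'
#' @param chrom character vector of contigs
#' @param pos integer vector of 0-based positions
#' @param ivs interval data.frame
#' @return logical vector
#' @export
in_intervals <- function(chrom, pos, ivs) {
  if (nrow(ivs) == 0L || length(pos) == 0L) return(rep(FALSE, length(pos)))
  vapply(seq_along(pos), function(i) {
    any(ivs$chrom == chrom[i] & ivs$start <= pos[i] & pos[i] < ivs$end)
  }, logical(1L))
}

#' Write intervals as a BED file
#'
#' @param ivs interval data.frame
#' @param path output file
#' @param names optional name column
#' @export
write_bed <- function(ivs, path, names = NULL) {
  d <- ivs[, c("chrom", "start", "end")]
  if (!is.null(names)) d$name <- names
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
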