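#' Per-base depth profile
#'
#' @param chrom contig
#' @param start 0-based position of the first base of `depths`
#' @param depths non-negative integer vector, one entry per base
#' @return list of class `ird_depth`
#' @export
depth_profile <- function(chrom, start, depths) {
  depths <- as.integer(depths)
  if (length(depths) < 1L || any(is.na(depths)) || any(depths < 0L)) {
    stop("depths must be a non-empty vector of non-negative integers")
  }
  structure(list(chrom = chrom, start = as.integer(start), depths = depths),
            class = "ird_depth")
}

#' Read a depth profile from a three-column TSV (chrom, 1-based pos, depth)
#'
#' Positions must be contiguous; expanded to a dense per-base vector.
#'
#' @param path TSV path (with header)
#' @return an `ird_depth`
#' @export
read_depth_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "depth") %in% names(d)))
  d <- d[order(d$pos), ]
  if (length(unique(d$chrom)) != 1L) stop("one contig per depth profile")
  if (!all(diff(d$pos) == 1L)) stop("depth positions must be contiguous")
  depth_profile(d$chrom[1L], as.integer(d$pos[1L]) - 1L, d$depth)
}

region_depths <- function(profile, region) {
  if (nrow(region) == 0L) stop("empty region")
  span_end <- profile$start + length(profile$depths)
  out <- list()
  for (i in seq_len(nrow(region))) {
    if (region$chrom[i] != profile$chrom ||
        region$start[i] < profile$start || region$end[i] > span_end) {
      stop("region extends outside the depth profile span")
    }
    idx <- (region$start[i] - profile$start + 1L):(region$end[i] - profile$start)
    out[[i]] <- list(start = region$start[i], depths = profile$depths[idx])
  }
  out
}

#' Fraction of region bases at or above a depth threshold
#'
#' @param profile an `ird_depth`
#' @param region interval data.frame (within the profile span)
#' @param threshold depth threshold (inclusive)
#' @return fraction in [0, 1]
#' @export
region_fraction <- function(profile, region, threshold) {
  segs <- region_depths(profile, merge_intervals(region))
  d <- unlist(lapply(segs, `[[`, "depths"))
  mean(d >= threshold)
}

#' Maximal low-coverage runs within a region
#'
#' Finds maximal stretches of consecutive bases with depth strictly below
#' `threshold` and length at least `min_len`; these are the stretches that
#' warrant capillary-sequencing fallback.
#'
#' @param profile an `ird_depth`
#' @param region interval data.frame
#' @param threshold depth threshold (bases below it are low)
#' @param min_len shortest run reported (default 1: report all runs)
#' @return interval data.frame of runs
#' @export
low_coverage_runs <- function(profile, region, threshold, min_len = 1L) {
  segs <- region_depths(profile, merge_intervals(region))
  runs <- list()
  for (s in segs) {
    low <- which(s$depths < threshold)
    if (!length(low)) next
    brk <- c(0L, which(diff(low) > 1L), length(low))
    for (j in seq_len(length(brk) - 1L)) {
      r <- low[(brk[j] + 1L):brk[j + 1L]]
      if (length(r) >= min_len) {
        runs[[length(runs) + 1L]] <-
          genomic_intervals(profile$chrom, s$start + r[1L] - 1L,
                            s$start + r[length(r)])
      }
    }
  }
  if (!length(runs)) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  do.call(rbind, runs)
}

#' GC content of a nucleotide sequence
#'
#' @param seq A/C/G/T/N string; N bases are excluded from the denominator
#' @return (G + C) / (non-N length)
#' @export
gc_content <- function(seq) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty sequence")
  f <- Biostrings::alphabetFrequency(Biostrings::DNAString(seq),
                                     baseOnly = TRUE)
  denom <- sum(f[c("A", "C", "G", "T")])
  if (denom == 0L) stop("sequence contains no unambiguous bases")
  unname((f[["G"]] + f[["C"]]) / denom)
}

#' Coverage report over a clinical region
#'
#' @param profile an `ird_depth`
#' @param region interval data.frame
#' @param thresholds depth thresholds to tabulate (the service reports 20x
#'   and 50x)
#' @param run_threshold,run_min_len parameters of the fallback-run search
#' @return list with per-threshold fractions and flagged fallback runs
#' @export
coverage_report <- function(profile, region, thresholds = c(20L, 50L),
                            run_threshold = 50L, run_min_len = 100L) {
  fr <- vapply(thresholds, function(t) region_fraction(profile, region, t),
               numeric(1L))
  list(fractions = stats::setNames(fr, paste0("ge", thresholds, "x")),
       fallback_runs = low_coverage_runs(profile, region, run_threshold,
                                         run_min_len))
}
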