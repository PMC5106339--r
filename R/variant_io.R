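#' Classify an allele pair as SNV, insertion, deletion or delins
#'
#' @param ref,alt allele strings (VCF spelling)
#' @return one of "SNV", "insertion", "deletion", "delins"
#' @export
variant_class <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  ifelse(nr == 1L & na == 1L, "SNV",
         ifelse(nr == na, "delins",
                ifelse(nr > na, "deletion", "insertion")))
}

trim_alleles <- function(pos, ref, alt) {
  # shared suffix first, then shared prefix; keep >= 1 base per allele
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalise a variant against its reference window
#'
#' Trims shared flanking bases and left-aligns indels to the smallest
#' position that spells an identical haplotype (the parsimony convention:
#' indels keep a single anchor base). Idempotent.
#'
#' @param pos 0-based position of `ref` within the contig
#' @param ref,alt allele strings
#' @param reference_window reference sequence context containing the variant
#' @param window_start 0-based contig position of the first base of
#'   `reference_window`
#' @return list with pos, ref, alt, vclass
#' @export
normalize_variant <- function(pos, ref, alt, reference_window, window_start = 0L) {
  pos <- as.integer(pos); window_start <- as.integer(window_start)
  ref <- toupper(ref); alt <- toupper(alt)
  reference_window <- toupper(reference_window)
  off <- pos - window_start
  if (off < 0L || off + nchar(ref) > nchar(reference_window)) {
    stop("variant falls outside the supplied reference window")
  }
  if (substr(reference_window, off + 1L, off + nchar(ref)) != ref) {
    stop("REF allele does not match the reference sequence at position ", pos)
  }
  if (ref == alt) stop("REF and ALT are identical")
  v <- trim_alleles(pos, ref, alt)
  # left-align pure indels: while alleles end with the same base and a
  # reference base precedes, roll the representation one base left
  while (nchar(v$ref) != nchar(v$alt) &&
         (nchar(v$ref) == 1L || nchar(v$alt) == 1L) &&
         v$pos > window_start &&
         substr(v$ref, nchar(v$ref), nchar(v$ref)) ==
           substr(v$alt, nchar(v$alt), nchar(v$alt))) {
    prev <- substr(reference_window, v$pos - window_start, v$pos - window_start)
    v$ref <- paste0(prev, substr(v$ref, 1L, nchar(v$ref) - 1L))
    v$alt <- paste0(prev, substr(v$alt, 1L, nchar(v$alt) - 1L))
    v$pos <- v$pos - 1L
    v <- trim_alleles(v$pos, v$ref, v$alt)
  }
  if (v$ref == v$alt) stop("alleles are identical after trimming")
  list(pos = v$pos, ref = v$ref, alt = v$alt,
       vclass = variant_class(v$ref, v$alt))
}

#' Apply a variant to a sequence (haplotype splice)
#'
#' Utility used for equivalence checks: returns the sequence with `ref`
#' replaced by `alt` at `pos` (0-based within `seq`).
#'
#' @param seq reference sequence
#' @param pos 0-based offset of ref within seq
#' @param ref,alt allele strings
#' @return the edited sequence
#' @export
splice_variant <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos + 1L, pos + nchar(ref)) == ref)
  paste0(substr(seq, 1L, pos), alt,
         substr(seq, pos + 1L + nchar(ref), nchar(seq)))
}

zygosity_from_gt <- function(gt, chrom, sex) {
  gt <- sub("|", "/", gt, fixed = TRUE)
  alleles <- strsplit(gt, "/", fixed = TRUE)[[1L]]
  if (length(alleles) == 1L) {
    if (!chrom %in% c("chrX", "chrY", "X", "Y") || !identical(sex, "M")) {
      stop("haploid genotype outside male chrX/chrY: GT=", gt)
    }
    return("hemi")
  }
  nonref <- unique(alleles[alleles != "0"])
  if (length(nonref) > 1L) "het_het"
  else if (all(alleles == nonref)) "hom"
  else "het"
}

#' Read a per-patient VCF into a patient case
#'
#' One genotype call is emitted per alternate allele; sites with two distinct
#' alternate alleles (GT 1/2) yield two calls, each tagged `het_het`. Depth is
#' read from FORMAT/DP, alternate-supporting reads from FORMAT/AD, and the
#' per-call quality from `mqv_key` (falling back to GQ when absent).
#'
#' @param path VCF 4.x file (single sample)
#' @param patient_id patient identifier
#' @param sex "M" or "F"
#' @param referral_category one of [referral_classes()]
#' @param platform "SOLiD" or "HiSeq"
#' @param mqv_key FORMAT key carrying the mean quality value
#' @return an object of class `ird_patient` with a `calls` data.frame
#'   (chrom, pos 0-based, ref, alt, vclass, zygosity, depth, mqv, alt_reads)
#' @export
read_vcf <- function(path, patient_id, sex, referral_category, platform,
                     mqv_key = "MQV") {
  stopifnot(sex %in% c("M", "F"), platform %in% c("SOLiD", "HiSeq"))
  if (!referral_category %in% REFERRAL_CLASSES) {
    stop("unknown referral category: ", referral_category)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  calls <- list()
  if (n > 0L) {
    if (ncol(v@gt) < 2L) stop("VCF carries no sample genotype column")
    fmt <- v@gt[, 1L]
    smp <- v@gt[, 2L]
    for (i in seq_len(n)) {
      keys <- strsplit(fmt[i], ":", fixed = TRUE)[[1L]]
      vals <- strsplit(smp[i], ":", fixed = TRUE)[[1L]]
      names(vals) <- keys[seq_along(vals)]
      if (!"GT" %in% names(vals)) {
        stop("missing GT at VCF line for ", fix[i, "CHROM"], ":", fix[i, "POS"])
      }
      gt <- vals[["GT"]]
      zyg <- tryCatch(zygosity_from_gt(gt, fix[i, "CHROM"], sex),
                      error = function(e) stop(conditionMessage(e),
                                               " (record ", i, ")", call. = FALSE))
      depth <- if ("DP" %in% names(vals)) as.integer(vals[["DP"]]) else NA_integer_
      mqv <- if (mqv_key %in% names(vals)) as.numeric(vals[[mqv_key]])
             else if ("GQ" %in% names(vals)) as.numeric(vals[["GQ"]])
             else NA_real_
      ad <- if ("AD" %in% names(vals))
        suppressWarnings(as.integer(strsplit(vals[["AD"]], ",", fixed = TRUE)[[1L]]))
      else NA_integer_
      alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
      gt_alleles <- strsplit(sub("|", "/", gt, fixed = TRUE), "/", fixed = TRUE)[[1L]]
      used <- sort(unique(as.integer(gt_alleles[gt_alleles != "0" & gt_alleles != "."])))
      if (length(used) == 0L) next
      for (a in used) {
        if (a > length(alts)) stop("GT refers to missing ALT allele (record ", i, ")")
        alt_reads <- if (length(ad) > a) ad[a + 1L] else NA_integer_
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = fix[i, "CHROM"],
          pos = as.integer(fix[i, "POS"]) - 1L,  # VCF is 1-based
          ref = fix[i, "REF"], alt = alts[a],
          vclass = variant_class(fix[i, "REF"], alts[a]),
          zygosity = zyg, depth = depth, mqv = mqv, alt_reads = alt_reads,
          stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), vclass = character(), zygosity = character(),
               depth = integer(), mqv = numeric(), alt_reads = integer(),
               stringsAsFactors = FALSE)
  bad <- !is.na(calls$alt_reads) & !is.na(calls$depth) &
    (calls$alt_reads < 0L | calls$alt_reads > calls$depth)
  if (any(bad)) stop("alt_reads outside [0, depth] in ", path)
  structure(list(patient_id = patient_id, sex = sex,
                 referral_category = referral_category, platform = platform,
                 calls = calls),
            class = "ird_patient")
}

#' Construct a patient case programmatically
#'
#' @param patient_id patient identifier
#' @param sex "M" or "F"
#' @param referral_category one of [referral_classes()]
#' @param platform "SOLiD" or "HiSeq"
#' @param calls call data.frame (chrom, pos 0-based, ref, alt, vclass,
#'   zygosity, depth, mqv, alt_reads); defaults to no calls
#' @return an `ird_patient`
#' @export
patient_case <- function(patient_id, sex, referral_category, platform,
                         calls = NULL) {
  stopifnot(sex %in% c("M", "F"), platform %in% c("SOLiD", "HiSeq"),
            referral_category %in% REFERRAL_CLASSES)
  if (is.null(calls)) {
    calls <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        vclass = character(), zygosity = character(),
                        depth = integer(), mqv = numeric(),
                        alt_reads = integer(), stringsAsFactors = FALSE)
  }
  structure(list(patient_id = patient_id, sex = sex,
                 referral_category = referral_category, platform = platform,
                 calls = calls),
            class = "ird_patient")
}

#' @export
print.ird_patient <- function(x, ...) {
  cat("patient", x$patient_id, sprintf("(%s, %s, %s):", x$sex,
      x$referral_category, x$platform), nrow(x$calls), "calls\n")
  invisible(x)
}

#' Variant key string
#'
#' Canonical `chrom:pos:ref:alt` key (1-based position, matching VCF output
#' convention).
#'
#' @param chrom,pos,ref,alt vectors; pos 0-based internally
#' @return character vector of keys
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  sprintf("%s:%d:%s:%s", chrom, as.integer(pos) + 1L, ref, alt)
}

#' Write a results table as TSV
#'
#' Fixed column order; positions are emitted 1-based.
#'
#' @param results data.frame of per-variant results
#' @param path output file
#' @export
write_results_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
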