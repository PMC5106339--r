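#' Platform quality-control profile
#'
#' @param platform platform label
#' @param snv_min_depth minimum sequencing depth for SNVs (inclusive)
#' @param snv_min_mqv minimum mean quality value for SNVs
#' @param snv_mqv_strict TRUE when the MQV bound is a strict inequality
#' @param min_alt_reads indel rule: strict lower bound on alt-supporting reads
#'   (exclusive), or NULL
#' @param min_alt_fraction indel rule: strict lower bound on the alt-read
#'   fraction (exclusive), or NULL; exactly one of the two indel rules applies
#' @return an object of class `ird_qc`
#' @export
platform_qc <- function(platform, snv_min_depth, snv_min_mqv, snv_mqv_strict,
                        min_alt_reads = NULL, min_alt_fraction = NULL) {
  if (is.null(min_alt_reads) == is.null(min_alt_fraction)) {
    stop("exactly one indel rule (min_alt_reads or min_alt_fraction) is required")
  }
  stopifnot(snv_min_depth > 0, snv_min_mqv > 0)
  structure(list(platform = platform,
                 snv_min_depth = as.integer(snv_min_depth),
                 snv_min_mqv = as.numeric(snv_min_mqv),
                 snv_mqv_strict = isTRUE(snv_mqv_strict),
                 min_alt_reads = min_alt_reads,
                 min_alt_fraction = min_alt_fraction),
            class = "ird_qc")
}

#' Default QC profiles of the two sequencing platforms
#'
#' SOLiD: SNVs need >=18x depth and MQV strictly >18; indels need support
#' from strictly more than 5 independent reads. HiSeq: SNVs need >=50x depth
#' and MQV >=45; indels need support from strictly more than 25% of aligned
#' reads.
#'
#' @return named list of `ird_qc` profiles
#' @export
default_qc_profiles <- function() {
  list(
    SOLiD = platform_qc("SOLiD", snv_min_depth = 18L, snv_min_mqv = 18,
                        snv_mqv_strict = TRUE, min_alt_reads = 5L),
    HiSeq = platform_qc("HiSeq", snv_min_depth = 50L, snv_min_mqv = 45,
                        snv_mqv_strict = FALSE, min_alt_fraction = 0.25)
  )
}

#' Apply platform QC to one genotype call
#'
#' @param call one-row data.frame (or list) with vclass, depth, mqv, alt_reads
#' @param qc an `ird_qc` profile
#' @return list(pass = logical, reason = character)
#' @export
apply_qc <- function(call, qc) {
  stopifnot(inherits(qc, "ird_qc"))
  if (call$vclass == "SNV") {
    if (is.na(call$depth) || is.na(call$mqv)) {
      return(list(pass = FALSE, reason = "qc_fail(missing_metric)"))
    }
    mqv_ok <- if (qc$snv_mqv_strict) call$mqv > qc$snv_min_mqv
              else call$mqv >= qc$snv_min_mqv
    pass <- call$depth >= qc$snv_min_depth && mqv_ok
  } else {
    if (!is.null(qc$min_alt_reads)) {
      if (is.na(call$alt_reads)) {
        return(list(pass = FALSE, reason = "qc_fail(missing_metric)"))
      }
      pass <- call$alt_reads > qc$min_alt_reads
    } else {
      if (is.na(call$alt_reads) || is.na(call$depth) || call$depth == 0L) {
        return(list(pass = FALSE, reason = "qc_fail(missing_metric)"))
      }
      pass <- call$alt_reads / call$depth > qc$min_alt_fraction
    }
  }
  list(pass = pass, reason = if (pass) NA_character_ else "qc_fail")
}

#' Read a population-frequency table
#'
#' TSV with columns chrom, pos (1-based), ref, alt, dbsnp_af, evs_af,
#' evs_mean_depth, evs_cohort_ok, exac_af, inhouse_count; empty cells mean
#' "absent from that database".
#'
#' @param path TSV path
#' @param inhouse_cohort_size number of in-house samples behind inhouse_count
#' @return data.frame keyed by a `key` column (`chrom:pos:ref:alt`)
#' @export
read_frequency_table <- function(path, inhouse_cohort_size = NA_integer_) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  num <- c("dbsnp_af", "evs_af", "evs_mean_depth", "exac_af")
  for (cn in num) if (cn %in% names(d)) d[[cn]] <- as.numeric(d[[cn]])
  if ("evs_cohort_ok" %in% names(d)) d$evs_cohort_ok <- as.logical(d$evs_cohort_ok)
  if (!"inhouse_count" %in% names(d)) d$inhouse_count <- 0L
  d$inhouse_count[is.na(d$inhouse_count)] <- 0L
  d$key <- sprintf("%s:%d:%s:%s", d$chrom, as.integer(d$pos), d$ref, d$alt)
  attr(d, "inhouse_cohort_size") <- inhouse_cohort_size
  d
}

#' Look up a frequency record for a variant key
#'
#' @param freqs frequency table from [read_frequency_table()]
#' @param key variant key (`chrom:pos:ref:alt`, 1-based)
#' @return one-row list of frequency fields; absent variants give all-NA
#'   frequencies and an in-house count of zero
#' @export
frequency_record <- function(freqs, key) {
  i <- match(key, freqs$key)
  if (is.na(i)) {
    return(list(dbsnp_af = NA_real_, evs_af = NA_real_,
                evs_mean_depth = NA_real_, evs_cohort_ok = FALSE,
                exac_af = NA_real_, inhouse_count = 0L))
  }
  list(dbsnp_af = freqs$dbsnp_af[i], evs_af = freqs$evs_af[i],
       evs_mean_depth = freqs$evs_mean_depth[i],
       evs_cohort_ok = isTRUE(freqs$evs_cohort_ok[i]),
       exac_af = freqs$exac_af[i], inhouse_count = freqs$inhouse_count[i])
}

#' Is a variant a benign common polymorphism?
#'
#' True when the allele frequency exceeds 1% in dbSNP, or exceeds 1% in the
#' Exome Variant Server with a sufficiently large and diverse cohort and a
#' mean EVS read depth above 18x.
#'
#' @param freq frequency record (list or one-row data.frame)
#' @return logical
#' @export
is_common_polymorphism <- function(freq) {
  db <- !is.na(freq$dbsnp_af) && freq$dbsnp_af > 0.01
  evs <- !is.na(freq$evs_af) && freq$evs_af > 0.01 &&
    isTRUE(freq$evs_cohort_ok) &&
    !is.na(freq$evs_mean_depth) && freq$evs_mean_depth > 18
  db || evs
}

#' Flag a rare variant recurring suspiciously often in-house
#'
#' Variants below 1% in population databases but recurring at a high rate in
#' the in-house cohort are treated as neutral or as platform artefacts.
#'
#' @param freq frequency record with inhouse_count
#' @param inhouse_cohort_size total in-house cohort size (> 0)
#' @param threshold recurrence fraction; recurrence strictly above it flags
#' @return logical
#' @export
recurrence_flag <- function(freq, inhouse_cohort_size, threshold = 0.10) {
  inhouse_cohort_size <- as.integer(inhouse_cohort_size)
  if (is.na(inhouse_cohort_size) || inhouse_cohort_size <= 0L) {
    stop("inhouse_cohort_size must be positive")
  }
  freq$inhouse_count / inhouse_cohort_size > threshold
}

#' Triage a patient's calls down to the clinically analysable set
#'
#' Filters are applied in order: region restriction (coding regions +/- 5 bp
#' plus special intronic sites), platform QC, common-polymorphism removal,
#' in-house recurrence removal. The first failing filter is recorded as the
#' drop reason; retained and dropped calls partition the input.
#'
#' @param case an `ird_patient`
#' @param pan an `ird_panel`
#' @param freqs frequency table ([read_frequency_table()])
#' @param qc_profiles named list of `ird_qc`, e.g. [default_qc_profiles()]
#' @param inhouse_cohort_size in-house cohort size for the recurrence rule
#' @param recurrence_threshold see [recurrence_flag()]
#' @return an `ird_triage` object: list(retained, dropped) of call
#'   data.frames; `dropped` carries a `reason` column; both carry `gene`
#' @export
triage_patient <- function(case, pan, freqs, qc_profiles = default_qc_profiles(),
                           inhouse_cohort_size = NA_integer_,
                           recurrence_threshold = 0.10) {
  stopifnot(inherits(case, "ird_patient"), inherits(pan, "ird_panel"))
  qc <- qc_profiles[[case$platform]]
  if (is.null(qc)) stop("no QC profile for platform ", case$platform)
  if (is.na(inhouse_cohort_size)) {
    ics <- attr(freqs, "inhouse_cohort_size")
    inhouse_cohort_size <- if (is.null(ics)) NA_integer_ else as.integer(ics)
  }
  calls <- case$calls
  regions <- panel_clinical_regions(pan)
  n <- nrow(calls)
  gene <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    hit <- regions$chrom == calls$chrom[i] &
      regions$start <= calls$pos[i] & calls$pos[i] < regions$end
    # deletions/delins overlapping the region by any base also count
    if (!any(hit) && nchar(calls$ref[i]) > 1L) {
      hit <- regions$chrom == calls$chrom[i] &
        regions$start < calls$pos[i] + nchar(calls$ref[i]) &
        calls$pos[i] < regions$end
    }
    if (!any(hit)) { reason[i] <- "off_region"; next }
    gene[i] <- regions$gene[which(hit)[1L]]
    q <- apply_qc(calls[i, ], qc)
    if (!q$pass) { reason[i] <- q$reason; next }
    fr <- frequency_record(freqs, variant_key(calls$chrom[i], calls$pos[i],
                                              calls$ref[i], calls$alt[i]))
    if (is_common_polymorphism(fr)) { reason[i] <- "common_polymorphism"; next }
    if (!is.na(inhouse_cohort_size) && inhouse_cohort_size > 0L &&
        recurrence_flag(fr, inhouse_cohort_size, recurrence_threshold)) {
      reason[i] <- "recurrent_artefact"; next
    }
  }
  calls$gene <- gene
  keep <- is.na(reason)
  dropped <- calls[!keep, , drop = FALSE]
  dropped$reason <- reason[!keep]
  structure(list(retained = calls[keep, , drop = FALSE], dropped = dropped,
                 patient_id = case$patient_id),
            class = "ird_triage")
}

#' @export
print.ird_triage <- function(x, ...) {
  cat("triage for", x$patient_id, "-", nrow(x$retained), "retained,",
      nrow(x$dropped), "dropped\n")
  if (nrow(x$dropped)) print(table(x$dropped$reason))
  invisible(x)
}

#' Summarise retrospective population frequencies of a variant set
#'
#' Matches variant keys against a retrospective frequency table (ExAC-style);
#' variants absent from the table count as frequency zero.
#'
#' @param keys character vector of variant keys (`chrom:pos:ref:alt`)
#' @param exac named numeric vector or data.frame with key/af columns
#' @param above threshold for the "fraction above" statistic (default 1%)
#' @return list(mean_af, median_af, max_af, frac_above)
#' @export
retrospective_af_summary <- function(keys, exac, above = 0.01) {
  if (is.data.frame(exac)) {
    af <- exac$af[match(keys, exac$key)]
  } else {
    af <- unname(exac[keys])
  }
  af[is.na(af)] <- 0
  list(mean_af = mean(af), median_af = stats::median(af), max_af = max(af),
       frac_above = mean(af > above))
}
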