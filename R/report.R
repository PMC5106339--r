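ZYGOSITIES <- c("hom", "het", "hemi", "het_het")
STAGES <- c("raw", "analysed", "reported")
VCLASSES <- c("SNV", "indel")

#' Round half away from zero to a fixed number of decimals
#'
#' Printed percentages and rates use commercial (round-half-up) rounding,
#' not banker's rounding.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Assemble cohort-level results
#'
#' The container every reporting operation consumes. `variants` holds one
#' row per raw genotype call with stage flags: `analysed` marks calls that
#' survived triage, `reported` marks calls reported as (potentially) disease
#' causing. Zygosity is carried per stage (`zyg_analysed` from the NGS
#' pileup, `zyg_reported` as confirmed by capillary sequencing) because
#' confirmation can revise it.
#'
#' @param patients data.frame: patient_id, sex, referral_category, platform
#' @param variants data.frame: patient_id, key, vclass (SNV/indel), subtype,
#'   zyg_analysed, zyg_reported, analysed, reported, novel_db, term,
#'   truncating, coding, gene, novel_cause
#' @param diagnoses data.frame: patient_id, status, mode, gene, comphet,
#'   referral_category, concordant
#' @param carriers data.frame: patient_id, gene, key
#' @param panel_years data.frame: symbol, year (every panel gene)
#' @return list of class `ird_cohort`
#' @export
cohort_results <- function(patients, variants, diagnoses, carriers,
                           panel_years) {
  stopifnot(!anyDuplicated(patients$patient_id),
            all(variants$patient_id %in% patients$patient_id),
            all(diagnoses$patient_id %in% patients$patient_id),
            all(variants$vclass %in% VCLASSES))
  if (any(variants$reported & !variants$analysed)) {
    stop("reported variants must be a subset of analysed variants")
  }
  structure(list(patients = patients, variants = variants,
                 diagnoses = diagnoses, carriers = carriers,
                 panel_years = panel_years),
            class = "ird_cohort")
}

#' @export
print.ird_cohort <- function(x, ...) {
  cat("IRD cohort:", nrow(x$patients), "patients,", nrow(x$variants),
      "raw calls,", sum(x$variants$analysed), "analysed,",
      sum(x$variants$reported), "reported;",
      sum(x$diagnoses$status != "none"), "molecular diagnoses\n")
  invisible(x)
}

stage_counts <- function(v, stage) {
  rows <- switch(stage, raw = rep(TRUE, nrow(v)), analysed = v$analysed,
                 reported = v$reported)
  zyg <- if (stage == "reported") v$zyg_reported else v$zyg_analysed
  t(vapply(VCLASSES, function(cl) {
    vapply(ZYGOSITIES, function(z) sum(rows & v$vclass == cl & zyg == z,
                                       na.rm = TRUE), numeric(1L))
  }, numeric(length(ZYGOSITIES))))
}

#' Tabulate cohort counts (the screening-process summary table)
#'
#' Produces the stage x class x zygosity tallies plus per-patient means,
#' novelty tallies and indel breakdowns.
#'
#' @param cohort an `ird_cohort`
#' @return an `ird_cohort_summary` list with elements `counts` (3-d array
#'   stage x class x zygosity), `totals`, `n_patients`, `means`, `novelty`,
#'   `indels` and `consequences`
#' @export
tabulate_cohort <- function(cohort) {
  v <- cohort$variants
  n_pat <- nrow(cohort$patients)
  counts <- array(0, dim = c(length(STAGES), length(VCLASSES),
                             length(ZYGOSITIES)),
                  dimnames = list(stage = STAGES, class = VCLASSES,
                                  zygosity = ZYGOSITIES))
  for (s in STAGES) counts[s, , ] <- stage_counts(v, s)
  totals <- apply(counts, c(1L, 2L), sum)
  an <- v[v$analysed, , drop = FALSE]
  rep_rows <- v[v$reported, , drop = FALSE]
  means <- list(
    analysed_per_patient = mean_per_patient(nrow(an), n_pat, 1L),
    snv_per_patient = mean_per_patient(sum(an$vclass == "SNV"), n_pat, 1L),
    het_snv_per_patient = mean_per_patient(
      sum(an$vclass == "SNV" & an$zyg_analysed == "het"), n_pat, 1L))
  novelty <- list(
    analysed = lapply(stats::setNames(VCLASSES, VCLASSES), function(cl) {
      tot <- sum(an$vclass == cl)
      nov <- sum(an$vclass == cl & an$novel_db)
      c(novel = nov, total = tot,
        pct = if (tot) round_half_up(100 * nov / tot) else 0)
    }),
    analysed_novel_terms = table(an$term[an$novel_db]))
  ind <- an[an$vclass == "indel", , drop = FALSE]
  indels <- list(
    total = nrow(ind),
    coding = sum(ind$coding),
    pct_coding = if (nrow(ind)) round_half_up(100 * sum(ind$coding) / nrow(ind))
                 else 0,
    truncating = sum(ind$truncating),
    truncating_het = sum(ind$truncating & ind$zyg_analysed == "het"),
    truncating_hom = sum(ind$truncating & ind$zyg_analysed == "hom"),
    subtypes = table(factor(ind$subtype,
                            levels = c("deletion", "insertion", "delins"))))
  structure(list(counts = counts, totals = totals, n_patients = n_pat,
                 means = means, novelty = novelty, indels = indels,
                 consequences = table(rep_rows$term)),
            class = "ird_cohort_summary")
}

#' @export
print.ird_cohort_summary <- function(x, ...) {
  cat("cohort of", x$n_patients, "patients\n")
  for (s in STAGES) {
    cat("\n", s, " calls:\n", sep = "")
    m <- cbind(x$counts[s, , ], total = x$totals[s, ])
    print(m)
  }
  cat("\nmean clinically analysed variants/patient:",
      x$means$analysed_per_patient,
      "(SNVs:", paste0(x$means$snv_per_patient, ")"), "\n")
  invisible(x)
}

#' Mean count per patient, rounded half-up
#'
#' @param count total count
#' @param n_patients number of patients (> 0)
#' @param decimals decimal places to report
#' @return rounded mean
#' @export
mean_per_patient <- function(count, n_patients, decimals = 1L) {
  if (n_patients <= 0L) stop("n_patients must be positive")
  round_half_up(count / n_patients, decimals)
}

#' Diagnostic yield and inheritance-mode breakdown
#'
#' @param cohort an `ird_cohort`
#' @return list(n_diagnosed, n_patients, yield_pct, by_mode, ar_hom,
#'   ar_comphet, by_status, n_carrier_patients, n_diagnosed_with_carrier)
#' @export
yield_stats <- function(cohort) {
  d <- cohort$diagnoses[cohort$diagnoses$status != "none", , drop = FALSE]
  n_pat <- nrow(cohort$patients)
  by_mode <- vapply(c(AR = "AR", AD = "AD", XL = "XL"),
                    function(m) sum(d$mode == m), numeric(1L))
  carrier_pat <- unique(cohort$carriers$patient_id)
  list(n_diagnosed = nrow(d), n_patients = n_pat,
       yield_pct = if (n_pat) round_half_up(100 * nrow(d) / n_pat) else 0,
       by_mode = by_mode,
       ar_hom = sum(d$mode == "AR" & !d$comphet),
       ar_comphet = sum(d$mode == "AR" & d$comphet),
       by_status = table(factor(d$status, levels = c("confirmed", "provisional"))),
       n_carrier_patients = length(carrier_pat),
       n_diagnosed_with_carrier = sum(carrier_pat %in% d$patient_id))
}

#' Diagnoses binned by gene-discovery era
#'
#' Rates divide the diagnoses attributed to an era's genes by the number of
#' panel genes discovered in that era (diagnosed or not).
#'
#' @param cohort an `ird_cohort`
#' @param breaks year cut points; defaults partition into pre-1995,
#'   1995-2004 and post-2005
#' @param labels era labels
#' @return data.frame: era, n_genes, n_diagnoses, diagnoses_per_gene
#'   (1 decimal), pct_of_diagnoses (whole percent)
#' @export
discovery_year_rates <- function(cohort,
                                 breaks = c(-Inf, 1994.5, 2004.5, Inf),
                                 labels = c("pre-1995", "1995-2004",
                                            "post-2005")) {
  d <- cohort$diagnoses[cohort$diagnoses$status != "none", , drop = FALSE]
  py <- cohort$panel_years
  yr <- py$year[match(d$gene, py$symbol)]
  if (any(is.na(yr))) {
    stop("diagnosed gene(s) missing a discovery year: ",
         paste(unique(d$gene[is.na(yr)]), collapse = ", "))
  }
  era_genes <- table(cut(py$year, breaks, labels))
  era_diag <- table(cut(yr, breaks, labels))
  total <- nrow(d)
  data.frame(era = labels,
             n_genes = as.integer(era_genes[labels]),
             n_diagnoses = as.integer(era_diag[labels]),
             diagnoses_per_gene = round_half_up(
               as.integer(era_diag[labels]) / as.integer(era_genes[labels]), 1L),
             pct_of_diagnoses = round_half_up(
               100 * as.integer(era_diag[labels]) / total),
             stringsAsFactors = FALSE)
}

#' Per-gene diagnostic spectrum across referral categories
#'
#' Partitions diagnosed genes by the number of distinct referral categories
#' among their diagnosed patients.
#'
#' @param cohort an `ird_cohort`
#' @return list(per_gene = data.frame(gene, n_patients, n_categories,
#'   categories), n_single_category, n_multi_category)
#' @export
gene_spectrum <- function(cohort) {
  d <- cohort$diagnoses[cohort$diagnoses$status != "none", , drop = FALSE]
  if (!nrow(d)) {
    return(list(per_gene = data.frame(gene = character(),
                                      n_patients = integer(),
                                      n_categories = integer(),
                                      categories = character(),
                                      stringsAsFactors = FALSE),
                n_single_category = 0L, n_multi_category = 0L))
  }
  per <- lapply(split(d, d$gene), function(g) {
    cats <- sort(unique(g$referral_category))
    data.frame(gene = g$gene[1L], n_patients = nrow(g),
               n_categories = length(cats),
               categories = paste(cats, collapse = "|"),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  per <- per[order(-per$n_patients, per$gene), , drop = FALSE]
  list(per_gene = per,
       n_single_category = sum(per$n_categories == 1L),
       n_multi_category = sum(per$n_categories > 1L))
}

#' Unique-variant statistics of the clinically reported set
#'
#' Deduplicates reported calls by variant key and tallies consequences,
#' dbSNP/EVS novelty and novel-cause-of-disease status.
#'
#' @param cohort an `ird_cohort`
#' @return list with unique counts, per-consequence novelty fractions and
#'   truncating-event statistics
#' @export
reported_variant_stats <- function(cohort) {
  v <- cohort$variants[cohort$variants$reported, , drop = FALSE]
  u <- v[!duplicated(v$key), , drop = FALSE]
  occ <- table(v$key)
  pct <- function(n, d) if (d) round_half_up(100 * n / d) else 0
  grp <- function(terms) u$term %in% terms
  sub <- function(sel) {
    c(novel = sum(u$novel_db[sel]), total = sum(sel),
      pct_novel = pct(sum(u$novel_db[sel]), sum(sel)))
  }
  # "premature termination" events: nonsense SNVs and out-of-frame indels
  truncating_u <- u$term %in% c("stop_gained", "frameshift")
  list(n_occurrences = nrow(v),
       n_unique = nrow(u),
       n_single = sum(occ == 1L),
       n_multi = sum(occ > 1L),
       max_occurrences = if (nrow(v)) max(occ) else 0L,
       consequences = table(u$term),
       novelty = list(all = sub(rep(TRUE, nrow(u))),
                      missense = sub(grp("missense")),
                      nonsense = sub(grp("stop_gained")),
                      oof_indel = sub(grp("frameshift"))),
       truncating = list(
         total = sum(truncating_u),
         snv = sum(truncating_u & u$vclass == "SNV"),
         indel = sum(truncating_u & u$vclass == "indel"),
         novel_cause = sum(truncating_u & u$novel_cause),
         pct_novel_cause = pct(sum(truncating_u & u$novel_cause),
                               sum(truncating_u))),
       n_novel_cause = sum(u$novel_cause))
}

#' Serialise a cohort summary to JSON
#'
#' @param cohort an `ird_cohort`
#' @param path output file
#' @return the path, invisibly
#' @export
write_cohort_json <- function(cohort, path) {
  tab <- tabulate_cohort(cohort)
  out <- list(
    n_patients = tab$n_patients,
    counts = lapply(STAGES, function(s) {
      m <- cbind(tab$counts[s, , ], total = tab$totals[s, ])
      stats::setNames(lapply(seq_len(nrow(m)), function(i) as.list(m[i, ])),
                      rownames(m))
    }),
    means = tab$means,
    yield = yield_stats(cohort)[c("n_diagnosed", "yield_pct", "by_mode")],
    discovery_year = discovery_year_rates(cohort))
  names(out$counts) <- STAGES
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
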