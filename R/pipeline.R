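#' Run the full diagnostic pipeline over a cohort directory
#'
#' Consumes the file set written by [simulate_cohort()] (or assembled in the
#' same layout from real data): `panel.tsv` + `cds.fasta`,
#' `reference.fasta`, `patients.tsv`, `frequency.tsv`, `evidence.tsv`,
#' `families.tsv` and one VCF per patient under `vcf/`. Each patient's
#' calls are normalised, triaged, annotated, classified and resolved into a
#' molecular diagnosis with carrier findings; compound-heterozygous
#' diagnoses are phased against the family file where genotypes exist.
#'
#' @param dir cohort directory
#' @param recurrence_threshold in-house recurrence fraction treated as
#'   artefact (strictly above)
#' @param strict_phase see [call_diagnosis()]
#' @return list with `cohort` (an `ird_cohort`), `diagnoses` (list of
#'   `ird_diagnosis`) and `triage` (list of `ird_triage`)
#' @export
run_cohort <- function(dir, recurrence_threshold = 0.10, strict_phase = FALSE) {
  pan <- load_panel(file.path(dir, "panel.tsv"), file.path(dir, "cds.fasta"))
  ref <- Biostrings::readDNAStringSet(file.path(dir, "reference.fasta"))
  patients <- utils::read.delim(file.path(dir, "patients.tsv"),
                                stringsAsFactors = FALSE)
  freqs <- read_frequency_table(file.path(dir, "frequency.tsv"),
                                inhouse_cohort_size = nrow(patients))
  evtab <- read_evidence_table(file.path(dir, "evidence.tsv"))
  fam_path <- file.path(dir, "families.tsv")
  fams <- if (file.exists(fam_path)) read_family_table(fam_path) else list()
  qc <- default_qc_profiles()

  variants <- list(); diagnoses <- list(); triages <- list()
  carrier_rows <- list(); diag_rows <- list()
  for (i in seq_len(nrow(patients))) {
    p <- patients[i, ]
    case <- read_vcf(file.path(dir, "vcf", paste0(p$patient_id, ".vcf")),
                     p$patient_id, p$sex, p$referral_category, p$platform)
    case <- normalize_case(case, ref)
    tri <- triage_patient(case, pan, freqs, qc,
                          recurrence_threshold = recurrence_threshold)
    ret <- tri$retained
    cls <- classify_retained(ret, pan, freqs, evtab)
    dx <- call_diagnosis(case, cls, pan, strict_phase = strict_phase)
    fam <- fams[[p$patient_id]]
    if (!is.null(fam) && dx$status != "none" &&
        nrow(dx$causal_variants) == 2L &&
        all(dx$causal_variants$zygosity %in% c("het", "het_het"))) {
      ph <- resolve_phase(dx$causal_variants$key, fam)
      dx <- apply_segregation(dx, ph$phase)
    }
    diagnoses[[p$patient_id]] <- dx
    triages[[p$patient_id]] <- tri
    diag_rows[[i]] <- data.frame(
      patient_id = p$patient_id, status = dx$status,
      mode = if (is.na(dx$mode)) NA_character_ else dx$mode,
      gene = dx$gene,
      comphet = dx$status != "none" && nrow(dx$causal_variants) == 2L &&
        all(dx$causal_variants$zygosity %in% c("het", "het_het")),
      referral_category = p$referral_category,
      concordant = dx$phenotype_concordant,
      stringsAsFactors = FALSE)
    if (nrow(dx$carrier_findings)) {
      carrier_rows[[i]] <- cbind(patient_id = p$patient_id,
                                 dx$carrier_findings)
    }
    variants[[i]] <- cohort_variant_rows(p$patient_id, case, tri, cls, dx)
  }
  variants <- do.call(rbind, variants)
  carriers <- if (length(carrier_rows)) do.call(rbind, carrier_rows) else
    data.frame(patient_id = character(), gene = character(),
               key = character(), stringsAsFactors = FALSE)
  panel_years <- data.frame(
    symbol = names(pan$genes),
    year = vapply(pan$genes, `[[`, integer(1L), "discovery_year"),
    stringsAsFactors = FALSE)
  cohort <- cohort_results(patients, variants, do.call(rbind, diag_rows),
                           carriers, panel_years)
  list(cohort = cohort, diagnoses = diagnoses, triage = triages)
}

#' Normalise every call of a patient case against the reference
#'
#' @param case an `ird_patient`
#' @param ref `DNAStringSet` of reference contigs
#' @return the case with trimmed, left-aligned calls
#' @export
normalize_case <- function(case, ref) {
  calls <- case$calls
  for (i in seq_len(nrow(calls))) {
    ctg <- calls$chrom[i]
    if (!ctg %in% names(ref)) stop("contig absent from reference: ", ctg)
    v <- normalize_variant(calls$pos[i], calls$ref[i], calls$alt[i],
                           as.character(ref[[ctg]]), 0L)
    calls$pos[i] <- v$pos; calls$ref[i] <- v$ref; calls$alt[i] <- v$alt
    calls$vclass[i] <- v$vclass
  }
  case$calls <- calls
  case
}

#' Annotate and classify triage-retained calls
#'
#' @param retained retained-call data.frame from [triage_patient()] (with a
#'   `gene` column)
#' @param pan an `ird_panel`
#' @param freqs frequency table
#' @param evtab evidence table
#' @return data.frame with key, gene, zygosity, vclass, term, truncating,
#'   protein_change, novel_db, class
#' @export
classify_retained <- function(retained, pan, freqs, evtab) {
  n <- nrow(retained)
  out <- data.frame(key = character(n), gene = character(n),
                    zygosity = character(n), vclass = character(n),
                    term = character(n), truncating = logical(n),
                    protein_change = NA_character_,
                    novel_db = logical(n), class = character(n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  for (i in seq_len(n)) {
    call <- retained[i, ]
    g <- pan$genes[[call$gene]]
    sp <- pan$special_intronic_sites
    sp <- sp[sp$gene == call$gene, , drop = FALSE]
    cons <- annotate_variant(call, g, sp)
    key <- variant_key(call$chrom, call$pos, call$ref, call$alt)
    fr <- frequency_record(freqs, key)
    ev <- evidence_for_key(evtab, key)
    out$key[i] <- key
    out$gene[i] <- call$gene
    out$zygosity[i] <- call$zygosity
    out$vclass[i] <- if (call$vclass == "SNV") "SNV" else "indel"
    out$term[i] <- cons$term
    out$truncating[i] <- cons$truncating
    out$protein_change[i] <- cons$protein_change
    out$novel_db[i] <- is_novel(fr)
    out$class[i] <- classify_variant(cons, g, fr, ev)
  }
  out
}

# one cohort-container row per raw call of one patient
cohort_variant_rows <- function(patient_id, case, tri, cls, dx) {
  calls <- case$calls
  if (nrow(calls) == 0L) {
    return(data.frame(patient_id = character(), key = character(),
                      vclass = character(), subtype = character(),
                      zyg_analysed = character(), zyg_reported = character(),
                      analysed = logical(), reported = logical(),
                      novel_db = logical(), novel_cause = logical(),
                      term = character(), truncating = logical(),
                      coding = logical(), gene = character(),
                      stringsAsFactors = FALSE))
  }
  key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  m <- match(key, cls$key)
  term <- cls$term[m]
  reported <- key %in% dx$causal_variants$key
  data.frame(
    patient_id = patient_id, key = key,
    vclass = ifelse(calls$vclass == "SNV", "SNV", "indel"),
    subtype = calls$vclass,
    zyg_analysed = calls$zygosity,
    zyg_reported = ifelse(reported, calls$zygosity, NA_character_),
    analysed = !is.na(m), reported = reported,
    novel_db = cls$novel_db[m], novel_cause = NA,
    term = term,
    truncating = !is.na(term) & term %in% c("stop_gained", "frameshift"),
    coding = !is.na(term) & !term %in% c("canonical_splice", "splice_region",
                                         "intronic_special"),
    gene = cls$gene[m], stringsAsFactors = FALSE)
}

#' Read the truth records written by [simulate_cohort()]
#'
#' @param dir cohort directory
#' @return list of per-patient truth records
#' @export
read_truth <- function(dir) {
  jsonlite::read_json(file.path(dir, "truth.json"))
}

#' Compare pipeline diagnoses with simulation truth
#'
#' @param diagnoses list of `ird_diagnosis` (from [run_cohort()])
#' @param truth truth list (from [read_truth()])
#' @return data.frame with one row per patient and a `match` column for the
#'   (status, gene, mode) triple
#' @export
compare_to_truth <- function(diagnoses, truth) {
  rows <- lapply(names(truth), function(pid) {
    tr <- truth[[pid]]
    dx <- diagnoses[[pid]]
    t_status <- tr$status
    t_gene <- if (is.null(tr$gene) || t_status == "none") NA_character_
              else tr$gene
    t_mode <- if (is.null(tr$mode) || t_status == "none") NA_character_
              else tr$mode
    data.frame(patient_id = pid,
               truth_status = t_status, status = dx$status,
               truth_gene = t_gene, gene = dx$gene,
               truth_mode = t_mode, mode = dx$mode,
               match = identical(t_status, dx$status) &&
                 identical(t_gene, dx$gene) && identical(t_mode, dx$mode),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
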