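PATHOGENIC_CLASSES <- c("likely_pathogenic", "clearly_pathogenic")

new_diagnosis <- function(patient_id, status = "none", mode = NA_character_,
                          gene = NA_character_, causal = NULL,
                          phase_confirmed = FALSE,
                          phenotype_concordant = NA,
                          mdt_review = FALSE, candidate_genes = character(),
                          carrier_findings = NULL) {
  if (is.null(causal)) {
    causal <- data.frame(key = character(), class = character(),
                         zygosity = character(), stringsAsFactors = FALSE)
  }
  if (is.null(carrier_findings)) {
    carrier_findings <- data.frame(gene = character(), key = character(),
                                   stringsAsFactors = FALSE)
  }
  structure(list(patient_id = patient_id, status = status, mode = mode,
                 gene = gene, causal_variants = causal,
                 phase_confirmed = phase_confirmed,
                 phenotype_concordant = phenotype_concordant,
                 mdt_review = mdt_review, candidate_genes = candidate_genes,
                 carrier_findings = carrier_findings),
            class = "ird_diagnosis")
}

#' @export
print.ird_diagnosis <- function(x, ...) {
  cat("diagnosis for", x$patient_id, "-", x$status)
  if (x$status != "none") {
    cat(sprintf(" (%s, %s%s%s)", x$gene, x$mode,
                if (x$phase_confirmed) ", phase confirmed" else "",
                if (isFALSE(x$phenotype_concordant)) ", phenotype discordant" else ""))
  }
  cat("\n")
  if (x$mdt_review) {
    cat("  MDT review:", paste(x$candidate_genes, collapse = ", "), "\n")
  }
  if (nrow(x$carrier_findings)) {
    cat("  carrier findings:", nrow(x$carrier_findings), "\n")
  }
  invisible(x)
}

# disease-state search within one gene; returns NULL or a state list
gene_disease_state <- function(g, vars, sex) {
  modes <- g$inheritance_modes
  path <- vars[vars$class %in% PATHOGENIC_CLASSES, , drop = FALSE]
  vus <- vars[vars$class == "vus", , drop = FALSE]
  het_like <- function(d) d[d$zygosity %in% c("het", "het_het"), , drop = FALSE]
  if ("AR" %in% modes) {
    hom <- path[path$zygosity == "hom", , drop = FALSE]
    if (nrow(hom)) {
      return(list(mode = "AR", comphet = FALSE,
                  causal = hom[1L, c("key", "class", "zygosity")]))
    }
    ph <- het_like(path)
    if (nrow(ph) >= 2L) {
      return(list(mode = "AR", comphet = TRUE,
                  causal = ph[1:2, c("key", "class", "zygosity")]))
    }
    if (nrow(ph) == 1L && nrow(het_like(vus)) >= 1L) {
      return(list(mode = "AR", comphet = TRUE,
                  causal = rbind(ph[1L, c("key", "class", "zygosity")],
                                 het_like(vus)[1L, c("key", "class", "zygosity")])))
    }
  }
  if ("XL" %in% modes && identical(sex, "M")) {
    hemi <- path[path$zygosity == "hemi", , drop = FALSE]
    if (nrow(hemi)) {
      return(list(mode = "XL", comphet = FALSE,
                  causal = hemi[1L, c("key", "class", "zygosity")]))
    }
  }
  if ("AD" %in% modes) {
    dom <- path[path$zygosity %in% c("het", "hom", "het_het"), , drop = FALSE]
    if (nrow(dom)) {
      return(list(mode = "AD", comphet = FALSE,
                  causal = dom[1L, c("key", "class", "zygosity")]))
    }
  }
  NULL
}

gene_carrier_findings <- function(g, vars, sex) {
  path <- vars[vars$class %in% PATHOGENIC_CLASSES, , drop = FALSE]
  keep <- path$zygosity %in% c("het", "het_het") &
    ("AR" %in% g$inheritance_modes |
       ("XL" %in% g$inheritance_modes & identical(sex, "F")))
  path <- path[keep, , drop = FALSE]
  if (!nrow(path)) {
    return(data.frame(gene = character(), key = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(gene = g$symbol, key = path$key, stringsAsFactors = FALSE)
}

#' Call a molecular diagnosis from a patient's classified variants
#'
#' Per gene, pathogenic-spectrum variants are assembled into disease states:
#' an AR gene with a homozygous pathogenic variant or two heterozygous
#' pathogenic variants is confirmed, pathogenic + VUS compound heterozygous
#' is provisional; an AD gene with one pathogenic het/hom is confirmed; an
#' XL gene with a hemizygous pathogenic variant in a male is confirmed. A
#' single heterozygous pathogenic variant in a recessive gene is a carrier
#' finding. Pathogenic disease states in more than one gene trigger
#' multidisciplinary-team review with no automatic status. Phenotype
#' concordance compares the diagnosed gene's phenotype categories with the
#' referral classification.
#'
#' @param case an `ird_patient`
#' @param classified data.frame with columns key, gene, zygosity, class
#'   (pathogenicity), one row per triage-retained variant
#' @param pan an `ird_panel`
#' @param strict_phase when TRUE, a compound heterozygote without confirmed
#'   phase is reported provisional rather than confirmed
#' @return an `ird_diagnosis`
#' @export
call_diagnosis <- function(case, classified, pan, strict_phase = FALSE) {
  stopifnot(inherits(case, "ird_patient"), inherits(pan, "ird_panel"))
  if (nrow(classified) > 0L) {
    if (any(is.na(classified$class)) ||
        !all(classified$class %in% PATHOGENICITY_LEVELS)) {
      stop("every variant must carry a pathogenicity class before diagnosis")
    }
    if (!all(classified$gene %in% names(pan$genes))) {
      stop("classified variant in a gene absent from the panel")
    }
    classified <- classified[order(classified$gene, classified$key), , drop = FALSE]
  }
  states <- list()
  for (gsym in unique(classified$gene)) {
    st <- gene_disease_state(pan$genes[[gsym]],
                             classified[classified$gene == gsym, , drop = FALSE],
                             case$sex)
    if (!is.null(st)) { st$gene <- gsym; states[[gsym]] <- st }
  }
  # a disease state counts as pathogenic-grade when it rests on at least one
  # clearly/likely pathogenic variant (all do, by construction)
  carrier_all <- function(exclude = character()) {
    out <- lapply(setdiff(unique(classified$gene), exclude), function(gsym) {
      gene_carrier_findings(pan$genes[[gsym]],
                            classified[classified$gene == gsym, , drop = FALSE],
                            case$sex)
    })
    out <- do.call(rbind, out)
    if (is.null(out)) out <- data.frame(gene = character(), key = character(),
                                        stringsAsFactors = FALSE)
    out
  }
  if (length(states) > 1L) {
    return(new_diagnosis(case$patient_id, status = "none",
                         mdt_review = TRUE, candidate_genes = names(states),
                         carrier_findings = carrier_all(names(states))))
  }
  if (length(states) == 0L) {
    return(new_diagnosis(case$patient_id, status = "none",
                         carrier_findings = carrier_all()))
  }
  st <- states[[1L]]
  any_vus <- any(st$causal$class == "vus")
  status <- if (any_vus) "provisional" else "confirmed"
  if (strict_phase && isTRUE(st$comphet)) status <- "provisional"
  g <- pan$genes[[st$gene]]
  new_diagnosis(case$patient_id, status = status, mode = st$mode,
                gene = st$gene, causal = st$causal,
                phase_confirmed = FALSE,
                phenotype_concordant =
                  case$referral_category %in% g$phenotype_categories,
                carrier_findings = carrier_all(st$gene))
}

#' Family genotype container
#'
#' @param proband_id proband identifier
#' @param relatives named list: role (e.g. "mother", "father") -> named
#'   character vector mapping variant key to zygosity ("het", "hom", "hemi")
#'   or "absent" for a tested-negative site; an unlisted key means the
#'   relative was not genotyped for it
#' @return list of class `ird_family`
#' @export
family_genotypes <- function(proband_id, relatives = list()) {
  if (anyDuplicated(names(relatives))) stop("relative roles must be unique")
  structure(list(proband_id = proband_id, relatives = relatives),
            class = "ird_family")
}

#' Read a family genotype table
#'
#' TSV with columns proband_id, role, key, zygosity.
#'
#' @param path TSV path
#' @return named list of `ird_family`, keyed by proband
#' @export
read_family_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(d, d$proband_id), function(p) {
    rel <- lapply(split(p, p$role), function(r) {
      stats::setNames(r$zygosity, r$key)
    })
    family_genotypes(p$proband_id[1L], rel)
  })
  out
}

parent_carries <- function(fam, role, key) {
  rel <- fam$relatives[[role]]
  if (is.null(rel) || !key %in% names(rel)) return(NA)
  rel[[key]] %in% c("het", "hom", "hemi")
}

#' Resolve the phase of a heterozygous variant pair from parental genotypes
#'
#' Each variant inherited from a different parent is in-trans; both from the
#' same parent in-cis; a missing parental genotype leaves the pair
#' unresolved. A variant carried by neither genotyped parent is flagged de
#' novo.
#'
#' @param keys character vector of the two proband-heterozygous variant keys
#' @param fam an `ird_family`
#' @param proband_keys keys present in the proband (for validation); NULL
#'   skips the check
#' @return list(phase = "in_trans"/"in_cis"/"unresolved",
#'   de_novo = named logical)
#' @export
resolve_phase <- function(keys, fam, proband_keys = NULL) {
  stopifnot(length(keys) == 2L, inherits(fam, "ird_family"))
  if (!is.null(proband_keys) && !all(keys %in% proband_keys)) {
    stop("variant pair not found in the proband")
  }
  m <- vapply(keys, function(k) parent_carries(fam, "mother", k), logical(1L))
  f <- vapply(keys, function(k) parent_carries(fam, "father", k), logical(1L))
  de_novo <- !is.na(m) & !is.na(f) & !m & !f
  names(de_novo) <- keys
  if (any(is.na(m)) || any(is.na(f))) {
    return(list(phase = "unresolved", de_novo = de_novo))
  }
  src <- function(i) c(if (m[i]) "mother", if (f[i]) "father")
  s1 <- src(1L); s2 <- src(2L)
  phase <- if (length(s1) == 1L && length(s2) == 1L) {
    if (s1 == s2) "in_cis" else "in_trans"
  } else "unresolved"
  list(phase = phase, de_novo = de_novo)
}

#' Update a compound-heterozygous diagnosis with segregation results
#'
#' In-trans confirms the phase; in-cis withdraws the recessive diagnosis and
#' converts both alleles to carrier findings; unresolved leaves the result
#' unchanged.
#'
#' @param result an `ird_diagnosis` resting on a compound heterozygote
#' @param phase "in_trans", "in_cis" or "unresolved" (e.g. from
#'   [resolve_phase()])
#' @return the updated `ird_diagnosis`
#' @export
apply_segregation <- function(result, phase) {
  stopifnot(inherits(result, "ird_diagnosis"),
            phase %in% c("in_trans", "in_cis", "unresolved"))
  if (phase == "in_trans") {
    result$phase_confirmed <- TRUE
  } else if (phase == "in_cis") {
    # both alleles sit on one haplotype: no disease state, but each remains
    # reportable as a carrier finding
    extra <- data.frame(gene = rep(result$gene, nrow(result$causal_variants)),
                        key = result$causal_variants$key,
                        stringsAsFactors = FALSE)
    result$carrier_findings <- rbind(result$carrier_findings, extra)
    result$status <- "none"
    result$mode <- NA_character_
    result$gene <- NA_character_
    result$causal_variants <- result$causal_variants[0L, , drop = FALSE]
    result$phase_confirmed <- FALSE
    result$phenotype_concordant <- NA
  }
  result
}
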