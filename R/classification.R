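PATHOGENICITY_LEVELS <- c("benign", "likely_benign", "vus",
                          "likely_pathogenic", "clearly_pathogenic")

#' Assemble an evidence bundle for one variant
#'
#' Evidence flags are inputs (curated from the literature and in-silico
#' tools), not computed by the package.
#'
#' @param functional_support published functional evidence of protein
#'   disruption
#' @param prior_segregation_report disease segregation reported in the
#'   literature without functional support
#' @param same_residue_alternative a different substitution of the same
#'   residue is an established cause of disease
#' @param insilico one of concordant_damaging / conflicting /
#'   concordant_benign / unavailable (SIFT + PolyPhen consensus)
#' @param phenotype_match variant gene fits the referral phenotype
#' @param novel not previously reported as disease causing
#' @return list of class `ird_evidence`
#' @export
evidence_bundle <- function(functional_support = FALSE,
                            prior_segregation_report = FALSE,
                            same_residue_alternative = FALSE,
                            insilico = "unavailable",
                            phenotype_match = FALSE,
                            novel = TRUE) {
  insilico <- match.arg(insilico, c("concordant_damaging", "conflicting",
                                    "concordant_benign", "unavailable"))
  structure(list(functional_support = isTRUE(functional_support),
                 prior_segregation_report = isTRUE(prior_segregation_report),
                 same_residue_alternative = isTRUE(same_residue_alternative),
                 insilico = insilico,
                 phenotype_match = isTRUE(phenotype_match),
                 novel = isTRUE(novel)),
            class = "ird_evidence")
}

#' Read a per-variant evidence table
#'
#' TSV keyed by variant (`key` column) with the [evidence_bundle()] fields.
#'
#' @param path TSV path
#' @return data.frame with a `key` column
#' @export
read_evidence_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (cn in c("functional_support", "prior_segregation_report",
               "same_residue_alternative", "phenotype_match", "novel")) {
    if (cn %in% names(d)) d[[cn]] <- as.logical(d[[cn]])
  }
  d
}

evidence_for_key <- function(evtab, key) {
  i <- match(key, evtab$key)
  if (is.na(i)) return(evidence_bundle())
  evidence_bundle(evtab$functional_support[i], evtab$prior_segregation_report[i],
                  evtab$same_residue_alternative[i], evtab$insilico[i],
                  evtab$phenotype_match[i], evtab$novel[i])
}

#' Classify the pathogenicity of an annotated variant
#'
#' A first-match-wins rule cascade, ordered by evidence strength and aligned
#' with ACMG practice:
#' (a) common polymorphism -> benign;
#' (b) truncating consequence in a gene with an established loss-of-function
#'     mechanism -> clearly_pathogenic when previously reported,
#'     likely_pathogenic when novel;
#' (c) functional support -> clearly_pathogenic;
#' (d) prior segregation report -> likely_pathogenic;
#' (e) alternative substitution of the same residue + concordant damaging
#'     in-silico + phenotype match -> likely_pathogenic;
#' (f) novel missense with concordant damaging in-silico + phenotype match
#'     -> vus;
#' (g) otherwise vus, or likely_benign when in-silico tools concordantly
#'     predict benign.
#'
#' @param cons consequence list from [annotate_variant()]
#' @param gene an `ird_gene`
#' @param freq frequency record for the variant
#' @param ev an `ird_evidence` bundle
#' @return one of benign / likely_benign / vus / likely_pathogenic /
#'   clearly_pathogenic
#' @export
classify_variant <- function(cons, gene, freq, ev) {
  if (is.null(cons$term) || is.na(cons$term)) stop("missing consequence term")
  if (is_common_polymorphism(freq)) return("benign")
  if (isTRUE(cons$truncating) && isTRUE(gene$lof_mechanism)) {
    return(if (ev$novel) "likely_pathogenic" else "clearly_pathogenic")
  }
  if (ev$functional_support) return("clearly_pathogenic")
  if (ev$prior_segregation_report) return("likely_pathogenic")
  if (ev$same_residue_alternative && ev$insilico == "concordant_damaging" &&
      ev$phenotype_match) {
    return("likely_pathogenic")
  }
  if (ev$novel && cons$term == "missense" &&
      ev$insilico == "concordant_damaging" && ev$phenotype_match) {
    return("vus")
  }
  if (ev$insilico == "concordant_benign") "likely_benign" else "vus"
}

#' Rank of a pathogenicity class
#'
#' @param class pathogenicity class label(s)
#' @return integer rank, benign = 1 ... clearly_pathogenic = 5
#' @export
pathogenicity_rank <- function(class) {
  match(class, PATHOGENICITY_LEVELS)
}
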