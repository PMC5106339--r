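set.seed(505)

lof_gene <- local({
  tg <- toy_gene("CLS1", lof = TRUE)
  tg$gene
})
no_lof_gene <- local({
  tg <- toy_gene("CLS2", lof = FALSE)
  tg$gene
})

freq_absent <- list(dbsnp_af = NA, evs_af = NA, evs_mean_depth = NA,
                    evs_cohort_ok = FALSE, exac_af = NA, inhouse_count = 0L)
freq_common <- list(dbsnp_af = 0.05, evs_af = 0.05, evs_mean_depth = 40,
                    evs_cohort_ok = TRUE, exac_af = 0.05, inhouse_count = 0L)
cons <- function(term, truncating = term %in% c("stop_gained", "frameshift",
                                                "start_lost")) {
  list(term = term, truncating = truncating, protein_change = NA)
}

test_that("the rule cascade reproduces the documented class assignments", {
  # novel truncating variant in a LoF-mechanism gene
  expect_equal(classify_variant(cons("stop_gained"), lof_gene, freq_absent,
                                evidence_bundle(novel = TRUE)),
               "likely_pathogenic")
  # previously reported truncating variant
  expect_equal(classify_variant(cons("frameshift"), lof_gene, freq_absent,
                                evidence_bundle(novel = FALSE)),
               "clearly_pathogenic")
  # missense with published functional support
  expect_equal(classify_variant(cons("missense"), lof_gene, freq_absent,
                                evidence_bundle(functional_support = TRUE,
                                                novel = FALSE)),
               "clearly_pathogenic")
  # segregation evidence without functional support
  expect_equal(classify_variant(cons("missense"), lof_gene, freq_absent,
                                evidence_bundle(prior_segregation_report = TRUE,
                                                novel = FALSE)),
               "likely_pathogenic")
  # alternative substitution of the same residue + damaging + phenotype fit
  expect_equal(classify_variant(cons("missense"), lof_gene, freq_absent,
                                evidence_bundle(same_residue_alternative = TRUE,
                                                insilico = "concordant_damaging",
                                                phenotype_match = TRUE,
                                                novel = TRUE)),
               "likely_pathogenic")
  # common variants are benign regardless of other evidence
  expect_equal(classify_variant(cons("stop_gained"), lof_gene, freq_common,
                                evidence_bundle(functional_support = TRUE)),
               "benign")
  # novel damaging-predicted phenotype-matched missense stays a VUS
  expect_equal(classify_variant(cons("missense"), lof_gene, freq_absent,
                                evidence_bundle(insilico = "concordant_damaging",
                                                phenotype_match = TRUE,
                                                novel = TRUE)),
               "vus")
  # conflicting in-silico, no positive evidence path
  expect_equal(classify_variant(cons("missense"), lof_gene, freq_absent,
                                evidence_bundle(insilico = "conflicting",
                                                novel = TRUE)),
               "vus")
  # concordant benign predictions demote to likely benign
  expect_equal(classify_variant(cons("synonymous"), lof_gene, freq_absent,
                                evidence_bundle(insilico = "concordant_benign",
                                                novel = TRUE)),
               "likely_benign")
  # truncating term without an established LoF mechanism needs evidence
  expect_equal(classify_variant(cons("stop_gained"), no_lof_gene, freq_absent,
                                evidence_bundle(novel = TRUE)),
               "vus")
  expect_error(classify_variant(list(term = NA), lof_gene, freq_absent,
                                evidence_bundle()), "consequence")
})

test_that("synonymous and splice-region variants reach pathogenic classes only via evidence", {
  for (term in c("synonymous", "splice_region")) {
    expect_equal(classify_variant(cons(term), lof_gene, freq_absent,
                                  evidence_bundle(novel = TRUE)), "vus")
    expect_equal(classify_variant(cons(term), lof_gene, freq_absent,
                                  evidence_bundle(functional_support = TRUE,
                                                  novel = FALSE)),
                 "clearly_pathogenic")
    expect_equal(classify_variant(cons(term), lof_gene, freq_absent,
                                  evidence_bundle(prior_segregation_report = TRUE,
                                                  novel = FALSE)),
                 "likely_pathogenic")
  }
})

test_that("adding positive evidence never demotes the class and classification is pure", {
  terms <- c("missense", "synonymous", "splice_region", "stop_gained",
             "canonical_splice")
  flags <- expand.grid(fs = c(FALSE, TRUE), seg = c(FALSE, TRUE),
                       sr = c(FALSE, TRUE), pm = c(FALSE, TRUE),
                       ins = c("concordant_benign", "conflicting",
                               "unavailable", "concordant_damaging"),
                       stringsAsFactors = FALSE)
  insilico_rank <- c(concordant_benign = 1, conflicting = 2, unavailable = 2,
                     concordant_damaging = 3)
  for (term in terms) {
    for (g in list(lof_gene, no_lof_gene)) {
      cls <- apply(flags, 1L, function(r) {
        ev <- evidence_bundle(as.logical(r[["fs"]]), as.logical(r[["seg"]]),
                              as.logical(r[["sr"]]), r[["ins"]],
                              as.logical(r[["pm"]]), novel = TRUE)
        classify_variant(cons(term), g, freq_absent, ev)
      })
      # purity: recomputation gives identical classes
      cls2 <- apply(flags, 1L, function(r) {
        ev <- evidence_bundle(as.logical(r[["fs"]]), as.logical(r[["seg"]]),
                              as.logical(r[["sr"]]), r[["ins"]],
                              as.logical(r[["pm"]]), novel = TRUE)
        classify_variant(cons(term), g, freq_absent, ev)
      })
      expect_identical(cls, cls2)
      # monotonicity along the evidence partial order
      rk <- pathogenicity_rank(cls)
      fl <- as.matrix(flags[, 1:4]) * 1L
      ir <- insilico_rank[flags$ins]
      violations <- 0L
      for (i in seq_len(nrow(flags))) {
        dominates <- rowSums(fl >= rep(fl[i, ], each = nrow(fl))) == 4L &
          ir >= ir[i]
        violations <- violations + sum(dominates & rk < rk[i])
      }
      expect_identical(violations, 0L)
    }
  }
})
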