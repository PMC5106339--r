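set.seed(808)

random_cohort <- function(n_pat = 12L, n_var = 300L) {
  pats <- sprintf("P%02d", seq_len(n_pat))
  patients <- data.frame(patient_id = pats,
                         sex = sample(c("M", "F"), n_pat, TRUE),
                         referral_category = sample(referral_classes(),
                                                    n_pat, TRUE),
                         platform = sample(c("SOLiD", "HiSeq"), n_pat, TRUE),
                         stringsAsFactors = FALSE)
  analysed <- runif(n_var) < 0.4
  reported <- analysed & runif(n_var) < 0.2
  vclass <- sample(c("SNV", "indel"), n_var, TRUE, prob = c(0.9, 0.1))
  term <- ifelse(vclass == "SNV",
                 sample(c("missense", "synonymous", "stop_gained"), n_var, TRUE),
                 sample(c("frameshift", "inframe_deletion", "splice_region"),
                        n_var, TRUE))
  variants <- data.frame(
    patient_id = sample(pats, n_var, TRUE),
    key = sprintf("k%03d", sample.int(200L, n_var, TRUE)),
    vclass = vclass, subtype = vclass,
    zyg_analysed = sample(c("hom", "het", "hemi", "het_het"), n_var, TRUE,
                          prob = c(0.2, 0.7, 0.05, 0.05)),
    analysed = analysed, reported = reported,
    novel_db = runif(n_var) < 0.3, novel_cause = runif(n_var) < 0.1,
    term = ifelse(analysed, term, NA),
    gene = sample(c("G1", "G2", "G3"), n_var, TRUE),
    stringsAsFactors = FALSE)
  variants$zyg_reported <- ifelse(reported, variants$zyg_analysed, NA)
  variants$truncating <- !is.na(variants$term) &
    variants$term %in% c("stop_gained", "frameshift")
  variants$coding <- !is.na(variants$term) & variants$term != "splice_region"
  n_dx <- n_pat %/% 2L
  diagnoses <- data.frame(
    patient_id = pats,
    status = c(sample(c("confirmed", "provisional"), n_dx, TRUE),
               rep("none", n_pat - n_dx)),
    mode = c(sample(c("AR", "AD", "XL"), n_dx, TRUE),
             rep(NA_character_, n_pat - n_dx)),
    gene = c(sample(c("G1", "G2", "G3"), n_dx, TRUE),
             rep(NA_character_, n_pat - n_dx)),
    comphet = FALSE,
    referral_category = patients$referral_category,
    concordant = TRUE, stringsAsFactors = FALSE)
  carriers <- data.frame(patient_id = sample(pats, 3L), gene = "G1",
                         key = sprintf("c%d", 1:3), stringsAsFactors = FALSE)
  panel_years <- data.frame(symbol = c("G1", "G2", "G3"),
                            year = c(1993L, 1999L, 2007L),
                            stringsAsFactors = FALSE)
  cohort_results(patients, variants, diagnoses, carriers, panel_years)
}

test_that("printed-precision rounding is half-up, not banker's", {
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(1.5), 2)
  expect_equal(round_half_up(2.5), 3)   # round() would give 2
  expect_equal(round_half_up(8.45, 1), 8.5)
  expect_equal(round_half_up(-1.5), -2)
  expect_equal(round_half_up(77.69, 0), 78)
})

test_that("per-patient means reproduce the printed cohort averages", {
  expect_equal(mean_per_patient(4358L, 537L, 1L), 8.1)
  expect_equal(mean_per_patient(4172L, 537L, 1L), 7.8)
  expect_equal(mean_per_patient(0L, 537L, 1L), 0.0)
  expect_error(mean_per_patient(10L, 0L), "positive")
})

test_that("cohort tabulation matches a nested-loop recount on random cohorts", {
  ch <- random_cohort()
  tab <- tabulate_cohort(ch)
  v <- ch$variants
  for (stage in c("raw", "analysed", "reported")) {
    sel <- switch(stage, raw = rep(TRUE, nrow(v)), analysed = v$analysed,
                  reported = v$reported)
    zyg <- if (stage == "reported") v$zyg_reported else v$zyg_analysed
    for (cl in c("SNV", "indel")) {
      for (z in c("hom", "het", "hemi", "het_het")) {
        cnt <- 0L
        for (i in seq_len(nrow(v))) {
          if (sel[i] && v$vclass[i] == cl && !is.na(zyg[i]) && zyg[i] == z) {
            cnt <- cnt + 1L
          }
        }
        expect_equal(unname(tab$counts[stage, cl, z]), cnt)
      }
    }
    # zygosity cells always sum to the class totals
    expect_equal(rowSums(tab$counts[stage, , ]), tab$totals[stage, ])
  }
  # stage containment as variant-key multisets
  expect_true(all(v$key[v$reported] %in% v$key[v$analysed]))
})

test_that("an empty cohort tabulates to all zeros", {
  ch <- random_cohort()
  empty <- cohort_results(ch$patients, ch$variants[0, ],
                          ch$diagnoses[ch$diagnoses$status == "none", ],
                          ch$carriers[0, ], ch$panel_years)
  tab <- tabulate_cohort(empty)
  expect_true(all(tab$counts == 0))
  expect_equal(yield_stats(empty)$n_diagnosed, 0L)
  expect_equal(yield_stats(empty)$yield_pct, 0)
})

test_that("yield and mode counts recover a configured truth table", {
  ch <- random_cohort()
  ys <- yield_stats(ch)
  d <- ch$diagnoses[ch$diagnoses$status != "none", ]
  expect_equal(ys$n_diagnosed, nrow(d))
  expect_equal(unname(ys$by_mode["AR"]), sum(d$mode == "AR"))
  expect_equal(ys$yield_pct, round_half_up(100 * nrow(d) / nrow(ch$patients)))
})

test_that("discovery-year rates follow the era bins and fail on missing years", {
  ch <- random_cohort()
  dy <- discovery_year_rates(ch)
  d <- ch$diagnoses[ch$diagnoses$status != "none", ]
  yr <- ch$panel_years$year[match(d$gene, ch$panel_years$symbol)]
  expect_equal(dy$n_diagnoses,
               c(sum(yr < 1995), sum(yr >= 1995 & yr <= 2004), sum(yr > 2004)))
  expect_equal(sum(dy$n_diagnoses), nrow(d))
  expect_equal(dy$diagnoses_per_gene,
               round_half_up(dy$n_diagnoses / dy$n_genes, 1))
  # one gene, one diagnosis
  one <- cohort_results(ch$patients[1, ],
                        ch$variants[0, ],
                        data.frame(patient_id = ch$patients$patient_id[1],
                                   status = "confirmed", mode = "AR",
                                   gene = "G1", comphet = FALSE,
                                   referral_category = "RCD/RP",
                                   concordant = TRUE),
                        ch$carriers[0, ],
                        data.frame(symbol = "G1", year = 1990L))
  expect_equal(discovery_year_rates(one)$diagnoses_per_gene, c(1.0, NaN, NaN))
  bad <- ch
  bad$panel_years <- bad$panel_years[-1L, ]
  expect_error(discovery_year_rates(bad), "missing a discovery year")
})

test_that("gene spectrum partitions genes by distinct referral categories with a recount oracle", {
  ch <- random_cohort()
  gs <- gene_spectrum(ch)
  d <- ch$diagnoses[ch$diagnoses$status != "none", ]
  for (g in unique(d$gene)) {
    expected <- length(unique(d$referral_category[d$gene == g]))
    expect_equal(gs$per_gene$n_categories[gs$per_gene$gene == g], expected)
    expect_equal(gs$per_gene$n_patients[gs$per_gene$gene == g],
                 sum(d$gene == g))
  }
  expect_equal(gs$n_single_category + gs$n_multi_category,
               length(unique(d$gene)))
  # all diagnoses in one gene and category
  single <- ch
  single$diagnoses$gene[single$diagnoses$status != "none"] <- "G2"
  single$diagnoses$referral_category[single$diagnoses$status != "none"] <- "CD"
  gs1 <- gene_spectrum(single)
  expect_equal(gs1$n_single_category, 1L)
  expect_equal(gs1$n_multi_category, 0L)
})

test_that("cohort JSON serialisation writes the summary surfaces", {
  ch <- random_cohort()
  path <- withr::local_tempfile(fileext = ".json")
  write_cohort_json(ch, path)
  out <- jsonlite::read_json(path)
  expect_equal(out$n_patients, nrow(ch$patients))
  expect_named(out$counts, c("raw", "analysed", "reported"))
  expect_equal(out$yield$n_diagnosed, yield_stats(ch)$n_diagnosed)
})
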