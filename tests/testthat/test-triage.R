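set.seed(303)

qc <- default_qc_profiles()

test_that("platform QC applies the documented depth, quality and indel-support bounds", {
  snv <- function(depth, mqv) list(vclass = "SNV", depth = depth, mqv = mqv,
                                   alt_reads = NA_integer_)
  indel <- function(alt, depth) list(vclass = "deletion", depth = depth,
                                     mqv = 60, alt_reads = alt)
  # SOLiD SNVs: depth >= 18, MQV strictly > 18
  expect_true(apply_qc(snv(18L, 19), qc$SOLiD)$pass)
  expect_false(apply_qc(snv(18L, 18), qc$SOLiD)$pass)
  expect_false(apply_qc(snv(17L, 40), qc$SOLiD)$pass)
  # SOLiD indels: strictly more than 5 supporting reads
  expect_true(apply_qc(indel(6L, 30L), qc$SOLiD)$pass)
  expect_false(apply_qc(indel(5L, 30L), qc$SOLiD)$pass)
  # HiSeq SNVs: depth >= 50, MQV >= 45 (non-strict)
  expect_true(apply_qc(snv(50L, 45), qc$HiSeq)$pass)
  expect_false(apply_qc(snv(49L, 60), qc$HiSeq)$pass)
  expect_false(apply_qc(snv(60L, 44.9), qc$HiSeq)$pass)
  # HiSeq indels: strictly more than 25% supporting reads
  expect_true(apply_qc(indel(13L, 50L), qc$HiSeq)$pass)   # 26%
  expect_false(apply_qc(indel(12L, 50L), qc$HiSeq)$pass)  # 24%
  # missing metrics fail with an explicit reason
  r <- apply_qc(list(vclass = "SNV", depth = NA_integer_, mqv = 50,
                     alt_reads = NA_integer_), qc$HiSeq)
  expect_false(r$pass)
  expect_match(r$reason, "missing_metric")
  expect_error(platform_qc("X", 10, 10, TRUE), "exactly one indel rule")
})

test_that("common-polymorphism calls require >1% frequency with adequate EVS support", {
  fr <- function(db = NA, evs = NA, depth = NA, ok = FALSE) {
    list(dbsnp_af = db, evs_af = evs, evs_mean_depth = depth,
         evs_cohort_ok = ok, exac_af = NA, inhouse_count = 0L)
  }
  expect_true(is_common_polymorphism(fr(evs = 0.02, depth = 20, ok = TRUE)))
  expect_false(is_common_polymorphism(fr(evs = 0.005, depth = 20, ok = TRUE)))
  expect_false(is_common_polymorphism(fr(evs = 0.02, depth = 10, ok = TRUE)))
  expect_false(is_common_polymorphism(fr(evs = 0.02, depth = 20, ok = FALSE)))
  expect_true(is_common_polymorphism(fr(db = 0.05)))
  expect_false(is_common_polymorphism(fr(db = 0.01)))  # strictly above 1%
  expect_false(is_common_polymorphism(fr()))
})

test_that("in-house recurrence flags rare variants recurring above the threshold", {
  fr <- function(n) list(inhouse_count = n)
  expect_true(recurrence_flag(fr(200L), 537L, 0.10))
  expect_false(recurrence_flag(fr(1L), 537L, 0.10))
  expect_false(recurrence_flag(fr(10L), 100L, 0.10))  # exactly at threshold
  expect_error(recurrence_flag(fr(1L), 0L), "positive")
})

test_that("triage partitions calls with ordered drop reasons and a stepwise oracle agrees", {
  tg <- toy_gene("TRI1", n_codons = 60L)
  pan <- toy_panel(tg)
  pos <- cds_positions(tg)
  refs <- strsplit(tg$contig, "")[[1L]]
  pick_alt <- function(p) sample(setdiff(BASES, refs[p + 1L]), 1L)
  # 8 clean calls + 3 off-region + 2 QC-fail + 2 common + 1 recurrent
  p_clean <- pos[10:17]
  p_qc <- pos[20:21]
  p_common <- pos[24:25]
  p_rec <- pos[28]
  p_off <- c(10L, 20L, 30L)  # far upstream of the exons
  mk <- function(p, depth, mqv) {
    make_calls(tg$tx$chrom, p, refs[p + 1L], vapply(p, pick_alt, ""),
               depth = depth, mqv = mqv, alt_reads = as.integer(depth / 2))
  }
  calls <- rbind(mk(p_clean, 100L, 60), mk(p_off, 100L, 60),
                 mk(p_qc, 30L, 60), mk(p_common, 100L, 60), mk(p_rec, 100L, 60))
  case <- patient_case("P1", "F", "RCD/RP", "HiSeq", calls)
  key2 <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  freqs <- data.frame(
    chrom = calls$chrom, pos = calls$pos + 1L, ref = calls$ref,
    alt = calls$alt,
    dbsnp_af = ifelse(key2 %in% key2[14:15], 0.2, NA),
    evs_af = NA_real_, evs_mean_depth = NA_real_, evs_cohort_ok = FALSE,
    exac_af = NA_real_,
    inhouse_count = ifelse(key2 %in% key2[16], 80L, 0L),
    stringsAsFactors = FALSE)
  freqs$key <- key2
  attr(freqs, "inhouse_cohort_size") <- 200L
  tri <- triage_patient(case, pan, freqs)
  expect_equal(nrow(tri$retained), 8L)
  expect_equal(nrow(tri$retained) + nrow(tri$dropped), nrow(calls))
  reasons <- table(tri$dropped$reason)
  expect_equal(as.integer(reasons[c("off_region", "qc_fail",
                                    "common_polymorphism",
                                    "recurrent_artefact")]),
               c(3L, 2L, 2L, 1L))
  # independent re-application of each predicate
  regions <- panel_clinical_regions(pan)
  in_reg <- in_intervals(calls$chrom, calls$pos, regions)
  qc_ok <- vapply(seq_len(nrow(calls)), function(i) {
    apply_qc(calls[i, ], qc$HiSeq)$pass
  }, logical(1L))
  common <- vapply(key2, function(k)
    is_common_polymorphism(frequency_record(freqs, k)), logical(1L))
  recurrent <- vapply(key2, function(k)
    recurrence_flag(frequency_record(freqs, k), 200L, 0.10), logical(1L))
  oracle_keep <- in_reg & qc_ok & !common & !recurrent
  expect_setequal(variant_key(tri$retained$chrom, tri$retained$pos,
                              tri$retained$ref, tri$retained$alt),
                  key2[oracle_keep])

  # empty input gives an empty result
  tri0 <- triage_patient(patient_case("P0", "F", "CD", "HiSeq"), pan, freqs)
  expect_equal(nrow(tri0$retained) + nrow(tri0$dropped), 0L)
})

test_that("raising quality never drops a retained call and raising AF never rescues one", {
  tg <- toy_gene("TRI2", n_codons = 30L)
  pan <- toy_panel(tg)
  refs <- strsplit(tg$contig, "")[[1L]]
  p <- cds_positions(tg)[5]
  base <- make_calls(tg$tx$chrom, p, refs[p + 1L],
                     setdiff(BASES, refs[p + 1L])[1L],
                     depth = 50L, mqv = 45, alt_reads = 25L)
  case <- patient_case("P1", "F", "CD", "HiSeq", base)
  tri_pass <- triage_patient(case, pan, empty_freq_table())
  expect_equal(nrow(tri_pass$retained), 1L)
  for (k in 1:20) {
    better <- base
    better$depth <- base$depth + sample(0:100, 1L)
    better$mqv <- base$mqv + sample(0:40, 1L)
    tri <- triage_patient(patient_case("P1", "F", "CD", "HiSeq", better),
                          pan, empty_freq_table())
    expect_equal(nrow(tri$retained), 1L)
  }
  # increasing population AF can only move a call from retained to dropped
  for (af in c(0.001, 0.009, 0.02, 0.2, 0.6)) {
    freqs <- data.frame(chrom = base$chrom, pos = base$pos + 1L,
                        ref = base$ref, alt = base$alt, dbsnp_af = af,
                        evs_af = NA_real_, evs_mean_depth = NA_real_,
                        evs_cohort_ok = FALSE, exac_af = NA_real_,
                        inhouse_count = 0L, stringsAsFactors = FALSE)
    freqs$key <- variant_key(base$chrom, base$pos, base$ref, base$alt)
    tri <- triage_patient(case, pan, freqs)
    expect_equal(nrow(tri$retained), if (af > 0.01) 0L else 1L)
  }
})

test_that("retrospective frequency summaries match direct arithmetic", {
  exac <- data.frame(key = sprintf("k%d", 1:10),
                     af = c(0, 0, 0, 0, 0, 0, 0.01, 0.05, 0.3, 0.78))
  s <- retrospective_af_summary(sprintf("k%d", 1:10), exac)
  expect_equal(s$mean_af, sum(exac$af) / 10)
  expect_equal(s$median_af, 0)
  expect_equal(s$max_af, 0.78)
  expect_equal(s$frac_above, 3 / 10)
  # variants absent from the table count as frequency zero
  s0 <- retrospective_af_summary(c("absent1", "absent2"), exac)
  expect_equal(s0$mean_af, 0)
  expect_equal(s0$max_af, 0)
})
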