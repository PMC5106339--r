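# Deterministic worked-example cohort ------------------------------------
#
# paper_fixture() builds a synthetic 537-patient cohort whose stage tallies,
# per-patient means, novelty splits, indel breakdowns, diagnostic yield,
# inheritance-mode counts, gene spectrum and discovery-year statistics
# reproduce the published summary surfaces of the diagnostic service. The
# construction is purely arithmetic (no RNG): counts are laid out
# round-robin and validated with stopifnot along the way. Genes discussed in
# the source cohort keep their real symbols; filler genes carry synthetic
# IRDM/IRDP/IRDQ symbols and synthetic geometry.

fixture_gene_table <- function() {
  named <- data.frame(
    symbol = c("RHO", "CHM", "RPE65", "ABCA4", "USH2A", "CERKL", "PRPF31",
               "GUCY2D", "RPGR", "CRB1", "EYS", "CEP290"),
    year = c(1990L, 1990L, 1993L, 1997L, 1998L, 2004L, 2001L, 1996L, 1996L,
             1999L, 2008L, 2006L),
    modes = c("AD", "XL", "AR", "AR", "AR", "AR", "AD", "AR|AD", "XL", "AR",
              "AR", "AR"),
    cats = c("RCD/RP", "Other", "EORD/LCA|RCD/RP", "MD/STGD|CRD|RCD/RP|CD",
             "Usher|RCD/RP", "RCD/RP|CRD|CD|MD/STGD", "RCD/RP",
             "EORD/LCA|CD", "RCD/RP", "EORD/LCA|RCD/RP", "RCD/RP",
             "EORD/LCA|BBS/ciliopathy"),
    stringsAsFactors = FALSE)
  pre <- data.frame(symbol = sprintf("IRDP%02d", 1:4),
                    year = c(1990L, 1991L, 1992L, 1994L),
                    modes = "AR", cats = "RCD/RP", stringsAsFactors = FALSE)
  mid <- data.frame(symbol = sprintf("IRDM%02d", 1:58),
                    year = rep(1995:2004, length.out = 58L),
                    modes = c(rep("AD", 8L), rep("AR", 50L)),
                    cats = "RCD/RP|CRD", stringsAsFactors = FALSE)
  post <- data.frame(symbol = sprintf("IRDQ%02d", 1:31),
                     year = rep(2005:2015, length.out = 31L),
                     modes = "AR", cats = "RCD/RP|MD/STGD",
                     stringsAsFactors = FALSE)
  g <- rbind(named, pre, mid, post)
  stopifnot(nrow(g) == 105L,
            sum(g$year < 1995L) == 7L,
            sum(g$year >= 1995L & g$year <= 2004L) == 65L,
            sum(g$year > 2004L) == 33L)
  g
}

# one row per diagnosis: gene, mode, referral category
fixture_diagnosis_plan <- function() {
  plan <- function(gene, mode, cats) {
    data.frame(gene = gene, mode = mode, referral_category = cats,
               stringsAsFactors = FALSE)
  }
  p <- rbind(
    plan("ABCA4", "AR", c(rep("MD/STGD", 12L), rep("CRD", 5L),
                          rep("RCD/RP", 4L), "CD", "Usher")),
    plan("CERKL", "AR", c("CD", rep("CRD", 3L), rep("RCD/RP", 4L),
                          rep("MD/STGD", 3L))),
    plan("USH2A", "AR", c(rep("Usher", 14L), rep("RCD/RP", 6L))),
    plan("GUCY2D", "AR", rep("EORD/LCA", 3L)),
    plan("GUCY2D", "AD", "CD"),
    plan("CRB1", "AR", c(rep("EORD/LCA", 3L), rep("RCD/RP", 2L))),
    plan("RPE65", "AR", c(rep("EORD/LCA", 2L), rep("RCD/RP", 2L))),
    plan("RHO", "AD", rep("RCD/RP", 6L)),
    plan("CHM", "XL", rep("RCD/RP", 2L)),          # choroideremia referred as RP
    plan("PRPF31", "AD", rep("RCD/RP", 5L)),
    plan("RPGR", "XL", rep("RCD/RP", 11L)),
    plan("EYS", "AR", rep("RCD/RP", 7L)),
    plan("CEP290", "AR", c(rep("EORD/LCA", 3L), rep("BBS/ciliopathy", 2L))),
    plan("IRDP01", "AR", rep("RCD/RP", 3L)),
    plan("IRDP02", "AR", "RCD/RP"))
  # dominant filler genes: 38 diagnoses over 8 genes, first six spanning two
  # referral categories
  ad_counts <- c(5L, 5L, 5L, 5L, 5L, 5L, 4L, 4L)
  for (i in seq_along(ad_counts)) {
    cats <- if (i <= 6L) rep(c("RCD/RP", "CRD"), length.out = ad_counts[i])
            else rep("RCD/RP", ad_counts[i])
    p <- rbind(p, plan(sprintf("IRDM%02d", i), "AD", cats))
  }
  # recessive filler genes: 97 diagnoses over 32 genes (IRDM09..IRDM40),
  # first six spanning two categories
  ar_counts <- c(4L, rep(3L, 31L))
  for (i in seq_along(ar_counts)) {
    cats <- if (i <= 6L) rep(c("RCD/RP", "CRD"), length.out = ar_counts[i])
            else rep("RCD/RP", ar_counts[i])
    p <- rbind(p, plan(sprintf("IRDM%02d", i + 8L), "AR", cats))
  }
  # post-2005 filler genes: 29 diagnoses over 8 genes, two multi-category
  q_counts <- c(5L, 5L, 4L, 4L, 3L, 3L, 3L, 2L)
  for (i in seq_along(q_counts)) {
    cats <- if (i <= 2L) rep(c("RCD/RP", "MD/STGD"), length.out = q_counts[i])
            else rep("RCD/RP", q_counts[i])
    p <- rbind(p, plan(sprintf("IRDQ%02d", i), "AR", cats))
  }
  stopifnot(nrow(p) == 271L,
            sum(p$mode == "AR") == 208L, sum(p$mode == "AD") == 50L,
            sum(p$mode == "XL") == 13L,
            length(unique(p$gene)) == 62L)
  p
}

# mark 120 of the 208 recessive diagnoses as compound heterozygous
fixture_assign_comphet <- function(p) {
  forced <- c(CEP290 = 5L, CERKL = 11L, ABCA4 = 15L, USH2A = 12L, EYS = 4L,
              CRB1 = 4L, GUCY2D = 2L, RPE65 = 2L)
  p$comphet <- FALSE
  for (g in names(forced)) {
    idx <- which(p$gene == g & p$mode == "AR")[seq_len(forced[[g]])]
    p$comphet[idx] <- TRUE
  }
  need <- 120L - sum(p$comphet)
  filler <- which(p$mode == "AR" & !p$comphet &
                    grepl("^IRD", p$gene))[seq_len(need)]
  p$comphet[filler] <- TRUE
  stopifnot(sum(p$comphet) == 120L,
            sum(p$mode == "AR" & !p$comphet) == 88L)
  p
}

# causal-allele slots: one per reported occurrence (402 in total)
fixture_slots <- function(diag) {
  rows <- list()
  for (i in seq_len(nrow(diag))) {
    z <- if (diag$mode[i] == "XL") "hemi"
         else if (diag$mode[i] == "AD") "het"
         else if (diag$comphet[i]) c("het", "het")
         else "hom"
    rows[[i]] <- data.frame(patient_id = diag$patient_id[i],
                            gene = diag$gene[i], zyg = z,
                            stringsAsFactors = FALSE)
  }
  slots <- do.call(rbind, rows)
  # eleven additional causal occurrences beyond one-per-allele bookkeeping:
  # one further homozygous finding and ten further heterozygous findings in
  # already-diagnosed patients
  hom_extra <- diag[diag$mode == "AR" & !diag$comphet, ][1L, ]
  ad_extra <- diag[diag$mode == "AD", ][1:10, ]
  slots <- rbind(slots,
                 data.frame(patient_id = hom_extra$patient_id,
                            gene = hom_extra$gene, zyg = "hom",
                            stringsAsFactors = FALSE),
                 data.frame(patient_id = ad_extra$patient_id,
                            gene = ad_extra$gene, zyg = "het",
                            stringsAsFactors = FALSE))
  stopifnot(nrow(slots) == 402L, sum(slots$zyg == "hom") == 89L,
            sum(slots$zyg == "het") == 300L, sum(slots$zyg == "hemi") == 13L)
  slots$uid <- NA_integer_
  slots
}

# take n free slots of a gene/zygosity, at most one per patient when a
# multi-patient variant is being placed
take_slots <- function(slots, gene, zyg, n, distinct = FALSE) {
  free <- which(is.na(slots$uid) & slots$gene == gene & slots$zyg == zyg)
  if (distinct) free <- free[!duplicated(slots$patient_id[free])]
  if (length(free) < n) {
    stop("fixture slot shortage: ", gene, " ", zyg, " need ", n,
         " have ", length(free))
  }
  free[seq_len(n)]
}

#' Deterministic worked-example cohort
#'
#' Builds a synthetic 537-patient cohort whose triage, classification and
#' diagnosis outputs tally exactly to the published summary counts of the
#' diagnostic service (stage totals, zygosity cells, per-patient means,
#' novelty splits, indel breakdowns, yield and inheritance-mode counts,
#' gene spectrum and gene-discovery-year statistics). The cohort is built
#' arithmetically and is identical on every call.
#'
#' @return an `ird_cohort`; the retrospective ExAC-style allele-frequency
#'   table is attached as attribute `exac`
#' @export
paper_fixture <- function() {
  genes <- fixture_gene_table()
  diag <- fixture_diagnosis_plan()
  diag <- fixture_assign_comphet(diag)
  diag$patient_id <- sprintf("P%04d", seq_len(nrow(diag)))
  diag$status <- "confirmed"
  # an (unconstrained) share of compound-heterozygous filler diagnoses rests
  # on a pathogenic + VUS pair and is reported provisional
  prov <- which(diag$comphet & grepl("^IRD", diag$gene))[1:30]
  diag$status[prov] <- "provisional"
  gene_cats <- strsplit(genes$cats, "|", fixed = TRUE)
  names(gene_cats) <- genes$symbol
  diag$concordant <- mapply(function(g, r) r %in% gene_cats[[g]],
                            diag$gene, diag$referral_category)

  slots <- fixture_slots(diag)

  # ---- unique reported variants ----------------------------------------
  uid <- 0L
  uniq <- list()
  add_unique <- function(vclass, term, novel_db, novel_cause, mult,
                         evidence = NA_character_, af = 0) {
    uid <<- uid + 1L
    uniq[[uid]] <<- data.frame(uid = uid, vclass = vclass, term = term,
                               novel_db = novel_db, novel_cause = novel_cause,
                               mult = mult, evidence = evidence, af = af,
                               stringsAsFactors = FALSE)
    uid
  }

  # indel multi-patient variants: six recurrent frameshifts, all novel
  indel_multi <- data.frame(gene = c("ABCA4", "USH2A", "EYS", "CRB1",
                                     "GUCY2D", "RPE65"),
                            mult = c(8L, 8L, 4L, 4L, 2L, 2L),
                            stringsAsFactors = FALSE)
  for (i in seq_len(nrow(indel_multi))) {
    u <- add_unique("indel", "frameshift", TRUE, TRUE, indel_multi$mult[i])
    slots$uid[take_slots(slots, indel_multi$gene[i], "het",
                         indel_multi$mult[i], distinct = TRUE)] <- u
  }

  # SNV multi-patient variants: a missense reported in 11 individuals
  # (CERKL), plus recurrent missense/nonsense variants
  u <- add_unique("SNV", "missense", FALSE, FALSE, 11L)
  slots$uid[take_slots(slots, "CERKL", "het", 11L, distinct = TRUE)] <- u
  snv_multi <- rbind(
    data.frame(gene = c("ABCA4", "USH2A", "RHO", "PRPF31", "IRDM01", "IRDM02"),
               mult = 5L, term = "missense"),
    data.frame(gene = c("ABCA4", "USH2A", "EYS", "IRDM03", "IRDM04"),
               mult = 4L, term = "missense"),
    data.frame(gene = c("ABCA4", "USH2A", "CERKL", "GUCY2D", "RPE65",
                        "IRDM05", "IRDM06", "IRDM09"),
               mult = 2L, term = "missense"),
    data.frame(gene = c("ABCA4", "USH2A", "CERKL", "CRB1", "IRDM10",
                        "IRDM11", "IRDM12", "IRDM13", "IRDM14", "IRDM15",
                        "IRDM16", "IRDM17"),
               mult = 2L, term = "stop_gained"))
  for (i in seq_len(nrow(snv_multi))) {
    u <- add_unique("SNV", snv_multi$term[i], FALSE, FALSE, snv_multi$mult[i])
    slots$uid[take_slots(slots, snv_multi$gene[i], "het", snv_multi$mult[i],
                         distinct = TRUE)] <- u
  }

  # single-occurrence indels: 28 homozygous frameshifts, 3 homozygous
  # inframe deletions, 4 hemizygous inframe deletions (XL genes), 20
  # heterozygous frameshifts
  hom_free_genes <- function(n) {
    free <- which(is.na(slots$uid) & slots$zyg == "hom")
    free[seq_len(n)]
  }
  idx <- hom_free_genes(31L)
  for (k in seq_along(idx)) {
    term <- if (k <= 28L) "frameshift" else "inframe_deletion"
    slots$uid[idx[k]] <- add_unique("indel", term, FALSE, FALSE, 1L)
  }
  for (g in c("CHM", "CHM", "RPGR", "RPGR")) {
    free <- which(is.na(slots$uid) & slots$gene == g & slots$zyg == "hemi")[1L]
    slots$uid[free] <- add_unique("indel", "inframe_deletion", FALSE, FALSE, 1L)
  }
  free_het <- which(is.na(slots$uid) & slots$zyg == "het")
  for (k in seq_len(20L)) {
    slots$uid[free_het[k]] <- add_unique("indel", "frameshift", FALSE, FALSE, 1L)
  }

  # the deep-intronic CEP290 variant underpins one reported occurrence
  free <- which(is.na(slots$uid) & slots$gene == "CEP290" & slots$zyg == "het")[1L]
  slots$uid[free] <- add_unique("SNV", "intronic_special", FALSE, TRUE, 1L)

  # remaining single-occurrence SNVs fill every leftover slot
  singles <- c(rep("missense", 117L), rep("stop_gained", 64L),
               rep("canonical_splice", 20L), "start_lost",
               rep("synonymous", 6L), rep("splice_region", 9L))
  free <- which(is.na(slots$uid))
  stopifnot(length(free) == length(singles))
  for (k in seq_along(free)) {
    slots$uid[free[k]] <- add_unique("SNV", singles[k], FALSE, FALSE, 1L)
  }
  uniq <- do.call(rbind, uniq)
  stopifnot(nrow(uniq) == 311L, sum(uniq$mult) == 402L,
            sum(uniq$mult > 1L) == 38L)

  # novelty (dbSNP/EVS absence) at the unique-variant level
  set_flag <- function(u, col, sel, n, value = TRUE) {
    idx <- which(sel)[seq_len(n)]
    u[[col]][idx] <- value
    u
  }
  uniq <- set_flag(uniq, "novel_db",
                   uniq$vclass == "SNV" & uniq$term == "missense" &
                     uniq$mult == 1L, 97L)
  uniq <- set_flag(uniq, "novel_db",
                   uniq$vclass == "SNV" & uniq$term == "stop_gained" &
                     uniq$mult == 1L, 42L)
  uniq <- set_flag(uniq, "novel_db",
                   uniq$vclass == "indel" & uniq$term == "frameshift" &
                     uniq$mult == 1L & !uniq$novel_db, 28L)
  stopifnot(sum(uniq$novel_db[uniq$vclass == "indel"]) == 34L)

  # novel-cause-of-disease flags (144 in total)
  nc <- list(missense = 52L, stop_gained = 35L, canonical_splice = 12L,
             synonymous = 4L, splice_region = 5L, start_lost = 1L,
             frameshift = 31L, inframe_deletion = 3L)
  for (term in names(nc)) {
    uniq <- set_flag(uniq, "novel_cause", uniq$term == term &
                       (term != "missense" | uniq$novel_db), nc[[term]])
  }
  stopifnot(sum(uniq$novel_cause) == 144L)

  # curated evidence category of the reported missense variants
  mis <- which(uniq$term == "missense")
  ev <- character(length(mis))
  ev[uniq$novel_cause[mis]] <- "novel"
  rest <- which(!nzchar(ev))
  ev[rest] <- rep(c(rep("functional", 30L), rep("segregation", 49L),
                    rep("same_residue", 6L)), length.out = length(rest))
  uniq$evidence[mis] <- ev

  # retrospective ExAC-style frequencies of reported variants: mean 0.02,
  # median 0, maximum 0.78 over the 311 unique variants
  nz <- which(uniq$vclass == "SNV" & !uniq$novel_db & uniq$mult == 1L &
                uniq$term %in% c("missense", "stop_gained"))
  stopifnot(length(nz) >= 35L)
  uniq$af[nz[1L]] <- 0.78
  uniq$af[nz[2:35]] <- 0.16
  stopifnot(abs(sum(uniq$af) / 311 - 0.02) < 1e-12)

  # ---- reported occurrence rows ----------------------------------------
  rep_rows <- data.frame(
    patient_id = slots$patient_id, gene = slots$gene,
    uid = slots$uid, zyg_reported = slots$zyg, stringsAsFactors = FALSE)
  rep_rows <- cbind(rep_rows,
                    uniq[match(rep_rows$uid, uniq$uid),
                         c("vclass", "term", "novel_db", "novel_cause", "af")])
  rep_rows$key <- sprintf("RPT%04d", rep_rows$uid)
  rep_rows$zyg_analysed <- rep_rows$zyg_reported
  # capillary confirmation revised six pileup-estimated heterozygotes to
  # homozygous: four frameshifts and two inframe deletions
  conv_fs <- which(rep_rows$term == "frameshift" &
                     rep_rows$zyg_reported == "hom")[1:4]
  conv_if <- which(rep_rows$term == "inframe_deletion" &
                     rep_rows$zyg_reported == "hom")[1:2]
  rep_rows$zyg_analysed[c(conv_fs, conv_if)] <- "het"
  rep_rows$analysed <- TRUE
  rep_rows$reported <- TRUE

  # ---- clinically analysed but unreported rows -------------------------
  # SNVs: 2016 additional unique variants over 4039 occurrences
  an_snv_u <- data.frame(
    uid = 311L + seq_len(2016L),
    mult = c(rep(1L, 1474L), rep(2L, 117L), rep(5L, 219L), rep(6L, 206L)),
    novel_db = FALSE, af = 0, term = NA_character_,
    stringsAsFactors = FALSE)
  # novel variants are all single-occurrence
  an_snv_u$novel_db[1:1172] <- TRUE
  an_snv_u$term[1:1172] <- c(rep("missense", 714L), rep("stop_gained", 28L),
                             rep("synonymous", 350L), rep("start_lost", 2L),
                             rep("canonical_splice", 32L),
                             rep("splice_region", 46L))
  # frequencies above 1% in the retrospective database: 248 singletons and
  # 117 two-patient variants
  a_single <- 1172L + seq_len(248L)
  a_double <- which(an_snv_u$mult == 2L)
  af_vals <- c(rep(0.9, 286L), rep(0.105, 78L), 0.11)
  an_snv_u$af[c(a_single, a_double)] <- af_vals
  # consequence terms of the non-novel uniques, filled to occurrence budgets
  budgets <- c(synonymous = 1500L, missense = 1200L, splice_region = 162L,
               intronic_special = 5L)
  todo <- which(is.na(an_snv_u$term))
  todo <- todo[order(-an_snv_u$mult[todo])]
  for (i in todo) {
    m <- an_snv_u$mult[i]
    pick <- names(budgets)[budgets >= m][which.max(budgets[budgets >= m])]
    an_snv_u$term[i] <- pick
    budgets[pick] <- budgets[pick] - m
  }
  stopifnot(all(budgets == 0L))
  an_snv <- an_snv_u[rep(seq_len(nrow(an_snv_u)), an_snv_u$mult), ]
  stopifnot(nrow(an_snv) == 4039L)
  an_snv$vclass <- "SNV"
  an_snv$zyg_analysed <- c(rep("hom", 108L), rep("het", 3920L),
                           rep("hemi", 11L))

  # indels: 101 additional singleton occurrences
  an_ind <- data.frame(
    uid = 2327L + seq_len(101L), mult = 1L,
    novel_db = c(rep(TRUE, 34L + 15L + 26L), rep(FALSE, 26L)),
    af = 0,
    term = c(rep("frameshift", 34L), rep("inframe_deletion", 15L),
             rep("splice_region", 26L), rep("inframe_deletion", 14L),
             "coding_delins", rep("splice_region", 11L)),
    stringsAsFactors = FALSE)
  an_ind$vclass <- "indel"
  an_ind$zyg_analysed <- "het"
  an_ind$zyg_analysed[an_ind$term == "frameshift"][1:2] <- "hom"
  an_ind$zyg_analysed[which(an_ind$term == "splice_region")[1:3]] <- "hemi"

  an_rows <- rbind(an_snv[, c("uid", "vclass", "term", "novel_db", "af",
                              "zyg_analysed")],
                   an_ind[, c("uid", "vclass", "term", "novel_db", "af",
                              "zyg_analysed")])
  an_rows$key <- sprintf("ANL%04d", an_rows$uid)
  an_rows$gene <- NA_character_
  an_rows$novel_cause <- FALSE
  an_rows$zyg_reported <- NA_character_
  an_rows$analysed <- TRUE
  an_rows$reported <- FALSE
  # occurrences of a multi-patient variant must land in distinct patients:
  # assign patients by striding the patient list
  pats <- sprintf("P%04d", 1:537)
  ord <- order(an_rows$uid)
  an_rows <- an_rows[ord, ]
  an_rows$patient_id <- pats[1L + (seq_len(nrow(an_rows)) %% 537L)]

  # ---- raw-only rows ----------------------------------------------------
  raw_cells <- rbind(
    data.frame(vclass = "SNV", zyg = ZYGOSITIES,
               n = c(46405L - 166L, 90981L - 4172L, 338L - 20L, 82L)),
    data.frame(vclass = "indel", zyg = ZYGOSITIES,
               n = c(2182L - 27L, 3653L - 150L, 12L - 7L, 22L)))
  raw_rows <- data.frame(
    vclass = rep(raw_cells$vclass, raw_cells$n),
    zyg_analysed = rep(raw_cells$zyg, raw_cells$n),
    stringsAsFactors = FALSE)
  raw_rows$key <- sprintf("RAW%06d", seq_len(nrow(raw_rows)))
  raw_rows$uid <- NA_integer_
  raw_rows$term <- NA_character_
  raw_rows$novel_db <- NA
  raw_rows$novel_cause <- NA
  raw_rows$af <- NA_real_
  raw_rows$gene <- NA_character_
  raw_rows$zyg_reported <- NA_character_
  raw_rows$analysed <- FALSE
  raw_rows$reported <- FALSE
  raw_rows$patient_id <- pats[1L + (seq_len(nrow(raw_rows)) %% 537L)]

  cols <- c("patient_id", "key", "vclass", "zyg_analysed", "zyg_reported",
            "analysed", "reported", "novel_db", "novel_cause", "term",
            "af", "gene")
  variants <- rbind(rep_rows[, cols], an_rows[, cols], raw_rows[, cols])
  rownames(variants) <- NULL
  variants$truncating <- !is.na(variants$term) &
    variants$term %in% c("frameshift", "stop_gained")
  variants$coding <- !is.na(variants$term) &
    !variants$term %in% c("canonical_splice", "splice_region",
                          "intronic_special")
  # indel subtypes: 135 deletions, 48 insertions, 1 deletion-insertion
  variants$subtype <- variants$vclass
  ind_idx <- which(variants$vclass == "indel" & variants$analysed)
  stopifnot(length(ind_idx) == 184L)
  sub <- rep("deletion", 184L)
  sub[variants$term[ind_idx] == "coding_delins"] <- "delins"
  sub[rev(which(sub == "deletion"))[1:48]] <- "insertion"
  variants$subtype[ind_idx] <- sub

  # ---- patients ---------------------------------------------------------
  referral <- c(diag$referral_category, rep(NA_character_, 537L - 271L))
  n_rp <- sum(referral == "RCD/RP", na.rm = TRUE)
  n_ush <- sum(referral == "Usher", na.rm = TRUE)
  fill <- c(rep("RCD/RP", 250L - n_rp), rep("Usher", 38L - n_ush))
  rest <- setdiff(REFERRAL_CLASSES, c("RCD/RP", "Usher"))
  fill <- c(fill, rep(rest, length.out = 266L - length(fill)))
  referral[272:537] <- fill
  sex <- rep("F", 537L)
  sex[match(diag$patient_id[diag$mode == "XL"], pats)] <- "M"
  sex[which(sex == "F")[seq_len(287L - 13L)]] <- "M"
  patients <- data.frame(patient_id = pats, sex = sex,
                         referral_category = referral,
                         platform = c(rep("SOLiD", 235L), rep("HiSeq", 302L)),
                         stringsAsFactors = FALSE)

  # ---- carrier findings: 154 individuals, 59 of them diagnosed ----------
  car_diag <- c(diag$patient_id[diag$mode == "AR"][1:48],
                diag$patient_id[diag$mode == "AD"][1:11])
  car_none <- pats[272:366]  # 95 undiagnosed carriers
  car_pat <- c(car_diag, car_none)
  car_gene <- ifelse(car_pat %in% diag$patient_id &
                       diag$gene[match(car_pat, diag$patient_id)] == "USH2A",
                     "ABCA4", "USH2A")
  carriers <- data.frame(patient_id = car_pat, gene = car_gene,
                         key = sprintf("CAR%04d", seq_along(car_pat)),
                         stringsAsFactors = FALSE)
  stopifnot(nrow(carriers) == 154L)

  diag_full <- rbind(diag[, c("patient_id", "status", "mode", "gene",
                              "comphet", "referral_category", "concordant")],
                     data.frame(patient_id = pats[272:537], status = "none",
                                mode = NA_character_, gene = NA_character_,
                                comphet = FALSE,
                                referral_category = referral[272:537],
                                concordant = NA, stringsAsFactors = FALSE))

  cohort <- cohort_results(patients, variants, diag_full, carriers,
                           data.frame(symbol = genes$symbol,
                                      year = genes$year,
                                      stringsAsFactors = FALSE))
  attr(cohort, "exac") <- data.frame(
    key = variants$key[variants$analysed | variants$reported],
    af = variants$af[variants$analysed | variants$reported],
    stringsAsFactors = FALSE)
  cohort
}
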