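# Synthetic-cohort generator ---------------------------------------------
#
# Emits exactly the file formats the pipeline consumes (panel TSV + CDS
# FASTA, per-contig reference FASTA, per-patient VCFs, frequency TSV,
# evidence TSV, family TSV, per-base depth TSVs) together with a truth
# record per patient, so that every stage is testable without external
# data. One toy contig per gene; X-linked genes share a "chrX" contig.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of the diagnostic service: ~268
#' raw calls per patient collapsing to ~8 clinically analysable variants, a
#' SOLiD/HiSeq platform mix of 235:302, a planted-causal-genotype
#' probability of 0.51 with mode mix 88:120:50:13
#' (AR-hom:AR-comphet:AD:XL), and a carrier-finding rate of 154/537.
#'
#' @param seed integer seed driving all randomness
#' @param n_patients cohort size
#' @param platform_mix named fractions over SOLiD/HiSeq (sums to 1)
#' @param raw_rate mean raw variant calls per patient
#' @param off_region_frac fraction of raw calls outside the clinical region
#' @param qc_fail_frac fraction of raw calls failing platform QC
#' @param common_af_mix fraction of in-region QC-passing calls drawn from
#'   common (>1% AF) polymorphism sites
#' @param pathogenic_rate per-patient probability of a planted causal
#'   genotype
#' @param mode_mix fractions over AR_hom/AR_comphet/AD/XL (sums to 1)
#' @param carrier_rate per-patient probability of a planted single
#'   heterozygous pathogenic allele in a recessive gene
#' @param evidence_profile "definitive" gives every planted variant
#'   decisive curated evidence and every background variant concordant
#'   benign in-silico predictions; "realistic" makes one comphet allele a
#'   VUS-grade missense and leaves background in-silico support mixed
#' @param male_fraction fraction of male patients
#' @param comphet_in_cis number of comphet-planted patients whose two
#'   alleles are placed on the same parental haplotype
#' @param n_depth_patients how many patients receive a per-base depth file
#' @return list of class `ird_sim_config`
#' @export
sim_config <- function(seed = 1L, n_patients = 200L,
                       platform_mix = c(SOLiD = 235 / 537, HiSeq = 302 / 537),
                       raw_rate = 268,
                       off_region_frac = 0.55,
                       qc_fail_frac = 0.045,
                       common_af_mix = 0.92,
                       pathogenic_rate = 0.51,
                       mode_mix = c(AR_hom = 88, AR_comphet = 120, AD = 50,
                                    XL = 13) / 271,
                       carrier_rate = 154 / 537,
                       evidence_profile = c("definitive", "realistic"),
                       male_fraction = 287 / 537,
                       comphet_in_cis = 0L,
                       n_depth_patients = 3L) {
  stopifnot(abs(sum(platform_mix) - 1) < 1e-9, abs(sum(mode_mix) - 1) < 1e-9,
            raw_rate >= 0, pathogenic_rate >= 0, pathogenic_rate <= 1,
            carrier_rate >= 0, carrier_rate <= 1)
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 platform_mix = platform_mix, raw_rate = raw_rate,
                 off_region_frac = off_region_frac,
                 qc_fail_frac = qc_fail_frac, common_af_mix = common_af_mix,
                 pathogenic_rate = pathogenic_rate, mode_mix = mode_mix,
                 carrier_rate = carrier_rate,
                 evidence_profile = match.arg(evidence_profile),
                 male_fraction = male_fraction,
                 comphet_in_cis = as.integer(comphet_in_cis),
                 n_depth_patients = as.integer(n_depth_patients)),
            class = "ird_sim_config")
}

# stable per-patient substream seed derived from the cohort seed and the
# patient identifier, so patient sets are reproducible under subsetting
stable_hash <- function(id, seed) {
  h <- as.numeric(seed) %% 2147483647
  for (k in utf8ToInt(id)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

SIM_GENE_TABLE <- data.frame(
  symbol = c("ABCA4", "USH2A", "CERKL", "EYS", "CRB1", "RPE65", "CEP290",
             "GUCY2D", "RHO", "PRPF31", "CHM", "RPGR"),
  modes = c("AR", "AR", "AR", "AR", "AR", "AR", "AR", "AR|AD", "AD", "AD",
            "XL", "XL"),
  cats = c("MD/STGD|CRD|RCD/RP|CD", "Usher|RCD/RP", "RCD/RP|CRD", "RCD/RP",
           "EORD/LCA|RCD/RP", "EORD/LCA|RCD/RP", "EORD/LCA|BBS/ciliopathy",
           "EORD/LCA|CD", "RCD/RP", "RCD/RP", "Other", "RCD/RP"),
  year = c(1997L, 1998L, 2004L, 2008L, 1999L, 1993L, 2006L, 1996L, 1990L,
           2001L, 1990L, 1996L),
  strand = c("+", "+", "-", "+", "+", "+", "+", "+", "+", "+", "+", "-"),
  base = c(rep(0L, 10L), 0L, 20000L),
  stringsAsFactors = FALSE)
SIM_GENE_TABLE$contig <- ifelse(SIM_GENE_TABLE$modes == "XL", "chrX",
                                paste0("chr_", SIM_GENE_TABLE$symbol))

random_cds <- function(n_codons) {
  codons <- apply(matrix(sample(c("A", "C", "G", "T"), 3L * (n_codons - 2L),
                                replace = TRUE), ncol = 3L), 1L, paste,
                  collapse = "")
  stops <- codons %in% c("TAA", "TAG", "TGA")
  codons[stops] <- "TGG"  # replace accidental stops
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

# exon geometry shared by all toy genes, shifted by a per-gene base offset
sim_exons <- function(base, chrom) {
  genomic_intervals(rep(chrom, 3L), base + c(2000L, 3000L, 4000L),
                    base + c(2600L, 3600L, 4300L))
}

# build one gene: transcript and variant candidate pools; paints the CDS
# onto the (possibly shared) contig character vector and returns it
sim_build_gene <- function(row, contig) {
  base <- row$base
  exons <- sim_exons(base, row$contig)
  cds_start <- base + 2100L
  cds_end <- base + 4250L
  cds <- random_cds(450L)  # (500 + 600 + 250) / 3 codons
  # paint the CDS onto the contig in coding order
  seg <- data.frame(start = pmax(exons$start, cds_start),
                    end = pmin(exons$end, cds_end))
  seg <- seg[seg$start < seg$end, ]
  gpos <- integer(0)  # genomic position of each CDS base (coding order)
  if (row$strand == "+") {
    for (i in seq_len(nrow(seg))) gpos <- c(gpos, seg$start[i]:(seg$end[i] - 1L))
    contig[gpos + 1L] <- strsplit(cds, "")[[1L]]
  } else {
    for (i in rev(seq_len(nrow(seg)))) gpos <- c(gpos, (seg$end[i] - 1L):seg$start[i])
    contig[gpos + 1L] <- unname(COMPLEMENT[strsplit(cds, "")[[1L]]])
  }
  tx <- transcript(paste0("TX_", row$symbol), row$symbol, row$contig,
                   row$strand, exons, cds_start, cds_end, cds)
  cds_chars <- strsplit(cds, "")[[1L]]
  # SNV candidates by CDS index, classified by translating the codon
  idx0 <- seq(4L, 1340L)
  alt_mat <- vapply(cds_chars[idx0],
                    function(b) setdiff(c("A", "C", "G", "T"), b),
                    character(3L))
  idx <- rep(idx0, each = 3L)
  alt_cds <- as.vector(alt_mat)
  codon_no <- (idx - 1L) %/% 3L + 1L
  within <- (idx - 1L) %% 3L
  codon <- substring(cds, 3L * codon_no - 2L, 3L * codon_no)
  new_codon <- codon
  substr(new_codon, within + 1L, within + 1L) <- alt_cds
  aa_old <- unname(Biostrings::GENETIC_CODE[codon])
  aa_new <- unname(Biostrings::GENETIC_CODE[new_codon])
  keep <- aa_old != "*"
  g <- gpos[idx]
  all_cand <- data.frame(
    pos = g[keep], ref = contig[g + 1L][keep],
    alt = if (row$strand == "+") alt_cds[keep]
          else unname(COMPLEMENT[alt_cds[keep]]),
    term = ifelse(aa_new[keep] == "*", "stop_gained",
                  ifelse(aa_new[keep] == aa_old[keep], "synonymous",
                         "missense")),
    stringsAsFactors = FALSE)
  cand <- split(all_cand, all_cand$term)
  benign <- cand$synonymous
  missense <- cand$missense
  # background pool: synonymous plus a slice of missense; a disjoint
  # missense slice is reserved for pathogenic planting
  n_mis <- nrow(missense)
  background <- rbind(benign, missense[seq_len(min(200L, n_mis %/% 2L)), ])
  path_missense <- missense[(n_mis %/% 2L + 1L):n_mis, ]
  # frameshift candidates: anchored single-base deletions inside the CDS
  fs <- list()
  for (g in gpos[seq(30L, 1200L, by = 37L)]) {
    if ((g + 1L) %in% gpos) {
      fs[[length(fs) + 1L]] <- data.frame(
        pos = g, ref = paste0(contig[g + 1L], contig[g + 2L]),
        alt = contig[g + 1L], term = "frameshift", stringsAsFactors = FALSE)
    }
  }
  stop_pool <- cand$stop_gained[!duplicated(cand$stop_gained$pos), ]
  list(gene = list(symbol = row$symbol, contig = row$contig,
                   strand = row$strand, tx = tx,
                   background = background[sample.int(nrow(background)), ],
                   stop_pool = stop_pool,
                   missense_pool = path_missense[!duplicated(path_missense$pos), ],
                   fs_pool = do.call(rbind, fs),
                   off_positions = c(base + 500:1500, base + 6000:8000)),
       contig = contig)
}

sim_write_panel <- function(genes, contig_seqs, table, dir) {
  rows <- lapply(genes, function(g) {
    i <- match(g$symbol, table$symbol)
    data.frame(symbol = g$symbol, transcript_id = g$tx$id,
               chrom = g$contig, strand = g$strand,
               exons = format_interval_list(g$tx$exons),
               cds_start = g$tx$cds_start, cds_end = g$tx$cds_end,
               modes = table$modes[i], categories = table$cats[i],
               year = table$year[i], lof_mechanism = TRUE,
               special_intronic = if (g$symbol == "CEP290") "3800-3801" else "",
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), file.path(dir, "panel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cds <- Biostrings::DNAStringSet(vapply(genes, function(g) g$tx$cds_sequence,
                                         character(1L)))
  names(cds) <- vapply(genes, function(g) g$tx$id, character(1L))
  Biostrings::writeXStringSet(cds, file.path(dir, "cds.fasta"))
  ref <- Biostrings::DNAStringSet(vapply(contig_seqs, paste, character(1L),
                                         collapse = ""))
  Biostrings::writeXStringSet(ref, file.path(dir, "reference.fasta"))
}

sim_metrics <- function(platform, vclass, pass) {
  if (platform == "SOLiD") {
    if (vclass == "SNV") {
      if (pass) list(dp = 18L + stats::rpois(1L, 40L),
                     mqv = round(stats::runif(1L, 19, 60), 1), ar = NA)
      else list(dp = stats::rpois(1L, 10L),
                mqv = round(stats::runif(1L, 2, 18), 1), ar = NA)
    } else {
      dp <- 20L + stats::rpois(1L, 20L)
      ar <- if (pass) 6L + stats::rpois(1L, 6L) else sample(0:5, 1L)
      list(dp = dp, mqv = 40, ar = min(ar, dp))
    }
  } else {
    if (vclass == "SNV") {
      if (pass) list(dp = 50L + stats::rpois(1L, 80L),
                     mqv = round(stats::runif(1L, 45, 95), 1), ar = NA)
      else list(dp = stats::rpois(1L, 30L),
                mqv = round(stats::runif(1L, 10, 44), 1), ar = NA)
    } else {
      dp <- 60L + stats::rpois(1L, 60L)
      ar <- if (pass) as.integer(ceiling(dp * stats::runif(1L, 0.28, 0.5)))
            else as.integer(floor(dp * stats::runif(1L, 0.02, 0.24)))
      list(dp = dp, mqv = 60, ar = ar)
    }
  }
}

sim_write_vcf <- function(path, sample_id, contigs, rows) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               "##FORMAT=<ID=MQV,Number=1,Type=Float,Description=\"Mean quality value\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      sample_id)), con)
  if (nrow(rows)) {
    rows <- rows[order(rows$chrom, rows$pos), ]
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP:MQV:AD\t%s:%d:%s:%s",
                       rows$chrom, rows$pos + 1L, rows$ref, rows$alt,
                       rows$gt, rows$dp, format(rows$mqv), rows$ad), con)
  }
  invisible(path)
}

#' Simulate a diagnostic cohort with known truth
#'
#' Writes a complete input set for the pipeline under `dir` (panel.tsv,
#' cds.fasta, reference.fasta, patients.tsv, frequency.tsv, evidence.tsv,
#' families.tsv, vcf/<patient>.vcf, depth/<patient>.tsv, truth.json) and
#' returns the truth records. Deterministic given `config$seed`.
#'
#' @param config an `ird_sim_config`
#' @param dir output directory (created if needed)
#' @return invisibly, a list with `truth` (list of per-patient truth
#'   records) and `dir`
#' @export
simulate_cohort <- function(config, dir) {
  stopifnot(inherits(config, "ird_sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "vcf"), showWarnings = FALSE)
  dir.create(file.path(dir, "depth"), showWarnings = FALSE)
  set.seed(config$seed)
  table <- SIM_GENE_TABLE
  contigs <- tapply(table$base + 9000L, table$contig, max)
  contig_seqs <- lapply(contigs, function(L) {
    sample(c("A", "C", "G", "T"), L, replace = TRUE)
  })
  genes <- list()
  for (i in seq_len(nrow(table))) {
    ct <- table$contig[i]
    built <- sim_build_gene(table[i, ], contig_seqs[[ct]])
    contig_seqs[[ct]] <- built$contig
    genes[[table$symbol[i]]] <- built$gene
  }
  sim_write_panel(genes, contig_seqs, table, dir)

  key_of <- function(contig, d) variant_key(contig, d$pos, d$ref, d$alt)

  # site pools shared across the cohort
  freq_rows <- list(); ev_rows <- list()
  common_pool <- list(); rare_pool <- list(); artefact_pool <- list()
  for (g in genes) {
    bg <- g$background
    n_common <- 30L; n_known <- 75L; n_novel <- 75L
    stopifnot(nrow(bg) >= n_common + n_known + n_novel)
    com <- bg[seq_len(n_common), ]
    kno <- bg[n_common + seq_len(n_known), ]
    nov <- bg[n_common + n_known + seq_len(n_novel), ]
    art <- bg[n_common + n_known + n_novel + seq_len(2L), ]
    af <- round(stats::runif(n_common, 0.02, 0.5), 4)
    freq_rows[[length(freq_rows) + 1L]] <- data.frame(
      chrom = g$contig, pos = com$pos + 1L, ref = com$ref, alt = com$alt,
      dbsnp_af = af, evs_af = af, evs_mean_depth = 60, evs_cohort_ok = TRUE,
      exac_af = af, inhouse_count = 0L, stringsAsFactors = FALSE)
    freq_rows[[length(freq_rows) + 1L]] <- data.frame(
      chrom = g$contig, pos = kno$pos + 1L, ref = kno$ref, alt = kno$alt,
      dbsnp_af = signif(10^stats::runif(n_known, -5, -2.2), 3), evs_af = NA,
      evs_mean_depth = NA, evs_cohort_ok = FALSE, exac_af = NA,
      inhouse_count = 0L, stringsAsFactors = FALSE)
    bg_all <- rbind(kno, nov)
    benign_insilico <- if (config$evidence_profile == "definitive")
      "concordant_benign" else sample(c("concordant_benign", "conflicting"),
                                      nrow(bg_all), replace = TRUE,
                                      prob = c(0.9, 0.1))
    ev_rows[[length(ev_rows) + 1L]] <- data.frame(
      key = key_of(g$contig, bg_all), functional_support = FALSE,
      prior_segregation_report = FALSE, same_residue_alternative = FALSE,
      insilico = benign_insilico, phenotype_match = FALSE,
      novel = c(rep(FALSE, n_known), rep(TRUE, n_novel)),
      stringsAsFactors = FALSE)
    common_pool[[g$symbol]] <- cbind(com, contig = g$contig, gene = g$symbol)
    rare_pool[[g$symbol]] <- cbind(bg_all, contig = g$contig, gene = g$symbol)
    artefact_pool[[g$symbol]] <- cbind(art, contig = g$contig, gene = g$symbol)
  }
  artefacts <- do.call(rbind, artefact_pool)[1:5, ]
  # artefact sites carry benign curated evidence so that a site falling
  # below the recurrence threshold in a small cohort still classifies benign
  ev_rows[[length(ev_rows) + 1L]] <- data.frame(
    key = variant_key(artefacts$contig, artefacts$pos, artefacts$ref,
                      artefacts$alt),
    functional_support = FALSE, prior_segregation_report = FALSE,
    same_residue_alternative = FALSE, insilico = "concordant_benign",
    phenotype_match = FALSE, novel = TRUE, stringsAsFactors = FALSE)
  com_all <- do.call(rbind, common_pool)
  rare_all <- do.call(rbind, rare_pool)

  mode_genes <- list(
    AR = table$symbol[grepl("AR", table$modes)],
    AD = table$symbol[grepl("AD", table$modes)],
    XL = table$symbol[table$modes == "XL"],
    # a single heterozygous pathogenic allele is only a carrier state in a
    # strictly recessive gene
    AR_only = table$symbol[table$modes == "AR"])

  pats <- sprintf("S%04d", seq_len(config$n_patients))
  truth <- vector("list", config$n_patients)
  patient_rows <- list(); fam_rows <- list()
  artefact_counts <- integer(nrow(artefacts))
  in_region_pass <- config$raw_rate *
    (1 - config$off_region_frac - config$qc_fail_frac)
  n_cis_left <- config$comphet_in_cis

  for (i in seq_len(config$n_patients)) {
    pid <- pats[i]
    set.seed(stable_hash(pid, config$seed))
    platform <- sample(names(config$platform_mix), 1L,
                       prob = config$platform_mix)
    sex <- if (stats::runif(1L) < config$male_fraction) "M" else "F"
    planted <- NULL
    mode <- "none"
    if (stats::runif(1L) < config$pathogenic_rate) {
      mode <- sample(names(config$mode_mix), 1L, prob = config$mode_mix)
      if (mode == "XL") sex <- "M"
    }
    rows <- list(); plant_keys <- character(); plant_gene <- NA_character_
    ev_extra <- list()
    definitive <- config$evidence_profile == "definitive"
    add_plant <- function(g, cand, gt, vus = FALSE) {
      m <- sim_metrics(platform, if (nchar(cand$ref) == nchar(cand$alt))
        "SNV" else "indel", pass = TRUE)
      ar <- if (is.na(m$ar)) as.integer(round(m$dp * ifelse(gt == "0/1", 0.5,
                                                            1))) else m$ar
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = g$contig, pos = cand$pos, ref = cand$ref, alt = cand$alt,
        gt = gt, dp = m$dp, mqv = m$mqv,
        ad = paste(m$dp - ar, ar, sep = ","), stringsAsFactors = FALSE)
      k <- key_of(g$contig, cand)
      plant_keys <<- c(plant_keys, k)
      ev_extra[[length(ev_extra) + 1L]] <<- if (vus) data.frame(
        key = k, functional_support = FALSE, prior_segregation_report = FALSE,
        same_residue_alternative = FALSE, insilico = "concordant_damaging",
        phenotype_match = TRUE, novel = TRUE, stringsAsFactors = FALSE)
      else if (cand$term == "missense") data.frame(
        key = k, functional_support = TRUE, prior_segregation_report = FALSE,
        same_residue_alternative = FALSE, insilico = "concordant_damaging",
        phenotype_match = TRUE, novel = FALSE, stringsAsFactors = FALSE)
      else data.frame(
        key = k, functional_support = FALSE,
        prior_segregation_report = stats::runif(1L) < 0.5,
        same_residue_alternative = FALSE, insilico = "unavailable",
        phenotype_match = TRUE, novel = stats::runif(1L) < 0.5,
        stringsAsFactors = FALSE)
      k
    }
    planted_phase <- NA_character_
    if (mode != "none") {
      plant_gene <- sample(mode_genes[[sub("_.*", "", mode)]], 1L)
      g <- genes[[plant_gene]]
      trunc_pool <- rbind(g$stop_pool[, c("pos", "ref", "alt", "term")],
                          g$fs_pool)
      if (mode == "AR_hom") {
        add_plant(g, trunc_pool[sample.int(nrow(trunc_pool), 1L), ], "1/1")
      } else if (mode == "AR_comphet") {
        # two nonsense SNVs: their keys are normalisation-stable, so the
        # family genotype file can reference them directly
        picks <- g$stop_pool[sample.int(nrow(g$stop_pool), 2L),
                             c("pos", "ref", "alt", "term")]
        vus2 <- !definitive && stats::runif(1L) < 0.5
        k1 <- add_plant(g, picks[1L, ], "0/1")
        k2 <- if (vus2)
          add_plant(g, g$missense_pool[sample.int(nrow(g$missense_pool), 1L), ],
                    "0/1", vus = TRUE)
        else add_plant(g, picks[2L, ], "0/1")
        in_cis <- n_cis_left > 0L
        if (in_cis) n_cis_left <- n_cis_left - 1L
        planted_phase <- if (in_cis) "in_cis" else "in_trans"
        fam_rows[[length(fam_rows) + 1L]] <- data.frame(
          proband_id = pid,
          role = c("mother", "mother", "father", "father"),
          key = c(k1, k2, k1, k2),
          zygosity = if (in_cis) c("het", "het", "absent", "absent")
                     else c("het", "absent", "absent", "het"),
          stringsAsFactors = FALSE)
      } else if (mode == "AD") {
        add_plant(g, g$missense_pool[sample.int(nrow(g$missense_pool), 1L), ],
                  "0/1")
      } else {
        add_plant(g, trunc_pool[sample.int(nrow(trunc_pool), 1L), ], "1")
      }
    }
    carrier_gene <- NA_character_; carrier_key <- NA_character_
    if (stats::runif(1L) < config$carrier_rate) {
      carrier_gene <- sample(setdiff(mode_genes$AR_only, plant_gene), 1L)
      g <- genes[[carrier_gene]]
      trunc_pool <- rbind(g$stop_pool[, c("pos", "ref", "alt", "term")],
                          g$fs_pool)
      carrier_key <- add_plant(g, trunc_pool[sample.int(nrow(trunc_pool), 1L), ],
                               "0/1")
    }
    # background: common polymorphisms, rare benign variants, QC failures,
    # off-region calls and shared artefact sites
    draw_background <- function(pool, n, pass) {
      if (n <= 0L) return()
      k <- min(n, nrow(pool))
      s <- pool[sample.int(nrow(pool), k), , drop = FALSE]
      if (platform == "SOLiD") {
        dp <- if (pass) 18L + stats::rpois(k, 40L) else stats::rpois(k, 10L)
        mqv <- if (pass) round(stats::runif(k, 19, 60), 1)
               else round(stats::runif(k, 2, 18), 1)
      } else {
        dp <- if (pass) 50L + stats::rpois(k, 80L) else stats::rpois(k, 30L)
        mqv <- if (pass) round(stats::runif(k, 45, 95), 1)
               else round(stats::runif(k, 10, 44), 1)
      }
      gt <- ifelse(s$contig == "chrX" & sex == "M", "1",
                   ifelse(stats::runif(k) < 0.25, "1/1", "0/1"))
      ar <- as.integer(round(dp * ifelse(gt == "0/1", 0.5, 1)))
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = s$contig, pos = s$pos, ref = s$ref, alt = s$alt, gt = gt,
        dp = dp, mqv = mqv, ad = paste(dp - ar, ar, sep = ","),
        stringsAsFactors = FALSE)
    }
    draw_background(com_all, stats::rpois(1L, in_region_pass *
                                            config$common_af_mix), TRUE)
    draw_background(rare_all, stats::rpois(1L, in_region_pass *
                                             (1 - config$common_af_mix)), TRUE)
    draw_background(rare_all, stats::rpois(1L, config$raw_rate *
                                             config$qc_fail_frac), FALSE)
    # off-region calls: random intronic / flanking positions
    n_off <- stats::rpois(1L, config$raw_rate * config$off_region_frac)
    if (n_off > 0L) {
      off_genes <- sample(length(genes), n_off, replace = TRUE)
      ct <- vapply(genes[off_genes], `[[`, "", "contig")
      p <- vapply(genes[off_genes], function(g) sample(g$off_positions, 1L),
                  integer(1L))
      refb <- mapply(function(cc, pp) contig_seqs[[cc]][pp + 1L], ct, p)
      altb <- vapply(refb, function(r) sample(setdiff(c("A", "C", "G", "T"),
                                                      r), 1L), "")
      dp <- if (platform == "SOLiD") 18L + stats::rpois(n_off, 40L)
            else 50L + stats::rpois(n_off, 80L)
      mqv <- if (platform == "SOLiD") round(stats::runif(n_off, 19, 60), 1)
             else round(stats::runif(n_off, 45, 95), 1)
      gt <- ifelse(ct == "chrX" & sex == "M", "1", "0/1")
      ar <- as.integer(round(dp * 0.5))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ct, pos = p, ref = unname(refb), alt = altb, gt = gt,
        dp = dp, mqv = mqv, ad = paste(dp - ar, ar, sep = ","),
        stringsAsFactors = FALSE)
    }
    for (j in seq_len(nrow(artefacts))) {
      if (stats::runif(1L) < 0.2 &&
          !(artefacts$contig[j] == "chrX" && sex == "M")) {
        s <- artefacts[j, ]
        m <- sim_metrics(platform, "SNV", pass = TRUE)
        ar <- as.integer(round(m$dp * 0.5))
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = s$contig, pos = s$pos, ref = s$ref, alt = s$alt, gt = "0/1",
          dp = m$dp, mqv = m$mqv, ad = paste(m$dp - ar, ar, sep = ","),
          stringsAsFactors = FALSE)
        artefact_counts[j] <- artefact_counts[j] + 1L
      }
    }
    vcf <- do.call(rbind, rows)
    vcf <- vcf[!duplicated(vcf[, c("chrom", "pos")]), , drop = FALSE]
    sim_write_vcf(file.path(dir, "vcf", paste0(pid, ".vcf")), pid, contigs, vcf)
    referral <- if (mode != "none") {
      cats <- strsplit(table$cats[match(plant_gene, table$symbol)], "|",
                       fixed = TRUE)[[1L]]
      cats[1L]
    } else sample(REFERRAL_CLASSES, 1L,
                  prob = c(0.45, 0.05, 0.07, 0.1, 0.08, 0.05, 0.03, 0.07,
                           0.02, 0.08))
    patient_rows[[i]] <- data.frame(patient_id = pid, sex = sex,
                                    referral_category = referral,
                                    platform = platform,
                                    stringsAsFactors = FALSE)
    truth[[i]] <- list(
      patient_id = pid,
      status = if (mode == "none") "none"
               else if (!definitive && mode == "AR_comphet" &&
                        any(vapply(ev_extra, function(e)
                          identical(e$insilico, "concordant_damaging") &&
                            !e$functional_support, logical(1L)))) "provisional"
               else "confirmed",
      mode = if (mode == "none") NA else sub("_.*", "", mode),
      comphet = identical(mode, "AR_comphet"),
      gene = plant_gene, causal = plant_keys[
        if (is.na(carrier_gene)) TRUE else plant_keys != carrier_key],
      carrier_gene = carrier_gene, carrier_key = carrier_key,
      phase = planted_phase)
    ev_rows <- c(ev_rows, ev_extra)
  }

  freq <- do.call(rbind, freq_rows)
  art_freq <- data.frame(chrom = artefacts$contig, pos = artefacts$pos + 1L,
                         ref = artefacts$ref, alt = artefacts$alt,
                         dbsnp_af = NA, evs_af = NA, evs_mean_depth = NA,
                         evs_cohort_ok = FALSE, exac_af = NA,
                         inhouse_count = artefact_counts,
                         stringsAsFactors = FALSE)
  utils::write.table(rbind(freq, art_freq), file.path(dir, "frequency.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- do.call(rbind, ev_rows)
  ev <- ev[!duplicated(ev$key), ]
  utils::write.table(ev, file.path(dir, "evidence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fams <- if (length(fam_rows)) do.call(rbind, fam_rows) else
    data.frame(proband_id = character(), role = character(),
               key = character(), zygosity = character())
  utils::write.table(fams, file.path(dir, "families.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, patient_rows),
                     file.path(dir, "patients.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # per-base depth profiles over the GUCY2D enrichment region; the first
  # patient carries a contiguous 460-base stretch below 50x in a coding exon
  set.seed(stable_hash("depth", config$seed))
  gex <- genes$GUCY2D
  span <- c(1950L, 4350L)
  for (i in seq_len(min(config$n_depth_patients, config$n_patients))) {
    pos <- span[1L]:(span[2L] - 1L)
    dp <- stats::rpois(length(pos), 120L)
    if (i == 1L) dp[(3050L - span[1L]):(3509L - span[1L]) + 1L] <-
      stats::rpois(460L, 20L)
    utils::write.table(data.frame(chrom = gex$contig, pos = pos + 1L,
                                  depth = dp),
                       file.path(dir, "depth", paste0(pats[i], ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  names(truth) <- pats
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(truth = truth, dir = dir))
}
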