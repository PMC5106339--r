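# shared builders for toy transcripts, panels, VCFs and oracles

BASES <- c("A", "C", "G", "T")

# a CDS of n codons with no internal stops, ATG...TAA
toy_cds <- function(n_codons) {
  mid <- replicate(n_codons - 2L, {
    repeat {
      c3 <- paste(sample(BASES, 3L, replace = TRUE), collapse = "")
      if (!c3 %in% c("TAA", "TAG", "TGA")) return(c3)
    }
  })
  paste0("ATG", paste(mid, collapse = ""), "TAA")
}

# two-exon toy gene: CDS split over exons [100, 100+l1) and [200, 200+l2);
# returns the transcript, the painted contig sequence and the gene record
toy_gene <- function(symbol = "TOY1", strand = "+", n_codons = 40L,
                     modes = "AR", cats = "RCD/RP", year = 2000L,
                     lof = TRUE, chrom = paste0("chr_", symbol)) {
  cds <- toy_cds(n_codons)
  L <- nchar(cds)
  l1 <- L %/% 2L
  l2 <- L - l1
  e2s <- 100L + l1 + 60L  # 60-base intron between the exons
  exons <- genomic_intervals(rep(chrom, 2L), c(100L, e2s),
                             c(100L + l1, e2s + l2))
  contig <- sample(BASES, e2s + l2 + 200L, replace = TRUE)
  cds_chars <- strsplit(cds, "")[[1L]]
  if (strand == "+") {
    contig[(100L:(99L + l1)) + 1L] <- cds_chars[1:l1]
    contig[(e2s:(e2s + l2 - 1L)) + 1L] <- cds_chars[(l1 + 1L):L]
  } else {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    # coding order runs right-to-left on the genome
    contig[((e2s + l2 - 1L):e2s) + 1L] <- comp[cds_chars[1:l2]]
    contig[((99L + l1):100L) + 1L] <- comp[cds_chars[(l2 + 1L):L]]
  }
  tx <- transcript(paste0("TX_", symbol), symbol, chrom, strand, exons,
                   100L, e2s + l2, cds)
  g <- gene_record(symbol, tx, strsplit(modes, "|", fixed = TRUE)[[1L]],
                   strsplit(cats, "|", fixed = TRUE)[[1L]], year, lof)
  list(gene = g, tx = tx, contig = paste(contig, collapse = ""),
       cds = cds)
}

toy_panel <- function(...) {
  gs <- list(...)
  panel(lapply(gs, `[[`, "gene"))
}

# independent splice-mutate-translate oracle for SNV consequences in the CDS
oracle_cds_snv <- function(tg, pos, alt) {
  contig <- tg$contig
  old <- substr(contig, pos + 1L, pos + 1L)
  mut <- paste0(substr(contig, 1L, pos), alt,
                substr(contig, pos + 2L, nchar(contig)))
  extract_cds <- function(seqstr) {
    tx <- tg$tx
    seg <- tx$exons
    seg$start <- pmax(seg$start, tx$cds_start)
    seg$end <- pmin(seg$end, tx$cds_end)
    seg <- seg[seg$start < seg$end, ]
    parts <- vapply(seq_len(nrow(seg)), function(i) {
      substr(seqstr, seg$start[i] + 1L, seg$end[i])
    }, character(1L))
    s <- paste(parts, collapse = "")
    if (tx$strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }
  p_old <- translate_cds(extract_cds(contig))
  p_new <- translate_cds(extract_cds(mut))
  if (p_old == p_new) return("synonymous")
  diff <- which(strsplit(p_old, "")[[1L]] != strsplit(p_new, "")[[1L]])[1L]
  aa_new <- substr(p_new, diff, diff)
  if (diff == 1L) "start_lost" else if (aa_new == "*") "stop_gained"
  else "missense"
}

# genomic CDS positions of a toy gene (any strand)
cds_positions <- function(tg) {
  tx <- tg$tx
  seg <- tx$exons
  seg$start <- pmax(seg$start, tx$cds_start)
  seg$end <- pmin(seg$end, tx$cds_end)
  unlist(Map(function(s, e) s:(e - 1L), seg$start, seg$end))
}

make_calls <- function(chrom, pos, ref, alt, zygosity = "het", depth = 100L,
                       mqv = 60, alt_reads = 50L) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             vclass = variant_class(ref, alt), zygosity = zygosity,
             depth = as.integer(depth), mqv = mqv,
             alt_reads = as.integer(alt_reads), stringsAsFactors = FALSE)
}

empty_freq_table <- function() {
  f <- data.frame(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), dbsnp_af = numeric(), evs_af = numeric(),
                  evs_mean_depth = numeric(), evs_cohort_ok = logical(),
                  exac_af = numeric(), inhouse_count = integer(),
                  key = character(), stringsAsFactors = FALSE)
  attr(f, "inhouse_cohort_size") <- NA_integer_
  f
}

write_test_vcf <- function(path, lines, sample_id = "S1") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=MQV,Number=1,Type=Float,Description=\"Mean quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_id))
  writeLines(c(header, lines), path)
  path
}

# one simulated 200-patient cohort with definitive evidence, shared across
# test files (built on first use)
.shared <- new.env(parent = emptyenv())
shared_sim_cohort <- function() {
  if (is.null(.shared$res)) {
    dir <- file.path(tempdir(), "retinaldx-sim200")
    simulate_cohort(sim_config(seed = 42L, n_patients = 200L,
                               evidence_profile = "definitive"), dir)
    .shared$dir <- dir
    .shared$truth <- read_truth(dir)
    .shared$res <- run_cohort(dir)
  }
  list(dir = .shared$dir, truth = .shared$truth, res = .shared$res)
}
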