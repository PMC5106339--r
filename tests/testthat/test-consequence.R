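set.seed(404)

test_that("coding SNVs translate to the expected consequence on a toy CDS", {
  # hand-built gene: single CDS exon ATG AAA TGG TAA at positions 100..111
  cds <- "ATGAAATGGTAA"
  ex <- genomic_intervals("c1", 100L, 112L)
  contig <- rep("C", 200L)
  contig[101:112] <- strsplit(cds, "")[[1L]]
  tx <- transcript("T1", "G1", "c1", "+", ex, 100L, 112L, cds)
  g <- gene_record("G1", tx, "AR", "RCD/RP", 2000L, TRUE)
  # codon 2 AAA -> TAA: stop gained, truncating
  cons <- annotate_variant(list(pos = 103L, ref = "A", alt = "T",
                                vclass = "SNV"), g)
  expect_equal(cons$term, "stop_gained")
  expect_true(cons$truncating)
  expect_equal(cons$protein_change, "p.(Lys2Ter)")
  # codon 2 AAA -> AAG: synonymous (Lys)
  cons <- annotate_variant(list(pos = 105L, ref = "A", alt = "G",
                                vclass = "SNV"), g)
  expect_equal(cons$term, "synonymous")
  expect_equal(cons$protein_change, "p.(Lys2=)")
  # start codon disruption
  cons <- annotate_variant(list(pos = 100L, ref = "A", alt = "G",
                                vclass = "SNV"), g)
  expect_equal(cons$term, "start_lost")
  expect_true(cons$truncating)
  # codon 3 TGG -> TGC: missense Trp -> Cys
  cons <- annotate_variant(list(pos = 108L, ref = "G", alt = "C",
                                vclass = "SNV"), g)
  expect_equal(cons$term, "missense")
  expect_equal(cons$protein_change, "p.(Trp3Cys)")
})

test_that("intronic SNV distance sets canonical-splice vs splice-region terms", {
  tg <- toy_gene("SPL1")
  ex <- tg$tx$exons
  snv <- function(p) list(pos = p, ref = "N", alt = "A", vclass = "SNV")
  at <- function(p) {
    refs <- strsplit(tg$contig, "")[[1L]]
    list(pos = p, ref = refs[p + 1L],
         alt = setdiff(BASES, refs[p + 1L])[1L], vclass = "SNV")
  }
  # first intronic base after exon 1
  expect_equal(annotate_variant(at(ex$end[1L]), tg$gene)$term,
               "canonical_splice")
  expect_equal(annotate_variant(at(ex$end[1L] + 1L), tg$gene)$term,
               "canonical_splice")
  expect_equal(annotate_variant(at(ex$end[1L] + 2L), tg$gene)$term,
               "splice_region")
  expect_equal(annotate_variant(at(ex$end[1L] + 4L), tg$gene)$term,
               "splice_region")
  expect_equal(annotate_variant(at(ex$start[2L] - 1L), tg$gene)$term,
               "canonical_splice")
  expect_error(annotate_variant(at(ex$end[1L] + 20L), tg$gene),
               "outside the annotatable region")
})

test_that("indel length arithmetic drives frameshift vs inframe terms", {
  tg <- toy_gene("IND1", n_codons = 50L)
  refs <- strsplit(tg$contig, "")[[1L]]
  p <- cds_positions(tg)[10]
  del2 <- list(pos = p, ref = paste(refs[p + (1:3)], collapse = ""),
               alt = refs[p + 1L], vclass = "deletion")
  expect_equal(annotate_variant(del2, tg$gene)$term, "frameshift")
  expect_true(annotate_variant(del2, tg$gene)$truncating)
  del3 <- list(pos = p, ref = paste(refs[p + (1:4)], collapse = ""),
               alt = refs[p + 1L], vclass = "deletion")
  expect_equal(annotate_variant(del3, tg$gene)$term, "inframe_deletion")
  ins3 <- list(pos = p, ref = refs[p + 1L],
               alt = paste0(refs[p + 1L], "ACG"), vclass = "insertion")
  expect_equal(annotate_variant(ins3, tg$gene)$term, "inframe_insertion")
  # a frameshifting deletion spanning the exon boundary stays frameshift
  # (most severe applicable term)
  e1 <- tg$tx$exons$end[1L]
  span <- list(pos = e1 - 2L, ref = paste(refs[e1 - 2L + (1:3)], collapse = ""),
               alt = refs[e1 - 1L], vclass = "deletion")
  expect_equal(annotate_variant(span, tg$gene)$term, "frameshift")
  # an inframe-length deletion across the boundary takes the splice term
  span3 <- list(pos = e1 - 2L, ref = paste(refs[e1 - 2L + (1:4)], collapse = ""),
                alt = refs[e1 - 1L], vclass = "deletion")
  expect_equal(annotate_variant(span3, tg$gene)$term, "canonical_splice")
})

test_that("the special intronic site annotates as intronic_special", {
  tg <- toy_gene("CEP290")
  sp <- data.frame(gene = "CEP290", chrom = tg$tx$chrom, start = 180L,
                   end = 181L, stringsAsFactors = FALSE)
  cons <- annotate_variant(list(pos = 180L, ref = "N", alt = "A",
                                vclass = "SNV"), tg$gene, sp)
  expect_equal(cons$term, "intronic_special")
  expect_false(cons$truncating)
})

test_that("random coding SNVs agree with the splice-mutate-translate oracle on both strands", {
  for (strand in c("+", "-")) {
    tg <- toy_gene(paste0("ORA", strand), strand = strand, n_codons = 60L)
    refs <- strsplit(tg$contig, "")[[1L]]
    pos_pool <- cds_positions(tg)
    for (k in 1:150) {
      p <- sample(pos_pool, 1L)
      alt <- sample(setdiff(BASES, refs[p + 1L]), 1L)
      got <- annotate_variant(list(pos = p, ref = refs[p + 1L], alt = alt,
                                   vclass = "SNV"), tg$gene)$term
      expect_equal(got, oracle_cds_snv(tg, p, alt),
                   info = sprintf("strand %s pos %d alt %s", strand, p, alt))
    }
  }
})

test_that("reverse-strand genes mirror their reverse-complemented forward twins", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  tg <- toy_gene("TWF", strand = "+", n_codons = 30L)
  L <- nchar(tg$contig)
  # twin: reverse-complemented contig, mirrored exon coordinates
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(tg$contig)))
  ex <- tg$tx$exons
  ex_rc <- genomic_intervals(rep("c_rc", 2L), L - rev(ex$end),
                             L - rev(ex$start))
  tx_rc <- transcript("T_rc", "TWR", "c_rc", "-", ex_rc,
                      L - tg$tx$cds_end, L - tg$tx$cds_start,
                      tg$tx$cds_sequence)
  g_rc <- gene_record("TWR", tx_rc, "AR", "RCD/RP", 2000L, TRUE)
  tg_rc <- list(gene = g_rc, tx = tx_rc, contig = rc)
  refs <- strsplit(tg$contig, "")[[1L]]
  for (p in sample(cds_positions(tg), 40L)) {
    alt <- sample(setdiff(BASES, refs[p + 1L]), 1L)
    fwd <- annotate_variant(list(pos = p, ref = refs[p + 1L], alt = alt,
                                 vclass = "SNV"), tg$gene)
    rev_ <- annotate_variant(list(pos = L - 1L - p, ref = comp[[refs[p + 1L]]],
                                  alt = comp[[alt]], vclass = "SNV"), g_rc)
    expect_equal(fwd$term, rev_$term)
    expect_equal(fwd$protein_change, rev_$protein_change)
  }
})

test_that("novelty requires absence from both dbSNP and EVS", {
  expect_true(is_novel(list(dbsnp_af = NA, evs_af = NA)))
  expect_false(is_novel(list(dbsnp_af = 1e-4, evs_af = NA)))
  expect_false(is_novel(list(dbsnp_af = NA, evs_af = 1e-4)))
})
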