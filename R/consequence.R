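AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

TERM_SEVERITY <- c(stop_gained = 10, frameshift = 9, start_lost = 8,
                   canonical_splice = 7, coding_delins = 6,
                   inframe_deletion = 5, inframe_insertion = 5,
                   missense = 4, splice_region = 3, intronic_special = 2,
                   synonymous = 1)

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Translate a coding sequence to protein
#'
#' @param cds coding nucleotide string (length multiple of 3 not required;
#'   trailing partial codon is dropped)
#' @return amino-acid string, stop spelled `*`
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return("")
  paste(vapply(seq_len(n), function(i) {
    translate_codon(substr(cds, 3L * i - 2L, 3L * i))
  }, character(1L)), collapse = "")
}

# ordered CDS segments with cumulative coding offsets, 5'->3' on the
# coding strand
cds_segment_map <- function(tx) {
  seg <- cds_exon_segments(tx)
  if (tx$strand == "-") seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
  len <- seg$end - seg$start
  seg$cds_offset <- cumsum(c(0L, len))[seq_len(nrow(seg))]
  seg
}

# 0-based coding-strand CDS index of a genomic position, or NA
genomic_to_cds <- function(tx, pos) {
  seg <- cds_segment_map(tx)
  for (i in seq_len(nrow(seg))) {
    if (pos >= seg$start[i] && pos < seg$end[i]) {
      return(if (tx$strand == "+") seg$cds_offset[i] + (pos - seg$start[i])
             else seg$cds_offset[i] + (seg$end[i] - 1L - pos))
    }
  }
  NA_integer_
}

# distance of an intronic position to the nearest CDS-exon boundary:
# 1 = first intronic base. Inf when the position is exonic/CDS.
intron_distance <- function(tx, pos) {
  seg <- cds_exon_segments(tx)
  d <- Inf
  for (i in seq_len(nrow(seg))) {
    if (pos < seg$start[i]) d <- min(d, seg$start[i] - pos)
    else if (pos >= seg$end[i]) d <- min(d, pos - seg$end[i] + 1L)
    else return(Inf)
  }
  d
}

protein_change_string <- function(ref_aa, codon_no, alt_aa) {
  if (ref_aa == alt_aa) {
    sprintf("p.(%s%d=)", AA3[[ref_aa]], codon_no)
  } else {
    sprintf("p.(%s%d%s)", AA3[[ref_aa]], codon_no, AA3[[alt_aa]])
  }
}

annotate_cds_snv <- function(tx, pos, ref, alt) {
  idx <- genomic_to_cds(tx, pos)
  cref <- if (tx$strand == "+") ref else COMPLEMENT[[ref]]
  calt <- if (tx$strand == "+") alt else COMPLEMENT[[alt]]
  cds <- tx$cds_sequence
  if (substr(cds, idx + 1L, idx + 1L) != cref) {
    stop("reference allele disagrees with the transcript CDS sequence at CDS index ",
         idx, " (", substr(cds, idx + 1L, idx + 1L), " vs ", cref, ")")
  }
  codon_no <- idx %/% 3L + 1L
  within <- idx %% 3L
  codon <- substr(cds, 3L * codon_no - 2L, 3L * codon_no)
  new_codon <- codon
  substr(new_codon, within + 1L, within + 1L) <- calt
  ref_aa <- translate_codon(codon)
  alt_aa <- translate_codon(new_codon)
  term <- if (codon_no == 1L && alt_aa != ref_aa) "start_lost"
          else if (alt_aa == ref_aa) "synonymous"
          else if (alt_aa == "*") "stop_gained"
          else "missense"
  list(term = term,
       protein_change = protein_change_string(ref_aa, codon_no, alt_aa),
       truncating = term %in% c("stop_gained", "start_lost"))
}

# does applying an equal-length edit to the CDS introduce a premature stop?
delins_introduces_stop <- function(tx, pos, ref, alt) {
  idx <- genomic_to_cds(tx, pos)
  cds <- tx$cds_sequence
  if (tx$strand == "+") {
    new_cds <- splice_variant(cds, idx,
                              substr(cds, idx + 1L, idx + nchar(ref)), alt)
  } else {
    # on the minus strand the edited genomic span maps to CDS indices
    # [idx - len + 1, idx]; reverse-complement the alleles
    rc <- function(s) paste(rev(COMPLEMENT[strsplit(s, "")[[1L]]]), collapse = "")
    start_idx <- idx - nchar(ref) + 1L
    new_cds <- splice_variant(cds, start_idx,
                              substr(cds, start_idx + 1L, start_idx + nchar(ref)),
                              rc(alt))
  }
  old_prot <- translate_cds(cds)
  new_prot <- translate_cds(new_cds)
  old_stop <- regexpr("*", old_prot, fixed = TRUE)
  new_stop <- regexpr("*", new_prot, fixed = TRUE)
  new_stop > 0L && (old_stop < 0L || new_stop < old_stop)
}

#' Predict the consequence of a variant on a gene's designated transcript
#'
#' SNVs inside the CDS are translated on the coding strand (synonymous /
#' missense / stop_gained / start_lost). Intronic SNVs at positions 1-2 from
#' an exon boundary are canonical_splice, positions 3-5 splice_region.
#' Indels overlapping the CDS are frameshift when the length change is not a
#' multiple of three, otherwise inframe; equal-length coding substitutions
#' are coding_delins, truncating only when translation shows a premature
#' stop. Variants at a configured special intronic site are
#' intronic_special. Variants spanning an exon/intron junction take the more
#' severe of the applicable terms.
#'
#' @param call list/one-row data.frame with pos (0-based), ref, alt, vclass
#' @param gene an `ird_gene`
#' @param special_sites optional interval data.frame of special intronic
#'   sites for this gene
#' @return list(term, protein_change, truncating)
#' @export
annotate_variant <- function(call, gene, special_sites = NULL) {
  tx <- gene$transcript
  pos <- as.integer(call$pos); ref <- call$ref; alt <- call$alt
  span <- genomic_intervals(tx$chrom, pos, pos + max(1L, nchar(ref)))
  if (!is.null(special_sites) && nrow(special_sites) > 0L) {
    sp <- genomic_intervals(special_sites$chrom, special_sites$start,
                            special_sites$end)
    if (any(sp$chrom == span$chrom & sp$start < span$end & span$start < sp$end)) {
      return(list(term = "intronic_special", protein_change = NA_character_,
                  truncating = FALSE))
    }
  }
  vclass <- variant_class(ref, alt)
  if (vclass == "SNV") {
    if (!is.na(genomic_to_cds(tx, pos))) {
      return(annotate_cds_snv(tx, pos, ref, alt))
    }
    d <- intron_distance(tx, pos)
    if (d <= 2) return(list(term = "canonical_splice",
                            protein_change = NA_character_, truncating = FALSE))
    if (d <= 5) return(list(term = "splice_region",
                            protein_change = NA_character_, truncating = FALSE))
    stop("variant at ", tx$chrom, ":", pos + 1L,
         " lies outside the annotatable region of ", gene$symbol)
  }
  # indel / delins: which bases of the REF span (for insertions, the anchor
  # base and the base after) touch CDS vs the splice flanks?
  touched <- if (vclass == "insertion") pos else pos:(pos + nchar(ref) - 1L)
  in_cds <- vapply(touched, function(p) !is.na(genomic_to_cds(tx, p)), logical(1L))
  dists <- vapply(touched, function(p) intron_distance(tx, p), numeric(1L))
  dists <- dists[is.finite(dists)]
  terms <- character()
  if (any(in_cds)) {
    ldiff <- nchar(alt) - nchar(ref)
    if (ldiff == 0L) {
      trunc <- all(in_cds) && delins_introduces_stop(tx, pos, ref, alt)
      terms <- c(terms, "coding_delins")
      if (trunc) {
        return(list(term = "coding_delins", protein_change = NA_character_,
                    truncating = TRUE))
      }
    } else if (abs(ldiff) %% 3L != 0L) {
      terms <- c(terms, "frameshift")
    } else {
      terms <- c(terms, if (ldiff < 0L) "inframe_deletion" else "inframe_insertion")
    }
  }
  if (length(dists)) {
    if (min(dists) <= 2) terms <- c(terms, "canonical_splice")
    else if (min(dists) <= 5) terms <- c(terms, "splice_region")
  }
  if (!length(terms)) {
    stop("variant at ", tx$chrom, ":", pos + 1L,
         " lies outside the annotatable region of ", gene$symbol)
  }
  term <- terms[which.max(TERM_SEVERITY[terms])]
  list(term = term, protein_change = NA_character_,
       truncating = term %in% c("frameshift", "stop_gained", "start_lost"))
}

#' Is a variant novel with respect to dbSNP and EVS?
#'
#' Novel means absent from both databases; presence at any frequency in
#' either disqualifies.
#'
#' @param freq frequency record (list with dbsnp_af / evs_af, NA = absent)
#' @return logical
#' @export
is_novel <- function(freq) {
  is.na(freq$dbsnp_af) && is.na(freq$evs_af)
}
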