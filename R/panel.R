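#' @importFrom Biostrings readDNAStringSet DNAString DNAStringSet writeXStringSet
NULL

# the ten clinical referral classifications used by the diagnostic service
REFERRAL_CLASSES <- c("RCD/RP", "CD", "CRD", "MD/STGD", "EORD/LCA", "CSNB",
                      "FEVR", "Usher", "BBS/ciliopathy", "Other")

INHERITANCE_MODES <- c("AD", "AR", "XL")

#' The ten clinical referral classifications
#' @return character vector of the referral classes
#' @export
referral_classes <- function() REFERRAL_CLASSES

#' Construct a transcript model
#'
#' One designated transcript per gene carries the exon geometry, CDS bounds
#' and CDS sequence against which consequences are predicted. For minus-strand
#' genes `cds_sequence` is the coding (mRNA-sense) sequence, i.e. the
#' reverse complement of the genomic CDS span.
#'
#' @param id transcript identifier
#' @param gene gene symbol
#' @param chrom contig name
#' @param strand "+" or "-"
#' @param exons interval data.frame of exons (0-based half-open), sorted,
#'   non-overlapping
#' @param cds_start,cds_end genomic CDS bounds (0-based half-open), inside the
#'   exon union
#' @param cds_sequence coding sequence; length divisible by 3, starting ATG
#' @return an object of class `ird_transcript`
#' @export
transcript <- function(id, gene, chrom, strand, exons, cds_start, cds_end,
                       cds_sequence) {
  stopifnot(is.character(id), nzchar(id), strand %in% c("+", "-"))
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if (nrow(exons) == 0L) stop("transcript requires at least one exon")
  if (is.unsorted(exons$start, strictly = TRUE) ||
      any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    stop("exons must be sorted and non-overlapping")
  }
  if (cds_start >= cds_end) stop("cds_start must be < cds_end")
  if (!all(in_intervals(rep(chrom, 2L), c(cds_start, cds_end - 1L),
                        genomic_intervals(exons$chrom, exons$start, exons$end)))) {
    stop("CDS bounds must fall inside the exon union")
  }
  cds_sequence <- toupper(as.character(cds_sequence))
  if (nchar(cds_sequence) %% 3L != 0L) {
    stop("cds_sequence length must be a multiple of 3")
  }
  if (substr(cds_sequence, 1L, 3L) != "ATG") {
    stop("cds_sequence must begin with the ATG start codon")
  }
  structure(list(id = id, gene = gene, chrom = chrom, strand = strand,
                 exons = exons, cds_start = cds_start, cds_end = cds_end,
                 cds_sequence = cds_sequence),
            class = "ird_transcript")
}

#' Construct a gene record
#'
#' @param symbol gene symbol
#' @param tx an `ird_transcript`
#' @param inheritance_modes subset of AD/AR/XL (at least one)
#' @param phenotype_categories subset of [referral_classes()]
#' @param discovery_year year the gene was established as an IRD cause
#' @param lof_mechanism is loss of function an established disease mechanism?
#' @return an object of class `ird_gene`
#' @export
gene_record <- function(symbol, tx, inheritance_modes, phenotype_categories,
                        discovery_year, lof_mechanism) {
  stopifnot(inherits(tx, "ird_transcript"))
  inheritance_modes <- unique(inheritance_modes)
  if (length(inheritance_modes) == 0L ||
      !all(inheritance_modes %in% INHERITANCE_MODES)) {
    stop("gene ", symbol, ": at least one inheritance mode of ",
         paste(INHERITANCE_MODES, collapse = "/"), " is required")
  }
  if (!all(phenotype_categories %in% REFERRAL_CLASSES)) {
    stop("gene ", symbol, ": unknown phenotype category")
  }
  discovery_year <- as.integer(discovery_year)
  if (is.na(discovery_year) || discovery_year < 1980L || discovery_year > 2016L) {
    stop("gene ", symbol, ": discovery_year must lie in [1980, 2016]")
  }
  structure(list(symbol = symbol, transcript = tx,
                 inheritance_modes = inheritance_modes,
                 phenotype_categories = phenotype_categories,
                 discovery_year = discovery_year,
                 lof_mechanism = isTRUE(lof_mechanism)),
            class = "ird_gene")
}

#' Construct a gene panel
#'
#' @param genes list of `ird_gene` records (symbols must be unique)
#' @param special_intronic_sites data.frame (gene, chrom, start, end) of
#'   clinically surveyed intronic sites outside the coding +/- 5 bp window,
#'   such as the CEP290 deep-intronic hotspot
#' @return an object of class `ird_panel`
#' @export
panel <- function(genes, special_intronic_sites = NULL) {
  syms <- vapply(genes, function(g) g$symbol, character(1L))
  if (anyDuplicated(syms)) {
    stop("duplicate gene symbol in panel: ",
         paste(unique(syms[duplicated(syms)]), collapse = ", "))
  }
  o <- order(syms)
  genes <- genes[o]
  names(genes) <- syms[o]
  if (is.null(special_intronic_sites)) {
    special_intronic_sites <- data.frame(gene = character(), chrom = character(),
                                         start = integer(), end = integer(),
                                         stringsAsFactors = FALSE)
  }
  if (nrow(special_intronic_sites) > 0L &&
      !all(special_intronic_sites$gene %in% names(genes))) {
    stop("special intronic site refers to a gene absent from the panel")
  }
  structure(list(genes = genes, special_intronic_sites = special_intronic_sites),
            class = "ird_panel")
}

#' @export
print.ird_panel <- function(x, ...) {
  cat("IRD gene panel:", length(x$genes), "genes,",
      nrow(x$special_intronic_sites), "special intronic site(s)\n")
  modes <- table(unlist(lapply(x$genes, `[[`, "inheritance_modes")))
  cat("inheritance modes:",
      paste(names(modes), as.integer(modes), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

parse_interval_list <- function(s, chrom) {
  if (is.na(s) || !nzchar(s)) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  genomic_intervals(rep(chrom, length(parts)),
                    vapply(parts, function(p) as.integer(p[1L]), integer(1L)),
                    vapply(parts, function(p) as.integer(p[2L]), integer(1L)))
}

format_interval_list <- function(ivs) {
  paste(sprintf("%d-%d", ivs$start, ivs$end), collapse = ";")
}

#' Load a gene panel from a TSV definition plus CDS FASTA
#'
#' The TSV needs columns symbol, transcript_id, chrom, strand, exons
#' (`start-end` pairs joined by `;`, 0-based half-open), cds_start, cds_end,
#' modes (`|`-separated), categories (`|`-separated), year, lof_mechanism and
#' optionally special_intronic (interval list as for exons). CDS sequences
#' come from `cds_fasta`, keyed by transcript_id.
#'
#' @param panel_file path to the panel TSV
#' @param cds_fasta path to the companion FASTA of CDS sequences
#' @return an `ird_panel`
#' @export
load_panel <- function(panel_file, cds_fasta) {
  d <- utils::read.delim(panel_file, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("symbol", "transcript_id", "chrom", "strand", "exons",
                "cds_start", "cds_end", "modes", "categories", "year",
                "lof_mechanism")
  if (!all(required %in% names(d))) {
    stop("panel file missing required column(s): ",
         paste(setdiff(required, names(d)), collapse = ", "))
  }
  if (nrow(d) == 0L) stop("panel file contains no genes")
  if (anyDuplicated(d$symbol)) {
    stop("duplicate gene symbol in panel file: ",
         paste(unique(d$symbol[duplicated(d$symbol)]), collapse = ", "))
  }
  cds <- Biostrings::readDNAStringSet(cds_fasta)
  genes <- vector("list", nrow(d))
  specials <- list()
  for (i in seq_len(nrow(d))) {
    row <- d[i, ]
    if (!nzchar(row$modes)) stop("gene ", row$symbol, ": missing inheritance mode")
    if (!row$transcript_id %in% names(cds)) {
      stop("no CDS sequence for transcript ", row$transcript_id)
    }
    tx <- transcript(row$transcript_id, row$symbol, row$chrom, row$strand,
                     parse_interval_list(row$exons, row$chrom),
                     row$cds_start, row$cds_end,
                     as.character(cds[[row$transcript_id]]))
    genes[[i]] <- gene_record(row$symbol, tx,
                              strsplit(row$modes, "|", fixed = TRUE)[[1L]],
                              if (nzchar(row$categories))
                                strsplit(row$categories, "|", fixed = TRUE)[[1L]]
                              else character(),
                              row$year,
                              toupper(row$lof_mechanism) %in% c("TRUE", "1", "T"))
    if ("special_intronic" %in% names(row) && !is.na(row$special_intronic) &&
        nzchar(row$special_intronic)) {
      sp <- parse_interval_list(row$special_intronic, row$chrom)
      sp$gene <- row$symbol
      specials[[length(specials) + 1L]] <- sp[, c("gene", "chrom", "start", "end")]
    }
  }
  panel(genes, if (length(specials)) do.call(rbind, specials) else NULL)
}

cds_exon_segments <- function(tx) {
  # exon segments clipped to the CDS span ("coding regions"; UTRs excluded)
  seg <- tx$exons
  seg$start <- pmax(seg$start, tx$cds_start)
  seg$end <- pmin(seg$end, tx$cds_end)
  seg <- seg[seg$start < seg$end, , drop = FALSE]
  genomic_intervals(rep(tx$chrom, nrow(seg)), seg$start, seg$end)
}

region_for_gene <- function(pan, gene, flank, include_special) {
  if (!gene %in% names(pan$genes)) stop("unknown gene: ", gene)
  g <- pan$genes[[gene]]
  ivs <- flank_intervals(cds_exon_segments(g$transcript), flank)
  sp <- pan$special_intronic_sites
  if (include_special && nrow(sp) > 0L && any(sp$gene == gene)) {
    sp <- sp[sp$gene == gene, , drop = FALSE]
    ivs <- rbind(ivs, genomic_intervals(sp$chrom, sp$start, sp$end))
  }
  merge_intervals(ivs)
}

#' Clinically analysed region of a gene
#'
#' CDS-overlapping exon segments expanded by +/- 5 bp and merged, plus any
#' configured special intronic site (the CEP290 deep-intronic hotspot).
#'
#' @param pan an `ird_panel`
#' @param gene gene symbol
#' @return merged interval data.frame
#' @export
clinical_region <- function(pan, gene) {
  region_for_gene(pan, gene, 5L, include_special = TRUE)
}

#' Enrichment (capture) region of a gene
#'
#' CDS-overlapping exon segments expanded by +/- 50 bp and merged, plus any
#' special intronic site; this is the designed capture target.
#'
#' @inheritParams clinical_region
#' @return merged interval data.frame
#' @export
enrichment_region <- function(pan, gene) {
  region_for_gene(pan, gene, 50L, include_special = TRUE)
}

#' Clinical region of every panel gene
#'
#' @param pan an `ird_panel`
#' @return interval data.frame with a `gene` column
#' @export
panel_clinical_regions <- function(pan) {
  out <- lapply(names(pan$genes), function(g) {
    r <- clinical_region(pan, g)
    if (nrow(r)) r$gene <- g
    r
  })
  do.call(rbind, out[vapply(out, nrow, integer(1L)) > 0L])
}
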