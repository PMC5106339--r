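---
title: "The retinaldx diagnostic pipeline: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The retinaldx diagnostic pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinaldx)
```

# Scope and model

`retinaldx` models the computational half of a targeted diagnostic NGS
service for inherited retinal disease (IRD): everything downstream of
variant calling. The inputs are per-patient VCFs, a panel definition
(genes, designated transcripts, inheritance modes, phenotype categories,
discovery years), population-frequency tables, curated per-variant
evidence, family genotypes and per-base depth profiles. The outputs are
per-patient molecular diagnoses with carrier findings, and cohort-level
summary tables.

The pipeline is a deterministic rule system, not a statistical estimator:
given the same inputs it always produces the same classifications and
diagnoses. Its stages are strictly ordered, which matters for how drop
reasons are attributed (see *Triage*).

## Coordinates and variant normalisation

All internal coordinates are 0-based, half-open (the BED convention);
VCF positions are converted on ingest and restored on output. Interval
arithmetic (flanking, merging, membership) is delegated to `IRanges`.

Alleles are normalised to the parsimonious left-aligned representation:
shared suffixes then prefixes are trimmed (indels keep one anchor base)
and pure indels are rolled left while the spelled haplotype is unchanged.
The test suite checks idempotence and haplotype preservation against a
string-splicing oracle, and left-alignment against exhaustive placement
enumeration. Compound substitutions (`delins`) are trimmed but not
decomposed.

## Clinical and enrichment regions

"Coding regions" are the CDS-overlapping exon segments of the designated
transcript; UTR-only exon parts are excluded, because the consequence
vocabulary of the service is protein-centric. The clinically analysed
region flanks these segments by ±5 bp; the capture (enrichment) region by
±50 bp. Special deep-intronic sites — in practice the *CEP290*
c.2991+1655A>G hotspot — are configured per panel and appended to both.
One designated transcript per gene is assumed throughout; multi-transcript
annotation is out of scope.

## Triage

Filters apply in a fixed order: **off-region → platform QC →
common polymorphism → in-house recurrence**. A call is dropped at the
first failing filter, which makes reason tallies unambiguous; the retained
set is unchanged under filter permutation (only reasons move), and the
suite asserts retention/drop conservation at every stage.

Platform QC thresholds are configurable per platform and ship with two
profiles:

| platform | SNVs | indels |
|---|---|---|
| SOLiD | depth ≥ 18× and MQV > 18 (strict) | > 5 supporting reads (strict) |
| HiSeq | depth ≥ 50× and MQV ≥ 45 | > 25% supporting fraction (strict) |

The mean quality value (MQV) is treated as an abstract per-call quality
number read from a configurable FORMAT key (default `MQV`, falling back to
`GQ`); callers differ in how they define it.

A variant is a benign common polymorphism when its allele frequency
exceeds 1% in dbSNP, or exceeds 1% in the Exome Variant Server provided
the EVS cohort is adequate ("sufficiently large and diverse" is a per-record
input flag, since no numeric criterion exists) and the mean EVS depth
exceeds 18×. Rare variants recurring in-house above a configurable
fraction of the cohort (default 0.10 — the source service describes only a
"high recurrence rate", so the default is a deliberate, conservative
choice) are treated as neutral or platform artefacts. Both bounds are
strict inequalities; boundary semantics are pinned by tests.

## Consequence annotation

Coding SNVs are translated codon-wise on the coding strand:
same residue → synonymous; new stop → stop_gained; any change in codon 1 →
start_lost; otherwise missense. Intronic SNVs at 1–2 bases from a
CDS-exon boundary are canonical_splice; 3–5 bases, splice_region — the
±5 bp analysis window fixes the splice-region definition, and exonic
splice-region terms are not used. Indels overlapping the CDS are
frameshift when the length change is not a multiple of three, otherwise
in-frame; equal-length substitutions are `coding_delins` and count as
truncating only when translation of the edited CDS shows a premature
stop. Variants spanning an exon/intron junction take the most severe
applicable term (stop_gained > frameshift > start_lost >
canonical_splice > …). Stop-loss changes have no term of their own and
fall back to missense; they did not occur in the data the vocabulary was
built for.

The annotator is validated against an independent oracle that splices the
variant into the genomic sequence, re-extracts and translates the whole
CDS, and diffs the proteins — on forward- and reverse-strand toy genes,
and on 1000 random coding SNVs in the acceptance suite.

## Pathogenicity classification

Classification is a pure, first-match-wins cascade over the consequence,
the gene's loss-of-function annotation, population frequency and a
structured evidence bundle:

1. common polymorphism → benign;
2. truncating term in a LoF-mechanism gene → clearly pathogenic if
   previously reported, likely pathogenic if novel;
3. functional support → clearly pathogenic;
4. literature segregation → likely pathogenic;
5. alternative substitution of the same residue + concordant damaging
   in-silico + phenotype match → likely pathogenic;
6. novel missense with concordant damaging in-silico + phenotype match →
   VUS;
7. otherwise VUS, or likely benign under concordant benign predictions.

Synonymous and splice-region variants therefore reach pathogenic classes
only through curated evidence. The cascade is monotone: adding positive
evidence never demotes a class (property-tested over the full evidence
lattice). Evidence flags are inputs — the package performs no literature
or in-silico computation itself.

## Diagnosis and segregation

Per gene, pathogenic-spectrum variants (clearly/likely pathogenic, with
VUS admitted only as the partner allele) are assembled into disease
states: AR — homozygous pathogenic, two heterozygous pathogenic
(confirmed) or pathogenic + VUS (provisional); AD — one pathogenic
het/hom; XL — hemizygous pathogenic in a male. A lone heterozygous
pathogenic allele in a recessive gene, or a heterozygous pathogenic
allele in an X-linked gene in a female, is a carrier finding. Pathogenic
disease states in more than one gene yield no automatic status and set
the MDT-review flag: the engine only flags, it never adjudicates between
candidate genes, because that adjudication is a clinical judgement.

A compound heterozygote without family data is reported confirmed with
`phase_confirmed = FALSE` (the service reported diagnoses ahead of
cascade testing); `strict_phase = TRUE` demotes such calls to
provisional. Parental genotypes resolve phase by exclusion: alleles from
different parents are in-trans; both from one parent in-cis, which
withdraws the recessive diagnosis and converts both alleles to carrier
findings; any missing parental genotype leaves the pair unresolved and
the result unchanged. Alleles absent from both genotyped parents are
flagged de novo. Two distinct alternate alleles at one site (het–het) are
evaluated as separate alleles and may pair with each other, never with
themselves.

Phenotype concordance compares the referral classification (one of ten
clinical classes) with the diagnosed gene's category set; a diagnosis in
a gene outside the referral category (the choroideremia-under-RP pattern)
is retained but marked discordant.

## Coverage QC

Depth profiles are dense per-base vectors. The service-level statistics
are the fraction of the clinical region at ≥20× and ≥50×, and maximal
runs of consecutive bases below a threshold; runs at least `min_len` long
(default 1; the fallback report filters at 100) are flagged for
capillary-sequencing fallback. Run detection is validated against a
run-length-encoding oracle. GC content excludes ambiguous bases from the
denominator.

## Reporting and rounding

All printed-precision percentages and rates use round-half-up (commercial
rounding), with a small epsilon guard against binary-representation
artefacts; rates are reported to one decimal, percentages to whole
percents. Two published figures are known not to follow this convention
(271/537 printed as 51%, and 4542/537 = 8.458 printed as 8.4); the
package reports the computed values (50% and 8.5) and makes no attempt to
match those two.

Because capillary confirmation can revise pileup-estimated zygosity, the
cohort container carries separate analysed-stage and reported-stage
zygosity columns; stage containment (`reported ⊆ analysed ⊆ raw`) is
enforced on variant keys, not on zygosity cells.

# The synthetic cohort generator

`simulate_cohort()` emulates the study conditions of the service: ~268
raw calls per patient collapsing to ~8 clinically analysable variants, a
SOLiD:HiSeq mix of 235:302, a male fraction of 287/537, a planted causal
genotype in 51% of patients with mode mix 88:120:50:13
(AR-hom : AR-comphet : AD : XL), and a carrier plant in 154/537. Raw
calls decompose into off-region calls (55%), QC failures (4.5%) and
in-region passing calls, of which 92% are drawn from common-polymorphism
sites — values chosen once so that the expected analysable count lands
near 8 under the region and QC geometry of the toy panel. Population
frequencies follow the configured mixture: a point mass at zero for novel
variants, log-uniform 10⁻⁵–10⁻²·² for rare known variants, uniform
0.02–0.5 for common ones.

The toy genome places each gene on its own contig (the two X-linked genes
share a "chrX" contig) with a fixed three-exon geometry and a 1350-base
CDS, including reverse-strand genes. Planted causal variants are
nonsense/frameshift events in LoF-mechanism genes (missense with
functional support for dominant plants); compound-het plants are two
nonsense SNVs so their keys are stable under normalisation and can be
referenced from the family file, in-trans unless configured in-cis.
Background variants carry decisive benign evidence under the
`definitive` profile, which is what makes exact truth recovery a fair
target; the `realistic` profile mixes in VUS-grade partner alleles
(provisional diagnoses) and occasional conflicting in-silico calls, under
which exact recovery is not guaranteed — deliberately.

Determinism: one cohort seed; per-patient substreams are derived by a
stable string hash of the patient identifier, so patient `S0007` is
identical in any cohort with the same seed regardless of cohort size.
Depth files are written for a configurable number of patients (default
3), the first carrying a planted 460-base sub-50× stretch in a coding
exon — the capillary-fallback scenario.

What the generator does **not** emulate: read-level error processes (no
FASTQ/BAM), linkage between neighbouring variants, population structure,
indel-rich repeat regions, multi-sample VCFs, structural variants, and
genuinely ambiguous evidence. Passing the truth-recovery test therefore
demonstrates the correctness of the rule engine on cleanly labelled
inputs, not robustness to noisy real-world annotation.

# The worked-example cohort

`paper_fixture()` is a deterministic, RNG-free 537-patient cohort whose
tallies encode the published summary surfaces of a clinical IRD service:
the raw/analysed/reported stage table with zygosity cells, novelty splits
at occurrence and unique-variant level, the coding-indel and
premature-termination breakdowns, 271 diagnoses (208 AR = 88 homozygous +
120 compound-het, 50 AD, 13 XL), 154 carrier patients (59 of them also
diagnosed), the 62-gene spectrum with 41 single-category and 21
multi-category genes (ABCA4 spanning five categories with 23 patients),
the discovery-era structure (7/65/33 panel genes carrying 16/214/41
diagnoses — rates of 3.3 and 1.2 diagnoses per gene in the two later
eras), and retrospective
allele-frequency summaries. Counts the publication does not constrain
(e.g. the confirmed/provisional split, or per-gene homozygote fractions)
are fixed by round-robin convention and documented as such. Two
internal inconsistencies in the published breakdowns (the overall
reported-novelty fraction versus its own per-class splits, and the
deletion/insertion zygosity sub-splits versus the stage table) are
resolved in favour of the more specific per-class and stage-table
figures.

The fixture exists so that the reporting layer can be validated to
printed precision without patient data; it exercises `tabulate_cohort()`,
`yield_stats()`, `discovery_year_rates()`, `gene_spectrum()`,
`reported_variant_stats()` and `retrospective_af_summary()` exactly as a
real cohort would.

# Problem sizes and runtime

The test suite uses toy transcripts of 30–80 codons, 1000-variant oracle
sweeps, and one shared simulated cohort of 200 patients with definitive
evidence — sizes chosen to exercise every rule path while keeping the
default run in minutes. The acceptance script simulates its own
200-patient cohort from the caller's seed. Larger cohorts scale linearly
in patients.

# Known limitations

* One transcript per gene; no multi-transcript consequence sets, no NMD
  prediction, no HGVS validation of protein strings.
* No digenic/polygenic or mitochondrial inheritance models (none were
  observed in the source cohort); the engine flags multi-gene findings
  for MDT instead.
* Frequency resources are abstracted to generic tables; no live
  database queries or genome-build liftover.
* The in-house recurrence rule is applied at triage time; whether the
  source service applied it before or after confirmation is not
  documented.
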