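---
title: "Triage of cardiac channelopathy variants at cohort scale: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage of cardiac channelopathy variants at cohort scale: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Inherited cardiac ion channelopathies (Long QT, Brugada, CPVT, Short QT)
are individually rare, frequently actionable, and strongly
population-dependent in their variant spectrum. Screening a population
cohort against a channelopathy gene panel asks a chain of questions: which
variants are rare enough to be candidate disease alleles, which are
plausibly damaging, which survive curated ACMG/AMP evidence combination as
pathogenic or likely pathogenic, how their allele frequencies compare with
global reference datasets, and what fraction of the cohort carries at
least one qualifying genotype (the *genotypic prevalence* — a statement
about genotypes, never about diagnoses).

`channelscan` implements that chain as composable, individually tested
steps, plus a synthetic-cohort generator that produces inputs with known
ground truth at every step, so the whole pipeline can be validated end to
end without any external download.

## Pipeline model

Two branches run independently over the annotated cohort variants and are
merged by variant key (the pLoF branch wins on overlap, so a truncating
variant is never double-counted):

1. **Nonsynonymous cascade** (`run_cascade()`): rare → exonic → missense
   SNV → predicted deleterious → not ClinVar-benign. Each stage is a pure
   subset operation; stages are idempotent, the cascade is monotone, and a
   funnel report records per-stage counts and dropped keys.
2. **pLoF branch** (`collect_plof()`): stopgain / frameshift /
   splice-site calling against transcript models, graded high or low
   confidence; only high-confidence calls in panel genes continue.

Merged survivors receive ACMG/AMP attributes (`assign_attributes()`),
are combined into a five-class call with a subclass tier
(`acmg_combine()`), flagged for population uniqueness, compared against
reference allele frequencies by Fisher's exact test, and fed into carrier
counting and prevalence estimation.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `maf_threshold` | 0.05 | folded minor-allele-frequency cut-off, strict `<` |
| `reference_datasets` | 1000g, gnomAD, ESP6500 ("all" columns) | datasets consulted by the rarity filter |
| `cadd_cutoff` | 15 | CADD phred; deleterious strictly above |
| SIFT / PolyPhen deleterious calls | D / D,P | one affirmative tool suffices |
| `pm2_af_max` | 1e-4 | below this (or absent) in every reference dataset ⇒ PM2 |
| `insilico_k` | 2 | tools that must agree for PP3/BP4, capped at availability |
| `splice_window` | 2 bp | how far into the intron still counts as splice-disrupting |
| `alpha` | 0.05 | significance level for AF comparisons (no multiplicity correction by default; raw p-values are reported and a Bonferroni adjustment can be applied downstream) |

Rarity-filter semantics that deserve emphasis:

* **MAF is folded**: `min(af, 1 − af)` is compared to the threshold, so a
  0.96-frequency ALT allele is rare (its minor allele is at 0.04). "MAF"
  names the minor allele; comparing the raw ALT frequency would silently
  misclassify ref/alt-swapped sites.
* **Absence is rarity**: a variant with no frequency in any reference
  dataset passes. Unobserved variants are the rarest of all, and treating
  absence as failure would delete exactly the population-unique variants
  the analysis is after.
* **Rarity is demanded in every dataset where the variant is observed**,
  not just one: a variant common in any major population is not a rare
  disease-allele candidate. Which gnomAD column (exome/genome, global or
  subpopulation) enters the filter is configurable, since reasonable
  pipelines differ here.

## The ACMG/AMP engine

Attribute assignment is deterministic given the annotations, the pLoF
call, the gene-panel entry and a curated-evidence container: PVS1
(high-confidence LoF in a gene with an established LoF mechanism), PS3/BS3
(curated functional studies, citation required for a damaging assertion),
PM1 (curated hotspot intervals), PM2 (absent/ultra-rare everywhere), PM5,
PP1, PP2 (missense in a missense-constrained gene), PP3/BP4 (in-silico
consensus), PP5/BP6 (reputable source; a ClinVar pathogenic/benign
significance stands in when no curated value exists), BP1 (missense in a
truncating-mechanism gene). Codes with no shipped assigner (PS1, PS2,
PS4, PM3, PM4, PM6, PP4, BS1, BS2, BS4, remaining BP codes) are accepted
by the combiner and can be injected per variant through curated
`add_codes`/`remove_codes` overrides — curator judgment is part of the
ACMG/AMP framework and cannot be fully mechanized, so the container makes
every per-variant decision explicit and reviewable.

`acmg_combine()` applies the combining sub-rules in a fixed first-match
order and reports which sub-rule fired as the tier:

* Pathogenic: Ia (PVS1 + ≥1 PS), Ib (PVS1 + ≥2 PM), **Id (PVS1 + ≥2 PP),
  Ic (PVS1 + 1 PM + 1 PP)** — Id is deliberately evaluated before Ic.
  With PVS1 + PM2 + PP3 the call is Ic, but adding one more supporting
  code (PVS1 + PM2 + PP3 + PP5) must yield Id; evaluating Ic first would
  make Id unreachable for any set containing a moderate code. Then II
  (≥2 PS), IIIa (PS + ≥3 PM), IIIb (PS + 2 PM + ≥2 PP), IIIc
  (PS + 1 PM + ≥4 PP).
* Likely pathogenic: I (PVS1 + 1 PM), II (1 PS + 1–2 PM), III
  (1 PS + ≥2 PP), IV (≥3 PM), V (2 PM + ≥2 PP), VI (1 PM + ≥4 PP). The
  order puts II before III, so one strong plus one moderate plus many
  supporting codes is tier II — the behaviour observed in curated
  classification tables for sets like PS3 PM1 PP2 PP3.
* Benign: BA1 stand-alone (in both modes), ≥2 BS; Likely benign:
  1 BS + 1 BP or ≥2 BP; otherwise VUS.

Two conflict modes exist because practice and guideline text disagree. In
the guideline's strict reading, any benign code alongside a
pathogenic-side match means "conflicting ⇒ VUS". Curated tables, however,
routinely report sets like `PM1 PM2 PP2 PP3 BS3` as Likely Pathogenic (V).
The default `table_faithful` mode therefore records benign codes in the
rule trace without letting them veto; `strict` mode is available for
guideline purists. The reporting bands collapse tiers into
`pathogenic` / `lp_high` (LP I–III, functional-evidence-backed) /
`lp_low` (LP IV–VI, in-silico-dominated) / `other`.

An exhaustive-enumeration test compares the engine against an
independently written brute-force evaluator over every subset of
{PVS1, one PS, two PM, four PP} (256 sets), and the 42 published attribute
sets shipped as fixtures must reproduce their printed class *and* tier
exactly.

## The pLoF confidence heuristic

Full LOFTEE re-implementation is out of scope; what matters downstream is
only the HC/LC distinction that gates PVS1. The shipped heuristic demotes
a LoF call to low confidence when any of three rules fire: (a) truncation
in the last coding exon or within 50 bp upstream of the final exon–exon
junction (transcripts likely to escape nonsense-mediated decay), (b) a
splice variant outside the canonical ±1/±2 intronic dinucleotide, (c) a
non-canonical transcript. Stop-codon detection translates the affected
codon against the transcript's genomic sequence, strand-aware (a mirrored
minus-strand locus gives identical calls — this is property-tested);
frameshift is indel length mod 3 within the CDS; splice distance is
measured into the intron. The splice window is a parameter: at its
default of 2 only canonical positions are called at all, while widening it
(e.g. to 8) calls the extended splice region and grades the non-canonical
positions LC.

## Population comparison and uniqueness

`fisher_exact_two_sided()` implements the conventional two-sided exact
test by point-probability ordering: the p-value sums hypergeometric
probabilities of all tables with the observed margins whose probability
does not exceed the observed table's, with ties included at a relative
tolerance of 1e-7 (exact floating-point equality would make tied tables
platform-dependent). Tests compare it against a brute-force fixed-margin
enumeration and against `stats::fisher.test()`. References that publish
only a frequency (ESP-style) are reported AF-only with no p-value rather
than silently reconstructing counts.

A variant is *population-unique* when it is absent from every queried
resource: no allele frequency in any reference dataset, no dbSNP id, no
ClinVar entry, not reported in the literature. Uniqueness is monotone:
adding one observed resource can only revoke it.

## Prevalence conventions

Carriers are distinct individuals with zygosity ≥ 1 for any variant in
the selected bands; an individual carrying two variants counts once.
Heterozygotes in autosomal-recessive genes (e.g. CASQ2, TRDN) are flagged
`ar_het` — carriers, not expected to be affected — but remain in the
genotypic count, which is a statement about genotype frequency, not
disease risk. Two deliberate rendering conventions:

* ratios round: `1:N` with `N = round(cohort / carriers)`
  (1029/10 = 102.9 → `1:103`; 1029/19 = 54.2 → `1:54`);
* percentages truncate at one decimal (10/1029 = 0.972% → `0.9%`;
  19/1029 = 1.846% → `1.8%`).

This is the only pair of conventions under which the two renderings of
the same fractions are mutually consistent in the published style this
package reproduces; mixing round/round or truncate/truncate breaks one of
them.

## The synthetic cohort: what it does and does not emulate

`generator_spec()` defaults *are* the study conditions: 1029 diploid
samples; 440 nonsynonymous cascade survivors (the 36 published P/LP
attribute sets, 16 likely benign of which 13 sit in KCNH2/PKP2, 388 VUS
with 58.2% concentrated in AKAP9/ANK2/RYR2/SCN10A/SCN5A/TRPM4); 30
high-confidence pLoF calls (10 splice / 11 stopgain / 9 frameshift across
14 genes, 6 pathogenic) plus 3 planted low-confidence NMD-escape cases;
population-uniqueness fractions of 114/440 and 10/30; and exact disjoint
heterozygous carrier counts (1,1,1,2,2,2,3) and (1,1,1,1,1,2). Planted
failures (60 common, 50 intronic, 40 synonymous, 30 benign-predicted, 20
ClinVar-benign) give every cascade stage work to do; the counts are a
desk-scale choice sized so each stage's behaviour is exercised with a
strictly decreasing funnel, not an attempt to mimic genome-wide variant
counts, which depend on the full cohort callset. Genotypes are
Hardy–Weinberg binomial at a background cohort frequency
(5×10⁻⁴–5×10⁻³) except planted-carrier variants, which receive exact
counts — that keeps carrier arithmetic deterministic while the rest stays
stochastic. Reference datasets get large allele numbers (gnomAD-scale
2.5×10⁵) so rarity labels never sit on a sampling boundary.

Synthetic loci are one contig region per gene with three-exon,
300-codon transcripts, a few of them minus-strand to keep the pipeline
honest about orientation. What the generator does **not** emulate:
linkage and haplotype structure, sequencing and genotyping error,
annotation disagreement between tools, multi-transcript effect
heterogeneity, relatedness or population substructure. Passing the
truth-book tests therefore demonstrates that the pipeline's logic is
faithful to its contracts on clean inputs — not that real-cohort
performance figures would be identical.

The truth book records every variant's intended label at every stage, and
the signature test asserts *set equality* between each stage's survivors
and the truth labels — under any seed, since no tolerance is involved.

## Numerical and degenerate-input choices

* Strict inequalities exactly where stated: MAF `< 0.05`, CADD `> 15`
  (a CADD of exactly 15.0 does not pass), PM2 `< 1e-4`.
* Fisher tie tolerance 1e-7 (relative), degenerate margins give p = 1.
* Empty cohorts, empty evidence sets and zero-carrier bands all return
  well-formed empty/none results rather than errors; zero carriers yield
  an explicit `none_observed` prevalence.
* Multiallelic VCF records are decomposed into one row per ALT with
  per-allele zygosity; inputs are assumed normalized (no left-alignment
  is attempted, deliberately — the pipeline consumes already-annotated
  calls, and silently re-normalizing would desynchronize the annotation
  join key).
* All-`NA` annotation fields stay `NA`; no sentinel values, so "unknown"
  never collides with "0".

## Panel and fixture provenance

The shipped 36-gene panel is a documented synthetic reconstruction (see
the header of `inst/extdata/gene_panel.tsv`): 12 definitive genes, the
KCNE1/KCNE2 acquired-LQTS special case, and 22 limited/disputed genes,
with per-gene LoF-mechanism and missense-constraint flags chosen to be
consistent with every published classification row the package
reproduces. One genuine curation wrinkle is preserved rather than
smoothed away: KCNQ1 is a LoF-mechanism gene (its truncating variants take PVS1),
which would mechanically give its missense variants BP1, yet the
published missense row carries no BP1 — the shipped curated-evidence
table encodes that curator decision as an explicit per-variant `BP1`
removal. The 42 published evidence rows, the carrier counts and the
genome-scale funnel ship as checksummed fixtures; the funnel numbers are
reference-only, since they derive from a full cohort callset that cannot
be reconstructed at desk scale.

## Problem sizes and runtime

The default cohort is 1029 samples × ~670 variants; generation takes a
few seconds and a full pipeline run under ten on one CPU. The test suite
(including exhaustive rule-table and Fisher enumerations and two
full-size end-to-end runs) completes in about a minute. These sizes were
chosen so every stage is exercised with comfortable margins while the
suite stays quick enough to run on every change.

## Known limitations

* The HC/LC heuristic is a three-rule simplification; it reproduces the
  HC semantics the classifier needs, not LOFTEE's full flag set
  (ancestral alleles, end-truncation percentage, ...).
* Attribute assigners ship only for the codes the reproduced analysis
  used; everything else enters via curated overrides.
* X-linked dosage is not modelled: cohort allele number is `2n`
  (autosomal) throughout the panel, which is correct for these 36 genes.
* No liftover, no reference-FASTA validation, no structural or copy-number
  variants (explicitly out of scope for this analysis).
* Fisher comparisons are per-dataset and uncorrected by default; the raw
  p-value convention follows the reproduced analysis, and users testing
  many variants across many datasets should apply the provided
  Bonferroni-style correction or control FDR downstream.
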