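---
title: "Comparing somatic mutations before and after neoadjuvant chemotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing somatic mutations before and after neoadjuvant chemotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nactmut)
```

## The question and the model

High-grade serous ovarian carcinoma treated with neoadjuvant chemotherapy
(NACT) offers a rare natural experiment: the same tumor is sampled before
any systemic therapy and again at interval surgery after 3–5 platinum-based
cycles. If chemotherapy mostly prunes a clonally homogeneous tumor, the two
samples should share most of their somatic mutations. If the tumor is a
mixture of subclones and treatment is a selective bottleneck, the post
sample will be dominated by lineages that were minor (possibly undetectable)
before treatment, and the shared fraction will be small.

nactmut operationalizes this as presence/absence set algebra over each
sample's **non-synonymous exonic mutations** — exonic calls classified as
nonsynonymous SNV, stopgain or stoploss. Synonymous SNVs are tabulated but
excluded from comparisons; indels are retained and classified
(frameshift/non-frameshift) but excluded from the non-synonymous SNV
universe, with an opt-in switch to include them in position-based
comparisons only. No clonality deconvolution (CCF clustering) is attempted:
the design reports presence/absence plus raw allele fractions, which is the
strongest claim the underlying two-timepoint, depth-limited data support.

### Statistics computed

For each case with one pre-treatment sample $P$ and post-treatment samples
$Q_1, \dots, Q_m$:

* **Shared fractions** (`shared_fraction()`, `case_shared_fractions()`):
  the pre row reports $|P \cap \bigcup_j Q_j| / |P|$ ("shared with at least
  one post sample"); each post row reports $|Q_j \cap P| / |Q_j|$. The
  asymmetry is deliberate and matches how paired designs are reported; it
  makes multi-site cases directly comparable. Units are either normalized
  variant keys (position basis) or gene symbols (gene basis). A shared
  position always implies a shared gene, but not conversely, so the two
  bases can disagree in either count.
* **Gene status** (`gene_status()`): stable (pre and ≥ 1 post), emergent
  (post only), lost (pre only). These partition the case's gene universe,
  so $|stable| + |emergent|$ equals the post universe and
  $|stable| + |lost|$ the pre universe — both asserted in tests.
* **Recurrence and exclusivity** (`build_presence()`, `exclusivity()`):
  presence is aggregated to case level under a *stratum* (any timepoint,
  pre only, post only, stable-within-case, emergent-within-case) before any
  cross-case comparison. Resistant-exclusive means present in ≥ 2 resistant
  cases and no sensitive case; sensitive-exclusive means present in **all**
  sensitive cases and no resistant case. The "all" rule generalizes the
  two-sensitive-case design ("both") this package was built around;
  with larger sensitive arms it is intentionally strict.
* **Cross-stratum narrowing** (`emergent_exclusive()`): genes recurrently
  emergent in resistant cases are additionally filtered against the
  any-stratum matrix, because a gene can be treatment-emergent in resistant
  cases yet mutated pre-treatment in a sensitive case; exclusivity claims
  must survive the stronger check. Both the raw emergent-recurrent list and
  the narrowed list are reported rather than silently choosing one.
* **Multi-site partition** (`site_venn()`): for a case with ≥ 2 samples,
  every mutated gene is assigned to exactly one region of the k-sample Venn
  diagram; for the pre + two-post-sites configuration the regions get named
  categories (all samples; same-site pre+post; emergent in both posts;
  emergent site-specific).

### Clinical derivations

Platinum resistance is recurrence strictly within 6 months of first-line
platinum chemotherapy; recurrence at exactly 6.0 months is sensitive
("6 months and more"). CA-125 response is the percent decrease from the
pre-NACT level, half-up-rounded to integer percent; a rise is reported as a
negative decrease rather than clamped. Group means are reported to one
decimal. `vital_status` of alive-with-disease is carried as a censoring
flag only — no survival model is fit, because five cases cannot support
one.

## Rounding

All printed percentages use **round-half-up** (`round_half_up()`,
`round_pct()`), not base R's banker's rounding: tabular clinical reporting
rounds 67.5% to 68%, and the one observed tie in the reference tables is
consistent with half-up. An epsilon of `sqrt(.Machine$double.eps)` guards
against binary representation of exact halves. A zero denominator is an
error in `round_pct()` and a flagged `NA` (with warning) in
`shared_fraction()`, since a sample with no non-synonymous calls has no
defined shared fraction.

## Variant normalization and I/O

Calls are compared on normalized keys: alleles uppercased, shared ref/alt
suffix trimmed first, then the shared prefix with the position advanced
(left-trim last), always keeping one base of each allele. The operation is
idempotent and tested against a constructive oracle (padding a known SNV
core with random shared sequence). Multi-allelic VCF records are split one
call per alternate allele *before* normalization; multi-gene annotations
expand to one row per gene, flagged so position-based counts can
deduplicate. Position matching defaults to the full chrom:pos:ref:alt key;
a `position_only` switch relaxes to chrom:pos for compatibility with
reports that compare "by genomic position" without stating allele
awareness.

VCF parsing is delegated to Bioconductor's VariantAnnotation; the
annotation schema (ANNOVAR-style Func/Gene/ExonicFunc keys by default) is a
configurable dialect because annotated somatic VCFs do not share a fixed
INFO layout. Records violating the type invariants (exonic without a
functional class, alt reads exceeding depth, malformed alleles) go to a
reject table with reasons — counted, logged, never silently dropped.

## The synthetic cohort: what it states and what it does not

`synthetic_config()` defaults state the simulated world, chosen once to
match the study design this package mirrors, and are not tuned to test
outcomes:

| parameter | default | rationale |
|---|---|---|
| cohort | 3 resistant + 2 sensitive cases | study design |
| purity | 0.8 | macrodissection enriched to > 80% cellularity |
| exome depth | 100x (panel 5000x) | stated sequencing targets |
| detection | ≥ 3 alt reads and ≥ 5% VAF | typical somatic-caller floor |
| subclones | 3 per case, pre fractions 0.6/0.3/0.1 | minor pre-existing resistant clone |
| bottleneck | resistant post 0.05/0.15/0.80; sensitive 0.50/0.35/0.15 | resistant cases expand the minor clone |
| post-private clone | mean 20 mutations at CCF 0.35 | treatment-emergent lineage in every case |
| shared genes | 6 resistant / 3 sensitive | cross-case exclusivity structure |
| copy number | categorical on {1, 2, 3, 7, 9} | exercises loss/neutral/amplified thresholds |

Expected VAF is `purity * ccf / (purity * cn + (1 - purity) * 2)` for one
mutated copy; reads are Poisson-depth binomial draws. A mutation appears in
a sample's table iff a clone carrying it has non-zero CCF there; false
positive calls are not modeled. Ground truth is exact clone algebra, and
`truth_statistics()` recomputes every pipeline statistic from it by direct
set enumeration, sharing no comparison code with the pipeline — on
noiseless settings (thresholds 0) the two must agree field for field, and
the test suite asserts that they do.

What a green synthetic test does **not** establish: realism of mutation
spectra (no trinucleotide signatures), read-level artifacts (no FASTQ/BAM
simulation), caller-specific biases, or contamination. The simulator's
purpose is oracle testing and interface exercise, not benchmarking.

The dropout property is one-sided by design: shallow depth can only break
observed sharing (a mutation missed in either sample of a pair), so the
detected shared fraction should not systematically exceed the clone-algebra
truth; the suite checks this over 200 seeded replicates of a deliberately
shallow (25x) world.

## Design choices where the design was open

* **Resistant recurrence boundary.** Exactly 6.0 months classifies as
  sensitive, because resistance is defined strictly "within 6 months".
* **Sensitive-exclusivity quantifier.** "All sensitive cases" rather than
  "≥ 2", keeping the published two-case semantics exact while remaining
  defined for larger cohorts.
* **Copy-number loss cutoff.** Loss is reported without a published
  threshold; ≤ 1 copy against the diploid normal is the documented choice,
  inclusive, mirroring the inclusive ≥ 7 amplification rule.
* **Criterion 3 VAF arm.** "Increased percentage of variant reads" has no
  published magnitude; the default is +0.10 absolute VAF in a resistant
  case, configurable.
* **Platform field.** Study samples frequently ran on both exome and
  targeted platforms, so the shipped cohort fixture carries two logical
  availability columns alongside the single `platform` string the generic
  sample table uses.
* **Within-case timepoint placement in the recurrent-gene fixture.** The
  encoded gene-by-case pattern is exact at case level; the pre/post
  placement inside resistant cases is reconstructed to satisfy every
  published stratum statement simultaneously (pre-exclusive sets,
  post-exclusive sets, stable pairs, emergent narrowing). Tests assert all
  of those statements, so any placement inconsistent with the publication
  would fail.
* **Fig-style multi-site fixture.** Region sizes of the two-site case are
  derived exactly from the published overlap counts; gene symbols not
  printed for a region use clearly synthetic `FILLnn` placeholders, and the
  ovary/omentum split of the named emergent genes is an arbitrary but
  documented reconstruction.

## Known limitations

* Five cases cannot support enrichment statistics; none are computed.
  Exclusivity sets are descriptive classifications, not hypothesis tests.
* Gene-level presence/absence ignores allele identity across cases: two
  cases "sharing" a mutated gene may carry different variants. Position
  basis is stricter and reported alongside.
* The one case with no pre-treatment sample on a platform is flagged, not
  imputed; validation records for it carry `platform_missing`.
* The CA-125 percent-decrease fixture follows the clinical table where the
  running text disagrees with it (a 62% vs 66% discrepancy in the source
  material); the package does not attempt to resolve source-internal
  inconsistencies.
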