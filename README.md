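# nactmut

Somatic-mutation comparison between matched tumor samples taken **before and
after neoadjuvant chemotherapy (NACT)**, built for paired-sample studies of
high-grade serous ovarian carcinoma (HGSC) but applicable to any pre/post
treatment design with annotated somatic calls.

Patients treated with NACT before interval surgery recur faster and more
often with platinum-resistant disease than patients operated first. One
proposed mechanism is that chemotherapy acts as a selective bottleneck on a
heterogeneous tumor, enriching pre-existing resistant subclones. Testing
this from sequencing data reduces to a family of set comparisons over each
patient's *non-synonymous exonic* mutations (nonsynonymous SNV, stopgain or
stoploss):

- **Shared fraction.** For a sample with mutation set $M$ compared against
  samples with union $M'$, the shared fraction is $|M \cap M'| / |M|$,
  computed on two bases: genomic position (normalized chrom:pos:ref:alt
  keys) and gene symbol. Pre-treatment samples compare against the union of
  the case's post-treatment samples; each post sample compares against the
  pre sample.
- **Gene status within a case.** Genes mutated pre and post are *stable*,
  post-only *emergent*, pre-only *lost*; statuses partition the case's gene
  universe.
- **Cross-case exclusivity.** A gene is *resistant-exclusive* if mutated in
  ≥ 2 platinum-resistant cases (recurrence < 6 months) and in no
  platinum-sensitive case; *sensitive-exclusive* if mutated in all
  sensitive cases and no resistant case.
- **Panel selection and validation.** Five criteria (group exclusivity,
  resistant recurrence, post-only/VAF-increase in resistant cases, plus two
  external gene lists) rank candidates for a deep targeted panel; calls are
  validated across platforms by normalized key, and gene-level copy number
  is flagged (amplified ≥ 7 copies, loss ≤ 1, against a diploid normal).

A clonal-evolution **simulator** generates cohorts with truncal and
subclonal mutations, a chemotherapy bottleneck, purity/copy-number-aware
allele fractions and depth-limited binomial detection — together with exact
ground truth, so every pipeline statistic can be tested against independent
set algebra on noiseless runs.

## Worked example

The package ships the published five-case HGSC cohort (3 resistant, 2
sensitive) as plain-text fixtures: the clinical table, the per-sample
mutation counts with overlap numerators/denominators, and the
recurrent-gene presence pattern.

```r
library(nactmut)

coh <- hgsc_cohort()
cohort_summary(coh$cases)
#>   platinum_status n mean_time_to_recurrence mean_time_to_death_or_fu
#> 1       resistant 3                     4.2                     17.2
#> 2       sensitive 2                    20.2                     45.1

tab <- hgsc_mutation_counts()
round_pct(tab$shared_gene_n, tab$shared_gene_d)
#>  [1] 17  1 41 51 68 64 47 44 43 17 58
round_half_up(mean(round_pct(tab$shared_gene_n, tab$shared_gene_d)))
#> [1] 41

ex <- exclusivity(build_presence(hgsc_gene_presence(), "any"), hgsc_groups())
length(ex$resistant_exclusive)   # 16
length(ex$sensitive_exclusive)   # 5
ex$recurrent_any[1:4]
#>   MUC2  DDX11   TP53 TUBA3D
#>      5      4      4      4
```

Reading: resistant cases recurred after 4.2 months on average versus 20.2
for sensitive cases; on the gene basis an average of 41% (range 1–68%) of
each sample's mutated genes were mutated at the other timepoint too; 16
genes are mutated exclusively in > 1 resistant case and 5 exclusively in
both sensitive cases; MUC2 is mutated in all 5 cases.

Simulated cohorts run through the same pipeline:

```r
sim <- simulate_cohort(synthetic_config(), seed = 1)
v   <- detected_variants(sim)
case_shared_fractions(v, sim$manifest$samples)
gene_status_cohort(v, sim$manifest$samples)
truth_statistics(sim)    # independent ground-truth oracle
```

## Command line

```sh
Rscript inst/cli/nactmut.R simulate --out_dir sim --seed 7
Rscript inst/cli/nactmut.R all \
  --variants sim/variants.tsv --cases sim/cases.tsv \
  --samples sim/samples.tsv --copy_number sim/copy_number.tsv \
  --out_dir reports
```

Subcommands: `summarize`, `overlap`, `recurrence`, `sites`, `panel`,
`simulate`, `all`. Outputs are deterministic TSV reports
(`summary.tsv`, `overlap.tsv`, `genestatus.tsv`, `presence.tsv`,
`exclusivity.tsv`, `venn.tsv`, `panel.tsv`, `cnflags.tsv`, ...).

### Manifest format

`cases.tsv` columns: `case_id`, `stage`, `nact_cycles`, `total_cycles`,
`ca125_pre`, `ca125_pct_decrease`, `residual_disease` (`none`/`<=1cm`/`>1cm`),
`time_to_recurrence`, `time_to_death_or_fu`, `vital_status` (`DOD`/`AWD`),
`platinum_status` (`resistant`/`sensitive`).
`samples.tsv` columns: `sample_id`, `case_id`, `timepoint` (`pre`/`post`),
`site`, `platform`, `tumor_cellularity`.
Variant tables: `sample_id`, `chrom`, `pos` (1-based), `ref`, `alt`,
`gene`, `region_class`, `exonic_function`, `aa_change`, `alt_reads`,
`total_reads` (tab-separated; `.` for missing), or VCF 4.x with
ANNOVAR-style INFO keys (configurable via `default_dialect()`).

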