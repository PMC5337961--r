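# snprisk

Functional prioritization of regulatory risk SNPs and genetic-risk evaluation
for case/control cohorts.

Genome-wide association studies report *tag* SNPs, but the causal variant at a
locus is usually one of the many correlated neighbours, most of them
non-coding. `snprisk` implements, as reusable and tested R functions, the
complete chain from tag SNP to risk model:

1. **LD-proxy expansion** — two-locus r² from phased haplotypes by direct
   counting, or from unphased genotypes by an EM fit of the
   double-heterozygote ambiguity; proxy search within a configurable window
   (default 1 Mb around the tag, i.e. ±500 kb) at a configurable threshold
   (default r² ≥ 0.5).
2. **Multi-layer annotation** — coding exon / UTR / TSS-window (±2 kb)
   classification and histone-mark membership (H3K4me1, H3K4me3, H3K27ac for
   activation, H3K27me3 for repression), with mark co-occurrence matrices and
   cross-tissue intersections.
3. **Motif-disruption scoring** — JASPAR-style PFMs converted to PWMs; the
   match score of a width-*w* window is `S = Σᵢ p(baseᵢ, i)`, min–max scaled
   per matrix to [0, 1]; a SNP×motif pair is *matched* when the better
   allele's best placement (both strands, all windows covering the SNP)
   reaches 0.85, and *strong* when additionally
   `|score_ref − score_alt| ≥ 0.4`.
4. **Prioritization** — exon stratum: missense SNPs called damaging by ≥ 1 of
   four predictors (SIFT / PolyPhen2 / PROVEAN / FATHMM); TSS stratum: strong
   disruption at the promoter of a curated disease gene; histone stratum: the
   three-condition regulatory rule (mark overlap ∧ strong disruption ∧
   disrupted TF targets an expressed gene, FPKM > 1).
5. **Risk evaluation** — unweighted genotype score (sum of risk-allele
   counts, the risk allele being the one more frequent in cases), logistic
   association models with Wald OR/CI tables, likelihood-ratio comparison of
   nested models, stratified 10-fold cross-validated AUC (pooled out-of-fold
   Mann–Whitney statistic), and categorical/continuous net reclassification
   improvement (NRI) plus integrated discrimination improvement (IDI) with
   asymptotic standard errors.

A deterministic synthetic-data generator (`sim_config()`,
`simulate_haplotype_panel()`, `simulate_case_control()`,
`simulate_regulatory_landscape()`) produces LD-blocked haplotypes, cohorts
from an additive-logit disease model, and regulatory landscapes with planted
ground truth, so every stage is testable without external genomic resources.

## Worked example: reclassification after adding new biomarkers

The package ships the printed 4×4 reclassification count matrices of a
published type-2-diabetes study (1989 cases, 3000 controls) as plain-text
fixtures. Feeding them through the NRI engine:

```r
library(snprisk)
ext <- system.file("extdata", package = "snprisk")
cases    <- read_reclass_counts(file.path(ext, "table4_reclass_cases.csv"), "cases")
controls <- read_reclass_counts(file.path(ext, "table4_reclass_controls.csv"), "controls")
nri_categorical(cases, controls)
#> categorical NRI = 10.03% (95% CI 6.58% to 13.47%), P = 1.22e-08
#>   events:     up 497 / down 285 of 1989 -> +10.66%
#>   non-events: up 539 / down 520 of 3000 -> -0.63%
```

Cases net-moved up by 10.66 percentage points, controls slightly net-moved up
as well (−0.63 on the non-event component); the total categorical NRI is
10.03% with a clearly positive asymptotic CI — the added biomarkers chiefly
improve identification of cases. (Two-decimal truncation of the components,
as some reports print, gives 10.65 − 0.63 = 10.02; the object's `$report`
carries both renderings.)

The exon stratum's damaging-missense rule on the packaged 17-row
predictor-call table:

```r
flag_damaging_missense(read_predictor_calls(
  file.path(ext, "table1_missense_calls.tsv")))
#> [1] "rs2228603"  "rs58542926" "rs17240268" "rs13266634" "rs1260326"  "rs1051334"
```

Six SNPs are called damaging by at least one predictor.

## Package layout

| Area | Functions |
|---|---|
| I/O | `read_genotype_matrix`, `read_intervals`, `read_pwm_set`, `read_expression`, `read_tf_targets`, `read_predictor_calls`, `read_fasta`, `write_vcf`, … |
| LD | `haplotype_freqs_phased`, `haplotype_freqs_em`, `find_proxies` |
| Annotation | `build_tss_windows`, `classify_region`, `mark_cooccurrence`, `tissue_intersection` |
| Motifs | `scaled_pwm_score`, `score_allele_disruption`, `scan_motif_disruptions`, `filter_strong` |
| Prioritization | `flag_damaging_missense`, `expressed_genes`, `prioritize_regulatory`, `prioritize_tss` |
| Risk model | `assign_risk_alleles`, `genotype_score`, `fit_logistic`, `lr_test`, `cv_auc`, `score_separation_test` |
| Reclassification | `build_reclass_tables`, `nri_categorical`, `nri_continuous`, `idi` |
| Synthetic data | `sim_config`, `simulate_haplotype_panel`, `simulate_case_control`, `simulate_regulatory_landscape` |

See `vignettes/regulatory-snp-prioritization.Rmd` for the methods account:
model assumptions, parameter defaults and their rationale, what the synthetic
generators do and do not emulate, and known limitations.
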