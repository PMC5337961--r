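---
title: "Prioritizing regulatory risk SNPs and evaluating genetic risk: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing regulatory risk SNPs and evaluating genetic risk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snprisk)
```

# The problem

A GWAS tag SNP marks a risk locus, but the association signal is shared by
every variant in strong linkage disequilibrium with it, and the functional
variant is usually one of these non-coding neighbours. `snprisk` implements a
pipeline that (i) expands tag SNPs to LD proxies, (ii) sorts the proxies into
coding-exon, promoter (TSS) and distal-regulatory (histone-mark) strata,
(iii) asks which of them plausibly change protein function or transcription
factor (TF) binding, and (iv) measures whether the prioritized set actually
improves a genetic risk model in a case/control cohort. This vignette
documents the models, the tunable parameters, the numerical choices, and what
the synthetic generators can and cannot tell you about real data.

# Linkage disequilibrium

For two biallelic loci with haplotype frequency $p_{AB}$ and allele
frequencies $p_A$, $p_B$,

$$D = p_{AB} - p_A p_B, \qquad
  r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)}.$$

`haplotype_freqs_phased()` counts haplotypes directly. For unphased
genotypes, `haplotype_freqs_em()` runs the classical EM over the
double-heterozygote phase ambiguity: allele frequencies stay at their sample
values, so the only free parameter is $p_{AB}$, and the tests verify the EM
optimum against a brute-force likelihood grid over $p_{AB}$. Defaults:
tolerance `1e-8` on the maximum haplotype-frequency change, 1000 iterations,
initialization at linkage equilibrium — deterministic and, for this
one-parameter likelihood, effectively exact. A monomorphic locus makes $r^2$
undefined; we return a flagged result rather than a silent zero, and the
proxy scan skips such SNPs with a logged count.

`find_proxies()` reads "a window of $W$ bp around the tag" as $\pm W/2$
(default $W = 10^6$): "around" most naturally denotes total width. The
r² threshold is inclusive ($\ge 0.5$ by default); both are arguments.

# Region annotation

Coordinates follow the two field conventions and convert only at the I/O
boundary: variants are 1-based (VCF), intervals 0-based half-open (BED). A
SNP at 1-based $p$ overlaps $[s, e)$ iff $s \le p-1 < e$ — the tests probe
all four boundary positions of random intervals.

TSS windows span $\pm$`flank_bp` (default 2000) around the start site in
closed 1-based coordinates and are strand-agnostic, because proximal
regulatory elements occur on both sides of a start site; strand is kept for
reporting only. Windows are truncated at position 1 with a message. When a
position falls in both a coding-exon and a UTR interval, coding wins and the
conflict is logged — coding consequence dominates interpretation.

Histone-mark co-occurrence (`mark_cooccurrence()`) counts each SNP once per
mark pair regardless of how many intervals cover it; the matrix is symmetric
with per-mark counts on the diagonal, and off-diagonal entries can never
exceed either diagonal. For cross-tissue confidence, a SNP counts as
"overlapped" in a tissue when it lies in at least `min_marks` (default 2)
distinct marks there, and `tissue_intersection()` keeps SNPs overlapped in
both tissues.

# Motif disruption

JASPAR-style counts convert to column probabilities with an equal-background
pseudocount $s$ (default 1): $p = (c + 0.25s)/(N + s)$. The match score of a
width-$w$ sequence is the sum of per-position probabilities, min–max scaled
to $[0,1]$ using the attainable bounds (column minima/maxima); 1 is a
consensus match, 0 an anti-consensus. This scaled sum-of-probabilities score
is bounded, cheap, and makes a single match threshold meaningful across
matrices of different widths and information contents; a log-odds variant was
considered and rejected as the default because its scale varies by matrix,
which would make the fixed 0.85 match threshold incoherent.

`score_allele_disruption()` scans every $w$-window covering the SNP on both
strands, scores the window with the reference and with the alternate allele,
and takes the placement maximizing the better allele's score (ties: smaller
SNP offset, then plus strand). The pair is *matched* when that maximum
reaches `match_thresh` (default 0.85, applied to the best allele) and
*strong* when additionally $|\mathrm{score}_{ref} - \mathrm{score}_{alt}|$
reaches `effect_thresh`. The 0.4 default for `effect_thresh` is a package
default chosen to demand a substantial fraction of the attainable score
range; it is configurable and should be reported alongside results. Contexts
with at least $w-1$ bases per flank expose all placements; shorter flanks
restrict the scan, and a context with no complete window is an error.
Ambiguous bases (N) are rejected — the caller must supply resolved sequence.

# Prioritization rules

*Exon stratum*: a missense SNP is flagged when at least one of the four
predictor calls (SIFT, PolyPhen2, PROVEAN, FATHMM vocabularies, normalized
case-insensitively) is `possibly_damaging`, `probably_damaging` or
`damaging`; `NA` never counts. *TSS stratum*: a TSS-window SNP is kept when
it strongly disrupts a motif and its TSS gene is on a curated disease-gene
list (a documented input; `t2d_gene_list()` ships a published
type-2-diabetes list as default). The gene-set enrichment that produced such
lists depends on a remote knowledge base and is out of scope. *Histone
stratum*: the three-condition rule — (1) the SNP lies in a histone-mark
interval and matches at least one motif, (2) at least one match survives the
strong filter, (3) at least one strongly disrupted TF has a target gene above
the expression floor (FPKM strictly greater than `fpkm_min`, default 1).
Condition 3 accepts a target expressed in *either* tissue by default (the
caller controls the expressed set, so a both-tissues policy is one
`intersect()` away); requiring both tissues would make the rule hostage to
coverage differences between RNA-seq libraries. Every retained SNP carries a
per-condition audit flag and the motifs/genes that satisfied condition 3.

Raising `fpkm_min`, `match_thresh` or `effect_thresh` can only shrink the
prioritized set; the tests check this monotonicity.

# Risk model

The genotype score is the unweighted sum of risk-allele counts; the risk
allele is the one more frequent in cases than in controls, with exact ties
flagged and excluded. Unweighted scoring matches the common practice of
summing risk alleles without effect-size weights (a log-OR-weighted variant
would require externally estimated weights and is deliberately not the
default). Missing genotypes are imputed as twice the control risk-allele
frequency — mean imputation keeps scores comparable across samples with
different missingness; a drop-and-rescale policy is available behind
`missing_policy`.

Association models are maximum-likelihood logistic fits (IRLS, tolerance
`1e-10`) with Wald ORs, 95% CIs and p-values; on a single binary predictor
the fitted OR equals the 2×2 cross-product ratio to $10^{-6}$ relative error
(tested on random tables). Nested models are compared by the likelihood-ratio
chi-square. Discrimination uses stratified $k$-fold cross-validation
(default $k = 10$) with a mandatory fold seed; out-of-fold probabilities are
pooled and the AUC is the tie-corrected Mann–Whitney statistic — one AUC
"through the overall results", not a per-fold average, so the estimate is
well-defined even when folds are small.

# Reclassification

Risk categories are left-closed, right-open on predicted probability with
default boundaries $\{0.2, 0.4, 0.6\}$ (a probability exactly at a boundary
falls in the upper category, matching the conventional
"<20%, 20 to <40%, 40 to <60%, ≥60%" labels). The categorical NRI is

$$\mathrm{NRI} = \frac{up_e - down_e}{n_e} + \frac{down_{ne} - up_{ne}}{n_{ne}},$$

with the standard asymptotic variance
$\sum_g [(p_{up,g} + p_{down,g}) - (p_{up,g} - p_{down,g})^2]/n_g$, a
symmetric 95% CI and a two-sided normal p-value. The continuous NRI counts
any probability increase as up and any decrease as down (ties neither), and
the IDI is the case/control difference in mean probability change with a
two-sample SE. All arithmetic is in proportions; percent rendering happens at
report time. Because two-decimal *rounding* and two-decimal *truncation* of
the components produce slightly different printed totals (e.g. 10.03 vs
10.02 when the event component is 10.6586…%), the result object's `$report`
carries both renderings; the unrounded proportions are authoritative.

The categorical NRI computed from probabilities and from pre-tabulated count
matrices agree exactly (tested on random cohorts), so published count tables
can be re-analysed directly via `read_reclass_counts()`.

# Synthetic data: what it emulates

`simulate_haplotype_panel()` builds LD by block copying: within a block every
haplotype copies a biallelic founder and each site mutates with probability
$\mu$; the founder-carrier probability is solved so the post-mutation allele
frequency hits its target. $\mu = 0$ gives $r^2 = 1$ within blocks; blocks
are independent. This exercises the r² machinery but is not coalescent
realism: no recombination gradient, no allele-frequency spectrum, no
population structure.

`simulate_case_control()` assigns disease by an additive-logit model,
$\Pr(\text{case}) = \mathrm{logit}^{-1}(\alpha + \sum_s \log(\mathrm{OR}_s)
g_s)$, and fills the case/control quotas by rejection sampling (cap $10^7$
draws) — exact retrospective sampling at this scale without retrospective
likelihood formulas. Dominance and interaction effects are out of scope. The
default cohort size (1989 cases, 3000 controls) mirrors the study scale the
package's worked examples come from.

`simulate_regulatory_landscape()` plants ground truth for the
three-condition rule. Planted motifs have two high-information anchor
columns (SNP column consensus `A`; a second anchor two columns right, `C`
for TFs with expressed targets, `G` for decoy TFs) over a near-uniform
background. The geometry is chosen so that, deterministically: the planted
reference context scores 1.0 (matched) and the alternate allele loses the
anchor-1 range (strong); a motif of one TF class cannot reach the match
threshold on a site planted for the other class (the second anchor
mismatches); and decoy SNPs with `C/G` alleles can never sit on an anchor
with a consensus base on either strand, so their best placements are matched
at most weakly. Consequently the prioritizer's exact recovery of the planted
set is a property of the construction, not a statistical accident — which is
precisely what makes it a sharp correctness test and a weak realism test:
real motif hits are graded, not engineered.

Expression tables draw a configured fraction of free genes above the FPKM
floor; mark intervals are scattered with a configured probability of
co-locating with the first mark's intervals, which controls pairwise overlap
without solving a general 4-set intersection geometry.

Every generator seeds the RNG from `cfg$seed` plus a fixed per-stage offset
and restores the caller's RNG state: outputs are pure functions of the
configuration, and the panel's VCF emission is byte-identical across runs.

# Problem sizes and numerical choices

The test suite and the acceptance script use cohorts of 2000 cases / 3000
controls for the risk-model properties (Wald-CI coverage of a true OR of 3
over 50–100 replicates; null-cohort CV-AUC within 0.03 of 0.5; AUC growth
over SNP sets of 5/20/50 at per-SNP OR 1.15), panels of 2000–10 000
haplotypes for frequency calibration, and 20 random landscapes for planted
recovery — sizes at which the binomial noise of each check is an order of
magnitude below its tolerance. EM convergence is `1e-8`; the grid oracle
refines to `1e-7` in $p_{AB}$; logistic convergence is `1e-10` on the
log-likelihood; a likelihood decrease beyond `1e-8` between nested fits is
treated as a fitting inconsistency and raised, not absorbed.

Note that the null-cohort CV AUC averages slightly above 0.5 (~0.52, not
0.50): the risk-allele directions are estimated on the same cohort that is
scored, as is standard for genotype scores, and this in-sample choice of
direction leaks a little optimism even though the logistic fits themselves
are cross-validated. The 0.03 tolerance accommodates this known, documented
bias; removing it would require a nested (double) cross-validation of the
risk-allele assignment.

# Known limitations

* The EM fit assumes Hardy–Weinberg random pairing of haplotypes; strong
  inbreeding or copy-number artefacts violate it.
* The scaled PWM score has no p-value calibration against a background
  model; the 0.85/0.4 thresholds are operating points, not significance
  levels.
* Risk-allele assignment ignores sampling error in allele-frequency
  differences; with few samples the assigned direction can be wrong, which
  attenuates the genotype score (documented bias, not corrected).
* Asymptotic NRI/IDI inference only; no bootstrap, no survival-time
  variants.
* No genome-build liftover, no remote resources: annotation inputs are
  supplied as files or generated synthetically.
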