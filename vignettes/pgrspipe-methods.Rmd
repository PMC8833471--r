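---
title: "Methods behind pgrspipe: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind pgrspipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgrspipe)
```

`pgrspipe` is built around a case-control design for Barrett's-esophagus
(BE) susceptibility in esophageal-atresia (EA) survivors: four genotyped
groups (EA/BE, EA-only, BE-only, controls) scored for risk-allele burden,
and paired expression experiments probing the transcriptional response to
acid exposure. This vignette explains each model, the parameters that
matter, the simulators' scope, and the numerical decisions taken where the
design was genuinely open.

## The additive polygenic risk score

The score is a plain weighted allele count over a curated panel of
literature risk SNPs:

$$\mathrm{PGRS}_s = \sum_j \ln(\mathrm{OR}_j)\, g_{sj},$$

with $g_{sj} \in \{0,1,2\}$ the risk-allele dosage and $\mathrm{OR}_j$ the
per-allele odds ratio. Assumptions: loci act additively on the log-odds
scale, independently (no LD weighting or clumping), with no covariate or
ancestry adjustment — appropriate for a small curated panel of lead/proxy
SNPs, not for genome-wide scores.

Two conventions deserve emphasis:

- **OR direction.** ORs are stored with respect to the declared risk
  allele and are *not* re-polarized: a "risk" allele with OR < 1 (a
  protective allele that the literature happens to index) contributes a
  negative weight. Flipping every locus's allele labels and inverting its
  OR shifts every score by the same constant, $-2\sum_j \ln \mathrm{OR}_j$,
  and therefore leaves all rank-based comparisons unchanged — a property
  the test suite checks to $10^{-12}$.
- **Missing dosages.** The default imputes $2f_j$ (twice the cohort-wide
  risk-allele frequency among non-missing samples), keeping scores
  comparable across samples with different missingness; omitting the locus
  or the sample are selectable alternatives. The number of imputed loci is
  recorded per sample.

In-sample per-SNP ORs come from allele-count 2×2 tables (two alleles per
diploid sample — the score itself is allele-count additive, so genotype
tables would be inconsistent). The point estimate uses the
Haldane–Anscombe +0.5 on all four cells when any cell is zero (flagged in
the output); the Fisher exact p is always computed on the raw counts.
Which groups serve as "cases" and "controls" for in-sample weighting is a
parameter (`estimate_insample_ors(gm, case_group, control_group)`), not a
baked-in choice.

## Group comparison

`compare_groups()` runs a Kruskal–Wallis omnibus test plus all pairwise
two-sided Mann–Whitney tests. Pairwise p-values are exact (full
enumeration) when both groups have at most 10 observations and the pooled
values are tie-free; otherwise the normal approximation with tie
correction is used, and the method is recorded per pair. With ties, even
two identical samples yield an approximate p slightly below 1 — the exact
route is deliberately reserved for tie-free data. Pairwise p-values are
unadjusted by default (raw pairwise reporting alongside the omnibus test
is the convention this pipeline follows); a Bonferroni option exists.

## The three-criterion differential-expression filter

Genes first pass an expression floor: mean RPKM across all samples
≥ 2 (inclusive). A gene is then called differentially expressed iff all
three hold:

1. larger group mean > 2 RPKM (strict inequality);
2. symmetric fold change ≥ 1.5, computed on untransformed RPKM means as
   larger/smaller mean — scale-free in direction; a zero smaller mean gives
   an infinite fold change (passing criterion 2, with a warning) rather
   than a pseudocount-distorted ratio;
3. Benjamini–Hochberg q < 0.05 across the tested genes.

The per-gene test is Welch's unequal-variance t on $\log_2(\mathrm{RPKM}+1)$
(a rank-sum alternative is available behind a flag). The filter is
threshold-driven rather than test-driven, so a robust, dependency-light
test suffices; no dispersion-sharing DE framework is used, and none is
intended — this is the stated filter, not a general DE method. Degenerate
zero-variance genes are resolved explicitly: identical in both groups →
p = 1; constant but different → p = 0. The fold-change scale (linear, not
log) and the use of gene length (not transcript length) in RPKM were open
choices; both defaults are the plainest reading and are parameterized
nowhere else.

PCA QC operates on gene-centered $\log_2(\mathrm{RPKM}+1)$ of floor-passing
genes; a sample is flagged when its distance to its condition centroid in
the first *k* components exceeds median + 3·MAD of within-condition
distances. Flags are reports: exclusion always requires an explicit list,
so no sample ever disappears silently.

## Enrichment: a transparent stand-in

Commercial pathway engines couple a proprietary knowledge base with
unpublished causal analytics. `pgrspipe` deliberately replaces that engine
with fully transparent primitives over user-supplied GMT sets: the
upper-tail hypergeometric probability of the observed overlap, and a
directional score $z = (n_\mathrm{up} - n_\mathrm{down})/\sqrt{n}$ over a
set's differential genes ($z$ undefined at zero overlap, mirroring N/A
entries in knowledge-base reports; such sets are evaluated in p-only
mode). The significance convention — p < 0.05 **and** |z| ≥ 2 — and the
pathway-by-experiment overlap-table shape are preserved, so downstream
decision structure is comparable, but numerical z values are **not**
expected to match any proprietary tool's output. −log p is reported base
10. No multiple-testing correction is applied across gene sets by default
(raw p < 0.05 is the convention mirrored here); BH across sets is a flag.

## What the simulators emulate — and what they do not

`simulate_genotypes()` draws dosages as $\mathrm{Binomial}(2, f)$ under
Hardy–Weinberg, loci independent, then masks genotypes at a missingness
rate (default 1%). Defaults are the study-scale conditions: groups of
19/44/10/730, a 30-SNP panel with control frequencies spanning 0.2–0.5 and
published ORs spanning 1.1–1.6 — values typical of BE/EAC GWAS lead SNPs.
The EA/BE group's frequencies are obtained by applying each locus's
published OR to the control allele odds, which implies a mean score
elevation of about 1.4 natural-log units; the other groups sit at control
frequencies. Not emulated: linkage disequilibrium, population structure,
genotyping batch effects, or per-group frequency differences beyond the
case group. A passing pipeline on these data shows the statistics behave
correctly under the stated model — not that any real cohort satisfies it.

`simulate_counts()` draws negative-binomial counts with
$\mathrm{Var} = \mu + \phi\mu^2$ (`size = 1/φ`; φ → 0 approaches Poisson;
default φ = 0.1), per-gene baseline means log-normal around 100 counts,
and gene lengths uniform on 200–10,000 bases. Planted genes have their
mean in the first-named condition multiplied (or divided) by the planted
fold change; the pathway plan builds gene sets in which the enriched sets
draw half their members from planted genes. Defaults follow the paired
fibroblast design at its real scale — two conditions of three samples.
Not emulated: library-size variation beyond what NB sampling induces,
gene–gene correlation, batch or exposure-time effects, isoform structure.

The one-shot `run_demo()` uses six samples per expression arm instead of
three, and plants 30 of the exposure experiment's 100 effect genes in the
no-exposure experiment as "patient-intrinsic" responses. Both are demo
choices, made so every stage (the filter, the subtraction, the overlap)
produces non-trivial output in a single run; with three samples per arm
the per-gene Welch test at q < 0.05 has little power — an honest property
of threshold filters at that scale, and the generator's own defaults keep
that scale. No test or reported result depends on the demo's sizes.

## Numerical and policy choices

- Palindromic (A/T, C/G) SNPs are dropped during VCF harmonization by
  default — strand cannot be resolved without frequency heuristics on a
  small panel; `allow_ambiguous = TRUE` matches them by identity.
  Multiallelic records are skipped (`not_found`): the risk panel is
  strictly biallelic. Matching is by rsID first, position second (with a
  warning).
- Exact Mann–Whitney enumeration is capped at group sizes of 10 — beyond
  that, $\binom{n+m}{n}$ grows needlessly while the tie-corrected
  approximation is already accurate.
- TPM sums to $10^6$ per sample within $10^{-3}$; additivity and flip
  invariances are asserted to $10^{-12}$.
- All simulators are pure functions of their config (including the seed)
  and restore the caller's RNG state.

Test problem sizes are the package's own: calibration and power
simulations use 200 replicates at the study's group sizes (19/44/10/730),
OR-recovery uses 500 samples per group, null DE calibration uses 10,000
genes and the power check 2,000 genes with 50 planted eight-fold effects —
scales at which the checked properties are stable yet the full suite runs
in well under a minute.

## Known limitations

- The score model ignores LD, ancestry and covariates by design; it is not
  a substitute for a modern genome-wide PRS with clumping/thresholding.
- The DE filter's per-gene Welch test does not share dispersion across
  genes and is underpowered at n ≈ 3 per group; users with real RNA-seq at
  that scale should expect conservative calls.
- The enrichment stand-in inherits none of a curated knowledge base's
  content; its results depend entirely on the supplied GMT sets, and its
  directional z is a census statistic, not a causal activation score.
- Harmonization resolves strand only through reverse-complement matching;
  allele-frequency-based resolution of palindromic SNPs is intentionally
  out of scope.
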