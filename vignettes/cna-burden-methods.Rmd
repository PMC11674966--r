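---
title: "Arm-level CNA burden scoring: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arm-level CNA burden scoring: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnaburden)
```

## The analysis in one paragraph

Chromosomal instability leaves a cumulative record in a tumor genome: whole
chromosome arms gained or lost. This package measures that record per case —
the *altered-arm burden* — from gene-level discrete copy-number calls, splits
a cohort into CNA-high and CNA-low halves at the median burden, and asks
whether the expression of a designated gene (by default *STIL*, a centriole
duplication regulator whose overexpression drives centrosome amplification)
differs between the halves. Around this core sit an IHC H-score layer with
its clinicopathological cross-tabulations, the small-sample statistics the
comparisons need, and a synthetic-cohort generator that makes the whole
analysis reproducible offline.

## Arm status: the two-thirds rule

An arm's status in a case is decided by the majority of its informative
(non-missing) gene calls: deletion when the genes called −2 or −1 reach
two-thirds of the informative genes, amplified/gained when the +1/+2 genes
do, diploid otherwise, no-call when no gene is informative.

Numerical choices worth making explicit:

* **Inclusive boundary, exact arithmetic.** "Two-thirds or more" is decided
  as `3 * k >= 2 * n` on integers, never as `k/n >= 0.6666...`; 2/3 has no
  exact binary representation and a floating-point comparison can flip a
  boundary case (8 deleted of 12 genes *is* a deletion). The threshold is
  therefore an integer numerator/denominator pair.
* **Deletion before gain.** For any majority threshold above 1/2 the two
  criteria are provably exclusive (`k_del + k_amp <= n`), so the order is
  irrelevant; if a user forces a threshold ≤ 1/2 and both criteria hold, the
  arm is returned diploid with a warning rather than silently preferring one
  direction.
* **Missing calls shrink the denominator.** A missing gene call carries no
  evidence either way; counting it as diploid would bias arms toward
  diploid exactly where data are poorest.
* **No-call arms join neither the numerator nor the evaluable count**, and a
  case with more than half its arms no-call is excluded outright (the
  completeness rule below).

## Arm universe

The default universe is the 41 gene-bearing arms: 1p…22q excluding the
acrocentric short arms (13p, 14p, 15p, 21p, 22p), plus Xp and Xq; Y is
excluded. The acrocentric p-arms carry essentially no protein-coding genes
in GISTIC gene tables, so a gene-majority rule is vacuous there — including
them would add permanent no-call rows, not information. The universe is a
plain argument (`arm_universe()`), so the full 48-arm set is one call away.
Gene-to-arm assignment accepts cytoband strings (`"17p13.1"` → 17p), which
is what cBioPortal exports usually carry, or BED input (0-based half-open,
converted to the package's 1-based inclusive convention on read). The
bundled `synthetic_gene_locations.tsv` is a synthetic stand-in used by
examples and tests, not a real annotation; reproducing the analysis on real
TCGA matrices requires the user's own gene-location table, and arm gene
counts will differ from the stand-in's.

## Completeness and the median split

The source analysis excluded 3 of 515 LUAD and 3 of 501 LUSC cases for
"incomplete data" without stating a criterion. The package makes the rule
explicit and configurable: a case is excluded when more than 50% of the
universe arms are no-call, or (optionally) when it lacks a matched
expression value. Excluded cases take no part in the median computation.

The split itself is inclusive: burden **≥** median ⇒ CNA-high. With discrete
burden counts many cases can sit exactly at the median, so the two groups
are generally unequal — a cohort where every case has the same burden is
entirely CNA-high by this rule, which the tests pin down as intended
behavior rather than an edge-case accident.

## IHC scoring

The H-score is Σᵢ i·pctᵢ over intensity levels 0–3, giving 0–300. The
dichotomization cutoff is three times the median score of normal tissue
(150 when the normal median is 50), and the inequality is strict on the
high side: score ≤ cutoff is low, score > cutoff is high. Percentages must
sum to 100 within 10⁻⁶; renormalization of hand-entered 99/101 sums is
available but off by default so data-entry errors surface.

## Statistics

Fisher's exact test (two-sided, point-probability rule), Mann–Whitney U,
Wilcoxon signed-rank and the t-test are delegated to R's `stats` engines
behind the package's interface: exact enumeration for small tie-free
samples (Mann–Whitney at min(n) ≤ 8, signed-rank at n ≤ 12), otherwise the
normal approximation with tie and continuity corrections. The t-test
defaults to Welch's unequal-variance form — the variant behind the original
figure is unstated, and Welch is the robust default — with the pooled form
available by flag. The test suite cross-checks each test against
independent brute-force enumerations (all rank splits, all sign
assignments, full hypergeometric support). One calibration fact found
during that checking: at four observations per group the continuity-
corrected normal approximation can sit up to ≈ 0.031 from the exact
Mann–Whitney p, so the exact path matters at the smallest sizes; from five
per group the gap stays below 0.02.

No multiple-testing correction is applied anywhere: the per-factor Fisher
p-values are reported raw, matching the reporting style of the analysis
this package re-implements.

## The synthetic-cohort generator

`generate_cohort()` draws, per case: independent per-arm alteration
indicators (probability `p_arm_alter`), a deletion/gain direction
(`del_vs_amp`), gene calls that copy the arm's call with probability
`within_arm_coherence` (deep state −2/+2 with probability `deep_call_prob`,
else shallow) and are 0 otherwise, cell-level missingness, and
`n_incomplete_cases` cases whose entire call profile is blanked so they
fail the completeness rule. Expression is log-normal with a tumor log-fold
on every gene and an extra `burden_coupling_beta` log-increment per truly
altered arm on the designated gene only. IHC scores are log-normal around
tissue-specific medians, capped at 300, and realized exactly as two-level
intensity distributions. The clinical table links advanced pT/pN/stage to
the high-expression label through a logistic odds-ratio.

Default parameter choices (fixed once, with their reasoning):

| parameter | default | why |
|---|---|---|
| `n_tumor` / `n_normal` | 515 / 59 | LUAD cohort shape; LUSC (501/51) in `analysis/01_simulate.R` |
| `genes_per_arm` | 30 | enough that a 95%-coherent altered arm essentially always clears the two-thirds rule, small enough to stay fast |
| `p_arm_alter` | 0.35 | median burden ≈ 14 of 41 arms, a realistic NSCLC aneuploidy level with spread on both sides of the median |
| `within_arm_coherence` | 0.95 | arm events are coherent but GISTIC gene calls are not perfectly so |
| `deep_call_prob` | 0.3 | minority of deep (−2/+2) calls within an altered arm |
| `missing_rate` | 0.02 | low cell-level missingness typical of processed call matrices |
| `n_incomplete_cases` | 3 | the excluded-case count of the source cohorts |
| expression baseline / tumor fold | log(40), log(221/40) | designated-gene medians ≈ 40 (normal) and 221 (tumor) |
| `burden_coupling_beta` | 0.05 | per-arm log-increment giving ≳ 85% power at 500 cases |
| IHC medians | 50 (normal), 200 (tumor), sdlog 0.5 | normal median 50 ⇒ cutoff 150; tumor median ≈ 200 |
| `clinical_association_or` | 3 | stage–expression odds ratio of the magnitude seen in the published tables |

What the generator deliberately does **not** model: whole-genome doubling
(arm events are independent, so the bimodal burden distributions of doubled
tumors are absent), per-chromosome differences in alteration frequency,
negative-binomial count noise (expression is continuous log-normal, which
is adequate because only rank-based tests consume it), and any spatial or
clonal structure. Passing tests on generated cohorts therefore demonstrate
the pipeline's correctness and calibration, not that real TCGA data would
yield the same medians or group sizes.

## Verification at a glance

The suite checks, at fixed seeds: exact agreement of the burden pipeline
with a cell-level brute-force recount on 200 random small matrices;
≥ 95% recovery of the generator's true CNA labels at coherence 0.9 and 5%
missingness over 20 seeds (120 cases each); a null pipeline (coupling β = 0,
1000 cohorts of 100 cases on a 10-arm universe) rejecting at 5% ± 2% with a
uniform p-distribution; detection power ≥ 80% at the default coupling over
100 seeds of 500 cases; and reproduction of all eight published
clinicopathological Fisher p-values to four decimals from the printed
counts. Cohort sizes in these checks are scaled for runtime — the rule and
the calibration are size-free — and the full-size (515-case) configuration
is exercised by the exclusion-accounting check and the analysis scripts.

## Known limitations

* Tumor ploidy is ignored: a near-tetraploid genome scores arms relative to
  the GISTIC baseline, not to its own ploidy — inherited from the source
  analysis, which stated the same limitation.
* The bundled gene-location table is synthetic; real-data runs need a real
  annotation, and the per-arm gene counts (hence the two-thirds
  denominators) will shift with the annotation and genome build chosen.
* The median split is cohort-relative: labels are not comparable across
  cohorts with different burden distributions.
* Sex-chromosome handling (Xp/Xq in, Y out) is a default, not a finding;
  the original report does not say how "all chromosomes" treated X and Y.
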