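---
title: "Case-control rare-variant prioritization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-control rare-variant prioritization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avnrtwes)
```

## Scope

`avnrtwes` implements the statistical core of a case-control whole-exome
rare-variant prioritization study of atrioventricular nodal reentrant
tachycardia (AVNRT): qualification of deleterious rare variants at two
minor-allele-frequency (MAF) strata, gene-based carrier-collapsing burden
tests, single-variant allelic association with QC and inflation
diagnostics, hypergeometric pathway over-representation, a dual-network
protein-protein-interaction (PPI) gene ranking, and cross-cohort variant
overlap validation. Upstream sequence processing (alignment, variant
calling, annotation) is out of scope: the pipeline starts from annotated
variant tables and genotypes.

## Variant qualification

A variant qualifies for collapsing when its functional class is one of
*nonsense, missense, splice_site, frameshift, inframe_indel* and its
reference-panel allele frequencies fall below the stratum threshold.
Two nested strata are used, MAF < 0.001 and MAF < 0.01; the strict subset
relationship between them is asserted as an invariant.

Two decisions here deserve comment:

* **Missing panel frequencies count as rare.** A variant absent from every
  configured reference panel (ExAC-style, 1000-Genomes-style) is treated
  as AF 0. Ultra-rare variants are systematically absent from panels, so
  the alternative (dropping them) would discard exactly the variants the
  analysis is about. When several panels report the variant, *all* must be
  below the threshold.
* **Carrier = dosage ≥ 1; missing genotype = non-carrier.** Collapsing
  uses a binary carrier indicator per sample per gene. Treating a missing
  call as non-carrier biases carrier counts downward symmetrically in
  cases and controls; an alternative (dropping samples per gene) would
  change the margins per gene and complicate cross-gene comparison.

## The collapsing burden test

For gene $g$ at stratum $s$, samples are cross-classified as
carrier/non-carrier versus case/control:

$$\begin{array}{lcc} & \text{carrier} & \text{non-carrier}\\
\text{cases} & a & b\\ \text{controls} & c & d \end{array}$$

The reported effect size is the plain cross-product odds ratio
$\widehat{OR} = ad/bc$, with `NA` when $bc = 0$ (a zero cell makes the
ratio infinite or undefined) and 0 when $ad = 0$ — matching how such rows
are reported in the field's tables. No Haldane–Anscombe correction is
applied; the p-value, not the OR, carries the inference for sparse tables.

The p-value is an exact conditional test on the hypergeometric
distribution of $a$ given the margins. Two conventions are implemented:

* `two_sided_minlik` (default): the sum of probabilities of all tables no
  more likely than the observed one — the convention of
  `stats::fisher.test`.
* `greater`: the one-sided upper tail $P(X \ge a)$, appropriate when only
  carrier *enrichment* in cases is of interest.

Published AVNRT burden tables turn out to follow the one-sided convention
(verified by enumeration over the printed carrier counts), while
zero-control-carrier tables are the most extreme in their tail so both
conventions coincide there. The convention is an explicit argument
everywhere rather than a hidden default, because the two can differ by a
factor near 2 for balanced tables.

Implementation note: the test is computed by direct enumeration of the
hypergeometric support with a $1+10^{-7}$ relative guard on probability
ties. The test suite checks it against an independent log-binomial
enumeration oracle and against `stats::fisher.test` on random margins up
to 200.

## Calibration of an exact test: what passing tests mean

Exact conditional tests are **conservative by construction**: their null
rejection rate at level $\alpha$ is at most $\alpha$ and, for sparse
tables, far below it. Two consequences shaped the test suite:

* Null burden p-values are *not* uniform. Over a panel of rare genes
  (carrier probabilities around 1%), $P(p \le 0.05)$ is about 0.01–0.03,
  and a Kolmogorov–Smirnov test against the uniform rejects overwhelmingly
  no matter how well the code works. The suite therefore asserts the
  correct property — stochastic dominance over the uniform
  ($P(p \le t) \le t$ up to Monte-Carlo slack) — rather than uniformity.
* Even in the common-carrier regime (carrier probabilities 0.1–0.5 at the
  study's 82/100 margins) the exact size, computed by full enumeration of
  the binomial-carrier model, is ≈ 0.040 rather than 0.050. The
  calibration test therefore checks the empirical rejection rate against
  the *enumerated* size (99% Monte-Carlo interval over 600 genes) plus an
  upper bound at the nominal level: the test must never be
  anti-conservative.
* The same conservatism deflates the genomic-inflation factor: with exact
  allelic tests on null markers the median p-value sits near 0.56 and
  $\lambda_{GC} \approx 0.8$, the familiar deflation of Fisher-based GWAS
  scans. The diagnostics assert *no inflation* ($\lambda < 1.05$) and
  bounded deflation, and $\lambda = 1$ exactly on uniform quantiles.

## Single-variant scan

QC removes markers with genotype missingness > 0.1, sample-wide MAF
< 0.01, or an exact Hardy–Weinberg p below $10^{-4}$. HWE is computed on
the pooled cohort (one marker-wide filter, configurable to controls-only);
the exact conditional test enumerates heterozygote counts given the
allele counts. Allele counts for the association test come from dosage
sums with two alleles per called genotype, so missing calls shrink the
per-variant denominator — the standard frequency semantics of
case/control allelic tables. The allelic OR is the cross-product for the
tested allele; zero-frequency rows give OR 0 and zero-denominator cells
give `NA`.

## Pathway over-representation

Enrichment is the upper-tail hypergeometric test
$P(X \ge k)$ with population = background universe, successes = pathway
size within the background, draws = input genes within the background.
The *rich factor* is $k / |{\rm pathway} \cap {\rm background}|$. Choices:

* **Background defaults to the union of the loaded gene sets.** The web
  service used in the original analysis has an internal background that
  cannot be recovered; a supplied list can override the default. Because
  the background is not recoverable, published corrected p-values for the
  pathway tables are treated as non-reproducible and are not targets.
* **Correction defaults to Benjamini–Hochberg** and the method is recorded
  in the result; the published tables do not state their method.
* **Candidate extraction is configuration, not inference.** Which enriched
  pathways are "disease-relevant" is a domain judgment; it enters as a
  list of set-id tags, and the candidate gene list is the deduplicated
  union of the tagged pathways' overlap genes. On the bundled published
  pathway tables this union yields 35 symbols; the original study lists 36
  (one gene evidently came from a pathway outside the printed rows).

## Dual-network PPI ranking

Edges are undirected, canonically ordered, deduplicated and self-loop
free, with confidence scores in [0, 1]; edges strictly above 0.4 (medium
confidence) are retained. Each gene in a network construction is scored
by its number of distinct retained interactors and the sum of retained
edge scores. Two constructions are combined per gene as
$(t_1 + t_2)/2$ and $(n_1 + n_2)/2$, where an absent construction
contributes zero *but the divisor stays 2* — a rule forced by the
published rows where single-construction genes score exactly half their
single total. Ranking is by combined total, ties by combined nodes then
symbol, making the order fully deterministic. The published 29-row
ranking is reproduced to printing precision from the per-group values
(one row is 0.0025 off, an arithmetic slip in the source table; all
others agree within half an ulp of the printed mean).

## Synthetic cohorts: what they emulate and what they do not

The generator simulates the quantity the collapsing statistic consumes —
per-sample carrier status — rather than site-level haplotypes. Per gene,
the control carrier probability is
$p_0 = 1 - \prod_s (1 - f_s)^2$ over the gene's deleterious site
frequencies (or an explicit override for calibration studies), and the
case probability tilts $p_0$ on the carrier/non-carrier odds scale by the
planted odds ratio. Carriers receive one heterozygous deleterious site
(AF-weighted); non-deleterious and common sites get Hardy–Weinberg
genotypes independent of status. Defaults mirror the study design: 82
cases, 100 controls, a 40-gene panel with 2–8 rare sites each, a
rare-skewed AF spectrum $0.05\,\mathrm{Beta}(0.3, 12)$ on [0, 0.05]
(median cohort carrier probability near 1%, matching the mostly 0–5/100
control carrier counts of the published burden table), 2000 common null
markers, and panel AFs drawn independently of cohort genotypes with 10%
set missing to exercise the missing-AF rule. All randomness flows from
one integer seed; identical config + seed reproduces the bundle
byte-identically.

Not emulated: linkage disequilibrium and haplotype structure, population
stratification, relatedness, sequencing/batch artefacts, and
annotation error. Passing tests on synthetic data therefore demonstrate
the statistics and plumbing, not robustness to those real-data
complications — which the original study handled with external tools
upstream of this pipeline's inputs.

Problem sizes used in the checked experiments were chosen to keep each
property sharply testable: 600 genes for null calibration (common-carrier
regime, where discreteness is mild and the enumerated size is a tight
reference), 200 replicates for power and recovery (planted carrier OR 5
at control carrier rate 0.05 over a 40-gene panel — the scale of the
study's candidate panel), and 5000 markers for the scan diagnostics.

## External validation

Cross-cohort matching is keyed on gene symbol plus normalised HGVS
strings (whitespace stripped, unicode dashes unified), at the strongest
level available per pair: protein-exact, then cDNA-exact, then gene-only.
Coordinate-level matching is deliberately not attempted: external tables
report different transcripts (XM_ vs ENST accessions), so the
protein-level string is the strongest comparable claim. The phenotype-
category enrichment p-value reported for the biobank validation in the
original study has no stated method and is not implemented; the report
lists per-gene overlap counts instead.

## Known limitations

* The collapsing test is unweighted carrier collapsing (CAST-style); no
  variance-component or kernel alternatives, no covariate adjustment.
* The burden OR is undefined for zero-cell tables by design; downstream
  consumers must rank such genes by p-value, as the pipeline does.
* Enrichment ignores pathway topology and gene-set redundancy.
* HGVS normalisation is string-level; it does not re-map transcript
  coordinates, so equivalent variants described on different transcripts
  match only at gene level.
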