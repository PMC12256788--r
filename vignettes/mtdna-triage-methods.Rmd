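---
title: "Methods: phenotype-driven triage of mitochondrial DNA variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype-driven triage of mitochondrial DNA variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotriage)
```

## The problem

Mitochondrial DNA (mtDNA) diseases are routinely missed by exome- and
genome-sequencing pipelines tuned to the nuclear genome. Off-capture reads
do cover the 16.6 kb mitochondrial genome in most exomes, so a reanalysis
pipeline can call mtDNA variants at no extra sequencing cost — but the
calls are noisy (variable coverage, heteroplasmy, nuclear-embedded mtDNA
segments) and most of what survives is benign lineage polymorphism. The
package implements a two-sided triage:

* **genotype side** — sample-level QC, exclusion of haplogroup-defining
  markers, and a disease-association prioritization cascade;
* **phenotype side** — a semantic-similarity score between the patient's
  Human Phenotype Ontology (HPO) profile and a reference table of
  published mtDNA-disease proband profiles, calibrated into screening
  tiers by ROC analysis.

Everything is exercised on synthetic cohorts with known ground truth; the
package ships the generator as first-class, tested code.

## Genotype-side model

A sample enters the analysis when at least 50% of the mitochondrial genome
was assembled **and** mean chrM depth is at least 5x (both inclusive;
`apply_sample_qc()`). These thresholds are deliberately permissive: exome
mtDNA coverage varies over an order of magnitude across capture kits, and
true positives have been recovered from coverage as low as 7x.

A variant-sample pair is prioritized (`passes_prioritization()`) when

1. heteroplasmy >= 1% — **mandatory**, and at least one of
2. "confirmed" disease association in the MITOMAP-style annotation,
3. membership in the MitoPhen-style reference of published probands,
4. "reported" association with population allele frequency < 0.2%
   (strict inequality; a reported variant with missing frequency fails
   this clause and is logged).

The heteroplasmy clause is conjunctive with the disjunction of the other
three: a pure four-way disjunction would pass essentially every >= 1%
call, which is inconsistent with a funnel that reduces thousands of
samples to a few hundred candidate pairs. The first satisfied
disease-association clause is reported, in the order confirmed >
mitophen > reported_rare.

Haplogroup-defining variants of the *sample's own* haplogroup are excluded
as benign lineage polymorphisms. Assignment (`assign_haplogroup()`) is a
deliberately simple best-marker-fraction classifier: the haplogroup
maximizing the fraction of its defining markers present at heteroplasmy
>= 0.9, ties broken lexicographically. The 0.9 floor reflects that
lineage markers are essentially homoplasmic, and keeps low-level artifacts
from driving assignment. This is a stand-in for full phylogenetic
assignment (which belongs to the upstream caller); a pre-computed
haplogroup column in the QC table takes precedence when supplied.

Coordinates are rCRS (16,569 bp, 1-based). Variants are keyed as
(position, ref, alt); indels are left-aligned by suffix-then-prefix
trimming on VCF ingestion, multiallelic rows are split, and
control-region-spanning alleles are out of scope.

## Phenotype-side model

With an ontology term's **information content** defined from an
annotation corpus of profiles as

$$IC(t) = -\log \frac{freq(t)}{N},$$

where $freq(t)$ counts the corpus profiles containing $t$ or any
descendant of $t$, similarity between two terms is **Lin's measure**

$$sim(t_1, t_2) = \frac{2\,IC(\mathrm{MICA})}{IC(t_1) + IC(t_2)},$$

with the MICA the common ancestor (reflexively) of maximal IC. Profile
similarity is the symmetric best-match average, and a patient's score is
the maximum over reference profiles, with the best-matching reference
reported.

Numerical choices, each fixed once and exposed in configuration:

* **Log base** — natural log (nats). Lin's ratio is base-invariant, so
  the choice only affects reported IC values.
* **Zero-frequency smoothing** — terms absent from the corpus get
  probability $1/(N+1)$, keeping IC finite for rare reference terms
  without infinities leaking into scores. IC anti-monotonicity along
  edges is preserved.
* **0/0 Lin cases** return 0, never NaN (e.g. root against root), so the
  score is always in [0, 1].
* **Corpus** — the IC corpus is an explicit argument; the pipeline
  defaults to the reference-profile table, the one corpus always present.
  A cohort-wide corpus is a reasonable alternative (we measured it; it
  changes scores only slightly on the synthetic cohorts).
* **Aggregation** — symmetric best-match average at the profile level and
  max over references at the patient level. Max is the aggregation
  consistent with "similarity to the closest previously reported case";
  an asymmetric (patient-to-reference) direction and mean aggregation are
  switchable in `pipeline_config()`.
* **Reduction** — patient term sets are scored *without* non-redundant
  reduction (removing redundant ancestors changes best-match means),
  while the reported per-person term count and mean IC use the reduced
  set, where redundancy would inflate both.
* **Ties** — the best-matching reference on exact score ties is the first
  in table order, deterministically.
* Obsolete terms are mapped through `replaced_by` when available, else
  dropped with a warning; profiles empty after validation are an error in
  the scoring functions, and the pipeline retains such patients with
  missing scores rather than dropping them — sparse phenotype data is
  exactly the failure mode that should stay visible in the report.

## Threshold calibration

`roc()` evaluates the rule score >= threshold => mtDNA over candidate
thresholds at midpoints between adjacent distinct scores (plus
$\pm\infty$ sentinels). The AUC is the area under the empirical step
curve, identical to the Mann–Whitney probability that a random positive
outscores a random negative with ties counted 1/2; the 95% CI uses the
DeLong structural-component variance (a percentile bootstrap is available
as a cross-check). Youden's $J = sens + spec - 1$ picks the operating
threshold; ties break toward the *smallest* threshold, i.e. maximal
sensitivity, because the score is used as a screening filter where a
missed mtDNA case is the costly error.

Scores partition into tiers at fixed boundaries: low < 0.3,
0.3 <= medium < 0.5, high >= 0.5. The default action map sends high to
expert review, medium to an information request, low to no action;
variants flagged `actionable` (LHON/SNHL-class homoplasmic alleles with
variable penetrance) escalate any tier to report-back, since they are
reportable findings regardless of phenotype fit.

Group differences (mtDNA vs nuclear-mitochondrial vs nuclear-other) use
the Kruskal–Wallis test (via `stats::kruskal.test()`, tie-corrected)
followed by Dunn's pairwise z tests on pooled mid-ranks with Bonferroni
correction; in the two-group case Dunn's $z^2$ equals the tie-corrected
$H$, which the tests verify numerically.

## What the synthetic cohort emulates

`generate_cohort()` produces, deterministically per seed:

* a fixture ontology of ~60 terms shaped like the mitochondrial-disease
  corner of a phenotype ontology (multi-parent diamonds included), plus a
  random-DAG generator for property tests;
* reference profiles drawn depth-biased (probability proportional to
  term depth), emulating how curated disease annotations skew specific;
* mtDNA-group patients as noisy copies of a random reference: each term
  dropped with probability 0.3 (**dropout**), surviving terms replaced by
  a strict non-root ancestor with probability 0.2 (**imprecision** — the
  clinician recording a less specific term), and 2 unrelated uniform
  terms appended (**noise**). If dropout removes everything, one
  reference term is retained, since scoring is undefined on empty
  profiles;
* one spiked causal variant per mtDNA case (disease-associated in the
  annotation table, heteroplasmy uniform on 1–100%), haplogroup markers
  at near-homoplasmy for every sample, and benign background variants;
* nuclear-group patients with fresh random term sets and background
  variants only;
* ~10% of samples failing QC, matching the fraction of real datasets
  that fail mtDNA quality screening.

The default cohort sizes (47 mtDNA vs 122 + 1,338 nuclear) mirror a
realistic phenotype test cohort. The noise parameters are our
construction — no quantitative annotation-noise model exists to copy —
and are exposed in `cohort_spec()`.

What the generator does **not** emulate: sequencing reads, NUMT
contamination, capture-kit coverage structure, real database content
(annotation and marker tables are synthetic stand-ins of identical
schema), correlated phenotypes between nuclear-mitochondrial patients and
mtDNA references, or real HPO scale. The last point matters for
interpreting tests: on a ~60-term ontology the reference profiles cover
most of the term space, so unrelated random profiles score ~0.5 by chance
overlap, and the synthetic AUC (~0.9) should be read as a property of
these study conditions, not a clinical performance claim. Notably the
same compression appears in the clinical data this design mirrors, where
the sensitive 0.3 screening threshold has specificity of only ~15%.

## Problem sizes in the test suite

The property tests run brute-force oracles (breadth-first ancestor
closure, full common-ancestor enumeration, full pairwise similarity
matrices, exhaustive threshold scans, rank-based AUC) on 200 random
ontologies of up to 30 terms, 500 random labeled score sets, and
DeLong-coverage simulations of 500 replicates at 50/500 — sizes at which
the oracles are exact and fast. The end-to-end recovery check uses 20
cohorts of 50 mtDNA-like vs 500 nuclear-like patients. These sizes are
the package's chosen trade-off between statistical resolution and a test
suite that runs in minutes.

## Known limitations

* Haplogroup assignment is marker-fraction only; fine lineage structure
  (sub-haplogroups sharing markers) is not modeled.
* No ACMG criterion automation and no significance testing for
  similarity scores; the score ranks candidates, it does not test them.
* The annotation join is exact on (position, ref, alt); complex alleles
  that normalize differently upstream will not join.
* OBO support is the is_a subset only (no OWL, no cross-ontology
  mappings); all other relationship types are ignored, which matches
  standard practice for HPO similarity but discards part-of structure.
* Patients lacking phenotype data are carried with missing scores; any
  downstream consumer must decide what to do with them, as the package
  deliberately does not.
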