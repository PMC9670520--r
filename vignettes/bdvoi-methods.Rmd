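---
title: "Methods: case-exclusive recurrent variant discovery and risk labeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-exclusive recurrent variant discovery and risk labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Birth-defect (BD) cohorts carry a substantially elevated pediatric
cancer risk, and the hypothesis behind this analysis is that some of
that risk is visible as germline variants recurrent in BD patients who
developed malignant tumors and absent from BD patients who did not.
`bdvoi` operationalizes that hypothesis as a set-theoretic filter over
a three-group cohort — BD+cancer probands (cases), BD-only probands
(disease controls), and healthy parents/siblings of probands (family
controls):

* **identity rule** — two calls are the same variant when they share
  contig, position, reference and alternative allele after parsimony
  normalization (trim shared trailing bases, then shared leading bases,
  advancing the position; at least one base retained per allele;
  multi-allelic records are split before normalization);
* **selection rule** — a variant of interest is carried by at least
  `min_cases` (default 3) *unrelated* cases — carriers are collapsed to
  one per `family_id` — and by zero BD-only probands and zero family
  controls.

Carrier status is dominance-coded (any alternative-allele dosage
counts as carriage) because the analysis counts variant occurrence per
individual, never zygosity. Missing genotypes count as non-carriers:
the exclusivity clause needs a definite 0/1 per sample, so users who
distrust low-quality sites should pre-filter them (a `pass_only`
toggle restricts to `FILTER == PASS`).

The family controls are what make the filter selective: inherited
background variation in a case is usually visible in a parent or
sibling, and one such carrier disqualifies the variant.

## Region strata, gene mapping and feature weights

Selected variants are classified against a user-supplied (or
simulated) gene model with precedence CODING > UTR > NCRNA > INTRONIC >
INTERGENIC, then grouped into the analysis' three strata: coding,
non-coding (UTR, ncRNA exon, intronic) and intergenic. The precedence
order is a package choice — the strata must be disjoint, and a
position inside both a CDS and, say, an overlapping ncRNA exon has to
land somewhere; coding-first mirrors the usual annotator convention.
Two further conventions: a position inside a gene span but in no
annotated feature is intronic, and intergenic positions take the
nearest gene span (both genes on an exact distance tie, as common
annotators do). Strand is stored but ignored — containment is
strand-symmetric. Internally all intervals are 0-based half-open;
VCF and GFF3 coordinates are converted at the I/O boundary.

Per stratum, the feature matrix is probands x genes, and the entry for
(sample, gene) counts the selected variants in that gene the sample
carries — the gene's mutation-load "weight". A variant mapped to k
genes contributes to all k columns (a `first_gene_only` toggle avoids
the double count; a `binarize` toggle reduces to presence/absence for
sensitivity analysis).

## Two-layer feature reduction

1. **Importance filter.** A random forest (impurity importance,
   `ranger`, 200 trees, single-threaded for reproducibility) is fit to
   (loads, labels); importances are rescaled to sum to 1 and genes
   below 1e-5 relative importance are dropped.
2. **Forward selection.** Greedy wrapper: starting empty, repeatedly
   add the gene maximizing stratified cross-validated balanced accuracy
   of a 100-tree forest (5 folds by default). The first pick — the best
   single gene — is always retained; afterwards the search stops once
   the best candidate has failed to improve the running best score for
   more than `patience` (default 1) consecutive rounds, and the
   best-scoring prefix is returned.

The scoring model for the wrapper is the same tree ensemble rather
than the final MLP: wrapper selection with the deployment model costs
an MLP fit per candidate per fold per round, and a tree scorer is the
standard default. Balanced accuracy is used because the discovery
labels are imbalanced (60/80 at default scale).

## Classifiers, tuning and the majority vote

Each stratum trains a multilayer perceptron (binary cross-entropy with
class weights inverse to class frequency, L2 penalty `alpha`,
full-batch Adam or momentum SGD, Glorot initialization). Tuning is
sequential model-based optimization: after an initial random design, a
Gaussian-process surrogate (RBF kernel on the unit-scaled encoding of
the configuration, one-hot for categoricals) proposes the next
configuration by expected improvement until the evaluation budget is
spent; the objective is 3-fold cross-validated class-weighted
log-loss, non-finite trials are recorded as failures, and the best
configuration is refit on all discovery probands. The searched space:
iteration cap 100–400, alpha 1e-5–1e-1 (log), activation
{relu, tanh, logistic}, solver {adam, sgd}, learning rate 1e-3–1e-1
(log) with constant or adaptive schedule (divide by 5 after 10
non-improving iterations), 1–3 hidden layers of 4–32 neurons.

Validation samples are scored with feature matrices built on the
*discovery* gene order (genes absent from the validation VCF become
zero columns — re-running feature selection on validation data would
leak). Each stratum casts one vote; the combined label is the one with
at least two of three votes. With three votes a tie is impossible; if
a stratum has no trainable model its vote abstains and a 1–1 tie
between the remaining votes falls to label 0 (the less harmful error
in a screening context is a missed non-cancer label; the tie-break is
documented rather than principled, since a full run always has three
models).

Mutation loads (selected variants carried per individual) are compared
between validation groups with a two-sided Wilcoxon rank-sum test.
For small groups (at most 10,000 group assignments) the permutation
distribution is enumerated exactly with ties counted 1/2 — `wilcox.test`
falls back to a normal approximation whenever ties are present, which
is exactly the small-count regime here; identical samples short-circuit
to p = 1.

## Enrichment and catalogue overlap

Retained genes are tested per gene set with the one-sided
hypergeometric upper tail (equivalently one-sided Fisher) against a
universe defaulting to all genes in the model, with
Benjamini–Hochberg adjustment across sets. Gene sets come from any GMT
file, so the step runs offline; reproducing any specific curated
database's tables is out of scope. The catalogue screen intersects
selection and catalogue on exact normalized keys — same locus, same
alternative allele — normalizing unnormalized catalogue records on the
fly.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults define the study conditions used throughout
the tests:

| parameter | default | meaning |
|---|---|---|
| `n_case / n_bd_only / n_control` | 60 / 80 / 40 | discovery group sizes (scaled-down cohort; `scale = "full"` switches to 541/767/345) |
| `n_val_case / n_val_bd_only` | 25 / 15 | validation cohort shape |
| `n_background` | 2,000 | background variants, carrier frequency log-uniform on [0.005, 0.2] so both rare and common variation exists |
| `transmission_rate` | 0.5 | probability a family control inherits each background carrier allele of its proband |
| `n_signal` | 10 per stratum | planted case-exclusive variants, each carried by 3–6 unrelated cases |
| `replant_rate` | 0.5 | probability a validation case carries each signal variant |

Background carriage is i.i.d. across probands at the drawn frequency;
each control is attached to one proband and inherits each of its
carrier alleles with probability 0.5 on top of an independent
background draw — an approximation of Mendelian transmission that is
sufficient to stress the family-exclusivity logic without pedigree
simulation. Signal variants are carried only by their designated
cases, so they satisfy the filter by construction (recall 1 is a
structural property, not a finding); optional adversarial decoys recur
in cases but leak into one BD-only proband and must be filtered out.
The number of *background* variants passing the filter has a closed
binomial form (implemented in `expected_spurious_selections()`,
accounting for control inheritance), which the tests use as the null
calibration oracle.

The simulator deliberately omits: linkage disequilibrium and
population structure, mutation-rate heterogeneity along the genome,
sequencing and genotyping error, real pedigree structure beyond one
relative per proband, and overlapping genes. Passing tests therefore
demonstrate the pipeline's logic and calibration under its own
assumptions — not performance on real WGS cohorts, where background
sharing is stronger and exclusivity filters behave less cleanly.

## The permutation null

A null check asks that validation accuracy be indistinguishable from
chance when discovery labels carry no information. The permutation is
applied to the BD_CANCER/BD_ONLY labels of discovery probands *before
variant selection*: permuting later (at the classifier stage) is not a
valid null for this design, because the case-exclusive filter has
already encoded the true labels into the features — any nonzero
validation load identifies a true case regardless of what the
classifier was trained on, and a wrapper selector then cherry-picks
genes whose few carriers happened to draw label 1 (we measured ~0.7
"null" accuracy that way). With the pre-selection permutation the
selected set shrinks to the spurious-pass level and accuracy settles
around chance. Because a 25/15 validation split makes degenerate
constant predictions score 0.375, and because the permutation
distribution has a genuine tail (occasionally every carrier of one
planted variant lands in the pseudo-case group and the variant
survives), the check is formulated on the *median* accuracy across
seeds, compared against the exact binomial 95% interval for 40 fair
coin flips (14/40 to 26/40).

## Numerical and reproducibility choices

* All randomness flows from explicit seeds; forests run
  single-threaded with fixed seeds, the MLP initializes from the seed,
  and pipeline stages derive per-stage seeds from the global seed and
  the stage name (kept below 2^31).
* Simulated artifacts are written in binary mode with fixed
  formatting, so a seed reproduces them byte-for-byte.
* Forward selection treats score improvements below 1e-9 as ties;
  the trivial-classifier baseline is balanced accuracy 0.5.
* Degenerate inputs have defined behavior rather than errors where a
  sentinel is more useful: an empty stratum yields an empty feature
  matrix; a group with fewer than two observations skips the rank-sum
  test with a warning; identical load vectors give p = 1.
* Duplicate variant keys from different VCF records merge by logical
  OR with a warning; the carrier matrix is always 0/1.

## Problem sizes used by the test suite

The suite runs the full study at the default scaled conditions:
10 seeds for planted-signal recovery and for the end-to-end
classification check (each with a matched permutation-null run), a
per-stratum tuning budget of 6 evaluations, 200 random toy cohorts for
the filter-oracle equivalence, 2,000 null simulations for rank-sum
calibration, and exhaustive enumeration of all hypergeometric tables
with universe at most 20. These sizes are the package's chosen working
scale for a complete, reproducible demonstration; larger cohorts are a
matter of the same code and more time (`scale = "full"` in
`sim_config()`).

## Known limitations

* The annotator is transcript-unaware: no consequence prediction, no
  isoform resolution, one region class per position.
* Genotype likelihoods, phasing and VAF-based QC are out of scope;
  sites must arrive as called genotypes.
* The recurrence threshold interacts with cohort size — 3 carriers in
  60 cases is a different stringency than 3 in 541 — and the package
  treats it as a fixed constant of the design, not something it tunes.
* Wrapper-based feature selection is greedy; it returns *a* compact
  informative set, not the unique optimum, and its contents vary
  across seeds even when accuracy does not.
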