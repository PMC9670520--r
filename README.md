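# bdvoi — case-exclusive recurrent variants and cancer-risk labeling in birth-defect cohorts

Children with non-chromosomal birth defects (BD) are roughly 2.5 times
more likely to develop cancer than children without anomalies, yet few
germline variants tying the two phenotypes together are known. `bdvoi`
implements an end-to-end analysis for prioritizing such variants from
multi-sample whole-genome genotypes of a three-group cohort — BD
probands with a malignant tumor, BD probands without cancer, and
healthy family controls (parents/siblings of probands) — and for
testing whether the prioritized variants predict cancer status in an
independent validation cohort.

## The method

**Variants of interest.** Two variant calls are *identical* when, after
parsimony normalization, they share (contig, position, ref, alt) — the
same locus and the same alternative allele. Writing `C_A(v)` for the
number of *unrelated* BD+cancer probands carrying at least one copy of
variant `v` (at most one carrier counted per family), and `C_B(v)`,
`C_H(v)` for carrier counts among BD-only probands and family controls,
the selection rule is set-theoretic:

```
v is a variant of interest  <=>  C_A(v) >= 3  and  C_B(v) = 0  and  C_H(v) = 0
```

Family controls make the exclusivity clause powerful: inherited
background variation present in a proband is typically also present in
a parent or sibling and is therefore filtered out.

**Region strata and gene weights.** Each selected variant is classified
by position against a gene model into CODING, UTR, NCRNA, INTRONIC or
INTERGENIC (precedence in that order; intergenic variants are assigned
their nearest gene, both genes on an exact distance tie), and grouped
into three strata: coding, non-coding (UTR + ncRNA + intronic) and
intergenic. Within a stratum, the number of selected variants a proband
carries in gene `g` is the gene's mutation-load *weight* — the feature
value for classification.

**Two-layer feature reduction.** Per stratum, genes are reduced by
(1) a random-forest importance filter (impurity importances rescaled to
sum to 1; genes below 1e-5 dropped) and (2) greedy forward feature
selection maximizing cross-validated balanced accuracy.

**Per-stratum classifiers and majority vote.** A multilayer perceptron
is tuned per stratum by sequential model-based (Gaussian-process)
minimization of cross-validated class-weighted log-loss over iteration
cap, L2 alpha, activation, solver, learning rate and schedule, and
layer/neuron counts. Each stratum model casts one vote per validation
sample; the combined label is the majority of the three votes.

**Supporting analyses.** Per-individual mutation loads are compared
between validation groups with a two-sided Wilcoxon rank-sum test
(exact permutation enumeration for small groups); retained genes are
tested for gene-set over-representation with a one-sided
hypergeometric test and Benjamini–Hochberg FDR; the selection can be
screened against a somatic-variant catalogue by exact key identity.

Because the motivating cohorts are access-restricted, the package
ships a synthetic-cohort simulator (`sim_config()`,
`simulate_gene_model()`, `simulate_cohort()`, `simulate_validation()`)
that reproduces the statistical structure the analysis assumes —
family-shared background variation and planted case-exclusive
recurrent signal per stratum, with ground truth — so every stage is
testable end to end.

## Worked example

The `analysis/` directory holds the study as numbered stages; each
reads only the files written by earlier stages under `results/`:

```sh
Rscript analysis/01_simulate.R        # cohort + gene model + truth
Rscript analysis/02_discover.R       # recurrence/exclusivity filter
Rscript analysis/03_features.R       # gene loads + two-layer reduction
Rscript analysis/04_classify.R       # MLPs, majority vote, load boxstats
Rscript analysis/05_enrich_overlap.R # enrichment + catalogue screen
```

Output of stages 2 and 4 on the default simulated study (seed 1):

```
selected 34 variants of interest -> results/selection.tsv
per stratum: coding=11, intergenic=12, noncoding=11
planted-signal recall: 100%
spurious passes: 4 observed vs 4.8 expected analytically (SD 2.19)

prediction_report: 40 samples
  per-stratum correct: coding=40 noncoding=40 intergenic=40 of 40
  majority vote: 40/40 correct (100%, fraction 1)
mutation-load comparison (BD+cancer vs BD-only)
          min q1 median q3 max
bd_cancer   9 15     15 19  22
bd_only     0  0      0  0   0
rank-sum W = 375 , two-sided p = 7.21e-08
```

All 30 planted variants pass the filter (they satisfy it by
construction), the 4 extra selections agree with the closed-form
binomial expectation for background variation slipping through, and
the majority vote labels the whole validation cohort correctly —
validation cases carry half the planted signal on average (median load
15) while BD-only probands carry essentially none.

The same pipeline can be driven programmatically through
`run_pipeline(pipeline_config(...))`, which writes a manifest of stage
seeds, effective parameters and artifact checksums, or through
`run_study(seed)`, which returns the headline metrics of one simulated
study.

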