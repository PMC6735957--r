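---
title: "lncforge: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncforge: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncforge)
```

lncforge implements the computational core of a large-scale human lncRNA
catalog-construction pipeline: merging reference gene models, separating
genuine assembled transcripts from background transcriptional noise with
a composite confidence score, applying noncoding filters and genomic
classification, and associating the resulting transcripts with
physiological traits and clinical outcomes. This vignette explains the
models, the tunable parameters, and the design choices made where the
procedure was genuinely open.

## Coordinate conventions and gene models

All coordinates are 1-based inclusive (the GTF convention). BED-style
inputs (SNPs, exclusion regions) are converted on read and never stored
half-open. Transcripts must be stranded, because the genomic-context
classification is strand-aware; `"."` strands are accepted only for
SNPs. A `transcript_model` is an ordered, non-overlapping exon list on
one chromosome; its *intron chain* — the gaps between consecutive
exons — is the unit of identity for multi-exon transcripts throughout
the package.

## Reference merging

Two multi-exon transcripts are redundant when their intron chains are
identical on the same strand; terminal exon ends are free. This is the
standard cuffcompare `=` convention, with zero tolerance on intron
boundaries since no tolerance is specified anywhere. Two single-exon
transcripts are redundant when their same-strand genomic overlap exceeds
80% of the shorter one (strict). The 80% rule is stated as "sequence
similarity" in the original procedure without naming an aligner or
scoring scheme; genomic overlap is the only reproducible
operationalization available and is documented as such. A
single-exon/multi-exon pair is never redundant.

Redundancy classes are the transitive closure of the pairwise relation
(union–find). One representative survives per class: the transcript from
the highest-priority source (GENCODE > RefSeq > lncRNAdb > assembled by
default), ties broken by lexicographically smallest transcript id so the
merge is deterministic. The merge is idempotent and its output contains
no redundant pair — both are tested properties, not assumptions.

## Class codes and novelty

`assign_class_code()` implements the minimal subset of the cuffcompare
code table the pipeline logic needs: `=` (chain identity; single-exon:
reciprocal >80% overlap), `c` (contiguous sub-chain, exonically
contained), `u` (no locus overlap), `o` (same-strand exonic overlap),
`x` (opposite-strand exonic overlap only), `i` (contained in an intron,
same strand), and `other`. Full cuffcompare emulation is a non-goal.
A transcript is *novel* exactly when its code is neither `=` nor `c`.
Precedence is global: `=` beats `c` beats the overlap codes, evaluated
across the whole reference set, not per reference transcript.

## The Transcript Confidence Score

For transcript *t* over a set of samples:

* `J` — junction-read count in the maximally expressed sample. FPKM ties
  resolve toward the larger junction count. Single-exon transcripts have
  no junctions and score `J = 0`; they are scored with the same formula
  rather than a special case, matching their presence in the catalog.
* `E` — the 95th percentile of per-sample FPKM. Percentiles use linear
  interpolation between order statistics (R type 7) everywhere in the
  package (also for Q1/Q3 below), because no convention is stated and
  consistency matters more than the choice.
* `R` — the number of samples with FPKM strictly greater than 0.1.

The score is `TCS = 100/3 · (J/maxJ + E/maxE + R/maxR)`, in [0, 100].
The normalizers are the maxima over the *universe of transcripts scored
together in one run* — positives, decoys and candidates combined — so
scores are comparable within a run; the original procedure does not
state the universe, and this is the only choice under which a single ROC
over positives and negatives is meaningful. A component exceeding its
normalizer is a context mismatch and raises an error rather than a
silent score above 100.

## Background filtration

Negative controls are decoy transcripts: each template's exon/intron
length structure and strand are preserved and the locus is repositioned
uniformly at random — chromosome chosen proportionally to its length,
start uniform, placement rejected while it intersects an exclusion set
(typically annotated genes), with a bounded attempt count. Decoys may
overlap each other; nothing in the procedure forbids it and forbidding
it would bias placements on small genomes.

The retention cutoff is the ROC point closest (Euclidean distance) to
the perfect corner (sensitivity = specificity = 1); distance ties break
toward the *larger* threshold, i.e. the stricter filter. Retention is
`TCS >= cutoff`, since transcripts *below* the cutoff are excluded. The
AUC is the Mann–Whitney pair statistic with ties counted ½, which equals
the trapezoidal area under the empirical curve; the test suite checks
the three-way agreement explicitly.

Independent verification of a transcript uses mean per-base read depth
over its exonic bases, strictly greater than 2.

## lncRNA identification and classification

A candidate survives when (i) its spliced length exceeds 200 nt
(strict), (ii) either CPC or CPAT calls it noncoding (union — one
permissive prediction suffices for the preliminary set), and (iii) it
has no Pfam, mass-spectrometry or Ribo-Seq hit. The external predictors
are consumed as precomputed evidence; running them is a non-goal.
Missing evidence flags are an error, never a default: silently assuming
a coding call either way would corrupt the catalog.

Classification order: `intergenic` (class code `u`) → `sense` (≥ 1 bp
same-strand exonic overlap with a coding transcript; no minimum overlap
is stated, so 1 bp) → `antisense` (opposite-strand overlap with a coding
gene *locus*, exons or introns — locus-level because the definition
speaks of the antisense strand of protein-coding *genes*) → `others`.
Catalog-to-catalog comparison uses the blunter criterion of ≥ 1 bp exon
overlap ignoring strand.

## Expression metrics

**Quantile normalization** forces each sample onto the across-sample
mean of order statistics. Ties within a column share the mean of the
target values they span, making the map well defined; the suite
cross-checks against `limma::normalizeQuantiles` on tie-free data.

**Tissue specificity** is the Jensen–Shannon score: the per-tissue
expression vector is normalized as
`p_i = log2(e_i + 1) / Σ log2(e_j + 1)` and compared against each
single-tissue extremal pattern; the score is
`max_t (1 − sqrt(JS(p, e^t)))`. Entropy is taken in bits. The source
writes "log" unqualified; base 2 is chosen because it bounds the JS
divergence by 1, which is what makes 0.6 a meaningful specificity
threshold on a [0, 1] scale. The score is 1 exactly for single-tissue
patterns. Note the pipeline is *not* scale-free: the log2(e+1)
normalization precedes the probability step, so rescaling inputs changes
the score slightly — tests exercise the implemented pipeline end to end
rather than asserting a proportionality the procedure does not have.
Per-tissue expression is summarized as the mean over samples by default
(configurable); the original choice between mean and median is unstated.

**Splicing efficiency** of a gene quantified against an annotation
augmented with a locus-spanning unspliced isoform is
`Σ annotated / (Σ annotated + spanning)`, in [0, 1], undefined (NA) at
zero total abundance.

**Conservation** is the track sum over exonic bases divided by
transcript length; bases missing from the track contribute 0. Exonic
bases (not the locus span) are used because the transcript length is the
stated divisor.

**Inter-individual variability** is the coefficient of variation
(sample SD over mean) across donors, scale-invariant by construction;
sex-chromosome transcripts and never-expressed transcripts are excluded
upstream by the caller.

**Moderate-to-high expression** in a tissue means
`Q3 + 1.5·(Q3 − Q1) > 0.1` FPKM over that tissue's samples — the upper
Tukey fence, which degenerates to `value > 0.1` for a single sample.

Reported catalog percentages are rounded half-up to one decimal, the
presentation convention of the figures they reproduce (R's `round()`
banker's rounding would get 0.125 → 0.1 cases wrong in the other
direction).

## Association layer

All mixed models are `nlme::lme` fits of log2(FPKM + 0.01) with a
per-individual random intercept and Wald tests on the fixed effects; the
pseudocount is small enough (≤ 0.01 log2 units of bias at 1 FPKM) not to
perturb effect recovery at the tested tolerances. Covariates with a
single observed level are dropped with a warning — the dropped-level
behaviour is logged, not guessed. Singular or non-converged fits are
flagged and excluded from FDR adjustment, which is BH within each
analysis and term, never across analyses.

Differential expression calls require condition FDR < 0.05 **and** raw
fold change > 1.5 in either direction (`max(FC, 1/FC)`, symmetric,
because the stated ">1.5" names no direction). Metastasis/recurrence
associations additionally require the expression filter in that tumor;
stage (ordered, numeric 1–4) drops the fold-change gate but keeps FDR
and the expression filter.

Cox models regress survival on expression with sex, age and race, one
sample per individual (lexicographically first sample id — the
deduplication rule is unstated, so a deterministic one is imposed).
The proportional-hazards assumption is tested per covariate via scaled
Schoenfeld residuals; when age violates it, the model is refit with age
stratified into quartiles (the stated "dividing the age into strata"
with quartiles as the unstated rule). HR < 1 is protective, HR > 1
risky. Kaplan–Meier splits use the median expression *of patients with
available survival information*, computed after excluding patients
without it; the log-rank test compares the groups.

The tissue-enrichment odds ratio is `(a/b)/(c/d)` over biased/non-biased
× specific/other counts with a one-tailed Fisher p-value; it exceeds 1
exactly when the specific fraction is higher among biased transcripts.
GWAS overlap counts SNPs inside the whole transcript locus, introns
included, bounds inclusive, strand ignored.

## What the synthetic generators emulate — and what they do not

`generate_annotation` packs non-overlapping coding genes on a toy genome
(2 chromosomes × 1 Mb by default; everything runs in seconds) and plants
lncRNAs whose true class label is known by construction. Hosts for
anchored classes cycle deterministically so same-class plants are never
redundant copies of each other. `generate_expression_cohort` draws
log2-scale expression: baseline 3 (≈ 8 FPKM), per-transcript tissue
offsets (SD 0.5), per-individual intercepts (SD 0.3), residual noise
(SD 0.5 by default), with injected sex/age/race/condition effects in
log2 units — a condition effect of 2 is a true 4-fold change.
`generate_evidence` separates real transcripts (junction reads
Poisson(20), FPKM log-normal around 5) from decoys (Poisson(1),
log-normal around 0.05), the separation the ROC calibration assumes.
`generate_survival` draws exponential event times with hazard
`λ0·exp(log_hr · expression)` and independent exponential censoring.

These generators state a world, and the green tests establish recovery
*in that world*: additive log-scale effects, Gaussian noise, exponential
hazards, no splicing-graph complexity, no read-level noise, no
mapping/assembly artifacts, no batch structure beyond what quantile
normalization removes. A green recovery test says the estimators are
implemented correctly, not that real tissue compendia satisfy the
model.

## Numerical choices and degenerate inputs

* Percentile/quartile convention: linear interpolation (type 7),
  uniformly.
* Strict inequalities wherever the source states them: FPKM > 0.1,
  length > 200, coverage mean > 2, FC > 1.5, overlap > 80%.
* Constant-response mixed models short-circuit to zero effects with
  p = 1 rather than fitting a zero-variance model.
* Zero-total splicing efficiency, zero-mean CV and zero-denominator odds
  ratios return NA markers; zero-denominator percentages are errors.
* All generators and the decoy sampler take explicit seeds; identical
  seeds give byte-identical outputs, which the suite asserts at the file
  level for every CLI preset.

## Known limitations

Sequence-level similarity for single-exon redundancy is approximated
genomically; full cuffcompare code semantics, eQTL analysis,
co-expression enrichment and read-level simulation are out of scope. The
class-code comparator is quadratic in reference size per query — fine
for catalog-scale fixtures and tests, not tuned for whole-genome
annotation scans.
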