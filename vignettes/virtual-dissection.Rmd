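---
title: "Virtual dissection of xenograft transcriptomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual dissection of xenograft transcriptomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenodissect)
```

## The problem

A patient-derived xenograft (PDX) is human tumor tissue growing in a mouse.
Bulk RNA-seq of a PDX tumor, and even more so of a PDX metastasis, is a
mixture of two transcriptomes: the cancer cells (human) and the organ
microenvironment (mouse).  Because the two genomes differ in sequence, reads
can be assigned to their species of origin, splitting one library into a
*cancer dataset* and a *microenvironment dataset* — a virtual dissection
that needs no cell sorting or microdissection.  Everything downstream in
this package exists to make that split and then use it: expression
normalization that is immune to the mixing ratio, differential expression
that adjusts for it where it cannot be removed, enrichment analyses run per
compartment, and a triad design that separates reversible
microenvironment-induced expression changes from heritable
metastasis-selected ones.

## Species partitioning

The original pipelines align reads to a concatenated human+mouse(+viral)
genome whose chromosomes carry organism prefixes and keep only uniquely
mapping reads.  At desk scale we reproduce those *semantics* with an
organism-unique k-mer classifier:

* every canonical k-mer (default `k = 31`, the standard size for
  species-level discrimination) of every reference transcript is indexed
  with the organism and gene it came from;
* a k-mer present in more than one organism is *shared* and carries no
  information;
* a read is assigned to an organism only if it has at least
  `min_informative` (default 2) organism-unique k-mer hits for that
  organism and none for any other.  Evidence for two organisms discards the
  read as `ambiguous` — the analogue of discarding multi-mapping reads.
  No informative hits leave it `unmapped`.

An error-free read copied from one reference can never contain a k-mer
unique to the other organism (all its k-mers exist in its own reference),
so misassignment requires sequencing error; `min_informative = 2`
suppresses the single-k-mer false hits that substitutions can create.
Gene-level counts go to the gene holding the plurality of a read's
informative hits; plurality ties are counted for the organism but not for
any gene.  Mates of a pair are classified independently and the fragment
takes their agreement (conflict or any ambiguous mate discards the pair;
an unmapped mate defers to the informative one).  Re-sequenced runs of one
library are merged by adding partition results.

Composition is reported over *classified* reads only:
`pct_o = 100 * reads_o / sum(reads_retained)`, with ambiguous and unmapped
reads — and any organism explicitly excluded, such as a viral decoy —
outside the denominator.

## Per-species TPM

For one organism's count matrix with effective lengths `l_g`,

    TPM_gs = 1e6 * (c_gs / l_g) / sum_h (c_hs / l_h).

Because the denominator runs over that organism's genes only, a change in
the *other* species' share of the library cancels out: per-species TPM is
compositionally invariant, which is exactly why it is the right unit for
mixed samples.  The test suite verifies this property directly by
simulation (paired samples with identical human-side composition and very
different mouse fractions).

All analyses use `log2(TPM + 1)`.  The +1 pseudocount keeps zeros at zero,
which is what makes "genes with log2 TPM of zero across all samples" a
well-defined removal rule (`drop_all_zero_genes()`).

Upper-quantile normalization (used before cross-cohort clustering) is an
additive shift on the log scale — equivalently a scaling on the linear
scale — aligning each column's 75th percentile, computed over the genes
nonzero in that column, to the cross-column mean of those percentiles.
Zero entries are left untouched: they mean "not detected", not "low", and
preserving them makes the operation idempotent.  Row-median centering,
top-variable-gene selection (ties broken lexicographically for
determinism), PCA on centered and unit-scaled gene rows (component signs
fixed by making the largest-magnitude loading positive), and hierarchical
clustering with distance `1 - r` (Pearson) under Ward.D2 linkage complete
the representation toolkit.

The correlation-based label-swap QC infers each sample's line as the line
whose labelled samples have the highest *median* correlation with it.  The
median matters: with a single best-neighbour rule, the line-mates of a
swapped sample get flagged through the mislabelled neighbour itself,
whereas the median is robust to one bad label per line, so a genuine swap
surfaces as exactly one mutual pair.

## Composition-adjusted differential expression

Per gene, counts are modelled as negative binomial with a log link:

    log mu_gs = log(sf_s) + b0 + b1 * percent_s + sum_c b_c [condition_s = c]

* `sf_s` are median-of-ratios size factors (geometric mean rescaled to 1);
* `percent_s` is the per-sample percentage of reads from the focal
  organism — mouse percent for the mouse matrix, human percent for the
  human matrix — centered before fitting.  It absorbs the gene-specific
  coupling between composition and measured expression (mapping
  bleed-through, depth-dependent effects) that global size factors cannot
  remove because they are shared across genes;
* fitting is iteratively reweighted least squares with the dispersion held
  fixed (relative tolerance 1e-8, at most 100 iterations), coefficients
  reported on the log2 scale, and a two-sided normal Wald test on the
  contrast coefficient.

Dispersion is estimated per gene by method of moments on normalized
counts, `alpha = (s^2 - mu) / mu^2`, floored at 1e-8, with the moments
taken *within* condition groups so that a genuine condition effect does
not masquerade as biological noise.  With 6 samples per group the raw
estimator is very noisy, and genes whose sample variance fluctuates low
would receive overconfident tests; `run_de()` therefore moderates each
estimate toward the cross-gene median with 10 pseudo-degrees of freedom —
the standard information-pooling remedy in this field, deliberately
lighter than a full trended empirical-Bayes machinery.  The bare estimator
remains available (`prior_df = 0`).

Two conventions reproduce the familiar result-table shape: independent
filtering (a 20-point scan over base-mean quantile cutoffs keeping the one
that maximizes BH rejections; genes below it get `padj = NA`) and an
outlier rule (genes whose apparent >= 2-fold change flips sign when a
single contrast sample is left out get `padj = NA`; their p-values are
kept).  Benjamini–Hochberg adjustment at 0.05 is the significance
threshold throughout.

Recurrence across PDX lines (`recurrent_genes()`) keeps a gene when its
direction-signed fold change meets a threshold in at least `min_lines`
tables, optionally also requiring `padj < 0.05` in those same tables —
the rule family used for cross-line metastasis genes (e.g. at least
2-fold in 5 of 7 lines) and for the host liver response (2-fold in 6 of
7 at FDR < 0.05).

## Enrichment scoring and the sum-of-ES ranking

`ssgsea_score()` implements single-sample GSEA: genes ranked by descending
expression (ties broken by gene id for cross-platform determinism), in-set
genes weighted by `rank^alpha` with `alpha = 0.25`, and the score is the
sum over all positions of the difference between the normalized in-set
weight CDF and the uniform out-of-set CDF.  Scores are rank-based, hence
invariant to any monotone per-sample transform; the matrix form optionally
divides all scores by the matrix-wide range, following the convention of
the reference implementation of ssGSEA.  Samples are first restricted to
those with more than 50 % of reads from the focal organism
(`sample_fraction_filter()`, strict inequality).

For each gene set and PDX line, `es_group_difference()` takes mean ES in
metastases minus mean ES in mammary tumors; `sum_es_ranking()` sums the
differences across lines and ranks sets by the descending sum.  The sum —
not a vote — is the ranking statistic, so a set with a moderate consistent
shift across six lines outranks a set with one large and five null
differences only when its total is larger.

## Attribution of signature genes to the host compartment

Given a metastasis gene signature derived from bulk human biopsies, some
members may really be expressed by the *organ*, not the cancer.
`anova_origin_filter()` tests each candidate in the mouse (host)
expression matrix with a one-way ANOVA between metastasis-bearing and
normal organ samples, retaining genes significant at `p < 0.05` and higher
in the metastasis-bearing group.  Candidates map into the host namespace
by case-insensitive symbol equality unless an explicit two-column map is
supplied.  The degenerate zero-residual-variance case is defined
explicitly (equal means give `p = 1`).  ANOVA runs on `log2(TPM + 1)` by
default in our fixtures: raw TPM ANOVA is dominated by variance
heterogeneity between high and low expressors.  `mean_signature_score()`
is the companion scorer: the unweighted mean of the signature genes'
values per sample, over genes present.

## Triads: transient versus selected programs

A triad is a matched triple from one PDX line: parental mammary tumors,
metastases grown from them, and mammary tumors regrown from those
metastases.  On linear TPM with pseudocount 1,

    FC1 = (mean_met + 1) / (mean_MGT + 1)
    FC2 = (mean_regrown + 1) / (mean_MGT + 1)

and the twofold-cutoff rules classify every gene into exactly one class:
`transient` (FC1 >= 2, FC2 < 2 — induced by the microenvironment,
reverting on regrowth), `selected` (FC1 >= 2, FC2 >= 2 — retained after
regrowth, evidence of clonal selection), the mirrored down-classes, or
`unchanged`.  "Reverted" is operationalized as "within threshold-fold of
the parental level" because the cutoff rules are applied globally; fold
changes are computed from expression means rather than from the DE model
because the classification describes expression levels, not test
statistics.  Raising the threshold can only move genes toward
`unchanged` (monotonicity), which the property tests verify.

## The synthetic cohort generator

The generator emulates the structure the analyses assume, not the biology
of any particular tumor:

* **References** — one transcript per gene, uniform-random sequence;
  ortholog pairs differ by independent per-base substitutions at a
  divergence of 0.10, high enough that nearly every 31-mer is informative
  yet low enough to exercise shared-k-mer handling.  A viral decoy can be
  added as a third reference with zero expression.
* **Counts** — `NB(mean = base_g * effect * fraction^gamma_g * library,
  dispersion)`, with lognormal base abundances and lengths.  `gamma_g ~
  N(1, sd)` is the per-gene composition sensitivity; at the default
  `sd = 0` the species fraction is a purely global column scaling (which
  size factors remove exactly), while the DE fixture uses `sd = 0.2` so
  that composition has the gene-specific effects the percent covariate
  exists to absorb.
* **Reads** — uniform substrings of transcripts drawn proportional to
  per-sample expression; single-end by default (classification logic is
  identical per mate), optional paired mode and uniform substitution
  errors.  Every read, gene and sample carries a truth label.
* **Effects** — log2 fold-change tables for the metastasis program,
  transient program (applied in metastases only), selected program
  (applied in metastases and regrown tumors), and the host organ response
  (applied in `met_*` tissues); per-line baseline offsets give lines
  distinguishable profiles where needed.

Four presets pin down the test surfaces.  `partition_demo`: four samples
at fractions 0.8/0.5/0.2/0.95, 1e5 reads each.  `de_demo`: one line, 6
mammary tumors at human fractions 0.72–0.91 versus 6 liver metastases at
0.25–0.90 (fixed grids — with six samples per group, independently drawn
compositions make the covariate's collinearity, and hence the fixture's
power, a per-seed lottery; a deterministic spread over the observed ranges
is the study condition, while count noise stays seeded), 50 genes planted
4-fold up, dispersion 0.1.  `triad_demo`: three lines, 30 transient + 30
selected genes planted 4-fold, noiseless by default with an NB option.
`signature_demo`: six lines, one 20-gene program planted 2-fold up in
every line's metastases among 100 random decoy sets.  Library sizes are
~2e6 reads so the full suite runs in minutes; planted genes are drawn from
the upper 70 % of base abundance, reflecting that reported recurrence
lists concern detectably expressed genes.

What the generator does **not** emulate — isoform structure, GC and
length biases, realistic error profiles, strandedness, batch effects —
bounds what a passing suite shows: the pipeline's logic and statistics
are correct under the stated noise model, not that any aligner-specific
artifact is handled.

## Numerical choices and degenerate inputs

* Prefilter ratio clause: `max / (min + [min == 0])` — the guard is
  applied only for zero minima so that a constant positive gene passes
  with ratio 1, and the threshold (0.5 as printed, almost always
  satisfied) is an exposed flag.
* All-zero TPM columns stay all-zero and are flagged rather than
  producing NaN.
* `percent` constant in a DE design: the covariate column is dropped with
  a warning rather than producing a singular fit; conditions with fewer
  than two samples are refused outright.
* Gene sets with no member present score as an error, not silently 0;
  a set equal to the whole universe scores exactly 0.
* Ties everywhere (expression ranks, variable-gene selection, ranking
  sums) break on identifiers so results are platform-independent.

## Limitations

The percent covariate costs power when composition is strongly confounded
with condition — the extreme case being host-compartment contrasts where
normal organs are 100 % mouse, making percent nearly collinear with the
group indicator; identifiability then rests entirely on the composition
spread *within* the metastasis group.  The partitioner is
transcriptome-based and ignores splicing, so it is a stand-in for genome
alignment, not a replacement at scale.  The dispersion
model is method-of-moments with median moderation, adequate for the
calibration and power regimes tested here but not a substitute for full
empirical-Bayes machinery at very small counts.  Subtype classification is
a generic nearest-centroid operation: trained centroid models are inputs,
never shipped.  External cohort operations (merging, upper-quantile
normalization) accept any conforming matrix and make no attempt to
reproduce a specific consortium's processing.
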