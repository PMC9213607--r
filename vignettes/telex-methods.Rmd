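---
title: "Models and methods behind telex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind telex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`telex` analyzes transposable-element (TE) expression at the resolution of
individual genomic insertions: assembled transcripts are assigned to unique
reference loci, locus counts are normalized and tested for differential
expression between a paired pre/post phenoconversion cohort and independent
controls, and the resulting DE sets are characterized by class composition,
chromatin state and a sparse random-forest classifier. This vignette
explains each model, the tunable parameters, the synthetic-data design the
tests rely on, and the numerical choices that were genuinely open.

## Transcript-to-locus assignment

TE-derived transcripts align well to many copies of their family. The
pipeline therefore accepts a transcript only when a local alignment covers
at least 90% of the transcript's length (the denominator is the transcript,
not the reference element) at a sequence identity of at least 95%, both
thresholds inclusive. A transcript whose passing hits touch two or more
distinct loci is removed outright — multiple passing hits to the *same*
locus (split alignments) count as one location. Strict discard is the
default because no principled tie-break exists without an error model for
the aligner's scores; a `best_hit_margin` option (off by default) rescues a
multi-mapper whose top bitscore exceeds the runner-up locus by a stated
margin, and is documented as an extension rather than part of the core
method. `align_semiglobal()` (query-global dynamic programming with free
end-gaps on the target) exists so that test fixtures can be recomputed from
FASTA alone; it is a test-scale stand-in, not a seeded genome aligner.

## Quantification and normalization

The pipeline's default abundance unit divides each locus's count by the
sample total and multiplies by one million. That formula has no length
term — it is formally CPM — but it is kept as the default because it is the
quantity the downstream analysis consumes; `calc_tpm_length_normalized()`
implements the standard length-normalized TPM for users who need it. Which
of the two is "correct" depends on whether upstream quantification already
normalized by effective transcript length, so both are exposed and neither
is silently substituted for the other.

Loci pass the expression filter when they reach `CPM >= 1` (on raw library
sizes) in at least 2 samples. TMM factors then correct for composition
bias: against a reference sample (automatically the one whose
75th-percentile CPM is closest to the mean of those percentiles), per-locus
log-ratios M and log-abundances A are computed on loci with positive counts
in both samples (zeros are dropped pairwise — the log-ratio is undefined),
the most extreme 30% by M and 5% by A are trimmed on both sides (the
established defaults; the method's description names the trimming but not
the fractions), and the factor is the mean of the surviving M weighted by
the inverse of the delta-method variance
`(N_k−Y)/(N_k Y) + (N_r−Y_r)/(N_r Y_r)`. Factors are rescaled to geometric
mean 1. Note one property the formulas do *not* have: rescaling a single
sample's depth leaves M and A unchanged but perturbs the weights by
O(count/library size), so factors are depth-stable only to about 1%, not
exactly — the tests assert exactly this bound and verify the implementation
against an independent one instead.

`calc_logcpm()` uses a prior count of 0.5:
`log2((Y + 0.5)/(N f + 1) × 10⁶)`. The prior's effect on a
depth-doubling comparison is `≈ 0.25/(Y ln 2)`, i.e. ~3.6×10⁻³ at Y = 100,
which the tests check in closed form.

## Differential expression

Counts are modeled per locus as negative binomial with mean
`μ_gk = exp(x_kᵀβ_g + log(N_k f_k))` and variance `μ + φ μ²`. The paired
contrast (pre vs post, same subjects) uses `~ subject + condition` — a
blocking factor absorbing each subject's baseline, with no interaction
term; unpaired contrasts use `~ condition`. Subjects missing one condition
are dropped with a warning. The condition term is tested by likelihood
ratio against the nested reduced model, `p` from χ² with 1 df.

Dispersion is estimated by Cox–Reid adjusted profile likelihood: fitted
means come from a Poisson working fit (the mean structure is nearly free of
φ), and the adjusted likelihood `ℓ(φ) − ½ log det(XᵀWX)` is maximized over
a log grid on [10⁻⁴, 4] with golden-section refinement. The adjustment
matters: with a subject-blocked design the plug-in profile likelihood
underestimates φ roughly by the ratio of residual to total degrees of
freedom, which would make the LRT anticonservative. Tagwise dispersions
maximize the per-locus adjusted likelihood plus `prior_df` (default 10)
times the average likelihood across loci, so they shrink toward the common
value and collapse onto it as `prior_df → ∞`. Under the null at the study's
scale (2000 loci, 20 paired subjects, φ = 0.2) the realized fraction of
p < 0.05 is ~0.04 and the p-value distribution is uniform by KS test; the
acceptance suite recomputes this every run.

Selection follows the analysis the pipeline reproduces: nominal `p < 0.01`
and `|log2FC| ≥ 1.5`, applied two-sided because both up- and down-regulated
sets are reported under the same criteria (a one-sided option exists); 1.5
is interpreted on the log2 scale, matching the volcano-plot axis the rule
annotates. BH FDR is always computed and written alongside, but plays no
role in selection. The logFC sign convention is second condition of the
contrast name over the first (`pre_vs_post` → log2 post/pre).

`pca_qc()` reports centered PCA scores and a mean-silhouette
group-separation score without making a decision: in the motivating design
the three groups are *not* expected to separate globally, and the score
exists to document that. The same machinery supports the age-null check:
regressing PC1/PC2 of DE-locus expression on age in the control group
should be non-significant when age carries no expression signal, which the
generator guarantees by construction.

## Enrichment, intersection, cis genes

Class/family enrichment uses the Fisher exact test on 2×2 tables of DE
membership × label, with the expressed (filter-surviving) loci as
background. The two-sided p sums hypergeometric probabilities of all tables
(at fixed margins) no more probable than the observed one — stated
explicitly because two-sided Fisher definitions differ between ecosystems.
Labels are flagged at raw `p ≤ 0.01` with no multiplicity correction (the
flagging convention of the analysis reproduced); BH values are written for
transparency. The overlap of two DE sets is tested against the
hypergeometric upper tail in the shared tested universe, with an up/down
concordance cross-tabulation. Cis genes are assigned when the gene body
intersects the locus expanded by ±5000 bp (half-open intervals); mapping to
the gene body rather than the TSS is a documented choice — regulatory-domain
logic in the style of genomic-region enrichment tools is out of scope.

## Chromatin states

Per tissue, loci are intersected with a Core 15-state segmentation
(mnemonics `1_TssA` … `15_Quies`, accepted with or without the numeric
prefix). Adjacent same-state segments are merged before labeling, so the
labels are invariant to how a tiling was split. A locus overlapping exactly
one state inherits it; two or more states with ≥ 1 bp each yield the
sentinel `Mx` (mixed); no coverage yields `NA`. A `min_minor_fraction`
option can ignore trace overlaps when calling `Mx` (default 0: any overlap
counts). "Functionally active" states default to the
promoter/transcription/enhancer block (states 1–8); the source analyses
never enumerate the set, so it is a config key echoed in every report, and
`active_fraction()` reports both the label-based reading (Mx counts
inactive) and the any-overlap reading (Mx counts active if any of its
states is active) — the underlying published fractions do not state which
rule they used, so neither is privileged. Inputs must share one coordinate
system; no genome lift-over is performed.

## Entropy, Boruta, classifier

Feature prefiltering ranks loci by the Shannon entropy of their expression
profile: values are transformed `log2(x+1)` and binned into 10 equal-width
bins over the observed range; `H = −Σ p log2 p` in bits, 0 for constants
and `log2(10)` at most. The histogram construction is a documented choice
(the original "entropy of expression" function is unpublished), so the bin
count is a parameter recorded in reports. Ties rank lexicographically by
locus id so the retained set is deterministic. The default `top_k` is
10,000, matching the analysis reproduced; synthetic runs have fewer loci
and keep everything.

Boruta: per iteration, every feature gets a row-permuted shadow copy; a
random forest (default `ntree` 10,000, configurable down for quick runs;
importance = out-of-bag permutation importance) is fitted to the doubled
matrix, and a feature scores a hit when its importance exceeds the best
shadow's. After each iteration, binomial tests on the hit count (success
probability ½, Bonferroni over all features, the canonical correction of
the reference implementation) confirm via the upper tail or reject via the
lower tail at `p < 0.05`; whatever is undecided at `max_runs` (default
100) stays tentative. One behavior worth knowing: with ~50 features and
~60 samples, a fixed label permutation typically leaves one noise feature
with |cor| ≈ 0.3 to the labels — genuine signal *with respect to those
labels* — so roughly one permutation in ten confirms a feature no matter
how strict the sequential boundary is. That is a property of all-relevant
selection at this n/p, not of the implementation.

Classification uses a probability forest on the Boruta-confirmed features,
a 70/30 train/test split performed at subject level whenever paired
samples exist (both samples of a subject stay on one side — sample-level
splitting would leak subject identity into the test set), optional
down-sampling of the training classes to the minority size, stratified
5-fold cross-validation inside the training set as a sanity readout
("five times cross-validation" is read as 5-fold), and test-set AUC as the
midrank Mann–Whitney statistic, which handles probability ties and is
invariant under monotone transforms of the scores.

## The synthetic-data generator

The generator emulates the structure of the motivating study, not its
biology. Defaults are the study's design: 25 paired converter subjects
(age ~ N(81.2, 4.1²), 14:11 F:M) and 64 independent controls
(N(81.6, 3.9²), 43:21), TE classes mixed LINE 0.35 / SINE 0.30 / LTR 0.20 /
DNA 0.10 / SVA 0.05, locus lengths uniform on 300–7000 nt. Counts are NB
(`dispersion` φ = 0.1 by default; the source data's locus-level
distribution is unpublished, so NB with log-normal subject effects is an
assumption, stated as such) around library size × relative abundance, with
a per-locus, per-subject N(0, `subject_sd`² = 1) log2 intercept shared by a
subject's two samples — the mechanism that makes the paired design
demonstrably more powerful, which the tests assert. Planted DE
(`de_fraction`, default 5%, |log2FC| = `planted_lfc` = 2) splits into a
pre-specific shared signature (`frac_pre_signature`) shifted in the pre
samples only — so it appears in both contrasts with concordant direction —
and contrast-specific remainders; DE loci are drawn with double weight on
LINE/LTR loci so class enrichment has signal. Age is drawn independently of
expression, giving the QC module a true null. Chromatin tracks tile each
toy chromosome exactly, with per-locus states drawn from `state_probs` and
designated straddle loci split mid-locus into two states to exercise `Mx`.
Each generator draws from its own RNG stream derived from the master seed
by a fixed label, so outputs are stable when one generator's call count
changes.

What the generator does **not** emulate: read-level sequencing error,
assembly artifacts, GC/length biases, correlated TE co-expression, batch
effects, or any real linkage between chromatin state and expression.
Passing tests therefore demonstrate the pipeline's statistical behavior
under its stated model, not performance on real libraries.

The demo dataset (`make_demo()`) is deliberately compact — 300 loci, 12
paired converters, 20 controls — so the full pipeline runs in a few
minutes on one CPU; the DE calibration and power checks use 2000 loci and
20 paired subjects. The demo plants a 15-locus pre-specific signature at
|log2FC| = 2.5 with 10% of DE loci in each contrast: sized so the
signature robustly survives the ~20% transcript-level attrition from the
planted low-identity/multi-map fractions and the moderate power of the
12-vs-20 unpaired contrast, keeping the end-to-end recovery property
stable across seeds.

## Numerical choices and degenerate inputs

* NB GLMs are fitted by IRLS (`glm.fit` with a fixed-dispersion NB family),
  convergence 10⁻¹⁰ or 100 iterations; all-zero loci are flagged degenerate
  with LR 0 and p 1; non-converged fits propagate `NA` p-values and are
  counted rather than hidden.
* Likelihood ratios in (−10⁻⁶, 0) are clamped to 0 (IRLS round-off);
  anything more negative raises an error, since it indicates a broken fit.
* Fisher tables with a zero margin return p = 1; odds ratios use the
  `ad/bc` conventions 0/∞, `NA` when both products are 0.
* Dispersion tagwise optimization interpolates the shared likelihood with a
  natural spline over the grid so the per-locus step stays O(grid) instead
  of O(loci × grid).
* All genomic intervals are 0-based half-open internally; BED output is
  0-based half-open, the RepeatMasker-style table 1-based inclusive.

## Known limitations

* The NB model assumes counts; the quantification stage nevertheless
  accepts non-integer "counts" (e.g. expected counts), which the LRT treats
  as-is.
* Covariate adjustment (sex, age) in the unpaired contrast is supported by
  the design machinery but off by default; the source analysis does not
  state whether it adjusted.
* The chromatin module annotates, it does not learn states; cross-tissue
  clustering is descriptive.
* Boruta decisions at small n with many features inherit the all-relevant
  caveat above; treat confirmations on ~60 samples as candidates, not
  biomarkers.
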