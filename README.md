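# telex — locus-level transposable-element expression analysis

Transposable elements (TEs — LINEs, SINEs/Alus, LTR/HERVs, SVAs, DNA
transposons) are mostly silenced in adult tissue, but a subset escapes
silencing and is transcribed. Changes in locus-resolved TE expression in
peripheral blood have been proposed as biomarkers of presymptomatic
neurodegeneration, using a longitudinal design in which the same subjects
are sampled before ("Converter_pre") and after ("Converter_post") clinical
phenoconversion, alongside an independent never-converting control group
("NC").

`telex` implements the bespoke computation of that analysis as a tested,
reusable R pipeline for anyone quantifying TE expression at the level of
individual genomic insertions rather than family consensus sequences:

* **Unique-locus assignment** — transcript-vs-reference alignments are
  filtered at ≥ 95% identity and ≥ 90% transcript-length coverage
  (inclusive), and transcripts whose passing hits span more than one locus
  are discarded as multi-mappers.
* **Quantification and normalization** — per-million scaling
  (`T_gk = Y_gk / N_k × 10⁶`, a length-free TPM; a length-normalized
  variant is provided), the `CPM ≥ 1 in ≥ 2 samples` expression filter,
  and TMM factors: the precision-weighted mean of per-locus log-ratios
  `M_g = log2((Y_gk/N_k)/(Y_gr/N_r))` after two-sided trimming of 30% by M
  and 5% by A, rescaled to geometric mean 1.
* **Differential expression** — per-locus negative-binomial log-linear
  models with offsets `log(N_k f_k)`; the paired contrast uses a subject
  blocking factor plus condition term (no interaction), tested by
  likelihood ratio against the reduced model (χ², 1 df). Dispersion is
  estimated by Cox–Reid adjusted profile likelihood with tagwise
  shrinkage. Selection uses nominal `p < 0.01` and `|log2FC| ≥ 1.5`; BH
  FDR is always reported.
* **Enrichment and annotation** — Fisher exact tests of TE class/family
  composition of DE sets against the expressed background, hypergeometric
  intersection tests between contrasts, fold-change correlation, and cis
  gene assignment within ±5 kb.
* **Chromatin states** — overlap of loci with Core 15-state segmentations
  per tissue; loci overlapping ≥ 2 states are labeled `Mx` (mixed);
  active-state fractions, per-state enrichment, and cross-tissue
  concordance with average-linkage clustering.
* **Classifier** — Shannon-entropy feature prefiltering (top 10,000 by
  default), Boruta shadow-feature selection over random forests, and a
  random-forest classifier evaluated with a subject-aware 70/30 split
  (both samples of a subject stay on one side), down-sampling, 5-fold CV,
  and midrank (Mann–Whitney) AUC.
* **Synthetic data** — a generator producing every input with known
  ground truth: NB counts with a per-subject random intercept shared by
  paired samples, planted log2 fold-changes including a pre-specific
  shared signature, transcripts with controlled identity/coverage and
  multi-mapping, tiling chromatin tracks, and an age covariate independent
  of expression.

## Worked example

```r
library(telex)

dir <- tempfile()
make_demo(dir, seed = 1)                     # writes FASTA/BED/TSV inputs + truth.json
report <- run_pipeline(dir, pipeline_config(seed = 1))
report
#> <telex pipeline report>
#>   transcripts: 300 in, 240 assigned
#>   loci tested: 240
#>   pre_vs_post: 16 up, 6 down
#>   pre_vs_nc: 13 up, 11 down
#>   classifier (pre_vs_post): AUC 1.000 with 20 features

report$enrichment$intersection$overlap_size  #> 11
signif(report$enrichment$intersection$p, 3)  #> 3.2e-07
report$enrichment$intersection$concordant_fraction  #> 1
```

Reading the numbers: of 300 simulated transcripts, 240 survive the
identity/coverage/multi-map filters (the demo plants 10% low-identity and
10% multi-mapping transcripts). Both contrasts are tested on the 240
surviving loci; the planted pre-specific signature appears in both DE
sets — 11 shared loci, far more than the ~1 expected by chance
(hypergeometric p ≈ 3×10⁻⁷), all changing in the same direction — and the
classifier separates pre from post samples perfectly on held-out subjects.

Each stage is also a plain function on data frames: `assign_transcripts()`,
`calc_tmm_factors()`, `de_test()`, `class_enrichment()`,
`overlap_states()`, `boruta_select()`, `train_evaluate()` … with
`tidy()`/`glance()` methods and `autoplot()` volcano/PCA/ROC plots. A thin
command-line wrapper lives in `inst/scripts/telex`.

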