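# mirdeg — degradation-bias screening for miRNA expression profiles

RNA degrades quickly in unfrozen tissue, and on a miRNA microarray that
degradation does something counter-intuitive: because the labeling chemistry
tags *every* RNA species, fragments of degrading mRNAs and rRNAs can
cross-hybridize to miRNA capture probes, so the number of "detected" miRNAs
can *increase* as RNA quality (the RIN score, 10 = intact … 1 = destroyed)
collapses. The miRNAs that appear this way are disproportionately those
added to miRBase in its recent, sequencing-driven releases — a systematic
annotation bias with direct consequences for biomarker studies run on
clinical tissue of imperfect quality.

`mirdeg` is an R package for quantifying and dissecting that bias. For each
miRNA *i* it models the normalized log2 array signal across a degradation
time course as

    y_i(s) = b_i + e_i * D(s) + noise,    D(s) = (10 - RIN_s) / 9,

and classifies miRNAs by integrating two experiments: a tissue/temperature
storage time course and a control design that hybridizes intact vs degraded
RNA (with/without DNase digestion) and small-RNA-depleted RNA fragmented
with RNase doses. The rule cascade separates:

* `resilient` — flat signal in degrading tissue (e ≈ 0);
* `sensitive` — signal lost with the tissue (e < 0);
* `likely_artifact` — signal gained with degradation **and** reproducible
  from small-RNA-free fragmented RNA (cross-hybridization);
* `dna_background` — signal appearing only when DNase digestion is omitted;
* plus `degradation_associated_unexplained` and `unclassified`.

Around the classifier the package provides the full pipeline: generalized-log
(variance-stabilizing) normalization, detection filtering, per-miRNA Pearson
screens against RIN and storage time with Benjamini–Hochberg control,
high- vs low-integrity Wilcoxon–Mann–Whitney differential expression with a
2-fold rule, complete-linkage clustering, miRBase version-era summaries, an
approximate-substring homology screen of mature sequences against transcript
sets (≥ 90 % contiguous overlap, ≤ 1 mismatch), and a ground-truth simulator
of both experimental designs for validation and power exploration.

## Worked example

Simulate the default study (900 miRNAs with latent classes
300 resilient / 200 sensitive / 300 artifact / 100 DNA-background;
48 time-course + 24 control arrays), analyze it, and compare the labels to
the simulated truth:

```r
library(mirdeg)

study   <- pipeline_simulate("sim_dir", sim_config(seed = 7))
summary <- pipeline_analyze("sim_dir", "out_dir")

str(summary$classification)
#> List of 6
#>  $ resilient                         : int 299
#>  $ sensitive                         : int 180
#>  $ likely_artifact                   : int 293
#>  $ degradation_associated_unexplained: int 1
#>  $ dna_background                    : int 110
#>  $ unclassified                      : int 17

str(summary$differential_expression)
#> List of 3
#>  $ n_significant: int 544
#>  $ n_up_in_low  : int 358
#>  $ n_down_in_low: int 186

truth <- read.delim("sim_dir/truth.tsv")
cls   <- read.delim("out_dir/classification.tsv")
recovery_metrics(cls, truth)$balanced_accuracy
#> [1] 0.945

pipeline_report("out_dir")   # renders out_dir/report.md
```

Reading the output: of 900 simulated miRNAs the cascade recovers the four
latent classes at 94.5 % balanced accuracy — 293 of the 300 planted
cross-hybridization artifacts are called `likely_artifact`, and the liver
high- vs low-RIN contrast finds 544 differentially expressed miRNAs, most of
them (358) *elevated* in the low-integrity samples, the signature of
fragment cross-hybridization rather than miRNA biology. Stage-level tables
(`correlation_*.tsv`, `de_liver.tsv`, `mirna_clusters.tsv`,
`classification.tsv`, `homology_hits.tsv`) and a JSON summary are written to
the output directory; `pipeline_report()` assembles them into a markdown
report.

For real arrays, read your own matrices with `read_expression_matrix()`
(TSV or GEO series-matrix format, with companion `.flags` detection tables),
metadata with `read_sample_metadata()`, and annotation with
`read_mirbase_annotation()`; see the methods vignette
(`vignettes/degradation-bias-methods.Rmd`) for the model, parameter
meanings, and the normalization caveats that matter in degradation designs.

A thin command-line wrapper lives at `inst/cli/mirdeg.R`
(`simulate` / `analyze` / `report` subcommands).

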