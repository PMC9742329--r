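# tmtsurface

Ratiometric extraction of cell-surface proteomes from multiplexed TMT
proximity-labeling experiments, with a moderated-t differential-enrichment
model for comparing developmental stages.

## The problem

Proximity labeling with a membrane-impermeant biotin-phenol substrate tags
proteins at the cell surface, but streptavidin enrichment always carries
along abundant intracellular contaminants. When the labeled samples and
negative controls (no peroxidase or no H₂O₂) are multiplexed in one 8-plex
tandem-mass-tag (TMT) run, each protein's experimental:control reporter-ion
ratio separates genuine surface labeling from background — a *ratiometric*
design. The remaining question is where to cut the ranked ratio list, and
how to compare two developmental stages measured in the same plex.

`tmtsurface` implements that workflow end to end:

1. **Evidence filter** — keep proteins with ≥ 2 distinct peptides and ≥ 2
   ratio counts.
2. **Median normalization** — divide each protein's eight channel
   intensities by their median, so every channel shares one denominator
   (pair ratios are unchanged by this step; the model below needs it).
3. **Pair ratios** — experimental/control per replicate pairing
   (default plex: 129C/127C and 128C/127N for the developing stage,
   130N/128N and 129N/126 for the mature stage).
4. **Annotation-anchored ROC cutoff** — proteins with a plasma-membrane
   localization annotation are true positives (TP); proteins with nuclear,
   mitochondrial or cytoplasmic annotation but no plasma-membrane term are
   false positives (FP). Ranking each replicate by descending ratio and
   accumulating TP/FP counts gives an ROC curve; the cutoff is placed where
   **J = TPR − FPR** is maximal. All proteins above the cutoff —
   including unannotated ones — are retained.
5. **Replicate intersection** — each stage's proteome is the intersection
   of its two replicates' post-cutoff lists (a stringent all-four-ratios
   variant is available).
6. **Differential enrichment** — per protein, an interaction linear model
   on log2 median-normalized values,

   `log2(value) = b0 + b1·MATURE + b2·TRT + b3·(MATURE×TRT)`,

   where `MATURE` indicates mature-stage channels and `TRT` labeled
   channels. `b3` is the stage difference in labeling enrichment,
   normalized by the in-plex negative controls. Residual variances are
   shrunk with an empirical-Bayes scaled-F prior `(d0, s0²)` estimated
   across proteins by digamma/trigamma moment matching; `b3 = 0` is tested
   with the moderated t on `d0 + 4` degrees of freedom, and p-values are
   Benjamini–Hochberg adjusted.

A seeded generator (`simulate_study()`) emulates the paired two-stage
design — compartment-dependent enrichment, per-stage effect modulation,
channel noise, and isobaric **ratio compression** (observed log2 ratio =
γ × true log2 ratio, γ ∈ (0, 1]) — so the whole pipeline can be exercised
against known ground truth without any download.

## Worked example

```r
library(tmtsurface)
library(dplyr)

sim    <- simulate_study(simulation_config(n_proteins = 1000, seed = 42))
quant  <- filter_evidence(sim$quant)
labels <- classify_localization(truth_to_annotation(sim), quant$accession)
class_counts(labels)
#> # A tibble: 1 × 3
#>    n_tp  n_fp n_unclassified
#> 1   163   480            343

normalized <- normalize_to_protein_median(quant, sim$design)
ratios     <- compute_pair_ratios(normalized, sim$design)
ext        <- extract_surfaceome(ratios, labels, sim$design)
ext$cutoffs
#> # A tibble: 4 × 7
#>   replicate threshold   tpr    fpr     j stage      n_retained
#> 1 129C/127C      1.47 0.902 0.0854 0.816 developing        220
#> 2 128C/127N      1.46 0.933 0.0833 0.849 developing        231
#> 3 130N/128N      1.55 0.902 0.0708 0.831 mature            209
#> 4 129N/126       1.52 0.914 0.0729 0.841 mature            203
glance(ext)
#> # A tibble: 1 × 5
#>   n_developing n_mature n_shared n_union strict
#> 1          140      144      116     168 FALSE
```

Each replicate's cutoff sits where ranking by ratio best separates
plasma-membrane from intracellular annotations (here J ≈ 0.82–0.85:
~90 % of TPs retained at ~7–9 % of FPs); intersecting replicates leaves
140- and 144-protein stage proteomes, 116 of them shared.

```r
fit <- fit_interaction_model(normalized, sim$design)
glance(fit)
#> # A tibble: 1 × 5
#>      d0   s0_2 n_proteins n_excluded n_significant
#> 1   Inf 0.0930        986          0             1
head(arrange(tidy(fit), q), 2)[, c("accession", "b3", "t_moderated", "q")]
#> # A tibble: 2 × 4
#>   accession    b3 t_moderated      q
#> 1 SIM00889   1.92        4.46 0.0824
#> 2 SIM00023   1.15        2.68 0.7799
```

The generator's channel noise is homoskedastic, so the variance prior
correctly collapses to `d0 = Inf` with `s0² ≈ 2·(0.3 log2-units)²`; `b3`
estimates recover the compression-scaled true interaction effects
(γ = 0.6 by default). `autoplot(ext)` draws the four ROC curves with
their operating points and `autoplot(fit)` the volcano plot.

`run_pipeline(pipeline_config(...))` performs all of the above from files
on disk and writes every intermediate (ROC curves, cutoffs, per-replicate
lists, stage proteomes, comparison report, differential table) plus a
manifest of stage-wise counts.

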