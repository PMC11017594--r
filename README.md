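# mvconsensus

Consensus multi-view feature selection for small-sample, paired multi-omic
case/control studies.

The motivating setting is a two-arm intervention study (9 subjects per arm)
with fecal samples profiled on three platforms — untargeted metabolite
intensities, 16S-derived bacterial genus counts, and host gene counts from
exfoliated intestinal epithelial cells — at baseline (day 0) and after
treatment (day 10). With hundreds of features per view and 18 samples, no
single selection method is trustworthy; `mvconsensus` implements a consensus
strategy: run three methods with different strengths, intersect their
selections, and augment the intersection with the redundancy the sparse
methods deliberately discard.

## The statistics

**MV screening** ranks each feature by the mean-variance index

    MV(x | y) = (1/n) Σ_j Σ_r p̂_r (F̂_r(x_j) − F̂(x_j))²

the class-weighted integrated squared gap between conditional and pooled
empirical CDFs — model-free, rank-based, and exactly 0 for a constant
feature. The top k (default min(300, p)) features are carried forward.

**Sparse linear discriminant analysis** estimates the direction

    v̂ = argmin_v  ½ v′Wv − d′v + λ‖v‖₁

with W the ridged within-group covariance and d the scaled group-mean
contrast, solved by coordinate descent with an exact active-set finish. The
penalty λ is chosen by leave-one-out cross-validation over a 50-point path
(standardization and W, d rebuilt inside every fold), keeping the sparsest
model that attains the minimal LOO misclassification count.

**Joint association and classification** couples 2–3 views through optimal
scores ỹ:

    F = Σ_d (1−α)/(2n) ‖ỹ − X_d w_d‖² + Σ_{d<d′} α/(2n) ‖X_d w_d − X_{d′} w_{d′}‖²
        + Σ_d λ_d ‖w_d‖₁

so selected features both discriminate the groups and carry correlated
signal across views. Block coordinate descent; a shared penalty multiplier
is selected by LOO.

**Consensus:** per view, features selected by all three methods form the
core; features correlated at |R| > 0.95 with the top-loading discriminant
feature, and the top third of joint-model selections by loading magnitude,
are added with provenance tags.

The package also ships the study-matched preprocessing (median
normalization, drug-feature removal, genus aggregation, prevalence
filtering, relative abundance, paired day10 − day0 differencing, log-CPM)
and a seeded synthetic three-view generator with planted ground truth, so
the whole workflow is testable end to end.

## Worked example

```r
library(mvconsensus)

study <- default_study_analogue()   # 18 subjects, 3 views, planted truth
res   <- run_pipeline(study)        # preprocess -> screen -> SDA -> joint -> consensus
res
#> pipeline_result
#>   metabolome: 4 consensus feature(s) (core 3), MGSDA LOO MCR 0.000
#>   microbiome: 6 consensus feature(s) (core 1), MGSDA LOO MCR 0.278
#>   exfoliome: 6 consensus feature(s) (core 6), MGSDA LOO MCR 0.000
#>   joint model LOO MCR 0.056
#>       view_1     view_2         r
#> 1 metabolome microbiome 0.9715089
#> 2 metabolome  exfoliome 0.9871061
#> 3 microbiome  exfoliome 0.9790491

res$consensus$microbiome$entries
#>   feature        provenance  anchor         r jaca_rank
#> 1 mic_027   selected_by_all    <NA>        NA        NA
#> 2 mic_006  correlate_of_top mic_027 0.9789833        NA
#> 3 mic_035  correlate_of_top mic_027 0.9545497        NA
#> 4 mic_109  correlate_of_top mic_027 0.9775270        NA
#> 5 mic_072 jaca_top_fraction    <NA>        NA         3
#> 6 mic_078 jaca_top_fraction    <NA>        NA         2

truth_metrics(res$features$feature, unlist(study$truth$informative))
#> sensitivity 0.345, FDR 0.375
```

Reading the output: each view gets a consensus table whose `provenance`
column says *why* a feature is in the model — selected by every method,
a near-duplicate (here |R| ≈ 0.95–0.98) of the top discriminant feature,
or a top joint-model loading with its rank. The per-view LOO
misclassification rates (MCR) estimate out-of-sample error of the selected
discriminants; the pairwise correlations are between the per-view sample
scores X_d w_d of the joint model — high values mean the three views carry
a shared group signal. On this analogue the microbiome consensus recovers
all 4 planted genera (one via the core, three via the correlation rule).
In the generator, every informative feature loads on a single latent
factor whose arms are 2 sd apart, so LOO MCRs near Φ(−1) ≈ 0.16 mean the
signal is fully used; the counts view's negative-binomial noise caps
feature-feature correlations well below the 0.95 augmentation threshold,
which bounds attainable sensitivity there (see the methods vignette).

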