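# mitoprofiler

Multiparametric phenotypic profiling for image-based RNAi screens that
link errors in mitosis to DNA damage in daughter cells.

High-content screens of mitotic regulators read out, per cell, nuclear
morphology, the DSB markers 53BP1 and γ-H2AX, p53 and EdU incorporation.
The phenotypes are heterogeneous — a perturbation shifts a readout in only
a fraction of cells, by variable amounts, across several correlated
features — so simple per-feature thresholds underestimate both magnitude
and penetrance. `mitoprofiler` implements the probability-based analysis
chain for such screens and ships a synthetic-screen generator with full
ground truth, so every estimator is validated by parameter recovery. It
is aimed at analysts of high-content microscopy screens and at method
developers who need a fully controlled test bed.

## The model

For each readout, a logistic-regression model trained on one siRNA's
cells (y = 1) versus control cells (y = 0) assigns each cell a
probability

π(x) = 1 / (1 + exp(−(w₀ + Σⱼ wⱼ x̃ⱼ)))

on features x̃ standardized by the training mean/sd, fitted by
ridge-stabilized IRLS (ridge 10⁻⁶ on weights, not the intercept). One
model is fitted per candidate siRNA; the ten best by training AUC form
the scoring ensemble — the ten siRNAs with phenotypes maximally different
from control, replacing designed positive controls. A cell's score is the
mean of the member probabilities; a population's score is the mean of its
cells' scores, reflecting both magnitude and frequency of the phenotype.
Training is leave-one-replicate-out (with three replicates, each fold
trains on ≈66% of cells) so all reported scores are out-of-sample. Each
siRNA gets a statistics panel versus control: t-based 95% CI,
Kolmogorov–Smirnov normality flag on standardized scores, two-sided
Mann–Whitney U, Hedges' g and AUC, plus a DeLong test for comparing
ROC curves. Downstream, per-target five-readout probability profiles are
clustered by k-means (k-means++ starts, best of 50 restarts, silhouette
selection of k), and time-lapse trajectories are turned into
control-normalized time courses classified as mitosis-first (morphology
≥ 3-fold over control first), ddr-first (DNA damage ≥ 1.5-fold first) or
mild, with S-phase and mitotic-duration estimators.

## Worked example

Generate a small synthetic screen (6 targets × 2 siRNAs × 3 replicates,
~120 cells per well), score the 53BP1 readout with held-out replicates,
and build the per-siRNA report:

```r
library(mitoprofiler)

cfg <- screenConfig(nTargets = 6, meanCellsPerSirna = 120, seed = 1)
scr <- generateFeatureTable(cfg)
scored <- crossvalidate(scr$cells, "NEG", "b53bp1")
rep <- populationReport(scored, "NEG")
rep[, c("sirna_id", "n", "mean", "hedges_g", "auc", "mwu_p")]
```

```
   sirna_id   n  mean hedges_g   auc     mwu_p
1    T01_s1 439 0.311   0.1763 0.539  4.73e-02
2    T01_s2 430 0.298   0.0818 0.532  9.95e-02
3    T02_s1 346 0.348   0.4354 0.626  1.08e-09
4    T02_s2 382 0.336   0.3608 0.610  4.86e-08
5    T03_s1 300 0.816   4.0307 0.986 4.78e-112
6    T03_s2 297 0.717   2.8596 0.963 1.76e-101
7    T04_s1 192 0.923   6.3855 0.998  2.07e-88
8    T04_s2 235 0.851   4.5652 0.989  1.08e-97
9    T05_s1 443 0.303   0.1200 0.539  4.31e-02
10   T05_s2 469 0.303   0.1176 0.526  1.68e-01
11   T06_s1 302 0.380   0.6477 0.690  9.89e-19
12   T06_s2 364 0.345   0.4441 0.647  5.67e-13
```

The generator planted four phenotype archetypes. T01/T05 (mild) stay near
the control score with g ≈ 0.1 and AUC ≈ 0.53; T03 and T04 carry strong
planted DSB phenotypes and score 0.72–0.92 with g ≈ 3–6 and AUC ≈ 0.96–1;
the weaker second siRNA (\_s2) of each pair scores consistently below the
first, as planted. Note also the smaller n for T03/T04 — their planted
mitotic-error strength couples to reduced proliferation. The full
pipeline (generation → scoring of all five readouts → clustering →
temporal classification, with all artifacts on disk) runs with:

```r
report <- runPipeline(runConfig(screen = cfg, outputDir = "run1"))
```

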