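---
title: "Probability-based phenotypic profiling of mitotic-error screens"
author: "mitoprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probability-based phenotypic profiling of mitotic-error screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Errors in mitosis — chromosome missegregation, cytokinesis failure,
mitotic delay — can translate into DNA double-strand breaks (DSBs) in the
daughter cells. Image-based RNAi screens probe this link by depleting
mitotic regulators (here modelled after a 47-target, two-siRNAs-per-target,
three-replicate screen in U-2-OS cells) and reading out, per cell, five
markers: nuclear morphology (DAPI / H2B), 53BP1 foci and γ-H2AX (DSB
markers), p53 (stress response) and EdU incorporation (DNA replication).
The analytical challenge is that phenotypes are heterogeneous: a
perturbation may shift a readout in only a fraction of cells, by variable
amounts, across several correlated features. `mitoprofiler` implements the
full analysis chain for such screens, and ships a synthetic-screen
generator with complete ground truth so that every estimator can be
validated by parameter recovery rather than by eye.

## The probability-scoring model

For each readout, every cell is summarized by a feature vector
$x = (x_1, \ldots, x_k)$ ($k = 7$ for morphology, 3 for 53BP1, 10 for
γ-H2AX, 2 each for p53 and EdU). A logistic-regression (LR) model trained
on one siRNA's cells (class $y=1$) against control cells ($y=0$) assigns

$$\pi(x) = \frac{1}{1 + e^{-(w_0 + \sum_j w_j \tilde x_j)}},$$

where $\tilde x$ is standardized by the training mean and sd. Weights
maximize the Bernoulli likelihood via iteratively reweighted least squares
(IRLS; convergence when the largest weight change falls below $10^{-8}$,
cap 100 iterations). A ridge penalty of $10^{-6}$ on the feature weights
(never the intercept) keeps weights finite under complete separation while
being numerically indistinguishable from plain maximum likelihood
otherwise.

One model is fitted per candidate siRNA; models are ranked by their
training AUC and the ten best — the ten siRNAs with phenotypes maximally
different from control — form the scoring ensemble. This removes the need
for pre-designed positive controls. A cell's probability score is the
arithmetic mean of the member probabilities; a population's score is the
mean of its per-cell scores, so the score reflects both the magnitude and
the frequency of the phenotype. Training uses leave-one-replicate-out:
with three replicates each fold trains on about 66% of the cells and
scores only the held-out replicate, so reported scores are always
out-of-sample. Where the combination rules were not prescribed
(ensemble combination, population aggregation), we chose the unweighted
mean as the simplest symmetric statistic and document it here; ranking
"strongest phenotypes" uses training AUC because ROC ranking is the stated
selection criterion, with ties broken by larger training sample and then
siRNA id so selection is deterministic.

Per siRNA, the statistics panel reports mean, sd, sem, IQR, a Student-t
95% CI for the mean, a two-sided Kolmogorov–Smirnov goodness-of-fit test
against the standard normal, the two-sided Mann–Whitney U test versus
control, Hedges' g (pooled-sd effect size, no small-sample correction, so
numerically Cohen's d), and the AUC separating the siRNA's scores from
control's. Because probability scores live on $[0,1]$, a standard-normal
reference only makes sense after standardization; the KS test is therefore
applied to $(s - \bar s)/\mathrm{sd}(s)$. This is our documented reading
of an ambiguous convention, not an assertion about the original one. The
Mann–Whitney test uses exact enumeration for small samples and the
normal approximation with continuity and tie correction otherwise
(`stats::wilcox.test`'s policy). P-values are reported raw, with a
Bonferroni column added for convenience. The DeLong test (placement-value
covariance of paired AUCs, two-sided z-test) is provided to verify that
growing the ensemble beyond ten models does not buy discrimination.

## The synthetic screen generator

The generator is first-class, tested code: its defaults *are* the study
conditions, and all recovery tests measure against its planted truth.

**Feature tables.** Control cells draw intensity-type features from
log-normal distributions, shape features from normals, and focus counts
from Poisson rates — distributions chosen for positivity and realism since
none are prescribed. A treated condition shifts each readout's features by
a standardized mean shift $\delta$ (applied on the log scale for
log-normal features) and multiplies focus-count rates by
$e^{0.4\delta}$. The 47 targets are assigned round-robin to four
archetypes (mild; mitotic-dominant; mitotic with strong DDR; strong
combined) with deterministic within-archetype jitter, so planted effect
magnitudes are graded — this is what makes Spearman-type recovery checks
meaningful. The second siRNA per target applies 0.8 of the first's shift,
emulating imperfect on-target concordance. Cell counts per well are
Poisson; anti-proliferative conditions are thinned by
$e^{-0.3\,\delta_{\mathrm{morphology}}}$, and the Poisson baseline is
calibrated so the *screen-wide* mean matches the configured 700 cells per
siRNA — the stated average is a property of the whole screen, while
strong mitotic phenotypes still show proportionally fewer cells.

**Images.** Nuclei are rendered as rotated ellipses with a flattened
ellipsoidal intensity profile, foci as Gaussian blobs planted at recorded
coordinates, followed by a 1-px Gaussian point-spread blur and additive
camera noise, clipped to 16-bit. Foci within one nucleus keep a minimum
separation (6 px): merged blobs are unresolvable by any detector at this
scale, and the generator models discrete resolvable repair foci. The
label map and focus list are the ground truth for segmentation and
detection tests.

**Trajectories.** Each trajectory follows one cell through one cycle on a
30-min frame grid over 72 h: G1, S (PCNA-like pattern), G2, one mitosis
carrying the planted delay, then interphase/binucleation, with optional
death (absorbing) and a planted DDR-onset time after which 53BP1 counts
jump. Control S phases are Normal(16 h, 1 h) — the 16 h centre is the
observed control S-phase duration; the 1 h sd is a free choice, as no
dispersion is reported. Cells that already passed $k$ aberrant mitoses
carry an S-phase extension of $(2^k - 1)\cdot$`s_extension_h`; with the
KIF23-like default of 2 h this reproduces 16 → 18 → 22 h after the first
and second aberrant mitosis. A configurable 5% per-frame misclassification
rate corrupts observed states; it exists precisely to exercise the
smoothing in the duration estimators.

## Feature extraction

Nuclear masks come from the DAPI channel: Otsu (or fixed) threshold, hole
filling, watershed on the distance transform to split touching nuclei,
area gating, and removal of border-touching objects (their features would
be truncated; the original protocol is silent, so this is our choice).
Focus detection is a white top-hat with a disk structuring element
(default radius 5 px ≈ 1.6 µm at 0.32 µm/px — sized to pass typical 53BP1
foci; the original radius is unstated), thresholded per nucleus at
median + 3·MAD of the response with an absolute floor of 2000 camera
units (the shallow dome/rim response of a smooth nucleus never reaches
it), and split at response saddles by a watershed (tolerance 3000).
Per-nucleus features follow fixed definitions: perimeter by
boundary-pixel contour length; cell length/breadth as the major/minor
axes of the intensity-weighted second-moment ellipse; elliptical form
factor = length/breadth; integrated = average × area exactly. The
γ-H2AX "minimum/maximum average intensities" are implemented as the
per-nucleus extrema of the 3×3-mean-filtered channel — the original
definition is ambiguous and this reading is flagged here. The mitotic
γ-H2AX score thresholds average DAPI intensity to isolate condensed
mitotic chromatin and averages the per-cell summed focus intensities.
Coordinates are 0-based (row, column); areas in pixels; intensities in
camera units.

## Clustering and concordance

Per-target five-variable probability profiles (the combined
mitotic-phenotype score is the morphology readout's score; the five
variables are morphology, 53BP1, γ-H2AX, p53, EdU, from siRNA #1) are
clustered by k-means: Lloyd iterations from k-means++ starts, best of 50
restarts by WCSS, empty clusters re-seeded from the farthest point.
Profiles are probabilities on a common $[0,1]$ scale, so no feature
scaling is applied. Labels are renumbered by descending centroid norm so
the highest label is the strongest combined phenotype — a presentation
convention only. Since the original fixes k = 4 without a criterion,
`chooseK` scores candidate k by mean silhouette width; on profiles with
four well-separated planted groups it recovers k = 4. siRNA #1 / #2
concordance uses the Pearson product-moment correlation with a Fisher-z
CI and the t-test for zero correlation.

## Temporal profiling

Per frame, the composite morphology value is the unweighted sum of the
fractions of aberrant, mitotic and dead cells ("aggregated" is
unspecified; the sum preserves additivity of event fractions), normalized
to control frame by frame with the control floored at $\varepsilon =
10^{-3}$ to keep early-time folds finite. The DNA-damage course is mean
53BP1 foci per interphase cell, control-normalized; frames with no
interphase cells carry the previous value forward with a warning.
Conditions split into mitosis-first (morphology reaches 3-fold over
control first), ddr-first (DNA damage reaches 1.5-fold first) and mild
(neither crossed); a tie counts as mitosis-first (our documented
tie-break). The heat map places the mild group on top and sorts within
groups by the first time point with increased DNA damage, which we read
as the 1.5-fold crossing — the same threshold that defines the grouping.
Colors anchor white at each series' own mean, blue below (control = 1
included), red above. Duration estimators median-filter the per-frame
indicator (window 3) and take the longest contiguous run times the frame
interval: exact on noiseless trajectories, robust to isolated
misclassified frames, and applied to both the S-phase and the mitotic
estimators since both face the same 5% frame noise. Replication
asymmetry in binucleated cells is the absolute difference of the two
nuclei's S-start times.

## Problem sizes and what the tests show

The test suite validates on synthetic screens of 6–8 targets with ~60–120
cells per well for unit-level checks, and on the full default screen
(47 × 2 × 3, ~700 cells per siRNA, ~200,000 cells) for end-to-end
parameter recovery: Spearman rank correlation ≥ 0.8 between planted
per-readout effect sizes and held-out population scores (in practice
≈ 0.99), chance-level AUCs on all-null screens, and no Bonferroni-level
false positives under the null. Focus detection reaches exact per-nucleus
count agreement on fields of 100 nuclei with Poisson(4) foci under
moderate noise. These results show the estimators are correct and
well-calibrated *under the generator's assumptions*. Real screens add
what the generator deliberately omits: correlated features within a
readout, spatially varying illumination and focus drift, segmentation
errors on clumped or apoptotic nuclei, batch effects between replicates,
and cell-cycle-dependent marker baselines. Passing these tests therefore
certifies the analysis chain, not the biology of any particular screen.

## Known limitations

* Fixed-image analysis covers interphase and mitotic cells; dying cells
  are handled only in the live-cell (trajectory) arm.
* Trajectories follow one cell through a single cycle; lineage tracking
  across divisions is out of scope.
* The ensemble is selected per readout; a global selection across
  readouts is a plausible alternative we did not take.
* Whether ensemble standardization should pool all conditions' cells is
  unstated; each model standardizes by its own training cells.
* The k-means profiles are left unscaled; if readouts had very different
  dynamic ranges on $[0,1]$, scaling could change memberships.
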