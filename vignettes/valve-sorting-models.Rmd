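---
title: "Models behind icasort: rare-cell evaluation, valve-coincidence sorting, and SNP purity"
author: "icasort authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models behind icasort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icasort)
```

# Scope

`icasort` models the computational core of an image-activated cell sorter at
desk scale. On the real instrument a convolutional network classifies
brightfield images of cells in flow and a pair of pneumatic microvalves
diverts selected cells into a collection reservoir. Nothing in this package
touches images, networks or hardware; instead, synthetic class-conditional
classifier scores stand in for the trained model, and the package implements
the quantitative machinery wrapped around such a classifier:

* in silico evaluation of rare-cell detection (ROC curves and
  precision–recall curves reweighted to extreme target proportions),
* an event-driven stochastic simulation of valve sorting with coincidence
  capture, dead time and arrival-prediction jitter,
* estimation of sorted-pool purity and fold enrichment from SNP-panel allele
  fractions, and
* the embedding-clustering annotation workflow used to build training sets.

# The synthetic score model

A trained classifier's softmax outputs are unknowable without the trained
network, so `ScoreModel` generates a parametric stand-in: for a cell of true
class $c$, a logit vector is drawn as $z \sim N(\mu_c, \sigma^2 I_K)$ and
pushed through softmax. By default $\mu_c$ puts a margin $s$
("separability", default 4) on the own-class coordinate and 0 elsewhere,
with $\sigma = 1$ (`logitScale`). Two limits anchor the parameterisation:
$s = 0$ makes all classes exchangeable (expected score $1/K$ each), and
large $s$ makes the argmax recover the true class almost surely. One-vs-rest
AUC between two classes is monotone in $s$, which the test suite checks by
simulation under common random numbers.

This family is a deliberate stand-in: real CNN score distributions are
unknown and nothing downstream is allowed to depend on matching any
particular printed AUC. What the package validates are *identities* —
reweighting formulas, coincidence arithmetic, estimator consistency — which
hold for any score distribution; the Gaussian-logit family merely provides a
controllable test bed.

Quality classes (`debris`, `out_of_focus`) are ordinary classes with their
own mixture fractions. `circulatingPreset()` reproduces a realistic stream
composition (39.01% out-of-focus, 6.57% debris), so that quality filtering
(`filterEvaluable()`) retains an evaluable fraction of 0.5442 in
expectation.

Embeddings are isotropic Gaussian clouds around per-class centroids
(`sampleEmbeddings()`); anisotropic covariance is out of scope. Arrival
streams are homogeneous Poisson; the mild regularisation that inertial
microfluidic focusing imposes on real interarrival times is ignored (see
*Limitations*).

# Rare-mixture precision–recall reweighting

TPR and FPR at a threshold are properties of the class-conditional score
distributions alone. For a mixture with target proportion $\pi$, Bayes'
rule gives

$$\mathrm{precision}(t) =
  \frac{\pi\,\mathrm{TPR}(t)}{\pi\,\mathrm{TPR}(t) + (1-\pi)\,\mathrm{FPR}(t)},
  \qquad \mathrm{recall}(t) = \mathrm{TPR}(t).$$

`mixturePRCurve()` applies this pointwise to an empirical ROC. Reweighting
is the default because physically subsampling a 1:100,000 mixture with
useful resolution needs $\ge 10^7$ cells; `resampleMixture()` constructs an
explicit mixture (background resampled to exactly $(1-\pi)/\pi$ cells per
target) and `empiricalPRCurve()` counts it directly, so the two routes
cross-validate each other. The tests compare them at $\pi = 10^{-2}$ and
$10^{-3}$ with $10^5$-cell mixtures at matched score cutoffs.

Numerical conventions, chosen once and applied everywhere: thresholds sweep
the distinct score values in descending order starting at $+\infty$, so
every curve runs from (0,0) to (1,1); tied scores move between thresholds as
a block; AUC is the trapezoidal integral, which under tie-grouping equals
the Mann–Whitney pair statistic with half credit for ties; at the degenerate
all-negative threshold precision is defined as 1; argmax ties in the
confusion matrix break by class-name sort order. "AUC" always means ROC-AUC
here; PR curves are reported alongside but never summarised into a single
headline number.

# The valve-coincidence sorting model

Arrivals are Poisson at total rate $\lambda$ (configured in cells/minute,
converted to per-ms). A cell whose selection score clears the decision
threshold triggers a valve opening of length $w$ — unless the valve is
already open (a coincident target is collected but does not retrigger) or
the post-window dead time has not elapsed. Quality-class cells do not
trigger by default, mirroring the use of debris/out-of-focus calls for
sample-quality reporting rather than sorting.

The valve opens centred on the *predicted* arrival of the triggering cell:
in real time the window is $[t - e - w/2,\; t - e + w/2]$, where the
prediction error $e$ is zero-mean Gaussian with scale `jitterScaleMs`. The
triggering cell is therefore captured iff $|e| \le w/2$, and *every* cell
arriving inside an open window is collected — the coincidence mechanism
that sets the purity/yield tradeoff.

In the rare-target, zero-jitter, zero-dead-time limit each window collects
its target plus on average $\lambda w$ contaminants, giving the closed form

$$\mathrm{purity} \approx \frac{1}{1 + \lambda w},$$

implemented in `analyticCoincidencePurity()` and used as the simulation's
oracle. At 3000 cells/min and $w = 15$ ms, $\lambda w = 0.75$ and the
expected purity is $1/1.75 \approx 0.571$.

The hardware description gives no mechanism for yield loss, so the package
takes a position: yield loss arises from arrival-prediction jitter against
window coverage. The capture probability is $2\Phi(w/2\sigma) - 1$, and
`jitterForCapture()` inverts it; $\sigma \approx 5.85$ ms makes a 15 ms
window capture ~80% of triggering targets. This calibration reproduces the
~80% yield / ~60% purity operating point as a *demonstration* of the model,
not a validation — the printed operating point may also contain latency and
dead-time losses the hardware description does not quantify. Dead time
defaults to 0 (real valve pairs have refractory periods, so it is exposed);
"purity" counts every collected non-target cell as a contaminant, including
quality classes.

Problem sizes: the test suite simulates $2\text{–}3 \times 10^5$ arrivals
per check (Monte-Carlo SE on purity well under one point), and the
acceptance script uses $3 \times 10^6$ arrivals at a 1:1000 target
fraction, its results reported next to the analytic value. Monotonicity
checks (purity non-increasing, yield non-decreasing in $w$; purity
non-increasing in $\lambda$) run under common random numbers: within a rate
all windows share a seed, and because exponential interarrivals scale
inversely with the rate the same underlying draws recur across rates.

# SNP-panel purity estimation

A pool containing a fraction $p$ of target cells has expected
alternate-allele fraction

$$f_i = p\,g_{t,i} + (1-p)\,g_{b,i}$$

at variant $i$, with known dosages $g \in \{0, \tfrac12, 1\}$ under an
equal-ploidy, copy-neutral assumption (CNV-aware dosages are out of scope).
Only informative variants ($g_t \ne g_b$) constrain $p$.
`estimatePurity()` maximises the binomial likelihood
$\prod_i \binom{d_i}{a_i} f_i^{a_i} (1-f_i)^{d_i - a_i}$ over those
variants — robust to depth variation, unlike averaging per-variant
fractions — by bounded scalar search on $[0,1]$ polished with Newton steps
on the score function (tolerance $10^{-8}$); the SE comes from observed
Fisher information and the Wald 95% interval is truncated to $[0,1]$ with a
clamping flag. A depth-weighted least-squares fallback
(`estimatePurityWLS()`) serves depth-free fraction inputs; with depth
weights it coincides with the MLE on hom-alt/hom-ref panels. For a single
homozygous-target/reference-background variant the MLE reduces to the
sample fraction — a pool at 23% purity shows the target's private mutation
at 23% allele fraction, and conversely.

`sampleAlleleCounts()` draws per-variant depth as Poisson around the mean
depth, then the alternate count binomially — depth is a sequencing average,
not a constant. Parameter recovery is checked at 50 informative SNPs ×
depth 1000 over $p \in \{0.01, 0.1, 0.23, 0.5, 0.9\}$ (200 replicates per
level; bias under 0.01, CI coverage between 0.90 and 0.99).

`enrichmentReport()` reports fold enrichment as the purity ratio with a
delta-method CI; `foldEnrichment()` is the bare ratio of a post-sort purity
to a pre-sort fraction. Because how a pre-sort fraction was measured (flow
counting vs nominal spike ratio) changes the headline fold, reports should
carry both nominal and estimated pre-fractions when both exist.

# Annotation workflow

`hierarchicalClusters()` wraps deterministic agglomerative clustering
(average linkage; Euclidean metric by default, cosine exposed because CNN
embeddings are often directionally structured — the linkage/metric choice
is otherwise unconstrained and was fixed once). Cluster ids are dense
1-based integers. Label vocabularies are lineage forests
(`LabelTaxonomy`), so a cell may carry every annotation along its lineage
path. Constraints (`LabelConstraint`) are serialisable field-equality rules
on sample metadata rather than arbitrary predicates, so a session
round-trips losslessly through its JSON sidecar; the canonical example
disallows fetal cell classes for non-pregnant adult donors.
`batchAssign()` labels whole clusters with per-cell overrides, records
batch/override provenance, and is atomic: a single disallowed label rejects
the entire call naming the offending cell. `labelerMismatch()` flags QC
only when the inter-labeler disagreement rate *strictly exceeds* 5%: 5
disagreements in 100 pass, 6 do not. `mineHardExamples()` ranks a weaker
model's misclassifications by its confidence in the wrong call (its score
for its own argmax) and truncates to a per-class quota. The second
annotation mode — proximity to previously labeled cells — is
`suggestLabels()`: nearest-labeled-neighbour suggestions gated by a
distance ceiling (default the 90th percentile of within-cluster pairwise
distances), advisory only.

# What the synthetic generators do and do not show

The generators emulate the *statistical interfaces* the methods consume:
simplex score vectors with controllable class overlap, Poisson arrival
streams, Gaussian embedding clouds, binomial allele counts. They do not
emulate real CNN score distributions (typically far from Gaussian in logit
space), correlated arrivals under inertial focusing, embedding manifolds
with within-class structure, or sequencing artifacts (strand bias, mapping
error, contamination). Passing tests therefore demonstrate that the
evaluation, sorting and estimation machinery is *correct* — identities
hold, estimators recover truth, simulations match closed forms — not that
any particular instrument or model attains any particular performance.
Printed performance figures of a trained classifier (confusion diagonals,
selection AUCs) are properties of that classifier and its validation images
and are deliberately not reproduction targets here.

# Degenerate inputs and edge conventions

* Empty draws (`n = 0`) return empty containers with the right shape.
* A zero-length valve window captures exactly the triggering cell.
* `operatingPoint()` returns an explicit "unattainable" result rather than
  an error when no threshold meets the precision floor.
* Score rows off the simplex by up to $10^{-6}$ are accepted, up to
  $10^{-3}$ renormalised with a warning, beyond that rejected.
* VCF panels keep biallelic SNVs only; multi-allelic, indel and
  missing-genotype records are skipped and counted.
* All randomised operations take an explicit seed, restore the caller's RNG
  state, and derive child streams with `childSeed()` (Lehmer step modulo
  $2^{31}-1$), so every report can be reproduced bit-for-bit from its
  recorded configuration.

# Limitations

* The arrival process is homogeneous Poisson; real microfluidic focusing
  regularises interarrivals, which would *raise* purity slightly at a given
  rate relative to this model.
* Yield loss is attributed entirely to prediction jitter; classification
  latency and valve actuation delays are not modeled separately.
* The score family is a stand-in; absolute AUC or precision values produced
  from it characterise the synthetic model only.
* Dosage arithmetic assumes copy-neutral diploid genomes; amplified or
  deleted regions violate $f = p\,g_t + (1-p)\,g_b$.
* Annotation clustering operates on synthetic embeddings; the feature
  source of a production annotation pipeline (pre-trained CNNs) is not
  reproducible here.
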