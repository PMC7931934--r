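---
title: "Annual plantation mapping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annual plantation mapping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantmapr)
```

## The problem

Tropical plantation expansion (oil palm, timber, rubber) is a leading
driver of deforestation in Southeast Asia, and monitoring it requires
maps at annual resolution. Manually interpreted reference products exist
only for scattered epochs and carry complementary error structures: a
single-epoch tree-plantation mask tends to cover most real plantations
but includes much that is not plantation (high recall, low precision),
while detailed anchor-year land-cover maps are conservative (high
precision, low recall). `plantmapr` implements a pipeline that learns
from such imperfect labels and multi-temporal satellite reflectance to
produce yearly plantation maps, together with a synthetic scene
simulator so that every stage can be exercised and tested without any
external data.

A pixel-year is described by 46 eight-day reflectance composites in 7
spectral bands (the MOD09A1 convention at 500 m), concatenated
composite-major into a 322-length feature vector.

## Class taxonomy and aggregation

Labels come from a 19-type land-cover taxonomy. Each type aggregates to
one of three classes used for learning: plantation (P: oil palm, timber,
rubber), forest (F: disturbed upland, undisturbed upland, undisturbed
swamp forest), and other (O: the remaining 13 types). Forest is kept
separate from "other" for two reasons: mature plantations are
spectrally closest to forest, so this is the hard boundary worth its own
classifier; and forest-to-plantation conversion is the quantity of
ecological interest. The aggregation is row-by-row over the taxonomy
table, not by high-level class — notably, rubber plantation sits under
the *Agriculture* high-level class yet aggregates to plantation, and the
*Disturbed forest* high-level class splits between F (disturbed upland
forest) and O (disturbed mangrove and swamp forest). The mapping ships
as a packaged CSV, so alternative taxonomies with the same column
contract can be substituted; totality over the codes is enforced
strictly.

Additional schemes are available for the baseline variants: binary
(P vs nonP), four-class (bare soil carved out of O), the nine high-level
classes, and the 19 types themselves.

## The pairwise ensemble

For a k-class scheme, `train_ensemble()` fits k(k−1)/2 binary
classifiers, one per unordered pair of labels, each trained only on
samples of its two classes. At prediction time each classifier casts a
vote and `aggregate_votes()` returns the unique majority label; when the
maximal vote count is tied (for three classes: the three classifiers
mutually disagree) the pixel-year is labeled Unknown (U). For the
three-class scheme this reproduces the full 8-row vote table, including
both U rows, and the tests verify it by exhaustive enumeration. U is an
honest abstention, not a land-cover class; the evaluation treats it as
non-plantation, since the quantity of interest is plantation coverage.

Classifier backends are pluggable behind a two-function contract
(`fit_backend()` / `predict_backend()`):

* `mlp` (default): a feed-forward network 322 → 158 → 64 → 20 → 1
  logit with ReLU activations, trained full-batch by Adam on the
  logistic loss (150 epochs, step 5e-3, L2 1e-4). The hidden sizes
  158-64-20 are the architecture the method was designed around; the
  original formulation used generatively pre-trained deep belief
  networks, but no pre-training protocol is specified anywhere, so
  plain gradient training is the package's choice and is sufficient on
  the synthetic scenes.
* `svm`: an RBF-kernel SVM (via `e1071`), the margin-based baseline.
* `logistic`: ridge-regularized logistic regression, a fast linear
  reference used widely in the test suite.

Features are standardized per spectral band (seven means and standard
deviations pooled over the 46 composites), fitted on the training set
only and stored with the model. Votes are hard labels; no probability
thresholds enter the aggregation. All stochastic steps (weight
initialization, sampling) are seeded, and identical seeds give
identical models.

## Subclass-balanced sampling

Land-cover frequencies are severely skewed (two classes cover half the
region), so uniform sampling within an aggregated class lets the common
subclasses dominate training and starves exactly the rare subclasses —
such as open shrub or grassland patches — that most resemble young
plantations, inflating commission error. `balanced_sample()` therefore
draws the *same* number of pixel-years from every 19-type subclass,
across all available years; `uniform_sample()` implements the baseline
that splits the total equally over aggregated classes but ignores
subclasses. Subclasses smaller than the requested draw are sampled with
replacement and flagged in the result metadata, which preserves exact
balance while keeping the fallback auditable. Train/test splits are by
pixel — every year of a pixel falls on the same side — to avoid
temporal leakage; the strategy comparison in the acceptance suite shows
the balanced draw yielding higher overall precision than the uniform
baseline under a scene containing a rare plantation-mimicking "other"
subclass.

## Temporal smoothing

The ensemble labels each pixel-year independently, so a pixel's yearly
sequence can contain transitions that are implausible on the ground —
most importantly plantation reverting to forest, which essentially does
not happen on annual timescales. `smooth_map()` post-processes each
pixel's sequence with a hidden Markov model: latent states are
land-cover classes (19 types by default; 9 high-level or 3 aggregated
classes as variants), observations are the yearly P/F/O/U labels, and
decoding is by the Viterbi algorithm, returning the most probable latent
path mapped back to P/F/O.

`default_hmm()` builds the parametric model:

* **Transition**: self-transition `rho` (default 0.9/yr) on the
  diagonal; the remaining mass spread uniformly; every
  plantation-to-forest entry capped at `delta` (default 1e-6) and rows
  renormalized. The cap (rather than an unconditional overwrite) means
  `rho = 1` still yields the identity matrix.
* **Emission**: probability `q` (default 0.9) on the latent class's own
  aggregated label — a direct model of classifier accuracy; a small
  constant mass `u_mass` (default 0.02, capped at `1 − q`) on the U
  observation, *identical across latent classes* so that a U is
  uninformative about the latent state (U records classifier
  disagreement, not a land cover); the remainder split over the other
  two labels.
* **Initial**: uniform over latent classes.

With these defaults, the sequence F, F, P, P, F, P decodes to
F, F, P, P, P, P: the isolated forest dip inside an established
plantation is corrected, because explaining it as a real
plantation-to-forest-to-plantation excursion costs a `delta` transition
while explaining it as a one-year label error costs only `1 − q`. The
test suite verifies Viterbi decoding against brute-force enumeration of
all latent paths for every short observation sequence and all three
latent spaces.

Design choices worth recording:

* Decoding defaults to joint MAP (Viterbi), not per-year posterior
  marginals, because the correction of interest is sequence-level
  consistency; per-year posterior decoding (forward–backward argmax) is
  available via `smooth_map(..., method = "posterior")`. Ties are
  broken toward the lowest latent-class index (taxonomy order), so
  decoding is deterministic.
* Binary-scheme maps emit `nonP`, which the decoder accepts as the
  union event "F or O" (summed emission likelihood), so every scheme
  variant can share the same post-processing; a binary run's smoothed
  map is collapsed back to P/nonP. Comparisons between learning
  strategies in the acceptance suite are therefore full pipelines that
  differ only in the factor under study.
* For the nine-class latent space, a high-level class can mix
  aggregated labels among its subclasses; each is assigned the
  aggregated label holding the majority of its published 2000 pixel
  count (Disturbed forest → F, Agriculture → O). This is a declared
  convention — nothing in the source material defines it.
* `estimate_transitions()` provides maximum-likelihood annual
  transition estimates (with pseudocount smoothing) from yearly truth
  sequences, available in simulation. Annualizing transitions observed
  only across multi-year anchor gaps (a matrix-root problem) is out of
  scope; when yearly truth is unavailable the parametric
  `default_hmm()` is the supported route.

## The synthetic scene

`simulate_scene()` generates the full study universe: ground truth,
reflectance, and both reference products, bit-identically reproducible
from the config seed.

* **Land-use change** is a per-pixel independent Markov chain over the
  19 types. The default initial mix mirrors the relative class
  frequencies published for the mapped region in 2000 (plantations
  ≈ 4–5% of pixels), and default conversion rates (logging,
  plantation establishment from disturbed forest, shrub land and
  cropland; no reversion) grow total plantation area by roughly 8% per
  year over the anchor span, decelerating thereafter — the same order
  as the region's published 2000–2009 trajectory of about 10% per
  year.
* **Reflectance** per pixel-year is a per-class harmonic:
  `mu + amp * sin(2*pi*t/46 + phase)` per band plus Gaussian noise
  (default SD 0.03, a typical composite-level residual for 500 m
  surface reflectance), clipped to [0, 1]. Signatures encode the
  landscape's qualitative structure — forest dark-visible/bright-NIR
  and aseasonal, cropland strongly seasonal, plantation intermediate —
  and upland grassland is deliberately parameterized close to young
  plantation so the scene contains the rare plantation-mimicking
  subclass that motivates balanced sampling.
* **Reference products**: the TP-like mask keeps true plantations at
  the mask epoch with probability `1 − tp_fnr` (default 0.95) and adds
  non-plantations with probability `tp_fpr` (default 0.10) — high
  recall, low precision; the RSPO-like anchor-year maps (2000, 2005,
  2009) drop true plantations at rate `rspo_fnr` (default 0.30) and
  flip non-plantations at rate `rspo_fpr` (default 0.01) — high
  precision, low recall. The real products' error rates are not
  characterized numerically anywhere, so these defaults are declared,
  user-tunable choices, and the tests verify only that configured rates
  are recovered empirically within binomial bounds.

What the simulator deliberately does **not** model: spatial
autocorrelation of change or of noise, clouds/missing composites, mixed
pixels, sensor drift, or label noise in the *training* pool (training
labels come from the simulated truth). Passing tests therefore
demonstrate correctness of the algorithms and the claimed qualitative
orderings under these idealized conditions — not performance on real
imagery.

## Evaluation protocol

Because neither reference product can serve as a full ground truth, the
metrics use each where it is strong:

* **Yearly recall**: a pixel-year is a *confident plantation location*
  if the anchor-year maps label the pixel plantation at both ends of a
  consecutive anchor pair; it is confident for every year of that
  interval, inclusive. Yearly recall is the detected fraction of these
  locations (U counts as not detected).
* **Overall precision**: of all pixels predicted plantation in any year
  of the detection window, the fraction inside the high-recall mask.
* **Overall recall**: of all pixels the anchor-year map labels
  plantation at the last anchor year, the fraction the method detects.

The detection window defaults to the second predicted year through the
last. `pixels_to_area()` converts counts at 500 m (0.25 km² per pixel);
`area_1e3_km2()` applies the half-up two-decimal reporting convention
of the published area tables, whose cells the tests reproduce from the
printed pixel counts (one cell is excluded as a misprint: its printed
area is exactly ten times the value implied by its own pixel count).
`annual_area_series()` summarizes growth as the geometric mean of
year-over-year area ratios.

`auc_learning_curve()` reruns training at increasing balanced
training-set sizes and scores a fixed held-out set (equal parts
confident plantation and non-plantation pixel-years) by the share of
plantation-involving classifiers voting P — a rankable statistic from
hard votes, since the ensemble itself produces no probabilities.

## Problem sizes and numerical choices

The shipped tests and acceptance script run on desk-scale scenes chosen
as the package's own study conditions: 30 × 30 pixels × 15 years for
pipeline-level comparisons (10 replicate scenes for the strategy
orderings), 40 × 40 for the learning curve (sizes 60–6000, five
replicate seeds), 500 sequences × 20 seeds for the smoothing
noise-reduction property. Viterbi runs in log-space; stochastic-matrix
validation uses a 1e-9 row-sum tolerance; degenerate subclasses (single
member) are handled by explicit index sampling; zero-variance bands
standardize with unit scale. All random draws flow from explicit seeds,
and the RNG state of the caller is always restored.

## Limitations

Beyond the simulator's idealizations listed above: the ensemble carries
no spatial context (each pixel is classified independently); the HMM
parameters are declared priors, not estimated from reference data; the
AUC score has only three levels for the three-class scheme, so ROC
resolution is coarse; and quantitative accuracy values obtained on
synthetic scenes say nothing about accuracy on real satellite data —
only the algorithmic properties (vote semantics, decoding optimality,
metric arithmetic, qualitative orderings) transfer.
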