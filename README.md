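# plantmapr

Annual plantation mapping from multi-temporal satellite reflectance, for
ecologists and remote-sensing scientists studying plantation-driven
deforestation. The package implements a complete mapping pipeline — a
one-vs-one pairwise ensemble classifier, subclass-balanced training-set
construction, hidden-Markov-model temporal smoothing, and an evaluation
protocol built for asymmetric noisy reference products — together with a
synthetic scene simulator so every stage runs and is tested without any
external satellite data.

## The method

Each pixel-year is a feature vector **x** ∈ R³²² — 46 eight-day
composites × 7 spectral bands (MOD09A1 convention, 500 m pixels). A
19-type land-cover taxonomy aggregates to three classes: plantation
(P), forest (F), other (O).

**Pairwise ensemble.** Rather than one k-way classifier, the method
trains one binary classifier per unordered class pair (P–F, P–O, F–O),
each on samples of its two classes only, so each focuses on one
discriminative boundary — in particular the hard P–F boundary, since
mature plantations approach forest greenness. Votes are aggregated by
unique majority; when all classifiers mutually disagree the pixel-year
is labeled Unknown (U). The default backend is a 322→158→64→20→1
feed-forward network; RBF-SVM and logistic backends are included.

**Balanced sampling.** Land-cover frequencies are heavily skewed, so the
training set draws an equal number of pixel-years from every 19-type
subclass (`balanced_sample()`), keeping rare plantation-mimicking
subclasses represented; `uniform_sample()` provides the
prevalence-weighted baseline.

**Temporal smoothing.** Each pixel's yearly P/F/O/U sequence is decoded
through an HMM whose latent states are land-cover classes (19 by
default) with self-transition probability ρ, emission correctness q,
and plantation→forest transitions capped at δ ≈ 0 — plantations are
rarely converted back to forest, so an isolated "forest" year inside a
plantation run is corrected:

```r
spec <- default_hmm(class_scheme("nineteen"), rho = 0.9, q = 0.9, delta = 1e-6)
viterbi_smooth(spec, c("F", "F", "P", "P", "F", "P"))
#> [1] "F" "F" "P" "P" "P" "P"
```

**Evaluation.** Yearly recall is measured on *confident plantation
locations* (pixels labeled plantation at both ends of a consecutive
anchor-year pair of the high-precision reference maps); overall
precision against the high-recall single-epoch plantation mask; overall
recall against the last anchor-year map.

## Worked example

Simulate a 20 × 20-pixel scene over 2000–2014, train the three-class
ensemble on a balanced draw, predict, smooth, and evaluate:

```r
library(plantmapr)

cfg <- run_config(
  scene = scene_config(n_rows = 20, n_cols = 20, seed = 42),
  scheme = "three", sampling = "balanced", n_per_subclass = 25,
  backend = backend_spec("mlp"), smoothing = "hmm19", seed = 42
)
res <- run_pipeline(cfg)
print(res$model)
#> <ensemble_model> three scheme, 3 pairwise mlp classifier(s): P-F, P-O, F-O
#>   trained on 400 samples (seed 42)
print(res$metrics)
#> <metrics_report>
#>   yearly recall: 2000=1.000 2001=1.000 2002=1.000 2003=1.000 2004=1.000
#>                  2005=1.000 2006=1.000 2007=1.000 2008=0.947 2009=0.947
#>   overall precision: 0.9464  overall recall: 0.9706
#>   mean annual area growth: 4.9%
```

Yearly recall is the detected fraction of confident plantation
locations in each year; overall precision says 94.6% of all pixels the
model ever flags as plantation lie inside the (high-recall, noisy)
reference mask; overall recall says 97.1% of the plantations in the
conservative 2009 anchor map are detected. The annual area series is in
km² (0.25 km² per pixel):

```r
area <- annual_area_series(res$smoothed)
area$area_km2[c("2001", "2014")]
#> 2001  2014
#> 7.00 13.75
```

A thin CLI wrapping the same functions ships in `inst/cli/plantmap.R`
(subcommands `simulate`, `sample`, `train`, `predict`, `smooth`,
`evaluate`, `learning-curve`, `pipeline`).

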