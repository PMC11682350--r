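---
title: "Scent design from mass spectra: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scent design from mass spectra: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scentforge)
```

`scentforge` implements an inverse-design loop for scents: a target set of
odor descriptors goes in, a blendable recipe of odor components comes out.
This vignette is the package's own account of the science: the three models
involved, their assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, and the choices made where the design
was genuinely open.

## 1. Data model

Everything lives on a fixed unit-resolution m/z grid from 50 to 250 — 201
integer bins (`mz_axis()`). A library is a plain non-negative matrix with one
row per oil. Two normalizations recur and both have exact Jacobians used by
the search:

* **max-normalization** of a spectrum, `MSⁿ = MS / max(MS)` — the form the
  predictor consumes;
* **sum-normalization** of a recipe, `OCⁿ = OC / Σ OC` — mixing ratios as
  proportions.

All-zero inputs are rejected rather than normalized: both maps divide by an
aggregate, and an all-zero spectrum or recipe always indicates an upstream
bug (an empty library row, a collapsed search state), never valid data.
Replicate measurements are averaged elementwise and then floored: bins below
a configurable fraction (default 0.1%) of the spectrum maximum are zeroed.
The floor is this package's simple, documented pretreatment for baseline
noise; it is deliberately minimal and is the first thing to replace if you
have a calibrated noise model for your instrument.

The central physical assumption, inherited from headspace mass spectrometry
of mixtures, is **linear superposition**: the spectrum of a blend is the
ratio-weighted sum of the ingredient spectra, and descriptor profiles mix
approximately the same way. Every stage leans on it: the NMF reconstruction,
the mixture augmentation, and the forward model of the search.

## 2. Odor components (KL-NMF)

`fit_components()` factors the library `MS ≈ W H` with `W ≥ 0` (oils ×
components) and `H ≥ 0` (components × 201), minimizing the generalized
Kullback–Leibler divergence

$$D(V\,\|\,WH)=\sum_{ij}\Big[V_{ij}\log\frac{V_{ij}}{(WH)_{ij}}
-V_{ij}+(WH)_{ij}\Big],\qquad 0\log 0:=0,$$

by the classical multiplicative updates, which never increase the loss — a
property the test suite asserts on every fit with a 1e-10 relative slack for
floating-point round-off. KL (rather than least squares) weights low-intensity
bins more evenly, which suits spectra whose informative fragments span orders
of magnitude.

Numerical choices:

* **Initialization** is `Uniform(1e-6, 1)`, seeded; fits are bit-reproducible
  for a fixed seed and iteration count.
* **Zeros**: an `eps = 1e-12` is added inside denominators and the divergence
  so sparse spectra cannot produce 0/0 or log 0.
* **Scale indeterminacy** (`WH = (Wc)(c⁻¹H)`): after convergence each row of
  `H` is rescaled to maximum 1 and `W` inversely, changing nothing about the
  reconstruction (verified to 1e-12) but making component spectra directly
  comparable to max-normalized library spectra.
* **Convergence** is declared when the relative loss change drops below
  `tol` (default 1e-8) or at `max_iter` (default 500).
* `K` defaults to **20**, matching the channel count of the olfactory
  displays this kind of recipe is destined for; it is fully configurable.
  Component sparsity is emergent, not enforced by a penalty.

Spectra enter the factorization raw (unnormalized); the summary metric
`reconstruction_rmse()` is computed on max-normalized spectra projected by
non-negative least squares (`project_nnls()`, backed by
`pracma::lsqnonneg`), so it is comparable across libraries with different
intensity scales. On a noiseless synthetic library of latent rank 8 the K=8
fit reaches RMSE below 1e-4 (the acceptance script reports ~1e-13); with real
instrument data the attainable error is set by the noise floor instead.

## 3. Descriptor predictor

`train_predictor()` fits a fully connected feed-forward network from the
max-normalized spectrum to real-valued scores, one per descriptor. Every
layer — including the output — uses a leaky ReLU with slope 0.01, so
predictions are not confined to [0, 1]; labels are recovered by
`binarize()` at 0.5. Training minimizes MSE against the 0/1 labels plus an
L1 penalty on all weights and a per-layer L2 penalty, with Adam
(β₁ = 0.9, β₂ = 0.999), a per-epoch multiplicative learning-rate decay, and
inverted dropout (rates are DROP probabilities) active only during training.
Inference is deterministic.

Two presets:

| parameter | `"full"` | `"reduced"` |
|---|---|---|
| layers | 201-4754-3565-2377-423-39 | 201-256-128-*k* |
| dropout | 0.9 (2377), 0.75 (423) | 0.1 (128) |
| L1 / L2 | 0.005 / 1e-4 | 1e-4 / 1e-4 |
| lr, decay | 0.001, ×0.995/epoch | 0.003, ×0.995/epoch |
| minibatch / epochs | 150 / 1000 | 150 / 300 |

The full preset is the fidelity architecture for real libraries of ~100 oils
and 39 descriptors, where extreme dropout plus augmentation is what stands
between a 27-million-parameter network and memorizing 94 samples. The
reduced preset is the package's own desk-scale choice for development,
validation and the test suite, where fixtures have tens of oils and ~10
descriptors: at that scale the full net's 0.9 dropout and heavy L1 would
swamp the signal, so the reduced preset keeps the same training machinery
(augmentation, decay, leaky output, L1+L2) with capacity and regularization
matched to the fixture sizes. Its hyperparameters were fixed once while
developing against synthetic fixtures and are not tuned per test.

**Augmentation** (`augment_batch()`): each minibatch is 50% original oils and
50% fresh two-oil mixtures — spectra mixed at `r ~ U(0,1)`, perturbed by
per-bin multiplicative `U(−0.1, 0.1)` noise, clipped and re-normalized;
labels mixed with the same `r`, giving real-valued targets in [0, 1]. Fresh
mixtures are drawn at every step, so the network effectively sees an
unbounded training set concentrated on the superposition manifold.

**Evaluation** uses balanced accuracy — the mean of sensitivity and
specificity — because descriptor prevalences are strongly imbalanced and
plain accuracy would reward all-negative predictions. `leave_one_out()`
retrains once per held-out oil. Two "All" summaries are reported, since
either convention appears in practice: `pooled` (every oil × descriptor cell
as one observation) and `macro` (mean of per-descriptor balanced
accuracies); descriptors with no positives or no negatives contribute only
their defined half and are flagged. The binarization threshold for
evaluation is 0.5, the midpoint of the label codes, and is configurable.

## 4. Recipe search

`design_recipe()` minimizes the mean squared error between a target
descriptor vector and the predicted descriptors of a component mixture,

$$L(\widehat{OD}) = \tfrac1n\textstyle\sum_p (OD^t_p - \widehat{OD}_p)^2,$$

by plain gradient descent on the **raw** ratios `OC`, differentiating
analytically through the chain
`OC → OCⁿ → MS = OCⁿH → MSⁿ → DNN → L`:

* the loss term is `∂L/∂ÔD_p = −(2/n)(OD^t_p − ÔD_p)`; the `1/n` factor is
  kept so that the analytic gradient equals finite differences of the loss
  as defined (a convention check the suite enforces to 1e-4 relative error
  over hundreds of random instances — in practice agreement is ~1e-8);
* the network input-Jacobian is an exact backward pass (dropout off);
* the max-normalization Jacobian has an identically zero row and column at
  the argmax bin `m`, `1/MS_m` on the rest of the diagonal and
  `−MS_q/MS_m²` in column `m`. `m` is **frozen** within an iteration: the
  map is only piecewise smooth, and the frozen-argmax derivative is used
  consistently in forward and backward passes. Ties at the maximum are
  broken to the lowest index with a warning;
* `∂MS/∂OCⁿ = H`; the sum-normalization Jacobian is the standard quotient
  rule `(δ_{si}·S − OC_s)/S²`, whose structure makes the whole forward map
  invariant to rescaling the raw recipe (degree-0 homogeneity; the gradient
  is orthogonal to the recipe direction, which the tests check).

Non-negativity is maintained by **projection** — clip at zero after each
step — chosen over a softmax-style reparametrization for transparency: the
iterate is always itself a valid recipe. If a step ever zeroes the whole
recipe, the entry with the largest pre-clip value is reset to
`eps_reset = 1e-8` rather than letting the search die in an absorbing state.
Defaults: learning rate 0.1, `max_iters` 5000, convergence at loss
< 1e-4 — loose enough that "converged" means "descriptor sets agree to
plotting accuracy", tight enough to stop well before numerical stagnation.
MSE (not RMSE) is the optimized loss; its square root would only rescale the
gradient. The landscape is non-convex: `self_consistency_suite()` — target
each component's own predicted descriptor profile and ask the search to
rediscover it — is the standing diagnostic, and a minority of components
settling in a local minimum (recipe not one-hot although the descriptor
error is small) is expected behavior, observed in the test suite's separable
three-component case.

`recipe_to_blend()` converts a component recipe to per-oil volumes through
the column-normalized `W`, conserving the total volume.

## 5. Sensory discrimination statistics

Both panel designs (two-alternative forced choice; duo-trio) reduce to
correct/incorrect counts with chance probability ½. `chisq_equal()` is the
1-df goodness-of-fit statistic `X² = (correct − incorrect)²/n` without
continuity correction, with two-sided p-values from the chi-square survival
function. That convention reproduces the published per-group and aggregated
statistics of both panel tables from their printed counts (the one printed
statistic it cannot reproduce, the 2AFC "Woody" group's, is inconsistent
with its own printed counts — 13 vs 17 gives 0.533, whose p-value 0.465 *is*
the printed one — so the counts, not the typo, are trusted). Under simulated
chance responding the test's empirical size matches the exact binomial
enumeration of its rejection region (~4.6% at nominal 5% for 208 trials;
the discreteness, not the implementation, causes the gap).

## 6. The synthetic generator

`generate_library()` produces libraries with exactly the structure the
method assumes, plus ground truth for recovery tests:

* latent basis spectra: sparse rows (default 10% of bins), peak positions
  uniform, heights Exp(1) — mimicking the sparse, spiky look of unit-binned
  electron-ionization spectra;
* oil loadings: sparse non-negative (default 35% of latent components
  active, magnitudes U(0.2, 1)); spectra are `loadings × basis`, optionally
  perturbed by multiplicative uniform noise and clipped;
* descriptors: 1 when a fixed random linear functional of the loadings
  exceeds a per-descriptor threshold, thresholds placed so prevalences span
  0.05–0.6 (the imbalance real descriptor vocabularies show), then flipped
  with a small probability.

Defaults mirror the study conditions the method targets — 94 oils, 39
descriptors, 201 bins, K = 20 downstream — with latent rank 10 and noise
levels (5% spectral, 5% label flips) chosen once as plausible for averaged
replicate spectra and expert-curated labels. What it deliberately does
**not** emulate: isotope patterns, fragmentation chemistry shared between
similar molecules (real oils have correlated spectra; latent rows here are
independent), instrument drift, and descriptor semantics (labels are
exchangeable). Consequently, green tests certify the *algorithms* —
factorization, learning, gradients, search — under the method's own
assumptions; they do not certify that real oils satisfy those assumptions.

## 7. Validation scales and the acceptance script

`scripts/acceptance.R` re-derives the headline numbers at sizes chosen so
the whole script re-runs in minutes on one core, as a package this size
should: NMF recovery on a 60-oil rank-8 noiseless library at K = 8;
gradient-vs-finite-difference agreement over 100 random instances with K
from 3 to 20; a K = 5 self-consistency sweep (40 oils, 12 descriptors,
reduced predictor) where all five components reach SAE < 0.2; and
leave-one-out balanced accuracy on a 24-oil fixture whose eight descriptors
flag the presence of each latent component — labels that are deterministic
functions of the spectrum, hence learnable by construction — reaching pooled
balanced accuracy above 0.9, against a shuffled-label control at chance.
The shuffled control is the noisiest of these quantities: 192 correlated
held-out cells leave its chance level with a spread of roughly ±0.1 across
seeds. Full-scale figures (a 39-descriptor vocabulary, the 4754-wide
network, ~100 leave-one-out retrainings) require the corresponding real
library and compute budget and are intentionally out of the desk-scale
validation surface.

## 8. Known limitations

* The search returns a local minimum by design; use restarts (the CLI's
  `--restarts`) when the recipe, not just the descriptor error, matters.
* The frozen-argmax gradient is wrong exactly at argmax switches; in
  practice the iterates cross such boundaries without trouble, but a line
  search assuming smoothness would not be safe.
* MSP import handles the common `Name:`/`Num Peaks:` dialect only, and
  integer-bins all peaks; profile-mode data should be binned upstream.
* The predictor's leaky-ReLU output can produce scores outside [0, 1];
  downstream consumers must binarize (or clamp) rather than interpret
  scores as probabilities.
* `chisq_equal()` uses the asymptotic chi-square null; for panels with
  fewer than ~10 trials an exact binomial test would be preferable.
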