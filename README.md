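# scentforge

Algorithmic scent design from mass spectra. Given a library of essential-oil
mass spectra (unit-resolution m/z 50–250, 201 bins) and binary odor-descriptor
annotations ("Floral", "Woody", ...), `scentforge`:

1. **decomposes** the library into a small non-negative basis of *odor
   components* — physically blendable sub-mixtures of oils — by non-negative
   matrix factorization under the generalized Kullback–Leibler divergence,
2. **predicts** the odor-descriptor profile of any spectrum with a regularized
   leaky-ReLU feed-forward network trained with two-oil mixture augmentation
   (both spectra and labels are mixed at a shared random ratio) and
   multiplicative uniform noise, and
3. **inverts** the predictor: starting from a uniform blend, gradient descent
   on the component mixing ratios — with exact analytic Jacobians through the
   sum-normalization of the recipe, the linear spectral mixing, the
   max-normalization of the spectrum and the network — finds a recipe whose
   predicted descriptors match a target descriptor set.

It also ships the chi-square statistics used to analyze the 2AFC and duo-trio
sensory panels that validate designed scents, and a synthetic library
generator with known ground truth so the entire pipeline can be exercised and
tested without any instrument data.

It is aimed at researchers in digital olfaction / cheminformatics who want a
self-contained, reproducible implementation of spectrum-based scent creation.

## The method in brief

With `MS` the `n × 201` library matrix, the component basis solves

    MS ≈ W H,   W ≥ 0 (n × K),  H ≥ 0 (K × 201),  K = 20 by default,

minimizing `D(MS‖WH) = Σ [MS log(MS/WH) − MS + WH]` by multiplicative
updates. A recipe is a non-negative vector `OC` of K mixing ratios. The
forward model is

    OCⁿ = OC / Σ OC →  MS = OCⁿ·H  →  MSⁿ = MS / max(MS)  →  ÔD = DNN(MSⁿ)

and the search minimizes `L = mean_p (OD^t_p − ÔD_p)²` over `OC` by gradient
descent through the whole chain, clipping at zero; the max-normalization
Jacobian is singular at the argmax bin `m` (its row and column vanish), which
the backward pass reproduces exactly. Panel counts are tested against chance
with `X² = (correct − incorrect)² / n` on 1 df, no continuity correction.

## Worked example

```r
library(scentforge)

# a synthetic library standing in for the essential-oil data
sim <- generate_library(synthetic_config(n_oils = 40, n_latent = 5,
                                         n_descriptors = 12, seed = 11))

# 1. odor components by KL-NMF
basis <- fit_components(sim$library, K = 5, max_iter = 1000, seed = 2)
#> Odor component basis: K = 5 components over 40 oils
#>   generalized KL at convergence: 19.31202 in 347 iterations (converged)

# 2. descriptor predictor (reduced preset)
pred <- train_predictor(sim$library, sim$descriptors,
                        predictor_config(preset = "reduced",
                                         n_outputs = 12, seed = 3))
#> Odor-descriptor predictor: 201-256-128-12 (preset 'reduced')
#>   final training loss: 0.05762176

# 3. invert the predictor: target the descriptor profile of component 1
target <- unname(predict(pred, max_normalize(basis$H[1, ])))
res <- design_recipe(target, basis, pred)
#> Recipe search: 49 iterations, converged
#>   final loss: 9.307786e-05 | SAE: 0.08293157
#>   leading components: 1 (0.93), 5 (0.03), 4 (0.02)

round(recipe_to_blend(res$recipe, basis, volume = 35)[1:5], 3)
#> oil_001 oil_002 oil_003 oil_004 oil_005
#>   0.132   1.424   3.103   0.036   0.125

# sensory discrimination statistics from panel counts
chisq_equal(81, 55)
#> Chi-square vs. chance: 4.971 on 1 df, p = 0.0258 (n = 136 trials)
```

The search converges in 49 iterations to a recipe dominated (weight 0.93) by
the component whose descriptor profile was the target — the self-consistency
behavior the method relies on — with a mean-squared descriptor error below
1e-4 and a sum of absolute errors of 0.08 over 12 descriptors.
`recipe_to_blend()` turns the component recipe into per-oil volumes (here for
a 35 ml vial). The chi-square summarizes a 136-trial two-alternative
forced-choice panel: 81 correct identifications reject chance responding at
p ≈ 0.026.

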