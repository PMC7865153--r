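# descrambler

Neural networks that invert ill-posed integral equations work strikingly
well, and nobody can see why by staring at their weight matrices: back-
propagation leaves every internal ("link") dimension in a random basis.
**descrambler** implements a group-theoretical cure for this. For a chosen
fully connected layer it searches the special orthogonal group SO(d) for a
transformation **P** that makes the layer's signals interpretable, inserting
the unit operator **P**⁻¹**P** at the tap point so the network's function
never changes. The search is parameterized through the Cayley transform

&nbsp;&nbsp;&nbsp;&nbsp;**P** = (**1** − **Q**)(**1** + **Q**)⁻¹,&nbsp;&nbsp;**Q**ᵀ = −**Q**,

and driven by L-BFGS with an exact analytic gradient of the interpretability
functional — by default Tikhonov smoothness ‖**D P W**ₖ⋯F₁**W**₁**X**‖²_F with a
Fourier spectral second-derivative operator **D**, plus diagonal-dominance
functionals Tr(**PW**) and ‖diag(**PW**)‖²₂ for weight-matrix-level descrambling.

The package exercises the method end-to-end on the problem it was designed
around: double electron–electron resonance (DEER) distance determination in
structural biology. It ships

* the DEER physics: dipolar kernel γ(r,t) from Fresnel integrals, the
  Fredholm forward map Γ(t) = ∫ p(r) γ(r,t) dr, and a synthetic generator of
  distance distributions with realistic baselines, modulation depths and
  noise (`build_kernel`, `fredholm_forward`, `generate_dataset`);
* small fully connected solver networks (tanh hidden layer, logistic output)
  with Adam training, ensembles, and SVD-based link-rank reduction
  (`init_network`, `train_network`, `ensemble_train`, `rank_truncate`);
* the descrambler itself (`descrambler_problem`, `descramble`,
  `apply_descrambler`) returning a classed fit with `print`, `summary`,
  `coef` and `plot` methods;
* interpretation diagnostics: frequency-domain conjugation **F**₊**W F**₋,
  symmetrized 2-D Fourier magnitude maps, SVD signal libraries,
  row/column orthogonality scores (`frequency_conjugate`, `sym_abs_fft2`,
  `svd_breakdown`, `orthogonality_score`);
* the rational DSP replica of the interpreted network: a DC notch and a
  low-pass FIR filter followed by a regularized time–distance transform
  **T** = ((**FF**ᵀ + λ**1**)⁻¹**F P**ᵀ)ᵀ with λ chosen by the L-curve
  (`design_fir`, `apply_filter`, `build_transform`, `lcurve_lambda`,
  `train_replica`, `replica_pipeline`);
* a staged command-line workflow (`run_command` and
  `inst/cli/descrambler.R`) with YAML configuration and plain-text
  artifacts.

## Worked example

Train a 64 → 32 → 64 solver on 5,000 synthetic records, descramble its first
layer, and run the DSP replica:

```r
library(descrambler)

tg <- time_grid(3.2, 64); dg <- distance_grid(1.5, 8, 64)
kernel <- build_kernel(dg, tg)
ds <- generate_dataset(5000, kernel, seed = 42)

net <- init_network(64, list(layer_spec(32, "sigmoid"),
                             layer_spec(64, "logsig")), seed = 1)
net <- train_network(net, ds, train_config(seed = 2))
net
#> Fredholm solver network: 64 -> 32 -> 64 (tanh, logsig)
#> trained, final loss 0.0001193596
attr(net, "val_nrmse")
#> 0.365

prob <- descrambler_problem(net, ds$inputs, layer_index = 1,
                            tap = "before_activation", objective = "tikhonov")
fit <- descramble(prob, descramble_control(maxiter = 2000))
summary(fit)
#> Descrambler fit summary
#>   objective      : tikhonov (d = 32 )
#>   value          : 1.590619e+14 -> 998662127
#>   factor         : 159275
#>   ||PP' - I||_F  : 2.68681e-15
#>   det(P)         : 1
```

The smoothness functional drops by five orders of magnitude: the rotated
signals `coef(fit) %*% net$weights[[1]] %*% x` are smooth functions of the
link index, and `frequency_conjugate(coef(fit) %*% net$weights[[1]])` shows
the layer acting as a band filter in frequency space. The same structure
reappears for independently trained networks up to a circular shift and
reversal of the link dimension (`aligned_map_correlation`).

The rational replica reproduces the interpreted processing chain without any
network:

```r
replica <- train_replica(kernel, n_pairs = 2000, seed = 3)
p <- distance_distribution(dnorm(dg$r, 3, 0.3), dg, normalize = TRUE)
trace <- corrupt_trace(fredholm_forward(p, kernel),
                       depth = 0.35, k_bg = 0.05, sigma = 0.01, seed = 12)
est <- replica_pipeline(trace, replica)
#> true peak: 3.05 nm,  replica peak: 2.94 nm
```

The peak of the true distance distribution is recovered to within one grid
step (0.10 nm).

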