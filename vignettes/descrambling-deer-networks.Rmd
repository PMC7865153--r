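---
title: "Descrambling Fredholm solver networks: models, objectives, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descrambling Fredholm solver networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Double electron–electron resonance (DEER) measures the distance-dependent
magnetic dipolar coupling between two spin labels attached to a biomolecule.
The measured echo modulation is an ensemble average over the distance
distribution $p(r)$,

$$\Gamma(t) = \int p(r)\,\gamma(r,t)\,dr,$$

a Fredholm integral of the first kind whose inversion is ill-posed. The
orientation-averaged kernel of an isolated spin pair has the closed form

$$\gamma(r,t) = \sqrt{\frac{\pi}{6Dt}}\left[\cos(Dt)\,C\!\left(\sqrt{\tfrac{6Dt}{\pi}}\right)
 + \sin(Dt)\,S\!\left(\sqrt{\tfrac{6Dt}{\pi}}\right)\right],
 \qquad D = \frac{\mu_0\gamma_e^2\hbar}{4\pi r^3},$$

with $C$ and $S$ the *normalized* Fresnel integrals
($C(x)=\int_0^x\cos(\pi u^2/2)\,du$). We verified this convention against the
direct powder average $\int_0^1 \cos\!\big[(3z^2-1)Dt\big]\,dz$: with the
normalized convention the two agree to machine precision, with the
unnormalized one they do not, so the normalized form is what the prefactor
$\sqrt{\pi/6Dt}$ belongs to. Below $Dt = 10^{-6}$ the series limit
$\gamma \to 1$ is substituted to avoid $0/0$.

Small fully connected networks of the layout
*input → fully connected → tanh → fully connected → logistic → output*
can be trained to map corrupted traces back to distance distributions. The
logistic output keeps densities positive. Such networks work despite the
ill-posedness, and the purpose of this package is to find out *how*, by
descrambling their weight matrices.

## The descrambler group and the Cayley chart

A trained layer's link dimension carries no preferred basis: any invertible
linear reshuffling of the hidden units, compensated downstream, leaves the
network function unchanged. We search the special orthogonal group
$SO(d)$ — connected, continuous, norm-preserving, and a supergroup of the
hidden-unit permutations — for the transformation $\mathbf{P}$ that makes
the wiretapped signals interpretable. $\mathbf{P}$ is chart-parameterized by
the Cayley transform of an antisymmetric generator,

$$\mathbf{P} = (\mathbf{1}-\mathbf{Q})(\mathbf{1}+\mathbf{Q})^{-1},$$

stored as the $d(d-1)/2$ strictly-lower-triangular entries of $\mathbf{Q}$.
For real antisymmetric $\mathbf{Q}$ the eigenvalues of
$\mathbf{1}+\mathbf{Q}$ are $1+i\omega$, so the inverse always exists, and
the two operator orders commute (both factors are rational functions of
$\mathbf{Q}$) — the package asserts both numerically. The chart misses the
measure-zero subset of $SO(d)$ with eigenvalue $-1$; optimizations started
at $\mathbf{Q}=0$ have never hit it in our use, and the package documents
rather than special-cases this.

### Objectives

* **Tikhonov smoothness** (default): $\eta_T(\mathbf{Q}) =
  \lVert \mathbf{D}\,\mathbf{P}\,\mathbf{M}\rVert_F^2$, where $\mathbf{M}$
  are the tapped signals over the input library $\mathbf{X}$ and $\mathbf{D}$
  is the periodic Fourier spectral second-derivative matrix on $d$ points of
  a unit interval (DFT conjugation of $-(2\pi k)^2$, Nyquist mode included).
  The unit-interval convention keeps the penalty scale-consistent across
  layer widths. Because the functional depends on $\mathbf{M}$ only through
  its Gram matrix $\mathbf{M}\mathbf{M}^\mathsf{T}$, the library is consumed
  once — in column batches of any size — and each optimizer iteration costs
  $O(d^3)$ regardless of library size.
* **Smoothness plus link smoothness** for the second layer: the above plus
  `link_weight` $\cdot\,\lVert \mathbf{W}_{k+1}\mathbf{P}^\mathsf{T}\mathbf{D}\rVert_F^2$,
  the second-derivative norm of the downstream weight matrix along its
  descrambled link dimension. The two terms are combined with default weight
  1; no weighting was specified by the method's origin, and equal weighting
  treats signal and weight smoothness symmetrically.
* **Diagonal dominance** for filter-like layers:
  $\eta_{\text{MDSQ}} = \mathrm{Tr}(\mathbf{P}\mathbf{W})$ and
  $\eta_{\text{MDNSQ}} = \lVert\mathrm{diag}(\mathbf{P}\mathbf{W})\rVert_2^2$,
  maximized (by negation inside the minimizer).

### The analytic gradient

For any objective with known $\partial\eta/\partial\mathbf{P}=\mathbf{G}$,
differentiating the Cayley map gives
$d\mathbf{P} = -(\mathbf{1}+\mathbf{P})\,d\mathbf{Q}\,(\mathbf{1}+\mathbf{Q})^{-1}$,
hence the unconstrained gradient
$\mathbf{E} = -(\mathbf{1}+\mathbf{P})^\mathsf{T}\mathbf{G}\,(\mathbf{1}-\mathbf{Q})^{-1}$,
projected onto the antisymmetric subspace as $(\mathbf{E}-\mathbf{E}^\mathsf{T})/2$.
The derivation was validated against central finite differences before use;
the test suite keeps that check (relative error below $10^{-6}$ on random
8-dimensional problems, typically $10^{-9}$).

### Optimization

Limited-memory BFGS (`stats::optim`, memory 10) over the triangle
parameters, started at $\mathbf{Q}=0$, stopping at gradient
$\infty$-norm $\le 10^{-8}$ or an iteration cap (500 by default; 2000 for
the interpretation-grade runs below, where the extra iterations visibly
sharpen the frequency maps). Hitting the cap is reported through a
`converged` flag, never an exception: the objective values are then already
within a fraction of a percent of their floor while the gradient norm is
still large relative to the enormous objective scale, which is the expected
behavior of an almost-flat valley. The recorded objective history is the
best value seen at each function evaluation and is therefore monotone.

### Wiretap absorption

Inserting $\mathbf{P}^{-1}\mathbf{P}$ never changes the network function,
but where the factors can be *absorbed* depends on the tap. For a tap on the
affine output (`before_activation`), $\mathbf{W}_k \to \mathbf{PW}_k$ and the
bias rotates with it, while $\mathbf{P}^\mathsf{T}$ must remain an explicit
orthogonal undo between the affine map and the activation — the elementwise
nonlinearity does not commute with rotations. For a tap on the activation
output (`after_activation`), $\mathbf{P}^\mathsf{T}$ absorbs into
$\mathbf{W}_{k+1}$ (or is recorded as an output-side undo on the last
layer). `apply_descrambler` implements exactly this, and the equivalence is
asserted to $10^{-8}$ relative over random networks.

## The synthetic-data generator

The generator stands in for a measured training database; its defaults *are*
the study conditions of every test in the package.

| quantity | default | rationale |
|---|---|---|
| grids | 256 points, $t \in [0, 3.2]\,\mu s$, $r \in [1.5, 8]$ nm (64-point versions for the scaled studies) | 256-wide input/output matches the original solver networks; the physical windows are standard DEER practice |
| distributions | 1–3 truncated Gaussians, centres 2–4.5 nm, widths 0.15–0.5 nm | simplest family giving multi-peak densities; centres restricted to the distance window a 3.2 µs trace can determine (roughly $r \lesssim (52\,\mathrm{MHz\,\mu s}\cdot t_{max}/2)^{1/3}$ nm by the two-period rule) |
| background | $B(t) = e^{-kt}$, $k \in [0, 0.15]\,\mu s^{-1}$ | single exponential: 3-D homogeneous spin bath, the canonical DEER background and what a zero-frequency notch removes |
| composition | $V = B\,(1-\lambda(1-\Gamma)) + \varepsilon$, $\lambda \in [0.2, 0.5]$ | the standard form-factor convention |
| noise | iid Gaussian, $\sigma \in [0.002, 0.02]$ | typical averaged-echo SNR |

Every record is a pure function of a seed derived from the master seed by a
fixed linear congruence (all intermediate values stay below $2^{31}$), so
datasets are bit-reproducible.

What the generator does **not** emulate: orientation selection, multi-spin
contributions, exchange coupling, excitation-bandwidth effects, and
instrument-specific distortions. Tests passing on this data therefore
demonstrate the *mechanics* of the method — trainability, descrambling,
replica fidelity — not performance on experimental traces.

Network targets are per-bin probability masses (density × grid step), which
keeps them inside the logistic output range; predictions are rescaled to
densities per nm. Training uses Adam (mean squared error,
learning rate $2\times10^{-3}$, batch 100) with Glorot-uniform
initialization from the run seed. The scaled study below uses 600 epochs,
chosen in a pilot as the point where training is well converged — the
stability of the interpretation across runs depends on training quality, so
the study conditions specify a well-trained network.

## Link-rank reduction

The weight matrices of trained solver networks are numerically low-rank; a
256-wide link carries roughly 80 significant singular values.
`rank_truncate` makes the bottleneck explicit by factorizing layer $k$
through its SVD into two sub-layers,
$\sqrt{\mathbf{S}_r}\mathbf{V}_r^\mathsf{T}$ (identity activation) feeding
$\mathbf{U}_r\sqrt{\mathbf{S}_r}$ with the original bias and activation.
This keeps outputs bit-identical at full rank (the factors reassemble before
the nonlinearity) and bounds the perturbation by the discarded singular
values in general — splitting the factors *across* the activation would not.
The balanced $\sqrt{\mathbf{S}}$ split keeps the two factors on the same
scale.

## The rational replica

The interpreted first layer is a digital filter; the second is a regularized
time–distance transform. The replica rebuilds both rationally:

* **FIR filters.** Linear-phase type-I designs by weighted least squares
  over the declared bands with the transition band unconstrained. For the
  zero-frequency notch an exact DC zero is imposed as an equality
  constraint — DC rejection is the filter's entire purpose, and at the fixed
  order 256 with band edges 0.001/0.008 (normalized to Nyquist) no
  unconstrained equiripple design can push $|H(0)|$ below $10^{-3}$ while
  keeping the passband usable: the transition is simply too narrow for the
  order (a ~60 dB equiripple design would need roughly twice the order).
  A consequence of pinning the zero is a ~2 dB dip right at the nominal
  passband edge; the response is flat to better than 1 dB beyond ~1.5× the
  edge frequency. The low-pass (order 32, edges 0.01/0.3) is unconstrained
  least squares and meets all its figures comfortably. For 64-point traces
  the same roles are filled by scaled designs (notch order 56, edges
  0.006/0.065; low-pass order 16, edges 0.1/0.6), the notch passband chosen
  to pass the slowest oscillation the sampled distance window produces.
* **Zero-phase application.** Forward–backward filtering with antisymmetric
  reflection padding, so the oscillation phase the downstream transform
  relies on is untouched and the squared magnitude response applies. This
  also handles traces shorter than the filter (the order-256 notch on a
  256-point trace).
* **Time–distance transform.** $\mathbf{T} = ((\mathbf{F}\mathbf{F}^\mathsf{T}
  + \lambda\mathbf{1})^{-1}\mathbf{F}\mathbf{P}^\mathsf{T})^\mathsf{T}$
  trained on 2,000 synthetic pairs — many more than the matrix dimension —
  of *filtered* traces, consistent with the order of stages at prediction
  time. The frequency-axis rescaling the interpretation reveals needs no
  separate stage: it is linear and lives inside $\mathbf{T}$.
* **L-curve.** $\lambda$ maximizes the curvature of the
  (log residual, log solution) curve over a 40-point grid,
  $\lambda \in [10^{-6}, 10^2]$. Raw finite-difference curvature is noise-
  dominated wherever the curve is flat, so both coordinates are smoothed by
  splines in $\log\lambda$ before the parametric curvature is evaluated, and
  the maximizer is snapped back to the grid. On synthetic scans the selected
  $\lambda$ lands within a decade of the set of near-optimal values from an
  exhaustive true-error scan; the true-error curve of this problem class is
  flat over several decades, which is why the near-optimal *set* — not a
  single point — is the meaningful oracle.
* **Pipeline.** notch → low-pass → $\mathbf{T}$ → clip negatives →
  renormalize to unit integral (skipped, and flagged, for an identically
  zero estimate).

## Study scales and what the checks show

The heavyweight checks run at a deliberately reduced scale so the whole
suite completes in minutes on one CPU: 64-point grids, a 64→32→64 network,
5,000 training records, three training seeds. At that scale training reaches
validation NRMSE ≈ 0.35–0.45 (pilot-calibrated ceiling 0.55), descrambling
the first layer reduces the smoothness functional by four to five orders of
magnitude, and the descrambled frequency-domain maps of independently
trained networks agree pairwise with correlation above 0.7 after aligning
the circular shift and possible reversal of the link dimension — the
symmetries of the periodic smoothness functional, and exactly the
"insignificant details" by which independently trained networks may differ.
Planted-scrambling recovery (a smooth-rowed matrix hidden behind a random
rotation) is checked at $d = 32$ with 256 signal columns: the optimizer
reliably reaches an objective at or below the planted configuration's.

## Known limitations

* Descrambling is implemented for fully connected layers with square signal
  spaces at the tap; convolutional layers and non-orthogonal descrambler
  subgroups are out of scope.
* The spectral second-derivative operator assumes an even dimension
  (the Nyquist-symmetric construction); odd widths are rejected.
* Interpretation remains human-in-the-loop: the package computes maps,
  libraries and scores (including a descriptive cosine similarity of output
  singular vectors to the Chebyshev basis) but attaches no automatic
  semantic labels. Why trained solvers favor Chebyshev-like output
  libraries is measured here, not explained.
* Containers are plain text (JSON with 17 significant digits, TSV, YAML);
  round trips are exact for IEEE doubles.
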