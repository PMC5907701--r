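---
title: "Ridge detection and stacked forests for beta-beta contact refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ridge detection and stacked forests for beta-beta contact refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betaridge)
```

## The problem

Coevolution-based residue contact predictors emit an $L \times L$ score
matrix that is frequently dominated by noise, especially for protein
families with shallow alignments. Residue pairing between interacting
$\beta$-strands is nevertheless recoverable, because consecutive
$\beta$-$\beta$ contacts form collective patterns that individual prediction
errors rarely destroy: a run of contacts between two parallel strands lies
along a diagonal of the map, an antiparallel pairing along an anti-diagonal.
`betaridge` treats the predicted map as a 2D image, extracts those elongated
bands with scale-space ridge detection, and refines them with a three-stage
random-forest stack into per-pair $\beta$-$\beta$ contact probabilities.
The refined pairs can be exported as distance restraints for
contact-assisted folding.

## Ridge features

For every cell we fit the quadratic surface
$f(x, y) = a + bx + cy + dx^2 + exy + gy^2$ by ordinary least squares on
the $5 \times 5$ neighborhood (reflection padding at map borders), giving a
gradient $\nabla f$ and Hessian $\mathbf{H}$. Eigendecomposition
$\mathbf{H} = [\mathbf{v}_p\ \mathbf{v}_q]\,
\mathrm{diag}(\lambda_p, \lambda_q)\,[\mathbf{v}_p\ \mathbf{v}_q]^{-1}$
with $\lambda_p \le \lambda_q$ yields the principal curvatures. A ridge
point must be concave across the ridge and flat along $\mathbf{v}_p$:

$$\lambda_p < 0, \qquad \nabla f \cdot \mathbf{v}_p = 0 .$$

On discrete data the equality is enforced up to a relative tolerance
(default `ridge_tol = 0.1` of the gradient norm): the exact condition is
almost never met between grid points, while a tolerance of this size keeps
the on-axis cells of a one-to-three-cell-wide band and discards its flanks.
Under the quadratic model the ridge is the straight line
$\{\mathbf{x} : \mathbf{v}_p \cdot (\nabla f + \mathbf{H}\mathbf{x}) = 0\}$,
from which we read the direction $\phi \in [0, \pi)$ (angle of
$\mathbf{v}_q$; anti-diagonal bands sit at $3\pi/4$, diagonal at $\pi/4$)
and the distance $d = |\mathbf{v}_p \cdot \nabla f| / |\lambda_p|$ from the
cell to the line.

Ridge strength is quantified by the squared principal-curvature difference
$NL = (\lambda_p^2 - \lambda_q^2)^2$ computed on Gaussian-smoothed copies of
the map, and scale-normalized as

$$NL_\gamma = \sigma^6 \, (\lambda_p^2 - \lambda_q^2)^2 ,$$

whose maximum over the smoothing scale $\sigma$ sits at the ridge width
(Lindeberg scale selection). The $\gamma$ exponent is absorbed into the
$\sigma^6$ factor; no separate $\gamma$ parameter is exposed.

### Numerical choices

* **Scale grid.** 12 log-spaced scales in $[0.5, 4]$ grid units.
  Strand-contact ridges are one to three cells wide, so the grid brackets
  every realistic width with the response maximum in its interior; the
  scale-covariance test (argmax linear in the true width, $R^2 \ge 0.99$)
  validates the range.
* **Argmax refinement.** The discrete argmax is refined by log-parabolic
  interpolation between its grid neighbors. Without it the 12-point grid
  quantizes $\sigma^\ast$ by up to $\sim$20 %.
* **Width calibration.** In the continuum the $\sigma^6$-normalized
  response on a Gaussian ridge of cross-section std $s$ peaks exactly at
  $\sigma = s$, but the $5 \times 5$ OLS Hessian damps the curvature of
  narrow ridges and shifts the measured argmax high, with a mild
  orientation dependence (grid anisotropy). The constant in
  $w = c\,\sigma^\ast$ was therefore fixed once by a brute-force sweep on
  grid-centered analytic Gaussian ridges of std 1.5 — the reference ridge
  of the recovery tests — giving measured argmaxes 1.749 (axis-aligned) and
  1.910 (diagonal) and $c = 1.5/\text{mean} = 0.82$, stored in the model
  bundle. Recovery is exact near the calibration width and biased by
  roughly $\pm$10-25 % far from it; since $w$ is consumed as a relative
  feature (and is in fact dropped by feature selection, see below), this
  bias is harmless downstream but is a known limitation of $w$ as a
  physical measurement.
* **Height.** $h$ is the amplitude above baseline of a Gaussian of std $w$
  least-squares fitted to the *unsmoothed* cross-section sampled by
  bilinear interpolation along $\mathbf{v}_p$ through the ridge-line foot
  point (span $\pm 3w$). The additive baseline matters because contact maps
  have a nonzero noise floor; with it, $h$ is invariant to constant offsets
  and linear in the ridge amplitude.
* **Sentinels.** Cells failing the ridge condition at every scale carry
  `h = 0, phi = 0, d = -1, w = -1` and `valid = FALSE`, so downstream
  features distinguish "no ridge" from "weak ridge".
* **Boundaries.** Half-sample reflection padding everywhere (it conserves
  total mass under smoothing and avoids the spurious edge ridges of
  zero-padding).

## Features and the three-stage stack

Candidate pairs are all $i < j$ with $j - i \ge 3$ (closer pairs cannot be
$\beta$-partners sterically; the bound also fixes the negative universe).
Stage-1 rows concatenate, per 2D map (raw scores, ridge $h$, ridge $\phi$),
the values over a cross-shaped window mask — a $ws \times ws$ stencil
keeping the diagonal and anti-diagonal bands of width `dw = 3`, the
directions along which contact runs propagate — plus length-$ws$
secondary-structure windows (H/E/C probabilities) around both residues,
five position features (sequence separation and the four distances to the
chain ends) and two map-level features (MSA depth per residue and the
standard deviation of candidate scores). Ridge $d$ and $w$ are excluded
from the models: cross-validated feature selection finds them
non-essential, so only $h$ and $\phi$ enter as ridge features. Out-of-map window cells carry the
sentinel $-1$; out-of-chain secondary-structure positions carry zeros.

Four stage-1 forests are trained at window sizes 3/5/7/9. Stage 2 combines
their score maps and row/column rank maps (descending ordinal rank within
each row/column, ties broken by index, normalized by $L$ so the feature is
length-invariant; the ranks let the forest learn geometric constraints such
as "a residue pairs with at most two partners" without hard-coding them)
with ridge $h$, $\phi$ and secondary structure in a full $3 \times 3$
window — 144 features. Stage 3 repeats the protocol on the stage-2 map (63
features). Position and map features are dropped from the later stages,
whose feature selection retains only map-derived and secondary-structure
blocks.

Training uses protein-wise 1:40 positive/negative under-sampling (all
positives kept, negatives drawn without replacement from a per-protein
stream), 500 trees per forest by default, and protein-wise 5-fold
cross-validation. **Later stages train on out-of-fold earlier-stage
predictions.** In-fold stage-1 scores on training proteins are strongly
overfit relative to what the model produces on new proteins, so training
stages 2-3 on them would leak labels and inflate cross-validation. The
out-of-fold choice is the conservative one; prediction maps carry a
provenance flag and the training entry points refuse in-fold inputs. The
suggested cutoff shipped with a bundle is the grid value (0.01-0.99, step
0.01, ties to the smaller cutoff) maximizing pooled out-of-fold
residue-level F1 of the final stage. Forest hyperparameters beyond the tree
count stay at `ranger` defaults; every stochastic step draws from a stream
derived from the single master seed, so a full training run is reproducible
bit for bit.

DSSP mode is the same pipeline with one-hot native secondary structure
(probability 1 for the native state); strand-level evaluation — two strands
interact if at least one residue pair between them is predicted as
contacting — is only defined in this mode.

## The synthetic generator

Real benchmark maps require external predictors, so the package ships a
generator that emulates the geometry the method exploits: random strand
topologies (strands of 3-8 residues, $\ge 2$ coil residues apart, chained
so each strand pairs with 1-2 partners, parallel or antiparallel with small
register offsets), contact maps in which every true contact contributes a
Gaussian bump of amplitude `signal = 1` and std `bump_std = 1` on a
rectified-Gaussian background (`noise_scale = 0.35`), plus `~L/12` decoy
segments of the same brightness placed off the truth — so a model cannot
succeed by brightness alone — and secondary-structure profiles whose argmax
matches the truth with probability `q = 0.8` (the measured three-state
accuracy of practical predictors is about 80 %) at concentration
`sharpness = 6`. These defaults are the package's study conditions and the
recovery/benchmark tests run under them. The candidate-pair imbalance under
these settings is roughly 1:100-1:1000, qualitatively matching the
$\sim$1:600 regime of real $\beta$-protein maps.

What the generator does *not* emulate: correlated coevolution noise
(false-positive chains between non-interacting but covarying positions),
helix-helix and local-contact patterns, alignment-depth-dependent noise
structure, and realistic map score distributions. Passing the end-to-end
benchmark therefore shows that the machinery extracts ridge-structured
signal from noise under honest imbalance — not that the shipped synthetic
bundle transfers to real CCMpred maps; for real use, retrain on real maps
via the same entry points.

## Scaled problem sizes

The benchmark suite trains on 40 synthetic proteins ($L \in [60, 120]$)
with 60 trees per forest and evaluates on 10 held-out proteins; the
determinism check repeats a 10-protein, 30-tree run twice. These sizes keep
a full training run around two minutes while leaving the qualitative
orderings (window size 5 best among stage-1 models, stage 2 above stage 1,
stage 3 at or above stage 2) stable; the package defaults
(`n_trees = 500`) are what one would use on real data.

## Restraint export

`export_restraints()` reproduces the folding-pipeline interface: every
refined pair at or above the cutoff becomes a strict 3.5-6 Å
C$\beta$-C$\beta$ restraint; the list is then enriched to $L$ records with
the top raw-map pairs outside a $(2k+1) \times (2k+1)$ exclusion window
(default $k = 2$, i.e. a 5×5 window; configurable, since no single size is
canonical) around every strict pair, as loose 3.5-10 Å restraints. The
control mode exports the top-$L$ raw pairs at uniform 3.5-8 Å. Output is
CASP-RR-like text, 1-based.

## Known limitations

* Ridge width is calibrated at one reference width; see above.
* The ridge condition tolerance (0.1) trades recall for precision on
  discrete data; cells midway between two grid-aligned crests can fail it.
* `phi` is reported modulo $\pi$; parallel/antiparallel disambiguation is
  left to the forests, which see the signed window context.
* Strand-level evaluation requires native secondary structure by
  construction.
* The 0/1 asymmetric-input convention: maps are symmetrized by averaging on
  load, which is order-independent but halves genuinely one-sided signals.
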