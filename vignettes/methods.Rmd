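---
title: "Direct group-equivariant convolutions on the icosahedral rotation group"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct group-equivariant convolutions on the icosahedral rotation group}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icoseg)
```

## The problem

A diffusion-weighted MRI (DWI) scan measures, in every voxel, the signal
attenuation along N gradient directions (here N = 90 at b = 1000 s/mm²,
plus unweighted b0 volumes). The signal is therefore a function on
ℝ³ × S²: a volume of spherical signals. Voxel-wise tissue classification
(CSF, subcortical, white matter, gray matter) should not depend on how the
head happened to be oriented in the scanner — when the anatomy rotates,
the voxel grid rotates *and* the per-voxel spherical signals rotate with
it. `icoseg` implements convolutional networks that respect this joint
action of 3D rotations and translations (SE(3)) in *direct* (regular
representation) form: kernels are small sets of learnable weights that are
transported by explicit group elements, with no spherical-harmonic or
irreducible-representation machinery.

## Discretization

**The sphere** is discretized by a regular icosahedron. Vertices sit at
the normalized cyclic permutations of (0, ±1, ±φ). This embedding is a
deliberate choice: it places three two-fold symmetry axes of the solid on
the coordinate axes, so three 180° rotations of the voxel grid are exact
elements of the discrete rotation group and end-to-end equivariance can be
verified without interpolation error. The orientation of the icosahedron
relative to the voxel grid is otherwise a free convention.

**SO(3)** is discretized by the 60 rotational symmetries of the
icosahedron, generated by closing a 2π/5 rotation about the reference
vertex v0 and a 2π/3 rotation about an adjacent face center under
composition (deduplication at 1e−6 Frobenius distance; the finished tables
are re-verified at 1e−9). Every element maps v0 to one of the 12 vertices;
the five elements sharing a target vertex form a left coset ("fiber") of
the order-5 stabilizer of v0, so the group factors as 12 vertices × 5
spins. Elements are ordered by (vertex, spin) with spin 1 the coset
representative, chosen deterministically; the identity is element 1. All
group structure is tabulated once (Cayley table, inverses, fibers, vertex
permutations) and every layer operates by pure index lookups.

**Spherical signals** are used in two forms. Type 1 ignores the spherical
structure and treats the N measurements as channels of an ℝ³ image (the
classical CNN input). Type 2 interpolates each voxel's measurements into a
proper spherical function with an antipodally symmetric Watson kernel,
w(q, v) ∝ exp(κ(q·v)²), with κ = 10 for all network inputs. The weights
are row-normalized (Nadaraya–Watson), which the kernel's originators leave
open: normalization keeps interpolated values inside the convex hull of
the measurements and makes κ = 0 the uniform average, both convenient
invariants to test. Squaring the dot product already symmetrizes antipodal
directions, so no hemisphere duplication is performed.

## The three operators

**Lifting (S² → group).** A star-shaped kernel with 11 sample points — the
reference vertex, the five arc-midpoints of its incident edges, and its
five one-ring neighbors — is transported by each of the 60 rotations and
correlated with the spherical signal, producing a feature map indexed by
(voxel, group element, channel). The support size of 11 is pinned by the
published parameter counts; the radial placement of the two rings
(midpoints and neighbor vertices) is this package's choice. The input is
sampled on the orbit of the 11 points under the group (42 distinct points:
12 vertices + 30 edge midpoints), so a rotation of the input is an exact
permutation of samples and the lift is exactly equivariant — a property
asserted, for all 60 rotations, in the test suite.

**Fiber group convolution (group → group).** The kernel is supported on
exactly one fiber: five weights indexed by stabilizer spin. The output at
g is `sum_k F(g·σ_k⁻¹) K(σ_k)` — a cyclic correlation within each coset,
implemented entirely through the Cayley table, hence exactly equivariant
under all 60 left translations. (The sign convention — which index
direction is "forward" — is fixed by this formula.)

**Rotation-tied spatial convolution (ℝ³).** A standard valid, stride-1
3×3×3 correlation applied per group slot. Three orientation modes
implement the ablation family: `none` uses the unrotated kernel everywhere
(decoupled 𝕋³×SO(3) action); `full` rotates the kernel by the slot's own
rotation R_g (SE(3)); `partial` uses one rotation per vertex (the spin-1
coset representative). Rotated kernels are resampled by trilinear
interpolation with value zero outside the 3³ support; corners rotate
partially out of support, an accepted discretization error. For the
grid-exact 180° rotations the resampling is an exact index flip, which is
what makes the end-to-end equivariance tests sharp.

**Projection.** A component-wise maximum over the group coordinate: over
all 60 slots (to ℝ³, invariant) or over the 5 spins within each fiber (to
the sphere, for the single-voxel SO(3) network). ReLU activations are
interleaved between the S² and ℝ³ sublayers (conv → bias → ReLU); pointwise
maps commute with the permutation action, so every equivariance statement
survives the interleaving. Whether the bias precedes the activation is not
dictated by anything structural; conv → bias → ReLU is this package's
convention.

## Architectures and parameter accounting

Width lists for the separable variants alternate S²/ℝ³ sublayer outputs
starting with the lift; with a 7³ input patch, three spatial sublayers
shrink the grid 7³→5³→3³→1³, so a trailing S² sublayer needs no spatial
partner. Every convolutional sublayer carries one bias per output channel,
and the fully connected head carries biases. Under these conventions the
counts are exact: classical 90−5−5−5 → 13,539; classical 90−120−120−90 →
972,694; single-voxel baseline 1−5 → 286 and 10−20 → 2,104; decoupled /
partial / full 5−5−5−5−5−5−5 → 2,514 and 10−20−20−40−40−20−10 → 59,914;
the comparison configuration 10−10−20−40−20−10 → 34,964. The
rotation-averaged classical CNN shares one weight set across its 12 or 60
rotated branch copies (averaged logits; with only the identity copy it
reduces exactly to the classical network), so its count stays 13,539.
`count_parameters()` computes these arithmetically and the test suite
checks it against an independent enumeration of every built network's
tensors.

Weight initialization (He-uniform over fan-in = channels × kernel
support, biases at a small positive constant so no ReLU path is dead at
the start) is seedable and is this package's choice; nothing in the
architecture pins it. Network inputs are standardized by a fixed affine
map, (x − 0.5)/0.3, which centers b0-normalized attenuations — all-positive
inputs condition ReLU optimization poorly — without losing the mean-signal
contrast that separates tissue classes.

## Training

Training uses focal loss, −α_y(1−p_y)^γ log p_y with γ = 2 and
α = (0.35, 0.35, 0.15, 0.15) for CSF, subcortical, WM, GM, batch size 100
and learning rate 0.001. The optimizer is Adam: only the batch size and
learning rate are externally fixed, and Adam is the default a practitioner
would reach for. Gradients for every layer — including the pull-back of
rotated-kernel gradients through the trilinear resampling matrices and the
shared-weight accumulation of the rotation-averaged variant — are
hand-derived and validated against central finite differences (biases are
randomized away from zero in those tests so no activation sits exactly on
a ReLU kink, where the loss is genuinely non-differentiable). Training is
deterministic given the seed at single-threaded BLAS; epoch budgets are
exposed in configuration rather than replicating any particular stopping
rule.

Rotation augmentation draws from the 24-element octahedral group, which
maps the voxel grid to itself so the spatial part is interpolation-free.
The directional signals are re-expressed by Watson interpolation from the
rotated gradient scheme — at the original b-vectors for Type 1 input, at
the icosahedral orbit for Type 2. A rotated test set assigns one
independent uniform octahedral element per patch (seeded); only three of
the 24 are icosahedral group elements, so even the fully equivariant
network is only approximately invariant there, which is the point of the
protocol.

## The synthetic phantom

Real DWI with expert tissue labels is access-restricted, so the package
ships a seeded diffusion-tensor phantom: a 32³ grid with a CSF core plus
two CSF blobs, a subcortical ring, a white-matter interior whose principal
fiber direction rotates circumferentially with position (spatially
coherent anisotropy for the spatial layers to exploit), and a gray-matter
shell. Signals follow the mono-exponential tensor model
S = S0·exp(−b·vᵀDv) at 90 repulsion-distributed directions (b = 1000,
five b0 volumes), with eigenvalues (mm²/s) CSF (3.0, 3.0, 3.0)e−3, WM
(1.7, 0.3, 0.3)e−3, GM (0.9, 0.7, 0.7)e−3 and subcortical a 50/50
two-tensor WM/GM mixture — literature-typical contrast, not values taken
from any dataset. Rician noise (default σ = 0.02 of S0) is optional.

The phantom reproduces the *statistical structure* the networks assume —
antipodally symmetric per-voxel spherical signals with class-dependent
anisotropy and spatial coherence — but not crossing fibers, multi-shell
acquisitions, partial-volume boundaries, or scanner artifacts. Passing
tests on the phantom therefore validate the operators, gradients and
training loop, and the *relative* rotation-robustness of the variants; they
do not certify segmentation accuracy on real brains.

## Study sizes used by the test suite

The end-to-end suite trains on one phantom "scan": 600 patches of 7³
voxels (150 per class; the CSF core contributes what it has), batch 100,
30 epochs, and evaluates on ~400 held-out patches (100 per class where
available, training centers excluded), both in original orientation and
under a random octahedral rotation per patch. At these sizes the
decoupled network reliably exceeds 0.8 held-out overall accuracy, and the
accuracy drop under rotation orders classical > decoupled ≥ full SE(3) —
the qualitative robustness finding at phantom scale, with the fully
rotation-tied network both the most accurate and the most robust. These
sizes are the package's chosen study conditions; the phantom geometry and
tissue models were fixed first and the learning checks calibrated to them
during development.

## Numerical choices and degenerate inputs

* Group deduplication at 1e−6 Frobenius during closure; final tables
  re-verified at 1e−9; orbit points deduplicated at 1e−9.
* Watson weights are computed with a max-shift before exponentiation, so
  large κ (used in self-consistency tests) cannot overflow.
* b0 normalization guards the mean-b0 denominator at 1e−6 and removes
  failing voxels from the mask; focal loss clamps p_y at 1e−8 before the
  logarithm; training aborts with a diagnostic on non-finite loss.
* Max-projection ties (e.g. a fiber of all-zero ReLU outputs) route the
  gradient to the first maximal slot; ties are measure-zero under
  continuous weights.
* Patch centers whose window would overrun the volume are skipped;
  unmasked centers are excluded (background is ignored).
* The performance-drop summary L(x) with x = c_reference/c_perturbed is
  provided in two readings — exp(−αx) and a logistic 1/(1+exp(−α(x−1))),
  α = 20 — because the printed formula it implements is typographically
  ambiguous; the exponential reading is the default and the report records
  which was used.

## Known limitations

* The 60-element group is a coarse SO(3) sample; rotations outside it
  (including 21 of the 24 octahedral elements) are only approximately
  respected.
* Trilinear kernel rotation loses corner mass outside the 3³ support.
* The phantom's single-tensor voxels cannot probe crossing-fiber effects.
* Training here is CPU-scale: the suite's sizes are chosen for minutes,
  not for reproducing full-scan segmentation scores.
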