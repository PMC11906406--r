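# icoseg

Group-equivariant convolutional networks for voxel-wise tissue
segmentation of diffusion-weighted MRI (DWI), built directly on the
60-element icosahedral rotation group.

A DWI scan assigns to every voxel a spherical signal: attenuations
measured along N ≈ 90 gradient directions. Segmenting such a volume into
CSF, subcortical, white matter and gray matter should commute with rigid
motions of the head — rotating the anatomy rotates both the voxel grid
and each voxel's directional signal. `icoseg` implements the regular
representation of this action in fully discrete form:

* **S² lifting convolution** — an 11-point star-shaped kernel (vertex +
  5 edge-midpoints + 5 ring neighbors) transported by all 60 icosahedral
  rotations, lifting a spherical signal f to a function on the group:
  `(f ∗ κ)(g) = Σ_j f(g·p_j) κ(p_j)`.
* **SO(3) fiber group convolution** — a 5-weight kernel supported on one
  fiber (coset of the vertex stabilizer), applied as a cyclic correlation
  through the Cayley table: `(F ∗ K)(g) = Σ_k F(g·σ_k⁻¹) K(σ_k)`.
* **Rotation-tied 3×3×3 spatial convolution** — the grid kernel is
  rotated (trilinear resampling) by the same 60 rotations, coupling the
  spatial and spherical parts into an SE(3)-equivariant layer; untied and
  per-vertex-tied modes give the 𝕋³×SO(3) and SE(3)* ablations.
* **Max projection** — channel-wise max over the group coordinate
  (invariant head) or over each fiber (spherical output).

On top of these the package provides the full ablation family with exact
parameter accounting (classical CNN, single-voxel SO(3) baseline,
decoupled, partial and full SE(3), rotation-averaged classical), focal
loss (γ = 2, α = (0.35, 0.35, 0.15, 0.15)), seeded Adam training with
hand-derived backpropagation, octahedral rotation augmentation and
rotated-test-set robustness protocols, segmentation metrics (per-class
accuracy, Dice, overall accuracy, mean ± sd across scans), NIfTI +
FSL bval/bvec I/O, and a seeded diffusion-tensor phantom generator so
everything is testable without restricted clinical data.

Intended users: researchers in geometric deep learning and diffusion-MRI
analysis who want a transparent, fully inspectable reference
implementation of direct (non-steerable) group convolution on ℝ³ × S².

## Worked example

```r
library(icoseg)

# the discrete rotation group and its structure
group <- build_rotation_group(build_icosahedron())
dim(group$elements)[3]
#> [1] 60

# exact parameter accounting of the ablation family
count_parameters(architecture_preset("classical-"))   # Type 1 CNN, 90-5-5-5
#> [1] 13539
count_parameters(architecture_preset("decoupled-"))   # T3xSO(3), 5-...-5
#> [1] 2514
count_parameters(architecture_preset("full-compare")) # SE(3), 10-10-20-40-20-10
#> [1] 34964

# a synthetic DWI phantom: 32^3 voxels, 90 directions at b = 1000, Rician noise
ph <- generate_phantom(phantom_config(seed = 11))
table(ph$labels[ph$labels > 0]) # CSF, subcortical, WM, GM voxels
#>    1    2    3    4
#>  224 1448 3944 5920

# train the decoupled T3xSO(3) network on 7^3 patches (a few CPU-minutes)
train_ds <- extract_patches(ph$volume, ph$labels, 7, n_per_class = 150, seed = 2)
net <- build_network(architecture_preset("decoupled-"), group, seed = 5)
tr <- train_network(net, train_ds, epochs = 30, batch_size = 100, lr = 0.001, seed = 6)

# held-out evaluation, original and rotated orientations
test_ds <- extract_patches(ph$volume, ph$labels, 7, n_per_class = 100, seed = 99,
                           exclude = train_ds$centers)
pred <- predict_patches(tr$network, test_ds)
evaluate_predictions(pred, test_ds$labels)
#> Segmentation evaluation across 1 scan(s)
#>        class accuracy_mean accuracy_sd dice_mean dice_sd n_scans
#>          CSF     0.9864865           0 0.9480519       0       1
#>  subcortical     0.9600000           0 0.8687783       0       1
#>           WM     0.8700000           0 0.8923077       0       1
#>           GM     0.7600000           0 0.8539326       0       1
#> overall accuracy: 0.8877 +/- 0.0000

rot_ds <- build_rotated_testset(test_ds, seed = 7)
mean(predict_patches(tr$network, rot_ds) == rot_ds$labels)
#> [1] 0.8502674
```

The per-class rows are recall-style accuracy and Dice per tissue class;
the held-out overall accuracy is 0.888, dropping only to 0.850 under a
random octahedral rotation of every test patch. The same protocol in the
test suite shows the contrast this design is for: the classical CNN's
accuracy drop under rotation (0.259) dwarfs the decoupled (0.037) and
fully rotation-tied SE(3) (0.016) networks'.

The structural guarantees can be checked directly:

```r
equiv_check(group, seed = 1)
#>                    suite    max_error tolerance pass
#> 1          group_closure 4.924076e-15     1e-09 TRUE
#> 2        fiber_structure 0.000000e+00     0e+00 TRUE
#> 3      lift_equivariance 0.000000e+00     1e-06 TRUE
#> 4     gconv_equivariance 0.000000e+00     1e-06 TRUE
#> 5  projection_invariance 0.000000e+00     1e-06 TRUE
#> 6       se3_pipeline_180 2.966030e-15     1e-05 TRUE
#> 7 decoupled_contrast_180 4.607064e-01     1e-02 TRUE
```

The last row is a negative control: the same 180° grid rotation that the
SE(3) pipeline commutes with (row 6, error at machine precision) moves the
output of the untied pipeline by a relative 0.46.

A thin command-line wrapper is installed at `inst/cli/icoseg`
(`simulate`, `train`, `evaluate`, `equiv-check`, `count-params`,
`rotate-testset`); every command writes a manifest with its config and
seeds.

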