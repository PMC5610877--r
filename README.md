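# atlascut

Interactive, seed-based segmentation of organs in 3D scalar volumes
(CT-like images), combining two sources of information:

* **expert annotation** — a handful of "scribble" seed voxels marking
  definitely-organ and definitely-background tissue, and
* **statistical shape information** — a probabilistic atlas (PA) built from
  labeled training volumes, fitted to the seeds by a 3D projective
  (homography) transformation.

The package is aimed at researchers in medical image analysis who need a
reproducible, scriptable implementation of atlas-weighted interactive graph
cuts — for instance to bootstrap ground-truth labels for difficult organs
such as the pancreas, where purely automatic atlas methods fail on irregular
anatomy and purely intensity-driven methods leak into neighbouring organs
with similar attenuation.

## Method

**Atlas construction.** Each training mask is cropped to its organ bounding
box, resampled to a fixed lattice of `S_x x S_y x S_z` voxels, and converted
to a signed Euclidean distance map `d` (positive inside the organ, negative
outside). Distances become probabilities through a sigmoid with gain `a_p`,

    sigma(d; a_p) = 1 / (1 + exp(-a_p * d)),

and the atlas `A` is the voxelwise mean of the per-case probability maps.

**Atlas fitting.** Seeds are encoded as `S(x,y,z)` with value −1 on organ
seeds, `+alpha` on background seeds and 0 elsewhere. A 4×4 homography `H`
maps test-image coordinates to atlas coordinates (with the usual division by
the fourth homogeneous coordinate), and the fidelity energy

    E_H = sum_{x,y,z} A(X, Y, Z) * S(x, y, z)

is minimized by preconditioned steepest descent over the free entries of `H`
(3 for translation, 12 for affine, 15 for full projective; `h44` is fixed to
1 as the gauge). The fitted prior `A*` is the atlas warped onto the test
grid.

**Segmentation.** The binary labeling `Omega` minimizes

    E(Omega) = B(Omega) + lambda * R(Omega),

where `B` sums boundary weights `exp(-(v_p - v_q)^2 / (2 sigma^2)) / dist(p,q)`
over neighbouring voxel pairs with different labels, and `R` sums per-voxel
data terms: negative log intensity likelihoods estimated from seed-region
histograms, optionally weighted by the fitted prior,

    R_p(PC) = -log( Pr(v_p | PC) * A*(p) + eps )
    R_p(BG) = -log( Pr(v_p | BG) * (1 - A*(p)) + eps ).

Seeds are hard constraints. The energy is submodular and solved exactly by
Boykov–Kolmogorov max-flow (implemented in C++ in this package). Without the
prior this is the conventional graph cut (CGC); with it, the atlas-weighted
graph cut (AGC). Accuracy is scored with the Jaccard index
`JI(E, G) = |E ∩ G| / |E ∪ G|` against ground truth, and an iterative
protocol alternates corrective seeding, atlas re-fitting and re-cutting.

A synthetic phantom generator (deformed ellipsoidal organs, distractor
structures sharing the organ's intensity distribution, Gaussian noise,
simulated seed strokes) makes the whole pipeline testable without clinical
data.

## Worked example

```r
library(atlascut)

# 15 synthetic cases: organ + two intensity-confounding distractors
cohort <- make_cohort(15, confounded_phantom_spec(c(40, 40, 26), rng_seed = 11))
case   <- cohort[[1]]
seeds  <- simulate_seeds(case$mask, rng_seed = 1112)
seeds
#> <seed_image> 40x40x26 voxels, 121 organ / 296 background seeds, alpha = 1

# atlas from the other 14 cases
atlas <- build_atlas(lapply(cohort[-1], `[[`, "mask"),
                     atlas_config(lattice = c(32, 32, 16), margin = 0.25))
atlas
#> <prob_atlas> lattice 32x32x16, values in [1.05e-06, 0.991]

# fit the atlas to the seeds and warp it onto the test grid
fit <- fit_homography(atlas, seeds)
fit
#> <fit_result> mode projective, E = -113.616 after 121 iterations (converged)
prior <- warp_atlas_to_image(atlas, fit$homography, dim(case$volume$data))

# conventional vs atlas-weighted graph cut, same seeds
cgc <- segment_volume(case$volume, seeds)
agc <- segment_volume(case$volume, seeds, prior = prior)
sprintf("JI conventional: %.3f | atlas-weighted: %.3f",
        jaccard(cgc, case$mask), jaccard(agc, case$mask))
#> "JI conventional: 0.748 | atlas-weighted: 1.000"
```

The conventional cut leaks into the distractor blobs because they share the
organ's intensity distribution; the fitted atlas prior suppresses them.

## Command-line interface

A thin launcher over the same functions ships in `inst/cli/`:

```sh
Rscript inst/cli/atlascut.R simulate    --cases 15 --out cohort/ --seed 7
Rscript inst/cli/atlascut.R build-atlas --masks 'cohort/case*_mask.nii.gz' \
    --out atlas.nii.gz --lattice 32,32,16 --margin 0.25
Rscript inst/cli/atlascut.R fit     --atlas atlas.nii.gz --seeds s.nii.gz \
    --volume v.nii.gz --out prior.nii.gz --transform-out H.json
Rscript inst/cli/atlascut.R segment --volume v.nii.gz --seeds s.nii.gz \
    --prior prior.nii.gz --out mask.nii.gz
Rscript inst/cli/atlascut.R evaluate --cohort cohort/manifest.yaml --out results/
```

Volumes are read and written as NIfTI-1 (`.nii`, `.nii.gz`) or MetaImage
(`.mha`, `.mhd`). Every run writes its resolved settings as YAML next to its
outputs.

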