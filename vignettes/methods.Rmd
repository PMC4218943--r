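---
title: "Post-mortem brain segmentation and volumetry: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-mortem brain segmentation and volumetry: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Brain weight is a core measurement of perinatal autopsy: deviations from
the normal range for gestational age point to pathology. When a family
declines invasive autopsy, post-mortem MRI can substitute — if the brain
can be segmented and its volume converted to a weight. Post-mortem tissue
is a hostile target for segmentation: after death the T1 and T2
relaxation times of brain tissue rise toward free-water values, so the
usual gray/white/CSF contrast collapses and cerebrum and CSF become
nearly indistinguishable on heavily T2-weighted images. This package
implements the full analysis chain for that setting — atlas-prior EM
segmentation with a Markov random field, groupwise atlas construction,
CSF-threshold volumetry and density-based weight estimation, and the
Bland–Altman agreement layer — together with a synthetic phantom
generator that makes every stage testable without any image download.

`pmbrainvol` is organised as an analysis: the numbered scripts under
`analysis/` are thin drivers over the package functions, and every
computation they report is also exercised by the test suite.

## The phantom generator

Real scans from this setting cannot be redistributed, so the generator is
a first-class module, not a fixture. A phantom is a set of nested
ellipsoids: a head envelope filled with CSF, a cerebrum containing two
ventricular CSF pockets, a cerebellum and a brainstem. Ellipsoids were
chosen because their volumes are analytic (`4/3*pi*a*b*c`), which gives
the volumetry layer an exact oracle; where regions overlap on the voxel
grid the smaller structure wins (brainstem > cerebellum > ventricular
CSF > cerebrum > surrounding CSF).

The default conditions emulate the acquisition the method targets:
0.6 mm isotropic voxels; per-class mean intensities (cerebrum 600,
cerebellum 420, brainstem 300, CSF 900, dimensionless) with the cerebrum
mean freely settable up to equality with CSF to reproduce the
post-mortem contrast collapse; additive Gaussian noise (SD 30); a smooth
multiplicative bias field (random degree-2 log-polynomial, peak-to-trough
ratio 1.3 by default); and per-subject smooth random deformations (RMS
1.5 mm, built from Gaussian-smoothed white noise with correlation length
8 voxels, rejection-sampled to keep a positive Jacobian). Gaussian rather
than Rician noise is deliberate: the EM intensity model is Gaussian, and
magnitude-MR noise modelling is out of scope.

An optional smooth intra-tissue *texture* (disabled by default) adds a
random intensity pattern that deforms with the anatomy. It exists for
identifiability: on a piecewise-constant phantom the image is invariant
to any warp component tangential to a boundary or interior to a uniform
region, so no registration algorithm can recover such a warp from image
data. The known-warp recovery experiment therefore uses a textured
phantom (texture SD 80, correlation 3 voxels) — this mimics real
parenchymal texture and makes "the registration recovered the warp" a
well-posed claim. Cohort generation for the segmentation and volumetry
experiments keeps texture off; those results do not depend on it.

What the phantoms do **not** emulate: cortical folding, partial-volume
mixing along curved boundaries, Rician noise, maceration gradients, or
multi-contrast acquisitions. Passing tests demonstrate that the
algorithms are implemented correctly and behave as designed under
controlled conditions; they do not certify accuracy on clinical images.

## Bias-field estimation

The multiplicative inhomogeneity field is estimated by a log-domain
weighted least-squares fit of a tensor-polynomial basis (per-axis degree
2 by default) to within-mask log-intensities. Tissue structure is kept
out of the field by interleaving a deterministic 1-D Lloyd clustering of
the corrected log-intensities (6 clusters by default; deliberately more
clusters than tissues, because over-segmentation is harmless while
under-segmentation leaks anatomy into the field) and subtracting the
per-cluster means before each refit. The loop runs to a 1e-5 field
change or 8 rounds. The field is normalized to mean 1 inside the mask so
that correction preserves mean brightness — necessary because the
per-subject CSF thresholds are applied to corrected intensities and must
stay comparable across subjects. The fitted field is validated against
the phantom's known field (Pearson r, see `analysis/05`).

This estimator is not N3/N4: it shares the smooth-multiplicative-field
model but replaces histogram-sharpening deconvolution with an explicit
basis fit that is fully specified and testable.

## Registration

Transforms map points from the fixed (target) space to the moving
(source) space in millimetres — the pull-back convention, so resampling
is one forward application per target voxel. Three kinds are supported:
rigid (6 dof), affine (12 dof) and cubic-B-spline free-form deformation
(a control-point displacement lattice; dense fields are evaluated with
the standard cubic B-spline tensor basis). Composites apply right to
left, and affine pairs collapse to a matrix product.

Similarity is normalized cross-correlation, appropriate for the
same-modality phantom work (the cohorts here share one contrast
mechanism). Linear registration runs BFGS over a coarse-to-fine image
pyramid (downsampling factors 4 and 2); transforms that lose image
overlap score a flat penalty so line searches back off rather than
error. The B-spline stage works at half resolution with a knot-spacing
ladder of 16 then 8 full-resolution voxels; each stage does backtracking
gradient ascent with the analytic NCC gradient splatted onto the lattice
(the adjoint of the field evaluation), so the accepted objective is
non-decreasing by construction — the optimizer trace and stage
boundaries are attached to the returned transform. A bending-energy
penalty (squared second differences of the lattice, weight 1e-6)
discourages folding; the weight is small because NCC changes near the
optimum are of order 1e-3 and larger weights freeze the data term.
Folding in generated deformations is excluded by a positive-Jacobian
check; the registration itself reports non-convergence with a warning
and returns its best transform.

No attempt is made to reproduce any external registration package's
output; recovery of known transforms on phantoms (translation to a
fraction of a voxel, smooth warps to below one voxel mean displacement
error) is the correctness standard.

## EM segmentation with prior relaxation and MRF

The intensity model is a Gaussian per class (cerebrum, cerebellum,
brainstem, CSF — fixed order; argmax ties break toward the lowest
index). Each iteration:

* **E-step** — responsibilities proportional to
  `effective_prior * N(y; mu, sigma^2) * exp(beta * sum of 6-neighbour
  posteriors)`, the mean-field form of a Potts MRF (`mrf_beta` 0.5 by
  default);
* **M-step** — means and variances from the responsibilities, with a
  variance floor and a warning if a class's total responsibility
  vanishes (the class is retained);
* **relaxation** — `effective_prior <- (1 - alpha) * atlas_prior +
  alpha * G_sigma(posterior)` with `relaxation_alpha` 0.2 and
  `relaxation_sigma` 2 voxels, letting the segmentation depart from an
  imperfect atlas.

Initialization is deterministic (prior-weighted intensity moments; if
spatially uniform priors make all classes identical, intensity quantiles
break the symmetry). Convergence is a 1e-5 relative change of the
mean-field objective or 100 iterations. With `mrf_beta = 0` and
`relaxation_alpha = 0` the algorithm reduces to exact EM for a Gaussian
mixture with per-voxel priors; the test suite verifies that limit
against an independent brute-force implementation at 1e-10 and checks
objective monotonicity.

The second stage merges cerebrum and CSF by summing posteriors and
re-taking the argmax. Keeping CSF as a separate class during EM is what
protects the cerebellum and brainstem, which are surrounded by fluid;
merging afterwards acknowledges that the collapsed contrast makes the
cerebrum/CSF boundary unreliable.

## Groupwise atlas

The average atlas is built by registering every subject to the current
average with an increasing-degrees-of-freedom schedule — one rigid, four
affine, four B-spline rounds by default, configurable because the
appropriate depth depends on cohort diversity — re-averaging
(arithmetic mean) after each round. After the last round the per-subject
average-to-native transforms propagate the soft posteriors (averaged
into priors; the alternative of averaging hard labels discards boundary
information) and the masks (majority vote at 50%). The per-round mean
absolute template change is recorded as the stability diagnostic; the
suite asserts it falls below 5% of the intensity range by the final
round.

## Volumetry and agreement statistics

Fluid is removed from the merged cerebrum+CSF region by a per-subject
intensity threshold on the bias-corrected image; exclusion is strict
(`> threshold` removed, boundary voxels retained). Volume is the binary
voxel count times the voxel volume; weight is volume times a density of
1.08 g/mL (configurable — the literature constant may not hold exactly
post mortem). A histogram-valley helper can suggest a threshold but is
flagged experimental; the packaged cohort tables carry the thresholds
actually used per subject.

Agreement uses differences `reference - test` (autopsy minus MRI), the
n−1 standard deviation, and 95% limits of agreement at mean ± 1.96 SD;
aggregates are reported to the nearest gram with half-away-from-zero
rounding. The n−1 denominator and the sign convention are verified
against the packaged tables by the suite. Dice is
`2|A∩B| / (|A| + |B|)`; two empty regions score 1 with a warning so a
degenerate phantom class cannot poison a suite.

## Problem sizes and numerical choices

The validation experiments run at desk scale, chosen once: the
end-to-end cohort experiment uses 5 subjects at 64^3 voxels; the
prior-source comparison 5 repeats at 48^3; component recovery at 48^3;
unit tests mostly at 24–48^3. The EM oracle instance is 8^3 so a naive
loop implementation stays exact and fast. Matched-vs-mismatched Dice is
compared at the 3-decimal precision such scores are conventionally
reported to, because two near-perfect segmentations can differ by
numeric dust.

Other numerical choices: resampling uses trilinear interpolation for
intensities and priors (priors renormalized to a per-voxel sum of at
most 1) and nearest-neighbour for label maps (enforced); B-spline
displacement fields are edge-extended outside their defining grid; a
uniform prior floor of 1e-3 inside the mask absorbs residual
registration error at the prior support boundary; propagated brain masks
drop voxels below 0.25 × the within-mask median intensity before EM —
the automated analogue of manually excluding non-brain voxels from a
propagated mask, without which background leaks capture the smallest
class.

## Design decisions on genuinely open points

* Soft posteriors, not hard labels, are averaged into the atlas priors.
* Pipeline stages return in memory with provenance rather than caching
  to disk keyed by a config hash: at these problem sizes a full rerun is
  minutes and determinism under a fixed seed makes a cache a source of
  staleness risk rather than a saving.
* The command-line surface is the set of `analysis/` scripts over
  exported functions; a separate binary-style CLI would duplicate them.
* The two newborn table rows whose printed weights are inconsistent with
  their printed volumes (subjects 274 and 306) are packaged verbatim and
  surfaced by the round-trip report, not corrected: the tables are
  inputs, not outputs.

## Limitations

Segmentation quality on phantoms bounds nothing about clinical images —
real post-mortem scans add maceration gradients, partial-volume mixing,
motion and coil artefacts absent here. The CSF threshold remains a
per-subject manual choice; the histogram helper is unvalidated. The
density constant is a single literature value applied to all subjects.
Rigid/affine recovery is validated to fractions of a voxel, but B-spline
recovery is only meaningful up to the identifiability limit discussed
above; on textureless regions the reported warp is an extrapolation of
the regularizer, not a measurement.
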