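---
title: "Methods: multiphoton multiparametric 3D skin quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiphoton multiparametric 3D skin quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

In vivo multiphoton microscopy of human skin acquires z-stacks that combine
two endogenous contrasts: two-photon excited fluorescence (2PEF) from
keratin, NAD(P)H, melanin and elastin, recorded in four temporally binned
FLIM channels of 2.08 ns each (0–8.33 ns range, intensity peak near
1.33 ns), and second harmonic generation (SHG), which is specific to
fibrillar collagen. From one such stack, `mpskin` computes the quantities
that characterize skin aging in 3D:

* **morphology** — mean stratum corneum (SC), living epidermis (LED) and
  total epidermal thickness, and the *normalized DEJ area* (3D area of the
  dermal–epidermal junction divided by its horizontal projection; 1 for a
  flat junction, larger the more undulated);
* **melanin** — a 3D melanin voxel mask from Pseudo-FLIM slope analysis,
  its global epidermal density (melanin voxels / epidermal voxels), basal
  and LED densities, and a z-profile over 10 thickness-normalized epidermal
  sublayers running from the DEJ (index 1) to the SC (index 10);
* **dermal fibers** — elastin (2PEF) and collagen (SHG) masks within the
  dermis, their 3D densities in DEJ-following dermal bands, the SHGto2PEF
  ratio, the density-based SAAID index `(C − E)/(C + E)`, and the
  normalized imbrication ImbrN, the Jaccard overlap `|E ∩ C| / |E ∪ C|` of
  the two fiber networks;
* **statistics** — folded F variance tests, pooled Student t contrasts and
  Cohen's d with the interpretation bands very weak [0, 0.3), weak
  [0.3, 0.5), moderate [0.5, 0.8), strong [0.8, 1.3), very strong
  [1.3, ∞), plus an ROI-robustness analysis (2 vs 3 and 2 vs 4 ROIs per
  subject) and Pearson correlation screening.

All indices in the R API are 1-based; the depth of plane *k* is
`(k − 1) · z_step` µm below the first acquired plane. Channel order is the
four time channels in ascending time, then SHG.

## Layer segmentation

The segmentation produces three regularized depth maps (skin surface,
SC/LED boundary, DEJ) and a voxel label volume {background, SC, LED,
dermis}, with the invariant `surface ≤ sc_led ≤ dej` enforced by
projection.

**Skin surface.** Per column, the first depth at which the
Gaussian-smoothed total-2PEF signal exceeds the detection threshold for two
consecutive planes. The threshold is the larger of the background level
(top-plane mean + 3 SD) and half the column maximum, so the crossing sits
at the half-rise of the intensity edge rather than its noise toe. The
surface is placed midway between the last background plane and the first
tissue plane — the continuous, unbiased convention for a boundary sampled
on a plane grid.

**DEJ.** Collagen SHG is sparse at the voxel level, so the detector works
on an *occupancy* volume: SHG-above-background voxels smoothed with a wide
lateral Gaussian (σ = 2.5 px; no axial smoothing, which would bleed
occupancy above the junction). A voxel counts as collagen-occupied when its
occupancy exceeds 0.45 of the deep-dermis occupancy level. Each candidate
depth is scored with a changepoint cost — every plane at or below the
candidate contributes +1 if occupied, −1 if not — and a dynamic program per
image line finds the minimal-cost surface under a hard lateral slope
constraint (±2 planes/pixel) plus a soft slope penalty (2 score units per
plane) that damps plane-to-plane jitter on flat junctions. The map is the
midpoint between the last epidermal plane and the occupancy onset plane;
voxel labelling assigns the onset plane itself to the dermis (half-voxel
rounding). Placing the label cut at the onset plane rather than at the
continuous midpoint matters: the alternative flips bright epidermal
boundary voxels into the dermis, where they masquerade as elastin.

**SC/LED boundary.** The SC is brighter than the LED (keratin); the
boundary is the steepest drop of the smoothed 2PEF profile within the upper
60 % of the epidermis. Columns without detectable contrast (top/mid
intensity ratio < 1.15) fall back to a configurable prior (0.2 of the
epidermal thickness, with a warning) or, optionally, collapse to the
surface — the choice `noContrastBoundary = "prior" | "surface"` exists
because a zero-thickness SC and a uniformly bright epidermis are
observationally identical.

All maps receive 5×5 median regularization followed by a Gaussian smooth
(σ = 2 px) that removes the z-quantization staircase which would otherwise
inflate the normalized DEJ area. Defaults were calibrated on phantoms with
known ground truth; with the shipped defaults the phantom recovery is:
surfaces within one z-step (median; max for the skin surface), voxel label
agreement ≥ 95 %, epidermal and SC thickness within one z-step, melanin
global density within ±10 % relative, band fiber densities within ±0.02.

## Pseudo-FLIM melanin detection

Melanin's fluorescence lifetime (≈ 0.2 ns) is far shorter than that of the
other epidermal fluorophores (≈ 1.5–2 ns). Over four coarse temporal bins a
full lifetime fit is pointless; instead the per-voxel decay rate is the
ordinary least-squares slope of `ln(counts + 1)` against the bin mid-times,
over all four bins (the peak at 1.33 ns lies inside bin 1, and with 2.08 ns
bins dropping it costs more statistical power than its rise-time bias
adds). Voxels with fewer than 25 total counts are excluded (undefined
slope). The melanin mask is the epidermal voxels whose decay rate exceeds a
threshold calibrated as the midpoint of the noiseless rates of the two
reference populations (0.2 ns vs 1.8 ns at the calibration photon budget);
it ships as a config value, never a hard-coded constant.

The z-profile divides the epidermis of each column into K = 10 sublayers of
equal normalized thickness (`ceil(K (dej − z)/(dej − surface))`, clamped),
so sublayer 1 touches the DEJ and sublayer 10 the SC; the voxel-weighted
mean of the profile equals the global density exactly, which the tests
assert as an identity.

## Dermal fiber metrics

Within the dermis only, the total-2PEF and SHG volumes are thresholded
(default: Otsu on the within-dermis histogram, per channel per stack;
alternative: background mean + k·SD). Densities are voxel fractions within
a scope — the whole imaged dermis, or fixed-thickness bands measured
axially below the DEJ map so they follow its shape; band k covers
depths-below-DEJ [(k−1)T, kT), and voxels deeper than the last band form a
flagged remainder that headline outputs exclude. The 50 µm single band is
the default summary scope. SAAID and SHGto2PEF satisfy
`SAAID = (r − 1)/(r + 1)` exactly; ImbrN is computed on raw masks, with an
optional tolerance dilation (default 0 µm) for analyses that want to accept
one-voxel offsets between the networks.

## The phantom: what it emulates, what it does not

The generator (`generatePhantom`) builds a skin volume with full ground
truth under the acquisition geometry of the clinical stacks: 2.346 µm
z-step, four 2.08 ns time channels peaking at 1.33 ns, and a
130.3 × 130.3 µm² field of view sampled by default on a 128 × 128 grid
(1.02 µm/pixel, a 4× spatially binned emulation of the 511 × 511
acquisition; tests use smaller grids, the acceptance script 96 × 96 × 48).
Structure: a flat-to-tilted surface, an SC of constant thickness
(2× brighter than the LED), a sinusoidal or bump-like DEJ (default
amplitude 10 µm, period 50 µm, young forearm), melanin occupying basal
voxels with probability decaying exponentially in normalized height above
the DEJ (basal fraction 0.3, e-folding 0.25), and a dermis of tubular
fibers grown as persistent-direction random walks dilated to a 1 µm
radius — collagen (SHG-emitting, 15 % volume fraction) first, then elastin
(2PEF, 5 % young / 15 % old) with a configurable fraction of walks seeded
along collagen paths to control the true imbrication. Walks start at
uniformly random columns and uniformly random depths below the local DEJ,
so coverage under the undulated junction is laterally uniform (as in real
papillary dermis, whose superficial collagen is why SHG onset marks the
DEJ at all) while the depth profile of fiber density stays flat. Emission integrates
a shifted mono-exponential decay over each bin, scales by structure
brightness and photon budget (200 expected counts per unit-brightness
voxel), attenuates with depth (e-folding 50 µm) unless the instrument-style
exponential excitation gain is enabled (the default, as on the clinical
systems), and Poisson-samples.

Deliberately absent: optical PSF and scattering, instrument response
deconvolution, nuclei and capillaries, melanin-dependent attenuation
(attenuation depends on depth only). Passing recovery tests therefore shows
the *estimators* are unbiased under realistic counting noise and geometry —
not that segmentation would survive contrast mechanisms the phantom does
not model. Where neither the acquisition description nor the metric
definitions fix a value (fiber radii, melanin decay shape, photon budget),
the defaults are one-time choices of plausible magnitudes, not fitted
quantities.

Cohorts add two levels of variability: multiplicative lognormal
between-subject perturbation of the structural parameters (CV 0.1) and
fresh Poisson noise per ROI — the same structure as the clinical designs
(~2 ROIs per subject). The repeat series re-samples noise on a fixed truth,
optionally with a rigid drift, mirroring the repeatability experiment of
re-imaging one region every 10 min.

## Statistics

Mixed models with subject as a random factor are simplified to ROI-averaged
subject-level contrasts: the folded F (larger variance over smaller,
two-sided folded p), the pooled-variance Student t, and Cohen's
d = (mean difference)/(pooled SD). For balanced two-ROI designs this
pooled-SD denominator coincides with the between-subject variance the mixed
model would use; the equivalence is approximate otherwise and is stated as
a simplification, not an identity. Significance is 5 % two-sided with no
multiplicity adjustment (exploratory stance). ROI-robustness uses the first
k ROIs in acquisition order — deterministic, not random subsets.

## Numerical choices and degenerate inputs

* `ln(counts + 1)` regularizes zero bins in the slope regression.
* Otsu runs on a 256-level histogram of the within-dermis counts.
* The DEJ area triangulates each pixel quad along the same diagonal;
  the 90°-rotation discrepancy of that choice is below 10⁻³ on smooth maps.
* Degenerate inputs raise errors, not wrong numbers: all-noise stacks ("no
  skin detected"), SHG absent ("no dermis detected"), SHG from the first
  plane ("empty epidermis"), empty scopes, zero variances.
* Determinism: identical (config, seed) gives bit-identical phantoms;
  identical (stack, config) gives identical metric rows. Package functions
  restore the caller's RNG state.

## Known limitations

* A perfectly flat DEJ measured on the plane grid retains a normalized-area
  roughness excess of ≈ 0.02–0.05, because sparse SHG onsets land on
  neighbouring planes.
* Dermal papilla tips are partially clipped: at 15 % collagen occupancy a
  narrow dermal peak holds only a handful of SHG voxels, below what the
  occupancy-onset detector can resolve, so the recovered undulation
  amplitude is attenuated (≈ 60–70 % of truth at the default sparsity and
  sampling) while its lateral phase structure is preserved (pattern
  correlation > 0.8) and the median junction error stays below one z-step.
  Group comparisons of the normalized DEJ area are unaffected since the
  attenuation is shared.
* The surface and SC thickness inherit up to half a z-step of quantization
  bias when the true boundary falls between planes.
* The dermal 2PEF mask does not exclude cellular fluorescence (fibroblasts,
  blood cells); on real data the "mainly elastin" mask slightly overcounts.
* The phantom's lifetimes are mono-exponential per structure; bi-exponential
  or phasor FLIM analyses are out of scope.
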