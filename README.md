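# mpskin

Multiphoton multiparametric 3D quantification of in vivo human skin.

In vivo multiphoton microscopy records z-stacks of human skin combining two
endogenous contrasts: two-photon excited fluorescence (2PEF, from keratin,
NAD(P)H, melanin and elastin) split into four temporally binned FLIM
channels of 2.08 ns, and second harmonic generation (SHG), specific to
fibrillar collagen. `mpskin` turns one such 5-channel stack into the 3D
quantities used to characterize skin pigmentation and aging:

* **Layer segmentation** — skin surface, stratum corneum / living epidermis
  (SC/LED) boundary and dermal–epidermal junction (DEJ) as regularized depth
  maps (the DEJ via a smoothness-constrained minimal-cost surface through an
  SHG-occupancy changepoint cost), composed into a voxel label volume.
* **Morphology** — mean SC, LED and epidermal thickness; normalized DEJ area
  `A(DEJ) / A(projection)` (1 = flat junction, larger = more undulated).
* **Melanin** — Pseudo-FLIM detection: per-voxel decay rate from the OLS
  slope of `ln(counts + 1)` over the bin mid-times (melanin's ~0.2 ns
  lifetime decays much faster than the ~1.8 ns background); global epidermal
  density, basal-layer density, and a z-profile over 10 thickness-normalized
  epidermal sublayers from the DEJ (1) to the SC (10).
* **Dermal fibers** — elastin (2PEF) and collagen (SHG) masks within the
  dermis; 3D densities in DEJ-following dermal bands; the SHGto2PEF ratio
  `r = C/E`; the density-based aging index `SAAID = (C − E)/(C + E)`; the
  normalized imbrication `ImbrN = |E ∩ C| / |E ∪ C|` (Jaccard overlap of the
  two fiber networks).
* **Statistics** — folded F variance test, pooled Student t contrasts,
  Cohen's d with effect-size bands (very weak [0, 0.3) … very strong
  [1.3, ∞)), ROI-robustness comparison (2 vs 3 and 2 vs 4 ROIs per subject)
  and Pearson correlation screening.
* **Synthetic phantom** — a full-ground-truth skin simulator (undulated DEJ,
  melanin-graded epidermis, tubular elastin/collagen networks, Poisson
  counting noise, depth attenuation) so every estimator is validated by
  parameter recovery.

Stacks are read and written as multipage 16-bit TIFF plus a YAML metadata
sidecar (`readStack()` / `writeStack()`); a command-line wrapper lives at
`inst/scripts/mpskin.R` (`quantify`, `phantom`, `compare`, `validate`).

## Worked example

```r
library(mpskin)

cfg <- phantomPreset("young_forearm", dims = c(64L, 64L, 40L), seed = 7L)
ph  <- generatePhantom(cfg)
ph$stack
#> MultiphotonStack 'phantom': 64 x 64 x 40 voxels, 5 channels
#> AcquisitionMeta: 4 time channels x 2.08 ns + SHG (channel 5); 1.017969 um/pixel, 2.346 um z-step
#>   depth range: 0 - 91.49 um; max count: 290

q <- quantifyStack(ph$stack)
round(t(q$metrics[, c("meanEpidermalThicknessUm", "dejNormalizedArea",
                      "melaninGlobalDensity", "elastinDensity50",
                      "collagenDensity50", "shgTo2pef50", "saaid50",
                      "imbrn50")]), 3)
#> meanEpidermalThicknessUm 52.278
#> dejNormalizedArea         1.289
#> melaninGlobalDensity      0.072
#> elastinDensity50          0.054
#> collagenDensity50         0.160
#> shgTo2pef50               2.987
#> saaid50                   0.498
#> imbrn50                   0.045
```

The measured epidermal thickness (52.3 µm) recovers the phantom's ground
truth (50.2 µm) within about one z-step (2.346 µm); the melanin density
(0.072) matches the truth-mask density (0.076) within a few percent; the
elastin/collagen densities in the 50 µm DEJ-following dermal band give the
young-skin signature of a high SHGto2PEF ratio and positive SAAID. Group
contrasts follow with `generateCohort()` → `aggregateRois()` →
`compareGroups()`, which reports t, p, Cohen's d and its band per metric;
an "old temple" preset (thinner epidermis, flatter DEJ, elastosis) against
a "young forearm" preset reproduces the qualitative aging signature:
elastin density up, SAAID / SHGto2PEF / epidermal thickness / DEJ area
down, ImbrN up.

See `vignettes/mpskin-methods.Rmd` for the model, parameter defaults and
their calibration, and known limitations.

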