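# extrafib

Quantifying how much of the mineral in cortical bone lies **outside** the
collagen fibrils.

Bone is a composite of type I collagen fibrils and hydroxyapatite (HA).
A volume balance already shows the classical gap-zone picture cannot hold
all of it: with mineral at ~45 vol% of bone and gap zones at ~12 vol% of
the fibrils, at least 73% of the mineral must be extragap. TEM of
ion-milled sections shows where it is — 5 × 65 × 200 nm plate-like
"mineral structures" cladding the fibrils — and EDXS Ca count rates let
that fraction be quantified. This package implements that analysis and a
fully synthetic validation pipeline for it:

* **Unit-cell geometry** — the rectangular unit volume of the
  ultrastructure (gap zone G, overlap zone O, vertical inter-fibril plate
  stack V, over/underlying plates H) and its projected areas
  `A_G = 2000`, `A_V = 1809`, `A_H = 5159` nm² at the default
  50/40/27/27 nm dimensions.
* **EDXS count partition** — from count rates `C_O`, `C_G`, `C_V`
  (counts/nm² over overlap, gap and stack regions), correct for the
  plates the beam always traverses, `C'_G = C_G − C_O`,
  `C'_V = C_V − C_O`, and estimate the extrafibrillar fraction

  $$X_{ext} = \frac{A_H C_O + A_V C'_V}
                   {A_H C_O + A_V C'_V + A_G C'_G}$$

* **Synthetic ultrastructure** — a periodic voxel model (cylindrical
  banded fibrils on a square lattice, stacks of mineral plates with
  ±18° long-axis dispersion) with exact ground-truth mineral partition,
  sectioning at arbitrary plane normals, projection images, Poisson EDXS
  simulation, and two realistic count read-out protocols.
* **Image measurements** — D-period and lane spacing by autocorrelation,
  plate thickness by FWHM, hole-ellipse fitting by image moments.
* **Diffraction texture** — 00l arc extent and view-dependent 00l
  visibility from the plate orientation distribution.

## Worked example

```r
library(extrafib)

## the packaged reference count rates (three longitudinal-section areas)
rep <- reproduceReferenceTable()
rep$table[c("sample", "C_O", "C_G", "C_V", "Cp_G", "Cp_V", "X_ext")]
#>     sample  C_O  C_G  C_V Cp_G Cp_V     X_ext
#> 1 Sample 1 1.66 4.55 7.02 2.89 5.36 0.7596394
#> 2 Sample 2 3.16 5.20 6.03 2.04 2.87 0.8405023
#> 3 Sample 3 3.16 5.20 7.37 2.04 4.21 0.8543154
rep$summary
#> $mean      0.8181523     # 81.8% of the mineral is extrafibrillar
#> $spread    0.04175744    # population SD, "81 ± 4 %"
#> $n         3
```

The corrected counts `Cp_G`, `Cp_V` isolate the gap-zone and
vertical-stack signals; `X_ext` is the fraction of all mineral external
to the fibrils in each sampled area.

Validating the estimator on a synthetic scene with known truth:

```r
cfg <- SceneConfig()                       # 3×3 fibrils, 3 D-periods, 1 nm voxels
r <- runRecoveryExperiment(cfg, nSeeds = 1)   # noise-free read-out
r$perSeed
#>   seed  X_true     X_est        error
#> 1    1 0.801577 0.7960568 -0.005520197
```

The ground-truth partition of the 100 nm section is 0.802; the estimator
applied to its noise-free projection returns 0.796 — a model-mismatch
bias of −0.006, far inside the ±0.05 budget. With Poisson-counted 100 nm²
probes (`doseScale = 0.05`, a few hundred counts per probe) the per-sample
estimates scatter like the real measurements do (SD ≈ 0.03).

Measurements on the same scene recover the configured dimensions:

```r
sc <- buildScene(cfg)
estimateDPeriod(projectScene(sc, "y"))$value_nm     # 67.06 (configured: 67)
measureLaneSpacing(projectScene(sc, "y"))$value_nm  # 76.98 (configured: 77)
arcExtent(plateAngles(sc))                          # ≤ 36, from ±18° dispersion
```

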