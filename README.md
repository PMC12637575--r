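# centroshell

Quantitative image analysis for centromeres and inner kinetochores that
appear as ~200–300 nm ring- or shell-like foci in super-resolution
fluorescence microscopy.

In interphase nuclei, CENP-A and the constitutive centromere-associated
network (CCAN) organize into hollow, semi-enclosed shells around a
chromatin-poor cavity occupied by the CENP-A chaperone machinery.
Establishing that picture quantitatively requires a small set of image
measurements that this package implements as tested, reusable code:

* **Synthetic phantom generation** (`render_dataset()`): seeded 3D nuclei
  containing shell- or punctum-shaped centromeric structures with known
  ("ground truth") diameters, intensities and positions, imaged through an
  anisotropic PSF (lateral FWHM ≈ 125 nm, axial ≈ 360 nm; band-limited SIM
  or Gaussian lateral model), with Poisson + read noise and a chromatin
  texture channel whose density is reduced inside each shell cavity.
  Because no raw imaging data accompany the study this emulates, every
  downstream stage is validated against this generator's truth tables.
* **Isotropic resolution enhancement** (`isotropize_volume()`): the
  lateral-degradation model used to build training pairs for an axial
  super-resolution restorer (`degrade()`, `make_training_pairs()`), and the
  application protocol — resample to a 40 nm isotropic grid, degrade,
  restore along x in frames rotated about the y axis, and fuse all angles
  by per-frequency Fourier maximum. The restorer is pluggable: an analytic
  1D Wiener (or Richardson–Lucy) deconvolver by default, a trained neural
  restorer via `restorer_spec("external", fn = ...)`.
* **Linescan morphometrics** (`extract_linescan()`, `normalize_and_align()`,
  `measure_ring_diameter()`): background-corrected, max-normalized line
  profiles aligned on their central extremum, and the ring-diameter
  measurement — the distance between the two highest peaks along the
  longest axis of the ring.
* **Spot quantification** (`detect_centromeres()`,
  `corrected_spot_intensity()`, `classify_structure()`, `ring_fraction()`,
  `compare_conditions()`): Laplacian-of-Gaussian spot detection, the
  dual-box background estimator (inner 9×9 and outer 13×13 pixel boxes;
  `corrected = inner − (outer − inner) × 81/88`), ring/punctum
  classification from radial profiles, per-nucleus ring fractions, and
  two-condition comparisons by unpaired t-test.
* **Pipeline driver** (`run_pipeline()`): simulate → isotropize → profile →
  quantify → report under one seed, with YAML configuration, CSV/TIFF
  outputs and a JSON run manifest. A thin command-line wrapper is installed
  at `inst/scripts/run-pipeline.R`.

## Worked example

Simulate two nuclei with CENP-T-like shells (truth diameter 278 ± 42 nm),
then detect, classify and measure every structure in the first nucleus:

```r
library(centroshell)

img <- imaging_spec()   # 3D-SIM-like: 125/360 nm PSF, 40/125 nm voxels
ds  <- render_dataset(preset("cenpt"), n_nuclei = 2,
                      structures_per_nucleus = 10,
                      imaging = img, seed = 42, dna = FALSE)

q <- quantify_structures(ds$nuclei[[1]]$marker,
                         background = img$background_level)
head(q[q$label == "ring" & q$quality == "ok",
       c("roi_id", "diameter", "central_dip_ratio")], 5)
#>   roi_id diameter central_dip_ratio
#> 1      1      263           -0.0838
#> 2      2      235           -0.0445
#> 3      3      289           -0.0471
#> 4      4      279           -0.0451
#> 5      5      270           -0.0566

measured <- q$diameter[q$label == "ring" & q$quality == "ok"]
sprintf("mean ring diameter: %.0f +/- %.0f nm (truth: 278 +/- 42 nm)",
        mean(measured), sd(measured))
#> "mean ring diameter: 285 +/- 38 nm (truth: 278 +/- 42 nm)"
```

Each `diameter` is the peak-to-peak separation (nm) of the two highest
linescan peaks along the structure's longest axis; `central_dip_ratio` is
the centre-to-rim intensity ratio used to call a structure ring-like
(≤ 0.9) — values near 0 mean a deeply hollow ring. On this nucleus all 9
resolvable structures are rings (ring fraction 100%), as expected for a
generator preset with ring probability 1.

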