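---
title: "Estimating hepatocyte ploidy in situ: models, gates and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating hepatocyte ploidy in situ: models, gates and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepaploidy)
```

## The problem

Adult mammalian hepatocytes are routinely polyploid: a healthy liver
contains diploid (2c), tetraploid (4c), octoploid (8c) and even 16c
nuclei, and the balance between these populations shifts during injury
and regeneration. Flow cytometry measures ploidy precisely but destroys
the tissue context. `hepaploidy` implements an image-cytometry
alternative: DNA content is estimated for every segmented nucleus
directly in Hoechst/HNF4α-stained 2D tissue sections, so that ploidy can
be read out *in situ*, alongside position, morphology and marker status.

## The DNA-content model

A 2D section gives the projected area $A$ of each nucleus and the mean
Hoechst intensity $\bar{I}$ over its mask. Treating the nucleus as a
sphere whose radius is the equivalent radius of the projection,

$$r_{eq} = \sqrt{A/\pi}, \qquad
  V = \tfrac{4}{3}\pi r_{eq}^{3}, \qquad
  \text{content} = \bar{I} \times V,$$

the mean intensity plays the role of a DNA *density* and the interpolated
spherical volume converts it to an amount. The quantity $\bar I V$ is in
arbitrary intensity·µm³ units; it becomes interpretable through internal
calibration (below). Two consequences of this functional form drive much
of the package's design:

* it is exactly invertible on synthetic data, so every pipeline stage can
  be validated against ground truth with tight tolerances;
* it is linear in intensity, so any global intensity scale (exposure,
  gain, staining strength) cancels after calibration.

Only near-circular nuclei are analysed: the spherical interpolation is
meaningless for elongated or bilobular nuclei, so a circularity gate
keeps nuclei with fitted-ellipse elongation (minor/major axis ratio)
strictly above 0.8. Elongation is computed from the second central
moments of the binary mask; a perimeter-based circularity
($4\pi A/P^2$) was considered but rejected because it is far more
sensitive to mask discretisation at small radii.

## Internal 2n calibration

Absolute intensities are not comparable across sections, so the scale is
anchored *within each field*: the HNF4α-negative nonparenchymal cells
(stellate, endothelial and immune cells) are overwhelmingly diploid, and
the **median** DNA content of the circularity-gated HNF4α− nuclei is
taken to define 2c. The median (rather than mean) resists segmentation
outliers and the occasional missegmented clump; an area cap on
reference candidates (default 40 µm²) removes the rare large HNF4α−
objects that are doublets rather than nuclei. Calibration refuses to run
with fewer than `min_reference_n` (default 50) reference nuclei: a
median over a handful of NPCs would silently dominate every downstream
number.

Continuous ploidy is then $c = 2 \cdot \text{content} /
\text{content}_{2n}$ and discrete classes are assigned by the nearest
doubling in log2 space: a nucleus is 2c/4c/8c/16c when
$\log_2 c$ falls within a half-open window
$[\log_2 v - w,\ \log_2 v + w)$ around the class value $v$, with
$w = 0.5$ by default so class boundaries sit at the geometric midpoints
(e.g. $2\sqrt 2 \approx 2.83$ between 2c and 4c). The half-open
convention removes boundary ties; shrinking $w$ can only move nuclei
from an assigned class to *unassigned*, never between classes, which
makes the window a pure stringency knob.

Multimodality of the content distribution is summarised by the local
maxima of a Gaussian kernel-density estimate of $\log_2$ content
(bandwidth by Silverman's rule, the `stats::density()` default). Maxima
below 5% of the tallest peak are discarded as estimator ripple. On
log-content, ploidy peaks are equally spaced and equally wide, which is
why detection is run there rather than on raw content.

## Population gates

Three published gates are reproduced with their exact boundary
semantics:

| gate | definition | bounds |
|---|---|---|
| circularity | elongation > 0.8 | strict |
| 2c hepatocyte | HNF4α+ and area in 19.99–34.99 µm² and elongation > 0.8 | area inclusive |
| small hepatocyte | HNF4α+ and area < 75 µm² | strict |

Because 34.99 < 75, the 2c gate is provably a subset of the
small-hepatocyte gate on any input — a structural invariant the test
suite asserts. Densities (nuclei/mm²) and the HNF4α+ nuclear-area
histogram complete the per-field summary.

## Segmentation

Nuclei are identified from the Hoechst channel by: optional Gaussian
smoothing → global Otsu threshold → hole filling → distance-transform
watershed → minimum-area filter (default 5 µm²) → optional removal of
edge-touching nuclei (default on, since their morphometry is clipped).

Two choices deserve explanation.

**Otsu on square-root intensities.** Under the density × volume model
the per-pixel Hoechst density scales as $c/V \propto c^{-1/2}$: a 16c
nucleus is roughly $\sqrt 8 \approx 2.8\times$ dimmer per pixel than a
2c one. With that dynamic range a linear-domain Otsu can maximise
between-class variance by splitting *within* the foreground — brightest
diploid nuclei against everything else — and silently delete the dim
polyploid nuclei the study is about. The square-root transform
compresses the foreground spread (and stabilises Poisson shot-noise
variance) so the threshold settles at the background/foreground
boundary. It is also exactly equivariant under intensity rescaling
($\sqrt{sx} = \sqrt s \sqrt x$ preserves the Otsu cut), so the
segmentation mask — and hence every calibrated ploidy value — is
invariant to exposure. The implementation is an exact (unbinned) Otsu
whose threshold is a midpoint between observed values, avoiding
histogram-bin artefacts. A log transform was tried first and rejected:
it over-expands the dark background tail and Otsu then splits inside
the background.

**Watershed tolerance 2 px.** The watershed must separate distinct
nuclei that touch, yet must *not* cut bilobular nuclei into two
plausible-looking round lobes — those would pass the circularity gate
carrying half their true content each and contaminate the class
fractions one doubling down. The distance-transform saddle depth
discriminates the two cases: touching distinct nuclei meet at a waist
close to zero thickness, giving a saddle depth near a full nuclear
radius (≳ 4 px for the smallest nuclei at 0.5 µm/px), while strongly
fused lobes (centre separation equal to the lobe radius) have a shallow
saddle of about 0.13 lobe radii (≲ 1.7 px even for 16c nuclei). The
default seed tolerance of 2 px sits between the two regimes.

## The synthetic-tissue generator

No image data accompany the methodology this package implements, so
validation rests on a generator that emulates exactly the statistical
structure the analysis assumes — and states what it does not emulate.

Each field draws nuclei from five classes with class means chosen so the
published gates are meaningful at the defaults: 2c hepatocyte nuclei
average 27.49 µm² (the centre of the 19.99–34.99 µm² 2c window),
projected area doubles with each ploidy doubling (4c ≈ 55, 8c ≈ 110,
16c ≈ 220 µm²), and NPC nuclei average 22 µm², comfortably under the
40 µm² reference cap. Within-class areas are lognormal with 8% CV;
regular nuclei are ellipses with axis ratio drawn in (0.85, 1), so they
pass the 0.8 gate. The default pixel size is 0.5 µm/px — typical of a
20× high-content objective — and is configurable.

The Hoechst plane is filled at a uniform density $d$ per nucleus with
$d\,\tfrac43\pi r_{eq}^3 = k\,c$ for one global constant $k$ (default
20 000 intensity·µm³ per c), where $r_{eq}$ comes from the *rendered*
mask, so the pipeline's model holds exactly up to detector quantisation.
Uniform density deliberately omits chromatin texture: the generator's
job is to isolate pipeline error from biological texture, and this is
the main respect in which passing tests do **not** certify behaviour on
real tissue (alongside the absence of optical PSF blur, z-structure,
uneven illumination and staining chemistry). Noise is applied after
rendering — optional Poisson on signal, additive Gaussian (default 2% of
mean nuclear signal), then a constant background offset (default 10) —
and intensities are rounded to the 16-bit grid.

A configurable fraction of hepatocyte nuclei is rendered bilobular (two
fused circular lobes, centre separation = lobe radius); their fitted
elongation lands near 0.65, well below the 0.8 gate, and the watershed
keeps them whole by the saddle-depth argument above. Independent nuclei
are placed by rejection sampling with a one-pixel clearance ring, so
fields are genuinely disjoint unless a `touching_fraction` explicitly
requests adjacent (boundary-to-boundary, non-overlapping) pairs for
stress-testing the watershed. Packing is refused above 40% nominal
coverage, with an error naming the constraint. One seeded RNG stream per
call leaves the caller's RNG state untouched; the same seed reproduces
the field bit for bit.

## Numerical and degenerate-input conventions

* Pixel-centre membership defines all rendered masks; areas are pixel
  counts × (pixel size)²; coordinates are top-left-origin, row-major,
  and centroids are reported in µm.
* A blank Hoechst image segments to zero labels (not an error); a
  constant image has no objects.
* Otsu thresholding (image-level and per-nucleus) refuses inputs with
  fewer than two distinct values and asks for an explicit threshold.
* Modal pixel intensity bins by `floor()` and breaks ties toward the
  lowest bin, so the readout is deterministic.
* Marker fractions with an empty denominator are reported as undefined
  (`NA` + flag), never as 0 or 1; every thresholded result records the
  thresholds actually used.
* The t machinery flags zero-variance degeneracies instead of returning
  infinite statistics: identical means give $t = 0, p = 1$; unequal
  means with zero variance are flagged degenerate.

## Validation problem sizes

The shipped validation suite regenerates everything from code: the
standard cohort is one 1500×1500 px field (0.5 µm/px) with 2,000 nuclei
(40% NPC, 30% 2c, 20% 4c, 7% 8c, 3% 16c, 10% bilobular, 2% noise), on
which class fractions among gated hepatocyte nuclei are recovered within
±3 percentage points and the 2n calibration within ±5% of the
generator's 2c content; smaller noiseless fields (50–150 nuclei) carry
the exact-oracle and scale-invariance checks; a 600-nucleus field with
20% touching pairs exercises the watershed; a 1,000-nucleus field with
planted Spp1/Ki67 prevalences validates marker fractions to ±2
percentage points.

## Known limitations

* The spherical interpolation assumes near-spherical nuclei — hence the
  hard circularity gate; flattened or sectioned nuclei (caps cut by the
  microtome) bias content downward and are not modelled.
* The constant background offset is not subtracted before content
  computation; with the default synthetic settings this contributes a
  ~2% upward bias to the 2n reference and slightly more for dim large
  nuclei, which is why the calibration tolerance is ±5%. On real data,
  background subtraction upstream of the pipeline is advisable.
* Classes beyond 16c are not assigned; contents above the 16c window
  report as unassigned.
* Binucleation (two separate nuclei in one cell) is outside scope: the
  pipeline counts nuclei, not cells, and bilobular exclusion is a
  shape gate, not a binucleation detector.
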