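# hepaploidy

In situ estimation of hepatocyte ploidy from Hoechst/HNF4α-stained liver
tissue images, for liver biologists quantifying how the 2c/4c/8c/16c
nuclear populations shift during injury and regeneration without
dissociating the tissue.

## The method

For every segmented, near-circular nucleus (fitted-ellipse elongation
> 0.8), DNA content is computed as

> content = mean nuclear Hoechst intensity × (4/3)·π·r_eq³,  with
> r_eq = √(area/π)

i.e. a DNA *density* multiplied by a spherical nuclear volume
interpolated from the projected area. The arbitrary intensity scale is
anchored internally: the median content of the HNF4α-negative
nonparenchymal nuclei in the same field — an overwhelmingly diploid
population — defines 2c. Continuous ploidy is
`c = 2 · content / content_2n`, and discrete classes (2c, 4c, 8c, 16c)
are assigned by the nearest DNA-content doubling in log2 space within a
half-open ±0.5 window. The package also provides the companion
quantifications used alongside ploidy profiling — marker-positive cell
fractions, staining-area and co-staining fractions, modal pixel
intensity, nuclear densities and size distributions, mean ± SEM
summaries and pooled two-sample t tests — plus a seeded synthetic-tissue
generator that renders ground-truthed multi-channel fields on which the
whole pipeline is validated.

## Worked example

```r
library(hepaploidy)

spec <- acquisition_spec(pixel_size_um = 0.5,
                         height_px = 1500, width_px = 1500)
comp <- population_composition(
  c(NPC_2n = 0.4, HEP_2c = 0.3, HEP_4c = 0.2,
    HEP_8c = 0.07, HEP_16c = 0.03),
  n_nuclei = 2000, bilobular_fraction = 0.1)

field <- generate_field(spec, comp, noise_model(), seed = 42)
run <- run_ploidy_pipeline(field)
print(run)
#> ploidy_run: 2000 nuclei (1883 gated, 1083 hepatocyte)
#>   2n reference: 4.077e+04 (n = 800)
#>   class fractions: 2c 0.506, 4c 0.327, 8c 0.115, 16c 0.052, unassigned 0.000
#>   content peaks: 41080, 83100, 169100, 343900
```

Reading the output: all 2,000 planted nuclei were segmented; 1,883
passed the circularity gate, of which 1,083 are HNF4α+ hepatocytes. The
2n reference content (40,767 intensity·µm³, from 800 HNF4α− nuclei) sits
within 2% of the generator's true 2c content (2 × 20,000), the recovered
class fractions match the planted composition, and the four
kernel-density peaks of the content distribution fall at ratios
1 : 2.02 : 4.12 : 8.37 — the 2c/4c/8c/16c doubling series. Per-nucleus
estimates are in `run$estimates`; gates and densities in `run$summary`.

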