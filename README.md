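# infarct3d

Multiscale 3D morphometry of bile infarcts in phase-contrast CT volumes
of liver tissue.

Bile infarcts — fields of necrotic hepatocytes that form under
obstructive cholestasis (the bile-duct-ligation model, days 1–7) — are
visible in propagation-based phase-contrast CT as dark lesions in the
parenchyma, down to roughly 10 µm at a 3.25 µm pixel size and down to
their ~3.4 µm drainage conduits at 0.65 µm. This package is for image
analysts and liver researchers who want to quantify such lesions
reproducibly in 3D, and to validate every step of that quantification
against synthetic volumes with known truth.

It implements, end to end:

- **Synthetic liver phantoms** at both acquisition scales, with seeded
  vascular trees, infarcts that grow, fuse and migrate across the days
  after ligation, infarct–sinusoidal microchannels, grayscale
  rendering, and a complete ground-truth catalogue.
- **A miniature phase-contrast CT simulator and reconstructor**:
  Fresnel propagation of the exit wave of a δ/β phantom
  (n = 1 − δ + iβ), flat/dark correction, single-distance
  phase–attenuation-duality retrieval (frequency filter
  1 + πλD(δ/β)|f|²), and filtered back-projection over 180°.
- **Segmentation**: seeded region growing for vessels, mixture-model
  threshold segmentation for infarcts, connected-component labelling.
- **The 3D equal-volume hepatic acinus**: parenchyma partitioned into
  zones III/II/I by distance from the central-vein tree, with the two
  cutoff radii chosen so each zone holds exactly one third of the
  parenchyma; infarcts are assigned the zone holding the largest share
  of their volume.
- **Per-infarct morphometry**: volume V, triangulated surface area A,
  sphericity Ψ = π^⅓(6V)^⅔ / A, confluence classification
  (h-maxima/watershed on the interior distance transform), and
  microchannel count and diameter via medial-path tracing of thin
  lumina between infarct and sinusoid surfaces.
- **Day-group statistics** in the field's reporting style:
  Shapiro–Wilk-gated choice between Welch's t test (mean ± SD) and the
  Mann–Whitney U test (median, IQR).

## Worked example

Generate a day-7 whole-lobe phantom, run the full measurement chain
(vessel growing, infarct thresholding, zonation, morphometry), and look
at the results:

```r
library(infarct3d)
params   <- phantom_params(day = "7", scale = "lobe",
                           grid_shape = 96, seed = 42)
phantom  <- generate_phantom(params)
analysis <- analyze_lobe_volume(phantom$volume,
                                vessel_seed_points(phantom$truth))
analysis$zones
#> <zone_map> r3 = 33.46 um, r2 = 77.52 um
#>   achieved fractions: I 0.3333, II 0.3333, III 0.3333
analysis$summary
#> <lobe_summary> 14 infarcts, total 1.718e+06 um^3 (5.66% of lobe)
#>   confluent fraction 0.214
#>   zone count_fraction total_volume_um3 psi_median    psi_iqr
#> 1    1      0.1428571         403115.2  0.8415526 0.14804615
#> 2    2      0.5000000         696174.4  0.9733546 0.02204823
#> 3    3      0.3571429         618661.5  0.9707770 0.12880617
head(analysis$records[, c("id", "V_um3", "psi", "zone", "confluence")])
#>   id    V_um3       psi zone confluence
#> 1  1 338200.7 0.6935065    1  confluent
#> 2  2 236726.8 0.7830307    2  confluent
#> 3  3 194365.8 0.9678448    2 individual
#> 4  4 165461.6 0.8501141    3 individual
#> 5  5 124988.7 0.7142261    3  confluent
#> 6  6 111944.0 0.9808978    3 individual
```

The zonation returns the two distance cutoffs (r3, r2) bounding zones
III and II and confirms the three zones each hold a third of the
parenchyma. The summary shows 14 detected infarcts occupying 5.7% of
the lobe, 21% of them confluent, with zone III and II together holding
most of the lesion load — the day-7 pattern. Per-infarct rows carry
volume (µm³), sphericity (1 = perfect sphere; the large fused lesions
score lowest), the acinus zone and the confluence class.

The same flow at the submicron scale
(`phantom_params(day = "7", scale = "submicron", ...)`, then
`analyze_submicron_volume()`) detects the infarct–sinusoidal
microchannels and estimates their diameters.

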