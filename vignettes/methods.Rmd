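---
title: "Models and methods behind infarct3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind infarct3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

infarct3d quantifies bile infarcts — fields of necrotic hepatocytes that
form under obstructive cholestasis — in 3D phase-contrast CT volumes of
liver tissue, across the two acquisition scales used for such material:
a whole-lobe scan at 3.25 µm voxels and a submicron (0.65 µm) volume of
interest inside a lobule. Because raw CT volumes of this kind are rarely
shareable, the package pairs every analysis step with a seeded synthetic
phantom generator that carries full ground truth, so the entire chain
can be validated quantitatively. This vignette explains the models, the
tunable parameters, the numerical choices, and what the validation does
and does not show.

## The synthetic liver phantoms

A phantom is defined by a day preset (`control`, `1`, `3`, `5`, `7`
days after bile-duct ligation), a scale, a grid and a seed; identical
parameters give bit-identical volumes because every generator stage
derives its own sub-seed from the master seed.

**Vasculature.** At the lobe scale the portal and central/hepatic vein
trees are random recursive bifurcations entering from opposite grid
faces (roots about 36 voxels apart, five to six generations, branch
length decaying by 0.65–0.8 and radius by 0.75 per generation, mean
branching angle 35°). The second tree is grown with the first as an
obstacle: a proposed branch is truncated or deflected before it comes
within its own radius plus 1.5 voxels of the other tree, so the trees
interdigitate without ever becoming 26-adjacent. This matters twice —
overlap would be anatomically wrong, and a later crossing cut would
disconnect distal subtrees, which in turn would corrupt both seeded
region growing and the distance-based zonation. At the submicron scale
the phantom is one lobule volume of interest: a single central-vein
trunk (9 µm radius at the reference 128³ grid, shrinking with smaller
test grids) through the middle, two portal trunks at opposite edges,
and a network of randomly oriented sinusoid tubes (6.5 µm diameter)
pervading the whole volume. No measured vascular geometry is claimed;
the topology is chosen for plausibility and spatial coverage.

**Infarcts.** An infarct unit is a sphere with a smooth random radial
perturbation: the radius is modulated by a trilinearly upsampled 4³
Gaussian field, clipped at ±2 sd, with amplitude `sphericity_roughness`
(0.06 on day 1 rising to 0.18 on day 7, mimicking the progressive loss
of sphericity). With probability `confluent_fraction` a unit is
generated as a fused cluster: one primary sphere plus one or two
satellites of 0.75–0.9 of its radius, centred at 98% of the sum of
radii, so the bodies kiss with a narrow fusion neck — the morphology a
reader would call "several infarcts whose shared boundary has partly
disappeared". Units are placed at centres drawn from the acinus zone
sampled from `zone_placement_weights`, never touch one another, never
enter vein lumina, and (at the submicron scale) may invade sinusoid
space, as the lesions do in tissue. Placement aborts with a capacity
error beyond an occupancy cap of 40% of the parenchyma.

**Day presets.** The presets encode the study conditions the analysis
is validated against: lobe-scale infarct counts 12/18/25/32 (per 128³
reference grid, close to linear growth), confluent fractions
8/15/21/25%, zone placement shifting from (0.65, 0.22, 0.13) on day 1
to (0.18, 0.34, 0.48) on day 7, and microchannel means per infarct of
1.86/2.47/3.38/5.47 with 3.41 µm diameter. The published record for
this disease model gives these rates but not absolute infarct counts,
so the counts are order-of-magnitude choices. Radius ranges
(13–26 µm on day 1, scaling to 18.25–36.5 µm by day 7) are calibrated
so that the *expected* total infarct volume follows the multipliers
(1, 2.3, 4.9, 9): the expectation accounts for the mean cubed radius,
the cluster-overlap surplus (+0.847 of a primary-sphere volume per
cluster under the kissing geometry, by Monte Carlo over the satellite
law) and the roughness volume inflation (1 + 3·a²·0.88 for clipped
amplitude a). Day-7/day-1 = 9 is the anchoring fold change; the
intermediate multipliers are a smooth near-exponential interpolation.

**Microchannels.** Channel counts per infarct follow a zero-truncated
Poisson law whose truncation parameter is solved (by `uniroot`) so the
*mean* equals the preset — recovered sample means are then directly
comparable to the preset. Draws are rank-matched to lesion size: a
13 µm lesion cannot host eight spatially distinct 3.4 µm conduits, so
the largest counts go to the largest lesions while the marginal law is
unchanged. Channels leave the infarct surface along a randomly rotated
spherical-Fibonacci direction set (maximally spread contact patches),
run to a nearby sinusoid chosen to be at least 3 voxels away and
preferentially along the exit direction, and are rasterized as
3.41 µm capsules through parenchyma only. Every channel is validated
at generation time to be one 26-connected component touching both its
infarct and a sinusoid. At the lobe scale (3.25 µm voxels) channels
are sub-voxel and the generator refuses to rasterize them.

**Rendering.** Classes map to intensities (parenchyma 120, infarct 75,
sinusoid 45, vein and channel lumina 25) with additive Gaussian noise
(sd 5, i.e. about 11% of the infarct–parenchyma gap); infarcts are
darker than parenchyma and lumina darkest, the contrast polarity of
phase-retrieved CT of cholestatic liver.

## The CT simulator and reconstructor

The X-ray interaction is the complex refractive index
n = 1 − δ + iβ; for soft tissue δ exceeds β by about three orders of
magnitude, which is why propagation-based phase contrast sees
structures that attenuation alone would not. For each projection angle
the δ and β volumes are line-integrated (ray-driven, bilinear, half-voxel
steps), the exit wave exp(iφ − µ̃) with φ = −(2π/λ)∫δ dz is propagated
to the detector with the paraxial Fresnel kernel
exp(−iπλD|f|²), the intensity is blurred by a Gaussian detector PSF
(default 1 px FWHM), modulated by a smooth illumination profile,
scaled to the photon budget and Poisson-sampled. Synthetic flat and
dark frames accompany every acquisition. Geometry presets follow the
two acquisition scales: 16 keV / 28 cm / 3.25 µm / 1200 angles, and
14 keV / 16 cm / 0.65 µm / 900 angles (reduced angle counts are used
on small simulated grids).

Two numerical points deserve mention. First, the exit-wave phase can
change by several radians per pixel at sharp edges, which aliases an
FFT-based Fresnel propagation; the wave is therefore computed on a
laterally supersampled grid (default 2×) and the intensity binned back
to detector pixels. Second, the optical constants
(`tissue_optics()`: parenchyma δ = 2×10⁻⁷, β = 2×10⁻¹⁰; infarct 15%
lower; lumina lower still; δ/β = 1000 throughout) are invented but
physically plausible fixtures chosen so that the supersampled
simulation stays faithful; they are not measured liver values.

Reconstruction is classical: flat/dark correction
(raw − dark)/(flat − dark) with masked-pixel fill, single-distance
phase–attenuation-duality retrieval — divide each frame's transform by
1 + πλD(δ/β)|f|², then −log, valid here because all materials share
one δ/β — and slice-by-slice filtered back-projection over 180°. The
ramp filter is built from the exact spatial-domain band-limited kernel
(sampling |f| directly on the frequency grid biases the DC term and
reconstructed values by several percent). The retrieval formula is
adopted in its standard single-distance form and its correctness is
defined operationally: a simulate–correct–retrieve–reconstruct round
trip on a homogeneous phantom must recover the β map (correlation
above 0.95 at 128³; interior RMS error under 1% in practice). Voxel
values of the reconstruction are the linear attenuation coefficient
µ = 4πβ/λ per µm.

## Segmentation

Vessels are segmented by seeded region growing: breadth-first from
each seed, accepting 26-neighbours within `grow_tolerance` of the
running region mean, first claim wins across labels, conflicts
counted. Seed placement was interactive in the original workflow; here
`vessel_seed_points()` provides one deterministic seed per connected
vessel trunk (the deepest lumen voxel). Strict monotonicity of the
grown region in the tolerance holds for well-separated intensity
classes (the regime the tests exercise); for arbitrary data the
running-mean rule is order-dependent and only approximately monotone.

Infarcts are thresholded: voxels darker than the cutoff, minus vessel
voxels (vessels win conflicts — infarcts are parenchymal lesions). The
automatic cutoff is a two-component Gaussian-mixture split (EM with
free weights and variances, boundary at equal posterior density, in
closed form). A plain Otsu split was rejected deliberately: with an
infarct fraction below 1% of voxels, the between-class-variance
objective prefers splitting the parenchyma mode in half, while the
mixture fit with a free weight stays on the true class boundary. A
degenerate (effectively unimodal) fit returns an empty mask with a
warning. In the lobe-scale analysis chain a second two-class split of
the sub-threshold voxels separates residual vessel lumina (darker)
from infarct tissue. Connected components are labelled under
configurable 6/18/26-connectivity (foreground default 26), filtered at
a minimum physical volume (default: a 10 µm sphere, the smallest
distinguishable lesion at the lobe scale) and sorted by volume.

## Zonation: the 3D equal-volume acinus

The classic hepatic acinus assigns hepatocytes to three zones by their
position in the periportal-to-pericentral gradient. The 3D
generalisation implemented here partitions the parenchyma by distance
to the central-vein tree: zone III is the shell nearest the veins,
zone II the next, zone I the remainder around the portal tree, with
the two cutoff radii chosen so the three zones have equal volume. The
construction sorts parenchyma voxels by (distance, linear index) and
assigns thirds, which makes the equal split achievable to within one
voxel regardless of ties; achieved fractions and radii are reported.
The distance is the Euclidean distance transform by default (the limit
of an isotropic sphere-dilation construction); a geodesic-in-tissue
variant is available since the two differ for strongly non-convex
organs, but the Euclidean form is the default for speed and exact
reproducibility. The portal mask is used only for exclusion, never as
a distance source — the construction grows outward from the central
veins and labels what remains near the portal tree as zone I. An
infarct spanning zones is labelled by largest volume share, excluded
voxels leaving the denominator; exact ties go to the lower zone index.

## Morphometry

Volume is voxel count times voxel volume. Surface area is measured on
a marching-tetrahedra triangulation of the 0.5-isosurface after mild
Gaussian smoothing (σ = 0.7 voxels). Voxel-face counting was rejected
because it overestimates the area of smooth bodies by roughly 50%,
which would destroy the sphericity scale Ψ = π^{1/3}(6V)^{2/3}/A; the
smoothing value is validated against closed forms (digital spheres of
radius ≥ 8 measure Ψ within 2% of 1; a digital cube of side 30 within
4% of (π/6)^{1/3} ≈ 0.806; isotropic rescaling changes Ψ by under 2%).
Components touching the grid border are measured but flagged, counted
in totals yet excluded from sphericity distributions.

Confluence is classified by a watershed rule that operationalises the
visual individual-versus-fused distinction: h-maxima of the interior
distance transform (depth threshold 2 voxels, via greyscale
reconstruction) seed a watershed, and a component is confluent when at
least two cores own basins of at least 10% of its volume. On the
generated morphology this recovers the preset confluent fractions
within sampling error and classifies over 95% of components correctly;
the residual misses are the smallest, roughest fused pairs, whose
necks genuinely vanish.

Microchannels are detected by restricting the dark-lumen mask to a
shell (default 13 µm) around each infarct, removing vein-trunk lumina
(any tube with interior radius above 4.5 voxels, dilated back to its
full calibre), and tracing cost-weighted shortest paths — cost
1/(0.5 + r) with r the interior radius, which keeps paths medial —
from each connected infarct-contact patch of a lumen component to the
nearest sinusoid contact. Distinct contact patches count as distinct
channels; paths sharing more than half their voxels are merged. The
diameter of a channel is twice the interior radius averaged over the
medial core of the lumen around the path, with the infarct and
sinusoid treated as open space so the end caps do not truncate the
radius; the minimum along the path is reported separately (whether a
published channel calibre refers to the mean or the narrowest point is
generally ambiguous). On rasterized 3.41 µm tubes the estimator is
accurate to about a third of a voxel (slightly conservative), well
within the one-voxel discretisation bound. Channels thinner than two
voxels are flagged unreliable.

## Statistics

Day groups are compared exactly as such data are usually reported:
Shapiro–Wilk normality on each sample; if both pass at α = 0.05, an
independent-samples t test and mean ± SD descriptives, otherwise the
Mann–Whitney U test and median (IQR). The t test is the Welch form —
the safer default when only "independent samples t test" is specified.
No multiple-testing correction is applied by default, matching common
per-pair reporting; a Benjamini–Hochberg column is available. The
two-branch procedure holds its nominal size: simulated null pairs at
n = 6 reject at 4.4% (the slight conservatism comes from the exact
Mann–Whitney branch's discreteness), within 0.05 ± 0.01.

## Validation scope and problem sizes

The test-suite simulations use 128³ grids for the preset-recovery
studies (five seeds per day group), 128³ with 400 angles for the
reconstruction round trip, and 64³ with 200 angles and a 20 000
photon budget for the detectability study (spheres of 2–6 voxel
diameter, ten noise realisations; the smallest sphere recovered in at
least 90% of runs is the 3-voxel, 9.75 µm one, matching the ~10 µm
smallest distinguishable lesion at this pixel size; the detection
cutoff sits at 40% of the known class contrast below the measured
parenchyma level because partial volume and the PSF halve the contrast
of near-resolution lesions).

What passing these tests shows is that the pipeline recovers the
parameters of data whose statistical structure it assumes — piecewise
constant tissue classes, additive Gaussian or Poisson noise, tubular
channels, spherical-ish lesions. Real phase-contrast volumes add
texture within classes, ring and motion artefacts, intensity
inhomogeneity, anisotropic PSFs and genuinely ambiguous anatomy; none
of those are emulated, and performance there is not certified by the
phantom results. The generator is a study-condition encoder, not a
liver simulator: its value is that every estimate the pipeline
produces can be scored against known truth under the published group
conditions.

## Known limitations

- The acinus model uses a single distance field from the central-vein
  tree; if an original interactive construction used anisotropic
  dilation parameters, zone shapes would differ in ways this package
  does not attempt to reproduce.
- Region growing is deterministic but order-dependent; its tolerance
  is a physical intensity unit and must be set relative to the class
  gap.
- The channel counter undercounts by roughly 10% on the densest day-7
  lesions, where physically merging conduits are counted once; this
  bias is visible in the validation numbers and left as an honest
  property of the rule rather than tuned away.
- The CT simulator is parallel-beam and single-distance only; no
  cone-beam, multi-distance holotomography, ring-artefact or motion
  correction is provided.
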