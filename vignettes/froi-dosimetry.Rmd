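---
title: "Dose modeling for filtered region-of-interest cone-beam rotational angiography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose modeling for filtered region-of-interest cone-beam rotational angiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(froidose)
```

## The problem

Three-dimensional cone-beam rotational angiography (3D CBRA) spins a C-arm
X-ray source around a patient's head to image cerebral vasculature.  In
filtered region-of-interest (FROI) imaging, an attenuating sheet with a
circular aperture is placed in the beam so that only the diagnostic region
of interest receives full exposure, while the periphery is strongly (but
not completely) attenuated, preserving enough signal for artifact-free
reconstruction.  `froidose` quantifies what this buys in *organ equivalent
dose* $H_T$ and *effective dose* $E$: it models the rotating source, the
filters, a labeled voxel head phantom, and photon transport under the kerma
approximation, and reports absolute and relative doses as functions of
filter thickness, aperture size, tube voltage, and isocenter position.

The dosimetric chain is the standard one:

$$D_{i,\mathrm{abs}} = D_{i,\mathrm{sim}} \cdot CF \cdot I\,t, \qquad
  H_T = w_r\,\frac{\sum_{i \in T} D_i\,\rho_i\,\nu_i}
                 {\sum_{i \in T} \rho_i\,\nu_i}, \qquad
  E = \sum_T w_T\,H_T,$$

with $w_r = 1$ for photons, $\rho_i \nu_i$ the voxel masses, $w_T$ the
ICRP 103 tissue weighting factors, and $CF$ a calibration factor anchoring
simulated dose-per-primary to a measured free-in-air kerma per mAs at the
isocenter.  Every *relative* quantity (transmissions, dose reductions)
is independent of $CF$ and of the spectrum normalization.

## Photon interaction data

The bundled table (`coefficient_table()`) holds, per element, total mass
attenuation $\mu/\rho$, mass energy-absorption $\mu_{en}/\rho$, and the
photoelectric/incoherent/coherent split on a 1--150 keV grid, with
absorption edges represented by grid-point pairs; lookups use log-log
interpolation.  The table was compiled from the standard NIST
compilations: the elements that dominate every reported number (H, C, N,
O, Al, Cu) and the air/water mixtures are anchored to the published
values (the bundled water $\mu/\rho$ at 100 keV reproduces the reference
0.1707 cm^2/g), while the incoherent part and its energy-transfer
fraction are exact Klein-Nishina integrals.  Entries for the heavier
elements (Gd, W; K/L edges included) carry a few-percent-to-ten-percent
uncertainty; they enter only *relative* FROI metrics (filter
transmission, dose reduction), never the graded absolute comparisons.
Gd$_2$O$_2$S uses the handbook density 7.32 g/cm^3; tissues use
ICRU-44-style compositions.

## The X-ray spectrum model

`generate_spectrum()` is a semi-empirical tungsten-anode model in 1 keV
bins: Kramers bremsstrahlung $(T-E)/E$ shaped by anode self-filtration --
a depth-averaged tungsten Beer-Lambert factor
$\langle e^{-\mu_W(E)\,x}\rangle$ with effective areal density
$0.05\,(1-(E/T)^2)\,\tan 12^\circ/\tan\theta$ g/cm^2 -- plus tungsten K
lines above 69.5 kV with relative yield $\propto (T/E_K - 1)^{1.63}$.
The two free constants (self-filtration areal density and K-line
amplitude) were fixed once against published beam-quality data for
2.5-mm-Al-filtered tungsten beams (first HVL 2.6/3.0/3.3/3.7 mm Al at
70/80/90/100 kV, second HVL near 4.3 mm Al at 80 kV, and HVL around
6 mm Al behind 0.3 mm Cu + 2.6 mm Al), all of which the model reproduces
within a few percent:

```{r beam-quality}
round(sapply(c(70, 80, 90, 100), function(k)
  half_value_layer(generate_spectrum(k,
    inherent_filtration = prefilter_al(2.5)))), 2)
```

No independent spectrum-generation code is bundled, so the spectral shape
is validated through these integral beam-quality observables rather than
bin-by-bin.  The anode angle (default 12 degrees) and the detector energy
response are configuration choices, not inferred quantities: broad-beam
transmission is *air-kerma weighted* by default
(`kerma_weighted_transmission()`, weight $E\cdot(\mu_{en}/\rho)_{air}$),
matching a solid-state air-kerma dosimeter; a plain fluence weighting is
available via `weighting = "fluence"`.

## Calibration fits

Both fits are bracketed root searches (bisection via `uniroot`) on
strictly monotone transmission curves, so the solutions are unique.

**Effective ROI-filter thickness.** `fit_effective_thickness()` finds the
pure-Gd$_2$O$_2$S slab thickness whose broad-beam transmission matches a
measurement; the plastic binder of the real Lanex screens is deliberately
not modeled.  The underlying transmission measurements for the screen
filters are not published, so this operation is validated by round trips
(recovery to 1e-4 mm across voltages and thicknesses).  The published
per-voltage effective thicknesses *are* bundled
(`roi_filter_thickness_data()`), and `average_effective_thickness()`
reproduces the published per-layer mean 0.102 mm, row averages
(0.204/0.306/0.408 mm), and 2-sigma spread 0.006 mm by plain arithmetic.

**Effective table density.** `fit_effective_density()` adjusts the density
of a carbon slab of fixed assumed thickness until the simulated
transmission matches each of the five bundled measured transmissions
(70--102 kVp, 2.5 mm Al).  The physically identified quantity is the
*areal density* $\rho t$: reported densities scale exactly inversely with
the assumed thickness (a tested invariant).  The default thickness is 40
mm, a typical carbon-fibre sandwich headrest.  With the bundled
measurements the per-voltage densities agree with their mean to better
than 2%:

```{r density-fit}
fit <- fit_effective_density(table_transmission_data(),
                             slab_thickness_mm = 40)
fit$per_kvp
c(mean = fit$mean_density, areal_g_cm2 = fit$areal_density)
```

Note the scale: the narrow-beam areal density fitted here (about 1.5
g/cm^2) is smaller than what a scatter-inclusive (broad-beam) transport
model would assign to the same measurements, because forward scatter from
a decimeter-scale slab inflates a broad-beam detector reading by roughly
ten percent.  Density values quoted by scatter-inclusive studies are
therefore systematically larger at equal measured transmission; the
narrow-beam model is self-consistent, and its *cross-prediction* -- fit at
70--102 kVp with 2.5 mm Al, predict 80 kVp behind 0.3 Cu + 2.6 Al --
lands at 0.75, close to the 0.77-0.8 range such measurements report.

**Calibration factor.** `calibration_factor()` is the measured/simulated
ratio per tube voltage; `air_kerma_at_isocenter()` provides the simulated
denominator from the calibration geometry (free in air, no phantom, no
table).  Applying the factor through `absolute_voxel_dose()` to the
calibration geometry itself reproduces the measured input exactly (a
tested closed loop).

## The synthetic head phantom

`make_synthetic_head()` builds a labeled voxel head-and-neck phantom from
analytic primitives: a skin-shelled soft-tissue head ellipsoid, a cranial
bone shell, a brain ellipsoid, anterior eye-lens spheres, infero-lateral
parotid (salivary) ellipsoids, a posterior spinal-cord cylinder descending
through a neck cylinder, air elsewhere.  World coordinates put the
midline at X = 265 mm, the head's anterior-posterior axis around
Y = 90--105 mm, and the orbital plane at Z = 1580 mm, so the isocenter
placements (265, 90, 1580) and the 30-mm-caudal variant (265, 90, 1550)
land in the orbit/brain region and toward the salivary glands,
respectively.  The grid is mirror-symmetric about the midline (left/right
organ volumes are exactly equal), the seed drives a 1% Gaussian per-voxel
density heterogeneity, and voxel centers follow the
`origin + (index + 0.5) * spacing` convention.

What it does *not* emulate: real cranial anatomy (sinuses, trabecular
bone and marrow, mandible, cervical spine), organ shape detail, or a
full torso for scatter realism.  Tests passing on this phantom therefore
validate the *transport and dosimetry machinery* and directional claims
(which organ gains or loses dose when the isocenter moves), not absolute
organ doses of any real patient or reference phantom -- reproducing
published absolute organ doses would require the (non-redistributable)
reference anthropomorphic phantom and the unpublished measured air kerma.

`attach_table()` replicates the voxel-matrix extension used to model a
patient table: the grid is padded posteriorly and a rectangular carbon
slab of the fitted effective density is inserted over the phantom's X-Z
footprint.

## Beam geometry

The gantry angle is measured in the axial plane with **0 degrees at the
posterior (+Y) direction** -- the resting tube-under-couch position of an
angiographic C-arm -- and the source at
$\mathit{iso} + R(\sin\alpha, \cos\alpha, 0)$.  With the protocol arc
(start 106 degrees, 106 projections at 2 degrees), the *excluded* sector
316--466 degrees is exactly the under-couch region a C-arm cannot sweep
through, which is why this orientation was adopted.  A consequence worth
knowing: almost no primary ray then crosses the attached table slab, so
the with/without-table difference in organ doses is small (a fraction of
a percent for the deterministic engine; a scatter-inclusive engine adds
table backscatter and yields somewhat larger, still single-digit-percent,
differences).  The protocol arithmetic 106 + 105 x 2 = 316 degrees
defines the final angle.

"ROI size x% of FOV" is interpreted as aperture **area** = x% of the
20 x 20 cm detector FOV (radius 5.05 cm at the detector plane for 20%),
with `interpretation = "linear"` available for the diameter reading; the
open solid-angle fraction then equals the aperture fraction (a tested
property).  The filter is characterized entirely by its detector-plane
aperture projection and its slab path length (thickness / cosine of
obliquity to the beam axis), consistent with weighted-attenuation
transport; filter scatter and fluorescence are not modeled.  The
source-isocenter distance defaults to 70 cm (the published source-surface
distance with the calibration chamber free in air at the isocenter); it
is configurable and flagged as an assumption.

## Dose engines

Both engines work under the kerma approximation -- secondary electrons
deposit locally, valid at diagnostic energies where electron ranges are
below the voxel size -- and treat all beam filters by weighted
attenuation.

**Deterministic primary kerma** (`primary_kerma_dose()`, the default):
for each projection and each body voxel inside the collimated cone, the
spectral fluence is source spectrum x ROI-filter Beer-Lambert factor x
exact Beer-Lambert line integral through the phantom (Siddon traversal,
exact to machine precision) x inverse square; the voxel dose is
$\sum_E \Phi(E)\,E\,(\mu_{en}/\rho)$.  No scatter.  It is exactly linear
in tube charge and matches the closed-form Beer-Lambert x inverse-square
solution on a water slab to 1e-6.  Collimation is decided at voxel
centers, so cone-edge voxels carry an $O(h^2)$ discretization error in
organ means (about 0.4% at 5 mm voxels, 0.1% at 2.5 mm on the test
geometries).

**Monte Carlo photon transport** (`mc_photon_dose()`): analog transport
with Woodcock (delta) tracking in the voxel grid; photoelectric events
deposit the full photon energy locally; incoherent scattering samples the
free-electron Klein-Nishina distribution (Kahn's method) and deposits the
transferred energy locally; coherent scattering changes direction with a
Thomson angular distribution (a form-factor-free approximation that
overweights large-angle Rayleigh events); photons below 1 keV are
deposited locally.  Doppler broadening, binding effects, fluorescence
escape, and bremsstrahlung in the patient are not modeled.  Runs are
bit-reproducible per seed; type-A uncertainties come from batch
statistics (default 20 batches), are returned per voxel and per label,
and scale as $1/\sqrt{N}$ (a tested property).  With scatter channels
disabled (`mode = "photoelectric_only"`) the engine estimates the same
quantity as the deterministic engine with `deposition = "attenuation"`,
and the two agree within 3 type-A standard deviations per organ -- the
cross-validation is run with an enlarged FOV so that it probes transport,
not the collimation discretization above.

Normalization: both engines report keV/g per source primary with the
source emitting one photon per steradian per unit spectrum weight; the
calibration factor absorbs the arbitrary scale, and all relative outputs
are invariant to it.

## Dosimetry and reporting

`organ_dose()` implements the mass-weighted organ mean with $w_r = 1$;
`effective_dose()` applies the bundled ICRP 103 weights.  On the head
phantom the mapping is explicit configuration (`head_tissue_map()`):
left/right salivary glands combine mass-weighted into the salivary-gland
tissue; cranial bone dose stands in for both bone marrow and bone
surface (the shell phantom has no separate marrow compartment); generic
head soft tissue is the only remainder representative, entering through
the ICRP arithmetic-mean remainder rule; eye lenses are reported
separately and never enter $E$ (they carry no tissue weight); the spinal
cord is likewise reported but unweighted.  Tissues absent from the head
(lung, thyroid, ...) contribute zero, and $E$ is labeled what it is: a
partial-body effective dose.  Because both the remaining-fraction and
the reduction conventions appear in the literature, `dose_reduction()`
reports $1 - H_T^{filt}/H_T^{unfilt}$ explicitly alongside both dose
columns.  `theoretical_reduction()` gives the dose-area-product
benchmark $R = (1 - a)(1 - T)$ for aperture fraction $a$ and filter
transmission $T$, the yardstick against which organ-specific deviations
(organs inside vs outside the shadowed region) are discussed.

`run_sweep()` drives the Cartesian grid over thickness (the averaged
effective thicknesses 0.102--0.408 mm are the natural grid), aperture
(20%/40%/none), tube voltage, isocenter Z, and table on/off, emitting a
tidy long-format table; `run_report()` re-checks the two structural
inequalities on any sweep output -- organ dose non-increasing in filter
thickness, and the 20% aperture reducing $E$ at least as much as the 40%
aperture at equal thickness -- and fails loudly on violations.

## Problem sizes and tolerances

Defaults chosen for desk-scale work, stated here as the package's own
choices: 2.5 mm isotropic voxels for full runs and 5 mm for the quicker
property checks (the reference phantom the study design points to is
finer; dose *ratios* are the target); 1e6 Monte Carlo histories with
organ-mean uncertainties as the quoted outputs (full-scale studies use
1e8 and quote voxel maps); root-search tolerances 1e-6 in transmission
(thickness recovery to 1e-4 mm); spectrum bins of 1 keV, 1--150 keV.
Degenerate inputs are defined: zero-thickness filters and empty stacks
are identities, a thickness-0 sweep cell is the unfiltered baseline,
single-voxel phantoms are valid, and all-zero spectra are rejected.

## Known limitations

Approximate heavy-element cross sections (Gd, W) at the few-percent
level; no scatter in the deterministic engine (scatter is an explicit,
switchable term via the MC engine, and every output records which engine
produced it); free-electron Compton and form-factor-free Rayleigh in the
MC engine; no electron transport anywhere (kerma approximation); the
synthetic phantom's anatomical simplifications above; narrow-beam
transmission modeling of broad-beam measurements (discussed under the
density fit); tube-current modulation deliberately not modeled.
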