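# froidose

Organ and effective dose in filtered region-of-interest (FROI) cone-beam
rotational angiography (3D CBRA).

In 3D CBRA a C-arm X-ray source rotates around the head to image cerebral
vasculature.  FROI imaging inserts an attenuating sheet (a gadolinium
oxysulfide screen) with a circular aperture into the beam, so only the
region of interest receives full exposure.  `froidose` is for medical
physicists who want to quantify what that buys in patient dose: it models
the tungsten-anode spectrum and all beam filters, calibrates effective
filter thickness and effective patient-table density from transmission
measurements, transports photons through a labeled voxel head phantom
under the kerma approximation, and reports organ equivalent doses,
effective dose, and relative dose reductions as functions of filter
thickness, aperture size, tube voltage, and isocenter position.

The dosimetric core, in the field's standard notation:

- absolute voxel dose: `D_abs = D_sim * CF * I*t`, with the calibration
  factor `CF = (D_air / I*t)_meas / (D_air / phi)_sim` anchored by a
  free-in-air kerma measurement at the isocenter;
- organ equivalent dose: `H_T = w_r * sum(D_i rho_i v_i) / sum(rho_i v_i)`
  (`w_r = 1` for photons);
- effective dose: `E = sum_T w_T H_T` with ICRP 103 tissue weights;
- theoretical (dose-area-product) FROI benchmark:
  `R = (1 - aperture_fraction) * (1 - transmission)`.

Two dose engines are provided: a deterministic primary-kerma ray tracer
(exact Siddon line integrals, no scatter — the default, exactly testable
against closed forms) and a simplified analog Monte Carlo photon transport
(Woodcock tracking, Klein–Nishina Compton, Thomson-sampled Rayleigh) that
adds scatter and serves as the fidelity reference.

## Worked example

Calibration from the bundled printed measurements, then a small
filter-thickness sweep on the synthetic voxel head phantom:

```r
library(froidose)

cal <- run_calibration(list(slab_thickness_mm = 40))
cal$thickness$per_layer_mean_mm   # 0.102 (+- 0.006 mm, 2 sigma)
cal$density$mean_density          # 0.375 g/cm3 at the 40 mm headrest
                                  # (areal density 1.50 g/cm2)

ph <- make_synthetic_head(voxel_mm = 5, seed = 1)
sw <- run_sweep(ph, thickness_mm = c(0, 0.408), aperture = c(0.2, 0.4),
                kvp = 100)
subset(sw, organ %in% c("brain", "salivary_left", "effective_dose"))
```

which prints (dose in relative units per source primary; `reduction` is
`1 - H_T/H_T(baseline)`):

```
thickness aperture          organ    H_T reduction theoretical_reduction
    0.000       NA          brain 0.1100     0.000                 0.000
    0.000       NA  salivary_left 0.0289     0.000                 0.000
    0.000       NA effective_dose 0.0805     0.000                 0.000
    0.408      0.2          brain 0.0777     0.294                 0.344
    0.408      0.2  salivary_left 0.0168     0.419                 0.344
    0.408      0.2 effective_dose 0.0518     0.357                 0.344
    0.408      0.4          brain 0.0888     0.193                 0.258
    0.408      0.4  salivary_left 0.0168     0.419                 0.258
    0.408      0.4 effective_dose 0.0585     0.273                 0.258
```

Reading it: the thickest filter with the small (20% of FOV) aperture cuts
the effective dose by 36%, more than the large (40%) aperture's 27%.  The
brain, which sits largely inside the open ROI, is reduced *less* than the
dose-area-product benchmark (29% vs 34%); the salivary glands, mostly in
the attenuated periphery, are reduced *more* (42%).  Organ position in the
field, not just filter transmission, governs the saving — the central
point of this kind of analysis.  `run_report(sw)` re-checks the structural
inequalities (dose monotone in thickness; small aperture dominates large)
and flags any violation.

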