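Package: froidose
Title: Organ and Effective Dose in Filtered Region-of-Interest Cone-Beam
    Rotational Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates photon dose in voxel head phantoms for 3D cone-beam
    rotational angiography (3D CBRA) with and without filtered
    region-of-interest (FROI) beam filtration.  Provides a tungsten-anode
    X-ray spectrum model with slab filtration, calibration of effective
    filter thickness and effective patient-table density from transmission
    measurements, a synthetic labeled voxel head phantom, a deterministic
    primary-kerma ray-tracing dose engine and a simplified Monte Carlo
    photon transport engine (both under the kerma approximation), and ICRP
    103 organ equivalent dose, effective dose, and relative dose-reduction
    reporting as functions of filter thickness, aperture size, tube
    voltage, and isocenter position.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
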