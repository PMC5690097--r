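#' Fit the effective thickness of a filter slab
#'
#' Finds the slab thickness of `mat` whose broad-beam transmission under
#' `spectrum` equals a measured target transmission.  The transmission is a
#' strictly decreasing function of thickness, so the root is unique; the
#' bracket is grown by doubling until it encloses a sign change.
#'
#' @param target_transmission measured transmission, in (0, 1].
#' @param mat slab [material()] (e.g. pure gadolinium oxysulfide standing in
#'   for a Lanex screen filter).
#' @param spectrum beam [froi_spectrum()] (already including prefiltration).
#' @param weighting transmission weighting, see
#'   [kerma_weighted_transmission()].
#' @param tol transmission-matching tolerance.
#' @return effective thickness in mm.
#' @export
fit_effective_thickness <- function(target_transmission, mat, spectrum,
                                    weighting = "kerma", tol = 1e-6) {
  if (target_transmission <= 0 || target_transmission > 1)
    stop("target transmission must be in (0, 1]")
  if (target_transmission == 1) return(0)
  f <- function(t) kerma_weighted_transmission(
    spectrum, filter_stack(mat, t), weighting) - target_transmission
  upper <- 0.1
  while (f(upper) > 0) {
    upper <- upper * 2
    if (upper > 1e4) stop("target transmission not bracketable")
  }
  stats::uniroot(f, c(0, upper), tol = tol * 1e-3)$root
}

#' Average effective thickness per filter layer
#'
#' Each fitted effective thickness is divided by its layer count; the
#' per-layer mean and twice the sample standard deviation of these
#' per-layer values summarize the spread over tube voltages and layer
#' counts, and each row's average thickness is layer count times the
#' per-layer mean (one uniform thickness per layer).
#'
#' @param fits data.frame with columns `layers` (layer count), `kvp`, and
#'   `effective_thickness_mm` (the per-voltage fitted thickness).
#' @return list with `per_layer_mean_mm`, `two_sigma_mm`, and `per_row`, a
#'   data.frame adding per-layer values, the row average (layers x mean)
#'   and the percent deviation of each fit from its row average.
#' @export
average_effective_thickness <- function(fits) {
  if (nrow(fits) < 1) stop("at least one fitted thickness is required")
  per_layer <- fits$effective_thickness_mm / fits$layers
  m <- mean(per_layer)
  s2 <- if (length(per_layer) > 1) 2 * stats::sd(per_layer) else 0
  per_row <- data.frame(
    fits,
    per_layer_mm = per_layer,
    average_mm = fits$layers * m,
    deviation_pct = 100 * abs(fits$effective_thickness_mm -
                                fits$layers * m) / (fits$layers * m))
  list(per_layer_mean_mm = m, two_sigma_mm = s2, per_row = per_row)
}

#' Bundled printed transmission measurements of the patient table
#'
#' The five measured broad-beam transmissions of the angiography patient
#' table's headrest (70-102 kVp, 2.5 mm Al total prefiltration) bundled
#' with the package.
#' @return data.frame with `kvp`, `transmission`, `prefilter_al_mm`.
#' @export
table_transmission_data <- function() {
  utils::read.csv(system.file("extdata", "table_transmission.csv",
                              package = "froidose", mustWork = TRUE))
}

#' @rdname average_effective_thickness
#' @details `roi_filter_thickness_data()` returns the bundled per-voltage
#'   effective ROI-filter thickness fits (1-4 Lanex layers at 80/90/100
#'   kVp) that feed the averaging step.
#' @export
roi_filter_thickness_data <- function() {
  utils::read.csv(system.file("extdata", "roi_filter_effective_thickness.csv",
                              package = "froidose", mustWork = TRUE))
}

#' Fit the effective density of the patient table
#'
#' For each transmission measurement, iteratively adjusts the density of a
#' carbon slab of fixed assumed thickness until the simulated broad-beam
#' transmission matches the measurement (bracketed root search on the
#' strictly monotone transmission-density curve).  The physically
#' identified quantity is the areal density (density x thickness):
#' reported densities scale inversely with the assumed slab thickness.
#'
#' @param measurements data.frame with columns `kvp`, `transmission`, and
#'   optionally `prefilter_al_mm` (default 2.5).
#' @param mat slab material, default pure carbon.
#' @param slab_thickness_mm assumed slab thickness (default 40 mm, a
#'   typical carbon-fibre sandwich headrest).
#' @param anode_angle_deg anode angle for the per-kVp spectra.
#' @param weighting see [kerma_weighted_transmission()].
#' @return list with `per_kvp` (data.frame: kvp, transmission, density,
#'   deviation_pct), `mean_density`, `areal_density` (g/cm^2), and the
#'   assumed `slab_thickness_mm`.
#' @export
fit_effective_density <- function(measurements,
                                  mat = froi_material("carbon"),
                                  slab_thickness_mm = 40,
                                  anode_angle_deg = 12,
                                  weighting = "kerma") {
  if (nrow(measurements) < 1) stop("no measurements")
  if (any(measurements$transmission <= 0 | measurements$transmission >= 1))
    stop("transmissions must lie strictly between 0 and 1")
  pf <- if ("prefilter_al_mm" %in% names(measurements))
    measurements$prefilter_al_mm else rep(2.5, nrow(measurements))
  dens <- vapply(seq_len(nrow(measurements)), function(i) {
    sp <- generate_spectrum(measurements$kvp[i], anode_angle_deg,
                            prefilter_al(pf[i]))
    f <- function(rho) kerma_weighted_transmission(
      sp, filter_stack(material(mat$name, mat$composition, rho),
                       slab_thickness_mm), weighting) -
      measurements$transmission[i]
    upper <- 0.25
    while (f(upper) > 0) {
      upper <- upper * 2
      if (upper > 1e3) stop("transmission not bracketable in density")
    }
    stats::uniroot(f, c(1e-9, upper), tol = 1e-9)$root
  }, numeric(1))
  m <- mean(dens)
  list(per_kvp = data.frame(kvp = measurements$kvp,
                            transmission = measurements$transmission,
                            density = dens,
                            deviation_pct = 100 * abs(dens - m) / m),
       mean_density = m,
       areal_density = m * slab_thickness_mm / 10,
       slab_thickness_mm = slab_thickness_mm)
}

#' Absolute-dose calibration factor
#'
#' Ratio of the measured free-in-air dose per mAs to the simulated air dose
#' per source primary, determined per tube voltage; multiplying simulated
#' voxel doses by CF x I x t yields absolute dose.
#'
#' @param measured_dair_per_mAs measured air kerma per mAs, Gy/mAs.
#' @param simulated_dair_per_fluence simulated air kerma per primary.
#' @param kvp tube voltage the factor belongs to.
#' @return object of class `froi_calibration_factor`.
#' @export
calibration_factor <- function(measured_dair_per_mAs,
                               simulated_dair_per_fluence, kvp) {
  if (measured_dair_per_mAs <= 0 || simulated_dair_per_fluence <= 0)
    stop("calibration inputs must be positive")
  structure(list(cf = measured_dair_per_mAs / simulated_dair_per_fluence,
                 measured_dair_per_mAs = measured_dair_per_mAs,
                 simulated_dair_per_fluence = simulated_dair_per_fluence,
                 kvp = kvp),
            class = "froi_calibration_factor")
}

#' @export
print.froi_calibration_factor <- function(x, ...) {
  cat(sprintf("<calibration factor> CF = %.4g (%g kVp)\n", x$cf, x$kvp))
  invisible(x)
}
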