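#' Run the calibration workflow from a configuration
#'
#' Reproduces the calibration chain on configured inputs: per-layer
#' effective ROI-filter thickness averaging, the effective table-density
#' fit from measured transmissions, and (when a measured free-in-air dose
#' is configured) the absolute-dose calibration factor from the
#' calibration-geometry simulation.  The resolved configuration is echoed
#' into the output for provenance.
#'
#' @param config a list or path to a YAML file.  Recognized entries:
#'   `thickness_csv` (layers, kvp, effective_thickness_mm; defaults to the
#'   bundled values), `transmission_csv` (kvp, transmission; defaults to
#'   the bundled table measurements), `slab_thickness_mm`,
#'   `measured_dair_per_mAs` + `kvp` for the calibration factor, and
#'   `output_json`.
#' @return list with `thickness`, `density`, and optionally `cf`;
#'   written as JSON when `output_json` is set.
#' @export
run_calibration <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  fits <- if (!is.null(config$thickness_csv)) {
    x <- utils::read.csv(config$thickness_csv)
    if (!nrow(x)) stop("empty thickness measurement file")
    x
  } else roi_filter_thickness_data()
  meas <- if (!is.null(config$transmission_csv)) {
    x <- utils::read.csv(config$transmission_csv)
    if (!nrow(x)) stop("empty transmission measurement file")
    x
  } else table_transmission_data()
  thick <- average_effective_thickness(fits)
  dens <- fit_effective_density(
    meas, slab_thickness_mm = config$slab_thickness_mm %||% 40)
  out <- list(thickness = thick, density = dens, config = config)
  if (!is.null(config$measured_dair_per_mAs)) {
    kvp <- config$kvp %||% 90
    prot <- scan_protocol(kvp = kvp)
    sim <- air_kerma_at_isocenter(prot)
    out$cf <- calibration_factor(config$measured_dair_per_mAs, sim, kvp)
  }
  if (!is.null(config$output_json))
    jsonlite::write_json(out, config$output_json, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dose-reduction parameter sweep
#'
#' Runs the dose pipeline over the Cartesian grid of ROI-filter thickness,
#' aperture fraction, tube voltage, isocenter Z position and table
#' on/off, and returns a tidy long-format table of organ equivalent
#' doses, effective dose, relative reductions against the matching
#' unfiltered baseline, and the theoretical (dose-area-product) reduction.
#'
#' @param phantom a [voxel_phantom()] (default: the synthetic head).
#' @param thickness_mm effective Gd2O2S thicknesses (0 = no filter);
#'   defaults to the averaged per-layer effective thicknesses.
#' @param aperture fractions of FOV (NA = no filter).
#' @param kvp tube voltages.
#' @param iso_z isocenter Z positions, mm.
#' @param table logical vector: attach the patient-table slab?
#' @param table_density,table_thickness_mm slab parameters (fitted
#'   effective density).
#' @param isocenter_xy isocenter X/Y, mm.
#' @param engine `"primary_kerma"` or `"mc_photon"`.
#' @param histories,seed Monte Carlo settings.
#' @param quick shrink the spectrum to 2 keV bins for fast runs.
#' @return long-format data.frame, one row per grid cell x organ (plus an
#'   `effective_dose` row per cell).
#' @export
run_sweep <- function(phantom = make_synthetic_head(),
                      thickness_mm = c(0, 0.102, 0.204, 0.306, 0.408),
                      aperture = c(0.2, 0.4), kvp = 100, iso_z = 1580,
                      table = FALSE, table_density = 0.375,
                      table_thickness_mm = 40,
                      isocenter_xy = c(265, 90),
                      engine = c("primary_kerma", "mc_photon"),
                      histories = 1e6, seed = 1L, quick = FALSE) {
  engine <- match.arg(engine)
  grid <- expand.grid(thickness = thickness_mm, aperture = aperture,
                      kvp = kvp, iso_z = iso_z, table = table,
                      stringsAsFactors = FALSE)
  # a thickness-0 cell is the unfiltered baseline regardless of aperture
  grid$aperture[grid$thickness == 0] <- NA
  grid <- unique(grid)
  phantoms <- list(`FALSE` = phantom)
  if (any(grid$table))
    phantoms[["TRUE"]] <- attach_table(phantom, density = table_density,
                                       thickness_mm = table_thickness_mm)
  rows <- list()
  baselines <- list()
  for (g in seq_len(nrow(grid))) {
    cell <- grid[g, ]
    ph <- phantoms[[as.character(cell$table)]]
    prot <- scan_protocol(kvp = cell$kvp)
    iso <- c(isocenter_xy, cell$iso_z)
    filt <- if (!is.na(cell$aperture) && cell$thickness > 0)
      roi_filter(cell$thickness, cell$aperture) else NULL
    sp <- generate_spectrum(cell$kvp, inherent_filtration = prefilter_cbra(),
                            bin_kev = if (quick) 2 else 1)
    res <- tryCatch({
      dg <- if (engine == "primary_kerma")
        primary_kerma_dose(ph, prot, iso, filt, spectrum = sp)
      else mc_photon_dose(ph, prot, iso, filt, spectrum = sp,
                          histories = histories, seed = seed)
      rep_ <- organ_dose_report(dg, ph)
      ed <- effective_dose(rep_)
      list(report = rep_, E = ed$E)
    }, error = function(e) stop("sweep cell failed (thickness=",
                                cell$thickness, ", aperture=", cell$aperture,
                                ", kvp=", cell$kvp, ", iso_z=", cell$iso_z,
                                ", table=", cell$table, "): ",
                                conditionMessage(e)))
    key <- paste(cell$kvp, cell$iso_z, cell$table)
    if (is.null(filt)) baselines[[key]] <- res
    theo <- if (is.null(filt)) 0 else {
      tr <- kerma_weighted_transmission(
        sp, filter_stack(filt$mat, filt$thickness_mm))
      theoretical_reduction(tr, cell$aperture)
    }
    df <- rbind(res$report[, c("organ", "H_T")],
                data.frame(organ = "effective_dose", H_T = res$E))
    df <- cbind(cell[rep(1, nrow(df)), , drop = FALSE], df,
                theoretical_reduction = theo, row.names = NULL)
    rows[[g]] <- df
  }
  out <- do.call(rbind, rows)
  out$reduction <- NA_real_
  for (i in seq_len(nrow(out))) {
    key <- paste(out$kvp[i], out$iso_z[i], out$table[i])
    base <- baselines[[key]]
    if (is.null(base)) next
    h0 <- if (out$organ[i] == "effective_dose") base$E
    else base$report$H_T[base$report$organ == out$organ[i]]
    if (length(h0) == 1 && h0 > 0) out$reduction[i] <- 1 - out$H_T[i] / h0
  }
  out
}

#' Summarize and check a sweep result
#'
#' Per-organ dose curves versus filter thickness plus the physical
#' consistency checks: within every (kvp, iso_z, table, aperture) series
#' the organ dose must decrease monotonically with filter thickness, and
#' at equal thickness the small (20% FOV) aperture must give at least the
#' effective-dose reduction of the large (40%) one.  Violations are
#' reported loudly.
#'
#' @param sweep result of [run_sweep()] (or a CSV path).
#' @param plot_pdf optional path: write dose-vs-thickness plots.
#' @return list with `curves` (wide table), `monotonic_violations`,
#'   `dominance_violations`, and `ok`.
#' @export
run_report <- function(sweep, plot_pdf = NULL) {
  if (is.character(sweep)) sweep <- utils::read.csv(sweep)
  need <- c("thickness", "aperture", "kvp", "iso_z", "table", "organ", "H_T")
  if (!all(need %in% names(sweep)))
    stop("malformed sweep results: need columns ",
         paste(need, collapse = ", "))
  mono <- list(); domi <- list()
  key <- interaction(sweep$kvp, sweep$iso_z, sweep$table, sweep$aperture,
                     drop = TRUE)
  for (k in levels(key)) {
    s <- sweep[key == k & !is.na(sweep$aperture), ]
    for (org in unique(s$organ)) {
      so <- s[s$organ == org, ]
      so <- so[order(so$thickness), ]
      if (nrow(so) > 1 && any(diff(so$H_T) > 1e-12 * max(so$H_T)))
        mono[[length(mono) + 1]] <- data.frame(series = k, organ = org)
    }
  }
  es <- sweep[sweep$organ == "effective_dose" & !is.na(sweep$aperture), ]
  if (nrow(es)) {
    sp <- split(es, list(es$kvp, es$iso_z, es$table, es$thickness),
                drop = TRUE)
    for (s in sp) {
      if (length(unique(s$aperture)) < 2) next
      small <- s$H_T[which.min(s$aperture)]
      large <- s$H_T[which.max(s$aperture)]
      if (small > large * (1 + 1e-9))
        domi[[length(domi) + 1]] <- s[1, c("kvp", "iso_z", "table",
                                           "thickness")]
    }
  }
  mono <- if (length(mono)) do.call(rbind, mono) else NULL
  domi <- if (length(domi)) do.call(rbind, domi) else NULL
  if (!is.null(mono))
    warning("dose not monotone in filter thickness for ", nrow(mono),
            " organ series")
  if (!is.null(domi))
    warning("aperture dominance violated in ", nrow(domi), " cells")
  if (!is.null(plot_pdf)) {
    grDevices::pdf(plot_pdf, width = 7, height = 5)
    on.exit(grDevices::dev.off())
    for (org in unique(sweep$organ)) {
      s <- sweep[sweep$organ == org, ]
      plot(s$thickness, s$H_T, xlab = "filter thickness (mm)",
           ylab = "H_T (rel.)", main = org,
           pch = ifelse(is.na(s$aperture), 1, ifelse(s$aperture <= 0.2,
                                                     16, 17)))
    }
  }
  list(curves = sweep, monotonic_violations = mono,
       dominance_violations = domi,
       ok = is.null(mono) && is.null(domi))
}
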