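#' Exact voxel traversal of a line segment
#'
#' Siddon-style traversal: returns every voxel crossed by the segment
#' p0 -> p1 together with the exact intersection length; lengths sum to the
#' in-grid chord length.
#'
#' @param phantom a [voxel_phantom()].
#' @param p0,p1 world endpoints, mm.
#' @return data.frame with 1-based array indices `ix, iy, iz` and
#'   `length_mm`; zero rows if the segment misses the grid.
#' @export
siddon_trace <- function(phantom, p0, p1) {
  if (all(p0 == p1)) stop("p0 and p1 must differ")
  d <- dim(phantom$labels)
  res <- cpp_siddon(d, phantom$spacing, phantom$origin,
                    as.numeric(p0), as.numeric(p1))
  if (!length(res$index))
    return(data.frame(ix = integer(), iy = integer(), iz = integer(),
                      length_mm = numeric()))
  ijk <- arrayInd(res$index + 1L, d)
  data.frame(ix = ijk[, 1], iy = ijk[, 2], iz = ijk[, 3],
             length_mm = res$length_mm)
}

# Assemble per-label coefficient matrices [nE x nLab] for the engines.
.label_matrices <- function(phantom, energies) {
  ids <- sort(as.integer(names(phantom$label_map)))
  if (!identical(ids, seq_along(ids) - 1L))
    stop("label ids must be contiguous 0..n-1")
  get <- function(kind) vapply(ids, function(id) {
    m <- phantom$label_map[[as.character(id)]]$material
    if (is.character(m)) m <- froi_material(m)
    mixture_mu(m, energies, kind)
  }, numeric(length(energies)))
  list(ids = ids,
       mu = matrix(get("attenuation"), nrow = length(energies)),
       muen = matrix(get("energy_absorption"), nrow = length(energies)),
       photo = matrix(get("photo"), nrow = length(energies)),
       incoh = matrix(get("incoh"), nrow = length(energies)))
}

.engine_spectrum <- function(protocol, prefilter, spectrum) {
  if (is.null(spectrum))
    spectrum <- generate_spectrum(protocol$kvp,
                                  inherent_filtration = prefilter)
  spectrum
}

.filter_args <- function(roi_filter, protocol, energies) {
  if (is.null(roi_filter))
    return(list(has = FALSE, muf = numeric(length(energies)), tf = 0,
                r = 0, u0 = 0, v0 = 0))
  muf <- mixture_mu(roi_filter$mat, energies) * roi_filter$mat$density
  list(has = TRUE, muf = muf, tf = roi_filter$thickness_mm,
       r = aperture_radius_cm(roi_filter, protocol) * 10,
       u0 = roi_filter$aperture_center_cm[1] * 10,
       v0 = roi_filter$aperture_center_cm[2] * 10)
}

.dose_grid <- function(dose, phantom, engine, protocol, roi_filter, meta) {
  structure(list(dose = dose, spacing = phantom$spacing,
                 origin = phantom$origin, engine = engine,
                 protocol = protocol, roi_filter = roi_filter, meta = meta),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> engine=%s, max=%.3g, nonzero voxels=%d\n",
              x$engine, max(x$dose), sum(x$dose > 0)))
  invisible(x)
}

#' Deterministic primary-kerma dose engine
#'
#' For every projection and every in-cone body voxel, the spectral fluence
#' at the voxel is the source spectrum after inherent filtration, the
#' ROI-filter Beer-Lambert factor for the voxel's ray, the exact
#' Beer-Lambert line integral through the phantom (Siddon traversal), and
#' the inverse-square factor from the source; the voxel dose is the
#' energy-fluence-weighted mass energy-absorption coefficient summed over
#' energy bins and projections (collision kerma = dose; no scatter, no
#' electron transport).  Deterministic and exactly linear in the tube
#' current-time product.
#'
#' @param phantom a [voxel_phantom()].
#' @param protocol a [scan_protocol()].
#' @param isocenter world isocenter, mm.
#' @param roi_filter a [roi_filter()] or NULL.
#' @param prefilter inherent filtration [filter_stack()].
#' @param spectrum optionally a precomputed filtered [froi_spectrum()]
#'   (overrides `protocol$kvp` + `prefilter`).
#' @param deposition `"energy_absorption"` (collision kerma, default) or
#'   `"attenuation"` (total interaction energy deposition; the quantity
#'   estimated by the scatter-free Monte Carlo mode).
#' @return a `dose_grid`: per-voxel dose in keV/g per source primary
#'   (relative units; calibrate with [absolute_voxel_dose()]).
#' @export
primary_kerma_dose <- function(phantom, protocol, isocenter,
                               roi_filter = NULL,
                               prefilter = prefilter_cbra(),
                               spectrum = NULL,
                               deposition = c("energy_absorption",
                                              "attenuation")) {
  deposition <- match.arg(deposition)
  sp <- .engine_spectrum(protocol, prefilter, spectrum)
  keep <- sp$weight > max(sp$weight) * 1e-9
  energies <- sp$energy_kev[keep]
  weights <- sp$weight[keep]
  lm <- .label_matrices(phantom, energies)
  dep <- if (deposition == "energy_absorption") lm$muen else lm$mu
  fa <- .filter_args(roi_filter, protocol, energies)
  srcs <- source_positions(protocol, isocenter)
  cand <- which(phantom$labels != 0L) - 1L
  d <- dim(phantom$labels)
  dose <- cpp_primary_kerma(
    as.integer(phantom$labels), d, phantom$spacing, phantom$origin,
    as.numeric(phantom$density), lm$mu, dep, energies, weights,
    as.matrix(srcs[, c("sx", "sy", "sz")]), as.numeric(isocenter),
    protocol$source_detector_cm * 10,
    protocol$fov_cm[1] * 10, protocol$fov_cm[2] * 10,
    fa$has, fa$muf, fa$tf, fa$r, fa$u0, fa$v0, cand)
  .dose_grid(array(dose, d), phantom, "primary_kerma", protocol, roi_filter,
             list(deposition = deposition, isocenter = isocenter,
                  n_energy_bins = length(energies)))
}

#' Monte Carlo photon dose engine
#'
#' Simplified analog photon transport in the voxel grid under the kerma
#' approximation: free paths from the total attenuation coefficient
#' (Woodcock delta tracking), photoelectric absorption with full local
#' deposition, incoherent scattering with free-electron Klein-Nishina
#' (Kahn) sampling and local deposition of the transferred energy, and
#' coherent scattering as a Thomson-distribution direction change.
#' Photons below 1 keV are deposited locally.  Inherent and ROI filters
#' are applied as entry weights (weighted-attenuation rule).  Reproducible
#' for a given seed.
#'
#' @inheritParams primary_kerma_dose
#' @param histories number of primary histories.
#' @param seed integer RNG seed.
#' @param batches number of batches for type-A uncertainty.
#' @param mode `"full"` or `"photoelectric_only"` (scatter channels
#'   disabled with forced full-energy absorption at each collision; this
#'   estimates the same quantity as the deterministic engine with
#'   `deposition = "attenuation"`).
#' @return a `dose_grid` with per-voxel dose (keV/g per primary, same
#'   normalization as [primary_kerma_dose()]), per-voxel relative type-A
#'   uncertainty, and per-label batch sums for organ-level uncertainty.
#' @export
mc_photon_dose <- function(phantom, protocol, isocenter, roi_filter = NULL,
                           prefilter = prefilter_cbra(), spectrum = NULL,
                           histories = 1e6, seed = 1L, batches = 20,
                           mode = c("full", "photoelectric_only")) {
  mode <- match.arg(mode)
  if (histories < 1) stop("histories must be >= 1")
  seed <- as.integer(seed)
  sp <- .engine_spectrum(protocol, prefilter, spectrum)
  # cross sections on the full 1..150 keV 1-keV grid for in-flight lookup
  xsE <- seq(1, 150)
  lm <- .label_matrices(phantom, xsE)
  dens_by_lab <- vapply(lm$ids, function(id) {
    w <- phantom$labels == id
    if (any(w)) max(phantom$density[w]) else 0
  }, numeric(1))
  mumax <- apply(sweep(lm$mu, 2, dens_by_lab, "*"), 1, max)
  fa <- .filter_args(roi_filter, protocol, xsE)
  srcs <- source_positions(protocol, isocenter)
  d <- dim(phantom$labels)
  res <- cpp_mc_dose(
    as.integer(phantom$labels), d, phantom$spacing, phantom$origin,
    as.numeric(phantom$density), lm$mu, lm$photo, lm$incoh, mumax,
    sp$energy_kev, sp$weight, as.matrix(srcs[, c("sx", "sy", "sz")]),
    as.numeric(isocenter), protocol$source_detector_cm * 10,
    protocol$fov_cm[1] * 10, protocol$fov_cm[2] * 10,
    fa$has, fa$muf, fa$tf, fa$r, fa$u0, fa$v0,
    histories, seed, as.integer(batches),
    if (mode == "full") 0L else 1L)
  voxmass <- phantom$density * prod(phantom$spacing) / 1000  # g
  dose <- array(res$edep_per_history, d)
  nz <- voxmass > 0
  dose[nz] <- dose[nz] / voxmass[nz]
  dose[!nz] <- 0
  g <- .dose_grid(dose, phantom, "mc_photon", protocol, roi_filter,
                  list(isocenter = isocenter, histories = histories,
                       seed = seed, batches = batches, mode = mode))
  g$rel_uncertainty <- array(res$rel_uncertainty, d)
  g$label_batch <- res$label_batch
  g
}

#' Free-in-air kerma at the isocenter
#'
#' Calibration-geometry simulation: the spectral fluence at the isocenter
#' (no phantom, no table) summed over all projections, converted to air
#' kerma with the air mass energy-absorption coefficient.  This is the
#' simulated denominator of the absolute-dose calibration factor.
#'
#' @inheritParams primary_kerma_dose
#' @return air kerma per source primary (keV/g per primary, same relative
#'   normalization as the dose engines).
#' @export
air_kerma_at_isocenter <- function(protocol, prefilter = prefilter_cbra(),
                                   roi_filter = NULL, spectrum = NULL) {
  sp <- .engine_spectrum(protocol, prefilter, spectrum)
  energies <- sp$energy_kev
  muen_air <- mixture_mu(froi_material("air"), energies, "energy_absorption")
  iso <- c(0, 0, 0)
  srcs <- source_positions(protocol, iso)
  fa <- .filter_args(roi_filter, protocol, energies)
  r_cm <- protocol$source_isocenter_cm
  total <- 0
  for (p in seq_len(nrow(srcs))) {
    src <- as.numeric(srcs[p, c("sx", "sy", "sz")])
    axis <- as.numeric(srcs[p, c("ax", "ay", "az")])
    path_cm <- 0
    if (!is.null(roi_filter))
      path_cm <- filter_path_length(roi_filter, protocol, src, axis,
                                    axis) / 10
    att <- exp(-fa$muf * path_cm)
    total <- total + sum(sp$weight * att * energies * muen_air) / r_cm^2
  }
  total
}
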