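#' Rotational cone-beam scan protocol
#'
#' Acquisition constants of the 3D CBRA spin.  Defaults are the
#' head-protocol values: 250 mA, 6.3 ms per frame, 106 projections at 2
#' degree spacing starting at 106 degrees, source-imager distance 110 cm,
#' source-isocenter distance 70 cm, 20 x 20 cm detector field of view.
#'
#' The gantry angle is measured in the axial (X-Y) plane with 0 degrees at
#' the posterior (+Y) direction -- the resting tube-under-table position of
#' an angiographic C-arm -- increasing toward the patient's left; the
#' source sits at `isocenter + R (sin a, cos a, 0)`.
#'
#' @param kvp tube voltage, kV.
#' @param tube_current_ma tube current I, mA.
#' @param exposure_time_ms exposure time per frame t, ms.
#' @param projections number of projections.
#' @param angular_spacing_deg angular spacing, degrees.
#' @param start_angle_deg starting gantry angle, degrees.
#' @param source_isocenter_cm source-isocenter distance, cm.
#' @param source_detector_cm source-imager distance, cm.
#' @param fov_cm detector field of view (width, height), cm.
#' @return object of class `scan_protocol`.
#' @export
scan_protocol <- function(kvp = 100, tube_current_ma = 250,
                          exposure_time_ms = 6.3, projections = 106,
                          angular_spacing_deg = 2, start_angle_deg = 106,
                          source_isocenter_cm = 70,
                          source_detector_cm = 110, fov_cm = c(20, 20)) {
  stopifnot(projections >= 1, angular_spacing_deg > 0,
            source_isocenter_cm > 0, source_detector_cm > 0,
            all(fov_cm > 0))
  structure(list(kvp = kvp, tube_current_ma = tube_current_ma,
                 exposure_time_ms = exposure_time_ms,
                 projections = as.integer(projections),
                 angular_spacing_deg = angular_spacing_deg,
                 start_angle_deg = start_angle_deg,
                 source_isocenter_cm = source_isocenter_cm,
                 source_detector_cm = source_detector_cm,
                 fov_cm = fov_cm),
            class = "scan_protocol")
}

#' Total tube charge of a protocol
#' @param protocol a [scan_protocol()].
#' @return total mAs (I x t summed over all frames).
#' @export
protocol_mAs <- function(protocol) {
  protocol$tube_current_ma * protocol$exposure_time_ms / 1000 *
    protocol$projections
}

#' Source positions of a rotational protocol
#'
#' Gantry angles are `start + k * spacing` for k = 0..projections-1; the
#' source moves on a circle of radius equal to the source-isocenter
#' distance in the axial plane about the isocenter.
#'
#' @param protocol a [scan_protocol()].
#' @param isocenter world isocenter, mm (length 3).
#' @return data.frame with `angle_deg`, source point `sx, sy, sz` (mm), and
#'   unit beam axis `ax, ay, az` (pointing source -> isocenter).
#' @export
source_positions <- function(protocol, isocenter) {
  k <- seq_len(protocol$projections) - 1
  ang <- protocol$start_angle_deg + k * protocol$angular_spacing_deg
  r <- protocol$source_isocenter_cm * 10
  a <- ang * pi / 180
  sx <- isocenter[1] + r * sin(a)
  sy <- isocenter[2] + r * cos(a)
  sz <- rep(isocenter[3], length(a))
  data.frame(angle_deg = ang, sx = sx, sy = sy, sz = sz,
             ax = (isocenter[1] - sx) / r, ay = (isocenter[2] - sy) / r,
             az = 0)
}

#' Region-of-interest beam filter
#'
#' An attenuating sheet with a circular aperture placed in the beam: rays
#' whose detector-plane intersection falls inside the projected aperture
#' pass unattenuated, all other in-FOV rays traverse the sheet.  "Aperture
#' size x% of FOV" is interpreted as aperture area = x% of the detector
#' FOV area (`interpretation = "area"`, the default); a linear-fraction
#' reading (`"linear"`: diameter = x% of the FOV side) is also available.
#'
#' @param thickness_mm effective sheet thickness, mm.
#' @param aperture_fraction fraction of FOV, in (0, 1).
#' @param mat sheet material, default pure gadolinium oxysulfide.
#' @param interpretation `"area"` or `"linear"`.
#' @param aperture_center_cm aperture center in detector coordinates (u, v),
#'   cm; (0, 0) is the beam axis.
#' @return object of class `roi_filter`.
#' @export
roi_filter <- function(thickness_mm, aperture_fraction = 0.2,
                       mat = froi_material("gadolinium_oxysulfide"),
                       interpretation = c("area", "linear"),
                       aperture_center_cm = c(0, 0)) {
  interpretation <- match.arg(interpretation)
  if (thickness_mm < 0) stop("thickness must be >= 0")
  if (aperture_fraction <= 0 || aperture_fraction >= 1)
    stop("aperture fraction must be in (0, 1)")
  structure(list(mat = mat, thickness_mm = thickness_mm,
                 aperture_fraction = aperture_fraction,
                 interpretation = interpretation,
                 aperture_center_cm = aperture_center_cm),
            class = "roi_filter")
}

#' Aperture radius of an ROI filter at the detector plane
#' @param filter a [roi_filter()].
#' @param protocol a [scan_protocol()].
#' @return radius in cm.
#' @export
aperture_radius_cm <- function(filter, protocol) {
  if (filter$interpretation == "area")
    sqrt(filter$aperture_fraction * prod(protocol$fov_cm) / pi)
  else filter$aperture_fraction * min(protocol$fov_cm) / 2
}

#' Filter material path length of a ray
#'
#' Zero if the ray's detector-plane intersection lies inside the projected
#' circular aperture; otherwise the slab path `thickness / cos(obliquity)`,
#' the obliquity measured against the beam axis (the filter normal).
#'
#' @param filter a [roi_filter()] (or NULL: always 0).
#' @param protocol a [scan_protocol()].
#' @param source source point, mm.
#' @param axis unit beam axis (source -> isocenter).
#' @param direction unit ray direction from the source.
#' @return path length through the filter material, mm.
#' @export
filter_path_length <- function(filter, protocol, source, axis, direction) {
  if (is.null(filter)) return(0)
  ct <- sum(axis * direction)
  if (ct <= 1e-12) stop("ray parallel to (or away from) the detector plane")
  sdd <- protocol$source_detector_cm * 10
  hit <- direction * (sdd / ct)            # source -> detector-plane point
  off <- hit - axis * sdd                  # in-plane offset, mm
  vhat <- c(0, 0, 1)
  uhat <- c(axis[2], -axis[1], 0)          # z x axis (axis is axial)
  u <- sum(off * uhat) / 10; v <- sum(off * vhat) / 10   # cm
  r <- aperture_radius_cm(filter, protocol)
  cc <- filter$aperture_center_cm
  if ((u - cc[1])^2 + (v - cc[2])^2 <= r^2) 0
  else filter$thickness_mm / ct
}
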