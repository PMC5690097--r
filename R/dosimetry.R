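#' ICRP 103 tissue weighting factors
#'
#' The bundled tissue weighting factors w_T (sum = 1).  `remainder` is the
#' 0.12 remainder-tissues weight, applied as the arithmetic mean of the
#' remainder organs present in the phantom.
#' @export
icrp103_weights <- function() {
  c(gonads = 0.08, bone_marrow = 0.12, colon = 0.12, lung = 0.12,
    stomach = 0.12, breast = 0.12, bladder = 0.04, oesophagus = 0.04,
    liver = 0.04, thyroid = 0.04, bone_surface = 0.01, brain = 0.01,
    salivary_glands = 0.01, skin = 0.01, remainder = 0.12)
}

#' Default organ-to-tissue mapping for the synthetic head phantom
#'
#' Maps phantom organ labels to ICRP 103 tissues for the effective-dose
#' sum.  The cranial bone dose stands in for both bone marrow and bone
#' surface; generic head soft tissue is the only remainder representative
#' (muscle / oral-mucosa surrogate); eye lenses and the spinal cord are
#' reported but never enter the effective dose.
#' @export
head_tissue_map <- function() {
  list(brain = "brain",
       skin = "skin",
       skull = c("bone_marrow", "bone_surface"),
       salivary_left = "salivary_glands",
       salivary_right = "salivary_glands",
       soft_tissue = "remainder")
}

#' Apply the absolute-dose calibration
#'
#' Scales every voxel by CF x I x t, with I x t the protocol's total tube
#' charge in mAs, converting simulated relative dose per primary into
#' absolute dose.
#'
#' @param grid a `dose_grid`.
#' @param cf a [calibration_factor()]; its tube voltage must match the
#'   protocol.
#' @param protocol a [scan_protocol()].
#' @return the calibrated `dose_grid` (units: those of the measured air
#'   kerma, typically Gy).
#' @export
absolute_voxel_dose <- function(grid, cf, protocol) {
  stopifnot(inherits(cf, "froi_calibration_factor"))
  if (!isTRUE(all.equal(cf$kvp, protocol$kvp)))
    stop("calibration factor tube voltage (", cf$kvp,
         " kVp) does not match the protocol (", protocol$kvp, " kVp)")
  out <- grid
  out$dose <- grid$dose * cf$cf * protocol_mAs(protocol)
  out$meta$calibrated <- TRUE
  out
}

#' Organ equivalent dose
#'
#' Mass-weighted mean voxel dose over the organ times the radiation
#' weighting factor (w_r = 1 for photons):
#' H_T = w_r * sum(D_i rho_i v_i) / sum(rho_i v_i).
#'
#' @param grid a `dose_grid`.
#' @param phantom the [voxel_phantom()] the grid was computed on.
#' @param organ organ name (label-map name) or integer label id.
#' @return one-row data.frame: `organ`, `H_T`, `w_r`, `n_voxel`, `mass_g`,
#'   `engine`, and `rel_uncertainty` (type-A, Monte Carlo engine only).
#' @export
organ_dose <- function(grid, phantom, organ) {
  ids <- as.integer(names(phantom$label_map))
  nms <- vapply(phantom$label_map, function(x) x$name, character(1))
  id <- if (is.character(organ)) ids[match(organ, nms)] else as.integer(organ)
  if (is.na(id) || !id %in% ids) stop("unknown organ: ", organ)
  w <- which(phantom$labels == id)
  if (!length(w)) stop("organ has no voxels: ", organ)
  rho_v <- phantom$density[w]                       # voxel volume cancels
  ht <- sum(grid$dose[w] * rho_v) / sum(rho_v)
  unc <- NA_real_
  if (!is.null(grid$label_batch)) {
    b <- grid$label_batch[id + 1L, ]
    if (mean(b) > 0 && length(b) > 1)
      unc <- stats::sd(b) / sqrt(length(b)) / mean(b)
  }
  data.frame(organ = nms[match(id, ids)], H_T = ht, w_r = 1,
             n_voxel = length(w),
             mass_g = sum(rho_v) * prod(phantom$spacing) / 1000,
             engine = grid$engine, rel_uncertainty = unc)
}

#' @rdname organ_dose
#' @param organs organ names; default: all non-air labels.
#' @export
organ_dose_report <- function(grid, phantom, organs = NULL) {
  nms <- vapply(phantom$label_map, function(x) x$name, character(1))
  if (is.null(organs)) organs <- setdiff(nms, c("air", "table"))
  do.call(rbind, lapply(organs, function(o) organ_dose(grid, phantom, o)))
}

#' Effective dose
#'
#' ICRP 103 tissue-weighted sum E = sum_T w_T H_T over the organs present.
#' Paired organs mapped to the same tissue (left/right salivary glands)
#' are combined as a mass-weighted mean before weighting; the remainder
#' weight uses the arithmetic mean of the remainder organs present (zero,
#' and flagged, if none).  Organs mapped to several tissues (cranial bone
#' as a bone-marrow and bone-surface surrogate) contribute to each.  E is
#' a partial-body effective dose: tissues absent from the phantom are
#' listed with zero contribution.
#'
#' @param reports data.frame from [organ_dose_report()].
#' @param tissue_map organ -> tissue mapping, see [head_tissue_map()].
#' @param weights tissue weighting factors, see [icrp103_weights()].
#' @return list with `E`, `terms` (tissue, w_T, H_T, contribution),
#'   `absent_tissues`, and `remainder_organs`.
#' @export
effective_dose <- function(reports, tissue_map = head_tissue_map(),
                           weights = icrp103_weights()) {
  if (anyDuplicated(reports$organ))
    stop("each organ may appear at most once")
  unknown <- setdiff(reports$organ,
                     c(names(tissue_map), "air", "table", "lens_left",
                       "lens_right", "spinal_cord"))
  if (length(unknown))
    stop("organ(s) not in the tissue map: ", paste(unknown, collapse = ", "))
  ht <- list(); mass <- list()
  for (i in seq_len(nrow(reports))) {
    org <- reports$organ[i]
    for (tis in tissue_map[[org]]) {
      ht[[tis]] <- c(ht[[tis]], reports$H_T[i])
      mass[[tis]] <- c(mass[[tis]], reports$mass_g[i])
    }
  }
  remainder_organs <- character(0)
  terms <- data.frame(tissue = names(weights), w_T = unname(weights),
                      H_T = 0, contribution = 0)
  for (tis in names(weights)) {
    if (is.null(ht[[tis]])) next
    h <- if (tis == "remainder") mean(ht[[tis]])   # ICRP arithmetic-mean rule
    else sum(ht[[tis]] * mass[[tis]]) / sum(mass[[tis]])
    terms$H_T[terms$tissue == tis] <- h
    terms$contribution[terms$tissue == tis] <- h * weights[[tis]]
    if (tis == "remainder")
      remainder_organs <- reports$organ[
        vapply(reports$organ,
               function(o) "remainder" %in% tissue_map[[o]], logical(1))]
  }
  list(E = sum(terms$contribution), terms = terms,
       absent_tissues = terms$tissue[terms$H_T == 0],
       remainder_organs = remainder_organs)
}

#' Relative dose reduction
#'
#' reduction = 1 - H_T(filtered) / H_T(unfiltered) per organ, and for the
#' effective dose when both reports carry one.  Calibration and tube
#' charge cancel, so uncalibrated grids are valid inputs.
#'
#' @param filtered,unfiltered organ-dose data.frames from
#'   [organ_dose_report()] for the same phantom and protocol, with and
#'   without the ROI filter.
#' @param e_filtered,e_unfiltered optional effective doses.
#' @return data.frame of per-organ reductions (plus an `effective_dose`
#'   row if both E values are given).
#' @export
dose_reduction <- function(filtered, unfiltered, e_filtered = NULL,
                           e_unfiltered = NULL) {
  m <- match(unfiltered$organ, filtered$organ)
  if (anyNA(m)) stop("reports cover different organs")
  if (any(unfiltered$H_T <= 0)) stop("zero unfiltered organ dose")
  out <- data.frame(organ = unfiltered$organ,
                    unfiltered = unfiltered$H_T,
                    filtered = filtered$H_T[m],
                    reduction = 1 - filtered$H_T[m] / unfiltered$H_T)
  if (!is.null(e_filtered) && !is.null(e_unfiltered)) {
    if (e_unfiltered <= 0) stop("zero unfiltered effective dose")
    out <- rbind(out, data.frame(organ = "effective_dose",
                                 unfiltered = e_unfiltered,
                                 filtered = e_filtered,
                                 reduction = 1 - e_filtered / e_unfiltered))
  }
  out
}

#' Theoretical (dose-area-product) dose reduction of an ROI filter
#'
#' The fraction of the dose-area product removed by attenuating the beam
#' area outside the aperture:
#' R = (1 - aperture_fraction) * (1 - transmission).
#'
#' @param transmission broad-beam transmission of the filter sheet, 0-1.
#' @param aperture_fraction open fraction of the FOV, 0-1.
#' @return reduction fraction in 0-1.
#' @export
theoretical_reduction <- function(transmission, aperture_fraction) {
  stopifnot(all(transmission >= 0 & transmission <= 1),
            all(aperture_fraction >= 0 & aperture_fraction <= 1))
  (1 - aperture_fraction) * (1 - transmission)
}
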