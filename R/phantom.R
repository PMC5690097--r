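#' Voxel phantom
#'
#' A labeled 3D voxel grid with per-voxel density and a per-label material
#' map.  Axes are ordered X (left-right), Y (anterior-posterior, +Y
#' posterior), Z (caudo-cranial); the world position of voxel (i,j,k)
#' (0-based) is `origin + (index + 0.5) * spacing` (voxel-center
#' convention), in mm.
#'
#' @param labels 3D integer array of label ids (0 = air outside the body).
#' @param spacing voxel size per axis, mm.
#' @param origin world position of the grid corner, mm.
#' @param label_map named list: label id (as character) -> list(name,
#'   material, density); `material` is a built-in material name or a
#'   [material()] object.
#' @param density optional 3D array of per-voxel densities (g/cm^3);
#'   defaults to the label densities.
#' @return object of class `voxel_phantom`.
#' @export
voxel_phantom <- function(labels, spacing, origin, label_map,
                          density = NULL) {
  stopifnot(length(dim(labels)) == 3, length(spacing) == 3,
            length(origin) == 3)
  present <- sort(unique(as.integer(labels)))
  missing <- setdiff(present, as.integer(names(label_map)))
  if (length(missing))
    stop("labels missing from label map: ", paste(missing, collapse = ", "))
  for (id in names(label_map)) {
    lm <- label_map[[id]]
    if (is.character(lm$material)) lm$material <- froi_material(lm$material)
    if (is.null(lm$density)) lm$density <- lm$material$density
    if (as.integer(id) != 0 && lm$density <= 0)
      stop("non-air label ", id, " must have positive density")
    label_map[[id]] <- lm
  }
  if (is.null(density)) {
    density <- array(0, dim(labels))
    for (id in names(label_map))
      density[labels == as.integer(id)] <- label_map[[id]]$density
  }
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), label_map = label_map,
                 density = density),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<voxel_phantom> %d x %d x %d voxels @ %s mm, %d labels\n",
              d[1], d[2], d[3], paste(x$spacing, collapse = "x"),
              length(x$label_map)))
  invisible(x)
}

#' Organ summary of a phantom
#'
#' Voxel counts, volumes, masses and centroids per label.
#' @param phantom a [voxel_phantom()].
#' @return data.frame, one row per label.
#' @export
phantom_organs <- function(phantom) {
  vv <- prod(phantom$spacing) / 1000   # cm^3
  ids <- as.integer(names(phantom$label_map))
  d <- dim(phantom$labels)
  out <- lapply(ids, function(id) {
    w <- which(phantom$labels == id)
    if (!length(w)) return(NULL)
    ijk <- arrayInd(w, d) - 1L
    ctr <- phantom$origin + (colMeans(ijk) + 0.5) * phantom$spacing
    data.frame(label = id, organ = phantom$label_map[[as.character(id)]]$name,
               n_voxel = length(w), volume_cm3 = length(w) * vv,
               mass_g = sum(phantom$density[w]) * vv,
               x_mm = ctr[1], y_mm = ctr[2], z_mm = ctr[3])
  })
  do.call(rbind, out)
}

#' Default anatomy of the synthetic head phantom
#'
#' All sizes in mm, world coordinates chosen so that the phantom midline is
#' at X = 265 mm, the head's anterior-posterior center at Y = 105 mm, and
#' the orbital (eye-lens) plane at Z = 1580 mm, matching the isocenter
#' coordinates used by head CBRA protocols; Z = 1550 mm then lies 30 mm
#' caudally, toward the salivary glands.
#' @param rel_density_sd relative per-voxel density heterogeneity (Gaussian,
#'   applied to non-air voxels).
#' @export
head_params <- function(rel_density_sd = 0.01) {
  list(
    center = c(265, 105, 1580),          # head center / eye-lens plane
    head_half = c(77, 97, 110),          # outer (skin) ellipsoid half-axes
    skin_mm = 3,                         # skin shell thickness
    skull_outer = c(70, 90, 103),
    skull_inner = c(63, 83, 96),
    brain_center_dz = 25,
    brain_half = c(62, 78, 65),
    cord_radius = 5.5, cord_y = 125, cord_top_z = 1545,
    neck_radius = 52, neck_y = 115, neck_top_z = 1500,
    salivary_dx = 45, salivary_y = 113, salivary_z = 1510,
    salivary_half = c(11, 16, 20),
    lens_dx = 31, lens_radius = 5, lens_depth_mm = 8,
    grid_pad_mm = 12,
    rel_density_sd = rel_density_sd
  )
}

#' Synthetic labeled voxel head phantom
#'
#' Deterministic (given seed) labeled head-and-neck phantom: soft tissue,
#' skin shell, cranial bone shell, brain, left/right eye lens, left/right
#' salivary (parotid) gland, and spinal cord, surrounded by air, with
#' ICRU-44-style tissue materials.  It stands in for a reference
#' anthropomorphic voxel phantom at desk scale; it is synthetic and its
#' organ shapes are analytic primitives.  The seed drives the per-voxel
#' density heterogeneity.
#'
#' @param voxel_mm isotropic voxel size, 1-5 mm (default 2.5).
#' @param params anatomy from [head_params()].
#' @param seed integer RNG seed.
#' @return a [voxel_phantom()]; `attr(, "organs")` holds the organ summary.
#' @export
make_synthetic_head <- function(voxel_mm = 2.5, params = head_params(),
                                seed = 1L) {
  if (voxel_mm < 1 || voxel_mm > 5)
    stop("voxel size must be within 1-5 mm")
  p <- params
  ctr <- p$center
  pad <- p$grid_pad_mm
  xr <- c(ctr[1] - p$head_half[1] - pad, ctr[1] + p$head_half[1] + pad)
  yr <- c(ctr[2] - p$head_half[2] - pad, ctr[2] + p$head_half[2] + pad)
  zr <- c(ctr[3] - p$head_half[3] - 50 - pad, ctr[3] + p$head_half[3] + pad)
  n <- ceiling(c(diff(xr), diff(yr), diff(zr)) / voxel_mm)
  if (any(n < 8)) stop("voxel grid too small to contain the head")
  # center the grid on the midline so the phantom is mirror-symmetric in X
  origin <- c(ctr[1] - n[1] * voxel_mm / 2, yr[1], zr[1])
  sp <- rep(voxel_mm, 3)
  xs <- origin[1] + (seq_len(n[1]) - 0.5) * voxel_mm
  ys <- origin[2] + (seq_len(n[2]) - 0.5) * voxel_mm
  zs <- origin[3] + (seq_len(n[3]) - 0.5) * voxel_mm
  X <- array(rep(xs, times = n[2] * n[3]), n)
  Y <- array(rep(rep(ys, each = n[1]), times = n[3]), n)
  Z <- array(rep(zs, each = n[1] * n[2]), n)

  ell <- function(c3, h3) ((X - c3[1]) / h3[1])^2 +
    ((Y - c3[2]) / h3[2])^2 + ((Z - c3[3]) / h3[3])^2
  lab <- array(0L, n)

  head_mask <- ell(ctr, p$head_half) <= 1
  neck_mask <- (X - ctr[1])^2 + (Y - p$neck_y)^2 <= p$neck_radius^2 &
    Z <= p$neck_top_z
  lab[head_mask | neck_mask] <- 1L                       # soft tissue
  skin_mask <- head_mask & ell(ctr, p$head_half - p$skin_mm) > 1
  lab[skin_mask] <- 2L                                   # skin
  skull <- ell(ctr, p$skull_outer) <= 1 & ell(ctr, p$skull_inner) > 1
  lab[skull] <- 3L                                       # cranial bone
  bctr <- ctr + c(0, 0, p$brain_center_dz)
  lab[ell(bctr, p$brain_half) <= 1] <- 4L                # brain
  cord <- (X - ctr[1])^2 + (Y - p$cord_y)^2 <= p$cord_radius^2 &
    Z <= p$cord_top_z
  lab[cord & (head_mask | neck_mask)] <- 5L              # spinal cord
  for (s in c(1, -1)) {
    sc <- c(ctr[1] + s * p$salivary_dx, p$salivary_y, p$salivary_z)
    m <- ell(sc, p$salivary_half) <= 1 & (head_mask | neck_mask)
    lab[m] <- if (s > 0) 6L else 7L                      # salivary glands
  }
  yhalf <- p$head_half[2] * sqrt(max(0, 1 - (p$lens_dx / p$head_half[1])^2))
  lens_y <- ctr[2] - yhalf + p$lens_depth_mm
  for (s in c(1, -1)) {
    lc <- c(ctr[1] + s * p$lens_dx, lens_y, ctr[3])
    m <- (X - lc[1])^2 + (Y - lc[2])^2 + (Z - lc[3])^2 <= p$lens_radius^2
    lab[m] <- if (s > 0) 8L else 9L                      # eye lenses
  }

  label_map <- list(
    "0" = list(name = "air", material = "air"),
    "1" = list(name = "soft_tissue", material = "soft_tissue"),
    "2" = list(name = "skin", material = "skin"),
    "3" = list(name = "skull", material = "bone_cortical"),
    "4" = list(name = "brain", material = "brain"),
    "5" = list(name = "spinal_cord", material = "spinal_cord"),
    "6" = list(name = "salivary_left", material = "salivary"),
    "7" = list(name = "salivary_right", material = "salivary"),
    "8" = list(name = "lens_left", material = "eye_lens"),
    "9" = list(name = "lens_right", material = "eye_lens"))

  ph <- voxel_phantom(lab, sp, origin, label_map)
  if (p$rel_density_sd > 0) {
    set.seed(as.integer(seed))
    nz <- which(lab != 0L)
    jit <- 1 + p$rel_density_sd * stats::rnorm(length(nz))
    ph$density[nz] <- ph$density[nz] * pmax(jit, 0.5)
  }
  attr(ph, "organs") <- phantom_organs(ph)
  attr(ph, "params") <- p
  attr(ph, "seed") <- as.integer(seed)
  ph
}

#' Attach a patient-table slab to a phantom
#'
#' Extends the voxel grid posteriorly (+Y) and inserts a rectangular
#' carbon slab of the fitted effective density spanning the phantom
#' content's X-Z footprint, replicating the voxel-matrix extension used to
#' model the table pillar under the head.  Original labels are untouched.
#'
#' @param phantom a [voxel_phantom()].
#' @param density slab density, g/cm^3 (the fitted effective density).
#' @param thickness_mm slab thickness, mm.
#' @param gap_mm air gap between the posterior body surface and the slab.
#' @return the extended [voxel_phantom()]; slab voxels carry a new label
#'   `"table"`.
#' @export
attach_table <- function(phantom, density = 0.375, thickness_mm = 40,
                         gap_mm = 0) {
  if (thickness_mm < 0 || gap_mm < 0) stop("thickness and gap must be >= 0")
  if (thickness_mm == 0) return(phantom)
  d <- dim(phantom$labels)
  dy <- phantom$spacing[2]
  nz_idx <- which(phantom$labels != 0L, arr.ind = TRUE)
  if (!nrow(nz_idx)) stop("empty phantom")
  xrange <- range(nz_idx[, 1]); zrange <- range(nz_idx[, 3])
  ymax <- max(nz_idx[, 2])
  gap_vox <- round(gap_mm / dy)
  thick_vox <- max(1L, round(thickness_mm / dy))
  need <- ymax + gap_vox + thick_vox
  add <- max(0L, need - d[2])
  lab <- array(0L, c(d[1], d[2] + add, d[3]))
  den <- array(0, dim(lab))
  lab[, seq_len(d[2]), ] <- phantom$labels
  den[, seq_len(d[2]), ] <- phantom$density
  new_id <- max(as.integer(names(phantom$label_map))) + 1L
  ys <- (ymax + gap_vox + 1):(ymax + gap_vox + thick_vox)
  lab[xrange[1]:xrange[2], ys, zrange[1]:zrange[2]] <- new_id
  den[xrange[1]:xrange[2], ys, zrange[1]:zrange[2]] <- density
  lm <- phantom$label_map
  lm[[as.character(new_id)]] <- list(
    name = "table", material = froi_material("carbon", density = density),
    density = density)
  out <- voxel_phantom(lab, phantom$spacing, phantom$origin, lm,
                       density = den)
  attr(out, "organs") <- phantom_organs(out)
  out
}

#' Mirror a phantom in X
#'
#' Flips the grid left-right and swaps paired left/right organ labels;
#' volumes and masses are invariant.
#' @param phantom a [voxel_phantom()].
#' @export
mirror_phantom <- function(phantom) {
  lab <- phantom$labels[dim(phantom$labels)[1]:1, , ]
  den <- phantom$density[dim(phantom$density)[1]:1, , ]
  swap <- c("salivary_left" = "salivary_right",
            "salivary_right" = "salivary_left",
            "lens_left" = "lens_right", "lens_right" = "lens_left")
  lm <- phantom$label_map
  nm <- vapply(lm, function(x) x$name, character(1))
  for (i in seq_along(lm))
    if (nm[i] %in% names(swap)) lm[[i]]$name <- unname(swap[nm[i]])
  voxel_phantom(lab, phantom$spacing, phantom$origin, lm, density = den)
}

#' Read and write voxel phantoms
#'
#' Phantoms are stored as a MetaImage-style text header (`.mhd`), a raw
#' little-endian int16 label grid (`.raw`), a raw float32 per-voxel density
#' grid (`_density.raw`), and a JSON sidecar (`.json`) holding the label
#' map (organ name, material name/composition, density).  The round trip
#' is lossless.
#'
#' @param phantom a [voxel_phantom()].
#' @param path file path without extension.
#' @return `read_phantom` returns a [voxel_phantom()].
#' @export
write_phantom <- function(phantom, path) {
  d <- dim(phantom$labels)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementSpacing =", paste(phantom$spacing, collapse = " ")),
           paste("Offset =", paste(phantom$origin, collapse = " ")),
           "ElementType = MET_SHORT",
           paste0("ElementDataFile = ", basename(path), ".raw"))
  writeLines(hdr, paste0(path, ".mhd"))
  con <- file(paste0(path, ".raw"), "wb")
  writeBin(as.integer(phantom$labels), con, size = 2, endian = "little")
  close(con)
  con <- file(paste0(path, "_density.raw"), "wb")
  writeBin(as.numeric(phantom$density), con, size = 4, endian = "little")
  close(con)
  side <- lapply(phantom$label_map, function(lm) list(
    name = lm$name, material_name = lm$material$name,
    composition = as.list(lm$material$composition),
    material_density = lm$material$density, density = lm$density))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  hdr <- readLines(paste0(path, ".mhd"))
  gv <- function(key) {
    ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)
    if (!length(ln)) stop("malformed header: missing ", key)
    strsplit(sub("^[^=]*= *", "", ln[1]), " +")[[1]]
  }
  d <- as.integer(gv("DimSize"))
  spacing <- as.numeric(gv("ElementSpacing"))
  origin <- as.numeric(gv("Offset"))
  con <- file(paste0(path, ".raw"), "rb")
  lab <- readBin(con, integer(), n = prod(d), size = 2, endian = "little")
  close(con)
  con <- file(paste0(path, "_density.raw"), "rb")
  den <- readBin(con, numeric(), n = prod(d), size = 4, endian = "little")
  close(con)
  side <- jsonlite::read_json(paste0(path, ".json"))
  label_map <- lapply(side, function(s) list(
    name = s$name,
    material = material(s$material_name,
                        unlist(s$composition), s$material_density),
    density = s$density))
  names(label_map) <- names(side)
  present <- unique(lab)
  unmapped <- setdiff(present, as.integer(names(label_map)))
  if (length(unmapped))
    stop("file contains unmapped label(s): ",
         paste(unmapped, collapse = ", "))
  voxel_phantom(array(lab, d), spacing, origin, label_map,
                density = array(den, d))
}
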