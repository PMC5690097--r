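# Small programmatic fixtures shared across the suite.

# homogeneous cube of a single material, centered at the origin
cube_phantom <- function(n = 20L, voxel_mm = 10, mat = "water",
                         center = c(0, 0, 0)) {
  lab <- array(1L, c(n, n, n))
  lm <- list("0" = list(name = "air", material = "air"),
             "1" = list(name = mat, material = mat))
  voxel_phantom(lab, rep(voxel_mm, 3), center - n * voxel_mm / 2, lm)
}

# cube with a single-voxel "probe" organ at the exact center
probe_phantom <- function(n = 21L, voxel_mm = 10, mat = "water") {
  lab <- array(1L, c(n, n, n))
  c0 <- (n + 1L) / 2L
  lab[c0, c0, c0] <- 2L
  lm <- list("0" = list(name = "air", material = "air"),
             "1" = list(name = mat, material = mat),
             "2" = list(name = "probe", material = mat))
  voxel_phantom(lab, rep(voxel_mm, 3), rep(-n * voxel_mm / 2, 3), lm)
}

mono_spectrum <- function(e_kev, kvp = 100) {
  froi_spectrum(kvp, 1:150, as.numeric(1:150 == e_kev))
}

# small head used by the heavier transport tests
test_head <- function(voxel_mm = 5) make_synthetic_head(voxel_mm, seed = 42)

ISO_HEAD <- c(265, 90, 1580)
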