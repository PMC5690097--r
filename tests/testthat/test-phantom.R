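test_that("synthetic head is deterministic and anatomically consistent", {
  p1 <- make_synthetic_head(voxel_mm = 5, seed = 7)
  p2 <- make_synthetic_head(voxel_mm = 5, seed = 7)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$density, p2$density)
  p3 <- make_synthetic_head(voxel_mm = 5, seed = 8)
  expect_false(identical(p3$density, p1$density))
  og <- phantom_organs(p1)
  need <- c("soft_tissue", "skin", "skull", "brain", "spinal_cord",
            "salivary_left", "salivary_right", "lens_left", "lens_right")
  expect_true(all(need %in% og$organ))
  expect_error(make_synthetic_head(voxel_mm = 9), "1-5 mm")
})

test_that("brain volume matches the analytic ellipsoid within a voxel shell", {
  vox <- 2.5
  ph <- make_synthetic_head(voxel_mm = vox, seed = 1)
  og <- phantom_organs(ph)
  p <- head_params()
  v_analytic <- 4 / 3 * pi * prod(p$brain_half) / 1000          # cm^3
  # surface-shell bound: area * one voxel
  a <- p$brain_half
  area_cm2 <- 4 * pi * ((a[1]^1.6 * a[2]^1.6 + a[1]^1.6 * a[3]^1.6 +
                         a[2]^1.6 * a[3]^1.6) / 3)^(1 / 1.6) / 100
  shell_cm3 <- area_cm2 * vox / 10
  v_grid <- og$volume_cm3[og$organ == "brain"]
  expect_lt(abs(v_grid - v_analytic), shell_cm3)
})

test_that("left and right organs are mirror images under symmetric anatomy", {
  ph <- make_synthetic_head(voxel_mm = 2.5, seed = 1)
  og <- phantom_organs(ph)
  v <- function(o) og$n_voxel[og$organ == o]
  expect_equal(v("lens_left"), v("lens_right"))
  expect_equal(v("salivary_left"), v("salivary_right"))
  # mirror flip swaps the paired labels and preserves every volume
  m <- mirror_phantom(ph)
  ogm <- phantom_organs(m)
  for (o in og$organ) {
    expect_equal(ogm$n_voxel[ogm$organ == o], v(o))
    expect_equal(ogm$volume_cm3[ogm$organ == o],
                 og$volume_cm3[og$organ == o])
  }
})

test_that("table attachment adds exactly the slab and conserves organ mass", {
  ph <- make_synthetic_head(voxel_mm = 5, seed = 3)
  og0 <- phantom_organs(ph)
  rho <- 0.42; th <- 40
  pht <- attach_table(ph, density = rho, thickness_mm = th)
  ogt <- phantom_organs(pht)
  for (o in setdiff(og0$organ, "air"))   # body organs untouched
    expect_equal(ogt$mass_g[ogt$organ == o], og0$mass_g[og0$organ == o])
  # slab voxel count = X-Z footprint box x thickness
  nz <- which(ph$labels != 0L, arr.ind = TRUE)
  foot <- diff(range(nz[, 1])) + 1
  footz <- diff(range(nz[, 3])) + 1
  tab_id <- max(as.integer(names(pht$label_map)))
  nslab <- sum(pht$labels == tab_id)
  expect_equal(nslab, foot * footz * round(th / 5))
  # slab mass = slab volume x density, exactly
  slab_mass <- sum(pht$density[pht$labels == tab_id]) *
    prod(pht$spacing) / 1000
  expect_equal(slab_mass, nslab * prod(pht$spacing) / 1000 * rho,
               tolerance = 1e-12)
  expect_identical(attach_table(ph, thickness_mm = 0), ph)
})

test_that("phantom IO round trip is lossless", {
  ph <- make_synthetic_head(voxel_mm = 5, seed = 11)
  path <- file.path(tempdir(), "head5")
  write_phantom(ph, path)
  rd <- read_phantom(path)
  expect_identical(rd$labels, ph$labels)
  expect_equal(rd$density, ph$density, tolerance = 1e-6)  # float32 raw
  expect_equal(rd$spacing, ph$spacing)
  expect_equal(rd$origin, ph$origin)
  expect_equal(vapply(rd$label_map, function(x) x$name, character(1)),
               vapply(ph$label_map, function(x) x$name, character(1)))
  # degenerate single-voxel phantom survives the round trip
  one <- voxel_phantom(array(1L, c(1, 1, 1)), c(2, 2, 2), c(0, 0, 0),
                       list("1" = list(name = "w", material = "water")))
  write_phantom(one, file.path(tempdir(), "one"))
  r1 <- read_phantom(file.path(tempdir(), "one"))
  expect_identical(r1$labels, one$labels)
})

test_that("reading a file with an unmapped label names the label", {
  ph <- cube_phantom(n = 4L, voxel_mm = 5)
  path <- file.path(tempdir(), "bad")
  write_phantom(ph, path)
  side <- jsonlite::read_json(paste0(path, ".json"))
  side[["1"]] <- NULL
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_phantom(path), "unmapped label.*1")
})

test_that("voxel phantom invariants are validated", {
  lab <- array(2L, c(2, 2, 2))
  expect_error(
    voxel_phantom(lab, rep(1, 3), rep(0, 3),
                  list("0" = list(name = "air", material = "air"))),
    "missing from label map")
  expect_error(
    voxel_phantom(array(1L, c(2, 2, 2)), rep(1, 3), rep(0, 3),
                  list("1" = list(name = "x", material = "water",
                                  density = -1))),
    "positive density")
})
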