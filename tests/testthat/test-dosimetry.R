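test_that("organ equivalent dose is the mass-weighted mean (hand oracle)", {
  # two voxels, doses 1 and 3, masses 1 g and 3 g -> H_T = 2.5
  lab <- array(0L, c(2, 1, 1)); lab[] <- 1L
  lm <- list("0" = list(name = "air", material = "air"),
             "1" = list(name = "organ", material = "water"))
  den <- array(c(1, 3), c(2, 1, 1))            # 1 cm^3 voxels
  ph <- voxel_phantom(lab, c(10, 10, 10), c(0, 0, 0), lm, density = den)
  grid <- structure(list(dose = array(c(1, 3), c(2, 1, 1)),
                         engine = "test"), class = "dose_grid")
  expect_equal(organ_dose(grid, ph, "organ")$H_T, 2.5)
  # uniform dose -> H_T = dose regardless of the density distribution
  grid$dose[] <- 7
  expect_equal(organ_dose(grid, ph, "organ")$H_T, 7)
  # equal densities -> plain mean
  ph2 <- voxel_phantom(lab, c(10, 10, 10), c(0, 0, 0), lm)
  grid$dose <- array(c(2, 4), c(2, 1, 1))
  expect_equal(organ_dose(grid, ph2, "organ")$H_T, 3)
  expect_error(organ_dose(grid, ph, "nonexistent"), "unknown organ")
})

test_that("effective dose implements the ICRP 103 weighted sum", {
  w <- icrp103_weights()
  expect_equal(sum(w), 1)
  mk <- function(organ, ht, mass = 100)
    data.frame(organ = organ, H_T = ht, w_r = 1, n_voxel = 10,
               mass_g = mass, engine = "test", rel_uncertainty = NA)
  # single organ, w_T = 0.01, H_T = 100 -> E = 1
  e1 <- effective_dose(mk("brain", 100))
  expect_equal(e1$E, 1)
  # all organs at zero -> E = 0
  reps <- do.call(rbind, lapply(
    c("brain", "skin", "skull", "salivary_left", "salivary_right",
      "soft_tissue"), mk, ht = 0))
  expect_equal(effective_dose(reps)$E, 0)
  # full weight set at uniform dose D -> E = D (weight normalization)
  tissues <- setdiff(names(w), "remainder")
  full_map <- c(as.list(tissues), list("rem_a", "rem_b"))
  names(full_map) <- c(tissues, "rem_a", "rem_b")
  full_map[["rem_a"]] <- "remainder"; full_map[["rem_b"]] <- "remainder"
  reps <- do.call(rbind, lapply(names(full_map), mk, ht = 5))
  ed <- effective_dose(reps, tissue_map = full_map, weights = w)
  expect_equal(ed$E, 5)
  expect_error(effective_dose(rbind(mk("brain", 1), mk("brain", 2))),
               "at most once")
  expect_error(effective_dose(mk("gizzard", 1)), "not in the tissue map")
})

test_that("paired salivary glands combine mass-weighted and lenses are
           excluded from E", {
  mk <- function(organ, ht, mass)
    data.frame(organ = organ, H_T = ht, w_r = 1, n_voxel = 10,
               mass_g = mass, engine = "test", rel_uncertainty = NA)
  reps <- rbind(mk("salivary_left", 2, 10), mk("salivary_right", 4, 30),
                mk("lens_left", 1000, 1), mk("lens_right", 1000, 1))
  ed <- effective_dose(reps)
  sal <- ed$terms$H_T[ed$terms$tissue == "salivary_glands"]
  expect_equal(sal, (2 * 10 + 4 * 30) / 40)
  expect_equal(ed$E, 0.01 * sal)   # lens contributes nothing
})

test_that("dose reduction is the complementary ratio and CF-invariant", {
  mk <- function(ht) data.frame(organ = c("brain", "skin"), H_T = ht,
                                mass_g = c(1, 1))
  expect_equal(dose_reduction(mk(c(1, 2)), mk(c(1, 2)))$reduction, c(0, 0))
  r <- dose_reduction(mk(c(0.5, 1)), mk(c(1, 2)), e_filtered = 0.25,
                      e_unfiltered = 0.5)
  expect_equal(r$reduction, c(0.5, 0.5, 0.5))
  expect_error(dose_reduction(mk(c(1, 2)), mk(c(0, 2))), "zero unfiltered")
})

test_that("full-shadow organ reaches the monoenergetic closed-form
           reduction exactly", {
  ph <- probe_phantom(n = 21L, voxel_mm = 10)
  sp <- mono_spectrum(60)
  prot <- scan_protocol(projections = 5, kvp = 100)
  # aperture center far off-axis: the probe at the isocenter stays in the
  # filter shadow for every projection, with normal incidence on the axis
  filt <- roi_filter(0.3, 0.05, aperture_center_cm = c(8, 8))
  base <- primary_kerma_dose(ph, prot, c(0, 0, 0), spectrum = sp)
  f <- primary_kerma_dose(ph, prot, c(0, 0, 0), roi_filter = filt,
                          spectrum = sp)
  red <- dose_reduction(organ_dose_report(f, ph, "probe"),
                        organ_dose_report(base, ph, "probe"))
  gos <- froi_material("gadolinium_oxysulfide")
  want <- 1 - exp(-mixture_mu(gos, 60) * gos$density * 0.03)
  expect_equal(red$reduction, want, tolerance = 1e-12)
})

test_that("theoretical DAP reduction covers its limiting cases", {
  expect_equal(theoretical_reduction(1, 0.2), 0)
  expect_equal(theoretical_reduction(0.5, 1), 0)
  expect_equal(theoretical_reduction(0, 0.2), 0.8)
  expect_equal(theoretical_reduction(0.6, 0.4), 0.24)
  expect_error(theoretical_reduction(1.2, 0.5), "is not TRUE")
})

test_that("absolute dose scaling validates the tube-voltage match", {
  ph <- cube_phantom(n = 4L, voxel_mm = 10)
  prot <- scan_protocol(projections = 1, kvp = 90)
  dg <- primary_kerma_dose(ph, prot, c(0, 0, 0),
                           spectrum = mono_spectrum(50, kvp = 90))
  cf_bad <- calibration_factor(1, 1, 100)
  expect_error(absolute_voxel_dose(dg, cf_bad, prot), "does not match")
  cf1 <- calibration_factor(1, 1, 90)   # CF x I x t = mAs
  out <- absolute_voxel_dose(dg, cf1, prot)
  expect_equal(out$dose, dg$dose * protocol_mAs(prot))
})
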