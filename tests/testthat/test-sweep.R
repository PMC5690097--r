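test_that("sweep emits one row per cell and organ with a consistent
           baseline", {
  ph <- test_head(voxel_mm = 5)
  sw <- run_sweep(ph, thickness_mm = c(0, 0.204), aperture = 0.2,
                  kvp = 90, quick = TRUE)
  organs <- setdiff(vapply(ph$label_map, function(x) x$name, character(1)),
                    "air")
  # cells: baseline (thickness 0) + one filtered; rows = cells x (organs+E)
  expect_equal(nrow(sw), 2 * (length(organs) + 1))
  base <- sw[sw$thickness == 0, ]
  expect_true(all(is.na(base$aperture)))
  expect_equal(base$reduction, rep(0, nrow(base)))
  filt <- sw[sw$thickness > 0, ]
  expect_true(all(filt$reduction > 0))
  expect_true(all(filt$theoretical_reduction > 0 &
                    filt$theoretical_reduction < 1))
})

test_that("a single-cell grid equals the matching pipeline run", {
  ph <- test_head(voxel_mm = 5)
  sw <- run_sweep(ph, thickness_mm = 0, aperture = 0.2, kvp = 90,
                  quick = TRUE)
  prot <- scan_protocol(kvp = 90)
  sp <- generate_spectrum(90, inherent_filtration = prefilter_cbra(),
                          bin_kev = 2)
  dg <- primary_kerma_dose(ph, prot, c(265, 90, 1580), spectrum = sp)
  rep_ <- organ_dose_report(dg, ph)
  for (o in rep_$organ)
    expect_equal(sw$H_T[sw$organ == o], rep_$H_T[rep_$organ == o])
})

test_that("report checks pass on sane sweeps and flag injected
           violations", {
  # synthetic proportional-dose fixture: every filtered dose = f * baseline
  organs <- c("brain", "skin")
  mk <- function(th, ap, f) data.frame(
    thickness = th, aperture = ap, kvp = 100, iso_z = 1580, table = FALSE,
    organ = organs, H_T = c(1, 2) * f, theoretical_reduction = 0,
    reduction = 1 - f)
  sweep <- rbind(mk(0, NA, 1), mk(0.1, 0.2, 0.8), mk(0.2, 0.2, 0.6),
                 mk(0.1, 0.4, 0.9), mk(0.2, 0.4, 0.7))
  rep_ <- run_report(sweep)
  expect_true(rep_$ok)
  # inject a monotonicity violation
  bad <- sweep
  bad$H_T[bad$thickness == 0.2 & bad$aperture == 0.2] <- c(1.5, 3)
  expect_warning(r2 <- run_report(bad), "not monotone")
  expect_false(r2$ok)
  # inject a dominance violation (small aperture above large at 0.1)
  bad2 <- sweep
  bad2$H_T[bad2$thickness == 0.1 & bad2$aperture == 0.2] <- c(1, 1.95)
  bad2 <- rbind(bad2, data.frame(thickness = c(0, 0.1, 0.2, 0.1, 0.2),
                                 aperture = c(NA, 0.2, 0.2, 0.4, 0.4),
                                 kvp = 100, iso_z = 1580, table = FALSE,
                                 organ = "effective_dose",
                                 H_T = c(1, 0.95, 0.6, 0.9, 0.7),
                                 theoretical_reduction = 0,
                                 reduction = NA))
  expect_warning(r3 <- run_report(bad2), "dominance")
  expect_false(r3$ok)
  expect_error(run_report(sweep[, 1:3]), "malformed")
})

test_that("calibration driver runs from configuration and validates input", {
  out <- run_calibration(list(slab_thickness_mm = 40))
  expect_equal(round(out$thickness$per_layer_mean_mm, 3), 0.102)
  expect_equal(nrow(out$density$per_kvp), 5)
  empty <- file.path(tempdir(), "empty.csv")
  write.csv(data.frame(kvp = numeric(), transmission = numeric()), empty,
            row.names = FALSE)
  expect_error(run_calibration(list(transmission_csv = empty)), "empty")
  # config round trip through YAML with JSON output
  cfg <- file.path(tempdir(), "cal.yaml")
  outj <- file.path(tempdir(), "cal.json")
  writeLines(c("slab_thickness_mm: 40", paste0("output_json: ", outj)), cfg)
  out2 <- run_calibration(cfg)
  expect_true(file.exists(outj))
  expect_equal(out2$density$mean_density, out$density$mean_density)
})
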