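test_that("mixture rule reduces to the elemental table", {
  et <- coefficient_table()
  carbon <- froi_material("carbon")
  grid_e <- c(20, 50, 100)
  for (e in grid_e)
    expect_equal(mixture_mu(carbon, e),
                 et$mu_rho[et$element == "C" & et$energy_kev == e])
  # 50/50 two-element mixture is the arithmetic mean of the coefficients
  mix <- material("mix", c(C = 0.5, Al = 0.5), 1.5)
  expect_equal(mixture_mu(mix, 60),
               (element_mu("C", 60) + element_mu("Al", 60)) / 2)
})

test_that("bundled water coefficients agree with the reference compilation", {
  water <- froi_material("water")
  # independently published values (NIST): mu/rho and mu_en/rho of water
  expect_equal(mixture_mu(water, 100), 0.1707, tolerance = 0.01)
  expect_equal(mixture_mu(water, 100, "energy_absorption"), 0.02546,
               tolerance = 0.01)
  expect_equal(mixture_mu(water, 50), 0.2269, tolerance = 0.01)
})

test_that("material invariants are enforced", {
  expect_error(material("m", c(C = 0.5, O = 0.4), 1), "sum to 1")
  expect_error(material("m", c(C = -0.5, O = 1.5), 1), "positive")
  expect_error(material("m", c(Xx = 1), 1), "unknown element")
  expect_error(material("m", c(C = 1), -2), "density")
  expect_error(element_mu("C", 500), "out of table range")
})

test_that("spectra respect the Duane-Hunt limit and harden under filtration", {
  sp <- generate_spectrum(80)
  expect_true(all(sp$weight[sp$energy_kev > 80] == 0))
  expect_true(any(sp$weight > 0))
  hard <- generate_spectrum(80, inherent_filtration = prefilter_al(2.5))
  expect_gt(mean_energy(hard), mean_energy(sp))
  expect_error(generate_spectrum(30), "40-150")
})

test_that("80 kVp spectrum behind 0.3 Cu + 2.6 Al has a realistic mean energy", {
  # literature-anchored band for a tungsten beam of this quality
  sp <- generate_spectrum(80, inherent_filtration = prefilter_cbra())
  expect_gt(mean_energy(sp), 49)
  expect_lt(mean_energy(sp), 57)
})

test_that("attenuate is the Beer-Lambert factor and composes over layers", {
  sp <- generate_spectrum(90, inherent_filtration = prefilter_al(2.5))
  al <- froi_material("aluminium")
  cu <- froi_material("copper")
  zero <- attenuate(sp, filter_stack(al, 0))
  expect_equal(zero$weight, sp$weight)
  ab <- attenuate(attenuate(sp, filter_stack(al, 1)), filter_stack(cu, 0.2))
  stack <- attenuate(sp, filter_stack(list(al, cu), c(1, 0.2)))
  expect_equal(ab$weight, stack$weight)
  # monoenergetic closed form
  mono <- mono_spectrum(60)
  att <- attenuate(mono, filter_stack(al, 1))
  expect_equal(att$weight[60] / mono$weight[60],
               exp(-element_mu("Al", 60) * 2.699 * 0.1))
})

test_that("kerma-weighted transmission behaves physically", {
  sp <- generate_spectrum(80, inherent_filtration = prefilter_al(2.5))
  carbon <- froi_material("carbon")
  expect_equal(kerma_weighted_transmission(sp, filter_stack(carbon, 0)), 1.0)
  tr <- vapply(c(5, 10, 20, 40), function(t)
    kerma_weighted_transmission(sp, filter_stack(carbon, t)), numeric(1))
  expect_true(all(diff(tr) < 0))
  # monoenergetic: equals exp(-mu t) independent of the kerma weighting
  mono <- mono_spectrum(50)
  slab <- filter_stack(carbon, 10)
  want <- exp(-element_mu("C", 50) * 2.267 * 1.0)
  expect_equal(kerma_weighted_transmission(mono, slab), want,
               tolerance = 1e-12)
  expect_equal(kerma_weighted_transmission(mono, slab, "fluence"), want,
               tolerance = 1e-12)
  expect_error(froi_spectrum(80, 1:150, rep(0, 150)), "positive bin")
})

test_that("transmission is normalization-invariant and bounded by the
           monoenergetic extremes", {
  sp <- generate_spectrum(90, inherent_filtration = prefilter_al(2.5))
  slab <- filter_stack(froi_material("carbon"), 20)
  t1 <- kerma_weighted_transmission(sp, slab)
  sp2 <- froi_spectrum(sp$kvp, sp$energy_kev, sp$weight * 37.5)
  expect_equal(kerma_weighted_transmission(sp2, slab), t1)
  pos <- sp$energy_kev[sp$weight > 0]
  mono_tr <- exp(-element_mu("C", pos) * 2.267 * 2.0)
  expect_gte(t1, min(mono_tr))
  expect_lte(t1, max(mono_tr))
})

test_that("a second identical slab transmits more than the first
           (beam hardening)", {
  sp <- generate_spectrum(80, inherent_filtration = prefilter_al(2.5))
  slab <- filter_stack(froi_material("carbon"), 20)
  t1 <- kerma_weighted_transmission(sp, slab)
  t2 <- kerma_weighted_transmission(attenuate(sp, slab), slab)
  expect_gte(t2, t1)
})
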