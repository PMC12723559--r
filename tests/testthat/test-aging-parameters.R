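test_that("interneuron loss reproduces the published 20-year fractions", {
  out <- interneuron_loss(loss_rates(), 20)
  expect_equal(unname(out$loss["sst"]), 0.242, tolerance = 1e-12)
  expect_equal(unname(out$loss["vip"]), 0.176, tolerance = 1e-12)
  # per-year rate times 20, not the rounded 10.3% print
  expect_equal(unname(out$loss["pv"]), 0.104, tolerance = 1e-12)
  expect_equal(unname(out$survival["sst"]), 0.758, tolerance = 1e-12)

  zero <- interneuron_loss(loss_rates(), 0)
  expect_true(all(zero$loss == 0))
  half <- interneuron_loss(loss_rates(), 10)
  expect_equal(unname(half$loss["sst"]), 0.121, tolerance = 1e-12)
  expect_error(interneuron_loss(loss_rates(), -1), "non-negative")
})

test_that("NMDA and connection-probability multipliers decline linearly and clamp", {
  expect_equal(nmda_multiplier(loss_rates(), 20), 0.5)
  expect_equal(nmda_multiplier(loss_rates(), 0), 1)
  expect_equal(nmda_multiplier(loss_rates(), 50), 0)
  expect_equal(spine_connection_multiplier(loss_rates(), 20), 0.8)
  expect_equal(spine_connection_multiplier(loss_rates(), 0), 1)
  expect_equal(spine_connection_multiplier(loss_rates(), 100), 0)
})

test_that("loss is linear in years below the clamp", {
  rates <- loss_rates()
  for (yrs in c(1, 3.5, 8)) {
    a <- interneuron_loss(rates, yrs)$loss
    b <- interneuron_loss(rates, 2 * yrs)$loss
    expect_equal(b, 2 * a, tolerance = 1e-12)
    expect_equal(1 - nmda_multiplier(rates, 2 * yrs),
                 2 * (1 - nmda_multiplier(rates, yrs)), tolerance = 1e-12)
  }
})

test_that("spine-geometry chain reproduces the published derivation", {
  geom <- spine_geometry()
  thin_mid <- thin_fraction_middle_age(geom$thin_fraction_old, 0.20)
  expect_equal(thin_mid, 0.3125)
  expect_equal(thin_fraction_middle_age(0.25, 0), 0.25)
  expect_equal(thin_fraction_middle_age(0.10, 0.50), 0.20)
  expect_error(thin_fraction_middle_age(0.25, 1), "0, 1")

  area <- thin_spine_surface_area(geom, thin_mid)
  expect_equal(area, 2782.57, tolerance = 0.005)

  red <- passive_reduction(geom, area, 0.20)
  expect_equal(red$area_fraction, 0.086, tolerance = 0.005)
  expect_equal(red$reduction, 0.0172, tolerance = 0.005)
  expect_equal(red$passive_multiplier, 1 - red$reduction)
})

test_that("thin-spine area degenerate geometries match closed forms", {
  geom0 <- spine_geometry(n_spines_total = 0)
  expect_equal(thin_spine_surface_area(geom0, 0.3125), 0)

  # base = tip with no end-cap reduces to a cylinder's lateral area
  cyl <- spine_geometry(base_to_tip_ratio = 1)
  r <- cyl$tip_diameter / 2
  per_spine <- thin_spine_surface_area(
    spine_geometry(base_to_tip_ratio = 1, n_spines_total = 1), 1
  ) - pi * r^2
  expect_equal(per_spine, pi * cyl$tip_diameter * cyl$thin_length,
               tolerance = 1e-12)
})

test_that("passive_reduction degenerate cases", {
  geom <- spine_geometry()
  expect_equal(passive_reduction(geom, 0, 0.2)$reduction, 0)
  whole <- geom$total_spine_area + geom$total_dendrite_area
  expect_equal(passive_reduction(geom, whole, 0.20)$reduction, 0.20)
})

test_that("profiles activate exactly the mechanisms their label names", {
  mid <- make_profile("middle_age", 20)
  expect_true(all(unlist(mid[c("sst_survival", "vip_survival", "pv_survival",
                               "nmda_multiplier",
                               "pyr_pyr_connection_multiplier",
                               "passive_multiplier")]) == 1))

  older <- make_profile("older", 20)
  expect_equal(older$sst_survival, 0.758)
  expect_equal(older$nmda_multiplier, 0.5)
  expect_equal(older$pyr_pyr_connection_multiplier, 0.8)
  expect_equal(older$passive_multiplier, 0.9828, tolerance = 0.005)

  nmda <- make_profile("nmda_loss", 20)
  expect_equal(nmda$nmda_multiplier, 0.5)
  expect_true(all(unlist(nmda[c("sst_survival", "vip_survival", "pv_survival",
                                "pyr_pyr_connection_multiplier",
                                "passive_multiplier")]) == 1))

  inhib <- make_profile("inhib_loss", 20)
  expect_equal(inhib$sst_survival, 0.758)
  expect_equal(inhib$nmda_multiplier, 1)
  expect_equal(inhib$pyr_pyr_connection_multiplier, 1)

  spine <- make_profile("spine_loss", 20)
  expect_equal(spine$pyr_pyr_connection_multiplier, 0.8)
  expect_equal(spine$sst_survival, 1)
  expect_equal(spine$nmda_multiplier, 1)

  expect_error(make_profile("young"), "arg")
})

test_that("the older profile is the composition of the single mechanisms", {
  for (yrs in c(5, 20, 35)) {
    older <- make_profile("older", yrs)
    inhib <- make_profile("inhib_loss", yrs)
    nmda <- make_profile("nmda_loss", yrs)
    spine <- make_profile("spine_loss", yrs)
    for (f in c("sst_survival", "vip_survival", "pv_survival",
                "nmda_multiplier", "pyr_pyr_connection_multiplier",
                "passive_multiplier")) {
      expect_equal(older[[f]], inhib[[f]] * nmda[[f]] * spine[[f]],
                   tolerance = 1e-12)
    }
  }
})

test_that("all multipliers stay in [0, 1] for any non-negative age offset", {
  for (yrs in c(0, 7, 20, 60, 150, 1000)) {
    p <- make_profile("older", yrs)
    vals <- unlist(p[c("sst_survival", "vip_survival", "pv_survival",
                       "nmda_multiplier", "pyr_pyr_connection_multiplier",
                       "passive_multiplier")])
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("profiles round-trip through YAML and JSON", {
  p <- make_profile("older", 20)
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_profile(p, f)
    q <- read_profile(f)
    expect_equal(unclass(p), unclass(q)[names(unclass(p))], tolerance = 1e-9)
    unlink(f)
  }
})
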