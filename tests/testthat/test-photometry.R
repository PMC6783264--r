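test_that("power to energy flux follows the printed constants", {
  m <- spectral_measurement(500, 1, "power_nW")
  e <- power_to_energy_flux(m)
  expect_equal(e$stage, "energy_flux_eV_per_s")
  expect_equal(e$values, 6.242e9)                 # 1 nW * 6.242e18 eV/J * 1e-9
  m2 <- spectral_measurement(500, 2, "power_nW")
  expect_equal(power_to_energy_flux(m2)$values, 2 * e$values)
  z <- spectral_measurement(500, 0, "power_nW")
  expect_equal(power_to_energy_flux(z)$values, 0)
  expect_error(power_to_energy_flux(e), "stage")
})

test_that("photon energy matches c*h/lambda and scales as 1/lambda", {
  expect_equal(photon_energy(500), 2.4796836, tolerance = 1e-7)
  expect_equal(photon_energy(1000), photon_energy(500) / 2)
  expect_error(photon_energy(0), "positive")
  expect_error(photon_energy(-5), "positive")
})

test_that("energy to photon flux divides by the photon energy", {
  m <- spectral_measurement(500, 6.242e9, "energy_flux_eV_per_s")
  ph <- energy_to_photon_flux(m)
  expect_equal(ph$stage, "photon_flux_per_s")
  expect_equal(ph$values, 2.517257e9, tolerance = 1e-6)
  z <- spectral_measurement(500, 0, "energy_flux_eV_per_s")
  expect_equal(energy_to_photon_flux(z)$values, 0)
  # equal energy flux at 400 and 800 nm gives photon flux ratio 1:2
  m2 <- spectral_measurement(c(400, 800), c(1e9, 1e9), "energy_flux_eV_per_s")
  v <- energy_to_photon_flux(m2)$values
  expect_equal(v[2] / v[1], 2)
})

test_that("flux density divides by the stimulus area", {
  g <- stimulus_geometry(spot_diameter = 1000)
  expect_equal(g$a_stim, pi * 500^2)              # ~7.854e5 um^2
  m <- spectral_measurement(500, 1e9, "photon_flux_per_s")
  expect_equal(flux_density(m, g)$values, 1e9 / (pi * 500^2))
  expect_equal(flux_density(m, g)$stage, "flux_density_per_s_per_um2")
  # unit area is the identity; doubling the diameter quarters the density
  expect_equal(flux_density(m, stimulus_geometry(area = 1))$values, 1e9)
  g2 <- stimulus_geometry(spot_diameter = 2000)
  expect_equal(flux_density(m, g2)$values, flux_density(m, g)$values / 4)
  expect_error(stimulus_geometry(area = 0), "positive")
})

test_that("effective activation reduces to opsin sensitivity for narrow LEDs", {
  grid <- default_grid()
  flat_opsin <- sensitivity_curve(grid, rep(1, length(grid)))
  led <- synth_led_spectrum(led_model("g", 576, 10, c(571, 581), 10))
  expect_equal(effective_activation(flat_opsin, led)$fraction, 1)

  s_opsin <- template_sensitivity(360)
  # LED entirely outside the opsin grid support
  off_led <- spectral_measurement(c(750, 760), c(1, 1), "power_nW")
  m_opsin <- sensitivity_curve(500:600, rep(1, 101))
  expect_warning(ea <- effective_activation(m_opsin, off_led), "no power")
  expect_equal(ea$fraction, 0)

  # delta-like (1-nm) LED at 400 nm picks out S_opsin(400)
  delta <- spectral_measurement(c(399.6, 400, 400.4), c(0, 5, 0), "power_nW")
  ea2 <- effective_activation(s_opsin, delta)
  expect_equal(ea2$fraction, s_opsin$sensitivity[s_opsin$wavelengths == 400],
               tolerance = 1e-6)

  # fraction never exceeds the opsin maximum over the LED support
  m508 <- template_sensitivity(508)
  uv <- synth_led_spectrum(led_model("UV", 387, 11, c(381.5, 392.5), 1))
  ea3 <- effective_activation(m508, uv)
  sup <- m508$wavelengths >= 381.5 & m508$wavelengths <= 392.5
  expect_lte(ea3$fraction, max(m508$sensitivity[sup]))
})

test_that("photoisomerisation rate has the closed form for flat inputs", {
  grid <- 400:499
  flux <- spectral_measurement(grid, rep(3, 100), "flux_density_per_s_per_um2")
  ones <- sensitivity_curve(grid, rep(1, 100))
  # flat P_E = k with unit sensitivity: R_iso = k * a_collect * N under both
  # weightings (the peak-normalised flat LED spectrum is also 1)
  for (w in c("as_printed", "opsin_only"))
    expect_equal(photoisomerisation_rate(flux, ones, weighting = w),
                 3 * 0.2 * 100)
  z <- spectral_measurement(grid, rep(0, 100), "flux_density_per_s_per_um2")
  expect_equal(photoisomerisation_rate(z, ones), 0)
  expect_error(
    photoisomerisation_rate(
      spectral_measurement(300:399, rep(1, 100), "flux_density_per_s_per_um2"),
      ones), "grids differ")
})

test_that("counts-to-rate chain is linear in counts", {
  grid <- default_grid()
  cal <- spectrometer_calibration(c(300, 720), c(0.002, 0.002))
  opsin <- template_sensitivity(508)
  geom <- stimulus_geometry(1000)
  base_counts <- exp(-(grid - 576)^2 / 50) * 1e4
  rate_for <- function(k) {
    m <- spectral_measurement(grid, k * base_counts, "counts")
    flux <- power_to_flux_density(counts_to_power(m, cal), geom)
    photoisomerisation_rate(flux, opsin)
  }
  r1 <- rate_for(1)
  expect_gt(r1, 0)
  for (k in c(0.5, 2, 7))
    expect_equal(rate_for(k), k * r1, tolerance = 1e-12)
})

test_that("activation matrix reproduces the mouse cross-activation pattern", {
  leds <- mouse_leds()
  cones <- species_preset("mouse")$cone_opsins
  for (w in c("as_printed", "opsin_only")) {
    am <- build_activation_matrix(leds, cones, weighting = w)
    r <- am$r_iso
    # green drives M but essentially not S; UV drives S more than M
    expect_lt(r["green", "S"], 1e-6 * r["green", "M"])
    expect_gt(r["UV", "S"], r["UV", "M"])
    expect_gt(r["UV", "M"], 0)     # beta-band cross-activation is real
    expect_true(all(am$effective_activation >= 0 &
                      am$effective_activation <= 1))
  }

  # composition: a 1x1 matrix equals the direct rate computation
  am1 <- build_activation_matrix(leds["UV"], cones["S"])
  flux <- power_to_flux_density(
    spectral_measurement(cones$S$wavelengths,
                         stats::approx(leds$UV$wavelengths, leds$UV$values,
                                       cones$S$wavelengths, rule = 1)$y,
                         "power_nW"),
    stimulus_geometry(1000))
  expect_equal(am1$r_iso[1, 1], photoisomerisation_rate(flux, cones$S))

  # permuting the LED list permutes rows identically
  am_a <- build_activation_matrix(leds, cones)
  am_b <- build_activation_matrix(rev(leds), cones)
  expect_equal(am_b$r_iso[rownames(am_a$r_iso), ], am_a$r_iso)
})

test_that("cross-activation is the published ratio and is scale invariant", {
  am <- mouse_riso_matrix()
  ca <- cross_activation(am, "M", reference_led = "green", cross_led = "UV")
  expect_equal(round(ca$s_cross_act, 3), 0.195)
  expect_equal(ca$s_cross_act, 3.8 / 19.5)

  # identity and zero cases
  expect_equal(cross_activation(am, "M", "green", "green")$s_cross_act, 1)
  expect_equal(cross_activation(am, "S", "UV", "green")$s_cross_act, 0)
  # scale invariance
  am2 <- activation_matrix(am$r_iso * 7.3)
  expect_equal(cross_activation(am2, "M", "green", "UV")$s_cross_act,
               ca$s_cross_act)
  # zero reference activation is an error
  expect_error(cross_activation(am, "S", "green", "UV"), "zero")
})
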