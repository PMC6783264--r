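test_that("sigmoid intensity fit recovers generating parameters within 1%", {
  px <- seq(0, 254, by = 2)
  truth <- c(k0 = 0, k1 = 10, k2 = 127, k3 = 30)
  y <- sigmoid4(px, truth["k0"], truth["k1"], truth["k2"], truth["k3"])
  f <- fit_intensity_curve(intensity_series(px, y))
  expect_equal(f$k1, unname(truth["k1"]), tolerance = 0.01)
  expect_equal(f$k2, unname(truth["k2"]), tolerance = 0.01)
  expect_equal(f$k3, unname(truth["k3"]), tolerance = 0.01)
  expect_lt(f$residual, 1e-6 * truth["k1"])
})

test_that("degenerate intensity series are handled", {
  px <- seq(0, 254, by = 2)
  # perfectly linear data: near-linear mid-segment, huge K3, warning
  expect_warning(f <- fit_intensity_curve(intensity_series(px, px / 25.4)),
                 "near-linear")
  expect_gt(f$k3, 2 * diff(range(px)))
  # monotone-decreasing data rejected
  expect_error(fit_intensity_curve(intensity_series(px, rev(px) + 1)),
               "decreases")
  # too few points
  expect_error(fit_intensity_curve(intensity_series(c(0, 50, 100, 255),
                                                    c(0, 1, 2, 3))),
               "8 points")
})

test_that("identity intensity curves produce the identity LUT", {
  ser <- intensity_series(0:255, 0:255)
  lut <- build_lut(ser)
  expect_equal(lut$entries, 0:255)
  expect_equal(lut_apply(lut, c(0, 100, 255)), c(0, 100, 255))
})

test_that("LUT linearises power-law intensity curves", {
  # gamma-style curve: intensity proportional to (v/255)^2.2
  curve <- function(v, g = 2.2) (v / 255)^g
  lut <- build_lut(intensity_series(0:255, curve(0:255)))
  expect_true(all(diff(lut$entries) >= 0))
  expect_true(all(lut$entries >= 0 & lut$entries <= 255))
  achieved <- curve(lut_apply(lut, 0:255))
  target <- (0:255) / 255
  expect_lt(max(abs(achieved - target)), 0.01)      # < 1% of range

  # composed response is linear across exponents 1..3
  for (g in c(1, 1.5, 2.2, 3)) {
    lg <- build_lut(intensity_series(0:255, curve(0:255, g)))
    expect_gt(stats::cor(curve(lut_apply(lg, 0:255), g), target), 0.999)
  }
})

test_that("LUT inversion from the fitted sigmoid matches the fit", {
  px <- seq(0, 254, by = 2)
  y <- sigmoid4(px, 0.2, 10, 127, 30)
  f <- fit_intensity_curve(intensity_series(px, y))
  lut <- build_lut(f)
  expect_true(all(diff(lut$entries) >= 0))
  expect_equal(lut$entries[1], 0L)
  expect_equal(lut$entries[256], 255L)
  achieved <- sigmoid4(lut$entries, 0.2, 10, 127, 30)
  f0 <- sigmoid4(0, 0.2, 10, 127, 30)
  f255 <- sigmoid4(255, 0.2, 10, 127, 30)
  target <- f0 + (0:255) / 255 * (f255 - f0)
  # within the 8-bit drive quantisation
  expect_lt(max(abs(achieved - target)) / (f255 - f0), 0.01)
})

test_that("non-invertible curves are rejected", {
  expect_error(build_lut(intensity_series(0:255, rep(1, 256))),
               "constant|not invertible")
  wig <- c(seq(0, 10, length.out = 128), seq(9.9, 20, length.out = 128))
  expect_error(build_lut(intensity_series(0:255, wig)), "monotone")
})

test_that("LUT files round-trip", {
  lut <- build_lut(intensity_series(0:255, (0:255)^2))
  p <- tempfile(fileext = ".lut")
  write_lut(lut, p)
  back <- read_lut(p)
  expect_equal(back$entries, lut$entries)
})

test_that("dichromatic silent substitution scales the counterphase stimulus", {
  expect_equal(silent_substitution_dichromatic(1, 1, 0.195), 0.805)
  expect_equal(silent_substitution_dichromatic(1, 0, 0.7), 1)   # no UV
  expect_equal(silent_substitution_dichromatic(1, 1, 0), 1)     # no cross-talk
  ca <- cross_activation(mouse_riso_matrix(), "M", "green", "UV")
  expect_equal(silent_substitution_dichromatic(1, 1, ca), 1 - 3.8 / 19.5)
})

test_that("general substitution solve isolates opsins", {
  # decoupled channels: weights are target over the diagonal
  d <- activation_matrix(rbind(A = c(x = 4, y = 0), B = c(x = 0, y = 5)))
  s <- substitution_solve(d, c(x = 2, y = 1), bounds = c(-1, 1))
  expect_equal(unname(s$weights), c(2 / 4, 1 / 5))
  expect_equal(max(abs(s$residual)), 0)

  # mouse 2x2: M-only modulation needs no UV
  am <- mouse_riso_matrix()
  sm <- substitution_solve(am, c(S = 0, M = 1), bounds = c(-1, 1))
  expect_equal(unname(sm$weights["UV"]), 0)
  expect_equal(unname(sm$weights["green"]), 1 / 19.5e3)

  # S-only modulation: green runs counterphase at the cross-activation ratio
  ss <- substitution_solve(am, c(S = 1, M = 0), bounds = c(-1, 1))
  expect_lt(ss$weights["green"], 0)
  expect_equal(unname(ss$weights["green"] / ss$weights["UV"]), -3.8 / 19.5,
               tolerance = 1e-9)
  # residual modulation of the non-target opsin is numerically zero
  expect_lt(abs(ss$residual["M"]),
            1e-9 * abs(sum(am$r_iso[, "S"] * ss$weights)))

  # singular matrix with inconsistent target
  sing <- activation_matrix(rbind(A = c(x = 1, y = 1), B = c(x = 2, y = 2)))
  expect_error(substitution_solve(sing, c(x = 1, y = 0)), "unsatisfiable")

  # out-of-gamut weights are flagged, not clipped
  big <- substitution_solve(d, c(x = 40, y = 0), bounds = c(-1, 1))
  expect_false(big$feasible)
  expect_equal(big$out_of_gamut, "A")
})

test_that("solver reduces to the dichromatic rule for zero off-diagonals", {
  # green does not touch S at all: solving for pure S modulation must give
  # the counterphase green/UV ratio -s_cross_act of the scalar rule
  am <- mouse_riso_matrix()
  ca <- cross_activation(am, "M", "green", "UV")$s_cross_act
  ss <- substitution_solve(am, c(S = 1, M = 0))
  expect_equal(unname(ss$weights["green"] / ss$weights["UV"]), -ca)
})
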