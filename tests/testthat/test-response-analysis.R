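test_that("dR/R is zero for proportional channels and steps correctly", {
  t <- seq(0, 10, by = 0.01)
  fd <- 2 + sin(t)
  r1 <- fret_ratio(t, fd, fd)
  expect_true(all(abs(r1$dr_over_r) < 1e-12, na.rm = TRUE))
  r2 <- fret_ratio(t, 2 * fd, fd)
  expect_true(all(abs(r2$dr_over_r) < 1e-12, na.rm = TRUE))
  expect_equal(r2$sample_rate_out, 500)
  expect_equal(diff(r2$time)[1], 1 / 500)

  # acceptor step from fd to 1.5 fd at t = 5 steps dR/R from 0 to 0.5
  fa <- ifelse(t < 5, fd, 1.5 * fd)
  r3 <- fret_ratio(t, fa, fd, baseline = c(0, 4))
  expect_equal(r3$dr_over_r[r3$time < 4.9], rep(0, sum(r3$time < 4.9)),
               tolerance = 1e-12)
  expect_equal(mean(r3$dr_over_r[r3$time > 5.1], na.rm = TRUE), 0.5,
               tolerance = 1e-6)

  expect_error(fret_ratio(t, fd, fd - 2), "non-positive")
})

test_that("detrending z-normalises the baseline and removes slow drift", {
  fs <- 100
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  set.seed(5)
  x <- stats::rnorm(length(t))
  z <- znorm_detrend(x, fs)
  in_base <- t >= 1 & t <= 6
  expect_equal(mean(z[in_base]), 0, tolerance = 1e-9)
  expect_equal(stats::sd(z[in_base]), 1, tolerance = 0.01)

  # a 0.01 Hz drift under the 0.1 Hz cutoff is attenuated > 10x relative
  # to a fast in-band component (amplitude ratio 10:1 before detrending)
  t2 <- seq(0, 400 - 1 / fs, by = 1 / fs)
  x2 <- 10 * sin(2 * pi * 0.01 * t2) + sin(2 * pi * 2 * t2)
  z2 <- znorm_detrend(x2, fs)
  amp <- function(y, f) {
    fit <- stats::lm(y ~ sin(2 * pi * f * t2) + cos(2 * pi * f * t2))
    sqrt(sum(stats::coef(fit)[2:3]^2))
  }
  ratio_after <- amp(z2, 0.01) / amp(z2, 2)
  expect_lt(ratio_after, 10 / 10)

  expect_error(znorm_detrend(rep(1, 2000), fs), "constant")
})

test_that("trial alignment reduces to reshaping for exact markers", {
  fs <- 500
  n_rep <- 4
  trial_t <- 2
  x <- rep(sin(2 * pi * seq(0, trial_t - 1 / fs, by = 1 / fs)), n_rep)
  markers <- (0:(n_rep - 1)) * trial_t
  tm <- align_trials(x, fs, markers, trial_duration = trial_t)
  expect_equal(dim(tm$c), c(trial_t * fs, n_rep))
  expect_equal(tm$c, matrix(x, trial_t * fs, n_rep), tolerance = 1e-9)

  # a one-line ROI offset shifts each trial by exactly that amount
  tm1 <- align_trials(x, fs, markers, trial_duration = trial_t,
                      line_index = 1, scan_line_period = 2)
  shift <- round(2e-3 * fs)
  expect_equal(tm1$c[1:100, 1], x[(1 + shift):(100 + shift)],
               tolerance = 1e-9)

  expect_error(align_trials(x, fs, markers, trial_duration = 3),
               "shorter than the trial window")
  expect_error(align_trials(x, fs, 1), "2 markers")
})

test_that("aligned synthetic sine trials agree in phase to under 2 ms", {
  fs <- 500
  f0 <- 1
  t_all <- seq(0, 12 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * f0 * t_all)
  markers <- c(0, 4, 8)
  tm <- align_trials(x, fs, markers, trial_duration = 4)
  t_rel <- (seq_len(nrow(tm$c)) - 1) / fs
  phases <- apply(tm$c, 2, function(y) {
    fit <- stats::lm(y ~ sin(2 * pi * f0 * t_rel) + cos(2 * pi * f0 * t_rel))
    atan2(stats::coef(fit)[3], stats::coef(fit)[2])
  })
  phase_sd_ms <- stats::sd(phases) / (2 * pi * f0) * 1000
  expect_lt(phase_sd_ms, 2)
})

test_that("quality index behaves like a repeatability SNR", {
  # identical non-constant repetitions give Qi = 1
  sig <- sin(2 * pi * seq(0, 1, length.out = 100))
  q1 <- quality_index(trial_matrix(matrix(sig, 100, 5), 100))
  expect_equal(q1$qi, 1)
  expect_true(q1$passes)

  # pure i.i.d. noise: Qi ~ 1/R
  set.seed(101)
  qn <- quality_index(trial_matrix(matrix(stats::rnorm(5000 * 10), 5000, 10),
                                   500))
  expect_lt(abs(qn$qi - 0.1), 0.02)
  expect_false(qn$passes)

  # mixed case at sigma_s = sigma_n, R = 4: expectation (1 + 1/4) / 2
  set.seed(102)
  s <- stats::rnorm(20000)
  cm <- matrix(s, 20000, 4) + matrix(stats::rnorm(20000 * 4), 20000, 4)
  qm <- quality_index(trial_matrix(cm, 500))
  expect_equal(qm$qi, 0.625, tolerance = 0.02)

  # affine invariance
  qa <- quality_index(trial_matrix(3.2 * cm - 7, 500))
  expect_equal(qa$qi, qm$qi, tolerance = 1e-12)

  expect_error(quality_index(trial_matrix(matrix(1, 10, 3), 10)),
               "constant")
})

test_that("spectral contrast has the Michelson limit behaviour", {
  fs <- 500
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  mk <- function(a) trial_matrix(matrix(a * sin(2 * pi * t), length(t), 3),
                                 fs)
  # equal responses: SC = 0
  expect_equal(spectral_contrast(mk(1), mk(1))$sc, 0)
  # UV-only response: SC = -1; green-only: +1
  expect_equal(spectral_contrast(mk(0), mk(1))$sc, -1)
  expect_equal(spectral_contrast(mk(1), mk(0))$sc, 1)
  # 2x green amplitude: power ratio 4:1, SC = 0.6
  sc <- spectral_contrast(mk(2), mk(1))
  expect_equal(sc$sc, 0.6)
  expect_equal(sc$p_g / sc$p_b, 4, tolerance = 1e-9)
  # amplitude convention changes magnitude, not sign
  expect_equal(spectral_contrast(mk(2), mk(1), type = "amplitude")$sc, 1 / 3)

  # antisymmetry under swapping the inputs
  expect_equal(spectral_contrast(mk(1.3), mk(0.4))$sc,
               -spectral_contrast(mk(0.4), mk(1.3))$sc)

  expect_error(spectral_contrast(mk(0), mk(0)), "zero power")
  bad <- trial_matrix(matrix(sin(2 * pi * t[1:1900]), 1900, 3), fs)
  expect_error(spectral_contrast(bad, bad), "integer number of cycles")
})

test_that("synthetic trials hit their design targets", {
  # zero noise: Qi = 1 and SC is exact
  st <- synth_trials(0.5, qi_target = 1, R = 3, seed = 7)
  expect_equal(quality_index(st$green_trials)$qi, 1, tolerance = 1e-9)
  expect_equal(spectral_contrast(st$green_trials, st$uv_trials)$sc, 0.5,
               tolerance = 1e-9)

  # determinism under a fixed seed
  a <- synth_trials(0.2, 0.6, R = 3, seed = 42)
  b <- synth_trials(0.2, 0.6, R = 3, seed = 42)
  expect_identical(a$green_trials$c, b$green_trials$c)

  # noise levels produce roughly the requested Qi
  set.seed(1)
  qis <- replicate(10, {
    st <- synth_trials(0, qi_target = 0.6, R = 4,
                       seed = sample.int(1e6, 1))
    quality_index(st$green_trials)$qi
  })
  expect_equal(mean(qis), 0.6, tolerance = 0.05)

  expect_error(synth_trials(2, 0.5), "sc_true")
  expect_error(synth_trials(0, 1.5), "infeasible")
  expect_error(synth_trials(0, 0.2, R = 3), "exceed 1/R")
})

test_that("SC recovery stays under 0.1 across contrast and quality levels", {
  errs <- c()
  for (sct in c(-1, -0.5, 0, 0.5, 1)) {
    for (qt in c(0.4, 0.8)) {
      st <- synth_trials(sct, qt, R = 3, T_dur = 4,
                         seed = 1000 + round(100 * sct) + round(10 * qt))
      sc <- spectral_contrast(st$green_trials, st$uv_trials)$sc
      expect_true(sc >= -1 && sc <= 1)
      errs <- c(errs, abs(sc - sct))
    }
  }
  expect_lt(mean(errs), 0.1)
})
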