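test_that("harmonic evaluator reproduces hand-computed values", {
  w <- pi / 12
  expect_equal(wave_harmonic(0, A = 1, gamma = 0, omega = w), 1.0)
  expect_equal(wave_harmonic(6, A = 1, gamma = 0, omega = w), 0.0,
               tolerance = 1e-12)
  expect_equal(wave_harmonic(12, A = 2, gamma = 0.1, omega = w, y = 0.5),
               2 * exp(0.6) * cos(pi) + 0.5)
})

test_that("square evaluator reproduces hand-computed values", {
  w <- pi / 12
  expect_equal(wave_square(0, A = 1, gamma = 0, omega = w), 0.0)
  expect_equal(wave_square(6, A = 1, gamma = 0, omega = w),
               sin(pi / 2) + 0.25 * sin(3 * pi / 2))
  # zero amplitude collapses to the baseline for any other parameters
  expect_equal(wave_square(7.7, A = 0, gamma = 0.3, omega = w, phi = 2,
                           y = 3.2), 3.2)
})

test_that("cycloid evaluator reproduces hand-computed values", {
  w <- pi / 12
  expect_equal(wave_cycloid(0, A = 1, gamma = 0, omega = w), 0.5)
  expect_equal(wave_cycloid(12, A = 1, gamma = 0, omega = w), -1.5)
  expect_equal(wave_cycloid(7.3, A = 0, omega = w, y = -1), -1.0)
})

test_that("transient evaluator gates a periodic Gaussian impulse", {
  w <- pi / 12
  expect_equal(wave_transient(6, A = 2, omega = w, p_tau = 6, sigma = 1,
                              y = 1), 3.0)
  expect_equal(wave_transient(5, A = 2, omega = w, p_tau = 6, sigma = 1,
                              y = 1), 1.0)
  expect_equal(wave_transient(8, A = 2, omega = w, p_tau = 6, sigma = 1,
                              y = 1), 2 * exp(-2) + 1)
  # t = 30 is congruent to t = 6 modulo the 24 h period
  expect_equal(wave_transient(30, A = 2, omega = w, p_tau = 6, sigma = 1,
                              y = 1), 3.0)
})

test_that("each evaluator matches its independent arithmetic oracle", {
  set.seed(42)
  for (kind in waveform_kinds()) {
    for (i in 1:25) {
      p <- draw_oracle_params(kind)
      t <- runif(5, 0, 48)
      expect_equal(wave_eval(kind, t, p), oracle_eval(kind, t, p),
                   tolerance = 1e-12)
    }
  }
})

test_that("waveforms with a flat envelope are periodic and collapse at A = 0", {
  set.seed(7)
  for (kind in waveform_kinds()) {
    for (i in 1:50) {
      p <- draw_oracle_params(kind, gamma_zero = TRUE)
      t <- runif(4, 0, 48)
      period <- 2 * pi / p$omega
      expect_equal(wave_eval(kind, t + period, p), wave_eval(kind, t, p),
                   tolerance = 1e-9)
      p0 <- p
      p0$A <- 0
      expect_identical(wave_eval(kind, t, p0), rep(p$y, length(t)))
    }
  }
})

test_that("the amplitude envelope factorizes out of the oscillatory families", {
  set.seed(11)
  for (kind in c("harmonic", "square", "cycloid")) {
    for (i in 1:30) {
      p <- draw_oracle_params(kind)
      p_flat <- p
      p_flat$gamma <- 0
      t <- runif(4, 0, 48)
      lhs <- wave_eval(kind, t, p) - p$y
      rhs <- exp(p$gamma * t / 2) * (wave_eval(kind, t, p_flat) - p$y)
      expect_equal(lhs, rhs, tolerance = 1e-9)
    }
  }
})

test_that("the pseudo-square wave is flatter-crested than a pure sinusoid", {
  t <- seq(0, 24, length.out = 4096)
  w <- 2 * pi / 24
  crest <- function(x) max(abs(x)) / sqrt(mean(x^2))
  sq <- wave_square(t, A = 1, gamma = 0, omega = w)
  si <- sin(w * t)
  expect_lt(crest(sq), crest(si))
})

test_that("invalid parameters are rejected with the offending symbol named", {
  expect_error(wave_harmonic(1, A = NaN, omega = 1), "`A`")
  expect_error(wave_cycloid(1, A = 1, omega = 1, y = Inf), "`y`")
  expect_error(wave_harmonic(1, A = 1, omega = -1), "`omega`")
  expect_error(wave_transient(1, A = 1, omega = 1, sigma = 0), "`sigma`")
  expect_error(wave_transient(1, A = 1, omega = 1, p_tau = 10, sigma = 1),
               "p_tau")
  expect_error(wave_harmonic(1, A = -1, omega = 1), "`A`")
})
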