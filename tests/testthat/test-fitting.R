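test_that("a noiseless harmonic series is recovered almost exactly", {
  p <- list(A = 2, gamma = 0, omega = 2 * pi / 24, phi = pi / 4, y = 1)
  df <- make_series("harmonic", p)
  fit <- fit_waveform(df, "harmonic")
  expect_true(fit$converged)
  expect_lt(fit$ssr, 1e-10)
  expect_equal(fit$par[["A"]], 2, tolerance = 1e-3)
  expect_equal(2 * pi / fit$par[["omega"]], 24, tolerance = 1e-3)
  expect_equal(fit$par[["phi"]], pi / 4, tolerance = 1e-3)
  expect_equal(fit$par[["y"]], 1, tolerance = 1e-3)
})

test_that("a constant series yields a flat zero-amplitude fit", {
  df <- data.frame(time = seq(0, 46, by = 2), value = 5.0)
  fit <- fit_waveform(df, "harmonic")
  expect_true(fit$converged)
  expect_equal(fit$par[["A"]], 0)
  expect_equal(fit$par[["y"]], 5.0)
  expect_equal(fit$rmse, 0)
  expect_true("constant_input" %in% fit$flags)
})

test_that("a noiseless transient recovers its impulse position", {
  p <- list(A = 3, y = 0, omega = 2 * pi / 24, p_tau = 8, sigma = 1.5)
  df <- make_series("transient", p, interval = 1, replicates = 1)
  fit <- fit_waveform(df, "transient")
  expect_true(fit$converged)
  expect_lt(abs(fit$par[["p_tau"]] - 8), 0.5)
  expect_equal(fit$par[["A"]], 3, tolerance = 0.05)
})

test_that("fit_waveforms returns four finite fits in canonical order", {
  set.seed(3)
  p <- list(A = 2, gamma = 0, omega = 2 * pi / 24, phi = 1, y = 0)
  df <- make_series("harmonic", p, noise_sd = 0.2)
  fits <- fit_waveforms(df)
  expect_identical(fits$kind, waveform_kinds())
  expect_true(all(is.finite(fits$ssr)))
})

test_that("noiseless square and cycloid series are won by their own family", {
  for (kind in c("square", "cycloid")) {
    p <- list(A = 2, gamma = 0, omega = 2 * pi / 24, phi = 0.7, y = 0.3)
    df <- make_series(kind, p)
    fits <- fit_waveforms(df)
    expect_identical(fits$kind[which.min(fits$ssr)], kind)
    expect_identical(select_best(fits)$kind, kind)
  }
})

fake_fit <- function(kind, ssr, converged = TRUE) {
  structure(list(kind = kind, ssr = ssr, converged = converged),
            class = "waveform_fit")
}

test_that("select_best takes the minimal SSR with the fixed-order tiebreak", {
  fits <- list(fake_fit("harmonic", 4), fake_fit("square", 2),
               fake_fit("cycloid", 3), fake_fit("transient", 5))
  expect_identical(select_best(fits)$kind, "square")
  # exact tie resolves to the earlier family in canonical order
  tie <- list(fake_fit("harmonic", 2), fake_fit("square", 2),
              fake_fit("cycloid", 3), fake_fit("transient", 5))
  expect_identical(select_best(tie)$kind, "harmonic")
  # a single converged fit wins regardless of the SSR of failed ones
  one <- list(fake_fit("harmonic", 1, converged = FALSE),
              fake_fit("cycloid", 9))
  expect_identical(select_best(one)$kind, "cycloid")
})

test_that("replicates enter the fit as individual observations", {
  set.seed(5)
  p <- list(A = 2, gamma = 0.02, omega = 2 * pi / 24, phi = 1, y = 0)
  df <- make_series("harmonic", p, noise_sd = 0.1)
  flat <- df[c("time", "value")]
  f1 <- fit_waveform(df, "harmonic")
  f2 <- fit_waveform(flat, "harmonic")
  expect_equal(f1$par, f2$par)
  expect_equal(f1$ssr, f2$ssr)
})

test_that("a converged fit is a local minimum of the SSR surface", {
  set.seed(9)
  p <- list(A = 2, gamma = 0, omega = 2 * pi / 24, phi = 2, y = 0.5)
  df <- make_series("harmonic", p, noise_sd = 0.1)
  control <- rhythm_control()
  fit <- fit_waveform(df, "harmonic", control)
  b <- rhythmfit:::fit_bounds("harmonic", df$time, control)
  for (nm in names(fit$par)) {
    for (mult in c(0.99, 1.01)) {
      par2 <- fit$par
      par2[nm] <- if (par2[nm] == 0) (mult - 1) * 0.01 else par2[nm] * mult
      if (par2[nm] < b$lower[nm] || par2[nm] > b$upper[nm]) next
      ssr2 <- sum((df$value -
                     rhythmfit:::model_predict("harmonic", par2, df$time))^2)
      expect_gte(ssr2, fit$ssr * (1 - 1e-9))
    }
  }
})

test_that("series shorter than the parameter count are rejected", {
  df <- data.frame(time = c(0, 6, 12, 18), value = c(1, 2, 1, 0))
  expect_error(suppressWarnings(fit_waveform(df, "harmonic")),
               "at least 5")
})
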