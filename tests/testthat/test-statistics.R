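test_that("zero-amplitude F-statistic follows the lack-of-fit arithmetic", {
  # no amplitude improvement
  eq <- ftest_zero_amplitude(ssr0 = 2, ssr1 = 2, n_obs = 10, n_params = 5)
  expect_equal(eq$f_stat, 0)
  expect_equal(eq$f_p, 1)
  # worked example: F = ((10 - 2) / 4) / (2 / 3) = 3 on (4, 3) df
  wk <- ftest_zero_amplitude(ssr0 = 10, ssr1 = 2, n_obs = 8, n_params = 5)
  expect_equal(wk$f_stat, 3.0)
  expect_equal(wk$f_p, oracle_f_tail(3.0, 4, 3), tolerance = 1e-12)
  # a better-fitting null is clamped, never negative
  cl <- ftest_zero_amplitude(ssr0 = 1, ssr1 = 2, n_obs = 10, n_params = 5)
  expect_equal(cl$f_stat, 0)
})

test_that("perfect fits and short series are handled explicitly", {
  pf <- ftest_zero_amplitude(ssr0 = 5, ssr1 = 0, n_obs = 10, n_params = 5)
  expect_true(pf$perfect_fit)
  expect_equal(pf$f_p, 0)
  flat <- ftest_zero_amplitude(ssr0 = 0, ssr1 = 0, n_obs = 10, n_params = 5)
  expect_equal(flat$f_p, 1)
  expect_error(ftest_zero_amplitude(1, 1, n_obs = 5, n_params = 5), "n_obs")
})

test_that("the F-statistic is monotone decreasing in the full-model SSR", {
  ssr1 <- seq(0.5, 9.5, by = 0.5)
  f <- vapply(ssr1, function(s)
    ftest_zero_amplitude(10, s, n_obs = 20, n_params = 5)$f_stat, numeric(1))
  expect_true(all(diff(f) <= 0))
})

test_that("Kendall agreement matches hand-enumerated concordance", {
  expect_equal(kendall_agreement(c(1, 5, 9), c(2, 3, 8))$tau, 1)
  expect_equal(kendall_agreement(c(1, 2, 3), c(3, 2, 1))$tau, -1)
  ex <- kendall_agreement(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(ex$tau, 4 / 6, tolerance = 1e-12)
  deg <- kendall_agreement(c(2, 2, 2), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_equal(deg$tau, 0)
  expect_equal(deg$tau_p, 1)
})

test_that("Kendall tau equals brute-force pair counting on tied data", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- sample(1:6, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_agreement(x, y)$tau, oracle_kendall_tau(x, y),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces the step-up procedure", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("BH adjustment is monotone, clipped, and permutation-consistent", {
  set.seed(33)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    q <- bh_adjust(p)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm])[order(perm)], q, tolerance = 1e-12)
  }
})

test_that("regulation classes follow the amplitude-change coefficient", {
  expect_identical(classify_regulation(0.005, "harmonic", 0.01), "stable")
  expect_identical(classify_regulation(-0.05, "square", 0.01), "damped")
  expect_identical(classify_regulation(0.05, "cycloid", 0.01), "forced")
  expect_identical(classify_regulation(0.5, "transient", 0.01),
                   "not_applicable")
  expect_identical(
    classify_regulation(c(-0.05, 0, 0.05), c("harmonic", "harmonic",
                                             "transient")),
    c("damped", "stable", "not_applicable"))
  expect_error(classify_regulation(0, "harmonic", threshold = 0))
})
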