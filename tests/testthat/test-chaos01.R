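test_that("translation components are the printed cumulative sums", {
  z <- translation_components(rep(0, 5), 1.2)
  expect_equal(z$p, rep(0, 5))
  expect_equal(z$q, rep(0, 5))
  one <- translation_components(1, 0.7)
  expect_equal(one$p, cos(0.7))
  expect_equal(one$q, sin(0.7))
  # phi == 1: partial sums of cos(jc) have the Dirichlet closed form
  c0 <- 1.1
  tc <- translation_components(rep(1, 50), c0)
  n <- 1:50
  closed <- sin(n * c0 / 2) * cos((n + 1) * c0 / 2) / sin(c0 / 2)
  expect_equal(tc$p, closed, tolerance = 1e-12)
})

test_that("mean-square displacement matches a brute-force double loop", {
  phi <- c(0.3, -1.2, 2.5, 0.7, -0.4)
  tc <- translation_components(phi, 0.9)
  for (n in 1:2) {
    expect_equal(mean_square_displacement(tc$p, tc$q, n),
                 msd_bruteforce(tc$p, tc$q, n), tolerance = 1e-12)
    expect_gte(mean_square_displacement(tc$p, tc$q, n), 0)
  }
  expect_equal(mean_square_displacement(rep(0, 5), rep(0, 5), 2), 0)
  expect_error(mean_square_displacement(tc$p, tc$q, 5), "smaller")
})

test_that("the modified MSD applies the mean correction as printed", {
  expect_equal(modified_msd(2.5, 0, 3, 1.1), 2.5)
  expect_equal(modified_msd(2.5, 1.3, 0, 1.1), 2.5)  # 1 - cos(0) = 0
  phi <- c(0.3, -1.2, 2.5, 0.7, -0.4)
  tc <- translation_components(phi, 0.9)
  for (n in 1:2)
    expect_equal(
      modified_msd(mean_square_displacement(tc$p, tc$q, n), mean(phi), n, 0.9),
      msd_bruteforce(tc$p, tc$q, n) -
        mean(phi)^2 * (1 - cos(n * 0.9)) / (1 - cos(0.9)),
      tolerance = 1e-12)
  expect_error(modified_msd(1, 1, 1, 0), "cos")
})

test_that("K_c follows the correlation conventions", {
  # zero signal: displacement vector has exactly zero variance, and the
  # declared convention applies
  expect_identical(kc_statistic(rep(0, 200), 1.2), 0)
  # every K_c lies in [-1, 1] on an arbitrary signal
  set.seed(4)
  phi <- rnorm(300)
  ks <- vapply(c(0.8, 1.2, 2.0), function(cc) kc_statistic(phi, cc),
               numeric(1))
  expect_true(all(ks >= -1 & ks <= 1))
})

test_that("the FFT displacement profile equals the direct estimator", {
  s <- generate_signal(signal_spec("logistic-map", N = 400, r = 3.9))
  a <- k_test(s, chaos01_config(n_c = 20), method = "fft")
  b <- k_test(s, chaos01_config(n_c = 20), method = "direct")
  expect_equal(a$kc_values$Kc, b$kc_values$Kc, tolerance = 1e-9)
})

test_that("K separates chaotic maps from harmonic motion", {
  k_chaos <- k_test(generate_signal(signal_spec("logistic-map", r = 4)))
  k_sine <- k_test(generate_signal(signal_spec("sine")))
  expect_gt(k_chaos$K, 0.9)
  expect_lt(k_sine$K, 0.1)
  # chaotic (p, q) orbits are diffusive, regular ones bounded
  expect_gt(k_chaos$median_diameter / sd(generate_signal(
    signal_spec("logistic-map", r = 4))$values),
    5 * k_sine$median_diameter / sd(generate_signal(
      signal_spec("sine"))$values))
})

test_that("K is the exact median and stable under seed and amplitude", {
  s <- generate_signal(signal_spec("logistic-map", N = 1500, r = 4))
  res <- k_test(s)
  expect_identical(res$K, median(res$kc_values$Kc))
  res2 <- k_test(s, chaos01_config(rng_seed = 999L))
  expect_lt(abs(res$K - res2$K), 0.05)
  res3 <- k_test(scalar_signal(37.5 * s$values, s$dt))
  expect_lt(abs(res$K - res3$K), 0.05)
})

test_that("chaos01 results export with a K summary row", {
  res <- k_test(generate_signal(signal_spec("sine", N = 300)),
                chaos01_config(n_c = 5))
  path <- tempfile(fileext = ".tsv")
  write_chaos01(res, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_identical(nrow(back), 6L)
  expect_equal(back$Kc[6], res$K, tolerance = 1e-6)
})
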