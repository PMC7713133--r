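test_that("default parameters carry the published constants verbatim", {
  p <- gf_parameters()
  expect_equal(unlist(p[paste0("k", 1:7)], use.names = FALSE),
               c(4.0e6, 2.0, 3000, 55.2, 7000, 0.09, 0.23))
  expect_equal(unlist(p[c("A", "M", "H", "C")], use.names = FALSE),
               c(0.1, 0.25, 0.26, 0.000833))
  expect_equal(p$alpha, 666.7)
  expect_equal(p$beta, 0.3478)
})

test_that("parameter validation rejects non-positive and missing values", {
  expect_error(gf_parameters(kf = 0), "strictly positive")
  expect_error(gf_parameters(A = -0.1), "strictly positive")
  expect_error(gf_parameters(k3 = -1), "non-negative")
  expect_error(gfchaos:::validate_gf_parameters(list(k1 = 1)), "missing")
})

test_that("ytilde vanishes when z or v vanishes and matches the printed formula", {
  p <- gf_parameters(kf = 3e-4)
  expect_identical(ytilde(c(1, 0, 1), p), 0)
  expect_identical(ytilde(c(1, 1, 0), p), 0)
  # frozen value from an independent single-line evaluation of
  # (alpha k6 Z0 V0 zv / (k1 H X0 x + k2 A H^2 + kf)) / Y0
  expect_equal(ytilde(c(1, 1, 1), p), 26.3501553332231, tolerance = 1e-12)
  expect_error(ytilde(c(-1, 1, 1), p), "non-negative")
})

test_that("the vector field reduces correctly in degenerate limits", {
  p0 <- outflow_params(kf = 3e-4)
  # only the outflow terms survive: T0 * (-kf x, -kf z, -kf v)
  s <- c(0.3, 1.7, 0.9)
  expect_equal(unname(gf_rhs(0, s, p0)), -p0$T0 * p0$kf * s,
               tolerance = 1e-12)
  # with kf formally zero as well the field vanishes (bypass the
  # constructor positivity gate for this structural identity)
  p00 <- unclass(p0); p00$kf <- 0
  class(p00) <- "gf_parameters"
  expect_equal(max(abs(gf_rhs(0, s, p00))), 0)
})

test_that("the vector field at (1,1,1) matches term-by-term independent evaluation", {
  p <- gf_parameters(kf = 3e-4)
  # frozen from an independent arithmetic evaluation of the three
  # printed equations with the default constants
  expect_equal(unname(gf_rhs(0, c(1, 1, 1), p)),
               c(673.446198378341, 464.98068373601, 0.47190260912903),
               tolerance = 1e-12)
})

test_that("jacobian agrees with central finite differences on random states", {
  p <- gf_parameters(kf = 3.5e-4)
  h <- 1e-6
  set.seed(11)
  for (rep in seq_len(100)) {
    s <- runif(3, 0.05, 2)
    J <- gf_jacobian(s, p)
    Jfd <- matrix(0, 3, 3)
    for (j in 1:3) {
      e <- rep(0, 3); e[j] <- h
      Jfd[, j] <- (gf_rhs(0, s + e, p) - gf_rhs(0, s - e, p)) / (2 * h)
    }
    expect_equal(unname(J), Jfd, tolerance = 1e-4)
  }
})

test_that("jacobian propagates the bromide coupling and guards x = 0", {
  p <- gf_parameters(kf = 3.5e-4)
  J <- gf_jacobian(c(1, 1, 1), p)
  expect_true(abs(J["x", "v"]) > 0)       # dx/dv through ytilde
  expect_error(gf_jacobian(c(0, 1, 1), p), "x > 0")
})

test_that("compiled and R vector fields produce the same trajectory", {
  p <- gf_parameters(kf = 3e-4)
  cfg <- sim_config(tau_final = 0.5, dt_out = 1e-3)
  a <- integrate_gf(p, cfg, engine = "compiled")
  b <- integrate_gf(p, cfg, engine = "R")
  expect_equal(a$states, b$states, tolerance = 1e-6)
})

test_that("parameters survive a key-value config round trip", {
  p <- gf_parameters(kf = 3.21e-4)
  path <- tempfile(fileext = ".cfg")
  write_gf_parameters(p, path)
  q <- read_gf_parameters(path)
  expect_equal(unclass(q), unclass(p))
  expect_error(read_gf_parameters({
    path2 <- tempfile(); writeLines("k1 = 1 = 2", path2); path2
  }), "malformed")
})
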