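test_that("sweep grids are validated and strictly increasing", {
  g <- sweep_grid(3e-4, 5e-4, n_points = 21)
  expect_identical(length(g$kf), 21L)
  expect_true(all(diff(g$kf) > 0))
  gs <- sweep_grid(3e-4, 3.1e-4, step = 2e-6)
  expect_equal(diff(gs$kf)[1], 2e-6)
  expect_error(sweep_grid(5e-4, 3e-4), "kf_max")
  expect_error(sweep_grid(-1e-4, 3e-4))
})

test_that("per-record seeds are deterministic and order-free", {
  expect_identical(gfchaos:::derive_seed(1L, 5L), gfchaos:::derive_seed(1L, 5L))
  expect_false(gfchaos:::derive_seed(1L, 5L) == gfchaos:::derive_seed(1L, 6L))
  expect_lt(gfchaos:::derive_seed(2147483646L, 1000L), 2^31)
})

test_that("showcase flow rates classify regular, regular, chaotic", {
  tab <- showcase_sweep()
  expect_identical(tab$class, c("regular", "regular", "chaotic"))
  expect_true(all(tab$K >= -1 & tab$K <= 1))
  expect_true(all(tab$ApEn >= 0))
  expect_true(all(is.na(tab$error)))
})

test_that("sweeps are order-independent and resumable", {
  tab <- showcase_sweep()
  g_perm <- sweep_grid(3e-4, 3.5e-4, n_points = 2)
  g_perm$kf <- c(3.5e-4, 3e-4, 3.2e-4)      # permuted evaluation order
  resumed <- run_sweep(g_perm, seed = 1L, previous = tab)
  expect_equal(as.data.frame(resumed), as.data.frame(tab))
  # partial table: only the missing record is recomputed
  partial <- tab[c(1, 3), ]
  attr(partial, "maxima") <- attr(tab, "maxima")[c(1, 3)]
  resumed2 <- run_sweep(g_perm, seed = 1L, previous = partial)
  expect_equal(resumed2$K, tab$K, tolerance = 1e-12)
})

test_that("failed records are captured without aborting the sweep", {
  g <- sweep_grid(1e-6, 3e-4, n_points = 2)
  g$kf <- c(3e-4, -1)           # second point fails parameter validation
  tab <- suppressWarnings(run_sweep(g, seed = 1L))
  expect_identical(sum(is.na(tab$K)), 1L)
  expect_true(any(!is.na(tab$error)))
})

test_that("nested zooms enforce strict containment", {
  g1 <- sweep_grid(3e-4, 5e-4, n_points = 5, level = "L1")
  g2 <- sweep_grid(3.25e-4, 3.35e-4, n_points = 5, level = "L2")
  g_bad <- sweep_grid(3.3e-4, 5.5e-4, n_points = 5)
  expect_error(nested_zoom(list(g1, g_bad)), "nesting violation")
  expect_error(nested_zoom(list(g2, g1)), "nesting violation")
})

test_that("a single-level zoom reduces to a plain sweep", {
  g <- sweep_grid(3e-4, 3.5e-4, n_points = 2, level = "only")
  g$kf <- c(3e-4, 3.5e-4)
  z <- nested_zoom(list(g), seed = 1L)
  direct <- run_sweep(g, seed = 1L)
  expect_equal(as.data.frame(z$levels[[1]]$table), as.data.frame(direct))
  expect_equal(z$mixture$chaotic_fraction, 0.5)
})

test_that("K-ApEn correlation demands variance and enough records", {
  tab <- data.frame(K = seq(0, 1, length.out = 12),
                    ApEn = seq(0.1, 1.3, length.out = 12))
  expect_equal(k_apen_correlation(tab), 1)
  expect_error(k_apen_correlation(data.frame(K = rep(0.5, 12),
                                             ApEn = runif(12))),
               "degenerate")
  expect_error(k_apen_correlation(tab[1:5, ]), "at least 10")
})

test_that("indicator tables export with a metadata sidecar", {
  tab <- showcase_sweep()
  path <- tempfile(fileext = ".tsv")
  write_indicator_table(tab, path, meta = list(seed = 1, stride = 100))
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_identical(nrow(back), 3L)
  meta <- gfchaos:::read_flat_config(paste0(path, ".meta"))
  expect_equal(meta$stride, 100)
})
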