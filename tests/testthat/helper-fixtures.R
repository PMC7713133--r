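# Shared fixtures.  The three showcase flow rates are integrated once per
# test session and cached; every consumer works on the kept (post-
# transient) window.

.fixture_env <- new.env(parent = emptyenv())

showcase_kept <- function(kf) {
  key <- sprintf("kept_%g", kf)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- discard_transient(
      integrate_gf(gf_parameters(kf = kf), sim_config()))
  .fixture_env[[key]]
}

showcase_signal <- function(kf, stride = 100) {
  resample_signal(norm_signal(showcase_kept(kf)), stride)
}

# degenerate parameter set: pure outflow (all reaction constants zero,
# scalings kept at their default values)
outflow_params <- function(kf = 3e-4) {
  sc <- gf_scalings()
  gf_parameters(kf = kf, k1 = 0, k2 = 0, k3 = 0, k4 = 0, k5 = 0,
                k6 = 0, k7 = 0, T0 = sc$T0, X0 = sc$X0, Y0 = sc$Y0,
                Z0 = sc$Z0, V0 = sc$V0)
}

# brute-force ApEn Phi, straight from the definition (double loop)
phi_bruteforce <- function(s, m, r) {
  N <- length(s)
  Nm <- N - (m - 1)
  logs <- numeric(Nm)
  for (i in seq_len(Nm)) {
    cnt <- 0
    for (j in seq_len(Nm)) {
      if (max(abs(s[i + 0:(m - 1)] - s[j + 0:(m - 1)])) < r) cnt <- cnt + 1
    }
    logs[i] <- log(cnt / Nm)
  }
  mean(logs)
}

# brute-force mean-square displacement (explicit double loop)
msd_bruteforce <- function(p, q, n) {
  N <- length(p)
  acc <- 0
  for (j in seq_len(N - n))
    acc <- acc + (p[j + n] - p[j])^2 + (q[j + n] - q[j])^2
  acc / (N - n)
}

showcase_sweep <- function() {
  if (is.null(.fixture_env$showcase_table)) {
    g <- sweep_grid(3e-4, 3.5e-4, n_points = 2)
    g$kf <- c(3e-4, 3.2e-4, 3.5e-4)
    .fixture_env$showcase_table <- run_sweep(g, seed = 1L)
  }
  .fixture_env$showcase_table
}

showcase_lyapunov <- function(kf) {
  key <- sprintf("lyap_%g", kf)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- suppressWarnings(
      lyapunov_spectrum(gf_parameters(kf = kf), lyapunov_config()))
  .fixture_env[[key]]
}
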