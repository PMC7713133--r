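## Approximate entropy (ApEn) of a scalar series.
##
## ApEn(m, r, N) = Phi^m(r) - Phi^{m+1}(r), where Phi^m(r) averages the
## log-frequency with which m-length embedded vectors stay within
## Chebyshev distance r of each other.  Low ApEn means high regularity.

#' Configuration for approximate entropy
#'
#' @param m embedding dimension (Pincus's canonical choice 2)
#' @param r neighborhood threshold.  With `r_scale = "sd"` (default) the
#'   signal is rescaled to unit standard deviation first, so `r = 0.1`
#'   means one tenth of the signal's standard deviation and ApEn is
#'   invariant under affine transformations of the signal.  With
#'   `r_scale = "raw"` the threshold applies on the original scale.
#' @param r_scale `"sd"` or `"raw"`
#' @param min_N advisory minimum series length for a robust estimate;
#'   series shorter than this (but at least 100) trigger a warning
#' @return object of class `apen_config`
#' @export
apen_config <- function(m = 2L, r = 0.1, r_scale = c("sd", "raw"),
                        min_N = 1000L) {
  r_scale <- match.arg(r_scale)
  stopifnot(m >= 1, m == as.integer(m), r > 0, min_N >= 100)
  structure(list(m = as.integer(m), r = r, r_scale = r_scale,
                 min_N = as.integer(min_N)),
            class = "apen_config")
}

#' Chebyshev distance of two embedded vectors
#'
#' `D(i, j) = max_{k = 0..m-1} |s(i+k) - s(j+k)|`.
#'
#' @param s numeric series
#' @param i,j start indices (1-based); `i + m - 1` and `j + m - 1` must
#'   not exceed `length(s)`
#' @param m embedding dimension
#' @return non-negative scalar
#' @export
embedded_distance <- function(s, i, j, m) {
  N <- length(s)
  stopifnot(m >= 1, i >= 1, j >= 1, i + m - 1 <= N, j + m - 1 <= N)
  max(abs(s[i + 0:(m - 1)] - s[j + 0:(m - 1)]))
}

#' Phi statistic of approximate entropy
#'
#' `Phi^m(r)` is the average over all embedded vectors of the logarithm
#' of `C_i^m(r)`, the fraction of embedded vectors within Chebyshev
#' distance `r` of vector `i`.  Self-matches are included (the distance
#' of a vector to itself is 0 < r), so every `C_i^m(r)` is positive and
#' the logarithm finite; consequently `Phi^m(r) <= 0`.
#'
#' @param s numeric series (already on the scale at which `r` applies)
#' @param m embedding dimension
#' @param r neighborhood threshold (raw scale of `s`)
#' @return scalar `Phi^m(r) <= 0`
#' @export
phi_m <- function(s, m, r) {
  N <- length(s)
  stopifnot(m >= 1, r > 0)
  if (N < m + 1) stop("series too short for embedding dimension ", m)
  Nm <- N - (m - 1)
  A <- abs(outer(s, s, "-"))
  D <- A[1:Nm, 1:Nm, drop = FALSE]
  if (m > 1) {
    for (k in seq_len(m - 1))
      D <- pmax(D, A[(1 + k):(Nm + k), (1 + k):(Nm + k), drop = FALSE])
  }
  Ci <- rowSums(D < r) / Nm
  mean(log(Ci))
}

#' Approximate entropy of a scalar signal
#'
#' @param sig a [scalar_signal()] or bare numeric series of length at
#'   least 100
#' @param cfg an [apen_config()]
#' @return scalar `ApEn(m, r, N) = Phi^m(r) - Phi^{m+1}(r)`; 0 for a
#'   constant series
#' @export
#' @examples
#' apen(generate_signal(signal_spec("white-noise", N = 500, seed = 1)))
apen <- function(sig, cfg = apen_config()) {
  s <- if (inherits(sig, "scalar_signal")) sig$values else as.numeric(sig)
  N <- length(s)
  if (N < 100) stop("approximate entropy requires at least 100 observations")
  if (N < cfg$min_N)
    warning(sprintf("series length %d below the advised minimum %d; ",
                    N, cfg$min_N),
            "ApEn estimate may be unstable")
  if (cfg$r_scale == "sd") {
    s_dev <- sd(s)
    if (s_dev == 0) return(0)          # constant series: fully regular
    s <- s / s_dev
  }
  phi_m_fast(s, cfg$m, cfg$r) - phi_m_fast(s, cfg$m + 1L, cfg$r)
}

# compiled pair-count path; numerically identical to phi_m (tested)
phi_m_fast <- function(s, m, r) {
  N <- length(s)
  stopifnot(m >= 1, r > 0)
  if (N < m + 1) stop("series too short for embedding dimension ", m)
  .C("apen_phi_kernel", as.double(s), as.integer(N), as.integer(m),
     as.double(r), phi = double(1), NAOK = TRUE)$phi
}
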