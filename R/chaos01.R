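## 0-1 test for chaos (Gottwald-Melbourne), correlation method.
##
## A scalar observation phi(j) is mapped to translation variables
##   p_c(n) = sum_{j<=n} phi(j) cos(jc),  q_c(n) = sum_{j<=n} phi(j) sin(jc).
## Bounded (p, q) orbits signal regular dynamics (K ~ 0); diffusive growth
## signals chaos (K ~ 1).  K_c is the Pearson correlation between the lag
## index and the modified mean-square displacement; K is the median of K_c
## over randomly drawn phase angles c.

#' Configuration for the 0-1 test for chaos
#'
#' @param n_c number of phase angles c drawn
#' @param c_range interval within `(0, 2*pi)` from which c is drawn
#'   uniformly.  The default `(pi/5, 4*pi/5)` avoids the resonance
#'   artifacts near 0 and pi.
#' @param ncut_fraction the mean-square displacement is evaluated at lags
#'   `1..ncut` with `ncut = floor(N * ncut_fraction)`; lags much shorter
#'   than the series are required, `ncut <= N/10`
#' @param rng_seed integer seed for drawing the phase angles
#' @return object of class `chaos01_config`
#' @export
chaos01_config <- function(n_c = 100, c_range = c(pi / 5, 4 * pi / 5),
                           ncut_fraction = 0.1, rng_seed = 42L) {
  stopifnot(n_c >= 1, length(c_range) == 2,
            c_range[1] > 0, c_range[1] < c_range[2], c_range[2] < 2 * pi,
            ncut_fraction > 0, ncut_fraction <= 0.1)
  structure(list(n_c = as.integer(n_c), c_range = c_range,
                 ncut_fraction = ncut_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "chaos01_config")
}

#' Translation components of the 0-1 test
#'
#' @param phi numeric observation series
#' @param c phase angle in `(0, 2*pi)`
#' @return list with cumulative-sum series `p` and `q` (index j runs from
#'   1 to N)
#' @export
translation_components <- function(phi, c) {
  stopifnot(length(phi) >= 1, is.numeric(phi), c > 0, c < 2 * pi)
  j <- seq_along(phi)
  list(p = cumsum(phi * cos(j * c)), q = cumsum(phi * sin(j * c)))
}

#' Mean-square displacement of the translation variables
#'
#' Finite-sample estimator: the squared displacement over lag `n` is
#' averaged over the `N - n` available start positions.
#'
#' @param p,q translation component series
#' @param n lag (positive integer, `n < N`)
#' @return scalar `M(n) >= 0`
#' @export
mean_square_displacement <- function(p, q, n) {
  N <- length(p)
  stopifnot(length(q) == N, n >= 1, n == as.integer(n))
  if (n >= N) stop("lag n must be smaller than the series length")
  j <- seq_len(N - n)
  mean((p[j + n] - p[j])^2 + (q[j + n] - q[j])^2)
}

#' Modified mean-square displacement
#'
#' Subtracts the oscillatory term driven by the series mean:
#' `D(n) = M(n) - E(phi)^2 (1 - cos(nc)) / (1 - cos c)`.
#'
#' @param msd value `M(n)`
#' @param mean_phi arithmetic mean of the observation series
#' @param n lag
#' @param c phase angle; `cos(c) != 1` required
#' @return scalar `D(n)`
#' @export
modified_msd <- function(msd, mean_phi, n, c) {
  if (cos(c) == 1) stop("modified MSD undefined where cos(c) = 1")
  msd - mean_phi^2 * (1 - cos(n * c)) / (1 - cos(c))
}

#' K_c statistic for one phase angle
#'
#' Pearson correlation of the lag index `1..ncut` against the modified
#' mean-square displacement at those lags.  A constant displacement
#' vector (zero variance) has undefined correlation and is regular by
#' construction; `K_c = 0` is returned in that case.
#'
#' @param phi observation series
#' @param c phase angle
#' @param cfg a [chaos01_config()]
#' @return `K_c` in `[-1, 1]`
#' @export
kc_statistic <- function(phi, c, cfg = chaos01_config()) {
  N <- length(phi)
  ncut <- floor(N * cfg$ncut_fraction)
  if (ncut < 3) stop("series too short: ncut < 3")
  tc <- translation_components(phi, c)
  m_phi <- mean(phi)
  lags <- seq_len(ncut)
  msd <- vapply(lags, function(n)
    mean_square_displacement(tc$p, tc$q, n), numeric(1))
  D <- modified_msd(msd, m_phi, lags, c)
  if (sd(D) == 0 || !is.finite(sd(D))) return(0)
  cor(lags, D)
}

#' The 0-1 test for chaos
#'
#' Draws `n_c` phase angles uniformly from `c_range`, computes `K_c` for
#' each, and reports the median `K`.  `K` close to 0 indicates regular
#' (periodic or quasi-periodic) dynamics, close to 1 chaos; intermediate
#' values flag trajectories that have not settled on the attractor or are
#' intermittent.
#'
#' @param sig a [scalar_signal()] (or bare numeric series), length at
#'   least 100
#' @param cfg a [chaos01_config()]
#' @param method displacement computation: `"fft"` evaluates the
#'   mean-square displacement at all lags at once through the
#'   autocorrelation of the complex orbit `p + iq` (numerically identical
#'   to the direct estimator); `"direct"` averages displacement by
#'   displacement via [mean_square_displacement()]
#' @return object of class `chaos01_result`: list with `K`, the
#'   data frame `kc_values` (columns `c`, `Kc`, `pq_diameter`), and
#'   `median_diameter` (median over c of the diameter of the `(p, q)`
#'   orbit -- bounded for regular dynamics, diffusively large for chaos)
#' @export
#' @examples
#' s <- generate_signal(signal_spec("logistic-map", N = 1000, r = 4))
#' k_test(s)$K
k_test <- function(sig, cfg = chaos01_config(),
                   method = c("fft", "direct")) {
  method <- match.arg(method)
  phi <- if (inherits(sig, "scalar_signal")) sig$values else as.numeric(sig)
  if (length(phi) < 100)
    stop("0-1 test requires at least 100 observations")
  N <- length(phi)
  ncut <- floor(N * cfg$ncut_fraction)
  if (ncut < 3) stop("series too short: ncut < 3")
  m_phi <- mean(phi)
  lags <- seq_len(ncut)
  set.seed(cfg$rng_seed)
  cs <- runif(cfg$n_c, cfg$c_range[1], cfg$c_range[2])
  kc <- numeric(cfg$n_c)
  diam <- numeric(cfg$n_c)
  for (i in seq_along(cs)) {
    tc <- translation_components(phi, cs[i])
    msd <- if (method == "fft") msd_profile(tc$p, tc$q, ncut)
           else vapply(lags, function(n)
             mean_square_displacement(tc$p, tc$q, n), numeric(1))
    D <- modified_msd(msd, m_phi, lags, cs[i])
    kc[i] <- if (sd(D) == 0 || !is.finite(sd(D))) 0 else cor(lags, D)
    diam[i] <- sqrt(diff(range(tc$p))^2 + diff(range(tc$q))^2)
  }
  structure(list(K = median(kc),
                 kc_values = data.frame(c = cs, Kc = kc, pq_diameter = diam),
                 median_diameter = median(diam)),
            class = "chaos01_result")
}

# M(n) for n = 1..ncut in one pass: expand the squared displacement and
# obtain the cross term from the autocorrelation of p + iq by FFT with
# zero padding (exact, no circular wrap for n <= ncut)
msd_profile <- function(p, q, ncut) {
  N <- length(p)
  stopifnot(ncut < N)
  cx <- complex(real = p, imaginary = q)
  L <- 2^ceiling(log2(N + ncut + 1))
  c0 <- c(cx, rep(0 + 0i, L - N))
  G <- fft(c0)
  ac <- fft(Conj(G) * G, inverse = TRUE) / L
  n <- seq_len(ncut)
  A <- Re(ac[1 + n])                    # sum_j p_j p_{j+n} + q_j q_{j+n}
  S <- cumsum(p^2 + q^2)
  ((S[N] - S[n]) + S[N - n] - 2 * A) / (N - n)
}

#' @export
print.chaos01_result <- function(x, ...) {
  cat(sprintf("0-1 test for chaos: K = %.4f (median of %d K_c values)\n",
              x$K, nrow(x$kc_values)))
  invisible(x)
}

#' Export a 0-1 test result as delimited text
#'
#' One row per phase angle with `K_c`, followed by a summary row holding
#' the median `K`.
#'
#' @param res a `chaos01_result`
#' @param path output file
#' @export
write_chaos01 <- function(res, path) {
  stopifnot(inherits(res, "chaos01_result"))
  df <- res$kc_values[, c("c", "Kc")]
  df <- rbind(df, data.frame(c = NA, Kc = res$K))
  df$row <- c(rep("Kc", nrow(df) - 1), "K_median")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
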