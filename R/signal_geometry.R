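## Geometry of trajectories and signals: local-maxima bifurcation data,
## Poincare sections, Fourier amplitude spectra.

#' Local maxima of a series
#'
#' A sample `s(k)` is a local maximum when `s(k-1) < s(k) >= s(k+1)`;
#' a plateau that is a maximum is counted once, at its first sample.
#' Projected against the swept parameter these peak values form the
#' bifurcation diagram.
#'
#' @param series numeric vector, length at least 3
#' @return numeric vector of peak values (possibly empty), with the
#'   sample indices as attribute `"index"`
#' @export
#' @examples
#' local_maxima(sin(seq(0, 10 * pi, by = 0.01)))
local_maxima <- function(series) {
  stopifnot(is.numeric(series), length(series) >= 3)
  n <- length(series)
  mid <- 2:(n - 1)
  is_peak <- series[mid] > series[mid - 1] & series[mid] >= series[mid + 1]
  idx <- mid[is_peak]
  structure(series[idx], index = idx)
}

#' Poincare section plane
#'
#' @param coordinate which state variable defines the plane: `"x"`,
#'   `"z"` or `"v"`
#' @param level section value of that coordinate
#' @param direction count crossings going `"up"`, `"down"` or `"both"`
#' @return object of class `poincare_plane`
#' @export
poincare_plane <- function(coordinate = c("v", "x", "z"), level,
                           direction = c("both", "up", "down")) {
  coordinate <- match.arg(coordinate)
  direction <- match.arg(direction)
  stopifnot(is.numeric(level), length(level) == 1, is.finite(level))
  structure(list(coordinate = coordinate, level = level,
                 direction = direction),
            class = "poincare_plane")
}

#' Poincare section of a trajectory
#'
#' Finds the crossings of the trajectory through a coordinate plane
#' (linear interpolation between samples) and returns the other two
#' coordinates at each crossing.  A periodic orbit leaves finitely many
#' points; a chaotic one a band.  When `plane` is omitted, the
#' convention is the centroid plane `v = mean(v)` over the supplied
#' (kept) window, crossed in both directions: the organic-bromide
#' coordinate varies smoothly over the orbit, so its centroid plane
#' separates all crossings of the period-doubled loops cleanly.
#'
#' @param traj a `gf_trajectory` (post-transient window)
#' @param plane a [poincare_plane()]; default centroid plane of `x`
#' @return matrix with one row per crossing and the two non-section
#'   coordinates as columns (plus attribute `"tau"` of crossing times)
#' @export
poincare_points <- function(traj, plane = NULL) {
  stopifnot(inherits(traj, "gf_trajectory"))
  if (is.null(plane))
    plane <- poincare_plane("v", mean(traj$states[, "v"]), "both")
  stopifnot(inherits(plane, "poincare_plane"))
  coord <- traj$states[, plane$coordinate]
  if (plane$level < min(coord) || plane$level > max(coord))
    stop("section level lies outside the range of coordinate ",
         plane$coordinate)
  g <- coord - plane$level
  n <- length(g)
  up <- g[-n] < 0 & g[-1] >= 0
  down <- g[-n] > 0 & g[-1] <= 0
  sel <- switch(plane$direction, up = up, down = down, both = up | down)
  i <- which(sel)
  if (!length(i)) stop("trajectory never crosses the section plane")
  th <- g[i] / (g[i] - g[i + 1])            # interpolation fraction
  others <- setdiff(c("x", "z", "v"), plane$coordinate)
  pts <- sapply(others, function(cn) {
    a <- traj$states[i, cn]
    a + th * (traj$states[i + 1, cn] - a)
  })
  pts <- matrix(pts, ncol = 2, dimnames = list(NULL, others))
  attr(pts, "tau") <- traj$tau[i] + th * (traj$tau[i + 1] - traj$tau[i])
  rng <- apply(traj$states, 2, range)
  attr(pts, "attractor_diameter") <- sqrt(sum((rng[2, ] - rng[1, ])^2))
  pts
}

#' Count distinct Poincare points
#'
#' Single-linkage clustering of the section points with linking radius
#' `tol` times the attractor diameter (attached by [poincare_points()];
#' the diameter of the point set is used as a fallback for bare
#' matrices); the number of clusters is the "number of intersection
#' points" of the section.  A periodic orbit gives a small stable count;
#' a chaotic band gives a count that grows with the number of crossings
#' retained.
#'
#' @param points matrix of section points (rows) from [poincare_points()]
#' @param tol relative linking radius
#' @param max_points cap on the number of points clustered (evenly spaced
#'   thinning beyond it) to bound the distance-matrix cost
#' @return integer number of clusters
#' @export
count_distinct_points <- function(points, tol = 1e-3, max_points = 2000) {
  scale <- attr(points, "attractor_diameter")
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 1, tol > 0)
  if (nrow(points) > max_points) {
    keep <- unique(round(seq(1, nrow(points), length.out = max_points)))
    points <- points[keep, , drop = FALSE]
  }
  if (nrow(points) == 1) return(1L)
  d <- dist(points)
  if (is.null(scale)) scale <- max(d)
  if (scale == 0 || max(d) == 0) return(1L)
  hc <- hclust(d, method = "single")
  length(unique(cutree(hc, h = tol * scale)))
}

#' One-sided Fourier amplitude spectrum
#'
#' Mean-removed, Hann-tapered FFT amplitude spectrum of a uniformly
#' sampled signal.  Amplitudes are corrected for the coherent gain of the
#' window, so a pure sinusoid of amplitude A shows a peak of height close
#' to A.
#'
#' @param sig a [scalar_signal()], length at least 64
#' @return object of class `spectrum_result`: list with `frequencies`
#'   (cycles per tau, ascending from 0) and `amplitudes` (signal units);
#'   the windowed series and window are attached for energy checks
#' @export
amplitude_spectrum <- function(sig) {
  stopifnot(inherits(sig, "scalar_signal"))
  s <- sig$values
  N <- length(s)
  if (N < 64) stop("spectrum requires at least 64 samples")
  w <- 0.5 * (1 - cos(2 * pi * seq(0, N - 1) / (N - 1)))   # Hann
  sw <- (s - mean(s)) * w
  ft <- fft(sw)
  half <- seq_len(floor(N / 2) + 1)
  amp <- 2 * Mod(ft[half]) / sum(w)
  amp[1] <- amp[1] / 2
  if (N %% 2 == 0) amp[length(half)] <- amp[length(half)] / 2
  freq <- (half - 1) / (N * sig$dt)
  structure(list(frequencies = freq, amplitudes = amp,
                 windowed = sw, window = w, dt = sig$dt),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  i <- which.max(x$amplitudes)
  cat(sprintf("amplitude spectrum: %d bins, dominant peak %.4g at %.4g cycles/tau\n",
              length(x$frequencies), x$amplitudes[i], x$frequencies[i]))
  invisible(x)
}

#' Fraction of spectral amplitude carried by the strongest peaks
#'
#' Regular regimes concentrate their spectrum in a few harmonic lines;
#' chaotic regimes are broadband.  Peaks are local maxima of the
#' amplitude spectrum; the `n_peaks` largest (each with its two
#' neighboring bins, covering spectral leakage) are summed and divided by
#' the total spectral amplitude.
#'
#' @param spec a `spectrum_result`
#' @param n_peaks number of dominant peaks
#' @return fraction in `[0, 1]`
#' @export
peak_amplitude_fraction <- function(spec, n_peaks = 5) {
  stopifnot(inherits(spec, "spectrum_result"))
  amp <- spec$amplitudes
  pk <- local_maxima(amp)
  if (!length(pk)) return(0)
  idx <- attr(pk, "index")
  top <- idx[order(pk, decreasing = TRUE)][seq_len(min(n_peaks, length(idx)))]
  cover <- unique(pmin(pmax(c(top - 1, top, top + 1), 1), length(amp)))
  sum(amp[cover]) / sum(amp)
}

#' Export section points or a spectrum as delimited text
#'
#' @param x matrix of Poincare points or a `spectrum_result`
#' @param path output file
#' @export
write_geometry <- function(x, path) {
  if (inherits(x, "spectrum_result")) {
    df <- data.frame(frequency = x$frequencies, amplitude = x$amplitudes)
  } else {
    df <- as.data.frame(as.matrix(x))
  }
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
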