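## Gyorgyi-Field three-variable model: parameters, vector field, Jacobian.

#' Scaling constants of the dimensionless Gyorgyi-Field model
#'
#' The dimensionless GF equations are written in scaled variables
#' `x = X/X0`, `z = Z/Z0`, `v = V/V0`, `tau = t/T0`, with `Y0` scaling the
#' algebraically eliminated bromide concentration.  This helper returns the
#' scaling set of the original Gyorgyi-Field reduction, expressed through
#' the rate constants and reactor concentrations:
#'
#' * `X0 = k2 A H^2 / k5` (M)
#' * `Z0 = C A / (40 M)` (M)
#' * `V0 = 4 A H C / M^2` (M)
#' * `Y0 = k2 A H^2 / (k1 H)` (M)
#' * `T0 = 1 / (10 k2 A H C)` (s)
#'
#' `Y0` cancels identically from the vector field (the bromide term enters
#' the equations only as `Y0 * ytilde`); it is carried so that `ytilde()`
#' reports the bromide concentration on a definite scale.
#'
#' @param k1,k2,k5 rate constants (see [gf_parameters()])
#' @param A,H,M,C reactor concentrations in M
#' @return named list with elements `T0`, `X0`, `Y0`, `Z0`, `V0`
#' @export
#' @examples
#' gf_scalings()
gf_scalings <- function(k1 = 4.0e6, k2 = 2.0, k5 = 7000,
                        A = 0.1, H = 0.26, M = 0.25, C = 0.000833) {
  list(T0 = 1 / (10 * k2 * A * H * C),
       X0 = k2 * A * H^2 / k5,
       Y0 = k2 * A * H^2 / (k1 * H),
       Z0 = C * A / (40 * M),
       V0 = 4 * A * H * C / M^2)
}

#' Parameters of the Gyorgyi-Field model
#'
#' Collects the rate constants `k1..k7`, the reactor concentrations
#' (bromate `A`, protons `H`, malonic acid `M`, total cerium `C`), the
#' stoichiometric factors `alpha` and `beta`, the flow rate `kf` (inverse
#' residence time of the reactor, in 1/s -- the bifurcation parameter of
#' the model) and the five scaling constants of the dimensionless form.
#' Defaults are the published constants of the GF reduction.
#'
#' @param kf flow rate in 1/s; the free parameter of the model
#' @param k1,k2,k3,k4,k5,k6,k7 rate constants (mixed M^-n s^-1 units)
#' @param A,H,M,C reactor concentrations (M)
#' @param alpha,beta dimensionless stoichiometric factors
#' @param T0,X0,Y0,Z0,V0 scaling constants; default [gf_scalings()]
#'   evaluated at the supplied rate constants and concentrations
#' @return object of class `gf_parameters` (a validated named list)
#' @seealso [gf_rhs()], [integrate_gf()], [read_gf_parameters()]
#' @export
#' @examples
#' p <- gf_parameters(kf = 3.5e-4)
#' p$T0
gf_parameters <- function(kf = 3e-4,
                          k1 = 4.0e6, k2 = 2.0, k3 = 3000, k4 = 55.2,
                          k5 = 7000, k6 = 0.09, k7 = 0.23,
                          A = 0.1, H = 0.26, M = 0.25, C = 0.000833,
                          alpha = 666.7, beta = 0.3478,
                          T0 = NULL, X0 = NULL, Y0 = NULL,
                          Z0 = NULL, V0 = NULL) {
  sc <- gf_scalings(k1 = k1, k2 = k2, k5 = k5, A = A, H = H, M = M, C = C)
  p <- list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6, k7 = k7,
            A = A, H = H, M = M, C = C, alpha = alpha, beta = beta,
            kf = kf,
            T0 = if (is.null(T0)) sc$T0 else T0,
            X0 = if (is.null(X0)) sc$X0 else X0,
            Y0 = if (is.null(Y0)) sc$Y0 else Y0,
            Z0 = if (is.null(Z0)) sc$Z0 else Z0,
            V0 = if (is.null(V0)) sc$V0 else V0)
  validate_gf_parameters(p)
}

gf_param_names <- c("k1", "k2", "k3", "k4", "k5", "k6", "k7",
                    "A", "H", "M", "C", "alpha", "beta", "kf",
                    "T0", "X0", "Y0", "Z0", "V0")

validate_gf_parameters <- function(p) {
  miss <- setdiff(gf_param_names, names(p))
  if (length(miss))
    stop("missing GF parameters: ", paste(miss, collapse = ", "))
  vals <- unlist(p[gf_param_names])
  if (!all(is.finite(vals)))
    stop("all GF parameters must be finite")
  pos <- c("A", "H", "M", "C", "kf", "T0", "X0", "Y0", "Z0", "V0")
  bad <- pos[vapply(p[pos], function(v) v <= 0, logical(1))]
  if (length(bad))
    stop("GF parameters must be strictly positive: ",
         paste(bad, collapse = ", "))
  # rate constants may be zero (degenerate flows used for closed-form
  # checks) but never negative
  ks <- paste0("k", 1:7)
  neg <- ks[vapply(p[ks], function(v) v < 0, logical(1))]
  if (length(neg))
    stop("rate constants must be non-negative: ", paste(neg, collapse = ", "))
  structure(p[gf_param_names], class = "gf_parameters")
}

#' @export
print.gf_parameters <- function(x, ...) {
  cat("Gyorgyi-Field model parameters\n")
  cat(sprintf("  flow rate kf = %g 1/s\n", x$kf))
  cat(sprintf("  rate constants k1..k7: %s\n",
              paste(signif(unlist(x[paste0("k", 1:7)]), 4), collapse = ", ")))
  cat(sprintf("  concentrations A=%g H=%g M=%g C=%g M\n", x$A, x$H, x$M, x$C))
  cat(sprintf("  alpha=%g beta=%g\n", x$alpha, x$beta))
  cat(sprintf("  scalings T0=%.6g s, X0=%.4g, Y0=%.4g, Z0=%.4g, V0=%.4g M\n",
              x$T0, x$X0, x$Y0, x$Z0, x$V0))
  invisible(x)
}

check_gf_state <- function(state) {
  if (length(state) != 3 || !is.numeric(state))
    stop("state must be a numeric triple (x, z, v)")
  if (!all(is.finite(state)))
    stop("state must be finite")
  if (any(state < -1e-12))
    stop("state components must be non-negative (x, z, v >= 0)")
  pmax(as.numeric(state), 0)
}

#' Dimensionless bromide concentration of the GF model
#'
#' The GF reduction eliminates bromide algebraically: its quasi-steady
#' concentration is `alpha k6 Z0 V0 z v / (k1 H X0 x + k2 A H^2 + kf)`,
#' reported here divided by the bromide scale `Y0`.
#'
#' @param state numeric triple `(x, z, v)`, all non-negative
#' @param p a [gf_parameters()] object
#' @return dimensionless bromide concentration (scalar, non-negative)
#' @export
ytilde <- function(state, p) {
  stopifnot(inherits(p, "gf_parameters"))
  s <- check_gf_state(state)
  den <- p$k1 * p$H * p$X0 * s[1] + p$k2 * p$A * p$H^2 + p$kf
  (p$alpha * p$k6 * p$Z0 * p$V0 * s[2] * s[3] / den) / p$Y0
}

#' Right-hand side of the dimensionless GF equations
#'
#' Evaluates the rates `(dx/dtau, dz/dtau, dv/dtau)` of the scaled GF
#' system.  The model is autonomous; `tau` is accepted for solver
#' compatibility and ignored.  The reference implementation in R; the
#' integrators use an equivalent compiled version.
#'
#' @param tau dimensionless time (unused)
#' @param state numeric triple `(x, z, v)`, non-negative (the `x^0.5`
#'   autocatalysis terms are undefined for negative `x`)
#' @param p a [gf_parameters()] object
#' @return numeric triple of rates in 1/tau units
#' @export
#' @examples
#' p <- gf_parameters(kf = 3e-4)
#' gf_rhs(0, c(1, 1, 1), p)
gf_rhs <- function(tau, state, p) {
  stopifnot(inherits(p, "gf_parameters"))
  s <- check_gf_state(state)
  x <- s[1]; z <- s[2]; v <- s[3]
  xs <- sqrt(x)
  b <- p$k2 * p$A * p$H^2
  den <- p$k1 * p$H * p$X0 * x + b + p$kf
  w <- if (den > 0) p$alpha * p$k6 * p$Z0 * p$V0 * z * v / den
       else 0                                      # = Y0 * ytilde
  c4 <- 0.5 * p$k4 * sqrt(p$A) * p$H^1.5 / sqrt(p$X0)
  d4 <- p$k4 * sqrt(p$A) * p$H^1.5 * sqrt(p$X0)
  f <- c(
    -p$k1 * p$H * x * w + (b / p$X0) * w - 2 * p$k3 * p$X0 * x^2 +
      c4 * (p$C - p$Z0 * z) * xs - 0.5 * p$k5 * p$Z0 * x * z - p$kf * x,
    d4 * (p$C / p$Z0 - z) * xs - p$k5 * p$X0 * x * z -
      p$alpha * p$k6 * p$V0 * z * v - p$beta * p$k7 * p$M * z - p$kf * z,
    2 * p$k1 * p$H * (p$X0 / p$V0) * x * w + (b / p$V0) * w +
      p$k3 * p$X0^2 / p$V0 * x^2 - p$alpha * p$k6 * p$Z0 * z * v - p$kf * v
  ) * p$T0
  if (!all(is.finite(f)))
    stop("GF right-hand side overflowed at state (",
         paste(signif(s, 6), collapse = ", "), ")")
  names(f) <- c("x", "z", "v")
  f
}

#' Jacobian of the GF vector field
#'
#' Analytic 3x3 matrix of partial derivatives of [gf_rhs()] with respect
#' to `(x, z, v)`, including the chain-rule coupling through the
#' quasi-steady bromide term.  Requires `x > 0` (the derivative of the
#' `x^0.5` terms diverges at zero).
#'
#' @inheritParams gf_rhs
#' @return 3x3 numeric matrix, rows and columns ordered `(x, z, v)`
#' @export
gf_jacobian <- function(state, p) {
  stopifnot(inherits(p, "gf_parameters"))
  s <- check_gf_state(state)
  x <- s[1]; z <- s[2]; v <- s[3]
  if (x <= 0)
    stop("gf_jacobian requires x > 0 (x^0.5 is not differentiable at 0)")
  xs <- sqrt(x)
  b <- p$k2 * p$A * p$H^2
  a <- p$k1 * p$H * p$X0
  den <- a * x + b + p$kf
  G <- p$alpha * p$k6 * p$Z0 * p$V0
  w <- G * z * v / den
  wx <- -w * a / den
  wz <- G * v / den
  wv <- G * z / den
  c4 <- 0.5 * p$k4 * sqrt(p$A) * p$H^1.5 / sqrt(p$X0)
  d4 <- p$k4 * sqrt(p$A) * p$H^1.5 * sqrt(p$X0)
  e1 <- 2 * p$k1 * p$H * p$X0 / p$V0
  e2 <- b / p$V0
  e3 <- p$k3 * p$X0^2 / p$V0
  g1 <- -p$k1 * p$H * x + b / p$X0
  J <- matrix(0, 3, 3, dimnames = list(c("x", "z", "v"), c("x", "z", "v")))
  J[1, 1] <- -p$k1 * p$H * (w + x * wx) + (b / p$X0) * wx -
    4 * p$k3 * p$X0 * x + 0.5 * c4 * (p$C - p$Z0 * z) / xs -
    0.5 * p$k5 * p$Z0 * z - p$kf
  J[1, 2] <- g1 * wz - c4 * p$Z0 * xs - 0.5 * p$k5 * p$Z0 * x
  J[1, 3] <- g1 * wv
  J[2, 1] <- 0.5 * d4 * (p$C / p$Z0 - z) / xs - p$k5 * p$X0 * z
  J[2, 2] <- -d4 * xs - p$k5 * p$X0 * x - p$alpha * p$k6 * p$V0 * v -
    p$beta * p$k7 * p$M - p$kf
  J[2, 3] <- -p$alpha * p$k6 * p$V0 * z
  J[3, 1] <- e1 * (w + x * wx) + e2 * wx + 2 * e3 * x
  J[3, 2] <- (e1 * x + e2) * wz - p$alpha * p$k6 * p$Z0 * v
  J[3, 3] <- (e1 * x + e2) * wv - p$alpha * p$k6 * p$Z0 * z - p$kf
  p$T0 * J
}

## flat key-value config I/O (shared format: "name = value" per line)

#' Read and write GF parameters as a flat key-value file
#'
#' One `key = value` pair per line, keys named exactly as the fields of
#' [gf_parameters()] (`k1..k7`, `A`, `H`, `M`, `C`, `alpha`, `beta`,
#' `kf`, `T0`, `X0`, `Y0`, `Z0`, `V0`).  Lines starting with `#` are
#' comments.
#'
#' @param p a [gf_parameters()] object
#' @param path file path
#' @return `read_gf_parameters()` returns a [gf_parameters()] object;
#'   `write_gf_parameters()` returns `path` invisibly.
#' @export
write_gf_parameters <- function(p, path) {
  stopifnot(inherits(p, "gf_parameters"))
  write_flat_config(unclass(p), path)
}

#' @rdname write_gf_parameters
#' @export
read_gf_parameters <- function(path) {
  vals <- read_flat_config(path)
  validate_gf_parameters(as.list(vals))
}

write_flat_config <- function(x, path) {
  stopifnot(is.list(x), !is.null(names(x)))
  lines <- sprintf("%s = %s", names(x),
                   vapply(x, function(v) format(v, digits = 17),
                          character(1)))
  writeLines(lines, path)
  invisible(path)
}

read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  vals <- vapply(kv, function(e) as.numeric(trimws(e[2])), numeric(1))
  names(vals) <- vapply(kv, function(e) trimws(e[1]), character(1))
  as.list(vals)
}
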