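#' Mean resultant vector of circular data
#'
#' The first trigonometric moment: `R = |mean(exp(i * theta))|` and its
#' argument. `R` is the per-trial synchronization consistency score;
#' the direction is the circular mean phase (negative = anticipation when
#' angles are referenced to the beat).
#'
#' @param angles Numeric vector of angles in radians.
#' @return List with `R` (in `[0, 1]`), `direction` (radians in
#'   `(-pi, pi]`) and `n`.
#' @examples
#' mean_resultant(c(0, pi / 2))$R  # sqrt(2)/2
#' @export
mean_resultant <- function(angles) {
  if (length(angles) == 0L) stop("`angles` must be non-empty")
  if (!is.numeric(angles) || any(!is.finite(angles)))
    stop("`angles` must be finite numeric")
  C <- mean(cos(angles))
  S <- mean(sin(angles))
  R <- min(sqrt(C^2 + S^2), 1)
  list(R = R, direction = atan2(S, C), n = length(angles))
}

#' Logit transform of a vector-length score
#'
#' `log(R / (1 - R))` with `R` clamped to `[epsilon, 1 - epsilon]` so that
#' degenerate trials (`R` of exactly 0 or 1) stay finite. Applied to
#' consistency scores before linear modelling to reduce the skew typical
#' of bounded synchronization measures.
#'
#' @param R Vector-length value(s) in `[0, 1]`.
#' @param epsilon Clamping bound, default `1e-6`.
#' @return Logit-transformed value(s).
#' @export
logit_transform <- function(R, epsilon = 1e-6) {
  if (any(!is.finite(R)) || any(R < 0) || any(R > 1))
    stop("`R` must lie in [0, 1]")
  Rc <- pmin(pmax(R, epsilon), 1 - epsilon)
  log(Rc / (1 - Rc))
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether angles are uniformly distributed on the circle using
#' `Z = n * R^2` and the standard approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - Z n)) - (1 + 2n))`.
#' A non-significant result marks chance-level (unsynchronized) tapping.
#'
#' @param angles Angles in radians; at least 4 required.
#' @return List with `Z`, `p` and `n`; `p = NA` when `n < 4`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 4L) return(list(Z = NA_real_, p = NA_real_, n = n))
  R <- mean_resultant(angles)$R
  Z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Z * n)) - (1 + 2 * n))
  list(Z = Z, p = min(max(p, .Machine$double.xmin), 1), n = n)
}

#' Ratio of modified Bessel functions I1/I0
#'
#' The population mean resultant length of a von Mises distribution with
#' concentration `kappa`: `A(kappa) = I1(kappa) / I0(kappa)`. Computed
#' with exponentially scaled Bessel functions so large `kappa` does not
#' overflow.
#'
#' @param kappa Concentration(s), `>= 0`; `Inf` allowed (returns 1).
#' @return Values in `[0, 1)` (1 at `kappa = Inf`).
#' @export
bessel_ratio <- function(kappa) {
  if (any(kappa < 0)) stop("`kappa` must be >= 0")
  out <- ifelse(is.infinite(kappa), 1,
                besselI(kappa, 1, expon.scaled = TRUE) /
                  besselI(kappa, 0, expon.scaled = TRUE))
  as.numeric(out)
}

#' Invert the Bessel ratio
#'
#' Finds the von Mises concentration whose population mean resultant
#' length equals `R`: the generative counterpart of a target consistency
#' score. Uses root finding on [bessel_ratio()].
#'
#' @param R Target mean resultant length(s) in `[0, 1)`.
#' @return Concentration(s) `kappa >= 0`.
#' @export
kappa_from_R <- function(R) {
  vapply(R, function(r) {
    if (!is.finite(r) || r < 0 || r >= 1) stop("`R` must lie in [0, 1)")
    if (r == 0) return(0)
    upper <- 2
    while (bessel_ratio(upper) < r) upper <- upper * 2
    stats::uniroot(function(k) bessel_ratio(k) - r, c(0, upper),
                   tol = 1e-10)$root
  }, numeric(1))
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler (wrapped-Cauchy envelope). `kappa = 0`
#' yields the uniform circular distribution; `kappa = Inf` returns the
#' mean direction exactly (noise-free limit).
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians.
#' @param kappa Concentration, `>= 0` (Inf allowed).
#' @return Angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("`kappa` must be >= 0")
  if (n == 0L) return(numeric(0))
  if (is.infinite(kappa)) return(rep(wrap_angle(mu), n))
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- n - length(out)
    z <- cos(pi * stats::runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(stats::runif(m) - 0.5) * acos(pmin(pmax(f, -1), 1))
    out <- c(out, theta[keep])
  }
  wrap_angle(out[seq_len(n)] + mu)
}

#' Wrap angles to (-pi, pi]
#'
#' @param theta Angles in radians.
#' @return Equivalent angles in `(-pi, pi]`.
#' @export
wrap_angle <- function(theta) {
  out <- theta - 2 * pi * floor(theta / (2 * pi) + 0.5)
  # floor(+0.5) maps the boundary to -pi; the convention here is +pi
  out[out <= -pi] <- pi
  out
}
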