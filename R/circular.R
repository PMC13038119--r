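# Circular arithmetic, von Mises density, and posterior summaries.
#
# Convention: data I/O is in degrees on [0, 360); signed errors are degrees on
# [-180, 180) (the 180-degree ambiguity resolves to -180). All likelihood
# computations are on the radian scale; conversion happens only at the
# boundary of the public functions.

DEG2RAD <- pi / 180

#' Wrap angles to the canonical degree range
#'
#' `wrap_angle()` maps angles to `[0, 360)`; `wrap_error()` maps signed
#' angular differences to `[-180, 180)`. Wrapping is idempotent and
#' periodic: `wrap_angle(a + 360) == wrap_angle(a)`.
#'
#' @param deg Numeric vector of angles in degrees.
#' @return Numeric vector of the same length.
#' @export
wrap_angle <- function(deg) {
  if (!is.numeric(deg) || any(!is.finite(deg))) {
    stop("angles must be finite numeric values", call. = FALSE)
  }
  deg %% 360
}

#' @rdname wrap_angle
#' @export
wrap_error <- function(deg) {
  if (!is.numeric(deg) || any(!is.finite(deg))) {
    stop("angles must be finite numeric values", call. = FALSE)
  }
  ((deg + 180) %% 360) - 180
}

#' Signed angular error of a response
#'
#' Computes the angular deviation of a reproduced feature from the true
#' feature on a 360-degree circular scale, wrapped to `[-180, 180)`.
#' Antisymmetric up to the wrap: `angular_error(a, b) == -angular_error(b, a)`
#' except when the deviation is exactly 180 degrees, which maps to -180 by
#' the half-open convention.
#'
#' @param response,target Numeric vectors of angles in degrees (recycled to a
#'   common length).
#' @return Signed errors in degrees on `[-180, 180)`.
#' @examples
#' angular_error(350, 10)  # -20
#' angular_error(190, 10)  # -180 (boundary case)
#' @export
angular_error <- function(response, target) {
  if (!is.numeric(response) || !is.numeric(target) ||
      any(!is.finite(response)) || any(!is.finite(target))) {
    stop("response and target must be finite numeric angles", call. = FALSE)
  }
  wrap_error(response - target)
}

# log of the modified Bessel function I0; asymptotic expansion beyond the
# range of besselI so extreme concentration proposals stay finite
log_bessel_i0 <- function(kappa) {
  out <- numeric(length(kappa))
  big <- kappa > 700
  if (any(big)) {
    k <- kappa[big]
    out[big] <- k - 0.5 * log(2 * pi * k) + log1p(1 / (8 * k))
  }
  if (any(!big)) {
    out[!big] <- log(besselI(kappa[!big], nu = 0, expon.scaled = TRUE)) +
      kappa[!big]
  }
  out
}

#' Von Mises density
#'
#' Density of the von Mises distribution, the normal distribution on the
#' circle, with mean `mu` and concentration (precision) `kappa`, evaluated on
#' the radian scale. `kappa = 0` gives the circular uniform density
#' `1 / (2 * pi)`, which is the identity the mixture models below rely on.
#'
#' @param theta Numeric vector of angles in radians.
#' @param mu Mean direction in radians.
#' @param kappa Concentration parameter, `kappa >= 0`.
#' @param log If `TRUE`, return the log density.
#' @return Densities (per radian) at `theta`.
#' @export
dvonmises <- function(theta, mu = 0, kappa = 1, log = FALSE) {
  if (!is.numeric(kappa) || any(!is.finite(kappa)) || any(kappa < 0)) {
    stop("kappa must be finite and >= 0", call. = FALSE)
  }
  ld <- kappa * cos(theta - mu) - log(2 * pi) - log_bessel_i0(kappa)
  if (log) ld else exp(ld)
}

#' Highest-density interval of a posterior sample
#'
#' The smallest contiguous interval containing at least `mass` of the
#' samples: among all windows of `ceiling(mass * n)` consecutive order
#' statistics, the narrowest is returned, ties broken by the lowest starting
#' index. Operates on raw draws pooled across chains.
#'
#' @param samples Numeric vector of at least 2 posterior draws.
#' @param mass Probability mass of the interval, in (0, 1). Default 0.95.
#' @return A one-row tibble with columns `low`, `high`, `mass`.
#' @export
hdi <- function(samples, mass = 0.95) {
  if (length(samples) < 2 || any(!is.finite(samples))) {
    stop("hdi() needs at least 2 finite samples", call. = FALSE)
  }
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass >= 1) {
    stop("mass must be a single value in (0, 1)", call. = FALSE)
  }
  x <- sort(samples)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) {
    lo <- x[1]
    hi <- x[n]
  } else {
    # window i covers x[i] .. x[i + k - 1]; which.min takes the first minimum
    widths <- x[k:n] - x[1:(n - k + 1)]
    i <- which.min(widths)
    lo <- x[i]
    hi <- x[i + k - 1]
  }
  tibble::tibble(low = lo, high = hi, mass = mass)
}

#' Posterior mode from MCMC draws
#'
#' The parameter value with the highest posterior density, estimated as the
#' argmax of a Gaussian kernel density with Silverman's rule-of-thumb
#' bandwidth on a 512-point grid spanning the sample range.
#'
#' @param samples Numeric vector of at least 2 posterior draws.
#' @return The estimated mode (scalar).
#' @export
posterior_mode <- function(samples) {
  if (length(samples) < 2 || any(!is.finite(samples))) {
    stop("posterior_mode() needs at least 2 finite samples", call. = FALSE)
  }
  rng <- range(samples)
  if (rng[1] == rng[2]) {
    return(rng[1])
  }
  d <- stats::density(samples, bw = "nrd0", n = 512, from = rng[1], to = rng[2])
  d$x[which.max(d$y)]
}

#' Circular resultant length
#'
#' Mean resultant length of a set of angles: 1 for a point mass, near 0 for a
#' circular uniform sample. Used to summarize how concentrated an error
#' distribution is (e.g., for self-reported guesses).
#'
#' @param deg Numeric vector of angles in degrees.
#' @return A value in `[0, 1]`.
#' @export
resultant_length <- function(deg) {
  if (length(deg) == 0) {
    return(NA_real_)
  }
  th <- deg * DEG2RAD
  sqrt(mean(cos(th))^2 + mean(sin(th))^2)
}
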