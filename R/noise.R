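#' Rician noise model
#'
#' The Rician scale `sigma` is the per-magnitude-image noise standard
#' deviation in b0-normalized signal units.  The same `sigma` applies to all
#' shells of a voxel (one noise map).  `n_dirs_averaged` records how many
#' magnitude images are averaged per shell in the powder average: the Rician
#' bias of the average equals the average of the per-image biases, so the
#' floor transform uses `sigma` itself, while the Gaussian spread of the
#' average scales with `1/sqrt(n_dirs_averaged)` in simulations.
#'
#' @param sigma Rician scale, >= 0.
#' @param n_dirs_averaged magnitude images averaged per shell, >= 1.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(sigma, n_dirs_averaged = 1L) {
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (n_dirs_averaged < 1) stop("n_dirs_averaged must be >= 1", call. = FALSE)
  structure(list(sigma = sigma, n_dirs_averaged = as.integer(n_dirs_averaged)),
            class = "noise_model")
}

#' Expected magnitude of a Rician-distributed measurement
#'
#' For a noise-free magnitude `nu` and independent Gaussian noise of
#' standard deviation `sigma` on both quadrature channels, the expected
#' magnitude is `sigma * sqrt(pi/2) * L_{1/2}(-nu^2 / (2 sigma^2))` with
#' `L_{1/2}` the generalized Laguerre function.  At `nu = 0` this is the
#' Rician noise floor `sigma * sqrt(pi/2)`; for large `nu/sigma` it
#' approaches `sqrt(nu^2 + sigma^2)`.
#'
#' The Laguerre expression is evaluated with exponentially-scaled Bessel
#' functions `I0`, `I1`; above `nu/sigma > 30` the asymptotic series
#' `nu + sigma^2/(2 nu) - sigma^4/(8 nu^3)` is used.
#'
#' @param nu noise-free magnitude(s), >= 0; vectorized.
#' @param sigma Rician scale, >= 0 (scalar or vector).
#' @return expected magnitude(s); monotone increasing in `nu` and bounded
#'   below by `max(nu, sigma * sqrt(pi/2))`.
#' @export
rician_mean <- function(nu, sigma) {
  if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  if (any(!is.finite(nu)) || any(nu < 0)) stop("nu must be finite and >= 0", call. = FALSE)
  n <- max(length(nu), length(sigma))
  nu <- rep_len(nu, n); sigma <- rep_len(sigma, n)
  out <- numeric(n)
  zero <- sigma == 0
  out[zero] <- nu[zero]
  big <- !zero & nu / sigma > 30
  if (any(big)) {
    s2 <- sigma[big]^2
    out[big] <- nu[big] + s2 / (2 * nu[big]) - s2^2 / (8 * nu[big]^3)
  }
  lag <- !zero & !big
  if (any(lag)) {
    t <- nu[lag]^2 / (2 * sigma[lag]^2)
    i0 <- besselI(t / 2, 0, expon.scaled = TRUE)
    i1 <- besselI(t / 2, 1, expon.scaled = TRUE)
    out[lag] <- sigma[lag] * sqrt(pi / 2) * ((1 + t) * i0 + t * i1)
  }
  out
}

#' Apply the Rician noise-floor transform to a model signal curve
#'
#' Elementwise [rician_mean()] of a (b0-normalized) predicted curve, used to
#' transform model predictions before computing fit residuals so that the
#' noise floor of high-b shells is part of the model rather than a bias.
#'
#' @param curve numeric vector (or matrix, row per curve) of signal values.
#' @param noise a [noise_model()] or a numeric sigma.
#' @return transformed curve of the same shape.
#' @export
apply_floor <- function(curve, noise) {
  sigma <- if (inherits(noise, "noise_model")) noise$sigma else as.numeric(noise)
  if (sigma == 0) return(curve)
  if (is.matrix(curve)) {
    out <- rician_mean(as.vector(curve), sigma)
    dim(out) <- dim(curve)
    out
  } else {
    rician_mean(curve, sigma)
  }
}

#' Draw Rician-distributed magnitudes
#'
#' Samples `|nu + e1 + i e2|` with `e1, e2 ~ N(0, sigma^2)` independent.
#'
#' @param nu noise-free magnitude(s); recycled against `n` if scalar.
#' @param sigma Rician scale.
#' @param n number of draws (per element of `nu` when `nu` is scalar;
#'   otherwise `length(nu)` draws are returned and `n` is ignored).
#' @param seed integer seed; required for reproducibility.
#' @return numeric vector of magnitudes.
#' @export
sample_rician <- function(nu, sigma, n = length(nu), seed) {
  if (!missing(seed)) set.seed(seed)
  if (length(nu) == 1) nu <- rep(nu, n)
  n <- length(nu)
  if (sigma == 0) return(nu)
  sqrt((nu + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}
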