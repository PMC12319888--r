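#' Tissue parameter vector for the exchange models
#'
#' Both NEXI and SMEX share the parameter vector `p = [t_ex, D_i, D_e, f]`:
#' inter-compartment exchange time (ms), intra-neurite diffusivity (um^2/ms),
#' extra-neurite diffusivity (um^2/ms), and intra-neurite signal fraction.
#'
#' @param t_ex exchange time in ms (> 0).
#' @param D_i intra-neurite (stick) diffusivity in um^2/ms (> 0).
#' @param D_e extra-neurite isotropic diffusivity in um^2/ms (> 0).
#' @param f intra-neurite signal fraction in `[0, 1]`.
#' @return named numeric vector of class `tissue_params`.
#' @export
tissue_params <- function(t_ex, D_i, D_e, f) {
  p <- c(t_ex = as.numeric(t_ex), D_i = as.numeric(D_i),
         D_e = as.numeric(D_e), f = as.numeric(f))
  if (any(!is.finite(p))) stop("non-finite tissue parameters", call. = FALSE)
  if (t_ex <= 0 || D_i <= 0 || D_e <= 0) stop("t_ex, D_i, D_e must be > 0", call. = FALSE)
  if (f < 0 || f > 1) stop("f must lie in [0, 1]", call. = FALSE)
  structure(p, class = "tissue_params")
}

# accept a tissue_params vector, an unnamed length-4 vector in
# [t_ex, D_i, D_e, f] order, or a matrix with one parameter set per row
as_param_matrix <- function(params) {
  if (is.matrix(params)) {
    if (ncol(params) != 4) stop("parameter matrix must have 4 columns", call. = FALSE)
    return(unname(params))
  }
  p <- as.numeric(params)
  if (length(p) != 4) stop("expected 4 parameters [t_ex, D_i, D_e, f]", call. = FALSE)
  matrix(p, nrow = 1)
}

# Gauss-Legendre nodes/weights on [0, 1], cached per order
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre_01 <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    gl <- pracma::gaussLegendre(n, 0, 1)
    .gl_cache[[key]] <- list(x = gl$x, w = gl$w)
  }
  .gl_cache[[key]]
}

#' NEXI kernel along a single orientation
#'
#' The two-compartment Karger solution at orientation cosine `u = g.n`:
#' `1' expm((R - q^2 D) t_d) (f, 1-f)'` with `D = diag(D_i u^2, D_e)`,
#' evaluated via the closed-form eigendecomposition of the 2x2 matrix.
#'
#' @param u orientation cosine(s) in `[0, 1]`; vectorized.
#' @param params tissue parameters (see [tissue_params()]).
#' @param q wave number in 1/um.
#' @param t_d effective diffusion time in ms.
#' @return kernel value(s), in `(0, 1]` for physical inputs.
#' @export
nexi_kernel <- function(u, params, q, t_d) {
  p <- drop(as_param_matrix(params))
  if (any(!is.finite(u)) || !is.finite(q) || !is.finite(t_d))
    stop("non-finite inputs to nexi_kernel", call. = FALSE)
  if (q < 0 || t_d <= 0) stop("need q >= 0 and t_d > 0", call. = FALSE)
  nexi_kernel_cpp(u, p[1], p[2], p[3], p[4], q, t_d)
}

# R-level kernel, valid for complex parameters (used for the complex-step
# Jacobian); mirrors the closed form in src/forward.cpp
nexi_kernel_generic <- function(u, tex, Di, De, f, q2, td) {
  kie <- (1 - f) / tex; kei <- f / tex
  a <- -kie - q2 * Di * u^2
  d <- -kei - q2 * De
  disc <- sqrt((a - d)^2 + 4 * kei * kie)
  l1 <- (a + d + disc) / 2; l2 <- (a + d - disc) / 2
  c0 <- -q2 * (f * Di * u^2 + (1 - f) * De)
  (exp(l1 * td) * (c0 - l2) - exp(l2 * td) * (c0 - l1)) / (l1 - l2)
}

shell_quadrature_check <- function(values32, values64) {
  max(abs(values32 - values64))
}

#' Powder-averaged NEXI signal
#'
#' Integrates the Karger kernel over the orientation cosine,
#' `S(b, t_d) = int_0^1 K(u) du`, by fixed-order Gauss-Legendre quadrature
#' (32 nodes by default; the integrand is smooth in `u`).  b = 0 shells
#' return exactly 1.
#'
#' @param params tissue parameters, or a matrix with one parameter set per
#'   row (columns `t_ex, D_i, D_e, f`).
#' @param protocol an [acq_protocol()] object.
#' @param n_nodes Gauss-Legendre order.
#' @param check_quadrature if `TRUE`, re-evaluate with twice the nodes and
#'   warn when any shell changes by more than 1e-8.
#' @return numeric vector of per-shell signals (or a matrix, one row per
#'   parameter set), aligned to the protocol shell order.
#' @export
nexi_signal <- function(params, protocol, n_nodes = 32, check_quadrature = FALSE) {
  stopifnot(inherits(protocol, "acq_protocol"))
  pm <- as_param_matrix(params)
  gl <- gauss_legendre_01(n_nodes)
  out <- nexi_curves_cpp(pm, protocol$b, protocol$t_d, gl$x, gl$w)
  if (check_quadrature) {
    gl2 <- gauss_legendre_01(2 * n_nodes)
    out2 <- nexi_curves_cpp(pm, protocol$b, protocol$t_d, gl2$x, gl2$w)
    if (shell_quadrature_check(out, out2) > 1e-8)
      warning("orientation quadrature not converged at ", n_nodes, " nodes")
  }
  if (nrow(pm) == 1) drop(out) else out
}

#' Powder-averaged SMEX signal (finite gradient pulses)
#'
#' Integrates the generalized rate equation `dM/dt = (R - k(t)^2 D) M`
#' through a rectangular PGSE waveform: `k(t)` ramps linearly over the pulse
#' duration `[0, delta]`, is constant at `q_max = sqrt(b / (Delta - delta/3))`
#' on `[delta, Delta]`, and ramps down over `[Delta, Delta + delta]`.  The
#' constant plateau uses the analytic matrix-exponential propagator; both
#' ramps are integrated with an adaptive Dormand-Prince RK45 (both pulses
#' explicitly -- `R` and `D` do not commute, so no symmetry shortcut is
#' taken).  The result is orientation-averaged as in [nexi_signal()].
#'
#' @inheritParams nexi_signal
#' @param rtol,atol relative/absolute tolerance of the ramp integrator.
#' @return per-shell signals as in [nexi_signal()].
#' @export
smex_signal <- function(params, protocol, n_nodes = 32, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(protocol, "acq_protocol"))
  pm <- as_param_matrix(params)
  gl <- gauss_legendre_01(n_nodes)
  out <- smex_curves_cpp(pm, protocol$b, protocol$Delta, protocol$delta,
                         gl$x, gl$w, rtol, atol)
  if (nrow(pm) == 1) drop(out) else out
}

#' Evaluate either forward model by name
#'
#' @param model `"nexi"` or `"smex"`.
#' @inheritParams nexi_signal
#' @param ... passed to the model function.
#' @return per-shell signals.
#' @export
model_signal <- function(model = c("nexi", "smex"), params, protocol, ...) {
  model <- match.arg(tolower(model), c("nexi", "smex"))
  if (model == "nexi") nexi_signal(params, protocol, ...)
  else smex_signal(params, protocol, ...)
}

#' Sensitivity of the forward signal to the tissue parameters
#'
#' Returns the per-shell Jacobian `dS/dp` with columns ordered
#' `(t_ex, D_i, D_e, f)`.  For NEXI the derivatives are obtained by
#' complex-step differentiation of the closed-form kernel (machine-precision,
#' no truncation error); for SMEX, by central finite differences through the
#' ODE forward model with tightened integrator tolerances.
#'
#' @param model `"nexi"` or `"smex"`.
#' @param params tissue parameters.
#' @param protocol an [acq_protocol()] object.
#' @param n_nodes Gauss-Legendre order for the orientation average.
#' @return matrix with one row per protocol shell and 4 columns.
#' @export
model_jacobian <- function(model = c("nexi", "smex"), params, protocol,
                           n_nodes = 32) {
  model <- match.arg(tolower(model), c("nexi", "smex"))
  p <- drop(as_param_matrix(params))
  gl <- gauss_legendre_01(n_nodes)
  ns <- nrow(protocol)
  J <- matrix(0, ns, 4, dimnames = list(NULL, c("t_ex", "D_i", "D_e", "f")))
  bpos <- !protocol$is_b0
  if (!any(bpos)) return(J)
  if (model == "nexi") {
    h <- 1e-100  # complex step: derivative = Im(S(p + ih)) / h, no cancellation
    for (j in 1:4) {
      pc <- as.complex(p)
      pc[j] <- pc[j] + 1i * h
      for (s in which(bpos)) {
        q2 <- protocol$b[s] / protocol$t_d[s]
        ker <- nexi_kernel_generic(gl$x, pc[1], pc[2], pc[3], pc[4], q2,
                                   protocol$t_d[s])
        J[s, j] <- sum(gl$w * Im(ker)) / h
      }
    }
  } else {
    # relative central differences; cube-root-of-eps step balances
    # truncation against the integrator noise floor
    for (j in 1:4) {
      h <- max(abs(p[j]), 1e-3) * 6e-6
      pp <- p; pp[j] <- pp[j] + h
      pmn <- p; pmn[j] <- pmn[j] - h
      Sp <- smex_signal(pp, protocol, n_nodes = n_nodes, rtol = 1e-10, atol = 1e-12)
      Sm <- smex_signal(pmn, protocol, n_nodes = n_nodes, rtol = 1e-10, atol = 1e-12)
      J[, j] <- (Sp - Sm) / (2 * h)
    }
    J[!bpos, ] <- 0
  }
  J
}
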