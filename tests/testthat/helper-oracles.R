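# Shared fixtures and independent oracles for the test suite.

mid_params <- c(t_ex = 30, D_i = 3, D_e = 1, f = 0.4)

# analytic powder average of impermeable sticks + ball (no-exchange limit):
# f * sqrt(pi/(4 b D_i)) erf(sqrt(b D_i)) + (1 - f) exp(-b D_e)
stick_ball_signal <- function(b, D_i, D_e, f) {
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  ifelse(b == 0, 1,
         f * sqrt(pi / (4 * b * D_i)) * erf(sqrt(b * D_i)) +
           (1 - f) * exp(-b * D_e))
}

# dense brute-force SMEX oracle: integrate dM/dt = (R - k(t)^2 D) M over the
# whole interval [0, Delta + delta] with deSolve (no analytic plateau),
# then average over the same Gauss-Legendre orientation nodes.
smex_dense_oracle <- function(params, b, Delta, delta, n_nodes = 32) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  tex <- params[1]; Di <- params[2]; De <- params[3]; f <- params[4]
  kie <- (1 - f) / tex; kei <- f / tex
  td <- Delta - delta / 3
  q2 <- b / td
  gl <- pracma::gaussLegendre(n_nodes, 0, 1)
  vapply(seq_len(n_nodes), function(k) {
    u2 <- gl$x[k]^2
    rhs <- function(t, M, parms) {
      w <- if (t <= delta) t / delta
           else if (t <= Delta) 1
           else (Delta + delta - t) / delta
      w2 <- w * w
      list(c(-(kie + w2 * q2 * Di * u2) * M[1] + kei * M[2],
             kie * M[1] - (kei + w2 * q2 * De) * M[2]))
    }
    sol <- deSolve::ode(c(f, 1 - f), c(0, Delta + delta), rhs, NULL,
                        method = "lsoda", rtol = 1e-11, atol = 1e-13)
    sum(sol[2, 2:3])
  }, numeric(1)) |> (\(v) sum(gl$w * v))()
}

# numeric-quadrature oracle for the Rician expectation:
# E|X| with X = sqrt((nu + e1)^2 + e2^2); the density is written with the
# exponentially-scaled Bessel so the integrand stays finite at high SNR
rician_mean_quadrature <- function(nu, sigma) {
  integrand <- function(x)
    x^2 / sigma^2 * exp(-(x - nu)^2 / (2 * sigma^2)) *
      besselI(x * nu / sigma^2, 0, expon.scaled = TRUE)
  stats::integrate(integrand, max(0, nu - 12 * sigma), nu + 12 * sigma,
                   rel.tol = 1e-12)$value
}

# memoised 500-voxel NEXI noise-propagation study (shared between the
# synthetic-module property tests and the acceptance suite)
.study_cache <- new.env(parent = emptyenv())
cached_nexi_study <- function() {
  if (is.null(.study_cache$nexi)) {
    gt <- sample_ground_truth(500, seed = 20260922)
    .study_cache$nexi <- recovery_study(
      gt,
      scenarios = list(list(delta = 16.5, models = "nexi"),
                       list(delta = 4, models = "nexi")),
      generating_model = "smex", sigma = 0.02, seed = 7)
  }
  .study_cache$nexi
}
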