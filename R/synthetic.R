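#' Draw ground-truth tissue parameters from flat ranges
#'
#' Uniform independent draws per parameter.  The default ranges span the
#' plausible cortical gray-matter values used for noise-propagation
#' studies: `t_ex` in \[1, 40\] ms, `D_i` in \[2.5, 3.5\] and `D_e` in
#' \[0.5, 1.5\] um^2/ms, `f` in \[0.2, 0.7\].
#'
#' @param n number of parameter sets.
#' @param ranges named list of `c(lo, hi)` ranges for `t_ex`, `D_i`, `D_e`,
#'   `f`.  Degenerate ranges `c(a, a)` pin a parameter.
#' @param seed integer seed (draws are deterministic under it).
#' @param require_di_gt_de keep only draws with `D_i > D_e` (redrawing
#'   until `n` are collected).
#' @return object of class `ground_truth`: list with `params` (n x 4
#'   matrix, columns `t_ex, D_i, D_e, f`), `source`, `seed`.
#' @export
sample_ground_truth <- function(n,
                                ranges = list(t_ex = c(1, 40), D_i = c(2.5, 3.5),
                                              D_e = c(0.5, 1.5), f = c(0.2, 0.7)),
                                seed = 1L, require_di_gt_de = FALSE) {
  stopifnot(n >= 1)
  for (nm in c("t_ex", "D_i", "D_e", "f")) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2 || r[1] > r[2])
      stop("range for ", nm, " must be c(lo, hi) with lo <= hi", call. = FALSE)
  }
  set.seed(seed)
  draw <- function(m) {
    cbind(t_ex = stats::runif(m, ranges$t_ex[1], ranges$t_ex[2]),
          D_i = stats::runif(m, ranges$D_i[1], ranges$D_i[2]),
          D_e = stats::runif(m, ranges$D_e[1], ranges$D_e[2]),
          f = stats::runif(m, ranges$f[1], ranges$f[2]))
  }
  params <- draw(n)
  if (require_di_gt_de) {
    keep <- params[, "D_i"] > params[, "D_e"]
    params <- params[keep, , drop = FALSE]
    while (nrow(params) < n) {
      extra <- draw(n)
      extra <- extra[extra[, "D_i"] > extra[, "D_e"], , drop = FALSE]
      params <- rbind(params, extra)
    }
    params <- params[seq_len(n), , drop = FALSE]
  }
  structure(list(params = params, source = "flat_ranges", seed = seed),
            class = "ground_truth")
}

#' Pack user-supplied parameter sets as a ground-truth object
#'
#' @param params matrix or data frame with columns `t_ex`, `D_i`, `D_e`, `f`.
#' @return a `ground_truth` object.
#' @export
ground_truth_table <- function(params) {
  params <- as.matrix(params[, c("t_ex", "D_i", "D_e", "f")])
  structure(list(params = params, source = "user_table", seed = NA_integer_),
            class = "ground_truth")
}

#' Generate a synthetic noisy dataset from ground-truth parameters
#'
#' For every voxel, the noiseless forward signal is computed per shell and
#' `n_dirs` Rician magnitudes are drawn around it and averaged, mimicking
#' the powder average over gradient directions (b = 0 shells get a single
#' draw).  Every shell is then normalized by the noisy b = 0 draw of its
#' diffusion time, emulating the real pipeline including the normalization
#' noise.
#'
#' @param gt a `ground_truth` object (see [sample_ground_truth()]).
#' @param protocol an [acq_protocol()] object.
#' @param model generating model, `"smex"` (default) or `"nexi"`.
#' @param sigma Rician scale per magnitude image, in b0-normalized units.
#' @param n_dirs magnitude draws averaged per b > 0 shell.
#' @param seed integer seed; the dataset is bit-identical under it.
#' @param as_volume also materialize the per-direction draws as a 4D array
#'   `[n, 1, 1, volumes]` with its per-volume table, for end-to-end tests
#'   of the image pipeline.
#' @return list with `curves` (voxels x shells, normalized), `noiseless`
#'   (same shape, before noise), `protocol`, `gt`, `sigma`, `n_dirs`,
#'   `seed`, and (when `as_volume`) `volume` and `vols`.
#' @export
generate_dataset <- function(gt, protocol, model = c("smex", "nexi"),
                             sigma = 0.02, n_dirs = 20L, seed = 1L,
                             as_volume = FALSE) {
  model <- match.arg(tolower(model), c("smex", "nexi"))
  stopifnot(inherits(protocol, "acq_protocol"), sigma >= 0, n_dirs >= 1)
  params <- gt$params
  nvox <- nrow(params)
  noiseless <- model_signal(model, params, protocol)
  if (nvox == 1) noiseless <- matrix(noiseless, 1)
  nshell <- nrow(protocol)
  set.seed(seed)
  draws_per_shell <- ifelse(protocol$is_b0, 1L, as.integer(n_dirs))
  raw <- vector("list", nshell)  # per shell: voxels x draws magnitudes
  for (s in seq_len(nshell)) {
    nd <- draws_per_shell[s]
    if (sigma == 0) {
      raw[[s]] <- matrix(noiseless[, s], nvox, nd)
    } else {
      e1 <- matrix(stats::rnorm(nvox * nd, 0, sigma), nvox, nd)
      e2 <- matrix(stats::rnorm(nvox * nd, 0, sigma), nvox, nd)
      raw[[s]] <- sqrt((noiseless[, s] + e1)^2 + e2^2)
    }
  }
  shell_mean <- vapply(raw, rowMeans, numeric(nvox))
  if (nvox == 1) shell_mean <- matrix(shell_mean, 1)
  curves <- shell_mean
  for (D in unique(protocol$Delta)) {
    sh <- which(protocol$Delta == D)
    b0 <- sh[protocol$is_b0[sh]]
    ref <- if (length(b0) == 1) shell_mean[, b0] else rowMeans(shell_mean[, b0, drop = FALSE])
    curves[, sh] <- curves[, sh, drop = FALSE] / ref
  }
  out <- list(curves = curves, noiseless = noiseless, protocol = protocol,
              gt = gt, sigma = sigma, n_dirs = as.integer(n_dirs), seed = seed)
  if (as_volume) {
    vols <- volume_table(protocol)
    vol4 <- array(NA_real_, c(nvox, 1, 1, nrow(vols)))
    col <- 1L
    for (s in seq_len(nshell)) {
      for (d in seq_len(draws_per_shell[s])) {
        vol4[, 1, 1, col] <- raw[[s]][, d]
        col <- col + 1L
      }
    }
    out$volume <- vol4
    out$vols <- vols[c("b", "Delta", "delta")]
  }
  out
}

#' Noise-propagation recovery study
#'
#' Generates synthetic signals with the finite-pulse model (SMEX) under one
#' or more pulse-duration scenarios, fits them with the requested models
#' using the standard grid-search + floor-corrected NLS routine, and
#' reports per-parameter bias and RMSE together with the paired
#' (truth, estimate) values.  Estimates from voxels whose fit hit a bound
#' or failed to converge are discarded from the summary, as is standard for
#' such studies.
#'
#' @param gt a `ground_truth` object.
#' @param scenarios list of scenarios, each a list with `delta` (pulse
#'   duration in ms; Delta and b of the clinical protocol are unchanged)
#'   and `models` (character vector of models to fit).
#' @param generating_model model used to synthesize the signals.
#' @param sigma Rician scale of the added noise.
#' @param n_dirs magnitude draws averaged per shell.
#' @param seed integer seed for the noise.
#' @param bounds a [fit_bounds()] object.
#' @param filter_bound_hits drop voxels whose estimate sits at a bound.
#' @param n_workers forked workers for the fits.
#' @return list of class `recovery_report` keyed by scenario label
#'   (`"delta16.5"` etc.); each scenario holds one entry per fitted model
#'   with `bias`, `rmse`, `truth`, `est`, `kept`, `n_kept`.
#' @export
recovery_study <- function(gt,
                           scenarios = list(
                             list(delta = 16.5, models = c("nexi", "smex")),
                             list(delta = 4, models = c("nexi", "smex"))),
                           generating_model = "smex", sigma = 0.02,
                           n_dirs = 20L, seed = 1L, bounds = fit_bounds(),
                           filter_bound_hits = TRUE, n_workers = 1L) {
  out <- list()
  for (sc in scenarios) {
    proto <- clinical_protocol(delta = sc$delta)
    ds <- generate_dataset(gt, proto, model = generating_model, sigma = sigma,
                           n_dirs = n_dirs, seed = seed)
    label <- paste0("delta", format(sc$delta))
    out[[label]] <- list(delta = sc$delta, sigma = sigma)
    for (model in sc$models) {
      fits <- fit_curves(ds$curves, proto, sigma, model = model,
                         bounds = bounds, n_workers = n_workers)
      est <- t(vapply(fits, function(f) f$params, numeric(4)))
      colnames(est) <- c("t_ex", "D_i", "D_e", "f")
      ok <- vapply(fits, function(f) f$converged, logical(1))
      if (filter_bound_hits)
        ok <- ok & !vapply(fits, function(f) any(f$at_bound), logical(1))
      truth <- gt$params
      err <- est[ok, , drop = FALSE] - truth[ok, , drop = FALSE]
      out[[label]][[model]] <- list(
        bias = colMeans(err),
        rmse = sqrt(colMeans(err^2)),
        truth = truth[ok, , drop = FALSE],
        est = est[ok, , drop = FALSE],
        kept = which(ok), n_kept = sum(ok)
      )
    }
  }
  structure(out, class = "recovery_report")
}

#' Fit a stack of signal curves
#'
#' Applies [fit_curve()] to each row of a curve matrix, optionally over
#' forked workers.  Deterministic: worker count never changes the result.
#'
#' @param curves matrix, one curve per row, shells in protocol order.
#' @param protocol an [acq_protocol()] object.
#' @param sigma Rician scale used in the floor-corrected objective.
#' @param model `"nexi"` or `"smex"`.
#' @param bounds a [fit_bounds()] object.
#' @param n_workers forked workers.
#' @return list of `fit_result` objects, one per row.
#' @export
fit_curves <- function(curves, protocol, sigma, model = c("nexi", "smex"),
                       bounds = fit_bounds(), n_workers = 1L) {
  model <- match.arg(tolower(model), c("nexi", "smex"))
  idx <- seq_len(nrow(curves))
  one <- function(i) fit_curve(curves[i, ], noise_model(sigma), model = model,
                               bounds = bounds, protocol = protocol)
  if (n_workers > 1) {
    # warm the grid-curve cache in the parent so forked workers inherit it
    invisible(grid_search(curves[1, ], sigma, model = model, bounds = bounds,
                          protocol = protocol))
    parallel::mclapply(idx, one, mc.cores = n_workers, mc.preschedule = TRUE)
  } else {
    lapply(idx, one)
  }
}
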