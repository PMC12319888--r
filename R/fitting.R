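#' Optimization bounds for the tissue parameters
#'
#' Defaults follow the fitting routine used for clinical-scanner data:
#' `t_ex` in \[1, 150\] ms, both diffusivities in \[0.1, 3.5\] um^2/ms and
#' `f` in \[0.1, 0.9\].
#'
#' @param t_ex,D_i,D_e,f numeric `c(lo, hi)` pairs.
#' @return object of class `fit_bounds`.
#' @export
fit_bounds <- function(t_ex = c(1, 150), D_i = c(0.1, 3.5),
                       D_e = c(0.1, 3.5), f = c(0.1, 0.9)) {
  b <- list(t_ex = as.numeric(t_ex), D_i = as.numeric(D_i),
            D_e = as.numeric(D_e), f = as.numeric(f))
  for (nm in names(b)) {
    if (length(b[[nm]]) != 2 || !all(is.finite(b[[nm]])) || b[[nm]][1] >= b[[nm]][2])
      stop("bound for ", nm, " must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  structure(b, class = "fit_bounds")
}

# cache of grid-search candidate curves, keyed by model/grid/shells
.grid_cache <- new.env(parent = emptyenv())

bounds_matrix <- function(bounds) {
  rbind(lo = c(bounds$t_ex[1], bounds$D_i[1], bounds$D_e[1], bounds$f[1]),
        hi = c(bounds$t_ex[2], bounds$D_i[2], bounds$D_e[2], bounds$f[2]))
}

#' A signal curve tied to its acquisition protocol
#'
#' Powder-averaged, b0-normalized signal values aligned to the shells of an
#' acquisition protocol (the fit target).
#'
#' @param values numeric vector, one value per protocol shell; must equal 1
#'   at b = 0 shells.
#' @param protocol an [acq_protocol()] object.
#' @return object of class `signal_curve`.
#' @export
signal_curve <- function(values, protocol) {
  stopifnot(inherits(protocol, "acq_protocol"))
  values <- as.numeric(values)
  if (length(values) != nrow(protocol))
    stop("curve length does not match protocol shell count", call. = FALSE)
  if (any(!is.finite(values))) stop("curve contains non-finite values", call. = FALSE)
  structure(list(values = values, protocol = protocol), class = "signal_curve")
}

resolve_curve <- function(curve, protocol) {
  if (inherits(curve, "signal_curve")) return(curve)
  signal_curve(curve, protocol)
}

floor_rss <- function(data_pos, model_pos, sigma) {
  pred <- apply_floor(model_pos, sigma)
  if (is.matrix(pred)) {
    rowSums((sweep(pred, 2, data_pos))^2)
  } else {
    sum((data_pos - pred)^2)
  }
}

#' Grid search for a nonlinear least-squares starting point
#'
#' Evaluates the Rician-floor-corrected residual sum of squares on a grid of
#' candidate parameters (log-spaced `t_ex` axis, linear axes for `D_i`,
#' `D_e`, `f`), restricted to candidates with `D_i > D_e`, and returns the
#' minimizer.  Only b > 0 shells enter the objective.
#'
#' For SMEX the grid is evaluated with relaxed numerical settings (fewer
#' orientation nodes, looser ODE tolerance): the grid is only an
#' initializer, and the relaxed forward model places the start in the same
#' basin at a fraction of the cost.
#'
#' @param curve a [signal_curve()], or a numeric vector with `protocol` given.
#' @param noise a [noise_model()] or numeric sigma.
#' @param model `"nexi"` or `"smex"`.
#' @param bounds a [fit_bounds()] object.
#' @param grid_sizes integer vector of grid points per axis
#'   `(t_ex, D_i, D_e, f)`.
#' @param protocol protocol, when `curve` is a bare numeric vector.
#' @param axes optional named list overriding the generated grid axes.
#' @return named parameter vector (the best grid point), with attribute
#'   `"rss"` carrying its objective value.
#' @export
grid_search <- function(curve, noise, model = c("nexi", "smex"),
                        bounds = fit_bounds(), grid_sizes = c(8, 8, 8, 8),
                        protocol = NULL, axes = NULL) {
  model <- match.arg(tolower(model), c("nexi", "smex"))
  curve <- resolve_curve(curve, protocol)
  proto <- curve$protocol
  sigma <- if (inherits(noise, "noise_model")) noise$sigma else as.numeric(noise)
  bpos <- !proto$is_b0
  if (sum(bpos) < 5)
    stop("need at least 5 b > 0 shells to fit 4 parameters", call. = FALSE)
  bm <- bounds_matrix(bounds)
  if (is.null(axes)) {
    axes <- list(
      t_ex = exp(seq(log(bm[1, 1]), log(bm[2, 1]), length.out = grid_sizes[1])),
      D_i = seq(bm[1, 2], bm[2, 2], length.out = grid_sizes[2]),
      D_e = seq(bm[1, 3], bm[2, 3], length.out = grid_sizes[3]),
      f = seq(bm[1, 4], bm[2, 4], length.out = grid_sizes[4])
    )
  }
  grid <- as.matrix(expand.grid(t_ex = axes$t_ex, D_i = axes$D_i,
                                D_e = axes$D_e, f = axes$f,
                                KEEP.OUT.ATTRS = FALSE))
  grid <- grid[grid[, "D_i"] > grid[, "D_e"], , drop = FALSE]
  if (nrow(grid) == 0)
    stop("no grid candidate satisfies D_i > D_e; check bounds/axes", call. = FALSE)
  subpos <- acq_protocol(proto$b[bpos], proto$Delta[bpos], proto$delta[bpos],
                         proto$n_dirs[bpos], name = attr(proto, "name"))
  # the candidate curves depend only on (model, grid, shells): cache them so
  # that fitting many voxels against one protocol pays the forward cost once
  key <- rlang::hash(list(model, grid, subpos$b, subpos$Delta, subpos$delta))
  curves <- .grid_cache[[key]]
  if (is.null(curves)) {
    curves <- if (model == "nexi") {
      nexi_signal(grid, subpos)
    } else {
      smex_signal(grid, subpos, n_nodes = 16, rtol = 1e-6, atol = 1e-8)
    }
    .grid_cache[[key]] <- curves
  }
  rss <- floor_rss(curve$values[bpos], curves, sigma)
  best <- which.min(rss)
  out <- grid[best, ]
  names(out) <- c("t_ex", "D_i", "D_e", "f")
  attr(out, "rss") <- rss[best]
  out
}

#' Fit a signal curve by Rician-floor-corrected nonlinear least squares
#'
#' Minimizes `sum_{b>0 shells} (data - E_Rice[model(p)])^2` with a bounded
#' quasi-Newton method (L-BFGS-B, convergence tolerance 1e-14 on the
#' objective scale), starting from the grid-search minimizer.  The
#' `D_i > D_e` constraint applies only to the initialization grid; during
#' the optimization the parameters move freely within the box bounds (it is
#' a soft constraint).  Parameters are optimized on a unit-scaled box for
#' even conditioning across their very different magnitudes.
#'
#' @inheritParams grid_search
#' @param init optional starting parameters; skips the grid search.
#' @param ... passed to [grid_search()].
#' @return object of class `fit_result`: list with elements `params`
#'   (named vector), `rss`, `n_points`, `aicc`, `at_bound` (named logical),
#'   `converged`, `init`, `model`.
#' @export
fit_curve <- function(curve, noise, model = c("nexi", "smex"),
                      bounds = fit_bounds(), protocol = NULL, init = NULL, ...) {
  model <- match.arg(tolower(model), c("nexi", "smex"))
  curve <- resolve_curve(curve, protocol)
  proto <- curve$protocol
  sigma <- if (inherits(noise, "noise_model")) noise$sigma else as.numeric(noise)
  bpos <- !proto$is_b0
  subpos <- acq_protocol(proto$b[bpos], proto$Delta[bpos], proto$delta[bpos],
                         proto$n_dirs[bpos], name = attr(proto, "name"))
  data_pos <- curve$values[bpos]
  bm <- bounds_matrix(bounds)
  lo <- bm["lo", ]; hi <- bm["hi", ]; span <- hi - lo

  if (is.null(init)) init <- grid_search(curve, noise, model, bounds, ...)
  init <- drop(as_param_matrix(init))
  x0 <- pmin(pmax((init - lo) / span, 0), 1)

  fwd <- if (model == "nexi") {
    function(p) nexi_signal(p, subpos)
  } else {
    function(p) smex_signal(p, subpos)
  }
  obj <- function(x) {
    p <- lo + x * span
    floor_rss(data_pos, fwd(p), sigma)
  }
  # central-difference gradient on the unit box, evaluated as one batched
  # forward-model call (4 forward + 4 backward perturbed parameter sets);
  # clipped one-sided at the box faces
  grad <- function(x) {
    h <- 1e-6
    X <- matrix(rep(x, 8), 8, 4, byrow = TRUE)
    xp <- pmin(x + h, 1)
    xm <- pmax(x - h, 0)
    X[1:4, ][cbind(1:4, 1:4)] <- xp
    X[5:8, ][cbind(1:4, 1:4)] <- xm
    P <- sweep(sweep(X, 2, span, "*"), 2, lo, "+")
    rss <- floor_rss(data_pos, fwd(P), sigma)
    (rss[1:4] - rss[5:8]) / (xp - xm)
  }
  rss0 <- obj(x0)
  res <- tryCatch(
    stats::optim(x0, obj, gr = grad, method = "L-BFGS-B", lower = 0, upper = 1,
                 control = list(factr = 45, pgtol = 0, maxit = 500)),
    error = function(e) NULL
  )
  if (is.null(res) || !is.finite(res$value) || res$value > rss0) {
    pars <- lo + x0 * span
    rss <- rss0
    converged <- FALSE
  } else {
    pars <- lo + res$par * span
    rss <- res$value
    converged <- res$convergence == 0
  }
  names(pars) <- c("t_ex", "D_i", "D_e", "f")
  at_bound <- (pars - lo < 1e-9 * span) | (hi - pars < 1e-9 * span)
  names(at_bound) <- names(pars)
  n_points <- sum(bpos)
  structure(list(
    params = pars, rss = rss, n_points = n_points,
    aicc = if (n_points > 5) aicc(max(rss, .Machine$double.xmin), n_points) else NA_real_,
    at_bound = at_bound, converged = converged,
    init = init, model = model
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit (%s, %d points): rss = %.3g, AICc = %.2f\n",
              toupper(x$model), if (x$converged) "converged" else "not converged",
              x$n_points, x$rss, x$aicc))
  print(round(x$params, 4))
  if (any(x$at_bound))
    cat("at bound:", paste(names(x$at_bound)[x$at_bound], collapse = ", "), "\n")
  invisible(x)
}

#' Corrected Akaike Information Criterion for a least-squares fit
#'
#' `AICc = n log(rss/n) + 2k + 2k(k+1)/(n-k-1)` under the Gaussian-residual
#' least-squares likelihood with the noise scale held fixed (not counted in
#' `k`).  A lower AICc indicates a better fit.
#'
#' @param rss residual sum of squares (> 0).
#' @param n_points number of fitted data points.
#' @param k number of free parameters (4 for NEXI/SMEX).
#' @return the criterion value.
#' @export
aicc <- function(rss, n_points, k = 4) {
  if (n_points <= k + 1)
    stop("AICc undefined for n_points <= k + 1", call. = FALSE)
  if (rss < 0) stop("rss must be >= 0", call. = FALSE)
  n_points * log(rss / n_points) + 2 * k + 2 * k * (k + 1) / (n_points - k - 1)
}

#' Voxelwise model fitting over a masked 4D acquisition
#'
#' Powder-averages and normalizes every masked voxel (see
#' [powder_average()]), fits it with [fit_curve()] using the voxel's sigma
#' from the noise map, and assembles 3D parameter maps.  Voxel order never
#' affects the results, and the fit is deterministic, so any worker count
#' yields identical maps.
#'
#' @param dwi 4D array (or `RNifti` image) of diffusion volumes.
#' @param protocol an [acq_protocol()] object describing the volume axis.
#' @param mask 3D logical/0-1 array; voxels outside are NaN in all outputs.
#' @param sigma_map 3D array of Rician sigma in b0-normalized units, or a
#'   single number used everywhere.
#' @param model `"nexi"` or `"smex"`.
#' @param bounds a [fit_bounds()] object.
#' @param n_workers forked workers for the voxel loop.
#' @param vols per-volume table mapping the 4th dimension to shells;
#'   defaults to [volume_table()] of the protocol.
#' @return named list of 3D arrays: `t_ex`, `D_i`, `D_e`, `f`, `rss`,
#'   `aicc`, `at_bound_n`, `converged`.
#' @export
fit_volume <- function(dwi, protocol, mask, sigma_map, model = c("nexi", "smex"),
                       bounds = fit_bounds(), n_workers = 1L,
                       vols = volume_table(protocol)) {
  model <- match.arg(tolower(model), c("nexi", "smex"))
  dwi <- as.array(dwi)
  if (length(dim(dwi)) != 4) stop("dwi must be 4D", call. = FALSE)
  dims <- dim(dwi)[1:3]
  # NIfTI readers may drop trailing singleton dimensions; restore them when
  # the voxel count matches
  conform_3d <- function(x, what) {
    x <- as.array(x)
    if (!identical(dim(x), dims)) {
      if (length(x) == prod(dims)) dim(x) <- dims
      else stop(what, " grid does not match dwi grid", call. = FALSE)
    }
    x
  }
  mask <- conform_3d(mask, "mask")
  sigma_map <- if (length(sigma_map) == 1) array(as.numeric(sigma_map), dims)
               else conform_3d(sigma_map, "sigma map")
  pa <- powder_average(dwi, vols, mask = mask, protocol = protocol)
  curves <- pa$curves
  vox <- pa$voxels
  fit_one <- function(i) {
    cv <- curves[i, ]
    if (all(!is.finite(cv)) || all(cv == 0)) return(rep(NA_real_, 8))
    fit <- tryCatch(
      fit_curve(cv, noise_model(sigma_map[vox[i, 1], vox[i, 2], vox[i, 3]]),
                model = model, bounds = bounds, protocol = pa$protocol),
      error = function(e) NULL
    )
    if (is.null(fit)) return(rep(NA_real_, 8))
    c(fit$params, fit$rss, fit$aicc, sum(fit$at_bound), as.numeric(fit$converged))
  }
  idx <- seq_len(nrow(curves))
  rows <- if (n_workers > 1) {
    parallel::mclapply(idx, fit_one, mc.cores = n_workers, mc.preschedule = TRUE)
  } else {
    lapply(idx, fit_one)
  }
  rows <- do.call(rbind, rows)
  maps <- list()
  nm <- c("t_ex", "D_i", "D_e", "f", "rss", "aicc", "at_bound_n", "converged")
  for (j in seq_along(nm)) {
    m <- array(NA_real_, dims)
    m[vox] <- rows[, j]
    maps[[nm[j]]] <- m
  }
  maps
}
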