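#' Powder-average and normalize a 4D diffusion acquisition
#'
#' Averages volumes over directions within each (b, Delta, delta) shell
#' (arithmetic mean) and normalizes every shell by the mean of the b = 0
#' volumes acquired at the same diffusion time Delta, so that b = 0 entries
#' become exactly 1.  Each Delta must therefore have at least one b = 0
#' volume.
#'
#' @param dwi 4D array `[x, y, z, volume]` (or `RNifti` image).
#' @param vols per-volume table with columns `b`, `Delta`, `delta`; row
#'   count must match the 4th dimension.
#' @param mask optional 3D logical/0-1 array; defaults to all voxels.
#' @param protocol optional [acq_protocol()]; derived from `vols` when
#'   absent.  Shell order follows the protocol.
#' @return list with `curves` (matrix, masked voxels x shells), `voxels`
#'   (integer matrix of voxel indices, same row order) and `protocol`.
#' @export
powder_average <- function(dwi, vols, mask = NULL, protocol = NULL) {
  dwi <- as.array(dwi)
  if (length(dim(dwi)) != 4) stop("dwi must be a 4D array", call. = FALSE)
  nvol <- dim(dwi)[4]
  if (nrow(vols) != nvol)
    stop("volume table rows (", nrow(vols), ") do not match 4th dimension (",
         nvol, ")", call. = FALSE)
  if (is.null(protocol)) protocol <- protocol_from_table(vols)
  vols$b <- convert_b_units(vols$b)
  dims <- dim(dwi)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  mask <- as.array(mask) != 0
  vox <- which(mask, arr.ind = TRUE)
  flat <- matrix(dwi, prod(dims), nvol)[which(mask), , drop = FALSE]

  skey <- paste(signif(protocol$b, 10), signif(protocol$Delta, 10),
                signif(protocol$delta, 10))
  vkey <- paste(signif(vols$b, 10), signif(vols$Delta, 10),
                signif(vols$delta, 10))
  shell_of <- match(vkey, skey)
  if (any(is.na(shell_of)))
    stop("volume table contains (b, Delta, delta) not in the protocol",
         call. = FALSE)
  nshell <- nrow(protocol)
  curves <- matrix(NA_real_, nrow(flat), nshell)
  for (s in seq_len(nshell)) {
    cols <- which(shell_of == s)
    if (!length(cols))
      stop("protocol shell ", s, " has no volumes in the table", call. = FALSE)
    curves[, s] <- if (length(cols) == 1) flat[, cols] else rowMeans(flat[, cols, drop = FALSE])
  }
  # per-Delta normalization by the mean b = 0 signal of that Delta
  for (D in unique(protocol$Delta)) {
    sh <- which(protocol$Delta == D)
    b0 <- sh[protocol$is_b0[sh]]
    if (!length(b0))
      stop("no b = 0 volume for Delta = ", D, "; cannot normalize", call. = FALSE)
    ref <- if (length(b0) == 1) curves[, b0] else rowMeans(curves[, b0, drop = FALSE])
    curves[, sh] <- curves[, sh, drop = FALSE] / ref
  }
  list(curves = curves, voxels = vox, protocol = protocol)
}

#' Signal-versus-diffusion-time slope test (exchange signature)
#'
#' At fixed b, inter-compartment exchange makes the powder-averaged signal
#' decrease with diffusion time, whereas restriction makes it increase.
#' This regresses signal on Delta by ordinary least squares and returns the
#' slope with its two-sided p-value for slope = 0.  A one-sided claim of
#' decrease corresponds to `slope < 0` with `p/2` below the level.
#'
#' @param signals powder-averaged signal values at a fixed b.
#' @param Deltas diffusion times (ms), same length, at least 3 points.
#' @return list with `slope` (1/ms), `p_value` (two-sided), `intercept`.
#' @export
slope_test <- function(signals, Deltas) {
  if (length(signals) != length(Deltas))
    stop("signals and Deltas must have equal length", call. = FALSE)
  if (length(signals) < 3)
    stop("need at least 3 (Delta, signal) pairs", call. = FALSE)
  fit <- stats::lm(signals ~ Deltas)
  # exact data triggers the "essentially perfect fit" warning; harmless here
  sm <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(sm["Deltas", "Estimate"]),
       p_value = unname(sm["Deltas", "Pr(>|t|)"]),
       intercept = unname(sm["(Intercept)", "Estimate"]))
}

#' Mode and highest-density interval of a sample
#'
#' Estimates the density with a Gaussian kernel (Silverman's rule-of-thumb
#' bandwidth) on a 512-point grid; the mode is the grid argmax and the
#' interval is the outer bounds of the smallest density-superlevel set
#' containing the requested probability mass ("integrating around the
#' mode").  For skewed distributions this interval is tighter than an
#' equal-tailed one and always contains the mode.
#'
#' @param values numeric sample (>= 10 values unless degenerate).
#' @param mass probability mass of the interval, in (0, 1).
#' @return list with `mode` and `interval = c(lo, hi)`.
#' @export
mode_hdi <- function(values, mass = 0.95) {
  values <- values[is.finite(values)]
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)", call. = FALSE)
  if (length(unique(values)) == 1)
    return(list(mode = values[1], interval = c(values[1], values[1])))
  if (length(values) < 10)
    stop("need at least 10 values for a density estimate", call. = FALSE)
  d <- stats::density(values, bw = "nrd0", n = 512)
  dx <- diff(d$x[1:2])
  p <- d$y / sum(d$y)
  ord <- order(d$y, decreasing = TRUE)
  cum <- cumsum(p[ord])
  k <- which(cum >= mass)[1]
  level <- d$y[ord[k]]
  inside <- d$y >= level
  list(mode = d$x[which.max(d$y)],
       interval = c(min(d$x[inside]), max(d$x[inside])))
}

check_roi_table <- function(tab) {
  need <- c("roi", "subject", "session", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("ROI table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab[c("roi", "subject", "session")]))
    stop("(roi, subject, session) must be unique in an ROI table", call. = FALSE)
  tab
}

#' Scan-rescan repeatability of ROI means
#'
#' Computes intra-subject differences `|session 1 - session 2|` per
#' (subject, ROI), inter-subject differences `|subject a - subject b|` over
#' all subject pairs using session 1, and the corresponding Pearson
#' correlations of ROI means (session 1 vs session 2 pooled over subjects
#' for intra; stacked subject pairs, session 1, for inter).  When a second
#' method's table is supplied, the intra- and inter-subject difference
#' distributions of the two methods are compared with paired Wilcoxon
#' signed-rank tests.
#'
#' @param tab ROI table: data frame with columns `roi`, `subject`,
#'   `session` (two sessions per subject), `value`.
#' @param tab_b optional second ROI table (another model/parameter) with the
#'   same (roi, subject, session) set.
#' @return list with `intra` and `inter` difference data frames,
#'   `intra_cor`, `inter_cor`, and (given `tab_b`) `wilcoxon_intra_p`,
#'   `wilcoxon_inter_p`.
#' @export
repeatability <- function(tab, tab_b = NULL) {
  tab <- check_roi_table(tab)
  sessions <- sort(unique(tab$session))
  if (length(sessions) != 2)
    stop("repeatability needs exactly two sessions", call. = FALSE)
  wide <- merge(tab[tab$session == sessions[1], c("roi", "subject", "value")],
                tab[tab$session == sessions[2], c("roi", "subject", "value")],
                by = c("roi", "subject"), suffixes = c("_s1", "_s2"))
  per_subj <- table(tab$subject, tab$session)
  if (any(per_subj == 0))
    stop("every subject needs both sessions", call. = FALSE)
  wide <- wide[order(wide$subject, wide$roi), ]
  intra <- data.frame(roi = wide$roi, subject = wide$subject,
                      diff = abs(wide$value_s1 - wide$value_s2))
  s1 <- tab[tab$session == sessions[1], ]
  subjects <- sort(unique(s1$subject))
  pairs <- utils::combn(subjects, 2)
  inter_list <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- s1[s1$subject == pairs[1, j], c("roi", "value")]
    b <- s1[s1$subject == pairs[2, j], c("roi", "value")]
    m <- merge(a, b, by = "roi", suffixes = c("_a", "_b"))
    data.frame(roi = m$roi, subject_a = pairs[1, j], subject_b = pairs[2, j],
               value_a = m$value_a, value_b = m$value_b,
               diff = abs(m$value_a - m$value_b))
  })
  inter <- do.call(rbind, inter_list)
  out <- list(
    intra = intra,
    inter = inter[c("roi", "subject_a", "subject_b", "diff")],
    intra_cor = stats::cor(wide$value_s1, wide$value_s2),
    inter_cor = stats::cor(inter$value_a, inter$value_b)
  )
  if (!is.null(tab_b)) {
    rb <- repeatability(tab_b)
    key <- function(d) paste(d$roi, d$subject)
    ka <- key(out$intra); kb <- key(rb$intra)
    m <- match(ka, kb)
    out$wilcoxon_intra_p <- stats::wilcox.test(out$intra$diff, rb$intra$diff[m],
                                               paired = TRUE)$p.value
    keyi <- function(d) paste(d$roi, d$subject_a, d$subject_b)
    mi <- match(keyi(out$inter), keyi(rb$inter))
    out$wilcoxon_inter_p <- stats::wilcox.test(out$inter$diff, rb$inter$diff[mi],
                                               paired = TRUE)$p.value
  }
  out
}

#' Correlate two maps at the ROI level
#'
#' Averages each table over subjects per ROI, joins on shared ROIs and
#' returns the Pearson correlation of the ROI means with its two-sided
#' p-value (e.g. an exchange-time map against a myelin water fraction map).
#'
#' @param a,b ROI tables with columns `roi`, `value` and optionally
#'   `subject` (averaged over when present).
#' @return list with `r`, `p_value`, `n_roi` and the joined `data`.
#' @export
correlate_roi_maps <- function(a, b) {
  agg <- function(tab) {
    if ("subject" %in% names(tab))
      stats::aggregate(value ~ roi, tab, mean)
    else tab[c("roi", "value")]
  }
  m <- merge(agg(a), agg(b), by = "roi", suffixes = c("_a", "_b"))
  if (nrow(m) < 3)
    stop("need at least 3 shared ROIs", call. = FALSE)
  ct <- stats::cor.test(m$value_a, m$value_b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_roi = nrow(m), data = m)
}

#' ROI means of a parameter map
#'
#' @param map 3D array of a fitted parameter.
#' @param labels 3D integer array of ROI labels (0 = background).
#' @param lut optional data frame with columns `id`, `name`.
#' @param robust use the median instead of the mean.
#' @return data frame with columns `roi`, `value`, `n_voxels`.
#' @export
roi_means <- function(map, labels, lut = NULL, robust = FALSE) {
  map <- as.array(map); labels <- as.array(labels)
  if (!identical(dim(map), dim(labels))) {
    if (length(map) == length(labels)) dim(labels) <- dim(map)
    else stop("map and label grids do not match", call. = FALSE)
  }
  ids <- sort(unique(labels[labels > 0]))
  stat <- if (robust) stats::median else mean
  rows <- lapply(ids, function(id) {
    v <- map[labels == id]
    v <- v[is.finite(v)]
    data.frame(roi = id, value = if (length(v)) stat(v) else NA_real_,
               n_voxels = length(v))
  })
  out <- do.call(rbind, rows)
  if (!is.null(lut)) out$roi <- lut$name[match(out$roi, lut$id)]
  out
}
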