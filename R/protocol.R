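#' Build an acquisition protocol from shell parameters
#'
#' An acquisition protocol is an ordered set of PGSE measurement shells, each
#' defined by its diffusion weighting `b` (ms/um^2), gradient pulse separation
#' `Delta` (ms), gradient pulse duration `delta` (ms) and number of gradient
#' directions.  The shell order is preserved exactly: signal curves and fits
#' index into it.
#'
#' Derived per-shell quantities are the effective diffusion time
#' `t_d = Delta - delta/3` and the wave number `q = sqrt(b / t_d)` (1/um),
#' so that `b = q^2 * t_d` for rectangular PGSE pulses.
#'
#' @param b numeric vector of b-values (ms/um^2).
#' @param Delta numeric vector of pulse separations (ms), recycled.
#' @param delta numeric vector of pulse durations (ms), recycled.
#' @param n_dirs integer vector of direction counts per shell, recycled.
#'   b = 0 shells conventionally have `n_dirs = 1`.
#' @param name free-text protocol label.
#' @return An object of class `acq_protocol`: a data frame with columns
#'   `b`, `Delta`, `delta`, `n_dirs`, `is_b0`, `t_d`, `q`.
#' @seealso [clinical_protocol()], [load_protocol()], [count_volumes()]
#' @export
acq_protocol <- function(b, Delta, delta, n_dirs = 1L, name = "protocol") {
  n <- length(b)
  shells <- data.frame(
    b = as.numeric(b),
    Delta = rep_len(as.numeric(Delta), n),
    delta = rep_len(as.numeric(delta), n),
    n_dirs = rep_len(as.integer(n_dirs), n)
  )
  validate_protocol(shells)
  shells$is_b0 <- shells$b == 0
  shells$t_d <- shells$Delta - shells$delta / 3
  shells$q <- sqrt(shells$b / shells$t_d)
  structure(shells, class = c("acq_protocol", "data.frame"), name = name)
}

validate_protocol <- function(shells) {
  with(shells, {
    if (any(!is.finite(b)) || any(!is.finite(Delta)) || any(!is.finite(delta)))
      stop("protocol contains non-finite values", call. = FALSE)
    if (any(b < 0)) stop("b-values must be >= 0", call. = FALSE)
    if (any(Delta <= 0)) stop("Delta must be > 0", call. = FALSE)
    if (any(delta <= 0) || any(delta > Delta))
      stop("delta must satisfy 0 < delta <= Delta", call. = FALSE)
    if (any(Delta - delta / 3 <= 0))
      stop("effective diffusion time t_d = Delta - delta/3 must be > 0",
           call. = FALSE)
    if (any(n_dirs < 1)) stop("n_dirs must be >= 1", call. = FALSE)
    # one delta per Delta: normalization and SMEX segments assume it
    dd <- unique(data.frame(Delta = Delta, delta = delta))
    if (anyDuplicated(dd$Delta))
      stop("shells sharing a Delta must share the same delta", call. = FALSE)
  })
  invisible(shells)
}

#' @export
print.acq_protocol <- function(x, ...) {
  cat(sprintf("Acquisition protocol '%s': %d shells (%d with b > 0), %d volumes\n",
              attr(x, "name"), nrow(x), sum(!x$is_b0), count_volumes(x)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' The built-in multi-shell multi-diffusion-time clinical protocol
#'
#' The default protocol targets a 3T clinical scanner with 80 mT/m gradients:
#' b = \{1, 2\} ms/um^2 at Delta = \{28.3, 36.0\} ms, b = \{1, 2, 3.2, 4.44\}
#' at Delta = 45.0 ms, b = \{1, 2, 3.2, 5\} at Delta = \{55.0, 65.0\} ms,
#' all with delta = 16.5 ms and 20 directions per b > 0 shell, plus one b = 0
#' volume per diffusion time.  This yields 21 shells and 325 volumes.
#'
#' @param delta gradient pulse duration in ms.  The default matches the
#'   clinical sequence; smaller values emulate high-performance gradient
#'   systems in simulation scenarios.
#' @return An [acq_protocol()] object with 21 shells.
#' @export
clinical_protocol <- function(delta = 16.5) {
  Deltas <- c(28.3, 36.0, 45.0, 55.0, 65.0)
  bsets <- list(c(1, 2), c(1, 2), c(1, 2, 3.2, 4.44), c(1, 2, 3.2, 5), c(1, 2, 3.2, 5))
  b <- numeric(0); Dl <- numeric(0); nd <- integer(0)
  for (i in seq_along(Deltas)) {
    bi <- c(0, bsets[[i]])
    b <- c(b, bi)
    Dl <- c(Dl, rep(Deltas[i], length(bi)))
    nd <- c(nd, ifelse(bi == 0, 1L, 20L))
  }
  acq_protocol(b, Dl, delta, nd, name = "clinical-3T")
}

#' Count diffusion volumes implied by a protocol
#'
#' Sums the direction count of every b > 0 shell and one volume per b = 0
#' shell.  Reversed-phase-encode calibration volumes are not part of a
#' protocol and are not counted.
#'
#' @param protocol an [acq_protocol()] object.
#' @return integer volume count.
#' @export
count_volumes <- function(protocol) {
  stopifnot(inherits(protocol, "acq_protocol"))
  as.integer(sum(ifelse(protocol$is_b0, 1L, protocol$n_dirs)))
}

#' Read an acquisition table
#'
#' Reads a TSV with one row per diffusion volume and columns `b`, `Delta`,
#' `delta` (and optionally `gx`, `gy`, `gz`, ignored beyond counting rows).
#' Rows are collapsed into shells by unique (`b`, `Delta`, `delta`) in order
#' of first appearance; b = 0 rows are grouped into one shell per `Delta`.
#'
#' b-value units are autodetected: values above 100 are taken as s/mm^2 and
#' divided by 1000 to obtain ms/um^2 (the two unit systems do not overlap in
#' practical protocols).
#'
#' @param path path to the TSV file.
#' @param name protocol label; defaults to the file name.
#' @return An [acq_protocol()] object.
#' @seealso [save_protocol()], [load_protocol_fsl()], [volume_table()]
#' @export
load_protocol <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("acquisition table not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  protocol_from_table(tab, name = name)
}

#' Build a protocol from a per-volume table
#'
#' @param tab data frame with one row per volume and numeric columns
#'   `b`, `Delta`, `delta`.
#' @param name protocol label.
#' @return An [acq_protocol()] object.
#' @export
protocol_from_table <- function(tab, name = "table") {
  need <- c("b", "Delta", "delta")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("acquisition table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (cn in need) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    if (any(is.na(v))) stop("column '", cn, "' does not parse as numeric", call. = FALSE)
    tab[[cn]] <- v
  }
  tab$b <- convert_b_units(tab$b)
  key <- paste(signif(tab$b, 10), signif(tab$Delta, 10), signif(tab$delta, 10))
  first <- !duplicated(key)
  shells <- tab[first, need]
  counts <- as.integer(table(factor(key, levels = key[first])))
  acq_protocol(shells$b, shells$Delta, shells$delta, counts, name = name)
}

convert_b_units <- function(b) {
  # > 100 means s/mm^2; 1 ms/um^2 == 1000 s/mm^2
  ifelse(b > 100, b / 1000, b)
}

#' Read an FSL-dialect protocol (bval/bvec plus timing table)
#'
#' FSL `bval`/`bvec` files carry no pulse timing, so a companion TSV with
#' columns `Delta` and `delta` (one row per volume, or a single row applied
#' to all volumes) is required.
#'
#' @param bval path to whitespace-separated b-values (s/mm^2 or ms/um^2, one line).
#' @param bvec path to the 3-line direction file (read for consistency checks
#'   only; the powder-average pipeline uses direction counts, not directions).
#' @param timing path to the timing TSV.
#' @param name protocol label.
#' @return An [acq_protocol()] object.
#' @export
load_protocol_fsl <- function(bval, bvec = NULL, timing, name = basename(bval)) {
  b <- scan(bval, quiet = TRUE)
  if (!is.null(bvec)) {
    g <- as.matrix(utils::read.table(bvec))
    if (ncol(g) != length(b))
      stop("bvec has ", ncol(g), " columns but bval has ", length(b), " entries",
           call. = FALSE)
  }
  tim <- utils::read.table(timing, header = TRUE, sep = "\t")
  if (!all(c("Delta", "delta") %in% names(tim)))
    stop("timing table needs columns 'Delta' and 'delta'", call. = FALSE)
  if (nrow(tim) == 1) tim <- tim[rep(1, length(b)), ]
  if (nrow(tim) != length(b))
    stop("timing table rows (", nrow(tim), ") do not match volume count (",
         length(b), ")", call. = FALSE)
  protocol_from_table(data.frame(b = b, Delta = tim$Delta, delta = tim$delta),
                      name = name)
}

#' Write an acquisition table
#'
#' Writes one row per volume (shells expanded by their direction count) with
#' columns `b`, `Delta`, `delta`, such that
#' `load_protocol(save_protocol(p, f))` reproduces the shell set and order
#' exactly.  b is written in ms/um^2.
#'
#' @param protocol an [acq_protocol()] object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
save_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "acq_protocol"))
  nrep <- ifelse(protocol$is_b0, 1L, protocol$n_dirs)
  idx <- rep(seq_len(nrow(protocol)), nrep)
  tab <- data.frame(b = protocol$b[idx], Delta = protocol$Delta[idx],
                    delta = protocol$delta[idx])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a protocol to YAML for provenance records
#'
#' @param protocol an [acq_protocol()] object.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
protocol_to_yaml <- function(protocol, path) {
  stopifnot(inherits(protocol, "acq_protocol"))
  obj <- list(
    name = attr(protocol, "name"),
    units = list(b = "ms/um^2", Delta = "ms", delta = "ms"),
    shells = lapply(seq_len(nrow(protocol)), function(i)
      list(b = protocol$b[i], Delta = protocol$Delta[i],
           delta = protocol$delta[i], n_dirs = protocol$n_dirs[i]))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Expand a protocol into a per-volume table
#'
#' Inverse of the shell-collapsing step of [load_protocol()]: one row per
#' volume in shell order, with a `shell` index column.  This is the volume
#' axis of a 4D acquisition generated from the protocol.
#'
#' @param protocol an [acq_protocol()] object.
#' @return data frame with columns `shell`, `b`, `Delta`, `delta`.
#' @export
volume_table <- function(protocol) {
  stopifnot(inherits(protocol, "acq_protocol"))
  nrep <- ifelse(protocol$is_b0, 1L, protocol$n_dirs)
  idx <- rep(seq_len(nrow(protocol)), nrep)
  data.frame(shell = idx, b = protocol$b[idx], Delta = protocol$Delta[idx],
             delta = protocol$delta[idx])
}

#' Select a subset of volumes by predicate on b and Delta
#'
#' Some workflows (e.g. noise-map estimation from high-SNR data) operate on a
#' subset of the acquisition such as the b = 0 and b = 1 ms/um^2 volumes.
#' The subset is a user choice; no fixed subset is hard-coded.
#'
#' @param protocol an [acq_protocol()] object.
#' @param b_max keep shells with `b <= b_max`.
#' @param Deltas optional vector of Delta values to keep.
#' @return An [acq_protocol()] object with the selected shells, order preserved.
#' @export
subset_protocol <- function(protocol, b_max = Inf, Deltas = NULL) {
  stopifnot(inherits(protocol, "acq_protocol"))
  keep <- protocol$b <= b_max
  if (!is.null(Deltas)) keep <- keep & protocol$Delta %in% Deltas
  acq_protocol(protocol$b[keep], protocol$Delta[keep], protocol$delta[keep],
               protocol$n_dirs[keep], name = attr(protocol, "name"))
}
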