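#' Write parameter maps as NIfTI volumes
#'
#' @param maps named list of 3D arrays, as returned by [fit_volume()].
#' @param dir output directory (created if needed).
#' @param reference optional `RNifti` image supplying grid and affine.
#' @return character vector of file paths, invisibly.
#' @export
write_maps <- function(maps, dir, reference = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(maps)) {
    img <- maps[[nm]]
    if (!is.null(reference)) {
      tpl <- reference
      img <- RNifti::asNifti(img, reference = tpl)
    }
    path <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(img, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a bounds override from YAML
#'
#' The YAML file may override any subset of the default [fit_bounds()]
#' entries, e.g. `t_ex: [1, 100]`.
#'
#' @param path YAML file path.
#' @return a [fit_bounds()] object.
#' @export
read_bounds_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- fit_bounds()
  args <- list()
  for (nm in c("t_ex", "D_i", "D_e", "f"))
    args[[nm]] <- if (!is.null(y[[nm]])) as.numeric(y[[nm]]) else defaults[[nm]]
  do.call(fit_bounds, args)
}
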