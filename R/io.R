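#' Write a volume as a multi-page TIFF with a YAML sidecar
#'
#' Pages are z planes, scaled to 16-bit; the voxel sizes (nm), channel name
#' and intensity scale are written to `<path>.yaml` so the volume
#' round-trips through [read_voxel_tiff()] to 16-bit quantization accuracy.
#'
#' @param grid A [voxel_grid].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_voxel_tiff <- function(grid, path) {
  stopifnot(is_voxel_grid(grid))
  scale <- max(grid$data, 1e-12)
  pages <- lapply(seq_len(dim(grid$data)[1]), function(iz) grid$data[iz, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(list(
    voxel_size_nm = as.list(stats::setNames(grid$voxel_size, c("z", "y", "x"))),
    channel = grid$channel,
    intensity_scale = scale
  ), paste0(path, ".yaml"))
  invisible(path)
}

#' Read a volume written by [write_voxel_tiff()]
#'
#' @param path TIFF path; `<path>.yaml` must exist alongside it.
#' @return A [voxel_grid].
#' @export
read_voxel_tiff <- function(path) {
  side <- paste0(path, ".yaml")
  if (!file.exists(side)) {
    stop(sprintf("no voxel-size sidecar found at '%s'; supply voxel metadata",
                 side), call. = FALSE)
  }
  meta <- yaml::read_yaml(side)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(length(pages), dim(pages[[1]])))
  for (iz in seq_along(pages)) arr[iz, , ] <- pages[[iz]]
  vs <- unlist(meta$voxel_size_nm)[c("z", "y", "x")]
  voxel_grid(arr * meta$intensity_scale, vs, meta$channel)
}
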