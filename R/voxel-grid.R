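#' 3D intensity grid with physical voxel sizes
#'
#' The universal image carrier of the package: a 3D array of nonnegative
#' intensities in fixed `(z, y, x)` axis order, together with the physical
#' voxel size along each axis in nanometres and a channel label.
#'
#' @param data Numeric 3D array, axis order `(z, y, x)`, all values `>= 0`.
#' @param voxel_size Numeric length-3 vector `(z, y, x)` voxel size in nm,
#'   all values `> 0`.
#' @param channel Character channel label (e.g. `"marker"`, `"dna"`).
#' @return An object of class `voxel_grid`.
#' @examples
#' vg <- voxel_grid(array(0, c(4, 8, 8)), voxel_size = c(125, 40, 40))
#' dim(vg)
#' @export
voxel_grid <- function(data, voxel_size, channel = "marker") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array in (z, y, x) order", call. = FALSE)
  }
  if (!is.numeric(data)) stop("`data` must be numeric", call. = FALSE)
  if (anyNA(data)) stop("`data` must not contain NA", call. = FALSE)
  if (min(data) < 0) stop("intensities must be nonnegative", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("`voxel_size` must be 3 positive values (z, y, x) in nm", call. = FALSE)
  }
  structure(
    list(data = data, voxel_size = voxel_size,
         channel = as.character(channel)[1]),
    class = "voxel_grid"
  )
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' @export
as.array.voxel_grid <- function(x, ...) x$data

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_grid> channel '%s': %d x %d x %d voxels (z,y,x), %g x %g x %g nm\n",
    x$channel, d[1], d[2], d[3],
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  intensity range [%.4g, %.4g], total %.6g\n",
              min(x$data), max(x$data), sum(x$data)))
  invisible(x)
}

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

# Coerce a lateral plane argument: either a plain y-by-x matrix or a
# voxel_grid with a single z plane (or with `z` given).  Returns a list with
# the matrix and the lateral pixel size in nm.
as_plane <- function(plane, pixel_nm = NULL, z = NULL) {
  if (is_voxel_grid(plane)) {
    nz <- dim(plane$data)[1]
    if (is.null(z)) {
      if (nz != 1L) stop("supply `z` to pick a plane from a multi-plane grid",
                         call. = FALSE)
      z <- 1L
    }
    px <- plane$voxel_size[2:3]
    if (abs(px[1] - px[2]) > 1e-9) {
      stop("lateral voxel sizes must be equal for plane operations", call. = FALSE)
    }
    list(m = plane$data[z, , ], pixel_nm = px[1])
  } else if (is.matrix(plane)) {
    if (is.null(pixel_nm)) stop("`pixel_nm` required with a plain matrix plane",
                                call. = FALSE)
    list(m = plane, pixel_nm = pixel_nm)
  } else {
    stop("`plane` must be a matrix or a voxel_grid", call. = FALSE)
  }
}
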