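#' Voxel volume container
#'
#' A `voxel_volume` is the unit of all structural analysis: a 3D intensity
#' grid with physical voxel spacing and an optional fibre mask restricting
#' analyses to the fibre interior.
#'
#' @param data numeric 3D array, dimensions (x, y, z). By convention the
#'   fibre's long axis runs along y (the long image axis is parallel with
#'   the long axis of the preparation).
#' @param voxel_size numeric length-3, physical voxel size in nm (dx, dy,
#'   dz). Structural imaging uses voxels finer than 90 nm in x/y and
#'   150 nm in z.
#' @param fibre_mask optional logical array of the same dimensions marking
#'   fibre-interior voxels.
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, voxel_size, fibre_mask = NULL) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be three positive lengths (nm)")
  if (!is.null(fibre_mask)) {
    if (!identical(dim(fibre_mask), dim(data)))
      stop("`fibre_mask` dimensions must match `data`")
    storage.mode(fibre_mask) <- "logical"
  }
  structure(list(data = data, voxel_size = voxel_size,
                 fibre_mask = fibre_mask),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, voxel %g x %g x %g nm\n",
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  if (!is.null(x$fibre_mask))
    cat(sprintf("  fibre mask: %d voxels (%.1f%% of grid)\n",
                sum(x$fibre_mask), 100 * mean(x$fibre_mask)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

as_voxel_volume <- function(x, voxel_size = NULL) {
  if (inherits(x, "voxel_volume")) return(x)
  if (is.null(voxel_size)) stop("voxel_size required for a bare array")
  voxel_volume(x, voxel_size)
}

#' Physical voxel volume in cubic micrometres
#' @param x a `voxel_volume` or a voxel-size vector in nm.
#' @return scalar volume of one voxel in um^3.
#' @export
voxel_um3 <- function(x) {
  vs <- if (inherits(x, "voxel_volume")) x$voxel_size else as.numeric(x)
  prod(vs) / 1e9
}
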