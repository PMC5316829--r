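#' Segment vacuoles by percentile thresholding
#'
#' Exploits the high fluorescence of vacuoles: the intensity histogram is
#' computed within the fibre mask only, the threshold set at the given
#' percentile (default 55, the midpoint of the typical 50-60th percentile
#' range), and voxels strictly greater than the threshold value are kept.
#' Connected components (26-connectivity) below `min_voxels` are removed.
#'
#' The strict inequality matters: in vacuolated fibres the tubule signal
#' falls to the (tie-heavy) background level, so the percentile value sits
#' on that level and only the bright vacuole tail survives. A constant
#' volume therefore yields an empty labelling rather than an error.
#'
#' @param volume a `voxel_volume` or 3D array.
#' @param percentile percentile in (0, 100) of the within-fibre histogram.
#' @param min_voxels minimum component size; default is the voxel count of
#'   a 0.4 um diameter sphere (half the minimum vacuole diameter), which
#'   rejects noise specks without excluding real vacuoles.
#' @param fibre_mask logical array; defaults to the volume's own mask, or
#'   the whole grid.
#' @return integer label array (0 = background) with attributes
#'   `threshold`, `percentile`, `min_voxels` and `n_components`.
#' @export
segment_vacuoles <- function(volume, percentile = 55, min_voxels = NULL,
                             fibre_mask = NULL) {
  arr <- if (inherits(volume, "voxel_volume")) volume$data else volume
  vs <- if (inherits(volume, "voxel_volume")) volume$voxel_size else NULL
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must be in (0, 100)")
  if (is.null(fibre_mask) && inherits(volume, "voxel_volume"))
    fibre_mask <- volume$fibre_mask
  if (is.null(fibre_mask)) fibre_mask <- array(TRUE, dim(arr))
  if (is.null(min_voxels)) {
    if (is.null(vs)) stop("min_voxels required when voxel size is unknown")
    min_voxels <- max(1L, round((4 / 3) * pi * 0.2^3 / voxel_um3(vs)))
  }
  # type-1 quantile: an actual data value, so the strict inequality
  # respects tie structure on quantized images
  thr <- as.numeric(quantile(arr[fibre_mask], percentile / 100, type = 1,
                             names = FALSE))
  mask <- arr > thr & fibre_mask
  d <- dim(arr)
  lab <- array(label3d_cpp(as.logical(mask), as.integer(d)), d)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    keep <- which(sizes >= min_voxels)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  attr(lab, "threshold") <- thr
  attr(lab, "percentile") <- percentile
  attr(lab, "min_voxels") <- min_voxels
  attr(lab, "n_components") <- max(lab)
  lab
}

#' Per-vacuole roundness
#'
#' Roundness is the inverse in-plane aspect ratio: for each z-plane slice
#' of a labelled component a 2D ellipse is fitted by second moments and
#' the minor/major axis ratio computed; the per-vacuole value is the
#' area-weighted mean over its planes. A needle along z therefore still
#' scores ~1 (the convention is strictly 2D, per plane).
#'
#' @param labels integer label array from [segment_vacuoles()].
#' @param voxel_size voxel size in nm.
#' @return data.frame with `id` and `roundness` in (0, 1].
#' @export
vacuole_roundness <- function(labels, voxel_size) {
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids))
    return(data.frame(id = integer(0), roundness = numeric(0)))
  d <- dim(labels)
  out <- data.frame(id = ids, roundness = NA_real_)
  # pixel self-variance so single-row/column slices have finite extent
  vpx <- voxel_size[1]^2 / 12
  vpy <- voxel_size[2]^2 / 12
  for (j in seq_along(ids)) {
    idx <- which(labels == ids[j], arr.ind = TRUE)
    r_acc <- 0
    w_acc <- 0
    for (z in unique(idx[, 3])) {
      sl <- idx[idx[, 3] == z, , drop = FALSE]
      npx <- nrow(sl)
      if (npx == 1L) {
        r <- 1   # single-voxel slice: roundness 1 by convention
      } else {
        x <- sl[, 1] * voxel_size[1]
        y <- sl[, 2] * voxel_size[2]
        cxx <- stats::var(x) * (npx - 1) / npx + vpx
        cyy <- stats::var(y) * (npx - 1) / npx + vpy
        cxy <- stats::cov(x, y) * (npx - 1) / npx
        tr <- cxx + cyy
        det2 <- sqrt(max(0, (cxx - cyy)^2 + 4 * cxy^2))
        l1 <- (tr + det2) / 2
        l2 <- (tr - det2) / 2
        r <- sqrt(max(l2, 0) / l1)
      }
      r_acc <- r_acc + r * npx
      w_acc <- w_acc + npx
    }
    out$roundness[j] <- r_acc / w_acc
  }
  out
}

#' Vacuole morphometric summary
#'
#' Per-vacuole volumes, centroids and roundness plus fibre-level
#' summaries: vacuole count, the percentage of the fibre volume occupied
#' by vacuoles, and the vacuole count density per 1000 um^3 of fibre
#' volume.
#'
#' @param labels integer label array from [segment_vacuoles()].
#' @param fibre_mask logical array of fibre-interior voxels.
#' @param voxel_size voxel size in nm.
#' @return a `vacuole_table`: data.frame of per-vacuole rows with a
#'   `summary` attribute (list with `vacuole_count`, `volume_fraction`,
#'   `count_density_per_1000um3`, `fibre_volume_um3`,
#'   `threshold_percentile`).
#' @export
vacuole_summary <- function(labels, fibre_mask, voxel_size) {
  n_fibre <- sum(fibre_mask)
  if (n_fibre == 0) stop("fibre mask is empty")
  vx <- voxel_um3(voxel_size)
  ids <- sort(unique(labels[labels > 0L]))
  rond <- vacuole_roundness(labels, voxel_size)
  rows <- lapply(ids, function(id) {
    idx <- which(labels == id, arr.ind = TRUE)
    data.frame(id = id, voxel_count = nrow(idx),
               volume_um3 = nrow(idx) * vx,
               centroid_x_nm = mean((idx[, 1] - 0.5) * voxel_size[1]),
               centroid_y_nm = mean((idx[, 2] - 0.5) * voxel_size[2]),
               centroid_z_nm = mean((idx[, 3] - 0.5) * voxel_size[3]),
               roundness = rond$roundness[match(id, rond$id)])
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), voxel_count = integer(0),
               volume_um3 = numeric(0), centroid_x_nm = numeric(0),
               centroid_y_nm = numeric(0), centroid_z_nm = numeric(0),
               roundness = numeric(0))
  fibre_um3 <- n_fibre * vx
  summ <- list(vacuole_count = length(ids),
               volume_fraction = 100 * sum(tab$voxel_count) / n_fibre,
               count_density_per_1000um3 = length(ids) / (fibre_um3 / 1000),
               fibre_volume_um3 = fibre_um3,
               threshold_percentile = attr(labels, "percentile"))
  class(tab) <- c("vacuole_table", "data.frame")
  attr(tab, "summary") <- summ
  tab
}

#' Cylinder volume of a tubular element
#'
#' Volume of a cylinder of the given diameter and length; used to reason
#' about vacuolation geometry (a tenfold increase in tubule diameter at
#' constant length implies a hundredfold increase in luminal volume).
#'
#' @param diameter cylinder diameter (any length unit).
#' @param length cylinder length (same unit).
#' @return volume in the cubed unit.
#' @export
tubule_cylinder_volume <- function(diameter, length) {
  if (any(diameter < 0) || any(length < 0)) stop("dimensions must be >= 0")
  pi * (diameter / 2)^2 * length
}

#' @export
print.vacuole_table <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(paste0("<vacuole_table> %d vacuole(s); %.3f%% of fibre volume; ",
                     "%.3f per 1000 um^3\n"),
              s$vacuole_count, s$volume_fraction,
              s$count_density_per_1000um3))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
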