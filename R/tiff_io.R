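# Minimal multi-page grayscale TIFF I/O (little-endian, uncompressed,
# one strip per page). The environment provides no TIFF bindings, and the
# subset needed here -- 16-bit integer acquisition volumes and 32-bit
# float intermediates, page-per-z-slice -- is small enough to write
# directly. Not a general-purpose TIFF implementation.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, StripOffsets = 273L,
               RowsPerStrip = 278L, StripByteCounts = 279L,
               SampleFormat = 339L)

#' Write a volume as a multi-page TIFF
#'
#' Pages run along z. `bits = 16` writes unsigned 16-bit integers
#' (intensities are clipped to [0, 65535] on export only); `bits = 32`
#' writes IEEE floats. A JSON sidecar with the voxel size and any extra
#' metadata is written alongside when `sidecar` is TRUE.
#'
#' @param volume a `voxel_volume` or 3D array.
#' @param path output file path.
#' @param bits 16 (integer) or 32 (float).
#' @param scale multiply intensities before integer export.
#' @param sidecar write `<path>.json` with voxel size and metadata.
#' @param metadata named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_tiff_volume <- function(volume, path, bits = 16L, scale = 1,
                              sidecar = TRUE, metadata = list()) {
  arr <- if (inherits(volume, "voxel_volume")) volume$data else volume
  d <- dim(arr)
  if (length(d) != 3L) stop("need a 3D array")
  if (!bits %in% c(16L, 32L)) stop("bits must be 16 or 32")
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  w(as.integer(c(0x49, 0x49)), 1L)         # "II"
  w(42L, 2L)
  # layout: header(8) | per page: pixel data then IFD
  n_tags <- 9L
  ifd_size <- 2L + n_tags * 12L + 4L
  bytes_pp <- d[1] * d[2] * (bits %/% 8L)
  offset <- 8L
  w(offset + bytes_pp, 4L)                  # first IFD after first page data
  for (z in seq_len(d[3])) {
    page <- arr[, , z]
    if (bits == 16L) {
      v <- as.integer(pmin(pmax(round(page * scale), 0), 65535))
      w(v, 2L)
    } else {
      w(as.numeric(page), 4L)
    }
    data_off <- offset
    ifd_off <- offset + bytes_pp
    tag <- function(id, type, value) {   # type 3 = SHORT, 4 = LONG
      w(as.integer(id), 2L)
      w(as.integer(type), 2L)
      w(1L, 4L)
      if (type == 3L) { w(as.integer(value), 2L); w(0L, 2L) }
      else w(as.integer(value), 4L)
    }
    w(n_tags, 2L)
    tag(256L, 4L, d[1])                     # width = x
    tag(257L, 4L, d[2])                     # length (rows) = y
    tag(258L, 3L, bits)
    tag(259L, 3L, 1L)                       # no compression
    tag(262L, 3L, 1L)                       # black is zero
    tag(273L, 4L, data_off)
    tag(278L, 4L, d[2])
    tag(279L, 4L, bytes_pp)
    tag(339L, 3L, if (bits == 32L) 3L else 1L)  # float vs unsigned int
    next_ifd <- if (z < d[3]) ifd_off + ifd_size + bytes_pp else 0L
    w(next_ifd, 4L)
    offset <- ifd_off + ifd_size
  }
  if (sidecar) {
    meta <- c(list(
      dim = d, bits = bits, scale = scale,
      voxel_size_nm = if (inherits(volume, "voxel_volume"))
        volume$voxel_size else NULL), metadata)
    jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF volume
#'
#' Reads the uncompressed single-sample subset written by
#' [write_tiff_volume()] (and equivalent exports from other tools). If a
#' JSON sidecar is present its voxel size is attached.
#'
#' @param path TIFF file path.
#' @return a `voxel_volume` when the voxel size is known (sidecar or
#'   `voxel_size`), otherwise a bare 3D array.
#' @param voxel_size optional voxel size in nm, overriding the sidecar.
#' @export
read_tiff_volume <- function(path, voxel_size = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n, size, what = "integer", signed = TRUE)
    readBin(con, what, n = n, size = size, endian = "little", signed = signed)
  magic <- rd(2L, 1L)
  if (!identical(as.integer(magic), c(73L, 73L)))
    stop("only little-endian TIFF is supported")
  if (rd(1L, 2L) != 42L) stop("not a TIFF file")
  ifd_off <- rd(1L, 4L)
  pages <- list()
  width <- height <- NULL
  while (ifd_off != 0) {
    seek(con, ifd_off)
    n_tags <- rd(1L, 2L)
    tags <- list()
    for (i in seq_len(n_tags)) {
      id <- rd(1L, 2L, signed = FALSE)
      type <- rd(1L, 2L)
      count <- rd(1L, 4L)
      val <- if (type == 3L) { v <- rd(1L, 2L, signed = FALSE); rd(1L, 2L); v }
      else rd(1L, 4L)
      tags[[as.character(id)]] <- c(type = type, count = count, value = val)
    }
    next_off <- rd(1L, 4L)
    g <- function(id, default = NULL) {
      t <- tags[[as.character(id)]]
      if (is.null(t)) default else unname(t["value"])
    }
    wd <- g(256L); ht <- g(257L)
    bits <- g(258L, 16L)
    if (g(259L, 1L) != 1L) stop("compressed TIFF not supported")
    fmt <- g(339L, 1L)
    off <- g(273L)
    if (g(277L, 1L) != 1L) stop("multi-sample TIFF not supported")
    seek(con, off)
    n_px <- wd * ht
    page <- if (fmt == 3L) rd(n_px, 4L, what = "numeric")
    else if (bits == 16L) rd(n_px, 2L, signed = FALSE)
    else if (bits == 8L) rd(n_px, 1L, signed = FALSE)
    else rd(n_px, 4L)
    pages[[length(pages) + 1L]] <- page
    width <- wd; height <- ht
    ifd_off <- next_off
  }
  arr <- array(as.numeric(unlist(pages)), c(width, height, length(pages)))
  side <- paste0(path, ".json")
  if (is.null(voxel_size) && file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    voxel_size <- meta$voxel_size_nm
  }
  if (!is.null(voxel_size)) voxel_volume(arr, voxel_size) else arr
}
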