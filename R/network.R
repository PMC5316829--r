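#' Binarize tubule-occupied voxels
#'
#' Thresholds a (typically deconvolved) volume into a tubule foreground
#' mask. The default Otsu threshold is computed within the fibre mask when
#' one is present so that extracellular background does not shift it.
#'
#' @param volume a `voxel_volume` or 3D array.
#' @param method `"otsu"` (default), `"triangle"` (better for skewed
#'   histograms where dim sub-resolution tubules ride on a dominant
#'   background mode) or a numeric threshold; values strictly greater
#'   than the threshold are foreground.
#' @return logical array with attributes `threshold` and `method`.
#' @export
binarize_tubules <- function(volume, method = "otsu") {
  arr <- if (inherits(volume, "voxel_volume")) volume$data else volume
  if (any(!is.finite(arr))) stop("volume intensities must be finite")
  vals <- arr
  if (inherits(volume, "voxel_volume") && !is.null(volume$fibre_mask))
    vals <- arr[volume$fibre_mask]
  if (all(arr %in% c(0, 1))) {           # binary input: idempotent
    out <- arr > 0
    attr(out, "threshold") <- 0
    attr(out, "method") <- "binary-passthrough"
    return(out)
  }
  thr <- if (is.numeric(method)) method else switch(
    method,
    otsu = otsu_threshold(vals),
    triangle = triangle_threshold(vals),
    stop("unknown threshold method: ", method))
  out <- arr > thr
  if (!any(out)) stop("binarization produced an empty mask (nothing to skeletonize)")
  attr(out, "threshold") <- thr
  attr(out, "method") <- if (is.numeric(method)) "fixed" else method
  out
}

# 26-neighbourhood adjacency graph of a skeleton's voxels
skeleton_graph <- function(skel, d) {
  vox <- which(skel)
  n <- length(vox)
  coords <- arrayInd(vox, d)
  id_of <- rep(NA_integer_, prod(d))
  id_of[vox] <- seq_len(n)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  adj <- vector("list", n)
  deg <- integer(n)
  for (r in seq_len(nrow(offs))) {
    nb <- coords + matrix(offs[r, ], n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- rep(NA_integer_, n)
    lin[ok] <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] +
      (nb[ok, 3] - 1L) * d[1] * d[2]
    hit <- which(ok & !is.na(id_of[lin]))
    for (i in hit) adj[[i]] <- c(adj[[i]], id_of[lin[i]])
    deg[hit] <- deg[hit] + 1L
  }
  list(n = n, vox = vox, coords = coords, adj = adj, deg = deg)
}

#' Skeletonize a tubule mask
#'
#' 3D topology-preserving medial-axis thinning to a one-voxel-thick
#' centreline, followed by graph extraction: branch points and endpoints
#' become nodes and the voxel chains between them become segment
#' polylines in physical (nm) coordinates.
#'
#' @param mask logical 3D array (from [binarize_tubules()]).
#' @param voxel_size voxel size in nm.
#' @param min_segment_voxels segments shorter than this many voxels whose
#'   both ends are branch points are suppressed as thinning artifacts.
#' @param prune_spurs terminal branches shorter than this many voxels are
#'   pruned (iteratively) before graph extraction; thinning of noisy
#'   thick tubes throws off short side spurs that would otherwise
#'   fragment the main centreline. 0 disables pruning.
#' @param min_component_voxels isolated skeleton components smaller than
#'   this are discarded as noise.
#' @return an object of class `skeleton`: list with `segments` (each a
#'   list with `points`, an n x 3 matrix of nm coordinates, and `n`
#'   voxels), `skeleton_mask`, `voxel_size`, `dim` and a
#'   `border_touching` provenance flag.
#' @export
skeletonize <- function(mask, voxel_size, min_segment_voxels = 3L,
                        prune_spurs = 5L, min_component_voxels = 4L) {
  if (!any(mask)) stop("cannot skeletonize an empty mask")
  d <- dim(mask)
  border <- any(mask[c(1, d[1]), , ]) || any(mask[, c(1, d[2]), ]) ||
    any(mask[, , c(1, d[3])])
  skel <- thin3d_cpp(as.logical(mask), as.integer(d))
  skel <- array(skel, d)

  # iterative spur pruning: delete terminal chains shorter than the
  # threshold, which re-fuses main-path pieces broken by thinning spurs
  if (prune_spurs > 0L) {
    for (pass in 1:10) {
      gr <- skeleton_graph(skel, d)
      if (gr$n == 0L) break
      drop <- logical(gr$n)
      for (e in which(gr$deg == 1L)) {
        path <- e
        cur <- e
        prev <- 0L
        while (length(path) <= prune_spurs) {
          nbs <- gr$adj[[cur]]
          nxt <- nbs[nbs != prev]
          if (length(nxt) != 1L) break  # reached a branch point or isolated
          prev <- cur
          cur <- nxt[1]
          if (gr$deg[cur] != 2L) break
          path <- c(path, cur)
        }
        at_branch <- length(gr$adj[[cur]]) > 2L
        if (at_branch && length(path) <= prune_spurs) drop[path] <- TRUE
      }
      if (!any(drop)) break
      skel[gr$vox[drop]] <- FALSE
    }
  }
  if (min_component_voxels > 1L) {
    lab <- array(label3d_cpp(as.logical(skel), as.integer(d)), d)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
      small <- which(sizes < min_component_voxels)
      if (length(small)) skel[lab %in% small] <- FALSE
    }
  }
  if (!any(skel)) stop("skeleton empty after pruning")

  gr <- skeleton_graph(skel, d)
  coords <- gr$coords
  n <- gr$n
  adj <- gr$adj
  deg <- gr$deg

  is_node <- deg != 2L
  visited_edge <- new.env(hash = TRUE)
  ekey <- function(a, b) paste0(min(a, b), "-", max(a, b))
  segments <- list()
  add_segment <- function(path) {
    pts <- coords[path, , drop = FALSE]
    pts_nm <- sweep(pts - 0.5, 2L, voxel_size, `*`)
    segments[[length(segments) + 1L]] <<- list(points = pts_nm, n = length(path))
  }
  trace_from <- function(start, nxt) {
    path <- c(start, nxt)
    prev <- start
    cur <- nxt
    while (!is_node[cur]) {
      nbs <- adj[[cur]]
      nxt2 <- nbs[nbs != prev][1]
      if (is.na(nxt2)) break
      path <- c(path, nxt2)
      prev <- cur
      cur <- nxt2
    }
    path
  }
  for (v in which(is_node)) {
    for (nb in adj[[v]]) {
      k <- ekey(v, nb)
      if (!is.null(visited_edge[[k]])) next
      path <- trace_from(v, nb)
      for (i in seq_len(length(path) - 1L))
        visited_edge[[ekey(path[i], path[i + 1L])]] <- TRUE
      # suppress tiny branch-to-branch stubs from thinning
      if (length(path) < min_segment_voxels &&
          is_node[path[1]] && is_node[path[length(path)]] &&
          (deg[path[1]] > 2L || deg[path[length(path)]] > 2L)) next
      add_segment(path)
    }
  }
  # pure cycles with no branch/end points
  left <- which(!is_node & deg == 2L)
  seen <- rep(FALSE, n)
  for (s in left) {
    if (seen[s]) next
    nbs <- adj[[s]]
    covered <- vapply(nbs, function(nb) !is.null(visited_edge[[ekey(s, nb)]]),
                      logical(1))
    if (all(covered)) { seen[s] <- TRUE; next }
    path <- s
    prev <- s
    cur <- nbs[!covered][1]
    while (cur != s) {
      path <- c(path, cur)
      nbs2 <- adj[[cur]]
      nxt <- nbs2[nbs2 != prev][1]
      if (is.na(nxt)) break
      prev <- cur
      cur <- nxt
    }
    path <- c(path, s)
    for (i in seq_len(length(path) - 1L))
      visited_edge[[ekey(path[i], path[i + 1L])]] <- TRUE
    seen[path] <- TRUE
    add_segment(path)
  }
  structure(list(segments = segments, skeleton_mask = skel,
                 voxel_size = voxel_size, dim = d,
                 border_touching = border),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  lab <- vapply(x$segments, function(s) s$label %||% "unlabelled", "")
  cat(sprintf("<skeleton> %d segments (%d voxels)",
              length(x$segments), sum(x$skeleton_mask)))
  if (any(lab != "unlabelled"))
    cat(sprintf(": %d transverse, %d longitudinal",
                sum(lab == "transverse"), sum(lab == "longitudinal")))
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify skeleton segments as transverse or longitudinal
#'
#' Computes each segment's orientation angle theta (degrees in [0, 90])
#' between its end-to-end chord and the fibre's transverse plane, and
#' labels segments `"transverse"` when theta is below the threshold and
#' `"longitudinal"` otherwise (a segment at exactly the threshold is
#' longitudinal).
#'
#' @param skel a `skeleton`.
#' @param angle_threshold degrees, default 45.
#' @param fibre_axis unit vector of the fibre's long axis (default y).
#' @return the skeleton with per-segment `theta` and `label` fields.
#' @export
classify_segments <- function(skel, angle_threshold = 45,
                              fibre_axis = c(0, 1, 0)) {
  fibre_axis <- fibre_axis / sqrt(sum(fibre_axis^2))
  keep <- logical(length(skel$segments))
  for (i in seq_along(skel$segments)) {
    s <- skel$segments[[i]]
    chord <- s$points[nrow(s$points), ] - s$points[1, ]
    len <- sqrt(sum(chord^2))
    if (len == 0) {
      # closed loops: use the principal direction of the polyline instead
      ctr <- colMeans(s$points)
      cc <- crossprod(sweep(s$points, 2, ctr))
      chord <- eigen(cc, symmetric = TRUE)$vectors[, 1]
      len <- 1
      if (nrow(s$points) < 3) {
        warning("dropping zero-length skeleton segment")
        next
      }
    }
    theta <- asin(pmin(1, abs(sum(chord * fibre_axis)) / len)) * 180 / pi
    s$theta <- theta
    # a chord at exactly the threshold is longitudinal; the small slack
    # keeps the tie break stable against floating-point rounding
    s$label <- if (theta < angle_threshold - 1e-9) "transverse"
    else "longitudinal"
    skel$segments[[i]] <- s
    keep[i] <- TRUE
  }
  skel$segments <- skel$segments[keep]
  skel$angle_threshold <- angle_threshold
  skel$fibre_axis <- fibre_axis
  skel
}

#' Estimate the fibre's long axis
#'
#' Principal axis of the intensity second-moment tensor; used when the
#' preparation is not assumed axis-aligned.
#'
#' @param volume a `voxel_volume`.
#' @return unit 3-vector in physical coordinates.
#' @export
estimate_fibre_axis <- function(volume) {
  arr <- volume$data
  d <- dim(arr)
  w <- pmax(arr, 0)
  tot <- sum(w)
  if (tot <= 0) stop("cannot estimate an axis from a non-positive volume")
  cx <- lapply(1:3, function(a) (seq_len(d[a]) - 0.5) * volume$voxel_size[a])
  m <- c(sum(apply(w, 1, sum) * cx[[1]]),
         sum(apply(w, 2, sum) * cx[[2]]),
         sum(apply(w, 3, sum) * cx[[3]])) / tot
  cov <- matrix(0, 3, 3)
  g <- expand.grid(x = cx[[1]] - m[1], y = cx[[2]] - m[2], z = cx[[3]] - m[3])
  wv <- as.numeric(w)
  for (a in 1:3) for (b in a:3) {
    cov[a, b] <- cov[b, a] <- sum(wv * g[[a]] * g[[b]]) / tot
  }
  v <- eigen(cov, symmetric = TRUE)$vectors[, 1]
  v / sqrt(sum(v^2))
}

#' Tubule directionality histogram
#'
#' Local-orientation analysis of a longitudinal (xy) section: per-pixel
#' orientation from the smoothed structure tensor, histogrammed with
#' gradient-energy weighting and expressed as percentages relative to the
#' fibre's transverse plane (0 deg = transverse, 90 deg = parallel with
#' the fibre axis).
#'
#' @param plane numeric matrix; rows run along the transverse (x)
#'   direction, columns along the fibre (y) axis.
#' @param n_bins number of bins (>= 4) over [0, 90] (or [-90, 90] when
#'   `signed`).
#' @param sigma_grad Gaussian pre-smoothing sigma (px) for gradients.
#' @param sigma_window structure-tensor integration window sigma (px).
#' @param signed use signed angles over [-90, 90].
#' @return a `directionality_histogram`: data.frame with `bin_start_deg`,
#'   `bin_end_deg`, `percent` (summing to 100).
#' @export
directionality_histogram <- function(plane, n_bins = 18L, sigma_grad = 1,
                                     sigma_window = 2, signed = FALSE) {
  if (n_bins < 4L) stop("n_bins must be >= 4")
  if (diff(range(plane)) == 0)
    stop("constant image has no orientation energy")
  kg <- gaussian_kernel_1d(sigma_grad)
  sm <- conv_sep2(plane, kg)
  gx <- grad_dim2(sm, 1L)   # along rows = transverse direction
  gy <- grad_dim2(sm, 2L)   # along columns = fibre axis
  kw <- gaussian_kernel_1d(sigma_window)
  jxx <- conv_sep2(gx * gx, kw)
  jyy <- conv_sep2(gy * gy, kw)
  jxy <- conv_sep2(gx * gy, kw)
  # dominant gradient orientation; the local structure runs perpendicular
  phi <- 0.5 * atan2(2 * jxy, jxx - jyy)
  alpha <- phi * 180 / pi + 90        # line direction vs x (transverse) axis
  alpha <- ((alpha + 90) %% 180) - 90 # wrap to (-90, 90]
  energy <- sqrt((jxx - jyy)^2 + 4 * jxy^2)
  # drop a border margin where the integration window is truncated
  mar <- ceiling(3 * sigma_window) + 1L
  d <- dim(plane)
  if (all(d > 2 * mar + 2)) {
    keep <- matrix(FALSE, d[1], d[2])
    keep[(mar + 1):(d[1] - mar), (mar + 1):(d[2] - mar)] <- TRUE
  } else keep <- matrix(TRUE, d[1], d[2])
  a <- alpha[keep]
  w <- energy[keep]
  if (sum(w) <= 0) stop("constant image has no orientation energy")
  if (!signed) a <- abs(a)
  lo <- if (signed) -90 else 0
  edges <- seq(lo, 90, length.out = n_bins + 1L)
  bin <- pmin(n_bins, pmax(1L, findInterval(a, edges, rightmost.closed = TRUE)))
  pct <- vapply(seq_len(n_bins), function(b) sum(w[bin == b]), 0)
  pct <- 100 * pct / sum(pct)
  out <- data.frame(bin_start_deg = edges[-length(edges)],
                    bin_end_deg = edges[-1], percent = pct)
  class(out) <- c("directionality_histogram", "data.frame")
  attr(out, "signed") <- signed
  out
}

#' Radial profile of longitudinal-tubule density
#'
#' Longitudinal segment length per radial shell, normalized by shell
#' volume, quantifying the peripheral placement of longitudinal tubules.
#'
#' @param skel a labelled `skeleton` (see [classify_segments()]).
#' @param fibre_centre_nm (x, z) coordinates of the fibre axis in nm.
#' @param fibre_radius_nm fibre radius in nm.
#' @param n_shells number of equal-width shells in normalized radius.
#' @return data.frame with `r_mid` (normalized radius), `length_nm` and
#'   `density` (length per unit shell volume, arbitrary units). All-zero
#'   when there are no longitudinal segments.
#' @export
longitudinal_radial_profile <- function(skel, fibre_centre_nm,
                                        fibre_radius_nm, n_shells = 4L) {
  edges <- seq(0, 1, length.out = n_shells + 1L)
  len <- numeric(n_shells)
  for (s in skel$segments) {
    if (is.null(s$label) || s$label != "longitudinal") next
    p <- s$points
    if (nrow(p) < 2) next
    steps <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    mid <- (p[-1, , drop = FALSE] + p[-nrow(p), , drop = FALSE]) / 2
    r <- sqrt((mid[, 1] - fibre_centre_nm[1])^2 +
                (mid[, 3] - fibre_centre_nm[if (length(fibre_centre_nm) == 3) 3 else 2])^2) /
      fibre_radius_nm
    b <- pmin(n_shells, pmax(1L, findInterval(r, edges, rightmost.closed = TRUE)))
    for (i in seq_along(steps)) len[b[i]] <- len[b[i]] + steps[i]
  }
  shell_vol <- diff(edges^2)  # per unit length, ~ r2^2 - r1^2
  data.frame(r_mid = (edges[-1] + edges[-length(edges)]) / 2,
             length_nm = len,
             density = ifelse(shell_vol > 0, len / shell_vol, 0))
}

#' Score recovery of ground-truth segments
#'
#' Matches phantom ground-truth centreline segments against a labelled
#' skeleton: a truth segment is recovered when at least `min_coverage` of
#' points sampled along it lie within `tol_vox` voxels (Chebyshev) of a
#' skeleton voxel, and the majority label among the matched points agrees
#' with the truth label.
#'
#' @param truth_segments `truth$segments` from [generate_tsys_volume()].
#' @param skel a labelled `skeleton`.
#' @param voxel_size voxel size in nm.
#' @param tol_vox matching tolerance in voxels.
#' @param min_coverage minimum fraction of matched sample points.
#' @return list with `recovered_percent`, and a per-segment data.frame
#'   `detail` (`label`, `coverage`, `label_ok`, `recovered`).
#' @export
segment_recovery <- function(truth_segments, skel, voxel_size, tol_vox = 2L,
                             min_coverage = 0.6) {
  d <- skel$dim
  lab_arr <- array(0L, d)
  for (s in skel$segments) {
    if (is.null(s$label)) next
    v <- sweep(s$points, 2L, voxel_size, `/`) + 0.5
    v <- round(v)
    v[, 1] <- pmin(pmax(v[, 1], 1), d[1])
    v[, 2] <- pmin(pmax(v[, 2], 1), d[2])
    v[, 3] <- pmin(pmax(v[, 3], 1), d[3])
    code <- if (s$label == "transverse") 1L else 2L
    lab_arr[cbind(v[, 1], v[, 2], v[, 3])] <- code
  }
  offs <- as.matrix(expand.grid(dx = -tol_vox:tol_vox, dy = -tol_vox:tol_vox,
                                dz = -tol_vox:tol_vox))
  offs <- offs[order(rowSums(offs^2)), , drop = FALSE]  # nearest first
  res <- data.frame(label = character(0), coverage = numeric(0),
                    label_ok = logical(0), recovered = logical(0))
  for (ts in truth_segments) {
    p0 <- ts$points[1, ]; p1 <- ts$points[nrow(ts$points), ]
    seg_len_vox <- sqrt(sum(((p1 - p0) / voxel_size)^2))
    n_samp <- max(5L, ceiling(seg_len_vox))
    tt <- seq(0, 1, length.out = n_samp)
    pts <- outer(1 - tt, p0) + outer(tt, p1)
    vi <- round(sweep(pts, 2L, voxel_size, `/`) + 0.5)
    # per sample point, the label of the nearest skeleton voxel within
    # tolerance (offsets are distance-ordered, so first hit wins)
    vote <- rep(0L, n_samp)
    for (r in seq_len(nrow(offs))) {
      open <- vote == 0L
      if (!any(open)) break
      q <- vi[open, , drop = FALSE] + matrix(offs[r, ], sum(open), 3,
                                             byrow = TRUE)
      ok <- q[, 1] >= 1 & q[, 1] <= d[1] & q[, 2] >= 1 & q[, 2] <= d[2] &
        q[, 3] >= 1 & q[, 3] <= d[3]
      lv <- rep(0L, sum(open))
      if (any(ok)) lv[ok] <- lab_arr[cbind(q[ok, 1], q[ok, 2], q[ok, 3])]
      vote[which(open)[lv > 0L]] <- lv[lv > 0L]
    }
    coverage <- mean(vote > 0L)
    want <- if (ts$label == "transverse") 1L else 2L
    label_ok <- any(vote > 0L) && mean(vote[vote > 0L] == want) >= 0.5
    res <- rbind(res, data.frame(label = ts$label, coverage = coverage,
                                 label_ok = label_ok,
                                 recovered = coverage >= min_coverage && label_ok))
  }
  list(recovered_percent = 100 * mean(res$recovered), detail = res)
}
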