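#' Multi-channel intensity volume
#'
#' Container for a microscopy volume: a named list of non-negative intensity
#' arrays, one per channel, all of identical shape, indexed (z, y, x) for 3D
#' data or (y, x) for single-plane data, with an isotropic voxel size.
#'
#' @param data named list of numeric arrays (one per channel), or a single
#'   array (treated as one channel `ch1`).
#' @param voxel_size physical voxel edge length (> 0; any length unit).
#' @param label condition/well label carried into downstream outputs.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, voxel_size = 1, label = "") {
  if (is.array(data)) data <- list(ch1 = data)
  stopifnot(is.list(data), length(data) >= 1L, voxel_size > 0)
  if (is.null(names(data)) || any(!nzchar(names(data)))) {
    names(data) <- sprintf("ch%d", seq_along(data))
  }
  dims <- lapply(data, dim)
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    stop("all channels must share the same shape")
  }
  if (any(vapply(data, function(a) any(a < 0), logical(1)))) {
    stop("intensities must be non-negative")
  }
  structure(
    list(data = data, voxel_size = voxel_size, label = label),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf(
    "<image_volume> %s: %s, channels [%s], voxel %g\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    paste(dim(x$data[[1]]), collapse = " x "),
    paste(names(x$data), collapse = ", "),
    x$voxel_size
  ))
  invisible(x)
}

#' Read / write an image volume as multi-page TIFF
#'
#' One TIFF file per channel; z-planes are stored as TIFF pages (a plain 2D
#' image round-trips as a single page). Intensities are normalized to
#' [0, 1] per channel on write (the 16-bit convention of the \pkg{tiff}
#' package), so absolute intensity scale is not preserved across a
#' round-trip. That is immaterial for this pipeline: segmentation is
#' intensity-scale equivariant above the floor, which itself is specified
#' as a fraction of the per-condition maxima.
#'
#' @param vol an [image_volume()].
#' @param paths named character vector of file paths, one per channel.
#' @return `read_volume_tiff` returns an [image_volume()].
#' @export
write_volume_tiff <- function(vol, paths) {
  stopifnot(inherits(vol, "image_volume"),
            all(names(vol$data) %in% names(paths)))
  for (ch in names(vol$data)) {
    a <- vol$data[[ch]]
    mx <- max(a, 1e-12)
    if (length(dim(a)) == 2L) {
      tiff::writeTIFF(a / mx, paths[[ch]], bits.per.sample = 16L)
    } else {
      planes <- lapply(seq_len(dim(a)[1]), function(z) a[z, , ] / mx)
      tiff::writeTIFF(planes, paths[[ch]], bits.per.sample = 16L)
    }
  }
  invisible(paths)
}

#' @rdname write_volume_tiff
#' @param voxel_size,label metadata for the reconstructed volume.
#' @export
read_volume_tiff <- function(paths, voxel_size = 1, label = "") {
  data <- lapply(paths, function(p) {
    pages <- tiff::readTIFF(p, all = TRUE)
    if (length(pages) == 1L) {
      pages[[1]]
    } else {
      a <- array(0, dim = c(length(pages), dim(pages[[1]])))
      for (z in seq_along(pages)) a[z, , ] <- pages[[z]]
      a
    }
  })
  names(data) <- names(paths)
  image_volume(data, voxel_size = voxel_size, label = label)
}

# Ridler-Calvard iterative intermeans threshold: t is repeatedly replaced by
# the mean of the class means above/below it until it stabilizes.
iterative_threshold <- function(x, max_iter = 200L, tol = 1e-8) {
  rng <- range(x)
  if (diff(rng) <= 0) return(Inf)  # flat image: nothing to segment
  t <- mean(x)
  for (i in seq_len(max_iter)) {
    hi <- x[x > t]
    lo <- x[x <= t]
    if (length(hi) == 0L || length(lo) == 0L) break
    t_new <- (mean(hi) + mean(lo)) / 2
    if (abs(t_new - t) < tol * diff(rng)) {
      t <- t_new
      break
    }
    t <- t_new
  }
  t
}

# label connected components (26-connectivity in 3D, 8 in 2D) by iterative
# minimum-label propagation over shifted copies of the label array
label_components <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  lab <- array(0L, dim = d)
  lab[mask] <- which(mask)
  offsets <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  shift_arr <- function(a, off) {
    idx <- lapply(seq_len(nd), function(k) {
      i <- seq_len(d[k]) - off[k]
      i[i < 1L | i > d[k]] <- NA_integer_
      i
    })
    out <- do.call(`[`, c(list(a), idx))
    out[is.na(out)] <- 0L
    array(out, dim = d)
  }
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(offsets))) {
      s <- shift_arr(lab, offsets[r, ])
      upd <- mask & s > 0L & (lab == 0L | s < lab)
      if (any(upd)) {
        lab[upd] <- s[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

#' Segment condensates in one channel
#'
#' Thresholds the channel at the larger of (i) the iterative intermeans
#' (Ridler-Calvard) threshold of the image and (ii) `floor_fraction` times
#' the mean of the per-image maximum intensities across images of the same
#' condition (well), then extracts connected components (26-connectivity in
#' 3D, 8-connectivity in 2D) and discards components smaller than `min_size`
#' voxels. An empty or uniformly flat image yields an empty object list.
#'
#' @param vol an [image_volume()].
#' @param channel channel name or index.
#' @param min_size minimum component size in voxels (default 50).
#' @param floor_fraction floor as a fraction of the condition-average maximum
#'   intensity (default 0.2).
#' @param condition_max_intensities numeric vector of per-image maximum
#'   intensities for all images of the same condition; defaults to the
#'   maximum of this image alone.
#' @return List of `condensate` objects, each with elements `voxels` (linear
#'   indices), `size` (voxel count), `centroid` (physical coordinates,
#'   geometric voxel centroid times voxel size), `radius`
#'   (equivalent-sphere radius \eqn{(3V/4\pi)^{1/3}} in 3D, area-equivalent
#'   circle radius in 2D) and `channel`. The applied threshold and
#'   parameters are attached as attributes of the list.
#' @export
segment_condensates <- function(vol, channel = 1L, min_size = 50L,
                                floor_fraction = 0.2,
                                condition_max_intensities = NULL) {
  stopifnot(inherits(vol, "image_volume"))
  a <- vol$data[[channel]]
  if (is.null(a)) stop("channel not found: ", channel)
  d <- dim(a)
  nd <- length(d)
  if (is.null(condition_max_intensities)) {
    condition_max_intensities <- max(a)
  }
  floor_t <- floor_fraction * mean(condition_max_intensities)
  thr <- max(iterative_threshold(as.numeric(a)), floor_t)
  mask <- a > thr
  out <- list()
  if (any(mask)) {
    lab <- label_components(mask)
    ids <- sort(unique(lab[lab > 0L]))
    vx <- vol$voxel_size
    for (id in ids) {
      voxels <- which(lab == id)
      if (length(voxels) < min_size) next
      coords <- arrayInd(voxels, d)
      centroid <- colMeans(coords) * vx
      volume <- length(voxels) * vx^nd
      radius <- if (nd == 3L) (3 * volume / (4 * pi))^(1 / 3)
                else sqrt(volume / pi)
      out[[length(out) + 1L]] <- structure(
        list(voxels = voxels, size = length(voxels), centroid = centroid,
             radius = radius, channel = channel, dim = nd),
        class = "condensate"
      )
    }
  }
  attr(out, "threshold") <- thr
  attr(out, "floor") <- floor_t
  attr(out, "min_size") <- min_size
  attr(out, "method") <- "iterative intermeans (Ridler-Calvard) with floor"
  out
}
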