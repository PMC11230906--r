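#' Pair overlapping condensates across two channels
#'
#' Emits one record per pair of objects (one from each channel) whose voxel
#' sets intersect. An object overlapping several partners contributes one
#' record per overlapping partner; no exclusive matching is performed.
#'
#' @param objects_a,objects_b lists of condensates from
#'   [segment_condensates()] run on two channels of the same volume.
#' @return List of pairs; each pair holds the two objects (`a`, `b`), their
#'   overlap size in voxels, the raw centre-to-centre distance and the
#'   normalized CTC distance (see [normalized_ctc()]).
#' @export
pair_overlapping <- function(objects_a, objects_b) {
  pairs <- list()
  for (i in seq_along(objects_a)) {
    for (j in seq_along(objects_b)) {
      ov <- sum(objects_a[[i]]$voxels %in% objects_b[[j]]$voxels)
      if (ov > 0L) {
        p <- list(a = objects_a[[i]], b = objects_b[[j]], overlap = ov)
        p$raw_ctc <- sqrt(sum((p$a$centroid - p$b$centroid)^2))
        p$norm_ctc <- normalized_ctc(p)
        pairs[[length(pairs) + 1L]] <- p
      }
    }
  }
  pairs
}

#' Normalized centre-to-centre (CTC) distance
#'
#' The Euclidean distance between the two condensates' centroids divided by
#' the sum of their equivalent radii. The value is approximately 0 for two
#' miscible (colocalized) condensates and approximately 1 for two associated
#' but immiscible condensates that touch externally.
#'
#' @param pair a pair record from [pair_overlapping()], or any list with
#'   elements `a` and `b` each holding `centroid` and `radius`.
#' @return Dimensionless normalized CTC distance (>= 0).
#' @export
normalized_ctc <- function(pair) {
  r_sum <- pair$a$radius + pair$b$radius
  if (!(r_sum > 0)) stop("normalized_ctc: sum of radii must be positive")
  sqrt(sum((pair$a$centroid - pair$b$centroid)^2)) / r_sum
}

#' Frequency distribution of normalized CTC distances
#'
#' Bins values into right-open intervals [k*w, (k+1)*w) starting at 0 and
#' reports frequencies as percentages summing to 100, together with the
#' median of the raw (unbinned) values. The default bin width of 0.1
#' absorbs measurement noise in the normalized distance.
#'
#' @param values numeric vector of normalized CTC distances (>= 1 value).
#' @param bin_width bin width (default 0.1).
#' @return data.frame with `bin_lo`, `bin_hi`, `count` and `percent`
#'   columns; the median and n are attached as attributes `median` and `n`.
#' @export
ctc_histogram <- function(values, bin_width = 0.1) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("ctc_histogram: no values supplied")
  if (any(values < 0)) stop("ctc_histogram: negative normalized distances")
  k <- floor(values / bin_width)
  n_bins <- max(k) + 1L
  counts <- tabulate(k + 1L, nbins = n_bins)
  out <- data.frame(
    bin_lo = (seq_len(n_bins) - 1L) * bin_width,
    bin_hi = seq_len(n_bins) * bin_width,
    count = counts,
    percent = 100 * counts / length(values)
  )
  attr(out, "median") <- median(values)
  attr(out, "n") <- length(values)
  out
}

#' End-to-end CTC analysis of a two-channel volume
#'
#' Runs [segment_condensates()] on both channels, pairs overlapping objects
#' and returns one row per pair with raw and normalized CTC distances.
#'
#' @param vol an [image_volume()] with at least two channels.
#' @param channels length-2 vector of channel names or indices.
#' @inheritParams segment_condensates
#' @return data.frame with columns `label`, `pair`, `size_a`, `size_b`,
#'   `radius_a`, `radius_b`, `raw_ctc`, `norm_ctc` (zero rows when no
#'   overlapping pairs exist).
#' @export
ctc_analysis <- function(vol, channels = c(1L, 2L), min_size = 50L,
                         floor_fraction = 0.2,
                         condition_max_intensities = NULL) {
  obj <- lapply(channels, function(ch) {
    cmi <- if (is.null(condition_max_intensities)) NULL
           else condition_max_intensities[[as.character(ch)]]
    segment_condensates(vol, ch, min_size = min_size,
                        floor_fraction = floor_fraction,
                        condition_max_intensities = cmi)
  })
  pairs <- pair_overlapping(obj[[1]], obj[[2]])
  if (length(pairs) == 0L) {
    return(data.frame(label = character(), pair = integer(),
                      size_a = integer(), size_b = integer(),
                      radius_a = numeric(), radius_b = numeric(),
                      raw_ctc = numeric(), norm_ctc = numeric()))
  }
  data.frame(
    label = vol$label,
    pair = seq_along(pairs),
    size_a = vapply(pairs, function(p) p$a$size, integer(1)),
    size_b = vapply(pairs, function(p) p$b$size, integer(1)),
    radius_a = vapply(pairs, function(p) p$a$radius, numeric(1)),
    radius_b = vapply(pairs, function(p) p$b$radius, numeric(1)),
    raw_ctc = vapply(pairs, function(p) p$raw_ctc, numeric(1)),
    norm_ctc = vapply(pairs, function(p) p$norm_ctc, numeric(1)),
    stringsAsFactors = FALSE
  )
}
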