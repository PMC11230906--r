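test_that("segmentation applies the size filter and intensity floor", {
  # a ~200-voxel and a ~40-voxel sphere: min_size 50 keeps exactly one
  spheres <- data.frame(
    channel = 1L, z = c(16, 16), y = c(12, 36), x = c(12, 36),
    r = c(3.7, 2.1), amplitude = 100  # ~212 and ~39 voxels
  )
  vol <- synth_two_channel_volume(dim = c(32, 48, 48), spheres = spheres)
  obj <- segment_condensates(vol, 1, min_size = 50, floor_fraction = 0.2)
  expect_length(obj, 1L)
  expect_gte(obj[[1]]$size, 150L)
  # with a permissive size filter both objects appear
  obj2 <- segment_condensates(vol, 1, min_size = 10, floor_fraction = 0.2)
  expect_length(obj2, 2L)
  # blank volume segments to nothing, without erroring
  blank <- image_volume(array(0, dim = c(16, 16, 16)))
  expect_length(segment_condensates(blank, 1, condition_max_intensities = 1), 0L)
})

test_that("objects below the condition floor are suppressed", {
  spheres <- data.frame(channel = 1L, z = 16, y = 16, x = 16, r = 5,
                        amplitude = 10)
  vol <- synth_two_channel_volume(dim = c(32, 32, 32), spheres = spheres)
  # other images of this condition were 10x brighter: floor = 0.2 * 100 > 10
  obj <- segment_condensates(vol, 1, min_size = 20,
                             condition_max_intensities = c(100, 100, 100))
  expect_length(obj, 0L)
  # with this image's own maximum the sphere is found
  obj2 <- segment_condensates(vol, 1, min_size = 20)
  expect_length(obj2, 1L)
})

test_that("segmentation is intensity-scale equivariant above the floor", {
  spheres <- data.frame(channel = 1L, z = c(12, 20), y = c(10, 22),
                        x = c(10, 22), r = c(4, 5), amplitude = c(80, 120))
  vol <- synth_two_channel_volume(dim = c(32, 32, 32), spheres = spheres,
                                  noise_sd = 3, seed = 2)
  cmx <- max(vol$data$ch1)
  obj1 <- segment_condensates(vol, 1, min_size = 20,
                              condition_max_intensities = cmx)
  vol2 <- vol
  vol2$data$ch1 <- vol$data$ch1 * 7.5
  obj2 <- segment_condensates(vol2, 1, min_size = 20,
                              condition_max_intensities = 7.5 * cmx)
  expect_identical(lapply(obj1, `[[`, "voxels"), lapply(obj2, `[[`, "voxels"))
})

test_that("equivalent radius of a synthetic sphere is recovered within a voxel", {
  for (r_true in c(4, 6, 9)) {
    spheres <- data.frame(channel = 1L, z = 24, y = 24, x = 24, r = r_true,
                          amplitude = 100)
    vol <- synth_two_channel_volume(dim = c(48, 48, 48), spheres = spheres)
    obj <- segment_condensates(vol, 1, min_size = 20)
    expect_length(obj, 1L)
    expect_lt(abs(obj[[1]]$radius - r_true), 1)
    # radius = (3 V / 4 pi)^(1/3) with V = count * voxel^3
    expect_equal(obj[[1]]$radius,
                 (3 * obj[[1]]$size / (4 * pi))^(1 / 3), tolerance = 1e-12)
  }
})

test_that("overlap pairing emits one record per intersecting pair", {
  mk <- function(vox, centroid, radius) {
    structure(list(voxels = vox, size = length(vox), centroid = centroid,
                   radius = radius, channel = 1L, dim = 3L),
              class = "condensate")
  }
  a1 <- mk(1:100, c(5, 5, 5), 3)
  b_far <- mk(1000:1100, c(20, 20, 20), 3)
  expect_length(pair_overlapping(list(a1), list(b_far)), 0L)
  # identical voxel sets: one pair at zero distance
  p <- pair_overlapping(list(a1), list(a1))
  expect_length(p, 1L)
  expect_identical(p[[1]]$raw_ctc, 0)
  expect_identical(p[[1]]$norm_ctc, 0)
  # one large object overlapping two small ones: two records
  big <- mk(1:500, c(10, 10, 10), 6)
  s1 <- mk(450:520, c(14, 10, 10), 2)
  s2 <- mk(1:30, c(6, 10, 10), 2)
  expect_length(pair_overlapping(list(big), list(s1, s2)), 2L)
})

test_that("normalized CTC geometry: concentric 0, tangent 1, half overlap 0.5", {
  mk <- function(centroid, radius) list(centroid = centroid, radius = radius)
  expect_equal(normalized_ctc(list(a = mk(c(0, 0, 0), 5), b = mk(c(0, 0, 0), 3))), 0)
  expect_equal(normalized_ctc(list(a = mk(c(0, 0, 0), 4), b = mk(c(7, 0, 0), 3))), 1)
  expect_equal(normalized_ctc(list(a = mk(c(0, 0, 0), 10), b = mk(c(10, 0, 0), 10))), 0.5)
  expect_error(normalized_ctc(list(a = mk(c(0, 0, 0), 0), b = mk(c(1, 0, 0), 0))),
               "positive")
})

test_that("normalized CTC is invariant to translation, axis order and voxel size", {
  base <- sphere_pair_spec(c(20, 24, 28), 6, 7, offset = 0.6)
  run <- function(spheres, voxel_size = 1) {
    vol <- synth_two_channel_volume(dim = c(48, 56, 64), spheres = spheres,
                                    voxel_size = voxel_size)
    ctc_analysis(vol, min_size = 20)$norm_ctc
  }
  v0 <- run(base)
  shifted <- base
  shifted$z <- shifted$z + 4
  shifted$y <- shifted$y - 3
  shifted$x <- shifted$x + 5
  expect_equal(run(shifted), v0, tolerance = 1e-6)
  swapped <- base
  swapped[, c("z", "y")] <- base[, c("y", "z")]
  expect_equal(run(swapped), v0, tolerance = 0.02)
  expect_equal(run(base, voxel_size = 0.25), v0, tolerance = 1e-6)
})

test_that("CTC histogram bins right-open, sums to 100%, reports raw median", {
  h <- ctc_histogram(c(0.05, 0.15, 0.25), bin_width = 0.1)
  expect_equal(h$percent, rep(100 / 3, 3))
  expect_equal(sum(h$percent), 100)
  expect_equal(h$bin_lo, c(0, 0.1, 0.2))
  # perfect colocalization reference: everything in the lowest bin
  h0 <- ctc_histogram(rep(0, 25), bin_width = 0.1)
  expect_equal(h0$percent[1], 100)
  expect_equal(attr(h0, "median"), 0)
  expect_equal(attr(ctc_histogram(c(0, 0.1, 0.3)), "median"), 0.1)
  # boundary values fall in the right-open upper bin
  hb <- ctc_histogram(c(0.1), bin_width = 0.1)
  expect_equal(hb$percent, c(0, 100))
  expect_error(ctc_histogram(numeric(0)), "no values")
})

test_that("programmed normalized offsets are recovered end to end", {
  offsets <- c(0, 0.25, 0.5, 0.75, 1.0)
  for (k in seq_along(offsets)) {
    sp <- sphere_pair_spec(c(24, 30, 24), 8, 8, offset = offsets[k])
    vol <- synth_two_channel_volume(dim = c(48, 60, 72), spheres = sp,
                                    noise_sd = 5, seed = 40 + k)  # 5% of amplitude
    res <- ctc_analysis(vol, min_size = 50, floor_fraction = 0.2)
    expect_equal(nrow(res), 1L)
    expect_lt(abs(res$norm_ctc - offsets[k]), 0.05)
  }
})
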