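#' Generate a series of K/E sequences with prescribed blockiness
#'
#' Builds charge-neutral, fixed-composition (half K, half E) sequences whose
#' normalized patterning scores Omega match a ladder of targets, by
#' simulated-annealing pair swaps. Each level starts from the strictly
#' alternating sequence (or the exact diblock when the target is 1) and
#' minimizes |Omega - target| by swapping opposite-charge positions, with a
#' geometric cooling schedule. The achieved Omega values are returned so a
#' caller can verify how closely each target was met; a level whose residual
#' exceeds `tol` is flagged (attribute `converged`), never silently dropped.
#'
#' @param length even sequence length (default 50, the conventional length
#'   for this model polyampholyte family).
#' @param targets strictly ascending Omega targets in (0, 1].
#' @param anneal_steps Monte-Carlo swap attempts per level.
#' @param seed integer seed; the series is deterministic given the seed.
#' @param tol residual |Omega - target| above which a level is flagged.
#' @param names optional names for the levels (default KE1, KE2, ...).
#' @return Named list of [charge_sequence()] objects with attributes
#'   `omega_achieved`, `omega_target` and `converged`.
#' @export
generate_sequence_series <- function(length = 50L,
                                     targets = c(0.02, 0.08, 0.16, 0.28,
                                                 0.33, 0.37, 0.42),
                                     anneal_steps = 20000L,
                                     seed = 1L,
                                     tol = 0.005,
                                     names = NULL) {
  n <- as.integer(length)
  if (n %% 2L != 0L || n < 4L) stop("length must be even and >= 4")
  if (any(diff(targets) <= 0) || any(targets <= 0) || any(targets > 1)) {
    stop("targets must be strictly ascending in (0, 1]")
  }
  if (is.null(names)) names <- sprintf("KE%d", seq_along(targets))

  w <- sqrt(abs(outer(seq_len(n), seq_len(n), "-")))
  # Omega = SCD/SCD_diblock; both SCDs negative, so the ratio is positive.
  qd <- c(rep(1, n / 2), rep(-1, n / 2))
  ref_signed <- (qd %*% w %*% qd)[1] / (2 * n)
  omega_of <- function(qWq) (qWq / (2 * n)) / ref_signed

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  out <- vector("list", length(targets))
  for (lev in seq_along(targets)) {
    target <- targets[lev]
    if (target == 1) {
      q <- qd
    } else {
      q <- rep(c(1, -1), n / 2)  # alternating start, Omega near 0
      qWq <- (q %*% w %*% q)[1]
      cost <- abs(omega_of(qWq) - target)
      temp <- 0.05
      cool <- exp(log(1e-4 / temp) / anneal_steps)
      for (step in seq_len(anneal_steps)) {
        a <- sample.int(n, 1L)
        b <- sample.int(n, 1L)
        if (q[a] == q[b]) { temp <- temp * cool; next }
        dqa <- -2 * q[a]; dqb <- -2 * q[b]
        dqWq <- 2 * dqa * sum(w[a, ] * q) + 2 * dqb * sum(w[b, ] * q) +
          2 * dqa * dqb * w[a, b]
        new_cost <- abs(omega_of(qWq + dqWq) - target)
        if (new_cost <= cost || runif(1) < exp((cost - new_cost) / temp)) {
          q[a] <- -q[a]; q[b] <- -q[b]
          qWq <- qWq + dqWq
          cost <- new_cost
        }
        temp <- temp * cool
        if (cost < 1e-4) break
      }
    }
    res <- ifelse(q > 0, "K", "E")
    s <- charge_sequence(res, name = names[lev])
    attr(s, "omega_target") <- target
    attr(s, "omega_achieved") <- compute_omega(s)
    attr(s, "converged") <- abs(attr(s, "omega_achieved") - target) <= tol
    if (!attr(s, "converged")) {
      warning(sprintf(
        "level %s: best achieved Omega %.4f for target %.4f (residual > %g)",
        names[lev], attr(s, "omega_achieved"), target, tol
      ))
    }
    out[[lev]] <- s
  }
  names(out) <- names
  out
}

#' Synthetic two-phase density profile with known truth
#'
#' Generates a density profile from the symmetric slab model
#' \deqn{\rho(z) = \frac{\rho_{den}+\rho_{dil}}{2} -
#'   \frac{\rho_{den}-\rho_{dil}}{2}\tanh\left(\frac{|z - L_z/2| - z_0}{w}\right)}
#' plus optional seeded Gaussian noise. The exact generating parameters are
#' stored in the `truth` attribute so the profile can serve as an oracle for
#' [fit_tanh()].
#'
#' @param rho_den,rho_dil dense and dilute plateau densities
#'   (`rho_den > rho_dil >= 0`).
#' @param z0 half-width of the dense region (distance of each interface from
#'   the slab centre).
#' @param w interface width.
#' @param Lz box length along z.
#' @param n_bins number of z bins.
#' @param noise_sd Gaussian noise standard deviation (0 for exact curve).
#' @param seed seed for the noise.
#' @return A `density_profile` object (see [density_profile()]) with a
#'   `truth` attribute.
#' @export
synth_density_profile <- function(rho_den, rho_dil, z0, w, Lz = 400,
                                  n_bins = 200L, noise_sd = 0, seed = 1L) {
  if (!(rho_den > rho_dil && rho_dil >= 0)) {
    stop("require rho_den > rho_dil >= 0")
  }
  edges <- seq(0, Lz, length.out = n_bins + 1L)
  z <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  rho <- (rho_den + rho_dil) / 2 -
    (rho_den - rho_dil) / 2 * tanh((abs(z - Lz / 2) - z0) / w)
  if (noise_sd > 0) {
    # zero-mean noise is added as-is (no clipping at 0): clipping would bias
    # plateau estimators that this generator exists to calibrate
    noise <- local({
      set.seed(seed)
      rnorm(n_bins, sd = noise_sd)
    })
    rho <- rho + noise
  }
  prof <- new_density_profile(z = z, rho = rho, Lz = Lz, n_frames = 1L,
                              species = "synthetic")
  attr(prof, "truth") <- list(rho_den = rho_den, rho_dil = rho_dil,
                              z0 = z0, w = w)
  prof
}

#' Synthetic two-channel condensate image volume
#'
#' Rasterizes spheres into a two-channel 3D intensity volume, with optional
#' Gaussian blur (an isotropic stand-in for a point-spread function), shot
#' noise and additive Gaussian read noise. Sphere pairs across channels can
#' be placed at programmed normalized centre-to-centre offsets, making the
#' volume a ground-truth oracle for the segmentation/CTC pipeline.
#'
#' @param dim integer vector (z, y, x) of the volume shape.
#' @param spheres data.frame with columns `channel` (1 or 2), `z`, `y`, `x`
#'   (centre, voxel coordinates), `r` (radius, voxels) and `amplitude`.
#' @param voxel_size physical edge length of a voxel (arbitrary length unit).
#' @param background constant background level.
#' @param noise_sd additive Gaussian noise sd (absolute intensity units).
#' @param shot_noise if TRUE, voxel intensities are Poisson-resampled.
#' @param blur_sd isotropic Gaussian blur sd in voxels (0 = no blur).
#' @param channels channel names.
#' @param seed noise seed.
#' @return An `image_volume` (see [image_volume()]) with a `truth` attribute
#'   holding the sphere table. Same-channel overlapping spheres are allowed
#'   but flagged via the `overlap_flag` attribute.
#' @export
synth_two_channel_volume <- function(dim = c(48L, 64L, 64L),
                                     spheres,
                                     voxel_size = 1,
                                     background = 0,
                                     noise_sd = 0,
                                     shot_noise = FALSE,
                                     blur_sd = 0,
                                     channels = c("ch1", "ch2"),
                                     seed = 1L) {
  stopifnot(length(dim) == 3L, all(dim >= 4L))
  needed <- c("channel", "z", "y", "x", "r", "amplitude")
  if (!all(needed %in% names(spheres))) {
    stop("spheres must have columns ", paste(needed, collapse = ", "))
  }
  for (i in seq_len(nrow(spheres))) {
    ctr <- as.numeric(spheres[i, c("z", "y", "x")])
    if (any(ctr - spheres$r[i] < 1) || any(ctr + spheres$r[i] > dim)) {
      stop("sphere ", i, " does not fit within the volume")
    }
  }
  data <- lapply(seq_along(channels), function(ch) {
    vol <- array(background, dim = dim)
    rows <- which(spheres$channel == ch)
    for (i in rows) {
      r <- spheres$r[i]
      cz <- spheres$z[i]; cy <- spheres$y[i]; cx <- spheres$x[i]
      zr <- max(1L, floor(cz - r)):min(dim[1], ceiling(cz + r))
      yr <- max(1L, floor(cy - r)):min(dim[2], ceiling(cy + r))
      xr <- max(1L, floor(cx - r)):min(dim[3], ceiling(cx + r))
      d2 <- outer(
        outer((zr - cz)^2, (yr - cy)^2, "+"),
        (xr - cx)^2, "+"
      )
      inside <- d2 <= r^2
      sub <- vol[zr, yr, xr]
      sub[inside] <- sub[inside] + spheres$amplitude[i]
      vol[zr, yr, xr] <- sub
    }
    if (blur_sd > 0) vol <- gaussian_blur_3d(vol, blur_sd)
    vol
  })
  names(data) <- channels
  if (shot_noise || noise_sd > 0) {
    set.seed(seed)
    data <- lapply(data, function(vol) {
      if (shot_noise) {
        vol[] <- rpois(length(vol), pmax(vol, 0))
      }
      if (noise_sd > 0) {
        vol <- vol + rnorm(length(vol), sd = noise_sd)
      }
      pmax(vol, 0)
    })
  }
  # flag same-channel overlaps (allowed, but relevant when interpreting truth)
  overlap <- FALSE
  for (ch in unique(spheres$channel)) {
    rows <- which(spheres$channel == ch)
    if (length(rows) > 1L) {
      for (i in rows) for (j in rows) {
        if (i < j) {
          d <- sqrt(sum((spheres[i, c("z", "y", "x")] -
                           spheres[j, c("z", "y", "x")])^2))
          if (d < spheres$r[i] + spheres$r[j]) overlap <- TRUE
        }
      }
    }
  }
  vol <- image_volume(data, voxel_size = voxel_size, label = "synthetic")
  truth <- spheres
  truth$equiv_radius <- spheres$r
  attr(vol, "truth") <- truth
  attr(vol, "overlap_flag") <- overlap
  if (overlap) warning("same-channel spheres overlap; truth table radii refer to isolated spheres")
  vol
}

#' Place a two-channel sphere pair at a programmed normalized offset
#'
#' Convenience constructor for [synth_two_channel_volume()] truth tables:
#' returns a two-row sphere table with one sphere per channel whose centre
#' separation equals `offset * (r1 + r2)`, i.e. the programmed normalized
#' centre-to-centre distance is `offset` by construction.
#'
#' @param centre (z, y, x) centre of the channel-1 sphere.
#' @param r1,r2 radii in voxels.
#' @param offset programmed normalized CTC offset (0 = concentric,
#'   1 = externally tangent).
#' @param axis axis (1 = z, 2 = y, 3 = x) along which the second sphere is
#'   displaced.
#' @param amplitude intensity amplitude for both spheres.
#' @return data.frame usable as the `spheres` argument.
#' @export
sphere_pair_spec <- function(centre, r1, r2, offset, axis = 3L,
                             amplitude = 100) {
  delta <- c(0, 0, 0)
  delta[axis] <- offset * (r1 + r2)
  data.frame(
    channel = c(1L, 2L),
    z = c(centre[1], centre[1] + delta[1]),
    y = c(centre[2], centre[2] + delta[2]),
    x = c(centre[3], centre[3] + delta[3]),
    r = c(r1, r2),
    amplitude = amplitude
  )
}

# separable 3D Gaussian blur with reflected edges; kernel truncated at 3 sd
gaussian_blur_3d <- function(vol, sd) {
  half <- max(1L, ceiling(3 * sd))
  k <- dnorm(seq(-half, half), sd = sd)
  k <- k / sum(k)
  conv_axis <- function(a, axis) {
    d <- dim(a)
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = dim(ap)[1])
    n <- nrow(m)
    idx <- outer(seq_len(n), seq(-half, half), "+")
    idx[idx < 1L] <- 2L - idx[idx < 1L]
    idx[idx > n] <- 2L * n - idx[idx > n]
    out <- matrix(0, n, ncol(m))
    for (j in seq_len(2L * half + 1L)) {
      out <- out + k[j] * m[idx[, j], , drop = FALSE]
    }
    ap[] <- out
    aperm(ap, order(perm))
  }
  for (ax in 1:3) vol <- conv_axis(vol, ax)
  vol
}
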