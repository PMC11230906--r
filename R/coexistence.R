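new_density_profile <- function(z, rho, Lz, n_frames, species,
                                rho_frames = NULL, area = NA_real_) {
  structure(
    list(z = z, rho = rho, Lz = Lz, n_frames = n_frames, species = species,
         rho_frames = rho_frames, area = area),
    class = "density_profile"
  )
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf(
    "<density_profile> species %s: %d bins over Lz = %g A, %d frame(s), peak %.3g\n",
    x$species, length(x$z), x$Lz, x$n_frames, max(x$rho)
  ))
  invisible(x)
}

# per-bead species labels (from per-molecule labels); CORE beads are scaffold
bead_species <- function(top) top$species[top$molecule_id]

# circular mean of z positions on a periodic axis of length Lz
circular_mean_z <- function(z, Lz) {
  th <- z / Lz * 2 * pi
  (atan2(mean(sin(th)), mean(cos(th))) %% (2 * pi)) * Lz / (2 * pi)
}

#' Number-density profile along z
#'
#' Bins polyampholyte beads (CORE scaffold beads are excluded: they are not
#' component material) of one species into `n_bins` z slabs, recentring each
#' frame on the dense material's centre of mass (circular mean over the
#' periodic z axis, computed from all polyampholyte beads) before averaging,
#' so the slab does not smear out by diffusing along z. Densities are bead
#' number concentrations (beads per cubic Angstrom); the integral of the
#' profile over the box recovers the total bead count of the species.
#'
#' @param traj a `cg_trajectory` from [run_coexistence()] / [run_md()] with
#'   stored frames.
#' @param species species label (as in the topology), or "all".
#' @param n_bins number of z bins (>= 10).
#' @param frames optional integer subset of frame indices.
#' @param mode `"bead"` bins polyampholyte beads (the default concentration
#'   measure); `"molecule"` bins molecule centroids, giving a molar
#'   concentration. At full scale the two are proportional within a phase;
#'   at reduced scale the molecule mode is robust to large molecules
#'   straddling an interface (arms reaching across a boundary do not smear
#'   the molecule's position), which matters for partition coefficients of
#'   oligomerized species in thin slabs.
#' @return A `density_profile` with the frame-resolved profiles in
#'   `$rho_frames` (bins x frames) for block analysis.
#' @export
density_profile <- function(traj, species = "all", n_bins = 100L,
                            frames = NULL, mode = c("bead", "molecule")) {
  mode <- match.arg(mode)
  if (length(traj$frames) < 1L) stop("trajectory has no stored frames")
  if (n_bins < 10L) stop("n_bins must be >= 10")
  top <- traj$topology
  Lz <- traj$box[3L]
  area <- traj$box[1L] * traj$box[2L]
  poly <- top$bead_type != "CORE"
  sel <- if (identical(species, "all")) poly else {
    poly & bead_species(top) == species
  }
  if (!any(sel)) stop("no beads for species '", species, "'")
  if (is.null(frames)) frames <- seq_along(traj$frames)
  edges <- seq(0, Lz, length.out = n_bins + 1L)
  binw <- Lz / n_bins
  rho_frames <- matrix(0, n_bins, length(frames))
  mol_of_sel <- top$molecule_id[sel]
  for (k in seq_along(frames)) {
    pos <- traj$frames[[frames[k]]]
    zc <- circular_mean_z(pos[poly, 3L], Lz)
    z <- (pos[sel, 3L] - zc + Lz / 2) %% Lz
    if (mode == "molecule") {
      # circular-mean centroid per molecule (molecules are compact relative
      # to the box, so the recentred coordinates are effectively unwrapped)
      z <- vapply(split(z, mol_of_sel), circular_mean_z, numeric(1), Lz = Lz)
    }
    counts <- tabulate(pmin(floor(z / binw) + 1L, n_bins), nbins = n_bins)
    rho_frames[, k] <- counts / (area * binw)
  }
  z_mid <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  new_density_profile(
    z = z_mid, rho = rowMeans(rho_frames), Lz = Lz,
    n_frames = length(frames),
    species = if (identical(species, "all")) "all" else species,
    rho_frames = rho_frames, area = area
  )
}

#' Fit a hyperbolic-tangent slab model to a density profile
#'
#' Least-squares fit of the symmetric two-interface slab model
#' \deqn{\rho(z) = \frac{\rho_{den}+\rho_{dil}}{2} -
#'   \frac{\rho_{den}-\rho_{dil}}{2}
#'   \tanh\!\left(\frac{|z - z_c| - z_0}{w}\right)}
#' with the slab centre fixed at \eqn{z_c = L_z/2} (profiles from
#' [density_profile()] are recentred there). The fit is parameterized as
#' \eqn{\rho_{den} = \rho_{dil} + \Delta} with \eqn{\Delta \ge 0}, so
#' \eqn{\rho_{den} \ge \rho_{dil}} holds by construction. Profiles without
#' usable dynamic range, and fits that fail to converge, fall back to robust
#' quantile plateau estimates (10th/90th percentiles) and are flagged via
#' `converged = FALSE` — never silently.
#'
#' @param profile a `density_profile`.
#' @param min_dynamic_range minimum (max - min) / max of the profile for a
#'   fit to be attempted.
#' @return list of class `tanh_fit`: `rho_den`, `rho_dil`, `z0`, `w`, `zc`,
#'   `cov` (parameter covariance or NULL), `converged`, `degenerate`.
#' @export
fit_tanh <- function(profile, min_dynamic_range = 0.2) {
  z <- profile$z
  rho <- profile$rho
  Lz <- profile$Lz
  zc <- Lz / 2
  q10 <- as.numeric(quantile(rho, 0.1))
  q90 <- as.numeric(quantile(rho, 0.9))
  fallback <- function(degenerate) {
    structure(
      list(rho_den = q90, rho_dil = q10,
           z0 = Lz / 4, w = Lz / 20, zc = zc, cov = NULL,
           converged = FALSE, degenerate = degenerate),
      class = "tanh_fit"
    )
  }
  rng <- max(rho) - min(rho)
  if (max(rho) <= 0 || rng / max(rho) < min_dynamic_range) {
    return(fallback(degenerate = TRUE))
  }
  mid <- (q90 + q10) / 2
  z0_start <- max(sum(rho > mid) / length(rho) * Lz / 2, Lz / 50)
  dat <- data.frame(az = abs(z - zc), rho = rho)
  # rho_dil must start on the profile's scale even when the dilute phase is
  # empty: a ~0 start makes the internally rescaled Jacobian singular
  starts <- list(
    list(rho_dil = max(q10, 0.02 * q90), delta = max(q90 - q10, 0.1 * q90),
         z0 = z0_start, w = Lz / 50),
    list(rho_dil = max(q10, 0.02 * q90), delta = max(q90 - q10, 0.1 * q90),
         z0 = Lz / 6, w = Lz / 20),
    list(rho_dil = 0.1 * q90, delta = 0.8 * q90, z0 = Lz / 3, w = Lz / 30)
  )
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        rho ~ (2 * rho_dil + delta) / 2 - delta / 2 * tanh((az - z0) / w),
        data = dat,
        start = st,
        lower = c(0, 0, 1e-6, 1e-6),
        upper = c(Inf, Inf, Lz / 2, Lz),
        control = nls.control(maxiter = 200, warnOnly = FALSE)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(fallback(degenerate = FALSE))
  p <- coef(fit)
  structure(
    list(rho_den = unname(p["rho_dil"] + p["delta"]),
         rho_dil = unname(p["rho_dil"]),
         z0 = unname(p["z0"]), w = unname(p["w"]), zc = zc,
         cov = tryCatch(vcov(fit), error = function(e) NULL),
         converged = TRUE, degenerate = FALSE),
    class = "tanh_fit"
  )
}

#' @export
print.tanh_fit <- function(x, ...) {
  cat(sprintf(
    "<tanh_fit> rho_den %.4g, rho_dil %.4g, z0 %.1f, w %.1f%s\n",
    x$rho_den, x$rho_dil, x$z0, x$w,
    if (!x$converged) " [fallback quantile estimates]" else ""
  ))
  invisible(x)
}

# evaluate a tanh_fit at |z - zc|
predict_tanh <- function(fit, z) {
  (fit$rho_den + fit$rho_dil) / 2 -
    (fit$rho_den - fit$rho_dil) / 2 * tanh((abs(z - fit$zc) - fit$z0) / fit$w)
}

#' Partition coefficient of species p in a binary slab
#'
#' Quantifies immiscibility as
#' \eqn{K_p = C_p^{den} / C_p^{dil}}, the concentration of component p in
#' the q-lean condensed phase divided by its concentration in the q-rich
#' phase. The condensed region is where the total (p + q) profile exceeds
#' the midpoint of its tanh fit (quantile plateaus when the fit is flagged);
#' within it, bins where q exceeds its own plateau midpoint are q-rich and
#' the rest are q-lean. Working bin-wise rather than from a symmetric
#' interface geometry keeps the rule valid for any slab arrangement —
#' centred q with a p annulus, or two side-by-side sub-slabs. One bin on
#' each side of every region boundary is eroded as interface exclusion.
#'
#' If the q-lean region is empty, or q's density there is not substantially
#' depleted (above `deplete_ratio` of its q-rich level, i.e. the "q-lean"
#' bins are noise rather than a phase), the components are co-condensed: the
#' result is flagged miscible and K_p falls back to the ratio of p's
#' concentration between the two geometric halves of the condensed core — an
#' unbiased null statistic equal to 1 in expectation for mixed components.
#'
#' The uncertainty is the standard error over `n_blocks` contiguous frame
#' blocks (after discarding the first `burn_in` fraction of frames), with
#' the region definitions held fixed across blocks.
#'
#' @param prof_p,prof_q `density_profile` objects for the two species from
#'   the same trajectory (matching bins), carrying frame-resolved profiles.
#' @param n_blocks number of blocks for the SEM (>= 2).
#' @param burn_in fraction of initial frames discarded.
#' @param deplete_ratio maximum mean_q(q-lean) / mean_q(q-rich) for the
#'   q-lean region to count as a distinct phase (default 0.5).
#' @param prof_p_measure optional profile of p used for the concentration
#'   ratio itself (the regions always come from the bead profiles). Passing
#'   p's molecule-centroid profile (see [density_profile()] `mode`) makes
#'   K_p a molar partition coefficient, robust at reduced scale to large
#'   oligomers whose arms straddle an interface. When a measurement block
#'   contains no p in the q-rich region, the denominator is floored at half
#'   a molecule in that region's volume (reported K_p is then a lower
#'   bound), rather than dropped.
#' @return list of class `kp_result`: `kp`, `sem`, `kp_blocks`, `miscible`,
#'   `regions` (logical bin masks), and the underlying fits.
#' @export
partition_coefficient <- function(prof_p, prof_q, n_blocks = 5L,
                                  burn_in = 0.2, deplete_ratio = 0.5,
                                  prof_p_measure = NULL) {
  stopifnot(length(prof_p$z) == length(prof_q$z))
  if (is.null(prof_p$rho_frames) || is.null(prof_q$rho_frames)) {
    stop("profiles must carry frame-resolved densities (rho_frames)")
  }
  n_fr <- ncol(prof_p$rho_frames)
  keep <- seq.int(floor(burn_in * n_fr) + 1L, n_fr)
  if (length(keep) < n_blocks) stop("fewer post-burn-in frames than blocks")
  z <- prof_p$z
  nb <- length(z)

  mean_p <- rowMeans(prof_p$rho_frames[, keep, drop = FALSE])
  mean_q <- rowMeans(prof_q$rho_frames[, keep, drop = FALSE])
  prof_tot <- new_density_profile(z, mean_p + mean_q, prof_p$Lz,
                                  length(keep), "total")
  prof_qm <- new_density_profile(z, mean_q, prof_q$Lz, length(keep),
                                 prof_q$species)
  fit_q <- fit_tanh(prof_qm)
  fit_tot <- fit_tanh(prof_tot)

  erode <- function(mask) {
    # drop bins adjacent to a region boundary (interface exclusion)
    up <- c(mask[-1L], FALSE)
    dn <- c(FALSE, mask[-nb])
    mask & up & dn
  }
  # region midpoints from robust plateau quantiles: a smeared or partially
  # converged tanh fit must not shift the region masks (the fits are still
  # reported for plateau values and diagnostics)
  tot <- mean_p + mean_q
  mid_tot <- (as.numeric(quantile(tot, 0.95)) +
                as.numeric(quantile(tot, 0.05))) / 2
  condensed <- erode(tot > mid_tot)
  if (sum(condensed) < 2L) {
    stop("no usable condensed region; the system may not be phase separated")
  }
  q_core <- mean_q[condensed]
  mid_q <- (as.numeric(quantile(q_core, 0.95)) +
              as.numeric(quantile(q_core, 0.05))) / 2
  q_rich <- erode(condensed & (mean_q > mid_q))
  q_lean <- erode(condensed & (mean_q <= mid_q))
  miscible <- sum(q_lean) < 2L || sum(q_rich) < 2L
  if (!miscible) {
    # guard against labelling noise as a phase: q must be genuinely
    # depleted in the candidate q-lean region
    depletion <- mean(mean_q[q_lean]) / max(mean(mean_q[q_rich]), 1e-300)
    miscible <- depletion > deplete_ratio
  }
  if (miscible) {
    core_idx <- which(condensed)
    half <- core_idx[seq_len(ceiling(length(core_idx) / 2))]
    q_rich <- condensed & (seq_len(nb) %in% half)
    q_lean <- condensed & !(seq_len(nb) %in% half)
  }
  if (sum(q_lean) < 1L || sum(q_rich) < 1L) {
    stop("no usable condensed region; the system may not be phase separated")
  }

  meas <- if (is.null(prof_p_measure)) prof_p else prof_p_measure
  stopifnot(length(meas$z) == nb)
  binw <- meas$Lz / nb
  block_id <- cut(seq_along(keep), breaks = n_blocks, labels = FALSE)
  kp_blocks <- vapply(seq_len(n_blocks), function(b) {
    cols <- keep[block_id == b]
    pb <- rowMeans(meas$rho_frames[, cols, drop = FALSE])
    num <- mean(pb[q_lean])
    den <- mean(pb[q_rich])
    if (den <= 0) {
      if (is.na(meas$area)) return(NA_real_)
      # half a molecule (or bead) over the region volume and block frames
      den <- 0.5 / (meas$area * binw * sum(q_rich) * length(cols))
    }
    num / den
  }, numeric(1))
  ok <- !is.na(kp_blocks)
  if (!any(ok)) stop("partition_coefficient: empty q-rich region in every block")
  kp <- mean(kp_blocks[ok])
  sem <- if (sum(ok) >= 2L) sd(kp_blocks[ok]) / sqrt(sum(ok)) else NA_real_
  structure(
    list(kp = kp, sem = sem, kp_blocks = kp_blocks, miscible = miscible,
         regions = list(q_rich = q_rich, q_lean = q_lean,
                        condensed = condensed),
         fit_q = fit_q, fit_total = fit_tot),
    class = "kp_result"
  )
}

#' @export
print.kp_result <- function(x, ...) {
  cat(sprintf("<kp_result> K_p = %.4g +/- %.3g (%d blocks)%s\n",
              x$kp, x$sem, length(x$kp_blocks),
              if (x$miscible) " [miscible: half-core fallback]" else ""))
  invisible(x)
}

#' Interfacial tension from the pressure-tensor anisotropy
#'
#' Mechanical (Kirkwood) route for a periodic slab with two interfaces:
#' \deqn{\gamma = \frac{L_z}{2}\left[\langle P_{zz}\rangle -
#'   \frac{\langle P_{xx}\rangle + \langle P_{yy}\rangle}{2}\right],}
#' where the factor 1/2 accounts for the two interfaces. The error is the
#' standard error over contiguous blocks of the FrameStats series. Reported
#' both in kcal/mol/A^2 and in reduced units of epsilon/sigma^2, with sigma
#' the composition-weighted mean bead diameter.
#'
#' @param stats FrameStats data.frame (columns `p_xx`, `p_yy`, `p_zz`, `lz`)
#'   or a `cg_trajectory`.
#' @param Lz box z edge; defaults to the `lz` column.
#' @param n_blocks number of blocks (>= 2) for the error estimate.
#' @param burn_in fraction of initial rows discarded.
#' @param ff force field for the reduced-unit conversion.
#' @param sigma_ref reference bead diameter; defaults to the mean K/E sigma.
#' @return list of class `gamma_result`: `gamma`, `sem` (kcal/mol/A^2),
#'   `gamma_reduced`, `sem_reduced` (epsilon/sigma^2), `blocks`.
#' @export
interfacial_tension <- function(stats, Lz = NULL, n_blocks = 5L,
                                burn_in = 0.2, ff = default_forcefield(),
                                sigma_ref = NULL) {
  if (inherits(stats, "cg_trajectory")) stats <- stats$stats
  n <- nrow(stats)
  keep <- seq.int(floor(burn_in * n) + 1L, n)
  if (length(keep) < n_blocks) stop("fewer reporting intervals than blocks")
  if (is.null(Lz)) Lz <- stats$lz[keep[length(keep)]]
  anis <- stats$p_zz[keep] - (stats$p_xx[keep] + stats$p_yy[keep]) / 2
  block_id <- cut(seq_along(keep), breaks = n_blocks, labels = FALSE)
  g_blocks <- vapply(seq_len(n_blocks), function(b) {
    Lz / 2 * mean(anis[block_id == b])
  }, numeric(1))
  gamma <- mean(g_blocks)
  sem <- sd(g_blocks) / sqrt(n_blocks)
  if (is.null(sigma_ref)) {
    ke <- ff$params$type %in% c("K", "E")
    sigma_ref <- mean(ff$params$sigma[ke])
  }
  conv <- sigma_ref^2 / ff$epsilon
  structure(
    list(gamma = gamma, sem = sem,
         gamma_reduced = gamma * conv, sem_reduced = sem * conv,
         sigma_ref = sigma_ref, epsilon = ff$epsilon, blocks = g_blocks),
    class = "gamma_result"
  )
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(
    "<gamma_result> gamma = %.4g +/- %.3g kcal/mol/A^2 = %.4g +/- %.3g eps/sigma^2\n",
    x$gamma, x$sem, x$gamma_reduced, x$sem_reduced
  ))
  invisible(x)
}

#' Heterotypic-to-homotypic bond ratio of the oligomerized species
#'
#' A non-covalent "bond" is an inter-molecular polyampholyte bead pair
#' within `cutoff_factor * sigma_ij` (first coordination shell of the
#' short-range potential). The bond ratio is
#' \eqn{\phi_B =} (contacts between the oligomerized species' beads and the
#' other species) / (contacts of the oligomerized species with itself,
#' intra-molecular pairs excluded), frame-averaged; low values mean
#' homotypic bonding dominates. The error is the SEM over frame blocks.
#'
#' @param traj a `cg_trajectory` with stored frames.
#' @param oligomer_species species label of the oligomerized component;
#'   defaults to the species with the highest valence.
#' @param cutoff_factor contact cutoff in units of sigma_ij (default 1.5;
#'   values in 1.2-2.0 give the same orderings, see the package vignette).
#' @param ff force field supplying the pair diameters.
#' @param n_blocks blocks for the SEM.
#' @param burn_in fraction of initial frames discarded.
#' @return list of class `phib_result`: `phi_b`, `sem`, `per_frame`,
#'   `undefined` (TRUE when a frame had zero homotypic contacts).
#' @export
contact_bond_ratio <- function(traj, oligomer_species = NULL,
                               cutoff_factor = 1.5,
                               ff = default_forcefield(),
                               n_blocks = 5L, burn_in = 0.2) {
  top <- traj$topology
  if (length(unique(top$species)) < 2L) {
    stop("bond ratio needs two species")
  }
  if (is.null(oligomer_species)) {
    oligomer_species <- top$species[which.max(top$valence)]
  }
  sp_bead <- bead_species(top)
  sp_int <- as.integer(sp_bead == oligomer_species)
  n_fr <- length(traj$frames)
  keep <- seq.int(floor(burn_in * n_fr) + 1L, n_fr)
  if (length(keep) < 1L) stop("no frames after burn-in")
  types <- ff_type_index(ff, top$bead_type)
  per_frame <- vapply(keep, function(k) {
    cc <- cpp_count_contacts(traj$frames[[k]], traj$box, types,
                             top$molecule_id, sp_int, ff_to_cpp(ff),
                             cutoff_factor, 1L)
    if (cc$homotypic == 0) return(NA_real_)
    cc$heterotypic / cc$homotypic
  }, numeric(1))
  undefined <- anyNA(per_frame)
  ok <- !is.na(per_frame)
  if (!any(ok)) {
    warning("bond ratio undefined: no homotypic contacts in any frame")
    return(structure(list(phi_b = NA_real_, sem = NA_real_,
                          per_frame = per_frame, undefined = TRUE),
                     class = "phib_result"))
  }
  nb <- min(n_blocks, sum(ok))
  if (nb < 2L) {
    return(structure(
      list(phi_b = mean(per_frame[ok]), sem = NA_real_,
           per_frame = per_frame, undefined = undefined),
      class = "phib_result"
    ))
  }
  block_id <- cut(seq_len(sum(ok)), breaks = nb, labels = FALSE)
  pb <- vapply(seq_len(nb), function(b) mean(per_frame[ok][block_id == b]),
               numeric(1))
  structure(
    list(phi_b = mean(pb), sem = sd(pb) / sqrt(nb), per_frame = per_frame,
         undefined = undefined),
    class = "phib_result"
  )
}

#' @export
print.phib_result <- function(x, ...) {
  cat(sprintf("<phib_result> phi_B = %.4g +/- %.3g%s\n", x$phi_b, x$sem,
              if (x$undefined) " [some frames had no homotypic contacts]" else ""))
  invisible(x)
}

#' Tidy summary of coexistence observables
#'
#' @param traj a `cg_trajectory` of a binary slab run.
#' @param species_p,species_q the two species labels (default: first two in
#'   the topology).
#' @param n_bins profile bins.
#' @param n_blocks SEM blocks.
#' @param ff force field.
#' @return data.frame with one row per observable (rho_den/rho_dil per
#'   species, K_p, gamma, phi_B) and columns `observable`, `species`,
#'   `value`, `sem`, `units`.
#' @export
coexistence_summary <- function(traj, species_p = NULL, species_q = NULL,
                                n_bins = 100L, n_blocks = 5L,
                                ff = default_forcefield()) {
  labs <- unique(traj$topology$species)
  if (is.null(species_p)) species_p <- labs[1L]
  if (is.null(species_q)) species_q <- labs[min(2L, length(labs))]
  prof_p <- density_profile(traj, species_p, n_bins)
  prof_q <- density_profile(traj, species_q, n_bins)
  fp <- fit_tanh(prof_p); fq <- fit_tanh(prof_q)
  kp <- partition_coefficient(prof_p, prof_q, n_blocks = n_blocks)
  ga <- interfacial_tension(traj, n_blocks = n_blocks, ff = ff)
  pb <- if (length(labs) >= 2L) {
    tryCatch(contact_bond_ratio(traj, ff = ff, n_blocks = n_blocks),
             error = function(e) NULL)
  } else NULL
  rows <- rbind(
    data.frame(observable = "rho_den", species = c(species_p, species_q),
               value = c(fp$rho_den, fq$rho_den), sem = NA_real_,
               units = "beads/A^3"),
    data.frame(observable = "rho_dil", species = c(species_p, species_q),
               value = c(fp$rho_dil, fq$rho_dil), sem = NA_real_,
               units = "beads/A^3"),
    data.frame(observable = "K_p", species = species_p, value = kp$kp,
               sem = kp$sem, units = ""),
    data.frame(observable = "gamma", species = "interface", value = ga$gamma,
               sem = ga$sem, units = "kcal/mol/A^2"),
    data.frame(observable = "gamma_reduced", species = "interface",
               value = ga$gamma_reduced, sem = ga$sem_reduced,
               units = "eps/sigma^2")
  )
  if (!is.null(pb)) {
    rows <- rbind(rows, data.frame(
      observable = "phi_B", species = "oligomerized", value = pb$phi_b,
      sem = pb$sem, units = ""))
  }
  rownames(rows) <- NULL
  rows
}
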