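#' Bead-spring topologies for linear and star polyampholytes
#'
#' A `system_topology` describes beads and bonds for one or more molecules:
#' per-bead residue identity (`"K"`, `"E"`, or `"CORE"` for the central
#' scaffold bead of a star), per-bead charge (CORE beads are neutral),
#' a two-column bond matrix of bead indices, per-bead molecule id, a
#' per-molecule species label and per-molecule valence `f` (1 = linear).
#'
#' @name system_topology
NULL

new_topology <- function(bead_type, charge, bonds, molecule_id,
                         species, valence) {
  structure(
    list(
      bead_type = bead_type,
      charge = charge,
      bonds = bonds,
      molecule_id = molecule_id,
      species = species,    # per molecule
      valence = valence     # per molecule
    ),
    class = "system_topology"
  )
}

#' @export
print.system_topology <- function(x, ...) {
  cat(sprintf(
    "<system_topology> %d beads, %d bonds, %d molecule(s), species [%s]\n",
    length(x$bead_type), nrow(x$bonds), length(x$species),
    paste(unique(x$species), collapse = ", ")
  ))
  invisible(x)
}

#' Build a linear polyampholyte chain
#'
#' N beads joined by N-1 consecutive harmonic bonds; equivalent to a star
#' with a single arm, minus the core bead.
#'
#' @param seq a [charge_sequence()] of length >= 2.
#' @param species species label for the molecule (default the sequence name).
#' @return A `system_topology` with one molecule of valence 1.
#' @export
build_linear <- function(seq, species = NULL) {
  seq <- as_charge_sequence(seq)
  n <- length(seq$residues)
  if (n < 2L) stop("build_linear: need at least 2 residues")
  if (is.null(species)) species <- seq$name
  bonds <- cbind(seq_len(n - 1L), 2:n)
  new_topology(
    bead_type = seq$residues,
    charge = as.numeric(seq$charges),
    bonds = bonds,
    molecule_id = rep(1L, n),
    species = species,
    valence = 1L
  )
}

#' Build a star (oligomerized) polyampholyte
#'
#' Models oligomerization by a multimeric scaffold: `f` copies of the
#' sequence are attached by their first residue to a single neutral CORE
#' bead, giving `f * L + 1` beads and `f * L` bonds (L-1 intra-arm bonds per
#' arm plus one arm-to-core bond per arm). The CORE bead interacts purely
#' repulsively and carries no charge (see [default_forcefield()]).
#'
#' @param seq a [charge_sequence()], the arm sequence.
#' @param f number of arms (valence), a positive integer.
#' @param species species label (default `<name>x<f>`).
#' @return A `system_topology` with one molecule of valence `f`.
#' @export
build_star <- function(seq, f, species = NULL) {
  seq <- as_charge_sequence(seq)
  f <- as.integer(f)
  if (is.na(f) || f < 1L) stop("build_star: valence f must be >= 1")
  L <- length(seq$residues)
  if (L < 2L) stop("build_star: arm length must be >= 2")
  if (is.null(species)) species <- sprintf("%sx%d", seq$name, f)
  n <- f * L + 1L
  bead_type <- c("CORE", rep(seq$residues, f))
  charge <- c(0, rep(as.numeric(seq$charges), f))
  bonds <- matrix(0L, nrow = f * L, ncol = 2L)
  k <- 0L
  for (arm in seq_len(f)) {
    base <- 1L + (arm - 1L) * L   # index of first arm bead minus 1
    k <- k + 1L
    bonds[k, ] <- c(1L, base + 1L)             # core to first residue
    for (i in seq_len(L - 1L)) {
      k <- k + 1L
      bonds[k, ] <- c(base + i, base + i + 1L)
    }
  }
  new_topology(
    bead_type = bead_type,
    charge = charge,
    bonds = bonds,
    molecule_id = rep(1L, n),
    species = species,
    valence = f
  )
}

# number of polyampholyte (non-CORE) beads in a single-molecule topology
polyampholyte_beads <- function(top) sum(top$bead_type != "CORE")

# replicate a single-molecule topology n times and merge with another set
merge_topologies <- function(tops) {
  bead_type <- character(0); charge <- numeric(0)
  bonds <- matrix(0L, 0L, 2L); molecule_id <- integer(0)
  species <- character(0); valence <- integer(0)
  offset <- 0L; mol_offset <- 0L
  for (top in tops) {
    nb <- length(top$bead_type)
    bead_type <- c(bead_type, top$bead_type)
    charge <- c(charge, top$charge)
    bonds <- rbind(bonds, top$bonds + offset)
    molecule_id <- c(molecule_id, top$molecule_id + mol_offset)
    species <- c(species, top$species)
    valence <- c(valence, top$valence)
    offset <- offset + nb
    mol_offset <- mol_offset + length(top$species)
  }
  new_topology(bead_type, charge, bonds, molecule_id, species, valence)
}

#' Choose copy numbers balancing the mass of two components
#'
#' Enumerates copy-number pairs near the requested total bead count and
#' returns the pair minimizing the polyampholyte-bead imbalance
#' |mass_p - mass_q| (CORE beads are scaffold, not component material, and
#' are excluded from the balance). The residual imbalance is returned so it
#' can be logged.
#'
#' @param beads_p,beads_q polyampholyte beads per molecule of each species.
#' @param total_beads target total polyampholyte bead count.
#' @return list with `n_p`, `n_q` and `imbalance` (beads).
#' @export
balance_copy_numbers <- function(beads_p, beads_q, total_beads) {
  beads_p <- as.integer(beads_p); beads_q <- as.integer(beads_q)
  n_p_max <- max(1L, as.integer(ceiling(total_beads / beads_p)))
  best <- NULL
  for (n_p in seq_len(n_p_max)) {
    n_q <- max(1L, as.integer(round((total_beads - n_p * beads_p) / beads_q)))
    for (nq in unique(pmax(1L, n_q + c(-1L, 0L, 1L)))) {
      imb <- abs(n_p * beads_p - nq * beads_q)
      tot <- n_p * beads_p + nq * beads_q
      score <- imb + abs(tot - total_beads)
      if (is.null(best) || score < best$score) {
        best <- list(n_p = n_p, n_q = nq, imbalance = imb, score = score)
      }
    }
  }
  best$score <- NULL
  best
}

#' Assemble a random binary mixture in a cubic box
#'
#' Places `n_p` copies of the p topology and `n_q` copies of the q topology
#' (chosen with [balance_copy_numbers()] unless given) at random positions
#' and orientations in a periodic cubic box, rejection-sampling placements so
#' that no inter-molecular bead pair is closer than `exclusion` (default
#' 0.9 times the smallest bead diameter, preventing force blow-up at step 0).
#' Molecule-internal coordinates are a self-avoiding-ish random walk at the
#' bond rest length. Reproducible for a fixed seed.
#'
#' @param top_p,top_q single-molecule `system_topology` objects.
#' @param total_beads target total polyampholyte bead count for the mixture.
#' @param box cubic box edge length (Angstrom).
#' @param seed integer seed.
#' @param exclusion minimal allowed inter-molecular bead distance (Angstrom).
#' @param n_p,n_q explicit copy numbers (optional; both or neither).
#' @param bond_length placement bond length (Angstrom).
#' @param max_tries placement attempts per molecule before erroring.
#' @param arrangement `"random"` places both species uniformly (the mixed
#'   start of the full-scale protocol); `"sandwich"` pre-demixes them along
#'   z — q molecules in the central half, p molecules in the outer quarters
#'   — which after slab expansion gives the vacuum | p | q | p | vacuum
#'   geometry of a demixed coexistence run. Scaled-down trend runs start
#'   from the sandwich so that the (slow, diffusion-limited) demixing is not
#'   itself the quantity under test; see the package vignette.
#' @return list with `topology` (merged `system_topology`), `positions`
#'   (N x 3 matrix, wrapped into [0, box)), `box` (length-3 edge vector) and
#'   `imbalance` (residual bead-mass imbalance).
#' @export
assemble_binary_mixture <- function(top_p, top_q, total_beads = 2000L,
                                    box = 500, seed = 1L, exclusion = NULL,
                                    n_p = NULL, n_q = NULL,
                                    bond_length = 3.8, max_tries = 500L,
                                    arrangement = c("random", "sandwich")) {
  arrangement <- match.arg(arrangement)
  if (is.null(n_p) != is.null(n_q)) stop("give both n_p and n_q or neither")
  if (is.null(n_p)) {
    bal <- balance_copy_numbers(polyampholyte_beads(top_p),
                                polyampholyte_beads(top_q), total_beads)
    n_p <- bal$n_p; n_q <- bal$n_q
  }
  if (is.null(exclusion)) exclusion <- 0.9 * 5.92  # 0.9 x smallest sigma (E)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  tops <- c(rep(list(top_p), n_p), rep(list(top_q), n_q))
  is_p <- rep(c(TRUE, FALSE), c(n_p, n_q))
  merged <- merge_topologies(tops)
  box3 <- rep(box, 3L)
  n_total <- length(merged$bead_type)
  positions <- matrix(0, n_total, 3L)
  placed <- matrix(numeric(0), 0L, 3L)
  offset <- 0L
  excl2 <- exclusion^2
  for (m in seq_along(tops)) {
    nb <- length(tops[[m]]$bead_type)
    local_xyz <- molecule_random_walk(tops[[m]], bond_length)
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      rot <- random_rotation()
      origin <- runif(3L) * box3
      if (arrangement == "sandwich") {
        # q in the central z half, p split across the outer quarters
        u <- runif(1L)
        origin[3L] <- if (is_p[m]) {
          box3[3L] * (if (u < 0.5) 0.5 * u else 0.75 + 0.5 * (u - 0.5))
        } else {
          box3[3L] * (0.25 + 0.5 * u)
        }
      }
      xyz <- sweep(local_xyz %*% rot, 2L, origin, "+")
      if (nrow(placed) > 0L &&
          min_image_min_dist2(xyz, placed, box3) < excl2) next
      positions[offset + seq_len(nb), ] <- xyz
      placed <- rbind(placed, xyz)
      ok <- TRUE
      break
    }
    if (!ok) {
      stop(sprintf(
        "assemble_binary_mixture: placement failed after %d tries at bead density %.3g / A^3; use a larger box",
        max_tries, n_total / prod(box3)
      ))
    }
    offset <- offset + nb
  }
  positions <- positions %% matrix(box3, n_total, 3L, byrow = TRUE)
  list(
    topology = merged,
    positions = positions,
    box = box3,
    n_p = n_p, n_q = n_q,
    imbalance = abs(n_p * polyampholyte_beads(top_p) -
                      n_q * polyampholyte_beads(top_q))
  )
}

# local coordinates for one molecule: a directionally persistent,
# self-avoiding random walk along the bond tree (arms radiate outward from
# the core for stars), so no intra-molecular non-bonded pair starts deep in
# the repulsive core of the pair potential; centred on the molecule centroid
molecule_random_walk <- function(top, bond_length, dmin = 4.6,
                                 n_retry = 60L) {
  n <- length(top$bead_type)
  xyz <- matrix(0, n, 3L)
  done <- rep(FALSE, n)
  dir_of <- matrix(0, n, 3L)      # incoming step direction per bead
  done[1L] <- TRUE
  is_core <- top$bead_type == "CORE"
  core_standoff <- 9.0            # first arm bead sits near the core surface
  unit <- function(v) v / sqrt(sum(v * v))
  # bonds are listed parent-before-child by construction
  for (k in seq_len(nrow(top$bonds))) {
    i <- top$bonds[k, 1L]; j <- top$bonds[k, 2L]
    if (done[j] && !done[i]) { tmp <- i; i <- j; j <- tmp }
    if (!(done[i] && !done[j])) next
    best <- NULL; best_d <- -Inf
    for (try in seq_len(n_retry)) {
      if (is_core[i]) {
        # arm attachment: radiate outward, start outside the core's
        # excluded volume (the bond is stretched, which relaxes quickly)
        d <- unit(rnorm(3L))
        cand <- xyz[i, ] + core_standoff * d
      } else {
        prev <- dir_of[i, ]
        d <- if (sum(prev^2) > 0) {
          # persistent direction: keeps consecutive bond angles open so
          # 1-3 distances stay >= bond_length * sqrt(2)
          unit(unit(prev) + 0.7 * rnorm(3L))
        } else {
          unit(rnorm(3L))
        }
        cand <- xyz[i, ] + bond_length * d
      }
      others <- which(done)
      others <- others[others != i]
      sep <- if (length(others) > 0L) {
        dd <- sweep(xyz[others, , drop = FALSE], 2L, cand)
        lim <- ifelse(is_core[others], core_standoff - 0.5, dmin)
        min(sqrt(rowSums(dd * dd)) - lim)
      } else Inf
      if (sep >= 0) { best <- list(p = cand, d = d); best_d <- sep; break }
      if (sep > best_d) { best <- list(p = cand, d = d); best_d <- sep }
    }
    xyz[j, ] <- best$p
    dir_of[j, ] <- best$d
    done[j] <- TRUE
  }
  sweep(xyz, 2L, colMeans(xyz))
}

random_rotation <- function() {
  # QR of a Gaussian matrix gives a Haar-random orthogonal matrix
  m <- matrix(rnorm(9L), 3L)
  qr_d <- qr(m)
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# minimum over all pairs of the periodic minimum-image squared distance
min_image_min_dist2 <- function(a, b, box3) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d <- sweep(b, 2L, a[i, ])
    d <- d - sweep(round(sweep(d, 2L, box3, "/")), 2L, box3, "*")
    best <- min(best, min(rowSums(d * d)))
  }
  best
}

#' Expand the box along z into a slab geometry
#'
#' Unwraps molecules across the periodic boundaries (so no molecule is split
#' by the new vacuum), recentres the material's centre of mass at
#' `Lz_target / 2`, and sets the z edge to `Lz_target`, leaving x/y edges and
#' relative positions untouched. The result is the standard direct
#' coexistence geometry: a dense region flanked by vacuum along z.
#'
#' @param config list with `positions`, `box`, `topology` (as returned by
#'   [assemble_binary_mixture()] or [compress_box()]).
#' @param Lz_target new z edge, must exceed the current one.
#' @return The modified configuration list.
#' @export
make_slab <- function(config, Lz_target) {
  box <- config$box
  if (Lz_target <= box[3L]) stop("make_slab: Lz_target must exceed current Lz")
  pos <- unwrap_molecules(config$positions, config$topology, box)
  # wrap molecule centroids into the old box so the dense block is contiguous
  mols <- split(seq_len(nrow(pos)), config$topology$molecule_id)
  for (idx in mols) {
    ctr <- colMeans(pos[idx, , drop = FALSE])
    shift <- floor(ctr / box) * box
    pos[idx, ] <- sweep(pos[idx, , drop = FALSE], 2L, shift)
  }
  com_z <- mean(pos[, 3L])
  pos[, 3L] <- pos[, 3L] - com_z + Lz_target / 2
  new_box <- c(box[1L], box[2L], Lz_target)
  pos <- pos %% matrix(new_box, nrow(pos), 3L, byrow = TRUE)
  config$positions <- pos
  config$box <- new_box
  config
}

# unwrap bonded molecules across periodic boundaries by walking the bond list
unwrap_molecules <- function(pos, top, box) {
  out <- pos
  done <- rep(FALSE, nrow(pos))
  done[setdiff(seq_len(nrow(pos)), unique(as.vector(top$bonds)))] <- TRUE
  # repeated sweeps over bonds handle arbitrary listing order
  remaining <- !done
  first <- !duplicated(top$molecule_id)
  done[first] <- TRUE
  repeat {
    progressed <- FALSE
    for (k in seq_len(nrow(top$bonds))) {
      i <- top$bonds[k, 1L]; j <- top$bonds[k, 2L]
      if (done[i] && !done[j]) {
        d <- out[j, ] - out[i, ]
        out[j, ] <- out[i, ] + d - round(d / box) * box
        done[j] <- TRUE; progressed <- TRUE
      } else if (done[j] && !done[i]) {
        d <- out[i, ] - out[j, ]
        out[i, ] <- out[j, ] + d - round(d / box) * box
        done[i] <- TRUE; progressed <- TRUE
      }
    }
    if (all(done) || !progressed) break
  }
  out
}

#' Export a configuration as XYZ text
#'
#' @param config configuration list (`positions`, `topology`, `box`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(config, path) {
  n <- nrow(config$positions)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(n), con)
  writeLines(sprintf("box %g %g %g", config$box[1], config$box[2],
                     config$box[3]), con)
  writeLines(sprintf("%s %.4f %.4f %.4f", config$topology$bead_type,
                     config$positions[, 1], config$positions[, 2],
                     config$positions[, 3]), con)
  invisible(path)
}
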