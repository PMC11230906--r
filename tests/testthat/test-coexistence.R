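test_that("density profiles conserve bead counts and recentre the slab", {
  set.seed(41)
  s <- random_neutral_sequence(10)
  top <- condmix:::merge_topologies(list(build_linear(s, "p"),
                                         build_linear(s, "p"),
                                         build_linear(s, "q")))
  box <- c(50, 50, 200)
  # synthetic frames: a compact blob around z = 60, plus frames shifted by
  # arbitrary offsets (recentring must make them equivalent)
  set.seed(7)
  base <- cbind(runif(30) * 50, runif(30) * 50, 60 + rnorm(30, sd = 6))
  shifts <- c(0, 35, 170, 90)
  frames <- lapply(shifts, function(dz) {
    f <- base
    f[, 3] <- (f[, 3] + dz) %% 200
    f
  })
  traj <- fake_trajectory(frames, box, top)
  prof <- density_profile(traj, "all", n_bins = 40)
  # conservation: integral over the box = bead count, per frame and average
  binw <- 200 / 40
  expect_equal(sum(prof$rho) * binw * 50 * 50, 30, tolerance = 1e-9)
  expect_equal(colSums(prof$rho_frames) * binw * 2500, rep(30, 4),
               tolerance = 1e-9)
  # recentring: every shifted frame gives the same binned profile
  for (k in 2:4) {
    expect_equal(prof$rho_frames[, k], prof$rho_frames[, 1],
                 tolerance = 1e-12)
  }
  # species selection
  prof_p <- density_profile(traj, "p", n_bins = 40)
  expect_equal(sum(prof_p$rho) * binw * 2500, 20, tolerance = 1e-9)
  expect_error(density_profile(traj, "nope", 40), "no beads")
  expect_error(density_profile(traj, "all", 5), ">= 10")
})

test_that("all beads in one plane occupy a single bin", {
  top <- gas_topology(50, type = "K")
  box <- c(40, 40, 160)
  pos <- cbind(runif(50) * 40, runif(50) * 40, rep(77, 50))
  traj <- fake_trajectory(list(pos), box, top)
  prof <- density_profile(traj, "all", n_bins = 40)
  expect_identical(sum(prof$rho > 0), 1L)
})

test_that("tanh fit recovers noiseless synthetic parameters to 1e-6", {
  p <- synth_density_profile(0.3, 0.01, 80, 8, Lz = 400, n_bins = 200)
  f <- fit_tanh(p)
  expect_true(f$converged)
  expect_equal(f$rho_den, 0.3, tolerance = 1e-6)
  expect_equal(f$rho_dil, 0.01, tolerance = 1e-4)  # relative to rho_den scale
  expect_equal(f$z0, 80, tolerance = 1e-6)
  expect_equal(f$w, 8, tolerance = 1e-6)
  expect_gte(f$rho_den, f$rho_dil)
})

test_that("tanh fit flags flat profiles instead of fitting them", {
  flat <- condmix:::new_density_profile(
    z = seq(1, 399, by = 2), rho = rep(0.2, 200), Lz = 400, n_frames = 1,
    species = "flat"
  )
  f <- fit_tanh(flat)
  expect_false(f$converged)
  expect_true(f$degenerate)
  expect_equal(f$rho_den, f$rho_dil, tolerance = 1e-12)
})

test_that("noisy tanh fits are unbiased within 2 SEM over 200 replicates", {
  truth <- list(rho_den = 0.3, rho_dil = 0.01, z0 = 80, w = 8)
  ests <- t(vapply(1:200, function(k) {
    p <- synth_density_profile(0.3, 0.01, 80, 8, Lz = 400, n_bins = 200,
                               noise_sd = 0.015, seed = 1000 + k)
    f <- fit_tanh(p)
    c(f$rho_den, f$rho_dil, f$z0, f$w)
  }, numeric(4)))
  for (j in 1:4) {
    bias <- mean(ests[, j]) - truth[[j]]
    sem <- sd(ests[, j]) / sqrt(200)
    expect_lt(abs(bias), 2 * sem + 1e-12)
  }
})

test_that("partition coefficient reproduces constructed two-slab profiles", {
  Lz <- 400; n_bins <- 200
  z <- (seq_len(n_bins) - 0.5) * Lz / n_bins
  model <- function(den, dil, z0, w) {
    (den + dil) / 2 - (den - dil) / 2 * tanh((abs(z - Lz / 2) - z0) / w)
  }
  # q occupies the centre (|z| < 50); p sits at 0.002 there and at 0.2 in
  # the condensed annulus 50 < |z| < 100 (piecewise: plateau means are exact)
  az <- abs(z - Lz / 2)
  rho_q <- model(0.2, 0.001, 50, 3)
  rho_p <- ifelse(az < 50, 0.002, ifelse(az < 100, 0.2, 0.001))
  mk <- function(rho, sp) condmix:::new_density_profile(
    z, rho, Lz, 10, sp, rho_frames = matrix(rho, n_bins, 10))
  kp <- partition_coefficient(mk(rho_p, "p"), mk(rho_q, "q"), n_blocks = 5)
  expect_false(kp$miscible)
  expect_equal(kp$kp, 100, tolerance = 0.02)
  # strongly vs weakly segregated: ordering preserved
  rho_p_weak <- ifelse(az < 50, 0.008, ifelse(az < 100, 0.2, 0.001))
  kp_weak <- partition_coefficient(mk(rho_p_weak, "p"), mk(rho_q, "q"))
  expect_gt(kp$kp, kp_weak$kp)
  expect_gt(kp_weak$kp, 1)
})

test_that("identical constructed profiles fall back to the miscible null", {
  Lz <- 400; n_bins <- 200
  z <- (seq_len(n_bins) - 0.5) * Lz / n_bins
  rho <- 0.15 - 0.149 / 2 * (1 + tanh((abs(z - 200) - 70) / 6))
  mk <- function(rho, sp, jitter) {
    m <- matrix(rho, n_bins, 10)
    set.seed(jitter)
    m <- m * matrix(1 + rnorm(length(m), sd = 0.02), n_bins, 10)
    condmix:::new_density_profile(z, rowMeans(m), Lz, 10, sp, rho_frames = m)
  }
  kp <- partition_coefficient(mk(rho, "p", 1), mk(rho, "q", 2))
  expect_true(kp$miscible)
  expect_equal(kp$kp, 1, tolerance = 0.05)
})

test_that("interfacial tension closed forms hold exactly", {
  # isotropic tensor: gamma = 0 exactly
  iso <- data.frame(p_xx = rep(0.37, 20), p_yy = 0.37, p_zz = 0.37, lz = 250)
  g <- interfacial_tension(iso, n_blocks = 4, burn_in = 0)
  expect_identical(g$gamma, 0)
  expect_identical(g$sem, 0)
  # constant anisotropy Delta: gamma = Lz * Delta / 2
  delta <- 3e-4
  an <- data.frame(p_xx = rep(0.1, 20), p_yy = 0.1, p_zz = 0.1 + delta,
                   lz = 250)
  g2 <- interfacial_tension(an, n_blocks = 4, burn_in = 0)
  expect_equal(g2$gamma, 250 * delta / 2, tolerance = 1e-12)
  # reduced units: gamma * sigma_ref^2 / epsilon
  expect_equal(g2$gamma_reduced, g2$gamma * (6.14^2) / 0.2, tolerance = 1e-12)
  expect_error(interfacial_tension(iso[1:3, ], n_blocks = 5, burn_in = 0),
               "fewer")
})

test_that("gamma is zero within error for a homogeneous bulk fluid", {
  # dilute repulsive gas in a cubic box: no interface, so the block-averaged
  # anisotropy must vanish within 2 SEM
  ff <- default_forcefield()
  top <- gas_topology(150, type = "K")
  set.seed(31)
  cfg <- list(positions = matrix(runif(450) * 200, 150, 3),
              box = c(200, 200, 200), topology = top)
  r <- run_md(cfg, ff, n_steps = 4000, seed = 7, report_every = 5)
  g <- interfacial_tension(r$stats, Lz = 200, n_blocks = 5)
  expect_lt(abs(g$gamma), 2 * g$sem)
})

test_that("contact counts match the brute-force oracle", {
  set.seed(51)
  ff <- default_forcefield()
  s <- random_neutral_sequence(10)
  mix <- assemble_binary_mixture(build_star(s, 3, "p"), build_linear(s, "q"),
                                 total_beads = 300, box = 70, seed = 9)
  top <- mix$topology
  sp <- condmix:::bead_species(top)
  types <- condmix:::ff_type_index(ff, top$bead_type)
  cc <- condmix:::cpp_count_contacts(
    mix$positions, c(70, 70, 70), types, top$molecule_id,
    as.integer(sp == "p"), condmix:::ff_to_cpp(ff), 1.5, 1L
  )
  # oracle: brute-force with CORE beads removed (they are not contacts)
  poly <- top$bead_type != "CORE"
  bf <- contacts_bruteforce(
    mix$positions[poly, ], c(70, 70, 70),
    ff$params$sigma[types + 1][poly], top$molecule_id[poly],
    (sp == "p")[poly], 1.5
  )
  expect_identical(as.integer(cc$heterotypic), bf$heterotypic)
  expect_identical(as.integer(cc$homotypic), bf$homotypic)
})

test_that("bond ratio: relabelled halves give phi_B near 1, demixed blobs 0", {
  set.seed(61)
  s <- random_neutral_sequence(8)
  # one species, labels split across molecules: contacts are exchangeable.
  # 30 molecules in a small box, positions from a short relaxation
  tops <- c(rep(list(build_linear(s, "p")), 15),
            rep(list(build_linear(s, "q")), 15))
  top <- condmix:::merge_topologies(tops)
  ff <- default_forcefield()
  mix <- assemble_binary_mixture(build_linear(s, "p"), build_linear(s, "q"),
                                 total_beads = 240, box = 55, seed = 3)
  r <- run_md(list(positions = mix$positions, box = mix$box,
                   topology = mix$topology),
              ff, n_steps = 500, seed = 5, report_every = 100,
              store_frames = TRUE)
  pb <- contact_bond_ratio(r, oligomer_species = "p", ff = ff,
                           n_blocks = 2, burn_in = 0.2)
  # expected hetero/homo for random labels: n_q / ((n_p - 1)/2) ~ 2.14;
  # normalized by pairing combinatorics phi_B ~ 15/7 for equal halves
  expect_gt(pb$phi_b, 1)
  expect_lt(pb$phi_b, 4)
  # fully demixed rigid clusters with no cross contacts: phi_B = 0
  blob <- function(cx) {
    t(vapply(1:40, function(i) cx + runif(3) * 12, numeric(3)))
  }
  top2 <- condmix:::merge_topologies(c(
    rep(list(build_linear(s, "p")), 5), rep(list(build_linear(s, "q")), 5)))
  pos2 <- rbind(blob(c(20, 20, 20)), blob(c(120, 120, 120)))
  traj2 <- fake_trajectory(list(pos2), c(200, 200, 200), top2)
  pb2 <- contact_bond_ratio(traj2, oligomer_species = "p", ff = ff,
                            n_blocks = 1, burn_in = 0)
  expect_identical(pb2$phi_b, 0)
})
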