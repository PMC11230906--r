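test_that("pair potential limits and continuity", {
  ff <- default_forcefield()
  # lambda_ij = 1: pure (shifted) Lennard-Jones at all r
  tab <- data.frame(type = c("A", "B"), sigma = 6, lambda = 1, mass = 100,
                    charge = 0, is_core = 0L)
  ff1 <- default_forcefield(params = tab)
  r <- seq(4.5, 19.9, by = 0.1)
  lj <- 4 * 0.2 * ((6 / r)^12 - (6 / r)^6)
  shift <- 4 * 0.2 * ((6 / 20)^12 - (6 / 20)^6)
  expect_equal(pair_energy(ff1, "A", "B", r), lj - shift, tolerance = 1e-12)
  # continuity at the 2^(1/6) sigma switch point for arbitrary lambda
  sij <- (6.36 + 5.92) / 2
  rmin <- 2^(1 / 6) * sij
  eps_r <- 1e-7
  u_lo <- pair_energy(ff, "K", "E", rmin - eps_r)
  u_hi <- pair_energy(ff, "K", "E", rmin + eps_r)
  expect_lt(abs(u_lo - u_hi), 1e-5)
  # value at the minimum: -lambda_ij * eps + DH + shifts
  lam_ke <- (0.514 + 0.459) / 2
  u_min_ah <- -lam_ke * ff$epsilon -
    lam_ke * 4 * ff$epsilon * ((sij / 20)^12 - (sij / 20)^6)
  u_dh <- -332.0637 / 80 * (exp(-rmin / 10) / rmin - exp(-35 / 10) / 35)
  expect_equal(pair_energy(ff, "K", "E", rmin), u_min_ah + u_dh,
               tolerance = 1e-10)
  # neutral pair has no electrostatic term; core pairs are purely repulsive
  # CORE pairs: repulsive below 2^(1/6) sigma_ij, exactly zero beyond
  expect_gt(pair_energy(ff, "CORE", "CORE", 14), 0)     # inside 14.28
  expect_equal(pair_energy(ff, "CORE", "CORE", 14.3), 0, tolerance = 1e-12)
  expect_gt(pair_energy(ff, "CORE", "K", 8), 0)
  expect_equal(pair_energy(ff, "CORE", "K", 12), 0, tolerance = 1e-12)
  expect_error(pair_energy(ff, "K", "E", 0), "positive")
})

test_that("forces are the exact negative gradient of the energy", {
  set.seed(13)
  ff <- default_forcefield()
  s <- random_neutral_sequence(26)
  mix <- assemble_binary_mixture(build_linear(s, "p"), build_linear(s, "q"),
                                 total_beads = 52, box = 70, seed = 4)
  cfg <- list(positions = mix$positions, box = mix$box,
              topology = mix$topology)
  fv <- compute_forces_virial(cfg, ff)
  en <- function(p) {
    c2 <- cfg
    c2$positions <- p
    compute_forces_virial(c2, ff, check_overlap = FALSE)$energy
  }
  h <- 1e-5
  for (k in 1:20) {
    i <- sample(52, 1); a <- sample(3, 1)
    pp <- cfg$positions
    pp[i, a] <- pp[i, a] + h
    e_plus <- en(pp)
    pp[i, a] <- pp[i, a] - 2 * h
    e_minus <- en(pp)
    f_num <- -(e_plus - e_minus) / (2 * h)
    expect_equal(f_num, fv$forces[i, a],
                 tolerance = 1e-5 * max(1, abs(fv$forces[i, a])))
  }
  # Newton's third law: forces sum to zero
  expect_lt(max(abs(colSums(fv$forces))), 1e-9)
})

test_that("harmonic dimer at rest length feels zero force", {
  ff <- default_forcefield()
  top <- build_linear(charge_sequence("KE", "dimer"))
  cfg <- list(positions = rbind(c(10, 10, 10), c(10 + 3.8, 10, 10)),
              box = c(60, 60, 60), topology = top)
  fv <- compute_forces_virial(cfg, ff, check_overlap = FALSE)
  expect_lt(max(abs(fv$forces)), 1e-10)
})

test_that("overlapping beads are rejected with the offending pair", {
  ff <- default_forcefield()
  s <- charge_sequence("KE", "a")
  top <- condmix:::merge_topologies(list(build_linear(s, "p"),
                                         build_linear(s, "q")))
  pos <- rbind(c(10, 10, 10), c(13.8, 10, 10),
               c(10.2, 10, 10), c(14, 13.8, 10))
  cfg <- list(positions = pos, box = c(50, 50, 50), topology = top)
  expect_error(compute_forces_virial(cfg, ff), "overlapping beads 1 and 3")
})

test_that("zero-friction, no-noise limit conserves energy and momentum", {
  ff <- default_forcefield()
  top <- build_linear(charge_sequence("KE", "dimer"))
  cfg <- list(positions = rbind(c(10, 10, 10), c(15, 10, 10)),
              box = c(60, 60, 60), topology = top,
              velocities = matrix(0, 2, 3))
  r <- run_md(cfg, ff, n_steps = 10000, dt_fs = 2, friction_ps = 0,
              thermostat = FALSE, report_every = 100)
  e_tot <- r$stats$e_pot + r$stats$e_kin
  expect_lt(max(abs(e_tot - e_tot[1])) / abs(e_tot[1]), 1e-4)
  # total momentum stays zero to machine precision
  mass <- c(128.174, 129.115)
  p_tot <- colSums(mass * r$velocities)
  expect_lt(max(abs(p_tot)), 1e-9)
})

test_that("trajectories are reproducible per seed and diverge across seeds", {
  set.seed(17)
  ff <- default_forcefield()
  s <- random_neutral_sequence(10)
  mix <- assemble_binary_mixture(build_linear(s, "p"), build_linear(s, "q"),
                                 total_beads = 100, box = 90, seed = 3)
  cfg <- list(positions = mix$positions, box = mix$box,
              topology = mix$topology)
  r1 <- run_md(cfg, ff, n_steps = 300, seed = 5, report_every = 100)
  r2 <- run_md(cfg, ff, n_steps = 300, seed = 5, report_every = 100)
  r3 <- run_md(cfg, ff, n_steps = 300, seed = 6, report_every = 100)
  expect_identical(r1$positions, r2$positions)
  expect_identical(r1$velocities, r2$velocities)
  expect_false(identical(r1$positions, r3$positions))
})

test_that("thermostat holds the kinetic temperature at the setpoint", {
  # dilute gas of unbonded repulsive beads: kinetic T within 2% of 250 K
  ff <- default_forcefield()
  top <- gas_topology(150, type = "K", species = "gas")
  set.seed(8)
  pos <- matrix(runif(450) * 190, 150, 3)
  cfg <- list(positions = pos, box = c(190, 190, 190), topology = top)
  r <- run_md(cfg, ff, n_steps = 4000, seed = 12, report_every = 10)
  t_kin <- r$stats$temperature[-(1:100)]
  expect_lt(abs(mean(t_kin) - 250) / 250, 0.02)
})

test_that("ideal-gas pressure matches N kB T / V and is isotropic", {
  # neutral, purely repulsive beads, dilute enough that the second-virial
  # correction (~1%) is inside the tolerance
  ff <- default_forcefield()
  top <- gas_topology(100, type = "CORE", species = "gas")
  set.seed(9)
  cfg <- list(positions = matrix(runif(300) * 400, 100, 3),
              box = c(400, 400, 400), topology = top)
  r <- run_md(cfg, ff, n_steps = 4000, seed = 2, report_every = 5)
  kb <- 0.0019872041
  p_ideal <- 100 * kb * 250 / 400^3
  keep <- -(1:100)
  p_mean <- c(mean(r$stats$p_xx[keep]), mean(r$stats$p_yy[keep]),
              mean(r$stats$p_zz[keep]))
  expect_true(all(abs(p_mean - p_ideal) / p_ideal < 0.05))
})

test_that("box compression conserves beads and hits the target volume", {
  set.seed(23)
  s <- random_neutral_sequence(10)
  mix <- assemble_binary_mixture(build_linear(s, "p"), build_linear(s, "q"),
                                 total_beads = 120, box = 100, seed = 2)
  cfg <- list(positions = mix$positions, box = mix$box,
              topology = mix$topology)
  out <- compress_box(cfg, 50, n_steps = 800, seed = 3)
  expect_equal(out$box, c(50, 50, 50))
  expect_identical(nrow(out$positions), nrow(cfg$positions))
  expect_true(all(out$positions >= 0 & out$positions <= 50))
  expect_equal(prod(cfg$box) / prod(out$box), 8, tolerance = 1e-9)
  expect_error(compress_box(cfg, 50, n_steps = 0), "positive")
  expect_error(compress_box(cfg, 120, n_steps = 100), "exceed")
})

test_that("zero production steps yield only the initial frame", {
  ff <- default_forcefield()
  top <- gas_topology(20, type = "K")
  set.seed(2)
  cfg <- list(positions = matrix(runif(60) * 100, 20, 3),
              box = c(100, 100, 300), topology = top)
  traj <- run_coexistence(cfg, ff,
                          protocol = list(equilibration_steps = 50,
                                          production_steps = 0,
                                          report_every = 10),
                          seed = 1)
  expect_length(traj$frames, 1L)
  expect_identical(nrow(traj$frames[[1]]), 20L)
})

test_that("trajectories round-trip through the RDS container", {
  ff <- default_forcefield()
  top <- gas_topology(10, type = "K")
  set.seed(3)
  cfg <- list(positions = matrix(runif(30) * 80, 10, 3),
              box = c(80, 80, 200), topology = top)
  traj <- run_coexistence(cfg, ff,
                          protocol = list(equilibration_steps = 20,
                                          production_steps = 100,
                                          report_every = 20),
                          seed = 4)
  f <- tempfile(fileext = ".rds")
  save_trajectory(traj, f)
  back <- load_trajectory(f)
  expect_identical(back$frames, traj$frames)
  expect_identical(back$stats, traj$stats)
})
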