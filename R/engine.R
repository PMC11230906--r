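# internal unit system: Angstrom / Dalton / kcal per mol
# derived time unit sqrt(Da A^2 mol / kcal) = 48.8882 fs
TIME_UNIT_FS <- 48.8882
KB_KCAL <- 0.0019872041

#' Forces, energy and pressure tensor of a configuration
#'
#' Evaluates the full potential (Ashbaugh-Hatch + Debye-Hueckel + harmonic
#' bonds) for a configuration, returning per-bead forces (the exact negative
#' gradient of the implemented potential), the potential energy, and the
#' diagonal of the pressure tensor P_aa = (sum_i m_i v_ia^2 + virial_aa) / V.
#' Without velocities the kinetic contribution is zero (configurational
#' pressure only).
#'
#' @param config list with `positions` (N x 3), `box` (length 3) and
#'   `topology` (a `system_topology`).
#' @param ff a [default_forcefield()].
#' @param velocities optional N x 3 matrix (Angstrom per internal time unit).
#' @param check_overlap error out when two beads sit closer than 20% of
#'   their pair diameter (force blow-up guard).
#' @return list with `forces` (kcal/mol/A), `energy`, `energy_pair`,
#'   `energy_bond` (kcal/mol) and `pressure` (length-3, kcal/mol/A^3).
#' @export
compute_forces_virial <- function(config, ff = default_forcefield(),
                                  velocities = NULL, check_overlap = TRUE) {
  top <- config$topology
  res <- cpp_compute_forces(
    config$positions, config$box, ff_type_index(ff, top$bead_type),
    top$charge, top$bonds, ff_to_cpp(ff), check_overlap
  )
  p_kin <- c(0, 0, 0)
  if (!is.null(velocities)) {
    mass <- ff$params$mass[ff_type_index(ff, top$bead_type) + 1L]
    p_kin <- colSums(mass * velocities^2) / prod(config$box)
  }
  res$pressure <- res$virial_pressure + p_kin
  res
}

#' Run Langevin dynamics on a configuration
#'
#' BAOAB-splitting Langevin integrator at constant N, V, T. The random
#' stream is counter-based (hashed from seed, step index and bead index), so
#' a run is exactly reproducible and a restart from step `step_offset`
#' continues the same stream. Setting `friction_ps = 0` with
#' `thermostat = FALSE` gives plain velocity-Verlet (NVE) integration.
#'
#' @param config list with `positions`, `box`, `topology`; optionally
#'   `velocities` from a previous run.
#' @param ff a [default_forcefield()].
#' @param n_steps number of time steps.
#' @param dt_fs time step in femtoseconds (default 10).
#' @param temperature thermostat setpoint (Kelvin, default 250).
#' @param friction_ps Langevin friction coefficient (1/ps, default 1).
#' @param seed integer master seed for the noise stream.
#' @param report_every steps between recorded FrameStats rows (0 = only the
#'   initial state).
#' @param store_frames keep position snapshots at every report interval.
#' @param box_end optional length-3 target box edges; edges are rescaled
#'   linearly over the run (used by [compress_box()]).
#' @param step_offset step counter offset for restarts.
#' @param thermostat logical; FALSE disables the stochastic O-step.
#' @param fcap per-bead force-magnitude cap (kcal/mol/A) applied while
#'   relaxing freshly assembled or compressing configurations; 0 (default)
#'   disables the cap, which is the production setting.
#' @return list of class `cg_trajectory`: final `positions`, `velocities`,
#'   `box`, `topology`, `frames` (list of N x 3 matrices), `stats`
#'   (data.frame: step, e_pot, e_kin, temperature, p_xx, p_yy, p_zz, lz),
#'   `aborted` flag and the run `params`. A run whose instantaneous kinetic
#'   temperature exceeds 10x the setpoint aborts, preserving partial output.
#' @export
run_md <- function(config, ff = default_forcefield(), n_steps = 1000L,
                   dt_fs = 10, temperature = 250, friction_ps = 1,
                   seed = 1L, report_every = 100L, store_frames = FALSE,
                   box_end = NULL, step_offset = 0L, thermostat = TRUE,
                   fcap = 0) {
  stopifnot(n_steps >= 0, dt_fs > 0)
  top <- config$topology
  vel <- config$velocities
  if (is.null(vel)) vel <- matrix(numeric(0), 0L, 3L)
  res <- cpp_run_md(
    config$positions, vel, config$box,
    ff_type_index(ff, top$bead_type), top$charge, top$bonds, ff_to_cpp(ff),
    as.integer(n_steps), dt_fs / TIME_UNIT_FS, temperature,
    friction_ps * TIME_UNIT_FS / 1000, as.integer(seed),
    as.integer(report_every), store_frames,
    if (is.null(box_end)) numeric(0) else as.numeric(box_end),
    as.integer(step_offset), thermostat, 10.0, fcap
  )
  if (isTRUE(res$aborted)) {
    warning("dynamics aborted (instability guard); partial output preserved")
  }
  structure(
    list(
      positions = res$positions, velocities = res$velocities,
      box = as.numeric(res$box), topology = top,
      frames = res$frames, stats = res$stats, aborted = res$aborted,
      params = list(dt_fs = dt_fs, temperature = temperature,
                    friction_ps = friction_ps, seed = seed,
                    n_steps = n_steps, report_every = report_every,
                    forcefield = ff)
    ),
    class = "cg_trajectory"
  )
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf(
    "<cg_trajectory> %d beads, %d frames, box %.1f x %.1f x %.1f A, T set %g K%s\n",
    nrow(x$positions), length(x$frames), x$box[1], x$box[2], x$box[3],
    x$params$temperature, if (isTRUE(x$aborted)) " [ABORTED]" else ""
  ))
  invisible(x)
}

#' Compress the simulation box with dynamics running
#'
#' Rescales the box edges linearly from their current values to
#' `target_edge` over `n_steps` Langevin steps, carrying the particle
#' positions along affinely each step so the configuration relaxes as it is
#' compressed (the standard preparation of a dense block before slab
#' expansion).
#'
#' @param config configuration list (`positions`, `box`, `topology`).
#' @param target_edge length-1 (cubic) or length-3 target edges, each at
#'   most the current edge.
#' @param n_steps compression steps (> 0).
#' @inheritParams run_md
#' @return The compressed configuration (same shape as `config`, with
#'   `velocities` and the compression `stats` attached).
#' @export
compress_box <- function(config, target_edge, n_steps = 5000L,
                         ff = default_forcefield(), dt_fs = 10,
                         temperature = 250, friction_ps = 1, seed = 1L,
                         fcap = 100) {
  if (n_steps < 1L) stop("compress_box: n_steps must be positive")
  target <- if (length(target_edge) == 1L) rep(target_edge, 3L) else target_edge
  if (any(target > config$box)) {
    stop("compress_box: target edges must not exceed current edges")
  }
  run <- run_md(config, ff = ff, n_steps = n_steps, dt_fs = dt_fs,
                temperature = temperature, friction_ps = friction_ps,
                seed = seed, report_every = max(1L, n_steps %/% 10L),
                store_frames = FALSE, box_end = target, fcap = fcap)
  if (isTRUE(run$aborted)) {
    stop("compress_box: dynamics diverged during compression; compress more slowly")
  }
  list(positions = run$positions, velocities = run$velocities,
       box = run$box, topology = config$topology, stats = run$stats)
}

#' Direct-coexistence production run in slab geometry
#'
#' Equilibrates and then runs production NVT Langevin dynamics on a slab
#' configuration (box elongated along z, as produced by [make_slab()]),
#' recording frames and per-interval statistics for the coexistence
#' analysis. All run metadata (protocol, seeds, force field) is carried in
#' the returned trajectory.
#'
#' @param config slab configuration (`positions`, `box`, `topology`,
#'   optionally `velocities`).
#' @param ff a [default_forcefield()].
#' @param protocol list with `equilibration_steps`, `production_steps`,
#'   `report_every`, and optionally `dt_fs`, `temperature`, `friction_ps`.
#' @param seed master seed.
#' @return A `cg_trajectory` (see [run_md()]) of the production phase with
#'   the equilibration stats in `$equilibration_stats`.
#' @export
run_coexistence <- function(config, ff = default_forcefield(),
                            protocol = list(equilibration_steps = 5000L,
                                            production_steps = 20000L,
                                            report_every = 200L),
                            seed = 1L) {
  if (config$box[3L] <= max(config$box[1:2])) {
    stop("run_coexistence expects slab geometry (Lz > Lx, Ly); see make_slab()")
  }
  dt_fs <- protocol$dt_fs %||% 10
  temperature <- protocol$temperature %||% 250
  friction_ps <- protocol$friction_ps %||% 1
  eq <- run_md(config, ff = ff, n_steps = protocol$equilibration_steps,
               dt_fs = dt_fs, temperature = temperature,
               friction_ps = friction_ps, seed = seed,
               report_every = max(1L, protocol$equilibration_steps %/% 20L),
               store_frames = FALSE)
  cfg2 <- list(positions = eq$positions, velocities = eq$velocities,
               box = eq$box, topology = config$topology)
  prod <- run_md(cfg2, ff = ff, n_steps = protocol$production_steps,
                 dt_fs = dt_fs, temperature = temperature,
                 friction_ps = friction_ps, seed = seed,
                 report_every = protocol$report_every, store_frames = TRUE,
                 step_offset = protocol$equilibration_steps)
  prod$equilibration_stats <- eq$stats
  prod$params$protocol <- protocol
  prod
}

#' Save / load a trajectory container
#'
#' Serializes the trajectory (positions per frame, FrameStats table,
#' topology and full run metadata) as a single RDS container.
#'
#' @param traj a `cg_trajectory`.
#' @param path file path (`.rds`).
#' @return `save_trajectory` returns `path` invisibly; `load_trajectory`
#'   returns the trajectory.
#' @export
save_trajectory <- function(traj, path) {
  saveRDS(traj, path)
  invisible(path)
}

#' @rdname save_trajectory
#' @export
load_trajectory <- function(path) readRDS(path)

`%||%` <- function(a, b) if (is.null(a)) b else a
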