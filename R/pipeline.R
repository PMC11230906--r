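#' Simulation presets for direct-coexistence runs
#'
#' Bundles the protocol parameters of a slab simulation. Two presets ship
#' with the package:
#' \describe{
#'   \item{`"desk"`}{a scaled-down protocol that runs on one CPU in minutes:
#'     ~1,000-1,500 beads, 120 A starting cube compressed to a dense block,
#'     slab Lz of 260 A, 10 fs steps. Used for trend-level science
#'     (orderings of K_p, gamma, phi_B), not absolute literature values.}
#'   \item{`"full"`}{the full-scale direct-coexistence protocol this model
#'     family is usually run at: 500 A cube compressed to 200-250 A, slab
#'     expanded to 1250 A, microsecond-scale sampling. Provided for
#'     completeness; it is not desk-runnable.}
#' }
#'
#' @param name `"desk"` or `"full"`.
#' @param ... overrides for individual fields.
#' @return list of protocol parameters.
#' @export
coexistence_preset <- function(name = c("desk", "full"), ...) {
  name <- match.arg(name)
  preset <- switch(name,
    desk = list(
      total_beads = 1200L,
      box_start = 130,
      box_compressed = 88,
      Lz_slab = 300,
      compress_steps = 3000L,
      equilibration_steps = 8000L,
      production_steps = 30000L,
      report_every = 150L,
      dt_fs = 10,
      temperature = 250,
      friction_ps = 1,
      cutoff_coul = 25
    ),
    full = list(
      total_beads = 50000L,
      box_start = 500,
      box_compressed = 250,
      Lz_slab = 1250,
      compress_steps = 200000L,
      equilibration_steps = 5e8,
      production_steps = 5e8,
      report_every = 10000L,
      dt_fs = 10,
      temperature = 250,
      friction_ps = 1,
      cutoff_coul = 35
    )
  )
  overrides <- list(...)
  preset[names(overrides)] <- overrides
  preset
}

#' Build, equilibrate and run a binary direct-coexistence simulation
#'
#' The full preparation protocol: build topologies for the two components
#' (star when the valence f > 1, linear otherwise), assemble them at equal
#' polyampholyte mass fraction in a cubic box, compress the box to a dense
#' block with dynamics running, expand the z axis into slab geometry, then
#' equilibrate and run NVT production, returning the production trajectory.
#'
#' @param seq_p,seq_q [charge_sequence()] objects for the two components.
#' @param f_p,f_q valence (arm count) of each component; 1 = linear chain.
#' @param preset protocol list from [coexistence_preset()].
#' @param seed master seed (assembly and dynamics derive their streams
#'   from it).
#' @param ff force field.
#' @param species_p,species_q species labels (default: sequence names).
#' @param arrangement initial arrangement of the species (see
#'   [assemble_binary_mixture()]); scaled-down trend runs use `"sandwich"`.
#' @return A `cg_trajectory` from [run_coexistence()]; the assembled copy
#'   numbers and residual mass imbalance are in `$params$assembly`.
#' @export
simulate_pair <- function(seq_p, seq_q, f_p = 1L, f_q = 1L,
                          preset = coexistence_preset("desk"), seed = 1L,
                          ff = NULL,
                          species_p = NULL, species_q = NULL,
                          arrangement = "random") {
  if (is.null(ff)) {
    # the desk preset trims the electrostatic cutoff to 25 A: the screened
    # tail beyond 2.5 Debye lengths is < 3% of kT and the neighbour lists
    # shrink accordingly
    ff <- default_forcefield(cutoff_coul = preset$cutoff_coul %||% 35)
  }
  seq_p <- as_charge_sequence(seq_p)
  seq_q <- as_charge_sequence(seq_q)
  if (is.null(species_p)) {
    species_p <- if (f_p > 1L) sprintf("%sx%d", seq_p$name, f_p) else seq_p$name
  }
  if (is.null(species_q)) {
    species_q <- if (f_q > 1L) sprintf("%sx%d", seq_q$name, f_q) else seq_q$name
  }
  if (species_p == species_q) species_q <- paste0(species_q, "_b")
  top_p <- if (f_p > 1L) build_star(seq_p, f_p, species_p)
           else build_linear(seq_p, species_p)
  top_q <- if (f_q > 1L) build_star(seq_q, f_q, species_q)
           else build_linear(seq_q, species_q)
  mix <- assemble_binary_mixture(top_p, top_q,
                                 total_beads = preset$total_beads,
                                 box = preset$box_start, seed = seed,
                                 arrangement = arrangement)
  cfg <- list(positions = mix$positions, box = mix$box,
              topology = mix$topology)
  cfg <- compress_box(cfg, preset$box_compressed,
                      n_steps = preset$compress_steps, ff = ff,
                      dt_fs = preset$dt_fs,
                      temperature = preset$temperature,
                      friction_ps = preset$friction_ps, seed = seed + 1L)
  cfg <- make_slab(cfg, preset$Lz_slab)
  traj <- run_coexistence(
    cfg, ff = ff,
    protocol = list(
      equilibration_steps = preset$equilibration_steps,
      production_steps = preset$production_steps,
      report_every = preset$report_every,
      dt_fs = preset$dt_fs,
      temperature = preset$temperature,
      friction_ps = preset$friction_ps
    ),
    seed = seed + 2L
  )
  traj$params$assembly <- list(n_p = mix$n_p, n_q = mix$n_q,
                               imbalance = mix$imbalance,
                               species_p = species_p, species_q = species_q)
  traj
}
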