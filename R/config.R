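#' Read a simulation configuration file
#'
#' A YAML run description bundles everything a coexistence simulation needs:
#'
#' ```yaml
#' sequences:
#'   A: KEKKEE...        # literal K/E strings, or
#'   fasta: seqs.fasta   # a FASTA file whose records are added by name
#' components:
#'   p: {sequence: A, f: 3}
#'   q: {sequence: B, f: 1}
#' preset: desk          # or "full"
#' overrides:            # any coexistence_preset() field
#'   total_beads: 900
#'   production_steps: 20000
#' arrangement: sandwich
#' seed: 7
#' forcefield:           # any default_forcefield() argument
#'   cutoff_coul: 25
#' ```
#'
#' @param path YAML file path.
#' @return list with `seq_p`, `seq_q`, `f_p`, `f_q`, `preset`, `seed`,
#'   `arrangement` and `ff`, ready for [run_simulation_config()].
#' @export
read_simulation_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$sequences) || is.null(cfg$components)) {
    stop("config needs 'sequences' and 'components' sections")
  }
  seqs <- list()
  for (nm in names(cfg$sequences)) {
    if (nm == "fasta") {
      fa <- read_charge_sequences(file.path(dirname(path), cfg$sequences$fasta))
      seqs[names(fa)] <- fa
    } else {
      seqs[[nm]] <- charge_sequence(cfg$sequences[[nm]], name = nm)
    }
  }
  comp <- function(role) {
    c <- cfg$components[[role]]
    if (is.null(c$sequence) || is.null(seqs[[c$sequence]])) {
      stop("component '", role, "' needs a 'sequence' naming a defined sequence")
    }
    list(seq = seqs[[c$sequence]], f = as.integer(c$f %||% 1L))
  }
  p <- comp("p"); q <- comp("q")
  preset <- do.call(coexistence_preset,
                    c(list(name = cfg$preset %||% "desk"),
                      cfg$overrides %||% list()))
  ff <- if (is.null(cfg$forcefield)) NULL else {
    do.call(default_forcefield, cfg$forcefield)
  }
  list(seq_p = p$seq, seq_q = q$seq, f_p = p$f, f_q = q$f,
       preset = preset, seed = as.integer(cfg$seed %||% 1L),
       arrangement = cfg$arrangement %||% "random", ff = ff)
}

#' Run a simulation described by a configuration file
#'
#' @param config path to a YAML file or the list from
#'   [read_simulation_config()].
#' @return A `cg_trajectory` from [simulate_pair()].
#' @export
run_simulation_config <- function(config) {
  if (is.character(config)) config <- read_simulation_config(config)
  simulate_pair(config$seq_p, config$seq_q, config$f_p, config$f_q,
                preset = config$preset, seed = config$seed,
                ff = config$ff, arrangement = config$arrangement)
}
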