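#' Coarse-grained force field for K/E polyampholytes
#'
#' One-bead-per-residue implicit-solvent model: an Ashbaugh-Hatch
#' (hydrophobicity-scaled Lennard-Jones) short-range potential with
#' arithmetic-mean mixing of per-type diameters and hydrophobicities,
#' Debye-Hueckel screened electrostatics between charged beads, and harmonic
#' bonds. The per-residue parameters (diameter sigma, hydrophobicity lambda,
#' mass) for lysine and glutamate follow the published hydrophobicity-scale
#' parameter set and ship in `inst/extdata/hps_params.csv`; every value can
#' be overridden. The CORE type is the star scaffold bead: neutral, purely
#' repulsive (its pair hydrophobicity is forced to zero regardless of the
#' mixing rule) and, by default, twice the lysine bead diameter.
#'
#' Energies are kcal/mol, lengths Angstrom, masses Dalton. Both pair
#' potentials are energy-shifted to zero at their cutoffs, so the potential
#' is continuous everywhere.
#'
#' @param epsilon pair energy scale (kcal/mol).
#' @param debye_length Debye screening length (Angstrom).
#' @param dielectric relative dielectric constant.
#' @param cutoff_lj short-range (Ashbaugh-Hatch) cutoff (Angstrom).
#' @param cutoff_coul electrostatic cutoff (Angstrom).
#' @param bond_k harmonic bond stiffness, kcal/mol/A^2 in the
#'   U = k/2 (r - r0)^2 convention.
#' @param bond_r0 bond rest length (Angstrom).
#' @param core_sigma scaffold bead diameter (Angstrom).
#' @param params optional data.frame overriding the per-type table; columns
#'   `type`, `sigma`, `lambda`, `mass`, `charge`, `is_core`.
#' @return An object of class `forcefield`.
#' @export
default_forcefield <- function(epsilon = 0.2,
                               debye_length = 10,
                               dielectric = 80,
                               cutoff_lj = 20,
                               cutoff_coul = 35,
                               bond_k = 2.39006,
                               bond_r0 = 3.8,
                               core_sigma = NULL,
                               params = NULL) {
  if (is.null(params)) {
    path <- system.file("extdata", "hps_params.csv", package = "condmix")
    params <- utils::read.csv(path, comment.char = "#",
                              stringsAsFactors = FALSE)
  }
  if (!is.null(core_sigma)) {
    params$sigma[params$type == "CORE"] <- core_sigma
  }
  stopifnot(all(c("type", "sigma", "lambda", "mass", "charge", "is_core")
                %in% names(params)))
  if (cutoff_lj < max(params$sigma) || cutoff_coul < max(params$sigma)) {
    stop("cutoffs must be at least the largest pair diameter")
  }
  structure(
    list(
      params = params,
      epsilon = epsilon,
      debye_length = debye_length,
      dielectric = dielectric,
      cutoff_lj = cutoff_lj,
      cutoff_coul = cutoff_coul,
      bond_k = bond_k,
      bond_r0 = bond_r0
    ),
    class = "forcefield"
  )
}

#' @export
print.forcefield <- function(x, ...) {
  cat(sprintf(
    "<forcefield> eps %g kcal/mol, Debye %g A (eps_r %g), cutoffs %g/%g A, bond k %g r0 %g\n",
    x$epsilon, x$debye_length, x$dielectric, x$cutoff_lj, x$cutoff_coul,
    x$bond_k, x$bond_r0
  ))
  print(x$params)
  invisible(x)
}

# map per-bead residue identities to 0-based type indices for the C++ core
ff_type_index <- function(ff, bead_type) {
  idx <- match(bead_type, ff$params$type)
  if (anyNA(idx)) {
    stop("bead type(s) without force-field parameters: ",
         paste(unique(bead_type[is.na(idx)]), collapse = ", "))
  }
  idx - 1L
}

ff_to_cpp <- function(ff) {
  list(
    sigma = ff$params$sigma,
    lambda = ff$params$lambda,
    mass = ff$params$mass,
    is_core = as.integer(ff$params$is_core),
    epsilon = ff$epsilon,
    debye_length = ff$debye_length,
    dielectric = ff$dielectric,
    cutoff_lj = ff$cutoff_lj,
    cutoff_coul = ff$cutoff_coul,
    bond_k = ff$bond_k,
    bond_r0 = ff$bond_r0
  )
}

#' Mixed pair parameters and the pair potential
#'
#' Evaluates the pair energy between two bead types at distance `r`:
#' Ashbaugh-Hatch (for r below `cutoff_lj`) plus Debye-Hueckel (for charged
#' pairs below `cutoff_coul`), each energy-shifted to zero at its cutoff.
#' Mirrors the compiled kernel exactly and exists for documentation,
#' testing and plotting.
#'
#' @param ff a [default_forcefield()].
#' @param type_i,type_j bead type names (e.g. "K", "E", "CORE").
#' @param r distance(s), Angstrom, > 0.
#' @return Numeric vector of pair energies (kcal/mol).
#' @export
pair_energy <- function(ff, type_i, type_j, r) {
  if (any(r <= 0)) stop("pair_energy: r must be positive")
  pi_ <- ff$params[ff$params$type == type_i, ]
  pj <- ff$params[ff$params$type == type_j, ]
  if (nrow(pi_) != 1L || nrow(pj) != 1L) stop("unknown bead type")
  sij <- (pi_$sigma + pj$sigma) / 2
  lij <- if (pi_$is_core || pj$is_core) 0 else (pi_$lambda + pj$lambda) / 2
  ulj <- function(rr) 4 * ff$epsilon * ((sij / rr)^12 - (sij / rr)^6)
  shift <- lij * ulj(ff$cutoff_lj)
  rmin <- 2^(1 / 6) * sij
  u <- ifelse(
    r < rmin,
    ulj(r) + (1 - lij) * ff$epsilon - shift,
    ifelse(r < ff$cutoff_lj, lij * ulj(r) - shift, 0)
  )
  qq <- pi_$charge * pj$charge
  if (qq != 0) {
    kq <- 332.0637 / ff$dielectric * qq
    u_dh <- ifelse(
      r < ff$cutoff_coul,
      kq * (exp(-r / ff$debye_length) / r -
              exp(-ff$cutoff_coul / ff$debye_length) / ff$cutoff_coul),
      0
    )
    u <- u + u_dh
  }
  u
}
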