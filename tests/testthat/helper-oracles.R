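# Independent oracles used across the suite. These are deliberately written
# as plain double loops / brute force so they share no code with the package
# implementations they check.

# O(N^2) double-loop SCD, the reference for the vectorized implementation
scd_bruteforce <- function(charges) {
  n <- length(charges)
  if (n < 2L) return(0)
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      total <- total + charges[i] * charges[j] * sqrt(j - i)
    }
  }
  total / n
}

# random charge-neutral K/E sequence of even length
random_neutral_sequence <- function(len, name = "rnd") {
  res <- sample(c(rep("K", len %/% 2), rep("E", len - len %/% 2)))
  suppressWarnings(charge_sequence(res, name = name))
}

# neutral length-n sequence built of alternating charge blocks of given size
block_sequence <- function(n, block, name = sprintf("b%d", block)) {
  pattern <- rep(c(rep("K", block), rep("E", block)), length.out = n)
  suppressWarnings(charge_sequence(pattern, name = name))
}

# brute-force inter-molecular contact counts with minimum-image convention;
# oracle for the compiled contact counter
contacts_bruteforce <- function(pos, box, sigma, molecule, is_target,
                                cutoff_factor) {
  n <- nrow(pos)
  het <- 0L; hom <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (molecule[i] == molecule[j]) next
      if (!is_target[i] && !is_target[j]) next
      d <- pos[i, ] - pos[j, ]
      d <- d - round(d / box) * box
      sij <- (sigma[i] + sigma[j]) / 2
      if (sum(d * d) < (cutoff_factor * sij)^2) {
        if (is_target[i] && is_target[j]) hom <- hom + 1L else het <- het + 1L
      }
    }
  }
  list(heterotypic = het, homotypic = hom)
}

# minimal trajectory-like object for analysis-only tests
fake_trajectory <- function(frames, box, topology) {
  structure(
    list(frames = frames, box = box, topology = topology,
         positions = frames[[length(frames)]],
         stats = NULL, params = list(temperature = NA)),
    class = "cg_trajectory"
  )
}

# gas topology: n unbonded single beads (uses internal constructor)
gas_topology <- function(n, type = "CORE", species = "gas") {
  condmix:::new_topology(
    bead_type = rep(type, n),
    charge = rep(0, n),
    bonds = matrix(integer(0), 0L, 2L),
    molecule_id = seq_len(n),
    species = rep(species, n),
    valence = rep(1L, n)
  )
}
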