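test_that("linear and star topologies satisfy the counting identities", {
  set.seed(21)
  for (L in c(5L, 20L, 50L)) {
    s <- random_neutral_sequence(L)
    lin <- build_linear(s)
    expect_length(lin$bead_type, L)
    expect_identical(nrow(lin$bonds), L - 1L)
    if (L %% 2L == 0L) expect_equal(sum(lin$charge), 0)
    for (f in c(1L, 2L, 3L, 5L)) {
      st <- build_star(s, f)
      expect_length(st$bead_type, f * L + 1L)
      expect_identical(nrow(st$bonds), f * L)
      # core bead: neutral, degree f
      expect_identical(st$bead_type[1], "CORE")
      expect_equal(st$charge[1], 0)
      expect_identical(sum(st$bonds == 1L), f)
      # bond graph is connected and acyclic (tree: V - 1 edges, all reachable)
      g <- lapply(seq_len(f * L + 1L), function(i) integer(0))
      for (b in seq_len(nrow(st$bonds))) {
        i <- st$bonds[b, 1]; j <- st$bonds[b, 2]
        g[[i]] <- c(g[[i]], j); g[[j]] <- c(g[[j]], i)
      }
      seen <- rep(FALSE, f * L + 1L); queue <- 1L; seen[1L] <- TRUE
      while (length(queue) > 0L) {
        v <- queue[1L]; queue <- queue[-1L]
        nxt <- g[[v]][!seen[g[[v]]]]
        seen[nxt] <- TRUE; queue <- c(queue, nxt)
      }
      expect_true(all(seen))
    }
  }
  # a star with f = 1 is the linear chain plus the core bead
  s <- random_neutral_sequence(20)
  st1 <- build_star(s, 1)
  expect_identical(st1$bead_type[-1], build_linear(s)$bead_type)
  expect_error(build_star(s, 0), "f must be")
})

test_that("copy numbers balance polyampholyte bead mass", {
  # star f=5 (251 beads, 250 polyampholyte) vs linear 50-mer: ~1:5 ratio
  bal <- balance_copy_numbers(250, 50, 2000)
  expect_equal(bal$n_q / bal$n_p, 5, tolerance = 0.2)
  expect_lte(bal$imbalance, 50)
  # identical topologies split evenly
  bal2 <- balance_copy_numbers(50, 50, 1000)
  expect_identical(bal2$n_p, bal2$n_q)
  expect_identical(bal2$imbalance, 0L)
})

test_that("assembled mixtures respect exclusion distance, balance and seed", {
  set.seed(31)
  s <- random_neutral_sequence(20)
  top_p <- build_star(s, 3, "p")
  top_q <- build_linear(s, "q")
  mix <- assemble_binary_mixture(top_p, top_q, total_beads = 400, box = 120,
                                 seed = 7)
  # equal polyampholyte mass within one molecule's worth
  n_poly_p <- mix$n_p * 60L; n_poly_q <- mix$n_q * 20L
  expect_lte(abs(n_poly_p - n_poly_q), 60L)
  expect_equal(mix$imbalance, abs(n_poly_p - n_poly_q))
  # positions wrapped into the box
  expect_true(all(mix$positions >= 0 & mix$positions <= 120))
  # no inter-molecular pair below the exclusion distance
  d_min <- Inf
  mol <- mix$topology$molecule_id
  pos <- mix$positions
  for (i in seq_len(nrow(pos) - 1)) {
    d <- sweep(pos[(i + 1):nrow(pos), , drop = FALSE], 2, pos[i, ])
    d <- d - round(d / 120) * 120
    dd <- sqrt(rowSums(d^2))
    dd[mol[(i + 1):nrow(pos)] == mol[i]] <- Inf
    d_min <- min(d_min, dd)
  }
  expect_gte(d_min, 0.9 * 5.92)
  # determinism: same seed gives bit-identical output, new seed differs
  mix2 <- assemble_binary_mixture(top_p, top_q, total_beads = 400, box = 120,
                                  seed = 7)
  expect_identical(mix$positions, mix2$positions)
  mix3 <- assemble_binary_mixture(top_p, top_q, total_beads = 400, box = 120,
                                  seed = 8)
  expect_false(identical(mix$positions, mix3$positions))
  # impossible density errors out with a density diagnostic
  expect_error(
    assemble_binary_mixture(top_p, top_q, total_beads = 400, box = 25,
                            seed = 1, max_tries = 10),
    "density"
  )
})

test_that("slab expansion preserves area, centres the material, adds vacuum", {
  set.seed(5)
  s <- random_neutral_sequence(10)
  mix <- assemble_binary_mixture(build_linear(s, "p"), build_linear(s, "q"),
                                 total_beads = 200, box = 80, seed = 3)
  cfg <- list(positions = mix$positions, box = mix$box,
              topology = mix$topology)
  slab <- make_slab(cfg, 400)
  expect_equal(slab$box, c(80, 80, 400))
  expect_identical(nrow(slab$positions), nrow(cfg$positions))
  # material centre of mass sits at Lz/2 within a bead diameter
  expect_lt(abs(mean(slab$positions[, 3]) - 200), 6.5)
  # vacuum fraction along z
  expect_equal(1 - 80 / 400, 0.8)
  expect_true(all(slab$positions[, 3] >= 0 & slab$positions[, 3] <= 400))
  # x/y coordinates untouched up to the wrap
  expect_equal(slab$positions[, 1:2] %% 80, cfg$positions[, 1:2] %% 80,
               tolerance = 1e-9)
  # no molecule is split across the new vacuum: bonded beads stay close
  b <- slab$topology$bonds
  dz <- abs(slab$positions[b[, 1], 3] - slab$positions[b[, 2], 3])
  expect_lt(max(pmin(dz, 400 - dz)), 20)
  expect_error(make_slab(slab, 100), "exceed")
})

test_that("XYZ export writes a readable snapshot", {
  s <- random_neutral_sequence(6)
  mix <- assemble_binary_mixture(build_linear(s, "p"), build_linear(s, "q"),
                                 total_beads = 24, box = 60, seed = 2)
  f <- tempfile(fileext = ".xyz")
  write_xyz(list(positions = mix$positions, box = mix$box,
                 topology = mix$topology), f)
  lines <- readLines(f)
  expect_identical(as.integer(lines[1]), nrow(mix$positions))
  expect_match(lines[2], "^box 60")
  expect_length(lines, nrow(mix$positions) + 2L)
})
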