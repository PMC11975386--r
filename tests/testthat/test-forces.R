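# force-field correctness: closed-form values and finite-difference gradients

small_system <- function(seed = 3, cargo_d = 2) {
  cfg <- npc_config(box = c(20, 20, 30), h = 5, D = 8, N = 6, n_FG = 2,
                    cargo_d = cargo_d, equil_steps = 0)
  sys <- build_system(cfg, seed = seed)
  sys <- run_bd(sys, 500)  # a short relaxation gives a generic configuration
  kmc_update(sys)
}

test_that("pair potentials match their closed forms at the standard values", {
  expect_equal(steric_potential(1), 400 * exp(-1))          # ~147.15 kBT
  expect_equal(steric_force(0.5), 400 * exp(-0.5))          # ~242.6 kBT/sigma
  expect_equal(steric_force(1.2), 0)                        # beyond cutoff
  expect_equal(steric_potential(1.2), 400 * exp(-1))        # held constant
  expect_equal(bond_potential(1 + 0.1), 1)                  # 1 kBT at req+0.1
  expect_equal(angle_potential(pi / 2), 0.5 * (1 - cos(-pi / 2)))
  expect_equal(angle_potential(pi), 0)
})

test_that("bond and angle terms vanish at their equilibria", {
  # straight dimer/trimer at rest length: all conservative forces zero
  st <- list(
    pos = cbind(10 + 0:2, 10, 10), chain_id = rep(1L, 3),
    anchored = logical(3), sticker = logical(3), pinned = logical(3),
    sticker_state = integer(3), partner = integer(3),
    box = rep(20, 3), env = c(h = 0, D = 0, zc = 10),
    ff = npcflux:::engine_ff(force_field(eps_r = 0)),
    kmc = c(rthre = 2, kon = 0, koff = 0, FFG = 0, bound_neighbor = 1),
    cargo = NULL, rng = derive_stream(1, "eq"))
  f <- npcflux:::cpp_forces(st)
  expect_equal(f$energy[["bond"]], 0)
  expect_equal(f$energy[["angle"]], 0)
  expect_equal(max(abs(f$bond)), 0)
  expect_equal(max(abs(f$angle)), 0)
  # stretched bond: U = kb dr^2, |F| = 2 kb dr
  st$pos[2, 1] <- 11.1
  f <- npcflux:::cpp_forces(st)
  expect_equal(f$energy[["bond"]], 100 * 0.1^2 + 100 * 0.1^2)
  expect_equal(abs(f$bond[1, 1]), 2 * 100 * 0.1, tolerance = 1e-9)
})

test_that("every conservative force equals minus the energy gradient", {
  sys <- small_system()
  st <- npcflux:::as_engine_state(sys)
  f <- npcflux:::cpp_forces(st)
  total <- f$bond + f$angle + f$steric + f$wall
  en <- function(s) sum(npcflux:::cpp_forces(s)$energy[c("bond", "angle",
                                                         "steric", "wall")])
  h <- 1e-6
  set.seed(11)
  for (i in sample(nrow(sys$pos), 5)) {
    for (k in 1:3) {
      sp <- st; sp$pos[i, k] <- sp$pos[i, k] + h
      sm <- st; sm$pos[i, k] <- sm$pos[i, k] - h
      fd <- -(en(sp) - en(sm)) / (2 * h)
      expect_equal(total[i, k], fd, tolerance = 1e-5)
    }
  }
})

test_that("pair forces are antisymmetric and sum to zero", {
  sys <- small_system()
  f <- compute_forces(sys)
  # bond + angle + steric are internal: their sum over all beads vanishes
  for (term in c("bond", "angle", "steric", "sticker")) {
    expect_equal(colSums(f$forces[[term]]), c(0, 0, 0), tolerance = 1e-9)
  }
  # an isolated interacting pair: forces equal and opposite
  st <- list(
    pos = rbind(c(10, 10, 10), c(10.6, 10, 10)), chain_id = c(0L, 0L),
    anchored = logical(2), sticker = logical(2), pinned = logical(2),
    sticker_state = integer(2), partner = integer(2),
    box = rep(20, 3), env = c(h = 0, D = 0, zc = 10),
    ff = npcflux:::engine_ff(force_field()),
    kmc = c(rthre = 2, kon = 0, koff = 0, FFG = 0, bound_neighbor = 1),
    cargo = NULL, rng = derive_stream(1, "pair"))
  f2 <- npcflux:::cpp_forces(st)
  expect_equal(f2$steric[1, ], -f2$steric[2, ])
  expect_equal(abs(f2$steric[1, 1]), 400 * exp(-0.6), tolerance = 1e-9)
})

test_that("wall force is constant-magnitude along the outward normal", {
  box <- c(30, 30, 40); env <- c(4, 10, 20) # h, D, zc
  # beyond sigma/2 of any surface: no force
  w <- npcflux:::cpp_wall_probe(c(15, 15, 22.7), box, env)
  expect_gt(w[1], 0.5)
  # 0.4 sigma above the top envelope face, over the solid annulus
  w <- npcflux:::cpp_wall_probe(c(15 + 8, 15, 22.4), box, env)
  expect_equal(w[1], 0.4, tolerance = 1e-9)
  expect_equal(w[2:4], c(0, 0, 1))
  # inside the pore, 0.3 sigma from the cylinder wall: inward radial normal
  w <- npcflux:::cpp_wall_probe(c(15 + 4.7, 15, 20), box, env)
  expect_equal(w[1], 0.3, tolerance = 1e-9)
  expect_equal(w[2:4], c(-1, 0, 0))
  # over the pore mouth: nearest solid is the rim circle
  w <- npcflux:::cpp_wall_probe(c(15, 15, 23), box, env)
  expect_equal(w[1], sqrt(5^2 + 1^2), tolerance = 1e-9)
})

test_that("zero-length bonds are rejected", {
  st <- list(
    pos = rbind(c(10, 10, 10), c(10, 10, 10)), chain_id = c(1L, 1L),
    anchored = logical(2), sticker = logical(2), pinned = logical(2),
    sticker_state = integer(2), partner = integer(2),
    box = rep(20, 3), env = c(h = 0, D = 0, zc = 10),
    ff = npcflux:::engine_ff(force_field()),
    kmc = c(rthre = 2, kon = 0, koff = 0, FFG = 0, bound_neighbor = 1),
    cargo = NULL, rng = derive_stream(1, "zero"))
  expect_error(npcflux:::cpp_forces(st), "zero length")
})
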