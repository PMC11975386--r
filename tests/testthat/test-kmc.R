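# sticker state machine: classification, exclusivity, lifetimes, bound forces

pair_system <- function(sep, extra = NULL, kon = 0, koff = 0, FFG = 0,
                        bound_neighbor = 1) {
  L <- 40
  pos <- rbind(c(L / 2, L / 2, L / 2), c(L / 2 + sep, L / 2, L / 2), extra)
  n <- nrow(pos)
  list(pos = pos, chain_id = integer(n), anchored = rep(TRUE, n),
       sticker = rep(TRUE, n), pinned = rep(TRUE, n),
       sticker_state = integer(n), partner = integer(n),
       box = rep(L, 3), env = c(h = 0, D = 0, zc = L / 2),
       ff = npcflux:::engine_ff(force_field()),
       kmc = c(rthre = 2, kon = kon, koff = koff, FFG = FFG,
               bound_neighbor = bound_neighbor),
       cargo = NULL, rng = derive_stream(1, "kmc"))
}

test_that("free stickers classify by the rthre neighbourhood rule", {
  # far apart: both free-outside
  st <- npcflux:::cpp_classify(pair_system(3))
  expect_equal(st$sticker_state, c(0L, 0L))
  # within rthre = 2: both free-inside
  st <- npcflux:::cpp_classify(pair_system(1.5))
  expect_equal(st$sticker_state, c(1L, 1L))
  # a bound pair counts as neighbours for a third sticker (default rule)
  base <- pair_system(1.5, extra = c(20 + 1.0, 20.8, 20))
  base$sticker_state <- c(2L, 2L, 0L)
  base$partner <- c(2L, 1L, 0L)
  st <- npcflux:::cpp_classify(base)
  expect_equal(st$sticker_state[3], 1L)
  # with the switch off, the same third sticker is free-outside
  base$kmc["bound_neighbor"] <- 0
  st <- npcflux:::cpp_classify(base)
  expect_equal(st$sticker_state[3], 0L)
})

test_that("binding and unbinding waiting times match the configured rates", {
  lt <- sample_bond_lifetimes(n_events = 600, seed = 11)
  expect_equal(mean(lt$bound_steps), 1 / 2e-4, tolerance = 0.1)
  expect_equal(mean(lt$free_steps), 1 / 2e-3, tolerance = 0.1)
  # geometric lifetimes: two-sample KS against the reference distribution
  set.seed(77)
  ref <- rgeom(20000, 2e-4) + 1
  ks <- suppressWarnings(ks.test(lt$bound_steps, ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("exclusive pairing holds among clustered stickers", {
  # three mutually-close FI stickers, driven hard (kon large): never more
  # than one bond per sticker, partner map an involution
  st <- pair_system(1.2, extra = c(20.6, 20 + 1.0, 20), kon = 0.5, koff = 0.3)
  audited <- 0L
  for (rep in 1:300) {
    st <- npcflux:::cpp_kmc_step(st)
    p <- st$partner
    bound <- which(p > 0)
    audited <- audited + length(bound)
    expect_true(all(p[p[bound]] == bound))      # involution
    expect_true(sum(st$sticker_state == 2L) %% 2 == 0)
    expect_true(!any(duplicated(p[bound])))
  }
  expect_gt(audited, 0L)
})

test_that("free-outside stickers never bind and unbinding lands in FI", {
  # within one integration step a sticker may pass FO -> FI -> B because
  # classification precedes the binding draw; the machine's real
  # constraints are that out-of-range (FO) stickers never bind and that an
  # unbinding pair becomes FI, never FO, at the moment of unbinding. Audit
  # both on held configurations where classification cannot change.
  st <- pair_system(3, kon = 0.5, koff = 0.1)   # beyond rthre: FO forever
  for (rep in 1:500) {
    st <- npcflux:::cpp_kmc_step(st)
    expect_true(all(st$sticker_state %in% c(0L, 1L)))
    expect_true(all(st$partner == 0L))
  }
  st <- pair_system(1.5, kon = 0.2, koff = 0.2) # in range: FI <-> B only
  n_bound_seen <- 0L
  for (rep in 1:500) {
    st <- npcflux:::cpp_kmc_step(st)
    expect_true(all(st$sticker_state %in% c(1L, 2L))) # never FO in range
    n_bound_seen <- n_bound_seen + sum(st$sticker_state == 2L)
  }
  expect_gt(n_bound_seen, 0L)
})

test_that("bound pairs feel the constant attraction FFG toward each other", {
  st <- pair_system(3, FFG = 2)
  st$sticker_state <- c(2L, 2L)
  st$partner <- c(2L, 1L)
  f <- npcflux:::cpp_forces(st)
  expect_equal(f$sticker[1, ], c(2, 0, 0))   # toward the partner, |F| = FFG
  expect_equal(f$sticker[2, ], c(-2, 0, 0))
  # unbound stickers feel nothing
  st$sticker_state <- c(1L, 1L); st$partner <- c(0L, 0L)
  f <- npcflux:::cpp_forces(st)
  expect_equal(max(abs(f$sticker)), 0)
})

test_that("bare steric repulsion balances FFG at r = ln(eps_r/(sigma_r FFG))", {
  # the untruncated balance point of the attraction against the repulsion
  r_star <- uniroot(function(r) steric_force(r, truncated = FALSE) - 2,
                    c(1, 10), tol = 1e-10)$root
  expect_equal(r_star, log(400 / 2), tolerance = 1e-8)
  expect_equal(r_star, 5.30, tolerance = 1e-3)
})
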