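# structural diagnostics: Flory fits, mesh estimator, scaling check

test_that("flory_fit recovers exact power-law data to machine precision", {
  df <- data.frame(N = c(10, 30, 90, 270))
  df$R_mean <- 0.86 * df$N^0.588
  fit <- flory_fit(df)
  expect_equal(fit$nu_hat, 0.588, tolerance = 1e-12)
  expect_equal(fit$b_hat, 0.86, tolerance = 1e-12)
  expect_error(flory_fit(data.frame(N = c(10, 10, 10), R_mean = 1:3)),
               "distinct")
})

test_that("freely jointed chains reproduce ideal random-walk scaling", {
  # oracle: exact freely jointed ensembles with the same bond-length
  # statistics, at the same chain lengths (finite-size slope ~ 0.52)
  Ns <- c(8, 16, 24)
  set.seed(31)
  oracle <- do.call(rbind, lapply(Ns, function(N) {
    R <- replicate(4000, {
      r <- 1 + rnorm(N - 1, 0, sqrt(1 / 200))
      u <- matrix(rnorm((N - 1) * 3), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      sqrt(sum(colSums(u * r)^2))
    })
    data.frame(N = N, R_mean = mean(R))
  }))
  nu_oracle <- flory_fit(oracle)$nu_hat
  sim <- sample_chain_ensemble(Ns, n_replicas = 12, seed = 2,
                               steric = FALSE, bending = FALSE)
  nu_sim <- flory_fit(sim)$nu_hat
  expect_equal(nu_sim, nu_oracle, tolerance = 0.15) # |diff| < ~3 SE
  expect_equal(nu_oracle, 0.5, tolerance = 0.1)     # near the ideal exponent
})

test_that("self-avoiding chains show good-solvent statistics (nu > 1/2)", {
  sim <- sample_chain_ensemble(c(8, 16, 24), n_replicas = 6, seed = 5,
                               steric = TRUE, bending = TRUE)
  fit <- flory_fit(sim)
  expect_gt(fit$nu_hat - 2 * fit$nu_se, 0.5)
})

test_that("the mesh estimator recovers constructed and Poisson spacings", {
  # two straight parallel chains at a known spacing
  L <- 40; spacing <- 2.5
  n <- 12
  pos <- rbind(cbind(L/2 - spacing/2, L/2, L/2 + seq_len(n) - n/2),
               cbind(L/2 + spacing/2, L/2, L/2 + seq_len(n) - n/2))
  sys <- list(pos = pos, chain_id = rep(1:2, each = n),
              box = rep(L, 3), env = c(h = 20, D = 16, zc = L/2),
              units = c(sigma_nm = 1, dt_ns = 0.02))
  class(sys) <- "npc_system"
  est <- mesh_size_from_configurations(list(pos), sys)
  expect_equal(est$xi_hat, spacing, tolerance = 1e-6)
  # Poisson points: mean nearest-neighbour distance = 0.554 rho^(-1/3)
  set.seed(8)
  rho <- 0.25
  Lp <- 14
  npts <- rpois(1, rho * Lp^3)
  frames <- lapply(1:12, function(i)
    matrix(runif(3 * npts, (40 - Lp) / 2, (40 + Lp) / 2), ncol = 3))
  # centre filter (radius D/2 - 1, central 80% of h) sits two typical
  # nearest-neighbour distances inside the point cloud, so the oracle
  # comparison carries no edge bias from the cloud's finite extent
  sysp <- list(pos = frames[[1]], chain_id = seq_len(npts), # all distinct
               box = rep(40, 3), env = c(h = Lp - 2, D = Lp - 4, zc = 20),
               units = c(sigma_nm = 1, dt_ns = 0.02))
  class(sysp) <- "npc_system"
  est <- mesh_size_from_configurations(frames, sysp)
  expect_equal(est$xi_hat, 0.554 * rho^(-1/3), tolerance = 0.05)
})

test_that("scaling_check matches the analytic exponent on synthetic data", {
  p <- polymer_params(N = 209)
  sc <- reference_scales(p)
  D <- c(36, 40, 44, 50, 56, 60, 64)
  xi <- mesh_size(D, p)
  chk <- scaling_check(xi, D, sc)
  expect_equal(chk$slope, 2 * 0.588 / (3 * 0.588 - 1), tolerance = 1e-10)
  expect_equal(chk$theory_slope, 1.539, tolerance = 1e-3)
  expect_equal(chk$r_squared, 1, tolerance = 1e-12)
  # shuffled control: no relationship
  set.seed(3)
  chk0 <- scaling_check(sample(xi), D, sc)
  expect_lt(abs(chk0$slope), abs(chk$slope))
  expect_error(scaling_check(xi[1:2], D[1:2], sc), "3 distinct")
})

test_that("in-pore mesh size follows the pore diameter scaling", {
  # reduced systems at three pore diameters; the estimator's log-log slope
  # against D should be positive and near the semi-dilute exponent
  xs <- c()
  Ds <- c(10, 12.5, 15)
  for (D in Ds) {
    cfg <- npc_config(box = c(30, 30, 40), h = 6, D = D, N = 21, n_FG = 10,
                      equil_steps = 0)
    sys <- build_system(cfg, seed = 13)
    sys <- run_bd(sys, 6e4)
    out <- run_bd(sys, 4e4, traj_every = 4000)
    est <- mesh_size_from_configurations(attr(out, "frames"), sys)
    xs <- c(xs, est$xi_hat)
  }
  expect_true(all(diff(xs) > 0)) # mesh coarsens with dilation
  p <- polymer_params(N = 21, n_FG = 12, h = 6)
  chk <- scaling_check(xs, Ds, reference_scales(p))
  # desk-scale systems: slope positive and within a broad band of the
  # asymptotic 1.54 (small pores feel wall and finite-chain corrections)
  expect_gt(chk$slope, 0.5)
  expect_lt(chk$slope, 2.5)
})

test_that("mesh estimates agree between split halves of a run", {
  cfg <- npc_config(box = c(30, 30, 40), h = 6, D = 12, N = 21, n_FG = 10,
                    equil_steps = 0)
  sys <- build_system(cfg, seed = 17)
  sys <- run_bd(sys, 4e4)
  out <- run_bd(sys, 4e4, traj_every = 2500)
  fr <- attr(out, "frames")
  half <- length(fr) %/% 2
  e1 <- mesh_size_from_configurations(fr[1:half], sys)
  e2 <- mesh_size_from_configurations(fr[(half + 1):length(fr)], sys)
  expect_lt(abs(e1$xi_hat - e2$xi_hat),
            2 * sqrt(e1$xi_se^2 + e2$xi_se^2) + 1e-9)
})
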