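#' Advance the system by overdamped Langevin dynamics
#'
#' Integrates the Euler–Maruyama discretization of the overdamped Langevin
#' equation `zeta dr/dt = -dU/dr + Lambda`, with per-bead Stokes friction
#' `zeta = 3 pi eta sigma` and Gaussian noise of variance `2 zeta kBT` per
#' unit time. Cargo translation and rotation use the rigid-body frictions
#' of [make_cargo()]. In parallel with each step, the sticker state machine
#' (free-outside / free-inside / bound) is advanced by one kinetic Monte
#' Carlo sweep unless `kmc = FALSE`.
#'
#' @param system An `npc_system`.
#' @param n_steps Number of steps (each `dt` ns).
#' @param seed If given, the engine stream is re-derived from it; otherwise
#'   the system's current stream continues.
#' @param log_every Record energies/bound count/cargo z every so many steps
#'   (0 = off).
#' @param traj_every Record chain frames and cargo trajectory every so many
#'   steps (0 = off).
#' @param noise Set `FALSE` for deterministic (noise-free) integration, a
#'   test hook.
#' @param kmc Advance sticker binding kinetics (default `TRUE`).
#' @param pinned Optional logical vector: beads to hold fixed in addition
#'   to the anchors.
#' @return The updated `npc_system`, with attributes `log` (tibble, energies
#'   in kBT, step index in steps) and `frames` (list of sigma-unit position
#'   matrices) when recording was requested.
#' @export
run_bd <- function(system, n_steps, seed = NULL, log_every = 0,
                   traj_every = 0, noise = TRUE, kmc = TRUE, pinned = NULL) {
  stopifnot(inherits(system, "npc_system"))
  if (!is.null(seed)) system$rng <- derive_stream(seed, "dynamics")
  if (!is.null(pinned)) {
    stopifnot(length(pinned) == nrow(system$pos))
    system$pinned <- pinned
  }
  res <- cpp_run(as_engine_state(system),
                 list(mode = "plain", n_steps = n_steps, noise = noise,
                      kmc_on = kmc, log_every = log_every,
                      traj_every = traj_every,
                      record_chains = traj_every > 0))
  out <- update_system(system, res$state)
  if (!is.null(res$log)) attr(out, "log") <- log_tibble(res$log)
  if (!is.null(res$frames)) attr(out, "frames") <- res$frames
  if (!is.null(res$cargo_traj))
    attr(out, "cargo_traj") <- tibble::as_tibble(as.data.frame(res$cargo_traj))
  out
}

log_tibble <- function(m) tibble::as_tibble(as.data.frame(m))

#' Mean-squared displacement of a free bead ensemble
#'
#' Simulates `n_walkers` independent non-interacting beads and returns the
#' ensemble MSD versus lag time — the Einstein-relation check
#' `MSD(t) = 6 (kBT / zeta) t`.
#'
#' @param n_walkers Ensemble size.
#' @param n_steps Steps per walker.
#' @param seed Master seed.
#' @param eta Viscosity, reduced units.
#' @return A tibble with `step` and `msd` (sigma^2 units) plus the implied
#'   diffusion coefficient in the `diffusion` attribute (sigma^2 per step).
#' @export
free_bead_msd <- function(n_walkers = 200, n_steps = 1e4, seed = 1,
                          eta = 37.1) {
  L <- 1e6 # effectively unbounded: walkers never wrap or meet
  every <- max(1, round(n_steps / 100))
  batch <- 50 # keep the pair search trivial
  frames_all <- list()
  done <- 0L
  while (done < n_walkers) {
    nw <- min(batch, n_walkers - done)
    k <- ceiling(nw^(1 / 3))
    g <- (expand.grid(x = seq_len(k), y = seq_len(k), z = seq_len(k)) - 1) * 100
    start <- as.matrix(g[seq_len(nw), , drop = FALSE]) + L / 4
    st <- list(
      pos = start, chain_id = integer(nw),
      anchored = logical(nw), sticker = logical(nw), pinned = logical(nw),
      sticker_state = integer(nw), partner = integer(nw),
      box = rep(L, 3), env = c(h = 0, D = 0, zc = L / 2),
      ff = engine_ff(force_field(eta = eta)),
      kmc = c(rthre = 2, kon = 0, koff = 0, FFG = 0, bound_neighbor = 1),
      cargo = NULL, rng = derive_stream(seed, "msd", done))
    res <- cpp_run(st, list(mode = "plain", n_steps = n_steps, kmc_on = FALSE,
                            traj_every = every, record_chains = TRUE))
    frames_all[[length(frames_all) + 1L]] <- res$frames
    done <- done + nw
  }
  # time- and ensemble-averaged MSD at a ladder of lags
  n_fr <- length(frames_all[[1]])
  lags <- unique(round(seq(1, min(20, n_fr - 1), length.out = 10)))
  msd <- vapply(lags, function(lg) {
    tot <- 0; cnt <- 0
    for (fr in frames_all) {
      for (o in seq_len(n_fr - lg)) {
        d <- fr[[o + lg]] - fr[[o]]
        tot <- tot + sum(d^2); cnt <- cnt + nrow(d)
      }
    }
    tot / cnt
  }, 0)
  out <- tibble::tibble(step = lags * every, msd = msd)
  attr(out, "diffusion") <- unname(coef(lm(msd ~ 0 + step, data = out))[1] / 6)
  out
}
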