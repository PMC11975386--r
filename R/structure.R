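#' Simulate an ensemble of free chains and measure their size
#'
#' Runs isolated (un-anchored) bead-spring chains in a large periodic box
#' and records the end-to-end distance at regular intervals after a
#' burn-in. With steric repulsion on, the chains are self-avoiding and
#' should show good-solvent statistics (`R ~ N^nu`, `nu ~ 0.588`); with
#' `steric = FALSE` they are ideal random walks (`nu = 1/2`).
#'
#' @param N_values Chain lengths to simulate.
#' @param n_steps Steps per chain after burn-in; `NULL` scales as
#'   `240 N^2` (the slowest conformational mode relaxes on the entropic
#'   Rouse time `zeta b^2 N^2 / (3 pi^2 kBT)`, about `12 N^2` steps).
#' @param burn_in Equilibration steps discarded; `NULL` scales as `60 N^2`
#'   (several relaxation times; chains also start from random-walk
#'   conformations rather than straight lines).
#' @param sample_every Sampling interval; `NULL` scales as `12 N^2` (one
#'   relaxation time, so samples are roughly independent).
#' @param n_replicas Independent replicas per chain length.
#' @param seed Master seed.
#' @param steric Include steric repulsion (self-avoidance).
#' @param bending Include the bending term; `FALSE` gives a freely jointed
#'   chain, the ideal random-walk control with `nu = 1/2`.
#' @param kmc Advance sticker binding kinetics (stickers attract via the
#'   state machine; `FALSE` isolates pure chain statistics).
#' @param eta Viscosity, reduced units. The default is the standard medium;
#'   a larger value refines the effective time step relative to the
#'   stiffest bond modes, which the ideal-chain control uses to sample the
#'   exact freely jointed ensemble.
#' @return A tibble: `N`, `R_mean` (sigma units), `R_se`, `n_samples`.
#' @export
sample_chain_ensemble <- function(N_values = c(8, 16, 32),
                                  n_steps = NULL, burn_in = NULL,
                                  sample_every = NULL, n_replicas = 4,
                                  seed = 1, steric = TRUE, bending = TRUE,
                                  kmc = FALSE, eta = 37.1) {
  rows <- purrr::map(N_values, function(N) {
    ee <- unlist(purrr::map(seq_len(n_replicas), function(rep) {
      chain_end_to_end(N,
                       n_steps %||% ceiling(240 * N^2),
                       burn_in %||% ceiling(60 * N^2),
                       sample_every %||% ceiling(12 * N^2),
                       derive_stream(seed, paste0("chain", N), rep),
                       steric = steric, bending = bending, kmc = kmc,
                       eta = eta)
    }))
    tibble::tibble(N = N, R_mean = mean(ee),
                   R_se = sd(ee) / sqrt(length(ee)), n_samples = length(ee))
  })
  dplyr::bind_rows(rows)
}

chain_end_to_end <- function(N, n_steps, burn_in, sample_every, rng,
                             steric = TRUE, bending = TRUE, kmc = FALSE,
                             eta = 37.1) {
  L <- max(40, 4 * N) # box always dwarfs the chain extension
  # start from a random-walk conformation (near equilibrium), not a rod
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()),
          add = TRUE)
  set.seed(strtoi(substr(rng[1], 10, 16), 16L))
  u <- matrix(rnorm(3 * (N - 1)), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pos <- rbind(c(0, 0, 0), apply(u, 2, cumsum))
  pos <- sweep(pos, 2, colMeans(pos)) + L / 2
  ff <- force_field(eps_r = if (steric) 400 else 0,
                    ka = if (bending) 0.5 else 0, eta = eta)
  st <- list(
    pos = pos, chain_id = rep(1L, N), anchored = logical(N),
    sticker = if (kmc) sticker_mask(N) else logical(N), pinned = logical(N),
    sticker_state = integer(N), partner = integer(N),
    box = rep(L, 3), env = c(h = 0, D = 0, zc = L / 2),
    ff = engine_ff(ff),
    kmc = c(rthre = 2, kon = if (kmc) 2e-3 else 0,
            koff = if (kmc) 2e-4 else 0, FFG = 2, bound_neighbor = 1),
    cargo = NULL, rng = rng)
  res <- cpp_run(st, list(mode = "plain", n_steps = burn_in, kmc_on = kmc))
  res <- cpp_run(res$state, list(mode = "plain", n_steps = n_steps,
                                 kmc_on = kmc, traj_every = sample_every,
                                 record_chains = TRUE))
  vapply(res$frames, function(f) {
    # min-image end-to-end (box >> chain, so images never fold back)
    d <- f[N, ] - f[1, ]
    d <- d - round(d / L) * L
    sqrt(sum(d^2))
  }, 0)
}

#' Fit the Flory exponent from chain sizes
#'
#' Log-log ordinary least squares of mean end-to-end distance on chain
#' length: `R = b N^nu` gives slope `nu` and intercept `log(b)`.
#'
#' @param chain_sizes Data frame with columns `N` and `R_mean` (>= 3
#'   distinct chain lengths).
#' @return A tibble with `nu_hat`, `b_hat`, `r_squared` and standard
#'   errors.
#' @export
flory_fit <- function(chain_sizes) {
  df <- tibble::as_tibble(chain_sizes)
  stopifnot(all(c("N", "R_mean") %in% names(df)))
  if (length(unique(df$N)) < 3)
    stop("need at least 3 distinct chain lengths to fit the Flory exponent")
  if (any(df$R_mean <= 0) || any(df$N <= 0))
    stop("chain lengths and sizes must be positive")
  fit <- lm(log(R_mean) ~ log(N), data = df)
  # noiseless inputs fit perfectly; the summary warning is expected
  sm <- suppressWarnings(summary(fit))
  tibble::tibble(
    nu_hat = unname(coef(fit)[2]),
    nu_se = sm$coefficients[2, 2],
    b_hat = exp(unname(coef(fit)[1])),
    r_squared = sm$r.squared
  )
}

#' Mesh size from equilibrated in-pore configurations
#'
#' Estimates the correlation length of the in-pore FG-Nup solution as the
#' mean nearest-neighbour distance between beads of *different* chains.
#' Centre beads are restricted to a core pore region (radius `D/2 - sigma`,
#' central 80% of the height) to avoid wall artefacts; candidate
#' neighbours are unrestricted so beads at the core's edge are not biased.
#' The bootstrap standard error resamples whole snapshots.
#'
#' @param frames List of position matrices (sigma units), e.g. the
#'   `frames` attribute of [run_bd()].
#' @param system The `npc_system` the frames came from.
#' @param n_boot Bootstrap resamples.
#' @return A tibble with `xi_hat` (nm), `xi_se` (nm), `n_pairs`.
#' @export
mesh_size_from_configurations <- function(frames, system, n_boot = 200) {
  stopifnot(inherits(system, "npc_system"), length(frames) >= 1)
  if (max(system$chain_id) < 2) stop("mesh estimation needs at least 2 chains")
  s <- system$units[["sigma_nm"]]
  per_frame <- purrr::map_dbl(frames, function(f)
    frame_mesh_nn(f, system$chain_id, system$box, system$env))
  per_frame <- per_frame[is.finite(per_frame)]
  if (length(per_frame) == 0)
    stop("no frame had enough in-pore beads on distinct chains")
  boot <- vapply(seq_len(n_boot), function(b) {
    mean(per_frame[sample.int(length(per_frame), replace = TRUE)])
  }, 0)
  tibble::tibble(xi_hat = mean(per_frame) * s,
                 xi_se = sd(boot) * s,
                 n_frames = length(per_frame))
}

# mean inter-chain nearest-neighbour distance for beads in the pore core;
# candidate neighbours are unrestricted so core-edge beads carry no bias
frame_mesh_nn <- function(pos, chain_id, box, env) {
  zc <- env[["zc"]]; h <- env[["h"]]; D <- env[["D"]]
  dx <- pos[, 1] - box[1] / 2
  dy <- pos[, 2] - box[2] / 2
  keep <- (dx^2 + dy^2 <= (D / 2 - 1)^2) &
    (abs(pos[, 3] - zc) <= 0.4 * h)
  if (sum(keep) < 1) return(NA_real_)
  ctr <- pos[keep, , drop = FALSE]
  id <- chain_id[keep]
  if (length(unique(chain_id)) < 2) return(NA_real_)
  # cross-distances centre beads -> all beads (core far from the boundary)
  d2 <- outer(rowSums(ctr^2), rowSums(pos^2), `+`) - 2 * ctr %*% t(pos)
  dm <- sqrt(pmax(d2, 0)) # pmax keeps the first argument's dim attributes
  dm[outer(id, chain_id, `==`)] <- Inf
  nn <- apply(dm, 1, min)
  mean(nn[is.finite(nn)])
}

#' Mesh-size vs pore-diameter scaling check
#'
#' Fits `log(xi / xi_star)` against `log(D / D_star)`; the scaling
#' prediction is a slope of `2 nu / (3 nu - 1)` (about 1.54 for
#' `nu = 0.588`).
#'
#' @param xi_hats Measured mesh sizes, nm.
#' @param D_values Corresponding pore diameters, nm (>= 3 distinct).
#' @param scales Reference scales from [reference_scales()].
#' @return A tibble with `slope`, `slope_se`, `intercept`, `r_squared` and
#'   the `theory_slope`.
#' @export
scaling_check <- function(xi_hats, D_values, scales) {
  if (length(xi_hats) != length(D_values))
    stop("xi_hats and D_values must have equal length")
  if (length(unique(D_values)) < 3)
    stop("need at least 3 distinct pore diameters")
  lx <- log(xi_hats / scales$xi_star)
  ld <- log(D_values / scales$D_star)
  fit <- lm(lx ~ ld)
  sm <- suppressWarnings(summary(fit)) # synthetic inputs may fit perfectly
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    slope_se = sm$coefficients[2, 2],
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    theory_slope = 2 / scales$alpha # 2 nu / (3 nu - 1)
  )
}
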