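#' Discretize a sphere surface into beads
#'
#' Places beads quasi-uniformly on a sphere of diameter `d` using a
#' Fibonacci (golden-spiral) lattice with an areal density of one bead per
#' `sigma^2`, so the bead count is `round(pi * (d/sigma)^2)`. A cargo no
#' larger than one bead (`d <= sigma`) degenerates to a single interaction
#' site at the centre.
#'
#' @param d Sphere diameter, nm.
#' @param sigma Bead diameter, nm.
#' @return Matrix of body-frame bead coordinates (sigma units), rows on the
#'   sphere of radius `d / (2 sigma)`.
#' @export
discretize_surface <- function(d, sigma = 0.86) {
  if (d < 0) stop("cargo diameter must be non-negative")
  dr <- d / sigma
  if (dr <= 1) return(matrix(0, 1, 3))
  n <- max(1L, as.integer(round(pi * dr^2)))
  i <- seq_len(n) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  th <- golden * (seq_len(n) - 1)
  (dr / 2) * cbind(rho * cos(th), rho * sin(th), z)
}

#' Create a rigid spherical cargo
#'
#' The transported molecule: a rigid sphere of diameter `d` whose surface is
#' discretized into beads ([discretize_surface()]). A spherical cap of area
#' `S = S_over_Sstar * 4 pi` nm^2 around the body-frame +z pole is flagged
#' as stickers ([assign_sticker_patch()]); those beads take part in the same
#' binding state machine as FG-Nup stickers. Translational and rotational
#' mobilities follow Stokes' law for a sphere of diameter `d`:
#' `zeta_t = 3 pi eta d`, `zeta_rot = pi eta d^3`.
#'
#' @param d Cargo diameter, nm.
#' @param S_over_Sstar Sticker patch area in units of `S* = 4 pi nm^2`.
#' @param sigma Bead diameter, nm.
#' @param eta Medium viscosity, reduced units (kBT dt / sigma^3).
#' @return An object of class `npc_cargo` (all lengths in sigma units;
#'   `d_nm` and `S_nm2` keep the physical values).
#' @examples
#' cg <- make_cargo(5, S_over_Sstar = 1)
#' nrow(cg$body)
#' @export
make_cargo <- function(d, S_over_Sstar = 0, sigma = 0.86, eta = 37.1) {
  if (d <= 0) stop("cargo diameter must be positive")
  body <- discretize_surface(d, sigma)
  dr <- d / sigma
  cargo <- structure(list(
    center = c(0, 0, 0),
    quat = c(1, 0, 0, 0),
    body = body,
    sticker = rep(FALSE, nrow(body)),
    d = dr,
    d_nm = d,
    S_nm2 = 0,
    zeta_t = 3 * pi * eta * dr,
    zeta_rot = pi * eta * dr^3
  ), class = "npc_cargo")
  assign_sticker_patch(cargo, S_over_Sstar * 4 * pi, sigma = sigma)
}

#' Flag a spherical cap of the cargo surface as stickers
#'
#' Beads within the cap of area `S` around the body-frame +z pole become
#' stickers. The cap half-angle solves `2 pi (d/2)^2 (1 - cos theta_c) = S`.
#'
#' @param cargo An `npc_cargo`.
#' @param S Patch area in nm^2 (0 = inert; `pi d^2` = whole sphere).
#' @param sigma Bead diameter in nm (to convert the stored sigma-unit radius).
#' @return The cargo with updated sticker flags and cap geometry.
#' @export
assign_sticker_patch <- function(cargo, S, sigma = 0.86) {
  stopifnot(inherits(cargo, "npc_cargo"))
  if (S < 0) stop("patch area must be non-negative")
  r_nm <- cargo$d_nm / 2
  if (S > 4 * pi * r_nm^2 + 1e-9)
    stop("patch area exceeds the sphere surface area")
  cargo$S_nm2 <- S
  if (S == 0) {
    cargo$sticker <- rep(FALSE, nrow(cargo$body))
    cargo$theta_c <- 0
    return(cargo)
  }
  cos_th <- 1 - S / (2 * pi * r_nm^2)
  cargo$theta_c <- acos(max(-1, min(1, cos_th)))
  if (nrow(cargo$body) == 1 && all(cargo$body == 0)) {
    cargo$sticker <- TRUE # single-site cargo: the whole bead is the patch
    return(cargo)
  }
  r_sig <- cargo$d / 2
  cargo$sticker <- cargo$body[, 3] / r_sig >= cos_th - 1e-12
  cargo
}

#' Aggregate per-bead forces into a net force and torque
#'
#' `F = sum f_i`, `tau = sum (r_i - center) x f_i` over the cargo's surface
#' beads in their current world-frame positions.
#'
#' @param cargo An `npc_cargo` (with current `center` and `quat`).
#' @param bead_forces Matrix (n_beads x 3) of forces on the surface beads.
#' @return List with `force` and `torque` (3-vectors).
#' @export
accumulate_force_torque <- function(cargo, bead_forces) {
  stopifnot(inherits(cargo, "npc_cargo"),
            nrow(bead_forces) == nrow(cargo$body))
  w <- cargo_world_beads(cargo)
  arms <- sweep(w, 2, cargo$center)
  torque <- colSums(cbind(
    arms[, 2] * bead_forces[, 3] - arms[, 3] * bead_forces[, 2],
    arms[, 3] * bead_forces[, 1] - arms[, 1] * bead_forces[, 3],
    arms[, 1] * bead_forces[, 2] - arms[, 2] * bead_forces[, 1]))
  list(force = colSums(bead_forces), torque = torque)
}

#' World-frame positions of the cargo surface beads
#'
#' @param cargo An `npc_cargo`.
#' @return n_beads x 3 matrix, sigma units.
#' @export
cargo_world_beads <- function(cargo) {
  R <- quat_to_matrix(cargo$quat)
  sweep(cargo$body %*% t(R), 2, cargo$center, `+`)
}

#' Rotation matrix of a unit quaternion
#'
#' @param q Quaternion `c(w, x, y, z)`.
#' @return 3 x 3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Simulate a free cargo (no chains, no walls)
#'
#' Integrates the translational and rotational Brownian motion of an
#' isolated cargo in a large periodic box — the reference case for checking
#' the Einstein relation and the rotational decorrelation
#' `<u(0).u(t)> = exp(-2 D_r t)`.
#'
#' @param d Cargo diameter, nm.
#' @param n_steps Number of integration steps.
#' @param seed Seed for the engine stream.
#' @param traj_every Sampling interval for the returned trajectory.
#' @param box_nm Box edge, nm (must dwarf the diffusive excursion).
#' @param sigma,dt,eta Unit and medium constants.
#' @return A tibble: `step`, centre coordinates (`x`, `y`, `z`, nm,
#'   unwrapped), quaternion and the world-frame body axis (`ux`, `uy`, `uz`).
#' @export
simulate_free_cargo <- function(d, n_steps, seed = 1, traj_every = 10,
                                box_nm = 5000, sigma = 0.86, dt = 0.02,
                                eta = 37.1) {
  cargo <- make_cargo(d, 0, sigma = sigma, eta = eta)
  L <- box_nm / sigma
  cargo$center <- c(L / 2, L / 2, L / 2)
  st <- list(
    pos = matrix(0, 0, 3), chain_id = integer(), anchored = logical(),
    sticker = logical(), pinned = logical(),
    sticker_state = integer(nrow(cargo$body)),
    partner = integer(nrow(cargo$body)),
    box = rep(L, 3), env = c(h = 0, D = 0, zc = L / 2),
    ff = engine_ff(force_field(eta = eta)),
    kmc = c(rthre = 2, kon = 0, koff = 0, FFG = 0, bound_neighbor = 1),
    cargo = cargo, rng = derive_stream(seed, "free_cargo"))
  res <- cpp_run(st, list(mode = "plain", n_steps = n_steps,
                          traj_every = traj_every, kmc_on = FALSE))
  tr <- tibble::as_tibble(as.data.frame(res$cargo_traj))
  # unwrap the periodic centre coordinates for MSD analysis
  for (cl in c("x", "y", "z")) {
    v <- tr[[cl]]
    jump <- c(0, diff(v))
    jump <- ifelse(jump > L / 2, -L, ifelse(jump < -L / 2, L, 0))
    tr[[cl]] <- (v + cumsum(jump)) * sigma
  }
  tr
}

#' Attach a cargo to an existing system
#'
#' Adds (or replaces) the rigid cargo of an `npc_system`, e.g. to reuse one
#' equilibrated chain configuration for several cargo sizes. The cargo is
#' placed on the pore axis above the entrance; rate calculations re-place
#' it randomly in basin A.
#'
#' @param system An `npc_system`.
#' @param d Cargo diameter, nm.
#' @param S_over_Sstar Attractive patch area in units of `S* = 4 pi nm^2`.
#' @return The system with the cargo attached and the binding registry
#'   reset to unbound for all stickers.
#' @export
attach_cargo <- function(system, d, S_over_Sstar = 0) {
  stopifnot(inherits(system, "npc_system"))
  s <- system$units[["sigma_nm"]]
  cargo <- make_cargo(d, S_over_Sstar = S_over_Sstar, sigma = s,
                      eta = system$ff[["eta"]])
  cargo$center <- c(system$box[1] / 2, system$box[2] / 2,
                    system$env[["zc"]] + system$env[["h"]] / 2 +
                      system$env[["D"]] / 2 + cargo$d / 2 + 1)
  system$cargo <- cargo
  n_tot <- nrow(system$pos) + nrow(cargo$body)
  system$sticker_state <- integer(n_tot)
  system$partner <- integer(n_tot)
  system
}
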