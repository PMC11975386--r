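#' Force-field parameters of the coarse-grained model
#'
#' The standard parameter set of the bead-spring model, in reduced units
#' (lengths in bead diameters sigma, energies in kBT, times in integration
#' steps dt). Defaults:
#' harmonic bonds `U = kb (r - req)^2` with `kb = 100 kBT/sigma^2`,
#' `req = 1 sigma`; bending `U = ka (1 - cos(theta - theta_eq))` with
#' `ka = 0.5 kBT`, `theta_eq = pi`; exponential steric repulsion
#' `U = eps_r exp(-r / sigma_r)` truncated at `r_cri` with
#' `eps_r = 400 kBT`, `sigma_r = r_cri = 1 sigma`; constant hard-surface
#' force `F_wall = 400 kBT/sigma`; medium viscosity
#' `eta = 37.1 kBT dt / sigma^3` (5.0 cP at 310.15 K for sigma = 0.86 nm,
#' dt = 0.02 ns), giving a per-bead Stokes friction `zeta = 3 pi eta sigma`.
#'
#' @param ... Named overrides of any default (reduced units), e.g.
#'   `eps_r = 0` to switch off steric repulsion in a test system.
#' @return Named numeric vector of class `npc_force_field`.
#' @examples
#' force_field()
#' force_field(eps_r = 0)
#' @export
force_field <- function(...) {
  ff <- c(kb = 100, req = 1, ka = 0.5, theta_eq = pi,
          eps_r = 400, sigma_r = 1, r_cri = 1, F_wall = 400,
          eta = 37.1)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), c(names(ff), "zeta"))
    if (length(bad)) stop("unknown force-field parameter(s): ",
                          paste(bad, collapse = ", "))
    for (nm in names(over)) ff[nm] <- over[[nm]]
  }
  if (!"zeta" %in% names(ff) || is.na(ff["zeta"]))
    ff["zeta"] <- 3 * pi * ff[["eta"]] * 1 # Stokes friction of a 1-sigma bead
  if (any(ff[c("kb", "eps_r", "sigma_r", "r_cri", "eta", "zeta")] < 0))
    stop("force-field parameters must be non-negative")
  structure(ff, class = "npc_force_field")
}

#' Pairwise potentials and forces in closed form
#'
#' Scalar closed forms of the bead-bead interactions, for inspection and for
#' validating the engine: the truncated exponential repulsion
#' `U(r) = eps_r exp(-r/sigma_r)` below the cutoff `r_cri` (constant beyond, so the
#' force vanishes there), the harmonic bond `U = kb (r - req)^2`, and the
#' bending term `U = ka (1 - cos(theta - theta_eq))`.
#'
#' @param r Separation(s), sigma units.
#' @param theta Angle(s), radians.
#' @param eps_r,sigma_r,r_cri,kb,req,ka,theta_eq Parameters as in
#'   [force_field()].
#' @param truncated If `FALSE`, ignore the cutoff (the untruncated
#'   exponential), e.g. to locate where bare repulsion balances an applied
#'   force.
#' @return Energy in kBT, or force magnitude in kBT/sigma
#'   (`steric_force()` is the repulsive magnitude, zero beyond the cutoff
#'   when truncated).
#' @name pair_potentials
NULL

#' @rdname pair_potentials
#' @export
steric_potential <- function(r, eps_r = 400, sigma_r = 1, r_cri = 1,
                             truncated = TRUE) {
  u <- eps_r * exp(-pmin(if (truncated) pmax(r, 0) else r, Inf) / sigma_r)
  if (truncated) u[r >= r_cri] <- eps_r * exp(-r_cri / sigma_r)
  u
}

#' @rdname pair_potentials
#' @export
steric_force <- function(r, eps_r = 400, sigma_r = 1, r_cri = 1,
                         truncated = TRUE) {
  f <- eps_r / sigma_r * exp(-r / sigma_r)
  if (truncated) f[r >= r_cri] <- 0
  f
}

#' @rdname pair_potentials
#' @export
bond_potential <- function(r, kb = 100, req = 1) kb * (r - req)^2

#' @rdname pair_potentials
#' @export
angle_potential <- function(theta, ka = 0.5, theta_eq = pi)
  ka * (1 - cos(theta - theta_eq))
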