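#' Build a coarse-grained NPC particle system
#'
#' Constructs the simulation state: a periodic box containing a hard
#' envelope slab with a cylindrical pore, `n_FG` bead-spring chains anchored
#' on the pore's inner wall, and (optionally) a rigid cargo. Anchors are
#' arranged on `n_rings` rings spread evenly over the pore height and
#' staggered azimuthally between adjacent rings, mimicking the pore's ring
#' symmetry. Each chain is grown as an anchored random walk with unit bond
#' length, rejecting steps that penetrate the envelope. The first (anchored)
#' bead is held fixed on the wall. Stickers follow the periodic pattern of
#' the configuration: with period 4, beads 4, 8, 12, ... of each chain (one
#' sticker after three spacers; the anchor is a spacer).
#'
#' Positions are stored internally in sigma units; the object's `units`
#' field carries the nm/ns conversions.
#'
#' @param config An [npc_config()].
#' @param seed Build seed (defaults to the config's seed). The build uses a
#'   stream derived from it and does not disturb R's global RNG.
#' @return An object of class `npc_system`.
#' @examples
#' sys <- build_system(npc_config(N = 9, n_FG = 4, box = c(30, 30, 60),
#'                                h = 8, D = 12))
#' @export
build_system <- function(config, seed = NULL) {
  stopifnot(inherits(config, "npc_config"))
  if (is.null(seed)) seed <- config$seed
  s <- config$sigma
  box <- config$box / s
  h <- config$h / s
  D <- config$D / s
  zc <- box[3] / 2
  N <- config$N
  n_FG <- config$n_FG

  n_rings <- config$n_rings %||% pick_n_rings(n_FG)
  per_ring <- n_FG / n_rings
  if (pi * D / per_ring < 1)
    stop("geometry too small: ", per_ring, " anchors per ring do not fit on ",
         "a pore of diameter ", config$D, " nm")

  # deterministic local RNG; restore the caller's state afterwards
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(strtoi(substr(derive_stream(seed, "build")[1], 10, 16), 16L))

  ring_z <- zc - h / 2 + (seq_len(n_rings) - 0.5) * h / n_rings
  pos <- matrix(0, N * n_FG, 3)
  chain_id <- rep(seq_len(n_FG), each = N)
  anchored <- rep(FALSE, N * n_FG)
  sticker <- rep(sticker_mask(N, config$sticker_period), n_FG)

  ci <- 0L
  for (ring in seq_len(n_rings)) {
    for (k in seq_len(per_ring)) {
      ci <- ci + 1L
      phi <- 2 * pi * (k - 1) / per_ring +
        (ring - 1) * pi / per_ring # azimuthal stagger between rings
      anchor <- c(box[1] / 2 + D / 2 * cos(phi),
                  box[2] / 2 + D / 2 * sin(phi),
                  ring_z[ring])
      rows <- (ci - 1L) * N + seq_len(N)
      pos[rows, ] <- grow_chain(anchor, N, box, c(h, D, zc))
      anchored[rows[1]] <- TRUE
    }
  }

  cargo <- NULL
  if (!is.null(config$cargo_d)) {
    cargo <- make_cargo(config$cargo_d,
                        S_over_Sstar = config$cargo_S_over_Sstar,
                        sigma = s, eta = config$ff[["eta"]])
    cargo$center <- c(box[1] / 2, box[2] / 2,
                      zc + h / 2 + D / 2 + cargo$d / 2 + 1)
  }

  n_tot <- nrow(pos) + if (is.null(cargo)) 0L else nrow(cargo$body)
  structure(list(
    pos = pos,
    chain_id = as.integer(chain_id),
    anchored = anchored,
    sticker = sticker,
    pinned = rep(FALSE, nrow(pos)),
    sticker_state = integer(n_tot),
    partner = integer(n_tot),
    box = box,
    env = c(h = h, D = D, zc = zc),
    ff = engine_ff(config$ff),
    kmc = c(rthre = config$rthre, kon = config$kon, koff = config$koff,
            FFG = config$FFG, bound_neighbor = as.numeric(config$bound_neighbor)),
    cargo = cargo,
    rng = derive_stream(seed, "dynamics"),
    units = c(sigma_nm = s, dt_ns = config$dt),
    config = config
  ), class = "npc_system")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# divisor of n_FG whose per-ring count is closest to 10 (80 -> 8 rings of 10)
pick_n_rings <- function(n_FG) {
  div <- which(n_FG %% seq_len(n_FG) == 0)
  div[which.min(abs(n_FG / div - 10))]
}

#' Sticker mask of a chain
#'
#' With period `p`, 0-based bead `i` is a sticker iff `i %% p == p - 1`:
#' one sticker after `p - 1` spacers, anchored bead a spacer.
#'
#' @param N Beads in the chain.
#' @param period Sticker periodicity (default 4).
#' @return Logical vector of length `N`.
#' @export
sticker_mask <- function(N, period = 4) {
  (seq_len(N) - 1) %% period == period - 1
}

# anchored random walk growth with envelope rejection (sigma units)
grow_chain <- function(anchor, N, box, env, max_try = 60) {
  pos <- matrix(0, N, 3)
  pos[1, ] <- anchor
  # initial direction: radially inward
  dir <- c(box[1] / 2 - anchor[1], box[2] / 2 - anchor[2], 0)
  dir <- dir / sqrt(sum(dir^2))
  for (i in 2:N) {
    placed <- FALSE
    for (try in seq_len(max_try)) {
      prop_dir <- dir + (0.6 + 0.1 * try) * rnorm(3)
      prop_dir <- prop_dir / sqrt(sum(prop_dir^2))
      cand <- pos[i - 1, ] + prop_dir
      w <- cpp_wall_probe(c(wrap_coord(cand[1], box[1]),
                            wrap_coord(cand[2], box[2]),
                            wrap_coord(cand[3], box[3])), box, env)
      if (is.na(w[1]) || w[1] > 0.35) {
        pos[i, ] <- cand
        dir <- prop_dir
        placed <- TRUE
        break
      }
    }
    if (!placed) { # fall back: step along the pore axis away from the wall
      pos[i, ] <- pos[i - 1, ] + c(0, 0, sample(c(-1, 1), 1))
      dir <- c(0, 0, sign(pos[i, 3] - pos[i - 1, 3]))
    }
    pos[i, ] <- vapply(1:3, function(k) wrap_coord(pos[i, k], box[k]), 0)
  }
  pos
}

wrap_coord <- function(x, L) ((x %% L) + L) %% L

engine_ff <- function(ff) {
  v <- unclass(ff)
  v[c("kb", "req", "ka", "theta_eq", "eps_r", "sigma_r", "r_cri",
      "F_wall", "eta", "zeta")]
}

#' @export
print.npc_system <- function(x, ...) {
  n <- nrow(x$pos)
  cat("Coarse-grained NPC system\n")
  cat(sprintf("  %d chain beads in %d chains (%d stickers), %d anchors\n",
              n, max(c(0, x$chain_id)), sum(x$sticker), sum(x$anchored)))
  cat(sprintf("  box %.1f x %.1f x %.1f sigma; pore D = %.1f sigma, h = %.1f sigma\n",
              x$box[1], x$box[2], x$box[3], x$env[["D"]], x$env[["h"]]))
  if (!is.null(x$cargo))
    cat(sprintf("  cargo: d = %.2f sigma (%d surface beads, %d stickers)\n",
                x$cargo$d, nrow(x$cargo$body), sum(x$cargo$sticker)))
  cat(sprintf("  bound stickers: %d\n", sum(x$sticker_state == 2L)))
  invisible(x)
}

#' Per-term forces and energies of the current configuration
#'
#' Evaluates the force field without advancing dynamics: bond, angle, steric
#' (shifted so the reported pair energy is continuous at the cutoff), wall
#' and bound-sticker terms. Forces are returned for every bead — chain beads
#' first, then cargo surface beads.
#'
#' @param system An `npc_system`.
#' @return List with `forces` (list of (n+m) x 3 matrices per term, kBT/sigma)
#'   and `energy` (named vector, kBT).
#' @export
compute_forces <- function(system) {
  stopifnot(inherits(system, "npc_system"))
  res <- cpp_forces(as_engine_state(system))
  list(forces = res[c("bond", "angle", "steric", "wall", "sticker")],
       energy = res$energy)
}

as_engine_state <- function(system) {
  st <- unclass(system)
  st$sticker_state <- as.integer(st$sticker_state)
  st$partner <- as.integer(st$partner)
  st
}

update_system <- function(system, state) {
  system$pos <- state$pos
  system$sticker_state <- as.integer(state$sticker_state)
  system$partner <- as.integer(state$partner)
  system$rng <- as.character(state$rng)
  if (!is.null(system$cargo) && !is.null(state$cargo)) {
    system$cargo$center <- as.numeric(state$cargo$center)
    system$cargo$quat <- as.numeric(state$cargo$quat)
  }
  system
}

# install a stored FFS snapshot into a system
apply_snapshot <- function(system, snap) {
  system$pos <- snap$pos
  system$sticker_state <- as.integer(snap$sticker_state)
  system$partner <- as.integer(snap$partner)
  if (!is.null(system$cargo)) {
    system$cargo$center <- as.numeric(snap$center)
    system$cargo$quat <- as.numeric(snap$quat)
  }
  system
}
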