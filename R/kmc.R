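#' Classify free stickers as free-outside or free-inside
#'
#' A free sticker with at least one other sticker within `rthre` of its
#' centre is free-inside (FI, eligible to bind); with none it is
#' free-outside (FO). Bound (B) stickers keep their state; whether they
#' count as neighbours of free stickers is controlled by the configuration's
#' `bound_neighbor` switch (default: they do). Stickers on the same rigid
#' cargo never count for each other. The FO <-> FI transition is purely
#' diffusive; FO <-> B transitions never occur.
#'
#' @param system An `npc_system`.
#' @return Character vector over all stickers' global bead indices:
#'   `"FO"`, `"FI"` or `"B"`, named by bead index (chain beads first, then
#'   cargo surface beads).
#' @export
classify_free_states <- function(system) {
  stopifnot(inherits(system, "npc_system"))
  st <- cpp_classify(as_engine_state(system))
  mask <- sticker_mask_global(system)
  states <- c("FO", "FI", "B")[st$sticker_state + 1L]
  setNames(states[mask], which(mask))
}

sticker_mask_global <- function(system) {
  c(system$sticker,
    if (!is.null(system$cargo)) system$cargo$sticker else logical())
}

#' One kinetic Monte Carlo sweep of sticker binding
#'
#' Without moving any bead: reclassify free stickers (FO/FI), draw
#' unbinding for each bound pair with probability `koff`, then draw binding
#' with probability `kon` for every eligible FI-FI pair within `rthre`, so
#' an isolated pair binds with mean waiting time `1/kon` steps. Each sticker
#' binds at most one partner; the partner map stays an involution.
#'
#' @param system An `npc_system`.
#' @return The updated system.
#' @export
kmc_update <- function(system) {
  stopifnot(inherits(system, "npc_system"))
  update_system(system, cpp_kmc_step(as_engine_state(system)))
}

#' Constant attraction between bound sticker pairs
#'
#' Every bound sticker receives a force of magnitude `FFG` directed at its
#' partner (minimum-image). Pair forces are antisymmetric; a pair at zero
#' separation is skipped (and counted) because its direction is undefined.
#'
#' @param system An `npc_system`.
#' @return (n + m) x 3 matrix of forces, kBT/sigma.
#' @export
bound_pair_forces <- function(system) {
  stopifnot(inherits(system, "npc_system"))
  cpp_forces(as_engine_state(system))$sticker
}

#' Bound-lifetime sample from an isolated sticker pair
#'
#' Holds two stickers at a fixed separation inside the binding radius and
#' runs only the binding state machine, recording how long each bound
#' episode lasts. Lifetimes are geometrically distributed with mean
#' `1 / koff` steps; waiting times to bind have mean `1 / kon`.
#'
#' @param n_events Number of unbinding events to collect.
#' @param separation Fixed pair separation, sigma units (< `rthre`).
#' @param kon,koff Per-step rates.
#' @param seed Engine stream seed.
#' @return A tibble with columns `bound_steps` and `free_steps` (lifetime of
#'   each bound episode and the preceding free episode).
#' @export
sample_bond_lifetimes <- function(n_events = 1000, separation = 1.5,
                                  kon = 2e-3, koff = 2e-4, seed = 1) {
  L <- 50
  pos <- rbind(c(L / 2, L / 2, L / 2),
               c(L / 2 + separation, L / 2, L / 2))
  st <- list(
    pos = pos, chain_id = c(0L, 0L), anchored = c(TRUE, TRUE),
    sticker = c(TRUE, TRUE), pinned = c(TRUE, TRUE),
    sticker_state = integer(2), partner = integer(2),
    box = rep(L, 3), env = c(h = 0, D = 0, zc = L / 2),
    ff = engine_ff(force_field()),
    kmc = c(rthre = 2, kon = kon, koff = koff, FFG = 0, bound_neighbor = 1),
    cargo = NULL, rng = derive_stream(seed, "lifetimes"))
  bound <- integer(0); free <- integer(0)
  state <- st
  # advance in blocks; episode lengths via run-length encoding with carry
  block <- as.integer(max(2e4, round(4 / koff)))
  cur_state <- FALSE; cur_len <- 0L
  while (length(bound) < n_events) {
    res <- cpp_run(state, list(mode = "plain", n_steps = block, noise = FALSE,
                               kmc_on = TRUE, log_every = 1))
    state <- res$state
    r <- rle(res$log[, "n_bound"] > 0)
    for (i in seq_along(r$values)) {
      if (r$values[i] == cur_state) {
        cur_len <- cur_len + r$lengths[i]
      } else {
        if (cur_len > 0L) {
          if (cur_state) bound <- c(bound, cur_len) else free <- c(free, cur_len)
        }
        cur_state <- r$values[i]
        cur_len <- r$lengths[i]
      }
    }
  }
  tibble::tibble(
    bound_steps = bound[seq_len(min(n_events, length(bound)))],
    free_steps = free[seq_len(min(n_events, length(free)))])
}
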