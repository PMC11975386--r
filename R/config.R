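#' Run configuration for the coarse-grained NPC simulator
#'
#' Collects everything a run needs: box and envelope geometry, chain layout,
#' cargo, force-field overrides, sticker-binding kinetics and forward-flux
#' settings. Defaults reproduce the standard parameter set of the model:
#' a 100 x 100 x 200 nm periodic box, a 40 nm-thick envelope with a 40 nm
#' pore, 80 FG-Nup chains of 209 beads with one sticker per three spacers,
#' bead diameter 0.86 nm and time step 0.02 ns.
#'
#' @param box Box lengths `c(Lx, Ly, Lz)` in nm (periodic in all axes).
#' @param h Envelope thickness / pore height, nm.
#' @param D Pore diameter, nm; must be smaller than `min(Lx, Ly)`.
#' @param N Beads per FG-Nup chain.
#' @param n_FG Number of chains anchored to the pore wall.
#' @param n_rings Number of anchor rings spread over the pore height;
#'   `NULL` picks the divisor of `n_FG` giving closest to 10 anchors per
#'   ring (80 chains -> 8 rings of 10).
#' @param sticker_period Chain periodicity of stickers; the default 4 places
#'   one sticker after every three spacers (0-based bead `i` is a sticker
#'   iff `i %% 4 == 3`, so the anchored bead is a spacer).
#' @param cargo_d Cargo diameter in nm, or `NULL` for a chains-only system.
#' @param cargo_S_over_Sstar Attractive patch area in units of
#'   `S* = 4 pi nm^2` (0 = inert cargo).
#' @param ff A [force_field()] object (reduced units).
#' @param rthre Sticker neighbourhood distance for the free-outside /
#'   free-inside classification, sigma units.
#' @param kon,koff Sticker binding/unbinding probabilities per step.
#' @param FFG Constant attraction between bound stickers, kBT/sigma.
#' @param bound_neighbor Whether bound stickers count as neighbours when
#'   classifying other stickers as free-inside.
#' @param n_ffs Number of cylindrical slabs for forward flux sampling.
#' @param n_trials Trials per FFS interface.
#' @param flux_min_crossings Stop the flux phase after this many entry
#'   crossings.
#' @param flux_max_steps Cap on flux-phase length, steps.
#' @param equil_steps Chain equilibration length before measurements, steps.
#' @param seed Master seed; all streams are derived from it.
#' @param sigma Bead diameter in nm (the internal length unit).
#' @param dt Integration step in ns (the internal time unit).
#' @return An object of class `npc_config` (a validated named list).
#' @examples
#' cfg <- npc_config(D = 40, cargo_d = 6)
#' @export
npc_config <- function(box = c(100, 100, 200), h = 40, D = 40,
                       N = 209, n_FG = 80, n_rings = NULL, sticker_period = 4,
                       cargo_d = NULL, cargo_S_over_Sstar = 0,
                       ff = force_field(),
                       rthre = 2, kon = 2e-3, koff = 2e-4, FFG = 2,
                       bound_neighbor = TRUE,
                       n_ffs = 8, n_trials = 500,
                       flux_min_crossings = 100, flux_max_steps = 5e7,
                       equil_steps = 1e6, seed = 1,
                       sigma = 0.86, dt = 0.02) {
  cfg <- list(box = as.numeric(box), h = h, D = D, N = as.integer(N),
              n_FG = as.integer(n_FG), n_rings = n_rings,
              sticker_period = as.integer(sticker_period),
              cargo_d = cargo_d, cargo_S_over_Sstar = cargo_S_over_Sstar,
              ff = ff, rthre = rthre, kon = kon, koff = koff, FFG = FFG,
              bound_neighbor = isTRUE(bound_neighbor),
              n_ffs = as.integer(n_ffs), n_trials = as.integer(n_trials),
              flux_min_crossings = flux_min_crossings,
              flux_max_steps = flux_max_steps,
              equil_steps = equil_steps, seed = seed,
              sigma = sigma, dt = dt)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(length(cfg$box) == 3 && all(cfg$box > 0), "box must be 3 positive lengths")
  chk(cfg$h > 0, "envelope thickness h must be positive")
  chk(cfg$D > 0, "pore diameter D must be positive")
  chk(cfg$D < min(cfg$box[1:2]), "pore diameter D must be < min(Lx, Ly)")
  chk(cfg$h < cfg$box[3], "envelope thickness h must be < Lz")
  chk(cfg$N >= 2, "chain length N must be >= 2")
  chk(cfg$n_FG >= 1, "n_FG must be >= 1")
  chk(cfg$sticker_period >= 2, "sticker_period must be >= 2")
  chk(is.null(cfg$cargo_d) || cfg$cargo_d > 0, "cargo_d must be positive")
  chk(cfg$cargo_S_over_Sstar >= 0, "cargo_S_over_Sstar must be >= 0")
  chk(inherits(cfg$ff, "npc_force_field"), "ff must be a force_field()")
  chk(cfg$rthre > 0, "rthre must be positive")
  chk(cfg$kon >= 0 && cfg$kon <= 1, "kon must be a per-step probability")
  chk(cfg$koff >= 0 && cfg$koff <= 1, "koff must be a per-step probability")
  chk(cfg$FFG >= 0, "FFG must be >= 0")
  chk(cfg$n_ffs >= 1, "n_ffs must be >= 1")
  chk(cfg$n_trials >= 0, "n_trials must be >= 0")
  chk(cfg$sigma > 0, "sigma must be positive")
  chk(cfg$dt > 0, "dt must be positive")
  chk(is.null(cfg$n_rings) ||
        (cfg$n_rings >= 1 && cfg$n_FG %% cfg$n_rings == 0),
      "n_rings must divide n_FG")
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  structure(cfg, class = "npc_config")
}

#' @export
print.npc_config <- function(x, ...) {
  cat("NPC run configuration\n")
  cat(sprintf("  box %g x %g x %g nm, envelope h = %g nm, pore D = %g nm\n",
              x$box[1], x$box[2], x$box[3], x$h, x$D))
  cat(sprintf("  %d chains of %d beads (sticker every %d beads)\n",
              x$n_FG, x$N, x$sticker_period))
  if (!is.null(x$cargo_d))
    cat(sprintf("  cargo d = %g nm, S/S* = %g\n", x$cargo_d,
                x$cargo_S_over_Sstar))
  cat(sprintf("  sigma = %g nm, dt = %g ns, seed = %s\n",
              x$sigma, x$dt, format(x$seed)))
  invisible(x)
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [npc_config()]; force-field overrides go
#' under an `ff:` mapping. Unknown keys are rejected with an exhaustive
#' listing, and an empty file yields the full default configuration.
#'
#' @param path Path to a YAML file.
#' @return A validated `npc_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping")
  known <- setdiff(names(formals(npc_config)), "ff")
  unknown <- setdiff(names(raw), c(known, "ff"))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  args <- raw[intersect(names(raw), known)]
  if (!is.null(raw$ff)) {
    if (!is.list(raw$ff)) stop("ff must be a mapping of force-field overrides")
    args$ff <- do.call(force_field, raw$ff)
  }
  do.call(npc_config, args)
}

#' Write a resolved configuration next to a run's outputs
#'
#' @param cfg An `npc_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "npc_config"))
  out <- unclass(cfg)
  out$ff <- as.list(unclass(out$ff))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Derive a reproducible RNG stream
#'
#' Hashes `(seed, purpose, index)` into an independent 256-bit generator
#' state, so that replicas and FFS trials get uncorrelated, individually
#' re-runnable streams from one master seed.
#'
#' @param seed Master seed (integer-valued).
#' @param purpose Short label, e.g. `"flux"` or `"trial3"`.
#' @param index Replica/trial index.
#' @return Character vector of 4 hex words (an engine RNG state).
#' @export
derive_stream <- function(seed, purpose = "run", index = 0L) {
  cpp_derive_stream(as.numeric(seed), as.character(purpose), as.integer(index))
}
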