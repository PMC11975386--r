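#' Forward-flux-sampling interfaces through the pore
#'
#' The order parameter is the cargo centre's staged progress along -z. The
#' first interface I0 is a hemisphere of radius `D/2` over the pore entrance
#' (the top face of the envelope); basin A is everything outside it on the
#' entry side. The pore is then cut into `n_ffs` equal cylindrical slabs of
#' height `h / n_ffs`; interfaces I1..In sit at the slab exit planes.
#' Basin B — commitment — is a matching hemisphere of radius `D/2` beyond
#' the exit: `n_ffs + 1` transition probabilities in total (entry slab
#' crossings plus the final commitment), matching the rate decomposition
#' `k_AB = Phi0 * prod(P_trans,i)`.
#'
#' @param D Pore diameter, nm.
#' @param h Pore height, nm.
#' @param n_ffs Number of slabs (>= 1).
#' @param Lz Box height, nm (the envelope sits at `Lz / 2`).
#' @param arm_buffer Hysteresis buffer, nm: the basin-A boundary used for
#'   re-arming the flux counter and for failing trials sits this far outside
#'   I0, suppressing spurious recrossing counts from single-step dithering
#'   on the interface. One bead diameter by default.
#' @return An object of class `npc_interfaces`: all coordinates in nm, with
#'   `z_entry`, exit-plane levels `z_levels` (length `n_ffs`), commitment
#'   level `z_commit`, and hemisphere radius `hemi_r`.
#' @export
define_interfaces <- function(D, h, n_ffs = 8, Lz = 200, arm_buffer = 0.86) {
  if (n_ffs < 1) stop("n_ffs must be >= 1")
  stopifnot(D > 0, h > 0, Lz > h, arm_buffer >= 0)
  zc <- Lz / 2
  z_entry <- zc + h / 2
  z_levels <- z_entry - seq_len(n_ffs) * h / n_ffs
  structure(list(
    n_ffs = as.integer(n_ffs),
    z_entry = z_entry,
    z_levels = z_levels,
    z_commit = (zc - h / 2) - D / 2,
    hemi_r = D / 2,
    arm_buffer = arm_buffer,
    D = D, h = h, Lz = Lz
  ), class = "npc_interfaces")
}

#' @export
print.npc_interfaces <- function(x, ...) {
  cat(sprintf("FFS interfaces: hemisphere r = %.1f nm at z = %.1f nm, %d slabs of %.2f nm, commit at z = %.1f nm\n",
              x$hemi_r, x$z_entry, x$n_ffs, x$h / x$n_ffs, x$z_commit))
  invisible(x)
}

interfaces_for <- function(system, n_ffs) {
  s <- system$units[["sigma_nm"]]
  define_interfaces(system$env[["D"]] * s, system$env[["h"]] * s,
                    n_ffs, system$box[3] * s)
}

hemi_opts <- function(system, ifc) {
  s <- system$units[["sigma_nm"]]
  c(system$box[1] / 2, system$box[2] / 2, ifc$z_entry / s, ifc$hemi_r / s,
    (ifc$hemi_r + ifc$arm_buffer) / s)
}

# place the cargo at a random point of basin A (entry side), clear of the
# hemisphere and the envelope
place_cargo_in_A <- function(system, ifc, seed) {
  stopifnot(!is.null(system$cargo))
  s <- system$units[["sigma_nm"]]
  rad <- system$cargo$d / 2
  z_lo <- ifc$z_entry / s + rad + 0.5
  z_hi <- system$box[3] - rad - 0.5
  hemi <- hemi_opts(system, ifc)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(strtoi(substr(derive_stream(seed, "place")[1], 10, 16), 16L))
  repeat {
    p <- c(runif(1, 0, system$box[1]), runif(1, 0, system$box[2]),
           runif(1, z_lo, z_hi))
    if (sqrt(sum((p - hemi[1:3])^2)) > hemi[4] + rad + 0.5) break
  }
  # random initial orientation: uniform quaternion
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  system$cargo$center <- p
  system$cargo$quat <- q
  system
}

#' Flux phase of forward flux sampling
#'
#' Runs the full system with the cargo wandering in basin A and measures
#' the effective positive flux onto the entry hemisphere I0: the number of
#' first crossings (re-armed only after a full return to basin A) divided
#' by the time spent on the A side of the barrier. Each crossing stores a
#' complete system snapshot for the interface phase. During rate
#' calculations the far z-boundary is reflective for the cargo, so
#' transport can only proceed through the pore.
#'
#' @param system An `npc_system` with a cargo (chains pre-equilibrated).
#' @param interfaces From [define_interfaces()] / `n_ffs` in the config.
#' @param seed Seed for this phase's streams.
#' @param min_crossings Stop after this many crossings.
#' @param max_steps Hard cap on the phase length.
#' @param store_max Snapshot storage cap.
#' @param place_cargo Re-place the cargo randomly in basin A first.
#' @return List: `Phi0` (ns^-1), `Phi0_se`, `crossings`, `steps`, `stored`
#'   (list of snapshots), `state` (final system).
#' @export
flux_phase <- function(system, interfaces, seed = 1, min_crossings = 100,
                       max_steps = 5e7, store_max = 500, place_cargo = TRUE) {
  stopifnot(inherits(system, "npc_system"), inherits(interfaces, "npc_interfaces"))
  if (is.null(system$cargo)) stop("flux phase requires a cargo")
  if (place_cargo) system <- place_cargo_in_A(system, interfaces, seed)
  system$rng <- derive_stream(seed, "flux")
  s <- system$units[["sigma_nm"]]
  res <- cpp_run(as_engine_state(system),
                 list(mode = "flux", n_steps = max_steps,
                      hemi = hemi_opts(system, interfaces),
                      store_max = as.integer(store_max),
                      min_crossings = min_crossings,
                      commit_z = interfaces$z_commit / s, reflect_z = TRUE))
  dt <- system$units[["dt_ns"]]
  crossings <- res$crossings
  time_A_ns <- res$time_A * dt
  Phi0 <- if (time_A_ns > 0) crossings / time_A_ns else 0
  if (crossings == 0)
    warning("no entry crossings observed in the flux phase; Phi0 = 0")
  list(Phi0 = Phi0,
       Phi0_se = if (time_A_ns > 0) sqrt(crossings) / time_A_ns else NA_real_,
       crossings = crossings, steps = res$steps, time_A_ns = time_A_ns,
       stored = res$stored,
       state = update_system(system, res$state))
}

#' Interface phase of forward flux sampling
#'
#' From stored configurations at interface `i`, launches `n_trials` runs
#' (uniformly resampled starting configurations, independent derived RNG
#' streams). A trial succeeds when the cargo reaches the next interface
#' (for the last interface: the commitment level beyond the pore exit) and
#' fails when it returns to basin A. Backward excursions within the pore
#' are allowed — a trajectory is only abandoned on full exit to A — which
#' is what gives persistent, backtracking trajectories their proper
#' statistical weight in the assembled rate.
#'
#' @param system Template `npc_system` (topology/parameters; coordinates
#'   are overwritten by each snapshot).
#' @param stored List of snapshots at interface `i`.
#' @param interfaces An `npc_interfaces`.
#' @param i Interface index, 0-based (0 = hemisphere I0, up to `n_ffs`).
#' @param n_trials Number of trials (> 0).
#' @param seed Seed; trial `t` uses stream `(seed, "trial<i>", t)`.
#' @param max_steps Per-trial step cap (capped trials count as failures
#'   and are reported).
#' @return List: `P` (success fraction), `se` (binomial), `n_trials`,
#'   `successes`, `timeouts`, `stored` (end snapshots at interface `i+1`).
#' @export
interface_phase <- function(system, stored, interfaces, i, n_trials = 500,
                            seed = 1, max_steps = 2e6) {
  stopifnot(inherits(system, "npc_system"), inherits(interfaces, "npc_interfaces"))
  if (length(stored) == 0) stop("no stored configurations at interface ", i)
  if (n_trials < 1) stop("n_trials must be positive")
  if (i < 0 || i > interfaces$n_ffs) stop("interface index out of range")
  s <- system$units[["sigma_nm"]]
  success_z <- if (i < interfaces$n_ffs) interfaces$z_levels[i + 1] else
    interfaces$z_commit
  hemi <- hemi_opts(system, interfaces)
  pick <- strtoi(substr(derive_stream(seed, paste0("pick", i))[1], 10, 16), 16L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(pick)
  idx <- sample.int(length(stored), n_trials, replace = TRUE)
  succ <- 0L; timeouts <- 0L
  next_stored <- vector("list", 0)
  for (t in seq_len(n_trials)) {
    trial_sys <- apply_snapshot(system, stored[[idx[t]]])
    trial_sys$rng <- derive_stream(seed, paste0("trial", i), t)
    res <- cpp_run(as_engine_state(trial_sys),
                   list(mode = "trial", n_steps = max_steps, hemi = hemi,
                        success_z = success_z / s, reflect_z = TRUE))
    if (isTRUE(res$success)) {
      succ <- succ + 1L
      next_stored[[length(next_stored) + 1L]] <- res$end_snapshot
    } else if (!isTRUE(res$returned_A)) {
      timeouts <- timeouts + 1L
    }
  }
  P <- succ / n_trials
  list(P = P, se = sqrt(P * (1 - P) / n_trials), n_trials = n_trials,
       successes = succ, timeouts = timeouts, stored = next_stored)
}

#' Assemble FFS transport rates
#'
#' `k_AB = Phi0 * prod(P_trans,i)` over all interfaces, and the partial
#' rate `k'_AB = Phi0 * P_trans,0` (flux into the pore times the first
#' crossing probability), a cheap proxy that tracks the full rate because
#' the insertion step dominates the barrier. Standard errors combine the
#' Poisson error of the flux with the binomial errors of the interface
#' probabilities in quadrature on the log scale.
#'
#' @param Phi0 Initial flux, ns^-1.
#' @param P_trans Numeric vector of transition probabilities, interfaces
#'   0..n_ffs.
#' @param Phi0_se,P_se Optional standard errors (same shapes).
#' @param n_trials Trials per interface (for bookkeeping).
#' @return An object of class `npc_ffs_result`.
#' @export
assemble_rates <- function(Phi0, P_trans, Phi0_se = NA_real_, P_se = NULL,
                           n_trials = NA_integer_) {
  if (length(Phi0) != 1 || Phi0 < 0) stop("Phi0 must be a single rate >= 0")
  if (any(P_trans < 0 | P_trans > 1)) stop("P_trans must lie in [0, 1]")
  if (!is.null(P_se) && length(P_se) != length(P_trans))
    stop("P_se length must match P_trans")
  k_AB <- Phi0 * prod(P_trans)
  k_partial <- Phi0 * P_trans[1]
  rel2 <- function(se, v) ifelse(v > 0, (se / v)^2, NA_real_)
  se_full <- se_part <- NA_real_
  if (!is.na(Phi0_se) && !is.null(P_se)) {
    se_full <- k_AB * sqrt(rel2(Phi0_se, Phi0) + sum(rel2(P_se, P_trans)))
    se_part <- k_partial * sqrt(rel2(Phi0_se, Phi0) + rel2(P_se[1], P_trans[1]))
  }
  structure(list(
    Phi0 = Phi0, Phi0_se = Phi0_se,
    P_trans = P_trans, P_se = P_se,
    k_AB = k_AB, k_AB_se = se_full,
    k_AB_partial = k_partial, k_AB_partial_se = se_part,
    n_trials = n_trials
  ), class = "npc_ffs_result")
}

#' @export
print.npc_ffs_result <- function(x, ...) {
  cat("Forward flux sampling result\n")
  cat(sprintf("  Phi0 = %.3g ns^-1 (se %.2g)\n", x$Phi0, x$Phi0_se))
  cat(sprintf("  P_trans,0..%d: %s\n", length(x$P_trans) - 1,
              paste(signif(x$P_trans, 3), collapse = ", ")))
  cat(sprintf("  k_AB  = %.3g ns^-1 (se %.2g)\n", x$k_AB, x$k_AB_se))
  cat(sprintf("  k'_AB = %.3g ns^-1 (se %.2g)\n", x$k_AB_partial,
              x$k_AB_partial_se))
  invisible(x)
}

#' @export
tidy.npc_ffs_result <- function(x, ...) {
  tibble::tibble(interface = seq_along(x$P_trans) - 1L,
                 P_trans = x$P_trans,
                 se = if (is.null(x$P_se)) NA_real_ else x$P_se)
}

#' @export
glance.npc_ffs_result <- function(x, ...) {
  tibble::tibble(Phi0 = x$Phi0, k_AB = x$k_AB, k_AB_se = x$k_AB_se,
                 k_AB_partial = x$k_AB_partial,
                 k_AB_partial_se = x$k_AB_partial_se)
}

#' @export
autoplot.npc_ffs_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$interface, y = .data$P_trans)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(0, .data$P_trans - .data$se),
                                        ymax = pmin(1, .data$P_trans + .data$se)),
                           width = 0.2) +
    ggplot2::labs(x = "interface i", y = expression(P[trans, i]),
                  title = sprintf("k_AB = %.3g /ns, k'_AB = %.3g /ns",
                                  object$k_AB, object$k_AB_partial))
}

#' Run forward flux sampling end to end
#'
#' Flux phase plus all interface phases; set `partial_only = TRUE` to stop
#' after interface 0 (the partial rate `k'_AB = Phi0 * P_trans,0`, used for
#' parameter sweeps).
#'
#' @param system Equilibrated `npc_system` with cargo.
#' @param n_ffs Number of slabs (default from the system's config).
#' @param seed Master seed for all phases.
#' @param n_trials Trials per interface.
#' @param min_crossings,flux_max_steps,store_max Flux-phase controls.
#' @param trial_max_steps Per-trial cap.
#' @param partial_only Stop after the first interface.
#' @return An `npc_ffs_result`; for `partial_only` the probabilities beyond
#'   interface 0 are `NA` and only `k_AB_partial` is meaningful.
#' @export
run_ffs <- function(system, n_ffs = NULL, seed = 1, n_trials = NULL,
                    min_crossings = NULL, flux_max_steps = NULL,
                    store_max = 500, trial_max_steps = 2e6,
                    partial_only = FALSE) {
  cfg <- system$config
  n_ffs <- n_ffs %||% cfg$n_ffs
  n_trials <- n_trials %||% cfg$n_trials
  min_crossings <- min_crossings %||% cfg$flux_min_crossings
  flux_max_steps <- flux_max_steps %||% cfg$flux_max_steps
  ifc <- interfaces_for(system, n_ffs)
  fl <- flux_phase(system, ifc, seed = seed, min_crossings = min_crossings,
                   max_steps = flux_max_steps, store_max = store_max)
  n_prob <- n_ffs + 1L
  P <- rep(NA_real_, n_prob); se <- rep(NA_real_, n_prob)
  stored <- fl$stored
  last <- if (partial_only) 0L else n_ffs
  for (i in 0:last) {
    if (length(stored) == 0 || fl$crossings == 0) { P[i + 1] <- 0; se[i + 1] <- NA; break }
    ph <- interface_phase(system, stored, ifc, i, n_trials = n_trials,
                          seed = seed, max_steps = trial_max_steps)
    P[i + 1] <- ph$P; se[i + 1] <- ph$se
    stored <- ph$stored
    if (ph$P == 0) { P[seq(i + 2, length.out = n_prob - i - 1)] <- 0; break }
  }
  if (partial_only) {
    res <- assemble_rates(fl$Phi0, c(P[1], rep(1, n_ffs)), fl$Phi0_se,
                          c(se[1], rep(0, n_ffs)), n_trials)
    res$P_trans <- P; res$P_se <- se
    res$k_AB <- NA_real_; res$k_AB_se <- NA_real_
  } else {
    P[is.na(P)] <- 0
    res <- assemble_rates(fl$Phi0, P, fl$Phi0_se, se, n_trials)
  }
  res$crossings <- fl$crossings
  res$flux_steps <- fl$steps
  res
}

#' Brute-force transport rate by direct simulation
#'
#' The independent check on FFS: run one long trajectory, label the system
#' by the basin it last committed to, and count A-to-B transitions per unit
#' time spent on the A side. Uses the same basin definitions and the same
#' reflecting far z-boundary as the FFS machinery.
#'
#' @param system Equilibrated `npc_system` with cargo.
#' @param n_steps Trajectory length.
#' @param n_ffs Interface count (only the basins matter here).
#' @param seed Seed.
#' @return List: `k_AB` (ns^-1), `se` (Poisson), `n_AB`, `time_A_ns`.
#' @export
direct_rate <- function(system, n_steps, n_ffs = NULL, seed = 1) {
  cfg <- system$config
  ifc <- interfaces_for(system, n_ffs %||% cfg$n_ffs)
  system <- place_cargo_in_A(system, ifc, seed)
  system$rng <- derive_stream(seed, "direct")
  s <- system$units[["sigma_nm"]]
  res <- cpp_run(as_engine_state(system),
                 list(mode = "direct", n_steps = n_steps,
                      hemi = hemi_opts(system, ifc),
                      commit_z = ifc$z_commit / s, reflect_z = TRUE))
  dt <- system$units[["dt_ns"]]
  tA <- res$time_A * dt
  list(k_AB = res$n_AB / tA, se = sqrt(max(1, res$n_AB)) / tA,
       n_AB = res$n_AB, time_A_ns = tA)
}
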