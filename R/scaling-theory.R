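#' Polymer-scaling parameters of the FG-Nup meshwork
#'
#' Bundles the constants of the scaling description of the FG-Nup-filled pore:
#' each chain obeys `R = b * N^nu`, and the meshwork's volume fraction at pore
#' diameter `D` is `phi = A * N / D^2` with `A = 4 * v_mon * n_FG / (pi * h)`.
#'
#' @param b Kuhn length (nm). Default is the bead diameter 0.86 nm.
#' @param nu Flory exponent (dimensionless, good solvent ~ 0.588).
#' @param N Number of segments (beads) per chain.
#' @param v_mon Monomer volume (nm^3), `pi * sigma^3 / 6` for spherical beads.
#' @param n_FG Number of FG-Nup chains anchored in the pore.
#' @param h Pore height / nuclear-envelope thickness (nm).
#'
#' @return An object of class `npc_polymer_params`.
#' @examples
#' p <- polymer_params(N = 209)
#' reference_scales(p)
#' @export
polymer_params <- function(b = 0.86, nu = 0.588, N = 209,
                           v_mon = pi * 0.86^3 / 6, n_FG = 80, h = 40) {
  stopifnot(is.numeric(b), is.numeric(nu), is.numeric(N),
            is.numeric(v_mon), is.numeric(n_FG), is.numeric(h))
  if (b <= 0) stop("Kuhn length `b` must be positive")
  if (nu <= 1 / 3 || nu >= 1) stop("Flory exponent `nu` must lie in (1/3, 1)")
  if (N < 1) stop("`N` must be >= 1")
  if (v_mon <= 0) stop("`v_mon` must be positive")
  if (n_FG < 1) stop("`n_FG` must be >= 1")
  if (h <= 0) stop("pore height `h` must be positive")
  structure(list(b = b, nu = nu, N = N, v_mon = v_mon, n_FG = n_FG, h = h),
            class = "npc_polymer_params")
}

#' @export
print.npc_polymer_params <- function(x, ...) {
  cat("FG-Nup scaling parameters\n")
  cat(sprintf("  b = %.3g nm, nu = %.3f, N = %d\n", x$b, x$nu, as.integer(x$N)))
  cat(sprintf("  v_mon = %.3g nm^3, n_FG = %d, h = %.3g nm\n",
              x$v_mon, as.integer(x$n_FG), x$h))
  invisible(x)
}

#' Reference scales of the semi-dilute FG-Nup solution
#'
#' Computes the overlap-concentration reference scales: the area prefactor
#' `A = 4 v_mon n_FG / (pi h)`, the single-chain size `xi_star = b N^nu`
#' (the mesh size at overlap), the overlap volume fraction
#' `phi_star = N^(1 - 3 nu)`, the critical pore diameter
#' `D_star = sqrt(A) N^(3 nu / 2)` at which the meshwork reaches overlap
#' concentration, and the scaling exponent `alpha = (3 nu - 1) / nu`.
#' The transport model applies below `D_star`, where the pore is fully
#' occupied by chains.
#'
#' @param params An [polymer_params()] object.
#' @return A tibble with one row and columns `A` (nm^2), `xi_star` (nm),
#'   `phi_star`, `D_star` (nm), `alpha`.
#' @examples
#' reference_scales(polymer_params(N = 209))$D_star # ~ 102 nm
#' @export
reference_scales <- function(params) {
  stopifnot(inherits(params, "npc_polymer_params"))
  A <- 4 * params$v_mon * params$n_FG / (pi * params$h)
  tibble::tibble(
    A        = A,
    xi_star  = params$b * params$N^params$nu,
    phi_star = params$N^(1 - 3 * params$nu),
    D_star   = sqrt(A) * params$N^(3 * params$nu / 2),
    alpha    = (3 * params$nu - 1) / params$nu
  )
}

#' Mesh (correlation) size of the in-pore FG-Nup solution
#'
#' The semi-dilute correlation length `xi = b * phi^(-nu/(3 nu - 1))` with
#' volume fraction `phi = A N / D^2`. Above overlap (`phi > 1`) the scaling
#' form is extrapolated and a warning is issued.
#'
#' @param D Pore diameter(s), nm.
#' @param params An [polymer_params()] object.
#' @return Mesh size(s) in nm.
#' @examples
#' mesh_size(c(40, 60), polymer_params(N = 209)) # ~ 4.7 and 8.7 nm
#' @export
mesh_size <- function(D, params) {
  stopifnot(inherits(params, "npc_polymer_params"), is.numeric(D))
  if (any(D <= 0)) stop("pore diameter `D` must be positive")
  A <- 4 * params$v_mon * params$n_FG / (pi * params$h)
  phi <- A * params$N / D^2
  if (any(phi > 1))
    warning("volume fraction phi = A*N/D^2 exceeds 1; scaling law extrapolated")
  params$b * phi^(-params$nu / (3 * params$nu - 1))
}

#' Normalized mesh-size ratio as a function of normalized pore diameter
#'
#' `xi / xi_star = (D / D_star)^(2 nu / (3 nu - 1))`, the normalized form of
#' the correlation-length law.
#'
#' @param D_tilde Normalized pore diameter(s) `D / D_star`, positive.
#' @param nu Flory exponent.
#' @return `xi / xi_star`.
#' @export
normalized_mesh_ratio <- function(D_tilde, nu) {
  stopifnot(is.numeric(D_tilde), is.numeric(nu))
  if (any(D_tilde <= 0)) stop("`D_tilde` must be positive")
  D_tilde^(2 * nu / (3 * nu - 1))
}

#' Free energy of inserting a cargo into the meshwork
#'
#' `dG / kBT = gamma * (d / xi)^((3 nu - 1) / nu)`: the work of inserting a
#' sphere of diameter `d` into a mesh of correlation size `xi`, in thermal
#' units. `gamma` collects mesh interactions and cargo-geometry detail into
#' one dimensionless barrier coefficient.
#'
#' @param d Cargo diameter(s), nm (>= 0).
#' @param xi Mesh size, nm (> 0).
#' @param gamma Dimensionless barrier coefficient.
#' @param nu Flory exponent.
#' @return Insertion free energy in units of kBT.
#' @export
insertion_free_energy <- function(d, xi, gamma, nu) {
  stopifnot(is.numeric(d), is.numeric(xi), is.numeric(gamma), is.numeric(nu))
  if (any(d < 0)) stop("`d` must be non-negative")
  if (any(xi <= 0)) stop("mesh size `xi` must be positive")
  gamma * (d / xi)^((3 * nu - 1) / nu)
}

#' Normalized transport rate as a function of normalized pore size
#'
#' The model's master curve `f(x) = exp(-gamma / x^2)` for the normalized
#' rate `k_AB / k0`, where `x = D_tilde / d_tilde^(alpha/2)` is the pore size
#' normalized by the cargo size. `f` rises monotonically from 0 to 1; its
#' derivative peaks at `x0 = sqrt(2 gamma / 3)` (see [peak_sensitivity()]),
#' the pore size at which dilation changes transport the most.
#'
#' @param x Normalized pore size(s), positive.
#' @param gamma Dimensionless barrier coefficient.
#' @return Normalized transport rate(s) in (0, 1).
#' @export
transport_rate_model <- function(x, gamma) {
  stopifnot(is.numeric(x), is.numeric(gamma))
  if (any(x <= 0)) stop("`x` must be positive")
  exp(-gamma / x^2)
}

#' Pore size of maximal sensitivity to dilation
#'
#' The derivative of the master curve `f(x) = exp(-gamma/x^2)` peaks at
#' `x0 = sqrt(2 gamma / 3)`: pores near `x0` convert small diameter changes
#' into the largest change in transport rate.
#'
#' @param gamma Dimensionless barrier coefficient, positive.
#' @return `x0`.
#' @export
peak_sensitivity <- function(gamma) {
  stopifnot(is.numeric(gamma))
  if (any(gamma <= 0)) stop("`gamma` must be positive")
  sqrt(2 * gamma / 3)
}

#' Normalize a table of transport-rate measurements
#'
#' Adds the model's dimensionless variables to a table of rate measurements:
#' `d_tilde = d / xi_star`, `D_tilde = D / D_star`, the regression abscissa
#' `u = d_tilde^alpha * D_tilde^-2` and the normalized pore size
#' `x = D_tilde / d_tilde^(alpha/2)`.
#'
#' @param points Data frame with columns `D` (nm), `d` (nm), `rate` (ns^-1)
#'   and optionally `kind` (`"full"` or `"partial"`).
#' @param scales A one-row tibble from [reference_scales()].
#' @return The input as a tibble with columns `d_tilde`, `D_tilde`, `u`, `x`
#'   appended.
#' @export
normalize_rates <- function(points, scales) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("D", "d", "rate") %in% names(points)),
            all(c("xi_star", "D_star", "alpha") %in% names(scales)))
  if (any(points$D <= 0) || any(points$d < 0) || any(points$rate < 0))
    stop("invalid rate point: need D > 0, d >= 0, rate >= 0")
  dplyr::mutate(points,
                d_tilde = .data$d / scales$xi_star,
                D_tilde = .data$D / scales$D_star,
                u = .data$d_tilde^scales$alpha * .data$D_tilde^-2,
                x = .data$D_tilde / .data$d_tilde^(scales$alpha / 2))
}

#' Fit the barrier coefficient and baseline rate from transport rates
#'
#' Linearizes the model `k_AB = k0 * exp(-gamma * u)` with
#' `u = d_tilde^alpha * D_tilde^-2` and fits ordinary least squares of
#' `log(rate)` on `u`: the slope is `-gamma`, the intercept `log(k0)`.
#' Points with zero rate carry no log-scale information and are dropped
#' (with a message), mirroring how zero-transport observations are excluded
#' when pores are effectively impassable.
#'
#' @param points Data frame with columns `D`, `d`, `rate` (and optionally
#'   `kind`); units nm and ns^-1.
#' @param scales Reference scales from [reference_scales()].
#' @return An object of class `npc_model_fit` with elements `gamma`, `k0`,
#'   `r_squared`, `n_points`, the underlying `lm` fit and the normalized
#'   data. Supports [generics::tidy()], [generics::glance()],
#'   [ggplot2::autoplot()] and `print()`.
#' @examples
#' sc <- reference_scales(polymer_params(N = 209))
#' pts <- expand.grid(D = c(40, 50, 60), d = 1:6)
#' pts$rate <- with(pts, 1.4e-5 * exp(-6.33 * (d / sc$xi_star)^sc$alpha *
#'   (D / sc$D_star)^-2))
#' fit_gamma_k0(pts, sc)
#' @export
fit_gamma_k0 <- function(points, scales) {
  pts <- normalize_rates(points, scales)
  n_zero <- sum(pts$rate == 0)
  if (n_zero > 0) {
    message(sprintf("dropping %d zero-rate point(s) from the log-linear fit", n_zero))
    pts <- dplyr::filter(pts, .data$rate > 0)
  }
  if (nrow(pts) < 2)
    stop("need at least 2 points with positive rate to fit gamma and k0")
  fit <- stats::lm(log(rate) ~ u, data = pts)
  co <- stats::coef(fit)
  # noiseless model data fits perfectly; the summary warning is expected
  sm <- suppressWarnings(summary(fit))
  structure(list(
    gamma     = unname(-co["u"]),
    k0        = unname(exp(co["(Intercept)"])),
    r_squared = sm$r.squared,
    n_points  = nrow(pts),
    n_dropped = n_zero,
    lm        = fit,
    summary   = sm,
    data      = pts
  ), class = "npc_model_fit")
}

#' @export
print.npc_model_fit <- function(x, ...) {
  cat("Polymer-scaling transport model fit: log(k) = log(k0) - gamma * u\n")
  cat(sprintf("  gamma = %.3f\n  k0    = %.3g ns^-1\n  R^2   = %.4f  (n = %d%s)\n",
              x$gamma, x$k0, x$r_squared, x$n_points,
              if (x$n_dropped > 0) sprintf(", %d zero-rate dropped", x$n_dropped) else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.npc_model_fit <- function(x, ...) {
  s <- x$summary$coefficients
  tibble::tibble(
    term      = c("gamma", "log_k0"),
    estimate  = c(x$gamma, log(x$k0)),
    std.error = c(s["u", "Std. Error"], s["(Intercept)", "Std. Error"]),
    statistic = c(-s["u", "t value"], s["(Intercept)", "t value"]),
    p.value   = c(s["u", "Pr(>|t|)"], s["(Intercept)", "Pr(>|t|)"])
  )
}

#' @export
glance.npc_model_fit <- function(x, ...) {
  tibble::tibble(gamma = x$gamma, k0 = x$k0, r.squared = x$r_squared,
                 n = x$n_points, n.dropped = x$n_dropped,
                 sigma = x$summary$sigma)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.npc_model_fit <- function(object, ...) {
  df <- object$data
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$rate)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$d))) +
    ggplot2::geom_line(
      data = tibble::tibble(
        u = seq(min(df$u), max(df$u), length.out = 200),
        rate = object$k0 * exp(-object$gamma *
                                 seq(min(df$u), max(df$u), length.out = 200))),
      linewidth = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(tilde(d)^alpha ~ tilde(D)^-2),
                  y = expression(k[AB] ~ (ns^-1)), colour = "d (nm)",
                  title = sprintf("gamma = %.2f, k0 = %.2g /ns", object$gamma, object$k0))
}

#' Quadratic open-pore comparison model
#'
#' The complementary regime above the overlap diameter, where an FG-Nup-free
#' hole of area ~ (D - D0 - d)^2 controls transport:
#' `k_AB ~ max(0, D - D0 - d)^2`. Provided for comparison with the
#' mesh-governed exponential model, which applies below `D_star`.
#'
#' @param D Pore diameter(s), nm.
#' @param D0 Shift constant, nm.
#' @param d Cargo diameter, nm.
#' @return Relative rate (arbitrary units), clamped to zero when no open
#'   hole exists (`D <= D0 + d`).
#' @export
quadratic_pore_model <- function(D, D0, d) {
  stopifnot(is.numeric(D), is.numeric(D0), is.numeric(d))
  pmax(0, D - D0 - d)^2
}

#' Effective dissociation constant of the sticker bond
#'
#' Converts the simulation's per-step unbinding rate into solution units:
#' `KD = koff / kon` with `koff` in s^-1 obtained from the per-step rate and
#' the physical time step. With the default diffusion-limited on-rate
#' `kon = 1e9 /M/s` and the standard `koff = 2e-4` per step at `dt = 0.02`
#' ns, `KD = 0.01 M` (10 mM), comparable to weak transport-receptor/FG-Nup
#' interactions.
#'
#' @param koff_per_step Unbinding probability per integration step.
#' @param dt_ns Integration step in ns.
#' @param kon Assumed bimolecular on-rate, per molar per second.
#' @return Dissociation constant in molar.
#' @export
effective_dissociation_constant <- function(koff_per_step = 2e-4, dt_ns = 0.02,
                                            kon = 1e9) {
  stopifnot(is.numeric(koff_per_step), is.numeric(dt_ns), is.numeric(kon))
  if (any(kon <= 0)) stop("`kon` must be positive")
  if (any(dt_ns <= 0)) stop("`dt_ns` must be positive")
  if (any(koff_per_step < 0)) stop("`koff_per_step` must be non-negative")
  (koff_per_step / (dt_ns * 1e-9)) / kon
}
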