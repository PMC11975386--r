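std_params <- polymer_params(N = 209)

test_that("reference scales reproduce the printed overlap diameters", {
  expect_equal(reference_scales(std_params)$D_star, 102, tolerance = 0.01)
  expect_equal(reference_scales(polymer_params(N = 150))$D_star, 76.4,
               tolerance = 0.01)
  expect_equal(reference_scales(polymer_params(N = 250))$D_star, 120,
               tolerance = 0.01)
  # unit/identity case: h chosen so the area prefactor A = 1, N = 1
  sc <- reference_scales(polymer_params(b = 1, nu = 0.5, N = 1,
                                        v_mon = pi / 6, n_FG = 1, h = 2 / 3))
  expect_equal(sc$xi_star, 1)
  expect_equal(sc$phi_star, 1)
  expect_equal(sc$alpha, (3 * 0.5 - 1) / 0.5)
})

test_that("mesh size matches the printed estimates and the overlap identity", {
  expect_equal(mesh_size(40, std_params), 4.6, tolerance = 0.03)
  expect_equal(mesh_size(60, std_params), 8.7, tolerance = 0.03)
  # xi(D*) = xi* for arbitrary parameter sets
  for (N in c(50, 209, 400)) {
    p <- polymer_params(N = N, nu = 0.6, b = 1.2, n_FG = 30, h = 25)
    sc <- reference_scales(p)
    expect_equal(mesh_size(sc$D_star, p), sc$xi_star, tolerance = 1e-10)
  }
  expect_error(mesh_size(-4, std_params), "positive")
  expect_warning(mesh_size(3, std_params), "exceeds 1")
})

test_that("normalized mesh ratio agrees with the mesh-size law", {
  sc <- reference_scales(std_params)
  expect_equal(normalized_mesh_ratio(1, 0.588), 1)
  expect_equal(normalized_mesh_ratio(4, 0.5), 16)
  # algebraic identity xi/xi* = (D/D*)^(2 nu/(3 nu - 1)) across a grid
  D <- seq(20, 90, by = 5)
  expect_equal(normalized_mesh_ratio(D / sc$D_star, std_params$nu),
               mesh_size(D, std_params) / sc$xi_star, tolerance = 1e-12)
  expect_error(normalized_mesh_ratio(-1, 0.588), "positive")
})

test_that("insertion free energy scales as (d/xi)^alpha", {
  expect_equal(insertion_free_energy(5, 5, 6.33, 0.588), 6.33)
  expect_equal(insertion_free_energy(0, 3, 6.33, 0.588), 0)
  expect_equal(insertion_free_energy(2, 4, 1, 0.5),
               (2 / 4)^((3 * 0.5 - 1) / 0.5))
  expect_error(insertion_free_energy(1, 0, 6.33, 0.588), "positive")
  expect_error(insertion_free_energy(-1, 1, 6.33, 0.588), "non-negative")
})

test_that("the rate master curve is monotone, bounded and has f(x0)=e^-1.5", {
  expect_equal(transport_rate_model(1, 9.15), exp(-9.15))
  x <- seq(0.2, 30, length.out = 400)
  for (gamma in c(0.7, 6.33, 9.15, 20)) {
    f <- transport_rate_model(x, gamma)
    expect_true(all(diff(f) > 0))        # strictly increasing
    expect_true(all(f > 0 & f < 1))      # bounded on finite x
    x0 <- peak_sensitivity(gamma)
    expect_equal(transport_rate_model(x0, gamma), exp(-1.5), tolerance = 1e-12)
  }
  expect_error(transport_rate_model(0, 1), "positive")
})

test_that("peak sensitivity coincides with the numerical argmax of f'(x)", {
  # dense-grid argmax of the derivative as the independent check
  argmax_fprime <- function(gamma) {
    x <- seq(1e-3, 10, length.out = 2e5)
    f <- exp(-gamma / x^2)
    x[which.max(diff(f) / diff(x))]
  }
  expect_equal(peak_sensitivity(1.5), 1)
  expect_equal(peak_sensitivity(6.33), argmax_fprime(6.33), tolerance = 1e-3)
  expect_equal(peak_sensitivity(9.15), argmax_fprime(9.15), tolerance = 1e-3)
  expect_equal(peak_sensitivity(6.33), 2.054, tolerance = 1e-3)
  expect_equal(peak_sensitivity(9.15), 2.470, tolerance = 1e-3)
  expect_error(peak_sensitivity(-1), "positive")
})

test_that("gamma/k0 regression inverts noiseless model data exactly", {
  sc <- reference_scales(std_params)
  pts <- expand.grid(D = c(40, 50, 60), d = 1:6)
  u <- (pts$d / sc$xi_star)^sc$alpha * (pts$D / sc$D_star)^-2
  pts$rate <- 1.4e-5 * exp(-6.33 * u)
  fit <- fit_gamma_k0(pts, sc)
  expect_equal(fit$gamma, 6.33, tolerance = 1e-10)
  expect_equal(fit$k0, 1.4e-5, tolerance = 1e-10)
  expect_equal(fit$n_points, nrow(pts))
  # broom-style accessors
  td <- tidy(fit)
  expect_identical(td$term, c("gamma", "log_k0"))
  expect_equal(td$estimate[1], 6.33, tolerance = 1e-8)
  gl <- glance(fit)
  expect_equal(gl$r.squared, 1, tolerance = 1e-10)
})

test_that("gamma/k0 regression is calibrated under lognormal noise", {
  sc <- reference_scales(std_params)
  pts <- expand.grid(D = c(40, 50, 60), d = 1:6)
  pts <- pts[rep(seq_len(nrow(pts)), length.out = 40), ]
  u <- (pts$d / sc$xi_star)^sc$alpha * (pts$D / sc$D_star)^-2
  set.seed(101)
  pts$rate <- 1.4e-5 * exp(-6.33 * u) * exp(rnorm(nrow(pts), 0, 0.2))
  fit <- fit_gamma_k0(pts, sc)
  se <- tidy(fit)$std.error[1]
  expect_lt(abs(fit$gamma - 6.33), 3 * se)
})

test_that("zero-rate points are dropped and degenerate fits error", {
  sc <- reference_scales(std_params)
  pts <- data.frame(D = c(40, 50, 60), d = c(2, 2, 2),
                    rate = c(0, 1e-6, 2e-6))
  expect_message(fit <- fit_gamma_k0(pts, sc), "zero-rate")
  expect_equal(fit$n_points, 2)
  expect_error(suppressMessages(
    fit_gamma_k0(data.frame(D = 40, d = 1, rate = 0), sc)), "at least 2")
  expect_error(fit_gamma_k0(data.frame(D = -1, d = 1, rate = 1), sc),
               "invalid")
})

test_that("quadratic open-pore comparison model clamps at zero", {
  expect_equal(quadratic_pore_model(50, 44, 6), 0)
  expect_equal(quadratic_pore_model(51, 44, 6), 1)
  expect_equal(quadratic_pore_model(40, 44, 6), 0)
  expect_equal(quadratic_pore_model(c(50, 53), 44, 6), c(0, 9))
})

test_that("sticker kinetics convert to a 10 mM dissociation constant", {
  expect_equal(effective_dissociation_constant(2e-4, 0.02, 1e9), 0.01)
  expect_equal(effective_dissociation_constant(2e-4, 0.02, 2e9), 0.005)
  expect_equal(effective_dissociation_constant(0, 0.02, 1e9), 0)
  expect_error(effective_dissociation_constant(2e-4, 0.02, 0), "positive")
})
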