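test_that("dipolar constant matches first-principles value and r^-3 scaling", {
  # independent oracle: C = mu0 g^2 muB^2 / (4 pi h), free-electron g
  mu0_4pi <- 1e-7
  muB <- 9.2740100783e-24
  h <- 6.62607015e-34
  g <- 2.00231930436
  C_oracle <- mu0_4pi * g^2 * muB^2 / h * 1e27 / 1e6  # Hz m^3 -> MHz nm^3
  expect_equal(C_oracle, 52.04, tolerance = 2e-4)
  expect_equal(dipolar_frequency(1), C_oracle, tolerance = 2e-4)
  expect_equal(dipolar_frequency(1), 52.04)
  expect_equal(dipolar_frequency(2), 52.04 / 8)
  # monotone decreasing toward 0
  nu <- dipolar_frequency(seq(1, 20, by = 0.5))
  expect_true(all(diff(nu) < 0))
  expect_lt(dipolar_frequency(100), 1e-4)
  expect_error(dipolar_frequency(0), "positive")
  expect_error(dipolar_frequency(-2), "positive")
})

test_that("kernel closed form agrees with quadrature oracle and K(0, r) = 1", {
  expect_identical(kernel_value(0, 2.3), 1)
  expect_identical(kernel_value(0, 7.9), 1)
  for (r in c(2, 3, 5)) {
    t <- seq(0, 4000, length.out = 41)
    expect_lt(max(abs(kernel_value(t, r) - kernel_value_quadrature(t, r))),
              1e-6)
  }
  expect_error(kernel_value(100, 0), "positive")
})

test_that("kernel is a damped oscillation within powder-average bounds", {
  t <- seq(0, 12000, by = 8)
  k <- kernel_value(t, 3)
  expect_true(all(k <= 1 + 1e-12 & k >= -0.5 - 1e-12))
  # envelope of the oscillation about its asymptote decays
  blocks <- split(abs(k), ceiling(seq_along(k) / 300))
  env <- vapply(blocks, max, numeric(1))
  expect_true(all(diff(env[-1]) < 0))
})

test_that("kernel_matrix applies kernel_value element-wise", {
  K <- kernel_matrix(0, 3)
  expect_equal(K$values, matrix(1, 1, 1))
  t <- c(0, 120, 480, 900)
  r <- c(2.2, 3.7, 6.1)
  K <- kernel_matrix(t, r)
  expect_equal(K$values[1, ], rep(1, 3))
  oracle <- matrix(NA_real_, length(t), length(r))
  for (i in seq_along(t)) for (j in seq_along(r)) {
    oracle[i, j] <- kernel_value(t[i], r[j])
  }
  expect_equal(K$values, oracle)
  expect_error(kernel_matrix(numeric(0), r), "nonempty")
  expect_error(kernel_matrix(t, c(2, -1)), "positive")
})

test_that("distance_distribution enforces its invariants", {
  r <- default_distance_grid()
  P <- gaussian_mixture(list(c(4, 0.3, 1)), r)
  expect_true(all(P$density >= 0))
  dr <- r[2] - r[1]
  expect_equal(sum((P$density[-1] + P$density[-256]) / 2 * dr), 1,
               tolerance = 1e-9)
  expect_error(distance_distribution(r, rep(-1, 256)), "non-negative")
  expect_error(distance_distribution(rev(r), rep(1, 256)), "ascending")
  expect_error(distance_distribution(r^1.1, rep(1, 256)), "uniform")
})

test_that("form factor: depth limits, single-distance oracle, plateau", {
  r <- default_distance_grid()
  t <- short_time_grid()
  K <- kernel_matrix(t, r)
  P <- gaussian_mixture(list(c(3.7, 0.1, 1)), r)
  expect_equal(form_factor(P, 0, K)$values, rep(1, length(t)))

  # delta spike at r0, lambda = 1: F(t) is the single-frequency powder
  # pattern; compare against direct quadrature and locate first minimum
  r0 <- r[which.min(abs(r - 4.0))]
  dens <- rep(0, length(r)); dens[which.min(abs(r - 4.0))] <- 1
  Pd <- distance_distribution(r, dens)
  Fd <- form_factor(Pd, 1, K)
  expect_lt(max(abs(Fd$values - kernel_value_quadrature(t, r0))), 1e-6)
  nu_ghz <- dipolar_frequency(r0) * 1e-3
  t_min_expected <- 1 / (2 * nu_ghz)
  expect_lt(abs(t[which.min(Fd$values)] - t_min_expected),
            0.25 * t_min_expected)

  # 19% scenario: F(0) = 1 and late-time plateau at 1 - lambda
  K2 <- kernel_matrix(default_time_grid(), r)
  F19 <- form_factor(P, 0.19, K2)
  expect_equal(F19$values[1], 1)
  expect_equal(mean(utils::tail(F19$values, 30)), 0.81, tolerance = 0.01)
  expect_error(form_factor(P, 0.19, kernel_matrix(t, r + 0.1)), "grid")
})

test_that("form factor is linear in the distribution", {
  r <- default_distance_grid()
  K <- kernel_matrix(short_time_grid(), r)
  P1 <- gaussian_mixture(list(c(3.5, 0.2, 1)), r)
  P2 <- gaussian_mixture(list(c(5.1, 0.3, 1)), r)
  w <- 0.37
  Pmix <- distance_distribution(r, w * P1$density + (1 - w) * P2$density,
                                normalize = FALSE)
  lhs <- form_factor(Pmix, 0.23, K)$values
  rhs <- w * form_factor(P1, 0.23, K)$values +
    (1 - w) * form_factor(P2, 0.23, K)$values
  expect_lt(max(abs(lhs - rhs)), 1e-12)
})

test_that("background model and application behave algebraically", {
  t <- default_time_grid()
  r <- default_distance_grid()
  P <- gaussian_mixture(list(c(4.2, 0.2, 1)), r)
  FF <- form_factor(P, 0.3, kernel_matrix(t, r))
  expect_equal(apply_background(FF, background_model(0, 3))$values, FF$values)

  Fone <- base::structure(list(t_grid = t, values = rep(1, length(t)),
                               depth = 0), class = "form_factor")
  V <- apply_background(Fone, background_model(2e-4, 3))
  expect_equal(V$values, exp(-2e-4 * t))
  expect_equal(V$values[1], 1)

  B <- background_model(1.3e-4, 3.5)
  V2 <- apply_background(FF, B)
  expect_lt(max(abs(V2$values / background_decay(B, t) - FF$values)), 1e-12)
  expect_error(background_model(-1), ">= 0")
  expect_error(background_model(1e-4, 7), "dim")
})

test_that("distributions entirely above 6 nm barely oscillate over 2500 ns", {
  r <- default_distance_grid()
  P <- gaussian_mixture(list(c(7.0, 0.25, 1)), r)
  FF <- form_factor(P, 1, kernel_matrix(default_time_grid(2500, 8), r))
  # less than one full oscillation: at most one local extremum
  d <- diff(FF$values)
  n_extrema <- sum(diff(sign(d[d != 0])) != 0)
  expect_lte(n_extrema, 1)
})
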