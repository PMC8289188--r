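test_that("irreversible isodesmic extent has the hyperbolic closed form", {
  expect_equal(isodesmic_extent(0, 3), 0)
  expect_equal(isodesmic_extent(1, 1), 0.5)
  t <- seq(0, 150, by = 0.5)
  p <- isodesmic_extent(t, 0.2)
  expect_true(all(diff(p) > 0))
  expect_true(all(p < 1))
  expect_equal(max(abs(p - ode_extent(t, 0.2, 0, 1))), 0, tolerance = 1e-6)
  expect_error(isodesmic_extent(-1, 1), "non-negative")
  expect_error(isodesmic_extent(1, -1), "non-negative")
})

test_that("reversible isodesmic extent matches the ODE and its limits", {
  t <- seq(0, 150, by = 1)
  p <- isodesmic_extent_reversible(t, k_f = 0.3, k_b = 0.05, c0 = 1)
  expect_equal(p[1], 0)
  expect_true(all(diff(p) >= -1e-12))  # saturates to p_eq at double precision
  expect_true(all(diff(p[t <= 20]) > 0))
  expect_lt(max(p), 1)
  expect_lt(max(abs(p - ode_extent(t, 0.3, 0.05, 1))), 1e-5)
  # equilibrium extent is the smaller Riccati root
  a <- 0.3; kb <- 0.05
  s <- sqrt(kb * (kb + 4 * a))
  expect_equal(isodesmic_extent_reversible(1e6, 0.3, 0.05, 1),
               (2 * a + kb - s) / (2 * a), tolerance = 1e-8)
  # kb = 0 limit is the irreversible form with k = kf*c0
  expect_identical(isodesmic_extent_reversible(t, 0.06, 0, 5),
                   isodesmic_extent(t, 0.3))
  # small-kb continuity
  expect_lt(max(abs(isodesmic_extent_reversible(t, 0.3, 1e-8, 1) -
                    isodesmic_extent(t, 0.3))), 1e-4)
  expect_error(isodesmic_extent_reversible(t, -1, 0, 1), "non-negative")
  expect_error(isodesmic_extent_reversible(t, 1, 0, 0), "positive")
})

test_that("rate-vs-concentration model behaves at its limits", {
  expect_equal(rate_vs_conc(0, 0.2, 0.05, 0.01), 0.21)
  expect_equal(rate_vs_conc(1e9, 0.2, 0.05, 0.01), 0.01)
  expect_equal(rate_vs_conc(c(0, 10, 100), 0.3, 0, 0.1), rep(0.4, 3))
  k <- rate_vs_conc(seq(0, 750, by = 50), 0.2, 0.01, 0.005)
  expect_true(all(diff(k) < 0))
  # scale parameterization: exp(-c/beta)
  expect_equal(rate_vs_conc(10, 0.2, 10, 0, parameterization = "scale"),
               0.2 * exp(-1))
  expect_error(rate_vs_conc(-1, 1, 1, 0), "non-negative")
})

test_that("one-site binding fraction is the Langmuir isotherm", {
  expect_equal(binding_fraction(0, 2.5), 0)
  expect_equal(binding_fraction(2.5, 2.5), 0.5)
  expect_equal(binding_fraction(9 * 2.5, 2.5), 0.9)
  c <- seq(0, 100, by = 0.5)
  th <- binding_fraction(c, 3)
  expect_true(all(th >= 0 & th < 1))
  expect_true(all(diff(th) > 0))
  expect_error(binding_fraction(1, 0), "positive")
  expect_error(binding_fraction(-1, 1), "non-negative")
})

test_that("depletion-corrected fraction reduces to Langmuir for small protein", {
  c <- seq(0.1, 25, by = 0.3)
  th_simple <- binding_fraction(c, 2.5)
  th_dep <- binding_fraction_depletion(c, 2.5, P = 1e-6)
  expect_equal(th_dep, th_simple, tolerance = 1e-5)
  # with appreciable protein, less apparent saturation at low total ligand
  expect_true(all(binding_fraction_depletion(c, 2.5, P = 4) < th_simple))
  expect_equal(binding_fraction_depletion(0, 2.5, 4), 0)
})

test_that("titration signal interpolates between endpoints", {
  expect_equal(titration_signal(0, 2.5, 100, 40), 100)
  expect_equal(titration_signal(1e9, 2.5, 100, 40), 40, tolerance = 1e-6)
  expect_equal(titration_signal(2.5, 2.5, 100, 40), 70)
  # increasing signals are handled too
  expect_equal(titration_signal(2.5, 2.5, 10, 30), 20)
})

test_that("sphere-of-action ratio generalizes the Stern-Volmer law", {
  expect_equal(sphere_of_action_ratio(0, 5, 2), 1)
  expect_equal(sphere_of_action_ratio(0.2, 5, 0), 2)
  V <- oracle_volume(7.7)
  expect_equal(sphere_of_action_ratio(0.1, 5.24, V),
               (1 + 5.24 * 0.1) * exp(V * 0.1))
  # strictly convex in Q when V > 0
  Q <- seq(0, 0.5, by = 0.05)
  ratio <- sphere_of_action_ratio(Q, 5.24, V)
  expect_true(all(diff(diff(ratio)) > 0))
  expect_true(all(ratio >= 1))
  expect_error(sphere_of_action_ratio(-0.1, 5, 0), "non-negative")
})

test_that("action volume and radius convert with the litre-based convention", {
  expect_equal(action_volume_to_radius(0), 0)
  expect_equal(radius_to_action_volume(0), 0)
  expect_equal(radius_to_action_volume(7.7), oracle_volume(7.7))
  expect_equal(radius_to_action_volume(7.7), 1.1516, tolerance = 1e-4)
  # round trip and monotone bijection
  r <- c(0.5, 1, 7.7, 8.4, 8.7, 20)
  expect_equal(action_volume_to_radius(radius_to_action_volume(r)), r,
               tolerance = 1e-10)
  expect_true(all(diff(radius_to_action_volume(r)) > 0))
  expect_error(action_volume_to_radius(-1), "non-negative")
})
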