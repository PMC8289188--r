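test_that("panel normalization maps the reference maximum to one", {
  t <- seq(0, 150, length.out = 50)
  mk <- function(peak, id, rep = 1) kinetic_trace(
    t, peak * isodesmic_extent(t, 0.1) / isodesmic_extent(max(t), 0.1),
    pom_id = id, replicate = rep)
  panel <- list(mk(990, "none", 1), mk(1010, "none", 2), mk(400, "POM"))
  norm <- normalize_panel(panel, "none")
  ref_max <- mean(c(990, 1010))
  expect_equal(max(norm[[1]]$signal) * ref_max, 990)
  expect_equal(max(norm[[3]]$signal), 400 / ref_max)   # plateau at 40%
  # idempotent: second pass divides by 1
  norm2 <- normalize_panel(norm, "none")
  expect_equal(norm2[[3]]$signal, norm[[3]]$signal)
  expect_error(normalize_panel(panel, "missing-label"), "not present")
})

test_that("kinetic fitter recovers noiseless parameters exactly", {
  tr <- make_noiseless_trace(k = 0.05, amplitude = 1, baseline = 0.02)
  f <- fit_kinetic_trace(tr)
  expect_equal(f$k, 0.05, tolerance = 1e-6)
  expect_equal(f$amplitude, 1, tolerance = 1e-6)
  expect_equal(f$baseline, 0.02, tolerance = 1e-6)
  expect_lt(f$rss, 1e-12)
})

test_that("kinetic fitter is unbiased at plate-reader noise levels", {
  t <- seq(0, 150, length.out = 90)
  clean <- 0.02 + isodesmic_extent(t, 0.1)
  ks <- vapply(1:100, function(s) {
    y <- withr::with_seed(s, clean * (1 + rnorm(length(t), sd = 0.02)))
    fit_kinetic_trace(kinetic_trace(t, y))$k
  }, numeric(1))
  expect_lt(abs(median(ks) / 0.1 - 1), 0.05)
})

test_that("kinetic fitter rejects degenerate traces", {
  t <- seq(0, 150, length.out = 40)
  expect_error(fit_kinetic_trace(kinetic_trace(t, rep(5, 40))), "constant")
  expect_error(fit_kinetic_trace(kinetic_trace(t, seq(5, 1, length.out = 40))),
               "decreasing")
  expect_error(fit_kinetic_trace(kinetic_trace(t[1:5], 1:5)), "8 time points")
})

test_that("normalization leaves the fitted rate invariant", {
  tr <- make_noiseless_trace(k = 0.08, amplitude = 950, baseline = 20)
  k1 <- fit_kinetic_trace(tr)$k
  for (scale in c(1e-3, 7, 1e4)) {
    tr2 <- tr
    tr2$signal <- tr$signal * scale
    expect_equal(fit_kinetic_trace(tr2)$k, k1, tolerance = 1e-8)
  }
})

test_that("rate-vs-concentration fitter recovers the exponential exactly", {
  conc <- c(0, 37.5, 75, 150, 300, 600, 750)   # 75 uM protein, 1:0.5-1:10
  k <- rate_vs_conc(conc, 0.2, 0.05, 0.01)
  f <- fit_rate_concentration(conc, k)
  expect_equal(f$alpha, 0.2, tolerance = 1e-6)
  expect_equal(f$beta, 0.05, tolerance = 1e-6)
  expect_equal(f$gamma, 0.01, tolerance = 1e-6)
  expect_false(f$beta_at_bound)
  # scale parameterization round-trips too
  k2 <- rate_vs_conc(conc, 0.2, 100, 0.01, parameterization = "scale")
  f2 <- fit_rate_concentration(conc, k2, parameterization = "scale")
  expect_equal(f2$beta, 100, tolerance = 1e-4)
})

test_that("rate fitter flags data that do not decay with concentration", {
  conc <- c(0, 50, 100, 200, 400)
  f_flat <- fit_rate_concentration(conc, rep(0.15, 5))
  # concentration-independent rates: fitted curve is the constant mean rate
  pred <- rate_vs_conc(conc, f_flat$alpha, f_flat$beta, f_flat$gamma)
  expect_equal(pred, rep(0.15, 5), tolerance = 1e-6)
  expect_true(f_flat$beta_at_bound)
  f_up <- fit_rate_concentration(conc, c(0.1, 0.12, 0.15, 0.2, 0.3))
  expect_true(f_up$beta_at_bound)
  expect_error(fit_rate_concentration(c(0, 1, 2), c(1, 1, 1)), "4 distinct")
})

test_that("titration fitter recovers a noiseless one-site isotherm", {
  conc <- seq(0, 25, length.out = 25)
  s <- titration_signal(conc, 2.5, 100, 40)
  f <- fit_titration(conc, s)
  expect_equal(f$Kd, 2.5, tolerance = 1e-6)
  expect_equal(f$S0, 100, tolerance = 1e-6)
  expect_equal(f$Sinf, 40, tolerance = 1e-6)
  expect_false(f$unidentifiable)
  # depletion-corrected variant round-trips on depletion-corrected data
  sd_ <- titration_signal(conc, 2.5, 100, 40, depletion = TRUE, P = 4)
  fd <- fit_titration(conc, sd_, depletion = TRUE, P = 4)
  expect_equal(fd$Kd, 2.5, tolerance = 1e-6)
})

test_that("titration fitter flags flat curves and supports the bootstrap", {
  conc <- seq(0, 25, length.out = 20)
  f <- fit_titration(conc, rep(50, 20))
  expect_true(f$unidentifiable)
  curve <- gen_titration_curve(2.48, noise_fraction = 0.02, seed = 11)
  fb <- fit_titration(curve$conc_uM, curve$signal, bootstrap = 200, seed = 5)
  expect_gt(fb$boot_se_Kd, 0)
  expect_equal(fb$Kd, 2.48, tolerance = 0.25)
  expect_error(fit_titration(c(0, 1, 2), c(3, 2, 1)), "5 concentrations")
})

test_that("quenching fitter recovers sphere-of-action parameters exactly", {
  qc <- gen_quenching_curve(5.24, 7.7, noise_fraction = 0)
  f <- fit_quenching(qc$Q_M, qc$F)
  expect_equal(f$Ksv, 5.24, tolerance = 1e-6)
  expect_equal(f$r, 7.7, tolerance = 1e-6)
  # purely dynamic quenching: V ~ 0 and Ksv equals the line slope
  Q <- seq(0, 0.5, length.out = 11)
  lin <- fit_quenching(Q, 1000 / (1 + 4 * Q))
  expect_equal(lin$V, 0, tolerance = 1e-6)
  expect_equal(lin$Ksv, 4, tolerance = 1e-6)
})

test_that("quenching fitter validates its input", {
  Q <- seq(0, 0.5, length.out = 11)
  F_ok <- 1000 / (1 + 4 * Q)
  expect_error(fit_quenching(Q[1:3], F_ok[1:3]), "at least 6")
  expect_error(fit_quenching(Q[-1], F_ok[-1]), "Q = 0")
  expect_error(fit_quenching(Q, 1000 * (1 + Q)), "does not decrease")
})

test_that("fit dispersion shrinks with noise and grid density", {
  spread_at <- function(noise, n_points) {
    conc <- seq(0, 25, length.out = n_points)
    kds <- vapply(1:30, function(s) {
      cur <- gen_titration_curve(2.5, conc_grid = conc,
                                 noise_fraction = noise, seed = s)
      fit_titration(cur$conc_uM, cur$signal)$Kd
    }, numeric(1))
    c(bias = abs(median(kds) - 2.5), iqr = IQR(kds))
  }
  lo <- spread_at(0.005, 25); mid <- spread_at(0.02, 25)
  hi <- spread_at(0.08, 25); sparse <- spread_at(0.02, 12)
  expect_lt(lo["iqr"], mid["iqr"])
  expect_lt(mid["iqr"], hi["iqr"])
  expect_lt(mid["iqr"], sparse["iqr"] * 1.5)
  expect_lt(lo["bias"], 0.1)
})
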