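#' Construct a kinetic trace
#'
#' One thioflavin-T time series with its condition metadata.
#'
#' @param times Time points in hours, strictly increasing.
#' @param signal ThT fluorescence (a.u.), same length as `times`, finite.
#' @param protein_conc Protein concentration in uM.
#' @param pom_id Inhibitor label (`"none"`, `"Nb10"`, `"TiNb9"`, ...).
#' @param pom_conc Inhibitor concentration in uM.
#' @param replicate Replicate index.
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(times, signal, protein_conc = NA_real_,
                          pom_id = "none", pom_conc = 0, replicate = 1L) {
  times <- as.numeric(times)
  signal <- as.numeric(signal)
  if (length(times) != length(signal))
    stop("times and signal must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(signal)))
    stop("signal must be finite", call. = FALSE)
  structure(
    list(times = times, signal = signal, protein_conc = protein_conc,
         pom_id = pom_id, pom_conc = pom_conc, replicate = replicate),
    class = "kinetic_trace"
  )
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> %d points, %.3g-%.3g h | %s %g uM (rep %s)\n",
              length(x$times), min(x$times), max(x$times),
              x$pom_id, x$pom_conc, x$replicate))
  invisible(x)
}

#' Normalize a kinetic panel to its inhibitor-free reference
#'
#' Divides every trace's signal by the maximum of the reference
#' (inhibitor-free) traces, averaged over reference replicates, so the
#' reference maximum maps to 1.0 — the normalization used for plotted
#' amyloid kinetics.
#'
#' @param traces List of [kinetic_trace()] objects.
#' @param reference_condition `pom_id` label of the reference condition.
#' @return The list of traces with rescaled signals.
#' @export
normalize_panel <- function(traces, reference_condition = "none") {
  ids <- vapply(traces, function(tr) tr$pom_id, character(1))
  ref <- traces[ids == reference_condition]
  if (length(ref) == 0L)
    stop(sprintf("reference condition '%s' not present in panel",
                 reference_condition), call. = FALSE)
  ref_max <- mean(vapply(ref, function(tr) max(tr$signal), numeric(1)))
  if (ref_max <= 0)
    stop("reference maximum is not positive; cannot normalize",
         call. = FALSE)
  lapply(traces, function(tr) {
    tr$signal <- tr$signal / ref_max
    tr
  })
}

# Bounded Levenberg-Marquardt fit with multi-start fallback: on failure the
# named start parameters in `perturb` are multiplied by 5 log-spaced factors.
.nls_multistart <- function(formula, data, start, lower, upper,
                            perturb = names(start), n_extra = 5L) {
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, maxiter = 500,
                                     maxfev = 2000)
  try_fit <- function(st) {
    tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        lower = lower, upper = upper, control = ctrl),
      error = function(e) e
    )
  }
  fit <- try_fit(start)
  if (!inherits(fit, "error")) return(fit)
  factors <- 10^seq(-1, 1, length.out = n_extra)
  for (f in factors) {
    st <- start
    for (nm in perturb) st[[nm]] <- st[[nm]] * f
    fit <- try_fit(st)
    if (!inherits(fit, "error")) return(fit)
  }
  fit
}

.se_of <- function(fit, name) {
  s <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  if (is.null(s) || !(name %in% rownames(s))) return(NA_real_)
  unname(s[name, "Std. Error"])
}

#' Fit the isodesmic kinetic model to a trace
#'
#' Least-squares fit of
#' `signal(t) = baseline + amplitude * k*t / (1 + k*t)`
#' with `k > 0` and `amplitude >= 0`. The starting rate comes from the
#' time at which the signal crosses half of its total change (`p = 0.5`
#' at `k*t = 1`); five log-spaced restarts are tried on non-convergence.
#'
#' @param trace A [kinetic_trace()]; at least 8 time points spanning the
#'   growth and the approach to plateau.
#' @return An object of class `kinetic_fit` with elements `k`,
#'   `amplitude`, `baseline`, `se_k`, `rss`, `n`, plus the trace
#'   metadata (`pom_id`, `pom_conc`, `replicate`).
#' @export
fit_kinetic_trace <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  t <- trace$times
  y <- trace$signal
  if (length(t) < 8L)
    stop("at least 8 time points are required", call. = FALSE)
  rng <- diff(range(y))
  if (rng == 0)
    stop("kinetic fit failed: constant signal", call. = FALSE)
  if (all(diff(y) <= 0))
    stop("kinetic fit failed: monotonically decreasing signal",
         call. = FALSE)
  base0 <- min(y)
  amp0 <- max(y) - base0
  half <- base0 + amp0 / 2
  i_half <- which(y >= half)[1]
  t_half <- max(t[i_half], t[t > 0][1], na.rm = TRUE)
  k0 <- 1 / t_half
  d <- data.frame(t = t, y = y)
  fit <- .nls_multistart(
    y ~ baseline + amplitude * (k * t / (1 + k * t)),
    data = d,
    start = list(k = k0, amplitude = amp0, baseline = base0),
    lower = c(k = 1e-12, amplitude = 0, baseline = -Inf),
    upper = c(k = Inf, amplitude = Inf, baseline = Inf),
    perturb = "k"
  )
  if (inherits(fit, "error"))
    stop("kinetic fit failed to converge: ", conditionMessage(fit),
         call. = FALSE)
  cf <- stats::coef(fit)
  structure(
    list(k = unname(cf["k"]), amplitude = unname(cf["amplitude"]),
         baseline = unname(cf["baseline"]), se_k = .se_of(fit, "k"),
         rss = sum(stats::residuals(fit)^2), n = length(t),
         pom_id = trace$pom_id, pom_conc = trace$pom_conc,
         replicate = trace$replicate),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> k = %.4g +/- %.2g 1/h, amplitude = %.4g, baseline = %.4g (rss %.3g, n %d)\n",
              x$k, x$se_k, x$amplitude, x$baseline, x$rss, x$n))
  invisible(x)
}

#' Fit the exponential rate-versus-concentration model
#'
#' Least-squares estimate of `k(c) = alpha*exp(-beta*c) + gamma` (or the
#' scale variant `exp(-c/beta)`) from apparent rates at a series of
#' inhibitor concentrations, with `alpha` and `beta` bounded at zero
#' (the model describes an inhibitor: a non-negative amplitude decaying
#' with concentration). If the rates do not decrease with concentration
#' the decay is unidentifiable — `beta` (or `alpha`) pins at its zero
#' bound — and the fit is flagged (`beta_at_bound`).
#'
#' @param conc Inhibitor concentrations in uM (>= 4 distinct values
#'   including 0).
#' @param rates Apparent rate constants in 1/h, same length.
#' @param parameterization Passed to [rate_vs_conc()].
#' @return An object of class `rate_conc_fit` with `alpha`, `beta`,
#'   `gamma`, standard errors, `rss` and the `beta_at_bound` flag.
#' @export
fit_rate_concentration <- function(conc, rates,
                                   parameterization = c("rate", "scale")) {
  parameterization <- match.arg(parameterization)
  if (length(conc) != length(rates))
    stop("conc and rates must have equal length", call. = FALSE)
  if (length(unique(conc)) < 4L)
    stop("at least 4 distinct concentrations are required", call. = FALSE)
  if (!any(conc == 0))
    stop("a zero-concentration point is required", call. = FALSE)
  d <- data.frame(c = conc, k = rates)
  gamma0 <- min(rates)
  alpha0 <- max(max(rates) - gamma0, 1e-8)
  c_pos <- sort(unique(conc[conc > 0]))
  c_mid <- c_pos[ceiling(length(c_pos) / 2)]
  form <- if (parameterization == "rate") {
    k ~ alpha * exp(-beta * c) + gamma
  } else {
    k ~ alpha * exp(-c / beta) + gamma
  }
  beta0 <- if (parameterization == "rate") log(2) / c_mid else c_mid / log(2)
  beta_lower <- if (parameterization == "rate") 0 else 1e-9
  fit <- .nls_multistart(
    form, data = d,
    start = list(alpha = alpha0, beta = beta0, gamma = gamma0),
    lower = c(alpha = 0, beta = beta_lower, gamma = -Inf),
    upper = c(alpha = Inf, beta = Inf, gamma = Inf),
    perturb = "beta"
  )
  if (inherits(fit, "error")) {
    # Degenerate (e.g. concentration-independent) rates: beta -> 0 leaves
    # only alpha + gamma identifiable; report the mean rate at the bound.
    return(structure(
      list(alpha = 0, beta = 0, gamma = mean(rates),
           se_alpha = NA_real_, se_beta = NA_real_,
           se_gamma = stats::sd(rates) / sqrt(length(rates)),
           rss = sum((rates - mean(rates))^2),
           beta_at_bound = TRUE, parameterization = parameterization),
      class = "rate_conc_fit"
    ))
  }
  cf <- stats::coef(fit)
  structure(
    list(alpha = unname(cf["alpha"]), beta = unname(cf["beta"]),
         gamma = unname(cf["gamma"]),
         se_alpha = .se_of(fit, "alpha"), se_beta = .se_of(fit, "beta"),
         se_gamma = .se_of(fit, "gamma"),
         rss = sum(stats::residuals(fit)^2),
         beta_at_bound = unname(cf["beta"]) <= beta_lower + 1e-10 ||
           unname(cf["alpha"]) <= 1e-6 * mean(abs(rates)),
         parameterization = parameterization),
    class = "rate_conc_fit"
  )
}

#' @export
print.rate_conc_fit <- function(x, ...) {
  cat(sprintf("<rate_conc_fit> alpha = %.4g, beta = %.4g, gamma = %.4g (rss %.3g)%s\n",
              x$alpha, x$beta, x$gamma, x$rss,
              if (isTRUE(x$beta_at_bound)) " [beta at bound]" else ""))
  invisible(x)
}

#' Fit a one-site binding isotherm to a fluorescence titration
#'
#' Least-squares fit of `S(c) = S0 + (Sinf - S0) * theta(c)` with
#' `theta` the one-site bound fraction (optionally depletion-corrected)
#' and `Kd > 0`. Standard errors come from the converged fit covariance;
#' a seeded residual bootstrap is available. A curve whose fitted signal
#' change is below the residual noise is flagged unidentifiable rather
#' than reported as a binding constant.
#'
#' @param conc Ligand concentrations in uM (>= 5 values spanning the
#'   apparent Kd, including a zero or near-zero point).
#' @param signal Measured signal (a.u.), same length.
#' @param depletion If `TRUE`, fit the depletion-corrected isotherm with
#'   protein concentration `P` uM.
#' @param P Protein concentration in uM for the depletion correction.
#' @param bootstrap Number of residual-bootstrap replicates (0 = none).
#' @param seed Seed for the bootstrap.
#' @return An object of class `binding_fit` with `Kd`, `S0`, `Sinf`,
#'   standard errors, `rss`, `unidentifiable` flag and (optionally)
#'   `boot_se_Kd`.
#' @export
fit_titration <- function(conc, signal, depletion = FALSE, P = 4,
                          bootstrap = 0, seed = 1L) {
  if (length(conc) != length(signal))
    stop("conc and signal must have equal length", call. = FALSE)
  if (length(conc) < 5L)
    stop("at least 5 concentrations are required", call. = FALSE)
  if (any(conc < 0)) stop("concentrations must be non-negative",
                          call. = FALSE)
  d <- data.frame(c = conc, S = signal)
  S0_0 <- signal[which.min(conc)]
  Sinf_0 <- signal[which.max(conc)]
  if (S0_0 == Sinf_0) Sinf_0 <- Sinf_0 * (1 + 1e-3) + 1e-6
  half <- (S0_0 + Sinf_0) / 2
  past_half <- if (Sinf_0 < S0_0) which(signal <= half) else which(signal >= half)
  Kd0 <- if (length(past_half)) max(conc[past_half[1]], min(conc[conc > 0]))
         else stats::median(conc[conc > 0])
  form <- if (depletion) {
    S ~ S0 + (Sinf - S0) * binding_fraction_depletion(c, Kd, P)
  } else {
    S ~ S0 + (Sinf - S0) * (c / (Kd + c))
  }
  fit <- .nls_multistart(
    form, data = d,
    start = list(Kd = Kd0, S0 = S0_0, Sinf = Sinf_0),
    lower = c(Kd = 1e-9, S0 = -Inf, Sinf = -Inf),
    upper = c(Kd = Inf, S0 = Inf, Sinf = Inf),
    perturb = "Kd"
  )
  if (inherits(fit, "error")) {
    # A curve with no resolvable signal change gives a singular fit:
    # report it as unidentifiable rather than fail.
    return(structure(
      list(Kd = NA_real_, S0 = mean(signal), Sinf = mean(signal),
           se_Kd = NA_real_, se_S0 = NA_real_, se_Sinf = NA_real_,
           rss = sum((signal - mean(signal))^2),
           unidentifiable = TRUE, depletion = depletion),
      class = "binding_fit"
    ))
  }
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  sigma <- sqrt(sum(res^2) / max(length(res) - 3L, 1L))
  unident <- abs(cf["Sinf"] - cf["S0"]) < 2 * sigma
  out <- list(Kd = unname(cf["Kd"]), S0 = unname(cf["S0"]),
              Sinf = unname(cf["Sinf"]),
              se_Kd = .se_of(fit, "Kd"), se_S0 = .se_of(fit, "S0"),
              se_Sinf = .se_of(fit, "Sinf"),
              rss = sum(res^2), unidentifiable = unname(unident),
              depletion = depletion)
  if (bootstrap > 0) {
    fitted_S <- stats::fitted(fit)
    boot_kd <- withr::with_seed(seed, {
      vapply(seq_len(bootstrap), function(i) {
        yb <- fitted_S + sample(res, replace = TRUE)
        fb <- tryCatch(
          fit_titration(conc, yb, depletion = depletion, P = P),
          error = function(e) NULL)
        if (is.null(fb)) NA_real_ else fb$Kd
      }, numeric(1))
    })
    out$boot_se_Kd <- stats::sd(boot_kd, na.rm = TRUE)
    out$boot_n <- bootstrap
  }
  structure(out, class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (isTRUE(x$unidentifiable)) {
    cat("<binding_fit> unidentifiable: signal change below residual noise\n")
  } else {
    cat(sprintf("<binding_fit> Kd = %.4g +/- %.2g uM, S0 = %.4g, Sinf = %.4g (rss %.3g)%s\n",
                x$Kd, x$se_Kd, x$S0, x$Sinf, x$rss,
                if (isTRUE(x$depletion)) " [depletion-corrected]" else ""))
  }
  invisible(x)
}

#' Fit the sphere-of-action quenching model
#'
#' Forms the Stern-Volmer ratio `F0/F` using the measured zero-quencher
#' point as `F0` (not fitted), then estimates `(Ksv, V)` in
#' `F0/F = (1 + Ksv*Q) * exp(V*Q)` by bounded least squares and derives
#' the sphere-of-action radius from the action volume.
#'
#' @param Q Quencher concentrations in M (>= 6 values including 0).
#' @param F Fluorescence (a.u.), same length, positive.
#' @return An object of class `quench_fit` with `Ksv`, `V`, `r`
#'   (Angstrom), standard errors (`se_r` by first-order propagation) and
#'   `rss` on the ratio scale.
#' @export
fit_quenching <- function(Q, F) {
  if (length(Q) != length(F))
    stop("Q and F must have equal length", call. = FALSE)
  if (length(Q) < 6L)
    stop("at least 6 quencher concentrations are required", call. = FALSE)
  if (!any(Q == 0))
    stop("a zero-quencher (Q = 0) point is required", call. = FALSE)
  if (any(F <= 0)) stop("fluorescence must be positive", call. = FALSE)
  F0 <- mean(F[Q == 0])
  slope <- stats::coef(stats::lm(I(F0 / F) ~ Q))[2]
  if (slope <= 0)
    stop("quenching fit failed: fluorescence does not decrease with quencher",
         call. = FALSE)
  d <- data.frame(Q = Q, ratio = F0 / F)
  fit <- .nls_multistart(
    ratio ~ (1 + Ksv * Q) * exp(V * Q),
    data = d,
    start = list(Ksv = max(unname(slope), 1e-6), V = 0),
    lower = c(Ksv = 0, V = 0),
    upper = c(Ksv = Inf, V = Inf),
    perturb = "Ksv"
  )
  if (inherits(fit, "error"))
    stop("quenching fit failed to converge: ", conditionMessage(fit),
         call. = FALSE)
  cf <- stats::coef(fit)
  V <- unname(cf["V"])
  se_V <- .se_of(fit, "V")
  r <- action_volume_to_radius(V)
  # dr/dV = r / (3V); undefined at V = 0
  se_r <- if (V > 0 && is.finite(se_V)) r / (3 * V) * se_V else NA_real_
  structure(
    list(Ksv = unname(cf["Ksv"]), V = V, r = r,
         se_Ksv = .se_of(fit, "Ksv"), se_V = se_V, se_r = se_r,
         F0 = F0, rss = sum(stats::residuals(fit)^2), n = length(Q)),
    class = "quench_fit"
  )
}

#' @export
print.quench_fit <- function(x, ...) {
  cat(sprintf("<quench_fit> Ksv = %.4g +/- %.2g 1/M, V = %.4g 1/M, r = %.3g A (rss %.3g)\n",
              x$Ksv, x$se_Ksv, x$V, x$r, x$rss))
  invisible(x)
}
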