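#' Design of a synthetic kinetic panel
#'
#' Defaults mirror the experimental design of the aggregation assay:
#' 75 uM protein, protein:inhibitor molar ratios 0 and 1:0.5 through
#' 1:10, 150 h of incubation sampled every 10 minutes, triplicate wells
#' and 2% multiplicative plate-reader noise.
#'
#' @param protein_conc Protein concentration in uM.
#' @param ratios Inhibitor:protein molar ratios (0 = inhibitor-free
#'   reference).
#' @param time_grid Time grid in hours, increasing.
#' @param noise_fraction Multiplicative Gaussian noise fraction.
#' @param n_replicates Replicates per condition.
#' @param seed Integer seed.
#' @return A list of class `panel_design`.
#' @export
panel_design <- function(protein_conc = 75,
                         ratios = c(0, 0.5, 1, 2, 4, 8, 10),
                         time_grid = seq(0, 150, by = 1 / 6),
                         noise_fraction = 0.02,
                         n_replicates = 3L,
                         seed = 1L) {
  if (any(ratios < 0)) stop("ratios must be non-negative", call. = FALSE)
  if (any(diff(time_grid) <= 0))
    stop("time grid must be increasing", call. = FALSE)
  if (noise_fraction < 0)
    stop("noise fraction must be non-negative", call. = FALSE)
  structure(list(protein_conc = protein_conc, ratios = ratios,
                 time_grid = time_grid, noise_fraction = noise_fraction,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "panel_design")
}

# Default dose-response shapes for the generator: an uninhibited apparent
# rate of ~0.2 1/h falling nearly to its offset across the 37.5-750 uM
# inhibitor range, and a plateau falling from 1.0 towards ~0.14 over the
# same range.
default_rate_model <- function() list(alpha = 0.2, beta = 0.01, gamma = 0.005)
default_plateau_model <- function() list(alpha = 0.9, beta = 0.004, gamma = 0.1)

#' Generate a synthetic aggregation-kinetics panel
#'
#' For each inhibitor:protein ratio in the design, the inhibitor
#' concentration is `ratio * protein_conc`; the apparent rate follows
#' the exponential dose-response [rate_vs_conc()] with `rate_model`, and
#' the plateau amplitude decays with the same functional family
#' (`plateau_model`), reproducing the joint suppression of rate and
#' plateau seen for polyoxometalate inhibition. Traces are
#' `baseline + amplitude * p(t)` from [isodesmic_extent()] (lag-free,
#' hyperbolic) with multiplicative Gaussian noise; fully reproducible
#' given the design seed.
#'
#' @param design A [panel_design()].
#' @param rate_model,plateau_model Lists with `alpha`, `beta`, `gamma`
#'   for [rate_vs_conc()].
#' @param baseline Baseline signal (a.u.).
#' @param pom_id Label for the inhibitor conditions.
#' @return A list of [kinetic_trace()] objects (reference conditions get
#'   `pom_id = "none"`).
#' @export
gen_kinetic_panel <- function(design = panel_design(),
                              rate_model = default_rate_model(),
                              plateau_model = default_plateau_model(),
                              baseline = 0.02,
                              pom_id = "POM") {
  stopifnot(inherits(design, "panel_design"))
  withr::with_seed(design$seed, {
    traces <- list()
    for (ratio in design$ratios) {
      c_pom <- ratio * design$protein_conc
      k <- rate_vs_conc(c_pom, rate_model$alpha, rate_model$beta,
                        rate_model$gamma)
      amp <- rate_vs_conc(c_pom, plateau_model$alpha, plateau_model$beta,
                          plateau_model$gamma)
      p <- isodesmic_extent(design$time_grid, k)
      for (rep_i in seq_len(design$n_replicates)) {
        y <- baseline + amp * p
        if (design$noise_fraction > 0)
          y <- y * (1 + stats::rnorm(length(y), sd = design$noise_fraction))
        traces[[length(traces) + 1L]] <- kinetic_trace(
          design$time_grid, y,
          protein_conc = design$protein_conc,
          pom_id = if (ratio == 0) "none" else pom_id,
          pom_conc = c_pom, replicate = rep_i)
      }
    }
    traces
  })
}

#' Generate a synthetic fluorescence titration curve
#'
#' One-site binding signal [titration_signal()] with multiplicative
#' Gaussian noise; seeded.
#'
#' @param Kd Dissociation constant in uM.
#' @param S0,Sinf Signals at zero ligand and saturation (a.u.).
#' @param conc_grid Ligand concentrations in uM.
#' @param noise_fraction Multiplicative Gaussian noise fraction.
#' @param seed Integer seed.
#' @return A data.frame with columns `conc_uM` and `signal`.
#' @export
gen_titration_curve <- function(Kd, S0 = 100, Sinf = 40,
                                conc_grid = seq(0, 25, length.out = 25),
                                noise_fraction = 0.02, seed = 1L) {
  s <- titration_signal(conc_grid, Kd, S0, Sinf)
  if (noise_fraction > 0)
    s <- withr::with_seed(seed,
      s * (1 + stats::rnorm(length(s), sd = noise_fraction)))
  data.frame(conc_uM = conc_grid, signal = s)
}

#' Generate a synthetic acrylamide quenching curve
#'
#' Fluorescence `F = F0 / ((1 + Ksv*Q) exp(V*Q))` from the
#' sphere-of-action model, with the action volume derived from the given
#' radius, plus multiplicative Gaussian noise on F. The grid includes
#' Q = 0 (required to form Stern-Volmer ratios).
#'
#' @param Ksv Stern-Volmer constant, 1/M.
#' @param r Sphere-of-action radius, Angstrom.
#' @param Q_grid Quencher concentrations in M (must include 0).
#' @param F0 Unquenched fluorescence (a.u.).
#' @param noise_fraction Multiplicative Gaussian noise fraction.
#' @param seed Integer seed.
#' @return A data.frame with columns `Q_M` and `F`.
#' @export
gen_quenching_curve <- function(Ksv, r, Q_grid = seq(0, 0.5, length.out = 11),
                                F0 = 1000, noise_fraction = 0.01, seed = 1L) {
  if (!any(Q_grid == 0)) stop("Q grid must include 0", call. = FALSE)
  V <- radius_to_action_volume(r)
  f <- F0 / sphere_of_action_ratio(Q_grid, Ksv, V)
  if (noise_fraction > 0)
    f <- withr::with_seed(seed,
      f * (1 + stats::rnorm(length(f), sd = noise_fraction)))
  data.frame(Q_M = Q_grid, F = f)
}

#' Generate a synthetic spectrum
#'
#' Sum-of-Gaussians signal on a wavelength grid with independent
#' additive Gaussian noise per repeat scan (noise sd = `noise_fraction`
#' x the maximum absolute noiseless signal).
#'
#' @param peaks List of `c(centre, width, amplitude)` triples
#'   (nm, nm, signal units).
#' @param grid Wavelength grid in nm.
#' @param noise_fraction Noise amplitude relative to the signal maximum.
#' @param n_repeats Number of repeat scans.
#' @param seed Integer seed.
#' @return A [spectrum_data()]; carries `repeats` when `n_repeats > 1`.
#' @export
gen_spectrum <- function(peaks = list(c(340, 20, 1)),
                         grid = seq(300, 400, by = 1),
                         noise_fraction = 0, n_repeats = 1L, seed = 1L) {
  base <- rep(0, length(grid))
  for (pk in peaks)
    base <- base + pk[3] * exp(-(grid - pk[1])^2 / (2 * pk[2]^2))
  sd_noise <- noise_fraction * max(abs(base))
  if (n_repeats <= 1L && sd_noise == 0)
    return(spectrum_data(grid, base))
  reps <- withr::with_seed(seed, {
    vapply(seq_len(max(n_repeats, 1L)), function(i) {
      base + if (sd_noise > 0) stats::rnorm(length(grid), sd = sd_noise)
             else 0
    }, numeric(length(grid)))
  })
  if (n_repeats > 1L) spectrum_data(grid, repeats = reps)
  else spectrum_data(grid, reps[, 1])
}

#' Generate synthetic fibril cross-sectional heights
#'
#' Draws from a log-normal distribution (guaranteeing positivity)
#' parameterized so that the population median equals `median` and the
#' population median absolute deviation from the median equals `spread`;
#' the sample summary converges to these targets as n grows.
#'
#' @param median Target median height in nm.
#' @param spread Target median deviation in nm.
#' @param n Number of measurements.
#' @param seed Integer seed.
#' @return Numeric vector of heights (nm).
#' @export
gen_heights <- function(median = 2.1, spread = 0.35, n = 100L, seed = 1L) {
  if (median <= 0 || spread <= 0) stop("median and spread must be positive",
                                       call. = FALSE)
  sigma <- .lognormal_sigma_for_mad(median, spread)
  withr::with_seed(seed,
    stats::rlnorm(n, meanlog = log(median), sdlog = sigma))
}

# Solve for the log-normal sdlog whose median absolute deviation about
# the median log(median)=mu equals the target spread.
.lognormal_sigma_for_mad <- function(med, target_mad) {
  mu <- log(med)
  mad_of <- function(sigma) {
    stats::uniroot(function(d) {
      stats::plnorm(med + d, mu, sigma) -
        stats::plnorm(max(med - d, 0), mu, sigma) - 0.5
    }, lower = 1e-12, upper = med * (exp(6 * sigma) + 1))$root
  }
  stats::uniroot(function(sigma) mad_of(sigma) - target_mad,
                 lower = 1e-6, upper = 5)$root
}
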