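#' Closed-form models for amyloid inhibition analysis
#'
#' Pure model functions used by the fitters and the synthetic-data
#' generators: isodesmic polymerization kinetics (irreversible and
#' reversible), exponential decay of the apparent rate with inhibitor
#' concentration, the one-site binding isotherm, sphere-of-action
#' fluorescence quenching, and the action-volume/radius conversion.
#'
#' @name models
NULL

#' Extent of reaction for irreversible isodesmic polymerization
#'
#' Step-growth (isodesmic) self-assembly with equal rate constants for
#' every addition step and negligible depolymerization gives a hyperbolic,
#' lag-free extent of reaction
#' \deqn{p(t) = \frac{k t}{1 + k t}}
#' where `k` is the apparent polymerization rate constant. This is the
#' kinetic model fitted to thioflavin-T traces of S100A9 aggregation.
#'
#' @param t Time in hours (vector, non-negative).
#' @param k Apparent polymerization rate constant in 1/h (non-negative
#'   scalar).
#' @return Extent of reaction in \[0, 1), same length as `t`.
#' @examples
#' isodesmic_extent(c(0, 1, 10), k = 1)
#' @export
isodesmic_extent <- function(t, k) {
  stopifnot(is.numeric(t), is.numeric(k), length(k) == 1L)
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  if (k < 0) stop("rate constant k must be non-negative", call. = FALSE)
  k * t / (1 + k * t)
}

#' Extent of reaction for reversible isodesmic polymerization
#'
#' Closed-form solution of the isodesmic step-growth kinetics with a
#' backward (depolymerization) step,
#' \deqn{dp/dt = k_f c_0 (1-p)^2 - k_b p, \quad p(0) = 0,}
#' a Riccati equation with constant coefficients. Writing
#' \eqn{a = k_f c_0}, \eqn{s = \sqrt{k_b (k_b + 4a)}} and root
#' \eqn{p_- = (2a + k_b - s) / (2a)} the solution is
#' \deqn{p(t) = \frac{1 - e^{-s t}}{s/a + p_- (1 - e^{-s t})}.}
#' The extent rises monotonically to the equilibrium value
#' \eqn{p_{eq} = p_- < 1}. When `k_b = 0` this reduces exactly to
#' [isodesmic_extent()] with `k = k_f * c0`.
#'
#' @param t Time in hours (vector, non-negative).
#' @param k_f Forward step rate, 1/(concentration h), non-negative.
#' @param k_b Backward step rate, 1/h, non-negative.
#' @param c0 Total monomer concentration (same concentration unit as
#'   `1/k_f`), positive.
#' @return Extent of reaction in \[0, 1), same length as `t`.
#' @export
isodesmic_extent_reversible <- function(t, k_f, k_b, c0) {
  stopifnot(is.numeric(t), length(k_f) == 1L, length(k_b) == 1L,
            length(c0) == 1L)
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  if (k_f < 0 || k_b < 0) stop("rates must be non-negative", call. = FALSE)
  if (c0 <= 0) stop("monomer concentration c0 must be positive", call. = FALSE)
  a <- k_f * c0
  if (k_b == 0) return(isodesmic_extent(t, a))
  if (a == 0) return(rep(0, length(t)))
  s <- sqrt(k_b * (k_b + 4 * a))
  p_minus <- (2 * a + k_b - s) / (2 * a)
  e <- -expm1(-s * t)            # 1 - exp(-s t), stable for small s*t
  e / (s / a + p_minus * e)
}

#' Apparent rate constant versus inhibitor concentration
#'
#' Single-exponential decay with offset,
#' \deqn{k(c) = \alpha e^{-\beta c} + \gamma}
#' describing the suppression of the apparent polymerization rate with
#' increasing polyoxometalate concentration. `beta` is the relative
#' susceptibility of the rate to the inhibitor; `alpha` and `gamma` set
#' the uninhibited amplitude and the residual rate at saturation. An
#' alternative scale parameterization \eqn{k(c) = \alpha e^{-c/\beta} +
#' \gamma} is available.
#'
#' @param c Inhibitor concentration in uM (vector, non-negative).
#' @param alpha Rate amplitude, 1/h.
#' @param beta Susceptibility (1/uM for `"rate"`, uM for `"scale"`),
#'   non-negative.
#' @param gamma Residual rate offset, 1/h.
#' @param parameterization `"rate"` (default, `exp(-beta*c)`) or
#'   `"scale"` (`exp(-c/beta)`).
#' @return Apparent rate k(c) in 1/h.
#' @export
rate_vs_conc <- function(c, alpha, beta, gamma,
                         parameterization = c("rate", "scale")) {
  parameterization <- match.arg(parameterization)
  if (any(c < 0)) stop("concentration must be non-negative", call. = FALSE)
  if (beta < 0) stop("beta must be non-negative", call. = FALSE)
  if (parameterization == "rate") {
    alpha * exp(-beta * c) + gamma
  } else {
    if (beta == 0) stop("scale parameterization requires beta > 0",
                        call. = FALSE)
    alpha * exp(-c / beta) + gamma
  }
}

#' One-site binding isotherm
#'
#' Fraction of the ligand-protein complex assuming a single class of
#' binding sites, \eqn{\theta(c) = c / (K_d + c)}, with `c` the total
#' ligand (polyoxometalate) concentration.
#'
#' @param c Ligand concentration in uM (vector, non-negative).
#' @param Kd Dissociation constant in uM, positive.
#' @return Bound fraction in \[0, 1).
#' @export
binding_fraction <- function(c, Kd) {
  if (any(c < 0)) stop("concentration must be non-negative", call. = FALSE)
  if (!is.numeric(Kd) || length(Kd) != 1L || Kd <= 0)
    stop("Kd must be a positive scalar", call. = FALSE)
  c / (Kd + c)
}

#' Depletion-corrected one-site binding fraction
#'
#' Exact solution for the bound fraction of protein when the titrated
#' ligand concentration `c` is the *total* (not free) concentration and
#' the protein concentration `P` is comparable to Kd, so ligand
#' depletion is non-negligible:
#' \deqn{\theta = \frac{(P + c + K_d) - \sqrt{(P + c + K_d)^2 - 4 P c}}{2P}.}
#'
#' @inheritParams binding_fraction
#' @param P Protein concentration in uM, positive.
#' @return Bound fraction of protein in \[0, 1\].
#' @export
binding_fraction_depletion <- function(c, Kd, P) {
  if (any(c < 0)) stop("concentration must be non-negative", call. = FALSE)
  if (Kd <= 0) stop("Kd must be positive", call. = FALSE)
  if (P <= 0) stop("protein concentration must be positive", call. = FALSE)
  b <- P + c + Kd
  (b - sqrt(b^2 - 4 * P * c)) / (2 * P)
}

#' Fluorescence signal along a titration
#'
#' Maps the bound fraction onto the measured signal,
#' \eqn{S(c) = S_0 + (S_\infty - S_0)\,\theta(c)}; handles both
#' decreasing (`Sinf < S0`, as observed for tryptophan and ANS
#' fluorescence on polyoxometalate binding) and increasing signals.
#'
#' @inheritParams binding_fraction
#' @param S0 Signal at zero ligand (a.u.).
#' @param Sinf Signal at saturation (a.u.).
#' @param depletion If `TRUE`, use the depletion-corrected bound
#'   fraction with protein concentration `P`.
#' @param P Protein concentration in uM (used when `depletion = TRUE`).
#' @return Signal in the units of `S0`/`Sinf`.
#' @export
titration_signal <- function(c, Kd, S0, Sinf, depletion = FALSE, P = 4) {
  theta <- if (depletion) binding_fraction_depletion(c, Kd, P)
           else binding_fraction(c, Kd)
  S0 + (Sinf - S0) * theta
}

#' Sphere-of-action Stern-Volmer quenching ratio
#'
#' Stern-Volmer law with a static sphere-of-action correction,
#' \deqn{F_0/F = (1 + K_{SV} Q)\, e^{V Q},}
#' where `Ksv` is the dynamic Stern-Volmer constant and `V` the
#' effective action volume (1/M) within which a quencher adjacent to the
#' fluorophore at the moment of excitation quenches instantly. The
#' upward curvature of the plot comes from the exponential factor;
#' `V = 0` recovers the linear Stern-Volmer law.
#'
#' @param Q Quencher concentration in M (vector, non-negative).
#' @param Ksv Stern-Volmer constant, 1/M, non-negative.
#' @param V Sphere-of-action volume, 1/M, non-negative.
#' @return F0/F ratio (>= 1).
#' @export
sphere_of_action_ratio <- function(Q, Ksv, V) {
  if (any(Q < 0)) stop("quencher concentration must be non-negative",
                       call. = FALSE)
  if (Ksv < 0 || V < 0) stop("Ksv and V must be non-negative", call. = FALSE)
  (1 + Ksv * Q) * exp(V * Q)
}

#' Convert a sphere-of-action volume to an equivalent radius
#'
#' Litre-based convention: the action volume in 1/M equals Avogadro's
#' number times the per-molecule sphere volume in litres,
#' \eqn{V = N_A \cdot \tfrac{4}{3}\pi r^3} with `r` expressed in dm
#' (1 Angstrom = 1e-9 dm). With this convention fitted Stern-Volmer-scale
#' volumes of order 1 1/M give radii of 7-9 Angstrom. The convention is
#' isolated here so an alternative can be swapped in one place.
#'
#' @param V Action volume, 1/M, non-negative.
#' @return Radius in Angstrom.
#' @seealso [radius_to_action_volume()]
#' @export
action_volume_to_radius <- function(V) {
  if (any(V < 0)) stop("action volume must be non-negative", call. = FALSE)
  (V / (.avogadro * 4 / 3 * pi))^(1 / 3) * 1e9
}

#' @rdname action_volume_to_radius
#' @param r Radius in Angstrom, non-negative.
#' @return `radius_to_action_volume`: action volume in 1/M.
#' @export
radius_to_action_volume <- function(r) {
  if (any(r < 0)) stop("radius must be non-negative", call. = FALSE)
  .avogadro * 4 / 3 * pi * (r * 1e-9)^3
}

.avogadro <- 6.02214076e23
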