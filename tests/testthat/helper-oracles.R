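# Independent ODE oracle for the isodesmic kinetics:
#   dp/dt = kf*c0*(1-p)^2 - kb*p, p(0) = 0
ode_extent <- function(times, k_f, k_b, c0) {
  a <- k_f * c0
  out <- deSolve::ode(
    y = c(p = 0), times = times,
    func = function(t, y, parms) list(a * (1 - y)^2 - k_b * y),
    parms = NULL, rtol = 1e-10, atol = 1e-12)
  unname(out[, "p"])
}

# Direct-arithmetic oracle for the litre-based action-volume convention
# (Avogadro's number times a sphere volume in dm^3, radius given in Angstrom).
oracle_volume <- function(r_angstrom) {
  6.02214076e23 * (4 / 3) * pi * (r_angstrom * 1e-9)^3
}

make_noiseless_trace <- function(k = 0.05, amplitude = 1, baseline = 0.02,
                                 n = 90, t_end = 150, ...) {
  t <- seq(0, t_end, length.out = n)
  kinetic_trace(t, baseline + amplitude * isodesmic_extent(t, k), ...)
}
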