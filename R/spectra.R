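#' Construct a spectrum
#'
#' A wavelength-indexed signal (CD ellipticity in mdeg, or fluorescence
#' in a.u.) with optional per-scan repeats. When repeats are supplied,
#' `values` defaults to their pointwise mean.
#'
#' @param wavelengths Wavelengths in nm, strictly increasing.
#' @param values Signal values, same length (may be omitted when
#'   `repeats` is given).
#' @param repeats Optional matrix of per-scan values, one column per
#'   repeat, `length(wavelengths)` rows.
#' @return An object of class `spectrum_data`.
#' @export
spectrum_data <- function(wavelengths, values = NULL, repeats = NULL) {
  wavelengths <- as.numeric(wavelengths)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (!is.null(repeats)) {
    repeats <- as.matrix(repeats)
    if (nrow(repeats) != length(wavelengths))
      stop("repeats must have one row per wavelength", call. = FALSE)
    if (is.null(values)) values <- rowMeans(repeats)
  }
  if (is.null(values))
    stop("either values or repeats must be supplied", call. = FALSE)
  values <- as.numeric(values)
  if (length(values) != length(wavelengths))
    stop("wavelengths and values must have equal length", call. = FALSE)
  if (any(!is.finite(values)))
    stop("spectrum values must be finite", call. = FALSE)
  structure(list(wavelengths = wavelengths, values = values,
                 repeats = repeats),
            class = "spectrum_data")
}

#' @export
print.spectrum_data <- function(x, ...) {
  cat(sprintf("<spectrum_data> %d points, %.4g-%.4g nm%s\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              if (is.null(x$repeats)) ""
              else sprintf(", %d repeats", ncol(x$repeats))))
  invisible(x)
}

# Interpolate spectrum `s` onto grid `wl` over the overlap only;
# extrapolation is forbidden.
.interp_spectrum <- function(s, wl) {
  lo <- min(s$wavelengths); hi <- max(s$wavelengths)
  keep <- wl >= lo & wl <= hi
  if (!any(keep))
    stop("wavelength ranges do not overlap", call. = FALSE)
  list(keep = keep,
       values = stats::approx(s$wavelengths, s$values, xout = wl[keep])$y)
}

#' Subtract a background spectrum
#'
#' Pointwise subtraction of a buffer/ligand background from a sample
#' spectrum (repeats on the sample are propagated). On mismatched grids
#' the background is linearly interpolated onto the sample grid over
#' the overlapping range; points outside the overlap are dropped.
#'
#' @param sample,background [spectrum_data()] objects.
#' @return A background-subtracted [spectrum_data()].
#' @export
subtract_background <- function(sample, background) {
  stopifnot(inherits(sample, "spectrum_data"),
            inherits(background, "spectrum_data"))
  if (identical(sample$wavelengths, background$wavelengths)) {
    bg <- background$values
    keep <- rep(TRUE, length(sample$wavelengths))
  } else {
    it <- .interp_spectrum(background, sample$wavelengths)
    keep <- it$keep
    bg <- it$values
  }
  spectrum_data(
    sample$wavelengths[keep],
    sample$values[keep] - bg,
    repeats = if (!is.null(sample$repeats))
      sample$repeats[keep, , drop = FALSE] - bg
  )
}

# Reference-magnitude weights normalized to mean one. Isolated so the
# weighting convention can be swapped in a single place.
wsd_weights <- function(ref_values) {
  m <- mean(abs(ref_values))
  if (m == 0)
    stop("all-zero reference spectrum: WSD weights undefined", call. = FALSE)
  abs(ref_values) / m
}

#' Weighted spectral difference between two spectra
#'
#' Scalar dissimilarity used to decide whether two CD spectra differ
#' beyond replicate noise:
#' \deqn{WSD = \sqrt{\tfrac{1}{n} \sum_i w_i (ref_i - test_i)^2},
#'   \quad w_i = |ref_i| / \overline{|ref|},}
#' i.e. squared differences weighted by the reference magnitude, with
#' weights averaging to 1. WSD is zero iff the spectra are identical and
#' scales linearly with a uniform scaling of the difference at fixed
#' reference. It is *not* symmetric: the weights come from the
#' reference.
#'
#' @param reference,test [spectrum_data()] objects on a common
#'   wavelength grid with at least 10 points.
#' @return A list of class `wsd_result` with `wsd`, `sd` (`NA` here; see
#'   [wsd_uncertainty()]) and `n_pairs`.
#' @export
weighted_spectral_difference <- function(reference, test) {
  stopifnot(inherits(reference, "spectrum_data"),
            inherits(test, "spectrum_data"))
  if (!isTRUE(all.equal(reference$wavelengths, test$wavelengths)))
    stop("spectra must share a common wavelength grid", call. = FALSE)
  n <- length(reference$wavelengths)
  if (n < 10L) stop("at least 10 common points are required", call. = FALSE)
  w <- wsd_weights(reference$values)
  wsd <- sqrt(mean(w * (reference$values - test$values)^2))
  structure(list(wsd = wsd, sd = NA_real_, n_pairs = 1L),
            class = "wsd_result")
}

#' @export
print.wsd_result <- function(x, ...) {
  cat(sprintf("<wsd_result> WSD = %.5g%s (n_pairs %d)\n", x$wsd,
              if (is.finite(x$sd)) sprintf(" +/- %.3g", x$sd) else "",
              x$n_pairs))
  invisible(x)
}

#' WSD with repeat-based uncertainty
#'
#' Computes the weighted spectral difference on the repeat-mean spectra
#' and estimates its standard deviation from all pairings of individual
#' repeat scans (reference repeat i x test repeat j), the way replicate
#' CD scans are used to put error bars on WSD.
#'
#' @param reference,test [spectrum_data()] objects each carrying >= 2
#'   repeats on a common grid.
#' @return A `wsd_result` with `wsd` (from the repeat means), `sd` over
#'   the pairings, and `n_pairs`.
#' @export
wsd_uncertainty <- function(reference, test) {
  stopifnot(inherits(reference, "spectrum_data"),
            inherits(test, "spectrum_data"))
  if (is.null(reference$repeats) || ncol(reference$repeats) < 2L ||
      is.null(test$repeats) || ncol(test$repeats) < 2L)
    stop("both spectra must carry at least 2 repeats", call. = FALSE)
  mean_res <- weighted_spectral_difference(
    spectrum_data(reference$wavelengths, rowMeans(reference$repeats)),
    spectrum_data(test$wavelengths, rowMeans(test$repeats)))
  pair_wsd <- as.vector(vapply(seq_len(ncol(test$repeats)), function(j) {
    vapply(seq_len(ncol(reference$repeats)), function(i) {
      weighted_spectral_difference(
        spectrum_data(reference$wavelengths, reference$repeats[, i]),
        spectrum_data(test$wavelengths, test$repeats[, j]))$wsd
    }, numeric(1))
  }, numeric(ncol(reference$repeats))))
  structure(list(wsd = mean_res$wsd, sd = stats::sd(pair_wsd),
                 n_pairs = length(pair_wsd)),
            class = "wsd_result")
}

#' Locate a spectral maximum by the first-derivative method
#'
#' Smooths the spectrum with a Savitzky-Golay filter, finds the
#' positive-to-negative zero crossing of the first derivative, and
#' refines the peak position by linear interpolation of the derivative
#' between the bracketing grid points.
#'
#' @param spectrum A [spectrum_data()] containing an interior maximum.
#' @param smoothing_window Savitzky-Golay window length in points (odd;
#'   values < 3 disable smoothing).
#' @param poly_order Polynomial order of the smoothing filter.
#' @return Peak wavelength in nm.
#' @export
spectral_maximum <- function(spectrum, smoothing_window = 9L,
                             poly_order = 2L) {
  stopifnot(inherits(spectrum, "spectrum_data"))
  wl <- spectrum$wavelengths
  y <- spectrum$values
  if (smoothing_window >= 3L) {
    n <- min(smoothing_window, length(y) - (1 - length(y) %% 2))
    if (n %% 2 == 0) n <- n - 1
    if (n > poly_order) y <- signal::sgolayfilt(y, p = poly_order, n = n)
  }
  # derivative at interval midpoints
  dmid <- diff(y) / diff(wl)
  mid <- (wl[-1] + wl[-length(wl)]) / 2
  cross <- which(dmid[-length(dmid)] > 0 & dmid[-1] <= 0)
  if (length(cross) == 0L)
    stop("no interior maximum: first derivative has no +/- zero crossing",
         call. = FALSE)
  # choose the crossing with the highest smoothed signal
  peak_vals <- y[cross + 1]
  i <- cross[which.max(peak_vals)]
  d1 <- dmid[i]; d2 <- dmid[i + 1]
  if (d1 == d2) return(mid[i])
  mid[i] + d1 * (mid[i + 1] - mid[i]) / (d1 - d2)
}
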