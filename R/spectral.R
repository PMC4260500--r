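# Burg autoregressive spectral estimation. The Burg lattice recursion
# (src/burg.cpp) minimises forward+backward prediction error under a
# Levinson update; reflection coefficients stay inside (-1, 1) so the
# fitted all-pole model is always stable, which matters for the short
# variable-length analysis intervals this pipeline feeds it.

FREQ_BANDS <- list(theta = 4:7, alpha = 8:13)

#' Fit an autoregressive model by the Burg algorithm
#'
#' @param x numeric signal (single channel)
#' @param order AR model order; the signal must be longer than `2 * order`
#' @param detrend remove a linear trend (least squares) plus mean before
#'   fitting; additive drift would otherwise be misattributed to the AR
#'   poles
#' @return object of class `burg_ar` with elements `ar` (coefficients in
#'   the convention `x_t = sum(ar_k x_(t-k)) + e_t`), `var_pred` (innovation
#'   variance), `reflection`, `order`, `n`
#' @export
burg <- function(x, order = 16, detrend = TRUE) {
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) stopf("signal contains non-finite values")
  if (length(x) <= 2L * order)
    stopf("signal too short (%d samples) for AR order %d", length(x), order)
  if (detrend) x <- detrend_linear(x)
  if (stats::sd(x) == 0) stopf("signal is constant; AR fit is degenerate")
  fit <- burg_cpp(x, as.integer(order))
  structure(list(ar = as.numeric(fit$ar), var_pred = fit$var,
                 reflection = as.numeric(fit$reflection),
                 order = as.integer(order), n = length(x)),
            class = "burg_ar")
}

#' @export
print.burg_ar <- function(x, ...) {
  cat("<burg_ar> order", x$order, "fit on", x$n, "samples; innovation var",
      signif(x$var_pred, 4), "\n")
  invisible(x)
}

#' @export
coef.burg_ar <- function(object, ...) object$ar

#' Remove linear trend and mean from a signal
#' @param x numeric vector
#' @export
detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n) - (n + 1) / 2            # centered regressor
  x - mean(x) - t * sum(t * x) / sum(t * t)
}

#' Evaluate the AR power spectral density at requested frequencies
#'
#' `P(f) = var_pred / |1 - sum_k ar_k exp(-2 pi i f k / rate)|^2`, evaluated
#' exactly at each requested frequency.
#'
#' @param fit a `burg_ar` object (or list with `ar` and `var_pred`)
#' @param rate sampling rate in Hz
#' @param freqs frequencies to evaluate, all below `rate / 2`
#' @return object of class `power_spectrum`: list with `freq`, `power`,
#'   `ar_order`, `noise_var`
#' @export
ar_psd <- function(fit, rate, freqs = 4:13) {
  if (any(freqs >= rate / 2) || any(freqs <= 0))
    stopf("frequencies must lie in (0, rate/2)")
  a <- fit$ar
  k <- seq_along(a)
  denom <- vapply(freqs, function(f) {
    h <- 1 - sum(a * exp(-2i * pi * f * k / rate))
    Mod(h)^2
  }, numeric(1))
  structure(list(freq = as.numeric(freqs), power = fit$var_pred / denom,
                 ar_order = length(a), noise_var = fit$var_pred),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat("<power_spectrum> AR order", x$ar_order, "at",
      length(x$freq), "frequencies",
      sprintf("(%g-%g Hz)\n", min(x$freq), max(x$freq)))
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, ...) {
  plot(x$freq, x$power, type = "b", xlab = "frequency (Hz)",
       ylab = "power", ...)
  invisible(x)
}

#' Mean spectral power over a frequency band
#'
#' The band mean (not sum) over the band's integer frequencies -- theta
#' (4-7 Hz, 4 grid points) and alpha (8-13 Hz, 6 grid points) stay
#' comparable.
#'
#' @param spectrum a `power_spectrum`
#' @param band "theta" (4-7 Hz) or "alpha" (8-13 Hz)
#' @export
band_power <- function(spectrum, band = c("alpha", "theta")) {
  band <- match.arg(band)
  bf <- FREQ_BANDS[[band]]
  if (!all(bf %in% spectrum$freq))
    stopf("%s band (%d-%d Hz) not fully covered by the spectrum grid",
          band, min(bf), max(bf))
  mean(spectrum$power[spectrum$freq %in% bf])
}
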