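## Gaussian low-pass FIR filter used both to shape simulated recording noise
## and (optionally) to smooth traces for display.  A Gaussian filter is the
## standard digital stand-in for the analog Bessel filter of a patch-clamp
## amplifier: both are approximately linear-phase and non-ringing, and the
## dead-time relation tau_dead ~ 1/(2 pi f_c) holds for either.

#' Gaussian low-pass filter kernel
#'
#' FIR kernel of a Gaussian filter with -3 dB cut-off frequency `fc` at
#' sampling rate `fs`.  The time-domain standard deviation follows the
#' standard single-channel convention \eqn{\sigma_t = 0.1325 / f_c}
#' (so that the frequency response is \eqn{\sqrt{1/2}} at \eqn{f_c}); the
#' kernel is truncated at 4 sigma and normalized to unit sum.
#'
#' @param fc cut-off frequency (Hz).
#' @param fs sampling rate (Hz); must exceed `2 * fc`.
#' @return Numeric vector of odd length, summing to 1.
#' @export
gaussianKernel <- function(fc, fs) {
    stopifnot(fc > 0, fs > 2 * fc)
    sigma_t <- sqrt(log(2)) / (2 * pi * fc)   # = 0.13249/fc
    sigma_n <- sigma_t * fs
    half <- max(1L, ceiling(4 * sigma_n))
    k <- stats::dnorm(seq(-half, half), sd = sigma_n)
    k / sum(k)
}

#' Apply a Gaussian low-pass filter to a sampled signal
#'
#' Zero-phase FIR convolution with the [gaussianKernel()]; edges are
#' handled by replicating the terminal samples so the output has the same
#' length as the input.
#'
#' @param x numeric signal vector.
#' @param fc cut-off frequency (Hz).
#' @param fs sampling rate (Hz).
#' @return Filtered signal, same length as `x`.
#' @export
gaussianFilter <- function(x, fc, fs) {
    k <- gaussianKernel(fc, fs)
    half <- (length(k) - 1L) / 2L
    xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
    stats::filter(xp, k, method = "convolution", sides = 2L)[(half + 1L):(half + length(x))]
}

## standard deviation attenuation of white noise passed through a unit-sum
## FIR kernel: sd_out = sd_in * sqrt(sum(k^2))
.kernelNoiseGain <- function(k) sqrt(sum(k^2))
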