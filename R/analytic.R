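#' Discrete analytic extension of a real signal
#'
#' Builds the one-sided-spectrum analytic signal: the Fourier transform of
#' `x` is zeroed on negative frequencies and doubled on strictly positive
#' ones (DC and, for even length, Nyquist are kept as-is).  The real part of
#' the result equals `x` to machine precision, and the samples are the
#' boundary values of the analytic extension on the uniform unit-circle grid
#' `z_t = exp(2i * pi * t / N)`.
#'
#' @param x finite real numeric vector, length at least 8.
#' @param sample_rate sampling rate in Hz (positive scalar).
#' @return an object of class `analytic_signal`: a list with elements
#'   `samples` (complex vector) and `sample_rate`.
#' @examples
#' a <- analytic_extension(cos(2 * pi * (0:63) / 64), 64)
#' max(abs(Re(a$samples) - cos(2 * pi * (0:63) / 64)))
#' @export
analytic_extension <- function(x, sample_rate) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("`x` must be a finite real numeric vector")
  n <- length(x)
  if (n < 8L) stop("`x` must have length >= 8")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a positive scalar")
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2L == 0L) {
    h[2:(n / 2)] <- 2
    h[n / 2 + 1L] <- 1
  } else {
    h[2:((n + 1L) / 2)] <- 2
  }
  samples <- fft(fft(as.numeric(x)) * h, inverse = TRUE) / n
  structure(list(samples = samples, sample_rate = sample_rate),
            class = "analytic_signal")
}

#' @export
print.analytic_signal <- function(x, ...) {
  cat(sprintf("<analytic_signal: %d samples @ %g Hz>\n",
              length(x$samples), x$sample_rate))
  invisible(x)
}

#' @export
length.analytic_signal <- function(x) length(x$samples)

# uniform grid z_t = exp(2i pi t / n) on the unit circle
circle_grid <- function(n) exp(2i * pi * (seq_len(n) - 1) / n)

# discrete inner product and norm: mean over the circle grid
ip_disc <- function(f, g) mean(f * Conj(g))
norm2_disc <- function(f) mean(Mod(f)^2)

as_analytic <- function(x, sample_rate) {
  if (inherits(x, "analytic_signal")) return(x)
  if (is.complex(x))
    return(structure(list(samples = x, sample_rate = sample_rate),
                     class = "analytic_signal"))
  analytic_extension(x, sample_rate)
}

# Hilbert envelope of a real signal
hilbert_envelope <- function(x, sample_rate = 1) {
  Mod(analytic_extension(x, sample_rate)$samples)
}
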