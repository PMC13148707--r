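# run `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a periodic pulse train through a damped resonance
#'
#' A train of impulses at repetition rate `rep_rate`, optionally jittered in
#' time, convolved with the impulse response of a damped resonance
#' `exp(-damping * t) * sin(2 * pi * resonance_freq * t)`.  This is the
#' structural model of a localized-fault vibration signature and, more
#' loosely, of ECG-like pulse sequences.
#'
#' @param rep_rate pulse repetition rate `f0` in Hz.
#' @param resonance_freq carrier resonance in Hz; must satisfy
#'   `rep_rate < resonance_freq < sample_rate / 2`.
#' @param damping exponential decay rate in 1/s; must be positive.
#' @param amplitude peak scale of each pulse (default 1).
#' @param jitter_fraction uniform timing jitter as a fraction of the pulse
#'   period, in `[0, 0.2]` (default 0).
#' @param duration signal duration in seconds; at least 4 pulses required.
#' @param sample_rate sampling rate in Hz.
#' @param seed integer RNG seed (used only when `jitter_fraction > 0`).
#' @return an object of class `pulse_train_spec`.
#' @export
pulse_train_spec <- function(rep_rate, resonance_freq, damping, amplitude = 1,
                             jitter_fraction = 0, duration = 1,
                             sample_rate = 1000, seed = 1L) {
  spec <- structure(
    list(rep_rate = rep_rate, resonance_freq = resonance_freq,
         damping = damping, amplitude = amplitude,
         jitter_fraction = jitter_fraction, duration = duration,
         sample_rate = sample_rate, seed = as.integer(seed)),
    class = "pulse_train_spec")
  validate_pulse_spec(spec)
  spec
}

validate_pulse_spec <- function(spec) {
  with(spec, {
    if (rep_rate <= 0 || resonance_freq <= rep_rate)
      stop("need 0 < rep_rate < resonance_freq")
    if (resonance_freq >= sample_rate / 2)
      stop("resonance_freq must be below the Nyquist frequency")
    if (damping <= 0) stop("`damping` must be positive (an undamped resonance rings forever)")
    if (jitter_fraction < 0 || jitter_fraction > 0.2)
      stop("`jitter_fraction` must be in [0, 0.2]")
    if (duration * rep_rate < 4)
      stop("duration must contain at least 4 pulses")
  })
  invisible(spec)
}

#' Generate a periodic pulse train
#'
#' Realises a [pulse_train_spec()]: impulses at (possibly jittered) multiples
#' of the period are placed on the sample grid and convolved with the damped
#' resonance kernel.  The generator is a pure function of the spec (and its
#' seed); the envelope spectrum of the clean output peaks at the repetition
#' rate.
#'
#' @param spec a [pulse_train_spec()].
#' @return numeric vector of length `round(duration * sample_rate)` with
#'   attribute `"spec"`.
#' @export
make_pulse_train <- function(spec) {
  stopifnot(inherits(spec, "pulse_train_spec"))
  validate_pulse_spec(spec)
  fs <- spec$sample_rate
  n <- round(spec$duration * fs)
  period <- 1 / spec$rep_rate
  k <- 0:floor(spec$duration / period)
  times <- k * period
  if (spec$jitter_fraction > 0) {
    jit <- with_seed(spec$seed,
                     runif(length(k), -1, 1) * spec$jitter_fraction * period)
    times <- times + jit
    times <- times[times >= 0]
  }
  idx <- round(times * fs) + 1L
  idx <- idx[idx >= 1L & idx <= n]
  impulses <- numeric(n)
  impulses[idx] <- 1
  # kernel truncated where the envelope has decayed to 1e-8
  tk <- seq(0, min(spec$duration, log(1e8) / spec$damping), by = 1 / fs)
  kernel <- exp(-spec$damping * tk) * sin(2 * pi * spec$resonance_freq * tk)
  # linear convolution via zero-padded FFT
  m <- n + length(kernel) - 1L
  pad <- function(v) c(v, numeric(m - length(v)))
  conv <- Re(fft(fft(pad(impulses)) * fft(pad(kernel)), inverse = TRUE)) / m
  x <- spec$amplitude * conv[seq_len(n)]
  attr(x, "spec") <- spec
  x
}

#' Specification of a signal mixture
#'
#' A mixture of pulse trains, pure tones and low-frequency baseline drift,
#' optionally corrupted by Gaussian white noise at an exact SNR.
#'
#' @param components list; each element is either a [pulse_train_spec()], a
#'   `tone(freq, amp)` or a `drift(cutoff, amp)` (see [tone()] / [drift()]).
#' @param snr_db signal-to-noise ratio in dB, or `Inf`/`NULL` for noiseless.
#' @param duration duration in seconds.
#' @param sample_rate sampling rate in Hz.
#' @param seed integer RNG seed for drift and noise.
#' @return an object of class `mixture_spec`.
#' @export
mixture_spec <- function(components, snr_db = Inf, duration = 1,
                         sample_rate = 1000, seed = 1L) {
  if (!length(components)) stop("`components` must be non-empty")
  if (is.null(snr_db)) snr_db <- Inf
  nyq <- sample_rate / 2
  for (cmp in components) {
    if (inherits(cmp, "pulse_train_spec")) {
      if (cmp$resonance_freq >= nyq) stop("component rate above Nyquist")
    } else if (inherits(cmp, c("tone_spec", "drift_spec"))) {
      if (cmp$freq >= nyq) stop("component rate above Nyquist")
    } else stop("unknown component type")
  }
  structure(list(components = components, snr_db = snr_db,
                 duration = duration, sample_rate = sample_rate,
                 seed = as.integer(seed)),
            class = "mixture_spec")
}

#' Tone and drift mixture components
#'
#' `tone()` is a pure sinusoid; `drift()` is low-pass-filtered Gaussian
#' noise (all Fourier content above `cutoff` removed, mean removed) scaled
#' to RMS `amp` -- a baseline-wander surrogate.
#'
#' @param freq tone frequency in Hz.
#' @param cutoff drift low-pass cutoff in Hz.
#' @param amp amplitude (tone peak / drift RMS).
#' @param phase tone phase in radians.
#' @return component spec objects used by [mixture_spec()].
#' @export
tone <- function(freq, amp = 1, phase = 0) {
  structure(list(freq = freq, amp = amp, phase = phase), class = "tone_spec")
}

#' @rdname tone
#' @export
drift <- function(cutoff, amp = 1) {
  structure(list(freq = cutoff, amp = amp), class = "drift_spec")
}

realize_component <- function(cmp, duration, fs, seed) {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  if (inherits(cmp, "pulse_train_spec")) {
    cmp$duration <- duration
    cmp$sample_rate <- fs
    as.numeric(make_pulse_train(cmp))
  } else if (inherits(cmp, "tone_spec")) {
    cmp$amp * sin(2 * pi * cmp$freq * t + cmp$phase)
  } else {  # drift
    raw <- with_seed(seed, rnorm(n))
    X <- fft(raw)
    freqs <- (seq_len(n) - 1) / n * fs
    freqs <- pmin(freqs, fs - freqs)          # two-sided frequency axis
    X[freqs > cmp$freq] <- 0
    X[1] <- 0
    d <- Re(fft(X, inverse = TRUE)) / n
    rms <- sqrt(mean(d^2))
    if (rms > 0) d <- d / rms * cmp$amp
    d
  }
}

#' Generate a signal mixture with ground-truth components
#'
#' Realises each component of a [mixture_spec()] on a common grid, sums
#' them, and (when `snr_db` is finite) adds Gaussian white noise scaled to
#' the exact SNR.  The ground-truth components and the noise are returned
#' separately and sum exactly to the emitted signal.
#'
#' @param spec a [mixture_spec()]; `ecg_like_mixture()` builds the default
#'   two-rate pulse mixture (1.2 Hz maternal-like, 2.2 Hz fetal-like, plus
#'   drift).
#' @return list with `signal`, `components` (list of numeric vectors),
#'   `noise`, `sample_rate`, `spec`.
#' @export
make_mixture <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  fs <- spec$sample_rate
  comps <- lapply(seq_along(spec$components), function(i)
    realize_component(spec$components[[i]], spec$duration, fs,
                      seed = spec$seed + i))
  clean <- Reduce(`+`, comps)
  if (is.finite(spec$snr_db)) {
    noisy <- add_noise_snr(clean, spec$snr_db, seed = spec$seed)
    noise <- noisy - clean
  } else {
    noisy <- clean
    noise <- numeric(length(clean))
  }
  list(signal = noisy, components = comps, noise = noise,
       sample_rate = fs, spec = spec)
}

#' @rdname make_mixture
#' @param duration,sample_rate,snr_db,seed forwarded to [mixture_spec()].
#' @export
ecg_like_mixture <- function(duration = 10, sample_rate = 200, snr_db = Inf,
                             seed = 1L) {
  mixture_spec(
    components = list(
      # maternal-like: slow strong pulses, QRS energy concentrated ~12 Hz
      pulse_train_spec(rep_rate = 1.2, resonance_freq = 12, damping = 15,
                       amplitude = 2, duration = duration,
                       sample_rate = sample_rate, seed = seed),
      # fetal-like: faster, weaker, narrower complexes centred higher
      pulse_train_spec(rep_rate = 2.2, resonance_freq = 50, damping = 15,
                       amplitude = 1, duration = duration,
                       sample_rate = sample_rate, seed = seed + 100L),
      # baseline wander well below the cardiac bands
      drift(cutoff = 0.3, amp = 0.15)),
    snr_db = snr_db, duration = duration, sample_rate = sample_rate,
    seed = seed)
}

#' Add Gaussian white noise at an exact SNR
#'
#' Draws standard Gaussian noise under the seed and rescales it so that
#' `10 * log10(signal power / noise power)` equals `snr_db` exactly.
#'
#' @param signal finite numeric vector with positive power.
#' @param snr_db target SNR in dB; `Inf` returns the signal unchanged.
#' @param seed integer RNG seed.
#' @return numeric vector `signal + noise`.
#' @export
add_noise_snr <- function(signal, snr_db, seed = 1L) {
  if (any(!is.finite(signal))) stop("`signal` must be finite")
  if (is.infinite(snr_db)) return(signal)
  p_sig <- mean(signal^2)
  if (p_sig <= 0) stop("`signal` must have positive power")
  raw <- with_seed(seed, rnorm(length(signal)))
  p_target <- p_sig / 10^(snr_db / 10)
  signal + raw * sqrt(p_target / mean(raw^2))
}
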