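# shared signal builders for the test suite (all deterministic under seed)

circle_grid_pts <- function(n) exp(2i * pi * (0:(n - 1)) / n)

# random real band-limited signal: harmonics 1..n_harm of an N-point record
band_limited_signal <- function(n, n_harm = 20, seed = 1) {
  co <- with_test_seed(seed, complex(real = rnorm(n_harm), imaginary = rnorm(n_harm)))
  X <- rep(0i, n)
  X[2:(n_harm + 1)] <- co
  X[seq(n, n - n_harm + 1)] <- Conj(co)
  Re(fft(X, inverse = TRUE)) / n
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# one-sided FFT coefficients of the discrete analytic extension of x
analytic_fourier_coeffs <- function(x, k) {
  a <- analytic_extension(x, 1)
  (fft(a$samples) / length(x))[seq_len(k)]
}

# vibration-style scenario: periodic fault pulses + meshing tone + white noise
vibration_scenario <- function(seed, snr_db = -5, duration = 0.4,
                               sample_rate = 8000) {
  n <- round(duration * sample_rate)
  spec <- pulse_train_spec(rep_rate = 125, resonance_freq = 2000, damping = 400,
                           duration = duration, sample_rate = sample_rate,
                           seed = seed)
  pulses <- as.numeric(make_pulse_train(spec))
  tone <- 0.5 * sin(2 * pi * 483 * (0:(n - 1)) / sample_rate)
  clean <- pulses + tone
  x <- if (is.finite(snr_db)) add_noise_snr(clean, snr_db, seed = seed + 1000L)
       else clean
  list(x = x, pulses = pulses, tone = tone, sample_rate = sample_rate,
       rep_rate = 125, bin_hz = sample_rate / n)
}

# identify the IMF matching a ground-truth component by max |Pearson r|
best_match <- function(result, truth) {
  cors <- vapply(result$imfs, function(s) abs(stats::cor(s$samples, truth)),
                 numeric(1))
  list(index = which.max(cors), cor = max(cors))
}
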