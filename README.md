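# ebmd — Empirical Blaschke Mode Decomposition

`ebmd` decomposes a uniformly sampled 1-D quasi-periodic signal — an ECG,
an EEG trace, a machine-vibration record — into a small number of
*intrinsic mode functions* (IMFs), each carrying one coherent
periodic-pulse constituent of the signal, plus a residual. It is aimed at
people who need to pull a fault signature out of noisy vibration data,
denoise a physiological recording, or separate superimposed pulse sources
(e.g. fetal from maternal ECG) without hand-designing filter banks.

## Method

The pipeline chains four stages:

1. **Adaptive Blaschke transform.** The analytic extension `f(z)` of the
   signal is expanded greedily over the Takenaka–Malmquist rational
   orthonormal system generated by parameters `a_k` inside the unit disk,

   `f(z) = Σ_k ⟨f_k, e_{a_k}⟩ B_k(z) + residual`,  with
   `e_a(z) = √(1−|a|²)/(1−ā z)` the normalised Szegő kernel and
   `B_k(z) = e_{a_k}(z) Π_{j<k} (z−a_j)/(1−ā_j z)`.

   At each order the parameter is chosen from a polar-grid dictionary by
   maximising a quasi-periodicity score, the aggregated autocorrelation
   `|Σ_m R(m)|/N` of the candidate component. With all `a_k = 0` the
   expansion reduces exactly to the one-sided Fourier series. The
   per-order mean energies `BS(k)` form the *Blaschke spectrum*.

2. **A-contrario unimodal pre-segmentation.** A spectrum (frequency bins
   by default; Blaschke orders as an option) is mean-truncated and
   max-filtered into a trend `z` (window `M`), whose amplitudes are read
   as sample counts. Runs of the trend are merged fine-to-coarse while
   statistically monotone — an interval deviates meaningfully from its
   Grenander (pool-adjacent-violators) monotone estimate when its number
   of false alarms `NFA = L(L+1)/2 · B(N, NQ, P)` drops below the
   threshold δ (default 0.5) — and paired into unimodal segments. Each
   segment is a *mono-component* band.

3. **Group sparse filtering.** Each mono-component's spectrum is
   thresholded by energy detection (`keep bin i ⇔ |c_y[i]|² ≥ λ w_i`,
   the exact minimiser of the weighted-ℓ₀ objective
   `‖c_y − c_y∘f‖² + λ‖f‖₀,w`), and the binary mask is regularised into
   compact, mutually separated groups — the frequency-domain signature of
   periodic pulses. λ is set from the in-band noise floor.

4. **Periodic-pulse fusion.** Fundamental modes whose Hilbert-envelope
   spectra share their active band (overlap ratio > `thr`) and dominant
   pulse frequency are summed into one IMF, preventing over-decomposition.
   Fusion conserves the sum of modes exactly.

## Worked example

Separate a synthetic single-channel "abdominal ECG": a 1.2 Hz
maternal-like pulse train, a 2.2 Hz fetal-like train, and baseline wander,
summed into one trace sampled at 200 Hz for 10 s.

```r
library(ebmd)

mix    <- make_mixture(ecg_like_mixture(duration = 10, sample_rate = 200, seed = 1))
result <- ebmd(mix$signal, sample_rate = 200, config = ebmd_config(M = 31))
result
#> <ebmd_result: 3 IMF(s), N = 2000 @ 200 Hz>
#>   IMF 1: dominant 0.1 Hz, members {1}, energy 0.02564
#>   IMF 2: dominant 1.2 Hz, members {2}, energy 0.07266
#>   IMF 3: dominant 2.2 Hz, members {3}, energy 0.03626
#>   reconstruction error (rel): 5.82e-16
```

The decomposition found three modes whose envelope spectra peak at
0.1 Hz (the baseline wander), 1.2 Hz (the maternal beat rate) and 2.2 Hz
(the fetal beat rate); the accounting identity
input = ΣIMFs + filtered-out + residual holds to machine precision.
Against the known ground-truth components the recovered modes correlate

```r
sapply(seq_along(mix$components), function(i)
  max(sapply(result$imfs, function(m) abs(cor(m$samples, mix$components[[i]])))))
#> [1] 0.972 0.971 0.961
```

`autoplot(result)` draws the stacked mode time series,
`plot_blaschke_spectrum(result)` the segmented spectrum, and
`plot_envelope_spectra(result)` the per-IMF envelope spectra.
`write_result(result, "out/")` saves modes as CSV and diagnostics as JSON.
A command-line front end lives at `inst/cli/ebmd`
(`ebmd decompose recording.wav --out out/`).

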