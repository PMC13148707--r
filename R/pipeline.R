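#' Configuration for the EBMD pipeline
#'
#' Collects every tunable of the decomposition with validated defaults.
#' `preset = "case1"` (vibration-style: trend window 101) and
#' `preset = "eeg"` (window 51) mirror the published parameterisations with
#' the pre-segmentation threshold 0.5; windows are clamped to the available
#' spectrum length at run time.
#'
#' @param K maximum Blaschke transform order (default 64).
#' @param dict_radii,dict_phases dictionary construction, see
#'   [disk_dictionary()].
#' @param spectrum_axis `"fourier"` (default): segment the Fourier
#'   magnitude spectrum over frequency bins and rebuild mono-components by
#'   band selection (the mono-component is recovered by inverse Fourier
#'   transform of its band); `"blaschke"`: segment the Blaschke spectrum
#'   over transform orders and rebuild by partial reconstruction.
#' @param M maximum-filter window (odd; default 101, clamped to the
#'   spectrum length at run time; on the order axis small values such as 5
#'   are appropriate).
#' @param delta pre-segmentation decision threshold (default 0.5).
#' @param epsilon NFA meaningfulness threshold (default 0.5; diagnostic).
#' @param count_total pseudo-count for the a-contrario test (default
#'   `NULL`: 100 per spectrum bin, see [presegment()]).
#' @param kappa threshold multiplier for the group-filter threshold
#'   (default 6: a bin survives when its smoothed energy is six times the
#'   in-band noise-floor estimate).
#' @param floor_quantile quantile of the smoothed in-band energies read as
#'   the noise floor (default 0.25, robust against dense harmonic combs
#'   occupying most of a band; see [design_group_filter()]).
#' @param energy_smooth odd moving-average width for bin energies before
#'   thresholding (default 5), see [design_group_filter()].
#' @param min_group_len,min_gap group-filter constraints (defaults 3, 2).
#' @param thr fusion overlap threshold (default 0.5).
#' @param freq_tol_bins fusion dominant-frequency tolerance (default 1).
#' @param preset optional name applying published parameter sets.
#' @param blaschke_diag also compute the Blaschke transform and store its
#'   spectrum in the diagnostics when the segmentation runs on the Fourier
#'   axis (default `FALSE`; it is always computed on the Blaschke axis).
#' @param use_cpp use the compiled dictionary scanner (default TRUE).
#' @param seed seed for any stochastic extension (unused by the core, kept
#'   for reproducibility contracts).
#' @return an object of class `ebmd_config` (a validated list).
#' @export
ebmd_config <- function(K = 64L, dict_radii = seq(0, 0.9, by = 0.1),
                        dict_phases = 64L,
                        spectrum_axis = c("fourier", "blaschke"),
                        M = 101L, delta = 0.5, epsilon = 0.5,
                        count_total = NULL, kappa = 6, floor_quantile = 0.25,
                        energy_smooth = 5L,
                        min_group_len = 3L, min_gap = 2L,
                        thr = 0.5, freq_tol_bins = 1L,
                        preset = NULL, blaschke_diag = FALSE,
                        use_cpp = TRUE, seed = 1L) {
  spectrum_axis <- match.arg(spectrum_axis)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("case1", "eeg"))
    delta <- 0.5
    M <- if (preset == "case1") 101L else 51L
  }
  cfg <- structure(
    list(K = as.integer(K), dict_radii = dict_radii,
         dict_phases = as.integer(dict_phases),
         spectrum_axis = spectrum_axis, M = as.integer(M), delta = delta,
         epsilon = epsilon, count_total = count_total, kappa = kappa,
         floor_quantile = floor_quantile,
         min_group_len = as.integer(min_group_len),
         min_gap = as.integer(min_gap),
         energy_smooth = as.integer(energy_smooth), thr = thr,
         freq_tol_bins = as.integer(freq_tol_bins),
         preset = preset, blaschke_diag = isTRUE(blaschke_diag),
         use_cpp = isTRUE(use_cpp), seed = as.integer(seed)),
    class = "ebmd_config")
  validate_ebmd_config(cfg)
  cfg
}

validate_ebmd_config <- function(cfg) {
  with(cfg, {
    if (K < 1L) stop("`K` must be >= 1")
    if (M < 1L || M %% 2L == 0L) stop("`M` must be a positive odd integer")
    if (delta <= 0 || delta > 1) stop("`delta` must be in (0, 1]")
    if (epsilon <= 0 || epsilon > 1) stop("`epsilon` must be in (0, 1]")
    if (kappa < 0) stop("`kappa` must be non-negative")
    if (floor_quantile <= 0 || floor_quantile > 0.5)
      stop("`floor_quantile` must be in (0, 0.5]")
    if (thr <= 0 || thr > 1) stop("`thr` must be in (0, 1]")
    if (min_group_len < 1L || min_gap < 1L || freq_tol_bins < 0L)
      stop("group/fusion integer parameters out of range")
  })
  invisible(cfg)
}

#' @export
print.ebmd_config <- function(x, ...) {
  cat("<ebmd_config>\n")
  flat <- x[!vapply(x, is.null, logical(1))]
  for (nm in names(flat))
    cat(sprintf("  %-14s %s\n", nm, paste(format(flat[[nm]]), collapse = " ")))
  invisible(x)
}

# mono-components + per-order bookkeeping for the chosen spectrum axis
extract_monocomponents <- function(x, decomp, seg, cfg) {
  n <- length(x)
  if (cfg$spectrum_axis == "blaschke") {
    monos <- lapply(seq_len(nrow(seg$segments)), function(i)
      partial_reconstruction(decomp, c(seg$segments$a[i], seg$segments$b[i])))
    covered <- unlist(lapply(seq_len(nrow(seg$segments)), function(i)
      seg$segments$a[i]:seg$segments$b[i]))
    uncovered <- setdiff(seq_len(length(decomp$coeffs)), covered)
    unseg <- if (length(uncovered))
      Re(rowSums(decomp$components[, uncovered, drop = FALSE]))
    else numeric(n)
    resid <- Re(decomp$residual) + unseg
  } else {
    cy <- fft(x)
    t_half <- n %/% 2L + 1L
    monos <- lapply(seq_len(nrow(seg$segments)), function(i) {
      mask <- numeric(t_half)
      mask[seg$segments$a[i]:seg$segments$b[i]] <- 1
      apply_filter(cy, mask)
    })
    covered <- numeric(t_half)
    for (i in seq_len(nrow(seg$segments)))
      covered[seg$segments$a[i]:seg$segments$b[i]] <- 1
    resid <- apply_filter(cy, 1 - covered)
  }
  list(monos = monos, resid = resid)
}

#' Empirical Blaschke mode decomposition
#'
#' Runs the full pipeline: adaptive Blaschke transform, Blaschke-spectrum
#' trend extraction, a-contrario unimodal pre-segmentation, per-segment
#' mono-component reconstruction, group sparse frequency filtering of each
#' mono-component, and periodic-pulse fusion of the resulting fundamental
#' modes into intrinsic mode functions (IMFs).  The accounting identity
#' `x = sum(IMFs) + filtered_out + residual` holds to numerical precision.
#'
#' @param x finite real numeric vector, length at least 64.
#' @param sample_rate sampling rate in Hz.
#' @param config an [ebmd_config()]; default configuration when missing.
#' @return an object of class `ebmd_result`: list with `imfs` (list of
#'   `intrinsic_mode`), `residual`, `filtered_out`, `sample_rate`, `config`
#'   and `diagnostics` (Blaschke spectrum, trend, segments, masks, fusion
#'   map, reconstruction error).
#' @export
ebmd <- function(x, sample_rate, config = ebmd_config()) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("`x` must be finite")
  if (length(x) < 64L) stop("`x` must have length >= 64")
  validate_ebmd_config(config)
  n <- length(x)
  if (sd(x) == 0) {
    warning("constant input: returning a single trivial IMF")
    imf <- structure(list(samples = x, members = 1L,
                          signature = envelope_signature(x, sample_rate)),
                     class = "intrinsic_mode")
    return(structure(list(imfs = list(imf), residual = numeric(n),
                          filtered_out = numeric(n),
                          sample_rate = sample_rate, config = config,
                          diagnostics = list(note = "constant input")),
                     class = "ebmd_result"))
  }
  decomp <- NULL
  if (config$spectrum_axis == "blaschke" || config$blaschke_diag) {
    dict <- disk_dictionary(config$dict_radii, config$dict_phases)
    K <- min(config$K, n %/% 2L)
    decomp <- blaschke_transform(x, sample_rate, K = K, dict = dict,
                                 use_cpp = config$use_cpp)
  }
  spec_seq <- if (config$spectrum_axis == "blaschke") decomp$spectrum
              else Mod(fft(x))[seq_len(n %/% 2L + 1L)]
  M <- min(config$M, length(spec_seq))
  if (M %% 2L == 0L) M <- M - 1L
  seg <- presegment(spec_seq, M = M, delta = config$delta,
                    count_total = config$count_total, clamp_window = FALSE)
  if (nrow(seg$segments) == 0L) {
    warning("no unimodal segment found: whole signal returned as residual")
    return(structure(list(imfs = list(), residual = x,
                          filtered_out = numeric(n),
                          sample_rate = sample_rate, config = config,
                          diagnostics = list(spectrum = spec_seq,
                                             trend = unclass(seg$trend),
                                             segments = seg$segments)),
                     class = "ebmd_result"))
  }
  mc <- extract_monocomponents(x, decomp, seg, config)
  filters <- list()
  fundamentals <- list()
  filtered_out <- numeric(n)
  for (i in seq_along(mc$monos)) {
    mono <- mc$monos[[i]]
    cy <- fft(mono)
    band_bins <- if (config$spectrum_axis == "fourier")
      seg$segments$a[i]:seg$segments$b[i] else NULL
    flt <- design_group_filter(cy, kappa = config$kappa, bins = band_bins,
                               floor_quantile = config$floor_quantile,
                               energy_smooth = config$energy_smooth,
                               min_group_len = config$min_group_len,
                               min_gap = config$min_gap)
    filters[[i]] <- flt
    fm <- apply_filter(cy, flt)
    filtered_out <- filtered_out + (mono - fm)
    if (nrow(flt$groups) > 0L && sum(fm^2) > 0)
      fundamentals[[length(fundamentals) + 1L]] <- fm
  }
  if (length(fundamentals)) {
    imfs <- fuse_modes(fundamentals, sample_rate, thr = config$thr,
                       freq_tol_bins = config$freq_tol_bins)
  } else {
    warning("group filters removed all content; no IMFs")
    imfs <- list()
  }
  recon <- Reduce(`+`, lapply(imfs, `[[`, "samples"), numeric(n)) +
    filtered_out + mc$resid
  diagnostics <- list(
    spectrum = spec_seq,
    spectrum_axis = config$spectrum_axis,
    blaschke_spectrum = if (!is.null(decomp)) decomp$spectrum,
    trend = unclass(seg$trend),
    segments = seg$segments,
    filters = lapply(filters, function(f)
      list(lambda = f$lambda, groups = f$groups)),
    n_monocomponents = length(mc$monos),
    n_fundamentals = length(fundamentals),
    fusion_members = lapply(imfs, `[[`, "members"),
    reconstruction_error = sqrt(sum((x - recon)^2) / sum(x^2)))
  structure(list(imfs = imfs, residual = mc$resid,
                 filtered_out = filtered_out, sample_rate = sample_rate,
                 config = config, diagnostics = diagnostics),
            class = "ebmd_result")
}

#' @export
print.ebmd_result <- function(x, ...) {
  cat(sprintf("<ebmd_result: %d IMF(s), N = %d @ %g Hz>\n",
              length(x$imfs), length(x$residual), x$sample_rate))
  for (i in seq_along(x$imfs)) {
    s <- x$imfs[[i]]
    cat(sprintf("  IMF %d: dominant %s Hz, members {%s}, energy %.4g\n",
                i, format(s$signature$dominant_freq),
                paste(s$members, collapse = ","), mean(s$samples^2)))
  }
  if (!is.null(x$diagnostics$reconstruction_error))
    cat(sprintf("  reconstruction error (rel): %.3g\n",
                x$diagnostics$reconstruction_error))
  invisible(x)
}

#' Matrix of IMF time series
#'
#' @param result an `ebmd_result`.
#' @return numeric matrix, one column per IMF (0-column when none).
#' @export
imf_matrix <- function(result) {
  stopifnot(inherits(result, "ebmd_result"))
  if (!length(result$imfs))
    return(matrix(numeric(0), nrow = length(result$residual), ncol = 0))
  m <- vapply(result$imfs, `[[`, numeric(length(result$residual)), "samples")
  colnames(m) <- paste0("IMF", seq_len(ncol(m)))
  m
}

#' Tidy long-format view of a decomposition
#'
#' @param x an `ebmd_result`.
#' @param ... unused.
#' @return data.frame with columns `time`, `series` (IMF1.., residual,
#'   filtered_out), `value`.
#' @export
tidy.ebmd_result <- function(x, ...) {
  n <- length(x$residual)
  tt <- (seq_len(n) - 1) / x$sample_rate
  m <- cbind(imf_matrix(x), residual = x$residual,
             filtered_out = x$filtered_out)
  data.frame(
    time = rep(tt, ncol(m)),
    series = rep(colnames(m), each = n),
    value = as.numeric(m))
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")
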