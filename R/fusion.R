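#' Envelope-spectrum signature of a mode
#'
#' Computes the Hilbert envelope (magnitude of the analytic extension),
#' removes its mean, and takes the magnitude spectrum over the non-negative
#' frequency bins.  The signature records the active band (the union of bin
#' intervals where the envelope spectrum exceeds its mean) and the dominant
#' pulse frequency (the spectrum's argmax).  For an (effectively) constant
#' envelope both are flagged as empty/undefined.
#'
#' @param mode real numeric vector, length at least 8.
#' @param sample_rate sampling rate in Hz.
#' @return an object of class `envelope_signature`: list with
#'   `env_spectrum` (numeric, bins `0..floor(N/2)`), `bin_hz`,
#'   `active_band` (data.frame `start`, `end` in 1-based bins),
#'   `dominant_bin` (1-based, `NA` if undefined), `dominant_freq` (Hz, `NA`
#'   if undefined).
#' @export
envelope_signature <- function(mode, sample_rate) {
  mode <- as.numeric(mode)
  n <- length(mode)
  if (n < 8L) stop("`mode` must have length >= 8")
  env <- hilbert_envelope(mode, sample_rate)
  envc <- env - mean(env)
  spec <- Mod(fft(envc))[seq_len(n %/% 2L + 1L)]
  bin_hz <- sample_rate / n
  scale_ref <- max(Mod(fft(env))[1], .Machine$double.eps)  # DC of raw envelope
  if (max(spec) <= 1e-10 * scale_ref) {
    band <- data.frame(start = integer(0), end = integer(0))
    dom <- NA_integer_
  } else {
    above <- spec > mean(spec)
    runs <- mask_runs(as.numeric(above))
    band <- data.frame(start = as.integer(runs[, "start"]),
                       end = as.integer(runs[, "end"]))
    dom <- which.max(spec)
  }
  structure(list(env_spectrum = spec, bin_hz = bin_hz, active_band = band,
                 dominant_bin = dom,
                 dominant_freq = if (is.na(dom)) NA_real_ else (dom - 1L) * bin_hz),
            class = "envelope_signature")
}

#' @export
print.envelope_signature <- function(x, ...) {
  cat(sprintf("<envelope_signature: dominant %s Hz, %d active band(s)>\n",
              format(x$dominant_freq), nrow(x$active_band)))
  invisible(x)
}

band_to_set <- function(band) {
  if (nrow(band) == 0L) return(integer(0))
  unlist(lapply(seq_len(nrow(band)), function(i) band$start[i]:band$end[i]))
}

#' Overlap ratio of two active bands
#'
#' The ratio of the overlapping length to the merged length of two unions
#' of bin intervals (overlap length over merged length); symmetric,
#' in `[0, 1]`, and defined as 0 when both unions are empty.
#'
#' @param L_i,L_j data.frames with columns `start`, `end` (inclusive bins),
#'   or integer vectors of bins.
#' @return scalar in `[0, 1]`.
#' @examples
#' overlap_ratio(data.frame(start = 1, end = 11), data.frame(start = 6, end = 16))
#' @export
overlap_ratio <- function(L_i, L_j) {
  si <- if (is.data.frame(L_i)) band_to_set(L_i) else as.integer(L_i)
  sj <- if (is.data.frame(L_j)) band_to_set(L_j) else as.integer(L_j)
  u <- length(union(si, sj))
  if (u == 0L) return(0)
  length(intersect(si, sj)) / u
}

#' Fuse fundamental modes into intrinsic mode functions
#'
#' Implements the periodic-pulse similarity fusion: a mode absorbs another
#' when their active envelope bands overlap by more than `thr` (overlap
#' ratio of band lengths) and their dominant pulse frequencies agree within
#' `freq_tol_bins` envelope-spectrum bins.  After each merge the combined
#' mode's signature is recomputed and scanning restarts, so the result is a
#' deterministic fixpoint.  The output modes partition the inputs and sum
#' exactly to the sum of the inputs.
#'
#' @param modes list of real numeric vectors (fundamental modes), all the
#'   same length, or a single numeric matrix (one column per mode).
#' @param sample_rate sampling rate in Hz.
#' @param thr fusion threshold in `(0, 1]` (default 0.5).
#' @param freq_tol_bins dominant-frequency tolerance in envelope-spectrum
#'   bins (default 1).
#' @return list of objects of class `intrinsic_mode`: each a list with
#'   `samples`, `members` (indices of the fused input modes) and
#'   `signature` (an `envelope_signature`).
#' @export
fuse_modes <- function(modes, sample_rate, thr = 0.5, freq_tol_bins = 1L) {
  if (is.matrix(modes)) modes <- lapply(seq_len(ncol(modes)), function(j) modes[, j])
  if (!length(modes)) stop("need at least one mode")
  if (thr <= 0 || thr > 1) stop("`thr` must be in (0, 1]")
  lens <- vapply(modes, length, integer(1))
  if (length(unique(lens)) != 1L) stop("all modes must have the same length")
  pool <- lapply(seq_along(modes), function(i)
    list(samples = as.numeric(modes[[i]]), members = i))
  out <- list()
  while (length(pool)) {
    cur <- pool[[1L]]
    pool <- pool[-1L]
    repeat {
      sig_i <- envelope_signature(cur$samples, sample_rate)
      merged <- FALSE
      j <- 1L
      while (j <= length(pool)) {
        sig_j <- envelope_signature(pool[[j]]$samples, sample_rate)
        r <- overlap_ratio(sig_i$active_band, sig_j$active_band)
        same_freq <- !is.na(sig_i$dominant_bin) && !is.na(sig_j$dominant_bin) &&
          abs(sig_i$dominant_bin - sig_j$dominant_bin) <= freq_tol_bins
        if (r > thr && same_freq) {
          cur$samples <- cur$samples + pool[[j]]$samples
          cur$members <- c(cur$members, pool[[j]]$members)
          pool <- pool[-j]
          merged <- TRUE
          break                      # signature changed: recompute, rescan
        }
        j <- j + 1L
      }
      if (!merged) break
    }
    out[[length(out) + 1L]] <- structure(
      list(samples = cur$samples, members = sort(cur$members),
           signature = envelope_signature(cur$samples, sample_rate)),
      class = "intrinsic_mode")
  }
  out
}

#' @export
print.intrinsic_mode <- function(x, ...) {
  cat(sprintf("<intrinsic_mode: %d samples, members {%s}, dominant %s Hz>\n",
              length(x$samples), paste(x$members, collapse = ", "),
              format(x$signature$dominant_freq)))
  invisible(x)
}
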