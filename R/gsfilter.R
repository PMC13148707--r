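#' Pointwise energy-detection mask
#'
#' The separable minimiser of the weighted-l0 filtering objective
#' `|c_y[i]|^2 (1 - f_i) + lambda * w_i * f_i`: bin `i` is kept exactly when
#' its energy `|c_y[i]|^2` is at least `lambda * w_i`.
#'
#' @param c_y complex (or real) spectrum coefficients over the bins to mask.
#' @param lambda non-negative threshold scale.
#' @param w positive per-bin weights (default all 1).
#' @return binary numeric vector (0/1) of the same length as `c_y`.
#' @export
pointwise_mask <- function(c_y, lambda, w = rep(1, length(c_y))) {
  if (length(lambda) != 1L || lambda < 0) stop("`lambda` must be a non-negative scalar")
  if (length(w) != length(c_y)) stop("`w` must match `c_y` in length")
  if (any(w <= 0)) stop("weights must be positive")
  as.numeric(Mod(c_y)^2 >= lambda * w)
}

# runs of ones in a binary vector -> matrix with columns start, end
mask_runs <- function(mask) {
  r <- rle(mask > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

#' Impose group structure on a binary mask
#'
#' Gaps between runs of ones shorter than `min_gap` are filled first; then
#' any remaining group shorter than `min_group_len` is dropped.  The result
#' is a union of compact groups, pairwise separated by at least `min_gap`
#' bins, each at least `min_group_len` bins long.
#'
#' @param mask binary (0/1) numeric vector.
#' @param min_group_len minimum surviving group length in bins (default 3).
#' @param min_gap minimum separation between groups in bins (default 2).
#' @return an object of class `group_sparse_filter`: list with `mask`
#'   (binary vector), `groups` (data.frame `start`, `end`, 1-based inclusive
#'   bins), `min_group_len`, `min_gap`.
#' @examples
#' enforce_group_structure(c(1, 1, 0, 1, 1), min_group_len = 3, min_gap = 2)$mask
#' @export
enforce_group_structure <- function(mask, min_group_len = 3L, min_gap = 2L) {
  mask <- as.numeric(mask != 0)
  min_group_len <- as.integer(min_group_len)
  min_gap <- as.integer(min_gap)
  if (min_group_len < 1L || min_gap < 1L)
    stop("`min_group_len` and `min_gap` must be positive")
  out <- mask
  runs <- mask_runs(out)
  if (nrow(runs) > 1L) {
    for (i in seq_len(nrow(runs) - 1L)) {
      gap <- runs[i + 1L, "start"] - runs[i, "end"] - 1L
      if (gap > 0L && gap < min_gap)
        out[(runs[i, "end"] + 1L):(runs[i + 1L, "start"] - 1L)] <- 1
    }
  }
  runs <- mask_runs(out)
  if (nrow(runs)) {
    for (i in seq_len(nrow(runs))) {
      if (runs[i, "end"] - runs[i, "start"] + 1L < min_group_len)
        out[runs[i, "start"]:runs[i, "end"]] <- 0
    }
  }
  runs <- mask_runs(out)
  groups <- data.frame(start = as.integer(runs[, "start"]),
                       end = as.integer(runs[, "end"]))
  structure(list(mask = out, groups = groups,
                 min_group_len = min_group_len, min_gap = min_gap),
            class = "group_sparse_filter")
}

#' @export
print.group_sparse_filter <- function(x, ...) {
  cat(sprintf("<group_sparse_filter: %d group(s) over %d bins>\n",
              nrow(x$groups), length(x$mask)))
  if (nrow(x$groups)) print(x$groups)
  invisible(x)
}

#' Apply a binary frequency filter by Hadamard product
#'
#' Multiplies the full discrete Fourier coefficients of a real signal by the
#' mask and inverse-transforms.  A mask given over the non-negative bins
#' (length `floor(N/2) + 1`) is mirrored onto the negative bins so the
#' output stays real; a full-length mask is used as given.
#'
#' @param c_y complex vector: full FFT of a real signal (length `N`).
#' @param filter a `group_sparse_filter` or binary vector (length `N` or
#'   `floor(N/2) + 1`).
#' @return real numeric vector of length `N`.
#' @export
apply_filter <- function(c_y, filter) {
  mask <- if (inherits(filter, "group_sparse_filter")) filter$mask
          else as.numeric(filter != 0)
  n <- length(c_y)
  t_half <- n %/% 2L + 1L
  if (length(mask) == n) {
    full <- mask
  } else if (length(mask) == t_half) {
    full <- numeric(n)
    full[seq_len(t_half)] <- mask
    if (n > 2L) {
      hi <- 2:(n - t_half + 1L)       # bins 2..(ceil(N/2)) mirror to N..
      full[n - hi + 2L] <- mask[hi]
    }
  } else {
    stop(sprintf("mask length %d matches neither N = %d nor N/2+1 = %d",
                 length(mask), n, t_half))
  }
  y <- fft(c_y * full, inverse = TRUE) / n
  if (max(Mod(Im(y))) > 1e-8 * max(1, max(Mod(y))))
    warning("filtered signal has a non-negligible imaginary residue")
  Re(y)
}

#' Threshold scale for the group sparse filter
#'
#' The default strategy sets `lambda = kappa * median(|c_y|^2)` over the
#' supplied bins: the median bin energy is a robust proxy for the noise
#' floor, and `kappa` (default 10) demands an order-of-magnitude prominence
#' for a bin to survive.
#'
#' @param c_y complex (or real) spectrum coefficients over the bins of
#'   interest (typically the non-negative half).
#' @param strategy only `"median"` is provided.
#' @param kappa non-negative multiplier (default 10).
#' @return scalar `lambda`.
#' @export
choose_lambda <- function(c_y, strategy = c("median"), kappa = 10) {
  strategy <- match.arg(strategy)
  if (length(c_y) == 0L) stop("empty spectrum")
  if (kappa < 0) stop("`kappa` must be non-negative")
  kappa * stats::median(Mod(c_y)^2)
}

#' Design a group sparse filter for a mono-component spectrum
#'
#' Convenience wrapper chaining [choose_lambda()], [pointwise_mask()] and
#' [enforce_group_structure()] over the non-negative frequency bins of a
#' full FFT.
#'
#' @param c_y complex vector: full FFT of a real signal.
#' @param lambda threshold scale; `NULL` (default) uses [choose_lambda()].
#' @param kappa multiplier passed to [choose_lambda()].
#' @param w per-bin weights over the non-negative bins.
#' @param bins optional 1-based indices of the non-negative bins over which
#'   `lambda` is estimated (e.g. the bins of the mono-component's band, so
#'   that exact zeros outside the band do not drag the median down).
#' @param energy_smooth odd moving-average width (in bins) applied to the
#'   bin energies before thresholding (default 1 = none).  Averaging tames
#'   the exponential fluctuation of noise-bin energies, so isolated noise
#'   excursions stop forming spurious groups while genuinely elevated bands
#'   keep their level.
#' @param floor_quantile quantile of the (smoothed) bin energies used as
#'   the noise-floor estimate (default 0.5, the median, matching
#'   [choose_lambda()]).  When genuine content occupies more than half of
#'   the band -- e.g. a dense harmonic comb -- the median sits on signal;
#'   a lower quantile such as 0.25 then still reads the floor.
#' @param min_group_len,min_gap group constraints, see
#'   [enforce_group_structure()].
#' @return a `group_sparse_filter` over the non-negative bins, with the
#'   chosen `lambda` stored in field `lambda`.
#' @export
design_group_filter <- function(c_y, lambda = NULL, kappa = 10, w = NULL,
                                bins = NULL, energy_smooth = 1L,
                                floor_quantile = 0.5,
                                min_group_len = 3L, min_gap = 2L) {
  n <- length(c_y)
  half <- c_y[seq_len(n %/% 2L + 1L)]
  e <- Mod(half)^2
  energy_smooth <- as.integer(energy_smooth)
  if (energy_smooth > 1L) {
    kern <- rep(1 / energy_smooth, energy_smooth)
    e <- as.numeric(stats::filter(e, kern, sides = 2))
    hw <- (energy_smooth - 1L) %/% 2L   # shrink-window average at the edges
    for (i in seq_len(hw)) {
      e[i] <- mean(Mod(half[1:(i + hw)])^2)
      j <- length(e) - i + 1L
      e[j] <- mean(Mod(half[(j - hw):length(half)])^2)
    }
  }
  if (is.null(w)) w <- rep(1, length(half))
  if (is.null(lambda)) {
    idx <- if (is.null(bins)) seq_along(e) else bins[bins <= length(e)]
    if (!length(idx)) stop("empty spectrum")
    if (kappa < 0) stop("`kappa` must be non-negative")
    lambda <- kappa * unname(stats::quantile(e[idx], floor_quantile))
  }
  flt <- enforce_group_structure(pointwise_mask(sqrt(e), lambda, w),
                                 min_group_len = min_group_len,
                                 min_gap = min_gap)
  flt$lambda <- lambda
  flt
}
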