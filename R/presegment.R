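#' Spectral trend by mean truncation and maximum-value filtering
#'
#' Values below the spectrum mean are set to zero, then a running maximum
#' over a centred window of `M` bins (clipped at the boundaries) extracts
#' the main trend:
#' `z(n) = max_{k in [n-(M-1)/2, n+(M-1)/2]} (s(k) if s(k) >= mu else 0)`.
#'
#' @param s non-negative numeric vector, length at least 3.
#' @param M odd positive window size, `M <= length(s)`.
#' @return an object of class `spectral_trend`: list with `values` (the
#'   trend `z`), `window`, `mu` (mean of `s`), `total` (`N = sum(z)`) and
#'   `length`.
#' @examples
#' spectral_trend(c(0, 0, 10, 0, 0), 3)$values
#' @export
spectral_trend <- function(s, M) {
  if (any(s < 0) || any(!is.finite(s))) stop("`s` must be finite and non-negative")
  L <- length(s)
  if (L < 3L) stop("`s` must have length >= 3")
  M <- as.integer(M)
  if (M < 1L || M %% 2L == 0L) stop("`M` must be a positive odd integer")
  if (M > L) stop("`M` must not exceed length(s)")
  mu <- mean(s)
  st <- ifelse(s >= mu, s, 0)
  half <- (M - 1L) %/% 2L
  z <- vapply(seq_len(L), function(n) {
    max(st[max(1L, n - half):min(L, n + half)])
  }, numeric(1))
  structure(list(values = z, window = M, mu = mu, total = sum(z), length = L),
            class = "spectral_trend")
}

#' @export
print.spectral_trend <- function(x, ...) {
  cat(sprintf("<spectral_trend: L = %d, M = %d, mu = %.4g, N = %.4g>\n",
              x$length, x$window, x$mu, x$total))
  invisible(x)
}

#' Proportion of trend mass on an interval
#'
#' `Q(a, b) = sum_{i = a..b} z(i) / N` where `N = sum(z)`; the full interval
#' has proportion 1.
#'
#' @param z a `spectral_trend` or non-negative numeric vector.
#' @param interval inclusive 1-based index pair `c(a, b)`.
#' @return scalar proportion in `[0, 1]`.
#' @export
proportions <- function(z, interval) {
  v <- if (inherits(z, "spectral_trend")) z$values else as.numeric(z)
  total <- sum(v)
  if (total <= 0) stop("degenerate trend: total mass is zero")
  a <- as.integer(interval[1L]); b <- as.integer(interval[2L])
  if (a < 1L || b > length(v) || a > b) stop("invalid interval")
  sum(v[a:b]) / total
}

#' Binomial upper tail, extended to real arguments
#'
#' `B(n, k, p) = sum_{j >= k} choose(n, j) p^j (1-p)^(n-j)`, the probability
#' of at least `k` successes out of `n`.  Non-integer `n`, `k` (which arise
#' when spectral amplitudes are read as sample counts) are handled through
#' the regularised incomplete beta function `I_p(k, n - k + 1)`, which
#' agrees with the sum at integer arguments.
#'
#' @param n number of trials (real, `>= 0`).
#' @param k success threshold (real, `0 <= k <= n`).
#' @param p success probability.
#' @return tail probability in `[0, 1]`.
#' @examples
#' binomial_tail(4, 2, 0.5)  # 11/16
#' @export
binomial_tail <- function(n, k, p) {
  if (any(p < 0) || any(p > 1)) stop("`p` must be in [0, 1]")
  if (k < 0 || n < 0 || k > n) stop("need 0 <= k <= n")
  if (k <= 0) return(1)
  if (p == 0) return(0)              # k > 0 successes impossible
  if (p == 1) return(1)              # all n successes, n >= k
  # I_p(k, n - k + 1); at k = n this is p^n
  stats::pbeta(p, k, n - k + 1)
}

#' Number of false alarms for an interval of a trend
#'
#' The a-contrario meaningfulness score
#' `NFA = L(L+1)/2 * B(N, NQ, P)` when the observed proportion `Q` exceeds
#' the model proportion `P`, and `L(L+1)/2 * B(N, N(1-Q), 1-P)` otherwise.
#' Small values (at most the acceptance threshold, 1/2 by default in the
#' segmentation) mean the interval deviates meaningfully from the model.
#'
#' @param interval index pair (diagnostic only; not used in the value).
#' @param Q observed proportion on the interval.
#' @param P model proportion on the interval.
#' @param L trend length (number of bins).
#' @param N total pseudo-count of the trend.
#' @return non-negative NFA value.
#' @examples
#' nfa(c(1, 3), Q = 1, P = 0.5, L = 3, N = 10)  # 6/1024
#' @export
nfa <- function(interval, Q, P, L, N) {
  if (Q < 0 || Q > 1 || P < 0 || P > 1) stop("`Q` and `P` must be in [0, 1]")
  ntests <- L * (L + 1) / 2
  tail <- if (Q >= P) binomial_tail(N, N * Q, P)
          else binomial_tail(N, N * (1 - Q), 1 - P)
  ntests * tail
}

# pool-adjacent-violators: least-squares projection onto the monotone
# non-increasing cone (iterated pooling of increasing runs to their mean)
pava_decreasing <- function(r) {
  n <- length(r)
  if (n <= 1L) return(as.numeric(r))
  # blocks with value, weight (length)
  val <- as.numeric(r)
  wt <- rep(1, n)
  m <- 0L
  bv <- numeric(n); bw <- numeric(n)
  for (i in seq_len(n)) {
    m <- m + 1L
    bv[m] <- val[i]; bw[m] <- 1
    while (m > 1L && bv[m - 1L] < bv[m]) {   # violation of non-increasing
      v <- (bv[m - 1L] * bw[m - 1L] + bv[m] * bw[m]) / (bw[m - 1L] + bw[m])
      bw[m - 1L] <- bw[m - 1L] + bw[m]
      bv[m - 1L] <- v
      m <- m - 1L
    }
  }
  rep(bv[seq_len(m)], bw[seq_len(m)])
}

#' Grenander-type monotone estimate of a sequence
#'
#' Nearest (least-squares) non-increasing approximation of a non-negative
#' sequence, computed by pooling adjacent violators -- i.e. repeatedly
#' replacing each increasing run by its mean until none remains.  The total
#' is preserved.  The non-decreasing case follows by symmetry (reversal).
#'
#' @param r finite non-negative numeric vector.
#' @return non-increasing numeric vector with `sum(out) == sum(r)`.
#' @examples
#' grenander_decreasing(c(1, 3, 2))  # 2 2 2
#' @export
grenander_decreasing <- function(r) {
  if (any(!is.finite(r)) || any(r < 0)) stop("`r` must be finite and non-negative")
  pava_decreasing(r)
}

#' @rdname grenander_decreasing
#' @export
grenander_increasing <- function(r) {
  if (any(!is.finite(r)) || any(r < 0)) stop("`r` must be finite and non-negative")
  rev(pava_decreasing(rev(r)))
}

grenander_monotone <- function(r, direction = c("non-increasing", "non-decreasing")) {
  direction <- match.arg(direction)
  if (direction == "non-increasing") grenander_decreasing(r)
  else grenander_increasing(r)
}

#' Nearest unimodal probability estimate (minimum KL divergence)
#'
#' Scans every candidate mode position, fits a non-decreasing Grenander
#' estimate to the left part and a non-increasing one to the right part,
#' renormalises, and returns the candidate minimising the Kullback-Leibler
#' divergence `KL(rt || candidate)`.  A sequence that is already unimodal is
#' returned unchanged (zero divergence).
#'
#' @param rt non-negative probability vector summing to 1.
#' @return list with `estimate` (unimodal probability vector), `mode`
#'   (1-based mode position) and `kl` (attained divergence).
#' @export
unimodal_kl_estimate <- function(rt) {
  rt <- as.numeric(rt)
  if (any(rt < 0)) stop("`rt` must be non-negative")
  if (sum(rt) <= 0) stop("degenerate input: all zeros")
  rt <- rt / sum(rt)
  L <- length(rt)
  kl_div <- function(p, q) {
    pos <- p > 0
    if (any(q[pos] <= 0)) return(Inf)
    sum(p[pos] * log(p[pos] / q[pos]))
  }
  best <- NULL; best_kl <- Inf; best_mode <- 1L
  for (cpos in seq_len(L)) {
    left <- if (cpos > 1L) grenander_increasing(rt[seq_len(cpos)]) else rt[1L]
    right <- if (cpos < L) grenander_decreasing(rt[(cpos + 1L):L]) else numeric(0)
    cand <- c(left, right)
    s <- sum(cand)
    if (s <= 0) next
    cand <- cand / s
    kl <- kl_div(rt, cand)
    if (kl < best_kl - 1e-15) {
      best_kl <- kl; best <- cand; best_mode <- cpos
    }
  }
  list(estimate = best, mode = best_mode, kl = max(best_kl, 0))
}

# smallest NFA over all sub-intervals of `r` against its monotone Grenander
# estimate; Inf when every interval matches the estimate (e.g. r already
# monotone). `total` is the pseudo-count the amplitudes stand for.  Long
# segments are pooled to at most `max_bins` mass-preserving super-bins
# before the quadratic interval sweep (the tested intervals are then a
# subset of the original ones), keeping the sweep O(max_bins^2).
monotone_min_nfa <- function(r, direction = "non-increasing", total = NULL,
                             max_bins = 200L) {
  r <- as.numeric(r)
  if (length(r) <= 1L || sum(r) <= 0) return(Inf)
  if (is.null(total)) total <- sum(r)
  rt <- r / sum(r)
  rbar <- grenander_monotone(rt, direction)
  rbar <- rbar / sum(rbar)
  if (length(rt) > max_bins) {
    pool <- ceiling(length(rt) / max_bins)
    grp <- (seq_along(rt) - 1L) %/% pool
    rt <- as.numeric(tapply(rt, grp, sum))
    rbar <- as.numeric(tapply(rbar, grp, sum))
  }
  L <- length(rt)
  cq <- c(0, cumsum(rt))
  cp <- c(0, cumsum(rbar))
  ab <- which(upper.tri(matrix(0, L + 1L, L + 1L)), arr.ind = TRUE)
  a <- ab[, 1L]; b2 <- ab[, 2L]          # interval [a, b2-1] in bin indices
  Q <- cq[b2] - cq[a]
  P <- cp[b2] - cp[a]
  keep <- abs(Q - P) >= 1e-12            # no deviation, not a testable event
  if (!any(keep)) return(Inf)
  Q <- Q[keep]; P <- P[keep]
  up <- Q >= P
  tail <- numeric(length(Q))
  # vectorised binomial tails via the regularised incomplete beta
  if (any(up)) {
    k <- pmin(total, total * Q[up])
    tail[up] <- ifelse(k <= 0, 1,
                       ifelse(P[up] == 0, 0,
                              stats::pbeta(P[up], k, total - k + 1)))
  }
  if (any(!up)) {
    k <- pmin(total, total * (1 - Q[!up]))
    tail[!up] <- ifelse(k <= 0, 1,
                        ifelse(P[!up] == 1, 0,
                               stats::pbeta(1 - P[!up], k, total - k + 1)))
  }
  L * (L + 1) / 2 * min(tail)
}

#' Statistical monotonicity test for a trend segment
#'
#' A segment is statistically monotone in the stated direction when no
#' sub-interval deviates meaningfully (NFA at most `delta`) from the
#' segment's Grenander monotone estimate.  Strictly monotone segments and
#' length-1 segments always pass.
#'
#' @param segment non-negative numeric vector (a slice of a spectral trend).
#' @param direction `"non-increasing"` or `"non-decreasing"`.
#' @param delta decision threshold in `(0, 1]`; default 0.5.
#' @param total optional pseudo-count override for the segment mass.
#' @return logical: `TRUE` when the segment passes.
#' @export
monotone_test <- function(segment, direction = c("non-increasing", "non-decreasing"),
                          delta = 0.5, total = NULL) {
  direction <- match.arg(direction)
  monotone_min_nfa(segment, direction, total = total) > delta
}

# split 1..L into maximal strictly monotone runs of z (plateaus attach to
# the running direction); returns data.frame(start, end, dir) with dir
# +1 = non-decreasing, -1 = non-increasing
monotone_runs <- function(z) {
  L <- length(z)
  if (L == 1L) return(data.frame(start = 1L, end = 1L, dir = 1L))
  d <- sign(diff(z))
  runs <- list()
  start <- 1L
  cur <- 0L
  for (i in seq_along(d)) {
    if (d[i] == 0) next
    if (cur == 0L) {
      cur <- d[i]
    } else if (d[i] != cur) {
      runs[[length(runs) + 1L]] <- c(start, i, cur)
      start <- i + 1L
      cur <- d[i]
    }
  }
  runs[[length(runs) + 1L]] <- c(start, L, if (cur == 0L) 1L else cur)
  out <- do.call(rbind, runs)
  data.frame(start = out[, 1L], end = out[, 2L], dir = out[, 3L])
}

# merge candidate: NFA-based score of treating runs i..j as one monotone run
merged_run_score <- function(zc, s, e) {
  up <- monotone_min_nfa(zc[s:e], "non-decreasing")
  down <- monotone_min_nfa(zc[s:e], "non-increasing")
  if (up >= down) list(score = up, dir = 1L) else list(score = down, dir = -1L)
}

# segment one positive block of the trend (zc already pseudo-count scaled)
segment_block <- function(zc, delta) {
  runs <- monotone_runs(zc)
  # fine-to-coarse: repeatedly merge the adjacent pair whose merged segment
  # is most plausibly monotone (largest min-NFA), while it passes the test
  repeat {
    if (nrow(runs) <= 1L) break
    best_i <- 0L; best_score <- -Inf; best_dir <- 1L
    for (i in seq_len(nrow(runs) - 1L)) {
      m <- merged_run_score(zc, runs$start[i], runs$end[i + 1L])
      if (m$score > best_score) {
        best_score <- m$score; best_i <- i; best_dir <- m$dir
      }
    }
    if (best_score <= delta) break    # every candidate merge is rejected
    runs <- data.frame(
      start = c(runs$start[seq_len(best_i - 1L)], runs$start[best_i],
                runs$start[-seq_len(best_i + 1L)]),
      end = c(runs$end[seq_len(best_i - 1L)], runs$end[best_i + 1L],
              runs$end[-seq_len(best_i + 1L)]),
      dir = c(runs$dir[seq_len(best_i - 1L)], best_dir,
              runs$dir[-seq_len(best_i + 1L)]))
  }
  # pair runs into unimodal segments: one non-decreasing run optionally
  # followed by one non-increasing run.  After the merge fixpoint every
  # surviving run boundary is statistically significant, so two runs of the
  # same direction must not be glued into a single ascending/descending
  # phase (the jump between them is a real feature of the trend).
  segs <- list()
  i <- 1L
  while (i <= nrow(runs)) {
    s <- runs$start[i]
    if (runs$dir[i] > 0L && i < nrow(runs) && runs$dir[i + 1L] < 0L) {
      e <- runs$end[i + 1L]
      i <- i + 2L
    } else {
      e <- runs$end[i]
      i <- i + 1L
    }
    segs[[length(segs) + 1L]] <- c(s, e)
  }
  segs
}

#' Unimodal pre-segmentation of a spectrum
#'
#' Extracts the spectral trend (mean truncation + maximum filter), splits its
#' positive support into strictly monotone runs, merges adjacent runs
#' fine-to-coarse while the merged run remains statistically monotone at
#' level `delta`, and pairs increasing/decreasing runs into unimodal
#' segments.  Segments are disjoint, ordered, and jointly cover all indices
#' where the trend is positive.
#'
#' @param spectrum non-negative numeric vector (e.g. a Blaschke spectrum),
#'   length at least 3.
#' @param M odd maximum-filter window (default 5); clamped to the spectrum
#'   length when `clamp_window = TRUE`.
#' @param delta decision threshold in `(0, 1]` for the monotone test
#'   (default 0.5).
#' @param count_total pseudo-count that the whole trend mass stands for in
#'   the a-contrario test; spectral amplitudes are treated as sample counts,
#'   so their arbitrary physical scale is normalised away.  The default
#'   `NULL` uses 100 counts per spectrum bin, keeping the test's power
#'   independent of both the amplitude units and the spectrum length.
#'   Use `NA` to take the raw trend sum as the count.
#' @param clamp_window clamp an over-long `M` to the largest odd value that
#'   fits, with a warning (default `FALSE`: error instead).
#' @return an object of class `unimodal_segmentation`: list with `segments`
#'   (data.frame with columns `a`, `b`, `peak`, `min_nfa`; 1-based inclusive
#'   indices), `trend` (the `spectral_trend`), `delta`, `count_total`.
#' @export
presegment <- function(spectrum, M = 5L, delta = 0.5, count_total = NULL,
                       clamp_window = FALSE) {
  spectrum <- as.numeric(spectrum)
  if (length(spectrum) < 3L) stop("`spectrum` must have length >= 3")
  if (delta <= 0 || delta > 1) stop("`delta` must be in (0, 1]")
  M <- as.integer(M)
  if (clamp_window && M > length(spectrum)) {
    M2 <- length(spectrum) - (1L - length(spectrum) %% 2L)
    warning(sprintf("window M = %d exceeds spectrum length; clamped to %d", M, M2))
    M <- M2
  }
  trend <- spectral_trend(spectrum, M)
  z <- trend$values
  empty <- data.frame(a = integer(0), b = integer(0), peak = integer(0),
                      min_nfa = numeric(0))
  if (all(z == 0)) {
    warning("degenerate trend: all zero; empty segmentation")
    return(structure(list(segments = empty, trend = trend, delta = delta,
                          count_total = count_total),
                     class = "unimodal_segmentation"))
  }
  if (is.null(count_total)) count_total <- 100 * length(spectrum)
  scale <- if (is.na(count_total)) 1 else count_total / sum(z)
  zc <- z * scale
  # maximal blocks of positive trend
  pos <- z > 0
  rl <- rle(pos)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  rows <- list()
  for (bi in seq_along(rl$values)) {
    if (!rl$values[bi]) next
    s <- starts[bi]; e <- ends[bi]
    segs <- if (e > s) segment_block(zc[s:e], delta) else list(c(1L, 1L))
    for (sg in segs) {
      a <- s + sg[1L] - 1L
      b <- s + sg[2L] - 1L
      peak <- a - 1L + which.max(z[a:b])
      mn <- min(
        if (peak > a) monotone_min_nfa(zc[a:peak], "non-decreasing") else Inf,
        if (peak < b) monotone_min_nfa(zc[peak:b], "non-increasing") else Inf)
      rows[[length(rows) + 1L]] <- data.frame(a = a, b = b, peak = peak,
                                              min_nfa = mn)
    }
  }
  segments <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(segments) <- NULL
  structure(list(segments = segments, trend = trend, delta = delta,
                 count_total = count_total),
            class = "unimodal_segmentation")
}

#' @export
print.unimodal_segmentation <- function(x, ...) {
  cat(sprintf("<unimodal_segmentation: %d segment(s), delta = %g>\n",
              nrow(x$segments), x$delta))
  if (nrow(x$segments)) print(x$segments)
  invisible(x)
}
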