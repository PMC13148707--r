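#' Dictionary of unit-disk parameters for the adaptive Blaschke transform
#'
#' Builds a polar grid of candidate parameters `a` strictly inside the unit
#' disk.  The origin `a = 0` is always included (the transform then contains
#' the Fourier basis as a special case); each positive radius contributes
#' `phase_count` uniformly spaced phases.
#'
#' @param radii radii in `[0, 1)`; default `seq(0, 0.9, by = 0.1)`.
#' @param phase_count phases per positive radius; default 64.
#' @return an object of class `disk_dictionary` with fields `atoms`
#'   (complex vector), `magnitude_grid` and `phase_count`.
#' @examples
#' d <- disk_dictionary(radii = c(0, 0.5), phase_count = 4)
#' d$atoms
#' @export
disk_dictionary <- function(radii = seq(0, 0.9, by = 0.1), phase_count = 64L) {
  if (any(radii < 0 | radii >= 1)) stop("all radii must lie in [0, 1)")
  phase_count <- as.integer(phase_count)
  if (phase_count < 1L) stop("`phase_count` must be >= 1")
  atoms <- 0 + 0i
  for (r in sort(unique(radii))) {
    if (r > 0)
      atoms <- c(atoms, r * exp(2i * pi * (seq_len(phase_count) - 1) / phase_count))
  }
  structure(list(atoms = atoms, magnitude_grid = sort(unique(radii)),
                 phase_count = phase_count),
            class = "disk_dictionary")
}

#' @export
print.disk_dictionary <- function(x, ...) {
  cat(sprintf("<disk_dictionary: %d atoms, radii {%s} x %d phases>\n",
              length(x$atoms), paste(x$magnitude_grid, collapse = ", "),
              x$phase_count))
  invisible(x)
}

dict_atoms <- function(dict) {
  if (inherits(dict, "disk_dictionary")) return(dict$atoms)
  atoms <- as.complex(dict)
  if (length(atoms) == 0L) stop("dictionary must contain at least one atom")
  if (any(Mod(atoms) >= 1)) stop("all dictionary atoms must satisfy |a| < 1")
  atoms
}

#' Normalised Szego kernel on the unit circle
#'
#' Evaluates `e_a(z) = sqrt(1 - |a|^2) / (1 - Conj(a) * z)`, the reproducing
#' kernel of the Hardy space normalised to unit norm on the circle, at the
#' given grid points.
#'
#' @param a complex parameter with `|a| < 1`.
#' @param grid complex vector of unit-circle points (e.g. `exp(2i*pi*t/N)`).
#' @return complex vector of kernel values.
#' @examples
#' szego_kernel(0.5 + 0i, 1 + 0i)  # sqrt(0.75) / 0.5
#' @export
szego_kernel <- function(a, grid) {
  a <- as.complex(a)
  if (length(a) != 1L || Mod(a) >= 1) stop("`a` must satisfy |a| < 1")
  sqrt(1 - Mod(a)^2) / (1 - Conj(a) * grid)
}

# Moebius/Blaschke factor (z - a)/(1 - Conj(a) z); unimodular on |z| = 1
blaschke_factor <- function(a, grid) (grid - a) / (1 - Conj(a) * grid)

#' Blaschke mono-component of a given order
#'
#' Evaluates the order-`n` element of the Takenaka-Malmquist rational
#' orthonormal system generated by the parameter sequence:
#' `B_n(z) = e_{a_n}(z) * prod_{k < n} (z - a_k) / (1 - Conj(a_k) z)`.
#' With all parameters zero this reduces to the Fourier basis `z^(n-1)`;
#' with `a_1 = 0`, `B_1` is the constant 1.
#'
#' @param params complex vector of parameters `a_1..a_m`, all `|a| < 1`.
#' @param n order, `1 <= n <= length(params)`.
#' @param grid complex vector of unit-circle points.
#' @return complex vector, the mono-component evaluated on the grid.
#' @examples
#' z <- exp(2i * pi * (0:15) / 16)
#' max(Mod(blaschke_mono_component(c(0i, 0i, 0i), 3, z) - z^2))
#' @export
blaschke_mono_component <- function(params, n, grid) {
  params <- as.complex(params)
  if (any(Mod(params) >= 1)) stop("all parameters must satisfy |a| < 1")
  n <- as.integer(n)
  if (n < 1L || n > length(params)) stop("`n` must be in 1..length(params)")
  out <- szego_kernel(params[n], grid)
  if (n > 1L) {
    for (k in seq_len(n - 1L)) out <- out * blaschke_factor(params[k], grid)
  }
  out
}

#' Quasi-periodicity score of a candidate component
#'
#' The selection functional of the adaptive transform: the magnitude of the
#' aggregated autocorrelation `|sum_{m>=1} R(m)| / N`, where `R(m)` is the
#' biased sample autocorrelation of the complex component at lag `m`.  The
#' score is non-negative, zero for a zero component, and invariant to a sign
#' flip (or any global phase) of the component.
#'
#' @param component complex (or real) vector, length at least 8.
#' @return non-negative scalar score.
#' @export
quasi_periodicity_score <- function(component) {
  g <- as.complex(component)
  n <- length(g)
  if (n < 8L) stop("`component` must have length >= 8")
  if (all(Mod(g) == 0)) return(0)
  prefix <- cumsum(g)
  s <- sum(Conj(g[-1L]) * prefix[-n])
  Mod(s) / n^2
}

# score + coefficient for every atom, pure R (reference path / oracle)
scan_atoms_r <- function(f, Bprod, atoms, grid) {
  n <- length(f)
  score <- numeric(length(atoms))
  coeff <- complex(length(atoms))
  for (j in seq_along(atoms)) {
    e <- szego_kernel(atoms[j], grid)
    u <- e / sqrt(norm2_disc(e))
    cc <- ip_disc(f, u)
    score[j] <- quasi_periodicity_score(cc * u * Bprod)
    coeff[j] <- cc
  }
  list(score = score, coeff = coeff)
}

#' Select the dictionary parameter with the strongest quasi-periodicity
#'
#' Scores every dictionary atom by the quasi-periodicity of its candidate
#' component (the projection of the current residual onto the atom's
#' normalised Szego kernel, carried by the accumulated Blaschke product) and
#' returns the argmax.  Ties are broken by the smallest dictionary index.
#'
#' @param f_k an [analytic_extension()] result or complex vector (current
#'   transform residual).
#' @param dict a [disk_dictionary()] or complex vector of atoms.
#' @param Bprod accumulated Blaschke product on the grid (default all ones,
#'   i.e. first order).
#' @param use_cpp use the compiled scanner (default `TRUE`); the R scanner
#'   is retained as a reference path.
#' @return list with `atom` (complex), `index`, `score`, `coeff`.
#' @export
select_parameter <- function(f_k, dict, Bprod = NULL, use_cpp = TRUE) {
  f <- if (inherits(f_k, "analytic_signal")) f_k$samples else as.complex(f_k)
  atoms <- dict_atoms(dict)
  n <- length(f)
  grid <- circle_grid(n)
  if (is.null(Bprod)) Bprod <- rep(1 + 0i, n)
  res <- if (use_cpp) scan_atoms_cpp(f, Bprod, atoms, grid)
         else scan_atoms_r(f, Bprod, atoms, grid)
  idx <- which.max(res$score)   # which.max returns the first maximum
  list(atom = atoms[idx], index = idx, score = res$score[idx],
       coeff = res$coeff[idx])
}

#' One order of the Blaschke recursion
#'
#' Projects the residual `f_k` onto the (discretely normalised) Szego kernel
#' of `a_k`, removes the projection, and divides by the Blaschke factor to
#' produce the next residual:
#' `f_{k+1} = (f_k - c_k u_{a_k}) / ((z - a_k)/(1 - Conj(a_k) z))`.
#' Energy is conserved exactly: `||f_k||^2 = |c_k|^2 + ||f_{k+1}||^2` under
#' the discrete inner product.
#'
#' @param f_k complex vector or `analytic_signal` (current residual).
#' @param a_k complex parameter, `|a_k| < 1`.
#' @return list with `coeff` (complex scalar) and `f_next` (complex vector).
#' @export
residual_update <- function(f_k, a_k) {
  f <- if (inherits(f_k, "analytic_signal")) f_k$samples else as.complex(f_k)
  a_k <- as.complex(a_k)
  if (Mod(a_k) >= 1) stop("`a_k` must satisfy |a_k| < 1")
  grid <- circle_grid(length(f))
  e <- szego_kernel(a_k, grid)
  u <- e / sqrt(norm2_disc(e))
  cc <- ip_disc(f, u)
  f_next <- (f - cc * u) / blaschke_factor(a_k, grid)
  list(coeff = cc, f_next = f_next)
}

#' Adaptive Blaschke transform
#'
#' Greedily decomposes a real signal into `K` coefficient-weighted Blaschke
#' mono-components plus a residual.  At each order the dictionary parameter
#' whose candidate component has the strongest quasi-periodicity score is
#' selected, the projection is removed and the residual is deflated by the
#' corresponding Blaschke factor.  The identity
#' `analytic(x) = sum_k component_k + residual` holds to near machine
#' precision, as does per-order energy conservation.
#'
#' @param x real numeric vector (length at least 8) or `analytic_signal`.
#' @param sample_rate sampling rate in Hz; ignored when `x` is already an
#'   `analytic_signal`.
#' @param K maximum transform order (default 64); values exceeding
#'   `length(x)/2` are clamped with a warning.
#' @param dict a [disk_dictionary()] or complex vector of atoms;
#'   default `disk_dictionary()`.
#' @param use_cpp use the compiled dictionary scanner (default `TRUE`).
#' @return an object of class `blaschke_decomposition`: list with `params`,
#'   `coeffs`, `components` (N x K complex matrix), `residual` (complex),
#'   `spectrum` (the Blaschke spectrum `BS(k)`), `sample_rate`, `n`.
#' @examples
#' x <- sin(2 * pi * 5 * (0:255) / 256)
#' d <- blaschke_transform(x, 256, K = 8, dict = 0i)
#' d$spectrum
#' @export
blaschke_transform <- function(x, sample_rate = 1, K = 64L,
                               dict = disk_dictionary(), use_cpp = TRUE) {
  a0 <- as_analytic(x, sample_rate)
  f <- a0$samples
  n <- length(f)
  K <- as.integer(K)
  if (K < 1L) stop("`K` must be >= 1")
  if (K > n %/% 2L) {
    warning(sprintf("K = %d exceeds N/2 = %d; clamping", K, n %/% 2L))
    K <- n %/% 2L
  }
  atoms <- dict_atoms(dict)
  grid <- circle_grid(n)
  Bprod <- rep(1 + 0i, n)
  comps <- matrix(0i, n, K)
  coeffs <- complex(K)
  params <- complex(K)
  for (k in seq_len(K)) {
    if (length(atoms) == 1L) {
      sel <- list(atom = atoms[1L], index = 1L)
    } else {
      sel <- select_parameter(f, atoms, Bprod = Bprod, use_cpp = use_cpp)
    }
    a <- sel$atom
    e <- szego_kernel(a, grid)
    u <- e / sqrt(norm2_disc(e))
    cc <- ip_disc(f, u)
    comps[, k] <- cc * u * Bprod
    coeffs[k] <- cc
    params[k] <- a
    bf <- blaschke_factor(a, grid)
    f <- (f - cc * u) / bf
    Bprod <- Bprod * bf
  }
  out <- structure(
    list(params = params, coeffs = coeffs, components = comps,
         residual = f * Bprod, spectrum = NULL,
         sample_rate = a0$sample_rate, n = n),
    class = "blaschke_decomposition")
  out$spectrum <- blaschke_spectrum(out)
  out
}

#' @export
print.blaschke_decomposition <- function(x, ...) {
  cat(sprintf(
    "<blaschke_decomposition: %d orders, N = %d @ %g Hz, resid energy %.3g>\n",
    length(x$coeffs), x$n, x$sample_rate, norm2_disc(x$residual)))
  invisible(x)
}

#' Blaschke spectrum of a decomposition
#'
#' The mean energy of each coefficient-weighted mono-component,
#' `BS(k) = mean(|c_k B_k|^2)`.  Because mono-components have unit discrete
#' norm this equals `|c_k|^2`; the per-order energies sum to at most the
#' mean power of the analytic input.
#'
#' @param decomp a `blaschke_decomposition`.
#' @return non-negative numeric vector of length `K`.
#' @export
blaschke_spectrum <- function(decomp) {
  stopifnot(inherits(decomp, "blaschke_decomposition"))
  colMeans(Mod(decomp$components)^2)
}

#' Partial reconstruction over an interval of orders
#'
#' Returns the real part of the sum of the coefficient-weighted
#' mono-components with orders in `order_interval`.  Partial reconstructions
#' over a disjoint cover of `1..K` sum to the full reconstruction minus the
#' residual.
#'
#' @param decomp a `blaschke_decomposition`.
#' @param order_interval integer vector `c(a, b)` with `1 <= a <= b <= K`.
#' @return real numeric vector of length `N`.
#' @export
partial_reconstruction <- function(decomp, order_interval) {
  stopifnot(inherits(decomp, "blaschke_decomposition"))
  K <- length(decomp$coeffs)
  a <- as.integer(order_interval[1L])
  b <- as.integer(order_interval[2L])
  if (is.na(a) || is.na(b) || a < 1L || b > K || a > b)
    stop(sprintf("order interval [%s, %s] out of range 1..%d", a, b, K))
  Re(rowSums(decomp$components[, a:b, drop = FALSE]))
}
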