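# weighted-l0 filtering objective of a binary mask (independent oracle form)
gs_objective <- function(energies, mask, lambda, w) {
  sum(energies * (1 - mask)) + lambda * sum(w * mask)
}

test_that("pointwise mask is the energy-detection threshold rule", {
  cy <- complex(modulus = c(3, 1, 0.5), argument = c(0.3, 1, 2))
  expect_equal(pointwise_mask(cy, 0), c(1, 1, 1))
  expect_equal(pointwise_mask(cy, 10), c(0, 0, 0))
  expect_equal(pointwise_mask(cy, 1), c(1, 1, 0))   # energies 9, 1, 0.25
  expect_error(pointwise_mask(cy, -1), "non-negative")
  expect_error(pointwise_mask(cy, 1, w = c(1, 2)), "match")
  expect_error(pointwise_mask(cy, 1, w = c(1, 0, 1)), "positive")
})

test_that("mask support is non-increasing in lambda", {
  for (s in 1:20) {
    cy <- with_test_seed(s, complex(real = rnorm(32), imaginary = rnorm(32)))
    lam <- sort(with_test_seed(s + 50, runif(5, 0, 4)))
    masks <- lapply(lam, function(l) pointwise_mask(cy, l))
    for (i in seq_len(4)) {
      expect_true(all(masks[[i + 1]] <= masks[[i]]))
    }
  }
})

test_that("group structure fills small gaps then drops short groups", {
  f <- enforce_group_structure(c(1, 1, 0, 1, 1), min_group_len = 3, min_gap = 2)
  expect_equal(f$mask, rep(1, 5))
  expect_equal(nrow(f$groups), 1L)

  f2 <- enforce_group_structure(c(0, 0, 1, 0, 0), min_group_len = 2, min_gap = 2)
  expect_equal(f2$mask, rep(0, 5))
  expect_equal(nrow(f2$groups), 0L)

  well <- c(1, 1, 1, 0, 0, 0, 1, 1, 1, 1)
  f3 <- enforce_group_structure(well, min_group_len = 3, min_gap = 2)
  expect_equal(f3$mask, well)

  # invariants on random masks: group lengths and separations respected
  for (s in 1:20) {
    m <- with_test_seed(s, rbinom(40, 1, 0.4))
    g <- enforce_group_structure(m, min_group_len = 3, min_gap = 3)
    if (nrow(g$groups)) {
      expect_true(all(g$groups$end - g$groups$start + 1 >= 3))
      if (nrow(g$groups) > 1)
        expect_true(all(g$groups$start[-1] - g$groups$end[-nrow(g$groups)] - 1 >= 3))
      rebuilt <- numeric(40)
      for (i in seq_len(nrow(g$groups)))
        rebuilt[g$groups$start[i]:g$groups$end[i]] <- 1
      expect_equal(g$mask, rebuilt)
    }
  }
})

test_that("applying a filter is a real-output projection", {
  n <- 128
  x <- with_test_seed(3, rnorm(n))
  cy <- fft(x)
  t_half <- n / 2 + 1

  expect_equal(apply_filter(cy, rep(1, t_half)), x, tolerance = 1e-10)
  expect_equal(apply_filter(cy, rep(0, t_half)), rep(0, n))

  # two tones; a mask over tone 1's bins isolates it
  t <- 0:(n - 1)
  tone1 <- sin(2 * pi * 5 * t / n)
  tone2 <- 0.8 * cos(2 * pi * 20 * t / n)
  mask <- numeric(t_half); mask[5:7] <- 1       # bin 6 = 5 cycles
  y <- apply_filter(fft(tone1 + tone2), mask)
  expect_gt(stats::cor(y, tone1), 0.999)

  # projection: same filter twice equals once
  flt <- enforce_group_structure(pointwise_mask(cy[1:t_half], 2), 3, 2)
  once <- apply_filter(cy, flt)
  twice <- apply_filter(fft(once), flt)
  expect_lt(max(abs(twice - once)), 1e-12 * max(1, max(abs(once))))
  # energy never grows (Parseval)
  expect_lte(sum(once^2), sum(x^2) * (1 + 1e-12))

  expect_error(apply_filter(cy, rep(1, 10)), "matches neither")
})

test_that("median-based lambda keeps dominant lines and drops the noise floor", {
  expect_equal(choose_lambda(rep(2, 16)), 10 * 4)
  expect_equal(choose_lambda(rep(2, 16), kappa = 0), 0)
  kept_line <- 0; dropped_frac <- numeric(50)
  for (s in 1:50) {
    noise <- with_test_seed(s, complex(real = rnorm(200, sd = sqrt(0.5)),
                                       imaginary = rnorm(200, sd = sqrt(0.5))))
    spec <- noise
    spec[77] <- 40 + 0i                  # dominant line, energy 1600 vs ~1
    lam <- choose_lambda(spec)
    m <- pointwise_mask(spec, lam)
    kept_line <- kept_line + m[77]
    dropped_frac[s] <- 1 - mean(m[-77])
  }
  expect_equal(kept_line, 50)
  expect_true(all(dropped_frac >= 0.9))
  expect_error(choose_lambda(complex(0)), "empty")
})

test_that("thresholding minimises the weighted-l0 objective (exhaustive check)", {
  all_masks <- as.matrix(expand.grid(rep(list(0:1), 12)))
  for (s in 1:20) {
    e <- with_test_seed(s, rexp(12))
    w <- with_test_seed(s + 100, runif(12, 0.5, 2))
    lam <- with_test_seed(s + 200, runif(1, 0, 2))
    m <- pointwise_mask(complex(modulus = sqrt(e), argument = rep(0, 12)), lam, w)
    jm <- gs_objective(e, m, lam, w)
    jall <- apply(all_masks, 1, function(f) gs_objective(e, f, lam, w))
    expect_lte(jm, min(jall) + 1e-12)
  }
})

test_that("design_group_filter smooths energies and estimates lambda in-band", {
  n <- 256
  t <- 0:(n - 1)
  x <- sin(2 * pi * 30 * t / n) + 0.05 * with_test_seed(8, rnorm(n))
  flt <- design_group_filter(fft(x), kappa = 4, energy_smooth = 5)
  expect_s3_class(flt, "group_sparse_filter")
  # the single line at bin 31 survives as a compact group
  expect_true(any(flt$groups$start <= 31 & flt$groups$end >= 31))
  expect_gt(flt$lambda, 0)
})
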