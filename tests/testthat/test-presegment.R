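# independent oracle for the binomial upper tail (direct summation of the sum)
binom_tail_direct <- function(n, k, p) {
  if (k <= 0) return(1)
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

# independent least-squares monotone fit via stats::isoreg
iso_decreasing <- function(r) -stats::isoreg(seq_along(r), -r)$yf

test_that("spectral trend applies mean truncation then a clipped maximum filter", {
  expect_equal(spectral_trend(rep(4, 7), 3)$values, rep(4, 7))
  tr <- spectral_trend(c(0, 0, 10, 0, 0), 3)
  expect_equal(tr$values, c(0, 10, 10, 10, 0))
  expect_equal(tr$mu, 2)
  expect_equal(tr$total, 30)
  s <- c(5, 0, 3, 8, 1)
  expect_equal(spectral_trend(s, 1)$values, ifelse(s >= mean(s), s, 0))
  expect_error(spectral_trend(s, 2), "odd")
  expect_error(spectral_trend(s, 7), "exceed")
  expect_error(spectral_trend(c(-1, 2, 3), 1), "non-negative")
})

test_that("interval proportions normalise the trend mass", {
  expect_equal(proportions(c(2, 2, 2, 2), c(1, 4)), 1)
  expect_equal(proportions(rep(1, 10), c(1, 5)), 0.5)
  expect_equal(proportions(c(1, 2, 3, 4), c(3, 4)), 0.7)
  expect_error(proportions(rep(0, 4), c(1, 2)), "degenerate")
  expect_error(proportions(1:4, c(3, 2)), "invalid")
})

test_that("binomial tail matches direct summation and its closed-form points", {
  expect_equal(binomial_tail(7, 0, 0.3), 1)
  expect_equal(binomial_tail(5, 5, 0.5), 0.03125)
  expect_equal(binomial_tail(4, 2, 0.5), 0.6875)
  with_test_seed(12, for (i in 1:50) {
    n <- sample(1:40, 1); k <- sample(0:n, 1); p <- runif(1)
    expect_equal(binomial_tail(n, k, p), binom_tail_direct(n, k, p),
                 tolerance = 1e-12)
  })
  # non-increasing in k
  ks <- seq(0, 12, by = 0.5)
  vals <- vapply(ks, function(k) binomial_tail(12, k, 0.4), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
  expect_error(binomial_tail(4, 5, 0.5), "k <= n")
})

test_that("NFA reproduces the worked example and respects its regimes", {
  expect_equal(nfa(c(1, 3), Q = 1, P = 0.5, L = 3, N = 10), 6 / 1024,
               tolerance = 1e-14)
  expect_equal(nfa(c(1, 1), Q = 1, P = 1, L = 1, N = 25), 1)
  # Q = P with large N is never a meaningful rejection at epsilon = 0.5
  expect_gt(nfa(c(2, 5), Q = 0.4, P = 0.4, L = 10, N = 500), 0.5)
  expect_error(nfa(c(1, 2), Q = 1.4, P = 0.5, L = 3, N = 10), "\\[0, 1\\]")
})

test_that("Grenander estimates equal the least-squares isotonic projection", {
  expect_equal(grenander_decreasing(c(5, 4, 2, 2, 1)), c(5, 4, 2, 2, 1))
  expect_equal(grenander_decreasing(c(1, 3, 2)), c(2, 2, 2))
  with_test_seed(13, for (i in 1:200) {
    r <- runif(sample(2:8, 1), 0, 5)
    g <- grenander_decreasing(r)
    expect_true(all(diff(g) <= 1e-12))
    expect_equal(sum(g), sum(r), tolerance = 1e-10)
    expect_equal(g, iso_decreasing(r), tolerance = 1e-10)
    gi <- grenander_increasing(r)
    expect_equal(gi, rev(iso_decreasing(rev(r))), tolerance = 1e-10)
  })
  expect_error(grenander_decreasing(c(1, -2)), "non-negative")
})

test_that("unimodal KL estimate is exact for unimodal inputs and unimodal always", {
  uni <- c(0.1, 0.3, 0.4, 0.15, 0.05)
  out <- unimodal_kl_estimate(uni)
  expect_equal(out$estimate, uni, tolerance = 1e-12)
  expect_equal(out$kl, 0, tolerance = 1e-12)

  flat <- rep(0.25, 4)
  expect_equal(unimodal_kl_estimate(flat)$kl, 0, tolerance = 1e-12)

  bim <- c(0.4, 0.1, 0.4, 0.1)
  ob <- unimodal_kl_estimate(bim)
  expect_gt(ob$kl, 0)
  d <- diff(ob$estimate)
  peak <- which.max(ob$estimate)
  expect_true(all(d[seq_len(peak - 1)] >= -1e-12))
  expect_true(all(d[seq(peak, length(d))] <= 1e-12) || peak > length(d))
  expect_equal(sum(ob$estimate), 1, tolerance = 1e-12)
  # no scanned mode position can beat the returned divergence
  kl_of <- function(p, q) { i <- p > 0; sum(p[i] * log(p[i] / q[i])) }
  for (cpos in 1:4) {
    left <- if (cpos > 1) grenander_increasing(bim[1:cpos]) else bim[1]
    right <- if (cpos < 4) grenander_decreasing(bim[(cpos + 1):4]) else numeric(0)
    cand <- c(left, right); cand <- cand / sum(cand)
    expect_gte(kl_of(bim, cand), ob$kl - 1e-12)
  }
  expect_error(unimodal_kl_estimate(rep(0, 4)), "degenerate")
})

test_that("statistical monotone test passes monotone segments and is monotone in delta", {
  expect_true(monotone_test(c(9, 7, 5, 3, 1), "non-increasing"))
  expect_true(monotone_test(5, "non-decreasing"))
  # a pronounced interior bump is rejected at delta = 0.5
  bump <- c(100, 90, 80, 300, 300, 300, 60, 50, 40)
  expect_false(monotone_test(bump, "non-increasing", delta = 0.5))
  # rejection set shrinks as delta decreases
  expect_true(monotone_test(bump, "non-increasing", delta = 1e-300))
})

test_that("presegmentation recovers single and double peaks and is deterministic", {
  tri <- c(0, 1, 3, 7, 10, 7, 3, 1, 0)
  seg <- presegment(tri, M = 1, delta = 0.5)
  expect_equal(nrow(seg$segments), 1L)
  support <- which(spectral_trend(tri, 1)$values > 0)
  expect_equal(seg$segments$a, min(support))
  expect_equal(seg$segments$b, max(support))
  expect_equal(seg$segments$peak, which.max(tri))

  two <- c(0, 8, 12, 8, 0, 0, 0, 9, 14, 9, 0)
  seg2 <- presegment(two, M = 1, delta = 0.5)
  expect_equal(nrow(seg2$segments), 2L)
  expect_equal(seg2$segments$peak, c(3L, 9L))

  # deterministic: repeated runs agree exactly
  spec <- with_test_seed(17, runif(64, 0, 10))
  r1 <- presegment(spec, M = 5)
  r2 <- presegment(spec, M = 5)
  expect_identical(r1$segments, r2$segments)

  expect_warning(sempty <- presegment(c(1, 1, 1) * 0, M = 1), "degenerate")
  expect_equal(nrow(sempty$segments), 0L)
})

test_that("lowering delta never splits the spectrum into more segments", {
  for (s in 1:5) {
    spec <- with_test_seed(100 + s, pmax(0, rnorm(80, 2, 2)))
    n_small <- nrow(presegment(spec, M = 3, delta = 0.01)$segments)
    n_large <- nrow(presegment(spec, M = 3, delta = 0.5)$segments)
    expect_lte(n_small, n_large)
  }
})

test_that("segments are disjoint, ordered, and cover the positive trend", {
  for (s in 1:5) {
    spec <- with_test_seed(200 + s, pmax(0, rnorm(120, 1, 2)))
    seg <- presegment(spec, M = 5, delta = 0.5)
    z <- seg$trend$values
    covered <- unlist(mapply(seq, seg$segments$a, seg$segments$b,
                             SIMPLIFY = FALSE))
    expect_false(any(duplicated(covered)))
    expect_true(all(diff(seg$segments$a) > 0))
    expect_true(all(seg$segments$a <= seg$segments$peak &
                      seg$segments$peak <= seg$segments$b))
    expect_setequal(setdiff(which(z > 0), covered), integer(0))
  }
})
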