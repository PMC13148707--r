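test_that("analytic extension has one-sided spectrum and exact real part", {
  n <- 64
  t <- 0:(n - 1)
  a <- analytic_extension(cos(2 * pi * t / n), n)
  expect_equal(a$samples, exp(2i * pi * t / n), tolerance = 1e-10)

  const <- analytic_extension(rep(3.5, 16), 10)
  expect_equal(const$samples, rep(3.5 + 0i, 16), tolerance = 1e-12)

  x <- with_test_seed(11, rnorm(257))
  ax <- analytic_extension(x, 100)
  expect_lt(max(abs(Re(ax$samples) - x)), 1e-10)
  # negative-frequency half of the spectrum is zero
  X <- fft(ax$samples)
  expect_lt(max(Mod(X[(ceiling(257 / 2) + 2):257])), 1e-8 * max(Mod(X)))

  expect_error(analytic_extension(c(1, NA, rep(0, 10)), 1), "finite")
  expect_error(analytic_extension(rnorm(5), 1), "length")
  expect_error(analytic_extension(rnorm(16), -1), "sample_rate")
})

test_that("Szego kernel matches its closed form and has unit discrete norm", {
  expect_equal(szego_kernel(0 + 0i, circle_grid_pts(32)), rep(1 + 0i, 32))
  expect_equal(szego_kernel(0.5 + 0i, 1 + 0i), complex(real = sqrt(0.75) / 0.5),
               tolerance = 1e-7)
  g <- circle_grid_pts(4096)
  e <- szego_kernel(0.3 + 0.2i, g)
  expect_equal(mean(Mod(e)^2), 1, tolerance = 1e-4)
  expect_error(szego_kernel(1 + 0i, g), "\\|a\\| < 1")
})

test_that("Takenaka-Malmquist components: Fourier limit, unimodularity, orthonormality", {
  g <- circle_grid_pts(256)
  # first-order convention: a_1 = 0 gives the constant component
  expect_equal(blaschke_mono_component(c(0i, 0.3 + 0.1i), 1, g), rep(1 + 0i, 256))
  # all-zero parameters give the Fourier basis z^(n-1)
  expect_equal(blaschke_mono_component(rep(0i, 5), 4, g), g^3, tolerance = 1e-12)
  # pure Blaschke product factor is unimodular on the circle
  atoms <- with_test_seed(5, complex(real = runif(6, -0.6, 0.6),
                                     imaginary = runif(6, -0.6, 0.6)))
  prod_factor <- blaschke_mono_component(atoms, 6, g) / szego_kernel(atoms[6], g)
  expect_lt(max(abs(Mod(prod_factor) - 1)), 1e-10)
  # distinct orders are orthonormal under the discrete inner product
  n <- 1024
  gg <- circle_grid_pts(n)
  atoms <- with_test_seed(7, 0.7 * runif(5) * exp(2i * pi * runif(5)))
  B <- vapply(1:5, function(k) blaschke_mono_component(atoms, k, gg),
              complex(n))
  gram <- crossprod(Conj(B), B) / n
  expect_lt(max(Mod(gram - diag(5))), 1e-6)
  expect_error(blaschke_mono_component(c(0i, 1.2 + 0i), 2, g), "\\|a\\| < 1")
})

test_that("quasi-periodicity score prefers periodic components and is sign-invariant", {
  n <- 1024
  per <- analytic_extension(sqrt(2) * cos(2 * pi * 8 * (0:(n - 1)) / n), 1)$samples
  sp <- quasi_periodicity_score(per)
  wins <- 0
  for (s in 1:100) {
    noise <- analytic_extension(with_test_seed(s, rnorm(n)), 1)$samples
    noise <- noise * sqrt(mean(Mod(per)^2) / mean(Mod(noise)^2))
    if (sp > quasi_periodicity_score(noise)) wins <- wins + 1
  }
  expect_gte(wins, 95)

  expect_identical(quasi_periodicity_score(rep(0 + 0i, 32)), 0)
  x <- with_test_seed(3, rnorm(64))
  expect_equal(quasi_periodicity_score(x), quasi_periodicity_score(-x))
})

test_that("select_parameter recovers a planted atom and matches the R scan oracle", {
  n <- 512
  g <- circle_grid_pts(n)
  # recovery guarantee within a fixed-radius ring (atoms of comparable
  # quasi-period content); across radii the score deliberately prefers the
  # slower of two nearly collinear kernels
  ring <- 0.6 * exp(2i * pi * (0:15) / 16)
  for (pos in c(2, 7, 13)) {
    a_star <- ring[pos]
    e <- szego_kernel(a_star, g)
    f <- 2 * e / sqrt(mean(Mod(e)^2)) +
      0.01 * analytic_extension(with_test_seed(pos, rnorm(n)), 1)$samples
    expect_equal(select_parameter(f, ring)$atom, a_star)
  }
  # in a mixed-radius dictionary the selected kernel still captures the
  # planted component's direction almost entirely
  dict <- disk_dictionary(radii = c(0, 0.3, 0.6), phase_count = 16)
  a_star <- dict$atoms[20]
  e <- szego_kernel(a_star, g)
  u_star <- e / sqrt(mean(Mod(e)^2))
  f <- 2 * u_star +
    0.01 * analytic_extension(with_test_seed(2, rnorm(n)), 1)$samples
  sel <- select_parameter(f, dict)
  e_sel <- szego_kernel(sel$atom, g)
  u_sel <- e_sel / sqrt(mean(Mod(e_sel)^2))
  expect_gte(Mod(mean(u_sel * Conj(u_star))), 0.9)

  # compiled scanner agrees with the plain-R exhaustive scan
  atoms <- with_test_seed(4, 0.8 * sqrt(runif(50)) * exp(2i * pi * runif(50)))
  for (s in 1:3) {
    f <- analytic_extension(with_test_seed(100 + s, rnorm(n)), 1)$samples
    cpp <- select_parameter(f, atoms, use_cpp = TRUE)
    ref <- select_parameter(f, atoms, use_cpp = FALSE)
    expect_identical(cpp$index, ref$index)
    expect_equal(cpp$score, ref$score, tolerance = 1e-10)
  }

  expect_equal(select_parameter(f, dict$atoms[7])$atom, dict$atoms[7])
  expect_error(select_parameter(f, complex(0)), "at least one atom")
})

test_that("residual update conserves energy and handles exact representations", {
  n <- 256
  g <- circle_grid_pts(n)
  a <- 0.3 - 0.25i
  e <- szego_kernel(a, g)
  ru <- residual_update(e, a)
  expect_equal(Mod(ru$coeff), 1, tolerance = 1e-6)
  expect_lt(max(Mod(ru$f_next)), 1e-12)

  # component orthogonal to the kernel: zero coefficient, energy preserved
  ru0 <- residual_update(g, 0 + 0i)      # <z, 1> = 0 on the grid
  expect_lt(Mod(ru0$coeff), 1e-12)
  expect_equal(mean(Mod(ru0$f_next)^2), 1, tolerance = 1e-12)

  f <- analytic_extension(with_test_seed(9, rnorm(n)), 1)$samples
  ru2 <- residual_update(f, 0.4i)
  lhs <- mean(Mod(f)^2)
  rhs <- Mod(ru2$coeff)^2 + mean(Mod(ru2$f_next)^2)
  expect_lt(abs(lhs - rhs), 1e-8 * lhs)
  expect_error(residual_update(f, 1.1 + 0i), "\\|a_k\\| < 1")
})

test_that("Blaschke transform reduces to the one-sided Fourier expansion for dict {0}", {
  n <- 1024
  x <- band_limited_signal(n, n_harm = 20, seed = 21)
  d <- blaschke_transform(x, 1, K = 32, dict = 0 + 0i)
  ref <- analytic_fourier_coeffs(x, 32)
  expect_lt(max(Mod(d$coeffs - ref)) / max(Mod(ref)), 1e-8)
  # and the spectrum equals the squared coefficient magnitudes
  expect_equal(d$spectrum, Mod(ref)^2, tolerance = 1e-10)
})

test_that("Blaschke transform reconstructs, conserves energy, and clamps K", {
  n <- 256
  x <- with_test_seed(31, rnorm(n))
  dict <- disk_dictionary(radii = c(0, 0.4), phase_count = 8)
  d <- blaschke_transform(x, 1, K = 12, dict = dict)
  ax <- analytic_extension(x, 1)$samples
  recon <- rowSums(d$components) + d$residual
  expect_lt(sqrt(mean(Mod(recon - ax)^2) / mean(Mod(ax)^2)), 1e-6)
  expect_true(all(d$spectrum >= 0))
  expect_lte(sum(d$spectrum), mean(Mod(ax)^2) * (1 + 1e-10))

  # residual energy is non-increasing in K
  d2 <- blaschke_transform(x, 1, K = 13, dict = dict)
  expect_lte(mean(Mod(d2$residual)^2), mean(Mod(d$residual)^2) + 1e-12)

  expect_warning(blaschke_transform(x, 1, K = 200, dict = 0 + 0i), "clamping")
  z <- blaschke_transform(rep(0, 64), 1, K = 4, dict = 0 + 0i)
  expect_true(all(Mod(z$coeffs) == 0))
})

test_that("a single planted mono-component concentrates the spectrum in order 1", {
  n <- 512
  g <- circle_grid_pts(n)
  dict <- disk_dictionary(radii = c(0, 0.5), phase_count = 8)
  a_star <- dict$atoms[4]
  x <- Re(3 * szego_kernel(a_star, g))
  d <- blaschke_transform(x, 1, K = 8, dict = dict)
  expect_gte(d$spectrum[1] / sum(d$spectrum), 0.99)
})

test_that("partial reconstructions are additive and select Fourier modes in the limit", {
  n <- 512
  x <- band_limited_signal(n, n_harm = 16, seed = 41)
  d <- blaschke_transform(x, 1, K = 20, dict = 0 + 0i)
  full <- partial_reconstruction(d, c(1, 20))
  expect_equal(full, Re(rowSums(d$components)), tolerance = 1e-12)
  split <- partial_reconstruction(d, c(1, 7)) + partial_reconstruction(d, c(8, 20))
  expect_lt(max(abs(split - full)), 1e-10)
  # Fourier limit: an order interval selects exactly those analytic modes
  ref <- analytic_fourier_coeffs(x, 20)
  g <- circle_grid_pts(n)
  direct <- Re(Reduce(`+`, lapply(3:6, function(k) ref[k] * g^(k - 1))))
  expect_equal(partial_reconstruction(d, c(3, 6)), direct, tolerance = 1e-8)
  expect_error(partial_reconstruction(d, c(0, 5)), "out of range")
  expect_error(partial_reconstruction(d, c(5, 21)), "out of range")
})
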