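# builds a square gray image with a prescribed radial amplitude that is
# constant over each rounded-integer-radius annulus (so annulus-mean power
# equals annulus-mean amplitude squared exactly)
annulus_exact_image <- function(n, amp_of_f, seed = 1) {
  r <- round(qipr:::.freq_radius(n))
  amp <- matrix(0, n, n)
  nz <- r >= 1
  amp[nz] <- amp_of_f(r[nz])
  set.seed(seed)
  W <- fft(matrix(rnorm(n * n), n, n))
  ph <- W / ifelse(Mod(W) > 0, Mod(W), 1)
  z <- Re(fft(amp * ph, inverse = TRUE)) / (n * n)
  rng <- range(z)
  qip_gray((z - rng[1]) / diff(rng) * 255)
}

test_that("radial spectrum is flat for an impulse and for unit-modulus noise", {
  m <- matrix(0, 64, 64); m[1, 1] <- 255
  sp <- radial_spectrum(qip_gray(m), "amplitude")
  expect_lt(diff(range(sp$value)) / mean(sp$value), 1e-9)

  wn <- random_phase_image(256, 0, seed = 3)
  fit <- fourier_slope(wn, "spehar")
  expect_lt(abs(fit$slope), 0.05)

  expect_error(radial_spectrum(qip_gray(matrix(0, 4, 8))), "square")
})

test_that("each protocol recovers the constructed spectral exponent", {
  im <- random_phase_image(1024, 1.0, seed = 21)
  expect_lt(abs(fourier_slope(im, "spehar")$slope - (-1)), 0.1)
  expect_lt(abs(fourier_slope(im, "redies")$slope - (-2)), 0.2)  # power scale
  expect_lt(abs(fourier_slope(im, "mather")$slope - (-1)), 0.1)

  # white noise at the protocols' native 1024 (no resampling distortion)
  wn <- random_phase_image(1024, 0, seed = 4)
  expect_lt(abs(fourier_slope(wn, "spehar")$slope), 0.05)
  expect_lt(abs(fourier_slope(wn, "mather")$slope), 0.05)
})

test_that("power-spectrum slope is twice the amplitude slope on annulus-exact input", {
  im <- annulus_exact_image(256, function(f) f^(-1.1))
  sa <- radial_spectrum(im, "amplitude")
  sp <- radial_spectrum(im, "power")
  fa <- qipr:::.ols(log10(sa$f), log10(sa$value))
  fp <- qipr:::.ols(log10(sp$f), log10(sp$value))
  expect_equal(fp$slope, 2 * fa$slope, tolerance = 1e-6)
})

test_that("slope and sigma are invariant under global intensity scaling", {
  im <- random_phase_image(256, 1.3, seed = 9)
  half <- qip_gray(im$pixels * 0.5, scale = "gray8")
  f1 <- fourier_slope(im, "spehar"); f2 <- fourier_slope(half, "spehar")
  expect_equal(f1$slope, f2$slope, tolerance = 1e-6)
  expect_equal(f1$sigma, f2$sigma, tolerance = 1e-6)
})

test_that("sigma vanishes on exact power laws and recovers a log-log ripple", {
  im <- annulus_exact_image(1024, function(f) f^(-1))
  expect_lt(fourier_sigma(im), 1e-3)
  expect_lt(fourier_sigma(im, binned = TRUE), 1e-3)

  # power spectrum with a sinusoidal log-log ripple of amplitude a (in
  # log10 power): integer number of cycles over the fitted decade range
  a <- 0.2
  cyc <- 8
  lrange <- log10(256) - log10(10)
  ripple <- annulus_exact_image(1024, function(f) {
    f^(-1) * 10^(a / 2 * sin(2 * pi * cyc * (log10(f) - 1) / lrange))
  })
  s <- fourier_sigma(ripple)
  expect_lt(abs(s - a^2 / 2) / (a^2 / 2), 0.25)
  # direct residual recomputation from the fit object matches exactly
  fit <- fourier_slope(ripple, "redies")
  rr <- fit$raw_logv - (fit$intercept + fit$slope * fit$raw_logf)
  expect_equal(s, mean(rr^2), tolerance = 1e-12)
  expect_gte(fourier_sigma(ripple, binned = TRUE), 0)
})

test_that("degenerate images give NaN slope and sigma with warnings", {
  flat <- qip_gray(matrix(60, 64, 64))
  expect_warning(f <- fourier_slope(flat, "spehar"), "degenerate")
  expect_true(is.nan(f$slope))
  expect_warning(s <- fourier_sigma(flat), "degenerate")
  expect_true(is.nan(s))
})

test_that("2D box counting matches closed forms and the per-box oracle", {
  # straight axis-aligned boundary: N(L) = side / L exactly -> D = 1
  hp <- qip_gray(cbind(matrix(0, 64, 32), matrix(255, 64, 32)))
  f <- fractal_dim_2d(hp)
  expect_equal(f$N, 64 / f$L)
  expect_equal(f$D, 1, tolerance = 1e-9)

  # salt-and-pepper noise: boundary boxes are nearly all boxes
  set.seed(5)
  sp <- qip_gray(matrix(255 * rbinom(256 * 256, 1, 0.5), 256, 256))
  expect_gte(fractal_dim_2d(sp)$D, 1.9)

  # 16 x 16 toys against the double-loop oracle
  set.seed(6)
  for (rep in 1:5) {
    m <- matrix(255 * rbinom(256, 1, runif(1, 0.2, 0.8)), 16, 16)
    if (length(unique(as.vector(m))) < 2) next
    f <- fractal_dim_2d(qip_gray(m))
    bw <- m < mean(m)
    expect_equal(f$N, vapply(f$L, function(L) oracle_boxcount_2d(bw, L),
                             integer(1)))
  }

  expect_warning(fd <- fractal_dim_2d(qip_gray(matrix(9, 32, 32))), "single class")
  expect_true(is.nan(fd$D))
})

test_that("3D box counting recovers smooth and fractal surface dimensions", {
  ramp <- qip_gray(matrix(rep(seq(0, 255, length.out = 256), each = 256),
                          256, 256))
  expect_equal(fractal_dim_3d(ramp)$D, 2, tolerance = 0.1)

  fb <- fbm_surface(256, 0.8, seed = 7)
  expect_lt(abs(fractal_dim_3d(fb)$D - 2.2), 0.15)

  expect_warning(fd <- fractal_dim_3d(qip_gray(matrix(77, 64, 64))), "constant")
  expect_true(is.nan(fd$D))
})

test_that("fractal dimension falls as the spectral exponent steepens", {
  alphas <- c(0.6, 1.0, 1.4, 1.8)
  d2 <- numeric(0); d3 <- numeric(0)
  for (a in alphas) {
    im <- random_phase_image(256, a, seed = 31)   # common random numbers
    d2 <- c(d2, fractal_dim_2d(im)$D)
    d3 <- c(d3, fractal_dim_3d(im)$D)
  }
  expect_true(all(diff(d2) < 0))
  expect_true(all(diff(d3) < 0))
})

test_that("fBm surfaces carry their prescribed power-spectrum slope", {
  for (H in c(0.3, 0.7)) {
    fb <- fbm_surface(256, H, seed = 8)
    ps <- radial_spectrum(fb, "power")
    keep <- ps$f >= 4 & ps$f <= 64   # resolved range away from alias folding
    fit <- qipr:::.ols(log10(ps$f[keep]), log10(ps$value[keep]))
    expect_lt(abs(fit$slope - (-(2 * H + 2))), 0.1)
  }
})
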