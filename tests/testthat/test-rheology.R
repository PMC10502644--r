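test_that("phase angle covers the solid and fluid limits", {
  expect_equal(phase_angle(complex(real = 1000, imaginary = 0)), 0)
  expect_equal(phase_angle(complex(real = 500, imaginary = 500)), pi / 4)
  expect_equal(phase_angle(complex(real = sqrt(3), imaginary = 1)), pi / 6)
  expect_equal(phase_angle(complex(real = 0, imaginary = 10)), pi / 2)
  expect_error(phase_angle(0 + 0i), "both zero")
  expect_error(phase_angle(complex(real = -1, imaginary = 1)),
               "non-negative")
})

test_that("fluidity endpoints are exact and the map inverts", {
  expect_identical(fluidity_from_phase(0), -1)
  expect_identical(fluidity_from_phase(pi / 2), 1)
  expect_equal(fluidity_from_phase(pi / 4), 0)
  phi <- seq(0, pi / 2, length.out = 101)
  expect_equal(phase_from_fluidity(fluidity_from_phase(phi)), phi,
               tolerance = 1e-12)
  fl <- seq(-1, 1, length.out = 101)
  expect_equal(fluidity_from_phase(phase_from_fluidity(fl)), fl,
               tolerance = 1e-12)
  expect_error(fluidity_from_phase(-0.1), "must lie in")
  expect_error(phase_from_fluidity(1.5), "must lie in")
})

test_that("speed-modulus conversion matches the elastic limit and inverts", {
  expect_equal(modulus_from_speed(1, 0, 1000), 1000)
  expect_equal(modulus_from_speed(0, pi / 3, 1000), 0)
  # glioblastoma-style point (c = 1.07 m/s, fluidity -0.54), frozen from
  # a direct hand evaluation of c^2 rho (1 + cos phi)/2
  phi_gb <- phase_from_fluidity(-0.54)
  expect_equal(modulus_from_speed(1.07, phi_gb, 1000), 1107.9449354485578,
               tolerance = 1e-12)
  cs <- seq(0.3, 3, length.out = 17)
  phis <- seq(0, pi / 2, length.out = 17)
  for (p in phis) {
    expect_equal(speed_from_modulus(modulus_from_speed(cs, p), p), cs,
                 tolerance = 1e-12)
  }
  expect_error(modulus_from_speed(-1, 0.1), "non-negative")
})

test_that("springpot modulus interpolates spring and dashpot", {
  expect_equal(springpot_modulus(springpot_params(123, 0), 77), 123 + 0i)
  expect_equal(springpot_modulus(springpot_params(5, 1), 3),
               2i * pi * 3, tolerance = 1e-12)
  g <- springpot_modulus(springpot_params(1, 0.5), 1 / (2 * pi))
  expect_equal(Mod(g), 1, tolerance = 1e-12)
  expect_equal(Arg(g), pi / 4, tolerance = 1e-12)
  expect_error(springpot_modulus(springpot_params(1, 0.5), -3), "positive")
  expect_error(springpot_params(-1, 0.5), "mu")
  expect_error(springpot_params(1, 1.2), "alpha")
})

test_that("springpot phase is frequency independent and equals alpha*pi/2", {
  freqs <- c(1, 10, 100, 500, 1000, 5000)
  for (alpha in c(0.1, 0.25, 0.5, 0.8, 0.95)) {
    args <- Arg(springpot_modulus(springpot_params(30, alpha), freqs))
    expect_equal(args, rep(alpha * pi / 2, length(freqs)),
                 tolerance = 1e-12)
  }
})

test_that("springpot magnitude is monotone in mu and phase linear in alpha", {
  f <- 500
  mus <- c(10, 20, 50, 100, 400)
  mags <- sapply(mus, function(m)
    Mod(springpot_modulus(springpot_params(m, 0.3), f)))
  expect_true(all(diff(mags) > 0))
  alphas <- seq(0.05, 0.95, by = 0.1)
  phases <- sapply(alphas, function(a)
    Arg(springpot_modulus(springpot_params(50, a), f)))
  expect_equal(phases, alphas * pi / 2, tolerance = 1e-12)
})

test_that("wavenumber to speed/attenuation arithmetic and lossless flag", {
  x <- wavenumber_to_speed_attenuation(complex(real = 2 * pi,
                                               imaginary = 1), 1)
  expect_equal(x$c_mps, 1)
  expect_equal(x$a_mps, 1)
  x <- wavenumber_to_speed_attenuation(complex(real = pi,
                                               imaginary = 10), 500)
  expect_equal(x$c_mps, 1000)
  expect_equal(x$a_mps, 50)
  x <- wavenumber_to_speed_attenuation(2 * pi + 0i, 1)
  expect_equal(x$c_mps, 1)
  expect_true(is.infinite(x$a_mps) && x$lossless)
  expect_error(wavenumber_to_speed_attenuation(-1 + 1i, 10),
               "invalid wavenumber")
})

test_that("fit_springpot recovers noise-free parameters to 1e-6", {
  p <- springpot_params(50, 0.4)
  d <- make_dispersion(p, freqs = seq(200, 800, by = 100))
  fit <- fit_springpot(d)
  expect_equal(fit$params$mu, 50, tolerance = 1e-6)
  expect_equal(fit$params$alpha, 0.4, tolerance = 1e-6)
})

test_that("fit_springpot handles the degenerate elastic case", {
  d <- make_dispersion(springpot_params(2000, 0),
                       freqs = seq(200, 800, by = 100))
  expect_true(all(d$lossless))
  fit <- fit_springpot(d)
  expect_lt(fit$params$alpha, 1e-6)
  expect_equal(fit$params$mu, 2000, tolerance = 1e-6)
})

test_that("fit_springpot reproduces a gel-style (c, fluidity) target", {
  # solid-leaning collagen scenario: c = 0.542 m/s, fluidity = -0.176
  # at 500 Hz; parameters derived analytically, data regenerated, refit
  p <- springpot_from_target(0.542, -0.176, 500)
  d <- make_dispersion(p, freqs = seq(200, 800, by = 100))
  s <- fit_springpot(d, report_freq = 500)$summary
  expect_equal(s$c_mps, 0.542, tolerance = 1e-3)
  expect_equal(s$fluidity, -0.176, tolerance = 1e-3)
})

test_that("fit_springpot rejects underdetermined tables", {
  d <- make_dispersion(springpot_params(50, 0.4), freqs = c(200, 300))
  expect_error(fit_springpot(d), "underdetermined")
})

test_that("fit_springpot bias under 5% noise stays below 2%", {
  p <- springpot_params(50, 0.4)
  freqs <- seq(200, 800, by = 100) # 7 frequencies
  est <- vapply(1:100, function(s) {
    f <- fit_springpot(make_dispersion(p, freqs, noise = 0.05, seed = s))
    c(f$params$mu, f$params$alpha)
  }, numeric(2))
  expect_lt(abs(median(est[1, ]) - 50) / 50, 0.02)
  expect_lt(abs(median(est[2, ]) - 0.4) / 0.4, 0.02)
})

test_that("dispersion tables validate and round trip through CSV", {
  expect_error(dispersion_table(c(300, 200, 400), c_mps = rep(1, 3),
                                a_mps = rep(1, 3)), "increasing")
  d <- make_dispersion(springpot_params(40, 0.35),
                       freqs = seq(200, 600, 100))
  tmp <- tempfile(fileext = ".csv")
  write_dispersion_csv(d, tmp)
  d2 <- read_dispersion_csv(tmp)
  expect_equal(d2$c_mps, d$c_mps, tolerance = 1e-9)
  expect_equal(d2$a_mps, d$a_mps, tolerance = 1e-9)
  # wavenumber-column dialect
  tmp2 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(freq_hz = d$freq_hz, k_re = d$k_re,
                              k_im = d$k_im), tmp2, row.names = FALSE)
  d3 <- read_dispersion_csv(tmp2)
  expect_equal(d3$c_mps, d$c_mps, tolerance = 1e-9)
  unlink(c(tmp, tmp2))
})
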