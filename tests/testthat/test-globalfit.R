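test_that("noise-free two-component data is recovered to 0.1%", {
  truth <- toy_truth(noise_scale = 0)
  img <- gen_streak(truth, seq(0, 400, length.out = 150),
                    seq(650, 780, by = 10), seed = 1)
  fit <- fit_global(img, 2, restarts = 2, seed = 1)
  expect_equal(fit$lifetimes, c(10.5, 45.5), tolerance = 1e-3)
  expect_lt(fit$rms, 1e-6)
})

test_that("single-exponential lifetime matches the log-linear regression oracle", {
  tau <- 37.2
  t <- seq(0, 200, by = 2)
  img <- gen_streak(
    kinetic_ground_truth(lifetimes = tau,
                         das_shapes = default_das_shapes(1, centers = 690,
                                                         fwhms = 20),
                         noise_scale = 0, irf_center = 0,
                         irf_fwhm = c(TR1 = 0)),
    t, 690, seed = 1
  )
  fit <- fit_global(img, 1, restarts = 1, seed = 1)
  oracle <- -1 / unname(coef(lm(log(img$intensity) ~ img$time))[2])
  expect_equal(oracle, tau, tolerance = 1e-12)  # regression oracle is exact here
  expect_equal(fit$lifetimes, oracle, tolerance = 1e-8)
})

test_that("variable projection equals brute-force lifetime grid search on a toy", {
  truth <- toy_truth(noise_scale = 0.02, lifetimes = c(10, 50),
                     rel_amplitude = c(0.5, 0.5))
  img <- gen_streak(truth, seq(0, 250, length.out = 80),
                    c(680, 690, 700), seed = 4)
  fit <- fit_global(img, 2, restarts = 3, seed = 1)
  prep <- list(psitrap:::unpack_image(img))
  grid1 <- seq(8, 12, by = 0.1)
  grid2 <- seq(45, 55, by = 0.1)
  costs <- outer(grid1, grid2, Vectorize(function(a, b) {
    psitrap:::varpro_solve(prep, c(a, b))$ss
  }))
  best <- arrayInd(which.min(costs), dim(costs))
  expect_lte(fit$ss, min(costs) + 1e-12)
  expect_equal(fit$lifetimes[1], grid1[best[1]], tolerance = 0.1 / 8)
  expect_equal(fit$lifetimes[2], grid2[best[2]], tolerance = 0.1 / 45)
})

test_that("fit is invariant to init permutation and image order; fixed stays fixed", {
  truth <- alpha_truth()
  imgs <- gen_streak_set(truth, seed = 8, n_time = 60,
                         wavelength_grid = seq(650, 760, by = 10))
  fx <- data.frame(index = 4, value = 6000)
  f1 <- fit_global(imgs, 4, init_lifetimes = c(5, 60, 900), fixed = fx,
                   restarts = 1, seed = 1)
  f2 <- fit_global(imgs, 4, init_lifetimes = c(900, 5, 60), fixed = fx,
                   restarts = 1, seed = 1)
  expect_equal(f1$lifetimes, f2$lifetimes, tolerance = 1e-6)
  expect_equal(f1$lifetimes[4], 6000)
  expect_true(f1$fixed[4])

  f3 <- fit_global(rev(imgs), 4, init_lifetimes = c(5, 60, 900), fixed = fx,
                   restarts = 1, seed = 1)
  expect_equal(sort(f3$lifetimes), sort(f1$lifetimes), tolerance = 1e-4)

  expect_error(fit_global(imgs, 0), ">= 1")
  expect_error(fit_global(imgs, 2, init_lifetimes = c(-5, 10)), "positive")
})

test_that("lifetime recovery is nearly unbiased over many noisy replicates", {
  truth <- toy_truth(noise_scale = 0.02)
  recovered <- vapply(1:50, function(s) {
    img <- gen_streak(truth, seq(0, 400, length.out = 90),
                      seq(650, 770, by = 12), seed = 3000 + s)
    fit_global(img, 2, restarts = 1, init_lifetimes = c(5, 100),
               seed = s)$lifetimes
  }, numeric(2))
  bias <- abs(rowMeans(recovered) - c(10.5, 45.5)) / c(10.5, 45.5)
  expect_lt(bias[1], 0.10)
  expect_lt(bias[2], 0.10)
})

test_that("fit residual grows monotonically with the generator noise level", {
  rms <- vapply(c(0.005, 0.02, 0.08), function(ns) {
    img <- gen_streak(toy_truth(noise_scale = ns),
                      seq(0, 400, length.out = 90),
                      seq(650, 770, by = 12), seed = 77)
    fit_global(img, 2, restarts = 1, init_lifetimes = c(5, 100), seed = 1)$rms
  }, numeric(1))
  expect_true(all(diff(rms) > 0))
})

test_that("relative amplitudes are signed DAS areas matching quadrature", {
  wl <- seq(640, 760, by = 0.5)
  centers <- c(687, 690, 681, 676)
  sig <- fwhm_to_sigma(c(28, 24, 22, 22))
  target <- c(0.331, 0.489, 0.11, 0.07)
  das <- t(vapply(1:4, function(i) {
    gauss_band(wl, centers[i], sig[i], target[i] / (sig[i] * sqrt(2 * pi)))
  }, numeric(length(wl))))
  fit <- structure(list(lifetimes = c(10.5, 45.5, 1700, 6000),
                        fixed = c(FALSE, FALSE, FALSE, TRUE),
                        das = das, wavelength = wl),
                   class = "kinetic_fit")
  ra <- relative_amplitudes(fit)
  expect_equal(ra$rel_amplitude, target, tolerance = 5e-3)

  # trapezoid area vs fine-grid quadrature oracle
  fine <- integrate(function(w) gauss_band(w, centers[1], sig[1],
                                           target[1] / (sig[1] * sqrt(2 * pi))),
                    min(wl), max(wl), rel.tol = 1e-12)$value
  expect_equal(ra$amplitude[1], fine, tolerance = 1e-6)

  # identical DAS split the amplitude evenly
  two <- structure(list(lifetimes = c(10, 50), fixed = c(FALSE, FALSE),
                        das = das[c(1, 1), ], wavelength = wl),
                   class = "kinetic_fit")
  expect_equal(relative_amplitudes(two)$rel_amplitude, c(0.5, 0.5))

  zero <- structure(list(lifetimes = 1, fixed = FALSE,
                         das = matrix(0, 1, length(wl)), wavelength = wl),
                    class = "kinetic_fit")
  expect_error(relative_amplitudes(zero), "zero")
})

test_that("average decay time implements the amplitude-weighted mean", {
  one <- tibble::tibble(lifetime = 45.5, amplitude = 3)
  expect_equal(average_decay_time(one), 45.5)

  alpha <- psi_lhc_kinetics("alpha")
  expect_equal(average_decay_time(alpha, included = 1:2),
               (10.5 * 33.1 + 45.5 * 48.9) / (33.1 + 48.9))
  beta <- psi_lhc_kinetics("beta")
  expect_equal(average_decay_time(beta, included = 1:2),
               (13.0 * 35.5 + 45.1 * 52.0) / (35.5 + 52.0))

  # invariant under overall amplitude rescaling
  scaled <- dplyr::mutate(alpha, amplitude = rel_amplitude * 123.4)
  expect_equal(average_decay_time(scaled, 1:2),
               average_decay_time(alpha, 1:2))

  expect_error(average_decay_time(alpha, included = 9), "missing component")
  expect_error(average_decay_time(alpha, included = integer(0)), "at least one")
})

test_that("components are classified by the lifetime threshold", {
  fitlike <- psi_lhc_kinetics("alpha")
  cls <- classify_components(fitlike)
  expect_equal(cls$label, c("connected", "connected", "disconnected",
                            "disconnected"))
  expect_true(all(classify_components(fitlike, 1e7)$label == "connected"))
  expect_true(all(classify_components(fitlike, 0)$label == "disconnected"))
})

test_that("model-order selection is parsimonious on simple data", {
  img <- gen_streak(
    kinetic_ground_truth(lifetimes = 30,
                         das_shapes = default_das_shapes(1, centers = 690,
                                                         fwhms = 24),
                         noise_scale = 0.02),
    seq(0, 300, length.out = 80), seq(660, 740, by = 10), seed = 6
  )
  expect_equal(as.integer(select_n_components(img, n_max = 3, restarts = 1,
                                              seed = 1)), 1L)
  # a degenerate 99% threshold can never be met, so one component wins
  expect_equal(as.integer(select_n_components(img, n_max = 3,
                                              rel_improvement = 0.99,
                                              restarts = 1, seed = 1)), 1L)
})
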