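test_that("exp_conv_gauss reduces to a sharp-onset exponential without an IRF", {
  expect_equal(exp_conv_gauss(5, tau = 10), exp(-0.5))
  expect_equal(exp_conv_gauss(c(-1, 0, 3), tau = 2, mu = 0),
               c(0, 1, exp(-1.5)))
  expect_error(exp_conv_gauss(1, tau = -3), "positive")
  expect_error(exp_conv_gauss(1, tau = 1, sigma = -1), ">= 0")
})

test_that("exp_conv_gauss matches brute-force quadrature over a (tau, sigma) grid", {
  # frozen spot values, confirmed by the quadrature oracle below
  expect_equal(exp_conv_gauss(0, 45.5, 0, 2), 0.4829, tolerance = 1e-4)
  expect_equal(exp_conv_gauss(100, 20, 0, 3), exp(9 / 800) * exp(-5),
               tolerance = 1e-6)
  for (tau in c(1, 12, 150)) {
    for (sigma in c(0.4, 3, 25)) {
      mu <- 7
      t <- seq(mu - 3 * sigma, mu + 20 * tau, length.out = 25)
      got <- exp_conv_gauss(t, tau, mu, sigma)
      want <- conv_quadrature(t, tau, mu, sigma)
      keep <- want > 1e-12 * max(want)  # quadrature itself degrades in the deep tail
      expect_lt(max(abs(got[keep] - want[keep]) / want[keep]), 1e-6)
    }
  }
})

test_that("exp_conv_gauss stays finite when the IRF dwarfs the lifetime", {
  v <- exp_conv_gauss(seq(-50, 50, by = 1), tau = 0.01, mu = 0, sigma = 10)
  expect_true(all(is.finite(v)))
  expect_true(all(v >= 0))
  # area of the convolution equals tau regardless of sigma
  t <- seq(-100, 100, by = 0.01)
  expect_equal(sum(v <- exp_conv_gauss(t, 0.01, 0, 10)) * 0.01, 0.01,
               tolerance = 1e-3)
})

test_that("sequential cascade populations match closed forms and an ODE oracle", {
  t <- seq(0, 200, by = 0.5)
  one <- sequential_profiles(10, t, mu = 0, sigma = 2)
  expect_equal(unname(one[, 1]), exp_conv_gauss(t, 10, 0, 2))

  pops <- sequential_profiles(c(10, 50), t, mu = 0, sigma = 0)
  k1 <- 1 / 10; k2 <- 1 / 50
  closed2 <- k1 / (k1 - k2) * (exp(-k2 * t) - exp(-k1 * t))
  expect_equal(unname(pops[, 2]), closed2, tolerance = 1e-12)
  expect_true(all(pops >= -1e-12))

  ode <- deSolve::ode(
    y = c(c1 = 1, c2 = 0), times = t,
    func = function(tt, y, p) list(c(-k1 * y[1], k1 * y[1] - k2 * y[2]))
  )
  expect_equal(unname(pops[t == 20, 2]), unname(ode[ode[, "time"] == 20, "c2"]),
               tolerance = 1e-6)
})

test_that("each compartment of the cascade has area equal to its lifetime", {
  lifetimes <- c(4, 19, 87)
  t <- seq(0, 20 * max(lifetimes), by = 0.05)
  pops <- sequential_profiles(lifetimes, t, mu = 0, sigma = 0)
  areas <- apply(pops, 2, function(y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2))
  expect_equal(unname(areas), lifetimes, tolerance = 1e-4)
})

test_that("degenerate lifetimes are rejected with advice to perturb", {
  expect_error(sequential_profiles(c(10, 10 * (1 + 1e-12)), 0:10), "Perturb")
  expect_error(bateman_matrix(c(5, -1)), "positive")
})

test_that("DAS/EAS conversion is exact, invertible, and model-equivalent", {
  expect_equal(das_from_eas(c(1, 2, 3), lifetimes = 10),
               rbind(c(1, 2, 3)))

  wl <- seq(650, 750, by = 10)
  e1 <- gauss_band(wl, 685, 8)
  e2 <- gauss_band(wl, 700, 10, 0.7)
  lt <- c(10, 50)
  das <- das_from_eas(rbind(e1, e2), lt)
  k1 <- 1 / 10; k2 <- 1 / 50
  expect_equal(unname(das[1, ]), e1 - k1 / (k1 - k2) * e2, tolerance = 1e-12)
  expect_equal(unname(das[2, ]), k1 / (k1 - k2) * e2, tolerance = 1e-12)

  # round trip on random spectra
  set.seed(7)
  lt3 <- c(3, 40, 900)
  spectra <- matrix(rnorm(3 * 11), 3, 11)
  expect_equal(das_from_eas(eas_from_das(spectra, lt3), lt3), spectra,
               tolerance = 1e-10)
  expect_error(das_from_eas(spectra, c(1, 2)), "must equal")

  # pointwise model equivalence: DAS-weighted exponentials == EAS-weighted
  # cascade populations
  t <- seq(0, 300, by = 1)
  pops <- sequential_profiles(lt, t, mu = 5, sigma = 3)
  basis <- cbind(exp_conv_gauss(t, lt[1], 5, 3), exp_conv_gauss(t, lt[2], 5, 3))
  expect_equal(basis %*% das, pops %*% rbind(e1, e2), tolerance = 1e-10)
})
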