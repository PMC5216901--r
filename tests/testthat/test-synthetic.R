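test_that("noise-free single-component image decays as a pure exponential", {
  truth <- kinetic_ground_truth(
    lifetimes = 25,
    das_shapes = default_das_shapes(1, centers = 687, fwhms = 28),
    noise_scale = 0, irf_center = 0, irf_fwhm = c(TR1 = 0)
  )
  t <- seq(0, 100, by = 1)
  img <- gen_streak(truth, t, 687, seed = 1)
  expect_equal(img$intensity / img$intensity[1], exp(-t / 25), tolerance = 1e-12)
})

test_that("noise-free default image matches the numerical convolution oracle", {
  truth <- alpha_truth(noise_scale = 0)
  wl <- seq(650, 760, by = 10)
  t_eval <- truth$irf_center
  img <- gen_streak(truth, c(0, t_eval, 50), wl, seed = 1, time_range = "TR1")
  sigma <- fwhm_to_sigma(truth$irf_fwhm[["TR1"]])
  at_mu <- img$intensity[img$time == t_eval]
  oracle <- vapply(wl, function(w) {
    sum(vapply(seq_along(truth$lifetimes), function(n) {
      sh <- truth$das_shapes[[n]]
      a <- sum(gauss_band(w, sh$center, sh$width, sh$amplitude))
      a * conv_quadrature(t_eval, truth$lifetimes[n], truth$irf_center, sigma)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(max(abs(at_mu - oracle) / abs(oracle)), 1e-6)
})

test_that("streak generation is seed-deterministic and validates its grids", {
  truth <- alpha_truth()
  t <- seq(0, 155, length.out = 40)
  wl <- seq(650, 750, by = 10)
  a <- gen_streak(truth, t, wl, seed = 11)
  b <- gen_streak(truth, t, wl, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a$intensity, gen_streak(truth, t, wl, seed = 12)$intensity))
  expect_error(gen_streak(truth, numeric(0), wl, seed = 1), "non-empty")
  expect_error(gen_streak(truth, rev(t), wl, seed = 1), "increasing")
  expect_error(gen_streak(truth, t, wl), "seed")
})

test_that("three-time-range set carries per-range IRF widths", {
  imgs <- gen_streak_set(alpha_truth(), seed = 3, n_time = 30,
                         wavelength_grid = seq(650, 750, 25))
  expect_named(imgs, c("TR1", "TR2", "TR4"))
  expect_equal(attr(imgs$TR4, "irf_sigma"), fwhm_to_sigma(20))
  expect_equal(max(imgs$TR1$time), 155)
  expect_equal(max(imgs$TR4$time), 1500)
})

test_that("synthetic absorption spectra peak where their bands dictate", {
  single <- gen_absorption(tibble::tibble(center = 680, fwhm = 8 * 2.3548,
                                          amplitude = 1),
                           wavelength_grid = seq(640, 720, by = 0.5))
  expect_equal(single$wavelength[which.max(single$value)], 680)

  four <- gen_absorption()
  pk <- four$wavelength[which.max(four$value)]
  expect_gte(pk, 669)
  expect_lte(pk, 685)

  expect_error(gen_absorption(tibble::tibble(center = numeric(0),
                                             fwhm = numeric(0),
                                             amplitude = numeric(0))),
               "at least one", ignore.case = TRUE)
  expect_error(gen_absorption(tibble::tibble(center = 680, fwhm = -1,
                                             amplitude = 1)), "positive")
})

test_that("synthetic 77 K emission is dominated by the red-form band", {
  pure <- gen_emission(free_chl_fraction = 0)
  expect_equal(pure$wavelength[which.max(pure$value)], 722)
  mixed <- gen_emission(free_chl_fraction = 0.2)
  expect_equal(mixed$wavelength[which.max(mixed$value)], 722)
  expect_error(gen_emission(free_chl_fraction = 1.5), "\\[0, 1\\]")
})

raw_shares <- function(tbl) {
  dplyr::mutate(dplyr::group_by(tbl, protein),
                share = intensity / sum(intensity)) |>
    dplyr::ungroup()
}

test_that("fraction tables honour archetype profiles in expectation", {
  pure <- gen_fraction_table(
    list(fraction_archetype("only4", c(0, 0, 0, 1), dispersion = 0)),
    n_proteins_per_archetype = 5, seed = 2
  )
  shares <- raw_shares(pure)
  expect_true(all(shares$share[shares$fraction == "PSI-LHC"] == 1))
  expect_true(all(shares$share[shares$fraction != "PSI-LHC"] == 0))

  tbl <- gen_fraction_table(
    list(fraction_archetype("PSI core", c(0.02, 0.03, 0.05, 0.90),
                            dispersion = 0.1)),
    n_proteins_per_archetype = 50, seed = 5
  )
  m <- mean(raw_shares(tbl)$share[tbl$fraction == "PSI-LHC"])
  expect_gte(m, 0.85)
  expect_lte(m, 0.95)

  expect_identical(gen_fraction_table(seed = 9), gen_fraction_table(seed = 9))
  expect_error(gen_fraction_table(list(), seed = 1), "archetype")
  expect_true(all(gen_fraction_table(seed = 1)$intensity >= 0))
})

test_that("archetype profiles are recovered in expectation at large n", {
  arch <- fraction_archetype("PSI antenna", c(0.05, 0.05, 0.10, 0.80),
                             dispersion = 0.1)
  tbl <- gen_fraction_table(list(arch), n_proteins_per_archetype = 200, seed = 21)
  d <- raw_shares(tbl)
  means <- tapply(d$share, d$fraction, mean)
  expect_equal(unname(as.vector(means)), arch$profile, tolerance = 0.02)

  # per-fraction acquisition factors distort raw intensities but cancel
  # exactly in the normalized distribution
  run_factors <- c(0.4, 2.5, 1.1, 0.7)[as.integer(tbl$fraction)]
  tbl_run <- dplyr::mutate(tbl, intensity = intensity * run_factors)
  expect_equal(fraction_distribution(tbl_run)$share,
               fraction_distribution(tbl)$share, tolerance = 1e-12)
})

test_that("pigment area generation inverts quantification exactly", {
  target <- setNames(psi_lhc_pigments("alpha")$mol_per_100chl,
                     psi_lhc_pigments("alpha")$pigment)
  areas <- gen_pigment_areas(target, chl_area = 5e5)
  quant <- quantify_pigments(areas, chl_area = 5e5)
  expect_equal(setNames(quant$mol_per_100chl, quant$pigment), target,
               tolerance = 1e-9)

  zero <- gen_pigment_areas(setNames(c(0, 0), c("violaxanthin", "zeaxanthin")))
  expect_true(all(zero$area == 0))

  expect_error(gen_pigment_areas(c(violaxanthin = 1),
                                 response_factors = c(violaxanthin = -5,
                                                      chlorophyll_a = 1500)),
               "positive")
})
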