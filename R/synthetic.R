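#' Published PSI-LHC kinetic components of Nannochloropsis gaditana
#'
#' The four-component global-fit solution (lifetimes, relative DAS amplitudes,
#' and which lifetime was held fixed) reported for the PSI-LHC supercomplex
#' purified with alpha-DM or beta-DM. These values parameterize the default
#' synthetic ground truth and are the reference inputs for the average time
#' to charge separation.
#'
#' @param sample `"alpha"` or `"beta"` (detergent used in the purification).
#' @return A tibble with columns `component`, `lifetime` (ps),
#'   `rel_amplitude` (unit interval, summing to 1) and `fixed` (logical; the
#'   6 ns free-chlorophyll lifetime is conventionally fixed).
#' @examples
#' psi_lhc_kinetics("alpha")
#' @export
psi_lhc_kinetics <- function(sample = c("alpha", "beta")) {
  sample <- match.arg(sample)
  if (sample == "alpha") {
    tibble::tibble(
      component = 1:4,
      lifetime = c(10.5, 45.5, 1700, 6000),
      rel_amplitude = c(0.331, 0.489, 0.11, 0.07),
      fixed = c(FALSE, FALSE, FALSE, TRUE)
    )
  } else {
    tibble::tibble(
      component = 1:4,
      lifetime = c(13.0, 45.1, 1600, 6000),
      rel_amplitude = c(0.355, 0.520, 0.063, 0.062),
      fixed = c(FALSE, FALSE, FALSE, TRUE)
    )
  }
}

#' Default decay-associated spectral shapes for the synthetic ground truth
#'
#' One Gaussian emission band per kinetic component. The fast, connected
#' components peak in the 685-690 nm bulk-emission region; the slow
#' components are blue-shifted: 681 nm for the disconnected-antenna
#' component and 676 nm for free chlorophyll (distinct species emit with
#' distinct spectra, which is what lets a global fit resolve their similar
#' slow decays). Band amplitudes are scaled so the signed area of each
#' component's spectrum equals its relative amplitude, making the generator
#' consistent with amplitude-weighted averages computed downstream.
#'
#' @param rel_amplitudes Target signed DAS areas (one per component).
#' @param centers,fwhms Band centres and full widths at half maximum (nm),
#'   recycled defaults for four components.
#' @return A list of one-row tibbles (`center`, `width`, `amplitude`), one
#'   per component; `width` is a Gaussian sigma.
#' @export
default_das_shapes <- function(rel_amplitudes,
                               centers = c(687, 690, 681, 676),
                               fwhms = c(28, 24, 22, 22)) {
  n <- length(rel_amplitudes)
  centers <- rep_len(centers, n)
  sig <- fwhm_to_sigma(rep_len(fwhms, n))
  purrr::map(seq_len(n), function(i) {
    tibble::tibble(
      center = centers[i],
      width = sig[i],
      amplitude = rel_amplitudes[i] / (sig[i] * sqrt(2 * pi))
    )
  })
}

#' Ground truth for the streak-image generator
#'
#' Bundles the kinetic components (lifetimes and per-component band-mixture
#' DAS shapes), the Gaussian instrument response per time range, and the
#' noise level. Defaults reproduce the published alpha-DM PSI-LHC solution
#' with the three streak-camera time ranges.
#'
#' @param lifetimes Strictly increasing positive lifetimes (ps).
#' @param das_shapes List (one element per component) of tibbles with columns
#'   `center` (nm), `width` (Gaussian sigma, nm), `amplitude` (signed).
#' @param irf_center IRF centre (ps), common to all time ranges.
#' @param irf_fwhm Named numeric vector of IRF full widths at half maximum
#'   (ps) per time range.
#' @param noise_scale Noise standard deviation at the image peak, as a
#'   fraction of the peak signal.
#' @param fixed Logical per lifetime: treat as held fixed when re-fitting.
#' @return An object of class `kinetic_ground_truth`.
#' @export
kinetic_ground_truth <- function(lifetimes = psi_lhc_kinetics("alpha")$lifetime,
                                 das_shapes = default_das_shapes(
                                   psi_lhc_kinetics("alpha")$rel_amplitude),
                                 irf_center = 15,
                                 irf_fwhm = c(TR1 = 4.5, TR2 = 6.5, TR4 = 20),
                                 noise_scale = 0.02,
                                 fixed = NULL) {
  if (length(lifetimes) < 1L) abort("At least one kinetic component is required.")
  if (any(lifetimes <= 0)) abort("Lifetimes must be strictly positive.")
  if (is.unsorted(lifetimes, strictly = TRUE)) {
    abort("Lifetimes must be strictly increasing.")
  }
  if (length(das_shapes) != length(lifetimes)) {
    abort("`das_shapes` must have one band table per lifetime.")
  }
  for (sh in das_shapes) {
    if (any(sh$width <= 0)) abort("DAS band widths must be positive.")
  }
  if (noise_scale < 0) abort("`noise_scale` must be >= 0.")
  if (is.null(fixed)) fixed <- rep(FALSE, length(lifetimes))
  structure(
    list(lifetimes = lifetimes, das_shapes = das_shapes,
         irf_center = irf_center, irf_fwhm = irf_fwhm,
         noise_scale = noise_scale, fixed = fixed),
    class = "kinetic_ground_truth"
  )
}

eval_bands <- function(bands, wavelength) {
  if (nrow(bands) == 0L) return(numeric(length(wavelength)))
  m <- vapply(seq_len(nrow(bands)), function(i) {
    bands$amplitude[i] * exp(-(wavelength - bands$center[i])^2 /
                               (2 * bands$width[i]^2))
  }, numeric(length(wavelength)))
  rowSums(matrix(m, nrow = length(wavelength)))
}

truth_das_matrix <- function(truth, wavelength) {
  das <- vapply(truth$das_shapes, eval_bands, numeric(length(wavelength)),
                wavelength = wavelength)
  t(matrix(das, nrow = length(wavelength)))
}

new_streak_image <- function(df, irf_center, irf_sigma, time_range) {
  tibble::new_tibble(df, irf_center = irf_center, irf_sigma = irf_sigma,
                     time_range = time_range,
                     class = "streak_image")
}

#' Simulate a streak-camera fluorescence image
#'
#' Noise-free signal at each (time, wavelength) point is the sum over kinetic
#' components of the component's DAS value times its exponential decay
#' convolved with the Gaussian instrument response
#' (see [exp_conv_gauss()]). Noise is Gaussian with variance proportional to
#' the local signal plus a floor, approximating photon statistics after
#' camera gain.
#'
#' @param truth A [kinetic_ground_truth()].
#' @param time_grid Monotone increasing time grid (ps).
#' @param wavelength_grid Monotone increasing wavelength grid (nm).
#' @param seed Integer seed; the same seed reproduces the image exactly.
#' @param time_range Label selecting the IRF width from `truth$irf_fwhm`
#'   (default: first entry).
#' @param noise_floor Variance floor as a fraction of the peak signal.
#' @return A `streak_image` tibble with columns `time`, `wavelength`,
#'   `intensity` and attributes `irf_center`, `irf_sigma`, `time_range`.
#' @export
gen_streak <- function(truth, time_grid, wavelength_grid, seed,
                       time_range = names(truth$irf_fwhm)[1],
                       noise_floor = 0.01) {
  if (length(time_grid) == 0L || length(wavelength_grid) == 0L) {
    abort("Time and wavelength grids must be non-empty.")
  }
  if (is.unsorted(time_grid, strictly = TRUE) ||
      is.unsorted(wavelength_grid, strictly = TRUE)) {
    abort("Grids must be strictly increasing.")
  }
  if (missing(seed)) abort("`seed` is required for reproducibility.")
  if (is.null(time_range)) time_range <- "TR1"
  sigma <- fwhm_to_sigma(unname(
    if (!is.null(names(truth$irf_fwhm)) && time_range %in% names(truth$irf_fwhm))
      truth$irf_fwhm[[time_range]] else truth$irf_fwhm[[1]]
  ))
  das <- truth_das_matrix(truth, wavelength_grid)   # n_comp x n_wl
  decays <- vapply(truth$lifetimes, function(tau) {
    exp_conv_gauss(time_grid, tau, truth$irf_center, sigma)
  }, numeric(length(time_grid)))                    # n_t x n_comp
  decays <- matrix(decays, nrow = length(time_grid))
  signal <- decays %*% das                          # n_t x n_wl
  if (truth$noise_scale > 0) {
    peak <- max(abs(signal))
    withr_seed <- .Random.seed_guard(seed)
    on.exit(withr_seed(), add = TRUE)
    sd_mat <- truth$noise_scale *
      sqrt(pmax(signal, 0) * peak + noise_floor * peak^2)
    signal <- signal + rnorm(length(signal)) * sd_mat
  }
  df <- tidyr::expand_grid(wavelength = wavelength_grid, time = time_grid)
  df <- df[, c("time", "wavelength")]
  df$intensity <- as.vector(signal)  # column-major: time fastest within wavelength
  new_streak_image(df, irf_center = truth$irf_center, irf_sigma = sigma,
                   time_range = time_range)
}

# Save/restore the RNG state around a seeded draw so generators are
# deterministic without clobbering the caller's stream.
.Random.seed_guard <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Simulate the three standard streak-camera time ranges
#'
#' Generates one image per acquisition window: 0-155 ps, 0-400 ps and
#' 0-1500 ps, with the per-range instrument response widths stored in the
#' ground truth, on a shared detection wavelength axis.
#'
#' @inheritParams gen_streak
#' @param wavelength_grid Shared wavelength axis (nm).
#' @param n_time Time samples per image.
#' @return Named list of `streak_image` tibbles.
#' @export
gen_streak_set <- function(truth, seed,
                           wavelength_grid = seq(640, 800, by = 5),
                           n_time = 140) {
  spans <- c(TR1 = 155, TR2 = 400, TR4 = 1500)
  ranges <- names(truth$irf_fwhm)
  if (is.null(ranges)) ranges <- names(spans)[seq_along(truth$irf_fwhm)]
  out <- purrr::imap(setNames(ranges, ranges), function(rg, nm) {
    span <- if (nm %in% names(spans)) spans[[nm]] else max(truth$lifetimes)
    gen_streak(truth, seq(0, span, length.out = n_time), wavelength_grid,
               seed = seed + match(nm, ranges) - 1L, time_range = nm)
  })
  out
}

#' Default 77 K Qy absorption band set of PSI-LHC
#'
#' Four Gaussian sub-bands at the positions resolved in the second derivative
#' of the 77 K absorption spectrum, with decreasing amplitude towards the
#' red forms.
#'
#' @return Tibble with columns `center` (nm), `fwhm` (nm), `amplitude`.
#' @export
psi_lhc_absorption_bands <- function() {
  tibble::tibble(
    center = c(669, 679.5, 685, 697.5),
    fwhm = c(9, 7, 6, 8),
    amplitude = c(1.0, 0.9, 0.6, 0.25)
  )
}

#' Simulate a steady-state absorption spectrum as a sum of Gaussian bands
#'
#' @param bands Tibble/data frame with columns `center` (nm), `fwhm` (nm)
#'   and `amplitude`; at least one band, positive widths.
#' @param wavelength_grid Monotone increasing wavelength axis (nm).
#' @param temperature Temperature tag (K), stored as metadata.
#' @return A [spectrum_record()] of kind `"absorption"`; the true band
#'   centres are kept in the `"true_centers"` attribute.
#' @export
gen_absorption <- function(bands = psi_lhc_absorption_bands(),
                           wavelength_grid = seq(620, 740, by = 0.5),
                           temperature = 77) {
  bands <- tibble::as_tibble(bands)
  if (nrow(bands) < 1L) abort("At least one band is required.")
  if (any(bands$fwhm <= 0)) abort("Band widths must be positive.")
  b <- tibble::tibble(center = bands$center,
                      width = fwhm_to_sigma(bands$fwhm),
                      amplitude = bands$amplitude)
  values <- eval_bands(b, wavelength_grid)
  spec <- spectrum_record(wavelength_grid, values, kind = "absorption",
                          temperature = temperature)
  attr(spec, "true_centers") <- bands$center
  spec
}

#' Simulate a 77 K fluorescence emission spectrum
#'
#' Two-band mixture: the dominant red-form emission band and a variable
#' admixture of free (energetically disconnected) chlorophyll emitting near
#' 678 nm. With `free_chl_fraction = 0` the spectrum is the red-form band
#' alone.
#'
#' @param red_form_center,free_chl_center Band maxima (nm).
#' @param free_chl_fraction Fraction of total emission area contributed by
#'   the free-chlorophyll band, in `[0, 1]`.
#' @param wavelength_grid Wavelength axis (nm).
#' @param red_fwhm,free_fwhm Band widths (nm FWHM).
#' @param temperature Temperature tag (K).
#' @return A [spectrum_record()] of kind `"emission"`.
#' @export
gen_emission <- function(red_form_center = 722, free_chl_center = 678,
                         free_chl_fraction = 0.1,
                         wavelength_grid = seq(640, 820, by = 0.5),
                         red_fwhm = 24, free_fwhm = 14,
                         temperature = 77) {
  if (free_chl_fraction < 0 || free_chl_fraction > 1) {
    abort("`free_chl_fraction` must lie in [0, 1].")
  }
  sr <- fwhm_to_sigma(red_fwhm)
  sf <- fwhm_to_sigma(free_fwhm)
  b <- tibble::tibble(
    center = c(red_form_center, free_chl_center),
    width = c(sr, sf),
    amplitude = c((1 - free_chl_fraction) / (sr * sqrt(2 * pi)),
                  free_chl_fraction / (sf * sqrt(2 * pi)))
  )
  spectrum_record(wavelength_grid, eval_bands(b, wavelength_grid),
                  kind = "emission", temperature = temperature)
}

#' Describe a protein archetype for the gradient-fraction generator
#'
#' @param name Label for the archetype (e.g. `"PSI core"`).
#' @param profile Expected share of total intensity in each gradient
#'   fraction; non-negative, summing to 1.
#' @param dispersion Multiplicative log-normal noise on each share.
#' @param abundance Relative mean total intensity of proteins of this
#'   archetype (bulk antenna proteins are far more abundant than
#'   photosystem-specific subunits).
#' @return An object of class `fraction_archetype`.
#' @export
fraction_archetype <- function(name, profile, dispersion = 0.1,
                               abundance = 1) {
  if (any(profile < 0)) abort("Profile shares must be non-negative.")
  if (abs(sum(profile) - 1) > 1e-9) abort("Profile shares must sum to 1.")
  if (dispersion < 0) abort("`dispersion` must be >= 0.")
  if (abundance <= 0) abort("`abundance` must be positive.")
  structure(list(name = name, profile = profile, dispersion = dispersion,
                 abundance = abundance),
            class = "fraction_archetype")
}

#' Default protein archetypes of a solubilized-thylakoid sucrose gradient
#'
#' PSI-core-like and PSI-antenna-like proteins concentrate in the heavy
#' PSI-LHC band; bulk LHC and PSII-core archetypes populate the lighter
#' bands. Abundances follow thylakoid stoichiometry (bulk antenna proteins
#' dominate the proteome), which also keeps the expected total intensity per
#' fraction roughly balanced — the condition under which sum-based
#' per-fraction normalization is unbiased.
#'
#' @param fractions Ordered fraction labels (light to heavy).
#' @return List of [fraction_archetype()] objects.
#' @export
default_archetypes <- function(fractions = c("LHC monomers", "LHC trimers",
                                             "PSII core", "PSI-LHC")) {
  stopifnot(length(fractions) == 4L)
  list(
    fraction_archetype("PSI core", c(0.02, 0.03, 0.05, 0.90), abundance = 1),
    fraction_archetype("PSI antenna", c(0.05, 0.05, 0.10, 0.80), abundance = 1),
    fraction_archetype("bulk LHC", c(0.45, 0.35, 0.15, 0.05), abundance = 4),
    fraction_archetype("PSII core", c(0.05, 0.10, 0.75, 0.10), abundance = 2)
  )
}

#' Simulate a protein-by-fraction non-normalized intensity table
#'
#' Each protein draws a log-normal total intensity (scaled by its
#' archetype's abundance) and splits it across fractions according to its
#' archetype profile perturbed by mean-one multiplicative log-normal noise,
#' so the expected share of each protein's raw intensity in each fraction
#' equals the configured profile. Optionally, a per-fraction acquisition
#' factor multiplies every intensity of a fraction, emulating the
#' between-run intensity differences that sum-based per-fraction
#' normalization is designed to remove.
#'
#' @param archetypes List of [fraction_archetype()] objects.
#' @param n_proteins_per_archetype Proteins simulated per archetype.
#' @param seed Integer seed.
#' @param fractions Ordered fraction labels; length must match the profiles.
#' @param run_factor_sd Log-scale standard deviation of the per-fraction
#'   acquisition factors; 0 (default) disables them.
#' @return Long tibble with columns `protein`, `archetype`, `fraction`
#'   (ordered factor) and `intensity`.
#' @export
gen_fraction_table <- function(archetypes = default_archetypes(),
                               n_proteins_per_archetype = 50, seed = 1,
                               fractions = c("LHC monomers", "LHC trimers",
                                             "PSII core", "PSI-LHC"),
                               run_factor_sd = 0) {
  if (length(archetypes) < 1L) abort("At least one archetype is required.")
  if (n_proteins_per_archetype < 1L) abort("Need at least one protein per archetype.")
  nf <- length(fractions)
  restore <- .Random.seed_guard(seed)
  on.exit(restore(), add = TRUE)
  run_factor <- if (run_factor_sd > 0) exp(rnorm(nf, sd = run_factor_sd))
                else rep(1, nf)
  rows <- purrr::imap(archetypes, function(arch, ai) {
    if (length(arch$profile) != nf) {
      abort("Archetype profile length must match the number of fractions.")
    }
    purrr::map(seq_len(n_proteins_per_archetype), function(p) {
      total <- rlnorm(1, meanlog = log(1e8 * (arch$abundance %||% 1)),
                      sdlog = 1)
      noise <- if (arch$dispersion > 0) {
        exp(rnorm(nf, sd = arch$dispersion) - arch$dispersion^2 / 2)
      } else rep(1, nf)
      tibble::tibble(
        protein = sprintf("%s_%02d", gsub("\\s+", "", arch$name), p),
        archetype = arch$name,
        fraction = fractions,
        intensity = total * arch$profile * noise * run_factor
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  out$fraction <- factor(out$fraction, levels = fractions)
  out
}

#' Default HPLC response factors for the pigment generator
#'
#' Arbitrary but fixed calibration constants (peak area per mol) for the
#' pigments of the PSI-LHC preparation; the vaucheriaxanthin factor is
#' derived from the violaxanthin one with the standard +10% correction
#' (see [vaucheriaxanthin_rf()]).
#'
#' @return Named numeric vector, including `chlorophyll_a`.
#' @export
default_response_factors <- function() {
  viola <- 1200
  c(violaxanthin = viola,
    vaucheriaxanthin = vaucheriaxanthin_rf(viola),
    anteraxanthin = 1150,
    zeaxanthin = 1100,
    beta_carotene = 900,
    chlorophyll_a = 1500)
}

#' Simulate HPLC peak areas from a target pigment stoichiometry
#'
#' Exact inverse of [quantify_pigments()]: given target contents in mol per
#' 100 chlorophylls and the response factors, computes the peak areas that
#' quantification recovers exactly (a round-trip identity used to validate
#' both directions).
#'
#' @param target_mol_per_100chl Named numeric vector of pigment contents.
#' @param response_factors Named numeric vector of response factors covering
#'   every target pigment; must be positive.
#' @param chl_area Chlorophyll-a peak area (area units).
#' @param chl_rf Chlorophyll-a response factor.
#' @return Tibble with columns `pigment`, `area`, `response_factor`.
#' @export
gen_pigment_areas <- function(target_mol_per_100chl,
                              response_factors = default_response_factors(),
                              chl_area = 1e6,
                              chl_rf = response_factors[["chlorophyll_a"]]) {
  if (any(response_factors <= 0) || chl_rf <= 0) {
    abort("Response factors must be positive.")
  }
  pig <- names(target_mol_per_100chl)
  if (is.null(pig) || !all(pig %in% names(response_factors))) {
    abort("Every target pigment needs a named response factor.")
  }
  rf <- response_factors[pig]
  chl_mol <- chl_area / chl_rf
  tibble::tibble(
    pigment = pig,
    area = unname(rf * (target_mol_per_100chl / 100) * chl_mol),
    response_factor = unname(rf)
  )
}
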