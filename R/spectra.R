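#' Build a spectrum record
#'
#' A tibble of `wavelength` (nm, strictly increasing) and `value` with the
#' spectrum kind and measurement temperature stored as attributes.
#'
#' @param wavelength Strictly increasing wavelength grid (nm).
#' @param value Finite numeric values, same length.
#' @param kind `"absorption"`, `"emission"` or `"cd"`.
#' @param temperature Temperature (K).
#' @return A `spectrum_record` tibble.
#' @export
spectrum_record <- function(wavelength, value,
                            kind = c("absorption", "emission", "cd"),
                            temperature = 293) {
  kind <- match.arg(kind)
  if (length(wavelength) != length(value)) {
    abort("`wavelength` and `value` must have the same length.")
  }
  if (is.unsorted(wavelength, strictly = TRUE)) {
    abort("`wavelength` must be strictly increasing.")
  }
  if (!all(is.finite(value))) abort("Spectrum values must be finite.")
  tibble::new_tibble(
    tibble::tibble(wavelength = wavelength, value = value),
    kind = kind, temperature = temperature, class = "spectrum_record"
  )
}

spectrum_like <- function(template, value) {
  spectrum_record(template$wavelength, value,
                  kind = attr(template, "kind") %||% "absorption",
                  temperature = attr(template, "temperature") %||% 293)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

trapz_integral <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Normalize a spectrum
#'
#' Three conventions used for comparing absorption/emission spectra across
#' preparations:
#' * `"max"` — peak value scaled to 1;
#' * `"qy_max"` — maximum within the chlorophyll Qy region (620-720 nm)
#'   scaled to 1;
#' * `"red_tail"` — the integral from `threshold` nm to the end of the grid
#'   scaled to 1, the convention used to put PSI spectra on a common
#'   red-form (long-wavelength) absorption scale.
#'
#' All modes are idempotent.
#'
#' @param spec A [spectrum_record()] (any data frame with `wavelength` and
#'   `value` columns works).
#' @param mode Normalization convention.
#' @param threshold Red-tail threshold (nm), default 705.
#' @param qy_range Wavelength window defining the Qy region (nm).
#' @return The normalized spectrum.
#' @export
normalize_spectrum <- function(spec, mode = c("max", "qy_max", "red_tail"),
                               threshold = 705, qy_range = c(620, 720)) {
  mode <- match.arg(mode)
  wl <- spec$wavelength
  v <- spec$value
  if (all(v == 0)) abort("Cannot normalize an all-zero spectrum.")
  scale <- switch(mode,
    max = max(v),
    qy_max = {
      sel <- wl >= qy_range[1] & wl <= qy_range[2]
      if (!any(sel)) abort("Spectrum does not cover the Qy region.")
      max(v[sel])
    },
    red_tail = {
      if (threshold >= max(wl)) {
        abort("`threshold` lies beyond the wavelength grid.")
      }
      sel <- wl >= threshold
      if (sum(sel) < 2L) abort("Too few points beyond the red-tail threshold.")
      trapz_integral(wl[sel], v[sel])
    }
  )
  if (scale == 0) abort("Normalization scale is zero for this spectrum.")
  spectrum_like(spec, v / scale)
}

#' Difference between two spectra
#'
#' Linearly interpolates `b` onto `a`'s wavelength grid and returns `a - b`
#' on the overlapping range.
#'
#' @param a,b Spectrum records.
#' @return Spectrum record on `a`'s grid restricted to the overlap.
#' @export
spectrum_difference <- function(a, b) {
  lo <- max(min(a$wavelength), min(b$wavelength))
  hi <- min(max(a$wavelength), max(b$wavelength))
  if (lo > hi) abort("Spectra have no overlapping wavelength range.")
  sel <- a$wavelength >= lo & a$wavelength <= hi
  if (!any(sel)) abort("Spectra have no overlapping wavelength range.")
  wl <- a$wavelength[sel]
  bi <- approx(b$wavelength, b$value, xout = wl)$y
  spectrum_like(a[sel, ], a$value[sel] - bi)
}

#' Detect absorption bands as minima of the smoothed second derivative
#'
#' Computes the Savitzky-Golay second derivative of the spectrum and returns
#' the local minima deeper than `min_depth` times the deepest minimum, with
#' sub-grid positions from a parabola through the three points around each
#' minimum. Negative second-derivative minima mark the positions of
#' overlapping absorption sub-bands that are invisible as distinct maxima in
#' the spectrum itself.
#'
#' @param spec A [spectrum_record()] on a uniform wavelength grid.
#' @param window Odd Savitzky-Golay window length (points), `> polyorder`.
#' @param polyorder Polynomial order of the smoothing filter.
#' @param min_depth Depth cutoff as a fraction of the deepest minimum.
#' @return Tibble with columns `position` (nm, ascending) and `depth`
#'   (positive second-derivative magnitudes).
#' @export
second_derivative_bands <- function(spec, window = 11, polyorder = 3,
                                    min_depth = 0.05) {
  wl <- spec$wavelength
  v <- spec$value
  if (window %% 2 == 0) abort("`window` must be odd.")
  if (window <= polyorder) abort("`window` must exceed `polyorder`.")
  if (length(v) <= window) abort("Spectrum is shorter than the filter window.")
  steps <- diff(wl)
  if (max(steps) - min(steps) > 1e-6 * mean(steps)) {
    abort("Second-derivative band detection requires a uniform wavelength grid.")
  }
  h <- mean(steps)
  d2 <- signal::sgolayfilt(v, p = polyorder, n = window, m = 2, ts = h)
  i <- which(diff(sign(diff(d2))) == 2) + 1L
  i <- i[d2[i] < 0 & i > 1L & i < length(d2)]
  if (length(i) == 0L) {
    return(tibble::tibble(position = numeric(0), depth = numeric(0)))
  }
  depth <- -d2[i]
  keep <- depth >= min_depth * max(depth)
  i <- i[keep]
  depth <- depth[keep]
  offset <- 0.5 * (d2[i - 1L] - d2[i + 1L]) / (d2[i - 1L] - 2 * d2[i] + d2[i + 1L])
  tibble::tibble(position = wl[i] + offset * h, depth = depth) |>
    dplyr::arrange(.data$position)
}

#' Emission maximum with sub-grid interpolation
#'
#' Argmax of the spectrum within a search range, refined by a parabola
#' through the three points around the discrete maximum. If the maximum sits
#' on the boundary of the range (monotone spectrum) the boundary wavelength
#' is returned with a warning.
#'
#' @param spec A [spectrum_record()].
#' @param range Two-element wavelength window (nm); default whole grid.
#' @return Wavelength of the maximum (nm).
#' @export
emission_maximum <- function(spec, range = NULL) {
  wl <- spec$wavelength
  v <- spec$value
  if (!is.null(range)) {
    sel <- wl >= range[1] & wl <= range[2]
    if (!any(sel)) abort("Search range does not overlap the spectrum grid.")
    wl <- wl[sel]
    v <- v[sel]
  }
  i <- which.max(v)
  if (i == 1L || i == length(v)) {
    warn("Maximum lies on the boundary of the search range.")
    return(wl[i])
  }
  denom <- v[i - 1L] - 2 * v[i] + v[i + 1L]
  offset <- if (denom == 0) 0 else 0.5 * (v[i - 1L] - v[i + 1L]) / denom
  wl[i] + offset * (wl[i + 1L] - wl[i])
}

#' @export
autoplot.spectrum_record <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavelength, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Wavelength (nm)",
      y = switch(attr(object, "kind") %||% "absorption",
                 absorption = "Absorbance (a.u.)",
                 emission = "Fluorescence (a.u.)",
                 cd = "CD (a.u.)"),
      title = sprintf("%s spectrum (%s K)",
                      attr(object, "kind") %||% "spectrum",
                      format(attr(object, "temperature") %||% NA))
    ) +
    ggplot2::theme_minimal()
}
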