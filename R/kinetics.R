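#' Exponential decay convolved with a Gaussian instrument response
#'
#' Closed-form convolution of a single-exponential decay `exp(-(t - mu)/tau)`
#' (zero before `t = mu`) with a normalized Gaussian of standard deviation
#' `sigma` centred at `mu`. This is the elementary kernel of streak-camera
#' kinetic models: every fitted component is a sum of these curves.
#'
#' For `sigma > 0` the result is
#' \deqn{\tfrac12 \exp\!\left(\frac{\sigma^2}{2\tau^2} - \frac{t-\mu}{\tau}\right)
#'       \,\mathrm{erfc}\!\left(\frac{\sigma/\tau - (t-\mu)/\sigma}{\sqrt 2}\right)}
#' evaluated through the scaled complementary error function when the erfc
#' argument is positive, so the kernel does not overflow even when
#' `sigma/tau` reaches 1e3 (very short lifetimes under a broad response).
#' At `sigma = 0` the sharp-onset limit `exp(-(t - mu)/tau)` for `t >= mu`
#' is returned.
#'
#' @param t Numeric vector of times (ps).
#' @param tau Lifetime of the decay (ps), `> 0`.
#' @param mu Centre of the Gaussian response (ps).
#' @param sigma Standard deviation of the Gaussian response (ps), `>= 0`.
#'   Note this is a sigma, not a FWHM; see [fwhm_to_sigma()].
#' @return Numeric vector of intensities, same length as `t`.
#' @examples
#' exp_conv_gauss(5, tau = 10)            # no IRF: exp(-0.5)
#' exp_conv_gauss(0, tau = 45.5, sigma = 2)
#' @export
exp_conv_gauss <- function(t, tau, mu = 0, sigma = 0) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    abort("`tau` must be a single positive number.")
  }
  if (sigma < 0) abort("`sigma` must be >= 0.")
  td <- t - mu
  if (sigma == 0) {
    out <- ifelse(td >= 0, exp(-td / tau), 0)
    return(out)
  }
  z <- (sigma / tau - td / sigma) / sqrt(2)
  out <- numeric(length(t))
  pos <- z > 0
  # z > 0: erfc(z) underflows / exp factor overflows; recombine exponents:
  # exp(A) * erfc(z) = erfcx(z) * exp(A - z^2) with A - z^2 = -td^2 / (2 sigma^2)
  if (any(pos)) {
    out[pos] <- 0.5 * erfcx_stable(z[pos]) * exp(-td[pos]^2 / (2 * sigma^2))
  }
  if (any(!pos)) {
    a <- sigma^2 / (2 * tau^2) - td[!pos] / tau
    out[!pos] <- 0.5 * exp(a) * pracma::erfc(z[!pos])
  }
  out
}

# Scaled complementary error function, exp(z^2) * erfc(z), valid for any
# positive argument: erfcx() implementations that form exp(z^2) explicitly
# break down near z ~ 26, where the asymptotic series in 1/z^2 is already
# accurate to machine precision.
erfcx_stable <- function(z) {
  out <- numeric(length(z))
  small <- z <= 20
  if (any(small)) out[small] <- pracma::erfcx(z[small])
  if (any(!small)) {
    zz <- z[!small]
    u <- 1 / (2 * zz^2)
    out[!small] <- (1 - u * (1 - 3 * u * (1 - 5 * u * (1 - 7 * u)))) /
      (zz * sqrt(pi))
  }
  out
}

#' Convert a full width at half maximum to a Gaussian sigma
#'
#' @param fwhm Full width at half maximum (same units as the result).
#' @return `fwhm / (2 sqrt(2 log 2))`.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

check_distinct_lifetimes <- function(lifetimes, tol = 1e-9) {
  lt <- sort(lifetimes)
  if (length(lt) > 1L && any(diff(lt) / lt[-length(lt)] < tol)) {
    abort(paste(
      "Lifetimes are degenerate (two values agree within 1e-9 relative);",
      "the sequential cascade solution is singular. Perturb one of them."
    ))
  }
  invisible(lifetimes)
}

#' Exponential-basis expansion of an unbranched sequential cascade
#'
#' For a sequential scheme `1 -> 2 -> ... -> n` with unit transfer efficiency
#' and rate constants `k_j = 1/tau_j`, the population of compartment `j` is a
#' linear combination of the decaying exponentials `exp(-k_i t)` with the
#' classical cascade (Bateman) coefficients. This returns the `n x n`
#' lower-triangular-in-`j` matrix `B` with `B[i, j]` the weight of
#' `exp(-k_i t)` in compartment `j`. The same matrix maps evolution-associated
#' spectra to decay-associated spectra.
#'
#' @param lifetimes Numeric vector of distinct positive lifetimes (ps), in
#'   cascade order (compartment 1 first).
#' @return An `n x n` numeric matrix.
#' @export
bateman_matrix <- function(lifetimes) {
  if (any(lifetimes <= 0)) abort("Lifetimes must be positive.")
  check_distinct_lifetimes(lifetimes)
  k <- 1 / lifetimes
  n <- length(k)
  b <- matrix(0, n, n)
  for (j in seq_len(n)) {
    pref <- if (j > 1L) prod(k[seq_len(j - 1L)]) else 1
    for (i in seq_len(j)) {
      denom <- prod(k[setdiff(seq_len(j), i)] - k[i])
      b[i, j] <- pref / ifelse(j == 1L, 1, denom)
    }
  }
  b
}

#' Compartment populations of a sequential kinetic scheme under a Gaussian IRF
#'
#' Populations of the unbranched cascade `1 -> 2 -> ... -> n` excited through
#' a Gaussian instrument response. Compartment 1 is [exp_conv_gauss()] itself;
#' later compartments are the cascade expansion with every exponential
#' convolved with the same response.
#'
#' @param lifetimes Distinct positive lifetimes (ps), cascade order.
#' @param t Time grid (ps).
#' @param mu,sigma Gaussian IRF centre and standard deviation (ps).
#' @return Matrix `length(t) x n`; column `j` is the population of
#'   compartment `j`.
#' @export
sequential_profiles <- function(lifetimes, t, mu = 0, sigma = 0) {
  b <- bateman_matrix(lifetimes)
  basis <- vapply(lifetimes, function(tau) exp_conv_gauss(t, tau, mu, sigma),
                  numeric(length(t)))
  basis <- matrix(basis, nrow = length(t))
  pops <- basis %*% b
  colnames(pops) <- paste0("compartment_", seq_along(lifetimes))
  pops
}

#' Convert evolution-associated to decay-associated spectra (and back)
#'
#' In a sequential scheme the measured signal can be written either as
#' compartment populations weighted by evolution-associated spectra (EAS) or
#' as pure exponentials weighted by decay-associated spectra (DAS). Expanding
#' the cascade populations on the exponential basis gives the exact linear
#' map between the two representations: `DAS = B %*% EAS` with `B` from
#' [bateman_matrix()] (rates in rate units cancel into the dimensionless
#' coefficients).
#'
#' @param eas,das Numeric matrix with one row per component/compartment and
#'   one column per wavelength (a plain vector is treated as one wavelength).
#' @param lifetimes Lifetimes (ps) in cascade order, one per row of the
#'   spectra matrix.
#' @return Matrix of the same shape in the other representation.
#' @export
das_from_eas <- function(eas, lifetimes) {
  eas <- rbind(eas)
  if (nrow(eas) != length(lifetimes)) {
    abort("Number of spectra must equal the number of lifetimes.")
  }
  bateman_matrix(lifetimes) %*% eas
}

#' @rdname das_from_eas
#' @export
eas_from_das <- function(das, lifetimes) {
  das <- rbind(das)
  if (nrow(das) != length(lifetimes)) {
    abort("Number of spectra must equal the number of lifetimes.")
  }
  solve(bateman_matrix(lifetimes), das)
}
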