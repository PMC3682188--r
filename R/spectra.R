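## CW-EPR lineshape forward model shared by the synthetic generator and the
## spin-dilution distance estimator.
##
## The basis lineshape is a sum of three first-derivative Lorentzian lines
## (the nitroxide 14N hyperfine triplet).  Intermolecular dipolar coupling at
## interspin distance r is modeled as convolution with a Gaussian broadening
## function in field whose standard deviation scales as r^-3:
##     sigma_B(r) = C / r^3,   C = 6.6e3 G Angstrom^3
## C is fixed so that sigma_B(13 A) ~ 3 G, comparable to the intrinsic
## linewidth, matching the magnitude of broadening seen for tightly coupled
## nitroxide pairs.  A distribution of distances (Gaussian, center r, width w)
## maps to a mixture of Gaussian kernels.

DIPOLAR_C <- 6.6e3 # G * Angstrom^3
EPR_R_MIN <- 5 # Angstrom, CW dipolar sensitivity range
EPR_R_MAX <- 25

dipolar_sigma <- function(r) DIPOLAR_C / r^3

## First derivative of a Lorentzian absorption centered at x0 with HWHM g
dlorentz <- function(x, x0, g) {
  u <- x - x0
  -2 * g^2 * u / (u^2 + g^2)^2
}

## Three-line nitroxide derivative lineshape on a field axis (Gauss)
nitroxide_lineshape <- function(field, center = mean(field), hyperfine = 15,
                                linewidth = 2.2, weights = c(1, 1, 0.85)) {
  y <- weights[1] * dlorentz(field, center - hyperfine, linewidth) +
    weights[2] * dlorentz(field, center, linewidth) +
    weights[3] * dlorentz(field, center + hyperfine, linewidth * 1.15)
  y
}

check_uniform_grid <- function(field) {
  d <- diff(field)
  if (length(d) < 2L || any(abs(d - d[1]) > 1e-8 * abs(d[1]))) {
    abort("Field axis must be a uniform grid.")
  }
  d[1]
}

## Cumulative trapezoid integral
cumtrapz1 <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

## Double integral of a derivative spectrum (= total spin count up to a
## constant); a linear baseline is removed from the derivative first.
double_integral <- function(field, deriv) {
  fit <- lm(deriv ~ field)
  d0 <- deriv - fitted(fit)
  absb <- cumtrapz1(field, d0)
  absb <- absb - min(absb)
  unname(tail(cumtrapz1(field, absb), 1))
}

## Normalize a derivative spectrum to unit double integral
normalize_spins <- function(field, deriv) {
  di <- double_integral(field, deriv)
  if (!is.finite(di) || di <= 0) abort("Spectrum has non-positive double integral.")
  deriv / di
}

## Same-length convolution with a normalized kernel on a uniform grid
conv_same <- function(y, kernel) {
  n <- length(y)
  m <- length(kernel)
  full <- stats::convolve(y, rev(kernel), type = "open")
  half <- (m - 1L) %/% 2L
  full[(half + 1L):(half + n)]
}

## Gaussian broadening kernel for a distance distribution N(r, w), sampled on
## the spectrum's field grid.  Kernel sums to 1 (integral-preserving).
dipolar_kernel <- function(dfield, r, width, n_sigma = 5) {
  ## distance distribution truncated at the CW sensitivity floor: shorter
  ## distances produce broadening too wide to retain in-window intensity
  rg <- seq(max(EPR_R_MIN, r - 3 * width), min(30, r + 3 * width), length.out = 15)
  wts <- dnorm(rg, r, max(width, 1e-3))
  wts <- wts / sum(wts)
  sig_max <- max(dipolar_sigma(rg))
  half <- max(3L, ceiling(n_sigma * sig_max / dfield))
  x <- seq(-half, half) * dfield
  k <- numeric(length(x))
  for (j in seq_along(rg)) {
    s <- dipolar_sigma(rg[j])
    k <- k + wts[j] * dnorm(x, 0, s)
  }
  k / sum(k)
}

## Apply dipolar broadening for distance r (Gaussian distribution width w)
broaden_spectrum <- function(field, deriv, r, width) {
  dfield <- check_uniform_grid(field)
  conv_same(deriv, dipolar_kernel(dfield, r, width))
}

#' Write or read a spectrum as two-column whitespace-delimited text
#'
#' The on-disk format is one header line followed by `field amplitude`
#' pairs, one per line (field in Gauss, first-derivative amplitude in
#' arbitrary units).
#'
#' @param spectrum A data frame with columns `field` and `amplitude`.
#' @param path File path.
#' @return `read_spectrum()` returns a tibble with columns `field`,
#'   `amplitude`; `write_spectrum()` returns `path` invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(all(c("field", "amplitude") %in% names(spectrum)))
  lines <- c("field_G amplitude",
             sprintf("%.6f %.10g", spectrum$field, spectrum$amplitude))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  dat <- utils::read.table(path, header = FALSE, skip = 1,
                           col.names = c("field", "amplitude"))
  as_tibble(dat)
}
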