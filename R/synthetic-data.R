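## Seeded synthetic-data generators.  These produce every input the analysis
## modules need -- elastic-network reference trajectories, CW-EPR spectrum
## pairs, sinusoidal accessibility profiles and depth-calibration point sets
## -- with the statistical structure the downstream estimators assume.

#' Specify an elastic-network model for reference-trajectory generation
#'
#' An `enm_spec` describes a bead chain (or general bead network) with
#' harmonic springs: its equilibrium coordinates, spring list and
#' temperature.  It is the stand-in for an atomistic reference trajectory:
#' [gen_enm_trajectory()] draws frames from the exact Gaussian ensemble of
#' this network so that coarse-graining operations can be validated against
#' analytic covariances.
#'
#' @param coords Numeric matrix, `n_beads` x 3, equilibrium positions (nm).
#' @param springs Data frame with columns `i`, `j`, `k`: 1-based bead indices
#'   and stiffness in kcal/(mol nm^2). All `k` must be positive.
#' @param temperature Temperature in K.
#' @return An object of class `enm_spec`.
#' @examples
#' sp <- enm_spec(cbind(0:2, 0, 0), data.frame(i = 1:2, j = 2:3, k = 1))
#' @export
enm_spec <- function(coords, springs, temperature = 300) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) abort("`coords` must be an n x 3 matrix.")
  springs <- as.data.frame(springs)
  stopifnot(all(c("i", "j", "k") %in% names(springs)))
  if (any(springs$k <= 0)) abort("All spring stiffnesses must be positive.")
  n <- nrow(coords)
  if (any(springs$i < 1 | springs$i > n | springs$j < 1 | springs$j > n)) {
    abort("Spring indices out of range.")
  }
  structure(list(n_beads = n, coords = coords,
                 springs = as_tibble(springs), temperature = temperature),
            class = "enm_spec")
}

## Connected components of the spring graph (BFS)
spring_components <- function(n, springs) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(springs))) {
    i <- springs$i[r]; j <- springs$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cur <- cur + 1L
      queue <- s
      comp[s] <- cur
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  split(seq_len(n), comp)
}

## Mass-unweighted ENM Hessian (3n x 3n) from coordinates and springs
enm_hessian <- function(coords, springs) {
  n <- nrow(coords)
  H <- matrix(0, 3 * n, 3 * n)
  for (r in seq_len(nrow(springs))) {
    i <- springs$i[r]; j <- springs$j[r]; k <- springs$k[r]
    d <- coords[j, ] - coords[i, ]
    L <- vnorm(d)
    if (L < 1e-12) abort("Coincident beads joined by a spring.")
    e <- d / L
    Kb <- k * tcrossprod(e)
    ii <- (3 * (i - 1) + 1):(3 * i)
    jj <- (3 * (j - 1) + 1):(3 * j)
    H[ii, ii] <- H[ii, ii] + Kb
    H[jj, jj] <- H[jj, jj] + Kb
    H[ii, jj] <- H[ii, jj] - Kb
    H[jj, ii] <- H[jj, ii] - Kb
  }
  H
}

## Eigendecomposition with rigid-body modes dropped.  Returns the internal
## modes (eigenvalues lam > tol, vectors V) of the Hessian.
enm_modes <- function(H, n_rigid = 6L) {
  eig <- eigen(H, symmetric = TRUE)
  lam <- rev(eig$values)
  V <- eig$vectors[, rev(seq_along(lam)), drop = FALSE]
  tol <- max(lam) * 1e-9
  nzero <- sum(lam < tol)
  keep <- (nzero + 1L):length(lam)
  list(values = lam[keep], vectors = V[, keep, drop = FALSE], n_zero = nzero)
}

## Covariance of positions: kB T * pseudoinverse(H), rigid modes removed
enm_covariance <- function(spec) {
  H <- enm_hessian(spec$coords, spec$springs)
  md <- enm_modes(H)
  kT <- kB * spec$temperature
  md$vectors %*% (t(md$vectors) * (kT / md$values))
}

#' Draw reference frames from an elastic-network Gaussian ensemble
#'
#' Frames are i.i.d. draws from the multivariate Gaussian with covariance
#' `kB T H^+` (pseudoinverse of the mass-unweighted Hessian), with the six
#' rigid-body modes projected out, added to the equilibrium coordinates.
#'
#' @param spec An [enm_spec()].
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments plus this seed.
#' @return A 3-d array of class `bead_trajectory`, dimensions
#'   `(frame, bead, xyz)`.
#' @export
gen_enm_trajectory <- function(spec, n_frames, seed) {
  stopifnot(inherits(spec, "enm_spec"))
  if (!is.numeric(n_frames) || n_frames < 1) abort("`n_frames` must be >= 1.")
  comps <- spring_components(spec$n_beads, spec$springs)
  if (length(comps) > 1L) {
    abort(paste0("Spring graph is disconnected; components: ",
                 paste(vapply(comps, function(x) paste0("{", paste(x, collapse = ","), "}"), ""),
                       collapse = " ")))
  }
  H <- enm_hessian(spec$coords, spec$springs)
  md <- enm_modes(H)
  ## all zero modes (6 rigid-body ones, plus any floppy internal modes of
  ## degenerate geometries such as straight chains) are projected out of
  ## the thermal ensemble
  kT <- kB * spec$temperature
  amp <- sqrt(kT / md$values)
  n <- spec$n_beads
  x0 <- as.numeric(t(spec$coords)) # length 3n, bead-major (x1 y1 z1 x2 ...)
  ## Our Hessian blocks are laid out bead-major already
  frames <- with_seed(seed, {
    z <- matrix(rnorm(n_frames * length(amp)), n_frames, length(amp))
    dx <- z %*% (t(md$vectors) * amp) # n_frames x 3n
    sweep(dx, 2, x0, "+")
  })
  out <- array(0, dim = c(n_frames, n, 3))
  for (ax in 1:3) out[, , ax] <- frames[, seq(ax, 3 * n, by = 3), drop = FALSE]
  structure(out, class = c("bead_trajectory", "array"))
}

#' Generate a matched pair of CW-EPR spectra with and without dipolar
#' broadening
#'
#' The spin-diluted spectrum is a three-line nitroxide derivative lineshape;
#' the fully labeled spectrum mixes an unbroadened component with one
#' convolved by a Gaussian dipolar broadening function whose field width
#' scales as `distance^-3`.  Both spectra are normalized to the same number
#' of spins by double integration.
#'
#' @param distance True interspin distance, Angstrom, in `[5, 25]`.
#' @param width Width (sd) of the Gaussian distance distribution, Angstrom.
#' @param fraction Interacting fraction in `[0, 1]`.
#' @param seed Integer seed (used for the optional additive noise).
#' @param n_points,scan_width,center Field grid: number of points, full scan
#'   width (Gauss; default 150) and center field (Gauss).
#' @param hyperfine,linewidth Intrinsic lineshape constants (Gauss).
#' @param noise_sd Additive Gaussian noise sd, relative to the peak-to-peak
#'   amplitude of the diluted spectrum (default 0).
#' @return A `spectrum_pair`: list with `spectra` (tibble: `field`,
#'   `full_labeled`, `spin_diluted`), plus the true parameters.
#' @export
gen_pair_spectrum <- function(distance, width, fraction, seed,
                              n_points = 1024, scan_width = 150, center = 3350,
                              hyperfine = 15, linewidth = 2.2, noise_sd = 0) {
  stopifnot_scalar(distance, "distance")
  if (distance < EPR_R_MIN || distance > EPR_R_MAX) {
    abort(sprintf("`distance` must lie in the CW dipolar sensitivity range [%g, %g] Angstrom.",
                  EPR_R_MIN, EPR_R_MAX))
  }
  if (fraction < 0 || fraction > 1) abort("`fraction` must be in [0, 1].")
  field <- seq(center - scan_width / 2, center + scan_width / 2, length.out = n_points)
  diluted <- nitroxide_lineshape(field, center, hyperfine, linewidth)
  broad <- broaden_spectrum(field, diluted, distance, width)
  full <- (1 - fraction) * diluted + fraction * broad
  if (noise_sd > 0) {
    app <- diff(range(diluted)) * noise_sd
    noise <- with_seed(seed, list(rnorm(n_points, 0, app), rnorm(n_points, 0, app)))
    full <- full + noise[[1]]
    diluted <- diluted + noise[[2]]
  }
  ## normalize to the same number of spins by double integration
  diluted <- normalize_spins(field, diluted)
  full <- normalize_spins(field, full)
  structure(list(
    spectra = tibble(field = field, full_labeled = full, spin_diluted = diluted),
    true_distance = distance, true_width = width,
    interacting_fraction = fraction
  ), class = "spectrum_pair")
}

#' Generate a sinusoidal per-residue accessibility profile
#'
#' Emulates the depth-parameter profile of an ideal amphipathic helix:
#' `Phi_i = amplitude * cos(2 pi i / period + phase) + offset + noise`.
#'
#' @param n_residues Number of residues (>= 5).
#' @param period Helical period in residues (> 2; ideal helix 3.6).
#' @param phase Phase in radians.
#' @param amplitude,offset Cosine amplitude and constant offset.
#' @param noise_sd Additive Gaussian noise sd.
#' @param seed Integer seed.
#' @return Tibble with columns `residue`, `phi`.
#' @export
gen_accessibility_profile <- function(n_residues, period = 3.6, phase = 0,
                                      amplitude = 1, noise_sd = 0, seed = 1,
                                      offset = 0) {
  if (n_residues < 5) abort("`n_residues` must be >= 5.")
  if (period <= 2) abort("`period` must exceed 2 residues (sub-Nyquist otherwise).")
  i <- seq_len(n_residues)
  phi <- amplitude * cos(2 * pi * i / period + phase) + offset
  if (noise_sd > 0) phi <- phi + with_seed(seed, rnorm(n_residues, 0, noise_sd))
  tibble(residue = i, phi = phi)
}

#' Generate depth-calibration points from the linear depth relation
#'
#' Depths are generated as `d = a * Phi + b` plus Gaussian noise, emulating
#' calibration measurements with spin labels at known acyl-chain depths.
#'
#' @param a Slope, Angstrom per Phi unit.
#' @param b Intercept, Angstrom.
#' @param phis Numeric vector of Phi values (>= 2 distinct values).
#' @param noise_sd Gaussian noise sd on depth, Angstrom.
#' @param seed Integer seed.
#' @return A `calibration_set` tibble with columns `phi`, `depth` and
#'   attributes `true_a`, `true_b`, `noise_sd`.
#' @export
gen_calibration_points <- function(a = 3.5, b = 0.37, phis, noise_sd = 0, seed = 1) {
  if (length(phis) < 2 || length(unique(phis)) < 2) {
    abort("Need at least two distinct Phi values (slope unidentifiable otherwise).")
  }
  depth <- a * phis + b
  if (noise_sd > 0) depth <- depth + with_seed(seed, rnorm(length(phis), 0, noise_sd))
  out <- tibble(phi = phis, depth = depth)
  attr(out, "true_a") <- a
  attr(out, "true_b") <- b
  attr(out, "noise_sd") <- noise_sd
  class(out) <- c("calibration_set", class(out))
  out
}
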