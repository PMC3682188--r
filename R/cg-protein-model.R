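## The 16-site CG ENTH domain model: variational site placement (essential
## dynamics coarse-graining), fluctuation-matched internal springs
## (heteroENM), role annotation of membrane-interacting sites, and the
## Boltzmann-inversion PMF utility.

## ---- essential dynamics coarse-graining -----------------------------------

## Per-bead-pair essential covariance traces M[i,j] = <d_i . d_j> restricted
## to the top PCA modes of the aligned displacement trajectory.
essential_covariance_traces <- function(frames, n_modes = NULL, var_capture = 0.9) {
  stopifnot(length(dim(frames)) == 3L)
  nf <- dim(frames)[1]; n <- dim(frames)[2]
  if (nf < 3) abort("Too few frames for a covariance estimate.")
  X <- matrix(0, nf, 3 * n) # bead-major columns
  for (ax in 1:3) X[, seq(ax, 3 * n, by = 3)] <- frames[, , ax]
  X <- sweep(X, 2, colMeans(X))
  C <- crossprod(X) / (nf - 1)
  eig <- eigen(C, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  if (sum(lam) <= 0) abort("Degenerate covariance: trajectory has no fluctuations.")
  if (is.null(n_modes)) {
    cum <- cumsum(lam) / sum(lam)
    n_modes <- which(cum >= var_capture)[1]
  }
  n_modes <- min(n_modes, length(lam))
  V <- eig$vectors[, seq_len(n_modes), drop = FALSE]
  Cess <- V %*% (t(V) * lam[seq_len(n_modes)])
  M <- matrix(0, n, n)
  for (ax in 1:3) {
    idx <- seq(ax, 3 * n, by = 3)
    M <- M + Cess[idx, idx]
  }
  M
}

#' Essential-dynamics coarse-graining: optimal contiguous site partition
#'
#' Finds the partition of the residue chain into `n_sites` contiguous
#' segments that minimizes the essential-subspace fluctuation residual: the
#' sum over segments of the intra-segment variance of essential-mode
#' displacements about the segment mean (what is lost by mapping each
#' segment to its center of geometry).  The optimizer is exact dynamic
#' programming over segment boundaries; ties are broken toward the earlier
#' boundary.
#'
#' @param frames A `(frame, bead, xyz)` array of aligned coordinates (rigid
#'   body motion removed), e.g. from [gen_enm_trajectory()].
#' @param n_sites Number of CG sites (segments); must be <= number of beads.
#' @param n_modes Number of essential PCA modes; default: smallest set
#'   capturing 90% of the total fluctuation variance.
#' @return A `site_partition`: tibble of segments (`site`, `from`, `to`)
#'   plus attributes `boundaries` (1-based inclusive segment starts) and
#'   `residual`.
#' @export
edcg_partition <- function(frames, n_sites, n_modes = NULL) {
  n <- dim(frames)[2]
  if (n_sites > n) abort("`n_sites` exceeds the number of residues.")
  if (n_sites < 1) abort("`n_sites` must be >= 1.")
  M <- essential_covariance_traces(frames, n_modes)
  ## prefix sums for O(1) segment cost: cost(a,b) = sum diag - rowsum/len
  dpre <- c(0, cumsum(diag(M)))
  S <- apply(apply(M, 2, cumsum), 1, cumsum) # S[i,j] = sum M[1:j, 1:i] (transposed)
  block_sum <- function(a, b) {
    tot <- S[b, b]
    if (a > 1) tot <- tot - S[a - 1, b] - S[b, a - 1] + S[a - 1, a - 1]
    tot
  }
  seg_cost <- function(a, b) {
    len <- b - a + 1
    (dpre[b + 1] - dpre[a]) - block_sum(a, b) / len
  }
  ## DP over boundaries
  INF <- Inf
  dp <- matrix(INF, n_sites + 1, n + 1) # dp[s+1, b+1]: first b residues in s segments
  dp[1, 1] <- 0
  choice <- matrix(NA_integer_, n_sites + 1, n + 1)
  for (s in seq_len(n_sites)) {
    for (b in s:n) {
      best <- INF; barg <- NA_integer_
      for (a in s:b) { # segment is a..b
        v <- dp[s, a] + seg_cost(a, b)
        if (v < best - 1e-15) { best <- v; barg <- a }
      }
      dp[s + 1, b + 1] <- best
      choice[s + 1, b + 1] <- barg
    }
  }
  bounds <- integer(n_sites)
  b <- n
  for (s in n_sites:1) {
    a <- choice[s + 1, b + 1]
    bounds[s] <- a
    b <- a - 1
  }
  starts <- bounds
  ends <- c(bounds[-1] - 1L, n)
  seg <- tibble(site = seq_len(n_sites), from = starts, to = ends)
  structure(seg, boundaries = starts, residual = max(dp[n_sites + 1, n + 1], 0),
            n_beads = n, class = c("site_partition", class(seg)))
}

#' @export
glance.site_partition <- function(x, ...) {
  tibble(n_sites = nrow(x), residual = attr(x, "residual"),
         n_beads = attr(x, "n_beads"))
}

#' Map a residue-level trajectory onto CG sites
#'
#' Each segment maps to its center of geometry (uniform weights).
#'
#' @param frames `(frame, bead, xyz)` array.
#' @param partition A [edcg_partition()] result (or tibble with `from`, `to`).
#' @return `(frame, site, xyz)` array of class `bead_trajectory`.
#' @export
map_to_sites <- function(frames, partition) {
  n <- dim(frames)[2]
  if (max(partition$to) != n || min(partition$from) != 1) {
    abort("Partition does not cover all residues.")
  }
  ns <- nrow(partition)
  out <- array(0, dim = c(dim(frames)[1], ns, 3))
  for (s in seq_len(ns)) {
    idx <- partition$from[s]:partition$to[s]
    if (length(idx) == 1L) {
      out[, s, ] <- frames[, idx, ]
    } else {
      out[, s, ] <- apply(frames[, idx, , drop = FALSE], c(1, 3), mean)
    }
  }
  structure(out, class = c("bead_trajectory", "array"))
}

## ---- heteroENM fluctuation matching ---------------------------------------

## Pair-distance fluctuations of an ENM at coords with given springs:
## Var(d_ij) ~ b_ij' (C_ii + C_jj - 2 C_ij) b_ij  (projection on mean bond)
enm_pair_variances <- function(coords, springs, temperature) {
  spec <- list(n_beads = nrow(coords), coords = coords,
               springs = springs, temperature = temperature)
  class(spec) <- "enm_spec"
  C <- enm_covariance(spec)
  vapply(seq_len(nrow(springs)), function(r) {
    i <- springs$i[r]; j <- springs$j[r]
    b <- normalize(coords[j, ] - coords[i, ])
    ii <- (3 * (i - 1) + 1):(3 * i); jj <- (3 * (j - 1) + 1):(3 * j)
    Cb <- C[ii, ii] + C[jj, jj] - C[ii, jj] - C[jj, ii]
    max(as.numeric(t(b) %*% Cb %*% b), 1e-14)
  }, 0)
}

## Observed pair-distance variances from a site trajectory
observed_pair_variances <- function(site_frames, pairs) {
  vapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs$i[r]; j <- pairs$j[r]
    d <- sqrt(rowSums((site_frames[, j, ] - site_frames[, i, ])^2))
    var(d)
  }, 0)
}

#' Fit heterogeneous ENM spring constants by fluctuation matching
#'
#' Places a spring on every site pair within `cutoff` at the mean structure
#' and iteratively updates each stiffness with the damped multiplicative
#' rule `k_ij <- k_ij * (var_model / var_target)^gamma` until the model's
#' pair-distance fluctuations (from the ENM Hessian pseudoinverse) match the
#' targets within `tolerance`, or `max_iter` is reached.  Stiffnesses are
#' clamped at a small positive floor.
#'
#' @param site_frames Either a `(frame, site, xyz)` trajectory (targets are
#'   its pair-distance variances) or a list with `coords` (mean structure,
#'   n x 3) and `targets` (tibble `i`, `j`, `var`).
#' @param cutoff Spring cutoff at the mean structure, nm.
#' @param tolerance Relative fluctuation-mismatch tolerance (`Inf` returns
#'   the initial guess unchanged).
#' @param max_iter Maximum iterations.
#' @param temperature Temperature (K) used in the model covariance.
#' @param k0 Initial stiffness guess, kcal/(mol nm^2).
#' @param gamma Damping exponent of the update rule.
#' @param k_floor Stiffness floor.
#' @return A `spring_network`: tibble `i`, `j`, `k`, `r0` with attributes
#'   `converged`, `iterations`, `max_mismatch`, `mismatch_trace`, `cutoff`.
#' @export
heteroenm_fit <- function(site_frames, cutoff = 2.0, tolerance = 0.01,
                          max_iter = 200, temperature = 300, k0 = 10,
                          gamma = 0.5, k_floor = 1e-3) {
  if (is.list(site_frames) && !is.null(site_frames$coords)) {
    coords <- as.matrix(site_frames$coords)
    targets <- as_tibble(site_frames$targets)
    stopifnot(all(c("i", "j", "var") %in% names(targets)))
    pairs <- targets[c("i", "j")]
    tvar <- targets$var
  } else {
    frames <- site_frames
    coords <- apply(frames, c(2, 3), mean)
    n <- nrow(coords)
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    d0 <- sqrt(rowSums((coords[pr[, 2], , drop = FALSE] - coords[pr[, 1], , drop = FALSE])^2))
    keep <- d0 <= cutoff
    pairs <- tibble(i = pr[keep, 1], j = pr[keep, 2])
    tvar <- observed_pair_variances(frames, pairs)
  }
  if (any(tvar <= 0)) abort("Target pair-distance variances must be positive.")
  r0 <- sqrt(rowSums((coords[pairs$j, , drop = FALSE] - coords[pairs$i, , drop = FALSE])^2))
  k <- rep(k0, nrow(pairs))
  springs <- tibble(i = pairs$i, j = pairs$j, k = k, r0 = r0)
  trace <- numeric(0)
  converged <- FALSE
  iters <- 0L
  if (is.finite(tolerance)) {
    for (it in seq_len(max_iter)) {
      mvar <- enm_pair_variances(coords, springs, temperature)
      mism <- abs(mvar / tvar - 1)
      trace <- c(trace, max(mism))
      if (max(mism) < tolerance) { converged <- TRUE; iters <- it - 1L; break }
      springs$k <- pmax(springs$k * (mvar / tvar)^gamma, k_floor)
      iters <- it
    }
    if (!converged) {
      mvar <- enm_pair_variances(coords, springs, temperature)
      trace <- c(trace, max(abs(mvar / tvar - 1)))
    }
  } else {
    converged <- TRUE
  }
  structure(springs, cutoff = cutoff, converged = converged,
            iterations = iters, max_mismatch = if (length(trace)) tail(trace, 1) else NA_real_,
            mismatch_trace = trace,
            class = c("spring_network", class(springs)))
}

#' @export
glance.spring_network <- function(x, ...) {
  tibble(n_springs = nrow(x), converged = attr(x, "converged"),
         iterations = attr(x, "iterations"),
         max_mismatch = attr(x, "max_mismatch"))
}

## ---- the 16-site ENTH topology --------------------------------------------

#' Reference coordinates of the idealized 16-site ENTH model
#'
#' A packaged synthetic stand-in for EDCG-mapped crystal-structure
#' coordinates: an idealized ENTH-shaped bead arrangement in the monomer
#' local frame (membrane plane `z = 0`, outward normal `+z`, H0 axis along
#' `+x`).  Sites 1 and 2 are the two H0 helix sites on the membrane plane,
#' site 5 the V50/V51 hydrophobic patch, site 10 the R114 loop and site 7
#' (default) the PIP2 pocket; the remaining sites form the globular body.
#'
#' @return A 16 x 3 matrix of coordinates (nm).
#' @export
enth16_reference_coords <- function() {
  ## compact globular body leaning away from the dimer interface (-y),
  ## so that the EPR-restrained dimer and offset tetramer pack without
  ## excluded-volume clashes
  body_ring1 <- t(sapply(seq(0, 2 * pi, length.out = 8)[-8] + 0.3, function(a) {
    c(0.55 * cos(a), -0.35 + 0.55 * sin(a), 0.70)
  }))
  body_ring2 <- t(sapply(seq(0, 2 * pi, length.out = 5)[-5] + 1.0, function(a) {
    c(0.30 * cos(a), -0.35 + 0.30 * sin(a), 1.25)
  }))
  coords <- matrix(0, 16, 3)
  ## H0 sites sit on the membrane plane at the dimer interface side
  ## (+y), so the antiparallel dimer pairs site 1 and site 2 of the two
  ## monomers at the contact distance of their attractive channel
  coords[1, ] <- c(-0.4, 0.31, 0)     # H0 site A (residues 1-8)
  coords[2, ] <- c(0.4, 0.31, 0)      # H0 site B (residues 9-15)
  coords[5, ] <- c(0.5, 0.7, 0.5)     # hydrophobic patch (V50/V51)
  coords[10, ] <- c(0.9, -0.35, 0.15) # R114 loop
  coords[7, ] <- c(-0.1, -0.55, 0.2)  # PIP2 pocket
  rest <- setdiff(3:16, c(5, 7, 10))
  ring <- rbind(body_ring1, body_ring2)
  coords[rest, ] <- ring[seq_along(rest), ]
  coords
}

## Nitroxide label-anchor local positions for the EPR-restrained residues.
## Anchors approximate R1 nitroxide positions: ~7-9 Angstrom from the H0
## site centers, laid out along the helix with side-chain directions chosen
## to reproduce the membrane-bound dimer geometry.
enth16_label_anchors <- function() {
  tibble(
    residue = c(4L, 5L, 6L, 10L, 13L, 14L),
    site = c(1L, 1L, 1L, 2L, 2L, 2L),
    ax = c(-0.6, -0.45, -0.3, 0.3, 0.75, 0.9),
    ay = c(-0.0617, 0.8, 0.223, 0.223, 0.3, 0.55),
    az = c(0.697, 0, 0.663, 0.663, 0.632, 0.433)
  )
}

#' Assemble the 16-site ENTH domain topology
#'
#' Builds the `enth_topology` object: site coordinates, per-site roles
#' (H0 sites 1 and 2, hydrophobic patch site 5, R114 loop site 10, one PIP2
#' pocket site), the internal spring network and the nitroxide label anchors
#' for the EPR-restrained H0 residues (4, 5, 6, 10, 13, 14).
#'
#' @param reference_coords 16 x 3 coordinate matrix (nm); default the
#'   packaged idealized arrangement [enth16_reference_coords()].
#' @param springs A `spring_network` over sites 1-16, or `NULL` to build a
#'   homogeneous network (k = 500 kcal/(mol nm^2), cutoff 1.3 nm, stiff
#'   enough that thermal bond fluctuations stay below 0.04 nm).
#' @param pip2_site Site index of the PIP2 binding pocket (default 7).
#' @return An `enth_topology`: `sites` tibble (`site`, `x`, `y`, `z`,
#'   `role`), `springs`, `label_anchors` (residue, owning site, local
#'   offset relative to the site).
#' @export
build_enth16 <- function(reference_coords = enth16_reference_coords(),
                         springs = NULL, pip2_site = 7L) {
  coords <- as.matrix(reference_coords)
  if (nrow(coords) != 16L || ncol(coords) != 3L) {
    abort("The ENTH model requires exactly 16 site coordinates.")
  }
  if (pip2_site %in% c(1L, 2L, 5L, 10L)) abort("`pip2_site` clashes with a named role site.")
  if (is.null(springs)) {
    n <- 16L
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    d0 <- sqrt(rowSums((coords[pr[, 2], ] - coords[pr[, 1], ])^2))
    keep <- d0 <= 1.3
    springs <- tibble(i = pr[keep, 1], j = pr[keep, 2], k = 500, r0 = d0[keep])
    class(springs) <- c("spring_network", class(springs))
  }
  if (max(springs$i, springs$j) > 16L || min(springs$i, springs$j) < 1L) {
    abort("Springs reference site indices outside 1..16.")
  }
  comps <- spring_components(16L, springs)
  if (length(comps) > 1L) abort("Spring network is not connected.")
  roles <- rep("generic", 16)
  roles[1] <- "H0_A"; roles[2] <- "H0_B"
  roles[5] <- "hydrophobic_patch"; roles[10] <- "R114_loop"
  roles[pip2_site] <- "PIP2_pocket"
  anchors <- enth16_label_anchors()
  anchors$ox <- anchors$ax - coords[anchors$site, 1]
  anchors$oy <- anchors$ay - coords[anchors$site, 2]
  anchors$oz <- anchors$az - coords[anchors$site, 3]
  structure(list(
    sites = tibble(site = 1:16, x = coords[, 1], y = coords[, 2], z = coords[, 3],
                   role = roles),
    springs = springs,
    label_anchors = anchors[c("residue", "site", "ox", "oy", "oz")]
  ), class = "enth_topology")
}

#' @export
print.enth_topology <- function(x, ...) {
  cat("16-site CG ENTH domain topology\n")
  cat("  roles:", paste(sprintf("%d=%s", x$sites$site[x$sites$role != "generic"],
                                x$sites$role[x$sites$role != "generic"]), collapse = ", "), "\n")
  cat(sprintf("  %d internal springs; %d label anchors\n",
              nrow(x$springs), nrow(x$label_anchors)))
  invisible(x)
}

#' Serialize / load an ENTH topology as JSON
#' @param topology An `enth_topology`.
#' @param path File path.
#' @return `read_topology()` returns an `enth_topology`.
#' @export
write_topology <- function(topology, path) {
  jsonlite::write_json(list(sites = topology$sites,
                            springs = as.data.frame(topology$springs),
                            label_anchors = topology$label_anchors),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  springs <- as_tibble(obj$springs)
  class(springs) <- c("spring_network", class(springs))
  structure(list(sites = as_tibble(obj$sites), springs = springs,
                 label_anchors = as_tibble(obj$label_anchors)),
            class = "enth_topology")
}

## ---- Boltzmann inversion ---------------------------------------------------

#' Potential of mean force by Boltzmann inversion of a radial distribution
#'
#' `PMF(r) = -kB T ln g(r)`, shifted so the PMF tends to zero at the largest
#' distance with `g > 0`.  Bins with `g = 0` are masked as unavailable.
#'
#' @param g_of_r Data frame with columns `r` (monotone grid) and `g` (>= 0).
#' @param temperature Temperature, K.
#' @return Tibble `r`, `pmf` (kcal/mol; `NA` where masked), `masked`.
#' @export
pmf_from_rdf <- function(g_of_r, temperature = 300) {
  g_of_r <- as.data.frame(g_of_r)
  stopifnot(all(c("r", "g") %in% names(g_of_r)))
  if (is.unsorted(g_of_r$r, strictly = TRUE)) abort("`r` grid must be strictly increasing.")
  if (any(g_of_r$g < 0)) abort("g(r) must be non-negative.")
  if (all(g_of_r$g == 0)) abort("g(r) is identically zero; PMF undefined.")
  kb_t <- kB * temperature
  pmf <- ifelse(g_of_r$g > 0, -kb_t * log(g_of_r$g), NA_real_)
  ref <- max(which(g_of_r$g > 0))
  pmf <- pmf - pmf[ref]
  tibble(r = g_of_r$r, pmf = pmf, masked = g_of_r$g == 0)
}
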