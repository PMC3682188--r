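## EPR-restrained construction of ENTH arrangements: the antiparallel-H0
## dimer, the offset dimer-of-dimers (tetramer), the helical tubule coat and
## randomly scattered vesicle monolayers.

#' Default EPR distance restraints for lattice construction
#'
#' Interlabel distances from the spin-dilution analysis of tubule-bound
#' ENTH: residues 6 and 10 at 13 Angstrom and residue 5 at 9 Angstrom
#' (intra-dimer, symmetric), residue 4 broad around 21 Angstrom
#' (intra-dimer, facing away from the interface), and residues 13/14 at
#' 15/10 Angstrom across dimers (inter-dimer, motivating the offset
#' packing).
#'
#' @return Tibble `residue`, `center` (Angstrom), `width` (Angstrom),
#'   `scope` (`"intra_dimer"` or `"inter_dimer"`).
#' @export
default_restraints <- function() {
  tibble(
    residue = c(6L, 10L, 5L, 4L, 13L, 14L),
    center = c(13, 13, 9, 21, 15, 10),
    width = c(2, 2, 2, 4, 2, 2),
    scope = c("intra_dimer", "intra_dimer", "intra_dimer", "intra_dimer",
              "inter_dimer", "inter_dimer")
  )
}

## ---- rigid placements ------------------------------------------------------

new_placements <- function(rotations, translations) {
  structure(purrr::map2(rotations, translations, function(R, t) list(R = R, t = t)),
            class = "placement_set")
}

#' Render placements into world-frame site coordinates
#'
#' @param topology An `enth_topology`.
#' @param placements A `placement_set` (list of rigid transforms).
#' @return Tibble `domain`, `site`, `role`, `x`, `y`, `z`.
#' @export
apply_placements <- function(topology, placements) {
  loc <- as.matrix(topology$sites[c("x", "y", "z")])
  purrr::imap_dfr(placements, function(pl, d) {
    w <- loc %*% t(pl$R)
    tibble(domain = as.integer(d), site = topology$sites$site,
           role = topology$sites$role,
           x = w[, 1] + pl$t[1], y = w[, 2] + pl$t[2], z = w[, 3] + pl$t[3])
  })
}

## world positions of the nitroxide label anchors
anchor_positions <- function(topology, placements) {
  an <- topology$label_anchors
  loc <- cbind(
    topology$sites$x[an$site] + an$ox,
    topology$sites$y[an$site] + an$oy,
    topology$sites$z[an$site] + an$oz
  )
  purrr::imap_dfr(placements, function(pl, d) {
    w <- loc %*% t(pl$R)
    tibble(domain = as.integer(d), residue = an$residue,
           x = w[, 1] + pl$t[1], y = w[, 2] + pl$t[2], z = w[, 3] + pl$t[3])
  })
}

#' Measure an interlabel anchor distance in a constructed arrangement
#'
#' The standalone verification routine: computes nitroxide-anchor world
#' positions directly from the rigid transforms and the topology's label
#' anchors, independent of any construction bookkeeping.  For
#' `scope = "intra_dimer"` it returns the anchor distance between the two
#' domains of the (first) dimer; for `scope = "inter_dimer"` the minimum
#' same-residue anchor distance across the two dimers of a tetramer.
#'
#' @param arrangement An `enth_dimer`, `enth_tetramer`, or a list with
#'   `placements` and `topology`.
#' @param residue Label residue index (4, 5, 6, 10, 13 or 14).
#' @param scope `"intra_dimer"` or `"inter_dimer"`.
#' @return Distance in Angstrom.
#' @export
measure_anchor_distance <- function(arrangement, residue,
                                    scope = c("intra_dimer", "inter_dimer")) {
  scope <- match.arg(scope)
  an <- anchor_positions(arrangement$topology, arrangement$placements)
  an <- an[an$residue == residue, ]
  if (nrow(an) < 2) abort("Residue has no anchors in this arrangement.")
  xyz <- as.matrix(an[c("x", "y", "z")])
  if (scope == "intra_dimer") {
    d <- vnorm(xyz[an$domain == 1, ] - xyz[an$domain == 2, ])
  } else {
    if (length(unique(an$domain)) < 4) abort("Inter-dimer scope needs a tetramer.")
    d1 <- which(an$domain %in% c(1, 2))
    d2 <- which(an$domain %in% c(3, 4))
    d <- min(apply(expand.grid(d1, d2), 1, function(ij) {
      vnorm(xyz[ij[1], ] - xyz[ij[2], ])
    }))
  }
  10 * d # nm -> Angstrom
}

## ---- dimer -----------------------------------------------------------------

dimer_transforms <- function(par) {
  ## par = (x0, y0, alpha, rho): monomer A pose; B is the two-fold image
  ## about the membrane-normal (z) axis through the origin
  R_A <- rot_z(par[3]) %*% rot_x(par[4])
  t_A <- c(par[1], par[2], 0)
  M <- diag(c(-1, -1, 1))
  new_placements(list(R_A, M %*% R_A), list(t_A, as.numeric(M %*% t_A)))
}

## local anchor coordinate matrix (one row per restrained residue)
anchor_local_matrix <- function(topology) {
  an <- topology$label_anchors
  cbind(topology$sites$x[an$site] + an$ox,
        topology$sites$y[an$site] + an$oy,
        topology$sites$z[an$site] + an$oz)
}

dimer_objective <- function(par, site_loc, anch_loc, anch_res, restr,
                            body_rows, clash_min = 0.7) {
  R_A <- rot_z(par[3]) %*% rot_x(par[4])
  t_A <- c(par[1], par[2], 0)
  aA <- anch_loc %*% t(R_A)
  aA <- sweep(aA, 2, t_A, "+")
  ## two-fold image about z: (x, y, z) -> (-x, -y, z)
  obj <- 0
  for (r in seq_len(nrow(restr))) {
    k <- which(anch_res == restr$residue[r])
    d <- 10 * 2 * sqrt(aA[k, 1]^2 + aA[k, 2]^2)
    obj <- obj + (d - restr$center[r])^2
  }
  sA <- sweep(site_loc %*% t(R_A), 2, t_A, "+")
  ## keep the body above the membrane plane
  obj <- obj + 100 * sum(pmin(sA[body_rows, 3], 0)^2)
  ## soft excluded-volume: distance of each site from its two-fold image
  dimg <- 2 * sqrt(sA[, 1]^2 + sA[, 2]^2)
  obj + 50 * sum(pmax(0, clash_min - dimg)^2)
}

#' Construct the antiparallel-H0 ENTH dimer from EPR restraints
#'
#' Places two copies of the domain related by a two-fold axis perpendicular
#' to the membrane plane, with H0 axes antiparallel, by least-squares
#' fitting of the intra-dimer interlabel restraints (residues 4, 5, 6, 10)
#' over the rigid placement of one monomer (in-plane position, in-plane
#' rotation and roll about the H0 axis; the symmetry generates the
#' partner).  Residues 6 and 10 must end within 1 Angstrom of their
#' 13-Angstrom restraint centers.
#'
#' @param topology An `enth_topology` (see [build_enth16()]).
#' @param restraints Restraint tibble as [default_restraints()].
#' @return An `enth_dimer`: `placements`, `topology`, `residuals` tibble
#'   (per restraint: measured, target, residual in Angstrom).
#' @export
build_h0_dimer <- function(topology = build_enth16(),
                           restraints = default_restraints()) {
  restr <- restraints[restraints$scope == "intra_dimer", ]
  if (!all(c(6, 10) %in% restr$residue)) {
    abort("Intra-dimer restraints for residues 6 and 10 are required.")
  }
  site_loc <- as.matrix(topology$sites[c("x", "y", "z")])
  anch_loc <- anchor_local_matrix(topology)
  anch_res <- topology$label_anchors$residue
  body_rows <- which(!topology$sites$role %in% c("H0_A", "H0_B"))
  starts <- expand.grid(x0 = c(-0.3, 0, 0.3), y0 = c(-1.2, -0.8, -0.5),
                        alpha = c(0, pi / 2, pi, 3 * pi / 2), rho = c(-0.5, 0, 0.5))
  fits <- purrr::pmap(starts, function(x0, y0, alpha, rho) {
    nlminb(c(x0, y0, alpha, rho), dimer_objective,
           site_loc = site_loc, anch_loc = anch_loc, anch_res = anch_res,
           restr = restr, body_rows = body_rows,
           control = list(iter.max = 400))
  })
  best <- fits[[which.min(purrr::map_dbl(fits, "objective"))]]
  pl <- dimer_transforms(best$par)
  ## canonical frame: domain-1 H0 axis along +x (rotation about the
  ## two-fold axis preserves the symmetry and all distances)
  ax1 <- pl[[1]]$R %*% c(1, 0, 0)
  alpha <- atan2(ax1[2], ax1[1])
  Rfix <- rot_z(-alpha)
  pl <- structure(purrr::map(pl, function(p) {
    list(R = Rfix %*% p$R, t = as.numeric(Rfix %*% p$t))
  }), class = "placement_set")
  out <- structure(list(placements = pl, topology = topology,
                        restraints = restraints),
                   class = "enth_dimer")
  meas <- purrr::map_dbl(restr$residue, function(rs) {
    measure_anchor_distance(out, rs, "intra_dimer")
  })
  resid <- tibble(residue = restr$residue, target = restr$center,
                  measured = meas, residual = meas - restr$center)
  key <- resid$residue %in% c(6, 10)
  if (any(abs(resid$residual[key]) > 1) || any(abs(resid$residual) > 2)) {
    abort(paste0("Infeasible restraint set; per-restraint residuals (Angstrom): ",
                 paste(sprintf("res%d: %+.2f", resid$residue, resid$residual),
                       collapse = ", ")))
  }
  out$residuals <- resid
  out
}

#' H0 axis direction of each placed domain
#' @param arrangement An arrangement with `placements` and `topology`.
#' @return Matrix (domains x 3) of unit axis vectors (site 1 -> site 2).
#' @export
placement_h0_axes <- function(arrangement) {
  sites <- apply_placements(arrangement$topology, arrangement$placements)
  t(sapply(sort(unique(sites$domain)), function(d) {
    s <- sites[sites$domain == d, ]
    normalize(c(s$x[s$site == 2] - s$x[s$site == 1],
                s$y[s$site == 2] - s$y[s$site == 1],
                s$z[s$site == 2] - s$z[s$site == 1]))
  }))
}

## ---- tetramer --------------------------------------------------------------

tetramer_cross_distance <- function(an, residue) {
  a <- an[an$residue == residue, ]
  xyz <- as.matrix(a[c("x", "y", "z")])
  d1 <- which(a$domain %in% c(1, 2)); d2 <- which(a$domain %in% c(3, 4))
  min(apply(expand.grid(d1, d2), 1, function(ij) vnorm(xyz[ij[1], ] - xyz[ij[2], ])))
}

#' Construct the offset dimer-of-dimers (tetramer) unit
#'
#' Places a second copy of the dimer by translation along the H0 axis
#' direction plus a lateral in-plane offset, fit so the cross-dimer
#' residue-13 and residue-14 anchor distances match their restraints and
#' the two hydrophobic patches (site 5) come into LJ contact.
#'
#' @param dimer An [build_h0_dimer()] result.
#' @param restraints Restraints including `inter_dimer` rows for residues
#'   13 and 14.
#' @param patch_sigma Patch contact length (nm); contact is enforced at
#'   `<= 1.2 * patch_sigma`.
#' @return An `enth_tetramer`: `placements` (4 domains: 1-2 first dimer,
#'   3-4 second), `topology`, `residuals`, `patch_distance` (nm).
#' @export
build_tetramer <- function(dimer, restraints = default_restraints(),
                           patch_sigma = 0.85) {
  restr <- restraints[restraints$scope == "inter_dimer", ]
  if (!all(c(13, 14) %in% restr$residue)) {
    abort("Inter-dimer restraints for residues 13 and 14 are required.")
  }
  topo <- dimer$topology
  axis <- placement_h0_axes(dimer)[1, ]
  axis <- normalize(c(axis[1], axis[2], 0))
  lat <- c(-axis[2], axis[1], 0)
  contact <- 1.2 * patch_sigma

  make_tetra <- function(par) {
    off <- par[1] * axis + par[2] * lat
    pl2 <- purrr::map(dimer$placements, function(p) list(R = p$R, t = p$t + off))
    structure(c(dimer$placements, pl2), class = "placement_set")
  }
  ## precomputed world-frame anchors and patch sites of the base dimer
  anch <- anchor_positions(topo, dimer$placements)
  aW <- lapply(1:2, function(d) as.matrix(anch[anch$domain == d, c("x", "y", "z")]))
  res_ids <- anch$residue[anch$domain == 1]
  sites0 <- apply_placements(topo, dimer$placements)
  p5 <- sites0[sites0$role == "hydrophobic_patch", ]
  p5m <- lapply(1:2, function(d) as.numeric(p5[p5$domain == d, c("x", "y", "z")]))
  cross_min <- function(v12, off) {
    min(vnorm(off), vnorm(v12 - off), vnorm(-v12 - off))
  }
  obj <- function(par) {
    off <- par[1] * axis + par[2] * lat
    o <- 0
    for (r in seq_len(nrow(restr))) {
      k <- which(res_ids == restr$residue[r])
      d <- 10 * cross_min(aW[[1]][k, ] - aW[[2]][k, ], off)
      o <- o + (d - restr$center[r])^2
    }
    pmin_d <- cross_min(p5m[[1]] - p5m[[2]], off)
    o + 25 * max(0, pmin_d - contact)^2
  }
  starts <- expand.grid(s = c(-2.4, -1.7, 1.7, 2.4), l = c(-0.6, 0.6))
  fits <- purrr::pmap(starts, function(s, l) {
    nlminb(c(s, l), obj, control = list(iter.max = 300))
  })
  best <- fits[[which.min(purrr::map_dbl(fits, "objective"))]]
  pl <- make_tetra(best$par)
  out <- structure(list(placements = pl, topology = topo,
                        restraints = restraints, offset = best$par),
                   class = "enth_tetramer")
  an <- anchor_positions(topo, pl)
  meas <- purrr::map_dbl(restr$residue, function(rs) 10 * tetramer_cross_distance(an, rs))
  resid <- tibble(residue = restr$residue, target = restr$center,
                  measured = meas, residual = meas - restr$center)
  if (any(abs(resid$residual) > 1.5)) {
    abort(paste0("Infeasible inter-dimer restraints; residuals (Angstrom): ",
                 paste(sprintf("res%d: %+.2f", resid$residue, resid$residual),
                       collapse = ", ")))
  }
  out$residuals <- resid
  out$patch_distance <- cross_min(p5m[[1]] - p5m[[2]],
                                  best$par[1] * axis + best$par[2] * lat)
  out
}

## ---- rendering onto membranes ---------------------------------------------

## attach placed domains to a membrane system, with overlap validation
attach_proteins <- function(system, placements, topology, check = TRUE) {
  pro <- apply_placements(topology, placements)
  sys2 <- system
  sys2$proteins <- pro
  sys2$topology <- topology
  if (check && !is.null(system$lipids) && nrow(system$lipids)) {
    sig_min <- 0.5 * min(system$interactions$pl_sigma[system$interactions$pl_sigma > 0])
    lx <- as.matrix(system$lipids[c("x", "y", "z")])
    px <- as.matrix(pro[c("x", "y", "z")])
    ## voxel grid over the lipids so the check scales to large systems
    cell <- 1.0
    key <- function(m) paste(floor(m[, 1] / cell), floor(m[, 2] / cell),
                             floor(m[, 3] / cell))
    lip_cells <- split(seq_len(nrow(lx)), key(lx))
    bad <- integer(0)
    base <- floor(px / cell)
    for (i in seq_len(nrow(px))) {
      nb <- as.vector(outer(base[i, 1] + (-1:1), outer(
        base[i, 2] + (-1:1), base[i, 3] + (-1:1), paste), paste))
      cand <- unlist(lip_cells[nb], use.names = FALSE)
      if (!length(cand)) next
      d2 <- (lx[cand, 1] - px[i, 1])^2 + (lx[cand, 2] - px[i, 2])^2 +
        (lx[cand, 3] - px[i, 3])^2
      if (any(d2 < sig_min^2)) bad <- c(bad, i)
    }
    if (length(bad)) {
      abort(paste0("Lipid-protein overlaps below 0.5 sigma at protein rows: ",
                   paste(head(bad, 20), collapse = ", ")))
    }
  }
  sys2
}

#' Helical coat specification for membrane tubes
#'
#' Lattice parameters of the tubule coat.  The coat is built from helical
#' strands of EPR-restrained dimers: along a strand, successive dimers
#' repeat the offset of the dimer-of-dimers (tetramer) unit, so every
#' consecutive pair shares the hydrophobic-patch contact and the
#' end-to-end H0 contacts; `dimers_per_turn` strands are started around
#' the azimuth.  All H0 axes are parallel to the tube axis at
#' construction.  Defaults give roughly the packing density implied by
#' 192 domains per 50 nm of 16-nm tube.
#'
#' @param tube_diameter Midplane diameter, nm.
#' @param rise_per_dimer Axial rise per dimer along a strand, nm; `NULL`
#'   uses the axial component of the fitted tetramer offset.
#' @param dimers_per_turn Number of azimuthal strands; `NULL` fills the
#'   circumference at `strand_spacing` (a laterally contiguous coat, as in
#'   the tubule lattice the restraints describe).
#' @param strand_spacing Azimuthal arc between strands, nm; the default
#'   default (3.85) puts neighboring strands just at the steric footprint
#'   of the dimer, giving a laterally contiguous coat.
#' @param n_rows Maximum number of dimers per strand (`NULL` fills the
#'   tube length).
#' @param cap_dimers For capped tubes: dimers per hemispherical cap
#'   (`NULL` scales with cap area).
#' @return A `coat_spec` list.
#' @export
coat_spec <- function(tube_diameter = 16, rise_per_dimer = NULL,
                      dimers_per_turn = NULL, strand_spacing = 3.85,
                      n_rows = NULL, cap_dimers = NULL) {
  structure(list(tube_diameter = tube_diameter, rise_per_dimer = rise_per_dimer,
                 dimers_per_turn = dimers_per_turn,
                 strand_spacing = strand_spacing, n_rows = n_rows,
                 cap_dimers = cap_dimers),
            class = "coat_spec")
}

## frame mapping local (x,y,z) -> (tube axis, tangent, radial) at azimuth phi
tube_frame <- function(phi) {
  rhat <- c(cos(phi), sin(phi), 0)
  zhat <- c(0, 0, 1)
  that <- c(rhat[2] * zhat[3] - rhat[3] * zhat[2],
            rhat[3] * zhat[1] - rhat[1] * zhat[3],
            rhat[1] * zhat[2] - rhat[2] * zhat[1]) # rhat x zhat
  cbind(zhat, that, rhat)
}

#' Coat a membrane tube with the EPR-restrained tetramer lattice
#'
#' Tiles the tetramer unit helically over the tube surface with the H0
#' sites at the outer-leaflet headgroup shell and all H0 axes parallel to
#' the tube axis.  The azimuthal origin is anchored to the membrane (the
#' first lipid's azimuth), so rotating the tube about its axis rotates the
#' coat with it.
#'
#' @param tube A [build_tube()] system.
#' @param spec A [coat_spec()].
#' @param topology An `enth_topology`.
#' @param restraints Restraints for the dimer/tetramer construction.
#' @return The tube system with `proteins` attached; attributes
#'   `n_domains` and `initial_order` record the placed count and the
#'   t = 0 global order parameter.
#' @export
coat_tube <- function(tube, spec = coat_spec(), topology = build_enth16(),
                      restraints = default_restraints()) {
  params <- tube$params
  half <- lipid_length(params) / 2
  r_mid <- spec$tube_diameter / 2
  r_place <- r_mid + leaflet_offset(params) + half # outer headgroup shell
  dimer <- build_h0_dimer(topology, restraints)
  tet <- build_tetramer(dimer, restraints)
  rise <- spec$rise_per_dimer %||% abs(tet$offset[1])
  ## lateral (azimuthal arc) offset per dimer; local +y maps to -phi_hat
  ## in the tube frame, hence the sign flip
  drift <- -tet$offset[2]
  if (tube$periodic[3]) {
    L <- tube$box[3]; zlo <- 0
  } else {
    ## cylindrical part of a capped tube (caps are coated separately)
    geo <- tube$geometry
    if (is.null(geo)) abort("Capped tubes must come from build_tube().")
    zlo <- geo$z0
    L <- geo$length
  }
  n_strands <- spec$dimers_per_turn %||%
    max(1, floor(2 * pi * r_place / spec$strand_spacing))
  seamless <- FALSE
  if (tube$periodic[3] && is.null(spec$n_rows) &&
      abs(L / rise - round(L / rise)) < 0.15) {
    ## seamless helical lattice: strands continue across the periodic
    ## boundary into the next strand; the helical drift is adjusted (by a
    ## fraction of an Angstrom) so the helix closes exactly
    seamless <- TRUE
    n_per_strand <- max(1, round(L / rise))
    rise <- L / n_per_strand
    drift <- sign(drift) * 2 * pi * r_place / (n_strands * n_per_strand)
    margin <- 0
  } else {
    ## open strands: leave a clearance so strand termini do not clash
    ## across the seam (or against the caps)
    n_per_strand <- max(1, floor((L - 1.2) / rise))
    if (!is.null(spec$n_rows)) n_per_strand <- min(n_per_strand, spec$n_rows)
    margin <- (L - n_per_strand * rise) / 2
  }
  phi_anchor <- atan2(tube$lipids$y[1], tube$lipids$x[1])
  placements <- list()
  for (s in seq_len(n_strands)) {
    for (k in seq_len(n_per_strand) - 1) {
      phi <- phi_anchor + 2 * pi * (s - 1) / n_strands + k * drift / r_place
      zc <- zlo + margin + rise / 2 + k * rise
      Q <- tube_frame(phi)
      base <- r_place * c(cos(phi), sin(phi), 0) + c(0, 0, zc)
      placements <- c(placements, purrr::map(dimer$placements, function(p) {
        list(R = Q %*% p$R, t = as.numeric(Q %*% p$t) + base)
      }))
    }
  }
  if (!tube$periodic[3]) {
    ## coat the hemispherical caps: dimers on tangent planes, axes along
    ## the local meridian (continuing the cylinder alignment)
    n_cap <- spec$cap_dimers %||% max(3, round(pi * r_place^2 / (2 * 16)))
    for (side in c(-1, 1)) {
      zc <- if (side < 0) zlo else zlo + L
      pts <- fibonacci_sphere(4 * n_cap, 1)
      pts <- pts[sign(pts$z) == side & abs(pts$z) > 0.25, ]
      pts <- pts[seq_len(min(n_cap, nrow(pts))), ]
      for (i in seq_len(nrow(pts))) {
        v <- normalize(c(pts$x[i], pts$y[i], pts$z[i]))
        merid <- c(0, 0, side) - side * v[3] * v # tube-axis direction projected
        if (vnorm(merid) < 1e-6) next
        merid <- normalize(merid)
        t2 <- cross3(v, merid)
        Q <- cbind(merid, t2, v)
        base <- c(0, 0, zc) + r_place * v
        placements <- c(placements, purrr::map(dimer$placements, function(p) {
          list(R = Q %*% p$R, t = as.numeric(Q %*% p$t) + base)
        }))
      }
    }
  }
  placements <- structure(placements, class = "placement_set")
  sys <- attach_proteins(tube, placements, topology)
  axes <- domain_axes(sys)
  field <- local_order(axes)
  ord0 <- attr(field, "global")
  if (is.finite(ord0) && ord0 < 0.98) {
    warning(sprintf("Initial coat order %.3f below the 0.98 construction contract.", ord0))
  }
  attr(sys, "n_domains") <- length(placements)
  attr(sys, "initial_order") <- ord0
  sys
}

#' Scatter ENTH monomers over a vesicle surface
#'
#' Domains are placed at uniformly random surface points with random
#' in-plane orientation, H0 sites `standoff` nm above the outer headgroup
#' shell; placement is by seeded rejection sampling with a retry cap.
#'
#' @param vesicle A [build_vesicle()] system.
#' @param n_domains Number of domains.
#' @param standoff Height of the H0 sites above the outer headgroup shell,
#'   nm (default 0.5).
#' @param seed Integer seed.
#' @param topology An `enth_topology`.
#' @param min_separation Minimum center-center separation between placed
#'   domains, nm.
#' @return The vesicle system with `proteins` attached.
#' @export
scatter_vesicle <- function(vesicle, n_domains, standoff = 0.5, seed = 1,
                            topology = build_enth16(), min_separation = 2.3) {
  half <- lipid_length(vesicle$params) / 2
  ctr <- vesicle$box / 2
  rad <- sqrt((vesicle$lipids$x - ctr[1])^2 + (vesicle$lipids$y - ctr[2])^2 +
                (vesicle$lipids$z - ctr[3])^2)
  r_shell <- max(rad) + half # outer headgroup shell
  r_place <- r_shell + standoff
  placements <- with_seed(seed, {
    acc <- list()
    centers <- matrix(0, 0, 3)
    tries <- 0L
    while (length(acc) < n_domains) {
      tries <- tries + 1L
      if (tries > 300L * n_domains) {
        abort("Placement retry cap exceeded; reduce `n_domains`.")
      }
      v <- normalize(rnorm(3))
      pos <- ctr + r_place * v
      if (nrow(centers) &&
          min(sqrt(rowSums(sweep(centers, 2, pos)^2))) < min_separation) next
      t1 <- normalize(c(-v[2], v[1], 0) + 1e-8)
      ang <- runif(1, 0, 2 * pi)
      t1 <- as.numeric(cos(ang) * t1 + sin(ang) * cross3(v, t1))
      t2 <- cross3(v, t1)
      Q <- cbind(t1, t2, v)
      acc <- c(acc, list(list(R = Q, t = pos)))
      centers <- rbind(centers, pos)
    }
    acc
  })
  placements <- structure(placements, class = "placement_set")
  attach_proteins(vesicle, placements, topology)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Scatter pre-built ENTH dimers over a vesicle surface
#'
#' As [scatter_vesicle()] but placing rigid copies of the EPR-restrained
#' dimer (two domains each), preserving the dimer internal geometry.
#'
#' @param vesicle A [build_vesicle()] system.
#' @param n_dimers Number of dimers (2 domains each).
#' @param dimer A [build_h0_dimer()] result; built from the default
#'   topology/restraints when `NULL`.
#' @inheritParams scatter_vesicle
#' @return The vesicle system with `proteins` attached.
#' @export
dimer_scatter_vesicle <- function(vesicle, n_dimers, standoff = 0.5, seed = 1,
                                  dimer = NULL, min_separation = 3.6) {
  if (is.null(dimer)) dimer <- build_h0_dimer()
  topology <- dimer$topology
  half <- lipid_length(vesicle$params) / 2
  ctr <- vesicle$box / 2
  rad <- sqrt((vesicle$lipids$x - ctr[1])^2 + (vesicle$lipids$y - ctr[2])^2 +
                (vesicle$lipids$z - ctr[3])^2)
  r_place <- max(rad) + half + standoff
  placements <- with_seed(seed, {
    acc <- list()
    centers <- matrix(0, 0, 3)
    tries <- 0L
    while (length(acc) < 2 * n_dimers) {
      tries <- tries + 1L
      if (tries > 300L * n_dimers) {
        abort("Placement retry cap exceeded; reduce `n_dimers`.")
      }
      v <- normalize(rnorm(3))
      pos <- ctr + r_place * v
      if (nrow(centers) &&
          min(sqrt(rowSums(sweep(centers, 2, pos)^2))) < min_separation) next
      t1 <- normalize(c(-v[2], v[1], 0) + 1e-8)
      ang <- runif(1, 0, 2 * pi)
      t1 <- as.numeric(cos(ang) * t1 + sin(ang) * cross3(v, t1))
      t2 <- cross3(v, t1)
      Q <- cbind(t1, t2, v)
      for (p in dimer$placements) {
        acc <- c(acc, list(list(R = Q %*% p$R, t = as.numeric(Q %*% p$t) + pos)))
      }
      centers <- rbind(centers, pos)
    }
    acc
  })
  placements <- structure(placements, class = "placement_set")
  attach_proteins(vesicle, placements, topology)
}

#' Serialize placements as JSON
#' @param placements A `placement_set`. @param path File path.
#' @export
write_placements <- function(placements, path) {
  obj <- purrr::map(placements, function(p) list(R = p$R, t = p$t))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_placements
#' @export
read_placements <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(purrr::map(obj, function(o) {
    list(R = matrix(unlist(o$R), 3, 3, byrow = TRUE), t = unlist(o$t))
  }), class = "placement_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
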