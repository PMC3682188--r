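## The CG membrane simulator surface: anisotropic-lipid parameters, system
## containers, flat/tube/vesicle builders, energies and NVT dynamics.

#' Gay-Berne lipid parameters
#'
#' Each lipid is a single-site Gay-Berne ellipsoid with a 3:1 aspect ratio
#' (length/breadth) mimicking the lipid shape, with the symmetry along the
#' long axis broken by a head-tail asymmetry term (amphiphilicity).  The
#' default constants are the package's fixture parameter set, calibrated so
#' a tensionless flat bilayer is stable at 300 K (see
#' [calibrate_site_membrane_eps()] for the matching protein-site adhesion
#' calibration).
#'
#' @param sigma0 Breadth (short axis contact length), nm.
#' @param epsilon0 Energy scale, kcal/mol.
#' @param aspect_ratio Length/breadth (default 3).
#' @param well_anisotropy Side-by-side vs end-to-end well-depth ratio
#'   parameter (kappa' of the Gay-Berne form).
#' @param mu,nu Gay-Berne well-depth exponents.
#' @param head_tail_asymmetry Amplitude (kcal/mol) of the term odd under
#'   director flip that makes head-head and tail-tail approaches differ.
#' @param cutoff,switch_on Smooth truncation bounds in reduced separation
#'   `rho = (r - sigma + sigma0)/sigma0` (orientation-dependent real-space
#'   cutoff; the largest real-space range is
#'   `sigma0 * (aspect_ratio - 1 + cutoff)`).
#' @param mass_lipid,mass_site,inertia CG masses (kcal mol^-1 ps^2 nm^-2)
#'   and lipid moment of inertia for director dynamics.
#' @param skin Verlet-list skin, nm.
#' @return A `gb_params` list.
#' @export
gb_params <- function(sigma0 = 0.77, epsilon0 = 0.95, aspect_ratio = 3,
                      well_anisotropy = 5, mu = 2, nu = 2,
                      head_tail_asymmetry = 0.5, cutoff = 2.5,
                      switch_on = 1.8, mass_lipid = 1, mass_site = 1,
                      inertia = 0.4, skin = 0.3) {
  stopifnot_scalar(epsilon0, "epsilon0", positive = TRUE)
  stopifnot_scalar(sigma0, "sigma0", positive = TRUE)
  structure(list(sigma0 = sigma0, epsilon0 = epsilon0,
                 aspect_ratio = aspect_ratio, well_anisotropy = well_anisotropy,
                 mu = mu, nu = nu, head_tail_asymmetry = head_tail_asymmetry,
                 cutoff = cutoff, switch_on = switch_on,
                 mass_lipid = mass_lipid, mass_site = mass_site,
                 inertia = inertia, skin = skin),
            class = "gb_params")
}

lipid_length <- function(params) params$aspect_ratio * params$sigma0

## Half-separation between leaflet center planes: half the end-to-end
## Gay-Berne pair minimum, so opposed leaflets sit at their tail-tail
## equilibrium.
leaflet_offset <- function(params) {
  0.5 * params$sigma0 * (params$aspect_ratio - 1 + 2^(1 / 6))
}

## protein site role -> integer code used by the compiled core
PTYPE_CODES <- c(generic = 0L, H0_A = 1L, H0_B = 2L, hydrophobic_patch = 3L,
                 R114_loop = 4L, PIP2_pocket = 5L)

#' The protein-membrane / protein-protein interaction table
#'
#' Encodes the attractive channels of the model: the H0-membrane
#' interaction (total well depth 4 kcal/mol, split evenly over the two H0
#' sites), the R114 loop-membrane interaction (1.2 kcal/mol), the PIP2
#' pocket-PIP2 lipid interaction (2.4 kcal/mol), and the inter-protein
#' H0-H0 and hydrophobic patch-patch interactions (2 kcal/mol each).  All
#' other protein pairs are repulsive-only (WCA excluded volume).
#'
#' The H0-membrane depth is the total helix-interface adhesion (its value
#' comes from an interfacial transfer free energy), so it is converted to a
#' per-pair LJ epsilon with the flat-leaflet calibration of
#' [calibrate_site_membrane_eps()]; the R114 depth is a site-lipid pair
#' potential of mean force and is used per pair directly, as are the
#' PIP2-pocket and inter-protein channels.
#'
#' @param h0_membrane Total H0-membrane well depth, kcal/mol (split over
#'   the two H0 sites).
#' @param r114_membrane R114 loop-lipid pair well depth, kcal/mol.
#' @param pip2_pocket,h0_h0,patch_patch Per-pair well depths, kcal/mol.
#' @param generic_protein Weak generic LJ well (kcal/mol) between all other
#'   cross-domain site pairs, tuned so domains cohere without condensing
#'   into an agglomerated phase; set 0 for pure excluded volume.
#' @param h0_h0_on Set `FALSE` for the control with the inter-protein
#'   H0-H0 attraction removed.
#' @return An `interaction_table` list consumed by [cg_system()].
#' @export
default_interactions <- function(h0_membrane = 4, r114_membrane = 1.2,
                                 pip2_pocket = 2.4, h0_h0 = 2,
                                 patch_patch = 2, generic_protein = 0.2,
                                 h0_h0_on = TRUE) {
  ## fixture calibration: per-pair epsilon giving the stated adhesion depth
  ## against a flat fixture leaflet (computed by
  ## calibrate_site_membrane_eps(); frozen here)
  ## H0-membrane: the printed 4 kcal/mol is the total helix-interface
  ## adhesion (an interfacial transfer free energy), split over the two H0 sites and
  ## converted to a per-pair epsilon by the flat-leaflet calibration.
  ## R114-membrane: the printed 1.2 kcal/mol is a site-lipid pair PMF
  ## well, used directly as the per-pair epsilon (as are the PIP2-pocket
  ## and interprotein channels).
  eps_h0_pair <- (h0_membrane / 2) * PL_EPS_PER_WELL[["h0"]]
  ## type order: generic, H0_A (site 1), H0_B (site 2), patch, R114,
  ## pocket, core (the per-domain excluded-volume center)
  pl_eps <- c(0, eps_h0_pair, eps_h0_pair, 0, r114_membrane, pip2_pocket, 0)
  pl_sigma <- c(0.80, 1.16, 1.16, 0.80, 1.00, 1.00, 0.80)
  pp_eps <- matrix(generic_protein, 7, 7)
  pp_sigma <- matrix(0.62, 7, 7)
  ## H0 sites are sterically bulky against everything except their
  ## designated partner, capping the coordination of the specific contact
  pp_sigma[2:3, ] <- 0.80; pp_sigma[, 2:3] <- 0.80
  pp_sigma[2, 2] <- 1.00; pp_sigma[3, 3] <- 1.00
  ## the inter-protein H0 attraction acts between CG site 1 and CG site 2
  ## of different domains (end-to-end lattice contact); the control
  ## (h0_h0_on = FALSE) keeps only the generic background there
  pp_sigma[2, 3] <- 0.88; pp_sigma[3, 2] <- 0.88
  if (h0_h0_on) {
    pp_eps[2, 3] <- h0_h0; pp_eps[3, 2] <- h0_h0
  }
  pp_eps[4, 4] <- patch_patch
  pp_sigma[4, 4] <- 0.85
  ## domain compactness core: purely repulsive against other cores at the
  ## lattice contact spacing; inert otherwise
  pp_eps[7, ] <- 0; pp_eps[, 7] <- 0
  pp_sigma[7, ] <- 0.30; pp_sigma[, 7] <- 0.30
  pp_sigma[7, 7] <- 1.38
  structure(list(
    well_depths = tibble(
      channel = c("h0_membrane_total", "r114_membrane", "pip2_pocket",
                  "h0_h0_interprotein", "patch_patch"),
      well_depth = c(h0_membrane, r114_membrane, pip2_pocket,
                     if (h0_h0_on) h0_h0 else 0, patch_patch)),
    pl_eps = pl_eps, pl_sigma = pl_sigma,
    pp_eps = pp_eps, pp_sigma = pp_sigma,
    lj_cutoff = 2.5, lj_switch_on = 2.0, eps_repulsive = 1.0
  ), class = "interaction_table")
}

#' Simulation configuration
#'
#' Constant-NVT setup: 300 K default with a Nose-Hoover thermostat
#' (single chain, coupling time `tau`), velocity Verlet integration with a
#' 0.001 ps default time step.
#'
#' @param temperature K. @param dt Time step, ps. @param thermostat_tau
#'   Nose-Hoover coupling time, ps.
#' @param seed Integer seed for velocity initialization.
#' @return A `sim_config` list.
#' @export
sim_config <- function(temperature = 300, dt = 0.001, thermostat_tau = 0.1,
                       seed = 1) {
  structure(list(temperature = temperature, dt = dt,
                 thermostat_tau = thermostat_tau, seed = seed),
            class = "sim_config")
}

#' Assemble a CG system
#'
#' @param lipids Tibble with columns `x`, `y`, `z`, `ux`, `uy`, `uz`,
#'   `is_pip2` (director is the head-to-tail unit vector), or `NULL`.
#' @param proteins Tibble with columns `domain`, `site`, `role`, `x`, `y`,
#'   `z`, or `NULL`.
#' @param topology The `enth_topology` shared by all protein domains
#'   (required when `proteins` is given).
#' @param params [gb_params()]. @param interactions
#'   [default_interactions()]. @param config [sim_config()].
#' @param box Numeric length-3 box lengths, nm. @param periodic Logical
#'   length-3 per-axis periodicity flags.
#' @return A `cg_system`.
#' @export
cg_system <- function(lipids = NULL, proteins = NULL, topology = NULL,
                      params = gb_params(), interactions = default_interactions(),
                      config = sim_config(), box = c(50, 50, 50),
                      periodic = c(FALSE, FALSE, FALSE)) {
  if (!is.null(proteins) && is.null(topology)) {
    abort("`topology` is required when protein domains are present.")
  }
  if (!is.null(lipids)) {
    nrm <- sqrt(lipids$ux^2 + lipids$uy^2 + lipids$uz^2)
    if (any(abs(nrm - 1) > 1e-6)) {
      lipids$ux <- lipids$ux / nrm; lipids$uy <- lipids$uy / nrm; lipids$uz <- lipids$uz / nrm
    }
  }
  structure(list(lipids = lipids, proteins = proteins, topology = topology,
                 params = params, interactions = interactions, config = config,
                 box = box, periodic = periodic),
            class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  nl <- if (is.null(x$lipids)) 0L else nrow(x$lipids)
  np <- if (is.null(x$proteins)) 0L else nrow(x$proteins)
  nd <- if (np) length(unique(x$proteins$domain)) else 0L
  cat(sprintf("CG system: %d lipids (%d PIP2), %d protein sites in %d domains\n",
              nl, if (nl) sum(x$lipids$is_pip2) else 0L, np, nd))
  cat(sprintf("  box %.1f x %.1f x %.1f nm, periodic (%s)\n",
              x$box[1], x$box[2], x$box[3],
              paste(ifelse(x$periodic, "T", "F"), collapse = ",")))
  invisible(x)
}

## flatten a cg_system into the list the compiled core consumes
as_sim_state <- function(system) {
  lip <- system$lipids
  pro <- system$proteins
  n_lip <- if (is.null(lip)) 0L else nrow(lip)
  pos_l <- if (n_lip) cbind(lip$x, lip$y, lip$z) else matrix(0, 0, 3)
  pos_p <- if (!is.null(pro)) cbind(pro$x, pro$y, pro$z) else matrix(0, 0, 3)
  springs <- matrix(0, 0, 4)
  ptype <- integer(0); domain <- integer(0)
  pos_c <- matrix(0, 0, 3)
  if (!is.null(pro)) {
    ptype <- unname(PTYPE_CODES[pro$role])
    domain <- as.integer(pro$domain)
    sp <- system$topology$springs
    doms <- unique(pro$domain)
    np <- nrow(pro)
    ## global index of (domain, site)
    key <- function(d, s) n_lip + match(paste(d, s), paste(pro$domain, pro$site))
    springs <- do.call(rbind, lapply(doms, function(d) {
      cbind(key(d, sp$i), key(d, sp$j), sp$k, sp$r0)
    }))
    ## one excluded-volume core per domain at the body centroid, pinned to
    ## the domain frame by stiff springs (not a topology site)
    core_springs <- vector("list", length(doms))
    for (ii in seq_along(doms)) {
      d <- doms[ii]
      rows <- which(pro$domain == d & pro$site >= 3)
      cpos <- colMeans(cbind(pro$x[rows], pro$y[rows], pro$z[rows]))
      pos_c <- rbind(pos_c, cpos)
      cidx <- n_lip + np + ii
      anch <- c(key(d, 1L), key(d, 2L), key(d, 15L), key(d, 16L))
      r0 <- sqrt((pro$x[anch - n_lip] - cpos[1])^2 +
                   (pro$y[anch - n_lip] - cpos[2])^2 +
                   (pro$z[anch - n_lip] - cpos[3])^2)
      core_springs[[ii]] <- cbind(anch, cidx, 500, r0)
    }
    springs <- rbind(springs, do.call(rbind, core_springs))
    ptype <- c(ptype, rep(6L, length(doms)))
    domain <- c(domain, as.integer(doms))
  }
  par <- c(system$params,
           system$interactions[c("pl_eps", "pl_sigma", "pp_eps", "pp_sigma",
                                 "lj_cutoff", "lj_switch_on", "eps_repulsive")])
  list(pos = rbind(pos_l, pos_p, pos_c),
       dir = if (n_lip) cbind(lip$ux, lip$uy, lip$uz) else matrix(0, 0, 3),
       n_lip = n_lip,
       pip2 = if (n_lip) as.integer(lip$is_pip2) else integer(0),
       ptype = ptype, domain = domain,
       springs = springs,
       box = as.numeric(system$box), periodic = as.logical(system$periodic),
       params = par,
       vel = system$vel, ang = system$ang)
}

#' Gay-Berne pair energy between two lipids
#'
#' @param pos_i,pos_j Positions (nm). @param dir_i,dir_j Unit directors.
#' @param params [gb_params()].
#' @return Energy in kcal/mol, with attributes `force_i` (force on lipid i)
#'   and `du_i`, `du_j` (orientation gradients).
#' @export
gb_pair_energy <- function(pos_i, pos_j, dir_i, dir_j, params = gb_params()) {
  if (sum((pos_i - pos_j)^2) < 1e-20) abort("Zero separation (overlap).")
  out <- gb_pair_cpp(pos_i, pos_j, normalize(dir_i), normalize(dir_j), params)
  structure(out$energy, force_i = out$force_i, du_i = out$du_i, du_j = out$du_j)
}

#' Total potential energy of a CG system, decomposed by term
#'
#' @param system A [cg_system()].
#' @return Tibble with `term` (`gb`, `protein_lipid`, `protein_protein`,
#'   `spring`, `total`) and `energy` (kcal/mol).
#' @export
total_energy <- function(system) {
  nl <- if (is.null(system$lipids)) 0L else nrow(system$lipids)
  np <- if (is.null(system$proteins)) 0L else nrow(system$proteins)
  if (nl + np == 0L) {
    return(tibble(term = c("gb", "protein_lipid", "protein_protein", "spring", "total"),
                  energy = 0))
  }
  e <- total_energy_cpp(as_sim_state(system))
  tibble(term = c("gb", "protein_lipid", "protein_protein", "spring", "total"),
         energy = c(e$gb, e$protein_lipid, e$protein_protein, e$spring, e$total))
}

## forces for finite-difference checks
system_forces <- function(system) {
  e <- total_energy_cpp(as_sim_state(system))
  list(forces = e$forces, dir_grad = e$dir_grad, total = e$total)
}

assign_pip2 <- function(n, fraction, seed) {
  k <- round(fraction * n)
  flag <- rep(FALSE, n)
  if (k > 0) flag[with_seed(seed, sample.int(n, k))] <- TRUE
  flag
}

#' Build a flat bilayer
#'
#' Two opposed leaflets on a square lattice with antiparallel directors
#' along the membrane normal (z); 10% of lipids are flagged PIP2 by a
#' seeded draw.
#'
#' @param nx,ny Lipids per leaflet along x and y.
#' @param params [gb_params()].
#' @param area_per_lipid nm^2 (fixture value 0.75).
#' @param pip2_fraction PIP2 fraction (default 0.10).
#' @param seed Seed for the PIP2 assignment.
#' @param box_height Box z, nm.
#' @return A [cg_system()] periodic in x and y.
#' @export
build_bilayer <- function(nx, ny, params = gb_params(), area_per_lipid = 0.75,
                          pip2_fraction = 0.10, seed = 1, box_height = 30) {
  if (nx < 1 || ny < 1) abort("Leaflet dimensions must be positive.")
  s <- sqrt(area_per_lipid)
  loff <- leaflet_offset(params)
  grid <- expand.grid(ix = seq_len(nx) - 1, iy = seq_len(ny) - 1)
  mk <- function(z, uz) tibble(x = (grid$ix + 0.5) * s, y = (grid$iy + 0.5) * s,
                               z = z, ux = 0, uy = 0, uz = uz)
  lip <- dplyr::bind_rows(mk(box_height / 2 + loff, -1), # top leaflet, head up
                          mk(box_height / 2 - loff, 1))  # bottom leaflet, head down
  lip$is_pip2 <- assign_pip2(nrow(lip), pip2_fraction, seed)
  cg_system(lipids = lip, params = params,
            box = c(nx * s, ny * s, box_height),
            periodic = c(TRUE, TRUE, FALSE))
}

## near-uniform points on a cylinder of radius r, length L (rows stacked in
## z, staggered rings)
cylinder_points <- function(r, L, apl, z0 = 0) {
  n_target <- max(1, round(2 * pi * r * L / apl))
  rows <- max(1, round(L / sqrt(apl)))
  per_ring <- max(3, round(n_target / rows))
  dz <- L / rows
  out <- lapply(seq_len(rows), function(k) {
    phi0 <- (k %% 2) * pi / per_ring
    phi <- seq(0, 2 * pi, length.out = per_ring + 1)[-(per_ring + 1)] + phi0
    tibble(x = r * cos(phi), y = r * sin(phi), z = z0 + (k - 0.5) * dz, phi = phi)
  })
  dplyr::bind_rows(out)
}

## Fibonacci-sphere points
fibonacci_sphere <- function(n, r) {
  i <- seq_len(n) - 0.5
  ga <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n
  rad <- sqrt(pmax(0, 1 - z^2))
  th <- ga * i
  tibble(x = r * rad * cos(th), y = r * rad * sin(th), z = r * z)
}

#' Build a cylindrical bilayer (membrane tube)
#'
#' A cylindrical bilayer with radial directors; leaflet lipid counts follow
#' the inner/outer leaflet area ratio at the leaflet center offsets.
#' `diameter` is the bilayer midplane diameter.  Periodic tubes extend
#' across the periodic z boundary; capped tubes are closed with
#' hemispherical caps.
#'
#' @param diameter Midplane diameter, nm (16 for the ENTH tubule systems).
#' @param length Cylinder length, nm.
#' @param area_per_lipid nm^2.
#' @param periodic Tube continues across the periodic box boundary.
#' @param capped Tube closed with hemispherical caps (exactly one of
#'   `periodic`/`capped` must be `TRUE`).
#' @param params,pip2_fraction,seed As in [build_bilayer()].
#' @param box Optional box lengths; for a periodic tube the z length must
#'   equal `length`.
#' @return A [cg_system()]; tube axis along z, centered at x = y = 0.
#' @export
build_tube <- function(diameter, length, area_per_lipid = 0.75,
                       periodic = TRUE, capped = FALSE, params = gb_params(),
                       pip2_fraction = 0.10, seed = 1, box = NULL) {
  if (periodic == capped) abort("Exactly one of `periodic`/`capped` must be TRUE.")
  loff <- leaflet_offset(params)
  r_mid <- diameter / 2
  if (diameter <= 4 * lipid_length(params)) {
    abort("Tube diameter must exceed four lipid lengths.")
  }
  r_out <- r_mid + loff
  r_in <- r_mid - loff
  mk_leaflet <- function(r, sgn) {
    pts <- cylinder_points(r, length, area_per_lipid)
    ## director radial: outer leaflet (sgn=-1) head outward, inner head inward
    tibble(x = pts$x, y = pts$y, z = pts$z,
           ux = sgn * cos(pts$phi), uy = sgn * sin(pts$phi), uz = 0)
  }
  lip <- dplyr::bind_rows(mk_leaflet(r_out, -1), mk_leaflet(r_in, 1))
  if (capped) {
    mk_cap <- function(r, sgn, zc, top) {
      n <- max(3, round(4 * pi * r^2 / 2 / area_per_lipid))
      sph <- fibonacci_sphere(2 * n, r)
      ## trim the hemisphere by half a lattice spacing so cap lipids do
      ## not overlap the cylinder-end rings at the seam
      seam <- 0.45 * sqrt(area_per_lipid)
      sph <- sph[if (top) sph$z > seam else sph$z < -seam, ]
      rad <- sqrt(sph$x^2 + sph$y^2 + sph$z^2)
      tibble(x = sph$x, y = sph$y, z = zc + sph$z,
             ux = sgn * sph$x / rad, uy = sgn * sph$y / rad, uz = sgn * sph$z / rad)
    }
    lip <- dplyr::bind_rows(
      lip,
      mk_cap(r_out, -1, length, TRUE), mk_cap(r_in, 1, length, TRUE),
      mk_cap(r_out, -1, 0, FALSE), mk_cap(r_in, 1, 0, FALSE))
  }
  lip$is_pip2 <- assign_pip2(nrow(lip), pip2_fraction, seed)
  margin <- 2 * (r_out + lipid_length(params)) + 6
  if (is.null(box)) {
    box <- if (periodic) c(margin, margin, length) else c(margin, margin, length + margin)
  }
  if (periodic && abs(box[3] - length) > 1e-9) {
    abort("Periodic tube length must match the periodic box z length.")
  }
  z0 <- if (capped) (box[3] - length) / 2 else 0
  if (capped) lip$z <- lip$z + z0
  sys <- cg_system(lipids = lip, params = params,
                   box = box, periodic = c(FALSE, FALSE, periodic))
  sys$geometry <- list(kind = "tube", diameter = diameter, length = length,
                       capped = capped, z0 = z0)
  sys
}

#' Build a spherical bilayer (vesicle)
#'
#' Fibonacci-sphere placement per leaflet with radial directors; per-leaflet
#' counts follow the sphere areas at the leaflet center radii so that the
#' lipid densities in the two leaflets balance.  `diameter` is the midplane
#' diameter.
#'
#' @inheritParams build_tube
#' @return A [cg_system()] centered in a non-periodic box.
#' @export
build_vesicle <- function(diameter, area_per_lipid = 0.75, params = gb_params(),
                          pip2_fraction = 0.10, seed = 1) {
  loff <- leaflet_offset(params)
  r_mid <- diameter / 2
  if (diameter <= 4 * lipid_length(params)) {
    abort("Vesicle diameter must exceed four lipid lengths.")
  }
  mk_leaflet <- function(r, sgn) {
    n <- max(12, round(4 * pi * r^2 / area_per_lipid))
    sph <- fibonacci_sphere(n, r)
    rad <- sqrt(sph$x^2 + sph$y^2 + sph$z^2)
    tibble(x = sph$x, y = sph$y, z = sph$z,
           ux = sgn * sph$x / rad, uy = sgn * sph$y / rad, uz = sgn * sph$z / rad)
  }
  lip <- dplyr::bind_rows(mk_leaflet(r_mid + loff, -1), mk_leaflet(r_mid - loff, 1))
  lip$is_pip2 <- assign_pip2(nrow(lip), pip2_fraction, seed)
  L <- 2 * (r_mid + loff + lipid_length(params)) + 8
  lip[c("x", "y", "z")] <- lip[c("x", "y", "z")] + L / 2
  sys <- cg_system(lipids = lip, params = params, box = c(L, L, L),
                   periodic = c(FALSE, FALSE, FALSE))
  sys$geometry <- list(kind = "vesicle", diameter = diameter,
                       center = c(L, L, L) / 2)
  sys
}

#' Run constant-NVT dynamics
#'
#' Velocity Verlet integration (director dynamics by torque integration
#' with per-step renormalization) coupled to a Nose-Hoover thermal bath.
#' Velocities are initialized from a seeded Maxwell-Boltzmann draw unless
#' the system already carries them from a previous run.
#'
#' @param system A [cg_system()].
#' @param n_steps Number of steps.
#' @param thermostat `FALSE` runs NVE (energy-conservation checks).
#' @param log_stride Steps between thermodynamic log rows.
#' @param snap_stride Steps between stored snapshots (0 = none).
#' @param seed Overrides the config seed for velocity initialization.
#' @param warmup Number of gentle start-up steps run before the `n_steps`
#'   production steps: the temperature and the time step are ramped up in
#'   stages (half at `dt/5` and half the target temperature, half at
#'   `dt/2` approaching it), after which the production run is stable at
#'   the target temperature and time step.
#' @param freeze_proteins Hold all protein sites fixed while the membrane
#'   moves (staged equilibration with positional restraints, released for
#'   the production run).
#' @return A `cg_trajectory`: `system` (final state, carrying velocities),
#'   `log` (tibble: step, temperature, energy terms), `frames` (list of
#'   snapshots with `pos`, `dir`, `step`).
#' @export
run_nvt <- function(system, n_steps, thermostat = TRUE,
                    log_stride = 200, snap_stride = 0, seed = NULL,
                    warmup = 0, freeze_proteins = FALSE) {
  if (n_steps < 0) abort("`n_steps` must be >= 0.")
  if (warmup > 0) {
    s1 <- system
    s1$config$dt <- system$config$dt / 5
    s1$config$temperature <- system$config$temperature / 2
    w1 <- run_nvt(s1, floor(warmup / 2), thermostat = TRUE,
                  log_stride = max(log_stride, 1), seed = seed)
    s2 <- w1$system
    s2$config <- system$config
    s2$config$dt <- system$config$dt / 2
    w2 <- run_nvt(s2, ceiling(warmup / 2), thermostat = TRUE,
                  log_stride = max(log_stride, 1))
    prod_config <- system$config
    system <- w2$system
    system$config <- prod_config
    seed <- NULL # velocities carried over from the warmup
  }
  cfg <- system$config
  if (!is.null(seed)) cfg$seed <- seed
  state <- as_sim_state(system)
  init_vel <- is.null(system$vel)
  if (n_steps == 0) {
    return(structure(list(system = system,
                          log = tibble(step = 0L),
                          frames = list()), class = "cg_trajectory"))
  }
  out <- run_nvt_cpp(state, as.integer(n_steps), cfg$dt, cfg$temperature,
                     cfg$thermostat_tau, as.integer(cfg$seed),
                     isTRUE(thermostat), as.integer(log_stride),
                     as.integer(snap_stride), init_vel, isTRUE(freeze_proteins))
  if (isTRUE(out$diverged)) {
    abort(paste0(out$divergence_message,
                 "; diagnostic frame retained in the condition data."),
          class = "enthcg_divergence")
  }
  nl <- state$n_lip
  sys2 <- system
  if (nl > 0) {
    sys2$lipids$x <- out$pos[seq_len(nl), 1]
    sys2$lipids$y <- out$pos[seq_len(nl), 2]
    sys2$lipids$z <- out$pos[seq_len(nl), 3]
    sys2$lipids$ux <- out$dir[, 1]; sys2$lipids$uy <- out$dir[, 2]; sys2$lipids$uz <- out$dir[, 3]
  }
  if (!is.null(system$proteins)) {
    np <- nrow(system$proteins)
    sys2$proteins$x <- out$pos[nl + seq_len(np), 1]
    sys2$proteins$y <- out$pos[nl + seq_len(np), 2]
    sys2$proteins$z <- out$pos[nl + seq_len(np), 3]
  }
  sys2$vel <- out$vel
  sys2$ang <- out$ang
  log <- as_tibble(as.data.frame(out$log))
  names(log) <- c("step", "temperature", "e_gb", "e_protein_lipid",
                  "e_protein_protein", "e_spring", "e_kinetic", "e_total")
  frames <- lapply(seq_along(out$snap_steps), function(i) {
    list(pos = out$snap_pos[[i]],
         dir = if (nl > 0) out$snap_dir[[i]] else NULL,
         step = out$snap_steps[i])
  })
  structure(list(system = sys2, log = log, frames = frames),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf("CG trajectory: %d logged points, %d snapshots\n",
              n, length(x$frames)))
  if (n > 1) {
    cat(sprintf("  final T = %.1f K, E_total = %.2f kcal/mol\n",
                x$log$temperature[n], x$log$e_total[n]))
  }
  invisible(x)
}

#' Mean kinetic temperature over a trailing window
#' @param trajectory A `cg_trajectory`.
#' @param window Fraction of the log to average over (from the end).
#' @return Mean temperature, K.
#' @export
mean_temperature <- function(trajectory, window = 0.5) {
  lg <- trajectory$log[-1, ] # drop the t=0 row
  k <- max(1, floor(nrow(lg) * (1 - window)))
  mean(lg$temperature[k:nrow(lg)])
}

## ---- snapshot export -------------------------------------------------------

#' Write a CG system snapshot as PDB
#'
#' One pseudo-atom per CG site; each lipid gets a second record marking its
#' head-to-tail director tip.  The `write_order_pdb()` variant stores a
#' local-order value in the B-factor column for coloring.
#'
#' @param system A [cg_system()]. @param path Output file.
#' @param order Optional per-domain order values for the B-factor column.
#' @return `path`, invisibly.
#' @export
write_snapshot_pdb <- function(system, path, order = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  at <- 0L
  fmt <- "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f"
  if (!is.null(system$lipids)) {
    for (i in seq_len(nrow(system$lipids))) {
      l <- system$lipids[i, ]
      at <- at + 1L
      writeLines(sprintf(fmt, at %% 100000L, "C", if (l$is_pip2) "PIP" else "LIP",
                         "L", i %% 10000L, l$x * 10, l$y * 10, l$z * 10, 1, 0), con)
      at <- at + 1L
      writeLines(sprintf(fmt, at %% 100000L, "D", if (l$is_pip2) "PIP" else "LIP",
                         "L", i %% 10000L, (l$x + 0.5 * l$ux) * 10,
                         (l$y + 0.5 * l$uy) * 10, (l$z + 0.5 * l$uz) * 10, 1, 0), con)
    }
  }
  if (!is.null(system$proteins)) {
    bf <- rep(0, nrow(system$proteins))
    if (!is.null(order)) bf <- order[match(system$proteins$domain, seq_along(order))]
    for (i in seq_len(nrow(system$proteins))) {
      p <- system$proteins[i, ]
      at <- at + 1L
      writeLines(sprintf(fmt, at %% 100000L, "P", "ENT", "P",
                         p$domain %% 10000L, p$x * 10, p$y * 10, p$z * 10, 1,
                         min(max(bf[i], -9.99), 99.99)), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Write the thermodynamic log as CSV
#' @param trajectory A `cg_trajectory`. @param path Output file.
#' @export
write_thermo_csv <- function(trajectory, path) {
  utils::write.csv(trajectory$log, path, row.names = FALSE)
  invisible(path)
}

#' Calibrate the per-pair site-membrane epsilon
#'
#' Computes the adhesion-energy profile of a single protein site approached
#' toward a frozen flat fixture leaflet (lattice at the fixture area per
#' lipid), per unit per-pair LJ epsilon, and returns the scaling that turns
#' a requested site-membrane well depth into the per-pair value.  The
#' package ships the frozen results as `PL_EPS_PER_WELL`.
#'
#' @param sigma_pl Protein-lipid contact length, nm.
#' @param params,area_per_lipid Fixture lipid parameters.
#' @return A list with the profile (tibble `z`, `energy`), the adhesion
#'   depth per unit epsilon, and `eps_per_kcal` (per-pair epsilon per
#'   kcal/mol of desired well depth).
#' @export
calibrate_site_membrane_eps <- function(sigma_pl, params = gb_params(),
                                        area_per_lipid = 0.75) {
  s <- sqrt(area_per_lipid)
  nn <- 9L
  grid <- expand.grid(ix = -nn:nn, iy = -nn:nn)
  lx <- grid$ix * s; ly <- grid$iy * s
  half <- lipid_length(params) / 2
  rcut <- 2.5; rsw <- 2.0
  lj <- function(r) {
    u <- 4 * ((sigma_pl / r)^12 - (sigma_pl / r)^6)
    t <- pmin(pmax((r - rsw) / (rcut - rsw), 0), 1)
    S <- 1 - t^3 * (10 - 15 * t + 6 * t^2)
    ifelse(r >= rcut, 0, u * S)
  }
  zs <- seq(-0.8, 3.5, by = 0.005)
  prof <- vapply(zs, function(z) {
    ## lipid centers at z = -half relative to the head shell plane (z = 0)
    r <- sqrt((z + half)^2 + lx^2 + ly^2)
    sum(lj(r))
  }, 0)
  depth <- -min(prof)
  list(profile = tibble(z = zs, energy = prof),
       depth_per_eps = depth, eps_per_kcal = 1 / depth)
}
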