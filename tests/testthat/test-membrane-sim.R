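normalize_ <- function(v) v / sqrt(sum(v^2))

test_that("Gay-Berne pair energy is symmetric, truncated and has the
           configured well anisotropy", {
  p <- gb_params()
  ## beyond the maximum range: exactly zero
  far <- p$sigma0 * (p$aspect_ratio - 1 + p$cutoff) + 1e-6
  expect_identical(as.numeric(
    gb_pair_energy(c(0, 0, 0), c(far, 0, 0), c(0, 0, 1), c(0, 0, 1), p)), 0)
  ## swapping particle labels leaves the energy unchanged
  set.seed(1)
  for (i in 1:5) {
    xi <- rnorm(3); xj <- xi + normalize_(rnorm(3)) * runif(1, 0.9, 2.5)
    ui <- normalize_(rnorm(3)); uj <- normalize_(rnorm(3))
    expect_equal(as.numeric(gb_pair_energy(xi, xj, ui, uj, p)),
                 as.numeric(gb_pair_energy(xj, xi, uj, ui, p)), tolerance = 1e-12)
  }
  ## side-by-side parallel minimum deeper than end-to-end by kappa'
  ## (with the truncation pushed out so the bare form is probed)
  pw <- gb_params(cutoff = 6, switch_on = 5.5)
  ss <- optimize(function(r) as.numeric(
    gb_pair_energy(c(0, 0, 0), c(r, 0, 0), c(0, 0, 1), c(0, 0, 1), pw)),
    c(0.6, 2))
  ee <- optimize(function(r) as.numeric(
    gb_pair_energy(c(0, 0, 0), c(0, 0, r), c(0, 0, 1), c(0, 0, 1), pw)),
    c(2, 3.4))
  expect_equal(ss$objective / ee$objective, pw$well_anisotropy, tolerance = 0.01)
  expect_error(gb_pair_energy(c(0, 0, 0), c(0, 0, 0), c(0, 0, 1), c(0, 0, 1), p),
               "overlap|Zero")
})

test_that("pair forces are the negative analytic gradient of the energy", {
  p <- gb_params()
  gbp <- enthcg:::gb_pair_cpp
  set.seed(4)
  worst_f <- 0; worst_g <- 0
  for (i in 1:12) {
    xi <- rnorm(3); xj <- xi + normalize_(rnorm(3)) * runif(1, 0.95, 3.2)
    ui <- normalize_(rnorm(3)); uj <- normalize_(rnorm(3))
    e <- gb_pair_energy(xi, xj, ui, uj, p)
    if (abs(as.numeric(e)) > 100) next # skip the clamped hard core
    h <- 1e-6
    for (k in 1:3) {
      d <- numeric(3); d[k] <- h
      fd <- (as.numeric(gb_pair_energy(xi + d, xj, ui, uj, p)) -
               as.numeric(gb_pair_energy(xi - d, xj, ui, uj, p))) / (2 * h)
      worst_f <- max(worst_f, abs(attr(e, "force_i")[k] + fd) / max(1, abs(fd)))
      gd <- (gbp(xi, xj, ui + d, uj, p)$energy -
               gbp(xi, xj, ui - d, uj, p)$energy) / (2 * h)
      worst_g <- max(worst_g, abs(attr(e, "du_i")[k] - gd) / max(1, abs(gd)))
    }
  }
  expect_lt(worst_f, 1e-5)
  expect_lt(worst_g, 1e-5)
})

test_that("builders count lipids and assign PIP2 and directors correctly", {
  sys <- build_bilayer(8, 8, seed = 2)
  expect_equal(nrow(sys$lipids), 128L)
  expect_equal(sum(sys$lipids$is_pip2), round(0.10 * 128))
  top <- sys$lipids$z > mean(sys$lipids$z)
  expect_true(all(sys$lipids$uz[top] == -1))
  expect_true(all(sys$lipids$uz[!top] == 1))

  ## tube: leaflet counts follow the cylinder area ratio
  params <- gb_params()
  tube <- build_tube(16, 10, periodic = TRUE, seed = 3)
  rad <- sqrt(tube$lipids$x^2 + tube$lipids$y^2)
  loff <- enthcg:::leaflet_offset(params)
  n_out <- sum(rad > 8); n_in <- sum(rad < 8)
  expect_equal(n_out / n_in, (8 + loff) / (8 - loff), tolerance = 0.02)
  ## directors radial, heads outward/inward
  urad <- (tube$lipids$ux * tube$lipids$x + tube$lipids$uy * tube$lipids$y) / rad
  expect_true(all(abs(abs(urad) - 1) < 1e-9))
  expect_true(all(urad[rad > 8] < 0) && all(urad[rad < 8] > 0))
  expect_error(build_tube(16, 10, periodic = TRUE, box = c(30, 30, 12)),
               "match")
  expect_error(build_tube(16, 10, periodic = TRUE, capped = TRUE), "one of")

  ## vesicle: leaflet counts follow the sphere area ratio
  ves <- build_vesicle(16, seed = 4)
  ctr <- ves$box / 2
  rv <- sqrt((ves$lipids$x - ctr[1])^2 + (ves$lipids$y - ctr[2])^2 +
               (ves$lipids$z - ctr[3])^2)
  n_in <- sum(rv < 8); n_out <- sum(rv > 8)
  expect_equal(n_in / n_out, ((8 - loff) / (8 + loff))^2, tolerance = 0.02)
  ## every lipid within a lipid length of its leaflet radius
  expect_true(all(abs(rv - 8) < enthcg:::lipid_length(params)))
})

test_that("reference-scale builders hit the published lipid counts within 10%", {
  ## calibrated fixture area per lipid, 16-nm x 50-nm tube and 50-nm vesicle
  tube <- build_tube(16, 50, periodic = TRUE, seed = 1)
  expect_lt(abs(nrow(tube$lipids) - 6510) / 6510, 0.10)
  ves <- build_vesicle(50, seed = 1)
  expect_lt(abs(nrow(ves$lipids) - 20998) / 20998, 0.10)
})

test_that("energy decomposition sums to the total and empty systems are zero", {
  expect_equal(total_energy(cg_system())$energy, rep(0, 5))
  sys <- build_bilayer(6, 6, seed = 1)
  e <- total_energy(sys)
  expect_equal(sum(e$energy[1:4]), e$energy[5], tolerance = 1e-9)
  ## single protein at its reference geometry: zero spring energy
  topo <- build_enth16()
  pro <- apply_placements(topo, enthcg:::new_placements(
    list(diag(3)), list(c(10, 10, 25))))
  psys <- cg_system(proteins = pro, topology = topo, box = c(20, 20, 50))
  e2 <- total_energy(psys)
  expect_equal(e2$energy[e2$term == "spring"], 0, tolerance = 1e-9)
})

test_that("two H0 sites of different domains at contact give the printed
           2 kcal/mol well", {
  topo <- build_enth16()
  ## generic background switched off so the probe isolates the H0 channel
  ints <- default_interactions(generic_protein = 0)
  sigma <- ints$pp_sigma[2, 3]
  rmin <- 2^(1 / 6) * sigma
  ## end-on arrangement: domain B displaced along the H0 axis so B's site 1
  ## sits at the LJ minimum from A's site 2; every other cross pair is in
  ## a weak tail or beyond its excluded-volume reach
  d <- 0.8 + rmin
  near <- apply_placements(topo, enthcg:::new_placements(
    list(diag(3), diag(3)), list(c(0, 0, 0), c(d, 0, 0))))
  far <- apply_placements(topo, enthcg:::new_placements(
    list(diag(3), diag(3)), list(c(0, 0, 0), c(30, 0, 0))))
  box <- c(100, 100, 100)
  e_near <- total_energy(cg_system(proteins = near, topology = topo,
                                   interactions = ints, box = box))
  e_far <- total_energy(cg_system(proteins = far, topology = topo,
                                  interactions = ints, box = box))
  pp <- e_near$energy[3] - e_far$energy[3]
  ## the tabulated channel itself: switched 12-6 at its minimum is the
  ## printed -2 kcal/mol (the switch is unity there)
  lj_min <- 4 * ints$pp_eps[2, 3] * ((sigma / rmin)^12 - (sigma / rmin)^6)
  expect_equal(lj_min, -2)
  ## and it dominates the measured cross-domain energy; the residual is a
  ## grazing R114 excluded-volume contact plus a faint patch tail
  expect_lt(abs(pp - (-2)), 0.5)
})

test_that("NVE dynamics conserve energy and momentum; NVT holds 300 K", {
  sys <- build_bilayer(8, 8, seed = 5)
  nve <- run_nvt(sys, 10000, thermostat = FALSE, log_stride = 500, seed = 9)
  drift <- diff(range(nve$log$e_total)) / abs(mean(nve$log$e_total))
  expect_lt(drift, 2e-4) # < 0.02%
  ## momentum conserved to machine precision (masses all equal)
  ptot <- colSums(nve$system$vel)
  expect_lt(max(abs(ptot)), 1e-8)

  nvt <- run_nvt(sys, 20000, log_stride = 500, seed = 9)
  expect_lt(abs(mean_temperature(nvt) - 300) / 300, 0.03)

  ## n_steps = 0 returns the system unchanged
  same <- run_nvt(sys, 0)
  expect_identical(same$system$lipids, sys$lipids)
})

test_that("a flat fixture bilayer stays intact at 300 K", {
  ## scaled-down integrity check; the acceptance suite runs the long one
  sys <- build_bilayer(10, 10, seed = 3)
  tr <- run_nvt(sys, 30000, log_stride = 2000, seed = 13)
  z0 <- mean(tr$system$lipids$z)
  expect_lt(max(abs(tr$system$lipids$z - z0)),
            2 * enthcg:::lipid_length(gb_params()))
  ## directors still near the membrane normal
  expect_gt(mean(abs(tr$system$lipids$uz)), 0.9)
})

test_that("seeded runs are reproducible and divergence is reported", {
  sys <- build_bilayer(6, 6, seed = 1)
  t1 <- run_nvt(sys, 500, log_stride = 100, seed = 3)
  t2 <- run_nvt(sys, 500, log_stride = 100, seed = 3)
  expect_identical(t1$log$e_total, t2$log$e_total)
  t3 <- run_nvt(sys, 500, log_stride = 100, seed = 4)
  expect_false(identical(t1$log$e_total, t3$log$e_total))

  ## overlapping lipids -> energy divergence abort with diagnostics
  bad <- sys
  bad$lipids$x[2] <- bad$lipids$x[1] + 1e-4
  bad$lipids$y[2] <- bad$lipids$y[1]
  bad$lipids$z[2] <- bad$lipids$z[1]
  expect_error(run_nvt(bad, 100, seed = 1), "divergence|overlap|Zero")
})

test_that("snapshots and logs are exportable as text", {
  sys <- build_bilayer(4, 4, seed = 1)
  tr <- run_nvt(sys, 200, log_stride = 100, snap_stride = 100, seed = 2)
  pdb <- tempfile(fileext = ".pdb")
  write_snapshot_pdb(tr$system, pdb)
  lines <- readLines(pdb)
  expect_gt(sum(grepl("^ATOM", lines)), 32)
  csv <- tempfile(fileext = ".csv")
  write_thermo_csv(tr, csv)
  expect_equal(nrow(utils::read.csv(csv)), nrow(tr$log))
})
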