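test_that("the restraint-built dimer reproduces the interlabel distances", {
  dimer <- build_h0_dimer()
  ## two-fold symmetry: H0 axes exactly antiparallel
  ax <- placement_h0_axes(dimer)
  expect_equal(sum(ax[1, ] * ax[2, ]), -1, tolerance = 1e-9)

  r10 <- measure_anchor_distance(dimer, 10)
  r6 <- measure_anchor_distance(dimer, 6)
  r5 <- measure_anchor_distance(dimer, 5)
  r4 <- measure_anchor_distance(dimer, 4)
  expect_equal(r10, 13, tolerance = 0.08) # within 1 Angstrom
  expect_equal(r6, 13, tolerance = 0.08)
  expect_equal(r5, 9, tolerance = 0.12)
  expect_equal(r4, 21, tolerance = 0.08)
  ## residue 5 shortest, residue 4 largest of the restrained set
  expect_lt(r5, min(r6, r10, r4))
  expect_gt(r4, max(r5, r6, r10))

  ## infeasible restraints are rejected with residual reporting
  bad <- default_restraints()
  bad$center[bad$residue == 6] <- 40
  expect_error(build_h0_dimer(restraints = bad), "residual")
})

test_that("the offset tetramer satisfies the cross-dimer restraints and the
           patch contact", {
  tet <- build_tetramer(build_h0_dimer())
  expect_equal(measure_anchor_distance(tet, 13, "inter_dimer"), 15,
               tolerance = 0.1) # within 1.5 Angstrom
  expect_equal(measure_anchor_distance(tet, 14, "inter_dimer"), 10,
               tolerance = 0.15)
  expect_lte(tet$patch_distance, 1.2 * 0.85)
  ## the second dimer is a pure translation of the first
  expect_equal(tet$placements[[3]]$R, tet$placements[[1]]$R)
})

test_that("anchor measurement is rigid-motion invariant (independent check)", {
  dimer <- build_h0_dimer()
  set.seed(9)
  R <- enthcg:::random_rotation()
  t <- rnorm(3, 0, 5)
  moved <- dimer
  moved$placements <- structure(purrr::map(dimer$placements, function(p) {
    list(R = R %*% p$R, t = as.numeric(R %*% p$t) + t)
  }), class = "placement_set")
  for (res in c(4, 5, 6, 10)) {
    expect_equal(measure_anchor_distance(moved, res),
                 measure_anchor_distance(dimer, res), tolerance = 1e-9)
  }
})

test_that("tube coats tile without clashes, aligned with the tube axis", {
  tube <- build_tube(16, 7 * 1.647407, periodic = TRUE, seed = 7)
  sys <- coat_tube(tube)
  nd <- attr(sys, "n_domains")
  ## 16 sites per placed domain (192 domains would give 3072 sites)
  expect_equal(nrow(sys$proteins), 16L * nd)
  ## all H0 axes within 5 degrees of the tube axis at construction
  ax <- domain_axes(sys)
  expect_true(all(abs(ax$uz) > cos(5 * pi / 180)))
  ## construction contract: initial global order >= 0.98
  expect_gte(attr(sys, "initial_order"), 0.98)
  ## overlap validation passed inside coat_tube (would have errored);
  ## verify independently on a sample
  lx <- as.matrix(sys$lipids[c("x", "y", "z")])
  px <- as.matrix(sys$proteins[c("x", "y", "z")])
  idx <- seq(1, nrow(px), by = 7)
  mind <- min(vapply(idx, function(i) {
    sqrt(min((lx[, 1] - px[i, 1])^2 + (lx[, 2] - px[i, 2])^2 +
               (lx[, 3] - px[i, 3])^2))
  }, 0))
  expect_gt(mind, 0.5 * 0.8)
})

test_that("coating is equivariant under rotation about the tube axis", {
  tube <- build_tube(16, 7 * 1.647407, periodic = TRUE, seed = 7)
  th <- 0.7
  Rz <- enthcg:::rot_z(th)
  tube_rot <- tube
  xy <- as.matrix(tube$lipids[c("x", "y", "z")]) %*% t(Rz)
  uxy <- as.matrix(tube$lipids[c("ux", "uy", "uz")]) %*% t(Rz)
  tube_rot$lipids$x <- xy[, 1]; tube_rot$lipids$y <- xy[, 2]; tube_rot$lipids$z <- xy[, 3]
  tube_rot$lipids$ux <- uxy[, 1]; tube_rot$lipids$uy <- uxy[, 2]; tube_rot$lipids$uz <- uxy[, 3]
  coat_then_rot <- as.matrix(coat_tube(tube)$proteins[c("x", "y", "z")]) %*% t(Rz)
  rot_then_coat <- as.matrix(coat_tube(tube_rot)$proteins[c("x", "y", "z")])
  expect_equal(rot_then_coat, coat_then_rot, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("vesicle scattering is seeded, respects the standoff and scales to
           the reference count", {
  ves <- build_vesicle(16, seed = 5)
  s1 <- scatter_vesicle(ves, 20, seed = 3)
  s2 <- scatter_vesicle(ves, 20, seed = 3)
  expect_identical(s1$proteins, s2$proteins)
  s3 <- scatter_vesicle(ves, 20, seed = 4)
  expect_false(identical(s1$proteins, s3$proteins))

  ## H0 sites sit 0.5 nm above the outer headgroup shell
  ctr <- ves$box / 2
  params <- ves$params
  half <- enthcg:::lipid_length(params) / 2
  rad <- sqrt((ves$lipids$x - ctr[1])^2 + (ves$lipids$y - ctr[2])^2 +
                (ves$lipids$z - ctr[3])^2)
  shell <- max(rad) + half
  h0 <- s1$proteins[s1$proteins$role %in% c("H0_A", "H0_B"), ]
  rh <- sqrt((h0$x - ctr[1])^2 + (h0$y - ctr[2])^2 + (h0$z - ctr[3])^2)
  expect_equal(mean(rh), shell + 0.5, tolerance = 0.02)

  ## an impossible density hits the retry cap with advice
  expect_error(scatter_vesicle(ves, 5000, seed = 1), "retry cap")
})

test_that("the 50-nm vesicle accommodates the full published domain count", {
  ves <- build_vesicle(50, seed = 2)
  sys <- scatter_vesicle(ves, 441, seed = 6)
  expect_equal(length(unique(sys$proteins$domain)), 441L)
})

test_that("dimer scattering places rigid dimers preserving internal geometry", {
  ves <- build_vesicle(16, seed = 5)
  dimer <- build_h0_dimer()
  sys <- dimer_scatter_vesicle(ves, 6, seed = 3, dimer = dimer)
  expect_equal(length(unique(sys$proteins$domain)), 12L)
  ## all intra-pair site distances match the source dimer (rigid transform)
  ref <- apply_placements(dimer$topology, dimer$placements)
  refd <- as.matrix(dist(as.matrix(ref[c("x", "y", "z")])))
  for (k in 1:3) {
    pair <- sys$proteins[sys$proteins$domain %in% c(2 * k - 1, 2 * k), ]
    dd <- as.matrix(dist(as.matrix(pair[c("x", "y", "z")])))
    expect_equal(dd, refd, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("placements survive a JSON round trip", {
  dimer <- build_h0_dimer()
  path <- tempfile(fileext = ".json")
  write_placements(dimer$placements, path)
  back <- read_placements(path)
  expect_equal(back[[1]]$R, dimer$placements[[1]]$R, tolerance = 1e-12)
  expect_equal(back[[2]]$t, dimer$placements[[2]]$t, tolerance = 1e-12)
})
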