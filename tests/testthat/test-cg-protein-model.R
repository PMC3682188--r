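test_that("EDCG places the boundary at the hinge of two rigid blocks", {
  frames <- two_block_frames(n_frames = 300, n_per_block = 10)
  part <- edcg_partition(frames, n_sites = 2, n_modes = 1)
  expect_equal(attr(part, "boundaries"), c(1L, 11L))

  ## oracle: exhaustive search over all 19 single-boundary partitions with
  ## an independent residual implementation
  res <- vapply(2:20, function(b) {
    oracle_edcg_residual(frames, c(1L, b), n_modes = 1)
  }, 0)
  expect_equal(which.min(res) + 1L, 11L)
  ## and the optimal residual agrees with the oracle's
  expect_equal(attr(part, "residual"), min(res), tolerance = 1e-6)
})

test_that("EDCG residual behaves at the partition extremes", {
  sp <- chain_spec(8, k = 2)
  frames <- gen_enm_trajectory(sp, 400, seed = 3)
  ## finest partition: singleton segments, zero residual
  fine <- edcg_partition(frames, n_sites = 8)
  expect_equal(attr(fine, "residual"), 0, tolerance = 1e-12)
  expect_true(all(fine$from == fine$to))
  ## single segment: residual equals the total essential-subspace variance
  ## about the chain center of geometry (independent computation)
  one <- edcg_partition(frames, n_sites = 1, n_modes = 3)
  expect_equal(attr(one, "residual"),
               oracle_edcg_residual(frames, 1L, n_modes = 3),
               tolerance = 1e-6)
  ## residual is non-increasing in n_sites
  res <- vapply(1:6, function(k) attr(edcg_partition(frames, k), "residual"), 0)
  expect_true(all(diff(res) <= 1e-12))
  expect_error(edcg_partition(frames, 9), "exceeds")
})

test_that("site mapping is the per-segment center of geometry", {
  frames <- gen_enm_trajectory(chain_spec(6), 50, seed = 2)
  part <- edcg_partition(frames, n_sites = 6)
  expect_equal(map_to_sites(frames, part)[, , ], frames[, , ],
               ignore_attr = TRUE)
  part2 <- tibble::tibble(site = 1:3, from = c(1L, 3L, 5L), to = c(2L, 4L, 6L))
  mapped <- map_to_sites(frames, part2)
  expect_equal(mapped[, 1, ], (frames[, 1, ] + frames[, 2, ]) / 2)
  ## mapped variance never exceeds the residue-level variance of a segment
  v_map <- sum(apply(mapped[, 1, ], 2, var))
  v_res <- mean(c(sum(apply(frames[, 1, ], 2, var)),
                  sum(apply(frames[, 2, ], 2, var))))
  expect_lte(v_map, v_res + 1e-12)
})

test_that("heteroENM recovers homogeneous spring constants within 5%", {
  sp <- chain_spec(8, k = 10, spacing = 0.9)
  springs_full <- within(expand.grid(i = 1:8, j = 1:8), NULL)
  ## targets from the analytic ENM variances (independent oracle)
  C <- oracle_enm_covariance(sp$coords, as.data.frame(sp$springs))
  nn <- nrow(sp$coords)
  pairs <- subset(expand.grid(i = 1:nn, j = 1:nn), i < j)
  d0 <- sqrt(rowSums((sp$coords[pairs$j, ] - sp$coords[pairs$i, ])^2))
  keep <- d0 <= 1.0 # bonded pairs only (matches the generating topology)
  pairs <- pairs[keep, ]
  tvar <- vapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs$i[r]; j <- pairs$j[r]
    b <- (sp$coords[j, ] - sp$coords[i, ]); b <- b / sqrt(sum(b^2))
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    as.numeric(t(b) %*% (C[ii, ii] + C[jj, jj] - 2 * C[ii, jj]) %*% b)
  }, 0)
  fit <- heteroenm_fit(list(coords = sp$coords,
                            targets = data.frame(pairs, var = tvar)),
                       tolerance = 1e-3, k0 = 3)
  expect_true(attr(fit, "converged"))
  expect_true(all(abs(fit$k - 10) / 10 < 0.05))
})

test_that("heteroENM resolves a two-block stiffness contrast", {
  ## chain with soft half (k = 5) and stiff half (k = 50)
  n <- 10
  ktrue <- c(rep(5, 4), rep(50, 5))
  coords <- cbind((0:(n - 1)) * 0.9, 0, 0)
  springs <- data.frame(i = 1:(n - 1), j = 2:n, k = ktrue)
  C <- oracle_enm_covariance(coords, springs)
  tvar <- vapply(1:(n - 1), function(i) {
    b <- c(1, 0, 0)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * i + 1):(3 * i + 3)
    as.numeric(t(b) %*% (C[ii, ii] + C[jj, jj] - 2 * C[ii, jj]) %*% b)
  }, 0)
  fit <- heteroenm_fit(list(coords = coords,
                            targets = data.frame(i = 1:(n - 1), j = 2:n, var = tvar)),
                       tolerance = 5e-4, k0 = 10, max_iter = 400)
  ratio <- mean(fit$k[6:9]) / mean(fit$k[1:4])
  expect_lt(abs(ratio - 10) / 10, 0.10)
  ## mismatch decreases monotonically over accepted iterations
  trace <- attr(fit, "mismatch_trace")
  expect_true(all(diff(trace) < 1e-9))
})

test_that("heteroENM respects tolerance = Inf and rejects bad targets", {
  coords <- cbind(0:3, 0, 0)
  tg <- data.frame(i = 1:3, j = 2:4, var = c(0.01, 0.01, 0.01))
  fit <- heteroenm_fit(list(coords = coords, targets = tg),
                       tolerance = Inf, k0 = 7)
  expect_equal(unique(fit$k), 7)
  expect_equal(attr(fit, "iterations"), 0L)
  tg$var[2] <- 0
  expect_error(heteroenm_fit(list(coords = coords, targets = tg)), "positive")
})

test_that("the 16-site topology carries the published role assignment", {
  topo <- build_enth16()
  expect_equal(nrow(topo$sites), 16L)
  expect_equal(topo$sites$role[1], "H0_A")
  expect_equal(topo$sites$role[2], "H0_B")
  expect_equal(topo$sites$role[5], "hydrophobic_patch")
  expect_equal(topo$sites$role[10], "R114_loop")
  expect_equal(sum(topo$sites$role == "PIP2_pocket"), 1L)
  expect_setequal(topo$label_anchors$residue, c(4, 5, 6, 10, 13, 14))
  ## anchors live on the H0 sites with nitroxide-scale offsets
  off <- sqrt(topo$label_anchors$ox^2 + topo$label_anchors$oy^2 +
                topo$label_anchors$oz^2)
  expect_true(all(off > 0.3 & off < 1.0))

  expect_error(build_enth16(matrix(0, 15, 3)), "16")
  bad_springs <- tibble::tibble(i = 1, j = 17, k = 1, r0 = 1)
  expect_error(build_enth16(springs = bad_springs), "1..16")
})

test_that("topology survives a JSON round trip", {
  topo <- build_enth16()
  path <- tempfile(fileext = ".json")
  write_topology(topo, path)
  back <- read_topology(path)
  expect_equal(back$sites$x, topo$sites$x)
  expect_equal(back$springs$k, topo$springs$k)
  expect_equal(back$label_anchors$oz, topo$label_anchors$oz)
})

test_that("Boltzmann inversion of g(r) recovers the generating potential", {
  r <- seq(0.5, 3, by = 0.01)
  kT <- 0.0019872041 * 300
  U <- 4 * ((1 / r)^12 - (1 / r)^6)
  g <- exp(-U / kT)
  pmf <- pmf_from_rdf(data.frame(r = r, g = g), temperature = 300)
  ## identity up to the additive shift (U at the last grid point), on the
  ## unmasked support (deep-core bins underflow g to 0 and are masked)
  ok <- !pmf$masked
  expect_lt(max(abs(pmf$pmf[ok] - (U[ok] - U[length(U)]))), 1e-10)

  ## g == 1 -> flat PMF
  flat <- pmf_from_rdf(data.frame(r = r, g = rep(1, length(r))))
  expect_true(all(flat$pmf == 0))

  ## masked zero bins; all-zero input rejected
  g2 <- g; g2[1:5] <- 0
  pmf2 <- pmf_from_rdf(data.frame(r = r, g = g2))
  expect_true(all(is.na(pmf2$pmf[1:5])) && all(pmf2$masked[1:5]))
  expect_error(pmf_from_rdf(data.frame(r = r, g = 0)), "zero")
})

test_that("a 1.2 kcal/mol well in g(r) yields the R114 PMF magnitude", {
  ## construct g from a PMF whose minimum is -1.2 kcal/mol, invert, check
  r <- seq(0.2, 2.5, by = 0.005)
  kT <- 0.0019872041 * 300
  U <- 4 * 1.2 * ((0.35 / r)^12 - (0.35 / r)^6) # eps = 1.2 -> min = -1.2
  pmf <- pmf_from_rdf(data.frame(r = r, g = exp(-U / kT)), temperature = 300)
  expect_equal(min(pmf$pmf, na.rm = TRUE), -1.2, tolerance = 3e-3)
})
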