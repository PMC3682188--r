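## small helper: a synthetic field of domains on a line with given axes
axes_tbl <- function(pos, axes) {
  tibble::tibble(domain = seq_len(nrow(pos)),
                 x = pos[, 1], y = pos[, 2], z = pos[, 3],
                 ux = axes[, 1], uy = axes[, 2], uz = axes[, 3])
}

test_that("h0_axis is the unit site-1 to site-2 vector with the right equivariance", {
  m <- matrix(0, 16, 3)
  m[2, ] <- c(2, 0, 0)
  expect_equal(h0_axis(m), c(1, 0, 0))
  ## translation invariance
  expect_equal(h0_axis(sweep(m, 2, c(5, -3, 2), "+")), c(1, 0, 0))
  ## rotation equivariance on random rotations
  set.seed(1)
  for (i in 1:5) {
    R <- enthcg:::random_rotation()
    expect_equal(h0_axis(m %*% t(R)), as.numeric(R %*% c(1, 0, 0)),
                 tolerance = 1e-12)
  }
  expect_error(h0_axis(matrix(0, 16, 3)), "coincident")
})

test_that("local order is 1 for aligned or antiparallel axes and handles isolation", {
  pos <- cbind(seq_len(6), 0, 0)
  aligned <- matrix(rep(c(0, 0, 1), 6), ncol = 3, byrow = TRUE)
  f <- local_order(axes_tbl(pos, aligned), cutoff = 2)
  expect_true(all(f$s == 1))
  expect_equal(global_order(f), 1)
  ## unsigned: antiparallel pair still perfectly ordered
  anti <- rbind(c(0, 0, 1), c(0, 0, -1))
  f2 <- local_order(axes_tbl(cbind(0:1, 0, 0), anti), cutoff = 5)
  expect_equal(f2$s, c(1, 1))
  ## isolated domain: sentinel NA, excluded from the global mean
  pos3 <- rbind(cbind(0:1, 0, 0), c(100, 0, 0))
  f3 <- local_order(axes_tbl(pos3, matrix(rep(c(0, 0, 1), 3), ncol = 3, byrow = TRUE)),
                    cutoff = 5)
  expect_true(is.na(f3$s[3]))
  expect_equal(global_order(f3), 1)
})

test_that("isotropic axes give mean order 1/2 (E|cos| for random axes)", {
  set.seed(7)
  n <- 3000
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  f <- local_order(axes_tbl(matrix(runif(3 * n, 0, 10), ncol = 3), u),
                   cutoff = Inf, method = "brute")
  expect_equal(global_order(f), 0.5, tolerance = 0.01)
})

test_that("cell-list and brute-force neighbor searches agree exactly", {
  set.seed(3)
  n <- 400
  pos <- matrix(runif(3 * n, 0, 30), ncol = 3)
  u <- matrix(rnorm(3 * n), ncol = 3); u <- u / sqrt(rowSums(u^2))
  tb <- axes_tbl(pos, u)
  f_cell <- local_order(tb, cutoff = 5, method = "cell")
  f_brute <- local_order(tb, cutoff = 5, method = "brute")
  expect_identical(f_cell$n_neighbors, f_brute$n_neighbors)
  expect_equal(f_cell$s, f_brute$s)
})

test_that("local order is invariant under global rotation and axis flips", {
  set.seed(5)
  n <- 60
  pos <- matrix(runif(3 * n, 0, 12), ncol = 3)
  u <- matrix(rnorm(3 * n), ncol = 3); u <- u / sqrt(rowSums(u^2))
  f0 <- local_order(axes_tbl(pos, u), cutoff = 4)
  R <- enthcg:::random_rotation()
  f_rot <- local_order(axes_tbl(pos %*% t(R), u %*% t(R)), cutoff = 4)
  expect_equal(f_rot$s, f0$s, tolerance = 1e-10)
  flip <- sample(c(-1, 1), n, replace = TRUE)
  f_flip <- local_order(axes_tbl(pos, u * flip), cutoff = 4)
  expect_equal(f_flip$s, f0$s, tolerance = 1e-12)
})

test_that("order traces track constructed order and detect trends", {
  pos <- cbind(seq_len(20) * 0.5, 0, 0)
  mk_frame <- function(spread) {
    set.seed(50 + round(spread * 100))
    th <- rnorm(20, 0, spread)
    ph <- runif(20, 0, 2 * pi)
    u <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    pro <- tidyr::crossing(domain = 1:20, site = 1:2)
    pro$role <- ifelse(pro$site == 1, "H0_A", "H0_B")
    pro$x <- pos[pro$domain, 1] + (pro$site - 1) * u[pro$domain, 1]
    pro$y <- pos[pro$domain, 2] + (pro$site - 1) * u[pro$domain, 2]
    pro$z <- pos[pro$domain, 3] + (pro$site - 1) * u[pro$domain, 3]
    pro
  }
  ## static ordered trajectory: trace constant at 1, converged
  frames_static <- lapply(1:8, function(i) mk_frame(0))
  tr <- order_trace(frames_static)
  expect_true(all(tr$global_order == 1))
  expect_true(attr(tr, "converged"))
  ## interpolating ordered -> random decreases monotonically
  spreads <- seq(0, 1.2, length.out = 8)
  tr2 <- order_trace(lapply(spreads, mk_frame))
  expect_true(all(diff(tr2$global_order) < 0.05))
  expect_lt(tail(tr2$global_order, 1), 0.75)
})

test_that("segment means recover block structure and respect offsets", {
  pos <- cbind(0, 0, seq(0.25, 19.75, by = 0.5))
  n <- nrow(pos)
  u <- matrix(rep(c(0, 0, 1), n), ncol = 3, byrow = TRUE)
  f <- local_order(axes_tbl(pos, u), cutoff = 2)
  ## homogeneous synthetic order: paint s directly
  f$s <- rep(0.9, n)
  seg <- segment_order(f, n_segments = 4)
  expect_equal(seg$mean_order, rep(0.9, 4))
  ## two-block field: 0.95 below z = 10, 0.80 above
  f$s <- ifelse(f$z < 10, 0.95, 0.80)
  seg2 <- segment_order(f, n_segments = 4, cap_range = c(0, 20))
  expect_equal(seg2$mean_order, c(0.95, 0.95, 0.80, 0.80))
  ## half-bin offset changes only the boundary segment
  seg3 <- segment_order(f, n_segments = 4, offset_frac = 0.5, cap_range = c(0, 20))
  inner <- seg3[!is.na(seg3$mean_order) & seg3$segment %in% c(1, 3), ]
  expect_true(all(inner$mean_order %in% c(0.95, 0.80) |
                    abs(inner$mean_order - 0.875) < 0.076))
  expect_error(segment_order(f, 1), ">= 2")
})

test_that("defect identification flags the rotated domain", {
  pos <- cbind(seq_len(15) * 1.2, 0, 0)
  u <- matrix(rep(c(0, 0, 1), 15), ncol = 3, byrow = TRUE)
  u[8, ] <- c(1, 0, 0) # one domain rotated 90 degrees
  f <- local_order(axes_tbl(pos, u), cutoff = 2.5)
  def <- find_defects(f, threshold = 0.8)
  expect_true(8 %in% def$domain)
  expect_true(all(def$domain %in% c(6, 7, 8, 9, 10)))
  ## perfectly ordered field: no defects; threshold 0: empty by definition
  f2 <- local_order(axes_tbl(pos, matrix(rep(c(0, 0, 1), 15), ncol = 3, byrow = TRUE)),
                    cutoff = 2.5)
  expect_equal(nrow(find_defects(f2)), 0L)
  expect_equal(nrow(find_defects(f, threshold = 0)), 0L)
})

test_that("insertion depth uses the headgroup shell with the stated sign", {
  ## ideal cylindrical shell of lipids, protein H0 sites 0.5 nm above it
  params <- gb_params()
  half <- 1.5 * params$sigma0
  th <- seq(0, 2 * pi, length.out = 121)[-121]
  mk <- function(r, sgn) tibble::tibble(
    x = rep(r * cos(th), 3), y = rep(r * sin(th), 3),
    z = rep(c(2, 6, 10), each = length(th)),
    ux = sgn * rep(cos(th), 3), uy = sgn * rep(sin(th), 3), uz = 0,
    is_pip2 = FALSE)
  ## head shell: outer lipid centers at 8 - half so heads sit at r = 8
  lip <- dplyr::bind_rows(mk(8 - half, -1), mk(5 - half, 1))
  pro <- tidyr::crossing(domain = 1:10, site = 1:2)
  pro$role <- ifelse(pro$site == 1, "H0_A", "H0_B")
  ang <- pro$domain * 0.6
  r_site <- 8 + 0.5 # 0.5 nm above the 8-nm head shell
  pro$x <- r_site * cos(ang); pro$y <- r_site * sin(ang)
  pro$z <- 4 + 0.4 * pro$site
  sys <- cg_system(lipids = lip, proteins = pro, topology = build_enth16(),
                   params = params, box = c(40, 40, 12))
  prof <- insertion_depth_profile(sys, "cylinder")
  sh <- attr(prof, "shell")
  expect_equal(sh$radius, 8, tolerance = 0.01)
  expect_equal(attr(prof, "mean_depth"), -0.5, tolerance = 0.02)
  ## sites exactly on the shell: zero depth
  pro2 <- pro
  pro2$x <- 8 * cos(ang); pro2$y <- 8 * sin(ang)
  sys2 <- cg_system(lipids = lip, proteins = pro2, topology = build_enth16(),
                    params = params, box = c(40, 40, 12))
  expect_equal(attr(insertion_depth_profile(sys2, "cylinder"), "mean_depth"), 0,
               tolerance = 0.02)
})
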