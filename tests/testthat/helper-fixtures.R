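## Shared fixtures and independent oracles used across the test files.

## simple bead chain ENM spec
chain_spec <- function(n, k = 1, temperature = 300, spacing = 1) {
  enm_spec(cbind((seq_len(n) - 1) * spacing, 0, 0),
           data.frame(i = seq_len(n - 1), j = 2:n, k = k),
           temperature = temperature)
}

## Independent ENM covariance oracle: builds the Hessian from scratch
## (no package internals) and returns kB T times its pseudoinverse.
oracle_enm_covariance <- function(coords, springs, temperature = 300) {
  kb <- 0.0019872041
  n <- nrow(coords)
  H <- matrix(0, 3 * n, 3 * n)
  for (r in seq_len(nrow(springs))) {
    i <- springs$i[r]; j <- springs$j[r]
    d <- coords[j, ] - coords[i, ]
    e <- d / sqrt(sum(d^2))
    K <- springs$k[r] * (e %o% e)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, ii] <- H[ii, ii] + K; H[jj, jj] <- H[jj, jj] + K
    H[ii, jj] <- H[ii, jj] - K; H[jj, ii] <- H[jj, ii] - K
  }
  ev <- eigen(H, symmetric = TRUE)
  keep <- ev$values > max(ev$values) * 1e-9
  V <- ev$vectors[, keep, drop = FALSE]
  kb * temperature * V %*% (t(V) / ev$values[keep])
}

## two internally rigid blocks of beads joined in the middle: each frame
## displaces block 2 rigidly relative to block 1 (used by the EDCG
## boundary test -- within-block motion is uniform, so the optimal
## two-segment boundary sits exactly at the block interface)
two_block_frames <- function(n_frames = 400, n_per_block = 10, move_sd = 0.3,
                             seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_block
  base <- cbind(seq_len(n) - n_per_block - 0.5, 0, 0)
  arr <- array(0, dim = c(n_frames, n, 3))
  for (f in seq_len(n_frames)) {
    fr <- base
    fr[(n_per_block + 1):n, 2] <- fr[(n_per_block + 1):n, 2] + rnorm(1, 0, move_sd)
    ## small independent jitter
    arr[f, , ] <- fr + rnorm(n * 3, 0, 0.01)
  }
  arr
}

## independent EDCG residual: per-segment essential-subspace variance about
## the segment mean displacement, computed directly with prcomp
oracle_edcg_residual <- function(frames, starts, n_modes) {
  nf <- dim(frames)[1]; n <- dim(frames)[2]
  X <- matrix(0, nf, 3 * n)
  for (ax in 1:3) X[, seq(ax, 3 * n, by = 3)] <- frames[, , ax]
  X <- sweep(X, 2, colMeans(X))
  pc <- prcomp(X, center = FALSE)
  k <- n_modes
  E <- pc$x[, 1:k, drop = FALSE] %*% t(pc$rotation[, 1:k, drop = FALSE])
  ends <- c(starts[-1] - 1L, n)
  tot <- 0
  for (s in seq_along(starts)) {
    idx <- starts[s]:ends[s]
    for (f in seq_len(nf)) {
      d <- matrix(E[f, as.vector(outer(1:3, (idx - 1) * 3, "+"))], ncol = 3, byrow = FALSE)
      ## columns of d: need bead-major layout (x,y,z per bead)
      db <- cbind(E[f, (idx - 1) * 3 + 1], E[f, (idx - 1) * 3 + 2], E[f, (idx - 1) * 3 + 3])
      dm <- colMeans(db)
      tot <- tot + sum(sweep(db, 2, dm)^2)
    }
  }
  tot / (nf - 1)
}
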