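## Nematic order analysis of protein coats: per-domain H0 axes, the local
## orientational order parameter, convergence traces, segment-wise
## heterogeneity, defect identification and insertion-depth profiles.

#' H0 axis of a single domain
#'
#' The normalized vector from CG site 1 to CG site 2 (the two H0 helix
#' sites).
#'
#' @param domain_sites Data frame with columns `site`, `x`, `y`, `z`
#'   containing at least sites 1 and 2, or a 16 x 3 coordinate matrix.
#' @return Unit 3-vector.
#' @export
h0_axis <- function(domain_sites) {
  if (is.matrix(domain_sites)) {
    v <- domain_sites[2, ] - domain_sites[1, ]
  } else {
    s1 <- domain_sites[domain_sites$site == 1, ]
    s2 <- domain_sites[domain_sites$site == 2, ]
    v <- c(s2$x - s1$x, s2$y - s1$y, s2$z - s1$z)
  }
  if (vnorm(v) < 1e-9) abort("H0 sites are coincident; axis undefined.")
  normalize(v)
}

#' Per-domain H0 axes and centers of a protein-carrying system or frame
#'
#' @param x A `cg_system` with proteins, or a proteins tibble
#'   (`domain`, `site`, `x`, `y`, `z`).
#' @return Tibble `domain`, `x`, `y`, `z` (domain center of geometry),
#'   `ux`, `uy`, `uz` (H0 axis).
#' @export
domain_axes <- function(x) {
  pro <- if (inherits(x, "cg_system")) x$proteins else x
  if (is.null(pro) || !nrow(pro)) abort("No protein domains present.")
  pro |>
    dplyr::group_by(.data$domain) |>
    dplyr::summarise(
      cx = mean(.data$x), cy = mean(.data$y), cz = mean(.data$z),
      ux = .data$x[.data$site == 2] - .data$x[.data$site == 1],
      uy = .data$y[.data$site == 2] - .data$y[.data$site == 1],
      uz = .data$z[.data$site == 2] - .data$z[.data$site == 1],
      .groups = "drop") |>
    dplyr::mutate(nrm = sqrt(.data$ux^2 + .data$uy^2 + .data$uz^2),
                  ux = .data$ux / .data$nrm, uy = .data$uy / .data$nrm,
                  uz = .data$uz / .data$nrm) |>
    dplyr::select(domain = "domain", x = "cx", y = "cy", z = "cz",
                  "ux", "uy", "uz")
}

#' Local orientational order parameter of a domain field
#'
#' For each domain i, `S_i` is the mean over neighbors j (within `cutoff`
#' of the domain center, j != i) of the unsigned dot product
#' `|u_i . u_j|` between H0 axes: 1 for a locally aligned coat, 0.5 for
#' isotropic axes.  Domains with no neighbors carry `NA` and are excluded
#' from the global average.
#'
#' @param axes Tibble from [domain_axes()] (columns `domain`, `x`, `y`,
#'   `z`, `ux`, `uy`, `uz`).
#' @param cutoff Neighborhood cutoff, nm (default 5).
#' @param method `"cell"` (cell-list neighbor search) or `"brute"`
#'   (all-pairs); identical results, different cost.
#' @return An `order_field` tibble: `domain`, `x`, `y`, `z`, `s`,
#'   `n_neighbors`, with attributes `global` (mean over defined `S_i`) and
#'   `cutoff`.
#' @export
local_order <- function(axes, cutoff = 5, method = c("cell", "brute")) {
  method <- match.arg(method)
  n <- nrow(axes)
  if (n < 1) abort("Need at least one domain.")
  P <- as.matrix(axes[c("x", "y", "z")])
  U <- as.matrix(axes[c("ux", "uy", "uz")])
  ssum <- numeric(n)
  cnt <- integer(n)
  add_pair <- function(i, j) {
    s <- abs(sum(U[i, ] * U[j, ]))
    ssum[i] <<- ssum[i] + s; ssum[j] <<- ssum[j] + s
    cnt[i] <<- cnt[i] + 1L; cnt[j] <<- cnt[j] + 1L
  }
  if (method == "brute" || n <= 64) {
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        d2 <- (P[(i + 1):n, 1] - P[i, 1])^2 + (P[(i + 1):n, 2] - P[i, 2])^2 +
          (P[(i + 1):n, 3] - P[i, 3])^2
        for (j in which(d2 <= cutoff^2)) add_pair(i, i + j)
      }
    }
  } else {
    ## cell binning at the cutoff length
    cell <- floor(sweep(P, 2, apply(P, 2, min)) / cutoff)
    key <- paste(cell[, 1], cell[, 2], cell[, 3])
    cells <- split(seq_len(n), key)
    coords <- do.call(rbind, lapply(strsplit(names(cells), " "), as.numeric))
    for (ci in seq_along(cells)) {
      for (cj in ci:length(cells)) {
        if (any(abs(coords[ci, ] - coords[cj, ]) > 1)) next
        I <- cells[[ci]]; J <- cells[[cj]]
        if (ci == cj) {
          if (length(I) > 1) {
            for (a in seq_len(length(I) - 1)) for (b in (a + 1):length(I)) {
              i <- I[a]; j <- I[b]
              if (sum((P[i, ] - P[j, ])^2) <= cutoff^2) add_pair(i, j)
            }
          }
        } else {
          for (i in I) for (j in J) {
            if (sum((P[i, ] - P[j, ])^2) <= cutoff^2) add_pair(i, j)
          }
        }
      }
    }
  }
  s <- ifelse(cnt > 0, ssum / pmax(cnt, 1), NA_real_)
  out <- tibble(domain = axes$domain, x = axes$x, y = axes$y, z = axes$z,
                ux = axes$ux, uy = axes$uy, uz = axes$uz,
                s = s, n_neighbors = cnt)
  structure(out, global = mean(s, na.rm = TRUE), cutoff = cutoff,
            class = c("order_field", class(out)))
}

#' Global mean of an order field
#' @param field An `order_field`.
#' @return The mean local order over domains with neighbors.
#' @export
global_order <- function(field) attr(field, "global")

## Mann-Kendall trend test statistic; returns the two-sided p-value
mann_kendall_p <- function(x) {
  n <- length(x)
  if (n < 4) return(NA_real_)
  s <- 0
  for (i in seq_len(n - 1)) s <- s + sum(sign(x[(i + 1):n] - x[i]))
  v <- n * (n - 1) * (2 * n + 5) / 18
  z <- (s - sign(s)) / sqrt(v)
  2 * stats::pnorm(-abs(z))
}

#' Time series of the global order parameter over a trajectory
#'
#' Computes the global mean local order for each stored frame and flags
#' convergence when the trailing 25% window shows no Mann-Kendall trend at
#' the 5% level.
#'
#' @param trajectory A `cg_trajectory` with snapshots (run with
#'   `snap_stride > 0`), or a list of frames, each a tibble accepted by
#'   [domain_axes()].
#' @param system The `cg_system` that produced the trajectory (used for
#'   the protein layout); unnecessary when `trajectory` is a frame list.
#' @param cutoff Neighborhood cutoff, nm.
#' @return An `order_trace` tibble: `frame`, `step`, `global_order`;
#'   attribute `converged`.
#' @export
order_trace <- function(trajectory, system = NULL, cutoff = 5) {
  frames <- if (inherits(trajectory, "cg_trajectory")) {
    sys <- system %||% trajectory$system
    if (is.null(sys$proteins)) abort("Trajectory has no protein domains.")
    nl <- if (is.null(sys$lipids)) 0L else nrow(sys$lipids)
    lapply(trajectory$frames, function(fr) {
      pro <- sys$proteins
      pro$x <- fr$pos[nl + seq_len(nrow(pro)), 1]
      pro$y <- fr$pos[nl + seq_len(nrow(pro)), 2]
      pro$z <- fr$pos[nl + seq_len(nrow(pro)), 3]
      list(proteins = pro, step = fr$step)
    })
  } else {
    lapply(seq_along(trajectory), function(i) list(proteins = trajectory[[i]], step = i))
  }
  if (!length(frames)) abort("No frames available (run with snap_stride > 0).")
  vals <- purrr::map_dbl(frames, function(fr) {
    global_order(local_order(domain_axes(fr$proteins), cutoff = cutoff))
  })
  steps <- purrr::map_dbl(frames, "step")
  tail_n <- max(4, ceiling(length(vals) * 0.25))
  pv <- mann_kendall_p(tail(vals, tail_n))
  out <- tibble(frame = seq_along(vals), step = steps, global_order = vals)
  structure(out, converged = is.finite(pv) && pv > 0.05,
            class = c("order_trace", class(out)))
}

#' Converged tail average of an order trace
#' @param trace An `order_trace`. @param tail_frac Fraction of frames to
#'   average (from the end).
#' @export
converged_order <- function(trace, tail_frac = 0.25) {
  k <- max(1, ceiling(nrow(trace) * tail_frac))
  mean(tail(trace$global_order, k))
}

#' Segment-wise mean order along the tube axis
#'
#' Divides the tube length into `n_segments` axial bins and reports the
#' mean local order over member domains of each segment.  Two offset
#' segmentation choices are supported (`offset_frac` shifts all bin edges
#' by that fraction of a bin).  Domains beyond the axial range (e.g. on
#' the caps of a capped tube) are reported separately as segment 0 when
#' `cap_range` is given.
#'
#' @param field An `order_field`.
#' @param n_segments Number of axial segments (>= 2).
#' @param axis Axis name (`"z"` for the builders' tubes).
#' @param offset_frac Bin-edge offset as a fraction of one bin (0 or 0.5
#'   for the two segmentation choices).
#' @param cap_range Optional numeric range `c(lo, hi)` of the cylindrical
#'   part; domains outside it are binned as `segment = 0` (caps).
#' @return A `segment_report` tibble: `segment`, `lo`, `hi`, `mean_order`,
#'   `n_domains`, `empty`.
#' @export
segment_order <- function(field, n_segments, axis = "z", offset_frac = 0,
                          cap_range = NULL) {
  if (n_segments < 2) abort("`n_segments` must be >= 2.")
  pos <- field[[axis]]
  rng <- if (is.null(cap_range)) range(pos) else cap_range
  width <- diff(rng) / n_segments
  edges <- rng[1] + width * (seq_len(n_segments + 1) - 1 + offset_frac)
  in_cyl <- pos >= edges[1] & pos <= edges[n_segments + 1]
  seg <- findInterval(pos, edges, rightmost.closed = TRUE)
  seg[!in_cyl] <- 0L
  rows <- lapply(seq_len(n_segments), function(k) {
    sel <- seg == k & is.finite(field$s)
    tibble(segment = k, lo = edges[k], hi = edges[k + 1],
           mean_order = if (any(sel)) mean(field$s[sel]) else NA_real_,
           n_domains = sum(sel), empty = !any(sel))
  })
  if (any(seg == 0L)) {
    sel <- seg == 0L & is.finite(field$s)
    rows <- c(list(tibble(segment = 0L, lo = NA_real_, hi = NA_real_,
                          mean_order = if (any(sel)) mean(field$s[sel]) else NA_real_,
                          n_domains = sum(sel), empty = !any(sel))), rows)
  }
  out <- dplyr::bind_rows(rows)
  structure(out, offset_frac = offset_frac,
            class = c("segment_report", class(out)))
}

#' Identify lattice defects
#'
#' Domains whose local orientational order falls below `threshold`
#' (default 0.8, separating the ordered and disordered extremes of the
#' coat color maps).
#'
#' @param field An `order_field`.
#' @param threshold Order threshold.
#' @return Tibble of flagged domains (`domain`, `s`), with attribute
#'   `threshold`.
#' @export
find_defects <- function(field, threshold = 0.8) {
  sel <- is.finite(field$s) & field$s < threshold
  structure(tibble(domain = field$domain[sel], s = field$s[sel]),
            threshold = threshold, class = c("defect_list", "tbl_df", "tbl", "data.frame"))
}

## ---- insertion depth -------------------------------------------------------

## least-squares shell fits on head positions
fit_shell <- function(heads, geometry, center_hint = NULL) {
  if (geometry == "plane") {
    list(z0 = mean(heads[, 3]))
  } else if (geometry == "cylinder") {
    ## axis assumed along z through (x0, y0)
    x0 <- mean(heads[, 1]); y0 <- mean(heads[, 2])
    for (it in 1:20) {
      r <- sqrt((heads[, 1] - x0)^2 + (heads[, 2] - y0)^2)
      ## Gauss-Newton on (x0, y0): d r/d x0 = -(x - x0)/r
      R <- mean(r)
      gx <- -(heads[, 1] - x0) / r
      gy <- -(heads[, 2] - y0) / r
      J <- cbind(gx - mean(gx), gy - mean(gy))
      res <- r - R
      upd <- tryCatch(qr.solve(J, -res), error = function(e) c(0, 0))
      x0 <- x0 + upd[1]; y0 <- y0 + upd[2]
      if (sum(upd^2) < 1e-16) break
    }
    r <- sqrt((heads[, 1] - x0)^2 + (heads[, 2] - y0)^2)
    list(x0 = x0, y0 = y0, radius = mean(r))
  } else {
    ctr <- center_hint %||% colMeans(heads)
    for (it in 1:30) {
      d <- sweep(heads, 2, ctr)
      r <- sqrt(rowSums(d^2))
      R <- mean(r)
      g <- -d / r
      J <- sweep(g, 2, colMeans(g), "-")
      res <- r - R
      upd <- tryCatch(qr.solve(J, -res), error = function(e) c(0, 0, 0))
      ctr <- ctr + upd
      if (sum(upd^2) < 1e-16) break
    }
    d <- sweep(heads, 2, ctr)
    list(center = ctr, radius = mean(sqrt(rowSums(d^2))))
  }
}

#' Insertion depth of the H0 sites relative to the headgroup shell
#'
#' Fits the outer headgroup shell (plane, cylinder or sphere) to the lipid
#' head positions and reports signed distances of the H0 sites from the
#' shell.  Positive depth means below the headgroup shell (inserted);
#' a site `standoff` nm above the shell has depth `-standoff`.
#'
#' @param system A `cg_system` with lipids and proteins (or a list of such
#'   frames).
#' @param geometry `"plane"`, `"cylinder"` or `"sphere"`.
#' @return A `depth_profile` tibble: `domain`, `site`, `depth` (nm);
#'   attributes `mean_depth` and `shell` (the fit).
#' @export
insertion_depth_profile <- function(system, geometry = c("cylinder", "plane", "sphere")) {
  geometry <- match.arg(geometry)
  lip <- system$lipids
  pro <- system$proteins
  if (is.null(lip) || is.null(pro)) abort("Need both lipids and protein domains.")
  params <- system$params
  half <- lipid_length(params) / 2
  ## head positions: center - (len/2) * director
  heads <- cbind(lip$x - half * lip$ux, lip$y - half * lip$uy, lip$z - half * lip$uz)
  ## outer shell: keep the outward-facing leaflet
  h0 <- pro[pro$role %in% c("H0_A", "H0_B"), ]
  if (geometry == "plane") {
    keep <- heads[, 3] >= stats::median(heads[, 3])
    sh <- fit_shell(heads[keep, , drop = FALSE], "plane")
    depth <- sh$z0 - h0$z
    shell <- sh
  } else if (geometry == "cylinder") {
    r_all <- sqrt((heads[, 1] - mean(heads[, 1]))^2 + (heads[, 2] - mean(heads[, 2]))^2)
    keep <- r_all >= stats::median(r_all)
    sh <- fit_shell(heads[keep, , drop = FALSE], "cylinder")
    r_site <- sqrt((h0$x - sh$x0)^2 + (h0$y - sh$y0)^2)
    depth <- sh$radius - r_site
    shell <- sh
  } else {
    ctr0 <- colMeans(heads)
    r_all <- sqrt(rowSums(sweep(heads, 2, ctr0)^2))
    keep <- r_all >= stats::median(r_all)
    sh <- fit_shell(heads[keep, , drop = FALSE], "sphere", center_hint = ctr0)
    r_site <- sqrt((h0$x - sh$center[1])^2 + (h0$y - sh$center[2])^2 +
                     (h0$z - sh$center[3])^2)
    depth <- sh$radius - r_site
    shell <- sh
  }
  out <- tibble(domain = h0$domain, site = h0$site, depth = depth)
  structure(out, mean_depth = mean(depth), shell = shell,
            class = c("depth_profile", class(out)))
}

#' Export an order field as CSV
#' @param field An `order_field`. @param path Output file.
#' @export
write_order_csv <- function(field, path) {
  utils::write.csv(as.data.frame(field), path, row.names = FALSE)
  invisible(path)
}
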