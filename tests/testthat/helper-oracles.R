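# Independent oracles, deliberately written with different algorithms than
# the package implementation.

# Dijkstra shortest-path geodesic distances on the 8-connected pixel graph
# with weights 1 / sqrt(2); naive extract-min, fine for small grids.
oracle_geodesic <- function(m, seed_idx) {
  nr <- nrow(m); nc <- ncol(m)
  d <- matrix(Inf, nr, nc)
  d[seed_idx] <- 0
  visited <- matrix(FALSE, nr, nc)
  repeat {
    dv <- d
    dv[visited | !m] <- Inf
    i <- which.min(dv)
    if (!is.finite(dv[i])) break
    visited[i] <- TRUE
    r <- (i - 1) %% nr + 1
    cc <- (i - 1) %/% nr + 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; c2 <- cc + dc
      if (rr < 1 || rr > nr || c2 < 1 || c2 > nc || !m[rr, c2]) next
      w <- if (dr != 0 && dc != 0) sqrt(2) else 1
      if (d[i] + w < d[rr, c2]) d[rr, c2] <- d[i] + w
    }
  }
  d[!m] <- NA
  d[is.infinite(d)] <- NA
  d
}

# brute-force double-loop dispersal statistic for one frame
oracle_frame_dispersal <- function(x, y, ux, uy) {
  n <- length(x)
  s <- x * ux + y * uy
  p <- -x * uy + y * ux
  par_i <- per_i <- numeric(n)
  for (i in seq_len(n)) {
    sp <- sq <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      sp <- sp + abs(s[i] - s[j])
      sq <- sq + abs(p[i] - p[j])
    }
    par_i[i] <- sp / (n - 1)
    per_i[i] <- sq / (n - 1)
  }
  c(parallel = mean(par_i), perpendicular = mean(per_i))
}

# brute-force all-pairs minimum distance, nuclei x contour points
oracle_min_dist <- function(nx, ny, cx, cy) {
  vapply(seq_along(nx), function(i) {
    best <- Inf
    for (j in seq_along(cx)) {
      dd <- sqrt((nx[i] - cx[j])^2 + (ny[i] - cy[j])^2)
      if (dd < best) best <- dd
    }
    best
  }, 0)
}

# reference axis pointing along +x, static
axis_plus_x <- function(tip_x = 1000, y = 0) {
  reference_axis(data.frame(t = 0, x = tip_x, y = y, z = 0),
                 back = c(0, y, 0))
}

# rasterize an ellipse (optionally rotated) into a logical matrix
raster_ellipse <- function(a_um, b_um, theta_deg = 0, psz = 1, pad = 4) {
  ext <- max(a_um, b_um) + pad * psz
  n <- ceiling(2 * ext / psz)
  xs <- (0:(n - 1)) * psz - ext
  X <- matrix(rep(xs, each = n), n)
  Y <- matrix(rep(xs, n), n)
  th <- theta_deg * pi / 180
  Xr <- X * cos(th) + Y * sin(th)
  Yr <- -X * sin(th) + Y * cos(th)
  (Xr / a_um)^2 + (Yr / b_um)^2 <= 1
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# standard gradient-pipeline run on a simulated fixture
run_gradient_pipeline <- function(sim, config = run_config("explant")) {
  tab <- quiet(qc_filter(sim$table, config))
  tab <- distance_to_reference(tab, sim$contour)
  tab <- quiet(background_subtract(tab, sim$background_spots))
  tab
}

# axis-aligned rectangle as an 8-vertex polygon (cell outlines require >= 6)
rect8 <- function(x0, y0, x1, y1) {
  cbind(c(x0, (x0 + x1) / 2, x1, x1, x1, (x0 + x1) / 2, x0, x0),
        c(y0, y0, y0, (y0 + y1) / 2, y1, y1, y1, (y0 + y1) / 2))
}
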