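# Internal geometry helpers: polygon measures, boundary tracing, geodesic
# distance maps. Raster convention: matrices are indexed [row = y, col = x],
# pixel (0,0) at the centre of mask[1,1]; all polygon math in that frame.

polygon_perimeter <- function(xy) {
  n <- nrow(xy)
  d <- xy - xy[c(2:n, 1L), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

polygon_area <- function(xy) {
  # shoelace; positive magnitude
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polyline_length <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  d <- diff(as.matrix(xy))
  sum(sqrt(rowSums(d^2)))
}

# circular moving average of a closed polygon's vertices
smooth_closed <- function(xy, w) {
  if (w < 2L) return(xy)
  n <- nrow(xy)
  k <- floor(w / 2)
  out <- xy
  for (j in c(-(k:1), 1:k)) {
    idx <- ((seq_len(n) - 1L + j) %% n) + 1L
    out <- out + xy[idx, , drop = FALSE]
  }
  out / (2 * k + 1)
}

# Sub-pixel boundary of the largest foreground blob, as a closed polygon in
# pixel coordinates (x = col-1, y = row-1). Marching squares at the 0.5
# level; a 5-point moving average removes the half-pixel staircase so that
# perimeter estimates on smooth shapes are accurate to ~1%.
trace_boundary <- function(m, smooth_window = 5L) {
  z <- t(m * 1)  # contourLines wants z[x, y]
  # pad so blobs touching the border still close
  zp <- matrix(0, nrow(z) + 2L, ncol(z) + 2L)
  zp[2:(nrow(z) + 1L), 2:(ncol(z) + 1L)] <- z
  cl <- contourLines(x = seq_len(nrow(zp)) - 2, y = seq_len(ncol(zp)) - 2,
                     z = zp, levels = 0.5)
  if (!length(cl)) stop("no boundary found (empty mask?)")
  lens <- vapply(cl, function(cc) length(cc$x), 1L)
  cc <- cl[[which.max(lens)]]
  xy <- cbind(cc$x, cc$y)
  if (all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  smooth_closed(xy, smooth_window)
}

# vectorized even-odd point-in-polygon (boundary points counted in)
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:n, 1L), 1]; y2 <- poly[c(2:n, 1L), 2]
  inside <- logical(length(px))
  for (e in seq_len(n)) {
    crosses <- ((y1[e] > py) != (y2[e] > py))
    if (any(crosses)) {
      xint <- x1[e] + (py[crosses] - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
      flip <- xint > px[crosses]
      inside[crosses][flip] <- !inside[crosses][flip]
    }
  }
  inside
}

# Geodesic (within-mask) distance map from a set of seed pixels, 8-connected
# with step weights 1 and sqrt(2). Computed by repeated forward/backward
# chamfer sweeps until a fixed point: each sweep relaxes half the neighbor
# edges, so iterating converges to the exact shortest-path distances even in
# hooked or spiral masks.
#
# m: logical [y, x] foreground; seeds: logical [y, x] or n x 2 matrix of
# (row, col) indices. Returns matrix of distances in pixels, NA outside mask.
geodesic_distance_map <- function(m, seeds) {
  nr <- nrow(m); nc <- ncol(m)
  d <- matrix(Inf, nr, nc)
  if (is.logical(seeds) || (is.matrix(seeds) && all(dim(seeds) == dim(m)) &&
                            all(seeds %in% c(0, 1, TRUE, FALSE)))) {
    d[seeds & m] <- 0
  } else {
    seeds <- as.matrix(seeds)
    keep <- m[seeds]
    d[seeds[keep, , drop = FALSE]] <- 0
  }
  if (!any(d == 0)) stop("no seed pixels inside the mask")
  s2 <- sqrt(2)
  big <- Inf
  repeat {
    changed <- FALSE
    # forward sweep: top-left to bottom-right
    for (i in seq_len(nr)) {
      row <- d[i, ]
      if (i > 1L) {
        up <- d[i - 1L, ]
        cand <- up + 1
        cand <- pmin(cand, c(big, up[-nc] + s2))       # up-left
        cand <- pmin(cand, c(up[-1L] + s2, big))       # up-right
        row <- pmin(row, cand)
      }
      row[!m[i, ]] <- Inf          # mask before propagating within the row
      for (j in seq(2L, nc)) {
        if (!m[i, j]) next
        v <- row[j - 1L] + 1
        if (v < row[j]) row[j] <- v
      }
      if (any(row < d[i, ])) changed <- TRUE
      d[i, ] <- row
    }
    # backward sweep: bottom-right to top-left
    for (i in rev(seq_len(nr))) {
      row <- d[i, ]
      if (i < nr) {
        dn <- d[i + 1L, ]
        cand <- dn + 1
        cand <- pmin(cand, c(big, dn[-nc] + s2))
        cand <- pmin(cand, c(dn[-1L] + s2, big))
        row <- pmin(row, cand)
      }
      row[!m[i, ]] <- Inf
      for (j in seq(nc - 1L, 1L)) {
        if (!m[i, j]) next
        v <- row[j + 1L] + 1
        if (v < row[j]) row[j] <- v
      }
      if (any(row < d[i, ])) changed <- TRUE
      d[i, ] <- row
    }
    if (!changed) break
  }
  d[!m] <- NA_real_
  d[is.infinite(d)] <- NA_real_  # unreachable foreground (other components)
  d
}

# Convexity defects of a closed boundary polygon: for each gap between
# consecutive convex-hull vertices, the boundary point farthest from the
# hull edge. `turning` is the local corner angle at the defect: 180 deg
# minus the angle at the defect point between the boundary points at
# +/- turning_arc px of arclength, so a smooth boundary scores ~0 and a
# sharp concave corner scores its angular deficit. Convex boundaries give
# zero rows.
convexity_defects <- function(xy, turning_arc = 8) {
  n <- nrow(xy)
  h <- sort(chull(xy))
  arc_pt <- function(i, dir) {
    # walk dir = +1/-1 from vertex i until turning_arc of arclength
    acc <- 0; j <- i
    while (acc < turning_arc) {
      jn <- ((j - 1L + dir) %% n) + 1L
      acc <- acc + sqrt(sum((xy[jn, ] - xy[j, ])^2))
      j <- jn
      if (j == i) break
    }
    xy[j, ]
  }
  out <- list()
  hh <- c(h, h[1] + n)              # wrap
  for (g in seq_along(h)) {
    a <- hh[g]; b <- hh[g + 1]
    if (b - a < 2L) next            # no interior boundary points in this gap
    idx <- ((a:(b - 1L)) %% n) + 1L # boundary points strictly inside the gap
    idx <- idx[-1L]
    pa <- xy[((a - 1L) %% n) + 1L, ]
    pb <- xy[((b - 1L) %% n) + 1L, ]
    e <- pb - pa
    elen <- sqrt(sum(e^2))
    if (elen < 1e-9) next
    rel <- sweep(xy[idx, , drop = FALSE], 2, pa)
    depth <- abs(rel[, 1] * e[2] - rel[, 2] * e[1]) / elen
    k <- which.max(depth)
    i <- idx[k]
    p <- xy[i, ]
    va <- arc_pt(i, -1L) - p
    vb <- arc_pt(i, +1L) - p
    ca <- sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
    ang <- acos(pmin(pmax(ca, -1), 1)) * 180 / pi
    out[[length(out) + 1L]] <- data.frame(
      x = p[1], y = p[2], depth = depth[k], turning = 180 - ang, gap = g)
  }
  if (!length(out))
    return(data.frame(x = numeric(), y = numeric(), depth = numeric(),
                      turning = numeric(), gap = integer()))
  do.call(rbind, out)
}

# pixel-centre coordinate grids for a mask, in pixel units
pixel_grid <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  list(x = matrix(rep(0:(nc - 1L), each = nr), nr, nc),
       y = matrix(rep(0:(nr - 1L), nc), nr, nc))
}

# logical matrix: pixels whose centre lies within radius r of (cx, cy) (px)
disk_pixels <- function(nr, nc, cx, cy, r) {
  g <- pixel_grid(matrix(FALSE, nr, nc))
  (g$x - cx)^2 + (g$y - cy)^2 <= r^2
}

# fold an absolute angular difference (deg) between axial directions to [0, 90]
fold_axial <- function(delta) {
  d <- abs(delta) %% 180
  ifelse(d > 90, 180 - d, d)
}
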