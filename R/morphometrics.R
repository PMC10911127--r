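#' Explant silhouette mask
#'
#' Container for a 2D binary silhouette with its pixel calibration and
#' optional annotations: a manually placed indentation point (um), an
#' expression-domain submask (e.g. the EGFP-positive domain) and a central
#' reference box used by [shape_profile()].
#'
#' @param mask Logical matrix, `[row = y, col = x]`, `TRUE` = foreground.
#' @param calibration A [pixel_calibration()].
#' @param indentation_point Optional c(x, y) in um on the silhouette boundary.
#' @param domain Optional logical matrix of the same size (expression domain).
#' @param reference_box Optional list with `start`, `end` (c(x, y) um) and
#'   `width_px` (default 40) describing the central reference box.
#' @return An object of class `explant_mask`.
#' @export
explant_mask <- function(mask, calibration, indentation_point = NULL,
                         domain = NULL, reference_box = NULL) {
  stopifnot(is.matrix(mask), inherits(calibration, "pixel_calibration"))
  mask <- mask != 0
  if (!any(mask)) stop("empty mask")
  ncomp <- max(EBImage::bwlabel(mask * 1))
  if (ncomp > 1L)
    warning(sprintf("mask has %d connected components; explant analyses assume one",
                    ncomp))
  if (!is.null(domain)) {
    stopifnot(all(dim(domain) == dim(mask)))
    domain <- domain != 0
  }
  if (!is.null(reference_box)) reference_box$width_px <-
      reference_box$width_px %||% 40L
  structure(list(mask = mask, calibration = calibration,
                 indentation_point = indentation_point,
                 domain = domain, reference_box = reference_box,
                 n_components = ncomp),
            class = "explant_mask")
}

#' @export
print.explant_mask <- function(x, ...) {
  cat(sprintf("explant mask %d x %d px (%g um/px), area %.0f um^2\n",
              ncol(x$mask), nrow(x$mask), x$calibration$xy,
              sum(x$mask) * x$calibration$xy^2))
  invisible(x)
}

.mask_of <- function(x) if (inherits(x, "explant_mask")) x$mask else (x != 0)
.cal_of <- function(x, calibration = NULL) {
  if (inherits(x, "explant_mask")) x$calibration
  else calibration %||% stop("a pixel_calibration is required")
}

#' Explant circularity
#'
#' Circularity 4*pi*Area/Perimeter^2 of the silhouette, computed on the
#' traced sub-pixel boundary polygon (marching squares + 5-point smoothing)
#' so that a rasterized disk scores 1.00 within 2%. Values are clipped at 1.
#'
#' @param mask An `explant_mask` (single connected component).
#' @return Circularity in (0, 1].
#' @examples
#' cal <- pixel_calibration(2)
#' m <- make_explant_mask(400, 400, 0, calibration = cal)
#' circularity(m$mask)  # ~1
#' @export
circularity <- function(mask) {
  m <- .mask_of(mask)
  if (!any(m)) stop("empty mask")
  a <- sum(m)
  p <- polygon_perimeter(trace_boundary(m))
  min(4 * pi * a / p^2, 1)
}

# geodesic "diameter" endpoints of the mask via the classic two-sweep:
# farthest point from an arbitrary start, then farthest from that.
# Returns list(p1, p2, length_px, map_from_p1).
.geodesic_endpoints <- function(m) {
  start <- which(m, arr.ind = TRUE)[1L, , drop = FALSE]
  d0 <- geodesic_distance_map(m, start)
  p1 <- which(d0 == max(d0, na.rm = TRUE), arr.ind = TRUE)[1L, , drop = FALSE]
  d1 <- geodesic_distance_map(m, p1)
  p2 <- which(d1 == max(d1, na.rm = TRUE), arr.ind = TRUE)[1L, , drop = FALSE]
  list(p1 = p1, p2 = p2, length_px = d1[p2], map_from_p1 = d1)
}

.nearest_fg_pixel <- function(m, x_px, y_px) {
  idx <- which(m, arr.ind = TRUE)
  dd <- (idx[, 2] - 1 - x_px)^2 + (idx[, 1] - 1 - y_px)^2
  idx[which.min(dd), , drop = FALSE]
}

#' Classify an explant as extended or not
#'
#' Operationalizes the visual "clear indentation between the round and
#' extended part" criterion as a boundary-concavity detector: the silhouette
#' is extended when its boundary shows concavities of sufficient depth and
#' turning on both flanks of a candidate neck. Depth is measured from the
#' convex hull; turning is the angular deficit at the concave point. A
#' user-supplied indentation point overrides detection and is logged as a
#' manual annotation.
#'
#' @param mask An `explant_mask`.
#' @param depth_threshold_um Minimum concavity depth (default 15 um).
#' @param turning_threshold_deg Minimum turning angle (default 40 degrees).
#' @return A list: `extended` (logical), `indentation_point` (c(x, y) um, or
#'   `NULL`), `defects` (all detected concavities), `manual` (logical).
#' @export
classify_extension <- function(mask, depth_threshold_um = 15,
                               turning_threshold_deg = 40) {
  stopifnot(inherits(mask, "explant_mask"))
  if (!is.null(mask$indentation_point)) {
    message("classify_extension: using manually supplied indentation point")
    return(list(extended = TRUE, indentation_point = mask$indentation_point,
                defects = NULL, manual = TRUE))
  }
  psz <- mask$calibration$xy
  # unsmoothed boundary: corner angles must not be rounded off before the
  # turning measurement (taken over +/- 10 um of arclength)
  bd <- trace_boundary(mask$mask, smooth_window = 1L)
  def <- convexity_defects(bd, turning_arc = max(3, 10 / psz))
  def$depth_um <- def$depth * psz
  cand <- def[def$depth_um >= depth_threshold_um &
                def$turning >= turning_threshold_deg, , drop = FALSE]
  if (nrow(cand) >= 2L && length(unique(cand$gap)) >= 2L) {
    cand <- cand[order(-cand$depth_um), ]
    # the two deepest concavities on distinct hull gaps = the two neck flanks
    second <- which(cand$gap != cand$gap[1])[1]
    p1 <- c(cand$x[1], cand$y[1]); p2 <- c(cand$x[second], cand$y[second])
    ip <- (p1 + p2) / 2 * psz
    return(list(extended = TRUE, indentation_point = ip, defects = def,
                manual = FALSE))
  }
  if (nrow(def) && max(def$depth_um) >= depth_threshold_um / 2)
    message(sprintf(
      "classify_extension: borderline neck (depth %.1f um, turning %.0f deg) below threshold",
      max(def$depth_um), def$turning[which.max(def$depth_um)]))
  list(extended = FALSE, indentation_point = NULL, defects = def,
       manual = FALSE)
}

#' Normalized extension length
#'
#' Length of the extension, from the explant tip to the indentation point,
#' normalized to the full explant length (tip to back). Both lengths are
#' within-mask geodesic path lengths measured with the same chamfer metric
#' as [shape_profile()]; the tip and back are the endpoints of the mask's
#' geodesic diameter, the tip being the endpoint geodesically closer to the
#' indentation point.
#'
#' @param mask An `explant_mask`.
#' @param indentation_point c(x, y) in um; defaults to the mask's stored
#'   annotation or, failing that, automatic detection via
#'   [classify_extension()].
#' @return Normalized extension length in `[0, 1]`.
#' @export
extension_length <- function(mask, indentation_point = NULL) {
  stopifnot(inherits(mask, "explant_mask"))
  ip <- indentation_point %||% mask$indentation_point
  if (is.null(ip)) {
    cls <- classify_extension(mask)
    if (!cls$extended)
      stop("no indentation point: run classify_extension() or supply one")
    ip <- cls$indentation_point
  }
  psz <- mask$calibration$xy
  m <- mask$mask
  ge <- .geodesic_endpoints(m)
  ip_px <- .nearest_fg_pixel(m, ip[1] / psz, ip[2] / psz)
  d_from_p1 <- ge$map_from_p1
  d_from_p2 <- geodesic_distance_map(m, ge$p2)
  # tip = diameter endpoint geodesically nearer the indentation
  if (d_from_p1[ip_px] <= d_from_p2[ip_px]) {
    d_tip_ind <- d_from_p1[ip_px]
  } else {
    d_tip_ind <- d_from_p2[ip_px]
  }
  as.numeric(d_tip_ind / ge$length_px)
}

#' Geodesic half-width shape profile
#'
#' Reconstructs the explant's half-width as a function of axial position:
#' every foreground pixel's within-mask geodesic distance from the central
#' reference box is computed (8-connected chamfer metric, steps 1 and
#' sqrt(2)), and for each axial station the maximum geodesic distance among
#' pixels on the requested side of the axis is reported. Because distances
#' are geodesic, hooked or curved silhouettes report their unrolled
#' half-width rather than the Euclidean one.
#'
#' @param mask An `explant_mask`.
#' @param reference_box Overrides the mask's stored box: list with `start`,
#'   `end` (c(x, y) um) and optionally `width_px` (default 40).
#' @param side `"left"` or `"right"` of the axis direction (start -> end),
#'   in image coordinates (y down); `"left"` is the negative cross-product
#'   side.
#' @param station_px Axial station spacing in pixels (default 1).
#' @return A data.frame of class `shape_profile`: `station_um` (axial
#'   position of the station centre, from the box start), `halfwidth_um`
#'   (maximum geodesic distance), `n_px` (pixels contributing).
#' @export
shape_profile <- function(mask, reference_box = NULL,
                          side = c("left", "right"), station_px = 1) {
  stopifnot(inherits(mask, "explant_mask"))
  side <- match.arg(side)
  box <- reference_box %||% mask$reference_box
  if (is.null(box)) stop("no reference box supplied or stored in the mask")
  box$width_px <- box$width_px %||% 40L
  psz <- mask$calibration$xy
  m <- mask$mask
  p1 <- box$start / psz
  p2 <- box$end / psz
  u <- p2 - p1
  ulen <- sqrt(sum(u^2))
  if (ulen < 1e-9) stop("degenerate reference box (zero length)")
  u <- u / ulen
  g <- pixel_grid(m)
  relx <- g$x - p1[1]; rely <- g$y - p1[2]
  s <- relx * u[1] + rely * u[2]          # axial coordinate, px
  cr <- u[1] * rely - u[2] * relx         # cross product -> side
  perp <- abs(cr)
  in_box <- m & s >= 0 & s <= ulen & perp <= box$width_px / 2
  if (!any(in_box)) stop("reference box lies outside the mask")
  if (any((s >= 0 & s <= ulen & perp <= box$width_px / 2) & !m))
    stop("reference box extends outside the mask foreground")
  dmap <- geodesic_distance_map(m, in_box)
  keep <- m & if (side == "left") cr < 0 else cr > 0
  keep <- keep & !is.na(dmap)
  if (!any(keep)) stop("no foreground pixels on the requested side")
  station <- floor(s[keep] / station_px)
  dd <- dmap[keep]
  agg <- tapply(dd, station, max)
  cnt <- tapply(dd, station, length)
  st <- as.integer(names(agg))
  out <- data.frame(station_um = (st + 0.5) * station_px * psz,
                    halfwidth_um = as.numeric(agg) * psz,
                    n_px = as.integer(cnt))
  out <- out[order(out$station_um), ]
  rownames(out) <- NULL
  class(out) <- c("shape_profile", "data.frame")
  out
}

#' Expression-domain length/width ratio
#'
#' Length is the extent of the domain's support projected on the extension
#' axis; width is the extent along the perpendicular line through the
#' domain's axial midpoint. Both extents include one pixel of support.
#'
#' @param domain_mask Logical matrix or `explant_mask` of the domain.
#' @param extension_axis Axis as an angle in degrees (from +x towards +y) or
#'   a 2-vector direction.
#' @param calibration Required when `domain_mask` is a bare matrix.
#' @return length/width ratio (dimensionless).
#' @export
domain_length_width <- function(domain_mask, extension_axis,
                                calibration = NULL) {
  m <- .mask_of(domain_mask)
  cal <- .cal_of(domain_mask, calibration)
  if (!any(m)) stop("empty domain")
  psz <- cal$xy
  if (length(extension_axis) == 1L) {
    th <- extension_axis * pi / 180
    u <- c(cos(th), sin(th))
  } else {
    u <- extension_axis / sqrt(sum(extension_axis^2))
  }
  g <- pixel_grid(m)
  xs <- g$x[m] * psz; ys <- g$y[m] * psz
  s <- xs * u[1] + ys * u[2]
  w <- -xs * u[2] + ys * u[1]
  len <- diff(range(s)) + psz
  smid <- mean(range(s))
  mid <- abs(s - smid) <= psz / 2 + 1e-9
  if (!any(mid)) stop("degenerate domain: no pixels at the axial midpoint")
  wid <- diff(range(w[mid])) + psz
  if (wid <= psz / 2) stop("degenerate domain: zero width")
  len / wid
}

#' Area fraction of a domain within an outlined region
#'
#' @param domain_mask Logical matrix or `explant_mask` (binarized signal).
#' @param region_outline Closed polygon, n x 2 matrix in um.
#' @param calibration Required when `domain_mask` is a bare matrix.
#' @return (domain intersect region area) / (region area), in `[0, 1]`.
#' @export
domain_area_fraction <- function(domain_mask, region_outline,
                                 calibration = NULL) {
  m <- .mask_of(domain_mask)
  cal <- .cal_of(domain_mask, calibration)
  psz <- cal$xy
  g <- pixel_grid(m)
  inside <- matrix(points_in_polygon(as.vector(g$x) * psz,
                                     as.vector(g$y) * psz,
                                     as.matrix(region_outline)),
                   nrow(m), ncol(m))
  denom <- sum(inside)
  if (denom == 0) stop("region outline encloses zero area")
  sum(inside & m) / denom
}

#' Embryo axis length ratio
#'
#' Arc length of the mesendoderm axis polyline (front of the reporter
#' domain to the tailbud, traced along the embryo's curvature) divided by
#' the embryo height (Euclidean distance between two landmark points).
#'
#' @param axis_polyline n x 2 matrix of polyline vertices (um), n >= 2.
#' @param height_points 2 x 2 matrix: the two height landmark points (um).
#' @return Dimensionless ratio.
#' @examples
#' th <- seq(0, pi, length.out = 200)
#' arc <- cbind(cos(th), sin(th)) * 300
#' embryo_axis_ratio(arc, rbind(c(-300, 0), c(300, 0)))  # ~ pi/2
#' @export
embryo_axis_ratio <- function(axis_polyline, height_points) {
  axis_polyline <- as.matrix(axis_polyline)
  height_points <- as.matrix(height_points)
  if (nrow(axis_polyline) < 2L) stop("axis polyline needs >= 2 points")
  h <- sqrt(sum((height_points[2, ] - height_points[1, ])^2))
  if (h < 1e-9) stop("zero embryo height")
  polyline_length(axis_polyline) / h
}

#' Expression-domain area normalized to the explant area
#'
#' @param stain_mask Logical matrix or `explant_mask` of the outlined signal.
#' @param mask The whole-explant `explant_mask` (same calibration and size).
#' @return Stained area / explant area, in `[0, 1]`.
#' @export
expression_domain_area <- function(stain_mask, mask) {
  s <- .mask_of(stain_mask)
  m <- .mask_of(mask)
  stopifnot(all(dim(s) == dim(m)))
  a_stain <- sum(s)
  a_expl <- sum(m)
  if (a_expl == 0) stop("empty explant mask")
  if (a_stain > 0) {
    outside <- sum(s & !m) / a_stain
    if (outside > 0.05)
      warning(sprintf("%.0f%% of the stain lies outside the explant",
                      100 * outside))
  }
  sum(s & m) / a_expl
}

#' One-row morphometrics record for an explant
#'
#' Convenience wrapper assembling the shape measurements for one sample:
#' circularity, extension classification and normalized length, and (when a
#' domain submask is present) the domain length/width ratio and normalized
#' domain area.
#'
#' @param mask An `explant_mask`, optionally carrying a domain submask.
#' @param extension_axis Axis angle in degrees for the domain length/width
#'   measurement (default 0, the x axis).
#' @return A one-row data.frame.
#' @export
measure_explant <- function(mask, extension_axis = 0) {
  cls <- classify_extension(mask)
  ext_len <- if (cls$extended)
    extension_length(mask, cls$indentation_point) else NA_real_
  lw <- da <- NA_real_
  if (!is.null(mask$domain)) {
    lw <- domain_length_width(explant_mask(mask$domain, mask$calibration),
                              extension_axis)
    da <- expression_domain_area(mask$domain, mask)
  }
  data.frame(circularity = circularity(mask),
             extended = cls$extended,
             extension_length_norm = ext_len,
             length_width_ratio = lw,
             domain_area_norm = da)
}
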