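#' Cell outline on one imaging plane
#'
#' @param vertices n x 2 matrix of polygon vertices in um (>= 6, simple,
#'   positive area).
#' @param plane_depth Depth of the imaging plane, um from the tissue top.
#' @param nucleus_center Optional c(x, y) um of the nucleus centre.
#' @param id Cell identifier.
#' @param condition Optional condition/sample label.
#' @return An object of class `cell_outline`.
#' @export
cell_outline <- function(vertices, plane_depth = NA_real_,
                         nucleus_center = NULL, id = NA, condition = NA) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 6L) stop("outline needs >= 6 vertices")
  if (polygon_area(vertices) <= 0) stop("outline has zero area")
  structure(list(vertices = vertices, plane_depth = plane_depth,
                 nucleus_center = nucleus_center, id = id,
                 condition = condition),
            class = "cell_outline")
}

# signed area and raw second-order area moments of a polygon (Green's
# theorem); returns list(area, cx, cy, mu_xx, mu_yy, mu_xy) with central
# second moments normalized by area (i.e. the covariance of the uniform
# density over the polygon).
.polygon_moments <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) stop("zero-area polygon")
  cx <- sum((x + x[j]) * cr) / (6 * a)
  cy <- sum((y + y[j]) * cr) / (6 * a)
  sxx <- sum((x^2 + x * x[j] + x[j]^2) * cr) / 12
  syy <- sum((y^2 + y * y[j] + y[j]^2) * cr) / 12
  sxy <- sum((x * y[j] + 2 * x * y + 2 * x[j] * y[j] + x[j] * y) * cr) / 24
  list(area = abs(a), cx = cx, cy = cy,
       mu_xx = sxx / a - cx^2, mu_yy = syy / a - cy^2,
       mu_xy = sxy / a - cx * cy)
}

#' Best-fit-ellipse orientation of a cell outline
#'
#' Fits the ellipse with the same second-order area moments as the polygon
#' (the "best fit ellipse" of standard raster toolchains) and returns the
#' angle of its longest axis, in degrees in `[-90, 90)` measured from +x
#' towards +y, together with the aspect ratio (major/minor). Cells with
#' aspect ratio below 1.05 are flagged near-isotropic: their angle is still
#' returned but is numerically unstable.
#'
#' @param outline A [cell_outline()] or n x 2 vertex matrix.
#' @return List: `angle_deg`, `aspect_ratio`, `near_isotropic`.
#' @examples
#' rect <- cbind(c(-2, 2, 2, -2), c(-1, -1, 1, 1))
#' fit_orientation(rect)$angle_deg    # 0
#' fit_orientation(rect)$aspect_ratio # 2
#' @export
fit_orientation <- function(outline) {
  xy <- if (inherits(outline, "cell_outline")) outline$vertices
        else as.matrix(outline)
  mo <- .polygon_moments(xy)
  tr2 <- (mo$mu_xx + mo$mu_yy) / 2
  dif <- (mo$mu_xx - mo$mu_yy) / 2
  disc <- sqrt(dif^2 + mo$mu_xy^2)
  l1 <- tr2 + disc; l2 <- tr2 - disc
  ang <- 0.5 * atan2(2 * mo$mu_xy, mo$mu_xx - mo$mu_yy) * 180 / pi
  if (ang >= 90) ang <- ang - 180
  if (ang < -90) ang <- ang + 180
  ar <- sqrt(l1 / max(l2, .Machine$double.eps))
  list(angle_deg = ang, aspect_ratio = ar, near_isotropic = ar < 1.05)
}

#' Angular deviation of a cell axis from a reference axis
#'
#' Axial angles have period 180 degrees; the deviation is the absolute
#' difference folded into `[0, 90]`.
#'
#' @param angle,axis_angle Angles in degrees (vectorized).
#' @return Deviation in degrees, `[0, 90]`.
#' @examples
#' deviation_from_axis(80, -80)  # 20
#' @export
deviation_from_axis <- function(angle, axis_angle) {
  stopifnot(all(is.finite(angle)), all(is.finite(axis_angle)))
  fold_axial(angle - axis_angle)
}

# mean of an image within a circle of diameter d_px centred at (cx, cy) um
.circle_mean <- function(img, cx_um, cy_um, d_px, psz) {
  sel <- disk_pixels(nrow(img), ncol(img), cx_um / psz, cy_um / psz, d_px / 2)
  if (!any(sel)) stop("measurement circle lies outside the image")
  mean(img[sel])
}

#' Nuclear signaling intensity with cytoplasmic background subtraction
#'
#' Measures the mean signal within a circle (default 6 px wide) at the
#' nucleus, subtracts the mean over five 4-px-wide circles placed in the
#' cytoplasm (inside the cell outline, outside the nuclear circle), and
#' divides by the mean DAPI intensity in the nuclear circle for the
#' depth-corrected, normalized value. When cytoplasm spot positions are not
#' supplied they are drawn with the run seed and returned, so the
#' measurement is reproducible and loggable.
#'
#' @param outline A [cell_outline()] with a nucleus centre.
#' @param signal_image,dapi_image Matrices `[y, x]` of the two channels.
#' @param calibration A [pixel_calibration()].
#' @param cytoplasm_spots Optional n x 2 matrix of spot centres (um).
#' @param n_spots Number of random cytoplasm spots when not supplied.
#' @param config A [run_config()] providing the circle diameters and seed.
#' @return List: `corrected` (background-subtracted nuclear signal, clamped
#'   at 0 with a warning if the background exceeds it), `normalized`
#'   (corrected / nuclear DAPI), `background`, `dapi`, `spots` (the spot
#'   centres used).
#' @export
nuclear_signal <- function(outline, signal_image, dapi_image, calibration,
                           cytoplasm_spots = NULL, n_spots = 5L,
                           config = run_config()) {
  stopifnot(inherits(outline, "cell_outline"),
            !is.null(outline$nucleus_center))
  psz <- calibration$xy
  dn <- config$nuclear_circle_diameter_px
  dc <- config$cytoplasm_circle_diameter_px
  nc <- outline$nucleus_center
  if (is.null(cytoplasm_spots)) {
    set.seed(config$seed + as.integer(outline$id %||% 0))
    poly <- outline$vertices
    bb <- apply(poly, 2, range)
    spots <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(spots) < n_spots && tries < 2000L) {
      p <- c(runif(1, bb[1, 1], bb[2, 1]), runif(1, bb[1, 2], bb[2, 2]))
      tries <- tries + 1L
      if (!points_in_polygon(p[1], p[2], poly)) next
      if (sqrt(sum((p - nc)^2)) <= (dn / 2 + dc / 2) * psz) next
      spots <- rbind(spots, p)
    }
    if (nrow(spots) < n_spots)
      stop("could not place cytoplasm spots inside the outline")
    cytoplasm_spots <- spots
  }
  sig <- .circle_mean(signal_image, nc[1], nc[2], dn, psz)
  dap <- .circle_mean(dapi_image, nc[1], nc[2], dn, psz)
  bg <- mean(apply(cytoplasm_spots, 1, function(p)
    .circle_mean(signal_image, p[1], p[2], dc, psz)))
  corrected <- sig - bg
  if (corrected < 0) {
    warning("background exceeds nuclear signal; corrected value clamped at 0")
    corrected <- 0
  }
  list(corrected = corrected, normalized = corrected / dap,
       background = bg, dapi = dap, spots = cytoplasm_spots)
}

#' Depth-gate alignment records
#'
#' Keeps records whose imaging-plane depth lies 45-60 um from the top of
#' the explant (explant mode) or within 37.5 um of the top of the
#' mesendoderm (embryo mode), reducing depth-related intensity effects.
#'
#' @param records data.frame with a `plane_depth_um` column.
#' @param mode `"explant"` or `"embryo"`.
#' @return The filtered data.frame; the number kept/dropped is reported via
#'   `message()`.
#' @export
depth_gate <- function(records, mode = c("explant", "embryo")) {
  mode <- match.arg(mode)
  d <- records$plane_depth_um
  if (is.null(d)) stop("records lack a plane_depth_um column")
  keep <- if (mode == "explant") d >= 45 & d <= 60 else d <= 37.5
  message(sprintf("depth_gate (%s): kept %d of %d records",
                  mode, sum(keep), length(keep)))
  records[keep, , drop = FALSE]
}

#' Alignment records for a set of cell outlines
#'
#' Convenience wrapper: fits each outline's orientation, computes the
#' deviation from the tissue axis and assembles one record per cell.
#'
#' @param outlines List of [cell_outline()] objects.
#' @param axis_angle Tissue (mediolateral) axis angle in degrees.
#' @param include_isotropic Keep near-isotropic cells (default TRUE; they
#'   remain flagged).
#' @return data.frame: cell_id, angle_deg, aspect_ratio, deviation_deg,
#'   near_isotropic, plane_depth_um.
#' @export
alignment_table <- function(outlines, axis_angle = 0,
                            include_isotropic = TRUE) {
  rows <- lapply(outlines, function(o) {
    ft <- fit_orientation(o)
    data.frame(cell_id = o$id,
               angle_deg = ft$angle_deg,
               aspect_ratio = ft$aspect_ratio,
               deviation_deg = deviation_from_axis(ft$angle_deg, axis_angle),
               near_isotropic = ft$near_isotropic,
               plane_depth_um = o$plane_depth)
  })
  out <- do.call(rbind, rows)
  if (!include_isotropic) out <- out[!out$near_isotropic, , drop = FALSE]
  out
}
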