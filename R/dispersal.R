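#' Reference axis from anchor points
#'
#' The extension axis of a sample is annotated by a moving tip anchor
#' (placed sparsely in time, e.g. every ten frames, at the extension tip)
#' and one stable back anchor at the round part opposite the extension. All
#' directional decompositions are framed by this axis after projection
#' along z.
#'
#' @param tip data.frame with columns `t`, `x`, `y`, `z` (um): tip anchors.
#' @param back c(x, y, z) um: the stable back anchor.
#' @return An object of class `reference_axis`.
#' @export
reference_axis <- function(tip, back) {
  stopifnot(is.data.frame(tip), all(c("t", "x", "y", "z") %in% names(tip)),
            nrow(tip) >= 1L, length(back) == 3L)
  tip <- tip[order(tip$t), ]
  for (i in seq_len(nrow(tip)))
    if (all(abs(c(tip$x[i], tip$y[i], tip$z[i]) - back) < 1e-9))
      stop("tip anchor coincides with the back anchor at t = ", tip$t[i])
  structure(list(tip = tip, back = as.numeric(back)),
            class = "reference_axis")
}

#' Interpolate the reference axis at analysis frames
#'
#' The tip position is linearly interpolated in time between anchors and
#' held constant beyond the first/last anchor. The axis direction is the
#' unit vector from the back anchor to the interpolated tip after dropping
#' z (projection along the imaging axis); the perpendicular is its 90
#' degree in-plane rotation.
#'
#' @param axis A [reference_axis()].
#' @param times Numeric vector of query times.
#' @return data.frame with `t`, interpolated `tip_x`, `tip_y`, back
#'   coordinates, unit direction `ux`, `uy`, and `axis_length` (back-to-tip
#'   in-plane distance, um).
#' @export
build_reference_axis <- function(axis, times) {
  stopifnot(inherits(axis, "reference_axis"))
  tip <- axis$tip
  interp <- function(v) {
    if (nrow(tip) == 1L) rep(v[1], length(times))
    else approx(tip$t, v, xout = times, rule = 2)$y
  }
  tx <- interp(tip$x); ty <- interp(tip$y)
  dx <- tx - axis$back[1]; dy <- ty - axis$back[2]
  len <- sqrt(dx^2 + dy^2)
  if (any(len < 1e-9))
    stop("degenerate axis: tip and back coincide after projection at t = ",
         times[which(len < 1e-9)[1]])
  data.frame(t = times, tip_x = tx, tip_y = ty,
             back_x = axis$back[1], back_y = axis$back[2],
             ux = dx / len, uy = dy / len, axis_length = len)
}

# mean over j != i of |v_i - v_j|, averaged over i; vectorized O(n^2)
.mean_pairwise_1d <- function(v) {
  n <- length(v)
  mean(rowSums(abs(outer(v, v, "-"))) / (n - 1))
}

#' Clone dispersal curves parallel and perpendicular to the extension axis
#'
#' At each frame, cell positions are projected to the imaging plane
#' (z dropped) and, for every cell, the mean absolute separation from all
#' other clone cells is computed along the axis direction and perpendicular
#' to it; the per-cell means are averaged over the clone. Each series is
#' also reported normalized to its value at the initial time point, so the
#' normalized value at t0 is exactly 1 and the end value is the dispersal
#' fold change.
#'
#' Single-frame track gaps are filled by linear interpolation before the
#' statistic is computed; tracks with longer gaps (or starting after t0)
#' are excluded, mirroring manual track curation.
#'
#' @param clone `nucleus_table` (or data.frame) with columns id, t, x, y, z.
#' @param axis A [reference_axis()].
#' @param t0 Initial time point (default: earliest frame).
#' @return data.frame of class `dispersal_curves`: `t`, `parallel_um`,
#'   `perpendicular_um`, `parallel_norm`, `perpendicular_norm`, `n_cells`.
#' @export
dispersal_curves <- function(clone, axis, t0 = NULL) {
  df <- as.data.frame(clone)
  df <- fill_track_gaps(df, max_gap = 1L)
  times <- sort(unique(df$t))
  t0 <- t0 %||% times[1]
  if (!any(abs(times - t0) < 1e-9)) stop("t0 is not an observed frame")
  # keep only tracks covering the full analysis window
  counts <- table(df$id)
  full <- names(counts)[counts == length(times)]
  df <- df[df$id %in% full, ]
  ax <- build_reference_axis(axis, times)
  out <- data.frame(t = times, parallel_um = NA_real_,
                    perpendicular_um = NA_real_, n_cells = NA_integer_)
  for (k in seq_along(times)) {
    fr <- df[df$t == times[k], ]
    if (nrow(fr) < 2L)
      stop("fewer than 2 cells at frame t = ", times[k])
    s <- fr$x * ax$ux[k] + fr$y * ax$uy[k]
    p <- -fr$x * ax$uy[k] + fr$y * ax$ux[k]
    out$parallel_um[k] <- .mean_pairwise_1d(s)
    out$perpendicular_um[k] <- .mean_pairwise_1d(p)
    out$n_cells[k] <- nrow(fr)
  }
  k0 <- which(abs(times - t0) < 1e-9)
  out$parallel_norm <- out$parallel_um / out$parallel_um[k0]
  out$perpendicular_norm <- out$perpendicular_um / out$perpendicular_um[k0]
  class(out) <- c("dispersal_curves", "data.frame")
  out
}

#' Fill single-frame gaps in cell tracks
#'
#' Missing observations bounded by one frame on either side are linearly
#' interpolated; longer gaps are left missing (such tracks are excluded by
#' [dispersal_curves()]).
#'
#' @param df data.frame with id, t, x, y, z.
#' @param max_gap Largest run of consecutive missing frames to fill.
#' @return The completed data.frame.
#' @export
fill_track_gaps <- function(df, max_gap = 1L) {
  times <- sort(unique(df$t))
  filled <- list()
  for (cid in unique(df$id)) {
    tr <- df[df$id == cid, ]
    tr <- tr[order(tr$t), ]
    present <- times %in% tr$t
    first <- which(present)[1]; last <- tail(which(present), 1)
    inner <- seq(first, last)
    miss <- inner[!present[inner]]
    if (length(miss)) {
      runs <- split(miss, cumsum(c(1, diff(miss) != 1)))
      ok <- unlist(runs[vapply(runs, length, 1L) <= max_gap])
      if (length(ok)) {
        new <- data.frame(id = cid, t = times[ok],
                          x = approx(tr$t, tr$x, times[ok])$y,
                          y = approx(tr$t, tr$y, times[ok])$y,
                          z = approx(tr$t, tr$z, times[ok])$y)
        for (col in setdiff(names(tr), names(new))) new[[col]] <- tr[[col]][1]
        tr <- rbind(tr, new[, names(tr), drop = FALSE])
        tr <- tr[order(tr$t), ]
      }
    }
    filled[[length(filled) + 1L]] <- tr
  }
  common <- Reduce(intersect, lapply(filled, names))
  out <- do.call(rbind, lapply(filled, function(d) d[, common, drop = FALSE]))
  out[order(out$id, out$t), , drop = FALSE]
}

#' Dispersal fold change at a time point
#'
#' The normalized dispersal-curve values at `t_end` (linearly interpolated
#' between frames): the fold change in mean within-clone distance relative
#' to the initial time point, parallel and perpendicular to the axis.
#'
#' @param curves A [dispersal_curves()] result.
#' @param t_end Time at which to read the fold change.
#' @return Named numeric: `parallel`, `perpendicular`.
#' @export
fold_change <- function(curves, t_end) {
  if (t_end < min(curves$t) - 1e-9 || t_end > max(curves$t) + 1e-9)
    stop("t_end outside the curve support")
  c(parallel = approx(curves$t, curves$parallel_norm, t_end)$y,
    perpendicular = approx(curves$t, curves$perpendicular_norm, t_end)$y)
}

#' Tip-distance position correlation between two time points
#'
#' For each cell, the in-plane distance to the interpolated tip normalized
#' by the back-to-tip axis length is computed at t0 and t1; returns the
#' squared Pearson correlation of the paired values. R^2 near 1 indicates
#' that the relative organization of the tissue (cell order along the axis)
#' is preserved during the extension.
#'
#' @param clone `nucleus_table` with id, t, x, y, z.
#' @param axis A [reference_axis()].
#' @param t0,t1 The two time points (must be observed frames).
#' @return Squared Pearson correlation.
#' @export
position_correlation <- function(clone, axis, t0, t1) {
  df <- as.data.frame(clone)
  reldist <- function(tq) {
    fr <- df[abs(df$t - tq) < 1e-9, ]
    if (!nrow(fr)) stop("no cells observed at t = ", tq)
    ax <- build_reference_axis(axis, tq)
    d <- sqrt((fr$x - ax$tip_x)^2 + (fr$y - ax$tip_y)^2) / ax$axis_length
    setNames(d, fr$id)
  }
  d0 <- reldist(t0); d1 <- reldist(t1)
  ids <- intersect(names(d0), names(d1))
  if (length(ids) < 3L) stop("fewer than 3 cells present at both time points")
  cor(d0[ids], d1[ids])^2
}

#' Categorize a clone by its overlap with the mesendoderm domain
#'
#' A clone is `mostly_mesendodermal` when <25% of its cells lie outside the
#' reporter-positive domain, `mostly_ectodermal` when <25% lie inside, and
#' `mixed` when at least 25% lie in both.
#'
#' @param cells data.frame with `x`, `y` in um (one row per cell).
#' @param domain_mask `explant_mask` (or logical matrix) of the
#'   reporter-positive domain.
#' @param calibration Required when `domain_mask` is a bare matrix.
#' @return One of `"mostly_mesendodermal"`, `"mostly_ectodermal"`, `"mixed"`.
#' @export
categorize_clone <- function(cells, domain_mask, calibration = NULL) {
  m <- .mask_of(domain_mask)
  cal <- .cal_of(domain_mask, calibration)
  if (!nrow(cells)) stop("empty clone")
  col <- round(cells$x / cal$xy) + 1L
  row <- round(cells$y / cal$xy) + 1L
  ok <- row >= 1 & row <= nrow(m) & col >= 1 & col <= ncol(m)
  inside <- logical(nrow(cells))
  inside[ok] <- m[cbind(row[ok], col[ok])]
  frac_out <- mean(!inside)
  frac_in <- mean(inside)
  if (frac_out < 0.25) "mostly_mesendodermal"
  else if (frac_in < 0.25) "mostly_ectodermal"
  else "mixed"
}

#' @export
plot.dispersal_curves <- function(x, normalized = TRUE, ...) {
  ycols <- if (normalized) c("parallel_norm", "perpendicular_norm")
           else c("parallel_um", "perpendicular_um")
  ylab <- if (normalized) "mean within-clone distance (fold of t0)"
          else "mean within-clone distance (um)"
  plot(x$t, x[[ycols[1]]], type = "b", pch = 16, xlab = "time (min)",
       ylab = ylab, ylim = range(x[[ycols[1]]], x[[ycols[2]]]), ...)
  lines(x$t, x[[ycols[2]]], type = "b", pch = 1, lty = 2)
  legend("topleft", c("parallel", "perpendicular"), pch = c(16, 1),
         lty = c(1, 2), bty = "n")
  invisible(x)
}
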