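# Nuclear signaling-gradient pipeline: QC filtering, projected distance to a
# reference nucleus contour, cytoplasmic background subtraction, DAPI
# normalization, fixed-width binning with edge exclusion and control
# referencing, top-decile position, domain extent and graded/radial calls.

# separable Gaussian blur of a 3D array, replicate-padded edges
.gauss_blur3 <- function(arr, sigma_xy, sigma_z) {
  blur_dim <- function(a, sigma, d) {
    if (sigma <= 0) return(a)
    r <- max(1L, ceiling(3 * sigma))
    k <- dnorm(-r:r, 0, sigma); k <- k / sum(k)
    perm <- c(d, setdiff(1:3, d))
    ap <- aperm(a, perm)
    dm <- dim(ap)
    m <- matrix(ap, dm[1], dm[2] * dm[3])
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
                m[rep(nrow(m), r), , drop = FALSE])
    f <- stats::filter(mp, k, sides = 2)
    f <- f[(r + 1):(r + dm[1]), , drop = FALSE]
    array(aperm(array(f, dm), order(perm)), dim(a))
  }
  arr <- blur_dim(arr, sigma_xy, 1L)
  arr <- blur_dim(arr, sigma_xy, 2L)
  blur_dim(arr, sigma_z, 3L)
}

# strict local maxima over the 26-neighborhood
.local_maxima3 <- function(a) {
  d <- dim(a)
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
  best <- array(TRUE, d)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    nb <- pad[(2:(d[1] + 1)) + di, (2:(d[2] + 1)) + dj, (2:(d[3] + 1)) + dk]
    best <- best & (a >= nb)
  }
  best
}

#' Detect nuclei in a 3D DAPI stack
#'
#' A minimal difference-of-Gaussians blob detector at the configured
#' nuclear scale: local maxima of the DoG response above a threshold
#' relative to the strongest response. For each detection the mean
#' intensity within a fixed-radius sphere is measured in every supplied
#' channel. Nuclei closer together than the nuclear scale merge into one
#' detection (reported via message).
#'
#' @param dapi_stack 3D array `[y, x, z]`.
#' @param calibration [pixel_calibration()] with z spacing.
#' @param config [run_config()]; the nuclear circle diameter sets the blob
#'   scale.
#' @param channels Named list of further stacks (same dimensions) to
#'   measure, e.g. `list(psmad5 = ...)`.
#' @param threshold Relative DoG threshold in (0, 1] (default 0.25).
#' @return A `nucleus_table` with positions in um and per-channel mean
#'   intensities (`dapi` plus the names of `channels`). Blank stacks give
#'   zero rows.
#' @export
detect_nuclei <- function(dapi_stack, calibration, config = run_config(),
                          channels = list(), threshold = 0.25) {
  stopifnot(length(dim(dapi_stack)) == 3L, !is.null(calibration$z))
  psz <- calibration$xy; pz <- calibration$z
  empty <- function() as_nucleus_table(
    cbind(data.frame(id = integer(), t = numeric(), x = numeric(),
                     y = numeric(), z = numeric(), depth_um = numeric(),
                     dapi = numeric()),
          setNames(rep(list(numeric()), length(channels)), names(channels))),
    calibration)
  if (max(dapi_stack) <= 0) return(empty())
  s1 <- config$nuclear_circle_diameter_px / 2
  s1z <- s1 * psz / pz
  dog <- .gauss_blur3(dapi_stack, s1, s1z) -
    .gauss_blur3(dapi_stack, 1.6 * s1, 1.6 * s1z)
  peaks <- .local_maxima3(dog) & (dog > threshold * max(dog))
  idx <- which(peaks, arr.ind = TRUE)
  if (!nrow(idx)) return(empty())
  # merge maxima closer than the nuclear scale (plateau duplicates)
  ord <- order(-dog[peaks])
  idx <- idx[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(idx))
  merged <- 0L
  for (i in seq_len(nrow(idx))[-1]) {
    prev <- idx[seq_len(i - 1)[keep[seq_len(i - 1)]], , drop = FALSE]
    dd <- sqrt(((prev[, 1] - idx[i, 1]) * 1)^2 +
               ((prev[, 2] - idx[i, 2]) * 1)^2 +
               ((prev[, 3] - idx[i, 3]) * pz / psz)^2)
    if (any(dd < 2.5 * s1)) { keep[i] <- FALSE; merged <- merged + 1L }
  }
  if (merged > 0L)
    message(sprintf("detect_nuclei: merged %d detections within the nuclear scale",
                    merged))
  idx <- idx[keep, , drop = FALSE]
  # sphere means per channel
  r <- s1
  d <- dim(dapi_stack)
  sphere_mean <- function(stack, row, col, plane) {
    rs <- max(1, floor(row - r)):min(d[1], ceiling(row + r))
    cs <- max(1, floor(col - r)):min(d[2], ceiling(col + r))
    zs <- max(1, floor(plane - s1z)):min(d[3], ceiling(plane + s1z))
    sel <- outer(outer((rs - row)^2 / r^2, (cs - col)^2 / r^2, "+"),
                 (zs - plane)^2 / max(s1z, 0.5)^2, "+") <= 1
    vals <- stack[rs, cs, zs, drop = FALSE]
    mean(vals[sel])
  }
  out <- data.frame(id = seq_len(nrow(idx)), t = 0,
                    x = (idx[, 2] - 1) * psz,
                    y = (idx[, 1] - 1) * psz,
                    z = (idx[, 3] - 1) * pz)
  out$depth_um <- out$z
  out$dapi <- vapply(seq_len(nrow(idx)), function(i)
    sphere_mean(dapi_stack, idx[i, 1], idx[i, 2], idx[i, 3]), 0)
  for (nm in names(channels))
    out[[nm]] <- vapply(seq_len(nrow(idx)), function(i)
      sphere_mean(channels[[nm]], idx[i, 1], idx[i, 2], idx[i, 3]), 0)
  as_nucleus_table(out, calibration)
}

#' Quality-control filter for nucleus tables
#'
#' Removes nuclei carrying any exclusion flag (enveloping layer, yolk
#' syncytial layer, inhomogeneous DAPI, dividing) and restricts the
#' analyzed depth window: up to 180 um from the top for explants, 60-120 um
#' from the animal pole for embryos (the run config's `depth_limits`).
#' Removal counts per reason are reported and attached as an attribute.
#'
#' @param table A `nucleus_table`; depth is taken from `depth_um` (or `z`).
#' @param config A [run_config()].
#' @return The filtered table with `attr(, "removed")` (a named count
#'   vector).
#' @export
qc_filter <- function(table, config = run_config()) {
  df <- table
  flags <- intersect(c("enveloping_layer", "ysl", "inhomogeneous_dapi",
                       "dividing"), names(df))
  removed <- c()
  drop <- rep(FALSE, nrow(df))
  for (fl in flags) {
    v <- as.logical(df[[fl]])
    removed[fl] <- sum(v & !drop)
    drop <- drop | v
  }
  depth <- df$depth_um %||% df$z
  out_of_range <- depth < config$depth_limits[1] |
    depth > config$depth_limits[2]
  removed["depth"] <- sum(out_of_range & !drop)
  drop <- drop | out_of_range
  message(sprintf("qc_filter: removed %d of %d nuclei (%s)",
                  sum(drop), nrow(df),
                  paste(names(removed), removed, sep = "=", collapse = ", ")))
  out <- df[!drop, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Projected distance of each nucleus to the reference contour
#'
#' All nuclei and the contour points are projected along z; each nucleus'
#' distance is the minimum Euclidean distance to any reference point, and
#' the normalized distance divides by the maximum distance within the
#' sample (so the farthest nucleus sits at exactly 1).
#'
#' @param table A `nucleus_table` (>= 2 nuclei, else normalization is
#'   undefined).
#' @param contour data.frame with `x`, `y` (um) reference points; the line
#'   of nuclei drawn on the high-intensity side.
#' @return The table with `dist_um` and `dist_norm` columns added.
#' @export
distance_to_reference <- function(table, contour) {
  if (!nrow(contour)) stop("empty reference contour")
  if (nrow(table) < 2L)
    stop("normalized distance undefined for a single nucleus")
  cx <- contour$x; cy <- contour$y
  d <- vapply(seq_len(nrow(table)), function(i)
    sqrt(min((table$x[i] - cx)^2 + (table$y[i] - cy)^2)), 0)
  table$dist_um <- d
  table$dist_norm <- d / max(d)
  table
}

#' Cytoplasmic background subtraction
#'
#' The channel background is the mean of the cytoplasmic spot means
#' (12 spots placed on the low-intensity side at the bottom of the analysis
#' volume; for dual stainings, 12 per side). Corrected intensity is the raw
#' value minus the background, clamped at zero.
#'
#' @param table A `nucleus_table`.
#' @param spot_means Numeric vector of spot means (single channel) or a
#'   named list per channel.
#' @param channels Channel column names to correct (default `"psmad5"`).
#' @return The table with `<channel>_corrected` columns; backgrounds are in
#'   `attr(, "background")`.
#' @export
background_subtract <- function(table, spot_means, channels = "psmad5") {
  if (!is.list(spot_means)) spot_means <- setNames(list(spot_means), channels)
  bgs <- c()
  for (ch in channels) {
    sm <- spot_means[[ch]]
    if (is.null(sm) || !length(sm)) stop("no background spots for channel ", ch)
    bg <- mean(sm)
    corrected <- table[[ch]] - bg
    n_clamp <- sum(corrected < 0)
    if (n_clamp > 0)
      warning(sprintf("%s: background exceeds signal for %d nuclei; clamped at 0",
                      ch, n_clamp))
    table[[paste0(ch, "_corrected")]] <- pmax(corrected, 0)
    bgs[ch] <- bg
    message(sprintf("background_subtract: %s background = %.4g (%d spots)",
                    ch, bg, length(sm)))
  }
  attr(table, "background") <- bgs
  table
}

#' Binned, normalized signaling-gradient profile
#'
#' Per nucleus the DAPI-normalized ratio corrected/DAPI is computed (DAPI
#' normalization cancels depth-dependent imaging attenuation); nuclei are
#' assigned to half-open normalized-distance bins `[k*w, (k+1)*w)` (last
#' bin closed), bin 0 anchored at the reference-contour (high-intensity)
#' side. The first and last `edge_fraction` of the axis are excluded from
#' the reported curve (few nuclei live there owing to sample curvature):
#' one bin per edge at w = 0.04, two at w = 0.02. Reported values are
#' divided by the reference value: the supplied control reference, or the
#' sample's own designated bin (the first reported bin) with a logged
#' notice.
#'
#' @param table A `nucleus_table` with `dist_norm` and corrected
#'   intensities (see [distance_to_reference()], [background_subtract()]).
#' @param config A [run_config()] (bin width, edge fraction).
#' @param value_col Corrected intensity column (default
#'   `"psmad5_corrected"`).
#' @param dapi_col DAPI column.
#' @param reference Control reference value (> 0), e.g. from
#'   [control_reference()]; `NULL` self-references.
#' @return data.frame of class `gradient_profile`: `bin`, `bin_center`,
#'   `mean_ratio` (raw per-bin mean), `intensity` (referenced; `NA` in
#'   excluded or empty bins), `n`, `excluded`. Attributes: `bin_width`,
#'   `reference_value`, `designated_bin_mean`, `edge_bins`.
#' @export
build_profile <- function(table, config = run_config(),
                          value_col = "psmad5_corrected",
                          dapi_col = "dapi", reference = NULL) {
  if (is.null(table$dist_norm)) stop("run distance_to_reference() first")
  if (is.null(table[[value_col]]))
    stop("missing corrected intensity column ", value_col)
  w <- config$bin_width
  nb <- round(1 / w)
  ratio <- table[[value_col]] / table[[dapi_col]]
  bin <- pmin(floor(table$dist_norm / w), nb - 1L)  # last bin closed
  mean_ratio <- rep(NA_real_, nb)
  counts <- integer(nb)
  agg <- tapply(ratio, factor(bin, levels = 0:(nb - 1)), mean)
  cnt <- tapply(ratio, factor(bin, levels = 0:(nb - 1)), length)
  mean_ratio <- as.numeric(agg)
  counts <- ifelse(is.na(cnt), 0L, as.integer(cnt))
  n_edge <- max(1L, round(config$edge_fraction / w))
  excluded <- rep(FALSE, nb)
  excluded[seq_len(n_edge)] <- TRUE
  excluded[nb - seq_len(n_edge) + 1L] <- TRUE
  designated <- mean_ratio[n_edge + 1L]   # first reported bin
  if (is.null(reference)) {
    message("build_profile: self-referencing to the sample's designated bin")
    reference <- designated
  }
  if (is.na(reference) || reference <= 0)
    stop("reference value must be positive")
  interior_empty <- which(counts == 0 & !excluded)
  if (length(interior_empty))
    message(sprintf("build_profile: %d empty interior bin(s): %s",
                    length(interior_empty),
                    paste(interior_empty - 1L, collapse = ", ")))
  out <- data.frame(bin = 0:(nb - 1),
                    bin_center = (0:(nb - 1) + 0.5) * w,
                    mean_ratio = mean_ratio,
                    intensity = ifelse(excluded, NA_real_, mean_ratio / reference),
                    n = counts,
                    excluded = excluded)
  attr(out, "bin_width") <- w
  attr(out, "reference_value") <- reference
  attr(out, "designated_bin_mean") <- designated
  attr(out, "edge_bins") <- n_edge
  class(out) <- c("gradient_profile", "data.frame")
  out
}

#' Control reference value across replicates
#'
#' The reference value is computed per replicate from the control group's
#' designated high-intensity end bin (the first reported bin of each
#' control profile) and averaged across replicates.
#'
#' @param profiles List of control-group [build_profile()] results (one per
#'   replicate).
#' @return Mean designated-bin raw ratio.
#' @export
control_reference <- function(profiles) {
  vals <- vapply(profiles, function(p) attr(p, "designated_bin_mean"), 0)
  if (anyNA(vals)) stop("a control profile has an empty designated bin")
  mean(vals)
}

#' Mean normalized position of the top-decile intensity nuclei
#'
#' Ranks nuclei by DAPI-normalized corrected intensity, takes the
#' `ceiling(0.10 n)` highest (including all values tied with the k-th rank,
#' reported via message), and returns the mean of their normalized
#' distances. A gradient hugging the reference side gives a small value; a
#' spread-out domain of high signal pushes it up.
#'
#' @param table A `nucleus_table` with `dist_norm` and corrected intensity.
#' @param value_col,dapi_col Intensity columns.
#' @return Mean normalized distance of the top-decile nuclei.
#' @export
top_decile_position <- function(table, value_col = "psmad5_corrected",
                                dapi_col = "dapi") {
  n <- nrow(table)
  if (n < 10L) stop("need >= 10 nuclei for a top-decile statistic")
  intensity <- table[[value_col]] / table[[dapi_col]]
  k <- ceiling(0.10 * n)
  kth <- sort(intensity, decreasing = TRUE)[k]
  sel <- intensity >= kth - 1e-12
  if (sum(sel) > k)
    message(sprintf("top_decile_position: %d nuclei tie at the cutoff; all included",
                    sum(sel)))
  mean(table$dist_norm[sel])
}

#' Ratio of a perturbed top-decile position to its control
#'
#' @param positions Top-decile positions of the perturbed samples.
#' @param control_positions Positions of the corresponding controls.
#' @return mean(positions) / mean(control_positions).
#' @export
ratio_to_control <- function(positions, control_positions) {
  mean(positions) / mean(control_positions)
}

#' Normalized extent of a signaling or expression domain
#'
#' Positions nuclei along the normalized back-to-tip axis (their normalized
#' reference distance) and finds where the positivity rule holds: for a
#' signaling domain anchored at the back (`kind = "psmad5"`) the extent is
#' the farthest positive position; for a reporter domain entered from the
#' tip (`kind = "egfp"`) it is the first positive position. The default
#' positivity rule calls a nucleus positive when its DAPI-normalized
#' corrected ratio exceeds the mean + `k_sd` sd of the low-side background
#' nuclei (the `low_side_fraction` of the axis farthest from the
#' reference).
#'
#' @param table A `nucleus_table` with `dist_norm` and corrected intensity.
#' @param kind `"psmad5"` or `"egfp"`.
#' @param value_col,dapi_col Intensity columns.
#' @param threshold Explicit positivity threshold on the ratio; overrides
#'   the rule.
#' @param low_side_fraction Fraction of the axis treated as background.
#' @param k_sd Multiplier on the background sd.
#' @return Normalized extent in `[0, 1]` (0 with a warning when nothing is
#'   positive); the threshold used is attached as an attribute.
#' @export
domain_extent <- function(table, kind = c("psmad5", "egfp"),
                          value_col = "psmad5_corrected", dapi_col = "dapi",
                          threshold = NULL, low_side_fraction = 0.2,
                          k_sd = 2) {
  kind <- match.arg(kind)
  ratio <- table[[value_col]] / table[[dapi_col]]
  s <- table$dist_norm
  if (is.null(threshold)) {
    low <- ratio[s >= 1 - low_side_fraction]
    if (length(low) < 3L) stop("too few low-side nuclei to set a threshold")
    threshold <- mean(low) + k_sd * sd(low)
  }
  pos <- ratio > threshold
  if (!any(pos)) {
    warning("no positive signal; extent = 0")
    return(structure(0, threshold = threshold))
  }
  ext <- if (kind == "psmad5") max(s[pos]) else min(s[pos])
  structure(ext, threshold = threshold)
}

#' Domain extent along the central line of a binary mask
#'
#' Mask-based variant of [domain_extent()]: fraction of the back-to-tip
#' line at which the domain ends (farthest positive pixel within one pixel
#' of the line).
#'
#' @param domain_mask `explant_mask` or logical matrix of the positive
#'   domain.
#' @param back_point,tip_point c(x, y) um landmarks.
#' @param calibration Required for a bare matrix.
#' @return Normalized extent in `[0, 1]`.
#' @export
domain_extent_mask <- function(domain_mask, back_point, tip_point,
                               calibration = NULL) {
  m <- .mask_of(domain_mask)
  cal <- .cal_of(domain_mask, calibration)
  psz <- cal$xy
  u <- (tip_point - back_point)
  len <- sqrt(sum(u^2))
  if (len < 1e-9) stop("degenerate back/tip landmarks")
  u <- u / len
  g <- pixel_grid(m)
  relx <- g$x[m] * psz - back_point[1]
  rely <- g$y[m] * psz - back_point[2]
  s <- relx * u[1] + rely * u[2]
  perp <- abs(-relx * u[2] + rely * u[1])
  on_line <- perp <= psz
  if (!any(on_line)) {
    warning("no positive signal on the central line; extent = 0")
    return(0)
  }
  min(max(s[on_line]) / len, 1)
}

#' Classify a gradient profile as graded or radial
#'
#' Operationalizes the visual call: a profile is `graded` when the
#' high-side mean of the first three reported bins exceeds the low-side
#' mean of the last three by at least `ratio_threshold` AND the Spearman
#' trend of intensity against position is negative with |rho| >=
#' `rho_threshold`; otherwise `radial` (uniformly elevated). Empty bins in
#' the end windows widen the window to the next reported bins (logged).
#'
#' @param profile A [build_profile()] result with >= 5 reported bins.
#' @param ratio_threshold High/low ratio threshold (default 2).
#' @param rho_threshold Minimum |Spearman rho| (default 0.5).
#' @return List: `class` (`"graded"` or `"radial"`), `high_low_ratio`,
#'   `spearman_rho`.
#' @export
classify_profile <- function(profile, ratio_threshold = 2,
                             rho_threshold = 0.5) {
  rep_rows <- !profile$excluded & !is.na(profile$intensity)
  if (sum(rep_rows) < 5L) stop("need >= 5 reported bins")
  if (any(!profile$excluded & is.na(profile$intensity)))
    message("classify_profile: empty interior bins skipped; end windows widened")
  v <- profile$intensity[rep_rows]
  pos <- profile$bin_center[rep_rows]
  high <- mean(head(v, 3))
  low <- mean(tail(v, 3))
  ratio <- high / low
  rho <- suppressWarnings(cor(pos, v, method = "spearman"))
  cls <- if (is.finite(ratio) && ratio >= ratio_threshold &&
             !is.na(rho) && rho <= -rho_threshold) "graded" else "radial"
  list(class = cls, high_low_ratio = ratio, spearman_rho = rho)
}

#' Fit an exponential decay length to a reported profile
#'
#' Least-squares fit of `A * exp(-u / lambda)` to the reported bin means
#' (nls with a log-linear fallback); used to recover the gradient range
#' from binned data.
#'
#' @param profile A [build_profile()] result.
#' @return Estimated decay length (fraction of the axis).
#' @export
fit_exponential_profile <- function(profile) {
  ok <- !profile$excluded & !is.na(profile$intensity)
  u <- profile$bin_center[ok]
  v <- profile$intensity[ok]
  fit <- tryCatch({
    st <- list(A = max(v), lambda = 0.3)
    coef(nls(v ~ A * exp(-u / lambda), start = st,
             control = nls.control(warnOnly = TRUE)))[["lambda"]]
  }, error = function(e) NA_real_)
  if (is.na(fit) || fit <= 0) {
    pos <- v > 0
    fit <- -1 / coef(lm(log(v[pos]) ~ u[pos]))[[2]]
  }
  fit
}

#' @export
plot.gradient_profile <- function(x, ...) {
  ok <- !x$excluded & !is.na(x$intensity)
  plot(x$bin_center[ok], x$intensity[ok], type = "b", pch = 16,
       xlab = "normalized distance from high-intensity side",
       ylab = "intensity (relative to reference bin)", ...)
  invisible(x)
}
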