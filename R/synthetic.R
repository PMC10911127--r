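# Synthetic-data generators. Every generator returns the generated artifact
# together with a ground-truth record sufficient to replay the forward model,
# so each analysis stage can be tested against construction.

#' Anisotropic flow parameters for clone-advection fixtures
#'
#' The flow is a time-interpolated affine map: positions relative to the
#' clone centroid are scaled by `s_par^(k/(n_frames-1))` along the extension
#' axis and `s_perp^(...)` perpendicular to it at frame k (exponential-in-
#' time scaling, the simplest flow matching endpoint fold changes). Defaults
#' are the wild-type mesendoderm regime: 2.02-fold parallel and 0.88-fold
#' perpendicular over 260 min.
#'
#' @param s_par,s_perp Axial / perpendicular scale factor over the whole
#'   duration (> 0).
#' @param n_cells Number of clone cells (>= 2).
#' @param n_frames Number of frames (>= 2).
#' @param frame_dt Minutes between frames.
#' @param positional_noise_sd Per-frame Gaussian positional noise, um.
#' @param axis_drift_sd Gaussian jitter of the emitted tip anchors, um.
#' @param seed Integer seed.
#' @return An object of class `flow_params`.
#' @export
flow_params <- function(s_par = 2.02, s_perp = 0.88, n_cells = 60L,
                        n_frames = 14L, frame_dt = 20,
                        positional_noise_sd = 0, axis_drift_sd = 0,
                        seed = 1L) {
  if (s_par <= 0 || s_perp <= 0) stop("scale factors must be positive")
  if (n_cells < 2L) stop("n_cells must be >= 2")
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (positional_noise_sd < 0 || axis_drift_sd < 0)
    stop("noise sd must be >= 0")
  structure(list(s_par = s_par, s_perp = s_perp,
                 n_cells = as.integer(n_cells),
                 n_frames = as.integer(n_frames), frame_dt = frame_dt,
                 positional_noise_sd = positional_noise_sd,
                 axis_drift_sd = axis_drift_sd, seed = as.integer(seed)),
            class = "flow_params")
}

#' Flow presets for the measured dispersal regimes
#'
#' Noise-free parameter sets matching the printed clone-dispersal fold
#' changes: wild-type mesendoderm (2.02 parallel / 0.88 perpendicular over
#' 260 min), wild-type ectoderm (1.12 / 0.83 over 260 min), and the early-
#' phase mesendoderm and ectoderm regimes (1.2 and 0.99 parallel over
#' 122 min).
#'
#' @param name Preset name.
#' @param ... Overrides passed to [flow_params()].
#' @return A `flow_params`.
#' @export
flow_preset <- function(name = c("wildtype_mesendoderm", "wildtype_ectoderm",
                                 "early_mesendoderm", "early_ectoderm"),
                        ...) {
  name <- match.arg(name)
  base <- switch(name,
    wildtype_mesendoderm = list(s_par = 2.02, s_perp = 0.88,
                                n_frames = 14L, frame_dt = 20),
    wildtype_ectoderm    = list(s_par = 1.12, s_perp = 0.83,
                                n_frames = 14L, frame_dt = 20),
    early_mesendoderm    = list(s_par = 1.20, s_perp = 1.00,
                                n_frames = 7L,  frame_dt = 122 / 6),
    early_ectoderm       = list(s_par = 0.99, s_perp = 1.00,
                                n_frames = 7L,  frame_dt = 122 / 6))
  do.call(flow_params, utils::modifyList(base, list(...)))
}

#' Gradient parameters for nucleus-table fixtures
#'
#' @param profile_shape `"exponential"`, `"logistic"` or `"flat"` spatial
#'   profile f(u) of normalized distance u from the high-intensity side.
#' @param decay_length Exponential decay length (or logistic steepness) as a
#'   fraction of the axis.
#' @param amplitude Signal amplitude at u = 0, arbitrary units.
#' @param background_level Additive cytoplasmic background, a.u.
#' @param dapi_mean Mean DAPI intensity, a.u.
#' @param dapi_cv,intensity_cv Coefficients of variation of the DAPI and
#'   signal channels (0 <= cv < 1).
#' @param n_nuclei Number of nuclei.
#' @param depth_attenuation Fractional intensity loss per 100 um of depth,
#'   applied multiplicatively to both channels (so DAPI normalization can
#'   cancel it).
#' @param seed Integer seed.
#' @return An object of class `gradient_params`.
#' @export
gradient_params <- function(profile_shape = c("exponential", "logistic", "flat"),
                            decay_length = 0.25, amplitude = 100,
                            background_level = 20, dapi_mean = 50,
                            dapi_cv = 0.1, intensity_cv = 0.1,
                            n_nuclei = 800L, depth_attenuation = 0,
                            seed = 1L) {
  profile_shape <- match.arg(profile_shape)
  if (amplitude < 0) stop("amplitude must be >= 0")
  for (cv in c(dapi_cv, intensity_cv))
    if (cv < 0 || cv >= 1) stop("coefficients of variation must lie in [0, 1)")
  if (decay_length <= 0) stop("decay_length must be positive")
  structure(list(profile_shape = profile_shape, decay_length = decay_length,
                 amplitude = amplitude, background_level = background_level,
                 dapi_mean = dapi_mean, dapi_cv = dapi_cv,
                 intensity_cv = intensity_cv, n_nuclei = as.integer(n_nuclei),
                 depth_attenuation = depth_attenuation,
                 seed = as.integer(seed)),
            class = "gradient_params")
}

#' Orientation-field parameters for cell-outline fixtures
#'
#' Orientations are axial (period 180 degrees) and drawn from a wrapped
#' normal distribution on the doubled angle with standard deviation
#' `1/sqrt(concentration)`; `concentration = 0` gives the uniform
#' distribution and `Inf` puts every cell exactly at the mean.
#'
#' @param mean_angle Mean orientation in degrees, in `[-90, 90)`.
#' @param concentration Concentration parameter (>= 0).
#' @param n_cells Number of cells.
#' @param aspect_ratio_range Two-element range of ellipse aspect ratios
#'   (each >= 1).
#' @param seed Integer seed.
#' @return An object of class `orientation_params`.
#' @export
orientation_params <- function(mean_angle = 0, concentration = 4,
                               n_cells = 100L,
                               aspect_ratio_range = c(1.5, 3), seed = 1L) {
  if (mean_angle < -90 || mean_angle >= 90)
    stop("mean_angle must lie in [-90, 90)")
  if (concentration < 0) stop("concentration must be >= 0")
  if (any(aspect_ratio_range < 1)) stop("aspect ratios must be >= 1")
  structure(list(mean_angle = mean_angle, concentration = concentration,
                 n_cells = as.integer(n_cells),
                 aspect_ratio_range = aspect_ratio_range,
                 seed = as.integer(seed)),
            class = "orientation_params")
}

#' Generate a synthetic explant silhouette mask
#'
#' Builds a single-component silhouette of a round body (an ellipse of the
#' requested width) joined, when `extension_fraction > 0`, to a narrower
#' capsule-shaped lobe at a concave neck. The lobe half-width is the body
#' half-width minus `indentation_depth`, and the neck sits exactly
#' `extension_fraction * length_um` from the lobe tip, so the ground truth
#' stores the true extension length and indentation point by construction.
#'
#' @param length_um Total silhouette length (back to tip), um.
#' @param width_um Body width, um.
#' @param extension_fraction Fraction of the length taken by the extension,
#'   in `[0, 1)`. 0 gives a convex ellipse (a disk when
#'   `width_um == length_um`).
#' @param indentation_depth How much narrower the lobe is than the body
#'   half-width, um.
#' @param calibration A [pixel_calibration()].
#' @param seed Integer seed (recorded; the construction is deterministic).
#' @return A list: `mask` (an [explant_mask()] with the indentation point
#'   left unset so detection can be tested) and `truth` (extension length,
#'   normalized extension, indentation point, area).
#' @export
make_explant_mask <- function(length_um, width_um, extension_fraction = 0,
                              indentation_depth = 50,
                              calibration = pixel_calibration(2),
                              seed = 1L) {
  if (extension_fraction < 0 || extension_fraction >= 1)
    stop("extension_fraction must lie in [0, 1)")
  psz <- calibration$xy
  b <- width_um / 2
  margin <- 4 * psz
  L <- length_um
  f <- extension_fraction
  nx <- ceiling((L + 2 * margin) / psz)
  ny <- ceiling((width_um + 2 * margin) / psz)
  g <- pixel_grid(matrix(FALSE, ny, nx))
  X <- g$x * psz - margin        # shape frame: back of the body at x = 0
  Y <- g$y * psz - margin - b    # axis at y = 0
  if (f == 0) {
    a <- L / 2
    m <- ((X - a) / a)^2 + (Y / b)^2 <= 1
    truth <- list(extension_length_um = 0, extension_fraction = 0,
                  indentation_point = NULL)
  } else {
    w_e <- b - indentation_depth
    if (w_e <= 0)
      stop("self-intersecting geometry: indentation_depth >= half-width")
    x_ind <- L * (1 - f)
    if (x_ind <= 0) stop("extension_fraction leaves no body")
    k <- sqrt(1 - (w_e / b)^2)
    a <- x_ind / (1 + k)         # ellipse through (x_ind, +/- w_e), back at 0
    body <- ((X - a) / a)^2 + (Y / b)^2 <= 1
    lobe <- (X >= x_ind - psz) & (X <= L - w_e) & (abs(Y) <= w_e)
    cap <- (X - (L - w_e))^2 + Y^2 <= w_e^2
    m <- body | lobe | cap
    truth <- list(extension_length_um = f * L, extension_fraction = f,
                  indentation_point = c(x_ind + margin, b + margin))
  }
  truth$length_um <- L
  truth$width_um <- width_um
  truth$area_um2 <- sum(m) * psz^2
  truth$seed <- seed
  list(mask = explant_mask(m, calibration), truth = truth)
}

#' Simulate a tracked clone advected by an anisotropic affine flow
#'
#' Cells start in a compact uniform disk; at frame k the initial offsets
#' from the clone centroid are scaled by `s_par^(k/(n_frames-1))` along +x
#' and `s_perp^(...)` along +y, plus Gaussian positional noise. A reference
#' axis is emitted with a stable back anchor and tip anchors every ten
#' frames (jittered by `axis_drift_sd`), mirroring how the extension axis
#' is annotated on real time-lapse data.
#'
#' @param params A [flow_params()].
#' @return A list: `table` (tracked `nucleus_table`: id, t, x, y, z, label),
#'   `axis` (a [reference_axis()]), `truth` (scale factors and per-frame
#'   scaling).
#' @export
simulate_clone_flow <- function(params) {
  stopifnot(inherits(params, "flow_params"))
  set.seed(params$seed)
  K <- params$n_frames
  n <- params$n_cells
  centre <- c(300, 150)
  r0 <- 50
  rr <- r0 * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  dx <- rr * cos(th); dy <- rr * sin(th)
  z0 <- runif(n, 0, 60)
  times <- (seq_len(K) - 1L) * params$frame_dt
  alpha <- params$s_par^((seq_len(K) - 1) / (K - 1))
  beta <- params$s_perp^((seq_len(K) - 1) / (K - 1))
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    ns <- params$positional_noise_sd
    rows[[k]] <- data.frame(
      id = seq_len(n), t = times[k],
      x = centre[1] + dx * alpha[k] + rnorm(n, 0, ns),
      y = centre[2] + dy * beta[k] + rnorm(n, 0, ns),
      z = z0 + rnorm(n, 0, ns),
      label = "mesendoderm")
  }
  tbl <- as_nucleus_table(do.call(rbind, rows))
  anchor_frames <- unique(c(seq(1L, K, by = 10L), K))
  tip <- data.frame(
    t = times[anchor_frames],
    x = centre[1] + (r0 + 100) * alpha[anchor_frames] +
      rnorm(length(anchor_frames), 0, params$axis_drift_sd),
    y = centre[2] + rnorm(length(anchor_frames), 0, params$axis_drift_sd),
    z = 30)
  ax <- reference_axis(tip, back = c(50, centre[2], 30))
  truth <- list(s_par = params$s_par, s_perp = params$s_perp,
                scale_par = alpha, scale_perp = beta, times = times,
                axis_angle = 0, centre = centre)
  list(table = tbl, axis = ax, truth = truth)
}

.gradient_shape_fun <- function(shape, decay) {
  switch(shape,
         exponential = function(u) exp(-u / decay),
         logistic = function(u) 1 / (1 + exp((u - 0.5) / (decay / 4))),
         flat = function(u) rep(1, length(u)))
}

#' Simulate a gradient-bearing nucleus table
#'
#' Nuclei are placed uniformly in a box of the given geometry; the signal
#' channel is `amplitude * f(u) * atten(z) + background + noise` with u the
#' normalized distance from the high-intensity side (x = 0) and
#' `atten(z) = (1 - depth_attenuation)^(z/100)`; the DAPI channel carries
#' the same depth attenuation, so the signal/DAPI ratio cancels it. A dense
#' reference contour along x = 0 and a set of cytoplasmic background spot
#' means are emitted alongside.
#'
#' @param params A [gradient_params()].
#' @param geometry List with `axis_length_um`, `width_um`,
#'   `depth_range_um` (2-vector).
#' @param n_background_spots Number of emitted background spot means.
#' @return A list: `table` (`nucleus_table` with dapi/psmad5 intensities and
#'   QC flag columns), `contour` (reference contour data.frame),
#'   `background_spots` (numeric spot means), `truth` (per-nucleus f and u,
#'   plus the parameters).
#' @export
simulate_gradient_nuclei <- function(params,
                                     geometry = list(axis_length_um = 500,
                                                     width_um = 200,
                                                     depth_range_um = c(0, 60)),
                                     n_background_spots = 12L) {
  stopifnot(inherits(params, "gradient_params"))
  set.seed(params$seed)
  n <- params$n_nuclei
  L <- geometry$axis_length_um
  x <- runif(n, 0, L)
  y <- runif(n, 0, geometry$width_um)
  z <- runif(n, geometry$depth_range_um[1], geometry$depth_range_um[2])
  u <- x / L
  f <- .gradient_shape_fun(params$profile_shape, params$decay_length)(u)
  atten <- (1 - params$depth_attenuation)^(z / 100)
  signal <- params$amplitude * f * atten * (1 + rnorm(n, 0, params$intensity_cv)) +
    params$background_level
  dapi <- params$dapi_mean * atten * (1 + rnorm(n, 0, params$dapi_cv))
  tbl <- as_nucleus_table(data.frame(
    id = seq_len(n), t = 0, x = x, y = y, z = z, depth_um = z,
    dapi = pmax(dapi, 0), psmad5 = pmax(signal, 0),
    enveloping_layer = FALSE, ysl = FALSE, inhomogeneous_dapi = FALSE,
    dividing = FALSE,
    sample = "synthetic", condition = "control", replicate = 1L))
  contour <- data.frame(point_index = seq(0, geometry$width_um, by = 1),
                        x = 0, y = seq(0, geometry$width_um, by = 1),
                        z = mean(geometry$depth_range_um))
  spots <- params$background_level *
    (1 + rnorm(n_background_spots, 0, params$intensity_cv))
  truth <- list(u = u, f = f, params = unclass(params), geometry = geometry)
  list(table = tbl, contour = contour, background_spots = spots,
       truth = truth)
}

# axial wrapped-normal sampler on [-90, 90): doubled-angle wrapped normal
.sample_axial <- function(n, mean_deg, concentration) {
  if (concentration == 0) return(runif(n, -90, 90))
  if (!is.finite(concentration)) return(rep(mean_deg, n))
  phi <- 2 * mean_deg * pi / 180 + rnorm(n, 0, 1 / sqrt(concentration))
  phi <- ((phi + pi) %% (2 * pi)) - pi
  th <- phi / 2 * 180 / pi
  ifelse(th >= 90, th - 180, th)
}

#' Simulate cell outlines with a controlled orientation field
#'
#' Generates polygonal ellipse outlines (48 vertices) whose long-axis
#' orientations are drawn from the axial wrapped distribution of
#' [orientation_params()]. Aspect ratios are uniform in the requested range
#' at constant cell area (radius 10 um circle-equivalent); circles
#' (aspect ratio 1) have undefined orientation, marked `NA` in the truth.
#'
#' @param params An [orientation_params()].
#' @param depth_range_um Range of plane depths assigned to the cells.
#' @return A list: `outlines` (list of [cell_outline()]), `truth`
#'   (data.frame with cell_id, angle_deg, aspect_ratio, plane_depth_um).
#' @export
simulate_cell_outlines <- function(params, depth_range_um = c(30, 75)) {
  stopifnot(inherits(params, "orientation_params"))
  set.seed(params$seed)
  n <- params$n_cells
  angles <- .sample_axial(n, params$mean_angle, params$concentration)
  ar <- runif(n, params$aspect_ratio_range[1], params$aspect_ratio_range[2])
  depth <- runif(n, depth_range_um[1], depth_range_um[2])
  side <- ceiling(sqrt(n))
  tv <- seq(0, 2 * pi, length.out = 49L)[-49L]
  outlines <- vector("list", n)
  for (i in seq_len(n)) {
    a <- 10 * sqrt(ar[i]); b <- 10 / sqrt(ar[i])
    th <- angles[i] * pi / 180
    ex <- a * cos(tv); ey <- b * sin(tv)
    cx <- ((i - 1) %% side) * 50 + 25
    cy <- ((i - 1) %/% side) * 50 + 25
    vx <- cx + ex * cos(th) - ey * sin(th)
    vy <- cy + ex * sin(th) + ey * cos(th)
    outlines[[i]] <- cell_outline(cbind(vx, vy), plane_depth = depth[i],
                                  nucleus_center = c(cx, cy), id = i)
  }
  truth <- data.frame(cell_id = seq_len(n),
                      angle_deg = ifelse(abs(ar - 1) < 1e-12, NA_real_, angles),
                      aspect_ratio = ar, plane_depth_um = depth)
  list(outlines = outlines, truth = truth)
}

#' Render nucleus positions into a multi-channel image stack
#'
#' Renders each nucleus as a 3D Gaussian blob (amplitude = its channel
#' intensity) with Poisson photon noise plus Gaussian read noise at the
#' stated SNR (peak amplitude / read-noise sd). With zero nuclei a blank
#' stack is returned.
#'
#' @param table `nucleus_table` with intensity columns among dapi, psmad5,
#'   psmad2.
#' @param calibration [pixel_calibration()] with z spacing.
#' @param canvas_px Optional c(nx, ny, nz); defaults to fit the geometry.
#'   An error is raised if the requested canvas cannot hold it.
#' @param blob_sd_um Gaussian blob sd in um (isotropic).
#' @param snr Peak signal-to-read-noise ratio; `Inf` disables noise.
#' @param seed Integer seed for the noise.
#' @return A list: `channels` (named list of `[y, x, z]` arrays),
#'   `centers_px` (ground-truth 0-based pixel centres), `calibration`.
#' @export
render_channels <- function(table, calibration, canvas_px = NULL,
                            blob_sd_um = 3, snr = 20, seed = 1L) {
  stopifnot(inherits(calibration, "pixel_calibration"),
            !is.null(calibration$z))
  chan_names <- intersect(c("dapi", "psmad5", "psmad2"), names(table))
  psz <- calibration$xy; pz <- calibration$z
  margin_um <- 4 * blob_sd_um
  n <- nrow(table)
  if (n == 0L) {
    if (is.null(canvas_px)) canvas_px <- c(32L, 32L, 4L)
    ch <- lapply(chan_names %||% "dapi",
                 function(nm) array(0, c(canvas_px[2], canvas_px[1], canvas_px[3])))
    names(ch) <- if (length(chan_names)) chan_names else "dapi"
    return(list(channels = ch, centers_px = NULL, calibration = calibration))
  }
  need <- c(ceiling((max(table$x) + margin_um) / psz) + 1L,
            ceiling((max(table$y) + margin_um) / psz) + 1L,
            ceiling((max(table$z) + margin_um) / pz) + 1L)
  if (is.null(canvas_px)) canvas_px <- need
  if (any(canvas_px < need))
    stop("canvas too small for the supplied geometry")
  nx <- canvas_px[1]; ny <- canvas_px[2]; nz <- canvas_px[3]
  sx <- blob_sd_um / psz; sz <- blob_sd_um / pz
  channels <- lapply(chan_names, function(nm) array(0, c(ny, nx, nz)))
  names(channels) <- chan_names
  cx <- table$x / psz; cy <- table$y / psz; cz <- table$z / pz
  w <- ceiling(4 * sx); wz <- ceiling(4 * sz)
  for (i in seq_len(n)) {
    xs <- max(0, floor(cx[i] - w)):min(nx - 1, ceiling(cx[i] + w))
    ys <- max(0, floor(cy[i] - w)):min(ny - 1, ceiling(cy[i] + w))
    zs <- max(0, floor(cz[i] - wz)):min(nz - 1, ceiling(cz[i] + wz))
    gx <- dnorm(xs, cx[i], sx) / dnorm(0, 0, sx)
    gy <- dnorm(ys, cy[i], sx) / dnorm(0, 0, sx)
    gz <- dnorm(zs, cz[i], sz) / dnorm(0, 0, sz)
    blob <- outer(gy, gx) # [y, x]
    for (nm in chan_names) {
      amp <- table[[nm]][i]
      for (j in seq_along(zs))
        channels[[nm]][ys + 1L, xs + 1L, zs[j] + 1L] <-
          channels[[nm]][ys + 1L, xs + 1L, zs[j] + 1L] + amp * blob * gz[j]
    }
  }
  if (is.finite(snr)) {
    set.seed(seed)
    for (nm in chan_names) {
      amp_ref <- max(channels[[nm]])
      read_sd <- amp_ref / snr
      noisy <- rpois(length(channels[[nm]]), lambda = channels[[nm]]) +
        rnorm(length(channels[[nm]]), 0, read_sd)
      channels[[nm]] <- array(pmax(noisy, 0), dim(channels[[nm]]))
    }
  }
  list(channels = channels, centers_px = cbind(x = cx, y = cy, z = cz),
       calibration = calibration)
}
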