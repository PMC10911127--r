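#' Pixel calibration
#'
#' Records the physical size of a pixel so that every raster artifact can be
#' converted to micrometres on read. All downstream geometry is in um; pixel-
#' specified measurement parameters (e.g. the 6-px nuclear circle) are kept in
#' pixels and converted at use time through the calibration.
#'
#' @param xy Pixel size in the imaging plane, um per pixel (> 0).
#' @param z Plane spacing in um (> 0); may be `NULL` for purely 2D artifacts.
#' @return An object of class `pixel_calibration`.
#' @examples
#' cal <- pixel_calibration(0.5, 2)
#' @export
pixel_calibration <- function(xy, z = NULL) {
  if (!is.numeric(xy) || length(xy) != 1L || !is.finite(xy) || xy <= 0)
    stop("pixel_size_xy must be a single positive number")
  if (!is.null(z)) {
    if (!is.numeric(z) || length(z) != 1L || !is.finite(z) || z <= 0)
      stop("pixel_size_z must be a single positive number or NULL")
  }
  structure(list(xy = xy, z = z), class = "pixel_calibration")
}

#' @export
print.pixel_calibration <- function(x, ...) {
  cat(sprintf("pixel calibration: %g um/px (xy)%s\n", x$xy,
              if (is.null(x$z)) "" else sprintf(", %g um/plane (z)", x$z)))
  invisible(x)
}

#' Run configuration
#'
#' Bundles the per-run measurement parameters shared across the pipeline.
#' Defaults follow the explant analysis conventions: 0.04 bin width (0.02 for
#' embryos, about two cell diameters in either case), a 180 um analysis depth
#' for explants (60-120 um from the animal pole for embryos), 12 cytoplasmic
#' background spots, and 6-px nuclear / 4-px cytoplasmic measurement circles.
#'
#' @param analysis_mode `"explant"` or `"embryo"`; selects the bin width and
#'   depth window defaults.
#' @param bin_width Width of the normalized-distance bins, in (0, 0.5].
#' @param depth_limits Two-element um range of analyzed depths.
#' @param background_spot_count Number of cytoplasmic background spots (>= 1).
#' @param nuclear_circle_diameter_px Diameter in pixels of the nuclear
#'   measurement circle (>= 1).
#' @param cytoplasm_circle_diameter_px Diameter in pixels of the cytoplasmic
#'   background circles (>= 1).
#' @param edge_fraction Fraction of the normalized axis excluded at each
#'   sample edge when reporting binned profiles (few nuclei live there owing
#'   to sample curvature).
#' @param seed Integer seed recorded with every artifact this run produces.
#' @return An object of class `run_config`.
#' @examples
#' cfg <- run_config("explant")
#' cfg$bin_width   # 0.04
#' @export
run_config <- function(analysis_mode = c("explant", "embryo"),
                       bin_width = NULL,
                       depth_limits = NULL,
                       background_spot_count = 12L,
                       nuclear_circle_diameter_px = 6L,
                       cytoplasm_circle_diameter_px = 4L,
                       edge_fraction = 0.04,
                       seed = 1L) {
  analysis_mode <- match.arg(analysis_mode)
  bin_width <- bin_width %||% switch(analysis_mode, explant = 0.04, embryo = 0.02)
  depth_limits <- depth_limits %||%
    switch(analysis_mode, explant = c(0, 180), embryo = c(60, 120))
  if (!(bin_width > 0 && bin_width <= 0.5)) stop("bin_width must lie in (0, 0.5]")
  if (length(depth_limits) != 2L || depth_limits[1] > depth_limits[2])
    stop("depth_limits must be an increasing um range")
  counts <- c(background_spot_count, nuclear_circle_diameter_px,
              cytoplasm_circle_diameter_px)
  if (any(counts < 1)) stop("spot counts and circle diameters must be >= 1")
  structure(list(analysis_mode = analysis_mode,
                 bin_width = bin_width,
                 depth_limits = as.numeric(depth_limits),
                 background_spot_count = as.integer(background_spot_count),
                 nuclear_circle_diameter_px = as.integer(nuclear_circle_diameter_px),
                 cytoplasm_circle_diameter_px = as.integer(cytoplasm_circle_diameter_px),
                 edge_fraction = edge_fraction,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("run config (", x$analysis_mode, " mode)\n", sep = "")
  for (k in setdiff(names(x), "analysis_mode"))
    cat(sprintf("  %s = %s\n", k, paste(x[[k]], collapse = ", ")))
  invisible(x)
}

#' Read a run configuration from a flat key-value file
#'
#' The file format is one `key = value` pair per line (TOML-style scalars),
#' `#` comments allowed. Vector values are comma-separated.
#'
#' @param path Path to the configuration file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  args <- list()
  for (i in seq_along(keys)) {
    v <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
    v <- trimws(gsub("\"", "", v))
    num <- suppressWarnings(as.numeric(v))
    args[[keys[i]]] <- if (anyNA(num)) v else num
  }
  do.call(run_config, args)
}

#' Write a run configuration to a flat key-value file
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    v <- if (is.character(v)) sprintf("\"%s\"", v) else
      paste(format(v, digits = 15), collapse = ", ")
    sprintf("%s = %s", k, v)
  }, "")
  writeLines(lines, path)
  invisible(path)
}
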